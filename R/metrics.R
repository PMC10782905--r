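# Evaluation: confusion counts, threshold metrics, ROC/PR curves, amino-acid
# composition and KL divergence.

#' Confusion counts over aligned prediction and label tracks
#'
#' @param pred Named list of per-residue binding probabilities (numeric
#'   vectors or prediction tracks with a \code{p_bind} element).
#' @param truth Named list of 0/1 label tracks covering the same ids.
#' @param threshold Probability cutoff; \code{p >= threshold} is a positive
#'   call.
#' @return List with integer \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion <- function(pred, truth, threshold = 0.5) {
  stopifnot(length(pred) > 0, !is.null(names(pred)))
  missing_ids <- setdiff(names(pred), names(truth))
  if (length(missing_ids) > 0) {
    stop("no label track for id(s): ", paste(missing_ids, collapse = ", "))
  }
  tp <- fp <- tn <- fn <- 0L
  for (id in names(pred)) {
    p <- pred[[id]]
    if (is.list(p)) p <- p$p_bind
    y <- truth[[id]]
    if (length(p) != length(y)) {
      stop("length mismatch for id '", id, "': ", length(p), " predictions vs ",
           length(y), " labels")
    }
    call <- p >= threshold
    tp <- tp + sum(call & y == 1)
    fp <- fp + sum(call & y == 0)
    tn <- tn + sum(!call & y == 0)
    fn <- fn + sum(!call & y == 1)
  }
  list(TP = as.integer(tp), FP = as.integer(fp),
       TN = as.integer(tn), FN = as.integer(fn))
}

#' Threshold-dependent classification metrics
#'
#' Specificity TN/(TN+FP), precision TP/(TP+FP), recall TP/(TP+FN), F1 (the
#' harmonic mean of precision and recall) and the Matthews correlation
#' coefficient. Any metric whose denominator is zero is reported as 0 (and
#' MCC is 0 whenever a factor under its square root vanishes), the usual
#' convention that keeps reports total on degenerate inputs.
#'
#' @param counts Confusion counts, as from [confusion()].
#' @return List with \code{spe}, \code{pre}, \code{rec}, \code{f1},
#'   \code{mcc}.
#' @export
scalar_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * pre * rec, pre + rec)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fn * fp) / sqrt(denom)
  list(spe = spe, pre = pre, rec = rec, f1 = f1, mcc = mcc)
}

#' ROC and precision-recall curves with AUC and AUPR
#'
#' Curves are traced over all distinct score thresholds (ties grouped). The
#' area under the ROC curve uses the trapezoid rule and therefore equals the
#' Mann-Whitney pairwise concordance probability with ties counted one half.
#' The area under the PR curve uses step interpolation (precision held
#' constant between recall levels), which avoids the optimistic bias of
#' linear PR interpolation on imbalanced data.
#'
#' @param scores Numeric vector of predicted binding probabilities or scores.
#' @param truth 0/1 vector of the same length; both classes must occur.
#' @return List with \code{roc} (data.frame fpr/tpr), \code{pr} (data.frame
#'   recall/precision), \code{auc} and \code{aupr}.
#' @export
roc_pr_curves <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to trace ROC/PR curves")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y == 1)[last_of_group]
  cum_fp <- cumsum(y == 0)[last_of_group]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  recall <- cum_tp / n_pos
  precision <- cum_tp / (cum_tp + cum_fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recall, precision = precision),
       auc = auc, aupr = aupr)
}

#' Full evaluation report
#'
#' @param pred Named list of prediction tracks or probability vectors.
#' @param truth Named list of 0/1 label tracks.
#' @param threshold Cutoff for the threshold-dependent metrics.
#' @return A \code{metrics_report}: confusion counts, scalar metrics, ROC/PR
#'   curves, AUC and AUPR.
#' @export
evaluate_predictions <- function(pred, truth, threshold = 0.5) {
  cc <- confusion(pred, truth, threshold)
  sm <- scalar_metrics(cc)
  scores <- unlist(lapply(pred, function(p) if (is.list(p)) p$p_bind else p),
                   use.names = FALSE)
  y <- unlist(truth[names(pred)], use.names = FALSE)
  rp <- roc_pr_curves(scores, y)
  structure(c(list(counts = cc, threshold = threshold), sm, rp),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report @ threshold %.2f\n",
                     "  Spe %.3f  Pre %.3f  Rec %.3f  F1 %.3f  MCC %.3f\n",
                     "  AUC %.3f  AUPR %.3f\n"),
              x$threshold, x$spe, x$pre, x$rec, x$f1, x$mcc, x$auc, x$aupr))
  invisible(x)
}

#' Amino-acid composition of a residue selection
#'
#' Frequency of each of the 20 canonical amino acids among selected residues
#' (e.g. binding-labeled, predicted-binding, or non-binding); \code{'X'}
#' residues are excluded from the tally.
#'
#' @param sequences Named character vector of sequences.
#' @param selection Named list of logical or 0/1 vectors marking the selected
#'   residues of each sequence; default selects everything.
#' @return Named numeric vector over the 20 canonical letters, summing to 1.
#' @export
composition <- function(sequences, selection = NULL) {
  stopifnot(length(sequences) > 0)
  aa <- aa_alphabet(with_x = FALSE)
  tallies <- stats::setNames(numeric(20L), aa)
  for (id in names(sequences)) {
    chars <- strsplit(sequences[[id]], "")[[1]]
    sel <- if (is.null(selection)) rep(TRUE, length(chars))
           else as.logical(selection[[id]])
    if (length(sel) != length(chars)) {
      stop("selection length mismatch for id '", id, "'")
    }
    picked <- chars[sel]
    picked <- picked[picked %in% aa]
    if (length(picked) > 0) {
      tab <- table(factor(picked, levels = aa))
      tallies <- tallies + as.numeric(tab)
    }
  }
  total <- sum(tallies)
  if (total == 0) stop("selection contains no canonical residues")
  tallies / total
}

#' Kullback-Leibler divergence between two composition distributions
#'
#' \eqn{\sum_a p_a \log(p_a / q_a)} in nats, after additive smoothing with
#' \code{eps} and renormalization of both distributions (small selections
#' routinely have empty categories). Non-negative; zero iff p = q; not
#' symmetric, so forward and reverse divergences are reported separately by
#' callers.
#'
#' @param p,q Non-negative numeric vectors of equal length (normalized or
#'   not; they are renormalized after smoothing).
#' @param eps Additive smoothing constant.
#' @return Scalar divergence in nats.
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  if (sum(p) <= 0 || sum(q) <= 0) stop("distributions must have positive mass")
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  sum(p * log(p / q))
}
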