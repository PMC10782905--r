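# Loss algebra: effective-number class weights, class-balanced focal loss,
# triplet center loss with learnable centers, and the joint objective.
#
# Both loss terms are reduced as means over the real (masked-in) residues;
# because the same count divides both, their relative weighting under the
# joint coefficient lambda is identical to the summed form.

P_CLAMP_EPS <- 1e-8

#' Effective number of samples
#'
#' \eqn{E_n = (1 - \beta^n) / (1 - \beta)}, a saturating measure of the
#' coverage provided by n samples of a class; it grows from 1 (n = 1) toward
#' the asymptote \eqn{1/(1-\beta)}. Its reciprocal is the class weight used
#' by the class-balanced focal loss.
#'
#' @param n Sample count(s), >= 1.
#' @param beta Saturation parameter in \[0, 1); default 0.999.
#' @return Effective number(s), same length as \code{n}.
#' @export
effective_number <- function(n, beta = 0.999) {
  if (any(n < 1)) stop("n must be >= 1")
  if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  if (beta == 0) return(rep(1, length(n)) + 0 * n)
  (1 - beta^n) / (1 - beta)
}

#' Class-balance weights from residue counts
#'
#' @param counts Named or ordered numeric vector \code{c(n0, n1)} of
#'   non-binding and binding residue counts in the training set.
#' @param beta Effective-number saturation parameter.
#' @return Length-2 vector of weights \eqn{w_y = 1 / E_{n_y}}.
#' @export
class_weights <- function(counts, beta = 0.999) {
  stopifnot(length(counts) == 2L)
  if (any(counts < 1)) stop("both class counts must be >= 1")
  1 / effective_number(counts, beta)
}

#' Loss hyperparameters
#'
#' Defaults are the operating values of the reference method: \code{beta} =
#' 0.999 (effective number), \code{gamma} = 5 (focal modulation),
#' \code{lambda} = 0.1 (joint weight on the contrastive term), \code{margin}
#' = 9 (triplet hinge, in half-squared-Euclidean distance units of the
#' feature space) and \code{center_lr} = 0.01 (learning rate of the class
#' centers).
#'
#' @param beta Effective-number saturation in \[0, 1).
#' @param gamma Focal exponent >= 0.
#' @param lambda Weight of the triplet center loss in the joint objective.
#' @param margin Triplet hinge margin >= 0.
#' @param center_lr Learning rate for the class centers.
#' @param tcl_feature_layer Backbone layer (1-3) whose output features feed
#'   the triplet center loss; default 3, the penultimate 64-channel layer.
#' @return A \code{loss_config} list.
#' @export
loss_config <- function(beta = 0.999, gamma = 5, lambda = 0.1, margin = 9,
                        center_lr = 0.01, tcl_feature_layer = 3L) {
  if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  if (gamma < 0) stop("gamma must be >= 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (margin < 0) stop("margin must be >= 0")
  if (center_lr <= 0) stop("center_lr must be > 0")
  tcl_feature_layer <- as.integer(tcl_feature_layer)
  if (tcl_feature_layer < 1L || tcl_feature_layer > 3L) {
    stop("tcl_feature_layer must be a hidden layer index (1-3)")
  }
  structure(list(beta = beta, gamma = gamma, lambda = lambda, margin = margin,
                 center_lr = center_lr, tcl_feature_layer = tcl_feature_layer),
            class = "loss_config")
}

#' Class-balanced focal loss
#'
#' Mean over real residues of
#' \eqn{w_{y_i} (1 - p_i)^\gamma (-\log p_i)}, where \eqn{p_i} is the model
#' probability assigned to residue i's true class and \eqn{w_y = 1/E_{n_y}}
#' is the effective-number class weight. The focal modulator
#' \eqn{(1-p)^\gamma} down-weights confidently classified residues; the class
#' weight compensates the ~5-9% positive rate typical of binding-site data.
#'
#' @param p_true Probabilities assigned to the true class, in (0, 1\];
#'   zeros are clamped at 1e-8 with a warning.
#' @param labels 0/1 vector of true classes, same length.
#' @param counts Length-2 vector \code{c(n0, n1)} of training-set class
#'   counts.
#' @param cfg A [loss_config()] (uses \code{beta} and \code{gamma}).
#' @param mask Optional logical vector selecting real residues; default all.
#' @return Non-negative scalar; zero iff every \code{p_true} equals 1.
#' @export
cb_focal_loss <- function(p_true, labels, counts, cfg = loss_config(),
                          mask = NULL) {
  stopifnot(length(p_true) == length(labels))
  if (is.null(mask)) mask <- rep(TRUE, length(p_true))
  p <- p_true[mask]
  y <- labels[mask]
  if (length(p) == 0L) stop("mask selects no residues")
  if (any(p <= 0)) {
    warning("p_true values <= 0 clamped at ", P_CLAMP_EPS)
    p <- pmax(p, P_CLAMP_EPS)
  }
  w <- class_weights(counts, cfg$beta)[y + 1L]
  mean(w * (1 - p)^cfg$gamma * (-log(p)))
}

# gradient of the mean class-balanced focal loss w.r.t. the softmax logits:
# probs is n x 2, labels in {0,1}; rows outside mask get zero gradient
cb_focal_grad_logits <- function(probs, labels, counts, cfg, mask) {
  n <- sum(mask)
  w_all <- class_weights(counts, cfg$beta)
  t_idx <- labels + 1L
  p <- pmax(probs[cbind(seq_len(nrow(probs)), t_idx)], P_CLAMP_EPS)
  g <- cfg$gamma
  # dL_i/dp = w * (gamma (1-p)^(g-1) log p - (1-p)^g / p)
  one_m <- 1 - p
  if (g > 0) {
    mod_term <- g * one_m^(g - 1) * log(p)
    mod_term[one_m == 0] <- 0  # log(p) = 0 there; limit is 0
  } else {
    mod_term <- 0
  }
  dLdp <- w_all[t_idx] * (mod_term - one_m^g / p)
  # dp/dz_k = p (delta_{k,t} - probs_k)
  dlog <- probs * (-dLdp * p)
  dlog[cbind(seq_len(nrow(probs)), t_idx)] <-
    dlog[cbind(seq_len(nrow(probs)), t_idx)] + dLdp * p
  dlog[!mask, ] <- 0
  dlog / n
}

#' Initialize learnable class centers
#'
#' Centers are drawn from a standard normal and updated only by their own
#' optimizer during training.
#'
#' @param k Dimension of the contrastive feature space.
#' @param seed Integer seed.
#' @return 2 x k matrix; row 1 is the non-binding center, row 2 the binding
#'   center.
#' @export
init_centers <- function(k, seed = 0L) {
  with_local_seed(seed, matrix(stats::rnorm(2L * k), nrow = 2L, ncol = k))
}

#' Triplet center loss
#'
#' Mean over real residues of
#' \eqn{\max(D(f_i, c_{y_i}) + m - \min_{j \ne y_i} D(f_i, c_j),\ 0)} with
#' \eqn{D(f, c) = \tfrac12 \lVert f - c \rVert_2^2}: each residue's feature
#' is pulled toward its own learnable class center and pushed at least
#' \code{margin} away (in half-squared-Euclidean distance) from the nearest
#' other-class center. With two classes the min is over the single other
#' center.
#'
#' @param features M x K matrix of per-residue features.
#' @param labels 0/1 vector of length M.
#' @param centers 2 x K center matrix, as from [init_centers()].
#' @param margin Hinge margin m >= 0.
#' @param mask Optional logical vector selecting real residues; default all.
#' @return Non-negative scalar.
#' @export
triplet_center_loss <- function(features, labels, centers, margin,
                                mask = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            ncol(features) == ncol(centers), nrow(centers) == 2L)
  if (is.null(mask)) mask <- rep(TRUE, nrow(features))
  if (sum(mask) == 0L) stop("mask selects no residues")
  f <- features[mask, , drop = FALSE]
  y <- labels[mask]
  own <- centers[y + 1L, , drop = FALSE]
  oth <- centers[2L - y, , drop = FALSE]
  d_own <- 0.5 * rowSums((f - own)^2)
  d_oth <- 0.5 * rowSums((f - oth)^2)
  mean(pmax(d_own + margin - d_oth, 0))
}

# gradients of the mean TCL w.r.t. features (n x K, zero on masked-out rows)
# and w.r.t. the centers (2 x K)
tcl_grads <- function(features, labels, centers, margin, mask) {
  n <- sum(mask)
  own_idx <- labels + 1L
  own <- centers[own_idx, , drop = FALSE]
  oth <- centers[3L - own_idx, , drop = FALSE]
  d_own <- 0.5 * rowSums((features - own)^2)
  d_oth <- 0.5 * rowSums((features - oth)^2)
  active <- (d_own + margin - d_oth > 0) & mask
  dfeat <- matrix(0, nrow(features), ncol(features))
  dcent <- matrix(0, 2L, ncol(features))
  if (any(active)) {
    # d/df [D_own - D_oth] = (f - c_own) - (f - c_oth) = c_oth - c_own
    dfeat[active, ] <- (oth - own)[active, , drop = FALSE] / n
    for (cl in 1L:2L) {
      sel_own <- active & own_idx == cl
      sel_oth <- active & own_idx == (3L - cl)
      if (any(sel_own)) {
        dcent[cl, ] <- dcent[cl, ] -
          colSums(features[sel_own, , drop = FALSE] -
                    matrix(centers[cl, ], sum(sel_own), ncol(features),
                           byrow = TRUE)) / n
      }
      if (any(sel_oth)) {
        dcent[cl, ] <- dcent[cl, ] +
          colSums(features[sel_oth, , drop = FALSE] -
                    matrix(centers[cl, ], sum(sel_oth), ncol(features),
                           byrow = TRUE)) / n
      }
    }
  }
  list(dfeat = dfeat, dcenters = dcent)
}

#' Joint training objective
#'
#' \eqn{L = L_{focal} + \lambda L_{tc}}; \code{lambda = 0} recovers the pure
#' classification loss.
#'
#' @param focal Class-balanced focal loss value.
#' @param tcl Triplet center loss value.
#' @param lambda Non-negative weight of the contrastive term.
#' @return Scalar joint loss.
#' @export
joint_loss <- function(focal, tcl, lambda) {
  stopifnot(is.finite(focal), is.finite(tcl), lambda >= 0)
  focal + lambda * tcl
}
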