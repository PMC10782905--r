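# Joint training of the backbone and the class centers.
#
# Two optimizer groups: Adam on the convolutional parameters at model_lr, and
# plain gradient descent on the class centers at center_lr (the centers
# appear only in the triplet-center term, and follow its unweighted
# gradient, the usual center-loss convention). Embeddings are inputs, never
# parameters: no gradient ever reaches them.

ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8

#' Training configuration
#'
#' @param model_lr Learning rate of the backbone optimizer.
#' @param epochs Number of passes over the training sequences.
#' @param batch_size Sequences per batch.
#' @param seed Integer seed governing weight initialization, shuffling,
#'   dropout and the validation split.
#' @param threshold Probability cutoff for binary calls; default 0.5.
#' @param val_fraction Fraction of training sequences held out (by seeded
#'   shuffle) for per-epoch validation AUC/AUPR; when positive, the returned
#'   model carries the weights of the epoch with the best validation AUC
#'   (early stopping by snapshot). 0 disables validation.
#' @param weight_decay Decoupled weight decay applied to convolution weights
#'   (not biases or batch-norm parameters) each optimizer step.
#' @param lr_schedule \code{"cosine"} (default) anneals the backbone
#'   learning rate from \code{model_lr} to 5\% of it over the epochs, the
#'   usual way to let Adam settle into a flat optimum; \code{"constant"}
#'   keeps it fixed.
#' @param early_stop_metric Validation metric used to pick the snapshot
#'   epoch when \code{val_fraction > 0}: \code{"auc"} (default) or
#'   \code{"aupr"}.
#' @return A \code{train_config} list.
#' @export
train_config <- function(model_lr = 3e-3, epochs = 50L, batch_size = 16L,
                         seed = 1L, threshold = 0.5, val_fraction = 0.1,
                         weight_decay = 1e-3,
                         lr_schedule = c("cosine", "constant"),
                         early_stop_metric = c("auc", "aupr")) {
  lr_schedule <- match.arg(lr_schedule)
  early_stop_metric <- match.arg(early_stop_metric)
  stopifnot(model_lr > 0, epochs >= 1, batch_size >= 1,
            threshold >= 0, threshold <= 1,
            val_fraction >= 0, val_fraction < 1, weight_decay >= 0)
  structure(list(model_lr = model_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 threshold = threshold, val_fraction = val_fraction,
                 weight_decay = weight_decay, lr_schedule = lr_schedule,
                 early_stop_metric = early_stop_metric),
            class = "train_config")
}

# per-epoch learning rate under the configured schedule
epoch_lr <- function(cfg, epoch) {
  if (cfg$lr_schedule == "constant" || cfg$epochs == 1L) return(cfg$model_lr)
  frac <- (epoch - 1) / (cfg$epochs - 1)
  floor_lr <- 0.05 * cfg$model_lr
  floor_lr + (cfg$model_lr - floor_lr) * 0.5 * (1 + cos(pi * frac))
}

adam_init <- function(layers) {
  lapply(layers, function(lay) {
    lapply(lay[intersect(names(lay), c("W", "b", "gamma", "beta"))],
           function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, lr, t, weight_decay = 0) {
  corr1 <- 1 - ADAM_BETA1^t
  corr2 <- 1 - ADAM_BETA2^t
  for (l in seq_along(layers)) {
    for (nm in names(state[[l]])) {
      g <- grads[[l]][[nm]]
      st <- state[[l]][[nm]]
      st$m <- ADAM_BETA1 * st$m + (1 - ADAM_BETA1) * g
      st$v <- ADAM_BETA2 * st$v + (1 - ADAM_BETA2) * g^2
      state[[l]][[nm]] <- st
      step <- lr * (st$m / corr1) / (sqrt(st$v / corr2) + ADAM_EPS)
      if (nm == "W" && weight_decay > 0) {
        step <- step + lr * weight_decay * layers[[l]][[nm]]
      }
      layers[[l]][[nm]] <- layers[[l]][[nm]] - step
    }
  }
  list(layers = layers, state = state)
}

#' Train a binding-site model
#'
#' Optimizes the joint objective (class-balanced focal loss plus
#' \code{lambda} times the triplet center loss) over per-residue embeddings.
#' Class counts for the effective-number weights are the global counts of
#' the training label tracks. Fully reproducible from the configs and seed.
#'
#' @param ds A [labeled_dataset()].
#' @param embeddings Named list of L x D matrices covering every id in
#'   \code{ds} (e.g. from [embed_dataset()] or [load_embeddings()]).
#' @param backbone_cfg A [backbone_config()]; its \code{input_dim} must match
#'   the embeddings.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return A \code{binding_model}: backbone parameters, centers, configs,
#'   class counts and a per-epoch log (data.frame with focal, tcl and joint
#'   loss, plus validation AUC/AUPR when a split is requested).
#' @export
train_binding_model <- function(ds, embeddings,
                                backbone_cfg = NULL,
                                loss_cfg = loss_config(),
                                train_cfg = train_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  ids <- names(ds$sequences)
  missing_ids <- setdiff(ids, names(embeddings))
  if (length(missing_ids) > 0) {
    stop("missing embedding for id(s): ", paste(missing_ids, collapse = ", "))
  }
  dim_in <- ncol(embeddings[[ids[1L]]])
  if (is.null(backbone_cfg)) backbone_cfg <- backbone_config(input_dim = dim_in)
  if (backbone_cfg$input_dim != dim_in) {
    stop("backbone input_dim ", backbone_cfg$input_dim,
         " does not match embedding dimension ", dim_in)
  }
  for (id in ids) {
    if (nrow(embeddings[[id]]) != length(ds$labels[[id]])) {
      stop("embedding rows and label length differ for id '", id, "'")
    }
  }

  set.seed(train_cfg$seed)
  # validation split by seeded shuffle
  val_ids <- character(0)
  train_ids <- ids
  if (train_cfg$val_fraction > 0 && length(ids) >= 2L) {
    shuffled <- sample(ids)
    n_val <- max(1L, floor(train_cfg$val_fraction * length(ids)))
    val_ids <- shuffled[seq_len(n_val)]
    train_ids <- setdiff(shuffled, val_ids)
  }

  counts <- c(
    n0 = sum(vapply(ds$labels[train_ids], function(x) sum(x == 0), numeric(1))),
    n1 = sum(vapply(ds$labels[train_ids], sum, numeric(1))))
  if (any(counts < 1)) stop("training split must contain both classes")

  model <- init_backbone(backbone_cfg, seed = train_cfg$seed)
  tcl_layer <- loss_cfg$tcl_feature_layer
  k_feat <- backbone_cfg$layer_dims[tcl_layer]
  centers <- init_centers(k_feat, seed = train_cfg$seed + 1L)
  opt <- adam_init(model$layers)
  step <- 0L
  best_val_score <- -Inf
  best_snapshot <- NULL

  log_rows <- vector("list", train_cfg$epochs)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr_now <- epoch_lr(train_cfg, epoch)
    order_ids <- sample(train_ids)
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / train_cfg$batch_size))
    ep_focal <- ep_tcl <- ep_joint <- numeric(length(batches))
    ep_n <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      bids <- batches[[bi]]
      bt <- batchify(embeddings[bids])
      # labels flattened in the same (B, L) column-major order as the batch
      B <- length(bids); Lmax <- max(bt$lengths)
      ymat <- matrix(0L, B, Lmax)
      for (i in seq_len(B)) ymat[i, seq_len(bt$lengths[i])] <- ds$labels[[bids[i]]]
      yvec <- as.integer(ymat)
      mvec <- as.logical(bt$mask)

      fwd <- nn_forward(model, bt$x, bt$mask, training = TRUE)
      model <- fwd$model  # batch-norm running stats updated
      probs <- fwd$probs
      p_true <- probs[cbind(seq_along(yvec), yvec + 1L)]
      focal <- cb_focal_loss(p_true, yvec, counts, loss_cfg, mask = mvec)
      feats <- fwd$features[[tcl_layer]]
      tcl <- triplet_center_loss(feats, yvec, centers, loss_cfg$margin,
                                 mask = mvec)
      dlogits <- cb_focal_grad_logits(probs, yvec, counts, loss_cfg, mvec)
      extra <- vector("list", 3L)
      tg <- tcl_grads(feats, yvec, centers, loss_cfg$margin, mvec)
      if (loss_cfg$lambda > 0) {
        extra[[tcl_layer]] <- loss_cfg$lambda * tg$dfeat
      }
      grads <- nn_backward(model, fwd, dlogits, extra)
      step <- step + 1L
      upd <- adam_step(model$layers, grads, opt, lr_now, step,
                       train_cfg$weight_decay)
      model$layers <- upd$layers
      opt <- upd$state
      centers <- centers - loss_cfg$center_lr * tg$dcenters

      ep_focal[bi] <- focal; ep_tcl[bi] <- tcl
      ep_joint[bi] <- joint_loss(focal, tcl, loss_cfg$lambda)
      ep_n[bi] <- sum(mvec)
    }
    row <- data.frame(epoch = epoch,
                      focal = stats::weighted.mean(ep_focal, ep_n),
                      tcl = stats::weighted.mean(ep_tcl, ep_n),
                      joint = stats::weighted.mean(ep_joint, ep_n),
                      val_auc = NA_real_, val_aupr = NA_real_)
    if (length(val_ids) > 0) {
      # batch-norm statistics are re-estimated under eval conditions before
      # every validation pass, so model selection sees eval-mode behavior;
      # a fixed subsample keeps the per-epoch cost low (the final model is
      # recalibrated on the full training set below)
      recal_ids <- train_ids[seq_len(min(32L, length(train_ids)))]
      eval_model <- recalibrate_bn(model, embeddings[recal_ids],
                                   train_cfg$batch_size)
      preds <- predict_scores(eval_model, embeddings[val_ids])
      scores <- unlist(preds, use.names = FALSE)
      truth <- unlist(ds$labels[val_ids], use.names = FALSE)
      if (length(unique(truth)) == 2L) {
        rp <- roc_pr_curves(scores, truth)
        row$val_auc <- rp$auc
        row$val_aupr <- rp$aupr
        score_now <- if (train_cfg$early_stop_metric == "aupr") rp$aupr
                     else rp$auc
        if (score_now > best_val_score) {
          best_val_score <- score_now
          best_snapshot <- list(model = eval_model, centers = centers,
                                epoch = epoch)
        }
      }
    }
    log_rows[[epoch]] <- row
  }

  best_epoch <- train_cfg$epochs
  if (!is.null(best_snapshot)) {
    model <- best_snapshot$model
    centers <- best_snapshot$centers
    best_epoch <- best_snapshot$epoch
  }
  model <- recalibrate_bn(model, embeddings[train_ids], train_cfg$batch_size)

  structure(list(model = model, centers = centers, best_epoch = best_epoch,
                 backbone_cfg = backbone_cfg, loss_cfg = loss_cfg,
                 train_cfg = train_cfg, class_counts = counts,
                 train_ids = train_ids, val_ids = val_ids,
                 log = do.call(rbind, log_rows)),
            class = "binding_model")
}

# eval-mode binding probabilities for a named list of embeddings
predict_scores <- function(model, embeddings) {
  res <- backbone_forward(model, embeddings, mode = "eval")
  out <- lapply(res, `[[`, "p_bind")
  names(out) <- names(embeddings)
  out
}

#' Predict binding residues
#'
#' @param fit A \code{binding_model} from [train_binding_model()].
#' @param embeddings Named list of L x D embedding matrices.
#' @param threshold Probability cutoff for binary calls; defaults to the
#'   training configuration's threshold.
#' @return Named list of prediction tracks, each a list with \code{p_bind}
#'   (per-residue binding probability) and \code{calls} (0/1 at the
#'   threshold; \code{p_bind >= threshold} is a call, so threshold 0 calls
#'   every residue and threshold 1 only residues with probability 1).
#' @export
predict_binding <- function(fit, embeddings, threshold = NULL) {
  stopifnot(inherits(fit, "binding_model"))
  if (is.null(threshold)) threshold <- fit$train_cfg$threshold
  bad <- vapply(embeddings, ncol, integer(1)) != fit$backbone_cfg$input_dim
  if (any(bad)) {
    stop("embedding dimension mismatch for id(s): ",
         paste(names(embeddings)[bad], collapse = ", "),
         " (model expects ", fit$backbone_cfg$input_dim, ")")
  }
  scores <- predict_scores(fit$model, embeddings)
  out <- lapply(scores, function(p) {
    calls <- as.integer(if (threshold <= 0) rep(TRUE, length(p))
                        else if (threshold >= 1) p >= 1
                        else p >= threshold)
    list(p_bind = p, calls = calls)
  })
  names(out) <- names(embeddings)
  out
}

#' Save / load a trained binding model
#'
#' Checkpoints are RDS containers holding weights, centers, all configs and
#' the training log.
#'
#' @param fit A \code{binding_model}.
#' @param path Checkpoint path.
#' @return \code{save_binding_model}: invisibly, \code{path};
#'   \code{load_binding_model}: the restored \code{binding_model}.
#' @export
save_binding_model <- function(fit, path) {
  stopifnot(inherits(fit, "binding_model"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_binding_model
#' @export
load_binding_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "binding_model")) stop("not a binding model checkpoint: ", path)
  fit
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("binding_model: %d-dim input, %d epochs, final joint loss %.4f\n",
              x$backbone_cfg$input_dim, nrow(x$log), x$log$joint[nrow(x$log)]))
  invisible(x)
}
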