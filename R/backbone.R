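# Four-layer 1D convolutional per-residue classifier.
#
# Implemented directly on base-R arrays: convolutions are im2col + matrix
# multiply, so the heavy lifting is a handful of BLAS calls per batch. The
# backward pass is written out explicitly; a finite-difference check in the
# test suite guards every gradient path.
#
# Array convention: a batch is [B, L, C] (sequence, position, channel); the
# matching 2-D view is matrix(x, B*L, C) (column-major, so (b, l) pairs run
# fastest). Padded positions are zeroed before every convolution and excluded
# from batch-norm statistics, losses and metrics, so padding content can
# never leak into real positions.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Configure the convolutional backbone
#'
#' Four 1-D convolutional layers with stride 1 and same-length padding, each
#' of the first three followed by batch normalization, ReLU and dropout; the
#' final 2-channel layer feeds a softmax head. With 1024-dim language-model
#' embeddings the output channels are 1024, 128, 64 and 2; for other input
#' dimensions (e.g. compact synthetic embeddings) the channel ladder scales
#' down proportionally by default.
#'
#' @param input_dim Embedding dimension of the input (rows are residues).
#' @param layer_dims Output channels of the four layers; last must be 2.
#' @param kernel_sizes Odd kernel sizes, one per layer.
#' @param dropout Dropout rate in \[0, 1) applied after each hidden layer
#'   during training; the fairly strong default (0.6) counteracts the
#'   tendency of the small network to memorize individual residues of
#'   heavily imbalanced training sets.
#' @param batchnorm Apply batch normalization after each hidden convolution.
#' @return A \code{backbone_config} list.
#' @export
backbone_config <- function(input_dim = 1024L, layer_dims = NULL,
                            kernel_sizes = c(7L, 5L, 3L, 3L),
                            dropout = 0.6, batchnorm = TRUE) {
  input_dim <- as.integer(input_dim)
  if (is.null(layer_dims)) {
    layer_dims <- if (input_dim == 1024L) c(1024L, 128L, 64L, 2L)
                  else c(2L * input_dim, input_dim, max(4L, input_dim %/% 2L), 2L)
  }
  layer_dims <- as.integer(layer_dims)
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(layer_dims) != 4L) stop("exactly four layers are required")
  if (layer_dims[4L] != 2L) stop("the final layer must have 2 output channels")
  if (length(kernel_sizes) != 4L) stop("one kernel size per layer is required")
  if (any(kernel_sizes %% 2L == 0L) || any(kernel_sizes < 1L)) {
    stop("kernel sizes must be odd and positive (same-length padding)")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(input_dim = input_dim, layer_dims = layer_dims,
                 kernel_sizes = kernel_sizes, stride = 1L,
                 dropout = dropout, batchnorm = isTRUE(batchnorm)),
            class = "backbone_config")
}

#' Initialize backbone parameters
#'
#' He-style initialization for the convolution weights; batch-norm scales
#' start at 1 and shifts at 0.
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed for the weight draw.
#' @return A \code{backbone_model}: the config plus a list of per-layer
#'   parameter sets.
#' @export
init_backbone <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "backbone_config"))
  in_ch <- c(cfg$input_dim, cfg$layer_dims[-4L])
  layers <- with_local_seed(seed, lapply(seq_len(4L), function(l) {
    fan_in <- in_ch[l] * cfg$kernel_sizes[l]
    out <- cfg$layer_dims[l]
    lay <- list(
      W = matrix(stats::rnorm(fan_in * out, sd = sqrt(2 / fan_in)),
                 nrow = fan_in, ncol = out),
      b = numeric(out))
    if (cfg$batchnorm && l < 4L) {
      lay$gamma <- rep(1, out)
      lay$beta <- numeric(out)
      lay$run_mean <- numeric(out)
      lay$run_var <- rep(1, out)
    }
    lay
  }))
  structure(list(cfg = cfg, layers = layers), class = "backbone_model")
}

#' Pad a list of embedding matrices into a batch tensor with a mask
#'
#' @param mats Non-empty list of L_i x C matrices.
#' @return List with \code{x} (\[B, Lmax, C\] array, zero padded),
#'   \code{mask} (B x Lmax logical, TRUE on real residues) and
#'   \code{lengths}.
#' @export
batchify <- function(mats) {
  stopifnot(is.list(mats), length(mats) > 0)
  lens <- vapply(mats, nrow, integer(1))
  C <- ncol(mats[[1L]])
  stopifnot(all(vapply(mats, ncol, integer(1)) == C))
  B <- length(mats)
  Lmax <- max(lens)
  x <- array(0, dim = c(B, Lmax, C))
  mask <- matrix(FALSE, B, Lmax)
  for (i in seq_len(B)) {
    x[i, seq_len(lens[i]), ] <- mats[[i]]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  list(x = x, mask = mask, lengths = lens)
}

# Internally a batch lives as a flat (B*L) x C matrix whose rows are (b, l)
# pairs with b running fastest (the column-major flattening of [B, L, C]).
# Shifting along the sequence by `off` positions is then a row-index shift
# of off * B, which makes the convolution gather a single subscript copy
# per kernel offset instead of repeated array reshapes.

# im2col on the flat form: (B*L) x C -> (B*L) x (C*k), zero outside bounds
im2col <- function(M, B, L, k) {
  C <- ncol(M)
  h <- (k - 1L) %/% 2L
  n <- B * L
  pos <- rep(seq_len(L), each = B)  # sequence position of each row
  out <- matrix(0, n, C * k)
  for (j in seq_len(k)) {
    off <- j - 1L - h
    ok <- which(pos + off >= 1L & pos + off <= L)
    out[ok, ((j - 1L) * C + 1L):(j * C)] <- M[ok + off * B, , drop = FALSE]
  }
  out
}

# adjoint of im2col: (B*L) x (C*k) -> (B*L) x C
col2im <- function(dcol, B, L, C, k) {
  h <- (k - 1L) %/% 2L
  n <- B * L
  pos <- rep(seq_len(L), each = B)
  dM <- matrix(0, n, C)
  for (j in seq_len(k)) {
    off <- j - 1L - h
    ok <- pos + off >= 1L & pos + off <= L
    idx <- which(ok) + off * B
    dM[idx, ] <- dM[idx, , drop = FALSE] +
      dcol[ok, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dM
}

row_softmax <- function(z) {
  if (ncol(z) == 2L) {
    m <- pmax(z[, 1L], z[, 2L])
    e1 <- exp(z[, 1L] - m)
    e2 <- exp(z[, 2L] - m)
    s <- e1 + e2
    return(cbind(e1 / s, e2 / s))
  }
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# add a per-column constant / scale rows without sweep() overhead
add_cols <- function(M, v) M + rep(v, each = nrow(M))
mul_cols <- function(M, v) M * rep(v, each = nrow(M))

# full forward pass; training = TRUE draws dropout masks from the current RNG
# and updates batch-norm running statistics in the returned model.
# x may be the [B, L, C] array from batchify() or the flat (B*L) x C matrix.
nn_forward <- function(model, x, mask, training = FALSE) {
  cfg <- model$cfg
  B <- nrow(mask); L <- ncol(mask)
  mvec <- as.logical(mask)
  mnum <- as.numeric(mvec)
  n_real <- sum(mvec)
  caches <- vector("list", 4L)
  feats <- vector("list", 4L)
  h <- if (is.matrix(x)) x else matrix(x, B * L, dim(x)[3L])
  for (l in seq_len(4L)) {
    lay <- model$layers[[l]]
    k <- cfg$kernel_sizes[l]
    C_in <- if (l == 1L) cfg$input_dim else cfg$layer_dims[l - 1L]
    X2 <- im2col(h * mnum, B, L, k)
    Z <- add_cols(X2 %*% lay$W, lay$b)
    cache <- list(X2 = X2, C_in = C_in, k = k)
    if (l < 4L) {
      A <- Z
      if (cfg$batchnorm) {
        if (training) {
          mu <- colSums(A[mvec, , drop = FALSE]) / n_real
          Ac <- add_cols(A, -mu)
          va <- colSums(Ac[mvec, , drop = FALSE]^2) / n_real
          model$layers[[l]]$run_mean <-
            (1 - BN_MOMENTUM) * lay$run_mean + BN_MOMENTUM * mu
          model$layers[[l]]$run_var <-
            (1 - BN_MOMENTUM) * lay$run_var + BN_MOMENTUM * va
        } else {
          mu <- lay$run_mean
          va <- lay$run_var
          Ac <- add_cols(A, -mu)
        }
        inv_sd <- 1 / sqrt(va + BN_EPS)
        xhat <- mul_cols(Ac, inv_sd)
        A <- add_cols(mul_cols(xhat, lay$gamma), lay$beta)
        cache$xhat <- xhat
        cache$inv_sd <- inv_sd
        cache$n_real <- n_real
      }
      relu_mask <- A > 0
      A <- A * relu_mask
      cache$relu_mask <- relu_mask
      if (training && cfg$dropout > 0) {
        keep <- matrix(stats::runif(length(A)) >= cfg$dropout,
                       nrow = nrow(A))
        A <- A * keep / (1 - cfg$dropout)
        cache$drop_keep <- keep
      }
      h <- A
      feats[[l]] <- h
    } else {
      probs <- row_softmax(Z)
      cache$probs <- probs
      h <- Z
      feats[[l]] <- probs
    }
    caches[[l]] <- cache
  }
  list(model = model, probs = caches[[4L]]$probs,
       features = feats, caches = caches, mask = mask, B = B, L = L)
}

# backward pass from d(loss)/d(logits) of the final layer, plus optional
# extra gradients injected at hidden-layer outputs (used by the triplet
# center loss); returns per-layer parameter gradients
nn_backward <- function(model, fwd, dlogits, extra_feature_grads = NULL) {
  cfg <- model$cfg
  B <- fwd$B; L <- fwd$L
  grads <- vector("list", 4L)
  dA <- dlogits  # (B*L) x 2 at layer 4 pre-softmax handled by caller
  for (l in 4L:1L) {
    cache <- fwd$caches[[l]]
    lay <- model$layers[[l]]
    if (l < 4L) {
      if (!is.null(extra_feature_grads[[l]])) {
        dA <- dA + extra_feature_grads[[l]]
      }
      if (!is.null(cache$drop_keep)) {
        dA <- dA * cache$drop_keep / (1 - cfg$dropout)
      }
      dA <- dA * cache$relu_mask
      if (cfg$batchnorm) {
        mvec <- as.logical(fwd$mask)
        n <- cache$n_real
        dA[!mvec, ] <- 0  # padded rows carry no gradient
        g_grad <- colSums(dA * cache$xhat)
        b_grad <- colSums(dA)
        dxhat <- mul_cols(dA, lay$gamma)
        sum_dxhat <- colSums(dxhat[mvec, , drop = FALSE])
        sum_dxhat_xhat <- colSums((dxhat * cache$xhat)[mvec, , drop = FALSE])
        dZ <- add_cols(dxhat, -sum_dxhat / n) -
          mul_cols(cache$xhat, sum_dxhat_xhat / n)
        dZ <- mul_cols(dZ, cache$inv_sd)
        dZ[!mvec, ] <- 0
        grads[[l]] <- list(W = crossprod(cache$X2, dZ), b = colSums(dZ),
                           gamma = g_grad, beta = b_grad)
      } else {
        dZ <- dA
        grads[[l]] <- list(W = crossprod(cache$X2, dZ), b = colSums(dZ))
      }
    } else {
      dZ <- dA
      grads[[l]] <- list(W = crossprod(cache$X2, dZ), b = colSums(dZ))
    }
    if (l > 1L) {
      dX2 <- dZ %*% t(lay$W)
      dA <- col2im(dX2, B, L, cache$C_in, cache$k) *
        as.numeric(as.logical(fwd$mask))
    }
  }
  grads
}

# Re-estimate batch-norm population statistics under eval conditions
# (dropout off, earlier layers already recalibrated). Training collects
# running statistics with dropout active, which shifts the activation
# variance relative to eval mode; recalibrating layer by layer over the
# training embeddings removes that shift. Three forward sweeps, exact.
recalibrate_bn <- function(model, mats, batch_size = 16L) {
  cfg <- model$cfg
  if (!cfg$batchnorm) return(model)
  batches <- split(seq_along(mats),
                   ceiling(seq_along(mats) / batch_size))
  for (l in 1L:3L) {
    s <- s2 <- numeric(cfg$layer_dims[l])
    n <- 0
    for (bidx in batches) {
      bt <- batchify(mats[bidx])
      B <- nrow(bt$mask); L <- ncol(bt$mask)
      mnum <- as.numeric(as.logical(bt$mask))
      h <- matrix(bt$x, B * L, dim(bt$x)[3L])
      for (j in seq_len(l)) {
        lay <- model$layers[[j]]
        X2 <- im2col(h * mnum, B, L, cfg$kernel_sizes[j])
        Z <- add_cols(X2 %*% lay$W, lay$b)
        if (j == l) {
          Zm <- Z[mnum > 0, , drop = FALSE]
          s <- s + colSums(Zm)
          s2 <- s2 + colSums(Zm^2)
          n <- n + nrow(Zm)
        } else {
          xhat <- mul_cols(add_cols(Z, -lay$run_mean),
                           1 / sqrt(lay$run_var + BN_EPS))
          A <- add_cols(mul_cols(xhat, lay$gamma), lay$beta)
          A[A < 0] <- 0
          h <- A
        }
      }
    }
    mu <- s / n
    model$layers[[l]]$run_mean <- mu
    model$layers[[l]]$run_var <- pmax(s2 / n - mu^2, 0)
  }
  model
}

#' Run the backbone forward on one or more embedding matrices
#'
#' @param model A \code{backbone_model}.
#' @param emb A single L x D matrix or a list of them.
#' @param mode \code{"eval"} (dropout off, batch-norm running statistics) or
#'   \code{"train"}.
#' @return For a single matrix: list with \code{p_bind} (length-L vector of
#'   binding probabilities), \code{probs} (L x 2 matrix) and \code{features}
#'   (per-layer L x C matrices). For a list: a list of such results, one per
#'   sequence.
#' @export
backbone_forward <- function(model, emb, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "backbone_model"))
  single <- is.matrix(emb)
  mats <- if (single) list(emb) else emb
  if (any(vapply(mats, ncol, integer(1)) != model$cfg$input_dim)) {
    stop("embedding dimension does not match backbone input_dim = ",
         model$cfg$input_dim)
  }
  bt <- batchify(mats)
  fwd <- nn_forward(model, bt$x, bt$mask, training = (mode == "train"))
  out <- lapply(seq_along(mats), function(i) {
    Li <- bt$lengths[i]
    idx <- (seq_len(Li) - 1L) * length(mats) + i  # rows of sequence i
    feats <- lapply(fwd$features, function(f) f[idx, , drop = FALSE])
    probs <- fwd$probs[idx, , drop = FALSE]
    list(p_bind = probs[, 2L], probs = probs, features = feats)
  })
  if (single) out[[1L]] else out
}
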