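# Loop-based oracles, kept deliberately naive and independent of the
# vectorized implementations they check.

focal_loss_oracle <- function(p_true, labels, counts, beta, gamma) {
  total <- 0
  for (i in seq_along(p_true)) {
    n_y <- counts[labels[i] + 1L]
    w <- (1 - beta) / (1 - beta^n_y)
    if (beta == 0) w <- 1
    total <- total + w * (1 - p_true[i])^gamma * (-log(p_true[i]))
  }
  total / length(p_true)
}

tcl_oracle <- function(features, labels, centers, margin) {
  total <- 0
  for (i in seq_len(nrow(features))) {
    own <- centers[labels[i] + 1L, ]
    other <- centers[2L - labels[i], ]
    d_own <- 0.5 * sum((features[i, ] - own)^2)
    d_other <- 0.5 * sum((features[i, ] - other)^2)
    total <- total + max(d_own + margin - d_other, 0)
  }
  total / nrow(features)
}

test_that("effective_number matches closed form, limits and brute-force summation", {
  expect_equal(effective_number(1, 0.999), 1)
  expect_equal(effective_number(2, 0.5), 1.5)
  # geometric-series oracle: E_n = sum_{k=0}^{n-1} beta^k
  for (n in c(1, 3, 10, 250)) {
    expect_equal(effective_number(n, 0.99), sum(0.99^(0:(n - 1))),
                 tolerance = 1e-10)
  }
  expect_equal(effective_number(1e6, 0.999), 1 / (1 - 0.999),
               tolerance = 1e-6)
  expect_error(effective_number(5, 1), "beta")
  expect_error(effective_number(0, 0.5), "n must")
  # strictly increasing in n, bounded by 1/(1-beta)
  en <- effective_number(1:100, 0.9)
  expect_true(all(diff(en) > 0))
  expect_true(all(en <= 1 / (1 - 0.9)))
})

test_that("class weights favor the minority class", {
  w <- class_weights(c(1000, 50), beta = 0.999)
  expect_gt(w[2], w[1])
  expect_equal(unname(class_weights(c(1000, 50), beta = 0)), c(1, 1))
})

test_that("cb_focal_loss agrees with the per-residue loop oracle", {
  # worked example: 3 residues
  cfg <- loss_config(beta = 0.9, gamma = 2)
  val <- cb_focal_loss(c(0.6, 0.9, 0.4), c(1, 0, 0), counts = c(2, 1), cfg)
  expect_equal(val, focal_loss_oracle(c(0.6, 0.9, 0.4), c(1, 0, 0),
                                      c(2, 1), 0.9, 2), tolerance = 1e-10)
  # randomized batches
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    p <- runif(n, 0.01, 1)
    y <- rbinom(n, 1, 0.3)
    counts <- c(sample(1:500, 1), sample(1:500, 1))
    beta <- sample(c(0, 0.5, 0.9, 0.999), 1)
    gamma <- sample(c(0, 1, 2, 5), 1)
    cfg <- loss_config(beta = beta, gamma = gamma)
    expect_equal(cb_focal_loss(p, y, counts, cfg),
                 focal_loss_oracle(p, y, counts, beta, gamma),
                 tolerance = 1e-10)
  }
})

test_that("focal loss analytic limits hold", {
  set.seed(15)
  p <- runif(50, 0.05, 1)
  y <- rbinom(50, 1, 0.5)
  # gamma = 0, beta = 0 collapses to mean cross-entropy
  cfg <- loss_config(beta = 0, gamma = 0)
  expect_equal(cb_focal_loss(p, y, c(30, 20), cfg), mean(-log(p)),
               tolerance = 1e-12)
  # perfect predictions give exactly zero
  expect_equal(cb_focal_loss(rep(1, 10), rbinom(10, 1, 0.5), c(5, 5),
                             loss_config()), 0)
  # zero probabilities are clamped with a warning
  expect_warning(v <- cb_focal_loss(c(0, 0.5), c(1, 0), c(1, 1),
                                    loss_config(beta = 0, gamma = 0)),
                 "clamped")
  expect_true(is.finite(v))
})

test_that("cb_focal_loss is non-increasing in each p_true", {
  set.seed(16)
  cfg <- loss_config()
  p <- runif(10, 0.1, 0.9)
  y <- rbinom(10, 1, 0.3)
  base <- cb_focal_loss(p, y, c(7, 3), cfg)
  for (i in seq_along(p)) {
    p2 <- p
    p2[i] <- min(1, p[i] + 0.05)
    expect_lte(cb_focal_loss(p2, y, c(7, 3), cfg), base + 1e-12)
  }
})

test_that("triplet_center_loss matches hinge arithmetic and the loop oracle", {
  centers <- rbind(c(0, 0), c(4, 0))
  # features exactly at their centers, inter-center gap exceeds margin
  f <- centers[c(1, 2, 1), ]
  expect_equal(triplet_center_loss(f, c(0, 1, 0), centers, margin = 3), 0)
  # single sample at (2,0): own center at origin gives D = 2; other center
  # sqrt(8) away gives D = 4; hinge = max(2 + 3 - 4, 0) = 1
  f1 <- matrix(c(2, 0), nrow = 1)
  cen <- rbind(c(0, 0), c(2, sqrt(8)))
  expect_equal(triplet_center_loss(f1, 0L, cen, margin = 3), 1)
  # randomized batches against the loop oracle
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    k <- sample(2:6, 1)
    feats <- matrix(rnorm(n * k), n)
    y <- rbinom(n, 1, 0.4)
    cen <- matrix(rnorm(2 * k), 2)
    m <- runif(1, 0, 5)
    expect_equal(triplet_center_loss(feats, y, cen, m),
                 tcl_oracle(feats, y, cen, m), tolerance = 1e-10)
  }
})

test_that("TCL decreases as a sample moves straight toward its own center", {
  set.seed(18)
  centers <- rbind(rnorm(4), rnorm(4) + 3)
  f0 <- centers[1, ] + rnorm(4, sd = 2)
  y <- 0L
  steps <- seq(0, 1, by = 0.2)
  vals <- vapply(steps, function(a) {
    f <- (1 - a) * f0 + a * centers[1, ]
    triplet_center_loss(matrix(f, 1), y, centers, margin = 50)  # hinge active
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("joint loss is the exact weighted sum", {
  expect_equal(joint_loss(0.7, 2.0, 0.1), 0.9)
  expect_equal(joint_loss(1.23, 99, 0), 1.23)
})

test_that("losses are invariant to padding content via the mask", {
  set.seed(19)
  n <- 30
  mask <- rep(c(TRUE, FALSE), 15)
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, 0.3)
  p2 <- p; p2[!mask] <- runif(sum(!mask))
  y2 <- y; y2[!mask] <- 1 - y[!mask]
  cfg <- loss_config()
  expect_equal(cb_focal_loss(p, y, c(9, 4), cfg, mask),
               cb_focal_loss(p2, y2, c(9, 4), cfg, mask), tolerance = 1e-12)
  feats <- matrix(rnorm(n * 3), n)
  feats2 <- feats; feats2[!mask, ] <- rnorm(sum(!mask) * 3)
  cen <- matrix(rnorm(6), 2)
  expect_equal(triplet_center_loss(feats, y, cen, 2, mask),
               triplet_center_loss(feats2, y2, cen, 2, mask),
               tolerance = 1e-12)
})

test_that("joint gradient equals focal gradient plus lambda times TCL gradient", {
  # finite-difference check through the full network on a tiny problem
  ns <- asNamespace("resibind")
  set.seed(20)
  cfg <- backbone_config(input_dim = 3, layer_dims = c(4, 3, 2, 2),
                         kernel_sizes = c(3, 3, 3, 1), dropout = 0)
  model <- init_backbone(cfg, seed = 7)
  mats <- list(matrix(rnorm(15), 5), matrix(rnorm(24), 8))
  bt <- batchify(mats)
  y <- integer(2 * 8)
  y[c(1, 7, 12)] <- 1L
  mvec <- as.logical(bt$mask)
  counts <- c(sum(y[mvec] == 0), sum(y[mvec] == 1))
  lcfg <- loss_config(beta = 0.9, gamma = 2, lambda = 0.3, margin = 1.5)
  centers <- init_centers(2, seed = 3)

  loss_at <- function(model) {
    fwd <- ns$nn_forward(model, bt$x, bt$mask, training = TRUE)
    p_true <- fwd$probs[cbind(seq_along(y), y + 1L)]
    focal <- cb_focal_loss(p_true, y, counts, lcfg, mask = mvec)
    feats <- matrix(fwd$features[[3]], nrow = length(y))
    joint_loss(focal,
               triplet_center_loss(feats, y, centers, lcfg$margin, mvec),
               lcfg$lambda)
  }
  fwd <- ns$nn_forward(model, bt$x, bt$mask, training = TRUE)
  p_all <- fwd$probs
  feats <- matrix(fwd$features[[3]], nrow = length(y))
  dlog <- ns$cb_focal_grad_logits(p_all, y, counts, lcfg, mvec)
  tg <- ns$tcl_grads(feats, y, centers, lcfg$margin, mvec)
  extra <- vector("list", 3)
  extra[[3]] <- lcfg$lambda * tg$dfeat
  grads <- ns$nn_backward(model, fwd, dlog, extra)

  eps <- 1e-6
  set.seed(21)
  for (l in 1:4) {
    for (nm in intersect(names(grads[[l]]), c("W", "b", "gamma", "beta"))) {
      for (r in 1:2) {
        idx <- sample(length(model$layers[[l]][[nm]]), 1)
        up <- model; up$layers[[l]][[nm]][idx] <- up$layers[[l]][[nm]][idx] + eps
        dn <- model; dn$layers[[l]][[nm]][idx] <- dn$layers[[l]][[nm]][idx] - eps
        numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[l]][[nm]][idx], numeric_grad, tolerance = 1e-4)
      }
    }
  }
  # center gradients (TCL term only)
  for (idx in 1:4) {
    up <- centers; up[idx] <- up[idx] + eps
    dn <- centers; dn[idx] <- dn[idx] - eps
    tcl_up <- triplet_center_loss(feats, y, up, lcfg$margin, mvec)
    tcl_dn <- triplet_center_loss(feats, y, dn, lcfg$margin, mvec)
    expect_equal(tg$dcenters[idx], (tcl_up - tcl_dn) / (2 * eps),
                 tolerance = 1e-6)
  }
})
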