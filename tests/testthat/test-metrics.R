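# O(n^2) / per-residue oracles for the metric implementations.

confusion_oracle <- function(p, y, thr) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(p)) {
    call <- p[i] >= thr
    if (call && y[i] == 1) tp <- tp + 1L
    if (call && y[i] == 0) fp <- fp + 1L
    if (!call && y[i] == 0) tn <- tn + 1L
    if (!call && y[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

test_that("confusion counts match a per-residue loop oracle", {
  pred <- list(a = c(0.9, 0.2, 0.7), b = c(0.1, 0.6))
  truth <- list(a = c(1L, 0L, 1L), b = c(0L, 0L))
  cc <- confusion(pred, truth, 0.5)
  expect_equal(cc, list(TP = 2L, FP = 1L, TN = 2L, FN = 0L))
  # perfect and inverted predictions
  perfect <- confusion(list(a = c(1, 0, 1)), list(a = c(1L, 0L, 1L)))
  expect_equal(perfect$FP + perfect$FN, 0L)
  inverted <- confusion(list(a = c(0, 1, 0)), list(a = c(1L, 0L, 1L)))
  expect_equal(inverted$TP + inverted$TN, 0L)
  # randomized check
  set.seed(30)
  p <- runif(100)
  y <- rbinom(100, 1, 0.2)
  expect_equal(confusion(list(x = p), list(x = y), 0.4),
               confusion_oracle(p, y, 0.4))
  # length mismatch names the id
  expect_error(confusion(list(a = c(0.5, 0.5)), list(a = c(1L))), "'a'")
})

test_that("scalar metrics match direct formula evaluation on random tables", {
  set.seed(31)
  for (rep in 1:300) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               TN = sample(0:50, 1), FN = sample(0:50, 1))
    m <- scalar_metrics(cc)
    with(cc, {
      if (TN + FP > 0) expect_equal(m$spe, TN / (TN + FP), tolerance = 1e-12)
      if (TP + FP > 0) expect_equal(m$pre, TP / (TP + FP), tolerance = 1e-12)
      if (TP + FN > 0) expect_equal(m$rec, TP / (TP + FN), tolerance = 1e-12)
      if (m$pre + m$rec > 0) {
        expect_equal(m$f1, 2 * m$pre * m$rec / (m$pre + m$rec),
                     tolerance = 1e-12)
      }
      denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
      if (denom > 0) {
        expect_equal(m$mcc, (TP * TN - FN * FP) / sqrt(denom),
                     tolerance = 1e-12)
      } else {
        expect_equal(m$mcc, 0)
      }
    })
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
  }
})

test_that("scalar metrics handle canonical special cases", {
  perfect <- scalar_metrics(list(TP = 50L, FP = 0L, TN = 50L, FN = 0L))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  uninformative <- scalar_metrics(list(TP = 10L, FN = 10L, FP = 25L, TN = 25L))
  expect_equal(uninformative$mcc, 0)
  degenerate <- scalar_metrics(list(TP = 0L, FP = 0L, TN = 10L, FN = 0L))
  expect_equal(degenerate$pre, 0)
  expect_equal(degenerate$mcc, 0)
})

test_that("label swap exchanges specificity and recall", {
  set.seed(32)
  for (rep in 1:20) {
    cc <- list(TP = sample(1:40, 1), FP = sample(1:40, 1),
               TN = sample(1:40, 1), FN = sample(1:40, 1))
    swapped <- list(TP = cc$TN, FP = cc$FN, TN = cc$TP, FN = cc$FP)
    m1 <- scalar_metrics(cc)
    m2 <- scalar_metrics(swapped)
    expect_equal(m1$spe, m2$rec, tolerance = 1e-12)
    expect_equal(m1$rec, m2$spe, tolerance = 1e-12)
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("ROC AUC equals Mann-Whitney pair counting, including ties", {
  expect_equal(roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$aupr, 1)
  expect_equal(roc_pr_curves(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    scores <- round(runif(n), 1)  # rounding forces ties
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    expect_equal(roc_pr_curves(scores, truth)$auc,
                 mann_whitney_auc(scores, truth), tolerance = 1e-12)
  }
  expect_error(roc_pr_curves(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(34)
  scores <- runif(50)
  truth <- rbinom(50, 1, 0.3)
  base <- roc_pr_curves(scores, truth)
  for (f in list(function(x) 2 * x + 1, function(x) exp(x),
                 function(x) x^3)) {
    tr <- roc_pr_curves(f(scores), truth)
    expect_equal(tr$auc, base$auc, tolerance = 1e-12)
    expect_equal(tr$aupr, base$aupr, tolerance = 1e-12)
  }
})

test_that("composition counts selected residues and normalizes", {
  comp <- composition(c(p1 = "KKR"), list(p1 = c(1L, 1L, 1L)))
  expect_equal(unname(comp["K"]), 2 / 3)
  expect_equal(unname(comp["R"]), 1 / 3)
  expect_equal(sum(comp), 1)
  expect_error(composition(c(p1 = "KKR"), list(p1 = c(0L, 0L, 0L))),
               "no canonical")
  # law of large numbers on uniform sequences
  set.seed(35)
  big <- paste(sample(aa_alphabet(FALSE), 1e5, replace = TRUE),
               collapse = "")
  comp_big <- composition(c(p = big))
  expect_true(all(abs(comp_big - 1 / 20) < 0.01))
})

test_that("KL divergence is zero iff equal, asymmetric and matches the two-term oracle", {
  p <- c(0.5, 0.5)
  q <- c(0.9, 0.1)
  expect_equal(kl_divergence(p, p), 0, tolerance = 1e-8)
  expect_equal(kl_divergence(p, q),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-4)
  expect_equal(kl_divergence(p, q), 0.5108, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_gte(kl_divergence(q, p), 0)
  expect_error(kl_divergence(c(-0.1, 1.1), p), "non-negative")
})
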