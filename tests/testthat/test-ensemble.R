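# constant / affine dummy members used to test ensemble mechanics in
# isolation from any fitting backend
const_member <- function(value) {
  structure(list(value = value), class = "dummy_member")
}
predict.dummy_member <- function(object, newdata, ...) {
  rep(object$value, nrow(newdata))
}
registerS3method("predict", "dummy_member", predict.dummy_member,
                 envir = asNamespace("stats"))

test_that("VIF is exactly 1 for orthogonal variables and Inf for duplicates", {
  Q <- with_seed(1, qr.Q(qr(scale(matrix(stats::rnorm(600), 100, 6),
                                  scale = FALSE))))
  v <- vif(as.data.frame(Q))
  expect_equal(unname(v), rep(1, 6), tolerance = 1e-8)
  X <- with_seed(2, data.frame(a = stats::rnorm(50)))
  X$b <- X$a
  X$c <- with_seed(3, stats::rnorm(50))
  v2 <- vif(X)
  expect_true(is.infinite(v2[["a"]]))
  expect_true(is.infinite(v2[["b"]]))
})

test_that("VIF matches the 1/(1 - R^2) least-squares oracle", {
  X <- with_seed(4, {
    Z <- matrix(stats::rnorm(300 * 6), 300, 6)
    Z[, 6] <- 0.6 * Z[, 1] + 0.4 * Z[, 2] + 0.5 * Z[, 6]
    as.data.frame(Z)
  })
  v <- vif(X)
  oracle <- vapply(seq_len(6), function(j) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2)
  }, 0)
  expect_equal(unname(v), oracle, tolerance = 1e-8)
})

test_that("iterative VIF filtering removes constructed combinations only", {
  tab <- collinear_table(n = 3000, seed = 42)
  out <- vif_filter(tab, threshold = 10)
  expect_equal(sort(out$retained), sprintf("v%02d", 1:15))
  expect_equal(nrow(out$removed), ncol(tab) - length(out$retained))
  # nothing removed when all VIFs are already below the threshold
  clean <- with_seed(5, as.data.frame(matrix(stats::rnorm(500 * 4), 500, 4)))
  out2 <- vif_filter(clean, 10)
  expect_equal(out2$retained, names(clean))
  expect_equal(nrow(out2$removed), 0)
  # post-condition: no surviving variable has VIF above the threshold
  expect_true(all(vif(tab[out$retained]) <= 10))
})

test_that("GLM recovers a quadratic logit and separates held-out classes", {
  sim <- with_seed(10, {
    x <- stats::rnorm(2500, sd = 1.5)
    eta <- 3 - 4 * (x - 0.3)^2
    y <- stats::rbinom(2500, 1, stats::plogis(eta))
    data.frame(x = x, y = y)
  })
  fit <- fit_technique("GLM", sim["x"], sim$y, seed = 1)
  co <- stats::coef(fit$model)
  expect_lt(co[["I(x^2)"]], 0)  # concave response recovered
  holdout <- with_seed(11, {
    x <- stats::rnorm(2000, sd = 1.5)
    y <- stats::rbinom(2000, 1, stats::plogis(3 - 4 * (x - 0.3)^2))
    data.frame(x = x, y = y)
  })
  m <- evaluate_predictions(predict(fit, holdout["x"]), holdout$y)
  expect_gt(m$auc, 0.9)
})

test_that("all techniques respond monotonically to a separating covariate", {
  d <- with_seed(12, {
    x <- rep(c(0, 1), each = 200)
    data.frame(x = x, y = x)  # perfectly separating binary covariate
  })
  newdata <- data.frame(x = c(0, 1))
  for (tech in c("GLM", "GAM", "BRT")) {
    fit <- suppressWarnings(fit_technique(tech, d["x"], d$y, fast_hyper(), 1))
    p <- predict(fit, newdata)
    expect_gt(p[2], p[1])
  }
})

test_that("BRT fitting is deterministic under a fixed seed", {
  d <- with_seed(13, data.frame(a = stats::rnorm(400), b = stats::rnorm(400)))
  y <- with_seed(14, stats::rbinom(400, 1, stats::plogis(d$a)))
  f1 <- fit_technique("BRT", d, y, fast_hyper(), seed = 5)
  f2 <- fit_technique("BRT", d, y, fast_hyper(), seed = 5)
  expect_identical(predict(f1, d), predict(f2, d))
})

test_that("evaluation metrics hit their closed-form endpoints", {
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- evaluate_predictions(as.numeric(labels), labels)
  expect_equal(m$auc, 1)
  expect_equal(m$tss, 1)
  expect_equal(m$sensitivity + m$specificity - 1, m$tss)
})

test_that("label-independent predictions score near chance", {
  set.seed(20)
  pred <- stats::runif(10000)
  labels <- stats::rbinom(10000, 1, 0.3)
  m <- evaluate_predictions(pred, labels)
  expect_lt(abs(m$auc - 0.5), 0.02)
  expect_lt(abs(m$tss), 0.05)
  expect_error(evaluate_predictions(pred, rep(1, 10000)), "both classes")
})

test_that("rank AUC equals trapezoidal ROC integration, including ties", {
  # 6-point hand example with a tie across classes
  pred <- c(0.9, 0.8, 0.5, 0.5, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- evaluate_predictions(pred, labels)
  expect_equal(m$auc, auc_trapezoid(pred, labels))
  expect_equal(m$auc, 8.5 / 9)  # hand count: 8 wins + 1 tie at one half
  for (seed in 1:5) {
    p <- with_seed(seed, round(stats::runif(40), 2))
    l <- with_seed(seed + 50, stats::rbinom(40, 1, 0.4))
    if (length(unique(l)) < 2) next
    expect_equal(evaluate_predictions(p, l)$auc, auc_trapezoid(p, l),
                 tolerance = 1e-12)
  }
})

test_that("AUC of complemented predictions is the complement", {
  p <- with_seed(21, stats::runif(200))
  l <- with_seed(22, stats::rbinom(200, 1, 0.4))
  expect_equal(evaluate_predictions(p, l)$auc +
                 evaluate_predictions(1 - p, l)$auc, 1)
})

test_that("the selected threshold maximises TSS over the whole grid", {
  p <- with_seed(23, stats::runif(300))
  l <- with_seed(24, stats::rbinom(300, 1, stats::plogis(3 * (p - 0.5))))
  m <- evaluate_predictions(p, l)
  grid <- seq(0, 1, by = 0.001)
  tss_at <- vapply(grid, function(t) {
    mean(p[l == 1] >= t) + mean(p[l == 0] < t) - 1
  }, 0)
  expect_equal(m$tss, max(tss_at), tolerance = 1e-12)
  expect_equal(m$best_threshold, grid[which.max(tss_at)])
})

test_that("ensemble weights clip negative TSS and fall back to equal", {
  expect_equal(weights_from_tss(c(0.6, 0.3, 0.1)), c(0.6, 0.3, 0.1))
  expect_equal(weights_from_tss(c(0.5, -0.2, 0.5)), c(0.5, 0, 0.5))
  expect_equal(weights_from_tss(c(-0.1, -0.5, 0)), rep(1 / 3, 3))
})

test_that("ensemble prediction is the weighted mean of its members", {
  members <- list(const_member(0.2), const_member(0.6), const_member(1.0))
  nd <- data.frame(x = 1:2)
  expect_equal(ensemble_predict(members, c(1, 0, 0), nd), c(0.2, 0.2))
  expect_equal(ensemble_predict(members, c(0.5, 0.3, 0.2), nd),
               rep(0.5 * 0.2 + 0.3 * 0.6 + 0.2 * 1.0, 2))
  # identical members: the ensemble equals any member
  same <- list(const_member(0.4), const_member(0.4), const_member(0.4))
  expect_equal(ensemble_predict(same, c(0.2, 0.3, 0.5), nd), c(0.4, 0.4))
  bad <- list(const_member(1.2))
  expect_error(ensemble_predict(bad, 1, nd), "outside")
})

test_that("species retention is inclusive at both thresholds", {
  mk <- function(tss, auc) structure(list(tss = tss, auc = auc),
                                     class = "sdm_metrics")
  expect_true(retain_species(mk(0.3, 0.7)))
  expect_false(retain_species(mk(0.29, 0.9)))
  expect_false(retain_species(mk(0.9, 0.69)))
})

test_that("permutation importance isolates the driving variable", {
  d <- with_seed(30, data.frame(driver = stats::rnorm(800),
                                noise = stats::rnorm(800),
                                flat = rep(1, 800)))
  y <- with_seed(31, stats::rbinom(800, 1, stats::plogis(3 * d$driver)))
  fit <- fit_technique("BRT", d, y, fast_hyper(), seed = 2)
  imp <- permutation_importance(fit, d, n_perm = 3, seed = 3)
  expect_equal(unname(imp[["flat"]]), 0)  # constant column: never used
  expect_equal(names(which.max(imp)), "driver")
  expect_true(all(imp >= 0 & imp <= 1))
  expect_identical(imp, permutation_importance(fit, d, n_perm = 3, seed = 3))
})

test_that("ensemble importance stays within the member hull", {
  m <- matrix(c(0.9, 0.1, 0.5, 0.2, 0.3, 0.4), 2, 3,
              dimnames = list(c("a", "b"), NULL))
  w <- c(0.5, 0.25, 0.25)
  e <- ensemble_importance(m, w)
  expect_true(all(e >= apply(m, 1, min) - 1e-12))
  expect_true(all(e <= apply(m, 1, max) + 1e-12))
  expect_equal(unname(e["a"]), 0.9 * 0.5 + 0.5 * 0.25 + 0.3 * 0.25)
})

test_that("a strong-signal species yields a retained, well-scored ensemble", {
  f <- strong_species_fit()
  ens <- f$ens
  expect_true(ens$converged)
  expect_true(ens$retained)
  expect_gt(ens$ensemble_metrics$auc, 0.8)
  expect_gt(ens$ensemble_metrics$tss, 0.4)
  expect_equal(sum(ens$weights), 1)
  # the true driver dominates the importance ranking
  expect_equal(names(which.max(ens$importance)), "cov01")
  # ensemble predictions stay within the member envelope
  nd <- f$ds$pres_covs[1:50, ]
  preds <- vapply(ens$members, function(m) predict(m, nd), numeric(50))
  p_ens <- ensemble_predict(ens$members, ens$weights, nd)
  expect_true(all(p_ens >= apply(preds, 1, min) - 1e-9))
  expect_true(all(p_ens <= apply(preds, 1, max) + 1e-9))
})
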