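linear_member <- function(slope, intercept = 0) {
  structure(list(slope = slope, intercept = intercept), class = "lin_member")
}
predict.lin_member <- function(object, newdata, ...) {
  pmin(pmax(object$intercept + object$slope * newdata[[1]], 0), 1)
}
registerS3method("predict", "lin_member", predict.lin_member,
                 envir = asNamespace("stats"))

test_that("binarisation is inclusive at the threshold", {
  expect_equal(binarize(c(0.2, 0.5, 0.7), 0.5), c(FALSE, TRUE, TRUE))
  r <- raster_layer(matrix(c(0.1, 0.5, 0.49, 0.9), 2, 2), 1000)
  b <- binarize(r, 0.5)
  expect_equal(as.vector(b$values), c(0, 1, 0, 1))
  expect_equal(sum(binarize(raster_layer(matrix(0.3, 3, 3), 1), 0.6)$values), 0)
})

test_that("the maxTSS threshold reproduces its stored confusion matrix", {
  p <- with_seed(40, stats::runif(500))
  l <- with_seed(41, stats::rbinom(500, 1, stats::plogis(4 * (p - 0.5))))
  m <- evaluate_predictions(p, l)
  pred_pres <- binarize(p, m$best_threshold)
  expect_equal(mean(pred_pres[l == 1]), m$sensitivity)
  expect_equal(mean(!pred_pres[l == 0]), m$specificity)
})

test_that("occurrence cleaning drops flagged, dated, vague and outside records", {
  template <- raster_layer(matrix(0, 4, 4), 1000)
  recs <- data.frame(
    species_id = "sp",
    x = c(500, 500, 500, 500, 9500, 600, 3500),
    y = c(500, 500, 500, 500, 500, 700, 3500),
    year = c(1989, 2022, 2000, 2000, 2000, 2010, 1990),
    uncertainty_m = c(10, 10, 1500, 10, 10, 10, 1000),
    geospatial_issue = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  out <- filter_occurrences(recs, template, seed = 2)
  expect_equal(unname(out$rejections), c(1, 2, 1, 1))
  # records 6 and 7 survive; 6 shares a cell with nothing else
  expect_equal(nrow(out$records), 2)
  # two survivors in one cell thin to one
  dup <- data.frame(species_id = "sp", x = c(100, 900), y = c(100, 900),
                    year = 2000, uncertainty_m = 1,
                    geospatial_issue = FALSE, stringsAsFactors = FALSE)
  out2 <- filter_occurrences(dup, template, seed = 3)
  expect_equal(nrow(out2$records), 1)
  # an empty result is allowed
  none <- filter_occurrences(dup[0, ], template, seed = 1)
  expect_null(none$records)
})

test_that("true positive rate counts records in predicted-present cells", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1
  map <- raster_layer(m, 1000)
  # 5 hand-placed records: three in present cells, two in absent cells
  occ <- data.frame(x = c(500, 1500, 2500, 3500, 500),
                    y = c(500, 1500, 2500, 3500, 3500))
  expect_equal(true_positive_rate(map, occ), 3 / 5)
  all_pres <- raster_layer(matrix(1, 4, 4), 1000)
  expect_equal(true_positive_rate(all_pres, occ), 1)
  all_abs <- raster_layer(matrix(0, 4, 4), 1000)
  expect_equal(true_positive_rate(all_abs, occ), 0)
  expect_true(is.na(true_positive_rate(map, occ[0, ])))
})

test_that("evaluation strips honour weights and fix other covariates at means", {
  pres <- data.frame(a = c(0, 1), b = c(10, 30))
  members <- list(linear_member(1), linear_member(0.5), linear_member(0.25))
  # weight concentrated on the first member reproduces its curve
  c1 <- evaluation_strip(members, c(1, 0, 0), "a", pres, n_points = 5)
  expect_equal(c1$x, seq(0, 1, length.out = 5))
  expect_equal(c1$poo, seq(0, 1, length.out = 5))
  # identical members: ensemble curve equals the member curve
  same <- list(linear_member(0.5), linear_member(0.5), linear_member(0.5))
  c2 <- evaluation_strip(same, c(0.2, 0.3, 0.5), "a", pres, n_points = 5)
  expect_equal(c2$poo, 0.5 * c2$x)
  # weighted combination
  c3 <- evaluation_strip(members, c(0.5, 0.5, 0), "a", pres, n_points = 3)
  expect_equal(c3$poo, 0.75 * c3$x)
  expect_error(evaluation_strip(members, c(1, 0, 0), "zzz", pres), "zzz")
  expect_error(
    evaluation_strip(members, c(1, 0, 0), "a", data.frame(a = c(2, 2))),
    "zero range")
})

test_that("a fitted monotone response yields a monotone strip", {
  sim <- with_seed(42, {
    x <- stats::rnorm(2000)
    y <- stats::rbinom(2000, 1, stats::plogis(2.5 * x))
    data.frame(x = x, y = y)
  })
  fit <- fit_technique("GLM", sim["x"], sim$y, seed = 1)
  curve <- evaluation_strip(list(fit), 1, "x",
                            sim[sim$y == 1, "x", drop = FALSE])
  expect_true(all(diff(curve$poo) > -1e-9))
})

test_that("niche-optimum extraction follows the peak and the median tie rule", {
  uni <- structure(list(variable = "v", x = seq(0, 10, 0.1),
                        poo = exp(-(seq(0, 10, 0.1) - 3)^2)),
                   class = "response_curve")
  expect_equal(extract_miv(uni), 3)
  flat <- structure(list(variable = "v", x = seq(2, 8, length.out = 7),
                         poo = rep(0.4, 7)), class = "response_curve")
  expect_equal(extract_miv(flat), 5)  # median of the range midpoints
  # invariant under strictly monotone rescaling of the probabilities
  resc <- uni
  resc$poo <- uni$poo^3 / 2
  expect_equal(extract_miv(resc), extract_miv(uni))
})

test_that("Spearman test matches an independent mid-rank oracle", {
  expect_equal(spearman_test(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_test(1:10, (1:10)^2)$p, 0)
  for (seed in 1:4) {
    x <- with_seed(seed, stats::rnorm(20))
    y <- with_seed(seed + 10, sample(1:5, 20, replace = TRUE))  # ties
    got <- spearman_test(x, y)
    want <- spearman_oracle(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$n, 20)
  }
  expect_error(spearman_test(1:2, 2:1), "at least 3")
  expect_error(spearman_test(rep(1, 5), 1:5), "zero variance")
})

test_that("the t-approximation tracks the exact permutation law for small n", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  for (n in 6:7) {
    x <- seq_len(n)
    y <- with_seed(n, sample(n))
    got <- spearman_test(x, y)
    rho_perm <- vapply(perms(seq_len(n)), function(p) {
      stats::cor(x, y[p])
    }, 0)
    p_exact <- mean(abs(rho_perm) >= abs(got$rho) - 1e-12)
    expect_equal(got$rho, stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_lt(abs(got$p - p_exact), 0.06)
  }
})

test_that("the niche table enforces the importance cutoff and group NA rule", {
  ids <- sprintf("s%02d", 1:8)
  mu <- seq(-2, 2, length.out = 8)
  miv <- data.frame(species_id = ids, variable = "cov01", miv = mu)
  imp <- data.frame(species_id = ids, variable = "cov01",
                    importance = c(0.049, rep(0.5, 7)))
  eiv <- data.frame(species_id = ids, variable = "cov01", eiv = rank(mu))
  groups <- data.frame(species_id = ids,
                       group = rep(c("diagnostic_vascular", "non_diagnostic"),
                                   each = 4))
  pairs <- data.frame(eiv_name = "cov01", miv_name = "cov01")
  out <- build_niche_table(miv, imp, eiv, groups, pairs)
  # species below the 0.05 importance cutoff is excluded
  expect_false("s01" %in% out$pairs_table$species_id)
  expect_equal(nrow(out$pairs_table), 7)
  dv <- out$correlations[out$correlations$group == "diagnostic_vascular", ]
  expect_equal(dv$rho, 1)
  expect_equal(dv$n, 3)
  # inverted EIVs give a perfectly negative correlation
  eiv_neg <- transform(eiv, eiv = rank(-mu))
  out_neg <- build_niche_table(miv, imp, eiv_neg, groups, pairs)
  expect_equal(out_neg$correlations$rho[1], -1)
  # a group left with < 3 species reports NA
  imp2 <- transform(imp, importance = c(0.5, 0.5, 0.5, 0.5, 0.04, 0.04, 0.5, 0.5))
  out2 <- build_niche_table(miv, imp2, eiv, groups, pairs)
  nd <- out2$correlations[out2$correlations$group == "non_diagnostic", ]
  expect_equal(nd$n, 2)
  expect_true(is.na(nd$rho))
})

test_that("truth-map TPR beats spatially permuted maps", {
  f <- strong_species_fit()
  truth <- f$truths[[1]]
  occ <- gen_occurrences(f$truths, 400, seed = 51)
  occ <- filter_occurrences(occ, truth, seed = 52)$records
  # labels from plots sampled off the truth give the maxTSS threshold
  pm <- presence_matrix(f$plots, "sp_strong")[, 1]
  poo_at <- raster_values_at(truth, f$plots$x, f$plots$y)
  thr <- evaluate_predictions(poo_at, as.numeric(pm))$best_threshold
  bmap <- binarize(truth, thr)
  tpr_truth <- true_positive_rate(bmap, occ)
  for (seed in 1:10) {
    perm <- with_seed(seed, {
      v <- bmap$values
      raster_layer(matrix(sample(v), nrow(v)), bmap$cell_size)
    })
    expect_gte(tpr_truth, true_positive_rate(perm, occ))
  }
})
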