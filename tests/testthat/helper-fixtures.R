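# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fast_hyper <- function() {
  sdm_hyperparameters(brt_n_trees = 150, brt_learning_rate = 0.08,
                      brt_max_depth = 3)
}

tiny_landscape <- function() {
  fixture("tiny_landscape", function() {
    gen_landscape(landscape_config(40, 40, n_covariates = 4,
                                   spatial_range = 6000, seed = 3))
  })
}

tiny_stack <- function() {
  fixture("tiny_stack", function() build_covariate_stack(tiny_landscape()))
}

# One strong-signal species with a fitted ensemble, reused across ensemble
# and validation tests.
strong_species_fit <- function() {
  fixture("strong_species_fit", function() {
    L <- tiny_landscape()
    st <- tiny_stack()
    spec <- species_spec("sp_strong", "diagnostic_moss",
                         optima = c(cov01 = 0.5), breadths = c(cov01 = 0.8),
                         p_max = 0.9)
    truths <- gen_species(list(spec), st)
    plots <- gen_plots(8000, L, truths, seed = 7)
    fp <- filter_plots(plots, filter_config(), st)
    ds <- suppressWarnings(
      prepare_species_data("sp_strong", fp$plots, st, seed = 11))
    ens <- suppressWarnings(fit_ensemble(ds, fast_hyper(), seed = 5))
    list(landscape = L, stack = st, spec = spec, truths = truths,
         plots = fp$plots, ds = ds, ens = ens)
  })
}

# Scaled-down end-to-end configuration: 36 x 36 km landscape, one constructed
# collinear covariate, four viable species plus one whose niche lies far
# outside the landscape (so it must be dropped by the presence minimum).
tiny_pipeline_config <- function(seed = 5) {
  cfg <- default_config(seed = seed)
  cfg$landscape <- landscape_config(
    grid_rows = 36, grid_cols = 36, n_covariates = 5, spatial_range = 6000,
    collinear_spec = list(list(target = 5, sources = c(3, 4),
                               weights = c(0.8, 0.6), noise_sd = 0.05)),
    seed = child_seed(seed, 100))
  groups <- c("diagnostic_moss", "diagnostic_vascular", "non_diagnostic",
              "diagnostic_moss")
  mu <- c(-0.8, -0.2, 0.4, 1.0)
  cfg$species <- c(
    lapply(1:4, function(i) {
      species_spec(sprintf("sp%02d", i), groups[i],
                   optima = c(cov01 = mu[i], cov02 = -mu[i]),
                   breadths = c(cov01 = 1.0, cov02 = 1.4), p_max = 0.9)
    }),
    list(species_spec("sp_ghost", "non_diagnostic", optima = c(cov01 = 50),
                      breadths = c(cov01 = 0.05), p_max = 0.9))
  )
  cfg$n_plots <- 3500
  cfg$n_occurrences <- 400
  cfg$hyper <- fast_hyper()
  cfg$eiv$sign <- c(cov01 = 1, cov02 = -1)
  cfg$pairs <- data.frame(eiv_name = c("cov01", "cov02"),
                          miv_name = c("cov01", "cov02"),
                          stringsAsFactors = FALSE)
  cfg
}

tiny_pipeline_run <- function() {
  fixture("tiny_pipeline_run", function() {
    suppressWarnings(run_pipeline(tiny_pipeline_config()))
  })
}

# Random acyclic D8 grid: steepest descent on a random smooth surface.
random_flow_grid <- function(nr, nc, seed) {
  dem <- with_seed(seed, raster_layer(matrix(stats::rnorm(nr * nc), nr, nc) +
                                        outer(seq_len(nr), seq_len(nc)) / 4,
                                      cell_size = 1))
  list(dem = dem, flow = d8_from_dem(dem))
}

# Brute-force D8 accumulation oracle: for every cell, enumerate its full
# upstream set by walking every cell's flow path.
d8_oracle <- function(flow, weight) {
  code <- flow$values
  nr <- nrow(code); nc <- ncol(code)
  down <- wetsdm:::d8_downstream(flow)
  n <- nr * nc
  acc <- numeric(n)
  w <- as.vector(weight$values)
  for (src in seq_len(n)) {
    at <- src
    repeat {
      acc[at] <- acc[at] + w[src]
      at <- down[at]
      if (is.na(at)) break
    }
  }
  matrix(acc, nr)
}

# Independent mid-rank Spearman oracle: manual average ranks, Pearson moment
# formula, two-sided t p-value.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    s <- sort(v)
    vapply(v, function(vi) mean(which(s == vi)), 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

# Trapezoidal ROC-integration AUC oracle.
auc_trapezoid <- function(pred, labels) {
  th <- sort(unique(c(-Inf, pred, Inf)), decreasing = FALSE)
  tpr <- vapply(th, function(t) mean(pred[labels == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(pred[labels == 0] >= t), 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# 18-variable covariate table with 3 constructed strong linear combinations
# (the VIF screening scenario).
collinear_table <- function(n = 5000, seed = 42) {
  with_seed(seed, {
    X <- as.data.frame(matrix(stats::rnorm(n * 15), n, 15))
    names(X) <- sprintf("v%02d", 1:15)
    X$c16 <- 0.8 * X$v01 + 0.6 * X$v02 + stats::rnorm(n, sd = 0.05)
    X$c17 <- 0.7 * X$v03 + 0.5 * X$v04 + 0.5 * X$v05 + stats::rnorm(n, sd = 0.05)
    X$c18 <- 0.6 * X$v06 + 0.8 * X$v07 + stats::rnorm(n, sd = 0.05)
    X
  })
}
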