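#' Plot filtering configuration
#'
#' Defaults mirror the preparation rules of the workflow: surveys from 1990 to
#' 2018, location uncertainty of at most 1 km, and exclusion of marine (MA),
#' inland-water (P) and vegetated man-made (V) habitat classes.
#'
#' @param year_min,year_max inclusive survey-year range.
#' @param max_uncertainty_m maximum location uncertainty (m), inclusive.
#' @param excluded_habitat_prefixes habitat-code prefixes to drop.
#' @return a `filter_config` list.
#' @export
filter_config <- function(year_min = 1990, year_max = 2018,
                          max_uncertainty_m = 1000,
                          excluded_habitat_prefixes = c("MA", "P", "V")) {
  stopifnot(year_min <= year_max, max_uncertainty_m >= 0)
  structure(list(year_min = year_min, year_max = year_max,
                 max_uncertainty_m = max_uncertainty_m,
                 excluded_habitat_prefixes = excluded_habitat_prefixes),
            class = "filter_config")
}

habitat_excluded <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) {
    # level-1 prefix match: "V" must not swallow e.g. a (hypothetical) "VA";
    # EUNIS level-1 classes are letter(s) followed by digits, so a prefix
    # matches when the code starts with it followed by a digit or nothing.
    out <- out | grepl(paste0("^", p, "([0-9]|$)"), codes)
  }
  out
}

#' Filter vegetation plots
#'
#' Retains plots surveyed within the configured year range, with location
#' uncertainty at most the threshold (inclusive), a habitat code outside the
#' excluded classes, and -- when a covariate stack is supplied -- no missing
#' covariate value at the plot's cell. Idempotent.
#'
#' @param plots plot table (see [gen_plots()]).
#' @param cfg a [filter_config()].
#' @param covariates optional named list of `wet_raster` covariates.
#' @return list with `plots` (retained rows) and `rejections`, the per-rule
#'   counts of plots violating each rule (a plot may violate several).
#' @export
filter_plots <- function(plots, cfg = filter_config(), covariates = NULL) {
  need <- c("x", "y", "year", "uncertainty_m", "habitat_code")
  missing <- setdiff(need, names(plots))
  if (length(missing)) {
    stop("plot table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_year <- plots$year < cfg$year_min | plots$year > cfg$year_max
  bad_unc <- plots$uncertainty_m > cfg$max_uncertainty_m
  bad_hab <- habitat_excluded(plots$habitat_code, cfg$excluded_habitat_prefixes)
  bad_cov <- rep(FALSE, nrow(plots))
  if (!is.null(covariates)) {
    vals <- extract_covariates(covariates, plots$x, plots$y)
    bad_cov <- rowSums(is.na(vals)) > 0
  }
  keep <- !(bad_year | bad_unc | bad_hab | bad_cov)
  list(plots = plots[keep, , drop = FALSE],
       rejections = c(year = sum(bad_year), uncertainty = sum(bad_unc),
                      habitat = sum(bad_hab), covariate_nodata = sum(bad_cov)))
}

#' Thin records to one per grid cell
#'
#' Retains exactly one record per occupied cell, chosen uniformly at random
#' under the seed (reduces pseudo-replication and sampling bias).
#'
#' @param records table with `x`, `y` columns.
#' @param cell_size cell edge length (m).
#' @param seed integer seed.
#' @return the thinned table (row order follows sorted cell keys).
#' @export
thin_one_per_cell <- function(records, cell_size, seed = 1) {
  if (nrow(records) == 0) return(records)
  cc <- cell_of(records$x, records$y, cell_size)
  key <- paste(cc$row, cc$col, sep = ":")
  with_seed(seed, {
    groups <- split(seq_len(nrow(records)), key)
    pick <- vapply(groups[sort(names(groups))], function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }, 0L)
    records[pick, , drop = FALSE]
  })
}

#' Minimum number of presence records required for model fitting
#'
#' The smallest n such that, after holding out the evaluation fraction, at
#' least `per_var` presences per environmental variable remain for
#' calibration: smallest n with `floor((1 - eval_frac) * n) >= per_var *
#' n_vars`. With 15 variables, 5 presences per variable and a 20% hold-out
#' this is 94.
#'
#' @param n_vars number of environmental variables.
#' @param per_var required presences per variable (default 5).
#' @param eval_frac held-out fraction in \[0, 1) (default 0.2).
#' @return integer minimum presence count.
#' @export
min_presences <- function(n_vars, per_var = 5, eval_frac = 0.2) {
  stopifnot(n_vars >= 1, per_var >= 1, eval_frac >= 0)
  if (eval_frac >= 1) stop("eval_frac must be < 1")
  target <- per_var * n_vars
  n <- ceiling(target / (1 - eval_frac))
  while (floor((1 - eval_frac) * n) < target) n <- n + 1L
  as.integer(n)
}

#' Sample absence records for one modelling technique
#'
#' The candidate pool is one plot per cell where the species was not recorded
#' (pre-thinned). The sample size is `max(floor_min, n_presences)` -- with a
#' floor of 10,000 absences for GLM/GAM and 1,000 for BRT -- capped at the
#' pool size (with a warning), drawn without replacement.
#'
#' @param pool thinned absence-candidate plot table.
#' @param n_presences number of presence records for the species.
#' @param technique `"GLM"`, `"GAM"` or `"BRT"`.
#' @param seed integer seed.
#' @return sampled absence rows.
#' @export
sample_absences <- function(pool, n_presences, technique = c("GLM", "GAM", "BRT"),
                            seed = 1) {
  technique <- match.arg(technique)
  if (nrow(pool) == 0) stop("empty absence pool")
  floor_min <- if (technique == "BRT") 1000L else 10000L
  size <- max(floor_min, n_presences)
  if (size > nrow(pool)) {
    warning(sprintf("absence pool (%d) smaller than requested %d; using all",
                    nrow(pool), size))
    size <- nrow(pool)
  }
  with_seed(seed, pool[sample.int(nrow(pool), size), , drop = FALSE])
}

#' Calibration / evaluation split, stratified by label
#'
#' A single random split with `frac` of the records (per presence/absence
#' label) for calibration and the rest for evaluation. `frac = 1` yields an
#' empty evaluation set (used for the final refit on all data).
#'
#' @param labels 0/1 vector of presence labels.
#' @param frac calibration fraction in (0, 1\].
#' @param seed integer seed.
#' @return logical vector, `TRUE` = calibration.
#' @export
split_calibration <- function(labels, frac = 0.8, seed = 1) {
  stopifnot(length(labels) >= 1, frac > 0, frac <= 1)
  cal <- rep(TRUE, length(labels))
  if (frac == 1) return(cal)
  with_seed(seed, {
    for (lab in unique(labels)) {
      ix <- which(labels == lab)
      if (length(ix) < 2) stop("a label has fewer than 2 records; cannot split")
      n_eval <- round((1 - frac) * length(ix))
      cal[sample(ix, n_eval)] <- FALSE
    }
  })
  cal
}

#' Assemble the modelling dataset for one species
#'
#' Applies the full sampling protocol: presences thinned to one plot per cell,
#' a per-cell absence pool disjoint from presence cells, per-technique absence
#' samples (large for GLM/GAM, small for BRT), covariate extraction, and
#' stratified 80/20 calibration masks. Returns `NULL` when the species has
#' fewer thinned presences than the minimum-presence rule requires.
#'
#' @param species_id species to prepare.
#' @param plots filtered plot table.
#' @param stack named list of covariate `wet_raster` layers used for fitting.
#' @param seed integer seed (expanded to child seeds per component).
#' @param per_var,eval_frac passed to [min_presences()].
#' @param cal_frac calibration fraction.
#' @return a `species_dataset` list, or `NULL` if below the presence minimum.
#' @export
prepare_species_data <- function(species_id, plots, stack, seed = 1,
                                 per_var = 5, eval_frac = 0.2, cal_frac = 0.8) {
  cs <- stack[[1]]$cell_size
  has <- presence_matrix(plots, species_id)[, 1]
  pres <- thin_one_per_cell(plots[has, , drop = FALSE], cs,
                            child_seed(seed, 11))
  need <- min_presences(length(stack), per_var, eval_frac)
  if (nrow(pres) < need) return(NULL)  # caller logs reason "min_presences"
  pool <- thin_one_per_cell(plots[!has, , drop = FALSE], cs,
                            child_seed(seed, 12))
  pres_cells <- paste(floor(pres$x / cs), floor(pres$y / cs))
  pool_cells <- paste(floor(pool$x / cs), floor(pool$y / cs))
  pool <- pool[!(pool_cells %in% pres_cells), , drop = FALSE]

  abs_large <- sample_absences(pool, nrow(pres), "GLM", child_seed(seed, 13))
  abs_small <- sample_absences(pool, nrow(pres), "BRT", child_seed(seed, 14))

  covs_at <- function(tab) extract_covariates(stack, tab$x, tab$y)
  ds <- list(
    species_id = species_id,
    presences = pres, pres_covs = covs_at(pres),
    absences_large = abs_large, abs_large_covs = covs_at(abs_large),
    absences_small = abs_small, abs_small_covs = covs_at(abs_small),
    cal_pres = split_calibration(rep(1, nrow(pres)), cal_frac,
                                 child_seed(seed, 15)),
    cal_abs_large = split_calibration(rep(0, nrow(abs_large)), cal_frac,
                                      child_seed(seed, 16)),
    cal_abs_small = split_calibration(rep(0, nrow(abs_small)), cal_frac,
                                      child_seed(seed, 17))
  )
  structure(ds, class = "species_dataset")
}
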