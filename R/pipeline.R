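#' Derived covariate stack for a synthetic landscape
#'
#' Assembles the model-ready environmental layers: mean temperature of the
#' coldest month, total annual precipitation, growing degree days, water
#' balance, WWPI, TWI, upstream anthropogenic land cover, the coastal salt
#' flag, and the landscape's abstract (soil-like) covariates.
#'
#' @param landscape a `wet_landscape`.
#' @return named list of aligned `wet_raster` layers.
#' @export
build_covariate_stack <- function(landscape) {
  temps <- landscape$climate$temp
  tmin <- Reduce(function(a, b) raster_map(pmin, a, b), temps)
  tmin$name <- "MinTemp"; tmin$units <- "degC"
  prec <- Reduce(function(a, b) raster_map(`+`, a, b), landscape$climate$prec)
  prec$name <- "Precip"; prec$units <- "mm"
  stack <- c(
    list(MinTemp = tmin,
         Precip = prec,
         GDD = growing_degree_days(temps),
         WB = water_balance(landscape$climate),
         WWPI = wwpi(landscape$wetness),
         TWI = twi(landscape$dem, landscape$flow),
         ALC = upstream_alc(landscape$landcover, landscape$flow),
         Salt = salt_flag(landscape$dem, landscape$coastline)),
    landscape$covariates
  )
  check_aligned(stack)
  stack
}

default_species_specs <- function(driver_names = c("cov03", "cov04"),
                                  n_per_group = 4, p_max = 0.9,
                                  breadths = c(0.8, 1.2)) {
  groups <- c("diagnostic_moss", "diagnostic_vascular", "non_diagnostic")
  n <- n_per_group * length(groups)
  mu1 <- seq(-1.5, 1.5, length.out = n)
  mu2 <- seq(1.2, -1.2, length.out = n)
  lapply(seq_len(n), function(i) {
    species_spec(sprintf("sp%02d", i), groups[(i - 1) %% 3 + 1],
                 optima = stats::setNames(c(mu1[i], mu2[i]), driver_names),
                 breadths = stats::setNames(breadths, driver_names),
                 p_max = p_max)
  })
}

#' Default end-to-end run configuration
#'
#' Desk-scale study conditions: a 70 x 70 km autocorrelated landscape with
#' two constructed near-collinear covariates (so VIF screening has work to
#' do), 12 Gaussian-niche species (4 per group) driven by two independent
#' covariates, 12,000 plots with 5% of plots carrying each filterable defect,
#' 2,000 candidate occurrence records per species, and reduced boosted-tree
#' settings suited to a single CPU.
#'
#' @param seed global integer seed.
#' @param out_dir optional directory for CSV artefacts.
#' @return a nested configuration list for [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    landscape = landscape_config(
      grid_rows = 70, grid_cols = 70, cell_size = 1000, n_covariates = 8,
      spatial_range = 8000,
      # constructed near-collinear targets; their sources are disjoint from
      # the species driver covariates (cov03, cov04), so whichever side of a
      # collinear pair the iterative filter removes, the drivers survive
      collinear_spec = list(
        list(target = 7, sources = c(1, 2), weights = c(0.8, 0.6), noise_sd = 0.05),
        list(target = 8, sources = c(5, 6), weights = c(0.7, 0.7), noise_sd = 0.05)
      ),
      seed = child_seed(seed, 100)
    ),
    species = default_species_specs(),
    n_plots = 12000,
    attribute_noise = list(bad_year = 0.05, bad_uncertainty = 0.05,
                           bad_habitat = 0.05),
    n_occurrences = 2000,
    occurrence_noise = list(bad_year = 0.05, bad_uncertainty = 0.05,
                            geospatial_issue = 0.05),
    filter = filter_config(),
    vif_threshold = 10,
    hyper = sdm_hyperparameters(brt_n_trees = 300, brt_learning_rate = 0.05,
                                brt_max_depth = 3),
    per_var = 5, eval_frac = 0.2, cal_frac = 0.8,
    tss_min = 0.3, auc_min = 0.7,
    importance_cutoff = 0.05,
    eiv = list(scale = c(1, 10), sign = c(cov03 = 1, cov04 = -1),
               noise_sd = 0.5),
    pairs = data.frame(eiv_name = c("cov03", "cov04"),
                       miv_name = c("cov03", "cov04"),
                       stringsAsFactors = FALSE)
  )
}

#' Predict the ensemble occurrence-probability map
#'
#' @param ens an `sdm_ensemble`.
#' @param stack named list of covariate rasters (must contain the model's
#'   covariates).
#' @return `wet_raster` of ensemble probabilities.
#' @export
predict_map <- function(ens, stack) {
  check_aligned(stack)
  d <- dim(stack[[1]]$values)
  cells <- as.data.frame(lapply(stack, function(r) as.vector(r$values)))
  poo <- ensemble_predict(ens$members, ens$weights, cells)
  raster_layer(matrix(poo, d[1]), stack[[1]]$cell_size,
               name = paste0("poo_", ens$species_id), units = "probability")
}

#' Run the full workflow on a configuration
#'
#' generate landscape -> derive covariates -> VIF screening -> generate
#' species truths, plots, occurrences and EIVs -> plot protocol -> per-species
#' ensembles -> spatial validation (maxTSS binarisation + TPR) -> ecological
#' validation (evaluation strips, MIVs, Spearman tests) -> summary. Species
#' are dropped, with a logged reason, for too few presences, non-convergence
#' of any member, or failure of the retention rule. Deterministic under the
#' configuration seed.
#'
#' @param config a configuration list, see [default_config()].
#' @return list with `metrics`, `importance`, `miv`, `tpr`, `niche`,
#'   `drop_log`, `summary`, `retained_vars`, `vif_removed`, plus the
#'   generated `landscape`, `stack`, and per-species `ensembles`. CSV
#'   artefacts are written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  landscape <- gen_landscape(config$landscape)
  stack <- build_covariate_stack(landscape)

  cell_tab <- as.data.frame(lapply(stack, function(r) as.vector(r$values)))
  cell_tab <- cell_tab[stats::complete.cases(cell_tab), , drop = FALSE]
  keep_cols <- names(cell_tab)[vapply(cell_tab, function(x) stats::sd(x) > 0, TRUE)]
  vf <- vif_filter(cell_tab[, keep_cols, drop = FALSE], config$vif_threshold)
  stack_fit <- stack[vf$retained]

  truths <- gen_species(config$species, stack)
  groups <- data.frame(
    species_id = vapply(config$species, `[[`, "", "species_id"),
    group = vapply(config$species, `[[`, "", "group"),
    stringsAsFactors = FALSE)

  plots <- gen_plots(config$n_plots, landscape, truths,
                     config$attribute_noise, child_seed(config$seed, 200))
  fp <- filter_plots(plots, config$filter, stack_fit)

  occ <- gen_occurrences(truths, config$n_occurrences,
                         config$occurrence_noise, child_seed(config$seed, 300))
  occ_clean <- filter_occurrences(occ, stack[[1]],
                                  seed = child_seed(config$seed, 301))$records

  metrics <- list(); importance <- list(); miv <- list(); tpr <- list()
  drop_log <- list(); ensembles <- list()
  for (i in seq_along(groups$species_id)) {
    sid <- groups$species_id[i]
    sseed <- child_seed(config$seed, 400 + i)
    ds <- prepare_species_data(sid, fp$plots, stack_fit, sseed,
                               config$per_var, config$eval_frac,
                               config$cal_frac)
    if (is.null(ds)) {
      drop_log[[sid]] <- "min_presences"
      next
    }
    ens <- suppressWarnings(
      fit_ensemble(ds, config$hyper, sseed, config$tss_min, config$auc_min))
    if (!ens$converged) {
      drop_log[[sid]] <- "convergence"
      next
    }
    if (!ens$retained) {
      drop_log[[sid]] <- "retention"
      next
    }
    ensembles[[sid]] <- ens

    mm <- ens$member_metrics
    metrics[[sid]] <- data.frame(
      species_id = sid, group = groups$group[i],
      technique = c(names(mm), "ensemble"),
      auc = c(vapply(mm, `[[`, 0, "auc"), ens$ensemble_metrics$auc),
      tss = c(vapply(mm, `[[`, 0, "tss"), ens$ensemble_metrics$tss),
      threshold = c(vapply(mm, `[[`, 0, "best_threshold"), ens$threshold),
      weight = c(ens$weights, NA_real_),
      n_presences = nrow(ds$presences), stringsAsFactors = FALSE)

    importance[[sid]] <- data.frame(
      species_id = sid, variable = names(ens$importance),
      importance = unname(ens$importance), stringsAsFactors = FALSE)

    sp_miv <- lapply(names(stack_fit), function(v) {
      curve <- evaluation_strip(ens$members, ens$weights, v, ds$pres_covs)
      data.frame(species_id = sid, variable = v, miv = extract_miv(curve),
                 stringsAsFactors = FALSE)
    })
    miv[[sid]] <- do.call(rbind, sp_miv)

    pmap <- predict_map(ens, stack_fit)
    bmap <- binarize(pmap, ens$threshold)
    occ_sp <- occ_clean[occ_clean$species_id == sid, , drop = FALSE]
    tpr[[sid]] <- data.frame(
      species_id = sid, group = groups$group[i], n_records = nrow(occ_sp),
      tpr = true_positive_rate(bmap, occ_sp), stringsAsFactors = FALSE)
  }

  rbind_all <- function(lst) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else NULL
  }
  metrics <- rbind_all(metrics)
  importance <- rbind_all(importance)
  miv <- rbind_all(miv)
  tpr <- rbind_all(tpr)
  drop_log <- data.frame(
    species_id = as.character(names(drop_log)),
    reason = as.character(unlist(drop_log)),
    stringsAsFactors = FALSE, row.names = NULL)

  eivs <- gen_eivs(config$species, config$eiv$scale, config$eiv$sign,
                   config$eiv$noise_sd, child_seed(config$seed, 500))
  niche <- if (!is.null(miv) && nrow(miv)) {
    build_niche_table(miv, importance, eivs, groups, config$pairs,
                      config$importance_cutoff)
  } else NULL

  summary <- summarize_metrics(metrics, tpr, drop_log, groups)

  out <- list(metrics = metrics, importance = importance, miv = miv,
              tpr = tpr, niche = niche, drop_log = drop_log,
              summary = summary, retained_vars = vf$retained,
              vif_removed = vf$removed, filter_rejections = fp$rejections,
              landscape = landscape, stack = stack, stack_fit = stack_fit,
              truths = truths, ensembles = ensembles, eivs = eivs,
              occurrences = occ_clean)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, nm) {
      if (!is.null(tab) && nrow(tab)) {
        utils::write.csv(tab, file.path(config$out_dir, nm), row.names = FALSE)
      }
    }
    wr(metrics, "metrics.csv"); wr(importance, "importance.csv")
    wr(miv, "miv.csv"); wr(tpr, "tpr.csv"); wr(drop_log, "drop_log.csv")
    if (!is.null(niche)) {
      wr(niche$correlations, "niche_correlations.csv")
      wr(niche$pairs_table, "niche_pairs.csv")
    }
    wr(summary, "summary.csv")
  }
  out
}

#' Per-group summary of model performance
#'
#' Medians and quartiles of ensemble AUC, TSS and TPR per species group,
#' the fraction of species with TPR above 0.5, and retained/dropped counts.
#' Empty groups are omitted with a warning.
#'
#' @param metrics long metrics table from [run_pipeline()].
#' @param tpr per-species TPR table.
#' @param drop_log drop log with reasons.
#' @param groups data.frame `species_id, group` of all configured species.
#' @return data.frame, one row per non-empty group.
#' @export
summarize_metrics <- function(metrics, tpr, drop_log = NULL, groups = NULL) {
  if (is.null(metrics) || nrow(metrics) == 0) stop("no metrics to summarise")
  known <- c("diagnostic_moss", "diagnostic_vascular", "non_diagnostic")
  bad <- setdiff(unique(metrics$group), known)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ens <- metrics[metrics$technique == "ensemble", , drop = FALSE]
  rows <- lapply(known, function(g) {
    sub <- ens[ens$group == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("no retained species in group ", g)
      return(NULL)
    }
    tsub <- if (!is.null(tpr)) tpr$tpr[tpr$group == g & !is.na(tpr$tpr)] else numeric()
    q <- function(x, p) unname(stats::quantile(x, p, na.rm = TRUE))
    dropped <- if (!is.null(drop_log) && !is.null(groups) && nrow(drop_log)) {
      sum(groups$group[match(drop_log$species_id, groups$species_id)] == g)
    } else 0L
    data.frame(
      group = g, n_retained = nrow(sub), n_dropped = dropped,
      auc_median = stats::median(sub$auc), auc_q25 = q(sub$auc, .25),
      auc_q75 = q(sub$auc, .75),
      tss_median = stats::median(sub$tss), tss_q25 = q(sub$tss, .25),
      tss_q75 = q(sub$tss, .75),
      tpr_median = if (length(tsub)) stats::median(tsub) else NA_real_,
      tpr_q25 = if (length(tsub)) q(tsub, .25) else NA_real_,
      tpr_q75 = if (length(tsub)) q(tsub, .75) else NA_real_,
      frac_tpr_gt_0.5 = if (length(tsub)) mean(tsub > 0.5) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
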