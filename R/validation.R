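#' Binarise occurrence probabilities at a threshold
#'
#' A cell (or record) is predicted present when its probability of occurrence
#' is greater than or equal to the threshold -- inclusivity matches the maxTSS
#' search, which returns the smallest maximising threshold.
#'
#' @param poo numeric vector or `wet_raster` of probabilities.
#' @param threshold maxTSS threshold from [evaluate_predictions()].
#' @return logical vector, or 0/1 `wet_raster` for raster input.
#' @export
binarize <- function(poo, threshold) {
  stopifnot(is.finite(threshold))
  if (inherits(poo, "wet_raster")) {
    return(raster_map(function(v) as.numeric(v >= threshold), poo,
                      name = "presence", units = "binary"))
  }
  poo >= threshold
}

#' Clean independent occurrence records
#'
#' Drops records with a flagged geospatial issue, a collection year outside
#' the validation window (1990--2021 by default), a location uncertainty above
#' 1 km, or a location outside the study area; then thins to one random record
#' per grid cell. An empty result is allowed.
#'
#' @param records occurrence table (see [gen_occurrences()]).
#' @param template `wet_raster` defining the study area and cell size.
#' @param years inclusive year range.
#' @param max_uncertainty_m maximum location uncertainty (m).
#' @param seed seed for the per-cell thinning.
#' @return list with `records` (cleaned, thinned) and per-rule `rejections`.
#' @export
filter_occurrences <- function(records, template, years = c(1990, 2021),
                               max_uncertainty_m = 1000, seed = 1) {
  d <- dim(template$values); cs <- template$cell_size
  bad_issue <- records$geospatial_issue
  bad_year <- records$year < years[1] | records$year > years[2]
  bad_unc <- records$uncertainty_m > max_uncertainty_m
  cc <- cell_of(records$x, records$y, cs)
  outside <- cc$row < 0 | cc$row >= d[1] | cc$col < 0 | cc$col >= d[2]
  keep <- !(bad_issue | bad_year | bad_unc | outside)
  kept <- records[keep, , drop = FALSE]
  thinned <- do.call(rbind, lapply(split(kept, kept$species_id), function(tab) {
    thin_one_per_cell(tab, cs, seed)
  }))
  if (!is.null(thinned)) rownames(thinned) <- NULL
  list(records = thinned,
       rejections = c(geospatial_issue = sum(bad_issue), year = sum(bad_year),
                      uncertainty = sum(bad_unc), outside = sum(outside)))
}

#' True positive rate against independent occurrences
#'
#' The proportion of occurrence records that fall in cells predicted present.
#'
#' @param presence_map 0/1 `wet_raster` from [binarize()].
#' @param occurrences cleaned occurrence table for one species.
#' @return TPR in \[0, 1\]; `NA` when there are no records (the species is
#'   then excluded from TPR summaries).
#' @export
true_positive_rate <- function(presence_map, occurrences) {
  if (nrow(occurrences) == 0) return(NA_real_)
  pred <- raster_values_at(presence_map, occurrences$x, occurrences$y)
  mean(pred == 1, na.rm = FALSE)
}

#' Evaluation-strip response curve for one variable
#'
#' The variable of interest is varied over `n_points` evenly spaced values
#' across its range in the presence data while every other covariate is held
#' at its mean over the presence data; each technique's predictions along the
#' strip are combined as the TSS-weighted mean.
#'
#' @param members list of fitted `sdm_fit` models.
#' @param weights ensemble weights.
#' @param variable covariate name to vary.
#' @param presence_covs covariate data.frame of the species' presence plots.
#' @param n_points strip resolution (default 100).
#' @return a `response_curve` list with `variable`, `x`, `poo`.
#' @export
evaluation_strip <- function(members, weights, variable, presence_covs,
                             n_points = 100) {
  if (!variable %in% names(presence_covs)) {
    stop("variable not among the model covariates: ", variable)
  }
  rng <- range(presence_covs[[variable]])
  if (diff(rng) == 0) stop("variable has zero range over presence plots")
  x <- seq(rng[1], rng[2], length.out = n_points)
  newdata <- as.data.frame(lapply(presence_covs, function(col) rep(mean(col), n_points)))
  newdata[[variable]] <- x
  poo <- ensemble_predict(members, weights, newdata)
  structure(list(variable = variable, x = x, poo = poo),
            class = "response_curve")
}

#' Modelled indicator value (niche optimum) from a response curve
#'
#' The variable value at the curve's maximum occurrence probability; when the
#' maximum is attained at several grid points (within a small tolerance,
#' since exact ties only occur numerically), their median is returned -- a
#' flat curve therefore yields the midpoint of the variable range.
#'
#' @param curve a `response_curve`.
#' @param tol tie tolerance on the probability axis (default 1e-12).
#' @return MIV in the units of the variable.
#' @export
extract_miv <- function(curve, tol = 1e-12) {
  m <- max(curve$poo)
  stats::median(curve$x[curve$poo >= m - tol])
}

#' Spearman rank correlation with a t-approximated p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties allowed); the two-sided
#' p-value comes from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom (0 when rho is exactly +-1).
#'
#' @param miv,eiv paired numeric vectors (n >= 3).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_test <- function(miv, eiv) {
  stopifnot(length(miv) == length(eiv))
  ok <- !is.na(miv) & !is.na(eiv)
  miv <- miv[ok]; eiv <- eiv[ok]
  n <- length(miv)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(miv) == 0 || stats::sd(eiv) == 0) {
    stop("zero variance in ranks; correlation undefined")
  }
  rho <- stats::cor(rank(miv), rank(eiv))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Niche table: modelled vs empirical indicator values
#'
#' Joins per-species modelled indicator values (MIVs) with ordinal ecological
#' indicator values (EIVs) for the configured indicator-variable pairs. A
#' species enters a pair only when the ensemble importance of the modelled
#' variable is at least `min_importance`. Spearman tests are run per species
#' group and pair; groups with fewer than 3 admitted species report `NA`.
#'
#' @param miv_table data.frame `species_id, variable, miv`.
#' @param importance_table data.frame `species_id, variable, importance`.
#' @param eiv_table data.frame `species_id, variable, eiv` (EIV names).
#' @param groups data.frame `species_id, group`.
#' @param pairs data.frame `eiv_name, miv_name`.
#' @param min_importance admission cutoff (default 0.05).
#' @return list with `pairs_table` (admitted species x pair rows) and
#'   `correlations` (per group x pair: rho, p, n).
#' @export
build_niche_table <- function(miv_table, importance_table, eiv_table, groups,
                              pairs, min_importance = 0.05) {
  stopifnot(all(c("eiv_name", "miv_name") %in% names(pairs)))
  rows <- list(); cors <- list()
  for (i in seq_len(nrow(pairs))) {
    ev <- pairs$eiv_name[i]; mv <- pairs$miv_name[i]
    m <- miv_table[miv_table$variable == mv, c("species_id", "miv")]
    im <- importance_table[importance_table$variable == mv,
                           c("species_id", "importance")]
    e <- eiv_table[eiv_table$variable == ev, c("species_id", "eiv")]
    tab <- merge(merge(m, im, by = "species_id"), e, by = "species_id")
    tab <- merge(tab, groups, by = "species_id")
    tab <- tab[tab$importance >= min_importance, , drop = FALSE]
    if (nrow(tab)) {
      tab$eiv_name <- ev; tab$miv_name <- mv
      rows[[length(rows) + 1]] <- tab
    }
    for (g in unique(groups$group)) {
      sub <- tab[tab$group == g, , drop = FALSE]
      res <- if (nrow(sub) >= 3 && stats::sd(sub$miv) > 0 &&
                 stats::sd(sub$eiv) > 0) {
        spearman_test(sub$miv, sub$eiv)
      } else {
        list(rho = NA_real_, p = NA_real_, n = nrow(sub))
      }
      cors[[length(cors) + 1]] <- data.frame(
        eiv_name = ev, miv_name = mv, group = g,
        rho = res$rho, p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  list(pairs_table = if (length(rows)) do.call(rbind, rows) else
         data.frame(),
       correlations = do.call(rbind, cors))
}
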