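#' Configuration of a synthetic landscape
#'
#' Defines the grid, the number of spatially autocorrelated covariates, the
#' autocorrelation scale, and any constructed collinearity between covariates.
#' Constructed collinearity entries rebuild a target covariate as a weighted
#' sum of source covariates plus Gaussian noise, so that downstream
#' variance-inflation screening has a known answer.
#'
#' @param grid_rows,grid_cols grid dimensions (each >= 4).
#' @param cell_size cell edge length in metres.
#' @param n_covariates number of abstract environmental covariates.
#' @param spatial_range autocorrelation scale in metres (0 = white noise).
#' @param collinear_spec list of entries `list(target=, sources=, weights=,
#'   noise_sd=)` with covariate indices (1-based) and finite mixing weights.
#' @param seed integer seed; a fixed seed yields bit-identical landscapes.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(grid_rows, grid_cols, cell_size = 1000,
                             n_covariates = 6, spatial_range = 10000,
                             collinear_spec = list(), seed = 1) {
  stopifnot(grid_rows >= 4, grid_cols >= 4, cell_size > 0,
            n_covariates >= 1, spatial_range >= 0)
  for (cs in collinear_spec) {
    stopifnot(is.list(cs),
              all(c("target", "sources", "weights", "noise_sd") %in% names(cs)),
              all(is.finite(cs$weights)),
              length(cs$weights) == length(cs$sources),
              cs$target >= 1, cs$target <= n_covariates,
              all(cs$sources >= 1), all(cs$sources <= n_covariates),
              !(cs$target %in% cs$sources), cs$noise_sd >= 0)
  }
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, n_covariates = as.integer(n_covariates),
                 spatial_range = spatial_range, collinear_spec = collinear_spec,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Zero-mean unit-variance spatially autocorrelated field: white noise smoothed
# by circular convolution with a Gaussian kernel (range in cell units).
gaussian_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(z)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * range_cells^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic landscape
#'
#' Produces every raw layer the workflow consumes: a stack of autocorrelated
#' abstract covariates (soil-like fields, honouring any constructed
#' collinearity), a DEM with a derived acyclic D8 flow grid, monthly
#' temperature and precipitation, water/wet/total observation counts, a
#' categorical land-cover layer, and a coastline polyline along the western
#' grid edge.
#'
#' @param config a [landscape_config()].
#' @return a `wet_landscape` list with elements `covariates` (named list of
#'   `wet_raster`), `dem`, `flow` (D8 codes), `climate` (`$temp`, `$prec`,
#'   lists of 12 rasters), `wetness` (`$n_water`, `$n_wet`, `$n_total`),
#'   `landcover`, `coastline` (list of polyline vertex matrices), `config`.
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; cs <- config$cell_size
  rng <- config$spatial_range / cs

  lay <- function(v, name, units = "") raster_layer(v, cs, name, units)

  covs <- with_seed(child_seed(config$seed, 1), {
    lapply(seq_len(config$n_covariates), function(i) gaussian_field(nr, nc, rng))
  })
  names(covs) <- sprintf("cov%02d", seq_along(covs))
  covs <- with_seed(child_seed(config$seed, 2), {
    for (sp in config$collinear_spec) {
      mix <- Reduce(`+`, Map(function(w, s) w * covs[[s]], sp$weights, sp$sources))
      covs[[sp$target]] <- mix + matrix(stats::rnorm(nr * nc, sd = sp$noise_sd), nr, nc)
    }
    covs
  })
  if (!all(vapply(covs, function(m) all(is.finite(m)), TRUE))) {
    stop("non-finite covariate field generated")
  }
  cov_layers <- Map(function(m, nm) lay(m, nm, "z-score"), covs, names(covs))

  climate <- with_seed(child_seed(config$seed, 3), {
    t_ann <- 8 + 4 * gaussian_field(nr, nc, rng)
    t_amp <- 9 + 2 * gaussian_field(nr, nc, rng)  # continentality varies in space
    p_ann <- 60 + 25 * gaussian_field(nr, nc, rng)
    temp <- lapply(1:12, function(m)
      lay(t_ann + t_amp * cos(2 * pi * (m - 7) / 12), sprintf("temp%02d", m), "degC"))
    prec <- lapply(1:12, function(m)
      lay(pmax(p_ann + 10 * cos(2 * pi * (m - 10) / 12), 0),
          sprintf("prec%02d", m), "mm"))
    list(temp = temp, prec = prec)
  })

  dem_vals <- with_seed(child_seed(config$seed, 4),
                        150 * gaussian_field(nr, nc, rng) + 400)
  dem <- lay(dem_vals, "dem", "m")
  flow <- d8_from_dem(dem)

  wetness <- with_seed(child_seed(config$seed, 5), {
    wf <- gaussian_field(nr, nc, rng)
    n_total <- matrix(20L, nr, nc)
    p_water <- stats::plogis(1.5 * wf - 2.5)
    n_water <- matrix(stats::rbinom(nr * nc, 20L, p_water), nr, nc)
    p_wet <- stats::plogis(1.5 * wf - 1.5) * 0.5
    n_wet <- matrix(stats::rbinom(nr * nc, 20L - n_water, pmin(1, p_wet)), nr, nc)
    list(n_water = lay(n_water, "n_water", "count"),
         n_wet = lay(n_wet, "n_wet", "count"),
         n_total = lay(n_total, "n_total", "count"))
  })

  landcover <- with_seed(child_seed(config$seed, 6), {
    codes <- c("Q2", "S2", "T1", "R1", "V1", "J1")
    lay_lc <- matrix(sample(codes, nr * nc, replace = TRUE,
                            prob = c(.25, .2, .2, .15, .12, .08)), nr, nc)
    raster_layer(lay_lc, cs, "landcover", "EUNIS code")
  })

  coastline <- list(matrix(c(0, 0, 0, nr * cs), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("x", "y"))))

  structure(list(covariates = cov_layers, dem = dem, flow = flow,
                 climate = climate, wetness = wetness, landcover = landcover,
                 coastline = coastline, config = config),
            class = "wet_landscape")
}

#' Specification of a synthetic species with a Gaussian niche
#'
#' The species' true probability of occurrence in a cell is
#' `p_max * prod_k exp(-(x_k - mu_k)^2 / (2 sigma_k^2))` over its driver
#' covariates `k`; the optima `mu` are the ground truth that niche-optimum
#' recovery is scored against.
#'
#' @param species_id identifier string.
#' @param group one of `"diagnostic_moss"`, `"diagnostic_vascular"`,
#'   `"non_diagnostic"`.
#' @param optima named numeric vector of niche optima, one per driver covariate.
#' @param breadths named numeric vector of niche breadths (> 0), same names.
#' @param p_max maximum occurrence probability, in (0, 1].
#' @return a `species_spec` list.
#' @export
species_spec <- function(species_id, group, optima, breadths, p_max = 0.9) {
  group <- match.arg(group, c("diagnostic_moss", "diagnostic_vascular",
                              "non_diagnostic"))
  stopifnot(length(optima) >= 1, !is.null(names(optima)),
            setequal(names(optima), names(breadths)),
            all(breadths > 0), p_max > 0, p_max <= 1)
  structure(list(species_id = species_id, group = group,
                 optima = optima, breadths = breadths[names(optima)],
                 p_max = p_max),
            class = "species_spec")
}

#' True occurrence-probability rasters for synthetic species
#'
#' @param specs list of [species_spec()].
#' @param covariates named list of aligned `wet_raster` covariates containing
#'   every driver named in the specs.
#' @return named list of `wet_raster` (one per species) with values in
#'   \[0, p_max\].
#' @export
gen_species <- function(specs, covariates) {
  check_aligned(covariates)
  out <- lapply(specs, function(sp) {
    missing <- setdiff(names(sp$optima), names(covariates))
    if (length(missing)) {
      stop("unknown driver variable(s): ", paste(missing, collapse = ", "))
    }
    p <- sp$p_max
    for (k in names(sp$optima)) {
      x <- covariates[[k]]$values
      p <- p * exp(-(x - sp$optima[[k]])^2 / (2 * sp$breadths[[k]]^2))
    }
    raster_layer(p, covariates[[1]]$cell_size,
                 name = sp$species_id, units = "probability")
  })
  names(out) <- vapply(specs, `[[`, "", "species_id")
  out
}

GOOD_HABITATS <- c("Q1", "Q2", "S2", "T3", "R1")
BAD_HABITATS <- c("MA2", "P1", "V1")

# Assign disjoint index sets of the requested sizes (for attribute-noise
# bookkeeping: each corrupted record violates exactly one rule).
noise_indices <- function(n, fracs) {
  stopifnot(all(unlist(fracs) >= 0), all(unlist(fracs) <= 1),
            sum(unlist(fracs)) <= 1)
  sizes <- vapply(fracs, function(f) round(f * n), 0)
  perm <- sample.int(n)
  out <- list(); at <- 0
  for (nm in names(sizes)) {
    out[[nm]] <- perm[seq_len(sizes[[nm]]) + at]
    at <- at + sizes[[nm]]
  }
  out
}

#' Generate vegetation plots over a synthetic landscape
#'
#' Plot locations are uniform over cells; each species' presence is Bernoulli
#' with its true occurrence probability at the plot's cell. The stated
#' fractions of plots are corrupted with exactly one filterable defect each:
#' a survey year outside 1990--2018, a location uncertainty above 1 km, or an
#' excluded habitat code (MA/P/V prefix).
#'
#' @param n number of plots.
#' @param landscape a `wet_landscape`.
#' @param truths named list of true-probability rasters from [gen_species()].
#' @param attribute_noise list with fractions `bad_year`, `bad_uncertainty`,
#'   `bad_habitat` (each in \[0, 1\], summing to at most 1).
#' @param seed integer seed.
#' @return data.frame with columns `plot_id, x, y, year, uncertainty_m,
#'   habitat_code, species` (semicolon-joined species ids).
#' @export
gen_plots <- function(n, landscape, truths,
                      attribute_noise = list(bad_year = 0, bad_uncertainty = 0,
                                             bad_habitat = 0),
                      seed = 1) {
  stopifnot(n >= 1)
  nr <- landscape$config$grid_rows; nc <- landscape$config$grid_cols
  cs <- landscape$config$cell_size
  with_seed(seed, {
    cells <- sample.int(nr * nc, n, replace = TRUE)
    row <- (cells - 1L) %% nr; col <- (cells - 1L) %/% nr
    x <- (col + 0.5) * cs; y <- (row + 0.5) * cs
    year <- sample(1990:2018, n, replace = TRUE)
    uncertainty_m <- stats::runif(n, 0, 1000)
    habitat_code <- sample(GOOD_HABITATS, n, replace = TRUE)

    bad <- noise_indices(n, attribute_noise[c("bad_year", "bad_uncertainty",
                                              "bad_habitat")])
    if (length(bad$bad_year)) {
      year[bad$bad_year] <- sample(c(1960:1989, 2019:2025),
                                   length(bad$bad_year), replace = TRUE)
    }
    if (length(bad$bad_uncertainty)) {
      uncertainty_m[bad$bad_uncertainty] <-
        stats::runif(length(bad$bad_uncertainty), 1001, 5000)
    }
    if (length(bad$bad_habitat)) {
      habitat_code[bad$bad_habitat] <- sample(BAD_HABITATS,
                                              length(bad$bad_habitat),
                                              replace = TRUE)
    }

    ids <- names(truths)
    pres <- vapply(truths, function(r) {
      p <- r$values[cells]
      stats::runif(n) < p
    }, logical(n))
    pres <- matrix(pres, nrow = n)
    species <- vapply(seq_len(n), function(i) {
      paste(ids[pres[i, ]], collapse = ";")
    }, "")

    data.frame(plot_id = sprintf("plot%06d", seq_len(n)), x = x, y = y,
               year = year, uncertainty_m = uncertainty_m,
               habitat_code = habitat_code, species = species,
               stringsAsFactors = FALSE)
  })
}

#' Presence matrix from a plot table
#'
#' @param plots plot table from [gen_plots()] (or read from CSV).
#' @param species_ids species to tabulate.
#' @return logical matrix, plots x species.
#' @export
presence_matrix <- function(plots, species_ids) {
  lists <- strsplit(plots$species, ";", fixed = TRUE)
  out <- vapply(species_ids, function(id) {
    vapply(lists, function(s) id %in% s, TRUE)
  }, logical(nrow(plots)))
  matrix(out, nrow = nrow(plots), dimnames = list(NULL, species_ids))
}

#' Generate independent occurrence records for validation
#'
#' Emulates a GBIF-like download: records are importance-sampled over cells in
#' proportion to the species' true occurrence probability, so they fall where
#' the species truly occurs. Stated fractions carry exactly one defect each:
#' a year outside 1990--2021, uncertainty above 1 km, or a flagged geospatial
#' issue.
#'
#' @param truths named list of true-probability rasters.
#' @param n_per_species records to draw per species (before cleaning).
#' @param noise list with fractions `bad_year`, `bad_uncertainty`,
#'   `geospatial_issue`.
#' @param seed integer seed.
#' @return data.frame `species_id, x, y, year, uncertainty_m, geospatial_issue`.
#' @export
gen_occurrences <- function(truths, n_per_species,
                            noise = list(bad_year = 0, bad_uncertainty = 0,
                                         geospatial_issue = 0),
                            seed = 1) {
  check_aligned(truths)
  cs <- truths[[1]]$cell_size
  nr <- nrow(truths[[1]]$values)
  with_seed(seed, {
    tabs <- lapply(names(truths), function(id) {
      w <- as.vector(truths[[id]]$values)
      if (sum(w) <= 0) return(NULL)
      cells <- sample.int(length(w), n_per_species, replace = TRUE, prob = w)
      row <- (cells - 1L) %% nr; col <- (cells - 1L) %/% nr
      n <- n_per_species
      year <- sample(1990:2021, n, replace = TRUE)
      uncertainty_m <- stats::runif(n, 0, 1000)
      issue <- rep(FALSE, n)
      bad <- noise_indices(n, noise[c("bad_year", "bad_uncertainty",
                                      "geospatial_issue")])
      if (length(bad$bad_year)) {
        year[bad$bad_year] <- sample(c(1960:1989, 2022:2026),
                                     length(bad$bad_year), replace = TRUE)
      }
      if (length(bad$bad_uncertainty)) {
        uncertainty_m[bad$bad_uncertainty] <-
          stats::runif(length(bad$bad_uncertainty), 1001, 5000)
      }
      issue[bad$geospatial_issue] <- TRUE
      data.frame(species_id = id, x = (col + 0.5) * cs, y = (row + 0.5) * cs,
                 year = year, uncertainty_m = uncertainty_m,
                 geospatial_issue = issue, stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs[!vapply(tabs, is.null, TRUE)])
  })
}

#' Generate noisy ordinal ecological indicator values (EIVs)
#'
#' For each driver variable, species are ranked by their true niche optimum
#' (optionally with inverted sign, emulating indicators such as moisture that
#' run opposite to groundwater-table depth), binned onto the ordinal scale,
#' perturbed with rounded Gaussian noise, and clipped to the scale.
#'
#' @param specs list of [species_spec()] (>= 2 species).
#' @param scale two-element ordinal range, default `c(1, 10)`.
#' @param sign `+1` or `-1`, scalar or named per variable.
#' @param noise_sd standard deviation of the ordinal noise.
#' @param seed integer seed.
#' @return data.frame `species_id, variable, eiv` (long form).
#' @export
gen_eivs <- function(specs, scale = c(1, 10), sign = 1, noise_sd = 0, seed = 1) {
  stopifnot(length(specs) >= 2, length(scale) == 2)
  if (scale[2] <= scale[1]) stop("degenerate ordinal scale")
  ids <- vapply(specs, `[[`, "", "species_id")
  vars <- unique(unlist(lapply(specs, function(s) names(s$optima))))
  levels_n <- scale[2] - scale[1] + 1
  with_seed(seed, {
    rows <- lapply(vars, function(v) {
      mu <- vapply(specs, function(s) {
        if (v %in% names(s$optima)) s$optima[[v]] else NA_real_
      }, 0)
      keep <- !is.na(mu)
      if (sum(keep) < 2) return(NULL)
      sg <- if (length(sign) > 1) sign[[v]] else sign
      r <- rank(sg * mu[keep], ties.method = "average")
      eiv0 <- scale[1] - 1 + ceiling(r / sum(keep) * levels_n)
      eiv <- eiv0 + round(stats::rnorm(sum(keep), 0, noise_sd))
      eiv <- pmin(pmax(eiv, scale[1]), scale[2])
      data.frame(species_id = ids[keep], variable = v, eiv = eiv,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  })
}
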