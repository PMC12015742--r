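# D8 neighbour geometry. Codes follow the ESRI powers-of-two convention with
# row index increasing southwards: 1=E, 2=SE, 4=S, 8=SW, 16=W, 32=NW, 64=N,
# 128=NE; 0 marks an outlet (flow leaves the grid).
D8_CODES <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- sqrt(D8_DR^2 + D8_DC^2)

#' Fill closed depressions in a DEM
#'
#' Monotone carving by iterated morphological reconstruction: starting from
#' the DEM on the grid boundary and +Inf inside, each cell is lowered towards
#' `max(dem, min(neighbours) + eps)` until stable. Every interior cell of the
#' result has a neighbour lower by at least `eps`, so steepest-descent flow
#' routing is guaranteed acyclic.
#'
#' @param dem a numeric `wet_raster`.
#' @param eps strict-descent increment (m).
#' @return a `wet_raster` with pits filled.
#' @export
fill_sinks <- function(dem, eps = 1e-4) {
  z <- dem$values
  stopifnot(all(is.finite(z)))
  nr <- nrow(z); nc <- ncol(z)
  w <- matrix(Inf, nr, nc)
  w[1, ] <- z[1, ]; w[nr, ] <- z[nr, ]; w[, 1] <- z[, 1]; w[, nc] <- z[, nc]
  pad <- function(m) {
    p <- matrix(Inf, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- m; p
  }
  repeat {
    p <- pad(w)
    nb_min <- matrix(Inf, nr, nc)
    for (k in seq_along(D8_DR)) {
      nb_min <- pmin(nb_min, p[(2:(nr + 1)) + D8_DR[k], (2:(nc + 1)) + D8_DC[k]])
    }
    w2 <- pmax(z, pmin(w, nb_min + eps))
    if (isTRUE(all.equal(w2, w, tolerance = 0))) break
    w <- w2
  }
  raster_layer(w, dem$cell_size, name = "dem_filled", units = dem$units)
}

#' Derive a D8 flow-direction grid from a DEM
#'
#' Pits are filled with [fill_sinks()], then each cell drains to the neighbour
#' with the steepest downward gradient (drop / distance, diagonals weighted by
#' sqrt(2)). Boundary cells without a lower in-grid neighbour are outlets
#' (code 0). The result is acyclic by construction, which is verified.
#'
#' @param dem a numeric `wet_raster`.
#' @return integer-coded `wet_raster` of D8 directions.
#' @export
d8_from_dem <- function(dem) {
  filled <- fill_sinks(dem)
  z <- filled$values
  nr <- nrow(z); nc <- ncol(z)
  p <- matrix(Inf, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- z
  best_grad <- matrix(0, nr, nc)
  code <- matrix(0L, nr, nc)
  for (k in seq_along(D8_CODES)) {
    nb <- p[(2:(nr + 1)) + D8_DR[k], (2:(nc + 1)) + D8_DC[k]]
    grad <- (z - nb) / D8_DIST[k]
    take <- is.finite(grad) & grad > best_grad
    best_grad[take] <- grad[take]
    code[take] <- D8_CODES[k]
  }
  flow <- raster_layer(code, dem$cell_size, name = "d8", units = "code")
  # internal consistency check: accumulation fails loudly on a cycle
  d8_accumulate(flow, raster_layer(matrix(1, nr, nc), dem$cell_size))
  flow
}

# Linear index (column-major) of each cell's downstream cell; NA for outlets.
# Errors if any direction code is invalid.
d8_downstream <- function(flow) {
  code <- flow$values
  nr <- nrow(code); nc <- ncol(code)
  idx <- seq_len(nr * nc)
  r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr
  k <- match(as.vector(code), D8_CODES)
  bad <- is.na(k) & as.vector(code) != 0L
  if (any(bad)) stop("invalid D8 direction code")
  r2 <- r + ifelse(is.na(k), 0L, D8_DR[k])
  c2 <- c + ifelse(is.na(k), 0L, D8_DC[k])
  down <- r2 + c2 * nr + 1L
  down[is.na(k)] <- NA_integer_
  off <- !is.na(k) & (r2 < 0 | r2 >= nr | c2 < 0 | c2 >= nc)
  down[off] <- NA_integer_
  down
}

#' Accumulate a weight raster down a D8 flow grid
#'
#' AreaD8 convention: each cell's accumulated value includes its own weight
#' plus the accumulation of every cell draining into it. Evaluated in
#' topological order; a cycle in the flow grid is an explicit failure.
#'
#' @param flow D8 `wet_raster` (codes 1..128, 0 = outlet).
#' @param weight non-negative numeric `wet_raster` aligned with `flow`.
#' @return a `wet_raster` of accumulated weights.
#' @export
d8_accumulate <- function(flow, weight) {
  check_aligned(list(flow, weight))
  stopifnot(all(weight$values >= 0, na.rm = TRUE))
  down <- d8_downstream(flow)
  n <- length(down)
  acc <- as.vector(weight$values)
  acc[is.na(acc)] <- 0
  indeg <- tabulate(down[!is.na(down)], nbins = n)
  queue <- which(indeg == 0L)
  head <- 1L; processed <- 0L
  queue <- c(queue, integer(n - length(queue)))
  tail <- sum(indeg == 0L)
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L; processed <- processed + 1L
    d <- down[i]
    if (!is.na(d)) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) {
        tail <- tail + 1L
        queue[tail] <- d
      }
    }
  }
  if (processed < n) stop("cycle detected in D8 flow grid")
  raster_layer(matrix(acc, nrow(flow$values)), flow$cell_size,
               name = "accumulation", units = weight$units)
}

#' Monthly potential evapotranspiration from monthly mean temperature
#'
#' Piecewise-linear in temperature: 0 for T <= 0 degC, 58.93 * T between 0 and
#' 30 degC, and capped at 58.93 * 30 for T >= 30 degC. Continuous at both
#' breakpoints, non-negative, and non-decreasing in T.
#'
#' @param t_m monthly mean temperature (degC); numeric vector/matrix or a
#'   `wet_raster`. `NA` (nodata) propagates.
#' @return PET in mm, same shape as the input.
#' @export
pet_monthly <- function(t_m) {
  if (inherits(t_m, "wet_raster")) {
    return(raster_map(pet_monthly, t_m, name = "pet", units = "mm"))
  }
  58.93 * pmin(pmax(t_m, 0), 30)
}

#' Annual climatic water balance
#'
#' Sum over the 12 months of precipitation minus potential evapotranspiration.
#'
#' @param climate list with `temp` and `prec`, each 12 aligned `wet_raster`
#'   layers (degC and mm).
#' @return water balance `wet_raster` (mm).
#' @export
water_balance <- function(climate) {
  stopifnot(length(climate$temp) == 12, length(climate$prec) == 12)
  check_aligned(c(climate$temp, climate$prec))
  wb <- 0
  for (m in 1:12) {
    wb <- wb + climate$prec[[m]]$values - pet_monthly(climate$temp[[m]]$values)
  }
  raster_layer(matrix(wb, nrow(climate$temp[[1]]$values)),
               climate$temp[[1]]$cell_size, name = "wb", units = "mm")
}

MONTH_LEN <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# 365 x 12 matrix of interpolation weights: daily temperature (at day centres
# d - 0.5, d = 1..365, non-leap year) as a linear interpolation between
# consecutive month midpoints, wrapping December -> January.
daily_interp_weights <- function() {
  mids <- cumsum(MONTH_LEN) - MONTH_LEN / 2
  anchors <- c(mids[12] - 365, mids, mids[1] + 365)  # periodic extension
  month_of <- c(12, 1:12, 1)
  days <- (1:365) - 0.5
  w <- matrix(0, 365, 12)
  for (d in seq_along(days)) {
    j <- findInterval(days[d], anchors)
    t <- (days[d] - anchors[j]) / (anchors[j + 1] - anchors[j])
    w[d, month_of[j]] <- w[d, month_of[j]] + (1 - t)
    w[d, month_of[j + 1]] <- w[d, month_of[j + 1]] + t
  }
  w
}

#' Annual growing degree days from monthly mean temperatures
#'
#' A 365-day daily series is built by linear interpolation between month
#' midpoints (non-leap calendar, wrapping December to January). Under the
#' default `"excess"` convention GDD is the annual sum of daily exceedances
#' over the base temperature, `sum(max(T_day - base, 0))` -- the standard
#' agro-climatological degree-day definition. The `"literal"` convention sums
#' the daily temperature values themselves on days with `T_day > base`.
#'
#' @param t_m 12 monthly mean temperatures (numeric vector), or a list of 12
#'   aligned `wet_raster` layers.
#' @param base base temperature (degC), default 5.
#' @param convention `"excess"` (default) or `"literal"`.
#' @return GDD (degC day): a number for vector input, a `wet_raster` for
#'   raster input.
#' @export
growing_degree_days <- function(t_m, base = 5, convention = c("excess", "literal")) {
  convention <- match.arg(convention)
  w <- daily_interp_weights()
  if (is.list(t_m)) {
    stopifnot(length(t_m) == 12)
    check_aligned(t_m)
    tm <- vapply(t_m, function(r) as.vector(r$values), numeric(length(t_m[[1]]$values)))
    daily <- w %*% t(tm)  # 365 x ncell
    gdd <- if (convention == "excess") colSums(pmax(daily - base, 0))
           else colSums(daily * (daily > base))
    return(raster_layer(matrix(gdd, nrow(t_m[[1]]$values)), t_m[[1]]$cell_size,
                        name = "gdd", units = "degC day"))
  }
  stopifnot(length(t_m) == 12, all(is.finite(t_m)))
  daily <- as.vector(w %*% t_m)
  if (convention == "excess") sum(pmax(daily - base, 0))
  else sum(daily[daily > base])
}

#' Water and wetness probability index
#'
#' `WWPI = (n_water + 0.75 * n_wet) / n_total * 100`, the weighted frequency
#' of water and wet observations per cell on a 0--100 scale. Cells with zero
#' valid observations become nodata.
#'
#' @param counts list with `n_water`, `n_wet`, `n_total` count rasters
#'   satisfying `n_water + n_wet <= n_total`.
#' @return WWPI `wet_raster` in \[0, 100\].
#' @export
wwpi <- function(counts) {
  check_aligned(counts[c("n_water", "n_wet", "n_total")])
  nw <- counts$n_water$values; nt <- counts$n_wet$values
  tot <- counts$n_total$values
  stopifnot(all(nw + nt <= tot, na.rm = TRUE),
            all(nw >= 0, na.rm = TRUE), all(nt >= 0, na.rm = TRUE))
  v <- (nw + 0.75 * nt) / tot * 100
  v[!is.na(tot) & tot == 0] <- NA_real_
  raster_layer(v, counts$n_water$cell_size, name = "wwpi", units = "")
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(beta))` with `a` the upstream contributing area per unit
#' contour width (D8-accumulated cell count times cell size) and `tan(beta)`
#' the slope towards the downstream cell, floored at `slope_floor` so flats
#' and outlets never divide by zero.
#'
#' @param dem a numeric `wet_raster`.
#' @param flow its D8 flow grid.
#' @param slope_floor minimum slope (default 1e-6).
#' @return TWI `wet_raster` (dimensionless).
#' @export
twi <- function(dem, flow, slope_floor = 1e-6) {
  check_aligned(list(dem, flow))
  cs <- dem$cell_size
  ones <- raster_layer(matrix(1, nrow(dem$values), ncol(dem$values)), cs)
  acc <- d8_accumulate(flow, ones)
  a <- acc$values * cs
  down <- d8_downstream(flow)
  z <- as.vector(dem$values)
  k <- match(as.vector(flow$values), D8_CODES)
  dist <- ifelse(is.na(k), cs, D8_DIST[k] * cs)
  drop <- ifelse(is.na(down), 0, z - z[ifelse(is.na(down), 1L, down)])
  tanb <- pmax(drop / dist, slope_floor)
  raster_layer(matrix(log(a / tanb), nrow(dem$values)), cs,
               name = "twi", units = "")
}

#' Binary anthropogenic land-cover mask
#'
#' Flags cells whose EUNIS-style land-cover code denotes arable land and
#' market gardens (class V1) or constructed/industrial habitats (class J).
#'
#' @param landcover a `wet_raster` with character class codes.
#' @param unknown handling of codes outside the documented vocabulary:
#'   `"zero"` (treat as non-anthropogenic) or `"warn"` (same, with a warning).
#' @return numeric 0/1 `wet_raster`.
#' @export
anthropogenic_mask <- function(landcover, unknown = c("zero", "warn")) {
  unknown <- match.arg(unknown)
  codes <- as.vector(landcover$values)
  known <- grepl("^(MA|[C-Z])[0-9]*$", codes) | is.na(codes)
  if (!all(known) && unknown == "warn") {
    warning("unknown land-cover code(s): ",
            paste(unique(codes[!known]), collapse = ", "))
  }
  v <- as.numeric(grepl("^V1", codes) | grepl("^J", codes))
  v[is.na(codes)] <- NA_real_
  raster_layer(matrix(v, nrow(landcover$values)), landcover$cell_size,
               name = "anthropogenic", units = "binary")
}

#' Upstream anthropogenic land cover
#'
#' Total area of anthropogenic land cover (see [anthropogenic_mask()]) in each
#' cell's upstream catchment, by D8 accumulation of the masked cell areas.
#'
#' @param landcover character-coded land-cover `wet_raster`.
#' @param flow D8 flow grid.
#' @param unknown passed to [anthropogenic_mask()].
#' @return `wet_raster` in km^2.
#' @export
upstream_alc <- function(landcover, flow, unknown = "zero") {
  mask <- anthropogenic_mask(landcover, unknown)
  area_km2 <- (landcover$cell_size / 1000)^2
  w <- raster_layer(mask$values * area_km2, landcover$cell_size,
                    units = "km2")
  out <- d8_accumulate(flow, w)
  out$name <- "alc"
  out
}

# Euclidean distance from points to a polyline segment set.
dist_to_polylines <- function(px, py, polylines) {
  d <- rep(Inf, length(px))
  for (line in polylines) {
    if (nrow(line) < 2) next
    for (s in seq_len(nrow(line) - 1)) {
      ax <- line[s, 1]; ay <- line[s, 2]
      bx <- line[s + 1, 1]; by <- line[s + 1, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
      d <- pmin(d, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
    }
  }
  d
}

#' Coastal salt-influence flag
#'
#' Flags cells whose centre lies within `radius` metres (inclusive, Euclidean
#' in projected grid coordinates) of the nearest coastline segment.
#'
#' @param template a `wet_raster` defining the grid.
#' @param coastline list of polyline vertex matrices (columns x, y, metres).
#' @param radius buffer distance in metres (default 3000).
#' @return 0/1 `wet_raster`; all zero when the coastline is empty.
#' @export
salt_flag <- function(template, coastline, radius = 3000) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cc <- cell_centres(nr, nc, template$cell_size)
  v <- if (length(coastline) == 0) rep(0, nr * nc) else {
    as.numeric(dist_to_polylines(cc$x, cc$y, coastline) <= radius)
  }
  raster_layer(matrix(v, nr), template$cell_size, name = "salt", units = "binary")
}
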