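#' Construct a sea-surface temperature grid
#'
#' @param sst numeric lat x lon matrix of SST in degrees C; `NA` = masked.
#' @param latitudes,longitudes numeric vectors matching the matrix
#'   dimensions.
#' @param period_label free-text period tag, e.g. `"1961-1990"`.
#' @param ice_mask logical lat x lon matrix; TRUE cells are ignored in all
#'   classifications (sea ice in the climatology).
#' @return list of class `climate_grid`.
#' @export
climate_grid <- function(sst, latitudes, longitudes, period_label = "",
                         ice_mask = NULL) {
  sst <- as.matrix(sst)
  if (length(latitudes) != nrow(sst) || length(longitudes) != ncol(sst)) {
    stop("sst must be a latitudes x longitudes matrix")
  }
  if (is.null(ice_mask)) ice_mask <- matrix(FALSE, nrow(sst), ncol(sst))
  ice_mask <- as.matrix(ice_mask)
  if (!all(dim(ice_mask) == dim(sst))) stop("ice_mask shape mismatch")
  rng <- range(sst[!is.na(sst)])
  if (length(rng) == 2 && (rng[1] < -2 - 1e-9 || rng[2] > 45 + 1e-9)) {
    stop("SST outside physical bounds [-2, 45] degrees C")
  }
  structure(list(sst = sst, latitudes = latitudes, longitudes = longitudes,
                 period_label = period_label, ice_mask = ice_mask),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells, period '%s', %d ice-masked\n",
              nrow(x$sst), ncol(x$sst), x$period_label, sum(x$ice_mask)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!all(dim(a$sst) == dim(b$sst)) ||
      !isTRUE(all.equal(a$latitudes, b$latitudes)) ||
      !isTRUE(all.equal(a$longitudes, b$longitudes))) {
    stop("grids disagree on shape or coordinates")
  }
  invisible(TRUE)
}

#' Delta-method bias correction of projected SST
#'
#' Adds the per-cell difference between the observed climatology and the
#' model's historical run to the model projection:
#' `corrected = proj + (obs - hist)`. Cells masked anywhere stay masked.
#'
#' @param obs_clim,model_hist,model_proj `climate_grid`s on identical grids.
#' @return corrected `climate_grid` carrying the projection's period label
#'   and the climatology's ice mask.
#' @export
bias_correct <- function(obs_clim, model_hist, model_proj) {
  check_same_grid(obs_clim, model_hist)
  check_same_grid(obs_clim, model_proj)
  corrected <- model_proj$sst + (obs_clim$sst - model_hist$sst)
  # correction can push cells slightly past the physical guard; clamp
  corrected[corrected < -2] <- -2
  corrected[corrected > 45] <- 45
  climate_grid(corrected, obs_clim$latitudes, obs_clim$longitudes,
               period_label = model_proj$period_label,
               ice_mask = obs_clim$ice_mask)
}

#' Breakpoint-defined temperature band thresholds
#'
#' The three beta-diversity breakpoints define four SST bands: blue below
#' the 16S breakpoint, yellow up to the 18S breakpoint, orange up to the
#' metatranscriptome (Pfam) breakpoint, red above it.
#'
#' @param t_16S,t_18S,t_pfam band thresholds in degrees C; must increase.
#' @return named numeric vector of class `band_thresholds`.
#' @export
band_thresholds <- function(t_16S = 9.49, t_18S = 13.96, t_pfam = 18.06) {
  if (!(t_16S < t_18S && t_18S < t_pfam)) {
    stop("thresholds must satisfy t_16S < t_18S < t_pfam")
  }
  structure(c(t_16S = t_16S, t_18S = t_18S, t_pfam = t_pfam),
            class = "band_thresholds")
}

band_levels <- c("blue", "yellow", "orange", "red")

#' Classify grid cells into breakpoint temperature bands
#'
#' Half-open upward intervals: blue `< t_16S`, yellow `[t_16S, t_18S)`,
#' orange `[t_18S, t_pfam)`, red `>= t_pfam`. Ice-masked and missing cells
#' come back `NA`.
#'
#' @param grid a `climate_grid`.
#' @param thresholds a [band_thresholds()].
#' @return character lat x lon matrix with values in
#'   blue/yellow/orange/red or `NA`.
#' @export
classify_bands <- function(grid, thresholds = band_thresholds()) {
  sst <- grid$sst
  out <- matrix(NA_character_, nrow(sst), ncol(sst))
  ok <- !is.na(sst) & !grid$ice_mask
  cls <- cut(sst[ok], breaks = c(-Inf, unname(thresholds), Inf),
             labels = band_levels, right = FALSE)
  out[ok] <- as.character(cls)
  out
}

#' Band composition and transitions within a latitude band
#'
#' Compares two band classifications (e.g. the observed climatology versus a
#' bias-corrected projection) inside a latitude window: the fraction of
#' unmasked cells per band in each period and the 4x4 band-transition
#' matrix.
#'
#' @param before,after character band matrices from [classify_bands()],
#'   identical shape.
#' @param latitudes latitude of each row.
#' @param lat_band `c(lat_min, lat_max)` window, e.g. `c(40, 60)` for the
#'   North Atlantic belt.
#' @return list with `fraction_before`, `fraction_after` (named, summing to
#'   1) and `transitions` (4x4 counts, rows = before).
#' @export
band_shift_summary <- function(before, after, latitudes,
                               lat_band = c(40, 60)) {
  if (!all(dim(before) == dim(after))) stop("band grids differ in shape")
  rows <- latitudes >= lat_band[1] & latitudes <= lat_band[2]
  if (!any(rows)) stop("no grid rows inside the latitude band")
  b <- factor(before[rows, ], levels = band_levels)
  a <- factor(after[rows, ], levels = band_levels)
  ok <- !is.na(b) & !is.na(a)
  if (!any(ok)) stop("no unmasked cells inside the latitude band")
  list(fraction_before = prop.table(table(b[ok])),
       fraction_after = prop.table(table(a[ok])),
       transitions = table(before = b[ok], after = a[ok]))
}

#' Southernmost latitude (northern hemisphere) of a band boundary
#'
#' Utility for the poleward-shift diagnostics: for one threshold, the lowest
#' northern latitude at which the zonal-mean SST drops below it.
#'
#' @param grid a `climate_grid`.
#' @param threshold degrees C.
#' @return latitude in degrees, or `NA` if the boundary is off-grid.
#' @export
band_boundary_latitude <- function(grid, threshold) {
  north <- grid$latitudes >= 0
  zonal <- rowMeans(grid$sst, na.rm = TRUE)
  lat <- grid$latitudes[north]
  z <- zonal[north]
  below <- lat[!is.na(z) & z < threshold]
  if (length(below) == 0) return(NA_real_)
  min(below)
}
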