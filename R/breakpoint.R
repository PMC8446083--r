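#' Altered latitude: a single pole-to-pole axis
#'
#' Recodes latitude so the North pole is 0 degrees, the Equator 90 and the
#' South pole 180, making a pole-to-pole transect monotone on one axis:
#' `altered = 90 - latitude`.
#'
#' @param latitude numeric, degrees in `[-90, 90]`.
#' @return degrees altered latitude in `[0, 180]`.
#' @export
altered_latitude <- function(latitude) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("latitude must lie in [-90, 90]")
  }
  90 - latitude
}

#' Presence-absence matrix
#'
#' @param table stations x features matrix.
#' @param threshold abundances strictly greater than this count as present
#'   (default 0).
#' @return binary matrix of the same shape.
#' @export
presence_absence <- function(table, threshold = 0) {
  validate_feature_table(table)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number")
  }
  (table > threshold) * 1
}

#' Pairwise Sorensen dissimilarity on a presence-absence matrix
#'
#' `beta_sor(i, j) = (b + c) / (2a + b + c)` with a = shared presences and
#' b, c the presences unique to each station.
#'
#' @param pa binary stations x features matrix, each station with at least
#'   one presence.
#' @return symmetric stations x stations matrix in `[0, 1]`, zero diagonal,
#'   attribute `metric = "sorensen"`.
#' @export
sorensen_matrix <- function(pa) {
  pa <- (as.matrix(pa) > 0) * 1
  rs <- rowSums(pa)
  if (any(rs == 0)) {
    stop("station(s) with no present feature: ",
         paste(rownames(pa)[rs == 0], collapse = ", "))
  }
  shared <- pa %*% t(pa)               # a for each pair
  tot <- outer(rs, rs, "+")            # 2a + b + c
  d <- (tot - 2 * shared) / tot
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  attr(d, "metric") <- "sorensen"
  d
}

#' Reduce a pairwise dissimilarity matrix to one beta value per station
#'
#' @param dist symmetric stations x stations dissimilarity matrix.
#' @param reduction `"mean"` (default): mean dissimilarity of the station to
#'   all others; `"nearest"`: dissimilarity to its most similar other
#'   station; `"adjacent"`: mean dissimilarity to the neighbouring stations
#'   in the order given by `order_by`.
#' @param order_by numeric vector (e.g. latitude) defining adjacency for
#'   `reduction = "adjacent"`.
#' @return named numeric vector, one value per station.
#' @export
station_beta <- function(dist, reduction = c("mean", "nearest", "adjacent"),
                         order_by = NULL) {
  reduction <- match.arg(reduction)
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 stations")
  off <- function(i) d[i, -i]
  out <- switch(reduction,
    mean = vapply(seq_len(n), function(i) mean(off(i)), numeric(1)),
    nearest = vapply(seq_len(n), function(i) min(off(i)), numeric(1)),
    adjacent = {
      if (is.null(order_by) || length(order_by) != n) {
        stop("'adjacent' reduction needs an order_by vector of length n")
      }
      ord <- order(order_by)
      pos <- match(seq_len(n), ord)
      vapply(seq_len(n), function(i) {
        nb <- ord[c(pos[i] - 1, pos[i] + 1)]
        nb <- nb[!is.na(nb) & nb >= 1 & nb <= n]
        mean(d[i, nb])
      }, numeric(1))
    })
  stats::setNames(out, rownames(d))
}

# Exact Tukey halfspace depth of each point of (x, y).
# depth(p) = min over closed halfplanes through p of the number of points in
# the halfplane (p itself included). Using the complement identity, that is
# m - max over half-open semicircles [a, a + pi) of the points inside, + 1,
# and the maximizing semicircle can start at a data angle.
halfspace_depths <- function(x, y) {
  n <- length(x)
  two_pi <- 2 * pi
  vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    dy <- y[-i] - y[i]
    coincident <- dx == 0 & dy == 0
    ang <- atan2(dy[!coincident], dx[!coincident])
    m <- length(ang)
    if (m == 0) return(n) # all points identical
    maxcount <- max(vapply(ang, function(a) {
      d <- (ang - a) %% two_pi
      sum(d < pi - 1e-9 | d > two_pi - 1e-9)
    }, numeric(1)))
    (m - maxcount) + sum(coincident) + 1
  }, numeric(1))
}

point_in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  # hull vertices (hx, hy) ordered (as from grDevices::chull); inside or on
  nh <- length(hx)
  if (nh == 1) return(abs(px - hx) < tol & abs(py - hy) < tol)
  if (nh == 2) {
    # degenerate segment
    cross <- (hx[2] - hx[1]) * (py - hy[1]) - (hy[2] - hy[1]) * (px - hx[1])
    along <- (px - hx[1]) * (hx[2] - hx[1]) + (py - hy[1]) * (hy[2] - hy[1])
    len2 <- (hx[2] - hx[1])^2 + (hy[2] - hy[1])^2
    return(abs(cross) < tol & along > -tol & along < len2 + tol)
  }
  inside <- rep(TRUE, length(px))
  for (k in seq_len(nh)) {
    k2 <- if (k == nh) 1L else k + 1L
    cross <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    # chull returns vertices clockwise; interior has cross <= 0
    inside <- inside & (cross <= tol * (abs(px) + abs(py) + 1))
  }
  inside
}

#' Bagplot-style bivariate outlier detection
#'
#' Flags two-dimensional outliers the way a bagplot does: the "bag" is the
#' convex hull of the 50% deepest points by exact Tukey halfspace depth, the
#' fence is the bag inflated by `factor` about the depth median, and points
#' outside the fence are outliers. Degenerate inputs (fewer than 10 points,
#' or collinear) flag nothing, with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param factor fence inflation factor (default 3, the bagplot convention).
#' @return logical vector, TRUE for outliers.
#' @export
bag_outliers <- function(x, y, factor = 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 10) {
    warning("fewer than 10 points; no outliers flagged")
    return(rep(FALSE, n))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite coordinates")
  cen <- cbind(x - mean(x), y - mean(y))
  if (qr(cen)$rank < 2) {
    warning("collinear points; no outliers flagged")
    return(rep(FALSE, n))
  }
  depth <- halfspace_depths(x, y)
  # depth median: centroid of the deepest points
  dm <- depth == max(depth)
  mx <- mean(x[dm]); my <- mean(y[dm])
  # bag: smallest depth region holding at least half the points
  ds <- sort(unique(depth), decreasing = TRUE)
  cum <- vapply(ds, function(d) sum(depth >= d), numeric(1))
  dbag <- ds[which(cum >= n / 2)[1]]
  in_bag <- depth >= dbag
  hull_idx <- grDevices::chull(x[in_bag], y[in_bag])
  hx <- x[in_bag][hull_idx]
  hy <- y[in_bag][hull_idx]
  # outside the inflated bag <=> the point shrunk toward the depth median by
  # 'factor' falls outside the bag hull
  qx <- mx + (x - mx) / factor
  qy <- my + (y - my) / factor
  !point_in_hull(qx, qy, hx, hy)
}

#' Minimum-MSE broken-stick (segmented) regression
#'
#' Fits the continuous broken-stick model
#' `y = b0 + b1 * x + b2 * max(0, x - psi)` for every candidate breakpoint
#' psi (midpoints between consecutive sorted unique x values inside
#' `search_range`, leaving at least `min_segment` points on each side) and
#' returns the fit with the lowest mean squared error. The p-value compares
#' the broken stick against the straight line by an F-test with two extra
#' parameters (psi and the slope change); because psi is unidentified under
#' the null this p-value is approximate (the Davies problem).
#'
#' @param x,y numeric vectors of equal length.
#' @param search_range optional `c(x_min, x_max)` window for psi (e.g. the
#'   7 to 29.02 degrees C window used for amplicon transects).
#' @param min_segment minimum points on each side of the breakpoint
#'   (default 3).
#' @return object of class `breakpoint_fit`: `psi`, `coefficients` (b0, b1,
#'   b2), `mse`, `p_value`, `n_used`, `search_range`, `candidates`.
#' @export
fit_breakpoint <- function(x, y, search_range = NULL, min_segment = 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * min_segment + 1) {
    stop("need at least ", 2 * min_segment + 1, " points")
  }
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("x is constant")
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  if (!is.null(search_range)) {
    mids <- mids[mids >= search_range[1] & mids <= search_range[2]]
  } else {
    search_range <- range(x)
  }
  mids <- mids[vapply(mids, function(p) {
    sum(x < p) >= min_segment && sum(x > p) >= min_segment
  }, logical(1))]
  if (length(mids) == 0) stop("no admissible breakpoint candidates in range")

  best <- NULL
  for (psi in mids) {
    h <- pmax(0, x - psi)
    fit <- stats::lm.fit(cbind(1, x, h), y)
    mse <- mean(fit$residuals^2)
    if (is.null(best) || mse < best$mse) {
      best <- list(psi = psi, coef = fit$coefficients, mse = mse,
                   rss = sum(fit$residuals^2))
    }
  }
  line <- stats::lm.fit(cbind(1, x), y)
  rss0 <- sum(line$residuals^2)
  df2 <- n - 4 # straight line has 2 params; broken stick adds psi and b2
  p_value <- if (df2 > 0 && best$rss > 0) {
    f <- ((rss0 - best$rss) / 2) / (best$rss / df2)
    stats::pf(f, 2, df2, lower.tail = FALSE)
  } else if (best$rss == 0 && rss0 > 0) 0 else 1

  structure(list(psi = best$psi,
                 coefficients = c(b0 = unname(best$coef[1]),
                                  b1 = unname(best$coef[2]),
                                  b2 = unname(best$coef[3])),
                 mse = best$mse, p_value = p_value, n_used = n,
                 search_range = search_range, candidates = mids),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> psi = %.3f (MSE %.4g, p = %.3g, n = %d, window [%.2f, %.2f])\n",
    x$psi, x$mse, x$p_value, x$n_used, x$search_range[1], x$search_range[2]))
  cat(sprintf("  y = %.4g + %.4g x + %.4g max(0, x - psi)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  invisible(x)
}

#' Gap-fill scenarios for missing transect regions
#'
#' Reconstructs beta-diversity values for stations in a data gap (e.g. a
#' missing North Atlantic block) from donor stations, mirroring the four
#' sensitivity scenarios: nearest station by latitude among all non-gap
#' stations, donors from one named region, from a second region, or from
#' both pooled. Latitude ties go to the northern donor.
#'
#' @param beta named numeric vector of per-station beta values (donors must
#'   be present; gap stations may be absent or NA).
#' @param env data frame with row names = station ids and a `latitude`
#'   column covering gaps and donors.
#' @param gap_stations station ids to fill.
#' @param strategy one of `"nearest_latitude"`, `"donor_region_a"`,
#'   `"donor_region_b"`, `"both_donors"`.
#' @param donors_a,donors_b station id vectors for the named donor regions.
#' @return named numeric vector: `beta` with gap stations filled.
#' @export
scenario_gap_fill <- function(beta, env, gap_stations,
                              strategy = c("nearest_latitude",
                                           "donor_region_a",
                                           "donor_region_b", "both_donors"),
                              donors_a = NULL, donors_b = NULL) {
  strategy <- match.arg(strategy)
  pool <- switch(strategy,
    nearest_latitude = setdiff(names(beta)[!is.na(beta)], gap_stations),
    donor_region_a = donors_a,
    donor_region_b = donors_b,
    both_donors = c(donors_a, donors_b))
  pool <- intersect(pool, names(beta)[!is.na(beta)])
  if (length(pool) == 0) stop("empty donor pool for strategy ", strategy)
  missing_env <- setdiff(c(gap_stations, pool), rownames(env))
  if (length(missing_env) > 0) {
    stop("stations missing from env: ", paste(missing_env, collapse = ", "))
  }
  out <- beta
  for (g in gap_stations) {
    dlat <- abs(env[pool, "latitude"] - env[g, "latitude"])
    best <- which(dlat == min(dlat))
    if (length(best) > 1) { # tie: northern donor
      best <- best[which.max(env[pool[best], "latitude"])]
    }
    out[g] <- beta[[pool[best]]]
  }
  out
}
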