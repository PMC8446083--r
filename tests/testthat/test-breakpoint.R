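test_that("altered latitude maps the poles and the printed breakpoint", {
  expect_equal(altered_latitude(90), 0)
  expect_equal(altered_latitude(0), 90)
  expect_equal(altered_latitude(37.833), 52.167, tolerance = 1e-12)
  expect_equal(altered_latitude(-90), 180)
  expect_error(altered_latitude(91), "latitude")
})

test_that("presence-absence uses a strict threshold", {
  m <- rbind(s1 = c(0, 5, 10), s2 = c(1, 0, 2))
  colnames(m) <- paste0("f", 1:3)
  tab <- feature_table(m)
  expect_equal(unname(presence_absence(tab)["s1", ]), c(0, 1, 1))
  expect_equal(presence_absence(tab, threshold = 5)["s1", "f2"], 0)
  expect_true(all(presence_absence(tab * 0) == 0))
  expect_error(presence_absence(tab, threshold = -1), "threshold")
})

test_that("Sorensen dissimilarity matches set counting and vegan", {
  pa <- rbind(s1 = c(1, 1, 1, 0), s2 = c(1, 1, 0, 1))
  colnames(pa) <- paste0("f", 1:4)
  d <- sorensen_matrix(pa)
  expect_equal(d["s1", "s2"], 2 / 6, tolerance = 1e-12)  # a=2, b=1, c=1
  same <- rbind(s1 = c(1, 0, 1), s2 = c(1, 0, 1))
  colnames(same) <- paste0("f", 1:3)
  expect_equal(sorensen_matrix(same)["s1", "s2"], 0)
  disj <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1))
  colnames(disj) <- paste0("f", 1:4)
  expect_equal(sorensen_matrix(disj)["s1", "s2"], 1)
  set.seed(10)
  pa <- matrix(rbinom(80, 1, 0.5), 8, 10,
               dimnames = list(paste0("s", 1:8), paste0("f", 1:10)))
  pa[rowSums(pa) == 0, 1] <- 1
  d <- sorensen_matrix(pa)
  expect_lt(max(abs(d - oracle_sorensen(pa))), 1e-12)
  expect_lt(max(abs(d - as.matrix(vegan::vegdist(pa, "bray")))), 1e-10)
  empty <- rbind(s1 = c(1, 0), s2 = c(0, 0))
  colnames(empty) <- paste0("f", 1:2)
  expect_error(sorensen_matrix(empty), "s2")
})

test_that("per-station beta reductions behave on degenerate geometries", {
  pa <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(1, 1, 0, 0),
              s4 = c(0, 0, 1, 1))
  colnames(pa) <- paste0("f", 1:4)
  d <- sorensen_matrix(pa)
  b <- station_beta(d)
  expect_equal(unname(b["s4"]), 1)
  expect_equal(unname(b["s1"]), 1 / 3, tolerance = 1e-12)
  ident <- d * 0
  dimnames(ident) <- dimnames(d)
  expect_true(all(station_beta(ident) == 0))
  expect_true(all(b >= 0 & b <= 1))
  bn <- station_beta(d, "nearest")
  expect_equal(unname(bn["s1"]), 0)
  expect_equal(unname(bn["s4"]), 1)
  lat <- c(10, 20, 30, 40)
  ba <- station_beta(d, "adjacent", order_by = lat)
  expect_equal(unname(ba["s1"]), 0)          # one neighbour, identical
  expect_equal(unname(ba["s3"]), 0.5)        # neighbours s2 (0) and s4 (1)
  expect_error(station_beta(d[1:2, 1:2]), "at least 3")
  expect_error(station_beta(d, "adjacent"), "order_by")
})

test_that("bag outliers flag extreme points and match the depth oracle", {
  set.seed(11)
  x <- runif(30); y <- runif(30)   # tight, light-tailed cluster
  x[31] <- 100; y[31] <- 100
  flags <- bag_outliers(x, y)
  expect_true(flags[31])
  expect_equal(sum(flags), 1)

  gx <- rep(1:5, 5); gy <- rep(1:5, each = 5)
  expect_false(any(bag_outliers(gx, gy)))

  expect_warning(bag_outliers(1:5, 1:5 * 2), "fewer than 10")
  expect_warning(out <- bag_outliers(1:20, 2 * (1:20) + 3), "collinear")
  expect_false(any(out))

  set.seed(12)
  x <- rnorm(200); y <- rnorm(200)
  flags <- bag_outliers(x, y)
  expect_lt(mean(flags), 0.05)
  # the exact depths behind the bag agree with pair-direction enumeration
  depths <- poleward:::halfspace_depths(x[1:40], y[1:40])
  od <- vapply(1:40, function(i)
    oracle_halfspace_depth(x[i], y[i], x[1:40], y[1:40]), numeric(1))
  expect_equal(depths, od)
})

test_that("broken-stick search matches the exhaustive oracle and recovers kinks", {
  # noiseless planted stick: slope 0.5 then -0.2 after x = 10
  x <- seq(0, 20, by = 0.5)
  y <- 1 + 0.5 * x + ifelse(x > 10, -0.7 * (x - 10), 0)
  fit <- fit_breakpoint(x, y)
  expect_lt(abs(fit$psi - 10), 0.25 + 1e-9)   # within half the grid spacing
  expect_equal(unname(fit$coefficients["b2"]), -0.7, tolerance = 0.01)
  expect_lt(fit$p_value, 1e-10)

  # straight line plus noise: no significant breakpoint
  set.seed(13)
  xs <- runif(50, 0, 10)
  ys <- 2 + 0.3 * xs + rnorm(50, 0, 0.5)
  expect_gt(fit_breakpoint(xs, ys)$p_value, 0.05)

  # equality with an independently coded exhaustive candidate loop
  for (s in 1:10) {
    set.seed(100 + s)
    xr <- runif(30, 0, 10)
    yr <- rnorm(30)
    f <- fit_breakpoint(xr, yr)
    o <- oracle_breakpoint(xr, yr)
    expect_equal(f$psi, o$psi, tolerance = 1e-12)
    expect_equal(f$mse, o$mse, tolerance = 1e-12)
  }

  # invariances: shift in y; scale in x (noisy data, no candidate ties)
  f0 <- fit_breakpoint(xs, ys)
  f1 <- fit_breakpoint(xs, ys + 100)
  expect_equal(f0$psi, f1$psi)
  f2 <- fit_breakpoint(3 * xs, ys)
  expect_equal(f2$psi, 3 * f0$psi, tolerance = 1e-9)

  expect_error(fit_breakpoint(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_breakpoint(1:5, rnorm(5)), "at least")
})

test_that("the planted transect breakpoint is recovered end to end", {
  sim <- simulate_transect(transect_config(threshold_T = 14, noise_sd = 0.2,
                                           seed = 7))
  t18 <- sim$tables$taxon_18S
  keep <- rowSums(t18 > 0) > 0
  beta <- station_beta(sorensen_matrix(presence_absence(t18)[keep, ]),
                       "adjacent", order_by = sim$env$latitude[keep])
  x <- sim$env$temperature[keep]
  out <- suppressWarnings(bag_outliers(x, beta))
  fit <- fit_breakpoint(x[!out], beta[!out], search_range = c(7, 29.02))
  expect_lt(abs(fit$psi - 14), 1.5)
  expect_equal(fit$n_used + sum(out), length(x))
  expect_true(fit$psi >= 7 && fit$psi <= 29.02)
})

test_that("gap-fill scenarios use latitude donors with a northern tie-break", {
  env <- data.frame(latitude = c(60, 50, 40, 30, 20),
                    row.names = paste0("s", 1:5))
  beta <- setNames(c(0.5, NA, 0.3, NA, 0.1), rownames(env))
  # s2 (lat 50) equidistant from s1 (60) and s3 (40): northern donor wins
  filled <- scenario_gap_fill(beta, env, c("s2", "s4"), "nearest_latitude")
  expect_equal(unname(filled["s2"]), 0.5)
  expect_equal(unname(filled["s4"]), 0.3)    # s3 at 40 closer than s5 at 20
  one <- scenario_gap_fill(beta, env, c("s2", "s4"), "donor_region_a",
                           donors_a = "s5")
  expect_equal(unname(one[c("s2", "s4")]), c(0.1, 0.1))
  expect_error(scenario_gap_fill(beta, env, "s2", "donor_region_b"),
               "empty donor pool")

  # four scenarios on a masked mid-latitude block of a single-hemisphere
  # transect (no mirror stations to re-supply the gap) give distinct fits
  sim <- simulate_transect(transect_config(seed = 9, hemisphere = "north"))
  t16 <- sim$tables$taxon_16S
  beta_all <- station_beta(sorensen_matrix(presence_absence(t16)),
                           "adjacent", order_by = sim$env$latitude)
  gap <- rownames(sim$env)[sim$env$latitude > 20 & sim$env$latitude < 55]
  arctic <- rownames(sim$env)[sim$env$latitude >= 66]
  tropics <- rownames(sim$env)[sim$env$latitude <= 20]
  masked <- beta_all
  masked[gap] <- NA
  psis <- vapply(
    c("nearest_latitude", "donor_region_a", "donor_region_b",
      "both_donors"),
    function(strat) {
      filled <- scenario_gap_fill(masked, sim$env, gap, strat,
                                  donors_a = arctic, donors_b = tropics)
      fit_breakpoint(sim$env$temperature, unname(filled[rownames(sim$env)]),
                     search_range = c(7, 29.02))$psi
    }, numeric(1))
  expect_true(all(psis >= 7 & psis <= 29.02))
  expect_gte(length(unique(round(psis, 2))), 2)
})
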