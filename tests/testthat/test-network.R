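test_that("soft adjacency is the powered absolute correlation", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(1, 3, 2), f3 = c(3, 2, 1))
  rownames(m) <- paste0("s", 1:3)
  a <- soft_adjacency(feature_table(m), beta = 11, log_transform = FALSE)
  expect_equal(a["f1", "f3"], 1)            # r = -1, |r|^11 = 1
  expect_equal(a["f1", "f2"], 0.5^11, tolerance = 1e-12)
  expect_equal(unname(diag(a)), rep(1, 3))
  s <- soft_adjacency(feature_table(m), beta = 2, log_transform = FALSE,
                      type = "signed")
  expect_equal(s["f1", "f3"], 0)            # signed: ((1 + -1)/2)^2
  m0 <- cbind(m, flat = c(1, 1, 1))
  expect_error(soft_adjacency(feature_table(m0), 11, log_transform = FALSE),
               "flat")
})

test_that("TOM matches the brute-force triple loop", {
  n <- 5
  a0 <- diag(n)
  expect_equal(tom_matrix(a0), diag(n))
  a1 <- matrix(1, n, n)
  expect_true(all(abs(tom_matrix(a1) - 1) < 1e-12))
  set.seed(6)
  for (i in 1:25) {
    k <- sample(5:8, 1)
    a <- matrix(runif(k * k), k)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("f", 1:k), paste0("f", 1:k))
    expect_lt(max(abs(tom_matrix(a) - oracle_tom(a))), 1e-12)
  }
  tom <- tom_matrix(a)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(tom, t(tom))
  expect_error(tom_matrix(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
})

test_that("module detection recovers planted blocks and degenerate cuts", {
  sim <- simulate_transect(transect_config(seed = 3))
  pf <- sim$tables$pfam
  cfg <- network_config(soft_power = 12, min_module_size = 30)
  tom <- tom_matrix(soft_adjacency(pf, 12))
  labels <- detect_modules(tom, cfg)
  truth <- sim$truth$module_membership[names(labels)]
  expect_length(setdiff(unique(labels), "grey"), 2)
  # each detected module aligns with one planted regime
  for (mod in setdiff(unique(labels), "grey")) {
    expect_equal(length(unique(truth[labels == mod])), 1L)
  }
  # identity TOM: no similarity, everything grey
  idtom <- diag(10)
  dimnames(idtom) <- list(paste0("f", 1:10), paste0("f", 1:10))
  expect_true(all(detect_modules(idtom, network_config(min_module_size = 3))
                  == "grey"))
  # cut height 1.0 merges everything into one module
  one <- detect_modules(tom, network_config(soft_power = 12,
                                            cut_height = 1.0,
                                            min_module_size = 30))
  expect_length(setdiff(unique(one), "grey"), 1)
  expect_warning(detect_modules(idtom, network_config(min_module_size = 30)),
                 "min_module_size")
})

test_that("module eigengene equals the leading singular vector", {
  set.seed(8)
  base <- rnorm(20)
  m <- cbind(a = base, b = base * 2 + 5)   # identical after standardizing
  rownames(m) <- paste0("s", 1:20)
  m <- m - min(m) + 1
  labels <- c(a = "blue", b = "blue")
  e <- module_eigengene(feature_table(m), labels, "blue",
                        log_transform = FALSE)
  zs <- scale(m[, 1])[, 1]  # the shared standardized profile
  expect_equal(unname(e), unname(zs), tolerance = 1e-10)
  expect_gt(cor(e, m[, 1]), 0.999)

  # member and its negation: orientation deterministic, |cor| = 1
  m2 <- cbind(a = base, b = -base)
  rownames(m2) <- paste0("s", 1:20)
  m2 <- m2 - min(m2) + 1
  e2 <- module_eigengene(feature_table(m2), c(a = "x", b = "x"), "x",
                         log_transform = FALSE)
  expect_equal(abs(cor(e2, m2[, 1])), 1, tolerance = 1e-10)
  e2b <- module_eigengene(feature_table(m2), c(a = "x", b = "x"), "x",
                          log_transform = FALSE)
  expect_identical(e2, e2b)

  # random block: matches dense SVD up to sign; invariant to reordering
  x <- matrix(rexp(20 * 5), 20, 5,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
  lab <- setNames(rep("m", 5), colnames(x))
  e3 <- module_eigengene(feature_table(x), lab, "m", log_transform = FALSE)
  sv <- svd(scale(x))
  u1 <- sv$u[, 1] / sd(sv$u[, 1])
  expect_lt(min(max(abs(e3 - u1)), max(abs(e3 + u1))), 1e-10)
  perm <- sample(5)
  e4 <- module_eigengene(feature_table(x[, perm]), lab[perm], "m",
                         log_transform = FALSE)
  expect_equal(e3, e4, tolerance = 1e-10)
  expect_error(module_eigengene(feature_table(x), lab, "nope"), "nope")
})

test_that("module-trait correlation reproduces the t-distribution p-value", {
  set.seed(9)
  n <- 20
  env <- data.frame(temperature = rnorm(n), row.names = paste0("s", 1:n))
  eg <- matrix(rnorm(n), ncol = 1,
               dimnames = list(paste0("s", 1:n), "blue"))
  out <- module_trait_correlation(eg, env)
  ct <- cor.test(eg[, 1], env$temperature)
  expect_equal(out$r[1, 1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p[1, 1], ct$p.value, tolerance = 1e-12)
  # the printed formula at r = 0.5, n = 20
  r <- 0.5
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t, 2.4495, tolerance = 1e-4)
  expect_equal(2 * pt(t, n - 2, lower.tail = FALSE), 0.0247,
               tolerance = 5e-3)
  expect_error(module_trait_correlation(eg[1:3, , drop = FALSE],
                                        env[1:3, , drop = FALSE]),
               "at least 4")
})

test_that("planted module eigengenes carry the expected temperature signs", {
  for (s in 1:3) {
    sim <- simulate_transect(transect_config(seed = s))
    pf <- sim$tables$pfam
    labels <- sim$truth$module_membership[colnames(pf)]
    ew <- module_eigengene(pf, labels, "warm")
    ec <- module_eigengene(pf, labels, "cold")
    expect_gt(cor(ew, sim$env$temperature), 0)
    expect_lt(cor(ec, sim$env$temperature), 0)
    # nutrients correlate opposite to the warm module
    expect_lt(cor(ew, sim$env$nitrate_nitrite), 0)
  }
})

test_that("node geography maps the module abundance pool", {
  m <- rbind(s1 = c(4, 6), s2 = c(0, 0), s3 = c(0, 0))
  colnames(m) <- c("a", "b")
  lab <- c(a = "blue", b = "blue")
  g <- node_geography(feature_table(m), lab, "blue")
  expect_equal(unname(g), c(100, 0, 0))
  m2 <- rbind(s1 = c(1, 1), s2 = c(1, 1), s3 = c(1, 1), s4 = c(1, 1))
  colnames(m2) <- c("a", "b")
  g2 <- node_geography(feature_table(m2), lab, "blue")
  expect_equal(unname(g2), rep(25, 4))
  expect_equal(sum(g2), 100)
  # planted cold module concentrates below the threshold temperature
  sim <- simulate_transect(transect_config(seed = 4))
  t16 <- sim$tables$taxon_16S
  lab16 <- sim$truth$module_membership[colnames(t16)]
  gc <- node_geography(t16, lab16, "cold")
  expect_gt(sum(gc[sim$env$temperature < sim$truth$threshold_T]), 80)
})
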