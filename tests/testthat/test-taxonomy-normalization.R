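test_that("copy-number regression matches closed-form OLS and known lines", {
  # exact collinear data
  g <- c(1, 10, 100, 1000)
  fit <- suppressWarnings( # lm warns that a perfect fit is "unreliable"
    fit_copy_number_model(g, 10^(2 * log10(g) + 1)))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(42)
  g <- 10^rnorm(500, 1.5, 0.5)
  cp <- 10^(0.66 * log10(g) + 0.75 + rnorm(500, 0, 0.3))
  fit <- fit_copy_number_model(g, cp)
  o <- oracle_ols_log10(g, cp)
  expect_equal(fit$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-12)
  expect_lt(abs(fit$slope - 0.66), 3 * o$se_slope)

  expect_error(fit_copy_number_model(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_copy_number_model(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("copy-number prediction evaluates and inverts the power law", {
  flat <- list(slope = 0, intercept = 0)
  expect_equal(predict_copy_number(flat, 123), 1)
  m <- list(slope = 0.66, intercept = 0.75)
  expect_equal(predict_copy_number(m, 100), 10^(0.66 * 2 + 0.75),
               tolerance = 1e-12)
  expect_equal(predict_copy_number(m, 100), 117.49, tolerance = 1e-4)
  # algebraic inverse recovers the genome size
  g <- c(0.5, 7, 3200)
  cp <- predict_copy_number(m, g)
  expect_equal((log10(cp) - 0.75) / 0.66, log10(g), tolerance = 1e-12)
  expect_error(predict_copy_number(m, -1), "positive")
})

test_that("strain entries average to one copy number per species", {
  out <- average_copy_numbers_by_species(c("A", "A"), c(2, 4))
  expect_equal(unname(out["A"]), 3)
  expect_equal(unname(average_copy_numbers_by_species("B", 7)["B"]), 7)
  set.seed(7)
  sp <- sample(letters, 1000, replace = TRUE)
  cp <- runif(1000, 1, 15)
  out <- average_copy_numbers_by_species(sp, cp)
  for (s in unique(sp)) {
    naive <- mean(cp[sp == s])
    expect_equal(unname(out[s]), naive, tolerance = 1e-12)
  }
  expect_error(average_copy_numbers_by_species(character(), numeric()),
               "no copy-number entries")
})

test_that("attribute propagation averages children bottom-up", {
  tax <- data.frame(
    node_id = c("root", "g1", "s1", "s2", "c1", "s3"),
    parent_id = c("root", "root", "g1", "g1", "root", "c1"),
    rank = c("root", "genus", "species", "species", "class", "species"),
    name = c("r", "g1", "s1", "s2", "c1", "s3"))
  out <- propagate_attribute_up(tax, c(s1 = 2, s2 = 4, s3 = 5))
  expect_equal(unname(out["g1"]), 3)
  expect_equal(unname(out["c1"]), 5)   # chain: every ancestor gets 5
  expect_equal(unname(out["root"]), mean(c(3, 5)))

  # random 3-level tree against a recursive brute-force oracle
  set.seed(11)
  genera <- sprintf("g%02d", 1:6)
  species <- sprintf("s%02d", 1:30)
  parent <- sample(genera, 30, replace = TRUE)
  tax <- rbind(
    data.frame(node_id = "root", parent_id = "root", rank = "root",
               name = "root"),
    data.frame(node_id = genera, parent_id = "root", rank = "genus",
               name = genera),
    data.frame(node_id = species, parent_id = parent, rank = "species",
               name = species))
  vals <- setNames(runif(30, 1, 9), species)
  out <- propagate_attribute_up(tax, vals)
  for (g in genera) {
    kids <- species[parent == g]
    if (length(kids) == 0) {
      expect_false(g %in% names(out))
    } else {
      expect_equal(unname(out[g]), mean(vals[kids]), tolerance = 1e-12)
    }
  }
  expect_true(all(out >= min(vals) - 1e-12 & out <= max(vals) + 1e-12))
  expect_error(propagate_attribute_up(tax, c(zz = 1)), "absent")
})

test_that("imputation walks to the nearest valued ancestor", {
  tax <- data.frame(
    node_id = c("root", "fam", "gen", "spA", "spB", "spC"),
    parent_id = c("root", "root", "fam", "gen", "gen", "fam"),
    rank = c("root", "family", "genus", "species", "species", "species"),
    name = c("r", "f", "g", "a", "b", "c"))
  # genus average available
  out <- impute_missing_attribute(tax, c(spA = 3), c("spA", "spB"))
  expect_equal(unname(out["spB"]), 3)
  # genus empty, family level carries the value
  out <- impute_missing_attribute(tax, c(spC = 7), c("spA", "spB"))
  expect_equal(unname(out[c("spA", "spB")]), c(7, 7))
  expect_error(impute_missing_attribute(tax, c(spA = 1), "nope"), "absent")

  # 30% masked synthetic tree equals a per-node path-walk oracle
  sim <- simulate_transect(transect_config(seed = 8))
  ref <- sim$reference
  known <- setNames(ref$genome_size_Mbp[!is.na(ref$genome_size_Mbp)],
                    ref$name[!is.na(ref$genome_size_Mbp)])
  targets <- ref$name
  out <- impute_missing_attribute(sim$taxonomy, known, targets)
  prop <- propagate_attribute_up(sim$taxonomy, known)
  for (id in setdiff(targets, names(known))) {
    lin <- taxonomy_lineage(sim$taxonomy, id)[-1]
    anc <- lin[lin %in% names(prop)][1]
    expect_equal(unname(out[id]), unname(prop[anc]), tolerance = 1e-12)
  }
  expect_true(all(out[names(known)] == known))
})

test_that("copy-number division rescales each feature column", {
  tab <- random_feature_table(4, 3, seed = 1)
  expect_equal(unclass(normalize_by_copy_number(
    tab, setNames(rep(1, 3), colnames(tab)))), unclass(tab))
  cp <- setNames(c(2, 5, 10), colnames(tab))
  out <- normalize_by_copy_number(tab, cp)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(out[i, j], tab[i, j] / cp[[j]], tolerance = 1e-12)
  }
  expect_error(normalize_by_copy_number(tab, cp[-1]), "no copy number")
  cp["f001"] <- 0
  expect_error(normalize_by_copy_number(tab, cp), "f001")
})

test_that("hits per million rescales rows exactly and idempotently", {
  m <- matrix(c(1, 1, 2), 1, dimnames = list("s1", c("a", "b", "c")))
  out <- hits_per_million(feature_table(m))
  expect_equal(as.vector(out), c(250000, 250000, 500000))
  tab <- random_feature_table(6, 9, seed = 3)
  out <- hits_per_million(tab)
  expect_equal(unname(rowSums(out)), rep(1e6, 6), tolerance = 1e-6)
  expect_equal(unclass(hits_per_million(out)), unclass(out),
               tolerance = 1e-12)
  m2 <- rbind(m, s2 = c(0, 0, 0))
  expect_error(hits_per_million(feature_table(m2)), "s2")
})

test_that("rank aggregation applies the Nc./U. rules and conserves totals", {
  tax <- fixture_taxonomy()
  m <- matrix(c(5, 3, 2, 4, 10, 6),
              nrow = 1,
              dimnames = list("st1", c("cercozoa", "gromiidae",
                                       "unclass_rhiz", "rhizaria",
                                       "chlamy_s", "root")))
  out <- aggregate_to_rank(feature_table(m), tax, "class",
                           rank_order = c("species", "genus", "class",
                                          "phylum"))
  # no class under Rhizaria: leaves summed as Nc., phylum node itself as U.
  expect_equal(out[1, "Nc. Rhizaria"], 5 + 3 + 2)
  expect_equal(out[1, "U. Rhizaria"], 4)
  expect_equal(out[1, "Chlorophyceae"], 10)
  expect_equal(attr(out, "dropped_fraction"), 6 / sum(m))
  expect_equal(sum(out) + 6, sum(m))

  # already at the target rank with complete lineage: unchanged
  m2 <- matrix(c(8, 2), 1, dimnames = list("st1", c("chlorophyceae",
                                                    "chlamy_g")))
  out2 <- aggregate_to_rank(feature_table(m2), tax, "class",
                            rank_order = c("species", "genus", "class",
                                           "phylum"))
  expect_equal(out2[1, "Chlorophyceae"], 10)

  expect_error(aggregate_to_rank(
    feature_table(matrix(1, 1, 1, dimnames = list("s", "missing_node"))),
    tax, "class"), "absent")
})

test_that("normalize-then-aggregate conserves relative structure on transects", {
  sim <- simulate_transect(transect_config(seed = 10))
  t18 <- sim$tables$taxon_18S
  known <- sim$reference[!is.na(sim$reference$genome_size_Mbp), ]
  model <- fit_copy_number_model(known$genome_size_Mbp, known$copy_number)
  gsz <- impute_missing_attribute(
    sim$taxonomy, setNames(known$genome_size_Mbp, known$name),
    colnames(t18))
  cp <- predict_copy_number(model, gsz)
  norm <- hits_per_million(normalize_by_copy_number(t18, cp))
  expect_equal(unname(rowSums(norm)), rep(1e6, nrow(norm)),
               tolerance = 1e-6)
  agg <- aggregate_to_rank(norm, sim$taxonomy, "class",
                           rank_order = c("species", "genus", "class",
                                          "domain"))
  expect_equal(sum(agg) + attr(agg, "dropped_fraction") * sum(norm),
               sum(norm), tolerance = 1e-6)
})
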