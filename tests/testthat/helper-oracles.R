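# Independent oracles used across the suite. Each is deliberately written
# the slow, literal way (loops, per-pair set counting, brute-force
# enumeration) so it shares no code path with the package implementation.

oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

oracle_sorensen <- function(pa) {
  n <- nrow(pa)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- which(pa[i, ] > 0)
    sj <- which(pa[j, ] > 0)
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    d[i, j] <- if (i == j) 0 else (b + cc) / (2 * a + b + cc)
  }
  d
}

oracle_bray <- function(tab) {
  n <- nrow(tab)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (k in seq_len(ncol(tab))) {
      num <- num + abs(tab[i, k] - tab[j, k])
      den <- den + tab[i, k] + tab[j, k]
    }
    d[i, j] <- num / den
  }
  d
}

# closed-form simple OLS on log10 scale
oracle_ols_log10 <- function(g, cp) {
  x <- log10(g); y <- log10(cp)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  se_slope <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  list(slope = slope, intercept = intercept, r_squared = r2,
       se_slope = se_slope)
}

# Tukey halfspace depth by enumeration over directions normal to lines
# through the query point and every other point (plus tiny rotations to
# resolve boundary ties)
# the cloud (x, y) includes the query point itself
oracle_halfspace_depth <- function(px, py, x, y) {
  dx <- x - px; dy <- y - py
  keep <- !(dx == 0 & dy == 0)
  ndup <- sum(!keep) # the query point and any duplicates of it
  if (!any(keep)) return(length(x))
  dirs <- atan2(dy[keep], dx[keep]) + pi / 2
  dirs <- c(dirs, dirs + 1e-7, dirs - 1e-7, dirs + pi)
  best <- Inf
  for (a in dirs) {
    u <- c(cos(a), sin(a))
    cnt <- sum(dx[keep] * u[1] + dy[keep] * u[2] >= -1e-12)
    best <- min(best, cnt)
  }
  best + ndup
}

# exhaustive broken-stick search, independently coded with lm()
oracle_breakpoint <- function(x, y, search_range = NULL, min_segment = 3) {
  ux <- sort(unique(x))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  if (!is.null(search_range)) {
    mids <- mids[mids >= search_range[1] & mids <= search_range[2]]
  }
  mids <- Filter(function(p) sum(x < p) >= min_segment &&
                   sum(x > p) >= min_segment, mids)
  fits <- lapply(mids, function(p) {
    f <- lm(y ~ x + I(pmax(0, x - p)))
    list(psi = p, mse = mean(residuals(f)^2), coef = coef(f))
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "mse"))]]
}

oracle_cca_fraction <- function(Y, env) {
  Y <- as.matrix(Y)
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  z <- env - sum(r * env)
  xv <- sqrt(r) * z
  xv <- xv / sqrt(sum(xv^2))
  sum((t(Qbar) %*% xv)^2) / sum(Qbar^2)
}

# small fixture taxonomy: root -> phylum -> class -> genus -> species,
# with a Rhizaria-style phylum whose children skip the class rank
fixture_taxonomy <- function() {
  data.frame(
    node_id = c("root",
                "rhizaria", "cercozoa", "gromiidae", "unclass_rhiz",
                "chlorophyta", "chlorophyceae", "chlamy_g", "chlamy_s"),
    parent_id = c("root",
                  "root", "rhizaria", "rhizaria", "rhizaria",
                  "root", "chlorophyta", "chlorophyceae", "chlamy_g"),
    rank = c("root",
             "phylum", "no rank", "no rank", "no rank",
             "phylum", "class", "genus", "species"),
    name = c("cellular organisms",
             "Rhizaria", "Cercozoa", "Gromiidae", "unclassified Rhizaria",
             "Chlorophyta", "Chlorophyceae", "Chlamydomonas",
             "C. reinhardtii"),
    stringsAsFactors = FALSE)
}

random_feature_table <- function(n_stations, n_features, seed,
                                 kind = "taxon_16S") {
  set.seed(seed)
  m <- matrix(rexp(n_stations * n_features, 1 / 50), n_stations, n_features,
              dimnames = list(sprintf("st%02d", seq_len(n_stations)),
                              sprintf("f%03d", seq_len(n_features))))
  feature_table(m, kind)
}
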