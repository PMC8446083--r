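#' Shannon diversity index H' (natural log)
#'
#' `H' = -sum(p_i * ln p_i)` over features with positive abundance, where
#' `p_i` is the relative abundance of feature i in the sample.
#'
#' @param counts non-negative numeric vector with positive total.
#' @return H' in nats.
#' @export
shannon <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero abundance vector")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-feature occupancy and dispersion evenness across stations
#'
#' For each feature: occupancy is the number of stations where it occurs, and
#' the dispersion index is Pielou-style evenness of its abundance across the
#' occupied stations, `J = H' / ln(occupancy)`, defined as 1 when the feature
#' occurs at a single station (a point mass is trivially even over one site).
#'
#' @param table stations x features matrix.
#' @return data frame with columns `feature`, `occupancy`, `dispersion`,
#'   `total_abundance`.
#' @export
dispersion_evenness <- function(table) {
  validate_feature_table(table)
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty feature table")
  occ <- colSums(table > 0)
  disp <- vapply(seq_len(ncol(table)), function(j) {
    v <- table[, j]
    s <- sum(v > 0)
    if (s <= 1) return(1)
    shannon(v) / log(s)
  }, numeric(1))
  data.frame(feature = colnames(table),
             occupancy = as.integer(occ),
             dispersion = disp,
             total_abundance = colSums(table),
             row.names = NULL)
}

#' Pairwise Bray-Curtis dissimilarity between stations
#'
#' `BC_ij = sum_k |n_ik - n_jk| / sum_k (n_ik + n_jk)` — the ratio-of-sums
#' form. Note Bray-Curtis is a semimetric: the triangle inequality may fail.
#'
#' @param table stations x features matrix with positive row sums.
#' @return symmetric stations x stations matrix in `[0, 1]`, zero diagonal,
#'   with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table) {
  validate_feature_table(table)
  rs <- rowSums(table)
  if (any(rs <= 0)) {
    stop("zero-sum station(s): ",
         paste(rownames(table)[rs <= 0], collapse = ", "))
  }
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(table[i, ] - table[j, ]))
      den <- rs[i] + rs[j]
      d[i, j] <- d[j, i] <- num / den
    }
  }
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Hellinger transform of an abundance table
#'
#' Each cell becomes the square root of its within-station relative
#' abundance, so every row has unit Euclidean norm.
#'
#' @param table stations x features matrix with positive row sums.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(table) {
  validate_feature_table(table)
  rs <- rowSums(table)
  if (any(rs <= 0)) {
    stop("zero-sum station(s): ",
         paste(rownames(table)[rs <= 0], collapse = ", "))
  }
  sqrt(sweep(table, 1, rs, "/"))
}

#' Backward covariate selection for a Gaussian linear model
#'
#' Fits `response ~ covariates` and repeatedly removes the covariate with the
#' largest p-value at or above `alpha` (one per iteration, ties broken by
#' column order), refitting until every remaining covariate is significant
#' at `alpha` or none remain.
#'
#' @param response numeric vector (e.g. per-station Shannon H').
#' @param covariates data frame of numeric covariate columns.
#' @param alpha significance level retained covariates must beat (default
#'   0.05).
#' @return list with `selected` (character vector of retained covariate
#'   names), `model` (the final `glm` fit, or NULL if none retained) and
#'   `p_values` of the retained covariates.
#' @export
glm_backward_select <- function(response, covariates, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(response)) {
    stop("response and covariates disagree on the number of stations")
  }
  if (length(response) <= ncol(covariates) + 1) {
    stop("need more stations than covariates + 1")
  }
  keep <- names(covariates)
  repeat {
    if (length(keep) == 0) {
      return(list(selected = character(), model = NULL,
                  p_values = numeric()))
    }
    dat <- cbind(.response = response, covariates[keep])
    fit <- stats::glm(.response ~ ., data = dat, family = stats::gaussian())
    if (any(is.na(stats::coef(fit)))) {
      stop("rank-deficient design: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    }
    coefs <- summary(fit)$coefficients
    p <- coefs[rownames(coefs) != "(Intercept)", 4]
    names(p) <- keep # model matrix preserves column order
    if (all(p < alpha)) {
      return(list(selected = keep, model = fit, p_values = p))
    }
    worst <- keep[which.max(p)]
    keep <- setdiff(keep, worst)
  }
}

#' Fraction of community inertia explained by one environmental variable
#'
#' Runs a single-constraint Canonical Correspondence Analysis of the
#' abundance table on one covariate and returns constrained inertia divided
#' by total inertia.
#'
#' @param table stations x features matrix, non-negative, positive total.
#' @param env numeric covariate, one value per station; must vary.
#' @return fraction in `[0, 1]`.
#' @export
cca_inertia_fraction <- function(table, env) {
  validate_feature_table(table)
  if (length(env) != nrow(table)) stop("env must have one value per station")
  if (stats::sd(env) == 0) stop("degenerate constraint: env is constant")
  if (sum(table) <= 0) stop("table has zero grand total")
  # CCA drops empty rows/columns; guard explicitly
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  ord <- vegan::cca(table[keep_r, keep_c, drop = FALSE] ~ env[keep_r])
  unname(ord$CCA$tot.chi / ord$tot.chi)
}
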