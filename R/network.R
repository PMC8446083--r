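#' Network construction parameters
#'
#' @param soft_power soft-thresholding exponent applied to |Pearson r|
#'   (11 for the combined 16S/18S taxon network, 12 for Pfams).
#' @param linkage agglomeration method for hierarchical clustering on
#'   1 - TOM (default `"average"`).
#' @param cut_height static tree-cut height on the 1 - TOM dissimilarity
#'   scale, in (0, 1].
#' @param min_module_size clusters smaller than this are left unassigned
#'   ("grey").
#' @param log_transform log10(x + 1) the profiles before correlating
#'   (abundances are hits-per-million, so zeros are pervasive).
#' @param adjacency_type `"unsigned"` uses |r|^beta (the convention used
#'   here); `"signed"` uses ((1 + r)/2)^beta.
#' @return list of class `network_config`.
#' @export
network_config <- function(soft_power = 11, linkage = "average",
                           cut_height = 0.99, min_module_size = 10,
                           log_transform = TRUE,
                           adjacency_type = c("unsigned", "signed")) {
  adjacency_type <- match.arg(adjacency_type)
  if (soft_power < 1) stop("soft_power must be >= 1")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  structure(list(soft_power = soft_power, linkage = linkage,
                 cut_height = cut_height, min_module_size = min_module_size,
                 log_transform = log_transform,
                 adjacency_type = adjacency_type),
            class = "network_config")
}

# module colour names in WGCNA's conventional size order
module_palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple")

#' Soft-power adjacency between feature profiles
#'
#' `a_ij = |cor(x_i, x_j)|^beta` across stations (or the signed variant),
#' after optional log10(x + 1) transformation; the diagonal is 1.
#'
#' @param table stations x features matrix.
#' @param beta soft-thresholding power.
#' @param log_transform log10(x + 1) the profiles first (default TRUE).
#' @param type `"unsigned"` (|r|^beta) or `"signed"` (((1 + r)/2)^beta).
#' @return symmetric features x features adjacency in `[0, 1]`.
#' @export
soft_adjacency <- function(table, beta, log_transform = TRUE,
                           type = c("unsigned", "signed")) {
  type <- match.arg(type)
  validate_feature_table(table)
  if (nrow(table) < 3) stop("need at least 3 stations to correlate")
  x <- if (log_transform) log10(table + 1) else table
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  a <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix from a weighted adjacency
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over u distinct from i and j and `k_i = sum_{u != i} a_iu`; the
#' diagonal is 1. High TOM means two nodes share neighbourhoods as well as a
#' direct connection.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with unit diagonal.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1)) {
    stop("adjacency values must lie in [0, 1]")
  }
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  if (max(abs(diag(a) - 1)) > 1e-12) stop("adjacency diagonal must be 1")
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a            # sum over u != i,j (unit diagonal)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  (tom + t(tom)) / 2 # enforce exact symmetry against rounding
}

#' Detect co-occurrence modules by clustering on 1 - TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity, a
#' static cut at `cut_height`, and relabelling of clusters smaller than
#' `min_module_size` as `"grey"` (unassigned). Modules are named in
#' decreasing size order following the conventional colour sequence.
#'
#' @param tom TOM similarity matrix.
#' @param config a [network_config()].
#' @return named character vector: feature -> module name.
#' @export
detect_modules <- function(tom, config = network_config()) {
  n <- nrow(tom)
  if (is.null(rownames(tom))) stop("TOM must carry feature names")
  if (n < config$min_module_size) {
    warning("fewer features than min_module_size; all features unassigned")
    return(stats::setNames(rep("grey", n), rownames(tom)))
  }
  diss <- stats::as.dist(1 - tom)
  tree <- stats::hclust(diss, method = config$linkage)
  raw <- stats::cutree(tree, h = config$cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= config$min_module_size]
  big <- big[order(-sizes[big], as.integer(big))]
  labels <- rep("grey", n)
  for (i in seq_along(big)) {
    nm <- if (i <= length(module_palette)) module_palette[i] else
      paste0("module", i)
    labels[raw == as.integer(big[i])] <- nm
  }
  stats::setNames(labels, rownames(tom))
}

#' Module eigengene: first principal component of a module's profiles
#'
#' Member feature profiles are standardized across stations, the first left
#' singular vector of the stations x members block is taken, scaled to unit
#' sample variance, and the sign is oriented so the average correlation with
#' member profiles is positive.
#'
#' @param table stations x features matrix (same transform used for the
#'   network is applied: log10(x + 1) when `log_transform`).
#' @param labels named module labels as from [detect_modules()].
#' @param module module name to summarize.
#' @param log_transform apply log10(x + 1) first (default TRUE).
#' @return named numeric vector, one eigengene value per station.
#' @export
module_eigengene <- function(table, labels, module, log_transform = TRUE) {
  validate_feature_table(table)
  members <- names(labels)[labels == module]
  if (length(members) == 0) stop("unknown or empty module: ", module)
  if (length(members) < 2) stop("module must have at least 2 features")
  x <- table[, members, drop = FALSE]
  if (log_transform) x <- log10(x + 1)
  xs <- scale(x)
  if (any(!is.finite(xs))) stop("zero-variance member feature in module ", module)
  sv <- svd(xs, nu = 1, nv = 0)
  e <- sv$u[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, xs)) < 0) e <- -e
  stats::setNames(e, rownames(table))
}

#' Correlate module eigengenes with environmental covariates
#'
#' Pearson correlation of every eigengene with every covariate, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom.
#'
#' @param eigengenes stations x modules matrix (or a single named vector).
#' @param env data frame of numeric covariates with station row names
#'   matching the eigengenes.
#' @return list of matrices `r` and `p` (modules x covariates).
#' @export
module_trait_correlation <- function(eigengenes, env) {
  if (is.vector(eigengenes)) {
    eigengenes <- matrix(eigengenes, ncol = 1,
                         dimnames = list(names(eigengenes), "eigengene"))
  }
  shared <- intersect(rownames(eigengenes), rownames(env))
  if (length(shared) < 4) stop("need at least 4 shared stations")
  e <- eigengenes[shared, , drop = FALSE]
  v <- as.matrix(env[shared, , drop = FALSE])
  n <- length(shared)
  r <- stats::cor(e, v)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Geographic distribution of a module's abundance pool
#'
#' For one module, the percentage of the module's total abundance found at
#' each station (the quantity behind bubble maps of module biogeography).
#'
#' @param table stations x features matrix (raw or normalized abundances).
#' @param labels named module labels.
#' @param module module name.
#' @return named numeric vector of percentages summing to 100.
#' @export
node_geography <- function(table, labels, module) {
  validate_feature_table(table)
  members <- names(labels)[labels == module]
  if (length(members) == 0) stop("unknown or empty module: ", module)
  sums <- rowSums(table[, members, drop = FALSE])
  total <- sum(sums)
  if (total <= 0) stop("module ", module, " has zero total abundance")
  100 * sums / total
}
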