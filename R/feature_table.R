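#' Construct a validated station-by-feature abundance table
#'
#' Community inputs throughout the pipeline are plain numeric matrices with
#' stations as rows and features (taxa or Pfam domains) as columns. This
#' constructor attaches the feature kind and enforces the table invariants:
#' unique station and feature identifiers, no negative values, no missing
#' values.
#'
#' @param values numeric matrix, stations in rows, features in columns; both
#'   dimensions must carry unique names.
#' @param kind one of `"taxon_16S"`, `"taxon_18S"`, `"pfam"`.
#' @return the matrix with class `feature_table` and a `kind` attribute.
#' @export
feature_table <- function(values, kind = c("taxon_16S", "taxon_18S", "pfam")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_feature_table(values)
  attr(values, "kind") <- kind
  class(values) <- c("feature_table", class(values))
  values
}

#' Validate the invariants of a station-by-feature table
#'
#' @param x numeric matrix (stations x features).
#' @return `x`, invisibly, after checking dimnames, uniqueness, finiteness and
#'   non-negativity. Violations signal an error naming the offending cell.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature table must be a numeric matrix (stations x features)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("feature table must have station row names and feature column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate station ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid abundance at station '%s', feature '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d stations x %d features (kind: %s)\n",
              nrow(x), ncol(x), attr(x, "kind") %||% "unknown"))
  utils::str(unclass(x)[seq_len(min(4L, nrow(x))), seq_len(min(4L, ncol(x))),
                        drop = FALSE])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument checks --------------------------------------------------

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}
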