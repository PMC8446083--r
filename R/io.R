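#' Read a station-by-feature abundance table from delimited text
#'
#' Expects a header row of feature ids and a first column of station ids.
#' The delimiter is auto-detected (tab default, comma accepted) unless
#' given.
#'
#' @param path file path.
#' @param kind feature kind recorded on the table.
#' @param dialect `"auto"`, `"tab"` or `"comma"`.
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(path, kind = "taxon_16S",
                               dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, tab = "\t", comma = ",", auto = {
    first <- readLines(path, n = 1)
    if (grepl("\t", first)) "\t" else ","
  })
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  feats <- header[-1]
  if (anyDuplicated(feats)) {
    stop("duplicate feature column(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          row.names = NULL)
  if (ncol(df) < 2) stop("table must have a station column and >= 1 feature")
  stations <- as.character(df[[1]])
  if (anyDuplicated(stations)) {
    stop("duplicate station id(s): ",
         paste(unique(stations[duplicated(stations)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[, -1, drop = FALSE], is.numeric, logical(1)))[1]
    stop("non-numeric values in column '", colnames(df)[-1][bad], "'")
  }
  rownames(m) <- stations
  feature_table(m, kind)
}

#' Write a station-by-feature table as delimited text
#' @param table stations x features matrix.
#' @param path output path.
#' @param sep field separator (tab default).
#' @export
write_feature_table <- function(table, path, sep = "\t") {
  df <- data.frame(station_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a four-column taxonomy table (node_id, parent_id, rank, name)
#' @param path delimited text file, tab or comma separated, with header.
#' @return validated taxonomy data frame.
#' @export
read_taxonomy <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tax <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data frame.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome-size / copy-number reference table
#'
#' Three columns: `name`, `genome_size_Mbp`, `copy_number`; empty cells are
#' missing values.
#' @param path delimited text file.
#' @return data frame with NAs for missing entries.
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("name", "genome_size_Mbp", "copy_number")
  if (!all(need %in% names(df))) {
    stop("reference table needs columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write / read a square dissimilarity matrix with station ids
#' @param d symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(station_id = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("matrix on disk is not symmetric")
  }
  m
}

#' Write / read an SST grid as long-format CSV (lat, lon, value)
#' @param grid a `climate_grid`.
#' @param path file path.
#' @export
write_grid_csv <- function(grid, path) {
  df <- expand.grid(lat = grid$latitudes, lon = grid$longitudes,
                    KEEP.OUT.ATTRS = FALSE)
  df$sst <- as.vector(grid$sst)
  df$ice <- as.vector(grid$ice_mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param period_label period tag for the reconstructed grid.
#' @export
read_grid_csv <- function(path, period_label = "") {
  df <- utils::read.csv(path)
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  sst <- matrix(NA_real_, length(lats), length(lons))
  ice <- matrix(FALSE, length(lats), length(lons))
  i <- match(df$lat, lats)
  j <- match(df$lon, lons)
  sst[cbind(i, j)] <- df$sst
  if (!is.null(df$ice)) ice[cbind(i, j)] <- df$ice
  climate_grid(sst, lats, lons, period_label, ice)
}
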