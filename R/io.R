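#' Read a long-format measurement table
#'
#' Tab-separated, UTF-8, '.' decimal separator, with the exact header
#' \code{sample_id treatment timepoint replicate variable value}. Rows
#' with a non-numeric value or non-integer replicate are rejected with
#' their line number; duplicate (sample_id, variable) pairs are rejected.
#'
#' @param path input file.
#' @return Validated measurement data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  req <- c("sample_id", "treatment", "timepoint", "replicate", "variable", "value")
  unknown <- setdiff(names(df), req)
  if (length(unknown)) stop_("unknown column(s): %s", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) stop_("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop_("empty data section in %s", path)

  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    stop_("malformed numeric value at line %d of %s", which(is.na(val))[1] + 1L, path)
  }
  rep_n <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_n) || any(rep_n < 1)) {
    bad <- which(is.na(rep_n) | rep_n < 1)[1]
    stop_("malformed replicate at line %d of %s", bad + 1L, path)
  }
  df$value <- val
  df$replicate <- rep_n
  validate_measurements(df)
}

#' Write a measurement table
#' @param measurements measurement data frame.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_measurements <- function(measurements, path) {
  write.table(measurements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an effect-size table
#'
#' Columns \code{treatment timepoint variable g var_g ci_low ci_high
#' n_treated n_control transform}, tab-separated.
#' @param estimates table from [effect_size_table()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_effect_sizes <- function(estimates, path) {
  out <- estimates
  num <- c("g", "var_g", "ci_low", "ci_high")
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU count table
#'
#' Tab-separated with OTUs as rows: first column the OTU id, remaining
#' columns integer counts per sample. Returned transposed to the in-memory
#' samples-by-OTUs convention.
#'
#' @param path input file.
#' @return Samples-by-OTUs integer matrix.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop_("OTU table needs an id column and >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop_("duplicated OTU id(s) in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop_("OTU counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, colnames(df)[-1])
  t(m)
}

#' Write an OTU count table (OTUs as rows)
#' @param otu samples-by-OTUs matrix.
#' @param path output file.
#' @param id_column header of the OTU id column.
#' @return Invisibly, the path.
#' @export
write_otu_table <- function(otu, path, id_column = "otu_id") {
  df <- data.frame(colnames(otu), t(otu), check.names = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a labelled square distance matrix
#' @param dm square labelled matrix.
#' @param path file path.
#' @return Invisibly the path, or the matrix for the reader.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), signif(dm, 9), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write PCoA coordinates with an eigenvalue header line
#'
#' The first line is a comment carrying all eigenvalues (descending);
#' the table body holds the retained coordinates.
#' @param ord result of [pcoa()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_pcoa <- function(ord, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# eigenvalues:", paste(signif(ord$eigenvalues, 9), collapse = "\t")), con)
  df <- data.frame(sample_id = rownames(ord$coordinates),
                   signif(ord$coordinates, 9), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
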