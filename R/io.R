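# Readers and writers for labelled matrices and GMT gene-set files.
# The matrix parser is deliberately strict: ragged rows, duplicate labels and
# domain violations are hard errors that name the offending line or cell,
# because silent recycling is how feature tables and response matrices end up
# misaligned.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labelled numeric matrix from TSV/CSV
#'
#' Expects a header row of column labels and a first column of row labels.
#' The delimiter is chosen from the file extension (`.csv` -> comma,
#' anything else -> tab). `NA` or an empty field marks a missing value.
#'
#' @param path Path to the file.
#' @param value_domain `"real"` for unrestricted numeric values, `"binary"`
#'   to additionally require every non-missing value to be 0 or 1.
#' @return A numeric matrix with dimnames; `NA` where the file had a missing
#'   token. Wrap with [response_matrix()] or [feature_table()] as needed.
#' @export
read_labelled_matrix <- function(path, value_domain = c("real", "binary")) {
  value_domain <- match.arg(value_domain)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- delim_for(path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1) stop(sprintf("empty file: %s", path), call. = FALSE)
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  if (length(body) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  n_fields <- length(body[[1]])
  # header may or may not carry a corner label over the row-name column
  col_labels <- if (length(header) == n_fields) header[-1] else header
  if (length(col_labels) != n_fields - 1) {
    stop(sprintf("header of %s does not match row width", path), call. = FALSE)
  }
  bad <- which(lengths(body) != n_fields)
  if (length(bad) > 0) {
    stop(sprintf(
      "ragged row in %s: line %d has %d fields, expected %d",
      path, bad[1] + 1L, lengths(body)[bad[1]], n_fields
    ), call. = FALSE)
  }
  row_labels <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_labels)) {
    stop(sprintf(
      "duplicate row label '%s' in %s", row_labels[duplicated(row_labels)][1], path
    ), call. = FALSE)
  }
  if (anyDuplicated(col_labels)) {
    stop(sprintf(
      "duplicate column label '%s' in %s", col_labels[duplicated(col_labels)][1], path
    ), call. = FALSE)
  }
  cells <- vapply(body, function(f) f[-1L], character(n_fields - 1L))
  cells <- matrix(cells, nrow = n_fields - 1L)  # columns = file rows
  missing <- cells == "NA" | cells == ""
  num <- suppressWarnings(as.numeric(cells))
  bad_num <- which(is.na(num) & !missing)
  if (length(bad_num) > 0) {
    idx <- arrayInd(bad_num[1], dim(cells))
    stop(sprintf(
      "non-numeric value '%s' in %s at row '%s', column '%s'",
      cells[bad_num[1]], path, row_labels[idx[2]], col_labels[idx[1]]
    ), call. = FALSE)
  }
  num[missing] <- NA_real_
  out <- t(matrix(num, nrow = n_fields - 1L,
                  dimnames = list(col_labels, row_labels)))
  if (value_domain == "binary") {
    viol <- which(!is.na(out) & !(out %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(viol) > 0) {
      stop(sprintf(
        "non-binary value %g in %s at row '%s', column '%s'",
        out[viol[1, , drop = FALSE]], path,
        rownames(out)[viol[1, 1]], colnames(out)[viol[1, 2]]
      ), call. = FALSE)
    }
  }
  out
}

#' Read a response matrix from TSV/CSV
#'
#' @inheritParams read_labelled_matrix
#' @return A [response_matrix()] with `NA` entries masked as unobserved.
#' @export
read_response_matrix <- function(path) {
  response_matrix(read_labelled_matrix(path, "real"))
}

#' Read a feature table from TSV/CSV
#'
#' @inheritParams read_labelled_matrix
#' @param kind Feature kind; binary kinds are validated on read.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  domain <- if (kind %in% BINARY_KINDS) "binary" else "real"
  feature_table(read_labelled_matrix(path, domain), kind)
}

#' Write a labelled matrix to TSV/CSV
#'
#' Values are serialized at full double precision (17 significant digits) so
#' that a write/read round trip is bit-exact; missing entries are written as
#' `NA`. Accepts a plain matrix or any of the package's matrix containers.
#'
#' @param data Matrix, [response_matrix()], [feature_table()] or
#'   [similarity_matrix()].
#' @param path Output path; delimiter chosen from the extension.
#' @return Invisibly, `path`.
#' @export
write_labelled_matrix <- function(data, path) {
  m <- values_of(data)
  delim <- delim_for(path)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = delim)
  }, character(1))
  header <- paste(c("id", colnames(m)), collapse = delim)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: one tab-separated line per set,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Descriptions are ignored,
#' gene order preserved and duplicate genes within a set collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()]; empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate pathway name '%s'", nm[duplicated(nm)][1]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell line to tissue annotation table
#'
#' Two-column delimited file with a header; first column cell labels, second
#' tissue labels.
#'
#' @param path Path to the file.
#' @return A [tissue_annotation()] tibble.
#' @export
read_tissue_annotation <- function(path) {
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("tissue annotation needs two columns", call. = FALSE)
  tissue_annotation(df[[1]], df[[2]])
}

#' Write a tissue annotation table
#'
#' @param tissues A [tissue_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tissue_annotation <- function(tissues, path) {
  utils::write.table(as.data.frame(tissues), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
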