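#' Read a two-column association edge list
#'
#' Reads a TSV of `(miRNA id, partner id)` pairs into a binary incidence
#' matrix. When `rows`/`cols` are supplied they fix the matrix layout and any
#' identifier outside them is an error; otherwise identifiers are taken in
#' file order of first appearance. Duplicate pairs collapse to a single 1
#' with a warning.
#'
#' @param path TSV file with two columns; an optional header line is skipped
#'   when `header = TRUE`.
#' @param rows,cols optional identifier vectors fixing row/column order.
#' @param header whether the first line is a header.
#' @return binary matrix with miRNAs as rows, partners as columns.
#' @export
read_association_table <- function(path, rows = NULL, cols = NULL,
                                   header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    if (is.null(rows) || is.null(cols))
      stop("empty association file and no identifier lists supplied")
    A <- matrix(0, length(rows), length(cols),
                dimnames = list(rows, cols))
    return(validate_association_matrix(A))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed association line ", bad[1], ": expected two fields")
  r <- vapply(parts, `[[`, "", 1)
  c <- vapply(parts, `[[`, "", 2)
  if (is.null(rows)) rows <- unique(r)
  if (is.null(cols)) cols <- unique(c)
  if (length(miss <- setdiff(r, rows)))
    stop("unknown row identifier: ", miss[1])
  if (length(miss <- setdiff(c, cols)))
    stop("unknown column identifier: ", miss[1])
  if (anyDuplicated(paste0(r, "\r", c)))
    warning("duplicate association pairs collapsed to single entries")
  A <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  A[cbind(match(r, rows), match(c, cols))] <- 1
  validate_association_matrix(A)
}

#' Read miRNA sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Sequences are upper-cased and DNA-style `T` is converted to `U`.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ", ids[anyDuplicated(ids)][1])
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (any(empty <- nchar(seqs) == 0))
    stop("empty sequence for: ", ids[empty][1])
  names(seqs) <- ids
  seqs
}

#' Read a disease DAG from a parent/child edge list
#'
#' @param path TSV of `(parent id, child id)` pairs.
#' @param nodes optional isolated diseases to include (typically those that
#'   appear in the association table but not in the hierarchy).
#' @param delta contribution decay stored on the graph.
#' @param header whether the first line is a header.
#' @return a validated [disease_dag()].
#' @export
read_disease_dag <- function(path, nodes = NULL, delta = 0.5,
                             header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(disease_dag(character(), character(),
                                         nodes = nodes, delta = delta))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed DAG line ", bad[1], ": expected two fields")
  disease_dag(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2),
              nodes = nodes, delta = delta)
}

#' Read / write a labelled numeric matrix as TSV
#'
#' The format has a header row of column identifiers (first cell empty or
#' arbitrary) and a first column of row identifiers. `write_matrix_tsv()`
#' followed by `read_matrix_tsv()` reproduces values to full double
#' precision.
#'
#' @param path TSV file.
#' @return for `read_matrix_tsv`, a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  cols <- header[-1]
  body <- parts[-1]
  widths <- lengths(body)
  if (length(body) && any(widths != length(cols) + 1))
    stop("ragged matrix row ", which(widths != length(cols) + 1)[1] + 1,
         " in ", path)
  rows <- vapply(body, `[[`, "", 1)
  vals <- vapply(body, function(p) as.numeric(p[-1]),
                 numeric(length(cols)))
  M <- if (length(cols) == 1) matrix(vals, ncol = 1) else t(vals)
  if (!length(body)) M <- matrix(numeric(0), 0, length(cols))
  dimnames(M) <- list(rows, cols)
  M
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a localization label table
#'
#' A matrix TSV (see [read_matrix_tsv()]) whose columns are localization
#' names. Columns outside `labels` are dropped with a warning; missing
#' label columns are an error.
#'
#' @param path TSV file.
#' @param labels expected localization order.
#' @return binary label matrix in the canonical column order.
#' @export
read_label_matrix <- function(path, labels = mirna_localizations) {
  M <- read_matrix_tsv(path)
  extra <- setdiff(colnames(M), labels)
  if (length(extra))
    warning("ignoring localization columns outside the vocabulary: ",
            paste(extra, collapse = ", "))
  if (length(miss <- setdiff(labels, colnames(M))))
    stop("label table lacks column(s): ", paste(miss, collapse = ", "))
  Y <- M[, labels, drop = FALSE]
  validate_label_matrix(Y, labels)
  Y
}
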