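#' Target mRNA set of a miRNA
#'
#' The neighbors of a miRNA in the miRNA-mRNA association network.
#'
#' @param m miRNA identifier.
#' @param net miRNA x mRNA association matrix.
#' @return character vector of target mRNA identifiers (possibly empty).
#' @export
target_set <- function(m, net) {
  if (!m %in% rownames(net)) stop("unknown miRNA: ", m)
  colnames(net)[net[m, ] == 1]
}

#' mRNA co-localization ratio features
#'
#' For each miRNA, the fraction of its target mRNAs annotated to each of the
#' four retained mRNA compartments (cytoplasm, exosome, nucleolus, nucleus).
#' Components lie in \[0, 1\] and need not sum to 1 since mRNAs can carry
#' several localizations. A miRNA without targets gets the zero vector with
#' a warning (the ratio is otherwise undefined).
#'
#' @param net miRNA x mRNA association matrix.
#' @param mrna_labels binary mRNA localization matrix; columns outside the
#'   four-compartment vocabulary are dropped with a warning, and every
#'   target mRNA must be covered.
#' @param mirnas miRNAs to compute (default: all rows of `net`).
#' @return matrix `length(mirnas)` x 4 in the fixed compartment order.
#' @export
coloc_features <- function(net, mrna_labels, mirnas = rownames(net)) {
  validate_association_matrix(net)
  extra <- setdiff(colnames(mrna_labels), mrna_localizations)
  if (length(extra)) {
    warning("ignoring mRNA localization column(s): ",
            paste(extra, collapse = ", "))
    mrna_labels <- mrna_labels[, setdiff(colnames(mrna_labels), extra),
                               drop = FALSE]
  }
  validate_label_matrix(mrna_labels, mrna_localizations)
  if (length(miss <- setdiff(mirnas, rownames(net))))
    stop("unknown miRNA: ", miss[1])
  used <- colnames(net)[colSums(net[mirnas, , drop = FALSE]) > 0]
  if (length(miss <- setdiff(used, rownames(mrna_labels))))
    stop("target mRNA without localization annotation: ", miss[1])
  counts <- net[mirnas, rownames(mrna_labels), drop = FALSE] %*% mrna_labels
  ntarg <- rowSums(net[mirnas, , drop = FALSE])
  if (any(ntarg == 0))
    warning(sum(ntarg == 0), " miRNA(s) without targets; ",
            "zero co-localization vectors returned")
  R <- counts / pmax(ntarg, 1)
  R[ntarg == 0, ] <- 0
  dimnames(R) <- list(mirnas, mrna_localizations)
  R
}

#' Assemble the per-miRNA feature bundle
#'
#' Concatenates the five named feature blocks — `sequence` (64), `disease`
#' (128), `drug` (128), `mrna_network` (128) and `coloc` (4) under default
#' dimensions — into one flat matrix, preserving block order. Subsets of
#' blocks are allowed (ablation mode).
#'
#' @param blocks named list of numeric matrices sharing the same rownames.
#' @param expected block names that must be present (default: the names of
#'   `blocks`); a name listed here but absent or NULL in `blocks` is an
#'   error naming the block.
#' @return object of class `"feature_bundle"`: list with `blocks`, `flat`
#'   (the concatenated matrix), `widths` and `index`.
#' @export
assemble_features <- function(blocks, expected = names(blocks)) {
  canonical <- c("sequence", "disease", "drug", "mrna_network", "coloc")
  if (length(unknown <- setdiff(names(blocks), canonical)))
    stop("unknown feature block: ", unknown[1])
  present <- names(blocks)[!vapply(blocks, is.null, TRUE)]
  if (length(miss <- setdiff(expected, present)))
    stop("missing feature block: ", miss[1])
  blocks <- blocks[intersect(canonical, present)]
  idx <- rownames(blocks[[1]])
  if (is.null(idx) || nrow(blocks[[1]]) == 0)
    stop("feature blocks must be non-empty with row identifiers")
  for (nm in names(blocks)) {
    if (!identical(rownames(blocks[[nm]]), idx))
      stop("feature block index mismatch in block: ", nm)
  }
  widths <- vapply(blocks, ncol, 0L)
  flat <- do.call(cbind, lapply(blocks, unname))
  colnames(flat) <- unlist(lapply(names(blocks), function(nm)
    paste0(nm, "_", seq_len(widths[[nm]]))))
  rownames(flat) <- idx
  structure(list(blocks = blocks, flat = flat, widths = widths,
                 index = idx),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("Feature bundle:", length(x$index), "miRNAs,",
      sum(x$widths), "features\n")
  cat("  blocks:", paste(sprintf("%s(%d)", names(x$widths), x$widths),
                         collapse = " | "), "\n")
  invisible(x)
}
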