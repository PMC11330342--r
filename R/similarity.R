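#' Gaussian interaction profile kernel similarity
#'
#' Computes `GM(i, j) = exp(-lambda * ||A(i) - A(j)||^2)` over the rows of a
#' binary association matrix, with bandwidth
#' `lambda = n / sum_k ||A(k)||^2` so that the kernel adapts to the average
#' profile density.
#'
#' @param A association matrix (miRNAs in rows).
#' @return similarity matrix over the row identifiers.
#' @export
gip_kernel <- function(A) {
  validate_association_matrix(A)
  norms <- rowSums(A^2)
  if (sum(norms) == 0) stop("GIP bandwidth undefined: all-zero matrix")
  lambda <- nrow(A) / sum(norms)
  # ||a_i - a_j||^2 = ||a_i||^2 + ||a_j||^2 - 2 a_i . a_j
  cross <- tcrossprod(A)
  d2 <- outer(norms, norms, "+") - 2 * cross
  d2[d2 < 0] <- 0  # numeric guard
  G <- exp(-lambda * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- list(rownames(A), rownames(A))
  G
}

#' Smith-Waterman local alignment score
#'
#' Best local alignment score under match/mismatch scoring with a linear gap
#' penalty. Score-only; the empty sequence scores 0.
#'
#' @param a,b RNA sequences (strings over `A`, `C`, `G`, `U`).
#' @param scoring list with `match` (> 0), `mismatch` (<= 0), `gap` (<= 0).
#' @return nonnegative alignment score.
#' @export
smith_waterman_score <- function(a, b,
                                 scoring = list(match = 2, mismatch = -1,
                                                gap = -2)) {
  .check_scoring(scoring)
  .sw_score_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap)
}

#' All-pairs Smith-Waterman score matrix
#'
#' @param seqs named character vector of sequences.
#' @inheritParams smith_waterman_score
#' @return symmetric score matrix with the sequence names as identifiers.
#' @export
sw_score_matrix <- function(seqs, scoring = list(match = 2, mismatch = -1,
                                                 gap = -2)) {
  .check_scoring(scoring)
  sp <- .sw_score_matrix_cpp(unname(seqs), scoring$match, scoring$mismatch,
                             scoring$gap)
  dimnames(sp) <- list(names(seqs), names(seqs))
  sp
}

.check_scoring <- function(s) {
  if (s$match <= 0 || s$mismatch > 0 || s$gap > 0)
    stop("alignment scoring requires match > 0, mismatch <= 0, gap <= 0")
  invisible(s)
}

#' Normalized sequence similarity from alignment scores
#'
#' `SW(i, j) = sp(i, j) / sqrt(sp(i, i) * sp(j, j))`; the diagonal is exactly
#' 1. Self-scores must be positive.
#'
#' @param sp symmetric matrix of pairwise local alignment scores.
#' @return similarity matrix.
#' @export
sequence_similarity <- function(sp) {
  self <- diag(sp)
  if (any(bad <- self <= 0))
    stop("non-positive self-alignment score for: ",
         rownames(sp)[bad][1])
  S <- sp / sqrt(outer(self, self))
  diag(S) <- 1
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  validate_similarity_matrix(S)
  S
}

#' Fuse a sparse similarity with the GIP kernel
#'
#' Keeps `S(i, j)` where it is positive and falls back to the GIP kernel
#' similarity `G(i, j)` where it is zero. Applied both to the sequence
#' similarity and to the functional similarity.
#'
#' @param S primary similarity matrix (may contain many zeros).
#' @param G GIP kernel similarity over the same identifiers.
#' @return fused similarity matrix.
#' @export
fuse_with_gip <- function(S, G) {
  if (!identical(dimnames(S), dimnames(G)))
    stop("similarity matrices must share identifiers")
  out <- ifelse(S > 0, S, G)
  diag(out) <- 1
  dimnames(out) <- dimnames(S)
  validate_similarity_matrix(out)
  out
}

#' Semantic contributions of a disease's ancestors
#'
#' Within the ancestor closure `A(di)` of disease `di`, the contribution of
#' `di` to itself is 1 and the contribution of an ancestor `dt` is
#' `max(delta * contribution(dt'))` over the children `dt'` of `dt` that lie
#' in the closure. The semantic value `DS(di)` sums the contributions.
#'
#' @param dag a [disease_dag()].
#' @param di disease identifier.
#' @param delta contribution decay; defaults to the value stored on the DAG.
#' @return list with `contributions` (named vector over `A(di)`) and `ds`.
#' @export
semantic_values <- function(dag, di, delta = NULL) {
  if (!di %in% igraph::V(dag)$name) stop("unknown disease: ", di)
  if (is.null(delta)) delta <- dag$delta %||% 0.5
  anc <- names(igraph::subcomponent(dag, di, mode = "in"))
  contrib <- setNames(rep(NA_real_, length(anc)), anc)
  contrib[di] <- 1
  # process ancestors in increasing distance from di (children before parents)
  dist <- igraph::distances(dag, v = anc, to = di, mode = "out")[, 1]
  for (dt in anc[order(dist)]) {
    if (dt == di) next
    kids <- intersect(names(igraph::neighbors(dag, dt, mode = "out")), anc)
    contrib[dt] <- max(delta * contrib[kids], na.rm = TRUE)
  }
  list(contributions = contrib, ds = sum(contrib))
}

#' Semantic similarity of two diseases
#'
#' Shared-ancestor similarity: contributions of the common ancestors of both
#' diseases, normalized by the two semantic values. Symmetric, in \[0, 1\],
#' and 1 for identical diseases.
#'
#' @inheritParams semantic_values
#' @param dj second disease identifier.
#' @return similarity in \[0, 1\].
#' @export
disease_semantic_similarity <- function(dag, di, dj, delta = NULL) {
  vi <- semantic_values(dag, di, delta)
  vj <- semantic_values(dag, dj, delta)
  common <- intersect(names(vi$contributions), names(vj$contributions))
  if (!length(common)) return(0)
  sum(vi$contributions[common] + vj$contributions[common]) / (vi$ds + vj$ds)
}

#' All-pairs disease semantic similarity
#'
#' @inheritParams semantic_values
#' @param diseases identifiers to include (default: all DAG nodes).
#' @return similarity matrix over `diseases`.
#' @export
disease_similarity_matrix <- function(dag, diseases = NULL, delta = NULL) {
  if (is.null(diseases)) diseases <- igraph::V(dag)$name
  sv <- lapply(setNames(diseases, diseases),
               function(d) semantic_values(dag, d, delta))
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    ci <- sv[[i]]$contributions
    for (j in i:n) {
      cj <- sv[[j]]$contributions
      common <- intersect(names(ci), names(cj))
      v <- if (length(common))
        sum(ci[common] + cj[common]) / (sv[[i]]$ds + sv[[j]]$ds) else 0
      S[i, j] <- v
      S[j, i] <- v
    }
  }
  diag(S) <- 1
  S
}

#' miRNA functional similarity from associated disease sets
#'
#' Best-match averaging of disease semantic similarities: for miRNAs with
#' disease sets `DDi`, `DDj`,
#' `mFS = (sum_{d in DDi} max SS(d, DDj) + sum_{d in DDj} max SS(d, DDi)) /
#' (|DDi| + |DDj|)`. Pairs where both sets are empty get 0 off-diagonal; the
#' diagonal is forced to 1.
#'
#' @param disease_sets named list mapping each miRNA to a character vector of
#'   associated diseases (possibly empty).
#' @param dag a [disease_dag()] covering every referenced disease.
#' @param delta contribution decay override.
#' @return similarity matrix over the miRNA names.
#' @export
mirna_functional_similarity <- function(disease_sets, dag, delta = NULL) {
  mirnas <- names(disease_sets)
  all_dis <- unique(unlist(disease_sets, use.names = FALSE))
  if (length(miss <- setdiff(all_dis, igraph::V(dag)$name)))
    stop("disease not in DAG: ", miss[1])
  SS <- if (length(all_dis))
    disease_similarity_matrix(dag, all_dis, delta) else
    matrix(0, 0, 0)
  n <- length(mirnas)
  S <- matrix(0, n, n, dimnames = list(mirnas, mirnas))
  for (i in seq_len(n)) {
    di <- disease_sets[[i]]
    for (j in i:n) {
      dj <- disease_sets[[j]]
      tot <- length(di) + length(dj)
      if (tot == 0) { v <- 0 } else {
        sub <- SS[di, dj, drop = FALSE]
        best_i <- if (length(di) && length(dj)) apply(sub, 1, max) else
          numeric(0)
        best_j <- if (length(di) && length(dj)) apply(sub, 2, max) else
          numeric(0)
        v <- (sum(best_i) + sum(best_j)) / tot
      }
      S[i, j] <- v
      S[j, i] <- v
    }
  }
  diag(S) <- 1
  validate_similarity_matrix(S)
  S
}

#' Binarize a similarity matrix into a functional network
#'
#' Creates an unweighted edge between every pair whose similarity strictly
#' exceeds the threshold `T`; ties at exactly `T` yield no edge.
#'
#' @param S similarity matrix.
#' @param threshold binarization threshold in \[0, 1\].
#' @return an undirected [igraph::igraph] with unit edge weights.
#' @export
binarize_network <- function(S, threshold) {
  if (threshold < 0 || threshold > 1)
    stop("binarization threshold must lie in [0, 1]")
  similarity_graph(S, threshold = threshold, binary = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
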