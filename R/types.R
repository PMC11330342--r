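#' Validate an association matrix
#'
#' An association matrix is a binary miRNA-by-partner incidence matrix with
#' unique row and column identifiers. Used for miRNA-disease, miRNA-drug and
#' miRNA-mRNA associations.
#'
#' @param A numeric matrix with dimnames; entries must be 0 or 1.
#' @return `A`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_association_matrix <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop("association matrix must be a numeric matrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix must carry row and column identifiers")
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("association matrix identifiers must be unique")
  if (!all(A %in% c(0, 1)))
    stop("association matrix entries must be 0 or 1")
  invisible(A)
}

#' Validate a similarity matrix
#'
#' Similarity matrices are square, symmetric within tolerance, have a unit
#' diagonal and entries in \[0, 1\].
#'
#' @param S numeric matrix with identical row and column identifiers.
#' @param tol symmetry tolerance.
#' @return `S`, invisibly, if valid.
#' @export
validate_similarity_matrix <- function(S, tol = 1e-9) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("similarity matrix must be square")
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("similarity matrix must have matching row/column identifiers")
  if (max(abs(S - t(S))) > tol)
    stop("similarity matrix is not symmetric within tolerance")
  if (max(abs(diag(S) - 1)) > tol)
    stop("similarity matrix diagonal must be 1")
  if (min(S) < -tol || max(S) > 1 + tol)
    stop("similarity entries must lie in [0, 1]")
  invisible(S)
}

#' Validate a localization label matrix
#'
#' @param Y binary matrix, one row per molecule, one column per localization.
#' @param labels expected column order; defaults to the seven miRNA
#'   compartments.
#' @return `Y`, invisibly, if valid.
#' @export
validate_label_matrix <- function(Y, labels = mirna_localizations) {
  if (!is.matrix(Y) || is.null(rownames(Y)))
    stop("label matrix must be a matrix with row identifiers")
  if (!identical(colnames(Y), labels))
    stop("label matrix columns must be exactly: ",
         paste(labels, collapse = ", "))
  if (!all(Y %in% c(0, 1)))
    stop("label matrix entries must be 0 or 1")
  invisible(Y)
}

#' Construct a disease DAG
#'
#' Diseases live in an acyclic parent-to-child graph (as in MeSH). The decay
#' parameter `delta` controls how fast the semantic contribution of an
#' ancestor fades and is stored on the graph.
#'
#' @param parent,child character vectors of equal length giving directed
#'   parent -> child edges.
#' @param nodes optional extra (possibly isolated) disease identifiers.
#' @param delta contribution decay in (0, 1); 0.5 is the conventional value.
#' @return an [igraph::igraph] with attribute `delta`.
#' @export
disease_dag <- function(parent, child, nodes = NULL, delta = 0.5) {
  stopifnot(length(parent) == length(child))
  if (!(delta > 0 && delta < 1)) stop("delta must lie strictly in (0, 1)")
  all_nodes <- unique(c(parent, child, nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = parent, to = child, stringsAsFactors = FALSE),
    directed = TRUE, vertices = all_nodes)
  if (!igraph::is_dag(g)) {
    cyc <- .find_directed_cycle(g)
    stop("disease graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  g$delta <- delta
  g
}

# Locate one directed cycle for the error message.
.find_directed_cycle <- function(g) {
  loops <- igraph::which_loop(g)
  if (any(loops)) {
    v <- igraph::ends(g, igraph::E(g)[loops][1])[1, 1]
    return(c(v, v))
  }
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)[1]
  members <- names(comp$membership)[comp$membership == big]
  v <- members[1]
  succ <- intersect(names(igraph::neighbors(g, v, mode = "out")), members)
  path <- igraph::shortest_paths(g, from = succ[1], to = v,
                                 mode = "out")$vpath[[1]]
  c(v, names(path))
}

#' Build an undirected weighted graph from a similarity matrix
#'
#' Connects every pair `(i, j)`, `i != j`, whose similarity strictly exceeds
#' `threshold`; each edge carries the similarity as its weight (or weight 1
#' when `binary = TRUE`).
#'
#' @param S similarity matrix.
#' @param threshold strict lower bound for edge creation.
#' @param binary if `TRUE` all retained edges get weight 1.
#' @return an undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
similarity_graph <- function(S, threshold = 0, binary = FALSE) {
  validate_similarity_matrix(S)
  A <- S
  diag(A) <- 0
  A[A <= threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (binary && igraph::ecount(g) > 0)
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

#' Build the bipartite association graph
#'
#' Nodes are the miRNAs plus the partner entities; every 1 in the incidence
#' matrix becomes an unweighted edge. Row and column identifier sets must be
#' disjoint.
#'
#' @param A association matrix (see [validate_association_matrix()]).
#' @return an undirected [igraph::igraph] with unit edge weights.
#' @export
association_graph <- function(A) {
  validate_association_matrix(A)
  if (length(intersect(rownames(A), colnames(A))))
    stop("miRNA and partner identifiers must be disjoint")
  idx <- which(A == 1, arr.ind = TRUE)
  edges <- cbind(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]])
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = c(rownames(A), colnames(A)))
  if (igraph::ecount(g) > 0) igraph::E(g)$weight <- 1
  g
}
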