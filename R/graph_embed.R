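#' Generate biased second-order random walks
#'
#' node2vec walk sampling: from node `v`, having arrived from `t`, the
#' unnormalized probability of moving to neighbor `x` is the edge weight
#' scaled by `1/p` when `x == t`, by 1 when `x` is adjacent to `t`, and by
#' `1/q` otherwise. Isolated nodes yield length-1 walks.
#'
#' @param g undirected [igraph::igraph]; a `weight` edge attribute biases
#'   the walks (missing weights count as 1).
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param walks_per_node walks started from every node.
#' @param walk_length maximum walk length (nodes, including the start).
#' @param seed integer seed; walks are deterministic given the seed.
#' @return object of class `"walk_corpus"`: list with `walks` (list of
#'   character vectors of node names) and `nodes`.
#' @export
generate_walks <- function(g, p = 1, q = 1, walks_per_node = 10,
                           walk_length = 80, seed = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  if (igraph::vcount(g) == 0) stop("graph is empty")
  nodes <- igraph::V(g)$name
  adj <- .csr_adjacency(g)
  raw <- .node2vec_walks_cpp(adj$ptr, adj$nbr, adj$wt, p, q,
                             as.integer(walks_per_node),
                             as.integer(walk_length), as.integer(seed))
  walks <- lapply(raw, function(w) nodes[w])
  structure(list(walks = walks, nodes = nodes,
                 params = list(p = p, q = q, walks_per_node = walks_per_node,
                               walk_length = walk_length, seed = seed)),
            class = "walk_corpus")
}

# 0-based CSR adjacency with sorted neighbors, weights defaulting to 1.
.csr_adjacency <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  if (any(w <= 0)) stop("edge weights must be positive")
  # both directions
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  ptr <- integer(n + 1)
  tab <- tabulate(from, nbins = n)
  ptr[-1] <- cumsum(tab)
  list(ptr = as.integer(ptr), nbr = as.integer(to - 1), wt = ww)
}

#' Embed a walk corpus with skip-gram negative sampling
#'
#' Single-threaded word2vec-style training (unigram^0.75 noise distribution,
#' reduced-window context sampling, linearly decaying learning rate) so that
#' results are bit-reproducible for a given seed. Nodes absent from the
#' corpus receive a zero row with a warning.
#'
#' @param corpus a `"walk_corpus"` from [generate_walks()].
#' @param dim embedding dimension.
#' @param window context window half-width.
#' @param epochs passes over the corpus.
#' @param negative negative samples per context pair.
#' @param lr initial learning rate.
#' @param seed integer seed.
#' @return numeric matrix, one row per node in `corpus$nodes`.
#' @export
skipgram_embed <- function(corpus, dim = 128, window = 5, epochs = 5,
                           negative = 5, lr = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (!length(corpus$walks)) stop("walk corpus is empty")
  nodes <- corpus$nodes
  idx_walks <- lapply(corpus$walks, function(w) match(w, nodes))
  E <- .sgns_train_cpp(idx_walks, length(nodes), as.integer(dim),
                       as.integer(window), as.integer(epochs),
                       as.integer(negative), lr, as.integer(seed))
  seen <- unique(unlist(idx_walks, use.names = FALSE))
  absent <- setdiff(seq_along(nodes), seen)
  if (length(absent)) {
    warning(length(absent), " node(s) absent from the walk corpus; ",
            "zero rows returned")
    E[absent, ] <- 0
  }
  dimnames(E) <- list(nodes, NULL)
  E
}

#' Embed a network and keep the miRNA rows
#'
#' Runs [generate_walks()] and [skipgram_embed()] on a (possibly bipartite)
#' network and returns the embedding rows for `mirnas`, in that order.
#' miRNAs missing from the graph get zero rows with a warning.
#'
#' @param g undirected graph containing the miRNAs (plus, for association
#'   networks, the partner entities).
#' @param mirnas master miRNA identifier order.
#' @param dim embedding dimension (64 for the sequence network, 128 for
#'   association networks).
#' @param cfg node2vec parameter list as in [pipeline_config()].
#' @param seed integer seed.
#' @return `length(mirnas)` x `dim` embedding matrix.
#' @export
embed_network <- function(g, mirnas, dim, cfg = pipeline_config()$node2vec,
                          seed = 1) {
  present <- intersect(mirnas, igraph::V(g)$name)
  if (length(absent <- setdiff(mirnas, present)))
    warning(length(absent), " miRNA(s) missing from the graph; zero rows")
  corpus <- generate_walks(g, p = cfg$p, q = cfg$q,
                           walks_per_node = cfg$walks_per_node,
                           walk_length = cfg$walk_length, seed = seed)
  E <- skipgram_embed(corpus, dim = dim, window = cfg$window,
                      epochs = cfg$epochs, negative = cfg$negative,
                      lr = cfg$lr, seed = seed)
  out <- matrix(0, length(mirnas), dim, dimnames = list(mirnas, NULL))
  out[present, ] <- E[present, , drop = FALSE]
  out
}
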