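named_binary <- function(n, m, density = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n * m, 1, density), n, m,
              dimnames = list(paste0("m", seq_len(n)),
                              paste0("d", seq_len(m))))
  A[rowSums(A) == 0, 1] <- 1  # keep the bandwidth defined
  A
}

test_that("GIP kernel matches hand evaluation and the brute-force oracle", {
  A <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  G <- gip_kernel(A)
  expect_equal(G["m1", "m2"], 1)
  expect_equal(G["m1", "m3"], exp(-2))
  expect_equal(unname(diag(G)), rep(1, 3))

  for (rep in 1:100) {
    A <- named_binary(sample(2:6, 1), sample(2:9, 1), seed = rep)
    expect_equal(unname(gip_kernel(A)), oracle_gip(A), tolerance = 1e-12)
  }

  expect_error(gip_kernel(matrix(0, 2, 2,
                                 dimnames = list(c("a", "b"), c("x", "y")))),
               "bandwidth")
})

test_that("GIP similarity is 1 exactly for identical association rows", {
  A <- named_binary(6, 8, seed = 11)
  A["m2", ] <- A["m1", ]
  G <- gip_kernel(A)
  for (i in 1:6) for (j in 1:6) {
    same <- all(A[i, ] == A[j, ])
    expect_equal(G[i, j] == 1, same)
  }
})

test_that("Smith-Waterman scores match the exhaustive DP oracle", {
  sc <- list(match = 2, mismatch = -1, gap = -2)
  expect_equal(smith_waterman_score("ACGU", "ACGU", sc), 8)  # match * length
  expect_equal(smith_waterman_score("AAAA", "CCCC", sc), 0)
  expect_equal(smith_waterman_score("", "ACGU", sc), 0)

  set.seed(77)
  for (rep in 1:100) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(1:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(1:12, 1), TRUE),
               collapse = "")
    expect_equal(smith_waterman_score(a, b, sc),
                 oracle_sw(a, b, sc$match, sc$mismatch, sc$gap))
  }
})

test_that("sequence similarity normalizes alignment scores", {
  sp <- matrix(c(4, 2, 2, 9), 2, 2,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  S <- sequence_similarity(sp)
  expect_equal(S["m1", "m2"], 2 / 6)
  expect_equal(unname(diag(S)), c(1, 1))
  sp0 <- sp; sp0["m1", "m2"] <- 0; sp0["m2", "m1"] <- 0
  expect_equal(sequence_similarity(sp0)["m1", "m2"], 0)
  spbad <- sp; spbad["m1", "m1"] <- 0
  expect_error(sequence_similarity(spbad), "m1")
})

test_that("GIP fusion keeps positive entries and fills zeros", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0.4, 0, 0.4, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(ids, ids))
  G <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.3, 0.2, 0.3, 1), 3, 3,
              dimnames = list(ids, ids))
  out <- fuse_with_gip(S, G)
  expect_equal(out["a", "b"], 0.4)   # positive branch wins
  expect_equal(out["a", "c"], 0.2)   # zero falls back to GIP
  allpos <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(allpos) <- 1
  expect_equal(fuse_with_gip(allpos, G), allpos)
  G2 <- G[1:2, 1:2]
  expect_error(fuse_with_gip(S, G2), "identifiers")
})

test_that("semantic values follow the decaying max-over-children recursion", {
  dag <- disease_dag(c("R", "B"), c("B", "C"))
  v <- semantic_values(dag, "C")
  expect_equal(v$contributions[["C"]], 1)
  expect_equal(v$contributions[["B"]], 0.5)
  expect_equal(v$contributions[["R"]], 0.25)
  expect_equal(v$ds, 1.75)

  expect_equal(semantic_values(dag, "R")$ds, 1)  # root: closure is itself

  diamond <- disease_dag(c("R", "R", "A", "B"), c("A", "B", "C", "C"))
  vd <- semantic_values(diamond, "C")
  expect_equal(vd$contributions[["R"]], 0.25)
  expect_equal(vd$ds, 2.25)

  expect_error(semantic_values(dag, "nope"), "unknown")
})

test_that("semantic values are invariant to edge insertion order", {
  edges <- data.frame(parent = c("R", "R", "A", "B", "A"),
                      child = c("A", "B", "C", "C", "D"))
  v_ref <- NULL
  set.seed(5)
  for (rep in 1:5) {
    o <- sample(nrow(edges))
    dag <- disease_dag(edges$parent[o], edges$child[o])
    v <- semantic_values(dag, "C")
    if (is.null(v_ref)) v_ref <- v
    expect_equal(v$ds, v_ref$ds)
    expect_equal(v$contributions[sort(names(v$contributions))],
                 v_ref$contributions[sort(names(v_ref$contributions))])
  }
})

test_that("disease semantic similarity matches hand values and the oracle", {
  dag <- disease_dag(c("R", "R"), c("A", "B"))
  expect_equal(disease_semantic_similarity(dag, "A", "A"), 1)
  expect_equal(disease_semantic_similarity(dag, "A", "B"), 1 / 3)

  two_roots <- disease_dag(c("R1", "R2"), c("A", "B"))
  expect_equal(disease_semantic_similarity(two_roots, "A", "B"), 0)

  # random DAGs against the path-enumeration oracle
  set.seed(9)
  for (rep in 1:100) {
    nd <- sample(3:7, 1)
    ids <- paste0("D", seq_len(nd))
    parent <- ids[unlist(lapply(2:nd, function(j) sample(j - 1, 1)))]
    child <- ids[2:nd]
    edges <- data.frame(parent = parent, child = child)
    dag <- disease_dag(parent, child)
    pick <- sample(ids, 2)
    expect_equal(disease_semantic_similarity(dag, pick[1], pick[2]),
                 oracle_ss(edges, pick[1], pick[2], 0.5),
                 tolerance = 1e-12)
  }
})

test_that("miRNA functional similarity matches hand values and the oracle", {
  dag <- disease_dag(c("R", "R"), c("A", "B"))
  S1 <- mirna_functional_similarity(list(m1 = "A", m2 = "A"), dag)
  expect_equal(S1["m1", "m2"], 1)
  S2 <- mirna_functional_similarity(list(m1 = "A", m2 = "B"), dag)
  expect_equal(S2["m1", "m2"], 1 / 3)

  set.seed(13)
  for (rep in 1:100) {
    nd <- sample(4:6, 1)
    ids <- paste0("D", seq_len(nd))
    parent <- ids[unlist(lapply(2:nd, function(j) sample(j - 1, 1)))]
    child <- ids[2:nd]
    edges <- data.frame(parent = parent, child = child)
    dag <- disease_dag(parent, child)
    nm <- sample(2:5, 1)
    sets <- lapply(seq_len(nm), function(i)
      sample(ids, sample(0:3, 1)))
    names(sets) <- paste0("m", seq_len(nm))
    S <- mirna_functional_similarity(sets, dag)
    SSfull <- outer(ids, ids, Vectorize(function(x, y)
      oracle_ss(edges, x, y, 0.5)))
    dimnames(SSfull) <- list(ids, ids)
    i <- sample(nm, 1); j <- sample(nm, 1)
    expected <- if (i == j) 1 else oracle_mfs(sets[[i]], sets[[j]], SSfull)
    expect_equal(S[i, j], expected, tolerance = 1e-12)
  }

  # both sets empty: no evidence off-diagonal, unit diagonal
  S0 <- mirna_functional_similarity(list(m1 = character(), m2 = character()),
                                    dag)
  expect_equal(S0["m1", "m2"], 0)
  expect_equal(unname(diag(S0)), c(1, 1))
})

test_that("similarity outputs satisfy the matrix invariants", {
  for (rep in 1:20) {
    A <- named_binary(5, 7, seed = 100 + rep)
    expect_silent(validate_similarity_matrix(gip_kernel(A)))
  }
  dag <- disease_dag(c("R", "R", "A"), c("A", "B", "C"))
  sets <- list(m1 = c("A", "C"), m2 = "B", m3 = character())
  expect_silent(
    validate_similarity_matrix(mirna_functional_similarity(sets, dag)))
})

test_that("binarization uses a strict threshold", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.5, 0.3, 0.5, 1), 3, 3,
              dimnames = list(ids, ids))
  g <- binarize_network(S, 0.5)
  expect_equal(igraph::ecount(g), 1)  # only the 0.6 pair; tie at 0.5 drops
  expect_true(igraph::are_adjacent(g, "a", "b"))

  expect_equal(igraph::ecount(binarize_network(S, 1)), 0)
  Spos <- matrix(0.2, 3, 3, dimnames = list(ids, ids)); diag(Spos) <- 1
  expect_equal(igraph::ecount(binarize_network(Spos, 0)), 3)  # complete
})
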