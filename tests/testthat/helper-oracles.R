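# Independent brute-force oracles. Deliberately written in the most direct
# style possible (elementwise loops, path enumeration) so they share no code
# with the package implementations they check.

oracle_gip <- function(A) {
  n <- nrow(A)
  lambda <- n / sum(sapply(seq_len(n), function(k) sum(A[k, ]^2)))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- exp(-lambda * sum((A[i, ] - A[j, ])^2))
  }
  G
}

# full-table local alignment DP, no rolling arrays
oracle_sw <- function(a, b, match, mismatch, gap) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  H <- matrix(0, length(x) + 1, length(y) + 1)
  for (i in seq_along(x)) for (j in seq_along(y)) {
    sub <- if (x[i] == y[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, H[i, j + 1] + gap,
                           H[i + 1, j] + gap)
  }
  max(H)
}

# semantic contribution via explicit enumeration of downward paths
# from an ancestor to the disease: D_di(dt) = max over paths of delta^len
oracle_semantic <- function(edges, di, delta) {
  parents_of <- function(v) edges$parent[edges$child == v]
  anc <- di
  frontier <- di
  while (length(frontier)) {
    frontier <- unique(unlist(lapply(frontier, parents_of)))
    frontier <- setdiff(frontier, anc)
    anc <- c(anc, frontier)
  }
  paths_down <- function(from, to) {
    if (from == to) return(0)
    kids <- edges$child[edges$parent == from]
    lens <- unlist(lapply(kids, function(k) {
      r <- paths_down(k, to)
      if (is.null(r)) NULL else r + 1
    }))
    if (!length(lens)) NULL else min(lens)  # min length = max delta^len
  }
  contrib <- sapply(anc, function(dt) delta^paths_down(dt, di))
  names(contrib) <- anc
  contrib
}

oracle_ss <- function(edges, di, dj, delta) {
  ci <- oracle_semantic(edges, di, delta)
  cj <- oracle_semantic(edges, dj, delta)
  common <- intersect(names(ci), names(cj))
  if (!length(common)) return(0)
  sum(ci[common] + cj[common]) / (sum(ci) + sum(cj))
}

oracle_mfs <- function(sets_i, sets_j, SS) {
  if (length(sets_i) + length(sets_j) == 0) return(0)
  best <- function(d, dd) if (!length(dd)) 0 else max(SS[d, dd])
  num <- 0
  for (d in sets_i) num <- num + best(d, sets_j)
  for (d in sets_j) num <- num + best(d, sets_i)
  num / (length(sets_i) + length(sets_j))
}

oracle_bce <- function(y, yhat, eps = 1e-7) {
  total <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    p <- min(max(yhat[i, j], eps), 1 - eps)
    total <- total - (y[i, j] * log(p) + (1 - y[i, j]) * log(1 - p))
  }
  total
}

oracle_set_metrics <- function(Y, Yp) {
  n <- nrow(Y)
  M <- ncol(Y)
  aim <- cov <- acc <- atrue <- afalse <- numeric(n)
  for (i in seq_len(n)) {
    ti <- which(Y[i, ] == 1)
    pi <- which(Yp[i, ] == 1)
    inter <- intersect(ti, pi)
    uni <- union(ti, pi)
    aim[i] <- if (length(pi) == 0) 0 else length(inter) / length(pi)
    cov[i] <- length(inter) / length(ti)
    acc[i] <- length(inter) / length(uni)
    atrue[i] <- as.numeric(setequal(ti, pi))
    afalse[i] <- (length(uni) - length(inter)) / M
  }
  c(aiming = mean(aim), coverage = mean(cov), accuracy = mean(acc),
    absolute_true = mean(atrue), absolute_false = mean(afalse))
}

# concordant-pair AUC with half credit for ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
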