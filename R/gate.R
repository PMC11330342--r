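# Graph attention auto-encoder. The encoder updates every node
# representation from its neighbors with learned attention; the decoder
# reuses the encoder parameters in reverse (transposed weights, shared
# attention coefficients) to reconstruct the raw input. Training minimizes
#   ||X - Xhat||_F^2 + lambda_s * sum_{(i,j) in E} -log sigmoid(h_i . h_j).
# All gradients are analytic (verified by a finite-difference test).

.gate_act <- function(Z, activation) {
  if (activation == "sigmoid") sigmoid(Z) else Z
}

# derivative expressed through the activated value
.gate_act_deriv <- function(A, activation) {
  if (activation == "sigmoid") A * (1 - A) else array(1, dim = dim(A))
}

#' Attention coefficients of one encoder layer
#'
#' For node representations `H` and a graph (self-loops are always added),
#' the logit for edge `(i, j)` is
#' `sigmoid(v_s . act(W'h_i) + v_r . act(W'h_j))`; coefficients are the
#' softmax over each node's neighborhood, so every row sums to 1 and
#' non-neighbors get exactly 0.
#'
#' @param H numeric matrix of node representations (rows align with `mask`).
#' @param mask binary neighborhood matrix *including* the diagonal, or an
#'   [igraph::igraph] whose vertices align with the rows of `H`.
#' @param params list with `W`, `v_s`, `v_r`.
#' @param activation `"sigmoid"` or `"linear"`.
#' @return row-stochastic attention matrix.
#' @export
attention_weights <- function(H, mask, params, activation = "sigmoid") {
  if (inherits(mask, "igraph")) {
    M <- igraph::as_adjacency_matrix(mask, sparse = FALSE)
    M <- (M + t(M) > 0) * 1
  } else M <- (mask > 0) * 1
  diag(M) <- 1
  S <- .gate_act(H %*% params$W, activation)
  f <- drop(S %*% params$v_s)
  g <- drop(S %*% params$v_r)
  E <- sigmoid(outer(f, g, "+"))
  expE <- exp(E) * M
  expE / rowSums(expE)
}

# forward pass through all encoder layers and the mirrored decoder;
# returns every intermediate needed by the backward pass
.gate_forward <- function(X, params, mask, activation) {
  L <- length(params$W)
  enc <- vector("list", L)
  Hin <- X
  for (l in seq_len(L)) {
    W <- params$W[[l]]
    Zpre <- Hin %*% W
    Ssig <- .gate_act(Zpre, activation)
    f <- drop(Ssig %*% params$v_s[[l]])
    g <- drop(Ssig %*% params$v_r[[l]])
    E <- sigmoid(outer(f, g, "+"))
    expE <- exp(E) * mask
    alpha <- expE / rowSums(expE)
    Zh <- alpha %*% Zpre
    Hout <- .gate_act(Zh, activation)
    enc[[l]] <- list(Hin = Hin, Zpre = Zpre, Ssig = Ssig, E = E,
                     alpha = alpha, Zh = Zh, Hout = Hout)
    Hin <- Hout
  }
  H <- Hin
  # decoder: layers in reverse with transposed weights; last stage linear
  dec <- vector("list", L)
  D <- H
  for (l in rev(seq_len(L))) {
    M <- D %*% t(params$W[[l]])
    Zd <- enc[[l]]$alpha %*% M
    Dout <- if (l > 1) .gate_act(Zd, activation) else Zd
    dec[[l]] <- list(Din = D, M = M, Zd = Zd, Dout = Dout)
    D <- Dout
  }
  list(enc = enc, dec = dec, H = H, Xhat = D)
}

.gate_loss <- function(X, fw, edge_mask, structure_weight) {
  feat <- sum((X - fw$Xhat)^2)
  if (structure_weight > 0 && any(edge_mask > 0)) {
    P <- tcrossprod(fw$H)
    s <- sigmoid(P[edge_mask > 0])
    struct <- -sum(log(pmax(s, 1e-12))) / 2  # each unordered edge once
  } else struct <- 0
  list(feature = feat, structure = struct,
       total = feat + structure_weight * struct)
}

.gate_backward <- function(X, params, fw, mask, edge_mask, activation,
                           structure_weight) {
  L <- length(params$W)
  gW <- lapply(params$W, function(w) array(0, dim = dim(w)))
  gvs <- lapply(params$v_s, function(v) numeric(length(v)))
  gvr <- lapply(params$v_r, function(v) numeric(length(v)))
  dAlphaDec <- vector("list", L)

  # ---- decoder (stages were run l = L..1; backprop l = 1..L) ----
  dDout <- 2 * (fw$Xhat - X)
  for (l in seq_len(L)) {
    st <- fw$dec[[l]]
    dZd <- if (l > 1) dDout * .gate_act_deriv(st$Dout, activation) else dDout
    dAlphaDec[[l]] <- (dZd %*% t(st$M)) * mask
    dM <- t(fw$enc[[l]]$alpha) %*% dZd
    gW[[l]] <- gW[[l]] + t(dM) %*% st$Din
    dDout <- dM %*% params$W[[l]]
  }
  dH <- dDout  # gradient w.r.t. encoder output

  # ---- structure term ----
  if (structure_weight > 0 && any(edge_mask > 0)) {
    P <- tcrossprod(fw$H)
    C <- -structure_weight * (1 - sigmoid(P)) * edge_mask
    dH <- dH + C %*% fw$H
  }

  # ---- encoder (backprop l = L..1) ----
  dHout <- dH
  for (l in rev(seq_len(L))) {
    st <- fw$enc[[l]]
    dZh <- dHout * .gate_act_deriv(st$Hout, activation)
    dAlpha <- (dZh %*% t(st$Zpre)) * mask + dAlphaDec[[l]]
    dZpre <- t(st$alpha) %*% dZh
    rs <- rowSums(dAlpha * st$alpha)
    dE <- st$alpha * (dAlpha - rs)
    dFG <- dE * st$E * (1 - st$E)
    df <- rowSums(dFG)
    dg <- colSums(dFG)
    gvs[[l]] <- gvs[[l]] + drop(t(st$Ssig) %*% df)
    gvr[[l]] <- gvr[[l]] + drop(t(st$Ssig) %*% dg)
    dSsig <- outer(df, params$v_s[[l]]) + outer(dg, params$v_r[[l]])
    dZpre <- dZpre + dSsig * .gate_act_deriv(st$Ssig, activation)
    gW[[l]] <- gW[[l]] + t(st$Hin) %*% dZpre
    dHout <- dZpre %*% t(params$W[[l]])
  }
  list(W = gW, v_s = gvs, v_r = gvr)
}

.gate_masks <- function(g, ids) {
  nodes <- igraph::V(g)$name
  if (!setequal(nodes, ids))
    stop("graph vertices must match the embedding rows")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[ids, ids]
  A <- (A + t(A) > 0) * 1
  mask <- A
  diag(mask) <- 1          # self-loops for attention
  edge_mask <- A
  diag(edge_mask) <- 0     # structure loss over real edges only
  list(mask = mask, edge = edge_mask)
}

#' Fit the graph attention auto-encoder
#'
#' Refines raw node embeddings over a graph; the encoder output (same width
#' as the final layer) is the refined representation. Deterministic given
#' `cfg$seed`.
#'
#' @param X raw embedding matrix with miRNA rownames.
#' @param g graph over the same nodes (typically the functional similarity
#'   network).
#' @param cfg list with `layer_dims`, `lr`, `epochs`, `structure_weight`,
#'   `activation` (see [pipeline_config()]) and optionally `seed`.
#' @return list of class `"gate_model"` with elements `params`, `H`
#'   (refined embedding), `history` (total loss per epoch), `config`.
#' @export
gate_fit <- function(X, g, cfg = pipeline_config()$gate) {
  if (is.null(rownames(X))) stop("X must carry row identifiers")
  seed <- cfg$seed %||% 1L
  masks <- .gate_masks(g, rownames(X))
  dims <- c(ncol(X), cfg$layer_dims)
  L <- length(cfg$layer_dims)
  set.seed(seed)
  params <- list(
    W = lapply(seq_len(L), function(l) {
      r <- sqrt(6 / (dims[l] + dims[l + 1]))
      matrix(runif(dims[l] * dims[l + 1], -r, r), dims[l], dims[l + 1])
    }),
    v_s = lapply(seq_len(L), function(l) runif(dims[l + 1], -0.1, 0.1)),
    v_r = lapply(seq_len(L), function(l) runif(dims[l + 1], -0.1, 0.1))
  )
  flat <- .gate_flatten(params)
  state <- adam_init(flat)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fw <- .gate_forward(X, params, masks$mask, cfg$activation)
    loss <- .gate_loss(X, fw, masks$edge, cfg$structure_weight)
    history[ep] <- loss$total
    if (!is.finite(loss$total)) stop("non-finite GATE loss at epoch ", ep)
    gr <- .gate_backward(X, params, fw, masks$mask, masks$edge,
                         cfg$activation, cfg$structure_weight)
    upd <- adam_step(flat, .gate_flatten(gr), state, cfg$lr)
    flat <- upd$params
    state <- upd$state
    params <- .gate_unflatten(flat, params)
  }
  fw <- .gate_forward(X, params, masks$mask, cfg$activation)
  H <- fw$H
  rownames(H) <- rownames(X)
  structure(list(params = params, H = H, history = history, config = cfg),
            class = "gate_model")
}

.gate_flatten <- function(p) {
  out <- list()
  for (l in seq_along(p$W)) {
    out[[paste0("W", l)]] <- p$W[[l]]
    out[[paste0("vs", l)]] <- p$v_s[[l]]
    out[[paste0("vr", l)]] <- p$v_r[[l]]
  }
  out
}

.gate_unflatten <- function(flat, template) {
  for (l in seq_along(template$W)) {
    template$W[[l]] <- flat[[paste0("W", l)]]
    template$v_s[[l]] <- as.numeric(flat[[paste0("vs", l)]])
    template$v_r[[l]] <- as.numeric(flat[[paste0("vr", l)]])
  }
  template
}

#' Reconstruct inputs through a fitted (or initialized) auto-encoder
#'
#' @param model a `"gate_model"`.
#' @param X raw embedding matrix (rownames must match the fit).
#' @param g graph over the same nodes.
#' @return list with `Xhat`, `H`, and the `feature` / `structure` / `total`
#'   loss components.
#' @export
gate_reconstruct <- function(model, X, g) {
  cfg <- model$config
  masks <- .gate_masks(g, rownames(X))
  fw <- .gate_forward(X, model$params, masks$mask, cfg$activation)
  loss <- .gate_loss(X, fw, masks$edge, cfg$structure_weight)
  list(Xhat = fw$Xhat, H = fw$H, feature = loss$feature,
       structure = loss$structure, total = loss$total)
}
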