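# Multi-label classifier: per-block token projection, scaled dot-product
# self-attention across the feature-type tokens, then two ReLU hidden layers
# and a sigmoid output per localization, trained with summed binary
# cross-entropy and Adam. Implemented with analytic gradients (checked
# against finite differences in the test suite).

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

.block_starts <- function(widths) {
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  Map(function(s, e) s:e, starts, ends)
}

classifier_init <- function(widths, n_labels, cfg, seed = 1) {
  set.seed(seed)
  a <- cfg$attention_dim
  B <- length(widths)
  params <- list()
  if (cfg$use_attention) {
    for (b in seq_len(B)) {
      params[[paste0("P", b)]] <- .glorot(widths[b], a)
      params[[paste0("bP", b)]] <- numeric(a)
    }
    params$Wq <- .glorot(a, a)
    params$Wk <- .glorot(a, a)
    params$Wv <- .glorot(a, a)
    fc_in <- B * a
  } else {
    fc_in <- sum(widths)
  }
  h <- cfg$hidden
  params$W1 <- .glorot(fc_in, h[1]); params$b1 <- numeric(h[1])
  params$W2 <- .glorot(h[1], h[2]);  params$b2 <- numeric(h[2])
  params$W3 <- .glorot(h[2], n_labels); params$b3 <- numeric(n_labels)
  params
}

# forward through the attention stage only; returns tokens, Q/K/V, the
# attention array (n x B x B) and the concatenated output
.attention_forward <- function(F, widths, params, a) {
  B <- length(widths)
  n <- nrow(F)
  idx <- .block_starts(widths)
  Tk <- Q <- K <- V <- vector("list", B)
  for (b in seq_len(B)) {
    Tk[[b]] <- F[, idx[[b]], drop = FALSE] %*% params[[paste0("P", b)]] +
      rep(params[[paste0("bP", b)]], each = n)
    Q[[b]] <- Tk[[b]] %*% params$Wq
    K[[b]] <- Tk[[b]] %*% params$Wk
    V[[b]] <- Tk[[b]] %*% params$Wv
  }
  A <- array(0, c(n, B, B))
  for (b in seq_len(B)) {
    logit <- matrix(0, n, B)
    for (cc in seq_len(B))
      logit[, cc] <- .rowSums(Q[[b]] * K[[cc]], n, a) / sqrt(a)
    m <- logit[, 1]
    for (cc in seq_len(B)[-1]) m <- pmax(m, logit[, cc])
    e <- exp(logit - m)
    A[, b, ] <- e / .rowSums(e, n, B)
  }
  O <- vector("list", B)
  for (b in seq_len(B)) {
    Ob <- Tk[[b]]  # residual path keeps each token recoverable
    for (cc in seq_len(B)) Ob <- Ob + A[, b, cc] * V[[cc]]
    O[[b]] <- Ob
  }
  list(T = Tk, Q = Q, K = K, V = V, A = A, O = O,
       out = do.call(cbind, O))
}

.classifier_forward <- function(F, params, widths, cfg) {
  cache <- list()
  if (cfg$use_attention) {
    att <- .attention_forward(F, widths, params, cfg$attention_dim)
    X1 <- att$out
    cache$att <- att
  } else {
    X1 <- F
  }
  Z1 <- X1 %*% params$W1 + rep(params$b1, each = nrow(F))
  H1 <- relu(Z1)
  Z2 <- H1 %*% params$W2 + rep(params$b2, each = nrow(F))
  H2 <- relu(Z2)
  Z3 <- H2 %*% params$W3 + rep(params$b3, each = nrow(F))
  S <- sigmoid(Z3)
  c(cache, list(X1 = X1, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, S = S))
}

.classifier_backward <- function(F, Y, params, fw, widths, cfg) {
  n <- nrow(F)
  g <- list()
  dZ3 <- fw$S - Y                       # sigmoid + BCE
  g$W3 <- t(fw$H2) %*% dZ3; g$b3 <- colSums(dZ3)
  dH2 <- dZ3 %*% t(params$W3)
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- t(fw$H1) %*% dZ2; g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- t(fw$X1) %*% dZ1; g$b1 <- colSums(dZ1)
  dX1 <- dZ1 %*% t(params$W1)
  if (!cfg$use_attention) return(g)

  a <- cfg$attention_dim
  B <- length(widths)
  att <- fw$att
  idx <- .block_starts(widths)
  dO <- lapply(seq_len(B), function(b) dX1[, ((b - 1) * a + 1):(b * a),
                                           drop = FALSE])
  dA <- array(0, c(n, B, B))
  dV <- lapply(seq_len(B), function(b) matrix(0, n, a))
  for (b in seq_len(B)) for (cc in seq_len(B)) {
    dA[, b, cc] <- .rowSums(dO[[b]] * att$V[[cc]], n, a)
    dV[[cc]] <- dV[[cc]] + att$A[, b, cc] * dO[[b]]
  }
  dL <- array(0, c(n, B, B))
  for (b in seq_len(B)) {
    Ab <- matrix(att$A[, b, ], n, B)
    dAb <- matrix(dA[, b, ], n, B)
    rs <- .rowSums(dAb * Ab, n, B)
    dL[, b, ] <- Ab * (dAb - rs)
  }
  dQ <- lapply(seq_len(B), function(b) matrix(0, n, a))
  dK <- lapply(seq_len(B), function(b) matrix(0, n, a))
  for (b in seq_len(B)) for (cc in seq_len(B)) {
    dQ[[b]] <- dQ[[b]] + (dL[, b, cc] / sqrt(a)) * att$K[[cc]]
    dK[[cc]] <- dK[[cc]] + (dL[, b, cc] / sqrt(a)) * att$Q[[b]]
  }
  g$Wq <- matrix(0, a, a); g$Wk <- matrix(0, a, a); g$Wv <- matrix(0, a, a)
  for (b in seq_len(B)) {
    g$Wq <- g$Wq + t(att$T[[b]]) %*% dQ[[b]]
    g$Wk <- g$Wk + t(att$T[[b]]) %*% dK[[b]]
    g$Wv <- g$Wv + t(att$T[[b]]) %*% dV[[b]]
    dT <- dO[[b]] +  # residual path
      dQ[[b]] %*% t(params$Wq) + dK[[b]] %*% t(params$Wk) +
      dV[[b]] %*% t(params$Wv)
    g[[paste0("P", b)]] <- t(F[, idx[[b]], drop = FALSE]) %*% dT
    g[[paste0("bP", b)]] <- colSums(dT)
  }
  g
}

#' Self-attention over the feature-type blocks
#'
#' Splits a flat feature matrix into its blocks, projects each block to a
#' common width (one token per feature type), applies scaled dot-product
#' attention across the tokens with a residual connection (token plus
#' attended value), and concatenates the resulting tokens.
#' Exposed mainly for inspection; [train_classifier()] uses it internally.
#'
#' @param F flat feature matrix.
#' @param widths named integer vector of block widths summing to `ncol(F)`.
#' @param cfg classifier configuration list (see [pipeline_config()]).
#' @param params optional parameter list (as produced during training); when
#'   `NULL`, fresh random parameters are drawn from `seed`.
#' @param seed seed for fresh parameters.
#' @return list with `output` (n x `B * attention_dim`) and `attention`
#'   (n x B x B array of row-stochastic weights).
#' @export
self_attention <- function(F, widths, cfg = pipeline_config()$classifier,
                           params = NULL, seed = 1) {
  if (sum(widths) != ncol(F))
    stop("block widths do not match the feature layout")
  if (is.null(params))
    params <- classifier_init(widths, 1L, cfg, seed = seed)
  att <- .attention_forward(F, widths, params, cfg$attention_dim)
  list(output = att$out, attention = att$A)
}

#' Summed binary cross-entropy
#'
#' `L = -sum_i [y_i log yhat_i + (1 - y_i) log(1 - yhat_i)]` over every
#' sample-label pair, with predictions clipped to `[eps, 1 - eps]`.
#'
#' @param y binary matrix of observed labels.
#' @param yhat matrix of predicted probabilities, same shape.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (!all(dim(y) == dim(yhat))) stop("label/prediction shape mismatch")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the multi-label localization classifier
#'
#' Full-batch Adam minimization of the summed binary cross-entropy.
#' Deterministic given `seed`.
#'
#' @param F flat feature matrix (rows = miRNAs).
#' @param Y binary label matrix aligned with `F`.
#' @param widths named block widths summing to `ncol(F)`.
#' @param cfg classifier configuration (see [pipeline_config()]).
#' @param seed integer seed.
#' @return object of class `"mloc_model"` with `params`, `widths`, `cfg`,
#'   `labels` and the training loss `history`.
#' @export
train_classifier <- function(F, Y, widths,
                             cfg = pipeline_config()$classifier, seed = 1) {
  if (nrow(F) < 2) stop("need at least two samples to train")
  if (!identical(rownames(F), rownames(Y)))
    stop("features and labels must share the same index")
  if (sum(widths) != ncol(F))
    stop("block widths do not match the feature layout")
  params <- classifier_init(widths, ncol(Y), cfg, seed = seed)
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fw <- .classifier_forward(F, params, widths, cfg)
    history[ep] <- bce_loss(Y, fw$S)
    if (!is.finite(history[ep]))
      stop("non-finite training loss at epoch ", ep)
    g <- .classifier_backward(F, Y, params, fw, widths, cfg)
    upd <- adam_step(params, g, state, cfg$lr)
    params <- upd$params
    state <- upd$state
  }
  structure(list(params = params, widths = widths, cfg = cfg,
                 labels = colnames(Y), history = history, seed = seed),
            class = "mloc_model")
}

#' Predict localization scores
#'
#' @param object a trained `"mloc_model"`.
#' @param newdata flat feature matrix with the same block layout as used in
#'   training.
#' @param ... unused.
#' @return matrix of per-label probabilities in (0, 1).
#' @export
predict.mloc_model <- function(object, newdata, ...) {
  if (sum(object$widths) != ncol(newdata))
    stop("feature width mismatch: expected ", sum(object$widths),
         ", got ", ncol(newdata))
  fw <- .classifier_forward(newdata, object$params, object$widths,
                            object$cfg)
  S <- fw$S
  dimnames(S) <- list(rownames(newdata), object$labels)
  S
}

#' Turn per-label scores into predicted label sets
#'
#' A label is predicted when its score is greater than or equal to the
#' decision threshold; the predicted set may be empty.
#'
#' @param scores matrix of per-label probabilities.
#' @param threshold decision threshold in (0, 1).
#' @return binary matrix of the same shape.
#' @export
binarize_predictions <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("decision threshold must lie strictly in (0, 1)")
  out <- (scores >= threshold) * 1
  dimnames(out) <- dimnames(scores)
  out
}

#' @export
print.mloc_model <- function(x, ...) {
  cat("Multi-label localization classifier\n")
  cat("  feature blocks:",
      paste(sprintf("%s(%d)", names(x$widths), x$widths), collapse = " | "),
      "\n")
  cat("  self-attention:", if (x$cfg$use_attention) "yes" else "no",
      "| hidden:", paste(x$cfg$hidden, collapse = ", "),
      "| labels:", length(x$labels), "\n")
  cat("  final training loss:", signif(tail_int(x$history), 5), "\n")
  invisible(x)
}

#' Number of trainable parameters of a classifier
#'
#' @param model an `"mloc_model"` (or a parameter list).
#' @return integer count.
#' @export
n_parameters <- function(model) {
  p <- if (inherits(model, "mloc_model")) model$params else model
  sum(vapply(p, length, 0L))
}
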