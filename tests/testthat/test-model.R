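toy_widths <- c(sequence = 6, disease = 8, drug = 8, mrna_network = 8,
                coloc = 4)

toy_features <- function(n, widths = toy_widths, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * sum(widths)), n, sum(widths),
         dimnames = list(paste0("m", seq_len(n)), NULL))
}

toy_cfg <- function(...) {
  modifyList(list(attention_dim = 5L, hidden = c(12L, 8L), lr = 5e-3,
                  epochs = 60L, use_attention = TRUE), list(...))
}

test_that("self-attention produces row-stochastic weights and fixed width", {
  F <- toy_features(9)
  out <- self_attention(F, toy_widths, toy_cfg(), seed = 2)
  B <- length(toy_widths)
  expect_equal(dim(out$output), c(9, B * 5))
  for (b in seq_len(B)) {
    expect_equal(unname(rowSums(out$attention[, b, ])), rep(1, 9),
                 tolerance = 1e-6)
  }
  expect_error(self_attention(F, toy_widths[-1], toy_cfg()), "widths")
})

test_that("identical tokens receive uniform attention", {
  # five identical blocks -> identical tokens under shared-value projections
  ns <- asNamespace("mirlocfuse")
  widths <- c(sequence = 3, disease = 3, drug = 3, mrna_network = 3,
              coloc = 3)
  set.seed(3)
  block <- matrix(rnorm(6 * 3), 6, 3)
  F <- do.call(cbind, rep(list(block), 5))
  rownames(F) <- paste0("m", 1:6)
  cfg <- toy_cfg(attention_dim = 4L)
  params <- ns$classifier_init(widths, 7L, cfg, seed = 4)
  for (b in 2:5) {  # same projection per block -> identical tokens
    params[[paste0("P", b)]] <- params$P1
    params[[paste0("bP", b)]] <- params$bP1
  }
  out <- self_attention(F, widths, cfg, params = params)
  expect_equal(c(out$attention), rep(0.2, length(out$attention)),
               tolerance = 1e-10)
})

test_that("forward pass respects activation ranges and shapes", {
  ns <- asNamespace("mirlocfuse")
  F <- toy_features(10)
  cfg <- toy_cfg()
  params <- ns$classifier_init(toy_widths, 7L, cfg, seed = 5)
  fw <- ns$.classifier_forward(F, params, toy_widths, cfg)
  expect_equal(dim(fw$S), c(10, 7))
  expect_true(all(fw$S > 0 & fw$S < 1))

  # zero weights and biases -> sigmoid(0) = 0.5 everywhere
  zero <- lapply(params, function(p) p * 0)
  fz <- ns$.classifier_forward(F, zero, toy_widths, cfg)
  expect_true(all(fz$S == 0.5))
})

test_that("binary cross-entropy matches hand values and the oracle", {
  expect_equal(bce_loss(matrix(1), matrix(1 - 1e-12)), 0, tolerance = 1e-5)
  expect_equal(bce_loss(matrix(1), matrix(0.5)), -log(0.5),
               tolerance = 1e-4)
  set.seed(6)
  for (rep in 1:25) {
    y <- matrix(rbinom(28, 1, 0.5), 4, 7)
    yhat <- matrix(runif(28, 0.01, 0.99), 4, 7)
    expect_equal(bce_loss(y, yhat), oracle_bce(y, yhat), tolerance = 1e-9)
  }
  expect_error(bce_loss(matrix(1), matrix(c(0.5, 0.5))), "shape")
})

test_that("classifier gradients agree with finite differences", {
  ns <- asNamespace("mirlocfuse")
  widths <- c(sequence = 5, disease = 6, coloc = 3)
  set.seed(7)
  F <- matrix(rnorm(8 * 14), 8, 14, dimnames = list(paste0("m", 1:8), NULL))
  Y <- matrix(rbinom(8 * 4, 1, 0.4), 8, 4,
              dimnames = list(rownames(F), paste0("L", 1:4)))
  cfg <- toy_cfg(attention_dim = 4L, hidden = c(6L, 5L))
  params <- ns$classifier_init(widths, 4L, cfg, seed = 8)
  lossfn <- function(p)
    bce_loss(Y, ns$.classifier_forward(F, p, widths, cfg)$S)
  fw <- ns$.classifier_forward(F, params, widths, cfg)
  gr <- ns$.classifier_backward(F, Y, params, fw, widths, cfg)
  eps <- 1e-6
  set.seed(9)
  for (nm in names(params)) {
    P <- params[[nm]]
    for (k in sample(length(P), min(6, length(P)))) {
      p2 <- params
      p2[[nm]][k] <- P[k] + eps; up <- lossfn(p2)
      p2[[nm]][k] <- P[k] - eps; dn <- lossfn(p2)
      num <- (up - dn) / (2 * eps)
      denom <- max(abs(num), abs(gr[[nm]][k]), 1e-6)
      expect_lt(abs(num - gr[[nm]][k]) / denom, 1e-4)
    }
  }
})

test_that("training fits a separable toy problem and is deterministic", {
  set.seed(10)
  n <- 60
  F <- toy_features(n, seed = 10)
  # labels driven by feature signs -> separable signal
  Y <- cbind((F[, 1] > 0) * 1, (F[, 10] > 0) * 1, (F[, 20] > 0) * 1,
             (F[, 25] > 0) * 1, (F[, 30] > 0) * 1, (F[, 2] > 0) * 1,
             (F[, 3] > 0) * 1)
  dimnames(Y) <- list(rownames(F), mirna_localizations)
  cfg <- toy_cfg(epochs = 300L, lr = 2e-3)
  model <- train_classifier(F, Y, toy_widths, cfg, seed = 11)
  expect_lt(tail(model$history, 1), 0.1 * model$history[1])
  expect_true(all(is.finite(model$history)))

  model2 <- train_classifier(F, Y, toy_widths, cfg, seed = 11)
  expect_identical(model$params, model2$params)

  scores <- predict(model, F)
  expect_equal(dim(scores), c(n, 7))
  expect_true(all(scores > 0 & scores < 1))
})

test_that("all-zero labels drive scores toward zero", {
  F <- toy_features(30, seed = 12)
  Y <- matrix(0, 30, 7, dimnames = list(rownames(F), mirna_localizations))
  cfg <- toy_cfg(epochs = 250L, lr = 5e-3)
  model <- train_classifier(F, Y, toy_widths, cfg, seed = 13)
  expect_lt(mean(predict(model, F)), 0.1)
})

test_that("thresholding uses the >= rule and allows empty sets", {
  scores <- matrix(c(0.9, 0.4, 0.5, 0.1), 1, 4)
  pred <- binarize_predictions(scores, 0.5)
  expect_equal(unname(pred), matrix(c(1, 0, 1, 0), 1, 4))  # tie included
  expect_equal(sum(binarize_predictions(scores, 0.95)), 0)
  expect_error(binarize_predictions(scores, 0), "threshold")
})

test_that("removing self-attention shrinks the model but keeps it runnable", {
  F <- toy_features(20, seed = 14)
  set.seed(14)
  Y <- matrix(rbinom(140, 1, 0.4), 20, 7,
              dimnames = list(rownames(F), mirna_localizations))
  Y[rowSums(Y) == 0, 1] <- 1
  with_att <- train_classifier(F, Y, toy_widths, toy_cfg(epochs = 10L),
                               seed = 15)
  no_att <- train_classifier(F, Y, toy_widths,
                             toy_cfg(epochs = 10L, use_attention = FALSE),
                             seed = 15)
  expect_lt(n_parameters(no_att), n_parameters(with_att))
  expect_equal(dim(predict(no_att, F)), c(20, 7))
})

test_that("degenerate training inputs are rejected", {
  F <- toy_features(1)
  Y <- matrix(1, 1, 7, dimnames = list("m1", mirna_localizations))
  expect_error(train_classifier(F, Y, toy_widths, toy_cfg()), "two samples")
  F2 <- toy_features(5)
  Y2 <- matrix(1, 5, 7, dimnames = list(paste0("m", 1:5),
                                        mirna_localizations))
  model <- train_classifier(F2, Y2, toy_widths, toy_cfg(epochs = 2L))
  expect_error(predict(model, F2[, 1:10]), "width mismatch")
})
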