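rand_labels <- function(n, M = 7, seed = 1, allow_empty_pred = TRUE) {
  set.seed(seed)
  Y <- matrix(rbinom(n * M, 1, 0.4), n, M)
  Y[rowSums(Y) == 0, sample(M, 1)] <- 1
  Yp <- matrix(rbinom(n * M, 1, 0.4), n, M)
  if (!allow_empty_pred) Yp[rowSums(Yp) == 0, 1] <- 1
  labs <- paste0("c", seq_len(M))
  dimnames(Y) <- dimnames(Yp) <- list(paste0("s", seq_len(n)), labs)
  list(Y = Y, Yp = Yp)
}

test_that("set metrics match hand-worked values", {
  labs <- paste0("c", 1:7)
  Y <- matrix(0, 2, 7, dimnames = list(c("s1", "s2"), labs))
  Yp <- Y
  Y["s1", c("c1", "c2")] <- 1; Yp["s1", c("c2", "c3")] <- 1
  Y["s2", "c4"] <- 1;          Yp["s2", "c4"] <- 1
  m <- set_metrics(Y, Yp)
  expect_equal(m$aiming, 0.75)
  expect_equal(m$coverage, 0.75)
  expect_equal(m$accuracy, (1 / 3 + 1) / 2, tolerance = 1e-4)
  expect_equal(m$absolute_true, 0.5)
  expect_equal(m$absolute_false, (2 / 7) / 2, tolerance = 1e-4)

  # perfect prediction
  mperf <- set_metrics(Y, Y)
  expect_equal(unlist(mperf), c(aiming = 1, coverage = 1, accuracy = 1,
                                absolute_true = 1, absolute_false = 0))

  # universally empty prediction
  m0 <- set_metrics(Y, Y * 0)
  expect_equal(m0$aiming, 0)
  expect_equal(m0$coverage, 0)
  expect_equal(m0$accuracy, 0)
  expect_equal(m0$absolute_true, 0)
  expect_equal(m0$absolute_false, mean(rowSums(Y)) / 7)
})

test_that("set metrics match the per-sample set oracle on random instances", {
  for (rep in 1:200) {
    d <- rand_labels(sample(2:12, 1), seed = rep)
    m <- set_metrics(d$Y, d$Yp)
    o <- oracle_set_metrics(d$Y, d$Yp)
    expect_equal(unlist(m), o)
  }
})

test_that("AUC matches ranking intuition and the pair-counting oracle", {
  expect_equal(auc_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))[["auc"]], 1)
  expect_equal(auc_aupr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))[["auc"]], 0)
  expect_equal(auc_aupr(c(0.9, 0.6, 0.6, 0.1), c(1, 0, 1, 0))[["auc"]],
               0.875)

  set.seed(3)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)  # rounded: ties occur
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auc_aupr(scores, y)[["auc"]], oracle_auc(scores, y),
                 tolerance = 1e-12)
  }

  expect_warning(v <- auc_aupr(c(0.1, 0.9), c(1, 1)), "single-class")
  expect_true(all(is.na(v)))
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (rep in 1:20) {
    n <- 40
    scores <- runif(n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_aupr(scores, y)[["auc"]], ref, tolerance = 1e-12)
  }
})

test_that("AUPR equals the step-curve area on a hand case", {
  # scores: 0.9(+) 0.8(-) 0.7(+); thresholds give P/R points
  v <- auc_aupr(c(0.9, 0.8, 0.7), c(1, 0, 1))
  # R: 0.5 -> P 1; R 0.5 -> P 0.5 (no gain); R 1 -> P 2/3
  expect_equal(v[["aupr"]], 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("cross-validation folds partition the samples deterministically", {
  ns <- asNamespace("mirlocfuse")
  folds <- ns$.make_folds(50, 10, seed = 7)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 5))
  expect_identical(folds, ns$.make_folds(50, 10, seed = 7))
  expect_false(identical(folds, ns$.make_folds(50, 10, seed = 8)))
  expect_error(ns$.make_folds(5, 10, seed = 1), "at least")
})

simple_bundle <- function(n, seed = 5, signal = TRUE) {
  set.seed(seed)
  ids <- paste0("m", seq_len(n))
  Y <- matrix(rbinom(n * 7, 1, 0.4), n, 7,
              dimnames = list(ids, mirna_localizations))
  Y[rowSums(Y) == 0, 2] <- 1
  blocks <- list(
    sequence = matrix(rnorm(n * 6), n, 6, dimnames = list(ids, NULL)),
    coloc = (Y[, 1:4] + matrix(rnorm(n * 4, sd = 0.4), n, 4)))
  if (!signal) blocks$coloc <- matrix(rnorm(n * 4), n, 4,
                                      dimnames = list(ids, NULL))
  dimnames(blocks$coloc) <- list(ids, NULL)
  list(bundle = assemble_features(blocks), Y = Y)
}

test_that("cross-validation recovers signal and is seed-reproducible", {
  d <- simple_bundle(80)
  cfg <- pipeline_config(seed = 2, folds = 5,
                         classifier = list(attention_dim = 16L,
                                           hidden = c(32L, 16L), lr = 5e-3,
                                           epochs = 300L))
  cv1 <- cross_validate(d$bundle, d$Y, cfg)
  cv2 <- cross_validate(d$bundle, d$Y, cfg)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$folds, cv2$folds)
  # first four labels are encoded in the coloc block
  expect_gt(mean(cv1$per_label$auc[1:4]), 0.8)
  # averages are means of the per-label values
  expect_equal(cv1$average_auc, mean(cv1$per_label$auc), tolerance = 1e-12)
  expect_equal(cv1$average_aupr, mean(cv1$per_label$aupr),
               tolerance = 1e-12)
  g <- glance(cv1)
  expect_true(all(c("aiming", "average_auc") %in% names(g)))
  expect_equal(nrow(tidy(cv1)), 7)
})

test_that("label-shuffled features give chance-level AUC", {
  d <- simple_bundle(80, seed = 6, signal = FALSE)
  cfg <- pipeline_config(seed = 3, folds = 5,
                         classifier = list(attention_dim = 8L,
                                           hidden = c(16L, 8L),
                                           epochs = 60L))
  cv <- cross_validate(d$bundle, d$Y, cfg)
  expect_lt(abs(cv$average_auc - 0.5), 0.1)
})

test_that("ablation enumerates every non-empty block subset", {
  d <- simple_bundle(40, seed = 8)
  cfg <- pipeline_config(seed = 4, folds = 3,
                         classifier = list(attention_dim = 4L,
                                           hidden = c(8L, 6L),
                                           epochs = 20L))
  tbl <- ablation(d$bundle, d$Y, cfg)
  expect_equal(nrow(tbl), 3)  # 2 blocks -> 3 subsets
  expect_equal(sum(tbl$n_blocks == 2), 1)
  expect_equal(tbl$width[tbl$n_blocks == 2], sum(d$bundle$widths))
  summ <- ablation_size_summary(tbl)
  expect_equal(nrow(summ), 2)
})

test_that("group analysis splits by association count with stable ties", {
  ids <- paste0("m", 1:4)
  A <- matrix(0, 4, 10, dimnames = list(ids, paste0("d", 1:10)))
  A[1, 1:9] <- 1; A[2, 1:7] <- 1; A[3, 1:5] <- 1; A[4, 1:3] <- 1
  Y <- matrix(1, 4, 7, dimnames = list(ids, mirna_localizations))
  scores <- matrix(0.9, 4, 7, dimnames = dimnames(Y))
  g <- group_analysis(A, Y, scores)
  expect_equal(g$n, c(2, 2))
  expect_equal(g$min_count[g$group == "strongly"], 7)

  # all-equal counts: split by identifier order, odd n -> extra in weakly
  A2 <- matrix(1, 5, 2, dimnames = list(paste0("m", 1:5), c("d1", "d2")))
  Y2 <- matrix(1, 5, 7, dimnames = list(rownames(A2), mirna_localizations))
  s2 <- matrix(0.9, 5, 7, dimnames = dimnames(Y2))
  g2 <- group_analysis(A2, Y2, s2)
  expect_equal(g2$n, c(2, 3))
})
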