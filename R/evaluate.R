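#' Set-based multi-label metrics
#'
#' Chou-style metrics over predicted and observed label sets: aiming
#' (precision-like), coverage (recall-like), accuracy (Jaccard),
#' absolute true (exact-match rate) and absolute false (normalized symmetric
#' difference). An empty predicted set contributes 0 to aiming.
#'
#' @param Y binary matrix of observed labels; every row must have at least
#'   one label.
#' @param Ypred binary matrix of predicted labels, same shape and column
#'   order; empty rows are allowed.
#' @return one-row tibble with columns `aiming`, `coverage`, `accuracy`,
#'   `absolute_true`, `absolute_false`.
#' @export
set_metrics <- function(Y, Ypred) {
  if (!all(dim(Y) == dim(Ypred)) || !identical(colnames(Y), colnames(Ypred)))
    stop("observed and predicted label matrices must share shape and labels")
  if (any(rowSums(Y) == 0))
    stop("every sample must carry at least one observed label")
  M <- ncol(Y)
  inter <- rowSums(Y * Ypred)
  uni <- rowSums((Y + Ypred) > 0)
  sy <- rowSums(Y)
  sp <- rowSums(Ypred)
  tibble::tibble(
    aiming = mean(ifelse(sp == 0, 0, inter / pmax(sp, 1))),
    coverage = mean(inter / sy),
    accuracy = mean(inter / uni),
    absolute_true = mean(inter == uni),
    absolute_false = mean((uni - inter) / M)
  )
}

#' AUC and AUPR of one label column
#'
#' AUC is the concordance statistic with half credit for score ties
#' (equivalent to the rank-sum formulation). AUPR is the area under the
#' precision-recall step curve with tied scores grouped.
#'
#' @param scores numeric prediction scores.
#' @param y binary outcomes; must contain both classes, otherwise both
#'   values are `NA` with a warning.
#' @return named numeric vector `c(auc, aupr)`.
#' @export
auc_aupr <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class outcome: AUC/AUPR undefined")
    return(c(auc = NA_real_, aupr = NA_real_))
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # PR step curve over distinct thresholds, decreasing
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  grp_end <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  aupr <- sum(diff(c(0, rec)) * prec)
  c(auc = auc, aupr = aupr)
}

.make_folds <- function(n, k, seed) {
  if (n < k) stop("need at least as many samples as folds")
  set.seed(seed)
  shuffled <- sample.int(n)
  folds <- integer(n)
  folds[shuffled] <- rep(seq_len(k), length.out = n)
  folds
}

#' Cross-validated evaluation of the classifier
#'
#' Shuffled k-fold split (seeded); out-of-fold scores are pooled over all
#' samples before computing the set metrics and the per-label ROC/PR areas,
#' so each label has a single curve.
#'
#' @param features a `"feature_bundle"` from [assemble_features()], or a
#'   flat matrix (then `widths` must be given).
#' @param Y binary label matrix aligned with the features.
#' @param cfg a [pipeline_config()]; uses `classifier`, `threshold`,
#'   `folds` and `seed`.
#' @param widths block widths when `features` is a flat matrix.
#' @return object of class `"mloc_cv"`; see [glance.mloc_cv()] and
#'   [tidy.mloc_cv()].
#' @export
cross_validate <- function(features, Y, cfg = pipeline_config(),
                           widths = NULL) {
  if (inherits(features, "feature_bundle")) {
    widths <- features$widths
    F <- features$flat
  } else F <- features
  stopifnot(!is.null(widths))
  if (!identical(rownames(F), rownames(Y)))
    stop("features and labels must share the same index")
  n <- nrow(F)
  k <- cfg$folds
  folds <- .make_folds(n, k, stage_seed(cfg$seed, "cv-folds"))
  scores <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_classifier(F[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                              widths, cfg$classifier,
                              seed = stage_seed(cfg$seed, paste0("fold", f)))
    scores[!tr, ] <- predict(model, F[!tr, , drop = FALSE])
  }
  pred <- binarize_predictions(scores, cfg$threshold)
  metrics <- set_metrics(Y, pred)
  per_label <- purrr::map_dfr(colnames(Y), function(lab) {
    v <- suppressWarnings(auc_aupr(scores[, lab], Y[, lab]))
    tibble::tibble(label = lab, auc = v[["auc"]], aupr = v[["aupr"]])
  })
  if (anyNA(per_label$auc))
    warning("label(s) with a single class excluded from AUC/AUPR averages: ",
            paste(per_label$label[is.na(per_label$auc)], collapse = ", "))
  structure(list(metrics = metrics, per_label = per_label,
                 average_auc = mean(per_label$auc, na.rm = TRUE),
                 average_aupr = mean(per_label$aupr, na.rm = TRUE),
                 scores = scores, folds = folds,
                 threshold = cfg$threshold, seed = cfg$seed),
            class = "mloc_cv")
}

#' @export
print.mloc_cv <- function(x, ...) {
  cat(length(x$folds), "samples,", max(x$folds), "folds\n")
  m <- x$metrics
  cat(sprintf(paste0("  aiming %.4f | coverage %.4f | accuracy %.4f | ",
                     "absolute true %.4f | absolute false %.4f\n"),
              m$aiming, m$coverage, m$accuracy, m$absolute_true,
              m$absolute_false))
  cat(sprintf("  average AUC %.4f | average AUPR %.4f\n",
              x$average_auc, x$average_aupr))
  invisible(x)
}

#' Tidy / summarize a cross-validation report
#'
#' `tidy()` returns the per-label AUC and AUPR; `glance()` returns the five
#' set metrics plus the label-averaged AUC and AUPR in one row.
#'
#' @param x an `"mloc_cv"` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mloc_cv <- function(x, ...) x$per_label

#' @rdname tidy.mloc_cv
#' @export
glance.mloc_cv <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(average_auc = x$average_auc,
                                  average_aupr = x$average_aupr))
}

#' Feature-type ablation sweep
#'
#' Evaluates every non-empty subset of the feature blocks (31 subsets for
#' the five canonical blocks: 30 partial combinations plus the full model)
#' by cross-validation, optionally over several seeds.
#'
#' @param bundle a `"feature_bundle"` holding all blocks.
#' @param Y label matrix.
#' @param cfg a [pipeline_config()].
#' @param seeds integer vector of master seeds; each subset is evaluated
#'   once per seed.
#' @return tibble of class `"mloc_ablation"`: one row per subset x seed with
#'   logical block columns, `n_blocks`, `width`, the five set metrics,
#'   `average_auc` and `average_aupr`.
#' @export
ablation <- function(bundle, Y, cfg = pipeline_config(),
                     seeds = cfg$seed) {
  stopifnot(inherits(bundle, "feature_bundle"))
  nms <- names(bundle$blocks)
  B <- length(nms)
  subsets <- lapply(seq_len(2^B - 1), function(m)
    nms[bitwAnd(m, 2^(seq_len(B) - 1)) > 0])
  rows <- list()
  for (seed in seeds) {
    for (sub in subsets) {
      sb <- assemble_features(bundle$blocks[sub])
      cv <- cross_validate(sb, Y, modify_config(cfg, seed = seed))
      flags <- as.list(nms %in% sub)
      names(flags) <- nms
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::as_tibble(flags),
        tibble::tibble(n_blocks = length(sub), width = sum(sb$widths),
                       seed = seed),
        glance.mloc_cv(cv))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mloc_ablation", class(out))
  out
}

# replace top-level config entries without re-validating nested lists
modify_config <- function(cfg, ...) {
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Summarize an ablation sweep by subset size
#'
#' Averages every measure over all subsets using the same number of feature
#' blocks (and over seeds), the aggregation behind the
#' "more feature types help" trend.
#'
#' @param tbl an `"mloc_ablation"` tibble.
#' @return tibble with one row per subset size.
#' @export
ablation_size_summary <- function(tbl) {
  tbl |>
    dplyr::group_by(.data$n_blocks) |>
    dplyr::summarise(dplyr::across(
      c("aiming", "coverage", "accuracy", "absolute_true",
        "absolute_false", "average_auc", "average_aupr"), mean),
      n_subsets = dplyr::n(), .groups = "drop")
}

#' Strongly/weakly association-group analysis
#'
#' Ranks miRNAs by decreasing association count for one partner kind and
#' splits them into halves: the better-connected half ("strongly") and the
#' rest ("weakly"; with an odd number of miRNAs the extra one goes to
#' weakly, and ties at the boundary are resolved by index order). Set
#' metrics are computed separately per group from pooled cross-validation
#' scores.
#'
#' @param A association matrix for the partner kind (rows = miRNAs).
#' @param Y label matrix.
#' @param scores pooled out-of-fold score matrix (e.g. `cv$scores`).
#' @param threshold decision threshold.
#' @return tibble with one row per group: `group`, `n`, `min_count` (the
#'   data-driven association-count threshold of the group), the five set
#'   metrics and `mean_labels`.
#' @export
group_analysis <- function(A, Y, scores, threshold = 0.5) {
  stopifnot(identical(rownames(A), rownames(Y)))
  counts <- rowSums(A)
  n <- length(counts)
  o <- order(-counts)  # stable: ties keep index order
  strong <- rownames(A)[o[seq_len(floor(n / 2))]]
  weak <- setdiff(rownames(A), strong)
  pred <- binarize_predictions(scores, threshold)
  one <- function(ids, name) {
    dplyr::bind_cols(
      tibble::tibble(group = name, n = length(ids),
                     min_count = min(counts[ids])),
      set_metrics(Y[ids, , drop = FALSE], pred[ids, , drop = FALSE]),
      tibble::tibble(mean_labels = mean(rowSums(Y[ids, , drop = FALSE]))))
  }
  dplyr::bind_rows(one(strong, "strongly"), one(weak, "weakly"))
}
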