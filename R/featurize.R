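#' Build all similarity matrices of a dataset
#'
#' Computes the GIP kernel on the disease associations, the normalized
#' Smith-Waterman sequence similarity fused with the GIP kernel, and the
#' functional similarity (from the associated disease sets over the disease
#' hierarchy) fused with the GIP kernel.
#'
#' @param dataset an `"mloc_dataset"` (or any list with the same fields).
#' @param cfg a [pipeline_config()].
#' @param sp optional precomputed pairwise alignment score matrix; when
#'   `NULL` the scores are computed with [sw_score_matrix()].
#' @return list with `gm`, `sw_gm`, `mfs_gm` similarity matrices.
#' @export
compute_similarities <- function(dataset, cfg = pipeline_config(),
                                 sp = NULL) {
  gm <- gip_kernel(dataset$assoc$disease)
  if (is.null(sp)) sp <- sw_score_matrix(dataset$sequences, cfg$alignment)
  sw <- sequence_similarity(sp[dataset$mirnas, dataset$mirnas])
  sw_gm <- fuse_with_gip(sw, gm)
  disease_sets <- apply(dataset$assoc$disease, 1,
                        function(r) colnames(dataset$assoc$disease)[r == 1],
                        simplify = FALSE)
  mfs <- mirna_functional_similarity(disease_sets, dataset$dag)
  mfs_gm <- fuse_with_gip(mfs, gm)
  list(gm = gm, sw_gm = sw_gm, mfs_gm = mfs_gm)
}

#' Construct the five per-miRNA feature blocks
#'
#' The full feature pipeline: (1) embed the weighted sequence similarity
#' network (64-D) and the three bipartite association networks (128-D each)
#' with node2vec; (2) refine the three association embeddings with the
#' graph attention auto-encoder over the functional similarity network
#' (unless `cfg$use_gate` is `FALSE`); (3) add the four target-mRNA
#' co-localization ratios; (4) concatenate.
#'
#' @inheritParams compute_similarities
#' @param similarities optional precomputed result of
#'   [compute_similarities()].
#' @return a `"feature_bundle"` with blocks `sequence` (64), `disease`
#'   (128), `drug` (128), `mrna_network` (128) and `coloc` (4).
#' @export
featurize <- function(dataset, cfg = pipeline_config(), similarities = NULL,
                      sp = NULL) {
  mirnas <- dataset$mirnas
  if (is.null(similarities))
    similarities <- compute_similarities(dataset, cfg, sp = sp)

  n_s <- similarity_graph(similarities$sw_gm, threshold = 0)
  seq_block <- embed_network(n_s, mirnas, cfg$seq_dim, cfg$node2vec,
                             seed = stage_seed(cfg$seed, "embed:sequence"))

  n_f <- binarize_network(similarities$mfs_gm, cfg$functional_threshold)
  blocks <- list(sequence = seq_block)
  block_name <- c(disease = "disease", drug = "drug", mrna = "mrna_network")
  for (kind in c("disease", "drug", "mrna")) {
    g <- association_graph(dataset$assoc[[kind]])
    raw <- embed_network(g, mirnas, cfg$assoc_dim, cfg$node2vec,
                         seed = stage_seed(cfg$seed, paste0("embed:", kind)))
    if (cfg$use_gate) {
      gate_cfg <- cfg$gate
      gate_cfg$seed <- stage_seed(cfg$seed, paste0("gate:", kind))
      fit <- gate_fit(raw, n_f, gate_cfg)
      blocks[[block_name[[kind]]]] <- fit$H
    } else {
      blocks[[block_name[[kind]]]] <- raw
    }
  }
  blocks$coloc <- coloc_features(dataset$assoc$mrna, dataset$mrna_labels,
                                 mirnas)
  assemble_features(blocks,
                    expected = c("sequence", "disease", "drug",
                                 "mrna_network", "coloc"))
}

#' Run the full pipeline: features plus cross-validated evaluation
#'
#' @inheritParams featurize
#' @return list with `features` (the bundle) and `cv` (an `"mloc_cv"`).
#' @export
run_pipeline <- function(dataset, cfg = pipeline_config()) {
  features <- featurize(dataset, cfg)
  cv <- cross_validate(features, dataset$labels, cfg)
  list(features = features, cv = cv)
}
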