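#' Pipeline configuration
#'
#' Collects every tunable of the feature construction and classification
#' pipeline with its default. Any element can be overridden through `...`
#' (nested lists are merged, not replaced wholesale).
#'
#' @param ... named overrides, e.g. `folds = 5`,
#'   `node2vec = list(walk_length = 40)`.
#' @return a list of class `"mloc_config"`.
#' @details
#' * `seq_dim` (64) and `assoc_dim` (128) are the embedding widths for the
#'   sequence similarity network and the three association networks.
#' * `node2vec`: return parameter `p`, in-out parameter `q`, `walks_per_node`,
#'   `walk_length`, skip-gram `window`, `epochs`, `negative` samples and
#'   initial learning rate `lr` (word2vec-style linear decay).
#' * `gate`: encoder `layer_dims` (final must equal `assoc_dim`), Adam `lr`,
#'   `epochs`, `structure_weight` for the edge reconstruction term, and the
#'   hidden `activation` (`"sigmoid"` or `"linear"`).
#' * `alignment`: Smith-Waterman `match` / `mismatch` / `gap` scores.
#' * `functional_threshold`: binarization threshold `T` on the fused
#'   functional similarity when building the functional network.
#' * `classifier`: self-attention projection width `attention_dim`, hidden
#'   layer sizes, Adam `lr`, `epochs`, and `use_attention`.
#' * `threshold`: decision threshold turning per-label scores into label sets.
#' * `folds`: cross-validation folds. `use_gate`: refine association
#'   embeddings with the graph attention auto-encoder.
#' * `seed`: master seed; every stochastic stage derives its own stream from
#'   it via [stage_seed()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seq_dim = 64L,
    assoc_dim = 128L,
    node2vec = list(p = 1, q = 1, walks_per_node = 10L, walk_length = 80L,
                    window = 5L, epochs = 5L, negative = 5L, lr = 0.025),
    gate = list(layer_dims = 128L, lr = 1e-2, epochs = 400L,
                structure_weight = 1, activation = "sigmoid"),
    alignment = list(match = 2, mismatch = -1, gap = -2),
    functional_threshold = 0.65,
    classifier = list(attention_dim = 64L, hidden = c(256L, 64L), lr = 1e-3,
                      epochs = 300L, use_attention = TRUE),
    threshold = 0.5,
    folds = 10L,
    use_gate = TRUE,
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "mloc_config"
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$seq_dim > 0, cfg$assoc_dim > 0)
  if (cfg$functional_threshold < 0 || cfg$functional_threshold > 1)
    stop("functional_threshold must lie in [0, 1]")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("decision threshold must lie strictly in (0, 1)")
  if (cfg$folds < 2) stop("folds must be at least 2")
  if (cfg$node2vec$p <= 0 || cfg$node2vec$q <= 0)
    stop("node2vec p and q must be positive")
  if (tail_int(cfg$gate$layer_dims) != cfg$assoc_dim)
    stop("final GATE layer width must equal assoc_dim")
  if (cfg$gate$epochs < 1) stop("GATE epochs must be >= 1")
  with(cfg$alignment, {
    if (match <= 0 || mismatch > 0 || gap > 0)
      stop("alignment scoring requires match > 0, mismatch <= 0, gap <= 0")
  })
  invisible(cfg)
}

tail_int <- function(x) x[length(x)]

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may specify any subset of the [pipeline_config()] fields;
#' unspecified values keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `"mloc_config"`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml or .json, got: ", ext))
  do.call(pipeline_config, raw)
}

#' Derive a per-stage random seed
#'
#' Deterministically splits a master seed into independent streams, one per
#' named pipeline stage, so that end-to-end runs are reproducible while
#' stages stay decoupled.
#'
#' @param seed master integer seed.
#' @param stage stage name, e.g. `"walks:disease"`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483645 + 1)
}
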