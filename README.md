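# mirlocfuse

Multi-label prediction of miRNA subcellular localization from
multi-source association networks.

## The problem

A microRNA's function depends on where it is: mRNA silencing happens in
the cytoplasm and processing bodies, transcriptional regulation in the
nucleus, intercellular signalling through exosomes and microvesicles.
Experimentally mapping miRNAs to compartments is slow and expensive, and
most miRNAs occupy several compartments at once, so prediction is a
**multi-label** problem over seven classes: cytoplasm, exosome,
nucleolus, nucleus, extracellular vesicle, microvesicle, mitochondrion.

`mirlocfuse` builds a 452-dimensional representation of each miRNA from
five evidence sources and classifies it with a self-attention + MLP
multi-label network:

| block | source | method | dim |
|---|---|---|---|
| sequence | Smith–Waterman similarity network (GIP-backfilled) | node2vec | 64 |
| disease | miRNA–disease association network | node2vec + graph attention auto-encoder | 128 |
| drug | miRNA–drug association network | node2vec + graph attention auto-encoder | 128 |
| mRNA network | miRNA–mRNA association network | node2vec + graph attention auto-encoder | 128 |
| co-localization | target mRNAs' own 4-class localizations | per-compartment target ratios | 4 |

The core statistics, in the field's standard notation:

* GIP kernel: `GM(i,j) = exp(-λ‖A(i)−A(j)‖²)`, `λ = n / Σ_k ‖A(k)‖²`
  over binary association profiles;
* sequence similarity `SW(i,j) = sp(i,j)/√(sp(i,i)·sp(j,j))` from local
  alignment scores, zeros backfilled by `GM`;
* Wang-style functional similarity from disease semantic similarity over
  a disease DAG with decay Δ = 0.5, zeros backfilled by `GM`, binarized
  at a threshold `T` into the functional network used by the
  auto-encoder;
* co-localization ratios `R_loc(m) = |M_loc(m)| / |M(m)|` over the
  target set `M(m)`;
* training loss `L = −Σ_i [y_i log ŷ_i + (1−y_i) log(1−ŷ_i)]`;
* evaluation: aiming, coverage, accuracy, absolute true, absolute false
  (set-based multi-label metrics), plus per-label AUC/AUPR from pooled
  out-of-fold scores under seeded 10-fold cross-validation.

Because the real corpus (RNALocate labels, HMDD/ncDR/miRTarBase
associations, miRBase sequences) requires downloads, the package ships a
seeded synthetic generator that plants a recoverable localization signal
in the network structure — see `vignette("mirlocfuse-methods")`.

## Worked example

```r
library(mirlocfuse)

ds <- generate_dataset(synthetic_spec(n_mirna = 80, n_disease = 40,
                                      n_drug = 15, n_mrna = 120, s = 0.8,
                                      seed = 42))
cfg <- pipeline_config(seed = 42, folds = 5,
                       node2vec = list(walks_per_node = 5, walk_length = 40,
                                       epochs = 3),
                       gate = list(epochs = 150),
                       classifier = list(epochs = 200))
fb <- featurize(ds, cfg)
fb
#> Feature bundle: 80 miRNAs, 452 features
#>   blocks: sequence(64) | disease(128) | drug(128) | mrna_network(128) | coloc(4)

cv <- cross_validate(fb, ds$labels, cfg)
cv
#> 80 samples, 5 folds
#>   aiming 0.7998 | coverage 0.7488 | accuracy 0.6502 | absolute true 0.2750 | absolute false 0.1714
#>   average AUC 0.7057 | average AUPR 0.5129
tidy(cv)
#> # A tibble: 7 × 3
#>   label                   auc  aupr
#>   <chr>                 <dbl> <dbl>
#> 1 cytoplasm             0.782 0.767
#> 2 exosome               0.859 0.984
#> 3 nucleolus             0.613 0.104
#> 4 nucleus               0.876 0.623
#> 5 extracellular vesicle 0.712 0.230
#> 6 microvesicle          0.631 0.774
#> 7 mitochondrion         0.466 0.109
```

Reading the output: `accuracy` is the mean per-miRNA Jaccard overlap
between predicted and true label sets, `absolute true` the fraction of
exact set matches, and `absolute false` the normalized symmetric
difference. The per-label table shows where evidence is strong (common
compartments with many annotated partners) and where it is not — at this
deliberately small size (80 miRNAs) the rare compartments have only a
handful of positives and their AUC/AUPR are unstable; the shipped
300-miRNA benchmark reaches an average AUC of about 0.89
(`run_pipeline(benchmark_instance(), pipeline_config(seed = 1))`).

`autoplot(cv, ds$labels)` draws the pooled ROC curves,
`ablation(fb, ds$labels, cfg)` evaluates all 31 feature subsets, and
`group_analysis(ds$assoc$disease, ds$labels, cv$scores)` compares
strongly vs weakly associated miRNAs.

There is also a thin command-line interface over the same functions:

```sh
exec/mirlocfuse simulate  --out data/ --seed 7
exec/mirlocfuse featurize --data data/ --out features/ --seed 7
exec/mirlocfuse evaluate  --data data/ --features features/ --out eval/ --seed 7
```

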