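# visrep

Curation and evaluation tools for ecologically motivated image datasets and
deep-network models of the human ventral visual stream.

Datasets used to train deep neural networks as models of human vision are
usually engineering benchmarks, not reflections of what matters to human
observers. `visrep` implements the computational machinery for building a
dataset around *human* category statistics and for testing, with
representational similarity analysis (RSA), whether networks trained on such
a dataset better match cortical and behavioral data:

- **Lexical category selection.** Candidate basic-level categories are
  ranked by a frequency–concreteness index over a lexicon of nouns,

  FCI = ½ · f / max f + ½ · c / max c,

  where *f* is spoken-corpus word frequency and *c* the mean human
  concreteness rating (1–5 Likert). Only nouns with c ≥ 4.0 are considered;
  the top 3,500 by FCI go forward (`add_fci()`, `select_candidates()`).
- **Image curation.** Near-duplicate removal per category: center-crop,
  128×128 bilinear resize, PCA keeping 90% of variance, and flagging of
  image pairs whose PCA loadings correlate at Pearson *r* > 0.975; connected
  components form duplicate clusters, keeping the largest-resolution member
  (`dedup_category()` and stages). NSFW-score and minimum-image filters
  (`filter_nsfw()`, `filter_min_images()`).
- **Dataset trimming.** Two datasets are equated in category count and
  category-size distribution by rank-wise pairing of size-sorted categories
  and downsampling each pair to its minimum (`subsample_categories()`,
  `trim_pair()`).
- **RSA statistics.** Correlation-distance RDMs (`compute_rdm()`), Spearman
  model–brain comparison on upper triangles (`rdm_similarity()`,
  `model_score()`), leave-one-out lower bound of the noise ceiling
  (`noise_ceiling_lower()`), permutation tests over network instances with
  exhaustive enumeration for small designs (`permutation_test()`),
  Bonferroni correction, percentile bootstrap CIs (`bootstrap_ci()`),
  stimulus-wise decomposition and a directional animate-vs-inanimate
  interaction test (`stimuluswise_scores()`,
  `animacy_interaction_test()`), and percentage-bend robust correlation
  (`robust_correlation()`).
- **In-silico electrophysiology.** Face-selective units via one-sided
  rank-sum tests with network-wide Benjamini–Hochberg FDR
  (`selective_units()`), per-layer percentages (`layer_fractions()`), and
  paired signed-rank comparisons across training sets (`compare_groups()`).
- **Receptive-field arithmetic.** The rf/jump recursion for effective
  receptive fields of convolution/pooling stacks (`effective_rf()`) and a
  greedy solver choosing odd kernels so layer RFs track cortical pRF-size
  targets under a fixed field of view (`solve_kernels()`).
- **Synthetic data.** Seeded generators for every input the pipeline
  consumes — Zipfian lexicons, image sets with planted duplicates,
  multi-subject RDM stacks, instance scores, unit responses, category
  inventories, stimulus metadata — so everything runs and is validated
  without any download (`gen_*()`).

## Worked example

Score two families of model instances against a synthetic five-subject
brain-RDM stack, relative to the noise ceiling:

```r
library(visrep)

brain  <- gen_subject_rdms(n_subjects = 5, n_stimuli = 30,
                           noise_sd = 0.6, seed = 42)
inst_a <- gen_subject_rdms(10, 30, noise_sd = 0.7, seed = 42)$subjects
inst_b <- gen_subject_rdms(10, 30, noise_sd = 1.6, seed = 42)$subjects

sa <- vapply(inst_a, model_score, numeric(1), subjects = brain$subjects)
sb <- vapply(inst_b, model_score, numeric(1), subjects = brain$subjects)

mean(sa)                              # 0.492
mean(sb)                              # 0.229
noise_ceiling_lower(brain$subjects)   # 0.609

tidy(permutation_test(sa, sb, n_perm = 10000, seed = 1))
#>   statistic   p_value method      alternative n_splits   n_a   n_b
#> 1     0.263 0.0001000 monte_carlo two.sided      10000    10    10

bootstrap_ci(sa, seed = 2)
#>    mean lower upper level n_boot
#> 1 0.492 0.461 0.527  0.95   1000
```

The high-fidelity family A reaches a mean Spearman rho of 0.49 against the
subjects — about 81% of the lower noise-ceiling bound of 0.61, i.e. most of
the explainable representational variance — while the noisier family B
reaches 0.23. The permutation test re-splits the pooled instance scores
10,000 times and finds the 0.26 group difference essentially never under
the null (p = 1e-4, the add-one floor); the bootstrap CI resamples family
A's instances.

`autoplot()` on an RDM draws the dissimilarity heatmap;
`plot_rf_progression()` and `plot_layer_fractions()` visualise the
architecture solver and unit-selectivity results. See the methods vignette
(`vignettes/visrep-methods.Rmd`) for the statistical model behind each
step.

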