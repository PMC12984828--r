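# dysbioformer

Disease classification from gut-microbiome count tables with a
permutation-invariant multiset transformer, plus the full preprocessing
stack such a model needs: amplicon error-model denoising with chimera
removal, compositional normalization (zero replacement, CSS, CLR),
empirical-Bayes cross-study batch harmonization, phylogenetic kernel
embedding of taxa, leakage-safe study-aware cross-validation, and
attention-based biomarker attribution with cross-fold stability
selection.

## Who this is for

Microbiome researchers who want to (1) classify case vs control samples
across heterogeneous multi-study 16S collections, (2) test whether a
set-attention model recovers planted signal under realistic
compositional and batch confounding, or (3) rank taxa by how much a
trained model relies on them. A synthetic multi-study cohort generator
with known ground truth makes the entire pipeline testable end to end
with no downloads.

## The model

Each sample is an unordered multiset of taxon tokens. A token for taxon
*i* concatenates spectral features of the phylogenetic kernel
`K = exp(-lambda * d)` (patristic distances *d*), the harmonized CLR
abundance, and the compositional weight `w_i = log(1 + x*_i K̄_i)`; after
feature standardization the token is projected and scaled,
`z_i = w_i (W_e ẽ_i + b_e)`. Stacked Set Attention Blocks apply
multihead self-attention over the multiset,

    A_ij = (Q z_i)·(K z_j) / sqrt(d_k),   α = row-softmax(A),
    h_i  = Σ_j α_ij V z_j,

with residual connections, layer normalization and a per-token
feed-forward in each block. Pooling-by-Multihead-Attention attends from
learnable seed vectors onto the token set — a softmax over taxa per
seed — and the pooled seed outputs feed a feed-forward classifier. The
whole forward map is permutation-invariant; attention weights double as
the attribution signal. Training is Adam on class-weighted
cross-entropy with hand-derived backpropagation (verified against
finite differences in the test suite); the attention kernels are
RcppArmadillo.

Preprocessing is fitted on training folds only and applied frozen to
held-out samples; every fitted object carries its fitted-on sample list
and the cross-validation driver raises on any overlap with test IDs.

## Worked example

Simulate a two-clinic case–control cohort with one strongly
disease-enriched taxon and batch shifts, then train and evaluate with
whole clinics held out:

```r
library(dysbioformer)

tree <- simulate_tree(30, seed = 7)
cfg  <- sim_config(
  n_taxa = 30,
  studies = list(list(study_id = "clinic_a", n_case = 30, n_control = 30),
                 list(study_id = "clinic_b", n_case = 30, n_control = 30)),
  effect_taxa = c(taxon_0012 = 2.0),
  batch_shift_sd = 0.8, seed = 7)
sim <- simulate_cohorts(cfg, tree)
sim$counts
#> count_table: 30 taxa x 120 samples, total reads 1,206,131

net_cfg <- net_config(token_dim = 16, sab_layers = 2, n_heads = 2,
                      pma_seeds = 2, ffn_hidden = 32, head_hidden = 16,
                      lr = 2e-3, batch_size = 16, epochs = 40,
                      val_frac = 0, seed = 42)
res <- run_cv(sim$counts, sim$meta, tree, net_cfg,
              mode = "leave_study_out", n_folds = 2, seed = 42)
res
#> cv_result: 2 folds (leave_study_out)
#>   accuracy  0.675 +/- 0.035
#>   precision 0.609 +/- 0.030
#>   recall    0.983 +/- 0.024
#>   f1        0.752 +/- 0.016
#>   auc       0.937 +/- 0.069
```

Mean AUC 0.937: the model ranks held-out-clinic cases above controls
reliably. Accuracy at the fixed 0.5 threshold is lower (0.675) because
the held-out clinic's batch shift moves the probability calibration —
the correction cannot be fitted for a study it has never seen — while
the within-clinic ranking that AUC measures survives. Attribution
across the two folds puts the planted taxon near the top:

```r
stab <- stability_selection(lapply(res$folds, `[[`, "attribution"), k = 5)
head(stab, 5)
#>         taxon stability mean_combined
#> 9  taxon_0009       0.5     0.5763078
#> 13 taxon_0013       0.5     0.5620074
#> 12 taxon_0012       0.5     0.4769064
#> 26 taxon_0026       0.5     0.4586433
#> 1  taxon_0001       0.5     0.4473697
```

`taxon_0012` — the planted effect — ranks third of 30 by mean combined
attention score in this small two-fold run; on the full five-study
benchmark (100 taxa, five planted effects; see the methods vignette)
all five planted taxa enter the attribution top-10.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/dysbio.R simulate --out data/ --seed 42
Rscript inst/cli/dysbio.R validate --counts data/counts.tsv --meta data/meta.tsv
Rscript inst/cli/dysbio.R train    --counts data/counts.tsv --meta data/meta.tsv \
    --tree data/tree.nwk --mode leave_study_out --folds 5 --seed 42 --out results/
```

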