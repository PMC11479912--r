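# tcrcost

Structure-aware TCR–peptide binding prediction for R.

T-cell receptors (TCRs) recognise antigenic peptides mainly through their
CDR3α and CDR3β loops. Binding prediction from sequence alone has
plateaued, and predicted 3D structures of CDR3A:CDR3B:peptide complexes
are attractive inputs — but structure predictors handle these short,
hypervariable loops poorly, with side chains modelled worse than
backbones. `tcrcost` implements a two-stage pipeline for exactly this
setting:

1. **Structure correction.** A neural corrector refines low-quality
   predicted coordinates. Atoms are split into main chain (N, CA, C, O)
   and side chain via binary membership matrices; after a shared 1D
   convolution along the atom axis, each chain is corrected by a two-layer
   bidirectional LSTM, the chains are recombined, and a final LSTM adjusts
   the whole structure. Training uses three geometric losses:
   - `l_main()`: a frame-aligned point error — every residue's N/CA/C
     triad defines a local frame, and deviations are measured in every
     residue's frame, making the loss rigid-invariant,
     `L = (1/N²) Σᵢⱼ ‖Tᵢ⁻¹(xⱼ) − T̃ᵢ⁻¹(x̃ⱼ)‖`;
   - `l_side()`: a thresholded distance-difference loss over side-chain
     atom pairs (thresholds 0.5/1/2/4 Å, weights ¼), in [0, 1];
   - `l_all()`: the frame-aligned error of the full backbone plus L1
     penalties on peptide-bond lengths C(i)–N(i+1) and angles
     CA(i)–C(i)–N(i+1).
2. **Binding classification.** Complexes are rasterised onto a
   48×48×48×8 voxel grid (1 Å voxels, one channel per atom feature:
   element, charge, aromaticity, ring membership, hybridization, and
   explicit/implicit/total valence) and classified by a four-layer
   residual 3D CNN with batch normalisation and a sigmoid head.
   Peptide-swap negatives give a 1:1 class balance.

Structure quality is scored by `rmsd()` over paired atoms (no
superposition); classification by accuracy, recall, precision, F1 and
rank-based AUC (`classification_metrics()`, `auc_score()`).

A deterministic synthetic-complex generator (`synth_config()`,
`make_binding_dataset()`, `make_correction_pairs()`) builds idealized
CDR3A:CDR3B:peptide complexes with a planted geometric binding rule and a
noise model whose side-chain error exceeds its main-chain error, so the
whole pipeline trains and evaluates offline.

## Worked example

The snippet below generates a synthetic study, trains the corrector on 50
(predicted, precise) pairs, and trains the binding classifier on 160 of
200 labelled complexes (the correction run takes a few CPU-minutes):

```r
library(tcrcost)

# synthetic study: 50 (predicted, precise) pairs with the default noise
# model (main-chain sd 1 A, side-chain sd 2 A)
cfg <- synth_config(seed = 7)
pairs <- make_correction_pairs(cfg, n = 50)

# l_side worked example: every pairwise distance off by 5 A
Dr <- matrix(1, 3, 3); diag(Dr) <- 0
Dc <- matrix(6, 3, 3); diag(Dc) <- 0
l_side(Dc, Dr)
#> [1] 0.625

# losses on one (predicted, precise) pair
al <- align_atom_order(pairs$precise[[1]], pairs$predicted[[1]])
rmsd(al$predicted, al$precise)
#> [1] 2.849953
l_main(al$predicted, al$precise)
#> [1] 8.87105

# train the corrector and measure the mean RMSD before/after correction
fit <- train_correction(pairs, correction_config(
  lstm_hidden = 16, epochs = 300, learning_rate = 1e-2,
  batch_size = 10, seed = 1))
post <- sapply(seq_len(nrow(pairs)), function(i) {
  al_i <- align_atom_order(pairs$precise[[i]], pairs$predicted[[i]])
  rmsd(correct_structure(fit, al_i$predicted), al_i$precise)
})
pre <- sapply(seq_len(nrow(pairs)), function(i) {
  al_i <- align_atom_order(pairs$precise[[i]], pairs$predicted[[i]])
  rmsd(al_i$predicted, al_i$precise)
})
c(predicted = mean(pre), corrected = mean(post))
#> predicted corrected
#>  2.889873  2.692476

# binding: train on 160 complexes, hold out 40 (grouped by TCR)
ds <- make_binding_dataset(synth_config(n_complexes = 200, seed = 21))
sp <- cv_split(nrow(ds), ratio = 0.8, seed = 11, group = ds$tcr_id)
bfit <- train_binding(ds[sp$train, ], binding_config(
  channels = c(8, 16, 16, 32, 32), input_pool = 2, epochs = 10, seed = 5))
metric_report(ds$label[sp$test], predict_binding(bfit, ds[sp$test, ]))
#> # A tibble: 1 x 9
#>     acc   rec   pre    f1   auc    TP    FP    TN    FN
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <int> <int>
#> 1 0.875 0.895  0.85 0.872 0.962    17     3    18     2
```

`rmsd()` values are in Ångström and are computed on paired atoms with no
superposition, so the drop from 2.89 to 2.69 Å means the corrected
coordinates genuinely moved towards the reference structures.
`metric_report()` returns accuracy, recall, precision, F1 (on the 0.5
threshold) and rank-based AUC together with the confusion counts; an AUC
of 0.96 on the held-out TCRs shows the classifier recovered the planted
geometric binding rule from the voxelized structures.

The fitted objects follow broom conventions: `tidy()` returns the
per-epoch loss trace, `glance()` a one-row fit summary, and `autoplot()`
the training curves. A thin command-line front end is installed under
`inst/cli/tcrcost` with subcommands `simulate`, `train-correct`,
`correct`, `featurize`, `train-bind`, `predict` and `evaluate`.

## Package layout

- `R/structure.R` — PDB parsing/writing, canonical atom order, padding,
  chain membership matrices
- `R/geometry.R` — residue frames, the three losses, bond geometry, RMSD
- `R/correction.R`, `R/nn-core.R`, `src/` — the correction network and its
  hand-written training machinery
- `R/features.R`, `R/voxel.R` — atom features and voxelization
- `R/binding.R` — peptide-swap negatives, the residual 3D CNN
- `R/metrics.R` — classification metrics, AUC, splits
- `R/synthdata.R` — the synthetic-complex generator
- `vignettes/tcrcost-methods.Rmd` — model assumptions, design decisions
  and limitations
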