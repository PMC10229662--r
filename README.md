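# retrosynth

Semi-template **one-step retrosynthesis prediction** on molecular graphs, in
R. Given a target molecule (the product), `retrosynth` answers the question a
synthetic chemist asks first — *where do I disconnect this molecule, and
what reactants do I need?* — in two learned steps:

1. **Reaction-center identification.** A directed graph message-passing
   network encodes the product; typed heads score every candidate center:
   a newly formed bond (**BF**), a bond with a changed order (**BC**), or an
   atom that lost a fragment (**A**). All candidates of all three types are
   normalized by one shared softmax, so the likelihoods
   `l(x) = exp(s(x)) / Δ` are comparable across types. BF centers
   additionally predict induced order changes of their neighbor bonds and
   per-atom charge-change classes (accept one electron / donate one
   electron / no change).
2. **Synthon completion.** Reversing the center edit splits the product into
   *synthons* — incomplete fragments with open valence. Substructures (a
   bond with one new atom, or a whole ring) mined from training reactions
   are attached sequentially at frontier atoms, driven by a continuity head
   ("attach more here?") and a type head (softmax over the vocabulary),
   both conditioned on the current intermediate graph, the synthons and the
   product. Inference is a greedy beam search ranked by the summed
   log-likelihood of every decision along the path.

The package is aimed at computational chemists who want a transparent,
fully inspectable implementation of this two-step graph approach: the
encoder, losses, teacher forcing and beam search are plain R matrix code on
a small autodiff tape, with Open Babel (via ChemmineOB) supplying canonical
SMILES and Morgan fingerprints. It includes a USPTO-style atom-mapped
reaction reader, a synthetic reaction generator with known ground truth,
evaluation (top-k accuracy, module-level protocols, reaction-similarity
diversity clustering), and a pipeline CLI.

## Worked example

```r
library(retrosynth)

# 1. a small training set of atom-mapped reactions with known centers
fx   <- generate_fixtures(fixture_spec(n = 60, seed = 11,
          mix = c(BF = .5, BC = .2, A = .3, UNCOVERED = 0)))
fx   <- head(unique_product_fixtures(fx), 30)
recs <- lapply(fx, `[[`, "record")

# 2. substructure vocabulary mined from reactant-synthon differences
vocab <- build_vocabulary(recs)
names(vocab$entries)
#> [1] "-Br"          "-C"           "-Cl"          "-N"           "-O"
#> [6] "[c:1]1ccccc1"

# 3. train both modules (a small encoder suffices at this scale)
cfg <- encoder_config(hidden = 32, ta = 3)
cm  <- center_model(cfg, seed = 2)
cm  <- train_center_model(cm, recs, epochs = 250, lr = 1e-2, batch_size = 15)
sm  <- synthon_model(vocab, cfg, seed = 5)
sm  <- train_synthon_model(sm, completion_training_data(recs),
                           epochs = 150, lr = 1e-2, batch_size = 15)

# 4. predict reactants for a product (here methyl acetate, CC(=O)OC)
res <- predict_reactants(cm, sm, recs[[1]]$product, K = 5, N = 10)
head(as.data.frame(res), 3)
#>   rank   reactants   loglik  center
#> 1    1  C.COC(=O)C -0.01376 BF(4-5)
#> 2    2   C.CC(=O)O -5.42799 BF(4-5)
#> 3    3 CC.COC(=O)C -6.51943 BF(4-5)
canonical_smiles(recs[[1]]$reactants)
#> [1] "C.COC(=O)C"
```

The `reactants` column holds canonical, component-sorted SMILES for each
predicted reactant set; `loglik` is the summed log-likelihood of the center
choice and every completion decision (higher is better, 0 would be a
certain path); `center` names the disconnection that produced the
prediction — here the ester O–CH3 bond between product atoms 4 and 5 (a BF
center), correctly ranked first with the ground-truth reactant pair at a
path log-likelihood of -0.014.
`evaluate_models()` computes end-to-end and module-level top-k accuracies,
and `diversity_clusters()` groups products by the similarity profile of
their predictions.

A pipeline CLI wrapping these functions lives at
`inst/cli/retrosynth-cli.R` (subcommands `make-fixtures`, `preprocess`,
`build-vocab`, `train-center`, `train-synthon`, `predict`, `evaluate`).

## Package layout

- `R/mol_graph.R`, `R/smiles.R` — implicit-hydrogen molecular graphs and an
  atom-map-preserving SMILES parser/writer (canonical equality via Open
  Babel)
- `R/autodiff.R`, `R/encoder.R` — reverse-mode tape and the message-passing
  encoder
- `R/reaction_prep.R`, `R/substructure.R` — center labeling, product-to-
  synthon edits, completion paths, vocabulary
- `R/center_model.R`, `R/synthon_model.R`, `R/inference.R` — the two
  modules and beam-search prediction
- `R/evaluation.R`, `R/fixtures.R` — metrics, diversity analysis, the
  synthetic generator and USPTO-style I/O
- `vignettes/retrosynthesis-model.Rmd` — the model, its assumptions and
  design decisions
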