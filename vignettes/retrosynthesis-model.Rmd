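---
title: "A two-step graph model for one-step retrosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-step graph model for one-step retrosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosynth)
```

## The problem

One-step retrosynthesis asks: given a target molecule (the *product*), which
reactant molecules could produce it in a single reaction? `retrosynth`
implements a semi-template approach that mirrors how a chemist disconnects a
molecule: first find the *reaction center* — the place where the product
differs from its reactants — then rebuild the reactants from the resulting
fragments.

The pipeline has two learned modules over molecular graphs:

1. **Reaction center identification.** Every bond and atom of the product is
   scored as a candidate center of one of three types:
   - **BF** (bond formation): a product bond that did not exist in any
     reactant. Breaking it splits the product into two *synthons*. Bond
     formation can induce order changes in the bonds adjacent to the center,
     and atoms at or next to the center can gain or lose one electron
     (formal-charge change); both side effects are predicted by dedicated
     heads.
   - **BC** (bond change): a bond whose order differs between product and
     reactants; the head scores each of the three possible original orders,
     with the slot equal to the product's (kekulized) order inadmissible.
   - **A** (atom): an atom that carries a leaving fragment in the reactants;
     the synthon is the product itself.
   This typed definition intentionally does not cover reactions with several
   formed/changed bonds (rearrangements, cyclizations, click chemistry);
   those records are labeled UNCOVERED, excluded from training and counted
   as automatic misses in evaluation, which is why coverage bounds every
   top-k accuracy.
2. **Synthon completion.** Starting from the center atoms, substructures are
   attached one at a time: a *bond unit* (one new atom joined by a single,
   double or triple bond) or a *ring unit* (a whole single or polycyclic
   ring joined by a new single bond at its attachment atom). Two heads drive
   the process: a continuity head (attach more at this atom, or stop?) and a
   type head (which vocabulary substructure?). The vocabulary is mined from
   the training data as the canonical-keyed union of all reactant-minus-
   synthon differences.

## Graph encoder

Molecules are 2D graphs of heavy atoms (hydrogens are implicit counts;
stereochemistry is ignored). Atom features are one-hot blocks for element
(ten common elements plus a reserved "other" slot), total valence, formal
charge and hydrogen count, plus ring/aromaticity flags and an optional
ten-slot reaction-class block that stays all-zero when the class is unknown.
Bond features are the order one-hot plus conjugation, aromaticity and ring
flags.

The encoder is a directed-message-passing network: each bond carries two
messages, initialized to zero and updated for `ta` iterations from the
source atom's features, the bond's features, and the incoming messages at
the source *excluding the reverse message*. An atom's embedding is a
learned readout of its features and the concatenation of its incoming
messages from all iterations, so its receptive field is a ball of radius
about `ta + 1` bonds — a property the test suite checks directly. The graph
embedding is the plain sum of atom embeddings (so disconnected synthon
graphs encode additively), and a bond's embedding combines the sum and the
absolute difference of its endpoint embeddings, making it invariant to
endpoint order.

All heads are linear-plus-ReLU maps on these embeddings. Center scores of
all three types are normalized *jointly*: one softmax over every admissible
candidate (all bridge bonds for BF, two admissible order slots per bond for
BC, every atom for A), so scores are comparable across types at inference —
the same normalizer the training loss uses. Training minimizes the summed
cross entropies of the center choice, the neighbor-change classes and the
charge classes with Adam; the completion module is trained with teacher
forcing (ground-truth attachments are applied while the continuity and type
decisions are supervised).

Everything is implemented on a small reverse-mode automatic-differentiation
tape over dense matrices; gradients are verified against finite differences
in the test suite.

## Inference

For a product, the top-K centers (per type, then overall) seed one beam.
Each candidate's score is the sum of the log-likelihoods of every decision
on its path, initialized with the center's joint log-likelihood plus the
argmax log-probabilities of its induced-change predictions. At each step a
candidate spawns a "stop at this frontier atom" child and the top-N
attachment children; the top-N scored children survive. Search ends when N
completed reactant graphs exist and no incomplete candidate outscores the
N-th best completed one. Completed graphs are finalized (open valence
becomes hydrogens), canonicalized, deduplicated keeping the best score, and
ranked; score ties break lexicographically on the canonical SMILES so runs
are byte-reproducible.

## Design choices where the design was open

- **Attachment anchoring.** A bond unit is keyed only by its order and new
  atom (`-O`, `=O`, `-Cl`, ...): the anchor-side atom of the attached bond
  is the anchor itself. A ring unit fuses nowhere — it is joined to the
  anchor by a new single bond at a designated attachment atom, and is keyed
  by a canonical fragment string with that atom marked. Ring fusion sharing
  a bond or an atom with the synthon is not expressible; records needing it
  are excluded from training and counted.
- **Hydrogen bookkeeping.** Synthon atoms keep their product hydrogen
  counts, so the valence freed by the center edit stays open until
  completion; attachments may displace hydrogens, and finalization refills
  open valence at frontier atoms. This makes "leaving group replaced by H"
  exact rather than heuristic.
- **Depth-first order.** Ground-truth completion paths visit frontier atoms
  with a stack seeded by the center atoms; ties among siblings break by
  canonical atom rank (a Morgan-style refinement), which makes teacher
  forcing and replay deterministic.
- **Invalid attachments** are masked before the type softmax at inference
  and the distribution renormalized, so every completed graph is
  valence-valid by construction.
- **Joint normalizer at inference.** The training loss defines the shared
  normalizer over all candidate types; we reuse the same normalization for
  ranking so center log-likelihoods are comparable across types.
- **Duplicate reactant sets** reached by different paths are merged keeping
  the best score, since accuracy counts distinct predictions.
- **BC slots and aromatic bonds.** Admissible original orders exclude the
  bond's kekulized product order; aromatic bonds use a backtracking perfect
  matching to obtain that order.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden` | 300 | embedding width (tests and examples use 8–32) |
| `ta` | 5 | message-passing iterations (receptive radius) |
| `K` | 10 | center beam width |
| `N` | 10 | completion beam width / result length |
| `lr` | 1e-3 | Adam learning rate (recovery experiments use 1e-2) |
| `batch_size` | 32 | gradient accumulation size |
| `max_steps` | 30 | attachment cap per completion path |

Defaults follow common graph-message-passing practice; at the package's
experiment scale (tens of reactions, vocabularies under ten entries) a
width of 32 and two iterations are enough to drive the training losses near
zero, and all experiment sizes were chosen so the full suite runs in
minutes on one CPU core.

## The synthetic reaction generator

Real atom-mapped benchmarks are large external downloads, so the package
ships a generator that emulates their format with known ground truth. It
works in reverse: a product is sampled from a curated pool of sixteen small
scaffolds (amide, ester, ether, amine, aryl and nitrile motifs), randomly
decorated with up to two small substituents (so distinct records get
distinct products and the product-to-center mapping stays learnable), and a
center type is drawn from a configured mix. The inverse edit then builds
the reactants: a BF split attaches leaving groups from a pool (hydroxyl,
halides, methyl, amino, phenyl) to the freed valences with probability 0.7
per side, induces a neighbor-bond order change with probability 0.12 and a
charge edit with probability 0.08; a BC edit raises or lowers a bond order
where valence allows; an A edit appends a pool fragment at an atom with
spare hydrogens; UNCOVERED records break two bonds at once. The default mix
keeps 2.3% of records uncovered — the share of multi-edit reactions
reported for the patent-derived benchmark this format emulates — and makes
bond formation the dominant covered kind, as in bond-forming patent
chemistry.

What the generator does *not* emulate: the structural diversity of real
drug-like products (tens of heavy atoms, fused heterocycles), stereo
chemistry, reagents/catalysts, noisy or partial atom mappings, and class
imbalance across ten reaction types. Passing the recovery experiments
therefore shows that the model class, losses and search are implemented
correctly and can represent the mapping on clean data — not that the
trained toy models generalize to real chemistry.

## Numerical notes and degenerate inputs

- Probabilities are computed with stable log-softmax; a zero probability
  scores `-Inf` and prunes the candidate.
- Empty graphs cannot be encoded (typed error); a product with a single
  atom has only A candidates; identity reactions label UNCOVERED.
- Open Babel performs canonicalization and Morgan (ECFP4) fingerprints;
  fingerprints are folded from 4096 to 2048 bits by OR, and reaction
  similarity follows the 2-vs-2 best-pairing, 1-vs-2 composite-molecule and
  1-vs-1 definitions exactly, in [0, 1] and symmetric.
- K-means diversity clustering runs on relative-frequency histograms of
  pairwise prediction similarities (ten equal bins over (0, 1]); clusters
  are reported ordered by mean similarity, with a fixed seed for
  reproducible restarts.

## Known limitations

- Only single-center reactions are covered (one formed bond with induced
  changes, one changed bond, or one fragment-losing atom).
- Atom mappings are required as input; the package does not compute them.
- Substructures never fuse rings onto existing ring systems.
- The summed log-likelihood used for ranking is a search score, not a
  calibrated reaction probability.
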