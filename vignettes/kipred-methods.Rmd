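---
title: "Pair-feature prediction of kinase–inhibitor binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-feature prediction of kinase–inhibitor binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A binding panel of m protein kinases against n small-molecule inhibitors is
an m × n binary matrix. `kipred` casts its completion as classification on
pair instances: kinase i contributes a feature vector $K_i$, inhibitor j a
vector $I_j$, and the instance is the concatenation $(K_i, I_j)$ labelled by
the matrix cell $y_{ij} \in \{0, 1\}$. The assumption underneath is the
structure–activity paradigm: binding is driven by the chemical environment
of the kinase's ATP pocket (hence active-site–focused sequence features) and
by substructures and physico-chemical properties of the ligand. No single
feature family is expected to suffice; the design gives a classifier a
*diverse* pool — phylogeny, sequence motifs, alignment profiles, active-site
residues on the protein side; substructures, descriptors, pharmacophores and
binding-profile similarity on the ligand side — and lets it pick.

All classification is binary; graded affinities are assumed to have been
thresholded upstream, and the package refuses non-binary matrix cells
rather than guessing a threshold.

## Kinase features

**Frequent sequence patterns (`Apri`).** A levelwise search over
fixed-length contiguous motifs: level-1 candidates are single residues, and
two frequent length-k patterns merge into a length-(k+1) candidate when the
(k−1)-suffix of one equals the (k−1)-prefix of the other. Support is counted
once per sequence, so a motif repeated inside one kinase contributes 1. A
wildcard symbol matches exactly one arbitrary residue — not a gap, not a
run — because the motifs are fixed-length and contiguous; at most two
wildcards are allowed per pattern and never at the ends, where they carry no
information. Internally the search also carries patterns with boundary
wildcards: without them the merge operator cannot reach every interior
wildcard placement; they are scaffolding and are filtered from the output.
The frequent set is then reduced to *border elements* — patterns with no
frequent proper super-pattern, where "p is a sub-pattern of q" means p
occurs contiguously in q with p's wildcards matching anything. Defaults:
minimum support 50% of the corpus, minimum reported size 3, maximum length
10. These are deliberate conventions — nothing in the method pins them — and
are ordinary function arguments.

**PROSITE-style motifs (`PRO`).** Patterns are user-supplied in the classic
dash-separated syntax. The supported subset (residues, `x`, `[..]`, `{..}`,
`x(n)`, `x(n,m)`, anchors `<`/`>`) is translated to anchored regular
expressions; anything else is rejected loudly rather than silently
mis-matched.

**Alignment profiles (`glAli`, `locAli`).** Each kinase is represented by
its vector of alignment scores against all m reference kinases, so the
feature dimension grows with the panel. Global scores use Needleman–Wunsch
with PAM120 (default) or BLOSUM62 and a *linear* gap model — "uniform cost
for opening and extension" is read as opening = extension, implemented by
setting the affine opening cost to zero. Gap defaults are −8 (PAM120) and
−4 (BLOSUM62), conventional magnitudes for these matrices; the method
itself fixes no value. Full-length global scores are dominated by regions
irrelevant to binding, which motivates the frame-restricted variant:

* a column is *conserved* when one residue (gaps excluded) occurs in
  strictly more than a threshold number of rows. The threshold generalizes
  the "more than 100 of 113" rule to a fraction (default 100/113 ≈ 0.885)
  so alignments of any depth behave alike; an absolute count takes
  precedence when supplied.
* conserved columns that are not in the user-supplied active-site column
  set are discarded; each survivor spans a window of ±5 columns (the
  `flank` parameter, anchored at the "at most five amino acids away"
  geometry); overlapping or adjacent windows merge into one frame.
* a frame pair is scored either column-wise as cut from the MSA — a
  residue–gap column costs the gap penalty, a gap–gap column 0, a choice
  that keeps self-scores maximal where the method itself is silent — or
  after removing gaps and globally realigning the two cut-outs.

The frame geometry is not fully pinned by its verbal description (windows
could in principle be asymmetric, or near-anchors could stay separate);
±flank with merging is this package's explicit reading, and `flank` stays a
parameter. The group name `locAli` follows the field's table shorthand even
though the computation is frame-restricted MSA scoring, not Smith–Waterman.

**Position-specific features (`PSF`, `abPSF`).** The residue at each
active-site MSA column, as a nominal feature; a gap is its own category.
The abstract variant maps residues through a physico-chemical class map.
The shipped default has five classes — hydrophobic (AVLIMC), aromatic
(FWY), polar (STNQGP), positive (KRH), negative (DE) — and is overridable
from a TSV, since no canonical map exists.

## Inhibitor features

**Free trees (`FTs`).** Maximal frequent connected acyclic substructures,
matched by element symbol and bond order, hydrogens implicit. The miner
grows patterns one labelled leaf at a time, deduplicates by a canonical
form (root the tree at its one or two centroids, encode children in sorted
order, take the lexicographic minimum — centroids are isomorphism-invariant,
so the form is too), and counts support once per molecule by backtracking
subgraph isomorphism, restricted by anti-monotonicity to the parent
pattern's supporting molecules. The frequency threshold defaults to 10% —
deliberately low, so potentially important substructures are not excluded
up front — and the border-element reduction keeps only maximal patterns.
Pattern growth is capped at 8 atoms by default; the cap bounds an otherwise
exponential search and is an explicit tunable, not part of the method.

**Binding-profile KNN (`KNN`).** Inhibitor similarity is the Tanimoto
coefficient c/(a+b−c) on binding profiles (or the raw common-binding
count), with two all-zero profiles defined as similarity 0. The feature
vector of an inhibitor is its similarity to each of the n inhibitors with
all but the k = 3 most similar zeroed, ties at rank k broken by column
order. These features read the label matrix, so they are *leakage-sensitive*:
the evaluation loop recomputes them per split from the matrix with the test
kinase's row removed, and in the hard case — where no binding information
about the test molecules exists at all — they are emitted as zeros with a
warning.

**Descriptors (`CF`, `GF`).** The chemical descriptors are this package's
own engine over the hydrogen-suppressed graph: molecular weight (with
implicit hydrogens), H-bond donor count (N/O with ≥ 1 attached H), acceptor
count (N/O with non-positive formal charge), rotatable bonds (single,
acyclic, both ends non-terminal), heavy-atom, heteroatom and ring-bond
counts. Descriptor values of engines differ; tests pin this engine, not any
other. Geometry: topological diameter plus the extents of the
principal-axis-aligned bounding box of 2D coordinates; molecules without
stored coordinates get a deterministic classical-MDS layout of the
bond-distance matrix, so the features are reproducible.

**3-point pharmacophores (`P`).** Atom roles by priority POS > NEG > HBD >
HBA (charge sign first, then donor, then acceptor); every unordered triple
of role atoms is keyed by its sorted roles and sorted binned distances.
Distances are topological (bond counts) with default bins 1–2 / 3–4 / 5–6 /
≥ 7 — the 2D simplification makes bond-count distances the natural metric,
and the bins are a package convention. Feature columns are the 50 most
frequent triplet keys over the corpus (ties alphabetical).

## Classification

Nominal features go to the tree natively as factors; for SVMs they are
encoded nominal-to-binary (a 2-category column becomes one 0/1 column, a
k-category column k indicators) and all columns are min-max normalized with
statistics fitted on the training rows of each split, test values clipped
to [0, 1]. The SVM wrapper (libsvm via e1071) offers linear, quadratic
(homogeneous polynomial, degree 2, γ = 1, offset 0) and RBF kernels with
cost C = 1 by default. The tree is CART via rpart — an open stand-in for
the C4.5/C5 family, with the minimum leaf support mapped to `minbucket`
(default 2) and pruning strength to the complexity parameter (default
0.01); confidence-interval pruning has no exact rpart analogue, which is a
documented approximation, not an oversight. Decision scores are class-1
probabilities (tree) or signed decision values thresholded at 0 (SVM).

## Evaluation framework

One split per pair, m·n splits per run. Training-set contents by case:
soft = mn−1 pairs; hard = (m−1)(n−1); restricted soft (only pairs
containing a test molecule) = (m−1)+(n−1); mixed cases = hard +
`round_half_up(f_k · m)` pairs pairing the test inhibitor with distinct
training kinases + `round_half_up(f_i · n)` pairs pairing the test kinase
with distinct training inhibitors. Rounding is half-up, anchored by
50% of 113 → 57. Note the cross-multiplication: the amount of information
about the test *inhibitor* scales with the number of kinases available as
partners, and vice versa — the feasible reading of the worked numbers (57
kinase-partner and 10 inhibitor-partner pairs at 50% on a 113 × 20 panel),
since a test kinase has only n−1 = 19 possible partners. Insertions are
sampled uniformly without replacement, per split and per repeat
(resampling per test split is the more conservative choice where the
procedure's description leaves it open); mixed-case results average over
seeded repeats (default 10).

Leakage control is structural: every split asserts the test pair absent
from training (and, in the hard case, no shared molecule); KNN features and
normalization statistics are computed from training information only.
Training accuracy re-predicts each split's training pairs and pools them.

Metrics come from the confusion counts: accuracy, TPR, PPV, TNR, NPV, with
zero-denominator ratios reported as missing rather than 0. The identity
accuracy = π·TPR + (1−π)·TNR (π the positive prevalence) is asserted in the
tests. Baselines: majority class (ties predict no-binding) and the
probability-product rule — binding iff p̂_kin · p̂_inh strictly exceeds θ,
with both probabilities estimated on the test molecules' training pairs
(undefined in the hard case, and refused there) and θ chosen on a 0–1 grid
of step 0.01 to maximize mean accuracy, ties to the smallest θ.

The random-feature ablation (`randomize_features`) replaces numeric columns
of named groups by uniform integers within the observed column range —
degenerate ranges stay constant — and refuses nominal columns, for which the
ablation is undefined.

## The synthetic data generator

`generate_bundle()` emulates the statistical shape the pipeline assumes: a
panel whose positive rate is the canonical 26.4%, kinases whose active
sites determine binding, and inhibitors whose shared substructures do.

* **Kinases** are drawn pre-aligned (no indels), so the MSA is exact by
  construction; gap handling is exercised by dedicated hand-built fixtures
  instead, because no tested computation depends on indel realism beyond
  that. Active-site columns split into *anchor* columns, identical in every
  kinase (these are what conserved-column detection should recover), and
  *signature* columns carrying archetype-specific residues (these are what
  the classifier should exploit). Elsewhere each position shows its
  consensus residue with probability `conservation` (default 0.95).
* **Inhibitors** are linear/branched assemblies of 4–6 small acyclic
  fragments over C/N/O; carrier molecules additionally embed a
  thiourea-like S=C(N)N fragment — the grammar's only sulfur source, so
  substructure recovery cannot false-positive. Fragment counts are kept
  small deliberately: at the 10% mining threshold a small panel has a
  support floor of 1, and molecule size is the lever that keeps exhaustive
  pattern growth bounded.
* **Labels** follow Bernoulli(s · rule + (1−s) · π) where the rule is the
  conjunction "archetype-1 kinase ∧ carrier inhibitor". Archetype-1
  fraction 0.55 and carrier fraction 0.48 make the rule's expected rate
  0.55 × 0.48 = 0.264 = π, so at s = 1 the labels equal the rule exactly and
  no rebalancing noise is injected; if a realized rate ever misses π by
  more than two percentage points, a minimal random label subset is
  flipped toward it.

What passing the synthetic checks shows — and what it does not: the
pipeline detects a clean conjunctive signal planted in the very feature
families it computes, and stays at the majority rate when no signal exists.
Real panels have correlated noise, assay artefacts, non-conjunctive
structure–activity relationships and drug-like chemistry (rings, tautomers,
3D conformations) that the generator does not emulate; synthetic accuracy
says nothing quantitative about accuracy on a real screen.

## Problem sizes and numerical choices

The validation runs use a 40 × 10 panel (400 LOOCV splits) for the
signal-recovery and null-calibration checks and 6–20 × 4–8 panels in unit
tests; these sizes were chosen so a full leave-one-out sweep with per-split
feature recomputation remains a desk-scale computation while leaving the
binomial null interval tight enough (±4.3 points at n = 400) to be
informative. Determinism: every stochastic step (bundle generation, mixed
insertions, classifier fitting) flows from a single integer seed; repeated
runs are byte-identical. Ties are broken explicitly everywhere they can
arise (KNN rank ties by column order, θ ties to the smallest value,
majority ties to no-binding, pharmacophore column ties alphabetically).
Degenerate inputs have defined behaviour: empty pattern corpora give empty
sets, single atoms give all-zero geometry, all-zero profiles give
similarity 0, single-class training sets give a constant predictor with a
warning.

## Known limitations

* C5-style confidence pruning and Weka/SMO internals are approximated by
  rpart and libsvm respectively; numeric agreement with those engines is
  out of scope.
* `locAli` is frame-restricted MSA scoring, not true local alignment.
* The chemical descriptor engine is intentionally simple (counting-based);
  XlogP/TPSA-class descriptors are not computed.
* Hard-case KNN features are structurally undefined and zeroed; feature
  sets relying on them degrade to the majority predictor there, which is
  faithful behaviour, not a defect.
* The affine-gap model, Smith–Waterman, k-fold generalizations of the
  split framework, and affinity regression are deliberately not
  implemented.
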