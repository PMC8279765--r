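---
title: "pestiscan: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pestiscan: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pestiscan` detects bacterial pesticidal proteins with family-specific
profile hidden Markov models and compares the genomic neighbourhood of
genomic hits. This vignette is the package's own account of its methods:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## The profile HMM

A family model has `K` match states (one per consensus column of the
family alignment), interior insert states `I_1..I_{K-1}` and delete
states reachable between matches. Seven transition moves are modelled
per node — M→M, M→I, M→D, I→M, I→I, D→M, D→D — the Plan7 move set
without the J-state/multi-hit machinery. Scoring is **local**: a path
enters at any match state and exits from any match state, each with
probability `1/K`, and residues outside the aligned span score zero
log-odds against the background. All scores are reported in bits
(log base 2), the HMMER convention, so curated gathering-cutoff
magnitudes are comparable. Both the Viterbi (best-path) and forward
(all-path) scores are computed by one C++ dynamic program; **cutoffs
gate the full-sequence forward score**, a choice recorded in every model
file header (`SCORE_BASIS`), since the upstream tooling convention does
not pin down which score is gated.

Two consequences of the local entry/exit overlay are worth stating
plainly. First, the "model" is improper in the strict probabilistic
sense (as in HMMER's implicit local model): path mass is not
renormalised after adding entry/exit, and the brute-force oracle used in
the tests enumerates paths under exactly the same semantics. Second, any
model with `K ≥ 2` admits partial-entry paths, so `forward > viterbi`
strictly; the textbook single-path degenerate case exists only at
`K = 1`, which is how the equality test is written.

### Estimation

* **Match columns**: a column is a match column when its gap fraction is
  strictly below `gap_threshold` (default 0.5). The fixed fraction
  replaces hmmbuild's weighted heuristic because it is simple and
  directly testable.
* **Pseudocounts**: emission counts receive
  `alpha * 20 * background[r]` (default `alpha = 1`). With a uniform
  background this is exactly Laplace +1 — the hand-computable
  `(2+1)/(2+20)` case in the tests — and with the shipped Swiss-Prot-style
  background it is background-weighted. Full Dirichlet-mixture priors
  are out of scope. Transitions get Laplace pseudocounts over the legal
  moves (`pc_trans`, default 1).
* **Sequence weighting**: Henikoff position-based weights (normalised to
  the number of sequences), switchable off. This guards against the
  composition bias of over-represented subfamilies.
* **Insert emissions** default to estimated (counts + pseudocounts);
  `"background"` forces zero log-odds inserts, the HMMER default.
* **Transition counting corner case**: Plan7 has no I→D or D→I moves.
  An insert run flanked by a delete contributes its residues to insert
  emissions, but the node-to-node transition is counted as the direct
  move. This only matters for gappy, low-weight rows.
* **Consensus** is the per-state argmax of emission **odds**
  (emission / background), not raw emission: with background-weighted
  pseudocounts a raw argmax lets common residues (L, A) hijack the
  consensus of single-sequence models.
* **Ambiguity**: `X` scores as background (zero log-odds), `B→D`,
  `Z→E`, `U→C`, and `*` terminates a sequence.

## The model-building pipeline

* **Deduplication** collapses exact duplicates and exact full-length
  substrings (100% identity) onto the longest member; ties break
  lexicographically by id. The operation is idempotent.
* **Similarity graph**: edge weight is the raw Smith–Waterman score
  (BLOSUM62, gap open 10, extend 1; a gap of length *g* costs
  `10 + (g-1)`), with an edge floor of 50. Raw score rather than a
  bit-score conversion keeps the floor interpretable against the
  alignment matrix; the C++ kernel is checked against an independent
  naive implementation in the tests.
* **MCL** is implemented natively: self-loops at each node's maximum
  incident weight, column normalisation, then expansion (matrix
  squaring) alternating with inflation (elementwise power 2.0 by
  default, renormalise) until the maximum elementwise change is below
  1e-6 (cap 200 iterations — exceeding it is an error that reports the
  residual). Clusters are weakly connected components of the limit
  matrix's support. Column sums are tracked each iteration and stay
  within 1e-9 of 1. Inflation 2.0 is a declared default; the upstream
  literature names the algorithm, not its parameters.
* **Progressive alignment**: UPGMA guide tree on
  `1 − S(a,b)/min(S(a,a), S(b,b))` distances, then profile–profile
  Needleman–Wunsch with sum-of-pairs BLOSUM62 scoring, affine gaps and
  free end gaps. This is a deliberate stand-in for an external aligner;
  `build_models(aligner = ...)` accepts any function returning an
  alignment, so curators can substitute one.
* **Family size**: clusters need at least 5 members to become models
  (`min_size`); designated singletons can still be modelled explicitly,
  mirroring single-sequence models for rare groups.
* **Long crystal toxins**: sequences strictly longer than 1,000 aa can
  feed a dedicated C-terminal model. The toxin-core boundary is an
  explicit per-sequence input — domain coordinates are curation
  knowledge this package does not infer.

## Gathering-cutoff calibration

Positives and background sequences are scored with the forward
algorithm; a Gaussian KDE (Silverman's `bw.nrd0` on the pooled scores,
scalar override available) describes the mixture. The cutoff is placed:

* with **no background**: at `min(positives) − ε` (ε = 0.5 bits);
* when the sets are **separable** (`max(background) < min(positives)`):
  at the deepest density point inside the empty gap. This branch exists
  because with a narrow Silverman bandwidth a tight positive cluster
  fragments into micro-modes, and a mode-based valley search can land
  *inside* the positive cluster;
* otherwise: at the deepest density minimum between the mode nearest the
  positive median and the next mode below it; if the pooled density is
  unimodal the degenerate rule applies.

Inseparable inputs are never an exception: the validation report flags
criterion 4. The four model-quality criteria are (1) all positives at or
above the cutoff, (2) additional high-scoring matches listed for manual
review (informational), (3) negatives absent or below the cutoff,
(4) strictly positive separation.

## Scanning and classification

Every (query, model) pair is scored; one hit per pair (best local
alignment only — domain-level multi-hits are out of scope). With the
gate on, only above-cutoff hits are emitted; the disable switch surfaces
all positive-bit hits flagged `above_cutoff = FALSE`, so truncated
family members can be reviewed manually. A query's label is the group
label of its top above-cutoff model, reported as `candidate <group>` —
deliberately not a nomenclature assignment. GenBank queries come from
CDS `/translation` qualifiers (trusted over coordinates, with warnings
on inconsistency or internal stops), conceptual translation under
table 11 otherwise, and six-frame ORF calling (ATG/GTG/TTG starts,
≥ 50 aa) for records without CDS features.

Neighbour trees use 1 − fractional identity under the hit model's
profile alignment (identical residue columns over columns where either
row has a residue) — the upstream convention does not define the
distance, so this is the package's declared choice — with
neighbour joining on the query plus its 10 nearest group members
(clamped to group size) and negative branch lengths clamped to zero.

## Genetic context

Flank extraction takes up to 5,000 bp each side of the hit gene,
clipping at linear record edges (with truncation flags) and wrapping
across the origin of circular replicons. Re-annotation is uniform ORF
calling; ORFs overlapping a carried-over CDS by more than 80% are
suppressed. This replaces a full annotation pipeline on purpose: the
point is a *uniform* view across regions, not product names.

Region comparison seeds exact 12-mers, groups them per diagonal, merges
runs within 100 bp, extends ungapped with an X-drop of 20 (match +1,
mismatch −2) and filters blocks at ≥ 100 bp and ≥ 60% identity; the
reverse complement is searched separately and flagged `inverted`.
Consecutive display pairs are compared by default (all pairs on
request). **Limitation**: extension is ungapped, so an indel inside a
homologous tract splits it across diagonals into multiple blocks;
substitution-only homology — what the synthetic cassettes contain — is
recovered as single blocks. Coordinates are 0-based half-open
internally and 1-based inclusive in all user-facing TSV/SVG output. The
SVG renderer is plain deterministic text: byte-identical output for
identical input, shades scaled from the identity floor to 100%.

## The synthetic world

The generator's defaults state the world the tests run in: 3 families,
8 members each, 300 aa, divergence 0.15 expected substitutions per site
(members mutate independently from a random ancestor; substitutions
only), 40 decoys drawn from the pooled family composition, and 30 kb
AT-rich replicons (GC 0.35, like a *B. thuringiensis* plasmid) with the
cassette back-translated under uniform synonymous codon choice. These
sizes mirror a curated structural subgroup at desk scale: enough members
to build a model above the 5-member floor, divergence high enough that
members are clearly non-identical (~70% pairwise identity) yet far above
background. What the generator does **not** emulate: real codon usage,
indel processes within families, domain architecture (the planted
"toxin" has no three-domain structure), mobile elements, or database
contamination. A green end-to-end test therefore establishes that the
machinery is correct on its stated world, not that the curated-database
performance of the upstream publication is reproduced — that depends on
manually curated models and external databases and is explicitly out of
scope.

## Numerical and serialization notes

* All probabilities are carried in log2 space; log-sum-exp guards the
  forward recursion. Emission/transition distributions must sum to 1
  within 1e-9 (validated on construction and load).
* Ties everywhere break lexicographically by identifier; scan output is
  invariant to model and query order.
* The native model format prints doubles with 17 significant digits and
  round-trips bit-exactly; the HMMER3 ASCII export (5 decimals of
  −ln p) is interoperability-grade, and import of foreign HMMER3 files
  is best-effort (no prior reconstruction, mean-emission backfill for
  unparsed nodes).
* Every source of randomness flows through explicit seeds; a fixed seed
  reproduces model files byte for byte.
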