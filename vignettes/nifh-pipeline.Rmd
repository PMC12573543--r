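---
title: "Curating nifH amplicons and quantifying nitrogen fixation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating nifH amplicons and quantifying nitrogen fixation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package does

Surveys of nitrogen-fixing microorganisms (diazotrophs) in soil commonly
amplify an interior fragment of *nifH*, the gene encoding the nitrogenase
iron protein, with the degenerate PolF/PolR primer pair. Because *nifH* is a
protein-coding marker, amplicon sequence variants (ASVs) can and should be
curated at the protein level: a genuine NifH fragment translates without
internal stop codons and carries the two cysteines that ligate the
[4Fe-4S] cluster — positions 97 and 132 in the conventional *Azotobacter
vinelandii* numbering — inside the conserved `PGVGC` and `VVCGG` motifs,
with the MgATP-binding `YGKGGGIGK` motif further upstream in the full
protein. Frameshifted reads, pseudogenes that lost a ligating cysteine, and
off-target amplification products all fail one of these checks.

`nifhcurate` implements that curation logic as a tested pipeline:

1. **Reference database construction** (`build_database()`): candidate
   proteins are screened against characterised seed proteins by exhaustive
   pairwise alignment, filtered on the three conserved motifs,
   dereplicated, and labelled with a canonical NifH cluster (I–IV).
2. **ASV quality control** (`qc_filter()`): nucleotide ASVs are translated
   (best stop-free frame), mapped onto the numbering reference, and removed
   unless cysteines are present at mapped positions 97 and 132.
3. **Classification** (`classify_asv()`, `build_tree()`,
   `bootstrap_support()`): taxonomy and cluster are copied from the best
   database hit, and placement can be corroborated with a neighbor-joining
   protein distance tree with bootstrap support.
4. **Community statistics** (`aggregate_counts()`, `shannon_index()`,
   `anova_factorial()`, `tukey_hsd()`): relative-abundance profiles at
   cluster/phylum/family rank, Shannon diversity, and balanced factorial
   ANOVA with Tukey HSD letters.
5. **Isotope quantification** (`estimate_fixed_n()`,
   `summarize_fixation()`): biologically fixed nitrogen from
   ^15^N~2~-microcosm measurements.
6. **Synthetic data** (`generate_reference_corpus()`, `generate_asv_set()`,
   `generate_abundance_table()`, `generate_isotope_dataset()`): every input
   the pipeline consumes can be generated with known ground truth, so each
   stage is testable without field data.

# Models and procedures

## Alignment conventions

All pairwise alignment funnels through `align_protein()`: BLOSUM62
substitution scores with affine gap penalties (open 11, extend 1; a gap of
length $L$ costs $11 + L$), local (Smith–Waterman) or ends-free global
mode. Percent identity is matches divided by aligned columns after
stripping terminal-gap columns — the standard convention for comparing an
amplicon fragment with a full-length protein. Homology-screen coverage is
the aligned fraction of the shorter sequence. The default screen thresholds
(identity ≥ 40%, coverage ≥ 0.5) are deliberately permissive — NifH
homologs are well conserved — and both are exposed as parameters.

Multiple alignments for tree building are reference-anchored: every
sequence is aligned to the longest input with free terminal gaps and
projected onto its columns, insertions being dropped. For the scaffold
family this package analyses (fixed-length homologs differing by
substitutions) this projection is an exact multiple alignment; for
sequences with many indels relative to the anchor it is an approximation,
which is the main reason the tree module is described as desk-scale.

## Motif filter and QC rule

A candidate protein passes the motif filter iff all three motifs match
within their mismatch budget (default 0, exact). The budget exists because
the canonical motif list is representative rather than exhaustive; raising
it trades specificity for sensitivity and is left to the user.

The ASV filter is stricter than "motifs present": the translation is mapped
by ends-free alignment onto a full-length numbering reference and the
residues at mapped positions 97 and 132 must both be cysteine. Three
failure modes are distinguished — `no_frame` (no stop-free reading frame in
either orientation), `region_not_covered` (the alignment does not span
positions 97–132; such partial ASVs are removed, with their own reason code
so the two causes are never conflated), and `cys_absent`. Any internal stop
disqualifies a frame; an amplicon interior should contain none, so terminal
stops are treated as internal. Orientation: forward frames are tried first
and the reverse complement only consulted when the best forward score falls
below a floor (default raw score 50), since amplicon orientation is fixed
by the protocol but merged-read orientation can flip.

The bundled numbering reference (`nifh_reference_protein()`) is a
**synthetic** ~290-residue NifH-like scaffold with the canonical motif
architecture (Cys97 in `PGVGC`, Cys132 in `VVCGG`); it reproduces the
*A. vinelandii* numbering convention without shipping any database
accession. The four cluster anchors share the same architecture and diverge
to ~50% pairwise identity outside the motifs, giving four well-separated,
self-contained clusters.

## Cluster assignment and trees

`assign_cluster()` offers two routes: `best_hit` (label of the top-scoring
anchor, support = percent identity) and `nearest_leaf` (neighbor-joining
tree of query plus anchors; label of the leaf at the smallest patristic
distance; support = percentage of column-bootstrap replicates whose nearest
labelled leaf agrees). Trees are neighbor joining on protein distances —
Poisson-corrected $d = -\ln(1 - p)$ by default, plain p-distance for
hand-checkable work — with negative branch lengths clamped to zero.
Distance NJ replaces likelihood tree inference deliberately: it is exact on
additive metrics, fast, and deterministic; every tree carries a
`method = "NJ"` tag (also written into Newick output) so results are never
mistaken for maximum-likelihood trees. Bootstrap supports are properties of
unrooted bipartitions, so `bootstrap_support()` returns the unrooted tree;
the outgroup attachment edge carries no support of its own. Sequences
failing the motif filter never enter the database at all — in particular,
divergent cluster-IV-like paralogs without the motifs are excluded rather
than labelled, and cluster IV is assignable only via its anchor.

## Community statistics

Counts are aggregated by the label each ASV carries at the requested rank;
ASVs without an assignment (or with an empty rank field after
identity-based truncation, defaults: genus requires ≥ 97% identity, family
≥ 90%) pool under `unassigned`, so per-sample totals are conserved. Shannon
diversity uses natural logarithms by default (the scale on which *nifH*
soil surveys typically report H of 5.7–6.6 over ~1000 ASVs); the base is a
parameter. ANOVA is restricted to balanced complete designs, where Type
I/II/III sums of squares coincide and term order is irrelevant; empty cells
are an error, not a fallback. The response is the untransformed relative
abundance, matching common practice in amplicon treatment comparisons; a
log-ratio transformation is deliberately not applied by default so results
correspond to the proportions shown in stacked-bar figures, and users who
want compositional rigour can transform the response before calling.
Tukey HSD letters are produced by the insert-and-absorb algorithm; letter
displays are not unique, so the algorithm is fixed and documented rather
than left to chance.

## Isotope quantification

Fixed nitrogen follows two-pool isotope mixing. Newly fixed N enters the
soil pool at the headspace enrichment $a_h$ (25 atom% ^15^N), raising the
soil pool's atom% from its baseline $a_0$ to $a_f$:

$$\mathrm{fixed\ N\ (mg\,kg^{-1})} = N_{tot} \cdot \frac{a_f - a_0}{a_h - a_0},$$

with $N_{tot}$ the soil total N in mg kg^−1^. The baseline is either the
measured pre-incubation atom% (defaulting to natural abundance,
0.3663 atom%) or the mean of unenriched control vials
(`baseline = "control_vial"`); both modes are supported because studies
differ in which blank they subtract. Negative raw estimates (noise below
baseline) are clamped to zero and flagged. No correction is attempted for
headspace dilution by soil-emitted N gases over the incubation; that
process is not identifiable from these measurements and is recorded as a
caveat attribute on the output. Per-vial to per-kg conversion assumes the
vial's dry soil mass (2 g in the default microcosm); moisture corrections
are out of scope. `fym_nutrient_load()` does the amendment bookkeeping:
8 mg of farmyard manure at 13% C, 0.98% N, 0.3% P delivers 1.04, 0.0784 and
0.024 mg per vial (1, 0.078, 0.024 at the precision such studies print),
and 8 mg into 2 g of soil is a 0.4% amendment.

# The synthetic-data generator

The generator exists so that every downstream stage has planted ground
truth. What it emulates, and what it does not:

* **Reference corpus** — per-cluster descendants of the four anchors,
  mutated at a per-site substitution rate (≤ 0.3) outside protected motif
  windows, plus decoys that each violate a recorded rule (MgATP motif
  mutated, either ligating cysteine lost, or fully random off-target
  protein). Taxonomy is a synthetic GTDB-style 7-rank lineage drawn from
  family pools that mirror a paddy-soil diazotroph survey (Gallionellaceae,
  Geobacteraceae, Beijerinckiaceae, … in cluster I; anaerobes in III).
* **ASVs** — the reverse translation (standard genetic code, uniform
  synonymous codon choice; codon bias is irrelevant to the logic under
  test) of a reference window spanning residues 85–204 (360 nt), the
  approximate interior of a PolF/PolR amplicon. The exact window is a
  parameter since trimmed amplicon lengths vary by protocol. Frameshift
  ASVs carry one indel of length 1–2 placed between the Cys97 and Cys132
  codons, so no single reading frame retains both sites, and are certified
  by an exhaustive six-frame scan to have no stop-free translation — the
  typical fate of frameshifted pseudogenes, and the property that makes the
  class label "removed by QC" true by construction rather than true with
  high probability. Pseudogene ASVs substitute one ligating-cysteine codon
  with a non-cysteine codon. Off-target ASVs are random nucleotide strings,
  certified the same way.
* **Count tables** — Dirichlet-multinomial draws around a base family
  profile (default `paddy_family_profile()`: Geobacteraceae ~20%,
  Gallionellaceae 5%, several Pseudomonadota families at a few percent).
  The planted effect multiplies one taxon's expected proportion by a fold
  change in `+FYM` samples and renormalises. The Dirichlet concentration is
  `1/dispersion` (default dispersion 0.02, i.e. concentration 50 — visible
  but moderate overdispersion); dispersion 0 degenerates to the exact
  multinomial. Default depth 30,000 reads sits inside the 21,000–42,000
  valid-read range typical of soil *nifH* MiSeq runs.
* **Isotope measurements** — the mixing equation run in reverse plus
  Gaussian noise on the final atom% (default SD 0.001 atom%, a
  conservative figure for continuous-flow isotope-ratio mass
  spectrometry).

What the generator does **not** emulate: read-level artefacts (quality
scores, chimeras), denoising, codon bias, within-cluster phylogenetic
structure beyond star-like divergence from one anchor, rank-correlated
taxonomy errors, or spatial/temporal correlation between vials. Passing
tests therefore demonstrate that the pipeline's logic is correct on data
satisfying its stated assumptions, not that any field result is reproduced.

All generators are deterministic functions of an integer seed, and designs
are balanced with n = 3 replicates per cell by default, matching the
microcosm layout (3 fields × 2 soil histories × 2 FYM incubation
treatments) and the rhizosphere layout (2 FYM histories × 4 mineral
treatments).

# Numerical choices and degenerate inputs

* Alignment scores are integers under BLOSUM62; ties in best-hit
  classification break by higher identity, then lexicographic id, making
  results order-independent.
* Dereplication keeps the lexicographically smallest id.
* `anova_factorial()` reports F = 0 for a term whose sum of squares is
  zero relative to the response scale (constant responses otherwise yield
  0/0).
* Distances of 1 (saturation) under the Poisson correction, and sequence
  pairs with no shared aligned columns, are errors naming the pair rather
  than silent `Inf`/`NA`s.
* Zero-total samples are rejected by `relative_abundance()` and
  `shannon_index()` by name.
* Empty QC input returns an empty report; a zero-survivor database build
  warns and writes an empty database.

# Problem sizes used in the tests

The test and acceptance workloads are sized for a laptop-class run: corpora
of 4–40 references plus up to 20 decoys, 80-ASV QC mixes, 50 alignment
oracle pairs of ≤ 20 residues, 5-leaf additive-metric tree checks, 200
simulated experiments per power/size estimate, and 500 vials per isotope
recovery rate. These sizes are the package's choice of desk-scale
experiment; all of them are parameters of the generators and can be scaled
up.

# Known limitations

* The homology screen is exhaustive pairwise alignment: quadratic in corpus
  size, appropriate up to a few thousand sequences, not a replacement for a
  heuristic search engine on GTDB-scale corpora.
* The anchored multiple alignment is exact only when sequences are
  indel-free relative to the anchor.
* NJ trees are not ML trees; supports quantify resampling stability of a
  distance method, and the `method` tag should travel with any figure.
* Cluster labels depend on the supplied anchors; with the synthetic
  anchors the labels are internally consistent but not transferable to
  field data without real anchor sequences.
* The isotope estimator ignores headspace dilution and assumes the fixed N
  stays in the measured pool over the incubation.
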