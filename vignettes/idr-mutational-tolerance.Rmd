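---
title: "Mutational-tolerance landscapes of disordered regions: methods and design"
author: "idrmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-tolerance landscapes of disordered regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrmotifs)
```

## The problem

Intrinsically disordered regions (IDRs) of proteins lack stable tertiary
structure, yet many of them drive or participate in the liquid–liquid phase
separation that assembles membraneless organelles (nucleoli, stress granules,
P-bodies). Because IDRs align poorly, classical conservation analysis
struggles to say which disordered residues matter. Masked protein language
models offer an alignment-free alternative: for every position they score how
acceptable each of the 20 amino acids would be given the whole sequence
context, expressed as a log-likelihood ratio (LLR) of mutant to wild type.

`idrmotifs` turns per-residue LLR matrices (produced externally; running the
language model is out of scope) into a reproducible analysis of mutational
tolerance: a per-residue entropy score, residue classes, alignment-based
conservation as an independent check, discovery of conserved sequence motifs
inside disordered regions, classification of IDRs against experimentally
annotated phase-separation segments, and group-level statistics. A
synthetic-data generator with planted ground truth makes the whole pipeline
testable without any external download.

## The entropy score

At position $i$ the model provides $\mathrm{LLR}_{ik}$ for the 20 amino acids
$k$ (the wild-type letter scores 0, the ratio of the wild type to itself).
The per-residue score is the Shannon entropy, in nats, of the softmax over
those 20 values:

$$
S_i \;=\; -\sum_{k=1}^{20} p_{ik} \log p_{ik},
\qquad
p_{ik} = \frac{e^{\mathrm{LLR}_{ik}}}{\sum_{j=1}^{20} e^{\mathrm{LLR}_{ij}}}.
$$

$S_i$ ranges from 0 (only one residue tolerated) to $\ln 20 \approx 2.996$
(all 20 equally acceptable), so it reads directly as an effective number of
permissible amino acids, $e^{S_i}$. It is invariant to adding a constant to
all entries and to permuting them. A residue is called **conserved** when
$S_i \le 0.5$, **flexible** when $S_i \ge 2.0$, and intermediate otherwise;
these bounds sit naturally against the $\ln 20$ maximum.

Two conventions deserve note. First, the 20-vector includes the wild-type
letter with LLR fixed at 0; this is the only self-consistent choice (the
uniform landscape then scores exactly $\ln 20$) and the table readers enforce
it, rejecting files whose wild-type column deviates from 0 — such a file
follows a different convention and silently renormalising it would corrupt
every score. Second, all logarithms are natural: the published class bounds
(0.5, 2.0) only make sense against a maximum near 3.

One property worth knowing: lowering a single LLR entry does **not** always
lower the entropy. The gradient is $\partial S/\partial v_k = -p_k(v_k -
\mathbb{E}_p[v])$, so pushing down an entry that is still *above* the
softmax-weighted mean momentarily spreads the distribution. Only entries at
or below that mean are guaranteed to concentrate the distribution when
lowered; the test suite asserts exactly this corrected form.

## Structural order

Per-residue pLDDT values (from AlphaFold-convention coordinate files' B-factor
column, or a plain table) classify residues as disordered when
$\mathrm{pLDDT} \le 70$, the conventional proxy for structural disorder.
Disordered regions are maximal runs of such residues, with no minimum length.
Proteins qualify for disorder-focused datasets when at least 10% of residues
are disordered (inclusive), and sequence redundancy is removed greedily at
>50% pairwise identity (global alignment, unit match, zero mismatch, linear
gap cost 1; identity = matches / alignment length).

## Conservation from alignments

Reference-anchored alignments (A3M with lowercase insertions removed,
CLUSTAL, or aligned FASTA) give an independent conservation readout. Homologs
below 20% identity to the reference are dropped (inclusive boundary:
"at least 20%" keeps 0.20), where identity counts matching non-gap columns
over the *full* aligned reference length, gaps included. The conservation
score at reference position $i$ is

$$
\mathrm{CS}_i = \frac{n_i(\mathrm{ref=query})}{N_i(\mathrm{non\_gap})},
$$

the fraction of homologs whose residue matches the reference among homologs
with any residue at that column. The reference row itself is excluded from
both counts (configurable; including it only adds $+1/+1$). Columns where all
homologs have gaps yield a *missing* score, not 0 — zero would assert
observed divergence where there is no evidence — and downstream statistics
skip missing values. Columns where the reference itself has a gap carry no
reference residue and are dropped, with positions renumbered over reference
residues.

## Motif identification

Motifs are contiguous stretches whose average score is at most 0.5. The
search is a bidirectional greedy scan:

1. From one terminus, find the next anchor residue with score ≤ 0.5, then
   append residues toward the opposite terminus while the running mean stays
   ≤ 0.5. The first residue that pushes the mean above 0.5 ends the segment,
   and the search resumes at that residue. "Falls within 0.5" is read
   inclusively and "exceeds" strictly, so a running mean of exactly 0.5
   continues the extension; a segment that reaches the terminus without a
   breach is emitted open.
2. The same procedure runs from the other terminus, and the final candidates
   are the residue-level intersection of the two position sets. This trims
   terminal residues that ride on an adjacent low-scoring core without
   belonging to it. Because a subsegment of a ≤-threshold segment has no
   mean guarantee, any intersected run whose own mean exceeds the threshold
   is discarded, so every reported motif honours the definition.
3. Motifs whose separation is at most 8 residues are merged when the mean
   over the spanning segment is strictly below 0.5. Merging is *best-first*:
   among all currently eligible adjacent pairs, the pair with the smallest
   spanning mean merges first, repeating to a fixed point (a merged interval
   may merge again). A single directional pass would anchor spanning means
   at whichever terminus the pass started from and produce different motifs
   on the reversed sequence; best-first merging makes the output mirror
   exactly under sequence reversal, which the test suite verifies on random
   sequences.
4. Motifs shorter than 4 residues are dropped (configurable; conclusions are
   robust to this bound).

Running-mean comparisons carry a $10^{-9}$ absolute guard: sums like
$0.4+0.3+0.4+0.9$ evaluate to $2.0 + 2\times10^{-16}$ in binary floating
point, and a true mean of exactly the threshold must not register as a
breach.

By default the scan runs separately inside each disordered region (motifs are
an IDR-level concept); whole-protein scans are available and will also report
conserved folded domains, which is consistent but usually not what is wanted.

Motif composition is summarised by the **sticker fraction** — the proportion
of Y, F, W, R, K and Q, the residues that drive strong specific condensate
interactions in the stickers-and-spacers picture — and by per-amino-acid
**motif membership**: among residues of a letter with score ≤ 0.5, the
fraction inside any motif (letters with no conserved residues report a
missing value).

## IDR classification against phase-separation segments

Experimentally annotated phase-separation segments (1-based inclusive
intervals; the package deliberately avoids BED half-open coordinates
throughout) classify each disordered region by coverage = overlapping
residues / segment length:

* **driving** — the region covers more than half of some segment;
* **participating** — it overlaps a segment but never beyond half
  (coverage exactly 0.5 is participating, "over 50%" being strict);
* **non-participating** — no overlap, including proteins with no segments.

A region overlapping several segments takes the class of its maximum
coverage. Per protein, the localization probability $p$ is the fraction of
its conserved residues (score ≤ 0.5) lying inside driving or participating
regions; note that conserved residues in folded domains count in the
denominator, so heavily structured proteins dilute $p$ even when every
disordered motif sits in a phase-separating region.

## Group statistics

Score distributions between residue groups are compared with two-sided
Mann–Whitney U tests. With combined sample size at most 12 the p-value is
computed by exact enumeration of all group-label assignments — valid in the
presence of ties, where the classical exact distribution is not — and
otherwise by the tie-corrected normal approximation with continuity
correction. Significance tiers follow strict thresholds: `***` < 0.001,
`**` < 0.01, `*` < 0.05, `†` < 0.10, `n.s.` otherwise.

Per-amino-acid profiles average each letter's LLR vectors element-wise over a
chosen residue population, together with mean score and mean conservation.
The Pearson correlation between per-letter mean score and mean conservation
excludes methionine, whose frequent initiator position confounds
mutational-effect prediction (initiator methionines are still *scored* like
any residue; the exclusion applies only to this correlation). Letters absent
from a population are skipped. Profile clustering embeds the 20 mean-LLR
vectors in two dimensions and applies average-linkage hierarchical
clustering; the default embedding is the first two principal components —
deterministic, so tests are reproducible — with any embedding function
(e.g. a nonlinear neighbour-graph method with a fixed seed) pluggable.
Cluster labels are ordered by ascending cluster-mean score, so group 1 is
always the most conserved.

## The synthetic test-bed

`sim_config()` / `simulate_protein()` / `simulate_dataset()` generate
proteins with planted ground truth:

* **Architecture** — alternating folded and disordered runs (lengths uniform
  in 30–70 and 30–90 residues), pLDDT drawn uniformly in [80, 98] and
  [35, 68] respectively, protein length uniform in 240–400.
* **Composition** — disordered runs are enriched threefold in the
  disorder-typical residues G, S, P, Q, K, R, E; the enrichment weight is a
  fixed generator choice, not fitted to any reference composition.
* **LLR structure** — at planted motif sites every non-wild-type LLR is
  drawn N(−8, 0.5), giving entropy ≈ 0.06; at disordered background sites
  N(0, 0.3), giving entropy near ln 20; in folded runs N(−6, 0.5), giving
  entropy ≈ 0.32. Folded conservation matters twice: it reproduces the
  low-entropy ordered population seen in real landscapes, and it anchors
  homolog percent identity the way folded domains anchor real alignments —
  with a flat background everywhere, softmax-sampled homologs would sit near
  13% identity and the 20% filter would discard them all.
* **Coupling** — each homolog residue is sampled i.i.d. from the softmax of
  its site's LLR vector, then gapped at a 2% per-column indel rate. The
  expected conservation score at a site therefore *equals* the wild type's
  softmax weight (≈ 0.9937 at exact −8 motif sites), making the
  score–conservation correlation a mathematical consequence inside the
  test-bed and giving parameter recovery a sharp target.
* **Planted motifs** — counts are deterministic,
  `round(n_motifs_per_protein × multiplier)`, so each group's planted
  density is exactly controlled; lengths are uniform 4–15 and placements
  random inside disordered runs with at least 12 residues between motifs
  (beyond the merge gap of 8, keeping planted intervals identifiable as
  distinct motifs). When a demanded count cannot be placed the generator
  truncates by default; `motif_overflow = "error"` raises a generation
  error instead.
* **Phase-separation segments** — driver-like proteins get a segment inside
  each motif-bearing disordered run (the region covers all of it: driving);
  client-like proteins get a segment straddling a disordered-run boundary
  with $k$ residues inside and $k+1$ outside (coverage $k/(2k+1) < 0.5$:
  participating); background proteins get none.
* **Group design** — the default three tiers plant 0, 3 and a
  capacity-saturated number (≈ 6–7) of motifs per protein
  (multipliers 0 / 1.5 / 4 on a base of 2), emulating the gradient from
  non-phase-separating disordered regions through clients to drivers. The
  spacing comes from a power analysis: at 500 residues per group the
  Mann–Whitney z for a motif-fraction gap $d$ between two groups is roughly
  $27d$, so evenly spaced fractions (≈ 0, 0.16, 0.35) keep every adjacent
  comparison decisively significant while deterministic counts remove
  density fluctuation between replicates.

What the generator does **not** emulate: phylogenetic structure among
homologs (indels are i.i.d.; a tree would add realism but no power for the
implemented statistics), contextual correlations between neighbouring sites'
LLR vectors, compositional differences between motifs and their flanks, and
real pLDDT autocorrelation. Passing tests therefore demonstrate algorithmic
correctness and self-consistency of the pipeline, not biological validity on
real proteomes, where the score–conservation coupling is an empirical
finding rather than a construction.

## Reproducibility and problem sizes

Every stochastic step flows from a single integer seed; rerunning the
pipeline with the same inputs and configuration reproduces all tabular
outputs byte for byte (`report.json` contains no timestamps). The bundled
tests and the acceptance script work at deliberately compact sizes — proteins
of 240–400 residues, 3–36 proteins per experiment, 200 homologs where
conservation is measured, 10–20 generator seeds per property — chosen so the
full suite exercises every stage end to end in a couple of minutes while
keeping every statistical check comfortably powered.

## Limitations

* The package consumes LLR matrices; it neither runs a language model nor
  validates that the provided LLRs came from one.
* The entropy score treats the 20 LLRs of a site in isolation; epistasis and
  context dependence live entirely in the upstream model.
* The redundancy filter's alignment scoring is intentionally simple; for
  borderline redundancy decisions on real data a substitution-matrix-based
  identity may be preferable.
* Exact Mann–Whitney enumeration is limited to combined samples of 12; far
  beyond that the normal approximation is standard but approximate.
* The deterministic principal-components embedding for amino-acid clustering
  preserves global variance, not local neighbourhood structure; with a
  nonlinear embedding plugged in, cluster *contents* may differ even though
  the five-group contract and conservation-ordered labels are maintained.
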