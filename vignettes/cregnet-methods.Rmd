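---
title: "Methods: combinatorial TF–miRNA network inference in cregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial TF-miRNA network inference in cregnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregnet)
```

## The inference problem

Transcription factors (TFs) and microRNAs (miRNAs) are the two principal
classes of gene-expression regulators in metazoans: TFs act on genes and on
miRNA genes at the transcription level, miRNAs repress protein-coding
transcripts — including TF transcripts — post-transcriptionally. Because TFs
are themselves protein-coding genes, exactly three edge types can occur in a
combinatorial regulatory network: TF → gene (including TF → TF), TF → miRNA,
and miRNA → gene (including miRNA → TF). miRNA → miRNA regulation does not
exist and plain genes have no out-edges. The `regulatory_network` container
enforces these rules on every construction, so no code path can produce an
illegal edge.

Sequence complementarity (binding sites, seed matches) yields *putative*
regulations — edge libraries that hold everywhere and always. cregnet starts
from three such libraries (`TF2gene`, `TF2miR`, `miR2gene`, plain
two-column TSV) and uses condition-specific expression data to sift the
regulations actually active in that context. miRNA transcript identifiers
are consolidated to root form on every load (`hsa-let-7a-1` → `hsa-let-7a`),
because genomic-copy indexes fragment what is biologically one regulator;
the rule strips a trailing `-<digits>` group only when the remainder still
ends in a miR/let family token, which keeps `hsa-miR-1` (a family number)
and `hsa-miR-17-5p` (an arm suffix) intact and is idempotent.

## The MPGE engine

A miRNA-perturbed gene expression (MPGE) experiment transfects one miRNA
and reports one expression log-ratio $E_g$ per gene (after vs before).
The engine answers three questions.

**Does the miRNA degrade its targets at all?** The putative targets of the
perturbed miRNA are compared against all remaining genes with a one-sided
two-sample Kolmogorov–Smirnov test, statistic
$D^+ = \sup_x [F_{\mathrm{targets}}(x) - F_{\mathrm{non}}(x)]$, large when
target log-ratios are stochastically smaller. The p-value is exact (the
tie-aware permutation distribution of $D^+$) whenever
$n_t \cdot n_n \le 10^4$ — the same switch `stats::ks.test` applies — and
asymptotic for genome-scale datasets, where the two are indistinguishable.
The paired empirical CDFs are returned as PP-plot coordinates.

**Which targets are degraded?** Each putative target $g$ receives the
empirical one-sided tail probability
$p_g = (1 + \#\{\text{non-targets} \le E_g\}) / (1 + n_n)$, i.e. its rank
within the non-target distribution with an add-one correction that keeps
$p_g > 0$. These are Benjamini–Hochberg adjusted across the putative
targets; the refined set keeps adjusted $p \le \alpha$ (default 0.05). The
procedure is rank-based, hence invariant under any monotone transform of
the log-ratios. A per-gene test (rather than one global shift test) was
chosen so that individual decoy library edges can be rejected; this is the
main genuinely open design point in the refinement step.

**Which TFs mediate the secondary response?** Regulator selection runs in
two stages. A univariate pre-filter fits $E_g = c_0 + c_1 b_{ig}$ per TF
($b_{ig}$ = indicator that $g$ is a library target of TF $i$) and keeps
TFs with slope $p \le$ 0.01 (configurable), ordered by ascending p with
identifier ties — this caps the multivariate candidate set at a manageable,
deterministic list. The combinatorial model
$E_g = a_m b_{mg} + \sum_i a_{TF_i} b_{TF_ig} + c_0 + \varepsilon$
is then selected by bidirectional stepwise AIC with the miRNA indicator
$b_{mg}$ (the refined target set) forced in; candidate columns collinear
with earlier ones are dropped with a warning, and a base model that already
fits perfectly skips selection (AIC is degenerate there). An intercept is
always included: log-ratio data are not guaranteed zero-centred. Retained
TFs that are themselves putative targets of the perturbed miRNA are its
*mediating* TFs, and the two-layer network wires
miRNA → refined targets, miRNA → mediating TFs, and each retained
TF → its library targets, with fitted coefficients as edge weights.

## The parallel engine

A parallel dataset holds two expression matrices over identical ordered
conditions, one with miRNA rows, one with mRNA rows (TF profiles are mRNA
rows). For each gene $g$, the engine regresses its profile on the profiles
of its library candidates ($E_{tf_g}$ and $E_{m_g}$), and for each miRNA
$m$ on its `TF2miR` candidates ($E_{tf_m}$), again with bidirectional
stepwise AIC; candidates enter deterministically (TFs then miRNAs, each
lexicographic). Survivors must additionally reach coefficient $p \le$ 0.05,
enforced by backward pruning of the worst term with refit until all pass
(`p_survivor = 1` disables this, which is how the selection is compared
against an exhaustive best-subset-by-AIC oracle in the tests). Guards:
zero-variance profiles are dropped; when candidates outnumber
conditions − 2, only the top conditions − 2 by univariate |correlation| are
considered, with a warning. Expression values are used as given — no
internal normalisation; that is deliberately the caller's responsibility.
No sign constraint is placed on miRNA → gene coefficients by default;
`repression_only = TRUE` discards positive ones for users who want the
degradation-only reading. The union of retained edges over all responses
is the genome-wide three-edge-type network.

## Topology analytics

Vertices are ranked by total degree and by betweenness, edges by edge
betweenness; betweenness is computed on the directed graph with unweighted
shortest paths (regression coefficients are not distances) and reported as
raw Freeman counts, ties broken by identifier. Co-regulating regulator
pairs are scored with the one-sided Fisher exact test on the 2×2 table
that partitions the target universe — nodes with in-degree ≥ 1 in the
inferred network, not the genome — by membership in each regulator's target
set; pairs with $p <$ 0.01 are reported by default.

A *motif* is a closed typed triple-vertex circuit: every vertex pair joined
by at least one directed edge (mutual edges allowed where type-legal), at
least one TF and one miRNA among the vertices. This closure definition is
what makes the catalog size come out at exactly 18 — 3 types on
{TF, miRNA, gene} and 15 on {TF, TF, miRNA}, the latter confirmed by the
Burnside count $(27 + 3)/2$ over the two-TF symmetry, while {TF, miRNA,
miRNA} is empty because two miRNAs can never be joined. Motifs are
deduplicated by a canonical form (minimum over vertex permutations of a
typed adjacency encoding); a motif is a feed-backward loop (FBL) if it
contains any directed cycle, including a mutual edge pair, and a
feed-forward loop (FFL) otherwise. Counting visits each connected triple
once via triangle enumeration and matches its induced subgraph exactly
against the catalog.

Motif significance uses a degree-preserving null: double-edge swaps
performed within each edge class separately (default 10 attempts per edge,
1000 replicates), which preserves every node's typed in/out degree exactly
— so enrichment reflects edge *arrangement*, not degree structure. The
empirical upper-tail probability is
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + R)$, never zero.
Classes with fewer than two edges cannot be swapped and are left unshuffled
with a warning. Depletion testing is deliberately not reported; the
upper tail is what recurrent-circuit claims rest on.

## The simulators

`simulate_mpge()` emulates a perturbation experiment under exactly the
additive model the engine assumes:
$E_g = a_m b_{mg} + \sum_i a_{TF_i} b_{TF_ig} + \mathcal{N}(0, \sigma)$,
with defaults of 2000 genes, 50 direct targets at effect −2, 50 zero-effect
decoy library targets, three mediator TFs with coefficients (1, −1, 0.8)
among ten library TFs of 100 targets each, and noise sd 0.5 — effect sizes
and scales a transfection microarray study would plausibly produce.
Mediator TFs are wired as library targets of the miRNA and their own
expression rows are shifted like any direct target. TF target sets are
drawn from the background pool, disjoint from the miRNA's target sets, so
each planted mechanism is separately identifiable.

`simulate_parallel()` draws i.i.d. standard-normal TF profiles over 60
conditions (the scale of a cell-line panel), builds each miRNA as a planted
linear combination of 1–2 driver TFs plus noise, each gene from 0–3
regulators with coefficients of magnitude 0.5–2 and random sign, and emits
libraries containing the planted edges plus an equal number of decoys.
One constraint keeps the ground truth meaningful: a gene's planted
regulator set is pruned so the regulators' zero-noise profiles are linearly
independent (a miRNA together with its sole driver TF, or two miRNAs
sharing one driver, are exactly proportional at zero noise — no method
could attribute such coefficients, so "exact recovery in the noiseless
limit" would be vacuously unattainable).

What the simulations do *not* model: probe-level measurement artifacts,
normalisation residue, correlated (batch) noise, nonlinear or saturating
regulation, and combinatorial (AND/OR) logic. Passing recovery tests on
these fixtures therefore demonstrates that the estimators are correct under
their own model assumptions, not that real data meet those assumptions.

## Numerical and reproducibility choices

All stochastic steps (simulators, network shuffles) take explicit seeds and
restore RNG state on exit; reports rerun byte-identically under a fixed
seed. Stepwise selection is deterministic because candidate entry order is
fixed. Degenerate inputs are handled explicitly: identical target and
non-target distributions give $D^+ = 0$, $p = 1$; an all-zero response
retains no regulators with $a_m = 0$; empty networks produce complete,
header-only report tables with all 18 motif rows at count zero. Validation
scales used throughout the tests — networks of ≤ 50 nodes against
brute-force oracles, 10-seed recovery runs, 10⁵-shuffle permutation
comparisons — were chosen so the full suite exercises every guarantee at
sizes where exhaustive cross-checking is feasible.

## Known limitations

Stepwise AIC selection is greedy and can in principle miss the best
subset under strong candidate correlation (the tests verify agreement with
exhaustive best-subset selection on the fixture distribution, not in
adversarial cases). The per-regression p-values are not corrected across
the thousands of per-target fits in the parallel engine; the survivor
threshold is a per-model filter, and users comparing edge lists across
datasets should treat the p-value column accordingly. The co-regulation
universe is the inferred network's target set, which conditions the test on
the network actually recovered. Library quality bounds everything: the
engines can only remove putative edges, never discover a regulation absent
from the libraries.
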