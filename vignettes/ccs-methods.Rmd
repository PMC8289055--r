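---
title: "Detecting convergence at conservative sites: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergence at conservative sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsconv)
```

## The problem

Male pregnancy in syngnathid fishes (seahorses and pipefishes) and placental
gestation in mammals are a textbook case of phenotypic convergence across
roughly 420 million years of divergence. A genomic question follows: do
orthologous proteins in the two "placental" lineages accumulate *identical*
amino-acid substitutions more often than matched aplacental relatives do?
Naive scans for shared residues are dominated by two artifacts — chance
convergence at fast-evolving sites, and mis-inferred ancestral states. The
convergence-at-conservative-sites (CCS) strategy suppresses both by only
ever testing columns where the ancestral state is nailed down by
conservation, and by building the test symmetrically so that a matched
control group calibrates the background.

`ccsconv` implements that strategy end to end, together with the
substitution-model machinery needed to calibrate it by simulation, and two
molecular-rate utilities (Tajima's relative rate test and
fourfold-degenerate-site extraction with K2P distances) that belong to the
same analysis family.

## The symmetric design and the calling rule

The experimental unit is a 17-taxon layout: an outgroup `O`, two
*foreground* clusters of four taxa each (the placental-analog clades:
syngnathids, placental mammals), and two *background* clusters of four
aplacental controls (teleosts, tetrapods), each control cluster sister to
one foreground cluster. For an alignment column:

1. **Conservative for the foreground**: all eight background taxa carry,
   determinately, the same residue as the outgroup. The ancestors of both
   foreground clusters are then assumed to have carried that residue.
2. **Convergent in the foreground**: one residue `d` different from the
   outgroup residue is shared by at least `min_shared_per_cluster` taxa
   (default 3 of 4) in *each* foreground cluster — at least six of the
   eight taxa overall, with the support spread over both clusters.
3. The background direction is defined by exchanging the roles of the two
   groups; the caller is exactly symmetric.

Decisions the rule itself does not fix, and how this package fixes them:

* **Missing data** (`-`, `X`, `?`) never count as matching the outgroup
  (a gap breaks conservativeness when it sits in a control taxon) and
  never count as support for a derived residue. The one non-supporting
  taxon a cluster is allowed may carry anything, including a gap.
* **Gapped outgroup**: the assumed ancestral state is undefined, so the
  column is skipped.
* **Sites conservative in both directions** (all sixteen ingroup taxa
  equal to the outgroup) are convergent in neither and are counted toward
  neither direction.
* **Ambiguity**: if two distinct derived residues both reach the support
  threshold (impossible with 4-taxon clusters at threshold 3, possible in
  reduced designs), the column is rejected and flagged rather than
  arbitrated.
* The prose "at least six of the eight" admits a 6-total-any-split
  reading; the displayed condition constrains three taxa per cluster, so
  per-cluster support is the default and the any-split variant sits behind
  `rule = "total"`.
* Columns are reported 1-based with `D401E`-style labels.

Foreground and background totals are compared by a two-cell Pearson
goodness-of-fit statistic against the equal expectation the symmetric
design implies, \((f-b)^2/(f+b)\) on 1 df. With the motivating counts of
125 foreground and 36 background substitutions this gives
\(\chi^2 = 49.2\), \(P \approx 2\times10^{-12}\). A contingency-table
layout over additional strata would need per-stratum counts that a per-site
scan does not produce, so the two-cell form is the one reported and is
stated in the output header. The caller's totals are accompanied by an
*empirical* null from simulation (below), which does not rely on the
chi-square approximation at all.

## The substitution model

Amino-acid evolution is modeled as a reversible continuous-time Markov
chain with JTT exchangeabilities \(s_{ij}\) (the published 190-value
triangle, embedded as constants) and equilibrium frequencies \(\pi\):
\(Q_{ij} = s_{ij}\pi_j\), normalized so \(-\sum_i \pi_i Q_{ii} = 1\), i.e.
branch lengths are expected substitutions per site. Frequencies are either
the published JTT values or empirical counts from the data (the usual
`+F` practice; counting, not ML). Among-site rate variation is
discrete-gamma: shape \(\alpha\), `k` equiprobable categories, category
rates by Yang's mean-of-category discretization so the mean rate is
exactly 1. The number of categories is not dictated by the method; 4 is
the default throughout, configurable everywhere.

Transition matrices are computed by symmetric eigendecomposition of
\(\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)\), which keeps
\(P(t) = e^{Qt}\) accurate to ~1e-12 at ordinary branch lengths (the test
suite asserts the semigroup property \(P(t_1)P(t_2)=P(t_1+t_2)\) at 1e-10).
Tiny negative entries from round-off are clamped and rows renormalized.

## Likelihood and parameter fitting

`log_likelihood()` is Felsenstein pruning over unique site patterns, mixed
over the gamma categories with equal weights; gaps and unknowns contribute
a partial likelihood of one for every residue, and per-node rescaling in
log space prevents underflow on deep trees.

`fit_parameters()` estimates branch lengths and \(\alpha\) on the fixed
topology by coordinate ascent: each branch is optimized exactly by Brent's
method against up/down partial likelihoods that are refreshed along a
root-to-tip sweep (so every one-dimensional objective is the true
log-likelihood as a function of that branch), then \(\alpha\) is optimized
with full evaluations, bracketed within \([\alpha/3,\,3\alpha]\) per sweep
inside global bounds \([0.02, 50]\); branch lengths live in
\([10^{-8}, 20]\), and zero starting lengths are re-initialized to 0.05.
Sweeps stop when the log-likelihood gain drops below `tol` (default
\(10^{-6}\) log units; `max_iter` 200 sweeps, with a warning and
`converged = FALSE` past that). A 1-D move is accepted only if it improves
the objective, so the trajectory is monotone. On data simulated at 50,000
sites on a five-taxon tree the fit recovers \(\alpha = 0.8\) to ~0.1–3%
and branch lengths to under 5% relative error — comfortably inside the 15%
envelope the test suite enforces.

Whether parameters should be fitted per gene or once on concatenated data
is a user choice; both work, and the bundled pipeline fits one set on a
concatenated slice (default 2,000–3,000 columns) because the unique-pattern
count — and thus fit cost — grows with columns while \(\alpha\) and branch
lengths stabilize long before that.

## The simulator and its two calibrations

`simulate_gene()` mirrors the evolver recipe: a root sequence drawn i.i.d.
from \(\pi\), one gamma category per site (shared across the tree), and
child states drawn from \(P(t\cdot r)\) row by row down the tree, with
*every* internal-node state recorded. The RNG contract is a single seeded
generator consumed in a fixed order — site categories, root sequence, then
branches root-to-tip — so a seed reproduces a dataset bit for bit.

**Ancestral accuracy.** The CCS rule assumes the outgroup residue is the
ancestral state of both tested clusters at conservative sites. With
simulated internal nodes this is directly measurable:
`ancestral_accuracy()` restricts to sites that pass the conservative
criterion on simulated leaves and reports the fraction where the simulated
outgroup state equals the true state at both cluster MRCAs on the tested
side (optionally also the ingroup root). On the default 17-taxon tree with
all branches at 0.1 and \(\alpha = 0.8\) the assumption holds at ~94% of
conservative sites, and the package reports this quantity rather than
asserting any particular value, since it is a property of the tree scale.

**The convergence null.** `null_convergence()` repeats
simulate-then-call and returns per-replicate foreground/background counts.
This serves two purposes: an empirical reference distribution for observed
counts, and a check that the symmetric chi-square holds its nominal size.
For the size check the tree must be event-rich as well as mirrored: at
study-like branch lengths convergent calls are so rare (about 0.2 per
2,000 columns) that a count-based test is fully discrete and essentially
never rejects — a calibration with no events measures nothing. The
expected per-site call rate under a cluster-level caricature,
\(\sum_i \pi_i P_{ii}(t)^2 \sum_{j \ne i} P_{ij}(t)^2\), peaks near a
root-to-cluster path length of 0.6, so the calibration topology uses tip
and within-cluster branches of 0.02, cluster stems of 0.6, clade and
ingroup stems of 0.05, and homogeneous rates (heterogeneity only thins
events: slow sites cannot converge, fast sites break conservativeness).
That geometry yields ~18 calls per 2,000-site replicate, and over 400
replicates the chi-square rejects at \(\alpha = 0.05\) in about 5–6% of
them — the nominal rate, within sampling error.

## The synthetic study generator

`generate_study()` produces the desk-scale stand-in for a phylogenomic
ortholog set: the 17-taxon design and tree, `n_genes` alignments evolved
under JTT+\(\Gamma\) (default \(\alpha = 0.8\), a typical protein value),
and planted convergent columns at uniformly chosen positions. Planted
columns set outgroup and controls to an ancestral residue drawn from
\(\pi\) and the tested clusters to a derived residue drawn from \(\pi\)
excluding the ancestral one — keeping planted columns compositionally
similar to neutral ones. Strict mode (8-of-8 support) tests recall of
unambiguous signal; minimal mode (3+3, the weakest accepted pattern) tests
threshold behavior: at the default threshold all planted sites are
recovered, at `min_shared_per_cluster = 4` none are, and the test suite
pins both.

What the generator does *not* emulate: alignment error, indels and gapped
columns, ortholog mis-assignment, among-branch compositional drift, and
selection on the neutral background. Recovering 100% of planted sites
therefore demonstrates correctness of the caller, not expected sensitivity
on real alignments, where those artifacts all subtract.

## Rate utilities

`tajima_rrt()` counts lineage-unique differences between two ingroups
against an outgroup (sites with any missing symbol excluded) and tests
\(m_1 = m_2\) by \((m_1-m_2)^2/(m_1+m_2)\) on 1 df, the standard
chi-square approximation; an exact binomial alternative sits behind
`exact = TRUE`. `extract_4d()` keeps a codon column only when every taxon
has a determinate codon, all codons share the same first two nucleotides,
and that prefix heads a fourfold-degenerate family of the standard code —
the strictest reading, guaranteeing third-position neutrality in every
lineage; a per-reference-taxon relaxation is available via
`mode = "reference"`. Alternative genetic codes are out of scope.
`k2p_distance()` is the closed-form Kimura two-parameter distance with
pairwise deletion; saturated pairs return `Inf` with a warning rather than
a number. Full GTR+\(\Gamma\) re-optimization of a neutral tree is outside
this package's scope, so K2P distances here are a closed-form neutral
summary, not a drop-in for a GTR-based tree.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 19,683-column exhaustive
enumeration against a brute-force caller on a reduced 2+2+2+2+1 design;
400 null replicates of 2,000 sites for the size check; 50 planted sites
per recall study; 50,000 sites for parameter recovery and for
single-branch transition goodness-of-fit; 20,000 sites for equilibrium
composition and ancestral accuracy. These sizes make every stochastic
check tight enough to be meaningful while keeping a full run in minutes on
one core. Every stochastic entry point takes a seed, consumes a single RNG
stream, and restores the caller's RNG state, so whole-pipeline reruns are
byte-identical.

## Known limitations

* The caller infers ancestral states by the outgroup-identity rule alone;
  probabilistic ancestral reconstruction is deliberately out of scope.
* Divergent (non-identical) parallel substitutions are not detected — the
  criterion requires one shared derived residue.
* The two-cell chi-square treats substitutions as independent events;
  clustered convergent sites within a gene (which the report does tally)
  would mildly inflate its significance.
* Amino-acid models only; codon models and indel processes are not
  simulated or fitted.
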