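---
title: "Motif statistics and substratome definition for a secretory-pathway kinase"
author: "substratomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif statistics and substratome definition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substratomics)
```

# The problem

FAM20C is the serine kinase of the secretory pathway: a Golgi-lumen enzyme
whose consensus is a glutamate at the +2 position relative to the
phosphoacceptor serine (the S-x-E motif, where "x" is any residue and a
phospho-serine at +2 can substitute for the glutamate). Because the motif
is distinctive and the kinase is the only acidophilic kinase operating in
the secretory lumen, the combination of motif match and luminal
localization predicts its substrates from phosphoproteomic databases.
`substratomics` implements that prediction pipeline as reusable, tested
code: motif significance statistics, the localization/topology filter
cascade, kinase-panel preference profiling, novelty accounting against
validated substrate lists, annotation enrichment, and a clinical-variant
screen, together with a synthetic data generator that makes the whole
chain verifiable without database access.

# The probability-logo statistic

All motif analyses operate on 15-mer windows, offsets −7..+7 with the
phosphosite at 0 (`extractWindow()`). Sites within 7 residues of a
terminus are padded with `_`; pads are excluded from every count, so a
column's frequencies are over the windows actually covering it. Databases
rarely state how terminal sites were windowed; padding is the standard
probability-logo convention and keeps all sites usable.

For each (position, residue) cell with count $k$ among $n$ non-pad
characters and background frequency $p$, `binomialHeight()` returns

$$h = \begin{cases}
  -\log_{10} P(K \ge k), & k/n \ge p \\
  +\log_{10} P(K \le k), & k/n < p
\end{cases} \qquad K \sim \mathrm{Bin}(n, p),$$

an exact tail sum (computed in log space via `pbinom(log.p = TRUE)`, no
normal approximation), signed so that over-represented residues are
positive. The upper-tail branch is taken at exact equality $k/n = p$;
heights therefore satisfy $h(k,n) = -h(n-k,n)$ at $p = 1/2$ for every
$k \ne n/2$, while the identity cannot hold at the exact midpoint (both
$k$ and $n-k$ fall in the upper-tail branch there).

Significance uses a Bonferroni family of all 20 residues at the 14
non-center positions, threshold $-\log_{10}(\alpha/280)$ at
$\alpha = 0.05$ (3.748). The center column is excluded from testing:
strata are split by center residue before analysis (serine versus
threonine phosphoacceptors), so a center test would be circular; its S/T
composition is reported descriptively instead.

Background frequencies are position-independent, pooled over all columns
of a random-peptide background set (default 10,000 windows; the size of
published random backgrounds is rarely stated, and at this size the
background estimate contributes negligible variance). A user can instead
pass a fixed composition vector — e.g. `swissprotFrequencies()`, the
embedded Swiss-Prot average amino-acid composition — which is also the
default composition the generator samples from. Estimated background
frequencies are floored at $10^{-4}$ so that a residue absent from a
small background set cannot produce degenerate tails.

Note that a strong planted signal produces *mirror* cells: if 80% of
windows carry E at +2, every other residue is depleted at +2 and those
cells cross the threshold with negative heights. `significantCells()`
therefore ranks by $|h|$ (ties broken by position, then residue), and "the
motif is the top feature" means the top-ranked cell, not the only one.

# The filter cascade

`applyFilters()` reduces a phosphosite table to the putative substratome.
The rules run in a fixed order so every rejection carries exactly one
deterministic reason (the first failing rule):

1. `center_residue` — serine phosphoacceptor (configurable to S/T);
2. `motif` — glutamate at +2; a site whose +2 position does not exist
   cannot match; optionally an *annotated phospho-serine* at +2 satisfies
   the acidic requirement (`allowPSerPlus2`, off by default — the strict
   S-x-E selection is the stricter, database-reproducible choice);
3. `compartment` — at least one whitelisted term (Golgi lumen, ER lumen,
   extracellular matrix/region/space by default), matched
   case-insensitively against an open vocabulary; proteins annotated to
   both luminal and cytosolic compartments pass this step and are left to
   the topology and secretion rules, mirroring how manual curation treats
   noisy multi-compartment annotations;
4. `topology` — for membrane proteins, a site inside a cytoplasmic or
   transmembrane segment is rejected; a membrane protein's site covered by
   *no* segment is kept but flagged (`topology_warning`) rather than
   silently dropped or admitted — the ambiguity is surfaced;
5. `secretion_route` — proteins reaching the extracellular space by
   non-classical secretion are rejected.

Filter order is a package decision (the underlying curation rules have no
inherent order); fixing it makes rejection logs reproducible. Enabling any
additional rule can only shrink the kept set, and kept + rejected
partition the (deduplicated) input — both properties are enforced by
tests on randomized datasets.

Residue mismatches between a site record and the sequence are treated as
curation errors and dropped with a log (`validateSites()`), never
corrected in place.

`compareToValidated()` reports site- and protein-level overlap with
validated substrate lists, with novel fractions rounded to one decimal on
the percent scale, as such comparisons are conventionally quoted.

# Kinase preference profiling

Peptide-library selectivity matrices arrive with arbitrary, per-dataset
scaling, and the transformation behind published glutamate-preference
heatmaps is typically unstated. The default normalization is therefore the
**rank quantile**: the fraction of the 20 residues at a position scoring
below E, ties counted half. It is invariant to any monotone rescaling of a
matrix; a uniform column scores 0.475 and a column where E dominates all
19 other residues scores 0.95. Alternatives (`row_max`, and `log_odds_z`,
the normal CDF of E's z-score among log scores — mapped through the CDF so
values stay in [0, 1]) are provided for sensitivity checks.

`flagPlus2Specialists()` flags kinases whose +2 value exceeds every other
position *and* the cross-kinase median +2 value by a margin (default 0.2
on the [0, 1] scale — roughly half the spread between a tied column and a
dominant one, which separates a genuine specialist cleanly in panels of
the ~32-kinase size used for acidophilic panels). Strict inequality means
exact ties never qualify, so an all-uniform panel flags nothing even at
margin 0.

# Enrichment and the variant screen

Over-representation uses the exact hypergeometric upper tail
(`phyper`) with Benjamini–Hochberg adjustment across all terms with
nonzero overlap; the universe defaults to all genes in the annotation
collection (configurable — e.g. to a secretory-pathway universe). Terms
with zero overlap are not reported, matching over-representation
semantics.

The variant screen intersects missense variants (HGVS protein notation,
three- or one-letter) with substratome motifs, reporting hits on the
phosphoacceptor serine (`S_center`) and the +2 glutamate (`E_plus2`)
for the requested clinical classes (pathogenic / likely pathogenic by
default). Only S and +2 are screened by default — they are the two motif
positions with a defined biochemical role; the −2/−1/+1 flanks carry no
consensus constraint. Conflicting classifications of one variant across
submissions are retained as separate flagged rows, not resolved.
Reference residues are cross-checked against sequences when available;
mismatches are flagged and excluded from the main report.

# The synthetic data generator

`simulateDataset()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the study conditions:

* 260 proteins, mean length 400 aa, residues drawn from the Swiss-Prot
  average composition;
* compartment mix 45% secretory (extracellular / ER lumen / Golgi lumen),
  33% cytosol, 22% nuclear matrix; 25% of proteins membrane-anchored with
  a luminal / transmembrane / cytoplasmic segment triple; 10% of
  extracellular proteins flagged non-classically secreted;
* 500 secretory, 300 cytosolic and 200 nuclear phosphosites; serine
  fraction 0.85 (the phosphoacceptor is strongly serine-biased in this
  pathway); planted E@+2 probability 0.8 on secretory serines — the
  motif-dependence level reported for knockout secretome experiments;
* when a secretory serine is *not* planted, its +2 residue is drawn from
  the background conditioned on not-E, so the realized E@+2 fraction
  equals the planted probability exactly in expectation (an unconditioned
  draw would inflate it by the background E rate);
* site positions sit on a 10-residue grid, so one site's planted residues
  never fall inside another site's −7..+7 window and flanking-column
  statistics stay independent (denser, biologically realistic site
  clustering would induce real but uninteresting cross-window
  correlations);
* 15% of secretory sites on membrane proteins are placed in the
  cytoplasmic segment, emulating the annotation noise the topology filter
  removes; ~8% each of planted motif sites carry `validated_direct` /
  `ko_responsive` evidence so novelty accounting is exercised;
* 60 missense variants, half planted on motif S/+2 positions with
  pathogenic-tier classes;
* a single global seed, split into fixed per-stage streams (proteins,
  sites, background, variants), so regenerating one stage never perturbs
  another and outputs are byte-identical across runs.

An optional cytosolic signature (Pro@+1, Arg@−3; off by default)
reproduces the qualitative contrast with proline-directed and basophilic
kinase compartments.

What the generator does **not** emulate: real domain architecture,
sequence composition heterogeneity across proteins, PTM co-occurrence,
clustered phosphosites, or annotation vocabularies beyond the compartment
terms used by the cascade. Passing tests on synthetic data therefore
demonstrate the correctness of the statistics and the filter logic under
the stated model, not the biological fidelity of any particular substrate
call on real data.

# Packaged stand-in fixtures

The curated tables behind the published substratome (a licensed database
export plus manual curation) are not redistributable, so the package ships
deterministic *synthetic* stand-ins whose composition matches the curated
tables they emulate:

* `syntheticSubstratomeFixture()` — 256 luminal proteins carrying 443
  S-x-E phosphosites (187 proteins with two sites, 69 with one), 101 of
  them validated on 78 proteins, plus 60 decoys spanning every rejection
  reason. The cascade and the novelty comparison *recompute* 443 / 256 and
  342 novel sites (77.2%) / 178 novel proteins (69.5%) from this input.
* `syntheticValidatedWindows()` — 130 direct-substrate windows with E@+2
  planted in 78% (101/130 = 77.7% realized).
* `syntheticKinasePanel()` — 32 acidophilic-kinase scoring matrices with
  one planted +2 specialist.
* `syntheticVariantFixture()` — four secretory proteins with synthetic
  backbones and motif sites at the published positions of clinical
  interest (Ser72/Glu74, Ser47, Ser1517), with the corresponding
  ClinVar-style variant records.

Real tables supplied as TSV flow through the same functions unchanged.

# Numerical choices and problem sizes

Exact binomial and hypergeometric tails are used throughout (no
approximations); both are verified against independent brute-force oracles
(direct log-space summation; exhaustive subset enumeration) to $10^{-9}$
in the test suite. Ties in cell ranking break lexicographically by
(position, residue); rank-quantile ties average; BH q-values come from
`p.adjust`. Degenerate inputs (all-pad columns, empty strata, empty
selections, header-only outputs) are defined behaviors, not errors, except
where an analysis is meaningless (no windows, empty gene selection).

Test and acceptance runs use scaled problem sizes chosen to keep the
whole suite fast while leaving comfortable statistical margins: 20-seed
sweeps of ~500-window serine strata for planted-signal recovery, 100-run
sweeps for error-rate control, 100 randomized small datasets for the
filter invariants, and a 10,000-window background.

# Limitations

The cascade formalizes curation rules, but published substrate catalogues
also involve manual judgment that no rule set reproduces exactly;
recomputation from a raw database export is expected to differ at the
margins. Compartment matching is term-based (case-insensitive, open
vocabulary) with no ontology traversal. Enrichment term lists depend
heavily on the annotation collection version and are treated as
qualitative. The logo statistic tests cells marginally; it does not model
inter-position dependence.
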