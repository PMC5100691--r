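---
title: "Profiling two-target selectivity and Hansch SAR with seltrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling two-target selectivity and Hansch SAR with seltrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seltrend)
```

`seltrend` turns raw two-target potency tables into selectivity profiles at
three levels — measurements, compounds, and Bemis–Murcko scaffolds — and
closes with a classical Hansch regression on a substructure-defined series.
This vignette explains the underlying models and the design choices a user
should know about before trusting the output.

## The labeling model

All potencies enter in nanomolar and are transformed to negative log molar
activities, `p = 9 - log10(value_nM)`, so 1 µM corresponds to `p = 6.0`.
Units are *not* converted: a record carrying any other unit is rejected at
ingestion, because silent unit conversion is a classic source of
order-of-magnitude errors in public bioactivity data. A second ingestion
guard rejects values above 10^8 nM as presumptive data errors.

Binary activity labels are assigned against *drug-anchored cutoffs*,
derived independently per target and endpoint: among exact-value records of
drugs recognized as pharmacologically active on the target, the *least
potent* one sets the cutoff. The comparison is cutoff-inclusive
(`value <= cutoff` labels active) because the anchoring drug itself is, by
construction, still considered active. Cutoffs are never pooled across
endpoints — IC50 and Ki distributions differ systematically — which is why
the reference conditions carry four distinct anchors (A-target Ki 1110 nM
and IC50 2090 nM; B-target Ki 1460 nM and IC50 1830 nM).

Censored measurements need care. A record `> 1000 nM` with a cutoff of
1110 nM *appears* active under the base rule but only states that potency
is worse than 1000 nM; such records are forced inactive and flagged
(`censored_override`). Conversely `< x` records with `x` above the cutoff
cannot be settled either way; they are labelled inactive but flagged for
manual review, and a per-record override file can force individual labels
afterwards. The `~` relation is treated as `=` — an approximate value still
carries a point estimate, and the flag-and-override path covers the cases
where that is too optimistic.

## Profiles, medians and variability

Replicate labels per compound–target pair are aggregated by their median;
an even split yields exactly 0.5, which marks contradictory evidence. The
overlap matrix keeps the *full* label and p-activity lists alongside the
median, so no information is lost to aggregation. Profile categories
require measurements on both targets (`incomplete` otherwise) and
unambiguous medians (`ambiguous` at 0.5); completeness takes precedence
when both apply. The four remaining categories are the cross of the two
binary medians.

Two R² statistics quantify how much noise the data carry before any
modelling: the *intra*-assay statistic correlates the maximum against the
minimum replicate p-activity over compounds measured at least twice (per
target and endpoint), and the *inter*-endpoint statistic correlates
per-compound median pIC50 against median pKi. Only exact-value records
(`=`, `~`) enter either statistic — a censored bound is not a measurement
of the quantity being correlated. For the inter statistic the package
pairs one median per endpoint per compound; correlating all cross pairs
instead is available behind `inter_method = "all_pairs"`, and the median
pairing is the default because it weights each compound once regardless of
its replication depth.

## Scaffold trends

Bemis–Murcko frameworks are computed by graph pruning: the 2-core of the
bond graph retains exactly the ring systems and the linker paths between
them, and atoms attached to that core by a multiple bond are added back so
a carbonyl linker keeps its oxygen. Acyclic molecules map to an empty
sentinel and cluster together. Canonicalization goes through Open Babel.
Stereo descriptors present in the input are kept by default — frameworks
of stereoisomers may then differ, which is a documented property of the
method — and `strip_stereo = TRUE` gives coarser clusters. A practical
caveat inherited from the method itself: chemically coherent series can
split across frameworks when the amine is or is not part of a ring, which
is precisely why the SAR strand uses substructure queries rather than
scaffold membership to define its series.

Scaffold trend scores are the arithmetic mean of member *median* labels,
one value per compound, per target. A mean ≥ 0.6 on one target with ≤ 0.4
on the other classifies the scaffold as selective; both ≥ 0.6 is
promiscuous-active, both ≤ 0.4 inactive, anything else "no trend". The
mean-over-medians choice (rather than over all raw labels) keeps heavily
re-measured compounds from dominating a cluster; the raw alternative is
available via `label_source = "raw"`. Trends are only *reported* for
clusters with at least `min_size = 10` members — smaller clusters keep
their scores but carry `reported = FALSE`.

hERG liability is flagged per compound when any hERG-channel record lies
strictly below 10 µM with a relation that bounds potency from above
(`=`, `~`, `<`, `<=`); `>`-censored records never trigger the flag, and
IC50/Ki records pool, as the flag is a screening alert rather than a
potency estimate.

The benzoylethanamine query shipped as the default substructure filter,
`O=C(c1ccccc1)[#6][NX3]`, requires the benzoyl carbonyl and a trivalent
nitrogen on the alpha carbon but deliberately allows any carbon
substitution there. The exact required pattern is an assumption — the
motif admits stricter readings — so every consumer accepts an arbitrary
SMARTS override.

## The Hansch analysis

The descriptor set is the classical eleven for a benzoyl ethanamine
series: whole-molecule van der Waals volume, logP and molar refractivity;
incremental substituent volumes at the Cα to the carbonyl and at the amine
nitrogen; additive aromatic substituent constants π, MR, σm, σp; and
meta/para indicator variables. Multi-substituted rings sum their
constants, following standard Hansch practice; the bridged
3,4-methylenedioxy group counts once for π/MR, contributes its own σ
values, and sets both indicators.

Whole-molecule volumes come from a group-contribution scheme
(`V = Σ atoms − 5.92·bonds − 14.7·aromatic rings − 3.8·aliphatic rings`,
benzene = 81.2 ų), logP and MR from Open Babel's additive models.
Aromaticity for the ring corrections uses a bond-order heuristic (5–6
rings whose carbons each carry a multiple bond, with N/O/S passing as
lone-pair donors); it covers the chemistry of this package's domain but is
not a general aromaticity model. Substituent volume increments ship in an
editable constants table, computed by the same incremental-probe approach
the analysis itself is built on — the difference between two molecules
differing in a single position — so the table and the backend cannot
drift apart; a consistency test regenerates table entries from probes.
Hammett σ and aromatic π/MR values are literature constants and the table
is data, not code. Note a limitation of any group-contribution volume:
isomeric substituents (n-butyl vs isobutyl) receive identical increments.

Regression is ordinary least squares with an intercept; p values are
two-sided t tests on `n − p − 1` degrees of freedom. Backward elimination
repeatedly drops the least significant descriptor while its p value
exceeds `alpha = 0.05`, never drops the intercept, and breaks exact p-value
ties towards the later column so the procedure is deterministic. `ols_fit`
refuses zero-variance and rank-deficient inputs by name rather than
silently dropping terms; the pipeline pre-screens exactly collinear
descriptors (which arise naturally in small series, e.g. σm proportional
to the meta indicator when only one meta substituent occurs) before
handing the matrix to elimination. Two responses are fitted per series:
the B-target pIC50 and the log selectivity `log10(IC50_A/IC50_B)`, which
equals `p_B − p_A`. Compounds with censored responses are excluded from
the affected regression and listed by id in the exclusion report — this is
also the package's working rule for why such fits use fewer compounds than
the series holds. When a compound carries several B-target IC50 values the
lowest (most potent) is used, with the median available behind a flag.

## What the synthetic generator emulates

`generate_library()` draws compounds by prefixing acyclic decorations onto
ring-system templates, so Murcko clustering provably recovers the
templates; each template carries a selectivity class drawn from the
configured mix. Potencies are lognormal in nM (Gaussian in p-activity) —
the conventional model for potency data — with actives centred at
p = 7.0 (100 nM) and inactives at p = 4.7 (≈ 20 µM), scaffold-level
effects of sd 0.3 and compound-level spread of sd 0.5. The default class
mix (51% dual-active, 22% A-selective, 11% B-selective, 16% inactive)
mirrors the observed preponderance of dual actives and A-selectives in
the public transporter data. Measurements add replicate noise whose sd
is calibrated so that the duplicate max-vs-min correlation hits a target
R² of 0.74, the value observed for the best-behaved endpoint; pKi records
sit a systematic 0.25 log units above pIC50; 8% of records are
right-censored as `>` at a 10 µM assay limit; drug anchors are planted at
exactly the four reference cutoffs, so the drug-anchored derivation
reproduces them; and 30% of compounds carry a hERG record centred at
5 µM. Where the emulated study states no value (the Ki offset, the hERG
potency distribution, replication rates), defaults were chosen once as
field-typical magnitudes and are exposed in `library_config()`.

The calibration itself (`calibrate_replicate_noise()`) root-finds on a
10,000-pair pre-simulation with common random numbers; for duplicates the
closed form `cor = (τ² + σ²/π)/(τ² + σ²(1 − 1/π))` bounds the attainable
range (targets below ≈ 0.218 are impossible at any noise level) and
cross-checks the simulation in the test suite.

`generate_sar_series()` plants linear models over the package's own
descriptor matrix: the activity response with a negative logP, positive
Cα-volume and positive π-arom term; the selectivity response with a
negative molar-refractivity and positive Cα/N-volume terms — the
qualitative coefficient structure of the reference analysis, on this
package's descriptor scales. A-side potencies below p = 5 (4) are
reported as `> 10 µM` (`> 100 µM`), reproducing series in which roughly
half the A-side measurements are bounds; the selectivity intercept was set
once so that condition holds. The shipped 56-compound set is a frozen
draw (fixed seed) with one pinned exemplar — isobutyl at Cα,
pyrrolidine at the nitrogen, IC50_A = 34.5 µM, IC50_B = 100 nM, a
345-fold B-side ratio — exempted from censoring so its exact ratio is
carried; a determinism test regenerates the file bit-identically.

What the generator does *not* emulate: assay heterogeneity beyond a single
noise scale, correlated measurement errors within documents, chemically
realistic decoration–potency relationships in the library strand (potency
attaches to the scaffold class, not the decoration), or 3D structure.
Passing tests therefore demonstrate the pipeline's correctness and
statistical calibration, not performance on any particular real data set.

## Numerical choices and degenerate inputs

* Potency values are generated to six significant digits so CSV
  round-trips are bit-identical.
* `aggregate_median` is the standard sample median; only balanced
  even-length lists produce 0.5.
* Elimination down to zero descriptors returns an intercept-only summary
  with r² = 0 rather than an error.
* Empty profiling input exits cleanly with a "0 compounds" report; empty
  hERG input flags nothing.
* SD ingestion parses records and property tags with its own splitter
  (property values may legitimately begin with `>`; stock data-block
  parsers mis-read that as a tag header) and skips unparseable molecule
  blocks with a count.
* Problem sizes in the shipped tests and acceptance script — libraries of
  ~200 compounds, 100-compound SAR series, 200 replicate refits, 10,000
  calibration pairs — were chosen as the smallest sizes at which the
  statistical checks are stable.

## Known limitations

Stereochemistry survives framework extraction only as far as the
underlying format conversions carry it; clustering of stereo-rich series
should be validated or run with `strip_stereo = TRUE`. The volume backend
is isomer-blind at substituent level. The inter-endpoint variability
definition (median pairing) is one of two defensible readings, with the
alternative exposed. And the Hansch descriptor scales here are those of
the open backend — coefficients are comparable within analyses run by this
package, not with analyses run on proprietary descriptor implementations.
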