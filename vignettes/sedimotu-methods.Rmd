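---
title: "Methods: from tagged amplicon reads to spatio-temporal sediment ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tagged amplicon reads to spatio-temporal sediment ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sedimotu` implements a complete metabarcoding workflow for deep-sea
sediment eukaryote communities profiled with a short hypervariable 18S rRNA
(v7) marker, together with a synthetic-data module that emulates a
stratified sampling campaign so that every stage is testable without any
external download. This vignette explains the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic tests
do and do not demonstrate about real data.

## The pipeline

Raw paired-end reads travel through eight stages:

1. **Paired-end merging.** The forward read is aligned ungapped against the
   reverse-complemented mate at every relative offset; the overlap is scored
   +1 per match and -1 per mismatch and the best-scoring offset wins.
   Pairs scoring below `min_score = 40` are discarded, so an accepted merge
   is supported by roughly forty high-confidence overlapping bases.
   Conflicting overlap positions take the higher-quality base.
2. **Demultiplexing.** Each sample is labelled by one 8-base tag placed at
   *both* ends of the amplicon, with every tag pair differing at three or
   more positions (`design_tags()` verifies this by construction). A read
   is assigned only when both terminal tags match the same sample exactly;
   reads carrying two different valid tags are inter-sample PCR chimeras
   and this two-sided design is what makes them detectable — they are
   discarded and logged. Primers are matched IUPAC-aware with up to two
   mismatches (primers are universal/degenerate, so some tolerance is
   needed; tags, being the sample key with a Hamming-3 code, get none:
   there is no safe correction radius for a 1-mismatch tag). Inserts
   shorter than 75 bp after trimming are dropped.
3. **Dereplication and singleton removal.** Strictly identical sequences
   collapse to one record with per-sample counts; sequences whose summed
   count is one carry no corroborating evidence and are removed.
4. **Cleaning by similarity.** Sequences with best identity below 0.8
   against the reference database are removed. Identity is computed from a
   global alignment that maximises matched bases (match +1, mismatch and
   gap 0) and is normalised by the *alignment length* — the shortest
   alignment achieving the maximal match count. Normalising by alignment
   length (rather than query length, also available via
   `normalise = "query"`) penalises length outliers, which is what prunes
   long chimeric or non-specific products while retaining genuine marker
   sequences.
5. **MOTU clustering** (below).
6. **Taxonomic assignment** (below).
7. **Table filters.** In order: the cumulative-frequency filter, removal of
   MOTUs detected in blanks or negative controls, removal of MOTUs not
   assignable at the Super-Group level, and removal of non-marine MOTUs
   via the taxonomy's marine flag (a stand-in for an external marine
   species registry). A stage log records MOTUs and reads before and after
   every stage.
8. **Statistics** (below) on the presence/absence MOTU table.

## Flexible-threshold clustering

Real communities do not share a single similarity cut-off across taxa, so
MOTUs are delineated with a flexible-threshold procedure rather than one
fixed radius. `cluster_motus()` is a deterministic formulation of that
idea: sequences are seeded greedily in decreasing-abundance order at 99%
identity; each cluster then keeps a centre (its most abundant member, ties
broken lexicographically) and a distance scale $\sigma_c$ estimated as the
root-mean-square member-centre percent distance, clamped to
$[l, u] = [0.3, 0.5]$ (percent units — the parameterisation corresponding
to a 99% initial clustering level). Members move to the cluster maximising
the Gaussian kernel $N(d;\,0,\sigma_c)$, and clusters whose centre lies
within $3u$ of a more abundant cluster's centre are absorbed into it. The
absorption step is needed because the member-wise kernel step alone can
never merge two clusters (each centre is at distance zero from itself);
$3\sigma$ at the maximal allowed spread is the natural "could plausibly
belong" radius. Iteration stops at a fixed point or `max_iters`.

The original Bayesian tool explores cluster configurations by MCMC; at
desk scale we need determinism and a testable notion of correctness, so
correctness is defined by two independent oracles: (i) on well-separated
instances — all within-family pairwise identities above the 99% threshold
and between-family identities far below it — the partition must equal
single-linkage clustering at 99%; (ii) reads simulated from reference
species at 1% uniform substitution error and 30x coverage must yield
exactly one MOTU per species. Both are asserted in the test suite. The
final within-cluster spread can end up above or below the initial level,
which is the point of a flexible threshold.

## Best-hit / LCA assignment

For each MOTU representative the best reference hit is found at identity
$s^\*$; the co-assignment set collects every reference at least as similar
*to the best hit* as the query is, and the MOTU receives the lowest common
ancestor of the set's taxa. The alternative reading — references at least
$s^\*$ similar *to the query* — is available via
`neighbour_rule = "query"`; the best-hit reading is the default. Ties for
the best hit break by reference id for determinism. As $s^\*$ falls the
set widens and the assignment climbs the taxonomy, so poorly matched MOTUs
are only assigned at high ranks — a property asserted in the tests.
Assignments are rolled up to Super-Group, with Opisthokonta split into
Metazoa, Fungi and "other Opisthokonta", and metazoans further down to
Phylum; MOTUs with no supergroup-rank ancestor are flagged unassignable
and dropped by the corresponding filter.

## The cumulative-frequency filter

For each MOTU the per-sample counts are sorted ascending and every entry
whose running cumulative sum (including itself) stays below 3% of the row
total is zeroed; tied counts are zeroed together iff the cumulative
fraction through the last tied entry is below the threshold, so the result
is independent of sort order. This strips low-level tag bleed between
samples. One caveat discovered while testing: the rule is *not* exactly
idempotent, because zeroing shrinks the row total and can push a
borderline entry below the threshold on re-application. Re-application is
the identity whenever no entry's cumulative fraction lies in
$[t, t/(1-t))$ — a band of width under 0.1 percentage points at the
default $t = 0.03$ — and the filter is applied once, as in the original
workflow.

## Ecological statistics

All statistics run on presence/absence and the Jaccard distance
$d = 1 - |A \cap B| / |A \cup B|$ (similarities are reported as
$100(1-d)$ percent). Samples can be pooled by corer replicates or by
layers before distances, using the union of presences.

**PERMANOVA.** The distance matrix is partitioned sequentially over model
terms via the Gower-centred inner-product matrix and hat-matrix
projections; the one-way case equals the closed form
$SS_\text{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
$SS_\text{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$ (a test
asserts the equality). Pseudo-F uses the residual mean square; p-values
use the $(\#\{F^\pi \ge F\} + 1)/(n_\pi + 1)$ estimator, never exactly
zero, with ties counted as exceedances. Permutations may be free,
restricted within strata (for tests below a blocking factor, e.g. layers
within corers), or of whole equal-sized blocks. `exact = TRUE` enumerates
all relabellings for small n, and the permutation estimator is tested
against that enumeration. Arbitrary unbalanced random-effects
denominators are out of scope: the residual denominator is always used,
which is the main caveat when mimicking mixed-model tables.

**PERMDISP.** Samples are embedded by principal coordinates keeping
negative-eigenvalue axes; the distance of a sample to its group centroid
subtracts the imaginary-part contribution
($z^2 = d^2_\text{real} - d^2_\text{imag}$, clamped at zero). The one-way
F on those distances is permuted by relabelling groups and recomputing
centroids. Results match `vegan::betadisper(type = "centroid")` on the
same input.

**nMDS.** Kruskal stress-1 is minimised by alternating isotonic regression
of configuration distances on dissimilarity ranks with a Guttman
majorization update, over `n_starts` random starts (default 500, the
conventional choice for published ordinations; the first start is the
principal-coordinate configuration). Ties in the dissimilarities share one
fitted disparity (secondary tie treatment) — with many tied Jaccard values
this is the conservative choice, and it keeps genuinely non-embeddable
configurations (four equidistant points in the plane) at positive stress.
The best solution is centred and rotated to principal axes; stress on tied
data can therefore sit slightly above a primary-ties optimiser such as
`vegan::monoMDS` (about 0.01 on our fixtures).

**Vector fitting, rarefaction, tests.** An environmental variable is
regressed on the ordination axes; $r^2$ is the squared multiple
correlation and p comes from permuting the variable. Rarefaction uses the
exact hypergeometric expectation
$E[S_m] = \sum_i \left(1 - \binom{N-N_i}{m}\big/\binom{N}{m}\right)$
computed on the log scale, and is tested against a 10,000-draw Monte-Carlo
oracle and `vegan::rarefy`. Richness comparisons use pooled-variance or
paired t-tests; pairwise permutation tests between factor levels adjust
p-values with the Benjamini–Yekutieli FDR correction (`p.adjust`).

All permutation tests are calibrated: under simulated nulls the type-I
error at $\alpha = 0.05$ lies within $[0.03, 0.07]$ over 1,000
simulations (asserted in the acceptance tests and recomputed by
`scripts/acceptance.R`).

## The synthetic community model

The generator emulates the structure of a two-season deep-sea campaign:
five stations along a canyon–slope depth gradient (0.87–1.75 km), three
corer replicates per station, three sediment layers per core (first cm,
second cm, third–fifth cm), two seasons, plus PCR blanks and extraction
negatives; and a single-season DNA/RNA co-extraction subset in which each
core yields both templates.

Occupancy of MOTU $i$ in core $s$ is Bernoulli with

$$\mathrm{logit}\, p_{is} = \beta_0 + u_i + \beta_L\,\mathrm{layer}_s +
\beta_D\,\mathrm{depth}_s + \beta_Z\,\mathrm{zone}_s +
\beta_S\,\mathrm{season}_s,$$

with layer coded 0/1/2 down the core, depth in km centred at the design
mean, zone and season as 0/1 contrasts, and $u_i \sim N(0, \sigma^2_m)$ a
MOTU-level random intercept. The defaults — $\beta_0 = -2$ (about 12%
baseline occupancy, matching the reported per-sample richness relative to
dataset totals), $\beta_L = -1$, $\beta_D = -1.5$/km, $\beta_Z = 1$,
$\beta_S = 1$, $\sigma_m = 1$, 500 MOTUs — are the desk-scale conditions
under which the reported contrasts (surface-to-deep richness decline,
canyon–slope differentiation, seasonal turnover, depth gradient) are
recoverable. $\beta_S$ equals $\beta_Z$ because the study found season and
zone comparably strong (between-season and between-zone mean similarities
both in the 26–28% range).

**Templates.** Presence and activity are drawn once per physical core, so
DNA and RNA samples from the same core describe the same community. RNA
detects present-and-active MOTUs; activity is the product of a MOTU-level
capability and a core-level draw, each Bernoulli$(\sqrt{a})$, keeping the
marginal activity rate at $a = 0.7$. The MOTU-level component encodes
taxa occurring mainly as dormant or dead material — rarely active anywhere
— and is what lets total DNA richness exceed total RNA richness (about
20% at the defaults) while the per-sample excess sits near
$1/a - 1 \approx 43\%$; with purely core-level activity the totals would
almost coincide. DNA additionally re-detects, with probability
`legacy_rate` $= 0.2$, MOTUs absent from a core but present at the same
station/corer/layer location in the other season: persistent legacy DNA.
This temporal reading of persistence leaves the single-season
co-extraction subset unaffected and, in the two-season design, blends the
seasons' DNA communities — which is also why the season effect is the
hardest of the three to detect (its power hovers around 0.8–1.0 per
20-seed batch, against 1.0 for layer and zone).

**Reads.** Each sample's reads are allocated multinomially over detected
MOTUs with log-normal abundance weights; a read is
tag + forward primer + fragment + revcomp(reverse primer) + revcomp(tag),
sequenced from both ends at 120 bp with uniform substitution errors (1%
default; no indels, by design, so the round-trip identity oracle stays
exact). Tag chimeras (1%) carry a mismatched 3' tag; cross-sample
contamination (0.5%) re-tags whole reads to another sample, which is
precisely the signal the cumulative-frequency filter targets; singleton
injections (0.5%) add unique one-off sequences. The contamination and
chimera defaults are placeholders — the original study does not quantify
either rate. Reference fragments are 76–140 nt, drawn independently per
species (hence well separated), with an option to force species pairs to
share a sequence, mimicking markers that cannot separate all species.

**What the synthetic tests do not show.** Real 18S data have
phylogenetically structured similarity between species (random fragments
are ~25% identical; congeners can be >99% identical), quality-score
gradients, indels and chimeric PCR artefacts beyond the tag-swap kind, and
taxon-specific amplification bias. Passing the synthetic suites therefore
demonstrates the correctness of the algorithms under their stated models,
not field-scale accuracy of, say, the clustering threshold for closely
related species.

## Numerical choices and degenerate inputs

* Identity comparisons and cluster-joining thresholds carry a `1e-9`
  epsilon: `100 * (1 - 0.99)` is not exactly 1 in floating point.
* PERMANOVA's residual sum of squares is clamped at zero when cancellation
  drives it slightly negative (complete-separation designs), so the
  pseudo-F becomes `+Inf` rather than a negative number; `Inf >= Inf` ties
  count as exceedances.
* PERMDISP returns F = 0 when all centroid distances are numerically
  equal (all-equidistant inputs), instead of amplifying rounding noise.
* Jaccard distance between two empty samples is undefined and returned as
  `NA` with a warning.
* Empty member sets, empty reference sets, missing tags, duplicate tags
  and unknown factor levels raise typed errors at the module boundary.
* Problem sizes used by the tests and the acceptance script (e.g. 25–40
  species, 30x coverage, 12-sample calibration designs, 1,000 null
  simulations) were chosen so the whole suite completes in a few minutes
  on one CPU while keeping every Monte-Carlo interval tight enough to be
  informative.

## Known limitations

* The clustering refinement is a deterministic surrogate with the same
  parameter interpretation as the original Bayesian sampler, not a
  reimplementation of its MCMC; outside the well-separated regime the two
  can legitimately differ.
* PERMANOVA always uses the residual denominator; random-effect
  denominators of mixed-model tables are not constructed.
* The exact-enumeration path is limited to n <= 8.
* De novo chimera detection (beyond identical-tag elimination) and
  abundance-weighted dissimilarities are out of scope; the analyses here
  are presence/absence by design.
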