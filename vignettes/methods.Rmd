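---
title: "Methods: from peat organic matter to methane, stage by stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peat organic matter to methane, stage by stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxomics)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the parameters that matter,
and the places where the design was genuinely open and a choice had to
be made.

## The analysis in one paragraph

Anoxic peat incubations from two contrasting habitats (an acidic,
Sphagnum-dominated bog and a more neutral, sedge-dominated fen) are
profiled with untargeted LC–MS/MS metabolomics, genome-resolved
metatranscriptomics, and headspace gas measurements. The pipeline
cleans LC–MS artifacts, normalizes and contrasts metabolite
intensities, scores the thermodynamic quality of compounds via the
nominal oxidation state of carbon (NOSC), aggregates gene expression to
metabolic-pathway scores under geTMM normalization, applies
activity/encoding rules to metagenome-assembled genomes (MAGs),
relates metabolite co-expression modules to methane production with a
signed weighted network, and converts headspace ppm into total gas
production with Henry's law.

## In-source fragment removal

Electrospray ionization fragments a portion of many parent ions in the
source. The resulting artifact ions are not separate compounds: they
co-elute with the parent (identical retention time up to instrument
jitter), their intensity is a roughly fixed fraction of the parent's in
every sample (fixed ionization branching), and their *m/z* appears in
the parent's MS2 spectrum. The cleaning stage operationalizes exactly
these three signatures:

1. **RT binning** (`bin_by_rt`): single-linkage clustering on the
   sorted retention-time axis with an inclusive gap tolerance
   (default 0.005, in the units of the RT column). Single linkage was
   chosen because it is deterministic, order-free, and matches the
   tolerance-window reading of "binning"; an inclusive gap (`<=`) makes
   the boundary case explicit. The default is deliberately left
   unit-agnostic: 0.005 s would be implausibly narrow if RT were in
   minutes, so the tolerance simply applies to whatever unit the
   table's RT column uses.
2. **Co-elution correlation** (`coeluting_pairs`): Pearson correlation
   of *raw* (untransformed) intensities across all samples, strict
   `> 0.98`. Raw intensities are used because the fragment/parent
   relationship is multiplicative on the raw scale; transformation
   would only weaken it. Zero-variance features are excluded (their
   correlation is undefined). Correlated groups are taken as connected
   components: if A–B and B–C correlate but A–C does not, all three
   still co-elute as one cluster.
3. **MS2 matching** (`match_fragment_to_parent`): the heaviest ion of a
   group is the parent (*m/z* ties broken lexicographically by feature
   id, for determinism); a lighter member is removed when its *m/z* is
   within 5 ppm of a parent MS2 fragment (relative error computed
   against the fragment mass).

A manual inspection step in the original workflow is replaced here by
the automated MS2 criterion plus a removal report
(fragment, parent, *r*, ppm error) retained for human review — manual
curation is not implementable, but its audit trail is.

Features whose *predicted composition* contains F, Cl, Br or I are
removed as analysis artifacts (halogenated compounds are implausible in
natural peat DOM). Features without a predicted formula are kept:
absence of a prediction is not evidence of halogens.

## Normalization and per-feature statistics

**Generalized log.** The default transform is
x' = log2((x + sqrt(x^2 + a^2))/2) with the offset *a* equal to the
minimum nonzero intensity of the whole dataset. A second, "literal"
mode computes sqrt(x^2 + a^2)/2 only; it exists because workflows
occasionally apply that offset-magnitude form verbatim, and keeping it
callable makes faithfulness audits possible. It is not logarithmic and
is not the default.

**Pareto scaling** divides each feature row by the square root of its
standard deviation (n−1 denominator throughout the package),
down-weighting high-intensity features less aggressively than
unit-variance scaling. Zero-variance rows pass through unchanged; a
constant feature carries no contrast information and dividing by zero
would poison downstream stages.

**Per-feature models.** Each transformed feature is fit by OLS with
day (categorical), habitat, and their interaction. Day is categorical
because the sampling grid (0, 7, 14, then habitat-specific final days)
is uneven and a linear trend would be a stronger assumption than the
design supports. The two habitats end on different days (bog 28, fen
35); these are aligned as a single "final" level so the endpoint
contrast compares like with like. Habitat contrasts at each timepoint
use t-based p-values; BH correction is applied across features
*within* each timepoint (the per-timepoint feature lists are the
reported object; pooling across timepoints is available as a flag).
Constant features get estimate 0 and p 1 by construction rather than
trusting floating-point residuals near machine epsilon.

**NOSC.** For a formula with carbon count C, hydrogen H, nitrogen N,
oxygen O, phosphorus P, sulfur S and net charge Z,

NOSC = 4 − (−Z + 4C + H − 3N − 2O + 5P − 2S)/C.

Adding one oxygen raises NOSC by exactly 2/C; adding one hydrogen
lowers it by 1/C — both are asserted as properties in the test suite.
Higher NOSC means more oxidized carbon and less energy per electron on
oxidation, which is why the mean NOSC of methane-associated metabolite
sets is a meaningful thermodynamic summary.

## Pathway logic and geTMM

KEGG module definitions are logical expressions over KO identifiers.
The grammar implemented here: whitespace separates sequential steps,
`,` separates alternative enzymes (binds looser than `+`), `+` joins
subunits of a complex, parentheses group; KEGG's `-K`/`--`
non-essential markers are stripped with a warning since the
aggregation semantics do not model them. Expression aggregation:
alternatives are *summed* (substitutable routes add flux capacity),
complex subunits are *averaged* (a complex is limited by its average
subunit availability), and the pathway score is the *mean over steps*.
Steps whose KOs are entirely unmeasured score 0 by default — a pathway
with absent genes should score low, not be undefined — with an
exclusion flag (`skip_empty_steps`) for the alternative reading.

**geTMM.** Counts are converted to reads per kilobase (RPK), TMM scale
factors are computed on the RPK matrix, and RPK is scaled per-million
by effective library size. The TMM internals follow the canonical
algorithm: reference sample = upper quartile closest to the mean upper
quartile; per-sample factor = doubly trimmed (30% on M, 5% on A,
two-sided) weighted mean of M-values with inverse asymptotic
binomial-variance weights; factors normalized to geometric mean 1. All
four knobs are exposed. One numerical choice departs from computing on
raw RPK: factors are computed on *per-million-scaled* RPK. The
binomial-variance weights depend on absolute library size, so factors
computed on raw RPK shift by ~0.5% when one sample's counts are
rescaled — an artifact of the weight heuristic, not of composition.
On the per-million scale the factors are exactly invariant to
rescaling any single sample, and coincide with the canonical algorithm
whenever library sizes are equal (the test suite cross-checks against
edgeR on that scale). KO-level expression is the *sum* over genes
sharing a KO — total transcript output of that function — not the mean.

## MAG activity, encoding, and redox coupling

A MAG is **active** in a sample iff its summed transcript count is
strictly greater than 15; the boundary (15 inactive, 16 active) is
asserted exactly in tests. An active MAG **encodes** a pathway iff its
annotated KO set satisfies at least 60% of the pathway's steps
(inclusive: 3 of 5 qualifies). A step is satisfied by any one
alternative; a complex requires *all* subunits, because an incomplete
complex is non-functional — the any-subunit reading is available as a
configuration for sensitivity analysis. Encoding is genomic potential:
it depends only on annotation, never on expression level. The
encoding proportion reported per habitat is encoded-and-active over
active, with "active" meaning active in at least one sample of the
group under study.

Habitat comparisons use the two-sided Wilcoxon rank-sum test, exact
when the combined n is at most 20 with no ties and the
normal approximation with tie/continuity corrections otherwise; the
exact path is validated against full enumeration of rank assignments
for all layouts with n ≤ 8. Oxidative–fermentative coupling is the
Pearson correlation, across MAGs at one timepoint, between summed
oxidative (EMP + ED glycolysis) and summed fermentation pathway
expression.

## Methane-correlated modules

The module stage is a deliberately simplified signed weighted
co-expression analysis. Signed adjacency a_ij = ((1+r_ij)/2)^14 maps
anticorrelated features to ~0 rather than folding them into the same
module; β = 14 is the conventional signed-network default. Topological
overlap (TOM) rewards shared neighborhoods on top of direct adjacency,
and modules are average-linkage clusters of 1−TOM cut at a *static*
height (default 0.995) with a minimum size of 30. The dynamic tree cut
of the full WGCNA machinery is replaced by this static cut because it
is deterministic, has two transparent knobs, and recovers planted
partitions exactly — the properties the tests need; the cost is that
weakly-correlated background features can attach to a strong module at
permissive heights, which the retention ranking then demotes. Module
labels are deterministic (by size, then lexicographically smallest
member).

The eigengene is the first principal component of the standardized
member submatrix, sign-oriented so the mean member–eigengene
correlation is positive (flipping the stored PC cannot change the
result). For the most positively and most negatively
methane-correlated modules, the retained "top 100" features are ranked
by absolute per-feature Spearman correlation with methane — the same
statistic used to validate module relationships on raw data — rather
than by module membership strength (kME), which is available as a
flag. Features lacking MS2-based annotation (confidence level 1 or 2)
are dropped before retention when the annotation filter is on.

## Gas accounting

Total production = headspace + dissolved. Headspace moles follow the
ideal gas law at 1 atm (fugacity corrections are out of scope at these
pressures). Dissolved gas follows Henry's law with van 't Hoff
temperature adjustment KH(T) = KH(298.15) · exp(C·(1/T − 1/298.15));
for CO2 the dissolved pool is multiplied by the carbonate speciation
factor 1 + K1/[H⁺] + K1K2/[H⁺]², so bicarbonate and carbonate count
toward total dissolved inorganic carbon. CH4 has no acid–base
chemistry and is pH-invariant — asserted as an identity in tests.
Default constants (CO2 KH = 3.4e-2 mol/(L·atm), C = 2400 K; CH4
KH = 1.4e-3, C = 1700 K; pK1 = 6.35, pK2 = 10.33 at 25 °C) are
standard-compilation values; incubation studies rarely print the
constants they used, so every one is overridable, and temperature
correction of K1/K2 is off by default. A `balch_tube_preset()` ships
the incubation geometry (≈15 mL headspace, 11 mL liquid, 19 °C) as a
named configuration rather than hard-coded numbers.

## What the synthetic data emulates — and what it does not

The generators produce data with the statistical structure each stage
assumes, plus sidecar truth labels (never merged into analysis
inputs, to prevent leakage into pipeline tests):

* **Feature tables**: log-normal genuine features (a fifth carrying a
  habitat effect), in-source fragments with intensity = parent × fixed
  fraction × multiplicative log-normal noise (sd 0.005, which puts
  parent–fragment correlations safely above 0.98), RT jitter within
  ±0.002, fragment m/z drawn exactly from the parent's MS2 list, and
  halogenated artifact formulas.
* **Transcript counts**: negative binomial with variance μ + αμ²
  (α = 0.1, standard RNA-seq overdispersion), MAG-structured, with
  encoded pathways covered step-by-step in the gene catalog and
  activity truth enforced exactly (inactive MAG–sample totals drawn in
  0–15; active totals bumped above 15 when sampling noise dips below).
* **Gas series**: monotone production trajectories inverted through
  the same headspace+dissolved accounting, so noiseless series
  round-trip exactly; fen:bog CH4 ratio defaults to 40.
* **Module data**: one planted module sharing a latent factor whose
  sample correlation with the methane vector equals the requested
  value *exactly* before feature noise (constructed by
  orthogonalization), with independent background features.

Defaults mirror the study conditions: 24 samples = 2 habitats × 4
timepoints × triplicates; 500 genuine features, 50 fragments, 10
halogen artifacts; module size 30 at correlation 0.9. What the
generators do **not** emulate: raw spectra or chromatographic peak
shapes, adducts and isotopologues, read-level sequencing data,
annotation errors, batch effects, or compositional coupling between
features — so passing tests demonstrate correctness of the algorithms
under their stated assumptions, not robustness to every pathology of
real instruments.

Test and simulation sizes were chosen to exercise each claim at the
smallest scale that makes it meaningful: 100-seed recovery loops at 12
samples for network properties, 2000 features for the type-I-error
check, 1000 random ASTs for the parser/scorer oracle.

## Known limitations

* The static-height module cut admits weak background features into
  strong modules near the default height; exact recovery holds for
  well-separated blocks, and contaminated members rank low in
  retention, but module *sizes* are upward-biased relative to a
  dynamic cut.
* Pathway scores treat KOs as independent measurements; shared KOs
  between pathways double-count transcription (definitions are
  expected to be curated to minimize overlap).
* The per-feature linear models assume homoscedastic Gaussian errors
  on the transformed scale; the glog/Pareto pipeline makes this
  plausible but heavy-tailed features will inflate the interaction
  terms.
* Gas accounting assumes equilibrium between headspace and liquid at
  sampling time and ideal-gas behavior at 1 atm.
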