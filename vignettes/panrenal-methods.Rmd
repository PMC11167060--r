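---
title: "Methods: consensus scoring, enrichment, renal indices and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scoring, enrichment, renal indices and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrenal)
```

`panrenal` integrates result-level differential omics across missions,
species and tissues into a gene-level consensus, and quantifies renal
physiology and anatomy around it. This vignette is the package's account of
the methods: the statistics it computes, the assumptions they rest on, the
tunable parameters and their defaults, what the synthetic-data generators
emulate (and deliberately do not), and the design choices made where the
underlying conventions were genuinely open.

## Harmonisation to gene level

The atom of integration is one biomolecule's differential result in one
dataset: feature id, feature class (transcript, protein, phosphosite, CpG,
metabolite–gene link, taxon), native gene symbol, species, log2 fold change
(exposure over control) and p-value. Two steps bring every dataset onto a
common footing.

**Ortholog mapping** (`map_to_hgnc()`). Human symbols are their own HGNC
symbols; other species are looked up by (species, native symbol). Unmapped
symbols are dropped and counted, never silently imputed. One-to-many
orthologs are governed by a policy: the default `drop_ambiguous` removes
them, because a single native gene expanding to several HGNC symbols would
otherwise contribute several correlated observations to the consensus —
double counting that the product score, which rewards replication, is
especially sensitive to. `expand_all` and `first_alphabetical` are
available when coverage matters more than strict independence. Every
mapping run returns a per-dataset report (mapped / unmapped /
ambiguous-dropped / taxon-skipped) whose counts always sum to the input
size.

**Collapsing** (`collapse_features()`). Multiple features per gene —
phosphosites, isoforms, CpG sites — collapse to one call per (dataset,
gene): significant iff any feature has p < α; direction is the majority
sign of the significant features' fold changes; `best_p` the minimum p
over significant features (over all features when none is significant).
The intra-gene aggregation rule is a package choice: majority vote with
ties (and exact-zero fold changes) yielding direction 0, which downstream
counts toward neither the direction sum nor the observation count. The
alternative — letting one strongly significant site determine the gene —
was rejected because phosphosites on one protein routinely move in
opposite directions, and a gene whose own features disagree should not
testify about direction at all. α = 0.05 on unadjusted per-feature
p-values is the default, matching the convention of counting a gene
product as differentially regulated at p < 0.05 from the source study's
test (typically Wald); whether those p-values should first be adjusted
per dataset is left as an explicit option (`adjust`), not guessed.

Collapsing is idempotent and order-invariant; both are tested as
properties.

## The consensus product score

Only *core* datasets — kidney-specific proteome and transcriptome — feed
the score; epiproteome, epigenome, metabolome and plasma/exosome-derived
datasets are displayed in the direction matrix but never scored. The
rationale is confounding: phosphosite and methylation calls measure
regulation rather than abundance, and plasma sources measure a different
compartment.

For each gene, `score_drgp()` computes S (sum of ±1 over core datasets),
n (number of directional, significant core observations) and the product
score P = S·n. The plotting filter keeps |P| ≥ 9 while excluding
|P| = 12. Because every observation contributes exactly ±1, S ≡ n (mod 2),
so the achievable products are sparse (`achievable_products()`): 10 and 11
cannot occur, and 12 arises only as |S| = 2 with n = 6 — four datasets
against two, a directional margin of two. Excluding it makes the filter
equivalent to "majority margin of at least three datasets" *almost*
everywhere: P = 9 is also achievable as |S| = 1, n = 9 (margin one), a
documented inconsistency of the literal numeric rule that cannot bite
with six core datasets. The implementation applies the exclusion to |P|,
so −12 is excluded symmetrically; negation symmetry (flip every direction
⇒ flip every S and P, swap the up/down lists) is a tested invariant. Genes
never observed in a core dataset are retained with n = 0, P = 0 for
display parity.

`filter_and_rank()` orders each sign's genes by |P| descending, ties by n
descending, then symbol — so a 16 built from four unanimous datasets
outranks a 9, and among equal products the more-replicated gene wins.

## Over-representation and term ranking

`overrepresentation()` tests each gene-set term against the significant
genes of one dataset with the upper-tail hypergeometric probability
P[X ≥ k], X ~ Hypergeom(N, K, n_sig). The universe N is the set of genes
*measured in that dataset after harmonisation*, not the genome: detection
differs radically between, say, a phosphoproteome and a transcriptome, and
a genome-wide universe would manufacture enrichment out of detectability.
Term sizes K are computed after intersecting with the universe for the
same reason.

The *enrichment ratio* is k / n_sig — the fraction of the dataset's
significant hits that fall in the term. It is a composition measure, not a
fold enrichment: over a disjoint cover of the significant genes the ratios
sum to one (a tested property), which makes ratios comparable across
datasets of very different sizes.

The test is one-sided by default. The screening conventions the package
follows quote "two-tailed" −log10(p) cutoffs (2 for disease-ontology
screens, 1.3 for pathway modules); for a hypergeometric over-representation
statistic the upper tail is the only direction of interest, and the
two-tailed wording is read as describing the underlying differential
tests. A genuine `two.sided` mode (doubled smaller tail) exists for users
who read it otherwise; neither reading is asserted as the original intent.
P-values are unadjusted by default because the cutoffs above are defined
on unadjusted p; BH adjustment is available.

`rank_terms()` orders terms across datasets lexicographically: replication
count (number of datasets where significant) first, then best p, then best
enrichment ratio, then term id. A term significant in three datasets with
p = 10⁻³ therefore outranks one significant in two at p = 10⁻⁸ —
replication across missions is deliberately worth more than depth in one.

`directionality_matrix()` supports the categorical displays (up / down /
not-significant / not-observed at a configurable −log10 p threshold,
default 1.3) used for microbiome taxa and similar cross-dataset panels.

## Kinase/phosphatase activity (substrate-set z-score)

`ksea()` scores an enzyme by its substrate sites:
z = (mean substrate log2FC − mean all log2FC) · √m / sd(all log2FC),
two-sided normal p, BH across enzymes, activity called at q < 0.05. This
is the standard kinase-substrate enrichment statistic; network-smoothed
variants of activity inference are out of scope, so the package commits to
the transparent closed form. Enzymes with fewer than `min_m = 3` quantified
substrates are skipped — below that the normal approximation is poor and a
single site dominates. The permutation null of z is standard normal to
Kolmogorov–Smirnov precision for m ≥ 10 (tested); strictly its variance is
(N − m)/(N − 1) under sampling without replacement, a < 1% deflation at
the tested sizes.

## Renal clinical chemistry

The derived indices use standard clinical definitions with every constant
exposed:

- **Fractional excretion** FE_x = 100·(U_x·P_cr)/(P_x·U_cr) (%), invariant
  to consistent unit rescaling of each analyte pair.
- **FE_Mg corrected**: plasma magnesium replaced by `uf_fraction`·P_Mg,
  default 0.7 — the conventional ultrafilterable (non-albumin-bound)
  fraction. The exact correction used in any given study's supplement may
  differ; 0.7 is declared as this package's default, not inferred.
- **TmP/GFR** via the Walton–Bijvoet piecewise approximation from
  TRP = 1 − FE_PO4/100: TRP·P_phos for TRP ≤ 0.86, else
  0.3·TRP/(1 − 0.8·TRP)·P_phos. The two branches disagree by ≈ 0.03·P_phos
  at the junction; the function is continuous elsewhere and monotone in
  P_phos (tested).
- **TTKG** = (U_K/P_K)/(U_osm/P_osm), dimensionless.
- **eGFR**: CKD-EPI 2021 creatinine equation for human panels (strictly
  decreasing in creatinine, tested); rodent panels get no eGFR — there is
  no validated rodent equation — and should report creatinine clearance.
- **Aldosterone:renin** only when both analytes share a sample time;
  missing analytes propagate as `NA`, never 0.

`compare_timepoints()` implements the repeated-measures convention:
one-way RM ANOVA across timepoints (subject as error stratum) plus paired
contrasts of each post-baseline timepoint against baseline, Bonferroni
corrected with family size = number of post-baseline timepoints. Subjects
missing a timepoint are dropped per analyte (complete-case RM). A constant
response returns p = 1 rather than 0/0. `compare_groups()` covers the
two-factor design (treatment × sex), reporting the treatment-factor p;
`normalize_to_control()` produces fold-of-control displays, guarding zero
control means with `NA`.

## Morphometry

All computations take physical units from the raster sidecar
(`pixel_size_um`), never from resolution; a resolution-doubling test
confirms densities are invariant.

`tubule_morphometry()` labels discrete tubules by connected components of
the object channel restricted to the cortex. Connectivity is 8 by default
and configurable to 4 — whether touching tubule profiles merge is exactly
this choice, so it is a reported parameter rather than a constant.
Components under `min_area_um2 = 100` are discarded as staining noise
(at 1 µm/px that is a 10×10 µm blob, far below any tubule profile).
Tubules clipped by the cortex border count with their in-cortex area. The
three endpoints — mean area per tubule, tubules per mm² of cortex, summed
tubule area as % of cortex — satisfy
percent = density × mean area × 10⁻⁴ identically, and this identity is
asserted on every output.

`dot_density()` divides pre-detected dot counts by physical region areas;
the summary "Average" is the simple arithmetic mean of the four anatomical
regions (cortex, OSOM, ISOM, IM), not area-weighted, so a small
high-density region (e.g. ISOM) is not drowned out. Dot *detection* is out
of scope — inputs are coordinates. `fractional_area()` and
`normalized_kidney_weight()` are the corresponding plain quotient
endpoints; `group_compare()` provides one-way ANOVA with Dunnett
many-to-one contrasts (several exposure groups vs control) or Student's
t-test for two groups.

## The synthetic study and what it does (not) show

The generators emulate the *result-level* structure of a multi-mission
integration study; all parameters live in `simulation_config()` and every
artefact is a deterministic function of (seed, artefact name), so adding a
generator never perturbs another's stream.

Defaults, chosen once as the study-scale conditions: 12 datasets — three
kidney transcriptomes and three kidney proteomes (the six core datasets)
across mouse/human/rat, plus phosphoproteome, methylome, plasma
metabolome, plasma transcriptome, exosome proteome and a faecal metagenome
of 40 taxa; a 2,000-gene universe with 70% measured per dataset; 12
planted consensus genes cycling k = 3, 4, 5 core datasets and alternating
sign, with |log2FC| ~ N(1.5, 0.4) and significant p drawn from a
Beta(0.5, 20) truncated below α = 0.05 (sharply sub-threshold, as only the
0.05 cut is specified by convention); 5% unmapped and 3% one-to-many
native symbols (never hitting planted genes, so recovery statements stay
exact); 50 gene-set terms of 10–80 members with 3 planted terms receiving
≥ 8 planted genes each; a 20-subject astronaut-style chemistry panel over
pre-flight, FD30, FD60, R+0, R+30 with log-normal noise (σ_log 0.2,
between-subject 0.1) and a ×3 in-flight urinary calcium shift returning to
baseline; and a 1 µm/px kidney mask of concentric cortex/OSOM/ISOM/IM
annuli (outer radius 260 µm) holding 12 non-overlapping elliptical tubules
of 200–900 µm² (axis ratio U(1,3), placed by rejection sampling with a
one-pixel clearance so 8-connected components never merge), 6% planted
interstitium, and ISH dot intensities of 800/600/2000/400 dots/mm²
mirroring an ISOM-dominant probe.

Planted genes are deliberately *clean*: in datasets they are not planted
into, their p-values are drawn above α. Real data have no such guarantee —
a truly regulated gene also drifts into significance elsewhere. The
generator therefore supports exact parameter-recovery statements
(P = k², planted terms ranked top-m, ×3 shifts detected at > 90% power
with null familywise error at the Bonferroni-conservative level) but does
not demonstrate robustness to correlated significance across datasets,
batch effects between missions, realistic histology texture, or raw-data
processing noise — all explicitly out of scope. A Monte-Carlo calibration
with no planted effects shows chance alone produces at most 3
direction-consistent significant core observations per gene over the
default universe, i.e. occasional |P| = 9 singles and nothing above.

## Problem sizes and numerical choices

The test suite runs the full default conditions where the claim depends on
them (parameter recovery over 100 seeds, chemistry power and null
calibration over 200 seeds, Poisson dot-count envelopes over 500 seeds)
and a 400-gene configuration for per-module unit tests; exhaustive oracles
(brute-force consensus enumeration, all-draws hypergeometric enumeration
up to N = 25, pairwise ranking comparison, graph-based component
labelling) back every non-trivial statistic. Ties in rankings are broken
by identifiers so output is total and reproducible; degenerate inputs
(no significant genes, constant responses, zero denominators, zero-area
regions) return flagged values or errors naming the offending quantity,
never silent zeros.

## Known limitations

Gene-level collapsing discards effect sizes (direction only); the product
score treats datasets as exchangeable and independent; the enrichment
ratio ignores term overlap structure; the substrate z-score assumes
site-level independence; the clinical formulas are spot-sample
approximations (TTKG additionally assumes osmolar equilibration in the
collecting duct); and the morphometry assumes masks are correct — mask
*generation* from images is upstream of this package.
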