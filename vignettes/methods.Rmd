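---
title: "Models and methods behind hopperqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hopperqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopperqtl)
```

`hopperqtl` maps brown planthopper (BPH) resistance loci in rice from
pooled sequencing of phenotypic extremes and then dissects the candidate
regions gene by gene. This vignette explains the models the package
implements, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices taken where the design was genuinely open.

## Damage phenotyping

Seedling damage is scored daily on the IRRI SES 1–9 scale and summarised
per line × BPH population × replicate as the area under the damage curve,

$$\mathrm{AUC} = \sum_{i=1}^{n-1} \frac{s_i + s_{i+1}}{2}\,\Delta t,$$

with $\Delta t$ = 1 day by default. A constant series $s$ over $n$ days
gives $s(n-1)\Delta t$, so a 5-day screen saturates at 36 score·days and an
8-day screen at 63; AUCs from screens of different length are therefore
never compared directly, only within an experiment. Replicates are averaged
to one AUC per line × population *before* the cross-population mean, so
every population gets equal weight regardless of replicate count; the
line-level summary is reported to one decimal, the convention damage tables
use. `select_extremes()` takes the `n` lowest-AUC lines as the resistant
pool and the `n` highest as the susceptible pool, breaking ties by line id
so membership is deterministic and order-invariant.

## The QTL-seq scan

At a biallelic site, the SNP-index of a pool is the donor-allele read
fraction `donor_depth / (ref_depth + donor_depth)`; a site with zero depth
is undefined (`NA`), never zero — this matters because low-coverage cells
would otherwise masquerade as fixed reference. The scan statistic is the
absolute difference between the susceptible and resistant pool,
$\Delta\mathrm{SNP} = |SI_S - SI_R| \in [0,1]$; the sign is never stored,
as the direction of subtraction is irrelevant after the absolute value.

Windows of 2 Mb advance in 10-kb steps from position 1 of each chromosome;
membership is half-open `[start, start + 2e6)` and the window statistic is
the unweighted mean of its sites' $\Delta$SNP values. Windows with fewer
than `min_snps = 3` informative sites are reported but masked (the exact
minimum is a package choice — too few sites make the mean meaningless).
Chromosomes shorter than the window collapse to a single truncated window.
Window counts depend on this anchoring convention and are reported but
never asserted against external totals.

### The null model and its thresholds

Significance comes from Monte-Carlo simulation under "no QTL": resample the
pool's lines from the population's expected genotype frequencies (inbred
lines: homozygous donor with probability equal to the genome-wide
donor-allele frequency — robust to the selection history of a
backcross-derived panel, and overridable), then draw reads binomially at
the stratum depth, and record the upper quantiles of the statistic.
Thresholds are computed per depth stratum (5× bins to 100×) and forced
non-increasing in depth by isotonic regression, since binomial read
variance shrinks with coverage.

Two statistics need two nulls. The *per-SNP* null (default,
`snps_per_window = 1`) describes a single site. The *window* null draws one
pool composition per replicate — the sites of a 2-Mb window in an
inbred-line population are in near-complete linkage, so their pooled allele
frequencies are essentially shared — but independent read noise per site,
and records the mean per-site $|\Delta \mathrm{SNP}|$. The distinction is
not cosmetic: the window mean averages read noise over ~80 sites, so using
per-SNP thresholds for windows is severely conservative (we measured an
empirical false-positive proportion of under 1% instead of the nominal 5%),
while the window-aware null restores calibration (≈5% of disjoint null
windows exceed the 95% threshold). Each window inherits the thresholds of
the depth stratum nearest its mean site depth. Overlapping significant
windows are merged into maximal regions, each reporting its peak window.

## The synthetic study generator

`sim_config()` defaults describe the study design the package targets: a
recipient × donor cross advanced by 3 backcrosses and 4 selfing
generations (BC₃F₅) to 105 inbred lines; two resistance QTLs at 6.5 and
16.3 Mb of one chromosome with effects 10 and 8 score·days (donor allele
reducing damage); pools of 19 resistant and 16 susceptible lines; ~20×
pooled coverage with a 6× retention floor downstream; three BPH
populations × 3 replicates × 5 scoring days; and a fast-neutron mutation
spectrum of 56% single-base substitutions, 23% deletions, 21% insertions.

Meioses place a Poisson number of crossovers (default 1.5 per 25-Mb
chromosome, roughly 1 crossover per 100 cM with no interference — the
standard no-interference model) uniformly along the chromosome. Neutral
expectations follow: donor genome fraction $(1/2)^{b+1}$ after $b$
backcrosses, heterozygosity halving per selfing generation; both are
verified by the test suite on QTL-free configurations.

QTLs are *planted* on this neutral background: each line independently
carries, with probability `qtl_freq = 0.5`, a homozygous donor fragment of
length uniform on 0.25–5.1 Mb containing the QTL. This mirrors what
extreme-pool mapping populations actually look like — lines carry compact
donor fragments at the resistance loci rather than marginal-frequency
alleles, the line AUC distribution is strongly multimodal, and the
resistant pool is nearly fixed for the donor allele at the QTLs (pool
SNP-indexes near 0 vs near 1). An earlier design that emulated
marker-assisted retention of both QTL intervals during backcrossing was
rejected: co-selecting two linked intervals preserves the entire span
between them, which fuses the two QTLs into one called region — the
opposite of the fragmented introgression structure such populations show.
Classic foreground selection over arbitrary intervals remains available via
`retained_intervals`, default off.

Phenotypes are reconstructed from the genetic value
$\mathrm{AUC}_g = \mathrm{baseline} - \sum_k \beta_k \cdot \mathrm{dosage}_k/2$
(baseline 32 score·days, a susceptible-recipient level for a 5-day screen)
as a linear daily ramp whose trapezoid AUC equals $\mathrm{AUC}_g$ exactly,
then perturbed with i.i.d. Gaussian noise per day (`noise_sd = 1.5`) and
clamped to [1, 9]. Clamping slightly biases lines near the scale ends —
real susceptible checks saturate at 9 the same way. Pool sequencing draws
per-site depth Poisson around `mean_depth` and donor reads binomially at
the pool's true allele frequency; a negative-binomial depth model was not
used because depth overdispersion does not change the scan's calibration
once thresholds are depth-stratified.

What the generator does **not** emulate: read-level artefacts (mapping
error, allelic bias), restriction-site dropout of ddRAD libraries,
epistasis, and genotype–environment interaction beyond per-population
scaling. Passing tests therefore demonstrate correctness of the statistical
machinery under clean sampling assumptions, not robustness to alignment or
library artefacts.

## Coding-effect annotation

Gene models carry explicit ordered CDS segments and the spliced CDS; the
CDS must be divisible by three (a hard error, since codon arithmetic is
meaningless otherwise) while a missing start codon only warns (partial
models are common). Genomic positions map to CDS coordinates by cumulative
segment offsets, counted from the 3′-most genomic base on minus-strand
genes. A substitution's amino-acid position is `ceiling(cds_pos / 3)` and
the protein length is `cds_length / 3 - 1` (stop codon excluded) — the only
convention consistent with coordinate pairs like 568/1527 → 190/508 and
201/216 → 67/71. Codons are translated with the standard genetic code,
*literally*: position-1 codons are not given initiator-Met treatment, which
is the variant-annotation convention (and the property suite checks
equivalence with a whole-CDS translation oracle configured accordingly).
Indels are `inframe_indel` when the length change is divisible by three
(a 21-bp insertion reports `7-aa-ins`), else `frameshift`. Sites outside
the CDS return a `non_coding` row rather than an error. Multiallelic VCF
records are skipped with a warning; the analysis is strictly biallelic.

Site filtering retains sites with site quality ≥ 15, base quality ≥ 20 and
total depth ≥ 6 in *every* pool — a site failing coverage in one pool is
dropped everywhere because $\Delta$SNP needs both sides.

## Haplotype patterns and the DRR

A haplotype pattern (HP) is the ordered allele vector over one gene's
markers. HP1 is reserved for the wild-type line's vector; remaining
patterns observed among complete lines are numbered by descending member
count with lexicographic tie-break — deterministic, though the specific
order beyond HP1 is a package convention. Heterozygous calls are a distinct
allele state and are never collapsed onto a homozygote. A line with missing
calls is assigned only if its non-missing alleles match exactly one mined
pattern; ambiguity leaves it unassigned rather than guessed.

The damage-reducing ratio of an HP is its mean AUC divided by the wild-type
HP's mean AUC within the same BPH population (cross-population DRRs are
never computed: infestation pressure differs). Values below 1 mean reduced
damage. `hp_assoc()` runs the one-way ANOVA across HPs, compares every
non-WT HP with the WT pattern on the pooled ANOVA variance, and reports DRR
(3 decimals) for HPs significant at α = 0.05.

## Association, letters and classification

Single-marker association is one-way ANOVA / simple linear regression;
PVE = 100·R², identical between the dosage-regression and factor-ANOVA
routes in the two-class case (checked to 1e-10), with ANOVA F equal to the
squared pooled-variance t. Raw P values are reported with `*` at 0.05 and
`**` at 0.001; no multiplicity correction is applied by default because the
associated tabular outputs report raw P — `p.adjust()` composes naturally
with the tidy outputs when wanted.

Tukey HSD pairwise tests are summarised by an insert-and-absorb compact
letter display: groups share a letter iff their pairwise test is
non-significant. With zero pooled variance the display degenerates to
"distinct means, distinct letters". Resistance classification is anchored
on two checks present in the display: sharing a letter with the resistant
check and none with the susceptible check gives R, the converse S,
everything else MR. The rule is a package definition (field tables pair
letter displays with R/MR/S labels but rarely state the cut); if the two
checks share a letter the assay cannot separate the classes and
classification is refused.

## Linkage disequilibrium and Gabriel blocks

Inbred lines are mostly homozygous, so haplotypes are counted directly
(two per hom/hom line, one resolved haplotype per single-het call); only
double heterozygotes need EM phase resolution, and with none present the EM
estimate equals direct counting exactly. From haplotype frequencies:
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$, $r^2 = D^2/(p_A p_a p_B p_b)$.
The D′ confidence interval is the 5th–95th percentile of the normalised
likelihood profile on a D′ grid (step 0.005) with allele frequencies held
at their estimates — the quantity Gabriel-style block calling consumes.
Blocks use the published defaults: a pair is "strong LD" when CI lower
≥ 0.70 and upper ≥ 0.98, "strong recombination" when upper < 0.90, and a
span of consecutive markers is a block when ≥ 95% of its informative pairs
are strong LD; maximal non-overlapping blocks are taken greedily, longest
first. Marker filters before LD: MAF > 0.05 and call rate > 0.50 (strict
inequalities), no Hardy–Weinberg filter (cut-off 0) — appropriate for
inbred panels where HWE is meaningless. Pairwise r² values are reported
unpruned; the chi-squared `p_value` column is a reporting aid, not part of
the block definition.

## Introgression painting

Each informative marker (polymorphic and homozygous in both parents) is
classified donor / recipient / heterozygous / unknown per line; maximal
runs of one class become segments with boundaries at the midpoint between
adjacent markers of different class and terminal boundaries on the outer
markers. The painted donor fraction (heterozygous segments counted half)
tracks the true genotype-matrix donor fraction with r > 0.95 at 84-marker
density in the test suite.

## Problem sizes and determinism

The default simulated genome is 3 chromosomes × 25 Mb with markers every
25 kb — large enough for ~2,300 windows per chromosome and realistic linkage
structure, small enough that a full simulate-to-call run takes about two
seconds. The test suite's recovery study uses 20 seeded replicates of the
default design with 2,000 null simulations per threshold; the null
calibration checks use 10,000. Every `simulate_*` function is a pure
function of its seed, `run_pipeline()` logs the seed in its manifest, and a
rerun with the same configuration reproduces byte-identical TSV outputs.

## Known limitations

- The scan's null model resamples pools independently; the slight negative
  correlation induced by drawing both pools from one finite population is
  ignored, making thresholds marginally conservative.
- Window thresholds assume within-window linkage is complete; on
  populations with much weaker LD (e.g. diversity panels) the window null
  would need the per-SNP limit instead.
- Effect annotation handles substitutions and simple indels against a
  single supplied transcript; splice-site, UTR and regulatory effects, and
  isoform choice, are out of scope.
- HP mining assumes essentially inbred material; it does not phase
  unphased heterozygous diploids or impute missing genotypes.
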