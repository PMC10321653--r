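---
title: "Models and methods in cwrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cwrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cwrpop` packages the population-genomic computations that recur in
conservation assessments of crop wild relatives: a small, partly clonal wild
taxon living alongside — and exchanging genes with — its cultivated
counterpart. The motivating system is the wild kumquat, where five
population groups are commonly distinguished (cultivated apomicts CULAPO,
cultivated sexuals CULSEX, wild apomicts WILDAPO, and two wild sexual
subpopulations WILDSEX1 and WILDSEX2), with a distantly related citrus
species as outgroup. This vignette explains each model, its assumptions and
tunable parameters, the design choices taken where the methodology was
genuinely open, and what the synthetic-data tests do and do not establish.

## The genotype matrix and its provenance

Every genomic statistic consumes a `geno_matrix`: biallelic SNPs with
diploid calls coded 0/1/2 (count of ALT alleles), optional phased
haplotypes, and per-site quality fields. `read_vcf()` keeps biallelic SNPs
only; multiallelic records and indels are out of scope by design, as is
genotype calling itself. `filter_sites()` applies the variation-map filter
with strict inequalities: QD > 2, QUAL > 40, MQ > 30, per-call depth
inside (2, 100), and a missing fraction strictly below 20%. A site with
QUAL exactly 40, or with exactly 20% missing calls, is dropped. Half-called
diploid genotypes (`./1`) are treated as missing — the least-assuming
reading of an ambiguous call.

Coordinates are 1-based inclusive at the VCF boundary and 0-based
half-open inside every windowed computation; a site at position $p$ belongs
to the window $[s, e)$ iff $s \le p - 1 < e$. Tests assert this boundary
convention directly.

`polarize()` sets the ancestral allele per site to the allele for which all
non-missing outgroup calls are homozygous, requiring at least one call and
no heterozygous or discordant outgroup genotype; anything else yields
`unknown` and the site is excluded from every derived-allele computation.
This conservative rule trades sites for protection against mispolarization
by incomplete lineage sorting in the outgroup.

## Diversity, differentiation and the site frequency spectrum

Per-site diversity uses unbiased heterozygosity $2 p q\, n/(n-1)$ from
allele counts, so phased data are not required. Windowed $\pi$ and
$D_{xy}$ divide summed per-site values by the window length in bp
(25-kb default); the alternative of normalizing by accessible sites only is
deliberately not the default, since variant-only normalization makes windows
with different missingness incomparable. All ratio statistics are
ratio-of-sums, so two adjacent windows recombine exactly — a property the
suite checks.

For $F_{st}$ the Hudson ratio-of-sums estimator is fixed:
$F_{st} = 1 - \sum \pi_{within} / \sum d_{xy}$ with the within term
averaging the two groups' per-site heterozygosities. It is robust at small
sample sizes and window-combinable; the estimator name is recorded in
output headers. Under the package's own Balding–Nichols cohort generator
the expected Hudson $F_{st}$ between two groups with drift coefficients
$F_A, F_B$ is their mean $(F_A + F_B)/2$ (within-group heterozygosity
$2pq(1 - \bar F)$ against between-group $2pq$), which the tests verify by
simulation.

Tajima's D uses the standard constants ($a_1, a_2, b_1, b_2, c_1, c_2,
e_1, e_2$) on 100-kb windows; a window with no segregating sites is
reported missing, never zero. With missing data the haplotype count $n$ is
taken as the median per-site allele number in the window.

The unfolded SFS bins derived-allele frequencies in $(0, 1]$ into ten
half-open clusters $(k/10, (k+1)/10]$; a frequency of exactly 0.1 falls in
the first bin. Sites with unknown ancestral state are dropped rather than
folded, because the deleterious-load accounting that consumes the spectrum
is defined on derived alleles only.

## Runs of homozygosity

`detect_roh()` reimplements the PLINK-style scan: 50-SNP sliding windows
are called homozygous at up to 3 heterozygous calls; a SNP is eligible when
at least 5% of its overlapping windows are homozygous (the upstream tool's
default hit rate, not stated in conservation-genomics write-ups that use
it); maximal eligible runs are split at inter-SNP gaps of 100 kb or more
and kept when they carry at least 50 SNPs, span strictly more than 500 kb,
and reach 10 SNPs per 100 kb. The three boundary cases — a 60-SNP run that
passes, a 40-SNP run that fails the SNP minimum, and a gap-split run whose
halves both fail — are hand-traced in the tests.

## Introgression statistics

Patterson's D works on derived-allele frequencies of a (P1, P2; P3, O)
quartet: ABBA $=(1-p_1)p_2p_3(1-p_4)$, BABA $=p_1(1-p_2)p_3(1-p_4)$,
$D = \sum(\mathrm{ABBA}-\mathrm{BABA}) / \sum(\mathrm{ABBA}+\mathrm{BABA})$.
Standard errors come from a delete-one block jackknife over contiguous 5-Mb
genomic blocks, mirroring common practice; the naive leave-one-block-out
recomputation is the test oracle. Windowed $f_d$ replaces P2 and P3 by
whichever has the higher derived frequency per site in the denominator and
is reported missing where the window's D is negative, where the statistic
is undefined by construction. Because negative-numerator windows are
censored, the genome-wide mean of $f_d$ has a small positive bias in finite
windows; with chromosome-scale windows on the synthetic cohorts it stays
within $\pm 0.02$ of zero under the null, and recovers planted 25% donor
fractions at about 0.20–0.21 — the well-known conservative behaviour of
$f_d$ when the donor is itself polymorphic.

The f-branch statistic assigns excess allele sharing to branches of a
rooted binary group tree: for branch $b$ and donor $C$ not descended from
$b$, $f_b(C)$ is the median over sister-clade tips $A$ of the minimum over
tips $B$ below $b$ of $\hat f(A, B, C, O)$, with the homozygous-donor
denominator (P2 := P3). That denominator choice avoids subsampling
haplotypes within groups; it is flagged in output metadata. Negative cell
estimates are floored at zero. Each cell's Z score jackknifes the quartet
that attains the cell value (the lower-median one when the median
interpolates), with significance reported at $p < 0.001$.

Species-specific markers (SSMs) are sites where the cultivated defining
groups are fixed for one allele, the wild reference group is fixed for the
other, per-group missingness is at most a tolerance (default zero), and
the outgroup is fully genotyped and monomorphic. The outgroup condition is
this package's concrete reading of "use the outgroup to remove unfixed
variants" as an ILS control; it is recorded as such rather than asserted
as the only reading. Per-individual introgression is then the diagnostic
allele dosage over genotyped SSMs divided by twice their number — a
deterministic, assumption-free estimator at fully diagnostic sites, used
here in place of supervised ancestry software; on planted-truth cohorts it
recovers a 0.25 fraction to within 0.02 over 20 seeds.

## Haplotype divergence and leaky sex

For phased cohorts, windowed p-distances between haplotypes (25-kb
windows) are standardized by the mean distance over all cohort haplotype
pairs in the window, making windows with different SNP density comparable;
the standardization is scale-free. The mean over *all* cohort pairs is
used as background (the pair set was not fixed by precedent; a
per-sample-pairs alternative is one flag away). A sample's outlier
haplotype ("Hap2") is designated by the caller, or auto-picked as the
haplotype with the larger genome-wide mean distance to a reference group —
an explicit stand-in for tree-based clustering, which is out of scope.
`fraction_exceeding()` uses a strict inequality; ties do not count as
exceeding.

## Deleterious load

Annotation scores classify substitutions as deleterious at score
$\le 0.05$ and tolerated above; the scores themselves are inputs (their
computation is out of scope). Per individual, the derived deleterious
allele count is heterozygous-site count plus twice the homozygous-derived
site count, over polarizable deleterious sites only; the identity
$n_{total} = n_{het} + 2 n_{hom}$ holds for every sample in every run, and
sites with unknown ancestral state are excluded and counted in the report.
Fixed ancestral alleles that might be deleterious are not counted — the
derived-allele convention is applied as stated.

## The synthetic cohort generator

The generator is first-class, tested code: every planted quantity is
recorded in a truth channel that downstream stages must recover.
Population structure follows a Balding–Nichols model — group allele
frequencies are Beta-distributed around ancestral frequencies drawn from a
neutral-like $1/p$ spectrum truncated to $[0.05, 0.95]$ — chosen over
coalescent simulation because it gives exact, dependency-free truth values
for drift and diagnostic sites. Apomictic groups draw their two haplotypes
from two further-drifted source pools, reproducing the elevated
heterozygosity of clonal lineages. The outgroup is fixed ancestral at 95%
of sites; elsewhere it is polymorphic so that polarization failure paths
are exercised. Diagnostic sites (400 of 4,000 by default) are fixed
derived in cultivated groups and fixed ancestral in wild groups and the
outgroup.

Introgression is planted by copying contiguous donor-frequency tracts into
target haplotypes; requested per-sample allele fractions are met exactly
up to tract granularity by truncating the final tract. Default drift
coefficients put both wild sexual groups at $F = 0.1332$, so their
expected pairwise Hudson $F_{st}$ equals the headline differentiation of
the emulated system; the other groups sit at field-plausible 0.06–0.08.
A star-shaped drift model cannot simultaneously reproduce every printed
pairwise $F_{st}$ of a hierarchically structured system (some pairs would
need negative drift), a known limitation.

What passing these tests shows: the statistics recover planted structure,
dosage and load exactly or within stated tolerances under an idealized
model with free recombination between sites, no linkage disequilibrium
decay, no mutation-rate heterogeneity, and no genotyping error. What they
do not show: robustness to reference bias, calling error, or realistic LD —
properties real resequencing data would stress.

The occurrence-table generator emits two 19-variable Gaussian clouds
(244 wild, 152 cultivated records by default) with a two-block bioclim-like
correlation structure — a 10-variable temperature-like block, a 6-variable
precipitation-like block, three independent variables — and a cultivated
mean shift along the first block. The block correlations and shift are
calibrated so that, at the population level, the pooled standardized PCA
explains 47.5%/20.6% on its first two components and the directional 95%
niche-region overlap equals 58%, the published summaries of the system
being emulated. Finite samples estimate covariances in 19 dimensions
noisily, so sample-level plug-in overlap runs several points below the
population value — an estimator property, not a calibration error; both
quantities are reported.

## Forward Wright–Fisher simulation

`run_sim()` contrasts three arms under a bottleneck demography: an
ancestral population of $N = 1{,}000$ diploids burns in for $10N$
generations, contracts to $0.25N$ at 10,000 generations before present,
and at 2,000 generations before present splits into subpopulations of
$0.1N$ that either self (rate 1) or outcross (rate 0); the standard
neutral model (SNM) arm keeps constant $N$ throughout. Mutation and
recombination rates default to $\mu = 2.2\times10^{-8}$ and
$r = 1.0\times10^{-7}$ per bp per generation on a 1-Mb sequence. Under the
deleterious scenario, new exonic mutations draw $|s|$ from a gamma DFE
(shape 0.186, mean 0.01 — stand-in defaults, configurable) with dominance
$h = 0$; fitness is multiplicative across sites and applied as viability
selection on offspring. The exon mask is synthetic (exponential exon
lengths, 25% coverage, mean 300 bp), regenerated deterministically per
run — a documented substitution for a reference-genome exon table that is
not shipped. One caption of the emulated design reads its burn-in as 100k
generations where $10N$ gives 10,000; `burn_in` is therefore an explicit
parameter defaulting to $10N$, the internally consistent reading.

The engine is a sparse-haplotype C++ core using R's RNG, so results are
byte-identical under `(cfg, seed)`. Closed-form checks: neutral
constant-$N$ diversity matches $4N\mu$ within 15% over 20 replicates, and
complete selfing halves effective size ($\pi$ ratio $0.5 \pm 0.1$),
reached after several $2N_e$ generations of selfing. The headline
contrast — $\pi(\text{selfing}) < \pi(\text{outcrossing}) <
\pi(\text{SNM})$ with paired rank tests — is run at a reduced scale of
$N = 500$ and 30 replicates, a problem size chosen so the whole suite
stays interactive while the ordering is decisive (observed p-values are
below $10^{-4}$).

## Niche overlap

The niche region of a label is the central $\alpha$-probability ellipsoid
of its fitted multivariate normal ($\alpha = 0.95$ default); overlap
$A \to B$ is the probability that a draw from A's distribution lands in
B's region, estimated by Monte Carlo. Overlap is directional and both
directions are always reported. The default estimator is Bayesian —
normal–inverse-Wishart posterior draws under the noninformative prior
$|\Sigma|^{-(d+1)/2}$, 1,000 draws by default, reporting the posterior
mean and central 95% interval — mirroring the convention of the method
this module follows; a deterministic plug-in mode exists for tests. In
$d = 2$ with isotropic covariances the overlap has a noncentral
chi-square closed form, which serves as the Monte Carlo oracle; the MC
standard error obeys the binomial bound $0.5/\sqrt{\text{draws}}$.

## Command-line surface

Every stage is callable through `cwr_cli()` (and the thin `inst/cli/cwrpop`
wrapper): one global `--seed` from which stage seeds derive, outputs
confined to the `--out` directory, and a `manifest.json` per run recording
the subcommand, options, input checksums, seed and package version. The
`all` subcommand runs the synthetic end-to-end demo.

## Numerical and degenerate-input conventions

Zero-denominator windows ($d_{xy} = 0$, $f_d$ denominator 0, window mean
distance 0) yield missing values, never infinities. The D statistic raises
an error when no informative site exists. Samples without genotyped SSMs
are skipped with a warning rather than reported as zero. Monte Carlo
estimators take explicit seeds. Problem sizes in the test suite (cohorts
of 2,000–4,000 sites on two 25-Mb chromosomes; 20–50 seeds per
calibration; $N = 300$–500 simulations) are the package's documented
defaults for its own validation and keep the full suite within an
interactive development cycle.
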