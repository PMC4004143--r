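---
title: "Pooled-sequencing population genomics with poolscan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing population genomics with poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem this package addresses

Pool-seq resequencing — sequencing one DNA pool per population instead of
individually barcoded genotypes — is the cheapest way to survey allele
frequencies across many populations. The design this package implements
comes from population genomics of the western corn rootworm
(*Diabrotica virgifera virgifera*), a major maize pest: 26 populations,
each a pool of 5 diploid beetles (10 haploid chromosome sets), shotgun
sequenced to roughly 20–30X and aligned to a transcriptome assembly, so
that every assembled unigene is one locus. The questions are the classic
ones: how much diversity does each population carry ($\pi$), how divergent
are populations in absolute terms ($\pi_{xy}$) and relative terms
($F_{ST}$), which loci are outliers between phenotype-defined groups
(Bt-toxin response, diapause), is there isolation by distance, and which
SNPs can be turned into cheap CAPS genotyping assays?

All statistics operate on per-site base-count profiles
$(b_A, b_C, b_G, b_T)$ — filtered read counts per population, unigene and
position — so the package is agnostic about the upstream aligner: profiles
can be piled up from SAM records (`reads_to_profiles()`), read from a
sync-style tab file (`read_sync()`), or simulated with known ground truth
(`simulate_metapopulation()`).

## Site filters

Three rules precede every statistic (`filter_config()`, applied by
`filter_sites()`):

* coverage at least 5 (reliable frequency estimates) and at most 40
  (deeper sites are suspected collapsed paralogs or copy-number variants;
  the rule is strictly-greater-than, so a site at exactly 40 is kept);
* a minimum count $b$ (default 2) for any variant to be believed: bases
  with a lower non-zero count are zeroed and frequencies recomputed, so
  singleton sequencing errors never register as alleles;
* at the read level, mapping quality at least 25, base quality at least
  30, and removal of any soft-clipped read — when genomic reads are
  aligned to transcripts, intron boundaries surface as soft-clips, and
  those alignments misplace bases.

One subtlety is ordering: zeroing can push a site's usable coverage below
the minimum. We drop such sites, which reads the 5X rule as applying to
usable (post minimum-count) bases and makes `filter_sites()` idempotent —
re-filtering filtered output is the identity, a property the test suite
enforces. The depth rule is likewise applied to post-mapping-quality-filter
depth, since the profile is built only from reads that survived the
read-level rules.

## Within-pool diversity

Pool-seq reads are a two-stage sample: $M$ reads drawn with replacement
from a pool of $n$ chromosomes, which is itself a draw from the
population. The per-site estimator is expected heterozygosity with both
finite-sample corrections:

$$\hat\pi = \Bigl(1 - \sum_a f_a^2\Bigr)\,\frac{M}{M-1}\,\frac{n}{n-1},$$

with $f_a$ the post-zeroing base frequencies. Taking expectations through
both sampling stages shows each correction removes one stage's downward
bias, so $\mathbb{E}[\hat\pi]$ equals the population expected
heterozygosity; the test suite verifies this empirically against a
Monte-Carlo oracle that simulates pool-and-read sampling directly, at
$b = 1$. The default $b = 2$ truncates genuine rare variants along with
errors and therefore carries a small known downward bias; that is the
intended trade-off at 20–30X, where singletons are dominated by error.
Monomorphic sites contribute 0 but count toward $n_\text{sites}$:
$\pi$ is per-site over available sites, not over SNPs, which is what makes
per-population means of order 0.006 comparable across unigenes.

Per-unigene values above 0.15 (strict) are set aside by
`drop_pi_outlier_unigenes()` before any summary. Values that extreme are
not biologically plausible here and in practice mark paralogous alignment
collapse; on clean simulated data fewer than 1% of unigenes trip the rule.
`ne_estimate()` provides the standard neutral-equilibrium back-of-envelope
$N_e \approx \pi / 4\mu$.

## Absolute divergence: $\pi_{xy}$

$F_{ST}$ is relative to total diversity, so it conflates divergence with
within-population diversity. The complementary absolute statistic used
here is the average per-site expected heterozygosity among gametic unions
between populations $x$ and $y$:

$$\pi_{xy} = \frac{1}{n}\sum_{i=1}^{n}\Bigl(1 - \sum_{j} x_{ij}\,y_{ij}\Bigr),$$

an allele-frequency estimator of Nei's $d_{XY}$. Because it is linear in
each population's frequencies, it needs no pooled-sampling bias
correction. Only sites passing filters in *both* populations enter $n$.
When groups of populations are compared, members are first combined by the
**unweighted** mean of their frequency vectors (`group_profile()`) —
deliberately not coverage-weighted, so a deeply sequenced pool cannot
dominate the group profile.

## Relative divergence: per-unigene $F_{ST}$

`fst_unigene()` computes the classical
$F_{ST} = (\pi_T - \pi_S)/\pi_T$ with $\pi_S$ the mean of the two
within-population per-site diversities and $\pi_T$ the diversity of the
site-wise mean frequency profile, aggregated over a unigene's shared sites
as a ratio of sums (mirroring the windowed classical estimator of
established Pool-seq tooling, and avoiding single-site ratio instability).
With `corrected = TRUE` the within terms carry the $M/(M-1)\cdot n/(n-1)$
corrections and the total term uses the combined read depth and combined
chromosome count. Negative corrected values are reported, not clamped, so
genome-wide means and bootstrap intervals remain unbiased summaries.

Two properties of this estimator are worth stating plainly. First, under
an exchangeable null it is calibrated around zero once corrected (the
simulator tests verify this). Second, for a *pair* of demes under the
Balding–Nichols model with differentiation $F$, its expectation is not $F$
but approximately $(F/2)/(1 - F/2)$: with two demes
$\mathbb{E}[\pi_S] = H(1-F)$ and $\mathbb{E}[\pi_T] = H(1-F/2)$, because
the mean-frequency profile of two demes still tracks half of the
between-deme variance. Recovering $F$ itself would require a
deme-sampling correction of the Weir–Cockerham type, which the classical
pooled estimator deliberately omits. At the low differentiation typical of
this study system ($F \approx 0.05$) the distinction is a couple of
hundredths; at $F = 0.2$ it is material, and the regression-band test on
Balding–Nichols recovery documents exactly this behaviour (the pair
estimator plateaus near $F/(2-F)$). Consumers who need an unbiased
estimate of the Balding–Nichols $F$ from pairwise values can invert the
relationship; the package reports the classical statistic.

`pairwise_matrix()` assembles genome-wide values as unweighted means over
unigenes (the unit of analysis throughout), giving the
$26 \times 26$ matrices ($325$ pairs) used downstream, and
`bootstrap_mean_ci()` provides percentile bootstrap intervals over
unigenes for genome-wide means.

## The permutation outlier scan

`outlier_scan()` compares two phenotype-defined groups (e.g. 6 high-
versus 5 low-response populations) per unigene: the observed
group-combined statistic ($\pi_{xy}$ or $F_{ST}$ between unweighted group
mean profiles) is ranked against the same statistic under permuted
population labels. With group sizes $(k, m)$ there are
$\binom{k+m}{m}$ distinct label assignments; all are enumerated when that
count is at most `enumeration_cap` (462 for the 6/5 design), otherwise
`n_monte_carlo` distinct assignments are sampled uniformly without
replacement (1,000 for the 21/5 diapause design, where
$\binom{26}{5} = 65{,}780$). Unigenes with fewer than 50 shared filtered
sites are excluded — below that, single-site noise dominates the
per-unigene statistic.

Numerical conventions, chosen once and tested:

* **nearest-rank percentile**: the threshold is the
  $\lceil q K \rceil$-th order statistic of the $K$ permuted values —
  exact and unambiguous for $K = 462$ or $1{,}000$;
* the observed assignment is **not excluded** from the enumerated null
  (it is one of the 462), which is why the best attainable significance
  is $1/462$ or $1/1{,}000$;
* outlier calls use **strict** inequality. A consequence worth knowing:
  with $K = 462$ and the observed value included, `observed > threshold`
  holds exactly when the observed value ranks in the top 4, so the exact
  null flag probability is $4/462 \approx 0.87\%$, slightly below the
  nominal 1%. The calibration tests check against this exact rate, not
  the nominal one. (For small designs where
  $\lceil qK\rceil = K$ — e.g. 4 + 4 populations, $K = 70$ — nothing can
  ever be flagged at the 99th percentile; the scan needs a design with
  enough assignments, which the 6/5 and 21/5 contrasts provide.)
* the site set per unigene is fixed across permutations (sites passing
  filters in *all* populations of the comparison), so permuted and
  observed statistics are computed on identical data;
* no multiple-testing correction, by design: the scan produces inclusive,
  exploratory candidate lists, and output rows carry that caveat.

## The synthetic-data generator

`simulate_metapopulation()` is first-class, tested code, and every
downstream stage is validated against it. Its generative model per
segregating site: ancestral minor-allele frequency
$p \sim U(0.05, 0.5)$; population frequencies from the Balding–Nichols
Beta$\bigl(p(1-F)/F,\ (1-p)(1-F)/F\bigr)$ (degenerate at $p$ when
$F = 0$); pool allele counts Binomial$(n, p_\text{pop})$; read depth
Poisson($\lambda$); reads sampling the pool with replacement; uniform
substitution errors at rate $e$. Sites are biallelic with an ordered pair
of distinct bases drawn uniformly — the statistics operate on 4-base
profiles, and biallelic truth keeps recovery checks exact.
`inject_group_divergence()` regenerates a chosen fraction of unigenes
with between-group divergence at level `outlier_F`, recording ground
truth for power analyses.

Defaults are the study conditions: 26 populations, pools of 10
chromosomes, mean coverage 25 (the reported 20–30X), background
$F = 0.05$ (the magnitude of the observed genome-wide mean pairwise
$F_{ST}$), SNP density 2.5% of sites (about 530k SNPs over a ~20 Mb
transcriptome), and error rate $10^{-3}$ (residual error after the Q30
base filter). The coverage law is plain Poisson — the simplest
overdispersion-free choice consistent with "approximately 20–30X" — and
sites are independent: no linkage, no indels, no read pairs, no quality
strings. Passing tests therefore demonstrate correct behaviour under the
sampling model, not robustness to alignment artifacts, LD between sites,
or overdispersed coverage, which real pooled data certainly contain (the
high-$\pi$ outlier rule exists precisely because real alignments produce
artifacts the simulator does not).

## Structure analyses

* **PCoA** (`pcoa()`): classical multidimensional scaling — Gower
  double-centering of squared distances and eigendecomposition, delegated
  to `stats::cmdscale` — applied directly to the $\pi_{xy}$ (or $F_{ST}$)
  matrix treated as a distance. Axes are ordered by eigenvalue and signs
  fixed so each axis's largest-magnitude coordinate is positive (PCoA
  signs are otherwise arbitrary, and fixed signs make runs comparable).
* **Rarefaction** (`rarefaction()`): populations are added in 100 random
  orders; each step records the new SNPs contributed; the envelope is the
  2.5/97.5 percentile across orders rather than a normal approximation.
  The step sums are conserved (they always total the SNP union), which is
  tested for every sampled order.
* **Isolation by distance** (`ibd()`): linearized
  $F_{ST}/(1-F_{ST})$ regressed on $\ln(\text{km})$ of great-circle
  distance (haversine, spherical Earth $R = 6371$ km — the populations'
  locations are approximate, so sub-km geodesy would be false precision),
  with a one-sided Mantel test that permutes population labels jointly
  over rows and columns. When $n! \le$ the permutation budget the test
  enumerates all label permutations and the p-value is exact (the
  identity permutation counts); otherwise
  $p = (1 + \#\{r_\text{perm} \ge r_\text{obs}\})/(1 + n_\text{perm})$.
  The packaged 26-population table carries no coordinates because the
  source study published only approximate collection locations; IBD
  examples and tests use synthetic coordinates generated in code.

## CAPS marker design

`screen_snps()` emits a candidate whenever a SNP's two flanking
haplotypes differ in recognition-site count for an enzyme.
`count_sites()` matches IUPAC patterns (via Biostrings) on both strands,
maps reverse-strand matches to forward coordinates, counts palindromic
patterns once per position, and never lets `N` match — neither in the
sequence nor via a pattern `N`. A small vetted enzyme table ships with
the package (RsaI GT^AC, EcoRI G^AATTC, AluI AG^CT, HinfI G^ANTC, TaqI
T^CGA); user tables with the same columns are accepted, since marker
projects typically screen a full commercial database. The flank window
defaults to ±100 bp (within typical amplicon design) and is configurable
because validated markers' amplicon layouts vary.

## Assembly completeness

`ortholog_hit_ratio()` divides the query's non-gap aligned characters by
the subject ortholog's full length: near 0 means fragmented assembly,
near 1 fully assembled, above 1 (reported, flagged by common sense rather
than clamping) a query longer than its ortholog. When a query has several
hits, the best (lowest e-value, then highest bit score) is used.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible
given it; `run_all()` fans one master seed out to fixed per-stage child
seeds so stages stay independently reproducible. The test suite and the
acceptance script exercise the estimators at sizes chosen to make the
statistical assertions sharp while staying desk-scale: estimator recovery
on ~2 × 10^4 simulated sites (3-standard-error bands), Balding–Nichols
$F_{ST}$ recovery at 2,000 loci, and scan calibration on 2,000 unigenes
of 60 sites across 11 populations under the exact 462-assignment null
(3-binomial-SD band around the exact $4/462$ rate, power check on 5%
injected outliers at `outlier_F = 0.5`).

## Known limitations

* The per-unigene pairwise $F_{ST}$ estimates the classical statistic,
  whose two-deme expectation is $(F/2)/(1-F/2)$ under Balding–Nichols,
  as discussed above.
* The simulator omits LD, indels, overdispersed coverage and alignment
  artifacts; conclusions about robustness to those must come from real
  data.
* The scan's null assumes exchangeable populations within the comparison;
  hierarchical structure between groups inflates the null and the scan
  makes no attempt to model it (by design — the output is an exploratory
  candidate list).
* `read_snp_table()` implements this package's reading of the deposited
  genotype-table dialect (comma-separated, dash for missing, unigene
  sequence on first use); deposits in other dialects need reshaping.
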