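---
title: "Ploidy inference and clonality testing for mixed-ploidy ddRAD cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy inference and clonality testing for mixed-ploidy ddRAD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramet)
```

## The analysis problem

Whether a ring of grass around a bare desert circle is one clonal plant is
a genotype-identity question: ramets of one genet carry the same
multilocus genotype. Answering it from reduced-representation sequencing
is complicated by two features of wild grass cohorts. First, ploidy is
mixed — diploids, allotetraploids and occasional octoploids occur side by
side, sometimes within one circle. Second, in an allopolyploid the two
(or four) subgenomes carry fixed differences at homoeologous loci, so a
tetraploid looks "heterozygous" at thousands of sites where it is in fact
homozygous within each subgenome. Any analysis that takes diploid genotype
calls at face value, or that feeds mixed-ploidy genotypes to phylogenetic
models, will be misled. `ramet` therefore (i) infers ploidy per sample
before any comparison, (ii) recodes genotypes into a ternary code that is
agnostic to the source of intermediate allele balance, and (iii) expresses
relatedness through distances and ranks rather than model-based genotypes.

## Ploidy from allele balance and haplotype counts

For sample $j$ the allele-balance spectrum is the set of
$f = \mathrm{alt}/(\mathrm{alt}+\mathrm{ref})$ over sites with total depth
$\ge$ `min_depth` (default 11 reads) and $0.05 < f < 0.95$. The bounds
remove homozygous sites, whose $f$ sits near the error rate or its
complement, so the retained sites are those where the sample carries both
alleles; at a variant present on $d$ of $k$ haplotypes, $f$ concentrates
near $d/k$. Cohorts dominated by single-copy variants therefore peak at
$1/2$, $1/4$ or $1/8$ by ploidy.

The peak is located as the mode of a fixed-width histogram (bin width
0.02, bins $(0, 0.02], (0.02, 0.04], \dots$), returned as the modal bin
centre, with ties resolved toward the lower bin so that the symmetric
simplex/triplex pair of tetraploid peaks (0.25/0.75) resolves to the
sub-0.5 peak. A fixed-width histogram was chosen over kernel density
estimation because it is deterministic and has no bandwidth selection; the
price is a one-bin quantisation of the answer (a pure 0.5 peak reports
0.49, since 0.5 is a bin edge), well inside the tolerance of the
nearest-candidate rule. The mode is matched to the nearest of
$\{0.5, 0.25, 0.125\}$; a mode above 0.7, or one equidistant between
candidates, is flagged ambiguous.

Independently, samples with more than 1000 RAD loci carrying three or more
distinct haplotypes are called polyploid — a diploid has two haplotypes
per locus, so abundant third haplotypes indicate extra genome copies. The
1000-locus threshold is absolute (not scaled to library size) and
overridable; the classifier cannot separate tetraploid from octoploid and
flags its calls accordingly. When both lines of evidence agree on
diploid-versus-polyploid, the spectrum call (which resolves 4n from 8n) is
reported; a disagreement keeps the spectrum call with a `discordant`
flag, except that an `ambiguous` spectrum defers to the haplotype count.

## Ternary recoding and distances

With $\tau$ = `het_threshold` (default 0.05), a cell is coded 0 when
$f \le \tau$, 1 when $f \ge 1-\tau$, and 0.5 otherwise. The inequalities
are strict for the heterozygous band: a site needs *more than* 5% of
reads from each allele. Sites are kept only when every analysed sample
reaches the depth floor, so the recoded matrix has no missing cells by
construction; a `min_individuals_variant` option (set to 2 in robustness
runs, together with $\tau = 0.10$) additionally drops sites whose
non-reference code occurs in fewer samples than required. We read
"present in at least two individuals" as a non-reference code (0.5 or 1)
in at least two samples; the alternative reading (ALT allele observed in
two samples) differs only for sites recoded 1, and the option's purpose —
excluding singleton artefacts — is served either way. The stringent
"conserved subset" re-analysis is realised as a per-site flag rather than
an actual cross-species mapping, preserving the two-tier
permissive/stringent structure while keeping the pipeline self-contained.

Genetic distance is the raw Euclidean distance between recoded columns
(a per-site-normalised variant is available by flag), clustered with
`hclust`; complete linkage is the default because the original analysis
names only the clustering function, whose default it is, and single and
average linkage are exposed for robustness checks (the brute-force oracle
tests cover all three). Clone pairs are sample pairs at distance
$\le \varepsilon$; the default $\varepsilon = 0$ is appropriate for
error-free data, and for noisy data the report suggests (but never
silently applies) the 1st percentile of the between-circle pairwise
distance distribution.

## Clonality statistics

Per circle with at least two samples, the minimum intra-circle distance;
per unordered circle pair, the minimum cross-pair distance. Under
clonality the within-minima collapse to zero. The two sets of minima are
compared by a two-sided Wilcoxon rank-sum test (exact null when
$\min(n, m) \le 10$ without ties, otherwise the normal approximation with
tie and continuity correction; the path taken is reported). One caveat is
intrinsic to minimum statistics and worth stating plainly: a
between-circle minimum aggregates $s^2$ sample pairs while a within-circle
minimum aggregates $\binom{s}{2}$, so with $s = 3$ samples per circle the
between minima are stochastically smaller even for completely unstructured
data, and the two-sided test rejects far above its nominal level under
that null (we measured ~88% rejection at 15 circles × 3 samples). The
test is therefore evidence *against* clonality only in one direction —
within-minima at zero and below the between-minima — and its type-I
calibration is verified on identically distributed groups, not on the
min-aggregated pipeline output. The distance-decay analysis is an
ordinary least-squares line of the between-circle minimum genetic distance
on the Euclidean distance between circle centres (planar metres), with
Pearson $r$; a constant genetic distance yields slope 0 and a degenerate
flag, and zero spatial variance is an error.

## Inbreeding

On the diploid subset, with recoded values $\in \{0, 0.5, 1\}$ over $L$
sites polymorphic in that subset, per-sample
$F = (O_{hom} - E_{hom}) / (L - E_{hom})$, where $O_{hom}$ counts codes 0
or 1 and $E_{hom} = \sum_s (1 - 2\hat p_s \hat q_s \cdot 2k/(2k-1))$ with
$\hat p_s$ the subset allele frequency (0.5 codes counting half) and
$2k/(2k-1)$ the small-sample correction on the $2k$ allele copies carried
by $k$ diploid samples — the same estimator standard VCF tooling reports
for hard calls. The interval for the mean is a $t$-interval over the $k$
per-sample values (a percentile bootstrap is available by flag); this is
the simplest defensible interval for a mean over samples, and the two
agree closely on simulated data. Polyploids are excluded because their
0.5 codes conflate heterozygosity with homoeologous divergence.

## What the generator simulates — and what it does not

`simulate_population()` draws, per site, a population ALT frequency from a
truncated power-law site-frequency spectrum (density $\propto p^{-3/2}$ on
$(0.05, 0.95)$ by default). Diploid genets draw dosage with inbreeding
$F$ ($P(\mathrm{het}) = 2pq(1-F)$); an allotetraploid is two independent
diploid subgenomes and an octoploid four, except at two classes of
diagnostic sites: *homoeolog-fixed* sites (default 5% of sites), where
half the subgenomes are fixed ALT and half fixed REF so every polyploid
shows allele balance 0.5, and *cytotype-fixed* sites (default 5%), where
all polyploid subgenomes are fixed ALT while diploids segregate normally.
The second class reflects the fixed divergence of a polyploid lineage
from the diploid gene pool; it is what makes cytotypes separate in
recoded-genotype space, because 0.5 codes alone cannot — 0.5 is central
in the ternary metric, so a tetraploid rich in 0.5 codes is on average
*closer* to each diploid than two diploids are to each other. Being fixed
near balance 1, cytotype-fixed sites are excluded from the ploidy
spectrum by its 0.95 bound and do not disturb the mode.

Read depth per cell is negative binomial (mean `mean_depth`, default 30;
dispersion `depth_dispersion`, default 5, i.e. CV ≈ 0.47), the standard
overdispersed model for RAD coverage. The overdispersion matters
numerically as well as biologically: with near-constant depth $n$, the
observed fractions $k/n$ live on a lattice with spacing $1/n > 0.02$, and
a fixed-width histogram develops comb artifacts — the bin left of 0.5
always captures the central binomial atom, while the 0.25 peak's atoms
scatter over neighbouring bins — that can relocate the mode. Depth
diversity spreads the lattice and restores the histogram to its expected
shape; a `"poisson"` depth model remains available. Sequencing error
flips each read's allele with probability `error_rate` (default 0.005),
implemented exactly as a binomial draw at
$q' = q(1-e) + (1-q)e$.

Defaults mirror the targeted study design: 15 circles × 3 samples, two
"near" samples and one "far" sample per circle, centres on a jittered
grid at least 10 m apart within a ~1 ha square, a ploidy mix of
0.600/0.375/0.025 for 2n/4n/8n (the observed cohort composition, to the
nearest few percent), 5000 biallelic sites, and haplotype-count summaries
with ~63,000 loci per sample in which polyploids carry ≥ 2000 loci with
three or more haplotypes and diploids a ten-fold lower count. Clonal
circles copy one genet's genotype and ploidy to all their samples. A
`fixed_dosage` option overrides the population draw with a constant
dosage per sample (capped at the ploidy) and exists for spectrum
calibration: dosage 1 gives purely heterozygous diploids, simplex
tetraploids and 1-of-8 octoploids.

The generator does not simulate raw reads, restriction-site or allele
dropout, linkage (sites are independent), autopolyploids (the polyploids
are allopolyploids, as the homoeolog evidence in the target system
indicates), or spatial genetic structure (genets are panmictic, so the
expected distance-decay slope is 0). Haplotype-count summaries are drawn
at the summary level rather than derived from simulated RAD loci, because
the classifier consumes only the counts. Passing tests on these
simulations therefore validate the estimators under known truth; they do
not certify behaviour under dropout, linkage or contamination, which real
libraries have.

## Numerical choices and degenerate inputs

* Depth filters are inclusive ($\ge$ 11 reads), following the
  methods-text reading of the threshold; every filter is overridable.
* The haplotype-count rule is strictly `> 1000`; a sample at exactly 1000
  is diploid.
* Recoding boundaries go to the homozygous codes ($f = \tau$ is
  homozygous).
* Histogram ties take the lower bin; `which.max` makes this
  deterministic.
* Merge ties in `hclust` follow its deterministic input-order rule; the
  oracle tests use continuous random matrices where ties have probability
  zero.
* Empty spectra, zero surviving sites (the failing filter is named),
  monomorphic site sets, circles with fewer than two samples, non-finite
  distances and zero spatial variance all raise errors or warnings rather
  than propagating silently.
* Spectrum-calibration checks use cohorts of 30,000 sites so that the
  modal bin's expected lead (~9 sites per 1000 retained over the nearest
  out-of-tolerance bin) stands several standard deviations above
  multinomial noise; the cohort-level validation uses 20 replicate
  simulations of 30 samples at 5000 sites, and inbreeding recovery uses
  20 samples at 10,000 sites with $F \in \{0, 0.2\}$. The octoploid
  calibration cohort uses mean depth 40, because at depth 30 the 0.125
  peak spans bins whose lattice atoms (e.g. $f = 1/5$ fed by two dosage
  classes at low depth) jitter the mode by more than one bin.

## Known limitations

The ploidy caller assumes the spectrum is dominated by single-copy
variants; heavily homoeolog-dominated tetraploid libraries would shift
mass toward 0.5 and require the haplotype-count evidence to carry the
call. The clone threshold $\varepsilon = 0$ is exact only for error-free
data — at low depth, read sampling alone can flip a marginal cell across
the 5% boundary (at depth 11 a simplex tetraploid site drops all ALT
reads with probability $0.75^{11} \approx 0.04$), which is why the
clone-detection validation uses deep (60×) error-free diploid cohorts and
why real-data clone calling should use the reported between-circle
percentile instead of 0. The rank-sum comparison of minima is
directional evidence, as discussed above, not a calibrated two-sided
test. And the inbreeding estimator inherits a small downward bias from
sequencing error (hom cells misread as het), of order
$-e \cdot \Pr(\mathrm{hom}) / \overline{2pq}$ — about $-0.02$ at the
default error rate — which is inside the reported confidence intervals at
realistic sample sizes.
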