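---
title: "Methods: host-genetic association analysis of gut microbiome composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-genetic association analysis of gut microbiome composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgwas)
```

## The problem

Gut bacterial relative abundances are quantitative traits: after
sequencing-depth normalization each taxon's abundance varies across hosts,
and part of that variation may be attributable to host genotype. In a
founder population whose members live and eat communally, environmental
variance is unusually small, which makes even modest genetic effects
detectable — but everyone is related, so naive regression of abundance on
genotype is confounded by family structure. `microgwas` implements the
full analysis chain for this setting:

1. taxon count preprocessing (depth subsampling, replicate combination,
   prevalence filtering, rank-based inverse normal transformation,
   correlated-taxon pruning, season averaging, alpha diversity);
2. genotype quality control and a genomic relationship (kinship) matrix;
3. a univariate linear mixed model (LMM) with per-predictor
   likelihood-ratio tests, used both for covariate scans (age, sex) and
   per-SNP genome-wide scans;
4. REML variance components for chip heritability (PVE) with standard
   errors;
5. permutation tests for the overlap between heritable taxa and taxa with
   genome-wide hits;
6. candidate-tissue identification by fold enrichment of top GWAS SNPs in
   DNase-hypersensitivity (open chromatin) peaks, calibrated by full
   phenotype-permutation GWAS.

A synthetic-data module generates family-structured studies with known
ground truth so that every stage can be validated quantitatively.

## The mixed model

For a trait vector $y$ (one taxon's normalized abundance, residualized on
covariates), the model is

$$y \sim N\!\left(X\beta,\; \sigma_g^2 K + \sigma_e^2 I\right),$$

where $K$ is the kinship matrix. With the eigendecomposition $K = U D U^\top$
the rotated data $U^\top y$ have a diagonal covariance
$\sigma_e^2(\lambda D + I)$, $\lambda = \sigma_g^2/\sigma_e^2$, so for any
$\lambda$ the fixed effects and $\sigma_e^2$ have closed-form (weighted
least squares) profiles. The one-dimensional profiled likelihood in
$\log_{10}\lambda$ is maximized on a 50-point grid over $[-5, 5]$ followed
by Brent refinement on the bracketing interval; the grid guards against
the multimodality the profiled likelihood can exhibit. Maximum-likelihood
fits feed likelihood-ratio tests (REML likelihoods are not comparable
across fixed-effect changes); REML fits feed variance-component
estimation.

Per-SNP tests compare $y \sim 1$ against $y \sim 1 + g_s$, re-optimizing
$\lambda$ in each model, and refer $2(\ell_1-\ell_0)$ to $\chi^2_1$
(negative statistics clipped at zero). A *fast* mode reuses the null-model
$\lambda$ for all SNPs, which reduces each SNP test to a weighted simple
regression and vectorizes across the whole genotype matrix; it is the
default inside permutation loops, where $10^2$–$10^4$ complete genome
scans are needed, and agrees with the exact mode to the third decimal in
$-\log_{10} p$ under the null (both modes are covered by the calibration
tests).

### Chip heritability

PVE is estimated from the intercept-only REML fit as

$$\mathrm{PVE} = \frac{\hat\sigma_g^2 \, \overline{d}}
{\hat\sigma_g^2 \, \overline{d} + \hat\sigma_e^2},
\qquad \overline{d} = \mathrm{tr}(K)/n,$$

the trace factor making the estimate invariant to the overall scale of
$K$ (the centered genomic relationship matrix used here has diagonal well
below 1). The standard error is a delta-method transform of the inverse
observed information of $(\sigma_g^2, \sigma_e^2)$ at the optimum; at the
$\sigma_g^2 = 0$ boundary, where the observed-information surface is
one-sided, the expected (Fisher) information is substituted so that a
finite standard error is always reported. An estimate is flagged non-zero
when $\mathrm{PVE} - \mathrm{SE} > 0$, i.e. when the one-standard-error
bar does not intersect zero.

Two properties of this flag are worth stating plainly. First, simulations
at $n = 400$ (sibship kinship, 2,000 SNPs) recover planted heritabilities
of 0, 0.3 and 0.6 with mean absolute error under 0.05. Second, for a
truly non-heritable trait the flag fires in roughly 13–15% of replicates.
That rate is not an implementation defect: for a calibrated estimator of
a parameter sitting on its boundary, the estimate is (asymptotically) a
half-normal mixture and $P(\hat\theta > \widehat{\mathrm{SE}}) \approx
\tfrac12 P(|N(0,1)|>1) \approx 0.16$. We verified that observed
information, expected information and log-scale parameterizations of the
standard error all give the same rate, so a one-standard-error rule simply
is a lenient criterion; treating flagged taxa as *candidates* rather than
confirmed heritable traits is the right reading, and the large standard
errors relative to the estimates mean individual PVE values should not be
compared between taxa.

## Preprocessing decisions

* **Subsampling** uses a multivariate hypergeometric draw (sampling reads
  without replacement), capping each technical replicate at the configured
  depth (2 million reads by default) and leaving shallower replicates
  untouched. Proportions are preserved in expectation.
* **Prevalence filter**: a taxon is kept if it has at least one read in at
  least 75% of individuals, boundary inclusive.
* **Inverse normal transformation** maps ranks to
  $\Phi^{-1}((r-a)/(n+1-2a))$ with $a = 3/8$ for $n \le 10$ and $a = 1/2$
  otherwise — the classical normal-scores plotting positions. Ties get
  average ranks, so tied counts map to one value; the transform is then
  monotone and deterministic. Constant columns are an error: such taxa
  must be dropped upstream.
* **Correlated-taxon pruning** removes taxa until no pair correlates at
  $r \ge 0.9$. Across taxonomic levels the broader level is removed (the
  genus is more informative than the family that contains it); within a
  level the alphabetically first name is removed. Because no processing
  order is canonical, we fix one: violating pairs are handled in
  decreasing $r$ (ties broken lexicographically) with re-checking after
  every removal, which makes the output reproducible and matches a
  brute-force pair-enumeration oracle on small tables.
* **Season combining** averages the *within-season normalized* values for
  individuals sampled in both seasons, restricted to taxa passing
  prevalence in both seasons; pruning is applied after averaging. A
  PCA-based QC utility tests any per-individual label against the top 10
  components to confirm that a nuisance factor (e.g. season) does not
  dominate the combined matrix.
* **Alpha diversity** (richness, Shannon $H$ with natural log via vegan,
  Pielou $J = H/\ln S$) is computed on raw genus counts, before
  normalization and rarity filtering; $J$ is undefined for a single
  genus.

## Genotype handling

QC keeps SNPs with minor allele frequency $\ge 5\%$ (computed on
non-missing calls), call rate $\ge 95\%$ and exact Hardy–Weinberg
$p \ge 0.001$; all thresholds inclusive. The Hardy–Weinberg test is the
exact two-sided conditional test (summing probabilities of all
heterozygote counts no more probable than the observed one). A
pedigree-based Mendelian-error filter is listed in the QC report as not
applied: it requires pedigree records, which the package does not model.
Before each association analysis, SNPs with MAF strictly below 10% *in
the analyzed individuals* are removed.

Relatedness is estimated with the centered genomic relationship matrix
$K = p^{-1}\sum_s (g_s - 2f_s)(g_s - 2f_s)^\top$ (missing dosages
mean-imputed per SNP; optional standardized variant). A pedigree-based
identity-by-descent matrix would occupy the same slot when a pedigree is
available; the GRM fills the identical role in the LMM and is computable
from the data alone.

## The synthetic-data module

The generator is first-class, tested code; its defaults define the
conditions under which the package's statistical behavior is validated.

* **Genotypes**: non-overlapping sibships (default four children from two
  unobserved parents per family), per-SNP allele frequencies uniform on a
  configurable range (default 0.05–0.5), alleles dropped through the
  pedigree so the expected kinship is 1 on the diagonal, 0.5 within
  sibships, 0 between families (a monozygotic option makes within-family
  genotypes identical). SNPs are independent given the pedigree: the
  package does not model linkage disequilibrium beyond family sharing,
  so validation says nothing about fine-mapping resolution in real,
  LD-structured genomes.
* **Latent traits**: per taxon, planted per-allele SNP effects (in
  residual-SD units) + a polygenic term built from independent
  $N(0, h^2/m)$ effects on all $m$ standardized SNPs + covariate effects
  (sex, age, family-linked collection group) + $N(0, 1-h^2)$ noise. The
  SNP-based polygenic term makes the planted $h^2$ genuinely chip-tagged,
  which is what a chip-heritability estimator should be asked to recover.
* **Counts**: per replicate, reads are multinomial over
  softmax(baseline + latent + season shift), with baselines spread over
  several orders of magnitude — compositional counts with realistic
  skew. Real 16S data additionally exhibit overdispersion beyond
  multinomial and batch effects, which the generator does not emulate.
* **Open chromatin**: a genome-wide lattice of candidate peaks; each
  tissue activates a random subset; each cell line carries its tissue's
  peaks minus ~2% dropout plus matching private peaks (so same-tissue
  lines share ≥ 90% of intervals); peaks covering causal SNP positions
  are added to the causal tissue and never dropped.

All generators draw from child streams derived from one root seed by
fixed offsets, so a whole study is reproducible from a single integer.

## Tissue enrichment

Cell lines are clustered on binary peak-presence vectors over the
disjoint atoms of the union of all peaks, with Euclidean distance and
average-linkage hierarchical clustering cut into $k$ groups (default
matches the number of simulated tissues; 16 is the conventional choice
for the public DNase compendium). Only the distance is canonical; the
linkage is our choice, made for determinism on binary profiles. Tissue
peak sets take the word "intersection" literally — the base pairs present
in *every* member cell line — which is conservative for heterogeneous
tissues; a union rule is available as an explicit alternative.

For a GWAS, fold enrichment at threshold $t$ is the in-peak fraction
among SNPs with $p \le t$ divided by the in-peak fraction among all
tested SNPs, evaluated over the ladder 1.0 down to 5×10⁻⁶ but only where
the bin holds at least 50 SNPs. Significance for the smallest retained
bin comes from full phenotype permutation: abundances are reshuffled
across individuals, the entire genome scan is re-run (fast mode, reusing
the kinship eigendecomposition and the precomputed rotated genotypes),
and the top-$n$ SNPs (matched to the observed bin size) are scored. The
empirical $p$ is the fraction of permutations with fold at least the
observed one — literally count/$n_\mathrm{perm}$, which can be zero; a
`plus_one` option gives the $(c+1)/(B+1)$ estimator for users who prefer
never-zero p-values. Permutation preserves genotypes and masks exactly,
so the null respects the SNP-peak overlap structure. Reported per-tissue
p-values are deliberately not corrected across tissues, and the output
says so.

## Validation problem sizes

The automated checks run at desk scale, chosen to keep the full suite
within a coffee break while leaving the Monte-Carlo margins interpretable:
LMM calibration on 300 individuals × 5,000 SNPs (≥ 15,000 null tests);
PVE recovery at $n = 400$, 2,000 SNPs, 100 trait draws per heritability
level; QTL recovery over 100 studies of 300 individuals × 2,000 SNPs;
tissue recovery over 100 studies of 200 individuals × 5,000 SNPs with 200
permutations each (the acceptance script uses 30–60 replicates for the
slowest blocks). The thresholds themselves (prevalence 0.75, prune
$r \ge 0.9$, QC MAF 0.05 / call rate 0.95 / HWE 0.001, analysis MAF 0.10,
q-value cutoffs 0.1/0.2, 50-SNP minimum bins) are the canonical analysis
values and are the package defaults.

## Known limitations

* No LD simulation; no pedigree-file support; no Mendelian-error filter.
* Missing genotypes are mean-imputed — adequate for common variants at
  high call rates, not for low-frequency variants.
* The LMM is single-variance-component and quantitative-trait only.
* Empirical p-values at 200 permutations have a resolution of 0.005;
  published-scale analyses should use 10,000.
* The one-standard-error heritability flag is lenient by construction
  (see above); treat flagged taxa as candidates.
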