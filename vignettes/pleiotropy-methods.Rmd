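---
title: "Gene-level pleiotropy mapping from GWAS summary statistics: models and methods"
author: "pleiogene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level pleiotropy mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiogene)
```

# The problem

Psychiatric disorders co-occur far more often than chance predicts, and
genome-wide association studies (GWAS) of different disorders keep hitting
overlapping regions. Two distinct questions hide behind that observation.
First, *how much* of the genetic basis is shared — a genome-wide quantity,
answered by genetic correlation. Second, *which genes* drive the sharing —
a gene-by-gene question that is statistically delicate, because declaring a
gene "associated with both disorders" is a composite-null problem: the null
hypothesis is the union of "associated with neither" and "associated with
exactly one", and naive approaches that threshold each trait separately are
either badly conservative or invalid. A third question follows once shared
genes exist: does one disorder *cause* the other (mediated, or vertical,
pleiotropy), or do genes act on both directly (horizontal pleiotropy)?
Mendelian randomization (MR) separates these using genetic variants as
instruments.

`pleiogene` implements this whole chain as a reusable, tested pipeline
operating purely on GWAS summary statistics plus an LD reference panel:

1. **QC and harmonization** of per-trait summary statistics
   (`apply_qc_filters()`, `harmonize_alleles()`);
2. **gene-level association** by aggregating SNP Z-statistics under local
   linkage disequilibrium (`gene_assoc_table()`);
3. **composite-null pleiotropy testing** per trait pair on de-correlated,
   signed gene Z-statistics (`placo_pair_analysis()`), with direct-FDR and
   maximum-P comparators and an overall-pleiotropy likelihood-ratio test;
4. **LD score regression** for heritability, intercepts, and cross-trait
   genetic correlation, with hierarchical clustering of the trait
   correlation matrix (`ldsc_h2()`, `ldsc_rg()`, `cluster_traits()`);
5. **a bidirectional MR screen** with IVW, weighted-median, and MR-Egger
   estimators (`mr_screen()`).

Real consortium summary statistics are not distributed with the package; a
synthetic-data module generates inputs with the statistical structure the
methods assume, and doubles as the ground-truth source for the calibration
and power tests.

# Quality control

Five filters are applied in a fixed order, and each SNP is attributed to
the *first* filter it fails, so the QC report always reconciles to the
input count:

(i) non-biallelic SNPs and strand-ambiguous (palindromic A/T, C/G) pairs;
(ii) identifiers not matching `rs` + digits;
(iii) duplicated identifiers and SNPs absent from, or allele-incompatible
with, the reference panel;
(iv) the MHC region (chr6: 28.5–33.5 Mb, inclusive on both ends), excluded
for its extreme LD;
(v) MAF ≤ 0.01.

Two conventions are worth stating because the field varies on them.
Palindromic SNPs are *dropped*, never frequency-inferred. Duplicated
identifiers are removed entirely (all copies): with two conflicting records
there is no principled way to pick the right one from summary data alone.
Harmonization flips `beta`, `z`, and the allele frequency when a record's
alleles are swapped relative to the panel (directly or as strand
complements); it is an involution, so re-running it is a no-op. Odds ratios
are converted to log-odds at read time since many GWAS releases print OR.

# Gene-level association

For a gene with SNP Z-vector $z$ and local LD correlation matrix $R$, the
statistic is $S = \sum_j z_j^2$. Under the null, $S \sim \sum_i \lambda_i
\chi^2_1$ with $\lambda_i$ the eigenvalues of $R$. The tail probability is
computed by numerical inversion of the characteristic function (Imhof's
integral, absolute tolerance $10^{-12}$), with two guards: equal
eigenvalues collapse to an exact $\chi^2$ tail, and when quadrature fails
or hits its noise floor (below $10^{-10}$) a Satterthwaite moment match
takes over. Eigenvalues in $[-10^{-8}, 0)$ are clipped to zero; anything
more negative is rejected as a non-PSD input. P-values are floored at
$10^{-300}$ so that downstream Z conversion stays finite.

The gene's *direction* is the sign of $\sum_j \beta_j \cdot \mathrm{MAF}_j$
(a MAF-weighted vote of effect directions), with an exact zero resolved to
$+1$ — an arbitrary but fixed tie-break. The signed gene Z is
$z_g = \mathrm{sign} \cdot \Phi^{-1}(1 - p_g/2)$; the two-sided conversion
is used because the sign is attached explicitly, and a one-sided conversion
would count the sign twice.

SNPs map to genes by position, inclusive on both gene ends, with no window
padding by default (a `window_bp` knob exists). A SNP inside two
overlapping genes counts for both. Note the aggregation model here is the
sum-of-chi-squares ("SNP-wise mean" style) model only; covariate-adjusted
or competitive gene-set models are out of scope.

# The composite-null pleiotropy test

For a trait pair, the test statistic per gene is the product
$T = z_1^\ast \cdot z_2^\ast$ of *de-correlated* gene Z-statistics. Working
through the three sub-nulls:

- $H_{00}$: neither trait associated — both factors standard normal;
- $H_{10}$: trait 1 associated only — factor 1 has variance
  $\sigma_1^2 \ge 1$ reflecting its polygenic dispersion;
- $H_{01}$: symmetric.

Each sub-null p-value is the two-sided tail of a product-normal
distribution, whose density is $K_0(|w|/(s_1 s_2)) / (\pi s_1 s_2)$ with
$K_0$ the modified Bessel function of the second kind. The tail integral is
evaluated with exponentially scaled Bessel values, so it remains accurate
far into the tail, and the general case reduces to the standard one through
the scaling identity $P(t; s_1, s_2) = P(t/(s_1 s_2); 1, 1)$. The
intersection–union principle gives $p = \max(p_{00}, p_{10}, p_{01})$:
rejection requires rejecting *every* sub-null, which is exactly the
alternative "associated with both". This construction is self-contained and
validated by its own simulation gates (type-I error under all three
sub-nulls, power ordering against the comparators); it does not attempt to
reproduce any particular software's internal approximations.

Two nuisance quantities are estimated genome-wide per pair:

- **Null Z correlation** `rho_z`: the Pearson correlation of the two gene Z
  vectors after excluding genes with $\min(p_1, p_2) <$ `trim_p` (default
  $10^{-4}$), so genuinely associated genes do not masquerade as sample
  overlap. The Z pair is then transformed by the symmetric inverse square
  root of $[[1, \rho],[\rho, 1]]$. Pairs with $|\rho| \ge 0.99$ are refused
  as untestable.
- **Marginal Z variance** $\sigma_k^2$: the variance of the full gene Z
  vector, floored at 1. The floor matters: a variance below 1 would make
  the sub-null *narrower* than $H_{00}$ and the IUT anti-conservative.

FDR (Benjamini–Hochberg) is applied within each trait pair, matching how
per-pair discovery counts are reported; a global mode is a flag away.

**Comparators.** The direct-FDR method intersects the genes separately
significant (BH) in both traits; the maximum-P method applies BH to the
per-gene $\max(p_1, p_2)$. Both are implemented exactly and compared
against the composite-null test on planted-truth simulations; the expected
qualitative ordering (composite-null test most powerful, maximum-P least)
is an acceptance gate.

**Overall-pleiotropy LRT.** Across genes, the paired p-values are modeled
as a four-component mixture: each trait's p-value is uniform under no
association and $\mathrm{Beta}(\alpha_k, 1)$ (density
$\alpha p^{\alpha-1}$, $0 < \alpha < 1$) under association. The full model
has free mixing proportions $\pi_{00}, \pi_{10}, \pi_{01}, \pi_{11}$; the
constrained model forces independence of the two association indicators,
$\pi_{11} = (\pi_{10}+\pi_{11})(\pi_{01}+\pi_{11})$. Both are fit by EM
(closed-form M-steps, $\alpha$ clamped to $(10^{-4}, 1)$, 5000-iteration
cap) and twice the log-likelihood gap is referred to $\chi^2_1$.

**Gene characterization.** For each significant gene, the Pearson
correlation of per-SNP effect sizes across the pair (`NA` below 3 SNPs —
reported as missing rather than computed from too little data), and
per-SNP Cochran's Q for effect heterogeneity. Heterogeneity p-values are
adjusted by Benjamini–Yekutieli — not BH — because neighboring SNPs are in
LD and BY is valid under arbitrary dependence.

# LD score regression

The LD score $\ell_j = \sum_k \tilde r^2_{jk}$ sums bias-adjusted squared
correlations $\tilde r^2 = r^2 - (1-r^2)/(n_{\mathrm{ref}}-2)$ over SNPs
within a 10 Mb window (reference size default 503). Univariate LDSC
regresses $\chi^2_j$ on $\ell_j$,
$E[\chi^2_j] = \mathrm{intercept} + (N h^2 / M)\, \ell_j$, with the
standard heteroskedasticity-and-overcounting weights
$1/(\max(\ell_j,1) \cdot (1 + N h^2 \ell_j / M)^2)$ iterated twice from an
OLS start (further iterations move the estimates negligibly). Cross-trait
LDSC regresses $z_{1j} z_{2j}$ on $\ell_j$; the slope yields the genetic
covariance and the intercept estimates the sample-overlap term
$\rho N_s / \sqrt{N_1 N_2}$ — under the pure overlap architecture the
planted correlation is recovered (an acceptance gate). The genetic
correlation is $r_g = \rho_g / \sqrt{h^2_1 h^2_2}$, undefined (flagged)
when either heritability estimate is non-positive, and flagged when
$|r_g| > 1.25$.

Uncertainty comes from a delete-a-block jackknife over 200 contiguous SNP
blocks (a convention; a knob). The `rg` jackknife recomputes all three
regressions per deleted block, so the heritability uncertainty propagates
into the `rg` standard error. The genomic inflation factor is
$\lambda = \mathrm{median}(z^2) / \mathrm{median}(\chi^2_1)$.

Traits are clustered on distance $1 - r_g$ with average linkage; the
partition is invariant to trait ordering, and missing correlations are
imputed as 0 with a warning rather than silently.

# Mendelian randomization

The design enumerates one-sided childhood→adulthood relationships plus all
ordered adulthood pairs: with 2 childhood and 10 adulthood traits, 110
relationships (20 + 90), and 45 unordered adult pairs.

Instruments are selected by greedy clumping: candidates at $p < 10^{-5}$
ranked by p-value (ties broken by position then identifier); the top SNP is
kept and candidates within 10 Mb *and* $r^2 > 0.001$ of it are discarded.
The relaxed $10^{-5}$ threshold trades instrument strength for coverage;
the compensating guard is a Bonferroni filter that removes instruments
with outcome $p < 0.05/J$ over the $J$ selected instruments (the divisor is
the post-clumping count — the natural reading when no denominator is
stated). This filter also suppresses reverse-causation leakage through
linkage: in the planted-causal-pair simulations it is what empties the
reverse direction of mediated loci. A side effect worth knowing: because it
preferentially removes instruments with strong outcome signal, it slightly
attenuates genuinely mediated effects — a conservatism inherent to the
design, visible in the worked example (estimate ≈ 0.22 for a planted 0.3).

Estimators, per exposure–outcome cell with at least 3 instruments:

- **IVW**: ratio estimates $b_{yj}/b_{xj}$ weighted by $b_{xj}^2/s_{yj}^2$;
  multiplicative random-effects SE, $\sqrt{\max(1, Q/(J-1)) / \sum w}$, so
  heterogeneity widens but never narrows the interval (fixed-effect by
  flag).
- **Weighted median**: interpolated weighted median of the ratios,
  consistent when instruments holding half the weight are valid; SE by
  seeded parametric bootstrap.
- **MR-Egger**: after orienting every instrument to a non-negative exposure
  effect, WLS of $b_y$ on $b_x$ with a free intercept; the intercept
  indexes directional pleiotropy; SEs carry a multiplicative overdispersion
  factor floored at 1.

Instrument strength is reported as per-SNP $F = (b_x/s_x)^2$ and variance
explained $2\,\mathrm{MAF}(1-\mathrm{MAF})\,b_x^2$. BH FDR is applied over
IVW p-values across the whole design jointly by default (a per-design mode
exists, since correcting the childhood and adulthood analyses separately is
an equally defensible reading); bidirectionally significant pairs are
flagged.

# The synthetic-data generator

The generator emulates the *assumptions* of the downstream methods, not any
particular cohort; it is also the source of ground truth for every
calibration gate, so its design choices deserve scrutiny.

**LD**: block-diagonal AR(1) correlation, $r_{jk} = \rho^{|j-k|}$ — always
positive definite, closed-form, zero across blocks. Each block draws its
own $\rho$ uniformly from $(0.2, 0.9)$ by default: a single genome-wide
$\rho$ leaves the LD scores nearly constant, and a regression on a
constant-ish covariate cannot separate slope from intercept; heterogeneous
LD strength is also simply what genomes look like. Defaults: 50 SNPs per
block, 20 blocks per surrogate chromosome, MAF uniform on $(0.05, 0.5)$,
non-palindromic alleles, rs-style identifiers.

**Architecture**: 20% of genes causal per trait. Genetic correlation
$r_g$ is induced by sharing a fraction $f = \min(1, 2|r_g|)$ of causal
genes with cross-trait per-SNP effect correlation $r_g / f$, giving a
genome-wide genetic correlation of exactly $r_g$. Within causal genes, SNP
effects are i.i.d. by default (`gene_share_w = 0`). This was a considered
reversal: a gene-level shared effect component creates cross-SNP effect
covariance aligned with local LD, which inflates $E[\chi^2]$ beyond the
$\ell_j$ regressor and biased heritability estimates several-fold in
development runs — the LD-score model really does assume effects
uncorrelated across SNPs. Gene-level causal truth is still perfectly
defined (membership in a causal gene), which is all the power and type-I
gates need; the shared-component knob remains available for demonstrating
the violation. Realized standardized effects are rescaled so
$\sum \beta^2$ equals the target $h^2$ exactly, removing one source of
between-replicate variance.

**Z-statistics**: per block, jointly normal with mean
$\sqrt{N_k}\, R\, \beta_k$ (the standard non-centrality of marginal tests
under LD), per-trait covariance $R$, and cross-trait covariance
$\rho_{\mathrm{overlap}} R$ — the sample-overlap model. Allelic-scale
output uses $\mathrm{se} = 1/\sqrt{2 N \mathrm{MAF}(1-\mathrm{MAF})}$ and
$\hat\beta = z \cdot \mathrm{se}$.

**MR instruments**: true exposure effects normal with SD 0.1, truncated to
a true $F$ above 20 — the relevance assumption of a significance-selected
instrument set, matching the minimum-F range (roughly 21–27) reported for
instrument sets selected at $10^{-5}$. Without the floor, weak instruments'
observed signs flip and the directional-pleiotropy constant (defined on the
exposure-increasing orientation, where the Egger intercept lives) partially
cancels. Outcome effects are
$\beta_{xy} b_x + \alpha_j + c \cdot \mathrm{sign}(b_x)$ with balanced
pleiotropy $\alpha_j \sim N(0, \sigma_\alpha^2)$ and directional constant
$c$. A separate trait-level generator (`simulate_mr_trait_pair()`) plants a
causal effect between two genome-wide traits with trait-specific instrument
loci, which is what makes the reverse direction a true null for the screen.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: real LD is not block-diagonal and couples
with MAF; effect sizes are not MAF-independent; populations are
homogeneous here (no stratification, so the LDSC intercept only ever
absorbs overlap, never confounding); indels, sex chromosomes, and
imputation error do not exist; and gene boundaries align with LD blocks by
construction, so gene tests never straddle blocks. The pipeline's behavior
under those violations is untested by design.

# Numerical and scale choices

Degenerate inputs are handled explicitly: empty genes are rejected;
constant Z vectors floor $\sigma^2$ at 1; a $T = 0$ product yields $p = 1$
exactly; single-instrument Wald ratios hide behind an explicit flag;
two-instrument Egger fits exist only behind a test override. All written
tables are TSV with 6 significant digits; reruns under a fixed seed are
byte-identical (an acceptance gate). Every random routine takes an explicit
seed and restores the caller's RNG state.

Test and acceptance problem sizes were chosen to make each statistical gate
informative at interactive timescales: $10^4$ genes per type-I scenario
(Monte-Carlo SE ≈ 0.2% at $\alpha = 0.05$), 5000-SNP panels with 20
replicates for LDSC coverage, 200 replicates for MR bias, and $10^6$–$10^7$
draws for the Monte-Carlo oracles of the two tail distributions. The
acceptance script reruns all of these from scratch in a few minutes.

# Known limitations

- The gene test fixes one aggregation model; results are conditional on it.
- $\sigma^2$ from the marginal Z variance is a pragmatic estimator; under
  extreme polygenicity with strong LD it can overshoot, making the IUT more
  conservative (never anti-conservative, because of the floor).
- LDSC at a few thousand SNPs has wide jackknife intervals; point estimates
  in the worked example scatter accordingly. Coverage, not precision, is
  the tested property.
- The Egger intercept inherits regression-dilution bias from noisy exposure
  effects (NOME violation); with the generator's F > 20 instruments this is
  a few percent of the intercept, visible only as a small mean shift.
- The MR screen's outcome-Bonferroni filter attenuates mediated effects
  (see above); estimates for genuinely causal pairs are conservative.
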