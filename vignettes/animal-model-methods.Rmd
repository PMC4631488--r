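---
title: "Methods: animal-model REML for induced immune traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: animal-model REML for induced immune traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoQG)
```

## The model and its assumptions

The package estimates the genetic architecture of a quantitative trait —
in the motivating application, the zymosan-induced concentration of HSP70
(μg per mg total protein) in abalone haemocytes or serum — from a
paternal half-sib nested breeding design with repeated measures. The
working model is the individual animal model

$$y = Xb + Z_a a + Z_m f + e,$$

where $y$ stacks all phenotype records, $b$ holds fixed effects, $a$ the
additive genetic effects (breeding values) with
$\mathrm{var}(a) = V_A A$, $f$ any further independent random effects
(family common environment $V_C$; permanent environment $V_{PE}$ for
repeated measures) and $e$ the residuals with variance $V_R I$. $A$ is
the numerator relationship matrix built from the pedigree by the tabular
recursion $A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)})$,
$A_{ii} = 1 + \tfrac12 A_{s(i),d(i)}$, with unknown parents contributing
zero. The model assumes multivariate-normal effects, no
genotype-by-environment interaction, and — as in the source design —
unrelated, non-inbred founders. Animals whose parents are missing are
treated as founders; in a nested full-sib design this gives diagonals of
exactly 1 and off-diagonals in {0, ¼, ½}.

In full-sib designs $V_C$ confounds maternal, early common-environment
and non-additive genetic variance; the package therefore reports it as a
single "family" component, mirrored by the `family` random term, and
screens it by a boundary log-likelihood-ratio test before it is retained.

## Estimation

Variance components maximise the restricted log-likelihood
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py] + \text{const}$ over the
non-negative orthant, with $V = \sum_k \sigma^2_k Z_k G_k Z_k' +
\sigma^2_R I$. Updates are average-information (AI) steps; a proposal
that leaves the orthant is clamped at the boundary and step-halved, and
if it still fails to improve the likelihood an expectation-maximisation
step is taken instead (EM is slow but monotone, which makes the hybrid
robust near boundaries). A component collapsing onto zero with a
non-positive score is pinned there and flagged `boundary`; published
analyses of this design report essentially-zero additive variances (e.g.
7×10⁻⁷), which the package renders as a clean 0 with the flag. Standard
errors come from the inverse AI matrix over free components, and SEs of
h² and R by the first-order delta method from that covariance — the SE
method is always reported with the estimate because source reports often
leave it unstated.

Two numerical choices matter for reproducibility. First, initialisation
is deterministic: the phenotypic variance after an ordinary
least-squares fit of the fixed part is split equally across all
components, so a fit has no stochastic element at all. Second, when the
model holds exactly one non-residual random term (the most common case
here: the per-age models, and the balanced sire model used as an oracle)
the whole computation is carried out in the eigenbasis of that term's
covariance contribution, where $V$ is diagonal; this is algebraically
identical to the dense path and reduces an iteration from cubic to
linear cost. Convergence requires a relative likelihood change below
1e-8 and relative component changes below 1e-6 (tightened to 1e-12/1e-10
where the tests compare against closed forms).

Degenerate inputs are handled explicitly: rows with missing responses or
model variables are dropped and counted (no imputation); a fixed factor
reduced to one level is an error; a specification with no random terms
is allowed only because it is the closed-form reduced model of a
boundary likelihood-ratio test.

## Hypothesis tests

Fixed terms use the Wald F statistic on the term's estimable (pruned)
coefficients at the converged components, with the residual-containment
denominator convention $ddf = n - \mathrm{rank}(X)$. This convention is
declared in every result; the more elaborate adjusted-df algorithms of
commercial mixed-model software are deliberately out of scope, and the
simulation suite checks that the resulting test holds its nominal size
in the designs used here.

Variance components use $\Lambda = 2(\ell_{full} - \ell_{reduced})$
clipped at zero. Because the null value sits on the boundary, the
reference distribution is the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, so $p = \tfrac12 P(\chi^2_1 \ge
\Lambda)$, reported as 0.5 at $\Lambda = 0$ by convention; a plain
$\chi^2_1$ switch is provided for comparability with reports that used
it. The mixture is asymptotic in the number of independent groups: at 60
full-sib families (the study's count) the simulated size is ≈ 0.05,
while at 20 groups the test is mildly conservative (empirical size
≈ 0.036, with slightly more than half the null mass at zero). The
calibration checks therefore use 60 groups.

## Derived genetic parameters

$h^2 = V_A/V_P$ with $V_P$ the sum of all fitted components;
$R = (V_A + V_{PE} + V_C)/V_P$, pooling all permanent between-individual
variance, so $R \ge h^2$ whenever the pooled terms are non-negative.
The evolvability coefficients are $CV_A = 100\sqrt{V_A}/\bar X$ and
$CV_R = 100\sqrt{V_P - V_A}/\bar X$ — note the residual coefficient uses
$V_P - V_A$, not $V_R$ alone, so that $CV_A^2 + CV_R^2 =
(100\,\sigma_P/\bar X)^2$ holds exactly; with separately rounded inputs
the two variants can disagree in the terminal digit.

Predicted response to truncation selection is the breeder's equation
$G = i h^2 \sigma_P$ with $i = \phi(z_p)/p$ under normality
($i = 2.063$ for the top 5 %). $\sigma_P$ is taken as $\sqrt{V_P}$ from
the fitted (or reported) model rather than the raw phenotypic SD: for
the published per-age estimates this convention reproduces three of the
four reported per-generation percentages to the printed decimal and the
fourth to terminal-digit rounding, while the raw SD does not. The
scenario report is single-generation only — no Bulmer correction, no
multi-trait index.

## Phenotypic comparisons

The challenge-effect and age-by-fraction comparisons are fixed-effects
ANOVAs. With two factors and unbalanced cells the package uses type-III
sums of squares (sum-to-zero contrasts), matching the least-squares-means
logic of the follow-up pairwise contrasts; on balanced data these
coincide with sequential sums of squares, which the tests verify.
Assumption checks are Shapiro–Wilk on residuals and the median-centred
(Brown–Forsythe) Levene variant, chosen for robustness; the mean-centred
form is available. "Sequential Bonferroni" is implemented as Holm's
step-down procedure with the monotonicity (running-maximum) step —
without it the adjusted values are not a valid step-down adjustment.
Letter displays are built greedily over maximal contiguous runs of
mutually non-significant groups ordered by ascending mean, with
contained runs absorbed; ties break by ascending mean. These ANOVAs do
not model relatedness — they reproduce the fixed-effects phenotypic
comparisons as reported, and the animal model is the instrument for
anything genetic.

## The synthetic-data generator

The generator is the package's study stand-in, since no phenotypes were
deposited. It emulates: 20 sires × 3 dams (60 full-sib families) with
5–10 measured offspring per family drawn uniformly; records on every
offspring in year 1 (age ≈ 3) and on a simple random ~73 % subset
(357/492) in year 2; two haemolymph fractions with distinct parameter
sets; fraction-by-age trait means at the reported scale (16.40/32.27
intracellular, 26.59/30.87 extracellular); a linear sampling-order
effect over four batches assigned by random permutation within year
(1.5 trait units per batch step by default, echoing the significant
order effect near harvest); an age covariate whose slope is implied by
the two year means; and a challenge experiment with controls at baseline
and the stimulated group at 3× baseline with lognormal noise, 6–10
animals per condition. Default variance components (intracellular
V_A = 5, V_R = 46; extracellular V_A = 18, V_R = 200) place simulated
phenotypic variances on the scale of the reported per-age tables, with
V_C = V_PE = 0 as the default because the source analysis found no
family or permanent-environment signal.

Breeding values descend the pedigree generatively: founders from
$N(0, V_A)$, offspring as the parent average plus a Mendelian deviation
from $N(0, V_A/2)$ (exact for non-inbred pedigrees). Each stage draws
from its own deterministic sub-seed, so adding a stage never perturbs
earlier draws and identical seeds give byte-identical datasets.

What the generator does **not** emulate: the trait scale is Gaussian
(negative values are possible at low means), chosen because REML's
validity is what the tests probe — a lognormal mode exists for realism
but is not the default; there is no mortality model beyond uniform
attrition, no genotype-by-environment interaction, no tank/density
structure beyond the optional columns, and no genetic correlation
between fractions (each is simulated as an independent trait). Passing
tests therefore demonstrate correctness of the estimation machinery
under the design, not robustness to the messiness of real haemolymph
assays.

## Simulation problem sizes

The verification suite chooses sizes that make each check sharp but
cheap: the relationship-matrix oracle runs 50 random pedigrees of 20–200
animals against a memoised pairwise recursion (agreement to 1e-12); the
REML engine is compared with the closed-form balanced-ANOVA estimator on
500 datasets of 20 sires × 15 offspring (interior solutions, agreement
to 1e-6); heritability recovery uses 200 replicates of the full
two-year, 60-family design at true h² of 0.05 and 0.30; and test
calibration uses 1,000 null replicates each for the boundary log-LR
(60 groups × 8) and Wald F (20 × 15 with a 4-level null factor) tests,
asserting the empirical size within the binomial 95 % band of 0.05. At
the low-heritability setting the mean delta-method SE (≈ 0.03) is of
the same order as the estimate itself — the design genuinely cannot
separate h² ≈ 0.05 from zero in a single realisation, which is the
qualitative finding the recovery study reproduces.

## Known limitations

Single-trait models only (no genetic correlations or random
regression); dense linear algebra throughout, sized for pedigrees up to
a few thousand animals — the sparse inverse-A machinery of large-scale
evaluations is out of scope; the Wald ddf convention is approximate for
severely unbalanced fixed structures; and the boundary-mixture null is
asymptotic in the group count, as quantified above.
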