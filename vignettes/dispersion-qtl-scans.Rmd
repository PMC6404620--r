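---
title: "Mapping phenotypic dispersion loci in F2 intercrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phenotypic dispersion loci in F2 intercrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispscan)
```

## The problem

Most QTL mapping asks where genotype shifts the *mean* of a trait. Variance
QTL (vQTL) mapping asks a different question: where does genotype change the
*residual spread* of a trait — the tendency of individuals to scatter away
from the value their genotype and covariates predict? For a progressive
renal phenotype such as urinary albumin in mouse F2 intercrosses, loci of
this kind capture genetic control over the stochasticity of disease onset
and progression rather than its average severity.

`dispscan` implements a two-stage scan for such loci in an F2 cohort
(two inbred parental strains, genotypes segregating 1:2:1), together with a
synthetic cohort generator so that every stage of the pipeline can be
exercised and validated without any external data.

## The model

### Stage 1: covariate model and the dispersion phenotype

For each trait (albumin, creatinine, optionally BUN) and each marker, an
ordinary least-squares model is fitted on casewise-complete data:

$$y_{ij} = \mu + \alpha_i + \beta_{MLH} X_{MLH} + \beta_{UCrea} X_{UCrea} + \varepsilon_{ij},$$

where $\alpha_i$ is the marker's genotype effect (a 3-level factor with the
second parental strain's homozygote as reference), $X_{MLH}$ is multilocus
heterozygosity (the fraction of an individual's typed markers that are
heterozygous, a proxy for genome-wide inbreeding) and $X_{UCrea}$ is urinary
creatinine, included only when the response is albumin (creatinine serves as
the baseline measure of glomerular throughput). MLH enters the model when
its association with the locus-free dispersion of the trait has two-sided
$P < 0.1$; this probe is run once per trait before the scan.

The mapped phenotype is **phenotypic dispersion** (PD): the absolute
externally Studentized residual

$$t_i = \frac{\hat\varepsilon_i}{\hat\sigma_{(i)}\sqrt{1 - h_{ii}}},
\qquad PD_i = |t_i|,$$

with leverage $h_{ii}$ and the deleted scale
$\hat\sigma_{(i)}^2 = \sum_{j \ne i} \hat\varepsilon_j^2 / (n - m - 1)$.
External Studentization protects against single extreme individuals
inflating their own scale estimate; PD is invariant to positive affine
transformation of the trait, so units do not matter downstream.

By default PD is recomputed **per marker** from the model containing that
marker's locus term, so the dispersion phenotype at each marker is the
scatter left over after that marker's own mean effect (and the covariates)
have been absorbed. A `global` residualization mode (one locus-free PD
vector per trait) is available in `scan_config()` for sensitivity analysis.

### Stage 2: left-bounded regression of dispersion on genotype

PD is non-negative with a strong lower bound at zero, so its regression on
genotype uses a left-bounded Gaussian (Tobit) model. Two variants are
implemented:

* **truncated** (the scan default): the Gaussian density is renormalized
  above the bound, $L = \prod_i f(y_i) / (1 - \Phi(\alpha_i))$ with
  $\alpha_i = (\tau - x_i'\beta)/\sigma$. This matches a response that is
  *defined* only above the bound, as an absolute residual is.
* **censored**: observations at the bound contribute the probability mass
  $\Phi(\alpha_i)$. The conventional econometric Tobit; provided because the
  two readings cannot be distinguished for historic fits, and the variant is
  a logged configuration field (`scan_config(tobit_variant=)`).

The likelihood is maximized by BFGS (`stats::optim`) on $(\beta, \log\sigma)$
with an analytic gradient, started from OLS estimates and finished with
damped Newton steps until the gradient norm falls below $10^{-6}$ (the
convergence criterion). Standard errors come from the inverse of the
observed information, differentiated numerically from the analytic gradient
by central differences with step $10^{-5}(1 + |\theta_j|)$; the scale is
reported on the natural scale via the delta method.

Each marker's significance is the joint Wald "nonequivalence" contrast of
both genotype coefficients against the reference homozygote
($\chi^2$, 2 df; 1 df for markers with only two observed classes, e.g. the
hemizygous X in an all-male cohort).

### Architecture contrasts

Genetic architecture at a locus is described by single-degree-of-freedom
Wald contrasts on the fitted genotype means $(\mu_{CC}, \mu_{CA},
\mu_{AA})$:

* the homozygote linear contrast $(+1, 0, -1)$, feeding the additive label
  `A` (the heterozygote-vs-midparent contrast $(-0.5, +1, -0.5)$ is also
  reported);
* four dominance vectors applied sequentially, $(+0.5, +0.5, -1)$ and
  $(-1, +0.5, +0.5)$ for positive dominance, $(+1, -0.5, -0.5)$ and
  $(-0.5, -0.5, +1)$ for negative dominance. Each vector isolates one
  homozygote; the preserved sign conventions identify which homozygote is
  the isolated high-dispersion class;
* heterozygote-vs-each-homozygote contrasts for over-/underdominance.

Labels (`A`, `D+`, `D-`, `OD`, `UD`) are assigned per significant contrast
family at a nominal `alpha_label = 0.05`; several labels may coexist
(partial negative dominance typically reports `{D-, A}`). Two deliberate
design choices here:

* a dominance vector only yields its label when the fitted heterozygote
  mean actually sides with the class the vector claims (closer to the high
  homozygote for `D+`, to the low one for `D-`). Without this gate an
  overdominant pattern like $(1, 3, 1)$ would nominally fire a
  positive-dominance vector it does not represent;
* genuinely contradictory simultaneous families (`D+` with `D-`, `OD` with
  `UD`) are all reported and flagged ambiguous rather than suppressed —
  with small samples the contrasts can disagree, and hiding one side would
  bias the reported architecture.

Griffing's potence ratio
$h_P = (2\mu_{CA} - (\mu_{CC}+\mu_{AA}))/(\mu_{CC}-\mu_{AA}) = Q/L$
summarizes dominance continuously (0 additive, $\pm 1$ complete dominance,
$|h_P|>1$ over-/underdominance). Note that the *sign* of $h_P$ tracks which
homozygote the heterozygote resembles (positive: the CC side), not whether
that homozygote is high or low; when $\mu_{CC} = \mu_{AA}$ (within
$10^{-12}$) the ratio is undefined and flagged rather than returned as a
silent `NaN`. The high-dispersion allele is reported by strain name from
the fitted genotype means, and left `NA` when the heterozygote is the top
class.

### Multiple testing

Across all tested markers of a cohort-trait pair, the joint-test P-values
enter step-up Benjamini–Hochberg at `alpha_fdr = 0.05` with a **hard
floor**: rejection additionally requires nominal $P \le 0.01$. The floor is
an intersection — it can only remove BH rejections, never add them; the
alternative reading (floor as an override that rescues sub-floor markers BH
would not reject) is anti-conservative and was rejected. The family size
`m` is markers per cohort × trait; ties share the maximal qualifying rank;
`NA` P-values are excluded from `m` with a warning.

### Consensus loci

Markers rejected in two independent cohorts on the same chromosome within
`window_mb = 10` of each other (single-linkage chaining) and sharing the
same high-dispersion allele are grouped into named consensus loci
(`PDUAlb1`, `PDUAlb2`, … ordered by chromosome then position). A window of
10 Mb groups peaks a recombination-plausible distance apart while keeping
independent signals on the same chromosome separate; it is a configuration
field. Clusters whose two cohorts disagree on the high-dispersion allele
are reported as *contrast pairs* — biologically interesting (architecture
inversion) but not replication.

## The synthetic cohort generator

`simulate_cohort()` produces complete cohorts with the statistical
structure the analysis assumes. Genotypes: each individual is two
independent gametes; each gamete is a Markov chain along each chromosome
with inter-marker recombination $r = (1 - e^{-2d})/2$ (Haldane, no
interference; $d$ in Morgans); chromosomes independent. The default map has
19 autosomes with approximate mouse genetic lengths and 17 cM marker
spacing (~100 markers); synthetic bp positions are $cM \times 2 \cdot 10^6$
since only relative positions matter to consensus grouping.

Phenotype defaults (all one-time choices, stated with units):

| parameter | default | rationale |
|---|---|---|
| cohort size `n` | 383 males | full-size study cohort |
| creatinine | $N(76, 20^2)$ mg/dl | observed cohort mean; SD spans the observed 29–150 range |
| albumin mean | 0.72 mg/dl | observed cohort mean |
| albumin ~ creatinine slope | 0.013 | reported positive association |
| albumin ~ MLH slope | −4.87 mg/dl | reported negative association |
| baseline albumin residual SD | 0.5 mg/dl | keeps dispersion effects of ratio 1.2–3 in the detectable range at n ≈ 200–400 |
| MLH → log residual SD slope | −2 | qualitative direction of the reported MLH–dispersion association; magnitude is a generator choice |
| detection floor | at 0, on | concentration assays cannot go negative; observed ranges start at 0 |
| BUN | $N(20.4, 3^2)$ mg/dl, absent by default | only one cohort recorded it |

A vQTL effect (`vqtl_effect()`) multiplies the albumin residual SD by a
per-genotype factor — e.g. `D-` with the P2 allele high is
$(1, 1, \text{ratio})$ for (CC, CA, AA) — so dispersion acts
multiplicatively on the scale, not additively on the variance (an
additive-on-log-variance reading of the same factors). Mean-QTL components
can be added through `mean_shift`.

What the generator deliberately does **not** emulate: linkage
disequilibrium beyond F2 meiosis, genotyping error, litter or sex
structure, and the heavy right tail of real albumin distributions (the
generator's albumin is floored Gaussian; real cohorts range up to 35 mg/dl
on a mean of 0.72). Passing tests therefore demonstrate correct behaviour
of the *statistical machinery* under the assumed model, not robustness to
every feature of real excretion data.

## Numerical choices and degenerate inputs

* $\sigma$ is optimized as $\log\sigma$; tail probabilities use `log.p`
  CDF asymptotics; a non-finite likelihood value is returned as a large
  finite penalty so BFGS line searches can back off.
* Exact zeros in PD (possible only on degenerate toy data) are dropped
  before a truncated fit, which is undefined at the bound.
* Markers with fewer than `min_class_n = 5` individuals in an observed
  genotype class are skipped with a reason (class imbalance makes the
  genotype-class contrasts unstable); monomorphic markers likewise, and
  both are excluded from the FDR family size.
* Non-convergent Tobit fits (gradient norm ≥ $10^{-6}$ after polishing)
  are reported with `converged = FALSE` and a warning, never silently.
* The scan contains no random number generation: identical configuration
  and input give byte-identical scan tables.

## Validation problem sizes

The test suite validates the pipeline at the following scales, chosen to
estimate each operating characteristic with useful precision: null
calibration over 200 replicate scans of ~105 markers at $n = 300$;
localization and architecture recovery over 100–150 replicates of a
negative-dominant locus with SD ratio 2 at $n = 400$; SD-ratio recovery at
$n = 10{,}000$ via per-genotype-class censored-Tobit fits (consistent under
the detection floor, unlike raw sample SDs); Mendelian segregation and the
Haldane map at $n = 10{,}000$ individuals and 40,000 gametes. The joint
Wald test is mildly conservative at these sample sizes (empirical size
≈ 0.044–0.045 at nominal 0.05, both for correctly specified
truncated-normal data and for scans of |t|-shaped dispersion), which
protects rather than inflates the FDR.

## Known limitations

* The Wald tests rely on observed-information standard errors; PD is not
  literally truncated-normal, so stage-2 inference is quasi-likelihood in
  spirit and slightly conservative (above). No
  heteroskedasticity-consistent (sandwich) option is provided.
* Tests are at genotyped markers only — no interval mapping or pseudomarker
  imputation between markers.
* No epistasis or two-locus architecture tests; no random effects; no
  double-GLM dispersion modelling.
* `r2` for a Tobit fit has no canonical definition; the default is the
  squared Pearson correlation between fitted and observed PD, with a
  latent-scale (McKelvey–Zavoina-style) alternative behind
  `scan_config(r2_method = "mckelvey_zavoina")`.

## A worked example

```{r example, eval = FALSE}
library(dispscan)

map <- sim_map()
effect <- vqtl_effect(map$marker[3], "D-", sigma_ratio = 2)
cohort <- simulate_cohort(map = map, effects = effect,
                          config = sim_config(n = 383), seed = 1)

scan <- scan_trait(cohort, "ualb", scan_config())
scan                       # top markers, FDR rejections
autoplot(scan)             # -log10 P by genomic position

# architecture at the strongest marker
top <- scan$table$marker[which.min(scan$table$p_joint)]
scan$table$forms[[match(top, scan$table$marker)]]

# replicate in a second cohort and group consensus loci
cohort_b <- simulate_cohort(map = map, effects = effect,
                            config = sim_config(n = 340), seed = 2,
                            name = "replication")
scan_b <- scan_trait(cohort_b, "ualb", scan_config())
consensus_loci(list(scan, scan_b))
```
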