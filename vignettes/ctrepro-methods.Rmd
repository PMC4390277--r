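---
title: "Models and methods behind ctrepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctrepro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrepro)
```

## Scope

ctrepro studies how methodological choices in plasma microRNA RT-qPCR —
time to plasma extraction, RNA extraction method, cycle-threshold setting,
and operator — propagate into relative-quantification results. It couples a
mechanistic amplification-curve simulator with known ground truth to a
Ct-calling engine, delta-Ct normalization, a six-variant ANOVA family, and
the standard battery of reproducibility analyses, so that every downstream
statistic can be validated against effects that were injected on purpose.

## The amplification-curve model

A well's fluorescence over cycles $c = 1, \dots, 40$ is modelled as

$$F(c) = b + \delta c + X(c) + \varepsilon(c), \qquad
X(c) = \frac{x_{max}\, x_0 (1+E)^c}{x_{max} + x_0\left((1+E)^c - 1\right)},$$

a saturating-growth (logistic-in-amount) curve with initial signal $x_0$,
per-cycle efficiency $E \in (0, 1]$ (amplification factor $1+E$; $E = 1$ is
perfect doubling) and plateau $x_{max}$, plus baseline $b$, optional drift
$\delta$ and noise. This is the simplest form that produces the four
canonical phases of a PCR curve — baseline, exponential, linear, plateau —
while keeping a closed-form exponential regime
($X(c) \approx x_0 (1+E)^c$ for $x_0(1+E)^c \ll x_{max}$) for analytic
tests: in that regime the Ct at threshold $T$ is exactly
$\log(T/x_0)/\log(1+E)$, and two thresholds differ by
$\log(T_1/T_2)/\log(1+E)$ cycles. Noise is multiplicative log-normal on the
amplification signal with a small additive floor; both vanish at
`noise_sd = 0`, which the determinism tests rely on.

## Ct calling

Fixed-threshold calling baseline-corrects first (subtracting the mean
fluorescence over a window, default cycles 3–15, which ends before the
earliest exponential phase this panel produces) and then locates the first
upward crossing of the threshold that stays above it for at least two
subsequent cycles. The sustained-crossing rule exists because single-point
crossings in a noisy baseline are artifacts. Interpolation between the
flanking cycles is log-linear, not linear, because fluorescence is
geometric in the exponential phase. Whether fixed thresholds should apply
to raw or corrected fluorescence is not standardized across instruments;
we correct first, as a configuration choice.

The instrument-style "automatic Ct" mode assigns one threshold per target
per plate. Vendor algorithms are unpublished; ours detects each curve's
exponential phase as the maximal cycle run over which the log2-fluorescence
slope is positive and uniform within tolerance, then places the threshold
at the geometric midpoint of the intersection of the per-curve
phase-fluorescence ranges (falling back to the pooled range when the
intersection is empty). This stand-in reproduces the property that matters
downstream: automatic thresholds differ across targets and plates, so Ct
values are only comparable after the $\log_2(T_t/T_R)$ correction. A well
never crossing within 40 cycles is *not expressed* and is treated as
missing everywhere — never recoded as Ct = 40.

## Delta-Ct and the threshold correction

With target Ct $C_t$ called at threshold intensity $T_t$ and reference
(RNU6) Ct $C_R$ at $T_R$, the package computes

* **FIXED**: $\nabla C_t = C_t - C_R$ (one common threshold; no
  correction needed);
* **VARIABLE_NORMALIZED**: $\nabla C_t = C_t - C_R - \log_2(T_t/T_R)$;
* **VARIABLE_COVARIATE**: $\nabla C_t = C_t - C_R$ with
  $\log_2(T_t/T_R)$ carried as a model covariate.

On ideal doubling curves $C_t = \log_2 T_t - \log_2 x_{0,t}$, so
$C_t - C_R = \log_2(T_t/T_R) + \log_2(x_{0,R}/x_{0,t})$: the raw
difference depends on the thresholds with coefficient exactly $+1$, and
subtracting $\log_2(T_t/T_R)$ removes that dependence. Consequently the
NORMALIZED-response regression is algebraically identical to the COVARIATE
regression with the threshold coefficient constrained at its
ideal-doubling-curve value ($\beta_4 = +1$ in the parameterisation
$\nabla C_t = \alpha + \dots + \beta_4 \log_2(T_t/T_R) + \varepsilon$),
and an unconstrained fit on ideal curves estimates $\beta_4 \approx +1$.
`fit_variant(..., constrain_beta4 =)` exposes the constraint so the
identity is testable exactly.

## The six-variant ANOVA family

The model on $\nabla C_t$ is
$\nabla C_t = \alpha + \beta_1\,\mathrm{Group} + \beta_2\,\mathrm{Operator}
+ \beta_3\,\mathrm{Group\times Operator} + \beta_4 \log_2(T_t/T_R) +
\varepsilon$ with 0/1 indicator coding (control = 0, case = 1;
operator 1 = 0, operator 2 = 1). Indicator rather than sum coding makes
$\beta_1$ directly the case-vs-control delta-delta-Ct, comparable to the
tabulated contrasts. The six variants are: both operators with operator
term and interaction; with operator term only; with neither; operator 1
only; operator 2 only; and the per-sample average of the two operators.
Subject is not a blocking factor: the error term deliberately pools
subject and operator/machine variability, matching how the summary tables
are computed. Degenerate designs (an interaction requested with a single
operator level) error rather than silently dropping terms.

## The synthetic study design

`study_preset("paper_design")` encodes the study-shaped conditions: 16
cases (colorectal advanced adenoma analog) + 16 controls, 11 target miRNAs
plus RNU6, two operators, duplicate wells, two extraction methods, and
plasma-extraction timepoints 0/12/24/48/72 h. A well's starting signal is
$x_0 = \mathrm{yield} \cdot 2^{-A}$ with

$$A = \mathrm{abundance} + \beta_{group}\,\mathbb{1}[\mathrm{case}]
 + \mathrm{shift}_{op} + d \cdot \max(0, t - L)
 + u_{subject} + v_{run} + w_{well},$$

all on the log2 (Ct) scale, because Ct is log-abundance and the published
variability cells are symmetric on that scale. Specific choices:

* **Abundances** place targets at their typical delta-Ct levels relative
  to the reference, which sits 4 Ct below the least dilute target level
  (an abundant reference, far above any detection limit; this shifts all
  delta-Ct levels by a constant without touching any variability
  statistic).
* **Group effects** use the published fold changes of the
  adenoma-associated targets ($-\log_2 \mathrm{fold}$ in Ct units) and the
  measured case/control miR-21 Ct difference (−1.3 Ct); unaffected targets
  get 0.
* **Noise** decomposes into between-subject biology
  ($\sigma_u = 1.5$ Ct), an operator-run component shared by the
  duplicates of one processing run ($\sigma_v = 1.05$ Ct for the
  trizol-like workflow, 0.6 for the miRNeasy-like workflow), and
  independent per-well noise ($\sigma_w = 0.5$ Ct). These values are set
  so the per-arm delta-Ct SD lands in the published 2–2.5 Ct range and the
  implied mean $|\Delta\Delta C_t|$ matches the published 1.79 (trizol) /
  1.12 (miRNeasy) levels via the folded-normal identity
  $E|N(0, \sigma_d)| = \sigma_d\sqrt{2/\pi}$. The run-level component is a
  deliberate refinement of a pure subject+well decomposition: duplicate
  wells agree far better than operators do in the published tables, which
  a two-component model cannot produce.
* **Methods** are abstracted to a yield factor (0.25 vs 1) and a
  detection limit ($2^{-30.3}$ vs $2^{-37}$ in $x_0$ units), solved so the
  expected not-expressed fraction matches the published 15% vs 0.14%
  under the preset's abundances and noise. Because the model has no
  per-target method interactions (pre-amplification chemistry is out of
  scope), the simulated dropout concentrates on the most dilute targets
  rather than spreading exactly as printed.
* **Degradation** is piecewise linear with a 12 h lag: no change at 12 h,
  then $d$ Ct per hour, with per-target slopes fitted to the published
  72 h shifts (e.g. 0.099 Ct/h for the miR-122 analog). The reference
  does not degrade — a uniform shift would cancel in delta-Ct.
* **Operator shifts** apply to non-reference targets only: a plate-wide
  shift affecting the reference identically would cancel in delta-Ct by
  construction of relative quantification, making the parameter
  unrecoverable and the design uninformative.
* **Seeding**: one master seed; every subject-, run- and well-level draw
  comes from its own stream keyed by the design coordinates, so removing a
  target or operator from a design never changes the other wells' draws.
  Key hashes pass through extra multiplicative mixing because adjacent
  `set.seed` values produce measurably correlated first draws.
* The repeated-acquisition sub-design defaults to 7 subjects (exposed as
  a parameter, since the source material is internally inconsistent about
  7 vs 12).

What passing tests on these simulations do **not** show: robustness to
pre-amplification artifacts, per-target extraction chemistry,
multicomponent dye effects, or plate-position effects, none of which are
modelled.

## Statistical kernel

Two-sample t-tests are computed from (mean, SD, n) summaries so published
table cells can be re-tested without raw data; the pooled (Student) form is
the default because the published p-values are reproduced exactly under
pooled variance, with Welch available. The inter-operator test is unpaired
on delta-Ct, as tabulated, even though both operators process the same
extracted RNA; with large shared between-subject variance this is
conservative (it can only understate significance), and it is exactly
calibrated when between-operator processing noise dominates — the
calibration study therefore runs under that independence null, and type-I
error is asserted at 0.05 ± 0.02 there. The chi-squared dropout test is
uncorrected Pearson by default (Yates by flag). The screening alpha
follows the FDR relation $f = \alpha m_0/(\alpha m_0 + \pi\, m_1)$ with
power $\pi$: at $m = 380$, $\pi_1 = 0.05$, $f = 0.05$, $\pi = 0.8$ it
gives $\alpha^* = 0.00222$. The published value for this design is 0.0038,
which the stated relation does not reproduce; the package implements the
relation and reports the discrepancy rather than reverse-engineering the
printed constant. Detectable effects solve the noncentral-t power equation
numerically. ROC/AUC for the logistic panel are in-sample (the original
validation split is not reconstructible from printed data) and the AUC is
verified against the concordant-pair rank statistic.

Missing values are excluded pairwise everywhere and counted; duplicate
wells are averaged on the Ct scale before delta-Ct (the scale on which
duplicate means are tabulated), with the expressed-replicate count
retained.

## Problem sizes and numerical tolerances

The simulation studies in the test suite use 200 seeds for effect
recovery (group effect, operator shift, degradation slope; each asserted
within 3 Monte-Carlo standard errors of truth) and 400 seeds for type-I
calibration, on reduced 3-target designs that preserve the 32-subject,
two-operator structure; a full-design run (11 targets + reference, both
methods, duplicate wells, curve-level calling) backs the acceptance
script. Analytic identities are asserted at $10^{-6}$ (threshold shifts,
normalized delta-Ct invariance) or exactly (the constrained-regression
identity); closed-form recovery of zero-noise fits at $10^{-8}$. The
geometric-growth check runs where the signal is below $2 \times 10^{-4}$
of the plateau, since the slope deviates by $\mathcal{O}(E\,x/x_{max})$
as saturation begins.

## Known limitations

Extraction methods differ only in yield, detection limit and run noise, so
per-target method effects (visible in the published trizol delta-Ct
levels) are not reproduced; the automatic-threshold rule is a documented
stand-in for unpublished vendor logic; and the logistic-panel metrics are
in-sample and optimistic by construction. Supplementary raw tables of the
source study were never deposited in a machine-readable archive, so the
analyses that would consume them are exercised on synthetic data only.
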