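---
title: "Modelling money-pain trade-off choices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling money-pain trade-off choices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmaversion)
```

## The scientific problem

In money-pain trade-off experiments a decision maker repeatedly chooses
between two options: a *more painful* option (more electric shocks, but a
money advantage) and a *less painful* one. The shocks land either on the
decision maker (self) or on an anonymous receiver (other), and the money is
either a gain or a loss, giving a 2 (context) x 2 (recipient) within-subject
design; pharmacological studies add a third within-subject factor
(placebo vs. oxytocin sessions). The quantity of interest is
*hyperaltruism*: a greater willingness to forgo money to spare another
person's pain than one's own.

`harmaversion` implements the full computational chain of such a study —
stimulus construction, a generative choice model, per-subject estimation,
group statistics, and a moderated mediation analysis — together with a
synthetic-cohort generator, so that every stage can be exercised and tested
without human data.

## The harm-aversion model

A trial is summarised by the positive differences $\Delta m$ (money, yuan)
and $\Delta s$ (shock count) between the two options. The value advantage
of the more painful option is

$$\Delta V = (1 - \kappa)\,\Delta m - \kappa\,\Delta s,$$

where $\kappa \in [0, 1]$ is the harm-aversion weight, estimated separately
per context x recipient cell. Choices follow a softmax with consistency
$\gamma > 0$. One subtlety deserves a note: written as a probability of the
*less* painful option with $+\gamma\Delta V$ in the exponent, the softmax
would make larger $\kappa$ *reduce* less-painful choices, inverting the
parameter's meaning. The package therefore uses

$$P(\text{less painful}) = \frac{1}{1 + e^{-\gamma(\kappa\Delta s - (1-\kappa)\Delta m)}},$$

equivalently $P(\text{more painful}) = \text{logistic}(\gamma\Delta V)$ —
the only orientation under which $\kappa_{other} > \kappa_{self}$ expresses
hyperaltruism. Estimation is bounded multi-start maximum likelihood
(`fit_subject()`): L-BFGS-B with an analytic gradient, $\kappa \in [0,1]$,
$\gamma \in (0, 50]$, restarts drawn uniformly in the box (300 in the
study-faithful profile, 50 in the CI profile). The $\gamma$ upper bound of
50 value units keeps the softmax numerically sane; estimates within 0.1% of
a bound are flagged rather than dropped (all-one-option responders are the
typical case — exclusion is a caller policy, not a fitting side effect).
Model variants sharing $\gamma$ across all cells, per context, or per cell
can be compared on summed BIC with `compare_specs()`.

## Trial construction

Difference pairs live on an exhaustive grid: $\Delta s \in \{1,\dots,19\}$
by $\Delta m \in \{0.2,\dots,19.8\}$ in 0.2-yuan steps, 1881 pairs. For
each of 60 desired trade-off ratios $\Delta m/(\Delta s+\Delta m)$, evenly
spaced on $[0.01, 0.99]$, the closest pool pair is selected per cell.
Numerical choices worth recording:

* **Tie-breaking.** Exact distance ties (e.g. ratio 0.5, where every
  $\Delta m = \Delta s$ pair is equally close) are resolved by a uniform
  draw from the tied set under the run's seed — magnitudes spread across
  trials, yet sets are bit-reproducible.
* **Feasibility.** The constraints "shock + difference < 20" and "money +
  difference < 20" are unsatisfiable at the grid corners the extreme ratios
  select ($\Delta s = 19$, $\Delta m = 19.8$); the package relaxes both to
  $\le 20$, the minimal relaxation that makes the published grid
  realizable, and draws the less-painful option uniformly from the
  (possibly singleton) feasible set.
* **Exact money arithmetic.** Money is held internally as integer counts of
  0.2-yuan units, so additive identities hold exactly and tests can use
  exact equality.
* **Loss trials** are gain trials with money signs flipped and the two
  options' amounts swapped, keeping the more painful option's money
  advantage (the smaller loss) and both difference magnitudes; the
  transform is an involution.
* **A known descriptive mismatch.** Selecting the closest pair to an even
  ratio grid *structurally* couples the differences (extreme ratios pin
  corner pairs such as $(19, 0.2)$), giving a $\Delta s$–$\Delta m$
  correlation near $-0.4$ in every variant we measured. A decorrelated set
  is not achievable under this construction; the raw option *amounts*, in
  contrast, are independent uniform draws and are uncorrelated. No test
  asserts a near-zero difference correlation.

Pain calibration is a two-parameter logistic scaled to the 0–10 rating
ceiling, $r(x) = 10/(1+e^{-(x-m)/w})$ — the simplest monotone sigmoid
consistent with a bounded scale (the functional form is not otherwise
constrained). It is fitted by bounded least squares; inverting it at rating
7 (`intensity_for_rating()`) gives $m + w\ln(7/3)$. Ratings that decrease
with intensity drive the width to its bound and are returned flagged, never
silently "fixed".

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` states a generative world whose causal order mirrors the
hypothesised psychology (and makes the mediation recoverable by
construction):

1. **Traits.** (IH, IB, EC) from a truncated multivariate normal;
   IH, IB on 1–7, EC on 1–5; defaults IH $\sim N(3,1)$, IB $\sim N(4,1)$,
   EC $\sim N(3.8, 0.6)$ with $\rho(EC, IH) = -0.3$,
   $\rho(EC, IB) = +0.3$ (the correlations are reported but not quantified
   in the task literature; these are configuration values, not claims).
2. **Harm framing** (−4..4 integer report): mean
   $\alpha_0 + \alpha_{IH}\,IH$ per context x treatment cell with
   $\alpha_{IH} = -0.75$ active in the gain context under placebo and in
   *both* contexts under oxytocin, zero in loss-placebo; intercepts chosen
   so mean framing is about 1.2 (gain) vs 0 (loss) under placebo and
   1.4/1.2 under oxytocin; noise SD 1.5.
3. **Harm aversion.** $\kappa_{self}$ logit-normal around 0.45 (placebo) or
   0.40 (oxytocin, encoding the treatment main effect), SD 0.5 logit units;
   $\kappa_{other} = \kappa_{self} + 0.05\,\text{framing} + \varepsilon$,
   clamped to $[0,1]$; $\gamma$ log-normal around 2.
4. **Choices.** Independent Bernoulli draws from the softmax above on a
   freshly generated 240-trial set per subject and session.

Effect magnitudes were calibrated once, before any acceptance run, against
the published statistics of this task family: the implied
placebo-gain hyperaltruism gap is about $0.06$ with a between-subject SD
near $0.1$, i.e. Cohen's $d \approx 0.5$–$0.6$ at $n = 46$ — matching the
printed $F_{1,45}$ values of roughly 9 (placebo gain) and 18 (loss
restoration) — and the mediated path product $a \cdot b \approx -0.75
\times 0.05$ sits on the scale of published moderated-mediation tables. An
earlier draft with a weaker pass-through (0.04) failed the configuration's
own documented contract ("defaults reproduce the qualitative pattern") at
realistic cohort sizes and was recalibrated against those printed
statistics; no parameter was adjusted after that.

What a green end-to-end test does **not** establish: the generator draws
i.i.d. trials (no learning, fatigue, or serial dependence), traits are
jointly normal rather than Likert-discrete, framing noise is homoskedastic,
and session order has no effect. Real data violate all of these; the tests
certify the *pipeline*, not the psychology.

All randomness flows from one master seed through named child streams
(`child_seed()`), so traits, trial sets, choices, and bootstrap draws can
be regenerated independently.

## Two-stage sensitivity analysis

The task literature analyses choice sensitivity with mixed-effect logistic
regressions (choice on $\Delta m$, $\Delta s$ and their interactions with
context, recipient, treatment, with per-subject random slopes). This
package deliberately ships a *two-stage* approximation instead: a
per-subject, per-cell penalized logistic fit (`subject_cell_logit()`:
intercept + $\Delta m$ + $\Delta s$, Newton iterations to gradient norm
$10^{-8}$), then group-level contrasts — the relative harm sensitivity
$other\,\beta_{\Delta s} - self\,\beta_{\Delta s}$ and its money analogue —
analysed with paired t tests and OLS. The per-subject contrasts are exactly
the quantities a study of this design analyses downstream, two-stage
estimation of them is standard, and the seam is explicit: a GLMM backend
can replace `cell_logits()` without touching anything downstream. The
four-way mixed-model interaction coefficient is *not* asserted numerically
anywhere; the two-stage analogue is only approximately equivalent.

Two ridge penalties appear, on purpose. The single-fit contract uses a
near-zero penalty ($10^{-4}$, slopes only) whose role is merely to keep
complete separation finite; oracle tests run at this value. The
cohort-level wrapper defaults to a much stronger 0.3: at realistic
consistencies roughly a third of 60-trial cells are quasi-separated, and
measured against known per-subject truth the stronger penalty more than
halves the residual noise of the other-self contrast (SD 1.3 to 0.55)
while the contrast keeps tracking the truth (with some amplification) —
a strictly better operating point for the sign-level group inference the
pipeline performs. Fits that remain separated are flagged and carried, not
dropped.

Trait regressions follow the study family's Table-1 layout exactly: OLS of
a per-subject x context outcome on intercept, EC, IH, IB, context
(1 = gain, 0 = loss), and the three trait x context interactions, classical
SEs, two-tailed p on $n - 8$ df, EC as a covariate of no interest (it
correlates with both utilitarian subscales). No multiple-testing
correction, matching the reporting convention; Bonferroni appears only in
the Friedman follow-ups.

## Moderated mediation

With $M$ the framing report, $Y$ the relative harm sensitivity, $DC$ the
context code and IH the instrumental-harm score:

* model M: $M \sim 1 + IH + DC + IH{\times}DC + IB + EC$
* model Y (screen): adds $IH{\times}DC$ and $M{\times}DC$ to model Y'
* model Y' (reported): $Y \sim 1 + IH + M + DC + IB + EC$

Under the gain = 1 coding, $a_{loss}$ is the IH coefficient of model M and
$a_{gain}$ adds the interaction; $b$ and $c'$ come from model Y'. Indirect
effects are $ab$ per context and the moderation index is
$\Delta ab = ab_{gain} - ab_{loss}$.

Inference choices, each genuinely open in the source material and decided
here: the bootstrap resamples **subjects** (both context rows travel
together) because the rows are repeated measures and row resampling would
understate uncertainty; intervals are **percentile** by default with
bias-corrected available behind `type = "bc"`; p-values are the
sign-proportion form $2\min(\hat F(0), 1-\hat F(0))$, the convention of
common mediation software. Determinism is guaranteed given a seed; B < 100
is refused outright.

One calibration subtlety: percentile CIs for a *product* are conservative
at the origin. Under the complete null ($a = b = 0$) the $\Delta ab$
interval covers zero essentially always (measured: 100% of simulations),
so nominal-coverage checks are run under the **no-moderation null**
($a_{gain} = a_{loss} \ne 0$, $b \ne 0$, hence $\Delta ab = 0$ through the
path difference) — the hypothesis the moderation index actually tests —
where measured coverage is 0.94–0.95 at $n = 200$.

## Classical statistics

All within-subject factors in this design have two levels, so the
repeated-measures ANOVA reduces to single-df contrasts: per subject
contrast scores give $SS_{effect} = nC\bar\theta^2$ against the
effect-by-subject error on $(1, n-1)$ df, partial
$\eta^2 = SS_e/(SS_e + SS_{err})$, and sphericity corrections are vacuous
(df are $(1, n-1)$ throughout). Simple effects are paired t tests within
moderator levels, reported as $F = t^2$. The Friedman test carries the
standard tie correction and offers an exact permutation p-value for small
tables; follow-ups are Bonferroni-scaled Wilcoxon signed-rank contrasts.
The published framing-test statistics for this task family are *not*
asserted numerically: the printed values do not match a standard Friedman
table lookup at any df, so only the test's structure is implemented.
Post-hoc regression power uses the noncentral F with
$\lambda = f^2 N$; at the published design (7 regressors, $N = 46$) the
competing convention $\lambda = f^2(df_1 + df_2 + 1)$ coincides exactly,
and `power(f2 = 0) = alpha` serves as an analytic self-check.

## Profiles, budgets, limitations

The `"ci"` profile (50 restarts, B = 1000) exists so the full pipeline on a
46-subject two-session cohort completes in about a minute; `"paper"`
(300 restarts, B = 5000) is the study-faithful setting. Known limitations:
no hierarchical pooling in estimation (per-subject MLE only), no
reaction-time modelling, no GLMM backend (yet) behind the two-stage seam,
and the synthetic world's simplifications listed above. The optional
loading of an external deposited dataset is intentionally out of scope of
the tested surface.
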