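---
title: "Group factor analysis of twin-pair difference data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group factor analysis of twin-pair difference data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The co-twin control design

Monozygotic (MZ) co-twins share their genotype, age, sex and much of
their rearing environment. Within-pair differences between trait
discordant MZ twins therefore isolate acquired, environment-driven
variation: whatever differs between the heavier and the leaner co-twin
cannot be explained by the genome. `twingfa` analyses such data in
difference form: for every non-shared variable the model input is

> value in the heavier twin − value in the leaner twin,

with heavier/leaner defined once per pair by BMI. The BMI difference
column is by construction strictly positive, and an exact BMI tie is a
hard error unless the user configures an explicit tie-break
(`order_pairs_by_bmi(..., tie_break = )`): the design presumes
discordance, and a silent arbitrary ordering would leak into every
downstream sign.

Variables that are common to both co-twins — genotype dosages, age,
sex, study year, liver-fat discordance status — carry their shared
value instead of a (zero) difference, so pair-level components can use
them. This is why the genotype view is special throughout: its entries
are risk-allele dosages 0/1/2 taken from either twin.

## Preprocessing rules

`preprocess_cohort()` applies, in order:

1. **Categorical encoding.** Smoking status (never / former / current)
   is one-hot encoded into three 0/1 columns at the twin level, so
   differences take values in {−1, 0, 1} and are all zero when both
   co-twins share a status.
2. **Cytokine missingness (25%).** Cytokine panels lose variables with
   more than 25% missing values, applied at the *twin* level because
   that is the level at which assay dropout occurs.
3. **Pair ordering and differencing** as above. A difference is missing
   when either twin's value is missing; nothing is imputed — the
   sampler handles missingness exactly.
4. **General missingness (50%).** Any difference-view column missing in
   more than half the pairs is dropped.
5. **SNP carrier band.** A SNP is kept only when the number of pairs
   carrying a nonzero dosage lies in [4, 38] out of 43: SNPs carried by
   ≤3 pairs are too rare to be informative, and SNPs carried by more
   than 38 pairs are nearly universal and cannot be linked to
   within-pair differences. We read "values in ≤3 samples" as a
   *carrier* count (a SNP with dosage 0 everywhere has "values" in
   every sample but carries no information); both bounds are
   configurable.
6. **Scaling.** All views except genotype are mean-centred and scaled
   to unit column variance over observed entries. Centring is not
   explicitly part of the study's description, which mentions only unit
   variance; we centre because the factor model has no intercept, and
   expose `center = FALSE` for the literal reading. The genotype view
   is left untouched (neither centred nor scaled), which lets
   mean-capturing dosage components emerge; its noise prior is adapted
   per column instead (below).

Each filter reports every removed variable with the statistic that
removed it, and all filters are idempotent.

## The model

For views $X^{(m)} \in \mathbb{R}^{N \times D_m}$, $m = 1 \dots M$,
with $N$ matched pairs:

$$
\begin{aligned}
x^{(m)}_n &\sim N\!\big(W^{(m)} z_n,\ \Sigma^{(m)}\big), &
z_n &\sim N(0, I_K),\\
w^{(m)}_{d,k} &\sim h_{m,k}\, N\!\big(0, (\alpha^{(m)}_{d,k})^{-1}\big)
  + (1 - h_{m,k})\,\delta_0, &
h_{m,k} &\sim \text{Bernoulli}(\pi_k),\\
\pi_k &\sim \text{Beta}(a_\pi, b_\pi), &
\alpha^{(m)}_{d,k} &\sim \text{Gamma}(a_\alpha, b_\alpha),
\end{aligned}
$$

with diagonal noise $\Sigma^{(m)} = \operatorname{diag}(1/\tau^{(m)})$
and $\tau^{(m)}_d \sim \text{Gamma}(a_\tau, b_\tau(d))$. All Gamma
distributions are shape–rate. The beta-Bernoulli layer gives
*component-wise* sparsity: a component is either entirely on or
entirely off in a view (the spike is an exact zero, enforced as an
invariant of the `gfa_state` container), and the set of views a
component is on in is learned from data. The ARD precisions
$\alpha$ additionally shrink individual loadings within active blocks.

### Hyperparameter defaults, and why

| parameter | default | meaning |
|---|---|---|
| `K` | 40 | components; chosen large, surplus components empty out |
| `a_pi`, `b_pi` | 1, 1 | uniform prior on component inclusion probability |
| `a_alpha`, `b_alpha` | 1e-3 | vague ARD prior (prior mean 1, huge variance) |
| `a_tau` | 14 | strength of the informative noise prior |
| `noise_target` | 1/3 | prior-mean residual variance, as a fraction of column variance |

The noise prior is the one deliberately informative piece: twin
difference data are noisy, and an uninformative noise prior lets early
sweeps explain everything as noise. The rate is set per column as
$b_\tau(d) = \texttt{noise\_target} \times (a_\tau - 1) \times
\widehat{\text{var}}_d$ so the prior mean residual variance is one
third of the observed column variance — exactly `noise_target` for
unit-variance columns, and proportionally scaled for the unscaled
genotype view. `a_tau = 14` gives the prior the weight of roughly a
dozen pseudo-observations against $N = 43$ actual ones: informative
but far from dominant; both knobs are exposed. The inclusion and ARD
defaults are standard weakly-informative choices; only the noise
target is pinned by the study protocol, and none of the four are
claimed as the study's (unreported) values.

## Gibbs sampler

`run_chain()` sweeps, in order: $Z$; then per view and component the
**blocked** pair $(h_{m,k}, w^{(m)}_{:,k})$; then $\pi$, $\alpha$,
$\tau$. Design notes:

- **Blocked spike–slab update.** $h_{m,k}$ is drawn with the slab
  weights integrated out: under diagonal noise the marginal likelihood
  ratio factorises over variables,
  $\log \mathrm{BF}_d = \tfrac12 \log (\alpha_d / q_d) +
  (\tau_d c_d)^2 / (2 q_d)$ with
  $q_d = \alpha_d + \tau_d \sum_{n \in \text{obs}} z_{nk}^2$ and
  $c_d = \sum_{n \in \text{obs}} z_{nk} r_{nd}$ on the residual
  excluding component $k$. Updating $h$ with $w$ held fixed would
  almost never leave the spike; the blocked update is what lets empty
  components switch on and off.
- **$\alpha$ refresh under $h = 0$.** Inactive precisions are redrawn
  from their prior each sweep. Freezing them instead would leave the
  chain targeting the wrong joint — the successive-conditional
  validation below detects exactly this class of bug.
- **Missing data.** Missing cells are simply dropped from every sum:
  the score precision $\Lambda_n$ is assembled per sample from
  observed cells, $q_d$/$c_d$ use observed rows, and the $\tau$ update
  counts only observed residuals. This is exact under ignorable
  missingness; no imputation step exists.
- **Numerics.** Bayes factors are accumulated in log space;
  $\Lambda_n$ is solved by Cholesky factorisation (never inverted);
  samples with complete rows share one factorisation.
- **Initialisation.** All components start active with loadings
  $N(0, 0.1^2)$, $\alpha = 1$, $\tau$ at its prior mean. Starting from
  a draw of the vague ARD prior would initialise loadings at
  astronomical scale; starting all-active lets surplus components die
  rather than requiring rare activation events.
- **Protocol.** Defaults are 2000 sweeps, the first 90% discarded, no
  thinning: 200 retained draws. `H` and `pi` draws are stored in full;
  loadings, scores and precisions as streaming means/variances, which
  bounds memory at the study scale (D ≈ 3400, K = 40). The full log
  joint is recorded every sweep as a convergence trace; no formal
  diagnostic is applied for the user.

### How the sampler is validated

Three layers, all in the test suite:

1. **Per-conditional oracles**: closed-form conjugate moments for
   $\pi, \alpha, \tau$; the analytic Gaussian conditional for $Z$
   (including a missing cell); 1-D numerical quadrature over the slab
   weight for the activation probability.
2. **Getting-it-right**: on an $N=5$, $M=2$, $D=(3,4)$, $K=2$
   instance, $2 \times 10^5$ successive-conditional sweeps
   (regenerate data / one Gibbs sweep) are compared with
   marginal-conditional prior draws on five monitored moments
   ($\pi_1$, $\sum h$, $w^2$, $\tau$, $z^2$) within 4 standard errors
   (batch means on the chain side). This jointly validates every
   conditional against the joint density. The test uses moderate
   hyperparameters ($a_\alpha = b_\alpha = 2$, $a_\tau = 3$): under
   the vague 1e-3 defaults spike–slab transitions are so rare that no
   finite chain traverses the indicator space, and the comparison
   would be uninformative about exactly the transitions it is meant
   to check. The code path is identical; the hyperparameters are
   arguments.
3. **Parameter recovery**: data simulated from the model ($N = 100$,
   $D = (30, 40, 50)$, six true components, one-third noise) and
   refitted at $K = 15$ recover the planted components and activity
   mask (see below).

## Component summaries

- `component_activity()`: posterior mean of $h_{m,k}$, thresholded at
  0.5 by default. The study gives no numeric rule for calling a
  component empty; posterior inclusion below one half in every view is
  our documented choice, and the threshold is an argument.
- `prune_empty_components()`: a component inactive everywhere is
  empty; its presence is evidence K was large enough.
- `variance_explained()`: with unit-variance scores, component $k$
  contributes $\sum_d \bar w_{d,k}^2$ of expected variance to view
  $m$; fractions are taken against all components plus the posterior
  mean residual variance, so per-view fractions sum to at most 1.
- `match_components()`: the model is identifiable only up to
  permutation and sign of components, so estimates are compared to a
  reference by an exact optimal assignment (Hungarian algorithm)
  maximising summed |Pearson r| between score columns; constant
  columns get r = 0 and sort to the back. Matching a posterior against
  simulation truth also reports the fraction of view-by-component
  activity calls agreeing with the planted mask over matched
  components.

## The synthetic twin cohort

No twin data ship with the package; `simulate_twin_cohort()` generates
cohorts with the statistical structure the analysis assumes, plus
ground truth:

- 43 pairs, exactly 25 of them BMI-discordant beyond 3 kg/m²
  (discordant differences are drawn as 3.2 + Exp(mean 2.5) kg/m²,
  concordant ones uniform below 3), pair BMI means around 27.5 kg/m²;
- five views at scaled-down dimensions 20/20/60/60/20 by default
  (`preset = "study"` switches to 42/71/1587/1605/63);
- the four continuous views are an exact draw from the GFA model with
  a known activity mask over six components, per-variable signal
  variance normalised to $1 - \texttt{noise\_target}$ so columns have
  unit total variance and residual variance 1/3;
- twin-level values are reconstructed as pair mean ± half the planted
  difference, so preprocessing recovers the planted difference
  matrices *exactly* (this identity is a test);
- genotype is pair-identical Hardy–Weinberg dosage data with minor
  allele frequencies uniform on (0.05, 0.5) — deliberately carrying no
  within-pair signal, since MZ genotype differences are zero by
  design; the default cohort mask therefore has an all-zero genotype
  row;
- methylation-like columns are affinely squashed into [0, 1], with the
  ground-truth loadings and noise precisions rescaled by the same
  factor so the planted view remains an exact model draw (the model is
  applied to beta-value differences directly; no logit transform);
- smoking is a three-level categorical at the twin level; gender, age
  and study year are pair-constant;
- missingness is injected completely at random at per-view rates
  (defaults 2–5%, 0 for genotype). MCAR is the only mechanism the
  study's ignorable-missingness treatment is exact for; the hook
  accepts forced high-missingness columns to exercise the filters.

What the generator does **not** emulate: linkage disequilibrium among
SNPs, spatial autocorrelation of methylation, compositional structure
of dietary intakes, non-Gaussian tails of cytokine panels, or any
informative missingness. Passing recovery tests therefore show the
inference machinery is correct under the model's own assumptions — not
that real twin cohorts satisfy those assumptions.

### Recovery study design

The recovery experiment ($N = 100$, $M = 3$, $D = (30, 40, 50)$,
$K_{\text{true}} = 6$, fit at $K = 15$, 2000 sweeps) uses an activity
mask whose six components occupy six *distinct* active-view subsets
({1,2,3}, {1,2}, {1,3}, {2,3}, {1}, {2}). Distinctness matters: two
components active in exactly the same views are, under a Gaussian
slab, jointly identified only up to rotation within their plane, so
per-component score recovery is not a well-posed target for them
(their combined subspace and the activity pattern still are).
The empty-component study fits $K_{\text{true}} = 3$ data
($N = 60$, $D = (15, 20, 25)$) at $K = 10$ over 20 seeds and examines
the mode of the retained-component count; 600 sweeps suffice at this
size. These problem sizes are the package's validation conditions,
chosen so the whole suite runs comfortably on a laptop core.

## Known limitations

- Single chain, matching the study protocol; nothing prevents running
  several chains and aligning them with `match_components()`, but no
  automatic multi-chain diagnostic is provided.
- Under the vague ARD default, a component that empties mid-run
  re-activates only rarely; the all-active initialisation mitigates
  this, and the moderate-hyperparameter validation shows the updates
  themselves are exact.
- Ignorable (MCAR/MAR) missingness is assumed throughout.
- Diagonal noise only; no Student-t or count likelihoods.
- `variance_explained()` uses posterior means, not per-draw
  decompositions; with strongly multimodal posteriors the summary can
  blur modes.
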