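---
title: "Interval estimation of population allele frequencies from bulk-sample qPCR: models and methods"
author: "bulkCq package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bulkCq methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bulkCq)
```

## The estimation problem

Monitoring a specific allele (a pesticide-resistance mutation, an invasive
genotype, a contaminating seed line) at low population frequency is
labour-limited when every individual must be genotyped separately. Pooling
individuals into *bulk samples* and quantifying the allele ratio of each pool
by real-time PCR reduces handling cost, but introduces two layers of
uncertainty that a binomial model of individual genotyping does not have:

1. the number $m$ of carrier (R) individuals among the $n$ individuals of a
   pool is latent, $m \sim \mathrm{Bin}(n, p)$ for population frequency $p$;
2. individuals contribute unequal DNA amounts, so even given $m$ the pool's
   allelic ratio is random.

`bulkCq` implements a full likelihood treatment of both layers for
$\Delta\Delta$Cq-type qPCR designs, yielding a point estimate *and* an
asymptotic confidence interval for $p$ from as few as two bulk samples.

## DNA yield model

Per-individual DNA yield at one locus is modelled as gamma,
$X \sim \mathrm{Ga}(k, \theta)$. Gamma additivity then gives the pool's
allelic amounts $X_R \sim \mathrm{Ga}(mk, \theta)$ and
$X_S \sim \mathrm{Ga}((n-m)k, \theta)$ independently (a shape-zero gamma is
the constant 0), and the pool's allele ratio
$Y_R = X_R/(X_R + X_S) \sim \mathrm{Beta}(mk, (n-m)k)$. The shape $k$ tunes
yield variability: $k = 1$ is exponential (highly variable yields, e.g.
body-size variation plus degradation), large $k$ approaches equal
contributions. The scale $\theta$ cancels from every observable ratio and is
not identifiable; computations fix it to 1 without loss.

## The Cq observation model

Each bulk sample yields a quartet of quantification cycles: housekeeping and
target locus, each under a control (undigested, condition 0) and a test
(digested or allele-specific-primer, condition 1) condition. With
amplification factor $1 + \eta$ per cycle, threshold $X_\Theta$ (fixed at 1;
all template quantities are relative to it), target-to-reference content
ratio $\delta_T$, digestion change rate $\delta_B$, and residue rate $z$ (the
fraction of the susceptible allele surviving digestion, or amplified
off-target by a specific primer), the noise-free quartet is the log-linear
model of `expectedCq()`; each measured Cq adds independent
$N(0, \sigma_c^2)$ error.

Differencing target against housekeeping within a condition gives
$\Delta\tau_W$ and $\Delta\tau_D$ (each $N(\cdot, 2\sigma_c^2)$), and
differencing the conditions gives
$\Delta\Delta\tau = -\ln\{(X_R + zX_S)/(X_R+X_S)\}/\ln(1+\eta) + \varepsilon$,
from which $X_\Theta$, $\delta_B$ and $\delta_T$ have cancelled. The same
structure covers both the restriction-enzyme protocol (control = undigested
aliquot of the same extract) and the allele-specific-primer protocol
(control = pure-R reference solution): the pure-R control quantity cancels
within its $\Delta\tau$ exactly as $\delta_B$ does, so downstream code is
identical and `BulkCqData` only records which protocol the labels refer to.
Because $z > 0$, an all-susceptible pool still produces a finite expected
$\Delta\Delta\tau$ of $-\ln z/\ln(1+\eta)$ — about 9.5 cycles at the default
assay values — which is what makes rare-allele data informative at all.

## Marginal likelihood of one bulk sample

The per-sample observables are the pair $(\Delta\tau_W, \Delta\tau_D)$; they
share no Cq terms, so under the error model their densities multiply.
$\Delta\tau_W$ depends only on $(\delta_T, \eta, \sigma_c)$. For
$\Delta\tau_D$ the carrier count is marginalized:

$$P(\Delta\tau_D) = \sum_{m=0}^{n} \mathrm{Bin}(m \mid n, p)\,
  P(\Delta\tau_D \mid m),$$

where $m = 0$ and $m = n$ give plain normal densities (means
$-\ln(z\delta_T)/L$ and $-\ln\delta_T/L$, $L = \ln(1+\eta)$) and interior $m$
require marginalizing the latent ratio: the beta kernel `psiBeta()`
(single integral over $Y_R$) or the equivalent gamma kernel `psiGamma()`
(double integral over $(X_R, X_S)$; slower, kept as an independent
cross-check and compatibility path). The mixture is accumulated in log space;
binomial weights underflow long before they matter scientifically.

### Numerical quadrature

The integrands couple a normal kernel whose mean moves like
$-\ln\{z + y(1-z)\}/L$ — i.e. on a *relative* $y$ scale — with beta densities
that may be singular at the endpoints ($mk < 1$) or sharply concentrated
($mk \gg 1$). Three design choices follow:

* **Adaptive reference path.** `psiBeta()` integrates in $\log y$ below
  $1/2$ and $\log(1-y)$ above, with segment breakpoints where the normal
  kernel is centred ($\pm$ up to 8 SD). In these coordinates both the
  endpoint behaviour and arbitrarily deep tail features stay resolvable;
  the slivers $y < 10^{-6} z$ and $1 - y < 10^{-7}$ enter as atoms with the
  limiting means. `psiGamma()` applies the same idea twice ($\log r$ inner,
  $\log s$ outer, with segment anchors at the kernel's $(r, s)$ saddle),
  which is also why its $\theta$-invariance is numerically exact.
* **Fixed-rule fitting path.** Inside optimization, adaptive calls per
  sample, per $m$, per iteration would dominate runtime. The fitting engine
  instead builds one composite Gauss–Legendre grid per pool size (panels on
  the same log coordinates, edges augmented by beta quantiles, 8 nodes per
  panel by default), folds the binomial weights into the node weights, and
  evaluates the whole mixture for all samples of a pool size as a single
  weighted log-sum-exp. Grid geometry is cached against a lightly quantized
  $k$; the $k$- and $p$-dependent weights are recomputed exactly at every
  evaluation, so the objective stays smooth in all parameters. The two
  engines agree to about $10^{-4}$ in log-likelihood over the simulation
  conditions, and the default panel density is tuned for assay-scale noise
  ($\sigma_c \gtrsim 0.05$ cycles); `quadNodes` raises the density for
  unusually precise data.
* **Failure containment.** A non-finite objective evaluation returns a large
  finite penalty ($10^{12}$) so the quasi-Newton iteration survives wild
  intermediate parameter proposals.

## Frequency estimation

`estimateFreq()` maximizes the total log-likelihood over
$(p, k, \delta_T, \sigma_c)$, with $(z, \eta)$ fixed from calibration, by
`nlm()` on a transformed scale — logit for $p$, log for the positive
parameters — so back-transformed Wald intervals respect the domains (the
$p$ interval always lies in $[0,1]$, and the log-scale intervals are
multiplicatively symmetric). Standard errors come from the inverse of the
finite-difference Hessian at the optimum. A parameter whose inverse-Hessian
diagonal is not positive is reported without an interval; `fitSuccess()`
exposes both the per-parameter flags and the all-parameter flag. At least
two bulk samples are required — one sample gives two observables against up
to four parameters.

Starting values: $k$ from 1 (the exponential distribution; starting at large
$k$ is numerically fragile, and $k$'s likelihood information is weak, so the
fit is deliberately anchored at the variable-yield end), $p$ from the simple
averaging estimator clipped to $[10^{-3}, 1-10^{-3}]$, $\delta_T$ from 1,
$\sigma_c$ from 0.3 cycles. `fixK` fixes the shape (commonly `fixK = 1`),
which markedly improves interval-estimation success at small sample sizes
while scarcely moving $\hat p$ once the total sample size exceeds the
rule-of-three threshold $3/p$.

The simple averaging estimator $(1+\eta)^{-\overline{\Delta\Delta\tau}}$ is
provided by `conventionalFreq()` for comparison. It is biased downward as a
fixed total sample is divided into more pools (its average runs on the log
scale while the frequency is linear) and its naive interval can exceed 1;
both behaviours are exercised in the test suite.

### Boundary plateaus

When a dataset contains no carrier signal at all, the likelihood of $p$
decreases monotonically towards the $p = 0$ boundary, i.e. a plateau in logit
space. The optimizer then parks at some machine-precision-dependent point
whose curvature may underflow the finite-difference Hessian, in which case no
interval is returned. This is reported honestly rather than patched: with
data that cannot bound $p$ from below, interval-estimation failure is
informative, and the success-rate summaries of the grid harness quantify
exactly this as a function of design size.

## Calibration from known mixing ratios

The auxiliary parameters cannot all be estimated from field samples: $z$ is
structurally unidentified there and $\eta$ is fragile. `calibrateKnown()`
estimates all six assay parameters
($\mathrm{meanDNA} = X/X_\Theta$, $\delta_T$, $\delta_B$, $\sigma_c$, $z$,
$\eta$) from Cq measurements on solutions mixed from pure lines at known
ratios, each observation modelled as
$N(\mathrm{knownCqMean}(\cdot), \sigma_c^2)$. Incomplete designs — e.g.
measuring the undigested condition only on the pure-R solution, a common
thermal-cycler capacity compromise — are accepted (`paired = FALSE`);
identifiability pre-checks name the parameter that a degenerate design
leaves unconstrained.

Internally $\sigma_c$ is profiled out (its conditional MLE is the RMS
residual) and the five structural parameters are fitted as a nonlinear
least-squares problem by Levenberg–Marquardt, which remains accurate along
the softly identified meanDNA–$\eta$ direction and in the zero-residual
limit. Wald intervals come from the full six-parameter observed information
at the optimum; all parameters are fitted on the log scale, so the intervals
are multiplicatively symmetric. $\sigma_c$ is a free likelihood parameter
with its own interval, not a plug-in residual SD.

`linearityDiagnostics()` reproduces the classical assay validation: observed
$\Delta\Delta$Cq (or its linear-scale transform) regressed on the theoretical
value at the known ratio, with adjusted $R^2$ and a Breusch–Pagan
heteroscedasticity test in the $n R^2_{aux}$ (studentized) form, df = 1. Where a
design measures the control condition only at ratio 1, each replicate's
ratio-1 $\Delta\tau_W$ is reused across ratios — this leaves point estimates
unaffected but makes the diagnostic's implied $\sigma_c$ an underestimate,
one reason the likelihood fit uses raw Cq values instead. A sound assay is
homoscedastic on the Cq (log) scale and typically heteroscedastic on the
linear scale; the packaged synthetic example reproduces that contrast.

## The simulator and grid harness

`simulateBulkCq()` draws a dataset exactly from the generative model
($m_h$, then the gamma amounts with $\theta = \mathrm{meanYield}/k$, then
four independent Cq noises per sample — the $4\sigma_c^2$ variance of
$\Delta\Delta\tau$ emerges rather than being injected) and retains the
latent pool states for oracle tests. Defaults mirror a calibrated
restriction-digest assay on spider mites: $\delta_T = 1.2$,
$\delta_B = 0.24$, $z = 0.0016$, $\eta = 0.97$, $\sigma_c = 0.2$, mean
individual yield $10^{-6}$ relative to the qPCR threshold.

`gridDesigns()` enumerates the package's reference experiment: frequencies
$p \in \{0.01, 0.05, 0.1, 0.25, 0.5, 0.75\}$, shapes
$k \in \{1, 3, 9, 27\}$, and every power-of-two layout of $N \in [2, 64]$
bulk samples of $n \in [1, 64]$ individuals with total size
$4 \le Nn \le 128$ — 26 layouts, 624 regions. `runGrid()` simulates and fits
each region with one RNG stream per (region, replicate) derived from a
master seed by a fixed counter, records every attempt (including failures),
and summarizes per-region success rates and quartiles of the estimate and CI
bounds, for the likelihood and the simple-averaging estimators side by side.

```{r grid-example}
g <- gridDesigns()
sub <- g[g$p == 0.05 & g$N == 8 & g$n == 2, ]   # 16 individuals, split by 8
res <- runGrid(sub, replicates = 150, seed = 1)
median(res$replicates$pLower, na.rm = TRUE)     # about 0.009
median(res$replicates$pUpper, na.rm = TRUE)     # about 0.34
```

## Problem sizes used in the shipped checks

The package's own checks run the science at deliberately chosen sizes: the
kernel-equivalence grid at 80 parameter points; likelihood validation
against $10^6$-draw Monte Carlo at 20 random parameter points; recovery and
coverage at 200 replicates per condition; the full 624-region grid at 2
replicates per region (per-region success rates are equally weighted in the
overall rate, so a small per-region replicate count gives an unbiased
overall estimate with a standard error near one percentage point); and the
headline `ntotal = 16` interval experiment at 150 replicates per shape
level. These sizes are the package's choices for routine verification;
nothing prevents a user from rerunning `runGrid()` at 1000 replicates.

## What the synthetic data do and do not show

Everything stochastic in the tests is generated from the package's own
model, so green checks demonstrate internal consistency — correct
likelihood, calibrated intervals, unbiasedness under the stated assumptions
— not field validity. Real data deviate in ways the generator does not
emulate: technical-replicate structure (average replicates first;
`averageTechReps()`), non-gamma yield distributions, per-primer efficiency
differences (the model assumes one shared $1+\eta$; fitting $\delta_T$ on
known-ratio samples absorbs part of such differences), plateau-phase PCR
artefacts, and pipetting errors correlated across channels. The packaged
file `mite_red_ddcq_synthetic.csv` is likewise a *synthetic* stand-in
emulating the layout of a published mite calibration series (10 mixing
ratios, 4 replicates, undigested rows only at ratio 1) with realistic
parameter values; it exists so examples and diagnostics run on a
fixed, shareable table, not as a substitute for laboratory data. It is
reproducible exactly as

```{r fixture}
p <- QpcrParams(eta = 0.9712, deltaT = 1.170, deltaB = 0.2361,
                z = 0.001564, sigmaC = 0.2376, meanDNA = 1.256e-6)
writeCqTable(simulateKnownRatio(p, seed = 20211209), "mite_red_ddcq_synthetic.csv")
```

## Known limitations

* Wald/Hessian intervals only; no profile-likelihood or Bayesian intervals.
* Haploid pools; regular ploidy requires reinterpreting $n$ as allele count
  and is untested here.
* One housekeeping gene; multiple internal references and per-channel
  replicate variance models are out of scope.
* The fixed-rule engine's default panel density assumes assay-scale Cq noise
  (see `quadNodes`).
* Wall-clock behaviour: beta-kernel fits with fixed $k$ are fastest; the
  gamma kernel is several-fold slower and exists for cross-checking.
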