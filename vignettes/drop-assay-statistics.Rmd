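---
title: "Statistical methods for drop-off plaque titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for drop-off plaque titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagodrop)
```

## The assay and its titer model

A drop-off (direct spot) plaque assay deposits small drops — here 5 µL —
of ten-fold serial dilutions of a phage suspension onto an agar plate
overlaid with a bacterial lawn, in triplicate per dilution. After
incubation, each drop shows either nothing (`no_lysis`), individual
countable plaques (`counted`), or confluent clearance where plaques have
merged (`confluent`). The titer of the undiluted suspension follows from a
single countable spot:

$$T = \frac{c}{v}\,\times 10^{k}\quad
  \left[\frac{\mathrm{PFU}}{\mathrm{mL}}\right],$$

where $c$ is the plaque count, $v$ the drop volume in mL, and $k$ the
dilution exponent (dilution factor $10^{-k}$). `titer_from_count()`
implements exactly this; it is linear in the count, and one serial step
multiplies the titer estimate by ten.

Counts are Poisson: a drop of volume $v$ from a dilution with
concentration $C$ contains $\mathrm{Poisson}(Cv)$ infectious particles.
This makes the relative counting error of a triplicate with mean count
$N$ per spot approximately $1/\sqrt{3N}$, and the *within-triplicate*
coefficient of variation concentrate around $100/\sqrt{N}\,\%$ — the
reason the package flags precision rather than trusting any single count.

## Quantification rules

`quantification_rules()` bundles the thresholds that decide which dilution
is quantifiable:

* `min_countable = 1` plaque/spot. A spot with zero plaques carries no
  titer information; there is no tradition of a higher lower bound for
  spot assays (unlike the 30-plaque rule of full-plate assays), so the
  floor is one plaque.
* `max_countable = 50` plaques/spot. Beyond roughly 50 plaques in a 5 µL
  footprint, plaques overlap and counting becomes unreliable; spots past
  the ceiling are scored `confluent`.
* `cv_acceptable_percent = 15`. Triplicates with CV below 15% are flagged
  precise; by the Poisson law this needs a mean count of at least about
  $N = (100/15)^2 \approx 45$, and empirically assays reach it from
  roughly 15 PFU/spot upward because pipetting adds little on top.
* `min_reliable_pfu = 15` is that empirical guideline. It is a *flag*,
  never an exclusion: a triplicate of 5-plaque spots still yields a valid,
  if noisy, titer.

### Dilution selection

For each dilution, anomalies are first resolved into *effective replicate
counts* (below). A dilution is quantifiable when

1. it retains at least two effective counts (a single replicate gives no
   dispersion estimate, so the pipeline refuses to call it a titer),
2. every effective count lies in `[min_countable, max_countable]`, and
3. no replicate at that dilution is confluent — a confluent neighbour
   means the dilution straddles the ceiling and the readable counts are a
   downward-censored sample.

Among quantifiable dilutions the one with the **largest mean count** wins:
it has the most counting information, hence the smallest Poisson CV. The
remaining outcomes are classified by what the series shows:

* `no_activity` — no spot anywhere shows lysis;
* `excluded_unreliable_count` — even the highest tested dilution is still
  past the ceiling, so no reliable count exists;
* `excluded_no_pfu` — clearance at low dilutions without individual
  plaques at higher ones. This is the signature of lysis from without or
  abortive infection: killing at high dose without a productive viral
  cycle. Such series must not be scored active, and no rules
  configuration can coax a titer out of them.

### Anomaly resolution

Two robot-specific irregularities are handled explicitly:

* **Coalescence** (`merged`): two adjacent replicate drops merge on the
  agar. Both records carry the blob's combined count and symmetric
  `merge_partner` indices; each partner contributes *half* the combined
  count as its effective count. Halves are kept fractional — titer
  arithmetic is linear and rounding would bias it — and the resolution
  conserves the triplicate's total plaque count. An unreadable blob (a
  confluent partner) counts as confluent.
* **Missed drop** (`no_drop`): the drop stayed on the tip. It contributes
  nothing, reduces the usable replicate number (flag
  `missing_replicate`), and a triplicate reduced below two replicates is
  not quantified.

## Potency: EOP and the phagogram

Efficiency of plaquing compares a phage's titer on a test strain with its
titer on its reference host, titrated in parallel:

$$\mathrm{EOP} = \frac{T_\mathrm{test}}{T_\mathrm{reference\ host}}.$$

Classification uses the conventional bands, implemented as half-open
intervals so every positive EOP is classified (the printed literature
bands leave a gap between 0.099 and 0.1, and EOP can legitimately exceed
1 when the test strain supports better plaquing than the host):
$[0.1, \infty)$ highly virulent, $[0.001, 0.1)$ moderately virulent,
$(0, 0.001)$ weakly or avirulent. `build_phagogram()` assembles the
phage × strain matrix, forces the reference cell to exactly 1, maps
`no_activity` to `not_active` and exclusions to `not_evaluable`, and
requires an *explicit* reference-host map — for a cocktail there is no
principled default host, so the package never guesses one.

```{r eop}
classify_eop(c(2, 0.3, 0.02, 2e-4))
```

## Method agreement

Titers are ratio-scale measurements spanning decades, so all agreement
statistics work on $\log_{10}$ values.

**Bland–Altman, ratio form.** For pairs $(x_i, y_i)$ measured by the
reference and evaluated method, let $\ell_i = \log_{10}(y_i/x_i)$. The
bias is the geometric mean ratio $10^{\bar\ell}$, the 95% limits of
agreement are $10^{\bar\ell \pm 1.96\,s_\ell}$, and the bias CI uses the
$t$ distribution with $n-1$ df on the log scale (the CI convention is the
package's choice; limits follow the standard ±1.96 convention). Swapping
the methods inverts the bias exactly.

**Lin's concordance correlation coefficient.**

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with population ($n$-denominator) moments; the CI applies the Fisher
$z$ transform with Lin's 1989 variance formula. By construction
$|\rho_c| \le |r|$ (it penalises location and scale shift on top of
correlation loss). The default scale is $\log_{10}$: on the raw scale the
largest tube dominates all moments. A `ccc_scale = "raw"` option exists.
On the packaged fixture both conventions give ≈ 0.99.

**Variability comparison.** Per-group CVs of the two methods are compared
after a normality gate: a one-sample Kolmogorov–Smirnov test of each group
against a normal with sample-estimated moments. With estimated moments
the KS test is anti-conservative at small $n$ — it passes groups too
easily — which is why the branch actually taken (Student's equal-variance
$t$ or Mann–Whitney) is always part of the output rather than hidden.
Welch's form is available by option.

```{r agreement}
rep <- method_comparison_report(table1_titers())
rep
```

The packaged fixture (`table1_titers()`) holds 16 paired titers of one
virulent coliphage on its host — four dilution tubes × four independent
replicates, manual vs automated pipetting; `table1_summary()` carries the
published per-tube summaries for regression testing.

## The simulator

`simulate_assay()` generates complete factorial spot tables with known
ground truth. Its generative model, per phage–strain pair:

1. **Serial dilution.** $C_0$ is the stock; each transfer multiplies by
   $\varepsilon_k/10$ with $\varepsilon_k$ lognormal, *median 1*,
   CV `pipetting_cv` (default 0.05). A multiplicative, compounding error
   is the natural model for volumetric transfer and is what makes the
   downstream ratio-scale analysis appropriate; median-1 keeps the
   dilution unbiased on the log scale.
2. **Spotting.** With probability `p_no_drop` (default 0.0093) the drop
   never lands. Otherwise its volume is jittered (lognormal, CV
   `drop_volume_cv`, default 0.02) and the count is
   $\mathrm{Poisson}(Cv)$. Zero counts read `no_lysis`, counts above
   `max_countable` (default 50) read `confluent` — the package does not
   model a separate lawn-clearance threshold.
3. **Coalescence.** Within each replicate set, adjacent pairs are
   examined in order; each still-free pair of landed drops merges with
   probability `p_coalescence` (default 0.0197). A drop merges with at
   most one partner, triple merges are not modelled, and merges never
   cross phages or dilutions. Drops merge whether or not they carry
   plaques — the physical event is on the liquid, not the lysis — so
   even an all-negative panel shows merged (zero-count) spots.

The default anomaly rates, drop volume, triplicate layout and 8-step
series are the operating conditions of the validated instrument;
`example_susceptibility()` reproduces the shape of a large screening
campaign (126 strains × 11 phage wells, 151 susceptible interactions,
stocks above $10^8$ PFU/mL, positive titers log-uniform up to
$7\times10^{10}$).

Note one accounting subtlety: with a *per-pair* merge probability $p$,
the expected fraction of *spots* in merged state in triplicates is
$\tfrac{2}{3}(2p - p^2) \approx 1.33\,p$, not $p$.
`estimate_anomaly_rates()` therefore estimates $p$ itself — merge events
over sequentially eligible adjacent pairs, which is an exact binomial
experiment and gets exact Clopper–Pearson intervals — and reports the
merged-spot fraction alongside.

```{r simulator}
set.seed(1)
pan <- example_susceptibility(n_strains = 20, n_phages = 4, n_positive = 12)
cfg <- simulation_config(pan$susceptibility, pan$strain_ids, pan$phage_ids)
sim <- simulate_assay(cfg, seed = 2)
table(sim$spots$status)
```

**Reproducibility.** One seeded generator drives the whole assay; all
draws are vectorised in a fixed order (strains, then phages, dilutions,
replicates), so the same seed yields a byte-identical table and different
seeds change anomaly placements but never the table shape. Per-plate
sub-streams were considered and rejected: base R has no cheap independent
sub-stream API, and the fixed-order single stream gives the same
guarantee without one.

**Run planning.** `plan_run()` reproduces the instrument's throughput
arithmetic — spots per plate, plates per strain, runs, and the
$3vn + 10$ µL aspiration volume per tip for $n$ plates per run (three
replicate drops per plate plus dead volume).

### What the simulator does and does not emulate

It emulates the *counting statistics* of the assay: Poisson plaques,
compounding pipetting error, drop failures, coalescence, the countability
ceiling. It does **not** emulate plaque morphology and size (large
plaques merging below 50 counts), spatial position on the plate, reader
(counting) error, inter-observer differences, agar dryness effects, or
phage–bacteria kinetics. Tests that pass against the simulator therefore
validate the pipeline's arithmetic and decision rules under the stated
error model — not the biology of any particular phage collection.

## Numerical and testing choices

* Fractional effective counts (halved blobs) are never rounded.
* Exclusion statuses carry no numeric fields at all, rather than NA-laden
  partial results.
* CSV writers fix scientific notation to `%.6e` so diffs are stable
  across platforms.
* The test suite checks the Poisson precision law with the **pooled** CV
  estimator $100\sqrt{\overline{s_i^2}}/\overline{\bar x_i}$, which is
  consistent for the common CV. The mean of per-triplicate sample CVs is
  *not* used as the estimate because with $n = 3$ the sample CV carries
  the classic small-sample downward bias (factor ≈ $c_4 = 0.886$), about
  −10% — a property of the estimator, not of the simulated data. The mean
  CV is still used for the qualitative check that precision improves
  monotonically across count bins, where only ordering matters. The
  ceiling is raised to 500 in these experiments so that censoring at 50
  does not distort the law being measured.
* Problem sizes in the suite — 2,000 triplicates per count level, 100
  seeds for anomaly-rate coverage, full 33,264-spot panels — were chosen
  to keep Monte-Carlo error a few times smaller than the tolerances they
  support while the whole suite stays well under a minute.

## Known limitations

* The CCC confidence interval is degenerate at $|\rho_c| = 1$ and
  undefined when one variable is constant; both are reported as such.
* The KS normality gate with estimated moments is anti-conservative; for
  four-per-group designs the gate is best read as "no gross departure".
* `excluded_unreliable_count` inspects the highest *tested* dilution; a
  series truncated before counts fall into range cannot be rescued.
* The simulator draws Poisson counts directly; it does not model
  overdispersion from clumped phage particles.
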