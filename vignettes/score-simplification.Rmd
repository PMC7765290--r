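---
title: "Responsiveness-driven simplification of a semi-quantitative hand MRI score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responsiveness-driven simplification of a semi-quantitative hand MRI score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsamris)
```

## The problem

The OMERACT PsAMRIS is a semi-quantitative MRI score of inflammatory and
destructive hand-joint changes in psoriatic arthritis. A reader grades six
features — synovitis (0–3), flexor tenosynovitis (0–3), periarticular
inflammation (0–1), bone edema (0–3), bone erosion (0–10) and bone
proliferation (0–1) — at two sites of each MCP, PIP and DIP joint of digits
2–5. That is 12 joints × 2 sites × 6 features = 144 items per hand per
timepoint, which is the instrument's main practical obstacle: scoring a
study takes several minutes per scan, which has confined the score to
research use.

`spsamris` implements a clinimetric reduction of that instrument. The idea
is to keep only the joints whose overall sub-score is most *responsive to
change* under therapy, quantified by the standardized response mean (SRM),
and to validate the shortened instrument (sPsAMRIS, 3 joints / 36 items)
against the full one by relative efficacy, correlation, and inter-rater
reliability.

## The statistics

**Change and SRM.** For patient $i$ with sum scores $y_i(t_0)$ and
$y_i(t_1)$, the change is $d_i = y_i(t_0) - y_i(t_1)$ (scores that rise
under therapy give negative changes). The standardized response mean is

$$\mathrm{SRM} = \frac{\bar d}{s_d},$$

with $s_d$ the sample standard deviation (denominator $n-1$; only
complete-case patients contribute). Magnitudes are stratified as trivial
($|\mathrm{SRM}| < 0.2$), small ($[0.2, 0.5)$), moderate ($[0.5, 0.8)$) and
large ($\ge 0.8$). The strata are applied to the magnitude because
responsiveness is directionless: a score whose SRM is $-0.13$ is as
(un)responsive as one at $+0.13$. A feature absent from the whole cohort
has no defined SRM and is reported `NaN` / `not_available`; a present but
static score has SRM 0; zero variance with a nonzero mean is flagged as
degenerate.

**Selection.** Joints are ranked by the magnitude of their overall
sub-score SRM, with `NaN` last and ties broken by anatomical order (MCP
before PIP before DIP, digit ascending) so the ranking is deterministic.
The top $k$ (default 3) joints define the simplified schema. If the
magnitude at rank $k$ ties with rank $k+1$ the whole tie block is kept and
flagged, so the instrument definition never depends on an arbitrary cut
through a tie. Summation over the selected joints' items is unweighted: the
selection itself is the only weighting applied.

**Relative efficacy.** For the simplified score $s$ against the full score
as reference,

$$\mathrm{RE} = \left(\frac{\mathrm{SRM}_s}{\mathrm{SRM}_{\mathrm{ref}}}\right)^2,$$

with RE > 1 meaning the simplified score detects change more efficiently.
Confidence bounds come from a percentile bootstrap: complete-case patients
are resampled with replacement $B = 5000$ times — the patient is the only
exchangeable unit in a paired pre/post design, so resampling items or
timepoints would break the pairing — and the 2.5%/97.5% bounds are
*nearest-rank* empirical quantiles (`sorted[ceiling(p·m)]`), which makes
them reproducible bit-for-bit given a seed. Replicates whose RE is
undefined (zero-variance resamples, 0/0) are dropped from the ranking and
counted in the result; infinite REs are kept and rank last. RE is extremely
heavy-tailed in small cohorts with near-zero reference SRMs — a replicate
that nearly zeroes the reference SRM sends RE to enormous values, which is
why bounds like (0, 60) around a small point estimate are expected rather
than pathological, and why degenerate-replicate counts are surfaced rather
than hidden.

**Agreement.** Pearson correlation between full and simplified scores is
reported with the two-sided $t$-based p-value on $n-2$ degrees of freedom
and a Fisher-z 95% CI ($z \pm 1.96/\sqrt{n-3}$, back-transformed), with
Cohen strata on $|r|$ (0.1/0.3/0.5). Inter-rater reliability uses two-way
mixed intraclass correlations from the targets × raters ANOVA
decomposition: the consistency forms
$\mathrm{sICC} = (MS_R - MS_E)/(MS_R + (k-1)MS_E)$ (single measure,
ICC(3,1)) and $\mathrm{aICC} = (MS_R - MS_E)/MS_R$ (average measure,
ICC(3,k)); the absolute-agreement form is available via
`icc_two_way(type = "agreement")`. The consistency form is the default
because systematic severity offsets between raters do not change a
rank-preserving instrument's usefulness; both numbers are reported
neutrally and labelling (intra- vs inter-rater) is left to the caller.
Baseline-vs-follow-up comparisons use a two-sided paired t-test on complete
cases; identical timepoints return $t = 0, p = 1$, while zero-variance
differences with nonzero mean are an error since the statistic is
undefined.

## The data model

Cohorts are long-format tables keyed by (patient, timepoint, rater, joint,
site, feature) with integer values, validated against a `score_schema` that
carries the joints, the two abstract sites (`site_A`/`site_B`, with display
aliases proximal/dorsal and distal/palmar accepted on read), and the
feature ranges. All six features are stored per joint site — that is what
makes the item arithmetic come out at 24 × 6 = 144 — even though some
features are clinically read per joint; a per-joint reading is encodable by
scoring one site and zeroing the other.

Multiple raters are collapsed before analysis by `resolve_raters()`:
`consensus_required` (disagreements must be adjudicated by an explicit
`consensus` rater, the default posture of a consensus-reading workflow),
`mean` (rounding half away from zero to stay on the ordinal grid, or
fractional via `round_mean = FALSE`), or `single:<id>`. Missing items are
an error by default; the permissive zero-imputation mode exists behind an
explicit flag and announces itself, because silently imputing zeros biases
every SRM toward 0.

## The synthetic cohort generator

No patient-level data accompany the development study, so the package
ships a generator that reproduces the *structure* the analysis relies on,
not any particular table of values:

* 17 patients at baseline, 13 with follow-up (the last four patient ids
  drop out deterministically, keeping fixtures stable across seeds), two
  raters — the study's shape, via `adam_config()`.
* Per patient × item, a Bernoulli(prevalence) draw decides whether the item
  is *active*; inactive items are 0 at both timepoints. Default
  prevalences (synovitis 0.70, flexor tenosynovitis 0.50, periarticular
  inflammation 0.70, bone edema 0.20, bone erosion 0.25, bone
  proliferation 0.05) reproduce the qualitative frequency ordering of the
  development cohort: inflammation features frequent, bone edema/erosion
  less frequent, proliferation rare. Prevalence is uniform across joints
  within a feature, absent any finer information.
* Active items carry a latent Gaussian pair with equal unit variance at
  both timepoints, centred at a per-feature severity plus a shared patient
  frailty (SD 0.5), correlated so the latent change has SD
  `sigma_change` (default 1). The follow-up latent value is shifted by the
  configured effect, so effects are interpretable as standardized latent
  shifts. An equal-variance *exchangeable* pair is used deliberately
  instead of a random walk (`L1 = L0 + noise`): a random walk inflates the
  follow-up latent variance, and pushing that through clipped thresholds
  inflates follow-up scores even under a zero effect — a structural bias of
  about $-0.8$ SRM at $n = 500$ that would make null calibration
  impossible. With the exchangeable pair the two timepoints are
  distributionally identical under a zero effect, so the null SRM is
  centred at 0 by construction.
* Latent values map to grades through equal-width thresholds
  (`floor(L / width)` clipped to the feature range, width 1 by default).
* Each rater observes the true grade but deviates by one grade (within
  range) with probability 0.10 on active items — enough disagreement to
  exercise consensus handling and to keep ICCs high but below 1.
* `adam_config()` adds a uniform latent effect of +0.02, so the expected
  overall SRM sits in the trivial band with scores drifting slightly
  upward at follow-up, as in the development cohort. At 13 complete cases
  the sampling SD of any SRM is $1/\sqrt{13} \approx 0.28$, so individual
  synthetic runs scatter widely around that expectation — exactly as a
  single 13-patient study does.

What the generator does **not** emulate: spatial correlation between
neighbouring joints, feature co-occurrence (e.g. erosion and edema at the
same site), reader drift over time, and the marginal means/SDs of the
development cohort's descriptive table. Passing tests therefore demonstrate
that the pipeline's statistics behave correctly under a plausible
data-generating process, not that the original study's numbers are
recovered — with 13 patients those numbers are one draw from a wide
sampling distribution in any case.

## Numerical choices

* Sample SD (n−1) throughout; the choice is documented rather than
  configurable per call site so every SRM in a run is comparable.
* Tie detection in selection uses an absolute tolerance of 1e-12 — ties in
  printed two-decimal inputs are exact, ties in computed SRMs essentially
  never occur.
* Display rounding to two decimals happens only at serialization, with
  full-precision companions retained. Computing *from* rounded values is
  exactly what makes a squared SRM ratio irreproducible from a printed
  table (e.g. $(-0.13/-0.02)^2 = 42.25$ from two-decimal SRMs versus a
  full-precision ratio that can differ by tens of percent), and the
  pipeline must not repeat that.
* All randomness flows through explicit integer seeds; identical
  configurations produce byte-identical artifact bundles.

## Problem sizes used in the test suite

The stochastic checks run at deliberately modest sizes chosen for stable
behavior: null calibration on one cohort of 500 patients (SRM tolerance
$3/\sqrt{n}$), joint recovery over 100 replicates of 200 patients with a
latent effect of 0.5 on three target joints, p-value uniformity over
10,000 simulated paired t-tests, and exhaustive bootstrap enumeration at
$n = 3$ (all $3^3$ resamples).

## Known limitations

* The reduction is data-driven: with 13 complete cases the per-joint SRMs
  that drive selection are noisy, and a different cohort can select a
  different joint set. The package treats the published joint set
  \{MCP3, MCP4, PIP4\} (`spsamris_reference_srms()`) as the reference
  simplified instrument and exposes the machinery to re-derive a selection
  from any cohort.
* Only two timepoints (t0/t1) are modelled; longer longitudinal designs
  are out of scope.
* No wrist or foot joints, no extensor tenosynovitis, and no
  absolute-agreement bootstrap variants beyond the percentile method.
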