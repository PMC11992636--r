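---
title: "Modelling care-seeking behaviour and delayed diabetes diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling care-seeking behaviour and delayed diabetes diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careseek)
```

## The problem

A large share of diabetes cases remains undiagnosed for years: the disease
progresses slowly and asymptomatically, and whether a person seeks care in
time depends as much on attitudes, perceived control, social influence and
risk perception as on the availability of services. `careseek` simulates
this process at the level of individual agents in small rural communities
served by a handful of primary medical centres and one hospital, and asks
where and when undiagnosed diabetics are eventually diagnosed, at what
severity, and at what cost to the health system.

Three behavioural theories are wired together:

* **Theory of planned behaviour (TPB)** — intention to seek care arises
  from *attitude*, *perceived behavioural control* (PBC) and *social
  norms*;
* **Health belief model (HBM)** — *risk aversion* (driven by disease
  severity) and *self-efficacy* (driven by past care experiences);
* **Goal framing theory (GFT)** — *hedonic* (convenience: distance,
  travel time) and *normative* (reputation, trust) goals governing **which
  provider** is chosen. Gain goals are omitted: care is free at the point
  of use in the modelled system. GFT is active in every experiment; the
  TPB and HBM factor sets can be toggled per scenario.

## Model structure

### Disease process

Each diabetic agent carries a severity index $SI_t \in [0,1]$ advancing
linearly at a monthly base rate (`disease$rp_undiagnosed`, default 0.0145
per 30 days while undiagnosed; 0.004 once diagnosed — diagnosis brings the
disease under management but does not cure it). Symptom stages are
threshold classes of $SI$: asymptomatic below 0.2, mild to 0.5, noticeable
to 0.8, urgent above. Overall health is
$H = \sum_z w_z C_z + p \cdot SI$ (clamped to $[0,1]$), with every chronic
condition weighted equally at $w_z = 0.5$ and $p = 0.5$.

A diagnosis is classified **late** when $SI$ at diagnosis is at or above
`s_late`, which defaults to the noticeable threshold (0.5). The early/late
boundary is a modelling choice — the distinction is widely used but rarely
operationalised — and is exposed in the configuration.

### The daily decision

On routine self-check days (every 14–56 days per agent, more frequent for
older and more health-literate agents) and daily once symptoms are
noticeable, a symptomatic undiagnosed agent evaluates the health-seeking
score
$$HS = \frac{\sum_k \theta_k X_k}{\sum_k \theta_k},$$
a weighted mean over the *active* factors: attitude, PBC and social norms
(TPB); risk aversion and self-efficacy (HBM); and the hedonic goal of the
best available provider (GFT, always active — willingness to go is driven
by the best option on offer). The agent seeks care when $HS \ge 0.5$;
urgent-stage agents seek immediately regardless of the score. Factor
functions follow a logistic attitude, a logarithmically damped barrier
term in PBC, exponential experience terms in self-efficacy, and a
prospect-theory-style risk-aversion recursion; all recursively updated
scores are clamped to $[0,1]$ after every update (the source formulations
normalise their inputs but do not state overflow behaviour, so clamping is
the package's convention).

The social-norms term averages, over network contacts, the product of each
contact's behavioural consistency (the fraction of matching actions over a
14-day window) and a term mixing that consistency (divided by the current
day $t$, as printed in the source formulation) with normalised interaction
frequency. Dividing by $t$ makes behavioural alignment matter only in the
opening days of a simulation; `behavior$norms$time_mode = "window"`
substitutes the window length for $t$ as a documented deviation. Under the
default, social norms remain small throughout a run — most neighbours are
healthy and never seek care — so the norms weight acts mainly through the
denominator of the weighted mean.

### Provider choice, visits and appointments

A seeker chooses the provider maximising
$\theta_h HG + \theta_v NG$, where $HG$ falls linearly with normalised
distance and travel time and
$NG = \theta_r RP^{\alpha_r} + \theta_q TR^{\alpha_q}$ is nonlinear in
reputation and trust. Ties break by distance, then provider id, making the
choice order-invariant.

Hospitals are open around the clock; medical centres keep weekday
9:00–17:00 hours, with each visit attempt assigned a uniform 8:00–20:00
clock hour. A non-urgent seeker whose preferred provider is closed books
an appointment for the centre's next opening day rather than defaulting to
the emergency department — mild symptoms do not send people to an ED at
2 a.m. Without this booking behaviour more than half of all planned visits
would be forced into hospitals by the clock alone, which contradicts both
observed primary-care use and the regional diagnosis shares the model is
meant to reproduce. Urgent cases are served the same day: if no centre is
open (or its expected wait, arrivals over daily capacity, exceeds one
day), the agent proceeds directly to the nearest hospital.

At a hospital, diabetes diagnosis is certain for a diabetic visitor. A
medical centre diagnoses noticeable-stage visitors via lab-test referral,
diagnoses mild-stage visitors with per-visit probability `q_mild`
(default 0.75) and otherwise sends them home undiagnosed, and refers
urgent visitors directly to hospital. After three failed centre visits an
agent switches to hospital-only care until diagnosed. A diagnosis is
**planned** when the visit arose from a routine check plus a positive
decision (including a deliberately chosen hospital); urgent overrides and
referrals are **unplanned**.

Each visit updates trust in the visited provider (reinforced by success,
eroded by failure, with a correct urgent referral counting as success),
increments a saturating continuity-of-care score, and queues a feedback
message (1 on success, 0.3 otherwise) that network contacts receive with
the daily interaction probability, updating their reputation view of the
provider by exponential smoothing.

### The social network

Agents are joined in a distance-biased small-world graph: eight nearest
neighbours each, 10% of edges rewired with an exponential distance decay
(3 km scale), plus slow monthly churn (2% of agents swap their
least-interacted edge). The source describes the network as local, both
imposed and emergent, but specifies no topology; this construction is the
package's choice and every parameter is exposed in the region
configuration. Edge interaction counts advance in weekly Binomial(7, 0.2)
batches, which is statistically identical to daily Bernoulli firing for
the cumulative counts the norms term consumes.

## Synthetic populations

The population synthesiser draws every agent attribute independently from
configured marginals: age, gender, Indigenous status, a socioeconomic
composite, education, health literacy (gender-specific), mental health,
health behaviours, cultural health beliefs, barriers to care (lognormal),
and a chronic-condition load. The shipped Gilgandra (4,101 agents, 3
medical centres + 1 hospital on a 10 km square) and Narromine (6,190
agents, 1 centre + 1 hospital on a 16 km square) configurations are
*stylised*: the marginals are shaped on census/health-survey style
variables, not reproductions of any survey, and residential locations are
uniform within the extent — real settlement clustering, roads and travel
times are out of scope. Narromine's sparser roster, longer distances and
higher barriers drive its heavier reliance on hospital-based diagnosis.

Baseline diabetes prevalence is a configuration knob; the shipped default
assigns 5.8% of agents undiagnosed and 7.25% already diagnosed, the 4:5
undiagnosed-to-diagnosed ratio reflecting the motivating statistic that
four cases go undetected for every five diagnosed. Initial severities of
undiagnosed agents are uniform on $[0, 0.3]$, so disease stages are
heterogeneous from day one; initial self-efficacy and risk aversion are
uniform on $[0.3, 0.7]$; initial trust in a provider is its base
reputation plus uniform noise.

What passing tests on these synthetic populations do **not** show: that
the behavioural weights are identifiable from real individual-level data,
that the stylised marginals match the two real towns, or that the model
predicts real diagnosis records — validation against confidential health
data is outside this package's scope.

## Calibration and shipped defaults

The headline outputs of the source study are themselves model outputs
under parameters that were calibrated against confidential patient data
and never printed. The package therefore ships defaults produced by its
own calibration procedure, `calibrate_params()` — seeded random search
with local refinement minimising
$\sum \left((\text{simulated} - \text{target})/\text{tolerance}\right)^2$
over published summary statistics: the regional hospital shares of
diagnoses (≈60% Gilgandra, ≈80% Narromine), the planned share of
diagnoses before day 3,000 (≈60%), the ≈1,000-day initial diagnostic gap
of the HBM-only scenario, and the ≈AU$250,000 aggregate Gilgandra
screening cost. The behavioural decision weights, the progression rate,
`q_mild` and the hospital tariff are the fitted quantities; the defaults
are documented as *calibrated to published summaries*, not as estimates
from data.

Two fitted values deserve comment. The hospital tariff `cost_ed`
(AU$1,600 per presentation) aggregates diagnostic tests, consultation and
admission components that the source lists but does not decompose; with
the AU$100 screening tariff fixed, the regional cost total pins the
tariff given the realistic prevalence above. And the monthly progression
rate 0.0145 ties the HBM-only diagnostic gap (initial severities at most
0.3 must progress to the urgent threshold 0.8 before the first 5% of
diagnoses accumulate) to roughly 1,000 days.

## Experiments, interventions, sensitivity

`run_experiment()` replicates a scenario with consecutive seeds (100
replications by default, matching the source design; 20 suffice for the
shipped acceptance analyses) and reports means with normal-approximation
95% confidence intervals. `apply_intervention()` implements the two
programmes: **awareness** multiplies health literacy by 1.20 and the
social-interaction parameters by 1.15; **access** multiplies barriers by
0.70 and all agent-provider distances by 0.75. Under the shipped
defaults, awareness works almost entirely through the literacy-dominated
attitude function (the social channel is muted by the norms formulation,
as discussed above); access works through both the PBC barrier term and
the hedonic goal.

`ofat_sensitivity()` perturbs one decision weight at a time over a
±20% grid and reports the distribution of percentage changes in a summary
statistic against seed-matched baselines. With a weighted-mean decision
rule, a weight's leverage is proportional to the gap between its factor
and the overall score, so the attitude and norms weights are the most
sensitive and PBC/self-efficacy weights nearly inert — the median
parameter's dispersion stays well inside a ±25% band.

## Numerical and design choices

* Time advances in whole days; the within-day clock only decides whether
  a centre is open at the drawn visit hour. Each replication's randomness
  derives from one seed (population at `seed`, network at `seed + 1`,
  dynamics at `seed + 2`).
* Recursive scores (trust, reputation, self-efficacy, risk aversion,
  norms) update at the events that generate them — visits, feedback
  delivery, health checks — and are clamped to $[0,1]$.
* The diagnostic gap is operationalised as the first day on which
  cumulative diagnoses exceed 5% of the run's final total (configurable).
* Degenerate inputs: zero diagnoses make shares `NA` rather than 0; a
  roster without a hospital, prevalences summing above 1, non-summing
  category probabilities and unknown configuration keys are hard errors.
* Problem sizes: the shipped acceptance analyses use the full region
  populations over the 4,000-day horizon with 20 replications per arm,
  and a 1,000-agent subsample over 3,000 days for the sensitivity grid —
  by day 3,000 essentially every agent of the subsample is diagnosed, so
  the late-diagnosis rate tracked there is final.

## Known limitations

* No incidence: the undiagnosed cohort is fixed at initialisation, so
  long-horizon dynamics describe the depletion of that cohort.
* No post-diagnosis care pathway beyond the slower progression rate; no
  mortality, comorbidity interaction or glycaemic physiology.
* Abstract planar geography; no real travel-time or GIS data.
* The social-norms term is nearly inert under the printed formulation, so
  network structure matters mainly through reputation diffusion.
* Waiting times are a one-parameter heuristic (same-day arrivals over
  capacity), not a queueing model.
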