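---
title: "Peer networks and the diffusion of prescribed safer supply: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peer networks and the diffusion of prescribed safer supply: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When British Columbia's risk mitigation guidance opened the door to
prescribed safer supply (PSS) — pharmaceutical opioids, stimulants and
benzodiazepines offered as an alternative to the toxic unregulated drug
supply — uptake among the province's prescribers was left to passive
dissemination: documents, webinars, slide decks. Diffusion-of-innovation
theory predicts that in such a vacuum, adoption travels along professional
networks. `pssnet` implements the full analysis needed to quantify that
mechanism from administrative claims: who counts as an eligible prescriber,
which dispensations are PSS, how the patient-sharing network and a
prescriber's lagged *peer exposure* evolve month by month, and how strongly
exposure predicts starting — and continuing — to prescribe.

Because the administrative data this kind of study runs on are
privacy-restricted, the package is exercised end to end on a synthetic
claims generator with known diffusion parameters. The generator is
first-class, tested code: every acceptance-grade claim the package makes is
a claim about quantities the pipeline recovers from data whose truth is
known.

## Pipeline and definitions

**Cohort.** A client carries a substance-use-disorder (SUD) indication if
they ever received opioid agonist treatment (OAT), had three outpatient
visits on distinct dates with an SUD diagnostic code, one SUD-coded
acute-care visit, or an SUD-flagged perinatal record. The first indication
date is the earliest date any pathway is satisfied; for the visit rule that
is the third distinct visit date. A prescriber enters the cohort by
dispensing any medication, inside the study window (2020-03-27 to
2021-08-31 by default), to a client flagged *strictly before* that
dispensation. Ties on the same day do not qualify — "prior" is read
conservatively. The three-visit rule uses all available history; whether
the three visits must involve distinct prescribers is not specified
anywhere we could anchor it, so distinct *dates* are counted (a visible,
editable choice).

**Case-finding.** PSS prescriptions have no dedicated drug identification
numbers; they are recognized by keywords in the free-text directions-for-use
crossed with an eligible medication-class set, in two tiers: a sensitive
tier (the primary analysis) and a specific tier constrained at load time to
be a subset of the sensitive one, which makes the subset invariant between
the two classifications structural rather than empirical. The shipped
lexicon is an illustrative stand-in (the provincial lists are not public)
and every downstream result is parameterized by the YAML it lives in.
Records with blank directions are classified not-PSS and tallied, never
errored.

**Network and exposure.** For measurement month $t$, dispensations from the
study start through the end of $t$ (a cumulative window; a trailing-$k$
window is a config switch) are projected onto prescribers: an edge joins two
cohort prescribers who share at least one client, weighted by the number of
distinct shared clients. Per node we compute degree, degree centrality
$d_i/(N-1)$, the local clustering coefficient (share of neighbour pairs that
are themselves connected, 0 below degree 2), and *adjusted strength* — the
mean, over the prescriber's in-window clients, of the number of other
prescribers each client saw, computed from the client-attachment records
because that is how the quantity is defined. Peer exposure of node $i$ is
the fraction of its connected peers that had a PSS dispensation in any month
$\le t$; isolates get 0. Weighted (share of edge weight) and two-step
neighbourhood variants serve the sensitivity analyses. Exposure is
categorized as none / $\le$10% / >10–20% / >20%, boundaries closed on the
right to match the printed labels, with >20% being the fixed 3rd-quartile
threshold of the published analysis (an empirical-quartile mode exists).

**Panels.** The adoption panel is a discrete-time event history over months
May 2020 onward: a prescriber contributes one row per month while
un-adopted, plus the initiation month (outcome 1), and innovators — first
PSS in the March 27–April 30 window — never enter, since their event
precedes any peer influence the panel can measure. The discontinuation
panel follows PSS initiators from July 2020 (or first PSS month, if later)
until the first month opening a three-month PSS-free gap; the event month is
the first gap month and requires all three months to be observable, so a
trailing two-month silence is censored, not an event. Every time-varying
regressor in a month-$m$ row — exposure and its category, clustering,
adjusted strength, caseload, case-mix percentages, years of experience — is
the month-$(m-1)$ value, and the test suite re-derives them from
record streams truncated at the end of $m-1$ to prove no future leakage.
Caseload and experience enter as quartile bins: empirical type-1 quantile
cuts from the panel-entry distribution by default (computed once, not
re-quantiled monthly), or the published replication cut points
(caseload $\le$2 / 3–6 / 7–13 / $\ge$14 for adoption and $\le$18 / 19–43 /
44–85 / $\ge$86 for discontinuation, resolving an overlap in the printed
labels; experience <4.5 / 4.5–10.9 / 10.9–22.4 / $\ge$22.4 years and
<4 / 4–8.3 / 8.3–17.4 / $\ge$17.4 respectively). Empty monthly caseloads
yield zero percentages rather than missing values so the rows stay
estimable; the choice is visible in the code and here.

**Estimation.** The marginal model is logistic:
$\operatorname{logit} P(Y_{it}=1) = \mathbf{x}_{i,t-1}^\top \beta$,
estimated by generalized estimating equations over prescriber-month
clusters. `gee_logit()` implements the estimating equations directly, with
independence, exchangeable (moment estimator) and unstructured
(per-occasion-pair moment estimator over clusters observing both occasions)
working correlations, the binomial scale fixed at 1. The independence case
is verified in the tests against `glm()` point estimates and
`sandwich::vcovCL()` cluster-robust standard errors, which it must equal.
Three covariances are kept: the model-based one, the usual robust sandwich,
and the Mancl–DeRouen bias-corrected sandwich. Adjusted odds ratios are
$e^{\hat\beta}$ with 95% intervals $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$.
Because an unstructured correlation over 16 unbalanced occasions can be
singular, `fit_panel_model()` walks unstructured → exchangeable →
independence and records what it used; robust standard errors keep the
estimates valid under working-correlation misspecification, which is what
licenses the fallback. Complete separation — a factor level with no events,
which the sparse "Unknown" region produces readily at desk scale — is
detected and raised as a classed error naming the term, rather than letting
Wald output masquerade as inference. A random-intercept `glmer` counterpart
(`glmm_variance_check()`) reproduces the diagnostic that motivates the
marginal model: when the cluster variance collapses to zero, GEE loses
nothing.

**Reporting.** `table_one()` stratifies prescriber characteristics by
innovator / early adopter / non-adopter, measured at each adopter's
initiation month and at study end for non-adopters, with medians and
interquartile bounds and no test statistics. Cells below 10 are rendered as
"< 10"; when exactly one cell of a variable is suppressed within a stratum
the next-smallest cell is suppressed too, so the hidden count cannot be
recovered from the stratum total. Suppression runs after all aggregation
and is idempotent. Percentages round half-up to one decimal — banker's
rounding would make reports depend on digit parity. `monthly_active_series()`
gives active / cumulative / lapsed counts per month, and
`prune_edges_top_quantile()` reproduces the display rule that keeps an edge
only when its weight is in the top 20% of incident weights *for both
endpoints*, ties at the boundary retained.

## The synthetic study and what it does (and does not) emulate

`sim_config()` defaults define the package's reference study: 500
prescribers, 3000 clients, 18 months across the five regional health
authorities. Clients attach to $1 + \mathrm{Poisson}(\lambda)$ prescribers
with $\lambda$ set so the average client sees about one additional
prescriber, preferentially within region (10% cross-region mixing), with
prescriber choice weighted by a log-normal caseload weight (sd log 1.1) that
produces the heavy-tailed caseloads real claims show — a median-caseload
prescriber has a handful of SUD clients while hubs carry dozens. Ten
innovators (2% of prescribers, matching the 1.6% observed provincially) are
seeded preferentially among high-caseload prescribers, echoing the observed
concentration of innovators among OAT-prescribing hubs. Thereafter each
eligible prescriber's monthly adoption indicator is Bernoulli with
$$\operatorname{logit} p_{it} = \alpha + \beta_e \, e_{i,t-1} + \beta_c z_i,$$
where $e_{i,t-1}$ is computed *by the same network and exposure code the
analysis uses*, on the records available through month $t-1$ including
already-emitted PSS dispensations — so the planted $\beta_e$ is exactly the
estimand of the panel regression, a property the tests assert to machine
precision. $z_i$ is standardized log caseload. Defaults
$\alpha=-6$, $\beta_e=\log 3.79$ (echoing the published >20% adjusted odds
ratio as a configuration choice, not a ground truth), $\beta_c=0.9$ give
roughly 9% uptake over follow-up, matching the published 9.1%. Active
adopters face an analogous monthly cessation hazard
($\log \mathrm{OR} = \log 0.29$ per unit exposure, intercept $-1.6$) that
reproduces the published pattern of roughly half of adopters lapsing by
study end. Active months always emit at least one PSS dispensation carrying
a planted keyword, which is what makes the truth ledger exactly recoverable
by the case-finding algorithm; sporadic within-episode prescribing gaps are
therefore *not* emulated, and the discontinuation rule's tolerance of such
gaps is exercised by exhaustive small-case tests instead. Also not
emulated: secular time trends in the baseline hazard, client turnover
between prescribers, coding error in the directions text, and any client
outcome process. Passing recovery tests show the estimator recovers the
generator's mechanism at desk scale; they cannot show the mechanism is the
one operating in real claims.

One R lazy-evaluation subtlety is worth recording: each generator stage
seeds its own RNG substream derived from the master seed, and each stage
forces its input arguments *before* seeding, so nesting stage calls cannot
interleave streams. Regenerating with one config is byte-identical, which
the determinism tests check on the serialized text tables.

## Inference at desk scale

The replicated experiments (`pss_recovery_study()`) run the complete
pipeline — simulate, flag, classify, build 18 networks, assemble the panel,
fit — 50 times at the reference conditions. Problem sizes were chosen so
the full suite and experiments run in minutes on one CPU: 500 prescribers
give about 25–40 adoption events per replicate, the same order as the
published cohort scaled down, which makes the experiments honest about
small-sample behaviour rather than hiding it. Two such behaviours shaped
the design:

* *Estimation* uses the independence working correlation. The adoption
  panel is an event history whose cluster length is determined by the
  outcome; under that design the independence estimating equations coincide
  with the correctly specified pooled-logistic score, while non-diagonal
  working correlations are not generally consistent. The published-style model
  fits (which mirror the published specification) keep the unstructured →
  exchangeable → independence chain.
* *Intervals* are profile-likelihood, computed from the pooled-logistic
  likelihood the independence fit maximizes. With ~30 events the sampling
  distribution of the exposure coefficient is heavy-tailed and plain Wald
  sandwich intervals measurably undercover; profile intervals restore
  near-nominal coverage. Replicates in which an exposure category has no
  events at all are reported as a separation rate and excluded from
  coverage, the usual treatment of undefined Wald/profile inference in
  simulation studies — under the null configuration ($\beta_e = 0$) the
  sparse >20% category separates in roughly a fifth of replicates, which is
  information about the design, not a defect to silence.

## Numerical and degenerate-input conventions

Month indices come from integer arithmetic on days-since-epoch (no
per-record `format()`), with month 1 anchored at 2020-03 and an alternative
binning that assigns the 16th-through-15th span to the earlier month.
Exposure of an isolate is 0 and its category "none". Clustering below
degree 2 is 0. Empty record sets produce empty graphs and empty flag
tables, not errors. Quantile cut points use type-1 quantiles so empirical
quartile bins are balanced to within one count on distinct data; degenerate
(tied) distributions get infinitesimally separated cuts rather than
collapsing bins. The exchangeable correlation estimate is clamped to its
feasible range; the unstructured matrix is moment-estimated per occasion
pair, clamped off-diagonally, and rejected (triggering the fallback chain)
if not positive definite. All randomness in the generator flows from one
master seed through per-stage substreams.

## Known limitations

The GEE solver fixes the binomial scale at 1 and offers no jackknife
variance; the discontinuation model at the 500-prescriber scale rests on
~20 events and is reported descriptively rather than asserted against
planted values; the suppression logic protects single-table complements but
does not attempt cross-table disclosure control; and the keyword lexicon
ships as a stand-in, so absolute PSS counts from the defaults are only
meaningful for synthetic data that plants the same lexicon.
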