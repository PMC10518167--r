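---
title: "Methods: combining visual and towed-array acoustic line-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining visual and towed-array acoustic line-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pamvlt` combines a visual line-transect (VLT) survey and a simultaneous
towed-hydrophone passive acoustic (PAM) survey of deep-diving whales into
one abundance estimate with an in-situ estimate of surface availability.
This vignette is the package's own account of the statistical machinery:
the models, their assumptions, the tunable parameters, and the numerical
and design choices behind the implementation.

## The estimation problem

A dual survey observes two complementary slices of the population: whales
in their surface interval (available to the visual teams) and whales in
the vocal phase of a foraging dive (available to the array). The natural
combination

$$N_T = N_S + N_B - N_D, \qquad a_S = N_S / N_T$$

requires the number of duplicates $N_D$: whales that were available to
*both* platforms because they transitioned between states while inside
both detection zones. Duplicates cannot be identified pair-by-pair
(platforms are deliberately blind to each other, localizations are coarse,
and transitions happen minutes apart), so the package estimates their
*count* from the dive-state dynamics encoded in the acoustic capture
histories.

## Surface abundance: distance sampling and MRDS

`fit_ds()` fits a half-normal or hazard-rate detection function $g(y)$ to
perpendicular distances by random-walk Metropolis. The average detection
probability in the covered strip is $\hat p = \int_0^W g(y)\,dy / W$. For
the two-team visual survey, `fit_mrds()` uses the full-independence
mark-recapture form: both teams share a half-normal shape with scale
$\sigma$ and have team-specific trackline intercepts $\delta_k$, so the
capture history $(\omega_1, \omega_2)$ of each detected group, conditional
on detection by at least one team, identifies
$g(0) = 1 - (1-\delta_1)(1-\delta_2)$. This is the simplest model
consistent with one team serving as a trial for the other; point
independence, covariates on the detection function (Beaufort, glare, ...)
and left-truncation are out of scope, and covariate columns in the input
schema are accepted but not modelled.

**Abundance likelihood.** Writing $n$ for the number of detections,
$n \sim \mathrm{Binomial}(N, \hat p)$ with a flat prior on $N$ gives the
exact conditional $N - n \mid \hat p \sim \mathrm{NegBinomial}(n+1, \hat
p)$, which is sampled once per posterior draw of the detection
parameters. Everything stays in one posterior, so CVs and credible
intervals of any downstream combination propagate detection uncertainty
with no plug-in steps. Draws are capped at $20\,n/\hat p$ (a bound the
posterior essentially never reaches). Visual abundance is multiplied by
the mean observed group size (a switch, on by default); acoustic events
are treated as single animals.

**Priors.** Scale $\sigma \sim U(0, 5W)$; hazard-rate shape
$\sim U(1, 50)$; team intercepts $\mathrm{logit}(\delta_k) \sim N(0,
10^2)$. The upper bound $5W$ (not $W$) matters: with a tighter bound a
nearly flat detection curve — which genuinely occurs for acoustic
event-level detection of animals that click for half an hour — is not
representable and $\hat p$ saturates below 1. When the scale is
identified by the data the bound is inert.

## Subsurface abundance: the state-space capture-recapture model

Click trains are binned into one-minute capture histories. Because the
ship moves at constant speed, time bins are forward-distance bins: bin 1
is the farthest point ahead at which the array detects whales, and bins
continue past the ship (the array hears astern). For event $i$ and bin
$j$ the latent dive state $z_{ij} \in \{0, 1\}$ (1 = vocal, below the
surface) follows

* entry: while never yet in state, $z_{ij} \sim \mathrm{Bernoulli}(\gamma_j)$;
* persistence: $\mathrm{logit}(\phi_{ij}) = \alpha_0 + \alpha_T\,
  \mathrm{Time}_{ij}$, where $\mathrm{Time}_{ij}$ is the time already
  spent in state when entering bin $j$ — the latent time-at-entry
  $\mathrm{Time}_{i1} \sim U(0, \texttt{max\_time})$ for whales already
  vocal at bin 1, plus one bin duration per in-state bin since;
* exit is absorbing: a whale that surfaces does not re-enter within the
  window. Allowing re-entry would let one whale masquerade as several
  "repeat divers", exactly the double-counting the zone of overlap is
  designed to avoid; double divers are instead handled as separate events.

Detection is $Y_{ij} \sim \mathrm{Bernoulli}(p_{ij} z_{ij})$ with
$\mathrm{logit}(p_{ij}) = \beta_0 + \beta_1 R_{ij}$ and $R_{ij}$ the
radial distance from the array to the whale's localized perpendicular
distance at the bin midpoint. Data augmentation brings the $n$ observed
events up to $M$ individuals (default $2n$); pseudo-individuals carry
all-zero histories, an inclusion indicator with $\psi \sim U(0,1)$, and —
because the observation model needs a radial distance — a latent
perpendicular distance with a $U(0, W_{\mathrm{acoustic}})$ prior.

**Entry-rate structure.** Under stationary dive cycling the probability
of *already being vocal* when entering the grid (roughly the vocal share
of the dive cycle, ~0.6) is an order of magnitude larger than the
per-bin entry rate (~0.05 per minute). One shared rate cannot represent
both, so the default `gamma_model = "two_rate"` gives bin 1 its own rate
and shares one rate across later bins; `"constant"` and `"by_bin"` are
available. All rates take $U(0,1)$ priors with conjugate Beta updates.

**Derived quantities.** Per posterior draw, $F_j = \sum_i
(1-z_{i,j-1})z_{ij}$ counts entries and $S_j = \sum_i z_{i,j-1}(1-z_{ij})$
exits (convention $z_{i0} = 0$, so presence in bin 1 is an entry);
$F_T$, $S_T$ sum them over the zone of overlap; and the superpopulation
$N_B^{(CMR)}$ counts individuals ever in state within its zone.

### The zone of overlap

A transition is a duplicate only if the corresponding surfacing was
inside the visual search window. Ship-relative geometry fixes the
direction of the shifts. The whale is (to good approximation) stationary
while the ship advances, so between two events separated by $\Delta t$
the whale's relative forward position moves $v\,\Delta t$ *aft*:

* a whale seen at the surface that dives starts clicking after the silent
  descent, *aft* of where it was seen — the entry zone is the visual
  window shifted aft by $v \times$ descent duration;
* a whale that stops clicking surfaces after the silent ascent, aft of
  its exit — so exits that produce *visible* surfacings lie *ahead* of
  the window by $v \times$ ascent duration.

A surfacing also lasts several minutes, during which the relative
position drifts another $v \times$ surface duration; each zone is widened
on the appropriate side by this drift so that partially overlapping
surfacings count. This also honours the constraint that a whale
surfacing behind the ship is not visually available: with the shifts in
these directions, behind-ship exits fall outside the exit zone. Bounds
are clipped to the grid; shifting a zone entirely off the grid yields an
empty zone (a warning, and zero duplicate counts downstream).

### Sampler

The sampler is Metropolis-within-Gibbs (Rcpp):

1. **Path update by enumeration.** Each individual's state path is one of
   "never in state" or an (entry bin, exit bin) pair — at most
   $J(J+1)/2 + 1$ candidates, restricted for observed events to paths
   covering all detections. Prefix sums of the per-bin observation
   log-likelihood and of the persistence terms make each candidate O(1),
   and the path is drawn exactly from its full conditional. This mixes
   far better than single-site flips of $z_{ij}$ and is exact — validated
   against an exhaustive-enumeration oracle at small $J$ and $M$ in the
   test suite.
2. **Latent scalars.** Entry time (random walk on $(0,
   \texttt{max\_time})$, prior-refresh when not in state at bin 1) and
   augmented perpendicular distances (reflected random walk on $(0, W)$,
   prior draw while inactive).
3. **Rates.** $\gamma$ and $\psi$ by conjugate Beta Gibbs draws.
4. **Coefficients.** $(\alpha_0, \alpha_T)$ and $(\beta_0, \beta_1)$ by
   univariate random walks plus a joint anti-correlated move that shifts
   the intercept and counter-shifts the slope so the linear predictor is
   preserved at the typical covariate value. The posterior is a long thin
   ridge in these pairs; without the joint move the intercepts have
   effective sample sizes in the tens.

Proposal scales adapt toward 35% acceptance during burn-in only. Priors
on coefficients are $N(0, 10^2)$. Defaults follow common practice for
this model class — burn-in 10\,000, 15\,000 further iterations thinned by
15, 3 chains — and the fit reports Gelman-Rubin statistics when run with
at least two chains, warning when any $\hat R \ge 1.1$. All analysis and
test code in the package uses much shorter chains (hundreds to a few
thousand iterations), which the enumeration oracle and recovery tests
show is sufficient at these data sizes.

**Posterior predictive check.** During sampling the fit accumulates a
Freeman-Tukey discrepancy on per-bin detection counts of the observed
events, $D = \sum_j (\sqrt{c_j} - \sqrt{E[c_j]})^2$, for the observed and
a replicated dataset; `bayesian_pvalue()` returns
$P(D_{\mathrm{rep}} \ge D_{\mathrm{obs}})$, with ties counting toward the
p-value. The discrepancy targets the per-bin structure (entry smearing
and the radial detection gradient), which is where this model can
actually misfit; a saturated all-ones history set, by contrast, is
perfectly fittable and is not a useful power case.

## The three estimators

* **DS-DS**: $N_T = N_S + N_B^{(DS)}$, $N_D \equiv 0$. The baseline that
  ignores duplicates.
* **CMR-DS**: $N_T = N_S + N_B^{(CMR)} - (F_T + S_T)$, all terms
  draw-wise.
* **Hybrid**: when only a subset of click trains can be fully annotated,
  the subset fit supplies per-capita per-bin rates $P_F = \bar
  f^{(H)}/n_B^{(H)}$ and $P_S = \bar s^{(H)}/n_B^{(H)}$ (per-bin
  posterior counts averaged over the bins inside each zone, normalized by
  the subset superpopulation, draw-wise), and the duplicate counts are
  $F_T^{(H)} = N_B^{(DS)} P_F \cdot \mathrm{Zone}_F$ and
  $S_T^{(H)} = N_B^{(DS)} P_S \cdot \mathrm{Zone}_S$. The method assumes
  transition rates are homogeneous across bins and that the annotated
  subset is representative.

Posteriors fitted independently are combined by draw-wise arithmetic on
equal-length chains (resampled with replacement, with a warning, when
lengths differ). The identity $N_T = N_S + N_B - N_D$ holds exactly in
the stored draws. Draws with non-positive $N_T$ are retained in abundance
summaries — truncating them would hide bias — but dropped from the
availability ratio, and their fraction is reported. `apply_availability()`
implements the classical alternative (MRDS with an external availability
correction) for comparison, storing the implied subsurface component so
the identity still holds.

## The simulator

`simulate_dataset()` emulates the data-generating process the estimators
face in the field, deliberately *not* the fitted model:

* whales are placed uniformly in the strip (Poisson count) and cycle
  through surface interval, silent descent, vocal foraging phase, silent
  ascent, with per-whale lognormal mean multipliers (individual
  variation), gamma cycle-to-cycle variation, and an approximately
  stationary phase at time zero;
* the ship transits at constant speed; a whale surfacing inside the
  visual window is detected by team $k$ with probability
  $g_{0k} \exp(-x^2/2\sigma_v^2)$ (one trial per team per surfacing,
  linked duplicates recorded); a whale vocal during any part of bin $j$
  is detected there with probability $\exp(-R_j^2/2\sigma_a^2)$ — i.e.
  detection is half-normal in radial distance, while the CMR model fits a
  logit-linear form. This misspecification is intentional: passing tests
  demonstrate robustness, not self-consistency;
* each vocal phase detected at least once becomes one event, so an
  interrupted-and-resumed vocal phase yields two events ("double
  divers");
* the truth ledger records whale-level availability to each platform,
  availability-unit counts, and the dive/surfacing links that are true
  duplicates, so relative bias has an exact denominator.

**Default scenario** (`scenario_config()`): 10-knot ship (5.14 m/s),
one-minute bins (308.4 m), grid from 6 km ahead to 1.5 km astern
(25 bins), 4 km perpendicular truncation on both platforms, 0-5 km visual
window, half-normal scales 2.5 km on both platforms, team intercepts
0.9/0.85, 30% of events annotated. Dive-cycle means: surface 9 min,
silent descent 5 min, vocal phase 35 min, silent ascent 8 min (the
canonical sperm-whale characterization), individual CV 0.15, within-whale
CV 0.10. Density and transect length (0.18 whales/km^2 over 220 km) are
set so a survey yields on the order of 150 acoustic events, the scale of
the motivating field dataset; the density itself is a scenario knob, not
an ecological claim. Maximum dive depth is simulated per whale (for
completeness of the dive description) but does not affect detection:
depth correction is explicitly outside this framework.

What the simulator does *not* emulate: localization error in the event
perpendicular distances, acoustic propagation and beam-pattern effects,
whale movement during the encounter, group sizes on the acoustic side,
and non-foraging vocalizations. Passing tests therefore say nothing about
robustness to those features of real data.

## Numerical choices and degenerate inputs

* Bin count $J = \lceil (\text{ahead} + \text{behind}) / \text{width}
  \rceil$ — the rounding rule is fixed and tested; the last bin may
  extend past the aft limit by less than one bin.
* A click exactly on a bin boundary goes to the farther-ahead bin; clicks
  converting to positions outside the grid are dropped with a counted
  warning (real events extend beyond any truncation).
* Time-to-distance conversion anchors on the first recorded click and
  assumes constant ship speed and a horizontally stationary whale.
* The half-normal ESW uses the closed form via the normal CDF; the
  hazard-rate uses adaptive quadrature in `esw_phat()` and a fixed
  201-node Simpson rule inside samplers (the integrands are smooth; the
  two agree to ~1e-9 relative).
* Zero detections, all-zero capture histories, $M \le n$, zone bounds
  outside the grid, single chains passed to the Gelman-Rubin statistic,
  and degenerate draw vectors all raise immediate, named errors rather
  than propagating NaNs.
* Study replicates draw their seeds once from the study seed, so results
  are reproducible per replicate and independent of execution order.

## Problem sizes

The shipped tests and the acceptance script are sized for a single CPU:
the simulation study runs 25 replicates of the default scenario with
short chains (600 burn-in, 1200 kept) and single-chain CMR fits;
parameter-recovery checks use 20 replicates at $J = 20$, $n \approx
40$-$60$; the enumeration oracle uses $J = 4$, $M = 3$, 20\,000
iterations. These sizes were chosen because the recovery and oracle
checks show they are already well inside the regime where the estimators
are stable; production analyses of field data should use the fit
defaults (multiple chains, long runs) and check $\hat R$ and the
posterior-predictive p-value.

## Known limitations

* Transitions are modelled into/out of a single vocal state; silent
  phases are handled geometrically (zone shifts), not as latent classes.
* The per-bin entry rate is constant across bins (after the initial bin);
  strong along-track density gradients would violate it — and the Hybrid
  method leans on the same homogeneity twice.
* Event-level acoustic detection can be nearly flat in perpendicular
  distance while still missing short, edge-clipped vocal phases; a
  distance-sampling fit cannot see that kind of missingness, which is a
  small honest bias in the DS-based subsurface estimate (the CMR estimate
  models it properly).
* The availability estimate is survey-wide; spatial or temporal
  stratification is out of scope.
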