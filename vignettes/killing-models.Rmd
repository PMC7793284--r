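---
title: "Discriminating CTL killing mechanisms with an agent-based model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating CTL killing mechanisms with an agent-based model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlsim)
```

## The scientific question

Intravital 2-photon imaging of cytotoxic T lymphocytes (CTLs) attacking
virus-infected cells in the lymph node shows that an infected cell's
*observed* probability of dying rises with the number of CTL contacts it has
received. That observation is compatible with several very different
cellular mechanisms: CTLs might become more lethal with every target they
touch, targets might become more fragile with every hit they take, damage
might accumulate towards a threshold — or the rise might be an artefact of
how imaging data are scored. `ctlsim` implements a 3D agent-based model of
this system together with nine candidate death mechanisms and the
cost/AIC machinery needed to ask which mechanisms are consistent with a set
of imaging-style readouts.

A central confounder is the *zombie contact*: once a target has committed
to die it can persist visibly for `T_death` minutes, and CTLs may keep
initiating contacts with it. Those contacts inflate the contact counts of
cells that are scored as killed, so even a purely contact-history-independent
killing probability produces a rising observed kill-probability curve. The
package treats the zombie flag as a model structure (not a fitted
parameter) so this artefact can be switched on and off.

## The model

Cells live in a continuous `X_dim x Y_dim x Z_dim` box (default
700 µm per side) that is periodic in x and y and closed in z. Infected
cells are stationary and uniformly placed in the top `Z_lim = 40%` of the
z-axis, the region reachable by the microscope; CTLs are placed uniformly
in the whole volume and the lower part acts as a migration reservoir.
Placement rejects configurations in which nuclei overlap: nuclei occupy a
fraction `C_CF = 0.5` of the cell radius (`R_T = 4.8` µm for CTLs,
`R_I = 5.1` µm for targets), so two centres may not come closer than
`C_CF (r_a + r_b)`.

CTLs execute a persistent random walk. Every `T_pers = 2` minutes a cell
draws a fresh speed from a binned speed distribution and turns by an angle
drawn from a binned turning-angle distribution, applied in a uniformly
random plane around the current heading. Between draws it moves in a
straight line, truncated by nucleus-nucleus hard-core repulsion and by the
closed z-boundaries; a collision resamples the direction uniformly, resets
the persistence clock and forfeits the remainder of that tick's
displacement. Update order within a tick is a fresh random permutation of
the CTLs, so no cell systematically moves first.

A free, non-refractory CTL that comes within `I_CF (R_T + R_I)` = 14.85 µm
of an eligible target initiates a contact (the factor `I_CF = 1.5` stands
in for pseudopodial reach) and halts for the contact's duration, which is
drawn from a log-normal distribution with log-mean 2.1 and log-sd 1.2
(median about 8.2 min). A CTL holds at most one contact at a time; targets
may hold many, and simultaneous contacts act additively. When a contact
ends the CTL is released with a fresh direction and speed and may not
initiate again for one persistence time.

Death is decided by the active hypothesis. The probabilistic variants draw
one Bernoulli decision when a contact ends: constant `p` (null);
`k_I * C_I` (target integrates contacts); `k_T * C_T` or `k_T / C_T`
(CTL integrates contacts, positive or exhaustion-like negative
modulation); or fixed per-cell probabilities drawn once from
`Normal(k_m, k_s)` / `Normal(d_m, d_s)` (heterogeneity variants). The
damage variants integrate a damage level `I` with forward Euler at the
simulation step: `dI/dt = n_CTL d` (constant), the same with a per-contact
cap at `T_max` minutes (saturated), `dI/dt = n_CTL d - r I` (damage with
repair), or `dI/dt = sum_j k_T C_T(j)` over engaged CTLs (CTL contact
integration damage). A target whose damage reaches 1, or that loses its
Bernoulli draw, becomes *dying* and is removed `T_death` minutes later;
while dying it still occupies space and — if zombie contacts are enabled —
still attracts new contacts, which count in the observed statistics but
never in the death decision.

For a single sustained contact the damage-with-repair variant has the
closed form `I(t) = (d/r)(1 - exp(-rt))`, reaching the threshold after
`t_complete = -(1/r) log(1 - r/d)` (39.6 min at the fitted `d = 0.03`,
`r = 0.009`; exactly `1/d` = 33.3 min without repair). These closed forms
are used as the analytic oracle for the Euler integration: at `dt = 0.1`
min the integrated damage stays within 0.5% of the closed form over a
40-minute contact. Note that the `1/d` bound on the *wall-clock*
elimination time holds only when contacts do not overlap; because
simultaneous contacts are additive, a target held by two CTLs at once can
(rarely) be eliminated faster.

## Readouts and fitting

`compute_readouts()` reduces a contact log to the eight imaging-style
datasets used for fitting: the observed kill probability at interaction
ranks 1-6 (cells dying at exactly their *i*-th contact over cells with at
least *i* contacts), the elimination-time distribution (first contact to
removal, 10-minute bins), contact-count distributions for killed and
surviving cells (unit bins), and total and single contact-duration
distributions by fate (5-minute bins up to 60 minutes with an overflow
bin). Bin widths are package defaults — the source material does not state
them — and every histogram is normalized by its population so it sums to
one. The per-capita killing rate (kills per CTL extrapolated to 24 h), the
killed fraction and the never-contacted fraction are reported alongside.

An observation window `[obs_start, obs_end]` restricts what is "seen":
contacts initiated before `obs_start` are discarded (the delayed-observation
scenario uses `obs_start = 60` to mimic unknown pre-imaging history),
open contacts are truncated at `obs_end`, and killed cells whose contacts
all predate the window count as zero-contact deaths. The elimination-time
histogram is normalized over killed cells with an observed first contact.

Fitting scores a hypothesis against a reference readout set with the
summed squared deviation per dataset, averaged over replicate simulations,
and the mean cost `C` over the eight datasets. Hypotheses are ranked by
`AIC = 8 log(C) + 2k`, where `k` counts the variant's killing parameters
plus `T_death`; the zombie flag is a structure, not a parameter. This AIC
definition reproduces all eighteen published (cost, k, AIC) rows to within
0.1, which is how it was validated. `ctl_fit()` runs an exhaustive grid
search with replicate seeds derived deterministically from
`(seed, grid row, replicate)`, breaking cost ties towards smaller
`T_death` and then a smaller killing parameter. A two-sample KS statistic
on binned mass is reported for reference but never used for selection.

## Synthetic references and what they do (not) show

The measured speed, turning-angle and readout distributions exist only as
published figure panels, not as numbers. The package therefore ships
*synthetic stand-ins*, clearly labelled as such:

* `default_motility_model()` — a right-skewed speed histogram on
  [0, 12] µm/min with mean 4.5 µm/min (slow, antigen-engaged CTLs) and a
  forward-biased turning-angle histogram on [0, π] (mean turn ≈ 64°).
  Both are frozen constants in the source, never regenerated silently, and
  are meant to be replaced by measured histograms via `motility_model()`.
* `generate_reference_readouts()` — reference readout sets produced by the
  simulator itself under a known hypothesis, written with a provenance
  record naming that truth.

Self-consistency (parameter recovery from self-generated references) is
therefore the testable property: it demonstrates that the observables
carry enough information to identify the generating parameters, not that
any particular parameter value describes a real infection. Real imaging
data additionally contain tracking errors, irregular sampling, drift and
cell in/outflow, none of which are modelled.

## Numerical and design choices

* **Time step.** `dt = 0.1` min everywhere; event times are resolved to
  the tick, scheduled contact ends are recorded exactly.
* **Clamping.** The linear kill-probability formulas exceed 1 at high
  contact counts and normal heterogeneity draws can leave [0, 1]; both are
  clamped (no redrawing).
* **Counters.** Contact counters increment at initiation, so a contact
  counts towards its own end-of-contact decision ("including the current
  one"). Zombie contacts increment the observed counters but never drive
  decisions.
* **Simultaneous endings.** Contacts ending in the same tick decide in
  random order and stop once the target's death is decided.
* **Collisions.** A colliding CTL keeps its speed, draws a uniform random
  direction and loses the rest of the tick's displacement; z-boundaries
  are treated the same way (they are impermeable, not reflective). Whether
  a collision should also redraw the speed is unspecified in the source
  material; only the direction is resampled here.
* **Ongoing contacts on dying targets** persist until their scheduled end
  or the target's removal in both zombie modes; the zombie flag governs
  only new initiations.
* **Ties at initiation.** If several targets are in range the nearest
  wins; exact ties go to the lower id.
* **Window-truncated contacts** trigger no death decision — only contacts
  reaching their natural scheduled end do.
* **Placement** uses bounded rejection sampling (100,000 rejections by
  default) and fails with an error naming the over-dense constraint.

## Problem sizes used in the shipped checks

The published protocol runs 30 replicates per parameter set on the full
700³ µm arena. The package's own checks scale this down to keep a
single-CPU run practical, and state so here:

* Zombie-artefact and sweep properties: full arena, 10 and 5 replicates
  per point respectively, with rank curves pooled over replicates.
* Parameter recovery: a dense infection focus (250³ µm, 100 CTLs, 200
  targets) chosen so that per-replicate readout noise is small against the
  parameter signal; references average 30 replicates, grids refit with 10.
  For the two contact-integration variants the joint (slope, `T_death`)
  surface at this problem size has a shallow diagonal valley of
  compensating parameter pairs, so their recovery is checked along the
  killing-parameter axis at the generating `T_death`; the null variant's
  joint 5×5 recovery is checked in full.
* Structural invariants: one fully audited default-size run (2,400 ticks)
  with per-tick overlap, conservation and monogamy checks.

## Limitations

Targets are immobile; cells are spheres with nucleus-only volume
exclusion; there is no chemotaxis, no antigen heterogeneity between
targets (outside the heterogeneity variant), a single contact-duration
distribution shared by live and zombie contacts, and no cooperative
(non-additive) multi-CTL killing. The mixed first-contact hypothesis and
directed migration are out of scope. PCKR values depend strongly on the
chosen cell numbers and motility stand-ins, so only their *trends* across
cell-number sweeps — not their absolute magnitudes — are meaningful
checks.

## A worked example

```{r example, eval = FALSE}
library(ctlsim)

cfg <- sim_config()                       # the 700^3 um, 4 h imaging arena
null_z <- killing_hypothesis("null", p = 0.35, T_death = 25,
                             zombie_contacts = TRUE)
sim <- ctl_simulate(cfg, null_z, seed = 1)
summary(sim)
compute_readouts(sim)$kill_prob_by_rank   # rises although p is constant

# self-consistent reference + grid-search refit
focus <- sim_config(X_dim = 250, Y_dim = 250, Z_dim = 250,
                    N_T = 100, N_I = 200)
truth <- killing_hypothesis("null", p = 0.2, T_death = 15)
ref <- generate_reference_readouts(truth, focus, n_reps = 30, seed = 7)
fit <- ctl_fit("null", expand.grid(p = c(0.1, 0.15, 0.2, 0.25, 0.3),
                                   T_death = c(5, 10, 15, 20, 25)),
               ref, focus, n_reps = 10, seed = 11)
coef(fit)       # recovers p = 0.2, T_death = 15
plot(fit)       # cost-surface heatmap
```
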