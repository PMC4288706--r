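---
title: "Modelling calcium puffs and waves from a single IP3R cluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium puffs and waves from a single IP3R cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffwave)
```

## The model

`puffwave` simulates calcium release from a single cluster of sixteen
IP3 receptor (IP3R) channels in the ER membrane and analyzes the
resulting release events. The model couples two layers:

**Stochastic gating.** Each channel consists of four identical subunits;
each subunit carries an IP3 binding site, an activating Ca2+ site and an
inhibiting Ca2+ site, giving the eight subunit states `X_ijk` of the
modified DeYoung-Keizer (DYK) scheme (index order IP3, activation,
inhibition; 1 = bound). A channel is *open* when at least three subunits
are in `X110` and *activatable* when at least three subunits hold IP3.
Binding propensities are `a_i * [ligand]`, unbinding `b_i = a_i * d_i`,
with the rate index selected by the occupancy of the other sites: IP3
on/off uses index 1 while not inhibited and 3 while inhibited;
inhibition uses 2 with IP3 bound and 4 without; activation always uses
5. The dissociation constants obey the detailed-balance constraint
`d1 d2 = d3 d4` (= 0.078 uM^2 for the defaults), which is what allows
IP3 to unbind preferentially from inhibited subunits - the "inactivation"
that terminates long release events. Two off-rate table cells (`b1`,
`b4`) are derived from the `b_i = a_i d_i` identity, which holds for all
independently specified pairs.

**Deterministic concentrations.** Free Ca2+ `c` and a single mobile
buffer (bound form `b`) react and diffuse in a cuboidal cytosolic volume:

    dc/dt = D_c lap(c) - k_on c (B_total - b) + k_off b
    db/dt = D_b lap(b) + k_on c (B_total - b) - k_off b

The bottom face (`z = 0`) is the ER membrane and carries the flux
boundary condition for `c` (zero-flux for `b` and on all other faces):

    J = P_ch chi(x) (c_ER - c) - P_p c^2/(K_d^2 + c^2) + leak

`chi` is 1 on the pore disks (radius 6 nm, closed-disk convention) of
open channels, the SERCA pump is Hill type with coefficient 2, and the
leak balances the pump at rest. The single-channel current implied by
the pore-disk flux at `c << c_ER` is
`2 F P_ch pi r^2 c_ER` = `r signif(channel_current(4.58e6, 6, 700), 2)` pA.

**Hybrid coupling.** Concentrations advance with the open set frozen;
gating advances by exact CTMC sampling with rates frozen over macro
steps (capped at 1 ms while any channel is open, 10 ms at rest); any
open/close transition splits the step, so the fields never see a stale
open set. Open channels drive their own subunits with a fixed pore
concentration of 150 uM - driving them with the mesh value at the pore
would make gating depend on how well the pore is resolved. Closed
channels are driven by the local concentration at their pore center.
Initial subunit states are drawn from the stationary distribution at a
high Ca2+ concentration (default 10 uM, configurable), i.e. a cluster
with low excitability after strong activity; the first 100 s of every
run are excluded from statistics.

## Parameters

All interfaces use uM, nm, s and pA. Key defaults:

| block | parameter | default | meaning |
|---|---|---|---|
| gating | `a` | 0.20, 0.02, 0.40, 0.10, 100 /(uM s) | site on-rates |
| gating | `d` | 0.001, 78, 2, 0.039, 0.25 uM | dissociation constants |
| fields | `D_c` | 223e6 nm^2/s | free Ca2+ diffusion |
| fields | `B_total`, `k_on`, `k_off` | 200 uM, 150 /(uM s), 300 /s | mobile buffer |
| fields | `D_b` | 5e6 nm^2/s | buffer diffusion (see below) |
| membrane | `P_ch`, `P_p`, `K_d` | 4.58e6 nm/s, 20000 nm/s, 0.05 uM | channel / SERCA |
| membrane | `c_ER`, `c0` | 700, 0.02 uM | luminal / resting Ca2+ |
| cluster | spacing, pore radius | 120 nm, 6 nm | 4 x 4 grid |
| domain | `Lx, Ly, Lz` | 3250, 3250, 2000 nm | cytosolic volume |

Two parameter cells could not be read from the reference tables and are
genuinely open; both are configurable and were fixed once, by the
dynamical regime they must produce, before the acceptance machinery was
written:

* **Domain extents.** The height `Lz = 2 um` follows from converting
  the volumetric SERCA capacity (10 uM/s) into the boundary coefficient
  (10 uM/s x 2000 nm = 20,000 nm/s). The lateral extents are not
  similarly pinned. They control how strongly released Ca2+ accumulates
  in the (no-flux) volume: with a 2 x 2 um membrane, a flickering
  cluster releases more than the membrane's total pump capacity, the
  bulk runs away to several uM and all activity merges into one
  minutes-long event - incompatible with distinct puffs and with waves
  lasting up to ~10 s. The default 3.25 x 3.25 um keeps the same
  pump-per-volume ratio while placing the model in the regime where
  puffs stay clearly below the 0.25-uM domain-wide trigger level and
  only sustained events reach it.
* **Buffer diffusion `D_b`.** The buffer carries most of the calcium,
  so `D_b` sets the lifetime of the residual domain around the cluster
  after closings - the memory that re-opens channels before they are
  lost to inhibition recovery. 5 um^2/s (a protein/dextran-scale mobile
  buffer) makes that residual outlive the inhibition recovery time
  (1/b2 = 0.64 s) at the box scale, as the excitable mechanism requires.

The leak is `P_l (c_ER - c)` with `P_l` from `balance_leak()` (3.94 nm/s
for the defaults). A literal coefficient (e.g. the nominal 903 nm/s) can
be supplied instead; a constant offset then restores the rest-state
balance, which is the leak's stated purpose. The balanced form is the
default because no simple leak form reproduces 903 nm/s from the other
table values.

## The grid solver

The PDEs are discretized by a cell-centred finite-volume method on a
graded tensor mesh: spacing equals the pore radius (6 nm) across the
pore disks and at the membrane, growing linearly (rate 0.5) to 150 nm in
the far field (~90 x 90 x 20 cells for the default domain). The pore
flux is distributed over the membrane faces overlapping each disk with
area-fraction weights.

Time integration uses a Douglas-Gunn alternating-direction-implicit step
in delta (increment) form,

    (I - th dt Lx)(I - th dt Ly)(I - th dt Lz - dt J) du = dt F(u),

with `th = 0.55` (Crank-Nicolson weighting plus a small damping of the
stiff pore modes) and the linearized membrane term `J` fully implicit.
In delta form any steady state is an exact fixed point of the step, so
the balanced rest state is preserved to rounding for arbitrarily large
steps. The bimolecular buffer reaction is Strang-split around the
diffusion step and solved per cell in closed form (implicit midpoint of
the scalar Riccati ODE), conserving `c + b` exactly per cell; with all
boundary fluxes disabled the scheme conserves total calcium to rounding.

Step size is adaptive by a bounded-relative-change controller: a step is
rejected and halved when the Ca2+ field changes by more than 20%
(relative, with a 0.1 uM floor) outside the immediate pore vicinity, or
when any value leaves its physical bounds; accepted quiet steps grow
toward `dt_max`. The cells within 24 nm of a pore center are excluded
from the error metric: the near-singular source makes them ride a
bounded numerical limit cycle whose effect on the release flux is of
order `c/c_ER` (a few percent), while the quantities the model consumes
- concentrations at the other channel sites and the box average - are
controlled by the unmasked cells and converge under both step-bound and
mesh refinement (the test suite checks a replayed three-channel event
against a one-level-refined mesh). This purpose-built controller
replaces a formal embedded error estimator; the refinement study is the
accuracy contract.

## The reduced mode

Full-grid simulation resolves 6-nm pores in a 3.25-um box and cannot
reach the several-thousand-second traces the statistics need on one
workstation, so long runs use a reduced concentration model behind the
same simulator interface:

* two well-mixed compartments - the 500-nm cluster box and the
  remaining bulk - exchange total calcium with conductance `g_box` and
  feel the SERCA/leak membrane terms scaled by their membrane-area
  share; a rapid-buffer factor `beta(c) = 1 + B_total K/(K + c)^2`
  converts total-calcium fluxes into free-concentration rates. The bulk
  compartment stands in for the domain minimum in the wave criterion
  (in the grid the minimum is attained far from the cluster).
* each open channel contributes a nanodomain kernel
  `K(d) = A exp(-d/lambda)/d` to the driving concentration of closed
  channels at center distance `d`; a per-channel residual memorizes the
  kernel superposition at every open-set change and decays with
  `tau_domain`, implementing the transient Ca2+ left behind by closings.
* the baseline a closed channel sees is the box average corrected for
  the nanodomain inflation contributed by the open channels
  (`c_box - n_open * box_excess`, floored at the bulk value): the box
  *average* includes the hot nanodomains and overstates the membrane
  concentration at the other channel sites.

Every reduced-model coefficient is fitted against the grid solver by
`calibrate_reduced()`, never chosen freely: the kernel amplitude and
decay length from the steady excess concentrations at the other channel
sites during a single-channel replay, with the amplitude rescaled by a
joint fit including a four-channel replay (simultaneous nanodomains are
superlinear because the buffer saturates); `tau_domain` from the
post-closure decay of the nearest-neighbour excess; `g_box` by least
squares on the post-closure box-average decay; the per-channel release
rate from the pore-disk flux at the measured open-pore concentration.
The shipped defaults are this calibration on the default mesh. On a
two-second multi-channel validation replay the reduced box average
agrees with the grid within a few percent of the excursion peak, and
within ~10-20% pointwise during the active phase; in the near-rest tail
the reduction decays ~0.015 uM too fast (the well-mixed bulk pumps
faster than the stratified field, see the limitations). Macro-step caps are 1 ms (open), 2 ms
(box still elevated) and 10 ms (rest); halving them does not change
event statistics beyond sampling error.

## Event analysis

A collective event is a maximal interval during which the box-averaged
Ca2+ exceeds 0.1 uM, with crossing times interpolated linearly between
samples (10-ms output cadence), sub-threshold gaps shorter than 20 ms
merged (the debounce is configurable; all reported statistics use the
default), and events containing a single channel opening discarded. An
event is a *wave* if the domain-wide minimum reaches 0.25 uM - the
dissociation constant of activation, i.e. the event could trigger a
neighbouring cluster anywhere in the domain - and a *puff* otherwise.
Event amplitude is the peak number of open channels.

Interval conventions the source leaves open, fixed here and
configurable: inter-wave intervals are measured start-to-start (period
semantics); inter-puff intervals end-to-start with pairs split by a wave
excluded; the inter-wave phase of a puff is anchored at wave starts.

## What the generator emulates, and what it does not

Reduced-mode traces emulate the study conditions of the full
reaction-diffusion model: a single cluster, one mobile buffer, constant
luminal Ca2+ and constant ambient IP3. They do not emulate fluorescence
indicators, photon noise, multiple clusters, luminal depletion or IP3
metabolism, so passing tests say nothing about those aspects of real
recordings; comparisons with experiments are meaningful only at the
level of event statistics. The planted-event fixtures
(`make_fixture()`) exercise the analysis stage alone and carry their
ground truth with them.

## Problem sizes

The statistics protocol used by the tests and by
`scripts/acceptance.R` runs three seeds of 5100 s per IP3 condition
(10-80 nM; the first 100 s discarded), pooling events per condition -
about 500-2500 events per condition. Grid-mode checks use short
replayed events (0.15 s) on the default and a one-level-refined mesh.

## Known limitations

* The two-compartment reduction carries a single box-bulk exchange
  conductance for all open-set sizes, so it runs ~15% hot during
  multi-channel bursts; and because the well-mixed bulk pumps at the
  volume-mean concentration while the real field is stratified away
  from the membrane, the slow post-burst tail decays ~0.015 uM too
  fast (a pointwise-relative error of ~20-30% near rest).
* The post-wave suppression of puffs is weaker than in the reference
  phenomenology: the refractory span (bins with fewer than 5% of pooled
  inter-wave puffs) covers about 10% of the inter-wave interval rather
  than ~30%, because channels regain IP3 - and puffs reappear - somewhat
  too quickly after waves.
* The inter-wave-interval statistics at 20 nM are heavy-tailed
  (coefficient of variation above 1), which makes the fitted
  SD-versus-mean regression line, and especially its mean-axis
  intercept, sensitive to the random seed.
* The ~100-s IP3 (re)binding timescales mean the 100-s transient
  discard does not fully equilibrate the activatable-channel count at
  low IP3; the protocol keeps the stated discard.
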