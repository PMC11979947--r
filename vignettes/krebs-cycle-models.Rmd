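---
title: "Kinetic modelling and control analysis of the mitochondrial Krebs cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling and control analysis of the mitochondrial Krebs cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krebsmca)
```

## The models

`krebsmca` implements three tissue-specific kinetic models of the
mitochondrial Krebs (citric acid) cycle: AS-30D hepatoma mitochondria
(`HepM`), rat liver mitochondria (`RLM`) and rat heart mitochondria
(`RHM`), under the pyruvate/malate substrate condition (2 mM external
pyruvate, 5 mM external malate, state-3 respiration). Each model is an ODE
system dx/dt = S·v(x) over 17 variable matrix metabolites with 19–21
reactions: the cycle proper (CS, ACO, IDH-NAD, 2OGDH, SCS, SDH, FH, MDH),
the NADP-dependent IDH isoform, the anaplerotic enzymes (PDH, GDH, AST, and
tissue-dependently ALT and malic enzyme), glutathione reductase, the
pyruvate carrier, three dicarboxylate exchangers (Mal/Suc, Mal/Iso,
Mal/2-oxo), and two constant-flux boundary reactions: NADH consumption
(standing in for respiratory-chain complex I) and GSH oxidation (standing
in for peroxidase/ROS chemistry). Liver lacks malic enzyme and the
Mal/2-oxo exchanger; heart lacks ALT; heart PDH runs at twice its measured
activity (a documented adjustment of the source model).

Rate laws are reversible Michaelis–Menten forms: ordered ter-bi (PDH,
2OGDH), random bi-bi (CS), mono-reactant (ACO, pyruvate carrier; FH with
independent forward/reverse limiting rates), ordered bi-bi (SDH, AST, ALT,
ME, the exchangers; MDH with independent limiting rates; IDH-NADP with GSH
and NAD⁺ competitive inhibition), ordered ter-ter (SCS), ordered bi-ter
(GR), and Monod–Wyman–Changeux concerted-transition forms for IDH-NAD
(exclusive isocitrate binding, NADH as allosteric inhibitor, a Michaelis
gate in NAD⁺ with NADH competitive inhibition) and for the GDH ammonium
gate (GTP raises, ADP lowers the effective allosteric constant). CO₂ is
held at 2.2 mM and folded into the equilibrium constants of the three
decarboxylating steps as Keq/[CO₂]. The constant-flux reactions carry a
guard factor S/(S + 1e-6 mM) so the NADH and GSH pools cannot be driven
negative.

Four cofactor pools are conserved: NAD⁺+NADH, NADP⁺+NADPH, GSH+2·GSSG and
CoA+AcCoA+succinyl-CoA. Pool totals are fixed by the printed model steady
states (totals are invariants, so the published steady state determines
them exactly).

### Textual corrections to the printed rate equations

Three printed denominators are dimensionally inconsistent or leave a
constant unused; we implement the standard forms: the CS denominator term
`[Q]Kp` as Q/Kq, the SCS terms `[A][B]KaKa` and `[Q][R]KpKr` as AB/(KaKb)
and QR/(KqKr), and the IDH-NADP term `[P][A]KpKa` as AB/(KaKb) — without
the last, the rate would grow without bound in isocitrate and could not
approach its measured Vmax. The printed IDH-NAD MWC exponents (3, 4) are
the n = 4 special case; the general form with the fitted site counts
(n ≈ 1.9–2.33) is used, with numerator (B/Kb)(1+B/Kb)^(n−1) so the rate
vanishes at zero isocitrate. In the GDH gate the printed `(1+[ADP]KaADP)`
factor is placed as a divisor of L (ADP is an activator).

## Parameter provenance, in order of trust

1. **Measured kinetics** (`PAPER-Table1`): Vmax, Km, Ki, and the IDH-NAD
   L/n values, per tissue. These are data and are never fitted.
2. **Printed protocol values** (`PAPER-2.5`, `PAPER-2.6`): boundary
   concentrations of the incubation (2 mM Pyr, 5 mM Mal, 5 mM Pi, 0.3 mM
   ADP), 2.2 mM CO₂.
3. **Derived invariants** (`DERIVED-Table2`): conserved pool totals.
4. **Assumed constants** (`ASSUMED`): product-side Km values, equilibrium
   constants, transporter/SCS/GR kinetics and the remaining boundary
   concentrations, which the source describes only in supplementary
   material that is not part of the main text. These are single,
   literature-plausible choices made once; notably the effective
   aconitase Keq is set to 2 so that the *measured* intramitochondrial
   Iso/Cit ratios (≈1 in hepatoma and liver) are reachable in the forward
   direction, and aspartate (6 mM) is chosen so the near-equilibrium AST
   poise admits the measured OAA/2-oxoglutarate ratios.
5. **Calibrated activities** (`FREE` → `CALIBRATED`): what the source
   itself describes as "parameterized" or "adjusted": the pyruvate-carrier
   and exchanger activities, SCS, the NADH-consumption and GSH-oxidation
   flux constants; plus activities the source took from earlier work or
   could not measure (liver/hepatoma ACO within its measured range, liver
   IDH-NAD, liver PDH and 2OGDH, liver/hepatoma GDH, heart AST). These are
   determined by `calibrate()` against the printed in-vivo metabolite
   concentrations and cycle flux, and the fitted values ship as a
   `CALIBRATED` overlay fixture.

## Steady-state solution

No external ODE solver is assumed. `integrate_to_steady_state()` uses an
adaptive linearly implicit (backward-Euler/pseudo-transient) scheme with
numerical Jacobians and step-halving on negativity or divergence;
`newton_refine()` polishes the result with a damped chord Newton iteration
on the moiety-reduced system (one dependent species per conserved pool is
eliminated, which keeps the Jacobian non-singular). Convergence is declared
at max |dx/dt| < 1e-9 mM/min (default); pool drift is checked against
1e-6 mM. Reported stability comes from the eigenvalues of the reduced
Jacobian.

The default initial state is the printed in-vivo metabolite panel with
cofactor pools rebalanced to their configured totals. The models are
nonlinear enough to be **bistable**: next to the physiological branch there
is a collapsed branch in which NADH is pinned at the guard scale, malate
drains through near-equilibrium MDH, oxaloacetate vanishes and acetyl-CoA
sequesters the whole CoA pool. Trajectories that transiently exceed the
NADH-production capacity (e.g. when the NADH-consumption constant is set
above what the carbon state can sustain) fall onto this branch and stay
there. This is reported honestly by the solver (both branches are genuine
steady states); see "Known limitations" for where it bites.

## Calibration

`calibrate()` performs bounded least squares in log-parameter space
(activities span orders of magnitude and must stay positive) with
multi-start: the configured initial values, an optional log-uniform
pre-screen within the bounds, and a flux-consistent linear least-squares
initializer (`flux_consistent_start()`; every free parameter scales its
reaction rate linearly, so stationarity at the observed state is a linear
problem in the free parameters). Point targets contribute
(model−obs)/obs weighted by obs/SD; literature-range metabolites enter as
interval penalties, zero inside the range and log-scale distance outside
(so a collapsed pool is expensive but a near miss is cheap). Non-convergent
solves contribute a large flagged penalty. The objective always solves from
the configured reference state — warm-starting across evaluations is faster
but path-dependent under bistability, which we found leads the optimizer to
track the collapsed branch.

## What the synthetic-data generator does and does not emulate

`generate_observations()` draws multiplicative log-normal replicates around
the model steady state with a chosen coefficient of variation (default
0.25, matching the typical printed relative SDs, e.g. pyruvate
0.21 ± 0.17 mM) and reports means, SDs and replicate counts in the layout
of the printed observation table. It emulates the *statistical* structure
of the measurements — positive, noisy, few replicates — not their
*systematic* structure: no extraction losses, no inter-preparation
variability in enzyme content, no correlated errors across metabolites from
shared standards. A green recovery test therefore establishes that the
calibration machinery identifies free activities from data of the stated
noise and design, not that the biological measurements identify them.

## Numerical choices

* Elasticities: central differences with relative step 1e-5; entries for
  species absent from a rate law are exactly zero.
* Control coefficients: re-solved steady states at activity factors
  1 ± 1e-3 (central difference), warm-started from the reference solution;
  the classical matrix method (elasticities + link matrix) is available as
  a cross-check (`control_matrices()`). Activity scaling multiplies Vmaxf
  and Vmaxr together, and the flux constant of the boundary reactions.
* Titration grids are log-spaced in the activity factor; the half-effect
  factor is interpolated linearly in log-factor.
* Haldane consistency is not enforced for the two-Vmax forms;
  `haldane_vmaxr()` reports the implied reverse limiting rate as a
  diagnostic.

## Known limitations

* The supplementary parameterization of the source (product Km values,
  equilibrium constants, transporter kinetics, boundary concentrations,
  adjusted activities) is not recoverable from the main text. Our ASSUMED +
  CALIBRATED stated world reproduces the hepatoma and liver cycle fluxes
  and most of the hepatoma metabolite panel, but not every printed number:
  in particular the heart model's printed flux (153.4 nmol·min⁻¹·mg⁻¹) is
  not dynamically sustainable under our assumed exchanger and product-side
  kinetics — the required malate import cannot be held against
  near-equilibrium MDH once NADH consumption approaches the production
  ceiling, and the model falls onto the collapsed branch described above.
* The *magnitudes* of the published control coefficients (e.g. the
  hepatoma NADH-consumption flux control of 7.1) live on a knife edge of
  the source parameterization that our world does not reproduce; our
  hepatoma model gives the same dominant step and signs with smaller
  amplification. The liver model reproduces the flux but sits in a
  consumption-limited control regime (positive NADH-consumption
  coefficient), where the source reports a production-limited one.
* Only the pyruvate/malate condition is modelled; the glutamine, 2-oxo and
  succinate/rotenone panels activate partial cycle sections and are out of
  scope.
* GDH is modelled with NADP(H) cofactors as in the source equations, even
  though the activity assays used NAD(H); the discrepancy is inherited
  as printed.
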