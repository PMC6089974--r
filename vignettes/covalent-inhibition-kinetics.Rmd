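---
title: "Covalent-inhibition kinetics and ring-pucker classification: models, assumptions, and design choices"
author: "carbakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent-inhibition kinetics and ring-pucker classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbakin)
```

# The kinetic model

## The minimal covalent-inhibition cycle

Mechanism-based carbasugar inhibitors of retaining glycoside hydrolases are
processed through the same chemical steps as substrates: reversible binding
to the Michaelis complex, alkylation of the catalytic nucleophile
(pseudo-glycosylation), and hydrolysis of the resulting covalent adduct:

$$E + I
\underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} E{:}I
\overset{k_3}{\longrightarrow} E{-}I
\overset{k_5}{\longrightarrow} E + P$$

The package works with the four microscopic constants
(`rate_scheme(k1, k_minus1, k3, k5)`) and derives everything observable from
them. Three regimes follow from the ratio $k_3/k_5$:

* $k_3 < k_5$ — glycosylation is rate-determining, the covalent pool never
  builds up, and the compound is simply a (possibly poor) **substrate**: the
  steady-state fraction of covalent enzyme is bounded by $k_3/k_5$, so no
  time-dependent activity loss is measurable.
* $k_3 \gg k_5 > 0$ — the covalent intermediate accumulates; enzyme activity
  is lost on the alkylation timescale and returns on the hydrolysis
  timescale. This temporal ("hit-and-recover") behavior defines a
  **covalent inhibitor**.
* $k_5 \approx 0$ — no reactivation on any practical timescale: a
  **covalent inactivator**.

`classify_compound()` applies exactly this trichotomy; the accumulation
threshold ($k_3/k_5 > 10$ by default) is configurable because the boundary
is a modeling convention, not a measurable constant.

## Steady-state observables

Under rapid-equilibrium binding ($k_{-1} \gg k_3$, dissociation constant
$K_d = k_{-1}/k_1$), `derive_steady_state()` returns

$$k_{cat} = \frac{k_3 k_5}{k_3 + k_5},\qquad
K_m = K_d\,\frac{k_5}{k_3 + k_5},\qquad
k_{cat}/K_m = k_3/K_d$$

and, for the time-dependent loss of activity measured in labeling
experiments, $k_{inact} = k_3$ and $K_i = K_d$. Two consequences shape the
whole analysis:

1. $k_{cat}/K_m \equiv k_{inact}/K_i$ for *every* scheme — both equal
   $k_3/K_d$. Agreement between these two independently measured
   second-order constants is the fingerprint of the covalent mechanism, and
   the identity is enforced exactly in the code and checked on 1000 random
   schemes in the tests.
2. When $k_3 \gg k_5$, $k_{cat} \to k_5$ and
   $K_m \to K_d\,k_5/k_3 \ll K_d$: a low-micromolar $K_m$ can coexist with
   millimolar binding. The low $K_m$ is then a kinetic artifact of
   intermediate accumulation, not tight binding.

A steady-state binding variant ($K_d \to (k_{-1}+k_3)/k_1$) is available via
`derive_steady_state(..., binding = "steady-state")` for schemes where
alkylation competes with dissociation; rapid equilibrium is the default
because the systems this package targets have $k_{-1}$ (tens of s^-1 at
plausible association rates) far above $k_3$.

## Derived scalar quantities

* `half_life(k)` = $\ln 2 / k$ — the lifetime of the covalent intermediate
  is `half_life(k5)`; with the included reference constants this evaluates
  to ~7 s for the parent carbagalactoside and ~20 min for its
  2-deoxy-2-fluoro analog, the ~150-fold stabilization by fluorine that
  makes the intermediate crystallographically observable.
* `active_fraction_correction()` — continuous assays report
  $k_{cat}^{obs} = f \cdot k_{cat}$ with $f$ the catalytically active enzyme
  fraction. When an independent route fixes $k_5$ for a reference compound
  whose $k_{cat} = k_5$, $f = k_{cat}^{obs,ref}/k_5^{ref}$, and every other
  observed $k_{cat}$ on the same preparation divides by $f$. The correction
  is refused (error) if $f > 1$, which would mean the premise
  $k_{cat} \le k_5$ is violated.
* `fold_ratio()` — plain ratios reported both raw and rounded to significant
  figures, since fold-changes are conventionally quoted at 1 s.f.

# Simulation of the three laboratory assays

`simulate_cycle()` integrates the mass-action system with `deSolve::lsoda`
(stiff-aware, adaptive). Two numerical choices matter:

* **Conservation by construction.** Only the three independent pools
  ($E{:}I$, $E{-}I$, $P$) are integrated; free $E$ and $I$ are reconstructed
  from the conservation laws, so enzyme and inhibitor mass balance holds to
  machine precision at every output time (the tests assert 1e-9 relative).
  Integrating all five species instead leaves the balance at the mercy of
  solver drift, which for stiff parameter draws can exceed that bound by
  orders of magnitude.
* **Scaled absolute tolerance.** The default `atol` is
  `1e-12 * min(E0, I0)`: assays span nanomolar enzyme against up to
  millimolar inhibitor, and a fixed molar tolerance is either wasteful or
  meaningless across that range. Negative excursions beyond 1e5·atol abort;
  smaller ones are clipped to zero.

`simulate_stopped_flow()` emulates the sequential-mixing experiment: enzyme
and inhibitor are incubated (phase 1, full kinetics), then diluted into
saturating chromogenic reporter substrate where remaining activity is read.
Residual activity counts $E$ **and** $E{:}I$ but not $E{-}I$: the dilution
drops the inhibitor far below $K_d$, so the non-covalent complex dissociates
on the assay timescale while the covalent adduct does not. The dilution
factor defaults to 50 (a 10 uL aliquot into 500 uL, the classical dilution
assay) and the reporter parameters are carried as trace metadata; the
reporter progress curve itself is outside scope (initial-rate window only).
Neither the dilution factor nor the reporter concentration used in the
original stopped-flow experiments is published, so both are explicit,
documented assumptions here; the residual-activity fraction is insensitive
to them under the counting rule above.

The two-state reduction `activity_fraction(kobs, k5, t)`,

$$F(t) = F_{ss} + (1 - F_{ss})\,e^{-(k_{obs}+k_5)t},\qquad
F_{ss} = \frac{k_5}{k_{obs}+k_5},\qquad
k_{obs} = \frac{k_{inact}[I]}{K_i + [I]},$$

is the fitting model for such traces. Its assumptions — binding
pre-equilibrates, $[I] \gg E_0$ so $[I]$ is constant — hold in the simulated
and real designs to better than 1%, which is what the oracle tests assert
against the full ODE. At $k_5 = 0$ it degenerates to the single exponential
of a true inactivator.

`absorbance_from_product()` applies Beer-Lambert at 400 nm; the default
extinction coefficient (1.0e4 M^-1 cm^-1 for 4-nitrophenolate at pH 7.4) is
an assumption and configurable.

# Parameter inference

All nonlinear fits use Levenberg-Marquardt (`minpack.lm::nlsLM`), unweighted
by default to match common practice in kinetics software (optional
1/sigma^2 weights), with standard errors from the Jacobian at the optimum
(Gauss-Newton approximation) — the same quantities a Prism-style analysis
reports.

* `fit_michaelis_menten()` — $v = V_{max}S/(K_m+S)$; flags
  "Km poorly determined" when the estimate leaves the design range by more
  than 100x (no curvature information). Tests verify exact recovery at zero
  noise and agreement with a brute-force grid minimizer on noisy data.
* `fit_first_order_decay(with_plateau = TRUE)` — fits
  $F_{ss} + (1-F_{ss})e^{-k_{tot}t}$ and decomposes
  $k_{obs} = k_{tot}(1-F_{ss})$, $k_5 = k_{tot}F_{ss}$; the decomposition is
  exact algebra of the two-state model, and the identity
  $k_{tot} = k_{obs} + k_5$ is asserted on noiseless input. This is one of
  the two routes to $k_5$ "from the inactivation data"; the other (reading
  the plateau of a simulated/measured trace directly) is available through
  `simulate_stopped_flow()`, and the two agree by construction.
* `fit_inactivation()` — $k_{obs}$ vs $[I]$, hyperbolic
  ($k_{inact}[I]/(K_i+[I])$) or linear (slope $= k_{inact}/K_i$). In `auto`
  mode the hyperbolic model is kept only when it beats the linear one by at
  least 2 AIC units **and** its $K_i$ lands within 10x the largest assayed
  concentration; otherwise only the second-order slope is reported and the
  individual constants are flagged indeterminable — the situation that
  arises whenever the design sits entirely below $K_i$. The delta-AIC
  margin of 2 is the conventional "indistinguishable models" threshold; a
  bare AIC comparison lets the extra parameter win on noise in ~5% of truly
  linear panels, which would overcall saturation. How the original analysis
  made its "no curvature discernible" call is not stated; this quantified
  rule is our explicit stand-in.

# Synthetic data

The generator exists so that every statistical claim in the tests is made
against data whose truth is known exactly.

* Designs: `make_mm_design()` produces at least six log-spaced substrate
  concentrations spanning $K_m/4$ to $4K_m$ inclusive — the published design
  rule for the turnover assays.
* Noise: multiplicative Gaussian with CV 2% for initial rates and 3% for
  activity traces (plus an optional additive floor). The source data report
  only fitted standard errors, not raw scatter; these CVs were chosen once
  as values that make standard errors of the reported magnitude plausible
  for these designs, and are not revisited. Identical seeds give identical
  datasets (R's default Mersenne-Twister; traces in a panel draw
  deterministic sub-seeds).
* Inactivation panels follow the two-state model at each concentration —
  adequate because the ODE agrees with it to <1% in all regimes used.
* What is *not* emulated: substrate depletion within the 5-min initial-rate
  window, enzyme instability, pipetting (between-replicate) error
  structure, and the NMR-observed rearrangement equilibrium of the parent
  inhibitor (which makes its measured constants lower limits). Passing
  recovery tests therefore demonstrate estimator correctness under the
  stated noise model, not robustness to every real-world artifact.

Recovery benchmarks in the test suite (sizes chosen to keep the full suite
under a minute of simulation work): median over 200 replicates recovers a
184 uM $K_m$ within 10% at 2% CV; $k_{inact}$ within 15% and $k_5$ (by
plateau decomposition of 25-point, 0-3000 s traces at 3% CV — about eight
lifetimes of $k_{obs}+k_5$, enough to pin the plateau) within 15%.

# Ring puckering and conformer nomenclature

## Cremer-Pople coordinates

`cremer_pople()` implements the standard construction: center at the
centroid, mean plane from the two first-harmonic position sums, signed
displacements $z_j$, then

$$q_2 e^{i\phi_2} \propto \sum_j z_j e^{-4\pi i (j-1)/6},\qquad
q_3 = \sqrt{1/6}\sum_j (-1)^{j-1} z_j,\qquad
Q = \sqrt{q_2^2+q_3^2},\ \theta = \operatorname{atan2}(q_2, q_3).$$

Rings with $Q <$ 1e-4 A are flagged planar ($\theta,\phi$ undefined there).
`ideal_ring()` is the exact inverse: it places the displacement pattern on a
regular hexagon whose plane *is* the Cremer-Pople mean plane (the harmonic
sums of the flat hexagon vanish), so forward analysis of a generated ring
returns the requested $(Q,\theta,\phi)$ to 1e-6 over the whole sphere — the
round-trip property the tests enforce. The hexagon radius (default 1.46 A,
giving ~1.5 A bonds) does not enter the puckering coordinates.

**Orientation convention.** Conformer names only mean something once the
atom ordering and "above" direction are fixed. The package orders pyranose
rings `O5, C1, ..., C5` and builds/analyzes them so that the ideal
$^4C_1$ chair sits at $\theta = 0$ and $^1C_4$ at $\theta = 180$; the
"above" side is the one from which the ring numbering appears clockwise
(the IUPAC viewing rule), which coincides with the Cremer-Pople mean-plane
normal under this construction. A worked consequence: traversing the same
chair in reversed order classifies as the antipodal chair — the ordering is
part of the contract, and `map_carbasugar_ring()` exists precisely to
enforce it, putting the carbasugar's C6 (the carbon in the position of the
endocyclic oxygen) into the O5 slot so carbasugar conformers carry pyranose
names.

## The canonical table is constructed, not transcribed

`canonical_conformers()` builds all 38 canonical forms by displacing the
defining atoms of each name on an ideal hexagon (chairs: alternating;
envelopes: one atom; half-chairs: adjacent pair, opposite; boats: para
pair, together; twist-boats: meta pair, opposite) and running the forward
analysis. This avoids transcription errors from literature tables and makes
the latitude separating half-chairs from envelopes whatever the geometry
implies rather than a hard-coded constant. Name assignment is independent of
the construction displacement (tested at delta = 0.1 and 0.4 A). The only
conventional input is the choice of representative names for the six
twist-boat positions (each equator point admits two up/down descriptions;
the IUPAC-used set 1S3, 1S5, 2SO, 3S1, 5S1, OS2 is kept) — nomenclature, not
numbers.

## Classification

`classify_conformer()` assigns the nearest canonical point by great-circle
distance on the $(\theta,\phi)$ sphere; $Q$ deliberately does not enter, so
a flattened half-chair (small $Q$, half-chair direction) still classifies as
that half-chair — flattening is read from $Q$ itself. When the second-nearest
point is within 5 degrees of the nearest (configurable), the assignment is
reported as a blend such as `2H3/2E`, mirroring how crystallographic rings
"lying between" two forms are described. The classifier is validated against
a brute-force nearest-point search on 1000 random sphere points.

## Hill-Reilly angles

`hill_reilly()` gives the complementary three-flap description: reference
plane through alternating atoms 1, 3, 5; flap angles are the signed
dihedrals of the (1,2,3), (3,4,5), (5,6,1) triangles about their hinges,
positive when the flap atom lies on the side pointed to by the right-handed
normal of 1-3-5. Under this convention an ideal chair gives three
equal-magnitude, equal-sign angles (all flap atoms sit on one side of the
reference plane); mirroring the ring through its plane flips every sign.
Planarity and chair-vs-boat discrimination agree with the Cremer-Pople
description across all canonical forms (tested).

# Structure handling

`read_structure()` normalizes PDB and mmCIF input (via bio3d) into one atom
table; alternate locations are resolved to the highest-occupancy record
(ties to altloc A). `superpose_structures()` solves orthogonal Procrustes by
SVD over atom pairs matched by chain/residue/atom-name (default: all
alpha-carbons — the "protein frame"); improper solutions raise an error
rather than silently mirroring, except in the rank-deficient planar case
where the standard sign correction applies. `atom_displacement()` reports
the motion of a single named atom after frame superposition — the measure
behind statements like "covalent-bond formation moves the pseudo-anomeric
carbon by ~2 A, and hydrolysis returns it to within ~0.4 A of its Michaelis
position". `ligand_contacts()` calls hydrogen bonds by heavy-atom
donor-acceptor distance (default 3.5 A, no angle term since deposited
structures lack hydrogens) between ligand N/O/F and protein/water N/O atoms.

The test suite never fetches the deposited complexes; all structure
operations are exercised on synthetic fixtures built in code (ideal rings
written as single-residue PDB/mmCIF files and a small constructed
active-site complex). Users with the deposited
entries on disk can reproduce the displacement and contact analyses directly
with the same functions; which accession corresponds to which complex must
be identified by ligand content, as it is not stated alongside the
accessions.

# Known limitations

* The kinetic model has no explicit leaving-group departure step between
  binding and the covalent intermediate; the published scheme's stated
  consequences ($k_{cat} \approx k_5$, $k_{cat}/K_m = k_{inact}/K_i$)
  pin the three-step reduction used here, but a finer-grained mechanism
  would subdivide $k_3$.
* $k_1$ is not observable in any of the assays; the reference schemes use
  1e5 M^-1 s^-1, large enough that rapid equilibrium holds. Only $K_d$
  -dependent quantities are meaningful.
* Five-membered-ring (pseudorotation) analysis, itinerary interpolation
  along reaction coordinates, QM/MM energetics, and crystallographic noise
  are out of scope.
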