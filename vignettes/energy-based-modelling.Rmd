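---
title: "Energy-based modelling with bondgraphr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based modelling with bondgraphr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondgraphr)
```

# The modelling framework

A bond graph describes a physical system as a graph whose edges ("bonds")
each carry a conjugate pair of variables: an *effort* $e$ (a generalized
potential — voltage, chemical potential) and a *flow* $f$ (a generalized
flux — current, molar rate). Their product $e f$ is power, so the graph is
simultaneously a wiring diagram and an energy ledger. Because every
constitutive element either stores, dissipates, or losslessly transforms
energy, models built this way are thermodynamically consistent by
construction: no parameter choice can create a perpetual-motion cycle.

Vertices are of two kinds:

* **Components** carry acausal constitutive relations over their port
  variables. No input/output direction is assigned; the relations are
  equations, not assignments.
* **Junctions** impose conservation laws. A 0-junction forces equal effort
  on all attached bonds and a signed flow balance
  $\sum_b \sigma_b f_b = 0$; a 1-junction is the dual (equal flow, signed
  effort balance). The sign $\sigma_b$ is $+1$ for a bond oriented into the
  junction and $-1$ out of it; the bond arrow is purely a sign convention
  for which direction counts as positive power.

## Component conventions

All built-in relations are written with port flows **positive into the
component**. A component at the target end of a bond sees the bond flow
$+f$, at the source end $-f$. Under this convention:

| type | relations | role |
|------|-----------|------|
| `C`  | $e = q/C$, $\dot q = f$ | linear storage |
| `R`  | $e = R f$ | linear dissipation |
| `Se`/`Sf` | $e = e_s(t)$ / $f = f_s(t)$ | effort / flow source |
| `TF` | $e_0 = n e_1$, $f_1 = -n f_0$ | lossless transformer |
| `Ce` | $e = R T \ln(K x)$, $\dot x = f$ | chemical species store |
| `ce` | $e = R T \ln(K x_s(t))$ | chemostat |
| `Re` | $f_0 = \kappa (e^{e_0/RT} - e^{e_1/RT})$, $f_1 = -f_0$ | reaction element |

With inward-positive flows, "power-conserving" reads $e_0 f_0 + e_1 f_1 =
0$ (the transformer satisfies it identically) and "dissipative" reads
$e_0 f_0 + e_1 f_1 = (e_0 - e_1) f_0 \ge 0$, which holds for the reaction
element whenever $\kappa > 0$ — this is non-negative entropy production,
and it is what makes arbitrary swapped-in rate laws safe as long as the
flow has the sign of $e_0 - e_1$.

The `Re` element implements the Marcelin–de Donder flux: the forward and
reverse potentials enter through exponentials. When its ports collect
species potentials $\mu = R T \ln(K x)$, the exponentials collapse and the
flux becomes polynomial mass action
$v = \kappa\left(\prod_r (K_r x_r)^{s_r} - \prod_p (K_p x_p)^{s_p}\right)$,
i.e. $k_f = \kappa \prod K_r^{s_r}$ and $k_r = \kappa \prod K_p^{s_p}$.
Because both rate constants share the single $\kappa$ and the equilibrium
constant is a ratio of species $K$s, equilibrium constants around any
closed cycle multiply to one automatically (the Wegscheider condition) —
detailed balance is structural, not a parameter restriction.

Amounts are treated as molar quantities in a unit volume, so $K x$ is
dimensionless; compartment volumes are folded into $K$. Two-port components
index port 0 as the forward/scaled side and port 1 as the reverse/unscaled
side; this indexing is what makes symbolic assembly deterministic.

## Global constants

`R_gas` = 8.314 J mol⁻¹ K⁻¹, `T` = 310 K (physiological), `F_faraday` =
96485 C mol⁻¹, standard values carried per model and overridable at
construction (`bondgraph(globals = ...)`). Test code frequently sets all
three to 1 so that chemical potentials are plain logarithms and closed
forms are exact.

# Symbolic reduction

`assemble()` allocates one $(e_i, f_i)$ pair per bond (insertion order,
which makes naming reproducible across identical construction runs),
instantiates junction laws and name-prefixed constitutive relations, and
records per-reaction flux expressions, per-bond powers, and storage
energies. `reduce_system()` then eliminates the bond variables:

1. **Triangular linear elimination.** Repeatedly pick an equation in which
   some unknown (a bond variable or a state derivative $d(x)$) occurs
   linearly with a coefficient free of unknowns, solve, and substitute into
   all remaining equations and previously found solutions. Junction
   equalities are consumed by the same mechanism (they are trivially
   linear), so no separate aliasing pass is needed.
2. **Log/exp rewriting.** Expressions are normalised into a sum-of-products
   form over atomic factors; on entry to this form
   $\exp(s_1 \ln v_1 + s_2 \ln v_2 + r) \to v_1^{s_1} v_2^{s_2} e^{r}$ for
   numeric $s_i$, and symbolic or numeric $R T$ factors cancel exactly.
   This is the step that turns Ce+Re subsystems into polynomial mass
   action.
3. **Residuals.** Whatever the linear pass cannot resolve (an unknown
   buried inside an exponential, say) is returned in `algebraic` as a DAE
   constraint — never dropped. A leftover constraint touching neither
   unknowns nor states (two unequal effort sources forced equal) is a
   structural singularity and raises an error instead. DAEs are reported,
   not index-reduced, and the integrator refuses them.

States are ordered alphabetically by full path name; bonds by insertion
order; the normal form sorts terms by a radix (locale-independent) key.
These tie-breaks make `equations_text()` output identical across runs.
Symbolic zero tests tolerate coefficient round-off below $10^{-10}$, and
coefficients within $10^{-9}$ relative of an integer are snapped, which
absorbs floating-point noise from substituted numeric parameters (e.g.
$RT/RT$ products) without touching genuine fractions like $z/2$.

Hierarchical models are flattened before assembly: inner vertices are
renamed `subsystem/vertex`, and bonds attached to an exposed subsystem
port are reattached to the corresponding inner port. The reduced equations
of a nested model equal those of the hand-flattened model up to this
renaming, which the test suite checks on wrapped-species, wrapped-reaction,
and two-level-nested cases.

## Structural editing semantics

`swap_node()` reattaches bonds port-for-port, so a mass-action `Re` can be
exchanged for any registered two-port rate law without touching the
network. `insert_node()` splits a bond, preserving orientation; inserting
`TF` with $n = 1$ is verified to be an equation-level no-op.
`merge_nodes()` unifies two vertices representing the same object; it
requires identical definitions and refuses mismatched bound parameter
values rather than silently preferring one side.

One deliberate asymmetry: `connect()` refuses a second bond on a one-port
component, but `merge_nodes()` may leave a one-port store carrying several
bonds (merging two copies of a species, each already wired to its own
reaction, must keep both wires). Assembly gives such a vertex implicit
0-junction semantics — equal effort on all its bonds, flows summed into
the single constitutive relation — which is exactly the mass-balance
meaning of a shared species. Two-port components cannot grow this way, and
`swap_node()` keeps the strict arity check, so a three-bond junction still
cannot be swapped for a one-port.

# Reaction-network conversion

`parse_reactions()` reads one reversible reaction per line
(`(1, 1) A + 2 B <--> C`); the parenthesised placeholder rates are
accepted and discarded, since kinetics come from the energy parameters
$K$ (per species) and $\kappa$ (per reaction) set afterwards. Irreversible
arrows are deliberately unsupported: the reaction element is inherently
reversible, and a one-way reaction would break thermodynamic consistency.

`to_bondgraph()` gives each species a `Ce` (or `ce` if chemostatted) on a
dedicated 0-junction, each reaction an `Re` with a forward 1-junction
collecting reactant potentials and a reverse 1-junction collecting product
potentials, and realises a stoichiometric coefficient $s > 1$ as a
transformer of ratio $s$ with its scaled port on the reaction side (so the
1-junction sees $s \mu$ and the species sees $s v$). A 1-junction with a
single species-side bond is elided — a two-bond junction is an identity —
which matches compact published drawings; correctness of the elision is
pinned by the transformer-no-op equivalence property. A species appearing
on both sides of one reaction gets bonds to both 1-junctions, keeping the
stoichiometric matrix exact.

# Simulation and steady states

`simulate_model()` integrates with `deSolve::ode` (lsoda: stiff-capable,
switching automatically), default `rtol` $10^{-8}$ / `atol` $10^{-10}$ —
biochemical cycles are routinely stiff, and these tolerances keep
conserved totals flat to $\sim 10^{-9}$ over the horizons used here.
Time-driven inputs (chemostat amounts, source values) are plain R
functions of time evaluated at solver steps; they are assumed smooth, and
the shipped transient is a Gaussian bump (`spike_input()`), the package's
own stand-in for a generic signalling spike. Sharp discontinuities would
need integrator breakpoints, which are not implemented.

`steady_state()` runs damped Newton on the reduced right-hand side with a
numerical Jacobian, seeded from the endpoint of a relaxation integration
to $t = 100/\min \kappa$ (or a user guess). Closed networks have singular
Jacobians (one direction per conserved moiety); the Newton step then falls
back to the minimum-norm pseudo-inverse solution, which leaves the seed's
moiety totals untouched — so the answer is the equilibrium on the correct
stoichiometric compatibility class. Convergence is declared when the
residual infinity-norm falls below `tol` ($10^{-10}$) **or** the full
Newton step is below `tol` in state space; the second test matters for
multiphysics models where constants like the Faraday number scale residuals
by $10^5$ and the absolute residual floor sits at machine precision times
that scale.

`conserved_moieties()` computes the integer left null space of the
stoichiometric matrix by exact rational Gaussian elimination (numerators
and denominators as exact integers, well inside double precision for any
realistic network), then clears denominators and common factors, so the
reported moieties are exact small-integer weight vectors, not numerically
orthonormalised ones. Chemostatted species are removed first.

# Worked fixtures and what they pin down

**Ion pore.** The membrane potential is a capacitor on a voltage
0-junction; a transformer of ratio $F$ converts to molar electrical
potential, and two transformers $\pm z/2$ split it across the membrane
faces, so the pore's forward side sees $\mu_e - zFV/2$ and the reverse
side $\mu_i + zFV/2$. At steady state the flux vanishes and
$V = \frac{RT}{zF} \ln(x_e / x_i)$ — the Nernst potential in the standard
electrophysiology convention ($[\text{out}]/[\text{in}]$). Which face gets
$+z/2$ is a free sign choice; this package fixes it so that the recovered
potential follows that convention, and the test matrix covers
$z \in \{-1, 1, 2\}$ (Cl⁻, Na⁺/K⁺, Ca²⁺-like) and ratios 0.1 and 10.

**SERCA-type pump.** A six-state lumped conformational cycle built
entirely through the reaction-network interface, transporting two Ca²⁺
per ATP with ADP/Pi/H⁺ bookkeeping; metabolites and calcium pools are
chemostats, and the pump conformations carry a single conserved moiety.
The default parameters (all $K$, $\kappa$, and chemostat amounts equal to
one) are the package's own reference condition chosen to sit exactly at
detailed balance, not literature values; raising the ATP amount drives a
sustained positive cycle flux, and a calcium spike transiently loads the
calcium-bound states. Acceptance for this fixture is structural and
thermodynamic (counts, moiety conservation, detailed balance, pumping
sign), not trajectory matching.

**ABC cycle.** The minimal closed loop. Its equilibrium ratios are set by
the $K$s alone ($x_B/x_A = K_A/K_B$, independent of every $\kappa$), and
every individual flux vanishes there — no perpetual cycling.

# What the random-network generator does and does not emulate

Property tests and the acceptance script draw random reversible networks
with up to 5 species, up to 4 reactions, stoichiometric coefficients up to
2, and parameters uniform in $[0.2, 3]$ — the regime where exhaustive
symbolic and numeric cross-checking against the independent mass-action
oracle stays fast (the whole suite runs in well under a minute, and the
acceptance script integrates 8 random closed networks over $t \in [0,
10]$). These sizes are a choice of test economy, not a limit of the
machinery; the SERCA fixture (12 species, 6 reactions, transformers) is
the larger structured case. What the generator does **not** emulate:
irreversible steps, explicit compartment volumes, spatial transport,
stochasticity, and measurement noise. A green suite therefore certifies
the algebra and thermodynamics of the pipeline, not fit to any particular
experimental dataset.

# Known limitations

* DAE systems are detected and returned but not integrated or
  index-reduced.
* The stored-energy observable $RT(x \ln(Kx) - x)$ evaluates to `NaN` at
  exactly zero amounts (the $0 \cdot \ln 0$ limit is 0 mathematically, but
  the expression is evaluated literally); start trajectories you want
  energy accounting for at positive amounts.
* Michaelis–Menten-style reaction variants are not built in; they enter
  through `register_definition()` plus `swap_node()`, and their
  thermodynamic consistency is the definer's responsibility (the
  dissipativity property above is the criterion to meet).
* Function-valued (time-driven) parameters cannot be serialized to the
  JSON model document; bind them at simulation time.
* CLI option values beginning with `-` (negative numbers) are not
  supported by the lightweight argument scanner.
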