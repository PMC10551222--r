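# bondgraphr

Energy-based bond graph modelling for systems biology, in R.

Bond graphs describe a physical system as a graph whose edges carry a
conjugate *effort/flow* pair — chemical potential and molar rate, voltage
and current — whose product is power. Components (graph vertices) hold
acausal constitutive relations; junctions impose conservation laws
(0-junction: equal effort, flows balance; 1-junction: equal flow, efforts
balance). Because every element stores, dissipates, or losslessly
transforms energy, models assembled this way obey the laws of
thermodynamics by construction: detailed balance at equilibrium comes for
free, and no parameter choice can produce a perpetual-motion cycle.

The package is aimed at systems biologists and mathematical modellers who
want to build electro-chemical and biochemical network models that are
correct-by-construction, derive their ODEs symbolically, and simulate
them — without hand-writing rate equations.

## The core model

A chemical species store (`Ce`) has chemical potential

    mu = R T ln(K x)

and a reaction element (`Re`) carries the Marcelin–de Donder flux

    v = kappa * (exp(mu_f / RT) - exp(mu_r / RT))

where `mu_f`, `mu_r` are the total reactant/product potentials collected by
the reaction's junctions. When the ports see species potentials, the
exponentials collapse to polynomial mass action with

    k_f = kappa * prod(K_reactant^s),   k_r = kappa * prod(K_product^s)

so equilibrium constants are ratios of species `K`s and automatically
satisfy the Wegscheider cycle condition. Transformers (`TF`) scale
effort one way and flow the other (stoichiometric coefficients, the
Faraday constant), capacitors (`C`) store charge, chemostats (`ce`) clamp
species as energy sources.

Models are built vertex-by-vertex (`add_node()`, `connect()`), edited
structurally (`swap_node()`, `insert_node()`, `merge_nodes()`, subsystem
nesting with `as_subsystem()`), or generated from reaction-network text
(`parse_reactions()`, `to_bondgraph()`). `reduce_system()` eliminates the
per-bond variables symbolically — including the log/exp rewriting that
yields mass action — and `simulate_model()` / `steady_state()` handle the
numerics.

## Worked example: an enzyme mechanism

```r
library(bondgraphr)

rn <- parse_reactions(c("E + S <--> ES", "(1, 1) ES <--> E + P"))
bg <- to_bondgraph(rn, K = c(E = 1, S = 1, ES = 1, P = 1),
                   kappa = c(r1 = 1, r2 = 1),
                   x0 = c(E = 1, S = 2, ES = 0, P = 0),
                   globals = list(R_gas = 1, T = 1, F_faraday = 1))
derive_equations(bg)
#> <equation system> 4 state(s), 0 parameter(s)
#>   d x_E/dt = 2 * x_ES - x_E * x_P - x_E * x_S
#>   d x_ES/dt = -(2 * x_ES) + x_E * x_P + x_E * x_S
#>   d x_P/dt = x_ES - x_E * x_P
#>   d x_S/dt = x_ES - x_E * x_S
```

The mass-action equations were derived, not typed: with all `K = kappa = 1`
and `RT = 1`, both reactions get `k_f = k_r = 1`. The exact conserved
moieties (total enzyme, substrate minus product imbalance) fall out of the
stoichiometric matrix:

```r
conserved_moieties(bg)
#>      E  S ES  P
#> [1,] 1  0  1  0
#> [2,] 1 -1  0 -1
```

Simulate and find the equilibrium:

```r
tr <- simulate_model(bg, c(0, 10))
tr[c(1, 51, 201), c("time", "x_E", "x_S", "x_ES", "x_P", "v_r1")]
#>    time   x_E   x_S  x_ES   x_P    v_r1
#> 1   0   1     2     0     0     2
#> 2   2.5 0.562 1.00  0.438 0.559 0.125
#> 3  10   0.562 0.784 0.438 0.777 0.00185

round(steady_state(bg), 6)
#>      x_E     x_ES      x_P      x_S
#> 0.561553 0.438447 0.780776 0.780776
```

At the steady state every individual reaction flux is below `3e-14`:
detailed balance, guaranteed by the energy parameterization. Trajectories
are tibbles (`tidy()`, `glance()`, `autoplot()` provided), and include the
per-reaction fluxes, per-bond powers, and total stored energy as columns.

A multiphysics example — an ion pore coupling a membrane capacitor to
clamped ion pools through `F` and `±z/2` transformers — recovers the
Nernst potential at steady state:

```r
V <- steady_state(ion_pore(z = 1, x_e = 10, x_i = 1))[["q_mem"]]
round(1000 * V, 3)  # mV, R_gas*T/F * ln(10) at 310 K
#> [1] 61.507
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/bondgraph`:

```sh
bondgraph build network.rxn --chemostats A,B -o model.json
bondgraph equations model.json --format latex
bondgraph simulate model.json --tspan 0 10 --params K_A=1 kappa_r1=2 \
          --init x_B=1 -o traj.csv
bondgraph info model.json
```

Model documents are schema-versioned JSON with embedded custom component
definitions; trajectories are RFC 4180 CSV.

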