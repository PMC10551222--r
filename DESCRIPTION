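Package: bondgraphr
Title: Energy-Based Bond Graph Modelling for Systems Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct bond graph models of biophysical systems --
    energy-conserving directed multigraphs whose edges carry conjugate
    effort/flow (potential/flux) pairs -- and derive their governing
    equations symbolically. Components carry acausal constitutive
    relations (capacitors, resistors, chemical species with logarithmic
    chemical potential, Marcelin-de Donder reaction elements,
    transformers); junctions enforce conservation laws. Bond graphs can
    be edited structurally (swap, insert, merge, hierarchical nesting),
    generated automatically from chemical reaction network text, reduced
    to explicit ODE (or flagged DAE) systems with mass-action
    simplification, and integrated numerically with stiff solvers.
    Includes steady-state location, exact conserved-moiety computation,
    JSON model serialization, CSV trajectory export, and a command-line
    pipeline from reaction text to simulated trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    generics,
    jsonlite,
    MASS,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
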