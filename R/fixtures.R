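# Worked example models: an electrochemical ion pore, a SERCA-type calcium
# pump cycle built through the reaction-network interface, and a minimal
# closed three-species cycle.

#' Ion pore transport model (electrochemical)
#'
#' A pore carries an ion of charge number `z` across a membrane. The membrane
#' potential is an electrical capacitor `C:mem` on a 0-junction; a
#' transformer of ratio `F_faraday` converts voltage to molar electrical
#' potential; two transformers of ratio `+z/2` and `-z/2` split that
#' potential across the two faces of the membrane, so the external and
#' internal 1-junctions combine chemical potential (from clamped ion pools
#' `ce:ion_e`, `ce:ion_i`) with `-zFV/2` and `+zFV/2` respectively; the
#' energy-dissipating transport step is `Re:pore` between them.
#'
#' The reduced model has a single state, the membrane charge `q_mem`, with
#' net flux `kappa (exp((mu_e - zFV/2)/RT) - exp((mu_i + zFV/2)/RT))` and
#' `V = q_mem / C_mem`. At steady state the flux vanishes and `V` is the
#' Nernst potential `(R_gas T / zF) log(x_e / x_i)` (electrophysiology
#' convention, outside over inside).
#'
#' @param z integer charge number, nonzero (e.g. +1 Na+/K+, -1 Cl-, +2 Ca2+).
#' @param x_e,x_i external/internal clamped ion amounts, positive. `x_e` may
#'   also be a function of time.
#' @param C_mem membrane capacitance.
#' @param kappa pore rate constant.
#' @param K_ion ion energy parameter (same species on both sides).
#' @param q0 initial membrane charge.
#' @param globals global constants, see [default_globals()].
#' @return a `bondgraph` whose reduced system has one state `q_mem`.
#' @export
#' @examples
#' ss <- steady_state(ion_pore(z = 1, x_e = 10, x_i = 1))
#' V <- ss[["q_mem"]]  # C_mem = 1
ion_pore <- function(z = 1L, x_e = 10, x_i = 1, C_mem = 1, kappa = 1,
                     K_ion = 1, q0 = 0, globals = default_globals()) {
  if (z == 0) stop("the charge number z must be nonzero", call. = FALSE)
  if ((is.numeric(x_e) && x_e <= 0) || (is.numeric(x_i) && x_i <= 0)) {
    stop("ion amounts must be positive", call. = FALSE)
  }
  bg <- bondgraph("ion_pore", globals = globals)
  bg <- add_node(bg, component("C", "mem", C = C_mem, q = q0))
  bg <- add_node(bg, junction("zero", "J0_V"))
  bg <- add_node(bg, component("TF", "F", n = globals$F_faraday))
  bg <- add_node(bg, junction("zero", "J0_mu"))
  bg <- add_node(bg, component("TF", "zhalf_e", n = -z / 2))
  bg <- add_node(bg, component("TF", "zhalf_i", n = +z / 2))
  bg <- add_node(bg, junction("one", "J1_e"))
  bg <- add_node(bg, junction("one", "J1_i"))
  bg <- add_node(bg, component("ce", "ion_e", K = K_ion, xs = x_e))
  bg <- add_node(bg, component("ce", "ion_i", K = K_ion, xs = x_i))
  bg <- add_node(bg, component("Re", "pore", kappa = kappa))
  bg <- connect(bg, "J0_V", "mem")
  bg <- connect(bg, "J0_V", port("F", 1L))       # voltage side
  bg <- connect(bg, port("F", 0L), "J0_mu")      # F*V side
  bg <- connect(bg, "J0_mu", port("zhalf_e", 1L))
  bg <- connect(bg, "J0_mu", port("zhalf_i", 1L))
  bg <- connect(bg, port("zhalf_e", 0L), "J1_e")  # contributes -zFV/2
  bg <- connect(bg, port("zhalf_i", 0L), "J1_i")  # contributes +zFV/2
  bg <- connect(bg, "ion_e", "J1_e")
  bg <- connect(bg, "ion_i", "J1_i")
  bg <- connect(bg, "J1_e", port("pore", 0L))
  bg <- connect(bg, "J1_i", port("pore", 1L))
  bg
}

# six-state SERCA-type pump cycle; a lumped conformational cycle transporting
# two Ca2+ per ATP, with proton and phosphate bookkeeping
.SERCA_REACTIONS <- c(
  "# SERCA-type pump: six lumped conformations P1..P6",
  "(1, 1) P1 + ATP <--> P2",
  "(1, 1) P2 + 2 Cai <--> P3",
  "(1, 1) P3 <--> P4 + ADP",
  "(1, 1) P4 <--> P5 + 2 Casr",
  "(1, 1) P5 <--> P6 + Pi",
  "(1, 1) P6 <--> P1 + H"
)

#' SERCA-type pump model from the reaction-network interface
#'
#' A six-state lumped cycle of pump conformations (`P1`..`P6`) that couples
#' ATP hydrolysis to the transport of two Ca2+ ions per cycle, built entirely
#' through [parse_reactions()] / [to_bondgraph()]. Metabolites (`ATP`, `ADP`,
#' `Pi`, `H`) and the two calcium pools (`Cai` cytosolic, `Casr` luminal) are
#' chemostats; the pump conformations are states carrying one conserved
#' moiety (total pump).
#'
#' All energy parameters default to 1 and all chemostat amounts to 1, which
#' is a detailed-balance (equilibrium) condition; raising the ATP amount (or
#' driving `Cai`) pushes the cycle away from equilibrium and produces a
#' sustained pumping flux. Defaults here are the package's own reference
#' condition, not literature values.
#'
#' @param chemostat_amounts named amounts for the six chemostats; entries may
#'   be functions of time (e.g. a Ca2+ spike for `Cai`).
#' @param kappa named reaction rate constants `r1`..`r6`.
#' @param K named species energy constants.
#' @param pump0 named initial amounts for `P1`..`P6`.
#' @param cai_spike if `TRUE`, the cytosolic calcium chemostat is driven by
#'   [spike_input()] instead of held constant.
#' @param globals global constants.
#' @return a `bondgraph` with six states and six reactions.
#' @export
#' @examples
#' sys <- reduce_system(serca_like())
#' names(sys$states)
serca_like <- function(chemostat_amounts = NULL, kappa = NULL, K = NULL,
                       pump0 = NULL, cai_spike = FALSE,
                       globals = default_globals()) {
  rn <- parse_reactions(.SERCA_REACTIONS)
  chemostats <- c("ATP", "ADP", "Pi", "H", "Cai", "Casr")
  amounts <- stats::setNames(as.list(rep(1, 6)), chemostats)
  if (!is.null(chemostat_amounts)) amounts[names(chemostat_amounts)] <- chemostat_amounts
  if (cai_spike && is.null(chemostat_amounts$Cai)) amounts$Cai <- spike_input()
  pumps <- paste0("P", 1:6)
  p0 <- stats::setNames(rep(1 / 6, 6), pumps)
  if (!is.null(pump0)) p0[names(pump0)] <- unlist(pump0)
  kap <- stats::setNames(rep(1, 6), paste0("r", 1:6))
  if (!is.null(kappa)) kap[names(kappa)] <- unlist(kappa)
  Kv <- stats::setNames(rep(1, length(rn$species)), rn$species)
  if (!is.null(K)) Kv[names(K)] <- unlist(K)
  x0 <- c(as.list(p0), amounts)
  to_bondgraph(rn, chemostats = chemostats, K = as.list(Kv), kappa = kap,
               x0 = x0, name = "serca_like", globals = globals)
}

#' Smooth spike input function
#'
#' A Gaussian bump `baseline + A exp(-(t - t0)^2 / (2 sigma^2))`, used as a
#' smooth stand-in for transient signals such as a cytosolic Ca2+ spike.
#'
#' @param amplitude peak height above baseline.
#' @param t0 peak time.
#' @param sigma width.
#' @param baseline resting level.
#' @return a function of time.
#' @export
#' @examples
#' f <- spike_input(amplitude = 5, t0 = 2, sigma = 0.5)
#' f(2)
spike_input <- function(amplitude = 4, t0 = 5, sigma = 1, baseline = 1) {
  force(amplitude); force(t0); force(sigma); force(baseline)
  function(t) baseline + amplitude * exp(-(t - t0)^2 / (2 * sigma^2))
}

#' Closed three-species cycle A = B = C = A
#'
#' Minimal closed-loop test model: three species stores and three reversible
#' mass-action reactions in a loop. In the energy parameterization the
#' product of equilibrium constants around the cycle is automatically 1
#' (Wegscheider condition), so equilibrium shows detailed balance -- every
#' individual reaction flux vanishes and there is no perpetual cycle flux.
#'
#' @param K named species constants (`A`, `B`, `C`).
#' @param kappa named rate constants (`r1`, `r2`, `r3`).
#' @param x0 named initial amounts.
#' @param globals global constants.
#' @return a `bondgraph`.
#' @export
#' @examples
#' derive_equations(abc_cycle())
abc_cycle <- function(K = c(A = 1, B = 1, C = 1),
                      kappa = c(r1 = 1, r2 = 1, r3 = 1),
                      x0 = c(A = 1, B = 1, C = 1),
                      globals = default_globals()) {
  rn <- parse_reactions(c("A <--> B", "B <--> C", "C <--> A"))
  to_bondgraph(rn, K = as.list(K), kappa = kappa, x0 = x0,
               name = "abc_cycle", globals = globals)
}
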