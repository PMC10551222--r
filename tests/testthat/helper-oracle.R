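# Independent oracles and random-model generators used across tests.

# unit global constants make chemical potentials plain logs
unit_globals <- function() list(R_gas = 1, T = 1, F_faraday = 1)

# Textbook mass-action right-hand side for a reaction network, computed
# straight from the stoichiometric matrix with k_f = kappa * prod(K_reactant^s)
# and k_r = kappa * prod(K_product^s). Independent of the bond-graph pipeline.
mass_action_rhs <- function(rn, K, kappa, x) {
  N <- rn$stoichiometry
  v <- numeric(length(rn$reactions))
  for (j in seq_along(rn$reactions)) {
    r <- rn$reactions[[j]]
    kf <- kappa[[r$name]] * prod(K[names(r$reactants)]^r$reactants)
    kr <- kappa[[r$name]] * prod(K[names(r$products)]^r$products)
    v[j] <- kf * prod(x[names(r$reactants)]^r$reactants) -
      kr * prod(x[names(r$products)]^r$products)
  }
  drop(N %*% v)
}

# random reversible reaction network: <= n_species species, <= n_reactions
# reactions, stoichiometric coefficients <= 2
random_network <- function(n_species = 5, n_reactions = 4) {
  ns <- sample(2:n_species, 1)
  nr <- sample(1:n_reactions, 1)
  species <- LETTERS[seq_len(ns)]
  lines <- character(0)
  for (j in seq_len(nr)) {
    repeat {
      k_r <- sample(1:2, 1)
      k_p <- sample(1:2, 1)
      reac <- sample(species, k_r)
      prod <- sample(species, k_p)
      if (!setequal(reac, prod)) break
    }
    term <- function(sps) paste(vapply(sps, function(sp) {
      s <- sample(1:2, 1, prob = c(0.8, 0.2))
      if (s > 1) paste(s, sp) else sp
    }, character(1)), collapse = " + ")
    lines <- c(lines, paste(term(reac), "<-->", term(prod)))
  }
  parse_reactions(lines)
}

random_params <- function(rn) {
  list(
    K = stats::setNames(stats::runif(length(rn$species), 0.2, 3), rn$species),
    kappa = stats::setNames(stats::runif(length(rn$reactions), 0.2, 3),
                            vapply(rn$reactions, `[[`, "", "name"))
  )
}

# numeric equality of the reduced system and the oracle at random states
max_rel_err_vs_oracle <- function(rn, n_states = 20) {
  p <- random_params(rn)
  bg <- to_bondgraph(rn, K = as.list(p$K), kappa = p$kappa,
                     globals = unit_globals())
  sys <- reduce_system(assemble(bg))
  worst <- 0
  for (k in seq_len(n_states)) {
    x <- stats::setNames(stats::runif(length(rn$species), 0.1, 2), rn$species)
    vals <- as.list(stats::setNames(x, paste0("x_", rn$species)))
    got <- vapply(rn$species, function(sp) {
      eval(sys$odes[[paste0("x_", sp)]], envir = vals)
    }, numeric(1))
    want <- mass_action_rhs(rn, p$K, p$kappa, x)
    scale <- pmax(abs(want), 1e-8)
    worst <- max(worst, max(abs(got - want) / scale))
  }
  worst
}

expect_symbolic_zero <- function(expr) {
  expect_true(bondgraphr:::nf_is_zero(bondgraphr:::to_nf(expr)))
}

tempfile_model <- function(bg) {
  p <- tempfile(fileext = ".json")
  save_model(bg, p)
  p
}

# A <--> B bond graph with unit parameters, the analytically solvable model
ab_model <- function(x_A = 1, x_B = 0, kappa = 1) {
  to_bondgraph(parse_reactions("A <--> B"), K = c(A = 1, B = 1),
               kappa = c(r1 = kappa), x0 = c(A = x_A, B = x_B),
               globals = unit_globals())
}
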