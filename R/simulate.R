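# Numerical simulation, steady states, and conserved moieties.

# substitute numeric parameter values into every expression of a system
.bind_params <- function(sys, params) {
  if (length(params)) {
    bad <- setdiff(names(params), sys$params)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    map <- lapply(params, function(v) as.numeric(v))
    sys$odes <- lapply(sys$odes, expr_subst, map = map)
    sys$algebraic <- lapply(sys$algebraic, expr_subst, map = map)
    sys$observables$fluxes <- lapply(sys$observables$fluxes, expr_subst, map = map)
    sys$observables$powers <- lapply(sys$observables$powers, expr_subst, map = map)
    if (!is.null(sys$observables$energy)) {
      sys$observables$energy <- expr_subst(sys$observables$energy, map)
    }
    sys$params <- setdiff(sys$params, names(params))
  }
  sys
}

.apply_init <- function(sys, init) {
  if (length(init)) {
    bad <- setdiff(names(init), names(sys$states))
    if (length(bad)) {
      stop("unknown state(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    sys$states[names(init)] <- unlist(init)
  }
  sys
}

.prepare_problem <- function(sys, params, init) {
  if (inherits(sys, "bondgraph")) sys <- reduce_system(assemble(sys))
  stopifnot(inherits(sys, "bg_equation_system"))
  if (!sys$is_ode) {
    stop("the system is a DAE (", length(sys$algebraic),
         " algebraic residual(s)); only explicit ODE systems can be integrated",
         call. = FALSE)
  }
  sys <- .bind_params(sys, params)
  sys <- .apply_init(sys, init)
  if (length(sys$params)) {
    stop("unbound parameter(s): ", paste(sys$params, collapse = ", "), call. = FALSE)
  }
  if (anyNA(sys$states)) {
    stop("unbound initial state(s): ",
         paste(names(sys$states)[is.na(sys$states)], collapse = ", "), call. = FALSE)
  }
  sys
}

# compiled right-hand side closure for deSolve
.make_rhs <- function(sys) {
  fun_env <- list2env(sys$inputs, parent = baseenv())
  exprs <- sys$odes[names(sys$states)]
  function(t, y, parms) {
    env <- list2env(as.list(y), parent = fun_env)
    env$t <- t
    list(vapply(exprs, eval, numeric(1), envir = env))
  }
}

.eval_named <- function(exprs, values, t, fun_env) {
  env <- list2env(as.list(values), parent = fun_env)
  env$t <- t
  vapply(exprs, eval, numeric(1), envir = env)
}

#' Integrate a reduced bond-graph model
#'
#' Adaptive stiff-capable integration (lsoda) of the explicit ODE system,
#' with flux, per-bond power, and stored-energy observables evaluated along
#' the solution. Deterministic given identical inputs and tolerances.
#'
#' @param sys a `bg_equation_system` (or a `bondgraph`, reduced on the fly).
#' @param tspan numeric length-2, `(t0, t1)` with `t1 > t0`.
#' @param params named list/vector completing the parameter mapping.
#' @param init named list/vector completing (or overriding) initial states.
#' @param n_out number of equally spaced output times.
#' @param times explicit output times (overrides `n_out`).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method deSolve method name.
#' @return a `bg_trajectory` tibble: `time`, one column per state, one per
#'   reaction flux (`v_<name>`), per-bond powers `P_<i>`, and `E_total`.
#' @export
#' @examples
#' sys <- reduce_system(abc_cycle())
#' tr <- simulate_model(sys, c(0, 5))
simulate_model <- function(sys, tspan, params = list(), init = list(),
                           n_out = 201L, times = NULL,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  sys <- .prepare_problem(sys, params, init)
  stopifnot(is.numeric(tspan), length(tspan) == 2L, tspan[2] > tspan[1])
  if (is.null(times)) times <- seq(tspan[1], tspan[2], length.out = n_out)
  # integration starts at tspan[1] even when the first requested output
  # time lies later
  drop_first <- FALSE
  if (times[1] > tspan[1]) {
    times <- c(tspan[1], times)
    drop_first <- TRUE
  }
  rhs <- .make_rhs(sys)
  y0 <- sys$states
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("integration failed: ", paste(istate, collapse = " "), call. = FALSE)
  }
  if (drop_first) out <- out[-1, , drop = FALSE]
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  fun_env <- list2env(sys$inputs, parent = baseenv())
  obs_exprs <- c(
    stats::setNames(sys$observables$fluxes,
                    paste0("v_", names(sys$observables$fluxes))),
    sys$observables$powers
  )
  if (!is.null(sys$observables$energy)) obs_exprs$E_total <- sys$observables$energy
  if (length(obs_exprs)) {
    obs <- t(vapply(seq_len(nrow(df)), function(i) {
      .eval_named(obs_exprs, df[i, names(y0), drop = FALSE], df$time[i], fun_env)
    }, numeric(length(obs_exprs))))
    colnames(obs) <- names(obs_exprs)
    df <- cbind(df, as.data.frame(obs))
  }
  tr <- tibble::as_tibble(df)
  attr(tr, "state_names") <- names(y0)
  attr(tr, "flux_names") <- paste0("v_", names(sys$observables$fluxes))
  class(tr) <- c("bg_trajectory", class(tr))
  tr
}

#' Locate a steady state
#'
#' Damped Newton iteration on the reduced right-hand side, seeded either
#' from `guess` or from the endpoint of a long relaxation integration
#' (t = 100 / smallest reaction rate constant). Singular Jacobians (closed
#' networks with conserved moieties) are handled with a minimum-norm
#' (pseudo-inverse) Newton step, which preserves the seed's moiety totals.
#'
#' @param sys a `bg_equation_system` or `bondgraph`.
#' @param params,init as in [simulate_model()].
#' @param guess optional named state vector to seed Newton directly.
#' @param tol residual infinity-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return named steady-state vector with attributes `residual` (achieved
#'   infinity norm) and `fluxes` (reaction fluxes at the steady state).
#' @export
#' @examples
#' ss <- steady_state(abc_cycle(), init = list(x_A = 3, x_B = 0, x_C = 0))
steady_state <- function(sys, params = list(), init = list(), guess = NULL,
                         tol = 1e-10, max_iter = 100L) {
  # relaxation horizon from the slowest reaction timescale when visible:
  # t = 100 / min(kappa), falling back to 100
  kap <- unlist(params[grepl("^kappa", names(params))])
  t_relax <- if (length(kap) && all(kap > 0)) 100 / min(kap) else 100
  sys <- .prepare_problem(sys, params, init)
  rhs <- .make_rhs(sys)
  # steady states are sought for autonomous dynamics: inputs frozen at t = 0
  f <- function(x) unlist(rhs(0, stats::setNames(x, names(sys$states)), NULL))
  if (is.null(guess)) {
    relax <- simulate_model(sys, c(0, t_relax), n_out = 11L)
    x <- as.numeric(relax[nrow(relax), names(sys$states)])
  } else {
    x <- unlist(guess)[names(sys$states)]
    if (anyNA(x)) stop("guess must name every state", call. = FALSE)
  }
  names(x) <- names(sys$states)
  res <- f(x)
  converged <- max(abs(res)) < tol
  for (it in seq_len(max_iter)) {
    if (converged) break
    J <- pracma::jacobian(f, x)
    step <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(step) || anyNA(step) || any(!is.finite(step))) {
      step <- as.numeric(MASS::ginv(J) %*% res)
    }
    # state-space convergence: when the full Newton step is below tolerance
    # the root is resolved to machine precision even if the residual scale
    # (set by e.g. the Faraday constant) keeps its absolute norm larger
    if (max(abs(step)) < tol) {
      x <- x - step
      res <- f(x)
      converged <- TRUE
      break
    }
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      res_new <- f(x_new)
      if (all(is.finite(res_new)) && max(abs(res_new)) < max(abs(res))) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
    x <- x_new
    res <- res_new
    converged <- max(abs(res)) < tol
  }
  if (!converged && max(abs(res)) >= tol) {
    stop(sprintf("steady state did not converge: residual %.3e after %d iterations",
                 max(abs(res)), max_iter), call. = FALSE)
  }
  fun_env <- list2env(sys$inputs, parent = baseenv())
  fluxes <- if (length(sys$observables$fluxes)) {
    .eval_named(sys$observables$fluxes, as.list(x), 0, fun_env)
  } else numeric(0)
  structure(x, residual = max(abs(res)), fluxes = fluxes)
}

# ---- exact integer left null space ----------------------------------------

# rational arithmetic on (num, den) integer pairs held in doubles
.rat <- function(n, d = 1) {
  if (d < 0) { n <- -n; d <- -d }
  g <- .gcd(abs(n), d)
  if (g > 1) { n <- n / g; d <- d / g }
  c(n, d)
}
.gcd <- function(a, b) {
  while (b > 0) { tmp <- a %% b; a <- b; b <- tmp }
  max(a, 1)
}
.rat_add <- function(x, y) .rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
.rat_mul <- function(x, y) .rat(x[1] * y[1], x[2] * y[2])
.rat_neg <- function(x) c(-x[1], x[2])
.rat_div <- function(x, y) .rat(x[1] * y[2], x[2] * y[1])

# exact RREF over the rationals; input integer matrix
.rref_exact <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  A <- array(0, dim = c(nr, nc, 2))
  A[, , 1] <- M
  A[, , 2] <- 1
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    pr <- which(A[row:nr, col, 1] != 0)
    if (!length(pr)) next
    pr <- pr[1] + row - 1L
    if (pr != row) { tmp <- A[row, , ]; A[row, , ] <- A[pr, , ]; A[pr, , ] <- tmp }
    piv <- A[row, col, ]
    for (j in seq_len(nc)) A[row, j, ] <- .rat_div(A[row, j, ], piv)
    for (i in seq_len(nr)) {
      if (i == row) next
      fac <- A[i, col, ]
      if (fac[1] == 0) next
      for (j in seq_len(nc)) {
        A[i, j, ] <- .rat_add(A[i, j, ], .rat_neg(.rat_mul(fac, A[row, j, ])))
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(A = A, pivots = pivots)
}

.lcm2 <- function(a, b) a / .gcd(a, b) * b

#' Conserved moieties of a reaction network
#'
#' Computes an exact integer basis of the left null space of the
#' stoichiometric matrix: weight vectors `g` with `g %*% N == 0`, i.e.
#' weighted species totals invariant under every reaction. Chemostatted
#' species are removed first (their rows are clamped, so only moieties
#' supported on the remaining states survive).
#'
#' @param x a `reaction_network`, a CRN-derived `bondgraph`, or a
#'   `bg_equation_system` carrying one in its metadata.
#' @param chemostats species to clamp (defaults to those recorded on the
#'   model, if any).
#' @return integer matrix with one row per moiety (possibly zero rows),
#'   columns named by the retained species states.
#' @export
#' @examples
#' conserved_moieties(parse_reactions("A + B <--> C"))
conserved_moieties <- function(x, chemostats = NULL) {
  if (inherits(x, "bg_equation_system")) {
    rn <- x$meta$rn
    if (is.null(chemostats)) chemostats <- x$meta$chemostats
  } else if (inherits(x, "bondgraph")) {
    rn <- x$meta$rn
    if (is.null(chemostats)) chemostats <- x$meta$chemostats
  } else {
    rn <- x
  }
  if (is.null(rn) || !inherits(rn, "reaction_network")) {
    stop("no stoichiometric information available (model was not derived from a reaction network)",
         call. = FALSE)
  }
  if (is.null(chemostats)) chemostats <- character(0)
  keep <- setdiff(rn$species, chemostats)
  N <- rn$stoichiometry[keep, , drop = FALSE]
  if (!length(keep)) {
    return(matrix(0L, nrow = 0, ncol = 0))
  }
  # null space of t(N): solve N^T g = 0 exactly
  R <- .rref_exact(t(N))
  nc <- ncol(t(N))
  free <- setdiff(seq_len(nc), R$pivots)
  if (!length(free)) {
    out <- matrix(0L, nrow = 0, ncol = length(keep))
    colnames(out) <- keep
    return(out)
  }
  basis <- matrix(0, nrow = length(free), ncol = nc)
  for (k in seq_along(free)) {
    fc <- free[k]
    v_num <- numeric(nc); v_den <- rep(1, nc)
    v_num[fc] <- 1
    for (i in seq_along(R$pivots)) {
      pc <- R$pivots[i]
      # pivot row i: g[pc] = -A[i, fc]
      v_num[pc] <- -R$A[i, fc, 1]
      v_den[pc] <- R$A[i, fc, 2]
    }
    den_lcm <- Reduce(.lcm2, v_den)
    g <- v_num * (den_lcm / v_den)
    cont <- Reduce(.gcd, abs(g[g != 0]))
    g <- g / cont
    lead <- g[which(g != 0)[1]]
    if (lead < 0) g <- -g
    basis[k, ] <- g
  }
  storage.mode(basis) <- "integer"
  colnames(basis) <- keep
  basis
}

#' Export a trajectory as CSV
#'
#' RFC 4180 formatting: comma-separated, quoted header fields where needed.
#'
#' @param tr a `bg_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.bg_trajectory <- function(x, ...) {
  sn <- attr(x, "state_names")
  cat(sprintf("<trajectory> %d time points over [%g, %g], %d state(s)\n",
              nrow(x), min(x$time), max(x$time), length(sn)))
  NextMethod()
}
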