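# broom-style tidiers and plotting for reduced systems and trajectories.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reduced equation system
#'
#' @param x a `bg_equation_system`.
#' @param ... unused.
#' @return tibble with one row per state: `state`, `initial`, `rhs` (plain
#'   text right-hand side).
#' @method tidy bg_equation_system
#' @export
tidy.bg_equation_system <- function(x, ...) {
  tibble::tibble(
    state = names(x$odes),
    initial = unname(x$states[names(x$odes)]),
    rhs = vapply(x$odes, deparse1, character(1))
  )
}

#' One-row summary of a reduced equation system
#'
#' @param x a `bg_equation_system`.
#' @param ... unused.
#' @return tibble with `n_states`, `n_params`, `n_inputs`, `n_fluxes`,
#'   `n_algebraic`, `is_ode`.
#' @method glance bg_equation_system
#' @export
glance.bg_equation_system <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$states),
    n_params = length(x$params),
    n_inputs = length(x$inputs),
    n_fluxes = length(x$observables$fluxes),
    n_algebraic = length(x$algebraic),
    is_ode = x$is_ode
  )
}

#' Long-format view of a trajectory
#'
#' @param x a `bg_trajectory`.
#' @param ... unused.
#' @return tibble `time`, `variable`, `value`, `kind`
#'   (state/flux/power/energy).
#' @method tidy bg_trajectory
#' @export
tidy.bg_trajectory <- function(x, ...) {
  sn <- attr(x, "state_names")
  fn <- attr(x, "flux_names")
  vars <- setdiff(names(x), "time")
  out <- do.call(rbind, lapply(vars, function(v) {
    tibble::tibble(time = x$time, variable = v, value = x[[v]])
  }))
  out$kind <- ifelse(out$variable %in% sn, "state",
              ifelse(out$variable %in% fn, "flux",
              ifelse(out$variable == "E_total", "energy", "power")))
  out
}

#' Plot a simulated trajectory
#'
#' States (and optionally fluxes) against time, one line per variable.
#'
#' @param object a `bg_trajectory`.
#' @param vars which variables to show; defaults to the states.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bg_trajectory <- function(object, vars = attr(object, "state_names"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2", call. = FALSE)
  }
  long <- tidy.bg_trajectory(object)
  long <- long[long$variable %in% vars, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "amount", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Minimal layout export for external graph drawing
#'
#' Provides node and edge tables (with a simple circular layout) so external
#' tools can draw the graph; no plotting is done here.
#'
#' @param bg a `bondgraph`.
#' @return list of tibbles `nodes` (`name`, `label`, `role`, `x`, `y`) and
#'   `edges` (`from`, `to`, `bond`).
#' @export
layout_table <- function(bg) {
  gv <- graph_view(bg)
  vn <- names(bg$vertices)
  k <- length(vn)
  theta <- if (k) 2 * pi * (seq_len(k) - 1) / k else numeric(0)
  labels <- vapply(bg$vertices, function(v) {
    switch(v$role,
      component = paste0(v$def$type_symbol, ":", v$name),
      junction = paste0(if (v$kind == "zero") "0" else "1", ":", v$name),
      subsystem = paste0("BG:", v$name))
  }, character(1))
  list(
    nodes = tibble::tibble(name = vn, label = unname(labels),
                           role = vapply(bg$vertices, `[[`, "", "role"),
                           x = cos(theta), y = sin(theta)),
    edges = gv$adjacency[, c("from", "to", "bond")]
  )
}
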