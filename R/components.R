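# Component definitions and the built-in library.
#
# A component definition carries acausal constitutive relations written as
# two-sided formulas over port variables (e_0, f_0, e_1, f_1), declared
# states and parameters, time t, and the global physical constants R_gas,
# T (absolute temperature) and F_faraday. Port flows are positive INTO the
# component at every port; a power-conserving two-port therefore satisfies
# e_0*f_0 + e_1*f_1 = 0.

.GLOBAL_CONSTANT_NAMES <- c("R_gas", "T", "F_faraday")

#' Default global physical constants
#'
#' Gas constant (J mol^-1 K^-1), absolute temperature (K, physiological
#' default) and the Faraday constant (C mol^-1). Every bond graph carries its
#' own copy, overridable at construction.
#'
#' @return named list with `R_gas`, `T`, `F_faraday`.
#' @export
#' @examples
#' default_globals()
default_globals <- function() list(R_gas = 8.314, T = 310, F_faraday = 96485)

.port_var_names <- function(port_count) {
  idx <- seq_len(port_count) - 1L
  c(paste0("e_", idx), paste0("f_", idx))
}

#' Define a component type
#'
#' @param type_symbol short type tag, e.g. `"C"`, `"Re"`.
#' @param port_count number of power ports (1 or 2).
#' @param parameters named character vector: parameter name -> unit note.
#' @param states named character vector: state name -> unit note.
#' @param relations list of two-sided formulas over port variables
#'   `e_<i>`/`f_<i>` (flow positive into the component), states, parameters,
#'   `t` and the global constants; a state derivative is written `d(q) ~ f_0`.
#' @param energy optional one-sided formula (or two-sided `energy ~ expr`)
#'   giving stored energy as a function of the state and parameters.
#' @param description free-text note.
#' @return a `component_definition` object.
#' @export
#' @examples
#' component_definition("Cnl", 1, parameters = c(C = "compliance"),
#'   states = c(q = "displacement"),
#'   relations = list(e_0 ~ q^3 / C, d(q) ~ f_0))
component_definition <- function(type_symbol, port_count,
                                 parameters = character(0),
                                 states = character(0),
                                 relations = list(),
                                 energy = NULL,
                                 description = "") {
  stopifnot(is.character(type_symbol), length(type_symbol) == 1L, nzchar(type_symbol))
  if (!port_count %in% c(1L, 2L)) {
    stop("port_count must be 1 or 2 (junctions are not library components)", call. = FALSE)
  }
  rel <- lapply(relations, function(r) {
    if (inherits(r, "formula") && length(r) == 3L) {
      list(lhs = r[[2]], rhs = r[[3]])
    } else {
      stop("each relation must be a two-sided formula, e.g. e_0 ~ q / C", call. = FALSE)
    }
  })
  if (length(rel) < port_count) {
    stop("a definition needs at least as many relations as ports", call. = FALSE)
  }
  allowed <- c(names(parameters), names(states), .port_var_names(port_count),
               "t", .GLOBAL_CONSTANT_NAMES)
  for (r in rel) {
    used <- union(.relation_vars(r$lhs), .relation_vars(r$rhs))
    bad <- setdiff(used, allowed)
    if (length(bad)) {
      stop(sprintf("relation '%s ~ %s' of '%s' uses undeclared symbol(s): %s",
                   deparse1(r$lhs), deparse1(r$rhs), type_symbol,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  en <- NULL
  if (!is.null(energy)) {
    en <- if (inherits(energy, "formula")) energy[[length(energy)]] else energy
  }
  structure(list(type_symbol = type_symbol, port_count = as.integer(port_count),
                 parameters = parameters, states = states, relations = rel,
                 energy = en, description = description),
            class = "component_definition")
}

# symbols used in a relation side; arguments of d() count, the head does not
.relation_vars <- function(e) expr_vars(e)

#' Built-in component library
#'
#' Physical and biochemical one- and two-port components:
#' \describe{
#'   \item{C}{linear capacitor: `e = q/C`, `dq/dt = f`.}
#'   \item{R}{linear dissipator (Ohm's law): `e = R f`.}
#'   \item{Se / Sf}{effort / flow source; the bound value may be a constant
#'     or a function of time.}
#'   \item{TF}{transformer with ratio `n`: `e_0 = n e_1`, `f_1 = -n f_0`
#'     (power-conserving with inward-positive flows).}
#'   \item{Ce}{chemical species store: chemical potential
#'     `e = R_gas T log(K q)`, `dq/dt = f`. The amount `q` is molar in a
#'     unit volume so `K q` is dimensionless.}
#'   \item{ce}{chemostat: species clamped at amount `xs` (constant or
#'     driven), an effort source of chemical energy.}
#'   \item{Re}{Marcelin-de Donder reaction element:
#'     `f_0 = kappa (exp(e_0/R_gas T) - exp(e_1/R_gas T))`, `f_1 = -f_0`.}
#' }
#'
#' @return named list of [component_definition()] objects keyed by type symbol.
#' @export
#' @examples
#' names(builtin_library())
builtin_library <- function() {
  lib <- list()
  lib$C <- component_definition("C", 1L,
    parameters = c(C = "generalized capacitance"),
    states = c(q = "generalized displacement"),
    relations = list(e_0 ~ q / C, d(q) ~ f_0),
    energy = ~ q^2 / (2 * C),
    description = "linear storage (capacitor)")
  lib$R <- component_definition("R", 1L,
    parameters = c(R = "generalized resistance"),
    relations = list(e_0 ~ R * f_0),
    description = "linear dissipator (resistor)")
  lib$Se <- component_definition("Se", 1L,
    parameters = c(es = "imposed effort (constant or function of t)"),
    relations = list(e_0 ~ es),
    description = "effort source")
  lib$Sf <- component_definition("Sf", 1L,
    parameters = c(fs = "imposed flow (constant or function of t)"),
    relations = list(f_0 ~ fs),
    description = "flow source")
  lib$TF <- component_definition("TF", 2L,
    parameters = c(n = "transformer ratio (dimensionless)"),
    relations = list(e_0 ~ n * e_1, f_1 ~ -n * f_0),
    description = "power-conserving transformer")
  lib$Ce <- component_definition("Ce", 1L,
    parameters = c(K = "species thermodynamic constant (1/amount)"),
    states = c(x = "molar amount"),
    relations = list(e_0 ~ R_gas * T * log(K * x), d(x) ~ f_0),
    energy = ~ R_gas * T * (x * log(K * x) - x),
    description = "chemical species store")
  lib$ce <- component_definition("ce", 1L,
    parameters = c(K = "species thermodynamic constant (1/amount)",
                   xs = "clamped amount (constant or function of t)"),
    relations = list(e_0 ~ R_gas * T * log(K * xs)),
    description = "chemostat (clamped species, chemical energy source)")
  lib$Re <- component_definition("Re", 2L,
    parameters = c(kappa = "reaction rate constant (amount/time)"),
    relations = list(
      f_0 ~ kappa * (exp(e_0 / (R_gas * T)) - exp(e_1 / (R_gas * T))),
      f_1 ~ -f_0),
    description = "Marcelin-de Donder reaction element")
  lib
}

#' Register a custom component definition
#'
#' Adds a user definition to a library so it can be instantiated and swapped
#' into existing graphs (e.g. alternative thermodynamically consistent rate
#' laws in place of the mass-action `Re`).
#'
#' @param lib a library as returned by [builtin_library()].
#' @param def a [component_definition()].
#' @return the extended library.
#' @export
register_definition <- function(lib, def) {
  stopifnot(inherits(def, "component_definition"))
  if (def$type_symbol %in% names(lib)) {
    stop(sprintf("component type '%s' is already registered", def$type_symbol),
         call. = FALSE)
  }
  lib[[def$type_symbol]] <- def
  lib
}

#' Instantiate a component from a library
#'
#' The first three arguments are dot-prefixed so that arbitrary parameter
#' names passed through `...` can never partially match them.
#'
#' @param .lib component library (named list of definitions).
#' @param .type_symbol registered type tag.
#' @param .name component name, unique within its graph.
#' @param ... parameter values (numeric, or a function of time for source-like
#'   parameters) and initial state values, matched by name against the
#'   definition's declared parameters and states.
#' @return a `bg_component` vertex.
#' @export
#' @examples
#' mem <- instantiate(builtin_library(), "C", "membrane", C = 1)
instantiate <- function(.lib, .type_symbol, .name, ...) {
  lib <- .lib
  type_symbol <- .type_symbol
  name <- .name
  def <- lib[[type_symbol]]
  if (is.null(def)) {
    stop(sprintf("unknown component type '%s'", type_symbol), call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- list(...)
  params <- list()
  state0 <- list()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (nm %in% names(def$parameters)) {
      if (!is.function(v)) {
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
          stop(sprintf("parameter '%s' of '%s' must be a finite number or a function of time",
                       nm, name), call. = FALSE)
        }
        v <- as.numeric(v)
      }
      params[[nm]] <- v
    } else if (nm %in% names(def$states)) {
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop(sprintf("initial state '%s' of '%s' must be a finite number", nm, name),
             call. = FALSE)
      }
      state0[[nm]] <- as.numeric(v)
    } else {
      stop(sprintf("'%s' has no parameter or state named '%s'", type_symbol, nm),
           call. = FALSE)
    }
  }
  structure(list(name = name, role = "component", def = def,
                 params = params, state0 = state0),
            class = c("bg_component", "bg_vertex"))
}

#' Create a component using the built-in library
#'
#' Convenience wrapper around [instantiate()] with [builtin_library()],
#' mirroring constructor-style usage such as `component("C", "membrane", C = 1)`.
#'
#' @inheritParams instantiate
#' @param .lib library to draw from; defaults to the built-ins.
#' @return a `bg_component` vertex.
#' @export
component <- function(.type_symbol, .name, ..., .lib = builtin_library()) {
  instantiate(.lib, .type_symbol, .name, ...)
}

#' Create a junction vertex
#'
#' A `"zero"` junction enforces equal effort on all bonds and a signed flow
#' sum of zero (e.g. mass balance at a species); a `"one"` junction enforces
#' equal flow and a signed effort sum of zero (potentials adding along a
#' reaction path).
#'
#' @param kind `"zero"` (alias `"0"`) or `"one"` (alias `"1"`).
#' @param name vertex name.
#' @return a `bg_junction` vertex.
#' @export
#' @examples
#' junction("zero", "species_A")
junction <- function(kind, name) {
  kind <- as.character(kind)
  kind <- switch(kind, "0" = "zero", "1" = "one", kind)
  if (!kind %in% c("zero", "one")) {
    stop("junction kind must be 'zero'/'0' or 'one'/'1'", call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, role = "junction", kind = kind),
            class = c("bg_junction", "bg_vertex"))
}

# prefixed symbol for a component-local name ("C" of "mem" -> C_mem)
.pref <- function(local, name) paste0(local, "_", name)

#' Constitutive relations of a component
#'
#' Returns the component's relations with its local symbols renamed to
#' globally unique, name-prefixed symbols (state `q` of component `mem`
#' becomes `q_mem`; port variables become `e_mem`/`f_mem`, or indexed
#' `e_mem_0`, ... for two-ports).
#'
#' @param comp a `bg_component`.
#' @param substitute_params if `TRUE`, numerically bound parameters are
#'   substituted into the relations.
#' @return list of `list(lhs, rhs)` language pairs.
#' @export
#' @examples
#' constitutive_relations(component("C", "mem"))
constitutive_relations <- function(comp, substitute_params = FALSE) {
  stopifnot(inherits(comp, "bg_component"))
  def <- comp$def
  map <- list()
  for (p in names(def$parameters)) map[[p]] <- as.name(.pref(p, comp$name))
  for (s in names(def$states)) map[[s]] <- as.name(.pref(s, comp$name))
  if (def$port_count == 1L) {
    map[["e_0"]] <- as.name(.pref("e", comp$name))
    map[["f_0"]] <- as.name(.pref("f", comp$name))
  } else {
    for (i in seq_len(def$port_count) - 1L) {
      map[[paste0("e_", i)]] <- as.name(paste0(.pref("e", comp$name), "_", i))
      map[[paste0("f_", i)]] <- as.name(paste0(.pref("f", comp$name), "_", i))
    }
  }
  if (substitute_params) {
    for (p in names(comp$params)) {
      v <- comp$params[[p]]
      if (is.numeric(v)) map[[p]] <- v
    }
  }
  lapply(def$relations, function(r) {
    list(lhs = expr_subst(r$lhs, map), rhs = expr_subst(r$rhs, map))
  })
}

#' @export
print.component_definition <- function(x, ...) {
  cat(sprintf("<component definition '%s'> %d port(s)\n", x$type_symbol, x$port_count))
  if (length(x$parameters)) cat("  parameters:", paste(names(x$parameters), collapse = ", "), "\n")
  if (length(x$states)) cat("  states:", paste(names(x$states), collapse = ", "), "\n")
  for (r in x$relations) cat("  ", deparse1(r$lhs), "~", deparse1(r$rhs), "\n")
  invisible(x)
}

#' @export
print.bg_component <- function(x, ...) {
  p <- vapply(names(x$params), function(nm) {
    v <- x$params[[nm]]
    paste0(nm, "=", if (is.function(v)) "<fn(t)>" else format(v))
  }, character(1))
  cat(sprintf("%s:%s%s\n", x$def$type_symbol, x$name,
              if (length(p)) paste0(" (", paste(p, collapse = ", "), ")") else ""))
  invisible(x)
}

#' @export
print.bg_junction <- function(x, ...) {
  cat(sprintf("%s-junction:%s\n", if (x$kind == "zero") "0" else "1", x$name))
  invisible(x)
}
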