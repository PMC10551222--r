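# Equation assembly and symbolic reduction.
#
# Assembly gives every bond an (effort, flow) symbol pair e_i/f_i in bond
# insertion order, instantiates junction conservation laws and component
# constitutive relations over those variables, and reduction eliminates the
# bond variables by triangular linear solving plus exp/log rewriting,
# yielding explicit ODEs (or flagged DAE residuals) over the storage states.

# ---- flattening ------------------------------------------------------------

#' Flatten nested subsystems into a single-level bond graph
#'
#' Inner vertices are renamed `"<subsystem>/<vertex>"`; bonds attached to a
#' subsystem port are reattached to the corresponding exposed inner port.
#'
#' @param bg a `bondgraph`.
#' @return a `bondgraph` with no subsystem vertices.
#' @export
flatten_bg <- function(bg) {
  out <- bg
  out$vertices <- list()
  out$bonds <- list()
  # port_alias: "subname" -> list of list(name, index) in exposure order
  port_alias <- list()
  inner_bonds <- list()
  for (v in bg$vertices) {
    if (v$role != "subsystem") {
      out$vertices[[v$name]] <- v
      next
    }
    inner <- flatten_bg(v$inner)
    rename <- function(nm) paste0(v$name, "/", nm)
    for (iv in inner$vertices) {
      iv$name <- rename(iv$name)
      out$vertices[[iv$name]] <- iv
    }
    for (ib in inner$bonds) {
      ib$src <- rename(ib$src)
      ib$dst <- rename(ib$dst)
      inner_bonds[[length(inner_bonds) + 1L]] <- ib
    }
    # exposed ports of a flattened inner graph: an exposed port may itself
    # alias into a deeper subsystem, already resolved by the recursive call
    port_alias[[v$name]] <- lapply(v$exposed, function(p) {
      resolved <- .resolve_exposed(v$inner, p)
      list(name = rename(resolved$name), index = resolved$index)
    })
  }
  remap <- function(nm, idx) {
    al <- port_alias[[nm]]
    if (is.null(al)) return(list(name = nm, index = idx))
    if (idx + 1L > length(al)) {
      stop(sprintf("subsystem '%s' has no port %d", nm, idx), call. = FALSE)
    }
    al[[idx + 1L]]
  }
  for (b in bg$bonds) {
    s <- remap(b$src, b$src_port)
    d <- remap(b$dst, b$dst_port)
    out$bonds[[length(out$bonds) + 1L]] <- list(src = s$name, src_port = s$index,
                                                dst = d$name, dst_port = d$index)
  }
  out$bonds <- c(out$bonds, inner_bonds)
  out
}

# resolve an exposed port through possibly-nested subsystems of `inner`
.resolve_exposed <- function(inner, p) {
  v <- inner$vertices[[p$name]]
  if (!is.null(v) && v$role == "subsystem") {
    deeper <- .resolve_exposed(v$inner, v$exposed[[p$index + 1L]])
    return(list(name = paste0(p$name, "/", deeper$name), index = deeper$index))
  }
  list(name = p$name, index = p$index)
}

# ---- assembly --------------------------------------------------------------

.bond_sym <- function(kind, i) as.name(paste0(kind, "_", i))

.dkey <- function(state) deparse1(call("d", as.name(state)))

#' Bond variable table of a graph
#'
#' One `(effort, flow)` symbol pair per bond, named `e_1..e_n` / `f_1..f_n`
#' in bond insertion order (stable across identical construction runs).
#'
#' @param bg a `bondgraph` (flattened internally).
#' @return tibble with columns `bond`, `effort`, `flow`, `src`, `dst`.
#' @export
bond_variables <- function(bg) {
  flat <- flatten_bg(bg)
  n <- length(flat$bonds)
  tibble::tibble(
    bond = seq_len(n),
    effort = paste0("e_", seq_len(n)),
    flow = paste0("f_", seq_len(n)),
    src = vapply(flat$bonds, function(b) b$src, character(1)),
    dst = vapply(flat$bonds, function(b) b$dst, character(1))
  )
}

#' Conservation-law equations of a junction
#'
#' Zero junction: all bond efforts equal and the signed flow sum vanishes;
#' one junction: all bond flows equal and the signed effort sum vanishes.
#' Signs are +1 for bonds oriented into the junction, -1 for bonds out.
#'
#' @param kind `"zero"` or `"one"`.
#' @param bonds integer bond indices incident to the junction.
#' @param sigma +1/-1 orientation signs, same length as `bonds`.
#' @return list of `list(lhs, rhs)` language pairs.
#' @export
junction_equations <- function(kind, bonds, sigma) {
  stopifnot(length(bonds) >= 1L, length(bonds) == length(sigma))
  eqs <- list()
  shared <- if (kind == "zero") "e" else "f"
  summed <- if (kind == "zero") "f" else "e"
  for (k in seq_along(bonds)[-1]) {
    eqs[[length(eqs) + 1L]] <- list(lhs = .bond_sym(shared, bonds[1]),
                                    rhs = .bond_sym(shared, bonds[k]))
  }
  tot <- NULL
  for (k in seq_along(bonds)) {
    v <- .bond_sym(summed, bonds[k])
    if (is.null(tot)) {
      tot <- if (sigma[k] > 0) v else call("-", v)
    } else {
      tot <- call(if (sigma[k] > 0) "+" else "-", tot, v)
    }
  }
  eqs[[length(eqs) + 1L]] <- list(lhs = tot, rhs = 0)
  eqs
}

#' Assemble the raw equation system of a bond graph
#'
#' Flattens subsystems, allocates bond variables, and instantiates all
#' junction laws and constitutive relations. Component port variables map to
#' bond variables with inward-positive flow: a component at the target end of
#' a bond sees flow `+f_i`, at the source end `-f_i`.
#'
#' @param bg a `bondgraph`.
#' @return a `bg_raw_system` with fields `equations`, `bond_vars`, `states`
#'   (named numeric initial values, `NA` if unset), `params`, `inputs`,
#'   `fluxes`, `energies`, `junctions`, `globals`, `meta`.
#' @export
assemble <- function(bg) {
  stopifnot(inherits(bg, "bondgraph"))
  flat <- flatten_bg(bg)
  nb <- length(flat$bonds)
  port_map <- new.env(parent = emptyenv())
  for (i in seq_len(nb)) {
    b <- flat$bonds[[i]]
    assign(paste0(b$src, ":", b$src_port), list(bond = i, sigma = -1), envir = port_map)
    assign(paste0(b$dst, ":", b$dst_port), list(bond = i, sigma = +1), envir = port_map)
  }
  equations <- list()
  junctions <- list()
  states <- numeric(0)
  params <- character(0)
  inputs <- list()
  fluxes <- list()
  energies <- list()
  gl <- flat$globals

  for (v in flat$vertices) {
    if (v$role == "junction") {
      inc_b <- integer(0)
      inc_s <- integer(0)
      for (i in seq_len(nb)) {
        b <- flat$bonds[[i]]
        if (b$src == v$name) { inc_b <- c(inc_b, i); inc_s <- c(inc_s, -1L) }
        if (b$dst == v$name) { inc_b <- c(inc_b, i); inc_s <- c(inc_s, +1L) }
      }
      if (!length(inc_b)) {
        stop(sprintf("junction '%s' has no bonds after assembly", v$name), call. = FALSE)
      }
      equations <- c(equations, junction_equations(v$kind, inc_b, inc_s))
      junctions[[v$name]] <- list(kind = v$kind, bonds = inc_b, sigma = inc_s)
      next
    }
    # component
    def <- v$def
    map <- list(R_gas = gl$R_gas, T = gl$T, F_faraday = gl$F_faraday)
    for (p in names(def$parameters)) {
      pref <- .pref(p, v$name)
      bound <- v$params[[p]]
      if (is.function(bound)) {
        map[[p]] <- call(pref, as.name("t"))
        inputs[[pref]] <- bound
      } else if (is.numeric(bound)) {
        map[[p]] <- bound
      } else {
        map[[p]] <- as.name(pref)
        params <- c(params, pref)
      }
    }
    for (s in names(def$states)) {
      pref <- .pref(s, v$name)
      map[[s]] <- as.name(pref)
      states[pref] <- if (!is.null(v$state0[[s]])) v$state0[[s]] else NA_real_
    }
    if (def$port_count == 1L) {
      # a one-port component may carry several bonds after merge_nodes: it
      # behaves like the component behind an implicit 0-junction (equal
      # effort on all bonds, flows summing into the single relation)
      inc <- list()
      for (i in seq_len(nb)) {
        b <- flat$bonds[[i]]
        if (b$src == v$name) inc[[length(inc) + 1L]] <- list(bond = i, sigma = -1)
        if (b$dst == v$name) inc[[length(inc) + 1L]] <- list(bond = i, sigma = +1)
      }
      if (!length(inc)) {
        stop(sprintf("dangling port: port 0 of component '%s' is not bound", v$name),
             call. = FALSE)
      }
      map[["e_0"]] <- .bond_sym("e", inc[[1]]$bond)
      fsum <- NULL
      for (pm in inc) {
        if (pm$bond != inc[[1]]$bond) {
          equations[[length(equations) + 1L]] <-
            list(lhs = .bond_sym("e", inc[[1]]$bond), rhs = .bond_sym("e", pm$bond))
        }
        fterm <- .bond_sym("f", pm$bond)
        fsum <- if (is.null(fsum)) {
          if (pm$sigma > 0) fterm else call("-", fterm)
        } else {
          call(if (pm$sigma > 0) "+" else "-", fsum, fterm)
        }
      }
      map[["f_0"]] <- fsum
    } else {
      for (k in seq_len(def$port_count) - 1L) {
        pm <- port_map[[paste0(v$name, ":", k)]]
        if (is.null(pm)) {
          stop(sprintf("dangling port: port %d of component '%s' is not bound", k, v$name),
               call. = FALSE)
        }
        esym <- .bond_sym("e", pm$bond)
        fexp <- if (pm$sigma > 0) .bond_sym("f", pm$bond) else call("-", .bond_sym("f", pm$bond))
        map[[paste0("e_", k)]] <- esym
        map[[paste0("f_", k)]] <- fexp
      }
    }
    for (r in def$relations) {
      equations[[length(equations) + 1L]] <- list(lhs = expr_subst(r$lhs, map),
                                                  rhs = expr_subst(r$rhs, map))
    }
    # two-port dissipative elements (Re and swapped-in rate laws) define a
    # reaction flux observable: the inward flow at the forward port 0
    if (def$port_count == 2L && def$type_symbol != "TF") {
      fluxes[[v$name]] <- map[["f_0"]]
    }
    if (!is.null(def$energy)) {
      energies[[v$name]] <- expr_subst(def$energy, map)
    }
  }
  structure(list(equations = equations,
                 bond_vars = c(paste0("e_", seq_len(nb)), paste0("f_", seq_len(nb))),
                 n_bonds = nb,
                 states = if (length(states)) {
                   states[order(names(states), method = "radix")]
                 } else states,
                 params = sort(unique(params), method = "radix"),
                 inputs = inputs, fluxes = fluxes, energies = energies,
                 junctions = junctions, globals = gl, meta = flat$meta),
            class = "bg_raw_system")
}

# ---- reduction -------------------------------------------------------------

#' Reduce a raw system to explicit ODEs (or a flagged DAE)
#'
#' Eliminates bond variables and state-derivative unknowns by triangular
#' linear solving; exp/log composites are rewritten on the way so that
#' species/reaction (Ce/Re) subsystems reduce to polynomial mass-action
#' terms. Whatever cannot be resolved linearly is returned in `algebraic`
#' rather than dropped; a leftover constraint involving neither unknowns nor
#' states signals a structurally singular model and raises an error.
#'
#' @param raw a `bg_raw_system` from [assemble()], or a `bondgraph`
#'   (assembled on the fly), or a `bg_equation_system` (re-embedded and
#'   reduced again, a no-op).
#' @return a `bg_equation_system` with fields `odes` (state -> rhs),
#'   `algebraic`, `states`, `params`, `inputs`, `observables`
#'   (`fluxes`, `powers`, `energy`), `is_ode`, `globals`, `meta`.
#' @export
#' @examples
#' sys <- reduce_system(abc_cycle())
#' equations_text(sys)
reduce_system <- function(raw) {
  if (inherits(raw, "bondgraph")) raw <- assemble(raw)
  if (inherits(raw, "bg_equation_system")) raw <- .as_raw(raw)
  stopifnot(inherits(raw, "bg_raw_system"))
  dkeys <- vapply(names(raw$states), .dkey, character(1))
  unknowns <- c(raw$bond_vars, unname(dkeys))
  eqs <- lapply(raw$equations, function(r) call("-", r$lhs, r$rhs))
  sol <- solve_linear_system(eqs, unknowns)
  odes <- list()
  for (s in names(raw$states)) {
    rhs <- sol$solutions[[dkeys[[s]]]]
    if (!is.null(rhs)) odes[[s]] <- expr_canon(rhs)
  }
  algebraic <- sol$residuals
  # structural singularity: a leftover constraint that involves no remaining
  # unknown and no state is an inconsistency, not dynamics (e.g. two effort
  # sources with different values forced equal)
  remaining <- setdiff(unknowns, names(sol$solutions))
  for (res in algebraic) {
    vs <- expr_vars(res)
    has_deriv <- grepl("d(", deparse1(res), fixed = TRUE)
    if (!has_deriv && !any(vs %in% c(remaining, names(raw$states)))) {
      stop("structurally singular model: constraint '0 = ",
           deparse1(res), "' cannot be satisfied by any state", call. = FALSE)
    }
  }
  subst_all <- function(e) expr_canon(expr_subst(e, sol$solutions))
  fluxes <- lapply(raw$fluxes, subst_all)
  powers <- list()
  for (i in seq_len(raw$n_bonds)) {
    powers[[paste0("P_", i)]] <- subst_all(call("*", .bond_sym("e", i), .bond_sym("f", i)))
  }
  energy <- NULL
  if (length(raw$energies)) {
    tot <- NULL
    for (e in raw$energies) tot <- if (is.null(tot)) e else call("+", tot, e)
    energy <- expr_canon(tot)
  }
  structure(list(odes = if (length(odes)) {
                   odes[order(names(odes), method = "radix")]
                 } else odes,
                 algebraic = algebraic,
                 states = raw$states,
                 params = raw$params,
                 inputs = raw$inputs,
                 observables = list(fluxes = fluxes, powers = powers, energy = energy),
                 is_ode = length(algebraic) == 0L &&
                   length(odes) == length(raw$states),
                 globals = raw$globals,
                 meta = raw$meta),
            class = "bg_equation_system")
}

# re-embed a reduced system as a raw system (for idempotence checks)
.as_raw <- function(sys) {
  eqs <- lapply(names(sys$odes), function(s) {
    list(lhs = call("d", as.name(s)), rhs = sys$odes[[s]])
  })
  eqs <- c(eqs, lapply(sys$algebraic, function(a) list(lhs = a, rhs = 0)))
  structure(list(equations = eqs, bond_vars = character(0), n_bonds = 0L,
                 states = sys$states, params = sys$params, inputs = sys$inputs,
                 fluxes = sys$observables$fluxes, energies = list(),
                 junctions = list(), globals = sys$globals, meta = sys$meta),
            class = "bg_raw_system")
}

#' Derive the reduced equation system of a bond graph
#'
#' Convenience wrapper: [assemble()] then [reduce_system()].
#'
#' @param bg a `bondgraph`.
#' @return a `bg_equation_system`.
#' @export
derive_equations <- function(bg) reduce_system(assemble(bg))

#' Named observable expressions of a reduced system
#'
#' @param sys a `bg_equation_system`.
#' @return list with `fluxes` (per reaction element, inward flow at the
#'   forward port), `powers` (per bond, effort times flow over states), and
#'   `energy` (total stored energy of all storage components).
#' @export
observables <- function(sys) {
  stopifnot(inherits(sys, "bg_equation_system"))
  sys$observables
}

# ---- junction power check --------------------------------------------------

#' Verify power conservation at every junction
#'
#' For each junction, substitutes that junction's own constraint equations
#' into its signed power sum `sum(sigma_b e_b f_b)` and checks that the
#' result collects to zero symbolically.
#'
#' @param bg a `bondgraph`.
#' @return named logical vector, one entry per junction.
#' @export
#' @examples
#' all(check_junction_power(abc_cycle()))
check_junction_power <- function(bg) {
  raw <- assemble(bg)
  out <- logical(0)
  for (nm in names(raw$junctions)) {
    j <- raw$junctions[[nm]]
    eqs <- lapply(junction_equations(j$kind, j$bonds, j$sigma),
                  function(r) call("-", r$lhs, r$rhs))
    vars <- c(paste0("e_", j$bonds), paste0("f_", j$bonds))
    sol <- solve_linear_system(eqs, vars)
    pw <- NULL
    for (k in seq_along(j$bonds)) {
      piece <- call("*", .bond_sym("e", j$bonds[k]), .bond_sym("f", j$bonds[k]))
      if (j$sigma[k] < 0) piece <- call("-", piece)
      pw <- if (is.null(pw)) piece else call("+", pw, piece)
    }
    out[nm] <- nf_is_zero(to_nf(expr_subst(pw, sol$solutions)))
  }
  out
}

# ---- text output -----------------------------------------------------------

.expr_latex <- function(e) {
  if (is.numeric(e)) return(format(e))
  if (is.name(e)) {
    s <- as.character(e)
    s <- gsub("_", "\\\\_", s)
    s <- gsub("/", "\\\\textup{/}", s)
    return(paste0("\\mathit{", s, "}"))
  }
  if (!is.call(e)) return(deparse1(e))
  fn <- as.character(e[[1]])
  wrap <- function(x) paste0("\\left(", .expr_latex(x), "\\right)")
  prec_wrap <- function(x) {
    if (is.call(x) && as.character(x[[1]]) %in% c("+", "-")) wrap(x) else .expr_latex(x)
  }
  switch(fn,
    "+" = if (length(e) == 2L) .expr_latex(e[[2]])
          else paste(.expr_latex(e[[2]]), "+", .expr_latex(e[[3]])),
    "-" = if (length(e) == 2L) paste0("-", prec_wrap(e[[2]]))
          else paste(.expr_latex(e[[2]]), "-", prec_wrap(e[[3]])),
    "*" = paste(prec_wrap(e[[2]]), "\\cdot", prec_wrap(e[[3]])),
    "/" = paste0("\\frac{", .expr_latex(e[[2]]), "}{", .expr_latex(e[[3]]), "}"),
    "^" = paste0("{", prec_wrap(e[[2]]), "}^{", .expr_latex(e[[3]]), "}"),
    "(" = wrap(e[[2]]),
    "exp" = paste0("\\exp", wrap(e[[2]])),
    "log" = paste0("\\ln", wrap(e[[2]])),
    # opaque calls (inputs)
    paste0("\\mathit{", gsub("_", "\\\\_", fn), "}", wrap(e[[2]]))
  )
}

#' Render a reduced system as text
#'
#' Plain format emits one parseable line per state, `d <state>/dt = <rhs>`,
#' followed by `0 = <residual>` for any algebraic constraint, states in
#' alphabetical order. LaTeX format emits the same lines as math.
#'
#' @param sys a `bg_equation_system`.
#' @param format `"plain"` or `"latex"`.
#' @return character vector of lines.
#' @export
equations_text <- function(sys, format = c("plain", "latex")) {
  stopifnot(inherits(sys, "bg_equation_system"))
  format <- match.arg(format)
  lines <- character(0)
  for (s in names(sys$odes)) {
    lines <- c(lines, if (format == "plain") {
      paste0("d ", s, "/dt = ", deparse1(sys$odes[[s]]))
    } else {
      paste0("\\frac{d\\,\\mathit{", gsub("_", "\\\\_", gsub("/", "\\\\textup{/}", s)),
             "}}{dt} = ", .expr_latex(sys$odes[[s]]))
    })
  }
  for (a in sys$algebraic) {
    lines <- c(lines, if (format == "plain") paste0("0 = ", deparse1(a))
               else paste0("0 = ", .expr_latex(a)))
  }
  lines
}

#' Compare two reduced systems for symbolic equality
#'
#' Systems are equal when they have the same states (optionally after
#' renaming) and each right-hand side difference collects to zero.
#'
#' @param a,b `bg_equation_system` objects.
#' @param rename optional named character vector mapping state/symbol names
#'   of `b` onto those of `a`.
#' @return `TRUE` or `FALSE`.
#' @export
systems_equal <- function(a, b, rename = NULL) {
  odes_b <- b$odes
  if (!is.null(rename)) {
    map <- lapply(rename, as.name)
    odes_b <- lapply(odes_b, expr_subst, map = map)
    names(odes_b) <- ifelse(names(odes_b) %in% names(rename),
                            unname(rename[names(odes_b)]), names(odes_b))
  }
  if (!setequal(names(a$odes), names(odes_b))) return(FALSE)
  for (s in names(a$odes)) {
    if (!exprs_equal(a$odes[[s]], odes_b[[s]])) return(FALSE)
  }
  length(a$algebraic) == length(b$algebraic)
}

#' @export
print.bg_equation_system <- function(x, ...) {
  cat(sprintf("<equation system> %d state(s), %d parameter(s)%s\n",
              length(x$states), length(x$params),
              if (x$is_ode) "" else " [DAE]"))
  cat(paste0("  ", equations_text(x)), sep = "\n")
  invisible(x)
}

#' @export
print.bg_raw_system <- function(x, ...) {
  cat(sprintf("<raw system> %d equations over %d bond variables\n",
              length(x$equations), length(x$bond_vars)))
  invisible(x)
}
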