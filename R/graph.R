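# Bond graph data model and structural editing.
#
# A bond graph is a directed multigraph. Vertices are components, junctions,
# or subsystems (nested bond graphs exposing ports); edges ("bonds") connect
# ports and carry a conjugate effort/flow pair. Bond orientation is the power
# sign convention: positive power flows source -> target.
# All editors are functional: they return a modified copy.

#' Create an empty bond graph
#'
#' @param name model name.
#' @param globals global physical constants, see [default_globals()].
#' @return an empty `bondgraph`.
#' @export
#' @examples
#' bg <- bondgraph("demo")
bondgraph <- function(name = "model", globals = default_globals()) {
  stopifnot(is.list(globals), all(c("R_gas", "T", "F_faraday") %in% names(globals)))
  if (any(unlist(globals[c("R_gas", "T", "F_faraday")]) <= 0)) {
    stop("global constants must be strictly positive", call. = FALSE)
  }
  structure(list(name = name, vertices = list(), bonds = list(),
                 globals = globals, meta = list()),
            class = "bondgraph")
}

.vertex_port_count <- function(v) {
  switch(v$role,
    component = v$def$port_count,
    junction = Inf,
    subsystem = length(v$exposed),
    stop("unknown vertex role")
  )
}

# ports currently bound by bonds, per vertex name -> integer vector
.bound_ports <- function(bg, vname) {
  out <- integer(0)
  for (b in bg$bonds) {
    if (b$src == vname) out <- c(out, b$src_port)
    if (b$dst == vname) out <- c(out, b$dst_port)
  }
  out
}

.next_free_port <- function(bg, vname) {
  v <- bg$vertices[[vname]]
  bound <- .bound_ports(bg, vname)
  limit <- .vertex_port_count(v)
  if (is.infinite(limit)) {
    # junctions allocate ports on demand
    return(if (length(bound)) max(bound) + 1L else 0L)
  }
  free <- setdiff(seq_len(limit) - 1L, bound)
  if (!length(free)) {
    stop(sprintf("vertex '%s' has no free port (all %d bound)", vname, limit),
         call. = FALSE)
  }
  min(free)
}

#' Reference a specific port of a vertex
#'
#' Two-port components index port 0 as the primary/forward side and port 1 as
#' the secondary/reverse side (Re: forward/reverse; TF: scaled/unscaled).
#'
#' @param name vertex name.
#' @param index non-negative port index.
#' @return a `bg_port` reference usable in [connect()].
#' @export
port <- function(name, index) {
  structure(list(name = name, index = as.integer(index)), class = "bg_port")
}

.resolve_endpoint <- function(bg, x, auto = TRUE) {
  if (inherits(x, "bg_port")) {
    if (is.null(bg$vertices[[x$name]])) {
      stop(sprintf("vertex '%s' is not in the graph", x$name), call. = FALSE)
    }
    v <- bg$vertices[[x$name]]
    limit <- .vertex_port_count(v)
    if (!is.infinite(limit) && (x$index < 0L || x$index >= limit)) {
      stop(sprintf("vertex '%s' has no port %d", x$name, x$index), call. = FALSE)
    }
    return(list(name = x$name, index = x$index))
  }
  nm <- if (inherits(x, "bg_vertex")) x$name else as.character(x)
  if (is.null(bg$vertices[[nm]])) {
    stop(sprintf("vertex '%s' is not in the graph", nm), call. = FALSE)
  }
  if (!auto) return(list(name = nm, index = NA_integer_))
  list(name = nm, index = .next_free_port(bg, nm))
}

#' Add a vertex to a bond graph
#'
#' @param bg a `bondgraph`.
#' @param v a `bg_component`, `bg_junction` or `bg_subsystem`.
#' @return the extended graph (no bonds are added).
#' @export
#' @examples
#' bg <- add_node(bondgraph(), component("C", "mem", C = 1))
add_node <- function(bg, v) {
  stopifnot(inherits(bg, "bondgraph"), inherits(v, "bg_vertex"))
  if (v$name %in% names(bg$vertices)) {
    stop(sprintf("a vertex named '%s' already exists", v$name), call. = FALSE)
  }
  if (grepl("[/:]", v$name)) {
    stop("vertex names may not contain '/' or ':' (reserved for paths and ports)",
         call. = FALSE)
  }
  bg$vertices[[v$name]] <- v
  bg
}

#' Connect two vertices (or ports) with a bond
#'
#' When a vertex is given, its lowest-index free port is used; junctions
#' allocate ports on demand. The bond's orientation (src -> dst) is the sign
#' convention: positive power flows from `src` to `dst`.
#'
#' @param bg a `bondgraph`.
#' @param src,dst vertex names, vertex objects, or [port()] references.
#' @return the graph with one more bond.
#' @export
#' @examples
#' bg <- bondgraph() |>
#'   add_node(component("C", "mem", C = 1)) |>
#'   add_node(junction("zero", "j")) |>
#'   connect("mem", "j")
connect <- function(bg, src, dst) {
  s <- .resolve_endpoint(bg, src)
  d <- .resolve_endpoint(bg, dst)
  if (s$name == d$name && s$index == d$index) {
    stop("cannot connect a port to itself", call. = FALSE)
  }
  for (ep in list(s, d)) {
    if (ep$index %in% .bound_ports(bg, ep$name)) {
      stop(sprintf("port %d of '%s' is already bound", ep$index, ep$name),
           call. = FALSE)
    }
  }
  bg$bonds[[length(bg$bonds) + 1L]] <- list(src = s$name, src_port = s$index,
                                            dst = d$name, dst_port = d$index)
  bg
}

.find_bond <- function(bg, b) {
  for (i in seq_along(bg$bonds)) {
    if (identical(bg$bonds[[i]], b)) return(i)
  }
  NA_integer_
}

#' Remove a bond
#'
#' @param bg a `bondgraph`.
#' @param b either a bond index (in insertion order) or a bond record as
#'   found in `bg$bonds`.
#' @return the graph without that bond; both ports become free.
#' @export
disconnect <- function(bg, b) {
  i <- if (is.numeric(b)) as.integer(b) else .find_bond(bg, b)
  if (is.na(i) || i < 1L || i > length(bg$bonds)) {
    stop("no such bond in this graph", call. = FALSE)
  }
  bg$bonds[[i]] <- NULL
  bg
}

#' Swap one vertex for another
#'
#' Every bond that ended at port i of `old` is reattached to port i of `new`;
#' adjacency is otherwise unchanged. Useful for exchanging constitutive
#' relations (e.g. a mass-action reaction element for a custom rate law)
#' while keeping the network structure.
#'
#' @param bg a `bondgraph`.
#' @param old name of the vertex to replace.
#' @param new replacement vertex (must offer at least the bound ports of
#'   `old`; its name must not collide with remaining vertices).
#' @return the rewired graph.
#' @export
swap_node <- function(bg, old, new) {
  old_nm <- if (inherits(old, "bg_vertex")) old$name else as.character(old)
  if (is.null(bg$vertices[[old_nm]])) {
    stop(sprintf("vertex '%s' is not in the graph", old_nm), call. = FALSE)
  }
  stopifnot(inherits(new, "bg_vertex"))
  if (new$name != old_nm && new$name %in% names(bg$vertices)) {
    stop(sprintf("a vertex named '%s' already exists", new$name), call. = FALSE)
  }
  bound <- .bound_ports(bg, old_nm)
  limit <- .vertex_port_count(new)
  if (!is.infinite(limit) && length(bound) && max(bound) >= limit) {
    stop(sprintf("'%s' exposes %s port(s) but '%s' binds port %d",
                 new$name, limit, old_nm, max(bound)), call. = FALSE)
  }
  idx <- which(names(bg$vertices) == old_nm)
  bg$vertices[[old_nm]] <- NULL
  # keep position for deterministic ordering
  bg$vertices <- append(bg$vertices, stats::setNames(list(new), new$name), after = idx - 1L)
  bg$bonds <- lapply(bg$bonds, function(b) {
    if (b$src == old_nm) b$src <- new$name
    if (b$dst == old_nm) b$dst <- new$name
    b
  })
  bg
}

#' Insert a vertex into an existing bond
#'
#' The bond src -> dst is replaced by src -> v and v -> dst (orientation
#' preserved); typical use is adding a junction or a transformer on an
#' existing connection.
#'
#' @param bg a `bondgraph`.
#' @param b bond index or bond record.
#' @param v a junction, or a two-port component/subsystem with both ports free.
#' @return graph with one more vertex and one more bond.
#' @export
insert_node <- function(bg, b, v) {
  i <- if (is.numeric(b)) as.integer(b) else .find_bond(bg, b)
  if (is.na(i) || i < 1L || i > length(bg$bonds)) {
    stop("no such bond in this graph", call. = FALSE)
  }
  stopifnot(inherits(v, "bg_vertex"))
  limit <- .vertex_port_count(v)
  if (!is.infinite(limit) && limit != 2L) {
    stop(sprintf("'%s' must be a junction or a two-port to be inserted", v$name),
         call. = FALSE)
  }
  bond <- bg$bonds[[i]]
  bg <- add_node(bg, v)  # errors if name collides or v malformed
  if (is.infinite(limit)) {
    in_port <- 0L
    out_port <- 1L
  } else {
    # two-port: power enters the primary port 0, leaves the secondary port 1
    in_port <- 0L
    out_port <- 1L
  }
  bg$bonds[[i]] <- list(src = bond$src, src_port = bond$src_port,
                        dst = v$name, dst_port = in_port)
  bg$bonds <- append(bg$bonds, list(list(src = v$name, src_port = out_port,
                                         dst = bond$dst, dst_port = bond$dst_port)),
                     after = i)
  bg
}

.same_definition <- function(a, b) {
  identical(a$def$type_symbol, b$def$type_symbol) &&
    identical(lapply(a$def$relations, function(r) list(deparse1(r$lhs), deparse1(r$rhs))),
              lapply(b$def$relations, function(r) list(deparse1(r$lhs), deparse1(r$rhs))))
}

#' Merge two vertices representing the same object
#'
#' The surviving vertex (named after `a`) carries the union of both vertices'
#' bonds, keeping the model flat without duplicating system elements. The two
#' vertices must be of identical type/kind; components must share the same
#' constitutive definition, and parameter or initial-state values bound on
#' both must agree.
#'
#' @param bg a `bondgraph`.
#' @param a,b vertex names (or vertex objects).
#' @return graph with one fewer vertex and the same number of bonds.
#' @export
merge_nodes <- function(bg, a, b) {
  a_nm <- if (inherits(a, "bg_vertex")) a$name else as.character(a)
  b_nm <- if (inherits(b, "bg_vertex")) b$name else as.character(b)
  va <- bg$vertices[[a_nm]]
  vb <- bg$vertices[[b_nm]]
  if (is.null(va) || is.null(vb)) stop("both vertices must be in the graph", call. = FALSE)
  if (a_nm == b_nm) stop("cannot merge a vertex with itself", call. = FALSE)
  if (va$role != vb$role) {
    stop(sprintf("cannot merge a %s with a %s", va$role, vb$role), call. = FALSE)
  }
  if (va$role == "junction" && va$kind != vb$kind) {
    stop("cannot merge junctions of different kinds", call. = FALSE)
  }
  if (va$role == "component") {
    if (!.same_definition(va, vb)) {
      stop(sprintf("'%s' and '%s' have different constitutive definitions", a_nm, b_nm),
           call. = FALSE)
    }
    for (nm in intersect(names(va$params), names(vb$params))) {
      if (!identical(va$params[[nm]], vb$params[[nm]])) {
        stop(sprintf("parameter '%s' differs between '%s' and '%s'; refusing to merge",
                     nm, a_nm, b_nm), call. = FALSE)
      }
    }
    for (nm in intersect(names(va$state0), names(vb$state0))) {
      if (!identical(va$state0[[nm]], vb$state0[[nm]])) {
        stop(sprintf("initial state '%s' differs between '%s' and '%s'; refusing to merge",
                     nm, a_nm, b_nm), call. = FALSE)
      }
    }
  }
  if (va$role == "subsystem") stop("merging subsystems is not supported", call. = FALSE)
  bound_a <- .bound_ports(bg, a_nm)
  bound_b <- .bound_ports(bg, b_nm)
  limit <- .vertex_port_count(va)
  # one-port components merge junction-like: the surviving species/store
  # carries all bonds (equal effort, flows summed into the single relation);
  # multi-port components cannot grow without ambiguity
  if (limit == 2L && length(bound_a) + length(bound_b) > limit) {
    stop(sprintf("merging '%s' and '%s' would need %d ports but '%s' has %d",
                 a_nm, b_nm, length(bound_a) + length(bound_b), a_nm, limit),
         call. = FALSE)
  }
  # reattach b's bonds to fresh port indices of a
  free <- seq(from = if (length(bound_a)) max(bound_a) + 1L else 0L,
              length.out = length(bound_b))
  k <- 0L
  bg$bonds <- lapply(bg$bonds, function(bnd) {
    if (bnd$src == b_nm) {
      k <<- k + 1L
      bnd$src <- a_nm
      bnd$src_port <- free[k]
    }
    if (bnd$dst == b_nm) {
      k <<- k + 1L
      bnd$dst <- a_nm
      bnd$dst_port <- free[k]
    }
    bnd
  })
  bg$vertices[[b_nm]] <- NULL
  bg
}

#' Wrap a bond graph as a reusable subsystem vertex
#'
#' The inner graph's listed unbound ports become the ports of a vertex that
#' can be placed in an outer graph; on equation assembly the hierarchy is
#' flattened, with inner vertices addressed as `"<subsystem>/<vertex>"`.
#'
#' @param inner a `bondgraph`.
#' @param exposed list of [port()] references into `inner` (each must be
#'   unbound there); their order defines the subsystem's port indexing.
#' @param name subsystem vertex name.
#' @return a `bg_subsystem` vertex.
#' @export
as_subsystem <- function(inner, exposed, name) {
  stopifnot(inherits(inner, "bondgraph"))
  if (inherits(exposed, "bg_port")) exposed <- list(exposed)
  if (!length(exposed)) stop("a subsystem must expose at least one port", call. = FALSE)
  for (p in exposed) {
    stopifnot(inherits(p, "bg_port"))
    v <- inner$vertices[[p$name]]
    if (is.null(v)) {
      stop(sprintf("exposed port names unknown inner vertex '%s'", p$name), call. = FALSE)
    }
    limit <- .vertex_port_count(v)
    if (!is.infinite(limit) && p$index >= limit) {
      stop(sprintf("inner vertex '%s' has no port %d", p$name, p$index), call. = FALSE)
    }
    if (p$index %in% .bound_ports(inner, p$name)) {
      stop(sprintf("exposed port %d of inner vertex '%s' is already bound inside the subsystem",
                   p$index, p$name), call. = FALSE)
    }
  }
  structure(list(name = name, role = "subsystem", inner = inner, exposed = exposed),
            class = c("bg_subsystem", "bg_vertex"))
}

#' Structural snapshot of a bond graph
#'
#' @param bg a `bondgraph`.
#' @return list with `n_vertices`, `n_bonds`, `neighbors` (named list of
#'   neighbouring vertex names, undirected), `adjacency` (tibble of directed
#'   bonds: `from`, `from_port`, `to`, `to_port`, `bond`), and
#'   `adjacency_matrix` (symmetric undirected bond-count matrix).
#' @export
#' @examples
#' graph_view(abc_cycle())$n_vertices
graph_view <- function(bg) {
  stopifnot(inherits(bg, "bondgraph"))
  vn <- names(bg$vertices)
  nbrs <- stats::setNames(lapply(vn, function(x) character(0)), vn)
  m <- matrix(0L, length(vn), length(vn), dimnames = list(vn, vn))
  adj <- list(from = character(0), from_port = integer(0),
              to = character(0), to_port = integer(0), bond = integer(0))
  for (i in seq_along(bg$bonds)) {
    b <- bg$bonds[[i]]
    nbrs[[b$src]] <- union(nbrs[[b$src]], b$dst)
    nbrs[[b$dst]] <- union(nbrs[[b$dst]], b$src)
    m[b$src, b$dst] <- m[b$src, b$dst] + 1L
    m[b$dst, b$src] <- m[b$dst, b$src] + 1L
    adj$from <- c(adj$from, b$src)
    adj$from_port <- c(adj$from_port, b$src_port)
    adj$to <- c(adj$to, b$dst)
    adj$to_port <- c(adj$to_port, b$dst_port)
    adj$bond <- c(adj$bond, i)
  }
  list(n_vertices = length(vn), n_bonds = length(bg$bonds),
       neighbors = nbrs, adjacency = tibble::as_tibble(adj),
       adjacency_matrix = m)
}

#' @export
print.bondgraph <- function(x, ...) {
  cat(sprintf("<bondgraph '%s'> %d vertices, %d bonds\n",
              x$name, length(x$vertices), length(x$bonds)))
  for (v in x$vertices) {
    lab <- switch(v$role,
      component = sprintf("%s:%s", v$def$type_symbol, v$name),
      junction = sprintf("%s-junction:%s", if (v$kind == "zero") "0" else "1", v$name),
      subsystem = sprintf("subsystem:%s (%d ports)", v$name, length(v$exposed)))
    cat("  ", lab, "\n")
  }
  invisible(x)
}

#' @export
print.bg_subsystem <- function(x, ...) {
  cat(sprintf("subsystem:%s wrapping <%s> with %d exposed port(s)\n",
              x$name, x$inner$name, length(x$exposed)))
  invisible(x)
}

# integrity check used by property tests: every bond references existing
# vertices and ports, endpoints distinct, each port bound at most once
.check_graph_invariants <- function(bg) {
  seen <- character(0)
  for (b in bg$bonds) {
    for (side in list(c(b$src, b$src_port), c(b$dst, b$dst_port))) {
      nm <- side[[1]]
      if (is.null(bg$vertices[[nm]])) return(FALSE)
      key <- paste0(nm, ":", side[[2]])
      if (key %in% seen) return(FALSE)
      seen <- c(seen, key)
    }
    if (b$src == b$dst && b$src_port == b$dst_port) return(FALSE)
  }
  TRUE
}
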