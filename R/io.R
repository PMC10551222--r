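# Model document serialization (JSON).
#
# Schema "bondgraphr/1": a flat, human-diffable description of a bond graph
# with vertices, bonds ("name:port" endpoints), global constants, embedded
# custom component definitions, optional nested subsystem documents, and the
# originating reaction network when there is one. Field order is fixed, so
# save -> load -> save is byte-stable.

.SCHEMA <- "bondgraphr/1"

.doc_component <- function(v, builtin) {
  params <- list()
  for (nm in names(v$params)) {
    val <- v$params[[nm]]
    if (is.function(val)) {
      stop(sprintf("parameter '%s' of '%s' is a function of time and cannot be serialized; bind it at simulation time instead",
                   nm, v$name), call. = FALSE)
    }
    params[[nm]] <- val
  }
  list(name = v$name, role = "component", type = v$def$type_symbol,
       parameters = params, initial_state = v$state0)
}

.collect_custom_defs <- function(bg, builtin, acc = list()) {
  for (v in bg$vertices) {
    if (v$role == "subsystem") {
      acc <- .collect_custom_defs(v$inner, builtin, acc)
    } else if (v$role == "component") {
      ts <- v$def$type_symbol
      known <- builtin[[ts]]
      if (is.null(known) || !identical(known$relations, v$def$relations)) {
        acc[[ts]] <- v$def
      }
    }
  }
  acc
}

.doc_definition <- function(def) {
  list(type_symbol = def$type_symbol,
       port_count = def$port_count,
       parameters = as.list(def$parameters),
       states = as.list(def$states),
       relations = vapply(def$relations, function(r) {
         paste(deparse1(r$lhs), "~", deparse1(r$rhs))
       }, character(1)),
       energy = if (is.null(def$energy)) NULL else deparse1(def$energy),
       description = def$description)
}

.doc_rn <- function(rn) {
  list(species = rn$species,
       reactions = lapply(rn$reactions, function(r) {
         list(name = r$name,
              reactants = as.list(r$reactants),
              products = as.list(r$products))
       }))
}

.bg_to_doc <- function(bg, builtin) {
  vertices <- lapply(unname(bg$vertices), function(v) {
    switch(v$role,
      component = .doc_component(v, builtin),
      junction = list(name = v$name, role = "junction", kind = v$kind),
      subsystem = list(name = v$name, role = "subsystem",
                       exposed = vapply(v$exposed, function(p) {
                         paste0(p$name, ":", p$index)
                       }, character(1)),
                       inner = .bg_to_doc(v$inner, builtin)))
  })
  bonds <- lapply(bg$bonds, function(b) {
    list(source = paste0(b$src, ":", b$src_port),
         target = paste0(b$dst, ":", b$dst_port))
  })
  doc <- list(schema_version = .SCHEMA, name = bg$name,
              globals = bg$globals[c("R_gas", "T", "F_faraday")],
              definitions = lapply(unname(.collect_custom_defs(bg, builtin)),
                                   .doc_definition),
              vertices = vertices, bonds = bonds)
  if (!is.null(bg$meta$rn)) {
    doc$reaction_network <- .doc_rn(bg$meta$rn)
    doc$chemostats <- as.list(bg$meta$chemostats)
  }
  doc
}

#' Save a bond graph as a JSON model document
#'
#' @param bg a `bondgraph`. Function-valued (time-driven) parameters cannot
#'   be serialized and raise an error.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".json")
#' save_model(abc_cycle(), p)
save_model <- function(bg, path) {
  stopifnot(inherits(bg, "bondgraph"))
  doc <- .bg_to_doc(bg, builtin_library())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.load_endpoint <- function(s, where) {
  m <- regmatches(s, regexec("^(.*):([0-9]+)$", s))[[1]]
  if (!length(m)) {
    stop(sprintf("%s: endpoint '%s' is not of the form 'vertex:port'", where, s),
         call. = FALSE)
  }
  list(name = m[2], index = as.integer(m[3]))
}

.parse_def_doc <- function(dd) {
  rel <- lapply(dd$relations, function(s) {
    f <- str2lang(s)
    if (!is.call(f) || !identical(f[[1]], as.name("~")) || length(f) != 3L) {
      stop(sprintf("definition '%s': relation '%s' is not a two-sided formula",
                   dd$type_symbol, s), call. = FALSE)
    }
    stats::as.formula(f, env = baseenv())
  })
  component_definition(dd$type_symbol, dd$port_count,
                       parameters = unlist(dd$parameters) %||% character(0),
                       states = unlist(dd$states) %||% character(0),
                       relations = rel,
                       energy = if (!is.null(dd$energy)) str2lang(dd$energy),
                       description = dd$description %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.doc_to_bg <- function(doc, lib, where = "document") {
  need <- c("schema_version", "name", "globals", "vertices", "bonds")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop(sprintf("%s: missing field(s) %s", where, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(doc$schema_version, .SCHEMA)) {
    stop(sprintf("%s: unknown schema_version '%s' (expected '%s')",
                 where, doc$schema_version, .SCHEMA), call. = FALSE)
  }
  for (dd in doc$definitions %||% list()) {
    def <- .parse_def_doc(dd)
    if (!def$type_symbol %in% names(lib)) lib <- register_definition(lib, def)
  }
  bg <- bondgraph(doc$name, globals = doc$globals)
  for (i in seq_along(doc$vertices)) {
    vd <- doc$vertices[[i]]
    vwhere <- sprintf("%s/vertices[%d]", where, i)
    v <- switch(vd$role %||% "?",
      component = {
        if (is.null(lib[[vd$type]])) {
          stop(sprintf("%s: unknown component type '%s' (no embedded definition)",
                       vwhere, vd$type), call. = FALSE)
        }
        args <- c(vd$parameters, vd$initial_state)
        do.call(instantiate, c(list(lib, vd$type, vd$name), args))
      },
      junction = junction(vd$kind, vd$name),
      subsystem = {
        inner <- .doc_to_bg(vd$inner, lib, where = paste0(vwhere, "/inner"))
        exposed <- lapply(vd$exposed, function(s) {
          ep <- .load_endpoint(s, vwhere)
          port(ep$name, ep$index)
        })
        as_subsystem(inner, exposed, vd$name)
      },
      stop(sprintf("%s: unknown vertex role '%s'", vwhere, vd$role %||% "<none>"),
           call. = FALSE)
    )
    bg <- add_node(bg, v)
  }
  for (i in seq_along(doc$bonds)) {
    bd <- doc$bonds[[i]]
    bwhere <- sprintf("%s/bonds[%d]", where, i)
    s <- .load_endpoint(bd$source %||% "", bwhere)
    d <- .load_endpoint(bd$target %||% "", bwhere)
    for (ep in list(s, d)) {
      if (is.null(bg$vertices[[ep$name]])) {
        stop(sprintf("%s: endpoint references undefined vertex '%s'", bwhere, ep$name),
             call. = FALSE)
      }
    }
    bg <- connect(bg, port(s$name, s$index), port(d$name, d$index))
  }
  if (!is.null(doc$reaction_network)) {
    rnd <- doc$reaction_network
    species <- unlist(rnd$species)
    reactions <- lapply(rnd$reactions, function(r) {
      list(reactants = unlist(r$reactants), products = unlist(r$products),
           placeholder = NULL, name = r$name)
    })
    N <- matrix(0L, nrow = length(species), ncol = length(reactions),
                dimnames = list(species, vapply(reactions, `[[`, "", "name")))
    for (j in seq_along(reactions)) {
      r <- reactions[[j]]
      for (sp in names(r$reactants)) N[sp, j] <- N[sp, j] - r$reactants[[sp]]
      for (sp in names(r$products)) N[sp, j] <- N[sp, j] + r$products[[sp]]
    }
    bg$meta$rn <- structure(list(species = species, reactions = reactions,
                                 stoichiometry = N), class = "reaction_network")
    bg$meta$chemostats <- unlist(doc$chemostats) %||% character(0)
  }
  bg
}

#' Load a bond graph from a JSON model document
#'
#' @param path path to a document written by [save_model()].
#' @param lib component library used to resolve types; embedded custom
#'   definitions are registered automatically.
#' @return a `bondgraph` isomorphic to the saved one.
#' @export
load_model <- function(path, lib = builtin_library()) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s' as JSON: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  .doc_to_bg(doc, lib, where = basename(path))
}
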