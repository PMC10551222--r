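# Reaction network text parsing and conversion to bond graphs.
#
# Grammar, one reaction per line:
#   [(tok, tok)] <terms> <--> <terms>
# where <terms> is `+`-joined `[int] Name` entries; `#` starts a comment and
# blank lines are skipped. The optional `(tok, tok)` prefix carries
# placeholder kinetic rates, accepted for compatibility with compact
# reaction-network notation and discarded: kinetics of the generated bond
# graph come from the energy parameters K (per species) and kappa (per
# reaction) instead.

.SPECIES_RX <- "[A-Za-z][A-Za-z0-9_]*"

.parse_side <- function(txt, lineno) {
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  out <- integer(0)
  for (term in terms) {
    term <- trimws(term)
    if (!nzchar(term)) {
      stop(sprintf("line %d: empty term in '%s'", lineno, txt), call. = FALSE)
    }
    m <- regmatches(term, regexec(paste0("^([0-9]+)?\\s*(", .SPECIES_RX, ")$"), term))[[1]]
    if (!length(m)) {
      stop(sprintf("line %d: cannot parse term '%s'", lineno, term), call. = FALSE)
    }
    s <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    if (s <= 0L) {
      stop(sprintf("line %d: stoichiometry must be positive in '%s'", lineno, term),
           call. = FALSE)
    }
    sp <- m[3]
    out[sp] <- if (sp %in% names(out)) out[[sp]] + s else s
  }
  out
}

#' Parse reaction-network text
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines. Each non-blank, non-comment line is one reversible reaction,
#'   e.g. `"(1, 1) A + 2 B <--> C"`; the parenthesised placeholder rates are
#'   parsed and ignored.
#' @return a `reaction_network`: `species` (ordered by first appearance),
#'   `reactions` (each with `reactants`, `products`, `placeholder`, `name`),
#'   and `stoichiometry` (signed integer species x reactions matrix,
#'   column = products - reactants).
#' @export
#' @examples
#' rn <- parse_reactions("A + B <--> C")
#' rn$stoichiometry
parse_reactions <- function(text) {
  lines <- unlist(strsplit(text, "\r?\n"), use.names = FALSE)
  species <- character(0)
  reactions <- list()
  for (lineno in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[lineno]])
    line <- trimws(line)
    if (!nzchar(line)) next
    placeholder <- NULL
    pm <- regmatches(line, regexec("^\\(\\s*([^,()]+)\\s*,\\s*([^,()]+)\\s*\\)\\s*(.*)$", line))[[1]]
    if (length(pm)) {
      placeholder <- c(trimws(pm[2]), trimws(pm[3]))
      line <- pm[4]
    }
    sides <- strsplit(line, "<-->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) {
      stop(sprintf("line %d: expected exactly one '<-->' in '%s'", lineno, lines[[lineno]]),
           call. = FALSE)
    }
    reactants <- .parse_side(sides[1], lineno)
    products <- .parse_side(sides[2], lineno)
    for (sp in c(names(reactants), names(products))) {
      if (!sp %in% species) species <- c(species, sp)
    }
    reactions[[length(reactions) + 1L]] <-
      list(reactants = reactants, products = products,
           placeholder = placeholder,
           name = paste0("r", length(reactions) + 1L))
  }
  if (!length(reactions)) stop("no reactions found", call. = FALSE)
  N <- matrix(0L, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (sp in names(r$reactants)) N[sp, j] <- N[sp, j] - r$reactants[[sp]]
    for (sp in names(r$products)) N[sp, j] <- N[sp, j] + r$products[[sp]]
  }
  structure(list(species = species, reactions = reactions, stoichiometry = N),
            class = "reaction_network")
}

#' Read a reaction network from a file
#'
#' @param path path to a UTF-8 text file (`.rxn` by convention), LF or CRLF.
#' @return a `reaction_network`; see [parse_reactions()].
#' @export
read_reactions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  parse_reactions(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Convert a reaction network into a bond graph
#'
#' Each species gets a `Ce` store (or a `ce` chemostat) on a dedicated
#' 0-junction; each reaction gets an `Re` element whose forward 1-junction
#' collects the reactant potentials and whose reverse 1-junction collects the
#' product potentials. A stoichiometric coefficient `s > 1` is realised as a
#' transformer of ratio `s` between the species 0-junction and the reaction
#' 1-junction. 1-junctions with a single non-`Re` bond are elided (the
#' species side connects straight to the `Re` port); this changes no
#' equations, as a 2-bond junction is an identity.
#'
#' @param rn a `reaction_network`.
#' @param chemostats character vector of species names to clamp. A
#'   chemostatted species becomes an energy source and never appears as a
#'   state; its amount is the `xs` parameter of its `ce` component (constant
#'   or a function of time).
#' @param K optional named numeric/function list of species thermodynamic
#'   constants; unset entries stay symbolic (`K_<species>`).
#' @param kappa optional named numeric vector of reaction rate constants;
#'   unset entries stay symbolic (`kappa_<reaction>`).
#' @param x0 optional named numeric vector of initial amounts for
#'   non-chemostatted species; for chemostats the same value binds `xs`.
#' @param name model name.
#' @param globals global constants, see [default_globals()].
#' @return a `bondgraph`; the originating network is kept in `bg$meta$rn`.
#' @export
#' @examples
#' bg <- to_bondgraph(parse_reactions("A <--> B"), K = c(A = 1, B = 1),
#'                    kappa = c(r1 = 1), x0 = c(A = 1, B = 0))
to_bondgraph <- function(rn, chemostats = character(0), K = NULL, kappa = NULL,
                         x0 = NULL, name = "crn", globals = default_globals()) {
  stopifnot(inherits(rn, "reaction_network"))
  bad <- setdiff(chemostats, rn$species)
  if (length(bad)) {
    stop("unknown chemostat species: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bg <- bondgraph(name, globals = globals)
  jz <- function(sp) paste0("J0_", sp)
  # species stores and their 0-junctions
  for (sp in rn$species) {
    args <- list()
    if (!is.null(K) && sp %in% names(K)) args$K <- K[[sp]]
    if (sp %in% chemostats) {
      if (!is.null(x0) && sp %in% names(x0)) args$xs <- x0[[sp]]
      v <- do.call(component, c(list("ce", sp), args))
    } else {
      if (!is.null(x0) && sp %in% names(x0)) args$x <- x0[[sp]]
      v <- do.call(component, c(list("Ce", sp), args))
    }
    bg <- add_node(bg, v)
    bg <- add_node(bg, junction("zero", jz(sp)))
    bg <- connect(bg, sp, jz(sp))
  }
  # attach one side (reactants or products) of a reaction
  attach_side <- function(bg, side, rname, forward) {
    n_terms <- length(side)
    jname <- paste0(if (forward) "J1f_" else "J1r_", rname)
    use_junction <- n_terms > 1L
    if (use_junction) bg <- add_node(bg, junction("one", jname))
    ends <- list()  # endpoints to connect toward the Re port
    for (sp in names(side)) {
      s <- side[[sp]]
      src <- jz(sp)
      if (s > 1L) {
        tfname <- paste0("TF", s, "_", rname, "_", sp, if (forward) "_f" else "_r")
        bg <- add_node(bg, component("TF", tfname, n = s))
        # port 0 carries the scaled potential s*mu on the reaction side
        if (forward) {
          bg <- connect(bg, src, port(tfname, 1L))
          ep <- port(tfname, 0L)
        } else {
          bg <- connect(bg, port(tfname, 1L), src)
          ep <- port(tfname, 0L)
        }
        src <- ep
      }
      if (use_junction) {
        if (forward) {
          bg <- connect(bg, src, jname)
        } else {
          bg <- connect(bg, jname, src)
        }
      } else {
        ends[[length(ends) + 1L]] <- src
      }
    }
    re_end <- if (use_junction) jname else ends[[1L]]
    if (forward) {
      bg <- connect(bg, re_end, port(rname, 0L))
    } else {
      bg <- connect(bg, port(rname, 1L), re_end)
    }
    bg
  }
  for (r in rn$reactions) {
    args <- list("Re", r$name)
    if (!is.null(kappa) && r$name %in% names(kappa)) args$kappa <- kappa[[r$name]]
    bg <- add_node(bg, do.call(component, args))
    bg <- attach_side(bg, r$reactants, r$name, forward = TRUE)
    bg <- attach_side(bg, r$products, r$name, forward = FALSE)
  }
  bg$meta$rn <- rn
  bg$meta$chemostats <- chemostats
  bg
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction network> %d species, %d reversible reaction(s)\n",
              length(x$species), length(x$reactions)))
  for (r in x$reactions) {
    side <- function(v) paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
    cat(sprintf("  %s: %s <--> %s\n", r$name, side(r$reactants), side(r$products)))
  }
  invisible(x)
}

#' Tidy a reaction network into a long table
#'
#' @param x a `reaction_network`.
#' @param ... unused.
#' @return tibble with one row per (reaction, species) pair: `reaction`,
#'   `species`, `coefficient` (signed, products positive).
#' @method tidy reaction_network
#' @export
tidy.reaction_network <- function(x, ...) {
  N <- x$stoichiometry
  idx <- which(N != 0L, arr.ind = TRUE)
  tibble::tibble(
    reaction = colnames(N)[idx[, "col"]],
    species = rownames(N)[idx[, "row"]],
    coefficient = N[idx]
  )[order(idx[, "col"], idx[, "row"]), ]
}
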