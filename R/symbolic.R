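# Symbolic expression layer.
#
# Expressions are plain R language objects (numbers, names, calls) over the
# operators + - * / ^ ( ), exp(), log(), the derivative marker d(<state>),
# and opaque calls such as time-dependent inputs u(t).
#
# The workhorse is a normal form (nf): a sum of terms, each term a numeric
# coefficient times a product of atomic factors raised to numeric powers.
# Atomic factors are symbols or non-expandable calls, keyed by their deparsed
# canonical text. Expansion-and-collection over this form decides symbolic
# equality (nf_is_zero of a difference), and exp()/log() composites are
# rewritten on entry so that exp(s1*log(v1) + s2*log(v2) + r) becomes
# v1^s1 * v2^s2 * exp(r) -- the simplification that turns Marcelin-de Donder
# fluxes over logarithmic chemical potentials into polynomial mass action.

nf_zero <- list(terms = list())

.term <- function(coef, pows) {
  pows <- pows[pows != 0]
  if (length(pows) > 1) pows <- pows[order(names(pows), method = "radix")]
  list(coef = coef, pows = pows)
}

.term_sig <- function(pows) {
  if (!length(pows)) return("")
  paste(names(pows), pows, sep = "^", collapse = "*")
}

.snap <- function(x) {
  r <- round(x)
  ifelse(x != r & abs(x - r) <= 1e-9 * pmax(1, abs(x)), r, x)
}

nf_num <- function(x) {
  if (x == 0) return(nf_zero)
  list(terms = list(.term(as.numeric(x), numeric(0))))
}

nf_atom <- function(expr, p = 1) {
  # backtick = TRUE so non-syntactic names (nested "a/b" paths) survive the
  # deparse -> str2lang round trip as symbols, not operators
  key <- deparse1(expr, backtick = TRUE)
  list(terms = list(.term(1, stats::setNames(p, key))))
}

# combine term lists, collecting like signatures and dropping zeros
.nf_collect <- function(terms) {
  if (!length(terms)) return(nf_zero)
  sigs <- vapply(terms, function(tt) .term_sig(tt$pows), character(1))
  out <- vector("list", length(unique(sigs)))
  k <- 0L
  for (s in unique(sigs)) {
    idx <- which(sigs == s)
    coef <- .snap(sum(vapply(terms[idx], function(tt) tt$coef, numeric(1))))
    if (coef != 0) {
      k <- k + 1L
      out[[k]] <- list(coef = coef, pows = terms[[idx[1]]]$pows)
    }
  }
  list(terms = out[seq_len(k)])
}

nf_add <- function(a, b) .nf_collect(c(a$terms, b$terms))

nf_neg <- function(a) {
  a$terms <- lapply(a$terms, function(tt) {
    tt$coef <- -tt$coef
    tt
  })
  a
}

.pow_merge <- function(p1, p2) {
  all <- union(names(p1), names(p2))
  v <- stats::setNames(numeric(length(all)), all)
  v[names(p1)] <- p1
  v[names(p2)] <- v[names(p2)] + p2
  .term(1, v)$pows
}

nf_mul <- function(a, b) {
  if (!length(a$terms) || !length(b$terms)) return(nf_zero)
  terms <- vector("list", length(a$terms) * length(b$terms))
  k <- 0L
  for (ta in a$terms) for (tb in b$terms) {
    k <- k + 1L
    terms[[k]] <- list(coef = ta$coef * tb$coef, pows = .pow_merge(ta$pows, tb$pows))
  }
  .nf_collect(terms)
}

nf_inv <- function(a) {
  if (!length(a$terms)) stop("symbolic division by zero", call. = FALSE)
  if (length(a$terms) == 1L) {
    tt <- a$terms[[1]]
    return(list(terms = list(.term(1 / tt$coef, -tt$pows))))
  }
  nf_atom(from_nf(a), -1)
}

nf_pow <- function(a, p) {
  r <- round(p)
  if (abs(p - r) <= 1e-9 && abs(r) <= 8) {
    if (r == 0) return(nf_num(1))
    base <- if (r < 0) nf_inv(a) else a
    out <- base
    for (i in seq_len(abs(r) - 1)) out <- nf_mul(out, base)
    return(out)
  }
  nf_atom(call("^", from_nf(a), p), 1)
}

.is_log_call <- function(e) is.call(e) && identical(e[[1]], as.name("log")) && length(e) == 2L

nf_exp <- function(u) {
  out <- nf_num(1)
  rest <- list()
  for (tt in u$terms) {
    hit <- FALSE
    if (length(tt$pows) == 1L && tt$pows[[1]] == 1) {
      inner <- str2lang(names(tt$pows))
      if (.is_log_call(inner)) {
        out <- nf_mul(out, nf_pow(to_nf(inner[[2]]), tt$coef))
        hit <- TRUE
      }
    }
    if (!hit) rest[[length(rest) + 1L]] <- tt
  }
  if (length(rest)) out <- nf_mul(out, nf_atom(call("exp", from_nf(list(terms = rest))), 1))
  out
}

to_nf <- function(e) {
  if (is.numeric(e) || is.integer(e)) return(nf_num(as.numeric(e)))
  if (is.name(e)) return(nf_atom(e, 1))
  if (!is.call(e)) stop("unsupported expression node: ", deparse1(e), call. = FALSE)
  fn <- if (is.name(e[[1]])) as.character(e[[1]]) else ""
  switch(fn,
    "(" = to_nf(e[[2]]),
    "+" = if (length(e) == 2L) to_nf(e[[2]]) else nf_add(to_nf(e[[2]]), to_nf(e[[3]])),
    "-" = if (length(e) == 2L) nf_neg(to_nf(e[[2]])) else nf_add(to_nf(e[[2]]), nf_neg(to_nf(e[[3]]))),
    "*" = nf_mul(to_nf(e[[2]]), to_nf(e[[3]])),
    "/" = nf_mul(to_nf(e[[2]]), nf_inv(to_nf(e[[3]]))),
    "^" = {
      if (is.numeric(e[[3]])) nf_pow(to_nf(e[[2]]), as.numeric(e[[3]]))
      else nf_atom(call("^", expr_canon(e[[2]]), e[[3]]), 1)
    },
    "exp" = nf_exp(to_nf(e[[2]])),
    "log" = {
      if (length(e) != 2L) stop("only natural log(x) is supported", call. = FALSE)
      nf_atom(call("log", expr_canon(e[[2]])), 1)
    },
    # opaque call: derivative marker d(x), input functions u(t), ...
    {
      args <- as.list(e)[-1]
      e[-1] <- lapply(args, function(a) if (is.language(a)) expr_canon(a) else a)
      nf_atom(e, 1)
    }
  )
}

# rebuild a deterministic expression from a normal form
from_nf <- function(nf) {
  if (!length(nf$terms)) return(0)
  sigs <- vapply(nf$terms, function(tt) .term_sig(tt$pows), character(1))
  ord <- order(sigs, method = "radix")
  total <- NULL
  for (tt in nf$terms[ord]) {
    num <- NULL
    den <- NULL
    for (key in names(tt$pows)) {
      p <- tt$pows[[key]]
      f <- str2lang(key)
      ap <- abs(p)
      if (ap != 1) f <- call("^", f, ap)
      if (p > 0) num <- if (is.null(num)) f else call("*", num, f)
      else den <- if (is.null(den)) f else call("*", den, f)
    }
    co <- tt$coef
    piece <- num
    if (is.null(piece)) {
      piece <- abs(co)
    } else if (abs(co) != 1) {
      piece <- call("*", abs(co), piece)
    }
    if (!is.null(den)) piece <- call("/", piece, den)
    if (is.null(total)) {
      total <- if (co < 0) call("-", piece) else piece
    } else {
      total <- call(if (co < 0) "-" else "+", total, piece)
    }
  }
  total
}

expr_canon <- function(e) from_nf(to_nf(e))

nf_is_zero <- function(nf, tol = 1e-10) {
  !length(nf$terms) || all(vapply(nf$terms, function(tt) abs(tt$coef) <= tol, logical(1)))
}

#' Test two expressions for symbolic equality
#'
#' Expands both expressions into the package's sum-of-products normal form
#' (with exp/log rewriting) and checks that their difference collects to zero.
#'
#' @param a,b R language objects or numbers.
#' @return `TRUE` if the difference cancels identically.
#' @keywords internal
exprs_equal <- function(a, b) nf_is_zero(to_nf(call("-", a, b)))

# substitute symbols (and whole d(<state>) atoms) by name
expr_subst <- function(e, map) {
  if (is.name(e)) {
    hit <- map[[as.character(e)]]
    if (!is.null(hit)) return(hit)
    return(e)
  }
  if (is.call(e)) {
    if (identical(e[[1]], as.name("d"))) {
      hit <- map[[deparse1(e)]]
      if (!is.null(hit)) return(hit)
    }
    if (length(e) >= 2L) {
      for (i in 2:length(e)) e[[i]] <- expr_subst(e[[i]], map)
    }
    return(e)
  }
  e
}

# all symbols appearing in argument positions (not function heads)
expr_vars <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e) && length(e) >= 2L) {
    return(unique(unlist(lapply(as.list(e)[-1], expr_vars), use.names = FALSE)))
  }
  character(0)
}

.key_vars_cache <- new.env(parent = emptyenv())
.key_vars <- function(key) {
  hit <- .key_vars_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- expr_vars(str2lang(key))
  # a d(x) atom is an unknown in its own right, keyed by its full text
  e <- str2lang(key)
  if (is.call(e) && identical(e[[1]], as.name("d"))) v <- c(v, key)
  assign(key, v, envir = .key_vars_cache)
  v
}

# unknown keys present at top level of a normal form
.nf_unknowns <- function(nf, unknowns) {
  keys <- unique(unlist(lapply(nf$terms, function(tt) names(tt$pows)), use.names = FALSE))
  if (is.null(keys)) return(character(0))
  intersect(keys, unknowns)
}

# TRUE if any atom of the term mentions any unknown (including buried ones)
.term_mentions <- function(tt, unknowns) {
  for (key in names(tt$pows)) {
    if (key %in% unknowns) return(TRUE)
    if (any(.key_vars(key) %in% unknowns)) return(TRUE)
  }
  FALSE
}

# Solve nf == 0 for unknown v if v occurs linearly with a coefficient free of
# all unknowns and never buried inside another atom. Returns NULL otherwise.
nf_solve_for <- function(nf, v, unknowns) {
  coef_terms <- list()
  rest_terms <- list()
  for (tt in nf$terms) {
    p <- if (v %in% names(tt$pows)) tt$pows[[v]] else 0
    # v buried inside a composite atom (e.g. exp(... v ...)) blocks solving
    for (key in names(tt$pows)) {
      if (key != v && v %in% .key_vars(key)) return(NULL)
    }
    if (p == 0) {
      rest_terms[[length(rest_terms) + 1L]] <- tt
    } else if (p == 1) {
      ct <- .term(tt$coef, tt$pows[names(tt$pows) != v])
      if (.term_mentions(list(coef = ct$coef, pows = ct$pows), unknowns)) return(NULL)
      coef_terms[[length(coef_terms) + 1L]] <- ct
    } else {
      return(NULL)
    }
  }
  if (!length(coef_terms)) return(NULL)
  coef_nf <- .nf_collect(coef_terms)
  if (!length(coef_nf$terms)) return(NULL)
  from_nf(nf_mul(nf_neg(list(terms = rest_terms)), nf_inv(coef_nf)))
}

#' Triangular elimination of a symbolic equation system
#'
#' Repeatedly finds an equation in which some unknown appears linearly with a
#' coefficient free of unknowns, solves for it, and substitutes everywhere
#' (including previously found solutions). Equations that cannot be resolved
#' this way are returned as residuals.
#'
#' @param eq_exprs list of language objects, each representing `expr == 0`.
#' @param unknowns character vector of unknown keys (symbol names or
#'   `d(state)` atom texts).
#' @return list with `solutions` (named list unknown -> expression, fully
#'   substituted) and `residuals` (list of canonical leftover expressions).
#' @keywords internal
solve_linear_system <- function(eq_exprs, unknowns) {
  eqs <- eq_exprs
  sols <- list()
  remaining <- unknowns
  repeat {
    progress <- FALSE
    nfs <- lapply(eqs, to_nf)
    keep <- !vapply(nfs, nf_is_zero, logical(1))
    eqs <- eqs[keep]
    nfs <- nfs[keep]
    if (!length(eqs)) break
    ord <- order(vapply(nfs, function(x) length(x$terms), integer(1)))
    for (i in ord) {
      vs <- sort(.nf_unknowns(nfs[[i]], remaining), method = "radix")
      for (v in vs) {
        sol <- nf_solve_for(nfs[[i]], v, remaining)
        if (!is.null(sol)) {
          m <- stats::setNames(list(sol), v)
          eqs <- lapply(eqs[-i], expr_subst, map = m)
          sols <- lapply(sols, expr_subst, map = m)
          sols[[v]] <- sol
          remaining <- setdiff(remaining, v)
          progress <- TRUE
          break
        }
      }
      if (progress) break
    }
    if (!progress) break
  }
  residuals <- lapply(eqs, expr_canon)
  residuals <- residuals[!vapply(residuals, function(e) nf_is_zero(to_nf(e)), logical(1))]
  list(solutions = sols, residuals = residuals)
}

# numeric evaluation helper: evaluate expression with named values and
# optional function bindings (inputs); log/exp from base
expr_eval <- function(e, values = list(), funs = list()) {
  env <- list2env(funs, parent = baseenv())
  env <- list2env(values, envir = new.env(parent = env))
  eval(e, envir = env)
}
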