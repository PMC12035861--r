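# Helper operations on expression trees: occurrence search, substitution
# with derivative propagation, order-filtered elimination of response
# parameters, removal of time-differentiated quantities at zero strength,
# conjugate transposition, LaTeX export and JSON (de)serialization.

#' Find all occurrences of a symbol in an expression
#'
#' Returns every occurrence of the named base symbol or perturbed
#' parameter, in differentiated or undifferentiated form.
#'
#' @param expr An expression.
#' @param symbol An atomic symbol node, or its name.
#' @return A list of unique occurrence nodes (base symbols and derivative
#'   nodes).
#' @export
find_all <- function(expr, symbol) {
  name <- if (is.character(symbol)) symbol else symbol$name
  seen <- new.env(parent = emptyenv())
  out <- list()
  e_visit(expr, function(nd) {
    hit <- (is_atomic_expr(nd) && identical(nd$name, name)) ||
      (nd$kind == "deriv" && identical(nd$base$name, name))
    if (hit) {
      k <- e_key(nd)
      if (is.null(seen[[k]])) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <<- nd
      }
    }
  })
  out
}

# Maximum derivative order (optionally counted over a perturbation set)
# among all occurrences of `name`; -1 if absent.
max_deriv_order <- function(expr, name, perts = NULL) {
  occ <- find_all(expr, name)
  if (length(occ) == 0) return(-1L)
  max(vapply(occ, function(nd) {
    if (nd$kind != "deriv") return(0L)
    if (is.null(perts)) mc_length(nd$mc) else mc_count_in(nd$mc, perts)
  }, integer(1)))
}

#' Replace symbols (and their derivatives) throughout an expression
#'
#' Substitution keys are base symbols; every occurrence is replaced, and
#' derivative nodes of a key are replaced by the correspondingly
#' differentiated replacement expression.
#'
#' @param expr An expression.
#' @param substitutions A list of `list(from = <atomic node>, to =
#'   <expression>)` pairs.
#' @return The rewritten expression.
#' @export
replace_all <- function(expr, substitutions) {
  if (length(substitutions) == 0) return(expr)
  for (s in substitutions) {
    if (!is_atomic_expr(s$from))
      stop("substitution keys must be base symbols")
    if (!is_expr(s$to)) stop("substitution values must be expressions")
    if (!is.null(s$from$role) && !is.null(s$to$role) &&
        is_atomic_expr(s$to) && !identical(s$from$role, s$to$role))
      stop("shape mismatch between substitution key and replacement")
  }
  keymap <- stats::setNames(
    lapply(substitutions, `[[`, "to"),
    vapply(substitutions, function(s) e_key(s$from), character(1)))
  rebuild <- function(e) {
    k <- e_key(e)
    if (is_atomic_expr(e) && !is.null(keymap[[k]])) return(keymap[[k]])
    if (e$kind == "deriv") {
      bk <- e_key(e$base)
      if (!is.null(keymap[[bk]]))
        return(differentiate(keymap[[bk]], e$mc))
      return(e)
    }
    switch(e$kind,
      sum = expr_sum(lapply(e$terms, rebuild)),
      prod = expr_prod(lapply(e$factors, rebuild), coef = e$coef),
      trace = expr_trace(rebuild(e$arg), time_avg = e$time_avg),
      tdiff = time_derivative(rebuild(e$arg)),
      ct = make_conjugate_transpose(rebuild(e$arg)),
      re = real_part(rebuild(e$arg)),
      expect = expect_ref(rebuild(e$arg)),
      expectproj = expect_proj(rebuild(e$arg)),
      pgrad = pgrad(rebuild(e$arg), e$param_name),
      e)
  }
  rebuild(expr)
}

# Replace one exact node (any kind) by another, without derivative
# propagation; used for targeted substitutions such as swapping a full
# density derivative for its particular solution.
replace_node <- function(expr, from, to) {
  fk <- e_key(from)
  rebuild <- function(e) {
    if (identical(e_key(e), fk)) return(to)
    switch(e$kind,
      sum = expr_sum(lapply(e$terms, rebuild)),
      prod = expr_prod(lapply(e$factors, rebuild), coef = e$coef),
      trace = expr_trace(rebuild(e$arg), time_avg = e$time_avg),
      tdiff = time_derivative(rebuild(e$arg)),
      ct = make_conjugate_transpose(rebuild(e$arg)),
      re = real_part(rebuild(e$arg)),
      expect = expect_ref(rebuild(e$arg)),
      expectproj = expect_proj(rebuild(e$arg)),
      pgrad = pgrad(rebuild(e$arg), e$param_name),
      e)
  }
  rebuild(expr)
}

#' Eliminate derivatives of a response parameter by order filtering
#'
#' Removes every additive term that contains a derivative of the given
#' parameter whose order, counted over the given perturbations, lies in
#' `[min_order, length(perturbations)]`.  The undifferentiated parameter
#' counts as order 0, so `min_order = 0` removes all occurrences.  This
#' is a purely structural filter; its validity as an elimination rule
#' rests on the admissibility conditions enforced upstream by the
#' response-function driver.
#'
#' @param expr An expression.
#' @param parameter A [perturbed_parameter()] (or its name).
#' @param perturbations List of [perturbation()]s over which orders are
#'   counted (the extensive set).
#' @param min_order Nonnegative integer; must not exceed
#'   `length(perturbations) + 1`.
#' @return The filtered expression.
#' @export
eliminate <- function(expr, parameter, perturbations, min_order) {
  name <- if (is.character(parameter)) parameter else parameter$name
  k <- length(perturbations)
  if (min_order > k + 1)
    stop("min_order must not exceed length(perturbations) + 1")
  if (min_order > k) return(expr)
  hit <- function(nd) {
    ord <- NULL
    if (is_atomic_expr(nd) && identical(nd$name, name)) ord <- 0L
    else if (nd$kind == "deriv" && identical(nd$base$name, name))
      ord <- mc_count_in(nd$mc, perturbations)
    !is.null(ord) && ord >= min_order && ord <= k
  }
  keep <- Filter(function(t) !e_any(t, hit), e_terms(expr))
  expr_sum(keep)
}

#' Remove time-differentiated quantities that vanish at zero strength
#'
#' Drops every additive term containing (i) an unperturbed
#' time-differentiated quantity or an unperturbed temporal bookkeeping
#' matrix, or (ii) their perturbed counterparts whose frequency sum is
#' exactly zero.  Idempotent.
#'
#' @param expr An expression.
#' @return The cleaned expression.
#' @export
clean_temporum <- function(expr) {
  hit <- function(nd) {
    if (nd$kind == "tdiff") {
      a <- nd$arg
      if (a$kind == "ct") a <- a$arg
      if (a$kind != "deriv") return(TRUE)           # unperturbed d/dt
      return(lin_is_zero(sum_frequencies(a$mc)))    # zero frequency sum
    }
    if (nd$kind == "matsym" && isTRUE(nd$temporal)) return(TRUE)
    if (nd$kind == "deriv" && nd$base$kind == "matsym" &&
        isTRUE(nd$base$temporal))
      return(lin_is_zero(sum_frequencies(nd$mc)))
    FALSE
  }
  keep <- Filter(function(t) !e_any(t, hit), e_terms(expr))
  expr_sum(keep)
}

#' Conjugate transpose of a matrix-valued expression
#'
#' Distributes over sums, reverses products (conjugating the scalar
#' coefficient), and is an involution.  Derivatives commute with the
#' conjugate transpose (perturbation strengths enter as real-valued
#' envelopes), so derivative nodes are transposed through their base.
#'
#' @param expr A matrix- or vector-valued expression.
#' @return The conjugate-transposed expression.
#' @export
make_conjugate_transpose <- function(expr) {
  switch(expr$kind,
    const = qr_node("const", value = qrat_conj(expr$value)),
    freq = expr,
    sum = expr_sum(lapply(expr$terms, make_conjugate_transpose)),
    prod = expr_prod(rev(lapply(expr$factors, make_conjugate_transpose)),
                     coef = qrat_conj(expr$coef)),
    ct = expr$arg,
    tdiff = time_derivative(make_conjugate_transpose(expr$arg)),
    trace = stop("cannot conjugate-transpose a scalar trace"),
    qr_node("ct", arg = expr))
}

## ---- LaTeX export ------------------------------------------------------

latex_name <- function(name) {
  # map internal names to conventional macros where obvious
  greek <- c("lambda", "zeta", "tau", "rho", "omega", "epsilon", "xi")
  for (g in greek) {
    if (grepl(paste0("^", g, "(_|$)"), name))
      name <- sub(paste0("^", g), paste0("\\\\", g), name)
  }
  # subscript everything after the first underscore
  if (grepl("_", name)) {
    parts <- strsplit(name, "_", fixed = TRUE)[[1]]
    name <- paste0(parts[1], "_{", paste(parts[-1], collapse = ","), "}")
  }
  name
}

#' Export an expression as a LaTeX fragment
#'
#' Deterministic pretty printer; derivative multichains become
#' superscripts, traces map to `\mathrm{Tr}`, the time-averaged trace to
#' `\{\mathrm{Tr}...\}_T`.
#'
#' @param expr An expression.
#' @return A character scalar containing the LaTeX fragment.
#' @export
latexify <- function(expr) {
  lat <- function(e) {
    switch(e$kind,
      const = qrat_latex(e$value),
      freq = paste0("\\left(", lin_format(e$value), "\\right)"),
      sym = latex_name(e$name),
      matsym = latex_name(e$name),
      param = latex_name(e$name),
      deriv = paste0(lat(e$base), "^{",
                     paste(mc_labels(e$mc), collapse = ""), "}"),
      sum = paste(vapply(e$terms, lat, character(1)), collapse = " + "),
      prod = {
        co <- if (qrat_eq(e$coef, qrat_one())) "" else
          paste0(qrat_latex(e$coef), " ")
        paste0(co, paste(vapply(e$factors, lat, character(1)),
                         collapse = " "))
      },
      trace = if (isTRUE(e$time_avg))
        paste0("\\left\\{\\mathrm{Tr}\\left[", lat(e$arg),
               "\\right]\\right\\}_T")
      else paste0("\\mathrm{Tr}\\left[", lat(e$arg), "\\right]"),
      tdiff = paste0("\\dot{", lat(e$arg), "}"),
      ct = paste0("\\left(", lat(e$arg), "\\right)^{\\dagger}"),
      re = paste0("\\mathrm{Re}\\left\\{", lat(e$arg), "\\right\\}"),
      expect = paste0("\\langle ", lat(e$arg), " \\rangle"),
      expectproj = paste0("\\langle ", lat(e$arg), " \\rangle_{\\mu}"),
      pgrad = paste0("\\frac{\\partial}{\\partial ",
                     latex_name(e$param_name), "}\\left[", lat(e$arg),
                     "\\right]"),
      stop("unknown node kind"))
  }
  lat(expr)
}

qrat_latex <- function(q) {
  f1 <- function(n, d) {
    s <- if (n < 0) "-" else ""
    if (d == 1) paste0(s, abs(n)) else
      paste0(s, "\\frac{", abs(n), "}{", d, "}")
  }
  if (q[3] == 0) return(f1(q[1], q[2]))
  if (q[1] == 0) return(paste0(f1(q[3], q[4]), "\\mathrm{i}"))
  paste0("\\left(", f1(q[1], q[2]),
         if (q[3] > 0) " + " else " - ",
         f1(abs(q[3]), q[4]), "\\mathrm{i}\\right)")
}

## ---- JSON serialization ------------------------------------------------

FORMAT_VERSION <- 1L

ser_node <- function(e) {
  base <- list(kind = e$kind)
  add <- switch(e$kind,
    const = list(value = as.list(e$value)),
    freq = list(value = lin_ser(e$value)),
    sym = list(name = e$name),
    matsym = list(name = e$name, deps = deps_ser(e$deps), role = e$role,
                  vanishes_at_zero = e$vanishes_at_zero,
                  temporal = e$temporal),
    param = list(name = e$name, role = e$role),
    deriv = list(base = ser_node(e$base),
                 mc = lapply(e$mc$items, ser_pert)),
    sum = list(terms = lapply(e$terms, ser_node)),
    prod = list(coef = as.list(e$coef),
                factors = lapply(e$factors, ser_node)),
    trace = list(arg = ser_node(e$arg), time_avg = e$time_avg),
    tdiff = list(arg = ser_node(e$arg)),
    ct = list(arg = ser_node(e$arg)),
    re = list(arg = ser_node(e$arg)),
    expect = list(arg = ser_node(e$arg)),
    expectproj = list(arg = ser_node(e$arg)),
    pgrad = list(arg = ser_node(e$arg), param_name = e$param_name),
    stop("unknown node kind"))
  c(base, add)
}

deps_ser <- function(deps) {
  lapply(deps, function(v) if (is.infinite(v)) "inf" else v)
}

deps_deser <- function(deps) {
  lapply(deps, function(v) if (identical(v, "inf")) Inf else as.numeric(v))
}

ser_pert <- function(p) {
  list(label = p$label, strength = p$strength,
       frequency = lin_ser(p$frequency),
       n_components = p$n_components,
       max_diff_order = if (is.infinite(p$max_diff_order)) "inf" else
         p$max_diff_order)
}

deser_pert <- function(x) {
  perturbation(label = x$label,
               frequency = lin_deser(x$frequency),
               n_components = as.integer(x$n_components),
               max_diff_order = if (identical(x$max_diff_order, "inf")) Inf
                 else as.numeric(x$max_diff_order),
               strength = x$strength)
}

lin_ser <- function(lf) {
  list(coeffs = lapply(lf$coeffs, as.list), const = as.list(lf$const))
}

lin_deser <- function(x) {
  lin_make(lapply(x$coeffs, function(v) c(v[[1]], v[[2]])),
           c(x$const[[1]], x$const[[2]]))
}

deser_node <- function(x) {
  k <- x$kind
  if (is.null(k)) stop("malformed serialized expression: missing kind")
  switch(k,
    const = qr_node("const", value = unlist(x$value)),
    freq = freq_factor(lin_deser(x$value)),
    sym = scalar_symbol(x$name),
    matsym = matrix_symbol(x$name, deps = deps_deser(x$deps),
                           role = x$role,
                           vanishes_at_zero = isTRUE(x$vanishes_at_zero),
                           temporal = isTRUE(x$temporal)),
    param = perturbed_parameter(x$name, role = x$role),
    deriv = expr_deriv(deser_node(x$base),
                       multichain(lapply(x$mc, deser_pert))),
    sum = expr_sum(lapply(x$terms, deser_node)),
    prod = expr_prod(lapply(x$factors, deser_node),
                     coef = unlist(x$coef)),
    trace = expr_trace(deser_node(x$arg), time_avg = isTRUE(x$time_avg)),
    tdiff = time_derivative(deser_node(x$arg)),
    ct = make_conjugate_transpose(deser_node(x$arg)),
    re = real_part(deser_node(x$arg)),
    expect = expect_ref(deser_node(x$arg)),
    expectproj = expect_proj(deser_node(x$arg)),
    pgrad = pgrad(deser_node(x$arg), x$param_name),
    stop("malformed serialized expression: unknown kind ", k))
}

#' JSON serialization of expression trees
#'
#' `expr_to_json()` writes a versioned JSON document with a `kind` tag
#' per node; `expr_from_json()` restores a structurally equal
#' expression.
#'
#' @param expr An expression.
#' @param json A character scalar of JSON.
#' @return `expr_to_json()`: a JSON string; `expr_from_json()`: an
#'   expression.
#' @export
expr_to_json <- function(expr) {
  jsonlite::toJSON(list(format_version = FORMAT_VERSION,
                        expression = ser_node(expr)),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname expr_to_json
#' @export
expr_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(x$expression)) stop("malformed serialized expression")
  deser_node(x$expression)
}
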