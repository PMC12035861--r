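# Immutable symbolic expression trees.
#
# Every node is a list with class "qr_expr" and a `kind` field:
#   const      value (complex rational)
#   sym        scalar symbol: name
#   matsym     matrix/operator symbol: name, deps (named list label ->
#              max derivative order), role, and flags `vanishes_at_zero`
#              (field operators that are zero at zero perturbation
#              strength) and `temporal` (half-time-differentiated overlap
#              type quantities removed by clean_temporum)
#   param      perturbed response parameter: name, role; depends on all
#              perturbations to arbitrary order
#   deriv      derivative node: base (sym/matsym/param), mc (canonical
#              multichain); order-0 normalizes to the base itself
#   sum        terms (list), like terms collected, empty sum is zero
#   prod       coef (complex rational) and factors (noncommutative order)
#   trace      arg, time_avg flag (trace followed by period average)
#   tdiff      time derivative of an atomic quantity
#   ct         conjugate transpose
#   re         real-part marker
#   expect     reference expectation value <.>
#   expectproj projected expectation value <.>_mu
#   pgrad      formal gradient with respect to a perturbed parameter
#
# Constructors normalize: structural zeros collapse, sums flatten and
# collect, products flatten and pull scalar coefficients out.

qr_node <- function(kind, ...) {
  e <- structure(c(list(kind = kind), list(...)), class = "qr_expr")
  e$key <- node_key(e)
  e
}

# Canonical key, computed once at construction from the children's
# cached keys (term collection at high derivative orders is dominated
# by key comparisons).
node_key <- function(e) {
  switch(e$kind,
    const = paste0("c:", paste(e$value, collapse = "/")),
    sym = paste0("s:", e$name),
    matsym = paste0("m:", e$name),
    param = paste0("p:", e$name),
    freq = paste0("w:", lin_key(e$value)),
    deriv = paste0("d:", e_key(e$base), "^", mc_key(e$mc)),
    sum = paste0("S(", paste(sort(vapply(e$terms, e_key, character(1))),
                             collapse = "+"), ")"),
    prod = paste0("P[", paste(e$coef, collapse = "/"), "](",
                  paste(vapply(e$factors, e_key, character(1)),
                        collapse = "*"), ")"),
    trace = paste0(if (isTRUE(e$time_avg)) "trT(" else "tr(",
                   e_key(e$arg), ")"),
    tdiff = paste0("dt(", e_key(e$arg), ")"),
    ct = paste0("ct(", e_key(e$arg), ")"),
    re = paste0("re(", e_key(e$arg), ")"),
    expect = paste0("ev(", e_key(e$arg), ")"),
    expectproj = paste0("evp(", e_key(e$arg), ")"),
    pgrad = paste0("pg[", e$param_name, "](", e_key(e$arg), ")"),
    stop("unknown node kind ", e$kind))
}

is_expr <- function(x) inherits(x, "qr_expr")

#' Scalar constants
#'
#' @param nr,dr,ni,di Integer numerator/denominator of the real and
#'   imaginary parts.
#' @return A constant expression node.
#' @export
expr_const <- function(nr = 0, dr = 1, ni = 0, di = 1) {
  qr_node("const", value = qrat(nr, dr, ni, di))
}

expr_zero <- function() expr_const(0)
expr_one <- function() expr_const(1)

is_zero_expr <- function(e) e$kind == "const" && qrat_is_zero(e$value)

#' Scalar symbol
#' @param name Symbol name.
#' @return Expression node.
#' @export
scalar_symbol <- function(name) qr_node("sym", name = name)

#' Matrix and operator symbols
#'
#' A matrix (or operator) symbol carries a dependency table: the
#' perturbation labels it depends on and the maximum order to which it
#' can be differentiated with respect to each.  Differentiating past the
#' table yields a structural zero.
#'
#' @param name Symbol name.
#' @param deps Named list mapping perturbation label to maximum
#'   derivative order (`Inf` allowed); empty means perturbation
#'   independent.
#' @param role One of `"matrix"`, `"operator"`, `"row"`, `"col"`.
#' @param vanishes_at_zero Logical: is the undifferentiated symbol zero
#'   at zero perturbation strength (true for applied field operators)?
#' @param temporal Logical: is this a time-differentiation bookkeeping
#'   matrix removed by [clean_temporum()]?
#' @return Expression node.
#' @export
matrix_symbol <- function(name, deps = list(), role = "matrix",
                          vanishes_at_zero = FALSE, temporal = FALSE) {
  qr_node("matsym", name = name, deps = deps, role = role,
          vanishes_at_zero = vanishes_at_zero, temporal = temporal)
}

#' @rdname matrix_symbol
#' @export
operator_symbol <- function(name, deps = list(), vanishes_at_zero = FALSE) {
  matrix_symbol(name, deps, role = "operator",
                vanishes_at_zero = vanishes_at_zero)
}

#' Perturbed response parameter
#'
#' A named response parameter (density matrix, coupled-cluster amplitude
#' vector, Lagrangian multiplier, ...) that depends on all perturbations
#' to arbitrary order: differentiation never annihilates it, it only
#' accumulates a derivative multichain.
#'
#' @param name Parameter name.
#' @param role Shape role: `"matrix"`, `"row"`, or `"col"`.
#' @return Expression node.
#' @export
perturbed_parameter <- function(name, role = "matrix") {
  qr_node("param", name = name, role = role)
}

is_atomic_expr <- function(e) e$kind %in% c("sym", "matsym", "param")

#' Symbolic frequency factor
#'
#' A scalar factor holding an exact linear frequency form (e.g. the
#' frequency sum of a multichain); used when time derivatives are
#' resolved in the frequency domain.  A zero form collapses to the
#' structural zero.
#'
#' @param lf A frequency linear form ([freq_sym()], [freq_rational()],
#'   or [sum_frequencies()]).
#' @return Expression node.
#' @export
freq_factor <- function(lf) {
  if (lin_is_zero(lf)) return(expr_zero())
  qr_node("freq", value = lf)
}

#' Derivative node
#'
#' @param base An atomic symbol or perturbed parameter.
#' @param mc A [multichain()]; the empty multichain returns `base`.
#' @return Expression node.
#' @export
expr_deriv <- function(base, mc) {
  stopifnot(is_expr(base))
  if (base$kind == "deriv") {
    items <- c(base$mc$items, mc$items)
    base_ <- base$base
    mc <- mc_sorted(multichain(items))
    base <- base_
  } else {
    mc <- mc_sorted(mc)
  }
  if (!is_atomic_expr(base)) stop("derivative nodes wrap atomic symbols")
  if (mc_length(mc) == 0) return(base)
  qr_node("deriv", base = base, mc = mc)
}

#' Sums and products
#'
#' `expr_sum()` flattens nested sums, removes structural zeros and
#' collects like terms (equal up to scalar coefficient).  `expr_prod()`
#' flattens nested products, pulls scalar constants into the
#' coefficient, and collapses to zero if any factor is zero.  Matrix
#' factor order is preserved (noncommutative); scalar coefficients are
#' canonicalized.
#'
#' @param terms,factors Lists of expression nodes.
#' @param coef Complex rational coefficient (internal representation).
#' @return Expression node.
#' @export
expr_sum <- function(terms) {
  flat <- list()
  for (t in terms) {
    if (!is_expr(t)) stop("sum terms must be expressions")
    if (t$kind == "sum") flat <- c(flat, t$terms)
    else if (!is_zero_expr(t)) flat <- c(flat, list(t))
  }
  if (length(flat) == 0) return(expr_zero())
  # collect like terms: key on coefficient-stripped body
  e <- new.env(parent = emptyenv())
  ord <- character(0)
  for (t in flat) {
    sp <- split_coef(t)
    k <- e_key(sp$body)
    if (is.null(e[[k]])) {
      assign(k, list(coef = sp$coef, body = sp$body), envir = e)
      ord <- c(ord, k)
    } else {
      cur <- e[[k]]
      cur$coef <- qrat_add(cur$coef, sp$coef)
      assign(k, cur, envir = e)
    }
  }
  out <- list()
  for (k in ord) {
    cur <- e[[k]]
    if (qrat_is_zero(cur$coef)) next
    out <- c(out, list(apply_coef(cur$body, cur$coef)))
  }
  if (length(out) == 0) return(expr_zero())
  if (length(out) == 1) return(out[[1]])
  qr_node("sum", terms = out)
}

#' @rdname expr_sum
#' @export
expr_prod <- function(factors, coef = qrat_one()) {
  flat <- list()
  for (f in factors) {
    if (!is_expr(f)) stop("product factors must be expressions")
    if (f$kind == "const") { coef <- qrat_mul(coef, f$value); next }
    if (f$kind == "prod") {
      coef <- qrat_mul(coef, f$coef)
      flat <- c(flat, f$factors)
    } else if (is_zero_expr(f)) {
      return(expr_zero())
    } else flat <- c(flat, list(f))
  }
  if (qrat_is_zero(coef)) return(expr_zero())
  if (length(flat) == 0) return(qr_node("const", value = coef))
  # distribute over sum factors so that expressions stay in expanded form
  # (additive terms are the granularity of elimination and zero-strength
  # filtering)
  isum <- which(vapply(flat, function(f) f$kind == "sum", logical(1)))
  if (length(isum)) {
    i <- isum[1]
    terms <- lapply(flat[[i]]$terms, function(t) {
      fs <- flat
      fs[[i]] <- t
      expr_prod(fs, coef = coef)
    })
    return(expr_sum(terms))
  }
  if (length(flat) == 1 && qrat_eq(coef, qrat_one())) return(flat[[1]])
  qr_node("prod", coef = coef, factors = flat)
}

expr_scale <- function(e, nr, dr = 1, ni = 0, di = 1) {
  expr_prod(list(e), coef = qrat(nr, dr, ni, di))
}

expr_neg <- function(e) expr_scale(e, -1)

split_coef <- function(e) {
  if (e$kind == "prod") list(coef = e$coef,
                             body = qr_node("prod", coef = qrat_one(),
                                            factors = e$factors))
  else if (e$kind == "const") list(coef = e$value, body = expr_one())
  else list(coef = qrat_one(), body = e)
}

apply_coef <- function(body, coef) {
  if (body$kind == "const") return(qr_node("const",
                                           value = qrat_mul(body$value, coef)))
  if (body$kind == "prod") return(expr_prod(body$factors, coef = coef))
  expr_prod(list(body), coef = coef)
}

#' Traces, time derivatives, real part
#'
#' `expr_trace()` builds a trace node; with `time_avg = TRUE` it denotes
#' the trace followed by an average over one period of the applied
#' perturbations (the outer operation of the quasi-energy Lagrangians).
#' Traces distribute over sums and pull out scalar coefficients at
#' construction.
#'
#' @param arg Expression.
#' @param time_avg Logical.
#' @return Expression node.
#' @export
expr_trace <- function(arg, time_avg = FALSE) {
  if (is_zero_expr(arg)) return(expr_zero())
  if (arg$kind == "sum")
    return(expr_sum(lapply(arg$terms, expr_trace, time_avg = time_avg)))
  sp <- split_coef(arg)
  if (!qrat_eq(sp$coef, qrat_one()))
    return(apply_coef(expr_trace(sp$body, time_avg), sp$coef))
  qr_node("trace", arg = arg, time_avg = time_avg)
}

#' @rdname expr_trace
#' @export
time_derivative <- function(arg) {
  if (is_zero_expr(arg)) return(expr_zero())
  if (arg$kind == "sum")
    return(expr_sum(lapply(arg$terms, time_derivative)))
  sp <- split_coef(arg)
  if (!qrat_eq(sp$coef, qrat_one()))
    return(apply_coef(time_derivative(sp$body), sp$coef))
  inner <- if (arg$kind == "ct") arg$arg else arg
  if (!(is_atomic_expr(inner) || inner$kind == "deriv"))
    stop("time derivatives apply to atomic quantities")
  qr_node("tdiff", arg = arg)
}

#' @rdname expr_trace
#' @export
real_part <- function(arg) {
  if (is_zero_expr(arg)) return(expr_zero())
  qr_node("re", arg = arg)
}

#' Coupled-cluster expectation-value nodes
#'
#' `expect_ref()` is the reference expectation value of an operator
#' expression; `expect_proj()` its projection onto the excitation
#' manifold (one component per excitation index).  `pgrad()` is a formal,
#' unexpanded gradient of a scalar expression with respect to a perturbed
#' parameter; it commutes with strength differentiation.
#'
#' @param arg Expression.
#' @param param_name Parameter name for `pgrad`.
#' @return Expression node.
#' @export
expect_ref <- function(arg) {
  if (is_zero_expr(arg)) return(expr_zero())
  if (arg$kind == "sum") return(expr_sum(lapply(arg$terms, expect_ref)))
  sp <- split_coef(arg)
  if (!qrat_eq(sp$coef, qrat_one()))
    return(apply_coef(expect_ref(sp$body), sp$coef))
  qr_node("expect", arg = arg)
}

#' @rdname expect_ref
#' @export
expect_proj <- function(arg) {
  if (is_zero_expr(arg)) return(expr_zero())
  if (arg$kind == "sum") return(expr_sum(lapply(arg$terms, expect_proj)))
  sp <- split_coef(arg)
  if (!qrat_eq(sp$coef, qrat_one()))
    return(apply_coef(expect_proj(sp$body), sp$coef))
  qr_node("expectproj", arg = arg)
}

#' @rdname expect_ref
#' @export
pgrad <- function(arg, param_name) {
  if (is_zero_expr(arg)) return(expr_zero())
  if (arg$kind == "sum")
    return(expr_sum(lapply(arg$terms, pgrad, param_name = param_name)))
  qr_node("pgrad", arg = arg, param_name = param_name)
}

## ---- canonical keys and structural equality ----------------------------

e_key <- function(e) {
  if (!is.null(e$key)) e$key else node_key(e)
}

#' Structural equality of expressions
#'
#' Equality up to canonical term collection: sums compare regardless of
#' term order, scalar coefficients are exact rationals, matrix factor
#' order is significant.
#'
#' @param a,b Expressions.
#' @return Logical.
#' @export
expr_equal <- function(a, b) identical(e_key(a), e_key(b))

## ---- generic tree walking ----------------------------------------------

child_fields <- function(e) {
  switch(e$kind,
    sum = "terms", prod = "factors",
    trace = , tdiff = , ct = , re = , expect = , expectproj = ,
    pgrad = "arg",
    # deriv nodes are atomic occurrences: walkers must not treat the
    # wrapped base symbol as an undifferentiated occurrence
    character(0))
}

# Visit every node (pre-order); fn(node) called for side effects.
e_visit <- function(e, fn) {
  fn(e)
  for (f in child_fields(e)) {
    ch <- e[[f]]
    if (is_expr(ch)) e_visit(ch, fn)
    else for (c2 in ch) e_visit(c2, fn)
  }
  invisible(NULL)
}

# TRUE if any node satisfies pred.
e_any <- function(e, pred) {
  if (pred(e)) return(TRUE)
  for (f in child_fields(e)) {
    ch <- e[[f]]
    if (is_expr(ch)) { if (e_any(ch, pred)) return(TRUE) }
    else for (c2 in ch) if (e_any(c2, pred)) return(TRUE)
  }
  FALSE
}

# List the additive terms of an expression (a non-sum is one term).
e_terms <- function(e) if (e$kind == "sum") e$terms else list(e)

#' @export
print.qr_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.qr_expr <- function(x, ...) expr_format(x)

expr_format <- function(e) {
  switch(e$kind,
    const = qrat_format(e$value),
    freq = paste0("(", lin_format(e$value), ")"),
    sym = e$name,
    matsym = e$name,
    param = e$name,
    deriv = paste0(expr_format(e$base), "^{",
                   paste(mc_labels(e$mc), collapse = ""), "}"),
    sum = paste(vapply(e$terms, expr_format, character(1)),
                collapse = " + "),
    prod = {
      co <- if (qrat_eq(e$coef, qrat_one())) "" else
        paste0(qrat_format(e$coef), "*")
      paste0(co, paste(vapply(e$factors, expr_format, character(1)),
                       collapse = "*"))
    },
    trace = paste0(if (isTRUE(e$time_avg)) "TrT{" else "Tr{",
                   expr_format(e$arg), "}"),
    tdiff = paste0("d/dt[", expr_format(e$arg), "]"),
    ct = paste0("(", expr_format(e$arg), ")^H"),
    re = paste0("Re{", expr_format(e$arg), "}"),
    expect = paste0("<", expr_format(e$arg), ">"),
    expectproj = paste0("<", expr_format(e$arg), ">_mu"),
    pgrad = paste0("grad_", e$param_name, "[", expr_format(e$arg), "]"),
    stop("unknown node kind"))
}
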