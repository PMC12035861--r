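# Exact evaluation of response functions for a two-level atom.
#
# The model: a diagonal unperturbed Hamiltonian diag(E0, E1), the system
# initially in the ground state, and one Hermitian field operator per
# perturbation, differentiable only to first order.  The density
# operator obeys the Liouville equation, idempotency and unit trace.
# In the frequency domain the order-n strength derivative of the
# density operator follows from the order-(n-1) ones:
#
#   rho^{b1..bn}_{jk} = sum_i [V^{bi}, rho^{b1..\bi..bn}]_{jk}
#                       / (w_{b1..bn} - (E_j - E_k))
#
# so no linear response equation needs solving.  The switch-on
# infinitesimal only regularizes resonances; frequencies here are
# either generic symbols or rationals chosen off resonance, so it is
# taken to zero from the outset.  All arithmetic is exact (complex
# rationals; frequencies as exact linear forms), which keeps term
# counting and equality tests exact.

#' Construct a two-level atom model
#'
#' @param perturbations List of [perturbation()]s; each must have a
#'   registered field operator.
#' @param operators Either `NULL` (fully symbolic: operator matrix
#'   elements become transition-moment symbols `V<label>[i,j]` with the
#'   Hermitian relation `V[j,i] = conj(V[i,j])`) or a named list
#'   mapping perturbation label to a 2x2 R `complex` (or numeric)
#'   matrix with integer-valued real and imaginary parts (kept exact).
#' @param E0,E1 Energy eigenvalues: `NULL` for symbols (`E_0`, `E_1`,
#'   level splitting symbol `Delta_E`), or exact rationals given as
#'   numbers or `"p/q"` strings (then `E1 - E0` must be nonzero).
#' @param h0_name Name of the unperturbed Hamiltonian symbol in
#'   expressions.
#' @param density_name Name of the density parameter in expressions.
#' @return An object of class `"qr_two_level_model"`.
#' @export
two_level_model <- function(perturbations, operators = NULL,
                            E0 = NULL, E1 = NULL,
                            h0_name = "H_0", density_name = "D") {
  labels <- vapply(perturbations, `[[`, character(1), "label")
  names(perturbations) <- labels
  symbolic_E <- is.null(E0) || is.null(E1)
  if (symbolic_E) {
    dE <- lin_sym("Delta_E")
    E0s <- qs_sym("E_0"); E1s <- qs_sym("E_1")
  } else {
    f0 <- if (is.character(E0)) parse_frac(E0) else .qfrac(E0, 1)
    f1 <- if (is.character(E1)) parse_frac(E1) else .qfrac(E1, 1)
    dE <- lin_const(f1[1] * f0[2] - f0[1] * f1[2], f0[2] * f1[2])
    if (lin_is_zero(dE)) stop("degenerate levels: E1 - E0 must be nonzero")
    E0s <- qs_const(qrat(f0[1], f0[2])); E1s <- qs_const(qrat(f1[1], f1[2]))
  }
  ops <- list()
  for (lab in labels) {
    m <- if (is.null(operators)) NULL else operators[[lab]]
    ops[[lab]] <- if (is.null(m)) .symbolic_operator(lab) else
      .exact_operator(m, lab)
  }
  structure(list(perturbations = perturbations, ops = ops,
                 dE = dE, E0 = E0s, E1 = E1s,
                 symbolic_E = symbolic_E,
                 h0_name = h0_name, density_name = density_name,
                 cache = new.env(parent = emptyenv())),
            class = "qr_two_level_model")
}

.symbolic_operator <- function(lab) {
  m <- qm_zero()
  for (i in 0:1) for (j in 0:1)
    m <- qm_set(m, i, j, qs_sym(sprintf("V%s[%d,%d]", lab, i, j)))
  m
}

.exact_operator <- function(m, lab) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)))
  re <- Re(m); im <- Im(m)
  if (any(re != round(re)) || any(im != round(im)))
    stop("operator entries must have integer-valued parts (kept exact)")
  if (re[1, 2] != re[2, 1] || im[1, 2] != -im[2, 1] ||
      im[1, 1] != 0 || im[2, 2] != 0)
    stop("field operator for '", lab, "' is not Hermitian")
  out <- qm_zero()
  for (i in 0:1) for (j in 0:1)
    out <- qm_set(out, i, j, qs_const(qrat(re[i + 1, j + 1], 1,
                                           im[i + 1, j + 1], 1)))
  out
}

#' @export
print.qr_two_level_model <- function(x, ...) {
  cat(sprintf("<two-level model: %d operators (%s), %s energies>\n",
              length(x$ops), paste(names(x$ops), collapse = ", "),
              if (x$symbolic_E) "symbolic" else "exact rational"))
  invisible(x)
}

# frequency-difference denominator w_sum - (E_j - E_k)
.den_jk <- function(model, wsum, j, k) {
  if (j == k) return(wsum)
  if (j == 1) lin_sub(wsum, model$dE) else lin_add(wsum, model$dE)
}

#' Strength derivatives of the two-level density operator
#'
#' Evaluates the order-n derivative of the density operator by the
#' frequency-domain recursion from the order-(n-1) derivatives, with
#' the unperturbed density the ground-state projector diag(1, 0).
#' Results are cached per model, keyed by the canonical multichain.
#'
#' @param model A [two_level_model()].
#' @param mc A [multichain()] whose perturbations are all registered in
#'   the model.
#' @return A 2x2 matrix of exact scalar sums (internal representation;
#'   see [format_scalar()]).
#' @export
density_derivative <- function(model, mc) {
  labs <- mc_labels(mc)
  miss <- setdiff(unique(labs), names(model$ops))
  if (length(miss))
    stop("no field operator registered for perturbation(s): ",
         paste(miss, collapse = ", "))
  key <- paste0("mc:", paste(sort(vapply(mc$items, pert_key, character(1))),
                             collapse = ";"))
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- mc_length(mc)
  if (n == 0) {
    out <- qm_set(qm_zero(), 0, 0, qs_const(qrat_one()))
  } else {
    wsum <- sum_frequencies(mc)
    out <- qm_zero()
    for (i in seq_len(n)) {
      lab <- labs[i]
      rest <- multichain(mc$items[-i])
      C <- qm_comm(model$ops[[lab]], density_derivative(model, rest))
      for (j in 0:1) for (k in 0:1) {
        cjk <- qm_get(C, j, k)
        if (length(cjk) == 0) next
        out <- qm_set(out, j, k,
                      qs_add(qm_get(out, j, k),
                             qs_div_lin(cjk, .den_jk(model, wsum, j, k))))
      }
    }
  }
  assign(key, out, envir = model$cache)
  out
}

#' Evaluate an operator-valued expression on the two-level model
#'
#' Recursively realizes every operator symbol as its 2x2 matrix: the
#' unperturbed Hamiltonian as diag(E0, E1), first derivatives of field
#' operators as the registered matrices (higher derivatives are zero),
#' density-parameter derivatives through [density_derivative()], time
#' derivatives as multiplication by -i times the frequency sum, and
#' undifferentiated field operators as zero (zero perturbation
#' strength).
#'
#' @param model A [two_level_model()].
#' @param expr A matrix-valued expression.
#' @return A 2x2 matrix of exact scalar sums.
#' @export
evaluate_operator <- function(model, expr) {
  ev <- function(e) {
    switch(e$kind,
      const = stop("scalar constant in operator position"),
      matsym = {
        if (identical(e$name, model$h0_name)) {
          m <- qm_set(qm_zero(), 0, 0, model$E0)
          qm_set(m, 1, 1, model$E1)
        } else if (isTRUE(e$vanishes_at_zero) || isTRUE(e$temporal)) {
          qm_zero()
        } else stop("unmapped operator symbol: ", e$name)
      },
      param = {
        if (identical(e$name, model$density_name))
          density_derivative(model, multichain())
        else stop("unmapped parameter in evaluation: ", e$name)
      },
      deriv = {
        b <- e$base
        if (b$kind == "param" && identical(b$name, model$density_name))
          return(density_derivative(model, e$mc))
        if (b$kind == "matsym" && isTRUE(b$vanishes_at_zero)) {
          labs <- unique(mc_labels(e$mc))
          if (mc_length(e$mc) == 1 && labs %in% names(b$deps) &&
              labs %in% names(model$ops))
            return(model$ops[[labs]])
          return(qm_zero())
        }
        stop("unmapped derivative in evaluation: ", expr_format(e))
      },
      sum = Reduce(qm_add, lapply(e$terms, ev), qm_zero()),
      prod = {
        is_freq <- vapply(e$factors, function(f) f$kind == "freq",
                          logical(1))
        mats <- lapply(e$factors[!is_freq], ev)
        m <- if (length(mats)) Reduce(qm_mul, mats) else
          stop("product without matrix factors in operator position")
        for (f in e$factors[is_freq])
          m <- lapply(m, qs_mul_lin, lf = f$value)
        qm_scale(m, e$coef)
      },
      tdiff = {
        a <- e$arg
        sgn <- 1
        if (a$kind == "ct") { a <- a$arg; sgn <- -1 }
        w <- if (a$kind == "deriv") sum_frequencies(a$mc) else lin_zero()
        m <- ev(e$arg)
        m <- lapply(m, qs_mul_lin, lf = w)
        qm_scale(m, qrat(0, 1, -sgn, 1))
      },
      ct = qm_ct(ev(e$arg)),
      stop("cannot evaluate node of kind ", e$kind,
           " in operator position"))
  }
  ev(expr)
}

#' Evaluate a scalar expression (traces) on the two-level model
#'
#' Resolves every trace node through [evaluate_operator()] followed by
#' the 2x2 trace; sums and scalar products are combined exactly.
#'
#' @param model A [two_level_model()].
#' @param expr A scalar-valued expression (e.g. the expression of a
#'   `"qr_response"`).
#' @return An exact scalar sum (internal representation); use
#'   [canonical_terms()], [count_unique_terms()], [format_scalar()] or
#'   [scalar_value()] on it.
#' @export
evaluate_trace <- function(model, expr) {
  ev <- function(e) {
    switch(e$kind,
      const = qs_const(e$value),
      freq = qs_lin(e$value),
      sym = qs_sym(e$name),
      trace = qm_trace(evaluate_operator(model, e$arg)),
      sum = Reduce(qs_add, lapply(e$terms, ev), qs_zero()),
      prod = {
        s <- Reduce(qs_mul, lapply(e$factors, ev))
        qs_scale(s, e$coef)
      },
      stop("cannot evaluate node of kind ", e$kind,
           " in scalar position"))
  }
  ev(expr)
}

#' Evaluate a response-function result on the two-level model
#'
#' @param model A [two_level_model()].
#' @param response A `"qr_response"` object (from
#'   [dao_response_function()]).
#' @return An exact scalar sum.
#' @export
evaluate_response <- function(model, response) {
  stopifnot(inherits(response, "qr_response"))
  evaluate_trace(model, response$expr)
}

#' Canonical decomposition by transition-moment numerators
#'
#' Expands an evaluated scalar into terms, keys each term by the
#' canonical (sorted) product of transition-moment factors in its
#' numerator, merges terms with equal keys by summing their exact
#' rational frequency coefficients, and drops keys whose merged
#' coefficient is identically zero (decided by exact rational
#' evaluation at generic points).  Denominators are products of
#' sign-normalized linear frequency factors (leading level-splitting
#' coefficient positive).  This canonicalization is the package's
#' operational definition of a "unique term".
#'
#' @param scalar An evaluated scalar (from [evaluate_trace()]).
#' @return A list of response terms, each with fields `numerator`
#'   (character vector of transition-moment factors) and `coefficient`
#'   (the merged exact rational function, as a scalar sum free of
#'   moment symbols).
#' @export
canonical_terms <- function(scalar) {
  scalar <- qs_collect(scalar)
  if (length(scalar) == 0) return(list())
  keys <- vapply(scalar, function(t) paste(t$num_syms, collapse = "*"),
                 character(1))
  out <- list()
  for (k in unique(sort(keys))) {
    grp <- scalar[keys == k]
    coefs <- lapply(grp, function(t) { t$num_syms <- character(0); t })
    coefs <- qs_collect(coefs)
    if (qs_rational_is_zero(coefs)) next
    out[[length(out) + 1L]] <-
      structure(list(numerator = grp[[1]]$num_syms, coefficient = coefs),
                class = "qr_response_term")
  }
  out
}

#' Number of unique terms by transition-moment numerator
#'
#' @param scalar An evaluated scalar.
#' @return Nonnegative integer: `length(canonical_terms(scalar))`.
#' @export
count_unique_terms <- function(scalar) length(canonical_terms(scalar))

#' Display helpers for exact scalars
#'
#' `format_scalar()` renders an exact scalar sum as text;
#' `scalar_value()` extracts a purely numeric scalar as an R `complex`
#' (error if symbols remain).
#'
#' @param scalar An evaluated scalar.
#' @return A character scalar / a complex number.
#' @export
format_scalar <- function(scalar) qs_format(scalar)

#' @rdname format_scalar
#' @export
scalar_value <- function(scalar) {
  scalar <- qs_collect(scalar)
  if (length(scalar) == 0) return(0 + 0i)
  v <- qs_eval(scalar, list(), list())
  complex(real = v[1] / v[2], imaginary = v[3] / v[4])
}

## ---- end-to-end two-level response pipeline ----------------------------

#' Two-level response function through the density-matrix pipeline
#'
#' Convenience driver used by the worked examples: builds `order`
#' perturbations (labels a, b, c, ...), each carrying a symbolic
#' frequency (the frequency of `a` is the negative sum of the others,
#' so the total is zero) and one first-order Hermitian field operator;
#' constructs the orthonormal-basis density-matrix Lagrangian;
#' runs the elimination skeleton with all non-`a` perturbations
#' extensive; and evaluates the result exactly on the two-level model.
#'
#' @param order Total response order n+1 (>= 2): `a` plus n further
#'   perturbations.
#' @param min_wfn_exten Minimum density elimination order k_D; the
#'   default `order` (= k + 1) eliminates nothing; 0 means automatic
#'   (the admissibility lower bound).
#' @param operators As in [two_level_model()] (`NULL` for symbolic
#'   transition moments).
#' @param frequencies Optional named list label -> frequency (exact
#'   rationals as `"p/q"` strings); defaults to symbolic frequencies.
#' @param E0,E1 As in [two_level_model()].
#' @return A list with the model, the Lagrangian, the
#'   `"qr_response"`, and the exactly evaluated scalar (`value`).
#' @export
two_level_response <- function(order, min_wfn_exten = order,
                               operators = NULL, frequencies = NULL,
                               E0 = NULL, E1 = NULL) {
  stopifnot(order >= 2)
  labels <- letters[seq_len(order)]
  others <- labels[-1]
  freq_of <- function(lab) {
    if (!is.null(frequencies) && !is.null(frequencies[[lab]]))
      as_freq(frequencies[[lab]])
    else lin_sym(paste0("omega_", lab))
  }
  wsum <- lin_zero()
  perts <- list()
  for (lab in others) {
    f <- freq_of(lab)
    wsum <- lin_add(wsum, f)
    perts[[lab]] <- perturbation(lab, f, n_components = 3L,
                                 max_diff_order = 1L)
  }
  a <- perturbation("a", lin_neg(wsum), n_components = 3L,
                    max_diff_order = 1L)
  all_perts <- c(list(a = a), perts)

  ops <- lapply(all_perts, function(p)
    operator_symbol(paste0("V_", p$label),
                    deps = stats::setNames(list(1), p$label),
                    vanishes_at_zero = TRUE))
  h0 <- operator_symbol("H_0")
  lag <- dao_lagrangian(a, perts, one_electron = c(list(h0), unname(ops)))
  spec <- elimination_spec(extensive = unname(perts),
                           min_wfn_exten = min_wfn_exten)
  res <- dao_response_function(lag, spec)
  model <- two_level_model(unname(all_perts), operators = operators,
                           E0 = E0, E1 = E1)
  value <- evaluate_response(model, res)
  list(model = model, lagrangian = lag, response = res, value = value)
}
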