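# Symbolic differentiation with respect to perturbation strengths.
#
# Derivatives are taken one perturbation at a time; the product rule on
# n-ary products distributes the new perturbation over each factor in
# turn, which applied order-by-order reproduces the set-partition form
# of the higher-order product rule.  A symbol whose dependency table
# excludes the perturbation, or whose maximum differentiation order
# would be exceeded, differentiates to a structural zero; perturbed
# parameters always accumulate a derivative multichain.

diff1 <- function(e, p) {
  switch(e$kind,
    const = expr_zero(),
    sym = expr_zero(),
    freq = expr_zero(),
    matsym = {
      mx <- e$deps[[p$label]]
      if (is.null(mx) || mx < 1) expr_zero()
      else expr_deriv(e, multichain(list(p)))
    },
    param = expr_deriv(e, multichain(list(p))),
    deriv = {
      b <- e$base
      if (b$kind == "param") {
        expr_deriv(b, mc_insert(e$mc, p))
      } else if (b$kind == "matsym") {
        mx <- b$deps[[p$label]]
        cur <- sum(mc_labels(e$mc) == p$label)
        if (is.null(mx) || cur + 1 > mx) expr_zero()
        else expr_deriv(b, mc_insert(e$mc, p))
      } else expr_zero()
    },
    sum = expr_sum(lapply(e$terms, diff1, p = p)),
    prod = {
      n <- length(e$factors)
      terms <- vector("list", n)
      for (i in seq_len(n)) {
        fs <- e$factors
        fs[[i]] <- diff1(fs[[i]], p)
        terms[[i]] <- expr_prod(fs, coef = e$coef)
      }
      expr_sum(terms)
    },
    trace = expr_trace(diff1(e$arg, p), time_avg = e$time_avg),
    tdiff = {
      d <- diff1(e$arg, p)
      if (is_zero_expr(d)) expr_zero() else time_derivative(d)
    },
    ct = make_conjugate_transpose(diff1(e$arg, p)),
    re = real_part(diff1(e$arg, p)),
    expect = expect_ref(diff1(e$arg, p)),
    expectproj = expect_proj(diff1(e$arg, p)),
    pgrad = pgrad(diff1(e$arg, p), e$param_name),
    stop("cannot differentiate node of kind ", e$kind))
}

#' Differentiate an expression with respect to a perturbation multichain
#'
#' Applies the strength derivatives one perturbation at a time in the
#' order given by the multichain.  Mixed partial derivatives commute, so
#' derivative nodes store their multichains canonically; the order of
#' the requested multichain matters only for the shape metadata of the
#' result tensor.
#'
#' @param expr An expression.
#' @param mc A [multichain()] (or a single [perturbation()]).
#' @return The differentiated expression, canonically collected.
#' @export
differentiate <- function(expr, mc) {
  if (inherits(mc, "qr_perturbation")) mc <- multichain(list(mc))
  out <- expr
  for (p in mc$items) out <- diff1(out, p)
  out
}
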