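# Coupled-cluster quasi-energy response theory (orbital relaxation
# neglected).
#
# The time-dependent quasi-energy Lagrangian is
#
#   L = < e^{ad_{-T}}(H) >  +  lambda . ( < e^{ad_{-T}}(H) >_mu - i tdot^T )
#
# with cluster operator T = t . tau (amplitudes t as a perturbed
# parameter row vector, commuting excitation operators tau), Lagrangian
# multipliers lambda enforcing the amplitude equations, and the
# similarity transform expanded by the Baker-Campbell-Hausdorff series;
# for a Hamiltonian with at most two-body interactions the expansion
# terminates after 4-fold nested commutators.

#' Baker-Campbell-Hausdorff expansion of the similarity transform
#'
#' Expands `e^{ad_{-T}}(H) = sum_{j=0..J} (1/j!) (ad_{-T})^j (H)` into
#' explicit nested-commutator products, where `ad_{-T}(X) = X T - T X`.
#'
#' @param H Operator expression.
#' @param T_op Cluster-operator expression; a structural zero returns
#'   `H` unchanged.
#' @param J Truncation order (default 4: exact for Hamiltonians with at
#'   most two-body interactions).
#' @param commutes If `TRUE`, `[H, T] = 0` is declared and the expansion
#'   collapses to `H`.
#' @return The expanded operator expression.
#' @export
bch_expand <- function(H, T_op, J = 4L, commutes = FALSE) {
  stopifnot(J >= 0)
  if (commutes || is_zero_expr(T_op)) return(H)
  ad_negT <- function(X) expr_sum(list(expr_prod(list(X, T_op)),
                                       expr_neg(expr_prod(list(T_op, X)))))
  terms <- list(H)
  cur <- H
  fact <- 1
  for (j in seq_len(J)) {
    cur <- ad_negT(cur)
    fact <- fact * j
    terms <- c(terms, list(expr_scale(cur, 1, fact)))
  }
  expr_sum(terms)
}

#' Construct the coupled-cluster quasi-energy Lagrangian
#'
#' @param h0 [operator_symbol()] for the unperturbed Hamiltonian.
#' @param field_operators List of [operator_symbol()]s for the applied
#'   perturbation operators (each with its dependency table and
#'   `vanishes_at_zero = TRUE`).
#' @param amplitude_name,multiplier_name,excitation_name Names for the
#'   amplitude row vector (perturbed parameter), the multiplier row
#'   vector (perturbed parameter), and the excitation-operator vector
#'   (constant symbols).
#' @param J Truncation order of the similarity-transform expansion.
#' @return A Lagrangian contract usable with
#'   [get_response_functions()].
#' @export
cc_lagrangian <- function(h0, field_operators,
                          amplitude_name = "t",
                          multiplier_name = "lambda",
                          excitation_name = "tau",
                          J = 4L) {
  t_amp <- perturbed_parameter(amplitude_name, role = "row")
  lam <- perturbed_parameter(multiplier_name, role = "row")
  tau <- matrix_symbol(excitation_name, role = "col")
  H <- expr_sum(c(list(h0), field_operators))
  T_op <- expr_prod(list(t_amp, tau))
  Hbar <- bch_expand(H, T_op, J = J)

  # amplitude-equation vector: <Hbar>_mu - i d/dt t^T
  tdot_col <- time_derivative(make_conjugate_transpose(t_amp))
  amp_eq <- expr_sum(list(expect_proj(Hbar),
                          expr_scale(tdot_col, 0, 1, -1, 1)))
  L <- expr_sum(list(expect_ref(Hbar), expr_prod(list(lam, amp_eq))))

  hooks <- list(
    get_lagrangian = function(lag) lag$data$L,
    eliminate_wavefunction_parameter = function(lag, expr, ext, min_order) {
      eliminate(expr, lag$wfn_parameter, ext, min_order)
    },
    eliminate_lagrangian_multipliers = function(lag, expr, ext, min_order) {
      eliminate(expr, lag$multipliers[1], ext, min_order)
    },
    at_zero_strength = function(lag, expr) {
      clean_temporum(drop_vanishing_operators(expr))
    })

  new_lagrangian(name = "cc",
                 wfn_parameter = amplitude_name,
                 multipliers = multiplier_name,
                 hooks = hooks,
                 data = list(L = L, Hbar = Hbar, amp_eq = amp_eq,
                             t = t_amp, lambda = lam, tau = tau,
                             H = H, J = J, extra_order = 0L))
}

#' Coupled-cluster response function with elimination
#'
#' Runs the skeleton with the amplitudes as wave-function parameter and
#' the multipliers eliminated to the greatest admissible extent, and
#' wraps the result in a real-part marker (response functions are the
#' real part of the differentiated quasi-energy Lagrangian).  With all
#' perturbations extensive and automatic elimination this reproduces
#' the 2n+1 rule for the amplitudes and the 2n+2 rule for the
#' multipliers.
#'
#' @param lagrangian A [cc_lagrangian()].
#' @param spec An [elimination_spec()].
#' @return A `"qr_response"` object whose expression carries the
#'   real-part marker.
#' @export
cc_response_function <- function(lagrangian, spec) {
  stopifnot(inherits(lagrangian, "qr_lagrangian"),
            identical(lagrangian$name, "cc"))
  res <- get_response_functions(lagrangian, spec)
  res$expr <- real_part(res$expr)
  res
}

#' Right-hand sides of the coupled-cluster response equations
#'
#' Differentiates the relevant stationarity condition of the
#' quasi-energy Lagrangian to order n and removes every term containing
#' an order-n derivative of the parameter being solved for; what
#' remains is the right-hand-side vector of the linear response
#' equation (amplitude equation for `is_multiplier = FALSE`, the formal
#' multiplier stationarity condition otherwise).  The left-hand-side
#' operator structure is attached as metadata: `(A - w I)` acting on
#' the amplitude derivatives, `(A^T + w I)` on the multiplier
#' derivatives, with `A` the coupled-cluster Jacobian and `w` the
#' frequency sum of the multichain.  Solving the equations numerically
#' is left to the user.
#'
#' @param lagrangian A [cc_lagrangian()].
#' @param mc Nonempty [multichain()].
#' @param is_multiplier Logical: compute the multiplier right-hand side
#'   instead of the amplitude one.
#' @return Expression with attributes `lhs_pattern` and
#'   `lhs_frequency`.
#' @export
cc_response_rhs <- function(lagrangian, mc, is_multiplier = FALSE) {
  n <- mc_length(mc)
  stopifnot(n >= 1)
  if (!is_multiplier) {
    d <- differentiate(lagrangian$data$amp_eq, mc)
    rhs <- eliminate(d, lagrangian$wfn_parameter, mc$items, n)
  } else {
    stat_t <- pgrad(lagrangian$data$L, lagrangian$wfn_parameter)
    d <- differentiate(stat_t, mc)
    rhs <- eliminate(d, lagrangian$multipliers[1], mc$items, n)
  }
  rhs <- clean_temporum(drop_vanishing_operators(rhs))
  rhs <- expr_neg(rhs)
  attr(rhs, "lhs_pattern") <- if (is_multiplier) "(A^T + w I)" else
    "(A - w I)"
  attr(rhs, "lhs_frequency") <- sum_frequencies(mc)
  rhs
}
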