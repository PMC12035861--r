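# Atomic-orbital density-matrix quasi-energy response theory.
#
# The variational time-averaged quasi-energy derivative Lagrangian for a
# perturbation `a` and a time-independent basis reads
#
#   L^a = Tr_T[ E^{0,a} - S^a W - lambda_a Y - zeta_a Z ]
#
# with the TDSCF constraint Y = F D S - S D F - i S dD/dt S, the
# idempotency constraint Z = D S D - D, the generalized energy-weighted
# density W (kept opaque with declared dependencies), and multipliers
# lambda_a, zeta_a kept as bare perturbed parameters until the
# elimination step, after which surviving (un)differentiated multipliers
# are expanded through their ansaetze
#
#   lambda_a = D^a S D - D S D^a,
#   zeta_a   = F^a D S + S D F^a - F^a .
#
# In an orthonormal basis the overlap never enters (S = identity).
# Response functions follow the n+1 formulation: properties of order
# n+1 need density derivatives to no more than order n, further
# reducible through the generalized elimination rules.

#' Construct the density-matrix quasi-energy derivative Lagrangian
#'
#' @param a The [perturbation()] whose strength differentiates the
#'   quasi-energy once at construction (its frequency must equal the
#'   negative frequency sum of all remaining perturbations).
#' @param perturbations All perturbations the Lagrangian will be
#'   differentiated with respect to (used for the dependency tables of
#'   opaque symbols); `a` is added automatically.
#' @param one_electron List of [operator_symbol()]s making up the
#'   one-electron part of the Fock matrix; typically the unperturbed
#'   Hamiltonian plus one field operator per perturbation (each with its
#'   dependency table and `vanishes_at_zero = TRUE`).
#' @param overlap Either `NULL` for an orthonormal basis (the overlap
#'   matrix never appears) or a [matrix_symbol()] for the overlap.
#' @param two_electron,xc_potential Optional opaque
#'   [matrix_symbol()]s entering the generalized Fock matrix (scaled
#'   exchange two-electron matrix, exchange-correlation potential); they
#'   should carry dependencies on all perturbations.
#' @param xc_energy,nuclear Optional opaque symbols contributing
#'   additively to the differentiated generalized energy.
#' @param density_name,multiplier_names Names of the density parameter
#'   and of the TDSCF/idempotency multipliers.
#' @return A Lagrangian contract usable with
#'   [get_response_functions()].
#' @export
dao_lagrangian <- function(a, perturbations, one_electron,
                           overlap = NULL, two_electron = NULL,
                           xc_potential = NULL, xc_energy = NULL,
                           nuclear = NULL,
                           density_name = "D",
                           multiplier_names = c("lambda_a", "zeta_a")) {
  stopifnot(inherits(a, "qr_perturbation"))
  if (length(one_electron) == 0)
    stop("at least one one-electron operator symbol is required")
  D <- perturbed_parameter(density_name, role = "matrix")
  lam <- perturbed_parameter(multiplier_names[1], role = "matrix")
  zet <- perturbed_parameter(multiplier_names[2], role = "matrix")

  fock_parts <- c(one_electron,
                  Filter(Negate(is.null),
                         list(two_electron, xc_potential)))
  Fk <- expr_sum(fock_parts)
  orthonormal <- is.null(overlap)
  Smat <- overlap

  sdot <- function(x) if (orthonormal) x else expr_prod(list(Smat, x))
  dots <- function(x) if (orthonormal) x else expr_prod(list(x, Smat))

  # constraints
  Ddot <- time_derivative(D)
  Y <- expr_sum(list(
    dots(expr_prod(list(Fk, D))),                       # F D S
    expr_neg(sdot(expr_prod(list(D, Fk)))),             # - S D F
    expr_scale(sdot(dots(Ddot)), 0, 1, -1, 1)))         # - i S dD/dt S
  Z <- if (orthonormal)
    expr_sum(list(expr_prod(list(D, D)), expr_neg(D)))
  else
    expr_sum(list(expr_prod(list(D, Smat, D)), expr_neg(D)))

  # a-differentiated generalized energy (explicit a-dependence only)
  Fa <- diff1(Fk, a)
  e_terms_a <- list(expr_trace(expr_prod(list(Fa, D)), time_avg = TRUE))
  if (!is.null(xc_energy)) e_terms_a <- c(e_terms_a, list(diff1(xc_energy, a)))
  if (!is.null(nuclear)) e_terms_a <- c(e_terms_a, list(diff1(nuclear, a)))

  terms <- e_terms_a
  if (!orthonormal) {
    all_labels <- unique(c(a$label,
                           vapply(perturbations, `[[`, character(1),
                                  "label")))
    deps_all <- stats::setNames(rep(list(Inf), length(all_labels)),
                                all_labels)
    W <- matrix_symbol("W", deps = deps_all)
    Sa <- diff1(Smat, a)
    if (!is_zero_expr(Sa))
      terms <- c(terms, list(expr_neg(expr_trace(expr_prod(list(Sa, W)),
                                                 time_avg = TRUE))))
  }
  terms <- c(terms,
             list(expr_neg(expr_trace(expr_prod(list(lam, Y)),
                                      time_avg = TRUE)),
                  expr_neg(expr_trace(expr_prod(list(zet, Z)),
                                      time_avg = TRUE))))
  La <- expr_sum(terms)

  # multiplier ansaetze (expanded after elimination)
  lam_ansatz <- if (orthonormal)
    expr_sum(list(expr_prod(list(expr_deriv(D, multichain(list(a))), D)),
                  expr_neg(expr_prod(list(D, expr_deriv(D,
                                                        multichain(list(a)))))))
  ) else
    expr_sum(list(expr_prod(list(expr_deriv(D, multichain(list(a))), Smat,
                                 D)),
                  expr_neg(expr_prod(list(D, Smat,
                                          expr_deriv(D,
                                                     multichain(list(a))))))))
  Fa_nonzero <- if (is_zero_expr(Fa)) NULL else Fa
  zet_ansatz <- if (is.null(Fa_nonzero)) expr_zero() else if (orthonormal)
    expr_sum(list(expr_prod(list(Fa, D)), expr_prod(list(D, Fa)),
                  expr_neg(Fa)))
  else
    expr_sum(list(expr_prod(list(Fa, D, Smat)),
                  expr_prod(list(Smat, D, Fa)),
                  expr_neg(Fa)))

  hooks <- list(
    get_lagrangian = function(lag) lag$data$La,
    validate_perturbation_frequencies = function(lag, ext, int) {
      tot <- lin_add(lag$data$a$frequency,
                     sum_frequencies(multichain(c(ext, int))))
      if (!lin_is_zero(tot))
        qr_abort("validate_perturbation_frequencies",
                 paste0("frequency of perturbation '", lag$data$a$label,
                        "' must be the negative frequency sum of the ",
                        "others (total: ", lin_format(tot), ")"))
      invisible(TRUE)
    },
    eliminate_wavefunction_parameter = function(lag, expr, ext, min_order) {
      eliminate(expr, lag$wfn_parameter, ext, min_order)
    },
    eliminate_lagrangian_multipliers = function(lag, expr, ext, min_order) {
      for (m in lag$multipliers) expr <- eliminate(expr, m, ext, min_order)
      replace_all(expr, list(
        list(from = perturbed_parameter(lag$multipliers[1]),
             to = lag$data$lam_ansatz),
        list(from = perturbed_parameter(lag$multipliers[2]),
             to = lag$data$zet_ansatz)))
    },
    at_zero_strength = function(lag, expr) {
      clean_temporum(drop_vanishing_operators(expr))
    })

  new_lagrangian(name = "dao",
                 wfn_parameter = density_name,
                 multipliers = multiplier_names,
                 hooks = hooks,
                 data = list(a = a, La = La, D = D, Y = Y, Z = Z, Fk = Fk,
                             overlap = Smat, orthonormal = orthonormal,
                             lam_ansatz = lam_ansatz,
                             zet_ansatz = zet_ansatz,
                             extra_order = 1L))
}

# Remove additive terms containing an undifferentiated operator that is
# zero at zero perturbation strength (applied field operators).
drop_vanishing_operators <- function(expr) {
  hit <- function(nd) nd$kind == "matsym" && isTRUE(nd$vanishes_at_zero)
  expr_sum(Filter(function(t) !e_any(t, hit), e_terms(expr)))
}

#' Density-matrix response function with elimination
#'
#' Runs the template-method skeleton for a density-matrix Lagrangian:
#' the density derivatives are eliminated from order `min_wfn_exten`
#' (k_D) over the extensive perturbations, the multipliers from order
#' `max(k - k_D + 1, 0)`, surviving multipliers are expanded through
#' their ansaetze, and time-differentiated quantities vanishing at zero
#' strength are removed.
#'
#' @param lagrangian A [dao_lagrangian()].
#' @param spec An [elimination_spec()].
#' @return A `"qr_response"` object.
#' @export
dao_response_function <- function(lagrangian, spec) {
  stopifnot(inherits(lagrangian, "qr_lagrangian"),
            identical(lagrangian$name, "dao"))
  get_response_functions(lagrangian, spec)
}

#' Right-hand side of the density response equation
#'
#' Differentiates the TDSCF constraint to order n and substitutes the
#' full order-n density derivative by its particular solution, yielding
#' the symbolic right-hand side from which the homogeneous response
#' parameters are solved (the linear-response solve itself is left to
#' the user).  Undifferentiated field operators are removed (zero
#' perturbation strength).
#'
#' @param lagrangian A [dao_lagrangian()].
#' @param mc Nonempty [multichain()] of the perturbations b1...bn.
#' @param DP Expression standing for the particular solution (defaults
#'   to an opaque matrix symbol `"D_P"`).
#' @param Dw Expression for the full order-n density derivative being
#'   replaced (defaults to the derivative node of the density).
#' @return The symbolic right-hand side M.
#' @export
dao_response_rhs <- function(lagrangian, mc, DP = NULL, Dw = NULL) {
  stopifnot(mc_length(mc) >= 1)
  if (is.null(Dw)) Dw <- expr_deriv(lagrangian$data$D, mc)
  if (is.null(DP)) DP <- matrix_symbol("D_P")
  Yn <- differentiate(lagrangian$data$Y, mc)
  # frequency domain: d/dt of the order-n density derivative becomes
  # -i w_{b1..bn} times it, so the substituted particular solution
  # carries the frequency factor explicitly (it vanishes in the static
  # limit)
  DP_dot <- expr_prod(list(freq_factor(sum_frequencies(mc)), DP),
                      coef = qrat(0, 1, -1, 1))
  M <- replace_node(Yn, time_derivative(Dw), DP_dot)
  M <- replace_node(M, Dw, DP)
  drop_vanishing_operators(M)
}

#' Particular-solution source from the idempotency constraint
#'
#' The order-n derivative of the idempotency constraint with every
#' order-n density derivative removed (truncation after order n-1);
#' this is the quantity K from which the particular part of the density
#' response is assembled.
#'
#' @param lagrangian A [dao_lagrangian()].
#' @param mc Nonempty [multichain()].
#' @return Symbolic K of order n-1.
#' @export
dao_particular_density <- function(lagrangian, mc) {
  n <- mc_length(mc)
  stopifnot(n >= 1)
  Zn <- differentiate(lagrangian$data$Z, mc)
  eliminate(Zn, lagrangian$wfn_parameter, mc$items, n)
}
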