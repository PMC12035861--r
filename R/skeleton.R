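# Template-method driver: an abstract Lagrangian contract whose
# get_response_functions() runs validation -> differentiation -> two
# eliminations -> zero-strength cleanup, with hooks overridable by the
# concrete Lagrangians.

qr_abort <- function(step, msg, label = NULL) {
  stop(structure(class = c("qr_validation_error", "error", "condition"),
                 list(message = paste0("[", step, "] ", msg),
                      call = sys.call(-1), step = step, label = label)))
}

#' Elimination specification
#'
#' Fixes which perturbations are treated as extensive (elimination rules
#' are applied over these) and intensive, and the minimum order
#' `min_wfn_exten` (k_t for coupled-cluster, k_D for the density-matrix
#' formulation) from which wave-function-parameter derivatives are
#' eliminated.  `min_wfn_exten = 0` means "choose automatically": the
#' driver resolves it to the lower admissibility bound floor(k/2) + 1,
#' with k the number of extensive perturbations.  Values above k mean no
#' wave-function parameters are eliminated and all multipliers can be
#' removed.
#'
#' @param extensive,intensive Lists of [perturbation()]s (disjoint).
#' @param min_wfn_exten Nonnegative integer (0 = automatic).
#' @return An object of class `"qr_elimination_spec"`.
#' @export
elimination_spec <- function(extensive, intensive = list(),
                             min_wfn_exten = 0L) {
  if (inherits(extensive, "qr_perturbation")) extensive <- list(extensive)
  if (inherits(intensive, "qr_perturbation")) intensive <- list(intensive)
  if (min_wfn_exten < 0) stop("min_wfn_exten must be nonnegative")
  structure(list(extensive = extensive, intensive = intensive,
                 min_wfn_exten = as.integer(min_wfn_exten)),
            class = "qr_elimination_spec")
}

# Lower admissibility bound for the wave-function elimination order:
# floor(k/2) + 1 over k extensive perturbations.  Requesting a positive
# order below the bound is inadmissible; orders above k are valid and
# mean "eliminate nothing".
resolve_k_wfn <- function(k, min_wfn_exten) {
  lower <- k %/% 2 + 1L
  if (min_wfn_exten == 0L) return(lower)
  if (min_wfn_exten < lower)
    qr_abort("eliminate_wavefunction_parameter",
             sprintf(paste0("min_wfn_exten = %d violates the admissibility",
                            " condition (needs >= %d for k = %d)"),
                     min_wfn_exten, lower, k))
  min_wfn_exten
}

#' Minimum elimination order for the Lagrangian multipliers
#'
#' `k_lambda = max(k - k_wfn + 1, 0)`, which eliminates differentiated
#' multipliers to the greatest extent compatible with the chosen
#' wave-function elimination order.
#'
#' @param k Number of extensive perturbations.
#' @param k_wfn Minimum elimination order of the wave-function parameter.
#' @return Nonnegative integer.
#' @export
compute_k_lambda <- function(k, k_wfn) {
  stopifnot(k >= 0)
  as.integer(max(k - k_wfn + 1, 0))
}

# Abstract Lagrangian contract.  Hooks receive the contract object
# first; subclass constructors may override any hook without changing
# the driver.
new_lagrangian <- function(name, wfn_parameter, multipliers, hooks,
                           data = list()) {
  defaults <- list(
    validate_perturbation_frequencies = function(lag, ext, int) {
      tot <- sum_frequencies(multichain(c(ext, int)))
      if (!lin_is_zero(tot))
        qr_abort("validate_perturbation_frequencies",
                 paste0("perturbation frequencies do not sum to zero: ",
                        lin_format(tot)))
      invisible(TRUE)
    },
    validate_perturbation_disjointedness = function(lag, ext, int) {
      tryCatch(validate_disjoint(ext, int),
               error = function(e)
                 qr_abort("validate_perturbation_disjointedness",
                          conditionMessage(e)))
    },
    at_zero_strength = function(lag, expr) clean_temporum(expr))
  hooks <- utils::modifyList(defaults, hooks)
  required <- c("get_lagrangian", "eliminate_wavefunction_parameter",
                "eliminate_lagrangian_multipliers")
  miss <- setdiff(required, names(hooks))
  if (length(miss))
    stop("Lagrangian contract missing hooks: ", paste(miss, collapse = ", "))
  structure(list(name = name, wfn_parameter = wfn_parameter,
                 multipliers = multipliers, hooks = hooks, data = data),
            class = "qr_lagrangian")
}

#' Compute a response function through the template-method skeleton
#'
#' Runs, in order: frequency validation, extensive/intensive
#' disjointedness validation, retrieval of the time-averaged
#' quasi-energy (derivative) Lagrangian and its differentiation over the
#' union of extensive and intensive perturbations, elimination of
#' wave-function-parameter derivatives (orders >= `min_wfn_exten` over
#' the extensive perturbations), elimination of Lagrangian-multiplier
#' derivatives with minimum order `max(k - k_wfn + 1, 0)`, and the
#' zero-strength cleanup.  Concrete Lagrangians may override individual
#' hooks without changing this skeleton.
#'
#' @param lagrangian A concrete Lagrangian contract (see
#'   [dao_lagrangian()], [cc_lagrangian()]).
#' @param spec An [elimination_spec()].
#' @return An object of class `"qr_response"`: the final expression plus
#'   metadata (derivative order, elimination parameters, the recorded
#'   call trace of the skeleton steps, and per-step additive term
#'   counts — the raw material for comparing elimination rules).
#' @export
get_response_functions <- function(lagrangian, spec) {
  stopifnot(inherits(lagrangian, "qr_lagrangian"),
            inherits(spec, "qr_elimination_spec"))
  h <- lagrangian$hooks
  trace <- character(0)
  step <- function(s) trace <<- c(trace, s)
  counts <- integer(0)
  note_terms <- function(s, expr)
    counts[[s]] <<- length(e_terms(expr))

  step("validate_perturbation_frequencies")
  h$validate_perturbation_frequencies(lagrangian, spec$extensive,
                                      spec$intensive)
  step("validate_perturbation_disjointedness")
  h$validate_perturbation_disjointedness(lagrangian, spec$extensive,
                                         spec$intensive)

  step("get_lagrangian")
  expr <- h$get_lagrangian(lagrangian)
  all_perts <- c(spec$extensive, spec$intensive)
  expr <- differentiate(expr, multichain(all_perts))
  note_terms("differentiated", expr)

  k <- length(spec$extensive)
  k_wfn <- resolve_k_wfn(k, spec$min_wfn_exten)
  step("eliminate_wavefunction_parameter")
  expr <- h$eliminate_wavefunction_parameter(lagrangian, expr,
                                             spec$extensive,
                                             min(k_wfn, k + 1L))
  note_terms("wavefunction_eliminated", expr)
  k_lambda <- compute_k_lambda(k, k_wfn)
  step("eliminate_lagrangian_multipliers")
  expr <- h$eliminate_lagrangian_multipliers(lagrangian, expr,
                                             spec$extensive, k_lambda)
  note_terms("multipliers_eliminated", expr)
  step("at_zero_strength")
  expr <- h$at_zero_strength(lagrangian, expr)
  note_terms("zero_strength", expr)

  structure(list(expr = expr,
                 model = lagrangian$name,
                 perturbations = all_perts,
                 order = length(all_perts) +
                   (lagrangian$data$extra_order %||% 0L),
                 k = k, k_wfn = k_wfn, k_lambda = k_lambda,
                 call_trace = trace, term_counts = counts),
            class = "qr_response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qr_response <- function(x, ...) {
  cat(sprintf("<response function: %s model, k = %d, k_wfn = %d, k_lambda = %d>\n",
              x$model, x$k, x$k_wfn, x$k_lambda))
  cat(format(x$expr), "\n")
  invisible(x)
}
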