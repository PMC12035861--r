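# Density-matrix Lagrangian: construction, response functions, response
# equation right-hand sides and the particular-solution source.

mk_dao <- function(n, overlap = NULL, s_deps = NULL) {
  perts <- mk_zero_sum_perts(n)
  wsum <- Reduce(qresponse:::lin_add, lapply(perts, `[[`, "frequency"),
                 qresponse:::lin_zero())
  a <- perturbation("a", qresponse:::lin_neg(wsum), max_diff_order = 1)
  all_p <- c(list(a), perts)
  ops <- mk_field_ops(all_p)
  if (!is.null(s_deps)) overlap <- matrix_symbol("S", deps = s_deps)
  lag <- dao_lagrangian(a, perts,
                        one_electron = c(list(operator_symbol("H_0")),
                                         ops),
                        overlap = overlap)
  list(lag = lag, a = a, perts = perts, ops = ops)
}

test_that("the Lagrangian carries energy, TDSCF and idempotency terms", {
  d <- mk_dao(2)
  La <- d$lag$data$La
  # multipliers present, undifferentiated, one per constraint
  expect_length(find_all(La, "lambda_a"), 1L)
  expect_length(find_all(La, "zeta_a"), 1L)
  # the a-differentiated field operator contracts the density
  expect_length(find_all(La, "V_a"), 2L)   # in E^{0,a} and inside F
  # idempotency constraint shows the D.D - D pattern
  Z <- d$lag$data$Z
  DD <- expr_prod(list(perturbed_parameter("D"), perturbed_parameter("D")))
  expect_true(expr_equal(Z, expr_sum(list(DD,
    qresponse:::expr_neg(perturbed_parameter("D"))))))
  # TDSCF constraint carries the -i dD/dt coupling
  expect_true(qresponse:::e_any(d$lag$data$Y,
                                function(nd) nd$kind == "tdiff"))
})

test_that("orthonormal build never mentions the overlap", {
  d <- mk_dao(2)
  expect_length(find_all(d$lag$data$La, "S"), 0L)
})

test_that("general build reduces to the orthonormal one at S = identity", {
  orth <- mk_dao(2)
  gen <- mk_dao(2, s_deps = list())      # overlap symbol, no perturbation deps
  subs <- list(list(from = matrix_symbol("S", deps = list()),
                    to = expr_const(1)))
  for (n_ord in 0:2) {
    mcs <- list(multichain(),
                multichain(list(orth$perts[[1]])),
                multichain(orth$perts))[[n_ord + 1]]
    eo <- differentiate(orth$lag$data$La, mcs)
    eg <- replace_all(differentiate(gen$lag$data$La, mcs), subs)
    expect_true(expr_equal(eo, eg))
  }
})

test_that("order-1 response contains only unperturbed parameters", {
  perts <- list()
  a <- perturbation("a", "0", max_diff_order = 1)
  ops <- mk_field_ops(list(a))
  lag <- dao_lagrangian(a, perts,
                        one_electron = c(list(operator_symbol("H_0")), ops))
  res <- dao_response_function(lag, elimination_spec(list()))
  expect_identical(qresponse:::max_deriv_order(res$expr, "D"), 0L)
  expect_length(find_all(res$expr, "lambda_a"), 0L)
  expect_length(find_all(res$expr, "zeta_a"), 0L)
})

test_that("n+1 rule: no density derivative above order n survives", {
  for (n in 1:3) {
    d <- mk_dao(n)
    res <- dao_response_function(d$lag,
                                 elimination_spec(d$perts,
                                                  min_wfn_exten = n + 1L))
    expect_identical(qresponse:::max_deriv_order(res$expr, "D"),
                     as.integer(n))
  }
})

test_that("inadmissible k_D and frequency imbalance are rejected", {
  d <- mk_dao(2)
  err <- tryCatch(
    dao_response_function(d$lag, elimination_spec(d$perts,
                                                  min_wfn_exten = 1L)),
    condition = function(e) e)
  expect_s3_class(err, "qr_validation_error")
  # break the frequency balance of a
  bad_a <- perturbation("a", "omega_x", max_diff_order = 1)
  lag2 <- dao_lagrangian(bad_a, d$perts,
                         one_electron = c(list(operator_symbol("H_0")),
                                          mk_field_ops(c(list(bad_a),
                                                         d$perts))))
  err2 <- tryCatch(
    dao_response_function(lag2, elimination_spec(d$perts)),
    condition = function(e) e)
  expect_s3_class(err2, "qr_validation_error")
  expect_identical(err2$step, "validate_perturbation_frequencies")
})

test_that("response RHS substitutes the particular solution everywhere", {
  d <- mk_dao(2)
  mc <- multichain(d$perts)
  M <- dao_response_rhs(d$lag, mc)
  expect_true(length(find_all(M, "D_P")) > 0)
  full <- expr_deriv(perturbed_parameter("D"), mc)
  hits <- Filter(function(nd) expr_equal(nd, full), find_all(M, "D"))
  expect_length(hits, 0L)
  # surviving density derivatives are of lower order
  expect_lt(qresponse:::max_deriv_order(M, "D"), 2L)
})

test_that("static-limit RHS drops the frequency-weighted particular term", {
  b <- perturbation("b", "0", max_diff_order = 1)
  a <- perturbation("a", "0", max_diff_order = 1)
  ops <- mk_field_ops(list(a, b))
  lag <- dao_lagrangian(a, list(b),
                        one_electron = c(list(operator_symbol("H_0")), ops))
  M0 <- dao_response_rhs(lag, multichain(list(b)))
  expect_false(qresponse:::e_any(M0, function(nd) nd$kind == "freq"))
  # at a generic frequency the same term is present
  bw <- mk_pert("b")
  aw <- perturbation("a", qresponse:::lin_neg(bw$frequency),
                     max_diff_order = 1)
  ops2 <- mk_field_ops(list(aw, bw))
  lag2 <- dao_lagrangian(aw, list(bw),
                         one_electron = c(list(operator_symbol("H_0")),
                                          ops2))
  Mw <- dao_response_rhs(lag2, multichain(list(bw)))
  expect_true(qresponse:::e_any(Mw, function(nd) nd$kind == "freq"))
})

test_that("particular-solution source truncates the top density order", {
  d <- mk_dao(3)
  for (n in 1:3) {
    mc <- multichain(d$perts[seq_len(n)])
    K <- dao_particular_density(d$lag, mc)
    expect_lt(qresponse:::max_deriv_order(K, "D"), n)
  }
  # with a perturbation-independent overlap the first-order source is zero
  K1 <- dao_particular_density(d$lag, multichain(d$perts[1]))
  expect_true(qresponse:::is_zero_expr(K1))
  # with a perturbation-dependent overlap it keeps S-derivative terms
  g <- mk_dao(1, s_deps = list(b = Inf))
  Kg <- dao_particular_density(g$lag, multichain(g$perts[1]))
  expect_false(qresponse:::is_zero_expr(Kg))
  expect_true(length(find_all(Kg, "S")) > 0)
  expect_identical(qresponse:::max_deriv_order(Kg, "D"), 0L)
})
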