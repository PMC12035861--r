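# Two-level atom: density-operator recursion, operator and trace
# evaluation, canonical term decomposition, and the cross-checks between
# the full pipeline and independent perturbation theory.

mk_symbolic_model <- function(n) {
  # independent symbolic frequencies for b, c, ...; a balances the total
  perts <- lapply(letters[2:(n + 1)], mk_pert)
  wsum <- Reduce(qresponse:::lin_add, lapply(perts, `[[`, "frequency"),
                 qresponse:::lin_zero())
  a <- perturbation("a", qresponse:::lin_neg(wsum), max_diff_order = 1)
  list(model = two_level_model(c(list(a), perts)),
       a = a, perts = perts)
}

test_that("the unperturbed density is the ground-state projector", {
  m <- mk_symbolic_model(2)
  rho0 <- density_derivative(m$model, multichain())
  expect_identical(format_scalar(qresponse:::qm_get(rho0, 0, 0)), "1")
  for (ij in list(c(0, 1), c(1, 0), c(1, 1)))
    expect_length(qresponse:::qm_get(rho0, ij[1], ij[2]), 0L)
})

test_that("density derivatives of order >= 1 are traceless and cached", {
  m <- mk_symbolic_model(3)
  for (mc in list(multichain(m$perts[1]),
                  multichain(m$perts[1:2]),
                  multichain(m$perts))) {
    r <- density_derivative(m$model, mc)
    expect_true(qresponse:::qs_is_zero(qresponse:::qm_trace(r)))
  }
  expect_true(length(ls(m$model$cache)) >= 4)   # results were cached
  expect_error(density_derivative(m$model,
                                  multichain(list(mk_pert("z")))),
               "no field operator")
})

test_that("order-by-order idempotency holds up to order 3", {
  m <- mk_symbolic_model(3)
  labs <- vapply(m$perts, `[[`, character(1), "label")
  for (n in 1:3) {
    items <- m$perts[seq_len(n)]
    lhs <- qresponse:::qm_zero()
    for (s in 0:(2^n - 1)) {
      sel <- as.logical(bitwAnd(s, 2^(seq_len(n) - 1)))
      left <- density_derivative(m$model, multichain(items[sel]))
      right <- density_derivative(m$model, multichain(items[!sel]))
      lhs <- qresponse:::qm_add(lhs, qresponse:::qm_mul(left, right))
    }
    rhs <- density_derivative(m$model, multichain(items))
    # the two sides carry different (equivalent) denominator
    # factorizations, so the comparison needs the rational-function
    # zero test, not structural cancellation
    diff <- qresponse:::qm_sub(lhs, rhs)
    for (entry in diff)
      expect_length(canonical_terms(entry), 0L)
  }
})

test_that("operator evaluation realizes the model matrices", {
  m <- mk_symbolic_model(2)
  H0 <- evaluate_operator(m$model, operator_symbol("H_0"))
  expect_identical(format_scalar(qresponse:::qm_get(H0, 0, 0)), "E_0")
  expect_identical(format_scalar(qresponse:::qm_get(H0, 1, 1)), "E_1")
  Vb <- operator_symbol("V_b", deps = list(b = 1),
                        vanishes_at_zero = TRUE)
  # undifferentiated field operator: zero at zero strength
  expect_true(qresponse:::qm_is_zero(evaluate_operator(m$model, Vb)))
  # first derivative: the registered matrix; second derivative: zero
  d1 <- evaluate_operator(m$model,
                          expr_deriv(Vb, multichain(m$perts[1])))
  expect_identical(format_scalar(qresponse:::qm_get(d1, 0, 1)),
                   "Vb[0,1]")
  d2 <- evaluate_operator(m$model,
                          expr_deriv(Vb, multichain(rep(m$perts[1], 2))))
  expect_true(qresponse:::qm_is_zero(d2))
})

test_that("conjugate transposition of a Hermitian operator is the identity", {
  fx <- random_two_level_fixture(11, 2)
  perts <- lapply(fx$perturbations, function(p)
    perturbation(p$label, p$frequency, max_diff_order = 1))
  model <- two_level_model(perts, operators = fx$operators,
                           E0 = fx$E0, E1 = fx$E1)
  Vb <- operator_symbol("V_b", deps = list(b = 1),
                        vanishes_at_zero = TRUE)
  db <- expr_deriv(Vb, multichain(perts[2]))
  plain <- evaluate_operator(model, db)
  ct <- evaluate_operator(model, make_conjugate_transpose(db))
  expect_true(qresponse:::qm_is_zero(qresponse:::qm_sub(plain, ct)))
})

test_that("trace evaluation: ground-state energy and cyclic invariance", {
  m <- mk_symbolic_model(2)
  e <- expr_trace(expr_prod(list(perturbed_parameter("D"),
                                 operator_symbol("H_0"))))
  expect_identical(format_scalar(evaluate_trace(m$model, e)), "E_0")
  # tr(AB) = tr(BA) for the evaluated random model operators
  fx <- random_two_level_fixture(5, 3)
  perts <- lapply(fx$perturbations, function(p)
    perturbation(p$label, p$frequency, max_diff_order = 1))
  model <- two_level_model(perts, operators = fx$operators,
                           E0 = fx$E0, E1 = fx$E1)
  A <- model$ops[["a"]]; B <- model$ops[["b"]]
  tAB <- qresponse:::qm_trace(qresponse:::qm_mul(A, B))
  tBA <- qresponse:::qm_trace(qresponse:::qm_mul(B, A))
  expect_true(qresponse:::qs_is_zero(qresponse:::qs_sub(tAB, tBA)))
})

test_that("density derivatives at paired negated frequencies are adjoint", {
  fx <- random_two_level_fixture(3, 3)
  mk <- function(neg) {
    perts <- lapply(fx$perturbations, function(p) {
      f <- qresponse:::parse_frac(p$frequency)
      if (neg) f[1] <- -f[1]
      perturbation(p$label, qresponse:::lin_const(f[1], f[2]),
                   max_diff_order = 1)
    })
    list(model = two_level_model(perts, operators = fx$operators,
                                 E0 = fx$E0, E1 = fx$E1),
         perts = perts)
  }
  plus <- mk(FALSE); minus <- mk(TRUE)
  for (n in 1:2) {
    rp <- density_derivative(plus$model, multichain(plus$perts[1:n]))
    rm <- density_derivative(minus$model, multichain(minus$perts[1:n]))
    diff <- qresponse:::qm_sub(qresponse:::qm_ct(rp), rm)
    expect_true(qresponse:::qm_is_zero(diff))
  }
})

test_that("first-order density matches time-dependent perturbation theory", {
  for (seed in 1:5) {
    fx <- random_two_level_fixture(seed, 2)
    freqs <- fixture_freq_list(fx)
    # pipeline without elimination: L^{ab} = Tr(V^a D^b)
    r <- two_level_response(2, min_wfn_exten = 2, operators = fx$operators,
                            frequencies = freqs, E0 = fx$E0, E1 = fx$E1)
    expect_identical(qscal_as_qrat(r$value), tdpt_linear_response(fx))
  }
})

test_that("the eliminated linear response equals perturbation theory too", {
  for (seed in 1:3) {
    fx <- random_two_level_fixture(seed + 20, 2)
    freqs <- fixture_freq_list(fx)
    # automatic elimination at order 2 rewrites everything through the
    # multiplier ansaetze; the value must be unchanged
    r <- two_level_response(2, min_wfn_exten = 0, operators = fx$operators,
                            frequencies = freqs, E0 = fx$E0, E1 = fx$E1)
    expect_identical(qscal_as_qrat(r$value), tdpt_linear_response(fx))
  }
})

test_that("canonical terms: singletons, cancellation, merging", {
  single <- qresponse:::qs_sym("Va[0,1]")
  ct <- canonical_terms(single)
  expect_length(ct, 1L)
  expect_identical(ct[[1]]$numerator, "Va[0,1]")
  # exact cancellation leaves nothing
  gone <- qresponse:::qs_add(single, qresponse:::qs_neg(single))
  expect_length(canonical_terms(gone), 0L)
  expect_identical(count_unique_terms(gone), 0L)
  # rational-function cancellation across denominators is detected:
  # x/(w) - x/(w) written with opposite-sign forms
  w <- qresponse:::lin_sym("omega_b")
  t1 <- qresponse:::qs_div_lin(single, w)
  t2 <- qresponse:::qs_div_lin(single, qresponse:::lin_neg(w))
  expect_length(canonical_terms(qresponse:::qs_add(t1, t2)), 0L)
})

test_that("third-order response decomposes into 12 unique terms", {
  r <- two_level_response(3)
  terms <- canonical_terms(r$value)
  expect_length(terms, 12L)
  # each numerator is a product of one transition moment per perturbation
  for (t in terms) {
    expect_length(t$numerator, 3L)
    ops <- sort(sub("\\[.*$", "", t$numerator))
    expect_identical(ops, c("Va", "Vb", "Vc"))
  }
})

test_that("elimination choices change the expression but not the value", {
  r3 <- two_level_response(3, min_wfn_exten = 3)
  r2 <- two_level_response(3, min_wfn_exten = 2)
  expect_false(expr_equal(r3$response$expr, r2$response$expr))
  for (seed in 1:5) {
    fx <- random_two_level_fixture(seed, 3)
    freqs <- fixture_freq_list(fx)
    v3 <- two_level_response(3, min_wfn_exten = 3,
                             operators = fx$operators,
                             frequencies = freqs,
                             E0 = fx$E0, E1 = fx$E1)$value
    v2 <- two_level_response(3, min_wfn_exten = 2,
                             operators = fx$operators,
                             frequencies = freqs,
                             E0 = fx$E0, E1 = fx$E1)$value
    expect_identical(qscal_as_qrat(v3), qscal_as_qrat(v2))
  }
})
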