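# Expression trees: differentiation, search, substitution, elimination,
# zero-strength cleanup, conjugate transposition, serialization.

test_that("product rule: two-factor trace differentiates into two terms", {
  a <- mk_pert("a")
  A <- matrix_symbol("A", deps = list(a = 1))
  D <- perturbed_parameter("D")
  e <- expr_trace(expr_prod(list(A, D)))
  d <- differentiate(e, a)
  expected <- expr_sum(list(
    expr_trace(expr_prod(list(expr_deriv(A, multichain(list(a))), D))),
    expr_trace(expr_prod(list(A, expr_deriv(D, multichain(list(a))))))))
  expect_true(expr_equal(d, expected))
})

test_that("second derivative of a two-parameter product has four terms", {
  a <- mk_pert("a"); b <- mk_pert("b")
  f <- perturbed_parameter("f"); g <- perturbed_parameter("g")
  d <- differentiate(expr_prod(list(f, g)), multichain(list(a, b)))
  expect_length(qresponse:::e_terms(d), 4L)
  # one representative term: f^a g^b
  fa_gb <- expr_prod(list(expr_deriv(f, multichain(list(a))),
                          expr_deriv(g, multichain(list(b)))))
  expect_true(any(vapply(qresponse:::e_terms(d), expr_equal, logical(1),
                         fa_gb)))
})

test_that("nth derivative of a two-factor product has 2^n terms (n <= 6)", {
  # oracle: repeated single differentiation, counting terms at each step
  f <- perturbed_parameter("f"); g <- perturbed_parameter("g")
  e <- expr_prod(list(f, g))
  brute <- e
  for (n in 1:6) {
    p <- mk_pert(letters[n], max_order = Inf)
    brute <- differentiate(brute, p)
    expect_length(qresponse:::e_terms(brute), 2L^n)
    direct <- differentiate(expr_prod(list(f, g)),
                            multichain(lapply(seq_len(n), function(i)
                              mk_pert(letters[i], max_order = Inf))))
    expect_true(expr_equal(brute, direct))
  }
})

test_that("differentiation respects dependency tables and maximum orders", {
  a <- mk_pert("a"); b <- mk_pert("b")
  V <- matrix_symbol("V", deps = list(a = 1))
  expect_true(qresponse:::is_zero_expr(differentiate(V, b)))
  Va <- differentiate(V, a)
  expect_identical(Va$kind, "deriv")
  expect_true(qresponse:::is_zero_expr(differentiate(Va, a)))
  # perturbed parameters absorb derivatives indefinitely
  D <- perturbed_parameter("D")
  Dab <- differentiate(D, multichain(list(a, b)))
  expect_identical(qresponse:::mc_length(Dab$mc), 2L)
})

test_that("differentiation composes: d_c d_b equals d_{bc}", {
  b <- mk_pert("b"); c_ <- mk_pert("c")
  D <- perturbed_parameter("D")
  A <- matrix_symbol("A", deps = list(b = 2, c = 2))
  exprs <- list(
    expr_trace(expr_prod(list(A, D))),
    expr_trace(expr_prod(list(A, D, A))),
    expr_sum(list(expr_trace(expr_prod(list(A, D))),
                  expr_scale(expr_trace(expr_prod(list(D, D))), 3))),
    expr_prod(list(D, time_derivative(D))))
  for (e in exprs) {
    step <- differentiate(differentiate(e, b), c_)
    joint <- differentiate(e, multichain(list(b, c_)))
    expect_true(expr_equal(step, joint))
  }
})

test_that("find_all locates (un)differentiated occurrences uniquely", {
  b <- mk_pert("b"); c_ <- mk_pert("c")
  A <- matrix_symbol("A")
  D <- perturbed_parameter("D")
  Dbc <- expr_deriv(D, multichain(list(b, c_)))
  e <- expr_trace(expr_prod(list(A, Dbc)))
  occ <- find_all(e, "D")
  expect_length(occ, 1L)
  expect_true(expr_equal(occ[[1]], Dbc))
  expect_length(find_all(e, "Q"), 0L)
  # both the base and a derivative present -> two distinct occurrences
  e2 <- expr_sum(list(expr_trace(expr_prod(list(A, D))), expr_trace(Dbc)))
  expect_length(find_all(e2, "D"), 2L)
})

test_that("replace_all propagates derivatives of the replacement", {
  a <- mk_pert("a"); b <- mk_pert("b")
  lam <- perturbed_parameter("lam")
  D <- perturbed_parameter("D")
  # ansatz: lam := D^a; an occurrence lam^b must become D^{ab}
  e <- expr_trace(expr_deriv(lam, multichain(list(b))))
  out <- replace_all(e, list(list(from = lam,
                                  to = expr_deriv(D,
                                                  multichain(list(a))))))
  expect_true(expr_equal(out,
                         expr_trace(expr_deriv(D,
                                               multichain(list(a, b))))))
  expect_true(expr_equal(replace_all(e, list()), e))
})

test_that("replacing the overlap by the identity kills its derivatives", {
  b <- mk_pert("b")
  S <- matrix_symbol("S", deps = list(b = Inf))
  D <- perturbed_parameter("D")
  e <- differentiate(expr_trace(expr_prod(list(S, D))), b)
  out <- replace_all(e, list(list(from = S, to = expr_const(1))))
  # Tr(S^b D) term vanishes; Tr(S D^b) becomes Tr(D^b)
  expect_true(expr_equal(out,
                         expr_trace(expr_deriv(D, multichain(list(b))))))
})

test_that("eliminate removes exactly the orders in [min_order, k]", {
  b <- mk_pert("b"); c_ <- mk_pert("c")
  A <- matrix_symbol("A"); B <- matrix_symbol("B")
  D <- perturbed_parameter("D")
  e <- expr_sum(list(
    expr_trace(expr_prod(list(A, expr_deriv(D, multichain(list(b, c_)))))),
    expr_trace(expr_prod(list(B, expr_deriv(D, multichain(list(b))))))))
  out <- eliminate(e, D, list(b, c_), 2)
  expect_true(expr_equal(out,
    expr_trace(expr_prod(list(B, expr_deriv(D, multichain(list(b))))))))
  # min_order above the perturbation count: identity
  expect_true(expr_equal(eliminate(e, D, list(b, c_), 3), e))
  expect_error(eliminate(e, D, list(b, c_), 4), "min_order")
  # idempotent
  expect_true(expr_equal(eliminate(out, D, list(b, c_), 2), out))
  # orders counted over the given set only
  occ <- find_all(eliminate(e, D, list(b, c_), 2), "D")
  ords <- vapply(occ, function(nd)
    qresponse:::mc_count_in(nd$mc, list(b, c_)), integer(1))
  expect_true(all(ords < 2))
  # min_order = 0 removes undifferentiated occurrences too
  e0 <- expr_trace(expr_prod(list(A, D)))
  expect_true(qresponse:::is_zero_expr(eliminate(e0, D, list(b), 0)))
})

test_that("clean_temporum drops vanishing time-differentiated terms", {
  b <- mk_pert("b", freq = "2/5"); c_ <- mk_pert("c", freq = "-2/5")
  D <- perturbed_parameter("D")
  A <- matrix_symbol("A")
  unpert <- expr_trace(expr_prod(list(A, time_derivative(D))))
  zero_sum <- expr_trace(expr_prod(list(A,
    time_derivative(expr_deriv(D, multichain(list(b, c_)))))))
  alive <- expr_trace(expr_prod(list(A,
    time_derivative(expr_deriv(D, multichain(list(b)))))))
  e <- expr_sum(list(unpert, zero_sum, alive))
  out <- clean_temporum(e)
  expect_true(expr_equal(out, alive))
  expect_true(expr_equal(clean_temporum(out), out))   # idempotent
  # expressions without temporal nodes pass through
  plain <- expr_trace(expr_prod(list(A, D)))
  expect_true(expr_equal(clean_temporum(plain), plain))
  # the temporal bookkeeping matrix: unperturbed and zero-frequency-sum
  # derivatives are removed
  Tm <- matrix_symbol("T", deps = list(b = Inf, c = Inf), temporal = TRUE)
  e2 <- expr_sum(list(expr_trace(Tm),
                      expr_trace(expr_deriv(Tm, multichain(list(b, c_)))),
                      expr_trace(expr_deriv(Tm, multichain(list(b))))))
  expect_true(expr_equal(clean_temporum(e2),
                         expr_trace(expr_deriv(Tm, multichain(list(b))))))
})

test_that("conjugate transpose reverses products and is an involution", {
  A <- matrix_symbol("A"); B <- matrix_symbol("B")
  ab <- expr_prod(list(A, B))
  expect_true(expr_equal(make_conjugate_transpose(ab),
                         expr_prod(list(make_conjugate_transpose(B),
                                        make_conjugate_transpose(A)))))
  expect_true(expr_equal(make_conjugate_transpose(
    make_conjugate_transpose(ab)), ab))
  s <- expr_sum(list(A, expr_scale(B, 0, 1, 1, 1)))   # A + iB
  cts <- make_conjugate_transpose(s)
  expect_true(expr_equal(cts,
    expr_sum(list(make_conjugate_transpose(A),
                  expr_scale(make_conjugate_transpose(B), 0, 1, -1, 1)))))
})

test_that("JSON serialization round-trips structurally", {
  a <- mk_pert("a"); b <- mk_pert("b", freq = "-7/3")
  D <- perturbed_parameter("D")
  V <- matrix_symbol("V", deps = list(a = 1), vanishes_at_zero = TRUE)
  fixtures <- list(
    expr_const(3, 4, -1, 2),
    expr_deriv(D, multichain(list(a, b))),
    expr_trace(expr_prod(list(V, D)), time_avg = TRUE),
    time_derivative(expr_deriv(D, multichain(list(b)))),
    make_conjugate_transpose(expr_prod(list(V, D))),
    freq_factor(sum_frequencies(multichain(list(a, b)))),
    pgrad(expect_ref(expr_prod(list(V, D))), "t"),
    expr_sum(list(expr_scale(expr_trace(D), 2, 3),
                  expr_trace(expr_prod(list(V, D))))))
  for (e in fixtures) {
    rt <- expr_from_json(expr_to_json(e))
    expect_true(expr_equal(rt, e))
  }
  expect_error(expr_from_json("{\"bogus\": 1}"), "malformed")
})

test_that("latexify is deterministic and names its pieces", {
  A <- matrix_symbol("A"); D <- perturbed_parameter("D")
  tex <- latexify(expr_trace(expr_prod(list(A, D))))
  expect_match(tex, "\\\\mathrm\\{Tr\\}")
  expect_match(tex, "A")
  expect_match(tex, "D")
  expect_identical(tex, latexify(expr_trace(expr_prod(list(A, D)))))
})

test_that("latexified response functions are balanced LaTeX fragments", {
  # tokenizer oracle: every \left has its \right, braces balance
  r <- two_level_response(3)
  tex <- latexify(r$response$expr)
  expect_identical(lengths(regmatches(tex, gregexpr("\\\\left", tex))),
                   lengths(regmatches(tex, gregexpr("\\\\right", tex))))
  stripped <- gsub("\\\\\\{|\\\\\\}", "", tex)
  opens <- lengths(regmatches(stripped, gregexpr("\\{", stripped)))
  closes <- lengths(regmatches(stripped, gregexpr("\\}", stripped)))
  expect_identical(opens, closes)
})
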