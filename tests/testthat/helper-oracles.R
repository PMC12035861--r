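# Shared fixtures and independent oracles used across the suite.

# ---- perturbation fixtures ----------------------------------------------

mk_pert <- function(label, freq = paste0("omega_", label), max_order = 1,
                    components = 3L) {
  perturbation(label, freq, n_components = components,
               max_diff_order = max_order)
}

# n perturbations b, c, ... with symbolic frequencies, the last frequency
# replaced so the total sums to zero
mk_zero_sum_perts <- function(n) {
  perts <- lapply(letters[2:(n + 1)], mk_pert)
  wl <- Reduce(qresponse:::lin_add,
               lapply(perts[-n], `[[`, "frequency"),
               qresponse:::lin_zero())
  perts[[n]] <- perturbation(perts[[n]]$label, qresponse:::lin_neg(wl),
                             max_diff_order = 1)
  perts
}

mk_field_ops <- function(perts) {
  lapply(perts, function(p)
    operator_symbol(paste0("V_", p$label),
                    deps = stats::setNames(list(p$max_diff_order),
                                           p$label),
                    vanishes_at_zero = TRUE))
}

mk_cc_lagrangian <- function(n, J = 4L) {
  perts <- mk_zero_sum_perts(n)
  list(lag = cc_lagrangian(operator_symbol("H_0"), mk_field_ops(perts),
                           J = J),
       perts = perts)
}

# ---- combinatorial oracles ----------------------------------------------

# Stirling numbers of the second kind and Bell numbers by recurrence
# (independent of the restricted-growth enumeration in set_partitions)
stirling2 <- function(n, k) {
  S <- matrix(0, n + 1, n + 1)
  S[1, 1] <- 1
  for (i in seq_len(n)) for (j in seq_len(i))
    S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
  S[n + 1, k + 1]
}

bell_number <- function(n) sum(vapply(1:n, function(k) stirling2(n, k),
                                      numeric(1)))

# ---- numeric expression evaluator (complex doubles) ---------------------
#
# Maps matrix symbols to numeric matrices; used as the independent
# oracle for the similarity-transform expansion.
num_eval <- function(e, env) {
  switch(e$kind,
    const = (e$value[1] / e$value[2] + 1i * e$value[3] / e$value[4]),
    matsym = env[[e$name]],
    param = env[[e$name]],
    sum = Reduce(`+`, lapply(e$terms, num_eval, env = env)),
    prod = {
      coef <- e$coef[1] / e$coef[2] + 1i * e$coef[3] / e$coef[4]
      m <- Reduce(`%*%`, lapply(e$factors, num_eval, env = env))
      coef * m
    },
    ct = Conj(t(num_eval(e$arg, env))),
    stop("numeric oracle cannot evaluate kind ", e$kind))
}

# matrix exponential by scaling-and-squaring on the power series
mat_exp <- function(A, terms = 40) {
  s <- 8
  As <- A / 2^s
  X <- diag(nrow(A)); acc <- X
  for (k in seq_len(terms)) {
    X <- X %*% As / k
    acc <- acc + X
  }
  for (i in seq_len(s)) acc <- acc %*% acc
  acc
}

# ---- exact two-level TDPT oracle ----------------------------------------
#
# First-order time-dependent perturbation theory for the density matrix
# of a two-level system, coded directly from the Liouville equation in
# the frequency domain (closed form, no recursion, no expression trees):
#   rho^b_{jk} = [V^b, rho0]_{jk} / (w_b - (E_j - E_k))
#   L^{ab}     = sum_{jk} V^a_{kj} rho^b_{jk}
# Exact complex-rational arithmetic throughout.
tdpt_linear_response <- function(fx) {
  qr <- function(z) qresponse:::qrat(Re(z), 1, Im(z), 1)
  qmul <- qresponse:::qrat_mul; qadd <- qresponse:::qrat_add
  qsub <- qresponse:::qrat_sub; qdiv <- qresponse:::qrat_div
  Va <- fx$operators[["a"]]; Vb <- fx$operators[["b"]]
  wb <- qresponse:::parse_frac(Filter(function(p) p$label == "b",
                                      fx$perturbations)[[1]]$frequency)
  wb <- qresponse:::qrat(wb[1], wb[2])
  dE <- qresponse:::qrat(fx$E1 - fx$E0, 1)
  rho0 <- matrix(c(1, 0, 0, 0), 2, 2)   # ground-state projector
  acc <- qresponse:::qrat_zero()
  for (j in 1:2) for (k in 1:2) {
    # [V^b, rho0]_{jk} = sum_m Vb[j,m] rho0[m,k] - rho0[j,m] Vb[m,k]
    comm <- qresponse:::qrat_zero()
    for (m in 1:2) {
      comm <- qadd(comm, qmul(qr(Vb[j, m]), qr(rho0[m, k] + 0i)))
      comm <- qsub(comm, qmul(qr(rho0[j, m] + 0i), qr(Vb[m, k])))
    }
    Ej <- if (j == 1) qresponse:::qrat(fx$E0, 1) else
      qresponse:::qrat(fx$E1, 1)
    Ek <- if (k == 1) qresponse:::qrat(fx$E0, 1) else
      qresponse:::qrat(fx$E1, 1)
    den <- qsub(wb, qsub(Ej, Ek))
    acc <- qadd(acc, qmul(qr(Va[k, j]), qdiv(comm, den)))
  }
  acc
}

# exact scalar (qscal) -> qrat, requiring a fully numeric value
qscal_as_qrat <- function(s) {
  s <- qresponse:::qs_collect(s)
  qresponse:::qs_eval(s, list(), list())
}

fixture_freq_list <- function(fx) {
  out <- lapply(fx$perturbations, function(p) p$frequency)
  names(out) <- vapply(fx$perturbations, function(p) p$label, character(1))
  out
}
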