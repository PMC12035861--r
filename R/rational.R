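# Exact arithmetic layer: complex rationals, linear frequency forms, and
# sums of "response terms" (rational coefficient x transition-moment monomial
# x linear-form numerator factors / linear-form denominator factors).
#
# Rationals are stored as length-4 numeric vectors c(nr, dr, ni, di) holding
# exact integers in doubles (reduced, denominators positive).  All integers
# must stay below 2^53; qrat_make() checks this.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.qfrac <- function(n, d) {
  if (d == 0) stop("zero denominator in rational")
  if (d < 0) { n <- -n; d <- -d }
  if (n == 0) return(c(0, 1))
  g <- .gcd2(n, d)
  n <- n / g; d <- d / g
  if (abs(n) > 2^52 || d > 2^52)
    stop("rational arithmetic overflow (integer exceeds 2^52)")
  c(n, d)
}

#' @noRd
qrat <- function(nr = 0, dr = 1, ni = 0, di = 1) {
  r <- .qfrac(nr, dr); i <- .qfrac(ni, di)
  c(r, i)
}

qrat_zero <- function() c(0, 1, 0, 1)
qrat_one <- function() c(1, 1, 0, 1)
qrat_i <- function() c(0, 1, 1, 1)

qrat_is_zero <- function(q) q[1] == 0 && q[3] == 0

qrat_add <- function(a, b) {
  r <- .qfrac(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
  i <- .qfrac(a[3] * b[4] + b[3] * a[4], a[4] * b[4])
  c(r, i)
}

qrat_neg <- function(a) c(-a[1], a[2], -a[3], a[4])

qrat_sub <- function(a, b) qrat_add(a, qrat_neg(b))

qrat_mul <- function(a, b) {
  # (ar + i ai)(br + i bi)
  r <- .qfrac(a[1] * b[1] * a[4] * b[4] - a[3] * b[3] * a[2] * b[2],
              a[2] * b[2] * a[4] * b[4])
  i <- .qfrac(a[1] * b[3] * a[4] * b[2] + a[3] * b[1] * a[2] * b[4],
              a[2] * b[2] * a[4] * b[4])
  c(r, i)
}

qrat_conj <- function(a) c(a[1], a[2], -a[3], a[4])

qrat_inv <- function(a) {
  if (qrat_is_zero(a)) stop("division by zero rational")
  # 1/(r + i s) = (r - i s)/(r^2 + s^2); work over common denominator
  nr <- a[1] * a[4]; ni <- a[3] * a[2]; den <- a[2] * a[4]
  m <- nr * nr + ni * ni
  c(.qfrac(nr * den, m), .qfrac(-ni * den, m))
}

qrat_div <- function(a, b) qrat_mul(a, qrat_inv(b))

qrat_eq <- function(a, b) all(a == b)

qrat_scale <- function(a, n, d = 1) qrat_mul(a, qrat(n, d))

# Parse "p", "p/q", "-p/q" into a real rational c(p, q).
parse_frac <- function(s) {
  s <- trimws(s)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    .qfrac(as.numeric(parts[1]), as.numeric(parts[2]))
  } else {
    .qfrac(as.numeric(s), 1)
  }
}

qrat_format <- function(q) {
  fmt1 <- function(n, d) if (d == 1) sprintf("%g", n) else sprintf("%g/%g", n, d)
  if (q[3] == 0) return(fmt1(q[1], q[2]))
  if (q[1] == 0) return(paste0(fmt1(q[3], q[4]), "i"))
  sprintf("(%s%s%si)", fmt1(q[1], q[2]), if (q[3] > 0) "+" else "-",
          fmt1(abs(q[3]), q[4]))
}

## ---- Linear forms over real symbols ------------------------------------
#
# A linear form is a named list: coeffs = named list of real rationals
# (c(n, d)), const = real rational.  Symbols are frequency symbols and the
# level-splitting symbol; coefficients stay exact.  Canonical: zero coeffs
# dropped, names sorted (with "Delta_E" ordered first when present).

lin_sym_order <- function(nms) {
  pri <- ifelse(nms == "Delta_E", 0L, 1L)
  nms[order(pri, nms)]
}

lin_make <- function(coeffs = list(), const = c(0, 1)) {
  keep <- vapply(coeffs, function(cf) cf[1] != 0, logical(1))
  coeffs <- coeffs[keep]
  if (length(coeffs)) coeffs <- coeffs[lin_sym_order(names(coeffs))]
  list(coeffs = coeffs, const = const)
}

lin_zero <- function() lin_make()

lin_sym <- function(name, n = 1, d = 1) {
  lin_make(stats::setNames(list(.qfrac(n, d)), name))
}

lin_const <- function(n, d = 1) lin_make(const = .qfrac(n, d))

lin_add <- function(a, b) {
  cf <- a$coeffs
  for (nm in names(b$coeffs)) {
    cf[[nm]] <- if (is.null(cf[[nm]])) b$coeffs[[nm]] else
      .qfrac(cf[[nm]][1] * b$coeffs[[nm]][2] + b$coeffs[[nm]][1] * cf[[nm]][2],
             cf[[nm]][2] * b$coeffs[[nm]][2])
  }
  lin_make(cf, .qfrac(a$const[1] * b$const[2] + b$const[1] * a$const[2],
                      a$const[2] * b$const[2]))
}

lin_scale <- function(a, n, d = 1) {
  s <- .qfrac(n, d)
  if (s[1] == 0) return(lin_zero())
  cf <- lapply(a$coeffs, function(x) .qfrac(x[1] * s[1], x[2] * s[2]))
  lin_make(cf, .qfrac(a$const[1] * s[1], a$const[2] * s[2]))
}

lin_neg <- function(a) lin_scale(a, -1)

lin_sub <- function(a, b) lin_add(a, lin_neg(b))

lin_is_zero <- function(a) length(a$coeffs) == 0 && a$const[1] == 0

lin_is_const <- function(a) length(a$coeffs) == 0

lin_key <- function(a) {
  parts <- vapply(names(a$coeffs), function(nm) {
    cf <- a$coeffs[[nm]]
    sprintf("%g/%g*%s", cf[1], cf[2], nm)
  }, character(1))
  paste(c(parts, sprintf("%g/%g", a$const[1], a$const[2])), collapse = "+")
}

# Canonicalize the sign of a linear form used as a denominator factor: the
# leading coefficient (Delta_E first, then alphabetical) is made positive.
# Returns list(form, sign).
lin_signed <- function(a) {
  lead <- if (length(a$coeffs)) a$coeffs[[1]][1] else a$const[1]
  if (lead < 0) list(form = lin_neg(a), sign = -1) else list(form = a, sign = 1)
}

# Evaluate at an exact rational assignment (named list name -> c(n, d)).
lin_eval <- function(a, env) {
  acc <- a$const
  for (nm in names(a$coeffs)) {
    v <- env[[nm]]
    if (is.null(v)) stop("no value for symbol ", nm)
    cf <- a$coeffs[[nm]]
    acc <- .qfrac(acc[1] * cf[2] * v[2] + cf[1] * v[1] * acc[2],
                  acc[2] * cf[2] * v[2])
  }
  acc
}

lin_format <- function(a) {
  if (lin_is_zero(a)) return("0")
  parts <- character(0)
  for (nm in names(a$coeffs)) {
    cf <- a$coeffs[[nm]]
    co <- if (cf[1] == 1 && cf[2] == 1) "" else
      if (cf[1] == -1 && cf[2] == 1) "-" else
        paste0(if (cf[2] == 1) sprintf("%g", cf[1]) else
          sprintf("%g/%g", cf[1], cf[2]), "*")
    parts <- c(parts, paste0(co, nm))
  }
  if (a$const[1] != 0)
    parts <- c(parts, if (a$const[2] == 1) sprintf("%g", a$const[1]) else
      sprintf("%g/%g", a$const[1], a$const[2]))
  out <- paste(parts, collapse = " + ")
  gsub("\\+ -", "- ", out)
}

## ---- Scalar sums of response terms -------------------------------------
#
# A "qscal" is a list of terms; each term is
#   list(c = qrat, num_syms = sorted character vector (transition-moment
#        symbols, with multiplicity), num_lin = list of linear forms,
#        den_lin = list of canonically signed linear forms).
# The empty list is exact zero.  Terms with equal (num_syms, num_lin,
# den_lin) keys are merged on collection.

qs_zero <- function() list()

qs_const <- function(q) {
  if (qrat_is_zero(q)) return(qs_zero())
  list(list(c = q, num_syms = character(0), num_lin = list(), den_lin = list()))
}

qs_sym <- function(name) {
  list(list(c = qrat_one(), num_syms = name, num_lin = list(),
            den_lin = list()))
}

qs_lin <- function(lf) {
  if (lin_is_zero(lf)) return(qs_zero())
  if (lin_is_const(lf)) return(qs_const(qrat(lf$const[1], lf$const[2])))
  list(list(c = qrat_one(), num_syms = character(0), num_lin = list(lf),
            den_lin = list()))
}

.term_key <- function(t) {
  paste(paste(t$num_syms, collapse = "*"),
        paste(sort(vapply(t$num_lin, lin_key, character(1))), collapse = "|"),
        paste(sort(vapply(t$den_lin, lin_key, character(1))), collapse = "|"),
        sep = " ## ")
}

qs_collect <- function(terms) {
  if (length(terms) <= 1) return(terms)
  e <- new.env(parent = emptyenv())
  for (t in terms) {
    k <- .term_key(t)
    prev <- e[[k]]
    if (is.null(prev)) assign(k, t, envir = e)
    else { prev$c <- qrat_add(prev$c, t$c); assign(k, prev, envir = e) }
  }
  out <- as.list(e)
  out <- out[!vapply(out, function(t) qrat_is_zero(t$c), logical(1))]
  names(out) <- NULL
  out[order(vapply(out, .term_key, character(1)))]
}

qs_add <- function(a, b) qs_collect(c(a, b))

qs_neg <- function(a) lapply(a, function(t) { t$c <- qrat_neg(t$c); t })

qs_sub <- function(a, b) qs_add(a, qs_neg(b))

.term_mul <- function(s, t) {
  list(c = qrat_mul(s$c, t$c),
       num_syms = sort(c(s$num_syms, t$num_syms)),
       num_lin = c(s$num_lin, t$num_lin),
       den_lin = c(s$den_lin, t$den_lin))
}

qs_mul <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(qs_zero())
  out <- vector("list", length(a) * length(b))
  k <- 0L
  for (s in a) for (t in b) { k <- k + 1L; out[[k]] <- .term_mul(s, t) }
  qs_collect(out)
}

qs_scale <- function(a, q) {
  if (qrat_is_zero(q)) return(qs_zero())
  lapply(a, function(t) { t$c <- qrat_mul(t$c, q); t })
}

# Multiply every term by a linear-form factor (numerator).
qs_mul_lin <- function(a, lf) {
  if (lin_is_zero(lf)) return(qs_zero())
  if (lin_is_const(lf)) return(qs_scale(a, qrat(lf$const[1], lf$const[2])))
  lapply(a, function(t) { t$num_lin <- c(t$num_lin, list(lf)); t })
}

# Divide every term by a linear-form factor (denominator).
qs_div_lin <- function(a, lf) {
  if (lin_is_zero(lf)) stop("division by a zero linear form")
  if (lin_is_const(lf))
    return(qs_scale(a, qrat_inv(qrat(lf$const[1], lf$const[2]))))
  sg <- lin_signed(lf)
  lapply(a, function(t) {
    t$den_lin <- c(t$den_lin, list(sg$form))
    if (sg$sign < 0) t$c <- qrat_neg(t$c)
    t
  })
}

qs_conj <- function(a) {
  # Conjugation of a term: conjugate the coefficient; transition-moment
  # symbols "Op[i,j]" map to "Op[j,i]" (Hermitian operators); real linear
  # forms are unchanged.
  lapply(a, function(t) {
    t$c <- qrat_conj(t$c)
    t$num_syms <- sort(vapply(t$num_syms, .sym_conj, character(1),
                              USE.NAMES = FALSE))
    t
  })
}

.sym_conj <- function(s) {
  m <- regmatches(s, regexec("^(.*)\\[([01]),([01])\\]$", s))[[1]]
  if (length(m) == 4) paste0(m[2], "[", m[4], ",", m[3], "]") else s
}

qs_is_zero <- function(a) length(qs_collect(a)) == 0

# Exact evaluation at a rational assignment for every symbol (transition
# moments as complex rationals, linear-form symbols as real rationals).
qs_eval <- function(a, sym_env, lin_env) {
  acc <- qrat_zero()
  for (t in a) {
    v <- t$c
    for (s in t$num_syms) {
      sv <- sym_env[[s]]
      if (is.null(sv)) stop("no value for symbol ", s)
      v <- qrat_mul(v, sv)
    }
    for (lf in t$num_lin) {
      fv <- lin_eval(lf, lin_env)
      v <- qrat_mul(v, qrat(fv[1], fv[2]))
    }
    for (lf in t$den_lin) {
      fv <- lin_eval(lf, lin_env)
      v <- qrat_mul(v, qrat_inv(qrat(fv[1], fv[2])))
    }
    acc <- qrat_add(acc, v)
  }
  acc
}

# Deterministic "generic point" assignment for symbols appearing in the
# frequency linear forms: the i-th symbol (canonical order) receives
# base^-(i+1); integer-coefficient combinations of distinct powers of a
# prime never vanish unless all coefficients do, so denominators stay
# nonzero and accidental zeros of a nonzero rational function at both test
# points are impossible for the factor structure used here.
qs_generic_point <- function(syms, base = 2) {
  syms <- lin_sym_order(unique(syms))
  env <- list()
  p <- base
  for (s in syms) { env[[s]] <- .qfrac(1, p); p <- p * base }
  env
}

qs_lin_symbols <- function(a) {
  out <- character(0)
  for (t in a)
    for (lf in c(t$num_lin, t$den_lin)) out <- c(out, names(lf$coeffs))
  unique(out)
}

# Test whether a qscal is identically zero as a rational function, by exact
# evaluation at two deterministic generic points (transition-moment symbols
# are already separated out by the caller; here num_syms must be empty).
qs_rational_is_zero <- function(a) {
  if (length(a) == 0) return(TRUE)
  if (any(vapply(a, function(t) length(t$num_syms) > 0, logical(1))))
    stop("qs_rational_is_zero expects terms free of moment symbols")
  syms <- qs_lin_symbols(a)
  for (b in c(2, 3)) {
    env <- qs_generic_point(syms, base = b)
    if (!qrat_is_zero(qs_eval(a, list(), env))) return(FALSE)
  }
  TRUE
}

qs_format <- function(a) {
  if (length(a) == 0) return("0")
  paste(vapply(a, function(t) {
    parts <- qrat_format(t$c)
    if (length(t$num_syms)) {
      lead <- if (identical(parts, "1")) character(0) else parts
      parts <- paste(c(lead, t$num_syms), collapse = "*")
    }
    for (lf in t$num_lin) parts <- paste0(parts, "*(", lin_format(lf), ")")
    for (lf in t$den_lin) parts <- paste0(parts, "/(", lin_format(lf), ")")
    parts
  }, character(1)), collapse = " + ")
}

## ---- 2x2 matrices of qscal ---------------------------------------------

qm_zero <- function() list(qs_zero(), qs_zero(), qs_zero(), qs_zero())

# idx: row i, col j (0-based) -> position
.qm_at <- function(i, j) 2L * i + j + 1L

qm_get <- function(m, i, j) m[[.qm_at(i, j)]]

qm_set <- function(m, i, j, v) { m[[.qm_at(i, j)]] <- v; m }

qm_add <- function(a, b) Map(qs_add, a, b)

qm_sub <- function(a, b) Map(qs_sub, a, b)

qm_scale <- function(a, q) lapply(a, qs_scale, q = q)

qm_mul <- function(a, b) {
  out <- qm_zero()
  for (i in 0:1) for (j in 0:1) {
    s <- qs_zero()
    for (k in 0:1)
      s <- qs_add(s, qs_mul(qm_get(a, i, k), qm_get(b, k, j)))
    out <- qm_set(out, i, j, s)
  }
  out
}

qm_comm <- function(a, b) qm_sub(qm_mul(a, b), qm_mul(b, a))

qm_trace <- function(m) qs_add(qm_get(m, 0, 0), qm_get(m, 1, 1))

qm_ct <- function(m) {
  out <- qm_zero()
  for (i in 0:1) for (j in 0:1)
    out <- qm_set(out, i, j, qs_conj(qm_get(m, j, i)))
  out
}

qm_is_zero <- function(m) all(vapply(m, qs_is_zero, logical(1)))
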