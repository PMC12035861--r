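# Configuration-driven runs and fixture generation.
#
# A run configuration (YAML or JSON) describes perturbations, the model
# (dao | cc | twolevel), the elimination specification and the output
# format; run_config() executes it and writes the requested expression
# (LaTeX and/or JSON tree) plus a structured log of the skeleton steps.
# All numerics in configuration files are strings parsed to exact
# rationals.

#' Read a run configuration
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return The configuration as a named list (class `"qr_run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$model) || !cfg$model %in% c("dao", "cc", "twolevel"))
    stop("config: model must be one of dao, cc, twolevel")
  if (is.null(cfg$perturbations) || length(cfg$perturbations) == 0)
    stop("config: at least one perturbation is required")
  for (p in cfg$perturbations) {
    if (is.null(p$label) || is.null(p$frequency))
      stop("config: every perturbation needs label and frequency")
  }
  cfg$output <- cfg$output %||% "latex"
  if (!all(cfg$output %in% c("latex", "json")))
    stop("config: output must be latex and/or json")
  structure(cfg, class = c("qr_run_config", "list"))
}

config_perturbation <- function(p) {
  perturbation(label = p$label,
               frequency = as_freq(p$frequency),
               n_components = as.integer(p$components %||% 3L),
               max_diff_order = if (identical(p$max_order, "inf")) Inf else
                 as.numeric(p$max_order %||% 1))
}

#' Execute a run configuration
#'
#' Builds the requested Lagrangian, runs the elimination skeleton, and
#' writes the resulting expression under `out_dir` as `response.json`
#' (expression tree) and/or `response.tex`, together with `run_log.json`
#' recording the skeleton call trace and additive term counts per step
#' output.  For `model: twolevel` the expression is additionally
#' evaluated exactly on the configured (or symbolic) 2x2 model, and the
#' unique-term count is reported when `count_terms: true`.
#'
#' @param config A configuration list or a path to one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the response object, output paths,
#'   and (for the two-level model) the evaluated scalar and term count.
#' @export
run_config <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  perts <- lapply(cfg$perturbations, config_perturbation)
  names(perts) <- vapply(perts, `[[`, character(1), "label")
  elim <- cfg$elimination %||% list()
  ext_labels <- unlist(elim$extensive %||% list())
  int_labels <- unlist(elim$intensive %||% list())
  min_wfn <- as.integer(elim$min_wfn_exten %||% 0L)

  field_ops <- lapply(perts, function(p)
    operator_symbol(paste0("V_", p$label),
                    deps = stats::setNames(list(p$max_diff_order),
                                           p$label),
                    vanishes_at_zero = TRUE))
  h0 <- operator_symbol("H_0")

  result <- list()
  if (cfg$model == "cc") {
    lag <- cc_lagrangian(h0, unname(field_ops),
                         J = as.integer(cfg$bch_order %||% 4L))
    spec <- elimination_spec(perts[ext_labels], perts[int_labels],
                             min_wfn)
    res <- cc_response_function(lag, spec)
  } else {
    a_label <- cfg$response_perturbation %||% perts[[1]]$label
    a <- perts[[a_label]]
    rest <- perts[setdiff(names(perts), a_label)]
    # frequency "balance": the response perturbation takes the negative
    # frequency sum of all the others
    spec_a <- Filter(function(p) identical(p$label, a_label),
                     cfg$perturbations)[[1]]
    if (identical(spec_a$frequency, "balance")) {
      wsum <- Reduce(lin_add, lapply(rest, `[[`, "frequency"), lin_zero())
      a <- perturbation(a_label, lin_neg(wsum),
                        n_components = a$n_components,
                        max_diff_order = a$max_diff_order)
      perts[[a_label]] <- a
    }
    if (length(ext_labels) == 0)
      ext_labels <- setdiff(names(perts), a_label)
    lag <- dao_lagrangian(a, unname(rest),
                          one_electron = c(list(h0), unname(field_ops)))
    spec <- elimination_spec(perts[ext_labels], perts[int_labels],
                             min_wfn)
    res <- dao_response_function(lag, spec)
  }
  result$response <- res

  paths <- character(0)
  if ("json" %in% cfg$output) {
    p <- file.path(out_dir, "response.json")
    writeLines(expr_to_json(res$expr), p)
    paths <- c(paths, p)
  }
  if ("latex" %in% cfg$output) {
    p <- file.path(out_dir, "response.tex")
    writeLines(latexify(res$expr), p)
    paths <- c(paths, p)
  }

  if (cfg$model == "twolevel") {
    ops <- NULL
    if (!is.null(cfg$two_level$operators))
      ops <- lapply(cfg$two_level$operators, parse_operator_matrix)
    model <- two_level_model(unname(perts), operators = ops,
                             E0 = cfg$two_level$E0 %||% NULL,
                             E1 = cfg$two_level$E1 %||% NULL)
    result$value <- evaluate_response(model, res)
    if (isTRUE(cfg$count_terms))
      result$n_unique_terms <- count_unique_terms(result$value)
  }

  log <- list(model = cfg$model,
              call_trace = res$call_trace,
              k = res$k, k_wfn = res$k_wfn, k_lambda = res$k_lambda,
              term_counts = as.list(res$term_counts),
              n_terms_final = length(e_terms(res$expr)))
  if (!is.null(result$n_unique_terms))
    log$n_unique_terms <- result$n_unique_terms
  logp <- file.path(out_dir, "run_log.json")
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA), logp)
  result$paths <- c(paths, logp)
  invisible(result)
}

# Operator matrices in config files: nested lists of "re" / "re+imi"
# strings with integer parts, e.g. [["1", "2-1i"], ["2+1i", "0"]].
parse_operator_matrix <- function(rows) {
  m <- matrix(0 + 0i, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    s <- gsub(" ", "", as.character(rows[[i]][[j]]))
    mt <- regmatches(s, regexec("^(-?[0-9]+)(([+-][0-9]+)i)?$", s))[[1]]
    if (length(mt) == 0) stop("cannot parse operator entry: ", s)
    re <- as.numeric(mt[2])
    im <- if (nzchar(mt[4])) as.numeric(mt[4]) else 0
    m[i, j] <- complex(real = re, imaginary = im)
  }
  m
}

## ---- deterministic fixtures --------------------------------------------

# Small deterministic linear congruential generator: fixture output is a
# pure function of the seed, independent of R's RNG state.
.lcg_new <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (16807 * state) %% 2147483647
    state
  }
}

.lcg_int <- function(gen, lo, hi) lo + gen() %% (hi - lo + 1)

#' Generate a seeded random two-level model fixture
#'
#' Produces a deterministic model: one random Hermitian 2x2 operator
#' per perturbation (integer entries in [-5, 5]), random rational
#' frequencies for labels b, c, ... with the frequency of `a` set to
#' their negative sum (total zero), and a positive rational level
#' splitting, re-drawn deterministically until no frequency-difference
#' denominator of the density recursion vanishes (off-resonance
#' condition over all sub-multichains).
#'
#' @param seed Positive integer seed (fully determines the output).
#' @param n_operators Number of perturbations including `a` (>= 2).
#' @return A list with `perturbations` (frequencies as `"p/q"`
#'   strings), `operators` (named list of 2x2 complex matrices),
#'   `E0`, `E1`.
#' @export
random_two_level_fixture <- function(seed, n_operators = 3L) {
  stopifnot(n_operators >= 2)
  labels <- letters[seq_len(n_operators)]
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    gen <- .lcg_new(seed * 1009 + attempt)
    E0 <- 0
    E1 <- .lcg_int(gen, 1, 9)          # level splitting E1 - E0
    freqs <- list()
    for (lab in labels[-1]) {
      freqs[[lab]] <- c(.lcg_int(gen, -19, 19), .lcg_int(gen, 2, 7))
    }
    wa <- c(0, 1)
    for (f in freqs)
      wa <- .qfrac(wa[1] * f[2] - f[1] * wa[2], wa[2] * f[2])
    freqs[["a"]] <- wa
    # off-resonance check: every nonempty subset frequency sum must
    # differ from 0, +dE and -dE
    ok <- TRUE
    labs <- labels
    # proper nonempty subsets only: the full set sums to zero by
    # construction and never appears as a recursion denominator
    nsub <- 2^length(labs) - 2
    for (s in seq_len(nsub)) {
      sel <- labs[bitwAnd(s, 2^(seq_along(labs) - 1)) > 0]
      acc <- c(0, 1)
      for (lab in sel) {
        f <- freqs[[lab]]
        acc <- .qfrac(acc[1] * f[2] + f[1] * acc[2], acc[2] * f[2])
      }
      if (acc[1] == 0 || (acc[2] == 1 && abs(acc[1]) == E1)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    ops <- list()
    for (lab in labels) {
      d0 <- .lcg_int(gen, -5, 5); d1 <- .lcg_int(gen, -5, 5)
      re <- .lcg_int(gen, -5, 5); im <- .lcg_int(gen, -5, 5)
      ops[[lab]] <- matrix(c(complex(real = d0),
                             complex(real = re, imaginary = -im),
                             complex(real = re, imaginary = im),
                             complex(real = d1)), 2, 2)
    }
    frq <- lapply(freqs, function(f)
      if (f[2] == 1) sprintf("%d", f[1]) else sprintf("%d/%d", f[1], f[2]))
    return(list(perturbations = lapply(labels, function(lab)
                  list(label = lab, frequency = frq[[lab]],
                       components = 3L, max_order = 1)),
                operators = ops, E0 = E0, E1 = E1))
  }
}

#' Write a fixture model file
#'
#' Serializes a [random_two_level_fixture()] as YAML; the same seed
#' always produces a byte-identical file.
#'
#' @param path Output file path.
#' @param seed Positive integer seed.
#' @param n_operators Number of perturbations including `a`.
#' @return Invisibly, the fixture list.
#' @export
write_fixture_model <- function(path, seed, n_operators = 3L) {
  fx <- random_two_level_fixture(seed, n_operators)
  ser <- list(seed = seed,
              perturbations = fx$perturbations,
              E0 = as.character(fx$E0), E1 = as.character(fx$E1),
              operators = lapply(fx$operators, function(m) {
                lapply(1:2, function(i) lapply(1:2, function(j) {
                  z <- m[i, j]
                  if (Im(z) == 0) sprintf("%d", as.integer(Re(z)))
                  else sprintf("%d%+di", as.integer(Re(z)),
                               as.integer(Im(z)))
                }))
              }))
  writeLines(yaml::as.yaml(ser), path)
  invisible(fx)
}
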