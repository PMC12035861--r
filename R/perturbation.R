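#' Define an external perturbation
#'
#' A perturbation is characterized by its strength symbol (the complex
#' Fourier coefficient of the time-periodic field envelope), its angular
#' frequency, its number of tensor components (3 for dipole-like fields,
#' 3N for geometric displacements of N nuclei), and the maximum order to
#' which operators depending on it may be differentiated.  Two
#' perturbations are equal if and only if all characteristics agree.
#'
#' @param label Short identifier, e.g. `"b"`.
#' @param frequency Either a frequency symbol name (character), an exact
#'   rational given as `"p/q"` string or a whole number, or a linear form
#'   built with [freq_sym()] / [freq_rational()].  Kept exact; floating
#'   point input is rejected.
#' @param n_components Positive integer, number of tensor components.
#' @param max_diff_order Positive integer or `Inf`: highest derivative
#'   order to which operators depending on this perturbation survive.
#' @param strength Strength symbol name; defaults to `"eps_<label>"`.
#' @return An object of class `"qr_perturbation"`.
#' @export
perturbation <- function(label, frequency, n_components = 3L,
                         max_diff_order = Inf,
                         strength = paste0("eps_", label)) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (n_components < 1L) stop("n_components must be >= 1")
  if (!(is.infinite(max_diff_order) || max_diff_order >= 1L))
    stop("max_diff_order must be >= 1 or Inf")
  structure(list(label = label,
                 strength = strength,
                 frequency = as_freq(frequency),
                 n_components = as.integer(n_components),
                 max_diff_order = max_diff_order),
            class = "qr_perturbation")
}

#' Frequency symbols and exact rational frequencies
#'
#' Frequencies are carried as exact linear forms over named symbols with
#' rational coefficients, so that zero-sum checks are exact.
#'
#' @param name Symbol name, e.g. `"omega_b"`.
#' @param n,d Integer numerator and denominator.
#' @return A linear-form frequency object.
#' @export
freq_sym <- function(name, n = 1, d = 1) lin_sym(name, n, d)

#' @rdname freq_sym
#' @export
freq_rational <- function(n, d = 1) lin_const(n, d)

as_freq <- function(x) {
  if (is.list(x) && !is.null(x$coeffs)) return(x)
  if (is.character(x)) {
    if (grepl("^-?[0-9]+(/[0-9]+)?$", trimws(x))) {
      f <- parse_frac(x)
      return(lin_const(f[1], f[2]))
    }
    return(lin_sym(x))
  }
  if (is.numeric(x)) {
    if (x != round(x)) stop("frequencies must be exact; use \"p/q\" strings")
    return(lin_const(x))
  }
  stop("cannot interpret frequency")
}

freq_neg <- function(x) lin_neg(x)

#' @export
format.qr_perturbation <- function(x, ...) {
  sprintf("<perturbation %s: freq = %s, components = %d, max order = %s>",
          x$label, lin_format(x$frequency), x$n_components,
          if (is.infinite(x$max_diff_order)) "inf" else
            format(x$max_diff_order))
}

#' @export
print.qr_perturbation <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

pert_eq <- function(a, b) {
  identical(a$label, b$label) && identical(a$strength, b$strength) &&
    lin_is_zero(lin_sub(a$frequency, b$frequency)) &&
    a$n_components == b$n_components &&
    identical(a$max_diff_order, b$max_diff_order)
}

# Canonical sort key: (label, frequency as canonical string).  Used only
# for canonicalization of derivative bookkeeping, never to reorder a
# user-supplied multichain.
pert_key <- function(p) paste0(p$label, "#", lin_key(p$frequency))

#' Build a perturbation multichain
#'
#' A perturbation multichain is a totally ordered multiset of
#' perturbations denoting a mixed partial derivative with respect to
#' their strengths: its length is the derivative order, the order of its
#' members fixes the shape of the derivative tensor, and perturbations
#' that compare equal must be consecutive (so `abbc` is valid but `abcb`
#' is not).
#'
#' @param perturbations A list of [perturbation()] objects (possibly
#'   empty: the order-0 derivative).
#' @return An object of class `"qr_multichain"`.
#' @export
multichain <- function(perturbations = list()) {
  if (inherits(perturbations, "qr_perturbation"))
    perturbations <- list(perturbations)
  stopifnot(all(vapply(perturbations, inherits, logical(1),
                       "qr_perturbation")))
  n <- length(perturbations)
  if (n > 1) {
    keys <- vapply(perturbations, pert_key, character(1))
    for (i in seq_len(n - 1)) {
      if (keys[i] %in% keys[-(1:i)] && keys[i + 1] != keys[i])
        stop("equal perturbations must be consecutive in a multichain ",
             "(offending label: ", perturbations[[i]]$label, ")")
    }
  }
  structure(list(items = perturbations), class = "qr_multichain")
}

mc_length <- function(mc) length(mc$items)

mc_labels <- function(mc) vapply(mc$items, `[[`, character(1), "label")

mc_key <- function(mc) paste(vapply(mc$items, pert_key, character(1)),
                             collapse = ",")

# Canonical (sorted) copy used as derivative-node storage: mixed partial
# derivatives commute, so derivative nodes are keyed on the sorted chain.
mc_sorted <- function(mc) {
  if (mc_length(mc) <= 1) return(mc)
  keys <- vapply(mc$items, pert_key, character(1))
  multichain(mc$items[order(keys)])
}

# Append one perturbation keeping the chain canonical (insert next to its
# equals, or at the sorted position).
mc_insert <- function(mc, p) mc_sorted(multichain(c(mc$items, list(p))))

# Count members of mc that belong to a given set of perturbations.
mc_count_in <- function(mc, perts) {
  keys <- vapply(perts, pert_key, character(1))
  sum(vapply(mc$items, function(q) pert_key(q) %in% keys, logical(1)))
}

#' @export
format.qr_multichain <- function(x, ...) {
  if (mc_length(x) == 0) return("<empty multichain>")
  paste0("<multichain ", paste(mc_labels(x), collapse = ""), ">")
}

#' @export
print.qr_multichain <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Shape of the derivative tensor denoted by a multichain
#'
#' @param mc A [multichain()].
#' @return Integer vector: `shape[i]` is the component count of the i-th
#'   perturbation; the empty multichain gives a zero-length vector.
#' @export
tensor_shape <- function(mc) {
  vapply(mc$items, function(p) p$n_components, integer(1))
}

#' Sum of the frequencies carried by a multichain
#'
#' @param mc A [multichain()].
#' @return The exact (symbolic) frequency sum as a linear form; the empty
#'   multichain sums to zero.
#' @export
sum_frequencies <- function(mc) {
  acc <- lin_zero()
  for (p in mc$items) acc <- lin_add(acc, p$frequency)
  acc
}

#' Set partitions of the index chain \{1, ..., n\}
#'
#' Enumerates the partitions of the perturbation index chain into
#' nonempty, pairwise disjoint blocks whose union is the whole chain;
#' these drive the higher-order product rule for derivatives of products.
#'
#' @param n Chain length (positive integer).
#' @param k Optional: restrict to partitions with exactly `k` blocks.
#' @return A list of partitions; each partition is a list of strictly
#'   increasing integer vectors (the blocks), ordered by smallest element.
#' @export
set_partitions <- function(n, k = NULL) {
  stopifnot(n >= 1)
  if (!is.null(k) && (k < 1 || k > n)) stop("k must satisfy 1 <= k <= n")
  # Restricted growth strings: element i joins block a[i] with
  # a[i] <= 1 + max(a[1..i-1]).
  out <- list()
  recurse <- function(a, mx) {
    i <- length(a) + 1L
    if (i > n) {
      nb <- mx
      if (!is.null(k) && nb != k) return()
      blocks <- lapply(seq_len(nb), function(b) which(a == b))
      out[[length(out) + 1L]] <<- blocks
      return()
    }
    for (b in seq_len(mx + 1L)) recurse(c(a, b), max(mx, b))
  }
  recurse(integer(0), 0L)
  out
}

#' Check that extensive and intensive perturbations are disjoint
#'
#' A perturbation must not be classified as both extensive and intensive;
#' the elimination rules are applied over the extensive set only.
#'
#' @param extensive,intensive Lists of [perturbation()] objects.
#' @return Invisibly `TRUE`; signals an error naming the offending
#'   perturbation on overlap.
#' @export
validate_disjoint <- function(extensive, intensive) {
  ek <- vapply(extensive, pert_key, character(1))
  ik <- vapply(intensive, pert_key, character(1))
  both <- intersect(ek, ik)
  if (length(both)) {
    lab <- sub("#.*$", "", both[1])
    stop("perturbation '", lab, "' is classified as both extensive and ",
         "intensive")
  }
  invisible(TRUE)
}
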