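# Isotopic envelope computation by iterated convolution of per-atom
# isotope distributions.

#' Standard elemental isotope table
#'
#' Monoisotopic-first (mass, abundance) pairs for the elements of organic
#' molecules (C, H, N, O, S).
#'
#' @return Named list; each element is a data frame with columns `mass`
#'   (Da) and `abundance` (summing to 1).
#' @export
elemental_isotopes <- function() {
  list(
    C = data.frame(mass = c(12, 13.0033548378), abundance = c(0.9893, 0.0107)),
    H = data.frame(mass = c(1.0078250319, 2.0141017780), abundance = c(0.999885, 0.000115)),
    N = data.frame(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99632, 0.00368)),
    O = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                   abundance = c(0.99757, 0.00038, 0.00205)),
    S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                   abundance = c(0.9493, 0.0076, 0.0429, 0.0002))
  )
}

new_isotope_pattern <- function(grid, intensity) {
  structure(list(grid = grid, intensity = intensity), class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("Isotope pattern:", length(x$grid), "peaks,",
      sprintf("m/z %.4f - %.4f, total %.4g\n",
              min(x$grid), max(x$grid), sum(x$intensity)))
  invisible(x)
}

# convolve two (mass, p) peak lists and merge peaks closer than merge_tol
convolve_peaks <- function(a, b, merge_tol) {
  mass <- outer(a$mass, b$mass, `+`)
  p <- outer(a$p, b$p, `*`)
  merge_peaks(data.frame(mass = as.vector(mass), p = as.vector(p)), merge_tol)
}

merge_peaks <- function(d, merge_tol) {
  o <- order(d$mass)
  m <- d$mass[o]; p <- d$p[o]
  grp <- cumsum(c(TRUE, diff(m) > merge_tol))
  data.frame(mass = as.vector(tapply(m * p, grp, sum) / tapply(p, grp, sum)),
             p = as.vector(tapply(p, grp, sum)))
}

#' Isotopic ion distribution of an elemental composition
#'
#' Computes the in-silico isotopic envelope of a molecule by iterated
#' convolution of the per-atom isotope distributions, with pruning of
#' negligible peaks.
#'
#' @param composition Named integer vector of atom counts, e.g.
#'   `c(C = 6, H = 13, N = 2)`.
#' @param isotope_table Per-element isotope masses/abundances as returned by
#'   [elemental_isotopes()].
#' @param prune Relative intensity below which peaks are dropped after each
#'   convolution (default 1e-8); the final pattern is renormalised to unit
#'   total intensity.
#' @param merge_tol Peaks closer than this (Da) are merged (default 1e-3).
#' @return An `isotope_pattern`: list with `grid` (masses, Da) and
#'   `intensity` (unit total).
#' @examples
#' isotopic_pattern(c(C = 2))  # carbon-2 envelope
#' @export
isotopic_pattern <- function(composition, isotope_table = elemental_isotopes(),
                             prune = 1e-8, merge_tol = 1e-3) {
  stopifnot(prune >= 0, length(composition) >= 1)
  unknown <- setdiff(names(composition), names(isotope_table))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (el in names(composition)) {
    ab <- isotope_table[[el]]$abundance
    if (abs(sum(ab) - 1) > 1e-6) {
      stop("isotope abundances for ", el, " do not sum to 1", call. = FALSE)
    }
  }
  acc <- data.frame(mass = 0, p = 1)
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    atom <- data.frame(mass = isotope_table[[el]]$mass,
                       p = isotope_table[[el]]$abundance)
    # binary exponentiation of the per-atom distribution
    pow <- atom
    acc_el <- NULL
    k <- n
    while (k > 0) {
      if (k %% 2 == 1) {
        acc_el <- if (is.null(acc_el)) pow else convolve_peaks(acc_el, pow, merge_tol)
        acc_el <- acc_el[acc_el$p > prune * max(acc_el$p), , drop = FALSE]
      }
      k <- k %/% 2
      if (k > 0) {
        pow <- convolve_peaks(pow, pow, merge_tol)
        pow <- pow[pow$p > prune * max(pow$p), , drop = FALSE]
      }
    }
    acc <- convolve_peaks(acc, acc_el, merge_tol)
    acc <- acc[acc$p > prune * max(acc$p), , drop = FALSE]
  }
  acc <- acc[order(acc$mass), , drop = FALSE]
  new_isotope_pattern(grid = acc$mass, intensity = acc$p / sum(acc$p))
}
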