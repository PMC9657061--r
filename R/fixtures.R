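#' Reference finite-size theta series (chains of 10--27 steps)
#'
#' Published finite-size crossing temperatures \eqn{T^*(N)} for the ISAW on
#' the simple cubic lattice, obtained from exact enumeration up to 27 steps
#' and rounded to four decimals. They let the extrapolation stack run without
#' any enumeration cost; the package regenerates the small-N entries exactly
#' (see [crossing_series()]). Note that four-decimal rounding limits how
#' faithfully deep extrapolation tableaus built on these values can be
#' reproduced (see the methods vignette).
#'
#' @param correction \code{"none"} for the plain crossing equation,
#'   \code{"log"} for the renormalisation-group log-corrected variant.
#' @return A \code{"crossing_series"} tibble with columns \code{n},
#'   \code{t_star}, \code{parity}, \code{correction}: odd \eqn{N} 11--25 and
#'   even \eqn{N} 12--26.
#' @examples
#' reference_t_star()
#' scan_best(scan_omega(reference_t_star(), seq(0.5, 1.5, 0.001)))
#' @export
reference_t_star <- function(correction = c("none", "log")) {
  correction <- match.arg(correction)
  t_star <- if (correction == "none") {
    c(2.3826, 2.3710, 2.4961, 2.4889, 2.5904, 2.5860, 2.6697, 2.6670,
      2.7375, 2.7358, 2.7962, 2.7951, 2.8474, 2.8468, 2.8926, 2.8923)
  } else {
    c(2.5421, 2.5112, 2.6345, 2.6137, 2.7135, 2.6989, 2.7811, 2.7705,
      2.8396, 2.8316, 2.8907, 2.8845, 2.9356, 2.9307, 2.9754, 2.9715)
  }
  n <- as.integer(11:26)
  out <- tibble(
    n = n, t_star = t_star,
    parity = ifelse(n %% 2 == 1, "odd", "even"),
    correction = correction
  )
  class(out) <- c("crossing_series", class(out))
  out
}

#' Reference crossover-exponent series
#'
#' Published finite-size crossover exponents \eqn{\phi(N)} from the
#' derivative-ratio method at \eqn{T_\theta = 3.713}, for the same 10--27
#' step enumeration as [reference_t_star()].
#'
#' @return A \code{"phi_series"} tibble with columns \code{n}, \code{phi},
#'   \code{parity}, \code{t_theta}.
#' @examples
#' reference_phi()
#' @export
reference_phi <- function() {
  n <- as.integer(11:26)
  phi <- c(0.8944, 0.8107, 0.8350, 0.7753, 0.7936, 0.7485, 0.7628, 0.7271,
           0.7387, 0.7097, 0.7192, 0.6951, 0.7032, 0.6826, 0.6896, 0.6719)
  out <- tibble(
    n = n, phi = phi,
    parity = ifelse(n %% 2 == 1, "odd", "even"),
    t_theta = 3.713
  )
  class(out) <- c("phi_series", class(out))
  out
}
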