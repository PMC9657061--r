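#' Contact polynomials of an ISAW chain
#'
#' Collapses the density of states \eqn{c_{m,R^2}} into the two exact
#' integer-coefficient polynomials in the contact fugacity \eqn{x = e^{1/T}}:
#' the partition function \eqn{Z_N(x) = \sum_m c_m x^m} with
#' \eqn{c_m = \sum_{R^2} c_{m,R^2}}, and the end-to-end weight polynomial
#' \eqn{R^2_N(x) = \sum_m (\sum_{R^2} R^2 c_{m,R^2})\, x^m}.
#'
#' @param table A \code{"coef_table"} tibble from [enumerate_isaw()] (or read
#'   back with [read_coef_table()]).
#' @return A tibble of class \code{"isaw_poly"} with one row per contact
#'   number \code{m} and columns \code{z} (\eqn{c_m}) and \code{r2w}
#'   (\eqn{\sum R^2 c_{m,R^2}}); attribute \code{n_steps}.
#' @examples
#' contact_polynomials(enumerate_isaw(4))  # z = (89, 32), r2w = (592, 80)
#' @export
contact_polynomials <- function(table) {
  if (nrow(table) == 0) abort("empty coefficient table.")
  n <- attr(table, "n_steps")
  if (is.null(n)) abort("`table` lacks an n_steps attribute; not a coef_table?")
  agg <- dplyr::summarise(table,
                          z = sum(.data$count),
                          r2w = sum(.data$r2 * .data$count),
                          .by = "m") |>
    dplyr::arrange(.data$m)
  # the contact spectrum can have gaps just below the maximum (e.g. no
  # 8-contact 11-step walk exists although 9-contact ones do); absent
  # contact numbers get zero coefficients
  ms <- seq(0L, max(agg$m))
  z <- r2w <- numeric(length(ms))
  z[agg$m + 1L] <- agg$z
  r2w[agg$m + 1L] <- agg$r2w
  out <- tibble(m = ms, z = z, r2w = r2w)
  attr(out, "n_steps") <- as.integer(n)
  class(out) <- c("isaw_poly", class(out))
  out
}

#' @export
print.isaw_poly <- function(x, ...) {
  cat(sprintf("ISAW contact polynomials, N = %d steps, max contacts M = %d\n",
              attr(x, "n_steps"), max(x$m)))
  NextMethod()
}

poly_n_steps <- function(poly) {
  n <- attr(poly, "n_steps")
  if (is.null(n)) abort("polynomial lacks an n_steps attribute.")
  n
}

#' Mean-square end-to-end distance at temperature T
#'
#' Evaluates \eqn{\langle R^2 \rangle_N(T) = R^2_N(x) / Z_N(x)} with
#' \eqn{x = e^{1/T}} by Horner's scheme on the exact coefficients.
#'
#' @param poly An \code{"isaw_poly"} tibble from [contact_polynomials()].
#' @param temp Temperature(s) in units of \eqn{\epsilon/k_B}; must be > 0.
#' @param extended Use the extended-precision (long double) evaluation path;
#'   the default double-precision path agrees to well below 1e-12 relative.
#' @return Numeric vector of \eqn{\langle R^2 \rangle} values, one per
#'   temperature.
#' @examples
#' p4 <- contact_polynomials(enumerate_isaw(4))
#' mean_square_r(p4, 1)  # (80 e + 592) / (32 e + 89)
#' @export
mean_square_r <- function(poly, temp, extended = FALSE) {
  check_temp(temp)
  x <- exp(1 / temp)
  horner <- if (extended) {
    function(cf, xx) vapply(xx, function(v) .horner_ld(cf, v), double(1))
  } else {
    function(cf, xx) vapply(xx, function(v) {
      acc <- 0
      for (c in rev(cf)) acc <- acc * v + c
      acc
    }, double(1))
  }
  horner(poly$r2w, x) / horner(poly$z, x)
}

#' Root-mean-square end-to-end distance
#'
#' @inheritParams mean_square_r
#' @return \eqn{R_N(T) = \sqrt{\langle R^2 \rangle_N(T)}}.
#' @export
rms_r <- function(poly, temp, extended = FALSE) {
  sqrt(mean_square_r(poly, temp, extended = extended))
}

#' Temperature log-derivative of the end-to-end distance
#'
#' Analytic derivative \eqn{d \log R_N / dT}, computed from the exact
#' polynomial derivatives (no numerical differencing):
#' \deqn{\frac{d \log R_N}{dT} = \frac{1}{2}\,\frac{dx}{dT}
#'   \left[\frac{P'(x)}{P(x)} - \frac{Z'(x)}{Z(x)}\right],\qquad
#'   \frac{dx}{dT} = -\frac{x}{T^2},}
#' with \eqn{P = R^2_N}. This is the quantity whose finite-size ratio yields
#' the crossover exponent \eqn{\phi}.
#'
#' @inheritParams mean_square_r
#' @return Numeric vector of derivatives, one per temperature.
#' @export
dlog_r_dT <- function(poly, temp) {
  check_temp(temp)
  x <- exp(1 / temp)
  dxdT <- -x / temp^2
  vapply(seq_along(x), function(i) {
    lp <- poly_logderiv(poly$r2w, x[i])
    lz <- poly_logderiv(poly$z, x[i])
    0.5 * dxdT[i] * (lp - lz)
  }, double(1))
}

# P'(x)/P(x) for coefficient vector cf (index m = 0..M)
poly_logderiv <- function(cf, x) {
  m <- seq_along(cf) - 1
  dcf <- (cf * m)[-1]
  p <- 0; for (c in rev(cf)) p <- p * x + c
  if (length(dcf) == 0) return(0)
  dp <- 0; for (c in rev(dcf)) dp <- dp * x + c
  dp / p
}

check_temp <- function(temp) {
  if (!is.numeric(temp) || length(temp) < 1 || any(!is.finite(temp)) ||
      any(temp <= 0))
    abort("`temp` must be positive and finite (units of epsilon/k_B).")
  invisible(temp)
}
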