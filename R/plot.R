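#' Plot a finite-size crossing or crossover series
#'
#' Displays \eqn{T^*(N)} (or \eqn{\phi(N)}) against chain length, coloured by
#' parity; the two parity branches converge toward the infinite-chain limit.
#'
#' @param object A \code{"crossing_series"} or \code{"phi_series"} tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossing_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$t_star,
                                       colour = .data$parity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "chain length N (steps)",
                  y = expression(T^"*" * (N) ~ "(" * epsilon / k[B] * ")"),
                  colour = "parity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crossing_series
#' @export
autoplot.phi_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$phi,
                                       colour = .data$parity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "chain length N (steps)", y = expression(phi(N)),
                  colour = "parity") +
    ggplot2::theme_minimal()
}

#' Plot an omega scan
#'
#' Combined parity error of the extrapolation against the scaling exponent
#' \eqn{\omega}, with the error-minimising \eqn{\omega} marked.
#'
#' @param object An \code{"omega_scan"} tibble from [scan_omega()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omega_scan <- function(object, ...) {
  best <- scan_best(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$omega, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best$omega, linetype = "dashed") +
    ggplot2::labs(x = expression(omega), y = "combined parity error") +
    ggplot2::theme_minimal()
}

#' Plot the normalised end-to-end distance against temperature
#'
#' Curves of \eqn{R_N(T)/N} for one or more chains; near the theta
#' temperature the curves for different \eqn{N} intersect.
#'
#' @param polys List of \code{"isaw_poly"} objects (or a single one).
#' @param temps Temperature grid.
#' @return A ggplot object.
#' @export
plot_end_to_end <- function(polys, temps = seq(1, 10, length.out = 200)) {
  if (inherits(polys, "isaw_poly")) polys <- list(polys)
  df <- purrr::map_dfr(polys, function(p) {
    n <- poly_n_steps(p)
    tibble(n = factor(n), temp = temps, r_per_step = rms_r(p, temps) / n)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temp, y = .data$r_per_step,
                                   colour = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(T ~ "(" * epsilon / k[B] * ")"),
                  y = expression(R[N](T) / N), colour = "N") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
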