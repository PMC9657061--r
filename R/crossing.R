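#' Residual of the finite-size crossing equation
#'
#' The finite-size theta estimator \eqn{T^*(N)} solves
#' \eqn{\langle R^2\rangle_{N+1}(T)/D(N+1) = \langle R^2\rangle_{N-1}(T)/D(N-1)}
#' for chains of the same parity two steps apart. With \code{correction =
#' "none"} the per-step normalisation is \eqn{D(n) = n}; with
#' \code{correction = "log"} it carries the field-theoretic logarithmic
#' factor \eqn{D(n) = n\,(1 - 37/(363 \ln n))}.
#'
#' @param poly_hi,poly_lo \code{"isaw_poly"} objects for chain lengths
#'   \eqn{N+1} and \eqn{N-1} (same parity, difference exactly 2).
#' @param temp Temperature(s), \eqn{\epsilon/k_B}.
#' @param correction \code{"none"} or \code{"log"}.
#' @return Numeric residual(s); zero at the crossing temperature.
#' @export
crossing_residual <- function(poly_hi, poly_lo, temp,
                              correction = c("none", "log")) {
  correction <- match.arg(correction)
  n_hi <- poly_n_steps(poly_hi)
  n_lo <- poly_n_steps(poly_lo)
  if (n_hi - n_lo != 2L)
    abort("`poly_hi` must be exactly two steps longer than `poly_lo`.")
  mean_square_r(poly_hi, temp) / step_norm(n_hi, correction) -
    mean_square_r(poly_lo, temp) / step_norm(n_lo, correction)
}

step_norm <- function(n, correction) {
  if (correction == "log") n * (1 - 37 / (363 * log(n))) else n
}

#' Solve for a finite-size theta temperature
#'
#' Locates the unique sign change of [crossing_residual()] inside the
#' bracket (a 200-point scan guards against missing or multiple crossings)
#' and refines it with Brent's method to the requested tolerance.
#'
#' @inheritParams crossing_residual
#' @param bracket Numeric length-2 search interval in temperature.
#' @param tol Absolute tolerance on \eqn{T^*}.
#' @return The crossing temperature \eqn{T^*} (full precision).
#' @examples
#' \donttest{
#' p10 <- contact_polynomials(enumerate_isaw(10))
#' p12 <- contact_polynomials(enumerate_isaw(12))
#' solve_t_star(p12, p10)  # T*(11) = 2.3826...
#' }
#' @export
solve_t_star <- function(poly_hi, poly_lo, correction = c("none", "log"),
                         bracket = c(0.5, 20), tol = 1e-10) {
  correction <- match.arg(correction)
  if (length(bracket) != 2 || bracket[1] <= 0 || bracket[2] <= bracket[1])
    abort("`bracket` must be an increasing pair of positive temperatures.")
  f <- function(T) crossing_residual(poly_hi, poly_lo, T, correction)
  grid <- seq(bracket[1], bracket[2], length.out = 200)
  vals <- f(grid)
  flips <- which(diff(sign(vals)) != 0)
  if (length(flips) == 0)
    abort("no crossing: the residual does not change sign in the bracket.")
  if (length(flips) > 1)
    abort("ambiguous crossing: multiple sign changes detected in the bracket.")
  uniroot(f, lower = grid[flips], upper = grid[flips + 1],
          tol = tol, check.conv = TRUE)$root
}

#' Finite-size theta series split by parity
#'
#' Computes \eqn{T^*(N)} for every \eqn{N} in \code{n_min:n_max} whose
#' neighbours \eqn{N \pm 1} are available, and labels each estimate by the
#' parity of \eqn{N}. Odd- and even-step walks terminate on disjoint
#' sublattices of the simple cubic lattice and form two distinct finite-size
#' series that are extrapolated separately.
#'
#' @param tables Named list of \code{"coef_table"} objects (names are chain
#'   lengths) or \code{"isaw_poly"} objects.
#' @param n_min,n_max Integer range of central chain lengths \eqn{N};
#'   defaults span whatever the supplied tables allow.
#' @param correction Passed to [crossing_residual()].
#' @param bracket Temperature bracket for the root search. The default
#'   \code{c(1, 20)} spans the theta region; same-parity pairs can have a
#'   second, collapsed-phase crossing below \eqn{T \approx 0.5} which the
#'   narrower bracket excludes.
#' @param ... Passed to [solve_t_star()] (e.g. \code{tol}).
#' @return A tibble of class \code{"crossing_series"} with columns
#'   \code{n}, \code{t_star}, \code{parity} (\code{"odd"}/\code{"even"}) and
#'   \code{correction}, sorted by \code{n}.
#' @export
crossing_series <- function(tables, n_min = NULL, n_max = NULL,
                            correction = c("none", "log"),
                            bracket = c(1, 20), ...) {
  correction <- match.arg(correction)
  polys <- as_poly_list(tables)
  avail <- as.integer(names(polys))
  explicit <- !is.null(n_min) || !is.null(n_max)
  if (is.null(n_min)) n_min <- min(avail) + 1L
  if (is.null(n_max)) n_max <- max(avail) - 1L
  centers <- if (n_max < n_min) integer(0) else seq(n_min, n_max)
  if (explicit && length(centers) > 0) {
    need <- setdiff(c(centers - 1L, centers + 1L), avail)
    if (length(need) > 0)
      abort(sprintf("missing coefficient tables for N = %s",
                    paste(sort(unique(need)), collapse = ", ")))
  }
  centers <- centers[(centers - 1) %in% avail & (centers + 1) %in% avail]
  t_star <- vapply(centers, function(n) {
    solve_t_star(polys[[as.character(n + 1)]], polys[[as.character(n - 1)]],
                 correction = correction, bracket = bracket, ...)
  }, double(1))
  out <- tibble(
    n = centers,
    t_star = t_star,
    parity = ifelse(centers %% 2 == 1, "odd", "even"),
    correction = correction
  )
  class(out) <- c("crossing_series", class(out))
  out
}

as_poly_list <- function(tables) {
  if (inherits(tables, "isaw_poly") || inherits(tables, "coef_table"))
    tables <- list(tables)
  polys <- lapply(tables, function(t) {
    if (inherits(t, "isaw_poly")) t else contact_polynomials(t)
  })
  names(polys) <- vapply(polys, poly_n_steps, integer(1))
  polys
}
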