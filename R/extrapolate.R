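#' Neville or Bulirsch--Stoer extrapolation of a finite-size series
#'
#' Extrapolates finite-size estimates \eqn{T(N_i)} to \eqn{N \to \infty}
#' assuming a scaling variable \eqn{h_i = N_i^{-\omega}}. The Neville tableau
#' builds the interpolating polynomial in \eqn{h} and evaluates it at
#' \eqn{h = 0}:
#' \deqn{T_{i,j} = T_{i+1,j-1} + \frac{T_{i+1,j-1} - T_{i,j-1}}
#'   {(N_{i+j}/N_i)^{\omega} - 1}.}
#' The Bulirsch--Stoer variant inserts a correction factor that turns the
#' extrapolant into a rational function, with the pre-column
#' \eqn{T_{i,-1} = 0}:
#' \deqn{T_{i,j} = T_{i+1,j-1} + (T_{i+1,j-1} - T_{i,j-1})
#'   \left[\left(\frac{N_{i+j}}{N_i}\right)^{\omega}
#'   \left(1 - \frac{T_{i+1,j-1} - T_{i,j-1}}{T_{i+1,j-1} - T_{i,j-2}}\right)
#'   - 1\right]^{-1}.}
#' The quoted uncertainty is the difference of the two deepest subtableau
#' extrapolants, \eqn{\epsilon = |T_{0,k-2} - T_{1,k-2}|}.
#'
#' @param n Integer chain lengths \eqn{N_i}, strictly increasing.
#' @param value Finite-size estimates \eqn{T(N_i)}, same length as \code{n}.
#' @param omega Scaling exponent \eqn{\omega > 0} defining
#'   \eqn{h = N^{-\omega}}.
#' @param method \code{"bulirsch_stoer"} (rational, the default) or
#'   \code{"neville"} (polynomial).
#' @return An object of class \code{"isaw_extrap"}: a list with
#'   \code{value} (the \eqn{h = 0} extrapolant \eqn{T_{0,k-1}}),
#'   \code{error}, \code{method}, \code{omega}, \code{n}, \code{input}, and
#'   the full \code{tableau} (list of columns). [tidy()] returns the tableau
#'   as a tibble, [glance()] a one-row summary.
#' @examples
#' n <- seq(11, 25, 2)
#' extrapolate_series(n, 3.7 + 2 * n^-0.8, omega = 0.8)  # recovers 3.7
#' @export
extrapolate_series <- function(n, value, omega,
                               method = c("bulirsch_stoer", "neville")) {
  method <- match.arg(method)
  check_series(n, value)
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) || omega <= 0)
    abort("`omega` must be a single positive number.")
  cols <- tableau_columns(n, value, omega, method)
  k <- length(value)
  last <- cols[[k]]
  err <- if (k >= 2) abs(cols[[k - 1]][1] - cols[[k - 1]][2]) else NA_real_
  structure(
    list(value = last[1], error = err, method = method, omega = omega,
         n = n, input = value, tableau = cols),
    class = "isaw_extrap"
  )
}

# columns[[j+1]] holds T_{., j}; j = 0 is the input series
tableau_columns <- function(n, value, omega, method) {
  k <- length(value)
  cols <- vector("list", k)
  cols[[1]] <- value
  if (k == 1) return(cols)
  prev2 <- rep(0, k)       # T_{i,-1}
  for (j in seq_len(k - 1)) {
    cur <- cols[[j]]
    nxt <- double(k - j)
    for (i in seq_len(k - j)) {
      d1 <- cur[i + 1] - cur[i]
      ratio <- (n[i + j] / n[i])^omega
      if (method == "neville") {
        nxt[i] <- cur[i + 1] + d1 / (ratio - 1)
      } else {
        d2 <- cur[i + 1] - prev2[i]
        brk <- ratio * (1 - d1 / d2) - 1
        # continuity fallback: as the inner factor degenerates the rational
        # update tends to the polynomial one
        if (!is.finite(brk) || abs(d2) < 1e-300 || abs(brk) < 1e-300) {
          nxt[i] <- cur[i + 1] + d1 / (ratio - 1)
        } else {
          nxt[i] <- cur[i + 1] + d1 / brk
        }
      }
    }
    prev2 <- cur
    cols[[j + 1]] <- nxt
  }
  cols
}

# Neville tableau evaluated at arbitrary h (used to verify the interpolation
# property in tests); h_i = n_i^-omega.
neville_at <- function(n, value, omega, h) {
  hi <- n^-omega
  k <- length(value)
  cur <- value
  for (j in seq_len(k - 1)) {
    nxt <- double(k - j)
    for (i in seq_len(k - j)) {
      ratio <- (h - hi[i]) / (h - hi[i + j])
      nxt[i] <- cur[i + 1] + (cur[i + 1] - cur[i]) / (ratio - 1)
    }
    cur <- nxt
  }
  cur[1]
}

check_series <- function(n, value) {
  if (length(n) < 2) abort("need at least two points to extrapolate.")
  if (length(n) != length(value)) abort("`n` and `value` lengths differ.")
  if (anyDuplicated(n)) abort("duplicate chain lengths in `n`.")
  if (is.unsorted(n, strictly = TRUE))
    abort("`n` must be strictly increasing.")
  if (any(n < 1) || any(!is.finite(value)))
    abort("invalid series: n >= 1 and finite values required.")
  invisible(NULL)
}

#' @export
print.isaw_extrap <- function(x, ...) {
  cat(sprintf("%s extrapolation (omega = %g, %d points): %.6f +- %.6f\n",
              x$method, x$omega, length(x$n), x$value, x$error))
  invisible(x)
}

#' @rdname extrapolate_series
#' @param x,object An \code{"isaw_extrap"} object.
#' @param ... Unused.
#' @export
tidy.isaw_extrap <- function(x, ...) {
  purrr::imap_dfr(x$tableau, function(col, j) {
    tibble(i = seq_along(col) - 1L, j = j - 1L, t = col)
  })
}

#' @rdname extrapolate_series
#' @export
glance.isaw_extrap <- function(x, ...) {
  tibble(method = x$method, omega = x$omega, n_points = length(x$n),
         estimate = x$value, error = x$error)
}

#' Parity-paired omega scan
#'
#' For each \eqn{\omega} in a grid, extrapolates the odd- and even-parity
#' finite-size series separately and combines them: the theta estimate is
#' \eqn{(T_I + T_{II})/2} and the combined error
#' \eqn{\sqrt{\epsilon_I^2 + \epsilon_{II}^2}/2}. The best row minimises the
#' combined error (ties broken toward smaller \eqn{\omega}); requiring both
#' parity series to extrapolate consistently constrains \eqn{\omega} far more
#' tightly than a single series would.
#'
#' @param series A \code{"crossing_series"} tibble (or any tibble with
#'   columns \code{n}, \code{t_star} or \code{phi}, and \code{parity}
#'   containing both parities).
#' @param omegas Numeric grid of \eqn{\omega} values, sorted increasing.
#' @param method Extrapolation method, as in [extrapolate_series()].
#' @return A tibble of class \code{"omega_scan"} with columns \code{omega},
#'   \code{t_odd}, \code{t_even}, \code{mean}, \code{err_odd},
#'   \code{err_even}, \code{error}; the error-minimising row is stored in the
#'   \code{"best"} attribute (retrieve with [scan_best()]).
#' @examples
#' ref <- reference_t_star()
#' sc <- scan_omega(ref, seq(0.814, 0.825, 0.001))
#' scan_best(sc)
#' @export
scan_omega <- function(series, omegas, method = c("bulirsch_stoer", "neville")) {
  method <- match.arg(method)
  if (length(omegas) == 0 || any(!is.finite(omegas)) || any(omegas <= 0))
    abort("`omegas` must be a nonempty grid of positive values.")
  val_col <- if ("t_star" %in% names(series)) "t_star" else "phi"
  odd <- dplyr::filter(series, .data$parity == "odd") |> dplyr::arrange(.data$n)
  even <- dplyr::filter(series, .data$parity == "even") |> dplyr::arrange(.data$n)
  if (nrow(odd) == 0 || nrow(even) == 0)
    abort("`series` must contain both parities.")
  rows <- purrr::map_dfr(sort(omegas), function(om) {
    a <- extrapolate_series(odd$n, odd[[val_col]], om, method)
    b <- extrapolate_series(even$n, even[[val_col]], om, method)
    tibble(omega = om, t_odd = a$value, t_even = b$value,
           mean = (a$value + b$value) / 2,
           err_odd = a$error, err_even = b$error,
           error = sqrt(a$error^2 + b$error^2) / 2)
  })
  finite <- is.finite(rows$error) & is.finite(rows$mean)
  if (!any(finite)) abort("no finite extrapolants on this grid.")
  best_i <- which(finite)[which.min(rows$error[finite])]
  attr(rows, "best") <- rows[best_i, ]
  attr(rows, "method") <- method
  class(rows) <- c("omega_scan", class(rows))
  rows
}

#' @rdname scan_omega
#' @param scan An \code{"omega_scan"} tibble.
#' @export
scan_best <- function(scan) attr(scan, "best")

#' @rdname scan_omega
#' @param x An \code{"omega_scan"} object.
#' @param ... Unused.
#' @export
glance.omega_scan <- function(x, ...) {
  dplyr::mutate(scan_best(x), method = attr(x, "method"),
                .before = "omega")
}

#' Coarse-to-fine omega refinement
#'
#' Implements the scan protocol used throughout: a coarse grid over a wide
#' range, then repeated tenfold refinement of the grid around the current
#' error minimum until the requested resolution is reached.
#'
#' @inheritParams scan_omega
#' @param lower,upper Coarse scan range.
#' @param coarse_step Initial grid step.
#' @param final_step Target resolution of \eqn{\omega}.
#' @return The best \code{"omega_scan"} row at the final resolution (one-row
#'   tibble), with the final scan attached as attribute \code{"scan"}.
#' @export
refine_omega <- function(series, method = c("bulirsch_stoer", "neville"),
                         lower = 0.1, upper = 3.0,
                         coarse_step = 0.01, final_step = 1e-4) {
  method <- match.arg(method)
  step <- coarse_step
  lo <- lower; hi <- upper
  repeat {
    sc <- scan_omega(series, seq(lo, hi, by = step), method)
    best <- scan_best(sc)
    if (step <= final_step) {
      attr(best, "scan") <- sc
      return(best)
    }
    lo <- max(lower, best$omega - step)
    hi <- min(upper, best$omega + step)
    step <- step / 10
  }
}

#' Crossover-exponent series by the derivative ratio method
#'
#' Finite-size estimates of the crossover exponent \eqn{\phi} from the ratio
#' of temperature log-derivatives of the end-to-end distance at a fixed
#' theta temperature:
#' \deqn{\phi(N) = \frac{\log\left[(d\log R_{N+1}/dT) / (d\log R_{N-1}/dT)
#'   \right]_{T_\theta}}{\log[(N+1)/(N-1)]}.}
#' The ratio is invariant to whether the derivative uses \eqn{\log R} or
#' \eqn{\log \langle R^2 \rangle} (the factor 1/2 cancels).
#'
#' @param tables Named list of \code{"coef_table"} or \code{"isaw_poly"}
#'   objects covering the needed \eqn{N \pm 1}.
#' @param t_theta Fixed theta temperature at which derivatives are taken
#'   (default 3.713, \eqn{\epsilon/k_B}).
#' @param n_min,n_max Optional range of central \eqn{N}.
#' @return A tibble of class \code{"phi_series"} with columns \code{n},
#'   \code{phi}, \code{parity}, \code{t_theta}.
#' @export
phi_series <- function(tables, t_theta = 3.713, n_min = NULL, n_max = NULL) {
  if (!is.numeric(t_theta) || length(t_theta) != 1 || t_theta <= 0)
    abort("`t_theta` must be a single positive temperature.")
  polys <- as_poly_list(tables)
  avail <- as.integer(names(polys))
  if (is.null(n_min)) n_min <- min(avail) + 1L
  if (is.null(n_max)) n_max <- max(avail) - 1L
  centers <- if (n_max < n_min) integer(0) else seq(n_min, n_max)
  centers <- centers[(centers - 1) %in% avail & (centers + 1) %in% avail]
  phi <- vapply(centers, function(n) {
    d_hi <- dlog_r_dT(polys[[as.character(n + 1)]], t_theta)
    d_lo <- dlog_r_dT(polys[[as.character(n - 1)]], t_theta)
    if (!is.finite(d_hi) || !is.finite(d_lo) || d_hi / d_lo <= 0)
      abort(sprintf("nonpositive derivative ratio at N = %d.", n))
    log(d_hi / d_lo) / log((n + 1) / (n - 1))
  }, double(1))
  out <- tibble(
    n = centers, phi = phi,
    parity = ifelse(centers %% 2 == 1, "odd", "even"),
    t_theta = t_theta
  )
  class(out) <- c("phi_series", class(out))
  out
}
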