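#' Read and write coefficient tables as TSV
#'
#' The interchange format between enumeration and the downstream analysis:
#' \code{#}-prefixed header lines carry \code{n_steps}, \code{generator} and
#' \code{prefix_depth}, followed by tab-separated rows
#' \code{m<TAB>r2<TAB>count} with counts as full decimal integers, sorted by
#' \code{(m, r2)}. Round-trips are lossless.
#'
#' @param x A \code{"coef_table"} tibble.
#' @param path File path.
#' @return \code{write_coef_table()} returns \code{path} invisibly;
#'   \code{read_coef_table()} returns a \code{"coef_table"} tibble.
#' @export
write_coef_table <- function(x, path) {
  n <- attr(x, "n_steps")
  pd <- attr(x, "prefix_depth")
  header <- c(
    sprintf("# n_steps: %d", n),
    sprintf("# generator: %s", attr(x, "generator") %||% "unknown"),
    sprintf("# prefix_depth: %s", if (is.na(pd)) "NA" else pd)
  )
  rows <- sprintf("%d\t%d\t%s", x$m, x$r2,
                  format(x$count, scientific = FALSE, trim = TRUE))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_coef_table
#' @export
read_coef_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  n <- as.integer(get_field("n_steps"))
  if (is.na(n)) abort("missing '# n_steps:' header line.")
  pd <- suppressWarnings(as.integer(get_field("prefix_depth")))
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  if (ncol(parts) != 3) abort("malformed coefficient table rows.")
  new_coef_table(as.integer(parts[, 1]), as.integer(parts[, 2]),
                 as.numeric(parts[, 3]), n,
                 generator = get_field("generator"), prefix_depth = pd)
}

#' Read and write contact polynomials as JSON
#'
#' Serialises an \code{"isaw_poly"} object with coefficients as decimal
#' strings, preserving exact integer values.
#'
#' @param poly An \code{"isaw_poly"} tibble.
#' @param path File path.
#' @return \code{write_poly_json()} returns \code{path} invisibly;
#'   \code{read_poly_json()} the restored \code{"isaw_poly"}.
#' @export
write_poly_json <- function(poly, path) {
  obj <- list(
    n_steps = poly_n_steps(poly),
    z_coeffs = format(poly$z, scientific = FALSE, trim = TRUE),
    r2_coeffs = format(poly$r2w, scientific = FALSE, trim = TRUE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_poly_json
#' @export
read_poly_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(
    m = seq_along(obj$z_coeffs) - 1L,
    z = as.numeric(obj$z_coeffs),
    r2w = as.numeric(obj$r2_coeffs)
  )
  attr(out, "n_steps") <- as.integer(obj$n_steps)
  class(out) <- c("isaw_poly", class(out))
  out
}

#' Read and write crossing series as CSV
#'
#' Plain CSV with columns \code{parity,n,t_star,correction}, the interface
#' between the crossing solver and the extrapolation stage.
#'
#' @param series A \code{"crossing_series"} tibble.
#' @param path File path.
#' @return \code{write_crossing_series()} returns \code{path} invisibly;
#'   \code{read_crossing_series()} the restored tibble.
#' @export
write_crossing_series <- function(series, path) {
  readr::write_csv(series[, c("parity", "n", "t_star", "correction")], path)
  invisible(path)
}

#' @rdname write_crossing_series
#' @export
read_crossing_series <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    parity = readr::col_character(), n = readr::col_integer(),
    t_star = readr::col_double(), correction = readr::col_character()
  ))
  out <- out[, c("n", "t_star", "parity", "correction")]
  class(out) <- c("crossing_series", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
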