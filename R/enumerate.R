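#' Exact ISAW density of states by exhaustive enumeration
#'
#' Counts every \code{n_steps}-step interacting self-avoiding walk (ISAW) on
#' the simple cubic lattice, classified by the number of nonconsecutive
#' nearest-neighbour contacts \eqn{m} and the squared end-to-end distance
#' \eqn{R^2}. The first monomer sits at the origin and the second at
#' \eqn{(1,0,0)}, so totals are 1/6 of the free self-avoiding-walk count.
#' Beyond the fixed first step the remaining eightfold lattice symmetry is
#' removed by canonical orientation (the first step off the x axis must be
#' \eqn{+y}, the first step off the xy plane must be \eqn{+z}) and each
#' representative is weighted by its orbit size (1, 4 or 8).
#'
#' @param n_steps Integer chain length \eqn{N \ge 1} (number of steps; the
#'   walk has \eqn{N + 1} monomers).
#' @param prefix_depth Optional integer \eqn{\ge 2}. When supplied, the walk
#'   space is partitioned into independent prefix jobs of this depth (see
#'   [isaw_prefixes()]), each job is enumerated separately and the results are
#'   merged; the output is identical for every valid depth. The default
#'   enumerates in a single pass.
#' @return A tibble of class \code{"coef_table"} with integer columns \code{m}
#'   and \code{r2} and a \code{count} column (exact integers stored as
#'   doubles), sorted by \code{(m, r2)}. Attributes: \code{n_steps},
#'   \code{generator}, \code{prefix_depth}.
#' @examples
#' enumerate_isaw(4)              # 121 walks: Z_4(x) = 32 x + 89
#' enumerate_isaw(6, prefix_depth = 3)
#' @seealso [enumerate_isaw_naive()] for the independent brute-force oracle,
#'   [contact_polynomials()] for the derived polynomials.
#' @export
enumerate_isaw <- function(n_steps, prefix_depth = NULL) {
  n_steps <- check_n_steps(n_steps)
  if (is.null(prefix_depth)) {
    raw <- .enum_reduced(n_steps)
    return(new_coef_table(raw$m, raw$r2, raw$count, n_steps,
                          generator = "reduced", prefix_depth = NA_integer_))
  }
  prefix_depth <- check_count(prefix_depth, "prefix_depth", min = 2L)
  if (prefix_depth > n_steps)
    abort("`prefix_depth` must not exceed `n_steps`.")
  jobs <- isaw_prefixes(prefix_depth)
  parts <- purrr::map(jobs$sites, enumerate_prefix_job, n_steps = n_steps)
  out <- merge_coef_tables(parts, weights = jobs$multiplicity)
  attr(out, "generator") <- "reduced"
  attr(out, "prefix_depth") <- as.integer(prefix_depth)
  out
}

#' Brute-force enumeration oracle
#'
#' A deliberately naive, pure-R depth-first enumeration of all self-avoiding
#' walks with the fixed first step and no symmetry reduction; the contact
#' count of each completed walk is recomputed from scratch by scanning all
#' nonconsecutive monomer pairs. It shares no code with [enumerate_isaw()] and
#' exists as an independent cross-check; practical only for small chains.
#'
#' @param n_steps Integer chain length, \eqn{1 \le N \le 10}.
#' @return A \code{"coef_table"} tibble, same contract as [enumerate_isaw()].
#' @examples
#' identical(enumerate_isaw_naive(5)$count, enumerate_isaw(5)$count)
#' @export
enumerate_isaw_naive <- function(n_steps) {
  n_steps <- check_n_steps(n_steps)
  if (n_steps > 10)
    abort("the brute-force oracle is limited to n_steps <= 10")
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  counts <- new.env(parent = emptyenv())
  record <- function(sites) {
    n <- nrow(sites)
    m <- 0L
    for (i in seq_len(n - 2)) {
      for (j in (i + 2):n) {
        if (sum(abs(sites[i, ] - sites[j, ])) == 1L) m <- m + 1L
      }
    }
    r2 <- sum(sites[n, ]^2)
    key <- paste(m, r2)
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  grow <- function(sites) {
    if (nrow(sites) == n_steps + 1L) {
      record(sites)
      return(invisible())
    }
    last <- sites[nrow(sites), ]
    for (d in seq_len(6)) {
      nxt <- last + dirs[d, ]
      clash <- any(rowSums(abs(sites - matrix(nxt, nrow(sites), 3,
                                              byrow = TRUE))) == 0L)
      if (!clash) grow(rbind(sites, nxt))
    }
  }
  grow(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)))
  keys <- ls(counts)
  parts <- do.call(rbind, lapply(keys, function(k) {
    mr <- as.integer(strsplit(k, " ")[[1]])
    c(mr, counts[[k]])
  }))
  new_coef_table(parts[, 1], parts[, 2], parts[, 3], n_steps,
                 generator = "bruteforce", prefix_depth = NA_integer_)
}

#' Canonical walk prefixes for parallel decomposition
#'
#' Lists one representative walk prefix per symmetry orbit at the requested
#' depth, together with its orbit multiplicity (1 for the straight rod on the
#' x axis, 4 for prefixes confined to the xy plane, 8 otherwise). Completing
#' every prefix with [enumerate_prefix_job()] and merging with these weights
#' reproduces [enumerate_isaw()] exactly; the 22 depth-4 prefixes are the
#' classic parallel split of the 4-step enumeration.
#'
#' @param depth Integer prefix length \eqn{\ge 2}.
#' @return A tibble of class \code{"prefix_jobs"} with columns \code{job}
#'   (integer id), \code{multiplicity}, and \code{sites} (list of
#'   \eqn{(depth+1) \times 3} integer coordinate matrices).
#' @examples
#' nrow(isaw_prefixes(4))  # 22 representative 4-step prefixes
#' @export
isaw_prefixes <- function(depth) {
  depth <- check_count(depth, "depth", min = 2L)
  raw <- .list_prefixes(depth)
  out <- tibble(
    job = seq_along(raw),
    multiplicity = purrr::map_int(raw, "multiplicity"),
    sites = purrr::map(raw, "sites")
  )
  class(out) <- c("prefix_jobs", class(out))
  attr(out, "depth") <- as.integer(depth)
  out
}

#' Complete one prefix job
#'
#' Enumerates all \code{n_steps}-step walks extending a fixed prefix, with
#' counts weighted relative to the prefix's symmetry class, so that
#' multiplying by the prefix multiplicity and summing across jobs gives the
#' full reduced table.
#'
#' @param sites Integer matrix of prefix coordinates (rows are monomers,
#'   starting \code{(0,0,0)}, \code{(1,0,0)}), as produced by
#'   [isaw_prefixes()].
#' @param n_steps Total chain length to complete to.
#' @return A \code{"coef_table"} tibble for this job.
#' @export
enumerate_prefix_job <- function(sites, n_steps) {
  n_steps <- check_n_steps(n_steps)
  sites <- as.matrix(sites)
  storage.mode(sites) <- "integer"
  raw <- .enum_from_prefix(sites, n_steps)
  new_coef_table(raw$m, raw$r2, raw$count, n_steps,
                 generator = "prefix_job", prefix_depth = nrow(sites) - 1L)
}

#' Merge per-job coefficient tables
#'
#' Entrywise weighted integer sum of coefficient tables sharing a chain
#' length, used to collect parallel prefix jobs into the full density of
#' states.
#'
#' @param tables List of \code{"coef_table"} tibbles with a common
#'   \code{n_steps}.
#' @param weights Numeric vector of job weights (recycled if length 1).
#' @return A merged \code{"coef_table"} tibble.
#' @examples
#' jobs <- isaw_prefixes(2)
#' parts <- lapply(jobs$sites, enumerate_prefix_job, n_steps = 5)
#' merged <- merge_coef_tables(parts, jobs$multiplicity)
#' identical(merged$count, enumerate_isaw(5)$count)
#' @export
merge_coef_tables <- function(tables, weights = 1) {
  if (length(tables) == 0) abort("`tables` must be a nonempty list.")
  ns <- vapply(tables, function(t) attr(t, "n_steps"), integer(1))
  if (length(unique(ns)) != 1L)
    abort("all tables must share the same `n_steps` to be merged.")
  weights <- rep_len(weights, length(tables))
  stacked <- purrr::map2(tables, weights, function(t, w) {
    tibble(m = t$m, r2 = t$r2, count = t$count * w)
  })
  summed <- dplyr::bind_rows(stacked) |>
    dplyr::summarise(count = sum(.data$count), .by = c("m", "r2"))
  new_coef_table(summed$m, summed$r2, summed$count, ns[[1]],
                 generator = "merged", prefix_depth = NA_integer_)
}

# ---- constructor / validation ------------------------------------------------

new_coef_table <- function(m, r2, count, n_steps, generator, prefix_depth) {
  out <- tibble(m = as.integer(m), r2 = as.integer(r2), count = as.double(count))
  out <- dplyr::arrange(out, .data$m, .data$r2)
  attr(out, "n_steps") <- as.integer(n_steps)
  attr(out, "generator") <- generator
  attr(out, "prefix_depth") <- prefix_depth
  class(out) <- c("coef_table", class(out))
  validate_coef_table(out)
}

validate_coef_table <- function(x) {
  n <- attr(x, "n_steps")
  if (any(x$count < 0) || any(x$count != round(x$count)))
    abort("counts must be nonnegative integers.")
  if (any(x$count >= 2^53))
    abort("counts exceed exact double-precision integer range (2^53).")
  if (any(x$m < 0) || any(x$r2 < 1) || any(x$r2 > n^2))
    abort("(m, r2) keys out of range: need m >= 0 and 1 <= r2 <= N^2.")
  if (any((x$r2 - n) %% 2 != 0))
    abort("lattice parity violated: every r2 must have the parity of N.")
  x
}

#' @export
print.coef_table <- function(x, ...) {
  n <- attr(x, "n_steps")
  cat(sprintf("ISAW density of states: N = %d steps, %d (m, r2) classes, %s walks\n",
              n, nrow(x), format(sum(x$count), big.mark = ",", scientific = FALSE)))
  NextMethod()
}

# ---- shared input checks -----------------------------------------------------

check_n_steps <- function(n_steps) {
  check_count(n_steps, "n_steps", min = 1L)
}

check_count <- function(x, name, min) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  as.integer(x)
}
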