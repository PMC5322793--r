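#' Single-cell event table
#'
#' The data model for distribution-valued measurements: for each
#' measurement time, the list of per-cell observable values (arbitrary
#' fluorescence units).
#'
#' @param times numeric measurement times (minutes), strictly increasing.
#' @param values list with one numeric vector per time point; every time
#'   point needs at least two finite values.
#' @return An object of class `event_table` with fields `times`, `values`
#'   and per-time sample sizes `nm`.
#' @export
event_table <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  values <- lapply(values, as.numeric)
  nm <- vapply(values, length, integer(1))
  if (any(nm < 2L))
    stop("every time point needs at least 2 cells", call. = FALSE)
  if (any(!vapply(values, function(v) all(is.finite(v)), logical(1))))
    stop("event values must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = values, nm = nm),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d time points\n", length(x$times)))
  for (i in seq_along(x$times))
    cat(sprintf("  t = %g min: %d cells, median %.4g a.u.\n", x$times[i],
                x$nm[i], stats::median(x$values[[i]])))
  invisible(x)
}

#' Square-root bin-count rule
#'
#' `L = round(sqrt(nm))`, floored at 2 bins; the default binning rule for
#' single-cell histograms.
#'
#' @param nm sample size (>= 2).
#' @return Integer number of bins.
#' @export
bin_count <- function(nm) {
  if (!is.numeric(nm) || length(nm) != 1L || nm < 2)
    stop("nm must be a single number >= 2", call. = FALSE)
  max(2L, as.integer(round(sqrt(nm))))
}

#' Binned probability density functions
#'
#' Builds per-time-point normalized histograms (probability mass per bin,
#' summing to one) on a common number of bins. Edges default to `L`
#' equal-width bins spanning the data range at each time point; when an
#' explicit edge set is supplied (to evaluate simulated data on the
#' measured reference grid), values outside the range are clipped into
#' the terminal bins. A time point with zero range yields a single
#' degenerate bin carrying mass one, flagged in the result.
#'
#' @param x an [event_table()] or a list of numeric vectors.
#' @param L number of bins (>= 2); default, square-root rule on the
#'   smallest per-time sample size.
#' @param edges optional list of per-time edge vectors to reuse (from a
#'   reference `binned_pdf`).
#' @param times measurement times when `x` is a bare list.
#' @return An object of class `binned_pdf`: per time point `edges`,
#'   `centers`, `mass`, plus `L` and `times`.
#' @export
build_distributions <- function(x, L = NULL, edges = NULL, times = NULL) {
  if (inherits(x, "event_table")) {
    values <- x$values
    times <- x$times
  } else {
    values <- lapply(x, as.numeric)
    if (is.null(times)) times <- seq_along(values)
  }
  if (is.null(L)) L <- bin_count(min(vapply(values, length, integer(1))))
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2", call. = FALSE)
  bins <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    if (!is.null(edges)) {
      e <- edges[[i]]
      if (length(e) != L + 1L)
        stop("supplied edges do not match L", call. = FALSE)
      v <- pmin(pmax(v, e[1]), e[length(e)])   # clip into terminal bins
      cnt <- .bincount(v, e)
      bins[[i]] <- list(edges = e, centers = (e[-1] + e[-length(e)]) / 2,
                        mass = cnt / length(v), degenerate = FALSE)
    } else {
      rng <- range(v)
      if (rng[1] == rng[2]) {
        bins[[i]] <- list(edges = c(rng[1] - 0.5, rng[1] + 0.5),
                          centers = rng[1], mass = 1, degenerate = TRUE)
      } else {
        e <- seq(rng[1], rng[2], length.out = L + 1L)
        cnt <- .bincount(v, e)
        bins[[i]] <- list(edges = e, centers = (e[-1] + e[-length(e)]) / 2,
                          mass = cnt / length(v), degenerate = FALSE)
      }
    }
  }
  structure(list(bins = bins, L = L, times = as.numeric(times)),
            class = "binned_pdf")
}

# histogram counts with right-closed last bin
.bincount <- function(v, e) {
  idx <- findInterval(v, e, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(e) - 1L)
}

#' @export
print.binned_pdf <- function(x, ...) {
  cat(sprintf("Binned PDFs: %d time points, L = %d bins\n",
              length(x$bins), x$L))
  invisible(x)
}

#' Modes of a binned distribution
#'
#' Local maxima of the binned mass sequence at one time point (the final
#' one by default, where the population is assumed equilibrated),
#' filtered by topographic prominence relative to the tallest bin and by
#' a minimum pairwise separation; returned in ascending location order.
#'
#' @param dist a `binned_pdf`.
#' @param time index of the time point (default: last).
#' @param min_prominence minimum prominence as a fraction of the maximum
#'   bin mass.
#' @param min_separation_bins minimum index distance between reported
#'   modes; when two candidate peaks are closer, the less prominent one
#'   is dropped.
#' @param smooth_bins width (odd) of the centered moving average applied
#'   to the mass sequence before peak detection; damps per-bin sampling
#'   noise without displacing well-separated peaks. Use 1 to disable.
#' @return An object of class `mode_set`: data-frame-like list with
#'   `location` (bin centers, ascending), `prominence`, `bin`.
#' @export
find_modes <- function(dist, time = length(dist$bins),
                       min_prominence = 0.05, min_separation_bins = 8,
                       smooth_bins = 5) {
  b <- dist$bins[[time]]
  if (isTRUE(b$degenerate))
    stop("distribution is degenerate (zero range)", call. = FALSE)
  m <- b$mass
  n <- length(m)
  if (smooth_bins > 1 && n > smooth_bins) {
    h <- (smooth_bins %/% 2)
    padded <- c(rep(m[1], h), m, rep(m[n], h))
    m <- vapply(seq_len(n), function(i)
      mean(padded[i:(i + 2 * h)]), numeric(1))
  }
  # candidate peaks: strictly above both flanks (plateaus: left edge wins)
  cand <- integer(0)
  for (i in seq_len(n)) {
    left <- if (i > 1) m[i - 1] else -Inf
    right <- if (i < n) m[i + 1] else -Inf
    if (m[i] > left && m[i] >= right && m[i] > 0) cand <- c(cand, i)
  }
  if (length(cand) == 0L) stop("no mode found", call. = FALSE)
  # topographic prominence: height above the deepest saddle separating the
  # peak from any higher terrain (boundary counts as terrain height 0)
  prom <- vapply(cand, function(i) {
    higher_l <- which(m[seq_len(n)] > m[i] & seq_len(n) < i)
    higher_r <- which(m[seq_len(n)] > m[i] & seq_len(n) > i)
    saddle_l <- if (length(higher_l)) min(m[(max(higher_l)):i]) else 0
    saddle_r <- if (length(higher_r)) min(m[i:(min(higher_r))]) else 0
    m[i] - max(saddle_l, saddle_r) * (length(higher_l) > 0 || length(higher_r) > 0)
  }, numeric(1))
  # the global maximum gets full height as prominence
  prom[m[cand] == max(m)] <- m[cand][m[cand] == max(m)]
  keep <- prom >= min_prominence * max(m)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) stop("no mode found", call. = FALSE)
  # enforce separation: keep the more prominent of any close pair
  ord <- order(-prom, cand)
  sel <- integer(0)
  for (i in ord)
    if (all(abs(cand[i] - cand[sel]) >= min_separation_bins) ||
        length(sel) == 0L) sel <- c(sel, i)
  cand <- cand[sel]; prom <- prom[sel]
  ord <- order(cand)
  structure(list(location = b$centers[cand[ord]], prominence = prom[ord],
                 bin = cand[ord], q = length(cand)), class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("Modes (q = %d): %s\n", x$q,
              paste(signif(x$location, 6), collapse = ", ")))
  invisible(x)
}

#' Squared-difference distance between binned PDFs
#'
#' \deqn{F = \sum_i \sum_l (P_e(t_i, b_l) - P_s(t_i, b_l))^2} over the
#' shared time points and bin grid. Zero iff the binned masses are
#' identical; symmetric in its arguments.
#'
#' @param pe,ps two `binned_pdf` objects on identical time points, bin
#'   count and edges.
#' @return Nonnegative scalar.
#' @export
objective_F <- function(pe, ps) {
  if (!identical(pe$L, ps$L) || length(pe$bins) != length(ps$bins))
    stop("binned PDFs must share the bin count and time points",
         call. = FALSE)
  tot <- 0
  for (i in seq_along(pe$bins)) {
    if (!isTRUE(all.equal(pe$bins[[i]]$edges, ps$bins[[i]]$edges,
                          tolerance = 1e-12)))
      stop("binned PDFs must share bin edges", call. = FALSE)
    tot <- tot + sum((pe$bins[[i]]$mass - ps$bins[[i]]$mass)^2)
  }
  tot
}
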