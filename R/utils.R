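# Shared constants and small numeric helpers.

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041

# 1 m/s expressed in angstrom/ns
MS_TO_ANS <- 10

#' Convert a growth rate between m/s and angstrom/ns
#'
#' All internal geometry is in angstrom and ns; rates are reported in m/s.
#'
#' @param v numeric rate.
#' @return converted rate.
#' @keywords internal
ms_to_angstrom_ns <- function(v) v * MS_TO_ANS

#' @rdname ms_to_angstrom_ns
#' @keywords internal
angstrom_ns_to_ms <- function(v) v / MS_TO_ANS

#' Wrap angles into (-180, 180]
#' @param x angles in degrees.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Uniform random rotation matrix
#'
#' Drawn from the Haar measure via a random unit quaternion; uses the
#' current RNG state.
#' @keywords internal
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Histogram of a sample on a fixed-width binning
#'
#' @param x numeric sample.
#' @param binwidth bin width in the units of `x`.
#' @param range optional 2-vector; defaults to the span of `x` rounded
#'   outward to bin edges.
#' @return data.frame with columns `center` and `density` (integrates to 1).
#' @export
fixed_hist <- function(x, binwidth, range = NULL) {
  stopifnot(length(x) > 0, binwidth > 0)
  if (is.null(range)) range <- range(x)
  lo <- floor(range[1] / binwidth) * binwidth
  hi <- ceiling(range[2] / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  cnt <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                       length(breaks) - 1L),
                  nbins = length(breaks) - 1L)
  data.frame(center = breaks[-length(breaks)] + binwidth / 2,
             density = cnt / (sum(cnt) * binwidth))
}

#' Histogram-intersection overlap between two samples
#'
#' Both samples are histogrammed on a shared fixed-width binning spanning
#' their pooled range; the score is the integral of the pointwise minimum
#' of the two densities, in `[0, 1]`, 1 iff the binned distributions are
#' identical. Symmetric in its arguments.
#'
#' @param x,y numeric samples.
#' @param binwidth shared bin width.
#' @return scalar overlap score.
#' @export
overlap_score <- function(x, y, binwidth) {
  rng <- range(c(x, y))
  hx <- fixed_hist(x, binwidth, rng)
  hy <- fixed_hist(y, binwidth, rng)
  sum(pmin(hx$density, hy$density)) * binwidth
}

#' Distribution summary against a reference sample
#'
#' @param values numeric sample.
#' @param reference numeric reference sample (e.g. ice-lattice distances).
#' @param binwidth bin width for the histogram and the overlap score.
#' @return object of class `dist_summary`: histogram, mean, sd, the
#'   reference mean and sd, and the histogram-intersection overlap score.
#' @export
dist_summary <- function(values, reference, binwidth) {
  structure(list(
    hist = fixed_hist(values, binwidth),
    mean = mean(values), sd = sd(values),
    ref_mean = mean(reference), ref_sd = sd(reference),
    overlap = overlap_score(values, reference, binwidth),
    binwidth = binwidth, n = length(values)
  ), class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("distribution summary: n = %d, mean = %.3f, sd = %.3f\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  reference: %.3f +/- %.3f;  overlap score %.3f\n",
              x$ref_mean, x$ref_sd, x$overlap))
  invisible(x)
}
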