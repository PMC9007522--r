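# Free-energy estimators: well-tempered metadynamics on a 1D periodic
# (dihedral) collective variable with FES reconstruction, and the
# Bennett acceptance ratio estimator -- both validated against analytic
# oracles in the test suite.

#' Well-tempered metadynamics on a 1D periodic collective variable
#'
#' Overdamped (Euler-Maruyama) Langevin dynamics on a model potential
#' `V(phi)` over the periodic CV phi in (-180, 180] degrees, with
#' history-dependent Gaussian bias deposited every `stride` steps at
#' height `height * exp(-V_bias(phi) / ((bias_factor - 1) kT))`. The
#' bias is accumulated on a 1-degree grid (periodic wrap); forces are
#' taken from centred finite differences on that grid. The free-energy
#' estimate is `-(gamma/(gamma-1)) V_bias`, shifted so its minimum is 0.
#'
#' The model potential stands in for the molecular dihedral landscape
#' (e.g. the carboxylate-rotation torsion): the estimator mathematics is
#' identical, and analytically known landscapes make the engine
#' desk-testable.
#'
#' @param potential function of phi (degrees) returning kcal/mol;
#'   should be periodic over 360 degrees.
#' @param height Gaussian height, kcal/mol.
#' @param sigma Gaussian width, degrees.
#' @param bias_factor well-tempering factor gamma (> 1).
#' @param stride steps between depositions.
#' @param n_steps total integration steps.
#' @param friction friction coefficient (kcal/mol per (deg^2/step));
#'   sets the diffusion D = kT/friction.
#' @param temperature K.
#' @param seed RNG seed.
#' @param grid_n bias grid resolution (points over 360 degrees).
#' @return object of class `fes_profile`: `grid` (degrees), `fes`
#'   (kcal/mol, min 0), `bias`, trajectory summary and parameters.
#' @export
run_wtmetad <- function(potential, height = 0.08, sigma = 18,
                        bias_factor = 8, stride = 250, n_steps = 4e5,
                        friction = 0.075, temperature = 300, seed = 1,
                        grid_n = 360) {
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  set.seed(seed)
  kT <- KB_KCAL * temperature
  D <- kT / friction            # deg^2 per step
  dt <- 1
  grid <- seq(-180, 180 - 360 / grid_n, by = 360 / grid_n)
  vb <- numeric(grid_n)         # accumulated bias on the grid
  vpot <- vapply(grid, potential, 0)
  # periodic centred finite-difference force tables (rebuilt on deposit)
  dgrid <- 360 / grid_n
  grad <- function(v) {
    (v[c(2:grid_n, 1)] - v[c(grid_n, 1:(grid_n - 1))]) / (2 * dgrid)
  }
  fpot <- grad(vpot)
  fb <- grad(vb)
  gidx <- function(phi) {
    i <- as.integer(floor((phi + 180) / dgrid)) + 1L
    if (i < 1L) i <- 1L
    if (i > grid_n) i <- grid_n
    i
  }
  phi <- 0
  noise <- sqrt(2 * D * dt)
  dep_at <- numeric(0)
  # time-average the (min-shifted) bias profile over the second half of
  # the run: the well-tempered bias converges to (1 - 1/gamma) F plus a
  # time-dependent constant and a fluctuating part that averaging
  # suppresses
  vb_acc <- numeric(grid_n)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    i <- gidx(phi)
    force <- fpot[i] + fb[i]
    phi <- phi - (D / kT) * force * dt + noise * rnorm(1)
    phi <- wrap_angle(phi)
    if (s %% stride == 0) {
      i <- gidx(phi)
      h_eff <- height * exp(-vb[i] / ((bias_factor - 1) * kT))
      dphi <- wrap_angle(grid - phi)
      vb <- vb + h_eff * exp(-dphi^2 / (2 * sigma^2))
      fb <- grad(vb)
      dep_at <- c(dep_at, phi)
      if (s > n_steps / 2) {
        vb_acc <- vb_acc + (vb - max(vb))
        n_acc <- n_acc + 1L
      }
    }
  }
  vb_avg <- if (n_acc > 0) vb_acc / n_acc else vb
  fes <- -(bias_factor / (bias_factor - 1)) * vb_avg
  fes <- fes - min(fes)
  structure(list(grid = grid, fes = fes, bias = vb,
                 depositions = dep_at,
                 params = list(height = height, sigma = sigma,
                               bias_factor = bias_factor, stride = stride,
                               n_steps = n_steps, friction = friction,
                               temperature = temperature, seed = seed)),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf("free-energy profile: barrier %.2f kcal/mol, %d grid points\n",
              max(x$fes) - min(x$fes), length(x$grid)))
  invisible(x)
}

#' Locate the minima of a periodic free-energy profile
#'
#' Grid points lower than both periodic neighbours and within
#' `tol` kcal/mol of the global minimum of their basin.
#'
#' @param profile an `fes_profile` (or list with `grid`, `fes`).
#' @param tol ignore local minima more than `tol` above the global one.
#' @return data.frame with `phi` (degrees) and `value` (kcal/mol).
#' @export
fes_minima <- function(profile, tol = 1) {
  f <- profile$fes
  n <- length(f)
  left <- f[c(n, 1:(n - 1))]
  right <- f[c(2:n, 1)]
  idx <- which(f < left & f <= right & f <= min(f) + tol)
  data.frame(phi = profile$grid[idx], value = f[idx])
}

#' Unbiased free-energy profile from dihedral samples
#'
#' `-kT ln p(phi)` from a histogram on the periodic domain, min-shifted
#' to 0; empty bins give `Inf`.
#'
#' @param samples dihedral samples, degrees.
#' @param temperature K.
#' @param binwidth degrees.
#' @return object of class `fes_profile`.
#' @export
unbiased_fes <- function(samples, temperature = 300, binwidth = 5) {
  kT <- KB_KCAL * temperature
  h <- fixed_hist(wrap_angle(samples), binwidth, c(-180, 180))
  fes <- -kT * log(h$density)
  fes <- fes - min(fes[is.finite(fes)])
  structure(list(grid = h$center, fes = fes, bias = NULL,
                 params = list(temperature = temperature,
                               binwidth = binwidth)),
            class = "fes_profile")
}

#' Bennett acceptance ratio free-energy difference
#'
#' Solves the BAR self-consistency equation
#' `sum_F f(M + (W_F - dF)/kT) = sum_R f(-M + (W_R + dF)/kT)` (with
#' `f` the Fermi function and `M = ln(n_F/n_R)`) by bracketed root
#' finding over the pooled work range, and returns the asymptotic
#' standard error. Forward work is for the 0 -> 1 switch, reverse work
#' for 1 -> 0; `dF = F_1 - F_0`.
#'
#' @param work_forward,work_reverse numeric work samples, kcal/mol.
#' @param temperature K.
#' @return list with `dF` (kcal/mol), `se` (asymptotic standard error),
#'   and `overlap_warning` (TRUE when the work distributions barely
#'   overlap and the error estimate is unreliable).
#' @export
bar_estimate <- function(work_forward, work_reverse, temperature = 300) {
  stopifnot(length(work_forward) > 0, length(work_reverse) > 0,
            all(is.finite(work_forward)), all(is.finite(work_reverse)))
  kT <- KB_KCAL * temperature
  nf <- length(work_forward)
  nr <- length(work_reverse)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))
  gap <- function(dF) {
    sum(fermi(M + (work_forward - dF) / kT)) -
      sum(fermi(-M + (work_reverse + dF) / kT))
  }
  lo <- min(c(work_forward, -work_reverse)) - 10 * kT
  hi <- max(c(work_forward, -work_reverse)) + 10 * kT
  if (gap(lo) * gap(hi) > 0) {
    # degenerate (e.g. all-zero work): fall back to the wider bracket
    lo <- lo - 100 * kT
    hi <- hi + 100 * kT
  }
  dF <- uniroot(gap, c(lo, hi), tol = 1e-10)$root
  # asymptotic variance (Bennett): per-state relative fluctuation of the
  # Fermi weights
  fF <- fermi(M + (work_forward - dF) / kT)
  fR <- fermi(-M + (work_reverse + dF) / kT)
  relvar <- function(x) (mean(x^2) / mean(x)^2 - 1) / length(x)
  v <- relvar(fF) + relvar(fR)
  overlap_warning <- !is.finite(v) || mean(fF) < 1e-8 || mean(fR) < 1e-8
  list(dF = dF, se = kT * sqrt(max(v, 0)),
       overlap_warning = overlap_warning)
}
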