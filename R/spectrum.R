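#' Binned photon energy spectrum
#'
#' Constructs and validates a normalized, binned photon energy spectrum
#' g(E).  Weights are renormalized to unit sum on construction; a slope
#' attribute records the cumulative hardening/softening applied relative to
#' the initial spectrum.
#'
#' @param energy_mev strictly increasing bin-center energies in MeV.
#' @param weight nonnegative bin weights; renormalized to sum to one.
#' @param slope tuning slope (per MeV) already applied relative to the
#'   initial spectrum; bookkeeping only.
#' @return an object of class `energy_spectrum` with fields `energy_mev`,
#'   `weight`, `slope`.
#' @export
energy_spectrum <- function(energy_mev, weight, slope = 0) {
  energy_mev <- as.numeric(energy_mev)
  weight <- as.numeric(weight)
  if (length(energy_mev) != length(weight) || length(weight) < 1)
    stop("energy and weight must be nonempty and equal length")
  if (any(diff(energy_mev) <= 0))
    stop("energy bins must be strictly increasing")
  if (any(weight < 0))
    stop("spectrum weights must be nonnegative")
  s <- sum(weight)
  if (s <= 0) stop("spectrum has zero total weight")
  structure(list(energy_mev = energy_mev, weight = weight / s,
                 slope = slope),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d bins, %.3g-%.3g MeV, mean %.3f MeV, slope %.4g/MeV\n",
              length(x$energy_mev), min(x$energy_mev), max(x$energy_mev),
              mean_energy(x), x$slope))
  invisible(x)
}

#' Mean energy of a spectrum
#'
#' @param g an `energy_spectrum`.
#' @return mean energy in MeV.  For a slope-tuned spectrum this equals the
#'   initial mean plus slope times the initial variance.
#' @export
mean_energy <- function(g) {
  stopifnot(inherits(g, "energy_spectrum"))
  sum(g$energy_mev * g$weight)
}

#' Energy variance of a spectrum
#'
#' @param g an `energy_spectrum`.
#' @return variance of the bin-center energy under g, in MeV^2.
#' @export
spectrum_variance <- function(g) {
  m <- mean_energy(g)
  sum(g$weight * (g$energy_mev - m)^2)
}

#' Harden or soften a spectrum by a linear slope factor
#'
#' Applies the one-parameter spectrum adjustment
#' \deqn{g_s(E) = g_0(E)\,(1 + s\,(E - \bar E)),}
#' where \eqn{\bar E} is the mean energy of `g0`.  A positive slope shifts
#' weight above the mean (a harder beam), a negative one below it.  Because
#' the correction is linear in \eqn{E - \bar E}, the total weight is
#' conserved exactly, and the mean energy changes by `s` times the variance
#' of `g0`.
#'
#' @param g0 initial `energy_spectrum`.
#' @param s slope in 1/MeV; must keep `1 + s*(E - mean)` positive on every
#'   bin.
#' @return the adjusted `energy_spectrum`, with `slope` incremented by `s`.
#' @export
tune_spectrum <- function(g0, s) {
  stopifnot(inherits(g0, "energy_spectrum"), is.numeric(s), length(s) == 1)
  ebar <- mean_energy(g0)
  fac <- 1 + s * (g0$energy_mev - ebar)
  if (any(fac <= 0)) {
    bad <- g0$energy_mev[which(fac <= 0)[1]]
    stop(sprintf("slope %g makes the multiplicative factor nonpositive at bin %g MeV",
                 s, bad))
  }
  w <- g0$weight * fac
  # linear-in-(E - mean) correction: sum(w) == sum(g0$weight) analytically
  energy_spectrum(g0$energy_mev, w, slope = g0$slope + s)
}

#' Admissible slope interval for a spectrum
#'
#' Largest open interval of slopes keeping the tuning factor positive on all
#' bins of `g0`.
#'
#' @param g0 an `energy_spectrum`.
#' @return numeric length-2 vector (lower, upper).
#' @export
slope_bounds <- function(g0) {
  d <- g0$energy_mev - mean_energy(g0)
  lo <- if (any(d > 0)) -1 / max(d) else -Inf
  hi <- if (any(d < 0)) -1 / min(d) else Inf
  c(lo, hi)
}

#' Packaged representative 6 MV spectrum
#'
#' A generic, representative 6 MV LINAC photon spectrum shipped with the
#' package (two-column CSV under `extdata`).  Any spectrum of a similar
#' nominal energy serves as a starting point; commissioning adjusts it by
#' the slope parameter.
#'
#' @return an `energy_spectrum`.
#' @export
default_spectrum_6mv <- function() {
  read_spectrum(system.file("extdata", "spectrum_6mv.csv",
                            package = "beamforge", mustWork = TRUE))
}

#' Read / write a spectrum table
#'
#' Two-column CSV with header `energy_mev,weight`.
#'
#' @param path file path.
#' @return `read_spectrum` returns an `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("energy_mev", "weight") %in% names(df)))
    stop("spectrum file must have columns energy_mev, weight: ", path)
  energy_spectrum(df$energy_mev, df$weight)
}

#' @rdname read_spectrum
#' @param g an `energy_spectrum` to write.
#' @export
write_spectrum <- function(g, path) {
  utils::write.csv(data.frame(energy_mev = g$energy_mev, weight = g$weight),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the spectrum slope against a measured depth-dose curve
#'
#' One-dimensional bounded minimization of the mean-square deviation between
#' the forward-calculated reference-field PDD and the measured PDD,
#' \deqn{\hat s = \arg\min_s \int (D(g_s, z) - \mathrm{PDD}(z))^2\,dz,}
#' discretized as a trapezoidal sum over the measured depth grid.  The
#' forward engine is expected to fix its random seed per evaluation so the
#' objective is smooth in `s`.
#'
#' Two refinements of the raw least-squares form are available (both on by
#' default in commissioning): a free multiplicative scale on the calculated
#' curve, which removes the arbitrary percent normalization (measured PDDs
#' are normalized to a maximum that contains the electron-contamination
#' contribution, while the photon-only forward is not), and a lower depth
#' limit that confines the fit to the falloff region -- the buildup of a
#' measured PDD is contaminated by electrons the spectrum stage does not
#' yet model, and letting it into the objective biases the slope soft.
#'
#' @param pdd_meas a `pdd_curve` (depths in cm, values in percent of max).
#' @param forward function of one argument: an `energy_spectrum`, returning
#'   PDD values (percent, max 100) on `pdd_meas$depth_cm`.
#' @param g0 initial `energy_spectrum`.
#' @param bounds length-2 search interval for the slope (1/MeV); clipped to
#'   the positivity bounds of `g0`.
#' @param tol absolute tolerance on the slope (default 1e-3).
#' @param scale `"log"` compares log dose with a free additive offset
#'   (equivalent to a free multiplicative scale with weights matched to
#'   the multiplicative Monte Carlo noise of the curves -- the efficient
#'   choice, and the one commissioning uses); `"free"` fits a
#'   least-squares scale factor on the linear curve; `"fixed"` compares
#'   the percent values directly.
#' @param min_depth_cm fit only depths at or beyond this value (0 = all).
#' @return list with `slope` (the fitted value) and `objective` at the
#'   optimum.
#' @export
fit_spectrum_slope <- function(pdd_meas, forward, g0,
                               bounds = c(-0.15, 0.15), tol = 1e-3,
                               scale = c("log", "free", "fixed"),
                               min_depth_cm = 0) {
  stopifnot(inherits(pdd_meas, "pdd_curve"))
  scale <- match.arg(scale)
  pb <- slope_bounds(g0)
  lo <- max(bounds[1], pb[1] + 1e-6)
  hi <- min(bounds[2], pb[2] - 1e-6)
  sel <- pdd_meas$depth_cm >= min_depth_cm
  if (sum(sel) < 3) stop("fewer than 3 depth samples in the fit region")
  z <- pdd_meas$depth_cm[sel]
  m <- pdd_meas$value[sel]
  wtrap <- trapezoid_weights(z)
  obj <- function(s) {
    d <- forward(tune_spectrum(g0, s))[sel]
    v <- if (scale == "log") {
      ok <- d > 0 & m > 0
      r <- log(m[ok]) - log(d[ok])
      cc <- sum(wtrap[ok] * r) / sum(wtrap[ok])
      sum(wtrap[ok] * (r - cc)^2)
    } else {
      cc <- if (scale == "free") sum(wtrap * d * m) / sum(wtrap * d^2) else 1
      sum(wtrap * (cc * d - m)^2)
    }
    if (!is.finite(v)) stop("spectrum objective non-finite at s = ", s)
    v
  }
  opt <- stats::optimize(obj, interval = c(lo, hi), tol = tol)
  list(slope = opt$minimum, objective = opt$objective)
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
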