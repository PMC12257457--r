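#' Photon interaction coefficients for water
#'
#' Mass attenuation and mass energy-absorption coefficients for liquid water
#' over 0.01--10 MeV, tabulated at standard grid energies and log-log
#' interpolated in between.  All transport media are treated as water with
#' density scaling; the beam model is commissioned entirely in water, so no
#' material composition lookup is carried.
#'
#' @format A data frame with columns `energy_mev`, `mu_over_rho`
#'   (cm^2/g, total attenuation without coherent scatter) and `muen_over_rho`
#'   (cm^2/g, mass energy absorption).
#' @keywords internal
water_photon_table <- function() {
  data.frame(
    energy_mev = c(0.010, 0.015, 0.020, 0.030, 0.040, 0.050, 0.060, 0.080,
                   0.100, 0.150, 0.200, 0.300, 0.400, 0.500, 0.600, 0.800,
                   1.000, 1.250, 1.500, 2.000, 3.000, 4.000, 5.000, 6.000,
                   8.000, 10.000),
    mu_over_rho = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                    0.1837, 0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.0969,
                    0.0896, 0.0786, 0.0707, 0.0632, 0.0575, 0.0494, 0.0397,
                    0.0340, 0.0303, 0.0277, 0.0243, 0.0222),
    muen_over_rho = c(4.944, 1.374, 0.5503, 0.1557, 0.0695, 0.0422, 0.0319,
                      0.0262, 0.0256, 0.0277, 0.0297, 0.0319, 0.0328, 0.0330,
                      0.0329, 0.0321, 0.0310, 0.0297, 0.0283, 0.0260, 0.0227,
                      0.0205, 0.0190, 0.0180, 0.0166, 0.0157)
  )
}

#' Electron total mass stopping power for water
#'
#' Total (collision + radiative) mass stopping power of liquid water for
#' electrons, 0.01--10 MeV kinetic energy.  The packaged CSDA range table is
#' derived from this table by quadrature, so stepping with these stopping
#' powers and the range oracle are mutually consistent.
#'
#' @format A data frame with columns `energy_mev` (kinetic) and `stopping`
#'   (MeV cm^2/g).
#' @keywords internal
water_estop_table <- function() {
  data.frame(
    energy_mev = c(0.010, 0.020, 0.030, 0.050, 0.070, 0.100, 0.150, 0.200,
                   0.300, 0.500, 0.700, 1.000, 1.500, 2.000, 3.000, 4.000,
                   5.000, 6.000, 8.000, 10.000),
    stopping = c(22.60, 13.20, 9.650, 6.750, 5.400, 4.120, 3.240, 2.790,
                 2.360, 2.060, 1.950, 1.870, 1.830, 1.840, 1.870, 1.910,
                 1.950, 2.000, 2.070, 2.150)
  )
}

loglog_interp <- function(x, xs, ys) {
  x <- pmin(pmax(x, xs[1]), xs[length(xs)])
  exp(stats::approx(log(xs), log(ys), xout = log(x), rule = 2)$y)
}

#' Water mass attenuation coefficient
#'
#' @param energy_mev photon energy in MeV (vectorized); clamped to the
#'   tabulated 0.01--10 MeV range.
#' @return mu/rho in cm^2/g.
#' @export
mu_water <- function(energy_mev) {
  tab <- water_photon_table()
  loglog_interp(energy_mev, tab$energy_mev, tab$mu_over_rho)
}

#' Water mass energy-absorption coefficient
#'
#' @inheritParams mu_water
#' @return muen/rho in cm^2/g.
#' @export
muen_water <- function(energy_mev) {
  tab <- water_photon_table()
  loglog_interp(energy_mev, tab$energy_mev, tab$muen_over_rho)
}

#' Electron total mass stopping power in water
#'
#' @param energy_mev electron kinetic energy in MeV (vectorized).
#' @return stopping power in MeV cm^2/g.
#' @export
estop_water <- function(energy_mev) {
  tab <- water_estop_table()
  loglog_interp(energy_mev, tab$energy_mev, tab$stopping)
}

#' CSDA range of electrons in water
#'
#' Continuous-slowing-down-approximation range, obtained by numerically
#' integrating the reciprocal packaged stopping power from 10 keV (the
#' transport cutoff) up to the requested kinetic energy.
#'
#' @param energy_mev electron kinetic energy in MeV (vectorized).
#' @return range in g/cm^2 (equals cm in unit-density water).
#' @export
csda_range_water <- function(energy_mev) {
  grid <- exp(seq(log(0.01), log(10), length.out = 400))
  inv_s <- 1 / estop_water(grid)
  cumr <- c(0, cumsum(diff(grid) * (inv_s[-1] + inv_s[-length(grid)]) / 2))
  stats::approx(grid, cumr, xout = pmin(pmax(energy_mev, 0.01), 10),
                rule = 2)$y
}

#' Mean Compton-electron energy fraction
#'
#' Average fraction of the photon energy transferred to the Compton electron,
#' used to pick the forward-smearing distance of the kerma estimator.
#'
#' @param energy_mev photon energy in MeV.
#' @return unitless fraction in (0, 1).
#' @keywords internal
compton_fraction <- function(energy_mev) {
  e <- c(0.05, 0.10, 0.20, 0.50, 1.0, 2.0, 4.0, 6.0, 10.0)
  f <- c(0.09, 0.14, 0.22, 0.34, 0.44, 0.535, 0.60, 0.64, 0.68)
  stats::approx(e, f, xout = pmin(pmax(energy_mev, e[1]), e[length(e)]),
                rule = 2)$y
}
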