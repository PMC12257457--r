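# R-side interface to the compiled transport engine.

#' Engine configuration
#'
#' @param n_photons,n_electrons history counts per calculation.
#' @param seed integer RNG seed (engine-internal stream, independent of R's).
#' @param n_batch batch count for per-voxel statistical uncertainty.
#' @param backend particle-position sampler: `"independence"` (inverse-CDF)
#'   or `"mh"` (Metropolis-Hastings random walk, Gaussian proposal).
#' @param mh_sigma_mm MH proposal standard deviation (mm).
#' @param mh_burnin MH burn-in samples.
#' @param photon_cutoff_mev,electron_cutoff_mev transport cutoffs (MeV;
#'   electron cutoff is kinetic energy); particles below cutoff are simply
#'   terminated with local deposition.
#' @param start_gap_cm distance of the particle start plane above the
#'   phantom surface (cm).
#' @param electron_step_cm condensed-history step length (cm).
#' @param scatter track Compton-scattered photons (disable for narrow-beam
#'   primary-attenuation studies).
#' @param smear spread the kerma score forward over the mean
#'   secondary-electron range (reproduces the buildup region in the
#'   expected-value scoring mode).
#' @param transport_secondaries analog secondary-electron transport instead
#'   of kerma scoring (slower, noisier; used for energy bookkeeping).
#' @param score `"dose"` or `"primary_fluence"` (track-length fluence of
#'   unscattered photons).
#' @return an `engine_config` list.
#' @export
engine_config <- function(n_photons = 1e6, n_electrons = 1e4, seed = 1,
                          n_batch = 10, backend = c("independence", "mh"),
                          mh_sigma_mm = 5, mh_burnin = 1000,
                          photon_cutoff_mev = 0.01,
                          electron_cutoff_mev = 0.1, start_gap_cm = 5,
                          electron_step_cm = 0.1, scatter = TRUE,
                          smear = TRUE, transport_secondaries = FALSE,
                          score = c("dose", "primary_fluence")) {
  stopifnot(n_photons > 0, n_electrons > 0, n_batch >= 2)
  structure(list(n_photons = as.integer(n_photons),
                 n_electrons = as.integer(n_electrons),
                 seed = as.numeric(seed), n_batch = as.integer(n_batch),
                 backend = match.arg(backend), mh_sigma_mm = mh_sigma_mm,
                 mh_burnin = as.integer(mh_burnin),
                 photon_cutoff_mev = photon_cutoff_mev,
                 electron_cutoff_mev = electron_cutoff_mev,
                 start_gap_cm = start_gap_cm,
                 electron_step_cm = electron_step_cm,
                 scatter = isTRUE(scatter), smear = isTRUE(smear),
                 transport_secondaries = isTRUE(transport_secondaries),
                 score = match.arg(score)),
            class = "engine_config")
}

# fine log-spaced lookup tables handed to the compiled engine
photon_tables <- function() {
  eg <- exp(seq(log(0.01), log(10), length.out = 256))
  mu <- mu_water(eg)
  # Klein-Nishina total cross section per electron -> Compton share of mu
  k <- eg / 0.51099895
  re2 <- 7.940787e-26  # classical electron radius squared, cm^2
  skn <- 2 * pi * re2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
  mu_c <- skn * 3.3428e23  # electrons per gram of water
  pc <- pmin(pmax(mu_c / mu, 0), 1)
  smear <- csda_range_water(compton_fraction(eg) * eg)
  list(egrid = eg, mu = mu, muen = muen_water(eg), pcompt = pc, smear = smear)
}

electron_tables <- function() {
  eg <- exp(seq(log(0.01), log(10), length.out = 256))
  list(egrid = eg, stop = estop_water(eg))
}

bfield_arg <- function(B) {
  if (is.null(B)) return(list())
  stopifnot(inherits(B, "b_field"))
  list(as.numeric(B$bx), as.numeric(B$by), as.numeric(B$bz))
}

# internal constructor bypassing the O(n) validation passes of dose_grid()
new_dose_grid <- function(dose, voxel_cm, origin_cm, uncertainty, component) {
  structure(list(dose = dose, voxel_cm = as.numeric(voxel_cm),
                 origin_cm = as.numeric(origin_cm),
                 uncertainty = uncertainty, component = component),
            class = "dose_grid")
}

#' Sample source particles from an energy fluence
#'
#' Draws particle positions on the SAD plane proportional to the fluence
#' map and energies proportional to the spectrum (the joint density is
#' separable), then back-projects each particle along the ray from the
#' point source through its sample position onto the start plane below the
#' collimators and above the phantom surface; the direction is the
#' source-to-sample unit vector.
#'
#' @param fg an `energy_fluence` (see [energy_weight()]).
#' @param n number of particles.
#' @param seed RNG seed.
#' @param config an `engine_config` (backend, start gap).
#' @param sad_cm source-to-axis distance; the fluence plane sits at the
#'   isocenter.
#' @param ssd_cm source-to-surface distance (phantom surface at
#'   `z = ssd - sad`, isocenter at z = 0, +z along the beam).
#' @return matrix with columns x, y, z (cm), vx, vy, vz, energy (MeV); the
#'   SAD-plane sample coordinates are recoverable by forward projection.
#' @export
sample_particles <- function(fg, n, seed = 1, config = engine_config(),
                             sad_cm = 100, ssd_cm = 100) {
  stopifnot(inherits(fg, "energy_fluence"))
  if (fg$total <= 0) stop("energy fluence has zero mass")
  start_z <- (ssd_cm - sad_cm) - config$start_gap_cm
  res <- cpp_sample_particles(
    fg$f$values, fg$f$px_cm, fg$f$x_cm[1], fg$f$y_cm[1],
    fg$g$energy_mev, fg$g$weight, as.integer(n), sad_cm, start_z,
    if (config$backend == "mh") 1L else 0L,
    config$mh_sigma_mm / (10 * fg$f$px_cm), config$mh_burnin,
    as.numeric(seed))
  res$particles
}

phantom_geom <- function(phantom, ssd_cm, sad_cm) {
  org <- phantom$origin_cm
  org[3] <- org[3] + (ssd_cm - sad_cm)  # surface at z = ssd - sad
  org
}

#' Photon transport
#'
#' Transports a photon stream through the voxel phantom (density-scaled
#' water) and scores the photon dose component Dx.  Scoring uses the
#' track-length collision-kerma estimator with forward electron-range
#' smearing unless `config$transport_secondaries` is set, in which case
#' secondary electrons from Compton/photoelectric/pair events are handed
#' to the condensed-history electron transport.  Particles leaving the
#' grid are silently terminated.
#'
#' @param phantom a `voxel_phantom`.
#' @param stream particle matrix from [sample_particles()], or an
#'   `energy_fluence` for fused on-the-fly sampling with
#'   `config$n_photons` histories.
#' @param B optional `b_field` (affects secondary electrons only).
#' @param config an `engine_config`.
#' @param seed overrides `config$seed`.
#' @param ssd_cm,sad_cm geometry (surface at `z = ssd - sad`).
#' @return a `dose_grid` (component `"photon"`) with per-voxel relative
#'   uncertainty from batch statistics; attribute `energy_in` carries the
#'   total sampled energy (MeV).
#' @export
transport_photons <- function(phantom, stream, B = NULL,
                              config = engine_config(), seed = NULL,
                              ssd_cm = 100, sad_cm = 100) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  seed <- if (is.null(seed)) config$seed else as.numeric(seed)
  xt <- photon_tables(); et <- electron_tables()
  fused <- inherits(stream, "energy_fluence")
  if (fused) {
    part <- matrix(0, 0, 7)
    fv <- stream$f$values; fpx <- stream$f$px_cm
    fx0 <- stream$f$x_cm[1]; fy0 <- stream$f$y_cm[1]
    eb <- stream$g$energy_mev; ew <- stream$g$weight
  } else {
    part <- as.matrix(stream)
    if (ncol(part) < 7) stop("particle stream needs 7 columns")
    fv <- matrix(1, 1, 1); fpx <- 0.1; fx0 <- 0; fy0 <- 0
    eb <- c(1, 2); ew <- c(0.5, 0.5)
  }
  start_z <- (ssd_cm - sad_cm) - config$start_gap_cm
  res <- cpp_transport_photons(
    as.numeric(phantom$density), dim(phantom$density), phantom$voxel_cm,
    phantom_geom(phantom, ssd_cm, sad_cm), part, fv, fpx, fx0, fy0, eb, ew,
    config$n_photons, sad_cm, start_z,
    if (config$backend == "mh") 1L else 0L,
    config$mh_sigma_mm / (10 * fpx), config$mh_burnin,
    xt$egrid, xt$mu, xt$muen, xt$pcompt, xt$smear,
    et$egrid, et$stop, bfield_arg(B), seed, config$n_batch,
    config$photon_cutoff_mev, config$electron_cutoff_mev, config$scatter,
    config$smear, config$transport_secondaries,
    if (config$score == "primary_fluence") 1L else 0L,
    config$electron_step_cm)
  # per-history statistical weight: the source strength is the fluence mass
  w0 <- if (fused) stream$total * stream$f$px_cm^2 / res$n else 1
  out <- new_dose_grid(array(res$dose * w0, dim(phantom$density)),
                       phantom$voxel_cm, phantom_geom(phantom, ssd_cm, sad_cm),
                       array(res$unc, dim(phantom$density)), "photon")
  attr(out, "energy_in") <- res$energy_in * w0
  attr(out, "n_histories") <- res$n
  out
}

#' Electron transport
#'
#' Condensed-history transport under the continuous slowing down
#' approximation: energy is deposited continuously along the path from the
#' packaged density-scaled water stopping power, the direction is perturbed
#' per step by Highland multiple scattering, and, when a magnetic field is
#' present, deflected to first order by the relativistic Lorentz force.
#'
#' @inheritParams transport_photons
#' @param stream particle matrix or `energy_fluence` (fused sampling of
#'   `config$n_electrons` histories).
#' @return a `dose_grid` (component `"electron"`).
#' @export
transport_electrons <- function(phantom, stream, B = NULL,
                                config = engine_config(), seed = NULL,
                                ssd_cm = 100, sad_cm = 100) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  seed <- if (is.null(seed)) config$seed else as.numeric(seed)
  et <- electron_tables()
  fused <- inherits(stream, "energy_fluence")
  if (fused) {
    part <- matrix(0, 0, 7)
    fv <- stream$f$values; fpx <- stream$f$px_cm
    fx0 <- stream$f$x_cm[1]; fy0 <- stream$f$y_cm[1]
    eb <- stream$g$energy_mev; ew <- stream$g$weight
  } else {
    part <- as.matrix(stream)
    fv <- matrix(1, 1, 1); fpx <- 0.1; fx0 <- 0; fy0 <- 0
    eb <- c(1, 2); ew <- c(0.5, 0.5)
  }
  start_z <- (ssd_cm - sad_cm) - config$start_gap_cm
  res <- cpp_transport_electrons(
    as.numeric(phantom$density), dim(phantom$density), phantom$voxel_cm,
    phantom_geom(phantom, ssd_cm, sad_cm), part, fv, fpx, fx0, fy0, eb, ew,
    config$n_electrons, sad_cm, start_z,
    if (config$backend == "mh") 1L else 0L,
    config$mh_sigma_mm / (10 * fpx), config$mh_burnin,
    et$egrid, et$stop, bfield_arg(B), seed, config$n_batch,
    config$electron_cutoff_mev, config$electron_step_cm)
  w0 <- if (fused) stream$total * stream$f$px_cm^2 / res$n else 1
  out <- new_dose_grid(array(res$dose * w0, dim(phantom$density)),
                       phantom$voxel_cm, phantom_geom(phantom, ssd_cm, sad_cm),
                       array(res$unc, dim(phantom$density)), "electron")
  attr(out, "energy_in") <- res$energy_in * w0
  out
}

#' Combine photon and electron dose components
#'
#' `D = Dx + we * De`; relative uncertainties are combined in quadrature of
#' the absolute componentwise uncertainties.
#'
#' @param dx photon `dose_grid`.
#' @param de electron `dose_grid` on the same grid.
#' @param we electron-contamination weight (>= 0).
#' @return combined `dose_grid`.
#' @export
combine_dose <- function(dx, de, we) {
  stopifnot(inherits(dx, "dose_grid"), inherits(de, "dose_grid"), we >= 0)
  if (!identical(dim(dx$dose), dim(de$dose)))
    stop("dose components are on different grids")
  d <- dx$dose + we * de$dose
  au <- sqrt((dx$dose * dx$uncertainty)^2 + (we * de$dose * de$uncertainty)^2)
  u <- array(0, dim(d))
  pos <- d > 0
  u[pos] <- au[pos] / d[pos]
  dose_grid(d, dx$voxel_cm, dx$origin_cm, u, "combined")
}

#' Relativistic gyroradius
#'
#' @param energy_mev electron kinetic energy (MeV).
#' @param b_tesla magnetic flux density magnitude perpendicular to the
#'   motion (T).
#' @return radius of the circle of deflection in cm, `pc / (c B)` with
#'   `pc = sqrt(T^2 + 2 T m_e c^2)`.
#' @export
gyroradius_cm <- function(energy_mev, b_tesla) {
  pc <- sqrt(energy_mev * (energy_mev + 2 * 0.51099895))
  pc / (2.99792458 * b_tesla)
}

#' First-order magnetic deflection of an electron direction
#'
#' `v' = normalize(v + (s/R) * (v x B)/|v x B|)` with `R` the relativistic
#' gyroradius for the field component perpendicular to the motion; the
#' direction is unchanged when `v x B` vanishes (no field, or motion
#' parallel to the field).
#'
#' @param v unit direction vector (length 3).
#' @param b magnetic field vector in tesla (length 3).
#' @param energy_mev electron kinetic energy (MeV).
#' @param step_cm condensed-history step length (cm).
#' @return the deflected unit direction.
#' @export
magnetic_deflect <- function(v, b, energy_mev, step_cm) {
  stopifnot(length(v) == 3, length(b) == 3, step_cm > 0)
  v <- v / sqrt(sum(v^2))
  cr <- c(v[2] * b[3] - v[3] * b[2],
          v[3] * b[1] - v[1] * b[3],
          v[1] * b[2] - v[2] * b[1])
  cn <- sqrt(sum(cr^2))
  if (cn < 1e-12) return(v)
  r <- gyroradius_cm(energy_mev, cn)  # |v x B| = B_perp since |v| = 1
  vp <- v + (step_cm / r) * cr / cn
  vp / sqrt(sum(vp^2))
}
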