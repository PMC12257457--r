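# Synthetic "golden machine": beam data generated from known ground-truth
# parameters by the same forward engine used in commissioning, enabling
# closed-loop recovery tests without measurements.

#' Golden-machine ground truth
#'
#' A synthetic machine whose beam data are generated from known parameters:
#' a true spectrum slope applied to the packaged 6 MV spectrum, a true
#' electron-contamination weight, a polynomial-in-radius off-axis scale and
#' a central-impulse-plus-exponential-tail scatter kernel (the smallest
#' family with the sharp central drop real kernels show).
#'
#' @param slope true spectrum slope s* (1/MeV).
#' @param we true electron weight.
#' @param kernel_w0 central impulse mass of the true kernel (unitless;
#'   fraction of the fluence delivered unscattered).
#' @param kernel_tail total mass of the exponential scatter tail.
#' @param kernel_r0 tail range (cm).
#' @param oas_coef polynomial coefficients (r, r^2, ... in cm) of the true
#'   OAS: `C(r) = 1 + sum_k coef[k] r^k`.
#' @param noise fractional multiplicative Gaussian noise applied to the
#'   generated beam data (0 = noiseless).
#' @param seed generator seed.
#' @param sad_cm,ssd_cm,d_ref_cm geometry.
#' @param largest_field_cm largest open field (cm).
#' @param fields_cm output-factor field sizes (cm).
#' @return a `golden_machine`.
#' @export
golden_machine <- function(slope = 0.03, we = 0.04, kernel_w0 = 0.95,
                           kernel_tail = 0.05, kernel_r0 = 1.0,
                           oas_coef = c(0.002, -1e-4), noise = 0, seed = 1,
                           sad_cm = 100, ssd_cm = 100, d_ref_cm = 10,
                           largest_field_cm = 20,
                           fields_cm = c(2, 3, 5, 10, 20)) {
  stopifnot(noise >= 0, kernel_w0 > 0, kernel_tail >= 0, kernel_r0 > 0)
  structure(list(slope = slope, we = we, kernel_w0 = kernel_w0,
                 kernel_tail = kernel_tail, kernel_r0 = kernel_r0,
                 oas_coef = oas_coef, noise = noise, seed = seed,
                 sad_cm = sad_cm, ssd_cm = ssd_cm, d_ref_cm = d_ref_cm,
                 largest_field_cm = largest_field_cm, fields_cm = fields_cm),
            class = "golden_machine")
}

#' True OAS map of a golden machine
#' @param gm a `golden_machine`.
#' @param half_size_cm map half-extent (default: half-diagonal of the
#'   largest field).
#' @param px_cm pixel size.
#' @return an `oas_map`.
#' @export
golden_oas <- function(gm, half_size_cm = NULL, px_cm = 0.1) {
  if (is.null(half_size_cm))
    half_size_cm <- gm$largest_field_cm * sqrt(2) / 2 + 0.5
  n <- as.integer(round(half_size_cm / px_cm))
  ax <- (-n:n) * px_cm
  r <- sqrt(outer(ax^2, ax^2, "+"))
  v <- matrix(1, 2 * n + 1, 2 * n + 1)
  for (k in seq_along(gm$oas_coef)) v <- v + gm$oas_coef[k] * r^k
  v[v < 0.2] <- 0.2
  oas_map(v / v[n + 1, n + 1], px_cm)
}

#' True scatter kernel of a golden machine
#'
#' Central impulse (all its mass in the axis pixel) plus a circularly
#' symmetric exponential tail `tail/(2 pi r0^2) exp(-r/r0)`.
#'
#' @param gm a `golden_machine`.
#' @param support_cm kernel half-extent (cm).
#' @param px_cm pixel size.
#' @return a `scatter_kernel`.
#' @export
golden_kernel <- function(gm, support_cm = 8, px_cm = 0.1) {
  n <- as.integer(round(support_cm / px_cm))
  ax <- (-n:n) * px_cm
  r <- sqrt(outer(ax^2, ax^2, "+"))
  v <- gm$kernel_tail / (2 * pi * gm$kernel_r0^2) * exp(-r / gm$kernel_r0)
  v[n + 1, n + 1] <- v[n + 1, n + 1] + gm$kernel_w0 / px_cm^2
  scatter_kernel(v, px_cm)
}

#' True spectrum of a golden machine
#' @param gm a `golden_machine`.
#' @return the slope-tuned packaged spectrum.
#' @export
golden_spectrum <- function(gm) tune_spectrum(default_spectrum_6mv(), gm$slope)

golden_meta <- function(gm, d_max_cm = NA_real_) {
  list(sad_cm = gm$sad_cm, ssd_cm = gm$ssd_cm, d_ref_cm = gm$d_ref_cm,
       d_max_cm = d_max_cm, largest_field_cm = gm$largest_field_cm,
       energy_label = "6X-synthetic")
}

#' Beam-data curves calculated from model components
#'
#' Shared forward route for golden-data generation and closed-loop
#' recalculation: for each square field the photon and electron components
#' are calculated, put on the percent scale (each normalized to the
#' central-axis maximum of the photon / electron component respectively)
#' and combined as `D = Dx + we * De`; PDDs and, for the 10x10 field,
#' cross-profiles at the requested depths (percent of the combined 10x10
#' central maximum) are extracted.
#'
#' @param spectrum an `energy_spectrum`.
#' @param we electron-contamination weight.
#' @param C an `oas_map`.
#' @param K a `scatter_kernel` (or NULL for no convolution).
#' @param machine machine metadata list.
#' @param config `engine_config` (history counts per calculation).
#' @param fields_cm PDD field sizes (must include 10).
#' @param profile_depths_cm depths of the 10x10 cross-profiles (NULL:
#'   `c(d_max, 5, 10)` with d_max read from the combined 10x10 PDD).
#' @param seed_base base seed; each calculation uses a fixed offset.
#' @return list with `pdds` (named by field), `profiles` (named by depth),
#'   `d_max_cm`, and `ref_value` (combined 10x10 central maximum).
#' @export
beam_curves <- function(spectrum, we, C, K, machine, config,
                        fields_cm = c(5, 10, 20), profile_depths_cm = NULL,
                        seed_base = 1000) {
  stopifnot(any(abs(fields_cm - 10) < 1e-9))
  phantom <- water_phantom(c(machine$largest_field_cm + 10,
                             machine$largest_field_cm + 10, 32))
  support <- if (is.null(K)) 8 else K$support_cm
  pdds <- list(); profiles <- list()
  d_max_cm <- NA_real_; ref_value <- NA_real_
  for (i in seq_along(fields_cm)) {
    f <- fields_cm[i]
    dx <- forward_open_field(spectrum, C, K, f, machine, phantom, config,
                             seed = seed_base + 10 * i + 1,
                             support_cm = support)
    de <- forward_open_field(spectrum, C, K, f, machine, phantom, config,
                             seed = seed_base + 10 * i + 2,
                             component = "electron", support_cm = support)
    dxc <- extract_pdd(dx, roi = 3L)  # percent of own max
    dec <- extract_pdd(de, roi = 3L)
    comb <- dxc$value + we * dec$value
    pdds[[sprintf("%gx%g", f, f)]] <- pdd_curve(dxc$depth_cm, comb)
    if (abs(f - 10) < 1e-9) {
      d_max_cm <- dxc$depth_cm[which.max(comb)]
      ref_value <- max(comb)
      # combined 3-D dose on the percent scale for profile extraction
      dxmax <- max(central_depth_curve(dx, roi = 3L))
      demax <- max(central_depth_curve(de, roi = 3L))
      comb3 <- dose_grid(100 * dx$dose / dxmax + we * 100 * de$dose / demax,
                         dx$voxel_cm, dx$origin_cm, component = "combined")
      if (is.null(profile_depths_cm))
        profile_depths_cm <- c(d_max_cm, 5, 10)
      for (dep in profile_depths_cm) {
        # the open square field is x/y- and mirror-symmetric: averaging the
        # two directions and the two signs quarters the MC variance
        px <- extract_profile(comb3, dep, "x", norm = "ref",
                              ref_value = ref_value, roi = 3L,
                              ssd_cm = machine$ssd_cm,
                              sad_cm = machine$sad_cm)
        py <- extract_profile(comb3, dep, "y", norm = "ref",
                              ref_value = ref_value, roi = 3L,
                              ssd_cm = machine$ssd_cm,
                              sad_cm = machine$sad_cm)
        v <- (px$value + py$value) / 2
        v <- (v + rev(v)) / 2
        profiles[[sprintf("d%g", dep)]] <-
          profile_curve(px$offset_cm, v, normalize = FALSE)
      }
    }
  }
  list(pdds = pdds, profiles = profiles, d_max_cm = d_max_cm,
       ref_value = ref_value)
}

central_depth_curve <- function(dose, roi = 1L) {
  d <- dim(dose$dose)
  ix <- axis_index(dose$origin_cm[1], dose$voxel_cm[1], d[1], 0)
  iy <- axis_index(dose$origin_cm[2], dose$voxel_cm[2], d[2], 0)
  xs <- max(1, ix - roi):min(d[1], ix + roi)
  ys <- max(1, iy - roi):min(d[2], iy + roi)
  apply(dose$dose[xs, ys, , drop = FALSE], 3, mean)
}

#' Generate golden-machine beam data
#'
#' Produces the measured-beam-data triplet from the ground truth: the
#' 10x10 PDD and the largest-field diagonal profile are calculated by the
#' transport engine with the true spectrum, OAS, kernel and electron
#' weight; the output factors combine the analytic kernel integral (the
#' in-air component) with engine-calculated phantom scatter,
#' `Scp = Sc* x Sp`, normalized to the 10x10 field.  Optional
#' multiplicative Gaussian noise is applied to every generated value; if
#' noise breaks the monotonicity of the output factors the table is
#' regenerated with a warning.
#'
#' @param gm a `golden_machine`.
#' @param config `engine_config` for the curve calculations (the
#'   scaled-down analogue of a commissioning measurement session).
#' @param sp_config optional separate config for the per-field
#'   phantom-scatter calculations (default: `config` with a quarter of the
#'   histories).
#' @return a `beam_data_set`; the ground truth is attached as attribute
#'   `"truth"`.
#' @export
generate_beam_data <- function(gm, config = engine_config(n_photons = 4e6,
                                                          n_electrons = 2e5,
                                                          seed = gm$seed),
                               sp_config = NULL) {
  stopifnot(inherits(gm, "golden_machine"))
  if (is.null(sp_config)) {
    sp_config <- config
    sp_config$n_photons <- max(1e5, config$n_photons %/% 2)
  }
  spec <- golden_spectrum(gm)
  C <- golden_oas(gm)
  K <- golden_kernel(gm)
  machine <- golden_meta(gm)
  phantom <- water_phantom(c(gm$largest_field_cm + 10,
                             gm$largest_field_cm + 10, 32))
  sbase <- gm$seed * 100000

  # 10x10 PDD (photon + weighted electron component).  The spectrum slope
  # is tuned against this single curve, so it gets the full history budget;
  # the other curves use half.
  dx10 <- forward_open_field(spec, C, K, 10, machine, phantom, config,
                             seed = sbase + 1, support_cm = K$support_cm)
  half_cfg <- config
  half_cfg$n_photons <- max(1e5, config$n_photons %/% 2L)
  de10 <- forward_open_field(spec, C, K, 10, machine, phantom, config,
                             seed = sbase + 2, component = "electron",
                             support_cm = K$support_cm)
  dxc <- extract_pdd(dx10, roi = 3L)
  dec <- extract_pdd(de10, roi = 3L)
  pdd_vals <- dxc$value + gm$we * dec$value
  d_max_cm <- dxc$depth_cm[which.max(pdd_vals)]

  # diagonal profile of the largest open field at d_max (photon component;
  # the OAS refinement loop is defined on the photon fluence)
  dlarge <- forward_open_field(spec, C, K, gm$largest_field_cm, machine,
                               phantom, half_cfg, seed = sbase + 3,
                               support_cm = K$support_cm)
  diag_prof <- radial_dose_profile(dlarge, d_max_cm,
                                   rmax_cm = gm$largest_field_cm * sqrt(2) / 2 + 0.2,
                                   ssd_cm = gm$ssd_cm, sad_cm = gm$sad_cm)
  # emulate a scanned measurement: the in-field portion of a real diagonal
  # is smooth; light spline smoothing there removes residual MC noise while
  # the penumbra and tail are kept as calculated
  diag_prof <- smooth_infield_profile(diag_prof,
                                      r_in = gm$largest_field_cm / 2 - 1)

  # output factors: central dose at the reference depth under the full
  # truth model per field, normalized to 10x10 -- what an ion chamber in
  # water measures.  (The separable approximation Sc x Sp differs from
  # the full calculation by a percent-level coupling term at large
  # fields; a measurement knows nothing of that factorization.)
  phantom_sp <- water_phantom(c(gm$largest_field_cm + 10,
                                gm$largest_field_cm + 10, 14))
  scp <- vapply(seq_along(gm$fields_cm), function(i) {
    d <- forward_open_field(spec, C, K, gm$fields_cm[i], machine,
                            phantom_sp, sp_config, seed = sbase + 30 + i,
                            support_cm = K$support_cm)
    central_dose(d, gm$d_ref_cm, hx = beamforge:::of_block_hx(gm$fields_cm[i]),
                 ssd_cm = gm$ssd_cm, sad_cm = gm$sad_cm)
  }, 0)
  i10 <- which(abs(gm$fields_cm - 10) < 1e-9)
  scp <- scp / scp[i10]

  # optional measurement-like multiplicative noise
  if (gm$noise > 0) {
    if (exists(".Random.seed", envir = globalenv()))
      old_seed <- get(".Random.seed", envir = globalenv())
    else old_seed <- NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(gm$seed)
    pdd_vals <- pdd_vals * (1 + gm$noise * stats::rnorm(length(pdd_vals)))
    dval <- diag_prof$value * (1 + gm$noise * stats::rnorm(length(diag_prof$value)))
    diag_prof <- profile_curve(diag_prof$offset_cm, dval)
    for (try in 1:20) {
      noisy <- scp * (1 + gm$noise * stats::rnorm(length(scp)))
      noisy <- noisy / noisy[i10]
      if (all(diff(noisy[order(gm$fields_cm)]) > 0)) break
      warning("noise broke output-factor monotonicity; regenerating")
    }
    scp <- noisy
  }

  bd <- beam_data_set(pdd_curve(dxc$depth_cm, pdd_vals), diag_prof,
                      of_table(gm$fields_cm, scp, gm$d_ref_cm),
                      golden_meta(gm, d_max_cm))
  attr(bd, "truth") <- gm
  bd
}

#' Reference validation curves from the golden-machine truth
#'
#' PDDs for the requested fields and 10x10 cross-profiles at three depths,
#' calculated from the ground-truth parameters -- the synthetic analogue
#' of the reference beam data a commissioned model is validated against.
#'
#' @inheritParams generate_beam_data
#' @param fields_cm PDD fields.
#' @param profile_depths_cm profile depths (NULL: d_max, 5, 10 cm).
#' @return see [beam_curves()].
#' @export
golden_reference_curves <- function(gm, config = engine_config(n_photons = 2e6,
                                                               n_electrons = 2e5,
                                                               seed = gm$seed),
                                    fields_cm = c(5, 10, 20),
                                    profile_depths_cm = NULL) {
  beam_curves(golden_spectrum(gm), gm$we, golden_oas(gm), golden_kernel(gm),
              golden_meta(gm), config, fields_cm, profile_depths_cm,
              seed_base = gm$seed * 100000 + 500)
}

# ------------------------------------------------------------- toy plans ---

#' Deterministic toy treatment plans
#'
#' * `open_square`: one open segment of the given field size and MU.
#' * `sliding_window`: `n_segments` equal-MU windows of width
#'   `field_cm/4` sliding across the field; the composite intensity is an
#'   analytic staircase.
#' * `step_and_shoot`: 5 nested centered squares (100%..20% of the field)
#'   with equal MU.
#'
#' @param kind plan type.
#' @param field_cm field size (cm).
#' @param mu total monitor units.
#' @param n_segments segment count for `sliding_window`.
#' @param grid_half_cm beam-grid half extent (default `field_cm/2 + 9`).
#' @return a `plan_set` (same structure as [read_plan()]).
#' @export
generate_plan <- function(kind = c("open_square", "sliding_window",
                                   "step_and_shoot"),
                          field_cm = 10, mu = 100, n_segments = 20L,
                          grid_half_cm = NULL) {
  kind <- match.arg(kind)
  if (is.null(grid_half_cm)) grid_half_cm <- field_cm / 2 + 9
  n <- as.integer(round(grid_half_cm / 0.1))
  ax <- ((-n):(n - 1) + 0.5) * 0.1
  grid <- list(x_cm = ax, y_cm = ax)
  sq_mask <- function(xlo, xhi, half_y)
    outer(ax > xlo & ax < xhi, abs(ax) < half_y) > 0
  segs <- switch(kind,
    open_square = list(list(mu = mu,
                            mask = sq_mask(-field_cm / 2, field_cm / 2,
                                           field_cm / 2))),
    sliding_window = {
      w <- field_cm / 4
      starts <- seq(-field_cm / 2, field_cm / 2 - w,
                    length.out = n_segments)
      lapply(starts, function(s)
        list(mu = mu / n_segments, mask = sq_mask(s, s + w, field_cm / 2)))
    },
    step_and_shoot = {
      fracs <- c(1, 0.8, 0.6, 0.4, 0.2)
      lapply(fracs, function(fr)
        list(mu = mu / 5, mask = sq_mask(-fr * field_cm / 2,
                                         fr * field_cm / 2,
                                         fr * field_cm / 2)))
    })
  structure(list(beams = list(list(gantry_deg = 0, grid = grid,
                                   segments = segs))),
            class = "plan_set")
}

#' Write a plan to the JSON dialect
#'
#' Masks are exported as headerless 0/1 CSV files next to the plan file.
#' @param plan a `plan_set`.
#' @param path plan JSON path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "plan_set"))
  dir <- dirname(path)
  beams <- lapply(seq_along(plan$beams), function(bi) {
    b <- plan$beams[[bi]]
    px <- round((b$grid$x_cm[2] - b$grid$x_cm[1]) * 10, 9)
    segs <- lapply(seq_along(b$segments), function(si) {
      fn <- sprintf("%s_b%d_s%d.csv",
                    sub("\\.json$", "", basename(path)), bi, si)
      utils::write.table(t(1 * b$segments[[si]]$mask), file.path(dir, fn),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      list(mu = b$segments[[si]]$mu, mask_csv = fn)
    })
    list(gantry_deg = b$gantry_deg,
         grid = list(x0_mm = (b$grid$x_cm[1] * 10) - px / 2,
                     y0_mm = (b$grid$y_cm[1] * 10) - px / 2,
                     nx = length(b$grid$x_cm), ny = length(b$grid$y_cm)),
         segments = segs)
  })
  jsonlite::write_json(list(format = "beamforge-plan-1", beams = beams),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
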