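# Dose-comparison metrics: curve extraction, output factors, gamma index,
# reference-point dose difference.

axis_index <- function(coord0, voxel, n, target) {
  i <- round((target - coord0) / voxel) + 1
  min(max(i, 1), n)
}

#' Extract a percent depth-dose curve from a dose grid
#'
#' Central-axis depth curve averaged laterally over a square
#' chamber-like region of interest, normalized to its maximum = 100.
#'
#' @param dose a `dose_grid`.
#' @param x_cm,y_cm lateral position of the axis (cm).
#' @param roi lateral half-width of the averaging region in voxels
#'   (1 gives 3x3, 2 gives 5x5).
#' @return a `pdd_curve` on the voxel-center depth grid.
#' @export
extract_pdd <- function(dose, x_cm = 0, y_cm = 0, roi = 1L) {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$dose)
  ix <- axis_index(dose$origin_cm[1], dose$voxel_cm[1], d[1], x_cm)
  iy <- axis_index(dose$origin_cm[2], dose$voxel_cm[2], d[2], y_cm)
  xs <- max(1, ix - roi):min(d[1], ix + roi)
  ys <- max(1, iy - roi):min(d[2], iy + roi)
  v <- apply(dose$dose[xs, ys, , drop = FALSE], 3, mean)
  depth <- dose$origin_cm[3] + (seq_len(d[3]) - 1) * dose$voxel_cm[3]
  pdd_curve(depth, v)
}

#' Extract a lateral profile from a dose grid
#'
#' Line profile at the given depth along x, y or the diagonal, averaged
#' over `2*roi+1` voxels in depth and across the line.  Offsets are
#' geometrically projected from the measurement depth back to the SAD
#' plane.  With `norm = "center"` the profile is normalized to 1 on the
#' axis (the open-field/OAS convention); with `norm = "ref"` values are
#' given in percent of `ref_value` (the reference-field maximum
#' convention for cross-profiles).
#'
#' @param dose a `dose_grid`.
#' @param depth_cm measurement depth below the surface (cm).
#' @param direction `"x"`, `"y"` or `"diagonal"` (step = voxel diagonal).
#' @param norm `"center"`, `"ref"` or `"none"`.
#' @param ref_value reference dose for `norm = "ref"`.
#' @param roi averaging half-width in voxels (depth and transverse).
#' @param ssd_cm,sad_cm geometry for the SAD-plane projection.
#' @return a `profile_curve`.
#' @export
extract_profile <- function(dose, depth_cm, direction = c("x", "y", "diagonal"),
                            norm = c("center", "ref", "none"),
                            ref_value = NULL, roi = 1L,
                            ssd_cm = 100, sad_cm = 100) {
  stopifnot(inherits(dose, "dose_grid"))
  direction <- match.arg(direction)
  norm <- match.arg(norm)
  d <- dim(dose$dose)
  surface_z <- ssd_cm - sad_cm
  iz <- axis_index(dose$origin_cm[3], dose$voxel_cm[3], d[3],
                   surface_z + depth_cm)
  zs <- max(1, iz - roi):min(d[3], iz + roi)
  ix0 <- axis_index(dose$origin_cm[1], dose$voxel_cm[1], d[1], 0)
  iy0 <- axis_index(dose$origin_cm[2], dose$voxel_cm[2], d[2], 0)
  if (direction == "x") {
    ys <- max(1, iy0 - roi):min(d[2], iy0 + roi)
    v <- apply(dose$dose[, ys, zs, drop = FALSE], 1, mean)
    off <- dose$origin_cm[1] + (seq_len(d[1]) - 1) * dose$voxel_cm[1]
  } else if (direction == "y") {
    xs <- max(1, ix0 - roi):min(d[1], ix0 + roi)
    v <- apply(dose$dose[xs, , zs, drop = FALSE], 2, mean)
    off <- dose$origin_cm[2] + (seq_len(d[2]) - 1) * dose$voxel_cm[2]
  } else {
    # diagonal, sampled at voxel-diagonal steps by bilinear interpolation
    step <- sqrt(dose$voxel_cm[1]^2 + dose$voxel_cm[2]^2)
    xmax <- min(abs(dose$origin_cm[1]),
                abs(dose$origin_cm[1] + (d[1] - 1) * dose$voxel_cm[1]))
    nmax <- floor(xmax * sqrt(2) / step)
    off <- (-nmax:nmax) * step
    plane <- apply(dose$dose[, , zs, drop = FALSE], c(1, 2), mean)
    xs_ax <- dose$origin_cm[1] + (seq_len(d[1]) - 1) * dose$voxel_cm[1]
    ys_ax <- dose$origin_cm[2] + (seq_len(d[2]) - 1) * dose$voxel_cm[2]
    v <- bilinear_at(plane, xs_ax, ys_ax, off / sqrt(2), off / sqrt(2))
  }
  proj <- sad_cm / (ssd_cm + depth_cm)  # back to SAD scale
  if (norm == "ref") {
    if (is.null(ref_value) || ref_value <= 0)
      stop("norm = 'ref' needs a positive ref_value")
    profile_curve(off * proj, 100 * v / ref_value, normalize = FALSE)
  } else {
    profile_curve(off * proj, v, normalize = (norm == "center"))
  }
}

#' Radially averaged dose profile at depth
#'
#' Annulus-averaged radial profile of an (by construction circularly
#' symmetric) open-field dose at the given depth, mirrored to signed
#' offsets and projected to the SAD plane.  Radial averaging uses every
#' voxel of the plane, which suppresses Monte Carlo noise far below a
#' single diagonal line-out; used for the off-axis-scale update.
#'
#' @inheritParams extract_profile
#' @param rmax_cm largest radius to report (default: grid limit).
#' @param norm_radius_cm the profile is normalized to the mean dose over
#'   the central disk of this radius rather than the single axis pixel: a
#'   lone pixel carries percent-level Monte Carlo noise that would rescale
#'   the entire curve.
#' @return a `profile_curve` normalized to the central disk mean.
#' @export
radial_dose_profile <- function(dose, depth_cm, rmax_cm = NULL, roi = 1L,
                                ssd_cm = 100, sad_cm = 100,
                                norm_radius_cm = 1) {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$dose)
  surface_z <- ssd_cm - sad_cm
  iz <- axis_index(dose$origin_cm[3], dose$voxel_cm[3], d[3],
                   surface_z + depth_cm)
  zs <- max(1, iz - roi):min(d[3], iz + roi)
  plane <- apply(dose$dose[, , zs, drop = FALSE], c(1, 2), mean)
  xs <- dose$origin_cm[1] + (seq_len(d[1]) - 1) * dose$voxel_cm[1]
  ys <- dose$origin_cm[2] + (seq_len(d[2]) - 1) * dose$voxel_cm[2]
  r <- sqrt(outer(xs^2, ys^2, "+"))
  if (is.null(rmax_cm)) rmax_cm <- max(abs(c(xs, ys)))
  step <- dose$voxel_cm[1]
  rbin <- round(r / step)
  keep <- r <= rmax_cm + step
  m <- tapply(plane[keep], rbin[keep], mean)
  rr <- as.numeric(names(m)) * step
  o <- order(rr); rr <- rr[o]; m <- as.numeric(m)[o]
  ctr <- mean(plane[r <= norm_radius_cm])
  if (!is.finite(ctr) || ctr <= 0) stop("degenerate central dose in profile")
  proj <- sad_cm / (ssd_cm + depth_cm)
  if (rr[1] == 0) {          # odd grids have an axis bin; do not mirror it
    off <- c(-rev(rr[-1]), rr) * proj
    val <- c(rev(m[-1]), m) / ctr
  } else {
    off <- c(-rev(rr), rr) * proj
    val <- c(rev(m), m) / ctr
  }
  profile_curve(off, val, normalize = FALSE)
}

# Smooth the in-field part of a radial dose profile with a rigid
# annulus-count-weighted quadratic in radius, and renormalize so the fit
# equals 1 on the axis.  The open-field interior is a gentle radial
# function (divergence cone plus mild horns), so a quadratic has the right
# capacity; crucially, a rigid polynomial cannot chase the statistical
# bumps of the sparsely-populated innermost annuli into its r -> 0 value
# -- a flexible smoother's free end would extrapolate such a bump
# straight into the axis anchor that normalizes the whole curve.  Used
# for both generated ("measured") and calculated diagonal profiles so
# the two sides of the off-axis-scale refinement share one convention;
# the penumbra and tail are kept as sampled.
smooth_infield_profile <- function(p, r_in, degree = 2L) {
  r <- abs(p$offset_cm)
  v <- p$value
  sel <- r <= r_in
  if (sum(sel) > 3 * (degree + 1)) {
    fit <- stats::lm(y ~ poly(x, degree = degree, raw = TRUE),
                     data = data.frame(x = r[sel], y = v[sel]),
                     weights = pmax(r[sel], 0.05))
    v[sel] <- stats::predict(fit, newdata = data.frame(x = r[sel]))
    v <- v / stats::predict(fit, newdata = data.frame(x = 0))
  }
  profile_curve(p$offset_cm, v, normalize = FALSE)
}

# central-block half-width (in voxels) for output-factor point doses:
# the estimator is ray-count limited (all primaries through the block are
# vertical), so large flat fields use a wider block -- up to 1.5 cm
# half-width, capped at a quarter of the field side so the block stays in
# the flat region.  Used identically wherever output factors or phantom
# scatter are computed, so the convention cancels in closed loops.
of_block_hx <- function(field_cm, vox_cm = 0.2) {
  max(2L, as.integer(round(min(1.5, field_cm / 4) / vox_cm)))
}

#' Mean dose in a chamber-like central block
#'
#' Mean over a `(2*hx+1) x (2*hx+1) x (2*hz+1)` voxel block centered on
#' the central axis at the requested depth -- the estimator used for
#' output-factor and phantom-scatter points.
#'
#' @param dose a `dose_grid`.
#' @param depth_cm depth of the block center (cm below surface).
#' @param hx,hz block half-widths in voxels.
#' @param ssd_cm,sad_cm geometry.
#' @return scalar mean dose.
#' @export
central_dose <- function(dose, depth_cm, hx = 2L, hz = 2L,
                         ssd_cm = 100, sad_cm = 100) {
  d <- dim(dose$dose)
  ix <- axis_index(dose$origin_cm[1], dose$voxel_cm[1], d[1], 0)
  iy <- axis_index(dose$origin_cm[2], dose$voxel_cm[2], d[2], 0)
  iz <- axis_index(dose$origin_cm[3], dose$voxel_cm[3], d[3],
                   (ssd_cm - sad_cm) + depth_cm)
  mean(dose$dose[max(1, ix - hx):min(d[1], ix + hx),
                 max(1, iy - hx):min(d[2], iy + hx),
                 max(1, iz - hz):min(d[3], iz + hz)])
}

#' Recompute output factors from a commissioned model
#'
#' Runs the full model (intensity, OAS, kernel convolution, transport) for
#' each square field, takes the central block dose at the reference depth
#' and normalizes to the 10x10 field.
#'
#' @param model a `beam_model`.
#' @param field_cm square field sides (cm); 10 is added if absent.
#' @param config an `engine_config` (seed is offset per field).
#' @param d_ref_cm reference depth (default from the model metadata).
#' @param phantom optional `voxel_phantom` (default: commissioning water
#'   phantom sized to the largest field).
#' @return an `of_table` of the recomputed relative outputs.
#' @export
compute_output_factors <- function(model, field_cm, config = engine_config(),
                                   d_ref_cm = NULL, phantom = NULL) {
  stopifnot(inherits(model, "beam_model"))
  if (is.null(d_ref_cm)) d_ref_cm <- model$machine$d_ref_cm
  field_cm <- sort(unique(c(field_cm, 10)))
  if (is.null(phantom))
    phantom <- water_phantom(c(max(field_cm) + 10, max(field_cm) + 10, 14))
  vals <- vapply(seq_along(field_cm), function(i) {
    f <- field_cm[i]
    flu <- model_open_fluence(model, f)
    fg <- energy_weight(flu, model$spectrum)
    cfg <- config; cfg$seed <- config$seed + 1000 * i
    dx <- transport_photons(phantom, fg, config = cfg,
                            ssd_cm = model$machine$ssd_cm,
                            sad_cm = model$machine$sad_cm)
    central_dose(dx, d_ref_cm, hx = of_block_hx(f),
                 ssd_cm = model$machine$ssd_cm,
                 sad_cm = model$machine$sad_cm)
  }, 0)
  of_table(field_cm, vals / vals[which(abs(field_cm - 10) < 1e-9)], d_ref_cm)
}

# ------------------------------------------------------------- gamma -------

#' Gamma comparison of two 1-D dose curves
#'
#' Global-normalization gamma index: the dose-difference criterion is a
#' percentage of the reference curve maximum, the search is exhaustive
#' within 3x the distance-to-agreement radius at a quarter-step
#' interpolation of the evaluated curve, and only reference points at or
#' above the low-dose threshold are evaluated.  The returned gamma carries
#' the sign of the local dose difference.
#'
#' @param ref_pos,ref_val reference curve (positions in cm).
#' @param ev_pos,ev_val evaluated curve.
#' @param dd dose-difference criterion in percent of the reference max.
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param threshold low-dose threshold in percent of the reference max.
#' @param subsample search-offset resolution as a fraction of the DTA
#'   (default 1/40: effectively exact for 1-D curves).
#' @return a `gamma_result`: list with `gamma` (signed, NA below
#'   threshold), `pass_rate` (percent), `n_evaluated`, `criteria`.
#' @export
gamma_curve <- function(ref_pos, ref_val, ev_pos, ev_val, dd = 3,
                        dta_mm = 2, threshold = 10, subsample = 40L) {
  dta_cm <- dta_mm / 10
  norm <- max(ref_val)
  ddn <- dd / 100 * norm
  eval_set <- ref_val >= threshold / 100 * norm
  if (!any(eval_set)) stop("no reference points above the low-dose threshold")
  offs <- seq(-3 * dta_cm, 3 * dta_cm, by = dta_cm / subsample)
  g <- rep(NA_real_, length(ref_pos))
  for (i in which(eval_set)) {
    x <- ref_pos[i]
    ev <- stats::approx(ev_pos, ev_val, xout = x + offs)$y
    ok <- !is.na(ev)
    if (!any(ok)) next
    gg <- sqrt((offs[ok] / dta_cm)^2 + ((ev[ok] - ref_val[i]) / ddn)^2)
    ev0 <- stats::approx(ev_pos, ev_val, xout = x, rule = 2)$y
    g[i] <- min(gg) * ifelse(ev0 >= ref_val[i], 1, -1)
  }
  structure(list(gamma = g,
                 pass_rate = 100 * mean(abs(g[eval_set]) <= 1, na.rm = TRUE),
                 n_evaluated = sum(eval_set),
                 criteria = list(dd = dd, dta_mm = dta_mm,
                                 threshold = threshold)),
            class = "gamma_result")
}

#' Gamma comparison of two dose grids
#'
#' Global-normalization 3-D gamma with exhaustive search within 3x the DTA
#' radius at 4x subsampled trilinear interpolation of the evaluated grid.
#' Voxels below the low-dose threshold (fraction of the reference maximum)
#' are excluded.  Exact at desk scale rather than fast; the two grids must
#' share geometry.
#'
#' @param reference,evaluated `dose_grid`s on the same grid.
#' @param dd dose difference criterion (percent of reference max).
#' @param dta_mm distance-to-agreement (mm).
#' @param threshold low-dose threshold (percent of reference max).
#' @param stride evaluate every `stride`-th voxel along each axis
#'   (>=1; coarse screening for large volumes).
#' @param subsample search-offset resolution in fractions of a voxel
#'   (default 4, the desk-scale-exact setting).
#' @return a `gamma_result` with a signed gamma array (NA below threshold).
#' @export
gamma_index <- function(reference, evaluated, dd = 3, dta_mm = 2,
                        threshold = 10, stride = 1L, subsample = 4L) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (!identical(dim(reference$dose), dim(evaluated$dose)))
    stop("gamma_index needs matching grids (resample first)")
  vox <- reference$voxel_cm
  dta_cm <- dta_mm / 10
  norm <- max(reference$dose)
  ddn <- dd / 100 * norm
  refd <- reference$dose
  evd <- evaluated$dose
  d <- dim(refd)
  sel <- array(FALSE, d)
  sel[seq(1, d[1], stride), seq(1, d[2], stride), seq(1, d[3], stride)] <- TRUE
  sel <- sel & (refd >= threshold / 100 * norm)
  if (!any(sel)) stop("no reference voxels above the low-dose threshold")
  idx <- which(sel, arr.ind = TRUE)
  rv <- refd[sel]
  # offsets within a sphere of radius 3*DTA at quarter-voxel steps
  steps <- lapply(1:3, function(a) {
    s <- vox[a] / subsample
    seq(-3 * dta_cm, 3 * dta_cm, by = s)
  })
  og <- expand.grid(dx = steps[[1]], dy = steps[[2]], dz = steps[[3]])
  og <- og[og$dx^2 + og$dy^2 + og$dz^2 <= (3 * dta_cm)^2, ]
  gmin <- rep(Inf, nrow(idx))
  for (r in seq_len(nrow(og))) {
    fi <- idx[, 1] + og$dx[r] / vox[1]
    fj <- idx[, 2] + og$dy[r] / vox[2]
    fk <- idx[, 3] + og$dz[r] / vox[3]
    ev <- trilinear_at(evd, fi, fj, fk)
    gg <- (og$dx[r]^2 + og$dy[r]^2 + og$dz[r]^2) / dta_cm^2 +
      ((ev - rv) / ddn)^2
    gg[is.na(ev)] <- Inf
    gmin <- pmin(gmin, gg)
  }
  gmin <- sqrt(gmin)
  garr <- array(NA_real_, d)
  garr[sel] <- gmin * ifelse(evd[sel] >= rv, 1, -1)
  structure(list(gamma = garr,
                 pass_rate = 100 * mean(gmin <= 1),
                 n_evaluated = nrow(idx),
                 criteria = list(dd = dd, dta_mm = dta_mm,
                                 threshold = threshold)),
            class = "gamma_result")
}

# trilinear interpolation at fractional (1-based) indices; NA outside
trilinear_at <- function(a, fi, fj, fk) {
  d <- dim(a)
  out <- rep(NA_real_, length(fi))
  ok <- fi >= 1 & fi <= d[1] & fj >= 1 & fj <= d[2] & fk >= 1 & fk <= d[3]
  if (!any(ok)) return(out)
  fi <- pmin(fi[ok], d[1] - 1e-9); fj <- pmin(fj[ok], d[2] - 1e-9)
  fk <- pmin(fk[ok], d[3] - 1e-9)
  i0 <- pmin(floor(fi), d[1] - 1); j0 <- pmin(floor(fj), d[2] - 1)
  k0 <- pmin(floor(fk), d[3] - 1)
  tx <- fi - i0; ty <- fj - j0; tz <- fk - k0
  v <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
      (if (dk) tz else 1 - tz)
    v <- v + w * a[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  out[ok] <- v
  out
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f%%/%g mm, threshold %g%%: pass rate %.2f%% (%d evaluated)\n",
              x$criteria$dd, x$criteria$dta_mm, x$criteria$threshold,
              x$pass_rate, x$n_evaluated))
  invisible(x)
}

# --------------------------------------------------- reference point -------

#' Deep reference point of a dose distribution
#'
#' The voxel of the 90% isodose volume V90 at maximum Euclidean distance
#' from the V90 boundary (the most interior high-dose voxel), found by a
#' distance transform against the boundary voxel set; ties are broken by
#' the lowest flat index.  The location is invariant to uniform dose
#' rescaling.
#'
#' @param dose a `dose_grid`.
#' @param level isodose level as a fraction of the maximum (default 0.9).
#' @return list with `index` (i, j, k), `location_cm`, `distance_cm`.
#' @export
reference_point <- function(dose, level = 0.9) {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$dose)
  v90 <- dose$dose >= level * max(dose$dose)
  # boundary: V90 voxels with a 6-neighbor outside V90 (grid edge counts)
  shift_out <- function(m, axis, dir) {
    out <- array(TRUE, dim(m))
    n <- dim(m)[axis]
    if (n == 1) return(out)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    ix <- lapply(dim(m), seq_len)
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- !m[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  outside_near <- array(FALSE, d)
  for (axis in 1:3) for (dir in c(-1, 1))
    outside_near <- outside_near | shift_out(v90, axis, dir)
  boundary <- v90 & outside_near
  vi <- which(v90, arr.ind = TRUE)
  bi <- which(boundary, arr.ind = TRUE)
  if (nrow(bi) == 0) stop("degenerate isodose volume")
  vox <- dose$voxel_cm
  vpos <- sweep(vi, 2, vox, "*")
  bpos <- sweep(bi, 2, vox, "*")
  best_d <- rep(Inf, nrow(vpos))
  chunk <- 2000
  for (s in seq(1, nrow(bpos), chunk)) {
    e <- min(s + chunk - 1, nrow(bpos))
    dd2 <- outer(rowSums(vpos^2), rep(1, e - s + 1)) +
      outer(rep(1, nrow(vpos)), rowSums(bpos[s:e, , drop = FALSE]^2)) -
      2 * vpos %*% t(bpos[s:e, , drop = FALSE])
    best_d <- pmin(best_d, apply(dd2, 1, min))
  }
  best_d <- sqrt(pmax(best_d, 0))
  flat <- (vi[, 3] - 1) * d[1] * d[2] + (vi[, 2] - 1) * d[1] + vi[, 1]
  o <- order(-best_d, flat)
  w <- o[1]
  list(index = as.integer(vi[w, ]),
       location_cm = dose$origin_cm + (vi[w, ] - 1) * vox,
       distance_cm = best_d[w])
}

#' Reference-point dose difference between two dose grids
#'
#' Percent difference `(d_eval - d_ref)/d_ref * 100` at the deep reference
#' point of the reference distribution.
#'
#' @param reference,evaluated `dose_grid`s on the same grid.
#' @return list with `point` (from [reference_point()]) and
#'   `diff_percent`.
#' @export
reference_point_diff <- function(reference, evaluated) {
  rp <- reference_point(reference)
  i <- rp$index
  dr <- reference$dose[i[1], i[2], i[3]]
  de <- evaluated$dose[i[1], i[2], i[3]]
  list(point = rp, diff_percent = 100 * (de - dr) / dr)
}
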