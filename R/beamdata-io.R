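# Beam-data, plan, phantom and dose containers with their file formats.
#
# Coordinate conventions: right-handed beam's-eye-view frame on the
# source-to-axis-distance (SAD) plane, origin on the central axis,
# x = leaf-travel direction.  Files carry millimetres; everything in memory
# is centimetres.  Grids are cell-centered with 0-based indexing.

#' Percent depth-dose curve
#'
#' @param depth_cm strictly increasing depths (cm), >= 0.
#' @param value dose values; renormalized so the maximum is exactly 100.
#' @return a `pdd_curve` with fields `depth_cm`, `value`.
#' @export
pdd_curve <- function(depth_cm, value) {
  depth_cm <- as.numeric(depth_cm); value <- as.numeric(value)
  if (length(depth_cm) != length(value) || length(value) < 2)
    stop("PDD needs >= 2 (depth, value) pairs")
  if (any(depth_cm < 0)) stop("PDD depths must be >= 0")
  if (any(diff(depth_cm) <= 0)) stop("PDD depths must be strictly increasing")
  if (max(value) <= 0) stop("PDD has no positive values")
  structure(list(depth_cm = depth_cm, value = 100 * value / max(value)),
            class = "pdd_curve")
}

#' Depth of maximum of a PDD curve
#' @param pdd a `pdd_curve`.
#' @return depth in cm of the (first) maximum.
#' @export
pdd_dmax <- function(pdd) pdd$depth_cm[which.max(pdd$value)]

#' Lateral profile curve on the SAD plane
#'
#' Signed offsets on the measurement plane geometrically projected to SAD
#' scale, values normalized to the central-axis value unless
#' `normalize = FALSE` (cross-profiles quoted in percent of the reference
#' field maximum keep their absolute scale).
#'
#' @param offset_cm signed offsets (cm), strictly increasing.
#' @param value profile values.
#' @param normalize divide by the value interpolated at offset 0.
#' @return a `profile_curve` with fields `offset_cm`, `value`.
#' @export
profile_curve <- function(offset_cm, value, normalize = TRUE) {
  offset_cm <- as.numeric(offset_cm); value <- as.numeric(value)
  if (length(offset_cm) != length(value) || length(value) < 2)
    stop("profile needs >= 2 points")
  if (any(diff(offset_cm) <= 0)) stop("profile offsets must be strictly increasing")
  if (normalize) {
    c0 <- stats::approx(offset_cm, value, xout = 0, rule = 2)$y
    if (!is.finite(c0) || c0 <= 0) stop("profile cannot be normalized at the center")
    value <- value / c0
  }
  structure(list(offset_cm = offset_cm, value = value), class = "profile_curve")
}

#' Total-scatter (output factor) table for square fields
#'
#' @param field_cm square field sides (cm), strictly increasing; must include
#'   the 10x10 reference field.
#' @param scp total scatter factors; renormalized so Scp(10) = 1.
#' @param d_ref_cm reference measurement depth (cm).
#' @return an `of_table` with fields `field_cm`, `scp`, `d_ref_cm`.
#' @export
of_table <- function(field_cm, scp, d_ref_cm) {
  field_cm <- as.numeric(field_cm); scp <- as.numeric(scp)
  if (length(field_cm) != length(scp) || length(scp) < 2)
    stop("output-factor table needs >= 2 fields")
  o <- order(field_cm)
  field_cm <- field_cm[o]; scp <- scp[o]
  if (any(diff(field_cm) <= 0)) stop("duplicate field sizes in output-factor table")
  i10 <- which(abs(field_cm - 10) < 1e-9)
  if (length(i10) != 1)
    stop("output-factor table is missing the 10x10 reference entry")
  if (any(diff(scp) <= 0))
    stop("Scp must be strictly increasing in field size")
  structure(list(field_cm = field_cm, scp = scp / scp[i10],
                 d_ref_cm = as.numeric(d_ref_cm)),
            class = "of_table")
}

#' Water-phantom beam data set
#'
#' The three measured inputs to commissioning -- the reference-field PDD,
#' the diagonal profile of the largest open field at d_max, and the square
#' -field output-factor table -- plus machine metadata.
#'
#' @param pdd_ref `pdd_curve` for the 10x10 cm^2 reference field.
#' @param diagonal_profile `profile_curve` of the largest open field at
#'   d_max, offsets on SAD scale.
#' @param scp_table `of_table` at the reference depth.
#' @param machine list with `sad_cm`, `ssd_cm`, `d_ref_cm`, `d_max_cm`,
#'   `largest_field_cm`, `energy_label`.
#' @return a `beam_data_set`.
#' @export
beam_data_set <- function(pdd_ref, diagonal_profile, scp_table, machine) {
  stopifnot(inherits(pdd_ref, "pdd_curve"),
            inherits(diagonal_profile, "profile_curve"),
            inherits(scp_table, "of_table"))
  need <- c("sad_cm", "ssd_cm", "d_ref_cm", "d_max_cm", "largest_field_cm",
            "energy_label")
  miss <- setdiff(need, names(machine))
  if (length(miss)) stop("machine metadata missing: ", paste(miss, collapse = ", "))
  if (max(pdd_ref$depth_cm) < 30)
    stop("reference PDD must extend to at least 30 cm depth")
  if (pdd_ref$depth_cm[1] > 1)
    stop("reference PDD must start within 1 cm of the surface")
  half_diag <- machine$largest_field_cm * sqrt(2) / 2
  if (max(abs(diagonal_profile$offset_cm)) < half_diag - 1e-6)
    stop(sprintf("diagonal profile must cover the half-diagonal (%.2f cm) of the largest field",
                 half_diag))
  structure(list(pdd_ref = pdd_ref, diagonal_profile = diagonal_profile,
                 scp_table = scp_table, machine = machine),
            class = "beam_data_set")
}

#' @export
print.beam_data_set <- function(x, ...) {
  cat(sprintf("<beam_data_set> %s, SAD %g / SSD %g cm, d_ref %g cm, largest field %g cm\n",
              x$machine$energy_label, x$machine$sad_cm, x$machine$ssd_cm,
              x$machine$d_ref_cm, x$machine$largest_field_cm))
  cat(sprintf("  PDD: %d depths to %.0f cm; diagonal: %d pts; Scp fields: %s cm\n",
              length(x$pdd_ref$depth_cm), max(x$pdd_ref$depth_cm),
              length(x$diagonal_profile$offset_cm),
              paste(x$scp_table$field_cm, collapse = "/")))
  invisible(x)
}

#' Write / read a beam data set
#'
#' One CSV per curve plus a JSON manifest (`manifest.json`) in `dir`.
#' Files carry millimetres; readers convert to centimetres and renormalize
#' (PDD max to 100, Scp to the 10x10 entry).
#'
#' @param bd a `beam_data_set`.
#' @param dir directory to create/use.
#' @return `read_beam_data` returns the validated `beam_data_set`.
#' @export
write_beam_data <- function(bd, dir) {
  stopifnot(inherits(bd, "beam_data_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(depth_mm = bd$pdd_ref$depth_cm * 10,
                              value = bd$pdd_ref$value),
                   file.path(dir, "pdd_10x10.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(offset_mm = bd$diagonal_profile$offset_cm * 10,
                              value = bd$diagonal_profile$value),
                   file.path(dir, "diagonal.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(field_mm = bd$scp_table$field_cm * 10,
                              scp = bd$scp_table$scp),
                   file.path(dir, "scp.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(format = "beamforge-beamdata-1",
                   machine = bd$machine,
                   files = list(pdd = "pdd_10x10.csv", diagonal = "diagonal.csv",
                                scp = "scp.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_beam_data
#' @param path path to the manifest JSON (or its directory).
#' @export
read_beam_data <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("beam data manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$format) || !identical(m$format, "beamforge-beamdata-1"))
    stop("not a beamforge beam-data manifest: ", path)
  dir <- dirname(path)
  pdd <- utils::read.csv(file.path(dir, m$files$pdd))
  dia <- utils::read.csv(file.path(dir, m$files$diagonal))
  scp <- utils::read.csv(file.path(dir, m$files$scp))
  if (!all(c("depth_mm", "value") %in% names(pdd)))
    stop("PDD file must have columns depth_mm,value")
  if (!any(abs(scp$field_mm - 100) < 1e-6))
    stop("Scp table is missing the field_mm=100 (10x10 cm) row")
  beam_data_set(
    pdd_curve(pdd$depth_mm / 10, pdd$value),
    profile_curve(dia$offset_mm / 10, dia$value),
    of_table(scp$field_mm / 10, scp$scp, m$machine$d_ref_cm),
    m$machine
  )
}

# ---------------------------------------------------------------- plans ----

#' Read a treatment-plan segment file
#'
#' Documented JSON dialect:
#' \preformatted{
#' {"format": "beamforge-plan-1",
#'  "beams": [
#'    {"gantry_deg": 0,
#'     "grid": {"x0_mm": -110, "y0_mm": -110, "nx": 220, "ny": 220},
#'     "segments": [
#'       {"mu": 100,
#'        "leaves": {"leaf_width_mm": 5, "y0_mm": -100,
#'                   "bank_a": [x..], "bank_b": [x..]}},
#'       {"mu": 50, "mask_csv": "mask.csv"}
#'     ]}]}
#' }
#' Leaf positions are millimetres on the SAD plane; leaf `i` (1-based)
#' covers y in `[y0 + (i-1) w, y0 + i w)` and is open for
#' `bank_a[i] < x < bank_b[i]`.  Apertures are rasterized onto the common
#' 1 mm beam grid (a pixel is open when its center is open);
#' `mask_csv` is a headerless 0/1 matrix (rows = y, columns = x) on the
#' beam grid, resolved relative to the plan file.  All segments of a beam
#' share the beam grid.
#'
#' @param path plan JSON file.
#' @return a `plan_set`: list of beams, each with `gantry_deg`, `grid`
#'   (`x_cm`, `y_cm` pixel centers) and `segments` (each `mu` + logical
#'   `mask` indexed `[x, y]`).
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(p$format) || !identical(p$format, "beamforge-plan-1"))
    stop("not a beamforge plan file: ", path)
  beams <- lapply(p$beams, function(b) {
    g <- b$grid
    if (is.null(g)) g <- list(x0_mm = -110, y0_mm = -110, nx = 220, ny = 220)
    x_cm <- (g$x0_mm + (seq_len(g$nx) - 0.5)) / 10
    y_cm <- (g$y0_mm + (seq_len(g$ny) - 0.5)) / 10
    segs <- lapply(b$segments, function(s) {
      mu <- as.numeric(s$mu)
      if (!is.finite(mu) || mu < 0) stop("segment MU must be >= 0")
      if (!is.null(s$leaves)) {
        mask <- rasterize_leaves(s$leaves, x_cm, y_cm)
      } else if (!is.null(s$mask_csv)) {
        mm <- as.matrix(utils::read.csv(file.path(dirname(path), s$mask_csv),
                                        header = FALSE))
        if (nrow(mm) != g$ny || ncol(mm) != g$nx)
          stop("mask_csv dimensions do not match the beam grid")
        mask <- t(mm) > 0.5   # file rows are y; internal layout is [x, y]
      } else stop("segment needs either 'leaves' or 'mask_csv'")
      if (!any(mask)) warning("segment rasterizes to an empty aperture")
      list(mu = mu, mask = mask)
    })
    list(gantry_deg = if (is.null(b$gantry_deg)) 0 else as.numeric(b$gantry_deg),
         grid = list(x_cm = x_cm, y_cm = y_cm), segments = segs)
  })
  structure(list(beams = beams), class = "plan_set")
}

rasterize_leaves <- function(lv, x_cm, y_cm) {
  a <- as.numeric(lv$bank_a) / 10; b <- as.numeric(lv$bank_b) / 10
  if (length(a) != length(b)) stop("leaf banks must have equal length")
  if (any(b < a)) stop("leaf bank_b positions must be >= bank_a")
  w <- as.numeric(lv$leaf_width_mm) / 10
  y0 <- as.numeric(lv$y0_mm) / 10
  mask <- matrix(FALSE, length(x_cm), length(y_cm))
  idx <- floor((y_cm - y0) / w) + 1
  ok <- idx >= 1 & idx <= length(a)
  for (j in which(ok)) {
    i <- idx[j]
    mask[, j] <- x_cm > a[i] & x_cm < b[i]
  }
  mask
}

# ------------------------------------------------- phantom, fields, dose ----

#' Voxel phantom
#'
#' @param density 3-D array of mass density (g/cm^3), indexed `[x, y, z]`
#'   with z along the beam axis (depth).
#' @param voxel_cm length-3 voxel size (cm).
#' @param origin_cm length-3 position (cm) of the center of voxel (1,1,1);
#'   z = 0 is the phantom surface on the central axis.
#' @return a `voxel_phantom`.
#' @export
voxel_phantom <- function(density, voxel_cm, origin_cm = NULL) {
  density <- as.array(density)
  if (length(dim(density)) != 3 || any(dim(density) < 1))
    stop("density must be a non-empty 3-D array")
  if (any(density < 0)) stop("density must be >= 0")
  voxel_cm <- as.numeric(voxel_cm)
  if (length(voxel_cm) != 3 || any(voxel_cm <= 0)) stop("voxel_cm must be 3 positive sizes")
  if (is.null(origin_cm))
    origin_cm <- c(-(dim(density)[1] - 1) / 2 * voxel_cm[1],
                   -(dim(density)[2] - 1) / 2 * voxel_cm[2],
                   voxel_cm[3] / 2)
  structure(list(density = density, voxel_cm = voxel_cm,
                 origin_cm = as.numeric(origin_cm)),
            class = "voxel_phantom")
}

#' Homogeneous water phantom
#'
#' @param size_cm length-3 physical extent (cm), x/y centered on the axis.
#' @param voxel_cm length-3 voxel size (cm), default 2 mm cubes.
#' @param density water-equivalent density (g/cm^3).
#' @return a `voxel_phantom`.
#' @export
water_phantom <- function(size_cm = c(30, 30, 35), voxel_cm = c(0.2, 0.2, 0.2),
                          density = 1) {
  n <- pmax(1L, as.integer(round(size_cm / voxel_cm)))
  voxel_phantom(array(density, dim = n), voxel_cm)
}

#' Static magnetic-field volume
#'
#' @param bx,by,bz 3-D arrays (tesla) with the same dimensions as the
#'   phantom density grid.
#' @param phantom the `voxel_phantom` the field is defined on.
#' @return a `b_field`.
#' @export
b_field <- function(bx, by, bz, phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  d <- dim(phantom$density)
  for (a in list(bx, by, bz))
    if (!identical(dim(as.array(a)), d))
      stop("magnetic-field volumes must match the phantom dimensions")
  structure(list(bx = bx, by = by, bz = bz, dim = d), class = "b_field")
}

#' Uniform magnetic field on a phantom grid
#' @param b_tesla length-3 field vector (T).
#' @param phantom a `voxel_phantom`.
#' @return a `b_field`.
#' @export
uniform_b_field <- function(b_tesla, phantom) {
  d <- dim(phantom$density)
  b_field(array(b_tesla[1], d), array(b_tesla[2], d), array(b_tesla[3], d),
          phantom)
}

#' Dose grid
#'
#' @param dose 3-D array of dose scores, `[x, y, z]`.
#' @param voxel_cm length-3 voxel size (cm).
#' @param origin_cm length-3 center of voxel (1,1,1) (cm).
#' @param uncertainty 3-D array of relative statistical uncertainty
#'   (fraction), same dimensions; 0 where undefined.
#' @param component `"photon"`, `"electron"` or `"combined"`.
#' @return a `dose_grid`.
#' @export
dose_grid <- function(dose, voxel_cm, origin_cm, uncertainty = NULL,
                      component = "combined") {
  dose <- as.array(dose)
  if (length(dim(dose)) != 3 || any(dim(dose) < 1))
    stop("dose must be a non-empty 3-D array")
  if (any(!is.finite(dose))) stop("dose contains non-finite values")
  if (any(dose < 0)) stop("dose must be >= 0")
  if (is.null(uncertainty)) uncertainty <- array(0, dim(dose))
  if (!identical(dim(as.array(uncertainty)), dim(dose)))
    stop("uncertainty dimensions must match dose")
  component <- match.arg(component, c("photon", "electron", "combined"))
  structure(list(dose = dose, voxel_cm = as.numeric(voxel_cm),
                 origin_cm = as.numeric(origin_cm),
                 uncertainty = uncertainty, component = component),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid:%s> %s voxels @ %s mm, max %.4g, mean rel. unc. %.2f%%\n",
              x$component, paste(dim(x$dose), collapse = "x"),
              paste(format(x$voxel_cm * 10), collapse = "x"),
              max(x$dose),
              100 * mean(x$uncertainty[x$dose > 0.5 * max(x$dose)])))
  invisible(x)
}

#' Write / read a dose grid
#'
#' Raw little-endian float64 voxel data (dose then uncertainty) with a JSON
#' sidecar header (`<path>.json`) holding dimensions, voxel size, origin,
#' component and byte order.  The round-trip is lossless.
#'
#' @param dose a `dose_grid`.
#' @param path binary file path; the header goes to `paste0(path, ".json")`.
#' @return `read_dose` returns the `dose_grid`.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  hdr <- list(format = "beamforge-dose-1", dims = dim(dose$dose),
              voxel_mm = dose$voxel_cm * 10, origin_mm = dose$origin_cm * 10,
              component = dose$component, dtype = "float64",
              byte_order = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(dose$dose), con, size = 8, endian = "little")
  writeBin(as.vector(dose$uncertainty), con, size = 8, endian = "little")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dose
#' @export
read_dose <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) stop("dose header not found: ", hdr_path)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (!identical(hdr$format, "beamforge-dose-1"))
    stop("not a beamforge dose file: ", path)
  dims <- as.integer(hdr$dims)
  n <- prod(dims)
  expect_bytes <- 2 * n * 8
  if (file.info(path)$size != expect_bytes)
    stop(sprintf("dose payload size mismatch: expected %d bytes, found %d",
                 expect_bytes, file.info(path)$size))
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "double", n = n, size = 8, endian = "little")
  u <- readBin(con, "double", n = n, size = 8, endian = "little")
  dose_grid(array(d, dims), hdr$voxel_mm / 10, hdr$origin_mm / 10,
            array(u, dims), hdr$component)
}
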