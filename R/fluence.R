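# Plan/segment fluence calculation on the SAD plane:
#   1. segment intensity  I = sum_i M_i T_i,  with
#      T_i = 1 on S_i minus its y-boundary, alpha on the y-boundary
#      (tongue-and-groove), beta outside S_i (leakage/transmission);
#   2. off-axis scaling   I <- I * C;
#   3. collimator scatter f = I (x) K  (discrete 2-D convolution);
#   4. energy weighting   fg ~ f(x,y) * g(E)  (separable joint density).

#' Fluence map on the SAD plane
#'
#' @param values matrix `[x, y]` on the common 1 mm beam grid.
#' @param x_cm,y_cm pixel-center coordinates (cm).
#' @param stage one of `"intensity"`, `"scaled"`, `"fluence"`.
#' @return a `fluence_map`.
#' @export
fluence_map <- function(values, x_cm, y_cm, stage = "intensity") {
  values <- as.matrix(values)
  if (any(values < 0)) stop("fluence values must be >= 0")
  if (nrow(values) != length(x_cm) || ncol(values) != length(y_cm))
    stop("fluence grid/axis mismatch")
  stage <- match.arg(stage, c("intensity", "scaled", "fluence"))
  structure(list(values = values, x_cm = x_cm, y_cm = y_cm,
                 px_cm = x_cm[2] - x_cm[1], stage = stage),
            class = "fluence_map")
}

#' Segment-intensity correction model
#'
#' @param alpha tongue-and-groove factor on y-direction boundary pixels
#'   (default 0.75).
#' @param beta leakage/transmission factor outside the aperture (default 0).
#' @param boundary_px boundary width in pixels (default 1).
#' @return a `segment_model`.
#' @export
segment_model <- function(alpha = 0.75, beta = 0, boundary_px = 1L) {
  if (!(beta >= 0 && beta <= alpha && alpha <= 1))
    stop("need 0 <= beta <= alpha <= 1")
  if (boundary_px < 0) stop("boundary width must be >= 0 pixels")
  structure(list(alpha = alpha, beta = beta, boundary_px = as.integer(boundary_px)),
            class = "segment_model")
}

#' y-direction boundary of an aperture mask
#'
#' Pixels of the aperture whose neighbor within `width` pixels along y
#' (the direction across the leaves; leaf motion is along x) lies outside
#' the aperture.  4-connectivity in y only.
#'
#' @param mask logical aperture matrix `[x, y]`.
#' @param width boundary width in pixels.
#' @return logical matrix of boundary membership.
#' @export
segment_boundary <- function(mask, width = 1L) {
  mask <- mask > 0
  if (width < 1) return(mask & FALSE)
  ny <- ncol(mask)
  out <- mask & FALSE
  for (k in seq_len(width)) {
    # beyond the grid there is no leaf edge: pad as in-field
    up <- cbind(mask[, -seq_len(k), drop = FALSE],
                matrix(TRUE, nrow(mask), k))
    dn <- cbind(matrix(TRUE, nrow(mask), k),
                mask[, seq_len(ny - k), drop = FALSE])
    out <- out | (mask & (!up | !dn))
  }
  out
}

#' Segment intensity of one beam
#'
#' `I = sum_i M_i T_i` over the beam's segments, with `T_i` equal to 1 in
#' the aperture interior, `alpha` on the y-direction aperture boundary and
#' `beta` outside the aperture.
#'
#' @param beam one element of a `plan_set$beams` list (fields `grid`,
#'   `segments`).
#' @param model a `segment_model`.
#' @return a `fluence_map` (stage `"intensity"`).
#' @export
segment_intensity <- function(beam, model = segment_model()) {
  stopifnot(inherits(model, "segment_model"))
  grid <- beam$grid
  nx <- length(grid$x_cm); ny <- length(grid$y_cm)
  acc <- matrix(0, nx, ny)
  for (seg in beam$segments) {
    if (!identical(dim(seg$mask), c(nx, ny)))
      stop("segment mask does not match the beam grid")
    s <- seg$mask > 0
    b <- segment_boundary(s, model$boundary_px)
    t_i <- ifelse(s & !b, 1, ifelse(b, model$alpha, model$beta))
    acc <- acc + seg$mu * t_i
  }
  fluence_map(acc, grid$x_cm, grid$y_cm, "intensity")
}

#' Scale an intensity map by the OAS
#'
#' @param I a `fluence_map`.
#' @param C an `oas_map`, evaluated bilinearly on the fluence grid.
#' @return a `fluence_map` (stage `"scaled"`).
#' @export
apply_oas <- function(I, C) {
  stopifnot(inherits(I, "fluence_map"), inherits(C, "oas_map"))
  g <- expand.grid(x = I$x_cm, y = I$y_cm)
  cv <- matrix(oas_at(C, g$x, g$y), nrow(I$values), ncol(I$values))
  fluence_map(I$values * cv, I$x_cm, I$y_cm, "scaled")
}

#' Convolve an intensity map with the collimator-scatter kernel
#'
#' Discrete 2-D convolution with zero padding,
#' `f(x) = sum_u I(x-u) K(u) px^2` (the kernel is a density per cm^2).
#' Direct summation is used for kernels up to 15 pixels wide, FFT-based
#' (cyclic convolution on a zero-padded grid) otherwise; both routes agree
#' to better than 1e-8 relative.
#'
#' @param I a `fluence_map`.
#' @param K a `scatter_kernel` on the same pixel size.
#' @param method `"auto"`, `"direct"` or `"fft"`.
#' @return a `fluence_map` (stage `"fluence"`).
#' @export
convolve_fluence <- function(I, K, method = c("auto", "direct", "fft")) {
  stopifnot(inherits(I, "fluence_map"), inherits(K, "scatter_kernel"))
  method <- match.arg(method)
  if (abs(I$px_cm - K$px_cm) > 1e-9)
    stop("fluence and kernel pixel sizes differ")
  nk <- nrow(K$values)
  if (method == "auto") method <- if (nk > 15) "fft" else "direct"
  vals <- if (method == "direct") {
    conv2_direct(I$values, K$values)
  } else {
    conv2_fft(I$values, K$values)
  }
  vals <- vals * K$px_cm^2
  vals[vals < 0 & vals > -1e-9 * max(abs(vals))] <- 0  # fft roundoff
  fluence_map(vals, I$x_cm, I$y_cm, "fluence")
}

conv2_direct <- function(a, k) {
  nk <- nrow(k); h <- (nk - 1) / 2
  nx <- nrow(a); ny <- ncol(a)
  out <- matrix(0, nx, ny)
  for (di in -h:h) for (dj in -h:h) {
    kv <- k[di + h + 1, dj + h + 1]
    if (kv == 0) next
    si <- max(1, 1 + di):min(nx, nx + di)
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    out[si - di, sj - dj] <- out[si - di, sj - dj] + kv * a[si, sj]
  }
  out
}

conv2_fft <- function(a, k) {
  nk <- nrow(k); h <- (nk - 1) / 2
  nx <- nrow(a) + nk - 1; ny <- ncol(a) + nk - 1
  nx2 <- stats::nextn(nx, c(2, 3, 5)); ny2 <- stats::nextn(ny, c(2, 3, 5))
  pa <- matrix(0, nx2, ny2); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pk <- matrix(0, nx2, ny2); pk[seq_len(nk), seq_len(nk)] <- k
  cc <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / (nx2 * ny2)
  cc[h + seq_len(nrow(a)), h + seq_len(ncol(a))]
}

#' Weight a fluence map by the energy spectrum
#'
#' Forms the separable joint sampling density over (pixel, energy bin)
#' proportional to `f(x, y) * g(E)` -- the energy fluence the particle
#' source draws from.
#'
#' @param f a `fluence_map`.
#' @param g an `energy_spectrum`.
#' @return an `energy_fluence` with fields `f` (the map), `g` (the
#'   spectrum) and `total` (the spatial mass of `f`).
#' @export
energy_weight <- function(f, g) {
  stopifnot(inherits(f, "fluence_map"), inherits(g, "energy_spectrum"))
  total <- sum(f$values)
  if (total <= 0) stop("fluence map has zero total mass")
  structure(list(f = f, g = g, total = total), class = "energy_fluence")
}

#' Fluence for one beam of a plan
#'
#' Runs the three fluence steps (segment intensity, OAS scaling, kernel
#' convolution) for one beam with a commissioned model's OAS and kernel.
#'
#' @param beam one element of `plan_set$beams`.
#' @param C an `oas_map`.
#' @param K a `scatter_kernel` (or `NULL` to skip convolution, as in the
#'   phantom-scatter calculation).
#' @param model a `segment_model`.
#' @return a `fluence_map`.
#' @export
beam_fluence <- function(beam, C, K, model = segment_model()) {
  I <- segment_intensity(beam, model)
  I <- apply_oas(I, C)
  if (is.null(K)) {
    fluence_map(I$values, I$x_cm, I$y_cm, "fluence")
  } else {
    convolve_fluence(I, K)
  }
}

#' Write a fluence map to CSV (for inspection)
#'
#' Headerless matrix, rows = y, columns = x, preceded by a JSON sidecar
#' with the axes.
#' @param f a `fluence_map`.
#' @param path CSV path.
#' @export
write_fluence_csv <- function(f, path) {
  utils::write.table(t(f$values), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(x_mm = f$x_cm * 10, y_mm = f$y_cm * 10,
                            stage = f$stage),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
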