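# Segment intensity, boundary flagging, OAS scaling, convolution, energy
# weighting.

test_that("y-boundary flagging matches brute-force neighborhood enumeration", {
  # 10x10 mm square on a 30x30 grid
  n <- 30
  ax <- ((-n / 2):(n / 2 - 1) + 0.5) * 0.1
  mask <- outer(abs(ax) < 0.5, abs(ax) < 0.5)
  b <- segment_boundary(mask, 1L)
  # oracle: plain double loop over pixels and y-neighbors
  oracle <- mask & FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!mask[i, j]) next
    up <- if (j < n) mask[i, j + 1] else TRUE  # no y-edge at the grid limit
    dn <- if (j > 1) mask[i, j - 1] else TRUE
    oracle[i, j] <- !up || !dn
  }
  expect_identical(b, oracle)
  # a 10 mm square has 10 pixels on each y-edge
  expect_equal(sum(b), 20)
  # full-grid aperture: no y-edge inside the grid, so no boundary
  full <- matrix(TRUE, 5, 5)
  expect_equal(sum(segment_boundary(full, 1L)), 0)

  # two abutting apertures in y flag the shared edge on both sides
  m1 <- outer(rep(TRUE, 6), 1:10 %in% 1:5)
  m2 <- outer(rep(TRUE, 6), 1:10 %in% 6:10)
  b1 <- segment_boundary(m1); b2 <- segment_boundary(m2)
  expect_true(all(b1[, 5]))
  expect_true(all(b2[, 6]))
})

test_that("segment intensity applies Table-defaults alpha on the boundary and beta outside", {
  plan <- generate_plan("open_square", field_cm = 2, mu = 1, grid_half_cm = 2)
  beam <- plan$beams[[1]]
  I <- segment_intensity(beam, segment_model())  # alpha 0.75, beta 0
  ax <- beam$grid$x_cm
  ctr <- which.min(abs(ax))
  ytop <- max(which(abs(ax) < 1))          # topmost in-aperture row
  expect_equal(I$values[ctr, ctr], 1)
  expect_equal(I$values[ctr, ytop], 0.75)
  expect_equal(I$values[ctr, length(ax)], 0)
  # x-edges are NOT tongue-and-groove boundaries (leaf motion along x)
  xedge <- max(which(abs(ax) < 1))
  expect_equal(I$values[xedge, ctr], 1)

  # leakage beta scales with MU outside the aperture
  plan2 <- generate_plan("open_square", field_cm = 2, mu = 100, grid_half_cm = 2)
  I2 <- segment_intensity(plan2$beams[[1]], segment_model(beta = 0.02))
  expect_equal(I2$values[1, 1], 2)

  # linearity in MU: two identical segments with MU 2 and 3 give interior 5
  b2 <- plan$beams[[1]]
  b2$segments <- list(list(mu = 2, mask = beam$segments[[1]]$mask),
                      list(mu = 3, mask = beam$segments[[1]]$mask))
  I3 <- segment_intensity(b2)
  expect_equal(I3$values[ctr, ctr], 5)
})

test_that("open-field intensity total equals MU x (interior + alpha x boundary)", {
  plan <- generate_plan("open_square", field_cm = 3, mu = 7, grid_half_cm = 3)
  beam <- plan$beams[[1]]
  m <- beam$segments[[1]]$mask
  b <- segment_boundary(m)
  I <- segment_intensity(beam, segment_model(alpha = 0.75, beta = 0))
  expect_equal(sum(I$values), 7 * (sum(m & !b) + 0.75 * sum(b)),
               tolerance = 1e-12)
})

test_that("plan fluence is invariant to segment ordering", {
  plan <- generate_plan("step_and_shoot", field_cm = 4, mu = 50,
                        grid_half_cm = 4)
  beam <- plan$beams[[1]]
  beam_rev <- beam
  beam_rev$segments <- rev(beam$segments)
  expect_equal(segment_intensity(beam)$values,
               segment_intensity(beam_rev)$values, tolerance = 1e-12)
})

test_that("OAS scaling is pixel-wise and leaves the center unchanged", {
  f <- tiny_fluence()
  C1 <- oas_map(matrix(1, 61, 61))
  expect_equal(apply_oas(f, C1)$values, f$values, tolerance = 1e-12)
  # radially varying map: off-axis value = I * C by hand
  n <- 30
  ax <- (-n:n) * 0.1
  cv <- 1 - 0.05 * sqrt(outer(ax^2, ax^2, "+"))
  C2 <- oas_map(cv)
  out <- apply_oas(f, C2)
  ctr <- 21  # fluence grid center (41x41)
  expect_equal(out$values[ctr, ctr], f$values[ctr, ctr], tolerance = 1e-9)
  i <- ctr + 5  # x = 0.5 cm, y = 0
  expect_equal(out$values[i, ctr], f$values[i, ctr] * (1 - 0.05 * 0.5),
               tolerance = 1e-9)
})

test_that("convolution: identity kernel, analytic patch, linearity, FFT/direct agreement", {
  f <- tiny_fluence()
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1 / 0.1^2   # unit-mass impulse
  Ki <- scatter_kernel(imp)
  expect_equal(convolve_fluence(f, Ki, method = "direct")$values, f$values,
               tolerance = 1e-10)

  # constant k over 3x3 mm on a unit pixel: f = k * px^2 on the patch
  one <- fluence_map(`[<-`(matrix(0, 21, 21), 11, 11, 1),
                     (-10:10) / 10, (-10:10) / 10)
  Kc <- scatter_kernel(matrix(2, 3, 3))
  out <- convolve_fluence(one, Kc, method = "direct")
  expect_equal(out$values[10:12, 10:12], matrix(2 * 0.01, 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(out$values > 0), 9)

  # linearity
  f2 <- tiny_fluence(field_cm = 1.2)
  dn <- stats::dnorm(seq(-2, 2, length.out = 9))
  K <- scatter_kernel(outer(dn, dn))
  lhs <- convolve_fluence(
    fluence_map(2 * f$values + 3 * f2$values, f$x_cm, f$y_cm), K)
  rhs <- 2 * convolve_fluence(f, K)$values + 3 * convolve_fluence(f2, K)$values
  expect_equal(lhs$values, rhs, tolerance = 1e-10)

  # FFT and direct routes agree
  big <- scatter_kernel(matrix(1, 41, 41) * exp(-as.matrix(
    sqrt(outer(((-20:20) * .1)^2, ((-20:20) * .1)^2, "+")))))
  a <- convolve_fluence(f, big, method = "direct")$values
  b <- convolve_fluence(f, big, method = "fft")$values
  expect_lt(max(abs(a - b)) / max(a), 1e-8)
})

test_that("convolution conserves mass up to kernel leakage off the grid", {
  f <- tiny_fluence(half_cm = 3, field_cm = 2)
  K <- golden_kernel(golden_machine(), support_cm = 2)
  out <- convolve_fluence(f, K)
  kmass <- sum(K$values) * K$px_cm^2
  expect_lte(sum(out$values), sum(f$values) * kmass + 1e-9)
  # central field far from edges: loss only from the truncated tail
  expect_gt(sum(out$values) / (sum(f$values) * kmass), 0.98)
})

test_that("energy weighting is a separable density with the right marginals", {
  f <- tiny_fluence()
  g <- two_bin_spectrum()
  fg <- energy_weight(f, g)
  expect_equal(fg$total, sum(f$values))
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  # joint mass = sum(f) x sum(g) = sum(f)
  expect_equal(fg$total * sum(fg$g$weight), sum(f$values))
  expect_error(energy_weight(fluence_map(matrix(0, 3, 3), 1:3, 1:3), g),
               "zero")
})

test_that("multi-beam plans yield independent per-beam fluences", {
  p1 <- generate_plan("open_square", field_cm = 4, mu = 30, grid_half_cm = 4)
  p2 <- generate_plan("step_and_shoot", field_cm = 4, mu = 60,
                      grid_half_cm = 4)
  two <- structure(list(beams = c(p1$beams, p2$beams)), class = "plan_set")
  C <- oas_map(matrix(1, 81, 81))
  f1 <- beam_fluence(two$beams[[1]], C, NULL)
  f2 <- beam_fluence(two$beams[[2]], C, NULL)
  expect_equal(f1$values, beam_fluence(p1$beams[[1]], C, NULL)$values,
               tolerance = 1e-12)
  expect_equal(f2$values, beam_fluence(p2$beams[[1]], C, NULL)$values,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$values, f2$values)))
})
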