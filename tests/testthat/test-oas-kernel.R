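# Off-axis-scale map, Sc extraction/interpolation and kernel derivation.

test_that("build_oas rotates the diagonal profile radially", {
  off <- seq(-15, 15, by = 0.1)
  # h(r) = 1 - 0.01 r  ->  C0(3,4) = 0.95 (r = 5 by hand)
  h <- profile_curve(off, 1 - 0.01 * abs(off))
  C0 <- build_oas(h, half_size_cm = 10)
  expect_equal(oas_at(C0, 0, 0), 1, tolerance = 1e-9)
  expect_equal(oas_at(C0, 3, 4), 0.95, tolerance = 1e-6)
  # flat profile -> flat map
  Cf <- build_oas(profile_curve(off, rep(1, length(off))), half_size_cm = 5)
  expect_true(all(abs(Cf$values - 1) < 1e-12))
  # beyond support the value is clamped to the last sample
  C2 <- build_oas(h, half_size_cm = 20)
  expect_equal(oas_at(C2, 19, 0), 1 - 0.01 * 15, tolerance = 1e-6)
  # unnormalized profiles are rejected
  expect_error(build_oas(profile_curve(off, 2 - 0.01 * abs(off),
                                       normalize = FALSE)),
               "normalized")
})

test_that("update_oas applies the radial measured/calculated ratio and renormalizes", {
  off <- seq(-12, 12, by = 0.1)
  h0v <- 1 - 0.005 * off^2 / 12
  h0 <- profile_curve(off, h0v)
  C0 <- build_oas(h0, half_size_cm = 10)
  # h == h0 -> unchanged
  C1 <- update_oas(C0, h0, h0, fit_degree = NULL)
  expect_equal(C1$values, C0$values, tolerance = 1e-9)
  # uniform 2% rescale cancels after center renormalization
  h <- profile_curve(off, 1.02 * h0v, normalize = FALSE)
  C2 <- update_oas(C0, h, h0, fit_degree = NULL)
  expect_equal(C2$values, C0$values, tolerance = 1e-9)
  # a genuine shape change moves the map toward the measurement
  hs <- profile_curve(off, h0v * (1 - 0.01 * abs(off) / 12))
  C3 <- update_oas(C0, hs, h0, fit_degree = NULL)
  expect_lt(oas_at(C3, 8, 0), oas_at(C0, 8, 0))
  # nonpositive calculated profile -> degenerate error
  bad <- profile_curve(off, ifelse(abs(off) > 8, -0.1, 1),
                       normalize = FALSE)
  expect_error(update_oas(C0, h0, bad), "degenerate")
})

test_that("Sc extraction divides Scp by Sp with 10x10 normalization", {
  scp <- of_table(c(2, 3, 5, 10, 20), c(0.90, 0.93, 0.96, 1, 1.03), 10)
  # Scp == Sp -> Sc identically 1
  sc1 <- extract_sc(scp, scp$scp)
  expect_equal(sc1$sc, rep(1, 5), tolerance = 1e-12)
  # hand division: Scp(5) = 0.95, Sp(5) = 0.97 -> Sc(5) = 0.9794
  scp2 <- of_table(c(5, 10), c(0.95, 1), 10)
  sc2 <- extract_sc(scp2, c(0.97, 1))
  expect_equal(sc2$sc[1], 0.95 / 0.97, tolerance = 1e-9)
  expect_equal(sc2$sc[2], 1)
  expect_error(extract_sc(scp, c(-1, 1, 1, 1, 1)), "positive")
})

test_that("Sc surface: diagonal consistency, geometric-mean rule, monotonicity", {
  f <- c(2, 3, 5, 10, 20)
  # Sc(f) = f^2/100 -> Sc(fx, fy) = fx*fy/100 under the equivalent square
  surf <- interpolate_sc_surface(f, f^2 / 100)
  for (ff in f) expect_equal(sc_surface_at(surf, ff, ff), ff^2 / 100,
                             tolerance = 1e-9)
  expect_equal(sc_surface_at(surf, 4, 9), 36 / 100, tolerance = 5e-3)
  # monotone nondecreasing in fx at fixed fy
  sc_fx <- sc_surface_at(surf, seq(1, 20, by = 0.5), 7)
  expect_true(all(diff(sc_fx) >= -1e-12))
  # clamped extrapolation warns
  expect_warning(sc_surface_at(surf, 25, 25), "clamped")
  # noisy non-monotone input is rejected unless monotonized
  expect_error(interpolate_sc_surface(f, c(0.95, 0.97, 0.96, 1, 1.01)),
               "nondecreasing")
  s2 <- interpolate_sc_surface(f, c(0.95, 0.97, 0.96, 1, 1.01),
                               monotonize = TRUE)
  expect_true(all(diff(s2$sc_square) >= 0))
})

test_that("a constant kernel solves the integral equation Sc = k fx fy exactly", {
  # Sc(fx,fy) = k fx fy with C == 1 has the analytic solution K == k
  k <- 0.011
  f <- c(2, 3, 5, 8)
  surf <- interpolate_sc_surface(f, k * f^2)
  n <- 41
  C1 <- oas_map(matrix(1, 2 * 80 + 1, 2 * 80 + 1))
  K <- derive_kernel(surf, C1, support_cm = 4, rt_tol = 0.02)
  inner <- K$values[21:61, 21:61]   # away from the clamped surface edge
  expect_lt(max(abs(inner - k)) / k, 0.05)
  # round-trip at the measured fields
  rt <- attr(K, "roundtrip")
  expect_lt(max(rt$rel_err), 0.01)
})

test_that("derived kernels are circularly symmetric with monotone falloff", {
  gm <- golden_machine()
  Kt <- golden_kernel(gm, support_cm = 6)
  C <- golden_oas(gm)
  sc <- vapply(gm$fields_cm, function(f) integrate_kernel_field(Kt, C, f), 0)
  surf <- interpolate_sc_surface(gm$fields_cm, sc / sc[4])
  K <- derive_kernel(surf, C, support_cm = 6)
  # symmetry: pixels at exactly equal radii carry exactly equal values
  n <- (nrow(K$values) + 1) / 2
  equal_r <- list(rbind(c(10, 0), c(0, 10), c(-10, 0), c(6, 8), c(-8, -6)),
                  rbind(c(5, 0), c(0, -5), c(3, 4), c(-4, 3)),
                  rbind(c(20, 0), c(12, 16), c(0, -20)))
  for (grp in equal_r) {
    vals <- apply(grp, 1, function(p) K$values[n + p[1], n + p[2]])
    expect_lt(diff(range(vals)), 1e-12)
  }
  # radially binned falloff outside the central pixel is nonincreasing
  rp <- radial_profile(K)
  tail_vals <- rp$value[rp$r_cm > 0.05]
  expect_true(all(diff(tail_vals) <= 1e-9))
  expect_gt(K$values[n, n], max(tail_vals))  # central impulse dominates
  # derivation failure surfaces as a diagnostic error when the round-trip
  # cannot hold
  expect_error(derive_kernel(surf, C, support_cm = 6, rt_tol = 1e-9),
               "round-trip")
})

test_that("golden-machine closed loop: derived kernel reproduces Sc and approximates K*", {
  gm <- golden_machine()
  Kt <- golden_kernel(gm)
  C <- golden_oas(gm)
  sc <- vapply(gm$fields_cm, function(f) integrate_kernel_field(Kt, C, f), 0)
  sc <- sc / sc[which(gm$fields_cm == 10)]
  surf <- interpolate_sc_surface(gm$fields_cm, sc)
  K <- derive_kernel(surf, C)
  rt <- attr(K, "roundtrip")
  expect_lt(max(rt$rel_err), 0.005)   # the integral-equation round trip
  # pointwise recovery, scaled by the kernel peak (the impulse cannot be
  # localized below the smallest measured field)
  expect_lt(sqrt(mean((K$values - Kt$values)^2)) / max(Kt$values), 0.02)
})
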