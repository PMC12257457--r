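# Curve extraction, gamma index, reference point.

synthetic_exp_dose <- function(mu = 0.05, dims = c(21, 21, 60), vox = 0.2) {
  z <- (seq_len(dims[3]) - 1) * vox + vox / 2
  d <- array(rep(exp(-mu * z), each = dims[1] * dims[2]), dims)
  dose_grid(d, rep(vox, 3),
            c(-(dims[1] - 1) / 2 * vox, -(dims[2] - 1) / 2 * vox, vox / 2))
}

test_that("extract_pdd recovers a synthetic exponential decay and normalizes to 100", {
  dg <- synthetic_exp_dose(mu = 0.05)
  p <- extract_pdd(dg)
  expect_equal(max(p$value), 100)
  fit <- stats::lm(log(p$value) ~ p$depth_cm)
  expect_lt(abs(-stats::coef(fit)[2] - 0.05) / 0.05, 0.01)
  # uniform dose -> flat 100 curve
  du <- dose_grid(array(1, c(5, 5, 9)), rep(0.2, 3), c(-0.4, -0.4, 0.1))
  expect_true(all(extract_pdd(du)$value == 100))
})

test_that("extract_profile handles symmetry, a linear ramp and SAD projection", {
  dims <- c(41, 21, 10); vox <- 0.2
  xs <- ((seq_len(dims[1]) - 1) - (dims[1] - 1) / 2) * vox
  ramp <- array(rep(2 + 0.1 * xs, times = dims[2] * dims[3]), dims)
  dg <- dose_grid(ramp, rep(vox, 3), c(min(xs), -2, 0.1))
  pr <- extract_profile(dg, depth_cm = 1, direction = "x", norm = "none")
  # projection: offsets shrink by sad/(ssd + depth)
  expect_equal(max(pr$offset_cm), max(xs) * 100 / 101, tolerance = 1e-9)
  fit <- stats::lm(pr$value ~ pr$offset_cm)
  expect_equal(unname(stats::coef(fit)[2]), 0.1 * 101 / 100, tolerance = 1e-6)

  # symmetric dose -> symmetric profile
  r2 <- outer(xs^2, rep(1, dims[2]))
  sym <- array(rep(exp(-r2 / 8), dims[3]), dims)
  dgs <- dose_grid(sym, rep(vox, 3), c(min(xs), -2, 0.1))
  ps <- extract_profile(dgs, 1, "x", norm = "center")
  expect_equal(ps$value, rev(ps$value), tolerance = 1e-9)
  expect_equal(stats::approx(ps$offset_cm, ps$value, 0)$y, 1, tolerance = 1e-9)

  # diagonal sampling step equals the voxel diagonal
  pd <- extract_profile(dgs, 1, "diagonal", norm = "center")
  expect_equal(diff(pd$offset_cm)[1], sqrt(2) * vox * 100 / 101,
               tolerance = 1e-9)
})

test_that("1-D gamma agrees with a brute-force oracle on the 5-point toy", {
  pos <- (0:4) * 0.2                       # 2 mm grid
  ref <- c(0, 50, 100, 50, 0)
  evs <- c(0, 50, 100, 50, 0)
  # identical curves: all gamma 0, pass rate 100
  g0 <- gamma_curve(pos, ref, pos, evs, dd = 3, dta_mm = 2, threshold = 10)
  expect_equal(g0$pass_rate, 100)
  expect_true(all(abs(g0$gamma) < 1e-9, na.rm = TRUE))

  # 1 mm spatial shift passes 3%/2 mm everywhere
  g1 <- gamma_curve(pos, ref, pos + 0.1, evs, dd = 3, dta_mm = 2,
                    threshold = 10)
  expect_equal(g1$pass_rate, 100)

  # brute-force oracle: dense search over a fine offset grid
  oracle <- function(ref_pos, ref_val, ev_pos, ev_val, dd, dta_cm, thr) {
    norm <- max(ref_val)
    out <- rep(NA_real_, length(ref_pos))
    for (i in seq_along(ref_pos)) {
      if (ref_val[i] < thr / 100 * norm) next
      best <- Inf
      for (off in seq(-3 * dta_cm, 3 * dta_cm, by = dta_cm / 400)) {
        ev <- stats::approx(ev_pos, ev_val, xout = ref_pos[i] + off)$y
        if (is.na(ev)) next
        gg <- sqrt((off / dta_cm)^2 + ((ev - ref_val[i]) / (dd / 100 * norm))^2)
        best <- min(best, gg)
      }
      out[i] <- best
    }
    out
  }
  ev2 <- c(0, 47, 104, 55, 1)
  g2 <- gamma_curve(pos, ref, pos, ev2, dd = 3, dta_mm = 2, threshold = 10)
  o2 <- oracle(pos, ref, pos, ev2, 3, 0.2, 10)
  # agreement to the search-grid resolution (oracle searches 10x finer)
  expect_lt(max(abs(abs(g2$gamma) - o2), na.rm = TRUE), 0.08)
  expect_identical(is.na(g2$gamma), is.na(o2))
  expect_identical(abs(g2$gamma) <= 1, o2 <= 1)

  # uniform 10% overdose on a flat curve fails everywhere at 3%/2 mm
  flat <- rep(100, 30)
  g3 <- gamma_curve(seq(0, 5.8, 0.2), flat, seq(0, 5.8, 0.2), 1.1 * flat,
                    dd = 3, dta_mm = 2, threshold = 10)
  expect_equal(g3$pass_rate, 0)
  expect_true(all(g3$gamma > 0))   # signed: evaluated above reference
})

test_that("gamma pass rate tightens monotonically with the criteria", {
  set.seed(8)
  pos <- seq(0, 10, 0.2)
  ref <- 100 * exp(-0.05 * pos)
  ev <- ref * (1 + 0.02 * sin(pos)) + rnorm(length(pos), 0, 0.5)
  rates <- sapply(list(c(3, 2), c(2, 2), c(2, 1), c(1, 1)), function(cr)
    gamma_curve(pos, ref, pos, ev, dd = cr[1], dta_mm = cr[2],
                threshold = 10)$pass_rate)
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("3-D gamma: self-comparison passes, role asymmetry respected", {
  dg <- synthetic_exp_dose(dims = c(9, 9, 20))
  g <- gamma_index(dg, dg, dd = 3, dta_mm = 2, threshold = 10)
  expect_equal(g$pass_rate, 100)
  # shifted evaluated grid: small shift passes at 3%/2 mm
  shifted <- dg
  shifted$dose <- dg$dose * 1.02
  g2 <- gamma_index(dg, shifted, dd = 3, dta_mm = 2, threshold = 10)
  expect_equal(g2$pass_rate, 100)
  # asymmetry: scaling up vs down gives different (signed) results
  g3 <- gamma_index(shifted, dg, dd = 3, dta_mm = 2, threshold = 10)
  s2 <- sign(g2$gamma[!is.na(g2$gamma)])
  s3 <- sign(g3$gamma[!is.na(g3$gamma)])
  expect_true(all(s2 >= 0) && all(s3 <= 0))
  # a gross mismatch fails
  bad <- dg; bad$dose <- dg$dose * 1.3
  expect_lt(gamma_index(dg, bad, 3, 2, 10)$pass_rate, 5)
  expect_error(gamma_index(dg, dose_grid(array(1, c(2, 2, 2)), rep(0.2, 3),
                                         rep(0, 3))), "matching grids")
})

test_that("reference point is the deepest interior voxel of the 90% isodose volume", {
  # spherical blob: center voxel wins
  dims <- c(15, 15, 15); vox <- 0.2
  cx <- (dims - 1) / 2
  idx <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                     k = 0:(dims[3] - 1))
  r2 <- (idx$i - cx[1])^2 + (idx$j - cx[2])^2 + (idx$k - cx[3])^2
  blob <- array(exp(-r2 / 18), dims)
  dg <- dose_grid(blob, rep(vox, 3), c(0, 0, 0.1))
  rp <- reference_point(dg)
  expect_equal(rp$index, c(8, 8, 8))
  # invariance to uniform rescaling
  dg2 <- dg; dg2$dose <- dg$dose * 7.3
  expect_equal(reference_point(dg2)$index, rp$index)

  # two disjoint blobs: the larger one wins (distance-transform oracle)
  two <- array(0, c(30, 9, 9))
  g1 <- expand.grid(i = 1:30, j = 1:9, k = 1:9)
  r2a <- (g1$i - 7)^2 + (g1$j - 5)^2 + (g1$k - 5)^2    # small blob
  r2b <- (g1$i - 22)^2 + (g1$j - 5)^2 + (g1$k - 5)^2   # larger blob
  two <- array(pmax(exp(-r2a / 4), exp(-r2b / 12)), c(30, 9, 9))
  dgt <- dose_grid(two, rep(vox, 3), c(0, 0, 0.1))
  rpt <- reference_point(dgt)
  expect_equal(rpt$index[1], 22)

  # single-voxel V90: that voxel, distance 0
  one <- array(0.1, c(5, 5, 5)); one[3, 3, 3] <- 1
  rpo <- reference_point(dose_grid(one, rep(vox, 3), c(0, 0, 0.1)))
  expect_equal(rpo$index, c(3, 3, 3))
  expect_equal(rpo$distance_cm, 0)
})

test_that("reference-point dose difference matches the hand value", {
  one <- array(0.5, c(5, 5, 5)); one[3, 3, 3] <- 1
  ref <- dose_grid(one, rep(0.2, 3), c(0, 0, 0.1))
  ev <- ref; ev$dose[3, 3, 3] <- 1.023
  expect_equal(reference_point_diff(ref, ev)$diff_percent, 2.3,
               tolerance = 1e-9)
})
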