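# Readers/writers and container validation.

test_that("beam data round-trips losslessly through the CSV+manifest format", {
  bd <- toy_beam_data()
  d <- file.path(tempdir(), "bd-rt")
  write_beam_data(bd, d)
  bd2 <- read_beam_data(d)
  expect_equal(bd2$pdd_ref$depth_cm, bd$pdd_ref$depth_cm, tolerance = 1e-12)
  expect_equal(bd2$pdd_ref$value, bd$pdd_ref$value, tolerance = 1e-12)
  expect_equal(bd2$diagonal_profile$value, bd$diagonal_profile$value,
               tolerance = 1e-12)
  expect_equal(bd2$scp_table$scp, bd$scp_table$scp, tolerance = 1e-12)
  expect_equal(bd2$machine$d_ref_cm, bd$machine$d_ref_cm)
})

test_that("PDD values are renormalized to max 100 on construction", {
  p <- pdd_curve(c(0.5, 1.5, 10), c(80, 98.7, 60))
  expect_equal(max(p$value), 100)
  expect_equal(p$value[2], 100)
})

test_that("format violations are rejected with informative errors", {
  expect_error(pdd_curve(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(pdd_curve(c(-1, 1), c(50, 100)), ">= 0")
  expect_error(of_table(c(3, 5, 20), c(0.95, 0.97, 1.02), 10), "10x10")
  expect_error(of_table(c(3, 5, 10), c(0.99, 0.97, 1), 10), "increasing")
  expect_error(profile_curve(c(-1, 0, 1), c(0, 0, 0)), "normalized")

  # missing Scp row in the file dialect
  bd <- toy_beam_data()
  d <- file.path(tempdir(), "bd-miss")
  write_beam_data(bd, d)
  scp <- utils::read.csv(file.path(d, "scp.csv"))
  utils::write.csv(scp[abs(scp$field_mm - 100) > 1, ],
                   file.path(d, "scp.csv"), row.names = FALSE)
  expect_error(read_beam_data(d), "10x10|field_mm=100")
})

test_that("plan JSON dialect rasterizes leaves and masks onto the 1 mm grid", {
  dir <- file.path(tempdir(), "plans")
  dir.create(dir, showWarnings = FALSE)
  # 10x10 cm open aperture from 20 leaves of 5 mm covering y in [-50, 50]
  plan <- list(format = "beamforge-plan-1", beams = list(list(
    gantry_deg = 0,
    grid = list(x0_mm = -60, y0_mm = -60, nx = 120, ny = 120),
    segments = list(list(
      mu = 100,
      leaves = list(leaf_width_mm = 5, y0_mm = -50,
                    bank_a = rep(-50, 20), bank_b = rep(50, 20)))))))
  pf <- file.path(dir, "open.json")
  jsonlite::write_json(plan, pf, auto_unbox = TRUE, digits = NA)
  ps <- read_plan(pf)
  expect_length(ps$beams, 1)
  seg <- ps$beams[[1]]$segments[[1]]
  expect_equal(seg$mu, 100)
  # mask area 100 cm^2 at 1 mm pixels
  expect_equal(sum(seg$mask) * 0.01, 100, tolerance = 0.02)

  # closed leaves -> empty mask with a warning
  plan$beams[[1]]$segments[[1]]$leaves$bank_b <- rep(-50, 20)
  jsonlite::write_json(plan, file.path(dir, "closed.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_warning(ps2 <- read_plan(file.path(dir, "closed.json")), "empty")
  expect_false(any(ps2$beams[[1]]$segments[[1]]$mask))

  # negative MU -> validation error
  plan$beams[[1]]$segments[[1]]$mu <- -1
  jsonlite::write_json(plan, file.path(dir, "neg.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_plan(file.path(dir, "neg.json")), "MU")
})

test_that("generated plans round-trip through write_plan/read_plan", {
  for (kind in c("open_square", "sliding_window", "step_and_shoot")) {
    plan <- generate_plan(kind, field_cm = 4, mu = 50, grid_half_cm = 4)
    pf <- file.path(tempdir(), paste0(kind, ".json"))
    write_plan(plan, pf)
    plan2 <- read_plan(pf)
    expect_length(plan2$beams[[1]]$segments,
                  length(plan$beams[[1]]$segments))
    for (i in seq_along(plan$beams[[1]]$segments)) {
      expect_equal(plan2$beams[[1]]$segments[[i]]$mu,
                   plan$beams[[1]]$segments[[i]]$mu)
      expect_identical(unname(plan2$beams[[1]]$segments[[i]]$mask),
                       unname(plan$beams[[1]]$segments[[i]]$mask))
    }
  }
})

test_that("dose volumes round-trip exactly through the raw+sidecar format", {
  set.seed(4)
  d <- array(runif(4 * 5 * 6), c(4, 5, 6))
  u <- array(runif(4 * 5 * 6, 0, 0.1), c(4, 5, 6))
  dg <- dose_grid(d, c(0.2, 0.2, 0.2), c(-0.3, -0.4, 0.1), u, "photon")
  f <- tempfile(fileext = ".bfd")
  write_dose(dg, f)
  dg2 <- read_dose(f)
  expect_identical(dg2$dose, dg$dose)
  expect_identical(dg2$uncertainty, dg$uncertainty)
  expect_equal(dg2$voxel_cm, dg$voxel_cm, tolerance = 1e-12)
  expect_equal(dg2$origin_cm, dg$origin_cm, tolerance = 1e-12)
  expect_identical(dg2$component, "photon")

  # shape mismatch on read -> format error
  hdr <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  hdr$dims <- c(4, 5, 7)
  jsonlite::write_json(hdr, paste0(f, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_dose(f), "size mismatch")

  # empty grids are rejected at construction
  expect_error(dose_grid(array(numeric(0), c(0, 1, 1)), rep(0.2, 3), rep(0, 3)),
               "non-empty")
})

test_that("phantom and magnetic-field invariants are enforced", {
  ph <- water_phantom(c(4, 4, 5), rep(0.2, 3))
  expect_equal(dim(ph$density), c(20, 20, 25))
  expect_error(voxel_phantom(array(-1, c(2, 2, 2)), rep(0.2, 3)), ">= 0")
  expect_error(b_field(array(0, c(2, 2, 2)), array(0, c(2, 2, 2)),
                       array(0, c(2, 2, 3)), ph), "dimensions")
  B <- uniform_b_field(c(0, 1.5, 0), ph)
  expect_equal(dim(B$by), dim(ph$density))
})
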