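# Small fixtures shared across tests; everything is built in code.

two_bin_spectrum <- function() energy_spectrum(c(1, 3), c(0.5, 0.5))

# analytic-ish beam data set with valid invariants (no engine involved)
toy_beam_data <- function() {
  z <- seq(0.05, 32, by = 0.25)
  pdd <- ifelse(z < 1.5, 100 * (z / 1.5)^0.7, 100 * exp(-0.045 * (z - 1.5)))
  off <- seq(-15, 15, by = 0.25)
  prof <- 1 - 0.002 * abs(off) - 1e-4 * off^2
  beam_data_set(
    pdd_curve(z, pdd),
    profile_curve(off, prof),
    of_table(c(2, 3, 5, 10, 20), c(0.93, 0.95, 0.97, 1, 1.02), 10),
    list(sad_cm = 100, ssd_cm = 100, d_ref_cm = 10, d_max_cm = 1.5,
         largest_field_cm = 20, energy_label = "6X-toy")
  )
}

# tiny uniform fluence over a square, on a small grid
tiny_fluence <- function(half_cm = 2, px_cm = 0.1, field_cm = 2) {
  n <- round(half_cm / px_cm)
  ax <- (-n:n) * px_cm
  v <- outer(abs(ax) < field_cm / 2, abs(ax) < field_cm / 2) * 1
  fluence_map(v, ax, ax)
}

small_water_phantom <- function(size = c(10, 10, 12), vox = 0.2)
  water_phantom(size, rep(vox, 3))
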