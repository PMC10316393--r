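# RDF, density profiles, adsorption/immersion enthalpies, PMF integration.

test_that("RDF of an ideal gas is flat at 1 with 1/sqrt(frames) convergence", {
  gen_gas <- function(n_frames, seed) {
    set.seed(seed)
    lapply(seq_len(n_frames), function(k)
      md_frame(rep("O", 150), matrix(runif(450, 0, 3), ncol = 3), c(3, 3, 3)))
  }
  band <- function(traj) {
    g <- rdf(traj, "O", "O", r_max = 1.4, bin = 0.05)
    sel <- g$centers > 0.4
    mean(abs(g$values[sel] - 1))
  }
  dev5 <- band(gen_gas(5, 1))
  dev45 <- band(gen_gas(45, 1))
  expect_lt(dev5, 0.2)
  expect_lt(dev45, dev5)          # more frames, closer to 1
  expect_lt(dev45, 0.06)
})

test_that("RDF of two fixed atoms occupies the single correct bin", {
  fr <- md_frame(c("O", "O"), rbind(c(1, 1, 1), c(1.2, 1, 1)), c(3, 3, 3))
  g <- rdf(fr, "O", "O", r_max = 1.0, bin = 0.01)
  occupied <- which(g$values > 0)
  expect_length(occupied, 1)
  expect_lt(abs(g$centers[occupied] - 0.2), 0.01)
  pk <- first_peak(g)
  expect_lt(abs(pk$r_peak - 0.2), 0.01)
})

test_that("RDF validates selections and range", {
  fr <- md_frame(c("O", "O"), rbind(c(1, 1, 1), c(1.2, 1, 1)), c(3, 3, 3))
  expect_error(rdf(fr, "O", "O", r_max = 2), "half")
  suppressWarnings(expect_error(rdf(fr, "Zn", "O", r_max = 1),
                                "empty selection"))
})

test_that("RDF first peak recovers a planted hydration-shell radius", {
  # solvation-shell toy: central O, 12 partners on a 0.28 nm shell + gas
  set.seed(7)
  frames <- lapply(1:10, function(k) {
    dirs <- matrix(rnorm(36), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    shell <- sweep(dirs * 0.28, 2, c(1.5, 1.5, 1.5), "+")
    gas <- matrix(runif(60, 0, 3), ncol = 3)
    md_frame(c("Zn", rep("O", 12 + 20)),
             rbind(c(1.5, 1.5, 1.5), shell, gas), c(3, 3, 3))
  })
  g <- rdf(frames, "Zn", "O", r_max = 1.2, bin = 0.02)
  expect_lt(abs(first_peak(g)$r_peak - 0.28), 0.021)
})

test_that("density profile integrates to N per unit area and finds planted layers", {
  set.seed(3)
  n <- 120
  z <- c(runif(n / 2, 0.95, 1.05), runif(n / 2, 1.95, 2.05))  # two layers
  fr <- md_frame(rep("O", n),
                 cbind(runif(n, 0, 2), runif(n, 0, 2), z), c(2, 2, 4))
  prof <- density_profile(fr, "O", bin = 0.05)
  widths <- rep(prof$bin_width, length(prof$centers))
  expect_equal(sum(prof$values * widths), n / (2 * 2), tolerance = 1e-9)
  peaks <- prof$centers[order(prof$values, decreasing = TRUE)][1:4]
  expect_true(any(abs(peaks - 1.0) < 0.1))
  expect_true(any(abs(peaks - 2.0) < 0.1))

  # uniform box is flat at the bulk density
  fr2 <- md_frame(rep("O", 500),
                  matrix(runif(1500, 0, 2.5), ncol = 3), c(2.5, 2.5, 2.5))
  prof2 <- density_profile(fr2, "O", bin = 0.5)
  bulk <- 500 / 2.5^3
  expect_equal(mean(prof2$values), bulk, tolerance = 0.05)
})

test_that("adsorption enthalpy is exact for linear energies and error-checked", {
  pts <- data.frame(n = seq(0, 40, by = 5), E = 5 - 43 * seq(0, 40, by = 5))
  curve <- adsorption_enthalpy(pts, e_ref = -41, area = 9)
  expect_equal(curve$dH, rep(-43 - (-41), nrow(curve)))  # exactly -2
  expect_equal(curve$coverage, (pts$n[-nrow(pts)] + pts$n[-1]) / 2 / 9)
  expect_error(adsorption_enthalpy(data.frame(n = c(3, 3), E = 1:2)),
               "duplicate")
})

test_that("two-regime energies yield a crossover at the planted coverage", {
  es <- gen_energy_series(seq(0, 60, by = 3), area = 9, strong_slope = -80,
                          weak_slope = -45, crossover = 3, noise = 0)
  curve <- adsorption_enthalpy(es, e_ref = -41.5, area = 9)
  cross <- detect_crossover(curve)
  expect_equal(cross, 3, tolerance = 3 / 9)  # within one grid spacing
  # both regimes visible at their planted levels
  expect_equal(min(curve$dH), -80 - (-41.5), tolerance = 1e-9)
  expect_equal(curve$dH[nrow(curve)], -45 - (-41.5), tolerance = 1e-9)
})

test_that("immersion enthalpy arithmetic and scaling, including unit conversion", {
  expect_equal(immersion_enthalpy(5, 3, 2, 3, 3), 0)
  # planted value chosen to give exactly 1 J/m^2 over a 3x3 box, both faces
  dE <- 2 * 9 * 1e-18 * 6.02214076e23 / 1000  # kJ/mol for 1 J/m^2
  expect_equal(immersion_enthalpy(-5000 + dE, -2000, -3000, 3, 3), 1.0,
               tolerance = 1e-9)
  expect_equal(immersion_enthalpy(-5000 + dE, -2000, -3000, 3 * sqrt(2),
                                  3 * sqrt(2)), 0.5, tolerance = 1e-9)
  expect_error(immersion_enthalpy(1, 1, 1, 0, 3), "positive")
})

test_that("PMF integration matches the harmonic closed form exactly on a linear force", {
  k <- 500; s0 <- 0.6
  s <- seq(0.3, 1.1, by = 0.01)
  f <- -k * (s - s0)
  expect_warning(p <- pmf_from_mean_force(s, f), "plateau")
  W_exact <- k / 2 * (s - s0)^2 - k / 2 * (1.1 - s0)^2
  expect_equal(p$W, W_exact, tolerance = 1e-10)  # trapezoid exact on linear F
  expect_equal(p$minima$s, s0, tolerance = 0.01)
  expect_equal(p$binding_free_energy, min(W_exact))
})

test_that("PMF of zero force is identically zero; grids must increase", {
  s <- seq(0.3, 1.2, by = 0.05)
  p <- pmf_from_mean_force(s, rep(0, length(s)))
  expect_equal(p$W, rep(0, length(s)))
  expect_error(pmf_from_mean_force(c(0.3, 0.2), c(0, 0)), "increasing")
})

test_that("PMF recovers a planted double well at the observed binding distances", {
  s <- seq(0.30, 1.50, by = 0.005)
  prof <- gen_force_profile(s, data.frame(pos = c(0.42, 0.59),
                                          depth = c(20, 8),
                                          width = c(0.03, 0.05)))
  p <- pmf_from_mean_force(prof$s, prof$force)
  expect_equal(max(abs(p$W - prof$W_true)), 0, tolerance = 0.5)
  wells <- p$minima[order(p$minima$W), ]
  expect_equal(sort(wells$s[1:2]), c(0.42, 0.59), tolerance = 0.01)
  expect_equal(p$binding_free_energy, min(prof$W_true), tolerance = 0.5)
})

test_that("PMF integrator error shrinks as O(step^2) against the Gaussian well", {
  s1 <- seq(0.3, 1.5, by = 0.02)
  s2 <- seq(0.3, 1.5, by = 0.005)
  err <- function(s) {
    prof <- gen_force_profile(s, data.frame(pos = 0.5, depth = 15,
                                            width = 0.04))
    p <- pmf_from_mean_force(prof$s, prof$force)
    max(abs(p$W - prof$W_true))
  }
  # step reduced 4x: error should drop by about 16x (allow 8x for slack)
  expect_gt(err(s1) / err(s2), 8)
})
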