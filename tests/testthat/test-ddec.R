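# Nonbonded parameter derivation from partitioning statistics and
# Boltzmann-inversion bonded fits.

test_that("volume scaling has the free-atom limits and hand-checked values", {
  # V = V0 recovers the free-atom dispersion coefficient and radius
  expect_equal(dispersion_B(78.99, 78.99, 276)$B_ha_bohr6, 276)
  expect_equal(vdw_radius(23.52, 23.52, 0.169), 0.169)
  # hand arithmetic: 0.9^2 * 276, 8 V0 -> 2 R0
  expect_equal(dispersion_B(0.9 * 78.99, 78.99, 276)$B_ha_bohr6, 223.56)
  expect_equal(vdw_radius(8 * 23.52, 23.52, 0.169), 2 * 0.169)
  expect_error(dispersion_B(-1, 78.99, 276), "positive")
  expect_error(vdw_radius(0, 23.52, 0.169), "positive")
})

test_that("hartree-bohr to kJ/mol-nm dispersion conversion matches CODATA arithmetic", {
  # independent arithmetic: 276 Ha a0^6 with 1 Ha = 2625.4996 kJ/mol,
  # 1 a0 = 0.052917721 nm
  expected <- 276 * 2625.4996 * 0.052917721^6
  expect_equal(dispersion_B(78.99, 78.99, 276)$B_kjmol_nm6, expected,
               tolerance = 1e-12)
})

test_that("scaling relations: B and R increase with volume; A scales as (2R)^6", {
  vs <- seq(10, 120, by = 5)
  Bs <- vapply(vs, function(v) dispersion_B(v, 78.99, 276)$B_ha_bohr6,
               numeric(1))
  Rs <- vapply(vs, function(v) vdw_radius(v, 78.99, 0.228), numeric(1))
  expect_true(all(diff(Bs) > 0))
  expect_true(all(diff(Rs) > 0))
  expect_equal(repulsive_A(1.5, 2 * 0.21) / repulsive_A(1.5, 0.21), 64)
})

test_that("sigma/eps <-> A/B is an exact involution and honours conventions", {
  # published free-water row round-trips
  ab <- sigma_eps_to_ab(0.315, 0.636)
  se <- ab_to_sigma_eps(ab$A, ab$B)
  expect_equal(se$sigma, 0.315)
  expect_equal(se$epsilon, 0.636)
  expect_equal(ab_to_sigma_eps(4, 4), list(sigma = 1, epsilon = 1))
  # property: random positive pairs round-trip to machine precision
  set.seed(1)
  for (k in 1:25) {
    A <- runif(1, 1e-8, 1e-2); B <- runif(1, 1e-6, 1e-1)
    se <- ab_to_sigma_eps(A, B)
    ab2 <- sigma_eps_to_ab(se$sigma, se$epsilon)
    expect_equal(ab2$A, A, tolerance = 1e-12)
    expect_equal(ab2$B, B, tolerance = 1e-12)
  }
  # zero-dispersion hydrogen convention
  expect_equal(ab_to_sigma_eps(1, 0), list(sigma = 0, epsilon = 0))
  # repulsive_A places the LJ minimum at 2R: sigma = 2R / 2^(1/6)
  B <- 9.8e-3; R <- 0.21
  se <- ab_to_sigma_eps(repulsive_A(B, R), B)
  expect_equal(se$sigma, 2 * R / 2^(1 / 6))
  expect_equal(se$epsilon, B / (2 * (2 * R)^6))
})

test_that("type statistics pool over frames and recover planted means", {
  d <- decorate_surface(slab_1010(), 0.5, 0.5, model = "NB", seed = 2)
  ty <- assign_atom_types(d)
  rec <- gen_partition_records(d, ty, partition_scenario(seed = 8),
                               n_frames = 40)
  st <- type_statistics(rec, ty)
  zna <- st[st$type == "ZnA", ]
  # sampling oracle: mean within 3 sd/sqrt(n) of the planted 0.918
  expect_lt(abs(zna$nac_mean - 0.918), 3 * 0.02 / sqrt(zna$n))
  expect_equal(zna$n, sum(ty$labels == "ZnA") * 40)

  # single atom, single frame: mean = value, sd = 0
  one <- partition_record(data.frame(element = "O", x = 0, y = 0, z = 0,
                                     nac = -0.9, cam = 25))
  st1 <- type_statistics(one, "OC")
  expect_equal(st1$nac_mean, -0.9)
  expect_equal(st1$nac_sd, 0)

  # pooling two records is sample-size weighted
  two <- partition_record(data.frame(element = c("O", "O"), x = 0, y = 0,
                                     z = 0, nac = c(-0.8, -0.8), cam = 25))
  stp <- type_statistics(list(one, two), list("OC", c("OC", "OC")))
  expect_equal(stp$nac_mean, (-0.9 - 0.8 - 0.8) / 3)
})

test_that("charge rules: water constraint and bulk neutrality for any stats", {
  st <- data.frame(type = c("ZnA", "ZnB", "OA", "OB", "OC", "OH", "OW", "HA"),
                   n = 10,
                   nac_mean = c(0.918, 0.949, -0.918, -0.827, -0.934,
                                -0.838, -0.71, 0.39),
                   nac_sd = 0.02, cam_mean = 30, cam_sd = 1)
  ch <- assign_charges(st)
  q <- setNames(ch$charge, ch$type)
  expect_equal(unname(q["OW"]), -0.834)
  expect_equal(unname(q["HA"]), 0.417)
  expect_equal(unname(q["ZnA"] + q["OA"]), 0)
  # neutrality follows the ZnA mean, whatever it is
  st$nac_mean[1] <- 1.0
  q2 <- with(assign_charges(st), setNames(charge, type))
  expect_equal(unname(q2["OA"]), -1.0)
  # OA without ZnA statistics cannot be neutralized
  expect_error(assign_charges(st[st$type != "ZnA", ]), "ZnA")
})

test_that("Boltzmann inversion recovers planted bond parameters within 5%", {
  b <- gen_bond_samples(k = 40000, b0 = 0.100, T = 300, n = 1e5, seed = 31)
  fit <- fit_bond_harmonic(b, T = 300)
  expect_equal(fit$b0, 0.100, tolerance = 0.005)
  expect_equal(fit$k, 40000, tolerance = 0.05)
  # inverse-variance scaling: quadrupled variance quarters k
  fit4 <- fit_bond_harmonic(rep(b - mean(b), 2) * 2 + mean(b), T = 300)
  expect_equal(fit4$k, fit$k / 4, tolerance = 1e-4)
  # degenerate samples are an error
  expect_error(fit_bond_harmonic(rep(0.1, 50)), "rigid")
  expect_error(fit_bond_harmonic(c(0.1, 0.2)), "30")
})

test_that("angle fits use degrees for theta0 and radians for the variance", {
  set.seed(5)
  th <- rnorm(2e4, 109.5, 3)
  fit <- fit_angle_harmonic(th, T = 300)
  expect_equal(fit$theta0, 109.5, tolerance = 0.01)
  kb <- ff_constants()$kb_kjmol
  expect_equal(fit$k_theta, kb * 300 / var(th * pi / 180), tolerance = 1e-9)
})

test_that("derive_ff builds a consistent table and applies the ZnB short sigma", {
  d <- decorate_surface(slab_1010(), 0.5, 0.5, model = "NB", seed = 2)
  ty <- assign_atom_types(d)
  rec <- gen_partition_records(d, ty, partition_scenario(seed = 8),
                               n_frames = 10)
  st <- type_statistics(rec, ty)
  ff <- derive_ff(st, model = "NB")
  at <- ff$atoms
  # A/B consistent with sigma/eps by exact algebra; HA zero LJ
  for (r in seq_len(nrow(at))) {
    if (at$B[r] > 0) {
      expect_equal(at$A[r], 4 * at$epsilon[r] * at$sigma[r]^12,
                   tolerance = 1e-9)
      expect_equal(at$B[r], 4 * at$epsilon[r] * at$sigma[r]^6,
                   tolerance = 1e-9)
    }
  }
  expect_equal(at$sigma[at$type == "HA"], 0)
  expect_equal(at$epsilon[at$type == "HA"], 0)
  # ZnB special case: short sigma, epsilon copied from ZnA
  expect_equal(at$sigma[at$type == "ZnB"], 0.150)
  expect_equal(at$epsilon[at$type == "ZnB"], at$epsilon[at$type == "ZnA"])
  # charge neutrality carried through
  expect_equal(at$charge[at$type == "OA"], -at$charge[at$type == "ZnA"])
  # effective radii implied by the defaults sit at the reported scale
  refs <- free_atom_reference()
  r_zn <- vdw_radius(st$cam_mean[st$type == "ZnA"], 78.99,
                     refs$R0[refs$element == "Zn"])
  r_o <- vdw_radius(st$cam_mean[st$type == "OA"], 23.52,
                    refs$R0[refs$element == "O"])
  expect_equal(r_zn, 0.210, tolerance = 0.02)
  expect_equal(r_o, 0.176, tolerance = 0.02)
})

test_that("ZnB rule is a warned no-op on BOND tables or when ZnB is absent", {
  ff <- reference_nb_ff()
  ff$model <- "BOND"
  expect_warning(out <- special_case_znb(ff), "NB")
  expect_equal(out$atoms, ff$atoms)
  ff2 <- reference_nb_ff()
  ff2$atoms <- ff2$atoms[ff2$atoms$type != "ZnB", ]
  expect_warning(special_case_znb(ff2), "no ZnB")
})
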