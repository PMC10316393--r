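# Connectivity classifier, population fractions, bond-order verification.

test_that("oxygen shells map to the documented type labels", {
  box <- c(4, 4, 4)
  # free water: O with two H, no Zn
  w <- md_frame(c("O", "H", "H"), water_at(c(2, 2, 2)), box)
  ty <- assign_atom_types(w)
  expect_equal(ty$labels, c("OW", "HA", "HA"))

  # O with 4 Zn -> OA (and those Zn see only 1 O here -> SOL warning)
  o4 <- md_frame(c("O", rep("Zn", 4)),
                 rbind(c(2, 2, 2), c(2.2, 2, 2), c(1.8, 2, 2),
                       c(2, 2.2, 2), c(2, 1.8, 2)), box)
  expect_warning(ty <- assign_atom_types(o4), "zinc")
  expect_equal(ty$labels[1], "OA")

  # O with 3 Zn + 1 H -> OB; 3 Zn -> OC; 1 Zn + 2 H -> OD; 1 Zn + 1 H -> OH
  shells <- list(
    list(el = c("O", "Zn", "Zn", "Zn", "H"),
         dx = rbind(c(0, 0, 0), c(0.2, 0, 0), c(-0.2, 0, 0), c(0, 0.2, 0),
                    c(0, -0.1, 0)), lab = "OB"),
    list(el = c("O", "Zn", "Zn", "Zn"),
         dx = rbind(c(0, 0, 0), c(0.2, 0, 0), c(-0.2, 0, 0), c(0, 0.2, 0)),
         lab = "OC"),
    list(el = c("O", "Zn", "H", "H"),
         dx = rbind(c(0, 0, 0), c(0, 0, -0.2), c(0.0957, 0, 0),
                    c(-0.024, 0.0927, 0)), lab = "OD"),
    list(el = c("O", "Zn", "H"),
         dx = rbind(c(0, 0, 0), c(0, 0, -0.2), c(0.098, 0, 0)), lab = "OH")
  )
  for (sh in shells) {
    fr <- md_frame(sh$el, sweep(sh$dx, 2, c(2, 2, 2), "+"), box)
    ty <- suppressWarnings(assign_atom_types(fr))
    expect_equal(ty$labels[1], sh$lab)
  }
})

test_that("hydroxide and hydronium oxygens become SOL with a warning", {
  box <- c(4, 4, 4)
  ohm <- md_frame(c("O", "H"), rbind(c(2, 2, 2), c(2.098, 2, 2)), box)
  expect_warning(ty <- assign_atom_types(ohm), "unclassifiable")
  expect_equal(ty$labels[1], "SOL")
})

test_that("non-ZnOH elements are rejected", {
  fr <- md_frame(c("Na", "O"), rbind(c(1, 1, 1), c(2, 2, 2)), c(4, 4, 4))
  expect_error(assign_atom_types(fr), "unsupported element")
})

test_that("water-coordinating Zn is typed ZnB, hydroxyl-coordinating Zn is ZnA", {
  d <- decorate_surface(slab_1010(), 0.5, 0, model = "BOND", seed = 3)
  ty <- assign_atom_types(d)
  dec <- attr(d, "decoration")
  expect_true(all(ty$labels[dec$oh_sites] == "ZnA"))
  expect_true(all(ty$labels[dec$water_sites] == "ZnB"))
  expect_true(all(ty$labels[d$elements == "H"] == "HA"))
})

test_that("classifier recovers planted decoration counts exactly (round trip)", {
  d <- decorate_surface(slab_1210(), 0.625, 0.625, model = "BOND", seed = 7)
  ty <- assign_atom_types(d)
  dec <- attr(d, "decoration")
  ct <- table(ty$labels)
  expect_equal(unname(ct[["OH"]]), length(dec$oh_sites))
  expect_equal(unname(ct[["OD"]]), length(dec$water_sites))
  expect_equal(unname(ct[["OB"]]), length(dec$h_sites))
})

test_that("classifier is invariant under atom permutation and rigid translation", {
  d <- decorate_surface(slab_1010(), 0.5, 0.5, model = "BOND", seed = 5)
  fr <- md_frame(d$elements, d$xyz, d$box)
  ref <- assign_atom_types(fr)

  set.seed(42)
  perm <- sample(length(fr$elements))
  fr_p <- md_frame(fr$elements[perm], fr$xyz[perm, ], fr$box)
  expect_equal(assign_atom_types(fr_p)$labels, ref$labels[perm])

  shift <- c(0.37, -1.21, 0.55)
  fr_t <- md_frame(fr$elements, sweep(fr$xyz, 2, shift, "+") %% rep(fr$box, each = length(fr$elements)), fr$box)
  expect_equal(table(assign_atom_types(fr_t)$labels), table(ref$labels))
})

test_that("population fractions are normalized and track planted composition", {
  slab <- build_slab("10-10", 4, 4, 2)
  sc <- hydration_scenario(f_oh = 0.625, f_h = 0.6875, tau_ps = 1,
                           fluctuation = 0, seed = 21)
  traj <- gen_hydration_trajectory(slab, sc, n_frames = 24, dt_ps = 0.5,
                                   n_free_water = 8)
  pf <- population_fractions(traj, attr(traj, "sites"), burn_in = 8)
  # initial all-molecular frame
  expect_equal(pf$frames$f_water[1], 1.0)
  expect_equal(pf$frames$f_od[1], 1.0)
  # per-frame normalizations
  expect_equal(pf$frames$f_ob + pf$frames$f_oc, rep(1, nrow(pf$frames)))
  expect_equal(pf$frames$f_oh + pf$frames$f_od, rep(1, nrow(pf$frames)))
  # equilibrium average equals the planted fractions exactly (32 sites)
  expect_equal(pf$summary$mean[pf$summary$fraction == "f_oh"], 0.625)
  expect_equal(pf$summary$mean[pf$summary$fraction == "f_ob"], 0.6875)
})

test_that("population fractions need a non-empty trajectory and sites", {
  sites <- enumerate_surface_sites(slab_1010())
  expect_error(population_fractions(list(), sites), "empty")
})

test_that("fitted equilibrium fraction matches the generator within 2 SE", {
  slab <- build_slab("10-10", 4, 4, 2)
  sc <- hydration_scenario(f_oh = 0.6, f_h = 0.6, tau_ps = 0.8,
                           fluctuation = 0.04, seed = 13)
  traj <- gen_hydration_trajectory(slab, sc, n_frames = 40, dt_ps = 0.5,
                                   n_free_water = 0)
  pf <- population_fractions(traj, attr(traj, "sites"), burn_in = 6)
  eq <- pf$frames[pf$frames$time >= 6, ]
  se <- sd(eq$f_oh) / sqrt(nrow(eq))
  expect_lt(abs(mean(eq$f_oh) - 0.6), 2 * se + 1 / 32)  # +1 count quantum
})

test_that("bond-order verification classifies covalent, partial and nonbonded pairs", {
  d <- decorate_surface(slab_1010(), 0.5, 0.5, model = "BOND", seed = 6)
  ty <- assign_atom_types(d)
  rec <- gen_partition_records(d, ty, partition_scenario(seed = 3),
                               n_frames = 1)
  rpt <- verify_bonds(ty, rec)
  cl <- setNames(rpt$classes$status, rpt$classes$class)
  expect_equal(unname(cl["OB-HA"]), "covalent")       # planted mean 0.75
  expect_equal(unname(cl["ZnA-OH"]), "covalent")      # planted mean 0.65
  expect_equal(unname(cl["ZnB-OD"]), "partially covalent")  # planted 0.45

  # a pair below threshold is nonbonded; a missing pair is unverifiable
  toy <- partition_record(
    data.frame(element = c("O", "H"), x = 0, y = 0, z = c(0, 0.1),
               nac = 0, cam = 1),
    data.frame(i = 1, j = 2, bo = 0.05))
  toy_ty <- structure(list(labels = c("OW", "HA"),
                           bonds = data.frame(i = 1, j = 2,
                                              class = "OW-HA", dist = 0.1)),
                      class = "type_assignment")
  expect_equal(verify_bonds(toy_ty, toy)$classes$status, "nonbonded")
  toy2 <- partition_record(toy$atoms, NULL)
  rep2 <- verify_bonds(toy_ty, toy2)
  expect_equal(rep2$classes$status, "unverifiable")
  expect_equal(rep2$unverifiable, 1)
})
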