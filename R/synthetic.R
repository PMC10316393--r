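## Synthetic generators for every input class the pipeline consumes:
## hydration trajectories with planted surface compositions, partitioning
## records with planted per-type distributions, energy series, force
## profiles and bond-length samples. All generators are deterministic
## given their seed.

#' Hydration scenario for trajectory generation
#'
#' Describes the surface chemistry a generated trajectory relaxes to: the
#' equilibrium hydroxylation and protonation fractions, the exponential
#' relaxation time of the surface reactions (on real surfaces the
#' hydroxylation/proton-transfer transient takes 1-3 ps), and the
#' frame-to-frame fluctuation amplitude of the fractions around
#' equilibrium.
#'
#' @param f_oh Equilibrium hydroxyl fraction per surface Zn site.
#' @param f_h Equilibrium protonation fraction per surface O site.
#' @param tau_ps Relaxation time (ps), default 1.5.
#' @param fluctuation Standard deviation of the per-frame fraction noise
#'   around equilibrium; 0 gives deterministic rounded counts every frame.
#' @param residual_hydroxide If TRUE, the protons in excess of hydroxyls
#'   are balanced by free OH- ions left in the water phase.
#' @param seed Integer seed.
#' @return Object of class `hydration_scenario`.
#' @export
hydration_scenario <- function(f_oh = 0.62, f_h = 0.64, tau_ps = 1.5,
                               fluctuation = 0.05,
                               residual_hydroxide = FALSE, seed = 1L) {
  stopifnot(f_oh >= 0, f_oh <= 1, f_h >= 0, f_h <= 1, tau_ps > 0,
            fluctuation >= 0)
  structure(list(f_oh = f_oh, f_h = f_h, tau_ps = tau_ps,
                 fluctuation = fluctuation,
                 residual_hydroxide = residual_hydroxide,
                 seed = as.integer(seed)),
            class = "hydration_scenario")
}

## place n free water molecules on a jittered grid in the upper gap
.free_waters <- function(slab, n, seed) {
  if (n <= 0) return(list(el = character(), xyz = NULL))
  z0 <- max(slab$xyz[slab$role == "slab", 3]) + 0.45
  z1 <- slab$box[3] - 0.15
  pitch <- 0.32
  gx <- seq(pitch / 2, slab$box[1] - pitch / 2, by = pitch)
  gy <- seq(pitch / 2, slab$box[2] - pitch / 2, by = pitch)
  gz <- seq(z0, z1, by = pitch)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  if (nrow(grid) < n)
    stop("gap too small for ", n, " free waters; enlarge the box gap")
  pos <- .with_seed(seed, {
    grid[sample.int(nrow(grid), n), , drop = FALSE] +
      matrix(stats::runif(3 * n, -0.04, 0.04), n, 3)
  })
  el <- character(); xyz <- NULL
  for (k in seq_len(n)) {
    o <- pos[k, ]
    el <- c(el, "O", "H", "H")
    xyz <- rbind(xyz, o, o + c(0.0957, 0, 0), o + c(-0.024, 0.0927, 0))
  }
  list(el = el, xyz = xyz)
}

#' Generate a hydration trajectory with a planted surface composition
#'
#' Frame 0 is fully molecular (every surface Zn site carries an intact
#' bound water, no hydroxyls or surface protons, so the OW+OD water
#' fraction is exactly 1). The hydroxylation and protonation counts then
#' relax exponentially toward the scenario's equilibrium fractions with
#' deterministic rounding, and, if the scenario's fluctuation amplitude is
#' positive, fluctuate around equilibrium thereafter. Site selection is
#' re-drawn each frame under a per-frame seed; the geometry of every placed
#' group is consistent with the classifier cutoffs, so
#' [assign_atom_types()] recovers the planted counts exactly.
#'
#' @param slab Undecorated [build_slab()] result.
#' @param scenario A [hydration_scenario()].
#' @param n_frames Number of frames.
#' @param dt_ps Frame spacing (ps), default 0.5.
#' @param n_free_water Free (bulk) water molecules placed in the gap,
#'   default 20.
#' @return List of [md_frame()]s; the planted per-frame counts are stored
#'   in `attr(, "planted")` (data.frame `frame`, `time`, `n_oh`, `n_h`),
#'   the site set in `attr(, "sites")`.
#' @export
gen_hydration_trajectory <- function(slab, scenario, n_frames, dt_ps = 0.5,
                                     n_free_water = 20) {
  stopifnot(inherits(scenario, "hydration_scenario"), n_frames >= 1)
  sites <- enumerate_surface_sites(slab)
  n_zn <- length(sites$zn_sites); n_o <- length(sites$o_sites)
  if (!n_zn) stop("slab has no enumerated surface sites")
  wat <- .free_waters(slab, n_free_water, scenario$seed)

  frames <- vector("list", n_frames)
  planted <- data.frame(frame = integer(), time = numeric(),
                        n_oh = integer(), n_h = integer())
  for (k in seq_len(n_frames)) {
    t_ps <- (k - 1) * dt_ps
    relax <- 1 - exp(-t_ps / scenario$tau_ps)
    eps <- if (scenario$fluctuation > 0 && k > 1)
      .with_seed(scenario$seed + 7919L * k,
                 stats::rnorm(2, 0, scenario$fluctuation)) * relax
      else c(0, 0)
    f_oh_t <- min(max(scenario$f_oh * relax + eps[1], 0), 1)
    f_h_t <- min(max(scenario$f_h * relax + eps[2], 0), 1)
    dec <- decorate_surface(slab, f_oh_t, f_h_t, model = "BOND",
                            seed = scenario$seed + k, sites = sites,
                            quiet = TRUE)
    el <- dec$elements; xyz <- dec$xyz
    if (length(wat$el)) { el <- c(el, wat$el); xyz <- rbind(xyz, wat$xyz) }
    if (scenario$residual_hydroxide) {
      d <- attr(dec, "decoration")
      n_excess <- length(d$h_sites) - length(d$oh_sites)
      if (n_excess > 0) {  # free OH- ions high in the gap
        zi <- slab$box[3] - 0.1
        for (m in seq_len(n_excess)) {
          o <- c(0.12 + 0.3 * m, 0.12, zi)
          el <- c(el, "O", "H"); xyz <- rbind(xyz, o, o + c(0.098, 0, 0))
        }
      }
    }
    frames[[k]] <- md_frame(el, xyz, dec$box, time = t_ps)
    d <- attr(dec, "decoration")
    planted <- rbind(planted, data.frame(frame = k, time = t_ps,
                                         n_oh = length(d$oh_sites),
                                         n_h = length(d$h_sites)))
  }
  attr(frames, "planted") <- planted
  attr(frames, "sites") <- sites
  frames
}

#' Partition scenario: planted per-type NAC/CAM and per-class bond orders
#'
#' Defaults reflect the distributions observed for these interfaces: bulk
#' and surface zinc NACs near +0.92/+0.95 e, oxygen NACs near -0.83 to
#' -0.93 e, zinc volumes contracted to ~62 bohr^3 and oxygen volumes
#' expanded to ~26.6 bohr^3 relative to the free atoms, proton-to-surface
#' oxygen bond orders near 0.75 and adsorbed-water-to-zinc bond orders
#' near 0.45.
#'
#' @param nac,cam Named lists `type -> c(mean, sd)`.
#' @param bo Named list `class -> c(mean, sd)` for bonded pair classes;
#'   unlisted Zn-O classes default to c(0.5, 0.05) and O-H classes to
#'   c(0.75, 0.05).
#' @param seed Integer seed.
#' @return Object of class `partition_scenario`.
#' @export
partition_scenario <- function(nac = NULL, cam = NULL, bo = NULL,
                               seed = 1L) {
  nac_def <- list(ZnA = c(0.918, 0.02), ZnB = c(0.949, 0.02),
                  OA = c(-0.918, 0.03), OB = c(-0.827, 0.03),
                  OC = c(-0.934, 0.03), OD = c(-0.834, 0.03),
                  OH = c(-0.838, 0.03), OW = c(-0.834, 0.03),
                  HA = c(0.417, 0.02))
  cam_def <- list(ZnA = c(62, 2), ZnB = c(62, 2),
                  OA = c(26.6, 1.5), OB = c(26.6, 1.5), OC = c(26.6, 1.5),
                  OD = c(26.6, 1.5), OH = c(26.6, 1.5), OW = c(26.6, 1.5),
                  HA = c(2.5, 0.3))
  bo_def <- list("OB-HA" = c(0.75, 0.05), "OH-HA" = c(0.75, 0.05),
                 "ZnA-OA" = c(0.50, 0.05), "ZnA-OB" = c(0.50, 0.05),
                 "ZnA-OC" = c(0.50, 0.05), "ZnA-OH" = c(0.65, 0.05),
                 "ZnA-OD" = c(0.45, 0.05), "ZnB-OD" = c(0.45, 0.05))
  merge_def <- function(user, def) { def[names(user)] <- user; def }
  sc <- list(nac = merge_def(nac %||% list(), nac_def),
             cam = merge_def(cam %||% list(), cam_def),
             bo = merge_def(bo %||% list(), bo_def),
             seed = as.integer(seed))
  for (v in sc$cam) if (v[1] <= 0) stop("CAM means must be positive")
  for (v in c(sc$nac, sc$cam, sc$bo))
    if (v[2] < 0) stop("standard deviations must be non-negative")
  structure(sc, class = "partition_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate partitioning records with planted per-type distributions
#'
#' Draws per-atom NACs and CAMs from the scenario's per-type normals and
#' per-pair bond orders from the per-class normals truncated at zero, for
#' `n_frames` independent snapshots of one typed configuration.
#'
#' @param frame An [md_frame()] providing elements and positions.
#' @param assignment Its `type_assignment` (labels and bonded pairs).
#' @param scenario A [partition_scenario()].
#' @param n_frames Number of snapshots to draw.
#' @param seed Integer seed (defaults to the scenario seed).
#' @return A [partition_record()] with `n_frames` frames.
#' @export
gen_partition_records <- function(frame, assignment, scenario,
                                  n_frames = 1, seed = scenario$seed) {
  labels <- assignment$labels
  unknown <- setdiff(unique(labels), names(scenario$nac))
  if (length(unknown))
    stop("scenario has no NAC parameters for label(s): ",
         paste(unknown, collapse = ", "))
  bonds <- assignment$bonds
  bo_class <- bonds$class
  miss <- setdiff(unique(bo_class), names(scenario$bo))
  bo_par <- scenario$bo
  for (cl in miss) {  # fallbacks by bond chemistry
    bo_par[[cl]] <- if (grepl("^Zn", cl)) c(0.5, 0.05) else c(0.75, 0.05)
  }
  n <- length(labels)
  .with_seed(seed, {
    atoms <- NULL; bo <- NULL
    for (f in seq_len(n_frames)) {
      nac <- vapply(labels, function(l)
        stats::rnorm(1, scenario$nac[[l]][1], scenario$nac[[l]][2]),
        numeric(1))
      cam <- vapply(labels, function(l)
        abs(stats::rnorm(1, scenario$cam[[l]][1], scenario$cam[[l]][2])),
        numeric(1))
      atoms <- rbind(atoms, data.frame(
        element = frame$elements, x = frame$xyz[, 1], y = frame$xyz[, 2],
        z = frame$xyz[, 3], nac = unname(nac), cam = unname(cam),
        frame = f))
      if (nrow(bonds)) {
        v <- vapply(bo_class, function(cl)
          stats::rnorm(1, bo_par[[cl]][1], bo_par[[cl]][2]), numeric(1))
        bo <- rbind(bo, data.frame(i = bonds$i, j = bonds$j,
                                   bo = pmax(unname(v), 0), frame = f))
      }
    }
    partition_record(atoms, bo)
  })
}

#' Generate a two-regime adsorption energy series
#'
#' Mean potential energy versus adsorbed-molecule count with a strongly
#' exothermic chemisorption slope up to a crossover coverage and a weaker
#' physisorption slope beyond, plus optional Gaussian noise.
#'
#' @param n_values Molecule counts (distinct, increasing).
#' @param area Surface area (nm^2) defining the coverage axis.
#' @param strong_slope,weak_slope Energy per added molecule (kJ/mol) below
#'   and above the crossover; defaults -80 and -45.
#' @param crossover Crossover coverage (molecules/nm^2), default 3.
#' @param noise Gaussian noise sd on each mean energy (kJ/mol).
#' @param E0 Energy offset (kJ/mol).
#' @param seed Integer seed.
#' @return data.frame with `n` and `E`, plus attributes `area` and
#'   `crossover`.
#' @export
gen_energy_series <- function(n_values, area, strong_slope = -80,
                              weak_slope = -45, crossover = 3, noise = 0,
                              E0 = 0, seed = 1L) {
  stopifnot(area > 0, noise >= 0)
  n_c <- crossover * area
  E <- E0 + strong_slope * pmin(n_values, n_c) +
       weak_slope * pmax(n_values - n_c, 0)
  if (noise > 0)
    E <- E + .with_seed(seed, stats::rnorm(length(E), 0, noise))
  out <- data.frame(n = n_values, E = E)
  attr(out, "area") <- area
  attr(out, "crossover") <- crossover
  out
}

#' Generate an analytic mean-force profile with Gaussian wells
#'
#' The underlying PMF is a sum of Gaussian wells
#' `W(s) = -sum depth_k exp(-(s - pos_k)^2 / (2 width_k^2))`; the returned
#' force is its exact negative gradient, so integration-based PMF
#' reconstruction can be checked against `W_true`.
#'
#' @param s Strictly increasing SSD grid (nm).
#' @param wells data.frame with `pos` (nm), `depth` (kJ/mol, positive =
#'   attractive), `width` (nm, positive).
#' @return List of class `force_profile`: `s`, `force`, `W_true`.
#' @export
gen_force_profile <- function(s, wells) {
  stopifnot(all(c("pos", "depth", "width") %in% names(wells)))
  if (any(wells$width <= 0)) stop("well widths must be positive")
  W <- numeric(length(s)); frc <- numeric(length(s))
  for (k in seq_len(nrow(wells))) {
    g <- exp(-(s - wells$pos[k])^2 / (2 * wells$width[k]^2))
    W <- W - wells$depth[k] * g
    frc <- frc - wells$depth[k] * g * (s - wells$pos[k]) / wells$width[k]^2
  }
  structure(list(s = s, force = frc, W_true = W - W[length(W)]),
            class = "force_profile")
}

#' Generate Boltzmann-distributed harmonic bond-length samples
#'
#' Samples from the length distribution of a harmonic bond `k/2 (b-b0)^2`
#' at temperature T: normal with mean `b0` and variance `kB T / k`.
#'
#' @param k Force constant (kJ mol^-1 nm^-2), > 0.
#' @param b0 Equilibrium length (nm).
#' @param T Temperature (K), > 0.
#' @param n Sample count.
#' @param seed Integer seed.
#' @return Numeric vector of lengths (nm).
#' @export
gen_bond_samples <- function(k, b0, T = 300, n = 1000, seed = 1L) {
  if (k <= 0 || T <= 0) stop("force constant and temperature must be positive")
  .with_seed(seed, stats::rnorm(n, b0, sqrt(ff_constants()$kb_kjmol * T / k)))
}
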