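## Structural and thermodynamic estimators used to validate the force
## field: RDF, z-density profile, differential adsorption enthalpy,
## immersion enthalpy, and PMF reconstruction from mean forces.

#' Binned profile container
#' @keywords internal
.profile_series <- function(centers, values, bin_width, kind, n_frames = 1,
                            meta = list()) {
  structure(list(centers = centers, values = values, bin_width = bin_width,
                 kind = kind, n_frames = n_frames, meta = meta),
            class = "profile_series")
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("%s profile: %d bins of %.4g nm, %d frame(s)\n",
              x$kind, length(x$centers), x$bin_width, x$n_frames))
  invisible(x)
}

#' @export
plot.profile_series <- function(x, ...) {
  ylab <- switch(x$kind, rdf = "g(r)", density = expression(rho(z)),
                 x$kind)
  graphics::plot(x$centers, x$values, type = "l",
                 xlab = "distance (nm)", ylab = ylab, ...)
  invisible(x)
}

## selection helper: indices matching a type label (via assignment) or an
## element symbol
.select_atoms <- function(frame, sel, assignment = NULL) {
  if (sel %in% unique(frame$elements)) return(which(frame$elements == sel))
  if (is.null(assignment)) assignment <- assign_atom_types(frame)
  which(assignment$labels == sel)
}

#' Radial distribution function between two selections
#'
#' Standard pair-distance histogram normalized by the ideal-gas shell
#' density, averaged over frames. Selections are force-field type labels
#' (typed per frame) or plain element symbols.
#'
#' @param traj List of [md_frame()]s (or one frame).
#' @param selection_A,selection_B Type label (e.g. `"OH"`) or element.
#' @param r_max Histogram range (nm); must not exceed half the smallest box
#'   length.
#' @param bin Bin width (nm), default 0.002.
#' @return A `profile_series` with `g(r)` values.
#' @export
rdf <- function(traj, selection_A, selection_B, r_max, bin = 0.002) {
  if (inherits(traj, "md_frame")) traj <- list(traj)
  if (!length(traj)) stop("empty trajectory")
  if (r_max > min(traj[[1]]$box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box length")
  edges <- seq(0, r_max, by = bin)
  counts <- numeric(length(edges) - 1)
  norm <- 0
  for (fr in traj) {
    ty <- if (selection_A %in% unique(fr$elements) &&
              selection_B %in% unique(fr$elements)) NULL
          else assign_atom_types(fr)
    ia <- .select_atoms(fr, selection_A, ty)
    ib <- .select_atoms(fr, selection_B, ty)
    if (!length(ia) || !length(ib))
      stop("empty selection: ", selection_A, " / ", selection_B)
    d2 <- pair_dist2(fr$xyz[ia, , drop = FALSE], fr$xyz[ib, , drop = FALSE],
                     fr$box)
    same <- identical(ia, ib)
    d <- sqrt(if (same) d2[upper.tri(d2)] else as.vector(d2))
    counts <- counts + graphics::hist(d[d < r_max], breaks = edges,
                                      plot = FALSE)$counts *
              (if (same) 2 else 1)
    vol <- prod(fr$box)
    norm <- norm + length(ia) * (length(ib) - same) / vol
  }
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (norm * shell)
  .profile_series((edges[-1] + edges[-length(edges)]) / 2, g, bin, "rdf",
                  length(traj),
                  meta = list(A = selection_A, B = selection_B))
}

#' First maximum of a profile
#'
#' Peak position and height of the first coordination shell, located as the
#' global maximum of the profile (for first-shell work `r_max` is chosen
#' inside the first minimum, where the global and first maxima coincide).
#'
#' @param profile A `profile_series`.
#' @return List with `r_peak` and `g_peak`.
#' @export
first_peak <- function(profile) {
  i <- which.max(profile$values)
  list(r_peak = profile$centers[i], g_peak = profile$values[i])
}

#' Number-density profile along the surface normal
#'
#' Per-bin number density (nm^-3) of a species along z, averaged over
#' frames. The profile integrates to the particle count per unit slab
#' area: `sum(rho * dz) = N / (box_x * box_y)`.
#'
#' @param traj List of [md_frame()]s (or one frame).
#' @param species Type label or element symbol.
#' @param bin Bin width (nm), default 0.02.
#' @return A `profile_series` of densities.
#' @export
density_profile <- function(traj, species, bin = 0.02) {
  if (inherits(traj, "md_frame")) traj <- list(traj)
  if (!length(traj)) stop("empty trajectory")
  box <- traj[[1]]$box
  edges <- seq(0, box[3], by = bin)
  if (edges[length(edges)] < box[3]) edges <- c(edges, box[3])
  counts <- numeric(length(edges) - 1)
  for (fr in traj) {
    ty <- if (species %in% unique(fr$elements)) NULL
          else assign_atom_types(fr)
    ii <- .select_atoms(fr, species, ty)
    z <- fr$xyz[ii, 3] %% box[3]
    counts <- counts + graphics::hist(z, breaks = edges, plot = FALSE)$counts
  }
  widths <- diff(edges)
  rho <- counts / (length(traj) * box[1] * box[2] * widths)
  .profile_series((edges[-1] + edges[-length(edges)]) / 2, rho, bin,
                  "density", length(traj), meta = list(species = species,
                                                       area = box[1] * box[2]))
}

#' Differential adsorption enthalpy versus coverage
#'
#' The differential heat of adsorption between consecutive loadings is the
#' slope of the mean potential energy in the number of adsorbed molecules,
#' `[<E(n2)> - <E(n1)>] / (n2 - n1)`, minus a per-molecule reference energy
#' (bulk liquid water by default, matching the calorimetric convention of
#' reporting enthalpies relative to liquid). The coverage axis is the
#' midpoint molecule count per surface area.
#'
#' @param points data.frame with columns `n` (molecule count) and `E`
#'   (mean potential energy, kJ/mol); at least 2 distinct `n`.
#' @param e_ref Per-molecule reference energy (kJ/mol).
#' @param area Surface area used for the coverage axis (nm^2).
#' @return data.frame of class `adsorption_curve`: `coverage`
#'   (molecules/nm^2) and `dH` (kJ/mol).
#' @export
adsorption_enthalpy <- function(points, e_ref = 0, area = 1) {
  stopifnot(all(c("n", "E") %in% names(points)), nrow(points) >= 2,
            area > 0)
  points <- points[order(points$n), ]
  dn <- diff(points$n)
  if (any(dn == 0)) stop("duplicate molecule counts n")
  dH <- diff(points$E) / dn - e_ref
  out <- data.frame(
    coverage = (points$n[-nrow(points)] + points$n[-1]) / 2 / area,
    dH = dH)
  class(out) <- c("adsorption_curve", "data.frame")
  out
}

#' Locate the adsorption-regime crossover of an enthalpy curve
#'
#' Real adsorption isotherms on hydroxylated oxides show two regimes:
#' strongly exothermic chemisorption at low coverage and weaker
#' physisorption beyond. The crossover is located at the largest jump
#' between consecutive differential enthalpies.
#'
#' @param curve An [adsorption_enthalpy()] result.
#' @return Crossover coverage (molecules/nm^2).
#' @export
detect_crossover <- function(curve) {
  stopifnot(nrow(curve) >= 2)
  jumps <- abs(diff(curve$dH))
  i <- which.max(jumps)
  (curve$coverage[i] + curve$coverage[i + 1]) / 2
}

#' Immersion enthalpy per unit area
#'
#' Enthalpy change when a dry surface is fully wetted:
#' `(E_interface - E_surface - E_solvent) / (2 box_x box_y)`, both faces
#' wetted, converted from kJ mol^-1 nm^-2 to J m^-2.
#'
#' @param E_interface,E_surface,E_solvent Mean potential energies (kJ/mol)
#'   of the hydrated slab, the dry slab, and bulk water with the same
#'   number of molecules.
#' @param box_x,box_y In-plane box lengths (nm).
#' @param both_faces Divide by both wetted faces (default TRUE).
#' @return Immersion enthalpy in J/m^2.
#' @export
immersion_enthalpy <- function(E_interface, E_surface, E_solvent,
                               box_x, box_y, both_faces = TRUE) {
  if (box_x <= 0 || box_y <= 0) stop("areas must be positive")
  area <- box_x * box_y * (if (both_faces) 2 else 1)
  .kjmol_nm2_to_J_m2((E_interface - E_surface - E_solvent) / area)
}

#' Potential of mean force from a mean-force profile
#'
#' Integrates the mean force acting on the adsorbate along the surface
#' separation distance, `W(s) = integral from s to s_bulk of F(s') ds'`
#' (trapezoidal rule), anchored to `W(s_bulk) = 0` at the bulk plateau so
#' that an attractive well comes out negative. If no plateau is detected
#' (mean force not flat near the far end of the grid), the profile is
#' anchored at the last grid point with a warning. The binding free energy
#' is the global minimum of W relative to bulk, with no standard-state
#' volume correction.
#'
#' @param s Strictly increasing SSD grid (nm).
#' @param force Mean force at each `s` (kJ mol^-1 nm^-1).
#' @param plateau_tol Plateau test: mean |F| over the last 10% of the grid
#'   must be below `plateau_tol * max(|F|)`. Default 0.05.
#' @return Object of class `pmf`: list with `s`, `W` (kJ/mol),
#'   `binding_free_energy` (kJ/mol), `minima` (data.frame `s`, `W` of all
#'   local minima).
#' @export
pmf_from_mean_force <- function(s, force, plateau_tol = 0.05) {
  stopifnot(length(s) == length(force), length(s) >= 2)
  if (any(diff(s) <= 0)) stop("SSD grid must be strictly increasing")
  n <- length(s)
  tail_ix <- seq(max(1, ceiling(0.9 * n)), n)
  if (max(abs(force)) > 0 &&
      mean(abs(force[tail_ix])) > plateau_tol * max(abs(force)))
    warning("no bulk plateau detected; anchoring W = 0 at the grid end")
  ## trapezoidal integral from s_i to s_n, accumulated from the far end
  seg <- diff(s) * (force[-n] + force[-1]) / 2
  W <- c(rev(cumsum(rev(seg))), 0)
  imin <- which(diff(sign(diff(W))) > 0) + 1
  if (W[1] < W[2]) imin <- c(1, imin)
  minima <- data.frame(s = s[imin], W = W[imin])
  structure(list(s = s, W = W,
                 binding_free_energy = min(W),
                 minima = minima),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("PMF over [%.3f, %.3f] nm; binding free energy %.2f kJ/mol\n",
              min(x$s), max(x$s), x$binding_free_energy))
  if (nrow(x$minima)) {
    cat("local minima:\n"); print(x$minima, digits = 3)
  }
  invisible(x)
}

#' @export
plot.pmf <- function(x, ...) {
  graphics::plot(x$s, x$W, type = "l", xlab = "SSD (nm)",
                 ylab = "W(s) (kJ/mol)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
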