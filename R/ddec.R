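## From electron-density partitioning output (NAC, CAM, BO) to classical
## force-field parameters: Tkatchenko-Scheffler volume scaling for the
## Lennard-Jones terms, mean NACs as partial charges, Boltzmann inversion
## for harmonic bonds and angles.

#' Per-atom electron-density partitioning record
#'
#' Container for the per-snapshot output of a density-partitioning code:
#' net atomic charges (NAC, e), cubed atomic moments (CAM, bohr^3) and a
#' pairwise bond-order table.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (nm),
#'   `nac` (e), `cam` (bohr^3) and optionally `frame`.
#' @param bo data.frame with columns `i`, `j` (atom indices), `bo`
#'   (dimensionless, >= 0) and optionally `frame`. Stored with `i < j`.
#' @return Object of class `partition_record`.
#' @export
partition_record <- function(atoms, bo = NULL) {
  stopifnot(all(c("element", "x", "y", "z", "nac", "cam") %in% names(atoms)))
  if (any(atoms$cam <= 0)) stop("cubed atomic moments must be positive")
  if (is.null(atoms$frame)) atoms$frame <- 1L
  if (is.null(bo))
    bo <- data.frame(i = integer(), j = integer(), bo = numeric(),
                     frame = integer())
  stopifnot(all(c("i", "j", "bo") %in% names(bo)))
  if (any(bo$bo < 0)) stop("bond orders must be non-negative")
  if (is.null(bo$frame)) bo$frame <- 1L
  ij <- cbind(pmin(bo$i, bo$j), pmax(bo$i, bo$j))
  bo$i <- ij[, 1]; bo$j <- ij[, 2]
  structure(list(atoms = atoms, bo = bo), class = "partition_record")
}

#' @export
print.partition_record <- function(x, ...) {
  cat(sprintf("partition record: %d atom rows over %d frame(s), %d bond-order pairs\n",
              nrow(x$atoms), length(unique(x$atoms$frame)), nrow(x$bo)))
  invisible(x)
}

#' Free-atom reference volumes, dispersion coefficients and radii
#'
#' Reference values for the Tkatchenko-Scheffler scaling: free-atom volumes
#' V0 (bohr^3) computed at the same level of theory as the training
#' ensemble (78.99 for Zn, 23.52 for O), free-atom dispersion coefficients
#' B0 (Ha bohr^6; 276 for Zn, 16.7 for O), and free-atom van der Waals
#' radii R0 (nm) at electron-density-contour scale. The R0 values are
#' overridable defaults: the effective in-material radii they imply
#' (about 0.210 nm for Zn, 0.176 nm for O at typical oxide volumes) are
#' consistency anchors, not fitted quantities.
#'
#' @return data.frame with columns `element`, `V0`, `B0`, `R0`.
#' @export
free_atom_reference <- function() {
  data.frame(
    element = c("Zn", "O", "H"),
    V0 = c(78.99, 23.52, 7.5),
    B0 = c(276, 16.7, 6.5),
    R0 = c(0.228, 0.169, 0.164)
  )
}

#' Per-type statistics of partitioning output
#'
#' Pools NAC and CAM values per force-field atom type over all atoms and
#' all frames (pooling across surfaces is the default: the per-type
#' distributions are very similar for the two cuts, which is what makes
#' connectivity-based types transferable).
#'
#' @param records A [partition_record()] or list of them.
#' @param labels Per-frame atom labels: a character vector, a
#'   `type_assignment`, or a list of either (one per record/frame).
#' @return Object of class `type_statistics`: data.frame with `type`, `n`,
#'   `nac_mean`, `nac_sd`, `cam_mean`, `cam_sd`.
#' @export
type_statistics <- function(records, labels) {
  if (inherits(records, "partition_record")) records <- list(records)
  if (inherits(labels, "type_assignment") || is.character(labels))
    labels <- list(labels)
  if (length(labels) != length(records))
    stop("need one label set per partition record")
  lab_chr <- lapply(labels, function(l)
    if (inherits(l, "type_assignment")) l$labels else l)
  nac <- numeric(); cam <- numeric(); typ <- character()
  for (k in seq_along(records)) {
    at <- records[[k]]$atoms
    lk <- lab_chr[[k]]
    per_frame <- split(seq_len(nrow(at)), at$frame)
    for (rows in per_frame) {
      if (length(rows) != length(lk))
        stop("label/record length mismatch: ", length(lk), " labels for ",
             length(rows), " atoms")
      nac <- c(nac, at$nac[rows]); cam <- c(cam, at$cam[rows])
      typ <- c(typ, lk)
    }
  }
  agg <- lapply(split(seq_along(typ), typ), function(ix) {
    data.frame(type = typ[ix[1]], n = length(ix),
               nac_mean = mean(nac[ix]),
               nac_sd = if (length(ix) > 1) stats::sd(nac[ix]) else 0,
               cam_mean = mean(cam[ix]),
               cam_sd = if (length(ix) > 1) stats::sd(cam[ix]) else 0)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  class(out) <- c("type_statistics", "data.frame")
  out
}

#' Dispersion coefficient from volume scaling
#'
#' Tkatchenko-Scheffler volume-square scaling of the free-atom dispersion
#' coefficient: `B = (V_mean / V0)^2 * B0`.
#'
#' @param V_mean Mean in-material atomic volume (CAM, bohr^3).
#' @param V0 Free-atom reference volume (bohr^3).
#' @param B0 Free-atom dispersion coefficient (Ha bohr^6).
#' @return List with `B_ha_bohr6` and `B_kjmol_nm6`.
#' @examples
#' dispersion_B(0.9 * 78.99, 78.99, 276)$B_ha_bohr6  # 223.56
#' @export
dispersion_B <- function(V_mean, V0, B0) {
  if (any(c(V_mean, V0, B0) <= 0)) stop("all inputs must be positive")
  b <- (V_mean / V0)^2 * B0
  list(B_ha_bohr6 = b, B_kjmol_nm6 = b * .ha_bohr6_to_kjmol_nm6())
}

#' Effective van der Waals radius from volume scaling
#'
#' `R = (V_mean / V0)^(1/3) * R0`: cube-root volume scaling of the
#' free-atom van der Waals radius.
#'
#' @param V_mean Mean atomic volume (bohr^3).
#' @param V0 Free-atom reference volume (bohr^3).
#' @param R0 Free-atom van der Waals radius (nm).
#' @return Radius in nm.
#' @export
vdw_radius <- function(V_mean, V0, R0) {
  if (any(c(V_mean, V0, R0) <= 0)) stop("all inputs must be positive")
  (V_mean / V0)^(1 / 3) * R0
}

#' Repulsive Lennard-Jones parameter from the contact-distance rule
#'
#' Empirical scaling `A = B * (2R)^6 / 2`, which places the Lennard-Jones
#' minimum at the contact distance 2R of two atoms of effective van der
#' Waals radius R (equivalently sigma = 2R / 2^(1/6), epsilon =
#' B / (2 (2R)^6)). This is a preliminary estimate by construction; in the
#' full workflow A is fine-tuned afterwards against first RDF maxima.
#'
#' @param B Dispersion coefficient (kJ mol^-1 nm^6).
#' @param R Effective van der Waals radius (nm).
#' @return A in kJ mol^-1 nm^12.
#' @export
repulsive_A <- function(B, R) {
  if (any(c(B, R) <= 0)) stop("B and R must be positive")
  B * (2 * R)^6 / 2
}

#' Convert A/B Lennard-Jones form to sigma/epsilon (and back)
#'
#' `sigma = (A/B)^(1/6)`, `epsilon = B^2 / (4A)`. For `B = 0` (hydrogen-like
#' types with no dispersion) the pair `(0, 0)` is returned by convention.
#'
#' @param A Repulsive coefficient (kJ mol^-1 nm^12), > 0.
#' @param B Dispersion coefficient (kJ mol^-1 nm^6), >= 0.
#' @return List with `sigma` (nm) and `epsilon` (kJ/mol).
#' @examples
#' ab <- sigma_eps_to_ab(0.315, 0.636)
#' ab_to_sigma_eps(ab$A, ab$B)  # round-trips
#' @export
ab_to_sigma_eps <- function(A, B) {
  stopifnot(A > 0 || B == 0, B >= 0)
  if (B == 0) return(list(sigma = 0, epsilon = 0))
  list(sigma = (A / B)^(1 / 6), epsilon = B^2 / (4 * A))
}

#' @rdname ab_to_sigma_eps
#' @param sigma,epsilon Lennard-Jones parameters (nm, kJ/mol).
#' @export
sigma_eps_to_ab <- function(sigma, epsilon) {
  stopifnot(sigma >= 0, epsilon >= 0)
  list(A = 4 * epsilon * sigma^12, B = 4 * epsilon * sigma^6)
}

## charge constraints shared with compatible water/biomolecule force fields
.TIP3P <- list(q_o = -0.834, q_h = 0.417, sigma_o = 0.315, eps_o = 0.636)

#' Assign per-type partial charges from NAC statistics
#'
#' Each type's charge is its mean net atomic charge, with three rules that
#' keep the force field compatible with a standard three-site water model
#' and a neutral bulk: free-water oxygen (OW) is forced to -0.834 e, every
#' hydrogen (HA) to 0.417 e, and bulk oxygen (OA) to the negative of the
#' bulk zinc (ZnA) charge so bulk ZnO is exactly neutral.
#'
#' @param stats A [type_statistics()] result.
#' @param q_ow,q_h Water-model charge constraints (e).
#' @return data.frame with `type` and `charge` (e).
#' @export
assign_charges <- function(stats, q_ow = .TIP3P$q_o, q_h = .TIP3P$q_h) {
  ch <- stats::setNames(stats$nac_mean, stats$type)
  ch["OW"] <- q_ow
  ch["HA"] <- q_h
  if ("OA" %in% names(ch)) {
    if (!"ZnA" %in% names(ch))
      stop("bulk neutrality rule needs ZnA statistics to set the OA charge")
    ch["OA"] <- -ch[["ZnA"]]
  }
  data.frame(type = names(ch), charge = unname(ch))
}

#' Fit a harmonic bond by Boltzmann inversion
#'
#' For bond-length samples drawn from an equilibrium ensemble at
#' temperature T, a harmonic well `k/2 (b - b0)^2` implies a normal length
#' distribution; the fit is therefore `b0 = mean(samples)` and
#' `k = kB T / var(samples)`.
#'
#' @param samples Bond lengths (nm); at least 30 with positive variance.
#' @param T Temperature (K), default 300.
#' @return List of class `harmonic_fit` with `b0` (nm),
#'   `k` (kJ mol^-1 nm^-2), `n`, `T`.
#' @export
fit_bond_harmonic <- function(samples, T = 300) {
  if (length(samples) < 30) stop("need at least 30 samples")
  v <- stats::var(samples)
  if (v <= 0)
    stop("zero sample variance: a rigid constraint is suggested, ",
         "not a harmonic bond")
  structure(list(b0 = mean(samples), k = ff_constants()$kb_kjmol * T / v,
                 n = length(samples), T = T),
            class = "harmonic_fit")
}

#' Fit a harmonic angle by Boltzmann inversion
#'
#' Same normal-distribution scheme as [fit_bond_harmonic()] on angle
#' samples: `theta0 = mean` (reported in degrees) and
#' `k_theta = kB T / var` with the variance taken in radians, so `k_theta`
#' is in kJ mol^-1 rad^-2.
#'
#' @param samples_deg Angle samples (degrees).
#' @param T Temperature (K).
#' @return List of class `harmonic_fit` with `theta0` (deg), `k_theta`
#'   (kJ mol^-1 rad^-2), `n`, `T`.
#' @export
fit_angle_harmonic <- function(samples_deg, T = 300) {
  if (length(samples_deg) < 30) stop("need at least 30 samples")
  v <- stats::var(samples_deg * pi / 180)
  if (v <= 0) stop("zero sample variance: a rigid constraint is suggested")
  structure(list(theta0 = mean(samples_deg),
                 k_theta = ff_constants()$kb_kjmol * T / v,
                 n = length(samples_deg), T = T),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  if (!is.null(x$b0))
    cat(sprintf("harmonic bond fit: b0 = %.4f nm, k = %.0f kJ/mol/nm^2 (n = %d, T = %g K)\n",
                x$b0, x$k, x$n, x$T))
  else
    cat(sprintf("harmonic angle fit: theta0 = %.2f deg, k = %.1f kJ/mol/rad^2 (n = %d, T = %g K)\n",
                x$theta0, x$k_theta, x$n, x$T))
  invisible(x)
}

#' Assemble a force-field table from partitioning statistics
#'
#' Combines [assign_charges()], the volume-scaled Lennard-Jones derivation
#' ([dispersion_B()], [vdw_radius()], [repulsive_A()]) and optional bonded
#' fits into a complete per-type table. Water-like oxygens (OW, and OD in
#' the NB flavour, where adsorbed water is ordinary water) keep the
#' three-site water-model Lennard-Jones parameters; hydrogens get zero LJ.
#' For the NB flavour [special_case_znb()] is applied.
#'
#' @param stats [type_statistics()] result covering the slab types.
#' @param model Force-field flavour, `"NB"` or `"BOND"`.
#' @param bonds Optional data.frame `class`, `b0`, `k` (e.g. from
#'   [fit_bond_harmonic()] per bond class).
#' @param angles Optional data.frame `class`, `theta0`, `k_theta`.
#' @param reference Free-atom reference table, [free_atom_reference()].
#' @return Object of class `ff_table`: list with `atoms` (data.frame
#'   `type`, `charge`, `sigma`, `epsilon`, `A`, `B`), `bonds`, `angles`,
#'   `model`.
#' @export
derive_ff <- function(stats, model = c("NB", "BOND"), bonds = NULL,
                      angles = NULL, reference = free_atom_reference()) {
  model <- match.arg(model)
  charges <- assign_charges(stats)
  ref <- split(reference, reference$element)  # named by element
  water_lj <- c("OW", if (model == "NB") "OD")
  rows <- lapply(charges$type, function(ty) {
    q <- charges$charge[charges$type == ty]
    if (ty == "HA") {
      se <- list(sigma = 0, epsilon = 0); AB <- list(A = 0, B = 0)
    } else if (ty %in% water_lj) {
      se <- list(sigma = .TIP3P$sigma_o, epsilon = .TIP3P$eps_o)
      AB <- sigma_eps_to_ab(se$sigma, se$epsilon)
    } else {
      el <- if (grepl("^Zn", ty)) "Zn" else "O"
      st <- stats[stats$type == ty, ]
      if (!nrow(st)) stop("no statistics for type ", ty)
      r <- ref[[el]]
      B <- dispersion_B(st$cam_mean, r$V0, r$B0)$B_kjmol_nm6
      R <- vdw_radius(st$cam_mean, r$V0, r$R0)
      A <- repulsive_A(B, R)
      se <- ab_to_sigma_eps(A, B); AB <- list(A = A, B = B)
    }
    data.frame(type = ty, charge = q, sigma = se$sigma,
               epsilon = se$epsilon, A = AB$A, B = AB$B)
  })
  ff <- structure(list(atoms = do.call(rbind, rows),
                       bonds = bonds, angles = angles, model = model),
                  class = "ff_table")
  if (model == "NB" && "ZnB" %in% ff$atoms$type) ff <- special_case_znb(ff)
  ff
}

#' Short-sigma special case for the water-coordinating surface zinc
#'
#' In the NB flavour, molecularly adsorbed water is held at its roughly
#' 2 A Zn-O distance only by nonbonded forces; to make that possible the
#' 3-coordinated surface zinc (ZnB) gets a deliberately short sigma of
#' 0.150 nm, with epsilon copied from bulk zinc (ZnA). The ZnB charge
#' stays at its own NAC mean. Applying this to a BOND-flavour table is a
#' no-op with a warning (BOND ties adsorbed water with a harmonic bond
#' instead).
#'
#' @param ff An `ff_table`.
#' @param sigma_znb The short sigma (nm), default 0.150.
#' @return The modified `ff_table`.
#' @export
special_case_znb <- function(ff, sigma_znb = 0.150) {
  if (ff$model != "NB") {
    warning("ZnB short-sigma rule applies to the NB flavour only; table unchanged")
    return(ff)
  }
  at <- ff$atoms
  if (!"ZnB" %in% at$type) {
    warning("no ZnB type present; table unchanged")
    return(ff)
  }
  if (!"ZnA" %in% at$type) stop("ZnB rule needs ZnA epsilon")
  i <- at$type == "ZnB"
  at$sigma[i] <- sigma_znb
  at$epsilon[i] <- at$epsilon[at$type == "ZnA"]
  AB <- sigma_eps_to_ab(at$sigma[i], at$epsilon[i])
  at$A[i] <- AB$A; at$B[i] <- AB$B
  ff$atoms <- at
  ff
}

#' @export
print.ff_table <- function(x, ...) {
  cat(sprintf("force-field table (%s flavour):\n", x$model))
  print(x$atoms, digits = 4)
  if (!is.null(x$bonds)) { cat("bonds:\n"); print(x$bonds, digits = 4) }
  if (!is.null(x$angles)) { cat("angles:\n"); print(x$angles, digits = 4) }
  invisible(x)
}
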