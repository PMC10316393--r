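## Surface charge of decorated slabs: density, integer neutralization with
## counterions, and solving decoration fractions for a target density.

#' Attach per-atom charges to a slab
#'
#' Types every atom with [assign_atom_types()] and looks its charge up in
#' the force-field table.
#'
#' @param slab A (possibly decorated) `zno_slab`.
#' @param ff An `ff_table` (or a data.frame with `type`, `charge`).
#' @param assignment Optional precomputed `type_assignment`.
#' @return The slab with a `charges` element (e) and the assignment stored
#'   in `attr(, "types")`.
#' @export
charged_slab <- function(slab, ff, assignment = NULL) {
  atoms <- if (inherits(ff, "ff_table")) ff$atoms else ff
  if (is.null(assignment)) assignment <- assign_atom_types(slab)
  q <- stats::setNames(atoms$charge, atoms$type)
  missing <- setdiff(unique(assignment$labels), names(q))
  if (length(missing))
    stop("no charge for type(s): ", paste(missing, collapse = ", "))
  slab$charges <- unname(q[assignment$labels])
  attr(slab, "types") <- assignment
  slab
}

#' Surface charge density of a charged slab
#'
#' Total slab charge (decorations included) divided by the total exposed
#' area; both faces count, so the area is `2 * box_x * box_y`. The sign is
#' preserved: hydrated ZnO at neutral pH comes out positive, consistent
#' with its measured zeta potential.
#'
#' @param slab A [charged_slab()] result.
#' @return Charge density in e/nm^2.
#' @export
surface_charge_density <- function(slab) {
  if (is.null(slab$charges)) stop("slab has no charges; see charged_slab()")
  area <- 2 * slab$box[1] * slab$box[2]
  if (area <= 0) stop("zero surface area")
  sum(slab$charges) / area
}

#' Shift surface charges to the nearest integer total and add counterions
#'
#' Classical MD needs an integer system charge: the slab total is brought
#' to the nearest integer by a uniform shift spread over the surface atoms
#' (decorating species plus the outermost Zn/O layer of each face), and the
#' rounded total is then compensated by counterions (Cl- for positive
#' slabs, Na+ for negative).
#'
#' @param slab A [charged_slab()] result.
#' @param surface_atoms Optional integer indices of the atoms absorbing the
#'   shift; defaults to decoration atoms plus the outermost layers.
#' @return List with `slab` (charges shifted), `shift` (e per surface
#'   atom), `total` (integer slab charge), `n_counterions`, `species`.
#' @export
neutralize_to_integer <- function(slab, surface_atoms = NULL) {
  if (is.null(slab$charges)) stop("slab has no charges; see charged_slab()")
  if (is.null(surface_atoms))
    surface_atoms <- which(slab$role != "slab" | slab$face %in% c("top", "bottom"))
  if (!length(surface_atoms)) stop("empty surface atom set")
  q_tot <- sum(slab$charges)
  target <- round(q_tot)
  shift <- (target - q_tot) / length(surface_atoms)
  slab$charges[surface_atoms] <- slab$charges[surface_atoms] + shift
  list(slab = slab, shift = shift, total = target,
       n_counterions = abs(target),
       species = if (target > 0) "Cl-" else if (target < 0) "Na+" else NA_character_)
}

## per-site charge increments of the two decoration moves, given a charge map
.decoration_increments <- function(q, model) {
  need <- c("ZnA", "OC", "OB", "OH", "HA",
            if (model == "NB") "ZnB" else "OD")
  missing <- setdiff(need, names(q))
  if (length(missing))
    stop("charge table lacks type(s): ", paste(missing, collapse = ", "))
  if (model == "NB") {
    ## bare ZnB site -> ZnA + OH + HA
    d_oh <- (q[["ZnA"]] - q[["ZnB"]]) + q[["OH"]] + q[["HA"]]
    base_zn <- q[["ZnB"]]
  } else {
    ## water-bound ZnA site (OD + 2 HA) -> ZnA + OH + HA
    d_oh <- q[["OH"]] + q[["HA"]] - (q[["OD"]] + 2 * q[["HA"]])
    base_zn <- q[["ZnA"]] + q[["OD"]] + 2 * q[["HA"]]
  }
  d_h <- (q[["OB"]] - q[["OC"]]) + q[["HA"]]  # OC + HA -> OB + HA
  list(d_oh = unname(d_oh), d_h = unname(d_h), base_zn = unname(base_zn),
       base_o = unname(q[["OC"]]))
}

#' Predicted surface charge density as a function of decoration fractions
#'
#' The density is linear in each fraction: every hydroxylation or
#' protonation event adds a fixed charge increment at a fixed site density.
#'
#' @param f_oh,f_h Decoration fractions.
#' @param ff An `ff_table` (its `model` selects BOND/NB accounting).
#' @param n_zn_sites,n_o_sites Surface site counts (both faces).
#' @param area In-plane box area `box_x * box_y` (nm^2), single face.
#' @return Density in e/nm^2.
#' @export
predict_charge_density <- function(f_oh, f_h, ff, n_zn_sites, n_o_sites,
                                   area) {
  q <- stats::setNames(ff$atoms$charge, ff$atoms$type)
  inc <- .decoration_increments(q, ff$model)
  (n_zn_sites * (inc$base_zn + f_oh * inc$d_oh) +
   n_o_sites * (inc$base_o + f_h * inc$d_h)) / (2 * area)
}

#' Solve decoration fractions for a target surface charge density
#'
#' The zeta potential (hence surface charge density) of ZnO depends on the
#' solvent, pH and ionic strength; the model is adapted by adjusting how
#' many surface sites carry hydroxyls and protons. The predicted density
#' is linear in `(f_oh, f_h)`, so one target leaves a one-parameter family
#' of solutions; it is resolved by the minimal Euclidean move from the
#' aqueous defaults (0.65, 0.65), which automatically raises `f_oh` and
#' lowers `f_h` for targets more negative than the aqueous density.
#'
#' @param target_density Target charge density (e/nm^2).
#' @param ff An `ff_table`.
#' @param n_zn_sites,n_o_sites Surface site counts (both faces).
#' @param area Single-face in-plane area (nm^2).
#' @param f_default Aqueous default fractions, `c(0.65, 0.65)`.
#' @return List with `f_oh`, `f_h`, `achieved` density, and the achievable
#'   `interval`.
#' @export
solve_fractions_for_target <- function(target_density, ff, n_zn_sites,
                                       n_o_sites, area,
                                       f_default = c(0.65, 0.65)) {
  pr <- function(f) predict_charge_density(f[1], f[2], ff, n_zn_sites,
                                           n_o_sites, area)
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  vals <- apply(corners, 1, pr)
  interval <- range(vals)
  if (target_density < interval[1] - 1e-12 ||
      target_density > interval[2] + 1e-12)
    stop(sprintf("target %.3f e/nm^2 infeasible; achievable interval [%.3f, %.3f]",
                 target_density, interval[1], interval[2]))
  q <- stats::setNames(ff$atoms$charge, ff$atoms$type)
  inc <- .decoration_increments(q, ff$model)
  s <- c(n_zn_sites * inc$d_oh, n_o_sites * inc$d_h) / (2 * area)
  lam <- (target_density - pr(f_default)) / sum(s^2)
  f <- f_default + lam * s
  if (any(f < 0 | f > 1)) {
    ## clamp one fraction to its bound, solve the other exactly
    cand <- list()
    for (k in 1:2) for (b in c(0, 1)) {
      other <- 3 - k
      fk <- f_default
      fk[k] <- b
      rhs <- target_density - (pr(c(0, 0)) + s[k] * b)
      fk[other] <- rhs / s[other]
      if (fk[other] >= -1e-12 && fk[other] <= 1 + 1e-12)
        cand[[length(cand) + 1]] <- pmin(pmax(fk, 0), 1)
    }
    if (!length(cand)) stop("no feasible clamped solution found")
    moves <- vapply(cand, function(fk) sum((fk - f_default)^2), numeric(1))
    f <- cand[[which.min(moves)]]
  }
  list(f_oh = f[1], f_h = f[2], achieved = pr(f), interval = interval)
}
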