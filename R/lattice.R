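## Wurtzite ZnO slab construction for the two dominant nonpolar faces,
## surface-site enumeration and hydroxyl/proton/water decoration.

.SUPPORTED_MILLER <- c("10-10", "1-210")

#' Wurtzite ZnO unit cell
#'
#' Hexagonal wurtzite cell parameters. The shipped defaults are per-surface:
#' each slab in the training set had its cell optimized independently at the
#' DFT level, so the in-plane lattice constants implied by the published box
#' dimensions differ slightly between the (10-10) and (1-210) cuts
#' (a = 0.33667 vs 0.32909 nm; c = 0.5300 nm for both). With these defaults
#' the built supercells reproduce the published in-plane boxes
#' (1.06 x 1.01 nm and 1.14 x 1.06 nm) to better than 0.1%.
#'
#' @param a,c Lattice constants (nm). If `NULL`, per-surface defaults are
#'   used (requires `miller`).
#' @param u Internal anion parameter (fractional); standard wurtzite value
#'   0.382 by default.
#' @param miller Surface cut the cell will be used for, `"10-10"` or
#'   `"1-210"`; only consulted when `a` or `c` is `NULL`.
#' @param species Cation/anion element symbols.
#' @return Object of class `wurtzite_cell`: list with `a`, `c`, `u`,
#'   `species`.
#' @examples
#' wurtzite_cell(miller = "10-10")
#' @export
wurtzite_cell <- function(a = NULL, c = NULL, u = 0.382,
                          miller = "10-10",
                          species = c(cation = "Zn", anion = "O")) {
  defaults <- list(
    "10-10" = list(a = 1.01 / 3, c = 0.53),
    "1-210" = list(a = 1.14 / (2 * sqrt(3)), c = 0.53)
  )
  if (is.null(a) || is.null(c)) {
    if (!miller %in% .SUPPORTED_MILLER)
      stop("unsupported Miller index '", miller, "'")
    if (is.null(a)) a <- defaults[[miller]]$a
    if (is.null(c)) c <- defaults[[miller]]$c
  }
  stopifnot(a > 0, c > 0, u > 0, u < 1)
  structure(list(a = a, c = c, u = u, species = species),
            class = "wurtzite_cell")
}

#' @export
print.wurtzite_cell <- function(x, ...) {
  cat(sprintf("wurtzite cell: a = %.5f nm, c = %.5f nm, u = %.3f (%s/%s)\n",
              x$a, x$c, x$u, x$species[1], x$species[2]))
  invisible(x)
}

## Orthorhombic surface repeat cells (8 atoms: 4 Zn + 4 O), slab frame
## x,y in-plane, z along the surface normal. Fractional coordinates.
## (10-10): box (c, a, a*sqrt(3)); atom planes at z = 1/6, 1/3, 2/3, 5/6
##   stack as bilayers, so the cell boundary cuts through the wide gap and
##   both faces terminate in stoichiometric Zn-O dimer rows.
## (1-210): box (a*sqrt(3), c, a); two stoichiometric planes per cell at
##   z = 0 and 1/2, uniform spacing a/2.
.surface_basis <- function(miller, cell) {
  u <- cell$u
  if (miller == "10-10") {
    frac <- rbind(
      c(0.0, 0.0, 1 / 3), c(0.5, 0.5, 1 / 6),
      c(0.0, 0.5, 5 / 6), c(0.5, 0.0, 2 / 3),
      c(u,       0.0, 1 / 3), c(u + 0.5, 0.5, 1 / 6),
      c(u,       0.5, 5 / 6), c(u + 0.5, 0.0, 2 / 3)
    )
    dims <- c(cell$c, cell$a, cell$a * sqrt(3))
  } else if (miller == "1-210") {
    frac <- rbind(
      c(1 / 3, 0.0, 0.25), c(1 / 6, 0.5, 0.75),
      c(5 / 6, 0.0, 0.75), c(2 / 3, 0.5, 0.25),
      c(1 / 3, u,       0.25), c(1 / 6, u + 0.5, 0.75),
      c(5 / 6, u,       0.75), c(2 / 3, u + 0.5, 0.25)
    )
    dims <- c(cell$a * sqrt(3), cell$c, cell$a)
  } else {
    stop("unsupported Miller index '", miller, "'; supported: ",
         paste(.SUPPORTED_MILLER, collapse = ", "))
  }
  list(frac = frac, dims = dims,
       elements = rep(c(cell$species[["cation"]], cell$species[["anion"]]),
                      each = 4))
}

#' Build a periodic ZnO slab
#'
#' Replicates the orthorhombic surface repeat cell of wurtzite ZnO
#' (8 atoms: 4 Zn + 4 O) into an `nx` x `ny` in-plane supercell, `nz_cells`
#' repeat cells thick, with the surface normal along z and a solvent/vacuum
#' gap above and below. Atom count is `nx * ny * nz_cells * 8` for both
#' supported cuts.
#'
#' @param miller Surface index, `"10-10"` or `"1-210"`.
#' @param nx,ny In-plane repetitions (x, y).
#' @param nz_cells Repeat cells along the surface normal (each holds two
#'   atomic layers for (1-210), one bilayer pair for (10-10)).
#' @param cell A [wurtzite_cell()]; defaults to the per-surface optimized
#'   constants.
#' @param gap Total solvent/vacuum gap along z (nm), split evenly above and
#'   below the slab. Default 2.5 nm.
#' @return Object of class `zno_slab` (also an `md_frame`): list with
#'   `elements`, `xyz` (n x 3 matrix, nm), `box` (nm), `miller`, `n_cells`,
#'   `cell`, `layer` (1-based atomic plane index from the bottom), `face`
#'   (`"bottom"`, `"interior"`, `"top"`) and `role` (all `"slab"`).
#' @examples
#' s <- build_slab("10-10", 2, 3, 2)
#' length(s$elements)  # 96
#' @export
build_slab <- function(miller, nx, ny, nz_cells,
                       cell = wurtzite_cell(miller = miller), gap = 2.5) {
  if (!miller %in% .SUPPORTED_MILLER)
    stop("unsupported Miller index '", miller, "'; supported: ",
         paste(.SUPPORTED_MILLER, collapse = ", "))
  stopifnot(nx >= 1, ny >= 1, nz_cells >= 1, gap >= 0)
  b <- .surface_basis(miller, cell)
  nrep <- nx * ny * nz_cells
  shifts <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1),
                                  z = 0:(nz_cells - 1)))
  frac <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i) {
    sweep(b$frac, 2, as.numeric(shifts[i, ]), "+")
  }))
  xyz <- sweep(frac, 2, b$dims, "*")
  elements <- rep(b$elements, nrep)

  ## shift slab so it sits gap/2 above the box floor
  zmin <- min(xyz[, 3]); zmax <- max(xyz[, 3])
  xyz[, 3] <- xyz[, 3] - zmin + gap / 2
  box <- c(b$dims[1] * nx, b$dims[2] * ny, (zmax - zmin) + gap)

  ## atomic plane index and face tags from z-plane rank
  zr <- round(xyz[, 3], 6)
  planes <- sort(unique(zr))
  layer <- match(zr, planes)
  face <- rep("interior", length(elements))
  face[layer == 1] <- "bottom"
  face[layer == length(planes)] <- "top"

  structure(list(elements = elements, xyz = unname(xyz), box = box,
                 time = 0,
                 miller = miller, n_cells = c(nx = nx, ny = ny, nz = nz_cells),
                 cell = cell, layer = layer, face = face,
                 role = rep("slab", length(elements))),
            class = c("zno_slab", "md_frame"))
}

#' @export
print.zno_slab <- function(x, ...) {
  dec <- attr(x, "decoration")
  cat(sprintf("ZnO (%s) slab: %d x %d x %d cells, %d atoms (%d Zn, %d O, %d H)\n",
              x$miller, x$n_cells[1], x$n_cells[2], x$n_cells[3],
              length(x$elements), sum(x$elements == "Zn"),
              sum(x$elements == "O"), sum(x$elements == "H")))
  cat(sprintf("box: %.4f x %.4f x %.4f nm\n", x$box[1], x$box[2], x$box[3]))
  if (!is.null(dec)) {
    cat(sprintf("decoration (%s model): %d hydroxyls, %d surface protons, %d bound waters\n",
                dec$model, length(dec$oh_sites), length(dec$h_sites),
                length(dec$water_sites)))
  }
  invisible(x)
}

#' Enumerate surface interaction sites of an undecorated slab
#'
#' Surface Zn interaction sites are Zn atoms with exactly 3 oxygen
#' neighbours under the minimum-image Zn-O cutoff (interior Zn are
#' 4-coordinated); surface oxygens are likewise the 3-coordinated O.
#' For the stoichiometric nonpolar cuts the two counts are equal and split
#' evenly over the two faces.
#'
#' @param slab An undecorated [build_slab()] result.
#' @param cutoff_ZnO First-shell Zn-O cutoff (nm); default 0.25.
#' @return Object of class `surface_sites`: list with `zn_sites`, `o_sites`
#'   (atom indices), `face` (named by atom index), and `n_per_face`.
#' @examples
#' sites <- enumerate_surface_sites(build_slab("10-10", 2, 3, 2))
#' length(sites$zn_sites)  # 12
#' @export
enumerate_surface_sites <- function(slab, cutoff_ZnO = 0.25) {
  stopifnot(inherits(slab, "zno_slab"))
  if (any(slab$role != "slab"))
    stop("enumerate_surface_sites() expects an undecorated slab; ",
         "see strip_decorations()")
  izn <- which(slab$elements == "Zn")
  io <- which(slab$elements == "O")
  d2 <- pair_dist2(slab$xyz[izn, , drop = FALSE],
                   slab$xyz[io, , drop = FALSE], slab$box)
  zn_coord <- rowSums(d2 < cutoff_ZnO^2)
  o_coord <- colSums(d2 < cutoff_ZnO^2)
  if (any(zn_coord < 3) || any(o_coord < 3))
    warning(sum(zn_coord < 3) + sum(o_coord < 3),
            " dangling atom(s) with < 3 counter-ion neighbours")
  zn_sites <- izn[zn_coord == 3]
  o_sites <- io[o_coord == 3]
  zmid <- mean(range(slab$xyz[, 3]))
  face <- ifelse(slab$xyz[c(zn_sites, o_sites), 3] > zmid, "top", "bottom")
  names(face) <- c(zn_sites, o_sites)
  structure(list(zn_sites = zn_sites, o_sites = o_sites, face = face,
                 n_per_face = table(face[as.character(zn_sites)])),
            class = "surface_sites")
}

#' @export
print.surface_sites <- function(x, ...) {
  cat(sprintf("surface sites: %d Zn (%s), %d O\n", length(x$zn_sites),
              paste(sprintf("%s: %d", names(x$n_per_face), x$n_per_face),
                    collapse = ", "), length(x$o_sites)))
  invisible(x)
}

## run expr with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## split a total count over two faces, difference <= 1
.split_faces <- function(n) c(top = ceiling(n / 2), bottom = floor(n / 2))

## geometry constants for placed groups (nm); equilibrium values of the
## fitted bonded terms -- these only seed later relaxation
.DECOR <- list(zn_oh = 0.180, o_h_hydroxyl = 0.098, o_h_proton = 0.100,
               zn_ow = 0.195, w_oh = 0.0957, w_half_angle_deg = 52.26)

#' Decorate a slab surface with hydroxyls, protons and bound water
#'
#' Places `round(f_oh * N_Zn_sites)` hydroxyl groups on surface Zn sites and
#' `round(f_h * N_O_sites)` protons on 3-coordinated surface oxygens,
#' split evenly between the two faces (per-face counts differ by at most 1).
#' In the BOND model every remaining (non-hydroxylated) Zn site receives a
#' molecularly bound water (one O, two H); in the NB model those sites stay
#' bare. Site selection is uniform without replacement per face and
#' deterministic given `seed`.
#'
#' @param slab Undecorated [build_slab()] result.
#' @param f_oh Fraction of surface Zn sites to hydroxylate, in [0, 1].
#' @param f_h Fraction of surface O sites to protonate, in [0, 1].
#' @param model `"BOND"` or `"NB"`.
#' @param seed Integer seed for site selection.
#' @param sites Optional precomputed [enumerate_surface_sites()] result.
#' @param quiet Suppress the rounding notice.
#' @return The decorated slab; added atoms carry `role` tags `"OH_O"`,
#'   `"OH_H"`, `"H"`, `"W_O"`, `"W_H"`, and the decoration bookkeeping is
#'   stored in `attr(, "decoration")`.
#' @examples
#' s <- decorate_surface(build_slab("10-10", 2, 3, 2), 0.65, 0.65,
#'                       model = "NB", seed = 1)
#' @export
decorate_surface <- function(slab, f_oh, f_h = 0, model = c("NB", "BOND"),
                             seed = 1L, sites = NULL, quiet = FALSE) {
  model <- match.arg(model)
  stopifnot(f_oh >= 0, f_oh <= 1, f_h >= 0, f_h <= 1)
  if (is.null(sites)) sites <- enumerate_surface_sites(slab)
  g <- .DECOR

  n_oh <- round(f_oh * length(sites$zn_sites))
  n_h <- round(f_h * length(sites$o_sites))
  if (!quiet && (abs(n_oh - f_oh * length(sites$zn_sites)) > 1e-9 ||
                 abs(n_h - f_h * length(sites$o_sites)) > 1e-9))
    message("decoration counts rounded to ", n_oh, " hydroxyls / ",
            n_h, " protons")

  pick <- .with_seed(seed, {
    res <- list(oh = integer(), h = integer())
    for (fc in c("top", "bottom")) {
      zn_f <- sites$zn_sites[sites$face[as.character(sites$zn_sites)] == fc]
      o_f <- sites$o_sites[sites$face[as.character(sites$o_sites)] == fc]
      res$oh <- c(res$oh, zn_f[sample.int(length(zn_f), .split_faces(n_oh)[[fc]])])
      res$h <- c(res$h, o_f[sample.int(length(o_f), .split_faces(n_h)[[fc]])])
    }
    res
  })
  oh_sites <- pick$oh
  h_sites <- pick$h
  water_sites <- if (model == "BOND") setdiff(sites$zn_sites, oh_sites)
                 else integer()

  new_el <- character(); new_xyz <- NULL; new_role <- character()
  add <- function(el, xyz, role) {
    new_el <<- c(new_el, el)
    new_xyz <<- rbind(new_xyz, xyz)
    new_role <<- c(new_role, role)
  }
  outward <- function(i) if (sites$face[as.character(i)] == "top") 1 else -1

  for (i in oh_sites) {  # O-H stick along the surface normal
    s <- outward(i); p <- slab$xyz[i, ]
    add("O", p + c(0, 0, s * g$zn_oh), "OH_O")
    add("H", p + c(0, 0, s * (g$zn_oh + g$o_h_hydroxyl)), "OH_H")
  }
  for (i in h_sites) {
    s <- outward(i); p <- slab$xyz[i, ]
    add("H", p + c(0, 0, s * g$o_h_proton), "H")
  }
  if (length(water_sites)) {
    dz <- g$w_oh * cos(g$w_half_angle_deg * pi / 180)
    dx <- g$w_oh * sin(g$w_half_angle_deg * pi / 180)
    for (i in water_sites) {  # water plane vertical, H pointing outward
      s <- outward(i); p <- slab$xyz[i, ]
      po <- p + c(0, 0, s * g$zn_ow)
      add("O", po, "W_O")
      add("H", po + c(dx, 0, s * dz), "W_H")
      add("H", po + c(-dx, 0, s * dz), "W_H")
    }
  }

  out <- slab
  if (length(new_el)) {
    out$elements <- c(slab$elements, new_el)
    out$xyz <- rbind(slab$xyz, new_xyz)
    out$layer <- c(slab$layer, rep(NA_integer_, length(new_el)))
    out$face <- c(slab$face, rep(NA_character_, length(new_el)))
    out$role <- c(slab$role, new_role)
  }
  attr(out, "decoration") <- list(model = model, f_oh = f_oh, f_h = f_h,
                                  oh_sites = oh_sites, h_sites = h_sites,
                                  water_sites = water_sites, seed = seed,
                                  sites = sites)
  out
}

#' Remove all decoration atoms from a slab
#'
#' Inverse of [decorate_surface()]: drops every atom whose `role` is not
#' `"slab"` and clears the decoration attribute.
#'
#' @param slab A (possibly decorated) `zno_slab`.
#' @return The undecorated slab.
#' @export
strip_decorations <- function(slab) {
  keep <- slab$role == "slab"
  out <- slab
  out$elements <- slab$elements[keep]
  out$xyz <- slab$xyz[keep, , drop = FALSE]
  out$layer <- slab$layer[keep]
  out$face <- slab$face[keep]
  out$role <- slab$role[keep]
  attr(out, "decoration") <- NULL
  out
}
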