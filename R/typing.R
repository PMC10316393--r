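## Connectivity-based force-field atom typing for ZnO-water systems and
## population analysis over trajectories.

#' Single snapshot of an atomistic configuration
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric n x 3 matrix of positions (nm).
#' @param box Orthorhombic box lengths (nm).
#' @param time Frame time (ps).
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(elements, xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(length(elements) == nrow(xyz), ncol(xyz) == 3,
            length(box) == 3, all(box > 0))
  structure(list(elements = elements, xyz = unname(xyz),
                 box = as.numeric(box), time = time),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms (%s), box %.3f x %.3f x %.3f nm, t = %g ps\n",
              length(x$elements),
              paste(sprintf("%s: %d", names(table(x$elements)),
                            table(x$elements)), collapse = ", "),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

.O_LABELS <- c("OA", "OB", "OC", "OD", "OH", "OW")
.ZN_LABELS <- c("ZnA", "ZnB")

#' Assign force-field atom types from first-shell connectivity
#'
#' Classifies every atom of a Zn/O/H configuration by its first coordination
#' shell under minimum-image cutoffs: oxygens by their (Zn, H) neighbour
#' counts -- (4,0) OA bulk, (3,1) OB protonated surface, (3,0) OC bare
#' surface, (1,2) OD molecularly adsorbed water, (1,1) OH hydroxyl,
#' (0,2) OW free water -- and every hydrogen as HA. Zinc is typed by its
#' count of non-water oxygen neighbours (the oxygen of a molecularly
#' adsorbed water does not count toward lattice coordination): 4 gives ZnA,
#' 3 gives ZnB. Each hydrogen is claimed by its nearest oxygen within the
#' O-H cutoff (ties broken toward the lower atom index).
#'
#' Oxygens with an unclassifiable shell (for example a free hydroxide (0,1)
#' or hydronium (0,3)) are labelled `"SOL"` (solute species) with a warning
#' and are excluded from surface population fractions.
#'
#' @param frame An [md_frame()] (a `zno_slab` works directly).
#' @param cutoff_ZnO Zn-O first-shell cutoff (nm), default 0.25.
#' @param cutoff_OH O-H first-shell cutoff (nm), default 0.13.
#' @return Object of class `type_assignment`: list with `labels` (per-atom
#'   character), `neighbors` (per-atom integer vectors of first-shell
#'   partners) and `bonds` (data.frame `i`, `j`, `class`, `dist` of
#'   first-shell Zn-O and O-H pairs, class named cation/oxygen first, e.g.
#'   `"ZnA-OH"`, `"OB-HA"`).
#' @examples
#' w <- md_frame(c("O", "H", "H"),
#'               rbind(c(1, 1, 1), c(1.0957, 1, 1), c(0.976, 1.06, 1)),
#'               box = c(3, 3, 3))
#' assign_atom_types(w)$labels  # OW HA HA
#' @export
assign_atom_types <- function(frame, cutoff_ZnO = 0.25, cutoff_OH = 0.13) {
  el <- frame$elements
  bad <- setdiff(unique(el), c("Zn", "O", "H"))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  izn <- which(el == "Zn"); io <- which(el == "O"); ih <- which(el == "H")
  n <- length(el)
  labels <- character(n)
  neighbors <- vector("list", n)

  ## O-Zn shells (dense hit matrix, O rows x Zn columns)
  if (length(izn) && length(io)) {
    d2_ozn <- pair_dist2(frame$xyz[io, , drop = FALSE],
                         frame$xyz[izn, , drop = FALSE], frame$box)
    hit_ozn <- d2_ozn < cutoff_ZnO^2
  } else {
    hit_ozn <- matrix(FALSE, length(io), length(izn))
  }
  n_zn_of_o <- rowSums(hit_ozn)

  ## H -> nearest O within cutoff; tie to lower O index (io is ascending,
  ## max.col("first") on negated distances honours that)
  o_of_h <- rep(NA_integer_, length(ih))
  if (length(ih) && length(io)) {
    d2_ho <- pair_dist2(frame$xyz[ih, , drop = FALSE],
                        frame$xyz[io, , drop = FALSE], frame$box)
    within <- d2_ho < cutoff_OH^2
    claims <- rowSums(within)
    nearest <- max.col(-d2_ho, ties.method = "first")
    o_of_h[claims > 0] <- io[nearest[claims > 0]]
    if (any(claims > 1))
      message(sum(claims > 1), " hydrogen(s) within the O-H cutoff of ",
              "several oxygens; assigned to the nearest")
  }
  n_h_of_o <- if (length(io))
    tabulate(match(o_of_h, io), nbins = length(io)) else integer()

  ## oxygen labels from (n_Zn, n_H)
  okey <- paste(n_zn_of_o, n_h_of_o)
  olab <- rep("SOL", length(io))
  map <- c("4 0" = "OA", "3 1" = "OB", "3 0" = "OC",
           "1 2" = "OD", "1 1" = "OH", "0 2" = "OW")
  known <- okey %in% names(map)
  olab[known] <- unname(map[okey[known]])
  labels[io] <- olab
  if (any(!known))
    warning(sum(!known), " oxygen(s) with unclassifiable coordination ",
            "shell labelled SOL and excluded from surface fractions")

  ## zinc labels: count non-water O neighbours
  if (length(izn)) {
    lattice_o <- !olab %in% c("OD", "OW")
    n_lat <- colSums(hit_ozn & lattice_o)
    labels[izn] <- ifelse(n_lat >= 4, "ZnA",
                          ifelse(n_lat == 3, "ZnB", "SOL"))
    if (any(labels[izn] == "SOL"))
      warning(sum(labels[izn] == "SOL"),
              " zinc atom(s) with < 3 lattice O neighbours labelled SOL")
  }
  labels[ih] <- "HA"

  ## neighbor lists and first-shell bond pairs (cation/oxygen listed first)
  pairs_ozn <- which(hit_ozn, arr.ind = TRUE)  # (O row, Zn col)
  bm <- rbind(cbind(izn[pairs_ozn[, 2]], io[pairs_ozn[, 1]]),
              cbind(o_of_h[!is.na(o_of_h)], ih[!is.na(o_of_h)]))
  neighbors[c(io, izn)] <- list(integer())
  if (nrow(bm)) {
    nb <- split(c(bm[, 2], bm[, 1]), c(bm[, 1], bm[, 2]))
    neighbors[as.integer(names(nb))] <- nb
  }
  for (k in seq_along(ih)) neighbors[[ih[k]]] <- o_of_h[k]
  if (nrow(bm)) {
    dist <- sqrt(rowSums(min_image(frame$xyz[bm[, 1], , drop = FALSE] -
                                   frame$xyz[bm[, 2], , drop = FALSE],
                                   frame$box)^2))
    bonds <- data.frame(i = bm[, 1], j = bm[, 2],
                        class = paste(labels[bm[, 1]], labels[bm[, 2]],
                                      sep = "-"),
                        dist = dist)
  } else {
    bonds <- data.frame(i = integer(), j = integer(),
                        class = character(), dist = numeric())
  }

  structure(list(labels = labels, neighbors = neighbors, bonds = bonds),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat("atom types:\n"); print(table(x$labels))
  invisible(x)
}

#' Surface population fractions over a trajectory
#'
#' Per-frame fractions of the surface-related oxygen types, normalized the
#' way surface population analyses report them: OH and OD per surface Zn
#' interaction site, OB and OC per 3-coordinated surface oxygen of the
#' undecorated reference slab, plus the fraction of originally-molecular
#' water oxygens still two-H-coordinated (OW + OD). Oxygens labelled `SOL`
#' (residual hydroxide/hydronium in the water phase) are counted separately
#' in `n_sol`, never folded into surface fractions.
#'
#' @param traj A list of [md_frame()]s (or a single frame).
#' @param site_set [enumerate_surface_sites()] result for the undecorated
#'   reference slab; provides the normalization counts.
#' @param burn_in Time (ps) discarded from the start when computing the
#'   equilibrium summary; default 0 (use all frames).
#' @param ... Passed to [assign_atom_types()].
#' @return Object of class `population_series`: list with `frames`
#'   (data.frame: `time`, `f_oh`, `f_od`, `f_ob`, `f_oc`, `f_water`,
#'   `n_sol`) and `summary` (mean and sd of each fraction over
#'   `time >= burn_in`).
#' @export
population_fractions <- function(traj, site_set, burn_in = 0, ...) {
  if (inherits(traj, "md_frame")) traj <- list(traj)
  if (!length(traj)) stop("empty trajectory")
  n_zn <- length(site_set$zn_sites)
  n_o <- length(site_set$o_sites)
  if (n_zn <= 0 || n_o <= 0) stop("site normalization count must be > 0")

  rows <- lapply(traj, function(fr) {
    ty <- assign_atom_types(fr, ...)
    ct <- table(factor(ty$labels, levels = c(.O_LABELS, .ZN_LABELS,
                                             "HA", "SOL")))
    n_wat <- ct[["OW"]] + ct[["OD"]] + ct[["OH"]]
    data.frame(
      time = fr$time,
      f_oh = ct[["OH"]] / n_zn, f_od = ct[["OD"]] / n_zn,
      f_ob = ct[["OB"]] / n_o, f_oc = ct[["OC"]] / n_o,
      f_water = if (n_wat > 0) (ct[["OW"]] + ct[["OD"]]) / n_wat else NA_real_,
      n_sol = ct[["SOL"]]
    )
  })
  frames <- do.call(rbind, rows)
  eq <- frames[frames$time >= burn_in, , drop = FALSE]
  cols <- c("f_oh", "f_od", "f_ob", "f_oc", "f_water")
  summary <- data.frame(
    fraction = cols,
    mean = vapply(cols, function(cc) mean(eq[[cc]]), numeric(1)),
    sd = vapply(cols, function(cc) stats::sd(eq[[cc]]), numeric(1)),
    row.names = NULL
  )
  structure(list(frames = frames, summary = summary, burn_in = burn_in,
                 n_zn_sites = n_zn, n_o_sites = n_o),
            class = "population_series")
}

#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("population series: %d frames, %d Zn / %d O surface sites, burn-in %g ps\n",
              nrow(x$frames), x$n_zn_sites, x$n_o_sites, x$burn_in))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Verify distance-based bonds against partitioning bond orders
#'
#' Cross-checks the first-shell pairs of a [assign_atom_types()] result
#' against pairwise bond orders from electron-density partitioning. Each
#' bond class is reported with its mean bond order and a status: below
#' `threshold` the contact is non-covalent (`"nonbonded"`, typical of
#' hydrogen bonds), between `threshold` and `partial_limit` it is
#' `"partially covalent"` (the regime of molecularly adsorbed water, where
#' the BOND/NB modeling choice lives), and at or above `partial_limit` it
#' is `"covalent"`. Pairs with no bond-order record are `"unverifiable"`.
#'
#' @param assignment A `type_assignment`.
#' @param records A [partition_record()] carrying the `bo` pair table.
#' @param threshold Covalency threshold (dimensionless), default 0.3.
#' @param partial_limit Lower bound of the fully covalent band, default 0.5.
#' @return Object of class `bond_report`: list with `classes` (data.frame
#'   `class`, `n`, `mean_bo`, `status`), `pairs` (per-pair table with `bo`
#'   and `flag`) and `unverifiable` count.
#' @export
verify_bonds <- function(assignment, records, threshold = 0.3,
                         partial_limit = 0.5) {
  bonds <- assignment$bonds
  bo_tab <- records$bo
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bo_map <- stats::setNames(bo_tab$bo, key(bo_tab$i, bo_tab$j))
  bo <- unname(bo_map[key(bonds$i, bonds$j)])
  pairs <- cbind(bonds, bo = bo,
                 flag = ifelse(is.na(bo), "unverifiable",
                        ifelse(bo < threshold, "nonbonded", "bonded")))
  agg <- lapply(split(pairs, pairs$class), function(pp) {
    m <- mean(pp$bo, na.rm = TRUE)
    data.frame(class = pp$class[1], n = nrow(pp), mean_bo = m,
               status = if (all(is.na(pp$bo))) "unverifiable"
                        else if (m < threshold) "nonbonded"
                        else if (m < partial_limit) "partially covalent"
                        else "covalent")
  })
  classes <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  structure(list(classes = classes, pairs = pairs,
                 unverifiable = sum(is.na(bo)),
                 threshold = threshold, partial_limit = partial_limit),
            class = "bond_report")
}

#' @export
print.bond_report <- function(x, ...) {
  cat(sprintf("bond-order verification (threshold %.2f, covalent >= %.2f):\n",
              x$threshold, x$partial_limit))
  print(x$classes, digits = 3)
  if (x$unverifiable)
    cat(x$unverifiable, "pair(s) without bond-order records\n")
  invisible(x)
}
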