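## Minimum-image geometry helpers. Orthorhombic boxes only; positions in nm.

#' Squared minimum-image distances between two coordinate sets
#'
#' Dense pairwise squared-distance matrix under the minimum-image convention
#' in an orthorhombic box. Periodicity is applied in all three directions;
#' for slab systems the solvent/vacuum gap along z makes z-wrapping inert.
#'
#' @param xa,xb Numeric matrices (n x 3), positions in nm.
#' @param box Numeric length-3, orthorhombic box lengths (nm).
#' @param periodic Logical length-3; which directions wrap. Default all TRUE.
#' @return Matrix `nrow(xa)` x `nrow(xb)` of squared distances (nm^2).
#' @keywords internal
pair_dist2 <- function(xa, xb, box, periodic = c(TRUE, TRUE, TRUE)) {
  stopifnot(ncol(xa) == 3, ncol(xb) == 3, length(box) == 3, all(box > 0))
  d2 <- matrix(0, nrow(xa), nrow(xb))
  for (d in 1:3) {
    dd <- outer(xa[, d], xb[, d], "-")
    if (periodic[d]) dd <- dd - box[d] * round(dd / box[d])
    d2 <- d2 + dd * dd
  }
  d2
}

#' Minimum-image displacement of one vector set
#' @keywords internal
min_image <- function(dx, box) {
  dx - rep(box, each = nrow(dx)) * round(dx / rep(box, each = nrow(dx)))
}

## neighbor pairs (i over rows of xa, j over rows of xb) within cutoff
.neighbor_pairs <- function(xa, xb, box, cutoff) {
  d2 <- pair_dist2(xa, xb, box)
  idx <- which(d2 < cutoff^2, arr.ind = TRUE)
  cbind(idx, dist = sqrt(d2[idx]))
}
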