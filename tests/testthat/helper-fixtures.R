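# Shared fixtures, all generated in code.

# small training-sized slabs (cached per session; building is cheap but
# repeated in many tests)
slab_1010 <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- build_slab("10-10", 2, 3, 2)
    s
  }
})

slab_1210 <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- build_slab("1-210", 2, 2, 4)
    s
  }
})

# force-field table with the published finalized NB charges; used where a
# charge table is an input rather than the thing under test
reference_nb_ff <- function() {
  atoms <- data.frame(
    type = c("ZnA", "ZnB", "OA", "OB", "OC", "OH", "OD", "OW", "HA"),
    charge = c(0.918, 0.949, -0.918, -0.827, -0.934, -0.838, -0.834,
               -0.834, 0.417),
    sigma = c(0.318, 0.150, 0.343, 0.323, 0.307, 0.313, 0.315, 0.315, 0),
    epsilon = c(1.241, 1.241, 0.372, 0.437, 0.709, 0.476, 0.636, 0.636, 0)
  )
  ab <- sigma_eps_to_ab(atoms$sigma, atoms$epsilon)
  atoms$A <- ab$A
  atoms$B <- ab$B
  structure(list(atoms = atoms, bonds = NULL, angles = NULL, model = "NB"),
            class = "ff_table")
}

# a single free water molecule at a given oxygen position
water_at <- function(o, flip = 1) {
  rbind(o, o + c(0.0957, 0, 0), o + c(-0.024, flip * 0.0927, 0))
}
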