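## File formats: XYZ (nm dialect, multi-frame), GRO (fixed-column),
## partitioning tables, force-field CSV and GROMACS-dialect topology
## fragments. All writers are deterministic (byte-identical on rewrite).

.fmt_num <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

#' Write frames to an XYZ file (nm dialect)
#'
#' Multi-frame XYZ with a structured comment line carrying the box and
#' time: `box <x> <y> <z> t <ps>`. Positions are written in nm with 6
#' decimals.
#'
#' @param frames An [md_frame()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    tm <- if (is.null(fr$time)) 0 else fr$time
    writeLines(as.character(length(fr$elements)), con)
    writeLines(sprintf("box %s %s %s t %g", .fmt_num(fr$box[1], 6),
                       .fmt_num(fr$box[2], 6), .fmt_num(fr$box[3], 6),
                       tm), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", fr$elements,
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ file (nm dialect)
#'
#' @param path Input file.
#' @param box Fallback box lengths (nm) if the comment line carries none.
#' @return List of [md_frame()]s (length-1 list for a single frame).
#' @export
read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  frames <- list(); ln <- 1
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln]))
      stop("XYZ parse error at line ", ln, ": expected atom count, got '",
           lines[ln], "'")
    n <- as.integer(lines[ln])
    comment <- lines[ln + 1]
    m <- regmatches(comment,
                    regexec("box\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)(\\s+t\\s+(\\S+))?",
                            comment))[[1]]
    fbox <- box; t <- 0
    if (length(m)) {
      fbox <- as.numeric(m[2:4])
      if (m[6] != "") t <- as.numeric(m[6])
    }
    if (is.null(fbox))
      stop("XYZ line ", ln + 1, ": no box in comment and no fallback given")
    block <- lines[ln + 2:(n + 1)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(toks) < 4)
    if (length(bad))
      stop("XYZ parse error at line ", ln + 1 + bad[1], ": need 4 fields")
    el <- vapply(toks, `[`, "", 1)
    xyz <- suppressWarnings(
      t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))))
    if (anyNA(xyz))
      stop("XYZ parse error near line ", ln + 2, ": non-numeric coordinate")
    frames[[length(frames) + 1]] <- md_frame(el, xyz, fbox, time = t)
    ln <- ln + n + 2
  }
  frames
}

#' Write a frame in GRO format
#'
#' Fixed-column GRO (positions in nm, 3 decimals). Atom names are the
#' element symbols; all atoms sit in residue 1 `ZNO`.
#'
#' @param frame An [md_frame()].
#' @param path Output file.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "oxideforge") {
  n <- length(frame$elements)
  tm <- if (is.null(frame$time)) 0 else frame$time
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%s, t= %g", title, tm), con)
  writeLines(sprintf("%5d", n), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     rep(1L, n), "ZNO", frame$elements,
                     seq_len(n) %% 100000L,
                     frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]), con)
  invisible(path)
}

#' Read a GRO file
#'
#' Strict fixed-column parse; malformed lines are reported with their line
#' number. Elements are recovered from the leading letters of the atom
#' name.
#'
#' @param path Input file.
#' @return An [md_frame()].
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  t <- 0
  m <- regmatches(lines[1], regexec("t=\\s*(\\S+)", lines[1]))[[1]]
  if (length(m)) t <- suppressWarnings(as.numeric(m[2]))
  if (is.na(t)) t <- 0
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error at line 2: bad atom count '",
                     lines[2], "'")
  if (length(lines) < n + 3)
    stop("GRO file truncated: expected ", n + 3, " lines, found ",
         length(lines))
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    li <- lines[k + 2]
    if (nchar(li) < 44)
      stop("GRO parse error at line ", k + 2, ": line too short")
    name <- trimws(substr(li, 11, 15))
    el[k] <- sub("[0-9].*$", "", name)
    xyz[k, ] <- suppressWarnings(as.numeric(c(substr(li, 21, 28),
                                              substr(li, 29, 36),
                                              substr(li, 37, 44))))
    if (anyNA(xyz[k, ]))
      stop("GRO parse error at line ", k + 2, ": non-numeric coordinate")
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                              "\\s+")[[1]][1:3]))
  if (anyNA(box))
    stop("GRO parse error at line ", n + 3, ": bad box line")
  md_frame(el, xyz, box, time = t)
}

#' Write / read a partitioning table
#'
#' Tabular dialect modeled on density-partitioning program output: a
#' header line with the atom count, a comment, then one row per atom
#' `element x y z nac cam` (nm, e, bohr^3), repeated per frame; the
#' pairwise bond orders go to a companion table `i j bo [frame]`.
#'
#' @param record A [partition_record()].
#' @param path Atom table file; bond orders are written to
#'   `paste0(path, ".bo")`.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(record, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (f in unique(record$atoms$frame)) {
    at <- record$atoms[record$atoms$frame == f, ]
    writeLines(as.character(nrow(at)), con)
    writeLines(sprintf("frame %d : element x y z nac cam", f), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f %10.6f %12.6f",
                       at$element, at$x, at$y, at$z, at$nac, at$cam), con)
  }
  utils::write.table(record$bo, paste0(path, ".bo"), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_table
#' @export
read_partition_table <- function(path) {
  lines <- readLines(path)
  atoms <- NULL; ln <- 1; f <- 0L
  while (ln <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n)) stop("partition table line ", ln, ": expected atom count")
    f <- f + 1L
    block <- lines[ln + 2:(n + 1)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(toks) != 6)
    if (length(bad))
      stop("partition table line ", ln + 1 + bad[1], ": need 6 fields")
    num <- suppressWarnings(
      t(vapply(toks, function(tk) as.numeric(tk[2:6]), numeric(5))))
    if (anyNA(num))
      stop("partition table near line ", ln + 2, ": non-numeric field")
    atoms <- rbind(atoms, data.frame(
      element = vapply(toks, `[`, "", 1), x = num[, 1], y = num[, 2],
      z = num[, 3], nac = num[, 4], cam = num[, 5], frame = f))
    ln <- ln + n + 2
  }
  bo_path <- paste0(path, ".bo")
  bo <- if (file.exists(bo_path))
    utils::read.table(bo_path, header = TRUE) else NULL
  partition_record(atoms, bo)
}

#' Write / read a force-field table as CSV
#'
#' Atom types go to `path`; bond and angle tables, when present, to
#' `paste0(path, ".bonds")` / `paste0(path, ".angles")`.
#'
#' @param ff An `ff_table`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_ff_csv <- function(ff, path) {
  at <- ff$atoms
  at$model <- ff$model
  utils::write.csv(at, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ff$bonds))
    utils::write.csv(ff$bonds, paste0(path, ".bonds"), row.names = FALSE,
                     quote = FALSE)
  if (!is.null(ff$angles))
    utils::write.csv(ff$angles, paste0(path, ".angles"), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ff_csv
#' @export
read_ff_csv <- function(path) {
  at <- utils::read.csv(path)
  model <- at$model[1]
  at$model <- NULL
  bonds <- if (file.exists(paste0(path, ".bonds")))
    utils::read.csv(paste0(path, ".bonds")) else NULL
  angles <- if (file.exists(paste0(path, ".angles")))
    utils::read.csv(paste0(path, ".angles")) else NULL
  structure(list(atoms = at, bonds = bonds, angles = angles, model = model),
            class = "ff_table")
}

.ATOMIC_MASS <- c(Zn = 65.38, O = 15.9994, H = 1.008)

#' Write a GROMACS-dialect topology for a typed slab
#'
#' Emits `[atomtypes]` (sigma/epsilon in nm and kJ/mol), `[moleculetype]` /
#' `[atoms]` with per-atom charges, `[bonds]` (function 1, harmonic, k in
#' kJ mol^-1 nm^-2) for every first-shell pair that the model treats as
#' covalent, `[angles]` when angle parameters are supplied, and a
#' `[system]`/`[molecules]` block including counterions from
#' [neutralize_to_integer()]. In the BOND flavour the zinc-to-adsorbed-
#' water (ZnA/ZnB-OD) contacts are written as bonds; in the NB flavour
#' they are omitted (that attraction is carried by the short-sigma ZnB
#' type). A companion GRO file is written alongside.
#'
#' @param slab Decorated `zno_slab`.
#' @param ff An `ff_table` (its `model` picks the flavour).
#' @param path Topology output (`.top`); coordinates go to
#'   `sub("\\\\.top$", ".gro", path)`.
#' @param neutralize Apply the integer-charge shift and counterions.
#' @return List with `path`, `gro`, `n_counterions`, `species`,
#'   `total_charge` (after shift), invisibly.
#' @export
write_topology <- function(slab, ff, path, neutralize = TRUE) {
  assignment <- assign_atom_types(slab)
  labels <- assignment$labels
  missing <- setdiff(unique(labels), ff$atoms$type)
  if (length(missing))
    stop("force-field table lacks parameters for type(s): ",
         paste(missing, collapse = ", "))
  cs <- charged_slab(slab, ff, assignment)
  nz <- if (neutralize) neutralize_to_integer(cs)
        else list(slab = cs, total = sum(cs$charges), n_counterions = 0,
                  species = NA_character_)
  charges <- nz$slab$charges

  bonds <- assignment$bonds
  if (ff$model == "NB")
    bonds <- bonds[!bonds$class %in% c("ZnA-OD", "ZnB-OD"), , drop = FALSE]
  bond_par <- if (!is.null(ff$bonds))
    stats::setNames(split(ff$bonds, ff$bonds$class), ff$bonds$class)
    else list()

  lines <- c("; oxideforge topology", "", "[ atomtypes ]",
             ";  name  at.num     mass   charge  ptype      sigma    epsilon")
  for (r in seq_len(nrow(ff$atoms))) {
    a <- ff$atoms[r, ]
    el <- if (grepl("^Zn", a$type)) "Zn" else if (grepl("^O", a$type)) "O"
          else "H"
    lines <- c(lines, sprintf("%6s %7d %8.4f %8.4f      A %10.6f %10.6f",
                              a$type, c(Zn = 30, O = 8, H = 1)[[el]],
                              .ATOMIC_MASS[[el]], a$charge, a$sigma,
                              a$epsilon))
  }
  lines <- c(lines, "", "[ moleculetype ]", "; name   nrexcl", "ZNOSLAB  1",
             "", "[ atoms ]",
             ";   nr   type  resnr  resid   atom  cgnr     charge       mass")
  for (i in seq_along(labels)) {
    el <- slab$elements[i]
    lines <- c(lines, sprintf("%6d %6s %6d %6s %6s %5d %10.6f %10.4f",
                              i, labels[i], 1L, "ZNO", el, i, charges[i],
                              .ATOMIC_MASS[[el]]))
  }
  lines <- c(lines, "", "[ bonds ]",
             ";   ai     aj  func         b0            k")
  for (r in seq_len(nrow(bonds))) {
    b <- bonds[r, ]
    par <- bond_par[[b$class]]
    b0 <- if (!is.null(par)) par$b0 else b$dist
    k <- if (!is.null(par)) par$k else 100000
    lines <- c(lines, sprintf("%6d %6d %5d %10.4f %12.1f", b$i, b$j, 1L,
                              b0, k))
  }
  if (!is.null(ff$angles) && nrow(ff$angles)) {
    lines <- c(lines, "", "[ angles ]",
               ";   class      theta0      k_theta (func 1)")
    for (r in seq_len(nrow(ff$angles))) {
      an <- ff$angles[r, ]
      lines <- c(lines, sprintf("; %8s %10.3f %12.3f", an$class, an$theta0,
                                an$k_theta))
    }
  }
  lines <- c(lines, "", "[ system ]", "ZnO slab", "", "[ molecules ]",
             "ZNOSLAB  1")
  if (nz$n_counterions > 0)
    lines <- c(lines, sprintf("%s  %d",
                              if (nz$species == "Cl-") "CL" else "NA",
                              nz$n_counterions))
  writeLines(lines, path)
  gro <- sub("\\.top$", ".gro", path)
  if (identical(gro, path)) gro <- paste0(path, ".gro")
  write_gro(slab, gro, title = "oxideforge slab")
  invisible(list(path = path, gro = gro, n_counterions = nz$n_counterions,
                 species = nz$species, total_charge = nz$total))
}
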