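# Atomic coordinate container, PDB reading (via bio3d) with altloc and
# multi-MODEL policy, fixed-column PDB writing, and deterministic toy
# structure builders used as analytic fixtures for the molecular-ruler
# metrics.

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, and optionally `occupancy`,
#'   `altloc`
#' @param title free-text metadata
#' @return a `structure_model` object
#' @export
structure_model <- function(atoms, title = "") {
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$atom, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom, altloc) records")
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# element guess from a PDB atom name (hydrogens and two-letter elements)
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- c("FE", "ZN", "MG", "CA", "NA", "CL", "BR", "MN", "CU", "SE")
  # CA is almost always an alpha-carbon in ATOM records; treat two-letter
  # symbols only when the name is exactly the symbol and not a standard
  # protein atom name
  el <- substr(nm, 1, 1)
  el[nm %in% setdiff(two, c("CA"))] <- nm[nm %in% setdiff(two, c("CA"))]
  el
}

#' Read a PDB structure (fixed-column ATOM/HETATM records)
#'
#' Parsing is delegated to [bio3d::read.pdb()] after line-level validation
#' (malformed coordinate fields are reported with their line number).
#' Policies applied: only the first MODEL block is kept (with a warning
#' when more are present); for alternate locations the highest-occupancy
#' record is kept, ties resolved in favour of altloc "A"; hydrogens are
#' dropped (`keep_hydrogens = TRUE` overrides).
#'
#' @param input a file path, or PDB text (single string with newlines or a
#'   character vector of lines)
#' @param keep_hydrogens retain hydrogen atoms (default FALSE)
#' @return a [structure_model()]
#' @export
read_structure <- function(input, keep_hydrogens = FALSE) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    lines <- readLines(input, warn = FALSE)
  else
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty input: no ATOM/HETATM records")
  # validate coordinate columns (31-54) before delegating
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error at line ", i, ": truncated ATOM/HETATM record")
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      stop("parse error at line ", i, ": malformed coordinate field")
  }
  # keep only the first MODEL block
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) > 1L) {
    warning("multiple MODEL blocks: keeping the first, ignoring ",
            length(model_starts) - 1L, " further model(s)")
    endmdl <- grep("^ENDMDL", lines)[1]
    lines <- lines[seq_len(endmdl)]
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  el <- a$elesy
  el[is.na(el) | trimws(el) == ""] <- NA
  el <- ifelse(is.na(el), guess_element(a$elety), trimws(el))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, resname = a$resid, atom = a$elety,
    element = el, x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  # altloc policy: highest occupancy wins, ties -> "A" (then first seen)
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$atom)
    ord <- order(key, -atoms$occupancy,
                 atoms$altloc != "A", seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom)), ,
                   drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
    atoms$altloc <- ""
  }
  rownames(atoms) <- NULL
  structure_model(atoms, title = "")
}

#' Write a structure model as fixed-column PDB ATOM records
#'
#' @param s a [structure_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  nm <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), nm, " ", a$resname, a$chain, a$resno, " ",
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build deterministic toy structures with known geometry
#'
#' Three kinds are available:
#' * `"helix"`: an idealized poly-alanine alpha-helix (backbone N, CA, C,
#'   O) with `n_res` residues, per-residue `rise` (A) and `twist`
#'   (degrees) and helix `radius` (A), chain "A", residues numbered from
#'   `first_resno`.
#' * `"pore_ring_stack"`: `length(ring_z)` rings of `n_atoms` carbon atoms
#'   at radius `ring_radius[i]` from the z axis, centred at z =
#'   `ring_z[i]`; the analytic pore radius at a ring plane is
#'   `ring_radius - vdW(C)`.
#' * `"duplicate_with_transform"`: a rigid copy of `base` rotated by
#'   `angle_deg` about `axis` and shifted by `translation`; optionally a
#'   subset of residues (`displace_resno`) is additionally displaced by
#'   the vector `displacement` after the rigid motion.
#'
#' @param kind one of `"helix"`, `"pore_ring_stack"`,
#'   `"duplicate_with_transform"`
#' @param ... kind-specific parameters, see Details
#' @return a [structure_model()]
#' @export
make_toy_structure <- function(kind = c("helix", "pore_ring_stack",
                                        "duplicate_with_transform"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  switch(kind,
    helix = {
      n_res <- p$n_res %||% 20L
      rise <- p$rise %||% 1.5
      twist <- p$twist %||% 100
      radius <- p$radius %||% 2.3
      first <- p$first_resno %||% 1L
      if (n_res < 1 || rise <= 0 || radius <= 0)
        stop("invalid helix parameters")
      rows <- vector("list", n_res)
      # local backbone offsets (A) relative to the CA position, rotated
      # with the helix phase so geometry is uniform along the chain
      offs <- rbind(N = c(-0.8, -0.9, -0.6), CA = c(0, 0, 0),
                    C = c(1.0, 0.7, 0.4), O = c(1.1, 1.8, 0.3))
      for (i in seq_len(n_res)) {
        th <- (i - 1) * twist * pi / 180
        ca <- c(radius * cos(th), radius * sin(th), (i - 1) * rise)
        rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                      3, 3, byrow = TRUE)
        pos <- t(rot %*% t(offs)) + matrix(ca, 4, 3, byrow = TRUE)
        rows[[i]] <- data.frame(
          chain = "A", resno = first + i - 1L, resname = "ALA",
          atom = rownames(offs),
          element = c("N", "C", "C", "O"),
          x = pos[, 1], y = pos[, 2], z = pos[, 3])
      }
      structure_model(do.call(rbind, rows), title = "toy helix")
    },
    pore_ring_stack = {
      ring_z <- p$ring_z %||% c(0, 4)
      ring_radius <- p$ring_radius %||% rep(6, length(ring_z))
      n_atoms <- p$n_atoms %||% 12L
      stagger <- p$stagger %||% rep(0, length(ring_z))
      vdw_c <- 1.7
      if (any(ring_radius <= vdw_c))
        stop("invalid geometry: ring radius must exceed the vdW radius")
      rows <- list()
      for (i in seq_along(ring_z)) {
        th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms + stagger[i]
        rows[[i]] <- data.frame(
          chain = "A", resno = i, resname = "RNG",
          atom = sprintf("C%d", seq_len(n_atoms)), element = "C",
          x = ring_radius[i] * cos(th), y = ring_radius[i] * sin(th),
          z = ring_z[i])
      }
      structure_model(do.call(rbind, rows), title = "toy pore ring stack")
    },
    duplicate_with_transform = {
      base <- p$base
      stopifnot(inherits(base, "structure_model"))
      angle <- (p$angle_deg %||% 0) * pi / 180
      axis <- p$axis %||% c(0, 0, 1)
      axis <- axis / sqrt(sum(axis^2))
      tr <- p$translation %||% c(0, 0, 0)
      R <- rotation_about_axis(axis, angle)
      xyz <- coords(base) %*% t(R)
      xyz <- sweep(xyz, 2, tr, "+")
      a <- base$atoms
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      if (!is.null(p$displace_resno)) {
        d <- p$displacement %||% c(1, 0, 0)
        sel <- a$resno %in% p$displace_resno
        a$x[sel] <- a$x[sel] + d[1]
        a$y[sel] <- a$y[sel] + d[2]
        a$z[sel] <- a$z[sel] + d[3]
      }
      structure_model(a, title = paste0(base$title, " (transformed)"))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rodrigues rotation matrix about a unit axis
rotation_about_axis <- function(axis, angle) {
  u <- axis; c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}
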