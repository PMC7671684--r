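# Molecular-ruler measurements: segment-anchored Kabsch superposition,
# per-residue backbone RMSD against a reference model, minimum
# inter-residue distances (hydrogen-bond pair geometry), and HOLE-style
# pore-radius profiles.

# Bondi van der Waals radii (A)
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                NA. = 2.27, K = 2.75, MG = 1.73, CA. = 2.31, ZN = 1.39,
                FE = 1.94, SE = 1.90)

vdw_radius <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."; el[el == "CA"] <- "CA."
  r <- .VDW_RADII[el]
  if (any(is.na(r)))
    stop("radius-table error: no van der Waals radius for element(s) ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

.BACKBONE <- c("N", "CA", "C", "O")

# resolve a selection (list with optional chain, resno, atoms) against an
# atom table; returns row indices
select_atoms <- function(atoms, selection) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selection$chain)) keep <- keep & atoms$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & atoms$resno %in% selection$resno
  if (!is.null(selection$atoms)) keep <- keep & atoms$atom %in% selection$atoms
  which(keep)
}

# pair atoms between two structures by (chain, resno, atom name) within a
# selection; returns list of matched coordinate matrices
pair_atoms <- function(mobile, reference, selection) {
  im <- select_atoms(mobile$atoms, selection)
  ir <- select_atoms(reference$atoms, selection)
  if (length(im) == 0L || length(ir) == 0L)
    stop("pairing error: selection matches no atoms in one of the structures")
  keym <- paste(mobile$atoms$chain[im], mobile$atoms$resno[im],
                mobile$atoms$atom[im])
  keyr <- paste(reference$atoms$chain[ir], reference$atoms$resno[ir],
                reference$atoms$atom[ir])
  common <- intersect(keym, keyr)
  if (length(common) == 0L)
    stop("pairing error: no atoms shared between the selections")
  P <- coords(mobile)[im[match(common, keym)], , drop = FALSE]
  Q <- coords(reference)[ir[match(common, keyr)], , drop = FALSE]
  list(P = P, Q = Q, keys = common)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid-body superposition of the selected atoms of
#' `mobile` onto the matching atoms of `reference` using the SVD-based
#' Kabsch algorithm with the proper-rotation (det = +1) correction. The
#' transform estimated on the selection is applied to all atoms of
#' `mobile`.
#'
#' @param mobile,reference [structure_model()] objects
#' @param selection list with optional elements `chain`, `resno`, `atoms`
#'   restricting the atoms used to estimate the transform (e.g.
#'   `list(resno = 550:570, atoms = c("N","CA","C","O"))`); atoms are
#'   paired by (chain, residue number, atom name)
#' @return list with `rotation` (3x3), `translation` (length 3),
#'   `transformed` (the transformed mobile structure), `rmsd` (over the
#'   selection, A), and `n_atoms`
#' @export
superpose_kabsch <- function(mobile, reference, selection = list()) {
  pr <- pair_atoms(mobile, reference, selection)
  P <- pr$P; Q <- pr$Q
  if (nrow(P) < 3L)
    stop("pairing error: need >= 3 paired atoms for a rigid superposition")
  Pc <- colMeans(P); Qc <- colMeans(Q)
  P0 <- sweep(P, 2, Pc); Q0 <- sweep(Q, 2, Qc)
  sv <- svd(crossprod(P0, Q0))          # H = P0' Q0 ; R = V diag(1,1,d) U'
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("rank error: selection is collinear or degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- unname(Qc - as.numeric(R %*% Pc))
  apply_tr <- function(X) sweep(X %*% t(R), 2, translation, "+")
  rmsd <- sqrt(mean(rowSums((apply_tr(P) - Q)^2)))
  a <- mobile$atoms
  xyz <- apply_tr(coords(mobile))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  list(rotation = R, translation = translation,
       transformed = structure_model(a, title = mobile$title),
       rmsd = rmsd, n_atoms = nrow(P))
}

#' Per-residue RMSD against a reference after segment-anchored alignment
#'
#' The mobile structure is first superposed on the reference using only
#' the `align` residue range (the anchoring segment, e.g. S4); the
#' per-residue RMSD over `atom_set` is then computed for every residue of
#' `analyze` without any re-fitting. Residues missing from either
#' structure are reported as `NA` (gaps), never as zeros.
#'
#' @param mobile,reference [structure_model()] objects
#' @param analyze residue numbers to profile
#' @param align residue numbers used for the superposition anchor
#' @param atom_set atoms per residue (default backbone N, CA, C, O;
#'   use `"CA"` for a CA-only profile)
#' @param chain optional chain restriction applied to both ranges
#' @return an `rmsd_profile` data.frame (`resno`, `rmsd_A`, `n_atoms`)
#'   with attributes `align_resno`, `atom_set`, `alignment_rmsd`
#' @export
per_residue_rmsd <- function(mobile, reference, analyze, align,
                             atom_set = .BACKBONE, chain = NULL) {
  sup <- superpose_kabsch(mobile, reference,
                          list(chain = chain, resno = align,
                               atoms = atom_set))
  m <- sup$transformed
  out <- data.frame(resno = analyze, rmsd_A = NA_real_,
                    n_atoms = 0L)
  for (i in seq_along(analyze)) {
    pr <- tryCatch(
      pair_atoms(m, reference,
                 list(chain = chain, resno = analyze[i], atoms = atom_set)),
      error = function(e) NULL)
    if (is.null(pr)) next
    out$rmsd_A[i] <- sqrt(mean(rowSums((pr$P - pr$Q)^2)))
    out$n_atoms[i] <- nrow(pr$P)
  }
  attr(out, "align_resno") <- align
  attr(out, "atom_set") <- atom_set
  attr(out, "alignment_rmsd") <- sup$rmsd
  class(out) <- c("rmsd_profile", "data.frame")
  out
}

#' Minimum distance between atom subsets of two residues
#'
#' The molecular-ruler distance: minimum pairwise Euclidean distance
#' between the chosen atoms of residue A and residue B (by default the
#' full sidechain-oxygen picture used for hydrogen-bond pairs is obtained
#' by passing the relevant atom names). When no chain is specified the
#' distance is computed independently within every chain containing both
#' residues (the per-subunit measurement of a homotetramer) and the mean
#' is reported alongside.
#'
#' @param s a [structure_model()]
#' @param resA,resB lists with `resno`, optional `chain`, optional `atoms`
#'   (atom-name subset; default all atoms of the residue)
#' @return if a chain is given (or the structure has one chain): the
#'   distance in A. Otherwise a list with `per_chain` (named vector) and
#'   `mean`
#' @export
residue_min_distance <- function(s, resA, resB) {
  one <- function(chain) {
    selA <- select_atoms(s$atoms, list(chain = chain, resno = resA$resno,
                                       atoms = resA$atoms))
    selB <- select_atoms(s$atoms, list(chain = chain, resno = resB$resno,
                                       atoms = resB$atoms))
    if (length(selA) == 0L)
      stop("missing-atom error: residue ", resA$resno, " atoms (",
           paste(resA$atoms, collapse = ","), ") not found",
           if (!is.null(chain)) paste0(" in chain ", chain) else "")
    if (length(selB) == 0L)
      stop("missing-atom error: residue ", resB$resno, " atoms (",
           paste(resB$atoms, collapse = ","), ") not found",
           if (!is.null(chain)) paste0(" in chain ", chain) else "")
    A <- coords(s)[selA, , drop = FALSE]
    B <- coords(s)[selB, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }
  chainA <- resA$chain %||% NULL
  if (!is.null(chainA)) return(one(chainA))
  chains <- unique(s$atoms$chain[s$atoms$resno == resA$resno])
  chains <- intersect(chains, unique(s$atoms$chain[s$atoms$resno == resB$resno]))
  if (length(chains) <= 1L) return(one(if (length(chains)) chains else NULL))
  per <- vapply(chains, one, numeric(1))
  list(per_chain = per, mean = mean(per))
}

#' Map mouse TRPV1 residue numbering onto rat structure numbering
#'
#' The functional work uses mouse numbering while the reference cryo-EM
#' structures are rat; the default offset is mouse = rat + 1 (so mouse
#' T551/E571 correspond to structure residues 550/570).
#'
#' @param mouse_resno residue number(s), mouse numbering
#' @param offset numbering offset (default 1)
#' @return structure (rat) residue number(s)
#' @export
mouse_to_rat_resno <- function(mouse_resno, offset = 1L) mouse_resno - offset

#' HOLE-style pore radius profile along the permeation axis
#'
#' At each axial position z the pore radius is the radius of the largest
#' sphere centred on the axis (mode `"fixed_axis"`) or centred at a
#' locally optimized point in the z-plane (mode `"optimized_center"`,
#' grid-then-refine search) that touches no atom:
#' radius = min over atoms of (distance from centre to atom centre - vdW
#' radius). Radii larger than `max_radius` are reported as `max_radius`
#' with `unbounded = TRUE`.
#'
#' @param s a [structure_model()]
#' @param axis `"z"` (default; the z axis through the xy centroid),
#'   `"principal"` (largest principal axis of the coordinates), or a list
#'   with `point` and `direction` defining an explicit line
#' @param z_range length-2 axial range, A (default the structure's z span)
#' @param step axial step, A
#' @param mode `"fixed_axis"` or `"optimized_center"`
#' @param max_radius radius at which a slice is declared unbounded, A
#' @return a `pore_profile` data.frame (`z`, `radius_A`, `unbounded`)
#' @export
pore_profile <- function(s, axis = "z", z_range = NULL, step = 0.5,
                         mode = c("fixed_axis", "optimized_center"),
                         max_radius = 10) {
  mode <- match.arg(mode)
  xyz <- coords(s)
  rad <- vdw_radius(s$atoms$element)
  # express coordinates in a frame whose third axis is the pore axis
  if (is.list(axis)) {
    u <- axis$direction / sqrt(sum(axis$direction^2))
    origin <- axis$point
  } else if (identical(axis, "principal")) {
    origin <- colMeans(xyz)
    u <- eigen(stats::cov(xyz))$vectors[, 1]
  } else {
    origin <- c(colMeans(xyz)[1:2], 0)
    u <- c(0, 0, 1)
  }
  # orthonormal basis (e1, e2, u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rel <- sweep(xyz, 2, origin)
  loc <- cbind(rel %*% e1, rel %*% e2, rel %*% u)
  if (is.null(z_range)) z_range <- range(loc[, 3])
  zs <- seq(z_range[1], z_range[2], by = step)

  radius_at <- function(cx, cy, z) {
    d <- sqrt((loc[, 1] - cx)^2 + (loc[, 2] - cy)^2 + (loc[, 3] - z)^2)
    min(d - rad)
  }
  res <- vapply(zs, function(z) {
    if (mode == "fixed_axis") {
      r <- radius_at(0, 0, z)
    } else {
      # coarse grid then Nelder-Mead refinement of the centre in-plane
      g <- seq(-2, 2, by = 0.5)
      grid <- expand.grid(cx = g, cy = g)
      vals <- mapply(radius_at, grid$cx, grid$cy, MoreArgs = list(z = z))
      best <- grid[which.max(vals), ]
      opt <- stats::optim(c(best$cx, best$cy),
                          function(p) -radius_at(p[1], p[2], z),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10))
      r <- -opt$value
    }
    r
  }, numeric(1))
  out <- data.frame(z = zs, radius_A = pmin(res, max_radius),
                    unbounded = res > max_radius)
  out$radius_A[out$radius_A < 0] <- 0
  class(out) <- c("pore_profile", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Write an RMSD or pore profile as TSV
#'
#' @param profile an `rmsd_profile` or `pore_profile`
#' @param path output path
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
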