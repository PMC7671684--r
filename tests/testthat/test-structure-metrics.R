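make_minimal_pdb <- function() {
  paste(
    "ATOM      1  OG1 THR A 550      10.000  10.000  10.000  1.00  0.00           O",
    "ATOM      2  OE1 GLU A 570      10.000  10.000  13.000  1.00  0.00           O",
    sep = "\n")
}

test_that("minimal ATOM records parse with exact coordinates", {
  s <- read_structure(make_minimal_pdb())
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$z, c(10, 13))
  expect_equal(s$atoms$resno, c(550L, 570L))
  expect_identical(s$atoms$element, c("O", "O"))
})

test_that("altloc policy keeps the highest-occupancy record, ties to A", {
  txt <- paste(
    "ATOM      1  CA BALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "ATOM      2  CA AALA A   1       2.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    sep = "\n")
  s <- read_structure(txt)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_equal(ca$x, 1)  # occupancy 0.70 wins
  expect_equal(cb$x, 3)  # tie resolved in favour of altloc A
})

test_that("truncated and empty inputs raise parse errors with line numbers", {
  bad <- paste(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       bad.00   0.000   0.0    1.00  0.00",
    sep = "\n")
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure("ATOM   1 CA"), "line 1")
  expect_error(read_structure("HEADER only\nEND"), "no ATOM")
})

test_that("only the first MODEL block is read, with a warning", {
  txt <- paste(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    sep = "\n")
  expect_warning(s <- read_structure(txt), "MODEL")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 1)
})

test_that("write-then-read preserves coordinates to PDB precision", {
  h <- make_toy_structure("helix", n_res = 8)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, p)
  rt <- read_structure(p)
  expect_equal(nrow(rt$atoms), nrow(h$atoms))
  for (col in c("x", "y", "z"))
    expect_lt(max(abs(rt$atoms[[col]] - h$atoms[[col]])), 5.1e-4)
})

test_that("self-superposition is the identity with zero RMSD", {
  h <- make_toy_structure("helix", n_res = 10)
  sup <- superpose_kabsch(h, h, list(atoms = "CA"))
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(sup$rmsd, 1e-12)
})

test_that("a rigid motion is recovered and inverted by superposition", {
  h <- make_toy_structure("helix", n_res = 12)
  moved <- make_toy_structure("duplicate_with_transform", base = h,
                              angle_deg = 90, axis = c(0, 0, 1),
                              translation = c(4, -7, 2))
  sup <- superpose_kabsch(moved, h, list())
  expect_lt(sup$rmsd, 1e-6)
  expect_lt(max(abs(coords(sup$transformed) - coords(h))), 1e-6)
})

test_that("Kabsch agrees with the quaternion oracle on noisy point clouds", {
  set.seed(77)
  for (i in 1:10) {
    P <- matrix(stats::rnorm(30, sd = 4), ncol = 3)
    ang <- stats::runif(1, 0, pi)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R0 <- trpv1ruler:::rotation_about_axis(ax, ang)
    Q <- sweep(P %*% t(R0), 2, stats::rnorm(3, sd = 5), "+") +
      matrix(stats::rnorm(30, sd = 0.1), ncol = 3)
    sm <- structure_model(data.frame(
      chain = "A", resno = 1:10, resname = "GLY", atom = "CA",
      element = "C", x = P[, 1], y = P[, 2], z = P[, 3]))
    sq <- structure_model(data.frame(
      chain = "A", resno = 1:10, resname = "GLY", atom = "CA",
      element = "C", x = Q[, 1], y = Q[, 2], z = Q[, 3]))
    sup <- superpose_kabsch(sm, sq, list())
    orc <- quaternion_superpose(P, Q)
    expect_lt(max(abs(sup$rotation - orc$rotation)), 1e-6)
    expect_lt(abs(sup$rmsd - orc$rmsd), 1e-6)
    expect_true(sup$rmsd > 0.05 && sup$rmsd < 0.2)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate selections raise rank and pairing errors", {
  line <- structure_model(data.frame(
    chain = "A", resno = 1:4, resname = "GLY", atom = "CA", element = "C",
    x = 1:4, y = 0, z = 0))
  expect_error(superpose_kabsch(line, line, list()), "rank|collinear")
  h <- make_toy_structure("helix", n_res = 5)
  expect_error(superpose_kabsch(h, h, list(resno = 100:110)), "pairing")
})

test_that("per-residue RMSD reports constructed displacements exactly", {
  h <- make_toy_structure("helix", n_res = 20)
  ident <- per_residue_rmsd(h, h, analyze = 1:20, align = 1:20)
  expect_true(all(ident$rmsd_A < 1e-12))
  # displace residues outside the alignment anchor by exactly 1 A
  moved <- make_toy_structure("duplicate_with_transform", base = h,
                              angle_deg = 40, translation = c(2, 1, -3),
                              displace_resno = 14:17,
                              displacement = c(0, 1, 0))
  pr <- per_residue_rmsd(moved, h, analyze = 1:20, align = 1:10)
  expect_equal(pr$rmsd_A[14:17], rep(1, 4), tolerance = 1e-9)
  expect_true(all(pr$rmsd_A[1:10] < 1e-9))
})

test_that("per-residue RMSD matches a direct per-atom recomputation", {
  set.seed(21)
  h <- make_toy_structure("helix", n_res = 15)
  moved <- h
  disp <- stats::runif(15, 0, 1)
  for (i in 1:15) {
    sel <- moved$atoms$resno == i
    dvec <- stats::rnorm(3); dvec <- dvec / sqrt(sum(dvec^2)) * disp[i]
    moved$atoms$x[sel] <- moved$atoms$x[sel] + dvec[1]
    moved$atoms$y[sel] <- moved$atoms$y[sel] + dvec[2]
    moved$atoms$z[sel] <- moved$atoms$z[sel] + dvec[3]
  }
  # identity anchor: residue 1 is left in place, so align on an
  # undisplaced copy appended as residues 100+ would be artificial;
  # instead verify against the brute-force sum over atoms after the same
  # superposition
  sup <- superpose_kabsch(moved, h, list(atoms = c("N", "CA", "C", "O")))
  pr <- per_residue_rmsd(moved, h, analyze = 1:15, align = 1:15)
  for (i in 1:15) {
    sel_m <- which(sup$transformed$atoms$resno == i)
    sel_r <- which(h$atoms$resno == i)
    d2 <- (coords(sup$transformed)[sel_m, ] - coords(h)[sel_r, ])^2
    expect_equal(pr$rmsd_A[i], sqrt(mean(rowSums(d2))), tolerance = 1e-12)
  }
  # sum-of-squares consistency with the alignment RMSD
  n_at <- pr$n_atoms
  expect_equal(sqrt(sum(pr$rmsd_A^2 * n_at) / sum(n_at)),
               attr(pr, "alignment_rmsd"), tolerance = 1e-9)
})

test_that("missing residues appear as gaps, not zeros", {
  h <- make_toy_structure("helix", n_res = 10)
  pr <- per_residue_rmsd(h, h, analyze = 1:12, align = 1:10)
  expect_true(all(is.na(pr$rmsd_A[11:12])))
  expect_true(all(pr$n_atoms[11:12] == 0))
})

test_that("minimum inter-residue distances with per-chain tetramer reporting", {
  s <- structure_model(data.frame(
    chain = "A", resno = c(1, 1, 2), resname = c("THR", "THR", "GLU"),
    atom = c("OG1", "CB", "OE1"), element = c("O", "C", "O"),
    x = c(0, 5, 0), y = 0, z = c(0, 0, 3)))
  expect_equal(residue_min_distance(s, list(resno = 1, atoms = "OG1"),
                                    list(resno = 2, atoms = "OE1")), 3)
  expect_equal(residue_min_distance(s, list(resno = 1, atoms = "OG1"),
                                    list(resno = 1, atoms = "OG1")), 0)
  expect_error(residue_min_distance(s, list(resno = 1, atoms = "OD9"),
                                    list(resno = 2)), "missing-atom")
  # two chains: per-chain breakdown plus mean
  s2 <- structure_model(data.frame(
    chain = rep(c("A", "B"), each = 2), resno = rep(c(1, 2), 2),
    resname = "GLY", atom = "O", element = "O",
    x = 0, y = 0, z = c(0, 3, 10, 15)))
  d <- residue_min_distance(s2, list(resno = 1), list(resno = 2))
  expect_equal(unname(d$per_chain), c(3, 5))
  expect_equal(d$mean, 4)
})

test_that("all ruler metrics are invariant under a common rigid transform", {
  h <- make_toy_structure("helix", n_res = 12)
  moved <- make_toy_structure("duplicate_with_transform", base = h,
                              angle_deg = 25, translation = c(1, 2, 3),
                              displace_resno = 8:9,
                              displacement = c(0.6, 0, 0))
  pr0 <- per_residue_rmsd(moved, h, analyze = 1:12, align = 1:6)
  common <- function(s) make_toy_structure("duplicate_with_transform",
                                           base = s, angle_deg = 120,
                                           axis = c(1, 1, 0),
                                           translation = c(-5, 3, 9))
  pr1 <- per_residue_rmsd(common(moved), common(h), analyze = 1:12,
                          align = 1:6)
  expect_equal(pr1$rmsd_A, pr0$rmsd_A, tolerance = 1e-9)
  d0 <- residue_min_distance(h, list(resno = 2), list(resno = 9))
  d1 <- residue_min_distance(common(h), list(resno = 2), list(resno = 9))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("pore radius of a single ring equals the analytic value", {
  rs <- make_toy_structure("pore_ring_stack", ring_z = 0, ring_radius = 6,
                           n_atoms = 12)
  pp <- pore_profile(rs, axis = "z", z_range = c(0, 0), step = 1)
  expect_equal(pp$radius_A, 6 - 1.7, tolerance = 1e-9)
  expect_error(make_toy_structure("pore_ring_stack", ring_z = 0,
                                  ring_radius = 1.5), "invalid geometry")
})

test_that("slices far from any atom are flagged unbounded", {
  rs <- make_toy_structure("pore_ring_stack", ring_z = 0, ring_radius = 6,
                           n_atoms = 12)
  pp <- pore_profile(rs, axis = "z", z_range = c(40, 40), step = 1,
                     max_radius = 10)
  expect_true(pp$unbounded[1])
  expect_equal(pp$radius_A[1], 10)
})

test_that("pore profile matches the brute-force sphere search oracle", {
  rs <- make_toy_structure("pore_ring_stack", ring_z = c(0, 3, 6),
                           ring_radius = c(6, 4.5, 5.2), n_atoms = 10,
                           stagger = c(0, 0.3, 0.1))
  xyz <- coords(rs)
  radii <- rep(1.7, nrow(xyz))
  # fixed-axis mode against the direct on-axis computation
  pp <- pore_profile(rs, axis = "z", z_range = c(0, 6), step = 1)
  for (i in seq_len(nrow(pp))) {
    expect_equal(pp$radius_A[i],
                 brute_force_pore_radius(xyz, radii, pp$z[i],
                                         fixed_centre = TRUE),
                 tolerance = 1e-9)
  }
  # optimized-centre mode against the exhaustive 0.05 A grid search
  rs_off <- make_toy_structure("duplicate_with_transform", base = rs,
                               translation = c(0.4, -0.3, 0))
  pp_opt <- pore_profile(rs_off, axis = "z", z_range = c(0, 6), step = 2,
                         mode = "optimized_center")
  xyz_off <- coords(rs_off)
  for (i in seq_len(nrow(pp_opt))) {
    bf <- brute_force_pore_radius(
      sweep(xyz_off, 2, c(colMeans(xyz_off)[1:2], 0)), radii, pp_opt$z[i])
    expect_lt(abs(pp_opt$radius_A[i] - bf), 0.05)
  }
})

test_that("pore radius never exceeds the distance to the nearest atom centre", {
  rs <- make_toy_structure("pore_ring_stack", ring_z = c(0, 4),
                           ring_radius = c(6, 5), n_atoms = 12)
  pp <- pore_profile(rs, axis = "z", z_range = c(0, 4), step = 0.5)
  xyz <- coords(rs)
  for (i in seq_len(nrow(pp))) {
    ctr <- c(colMeans(xyz)[1:2], pp$z[i])
    nearest <- min(sqrt(colSums((t(xyz) - ctr)^2)))
    expect_lte(pp$radius_A[i], nearest + 1e-9)
  }
})

test_that("mouse-to-structure residue numbering maps with the default offset", {
  expect_equal(mouse_to_rat_resno(c(551, 571)), c(550, 570))
  expect_equal(mouse_to_rat_resno(551, offset = 0), 551)
})
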