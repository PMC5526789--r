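test_that("a minimal hand-written PDB round-trips with coordinates intact", {
  pdb_lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(1.234, 4.567, 7.890), c(0.111, -2.222, 3.333),
            c(9.876, 5.432, 1.098)),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$resno, 1:3)
  expect_identical(m$atoms$x, c(1.234, 4.567, 7.890))
  expect_identical(m$atoms$y, c(0.111, -2.222, 3.333))
  expect_identical(m$atoms$z, c(9.876, 5.432, 1.098))
})

test_that("writer round-trips a generated coiled coil to format precision", {
  m <- make_monomer_arm(coil_params(n_residues = 20))
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = paste0(".", if (fmt == "pdb") "pdb" else "cif"))
    write_structure(m, f, format = fmt)
    m2 <- read_structure(f)
    expect_equal(xyz_of(m2), xyz_of(m), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(m2$atoms$resno, m$atoms$resno)
  }
})

test_that("unknown formats and unreadable files raise informative errors", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("not a structure", f)
  expect_error(read_structure(f), "format")
})

test_that("extract_ca preserves request order and reports missing residues", {
  m <- make_monomer_arm(coil_params(n_residues = 10))
  sel <- extract_ca(m, "A", c(5, 2, 9))
  expect_equal(sel$resno, c(5, 2, 9))
  expect_length(attr(sel, "missing"), 0)
  sel2 <- extract_ca(m, "A", c(3, 999))
  expect_equal(sel2$resno, 3)
  expect_equal(attr(sel2, "missing"), 999L)
  expect_error(extract_ca(m, "Z", 1), "chain")
  expect_error(extract_ca(m, "A", integer()), "empty")
})

test_that("superposition is exact on itself and inverts a known rigid motion", {
  set.seed(11)
  P <- matrix(rnorm(60, sd = 10), 20)
  self <- superpose(P, P)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$transform$R, diag(3), tolerance = 1e-9)
  tr <- rigid_transform(rotation_about_axis(c(1, 2, 2) / 3, 37 * pi / 180),
                        c(5, -3, 12))
  moved <- apply_transform(P, tr)
  back <- superpose(moved, P)
  expect_lt(back$rmsd, 1e-9)
  inv <- invert_transform(tr)
  expect_equal(back$transform$R, inv$R, tolerance = 1e-9)
  expect_equal(back$transform$t, inv$t, tolerance = 1e-9)
})

test_that("superposition rejects mismatched and degenerate inputs", {
  P <- matrix(rnorm(30), 10)
  expect_error(superpose(P, P[1:5, ]), "pairing")
  expect_error(superpose(P[1:2, ], P[1:2, ]), ">= 3")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition matches the quaternion oracle and is motion-invariant", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    P <- matrix(rnorm(3 * n, sd = 8), n)
    Q <- apply_transform(P, random_rigid()) + matrix(rnorm(3 * n, sd = 0.5), n)
    fit <- superpose(P, Q)
    expect_lt(abs(fit$rmsd - quaternion_superpose_rmsd(P, Q)), 1e-8)
    ## self-consistency: rmsd equals brute-force recomputation
    moved <- apply_transform(P, fit$transform)
    expect_lt(abs(fit$rmsd - sqrt(mean(rowSums((moved - Q)^2)))), 1e-9)
    ## invariance to a common pre-rotation
    com <- random_rigid()
    fit2 <- superpose(apply_transform(P, com), apply_transform(Q, com))
    expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-9)
    expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  }
  ## third route: bio3d's fitter agrees too
  for (i in 1:5) {
    P <- matrix(rnorm(45, sd = 8), 15)
    Q <- apply_transform(P, random_rigid()) + matrix(rnorm(45, sd = 0.4), 15)
    ours <- superpose(P, Q)$rmsd
    moved <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
    theirs <- suppressWarnings(bio3d::rmsd(as.vector(t(Q)), moved))
    expect_lt(abs(ours - theirs), 1e-3)   # bio3d::rmsd rounds to 3 decimals
  }
})

test_that("symmetry-mate distance is zero on the axis and reports unresolved positions", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 5), c(0, 0, 10))  # residues 1 and 3 on the z axis
  m <- point_model(xyz)
  dimer <- build_c2_dimer(m, c2_axis(c(0, 0, 1), c(0, 0, 0)))
  d <- symmetry_pair_distances(dimer, "A", "B", c(1, 2, 3, 99))
  expect_equal(d$position, c(1, 2, 3))
  expect_equal(d$distance[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_equal(d$distance[2], 6, tolerance = 1e-12)
  expect_equal(attr(d, "unresolved"), 99L)
  expect_error(symmetry_pair_distances(dimer, "A", "Q"), "chain")
})

test_that("clash counting matches brute force and the coincident-chain case", {
  far <- point_model(rbind(cbind(0, 0, seq(0, 36, by = 4))))
  far2 <- far$atoms; far2$chain <- "B"; far2$x <- far2$x + 100
  apart <- structure_model(rbind(far$atoms, far2))
  expect_identical(clash_count(apart, 4), 0L)

  dup <- far$atoms; dup$chain <- "B"
  coincident <- structure_model(rbind(far$atoms, dup))
  expect_equal(clash_count(coincident, 0.1), nrow(far$atoms))

  set.seed(5)
  m <- make_monomer_arm(coil_params(n_residues = 40))
  rod <- make_rod_dimer(m)
  expect_equal(clash_count(rod$dimer, 4), brute_clash(rod$dimer, 4))
  expect_equal(clash_count(rod$dimer, 6.5), brute_clash(rod$dimer, 6.5))
  expect_error(clash_count(rod$dimer, -1), "cutoff")
})

test_that("rigid transforms compose, invert and reject improper rotations", {
  set.seed(31)
  a <- random_rigid(); b <- random_rigid()
  ab <- compose_transforms(a, b)
  x <- matrix(rnorm(30), 10)
  expect_equal(apply_transform(apply_transform(x, b), a), apply_transform(x, ab),
               tolerance = 1e-10)
  ident <- compose_transforms(a, invert_transform(a))
  expect_equal(ident$R, diag(3), tolerance = 1e-9)
  expect_equal(ident$t, c(0, 0, 0), tolerance = 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("structure model invariants are enforced", {
  a <- data.frame(chain = "A", resno = c(1, 1), resid = "ALA", elety = "CA",
                  x = 0, y = 0, z = 0)
  expect_error(structure_model(a), "duplicate")
  b <- data.frame(chain = "A", resno = c(2, 1), resid = "ALA", elety = "CA",
                  x = 0:1, y = 0, z = 0)
  expect_error(structure_model(b), "increase")
  d <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                  x = NaN, y = 0, z = 0)
  expect_error(structure_model(d), "finite")
})
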