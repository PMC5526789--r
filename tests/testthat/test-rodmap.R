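make_rod_fixture <- function(n = 60, noise_sd = 0, seed = 1) {
  m <- make_monomer_arm(coil_params(n_residues = n))
  rod <- make_rod_dimer(m)
  tab <- simulate_efficiencies(rod$dimer, m$atoms$resno,
                               efficiency_noise_model(noise_sd = noise_sd,
                                                      seed = seed))
  list(monomer = m, rod = rod, table = tab)
}

test_that("annotation transfer follows the alignment and reports gap losses", {
  tab <- crosslink_table(c(10, 12, 20), c(0.5, 0.3, 0.1), protein_id = "Bs")
  ident <- alignment_map(1:30, 1:30, "Bs", "Py")
  same <- transfer_annotations(tab, ident)
  expect_equal(same$position, tab$position)
  expect_equal(same$efficiency, tab$efficiency)

  ## a 2-residue deletion in the target shifts downstream positions by -2
  map <- alignment_map(c(1:11, 14:25), c(1:11, 12:23), "Bs", "Py")
  out <- transfer_annotations(tab, map)
  expect_equal(out$position, c(10, 18))
  expect_equal(attr(out, "dropped"), 12)
  expect_equal(out$efficiency, c(0.5, 0.1))

  wrong <- alignment_map(1:30, 1:30, "Pf", "Py")
  expect_error(transfer_annotations(tab, wrong), "mismatch")
})

test_that("aligned FASTA files parse into strictly increasing residue maps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">src", "MKV-LDQ", ">tgt", "MRVAL-Q"), f)
  map <- read_alignment_fasta(f, source_start = 5, target_start = 1)
  ## columns: M/M K/R V/V -/A L/L D/- Q/Q
  expect_equal(map$pairs$source, c(5, 6, 7, 8, 10))
  expect_equal(map$pairs$target, c(1, 2, 3, 5, 6))
  expect_equal(map$source_id, "src")
  expect_error(alignment_map(c(1, 3, 2), c(1, 2, 3)), "increase")
})

test_that("profiles join efficiencies with symmetry-mate distances consistently", {
  fx <- make_rod_fixture()
  prof <- build_profile(fx$table, fx$rod$dimer)
  expect_equal(nrow(prof), sum(fx$table$tested))
  d <- symmetry_pair_distances(fx$rod$dimer, "A", "B", prof$position)
  expect_equal(prof$distance, d$distance)
  expect_equal(prof$within_reach, prof$distance <= 14)
  ## zero-noise simulation: efficiency strictly decreasing in distance
  ord <- order(prof$distance)
  dd <- prof$distance[ord]; ee <- prof$efficiency[ord]
  distinct <- diff(dd) > 1e-9
  expect_true(all(diff(ee)[distinct] < 0))
  uniq <- !duplicated(round(dd, 9))
  expect_equal(suppressWarnings(cor(ee[uniq], dd[uniq], method = "spearman")),
               -1, tolerance = 1e-9)
  ## high-efficiency rows sit at short distances
  expect_lt(max(prof$distance[prof$efficiency > 0.4]),
            min(prof$distance[prof$efficiency < 0.05]))
})

test_that("an all-untested table yields an empty profile with a full report", {
  fx <- make_rod_fixture(n = 20)
  untested <- crosslink_table(1:40, rep(NA_real_, 40))
  prof <- build_profile(untested, fx$rod$dimer)
  expect_equal(nrow(prof), 0)
  expect_length(attr(prof, "unresolved"), 0)
})

test_that("compatibility score counts axial violations and ignores rigid motion", {
  fx <- make_rod_fixture()
  prof <- build_profile(fx$table, fx$rod$dimer)
  cs <- compatibility_score(prof)
  expect_equal(cs$score, mean(prof$within_reach[prof$efficiency > 0.2]))
  expect_equal(nrow(cs$violations), cs$n_axial - round(cs$score * cs$n_axial))

  moved <- apply_transform(fx$rod$dimer, random_rigid())
  prof2 <- build_profile(fx$table, moved)
  expect_equal(compatibility_score(prof2)$score, cs$score, tolerance = 1e-9)

  ## planted violations: pushing 10% of the in-reach axial rows beyond
  ## reach lowers the score by exactly that count
  p <- prof[prof$efficiency > 0.2, , drop = FALSE]
  base <- compatibility_score(p)$score
  k <- max(1, round(0.1 * nrow(p)))
  idx <- which(p$within_reach)[seq_len(k)]
  p$distance[idx] <- 14 + 10
  p$within_reach <- p$distance <= 14
  expect_equal(compatibility_score(p)$score, base - k / nrow(p),
               tolerance = 1e-12)

  none <- prof; none$efficiency <- 0.01
  expect_error(compatibility_score(none), "axial")
})

test_that("collinearity is exact on a line and matches the brute-force fit under noise", {
  t <- seq(0, 80, length.out = 30)
  on_line <- cbind(1 + 0.3 * t, -2 + 0.8 * t, 0.52 * t)
  m <- point_model(on_line)
  cl <- collinearity(m, "A", 1:30)
  expect_lt(cl$rms, 1e-9)
  expect_error(collinearity(point_model(on_line[1:2, ]), "A", 1:2), ">= 3")

  ## Monte-Carlo oracle: isotropic sd-1 noise about a line leaves an RMS
  ## perpendicular residual near sqrt(2) (two perpendicular degrees of
  ## freedom), slightly shrunk by the fit; assert per-draw agreement with
  ## the independent eigen-based fit and the ensemble mean
  set.seed(99)
  rms <- replicate(120, {
    noisy <- on_line + matrix(rnorm(90), 30)
    got <- collinearity(point_model(noisy), "A", 1:30)$rms
    expect_lt(abs(got - brute_line_rms(noisy)), 1e-9)
    got
  })
  expect_gt(mean(rms), sqrt(2) - 0.12)
  expect_lt(mean(rms), sqrt(2) + 0.05)
})

test_that("axial residues are more collinear than random residue sets", {
  fx <- make_rod_fixture()
  axial <- call_axial(fx$table)
  perm <- collinearity_permutation(fx$monomer, "A", axial, n_perm = 200, seed = 4)
  expect_lt(perm$p_value, 0.05)
  expect_lt(perm$observed_rms, median(perm$perm_rms))
})

test_that("viewer attribute export tags untested residues", {
  tab <- crosslink_table(1:3, c(0.5, NA, 0.01))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_class_attributes(tab, "A", f)
  got <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(got$class, c("high", "untested", "none"))
})
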