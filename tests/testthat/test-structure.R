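test_that("PDB reading returns exact coordinates and hetero flags", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4 FE1  CLF X 900       0.000   0.000   0.000  1.00  0.00          FE",
    "HETATM    5  O   HOH W 700       2.500   0.000   0.000  1.00  0.00           O",
    "END"), pdb)
  m <- read_structure(pdb)
  expect_equal(nrow(m$atoms), 5L)
  expect_equal(m$atoms$x[1], 1.0)
  expect_equal(sum(m$atoms$hetero), 2L)
  expect_equal(sum(m$atoms$water), 1L)
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("models survive a write/read round trip", {
  ts <- generate_toy_structure(toy_structure_spec(n_residues = 10), seed = 4)
  p2 <- tempfile(fileext = ".pdb")
  write_structure(ts$model, p2)
  back <- read_structure(p2)
  expect_equal(back$atoms$chain, ts$model$atoms$chain)
  expect_equal(back$atoms$resno, ts$model$atoms$resno)
  expect_equal(back$atoms$x, ts$model$atoms$x, tolerance = 1e-3)
})

test_that("the contact-shell boundary is closed at the cutoff", {
  atoms <- data.frame(
    chain = c("A", "A", "X"), resno = c(1L, 2L, 900L),
    resid = c("GLY", "GLY", "CLF"), elety = c("CA", "CA", "FE1"),
    elesy = c("C", "C", "FE"),
    x = c(5.0, 5.001, 0), y = 0, z = 0, o = 1,
    hetero = c(FALSE, FALSE, TRUE), water = FALSE,
    stringsAsFactors = FALSE)
  m <- structure(list(atoms = atoms, path = NA), class = "structure_model")
  sh <- contact_shell(m, target_selection(m, "t", resid = "CLF"),
                      cutoff = 5.0)
  expect_identical(sh$entries$resno, 1L)  # exactly 5.0 A included, 5.001 not
  expect_equal(sh$entries$min_dist, 5.0)
  expect_error(contact_shell(m, target_selection(m, "t", resid = "CLF"),
                             cutoff = 0), "positive")
  expect_error(target_selection(m, "empty", resid = "ZZZ"), "empty")
})

test_that("shells match the all-pairs oracle and are monotone in cutoff", {
  for (seed in 1:8) {
    m <- random_toy_model(200, seed = seed)
    tsel <- target_selection(m, "cluster", resid = "CLF")
    for (cutoff in c(3, 5, 8)) {
      sh <- contact_shell(m, tsel, cutoff = cutoff)
      orc <- oracle_shell(m$atoms, tsel$idx, cutoff)
      expect_equal(shell_key(sh$entries), shell_key(orc))
      expect_equal(sh$entries$min_dist, orc$min_dist, tolerance = 1e-9)
    }
    # monotone: shell(a) subset of shell(b) for a <= b
    s3 <- contact_shell(m, tsel, cutoff = 3)
    s5 <- contact_shell(m, tsel, cutoff = 5)
    expect_true(all(shell_key(s3$entries) %in% shell_key(s5$entries)))
  }
})

test_that("shells are invariant under rigid-body motion", {
  m <- random_toy_model(150, seed = 42)
  tsel <- target_selection(m, "cluster", resid = "CLF")
  sh <- contact_shell(m, tsel)
  m2 <- rigid_transform(m)
  sh2 <- contact_shell(m2, target_selection(m2, "cluster", resid = "CLF"))
  expect_equal(shell_key(sh$entries), shell_key(sh2$entries))
  expect_equal(sh$entries$min_dist, sh2$entries$min_dist, tolerance = 1e-9)
})

test_that("water mediation requires a bridging water within both cutoffs", {
  mk <- function(res_d, wat_d) {
    atoms <- data.frame(
      chain = c("A", "W", "X"), resno = c(1L, 700L, 900L),
      resid = c("GLY", "HOH", "CLF"), elety = c("N", "O", "FE1"),
      elesy = c("N", "O", "FE"),
      x = c(wat_d + res_d, wat_d, 0), y = 0, z = 0, o = 1,
      hetero = c(FALSE, TRUE, TRUE), water = c(FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE)
    structure(list(atoms = atoms, path = NA), class = "structure_model")
  }
  m <- mk(3.0, 3.0)
  tsel <- target_selection(m, "t", resid = "CLF")
  wm <- water_mediated_contacts(m, tsel)
  expect_equal(wm$resno, 1L)
  # water too far from the target: no mediation
  m2 <- mk(3.0, 4.0)
  expect_equal(nrow(water_mediated_contacts(
    m2, target_selection(m2, "t", resid = "CLF"))), 0L)
  # residue too far from the water: no mediation
  m3 <- mk(4.0, 3.0)
  expect_equal(nrow(water_mediated_contacts(
    m3, target_selection(m3, "t", resid = "CLF"))), 0L)
  # no waters at all: empty
  m4 <- m; m4$atoms <- m4$atoms[!m4$atoms$water, ]
  expect_equal(nrow(water_mediated_contacts(
    m4, target_selection(m4, "t", resid = "CLF"))), 0L)
})

test_that("direct and water-mediated sets are disjoint on toy structures", {
  ts <- generate_toy_structure(
    toy_structure_spec(n_residues = 25, n_bridging_waters = 4,
                       n_far_waters = 3), seed = 9)
  m <- ts$model
  tsel <- target_selection(m, "cluster", resid = "CLF")
  sh <- contact_shell(m, tsel)
  wm <- water_mediated_contacts(m, tsel, direct_shell = sh)
  expect_equal(shell_key(sh$entries), shell_key(ts$expected_shell))
  expect_equal(paste(wm$chain, wm$resno),
               paste(ts$expected_water$chain, ts$expected_water$resno))
  expect_length(intersect(shell_key(sh$entries), paste(wm$chain, wm$resno)),
                0L)
})

test_that("shell annotation joins conservation classes by residue number", {
  # planted profiles: residues 1-9 invariant, 10-14 single variant, 15-19
  # variable, mirroring the cofactor-cluster pocket composition (9 + 5 + 5)
  set.seed(31)
  n <- 20
  mat <- cbind(
    matrix("G", n, 9),
    sapply(1:5, function(i) c(rep("R", n - 5), rep("K", 5))),
    sapply(1:5, function(i) sample(AA20[1:8], n, replace = TRUE)))
  rownames(mat) <- paste0("s", 1:n)
  aln <- make_aln(mat)
  rm <- build_reference_map(aln, "s1")
  prof <- conservation_profiles(aln, coaligned_columns(aln), refmap = rm)

  ts <- generate_toy_structure(
    toy_structure_spec(n_residues = 19, distances = rep(3, 19)), seed = 6)
  sh <- contact_shell(ts$model, ts$target)
  ann <- annotate_shell(sh, prof)
  expect_equal(unname(ann$tally["invariant"]), 9L)
  expect_equal(unname(ann$tally["single_variant"]), 5L)
  expect_equal(sum(ann$tally), nrow(sh$entries))

  # residues beyond alignment coverage are flagged, not dropped
  ts2 <- generate_toy_structure(
    toy_structure_spec(n_residues = 25, distances = rep(3, 25)), seed = 6)
  ann2 <- annotate_shell(contact_shell(ts2$model, ts2$target), prof)
  expect_equal(unname(ann2$tally["no_coverage"]), 6L)
  expect_equal(nrow(ann2$entries), 25L)
})
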