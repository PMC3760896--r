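test_that("indel fingerprints capture insertions, deletions and extensions", {
  # reference itself: empty fingerprint
  fam <- generate_family(family_spec(), seed = 2)
  aln <- fam$alignment
  rm <- build_reference_map(aln, fam$truth$reference_id)
  expect_equal(nrow(indel_fingerprint(aln, fam$truth$reference_id, rm)), 0L)

  # the Group II marker: one 52-residue insertion anchored after ref 391
  fpII <- indel_fingerprint(aln, "II-01", rm)
  expect_equal(nrow(fpII), 1L)
  expect_equal(fpII$kind, "insertion")
  expect_equal(fpII$anchor, 391L)
  expect_equal(fpII$length, 52L)

  # every group's fingerprint equals the generator's ground truth
  for (g in names(fam$truth$fingerprints)) {
    id <- paste0(g, "-01")
    fp <- indel_fingerprint(aln, id, rm)
    expect_equal(as.data.frame(fp), fam$truth$fingerprints[[g]],
                 ignore_attr = TRUE)
  }
})

test_that("fingerprints equal a brute-force run-length scan on random indels", {
  set.seed(99)
  for (rep in 1:10) {
    # build a 2-sequence alignment with random planted gap runs
    n_col <- 60
    ref <- sample(AA20, n_col, replace = TRUE)
    other <- sample(AA20, n_col, replace = TRUE)
    # plant deletions in 'other' and insertions (gaps in ref)
    for (k in seq_len(sample(1:3, 1))) {
      st <- sample(5:50, 1); len <- sample(1:4, 1)
      other[st:(st + len - 1)] <- "-"
    }
    for (k in seq_len(sample(1:3, 1))) {
      st <- sample(5:50, 1); len <- sample(1:3, 1)
      ref[st:(st + len - 1)] <- "-"
    }
    aln <- aa_alignment(c(ref = paste(ref, collapse = ""),
                          oth = paste(other, collapse = "")))
    rm <- build_reference_map(aln, "ref")
    fp <- indel_fingerprint(aln, "oth", rm)
    # brute force: walk the columns
    num <- oracle_refmap(aln$mat, "ref")
    dels <- integer(0); del_runs <- list()
    run <- NULL
    for (j in seq_len(n_col)) {
      if (!is.na(num[j])) {
        if (aln$mat["oth", j] == "-") {
          if (is.null(run)) run <- c(num[j], 0L)
          run[2] <- run[2] + 1L
        } else if (!is.null(run)) {
          del_runs[[length(del_runs) + 1L]] <- run; run <- NULL
        }
      }
    }
    if (!is.null(run)) del_runs[[length(del_runs) + 1L]] <- run
    got_dels <- fp[fp$kind == "deletion", ]
    expect_equal(nrow(got_dels), length(del_runs))
    for (i in seq_along(del_runs)) {
      expect_equal(got_dels$anchor[i], del_runs[[i]][1])
      expect_equal(got_dels$length[i], del_runs[[i]][2])
    }
    # insertions: residues of 'oth' in unnumbered columns
    ins_total <- sum(is.na(num) & aln$mat["oth", ] != "-")
    expect_equal(sum(fp$length[fp$kind != "deletion"]), ins_total)
  }
})

test_that("co-invariance counts common invariant residues between groups", {
  # construction planted to the published alpha-subunit Group I/II pattern:
  # 144 columns invariant in I, 110 in II, 71 co-invariant with the same
  # residue
  set.seed(21)
  nI <- 45; nII <- 18
  n_col <- 200
  mat <- matrix("", nI + nII, n_col)
  fill_varied <- function(rows, j) {
    v <- sample(AA20, length(rows), replace = TRUE)
    while (length(unique(v)) == 1) v <- sample(AA20, length(rows),
                                               replace = TRUE)
    mat[rows, j] <<- v
  }
  both <- 1:71; onlyI <- 72:144; onlyII <- 145:183; neither <- 184:200
  for (j in both) mat[, j] <- sample(AA20, 1)
  for (j in onlyI) {
    mat[1:nI, j] <- sample(AA20, 1)
    fill_varied(nI + 1:nII, j)
  }
  for (j in onlyII) {
    fill_varied(1:nI, j)
    mat[nI + 1:nII, j] <- sample(AA20, 1)
  }
  for (j in neither) {
    fill_varied(1:nI, j)
    fill_varied(nI + 1:nII, j)
  }
  rownames(mat) <- c(paste0("I-", 1:nI), paste0("II-", 1:nII))
  aln <- make_aln(mat, c(rep("I", nI), rep("II", nII)))
  part <- group_partition(aln)
  cim <- coinvariance_matrix(aln, coaligned_columns(aln), part)
  expect_equal(cim["I", "I"], 144L)
  expect_equal(cim["II", "II"], 110L)
  expect_equal(cim["I", "II"], 71L)
  expect_equal(cim["II", "I"], 71L)
  # empty groups are undefined, not zero
  expect_true(all(is.na(cim["III", ])))
})

test_that("co-invariance is symmetric, bounded and matches the oracle", {
  tg <- tiny_groups()
  for (seed in 1:15) {
    aln <- random_alignment(length(tg$ids), 30, seed = seed,
                            alphabet = AA20[1:4])
    rownames(aln$mat) <- tg$ids
    aln <- make_aln(aln$mat, tg$labels)
    part <- group_partition(aln)
    bl <- coaligned_columns(aln)
    cim <- coinvariance_matrix(aln, bl, part)
    sub <- unclass(cim)[names(tg$sizes), names(tg$sizes)]
    expect_identical(sub, oracle_coinvariance(aln$mat, tg$labels,
                                              bl$columns))
    expect_identical(sub, t(sub))
    for (g in rownames(sub)) for (h in colnames(sub)) if (g != h)
      expect_lte(sub[g, h], min(sub[g, g], sub[h, h]))
  }
})

test_that("strong motifs are exclusive group-invariant residues", {
  tg <- tiny_groups()
  n <- length(tg$ids)
  mat <- matrix(sample(c("A", "S"), n * 10, replace = TRUE), n, 10)
  rownames(mat) <- tg$ids
  # column 2: W in all Group I rows, Y in all others (the Trp444 pattern)
  mat[, 2] <- ifelse(tg$labels == "I", "W", "Y")
  # column 5: G in all nif rows, H in Anf, L in Vnf (the alpha-69 pattern)
  mat[, 5] <- ifelse(tg$labels %in% c("I", "II", "III", "IV"), "G",
                     ifelse(tg$labels == "Anf", "H", "L"))
  # column 7: universally invariant
  mat[, 7] <- "P"
  aln <- make_aln(mat, tg$labels)
  part <- group_partition(aln)
  bl <- coaligned_columns(aln)

  mI <- strong_motifs(aln, bl, part, "I")
  expect_true(any(mI$column == 2 & mI$residue == "W"))
  expect_false(any(mI$column == 7))

  # three disjoint motifs at the same column carry different residues
  m_nif <- strong_motifs(aln, bl, part, c("I", "II", "III", "IV"))
  m_anf <- strong_motifs(aln, bl, part, "Anf")
  m_vnf <- strong_motifs(aln, bl, part, "Vnf")
  expect_equal(m_nif$residue[m_nif$column == 5], "G")
  expect_equal(m_anf$residue[m_anf$column == 5], "H")
  expect_equal(m_vnf$residue[m_vnf$column == 5], "L")

  # subset = all groups: exclusivity is vacuous, result = invariant columns
  m_all <- strong_motifs(aln, bl, part, names(tg$sizes))
  prof <- conservation_profiles(aln, bl)
  expect_identical(m_all$column, prof$column[prof$class == "invariant"])

  expect_error(strong_motifs(aln, bl, part, character(0)), "non-empty")
})

test_that("strong motifs match the definitional oracle and shrink with data", {
  tg <- tiny_groups()
  subsets <- list("I", "Anf", c("I", "II"), c("Anf", "Vnf"))
  for (seed in 1:15) {
    aln <- random_alignment(length(tg$ids), 30, seed = seed,
                            alphabet = AA20[1:3])
    rownames(aln$mat) <- tg$ids
    aln <- make_aln(aln$mat, tg$labels)
    part <- group_partition(aln)
    bl <- coaligned_columns(aln)
    for (ss in subsets) {
      got <- strong_motifs(aln, bl, part, ss)
      exp <- oracle_motifs(aln$mat, tg$labels, bl$columns, ss)
      expect_equal(got$column, exp$column)
      expect_equal(got$residue, exp$residue)
      # exclusivity re-verification straight off the matrix
      out_rows <- which(!tg$labels %in% ss)
      for (i in seq_len(nrow(got)))
        expect_false(got$residue[i] %in% aln$mat[out_rows, got$column[i]])
    }
    # adding a sequence can only shrink or preserve a group's motif set
    extra <- aln$mat[1, , drop = FALSE]
    rownames(extra) <- "Vnf-99"
    aln2 <- make_aln(rbind(aln$mat, extra), c(tg$labels, "Vnf"))
    part2 <- group_partition(aln2)
    got2 <- strong_motifs(aln2, coaligned_columns(aln2), part2, "I")
    got1 <- strong_motifs(aln, bl, part, "I")
    expect_true(all(paste(got2$column, got2$residue) %in%
                      paste(got1$column, got1$residue)))
  }
})

test_that("group assignment votes over the motif ensemble", {
  fam <- generate_family(family_spec(), seed = 3)
  aln <- fam$alignment
  rm <- build_reference_map(aln, fam$truth$reference_id)
  bl <- coaligned_columns(aln)
  part <- group_partition(aln)
  groups <- names(attr(part, "sizes"))
  motifs <- setNames(lapply(groups, function(g)
    strong_motifs(aln, bl, part, g, sec_equivalence(), rm)), groups)

  # a training-set member comes back to its own group with a full match
  a <- assign_group(aln$mat["IV-02", , drop = FALSE], motifs, rm)
  expect_equal(a$assigned, "IV")
  expect_equal(unname(a$scores["IV"]), unname(a$n_sites["IV"]))

  # mislabeled-annotation scenario: a sequence carrying Vnf motif residues
  # is assigned Vnf regardless of its metadata label
  q <- aln$mat["Vnf-04", , drop = FALSE]
  rownames(q) <- "claims-to-be-nifD"
  a2 <- assign_group(q, motifs, rm)
  expect_equal(a2$assigned, "Vnf")

  # all motif sites gapped: unassignable and flagged
  q3 <- aln$mat["I-02", , drop = FALSE]
  allsites <- unique(unlist(lapply(motifs, function(m) m$column)))
  q3[1, allsites] <- "-"
  a3 <- assign_group(q3, motifs, rm)
  expect_true(is.na(a3$assigned))
  expect_match(a3$note, "unassignable")
})
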