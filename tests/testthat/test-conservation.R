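test_that("column classification follows the conservation-class rules", {
  expect_equal(classify_column(rep("G", 95))$class, "invariant")

  # Arg/Lys split like alpha-96 (72 R, 23 K): similar pair
  p <- classify_column(c(rep("R", 72), rep("K", 23)))
  expect_equal(p$class, "single_variant_similar")
  expect_equal(p$counts, c(R = 72L, K = 23L))

  # Trp/Tyr split like alpha-444: two aromatics, still a single variant
  expect_match(classify_column(c(rep("W", 45), rep("Y", 50)))$class,
               "^single_variant")

  # one-off minority takes the outlier subtype even for a similar pair
  expect_equal(classify_column(c(rep("I", 94), "V"))$class,
               "single_variant_outlier")

  # dissimilar pair
  expect_equal(classify_column(c(rep("G", 60), rep("H", 35)))$class,
               "single_variant_dissimilar")

  expect_equal(classify_column(c(rep("A", 40), rep("S", 30),
                                 rep("T", 25)))$class, "double_variant")

  # 4 distinct with one residue above 90%
  p4 <- classify_column(c(rep("A", 90), rep("S", 3), "T", "N"))
  expect_equal(p4$class, "dominant")
  expect_equal(p4$dominant_fraction, 90 / 95, tolerance = 1e-12)

  # 4 distinct without a >90% majority
  expect_equal(classify_column(c(rep("A", 50), rep("S", 20), rep("T", 15),
                                 rep("N", 10)))$class, "variable")

  expect_error(classify_column(c("A", "-", "A")), "gap")
})

test_that("Sec merges into Cys under the equivalence map", {
  col <- c(rep("C", 92), rep("U", 3))
  expect_equal(classify_column(col)$class, "single_variant_similar")
  p <- classify_column(col, equivalences = sec_equivalence())
  expect_equal(p$class, "invariant")
  expect_equal(p$counts, c(C = 95L))

  # position-restricted equivalence only applies at its positions
  eq <- sec_equivalence(positions = 62L)
  expect_equal(classify_column(col, equivalences = eq,
                               ref_number = 62L)$class, "invariant")
  expect_match(classify_column(col, equivalences = eq,
                               ref_number = 10L)$class, "single_variant")

  # merging equivalences never increases the distinct-residue count
  for (seed in 1:25) {
    set.seed(seed)
    col <- sample(c(AA20, "U"), 40, replace = TRUE)
    k0 <- classify_column(col)$n_distinct
    k1 <- classify_column(col, equivalences = sec_equivalence())$n_distinct
    expect_lte(k1, k0)
  }
})

test_that("classification matches the rule oracle and is order-invariant", {
  simfun <- function(a, b) residues_similar(a, b)
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(c(10, 35, 95), 1)
    pool <- sample(AA20, sample(1:8, 1))
    col <- sample(pool, n, replace = TRUE)
    expect_equal(classify_column(col)$class, oracle_classify(col, simfun))
    expect_equal(classify_column(sample(col))$class,
                 classify_column(col)$class)
  }
})

test_that("the summary agrees with independent per-column classification", {
  aln <- random_alignment(20, 60, seed = 11, gap_rate = 0.05)
  bl <- coaligned_columns(aln)
  s <- summarize_conservation(aln, bl)
  expected <- vapply(bl$columns, function(j)
    oracle_classify(aln$mat[, j], function(a, b) residues_similar(a, b)),
    character(1))
  expect_equal(unname(s$class_counts),
               as.integer(table(factor(expected,
                                       levels = names(s$class_counts)))))
  # the classes partition the co-aligned columns
  expect_equal(sum(s$class_counts), bl$total_columns)
  expect_equal(s$pct_invariant,
               100 * s$n_invariant / bl$total_columns)

  # all-identical alignment: everything invariant
  ident <- make_aln(matrix("A", 5, 12,
                           dimnames = list(paste0("s", 1:5), NULL)))
  s2 <- summarize_conservation(ident, coaligned_columns(ident))
  expect_equal(s2$n_invariant, 12L)
  expect_equal(s2$pct_invariant, 100)
})

test_that("amino-acid composition reports class-defining residues", {
  mat <- cbind(matrix("R", 10, 7), matrix("K", 10, 1))
  rownames(mat) <- paste0("s", 1:10)
  aln <- make_aln(mat)
  prof <- conservation_profiles(aln, coaligned_columns(aln))
  comp <- aa_class_composition(prof)
  expect_equal(comp["invariant", "R"], 7L)
  expect_equal(comp["invariant", "K"], 1L)
  expect_equal(comp["invariant", "R"] / comp["invariant", "K"], 7)
  expect_true(all(comp["variable", ] == 0L))
  expect_error(aa_class_composition(prof[0, ]), "no profiles")
})

test_that("covariation reports joint counts and exact conditionals", {
  # planted pair: K at i always co-occurs with Y at j (the Lys96/Tyr98
  # pattern); R at i pairs with N
  n <- 40
  set.seed(5)
  ri <- sample(c("R", "K"), n, replace = TRUE, prob = c(0.7, 0.3))
  rj <- ifelse(ri == "K", "Y", "N")
  mat <- cbind(ri, rj, matrix("A", n, 3))
  rownames(mat) <- paste0("s", 1:n)
  aln <- make_aln(mat)
  rm <- build_reference_map(aln, "s1")
  bl <- coaligned_columns(aln)
  cv <- covariation(aln, bl, rm, 1L, 2L)
  expect_equal(unname(cv$conditional_ij["K", "Y"]), 1)
  expect_equal(unname(cv$conditional_ij["R", "N"]), 1)
  # joint equals brute-force pair counting; marginals match column counts
  brute <- table(i = ri, j = rj)
  expect_equal(cv$joint, brute)
  expect_equal(sum(cv$joint), n)
  expect_equal(cv$marginal_i, rowSums(brute))

  # non-coaligned column refused
  mat2 <- mat; mat2[2, 3] <- "-"
  aln2 <- make_aln(mat2)
  expect_error(covariation(aln2, coaligned_columns(aln2),
                           build_reference_map(aln2, "s1"), 1L, 3L),
               "co-aligned")
})
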