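test_that("p-distance uses pairwise deletion and hand-checks", {
  expect_equal(p_distance("ACGT", "ACGT"), list(p = 0, n_compared = 4))
  # gap column dropped: 1 mismatch over 7 compared sites
  expect_equal(p_distance("AC-TACGT", "ACGTACCT"), list(p = 1 / 7, n_compared = 7))
  expect_equal(p_distance("ANRT", "AC-T")$n_compared, 2)
  expect_error(p_distance("NN--", "ACGT"), "no comparable sites")
  expect_error(p_distance("ACG", "ACGT"), "length")
})

test_that("p-distance is a bounded symmetric premetric", {
  set.seed(11)
  for (k in 1:20) {
    a <- sample(c("A", "C", "G", "T", "N", "-"), 30, replace = TRUE)
    b <- sample(c("A", "C", "G", "T", "N", "-"), 30, replace = TRUE)
    if (!any(a %in% c("A","C","G","T") & b %in% c("A","C","G","T"))) next
    ab <- p_distance(a, b)
    expect_identical(ab, p_distance(b, a))
    expect_gte(ab$p, 0); expect_lte(ab$p, 1)
    expect_equal(p_distance(a, a)$p, 0)
  }
})

test_that("removing a non-compared column leaves (p, n_compared) unchanged", {
  a <- c("A", "N", "G", "T", "A"); b <- c("A", "C", "-", "T", "T")
  full <- p_distance(a, b)
  expect_equal(p_distance(a[-2], b[-2]), full)
  expect_equal(p_distance(a[-3], b[-3]), full)
})

test_that("distance matrix matches per-pair recomputation and an ape cross-check", {
  aln <- random_alignment(8, 60, symbols = c("A", "C", "G", "T", "-"), seed = 3)
  dm <- distance_matrix(aln)
  expect_equal(dm$p, t(dm$p))
  expect_equal(diag(dm$p), setNames(rep(0, 8), dm$ids))
  for (i in 1:7) for (j in (i + 1):8) {
    ref <- p_distance(aln$seqs[i, ], aln$seqs[j, ])
    expect_equal(dm$p[i, j], ref$p)
    expect_equal(dm$compared[i, j], ref$n_compared)
  }
  ape_d <- ape::dist.dna(ape::as.DNAbin(tolower(aln$seqs)), model = "raw",
                         pairwise.deletion = TRUE)
  expect_equal(dm$p[lower.tri(dm$p)], unclass(ape_d)[seq_along(ape_d)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a pair with no comparable sites flags NA without aborting the matrix", {
  aln <- coral_alignment(c(a = "ACGT", b = "NNNN", c = "ACGA"))
  dm <- suppressWarnings(distance_matrix(aln))
  expect_true(is.na(dm$p["a", "b"]))
  expect_equal(dm$compared["a", "b"], 0)
  expect_equal(dm$p["a", "c"], 0.25)
  one <- distance_matrix(coral_alignment(c(x = "ACGT")))
  expect_equal(one$p, matrix(0, 1, 1, dimnames = list("x", "x")))
})

test_that("ti/tv tally separates A<->G / C<->T from transversions", {
  # rows differing only by transitions: ratio undefined
  a <- coral_alignment(c(x = "AGCT", y = "GGCC"))
  t1 <- titv_tally(a)
  expect_equal(t1$transitions, 2)
  expect_equal(t1$transversions, 0)
  expect_false(t1$ratio_defined)
  expect_true(is.na(t1$ratio))

  # 4x12 toy vs naive pooled count over all pairs and sites
  aln <- random_alignment(4, 12, symbols = c("A", "C", "G", "T", "N"), seed = 21)
  got <- titv_tally(aln)
  ti <- 0L; tv <- 0L
  for (i in 1:3) for (j in (i + 1):4) for (s in 1:12) {
    x <- aln$seqs[i, s]; y <- aln$seqs[j, s]
    if (!all(c(x, y) %in% c("A", "C", "G", "T")) || x == y) next
    if (paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")) ti <- ti + 1L
    else tv <- tv + 1L
  }
  expect_equal(got$transitions, ti)
  expect_equal(got$transversions, tv)
  expect_equal(got$ratio, ti / tv)
})

test_that("group distance extrema are attained matrix entries that bracket all pairs", {
  # 2 groups of 2 with hand-set sequences
  aln <- coral_alignment(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAC",
                           b1 = "GGGGGAAAAA", b2 = "GGGGGAAAAC"))
  dm <- distance_matrix(aln)
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gs <- group_distance_summary(dm, labels)
  expect_equal(gs$intra$max_p, c(0.1, 0.1))
  expect_equal(gs$inter$min_p, 0.5)
  expect_setequal(c(gs$inter$id_a, gs$inter$id_b)[1:2], c("a1", "b1"))

  aln2 <- random_alignment(9, 50, seed = 31)
  dm2 <- distance_matrix(aln2)
  lab2 <- setNames(rep(c("g1", "g2", "g3"), each = 3), dm2$ids)
  gs2 <- group_distance_summary(dm2, lab2)
  for (r in seq_len(nrow(gs2$intra))) {
    g <- gs2$intra$group[r]
    ids <- names(lab2)[lab2 == g]
    expect_equal(gs2$intra$max_p[r], max(dm2$p[ids, ids]))
    expect_equal(dm2$p[gs2$intra$id_a[r], gs2$intra$id_b[r]], gs2$intra$max_p[r])
  }
  for (r in seq_len(nrow(gs2$inter))) {
    ia <- names(lab2)[lab2 == gs2$inter$group_a[r]]
    ib <- names(lab2)[lab2 == gs2$inter$group_b[r]]
    expect_equal(gs2$inter$min_p[r], min(dm2$p[ia, ib]))
  }
  # single group: no inter section
  gs3 <- group_distance_summary(dm2, setNames(rep("g", 9), dm2$ids))
  expect_equal(nrow(gs3$inter), 0)
  expect_error(group_distance_summary(dm2, lab2[-1]), "unlabeled")
})

test_that("delimitation verdicts follow the two-threshold rule", {
  th <- delimitation_thresholds()
  expect_equal(th$intra_max, 0.049)
  expect_equal(th$inter_min, 0.038)
  expect_equal(assess_rank_delimitation(c(0, 0, 0)), "within_family")
  # candidate within 3.4% of the family: below the inter-family minimum
  expect_equal(assess_rank_delimitation(c(0.021, 0.034)), "within_family")
  # candidate at least 6.7% away: beyond the intra-family maximum
  expect_equal(assess_rank_delimitation(c(0.067, 0.101)), "distinct_family")
  expect_equal(assess_rank_delimitation(c(0.042)), "ambiguous")
  expect_equal(assess_rank_delimitation(c(0.01, 0.09)), "ambiguous")
  expect_error(assess_rank_delimitation(numeric(0)), "nonempty")
})

test_that("scaling distances up never moves a verdict back toward within_family", {
  rank_of <- c(within_family = 1, ambiguous = 2, distinct_family = 3)
  set.seed(5)
  for (k in 1:30) {
    d <- runif(4, 0, 0.08)
    v1 <- rank_of[[assess_rank_delimitation(d)]]
    v2 <- rank_of[[assess_rank_delimitation(d * 1.5)]]
    expect_gte(v2, v1)
  }
})
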