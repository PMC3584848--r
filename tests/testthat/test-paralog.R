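# paralog detection, guide trees, Tree Score, Taxonomy Balance and
# amplification ratios

test_that("paralog clusters need at least two proteins of the species", {
  mr <- fake_mapping(sprintf("p%02d", 1:18), "mapped",
                     map_cluster = c(rep(1L, 12), 2L, rep(3L, 2),
                                     rep(4L, 3)),
                     map_score = 0,
                     root = c(rep(10L, 12), 20L, rep(20L, 2),
                              rep(30L, 3)))
  par <- find_paralogs(mr)
  # the singleton-mapped cluster 2 is excluded
  expect_setequal(par$cluster, c(1L, 3L, 4L))
  expect_equal(par$count[par$cluster == 1], 12L)
  expect_equal(attr(par, "n_ge_bucket1"), 1L)  # the 12-copy cluster
  expect_equal(attr(par, "n_gt_bucket2"), 0L)
  # root level aggregation merges clusters 2 and 3
  par_root <- find_paralogs(mr, level = "root")
  expect_equal(par_root$count[par_root$cluster == 20], 3L)
  # species filter
  sp <- setNames(rep(c("a", "b"), 9), sprintf("p%02d", 1:18))
  par_a <- find_paralogs(mr, species_of = sp, species = "a")
  expect_equal(par_a$count[par_a$cluster == 1], 6L)
})

test_that("guide trees reproduce known topologies deterministically", {
  # two leaves: a single cherry
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  t2 <- build_guide_tree(d2)
  expect_s3_class(t2, "phylo")
  expect_equal(sort(t2$tip.label), c("a", "b"))

  # ultrametric 4-taxon matrix: the unique topology (((A,B),C),D)
  ids <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 2, 4, 6,
                 2, 0, 4, 6,
                 4, 4, 0, 6,
                 6, 6, 6, 0), 4, 4, dimnames = list(ids, ids))
  t4 <- build_guide_tree(d4)
  tsets <- phylo_tipsets(t4)
  expect_true(any(vapply(tsets, setequal, logical(1), y = c("A", "B"))))
  expect_true(any(vapply(tsets, setequal, logical(1),
                         y = c("A", "B", "C"))))
  expect_true(ape::is.binary(t4))

  # all-equal distances: topology fully determined by the id tie-break
  de <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(de) <- 0
  te1 <- build_guide_tree(de)
  te2 <- build_guide_tree(de)
  expect_identical(ape::write.tree(te1), ape::write.tree(te2))
  tsets_e <- phylo_tipsets(te1)
  # lowest pairs first: {A,B} and {C,D} cherries
  expect_true(any(vapply(tsets_e, setequal, logical(1), y = c("A", "B"))))
  expect_true(any(vapply(tsets_e, setequal, logical(1), y = c("C", "D"))))

  expect_error(build_guide_tree(d2[1, 1, drop = FALSE]), ">= 2")
  bad <- d2; bad[1, 2] <- 5
  expect_error(build_guide_tree(bad), "not symmetric")
})

test_that("tree score is the LCA-clade ratio", {
  # all leaves of interest: the whole tree is the minimal clade
  gc <- gen_guide_case(4, 0, intermix = FALSE, seed = 1)
  expect_equal(tree_score(gc$tree, gc$interest)$ts, 1.0)
  # a single protein of interest is its own subtree
  gc2 <- gen_guide_case(1, 5, intermix = FALSE, seed = 1)
  expect_equal(tree_score(gc2$tree, "I1")$ts, 1.0)
  # 3 proteins of interest scattered over 9 leaves: TS = 3/9
  gc3 <- gen_guide_case(3, 6, intermix = TRUE, seed = 1)
  res <- tree_score(gc3$tree, gc3$interest)
  expect_equal(res$ts, 1 / 3)
  expect_equal(res$d_count, 3L)
  expect_equal(res$min_subtree_leaves, 9L)
  expect_error(tree_score(gc3$tree, "Z9"), "absent|unknown")
})

test_that("tree score equals the exhaustive clade oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n)
    interest <- sample(phy$tip.label, sample(1:n, 1))
    res <- tree_score(phy, interest)
    expect_equal(res$ts, oracle_tree_score(phy, interest))
    expect_true(res$ts > 0 && res$ts <= 1)
    expect_equal(res$ts == 1, forms_clade(phy, interest))
  }
})

test_that("taxonomy balance measures per-root imbalance", {
  occ <- data.frame(root = 1:4,
                    daphnia = c(7L, 20L, 1L, 5L),
                    fly = c(7L, 1L, 10L, 0L))
  tb <- taxonomy_balance(occ, "daphnia", "fly")
  expect_equal(tb$tb[tb$root == 1], 1)
  expect_equal(tb$log2_tb[tb$root == 1], 0)
  expect_equal(tb$tb[tb$root == 2], 20)
  expect_true(tb$extreme_high[tb$root == 2])
  expect_true(tb$extreme_low[tb$root == 3])
  # the fly-absent root is undefined, not zero or infinite
  expect_false(4 %in% tb$root)
  expect_equal(attr(tb, "n_undefined"), 1L)
  # inversion identity: swapping species swaps the exact integer counts,
  # so the ratios invert (to within one ulp of the two divisions)
  tb_rev <- taxonomy_balance(occ, "fly", "daphnia")
  expect_identical(tb_rev$count_a, tb$count_b)
  expect_identical(tb_rev$count_b, tb$count_a)
  expect_equal(tb$tb * tb_rev$tb, rep(1, nrow(tb)), tolerance = 1e-14)
})

test_that("amplification ratios match the published worked examples", {
  expect_equal(amplification_ratio(498, 364), 1.37)
  expect_equal(amplification_ratio(169, 5), 33.80)
  expect_equal(amplification_ratio(114, 2), 57.00)
  expect_error(amplification_ratio(10, 0), "zero mapped clusters")
  expect_error(amplification_ratio(0, 1), ">= 1 mapped protein")
})

test_that("amplification tables always report ratios of at least one", {
  mr <- fake_mapping(sprintf("p%02d", 1:10), "mapped",
                     map_cluster = c(1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L, 4L,
                                     5L),
                     map_score = 0,
                     root = c(rep(10L, 5), rep(20L, 4), 30L))
  amp <- amplification_table(mr)
  expect_equal(amp$root, c(10L, 20L, 30L))       # sorted by count
  expect_equal(amp$n_proteins, c(5L, 4L, 1L))
  expect_equal(amp$n_map_clusters, c(2L, 2L, 1L))
  expect_equal(amp$ratio, c(2.5, 2, 1))
  expect_true(all(amp$ratio >= 1))
})

test_that("ts summaries stratify by paralog count", {
  s <- ts_summary(rep(1.0, 6), c(2, 2, 5, 5, 12, 30))
  expect_equal(unname(s$histogram[, "(0.9,1]"]), c(2L, 2L, 2L))
  expect_equal(sum(s$histogram), 6L)
  expect_equal(s$fraction_below_cutoff, 0)
  # planted pure clades sit at TS 1; intermixed mass falls below 0.2
  pure <- vapply(1:5, function(i) {
    gc <- gen_guide_case(10, 4, intermix = FALSE, seed = i)
    tree_score(gc$tree, gc$interest)$ts
  }, numeric(1))
  mixed <- vapply(1:5, function(i) {
    gc <- gen_guide_case(2, 12, intermix = TRUE, seed = i)
    tree_score(gc$tree, gc$interest)$ts
  }, numeric(1))
  expect_true(all(pure == 1))
  expect_true(all(mixed < 0.2))
  s2 <- ts_summary(c(pure, mixed), c(rep(10, 5), rep(2, 5)))
  expect_equal(s2$fraction_below_cutoff, 0.5)
})
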