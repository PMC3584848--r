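# term scoring (Correspondence Score, specificity), ProtoName selection
# and annotation transfer

# one planted family of 5 plus 5 cap-distant singles, so node 14 is the
# family cluster {P00001..P00005} and the universe has 10 proteins
family_fixture <- function(seed = 2) {
  g <- gen_similarity(synth_spec(n_families = 1,
                                 family_size_range = c(5, 5),
                                 orphan_fraction = 0.5), seed = seed)
  tr <- build_tree(g$matrix)
  fam_node <- tr$nodes$node_id[tr$nodes$size == 5 &
                                 tr$nodes$node_id > tr$n_leaves][1]
  list(tree = tr, truth = g$truth, fam_node = fam_node)
}

db_of <- function(...) {
  rows <- list(...)
  annotation_db(do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r$p, source = r$src, term_id = r$t,
               term_label = r$lab, stringsAsFactors = FALSE)
  })))
}

test_that("correspondence score is intersection over union", {
  expect_identical(correspondence_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(correspondence_score(c("a", "b", "c", "d"),
                                    c("c", "d", "e")), 0.4)
  expect_identical(correspondence_score(c("a", "b"), c("x", "y")), 0)
  expect_error(correspondence_score(character(0), "a"), "empty cluster")
  # carriers outside the declared universe are ignored
  expect_identical(correspondence_score(c("a", "b"), c("a", "b", "z"),
                                        universe = c("a", "b")), 1)
})

test_that("correspondence score shrinks as the term grows outside", {
  cluster <- paste0("c", 1:6)
  outside <- paste0("x", 1:10)
  cs <- vapply(0:10, function(k) {
    correspondence_score(cluster, c(cluster[1:4], outside[seq_len(k)]))
  }, numeric(1))
  expect_true(all(diff(cs) <= 0))
  expect_true(all(cs >= 0 & cs <= 1))
})

test_that("specificity is the annotated fraction of the cluster", {
  expect_identical(cluster_specificity(c("a", "b"), c("a", "b", "z")), 1)
  expect_equal(cluster_specificity(paste0("p", 1:5), "p1"), 0.2)
  expect_error(cluster_specificity(character(0), "a"), "empty cluster")
})

test_that("generator purity is reflected in planted-term specificity", {
  spec <- synth_spec(n_families = 1, family_size_range = c(20, 20),
                     annotation_purity = 0.8)
  g <- gen_similarity(spec, seed = 4)
  db <- gen_annotations(g$truth, spec, seed = 4)
  members <- g$truth$protein$id
  carriers <- db$protein_id[db$term_id == "T001"]
  sp <- cluster_specificity(members, carriers)
  expect_equal(sp, length(carriers) / 20)
  # within 4 binomial standard errors of the planted purity
  expect_lt(abs(sp - 0.8), 4 * sqrt(0.8 * 0.2 / 20))
})

test_that("protoname applies the size filter and per-source CS ranking", {
  fx <- family_fixture()
  fam <- cluster_members(fx$tree, fx$fam_node)
  # a size-4 sub-cluster is below the minimum size
  sub4 <- fx$tree$nodes$node_id[fx$tree$nodes$size == 4][1]
  db <- db_of(list(p = fam, src = "GO", t = "T1", lab = "kinase"))
  expect_null(protoname(fx$tree, sub4, db))
  # the family node is named with the planted term
  pn <- protoname(fx$tree, fx$fam_node, db)
  expect_equal(pn$term_id, "T1")
  expect_equal(pn$cs, 1)
  expect_equal(pn$specificity, 1)
  expect_equal(attr(pn, "composed"), "kinase")
})

test_that("blacklisted labels are never selected", {
  fx <- family_fixture()
  fam <- cluster_members(fx$tree, fx$fam_node)
  db <- db_of(
    list(p = fam, src = "Keyword", t = "K1", lab = "Complete Proteome"),
    list(p = fam[1:2], src = "Keyword", t = "K2", lab = "transporter"))
  # the perfect-CS blacklisted term is gone; the weaker real term wins
  pn <- protoname(fx$tree, fx$fam_node, db)
  expect_equal(pn$term_id, "K2")
  expect_false(any(grepl("proteome", db$term_label, ignore.case = TRUE)))
})

test_that("CS ties break toward the larger intersection", {
  fx <- family_fixture()
  fam <- cluster_members(fx$tree, fx$fam_node)
  other <- setdiff(fx$tree$ids, fam)
  # A: 2 of 5 members, no outsiders -> cs 2/5; B: 4 members + 5
  # outsiders -> cs 4/10 = 2/5, bigger intersection
  db <- db_of(
    list(p = fam[1:2], src = "GO", t = "A", lab = "term a"),
    list(p = c(fam[1:4], other), src = "GO", t = "B", lab = "term b"))
  pn <- protoname(fx$tree, fx$fam_node, db)
  expect_equal(pn$cs, 0.4)
  expect_equal(pn$term_id, "B")
  expect_equal(pn$n_intersect, 4L)
})

test_that("specificity filters terms before CS ranking", {
  fx <- family_fixture()
  fam <- cluster_members(fx$tree, fx$fam_node)
  # 1 of 5 members: specificity 0.2 passes; nothing below does
  db <- db_of(list(p = fam[1], src = "GO", t = "S", lab = "edge"))
  expect_equal(protoname(fx$tree, fx$fam_node, db)$term_id, "S")
  pn_strict <- protoname(fx$tree, fx$fam_node, db, min_spec = 0.21)
  expect_null(pn_strict)
})

test_that("annotation transfer reaches mapped proteins and skips others", {
  fx <- family_fixture()
  fam <- cluster_members(fx$tree, fx$fam_node)
  db <- db_of(list(p = fam, src = "GO", t = "T1", lab = "kinase"))
  plr <- family_pl_root(fx$tree, fx$truth)
  g <- gen_similarity(synth_spec(n_families = 1,
                                 family_size_range = c(5, 5),
                                 orphan_fraction = 0.5), seed = 2)
  mr <- map_proteome(g$matrix, fx$tree,
                     params = stability_params(lt_min = 1, pl_root = plr))
  md <- mr$mapping
  # family members map below the family node; their map cluster itself
  # is too small to be named, but the family root names them
  inf <- infer_protein_annotations(mr, fx$tree, db)
  expect_setequal(unique(inf$protein_id), fam)
  expect_true(all(inf$term_id == "T1"))
  una <- attr(inf, "unannotated")
  expect_setequal(una$protein_id, setdiff(md$protein_id, fam))
  # orphan singles are unmapped, flagged with their status
  expect_true(all(una$status %in% c("unmapped", "excluded", "mapped")))
})

test_that("annotation summary degenerates gracefully", {
  fx <- family_fixture()
  plr <- family_pl_root(fx$tree, fx$truth)
  g <- gen_similarity(synth_spec(n_families = 1,
                                 family_size_range = c(5, 5),
                                 orphan_fraction = 0.5), seed = 2)
  mr <- map_proteome(g$matrix, fx$tree,
                     params = stability_params(lt_min = 1, pl_root = plr))
  empty <- annotation_db(data.frame(protein_id = character(),
                                    source = character(),
                                    term_id = character(),
                                    term_label = character()))
  sm <- annotation_summary(mr, fx$tree, empty)
  expect_equal(sm$fraction_roots_named, 0)
  expect_equal(sm$fraction_proteins_annotated, 0)
  expect_equal(sm$mean_terms_per_root, 0)

  fam <- cluster_members(fx$tree, fx$fam_node)
  db <- db_of(list(p = fam, src = "GO", t = "T1", lab = "kinase"))
  sm2 <- annotation_summary(mr, fx$tree, db)
  expect_true(sm2$fraction_roots_named > 0)
  expect_equal(unname(sm2$source_shares["GO"]), 1)
})

test_that("annotation tables round-trip and drop blacklisted rows", {
  d <- data.frame(
    protein_id = c("p1", "p2", "p2", "p3"),
    source = c("GO", "GO", "GO", "Keyword"),
    term_id = c("T1", "T1", "T1", "K9"),
    term_label = c("kinase", "kinase", "kinase", "Hypothetical Protein"),
    stringsAsFactors = FALSE)
  db <- annotation_db(d)
  expect_equal(nrow(db), 2L)  # duplicate and blacklisted rows removed
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(db, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(db))
})
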