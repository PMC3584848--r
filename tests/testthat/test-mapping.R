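# mapping queries onto a frozen tree and the taxonomic Venn partition

# two planted families of sizes 5 and 8 over a cap background
two_family_tree <- function() {
  sizes <- c(5, 8)
  ids <- sprintf("t%02d", seq_len(sum(sizes)))
  fam <- rep(1:2, sizes)
  E <- matrix(100, 13, 13, dimnames = list(ids, ids))
  for (f in 1:2) {
    idx <- which(fam == f)
    E[idx, idx] <- 1e-25
  }
  m <- sim_matrix(E)
  list(tree = build_tree(m), fam = fam, ids = ids)
}

test_that("the minimal-sized eligible stable cluster wins", {
  tt <- two_family_tree()
  # force the two full family nodes as the stable set
  fams <- which(tt$tree$nodes$size %in% c(5, 8) &
                  tt$tree$nodes$node_id > tt$tree$n_leaves)
  stable <- tt$tree$nodes$node_id[fams]
  # query close to every tree protein: both families eligible
  scores <- setNames(rep(1e-20, 13), tt$ids)
  hit <- map_protein(scores, tt$tree, stable)
  expect_equal(tt$tree$nodes$size[hit$node], 5L)
  # score-first ordering flips the choice when the bigger family is closer
  scores2 <- setNames(ifelse(tt$fam == 2, 1e-30, 1e-20), tt$ids)
  expect_equal(tt$tree$nodes$size[
    map_protein(scores2, tt$tree, stable, prefer = "score")$node], 8L)
})

test_that("cap-level queries stay unmapped and empty stable sets error", {
  tt <- two_family_tree()
  scores <- setNames(rep(100, 13), tt$ids)
  st <- stable_clusters(tt$tree, stability_params(lt_min = 1))
  hit <- map_protein(scores, tt$tree, st, tau_map = 1)
  expect_true(is.na(hit$node))
  expect_error(map_protein(scores, tt$tree, integer(0)), "empty stable")
})

test_that("self-consistent queries map into their planted family", {
  g <- gen_similarity(synth_spec(n_families = 5,
                                 family_size_range = c(5, 8)), seed = 21)
  tr <- build_tree(g$matrix)
  st <- stable_clusters(tr, stability_params(lt_min = 1))
  prot <- g$truth$protein
  for (pid in prot$id[c(1, 10, 20)]) {
    hit <- map_protein(unclass(g$matrix)[pid, ], tr, st)
    mem <- cluster_members(tr, hit$node)
    expect_true(all(prot$family[match(mem, prot$id)] ==
                      prot$family[prot$id == pid]))
  }
})

test_that("proteome mapping is deterministic byte-for-byte", {
  g <- gen_similarity(synth_spec(n_families = 19,
                                 family_size_range = c(4, 6),
                                 orphan_fraction = 0.05), seed = 5)
  tr <- build_tree(g$matrix)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_mapping(map_proteome(g$matrix, tr), f1)
  write_mapping(map_proteome(g$matrix, tr), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("orphan queries surface as the unmapped fraction", {
  g <- gen_similarity(synth_spec(n_families = 19,
                                 family_size_range = c(8, 12),
                                 orphan_fraction = 0.05), seed = 8)
  orph <- g$truth$orphans
  core <- setdiff(g$truth$protein$id, orph)
  E <- unclass(g$matrix)
  # freeze a tree over the core proteins; orphans are pure queries that
  # share nothing with it
  tr <- build_tree(sim_matrix(E[core, core]))
  st <- stable_clusters(tr, stability_params(lt_min = 1))
  mr <- map_proteome(E[, core], tr, tau_map = 1, stable = st)
  md <- mr$mapping
  expect_true(all(md$status[md$protein_id %in% orph] == "unmapped"))
  expect_true(all(md$status[!md$protein_id %in% orph] != "unmapped"))
  expect_equal(mr$summary$fractions[["unmapped"]],
               length(orph) / nrow(md))
})

test_that("tightening the eligibility threshold never maps more proteins", {
  g <- gen_similarity(synth_spec(n_families = 6,
                                 family_size_range = c(4, 8)), seed = 13)
  tr <- build_tree(g$matrix)
  st <- stable_clusters(tr, stability_params(lt_min = 1))
  Q <- unclass(g$matrix)
  diag(Q) <- 100
  mapped_at <- function(tau) {
    md <- map_proteome(Q, tr, tau_map = tau, stable = st)$mapping
    md$protein_id[md$status != "unmapped"]
  }
  m1 <- mapped_at(1); m2 <- mapped_at(1e-15); m3 <- mapped_at(1e-35)
  expect_true(all(m2 %in% m1))
  expect_true(all(m3 %in% m2))
})

test_that("venn regions follow root co-occupancy", {
  # roots: 1 only A; 2 all three; 3 A+B
  mk <- function(ids, roots) {
    fake_mapping(ids, "mapped", map_cluster = roots, map_score = 0,
                 root = roots)
  }
  maps <- list(
    A = mk(c("a1", "a2", "a3"), c(1L, 2L, 3L)),
    B = mk(c("b1", "b2"), c(2L, 3L)),
    C = mk("c1", 2L))
  vp <- venn_partition(maps)
  rg <- vp$regions
  expect_equal(vp$n_roots_total, 3L)
  expect_equal(sum(rg$n_roots), 3L)
  expect_equal(rg$n_roots[rg$region == "A"], 1L)
  expect_equal(rg$n_roots[rg$region == "A+B"], 1L)
  expect_equal(rg$n_roots[rg$region == "A+B+C"], 1L)
  expect_equal(rg$proteins_A[rg$region == "A"], 1L)
  expect_equal(rg$proteins_B[rg$region == "A+B"], 1L)
  # per-species protein totals match the mapped counts
  expect_equal(sum(rg$proteins_A), 3L)
  expect_equal(sum(rg$proteins_B), 2L)
  expect_equal(sum(rg$proteins_C), 1L)

  # degenerate case: every root carries all three species
  all3 <- list(A = mk("a1", 7L), B = mk("b1", 7L), C = mk("c1", 7L))
  rg3 <- venn_partition(all3)$regions
  expect_equal(rg3$n_roots[rg3$region == "A+B+C"], 1L)
  expect_equal(sum(rg3$n_roots), 1L)

  expect_error(venn_partition(maps[1:2]), "exactly 3")
  expect_silent(venn_partition(maps[1:2], require_three = FALSE))
})

test_that("venn counts recover the planted species occupancy", {
  spec <- synth_spec(n_families = 19, family_size_range = c(4, 8))
  g <- gen_similarity(spec, seed = 17)
  tr <- build_tree(g$matrix)
  plr <- family_pl_root(tr, g$truth)
  prot <- g$truth$protein
  mr <- map_proteome(g$matrix, tr,
                     params = stability_params(pl_root = plr))
  # with the family-level ceiling every protein's root is its family node
  species_of <- setNames(prot$species, prot$id)
  per_sp <- lapply(spec$species, function(s) {
    sub <- mr$mapping[species_of[mr$mapping$protein_id] == s, ,
                      drop = FALSE]
    fake_mapping(sub$protein_id, sub$status, sub$map_cluster,
                 sub$map_score, sub$root)
  })
  names(per_sp) <- spec$species
  vp <- venn_partition(per_sp, spec$species)
  # expected from truth: region of a family = species with count >= 1
  cnt <- g$truth$species_counts
  region_of <- apply(cnt > 0, 1, function(r) {
    paste(spec$species[r], collapse = "+")
  })
  for (rg in vp$regions$region) {
    expect_equal(vp$regions$n_roots[vp$regions$region == rg],
                 sum(region_of == rg), info = rg)
    for (s in spec$species) {
      expect_equal(
        vp$regions[[paste0("proteins_", s)]][vp$regions$region == rg],
        sum(cnt[region_of == rg, s]), info = paste(rg, s))
    }
  }
})
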