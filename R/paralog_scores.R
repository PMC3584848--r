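# Paralog detection and the divergence / imbalance statistics computed on
# paralog-bearing clusters: Tree Score, Taxonomy Balance, amplification
# ratio.

#' Clusters carrying paralogs
#'
#' A cluster carries paralogs when at least `min_count` proteins of the
#' subject species map into it (default 2). Counts are reported per map
#' cluster or per family root, together with the standard expansion
#' buckets (clusters with >= 10 and with > 20 paralogs).
#'
#' @param mapping a `mapping_result`.
#' @param species_of optional named character vector giving each
#'   protein's species; with `species` set, only proteins of that species
#'   are counted.
#' @param species subject species (requires `species_of`).
#' @param min_count paralog threshold (default 2).
#' @param level `"map"` (stable map clusters) or `"root"` (family roots).
#' @param buckets thresholds of the two expansion buckets.
#' @return a data frame (`cluster`, `count`) sorted by decreasing count,
#'   with attributes `n_ge_bucket1` and `n_gt_bucket2`.
#' @export
find_paralogs <- function(mapping, species_of = NULL, species = NULL,
                          min_count = 2, level = c("map", "root"),
                          buckets = c(10, 20)) {
  stopifnot(inherits(mapping, "mapping_result"))
  level <- match.arg(level)
  md <- mapping$mapping
  md <- md[md$status == "mapped", , drop = FALSE]
  if (!is.null(species)) {
    if (is.null(species_of)) stop("species filter requires species_of")
    md <- md[species_of[md$protein_id] %in% species, , drop = FALSE]
  }
  key <- if (level == "map") md$map_cluster else md$root
  tt <- table(key)
  out <- data.frame(cluster = as.integer(names(tt)),
                    count = as.integer(tt))
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(-out$count, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ge_bucket1") <- sum(out$count >= buckets[1])
  attr(out, "n_gt_bucket2") <- sum(out$count > buckets[2])
  out
}

#' UPGMA guide tree over one cluster's proteins
#'
#' Average-linkage (UPGMA) agglomeration of a symmetric distance matrix
#' with the same deterministic tie-break as the main merge tree (lowest
#' node-id pair first); node heights are half the merge distance.
#'
#' @param d symmetric, non-negative distance matrix with zero diagonal
#'   and protein ids as dimnames; at least 2 proteins.
#' @return a rooted binary `phylo` tree (ape).
#' @export
build_guide_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L) stop("guide tree needs >= 2 proteins")
  if (any(d != t(d))) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) stop("distance matrix needs dimnames")
  tr <- build_tree(d, stability_params(merge_cutoff = Inf))
  as.phylo.merge_tree(tr)
}

#' Convert a merge tree to an ape phylo object
#'
#' Requires a fully merged tree (single root). Branch lengths derive
#' from ultrametric node heights at half the merge score (UPGMA
#' convention), clamped at zero.
#'
#' @param x a `merge_tree` with a single root.
#' @param ... unused.
#' @return a `phylo` object.
#' @exportS3Method ape::as.phylo
as.phylo.merge_tree <- function(x, ...) {
  n <- x$n_leaves
  if (x$n_merges != n - 1L) stop("tree is a forest; cannot convert to phylo")
  # merge step i -> phylo internal node n + (n_merges - i + 1), root = n + 1
  renum <- function(id) {
    ifelse(id <= n, id, n + (x$n_merges - (id - n) + 1L))
  }
  height <- c(rep(0, n), x$merge_log$score / 2)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (i in seq_len(x$n_merges)) {
    pid <- n + i
    for (ch in c(x$nodes$child1[pid], x$nodes$child2[pid])) {
      r <- r + 1L
      edge[r, ] <- c(renum(pid), renum(ch))
      elen[r] <- max(height[pid] - height[ch], 0)
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = x$ids, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Tree Score: clade isolation of the species of interest
#'
#' For a guide tree T and the set D of leaves belonging to the species
#' of interest, the Tree Score is `|D|` divided by the number of leaves
#' of the smallest rooted clade (subtree) containing all of D, i.e. the
#' clade rooted at the lowest common ancestor of D. TS = 1 means the
#' species' proteins form a pure clade (low divergence from each other);
#' small values mean they intermix with the other proteins.
#'
#' @param phy a rooted binary `phylo` guide tree.
#' @param interest tip labels of the species of interest (>= 1 present).
#' @return a list (`d_count`, `min_subtree_leaves`, `ts`).
#' @export
tree_score <- function(phy, interest) {
  stopifnot(inherits(phy, "phylo"))
  interest <- unique(interest)
  d <- interest[interest %in% phy$tip.label]
  if (length(d) == 0L) stop("species of interest absent from the tree")
  if (length(setdiff(interest, d)) > 0L) {
    stop("unknown tip label(s): ",
         paste(setdiff(interest, d), collapse = ", "))
  }
  if (length(d) == 1L) {
    return(list(d_count = 1L, min_subtree_leaves = 1L, ts = 1.0))
  }
  if (length(d) == length(phy$tip.label)) {
    nl <- length(phy$tip.label)
    return(list(d_count = nl, min_subtree_leaves = nl, ts = 1.0))
  }
  mrca <- ape::getMRCA(phy, d)
  clade <- ape::extract.clade(phy, mrca)$tip.label
  list(d_count = length(d), min_subtree_leaves = length(clade),
       ts = length(d) / length(clade))
}

#' Species occupancy of family roots
#'
#' Counts, per occupied family root, how many mapped proteins of each
#' species it contains.
#'
#' @param mapping a `mapping_result` over a (possibly multi-species)
#'   proteome.
#' @param species_of named character vector: species of each protein.
#' @return a data frame with a `root` column and one count column per
#'   species.
#' @export
root_species_counts <- function(mapping, species_of) {
  stopifnot(inherits(mapping, "mapping_result"))
  md <- mapping$mapping
  md <- md[md$status == "mapped", , drop = FALSE]
  sp <- species_of[md$protein_id]
  tt <- table(md$root, sp)
  out <- data.frame(root = as.integer(rownames(tt)))
  for (s in colnames(tt)) out[[s]] <- as.integer(tt[, s])
  out
}

#' Taxonomy Balance between two proteomes
#'
#' Within each shared family root, the ratio of the subject species'
#' protein count to the reference species' count. Only roots containing
#' at least one protein from each species are defined; the rest are
#' counted in the `n_undefined` attribute. Extreme lists use the default
#' thresholds TB >= 10 and TB <= 0.1.
#'
#' @param occupancy output of [root_species_counts()].
#' @param species_a,species_b subject and reference species (column
#'   names of `occupancy`).
#' @param extremes `c(high, low)` thresholds for the extreme flags.
#' @return a data frame (`root`, `count_a`, `count_b`, `tb`, `log2_tb`,
#'   `extreme_high`, `extreme_low`) with attribute `n_undefined`.
#' @export
taxonomy_balance <- function(occupancy, species_a, species_b,
                             extremes = c(10, 0.1)) {
  stopifnot(all(c("root", species_a, species_b) %in% names(occupancy)))
  ca <- occupancy[[species_a]]
  cb <- occupancy[[species_b]]
  ok <- ca >= 1 & cb >= 1
  tb <- ca[ok] / cb[ok]
  out <- data.frame(root = occupancy$root[ok],
                    count_a = ca[ok], count_b = cb[ok],
                    tb = tb, log2_tb = log2(tb),
                    extreme_high = tb >= extremes[1],
                    extreme_low = tb <= extremes[2])
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(!ok)
  out
}

# decimal round-half-up; the tiny guard absorbs binary representation of
# exact decimal .5 boundaries (e.g. 1.005 stored as 1.00499..)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-7) / p
}

#' Amplification ratio of a family root
#'
#' The number of the species' proteins mapped under a family root
#' divided by the number of distinct stable map clusters they occupy,
#' reported rounded half-up to two decimals. High values flag recent,
#' low-divergence duplication blocks (many paralogs in few stable
#' clusters); the ratio is always >= 1.
#'
#' @param n_proteins protein count(s) under the root(s).
#' @param n_clusters distinct stable map cluster count(s); must be >= 1.
#' @return the ratio(s), rounded half-up to 2 decimals.
#' @export
amplification_ratio <- function(n_proteins, n_clusters) {
  if (any(n_clusters < 1)) {
    stop("undefined amplification ratio: zero mapped clusters")
  }
  if (any(n_proteins < 1)) stop("roots must contain >= 1 mapped protein")
  .round_half_up(n_proteins / n_clusters, 2)
}

#' Per-root amplification table
#'
#' Computes, for every occupied family root, the number of mapped
#' proteins, the number of distinct map clusters, and their
#' [amplification_ratio()]; sorted by descending protein count.
#'
#' @param mapping a `mapping_result`.
#' @param species_of,species optional species restriction as in
#'   [find_paralogs()].
#' @return a data frame (`root`, `n_proteins`, `n_map_clusters`,
#'   `ratio`).
#' @export
amplification_table <- function(mapping, species_of = NULL,
                                species = NULL) {
  stopifnot(inherits(mapping, "mapping_result"))
  md <- mapping$mapping
  md <- md[md$status == "mapped", , drop = FALSE]
  if (!is.null(species)) {
    if (is.null(species_of)) stop("species filter requires species_of")
    md <- md[species_of[md$protein_id] %in% species, , drop = FALSE]
  }
  if (nrow(md) == 0L) {
    return(data.frame(root = integer(), n_proteins = integer(),
                      n_map_clusters = integer(), ratio = numeric()))
  }
  sp <- split(md, md$root)
  out <- data.frame(
    root = as.integer(names(sp)),
    n_proteins = vapply(sp, nrow, integer(1)),
    n_map_clusters = vapply(sp, function(g) {
      length(unique(g$map_cluster))
    }, integer(1))
  )
  out$ratio <- amplification_ratio(out$n_proteins, out$n_map_clusters)
  out <- out[order(-out$n_proteins, out$root), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tree Score histogram by paralog stratum
#'
#' Bins Tree Scores into intervals of width `bin_width` over (0, 1],
#' stratified by paralog count (default strata: exactly 2, 3-9, >= 10),
#' and reports the fraction of clusters in the high-divergence regime
#' (TS below `divergence_cutoff`).
#'
#' @param ts numeric Tree Scores in (0, 1].
#' @param n_paralogs paralog counts, parallel to `ts`.
#' @param strata `c(a, b)`: stratum boundaries (exactly `a`; `a+1..b`;
#'   `> b`).
#' @param bin_width histogram bin width.
#' @param divergence_cutoff high-divergence threshold (default 0.2).
#' @return a list (`histogram` count matrix strata x bins,
#'   `fraction_below_cutoff`, `n`).
#' @export
ts_summary <- function(ts, n_paralogs, strata = c(2, 9), bin_width = 0.1,
                       divergence_cutoff = 0.2) {
  stopifnot(length(ts) == length(n_paralogs))
  if (length(ts) == 0L) {
    return(list(histogram = NULL, fraction_below_cutoff = NA_real_, n = 0L))
  }
  stopifnot(all(ts > 0 & ts <= 1))
  labs <- c(as.character(strata[1]),
            paste0(strata[1] + 1, "-", strata[2]),
            paste0(">=", strata[2] + 1))
  stratum <- cut(n_paralogs,
                 breaks = c(-Inf, strata[1], strata[2], Inf),
                 labels = labs)
  bins <- cut(ts, breaks = seq(0, 1, by = bin_width), right = TRUE)
  list(histogram = unclass(table(stratum, bins)),
       fraction_below_cutoff = mean(ts < divergence_cutoff),
       n = length(ts))
}

#' k-mer Jaccard distance matrix
#'
#' `1 - J` over unique k-mer sets, the default distance for guide trees
#' when sequences are available.
#'
#' @param records proteome data frame (needs `id`, `sequence`).
#' @param k k-mer length.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
kmer_distance <- function(records, k = 3) {
  ids <- records$id
  sets <- lapply(records$sequence, .kmers, k = k)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- 1 - .jaccard(sets[[i]], sets[[j]])
      }
    }
  }
  d
}
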