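# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately recompute everything from first
# principles and share no code path with the package internals.

# O(n^3) average-linkage oracle: at every step recompute the linkage of
# every active cluster pair directly from the original matrix and merge
# the minimum, ties broken by the lexicographically smallest
# (min node_id, max node_id) pair. Node ids: leaves 1..n, merge i -> n+i.
oracle_merge_log <- function(E, cutoff = 100) {
  n <- nrow(E)
  clus <- lapply(seq_len(n), function(i) list(id = i, leaves = i))
  log_rows <- list()
  step <- 0L
  while (length(clus) > 1L) {
    k <- length(clus)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        li <- clus[[i]]$leaves; lj <- clus[[j]]$leaves
        lk <- sum(E[li, lj]) / (length(li) * length(lj))
        key <- c(min(clus[[i]]$id, clus[[j]]$id),
                 max(clus[[i]]$id, clus[[j]]$id))
        if (is.null(best) || lk < best$lk ||
            (lk == best$lk && (key[1] < best$key[1] ||
                               (key[1] == best$key[1] &&
                                key[2] < best$key[2])))) {
          best <- list(i = i, j = j, lk = lk, key = key)
        }
      }
    }
    if (best$lk > cutoff) break
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, left = best$key[1],
                                   right = best$key[2], score = best$lk)
    merged <- list(id = n + step,
                   leaves = sort(c(clus[[best$i]]$leaves,
                                   clus[[best$j]]$leaves)))
    clus <- c(clus[-c(best$i, best$j)], list(merged))
  }
  if (step == 0L) {
    return(data.frame(step = integer(), left = integer(),
                      right = integer(), score = numeric()))
  }
  do.call(rbind, log_rows)
}

# recursive tip sets per node of a phylo tree, written independently of
# ape's clade utilities
phylo_tipsets <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  tipset <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipset))
  }
  nodes <- c(seq_len(n), sort(unique(phy$edge[, 1])))
  setNames(lapply(nodes, tipset), nodes)
}

# exhaustive Tree Score: minimum leaf count over all rooted clades
# containing every interest leaf
oracle_tree_score <- function(phy, interest) {
  sizes <- vapply(Filter(function(tp) all(interest %in% tp),
                         phylo_tipsets(phy)), length, integer(1))
  length(interest) / min(sizes)
}

# does the interest set form exactly one clade?
forms_clade <- function(phy, interest) {
  any(vapply(phylo_tipsets(phy), function(tp) setequal(tp, interest),
             logical(1)))
}

# random symmetric capped E-value matrix; with ties = TRUE values come
# from a small set of exactly representable numbers so that tie-breaking
# is exercised
random_sim_matrix <- function(n, ties = FALSE) {
  ids <- sprintf("q%02d", seq_len(n))
  E <- matrix(100, n, n, dimnames = list(ids, ids))
  iu <- which(upper.tri(E), arr.ind = TRUE)
  vals <- if (ties) {
    sample(c(1, 2, 3, 4, 100), nrow(iu), replace = TRUE)
  } else {
    10^runif(nrow(iu), -30, 2)
  }
  E[iu] <- vals
  E[cbind(iu[, 2], iu[, 1])] <- vals
  sim_matrix(E)
}

# ProtoLevel boundary separating completed planted families from the
# cap-phase composites above them (no-orphan, single-root geometry)
family_pl_root <- function(tree, truth) {
  n_within <- sum(truth$families$size) - nrow(truth$families)
  100 * (n_within + 0.5) / tree$n_merges
}

planted_labels <- function(truth) {
  ifelse(is.na(truth$protein$family),
         paste0("orphan_", truth$protein$id),
         as.character(truth$protein$family))
}

# minimal proteome data frame from bare sequences
records_from_seqs <- function(seqs, species = "sp") {
  data.frame(id = sprintf("r%02d", seq_along(seqs)),
             species = rep_len(species, length(seqs)),
             sequence = seqs, length = nchar(seqs),
             is_fragment = FALSE, stringsAsFactors = FALSE)
}

# hand-built mapping_result
fake_mapping <- function(protein_id, status, map_cluster = NA_integer_,
                         map_score = NA_real_, root = NA_integer_) {
  md <- data.frame(protein_id = protein_id, status = status,
                   map_cluster = map_cluster, map_score = map_score,
                   root = root, stringsAsFactors = FALSE)
  structure(list(mapping = md, summary = NULL, params = NULL,
                 tau_map = NULL), class = "mapping_result")
}
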