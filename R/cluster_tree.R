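# Agglomerative merge tree with ProtoLevel / LifeTime bookkeeping.

#' Stability and pruning parameters
#'
#' @param lt_min minimum LifeTime (merge steps) for a cluster to count as
#'   stable. The mapping set at the default of 10 is the "Map10" analog.
#' @param pl_root ProtoLevel ceiling for family roots (default 70, the
#'   "ProRoot70" granularity).
#' @param merge_cutoff merging stops once the lowest linkage exceeds this
#'   value. The default equals the E-value cap, i.e. everything is merged
#'   into a single root; a lower value yields a forest.
#' @return an object of class `stability_params`.
#' @export
stability_params <- function(lt_min = 10, pl_root = 70, merge_cutoff = .E_CAP) {
  stopifnot(lt_min >= 0, pl_root > 0, pl_root <= 100, merge_cutoff > 0)
  structure(list(lt_min = lt_min, pl_root = pl_root,
                 merge_cutoff = merge_cutoff),
            class = "stability_params")
}

#' Build the agglomerative merge tree
#'
#' Average-linkage clustering of a capped E-value matrix: every protein
#' starts as a singleton and at each step the two clusters with the
#' lowest linkage merge, where `linkage(A, B)` is the arithmetic mean of
#' the pairwise E-values between the members of A and B. Linkage is
#' maintained as accumulated pair sums (`S(A,B)`; the reported linkage is
#' `S/(|A||B|)`), which is algebraically the Lance-Williams mean update
#' and keeps ties at the cap exact. Ties are broken by the
#' lexicographically smallest `(min node_id, max node_id)` pair, so trees
#' are bit-reproducible.
#'
#' Node ids 1..n are the singleton leaves (in matrix order); the node
#' created at merge step i has id n + i. After the build, each node
#' carries its ProtoLevel `pl = 100 * birth_step / n_merges` (0 for
#' singletons, 100 at the final merge) and its LifeTime
#' `lt = death_step - birth_step`, with surviving roots assigned
#' `death_step = n_merges + 1`.
#'
#' @param m a [sim_matrix()] (any exactly symmetric numeric matrix with
#'   dimnames is accepted; the diagonal is ignored).
#' @param params a [stability_params()] object.
#' @return an object of class `merge_tree`: a list with `ids`, a `nodes`
#'   data frame (`node_id`, `parent`, `child1`, `child2`, `size`,
#'   `birth_step`, `death_step`, `pl`, `lt`), per-node `members` (leaf
#'   indices), the `merge_log` (`step`, `left`, `right`, `score`) and
#'   `n_merges`.
#' @export
build_tree <- function(m, params = stability_params()) {
  E <- unclass(m)
  if (!is.matrix(E) || nrow(E) != ncol(E)) stop("m must be a square matrix")
  if (any(E != t(E))) stop("similarity matrix is not symmetric")
  ids <- rownames(E)
  if (is.null(ids)) stop("m must carry protein ids as dimnames")
  n <- nrow(E)
  if (n < 2L) stop("build_tree needs >= 2 proteins")

  n_max <- 2L * n - 1L
  parent <- child1 <- child2 <- rep(NA_integer_, n_max)
  birth <- c(rep(0L, n), rep(NA_integer_, n - 1L))
  death <- rep(NA_integer_, n_max)
  size <- c(rep(1L, n), rep(NA_integer_, n - 1L))
  members <- vector("list", n_max)
  members[seq_len(n)] <- as.list(seq_len(n))

  S <- E                         # pair-sum matrix between active clusters
  diag(S) <- 0
  act <- seq_len(n)              # node id at each active position
  step <- 0L
  log_left <- log_right <- integer(n - 1L)
  log_score <- numeric(n - 1L)

  while (length(act) > 1L) {
    sz <- size[act]
    L <- S / outer(sz, sz)
    L[lower.tri(L, diag = TRUE)] <- Inf
    mn <- min(L)
    if (mn > params$merge_cutoff) break
    cand <- which(L == mn, arr.ind = TRUE)
    a <- pmin(act[cand[, 1]], act[cand[, 2]])
    b <- pmax(act[cand[, 1]], act[cand[, 2]])
    kk <- order(a, b)[1L]
    p <- cand[kk, 1L]; q <- cand[kk, 2L]

    step <- step + 1L
    new <- n + step
    log_left[step] <- min(act[p], act[q])
    log_right[step] <- max(act[p], act[q])
    log_score[step] <- mn
    parent[act[p]] <- parent[act[q]] <- new
    child1[new] <- log_left[step]
    child2[new] <- log_right[step]
    death[act[p]] <- death[act[q]] <- step
    birth[new] <- step
    size[new] <- size[act[p]] + size[act[q]]
    members[[new]] <- sort(c(members[[act[p]]], members[[act[q]]]))

    newrow <- S[p, ] + S[q, ]    # additive pair-sum update, exact at the cap
    S[p, ] <- newrow
    S[, p] <- newrow
    S[p, p] <- 0
    S <- S[-q, -q, drop = FALSE]
    act[p] <- new
    act <- act[-q]
  }

  n_merges <- step
  n_nodes <- n + n_merges
  death[act] <- n_merges + 1L    # surviving roots
  idx <- seq_len(n_nodes)
  pl <- c(rep(0, n),
          if (n_merges > 0L) 100 * seq_len(n_merges) / n_merges)
  nodes <- data.frame(
    node_id = idx,
    parent = parent[idx], child1 = child1[idx], child2 = child2[idx],
    size = size[idx], birth_step = birth[idx], death_step = death[idx],
    pl = pl, lt = death[idx] - birth[idx]
  )
  structure(list(ids = ids, nodes = nodes, members = members[idx],
                 merge_log = data.frame(step = seq_len(n_merges),
                                        left = log_left[seq_len(n_merges)],
                                        right = log_right[seq_len(n_merges)],
                                        score = log_score[seq_len(n_merges)]),
                 n_merges = n_merges, n_leaves = n, params = params),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  n_roots <- sum(is.na(x$nodes$parent))
  cat("merge_tree:", x$n_leaves, "proteins,", x$n_merges, "merges,",
      n_roots, "root(s)\n")
  invisible(x)
}

#' Assign ProtoLevel coordinates
#'
#' Recomputes the ProtoLevel of every node: 0 for singleton leaves and
#' `100 * birth_step / n_merges` for the node created at each merge step,
#' so the final merge of the run sits at PL = 100. Idempotent
#' ([build_tree()] already calls this logic).
#'
#' @param tree a `merge_tree`.
#' @return the tree with the `pl` column refreshed.
#' @export
assign_protolevel <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- tree$n_leaves
  pl <- rep(0, nrow(tree$nodes))
  if (tree$n_merges > 0L) {
    internal <- tree$nodes$node_id > n
    pl[internal] <- 100 * tree$nodes$birth_step[internal] / tree$n_merges
  }
  tree$nodes$pl <- pl
  tree
}

#' Cluster LifeTimes
#'
#' The LifeTime of a cluster is the number of merge steps between its
#' creation and its absorption into a parent; surviving roots use
#' `n_merges + 1` as their death step, singletons are born at step 0.
#'
#' @param tree a `merge_tree`.
#' @param node_id optionally a single node id.
#' @return `lifetimes()` returns the named integer vector of all
#'   LifeTimes; `lifetime()` the LifeTime of one node.
#' @export
lifetimes <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  setNames(tree$nodes$lt, tree$nodes$node_id)
}

#' @rdname lifetimes
#' @export
lifetime <- function(tree, node_id) {
  stopifnot(inherits(tree, "merge_tree"))
  if (!node_id %in% tree$nodes$node_id) stop("unknown node: ", node_id)
  tree$nodes$lt[node_id]
}

#' Members of a cluster
#'
#' @param tree a `merge_tree`.
#' @param node_id a node id.
#' @return the protein ids contained in the cluster.
#' @export
cluster_members <- function(tree, node_id) {
  stopifnot(inherits(tree, "merge_tree"))
  if (!node_id %in% tree$nodes$node_id) stop("unknown node: ", node_id)
  tree$ids[tree$members[[node_id]]]
}

#' Stable clusters
#'
#' Nodes whose LifeTime reaches `params$lt_min`. With `maximal = TRUE`
#' only stable nodes with no stable proper ancestor are kept; these form
#' an antichain of disjoint clusters, the flat-partition view used for
#' partition-recovery assessments.
#'
#' @param tree a `merge_tree`.
#' @param params a [stability_params()]; defaults to the parameters the
#'   tree was built with.
#' @param maximal keep only maximal stable clusters.
#' @return a data frame with `node_id`, `size`, `pl`, `lt`.
#' @export
stable_clusters <- function(tree, params = tree$params, maximal = FALSE) {
  stopifnot(inherits(tree, "merge_tree"))
  nd <- tree$nodes
  st <- nd[nd$lt >= params$lt_min, c("node_id", "size", "pl", "lt")]
  if (nrow(st) > 0L && maximal) {
    in_stable <- logical(nrow(nd))
    in_stable[st$node_id] <- TRUE
    keep <- vapply(st$node_id, function(i) {
      p <- nd$parent[i]
      while (!is.na(p)) {
        if (in_stable[p]) return(FALSE)
        p <- nd$parent[p]
      }
      TRUE
    }, logical(1))
    st <- st[keep, , drop = FALSE]
  }
  rownames(st) <- NULL
  if (nrow(st) == 0L) warning("no stable clusters at lt_min = ", params$lt_min)
  st
}

#' Family root of a cluster (ProRoot)
#'
#' Climbs from a node to its highest ancestor-or-self whose ProtoLevel
#' does not exceed `pl_root`. A node that itself sits above `pl_root` is
#' excluded from the annotation scheme and `NA` is returned.
#'
#' @param tree a `merge_tree`.
#' @param node_id a node id.
#' @param pl_root ProtoLevel ceiling (default 70).
#' @return the root node id, or `NA_integer_` when the node is excluded.
#' @export
proroot <- function(tree, node_id, pl_root = 70) {
  stopifnot(inherits(tree, "merge_tree"))
  nd <- tree$nodes
  if (!node_id %in% nd$node_id) stop("unknown node: ", node_id)
  if (nd$pl[node_id] > pl_root) return(NA_integer_)  # excluded
  cur <- node_id
  repeat {
    p <- nd$parent[cur]
    if (is.na(p) || nd$pl[p] > pl_root) return(cur)
    cur <- p
  }
}

# newick string for the subtree rooted at node_id
.newick_node <- function(tree, node_id) {
  nd <- tree$nodes
  lab <- function(i) {
    if (i <= tree$n_leaves) tree$ids[i]
    else sprintf("%d|pl=%.4g|lt=%d", i, nd$pl[i], nd$lt[i])
  }
  rec <- function(i) {
    if (i <= tree$n_leaves) return(lab(i))
    paste0("(", rec(nd$child1[i]), ",", rec(nd$child2[i]), ")", lab(i))
  }
  paste0(rec(node_id), ";")
}

#' Export a merge tree as Newick
#'
#' Internal nodes are labeled `nodeID|pl=..|lt=..`. A forest (when
#' merging stopped at the cutoff) is written one tree per line.
#'
#' @param tree a `merge_tree`.
#' @param path optional output file; when `NULL` the newick string(s) are
#'   returned.
#' @return the newick strings, invisibly when written to file.
#' @export
tree_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  roots <- tree$nodes$node_id[is.na(tree$nodes$parent)]
  nwk <- vapply(roots, function(r) .newick_node(tree, r), character(1))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Tabular node view of a merge tree
#'
#' @param tree a `merge_tree`.
#' @return the `nodes` data frame extended with a comma-joined `members`
#'   column.
#' @export
node_table <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  out <- tree$nodes
  out$members <- vapply(out$node_id, function(i) {
    paste(tree$ids[tree$members[[i]]], collapse = ",")
  }, character(1))
  out
}

#' Serialize / restore a merge tree
#'
#' Text (JSON) round trip of the full `merge_tree` object, used by the
#' staged pipeline so that later stages can run in fresh sessions.
#'
#' @param tree a `merge_tree`.
#' @param path JSON file path.
#' @return `write_merge_tree()` returns `path` invisibly;
#'   `read_merge_tree()` the restored `merge_tree`.
#' @export
write_merge_tree <- function(tree, path) {
  stopifnot(inherits(tree, "merge_tree"))
  obj <- list(ids = tree$ids, nodes = tree$nodes,
              members = tree$members, merge_log = tree$merge_log,
              n_merges = tree$n_merges, n_leaves = tree$n_leaves,
              params = unclass(tree$params))
  jsonlite::write_json(obj, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_merge_tree
#' @export
read_merge_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  for (cc in c("node_id", "parent", "child1", "child2", "size",
               "birth_step", "death_step", "lt")) {
    nodes[[cc]] <- as.integer(nodes[[cc]])
  }
  members <- lapply(obj$members, as.integer)
  structure(list(ids = as.character(obj$ids), nodes = nodes,
                 members = members,
                 merge_log = as.data.frame(obj$merge_log),
                 n_merges = as.integer(obj$n_merges),
                 n_leaves = as.integer(obj$n_leaves),
                 params = do.call(stability_params, as.list(obj$params))),
            class = "merge_tree")
}
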