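# Map query proteins onto the best stable cluster of a frozen tree and
# lift them to their family root.

#' Map one query protein to its best stable cluster
#'
#' A stable cluster C is eligible when the mean capped E-value between
#' the query and the members of C is strictly below `tau_map`. Among
#' eligible clusters the minimal-sized one wins (the "best stable"
#' cluster); ties go to the lower score, then the lower node id. With
#' `prefer = "score"` the ordering is score first, then size.
#'
#' @param scores named numeric vector of capped E-values between the
#'   query and the tree proteins; missing ids read as the cap (100).
#' @param tree a frozen `merge_tree`.
#' @param stable the stable cluster set: a data frame from
#'   [stable_clusters()] or a vector of node ids.
#' @param tau_map eligibility threshold on the mean E-value.
#' @param prefer `"size"` (default, minimal-sized first) or `"score"`.
#' @param min_map_size smallest cluster size eligible as a map target
#'   (default 2: targets must be merged clusters, not stable
#'   singletons).
#' @return a list with `node` (node id or `NA` when unmapped) and `score`.
#' @export
map_protein <- function(scores, tree, stable, tau_map = 1,
                        prefer = c("size", "score"), min_map_size = 2) {
  stopifnot(inherits(tree, "merge_tree"))
  prefer <- match.arg(prefer)
  sid <- if (is.data.frame(stable)) stable$node_id else as.integer(stable)
  if (length(sid) == 0L) stop("empty stable set")
  sid <- sid[tree$nodes$size[sid] >= min_map_size]
  if (length(sid) == 0L) return(list(node = NA_integer_, score = NA_real_))
  x <- setNames(rep(.E_CAP, tree$n_leaves), tree$ids)
  common <- intersect(names(scores), tree$ids)
  x[common] <- pmin(scores[common], .E_CAP)
  msc <- vapply(sid, function(nid) mean(x[tree$members[[nid]]]), numeric(1))
  msz <- tree$nodes$size[sid]
  elig <- msc < tau_map
  if (!any(elig)) return(list(node = NA_integer_, score = NA_real_))
  o <- if (prefer == "size") {
    order(msz[elig], msc[elig], sid[elig])
  } else {
    order(msc[elig], msz[elig], sid[elig])
  }
  pick <- which(elig)[o[1L]]
  list(node = sid[pick], score = msc[pick])
}

#' Map a query proteome onto a frozen tree
#'
#' Applies [map_protein()] to every query and lifts each mapped protein
#' to its family root via [proroot()]. A mapped protein whose cluster
#' sits above `pl_root` is reported as `excluded` (separately from
#' `unmapped`), mirroring the exclusion of high-ProtoLevel mappings from
#' the annotation scheme.
#'
#' @param query_scores a numeric matrix of capped E-values, one row per
#'   query (rownames = query ids), columns named by tree protein ids;
#'   a [sim_matrix()] over the tree's own proteins gives a self-mapping.
#' @param tree a frozen `merge_tree`.
#' @param params a [stability_params()]; defaults to the tree's.
#' @param tau_map eligibility threshold on the mean E-value.
#' @param stable optionally a precomputed stable set.
#' @param prefer tie ordering, see [map_protein()].
#' @param min_map_size smallest eligible map-target size, see
#'   [map_protein()].
#' @return an object of class `mapping_result`: a list with the
#'   per-protein `mapping` data frame (`protein_id`, `status`,
#'   `map_cluster`, `map_score`, `root`) and a `summary` list of counts
#'   and fractions.
#' @export
map_proteome <- function(query_scores, tree, params = tree$params,
                         tau_map = 1, stable = NULL,
                         prefer = c("size", "score"), min_map_size = 2) {
  stopifnot(inherits(tree, "merge_tree"))
  prefer <- match.arg(prefer)
  Q <- unclass(query_scores)
  if (is.null(rownames(Q))) stop("query_scores must carry query ids as rownames")
  if (is.null(stable)) stable <- stable_clusters(tree, params)
  qids <- rownames(Q)
  nq <- length(qids)
  map_cluster <- rep(NA_integer_, nq)
  map_score <- rep(NA_real_, nq)
  root <- rep(NA_integer_, nq)
  status <- rep("unmapped", nq)
  for (i in seq_len(nq)) {
    hit <- map_protein(Q[i, ], tree, stable, tau_map = tau_map,
                       prefer = prefer, min_map_size = min_map_size)
    if (!is.na(hit$node)) {
      map_cluster[i] <- hit$node
      map_score[i] <- hit$score
      r <- proroot(tree, hit$node, params$pl_root)
      if (is.na(r)) {
        status[i] <- "excluded"
      } else {
        status[i] <- "mapped"
        root[i] <- r
      }
    }
  }
  mapping <- data.frame(protein_id = qids, status = status,
                        map_cluster = map_cluster, map_score = map_score,
                        root = root, stringsAsFactors = FALSE)
  structure(list(mapping = mapping,
                 summary = .mapping_summary(mapping),
                 params = params, tau_map = tau_map),
            class = "mapping_result")
}

.mapping_summary <- function(mapping) {
  n <- nrow(mapping)
  cnt <- c(mapped = sum(mapping$status == "mapped"),
           unmapped = sum(mapping$status == "unmapped"),
           excluded = sum(mapping$status == "excluded"))
  list(n_queries = n, counts = cnt,
       fractions = if (n > 0) cnt / n else cnt * NA_real_)
}

#' @export
print.mapping_result <- function(x, ...) {
  s <- x$summary
  cat("mapping_result:", s$n_queries, "queries;",
      sprintf("%.1f%% mapped, %.1f%% unmapped, %.1f%% excluded\n",
              100 * s$fractions["mapped"], 100 * s$fractions["unmapped"],
              100 * s$fractions["excluded"]))
  invisible(x)
}

#' Write / read a mapping report
#'
#' Tabular text form of the per-protein mapping
#' (`protein_id`, `status`, `map_cluster`, `map_score`, `root`).
#'
#' @param mr a `mapping_result`.
#' @param path file path.
#' @return `write_mapping()` returns `path` invisibly; `read_mapping()`
#'   restores a `mapping_result` (summary recomputed).
#' @export
write_mapping <- function(mr, path) {
  stopifnot(inherits(mr, "mapping_result"))
  write.table(mr$mapping, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  md$protein_id <- as.character(md$protein_id)
  md$map_cluster <- as.integer(md$map_cluster)
  md$root <- as.integer(md$root)
  structure(list(mapping = md, summary = .mapping_summary(md),
                 params = NULL, tau_map = NULL),
            class = "mapping_result")
}

#' Three-way taxonomic Venn partition of family roots
#'
#' Partitions the occupied family roots of a shared frozen tree by which
#' of three species map into them. Two views are reported: root-based
#' (each root assigned to the region of species present in it) and
#' protein-based (each mapped protein assigned to the region of species
#' co-occupying its root).
#'
#' @param mappings a named list of `mapping_result` objects, one per
#'   species, all against the same tree.
#' @param species the species (region axis) order; defaults to
#'   `names(mappings)`.
#' @param require_three enforce the three-way design (default). Set to
#'   `FALSE` to generalize to any number of species.
#' @return a list with `regions` (data frame: `region`, `n_roots`, one
#'   protein-count column per species) and `n_roots_total`.
#' @export
venn_partition <- function(mappings, species = names(mappings),
                           require_three = TRUE) {
  stopifnot(is.list(mappings), !is.null(species),
            all(species %in% names(mappings)))
  if (require_three && length(species) != 3L) {
    stop("venn partition is defined for exactly 3 species ",
         "(set require_three = FALSE to generalize)")
  }
  roots_by_sp <- lapply(mappings[species], function(m) {
    md <- m$mapping
    unique(md$root[md$status == "mapped"])
  })
  all_roots <- sort(unique(unlist(roots_by_sp)))
  pres <- vapply(species, function(s) all_roots %in% roots_by_sp[[s]],
                 logical(length(all_roots)))
  pres <- matrix(pres, nrow = length(all_roots),
                 dimnames = list(all_roots, species))
  region_of <- apply(pres, 1L, function(r) paste(species[r], collapse = "+"))
  # fixed region order: singles, pairs, ..., full combination
  combos <- unlist(lapply(seq_along(species), function(k) {
    apply(utils::combn(species, k), 2L, paste, collapse = "+")
  }))
  n_roots <- vapply(combos, function(rg) sum(region_of == rg), integer(1))
  prot <- sapply(species, function(s) {
    md <- mappings[[s]]$mapping
    md <- md[md$status == "mapped", , drop = FALSE]
    rg <- region_of[as.character(md$root)]
    vapply(combos, function(r) sum(rg == r, na.rm = TRUE), integer(1))
  })
  prot <- matrix(prot, nrow = length(combos),
                 dimnames = list(combos, paste0("proteins_", species)))
  regions <- data.frame(region = combos, n_roots = n_roots, prot,
                        row.names = NULL, check.names = FALSE)
  list(regions = regions, n_roots_total = length(all_roots))
}
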