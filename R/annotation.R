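# Per-cluster term scoring (Correspondence Score, specificity), ProtoName
# selection, and annotation transfer to mapped proteins.

#' Default blacklist of uninformative terms
#'
#' Term labels matching any of these (case-insensitive substring) are
#' never used for annotation.
#'
#' @return a character vector.
#' @export
annotation_blacklist <- function() {
  c("complete proteome", "taxonomy", "hypothetical protein")
}

.blacklisted <- function(labels, blacklist) {
  if (length(blacklist) == 0L) return(rep(FALSE, length(labels)))
  lo <- tolower(labels)
  Reduce(`|`, lapply(tolower(blacklist), function(b) {
    grepl(b, lo, fixed = TRUE)
  }))
}

#' Build or read an annotation database
#'
#' The database is a 4-column table `(protein_id, source, term_id,
#' term_label)`. Duplicate `(protein, source, term)` triples are dropped,
#' as are records whose label matches the blacklist.
#'
#' @param records a data frame with the four columns above.
#' @param blacklist labels to remove, see [annotation_blacklist()].
#' @return an object of class `annotation_db` (a data frame).
#' @export
annotation_db <- function(records, blacklist = annotation_blacklist()) {
  need <- c("protein_id", "source", "term_id", "term_label")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  d <- records[, need]
  for (cc in need) d[[cc]] <- as.character(d[[cc]])
  d <- d[!duplicated(d[, c("protein_id", "source", "term_id")]), ,
         drop = FALSE]
  d <- d[!.blacklisted(d$term_label, blacklist), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("annotation_db", "data.frame"),
            blacklist = blacklist)
}

#' @rdname annotation_db
#' @param path path to a tab-separated annotation table with a header row.
#' @export
read_annotations <- function(path, blacklist = annotation_blacklist()) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  annotation_db(d, blacklist = blacklist)
}

#' @rdname annotation_db
#' @param db an `annotation_db`.
#' @export
write_annotations <- function(db, path) {
  write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Correspondence Score of a term for a cluster
#'
#' Intersection-over-union between the cluster's member set and the
#' term's carrier set: `|cluster n term| / |cluster u term|`. When a
#' `universe` is given, carriers outside it are ignored.
#'
#' @param cluster_members protein ids in the cluster (non-empty).
#' @param term_members protein ids carrying the term.
#' @param universe optional analysis scope.
#' @return a number in `[0, 1]`; 1 exactly when the two sets coincide.
#' @export
correspondence_score <- function(cluster_members, term_members,
                                 universe = NULL) {
  if (length(cluster_members) == 0L) stop("empty cluster")
  if (!is.null(universe)) term_members <- intersect(term_members, universe)
  length(intersect(cluster_members, term_members)) /
    length(union(cluster_members, term_members))
}

#' Specificity (purity) of a term within a cluster
#'
#' The fraction of the cluster's members carrying the term:
#' `|cluster n term| / |cluster|`.
#'
#' @inheritParams correspondence_score
#' @return a number in `[0, 1]`.
#' @export
cluster_specificity <- function(cluster_members, term_members) {
  if (length(cluster_members) == 0L) stop("empty cluster")
  length(intersect(cluster_members, term_members)) / length(cluster_members)
}

# canonical source ordering for composed labels
.source_order <- function(sources) {
  canon <- c("GO", "InterPro", "Pfam", "Keyword", "EC", "SCOP", "CATH")
  c(intersect(canon, sources), sort(setdiff(sources, canon)))
}

#' ProtoName: the terms that best describe a cluster
#'
#' For a cluster of at least `min_size` proteins, picks per annotation
#' source the non-blacklisted term with the highest Correspondence Score
#' among terms whose specificity reaches `min_spec` (the specificity
#' filter is applied per term before CS ranking). Ties go to the larger
#' intersection, then the lexicographically smaller term id. Returns
#' `NULL` when the cluster is too small or no source yields a term.
#'
#' @param tree a `merge_tree`.
#' @param node_id the cluster node.
#' @param db an [annotation_db()].
#' @param min_size minimum cluster size (default 5).
#' @param min_spec minimum specificity (default 0.2).
#' @param universe analysis scope; defaults to the tree's proteins.
#' @param cs_scope denominator of the Correspondence Score: `"union"`
#'   (default, `|cluster u carriers|`) or `"carriers"` (`|carriers|`
#'   within the universe).
#' @return a data frame (`node_id`, `source`, `term_id`, `term_label`,
#'   `n_intersect`, `cs`, `specificity`), one row per source, with a
#'   `composed` label attribute; or `NULL`.
#' @export
protoname <- function(tree, node_id, db, min_size = 5, min_spec = 0.2,
                      universe = NULL, cs_scope = c("union", "carriers")) {
  stopifnot(inherits(tree, "merge_tree"), inherits(db, "annotation_db"))
  cs_scope <- match.arg(cs_scope)
  mem <- cluster_members(tree, node_id)
  if (length(mem) < min_size) return(NULL)
  if (is.null(universe)) universe <- tree$ids
  d <- as.data.frame(db)
  d <- d[!.blacklisted(d$term_label, attr(db, "blacklist")), , drop = FALSE]
  d <- d[d$protein_id %in% universe, , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)

  key <- paste(d$source, d$term_id, sep = "\r")
  carriers <- split(d$protein_id, key)
  meta <- d[!duplicated(key), c("source", "term_id", "term_label")]
  rownames(meta) <- key[!duplicated(key)]

  rows <- lapply(names(carriers), function(k) {
    car <- unique(carriers[[k]])
    ni <- length(intersect(mem, car))
    spec <- ni / length(mem)
    if (spec < min_spec || ni == 0L) return(NULL)
    cs <- if (cs_scope == "union") {
      ni / length(union(mem, car))
    } else {
      ni / length(car)
    }
    data.frame(node_id = node_id, source = meta[k, "source"],
               term_id = meta[k, "term_id"],
               term_label = meta[k, "term_label"],
               n_intersect = ni, cs = cs, specificity = spec,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) return(NULL)
  best <- do.call(rbind, lapply(split(rows, rows$source), function(g) {
    g[order(-g$cs, -g$n_intersect, g$term_id)[1L], , drop = FALSE]
  }))
  best <- best[match(.source_order(best$source), best$source), ,
               drop = FALSE]
  rownames(best) <- NULL
  attr(best, "composed") <- paste(best$term_label, collapse = "; ")
  best
}

#' ProtoNames for a set of clusters
#'
#' @param tree a `merge_tree`.
#' @param node_ids cluster node ids.
#' @inheritParams protoname
#' @return a data frame stacking the non-`NULL` [protoname()] results
#'   (zero rows when none).
#' @export
cluster_protonames <- function(tree, node_ids, db, min_size = 5,
                               min_spec = 0.2, universe = NULL,
                               cs_scope = "union") {
  out <- lapply(unique(node_ids), function(nid) {
    protoname(tree, nid, db, min_size = min_size, min_spec = min_spec,
              universe = universe, cs_scope = cs_scope)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(node_id = integer(), source = character(),
                      term_id = character(), term_label = character(),
                      n_intersect = integer(), cs = numeric(),
                      specificity = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# node chain from a map cluster up to (and including) its family root
.root_chain <- function(tree, node_id, root_id) {
  chain <- node_id
  cur <- node_id
  while (!is.na(cur) && cur != root_id) {
    cur <- tree$nodes$parent[cur]
    if (!is.na(cur)) chain <- c(chain, cur)
  }
  chain
}

#' Transfer annotations to mapped proteins
#'
#' Every mapped protein inherits the ProtoName terms of its map cluster
#' and of every ancestor up to and including its family root,
#' deduplicated by `(source, term_id)`. Unmapped and excluded proteins
#' receive nothing and are listed in the `unannotated` attribute with
#' their status.
#'
#' @param mapping a `mapping_result`.
#' @param tree the `merge_tree` the mapping was made against.
#' @param db an [annotation_db()].
#' @inheritParams protoname
#' @return a data frame (`protein_id`, `source`, `term_id`,
#'   `term_label`); attribute `unannotated` flags proteins with no terms.
#' @export
infer_protein_annotations <- function(mapping, tree, db, min_size = 5,
                                      min_spec = 0.2, universe = NULL,
                                      cs_scope = "union") {
  stopifnot(inherits(mapping, "mapping_result"))
  md <- mapping$mapping
  mapped <- md[md$status == "mapped", , drop = FALSE]
  chains <- lapply(seq_len(nrow(mapped)), function(i) {
    .root_chain(tree, mapped$map_cluster[i], mapped$root[i])
  })
  pn <- cluster_protonames(tree, unlist(chains), db, min_size = min_size,
                           min_spec = min_spec, universe = universe,
                           cs_scope = cs_scope)
  out <- lapply(seq_len(nrow(mapped)), function(i) {
    hit <- pn[pn$node_id %in% chains[[i]], , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    hit <- hit[!duplicated(hit[, c("source", "term_id")]), , drop = FALSE]
    data.frame(protein_id = mapped$protein_id[i], hit[, c("source",
               "term_id", "term_label")], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), source = character(),
                      term_id = character(), term_label = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  bare <- setdiff(md$protein_id, out$protein_id)
  attr(out, "unannotated") <- data.frame(
    protein_id = bare,
    status = md$status[match(bare, md$protein_id)],
    stringsAsFactors = FALSE)
  out
}

#' Summarize the annotation transfer
#'
#' Reports the fraction of occupied family roots that received a
#' ProtoName, the fraction of the query proteome with at least one
#' inferred term, the mean number of ProtoName terms per named root, and
#' the share of each annotation source among the selected terms.
#'
#' @param mapping a `mapping_result`.
#' @param tree the `merge_tree`.
#' @param db an [annotation_db()].
#' @inheritParams protoname
#' @return a list with the summary statistics plus the underlying
#'   `root_protonames` and `protein_annotations` tables.
#' @export
annotation_summary <- function(mapping, tree, db, min_size = 5,
                               min_spec = 0.2, universe = NULL,
                               cs_scope = "union") {
  md <- mapping$mapping
  roots <- unique(md$root[md$status == "mapped"])
  pn <- cluster_protonames(tree, roots, db, min_size = min_size,
                           min_spec = min_spec, universe = universe,
                           cs_scope = cs_scope)
  inf <- infer_protein_annotations(mapping, tree, db, min_size = min_size,
                                   min_spec = min_spec,
                                   universe = universe, cs_scope = cs_scope)
  named_roots <- unique(pn$node_id)
  annotated <- unique(inf$protein_id)
  shares <- if (nrow(pn) > 0L) {
    tt <- table(pn$source)
    setNames(as.numeric(tt) / sum(tt), names(tt))
  } else {
    numeric(0)
  }
  list(
    n_roots_occupied = length(roots),
    fraction_roots_named =
      if (length(roots) > 0L) length(named_roots) / length(roots) else 0,
    fraction_proteins_annotated =
      if (nrow(md) > 0L) length(annotated) / nrow(md) else 0,
    mean_terms_per_root =
      if (length(named_roots) > 0L) nrow(pn) / length(named_roots) else 0,
    source_shares = shares,
    root_protonames = pn,
    protein_annotations = inf
  )
}
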