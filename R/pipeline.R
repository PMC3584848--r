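# Staged orchestration: simulate -> score -> cluster -> map -> annotate ->
# scores -> report, each stage runnable independently with a manifest.

.STAGES <- c("simulate", "score", "cluster", "map", "annotate", "scores",
             "report")

#' Pipeline configuration
#'
#' One flat configuration document holding every stage parameter. The
#' defaults are the protocol's reference values: E-value cap 100,
#' LifeTime threshold 10, family-root ProtoLevel 70, minimum cluster
#' size 5 and specificity 0.2 for annotation transfer, Tree Score strata
#' 2 / 3-9 / >= 10 with divergence cutoff 0.2, and Taxonomy Balance
#' extremes at 10 and 0.1.
#'
#' @param ... overrides of the default fields.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cap = 100, e_floor = 1e-180,
    k = 3, s = 40,
    lt_min = 10, pl_root = 70, merge_cutoff = 100,
    tau_map = 1,
    min_size = 5, min_spec = 0.2,
    blacklist = annotation_blacklist(),
    ts_strata = c(2, 9), ts_divergence_cutoff = 0.2,
    tb_extremes = c(10, 0.1),
    paralog_min_count = 2,
    subject_species = NULL,    # defaults to the first species seen
    reference_species = NULL,  # defaults to the second species seen
    exclude_self = TRUE,       # self-mapping ignores the query's own row
    synth = synth_spec()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

.artifact <- function(out_dir, file) file.path(out_dir, file)

.require_artifact <- function(out_dir, file, stage_needed) {
  p <- .artifact(out_dir, file)
  if (!file.exists(p)) {
    stop("missing artifact '", file, "': run stage '", stage_needed,
         "' first")
  }
  p
}

.log_stage <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage, "] ", ...)
}

.write_manifest <- function(stage, config, out_dir, seed, files) {
  paths <- file.path(out_dir, files)
  ok <- file.exists(paths)
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    package_version = as.character(utils::packageVersion("protofam")),
    config = unclass(config),
    outputs = data.frame(file = files[ok],
                         md5 = unname(tools::md5sum(paths[ok])))
  )
  manifest$config$synth <- unclass(manifest$config$synth)
  jsonlite::write_json(manifest, .artifact(out_dir,
                       paste0("manifest_", stage, ".json")),
                       digits = NA, na = "null", auto_unbox = TRUE)
}

.stability_from_config <- function(config) {
  stability_params(lt_min = config$lt_min, pl_root = config$pl_root,
                   merge_cutoff = config$merge_cutoff)
}

.stage_simulate <- function(config, out_dir, seed) {
  gs <- gen_sequences(config$synth, seed)
  db <- gen_annotations(gs$truth, config$synth, seed)
  write_proteome(gs$records, .artifact(out_dir, "proteome.fasta"))
  write_annotations(db, .artifact(out_dir, "annotations.tsv"))
  write_truth(gs$truth, .artifact(out_dir, "truth.json"))
  c("proteome.fasta", "annotations.tsv", "truth.json")
}

.stage_score <- function(config, out_dir, seed) {
  fasta <- .require_artifact(out_dir, "proteome.fasta", "simulate")
  records <- suppressMessages(filter_full_length(read_proteome(fasta)))
  m <- all_vs_all(records, k = config$k, s = config$s,
                  cap = config$cap, e_floor = config$e_floor)
  writeLines(records$id, .artifact(out_dir, "ids.txt"))
  write_pairwise_scores(m, .artifact(out_dir, "scores.tsv"))
  c("ids.txt", "scores.tsv")
}

.stage_cluster <- function(config, out_dir, seed) {
  .require_artifact(out_dir, "scores.tsv", "score")
  ids <- readLines(.artifact(out_dir, "ids.txt"))
  m <- load_pairwise_scores(.artifact(out_dir, "scores.tsv"), ids,
                            cap = config$cap, e_floor = config$e_floor)
  tree <- build_tree(m, .stability_from_config(config))
  write_merge_tree(tree, .artifact(out_dir, "tree.json"))
  tree_to_newick(tree, .artifact(out_dir, "tree.newick"))
  write.table(node_table(tree), .artifact(out_dir, "nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  st <- stable_clusters(tree)
  write.table(st, .artifact(out_dir, "stable.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("tree.json", "tree.newick", "nodes.tsv", "stable.tsv")
}

.stage_map <- function(config, out_dir, seed) {
  .require_artifact(out_dir, "tree.json", "cluster")
  tree <- read_merge_tree(.artifact(out_dir, "tree.json"))
  m <- load_pairwise_scores(.artifact(out_dir, "scores.tsv"), tree$ids,
                            cap = config$cap, e_floor = config$e_floor)
  Q <- unclass(m)
  if (config$exclude_self) diag(Q) <- config$cap
  mr <- map_proteome(Q, tree, tau_map = config$tau_map)
  write_mapping(mr, .artifact(out_dir, "mapping.tsv"))
  out <- "mapping.tsv"
  records <- read_proteome(.require_artifact(out_dir, "proteome.fasta",
                                             "simulate"))
  species_of <- setNames(records$species, records$id)
  spp <- unique(stats::na.omit(species_of))
  if (length(spp) == 3L) {
    per_sp <- lapply(spp, function(s) {
      sub <- mr$mapping[species_of[mr$mapping$protein_id] %in% s, ,
                        drop = FALSE]
      structure(list(mapping = sub, summary = .mapping_summary(sub)),
                class = "mapping_result")
    })
    names(per_sp) <- spp
    vp <- venn_partition(per_sp, spp)
    jsonlite::write_json(vp, .artifact(out_dir, "venn.json"),
                         digits = NA, auto_unbox = TRUE)
    out <- c(out, "venn.json")
  } else {
    .log_stage("map", "venn skipped: ", length(spp),
               " species present (3 required)")
  }
  out
}

.stage_annotate <- function(config, out_dir, seed) {
  .require_artifact(out_dir, "mapping.tsv", "map")
  tree <- read_merge_tree(.require_artifact(out_dir, "tree.json",
                                            "cluster"))
  mr <- read_mapping(.artifact(out_dir, "mapping.tsv"))
  db <- read_annotations(.require_artifact(out_dir, "annotations.tsv",
                                           "simulate"),
                         blacklist = config$blacklist)
  sm <- annotation_summary(mr, tree, db, min_size = config$min_size,
                           min_spec = config$min_spec)
  write.table(sm$root_protonames, .artifact(out_dir, "protonames.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sm$protein_annotations,
              .artifact(out_dir, "protein_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sm[c("n_roots_occupied", "fraction_roots_named",
                            "fraction_proteins_annotated",
                            "mean_terms_per_root", "source_shares")],
                       .artifact(out_dir, "annotation_summary.json"),
                       digits = NA, auto_unbox = TRUE)
  c("protonames.tsv", "protein_annotations.tsv", "annotation_summary.json")
}

.stage_scores <- function(config, out_dir, seed) {
  .require_artifact(out_dir, "mapping.tsv", "map")
  tree <- read_merge_tree(.require_artifact(out_dir, "tree.json",
                                            "cluster"))
  mr <- read_mapping(.artifact(out_dir, "mapping.tsv"))
  records <- read_proteome(.require_artifact(out_dir, "proteome.fasta",
                                             "simulate"))
  species_of <- setNames(records$species, records$id)
  subject <- config$subject_species %||% unique(records$species)[1]
  reference <- config$reference_species %||%
    setdiff(unique(records$species), subject)[1]

  par_map <- find_paralogs(mr, species_of, subject,
                           min_count = config$paralog_min_count,
                           level = "map")
  par_root <- find_paralogs(mr, species_of, subject,
                            min_count = config$paralog_min_count,
                            level = "root")
  write.table(par_map, .artifact(out_dir, "paralogs_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(par_root, .artifact(out_dir, "paralogs_root.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # Tree Score per paralog-bearing map cluster: guide tree over the
  # cluster's members together with the mapped subject proteins
  d_all <- kmer_distance(records, k = config$k)
  md <- mr$mapping
  ts_rows <- lapply(seq_len(nrow(par_map)), function(i) {
    nid <- par_map$cluster[i]
    int <- md$protein_id[md$status == "mapped" &
                           md$map_cluster == nid &
                           species_of[md$protein_id] %in% subject]
    mem <- union(cluster_members(tree, nid), int)
    if (length(mem) < 2L) return(NULL)
    gt <- build_guide_tree(d_all[mem, mem, drop = FALSE])
    res <- tree_score(gt, int)
    data.frame(cluster = nid, n_paralogs = par_map$count[i],
               d_count = res$d_count,
               min_subtree_leaves = res$min_subtree_leaves, ts = res$ts)
  })
  ts_tab <- do.call(rbind, ts_rows)
  if (is.null(ts_tab)) {
    ts_tab <- data.frame(cluster = integer(), n_paralogs = integer(),
                         d_count = integer(),
                         min_subtree_leaves = integer(), ts = numeric())
  }
  write.table(ts_tab, .artifact(out_dir, "tree_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tss <- ts_summary(ts_tab$ts, ts_tab$n_paralogs,
                    strata = config$ts_strata,
                    divergence_cutoff = config$ts_divergence_cutoff)
  jsonlite::write_json(list(histogram = tss$histogram,
                            fraction_below_cutoff =
                              tss$fraction_below_cutoff,
                            n = tss$n),
                       .artifact(out_dir, "ts_summary.json"),
                       digits = NA, na = "null", auto_unbox = TRUE)

  occ <- root_species_counts(mr, species_of)
  tb <- if (!is.na(reference) && reference %in% names(occ) &&
            subject %in% names(occ)) {
    taxonomy_balance(occ, subject, reference,
                     extremes = config$tb_extremes)
  } else {
    data.frame(root = integer(), count_a = integer(),
               count_b = integer(), tb = numeric(), log2_tb = numeric(),
               extreme_high = logical(), extreme_low = logical())
  }
  write.table(tb, .artifact(out_dir, "taxonomy_balance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  amp <- amplification_table(mr, species_of, subject)
  write.table(amp, .artifact(out_dir, "amplification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("paralogs_map.tsv", "paralogs_root.tsv", "tree_scores.tsv",
    "ts_summary.json", "taxonomy_balance.tsv", "amplification.tsv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_report <- function(config, out_dir, seed) {
  .require_artifact(out_dir, "mapping.tsv", "map")
  .require_artifact(out_dir, "annotation_summary.json", "annotate")
  .require_artifact(out_dir, "ts_summary.json", "scores")
  tree <- read_merge_tree(.artifact(out_dir, "tree.json"))
  mr <- read_mapping(.artifact(out_dir, "mapping.tsv"))
  amp <- read.delim(.artifact(out_dir, "amplification.tsv"))
  tb <- read.delim(.artifact(out_dir, "taxonomy_balance.tsv"))
  report <- list(
    seed = seed,
    n_proteins = length(tree$ids),
    n_merges = tree$n_merges,
    n_stable_clusters = nrow(stable_clusters(tree)),
    mapping = mr$summary,
    annotation = jsonlite::read_json(
      .artifact(out_dir, "annotation_summary.json"),
      simplifyVector = TRUE),
    tree_score = jsonlite::read_json(
      .artifact(out_dir, "ts_summary.json"), simplifyVector = TRUE),
    taxonomy_balance = list(
      n_shared_roots = nrow(tb),
      n_extreme_high = sum(tb$extreme_high),
      n_extreme_low = sum(tb$extreme_low)),
    amplification = list(
      n_roots = nrow(amp),
      mean_ratio = if (nrow(amp) > 0) mean(amp$ratio) else NA,
      table_head = head(amp, 20))
  )
  if (file.exists(.artifact(out_dir, "venn.json"))) {
    report$venn <- jsonlite::read_json(.artifact(out_dir, "venn.json"),
                                       simplifyVector = TRUE)
  }
  truth_path <- .artifact(out_dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- read_truth(truth_path)
    report$recovery <- recovery_metrics(tree, mr, truth,
                                        .artifact(out_dir,
                                                  "protein_annotations.tsv"))
  }
  jsonlite::write_json(report, .artifact(out_dir, "report.json"),
                       digits = NA, na = "null", auto_unbox = TRUE)
  "report.json"
}

#' Ground-truth recovery metrics
#'
#' Compares the flat partition induced by the maximal stable clusters
#' with the planted families (adjusted Rand index; orphans count as
#' singleton families on both sides) and, when inferred annotations are
#' available, the fraction of non-orphan proteins whose inferred terms
#' include their family's planted term.
#'
#' @param tree a `merge_tree`.
#' @param mapping a `mapping_result`.
#' @param truth a `synth_truth`.
#' @param annotations_path optional path to an inferred-annotations
#'   table.
#' @return a list with `adjusted_rand_index` and (when available)
#'   `planted_term_recall`.
#' @export
recovery_metrics <- function(tree, mapping, truth,
                             annotations_path = NULL) {
  part <- stable_partition(tree)
  prot <- truth$protein
  planted <- ifelse(is.na(prot$family),
                    paste0("orphan_", prot$id), prot$family)
  out <- list(adjusted_rand_index =
                mclust::adjustedRandIndex(part[prot$id], planted))
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    ann <- read.delim(annotations_path, stringsAsFactors = FALSE)
    core <- prot[!is.na(prot$family), ]
    planted_term <- truth$families$term_id[core$family]
    got <- mapply(function(pid, term) {
      any(ann$protein_id == pid & ann$term_id == term)
    }, core$id, planted_term)
    out$planted_term_recall <- mean(got)
  }
  out
}

#' Flat partition from maximal stable clusters
#'
#' Assigns every protein the maximal stable cluster containing it;
#' proteins outside every stable cluster become their own singletons.
#'
#' @param tree a `merge_tree`.
#' @param params a [stability_params()]; defaults to the tree's.
#' @return a named character vector: partition label per protein id.
#' @export
stable_partition <- function(tree, params = tree$params) {
  st <- suppressWarnings(stable_clusters(tree, params, maximal = TRUE))
  lab <- setNames(paste0("self_", tree$ids), tree$ids)
  for (nid in st$node_id) {
    lab[tree$ids[tree$members[[nid]]]] <- as.character(nid)
  }
  lab
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic proteome + annotations + truth),
#' `score` (all-vs-all surrogate E-values), `cluster` (merge tree,
#' stability), `map` (self-mapping and Venn partition), `annotate`
#' (ProtoNames and transfer), `scores` (paralogs, Tree Score, Taxonomy
#' Balance, amplification), `report` (aggregate JSON with truth-aware
#' recovery metrics). Each stage checks its upstream artifacts and
#' writes a manifest with config and output checksums.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if missing).
#' @param seed integer seed (used by `simulate`).
#' @return the stage's output file names, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config(), out_dir,
                      seed = 1) {
  stage <- match.arg(stage, .STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_stage(stage, "starting (out = ", out_dir, ", seed = ", seed, ")")
  fn <- switch(stage,
               simulate = .stage_simulate, score = .stage_score,
               cluster = .stage_cluster, map = .stage_map,
               annotate = .stage_annotate, scores = .stage_scores,
               report = .stage_report)
  files <- fn(config, out_dir, seed)
  .write_manifest(stage, config, out_dir, seed, files)
  .log_stage(stage, "done: ", paste(files, collapse = ", "))
  invisible(files)
}

#' Run the full pipeline
#'
#' Executes every stage in order on one artifact directory.
#'
#' @inheritParams run_stage
#' @return the parsed `report.json`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  for (st in .STAGES) run_stage(st, config, out_dir, seed)
  invisible(jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE))
}
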