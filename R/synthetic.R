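# Planted-family synthetic inputs with ground truth: similarity matrices,
# sequences, annotations and guide-tree cases, all deterministic under a
# seed with per-component random streams.

#' Specification of a synthetic planted-family data set
#'
#' Families are planted with within-family E-values far below the cap
#' (log10-uniform in `within_log10_range`) and between-family values
#' exactly at the cap, multi-species membership drawn from `species_mix`,
#' and one planted annotation term per family assigned at
#' `annotation_purity`.
#'
#' The default of 19 families equals `2 * lt_min - 1` for the default
#' stability threshold `lt_min = 10`: during the terminal cap-tie merge
#' phase, family clusters are consumed pairwise in creation order, so
#' with 19 families every planted family persists at least 10 merge
#' steps while every chance composite of unrelated families dies sooner.
#' The planted partition is then exactly the set of maximal stable
#' clusters.
#'
#' @param n_families number of planted families.
#' @param family_size_range inclusive `(min, max)` of family sizes.
#' @param species species names (default three, exercising the Venn and
#'   Taxonomy Balance views).
#' @param species_mix per-member species probabilities.
#' @param within_log10_range `(lo, hi)` of log10 within-family E-values.
#' @param orphan_fraction fraction of proteins planted as orphans
#'   (cap-distant singletons).
#' @param annotation_purity probability that a family member carries its
#'   planted term.
#' @param n_decoy_terms number of uninformative decoy terms scattered
#'   uniformly.
#' @param mutation_rate per-residue substitution rate in sequence mode.
#' @param cap,e_floor E-value bounds.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_families = 19,
                       family_size_range = c(4, 20),
                       species = c("daphnia", "fly", "mouse"),
                       species_mix = c(0.5, 0.3, 0.2),
                       within_log10_range = c(-60, -20),
                       orphan_fraction = 0,
                       annotation_purity = 1,
                       n_decoy_terms = 0,
                       mutation_rate = 0.05,
                       cap = .E_CAP, e_floor = .E_FLOOR) {
  stopifnot(n_families >= 1,
            length(family_size_range) == 2,
            family_size_range[1] >= 1,
            family_size_range[1] <= family_size_range[2],
            length(species_mix) == length(species),
            all(species_mix >= 0), sum(species_mix) > 0,
            within_log10_range[1] < within_log10_range[2],
            within_log10_range[2] < log10(cap),
            orphan_fraction >= 0, orphan_fraction < 1,
            annotation_purity >= 0, annotation_purity <= 1,
            n_decoy_terms >= 0, mutation_rate >= 0, mutation_rate <= 1)
  structure(list(n_families = n_families,
                 family_size_range = family_size_range,
                 species = species,
                 species_mix = species_mix / sum(species_mix),
                 within_log10_range = within_log10_range,
                 orphan_fraction = orphan_fraction,
                 annotation_purity = annotation_purity,
                 n_decoy_terms = n_decoy_terms,
                 mutation_rate = mutation_rate,
                 cap = cap, e_floor = e_floor),
            class = "synth_spec")
}

# independent substream seeds (< 2^31) for layout / evalues / sequences /
# annotations, so toggling one output leaves the others unchanged
.synth_streams <- function(seed) {
  set.seed(seed)
  setNames(sample.int(2147483646L, 4), c("layout", "evalues",
                                         "sequences", "annotations"))
}

# family layout + species assignment; shared by all generators
.gen_layout <- function(spec, seed) {
  set.seed(.synth_streams(seed)[["layout"]])
  K <- spec$n_families
  size_choices <- seq(spec$family_size_range[1], spec$family_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), K,
                                   replace = TRUE)]
  n_core <- sum(sizes)
  n_orph <- round(spec$orphan_fraction * n_core / (1 - spec$orphan_fraction))
  n <- n_core + n_orph
  family <- c(rep(seq_len(K), sizes), rep(NA_integer_, n_orph))
  ids <- sprintf("P%05d", seq_len(n))
  species <- sample(spec$species, n, replace = TRUE,
                    prob = spec$species_mix)
  prot <- data.frame(id = ids, family = family, species = species,
                     stringsAsFactors = FALSE)
  fam_counts <- matrix(0L, K, length(spec$species),
                       dimnames = list(seq_len(K), spec$species))
  core <- prot[!is.na(prot$family), ]
  tt <- table(core$family, core$species)
  fam_counts[rownames(tt), colnames(tt)] <- tt
  structure(list(protein = prot,
                 families = data.frame(family = seq_len(K), size = sizes,
                                       term_id = sprintf("T%03d", seq_len(K))),
                 species_counts = fam_counts,
                 orphans = ids[is.na(family)],
                 spec = unclass(spec)),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("synth_truth:", nrow(x$protein), "proteins,",
      nrow(x$families), "families,", length(x$orphans), "orphan(s)\n")
  invisible(x)
}

#' Generate a planted-family similarity matrix
#'
#' Within-family entries are `10^U`, U ~ Uniform over
#' `within_log10_range`; between-family and orphan entries sit exactly
#' at the cap. Deterministic given the seed.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return a list with `matrix` (a [sim_matrix()]) and `truth`
#'   (the `synth_truth` ground truth).
#' @export
gen_similarity <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  truth <- .gen_layout(spec, seed)
  set.seed(.synth_streams(seed)[["evalues"]])
  prot <- truth$protein
  n <- nrow(prot)
  E <- matrix(spec$cap, n, n, dimnames = list(prot$id, prot$id))
  lo <- spec$within_log10_range[1]
  hi <- spec$within_log10_range[2]
  for (f in truth$families$family) {
    idx <- which(prot$family == f)
    m <- length(idx)
    if (m < 2L) next
    pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    vals <- 10^runif(nrow(pairs), lo, hi)
    E[cbind(idx[pairs[, 1]], idx[pairs[, 2]])] <- vals
    E[cbind(idx[pairs[, 2]], idx[pairs[, 1]])] <- vals
  }
  list(matrix = sim_matrix(E, cap = spec$cap, e_floor = spec$e_floor),
       truth = truth)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit) > 0L) {
    x[hit] <- vapply(x[hit], function(a) {
      sample(setdiff(.AA20, a), 1)
    }, character(1))
  }
  paste(x, collapse = "")
}

#' Generate planted-family protein sequences
#'
#' One random ancestor per family (length uniform in 120-400 residues);
#' each member is the ancestor with i.i.d. point substitutions at
#' `mutation_rate`; orphans are fresh random sequences. Species tags
#' follow the layout shared with [gen_similarity()] at the same seed.
#'
#' @inheritParams gen_similarity
#' @return a list with `records` (a proteome data frame as from
#'   [read_proteome()]) and `truth`.
#' @export
gen_sequences <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  truth <- .gen_layout(spec, seed)
  set.seed(.synth_streams(seed)[["sequences"]])
  prot <- truth$protein
  seqs <- character(nrow(prot))
  for (f in truth$families$family) {
    idx <- which(prot$family == f)
    anc <- .random_protein(sample(120:400, 1))
    seqs[idx] <- vapply(idx, function(i) {
      .mutate_protein(anc, spec$mutation_rate)
    }, character(1))
  }
  orph <- which(is.na(prot$family))
  for (i in orph) seqs[i] <- .random_protein(sample(120:400, 1))
  records <- data.frame(id = prot$id, species = prot$species,
                        sequence = seqs, length = nchar(seqs),
                        is_fragment = FALSE, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Generate a planted annotation database
#'
#' Each family's planted term is assigned to each member with
#' probability `annotation_purity`; decoy terms (if any) are scattered
#' over 1-5 random proteins each. One source label per term is drawn
#' from GO / InterPro / Pfam / Keyword.
#'
#' @param truth a `synth_truth` from one of the generators.
#' @param spec the [synth_spec()] used to generate it.
#' @param seed integer seed (annotation substream).
#' @return an [annotation_db()].
#' @export
gen_annotations <- function(truth, spec, seed) {
  stopifnot(inherits(truth, "synth_truth"), inherits(spec, "synth_spec"))
  set.seed(.synth_streams(seed)[["annotations"]])
  sources <- c("GO", "InterPro", "Pfam", "Keyword")
  prot <- truth$protein
  rows <- list()
  for (f in truth$families$family) {
    members <- prot$id[!is.na(prot$family) & prot$family == f]
    carriers <- members[runif(length(members)) < spec$annotation_purity]
    if (length(carriers) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = carriers,
      source = sample(sources, 1),
      term_id = truth$families$term_id[f],
      term_label = paste("planted family", f, "marker"),
      stringsAsFactors = FALSE)
  }
  if (spec$n_decoy_terms > 0L) {
    for (j in seq_len(spec$n_decoy_terms)) {
      carriers <- sample(prot$id, sample(1:5, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = carriers,
        source = sample(sources, 1),
        term_id = sprintf("D%03d", j),
        term_label = paste("decoy term", j),
        stringsAsFactors = FALSE)
    }
  }
  d <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(protein_id = character(), source = character(),
               term_id = character(), term_label = character(),
               stringsAsFactors = FALSE)
  }
  annotation_db(d)
}

# left-nesting chain of a leaf vector into newick
.nest_chain <- function(x) {
  Reduce(function(a, b) paste0("(", a, ",", b, ")"), x)
}

#' Generate a guide-tree Tree Score test case
#'
#' With `intermix = FALSE` the interest leaves form one planted clade,
#' so the Tree Score is exactly 1. With `intermix = TRUE` the interest
#' leaves are scattered so that their lowest common ancestor is the
#' root; the Tree Score is then exactly
#' `n_interest / (n_interest + n_other)`.
#'
#' @param n_interest number of leaves of the species of interest (>= 1).
#' @param n_other number of other leaves.
#' @param intermix scatter the interest leaves instead of planting a
#'   clade.
#' @param seed integer seed (shuffles leaf placement).
#' @return a list with `tree` (phylo), `interest` (tip labels) and
#'   `expected_ts`.
#' @export
gen_guide_case <- function(n_interest, n_other, intermix, seed = 1) {
  stopifnot(n_interest >= 1, n_other >= 0)
  if (intermix && n_other == 0L) {
    stop("intermix requires at least one non-interest leaf")
  }
  set.seed(seed)
  ti <- paste0("I", seq_len(n_interest))
  to <- if (n_other > 0L) paste0("O", seq_len(n_other)) else character(0)
  if (!intermix) {
    clade <- .nest_chain(sample(ti))
    txt <- if (n_other == 0L) clade else {
      paste0("(", clade, ",", .nest_chain(sample(to)), ")")
    }
    expected <- 1.0
  } else {
    # caterpillar with interest leaves first and last: the LCA of the
    # interest set is the root, so its clade is the whole tree
    if (n_interest == 1L) {
      mid <- sample(to)
      order <- c(ti, mid)
      expected <- 1.0
    } else {
      mid <- sample(c(to, ti[-c(1L, 2L)]))
      order <- c(ti[1L], mid, ti[2L])
      expected <- n_interest / (n_interest + n_other)
    }
    txt <- .nest_chain(order)
  }
  if (n_interest + n_other < 2L) {
    stop("guide case needs at least 2 leaves")
  }
  tree <- ape::read.tree(text = paste0(txt, ";"))
  list(tree = tree, interest = ti, expected_ts = expected,
       intermix = intermix)
}

#' Write / read the ground truth
#'
#' JSON round trip of a `synth_truth` object.
#'
#' @param truth a `synth_truth`.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   restored object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  obj <- unclass(truth)
  obj$species_counts <- as.data.frame(obj$species_counts)
  jsonlite::write_json(obj, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$protein <- as.data.frame(obj$protein)
  obj$protein$family <- as.integer(obj$protein$family)
  obj$families <- as.data.frame(obj$families)
  obj$species_counts <- as.matrix(obj$species_counts)
  obj$orphans <- as.character(obj$orphans)
  structure(obj, class = "synth_truth")
}
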