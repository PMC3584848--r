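# Capped all-vs-all E-value matrix: the substrate the clustering consumes.

#' Read a proteome from FASTA
#'
#' Headers follow the convention `>id species=<tag> [fragment=1]`; the
#' species tag and the fragment flag are optional free-text keys in the
#' description line. Sequences are uppercase amino acids (20-letter
#' alphabet plus `X`).
#'
#' @param path path to a FASTA file.
#' @return a data frame with columns `id`, `species`, `sequence`, `length`
#'   and `is_fragment`.
#' @seealso [write_proteome()], [filter_full_length()]
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  hdr <- names(aa)
  id <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(id)) {
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  species <- rep(NA_character_, length(hdr))
  has_sp <- grepl("species=", hdr, fixed = TRUE)
  species[has_sp] <- sub(".*species=(\\S+).*", "\\1", hdr[has_sp])
  seqs <- as.character(aa)
  if (any(nchar(seqs) == 0L)) stop("empty sequence for: ",
                                   paste(id[nchar(seqs) == 0L], collapse = ", "))
  data.frame(
    id = id,
    species = species,
    sequence = unname(seqs),
    length = unname(nchar(seqs)),
    is_fragment = grepl("(^|\\s)fragment=1(\\s|$)", hdr),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a proteome to FASTA
#'
#' Inverse of [read_proteome()]: emits `>id species=<tag> [fragment=1]`
#' headers.
#'
#' @param records a proteome data frame as returned by [read_proteome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  sp <- if ("species" %in% names(records)) records$species else NA
  fr <- if ("is_fragment" %in% names(records)) records$is_fragment else FALSE
  hdr <- paste0(records$id,
                ifelse(is.na(sp), "", paste0(" species=", sp)),
                ifelse(fr, " fragment=1", ""))
  aa <- Biostrings::AAStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Keep only full-length proteins
#'
#' Drops records flagged as fragments (`fragment=1` in the FASTA header),
#' preserving input order. The number of removed records is reported and
#' attached as attribute `n_removed`.
#'
#' @param records a proteome data frame with an `is_fragment` column.
#' @return the full-length subset of `records`.
#' @export
filter_full_length <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "is_fragment") %in% names(records)))
  keep <- !records$is_fragment
  if (!any(keep)) stop("no full-length proteins")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " fragment(s) removed, ", nrow(out), " retained")
  out
}

# unique k-mer set of one sequence
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k = ", k)
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

.jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Deterministic k-mer surrogate E-value
#'
#' A pluggable stand-in for an external aligner: maps the Jaccard index J
#' of the two sequences' k-mer sets onto an E-value-like scale through
#' `10^(2 - s * J)`, clamped to `[e_floor, cap]`. Unrelated sequences
#' (J = 0) land at the cap; identical ones at `10^(2 - s)`. Symmetric and
#' fully deterministic.
#'
#' @param a,b amino-acid sequences (character scalars), or rows of a
#'   proteome data frame (the `sequence` field is used).
#' @param k k-mer length (residues).
#' @param s steepness of the Jaccard-to-E-value map.
#' @param cap,e_floor clamp bounds.
#' @return a single numeric E-value in `[e_floor, cap]`.
#' @export
surrogate_evalue <- function(a, b, k = 3, s = 40,
                             cap = .E_CAP, e_floor = .E_FLOOR) {
  if (is.list(a)) a <- a$sequence
  if (is.list(b)) b <- b$sequence
  J <- .jaccard(.kmers(a, k), .kmers(b, k))
  min(max(10^(2 - s * J), e_floor), cap)
}

#' Construct a capped similarity matrix
#'
#' Validates and classes a symmetric matrix of pairwise E-values: all
#' values at or below `cap`, diagonal pinned to `e_floor`.
#'
#' @param E a square numeric matrix with protein ids as dimnames.
#' @param cap E-value cap (values less significant than this read as cap).
#' @param e_floor self-similarity floor.
#' @return an object of class `sim_matrix` (a numeric matrix with `cap`
#'   and `e_floor` attributes).
#' @export
sim_matrix <- function(E, cap = .E_CAP, e_floor = .E_FLOOR) {
  stopifnot(is.matrix(E), nrow(E) == ncol(E), !is.null(rownames(E)))
  if (any(E != t(E))) stop("similarity matrix is not symmetric")
  if (any(E > cap)) stop("similarity values above the cap of ", cap)
  diag(E) <- e_floor
  structure(E, class = "sim_matrix", cap = cap, e_floor = e_floor)
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("sim_matrix over", nrow(x), "proteins; cap =", attr(x, "cap"),
      "; floor =", attr(x, "e_floor"), "\n")
  invisible(x)
}

#' Score all protein pairs
#'
#' Applies a symmetric scorer to every unordered pair of proteins and
#' assembles the capped similarity matrix. The default scorer is the
#' k-mer surrogate ([surrogate_evalue()]), evaluated through a fast path
#' that precomputes each sequence's k-mer set once.
#'
#' @param records proteome data frame (needs `id` and `sequence`).
#' @param scorer optional `function(seq_a, seq_b) -> evalue`; `NULL` uses
#'   the surrogate with parameters `k` and `s`.
#' @param k,s surrogate parameters, ignored when `scorer` is supplied.
#' @param cap,e_floor matrix bounds.
#' @return a [sim_matrix()].
#' @export
all_vs_all <- function(records, scorer = NULL, k = 3, s = 40,
                       cap = .E_CAP, e_floor = .E_FLOOR) {
  ids <- records$id
  seqs <- records$sequence
  n <- length(ids)
  if (n < 2L) stop("all_vs_all needs >= 2 proteins")
  E <- matrix(cap, n, n, dimnames = list(ids, ids))
  if (is.null(scorer)) {
    sets <- lapply(seqs, .kmers, k = k)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        J <- .jaccard(sets[[i]], sets[[j]])
        E[i, j] <- E[j, i] <- min(max(10^(2 - s * J), e_floor), cap)
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- tryCatch(scorer(seqs[i], seqs[j]), error = function(e) {
          stop("scorer failed on pair (", ids[i], ", ", ids[j], "): ",
               conditionMessage(e), call. = FALSE)
        })
        E[i, j] <- E[j, i] <- min(max(v, e_floor), cap)
      }
    }
  }
  sim_matrix(E, cap = cap, e_floor = e_floor)
}

#' Load a pairwise score table
#'
#' Reads a 3-column tab-separated table `(query, subject, evalue)` over a
#' declared protein set. Values above the cap are replaced by the cap;
#' reciprocal (directed) pairs are symmetrized with the minimum (most
#' significant) of the two directions; absent pairs default to the cap;
#' the diagonal is pinned to `e_floor`. Lines starting with `#` and blank
#' lines are skipped.
#'
#' @param path path to the score table.
#' @param ids character vector: the full protein set the matrix is over.
#' @param cap,e_floor matrix bounds.
#' @return a [sim_matrix()] over `ids` in the given order.
#' @export
load_pairwise_scores <- function(path, ids, cap = .E_CAP, e_floor = .E_FLOOR) {
  if (anyDuplicated(ids)) stop("duplicate ids in declared proteome")
  n <- length(ids)
  M <- matrix(Inf, n, n, dimnames = list(ids, ids))
  lines <- readLines(path)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*(#|$)", line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("malformed row at line ", ln,
                              ": expected 3 tab-separated fields")
    q <- f[1]; s <- f[2]
    if (!q %in% ids) stop("unknown protein id '", q, "' at line ", ln)
    if (!s %in% ids) stop("unknown protein id '", s, "' at line ", ln)
    v <- suppressWarnings(as.numeric(f[3]))
    if (is.na(v)) stop("malformed evalue at line ", ln, ": '", f[3], "'")
    if (v < 0) stop("negative evalue at line ", ln)
    v <- min(v, cap)
    M[q, s] <- min(M[q, s], v)
  }
  M <- pmin(M, t(M))            # min-symmetrization of directed pairs
  M[is.infinite(M)] <- cap      # missing pairs read as the cap
  sim_matrix(M, cap = cap, e_floor = e_floor)
}

#' Write a pairwise score table
#'
#' Emits the upper triangle of a similarity matrix as 3-column
#' tab-separated text with a `#` header comment. The default of 17
#' significant digits makes [load_pairwise_scores()] reproduce the matrix
#' bit-exactly.
#'
#' @param m a [sim_matrix()].
#' @param path output file path.
#' @param digits significant digits for the scientific notation.
#' @return `path`, invisibly.
#' @export
write_pairwise_scores <- function(m, path, digits = 17) {
  ids <- rownames(m)
  iu <- which(upper.tri(m), arr.ind = TRUE)
  fmt <- paste0("%s\t%s\t%.", digits - 1L, "e")
  writeLines(c("# query\tsubject\tevalue",
               sprintf(fmt, ids[iu[, 1]], ids[iu[, 2]], m[iu])),
             path)
  invisible(path)
}
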