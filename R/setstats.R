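## setstats: target-set comparison statistics ------------------------------

#' Construct a labelled target gene set
#'
#' @param ids Character gene identifiers (duplicates collapsed).
#' @param label Set label.
#' @param universe Optional universe size (must be >= set size).
#' @param case_fold Lower-case identifiers before comparison.
#' @param strip_version Remove trailing `.N` version suffixes.
#' @return Object of class `target_set` (a character vector with
#'   attributes).
#' @export
target_set <- function(ids, label = "set", universe = NULL,
                       case_fold = FALSE, strip_version = FALSE) {
  ids <- normalize_gene_ids(as.character(ids), case_fold, strip_version)
  ids <- unique(ids[!is.na(ids) & nzchar(ids)])
  if (!is.null(universe) && universe < length(ids))
    stopf("universe (%d) smaller than the set (%d)", universe, length(ids))
  structure(ids, label = label, universe = universe, class = "target_set")
}

#' Canonicalize gene identifiers across list dialects
#' @param ids Character identifiers.
#' @inheritParams target_set
#' @return Character vector.
#' @export
normalize_gene_ids <- function(ids, case_fold = FALSE,
                               strip_version = FALSE) {
  if (strip_version) ids <- sub("\\.[0-9]+$", "", ids)
  if (case_fold) ids <- tolower(ids)
  ids
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set:%s> %d gene(s)%s\n", attr(x, "label"), length(x),
              if (!is.null(attr(x, "universe")))
                sprintf(" (universe %d)", attr(x, "universe")) else ""))
  invisible(x)
}

as_ids <- function(x) unique(as.character(x))

#' Jaccard similarity of two gene sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; 0 when both sets are empty.
#'
#' @param a,b [target_set()]s or character vectors.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' jaccard(letters[1:4], letters[3:6])  # 2/6
jaccard <- function(a, b) {
  a <- as_ids(a); b <- as_ids(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Binomial overlap enrichment between two gene sets
#'
#' Models the overlap as `|a|` draws each hitting set `b` with probability
#' `|b| / universe`; reports the observed intersection, its expectation
#' `|a||b|/universe`, the fold enrichment, and the upper-tail binomial
#' probability P(X >= k). The convention (what plays n and p) is recorded
#' in the result.
#'
#' @param a,b Gene sets.
#' @param universe Universe size; must be at least `|a U b|`.
#' @return list: `observed`, `expected`, `fold`, `p.value`, `universe`,
#'   `convention`.
#' @export
overlap_binomial <- function(a, b, universe) {
  a <- as_ids(a); b <- as_ids(b)
  if (universe < length(union(a, b)))
    stopf("universe (%d) smaller than |a U b| (%d)", universe,
          length(union(a, b)))
  k <- length(intersect(a, b))
  p <- length(b) / universe
  expected <- length(a) * p
  list(observed = k,
       expected = expected,
       fold = if (expected > 0) k / expected else NA_real_,
       p.value = pbinom(k - 1, size = length(a), prob = p,
                        lower.tail = FALSE),
       universe = universe,
       convention = "X ~ Binomial(n = |a|, p = |b|/universe); upper tail at k = |a n b|")
}

#' Ratio of two overlap counts
#' @param k1,k2 Counts; `k2` must be positive.
#' @return `k1 / k2`.
#' @export
#' @examples
#' fold_ratio(346, 77)  # ~4.5
fold_ratio <- function(k1, k2) {
  if (length(k2) != 1L || k2 <= 0) stopf("k2 must be a positive count")
  k1 / k2
}

#' Compile the union of top-ranked genes across several lists
#'
#' Takes the top `top_n_per_list` genes from each ranked list and returns
#' the deduplicated union, retaining provenance (which source lists each
#' gene came from) as a membership table.
#'
#' @param lists Named list of ranked gene vectors (or data.frames whose
#'   first column is the gene, already sorted best-first).
#' @param top_n_per_list Genes to take from the head of each list.
#' @return A [target_set()] with attribute `membership` (data.frame of
#'   gene x source logicals).
#' @export
compile_target_union <- function(lists, top_n_per_list = 100L) {
  stopifnot(is.list(lists), length(lists) > 0L)
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  tops <- lapply(lists, function(l) {
    ids <- if (is.data.frame(l)) as.character(l[[1L]]) else as.character(l)
    utils::head(ids, top_n_per_list)
  })
  all_ids <- unique(unlist(tops, use.names = FALSE))
  memb <- as.data.frame(lapply(tops, function(t) all_ids %in% t))
  rownames(memb) <- all_ids
  out <- target_set(all_ids, label = "union")
  attr(out, "membership") <- memb
  out
}

#' Multi-set overlap counts for Venn-style displays
#'
#' @param lists Named list of gene vectors.
#' @return `data.frame` with one row per membership pattern and its count.
#' @export
overlap_membership_table <- function(lists) {
  stopifnot(is.list(lists), !is.null(names(lists)))
  all_ids <- unique(unlist(lists, use.names = FALSE))
  memb <- vapply(lists, function(s) all_ids %in% s, logical(length(all_ids)))
  memb <- as.data.frame(memb)
  agg <- stats::aggregate(list(n = rep(1L, nrow(memb))), by = memb, FUN = sum)
  agg[order(-agg$n), , drop = FALSE]
}

#' Read a gene list file (one identifier per line, optional score column)
#' @param path Text or TSV file.
#' @return Character vector in file order.
#' @export
read_gene_list <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  as.character(dt[[1L]])
}

#' Write a gene list file
#' @param ids Character identifiers.
#' @param path Output path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
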