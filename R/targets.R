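## targets: per-UTR aggregation, residual ranking, top/bottom selection ----

#' Aggregate editing events per gene 3'UTR into a genes-by-samples matrix
#'
#' Sums editing events over each gene's 3'UTR intervals. Genes whose
#' transcripts all carry excluded biotypes (nonsense-mediated decay,
#' nonstop decay, processed transcript, retained intron, unprocessed
#' pseudogene by default) are dropped from the matrix entirely. Replicate
#' samples of a condition are summed into one column when `collapse` is on.
#'
#' @param events_by_sample Named list of [editing_events()] tables; names
#'   are sample labels (must be unique).
#' @param annotation A [utr_set()].
#' @param excluded_biotypes Biotypes to remove (default
#'   [EXCLUDED_BIOTYPES]).
#' @param conditions Optional character vector (same length/names as
#'   `events_by_sample`) giving each sample's condition.
#' @param collapse Sum replicates per condition (default TRUE when
#'   `conditions` given).
#' @return Integer matrix (class `editing_matrix`) of retained genes by
#'   samples or conditions, with a `conditions` attribute.
#' @export
aggregate_utr_editing <- function(events_by_sample, annotation,
                                  excluded_biotypes = EXCLUDED_BIOTYPES,
                                  conditions = NULL, collapse = TRUE) {
  stopifnot(is.list(events_by_sample), !is.null(names(events_by_sample)))
  if (anyDuplicated(names(events_by_sample)))
    stopf("sample labels must be unique")
  ann <- as.data.table(annotation)
  gene_bio <- ann[, .(all_excluded = all(biotype %in% excluded_biotypes)),
                  by = gene_id]
  keep_genes <- sort(gene_bio$gene_id[!gene_bio$all_excluded])
  samples <- names(events_by_sample)
  mat <- matrix(0L, length(keep_genes), length(samples),
                dimnames = list(keep_genes, samples))
  for (s in samples) {
    ev <- as.data.table(events_by_sample[[s]])
    if (!nrow(ev)) next
    unknown <- setdiff(stats::na.omit(unique(ev$gene_id)),
                       unique(ann$gene_id))
    if (length(unknown))
      warnf("sample '%s': %d event(s) reference unknown gene(s); skipped",
            s, sum(ev$gene_id %in% unknown))
    ev <- ev[!is.na(gene_id) & gene_id %in% keep_genes]
    if (!nrow(ev)) next
    tab <- ev[, .N, by = gene_id]
    mat[tab$gene_id, s] <- tab$N
  }
  cond <- conditions %||% samples
  if (collapse && length(unique(cond)) < length(samples)) {
    out <- vapply(unique(cond), function(cc)
      rowSums(mat[, cond == cc, drop = FALSE]), numeric(nrow(mat)))
    mat <- matrix(as.integer(out), nrow(mat),
                  dimnames = list(keep_genes, unique(cond)))
    cond <- unique(cond)
  }
  attr(mat, "conditions") <- cond
  class(mat) <- c("editing_matrix", class(mat))
  mat
}

#' Rank genes by regression residuals of test-condition editing
#'
#' Ordinary least squares of per-gene editing events in the test condition
#' on events in the background condition, with intercept. The ranking
#' statistic is the internally studentized residual
#' \eqn{e_i / (s \sqrt{1 - h_i})} (the conventional reading of
#' "standardized residuals"); genes with the most editing above the
#' background trend rank first. Ties break by ascending gene identifier.
#'
#' @param matrix An [aggregate_utr_editing()] matrix (or any genes x
#'   conditions matrix with rownames).
#' @param test_condition,background_condition Column names: the condition
#'   whose excess editing is of interest (y) and the editing background
#'   (x).
#' @param studentized Use studentized residuals (default); otherwise raw.
#' @return `data.frame`: `gene_id`, `x`, `y`, `fitted`, `std_residual`,
#'   `rank`, `class` (filled by [select_top_background()]).
#' @export
rank_residuals <- function(matrix, test_condition, background_condition,
                           studentized = TRUE) {
  stopifnot(test_condition %in% colnames(matrix),
            background_condition %in% colnames(matrix))
  x <- as.numeric(matrix[, background_condition])
  y <- as.numeric(matrix[, test_condition])
  fin <- is.finite(x) & is.finite(y)
  if (sum(fin) < 3L) stopf("need at least 3 genes with finite values")
  if (var(x[fin]) == 0)
    stopf(paste0("background-condition events have zero variance; ",
                 "rank by the test-condition counts instead"))
  gene_id <- rownames(matrix)
  fit <- lm(y ~ x, subset = fin)
  perfect <- stats::sigma(fit) < 1e-8 * (1 + mean(abs(y[fin])))
  res <- if (studentized && !perfect) rstandard(fit)
         else if (perfect) rep(0, sum(fin))
         else stats::residuals(fit)
  res[!is.finite(res)] <- 0          # zero-leverage degenerate rows
  out <- data.frame(gene_id = gene_id[fin], x = x[fin], y = y[fin],
                    fitted = stats::fitted(fit), std_residual = res,
                    stringsAsFactors = FALSE)
  ord <- order(-out$std_residual, out$gene_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$class <- "neither"
  rownames(out) <- NULL
  out
}

#' Select top-ranked targets and bottom-ranked background genes
#'
#' The `K_top` highest-residual genes are the fusion-specific targets; the
#' `K_bg` lowest-residual genes are the deaminase-only background set.
#' When the ranking is shorter than `K_top + K_bg`, both are shrunk to
#' half the available genes with a warning.
#'
#' @param ranked Output of [rank_residuals()].
#' @param K_top,K_bg Set sizes (defaults 1000/1000).
#' @return list: `targets`, `background` (character vectors), `ranked`
#'   (with `class` filled in), `K_top`, `K_bg`.
#' @export
select_top_background <- function(ranked, K_top = 1000L, K_bg = 1000L) {
  n <- nrow(ranked)
  if (K_top + K_bg > n) {
    K_top <- min(K_top, floor(n / 2))
    K_bg <- min(K_bg, n - K_top)
    warnf("ranking has %d genes; shrinking selections to %d/%d", n,
          K_top, K_bg)
  }
  ranked$class <- "neither"
  if (K_top > 0) ranked$class[seq_len(K_top)] <- "agoTRIBE"
  if (K_bg > 0) ranked$class[n - seq_len(K_bg) + 1L] <- "background"
  list(targets = ranked$gene_id[ranked$class == "agoTRIBE"],
       background = ranked$gene_id[ranked$class == "background"],
       ranked = ranked, K_top = K_top, K_bg = K_bg)
}
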