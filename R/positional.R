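## positional: editing vs binding-site distances within 3'UTRs -------------

#' Select 3'UTRs eligible for positional comparison
#'
#' Keeps genes with monoexonic (single-interval) 3'UTRs, takes the largest
#' isoform per gene (longest UTR; ties break by ascending transcript
#' identifier), requires exactly one binding-site event inside that UTR,
#' and discards UTRs shorter than 40 bp.
#'
#' @param annotation A [utr_set()].
#' @param clip_events data.frame with `contig` and `pos` (1-based) of
#'   binding-site events (e.g. crosslinking peaks summarized to points).
#' @param min_length Minimum UTR length (default 40 bp).
#' @return `data.table` with one row per eligible gene: `gene_id`,
#'   `transcript_id`, `contig`, `start`, `end`, `strand`, `length`,
#'   `clip_pos` (genomic) and `clip_local` (UTR-local, 1-based from the 5'
#'   end of the UTR in transcript orientation).
#' @export
select_eligible_utrs <- function(annotation, clip_events, min_length = 40L) {
  ann <- as.data.table(annotation)
  n_iv <- ann[, .N, by = transcript_id]
  mono <- ann[transcript_id %in% n_iv$transcript_id[n_iv$N == 1L]]
  if (!nrow(mono)) return(mono[, .(gene_id, transcript_id, contig, start,
                                   end, strand)][0])
  mono[, length := end - start + 1L]
  setorder(mono, gene_id, -length, transcript_id)
  largest <- mono[, .SD[1L], by = gene_id]
  ce <- as.data.table(clip_events)
  hits <- merge(largest, ce[, .(contig, clip_pos = as.integer(pos))],
                by = "contig", allow.cartesian = TRUE)
  hits <- hits[clip_pos >= start & clip_pos <= end]
  cnt <- hits[, .N, by = gene_id]
  one <- hits[gene_id %in% cnt$gene_id[cnt$N == 1L]]
  one <- one[length >= min_length]
  one[, clip_local := fifelse(strand == "+", clip_pos - start + 1L,
                              end - clip_pos + 1L)]
  setorder(one, gene_id)
  one[, .(gene_id, transcript_id, contig, start, end, strand, length,
          clip_pos, clip_local)]
}

#' Observed distances between editing events and binding sites
#'
#' For each eligible gene, the absolute bp distance between every editing
#' event inside the UTR and the gene's single binding site. All events
#' contribute by default; `nearest_only` keeps only each gene's closest
#' event.
#'
#' @param eligible Output of [select_eligible_utrs()].
#' @param editing_events An [editing_events()] table (genomic 1-based
#'   positions).
#' @param nearest_only Keep only the nearest event per gene.
#' @return Named numeric vector of distances (names are gene identifiers).
#' @export
observed_distances <- function(eligible, editing_events,
                               nearest_only = FALSE) {
  ev <- as.data.table(editing_events)
  el <- as.data.table(eligible)
  hits <- merge(el, ev[, .(contig, epos = pos)], by = "contig",
                allow.cartesian = TRUE)
  hits <- hits[epos >= start & epos <= end]
  if (!nrow(hits)) return(stats::setNames(numeric(), character()))
  hits[, dist := abs(epos - clip_pos)]
  if (nearest_only) hits <- hits[, .SD[which.min(dist)], by = gene_id]
  stats::setNames(as.numeric(hits$dist), hits$gene_id)
}

#' Uniform-random background distances
#'
#' For each of `n_iter` iterations and each eligible UTR, draws one dummy
#' editing position uniformly over the UTR (integer positions 1..L in
#' UTR-local coordinates) and records its distance to the binding site.
#' For a site at local position s in a UTR of length L the expected
#' distance is \eqn{(s^2 + (L-s)^2) / (2L)} as the number of draws grows.
#'
#' @param eligible Output of [select_eligible_utrs()].
#' @param n_iter Iterations (default 100; one dummy per gene per
#'   iteration).
#' @param seed Seed for the draws.
#' @return Numeric vector of length `n_iter * nrow(eligible)`.
#' @export
background_distances <- function(eligible, n_iter = 100L, seed = NULL) {
  el <- as.data.table(eligible)
  if (!nrow(el)) return(numeric())
  draw <- function() {
    L <- rep(el$length, n_iter)
    s <- rep(el$clip_local, n_iter)
    dummy <- 1L + floor(runif(length(L)) * L)
    abs(dummy - s)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assemble the two-class distance table
#'
#' @param observed Output of [observed_distances()].
#' @param background Output of [background_distances()].
#' @return `data.frame` with `class` (`observed` / `background`) and
#'   `distance`, the on-disk interchange format of this analysis.
#' @export
distance_table <- function(observed, background) {
  data.frame(
    class = rep(c("observed", "background"),
                c(length(observed), length(background))),
    distance = c(as.numeric(observed), as.numeric(background)))
}
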