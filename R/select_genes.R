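#' Resolve overlapping ORFs into a gene set
#'
#' The maximal-ORF scan of [predict_orfs()] reports every qualifying ORF in
#' all six frames, so overlapping calls in different frames are common and
#' a raw multiplicity-counted coding density computed on its output is
#' inflated far beyond what a production gene caller reports. This step
#' emulates the one-gene-per-locus behaviour of such callers with a
#' deterministic greedy rule: ORFs are ranked by decreasing length (ties by
#' start, end, strand) and kept unless they overlap an already-kept gene by
#' more than `max_overlap` nt (small overlaps between adjacent genes are
#' normal in phage genomes and are allowed).
#'
#' @param genes Gene-model data frame from [predict_orfs()].
#' @param max_overlap Maximum tolerated overlap with a kept gene, nt
#'   (default 60).
#' @return The selected subset, sorted by (`start`, `end`), with the same
#'   columns.
#' @export
select_genes <- function(genes, max_overlap = 60L) {
  if (nrow(genes) <= 1L) return(genes)
  len <- genes$end - genes$start
  ord <- order(-len, genes$start, genes$end, genes$strand)
  ir <- IRanges::IRanges(genes$start + 1L, genes$end)
  # conflicts: pairs overlapping by more than max_overlap nt
  hits <- IRanges::findOverlaps(ir, minoverlap = max_overlap + 1L,
                                drop.self = TRUE)
  conflict <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  keep <- logical(nrow(genes))
  blocked <- logical(nrow(genes))
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    cf <- conflict[[as.character(i)]]
    if (!is.null(cf)) blocked[cf] <- TRUE
  }
  out <- genes[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
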