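#' Predict open reading frames under a chosen genetic code
#'
#' Deterministic maximal-ORF caller over all six reading frames. Within each
#' frame, every stop-to-stop interval is scanned for its first (most
#' upstream) start codon, and a single ORF is emitted from that start to the
#' terminating stop codon; intervals running off the contig edge are emitted
#' without a stop (`includes_stop_codon = FALSE`). Codons containing N never
#' act as starts or stops and translate to X. There is no coding-statistics
#' or RBS scoring: the caller is intentionally simple so that the contrast
#' between translation tables (gene fragmentation under code 11 versus
#' restored frames under code 15) is driven by the code alone.
#'
#' Coordinates are 0-based half-open on the forward strand; minus-strand
#' genes store forward-axis coordinates and their protein is read from the
#' reverse complement.
#'
#' @param ctg A [contig] object.
#' @param table A `code_table` from [load_code_table()].
#' @param min_protein_len Minimum protein length (residues, stop excluded)
#'   for an ORF to be reported. Default 50: an unscored caller accepts any
#'   qualifying ORF, so it needs a higher floor than a scored caller's
#'   conventional 30 residues to keep chance ORFs (frequent even in AT-rich
#'   sequence) from flooding the gene set and the coding-density measure.
#'
#' @return A data frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `code_id`, `protein`, `includes_stop_codon`, sorted by
#'   (`start`, `end`, `strand`).
#'
#' @examples
#' ctg <- contig("c", "ATGAAATAGGAATAA")
#' predict_orfs(ctg, load_code_table(11), min_protein_len = 1)$protein  # "MK"
#' predict_orfs(ctg, load_code_table(15), min_protein_len = 1)$protein  # "MKQE"
#'
#' @export
predict_orfs <- function(ctg, table, min_protein_len = 50L) {
  stopifnot(inherits(ctg, "contig"), inherits(table, "code_table"),
            min_protein_len >= 0L)
  L <- nchar(ctg$sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") ctg$sequence else revcomp(ctg$sequence)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons < 1L) next
      cs <- frame + (seq_len(n_codons) - 1L) * 3L + 1L  # 1-based codon starts
      codons <- substring(sq, cs, cs + 2L)
      res <- .translate_codons(codons, table)
      is_stop <- res == "*"
      is_start <- codons %in% table$start_codons & !is_stop
      res_str <- paste(res, collapse = "")

      s_idx <- which(is_stop)
      begins <- c(1L, s_idx + 1L)                 # first codon of each interval
      last_res <- c(s_idx - 1L, n_codons)         # last non-stop codon
      stop_idx <- c(s_idx, NA_integer_)           # terminating stop codon index
      start_pos <- which(is_start)
      if (length(start_pos) == 0L) next
      first_start <- start_pos[findInterval(begins - 0.5, start_pos) + 1L]
      keep <- !is.na(first_start) & first_start <= last_res
      if (!any(keep)) next
      fs <- first_start[keep]
      lr <- last_res[keep]
      si <- stop_idx[keep]
      plen <- lr - fs + 1L
      ok <- plen >= min_protein_len
      if (!any(ok)) next
      fs <- fs[ok]; lr <- lr[ok]; si <- si[ok]
      protein <- substring(res_str, fs, lr)
      has_stop <- !is.na(si)
      end_codon <- ifelse(has_stop, si, lr)
      # local 0-based half-open coords on the scanned strand
      loc_start <- frame + (fs - 1L) * 3L
      loc_end <- frame + end_codon * 3L
      if (strand == "+") {
        g_start <- loc_start; g_end <- loc_end
      } else {
        g_start <- L - loc_end; g_end <- L - loc_start
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = ctg$contig_id, start = g_start, end = g_end,
        strand = strand, code_id = table$code_id, protein = protein,
        includes_stop_codon = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), code_id = integer(0),
                      protein = character(0),
                      includes_stop_codon = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(gene_id = paste0(ctg$contig_id, "_", seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the genomic coding sequence of a gene model
#'
#' Returns the strand-oriented nucleotide sequence of the gene span, i.e.
#' the sequence whose codon-wise translation (under the gene's code)
#' reproduces the stored protein.
#'
#' @param gene A single gene-model row (data frame or list).
#' @param ctg The [contig] the gene lies on.
#' @return DNA string in gene orientation.
#' @export
gene_cds <- function(gene, ctg) {
  stopifnot(inherits(ctg, "contig"))
  s <- substr(ctg$sequence, gene$start + 1L, gene$end)
  if (gene$strand == "-") s <- revcomp(s)
  s
}
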