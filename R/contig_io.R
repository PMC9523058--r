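#' Contig constructor
#'
#' A contig is a named DNA sequence with a topology flag. Sequences are
#' uppercased on construction; only A, C, G, T, N are accepted. Circular
#' contigs are analysed as linear sequences (no origin-spanning genes); the
#' flag is retained for reporting.
#'
#' @param contig_id Character scalar identifier.
#' @param sequence DNA string.
#' @param topology `"linear"` or `"circular"`.
#'
#' @return An object of class `contig`.
#' @export
contig <- function(contig_id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("contig sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", sequence)) {
    stop("contig '", contig_id,
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(list(contig_id = contig_id, sequence = sequence,
                 topology = topology), class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig>", x$contig_id, "-", nchar(x$sequence), "nt,", x$topology, "\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string over A, C, G, T, N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read contigs from a FASTA file
#'
#' Sequences are uppercased (soft-masked lowercase bases normalised) and
#' returned as a list of [contig] objects.
#'
#' @param path Path to a FASTA file of nucleotide sequences.
#' @param topology Topology flag assigned to every contig.
#' @return A named list of `contig` objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first) || !startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in '", path, "': expected '>' header at line ",
         if (is.na(first)) 1L else first, call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in '", path, "'", call. = FALSE)
  }
  out <- lapply(seq_along(ss), function(i) {
    contig(ids[i], as.character(ss[[i]]), topology)
  })
  stats::setNames(out, ids)
}

#' Write sequences to a FASTA file
#'
#' Accepts a list of [contig] objects (written as DNA) or a named character
#' vector (written as-is, e.g. protein sequences).
#'
#' @param records List of `contig` objects or named character vector.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  if (is.list(records) && inherits(records[[1L]], "contig")) {
    seqs <- vapply(records, function(x) x$sequence, character(1))
    names(seqs) <- vapply(records, function(x) x$contig_id, character(1))
    ss <- Biostrings::DNAStringSet(seqs)
  } else {
    stopifnot(is.character(records), !is.null(names(records)))
    ss <- Biostrings::BStringSet(records)
  }
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 uses 1-based inclusive
#' coordinates (`start0 + 1`, `end0`). The genetic code and whether the span
#' includes the terminal stop codon are carried as attributes.
#'
#' @param genes A gene-model data frame as produced by [predict_orfs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges   = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand   = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$code_id <- genes$code_id
  S4Vectors::mcols(gr)$includes_stop_codon <- genes$includes_stop_codon
  S4Vectors::mcols(gr)$source <- "ambercode"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
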