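#' Genetic code tables for standard and amber-suppressed translation
#'
#' Builds a genetic code table for NCBI translation table 11 (the standard
#' bacterial/archaeal code) or table 15 (identical to table 11 except that
#' the amber stop codon TAG is read as glutamine, Q). Table 15 is the code
#' used by several crAss-like gut phages, where TAG recoding restores open
#' reading frames that appear fragmented under the standard code.
#'
#' @param code_id Integer translation table identifier; one of 11 or 15.
#'
#' @return An object of class `code_table`: a list with elements
#'   `code_id` (integer), `codon_map` (named character vector over all 64
#'   DNA codons; stops map to `"*"`), `start_codons` and `stop_codons`
#'   (character vectors). Table 15 permits only ATG as a start codon;
#'   table 11 defaults to ATG, GTG and TTG.
#'
#' @examples
#' tab <- load_code_table(15)
#' tab$codon_map[["TAG"]]  # "Q"
#'
#' @export
load_code_table <- function(code_id) {
  code_id <- as.integer(code_id)
  if (length(code_id) != 1L || is.na(code_id) || !code_id %in% c(11L, 15L)) {
    stop("unsupported genetic code table: ", code_id,
         " (supported: 11, 15)", call. = FALSE)
  }
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  # standard code residues in TCAG order (first base slowest)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codon_map <- stats::setNames(aa, codons)
  if (code_id == 15L) {
    codon_map[["TAG"]] <- "Q"
    start_codons <- "ATG"
  } else {
    start_codons <- c("ATG", "GTG", "TTG")
  }
  structure(list(
    code_id      = code_id,
    codon_map    = codon_map,
    start_codons = start_codons,
    stop_codons  = names(codon_map)[codon_map == "*"]
  ), class = "code_table")
}

#' @export
print.code_table <- function(x, ...) {
  cat("<code_table> translation table", x$code_id, "\n")
  cat("  stop codons:", paste(x$stop_codons, collapse = ", "), "\n")
  cat("  start codons:", paste(x$start_codons, collapse = ", "), "\n")
  invisible(x)
}

# split a CDS string into its consecutive codons
.codon_split <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(cds, starts, starts + 2L)
}

# codon-wise residue lookup; codons containing N (or anything not in the
# 64-codon table) translate to X
.translate_codons <- function(codons, table) {
  res <- unname(table$codon_map[codons])
  res[is.na(res)] <- "X"
  res
}

#' Translate a coding sequence under a chosen genetic code
#'
#' Codon-wise translation of an in-frame DNA string. Codons containing an
#' ambiguous base (N) translate to `X` and never act as stops. Internal
#' stop codons are handled according to `stop_policy`.
#'
#' @param cds DNA string over A, C, G, T, N; length must be a multiple of 3.
#' @param table A `code_table` from [load_code_table()].
#' @param stop_policy One of `"truncate"` (return residues before the first
#'   stop), `"error"` (fail on any stop codon), or `"readthrough"` (render
#'   stops as `*` and keep translating).
#'
#' @return A single residue string.
#'
#' @examples
#' translate_cds("ATGAAATAGGAA", load_code_table(15))  # "MKQE"
#' translate_cds("ATGAAATAGGAA", load_code_table(11))  # "MK"
#'
#' @export
translate_cds <- function(cds, table,
                          stop_policy = c("truncate", "error", "readthrough")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(table, "code_table"))
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length (", nchar(cds),
         ") is not a multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGTN]", cds)) {
    stop("coding sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  res <- .translate_codons(.codon_split(cds), table)
  stop_at <- which(res == "*")
  if (length(stop_at)) {
    if (stop_policy == "error") {
      stop("stop codon at codon position ", stop_at[1L], call. = FALSE)
    }
    if (stop_policy == "truncate") {
      res <- res[seq_len(stop_at[1L] - 1L)]
    }
  }
  paste(res, collapse = "")
}
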