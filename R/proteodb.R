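# monoisotopic residue masses (Da), standard 20-letter alphabet
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.007276
.MOD_CAM <- 57.021464   # carbamidomethyl (fixed, Cys)
.MOD_OX <- 15.994915    # oxidation (variable, Met)

#' Monoisotopic peptide masses with fixed and variable modifications
#'
#' Computes the monoisotopic mass of a peptide (residue masses plus water),
#' applying a fixed modification to every cysteine and enumerating every
#' combination of variable-modification counts up to `max_var`. Variable
#' modifications are counted per modifiable residue type (site-count
#' enumeration, not per-site assignment, since site permutations are
#' isobaric).
#'
#' @param sequence Peptide string over the 20-letter residue alphabet.
#' @param fixed_cys_mod Mass added to every C (Da); default
#'   carbamidomethylation, +57.021464.
#' @param variable_mods Named numeric vector mapping residue letters to
#'   modification masses; default Met oxidation, +15.994915.
#' @param max_var Maximum total number of variable modifications (default 3).
#' @return Data frame with columns `mass` (Da), `n_var_mods`, and
#'   `modifications` (text such as `"2xM+15.9949"`, empty for the
#'   unmodified form), one row per mass variant.
#' @export
peptide_mass <- function(sequence, fixed_cys_mod = .MOD_CAM,
                         variable_mods = c(M = .MOD_OX), max_var = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), names(.AA_MONO))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  base <- sum(.AA_MONO[res]) + .MASS_WATER + fixed_cys_mod * sum(res == "C")
  if (length(variable_mods) == 0L || max_var == 0L) {
    return(data.frame(mass = base, n_var_mods = 0L, modifications = "",
                      stringsAsFactors = FALSE))
  }
  site_counts <- vapply(names(variable_mods),
                        function(a) sum(res == a), integer(1))
  grids <- lapply(seq_along(variable_mods),
                  function(i) 0:min(site_counts[i], max_var))
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) <= max_var, , drop = FALSE]
  mass <- base + as.vector(as.matrix(combos) %*% variable_mods)
  lab <- apply(combos, 1L, function(k) {
    on <- which(k > 0)
    if (!length(on)) return("")
    paste(sprintf("%dx%s%+.4f", k[on], names(variable_mods)[on],
                  variable_mods[on]), collapse = ",")
  })
  out <- data.frame(mass = mass, n_var_mods = as.integer(rowSums(combos)),
                    modifications = lab, stringsAsFactors = FALSE)
  out[order(out$n_var_mods, out$mass), , drop = FALSE]
}

# trypsin cleavage sites of a protein: 1-based residue indices i such that
# cleavage occurs after residue i (K/R not followed by P)
.tryptic_sites <- function(res) {
  n <- length(res)
  if (n < 2L) return(integer(0))
  which(res[-n] %in% c("K", "R") & res[-1L] != "P")
}

#' In-silico tryptic digestion
#'
#' Trypsin cleaves after K or R except before P. With
#' `specificity = "full"`, peptides are concatenations of consecutive fully
#' tryptic fragments with at most `max_missed` internal cleavage sites. With
#' `specificity = "semi"`, peptides with exactly one tryptic terminus (the
#' other terminus anywhere in the protein) are additionally emitted, so the
#' semi-specific output is a superset of the full-specific output. The
#' protein N- and C-termini count as tryptic. No length bounds are applied
#' unless `min_len`/`max_len` are set (a search-engine window such as 6-50
#' residues is applied by the callers that emulate a search).
#'
#' @param proteins Named character vector of protein sequences, or a
#'   protein-database data frame with columns `record_id` and `sequence`.
#' @param max_missed Maximum internal missed cleavages (default 3).
#' @param specificity `"full"` or `"semi"`.
#' @param min_len,max_len Peptide length bounds (residues).
#' @return Data frame with columns `sequence`, `parent_id`, `start`
#'   (0-based offset in the parent), `length`, `missed_cleavages`,
#'   `specificity` (`full`, `semi-N` for a tryptic N-terminus only,
#'   `semi-C` for a tryptic C-terminus only) and `mono_mass` (Da, fixed Cys
#'   modification included). Duplicates by (sequence, parent, offset) are
#'   removed; a peptide tryptic at both ends is always reported as `full`.
#' @export
digest_protein <- function(proteins, max_missed = 3L,
                           specificity = c("full", "semi"),
                           min_len = 1L, max_len = Inf) {
  specificity <- match.arg(specificity)
  if (is.data.frame(proteins)) {
    seqs <- stats::setNames(proteins$sequence, proteins$record_id)
  } else {
    stopifnot(is.character(proteins), !is.null(names(proteins)))
    seqs <- proteins
  }
  out <- lapply(names(seqs), function(id) {
    .digest_one(seqs[[id]], id, max_missed, specificity, min_len, max_len)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.digest_one <- function(sq, id, max_missed, specificity, min_len, max_len) {
  if (!nzchar(sq)) stop("empty protein sequence: ", id, call. = FALSE)
  res <- strsplit(sq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  sites <- .tryptic_sites(res)
  nterm <- c(0L, sites)        # 0-based start offsets with tryptic N-terminus
  cterm <- c(sites, n)         # exclusive ends with tryptic C-terminus
  pairs_s <- integer(0); pairs_e <- integer(0)
  # fully tryptic: each tryptic start with the next <= max_missed+1 tryptic ends
  for (s0 in nterm) {
    ends <- cterm[cterm > s0]
    ends <- ends[seq_len(min(length(ends), max_missed + 1L))]
    pairs_s <- c(pairs_s, rep.int(s0, length(ends)))
    pairs_e <- c(pairs_e, ends)
  }
  if (specificity == "semi") {
    for (s0 in nterm) {
      after <- sites[sites > s0]
      e_max <- if (length(after) > max_missed) after[max_missed + 1L] else n
      e_lo <- s0 + max(1L, min_len)
      if (e_lo <= e_max) {
        ee <- seq.int(e_lo, min(e_max, s0 + max_len))
        pairs_s <- c(pairs_s, rep.int(s0, length(ee)))
        pairs_e <- c(pairs_e, ee)
      }
    }
    for (e in cterm) {
      before <- sites[sites < e]
      s_min <- if (length(before) > max_missed) {
        before[length(before) - max_missed]
      } else 0L
      s_hi <- e - max(1L, min_len)
      if (s_min <= s_hi) {
        ss <- seq.int(max(s_min, e - max_len), s_hi)
        pairs_s <- c(pairs_s, ss)
        pairs_e <- c(pairs_e, rep.int(e, length(ss)))
      }
    }
  }
  len <- pairs_e - pairs_s
  keep <- len >= min_len & len <= max_len
  pairs_s <- pairs_s[keep]; pairs_e <- pairs_e[keep]
  dup <- duplicated(paste(pairs_s, pairs_e))
  pairs_s <- pairs_s[!dup]; pairs_e <- pairs_e[!dup]
  if (length(pairs_s) == 0L) {
    return(data.frame(sequence = character(0), parent_id = character(0),
                      start = integer(0), length = integer(0),
                      missed_cleavages = integer(0),
                      specificity = character(0), mono_mass = numeric(0),
                      stringsAsFactors = FALSE))
  }
  missed <- vapply(seq_along(pairs_s), function(i) {
    sum(sites > pairs_s[i] & sites < pairs_e[i])
  }, integer(1))
  nt_ok <- pairs_s %in% nterm
  ct_ok <- pairs_e %in% cterm
  spec <- ifelse(nt_ok & ct_ok, "full", ifelse(nt_ok, "semi-N", "semi-C"))
  # cumulative residue masses (fixed Cys mod folded in) for O(1) peptide mass
  cum <- c(0, cumsum(.AA_MONO[res] + ifelse(res == "C", .MOD_CAM, 0)))
  if (anyNA(cum)) {
    bad <- setdiff(unique(res), names(.AA_MONO))
    stop("unknown residue(s) in ", id, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mass <- cum[pairs_e + 1L] - cum[pairs_s + 1L] + .MASS_WATER
  out <- data.frame(
    sequence = substring(sq, pairs_s + 1L, pairs_e),
    parent_id = id, start = pairs_s, length = pairs_e - pairs_s,
    missed_cleavages = missed, specificity = spec, mono_mass = mass,
    stringsAsFactors = FALSE)
  out[order(out$start, out$length), , drop = FALSE]
}

#' Upstream start-extension of a code-15 gene
#'
#' Translates the in-frame codons strictly between the nearest upstream
#' in-frame TAA or TGA (or the 30-residue cap, or the contig edge, whichever
#' comes first) and the annotated start codon. Translation uses code 15, so
#' an upstream TAG reads as Q and is *not* a boundary: under the amber-
#' suppressed code only TAA and TGA terminate translation. The returned
#' string is what gets prepended to the protein in an extended database
#' record, used to test whether translation initiates upstream of the
#' predicted start.
#'
#' @param gene A single code-15 gene-model row.
#' @param ctg The [contig] the gene lies on.
#' @param max_ext Maximum extension length in residues (default 30).
#' @return Residue string (possibly empty).
#' @export
upstream_extension <- function(gene, ctg, max_ext = 30L) {
  stopifnot(inherits(ctg, "contig"))
  tab15 <- load_code_table(15L)
  L <- nchar(ctg$sequence)
  res <- character(0)
  for (k in seq_len(max_ext)) {
    if (gene$strand == "+") {
      s0 <- gene$start - 3L * k
      if (s0 < 0L) break
      codon <- substr(ctg$sequence, s0 + 1L, s0 + 3L)
    } else {
      e0 <- gene$end + 3L * k
      if (e0 > L) break
      codon <- revcomp(substr(ctg$sequence, e0 - 2L, e0))
    }
    if (codon %in% c("TAA", "TGA")) break
    res <- c(res, .translate_codons(codon, tab15))
  }
  paste(rev(res), collapse = "")
}

#' Build the layered proteome search database
#'
#' Assembles the search database used to interrogate peptide identifications
#' for stop-codon reassignment: one record per code-11 gene, per code-15
#' gene, and per code-15 gene with a non-empty upstream start-extension
#' (a separate suffix-tagged record, so that peptide evidence upstream of
#' the annotated start remains distinguishable by parent id), plus auxiliary
#' proteomes (e.g. host), contaminants, and, when `with_decoys`, one
#' whole-sequence reversed decoy per target record (id prefix `rev_`).
#'
#' @param genes_11,genes_15 Gene models predicted under tables 11 and 15.
#' @param ctg The [contig] the genes lie on (needed for extensions).
#' @param auxiliary,contaminants Named character vectors of protein
#'   sequences (or `NULL`).
#' @param with_decoys Append reversed decoys (default `TRUE`).
#' @param max_ext Upstream extension cap in residues (default 30).
#' @return A data frame of class `protein_db` with columns `record_id`,
#'   `sequence`, `source` (`phage-code11`, `phage-code15`,
#'   `phage-code15-extended`, `auxiliary`, `contaminant`), `gene_id`,
#'   `extension_len`, `is_decoy`.
#' @export
build_protein_db <- function(genes_11, genes_15, ctg,
                             auxiliary = NULL, contaminants = NULL,
                             with_decoys = TRUE, max_ext = 30L) {
  stopifnot(inherits(ctg, "contig"))
  mk <- function(ids, seqs, source, gene_ids, ext) {
    data.frame(record_id = ids, sequence = seqs, source = source,
               gene_id = gene_ids, extension_len = ext, is_decoy = FALSE,
               stringsAsFactors = FALSE)
  }
  parts <- list()
  if (nrow(genes_11)) {
    parts$c11 <- mk(paste0("c11|", genes_11$gene_id), genes_11$protein,
                    "phage-code11", genes_11$gene_id, 0L)
  }
  if (nrow(genes_15)) {
    parts$c15 <- mk(paste0("c15|", genes_15$gene_id), genes_15$protein,
                    "phage-code15", genes_15$gene_id, 0L)
    ext <- vapply(seq_len(nrow(genes_15)), function(i) {
      upstream_extension(genes_15[i, ], ctg, max_ext)
    }, character(1))
    has <- nzchar(ext)
    if (any(has)) {
      parts$c15ext <- mk(paste0("c15ext|", genes_15$gene_id[has]),
                         paste0(ext[has], genes_15$protein[has]),
                         "phage-code15-extended", genes_15$gene_id[has],
                         nchar(ext[has]))
    }
  }
  if (!is.null(auxiliary) && length(auxiliary)) {
    parts$aux <- mk(paste0("aux|", names(auxiliary)), unname(auxiliary),
                    "auxiliary", NA_character_, 0L)
  }
  if (!is.null(contaminants) && length(contaminants)) {
    parts$cont <- mk(paste0("cont|", names(contaminants)),
                     unname(contaminants), "contaminant", NA_character_, 0L)
  }
  db <- do.call(rbind, parts)
  if (is.null(db) || nrow(db) == 0L) {
    stop("no records: both gene sets empty and no auxiliary input",
         call. = FALSE)
  }
  rownames(db) <- NULL
  if (with_decoys) {
    dec <- db
    dec$record_id <- paste0("rev_", db$record_id)
    dec$sequence <- vapply(db$sequence, function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    dec$is_decoy <- TRUE
    db <- rbind(db, dec)
  }
  if (anyDuplicated(db$record_id)) {
    stop("record id collision: ",
         paste(unique(db$record_id[duplicated(db$record_id)]),
               collapse = ", "), call. = FALSE)
  }
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Write a protein database to FASTA
#'
#' Headers carry provenance `record_id source gene_id extension_len decoy`
#' delimited by `|` beyond the id's own tags.
#'
#' @param db A `protein_db` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(db, path) {
  hdr <- paste(db$record_id, db$source,
               ifelse(is.na(db$gene_id), ".", db$gene_id),
               db$extension_len,
               ifelse(db$is_decoy, "decoy", "target"), sep = "|")
  write_fasta(stats::setNames(db$sequence, hdr), path)
}
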