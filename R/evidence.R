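#' Read a peptide-identification (PSM) table
#'
#' Consumes the tab-separated export of a database search engine. Required
#' columns: `peptide`, `score`, `parents` (matched database record ids,
#' `;`-delimited). Modification annotations embedded in the peptide string
#' as parenthesised mass deltas, e.g. `"VM(+15.99)K"`, are stripped into a
#' side table attached as `attr(x, "modifications")`.
#'
#' A PSM is a decoy when *all* its parents carry the `rev_` decoy prefix;
#' PSMs with mixed target/decoy parents are classified as targets (standard
#' convention) and flagged in `mixed_parents`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `peptide` (stripped), `peptide_raw`,
#'   `score`, `parents`, `is_decoy`, `mixed_parents`.
#' @export
read_psm_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("peptide", "score", "parents")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw <- as.character(x$peptide)
  stripped <- gsub("\\([+-][0-9.]+\\)", "", raw)
  mods <- lapply(seq_along(raw), function(i) {
    m <- gregexpr("\\(([+-][0-9.]+)\\)", raw[i])[[1L]]
    if (m[1L] == -1L) return(NULL)
    pre <- gsub("\\([+-][0-9.]+\\)", "",
                substring(raw[i], 1L, m - 1L))
    data.frame(psm_row = i, position = nchar(pre),
               delta = as.numeric(gsub("[()]", "",
                                       regmatches(raw[i], m)[[1L]])),
               stringsAsFactors = FALSE)
  })
  mods <- do.call(rbind, mods)
  parent_list <- strsplit(as.character(x$parents), ";", fixed = TRUE)
  dec <- vapply(parent_list, function(p) all(startsWith(p, "rev_")), logical(1))
  mixed <- vapply(parent_list, function(p) {
    any(startsWith(p, "rev_")) && !all(startsWith(p, "rev_"))
  }, logical(1))
  out <- data.frame(peptide = stripped, peptide_raw = raw,
                    score = as.numeric(x$score),
                    parents = as.character(x$parents),
                    is_decoy = dec, mixed_parents = mixed,
                    stringsAsFactors = FALSE)
  attr(out, "modifications") <- mods
  out
}

#' Read a de novo sequence-tag table
#'
#' Required columns: `sequence`, `alc` (average local confidence, percent)
#' and `residue_conf` (`;`-delimited per-residue confidences, percent).
#' Rows whose confidence list length does not match the sequence length, or
#' whose ALC deviates from the mean residue confidence by more than 0.5, are
#' rejected with a warning.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `sequence`, `alc` and list-column
#'   `residue_conf`.
#' @export
read_tag_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sequence", "alc", "residue_conf")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("tag table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  conf <- lapply(strsplit(as.character(x$residue_conf), ";", fixed = TRUE),
                 as.numeric)
  len_ok <- lengths(conf) == nchar(x$sequence) &
    !vapply(conf, anyNA, logical(1))
  alc_ok <- rep(FALSE, nrow(x))
  alc_ok[len_ok] <- abs(vapply(conf[len_ok], mean, numeric(1)) -
                          x$alc[len_ok]) <= 0.5
  bad <- !(len_ok & alc_ok)
  if (any(bad)) {
    warning(sum(bad), " tag row(s) rejected (confidence list/ALC mismatch)",
            call. = FALSE)
  }
  out <- data.frame(sequence = as.character(x$sequence)[!bad],
                    alc = as.numeric(x$alc)[!bad],
                    stringsAsFactors = FALSE)
  out$residue_conf <- conf[!bad]
  out
}

#' Peptide-level target-decoy FDR filtering
#'
#' Collapses PSMs to the best-scoring PSM per (modification-stripped)
#' peptide sequence, ranks peptides by decreasing score (decoys before
#' targets at score ties, the conservative choice), estimates the FDR at
#' each rank as decoys/targets at or above that rank, monotonises into
#' q-values by a running minimum from the bottom of the list, and accepts
#' target peptides with q-value at or below `threshold`.
#'
#' @param psms PSM data frame from [read_psm_table()] (columns `peptide`,
#'   `score`, `is_decoy`; other columns carried through).
#' @param threshold Peptide-level FDR threshold (default 0.01).
#' @return List with `accepted` (accepted target peptides) and `table`
#'   (all collapsed peptides with `q_value` and `accepted` columns), both
#'   sorted by decreasing score.
#' @export
fdr_filter <- function(psms, threshold = 0.01) {
  stopifnot(is.data.frame(psms),
            all(c("peptide", "score", "is_decoy") %in% names(psms)))
  if (nrow(psms) == 0L) {
    psms$q_value <- numeric(0); psms$accepted <- logical(0)
    return(list(accepted = psms, table = psms))
  }
  o <- order(psms$peptide, -psms$score)
  best <- psms[o, , drop = FALSE]
  best <- best[!duplicated(best$peptide), , drop = FALSE]
  best <- best[order(-best$score, !best$is_decoy), , drop = FALSE]
  if (!any(best$is_decoy)) {
    warning("no decoy peptides: all q-values set to 0", call. = FALSE)
    best$q_value <- 0
  } else {
    d <- cumsum(best$is_decoy)
    t <- cumsum(!best$is_decoy)
    fdr <- d / pmax(t, 1L)
    best$q_value <- rev(cummin(rev(fdr)))
  }
  best$accepted <- !best$is_decoy & best$q_value <= threshold
  rownames(best) <- NULL
  list(accepted = best[best$accepted, , drop = FALSE], table = best)
}

#' Map a peptide onto the genome, codon by codon
#'
#' Locates every occurrence of a peptide in a database record, traces it to
#' the underlying gene model (applying the upstream-extension offset for
#' extended records, so residues upstream of the annotated start map to
#' negative protein indices and genome coordinates outside the gene span),
#' and assigns each residue its 3-nt genome span on the forward axis. The
#' genomic codon under each residue is looked up literally in the contig;
#' residues sitting on a TAG codon are recorded.
#'
#' @param peptide Modification-stripped residue string.
#' @param record One `protein_db` row (the matched parent).
#' @param gene The gene-model row the record traces to.
#' @param ctg The [contig].
#' @return List of alignments (one per occurrence), each of class
#'   `peptide_alignment`: `peptide`, `record_id`, `gene_id`, `contig_id`,
#'   `strand`, `codon_start` / `codon_end` (per-residue forward-axis spans),
#'   `codons` (literal genomic codons in gene orientation),
#'   `residues_at_TAG` (1-based peptide positions over TAG codons),
#'   `span` (c(min, max) forward-axis extent).
#' @export
map_peptide <- function(peptide, record, gene, ctg) {
  stopifnot(inherits(ctg, "contig"))
  occ <- gregexpr(peptide, record$sequence, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) {
    stop("peptide '", peptide, "' not found in record ", record$record_id,
         call. = FALSE)
  }
  L <- nchar(ctg$sequence)
  np <- nchar(peptide)
  tab15 <- load_code_table(15L)
  lapply(as.integer(occ), function(o) {
    idx <- (o - 1L) - record$extension_len + seq_len(np) - 1L  # codon index
    if (gene$strand == "+") {
      cs <- gene$start + 3L * idx
    } else {
      cs <- gene$end - 3L * (idx + 1L)
    }
    if (any(cs < 0L) || any(cs + 3L > L)) {
      stop("peptide maps outside contig bounds (record ",
           record$record_id, ")", call. = FALSE)
    }
    codons <- substring(ctg$sequence, cs + 1L, cs + 3L)
    if (gene$strand == "-") {
      codons <- vapply(codons, revcomp, character(1), USE.NAMES = FALSE)
    }
    tr <- .translate_codons(codons, tab15)
    pep_res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
    if (!all(tr == pep_res | tr == "X")) {
      stop("genomic translation disagrees with peptide '", peptide,
           "' in record ", record$record_id, call. = FALSE)
    }
    structure(list(
      peptide = peptide, record_id = record$record_id,
      gene_id = gene$gene_id, contig_id = ctg$contig_id,
      strand = gene$strand, codon_start = cs, codon_end = cs + 3L,
      codons = codons, residues_at_TAG = which(codons == "TAG"),
      span = c(min(cs), max(cs) + 3L)
    ), class = "peptide_alignment")
  })
}

#' Classify the recoding evidence carried by a mapped peptide
#'
#' Assigns all applicable evidence classes:
#' \describe{
#'   \item{code15-exclusive}{the peptide is a substring of no target record
#'     other than the code-15 phage proteome (code-11, auxiliary and
#'     contaminant records are all checked); otherwise it is `shared`.}
#'   \item{stop-readthrough}{at least one residue sits on a genomic TAG
#'     codon with at least one residue on each side within the peptide —
#'     direct evidence of translation through an amber stop.}
#'   \item{start-readthrough}{the peptide's genome span properly contains
#'     the start codon of a same-strand, same-frame code-11 gene with at
#'     least one residue upstream of it (in gene orientation) — the peptide
#'     could not exist under standard-code initiation at that start.}
#' }
#'
#' @param alignment A `peptide_alignment` from [map_peptide()].
#' @param db The `protein_db` data frame.
#' @param genes_11 Code-11 gene models on the same contig.
#' @param in_std Optional precomputed logical: does the peptide occur in
#'   any non-code-15 target record? When `NULL` it is computed from `db`.
#' @return Character vector of classes (sorted, unique).
#' @export
classify_peptide <- function(alignment, db, genes_11, in_std = NULL) {
  stopifnot(inherits(alignment, "peptide_alignment"))
  if (is.null(in_std)) {
    std <- db[!db$is_decoy &
                !db$source %in% c("phage-code15", "phage-code15-extended"), ,
              drop = FALSE]
    in_std <- length(.locate_peptides(alignment$peptide,
                                      std$sequence)[[1L]]) > 0L
  }
  classes <- if (in_std) "shared" else "code15-exclusive"
  np <- nchar(alignment$peptide)
  if (any(alignment$residues_at_TAG > 1L & alignment$residues_at_TAG < np)) {
    classes <- c(classes, "stop-readthrough")
  }
  if (nrow(genes_11)) {
    same <- genes_11[genes_11$strand == alignment$strand &
                       genes_11$contig_id == alignment$contig_id, ,
                     drop = FALSE]
    if (nrow(same)) {
      pep_lo <- alignment$span[1L]; pep_hi <- alignment$span[2L]
      if (alignment$strand == "+") {
        frame_ok <- (same$start - min(alignment$codon_start)) %% 3L == 0L
        contained <- pep_lo <= same$start & pep_hi >= same$start + 3L
        upstream <- min(alignment$codon_start) < same$start
      } else {
        frame_ok <- (same$end - max(alignment$codon_end)) %% 3L == 0L
        contained <- pep_lo <= same$end - 3L & pep_hi >= same$end
        upstream <- max(alignment$codon_end) > same$end
      }
      if (any(frame_ok & contained & upstream)) {
        classes <- c(classes, "start-readthrough")
      }
    }
  }
  sort(unique(classes))
}

# locate each peptide in a set of sequences: returns, per peptide, the
# integer indices of the sequences containing it. One C-level search per
# peptide over a \1-joined concatenation (peptides cannot span the
# separator).
.locate_peptides <- function(peptides, seqs) {
  if (length(seqs) == 0L) {
    return(lapply(peptides, function(p) integer(0)))
  }
  big <- paste(seqs, collapse = "\1")
  starts0 <- c(0L, cumsum(nchar(seqs) + 1L))[seq_along(seqs)]
  lapply(peptides, function(p) {
    m <- gregexpr(p, big, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(integer(0))
    unique(findInterval(as.integer(m) - 1L, starts0))
  })
}

# longest common contiguous substring of two residue strings under I=L
# equivalence; returns list(len, pos_a, pos_b) (1-based starts) or len 0
.longest_shared <- function(a, b) {
  ra <- strsplit(chartr("I", "L", a), "", fixed = TRUE)[[1L]]
  rb <- strsplit(chartr("I", "L", b), "", fixed = TRUE)[[1L]]
  na <- length(ra); nb <- length(rb)
  best <- list(len = 0L, pos_a = NA_integer_, pos_b = NA_integer_)
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_i <- ra[i] == rb
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    mx <- if (any(match_i)) max(cur) else 0L
    if (mx > best$len) {
      j <- which.max(cur)
      best <- list(len = mx, pos_a = i - mx + 1L, pos_b = j - mx + 1L)
    }
    prev <- cur
  }
  best
}

#' Corroborate a database peptide with de novo sequence tags
#'
#' A tag (pre-filtered to ALC above `min_alc`) corroborates a peptide when
#' the two share a contiguous stretch of at least `min_shared` residues
#' (I and L treated as equivalent, since de novo sequencing cannot
#' distinguish them). For each recoded position (a residue over a genomic
#' TAG), corroboration of the recoding event additionally requires that the
#' recoded Q and up to `flank` neighbours on each side (clipped at the tag
#' ends) each exceed `min_residue_conf` per-residue confidence, and that
#' the Q itself lies inside the shared stretch.
#'
#' @param peptide Residue string of the accepted peptide.
#' @param tags Tag data frame from [read_tag_table()].
#' @param alignment Optional `peptide_alignment` providing
#'   `residues_at_TAG`; when `NULL`, only the sharing verdict is computed.
#' @param min_shared Minimum shared contiguous residues (default 6).
#' @param min_alc Minimum ALC, exclusive (default 50).
#' @param min_residue_conf Minimum per-residue confidence, exclusive
#'   (default 90).
#' @param flank Number of neighbours on each side of the recoded Q that must
#'   pass the confidence threshold (default 2).
#' @return List: `shared` (logical; any tag shares >= `min_shared`),
#'   `recoded` (named logical vector per recoded peptide position),
#'   `tag_index` (index of the first corroborating tag or `NA`).
#' @export
corroborate_peptide <- function(peptide, tags, alignment = NULL,
                                min_shared = 6L, min_alc = 50,
                                min_residue_conf = 90, flank = 2L) {
  tag_pos <- if (!is.null(alignment)) alignment$residues_at_TAG else integer(0)
  recoded <- stats::setNames(rep(FALSE, length(tag_pos)),
                             as.character(tag_pos))
  shared <- FALSE
  tag_index <- NA_integer_
  if (nrow(tags)) {
    keep <- tags$alc > min_alc
    tags <- tags[keep, , drop = FALSE]
  }
  if (nrow(tags) == 0L) {
    return(list(shared = FALSE, recoded = recoded, tag_index = tag_index))
  }
  for (ti in seq_len(nrow(tags))) {
    ls <- .longest_shared(peptide, tags$sequence[ti])
    if (ls$len < min_shared) next
    if (!shared) { shared <- TRUE; tag_index <- ti }
    conf <- tags$residue_conf[[ti]]
    nt <- length(conf)
    for (p in tag_pos) {
      # position of the recoded Q within the shared stretch and the tag
      if (p < ls$pos_a || p > ls$pos_a + ls$len - 1L) next
      q_in_tag <- ls$pos_b + (p - ls$pos_a)
      lo <- max(1L, q_in_tag - flank)
      hi <- min(nt, q_in_tag + flank)
      if (all(conf[lo:hi] > min_residue_conf)) {
        recoded[as.character(p)] <- TRUE
      }
    }
  }
  list(shared = shared, recoded = recoded, tag_index = tag_index)
}

#' Collect recoding events from mapped peptide evidence
#'
#' Groups accepted, mapped peptides by the genomic TAG codons they cover and
#' emits one event per distinct TAG position. Every event is re-checked
#' against the contig: the codon at the event span must literally read TAG
#' (in gene orientation) and the supporting residue must be Q.
#'
#' @param alignments List of `peptide_alignment` objects (accepted peptides
#'   mapped to code-15 records).
#' @param classifications Named list (by peptide) of class vectors from
#'   [classify_peptide()], or `NULL`.
#' @param corroborations Named list (by peptide) of verdicts from
#'   [corroborate_peptide()], or `NULL`.
#' @param ctg The [contig].
#' @return Data frame with one row per recoded TAG position: `contig_id`,
#'   `tag_start`, `tag_end` (0-based half-open forward-axis span of the TAG
#'   codon), `strand`, `observed_residue`, `n_peptides`,
#'   `supporting_peptides` (`;`-joined), `evidence_classes`,
#'   `denovo_corroborated`.
#' @export
recoding_events <- function(alignments, classifications = NULL,
                            corroborations = NULL, ctg) {
  stopifnot(inherits(ctg, "contig"))
  rows <- list()
  for (al in alignments) {
    for (p in al$residues_at_TAG) {
      cs <- al$codon_start[p]
      codon <- substr(ctg$sequence, cs + 1L, cs + 3L)
      if (al$strand == "-") codon <- revcomp(codon)
      if (codon != "TAG") {
        stop("internal error: recoding event at non-TAG codon (",
             al$contig_id, ":", cs, ")", call. = FALSE)
      }
      res <- substr(al$peptide, p, p)
      if (res != "Q") {
        stop("internal error: residue at TAG codon is '", res, "', not Q",
             call. = FALSE)
      }
      cls <- if (!is.null(classifications) &&
                 !is.null(classifications[[al$peptide]])) {
        classifications[[al$peptide]]
      } else character(0)
      corr <- FALSE
      if (!is.null(corroborations) &&
          !is.null(corroborations[[al$peptide]])) {
        v <- corroborations[[al$peptide]]$recoded
        corr <- isTRUE(unname(v[as.character(p)]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = al$contig_id, tag_start = cs, tag_end = cs + 3L,
        strand = al$strand, observed_residue = res,
        peptide = al$peptide,
        evidence_classes = paste(cls, collapse = ","),
        denovo_corroborated = corr, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(0), tag_start = integer(0),
                      tag_end = integer(0), strand = character(0),
                      observed_residue = character(0),
                      n_peptides = integer(0),
                      supporting_peptides = character(0),
                      evidence_classes = character(0),
                      denovo_corroborated = logical(0),
                      stringsAsFactors = FALSE))
  }
  per <- do.call(rbind, rows)
  key <- paste(per$contig_id, per$tag_start, per$strand)
  out <- do.call(rbind, lapply(split(per, key), function(g) {
    data.frame(contig_id = g$contig_id[1L], tag_start = g$tag_start[1L],
               tag_end = g$tag_end[1L], strand = g$strand[1L],
               observed_residue = "Q",
               n_peptides = length(unique(g$peptide)),
               supporting_peptides = paste(unique(g$peptide),
                                           collapse = ";"),
               evidence_classes = paste(sort(unique(unlist(
                 strsplit(g$evidence_classes, ",", fixed = TRUE)))),
                 collapse = ","),
               denovo_corroborated = any(g$denovo_corroborated),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tag_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene evidence summary and coverage maps
#'
#' Tallies, per gene: total accepted peptide occurrences, distinct peptides,
#' unique peptides (peptides aligning to exactly one gene), code-15-
#' exclusive peptides, recoding events with corroboration, and a detection
#' flag (at least one unique peptide). A per-residue coverage map marks
#' residues covered by accepted database peptides and by corroborating de
#' novo tags, and flags recoded-Q positions.
#'
#' @param events Events data frame from [recoding_events()].
#' @param alignments List of `peptide_alignment` objects.
#' @param accepted Accepted-peptide data frame from [fdr_filter()].
#' @param genes Gene models the alignments refer to (typically code-15).
#' @param classifications,corroborations Named lists by peptide (optional).
#' @return List with `summary` (one row per gene) and `coverage` (one row
#'   per gene residue with logical flags `covered_by_peptide`,
#'   `covered_by_tag`, `recoded_q`).
#' @export
summarize_genes <- function(events, alignments, accepted, genes,
                            classifications = NULL, corroborations = NULL) {
  pep_gene <- unique(do.call(rbind, lapply(alignments, function(al) {
    data.frame(peptide = al$peptide, gene_id = al$gene_id,
               stringsAsFactors = FALSE)
  })))
  genes_per_pep <- if (!is.null(pep_gene)) {
    tapply(pep_gene$gene_id, pep_gene$peptide,
           function(g) length(unique(g)))
  } else integer(0)
  summary_rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    als <- Filter(function(a) a$gene_id == g$gene_id, alignments)
    peps <- unique(vapply(als, function(a) a$peptide, character(1)))
    uniq <- peps[vapply(peps, function(p) {
      isTRUE(genes_per_pep[[p]] == 1L)
    }, logical(1))]
    excl <- peps[vapply(peps, function(p) {
      !is.null(classifications[[p]]) &&
        "code15-exclusive" %in% classifications[[p]]
    }, logical(1))]
    g_events <- if (nrow(events)) {
      events[vapply(strsplit(events$supporting_peptides, ";", fixed = TRUE),
                    function(sp) any(sp %in% peps), logical(1)) &
               events$contig_id == g$contig_id &
               events$tag_start >= g$start - 90L &
               events$tag_end <= g$end + 90L, , drop = FALSE]
    } else events
    data.frame(gene_id = g$gene_id, contig_id = g$contig_id,
               code_id = g$code_id,
               total_peptide_occurrences = length(als),
               n_peptides = length(peps),
               n_unique_peptides = length(uniq),
               n_code15_exclusive = length(excl),
               n_recoding_events = nrow(g_events),
               n_corroborated_events = sum(g_events$denovo_corroborated),
               detected = length(uniq) >= 1L,
               stringsAsFactors = FALSE)
  })
  coverage_rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    plen <- nchar(g$protein)
    cov_pep <- logical(plen); cov_tag <- logical(plen); rec <- logical(plen)
    for (al in alignments) {
      if (al$gene_id != g$gene_id) next
      if (g$strand == "+") {
        idx <- (al$codon_start - g$start) %/% 3L + 1L
      } else {
        idx <- (g$end - al$codon_end) %/% 3L + 1L
      }
      ok <- idx >= 1L & idx <= plen
      cov_pep[idx[ok]] <- TRUE
      rtag <- al$residues_at_TAG
      rtag <- rtag[ok[rtag]]
      if (length(rtag)) rec[idx[rtag]] <- TRUE
      corr <- corroborations[[al$peptide]]
      if (!is.null(corr) && isTRUE(corr$shared)) cov_tag[idx[ok]] <- TRUE
    }
    if (plen == 0L) return(NULL)
    data.frame(gene_id = g$gene_id, residue = seq_len(plen),
               covered_by_peptide = cov_pep, covered_by_tag = cov_tag,
               recoded_q = rec, stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, summary_rows),
       coverage = do.call(rbind, coverage_rows))
}
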