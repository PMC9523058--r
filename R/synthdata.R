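# fast vectorized reverse complement for short strings (A,C,G,T,N)
.rc <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' structure the detection method assumes: a ~94 kb contig (the size of a
#' curated crAss-like gut phage genome) split into two replichores with
#' opposed GC skew, an amber-recoded (code 15) gene region occupying one
#' half and a standard-code (code 11) region the other, recoded genes
#' carrying several in-frame TAG codons each, tryptic peptides sampled from
#' both proteomes with separated target/decoy score distributions, and de
#' novo tags with high or low per-residue confidence.
#'
#' @param seed Integer seed; every stochastic choice derives from it.
#' @param contig_len Contig length in nt (default 94000).
#' @param n_genes_code15,n_genes_code11 Genes planted per region (30 each).
#' @param gene_len_range Protein length range in residues (250-450).
#' @param tag_per_gene Poisson mean of in-frame TAG codons per code-15 gene
#'   (default 10: in recoded crAss-like genomes TAG supplies the majority
#'   of glutamine codons, and Q is about 4 percent of residues); a
#'   `min_tag_fraction` of genes is forced to carry >= 1.
#' @param min_tag_fraction Fraction of code-15 genes forced to contain at
#'   least one TAG (default 1).
#' @param gc_content Genome GC fraction (default 0.35; crAss-like gut
#'   phages are AT-rich, which is also why stop codons are frequent in
#'   non-coding frames and spurious ORFs short).
#' @param gc_bias Expected per-window GC skew (G - C)/(G + C) on the
#'   forward strand of replichore 1 (sign flipped on replichore 2);
#'   default 0.2.
#' @param minus_strand_fraction Fraction of genes placed on the minus
#'   strand (default 0.3).
#' @param peptide_sample_rate Fraction of in-silico tryptic peptides
#'   observed as true PSMs (default 0.25).
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Gaussian score model for correct and incorrect identifications
#'   (defaults 50/7 and 20/6; scores are unitless — only rank order matters
#'   to FDR filtering).
#' @param noise Fraction of target PSM candidates that are incorrect and
#'   score like decoys (default 0.7).
#' @param denovo_rate Fraction of recoded-position-covering true peptides
#'   that receive a high-confidence de novo tag (default 0.8).
#' @param tag_conf_high,tag_conf_low Per-residue confidence levels of
#'   corroborating and non-corroborating tags (96 and 70).
#' @param min_protein_len ORF-caller floor used downstream (default 50).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       contig_len = 94000L,
                       n_genes_code15 = 30L,
                       n_genes_code11 = 30L,
                       gene_len_range = c(250L, 450L),
                       tag_per_gene = 10,
                       min_tag_fraction = 1,
                       gc_content = 0.35,
                       gc_bias = 0.2,
                       minus_strand_fraction = 0.3,
                       peptide_sample_rate = 0.25,
                       target_score_mean = 50, target_score_sd = 7,
                       decoy_score_mean = 20, decoy_score_sd = 6,
                       noise = 0.7,
                       denovo_rate = 0.8,
                       tag_conf_high = 96, tag_conf_low = 70,
                       min_protein_len = 50L) {
  fr <- c(min_tag_fraction = min_tag_fraction,
          minus_strand_fraction = minus_strand_fraction,
          peptide_sample_rate = peptide_sample_rate, noise = noise,
          denovo_rate = denovo_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "), call. = FALSE)
  }
  if (gc_bias < 0 || gc_bias > 1) stop("gc_bias must be in [0, 1]",
                                       call. = FALSE)
  if (gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must be in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

# sample n gene-sense codons, nucleotide-iid under probs p (gene sense),
# rejecting codons in `forbid`
.sample_codons <- function(n, p, forbid) {
  out <- character(0)
  b <- names(p)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    tri <- paste0(sample(b, m, TRUE, p), sample(b, m, TRUE, p),
                  sample(b, m, TRUE, p))
    out <- c(out, tri[!tri %in% forbid])
  }
  out[seq_len(n)]
}

#' Simulate a dual-code phage genome with known ground truth
#'
#' Builds a contig whose first half carries non-overlapping code-15 genes
#' (each with planted in-frame TAG codons read as Q) and whose second half
#' carries standard code-11 genes; the two halves carry opposed G/C strand
#' bias so that the cumulative GC skew peaks at the region boundary
#' (terminus) and bottoms at the contig edge (origin). Each gene cassette
#' is preceded (in gene orientation) by an in-frame TAA stop guard and a
#' short start-free spacer, so that the maximal-ORF caller recovers planted
#' genes exactly and upstream start-extensions are stop-bounded at a known
#' distance.
#'
#' @param config A [sim_config()].
#' @return List with `contig` (a [contig]) and `truth`: `genes` (planted
#'   gene models in the standard schema), `tags` (planted TAG positions:
#'   `gene_id`, `residue_index`, `tag_start` forward-axis codon start),
#'   `origin`, `terminus`, `mid` (region boundary), `upstream_ext` (per
#'   gene, planted stop-free spacer length in codons), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$contig_len)
  mid <- (L %/% 6L) * 3L   # region boundary, codon-aligned near L/2
  gc <- config$gc_content
  bias <- config$gc_bias
  at <- (1 - gc) / 2
  p1 <- c(A = at, C = gc / 2 * (1 - bias), G = gc / 2 * (1 + bias), T = at)
  p2 <- c(A = at, C = gc / 2 * (1 + bias), G = gc / 2 * (1 - bias), T = at)
  forbid_body15 <- c("TAA", "TGA", "TAG")
  forbid_body11 <- c("TAA", "TGA", "TAG")
  forbid_spacer <- c("TAA", "TGA", "TAG", "ATG", "GTG", "TTG")
  tab <- list(`11` = load_code_table(11L), `15` = load_code_table(15L))

  build_gene <- function(code, p_region, id) {
    strand <- if (stats::runif(1) < config$minus_strand_fraction) "-" else "+"
    # gene-sense nucleotide probs: complement of forward probs on minus
    pg <- if (strand == "+") p_region else {
      c(A = unname(p_region["T"]), C = unname(p_region["G"]),
        G = unname(p_region["C"]), T = unname(p_region["A"]))
    }
    P <- sample(config$gene_len_range[1L]:config$gene_len_range[2L], 1L)
    codons <- c("ATG",
                .sample_codons(P - 1L,
                               pg, if (code == 15L) forbid_body15
                                   else forbid_body11))
    tag_res <- integer(0)
    if (code == 15L) {
      k <- stats::rpois(1L, config$tag_per_gene)
      if (k == 0L && stats::runif(1) < config$min_tag_fraction) k <- 1L
      k <- min(k, P - 2L)
      if (k > 0L) {
        tag_res <- sort(sample(2:(P - 1L), k))
        codons[tag_res] <- "TAG"
      }
    }
    stop_codon <- sample(c("TAA", "TGA"), 1L)
    protein <- paste(.translate_codons(codons, tab[[as.character(code)]]),
                     collapse = "")
    f <- sample(0:10, 1L)  # stop-free, start-free spacer codons
    spacer <- if (f > 0L) paste(.sample_codons(f, pg, forbid_spacer),
                                collapse = "") else ""
    cass_sense <- paste0("TAATAATAA", spacer,
                         paste(codons, collapse = ""), stop_codon)
    cass_fwd <- if (strand == "+") cass_sense else revcomp(cass_sense)
    span <- 3L * (P + 1L)
    gene_off <- if (strand == "+") 9L + 3L * f else 0L
    list(id = id, code = code, strand = strand, protein = protein,
         cassette = cass_fwd, cass_len = nchar(cass_fwd),
         gene_off = gene_off, span = span, tag_res = tag_res,
         spacer_codons = f)
  }

  place_region <- function(genes, region_start, region_len, p_region) {
    total <- sum(vapply(genes, `[[`, integer(1), "cass_len"))
    n <- length(genes)
    min_gap <- 30L
    slack <- region_len - total - (n + 1L) * min_gap
    if (slack < 0L) {
      stop("planted genes do not fit in region (need ",
           total + (n + 1L) * min_gap, " nt, have ", region_len, ")",
           call. = FALSE)
    }
    extras <- as.integer(stats::rmultinom(1L, slack,
                                          rep(1 / (n + 1L), n + 1L)))
    gaps <- min_gap + extras
    pieces <- character(2L * n + 1L)
    rows <- vector("list", n)
    cursor <- region_start
    b <- names(p_region)
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- paste(sample(b, gaps[i], TRUE, p_region),
                                   collapse = "")
      cursor <- cursor + gaps[i]
      g <- genes[[i]]
      pieces[2L * i] <- g$cassette
      g$start <- cursor + g$gene_off
      g$end <- g$start + g$span
      rows[[i]] <- g
      cursor <- cursor + g$cass_len
    }
    pieces[2L * n + 1L] <- paste(sample(b, gaps[n + 1L], TRUE, p_region),
                                 collapse = "")
    list(seq = paste(pieces, collapse = ""), genes = rows)
  }

  g15 <- lapply(seq_len(config$n_genes_code15), function(i) {
    build_gene(15L, p1, sprintf("sim_g15_%02d", i))
  })
  g11 <- lapply(seq_len(config$n_genes_code11), function(i) {
    build_gene(11L, p2, sprintf("sim_g11_%02d", i))
  })
  r1 <- place_region(g15, 0L, mid, p1)
  r2 <- place_region(g11, mid, L - mid, p2)
  ctg <- contig("sim_contig", paste0(r1$seq, r2$seq))

  to_rows <- function(placed) {
    do.call(rbind, lapply(placed, function(g) {
      data.frame(gene_id = g$id, contig_id = "sim_contig",
                 start = g$start, end = g$end, strand = g$strand,
                 code_id = g$code, protein = g$protein,
                 includes_stop_codon = TRUE, stringsAsFactors = FALSE)
    }))
  }
  genes <- rbind(to_rows(r1$genes), to_rows(r2$genes))
  tags <- do.call(rbind, lapply(r1$genes, function(g) {
    if (length(g$tag_res) == 0L) return(NULL)
    ts <- if (g$strand == "+") g$start + 3L * (g$tag_res - 1L)
          else g$end - 3L * g$tag_res
    data.frame(gene_id = g$id, contig_id = "sim_contig",
               residue_index = g$tag_res, tag_start = ts,
               stringsAsFactors = FALSE)
  }))
  upstream_ext <- stats::setNames(
    vapply(c(r1$genes, r2$genes), `[[`, integer(1), "spacer_codons"),
    vapply(c(r1$genes, r2$genes), `[[`, character(1), "id"))
  list(contig = ctg,
       truth = list(genes = genes, tags = tags, origin = 0L,
                    terminus = mid, mid = mid,
                    upstream_ext = upstream_ext, contig = ctg,
                    config = config))
}

#' Draw synthetic PSM scores under the two-Gaussian model
#'
#' Target PSMs are a mixture: a `noise` fraction are incorrect and score
#' like decoys (null Gaussian); the rest are correct and score from the
#' shifted target Gaussian. Decoy PSMs all score from the null. Uses the
#' current RNG state.
#'
#' @param n_target,n_decoy Numbers of target and decoy PSMs.
#' @param config A [sim_config()] providing the score-model parameters.
#' @return Data frame with `peptide` (synthetic unique ids), `score`,
#'   `is_decoy`, `is_true` (ground-truth correctness label).
#' @export
simulate_scores <- function(n_target, n_decoy, config) {
  n_null <- round(config$noise * n_target)
  n_true <- n_target - n_null
  data.frame(
    peptide = sprintf("pep%06d", seq_len(n_target + n_decoy)),
    score = c(stats::rnorm(n_true, config$target_score_mean,
                           config$target_score_sd),
              stats::rnorm(n_null, config$decoy_score_mean,
                           config$decoy_score_sd),
              stats::rnorm(n_decoy, config$decoy_score_mean,
                           config$decoy_score_sd)),
    is_decoy = rep(c(FALSE, TRUE), c(n_target, n_decoy)),
    is_true = rep(c(TRUE, FALSE, FALSE), c(n_true, n_null, n_decoy)),
    stringsAsFactors = FALSE)
}

#' Simulate a peptide-identification experiment from a search database
#'
#' Samples tryptic peptides of the *expressed* proteome — the planted genes
#' of the simulated genome, i.e. what a mass spectrometer could actually
#' observe, not the spurious ORFs a six-frame scan also predicts — as
#' correct identifications with shifted-Gaussian scores; adds incorrect
#' target identifications (residue-shuffled peptides, null scores) and
#' decoy identifications (peptides of the reversed records, null scores).
#' Sampled peptides are required to be phage-specific and locus-specific:
#' a candidate occurring in a database record that does not belong to its
#' source gene's locus (its protein or upstream-extended protein context)
#' is discarded, mirroring the phage-specific peptide sets used in
#' metaproteomic validation. De novo tags: true peptides covering a planted
#' recoded position receive a matching tag with high per-residue confidence
#' with probability `denovo_rate` (otherwise a low-confidence tag); a fifth
#' of the remaining true peptides receive a high-confidence tag as ordinary
#' coverage.
#'
#' @param db A `protein_db` built from the simulated genome.
#' @param truth Ground truth from [simulate_genome()] (carries the contig).
#' @param config The same [sim_config()].
#' @return List with `psms` (columns `peptide`, `score`, `parents`),
#'   `tags` (columns `sequence`, `alc`, `residue_conf`), `labels`
#'   (`peptide`, `origin` in true/spurious/decoy, `is_true`), and
#'   `covering` (the sampled true peptides that cover a planted recoded
#'   position, with their source gene and protein offset).
#' @export
simulate_psms <- function(db, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(db) || nrow(db) == 0L) stop("empty database", call. = FALSE)
  set.seed(config$seed + 10007L)
  planted <- truth$genes
  expressed <- stats::setNames(planted$protein, planted$gene_id)
  context <- vapply(seq_len(nrow(planted)), function(i) {
    g <- planted[i, ]
    ext <- if (g$code_id == 15L) upstream_extension(g, truth$contig) else ""
    paste0(ext, g$protein)
  }, character(1))
  names(context) <- planted$gene_id
  dig <- digest_protein(expressed, max_missed = 1L, specificity = "full",
                        min_len = 7L, max_len = 30L)
  pool <- split(dig, dig$sequence)
  phage_t <- db[!db$is_decoy & startsWith(db$source, "phage"), ,
                drop = FALSE]
  cand <- names(pool)
  hits <- .locate_peptides(cand, phage_t$sequence)
  # locus specificity: every containing record must be explained by a
  # source gene of the candidate (record within the gene's extended
  # context, or the gene's whole protein within the record)
  specific <- vapply(seq_along(cand), function(i) {
    src <- unique(pool[[i]]$parent_id)
    all(vapply(hits[[i]], function(r) {
      rs <- phage_t$sequence[r]
      any(vapply(src, function(g) {
        grepl(rs, context[[g]], fixed = TRUE) ||
          grepl(expressed[[g]], rs, fixed = TRUE)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  pool_seqs <- cand[specific]
  hits <- hits[specific]
  n_true <- round(config$peptide_sample_rate * length(pool_seqs))
  empty_psms <- data.frame(peptide = character(0), score = numeric(0),
                           parents = character(0), stringsAsFactors = FALSE)
  empty_tags <- data.frame(sequence = character(0), alc = numeric(0),
                           residue_conf = character(0),
                           stringsAsFactors = FALSE)
  if (n_true == 0L) {
    return(list(psms = empty_psms, tags = empty_tags,
                labels = data.frame(peptide = character(0),
                                    origin = character(0),
                                    is_true = logical(0),
                                    stringsAsFactors = FALSE),
                covering = NULL))
  }
  sel <- sample(length(pool_seqs), n_true)
  true_seqs <- pool_seqs[sel]
  true_parents <- vapply(hits[sel], function(idx) {
    paste(phage_t$record_id[idx], collapse = ";")
  }, character(1))
  n_spur <- if (config$noise >= 1) {
    stop("noise must be < 1 for PSM simulation", call. = FALSE)
  } else round(config$noise / (1 - config$noise) * n_true)
  shuffle1 <- function(s) paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]),
                                collapse = "")
  spur_idx <- sample(sel, n_spur, replace = TRUE)
  spur_seqs <- vapply(pool_seqs[spur_idx], shuffle1, character(1),
                      USE.NAMES = FALSE)
  spur_parents <- vapply(hits[spur_idx], function(idx) {
    paste(phage_t$record_id[idx], collapse = ";")
  }, character(1))
  # decoy identifications from the reversed records
  dec_db <- db[db$is_decoy, , drop = FALSE]
  dig_dec <- digest_protein(dec_db, max_missed = 1L, specificity = "full",
                            min_len = 7L, max_len = 30L)
  dec_pool <- split(dig_dec, dig_dec$sequence)
  n_dec <- min(n_spur, length(dec_pool))
  dec_seqs <- sample(names(dec_pool), n_dec)
  dec_parents <- vapply(dec_seqs, function(s) {
    paste(unique(dec_pool[[s]]$parent_id), collapse = ";")
  }, character(1))

  # optionally annotate Met oxidation on a tenth of true peptides
  raw_true <- true_seqs
  modded <- which(stats::runif(n_true) < 0.1 & grepl("M", true_seqs,
                                                     fixed = TRUE))
  raw_true[modded] <- sub("M", "M(+15.99)", true_seqs[modded], fixed = TRUE)

  psms <- data.frame(
    peptide = c(raw_true, spur_seqs, dec_seqs),
    score = c(stats::rnorm(n_true, config$target_score_mean,
                           config$target_score_sd),
              stats::rnorm(n_spur, config$decoy_score_mean,
                           config$decoy_score_sd),
              stats::rnorm(n_dec, config$decoy_score_mean,
                           config$decoy_score_sd)),
    parents = c(true_parents, spur_parents, dec_parents),
    stringsAsFactors = FALSE)
  labels <- data.frame(
    peptide = c(true_seqs, spur_seqs, dec_seqs),
    origin = rep(c("true", "spurious", "decoy"),
                 c(n_true, n_spur, n_dec)),
    is_true = rep(c(TRUE, FALSE, FALSE), c(n_true, n_spur, n_dec)),
    stringsAsFactors = FALSE)

  # which sampled true peptides cover a planted recoded position?
  covering_rows <- list()
  covers <- vapply(true_seqs, function(s) {
    occ <- pool[[s]]   # occurrences in planted proteins
    hit <- FALSE
    for (i in seq_len(nrow(occ))) {
      gid <- occ$parent_id[i]
      tr <- truth$tags[truth$tags$gene_id == gid, , drop = FALSE]
      if (nrow(tr) == 0L) next
      lo <- occ$start[i]                         # 0-based protein offset
      hi <- lo + occ$length[i]
      cov <- tr$residue_index - 1L >= lo & tr$residue_index - 1L < hi
      if (any(cov)) {
        covering_rows[[length(covering_rows) + 1L]] <<- data.frame(
          peptide = s, gene_id = gid, start = lo,
          residue_index = tr$residue_index[cov],
          stringsAsFactors = FALSE)
        hit <- TRUE
      }
    }
    hit
  }, logical(1))
  covering <- if (length(covering_rows)) do.call(rbind, covering_rows)
              else NULL

  mk_tag <- function(s, high) {
    n <- nchar(s)
    conf <- if (high) {
      round(stats::runif(n, config$tag_conf_high - 2,
                         min(config$tag_conf_high + 2, 99.5)), 1)
    } else {
      round(stats::runif(n, config$tag_conf_low - 5,
                         config$tag_conf_low + 5), 1)
    }
    data.frame(sequence = s, alc = round(mean(conf), 2),
               residue_conf = paste(conf, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  tag_rows <- list()
  for (s in true_seqs[covers]) {
    tag_rows[[length(tag_rows) + 1L]] <-
      mk_tag(s, stats::runif(1) < config$denovo_rate)
  }
  plain <- true_seqs[!covers]
  for (s in plain[stats::runif(length(plain)) < 0.2]) {
    tag_rows[[length(tag_rows) + 1L]] <- mk_tag(s, TRUE)
  }
  tags <- if (length(tag_rows)) do.call(rbind, tag_rows) else empty_tags
  list(psms = psms, tags = tags, labels = labels, covering = covering)
}
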