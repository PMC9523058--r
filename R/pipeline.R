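#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the method's standard values
#' as defaults: 10/5 percentage-point coding-density thresholds (implied by
#' [assign_code()]), 30-residue upstream extensions, 3 missed cleavages,
#' 1\% peptide FDR, ALC > 50, per-residue confidence > 90, >= 6 shared
#' residues, +/-2-residue corroboration flank.
#'
#' @param out_dir Output directory for reports (created if missing).
#' @param min_protein_len ORF-caller protein length floor (residues).
#' @param max_overlap Overlap tolerance of [select_genes()] (nt).
#' @param gain_mode `"absolute"` or `"relative"` density-gain reading.
#' @param skew_window,skew_step GC-skew window and step (nt).
#' @param max_ext Upstream extension cap (residues).
#' @param max_missed Maximum missed cleavages (peptide export).
#' @param min_pep_len,max_pep_len Peptide length window (residues).
#' @param fdr Peptide-level FDR threshold.
#' @param min_shared,min_alc,min_residue_conf,flank De novo corroboration
#'   thresholds (see [corroborate_peptide()]).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`. Unknown arguments are
#'   rejected by normal R argument matching.
#' @export
pipeline_config <- function(out_dir = tempfile("ambercode_run_"),
                            min_protein_len = 50L,
                            max_overlap = 60L,
                            gain_mode = "absolute",
                            skew_window = 1000L, skew_step = 10L,
                            max_ext = 30L, max_missed = 3L,
                            min_pep_len = 6L, max_pep_len = 50L,
                            fdr = 0.01,
                            min_shared = 6L, min_alc = 50,
                            min_residue_conf = 90, flank = 2L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full detection and validation pipeline on one contig
#'
#' Composes the stages: ORF prediction under codes 11 and 15, coding-density
#' code assignment, GC-skew replichore profiling, search-database
#' construction, peptide-level target-decoy FDR filtering of the supplied
#' identifications, codon-level peptide-to-genome mapping, evidence
#' classification, de novo corroboration, recoding-event collection, and
#' per-gene summaries. Accepted peptides are located by substring search
#' across all target records (identifications whose sequence occurs nowhere
#' in the database, e.g. residue-shuffled noise, are dropped with a note in
#' the manifest).
#'
#' @param ctg A [contig] (or path to a FASTA with a single contig).
#' @param psms PSM data frame (columns `peptide`, `score`, `parents`) or a
#'   path readable by [read_psm_table()].
#' @param tags Tag data frame or path readable by [read_tag_table()]; may
#'   be `NULL`.
#' @param auxiliary,contaminants Named character vectors of protein
#'   sequences, or `NULL`.
#' @param config A [pipeline_config()].
#' @param write_reports Write TSV/GFF3/FASTA reports under
#'   `config$out_dir` (default `TRUE`).
#' @return List (class `pipeline_result`) with elements `assignment`,
#'   `skew`, `genes_11`, `genes_15`, `db`, `fdr` (list from
#'   [fdr_filter()]), `alignments`, `classifications`, `corroborations`,
#'   `events`, `gene_summary`, `coverage`, `unmapped_peptides`, `config`,
#'   and `out_dir` (when reports were written).
#' @export
run_pipeline <- function(ctg, psms, tags = NULL,
                         auxiliary = NULL, contaminants = NULL,
                         config = pipeline_config(),
                         write_reports = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(ctg)) ctg <- read_fasta(ctg)[[1L]]
  stopifnot(inherits(ctg, "contig"))
  if (is.character(psms)) psms <- read_psm_table(psms)
  if (is.character(tags)) tags <- read_tag_table(tags)
  if (is.null(tags)) {
    tags <- data.frame(sequence = character(0), alc = numeric(0),
                       stringsAsFactors = FALSE)
    tags$residue_conf <- list()
  }
  if (is.character(tags$residue_conf)) {
    tags$residue_conf <- lapply(strsplit(tags$residue_conf, ";",
                                         fixed = TRUE), as.numeric)
  }
  if (!"is_decoy" %in% names(psms)) {
    pl <- strsplit(psms$parents, ";", fixed = TRUE)
    psms$is_decoy <- vapply(pl, function(p) all(startsWith(p, "rev_")),
                            logical(1))
  }
  if (!grepl("\\(", paste(psms$peptide, collapse = ""))) {
    psms$peptide_raw <- psms$peptide
  } else {
    psms$peptide_raw <- psms$peptide
    psms$peptide <- gsub("\\([+-][0-9.]+\\)", "", psms$peptide)
  }

  tab11 <- load_code_table(11L); tab15 <- load_code_table(15L)
  genes_11 <- select_genes(predict_orfs(ctg, tab11, config$min_protein_len),
                           config$max_overlap)
  genes_15 <- select_genes(predict_orfs(ctg, tab15, config$min_protein_len),
                           config$max_overlap)
  assignment <- assign_code(ctg, genes_11, genes_15, config$gain_mode)
  skew <- gc_skew(ctg, config$skew_window, config$skew_step)
  db <- build_protein_db(genes_11, genes_15, ctg, auxiliary, contaminants,
                         with_decoys = TRUE, max_ext = config$max_ext)

  flt <- fdr_filter(psms, config$fdr)
  accepted <- flt$accepted

  # locate each accepted peptide in the target records and map phage hits
  targets <- db[!db$is_decoy, , drop = FALSE]
  std_mask <- !targets$source %in% c("phage-code15", "phage-code15-extended")
  c15_mask <- !std_mask
  peps <- unique(accepted$peptide)
  hit_idx <- .locate_peptides(peps, targets$sequence)
  alignments <- list()
  classifications <- list()
  corroborations <- list()
  unmapped <- character(0)
  for (k in seq_along(peps)) {
    pep <- peps[k]
    idx <- hit_idx[[k]]
    if (length(idx) == 0L) { unmapped <- c(unmapped, pep); next }
    in_std <- any(std_mask[idx])
    # map against code-15 records (and extended variants); code-11 records
    # describe the same genome through the standard-code lens
    map_hit <- targets[idx[c15_mask[idx]], , drop = FALSE]
    pep_aligns <- list()
    for (i in seq_len(nrow(map_hit))) {
      rec <- map_hit[i, ]
      gene <- genes_15[match(rec$gene_id, genes_15$gene_id), , drop = FALSE]
      pep_aligns <- c(pep_aligns, map_peptide(pep, rec, gene, ctg))
    }
    if (length(pep_aligns)) {
      cls <- sort(unique(unlist(lapply(pep_aligns, classify_peptide,
                                       db = db, genes_11 = genes_11,
                                       in_std = in_std))))
      classifications[[pep]] <- cls
      corroborations[[pep]] <- corroborate_peptide(
        pep, tags, pep_aligns[[1L]],
        min_shared = config$min_shared, min_alc = config$min_alc,
        min_residue_conf = config$min_residue_conf, flank = config$flank)
      alignments <- c(alignments, pep_aligns)
    }
  }
  events <- recoding_events(alignments, classifications, corroborations, ctg)
  gs <- summarize_genes(events, alignments, accepted, genes_15,
                        classifications, corroborations)

  out <- structure(list(
    contig = ctg, assignment = assignment, skew = skew,
    genes_11 = genes_11, genes_15 = genes_15, db = db, fdr = flt,
    alignments = alignments, classifications = classifications,
    corroborations = corroborations, events = events,
    gene_summary = gs$summary, coverage = gs$coverage,
    unmapped_peptides = unmapped, config = config
  ), class = "pipeline_result")
  if (write_reports) {
    out$out_dir <- render_reports(out, config$out_dir)
  }
  out
}

#' Write human-readable reports for a pipeline run
#'
#' Emits, under `out_dir`: `code_assignment.tsv`, `gc_skew.tsv`,
#' `genes_code11.gff3` / `genes_code15.gff3`, `search_db.fasta`,
#' `accepted_peptides.tsv`, `recoding_events.tsv`, `gene_summary.tsv`,
#' `coverage_map.tsv` and a `manifest.json` recording the configuration,
#' seed and row counts. Degenerate runs (no accepted peptides) produce
#' header-only tables, not errors.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
render_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$assignment, "code_assignment.tsv")
  w(as.data.frame(result$skew), "gc_skew.tsv")
  write_gff3(result$genes_11, file.path(out_dir, "genes_code11.gff3"))
  write_gff3(result$genes_15, file.path(out_dir, "genes_code15.gff3"))
  write_protein_db(result$db, file.path(out_dir, "search_db.fasta"))
  acc <- result$fdr$accepted
  w(acc[, setdiff(names(acc), "parents_list"), drop = FALSE],
    "accepted_peptides.tsv")
  w(result$events, "recoding_events.tsv")
  if (!is.null(result$gene_summary)) w(result$gene_summary,
                                       "gene_summary.tsv")
  if (!is.null(result$coverage)) w(result$coverage, "coverage_map.tsv")
  manifest <- list(
    package = "ambercode",
    version = as.character(utils::packageVersion("ambercode")),
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "out_dir")],
    contig = result$contig$contig_id,
    contig_len = nchar(result$contig$sequence),
    assigned_code = result$assignment$assigned_code,
    n_genes_11 = nrow(result$genes_11),
    n_genes_15 = nrow(result$genes_15),
    n_db_records = nrow(result$db),
    n_accepted_peptides = nrow(acc),
    n_recoding_events = nrow(result$events),
    n_unmapped_peptides = length(result$unmapped_peptides))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$contig$contig_id, "\n")
  cat(sprintf("  assigned code %s (rule %s): density 11 = %.3f, 15 = %.3f, gain = %.1f points\n",
              x$assignment$assigned_code, x$assignment$rule,
              x$assignment$density_11, x$assignment$density_15,
              x$assignment$gain_points))
  cat("  genes: ", nrow(x$genes_11), " (code 11), ", nrow(x$genes_15),
      " (code 15); db records: ", nrow(x$db), "\n", sep = "")
  cat("  accepted peptides:", nrow(x$fdr$accepted),
      "| recoding events:", nrow(x$events),
      "| corroborated:", sum(x$events$denovo_corroborated), "\n")
  invisible(x)
}
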