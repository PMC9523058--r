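# shared fixture: a plus-strand recoded gene and its minus-strand mirror
ev_fixture <- function() {
  sq <- "ATGAAATAGGAATAA"
  ctg <- contig("c", sq)
  g15 <- predict_orfs(ctg, load_code_table(15), min_protein_len = 1)
  rec <- data.frame(record_id = "c15|g", sequence = g15$protein,
                    source = "phage-code15", gene_id = g15$gene_id,
                    extension_len = 0L, is_decoy = FALSE,
                    stringsAsFactors = FALSE)
  list(ctg = ctg, gene = g15, rec = rec)
}

test_that("PSM tables are validated and modifications stripped aside", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tscore\tparents",
               "MKQE\t55\tc15|g1",
               "VM(+15.99)K\t48\tc15|g1;rev_c15|g2",
               "AAAK\t12\trev_c15|g1"), f)
  x <- read_psm_table(f)
  expect_equal(nrow(x), 3L)
  expect_identical(x$peptide[2], "VMK")
  expect_identical(x$peptide_raw[2], "VM(+15.99)K")
  mods <- attr(x, "modifications")
  expect_equal(mods$position, 2L)
  expect_equal(mods$delta, 15.99)
  expect_identical(x$is_decoy, c(FALSE, FALSE, TRUE))
  expect_identical(x$mixed_parents, c(FALSE, TRUE, FALSE))

  writeLines("peptide\tscore", f)
  expect_error(read_psm_table(f), "parents")
})

test_that("tag tables reject rows with inconsistent confidence lists", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\talc\tresidue_conf",
               "MKQE\t95\t95;95;95;95",
               "MKQE\t95\t95;95;95",          # wrong length
               "MKQE\t60\t95;95;95;95"), f)   # ALC far from the mean
  expect_warning(x <- read_tag_table(f), "rejected")
  expect_equal(nrow(x), 1L)
  expect_equal(x$residue_conf[[1]], rep(95, 4))
})

test_that("target-decoy q-values follow the rank-count estimate", {
  n <- 99L
  psms <- data.frame(
    peptide = sprintf("P%03d", 1:100),
    score = c(seq(200, 102, length.out = n), 100),
    is_decoy = c(rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE)
  r <- fdr_filter(psms, 0.01)
  expect_equal(nrow(r$accepted), 99L)
  # q at the decoy boundary ~ 1/99
  expect_equal(r$table$q_value[r$table$is_decoy], 1 / 99,
               tolerance = 1e-12)
  # adversarial order: all decoys above all targets
  bad <- data.frame(peptide = sprintf("B%02d", 1:20),
                    score = 20:1,
                    is_decoy = rep(c(TRUE, FALSE), each = 10))
  expect_equal(nrow(fdr_filter(bad, 0.01)$accepted), 0L)
})

test_that("q-values are non-increasing in score and collapse is per peptide", {
  set.seed(43)
  psms <- data.frame(
    peptide = sample(sprintf("P%02d", 1:40), 200, replace = TRUE),
    score = rnorm(200, 30, 10),
    is_decoy = runif(200) < 0.5, stringsAsFactors = FALSE)
  psms$is_decoy <- ave(psms$is_decoy, psms$peptide, FUN = function(x) x[1])
  r <- fdr_filter(psms, 0.05)
  tab <- r$table
  expect_equal(nrow(tab), length(unique(psms$peptide)))
  expect_true(all(diff(tab$q_value) >= -1e-12))   # sorted by falling score
  best <- tapply(psms$score, psms$peptide, max)
  expect_equal(tab$score, as.vector(best[tab$peptide]))
  expect_warning(fdr_filter(psms[!psms$is_decoy, ], 0.01), "no decoy")
})

test_that("peptides map codon by codon onto the forward strand", {
  fx <- ev_fixture()
  als <- map_peptide("KQE", fx$rec, fx$gene, fx$ctg)
  expect_length(als, 1L)
  al <- als[[1]]
  expect_equal(al$codon_start, c(3L, 6L, 9L))
  expect_equal(al$residues_at_TAG, 2L)
  expect_identical(al$codons[2], "TAG")
  expect_error(map_peptide("WWW", fx$rec, fx$gene, fx$ctg), "not found")
})

test_that("minus-strand mapping mirrors the forward case", {
  fx <- ev_fixture()
  L <- nchar(fx$ctg$sequence)
  ctg_m <- contig("m", revcomp(fx$ctg$sequence))
  g15 <- predict_orfs(ctg_m, load_code_table(15), min_protein_len = 1)
  g15 <- g15[g15$strand == "-", , drop = FALSE]
  expect_identical(g15$protein, "MKQE")
  rec <- fx$rec; rec$gene_id <- g15$gene_id
  al <- map_peptide("KQE", rec, g15, ctg_m)[[1]]
  # spans mirror the forward fixture on the forward axis
  expect_equal(al$codon_start, L - c(6L, 9L, 12L))
  expect_equal(al$residues_at_TAG, 2L)
})

test_that("extended records map residues upstream of the annotated start", {
  sq <- "GCTATGAAATAGGAATAA"
  ctg <- contig("c", sq)
  g15 <- predict_orfs(ctg, load_code_table(15), min_protein_len = 1)
  g15 <- g15[g15$start == 3L, , drop = FALSE]
  rec <- data.frame(record_id = "c15ext|g", sequence = "AMKQE",
                    source = "phage-code15-extended", gene_id = g15$gene_id,
                    extension_len = 1L, is_decoy = FALSE,
                    stringsAsFactors = FALSE)
  al <- map_peptide("AMK", rec, g15, ctg)[[1]]
  expect_equal(al$codon_start, c(0L, 3L, 6L))   # first residue upstream
  expect_true(min(al$codon_start) < g15$start)
})

test_that("multiple occurrences yield one alignment each", {
  ctg <- contig("c", "ATGGAAAAAGAAAAATAA")  # MEKEK
  g <- predict_orfs(ctg, load_code_table(11), min_protein_len = 1)
  rec <- data.frame(record_id = "c15|g", sequence = g$protein,
                    source = "phage-code15", gene_id = g$gene_id,
                    extension_len = 0L, is_decoy = FALSE,
                    stringsAsFactors = FALSE)
  als <- map_peptide("EK", rec, g, ctg)
  expect_length(als, 2L)
})

test_that("evidence classes capture readthrough geometry", {
  fx <- ev_fixture()
  db <- rbind(fx$rec,
              data.frame(record_id = "c11|h", sequence = "MK",
                         source = "phage-code11", gene_id = "h",
                         extension_len = 0L, is_decoy = FALSE,
                         stringsAsFactors = FALSE))
  g11 <- data.frame(gene_id = "h", contig_id = "c", start = 0L, end = 9L,
                    strand = "+", code_id = 11L, protein = "MK",
                    includes_stop_codon = TRUE, stringsAsFactors = FALSE)
  # Q flanked on both sides: stop-readthrough, and absent from code-11 records
  al <- map_peptide("KQE", fx$rec, fx$gene, fx$ctg)[[1]]
  expect_setequal(classify_peptide(al, db, g11),
                  c("code15-exclusive", "stop-readthrough"))
  # Q at the peptide edge is not flanked: no stop-readthrough call
  al2 <- map_peptide("QE", fx$rec, fx$gene, fx$ctg)[[1]]
  expect_false("stop-readthrough" %in% classify_peptide(al2, db, g11))
  # peptide also present in a code-11 record: shared, never exclusive
  al3 <- map_peptide("MK", fx$rec, fx$gene, fx$ctg)[[1]]
  cls3 <- classify_peptide(al3, db, g11)
  expect_true("shared" %in% cls3)
  expect_false("code15-exclusive" %in% cls3)
})

test_that("peptides spanning a standard-code start codon are start-readthrough", {
  # gene under code 15 begins upstream; a code-11 gene starts mid-peptide
  sq <- "ATGAAAGAAATGGAATAA"     # code 15/11 frame 0: M K E M E *
  ctg <- contig("c", sq)
  g15 <- predict_orfs(ctg, load_code_table(15), min_protein_len = 1)
  g15 <- g15[g15$start == 0L & g15$strand == "+", , drop = FALSE]
  g11 <- data.frame(gene_id = "inner", contig_id = "c", start = 9L,
                    end = 18L, strand = "+", code_id = 11L, protein = "ME",
                    includes_stop_codon = TRUE, stringsAsFactors = FALSE)
  rec <- data.frame(record_id = "c15|g", sequence = g15$protein,
                    source = "phage-code15", gene_id = g15$gene_id,
                    extension_len = 0L, is_decoy = FALSE,
                    stringsAsFactors = FALSE)
  al <- map_peptide("KEME", rec, g15, ctg)[[1]]
  expect_true("start-readthrough" %in% classify_peptide(al, rec, g11))
  # without residues upstream of the inner start there is no call
  al2 <- map_peptide("ME", rec, g15, ctg)
  al2 <- al2[[length(al2)]]   # the occurrence at the inner start
  expect_false("start-readthrough" %in% classify_peptide(al2, rec, g11))
})

test_that("classification is independent of database record order", {
  fx <- ev_fixture()
  extra <- data.frame(record_id = c("aux|1", "c11|h"),
                      sequence = c("GGGGG", "MKAAA"),
                      source = c("auxiliary", "phage-code11"),
                      gene_id = c(NA, "h"), extension_len = 0L,
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  db <- rbind(fx$rec, extra)
  g11 <- fx$gene[0, ]
  al <- map_peptide("MK", fx$rec, fx$gene, fx$ctg)[[1]]
  expect_identical(classify_peptide(al, db, g11),
                   classify_peptide(al, db[rev(seq_len(nrow(db))), ], g11))
})

test_that("corroboration enforces sharing, ALC and residue confidence", {
  fx <- ev_fixture()
  al <- map_peptide("MKQE", fx$rec, fx$gene, fx$ctg)[[1]]
  tag <- function(seq, alc, conf) {
    d <- data.frame(sequence = seq, alc = alc, stringsAsFactors = FALSE)
    d$residue_conf <- list(conf)
    d
  }
  # needs >= 6 shared residues: extend the fixture peptide context
  pep <- "MKQELK"
  rec <- fx$rec; rec$sequence <- "MKQELK"
  v <- corroborate_peptide(pep, tag("MKQELK", 95, rep(95, 6)), al)
  expect_true(v$shared)
  expect_true(all(v$recoded))
  # recoded Q below the residue threshold
  v2 <- corroborate_peptide(pep, tag("MKQELK", 93, c(95, 95, 85, 95, 95, 95)),
                            al)
  expect_true(v2$shared)
  expect_false(any(v2$recoded))
  # flanking residue below threshold also fails the recoding check
  v3 <- corroborate_peptide(pep, tag("MKQELK", 93, c(95, 85, 95, 95, 95, 95)),
                            al)
  expect_false(any(v3$recoded))
  # five shared residues are not enough however confident
  v4 <- corroborate_peptide(pep, tag("MKQEL", 99, rep(99, 5)), al)
  expect_false(v4$shared)
  # ALC gate is exclusive
  v5 <- corroborate_peptide(pep, tag("MKQELK", 50, rep(99, 6)), al)
  expect_false(v5$shared)
  # I/L equivalence in tag matching
  v6 <- corroborate_peptide("MKQEIK", tag("MKQELK", 95, rep(95, 6)), al)
  expect_true(v6$shared)
})

test_that("recoding events group supporting peptides by TAG position", {
  fx <- ev_fixture()
  als <- c(map_peptide("KQE", fx$rec, fx$gene, fx$ctg),
           map_peptide("MKQE", fx$rec, fx$gene, fx$ctg))
  ev <- recoding_events(als, NULL, NULL, fx$ctg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tag_start, 6L)
  expect_equal(ev$n_peptides, 2L)
  expect_identical(ev$observed_residue, "Q")
  # a corrupted alignment pointing at a non-TAG codon is a hard error
  bad <- als[[1]]
  bad$codon_start <- bad$codon_start - 3L
  expect_error(recoding_events(list(bad), NULL, NULL, fx$ctg), "non-TAG")
})

test_that("gene summaries recount the accepted evidence", {
  fx <- ev_fixture()
  als <- c(map_peptide("KQE", fx$rec, fx$gene, fx$ctg),
           map_peptide("MK", fx$rec, fx$gene, fx$ctg))
  cls <- list(KQE = c("code15-exclusive", "stop-readthrough"),
              MK = "shared")
  ev <- recoding_events(als, cls, NULL, fx$ctg)
  acc <- data.frame(peptide = c("KQE", "MK"), score = c(50, 40),
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  gs <- summarize_genes(ev, als, acc, fx$gene, cls, NULL)
  expect_equal(gs$summary$n_peptides, 2L)
  expect_equal(gs$summary$n_unique_peptides, 2L)
  expect_equal(gs$summary$n_code15_exclusive, 1L)
  expect_equal(gs$summary$n_recoding_events, 1L)
  expect_true(gs$summary$detected)
  cov <- gs$coverage
  expect_equal(nrow(cov), 4L)                     # MKQE
  expect_identical(cov$covered_by_peptide, rep(TRUE, 4))
  expect_identical(cov$recoded_q, c(FALSE, FALSE, TRUE, FALSE))
  # a gene without accepted peptides is not detected
  lone <- fx$gene; lone$gene_id <- "lonely"
  gs2 <- summarize_genes(ev, als, acc, lone, cls, NULL)
  expect_false(gs2$summary$detected)
  expect_equal(gs2$summary$n_peptides, 0L)
})
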