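test_that("tryptic digestion applies the K/R-not-P rule", {
  d0 <- digest_protein(c(p = "MKRAGQKPLR"), max_missed = 0)
  expect_setequal(d0$sequence, c("MK", "R", "AGQKPLR"))
  d1 <- digest_protein(c(p = "MKRAGQKPLR"), max_missed = 1)
  expect_setequal(d1$sequence, c("MK", "R", "AGQKPLR", "MKR", "RAGQKPLR"))
  expect_setequal(d1$missed_cleavages[d1$sequence %in% c("MKR", "RAGQKPLR")],
                  1L)
})

test_that("digestion equals brute-force substring enumeration", {
  set.seed(37)
  for (i in 1:40) {
    sq <- random_protein(sample(5:30, 1))
    mm <- sample(0:3, 1)
    for (semi in c(FALSE, TRUE)) {
      got <- digest_protein(stats::setNames(sq, "p"), max_missed = mm,
                            specificity = if (semi) "semi" else "full")
      exp <- oracle_digest(sq, mm, semi)
      key <- function(d) sort(paste(d$start, d$sequence,
                                    d$missed_cleavages, d$specificity))
      expect_identical(key(got), key(exp))
    }
  }
})

test_that("semi-specific output is a superset of full-specific output", {
  set.seed(41)
  sq <- random_protein(40)
  full <- digest_protein(c(p = sq), max_missed = 2, specificity = "full")
  semi <- digest_protein(c(p = sq), max_missed = 2, specificity = "semi")
  expect_true(all(paste(full$start, full$sequence) %in%
                    paste(semi$start, semi$sequence)))
  # every peptide is a substring of its parent at the recorded offset
  expect_true(all(substring(sq, semi$start + 1,
                            semi$start + nchar(semi$sequence)) ==
                    semi$sequence))
})

test_that("peptide length bounds restrict the emitted window", {
  sq <- "MKRAGQKPLR"
  d <- digest_protein(c(p = sq), max_missed = 3, specificity = "semi",
                      min_len = 6, max_len = 8)
  expect_true(all(nchar(d$sequence) >= 6 & nchar(d$sequence) <= 8))
})

test_that("monoisotopic masses match reference values", {
  expect_equal(peptide_mass("PEPTIDE")$mass, 799.3600, tolerance = 1e-3)
  expect_equal(peptide_mass("C")$mass, 103.00919 + 18.010565 + 57.021464,
               tolerance = 1e-5)
  mm <- peptide_mass("MM")
  expect_equal(nrow(mm), 3L)
  expect_equal(mm$n_var_mods, 0:2)
  expect_equal(diff(mm$mass), rep(15.994915, 2), tolerance = 1e-6)
  # cap on total variable modifications
  m4 <- peptide_mass("MMMM", max_var = 3)
  expect_equal(max(m4$n_var_mods), 3L)
  expect_error(peptide_mass("MBZ"), "unknown residue")
  # digestion masses agree with the standalone calculator
  d <- digest_protein(c(p = "ACDEFGHIKLMNPQR"), max_missed = 3)
  for (i in seq_len(nrow(d))) {
    expect_equal(d$mono_mass[i], peptide_mass(d$sequence[i])$mass[1],
                 tolerance = 1e-9)
  }
})

test_that("upstream extensions stop at TAA/TGA, read TAG as Q, cap at 30", {
  filler <- function(d) strrep("GCA", d)
  for (d in c(0:5, 28:35)) {
    for (B in c("TAA", "TGA", "TAG", "")) {
      sense <- paste0(B, filler(d), "ATGAAATAA")
      p <- nchar(B) + 3 * d          # gene start in sense coordinates
      # plus strand
      ctg <- contig("f", sense)
      gene <- list(gene_id = "g", start = p, end = p + 9L, strand = "+")
      ext <- upstream_extension(gene, ctg)
      expected_len <- if (B %in% c("TAA", "TGA")) min(d, 30)
                      else if (B == "TAG") min(d + 1, 30)
                      else min(d, 30)
      expect_identical(nchar(ext), as.integer(expected_len))
      # never a residue from a TAA/TGA codon; alanine filler plus at most
      # one Q from a crossed TAG
      expect_true(grepl("^Q?A*$", ext) || grepl("^A*$", ext))
      if (B == "TAG" && d <= 29) {
        expect_identical(ext, paste0("Q", strrep("A", d)))
      }
      # minus strand mirror
      L <- nchar(sense)
      ctg_m <- contig("m", revcomp(sense))
      gene_m <- list(gene_id = "g", start = L - (p + 9L), end = L - p,
                     strand = "-")
      expect_identical(upstream_extension(gene_m, ctg_m), ext)
    }
  }
})

test_that("the layered database has dual-code records plus reversed decoys", {
  sq <- paste0("ATGAAATAA", "ATGGAATAA")
  ctg <- contig("c", sq)
  g11 <- predict_orfs(ctg, load_code_table(11), min_protein_len = 1)
  g15 <- predict_orfs(ctg, load_code_table(15), min_protein_len = 1)
  db <- build_protein_db(g11, g15, ctg)
  # 2 genes per code, no upstream room on gene 1 and a TAA bound on gene 2
  expect_equal(nrow(db), 8L)
  expect_equal(sum(db$is_decoy), 4L)
  dec <- db[db$is_decoy, ]
  tgt <- db[!db$is_decoy, ]
  expect_identical(dec$sequence,
                   vapply(strsplit(tgt$sequence, ""), function(x) {
                     paste(rev(x), collapse = "")
                   }, character(1)))
  # same length distribution and residue composition
  expect_identical(sort(nchar(dec$sequence)), sort(nchar(tgt$sequence)))
  expect_identical(sort(strsplit(paste(dec$sequence, collapse = ""), "")[[1]]),
                   sort(strsplit(paste(tgt$sequence, collapse = ""), "")[[1]]))
})

test_that("decoy of MKQE is EQKM and extended records carry provenance", {
  ctg <- contig("c", "GCTATGAAATAGGAATAA")   # AQ codon then gene
  g15 <- predict_orfs(ctg, load_code_table(15), min_protein_len = 1)
  g15 <- g15[g15$strand == "+" & g15$start == 3L, , drop = FALSE]
  expect_identical(g15$protein, "MKQE")
  db <- build_protein_db(g15[0, ], g15, ctg)
  expect_identical(db$sequence[db$record_id == paste0("rev_c15|",
                                                      g15$gene_id)], "EQKM")
  ext <- db[db$source == "phage-code15-extended" & !db$is_decoy, ]
  expect_equal(nrow(ext), 1L)
  expect_identical(ext$sequence, "AMKQE")   # GCT upstream, bounded by edge
  expect_equal(ext$extension_len, 1L)
})

test_that("code-15 records reproduce the translated gene spans", {
  res <- sim_fixture(seed = 202L)
  db <- build_protein_db(res$p11, res$p15, res$sim$contig)
  c15 <- db[db$source == "phage-code15" & !db$is_decoy, ]
  idx <- match(c15$gene_id, res$p15$gene_id)
  for (i in sample(seq_len(nrow(c15)), 10)) {
    cds <- gene_cds(res$p15[idx[i], ], res$sim$contig)
    expect_identical(c15$sequence[i],
                     translate_cds(cds, load_code_table(15), "truncate"))
  }
  expect_false(anyDuplicated(db$record_id) > 0)
})
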