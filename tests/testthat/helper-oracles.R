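# Independent brute-force oracles and small fixture builders.

random_dna <- function(n, p = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(p), n, TRUE, p), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, TRUE), collapse = "")
}

# exhaustive six-frame ORF enumeration by a codon-by-codon state machine
# (structurally independent of the vectorised caller)
oracle_orfs <- function(sq, table, min_len) {
  L <- nchar(sq)
  out <- list()
  emit <- function(strand, fr, k_start, k_end, has_stop, codons) {
    aa <- unname(table$codon_map[codons[k_start:k_end]])
    aa[is.na(aa)] <- "X"
    prot <- paste(aa, collapse = "")
    if (nchar(prot) < min_len) return()
    last <- if (has_stop) k_end + 1L else k_end
    ls <- fr + (k_start - 1L) * 3L
    le <- fr + last * 3L
    if (strand == "+") {
      gs <- ls; ge <- le
    } else {
      gs <- L - le; ge <- L - ls
    }
    out[[length(out) + 1L]] <<- data.frame(
      start = gs, end = ge, strand = strand, protein = prot,
      includes_stop_codon = has_stop, stringsAsFactors = FALSE)
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sq else ambercode::revcomp(sq)
    for (fr in 0:2) {
      n <- (L - fr) %/% 3L
      if (n < 1L) next
      codons <- vapply(0:(n - 1L), function(k) {
        substr(s, fr + 3L * k + 1L, fr + 3L * k + 3L)
      }, character(1))
      is_stop <- !grepl("N", codons) &
        codons %in% table$stop_codons
      cur <- NA_integer_
      for (k in seq_len(n)) {
        if (is_stop[k]) {
          if (!is.na(cur)) emit(strand, fr, cur, k - 1L, TRUE, codons)
          cur <- NA_integer_
        } else if (is.na(cur) && !grepl("N", codons[k]) &&
                   codons[k] %in% table$start_codons) {
          cur <- k
        }
      }
      if (!is.na(cur)) emit(strand, fr, cur, n, FALSE, codons)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      includes_stop_codon = logical(0)))
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$end, d$strand), , drop = FALSE]
}

# brute-force tryptic digestion by testing every substring against the
# cleavage predicates
oracle_digest <- function(sq, max_missed, semi, min_len = 1, max_len = Inf) {
  res <- strsplit(sq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  site <- function(i) {
    i >= 1L && i <= n - 1L && res[i] %in% c("K", "R") && res[i + 1L] != "P"
  }
  rows <- list()
  for (s0 in 0:(n - 1L)) {
    for (e in (s0 + 1L):n) {
      len <- e - s0
      if (len < min_len || len > max_len) next
      inner <- if (e - 1L >= s0 + 1L) (s0 + 1L):(e - 1L) else integer(0)
      missed <- sum(vapply(inner, site, logical(1)))
      if (missed > max_missed) next
      nt <- s0 == 0L || site(s0)
      ct <- e == n || site(e)
      keep <- if (semi) (nt || ct) else (nt && ct)
      if (!keep) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(sq, s0 + 1L, e), start = s0,
        missed_cleavages = missed,
        specificity = if (nt && ct) "full" else if (nt) "semi-N"
                      else "semi-C",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      missed_cleavages = integer(0),
                      specificity = character(0)))
  }
  d <- do.call(rbind, rows)
  d[order(d$start, nchar(d$sequence)), , drop = FALSE]
}

# per-base coding density with multiplicity
oracle_density <- function(len, genes) {
  counts <- integer(len)
  for (i in seq_len(nrow(genes))) {
    idx <- (genes$start[i] + 1L):genes$end[i]
    counts[idx] <- counts[idx] + 1L
  }
  sum(counts) / len
}

# shared memoised synthetic run used by several acceptance checks
.sim_cache <- new.env(parent = emptyenv())
sim_fixture <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- ambercode::sim_config(seed = seed)
    sim <- ambercode::simulate_genome(cfg)
    p15 <- ambercode::select_genes(
      ambercode::predict_orfs(sim$contig, ambercode::load_code_table(15L)))
    p11 <- ambercode::select_genes(
      ambercode::predict_orfs(sim$contig, ambercode::load_code_table(11L)))
    .sim_cache[[key]] <- list(cfg = cfg, sim = sim, p15 = p15, p11 = p11)
  }
  .sim_cache[[key]]
}
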