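#' Coding density of a contig
#'
#' Summed gene length divided by contig length. With `method = "raw"`
#' (the definition used by the code-assignment rule) overlapping gene spans
#' are counted with multiplicity, so the value can exceed 1 when genes on
#' opposite strands overlap. `method = "union"` is a per-base union
#' diagnostic bounded by 1.
#'
#' @param ctg A [contig].
#' @param genes Gene-model data frame; all genes must lie on `ctg`.
#' @param method `"raw"` (default) or `"union"`.
#' @return Numeric fraction.
#' @export
coding_density <- function(ctg, genes, method = c("raw", "union")) {
  method <- match.arg(method)
  stopifnot(inherits(ctg, "contig"), is.data.frame(genes))
  L <- nchar(ctg$sequence)
  if (nrow(genes) == 0L) return(0)
  if (!all(genes$contig_id == ctg$contig_id)) {
    stop("genes reference a different contig than '", ctg$contig_id, "'",
         call. = FALSE)
  }
  if (any(genes$start < 0L) || any(genes$end > L) ||
      any(genes$start >= genes$end)) {
    stop("gene coordinates outside contig bounds [0, ", L, ")", call. = FALSE)
  }
  if (method == "raw") {
    sum(genes$end - genes$start) / L
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
    sum(IRanges::width(ir)) / L
  }
}

#' Assign the genetic code of a contig from its dual-code coding densities
#'
#' Applies contig-size-dependent thresholds to the gain in coding density
#' obtained by predicting genes under code 15 instead of code 11: contigs of
#' 5-100 kb are assigned code 15 when the gain strictly exceeds 10
#' percentage points; contigs of at least 100 kb when it strictly exceeds 5
#' points. Contigs shorter than 5 kb are reported as indeterminate rather
#' than silently defaulting to the standard code.
#'
#' @param ctg A [contig].
#' @param genes_11,genes_15 Gene models predicted on `ctg` under tables 11
#'   and 15 respectively.
#' @param gain_mode `"absolute"` (default; gain in percentage points of
#'   coding density) or `"relative"` (percent change relative to the code-11
#'   density).
#' @return One-row data frame with columns `contig_id`, `contig_len`,
#'   `density_11`, `density_15`, `gain_points`, `assigned_code`
#'   (`"11"`, `"15"` or `"indeterminate"`) and `rule`.
#' @export
assign_code <- function(ctg, genes_11, genes_15,
                        gain_mode = c("absolute", "relative")) {
  gain_mode <- match.arg(gain_mode)
  L <- nchar(ctg$sequence)
  d11 <- coding_density(ctg, genes_11)
  d15 <- coding_density(ctg, genes_15)
  gain <- if (gain_mode == "absolute") {
    (d15 - d11) * 100
  } else {
    if (d11 > 0) (d15 - d11) / d11 * 100 else Inf
  }
  # strict thresholds: shave float representation error so a gain that is
  # mathematically exactly at the boundary does not sneak past it
  gain <- round(gain, 9)
  if (L < 5000L) {
    assigned <- "indeterminate"; rule <- "below-size-floor"
  } else if (L < 100000L) {
    rule <- "5-100kb:>10"
    assigned <- if (gain > 10) "15" else "11"
  } else {
    rule <- ">=100kb:>5"
    assigned <- if (gain > 5) "15" else "11"
  }
  data.frame(contig_id = ctg$contig_id, contig_len = L,
             density_11 = d11, density_15 = d15, gain_points = gain,
             assigned_code = assigned, rule = rule,
             stringsAsFactors = FALSE)
}

#' GC skew profile and replichore landmarks
#'
#' Computes per-window GC skew (G - C)/(G + C) in sliding windows tiled from
#' position 0, the cumulative skew curve, and the positions of its global
#' extrema. Under the convention that the leading strand is G-rich, the
#' cumulative maximum marks the replication terminus and the minimum the
#' origin; the two arms between them are the replichores.
#'
#' @param ctg A [contig].
#' @param window Window size in nt (default 1000).
#' @param step Step between window starts in nt (default 10).
#' @return An object of class `skew_profile`: list with `contig_id`,
#'   `window`, `step`, `positions` (window centres), `skew`, `cumulative`,
#'   `origin_pos`, `terminus_pos`.
#' @export
gc_skew <- function(ctg, window = 1000L, step = 10L) {
  stopifnot(inherits(ctg, "contig"))
  L <- nchar(ctg$sequence)
  if (!(step > 0L && step <= window)) {
    stop("require 0 < step <= window", call. = FALSE)
  }
  if (window > L) {
    stop("window (", window, ") exceeds contig length (", L, ")",
         call. = FALSE)
  }
  ch <- strsplit(ctg$sequence, "", fixed = TRUE)[[1L]]
  cg <- c(0, cumsum(ch == "G"))
  cc <- c(0, cumsum(ch == "C"))
  starts0 <- seq.int(0L, L - window, by = step)
  g <- cg[starts0 + window + 1L] - cg[starts0 + 1L]
  c_ <- cc[starts0 + window + 1L] - cc[starts0 + 1L]
  denom <- g + c_
  skew <- ifelse(denom == 0, 0, (g - c_) / denom)
  cumulative <- cumsum(skew)
  positions <- starts0 + window / 2
  structure(list(
    contig_id = ctg$contig_id, window = window, step = step,
    positions = positions, skew = skew, cumulative = cumulative,
    origin_pos = positions[which.min(cumulative)],
    terminus_pos = positions[which.max(cumulative)]
  ), class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat("<skew_profile>", x$contig_id, "-", length(x$skew), "windows of",
      x$window, "nt (step", x$step, "nt)\n")
  cat("  origin ~", x$origin_pos, "nt; terminus ~", x$terminus_pos, "nt\n")
  invisible(x)
}

#' @rdname gc_skew
#' @param x A `skew_profile`.
#' @param ... Unused.
#' @return `as.data.frame()` returns columns `position`, `skew`,
#'   `cumulative`.
#' @export
as.data.frame.skew_profile <- function(x, ...) {
  data.frame(contig_id = x$contig_id, position = x$positions,
             skew = x$skew, cumulative = x$cumulative,
             stringsAsFactors = FALSE)
}
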