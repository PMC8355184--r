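#' Derive a child random seed from a global seed and a stage key
#'
#' All stochastic stages of the pipeline (per-gene permutation nulls, the
#' synthetic-data sub-generators, per-repetition train/test splits) derive
#' their own seed deterministically from the user-supplied global seed and a
#' stable text key. This makes every stage reproducible in isolation and
#' independent of iteration order.
#'
#' @param seed integer global seed.
#' @param key character key naming the stage (e.g. `"copnull:GENE1"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "copnull:G0001")
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  # 31-ary rolling hash; intermediate products stay < 2^53 so doubles are exact
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Largest adjusted p-value passing Benjamini-Hochberg at a given FDR
#'
#' @param p numeric vector of (adjusted, per-unit) p-values.
#' @param fdr target false discovery rate.
#' @return The largest p among units passing BH at `fdr`, or `NA_real_` if
#'   none passes.
#' @export
bh_threshold <- function(p, fdr) {
  stopifnot(fdr > 0, fdr < 1)
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  pass <- p.adjust(p, method = "BH") <= fdr
  if (!any(pass)) return(NA_real_)
  max(p[pass])
}

#' Canonical unordered pair key
#'
#' @param a,b character vectors of gene ids.
#' @return Character key `min(a,b)|max(a,b)`.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# count, per query, how many 0-based half-open track intervals intersect the
# 0-based half-open query [qs, qe); all on the same chromosome namespace
count_overlaps0 <- function(q_chrom, q_start, q_end, t_chrom, t_start, t_end) {
  n <- length(q_start)
  out <- integer(n)
  if (!length(t_start) || !n) return(out)
  for (chr in unique(q_chrom)) {
    qi <- which(q_chrom == chr)
    ti <- which(t_chrom == chr)
    if (!length(ti)) next
    q <- IRanges::IRanges(start = q_start[qi] + 1L, end = pmax(q_end[qi], q_start[qi] + 1L))
    t <- IRanges::IRanges(start = t_start[ti] + 1L, end = t_end[ti])
    keep <- q_end[qi] > q_start[qi]  # empty query intervals overlap nothing
    cnt <- IRanges::countOverlaps(q, t)
    cnt[!keep] <- 0L
    out[qi] <- cnt
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
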