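# 2x2 association summary: sample (cross-product) odds ratio with 0.5
# continuity correction on zero cells, Woolf 95% CI, Fisher exact p-value
or_test <- function(a, b, c, d, alternative = "two.sided") {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = alternative)$p.value
  zero <- any(tab == 0)
  if (zero) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(odds_ratio = or, p_value = p,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       continuity = zero)
}

#' Functional relatedness enrichment of co-expressed pairs
#'
#' For each pair-level annotation source (same GO term, same pathway, same
#' protein complex, paralogy), tests whether called pairs are related more
#' often than the other tested pairs with a one-sided Fisher's exact test
#' on the 2x2 table (COP vs not) x (related vs not). The odds ratio is the
#' sample cross-product (0.5 continuity correction on zero cells).
#'
#' @param pairs tested pair data.frame with an `is_cop` logical column.
#' @param related named list of logical vectors (length `nrow(pairs)`) or
#'   of pair-key character sets marking related pairs per source.
#' @return data.frame `annotation`, `odds_ratio`, `p_value`, `ci_low`,
#'   `ci_high`, and the 2x2 counts.
#' @export
pair_functional_enrichment <- function(pairs, related) {
  stopifnot("is_cop" %in% names(pairs), length(related) >= 1,
            !is.null(names(related)))
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  rows <- lapply(names(related), function(nm) {
    rel <- related[[nm]]
    if (is.character(rel)) rel <- key %in% rel
    stopifnot(length(rel) == nrow(pairs))
    a <- sum(pairs$is_cop & rel);  b <- sum(pairs$is_cop & !rel)
    c <- sum(!pairs$is_cop & rel); d <- sum(!pairs$is_cop & !rel)
    t <- or_test(a, b, c, d, alternative = "greater")
    data.frame(annotation = nm, odds_ratio = t$odds_ratio,
               p_value = t$p_value, ci_low = t$ci_low, ci_high = t$ci_high,
               cop_related = a, cop_unrelated = b,
               other_related = c, other_unrelated = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-gene annotation neighborhoods as TSS-relative, strand-mirrored
# half-open offset intervals within +/- window
gene_neighborhoods <- function(genes, catalog, track, window) {
  ci <- match(genes, catalog$gene_id)
  stopifnot(!anyNA(ci))
  lapply(seq_along(genes), function(k) {
    chr <- catalog$chrom[ci[k]]; tss <- catalog$tss[ci[k]]
    str <- catalog$strand[ci[k]]
    sel <- track$chrom == chr & track$start < tss + window &
      track$end > tss - window
    s <- track$start[sel]; e <- track$end[sel]
    if (identical(str, "-")) {
      # mirror [s, e) about the TSS (positions p -> 2 tss - p), expressed
      # directly as offsets from the TSS
      cbind(start = tss - e + 1L, end = tss - s + 1L)
    } else {
      cbind(start = s - tss, end = e - tss)
    }
  })
}

# strand-aware offset of a position from its gene's TSS
tss_offset <- function(pos, tss, strand) {
  ifelse(strand == "-", tss - pos, pos - tss)
}

#' Permutation enrichment of eQTLs in annotation intervals
#'
#' Tests whether lead eQTLs fall within an annotation track more often
#' than expected by chance, while preserving the layout of annotations
#' around genes: each gene's neighborhood (annotation intervals as
#' TSS-relative offsets, mirrored for minus-strand genes) is randomly
#' reassigned among the genes in each permutation, and the expected
#' overlap is the mean over permutations. Granularity is gene-eQTL pairs
#' (a variant leading two genes counts twice). The p-value is the
#' two-sided empirical permutation probability (floor `1/(n_perm+1)`);
#' the odds ratio compares observed vs rounded-expected overlap in a 2x2
#' Fisher layout.
#'
#' @param leads data.frame `gene_id`, `variant_id`.
#' @param variants variant table (`variant_id`, `pos`, `chrom`).
#' @param catalog gene catalog with `strand`.
#' @param track interval data.frame (`chrom`, `start`, `end`).
#' @param n_perm number of permutations (default 10,000).
#' @param window neighborhood half-width in bp (default 1 Mb).
#' @param seed integer seed.
#' @return One-row data.frame: `observed`, `expected`, `total`,
#'   `odds_ratio`, `p_value`, `ci_low`, `ci_high`, `n_perm`.
#' @export
eqtl_annotation_enrichment <- function(leads, variants, catalog, track,
                                       n_perm = 10000, window = 1e6,
                                       seed = 1) {
  stopifnot(n_perm >= 1, nrow(leads) >= 1)
  genes <- unique(leads$gene_id)
  nb <- gene_neighborhoods(genes, catalog, track, window)
  ci <- match(leads$gene_id, catalog$gene_id)
  vi <- match(leads$variant_id, variants$variant_id)
  off <- tss_offset(variants$pos[vi], catalog$tss[ci], catalog$strand[ci])
  gidx <- match(leads$gene_id, genes)

  # membership of each eQTL offset in each candidate neighborhood
  M <- matrix(FALSE, nrow = nrow(leads), ncol = length(genes))
  for (j in seq_along(genes)) {
    iv <- nb[[j]]
    if (!nrow(iv)) next
    M[, j] <- vapply(off, function(d)
      any(iv[, "start"] <= d & d < iv[, "end"]), logical(1))
  }
  observed <- sum(M[cbind(seq_len(nrow(leads)), gidx)])
  set.seed(derive_seed(seed, "fenrich"))
  perm_overlap <- vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(length(genes))
    sum(M[cbind(seq_len(nrow(leads)), pm[gidx])])
  }, numeric(1))
  expected <- mean(perm_overlap)
  total <- nrow(leads)
  t <- or_test(observed, total - observed,
               round(expected), total - round(expected))
  p_hi <- (sum(perm_overlap >= observed) + 1) / (n_perm + 1)
  p_lo <- (sum(perm_overlap <= observed) + 1) / (n_perm + 1)
  p_emp <- min(1, 2 * min(p_hi, p_lo))
  data.frame(observed = observed, expected = expected, total = total,
             odds_ratio = t$odds_ratio, p_value = p_emp,
             ci_low = t$ci_low, ci_high = t$ci_high, n_perm = n_perm)
}

#' Direct enrichment of shared vs other lead eQTLs in annotations
#'
#' For each annotation track, a two-sided Fisher's exact test of
#' (shared vs other lead eQTL) x (overlapping vs not).
#'
#' @param shared_pos,other_pos data.frames with `chrom`, `pos` of the two
#'   eQTL sets (both nonempty).
#' @param tracks named list of interval data.frames.
#' @return data.frame per track: `annotation`, overlap counts,
#'   `odds_ratio`, `p_value`, `ci_low`, `ci_high`.
#' @export
shared_vs_other_enrichment <- function(shared_pos, other_pos, tracks) {
  stopifnot(nrow(shared_pos) >= 1, nrow(other_pos) >= 1,
            !is.null(names(tracks)))
  hit <- function(pos, track)
    count_overlaps0(pos$chrom, pos$pos, pos$pos + 1L,
                    track$chrom, track$start, track$end) > 0
  rows <- lapply(names(tracks), function(nm) {
    hs <- hit(shared_pos, tracks[[nm]]); ho <- hit(other_pos, tracks[[nm]])
    t <- or_test(sum(hs), sum(!hs), sum(ho), sum(!ho))
    data.frame(annotation = nm,
               shared_overlap = sum(hs), shared_total = length(hs),
               other_overlap = sum(ho), other_total = length(ho),
               odds_ratio = t$odds_ratio, p_value = t$p_value,
               ci_low = t$ci_low, ci_high = t$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
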