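#' CTCF insulation metrics for gene pairs
#'
#' `total_ctcf` counts CTCF-site intervals intersecting the open interval
#' between the two TSSs; `inverted_ctcf` is the product of the numbers of
#' `+` and `-` oriented CTCF motifs in that interval - every
#' opposite-orientation pairing is a potential DNA loop anchor.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param catalog gene catalog.
#' @param ctcf_sites,ctcf_motifs interval data.frames (`chrom`, `start`,
#'   `end`, `strand`) in 0-based half-open coordinates.
#' @return `pairs` with `total_ctcf` and `inverted_ctcf` columns.
#' @export
ctcf_metrics <- function(pairs, catalog, ctcf_sites, ctcf_motifs) {
  tss <- setNames(catalog$tss, catalog$gene_id)
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  lo <- pmin(tss[pairs$gene_a], tss[pairs$gene_b])
  hi <- pmax(tss[pairs$gene_a], tss[pairs$gene_b])
  chr <- unname(chrom[pairs$gene_a])
  # open interval (lo, hi) -> half-open [lo + 1, hi)
  pairs$total_ctcf <- count_overlaps0(chr, lo + 1L, hi,
                                      ctcf_sites$chrom, ctcf_sites$start,
                                      ctcf_sites$end)
  mp <- ctcf_motifs[ctcf_motifs$strand == "+", , drop = FALSE]
  mm <- ctcf_motifs[ctcf_motifs$strand == "-", , drop = FALSE]
  n_pos <- count_overlaps0(chr, lo + 1L, hi, mp$chrom, mp$start, mp$end)
  n_neg <- count_overlaps0(chr, lo + 1L, hi, mm$chrom, mm$start, mm$end)
  pairs$inverted_ctcf <- n_pos * n_neg
  pairs
}

#' Chromatin contact between the TSS bins of a gene pair
#'
#' Looks up the normalised contact value between the `resolution`-sized
#' bins containing the two TSSs (`bin = floor(TSS / resolution) *
#' resolution`); absent bin pairs are zero.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param catalog gene catalog.
#' @param contacts data.frame `chrom`, `bin1`, `bin2`, `count` with
#'   `bin1 <= bin2`.
#' @param resolution bin size in bp (default 5000).
#' @return `pairs` with a `hic_contact` column.
#' @export
hic_contact <- function(pairs, catalog, contacts, resolution = 5000) {
  tss <- setNames(catalog$tss, catalog$gene_id)
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  b1 <- (tss[pairs$gene_a] %/% resolution) * resolution
  b2 <- (tss[pairs$gene_b] %/% resolution) * resolution
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  key <- paste(unname(chrom[pairs$gene_a]), lo, hi)
  idx <- match(key, paste(contacts$chrom, contacts$bin1, contacts$bin2))
  pairs$hic_contact <- ifelse(is.na(idx), 0, contacts$count[idx])
  pairs
}

#' Enhancer sharing and totals for gene pairs
#'
#' `enh_sharing` is the number of enhancers linked to both genes;
#' `enh_total` the number of distinct enhancers linked to either gene (a
#' common enhancer is counted once).
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param links data.frame `enhancer_id`, `gene_id`.
#' @return `pairs` with `enh_sharing` and `enh_total` columns.
#' @export
enhancer_metrics <- function(pairs, links) {
  sets <- split(links$enhancer_id, links$gene_id)
  get <- function(g) sets[[g]] %||% character(0)
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    ea <- unique(get(pairs$gene_a[i])); eb <- unique(get(pairs$gene_b[i]))
    c(length(intersect(ea, eb)), length(union(ea, eb)))
  }, numeric(2))
  pairs$enh_sharing <- res[1, ]
  pairs$enh_total <- res[2, ]
  pairs
}

#' Transcription-factor binding metrics for gene pairs
#'
#' Within the TSS +/- `flank` window of each gene: `tf_shared` counts the
#' distinct motif identifiers present in both windows; `tfbs_total` sums
#' all motif occurrences (redundant included) over the two windows, so an
#' instance overlapping both windows contributes once per window.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param catalog gene catalog.
#' @param motifs interval data.frame with `label` carrying the motif id.
#' @param flank half-window size in bp (default 50,000).
#' @return `pairs` with `tf_shared` and `tfbs_total` columns.
#' @export
tfbs_metrics <- function(pairs, catalog, motifs, flank = 50000) {
  tss <- setNames(catalog$tss, catalog$gene_id)
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  ws <- pmax(0, unname(tss[genes]) - flank)
  we <- unname(tss[genes]) + flank + 1L
  wchr <- unname(chrom[genes])
  total <- count_overlaps0(wchr, ws, we, motifs$chrom, motifs$start, motifs$end)
  names(total) <- genes
  # distinct motif ids per gene window
  idsets <- vector("list", length(genes))
  names(idsets) <- genes
  for (chr in unique(wchr)) {
    gi <- which(wchr == chr)
    ti <- which(motifs$chrom == chr)
    if (!length(ti)) { idsets[gi] <- list(character(0)); next }
    q <- IRanges::IRanges(start = ws[gi] + 1L, end = we[gi])
    t <- IRanges::IRanges(start = motifs$start[ti] + 1L, end = motifs$end[ti])
    hits <- IRanges::findOverlaps(q, t)
    lab <- split(motifs$label[ti][S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), levels = seq_along(gi)))
    idsets[gi] <- lapply(lab, unique)
  }
  pairs$tf_shared <- vapply(seq_len(nrow(pairs)), function(i)
    length(intersect(idsets[[pairs$gene_a[i]]], idsets[[pairs$gene_b[i]]])),
    numeric(1))
  pairs$tfbs_total <- unname(total[pairs$gene_a] + total[pairs$gene_b])
  pairs
}

#' Expression-level and variability similarity for gene pairs
#'
#' Relative differences on the raw expression scale:
#' `diff_expr_level = |m_a - m_b| / ((m_a + m_b) / 2)` with `m` the
#' per-gene summary (mean by default) of raw values, and `diff_coef_var`
#' the analogous quantity on the coefficient of variation (SD / mean).
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param expr_raw raw-scale [locop_expr] (or numeric matrix).
#' @param summary_stat `"mean"` (default) or `"median"` for the expression
#'   level summary.
#' @return `pairs` with `diff_expr_level` and `diff_coef_var` columns.
#' @export
expression_similarity <- function(pairs, expr_raw,
                                  summary_stat = c("mean", "median")) {
  summary_stat <- match.arg(summary_stat)
  v <- if (inherits(expr_raw, "locop_expr")) expr_raw$values else expr_raw
  m <- if (summary_stat == "mean") rowMeans(v) else apply(v, 1, median)
  cv <- apply(v, 1, sd) / rowMeans(v)
  # defined on positive expression units; non-positive pair means carry no
  # usable signal and are zeroed
  rel_diff <- function(x, y) {
    s <- (x + y) / 2
    out <- abs(x - y) / s
    if (any(s <= 0, na.rm = TRUE)) {
      warning("pair(s) with non-positive mean summary; difference set to 0")
      out[s <= 0] <- 0
    }
    out
  }
  pairs$diff_expr_level <- unname(rel_diff(m[pairs$gene_a], m[pairs$gene_b]))
  pairs$diff_coef_var <- unname(rel_diff(cv[pairs$gene_a], cv[pairs$gene_b]))
  pairs
}

#' Promoter linkage-disequilibrium proxy for gene pairs
#'
#' Maximum squared Pearson correlation of genotype dosages between the
#' variants flanking one gene's TSS (+/- `flank`) and those flanking the
#' other's. Monomorphic variants are skipped; empty flanks give 0.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param catalog gene catalog.
#' @param genotypes dosage matrix, variants x individuals.
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param flank half-window in bp (default 5000).
#' @return `pairs` with an `ld_proxy` column.
#' @export
ld_proxy <- function(pairs, catalog, genotypes, variants, flank = 5000) {
  tss <- setNames(catalog$tss, catalog$gene_id)
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  poly <- apply(genotypes, 1, sd) > 0
  flank_of <- function(g) {
    sel <- variants$chrom == chrom[[g]] &
      abs(variants$pos - tss[[g]]) <= flank
    ids <- variants$variant_id[sel]
    ids[poly[ids]]
  }
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  fl <- lapply(setNames(genes, genes), flank_of)
  pairs$ld_proxy <- vapply(seq_len(nrow(pairs)), function(i) {
    va <- fl[[pairs$gene_a[i]]]; vb <- fl[[pairs$gene_b[i]]]
    if (!length(va) || !length(vb)) return(0)
    r <- cor(t(genotypes[va, , drop = FALSE]), t(genotypes[vb, , drop = FALSE]))
    max(r^2)
  }, numeric(1))
  pairs
}

#' Shared GO-like terms for gene pairs
#'
#' Counts annotation terms (exact id match) common to both genes.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param gene_terms data.frame `gene_id`, `term`.
#' @return `pairs` with a `go_sharing` column.
#' @export
go_sharing <- function(pairs, gene_terms) {
  sets <- lapply(split(gene_terms$term, gene_terms$gene_id), unique)
  get <- function(g) sets[[g]] %||% character(0)
  pairs$go_sharing <- vapply(seq_len(nrow(pairs)), function(i)
    length(intersect(get(pairs$gene_a[i]), get(pairs$gene_b[i]))), numeric(1))
  pairs
}

feature_columns <- c("tss_distance", "total_ctcf", "inverted_ctcf",
                     "hic_contact", "enh_sharing", "enh_total", "tf_shared",
                     "tfbs_total", "diff_expr_level", "diff_coef_var",
                     "go_sharing", "ld_proxy", "eqtl_sharing", "coexp_egenes")

#' Assemble the pair-level feature table
#'
#' Merges metric tables into one complete row per pair in a deterministic
#' column order, zero-filling any metric absent for a pair (missing data
#' and NAs are treated as zero signal). Duplicate pair rows are an error.
#'
#' @param pairs labelled pair data.frame (`gene_a`, `gene_b`, `label`, and
#'   optionally `tss_distance`).
#' @param ... metric data.frames keyed by `gene_a`, `gene_b` (outputs of
#'   the metric functions, or an eQTL-sharing table with `sharing` /
#'   `coexp_egenes` columns renamed to `eqtl_sharing` / `coexp_egenes`).
#' @return data.frame: `gene_a`, `gene_b`, the feature columns present
#'   (stable order), `label`.
#' @export
assemble_features <- function(pairs, ...) {
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  if (anyDuplicated(key)) stop("duplicate pair rows")
  out <- pairs
  for (tab in list(...)) {
    if (is.null(tab)) next
    tkey <- pair_key(tab$gene_a, tab$gene_b)
    idx <- match(key, tkey)
    for (col in setdiff(names(tab), c("gene_a", "gene_b", "chrom",
                                      "tss_distance", "label"))) {
      vals <- tab[[col]][idx]
      vals[is.na(vals)] <- 0
      out[[col]] <- vals
    }
  }
  cols <- c("gene_a", "gene_b", intersect(feature_columns, names(out)),
            "label")
  out[, cols]
}

#' Compute all molecular-feature metrics for labelled pairs
#'
#' Convenience wrapper running every metric on a synthetic dataset's
#' tracks and assembling the feature table.
#'
#' @param pairs labelled pair data.frame (see [labelled_pairs()]).
#' @param sim a `locop_sim` dataset.
#' @param sharing optional eQTL sharing table (`gene_a`, `gene_b`,
#'   `sharing`, `coexp_egenes`).
#' @return Feature table (see [assemble_features()]).
#' @export
compute_features <- function(pairs, sim, sharing = NULL) {
  base <- pairs[, c("gene_a", "gene_b")]
  m1 <- ctcf_metrics(base, sim$catalog, sim$tracks$ctcf_sites,
                     sim$tracks$ctcf_motifs)
  m2 <- hic_contact(base, sim$catalog, sim$tracks$hic,
                    resolution = sim$config$hic_resolution)
  m3 <- enhancer_metrics(base, sim$tracks$enhancer_links)
  m4 <- tfbs_metrics(base, sim$catalog, sim$tracks$tf_motifs)
  m5 <- expression_similarity(base, sim$expr)
  m6 <- ld_proxy(base, sim$catalog, sim$genotypes, sim$variants)
  m7 <- go_sharing(base, sim$annotations$go)
  sh <- NULL
  if (!is.null(sharing)) {
    sh <- sharing[, c("gene_a", "gene_b")]
    sh$eqtl_sharing <- sharing$sharing
    sh$coexp_egenes <- sharing$coexp_egenes
  }
  assemble_features(pairs, m1, m2, m3, m4, m5, m6, m7, sh)
}
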