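# simple per-gene association scan: correlation of phenotype with each
# cis dosage vector, converted to the two-sided t-test of the OLS slope
scan_gene <- function(y, G) {
  n <- length(y)
  sds <- apply(G, 1, sd)
  poly <- sds > 0
  r <- rep(NA_real_, nrow(G))
  if (any(poly))
    r[poly] <- drop(suppressWarnings(cor(y, t(G[poly, , drop = FALSE]))))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  beta <- r * sd(y) / sds
  list(r = r, p = p, beta = beta, poly = poly)
}

cis_variant_idx <- function(variants, chrom, tss, window) {
  which(variants$chrom == chrom & abs(variants$pos - tss) <= window)
}

#' Nominal cis-eQTL pass
#'
#' For each gene, regresses inverse-normal expression on the dosage of
#' every variant within `window` of the TSS (variants assumed pre-filtered
#' to MAF >= 5%) and retains associations with nominal p below `p_keep`
#' (the lead variant is retained regardless).
#'
#' @param expr a [locop_expr] in state `int`.
#' @param genotypes dosage matrix, variants x individuals (columns aligned
#'   with `expr`).
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param catalog gene catalog.
#' @param window cis window in bp (default 1 Mb, inclusive).
#' @param p_keep retention threshold on nominal p (default 0.05).
#' @return data.frame `gene_id`, `variant_id`, `beta`, `nominal_p`,
#'   `is_lead`; genes without cis variants are skipped (ids in the
#'   `skipped` attribute).
#' @export
map_cis_nominal <- function(expr, genotypes, variants, catalog,
                            window = 1e6, p_keep = 0.05) {
  stopifnot(inherits(expr, "locop_expr"), expr$state == "int",
            identical(colnames(genotypes), sample_ids(expr)))
  v <- expr$values
  rows <- list()
  skipped <- character(0)
  for (g in rownames(v)) {
    ci <- match(g, catalog$gene_id)
    if (is.na(ci)) next
    idx <- cis_variant_idx(variants, catalog$chrom[ci], catalog$tss[ci],
                           window)
    if (!length(idx)) { skipped <- c(skipped, g); next }
    sc <- scan_gene(v[g, ], genotypes[variants$variant_id[idx], ,
                                      drop = FALSE])
    ok <- sc$poly & !is.na(sc$p)
    if (!any(ok)) { skipped <- c(skipped, g); next }
    lead <- which(ok)[which.min(sc$p[ok])]
    keep <- which(ok & (sc$p < p_keep | seq_along(sc$p) == lead))
    rows[[g]] <- data.frame(gene_id = g,
                            variant_id = variants$variant_id[idx][keep],
                            beta = sc$beta[keep], nominal_p = sc$p[keep],
                            is_lead = keep == lead,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), variant_id = character(0),
                      beta = numeric(0), nominal_p = numeric(0),
                      is_lead = logical(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Permutation cis-eQTL pass: lead variants with adjusted p-values
#'
#' For each gene, the observed best nominal p over its cis variants is
#' compared to a null distribution of best p-values obtained by shuffling
#' the phenotype `R` times. The adjusted p is either the empirical
#' `(r + 1) / (R + 1)` (default) or the CDF of a Beta distribution fitted
#' to the null minima by the method of moments (the small-R approximation
#' used by standard eQTL mappers).
#'
#' @inheritParams map_cis_nominal
#' @param R number of permutations.
#' @param seed global seed; per-gene streams derive from
#'   `derive_seed(seed, paste0("eqtlperm:", gene))`.
#' @param method `"empirical"` or `"beta"`.
#' @return data.frame `gene_id`, `variant_id` (lead), `beta`, `nominal_p`
#'   (best), `adjusted_p`.
#' @export
map_cis_permute <- function(expr, genotypes, variants, catalog,
                            window = 1e6, R = 1000, seed = 1,
                            method = c("empirical", "beta")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "locop_expr"), expr$state == "int", R >= 1)
  v <- expr$values
  n <- ncol(v)
  rows <- list()
  for (g in rownames(v)) {
    ci <- match(g, catalog$gene_id)
    if (is.na(ci)) next
    idx <- cis_variant_idx(variants, catalog$chrom[ci], catalog$tss[ci],
                           window)
    if (!length(idx)) next
    G <- genotypes[variants$variant_id[idx], , drop = FALSE]
    y <- v[g, ]
    sc <- scan_gene(y, G)
    ok <- sc$poly & !is.na(sc$p)
    if (!any(ok)) next
    lead <- which(ok)[which.min(sc$p[ok])]
    obs_p <- sc$p[lead]

    set.seed(derive_seed(seed, paste0("eqtlperm:", g)))
    P <- vapply(seq_len(R), function(r) y[sample.int(n)], numeric(n))
    # best nominal p per permutation corresponds to the max |r|
    null_r <- suppressWarnings(cor(P, t(G[ok, , drop = FALSE])))
    null_r[is.na(null_r)] <- 0
    max_abs_r <- apply(abs(null_r), 1, max)
    tt <- max_abs_r * sqrt((n - 2) / pmax(1 - max_abs_r^2,
                                          .Machine$double.eps))
    null_p <- 2 * pt(-tt, df = n - 2)
    adjusted_p <- if (method == "empirical") {
      (sum(null_p <= obs_p) + 1) / (R + 1)
    } else {
      m <- mean(null_p); s2 <- var(null_p)
      if (s2 <= 0) (sum(null_p <= obs_p) + 1) / (R + 1)
      else {
        common <- m * (1 - m) / s2 - 1
        pbeta(obs_p, shape1 = m * common, shape2 = (1 - m) * common)
      }
    }
    rows[[g]] <- data.frame(gene_id = g,
                            variant_id = variants$variant_id[idx][lead],
                            beta = sc$beta[lead], nominal_p = obs_p,
                            adjusted_p = adjusted_p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), variant_id = character(0),
                      beta = numeric(0), nominal_p = numeric(0),
                      adjusted_p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Call eGenes from lead records
#'
#' Benjamini-Hochberg over the genes' permutation-adjusted p-values; genes
#' passing at `fdr` are eGenes.
#'
#' @param leads output of [map_cis_permute()].
#' @param fdr FDR level (default 0.05).
#' @return `leads` with an `egene` logical column (threshold in the
#'   `threshold` attribute).
#' @export
call_egenes <- function(leads, fdr = 0.05) {
  thr <- bh_threshold(leads$adjusted_p, fdr)
  leads$egene <- !is.na(thr) & leads$adjusted_p <= thr
  attr(leads, "threshold") <- thr
  leads
}

#' Classify gene pairs by lead-eQTL sharing
#'
#' For each pair, counts how many of the (up to two) eGene lead eQTLs are
#' nominally associated (p < `p_thresh`) with the partner gene with the
#' same effect sign. The association of a lead variant with the partner
#' gene is recomputed directly from expression and dosages. Also reports
#' how many genes of the pair are eGenes.
#'
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param leads [call_egenes()] output (must carry `egene`).
#' @param expr a [locop_expr] in state `int`.
#' @param genotypes dosage matrix, variants x individuals.
#' @param p_thresh nominal significance threshold (default 0.05).
#' @return data.frame `gene_a`, `gene_b`, `sharing` (0/1/2),
#'   `coexp_egenes` (0/1/2), `supporting` (semicolon-joined
#'   variant:direction entries).
#' @export
eqtl_sharing <- function(pairs, leads, expr, genotypes, p_thresh = 0.05) {
  stopifnot("egene" %in% names(leads))
  v <- expr$values
  eg <- leads[leads$egene, , drop = FALSE]
  lead_of <- setNames(eg$variant_id, eg$gene_id)
  beta_of <- setNames(eg$beta, eg$gene_id)
  n <- ncol(v)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    sharing <- 0L; support <- character(0)
    test_dir <- function(owner, partner) {
      if (!owner %in% names(lead_of)) return(NULL)
      vid <- lead_of[[owner]]
      d <- genotypes[vid, ]
      if (sd(d) == 0 || !partner %in% rownames(v)) return(NULL)
      r <- cor(v[partner, ], d)
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tt), df = n - 2)
      if (p < p_thresh && sign(r) == sign(beta_of[[owner]]))
        sprintf("%s:%s", vid, if (r > 0) "+" else "-")
      else NULL
    }
    s1 <- test_dir(a, b); s2 <- test_dir(b, a)
    support <- c(s1, s2)
    data.frame(gene_a = a, gene_b = b,
               sharing = length(support),
               coexp_egenes = sum(c(a, b) %in% names(lead_of)),
               supporting = paste(support, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
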