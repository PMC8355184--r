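# chi-squared(1) median: qchisq(0.5, 1), to the precision used throughout
CHISQ1_MEDIAN <- 0.45494

#' Count trait associations per variant
#'
#' Number of traits in which a variant's GWAS p-value is strictly below
#' the genome-wide threshold. Variants absent from the table get NA and
#' are reported in the `missing` attribute.
#'
#' @param gwas data.frame `variant_id`, `trait_id`, `pval`.
#' @param variant_ids variants to query (default: all in the table).
#' @param threshold association threshold (default 5e-8, strict `<`).
#' @return Named integer vector of trait counts.
#' @export
trait_association_counts <- function(gwas, variant_ids = NULL,
                                     threshold = 5e-8) {
  if (is.null(variant_ids)) variant_ids <- unique(gwas$variant_id)
  sig <- gwas[gwas$pval < threshold, , drop = FALSE]
  tab <- table(sig$variant_id)
  counts <- setNames(rep(0L, length(variant_ids)), variant_ids)
  present <- variant_ids %in% gwas$variant_id
  counts[!present] <- NA_integer_
  idx <- match(names(tab), variant_ids)
  hit <- !is.na(idx)
  counts[idx[hit]] <- as.integer(tab[hit])
  if (any(!present))
    message(sum(!present), " queried variant(s) absent from the GWAS table")
  attr(counts, "missing") <- variant_ids[!present]
  counts
}

#' Compare trait pleiotropy between shared and other lead eQTLs
#'
#' Variants are deduplicated upstream (shared status wins across tissues).
#' Tests whether shared variants are associated with at least one trait,
#' and with more than one trait, more often than other variants (Fisher
#' 2x2, sample odds ratio), and compares pleiotropy counts between the
#' categories with a two-sided Wilcoxon rank-sum test - by default
#' restricted to variants associated with at least one trait, as the
#' count distributions are only meaningful among associated variants.
#'
#' @param counts named trait-association counts (see
#'   [trait_association_counts()]); NAs dropped.
#' @param shared logical vector aligned with `counts` (TRUE = shared).
#' @param include_zeros include unassociated variants in the Wilcoxon
#'   comparison (default FALSE).
#' @return A `locop_pleiotropy` list: `fisher_any`, `fisher_multi`
#'   (or_test results), `wilcoxon_p`, `mean_counts` (per category, among
#'   associated), `n` per category.
#' @export
pleiotropy_compare <- function(counts, shared, include_zeros = FALSE) {
  stopifnot(length(counts) == length(shared))
  ok <- !is.na(counts)
  counts <- counts[ok]; shared <- shared[ok]
  if (!any(shared) || all(shared)) stop("need both shared and other variants")
  any1 <- counts >= 1; multi <- counts > 1
  f_any <- or_test(sum(shared & any1), sum(shared & !any1),
                   sum(!shared & any1), sum(!shared & !any1))
  f_multi <- or_test(sum(shared & multi), sum(shared & !multi),
                     sum(!shared & multi), sum(!shared & !multi))
  sel <- if (include_zeros) rep(TRUE, length(counts)) else any1
  w_p <- if (length(unique(shared[sel])) == 2)
    suppressWarnings(wilcox.test(counts[sel][shared[sel]],
                                 counts[sel][!shared[sel]])$p.value)
  else NA_real_
  structure(list(
    fisher_any = f_any, fisher_multi = f_multi, wilcoxon_p = w_p,
    mean_counts = c(shared = mean(counts[shared & any1]),
                    other = mean(counts[!shared & any1])),
    n = c(shared = sum(shared), other = sum(!shared))),
    class = "locop_pleiotropy")
}

#' @export
print.locop_pleiotropy <- function(x, ...) {
  cat(sprintf(paste0("<locop_pleiotropy> OR(>=1 trait) = %.2f, ",
                     "OR(>1 trait) = %.2f, Wilcoxon p = %.3g\n"),
              x$fisher_any$odds_ratio, x$fisher_multi$odds_ratio,
              x$wilcoxon_p))
  invisible(x)
}

#' Genomic inflation factor and QQ coordinates
#'
#' Converts p-values to chi-squared(1) statistics through the upper-tail
#' quantile; lambda is the median statistic divided by the chi-squared(1)
#' median (0.45494). QQ coordinates pair sorted observed -log10 p with
#' expected uniform quantiles.
#'
#' @param p numeric p-values in (0, 1]; zeros are clipped to the smallest
#'   representable positive value with a message.
#' @param qq_sample optional cap on the number of variants in the QQ
#'   output (seed-controlled subsample).
#' @param seed seed for the QQ subsample.
#' @return List: `lambda`, `qq` (data.frame `expected`, `observed`,
#'   both -log10), `n`.
#' @export
genomic_inflation <- function(p, qq_sample = NULL, seed = 1) {
  stopifnot(length(p) >= 1, all(p <= 1, na.rm = TRUE))
  p <- p[!is.na(p)]
  if (any(p <= 0)) {
    message(sum(p <= 0), " p-value(s) at or below 0 clipped")
    p[p <= 0] <- .Machine$double.xmin
  }
  stat <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(stat) / CHISQ1_MEDIAN
  q <- p
  if (!is.null(qq_sample) && length(q) > qq_sample) {
    set.seed(derive_seed(seed, "qq"))
    q <- q[sample.int(length(q), qq_sample)]
  }
  q <- sort(q)
  qq <- data.frame(expected = -log10(stats::ppoints(length(q))),
                   observed = -log10(q))
  list(lambda = lambda, qq = qq, n = length(p))
}
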