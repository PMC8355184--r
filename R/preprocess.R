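#' Gene filtering rules
#'
#' Bundles the filters applied to a raw expression matrix before
#' co-expression discovery: biotype whitelist, excluded genomic regions
#' (e.g. the MHC locus), excluded chromosomes (sex chromosomes), a ceiling
#' on the fraction of individuals with zero expression, and optional
#' minimum-expression rules (value threshold met in at least a fraction of
#' samples; optionally the same for read counts).
#'
#' @param biotypes character vector of biotypes kept (default protein_coding
#'   and lincRNA).
#' @param exclude_regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); genes whose TSS falls inside are removed.
#' @param exclude_chroms character vector of chromosomes removed entirely.
#' @param zero_fraction_max genes with at least this fraction of zero values
#'   are removed (default 0.5).
#' @param expr_threshold,expr_fraction keep genes with value >
#'   `expr_threshold` in at least `expr_fraction` of samples (`NULL` = skip).
#' @param read_threshold,read_fraction same rule on a read-count matrix
#'   (`NULL` = skip).
#' @return A `locop_filter_rules` list.
#' @export
filter_rules <- function(biotypes = c("protein_coding", "lincRNA"),
                         exclude_regions = NULL,
                         exclude_chroms = character(),
                         zero_fraction_max = 0.5,
                         expr_threshold = NULL, expr_fraction = 0.2,
                         read_threshold = NULL, read_fraction = 0.2) {
  stopifnot(zero_fraction_max >= 0, zero_fraction_max <= 1,
            expr_fraction >= 0, expr_fraction <= 1,
            read_fraction >= 0, read_fraction <= 1)
  if (!is.null(exclude_regions))
    stopifnot(all(c("chrom", "start", "end") %in% names(exclude_regions)))
  structure(list(biotypes = biotypes, exclude_regions = exclude_regions,
                 exclude_chroms = exclude_chroms,
                 zero_fraction_max = zero_fraction_max,
                 expr_threshold = expr_threshold, expr_fraction = expr_fraction,
                 read_threshold = read_threshold, read_fraction = read_fraction),
            class = "locop_filter_rules")
}

#' Filter genes of a raw expression matrix
#'
#' Applies biotype, region, chromosome and expression-fraction rules. Each
#' removed gene is logged with the first rule that removed it.
#'
#' @param expr a [locop_expr] in state `raw`.
#' @param catalog gene catalog data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`, `biotype`).
#' @param rules a [filter_rules] object.
#' @param reads optional read-count matrix aligned with `expr` for the read
#'   rule.
#' @return A list with `expr` (state `filtered`) and `removed`
#'   (data.frame `gene_id`, `reason`).
#' @export
filter_genes <- function(expr, catalog, rules = filter_rules(), reads = NULL) {
  stopifnot(inherits(expr, "locop_expr"), expr$state == "raw",
            inherits(rules, "locop_filter_rules"))
  v <- expr$values
  ids <- rownames(v)
  cat_idx <- match(ids, catalog$gene_id)
  if (anyNA(cat_idx)) stop("genes missing from catalog: ",
                           paste(head(ids[is.na(cat_idx)]), collapse = ", "))
  cat_sub <- catalog[cat_idx, ]
  reason <- rep(NA_character_, length(ids))

  mark <- function(bad, why) {
    sel <- bad & is.na(reason)
    reason[sel] <<- why
  }
  if (length(rules$biotypes))
    mark(!(cat_sub$biotype %in% rules$biotypes), "biotype")
  if (length(rules$exclude_chroms))
    mark(cat_sub$chrom %in% rules$exclude_chroms, "chromosome")
  if (!is.null(rules$exclude_regions)) {
    er <- rules$exclude_regions
    in_region <- rep(FALSE, length(ids))
    for (i in seq_len(nrow(er))) {
      in_region <- in_region |
        (cat_sub$chrom == er$chrom[i] &
           cat_sub$tss >= er$start[i] & cat_sub$tss < er$end[i])
    }
    mark(in_region, "excluded_region")
  }
  zero_frac <- rowMeans(v == 0)
  mark(zero_frac >= rules$zero_fraction_max, "zero_fraction")
  if (!is.null(rules$expr_threshold))
    mark(rowMeans(v > rules$expr_threshold) < rules$expr_fraction, "low_expression")
  if (!is.null(rules$read_threshold)) {
    stopifnot(is.matrix(reads), all(dim(reads) == dim(v)))
    mark(rowMeans(reads >= rules$read_threshold) < rules$read_fraction, "low_reads")
  }

  keep <- is.na(reason)
  if (!any(keep)) stop("no genes survive filtering")
  out <- set_expr_state(expr, v[keep, , drop = FALSE], "filtered")
  list(expr = out,
       removed = data.frame(gene_id = ids[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Regress covariates out of each gene's expression
#'
#' Replaces each gene's values by the residuals of an ordinary least-squares
#' fit on the covariates (with intercept). Collinear covariate columns are
#' dropped with a warning.
#'
#' @param expr a [locop_expr] (state `filtered` or `raw`).
#' @param covariates numeric matrix, samples x k (rows aligned with
#'   `sample_ids(expr)`); `NULL` or 0 columns centers the values only.
#' @return A [locop_expr] in state `residualized`.
#' @export
residualize <- function(expr, covariates = NULL) {
  stopifnot(inherits(expr, "locop_expr"))
  v <- expr$values
  n <- ncol(v)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  if (ncol(covariates) >= n) stop("more covariates than samples")
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    warning(sprintf("dropping %d collinear covariate column(s)", length(drop)))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  # residuals of all genes at once: t(v) is samples x genes
  res <- qr.resid(qx, t(v))
  set_expr_state(expr, t(res), "residualized")
}

#' Principal-component covariates from an expression matrix
#'
#' Computes the top principal-component sample scores of the
#' gene-standardized matrix, the deterministic analogue of hidden-factor
#' correction used to absorb unknown technical variation before
#' co-expression and eQTL analysis.
#'
#' @param expr a [locop_expr] in state `filtered`.
#' @param n_pcs number of components (0 returns an empty matrix).
#' @return Numeric matrix samples x `n_pcs` of PC scores.
#' @export
expression_pcs <- function(expr, n_pcs) {
  stopifnot(inherits(expr, "locop_expr"), expr$state == "filtered",
            n_pcs >= 0)
  v <- expr$values
  if (n_pcs == 0)
    return(matrix(numeric(0), nrow = ncol(v), ncol = 0,
                  dimnames = list(colnames(v), NULL)))
  if (n_pcs >= min(dim(v))) stop("n_pcs must be < min(genes, samples)")
  sds <- apply(v, 1, sd)
  z <- v[sds > 0, , drop = FALSE]
  pc <- prcomp(t(z), center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- colnames(v)
  scores
}

#' Inverse-normal transform each gene
#'
#' Maps each gene's values rank-wise to standard-normal quantiles using the
#' rank/(n+1) convention with average ranks for ties, so every gene matches
#' N(0,1) and pairwise Pearson correlations become rank-based.
#'
#' @param expr a [locop_expr] (typically state `residualized`).
#' @return A [locop_expr] in state `int`.
#' @export
inverse_normal_transform <- function(expr) {
  stopifnot(inherits(expr, "locop_expr"))
  v <- expr$values
  n <- ncol(v)
  out <- t(apply(v, 1, function(x) {
    if (sd(x) == 0) return(rep(0, n))
    qnorm(rank(x, ties.method = "average") / (n + 1))
  }))
  dimnames(out) <- dimnames(v)
  if (any(apply(v, 1, sd) == 0))
    warning("constant gene(s) mapped to all-zero output")
  set_expr_state(expr, out, "int")
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper: filter, derive PC covariates, residualize known plus
#' PC covariates, inverse-normal transform.
#'
#' @param expr raw [locop_expr].
#' @param catalog gene catalog.
#' @param rules [filter_rules] object.
#' @param covariates optional known covariates (samples x k).
#' @param n_pcs number of expression PCs to regress out (default 0).
#' @return List with `expr` (state `int`), `removed` log and the covariate
#'   matrix used.
#' @export
preprocess_expression <- function(expr, catalog, rules = filter_rules(),
                                  covariates = NULL, n_pcs = 0) {
  flt <- filter_genes(expr, catalog, rules)
  covs <- covariates
  if (n_pcs > 0) {
    pcs <- expression_pcs(flt$expr, n_pcs)
    covs <- if (is.null(covs)) pcs else cbind(covs, pcs)
  }
  res <- residualize(flt$expr, covs)
  list(expr = inverse_normal_transform(res), removed = flt$removed,
       covariates = covs)
}
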