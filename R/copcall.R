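#' Enumerate cis-testable gene pairs
#'
#' All same-chromosome unordered gene pairs whose TSSs are strictly less
#' than `window` bp apart, listed once with canonical gene order (by id).
#'
#' @param catalog gene catalog (`gene_id`, `chrom`, `tss`).
#' @param window cis window in bp (default 1 Mb).
#' @return data.frame `gene_a`, `gene_b`, `chrom`, `tss_distance`.
#' @export
enumerate_cis_pairs <- function(catalog, window = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(catalog)))
  out <- lapply(split(catalog, catalog$chrom), function(cc) {
    cc <- cc[order(cc$tss), ]
    n <- nrow(cc)
    if (n < 2) return(NULL)
    # for each gene, partners downstream within the window
    hi <- findInterval(cc$tss + window, cc$tss, left.open = TRUE)
    i <- rep.int(seq_len(n), pmax(hi - seq_len(n), 0))
    j <- unlist(lapply(seq_len(n), function(k)
      if (hi[k] > k) (k + 1):hi[k] else integer(0)), use.names = FALSE)
    if (!length(i)) return(NULL)
    data.frame(gene_a = pmin(cc$gene_id[i], cc$gene_id[j]),
               gene_b = pmax(cc$gene_id[i], cc$gene_id[j]),
               chrom = cc$chrom[1],
               tss_distance = abs(cc$tss[j] - cc$tss[i]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_a = character(0), gene_b = character(0),
                      chrom = character(0), tss_distance = numeric(0))
  rownames(res) <- NULL
  res
}

#' Per-gene permutation null for local co-expression
#'
#' Shuffles the focal gene's expression values across individuals `R`
#' times, keeping all cis genes intact, and records the highest correlation
#' magnitude across the cis set in each shuffle. The adjusted p-value of
#' each pair is the empirical probability `(r + 1) / (R + 1)` that a null
#' maximum reaches the observed correlation; the gene-level adjusted p is
#' the adjusted p of the gene's best pair. Ties between an observed value
#' and a null maximum count toward the null.
#'
#' @param expr a [locop_expr] in state `int`.
#' @param gene focal gene id.
#' @param cis_set character vector of cis partner gene ids (>= 1).
#' @param R number of permutations (>= 1).
#' @param seed global seed; the gene's own stream is
#'   `derive_seed(seed, paste0("copnull:", gene))`.
#' @param statistic `"abs"` compares |r| to null max |r| (two-sided,
#'   default); `"signed"` compares signed r to null max r.
#' @return List: `gene`, `R`, `null_max` (length R), `obs_r` (signed, named
#'   by partner), `adj_p` (named by partner), `gene_p`, `best_partner`.
#' @export
gene_null <- function(expr, gene, cis_set, R = 1000, seed = 1,
                      statistic = c("abs", "signed")) {
  stopifnot(inherits(expr, "locop_expr"), expr$state == "int",
            R >= 1, length(cis_set) >= 1)
  statistic <- match.arg(statistic)
  v <- expr$values
  if (!gene %in% rownames(v)) stop("unknown gene: ", gene)
  y <- v[gene, ]
  X <- t(v[cis_set, , drop = FALSE])
  n <- length(y)
  if (sd(y) == 0) {
    warning("constant expression for gene ", gene, "; adjusted p = 1")
    adj <- setNames(rep(1, length(cis_set)), cis_set)
    return(list(gene = gene, R = R, null_max = rep(0, R),
                obs_r = setNames(rep(0, length(cis_set)), cis_set),
                adj_p = adj, gene_p = 1, best_partner = cis_set[1]))
  }
  obs_r <- drop(suppressWarnings(cor(y, X)))
  obs_r[is.na(obs_r)] <- 0
  obs_r <- setNames(as.numeric(obs_r), cis_set)

  set.seed(derive_seed(seed, paste0("copnull:", gene)))
  P <- vapply(seq_len(R), function(r) y[sample.int(n)], numeric(n))
  null_r <- suppressWarnings(cor(P, X))
  null_r[is.na(null_r)] <- 0
  stat_obs <- if (statistic == "abs") abs(obs_r) else obs_r
  stat_null <- if (statistic == "abs") abs(null_r) else null_r
  null_max <- apply(stat_null, 1, max)

  s <- sort(null_max)
  # count of null maxima >= each observed statistic (ties favour the null)
  ge <- R - findInterval(stat_obs, s, left.open = TRUE)
  adj_p <- setNames((ge + 1) / (R + 1), cis_set)
  best <- which.max(stat_obs)
  list(gene = gene, R = R, null_max = null_max, obs_r = obs_r,
       adj_p = adj_p, gene_p = unname(adj_p[best]),
       best_partner = cis_set[best])
}

#' Call co-expressed gene pairs from nulls
#'
#' Removes correlation artifacts (|r| >= `r_artifact`), applies
#' Benjamini-Hochberg over the gene-level adjusted p-values (each gene's
#' best remaining pair), keeps the largest adjusted p passing at `fdr` as
#' the global threshold, and calls a pair co-expressed when its adjusted p
#' is at or below the threshold from both member genes' nulls.
#'
#' @param pairs pair data.frame from [enumerate_cis_pairs()].
#' @param nulls named list of [gene_null()] results (one per gene with a
#'   nonempty cis set).
#' @param fdr gene-level FDR (default 0.01).
#' @param r_artifact absolute-correlation artifact ceiling (default 0.99).
#' @return A `locop_discovery` list: `pairs` (with `pearson_r`,
#'   `adj_p_from_a`, `adj_p_from_b`, `is_cop`, `filtered_reason`),
#'   `gene_table` (`gene_id`, `gene_p`, `bh_pass`), `threshold`, `fdr`,
#'   `settings`.
#' @export
call_cops <- function(pairs, nulls, fdr = 0.01, r_artifact = 0.99) {
  stopifnot(nrow(pairs) >= 1, fdr > 0, fdr < 1)
  getp <- function(g, partner) {
    nl <- nulls[[g]]
    if (is.null(nl)) stop("missing null for gene ", g)
    p <- nl$adj_p[partner]
    if (anyNA(p)) stop("pair not covered by null of gene ", g)
    unname(p)
  }
  pr <- pairs
  pr$pearson_r <- vapply(seq_len(nrow(pr)), function(i)
    unname(nulls[[pr$gene_a[i]]]$obs_r[pr$gene_b[i]]), numeric(1))
  pr$adj_p_from_a <- vapply(seq_len(nrow(pr)), function(i)
    getp(pr$gene_a[i], pr$gene_b[i]), numeric(1))
  pr$adj_p_from_b <- vapply(seq_len(nrow(pr)), function(i)
    getp(pr$gene_b[i], pr$gene_a[i]), numeric(1))
  pr$filtered_reason <- NA_character_
  pr$filtered_reason[abs(pr$pearson_r) >= r_artifact] <- "artifact"

  ok <- is.na(pr$filtered_reason)
  # gene-level adjusted p over non-artifact pairs only
  long <- data.frame(gene = c(pr$gene_a[ok], pr$gene_b[ok]),
                     p = c(pr$adj_p_from_a[ok], pr$adj_p_from_b[ok]))
  gene_p <- tapply(long$p, long$gene, min)
  thr <- bh_threshold(as.numeric(gene_p), fdr)
  gene_table <- data.frame(gene_id = names(gene_p),
                           gene_p = as.numeric(gene_p),
                           stringsAsFactors = FALSE)
  gene_table$bh_pass <- !is.na(thr) & gene_table$gene_p <= thr

  pr$is_cop <- ok & !is.na(thr) &
    pr$adj_p_from_a <= thr & pr$adj_p_from_b <= thr
  structure(list(pairs = pr, gene_table = gene_table,
                 threshold = if (is.na(thr)) NA_real_ else thr, fdr = fdr,
                 settings = list(r_artifact = r_artifact)),
            class = "locop_discovery")
}

#' Discover co-expressed gene pairs (full procedure)
#'
#' Orchestrates pair enumeration, the per-gene permutation nulls and the
#' FDR-controlled calling step.
#'
#' @param expr a [locop_expr] in state `int`.
#' @param catalog gene catalog.
#' @param window cis window (bp, strict upper bound on TSS distance).
#' @param R permutations per gene.
#' @param fdr gene-level FDR.
#' @param seed global seed (per-gene streams derived from it).
#' @param statistic `"abs"` or `"signed"` null statistic (see
#'   [gene_null()]).
#' @param r_artifact artifact correlation ceiling.
#' @return A `locop_discovery` object (see [call_cops()]); `nulls` holds
#'   the per-gene null records.
#' @export
discover_cops <- function(expr, catalog, window = 1e6, R = 1000, fdr = 0.01,
                          seed = 1, statistic = c("abs", "signed"),
                          r_artifact = 0.99) {
  statistic <- match.arg(statistic)
  catalog <- catalog[catalog$gene_id %in% gene_ids(expr), , drop = FALSE]
  pairs <- enumerate_cis_pairs(catalog, window)
  if (!nrow(pairs)) stop("no cis-testable gene pairs")
  cis_sets <- split(c(pairs$gene_b, pairs$gene_a),
                    c(pairs$gene_a, pairs$gene_b))
  nulls <- lapply(names(cis_sets), function(g)
    gene_null(expr, g, cis_sets[[g]], R = R, seed = seed,
              statistic = statistic))
  names(nulls) <- names(cis_sets)
  res <- call_cops(pairs, nulls, fdr = fdr, r_artifact = r_artifact)
  res$nulls <- nulls
  res$settings <- c(res$settings,
                    list(window = window, R = R, seed = seed,
                         statistic = statistic))
  res
}

#' @export
print.locop_discovery <- function(x, ...) {
  cat(sprintf("<locop_discovery> %d pairs tested, %d COPs (FDR %g, threshold %s)\n",
              nrow(x$pairs), sum(x$pairs$is_cop), x$fdr,
              format(x$threshold, digits = 3)))
  invisible(x)
}

#' Filter called pairs by sign and paralogy
#'
#' Removes co-expressed pairs that are negatively correlated or appear in a
#' paralog pair list (evolutionary duplicates can share regulatory
#' elements trivially); reasons are recorded and the pairs dropped from the
#' COP set.
#'
#' @param result a `locop_discovery` object.
#' @param paralog_pairs data.frame `gene_a`, `gene_b` (any order) or NULL.
#' @param keep_sign `"positive"` (default) keeps only r > 0 COPs; `"both"`
#'   skips the sign filter.
#' @return The updated `locop_discovery`; removal counts in
#'   `$filter_counts`.
#' @export
apply_pair_filters <- function(result, paralog_pairs = NULL,
                               keep_sign = c("positive", "both")) {
  keep_sign <- match.arg(keep_sign)
  pr <- result$pairs
  n_par <- 0L; n_neg <- 0L
  if (!is.null(paralog_pairs) && nrow(paralog_pairs)) {
    pk <- pair_key(paralog_pairs$gene_a, paralog_pairs$gene_b)
    hit <- pr$is_cop & pair_key(pr$gene_a, pr$gene_b) %in% pk
    n_par <- sum(hit)
    pr$filtered_reason[hit] <- "paralog"
    pr$is_cop[hit] <- FALSE
  }
  if (keep_sign == "positive") {
    neg <- pr$is_cop & pr$pearson_r < 0
    n_neg <- sum(neg)
    pr$filtered_reason[neg] <- "negative"
    pr$is_cop[neg] <- FALSE
  }
  result$pairs <- pr
  result$filter_counts <- c(paralog = n_par, negative = n_neg)
  result
}

#' Group co-expressed pairs into network components
#'
#' Builds the co-expression graph (genes as nodes, called pairs as edges)
#' and returns its connected components.
#'
#' @param result a `locop_discovery` object.
#' @return List: `membership` (data.frame `gene_id`, `component`),
#'   `summary` (data.frame `component`, `n_genes`, `n_edges`).
#' @export
build_components <- function(result) {
  cop <- result$pairs[result$pairs$is_cop, c("gene_a", "gene_b")]
  if (!nrow(cop))
    return(list(membership = data.frame(gene_id = character(0),
                                        component = integer(0)),
                summary = data.frame(component = integer(0),
                                     n_genes = integer(0),
                                     n_edges = integer(0))))
  g <- igraph::graph_from_data_frame(cop, directed = FALSE)
  comp <- igraph::components(g)
  membership <- data.frame(gene_id = names(comp$membership),
                           component = as.integer(comp$membership),
                           stringsAsFactors = FALSE)
  edge_comp <- comp$membership[cop$gene_a]
  summary <- data.frame(component = seq_len(comp$no),
                        n_genes = as.integer(comp$csize),
                        n_edges = as.integer(tabulate(edge_comp, comp$no)))
  list(membership = membership, summary = summary)
}

#' Cross-tissue sharing of co-expressed pairs
#'
#' For each ordered tissue pair (A, B) computes the percentage of A's COPs,
#' among those also assessed in B, that are COPs in B (a non-symmetric
#' matrix). Pairs co-present in at least `min_tissues` tissues are
#' categorised by the fraction of co-present tissues in which they are
#' called: `unique` (one tissue), `specific` (> 1 tissue, <= 15% of
#' co-present tissues), `prevalent` (<= 50%), `conserved` (> 50%).
#'
#' @param results named list of `locop_discovery` objects (>= 2 tissues).
#' @param presence logical matrix, pair keys x tissues: both genes of the
#'   pair pass the expression filter in that tissue. Row names are
#'   [pair_key()] keys; column names match `names(results)`.
#' @param min_tissues minimum co-present tissues for categorisation.
#' @return List: `sharing` (percentage matrix), `categories` (data.frame
#'   `pair`, `n_cop`, `n_present`, `category`), `excluded` (pair keys
#'   co-present in fewer than `min_tissues` tissues).
#' @export
tissue_sharing <- function(results, presence, min_tissues = 5) {
  stopifnot(length(results) >= 2, !is.null(names(results)),
            all(names(results) %in% colnames(presence)))
  tissues <- names(results)
  keys <- lapply(results, function(r) pair_key(r$pairs$gene_a, r$pairs$gene_b))
  cops <- lapply(results, function(r)
    pair_key(r$pairs$gene_a, r$pairs$gene_b)[r$pairs$is_cop])
  sharing <- matrix(NA_real_, length(tissues), length(tissues),
                    dimnames = list(tissues, tissues))
  for (a in tissues) for (b in tissues) {
    if (a == b) { sharing[a, b] <- 100; next }
    assessed <- cops[[a]][cops[[a]] %in% keys[[b]]]
    sharing[a, b] <- if (length(assessed))
      100 * mean(assessed %in% cops[[b]]) else NA_real_
  }
  all_cops <- unique(unlist(cops))
  pres <- presence[rownames(presence) %in% all_cops, , drop = FALSE]
  n_present <- rowSums(pres[, tissues, drop = FALSE])
  cop_mat <- matrix(vapply(tissues, function(t) rownames(pres) %in% cops[[t]],
                           logical(nrow(pres))), nrow = nrow(pres))
  n_cop <- if (nrow(pres)) rowSums(cop_mat) else integer(0)
  eligible <- n_present >= min_tissues
  frac <- n_cop[eligible] / n_present[eligible]
  nc <- n_cop[eligible]
  category <- ifelse(nc == 1, "unique",
                     ifelse(frac <= 0.15, "specific",
                            ifelse(frac <= 0.5, "prevalent", "conserved")))
  list(sharing = sharing,
       categories = data.frame(pair = rownames(pres)[eligible],
                               n_cop = nc,
                               n_present = n_present[eligible],
                               category = category,
                               stringsAsFactors = FALSE),
       excluded = rownames(pres)[!eligible])
}
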