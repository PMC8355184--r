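#' Distance-matched non-COP controls
#'
#' For every called co-expressed pair, samples one tested-but-not-called
#' pair whose TSS distance differs by at most `max_dist_diff` bp and whose
#' adjusted p-value exceeds `min_adj_p` from both genes, uniformly and
#' without replacement. COPs are visited in a seed-shuffled order so none
#' is systematically favoured when candidates are scarce; COPs with no
#' eligible candidate are dropped and logged.
#'
#' @param result a `locop_discovery` object.
#' @param seed integer seed for the matching order and sampling.
#' @param max_dist_diff maximum distance discrepancy in bp (default 100).
#' @param min_adj_p minimum adjusted p (both directions) for a candidate
#'   (default 0.5).
#' @return A `locop_controls` list: `matches` (data.frame with the COP,
#'   its control and the distance discrepancy), `unmatched` (pair keys),
#'   `seed`.
#' @export
match_noncops <- function(result, seed = 1, max_dist_diff = 100,
                          min_adj_p = 0.5) {
  pr <- result$pairs
  cops <- which(pr$is_cop)
  pool <- which(!pr$is_cop & is.na(pr$filtered_reason) &
                  pr$adj_p_from_a > min_adj_p & pr$adj_p_from_b > min_adj_p)
  if (!length(pool)) stop("empty non-COP candidate pool")
  set.seed(derive_seed(seed, "match_noncops"))
  cops <- cops[sample.int(length(cops))]
  used <- rep(FALSE, length(pool))
  pool_dist <- pr$tss_distance[pool]
  rows <- vector("list", length(cops))
  unmatched <- character(0)
  for (k in seq_along(cops)) {
    i <- cops[k]
    elig <- which(!used & abs(pool_dist - pr$tss_distance[i]) <= max_dist_diff)
    if (!length(elig)) {
      unmatched <- c(unmatched, pair_key(pr$gene_a[i], pr$gene_b[i]))
      next
    }
    pick <- elig[sample.int(length(elig), 1)]
    used[pick] <- TRUE
    j <- pool[pick]
    rows[[k]] <- data.frame(
      cop_a = pr$gene_a[i], cop_b = pr$gene_b[i],
      cop_distance = pr$tss_distance[i],
      control_a = pr$gene_a[j], control_b = pr$gene_b[j],
      control_distance = pr$tss_distance[j],
      discrepancy = abs(pr$tss_distance[j] - pr$tss_distance[i]),
      stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(matches))
    matches <- data.frame(cop_a = character(0), cop_b = character(0),
                          cop_distance = numeric(0),
                          control_a = character(0), control_b = character(0),
                          control_distance = numeric(0),
                          discrepancy = numeric(0))
  if (length(unmatched))
    warning(length(unmatched), " COP(s) had no eligible distance-matched control")
  structure(list(matches = matches, unmatched = unmatched, seed = seed,
                 mode = "noncop"), class = "locop_controls")
}

#' Build a trans pair pool from expression
#'
#' Samples gene pairs on different chromosomes (or beyond the cis window)
#' and records their correlations, keeping only pairs at or above
#' `min_r` - by construction the minimum significant cis correlation of a
#' discovery run, so the pool mirrors the correlation range of called
#' pairs.
#'
#' @param expr a [locop_expr] in state `int`.
#' @param catalog gene catalog.
#' @param min_r minimum |correlation| retained.
#' @param n_sample number of random cross-chromosome pairs examined.
#' @param seed integer seed.
#' @return data.frame `gene_a`, `gene_b`, `r`.
#' @export
trans_pair_pool <- function(expr, catalog, min_r, n_sample = 50000, seed = 1) {
  set.seed(derive_seed(seed, "transpool"))
  ids <- gene_ids(expr)
  chrom <- setNames(catalog$chrom, catalog$gene_id)[ids]
  i <- sample.int(length(ids), n_sample, replace = TRUE)
  j <- sample.int(length(ids), n_sample, replace = TRUE)
  keep <- i != j & chrom[i] != chrom[j]
  i <- i[keep]; j <- j[keep]
  key <- pair_key(ids[i], ids[j])
  dup <- duplicated(key)
  i <- i[!dup]; j <- j[!dup]
  v <- expr$values
  r <- vapply(seq_along(i), function(k) cor(v[i[k], ], v[j[k], ]), numeric(1))
  out <- data.frame(gene_a = pmin(ids[i], ids[j]),
                    gene_b = pmax(ids[i], ids[j]), r = r,
                    stringsAsFactors = FALSE)
  out[abs(out$r) >= min_r, , drop = FALSE]
}

#' Correlation-matched trans-COP controls
#'
#' For each cis co-expressed pair, samples without replacement one trans
#' pair whose correlation differs by at most `tol` (relative to the cis
#' pair's correlation).
#'
#' @param result a `locop_discovery` object.
#' @param trans_pool data.frame `gene_a`, `gene_b`, `r` (see
#'   [trans_pair_pool()]).
#' @param seed integer seed.
#' @param tol maximum relative correlation difference (default 0.05).
#' @return A `locop_controls` list: `matches`, `unmatched`, `seed`.
#' @export
match_transcops <- function(result, trans_pool, seed = 1, tol = 0.05) {
  pr <- result$pairs
  cops <- which(pr$is_cop)
  if (!nrow(trans_pool)) stop("empty trans pair pool")
  set.seed(derive_seed(seed, "match_transcops"))
  cops <- cops[sample.int(length(cops))]
  used <- rep(FALSE, nrow(trans_pool))
  rows <- vector("list", length(cops))
  unmatched <- character(0)
  for (k in seq_along(cops)) {
    i <- cops[k]
    rc <- pr$pearson_r[i]
    elig <- which(!used & abs(trans_pool$r - rc) <= tol * abs(rc))
    if (!length(elig)) {
      unmatched <- c(unmatched, pair_key(pr$gene_a[i], pr$gene_b[i]))
      next
    }
    pick <- elig[sample.int(length(elig), 1)]
    used[pick] <- TRUE
    rows[[k]] <- data.frame(
      cop_a = pr$gene_a[i], cop_b = pr$gene_b[i], cop_r = rc,
      control_a = trans_pool$gene_a[pick],
      control_b = trans_pool$gene_b[pick],
      control_r = trans_pool$r[pick],
      discrepancy = abs(trans_pool$r[pick] - rc) / abs(rc),
      stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(matches))
    matches <- data.frame(cop_a = character(0), cop_b = character(0),
                          cop_r = numeric(0), control_a = character(0),
                          control_b = character(0), control_r = numeric(0),
                          discrepancy = numeric(0))
  if (length(unmatched))
    warning(length(unmatched), " COP(s) had no correlation-matched trans pair")
  structure(list(matches = matches, unmatched = unmatched, seed = seed,
                 mode = "transcop"), class = "locop_controls")
}

#' Labelled pair table from a matched control set
#'
#' Stacks the COPs (label 1) and their matched controls (label 0) of a
#' [match_noncops()] result into one table ready for feature computation.
#'
#' @param controls a `locop_controls` object (mode `noncop`).
#' @param result the `locop_discovery` the controls came from.
#' @return data.frame `gene_a`, `gene_b`, `chrom`, `tss_distance`, `label`.
#' @export
labelled_pairs <- function(controls, result) {
  stopifnot(inherits(controls, "locop_controls"), controls$mode == "noncop")
  pr <- result$pairs
  key <- pair_key(pr$gene_a, pr$gene_b)
  take <- function(a, b, label) {
    idx <- match(pair_key(a, b), key)
    data.frame(gene_a = pr$gene_a[idx], gene_b = pr$gene_b[idx],
               chrom = pr$chrom[idx], tss_distance = pr$tss_distance[idx],
               label = label, stringsAsFactors = FALSE)
  }
  m <- controls$matches
  rbind(take(m$cop_a, m$cop_b, 1L), take(m$control_a, m$control_b, 0L))
}
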