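#' Configuration for the synthetic dataset generator
#'
#' Defines the conditions of a simulated population-scale expression +
#' genotype study: a gene catalog laid out along chromosomes, co-expression
#' blocks of nearby genes driven by shared latent factors, sample-level
#' confounders, cis genetic effects (optionally shared across both genes of
#' a block pair), annotation tracks enriched or depleted around truly
#' co-expressed pairs, and GWAS summary statistics in which shared-eQTL
#' variants are pleiotropic by construction.
#'
#' @param n_individuals number of individuals (columns of the expression
#'   matrix).
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes genes are spread over.
#' @param mean_tss_spacing mean distance (bp) between consecutive TSSs.
#' @param block_spec data.frame with columns `size` and `loading`:
#'   co-expression blocks of `size` consecutive genes whose members load on
#'   a shared latent factor with coefficient `loading` (in [0,1); pairwise
#'   correlation = loading^2 after confounder removal).
#' @param confounder_count,confounder_strength number of sample-level
#'   confounders and the standard deviation of their contribution to every
#'   gene.
#' @param maf_range minor-allele-frequency range (within (0, 0.5]) for
#'   simulated variants.
#' @param variant_density background (non-eQTL) variants per Mb.
#' @param eqtl_effect standardized effect size added to target gene(s) per
#'   simulated eQTL.
#' @param shared_fraction fraction of simulated eQTLs affecting both genes
#'   of their truth pair (equal sign).
#' @param track_densities named vector of intervals per Mb for
#'   `ctcf_site`, `ctcf_motif`, `tf_motif`, `enhancer` tracks.
#' @param ctcf_depletion keep-probability of CTCF sites/motifs lying between
#'   the TSSs of a true pair (1 = no depletion).
#' @param tfbs_depletion keep-probability of TF motifs within +/-50 kb of a
#'   true-pair gene TSS.
#' @param enhancer_depletion keep-probability of enhancer-gene links for
#'   true-pair genes.
#' @param enhancer_share_rate probability that a true pair receives one
#'   extra enhancer linked to both genes.
#' @param n_tf_motif_ids number of distinct TF motif identifiers.
#' @param hic_decay,hic_scale,hic_resolution,hic_boost power-law decay
#'   exponent, scale, bin size (bp) and true-pair contact multiplier for the
#'   chromatin-contact triplets.
#' @param expression_scale `"normal"` for standard-normal raw values or
#'   `"tpm"` for a positive, log-normal-like scale (so zero/TPM filters have
#'   something to act on).
#' @param gwas_traits number of GWAS traits.
#' @param assoc_rate_shared,assoc_rate_other probability that a shared /
#'   unshared eQTL variant is made genome-wide significant.
#' @param pleio_extra_traits extra traits (beyond the focal trait) in which
#'   a designated shared variant is significant.
#' @param focal_trait index of the trait receiving all designated hits (the
#'   "matched" trait of the inflation comparison).
#' @param go_terms,go_share_rate,go_background_rate size of the GO-like term
#'   pool, probability a true pair is given a common term, and background
#'   per-pair sharing rate via random assignment.
#' @param paralog_fraction fraction of cis gene pairs marked as paralogs.
#' @param seed global integer seed; all sub-generators derive child seeds
#'   from it via [derive_seed()].
#' @return A `locop_sim_config` list.
#' @export
sim_config <- function(n_individuals = 300L,
                       n_genes = 2000L,
                       n_chromosomes = 5L,
                       mean_tss_spacing = 1e5,
                       block_spec = data.frame(size = rep(3L, 260L),
                                               loading = 0.85),
                       confounder_count = 5L,
                       confounder_strength = 0.3,
                       maf_range = c(0.05, 0.5),
                       variant_density = 25,
                       eqtl_effect = 0.5,
                       shared_fraction = 0.5,
                       track_densities = c(ctcf_site = 20, ctcf_motif = 10,
                                           tf_motif = 80, enhancer = 40),
                       ctcf_depletion = 0.5,
                       tfbs_depletion = 0.6,
                       enhancer_depletion = 0.6,
                       enhancer_share_rate = 0.5,
                       n_tf_motif_ids = 50L,
                       hic_decay = -1,
                       hic_scale = 1000,
                       hic_resolution = 5000L,
                       hic_boost = 1.5,
                       expression_scale = c("normal", "tpm"),
                       gwas_traits = 35L,
                       assoc_rate_shared = 0.3,
                       assoc_rate_other = 0.15,
                       pleio_extra_traits = 1L,
                       focal_trait = 1L,
                       go_terms = 200L,
                       go_share_rate = 0.5,
                       go_background_rate = 0.05,
                       paralog_fraction = 0.02,
                       seed = 1L) {
  expression_scale <- match.arg(expression_scale)
  if (n_genes < 2 || n_chromosomes < 1) stop("need n_genes >= 2, n_chromosomes >= 1")
  if (mean_tss_spacing <= 0) stop("mean_tss_spacing must be positive")
  if (!is.null(block_spec) && nrow(block_spec)) {
    stopifnot(all(c("size", "loading") %in% names(block_spec)))
    if (sum(block_spec$size) > n_genes) stop("block sizes sum above n_genes")
    if (any(block_spec$loading < 0 | block_spec$loading >= 1))
      stop("loadings must be in [0, 1)")
    if (any(block_spec$size < 2)) stop("block size must be >= 2")
  }
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            shared_fraction >= 0, shared_fraction <= 1,
            gwas_traits >= 1, focal_trait >= 1, focal_trait <= gwas_traits)
  cfg <- as.list(environment())
  structure(cfg, class = "locop_sim_config")
}

#' Simulate a gene catalog
#'
#' Places genes along chromosomes with exponential inter-TSS gaps (strictly
#' increasing positions), random strands and biotypes.
#'
#' @param config a [sim_config()] object.
#' @return data.frame `gene_id`, `chrom`, `tss` (0-based), `strand`,
#'   `biotype`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "locop_sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$n_genes
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
  gaps <- pmax(1, round(rexp(n, rate = 1 / config$mean_tss_spacing)))
  tss <- integer(n)
  for (c in unique(chrom_of)) {
    idx <- which(chrom_of == c)
    tss[idx] <- cumsum(gaps[idx])
  }
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = paste0("chr", chrom_of),
    tss = tss,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(c("protein_coding", "lincRNA"), n, replace = TRUE,
                     prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
}

# assign blocks to runs of consecutive genes within chromosomes
assign_blocks <- function(catalog, block_spec) {
  if (is.null(block_spec) || !nrow(block_spec))
    return(data.frame(block = integer(0), gene_id = character(0),
                      loading = numeric(0)))
  per_chrom <- split(catalog$gene_id, catalog$chrom)
  max_run <- max(lengths(per_chrom))
  if (any(block_spec$size > max_run))
    stop("block larger than the number of genes on any chromosome")
  out <- vector("list", nrow(block_spec))
  ci <- 1L
  offset <- 0L
  chroms <- names(per_chrom)
  for (b in seq_len(nrow(block_spec))) {
    size <- block_spec$size[b]
    while (offset + size > length(per_chrom[[chroms[ci]]])) {
      ci <- ci + 1L
      offset <- 0L
      if (ci > length(chroms)) stop("not enough genes to place all blocks")
    }
    genes <- per_chrom[[chroms[ci]]][(offset + 1):(offset + size)]
    offset <- offset + size
    out[[b]] <- data.frame(block = b, gene_id = genes,
                           loading = block_spec$loading[b],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate expression with planted co-expression blocks
#'
#' Members of a block share a latent factor with the configured loading
#' (marginal variance 1), all genes receive sample-level confounder
#' contributions, and the truth table lists every within-block cis pair
#' (TSS distance < 1 Mb) with its nominal correlation loading^2.
#'
#' @param catalog output of [simulate_genome()].
#' @param config a [sim_config()] object.
#' @return List: `expr` (raw [locop_expr]), `truth_pairs` (data.frame
#'   `gene_a`, `gene_b`, `block`, `r_nominal`), `confounders` (samples x k
#'   matrix), `block_genes`.
#' @export
simulate_expression <- function(catalog, config) {
  stopifnot(nrow(catalog) >= 1)
  set.seed(derive_seed(config$seed, "expression"))
  n <- config$n_individuals
  g <- nrow(catalog)
  samples <- sprintf("IND%04d", seq_len(n))
  blocks <- assign_blocks(catalog, config$block_spec)

  z <- matrix(rnorm(g * n), nrow = g,
              dimnames = list(catalog$gene_id, samples))
  if (nrow(blocks)) {
    for (b in unique(blocks$block)) {
      rows <- blocks$gene_id[blocks$block == b]
      lam <- blocks$loading[blocks$block == b][1]
      f <- rnorm(n)
      z[rows, ] <- lam * matrix(f, nrow = length(rows), ncol = n, byrow = TRUE) +
        sqrt(1 - lam^2) * z[rows, , drop = FALSE]
    }
  }
  k <- config$confounder_count
  C <- matrix(rnorm(n * max(k, 1)), nrow = n)[, seq_len(k), drop = FALSE]
  rownames(C) <- samples
  if (k > 0 && config$confounder_strength > 0) {
    W <- matrix(rnorm(g * k, sd = 1 / sqrt(k)), nrow = g)
    z <- z + config$confounder_strength * (W %*% t(C))
  }
  if (config$expression_scale == "tpm") {
    mu <- rnorm(g, mean = 2, sd = 1)
    z <- exp(z + mu)
  }

  truth <- NULL
  if (nrow(blocks)) {
    tss <- setNames(catalog$tss, catalog$gene_id)
    pairs <- do.call(rbind, lapply(unique(blocks$block), function(b) {
      genes <- blocks$gene_id[blocks$block == b]
      lam <- blocks$loading[blocks$block == b][1]
      if (length(genes) < 2) return(NULL)
      cmb <- utils::combn(sort(genes), 2)
      data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], block = b,
                 r_nominal = lam^2, stringsAsFactors = FALSE)
    }))
    dist <- abs(tss[pairs$gene_a] - tss[pairs$gene_b])
    truth <- pairs[dist < 1e6, , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        block = integer(0), r_nominal = numeric(0))
  }
  list(expr = locop_expr(z, "raw"), truth_pairs = truth,
       confounders = C, block_genes = blocks)
}

#' Simulate genotypes and plant cis-eQTLs
#'
#' Background variants are scattered along chromosomes; one cis variant is
#' planted per truth pair, its standardized dosage effect added to one gene
#' (unshared) or to both genes with equal sign (shared, with probability
#' `shared_fraction`). Dosages are Binomial(2, MAF).
#'
#' @param catalog gene catalog.
#' @param sim_expr output of [simulate_expression()].
#' @param config a [sim_config()] object.
#' @return List: `genotypes` (variants x individuals dosage matrix),
#'   `variants` (data.frame `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`), `truth_eqtl` (`gene_id`, `variant_id`, `beta`, `shared`),
#'   `expr` (modified raw [locop_expr]).
#' @export
simulate_genotypes_and_eqtls <- function(catalog, sim_expr, config) {
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  chrom_len <- tapply(catalog$tss, catalog$chrom, max) + config$mean_tss_spacing

  vs <- lapply(names(chrom_len), function(chr) {
    m <- max(1L, rpois(1, config$variant_density * chrom_len[[chr]] / 1e6))
    data.frame(chrom = chr, pos = sort(sample.int(chrom_len[[chr]], m)),
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, vs)
  variants$planted <- NA_integer_

  truth <- sim_expr$truth_pairs
  if (nrow(truth)) {
    tss <- setNames(catalog$tss, catalog$gene_id)
    chrom <- setNames(catalog$chrom, catalog$gene_id)
    mid <- (tss[truth$gene_a] + tss[truth$gene_b]) %/% 2
    jitter <- sample(-50000:50000, nrow(truth), replace = TRUE)
    pos <- pmax(1, mid + jitter)
    if (any(pos - tss[truth$gene_a] > 1e6 | tss[truth$gene_a] - pos > 1e6 |
            pos - tss[truth$gene_b] > 1e6 | tss[truth$gene_b] - pos > 1e6))
      stop("no cis variant position available for a truth pair")
    variants <- rbind(variants,
                      data.frame(chrom = unname(chrom[truth$gene_a]),
                                 pos = as.integer(pos),
                                 planted = seq_len(nrow(truth)),
                                 stringsAsFactors = FALSE))
  }
  variants <- variants[order(variants$chrom, variants$pos), ]
  variants$variant_id <- sprintf("var%06d", seq_len(nrow(variants)))
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nrow(variants), replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(bases, r), 1), "")
  variants$maf <- runif(nrow(variants), config$maf_range[1], config$maf_range[2])
  planted_vid <- variants$variant_id[match(seq_len(nrow(truth)), variants$planted)]
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt", "maf")]
  rownames(variants) <- NULL

  G <- matrix(rbinom(nrow(variants) * n, 2, rep(variants$maf, n)),
              nrow = nrow(variants),
              dimnames = list(variants$variant_id,
                              sample_ids(sim_expr$expr)))

  expr <- sim_expr$expr
  truth_eqtl <- data.frame(gene_id = character(0), variant_id = character(0),
                           beta = numeric(0), shared = logical(0))
  if (nrow(truth)) {
    vid <- planted_vid
    shared <- runif(nrow(truth)) < config$shared_fraction
    beta <- config$eqtl_effect
    v <- expr$values
    on_tpm <- config$expression_scale == "tpm"
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      d <- G[vid[i], ]
      sdd <- sd(d)
      if (sdd == 0) next  # monomorphic draw, no effect to add
      dstd <- (d - mean(d)) / sdd
      add <- function(gene) {
        if (on_tpm) v[gene, ] <<- v[gene, ] * exp(beta * dstd)
        else v[gene, ] <<- v[gene, ] + beta * dstd
      }
      add(truth$gene_a[i])
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = truth$gene_a[i], variant_id = vid[i],
                   beta = beta, shared = shared[i], stringsAsFactors = FALSE)
      if (shared[i]) {
        add(truth$gene_b[i])
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = truth$gene_b[i], variant_id = vid[i],
                     beta = beta, shared = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) truth_eqtl <- do.call(rbind, rows)
    expr$values <- v
  }
  list(genotypes = G, variants = variants, truth_eqtl = truth_eqtl,
       expr = expr)
}

# homogeneous interval track along each chromosome
poisson_track <- function(chrom_len, density_per_mb, width, stranded = FALSE,
                          labels = NULL) {
  out <- lapply(names(chrom_len), function(chr) {
    m <- rpois(1, density_per_mb * chrom_len[[chr]] / 1e6)
    if (m == 0) return(NULL)
    s <- sort(sample.int(max(chrom_len[[chr]] - width, 1), m, replace = TRUE))
    data.frame(chrom = chr, start = s, end = s + width,
               strand = if (stranded) sample(c("+", "-"), m, TRUE) else "*",
               label = if (is.null(labels)) "." else
                 sample(labels, m, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      label = character(0))
  res
}

# thin track points falling in any of the given 0-based half-open windows
thin_in_windows <- function(track, win, keep_prob) {
  if (keep_prob >= 1 || !nrow(track) || !nrow(win)) return(track)
  mid <- (track$start + track$end) %/% 2
  inside <- count_overlaps0(track$chrom, mid, mid + 1L,
                            win$chrom, win$start, win$end) > 0
  drop <- inside & runif(nrow(track)) > keep_prob
  track[!drop, , drop = FALSE]
}

#' Simulate annotation tracks, enhancer links and chromatin contacts
#'
#' CTCF sites and oriented motifs are depleted between the TSSs of true
#' pairs, TF motifs are depleted in the +/-50 kb windows of true-pair genes,
#' enhancer-gene links are thinned for true-pair genes while each true pair
#' gains a common enhancer with probability `enhancer_share_rate`, and
#' chromatin contacts follow a distance power law with a contact boost for
#' true pairs.
#'
#' @param catalog gene catalog.
#' @param truth_pairs truth pair table from [simulate_expression()].
#' @param config a [sim_config()] object.
#' @return List: `ctcf_sites`, `ctcf_motifs`, `tf_motifs`, `enhancers`
#'   (interval data.frames), `enhancer_links` (`enhancer_id`, `gene_id`),
#'   `hic` (`chrom`, `bin1`, `bin2`, `count`).
#' @export
simulate_tracks <- function(catalog, truth_pairs, config) {
  set.seed(derive_seed(config$seed, "tracks"))
  chrom_len <- tapply(catalog$tss, catalog$chrom, max) + config$mean_tss_spacing
  tss <- setNames(catalog$tss, catalog$gene_id)
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  dens <- config$track_densities

  between <- if (nrow(truth_pairs)) {
    a <- pmin(tss[truth_pairs$gene_a], tss[truth_pairs$gene_b])
    b <- pmax(tss[truth_pairs$gene_a], tss[truth_pairs$gene_b])
    data.frame(chrom = unname(chrom[truth_pairs$gene_a]),
               start = unname(a) + 1L, end = unname(b))
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))

  ctcf_sites <- poisson_track(chrom_len, dens[["ctcf_site"]], 200L)
  ctcf_sites <- thin_in_windows(ctcf_sites, between, config$ctcf_depletion)
  ctcf_motifs <- poisson_track(chrom_len, dens[["ctcf_motif"]], 20L,
                               stranded = TRUE, labels = "CTCF")
  ctcf_motifs <- thin_in_windows(ctcf_motifs, between, config$ctcf_depletion)

  tf_ids <- sprintf("TF%03d", seq_len(config$n_tf_motif_ids))
  tf_motifs <- poisson_track(chrom_len, dens[["tf_motif"]], 12L,
                             stranded = TRUE, labels = tf_ids)
  if (nrow(truth_pairs)) {
    tg <- unique(c(truth_pairs$gene_a, truth_pairs$gene_b))
    flank <- data.frame(chrom = unname(chrom[tg]),
                        start = pmax(0, unname(tss[tg]) - 50000L),
                        end = unname(tss[tg]) + 50001L)
    tf_motifs <- thin_in_windows(tf_motifs, flank, config$tfbs_depletion)
  }

  enh <- poisson_track(chrom_len, dens[["enhancer"]], 500L)
  if (nrow(enh))
    enh$enhancer_id <- sprintf("ENH%05d", seq_len(nrow(enh)))
  # link each enhancer to genes with TSS within 100 kb, at random
  links <- NULL
  if (nrow(enh)) {
    links <- do.call(rbind, lapply(seq_len(nrow(enh)), function(i) {
      near <- catalog$gene_id[catalog$chrom == enh$chrom[i] &
                                abs(catalog$tss - enh$start[i]) <= 1e5]
      near <- near[runif(length(near)) < 0.5]
      if (!length(near)) return(NULL)
      data.frame(enhancer_id = enh$enhancer_id[i], gene_id = near,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(links))
    links <- data.frame(enhancer_id = character(0), gene_id = character(0))
  if (nrow(truth_pairs) && nrow(links)) {
    tg <- unique(c(truth_pairs$gene_a, truth_pairs$gene_b))
    drop <- links$gene_id %in% tg & runif(nrow(links)) > config$enhancer_depletion
    links <- links[!drop, , drop = FALSE]
    shared_idx <- which(runif(nrow(truth_pairs)) < config$enhancer_share_rate)
    if (length(shared_idx)) {
      extra_enh <- data.frame(
        chrom = unname(chrom[truth_pairs$gene_a[shared_idx]]),
        start = (unname(tss[truth_pairs$gene_a[shared_idx]]) +
                   unname(tss[truth_pairs$gene_b[shared_idx]])) %/% 2,
        end = (unname(tss[truth_pairs$gene_a[shared_idx]]) +
                 unname(tss[truth_pairs$gene_b[shared_idx]])) %/% 2 + 500L,
        strand = "*", label = ".",
        enhancer_id = sprintf("ENHS%05d", seq_along(shared_idx)),
        stringsAsFactors = FALSE)
      enh <- rbind(enh, extra_enh)
      links <- rbind(links,
                     data.frame(enhancer_id = rep(extra_enh$enhancer_id, 2),
                                gene_id = c(truth_pairs$gene_a[shared_idx],
                                            truth_pairs$gene_b[shared_idx])))
    }
  }

  # contacts for every cis-testable TSS bin pair, power-law decay
  pairs <- enumerate_cis_pairs(catalog, window = 1e6)
  res <- config$hic_resolution
  hic <- NULL
  if (nrow(pairs)) {
    b1 <- (tss[pairs$gene_a] %/% res) * res
    b2 <- (tss[pairs$gene_b] %/% res) * res
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    d <- pmax(hi - lo, res)
    mu <- config$hic_scale * (d / res)^config$hic_decay
    boost <- ifelse(pair_key(pairs$gene_a, pairs$gene_b) %in%
                      pair_key(truth_pairs$gene_a, truth_pairs$gene_b),
                    config$hic_boost, 1)
    cnt <- mu * boost * exp(rnorm(nrow(pairs), sd = 0.1))
    hic <- data.frame(chrom = pairs$chrom, bin1 = unname(lo), bin2 = unname(hi),
                      count = unname(cnt), stringsAsFactors = FALSE)
    hic <- hic[!duplicated(paste(hic$chrom, hic$bin1, hic$bin2)), ]
  } else {
    hic <- data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), count = numeric(0))
  }
  list(ctcf_sites = ctcf_sites, ctcf_motifs = ctcf_motifs,
       tf_motifs = tf_motifs, enhancers = enh, enhancer_links = links,
       hic = hic)
}

#' Simulate GO-like term and paralog pair annotations
#'
#' Each gene receives a Poisson number of terms from a common pool; true
#' pairs additionally share a private term with probability
#' `go_share_rate`. A random subset of cis pairs (avoiding true pairs) is
#' marked as paralogs.
#'
#' @param catalog gene catalog.
#' @param truth_pairs truth pair table.
#' @param config a [sim_config()] object.
#' @return List: `go` (data.frame `gene_id`, `term`), `paralog_pairs`
#'   (data.frame `gene_a`, `gene_b`).
#' @export
simulate_annotations <- function(catalog, truth_pairs, config) {
  set.seed(derive_seed(config$seed, "annotations"))
  terms <- sprintf("GO:%07d", seq_len(config$go_terms))
  counts <- rpois(nrow(catalog), 3)
  go <- data.frame(
    gene_id = rep(catalog$gene_id, counts),
    term = unlist(lapply(counts, function(k) sample(terms, min(k, length(terms))))),
    stringsAsFactors = FALSE)
  if (nrow(truth_pairs)) {
    sh <- which(runif(nrow(truth_pairs)) < config$go_share_rate)
    if (length(sh)) {
      priv <- sprintf("GO:P%06d", seq_along(sh))
      go <- rbind(go, data.frame(
        gene_id = c(truth_pairs$gene_a[sh], truth_pairs$gene_b[sh]),
        term = rep(priv, 2), stringsAsFactors = FALSE))
    }
  }
  pairs <- enumerate_cis_pairs(catalog, window = 1e6)
  truthk <- pair_key(truth_pairs$gene_a, truth_pairs$gene_b)
  cand <- pairs[!(pair_key(pairs$gene_a, pairs$gene_b) %in% truthk), ]
  npar <- round(config$paralog_fraction * nrow(pairs))
  par <- cand[sample.int(nrow(cand), min(npar, nrow(cand))),
              c("gene_a", "gene_b")]
  rownames(par) <- NULL
  list(go = go, paralog_pairs = par)
}

#' Simulate GWAS summary statistics
#'
#' Every variant receives a p-value for every trait; non-associated values
#' are Uniform(0,1). Shared-eQTL variants are made genome-wide significant
#' (p well below 5e-8) in the focal trait plus extra random traits with
#' probability `assoc_rate_shared`; unshared eQTL variants in the focal
#' trait only, with probability `assoc_rate_other`.
#'
#' @param variants variant table from [simulate_genotypes_and_eqtls()].
#' @param truth_eqtl truth eQTL table.
#' @param config a [sim_config()] object.
#' @return data.frame `variant_id`, `trait_id`, `pval`.
#' @export
simulate_gwas <- function(variants, truth_eqtl, config) {
  set.seed(derive_seed(config$seed, "gwas"))
  traits <- sprintf("trait%02d", seq_len(config$gwas_traits))
  m <- nrow(variants)
  gw <- data.frame(
    variant_id = rep(variants$variant_id, times = config$gwas_traits),
    trait_id = rep(traits, each = m),
    pval = runif(m * config$gwas_traits),
    stringsAsFactors = FALSE)
  hit_p <- function(k) 10^-runif(k, 9, 20)
  plant <- function(vids, rate, n_extra) {
    vids <- unique(vids)
    des <- vids[runif(length(vids)) < rate]
    for (v in des) {
      hit_traits <- traits[config$focal_trait]
      if (n_extra > 0) {
        pool <- setdiff(traits, hit_traits)
        hit_traits <- c(hit_traits, sample(pool, min(n_extra, length(pool))))
      }
      sel <- gw$variant_id == v & gw$trait_id %in% hit_traits
      gw$pval[sel] <<- hit_p(sum(sel))
    }
  }
  if (nrow(truth_eqtl)) {
    shared_v <- unique(truth_eqtl$variant_id[truth_eqtl$shared])
    other_v <- setdiff(unique(truth_eqtl$variant_id), shared_v)
    plant(shared_v, config$assoc_rate_shared, config$pleio_extra_traits)
    plant(other_v, config$assoc_rate_other, 0L)
  }
  gw
}

#' Generate a complete synthetic dataset
#'
#' Runs all sub-generators in order and bundles their outputs. Identical
#' configurations (including the seed) produce identical datasets.
#'
#' @param config a [sim_config()] object.
#' @return A `locop_sim` list: `catalog`, `expr` (raw), `confounders`,
#'   `truth_pairs`, `genotypes`, `variants`, `truth_eqtl`, `tracks`,
#'   `annotations`, `gwas`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  catalog <- simulate_genome(config)
  se <- simulate_expression(catalog, config)
  sg <- simulate_genotypes_and_eqtls(catalog, se, config)
  tracks <- simulate_tracks(catalog, se$truth_pairs, config)
  ann <- simulate_annotations(catalog, se$truth_pairs, config)
  gwas <- simulate_gwas(sg$variants, sg$truth_eqtl, config)
  structure(list(catalog = catalog, expr = sg$expr,
                 confounders = se$confounders,
                 truth_pairs = se$truth_pairs,
                 block_genes = se$block_genes,
                 genotypes = sg$genotypes, variants = sg$variants,
                 truth_eqtl = sg$truth_eqtl, tracks = tracks,
                 annotations = ann, gwas = gwas, config = config),
            class = "locop_sim")
}

#' @export
print.locop_sim <- function(x, ...) {
  cat(sprintf(paste0("<locop_sim> %d genes / %d individuals / %d variants; ",
                     "%d truth pairs, %d truth eQTL rows, %d GWAS traits\n"),
              nrow(x$catalog), x$config$n_individuals, nrow(x$variants),
              nrow(x$truth_pairs), nrow(x$truth_eqtl), x$config$gwas_traits))
  invisible(x)
}
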