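test_that("identical config and seed give byte-identical datasets", {
  cfg <- sim_config(n_individuals = 40, n_genes = 60, n_chromosomes = 2,
                    block_spec = data.frame(size = c(2L, 3L), loading = 0.8),
                    seed = 3L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$gwas, b$gwas)
  cfg2 <- sim_config(n_individuals = 40, n_genes = 60, n_chromosomes = 2,
                     block_spec = data.frame(size = c(2L, 3L), loading = 0.8),
                     seed = 4L)
  expect_false(identical(simulate_dataset(cfg2)$expr$values, a$expr$values))
})

test_that("genome layout respects spacing, chromosomes and validation", {
  cfg <- sim_config(n_genes = 10, n_chromosomes = 1, mean_tss_spacing = 5e4,
                    block_spec = NULL, seed = 1)
  cat10 <- simulate_genome(cfg)
  expect_true(all(diff(cat10$tss) > 0))
  # with 50 kb mean spacing, 10 genes span well under 1 Mb whp -> all 45
  # pairs are cis-testable
  expect_lt(max(cat10$tss) - min(cat10$tss), 1e6)
  expect_equal(nrow(enumerate_cis_pairs(cat10)), 45)

  cfg2 <- sim_config(n_genes = 2, n_chromosomes = 2, block_spec = NULL,
                     seed = 1)
  cat2 <- simulate_genome(cfg2)
  expect_equal(length(unique(cat2$chrom)), 2)
  expect_equal(nrow(enumerate_cis_pairs(cat2)), 0)

  expect_error(sim_config(mean_tss_spacing = 0), "positive")
  expect_error(sim_config(n_genes = 10, block_spec =
                            data.frame(size = 11L, loading = 0.5)), "sum")
  expect_error(sim_config(block_spec = data.frame(size = 2L, loading = 1)),
               "loadings")
})

test_that("block loading controls within-block correlation (loading^2)", {
  cfg <- sim_config(n_individuals = 500, n_genes = 40, n_chromosomes = 1,
                    mean_tss_spacing = 5e4,
                    block_spec = data.frame(size = rep(2L, 10L), loading = 0.9),
                    confounder_count = 3, confounder_strength = 0.5, seed = 21)
  catal <- simulate_genome(cfg)
  se <- simulate_expression(catal, cfg)
  expect_equal(unique(se$truth_pairs$r_nominal), 0.81)
  res <- residualize(locop_expr(se$expr$values, "raw"), se$confounders)
  r <- vapply(seq_len(nrow(se$truth_pairs)), function(i)
    cor(res$values[se$truth_pairs$gene_a[i], ],
        res$values[se$truth_pairs$gene_b[i], ]), numeric(1))
  expect_equal(mean(r), 0.81, tolerance = 0.05 / 0.81)

  # loading 0 -> correlations indistinguishable from null scale
  cfg0 <- sim_config(n_individuals = 500, n_genes = 40, n_chromosomes = 1,
                     block_spec = data.frame(size = rep(2L, 10L), loading = 0),
                     confounder_count = 0, seed = 22)
  se0 <- simulate_expression(simulate_genome(cfg0), cfg0)
  r0 <- vapply(seq_len(nrow(se0$truth_pairs)), function(i)
    cor(se0$expr$values[se0$truth_pairs$gene_a[i], ],
        se0$expr$values[se0$truth_pairs$gene_b[i], ]), numeric(1))
  expect_lt(max(abs(r0)), 4 / sqrt(500))

  # no confounders -> residualizing only centers the matrix
  cfgc <- sim_config(n_individuals = 50, n_genes = 10, n_chromosomes = 1,
                     block_spec = NULL, confounder_count = 0, seed = 23)
  sec <- simulate_expression(simulate_genome(cfgc), cfgc)
  res2 <- residualize(sec$expr, NULL)
  expect_equal(res2$values,
               sec$expr$values - rowMeans(sec$expr$values),
               tolerance = 1e-12)

  cfg5 <- sim_config(n_genes = 10, n_chromosomes = 5,
                     block_spec = data.frame(size = 5L, loading = 0.5))
  expect_error(simulate_expression(simulate_genome(cfg5), cfg5),
               "block larger")
})

test_that("genotype dosages, MAF and planted eQTL effects behave", {
  cfg <- sim_config(n_individuals = 500, n_genes = 60, n_chromosomes = 1,
                    block_spec = data.frame(size = rep(2L, 15L), loading = 0.6),
                    eqtl_effect = 0.5, shared_fraction = 1, seed = 31)
  catal <- simulate_genome(cfg)
  se <- simulate_expression(catal, cfg)
  sg <- simulate_genotypes_and_eqtls(catal, se, cfg)
  expect_true(all(sg$genotypes %in% 0:2))
  emp_maf <- rowMeans(sg$genotypes) / 2
  emp_maf <- pmin(emp_maf, 1 - emp_maf)
  expect_lt(max(abs(emp_maf - pmin(sg$variants$maf, 1 - sg$variants$maf))),
            0.1)
  # shared_fraction 1 -> every planted variant listed for both pair genes
  expect_true(all(sg$truth_eqtl$shared))
  expect_true(all(table(sg$truth_eqtl$variant_id) == 2))
  # every truth gene/variant exists in catalog/variant table
  expect_true(all(sg$truth_eqtl$gene_id %in% catal$gene_id))
  expect_true(all(sg$truth_eqtl$variant_id %in% sg$variants$variant_id))

  # OLS on standardized dosage recovers the planted standardized beta
  betas <- vapply(seq_len(nrow(sg$truth_eqtl)), function(i) {
    y <- sg$expr$values[sg$truth_eqtl$gene_id[i], ]
    d <- sg$genotypes[sg$truth_eqtl$variant_id[i], ]
    coef(lm(y ~ scale(d)))[2]
  }, numeric(1))
  expect_lt(max(abs(betas - 0.5)), 0.25)
  expect_equal(mean(betas), 0.5, tolerance = 0.1 / 0.5)

  # zero effect leaves expression unchanged
  cfg0 <- sim_config(n_individuals = 100, n_genes = 20, n_chromosomes = 1,
                     block_spec = data.frame(size = rep(2L, 5L), loading = 0.5),
                     eqtl_effect = 0, seed = 32)
  cat0 <- simulate_genome(cfg0)
  se0 <- simulate_expression(cat0, cfg0)
  sg0 <- simulate_genotypes_and_eqtls(cat0, se0, cfg0)
  expect_identical(sg0$expr$values, se0$expr$values)
})

test_that("track depletion and Hi-C decay follow their constructions", {
  cfg <- sim_config(n_individuals = 30, n_genes = 200, n_chromosomes = 1,
                    mean_tss_spacing = 1e5,
                    block_spec = data.frame(size = rep(2L, 50L), loading = 0.8),
                    track_densities = c(ctcf_site = 60, ctcf_motif = 10,
                                        tf_motif = 40, enhancer = 10),
                    ctcf_depletion = 0.5, seed = 41)
  catal <- simulate_genome(cfg)
  se <- simulate_expression(catal, cfg)
  tr <- simulate_tracks(catal, se$truth_pairs, cfg)

  # per-bp CTCF rate between true-pair TSSs is about half the rate
  # between distance-comparable non-pair TSSs (Poisson thinning)
  pairs <- enumerate_cis_pairs(catal)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  tkey <- pair_key(se$truth_pairs$gene_a, se$truth_pairs$gene_b)
  m <- ctcf_metrics(pairs, catal, tr$ctcf_sites, tr$ctcf_motifs)
  rate <- m$total_ctcf / pmax(pairs$tss_distance, 1)
  is_truth <- key %in% tkey
  comparable <- !is_truth & pairs$tss_distance <=
    max(pairs$tss_distance[is_truth])
  ratio <- mean(rate[is_truth]) / mean(rate[comparable])
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.75)

  # depletion 1.0 -> true-pair and non-pair rates differ only by noise
  cfg1 <- sim_config(n_individuals = 30, n_genes = 200, n_chromosomes = 1,
                     mean_tss_spacing = 1e5,
                     block_spec = data.frame(size = rep(2L, 50L),
                                             loading = 0.8),
                     track_densities = c(ctcf_site = 60, ctcf_motif = 10,
                                         tf_motif = 40, enhancer = 10),
                     ctcf_depletion = 1, tfbs_depletion = 1,
                     enhancer_depletion = 1, seed = 41)
  tr1 <- simulate_tracks(catal, se$truth_pairs, cfg1)
  m1 <- ctcf_metrics(pairs, catal, tr1$ctcf_sites, tr1$ctcf_motifs)
  rate1 <- m1$total_ctcf / pmax(pairs$tss_distance, 1)
  ratio1 <- mean(rate1[is_truth]) / mean(rate1[comparable])
  expect_gt(ratio1, 0.8)
  expect_lt(ratio1, 1.25)

  # power-law decay: log-count falls with slope ~ hic_decay in log-distance
  h <- tr$hic[tr$hic$bin2 > tr$hic$bin1, ]
  fit <- lm(log(h$count) ~ log(h$bin2 - h$bin1))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("GWAS planting gives the designated trait counts and null floor", {
  cfg <- sim_config(n_individuals = 30, n_genes = 100, n_chromosomes = 1,
                    block_spec = data.frame(size = rep(2L, 25L), loading = 0.7),
                    assoc_rate_shared = 1, assoc_rate_other = 1,
                    pleio_extra_traits = 2L, shared_fraction = 1, seed = 51)
  catal <- simulate_genome(cfg)
  se <- simulate_expression(catal, cfg)
  sg <- simulate_genotypes_and_eqtls(catal, se, cfg)
  gw <- simulate_gwas(sg$variants, sg$truth_eqtl, cfg)
  counts <- trait_association_counts(gw)
  planted <- unique(sg$truth_eqtl$variant_id)
  # designated in focal trait + 2 extras -> count 3
  expect_true(all(counts[planted] == 3))
  # non-designated variants essentially never cross 5e-8
  bg <- setdiff(names(counts), planted)
  expect_lte(mean(counts[bg] >= 1), 0.001)
})
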