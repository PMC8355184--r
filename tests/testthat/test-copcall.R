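test_that("cis pair enumeration is strict and chromosome-aware", {
  catal <- toy_catalog(c(100000, 600000))
  p <- enumerate_cis_pairs(catal)
  expect_equal(nrow(p), 1)
  expect_equal(p$tss_distance, 500000)

  catal2 <- toy_catalog(c(0, 1000000))
  expect_equal(nrow(enumerate_cis_pairs(catal2)), 0)  # exactly 1 Mb: excluded
  expect_equal(nrow(enumerate_cis_pairs(toy_catalog(c(0, 999999)))), 1)

  catal3 <- rbind(toy_catalog(1000), toy_catalog(2000, chrom = "chr2"))
  catal3$gene_id <- c("a", "b")
  expect_equal(nrow(enumerate_cis_pairs(catal3)), 0)
})

test_that("gene_null follows the (r+1)/(R+1) convention with ties to null", {
  set.seed(10)
  n <- 30
  base <- rnorm(n)
  v <- rbind(g1 = base, g2 = base + rnorm(n, sd = 0.01), g3 = rnorm(n))
  colnames(v) <- paste0("s", 1:n)
  e <- toy_expr(v)
  nl <- gene_null(e, "g1", c("g2", "g3"), R = 100, seed = 1)
  # g2 is almost a copy: observed |r| ~ 1 exceeds every null maximum
  expect_equal(unname(nl$adj_p["g2"]), 1 / 101)
  expect_equal(nl$gene_p, 1 / 101)
  expect_equal(nl$best_partner, "g2")
  expect_true(all(nl$null_max >= 0 & nl$null_max <= 1))
  expect_length(nl$null_max, 100)

  # constant partner: r treated as 0, every null maximum (also 0) ties -> p 1
  vc <- rbind(g1 = rnorm(n), g2 = rep(1, n))
  colnames(vc) <- paste0("s", 1:n)
  nlc <- gene_null(toy_expr(vc), "g1", "g2", R = 50, seed = 1)
  expect_equal(unname(nlc$adj_p["g2"]), 1)

  # constant focal gene warns and returns p 1
  vf <- rbind(g1 = rep(2, n), g2 = rnorm(n))
  colnames(vf) <- paste0("s", 1:n)
  expect_warning(nlf <- gene_null(toy_expr(vf), "g1", "g2", R = 10, seed = 1),
                 "constant")
  expect_equal(nlf$gene_p, 1)
  expect_error(gene_null(e, "g1", "g2", R = 0), "R >= 1")
})

test_that("gene_null matches a brute-force oracle permutation for permutation", {
  set.seed(11)
  n <- 25; R <- 40
  v <- matrix(rnorm(10 * n), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:n)))
  e <- toy_expr(v)
  for (g in c("g01", "g05")) {
    cis <- setdiff(rownames(v), g)
    nl <- gene_null(e, g, cis, R = R, seed = 99)
    # independent re-implementation: plain double loop over permutations
    y <- v[g, ]
    set.seed(derive_seed(99, paste0("copnull:", g)))
    null_max <- numeric(R)
    for (r in seq_len(R)) {
      yp <- y[sample.int(n)]
      null_max[r] <- max(vapply(cis, function(h) abs(cor(yp, v[h, ])),
                                numeric(1)))
    }
    expect_equal(nl$null_max, null_max, tolerance = 1e-12)
    obs <- vapply(cis, function(h) abs(cor(y, v[h, ])), numeric(1))
    adj <- (vapply(obs, function(o) sum(null_max >= o), numeric(1)) + 1) /
      (R + 1)
    expect_equal(unname(nl$adj_p[cis]), unname(adj), tolerance = 1e-12)
  }
})

test_that("discovery output is independent of gene iteration order", {
  sim <- fixture_sim()
  e <- fixture_int_expr()
  catal <- sim$catalog[1:60, ]
  d1 <- discover_cops(e, catal, R = 80, seed = 5)
  d2 <- discover_cops(e, catal[sample.int(60), ], R = 80, seed = 5)
  o1 <- d1$pairs[order(d1$pairs$gene_a, d1$pairs$gene_b), ]
  o2 <- d2$pairs[order(d2$pairs$gene_a, d2$pairs$gene_b), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("planted blocks are recovered and artifacts excluded before BH", {
  sim <- fixture_sim()
  disc <- fixture_discovery()
  truthk <- pair_key(sim$truth_pairs$gene_a, sim$truth_pairs$gene_b)
  copk <- pair_key(disc$pairs$gene_a, disc$pairs$gene_b)[disc$pairs$is_cop]
  expect_gte(mean(truthk %in% copk), 0.9)

  # a duplicated gene produces r ~ 1 and is filtered as an artifact
  v <- fixture_int_expr()$values[1:20, ]
  v <- rbind(v, dup = v[1, ])
  catal <- sim$catalog[match(rownames(v)[1:20], sim$catalog$gene_id), ]
  catal <- rbind(catal, data.frame(gene_id = "dup", chrom = catal$chrom[1],
                                   tss = catal$tss[1] + 50L, strand = "+",
                                   biotype = "protein_coding"))
  e2 <- toy_expr(v)
  d <- discover_cops(e2, catal, R = 50, seed = 2)
  dup_rows <- d$pairs$gene_a == "dup" | d$pairs$gene_b == "dup"
  art <- d$pairs[dup_rows & abs(d$pairs$pearson_r) >= 0.99, ]
  expect_true(nrow(art) >= 1)
  expect_true(all(art$filtered_reason == "artifact"))
  expect_false(any(art$is_cop))

  # raising the FDR level never removes a called pair
  d5 <- call_cops(disc$pairs[, c("gene_a", "gene_b", "chrom",
                                 "tss_distance")], disc$nulls, fdr = 0.05)
  called1 <- pair_key(disc$pairs$gene_a, disc$pairs$gene_b)[disc$pairs$is_cop]
  called5 <- pair_key(d5$pairs$gene_a, d5$pairs$gene_b)[d5$pairs$is_cop]
  expect_true(all(called1 %in% called5))
})

test_that("pair filters remove negative and paralog pairs with reasons", {
  pairs <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                      chrom = "chr1", tss_distance = c(1e3, 2e3, 3e3),
                      pearson_r = c(0.5, -0.3, 0.6),
                      adj_p_from_a = 0.001, adj_p_from_b = 0.001,
                      filtered_reason = NA_character_,
                      is_cop = TRUE)
  res <- fake_discovery(pairs)
  out <- apply_pair_filters(res, paralog_pairs = data.frame(gene_a = "f",
                                                            gene_b = "e"))
  expect_equal(out$pairs$filtered_reason, c(NA, "negative", "paralog"))
  expect_equal(out$pairs$is_cop, c(TRUE, FALSE, FALSE))
  expect_equal(unname(out$filter_counts), c(1L, 1L))

  # empty paralog list + all-positive correlations: identity
  pairs2 <- pairs; pairs2$pearson_r <- abs(pairs2$pearson_r)
  out2 <- apply_pair_filters(fake_discovery(pairs2))
  expect_equal(out2$pairs$is_cop, rep(TRUE, 3))
})

test_that("network components partition called genes", {
  pairs <- data.frame(gene_a = c("A", "B", "X"), gene_b = c("B", "C", "Y"),
                      chrom = "chr1", tss_distance = 1,
                      pearson_r = 0.5, adj_p_from_a = 0.001,
                      adj_p_from_b = 0.001,
                      filtered_reason = NA_character_, is_cop = TRUE)
  comp <- build_components(fake_discovery(pairs))
  expect_equal(nrow(comp$summary), 2)
  expect_setequal(comp$summary$n_genes, c(3L, 2L))
  sizes <- table(comp$membership$component)
  expect_setequal(as.integer(sizes), c(3L, 2L))

  # planted blocks of the fixture come back as components
  disc <- fixture_discovery()
  sim <- fixture_sim()
  comp2 <- build_components(disc)
  big <- comp2$summary$n_genes
  expect_gte(sum(big == 3), 0.8 * length(unique(sim$block_genes$block)))
})

test_that("tissue sharing matrix and categories follow their definitions", {
  mk <- function(cops, tested) {
    pairs <- data.frame(gene_a = sub("\\|.*", "", tested),
                        gene_b = sub(".*\\|", "", tested),
                        chrom = "chr1", tss_distance = 1, pearson_r = 0.5,
                        adj_p_from_a = 1, adj_p_from_b = 1,
                        filtered_reason = NA_character_,
                        is_cop = tested %in% cops)
    fake_discovery(pairs)
  }
  p1 <- "a|b"; p2 <- "c|d"; p3 <- "e|f"
  n_tissues <- 10
  # p1: COP in 1 of 10 co-present -> unique; p2: COP in 6 of 10 -> conserved
  # p3: co-present in 4 -> excluded
  results <- lapply(seq_len(n_tissues), function(t) {
    cops <- c(if (t == 1) p1, if (t <= 6) p2, if (t <= 2) p3)
    mk(cops, c(p1, p2, if (t <= 4) p3))
  })
  names(results) <- paste0("T", seq_len(n_tissues))
  presence <- matrix(TRUE, nrow = 3, ncol = n_tissues,
                     dimnames = list(c(p1, p2, p3), names(results)))
  presence[p3, 5:10] <- FALSE
  ts <- tissue_sharing(results, presence)
  cat_of <- setNames(ts$categories$category, ts$categories$pair)
  expect_equal(unname(cat_of[p1]), "unique")
  expect_equal(unname(cat_of[p2]), "conserved")
  expect_true(p3 %in% ts$excluded)
  # sharing percentage: T1's COPs {p1, p2, p3} assessed in T5 = {p1, p2},
  # of which only p2 is a COP in T5 -> 50%
  expect_equal(ts$sharing["T1", "T5"], 50)

  # 2 of 20 co-present tissues -> specific (10% <= 15%)
  results2 <- lapply(seq_len(20), function(t)
    mk(if (t <= 2) p1 else character(0), p1))
  names(results2) <- paste0("T", seq_len(20))
  presence2 <- matrix(TRUE, 1, 20, dimnames = list(p1, names(results2)))
  ts2 <- tissue_sharing(results2, presence2)
  expect_equal(ts2$categories$category, "specific")
})
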