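two_gene_pair <- function(tss_a, tss_b, chrom = "chr1") {
  list(catalog = data.frame(gene_id = c("gA", "gB"), chrom = chrom,
                            tss = c(tss_a, tss_b), strand = "+",
                            biotype = "protein_coding"),
       pairs = data.frame(gene_a = "gA", gene_b = "gB",
                          stringsAsFactors = FALSE))
}

iv <- function(start, end, strand = "*", label = ".", chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             label = label, stringsAsFactors = FALSE)
}

test_that("CTCF metrics count sites between TSSs and opposite motif pairs", {
  tp <- two_gene_pair(10000, 50000)
  sites <- iv(c(15000, 20000, 30000, 60000), c(15200, 20200, 30200, 60200))
  motifs <- iv(c(16000, 22000, 28000), c(16020, 22020, 28020),
               strand = c("+", "-", "-"), label = "CTCF")
  out <- ctcf_metrics(tp$pairs, tp$catalog, sites, motifs)
  expect_equal(out$total_ctcf, 3)       # the 60 kb site is outside
  expect_equal(out$inverted_ctcf, 2)    # 1 plus x 2 minus

  same <- ctcf_metrics(tp$pairs, tp$catalog, sites,
                       iv(c(16000, 22000), c(16020, 22020),
                          strand = c("+", "+"), label = "CTCF"))
  expect_equal(same$inverted_ctcf, 0)

  # intervals touching the TSS itself are outside the open interval
  edge <- ctcf_metrics(tp$pairs, tp$catalog, iv(49999, 50200), motifs[0, ])
  expect_equal(edge$total_ctcf, 1)      # 49999 < 50000: still inside
  edge2 <- ctcf_metrics(tp$pairs, tp$catalog, iv(50000, 50200), motifs[0, ])
  expect_equal(edge2$total_ctcf, 0)

  # symmetric in gene order
  swapped <- tp$pairs[, c("gene_b", "gene_a")]
  names(swapped) <- c("gene_a", "gene_b")
  expect_equal(ctcf_metrics(swapped, tp$catalog, sites, motifs)$total_ctcf, 3)
})

test_that("Hi-C lookup uses floor bins and zero-fills missing pairs", {
  tp <- two_gene_pair(12400, 27900)
  contacts <- data.frame(chrom = "chr1", bin1 = 10000, bin2 = 25000,
                         count = 42)
  expect_equal(hic_contact(tp$pairs, tp$catalog, contacts)$hic_contact, 42)

  # both TSSs in one bin -> diagonal entry
  tp2 <- two_gene_pair(12400, 12900)
  diagc <- data.frame(chrom = "chr1", bin1 = 10000, bin2 = 10000, count = 7)
  expect_equal(hic_contact(tp2$pairs, tp2$catalog, diagc)$hic_contact, 7)

  # absent bin pair -> 0
  expect_equal(hic_contact(tp$pairs, tp$catalog, diagc)$hic_contact, 0)
})

test_that("enhancer sharing and totals are set arithmetic", {
  links <- data.frame(enhancer_id = c("E1", "E2", "E2", "E3"),
                      gene_id = c("gA", "gA", "gB", "gB"))
  p <- data.frame(gene_a = "gA", gene_b = "gB")
  out <- enhancer_metrics(p, links)
  expect_equal(out$enh_sharing, 1)
  expect_equal(out$enh_total, 3)

  ident <- data.frame(enhancer_id = rep(c("E1", "E2"), 2),
                      gene_id = rep(c("gA", "gB"), each = 2))
  out2 <- enhancer_metrics(p, ident)
  expect_equal(out2$enh_sharing, 2)
  expect_equal(out2$enh_total, 2)  # common enhancers counted once

  out3 <- enhancer_metrics(p, links[links$gene_id == "gB", ])
  expect_equal(out3$enh_sharing, 0)
  expect_equal(out3$enh_total, 2)
})

test_that("TF metrics share ids and sum occurrences per window", {
  tp <- two_gene_pair(100000, 180000)
  # windows: gA [50k, 150k], gB [130k, 230k]
  motifs <- iv(c(60000, 70000, 140000, 200000, 210000),
               c(60010, 70010, 140010, 200010, 210010),
               strand = "+", label = c("A", "B", "B", "C", "C"))
  out <- tfbs_metrics(tp$pairs, tp$catalog, motifs)
  expect_equal(out$tf_shared, 1)    # only B present in both windows
  # occurrences: gA window has A,B,B(140k) = 3; gB window has B,C,C = 3
  # the 140 kb instance lies in both windows and counts once per window
  expect_equal(out$tfbs_total, 6)

  empty <- tfbs_metrics(tp$pairs, tp$catalog, motifs[0, ])
  expect_equal(empty$tf_shared, 0)
  expect_equal(empty$tfbs_total, 0)
})

test_that("expression similarity uses relative differences of raw summaries", {
  # gene means 10 and 30 -> |10-30| / 20 = 1
  v <- rbind(gA = c(8, 12, 10, 10), gB = c(28, 32, 30, 30))
  colnames(v) <- paste0("s", 1:4)
  p <- data.frame(gene_a = "gA", gene_b = "gB")
  out <- expression_similarity(p, v)
  expect_equal(out$diff_expr_level, 1)
  # CV check against direct arithmetic
  cva <- sd(v["gA", ]) / mean(v["gA", ]); cvb <- sd(v["gB", ]) / mean(v["gB", ])
  expect_equal(out$diff_coef_var, abs(cva - cvb) / ((cva + cvb) / 2))

  same <- expression_similarity(p, rbind(gA = v["gA", ], gB = v["gA", ]))
  expect_equal(same$diff_expr_level, 0)

  zero <- rbind(gA = rep(0, 4), gB = rep(0, 4))
  colnames(zero) <- paste0("s", 1:4)
  expect_warning(z <- expression_similarity(p, zero), "non-positive")
  expect_equal(z$diff_expr_level, 0)
})

test_that("LD proxy is the max r-squared over flanking variant dosages", {
  catal <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(100000, 300000), strand = "+",
                      biotype = "protein_coding")
  p <- data.frame(gene_a = "gA", gene_b = "gB")
  set.seed(4)
  d1 <- rbinom(100, 2, 0.3); d2 <- rbinom(100, 2, 0.4)
  G <- rbind(v1 = d1, v2 = d1, v3 = d2, v4 = rep(1, 100))
  colnames(G) <- paste0("s", 1:100)
  variants <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                         chrom = "chr1",
                         pos = c(99000, 301000, 302000, 299000))
  # v1 (gA flank) and v2 (gB flank) are identical dosages -> r^2 = 1
  out <- ld_proxy(p, catal, G, variants)
  expect_equal(out$ld_proxy, 1)

  # only independent variants: r^2 small; monomorphic v4 skipped
  out2 <- ld_proxy(p, catal, G[c("v1", "v3", "v4"), ], variants[c(1, 3, 4), ])
  expect_lt(out2$ld_proxy, 0.1)

  # empty flank -> 0
  out3 <- ld_proxy(p, catal, G["v3", , drop = FALSE], variants[3, ])
  expect_equal(out3$ld_proxy, 0)
})

test_that("GO sharing counts exact term intersections", {
  terms <- data.frame(gene_id = c("gA", "gA", "gB"),
                      term = c("GO:1", "GO:2", "GO:2"))
  p <- data.frame(gene_a = "gA", gene_b = "gB")
  expect_equal(go_sharing(p, terms)$go_sharing, 1)
  expect_equal(go_sharing(p, terms[1, ])$go_sharing, 0)
  t3 <- data.frame(gene_id = rep(c("gA", "gB"), each = 3),
                   term = rep(c("GO:1", "GO:2", "GO:3"), 2))
  expect_equal(go_sharing(p, t3)$go_sharing, 3)
})

test_that("feature assembly zero-fills, orders columns and rejects duplicates", {
  pairs <- data.frame(gene_a = c("gA", "gC"), gene_b = c("gB", "gD"),
                      tss_distance = c(100, 200), label = c(1L, 0L))
  m <- data.frame(gene_a = "gA", gene_b = "gB", hic_contact = 3.5)
  out <- assemble_features(pairs, m)
  expect_equal(out$hic_contact, c(3.5, 0))  # absent pair zero-filled
  expect_equal(names(out), c("gene_a", "gene_b", "tss_distance",
                             "hic_contact", "label"))
  dup <- rbind(pairs, pairs[1, ])
  expect_error(assemble_features(dup, m), "duplicate")

  # full assembly on the simulated dataset: complete, no NAs, stable order
  sim <- fixture_sim()
  disc <- fixture_discovery()
  ctl <- suppressWarnings(match_noncops(disc, seed = 7))
  lp <- labelled_pairs(ctl, disc)
  ft <- suppressWarnings(compute_features(lp, sim))
  expect_false(anyNA(ft))
  ft2 <- suppressWarnings(compute_features(lp, sim))
  expect_identical(names(ft), names(ft2))
  num <- as.matrix(ft[, setdiff(names(ft), c("gene_a", "gene_b", "label"))])
  expect_true(all(num >= 0))
})

test_that("configured depletion shows up as fewer features for called pairs", {
  sim <- fixture_sim()
  disc <- fixture_discovery()
  ctl <- suppressWarnings(match_noncops(disc, seed = 7))
  lp <- labelled_pairs(ctl, disc)
  ft <- suppressWarnings(compute_features(lp, sim))
  expect_lt(mean(ft$total_ctcf[ft$label == 1]),
            mean(ft$total_ctcf[ft$label == 0]))
  expect_lt(mean(ft$tfbs_total[ft$label == 1]),
            mean(ft$tfbs_total[ft$label == 0]))
  expect_lt(mean(ft$enh_total[ft$label == 1]),
            mean(ft$enh_total[ft$label == 0]))
  expect_gt(mean(ft$enh_sharing[ft$label == 1]),
            mean(ft$enh_sharing[ft$label == 0]))
})
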