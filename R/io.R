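#' Write / read an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param expr a [locop_expr].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  dt <- data.table::as.data.table(expr$values, keep.rownames = "gene_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param state processing-state flag assigned to the loaded matrix.
#' @export
read_expression_tsv <- function(path, state = "raw") {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  locop_expr(m, state = state)
}

#' Write a gene catalog as BED6
#'
#' One 1-bp interval per TSS; the score column encodes the biotype
#' (1 = protein_coding, 2 = lincRNA, 0 = other).
#'
#' @param catalog gene catalog data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  score <- match(catalog$biotype, c("protein_coding", "lincRNA"))
  score[is.na(score)] <- 0L
  bed <- data.frame(catalog$chrom, catalog$tss, catalog$tss + 1L,
                    catalog$gene_id, score, catalog$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_bed
#' @export
read_catalog_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  data.frame(gene_id = dt[[4]], chrom = dt[[1]], tss = dt[[2]],
             strand = dt[[6]],
             biotype = c("other", "protein_coding", "lincRNA")[dt[[5]] + 1L],
             stringsAsFactors = FALSE)
}

#' Write a gene catalog as minimal GTF
#'
#' One `gene` feature per gene; 1-based inclusive coordinates with the
#' TSS as the strand-aware start.
#'
#' @param catalog gene catalog data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog_gtf <- function(catalog, path) {
  attrs <- sprintf('gene_id "%s"; gene_type "%s";',
                   catalog$gene_id, catalog$biotype)
  lines <- sprintf("%s\tlocop\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   catalog$chrom, catalog$tss + 1L, catalog$tss + 1L,
                   catalog$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation track as BED6
#'
#' Strand carries motif orientation; the name column carries the label
#' (motif id / enhancer id).
#'
#' @param track interval data.frame (`chrom`, `start`, `end`, `strand`,
#'   `label` or `enhancer_id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  name <- track$label %||% track$enhancer_id %||% "."
  strand <- track$strand %||% "*"
  strand[strand == "*"] <- "."
  bed <- data.frame(track$chrom, track$start, track$end, name, 0L, strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_track_bed
#' @export
read_track_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  strand <- if (ncol(dt) >= 6) dt[[6]] else "."
  strand[strand == "."] <- "*"
  data.frame(chrom = dt[[1]], start = dt[[2]], end = dt[[3]],
             strand = strand,
             label = if (ncol(dt) >= 4) dt[[4]] else ".",
             stringsAsFactors = FALSE)
}

#' Write genotypes as VCF 4.2 with GT fields
#'
#' Dosages 0/1/2 become unphased genotypes 0/0, 0/1, 1/1.
#'
#' @param genotypes dosage matrix, variants x individuals.
#' @param variants variant table (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(identical(rownames(genotypes), variants$variant_id))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
               nrow = nrow(genotypes))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(genotypes)),
                    collapse = "\t"))
  body <- paste(variants$chrom, variants$pos + 1L, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF with GT fields
#'
#' Minimal reader for the VCF layout produced by [write_vcf()]: biallelic
#' records, GT-only FORMAT, positions returned 0-based.
#'
#' @param path VCF file.
#' @return List: `genotypes` (dosage matrix), `variants` (data.frame).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  variants <- data.frame(
    variant_id = vapply(fields, `[`, "", 3),
    chrom = vapply(fields, `[`, "", 1),
    pos = as.integer(vapply(fields, `[`, "", 2)) - 1L,
    ref = vapply(fields, `[`, "", 4),
    alt = vapply(fields, `[`, "", 5),
    stringsAsFactors = FALSE)
  G <- t(vapply(fields, function(f) {
    gt <- substr(f[-(1:9)], 1, 3)
    as.integer(substr(gt, 1, 1)) + as.integer(substr(gt, 3, 3))
  }, integer(length(samples))))
  dimnames(G) <- list(variants$variant_id, samples)
  list(genotypes = G, variants = variants)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the expression TSV, catalog BED + GTF, genotypes VCF, annotation
#' track BEDs, enhancer-link / Hi-C / GWAS / truth TSVs.
#'
#' @param sim a `locop_sim` dataset.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression_tsv(sim$expr, fp("expression.tsv"))
  write_catalog_bed(sim$catalog, fp("genes.bed"))
  write_catalog_gtf(sim$catalog, fp("genes.gtf"))
  write_vcf(sim$genotypes, sim$variants, fp("genotypes.vcf"))
  write_track_bed(sim$tracks$ctcf_sites, fp("ctcf_sites.bed"))
  write_track_bed(sim$tracks$ctcf_motifs, fp("ctcf_motifs.bed"))
  write_track_bed(sim$tracks$tf_motifs, fp("tf_motifs.bed"))
  write_track_bed(sim$tracks$enhancers, fp("enhancers.bed"))
  tsv <- function(x, f) data.table::fwrite(x, fp(f), sep = "\t")
  tsv(sim$tracks$enhancer_links, "enhancer_links.tsv")
  tsv(sim$tracks$hic, "hic.tsv")
  tsv(sim$gwas, "gwas.tsv")
  tsv(sim$truth_pairs, "truth_pairs.tsv")
  tsv(sim$truth_eqtl, "truth_eqtl.tsv")
  tsv(sim$annotations$go, "go.tsv")
  tsv(sim$annotations$paralog_pairs, "paralog_pairs.tsv")
  invisible(dir)
}

#' Write the pair table of a discovery result as TSV
#'
#' @param result a `locop_discovery` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(result, path) {
  data.table::fwrite(result$pairs, path, sep = "\t")
  invisible(path)
}
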