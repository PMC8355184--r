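# shared fixtures, built lazily and cached for the whole run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# moderate synthetic study: planted blocks, genotypes, tracks, GWAS
fixture_sim <- function() cached("sim", function() {
  simulate_dataset(sim_config(
    n_individuals = 150, n_genes = 300, n_chromosomes = 2,
    block_spec = data.frame(size = rep(3L, 30L), loading = 0.85),
    seed = 7L))
})

fixture_int_expr <- function() cached("int_expr", function() {
  sim <- fixture_sim()
  preprocess_expression(sim$expr, sim$catalog,
                        covariates = sim$confounders)$expr
})

fixture_discovery <- function() cached("discovery", function() {
  sim <- fixture_sim()
  discover_cops(fixture_int_expr(), sim$catalog, R = 400, fdr = 0.01,
                seed = 7)
})

# a hand-made catalog on one chromosome with evenly spaced TSSs
toy_catalog <- function(tss, chrom = "chr1", strand = NULL) {
  n <- length(tss)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
             tss = as.integer(tss),
             strand = strand %||% rep("+", n),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

# an expression object directly in a given state (bypassing the pipeline,
# for unit tests of single operations)
toy_expr <- function(values, state = "int") {
  locop_expr(values, state = "raw") |>
    (\(e) { e$state <- state; e })()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal discovery-like object for control-matching tests
fake_discovery <- function(pairs) {
  structure(list(pairs = pairs, threshold = 0.01, fdr = 0.01,
                 settings = list()), class = "locop_discovery")
}
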