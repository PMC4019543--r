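# Shared builders for small in-code fixtures.

# random transcript table with gene ids cycling over n_genes
random_transcripts <- function(n = 10, len = 200, n_genes = n, seed = 1) {
  set.seed(seed)
  data.frame(
    transcript_id = sprintf("t%03d", seq_len(n)),
    gene_id = sprintf("g%03d", ((seq_len(n) - 1) %% n_genes) + 1),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), ""),
    stringsAsFactors = FALSE)
}

random_probes <- function(n = 20, seed = 1) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
            collapse = ""), ""),
    sprintf("p%03d", seq_len(n)))
}

# small complete synthetic study used by several suites
small_fixture <- function(seed = 7, ...) {
  simulate_fixture(fixture_spec(
    seed = seed, n_genes = 30, n_probesets = 30, n_planted_de = 6,
    n_genesets = 10, geneset_size = 8, ...))
}

# build a library straight from a fixture (no redundancy expected)
fixture_library <- function(fx, config = match_config()) {
  idx <- build_seed_index(fx$transcriptome, config)
  hits <- find_hits(fx$probes$probe_tab, idx)
  sel <- select_probes_all(fx$probes$probe_tab, hits, config)
  col <- collapse_redundancy(sel$kept)
  list(library = build_library(col$kept, config = config, created = "test"),
       hits = hits,
       rejections = rbind(sel$rejections, col$rejections))
}

# identity setting for pipeline-equality tests: every grid cell is a PM
# probe of some probe set
identity_setup <- function(n_sets = 3, probes_per_set = 4, n_samples = 4,
                           seed = 11) {
  set.seed(seed)
  n <- n_sets * probes_per_set
  side_x <- probes_per_set
  side_y <- n_sets
  tab <- data.frame(
    probeset_id = rep(sprintf("ps%02d", seq_len(n_sets)),
                      each = probes_per_set),
    probe_id = sprintf("pr%03d", seq_len(n)),
    x = (seq_len(n) - 1) %% side_x,
    y = (seq_len(n) - 1) %/% side_x,
    interrogation_position = 13L,
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), ""),
    role = "PM", stringsAsFactors = FALSE)
  probesets <- lapply(split(tab, tab$probeset_id), function(rows) {
    structure(list(probeset_id = rows$probeset_id[1],
                   target_gene_id = paste0("gene_", rows$probeset_id[1]),
                   target_transcript_id = "t1",
                   retained_probes = data.frame(
                     probe_id = rows$probe_id, x = rows$x, y = rows$y,
                     tier = "EXACT", stringsAsFactors = FALSE),
                   n_probe_pairs = nrow(rows)),
              class = "ortholog_probeset")
  })
  lib <- build_library(unname(probesets), created = "test")
  cels <- lapply(seq_len(n_samples), function(j) {
    m <- matrix(stats::rexp(side_x * side_y, 1 / 200) + 20,
                nrow = side_y, ncol = side_x)
    structure(list(cols = side_x, rows = side_y, mean = m), class = "oa_cel")
  })
  names(cels) <- sprintf("s%02d", seq_len(n_samples))
  list(library = lib, cels = cels, probe_tab = tab)
}

# quadrature oracle for the posterior mean of the exponential + normal
# convolution model, rescaled to avoid underflow
normexp_quadrature <- function(x, mu, sigma, alpha) {
  logw <- function(s) -s / alpha + stats::dnorm(x - s, mu, sigma, log = TRUE)
  # posterior support: a normal of sd sigma centred near x - mu, truncated
  # to s > 0; integrate over a finite window that certainly contains it
  upper <- max(x - mu + 12 * sigma, 12 * sigma)
  grid <- seq(0, upper, length.out = 4096)
  C <- max(logw(grid))
  num <- stats::integrate(function(s) s * exp(logw(s) - C), 0, upper,
                          rel.tol = 1e-11, subdivisions = 500L)$value
  den <- stats::integrate(function(s) exp(logw(s) - C), 0, upper,
                          rel.tol = 1e-11, subdivisions = 500L)$value
  num / den
}
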