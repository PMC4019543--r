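test_that("the generator is a pure function of its spec", {
  s1 <- fixture_spec(seed = 5, n_genes = 12, n_probesets = 12,
                     n_planted_de = 3, n_genesets = 5, geneset_size = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_fixture(s1, d1)
  simulate_fixture(s1, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  simulate_fixture(fixture_spec(seed = 6, n_genes = 12, n_probesets = 12,
                                n_planted_de = 3, n_genesets = 5,
                                geneset_size = 5), d2)
  expect_false(identical(readLines(file.path(d1, "transcripts.fasta")),
                         readLines(file.path(d2, "transcripts.fasta"))))
})

test_that("transcriptome structure matches the spec", {
  spec <- fixture_spec(seed = 3, n_genes = 20, n_probesets = 20)
  tx <- make_transcriptome(spec)
  expect_true(all(sprintf("G%04d", 1:20) %in% tx$gene_id))
  ntx <- table(tx$gene_id)
  expect_true(all(ntx >= 1 & ntx <= 3))
  # transcripts of one gene share the core
  g <- names(ntx)[ntx > 1][1]
  if (!is.na(g)) {
    seqs <- tx$sequence[tx$gene_id == g]
    core <- substr(seqs[1], 1, spec$transcript_core_len)
    expect_true(all(vapply(seqs, grepl, TRUE, pattern = core, fixed = TRUE)))
  }
  # GC content near one half on aggregate
  all_bases <- strsplit(paste(tx$sequence, collapse = ""), "")[[1]]
  gc <- mean(all_bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("planted tier labels are honoured by the matcher", {
  fx <- small_fixture(seed = 51)
  cfg <- match_config(rescue_enabled = TRUE)
  hits <- find_hits(fx$probes$probe_tab,
                    build_seed_index(fx$transcriptome, cfg))
  truth <- fx$probes$truth
  key <- paste(hits$probe_id, hits$gene_id, hits$offset)
  found <- hits$tier[match(paste(truth$probe_id, truth$gene_id,
                                 truth$offset), key)]
  for (t in c("EXACT", "END_MM", "TANDEM", "RESCUE")) {
    expect_true(all(found[truth$tier_label == t] == t), label = t)
  }
  # NO_HIT probes produce zero hits anywhere, even with rescue enabled
  nohit <- truth$probe_id[truth$tier_label == "NO_HIT"]
  expect_equal(sum(hits$probe_id %in% nohit), 0L)
  # MULTI_GENE probes hit exactly two distinct genes
  mg <- truth$probe_id[truth$tier_label == "MULTI_GENE"]
  genes <- hits_to_genes(hits[hits$probe_id %in% mg, ])
  expect_true(all(lengths(genes) == 2L))
})

test_that("tier label counts follow largest-remainder rounding", {
  spec <- fixture_spec(seed = 9, n_genes = 13, n_probesets = 13)
  fx <- simulate_fixture(spec)
  total <- 13L * spec$probes_per_set
  want <- largest_remainder(total, spec$tier_mix)
  got <- table(factor(fx$probes$truth$tier_label,
                      levels = names(spec$tier_mix)))
  expect_equal(unname(c(got)), want)
})

test_that("planted DE truth matches the requested design", {
  fx <- small_fixture(seed = 13)
  de <- fx$intensities$truth_de
  expect_equal(sum(de$is_de), 6L)
  expect_true(all(abs(de$planted_log2fc[de$is_de]) == 2))
  expect_true(all(de$planted_log2fc[!de$is_de] == 0))
  samp <- fx$intensities$samples
  expect_equal(sum(samp$class == 0L), 6L)
  expect_equal(sum(samp$class == 1L), 12L)
  expect_true(all(vapply(fx$intensities$cels,
                         function(c) all(c$mean > 0), TRUE)))
})

test_that("noiseless intensities recover planted fold changes exactly", {
  spec <- fixture_spec(seed = 21, n_genes = 15, n_probesets = 15,
                       n_planted_de = 4, noise_sd = 0,
                       probe_affinity_sd = 0, bg_mean = 1e-6, bg_sd = 0,
                       n_genesets = 5, geneset_size = 5)
  fx <- simulate_fixture(spec)
  res <- fixture_library(fx)
  # normalization off: forcing identical distributions on arrays whose
  # groups genuinely differ cannot be exact in the noiseless few-gene limit
  expr <- rma_pipeline(fx$intensities$cels, res$library,
                       rma_config(background = FALSE,
                                  quantile_norm = FALSE))
  gmap <- stats::setNames(
    vapply(res$library$probesets, `[[`, "", "target_gene_id"),
    vapply(res$library$probesets, `[[`, "", "probeset_id"))
  labels <- stats::setNames(fx$intensities$samples$class,
                            fx$intensities$samples$sample_id)
  fc <- fold_change(expr, labels)
  truth <- fx$intensities$truth_de
  m <- match(unname(gmap[fc$gene_id]), truth$gene_id)
  expect_equal(fc$log2_ratio, truth$planted_log2fc[m], tolerance = 1e-6)
})

test_that("gene sets parse back and the planted overlap is as declared", {
  fx <- small_fixture(seed = 61)
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(fx$gene_sets, tf)
  back <- read_gmt(tf)
  strip <- function(x) { attributes(x) <- NULL; x }
  expect_equal(strip(back), strip(fx$gene_sets))
  expect_equal(names(back), names(fx$gene_sets))
  de <- fx$intensities$truth_de$gene_id[fx$intensities$truth_de$is_de]
  overlap <- length(intersect(back$PLANTED_ENRICHED, de))
  expect_equal(overlap, attr(fx$gene_sets, "planted_overlap"))
  # random sets' overlaps stay near the background rate
  rand <- setdiff(names(back), "PLANTED_ENRICHED")
  ov <- vapply(back[rand], function(s) length(intersect(s, de)), 0L)
  expect_lt(mean(ov), overlap)
})

test_that("ranking fixture plants the stated shift", {
  fx <- simulate_ranking_matrix(n_transcripts = 100, n_per_class = 6,
                                n_informative = 10, shift = 2, seed = 3)
  expect_equal(dim(fx$expr), c(100L, 12L))
  expect_equal(length(fx$informative), 10L)
  inf <- fx$expr[fx$informative, ]
  diffs <- rowMeans(inf[, fx$labels == 1]) - rowMeans(inf[, fx$labels == 0])
  # planted shift of 2 SD, class means over 6 samples (SE ~ 0.58)
  expect_gt(mean(diffs), 1.5)
  expect_true(all(diffs > 0))
  expect_identical(fx$expr,
                   simulate_ranking_matrix(100, 6, 10, 2, seed = 3)$expr)
})
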