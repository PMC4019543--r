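# helper: synthetic hits/probe rows for rule-level tests
make_rows <- function(psid, n, x0 = 0) {
  data.frame(probeset_id = psid,
             probe_id = sprintf("%s_p%02d", psid, seq_len(n)),
             x = x0 + seq_len(n) - 1, y = 0L,
             interrogation_position = 13L,
             sequence = strrep("A", 25), role = "PM",
             stringsAsFactors = FALSE)
}

make_hits <- function(rows, genes, tiers = "EXACT") {
  n <- nrow(rows)
  genes <- rep_len(genes, n)
  tiers <- rep_len(tiers, n)
  data.frame(probe_id = rows$probe_id,
             transcript_id = paste0("tx_", genes),
             gene_id = genes, offset = 0L, strand = "+",
             core_start = 0L, core_len = 25L,
             n_end_mismatch_left = 0L, n_end_mismatch_right = 0L,
             tier = tiers, stringsAsFactors = FALSE)
}

test_that("a clean probe set passes through with all probes", {
  rows <- make_rows("ps1", 11)
  ps <- select_probes(rows, make_hits(rows, "g1"))
  expect_s3_class(ps, "ortholog_probeset")
  expect_equal(ps$n_probe_pairs, 11L)
  expect_equal(ps$target_gene_id, "g1")
  expect_equal(ps$retained_probes$probe_id, rows$probe_id)
})

test_that("fewer than three surviving probes rejects with MIN_PROBES", {
  rows <- make_rows("ps1", 5)
  hits <- make_hits(rows[1:2, ], "g1")
  rej <- select_probes(rows, hits)
  expect_s3_class(rej, "probeset_rejection")
  expect_equal(rej$reason, "MIN_PROBES")
  # exactly three probes survive: kept
  expect_s3_class(select_probes(rows, make_hits(rows[1:3, ], "g1")),
                  "ortholog_probeset")
})

test_that("no hits and all-multi-gene probes reject with their reasons", {
  rows <- make_rows("ps1", 4)
  empty <- make_hits(rows, "g1")[0, ]
  expect_equal(select_probes(rows, empty)$reason, "NO_HITS")
  multi <- rbind(make_hits(rows, "g1"), make_hits(rows, "g2"))
  expect_equal(select_probes(rows, multi)$reason, "MULTI_GENE")
})

test_that("plurality gene wins and intermingling probes are dropped", {
  rows <- make_rows("ps1", 11)
  hits <- make_hits(rows, c(rep("g1", 6), rep("g2", 5)))
  ps <- select_probes(rows, hits)
  expect_equal(ps$target_gene_id, "g1")
  expect_equal(ps$n_probe_pairs, 6L)
  expect_setequal(ps$retained_probes$probe_id, rows$probe_id[1:6])
})

test_that("vote ties break by summed tier rank then gene id", {
  rows <- make_rows("ps1", 8)
  # 4 probes TANDEM to g2, 4 probes EXACT to g1 -> g1 on rank
  hits <- make_hits(rows, c(rep("g2", 4), rep("g1", 4)),
                    c(rep("TANDEM", 4), rep("EXACT", 4)))
  expect_equal(select_probes(rows, hits)$target_gene_id, "g1")
  # equal ranks -> lexicographically smallest gene
  hits2 <- make_hits(rows, c(rep("g9", 4), rep("g3", 4)))
  expect_equal(select_probes(rows, hits2)$target_gene_id, "g3")
})

test_that("probes hitting several transcripts of one gene stay specific", {
  rows <- make_rows("ps1", 4)
  h1 <- make_hits(rows, "g1")
  h2 <- make_hits(rows, "g1")
  h2$transcript_id <- "tx_g1_b"
  h2$offset <- 7L
  ps <- select_probes(rows, rbind(h1, h2))
  expect_equal(ps$n_probe_pairs, 4L)
  # representative transcript is the one hit by most retained probes
  expect_equal(ps$target_transcript_id, "tx_g1")
})

test_that("redundancy collapses to one probe set per gene", {
  r1 <- make_rows("ps1", 9)
  r2 <- make_rows("ps2", 6, x0 = 20)
  r3 <- make_rows("ps3", 5, x0 = 40)
  kept <- list(select_probes(r1, make_hits(r1, "g1")),
               select_probes(r2, make_hits(r2, "g1")),
               select_probes(r3, make_hits(r3, "g2")))
  col <- collapse_redundancy(kept)
  expect_equal(vapply(col$kept, `[[`, "", "probeset_id"), c("ps1", "ps3"))
  expect_equal(col$rejections$probeset_id, "ps2")
  expect_equal(col$rejections$reason, "REDUNDANT")
  # unique sets pass through unchanged
  col2 <- collapse_redundancy(kept[c(1, 3)])
  expect_equal(length(col2$kept), 2L)
  expect_equal(nrow(col2$rejections), 0L)
})

test_that("library invariants are enforced at build time", {
  r1 <- make_rows("ps1", 4)
  r2 <- make_rows("ps2", 4, x0 = 10)
  p1 <- select_probes(r1, make_hits(r1, "g1"))
  p2 <- select_probes(r2, make_hits(r2, "g2"))
  lib <- build_library(list(p1, p2), created = "t")
  expect_s3_class(lib, "oa_library")

  expect_error(build_library(list(p1, p1), created = "t"),
               "duplicate probeset_id")
  p2b <- p2; p2b$probeset_id <- "ps2b"; p2b$target_gene_id <- "g1"
  expect_error(build_library(list(p1, p2b), created = "t"),
               "not one-to-one")
  p2c <- p2; p2c$retained_probes$x <- p1$retained_probes$x
  p2c$retained_probes$y <- p1$retained_probes$y
  expect_error(build_library(list(p1, p2c), created = "t"),
               "coordinate shared")
  expect_warning(build_library(list(), created = "t"), "empty")
})

test_that("library JSON round-trips exactly", {
  fx <- small_fixture(seed = 19)
  lib <- fixture_library(fx)$library
  tf <- withr::local_tempfile(fileext = ".json")
  write_library_json(lib, tf)
  back <- read_library_json(tf)
  expect_equal(back, lib)
  # CDF-like text export exists and lists every unit
  tc <- withr::local_tempfile(fileext = ".cdf")
  write_cdf_text(lib, tc)
  txt <- readLines(tc)
  expect_equal(sum(grepl("^\\[Unit", txt)), length(lib$probesets))
})

test_that("planted fixture recovers exactly the single-gene orthologs", {
  for (seed in c(19, 402)) {
    fx <- small_fixture(seed = seed)
    res <- fixture_library(fx)
    truth <- fx$probes$truth
    planted_good <- sort(truth$probe_id[
      truth$tier_label %in% c("EXACT", "END_MM", "TANDEM")])
    retained <- sort(unname(unlist(lapply(res$library$probesets,
                                          function(p) p$retained_probes$probe_id))))
    expect_equal(retained, planted_good)  # precision = recall = 1
    # every set >= 3 pairs, bijective mapping
    npp <- vapply(res$library$probesets, `[[`, 0L, "n_probe_pairs")
    expect_true(all(npp >= 3L))
    genes <- vapply(res$library$probesets, `[[`, "", "target_gene_id")
    expect_false(anyDuplicated(genes) > 0)
    # retained tier equals planted tier
    for (p in res$library$probesets) {
      m <- match(p$retained_probes$probe_id, truth$probe_id)
      expect_equal(p$retained_probes$tier, truth$tier_label[m])
    }
  }
})

test_that("attrition is conserved and summary counts match ground truth", {
  fx <- small_fixture(seed = 23)
  res <- fixture_library(fx)
  n_in <- length(unique(fx$probes$probe_tab$probeset_id))
  expect_equal(length(res$library$probesets) + nrow(res$rejections), n_in)
  s <- library_summary(res$library, res$rejections)
  expect_equal(s$n_kept, length(res$library$probesets))
  tc <- table(fx$probes$truth$tier_label)
  expect_equal(unname(s$probes_by_tier["EXACT"]), unname(tc["EXACT"]))
  expect_equal(unname(s$probes_by_tier["END_MM"]), unname(tc["END_MM"]))
  expect_equal(unname(s$probes_by_tier["TANDEM"]), unname(tc["TANDEM"]))
  expect_equal(s$n_probes_retained,
               sum(tc[c("EXACT", "END_MM", "TANDEM")]))
})

test_that("tightening the match configuration never keeps more sets", {
  fx <- small_fixture(seed = 31)
  n_kept <- function(cfg) length(fixture_library(fx, cfg)$library$probesets)
  loose <- n_kept(match_config(rescue_enabled = TRUE))
  normal <- n_kept(match_config())
  tight <- n_kept(match_config(min_tandem = 24, max_end_mismatch = 1))
  expect_lte(normal, loose)
  expect_lte(tight, normal)
})
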