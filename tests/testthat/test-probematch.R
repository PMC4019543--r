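test_that("seed index counts and refusals follow the contract", {
  tx <- data.frame(transcript_id = "t1", gene_id = "g1",
                   sequence = strrep("A", 30), stringsAsFactors = FALSE)
  idx <- build_seed_index(tx, match_config(min_tandem = 20))
  km <- index_kmers(idx)
  expect_equal(nrow(km), 11L)  # 30 - 20 + 1
  expect_true(all(km$kmer == strrep("A", 20)))
  expect_equal(km$offset, 0:10)

  short <- data.frame(transcript_id = "t1", gene_id = "g1",
                      sequence = "ACGT", stringsAsFactors = FALSE)
  expect_warning(idx2 <- build_seed_index(short), "shorter than k")
  expect_equal(nrow(index_kmers(idx2)), 0L)

  # k < 8 refused (rescue shrinks k to 25 - rescue_max_end_mismatch)
  expect_error(
    build_seed_index(tx, match_config(min_tandem = 7)),
    "refus")
})

test_that("index contents equal direct enumeration of all k-mers", {
  tx <- random_transcripts(n = 50, len = 60, seed = 5)
  cfg <- match_config(min_tandem = 12)
  idx <- build_seed_index(tx, cfg)
  got <- index_kmers(idx)
  k <- 12L
  want <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    s <- tx$sequence[i]
    data.frame(kmer = substring(s, 1:(nchar(s) - k + 1), k:nchar(s)),
               transcript_id = tx$transcript_id[i],
               offset = 0:(nchar(s) - k), stringsAsFactors = FALSE)
  }))
  want <- want[order(want$transcript_id, want$offset), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("single planted hits are classified at the forced tier", {
  base <- random_transcripts(n = 1, len = 120, seed = 8)
  w <- substr(base$sequence, 41, 65)
  idx <- build_seed_index(base)

  h <- find_hits(c(probe = w), idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$tier, "EXACT")
  expect_equal(h$offset, 40L)
  expect_equal(h$core_len, 25L)

  # first 2 bases mismatched, remaining 23 contiguous
  w2 <- paste0(chartr("ACGT", "CGTA", substr(w, 1, 2)), substr(w, 3, 25))
  h2 <- find_hits(c(probe = w2), idx)
  h2 <- h2[h2$offset == 40L, ]
  expect_equal(h2$tier, "END_MM")
  expect_equal(h2$core_len, 23L)
  expect_equal(h2$n_end_mismatch_left, 2L)

  # 20-mer shared mid-probe, both flanks mismatched
  w3 <- w
  for (p in c(1, 2, 24, 25)) {
    substr(w3, p, p) <- chartr("ACGT", "CGTA", substr(w3, p, p))
  }
  substr(w3, 3, 3) <- chartr("ACGT", "CGTA", substr(w3, 3, 3))
  h3 <- find_hits(c(probe = w3), idx)
  h3 <- h3[h3$offset == 40L, ]
  expect_equal(h3$tier, "TANDEM")
  expect_gte(h3$core_len, 20L)

  # reverse complement is found on strand '-'
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]),
              collapse = "")
  h4 <- find_hits(c(probe = rc), idx)
  expect_equal(h4$strand, "-")
  expect_equal(h4$tier, "EXACT")
  expect_equal(h4$offset, 40L)
  # and is invisible when reverse-complement search is off
  idx_fwd <- build_seed_index(base,
                              match_config(search_reverse_complement = FALSE))
  expect_equal(nrow(find_hits(c(probe = rc), idx_fwd)), 0L)
})

test_that("indexed matcher equals brute-force scanner on random fixtures", {
  for (seed in 1:6) {
    tx <- random_transcripts(n = 30, len = 300, n_genes = 15, seed = seed)
    probes <- random_probes(n = 40, seed = seed + 100)
    # plant some true hits of each flavour
    probes[1] <- substr(tx$sequence[1], 11, 35)
    probes[2] <- paste0("TT", substr(tx$sequence[2], 13, 35))
    probes[3] <- paste0(substr(tx$sequence[3], 11, 30), "AAAAA")
    for (cfg in list(match_config(),
                     match_config(rescue_enabled = TRUE),
                     match_config(min_tandem = 16,
                                  max_end_mismatch = 1))) {
      idx <- build_seed_index(tx, cfg)
      a <- find_hits(probes, idx)
      b <- find_hits_bruteforce(probes, tx, cfg)
      expect_identical(a, b)
    }
  }
})

test_that("tightening the configuration never adds hits", {
  tx <- random_transcripts(n = 20, len = 400, seed = 31)
  probes <- random_probes(n = 30, seed = 77)
  probes[1:6] <- vapply(1:6, function(i) {
    w <- substr(tx$sequence[i], 50, 74)
    if (i %% 2) substr(w, 1, 1) <- "A"
    w
  }, "")
  hit_key <- function(cfg) {
    h <- find_hits(probes, build_seed_index(tx, cfg))
    paste(h$probe_id, h$transcript_id, h$offset, h$strand)
  }
  loose <- hit_key(match_config(min_tandem = 18))
  mid <- hit_key(match_config(min_tandem = 20))
  tight <- hit_key(match_config(min_tandem = 22, max_end_mismatch = 1))
  expect_true(all(mid %in% loose))
  expect_true(all(tight %in% mid))
})

test_that("repeated runs are byte-identical and totally ordered", {
  tx <- random_transcripts(n = 10, len = 500, seed = 13)
  probes <- random_probes(n = 10, seed = 14)
  probes[1] <- substr(tx$sequence[1], 1, 25)
  idx <- build_seed_index(tx)
  h1 <- find_hits(probes, idx)
  h2 <- find_hits(probes, build_seed_index(tx))
  expect_identical(h1, h2)
  key <- paste(h1$probe_id, h1$transcript_id,
               sprintf("%06d", h1$offset + 100), h1$strand)
  expect_false(is.unsorted(key))
})

test_that("hits to several transcripts of one gene collapse to one gene", {
  tx <- random_transcripts(n = 4, len = 100, n_genes = 2, seed = 21)
  tx$sequence[3] <- tx$sequence[1]  # t3 (gene g001) repeats t1's sequence
  probes <- c(pA = substr(tx$sequence[1], 21, 45),
              pB = substr(tx$sequence[2], 21, 45))
  hits <- find_hits(probes, build_seed_index(tx))
  genes <- hits_to_genes(hits, probe_ids = c("pA", "pB", "pC"))
  expect_equal(genes$pA, "g001")
  expect_equal(genes$pB, "g002")
  expect_equal(genes$pC, character())

  map <- data.frame(transcript_id = tx$transcript_id,
                    gene_id = rep("X", 4), stringsAsFactors = FALSE)
  expect_equal(unique(unlist(hits_to_genes(hits, map))), "X")
  expect_error(hits_to_genes(hits, map[1, , drop = FALSE]),
               "unmapped transcript")
})

test_that("N bases in transcripts never match probes", {
  tx <- data.frame(transcript_id = "t1", gene_id = "g1",
                   sequence = paste0(strrep("A", 12), "N", strrep("A", 30)),
                   stringsAsFactors = FALSE)
  probes <- c(p1 = strrep("A", 25))
  h <- find_hits(probes, build_seed_index(tx))
  # all alignments overlapping the N can core at most 25 bases of A runs
  expect_true(all(h$core_len <= 30))
  expect_true(nrow(h) >= 1L)
  brute <- find_hits_bruteforce(probes, tx)
  expect_identical(h, brute)
})
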