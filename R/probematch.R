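#' Matching configuration for probe-to-transcript search
#'
#' Controls how 25-mer perfect-match probes are classified against a
#' target-species cDNA database. Four tiers are recognised, in decreasing
#' order of stringency:
#'
#' * `EXACT`: all 25 bases identical.
#' * `END_MM`: a contiguous core of at least 23 bases with 1 to
#'   `max_end_mismatch` mismatching bases, which necessarily lie in the
#'   terminal positions flanking the core.
#' * `TANDEM`: a contiguous exact run of at least `min_tandem` bases
#'   anywhere in the probe (further mismatches allowed outside the run).
#' * `RESCUE` (opt-in): at most `rescue_max_end_mismatch` mismatches, all
#'   terminal (outside the core), and a contiguous core of at least
#'   `25 - rescue_max_end_mismatch` bases. This automates the otherwise
#'   manual salvage of probe sets that fail the standard criteria, and is
#'   off by default so the headline pipeline stays strict.
#'
#' @param min_tandem Minimum contiguous exact run for a `TANDEM` hit
#'   (nucleotides, default 20).
#' @param max_end_mismatch Maximum terminal mismatches for an `END_MM` hit
#'   (default 2; both ends may contribute).
#' @param rescue_enabled Enable the `RESCUE` tier (default `FALSE`).
#' @param rescue_max_end_mismatch Maximum terminal mismatches for `RESCUE`
#'   (default 9, must be < 10).
#' @param search_reverse_complement Also search the reverse complement of
#'   each probe, recording hits with strand `-` (default `TRUE`).
#' @return An object of class `match_config`.
#' @export
match_config <- function(min_tandem = 20L, max_end_mismatch = 2L,
                         rescue_enabled = FALSE,
                         rescue_max_end_mismatch = 9L,
                         search_reverse_complement = TRUE) {
  min_tandem <- as.integer(min_tandem)
  max_end_mismatch <- as.integer(max_end_mismatch)
  rescue_max_end_mismatch <- as.integer(rescue_max_end_mismatch)
  stopifnot(min_tandem >= 1L, min_tandem <= 25L,
            max_end_mismatch >= 0L, max_end_mismatch <= 2L,
            rescue_max_end_mismatch >= 1L, rescue_max_end_mismatch < 10L,
            is.logical(rescue_enabled), is.logical(search_reverse_complement))
  structure(list(min_tandem = min_tandem,
                 max_end_mismatch = max_end_mismatch,
                 rescue_enabled = isTRUE(rescue_enabled),
                 rescue_max_end_mismatch = rescue_max_end_mismatch,
                 search_reverse_complement = isTRUE(search_reverse_complement)),
            class = "match_config")
}

# Seed length guaranteeing completeness: any qualifying hit in any enabled
# tier contains a contiguous exact run at least this long.
seed_k <- function(config) {
  k <- min(config$min_tandem, 25L - config$max_end_mismatch)
  if (config$rescue_enabled) {
    k <- min(k, 25L - config$rescue_max_end_mismatch)
  }
  as.integer(k)
}

#' Build a k-mer seed index over a transcript database
#'
#' Indexes every k-mer occurrence of every transcript (k-mers containing N
#' are skipped, since N never matches a probe base). The seed length k is
#' derived from the configuration as the shortest contiguous core any
#' enabled tier can require, which guarantees that every qualifying hit is
#' discoverable through at least one seed.
#'
#' @param transcripts Data frame with `transcript_id`, `gene_id`, `sequence`
#'   (see [read_fasta()]).
#' @param config A [match_config()].
#' @return An object of class `seed_index` holding the index, the derived
#'   seed length `k`, the configuration and the transcript table.
#' @export
build_seed_index <- function(transcripts, config = match_config()) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) > 0L,
            inherits(config, "match_config"))
  k <- seed_k(config)
  if (k < 8L) {
    stop("derived seed length k = ", k,
         " is below the minimum of 8; refusing to build the index ",
         "(seed table would blow up)")
  }
  short <- nchar(transcripts$sequence) < k
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than k = ", k,
            " cannot be indexed: ",
            paste(utils::head(transcripts$transcript_id[short], 5L),
                  collapse = ", "))
  }
  ptr <- cpp_index_build(transcripts$sequence, transcripts$transcript_id,
                         transcripts$gene_id, k)
  structure(list(ptr = ptr, k = k, config = config,
                 transcripts = transcripts),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: k =", x$k, "over", nrow(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Enumerate the contents of a seed index
#'
#' Mainly a validation aid: returns every indexed (k-mer, transcript,
#' offset) triple so the index can be compared against direct enumeration.
#'
#' @param index A [build_seed_index()] result.
#' @return Data frame with columns `kmer`, `transcript_id`, `offset`
#'   (0-based), sorted.
#' @export
index_kmers <- function(index) {
  stopifnot(inherits(index, "seed_index"))
  df <- cpp_index_dump(index$ptr)
  df <- df[order(df$transcript_id, df$offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.as_pm_probes <- function(probes) {
  if (is.character(probes)) {
    ids <- names(probes)
    if (is.null(ids)) ids <- paste0("probe", seq_along(probes))
    probes <- data.frame(probe_id = ids, sequence = unname(probes),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence") %in% names(probes)))
  if ("role" %in% names(probes)) probes <- probes[probes$role == "PM", ]
  if (any(nchar(probes$sequence) != 25L) ||
      any(grepl("[^ACGT]", probes$sequence))) {
    stop("probes must be 25-mers over A/C/G/T")
  }
  probes
}

#' Find and classify probe hits against an indexed transcript database
#'
#' Seeds each probe's k-mers into the index, extends every candidate
#' alignment to its full 25-base window, and classifies it into the highest
#' qualifying tier (`EXACT` > `END_MM` > `TANDEM` > `RESCUE`). One hit is
#' reported per (transcript, offset, strand); alignments qualifying for no
#' tier are discarded. Output rows follow the total order (probe_id,
#' transcript_id, offset, strand), so repeated runs are byte-identical.
#'
#' @param probes A probe table ([read_probe_tab()]; MM rows are ignored), a
#'   data frame with `probe_id` and `sequence`, or a named character vector
#'   of 25-mer sequences.
#' @param index A [build_seed_index()] result.
#' @return Data frame with columns `probe_id`, `transcript_id`, `gene_id`,
#'   `offset` (0-based start of the 25-base alignment window on the
#'   transcript; may be negative or run past the transcript end when the
#'   probe overhangs), `strand`, `core_start`, `core_len` (longest
#'   contiguous exact run, probe coordinates), `n_end_mismatch_left`,
#'   `n_end_mismatch_right`, `tier`.
#' @export
find_hits <- function(probes, index) {
  stopifnot(inherits(index, "seed_index"))
  probes <- .as_pm_probes(probes)
  cfg <- index$config
  cpp_find_hits(index$ptr, probes$probe_id, probes$sequence,
                cfg$min_tandem, cfg$max_end_mismatch,
                cfg$rescue_enabled, cfg$rescue_max_end_mismatch,
                cfg$search_reverse_complement)
}

#' Reference brute-force probe matcher
#'
#' Scans every admissible alignment offset of every probe against every
#' transcript (both orientations when configured) and classifies each
#' window with bookkeeping independent of the seed-and-extend path. The
#' output contract is identical to [find_hits()]; this scanner exists to
#' validate the indexed matcher and is quadratic, so use it on small inputs
#' only.
#'
#' @inheritParams find_hits
#' @param transcripts Transcript data frame (see [read_fasta()]).
#' @param config A [match_config()].
#' @return Data frame as for [find_hits()].
#' @export
find_hits_bruteforce <- function(probes, transcripts,
                                 config = match_config()) {
  probes <- .as_pm_probes(probes)
  stopifnot(inherits(config, "match_config"))
  cpp_find_hits_brute(transcripts$sequence, transcripts$transcript_id,
                      transcripts$gene_id, probes$probe_id, probes$sequence,
                      config$min_tandem, config$max_end_mismatch,
                      config$rescue_enabled, config$rescue_max_end_mismatch,
                      config$search_reverse_complement)
}

#' Collapse probe hits to distinct target genes
#'
#' Hits to multiple transcripts of the same gene count as one gene: the
#' specificity rules downstream operate at the gene level, because cDNA
#' databases are redundant per gene.
#'
#' @param hits A [find_hits()] data frame.
#' @param transcript_gene_map Optional data frame (`transcript_id`,
#'   `gene_id`) overriding the gene ids carried in `hits`. Every transcript
#'   appearing in `hits` must be mapped.
#' @param probe_ids Optional character vector of probe ids to report; probes
#'   without hits get an empty gene set.
#' @return Named list (one element per probe) of sorted character vectors of
#'   distinct gene ids.
#' @export
hits_to_genes <- function(hits, transcript_gene_map = NULL,
                          probe_ids = NULL) {
  genes <- hits$gene_id
  if (!is.null(transcript_gene_map)) {
    idx <- match(hits$transcript_id, transcript_gene_map$transcript_id)
    if (anyNA(idx)) {
      stop("unmapped transcript id(s): ",
           paste(unique(hits$transcript_id[is.na(idx)]), collapse = ", "))
    }
    genes <- transcript_gene_map$gene_id[idx]
  }
  out <- lapply(split(genes, hits$probe_id), function(g) sort(unique(g)))
  if (!is.null(probe_ids)) {
    missing <- setdiff(probe_ids, names(out))
    out <- c(out, stats::setNames(rep(list(character()), length(missing)),
                                  missing))
    out <- out[probe_ids]
  }
  out
}
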