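#' Specification for a synthetic cross-species fixture
#'
#' Defines a complete synthetic study: a target-species transcriptome, an
#' array probe design planted with known orthology tiers, intensity data
#' with planted differential expression, and gene sets with one planted
#' enriched set. Everything downstream of a `fixture_spec` is a pure
#' function of it: the same spec always produces byte-identical artifacts.
#'
#' The default design mirrors a typical two-timepoint hepatocyte treatment
#' study: 6 vehicle-control and 12 treated samples (3 replicates at each of
#' 2 time points, treated at 2 dose levels), probe sets of 11 PM/MM pairs.
#'
#' @param seed Integer seed (mandatory, < 2^31).
#' @param n_genes Number of target genes.
#' @param n_probesets Number of probe sets; when larger than `n_genes` the
#'   surplus sets target already-covered genes, planting redundancy.
#' @param probes_per_set PM/MM probe pairs per probe set (default 11).
#' @param transcripts_per_gene Integer range (min, max) of transcripts per
#'   gene; transcripts of one gene share a common core sequence.
#' @param tier_mix Named proportions over EXACT, END_MM, TANDEM, RESCUE,
#'   MULTI_GENE, NO_HIT; must sum to 1. Planted counts follow
#'   largest-remainder rounding of `tier_mix * n_probesets *
#'   probes_per_set`.
#' @param n_control,n_treated Samples per class (class 0 = control,
#'   class 1 = treated).
#' @param n_planted_de Number of genes planted as differentially expressed.
#' @param de_effect_log2 Planted class effect in log2 units (alternating
#'   sign across the planted genes).
#' @param probe_affinity_sd SD of per-probe affinity offsets (log2 units).
#' @param noise_sd SD of per-measurement noise (log2 units).
#' @param bg_mean,bg_sd Mean and SD of the additive optical background on
#'   the linear intensity scale (every cell receives signal plus this
#'   background, mirroring scanner behaviour and giving the RMA
#'   convolution model a real quantity to remove).
#' @param transcript_core_len Length of each gene's core sequence; must
#'   accommodate the probe layout.
#' @param n_genesets,geneset_size Gene-set collection dimensions.
#' @param enrichment_fold Overlap enrichment of the planted set relative to
#'   the background rate.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_genes = 200L,
                         n_probesets = n_genes,
                         probes_per_set = 11L,
                         transcripts_per_gene = c(1L, 3L),
                         tier_mix = c(EXACT = 0.40, END_MM = 0.20,
                                      TANDEM = 0.15, RESCUE = 0.05,
                                      MULTI_GENE = 0.10, NO_HIT = 0.10),
                         n_control = 6L, n_treated = 12L,
                         n_planted_de = 10L, de_effect_log2 = 2,
                         probe_affinity_sd = 1.0, noise_sd = 0.25,
                         bg_mean = 32, bg_sd = 8,
                         transcript_core_len = 380L,
                         n_genesets = 25L, geneset_size = 20L,
                         enrichment_fold = 5) {
  if (missing(seed)) stop("fixture_spec requires an explicit seed")
  seed <- as.integer(seed)
  stopifnot(is.finite(seed), seed >= 0L, seed < 2147483000L,
            n_genes >= 2L, n_probesets >= 1L, probes_per_set >= 1L,
            length(transcripts_per_gene) == 2L,
            transcripts_per_gene[1L] >= 1L,
            abs(sum(tier_mix) - 1) < 1e-9, all(tier_mix >= 0),
            setequal(names(tier_mix),
                     c("EXACT", "END_MM", "TANDEM", "RESCUE",
                       "MULTI_GENE", "NO_HIT")),
            n_control >= 1L, n_treated >= 1L,
            n_planted_de >= 0L, n_planted_de <= n_genes,
            probe_affinity_sd >= 0, noise_sd >= 0,
            bg_mean > 0, bg_sd >= 0,
            transcript_core_len >= 5L + 30L * probes_per_set + 25L,
            n_genesets >= 1L, geneset_size >= 1L, enrichment_fold >= 1)
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 n_probesets = as.integer(n_probesets),
                 probes_per_set = as.integer(probes_per_set),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 tier_mix = tier_mix[c("EXACT", "END_MM", "TANDEM",
                                       "RESCUE", "MULTI_GENE", "NO_HIT")],
                 n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 n_planted_de = as.integer(n_planted_de),
                 de_effect_log2 = de_effect_log2,
                 probe_affinity_sd = probe_affinity_sd,
                 noise_sd = noise_sd, bg_mean = bg_mean, bg_sd = bg_sd,
                 transcript_core_len = as.integer(transcript_core_len),
                 n_genesets = as.integer(n_genesets),
                 geneset_size = as.integer(geneset_size),
                 enrichment_fold = enrichment_fold),
            class = "fixture_spec")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "",
           USE.NAMES = FALSE))
}

# all k-mers of both strands of a set of sequences (k-mers of the reverse
# complement of s are exactly the reverse complements of s's k-mers)
.kmers_both <- function(seqs, k) {
  c(unlist(lapply(seqs, .kmers, k = k), use.names = FALSE),
    unlist(lapply(.revcomp(seqs), .kmers, k = k), use.names = FALSE))
}

# Deterministic fixture layout shared by the generator stages: which gene
# each probe set targets, which tier each probe slot carries, and where on
# the gene's first transcript each slot's 25-mer window sits.
.fixture_layout <- function(spec) {
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  set_gene_idx <- ((seq_len(spec$n_probesets) - 1L) %% spec$n_genes) + 1L
  psids <- sprintf("PS%04d", seq_len(spec$n_probesets))
  P <- spec$probes_per_set
  total <- spec$n_probesets * P
  counts <- largest_remainder(total, spec$tier_mix)
  global <- rep(names(spec$tier_mix), counts)
  # deal round-robin so every set receives a near-identical tier profile
  tiers <- matrix("", nrow = spec$n_probesets, ncol = P)
  for (p in seq_len(P)) {
    idx <- (p - 1L) * spec$n_probesets + seq_len(spec$n_probesets)
    tiers[, p] <- global[idx]
  }
  offsets <- 5L + 30L * (seq_len(P) - 1L)  # 0-based window starts, disjoint
  partner <- (set_gene_idx %% spec$n_genes) + 1L
  list(genes = genes, psids = psids, set_gene_idx = set_gene_idx,
       tiers = tiers, offsets = offsets, partner_gene_idx = partner,
       tier_counts = stats::setNames(counts, names(spec$tier_mix)))
}

#' Generate a synthetic target-species transcriptome
#'
#' Random sequences, 1 to 3 transcripts per gene sharing a common core.
#' Cores are screened so that no 20-mer (either strand) is shared between
#' genes, guaranteeing that planted probes are specific to their gene. For
#' every probe slot planted as multi-gene, the slot's 25-mer window is
#' copied into the partner gene's first transcript behind an N spacer
#' (N matches nothing, so no spurious alignment spans the joint).
#'
#' @param spec A [fixture_spec()].
#' @return Transcript data frame (`transcript_id`, `gene_id`, `sequence`)
#'   with the fixture layout attached as attribute `layout`.
#' @export
make_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- .fixture_layout(spec)
  set.seed(spec$seed)
  seen20 <- new.env(hash = TRUE, parent = emptyenv())
  recs <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    for (try in 1:50) {
      ntx <- sample(spec$transcripts_per_gene[1L]:spec$transcripts_per_gene[2L],
                    1L)
      core <- .rand_dna(spec$transcript_core_len)
      seqs <- core
      if (ntx > 1L) {
        for (i in 2:ntx) {
          seqs <- c(seqs, paste0(.rand_dna(15L), core, .rand_dna(15L)))
        }
      }
      km <- unlist(lapply(seqs, .kmers, k = 20L), use.names = FALSE)
      if (!any(vapply(km, function(x) exists(x, envir = seen20,
                                             inherits = FALSE), TRUE))) {
        for (x in .kmers_both(seqs, 20L)) assign(x, TRUE, envir = seen20)
        recs[[g]] <- data.frame(
          transcript_id = sprintf("T%04d_%d", g, seq_len(ntx)),
          gene_id = layout$genes[g], sequence = seqs,
          stringsAsFactors = FALSE)
        break
      }
      if (try == 50L) stop("could not generate a gene-specific core for ",
                           layout$genes[g])
    }
  }
  tx <- do.call(rbind, recs)
  rownames(tx) <- NULL
  # plant multi-gene decoys: copy each MULTI_GENE slot window into the
  # partner gene's first transcript, isolated by an N spacer
  first_tx_row <- match(sprintf("T%04d_1", seq_len(spec$n_genes)),
                        tx$transcript_id)
  for (s in seq_len(spec$n_probesets)) {
    slots <- which(layout$tiers[s, ] == "MULTI_GENE")
    if (!length(slots)) next
    src_row <- first_tx_row[layout$set_gene_idx[s]]
    dst_row <- first_tx_row[layout$partner_gene_idx[s]]
    for (p in slots) {
      off <- layout$offsets[p]
      w <- substr(tx$sequence[src_row], off + 1L, off + 25L)
      tx$sequence[dst_row] <- paste0(tx$sequence[dst_row], "NNNNN", w)
    }
  }
  attr(tx, "layout") <- layout
  tx
}

.flip_base <- function(b) chartr("ACGT", "CGTA", b)

.flip_at <- function(seq, pos) {
  for (p in pos) {
    substr(seq, p, p) <- .flip_base(substr(seq, p, p))
  }
  seq
}

#' Generate the probe table with planted orthology tiers
#'
#' Each probe set's PM probes are copied from disjoint 25-mer windows of
#' its target gene's first transcript and mutated according to the planted
#' tier: EXACT (verbatim copy), END_MM (both terminal bases flipped),
#' TANDEM (bases 2 and 24 flipped, leaving a 21-base internal run),
#' RESCUE (4 bases flipped at each end, leaving a 17-base core -- below
#' the tandem threshold, recoverable only with the rescue tier enabled),
#' MULTI_GENE (verbatim copy that also occurs in the partner gene),
#' NO_HIT (random 25-mer rejection-sampled to share no 16-mer with the
#' transcriptome on either strand, so not even the rescue tier can fire).
#' MM partners complement base 13.
#'
#' @param spec A [fixture_spec()].
#' @param transcriptome [make_transcriptome()] output (layout attached).
#' @return List with `probe_tab` (see [read_probe_tab()]) and `truth`
#'   (data frame `probe_id`, `probeset_id`, `gene_id`, `tier_label`,
#'   `offset`).
#' @export
make_probes <- function(spec, transcriptome) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- attr(transcriptome, "layout")
  stopifnot(!is.null(layout))
  set.seed(spec$seed + 1L)
  seen16 <- new.env(hash = TRUE, parent = emptyenv())
  for (x in .kmers_both(transcriptome$sequence, 16L)) {
    assign(x, TRUE, envir = seen16)
  }
  first_tx <- transcriptome$sequence[
    match(sprintf("T%04d_1", layout$set_gene_idx), transcriptome$transcript_id)]
  P <- spec$probes_per_set
  n_sets <- spec$n_probesets
  rows <- vector("list", n_sets * P)
  truth <- vector("list", n_sets * P)
  for (s in seq_len(n_sets)) {
    tx1 <- first_tx[s]
    for (p in seq_len(P)) {
      tier <- layout$tiers[s, p]
      off <- layout$offsets[p]
      w <- substr(tx1, off + 1L, off + 25L)
      pm <- switch(tier,
        EXACT = w,
        MULTI_GENE = w,
        END_MM = .flip_at(w, c(1L, 25L)),
        TANDEM = .flip_at(w, c(2L, 24L)),
        RESCUE = .flip_at(w, c(1:4, 22:25)),
        NO_HIT = {
          ok <- FALSE
          cand <- ""
          for (try in 1:200) {
            cand <- .rand_dna(25L)
            hit <- any(vapply(.kmers(cand, 16L),
                              function(x) exists(x, envir = seen16,
                                                 inherits = FALSE), TRUE))
            if (!hit) { ok <- TRUE; break }
          }
          if (!ok) stop("could not sample a clean NO_HIT probe")
          cand
        })
      i <- (s - 1L) * P + p
      pid <- sprintf("%s_p%02d", layout$psids[s], p)
      rows[[i]] <- data.frame(
        probeset_id = layout$psids[s], probe_id = pid,
        interrogation_position = off + 13L, sequence = pm,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        probe_id = pid, probeset_id = layout$psids[s],
        gene_id = layout$genes[layout$set_gene_idx[s]],
        tier_label = tier, offset = off, stringsAsFactors = FALSE)
    }
  }
  pm_tab <- do.call(rbind, rows)
  mm_seq <- vapply(pm_tab$sequence, function(s) {
    substr(s, 13L, 13L) <- chartr("ACGT", "TGCA", substr(s, 13L, 13L))
    s
  }, "", USE.NAMES = FALSE)
  tab <- rbind(
    data.frame(pm_tab[, c("probeset_id", "probe_id")],
               role = "PM", sequence = pm_tab$sequence,
               interrogation_position = pm_tab$interrogation_position,
               stringsAsFactors = FALSE),
    data.frame(pm_tab[, c("probeset_id", "probe_id")],
               role = "MM", sequence = mm_seq,
               interrogation_position = pm_tab$interrogation_position,
               stringsAsFactors = FALSE))
  # interleave PM/MM pairs, then lay out on a square grid in row order
  ord <- order(tab$probeset_id, tab$probe_id, tab$role)
  tab <- tab[ord, , drop = FALSE]
  side <- as.integer(ceiling(sqrt(nrow(tab))))
  idx <- seq_len(nrow(tab)) - 1L
  tab$x <- idx %% side
  tab$y <- idx %/% side
  tab <- tab[, .probe_tab_cols]
  rownames(tab) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(probe_tab = tab, truth = truth, grid_side = side)
}

#' Generate sample metadata, planted expression truth and CEL intensities
#'
#' Per-probe log2 intensity is probe affinity + gene expression + noise,
#' where gene expression is a per-gene baseline plus the planted class
#' effect for differentially expressed genes. MM probes receive
#' affinity-plus-background only (non-specific signal); grid cells not
#' covered by probes receive low background. Intensities are exponentiated
#' to the linear scale and emitted as ASCII version-3 CEL structures.
#'
#' @param spec A [fixture_spec()].
#' @param probes [make_probes()] output.
#' @return List with `cels` (named list of `oa_cel`), `samples` (data frame
#'   `sample_id`, `class`, `time_h`, `dose`, `replicate`) and `truth_de`
#'   (data frame `gene_id`, `planted_log2fc`, `is_de`).
#' @export
make_intensities <- function(spec, probes) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  de_idx <- sort(sample(spec$n_genes, spec$n_planted_de))
  effect <- numeric(spec$n_genes)
  if (spec$n_planted_de > 0L) {
    effect[de_idx] <- spec$de_effect_log2 *
      rep_len(c(1, -1), spec$n_planted_de)
  }
  baseline <- stats::runif(spec$n_genes, 6, 10)
  truth_de <- data.frame(gene_id = genes, planted_log2fc = effect,
                         is_de = seq_len(spec$n_genes) %in% de_idx,
                         stringsAsFactors = FALSE)
  nc <- spec$n_control
  nt <- spec$n_treated
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nc + nt)),
    class = rep(c(0L, 1L), c(nc, nt)),
    time_h = c(rep_len(c(24L, 72L), nc), rep_len(c(24L, 72L), nt)),
    dose = c(rep(0, nc), rep_len(c(30, 100), nt)),
    replicate = c(seq_len(nc), seq_len(nt)),
    stringsAsFactors = FALSE)
  tab <- probes$probe_tab
  side <- probes$grid_side
  pm_rows <- which(tab$role == "PM")
  # per-pair affinity (PM and its MM share the probe_id)
  aff <- stats::rnorm(length(pm_rows), 0, spec$probe_affinity_sd)
  names(aff) <- tab$probe_id[pm_rows]
  gene_of_set <- stats::setNames(
    probes$truth$gene_id[!duplicated(probes$truth$probeset_id)],
    probes$truth$probeset_id[!duplicated(probes$truth$probeset_id)])
  gidx <- match(gene_of_set[tab$probeset_id], genes)
  cels <- vector("list", nrow(samples))
  n_cells <- side * side
  for (j in seq_len(nrow(samples))) {
    cls <- samples$class[j]
    gexpr <- baseline + cls * effect
    log2i <- numeric(nrow(tab))
    is_pm <- tab$role == "PM"
    log2i[is_pm] <- aff[tab$probe_id[is_pm]] + gexpr[gidx[is_pm]] +
      stats::rnorm(sum(is_pm), 0, spec$noise_sd)
    log2i[!is_pm] <- aff[tab$probe_id[!is_pm]] + 5 +
      stats::rnorm(sum(!is_pm), 0, spec$noise_sd)
    m <- matrix(NA_real_, nrow = side, ncol = side)
    m[cbind(tab$y + 1L, tab$x + 1L)] <- 2^log2i
    filler <- is.na(m)
    m[filler] <- 2^(4 + stats::rnorm(sum(filler), 0, 0.5))
    # additive optical background over every cell, truncated positive
    m <- m + pmax(stats::rnorm(n_cells, spec$bg_mean, spec$bg_sd),
                  spec$bg_mean / 4)
    cels[[j]] <- structure(list(cols = side, rows = side, mean = m),
                           class = "oa_cel")
  }
  names(cels) <- samples$sample_id
  list(cels = cels, samples = samples, truth_de = truth_de)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Random sets drawn uniformly from the gene universe, plus one planted
#' set whose overlap with the differentially expressed genes is
#' `enrichment_fold` times the background rate (capped at the number of
#' planted genes).
#'
#' @param spec A [fixture_spec()].
#' @param gene_ids Gene universe.
#' @param de_genes Planted differential genes (subset of `gene_ids`).
#' @return Named list of gene sets (GMT-compatible, see [write_gmt()]);
#'   the planted set is named `PLANTED_ENRICHED`. The planted overlap
#'   count is attached as attribute `planted_overlap`.
#' @export
make_genesets <- function(spec, gene_ids, de_genes) {
  stopifnot(inherits(spec, "fixture_spec"), all(de_genes %in% gene_ids))
  set.seed(spec$seed + 3L)
  size <- min(spec$geneset_size, length(gene_ids))
  bg_rate <- length(de_genes) / length(gene_ids)
  n_planted <- min(length(de_genes), size,
                   round(spec$enrichment_fold * size * bg_rate))
  sets <- vector("list", spec$n_genesets)
  names(sets) <- c("PLANTED_ENRICHED",
                   sprintf("RANDOM_SET_%02d", seq_len(spec$n_genesets - 1L)))
  non_de <- setdiff(gene_ids, de_genes)
  sets[["PLANTED_ENRICHED"]] <- sort(c(
    sample(de_genes, n_planted),
    sample(non_de, size - n_planted)))
  for (i in seq_len(spec$n_genesets - 1L)) {
    sets[[i + 1L]] <- sort(sample(gene_ids, size))
  }
  attr(sets, "descriptions") <- stats::setNames(
    c(sprintf("planted enriched set (%d of %d members differential)",
              n_planted, size),
      rep("random background set", spec$n_genesets - 1L)),
    names(sets))
  attr(sets, "planted_overlap") <- n_planted
  sets
}

#' Generate and write a complete synthetic fixture
#'
#' Runs all generator stages and writes every pipeline input plus the
#' ground-truth tables to `dir`: `transcripts.fasta`, `gene_map.tsv`,
#' `probes.tsv`, `cel/<sample>.CEL`, `labels.tsv`, `genesets.gmt`,
#' `truth_probes.tsv`, `truth_de.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed). `NULL` keeps
#'   everything in memory.
#' @return Invisibly, a list with all generated objects (`transcriptome`,
#'   `probes`, `intensities`, `gene_sets`, and `paths` when written).
#' @export
simulate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  tx <- make_transcriptome(spec)
  pr <- make_probes(spec, tx)
  it <- make_intensities(spec, pr)
  de_genes <- it$truth_de$gene_id[it$truth_de$is_de]
  gs <- make_genesets(spec, sprintf("G%04d", seq_len(spec$n_genes)),
                      de_genes)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "cel"), showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "transcripts.fasta"),
      gene_map = file.path(dir, "gene_map.tsv"),
      probe_tab = file.path(dir, "probes.tsv"),
      cel = file.path(dir, "cel", paste0(it$samples$sample_id, ".CEL")),
      labels = file.path(dir, "labels.tsv"),
      gmt = file.path(dir, "genesets.gmt"),
      truth_probes = file.path(dir, "truth_probes.tsv"),
      truth_de = file.path(dir, "truth_de.tsv"))
    write_fasta(tx, paths$fasta)
    write_gene_map(tx[, c("transcript_id", "gene_id")], paths$gene_map)
    write_probe_tab(pr$probe_tab, paths$probe_tab)
    for (j in seq_along(it$cels)) {
      write_cel_text(it$cels[[j]], paths$cel[j],
                     sample_name = it$samples$sample_id[j])
    }
    utils::write.table(it$samples, paths$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gmt(gs, paths$gmt)
    utils::write.table(pr$truth, paths$truth_probes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(it$truth_de, paths$truth_de, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(spec = spec, transcriptome = tx, probes = pr,
                 intensities = it, gene_sets = gs, paths = paths))
}

#' Simulate an expression matrix with planted informative transcripts
#'
#' A direct expression-level fixture for ranking experiments: standard
#' normal expression for every transcript, with the informative subset
#' shifted by `shift` standard deviations in the treated class.
#'
#' @param n_transcripts Number of transcripts (rows).
#' @param n_per_class Samples per class (columns = 2 * n_per_class).
#' @param n_informative Number of planted informative transcripts.
#' @param shift Class shift in SD units (default 2).
#' @param seed Integer seed.
#' @return List with `expr` (matrix, rownames `T0001`... and colnames
#'   sample ids), `labels` (0/1 named by sample), `informative`
#'   (transcript ids).
#' @export
simulate_ranking_matrix <- function(n_transcripts = 2000L,
                                    n_per_class = 9L,
                                    n_informative = 20L, shift = 2,
                                    seed = 1L) {
  stopifnot(n_informative <= n_transcripts)
  set.seed(seed)
  n <- 2L * n_per_class
  ids <- sprintf("T%04d", seq_len(n_transcripts))
  samples <- sprintf("S%02d", seq_len(n))
  labels <- stats::setNames(rep(c(0L, 1L), each = n_per_class), samples)
  expr <- matrix(stats::rnorm(n_transcripts * n), nrow = n_transcripts,
                 dimnames = list(ids, samples))
  informative <- sort(sample(n_transcripts, n_informative))
  expr[informative, labels == 1L] <- expr[informative, labels == 1L] + shift
  list(expr = expr, labels = labels, informative = ids[informative])
}
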