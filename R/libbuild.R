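.tier_rank <- c(RESCUE = 1L, TANDEM = 2L, END_MM = 3L, EXACT = 4L)

#' Apply the orthologous-probe specificity rules to one probe set
#'
#' Implements the per-probe-set selection pipeline:
#'
#' 1. Probes whose hits cover two or more distinct genes are dropped
#'    (multi-hit elimination at the gene level: hits to several transcripts
#'    of one gene still count as specific).
#' 2. The probe set is assigned to the gene hit by the plurality of the
#'    remaining probes; ties break to the gene with the higher summed tier
#'    rank (EXACT 4 > END_MM 3 > TANDEM 2 > RESCUE 1), then to the
#'    lexicographically smallest gene id.
#' 3. Remaining probes whose hits are to genes other than the assigned gene
#'    ("intermingling" probes) are dropped.
#' 4. The representative transcript is the assigned gene's transcript hit
#'    by the most retained probes (ties: smallest transcript id).
#' 5. The set is rejected if fewer than 3 probes remain.
#'
#' Rejections are data, not errors: a rejection record carries one of the
#' reason codes `NO_HITS` (no probe had any hit), `MULTI_GENE` (every
#' hitting probe was multi-gene), `MIN_PROBES` (fewer than 3 survivors).
#'
#' @param probeset_rows PM rows of one probe set from a probe table
#'   ([read_probe_tab()] format; MM rows are ignored).
#' @param hits [find_hits()] output covering this probe set's PM probes.
#' @param config The [match_config()] used to produce `hits` (recorded for
#'   provenance; no re-matching happens here).
#' @param min_probes Minimum surviving probe pairs (default 3).
#' @return An object of class `ortholog_probeset` (fields `probeset_id`,
#'   `target_gene_id`, `target_transcript_id`, `retained_probes` data frame
#'   with `probe_id`, `x`, `y`, `tier`, and `n_probe_pairs`) or of class
#'   `probeset_rejection` (fields `probeset_id`, `reason`, `n_probes_in`).
#' @export
select_probes <- function(probeset_rows, hits, config = match_config(),
                          min_probes = 3L) {
  probeset_rows <- probeset_rows[probeset_rows$role == "PM", , drop = FALSE]
  stopifnot(nrow(probeset_rows) > 0L)
  psid <- unique(probeset_rows$probeset_id)
  stopifnot(length(psid) == 1L)
  n_in <- nrow(probeset_rows)
  reject <- function(reason) {
    structure(list(probeset_id = psid, reason = reason, n_probes_in = n_in),
              class = "probeset_rejection")
  }
  hits <- hits[hits$probe_id %in% probeset_rows$probe_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(reject("NO_HITS"))
  genes_by_probe <- hits_to_genes(hits)
  # (1) multi-gene probes out
  specific <- names(genes_by_probe)[lengths(genes_by_probe) == 1L]
  if (length(specific) == 0L) return(reject("MULTI_GENE"))
  probe_gene <- vapply(genes_by_probe[specific], `[[`, "", 1L)
  # best tier rank of each specific probe for its gene
  sh <- hits[hits$probe_id %in% specific, , drop = FALSE]
  sh$rank <- .tier_rank[sh$tier]
  best_rank <- vapply(split(sh$rank, sh$probe_id), max, 0L)[specific]
  # (2) plurality gene, tie-break summed tier rank then smallest id
  votes <- tapply(rep(1L, length(specific)), probe_gene, sum)
  ranks <- tapply(best_rank, probe_gene, sum)
  cand <- data.frame(gene = names(votes), votes = as.integer(votes),
                     rank = as.integer(ranks[names(votes)]),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$votes, -cand$rank, cand$gene), , drop = FALSE]
  target_gene <- cand$gene[1L]
  # (3) intermingling probes out
  retained_ids <- specific[probe_gene == target_gene]
  if (length(retained_ids) < min_probes) return(reject("MIN_PROBES"))
  # (4) representative transcript of the target gene
  th <- sh[sh$probe_id %in% retained_ids & sh$gene_id == target_gene, ,
           drop = FALSE]
  tx_votes <- vapply(split(th$probe_id, th$transcript_id),
                     function(p) length(unique(p)), 0L)
  tx <- names(tx_votes)[order(-tx_votes, names(tx_votes))][1L]
  rows <- probeset_rows[match(sort(retained_ids), probeset_rows$probe_id), ,
                        drop = FALSE]
  retained <- data.frame(
    probe_id = rows$probe_id, x = rows$x, y = rows$y,
    tier = unname(.tier_names(best_rank[rows$probe_id])),
    stringsAsFactors = FALSE)
  structure(list(probeset_id = psid, target_gene_id = target_gene,
                 target_transcript_id = tx, retained_probes = retained,
                 n_probe_pairs = nrow(retained)),
            class = "ortholog_probeset")
}

.tier_names <- function(rank) names(.tier_rank)[rank]

#' Run probe selection over a whole probe table
#'
#' @param probe_tab Full probe table ([read_probe_tab()]).
#' @param hits [find_hits()] output for all PM probes of `probe_tab`.
#' @param config,min_probes Passed to [select_probes()].
#' @return List with `kept` (list of `ortholog_probeset`, in probe-set-id
#'   order) and `rejections` (data frame `probeset_id`, `reason`,
#'   `n_probes_in`).
#' @export
select_probes_all <- function(probe_tab, hits, config = match_config(),
                              min_probes = 3L) {
  pm <- probe_tab[probe_tab$role == "PM", , drop = FALSE]
  sets <- split(pm, pm$probeset_id)
  res <- lapply(sets[sort(names(sets))], select_probes, hits = hits,
                config = config, min_probes = min_probes)
  kept <- Filter(function(x) inherits(x, "ortholog_probeset"), res)
  rej <- Filter(function(x) inherits(x, "probeset_rejection"), res)
  rejections <- data.frame(
    probeset_id = vapply(rej, `[[`, "", "probeset_id"),
    reason = vapply(rej, `[[`, "", "reason"),
    n_probes_in = vapply(rej, function(x) as.integer(x$n_probes_in), 0L),
    stringsAsFactors = FALSE)
  rownames(rejections) <- NULL
  list(kept = kept, rejections = rejections)
}

#' Collapse redundant probe sets to one per target gene
#'
#' Several surviving probe sets may interrogate the same target gene. To
#' give the library a strict one probe set / one gene structure, only the
#' probe set with the most retained probes is kept per gene (ties: higher
#' summed tier rank, then smallest probe set id); the rest are recorded as
#' rejections with reason `REDUNDANT`.
#'
#' @param probesets List of `ortholog_probeset` ([select_probes_all()]
#'   `$kept`).
#' @return List with `kept` (one probe set per gene, probe-set-id order) and
#'   `rejections` (data frame as in [select_probes_all()]).
#' @export
collapse_redundancy <- function(probesets) {
  if (length(probesets) == 0L) {
    return(list(kept = list(),
                rejections = data.frame(probeset_id = character(),
                                        reason = character(),
                                        n_probes_in = integer(),
                                        stringsAsFactors = FALSE)))
  }
  tab <- data.frame(
    probeset_id = vapply(probesets, `[[`, "", "probeset_id"),
    gene = vapply(probesets, `[[`, "", "target_gene_id"),
    n = vapply(probesets, function(p) p$n_probe_pairs, 0L),
    rank = vapply(probesets, function(p) sum(.tier_rank[p$retained_probes$tier]),
                  0L),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene, -tab$n, -tab$rank, tab$probeset_id), ,
             drop = FALSE]
  winners <- tab$probeset_id[!duplicated(tab$gene)]
  losers <- setdiff(tab$probeset_id, winners)
  keep <- Filter(function(p) p$probeset_id %in% winners, probesets)
  keep <- keep[order(vapply(keep, `[[`, "", "probeset_id"))]
  n_in <- stats::setNames(tab$n, tab$probeset_id)
  list(kept = keep,
       rejections = data.frame(probeset_id = losers,
                               reason = rep("REDUNDANT", length(losers)),
                               n_probes_in = as.integer(n_in[losers]),
                               stringsAsFactors = FALSE))
}

#' Assemble a cross-species library file
#'
#' Packages one-to-one collapsed probe sets into the "virtual array"
#' library: the mapping from array grid coordinates to orthologous probe
#' sets, plus the provenance needed to reproduce it (matching parameters
#' and a checksum of the cDNA database).
#'
#' @param probesets [collapse_redundancy()] `$kept`.
#' @param name Library name.
#' @param source_array Name of the physical array design the probes come
#'   from.
#' @param target_species Target species of the cDNA database.
#' @param config The [match_config()] used for matching.
#' @param database_checksum Content checksum of the cDNA FASTA (see
#'   [fasta_checksum()]).
#' @param created Timestamp string recorded in the file. Defaults to the
#'   current UTC time; pass a fixed value for byte-reproducible outputs.
#' @return An object of class `oa_library`.
#' @export
build_library <- function(probesets, name = "cross-species-library",
                          source_array = "unknown",
                          target_species = "unknown",
                          config = match_config(),
                          database_checksum = NA_character_,
                          created = NULL) {
  ids <- vapply(probesets, `[[`, "", "probeset_id")
  if (anyDuplicated(ids)) stop("duplicate probeset_id in library input")
  genes <- vapply(probesets, `[[`, "", "target_gene_id")
  if (anyDuplicated(genes)) {
    stop("library input is not one-to-one: gene(s) ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         " appear in multiple probe sets; run collapse_redundancy() first")
  }
  coords <- do.call(rbind, lapply(probesets, function(p)
    p$retained_probes[, c("x", "y")]))
  if (!is.null(coords) && anyDuplicated(coords)) {
    stop("corrupt input: grid coordinate shared between probe sets")
  }
  npp <- vapply(probesets, function(p) as.integer(p$n_probe_pairs), 0L)
  if (any(npp < 3L)) {
    stop("probe set(s) with fewer than 3 probe pairs: ",
         paste(ids[npp < 3L], collapse = ", "))
  }
  if (length(probesets) == 0L) warning("building an empty library")
  probesets <- unname(probesets[order(ids)])
  probesets <- lapply(probesets, function(p) {
    rownames(p$retained_probes) <- NULL
    p
  })
  if (is.null(created)) {
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  structure(list(schema_version = 1L, name = name,
                 source_array = source_array,
                 target_species = target_species,
                 parameters = unclass(config),
                 database_checksum = database_checksum,
                 created = created,
                 probesets = probesets),
            class = "oa_library")
}

#' @export
print.oa_library <- function(x, ...) {
  cat("oa_library '", x$name, "': ", length(x$probesets),
      " probe sets (source ", x$source_array, " -> target ",
      x$target_species, ")\n", sep = "")
  invisible(x)
}

#' Content checksum of a transcript database
#'
#' MD5 of the canonical FASTA serialization of the transcript table, so the
#' same database always yields the same checksum regardless of original
#' file layout.
#'
#' @param transcripts Transcript data frame ([read_fasta()]).
#' @return Hex MD5 string.
#' @export
fasta_checksum <- function(transcripts) {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  write_fasta(transcripts, tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read the canonical library JSON
#'
#' The JSON document is the canonical, schema-versioned library format;
#' [write_cdf_text()] provides an additional CDF-like text export for
#' interoperability.
#'
#' @param library An `oa_library`.
#' @param path Output path.
#' @return `path` invisibly; for `read_library_json`, the `oa_library`.
#' @export
write_library_json <- function(library, path) {
  stopifnot(inherits(library, "oa_library"))
  doc <- unclass(library)
  doc$probesets <- lapply(doc$probesets, function(p) {
    list(probeset_id = p$probeset_id,
         target_gene_id = p$target_gene_id,
         target_transcript_id = p$target_transcript_id,
         n_probe_pairs = p$n_probe_pairs,
         retained_probes = p$retained_probes)
  })
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_library_json
#' @export
read_library_json <- function(path) {
  stopifnot(file.exists(path))
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported library schema version: ", doc$schema_version)
  }
  ps <- doc$probesets
  probesets <- lapply(seq_len(NROW(ps$probeset_id)), function(i) {
    rp <- ps$retained_probes[[i]]
    rp$x <- as.integer(rp$x)
    rp$y <- as.integer(rp$y)
    structure(list(probeset_id = ps$probeset_id[i],
                   target_gene_id = ps$target_gene_id[i],
                   target_transcript_id = ps$target_transcript_id[i],
                   retained_probes = rp,
                   n_probe_pairs = as.integer(ps$n_probe_pairs[i])),
              class = "ortholog_probeset")
  })
  cfg <- doc$parameters
  config <- match_config(cfg$min_tandem, cfg$max_end_mismatch,
                         cfg$rescue_enabled, cfg$rescue_max_end_mismatch,
                         cfg$search_reverse_complement)
  structure(list(schema_version = 1L, name = doc$name,
                 source_array = doc$source_array,
                 target_species = doc$target_species,
                 parameters = unclass(config),
                 database_checksum = if (is.null(doc$database_checksum))
                   NA_character_ else doc$database_checksum,
                 created = doc$created,
                 probesets = probesets),
            class = "oa_library")
}

#' Export a library as CDF-like text
#'
#' Writes one `[Unit...]` block per probe set listing the (x, y) grid
#' coordinates of its retained probes, for interoperability with tools that
#' consume text unit definitions. The JSON document is the canonical
#' format; binary CDF is out of scope.
#'
#' @param library An `oa_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdf_text <- function(library, path) {
  stopifnot(inherits(library, "oa_library"))
  out <- c("[CDF]", "Version=GC-text-1",
           paste0("Name=", library$name), "",
           "[Chip]", paste0("NumberOfUnits=", length(library$probesets)), "")
  for (i in seq_along(library$probesets)) {
    p <- library$probesets[[i]]
    out <- c(out,
             sprintf("[Unit%d]", i),
             paste0("Name=", p$probeset_id),
             paste0("Gene=", p$target_gene_id),
             paste0("NumCells=", p$n_probe_pairs),
             sprintf("Cell%d=%d\t%d\t%s", seq_len(nrow(p$retained_probes)),
                     p$retained_probes$x, p$retained_probes$y,
                     p$retained_probes$probe_id),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Summarize a library build
#'
#' Totals of probe sets kept and rejected per reason, retained probes per
#' tier, and the distribution of probes per set.
#'
#' @param library An `oa_library`.
#' @param rejections Combined rejection data frame (selection + redundancy).
#' @return An object of class `oa_library_summary`.
#' @export
library_summary <- function(library,
                            rejections = data.frame(probeset_id = character(),
                                                    reason = character())) {
  stopifnot(inherits(library, "oa_library"))
  tiers <- unlist(lapply(library$probesets,
                         function(p) p$retained_probes$tier))
  tier_counts <- vapply(names(.tier_rank),
                        function(t) sum(tiers == t), 0L)
  npp <- vapply(library$probesets, function(p) as.integer(p$n_probe_pairs), 0L)
  reasons <- c("NO_HITS", "MULTI_GENE", "MIN_PROBES", "REDUNDANT")
  rej_counts <- vapply(reasons, function(r) sum(rejections$reason == r), 0L)
  structure(list(
    n_kept = length(library$probesets),
    n_rejected = nrow(rejections),
    rejected_by_reason = rej_counts,
    probes_by_tier = tier_counts,
    probes_per_set = if (length(npp)) table(npp) else table(integer()),
    n_probes_retained = sum(npp)
  ), class = "oa_library_summary")
}

#' @export
print.oa_library_summary <- function(x, ...) {
  cat("probe sets kept:     ", x$n_kept, "\n")
  cat("probe sets rejected: ", x$n_rejected, "\n")
  for (r in names(x$rejected_by_reason)) {
    cat(sprintf("  %-11s %d\n", r, x$rejected_by_reason[[r]]))
  }
  cat("retained probes by tier:\n")
  for (t in names(x$probes_by_tier)) {
    cat(sprintf("  %-7s %d\n", t, x$probes_by_tier[[t]]))
  }
  cat("probes per set:\n")
  print(x$probes_per_set)
  invisible(x)
}
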