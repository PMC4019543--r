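#' Configuration for an end-to-end pipeline run
#'
#' Collects the input paths, stage configurations and the master seed for
#' [run_pipeline()]. Stage seeds are derived deterministically from the
#' master seed by stage name, so adding or skipping a stage never shifts
#' another stage's randomness.
#'
#' @param fasta Path to the target-species cDNA FASTA.
#' @param probe_tab Path to the probe table.
#' @param cel Character vector of CEL paths.
#' @param labels Path to a sample metadata TSV with columns `sample_id`
#'   and `class` (0/1).
#' @param gmt Path to a GMT gene-set file.
#' @param out_dir Output directory for all artifacts.
#' @param fc_threshold Absolute fold-change threshold for differential
#'   selection (explicit; no default).
#' @param gene_map Optional transcript/gene TSV path.
#' @param match A [match_config()].
#' @param rma An [rma_config()].
#' @param ann An [ann_config()]; its `seed` is overridden by the derived
#'   stage seed.
#' @param seed Master seed.
#' @param top_k Markers carried into interaction analysis.
#' @param skip_ann Skip the ranking/interaction stages.
#' @param library_name Name recorded in the library file.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta, probe_tab, cel, labels, gmt, out_dir,
                       fc_threshold, gene_map = NULL,
                       match = match_config(), rma = rma_config(),
                       ann = ann_config(), seed = 1L, top_k = 100L,
                       skip_ann = FALSE,
                       library_name = "cross-species-library") {
  paths <- c(fasta = fasta, probe_tab = probe_tab, labels = labels,
             gmt = gmt, cel = cel,
             if (!is.null(gene_map)) c(gene_map = gene_map))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(fc_threshold >= 1, inherits(match, "match_config"),
            inherits(rma, "rma_config"), inherits(ann, "ann_config"))
  structure(list(fasta = fasta, probe_tab = probe_tab, cel = cel,
                 labels = labels, gmt = gmt, gene_map = gene_map,
                 out_dir = out_dir, fc_threshold = fc_threshold,
                 match = match, rma = rma, ann = ann,
                 seed = as.integer(seed), top_k = as.integer(top_k),
                 skip_ann = isTRUE(skip_ann), library_name = library_name),
            class = "run_config")
}

.stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483629)
}

#' Run the full cross-species pipeline
#'
#' Executes match -> library build -> remap -> RMA -> (rank -> interact)
#' -> fold change -> enrichment, writing every stage artifact plus a
#' manifest with content hashes of all inputs and outputs under
#' `config$out_dir`. The run is deterministic: the same configuration and
#' inputs reproduce every output byte-identically (the library's `created`
#' field is content-derived, not wall clock).
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress and the attrition ledger.
#' @return Invisibly, a list with the principal in-memory results
#'   (`library`, `summary`, `expr`, `ranked`, `edges`, `fold_changes`,
#'   `enrichment`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  input_files <- c(config$fasta, config$probe_tab, config$labels,
                   config$gmt, config$cel,
                   if (!is.null(config$gene_map)) config$gene_map)
  input_md5 <- tools::md5sum(input_files)
  names(input_md5) <- basename(input_files)

  say("[match] reading inputs")
  tx <- read_fasta(config$fasta, gene_map = config$gene_map)
  probe_tab <- read_probe_tab(config$probe_tab)
  samples <- utils::read.delim(config$labels, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "class") %in% names(samples)))
  gene_sets <- read_gmt(config$gmt)

  say("[match] matching ", sum(probe_tab$role == "PM"), " PM probes against ",
      nrow(tx), " transcripts")
  index <- build_seed_index(tx, config$match)
  hits <- find_hits(probe_tab, index)
  utils::write.table(hits, out("hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("[build-lib] applying specificity rules")
  sel <- select_probes_all(probe_tab, hits, config$match)
  col <- collapse_redundancy(sel$kept)
  rejections <- rbind(sel$rejections, col$rejections)
  created <- paste0("content:", substr(paste(input_md5, collapse = ""), 1, 12))
  library <- build_library(col$kept, name = config$library_name,
                           source_array = basename(config$probe_tab),
                           target_species = basename(config$fasta),
                           config = config$match,
                           database_checksum = fasta_checksum(tx),
                           created = created)
  summary <- library_summary(library, rejections)
  if (verbose) print(summary)
  write_library_json(library, out("library.json"))
  utils::write.table(rejections, out("rejections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[rma] computing expression estimates for ", length(config$cel),
      " arrays")
  cels <- stats::setNames(lapply(config$cel, read_cel_text),
                          sub("\\.[Cc][Ee][Ll]$", "",
                              basename(config$cel)))
  stopifnot(setequal(names(cels), samples$sample_id))
  cels <- cels[samples$sample_id]
  expr <- rma_pipeline(cels, library, config$rma)
  write_expression_tsv(expr, out("expression.tsv"))

  labels <- stats::setNames(as.integer(samples$class), samples$sample_id)
  ranked <- NULL
  edges <- NULL
  if (!config$skip_ann) {
    say("[rank] ranking ", nrow(expr), " transcripts (",
        config$ann$n_resamples, " resamples)")
    ann <- config$ann
    ann$seed <- .stage_seed(config$seed, "rank")
    ranked <- rank_transcripts(expr, labels, ann)
    utils::write.table(ranked, out("ranked.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    k <- min(config$top_k, nrow(expr))
    say("[interact] interaction matrix over top ", k, " markers")
    ann$seed <- .stage_seed(config$seed, "interact")
    top <- top_ranked(ranked, k)
    imat <- interaction_matrix(expr[top, , drop = FALSE], ann)
    edges <- top_edges(imat, 10L)
    utils::write.table(edges, out("edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(marker = rownames(imat), imat, check.names = FALSE),
      out("interactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("[enrich] fold changes and gene-set enrichment (|FC| >= ",
      config$fc_threshold, ")")
  gene_expr <- expr
  gmap <- stats::setNames(
    vapply(library$probesets, `[[`, "", "target_gene_id"),
    vapply(library$probesets, `[[`, "", "probeset_id"))
  rownames(gene_expr) <- unname(gmap[rownames(expr)])
  fc <- fold_change(gene_expr, labels)
  utils::write.table(fc, out("fold_changes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  background <- sort(rownames(gene_expr))
  foreground <- select_differential(fc, config$fc_threshold)
  enrichment <- enrich_sets(gene_sets, foreground, background)
  utils::write.table(enrichment, out("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  artifacts <- c("hits.tsv", "library.json", "rejections.tsv",
                 "expression.tsv",
                 if (!config$skip_ann) c("ranked.tsv", "edges.tsv",
                                         "interactions.tsv"),
                 "fold_changes.tsv", "enrichment.tsv")
  output_md5 <- tools::md5sum(vapply(artifacts, out, ""))
  names(output_md5) <- artifacts
  manifest <- list(
    package = "orthoarray",
    version = as.character(utils::packageVersion("orthoarray")),
    seed = config$seed,
    fc_threshold = config$fc_threshold,
    top_k = config$top_k,
    skip_ann = config$skip_ann,
    parameters = list(match = unclass(config$match),
                      rma = unclass(config$rma),
                      ann = unclass(config$ann)),
    inputs = as.list(input_md5),
    outputs = as.list(output_md5))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), out("manifest.json"))
  say("[done] ", length(library$probesets), " probe sets; artifacts in ",
      config$out_dir)
  invisible(list(library = library, summary = summary, expr = expr,
                 ranked = ranked, edges = edges, fold_changes = fc,
                 enrichment = enrichment,
                 paths = stats::setNames(
                   vapply(c(artifacts, "manifest.json"), out, ""),
                   c(artifacts, "manifest.json"))))
}
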