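#' Read a transcript FASTA with embedded gene mapping
#'
#' Reads a target-species cDNA database. Each header is expected to carry the
#' transcript accession followed by an optional `gene=<id>` tag
#' (`>t1 gene=G1`). A separate two-column transcript/gene TSV may be supplied
#' instead of, or in addition to, the header tags; on conflict the explicit
#' TSV wins.
#'
#' @param path Path to a FASTA file.
#' @param gene_map Optional path to a two-column TSV (transcript_id, gene_id)
#'   or a data frame with those columns.
#' @return A data frame with columns `transcript_id`, `gene_id`, `sequence`
#'   (uppercase, alphabet A/C/G/T/N), in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 gene=G1", "acgtACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, gene_map = NULL) {
  stopifnot(file.exists(path))
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(dss)
  if (length(dss) == 0L) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", headers)
  genes <- rep(NA_character_, length(headers))
  has_tag <- grepl("(^|\\s)gene=\\S+", headers)
  genes[has_tag] <- sub("^.*\\bgene=(\\S+).*$", "\\1", headers[has_tag])
  seqs <- unname(toupper(as.character(dss)))
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA format error: empty sequence for ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA format error: non-ACGTN characters in ",
         paste(ids[bad], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate transcript_id ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(gene_map)) {
    map <- if (is.data.frame(gene_map)) gene_map else read_gene_map(gene_map)
    idx <- match(ids, map$transcript_id)
    genes[!is.na(idx)] <- map$gene_id[idx[!is.na(idx)]]
  }
  if (anyNA(genes)) {
    stop("missing gene mapping for transcript(s): ",
         paste(ids[is.na(genes)], collapse = ", "),
         " (supply gene= header tags or a gene_map TSV)")
  }
  data.frame(transcript_id = ids, gene_id = genes, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write a transcript FASTA with `gene=` header tags
#'
#' @param transcripts Data frame with `transcript_id`, `gene_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "gene_id", "sequence") %in% names(transcripts)))
  dss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(dss) <- paste0(transcripts$transcript_id, " gene=", transcripts$gene_id)
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read a two-column transcript-to-gene mapping TSV
#'
#' @param path Path to a headerless or headered TSV whose first two columns
#'   are transcript id and gene id. A header row is detected by the literal
#'   column name `transcript_id`.
#' @return Data frame with columns `transcript_id`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  header <- startsWith(lines[1L], "transcript_id")
  if (header) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("gene map format error: fewer than 2 columns at line ",
         which(lengths(parts) < 2L)[1L] + as.integer(header))
  }
  map <- data.frame(transcript_id = vapply(parts, `[[`, "", 1L),
                    gene_id = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$transcript_id)) {
    stop("gene map format error: duplicate transcript_id")
  }
  map
}

#' Write a transcript-to-gene mapping TSV
#' @param map Data frame with `transcript_id`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  writeLines(c("transcript_id\tgene_id",
               paste(map$transcript_id, map$gene_id, sep = "\t")), path)
  invisible(path)
}

.probe_tab_cols <- c("probeset_id", "probe_id", "x", "y",
                     "interrogation_position", "sequence", "role")

#' Read an Affymetrix-style tabular probe file
#'
#' The table must be tab-separated with a header row naming the seven fields
#' `probeset_id`, `probe_id`, `x`, `y`, `interrogation_position`, `sequence`,
#' `role`. Every sequence must be a 25-mer over A/C/G/T; grid coordinates are
#' 0-based and unique per array design; a PM and MM row sharing a `probe_id`
#' form a probe pair and must differ at exactly base 13 (1-based).
#'
#' @param path Path to the probe table.
#' @return Data frame of validated probe rows, in file order.
#' @export
read_probe_tab <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (!all(.probe_tab_cols %in% names(tab))) {
    stop("probe table format error: header must name fields ",
         paste(.probe_tab_cols, collapse = ", "))
  }
  tab <- tab[, .probe_tab_cols]
  tab$x <- as.integer(tab$x)
  tab$y <- as.integer(tab$y)
  tab$interrogation_position <- as.integer(tab$interrogation_position)
  tab$sequence <- toupper(tab$sequence)
  validate_probe_tab(tab)
  tab
}

#' Validate probe-table invariants
#'
#' @param tab Data frame of probe rows (see [read_probe_tab()]).
#' @return `tab`, invisibly, if valid; otherwise an error. Reported line
#'   numbers count the header as line 1.
#' @export
validate_probe_tab <- function(tab) {
  bad_len <- nchar(tab$sequence) != 25L
  if (any(bad_len)) {
    stop("probe table format error: non-25-mer sequence at line ",
         which(bad_len)[1L] + 1L)
  }
  bad_alpha <- grepl("[^ACGT]", tab$sequence)
  if (any(bad_alpha)) {
    stop("probe table format error: non-ACGT sequence at line ",
         which(bad_alpha)[1L] + 1L)
  }
  if (!all(tab$role %in% c("PM", "MM"))) {
    stop("probe table format error: role must be PM or MM at line ",
         which(!tab$role %in% c("PM", "MM"))[1L] + 1L)
  }
  if (any(tab$x < 0L) || any(tab$y < 0L) || anyNA(tab$x) || anyNA(tab$y)) {
    stop("probe table format error: grid coordinates must be non-negative integers")
  }
  coord <- paste(tab$x, tab$y)
  if (anyDuplicated(coord)) {
    stop("probe table validation error: duplicate grid coordinate (x=",
         tab$x[duplicated(coord)][1L], ", y=", tab$y[duplicated(coord)][1L], ")")
  }
  # PM/MM pairing: rows sharing probe_id must differ at base 13 only there
  pm <- tab[tab$role == "PM", ]
  mm <- tab[tab$role == "MM", ]
  shared <- intersect(pm$probe_id, mm$probe_id)
  if (length(shared)) {
    ps <- pm$sequence[match(shared, pm$probe_id)]
    ms <- mm$sequence[match(shared, mm$probe_id)]
    for (i in seq_along(shared)) {
      diffs <- which(strsplit(ps[i], "")[[1L]] != strsplit(ms[i], "")[[1L]])
      if (!identical(diffs, 13L)) {
        stop("probe table validation error: PM/MM pair '", shared[i],
             "' must differ at exactly base 13 (differs at ",
             paste(diffs, collapse = ","), ")")
      }
    }
  }
  invisible(tab)
}

#' Write a tabular probe file
#' @param tab Data frame of probe rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_tab <- function(tab, path) {
  stopifnot(all(.probe_tab_cols %in% names(tab)))
  utils::write.table(tab[, .probe_tab_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a version-3 ASCII CEL file
#'
#' Parses the text (version 3) CEL dialect: a `[CEL]` section with
#' `Version=3`, a `[HEADER]` section carrying the grid dimensions `Cols=` and
#' `Rows=`, and an `[INTENSITY]` section with `NumberCells=` and one
#' whitespace-separated `x y MEAN STDV NPIXELS` line per cell. Binary CEL
#' files (XDA/Calvin) are rejected. Any library name recorded in the header
#' is ignored: intensity data is bound to a library explicitly at analysis
#' time (see [remap_intensities()]).
#'
#' @param path Path to an ASCII CEL file.
#' @return An object of class `oa_cel`: a list with `cols`, `rows`, and
#'   `mean`, a `rows x cols` matrix of cell intensities where `mean[y+1, x+1]`
#'   is the MEAN of the cell at 0-based grid position (x, y).
#' @export
read_cel_text <- function(path) {
  stopifnot(file.exists(path))
  head_raw <- readBin(path, "raw", n = 8L)
  if (length(head_raw) >= 4L && (head_raw[1L] == as.raw(64L) ||
                                 head_raw[1L] == as.raw(59L))) {
    stop("binary CEL files (XDA/Calvin) are not supported; ",
         "export the ASCII version-3 dialect")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  sec_idx <- grep("^\\[.*\\]$", lines)
  if (!length(sec_idx)) stop("CEL format error: no sections found")
  sec_names <- gsub("^\\[|\\]$", "", lines[sec_idx])
  get_section <- function(name) {
    i <- match(name, sec_names)
    if (is.na(i)) stop("CEL format error: missing [", name, "] section")
    from <- sec_idx[i] + 1L
    to <- if (i < length(sec_idx)) sec_idx[i + 1L] - 1L else length(lines)
    if (from > to) character() else lines[from:to]
  }
  kv <- function(sec, key) {
    hit <- grep(paste0("^", key, "="), sec, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  cel_sec <- get_section("CEL")
  if (!identical(kv(cel_sec, "Version"), "3")) {
    stop("CEL format error: [CEL] Version must be 3")
  }
  header <- get_section("HEADER")
  cols <- as.integer(kv(header, "Cols"))
  rows <- as.integer(kv(header, "Rows"))
  if (anyNA(c(cols, rows)) || cols <= 0L || rows <= 0L) {
    stop("CEL format error: [HEADER] must carry positive Cols= and Rows=")
  }
  intens <- get_section("INTENSITY")
  ncells <- as.integer(kv(intens, "NumberCells"))
  if (is.na(ncells)) stop("CEL format error: [INTENSITY] missing NumberCells=")
  if (ncells != cols * rows) {
    stop("CEL format error: NumberCells (", ncells,
         ") != Cols*Rows (", cols * rows, ")")
  }
  data_lines <- intens[!grepl("^(NumberCells|CellHeader)=", intens)]
  data_lines <- trimws(data_lines)
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) != ncells) {
    stop("CEL format error: NumberCells=", ncells, " but ",
         length(data_lines), " cell lines present")
  }
  con <- textConnection(data_lines)
  on.exit(close(con))
  cells <- utils::read.table(con, col.names = c("x", "y", "mean", "stdv",
                                                "npixels"))
  if (any(cells$x < 0L | cells$x >= cols | cells$y < 0L | cells$y >= rows)) {
    stop("CEL format error: cell coordinate outside ", cols, "x", rows, " grid")
  }
  key <- cells$y * cols + cells$x
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("CEL format error: duplicate cell coordinate (x=", cells$x[d],
         ", y=", cells$y[d], ")")
  }
  if (any(cells$mean <= 0)) {
    stop("CEL format error: nonpositive intensity at (x=",
         cells$x[cells$mean <= 0][1L], ", y=", cells$y[cells$mean <= 0][1L],
         "); all intensities must be > 0")
  }
  m <- matrix(NA_real_, nrow = rows, ncol = cols)
  m[cbind(cells$y + 1L, cells$x + 1L)] <- cells$mean
  structure(list(cols = cols, rows = rows, mean = m), class = "oa_cel")
}

#' Write a version-3 ASCII CEL file
#'
#' @param cel An `oa_cel` object ([read_cel_text()]) or a plain matrix of
#'   positive intensities (`mean[y+1, x+1]` convention).
#' @param path Output path.
#' @param sample_name Optional name recorded in the header (advisory only).
#' @return `path`, invisibly.
#' @export
write_cel_text <- function(cel, path, sample_name = NULL) {
  if (is.matrix(cel)) {
    cel <- structure(list(cols = ncol(cel), rows = nrow(cel), mean = cel),
                     class = "oa_cel")
  }
  stopifnot(inherits(cel, "oa_cel"))
  if (any(!is.finite(cel$mean)) || any(cel$mean <= 0)) {
    stop("cannot write CEL: all intensities must be finite and > 0")
  }
  xs <- rep(0:(cel$cols - 1L), times = cel$rows)
  ys <- rep(0:(cel$rows - 1L), each = cel$cols)
  means <- cel$mean[cbind(ys + 1L, xs + 1L)]
  out <- c(
    "[CEL]", "Version=3", "",
    "[HEADER]",
    paste0("Cols=", cel$cols),
    paste0("Rows=", cel$rows),
    if (!is.null(sample_name)) paste0("DatHeader=", sample_name),
    "",
    "[INTENSITY]",
    paste0("NumberCells=", cel$cols * cel$rows),
    "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS",
    sprintf("%d\t%d\t%s\t%s\t%d", xs, ys,
            formatC(means, format = "f", digits = 1), "1.0", 25L)
  )
  writeLines(out, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate members within a set are deduplicated
#' (first-occurrence order kept); lines with no members are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member genes, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    stop("GMT format error: fewer than 3 columns at line ", which(short)[1L])
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("GMT format error: duplicate set name ", nm[duplicated(nm)][1L])
  }
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("GMT format error: set '", nm[empty][1L], "' has no members")
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors; an optional `descriptions`
#'   attribute supplies column 2 (defaults to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Probe sets are rows, samples are columns. Values are written with full
#' (round-trip safe) precision so that `read_expression_tsv(write_...)` is
#' bit-identical.
#'
#' @param mat Numeric matrix with probe-set rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(!is.finite(mat))) {
    stop("cannot write expression matrix: non-finite values present")
  }
  body <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(paste(c("probeset_id", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return For `read_expression_tsv`, the numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(parts[[1L]])
  if (any(lengths(parts) != width)) {
    stop("expression TSV format error: ragged rows (line ",
         which(lengths(parts) != width)[1L], ")")
  }
  samples <- parts[[1L]][-1L]
  body <- parts[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  vals <- vapply(body, function(p) as.numeric(p[-1L]), numeric(width - 1L))
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = width - 1L)
  dimnames(mat) <- list(ids, samples)
  mat
}
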