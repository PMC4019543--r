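#' Bind CEL intensities to a library file
#'
#' The logical replacement for retargeting CEL files at a custom library by
#' editing their headers: intensities and library are paired explicitly at
#' call time, no file is modified, and any library name in the CEL header
#' is ignored. For each library probe set the PM intensities of its
#' retained probes are looked up by grid coordinate in every sample.
#'
#' @param cels Named list of `oa_cel` objects ([read_cel_text()]) or a
#'   character vector of CEL paths (names become sample ids; basenames are
#'   used when unnamed).
#' @param library An `oa_library`.
#' @return Named list (by probe set id, in id order) of
#'   `probeset_intensities` objects: lists with `probeset_id` and `pm`, a
#'   probes x samples matrix with probe ids as rownames and sample ids as
#'   colnames. Values are pure lookups, never transformed.
#' @export
remap_intensities <- function(cels, library) {
  stopifnot(inherits(library, "oa_library"))
  cels <- .load_cels(cels)
  dims <- vapply(cels, function(c) as.integer(c(c$rows, c$cols)), integer(2))
  if (length(cels) > 1L && (length(unique(dims[1L, ])) > 1L ||
                            length(unique(dims[2L, ])) > 1L)) {
    stop("grid mismatch across samples: dimensions ",
         paste(unique(paste0(dims[1L, ], "x", dims[2L, ])), collapse = " vs "))
  }
  rows <- dims[1L, 1L]
  cols <- dims[2L, 1L]
  sample_ids <- names(cels)
  out <- lapply(library$probesets, function(p) {
    rp <- p$retained_probes
    oob <- rp$x < 0L | rp$x >= cols | rp$y < 0L | rp$y >= rows
    if (any(oob)) {
      stop("probe set ", p$probeset_id, ", probe ", rp$probe_id[oob][1L],
           ": coordinate (", rp$x[oob][1L], ",", rp$y[oob][1L],
           ") outside the ", cols, "x", rows, " grid of sample ",
           sample_ids[1L])
    }
    pm <- vapply(cels, function(cel) {
      v <- cel$mean[cbind(rp$y + 1L, rp$x + 1L)]
      if (anyNA(v)) {
        stop("probe set ", p$probeset_id, ", probe ",
             rp$probe_id[is.na(v)][1L], ": no intensity at (",
             rp$x[is.na(v)][1L], ",", rp$y[is.na(v)][1L], ")")
      }
      v
    }, numeric(nrow(rp)))
    pm <- matrix(pm, nrow = nrow(rp),
                 dimnames = list(rp$probe_id, sample_ids))
    structure(list(probeset_id = p$probeset_id, pm = pm),
              class = "probeset_intensities")
  })
  names(out) <- vapply(library$probesets, `[[`, "", "probeset_id")
  out
}

.load_cels <- function(cels) {
  if (is.character(cels)) {
    nm <- names(cels)
    if (is.null(nm)) nm <- sub("\\.[Cc][Ee][Ll]$", "", basename(cels))
    cels <- stats::setNames(lapply(cels, read_cel_text), nm)
  }
  stopifnot(is.list(cels), length(cels) > 0L,
            all(vapply(cels, inherits, TRUE, "oa_cel")))
  if (is.null(names(cels)) || any(!nzchar(names(cels)))) {
    stop("samples must be named")
  }
  cels
}

#' Write remapped PM intensities as a long-format TSV
#'
#' @param remapped [remap_intensities()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pm_long_tsv <- function(remapped, path) {
  rows <- lapply(remapped, function(p) {
    data.frame(probeset_id = p$probeset_id,
               probe_id = rep(rownames(p$pm), ncol(p$pm)),
               sample_id = rep(colnames(p$pm), each = nrow(p$pm)),
               intensity = as.vector(p$pm),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
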