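#' RMA configuration
#'
#' @param background Apply background correction before normalization
#'   (default `TRUE`).
#' @param quantile_norm Apply quantile normalization across arrays
#'   (default `TRUE`). Turning it off leaves each array on its own scale;
#'   useful for noiseless sanity checks, since forcing identical value
#'   distributions is exact only when the groups' distributions genuinely
#'   coincide.
#' @param mp_max_iter Maximum median-polish sweep iterations (default 10).
#' @param mp_tol Median-polish convergence tolerance: sweeps stop when the
#'   absolute change in the total absolute residual falls below this value
#'   (default 0.01, log2 units).
#' @param density_bandwidth_rule Bandwidth rule for the kernel density used
#'   to locate the intensity mode during background parameter estimation
#'   (any rule accepted by [stats::density()]'s `bw`; default `"nrd0"`).
#' @return An object of class `rma_config`.
#' @export
rma_config <- function(background = TRUE, quantile_norm = TRUE,
                       mp_max_iter = 10L, mp_tol = 0.01,
                       density_bandwidth_rule = "nrd0") {
  mp_max_iter <- as.integer(mp_max_iter)
  stopifnot(mp_max_iter >= 1L, mp_tol > 0, is.character(density_bandwidth_rule))
  structure(list(background = isTRUE(background),
                 quantile_norm = isTRUE(quantile_norm),
                 mp_max_iter = mp_max_iter, mp_tol = mp_tol,
                 density_bandwidth_rule = density_bandwidth_rule),
            class = "rma_config")
}

#' Estimate background model parameters for one array
#'
#' Observed PM intensities are modelled as signal + noise with the signal
#' exponential (rate 1/alpha) and the noise normal (mu, sigma). The
#' estimators are intentionally simple and fixed: mu is the mode of a
#' kernel density of the intensities; sigma is the spread of the sub-mode
#' half of the data (root mean square deviation below the mode, scaled by
#' sqrt(2) since only the lower half-distribution is seen); alpha is the
#' mean excess of the supra-mode intensities over the mode.
#'
#' @param x Positive intensities of one array.
#' @param bw Bandwidth rule for [stats::density()].
#' @return List with `mu`, `sigma`, `alpha`.
#' @export
normexp_params <- function(x, bw = "nrd0") {
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  d <- stats::density(x, bw = bw, n = 2048L)
  mu <- d$x[which.max(d$y)]
  below <- x[x < mu]
  if (length(below) < 2L) below <- x
  sigma <- sqrt(sum((below - mu)^2) / (length(below) - 1L)) * sqrt(2)
  above <- x[x > mu]
  alpha <- if (length(above)) mean(above - mu) else mean(abs(x - mu))
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(x)
  if (!is.finite(alpha) || alpha <= 0) alpha <- sigma
  list(mu = mu, sigma = sigma, alpha = alpha)
}

#' Posterior expected signal under the exponential + normal model
#'
#' Given observed intensity x = s + b with s ~ Exp(1/alpha) and
#' b ~ N(mu, sigma^2), the posterior of s given x is a normal truncated to
#' s > 0, and E(s | x) = mu_sf + sigma * phi(mu_sf/sigma) / Phi(mu_sf/sigma)
#' with mu_sf = x - mu - sigma^2/alpha. The Mills ratio is evaluated in log
#' space so deep-background intensities stay finite and strictly positive.
#'
#' @param x Observed intensities.
#' @param params List with `mu`, `sigma`, `alpha` ([normexp_params()]).
#' @return Corrected intensities, strictly positive, same length as `x`.
#' @export
normexp_signal <- function(x, params) {
  mu_sf <- x - params$mu - params$sigma^2 / params$alpha
  z <- mu_sf / params$sigma
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- mu_sf + params$sigma * mills
  pmax(out, .Machine$double.eps)
}

#' Background-correct one array's intensities
#'
#' @param x Positive intensities of one array.
#' @param config An [rma_config()].
#' @param reference Intensities used to estimate the background parameters
#'   (defaults to `x` itself). Passing the full grid's cells while
#'   correcting only the analysis probes gives the estimators a genuine
#'   background population, as whole-chip RMA implementations do.
#' @return Corrected intensities (strictly positive). A constant column
#'   cannot support the model; it falls back to subtracting the minimum and
#'   adding machine epsilon, with a warning.
#' @export
background_correct <- function(x, config = rma_config(), reference = x) {
  stopifnot(all(x > 0))
  if (length(unique(reference)) == 1L) {
    warning("constant intensity column: background model degenerate, ",
            "falling back to min-subtraction")
    return(x - min(x) + .Machine$double.eps)
  }
  p <- normexp_params(reference, bw = config$density_bandwidth_rule)
  normexp_signal(x, p)
}

#' Quantile-normalize the columns of a matrix
#'
#' Each column's sorted values are replaced by the row-wise mean of all
#' columns' sorted values, preserving within-column ranks. Ties within a
#' column all receive the mean of the reference quantiles they span.
#'
#' @param mat Numeric matrix (features x samples), at least 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) {
    warning("quantile normalization of a single column is the identity")
    return(mat)
  }
  ref <- rowMeans(apply(mat, 2L, sort, method = "radix"))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j], method = "radix")
    q <- numeric(nrow(mat))
    q[o] <- ref
    # ties share the mean of the quantile values they span
    out[, j] <- stats::ave(q, match(mat[, j], mat[, j]), FUN = mean)
  }
  out
}

#' Median polish of a probes x samples matrix
#'
#' Fits the additive model value = overall + probe + sample by alternately
#' sweeping row and column medians until the total absolute residual
#' changes by less than `tol` between sweeps, or `max_iter` sweeps are
#' reached. The per-sample expression estimates are overall + column
#' effects (the RMA summarization convention; probe effects absorb probe
#' affinity).
#'
#' @param mat Numeric matrix, probes as rows, samples as columns.
#' @param max_iter Maximum sweep iterations.
#' @param tol Convergence tolerance on the total absolute residual change.
#' @return List with `overall`, `row` (probe effects), `col` (sample
#'   effects), `residuals`, `estimates` (= overall + col, named by sample),
#'   `iterations`, `converged`.
#' @export
median_polish <- function(mat, max_iter = 10L, tol = 0.01) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L,
            all(is.finite(mat)))
  z <- mat
  r <- numeric(nrow(mat))
  c_eff <- numeric(ncol(mat))
  t_eff <- 0
  oldsum <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1L, stats::median)
    z <- z - rdelta
    r <- r + rdelta
    delta <- stats::median(c_eff)
    c_eff <- c_eff - delta
    t_eff <- t_eff + delta
    cdelta <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cdelta)
    c_eff <- c_eff + cdelta
    delta <- stats::median(r)
    r <- r - delta
    t_eff <- t_eff + delta
    newsum <- sum(abs(z))
    if (abs(newsum - oldsum) < tol) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  estimates <- t_eff + c_eff
  names(estimates) <- colnames(mat)
  list(overall = t_eff, row = r, col = c_eff, residuals = z,
       estimates = estimates, iterations = iter, converged = converged)
}

#' Full RMA pipeline against a library file
#'
#' Background-corrects each array, quantile-normalizes across arrays over
#' the union of the library's PM probes (or the whole grid with
#' `whole_chip = TRUE`), log2-transforms, and median-polishes each probe
#' set, yielding one log2 expression estimate per probe set and sample.
#'
#' @param cels Named list of `oa_cel` objects or character vector of CEL
#'   paths.
#' @param library An `oa_library`.
#' @param config An [rma_config()].
#' @param whole_chip Normalize over every grid cell rather than only the
#'   library's probes (default `FALSE`: the virtual library is the analysis
#'   unit).
#' @return Numeric matrix (probe sets x samples) of log2 expression
#'   estimates.
#' @export
rma_pipeline <- function(cels, library, config = rma_config(),
                         whole_chip = FALSE) {
  stopifnot(inherits(library, "oa_library"), inherits(config, "rma_config"))
  cels <- .load_cels(cels)
  remapped <- remap_intensities(cels, library)
  if (length(remapped) == 0L) {
    stop("library contains no probe sets")
  }
  sample_ids <- names(cels)
  # probe x sample matrix over the normalization universe
  if (whole_chip) {
    pm_all <- vapply(cels, function(cel) as.vector(cel$mean),
                     numeric(length(cels[[1L]]$mean)))
    probe_key <- paste0("cell", seq_len(nrow(pm_all)))
    cel1 <- cels[[1L]]
    xs <- rep(0:(cel1$cols - 1L), each = cel1$rows)
    ys <- rep(0:(cel1$rows - 1L), times = cel1$cols)
    key_of <- function(x, y) match(paste(x, y), paste(xs, ys))
  } else {
    pm_all <- do.call(rbind, lapply(remapped, `[[`, "pm"))
    probe_key <- unlist(lapply(remapped, function(p)
      paste0(p$probeset_id, ":", rownames(p$pm))), use.names = FALSE)
  }
  pm_all <- matrix(pm_all, ncol = length(sample_ids),
                   dimnames = list(probe_key, sample_ids))
  if (config$background) {
    for (j in seq_len(ncol(pm_all))) {
      # parameters from the whole grid (which carries the background
      # population); correction applied to the analysis probes
      pm_all[, j] <- background_correct(pm_all[, j], config,
                                        reference = as.vector(cels[[j]]$mean))
    }
  }
  if (config$quantile_norm && ncol(pm_all) >= 2L) {
    pm_all <- quantile_normalize(pm_all)
  }
  log_pm <- log2(pm_all)
  est <- vapply(remapped, function(p) {
    if (whole_chip) {
      lib_ps <- Filter(function(q) q$probeset_id == p$probeset_id,
                       library$probesets)[[1L]]
      idx <- key_of(lib_ps$retained_probes$x, lib_ps$retained_probes$y)
    } else {
      idx <- match(paste0(p$probeset_id, ":", rownames(p$pm)), probe_key)
    }
    m <- log_pm[idx, , drop = FALSE]
    median_polish(m, max_iter = config$mp_max_iter,
                  tol = config$mp_tol)$estimates
  }, numeric(length(sample_ids)))
  expr <- t(est)
  dimnames(expr) <- list(names(remapped), sample_ids)
  expr
}
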