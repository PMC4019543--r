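#' Configuration for ANN-based transcript ranking
#'
#' Each transcript is scored by training small feed-forward classifiers
#' (one input, `hidden_units` sigmoid hidden units, one sigmoid output)
#' that predict the 0/1 treatment class from that transcript alone, under
#' repeated random 60/20/20 train/validation/test splits ("random sample
#' cross-validation"). The transcript's score is its mean squared test
#' error across resamples; lower is more predictive.
#'
#' @param hidden_units Hidden layer size (default 2).
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param momentum Momentum coefficient (default 0.9).
#' @param patience Early-stopping patience: training stops once the
#'   validation error has not improved for this many cycles (default 25).
#' @param max_cycles Hard cap on training cycles (default 300).
#' @param n_resamples Number of random-sample cross-validation repetitions
#'   per transcript (default 50).
#' @param split Named fractions for train/validation/test; must sum to 1
#'   (default 0.6/0.2/0.2).
#' @param top_k Number of top-ranked transcripts selected for interaction
#'   analysis (default 100).
#' @param seed Master seed; per-(transcript, resample) streams are derived
#'   from it so rankings are reproducible and independent of evaluation
#'   order.
#' @param early_stop `"decrease"` (default) stops when the validation error
#'   stops decreasing; `"increase"` implements the alternative reading that
#'   waits for it to stop increasing.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden_units = 2L, learning_rate = 0.1,
                       momentum = 0.9, patience = 25L, max_cycles = 300L,
                       n_resamples = 50L,
                       split = c(train = 0.6, validation = 0.2, test = 0.2),
                       top_k = 100L, seed = 1L,
                       early_stop = c("decrease", "increase")) {
  early_stop <- match.arg(early_stop)
  stopifnot(hidden_units >= 1L, learning_rate > 0, momentum >= 0,
            momentum < 1, patience >= 1L, max_cycles >= 1L,
            n_resamples >= 1L, length(split) == 3L,
            abs(sum(split) - 1) < 1e-9, all(split > 0), top_k >= 1L)
  if (is.null(names(split))) names(split) <- c("train", "validation", "test")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, momentum = momentum,
                 patience = as.integer(patience),
                 max_cycles = as.integer(max_cycles),
                 n_resamples = as.integer(n_resamples), split = split,
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 early_stop = early_stop),
            class = "ann_config")
}

# Largest-remainder apportionment of `total` into parts proportional to
# `props` (ties by listed order).
largest_remainder <- function(total, props) {
  quota <- total * props / sum(props)
  base <- floor(quota)
  seats <- total - sum(base)
  if (seats > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(seats)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified random train/validation/test split
#'
#' Splits samples into disjoint train/validation/test subsets, stratified
#' by class, with subset sizes fixed by largest-remainder rounding of the
#' fractions within each class. If a class ends up absent from the training
#' subset the split is redrawn (bounded retries), then errors.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels 0/1 class labels, parallel to `sample_ids` (or named by
#'   them).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed; the same seed always produces the same split.
#' @return List with `train`, `validation`, `test` character vectors
#'   covering `sample_ids` disjointly.
#' @export
split_data <- function(sample_ids, labels,
                       fractions = c(train = 0.6, validation = 0.2,
                                     test = 0.2),
                       seed = 1L) {
  labels <- .check_labels(sample_ids, labels)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  codes <- .split_codes(labels, fractions, seed)
  list(train = sample_ids[codes == 0L],
       validation = sample_ids[codes == 1L],
       test = sample_ids[codes == 2L])
}

.check_labels <- function(sample_ids, labels) {
  if (!is.null(names(labels))) labels <- labels[sample_ids]
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(sample_ids),
            all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

# Subset codes 0 train / 1 validation / 2 test, stratified by class.
.split_codes <- function(labels, fractions, seed, max_retry = 100L) {
  n <- length(labels)
  set.seed(seed)
  for (attempt in seq_len(max_retry)) {
    codes <- integer(n)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      sizes <- largest_remainder(length(idx), fractions)
      perm <- sample(idx)
      codes[perm] <- rep(c(0L, 1L, 2L), times = sizes)
    }
    train_classes <- unique(labels[codes == 0L])
    if (length(train_classes) == 2L && all(0:2 %in% codes)) return(codes)
  }
  stop("could not produce a split with both classes in training after ",
       max_retry, " attempts; too few samples per class")
}

.n_weights <- function(hidden, inputs = 1L) {
  hidden * inputs + hidden + hidden + 1L
}

# Deterministic per-(transcript, resample) stream seed below 2^31.
.stream_seed <- function(master, t_index, r_index) {
  as.integer((as.numeric(master) * 7919 + t_index * 104729 + r_index * 131) %%
               2147483629)
}

#' Train and evaluate one single-transcript classifier
#'
#' Min-max scales the transcript's expression using the training subset,
#' trains a 1-input sigmoid network on the 0/1 class labels with momentum
#' gradient descent, early-stops on the validation subset, and reports the
#' squared error on the test subset at the best-validation snapshot.
#'
#' @param expr_row Numeric vector of one transcript's expression, named by
#'   sample id (or parallel to `splits`' sample ids).
#' @param labels 0/1 labels named by sample id.
#' @param splits A [split_data()] result.
#' @param config An [ann_config()].
#' @return List with `test_error`, `validation_trace` (per-cycle validation
#'   error), `cycles`, `failed`.
#' @export
train_single_input_net <- function(expr_row, labels, splits,
                                   config = ann_config()) {
  sample_ids <- c(splits$train, splits$validation, splits$test)
  if (!is.null(names(expr_row))) expr_row <- expr_row[sample_ids]
  labels <- labels[sample_ids]
  codes <- rep(c(0L, 1L, 2L),
               times = c(length(splits$train), length(splits$validation),
                         length(splits$test)))
  set.seed(config$seed)
  w0 <- stats::rnorm(.n_weights(config$hidden_units), sd = 0.5)
  res <- cpp_train_single(as.numeric(expr_row), as.numeric(labels), codes,
                          w0, config$hidden_units, config$learning_rate,
                          config$momentum, config$patience,
                          config$max_cycles,
                          config$early_stop == "increase")
  res
}

#' Rank transcripts by predictive error under random-sample cross-validation
#'
#' For every transcript, trains `n_resamples` independent single-input
#' classifiers (fresh stratified split and fresh initial weights per
#' resample, both derived deterministically from the master seed and the
#' transcript's row index) and averages the test errors. Transcripts are
#' ranked by ascending mean test error; ties break by standard deviation,
#' then id. Resamples whose training diverges (non-finite loss) are
#' excluded from the mean and counted in `n_failed`.
#'
#' @param expr Numeric matrix, transcripts x samples, with transcript ids
#'   as rownames and sample ids as colnames.
#' @param labels 0/1 labels named by (or parallel to) the columns of
#'   `expr`; both classes must have at least 2 samples.
#' @param config An [ann_config()].
#' @return Data frame of class `ranked_list`: `probeset_id`,
#'   `mean_test_error`, `sd_test_error`, `n_failed`, `rank`, ascending by
#'   error.
#' @export
rank_transcripts <- function(expr, labels, config = ann_config()) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  labels <- .check_labels(colnames(expr), labels)
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  tn <- nrow(expr)
  rs <- config$n_resamples
  n <- ncol(expr)
  codes <- matrix(0L, nrow = tn * rs, ncol = n)
  w0 <- matrix(0, nrow = tn * rs, ncol = .n_weights(config$hidden_units))
  for (t in seq_len(tn)) {
    for (r in seq_len(rs)) {
      row <- (t - 1L) * rs + r
      sd_seed <- .stream_seed(config$seed, t, r)
      codes[row, ] <- .split_codes(labels, config$split, sd_seed)
      w0[row, ] <- stats::rnorm(.n_weights(config$hidden_units), sd = 0.5)
    }
  }
  errs <- cpp_rank_nets(expr, as.numeric(labels), codes, w0, rs,
                        config$hidden_units, config$learning_rate,
                        config$momentum, config$patience, config$max_cycles,
                        config$early_stop == "increase")
  em <- matrix(errs, nrow = rs)  # resample x transcript
  mean_err <- colMeans(em, na.rm = TRUE)
  sd_err <- apply(em, 2L, stats::sd, na.rm = TRUE)
  n_failed <- colSums(is.na(em))
  out <- data.frame(probeset_id = rownames(expr),
                    mean_test_error = mean_err,
                    sd_test_error = sd_err,
                    n_failed = as.integer(n_failed),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_test_error, out$sd_test_error,
                   out$probeset_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Select the top-k transcripts of a ranked list
#'
#' @param ranked A [rank_transcripts()] result.
#' @param k Number of transcripts (defaults to 100).
#' @return Character vector of transcript ids, best first.
#' @export
top_ranked <- function(ranked, k = 100L) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::head(ranked$probeset_id, k)
}

#' Signed marker-interaction matrix
#'
#' For each top-ranked marker j, a network predicting j's (min-max scaled)
#' expression from the remaining markers is trained on all samples; the
#' influence of marker i on marker j is the mean over samples of the
#' signed partial derivative of the network output with respect to input
#' i. Constant markers carry no information: their rows and columns are
#' zeroed with a warning.
#'
#' @param expr_topk Numeric matrix, markers x samples (rownames = marker
#'   ids), typically the top-k rows of the expression matrix in ranked
#'   order.
#' @param config An [ann_config()]; `learning_rate`, `momentum`,
#'   `hidden_units`, `max_cycles` and `seed` are used.
#' @return Square numeric matrix of class `interaction_matrix`; entry
#'   (i, j) is the influence of marker i on predicted marker j; the
#'   diagonal is zero.
#' @export
interaction_matrix <- function(expr_topk, config = ann_config()) {
  stopifnot(is.matrix(expr_topk), !is.null(rownames(expr_topk)),
            nrow(expr_topk) >= 2L)
  k <- nrow(expr_topk)
  rng <- apply(expr_topk, 1L, range)
  const <- rng[1L, ] == rng[2L, ]
  scaled <- expr_topk
  for (i in seq_len(k)) {
    if (const[i]) {
      scaled[i, ] <- 0.5
    } else {
      scaled[i, ] <- (expr_topk[i, ] - rng[1L, i]) /
        (rng[2L, i] - rng[1L, i])
    }
  }
  if (all(const)) {
    warning("all markers constant: zero interaction matrix")
    m <- matrix(0, k, k, dimnames = list(rownames(expr_topk),
                                         rownames(expr_topk)))
    class(m) <- c("interaction_matrix", class(m))
    return(m)
  }
  if (any(const)) {
    warning("constant marker(s) ",
            paste(rownames(expr_topk)[const], collapse = ", "),
            ": their interactions are recorded as zero")
  }
  m <- matrix(0, k, k, dimnames = list(rownames(expr_topk),
                                       rownames(expr_topk)))
  nw <- .n_weights(config$hidden_units, inputs = k - 1L)
  for (j in seq_len(k)) {
    if (const[j]) next
    set.seed(.stream_seed(config$seed, j, 0L))
    w0 <- stats::rnorm(nw, sd = 0.5)
    m[, j] <- cpp_influence(scaled, j - 1L, w0, config$hidden_units,
                            config$learning_rate, config$momentum,
                            config$max_cycles)
  }
  m[const, ] <- 0
  m[, const] <- 0
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' Strongest positive and negative marker interactions
#'
#' @param imatrix An [interaction_matrix()] result.
#' @param n Number of edges of each sign (default 10).
#' @return Data frame `from`, `to`, `influence`, `sign`, strongest first
#'   within each sign (positive edges first).
#' @export
top_edges <- function(imatrix, n = 10L) {
  stopifnot(inherits(imatrix, "interaction_matrix"))
  k <- nrow(imatrix)
  off <- which(row(imatrix) != col(imatrix))
  df <- data.frame(
    from = rownames(imatrix)[row(imatrix)[off]],
    to = colnames(imatrix)[col(imatrix)[off]],
    influence = imatrix[off],
    stringsAsFactors = FALSE)
  pos <- df[df$influence > 0, , drop = FALSE]
  neg <- df[df$influence < 0, , drop = FALSE]
  pos <- utils::head(pos[order(-pos$influence, pos$from, pos$to), ], n)
  neg <- utils::head(neg[order(neg$influence, neg$from, neg$to), ], n)
  pos$sign <- if (nrow(pos)) "positive" else character()
  neg$sign <- if (nrow(neg)) "negative" else character()
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}
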