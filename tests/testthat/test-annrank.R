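test_that("splits are stratified, exact-sized, and seed-reproducible", {
  ids <- sprintf("S%02d", 1:10)
  labels <- stats::setNames(rep(c(0L, 1L), each = 5), ids)
  sp <- split_data(ids, labels, seed = 4)
  expect_equal(lengths(sp), c(train = 6L, validation = 2L, test = 2L))
  expect_setequal(unlist(sp), ids)
  expect_true(all(table(labels[sp$train]) >= 1))
  expect_identical(split_data(ids, labels, seed = 4), sp)
  expect_false(identical(split_data(ids, labels, seed = 5), sp))

  # sizes are a deterministic function of the fractions (largest remainder),
  # for every seed
  for (seed in 1:25) {
    sp2 <- split_data(ids, labels, seed = seed)
    expect_equal(lengths(sp2), c(train = 6L, validation = 2L, test = 2L))
  }
  # 18-sample two-dose design: 6 control / 12 treated
  ids18 <- sprintf("S%02d", 1:18)
  lab18 <- stats::setNames(rep(c(0L, 1L), c(6, 12)), ids18)
  sp18 <- split_data(ids18, lab18, seed = 1)
  expect_equal(sum(lengths(sp18)), 18L)
  # largest remainder per class: controls 4/1/1, treated 7/3/2
  expect_equal(length(sp18$train), 11L)
  expect_equal(table(lab18[sp18$train])[["0"]], 4L)
})

test_that("single-transcript nets separate signal from noise", {
  set.seed(31)
  ids <- sprintf("S%02d", 1:18)
  labels <- stats::setNames(rep(c(0L, 1L), c(6, 12)), ids)
  sp <- split_data(ids, labels, seed = 2)
  cfg <- ann_config(seed = 9)

  strong <- stats::setNames(rnorm(18, 0, 0.05) + 3 * labels, ids)
  res <- train_single_input_net(strong, labels, sp, cfg)
  expect_false(res$failed)
  expect_lte(res$test_error, 0.05)
  expect_true(length(res$validation_trace) >= 1)

  flat <- stats::setNames(rep(1.0, 18), ids)
  res0 <- train_single_input_net(flat, labels, sp, cfg)
  # no information: error comparable to predicting the class prior
  prior <- mean(labels[sp$train])
  base <- mean((labels[sp$test] - prior)^2)
  expect_lte(res0$test_error, base + 0.15)
  expect_gte(res0$test_error, base - 0.15)

  # identical inputs, identical seeds -> identical results
  res2 <- train_single_input_net(strong, labels, sp, cfg)
  expect_identical(res, res2)
})

test_that("ranking recovers planted informative transcripts", {
  fx <- simulate_ranking_matrix(n_transcripts = 300, n_per_class = 9,
                                n_informative = 8, shift = 2, seed = 5)
  cfg <- ann_config(seed = 17, n_resamples = 15)
  rk <- rank_transcripts(fx$expr, fx$labels, cfg)
  expect_equal(sort(rk$probeset_id), sort(rownames(fx$expr)))
  expect_false(is.unsorted(rk$mean_test_error))
  top <- top_ranked(rk, 30)
  expect_gte(sum(fx$informative %in% top), 7)
  # determinism under the fixed master seed
  rk2 <- rank_transcripts(fx$expr, fx$labels, cfg)
  expect_identical(rk, rk2)
  # top_k == n yields a permutation of all ids
  expect_setequal(top_ranked(rk, nrow(fx$expr)), rownames(fx$expr))
})

test_that("appending noise transcripts never disturbs existing streams", {
  fx <- simulate_ranking_matrix(n_transcripts = 60, n_per_class = 6,
                                n_informative = 5, seed = 8)
  cfg <- ann_config(seed = 21, n_resamples = 8)
  rk_small <- rank_transcripts(fx$expr, fx$labels, cfg)
  set.seed(99)
  extra <- matrix(rnorm(20 * ncol(fx$expr)), nrow = 20,
                  dimnames = list(sprintf("X%03d", 1:20),
                                  colnames(fx$expr)))
  rk_big <- rank_transcripts(rbind(fx$expr, extra), fx$labels, cfg)
  m <- match(rk_small$probeset_id, rk_big$probeset_id)
  expect_equal(rk_big$mean_test_error[m], rk_small$mean_test_error)
})

test_that("planted linear dependency dominates the interaction matrix", {
  set.seed(5)
  n <- 18; k <- 15
  expr <- matrix(rnorm(k * n), nrow = k,
                 dimnames = list(sprintf("M%02d", 1:k),
                                 sprintf("S%02d", 1:n)))
  expr[2, ] <- 0.8 * expr[1, ] + rnorm(n, 0, 0.2)
  im <- interaction_matrix(expr, ann_config(seed = 3, max_cycles = 500))
  expect_equal(dim(im), c(k, k))
  expect_true(all(diag(im) == 0))
  into2 <- im[-2, "M02"]
  expect_gt(im["M01", "M02"], 0)
  expect_equal(names(which.max(into2)), "M01")
  # determinism
  im2 <- interaction_matrix(expr, ann_config(seed = 3, max_cycles = 500))
  expect_identical(im, im2)
})

test_that("independent markers give near-zero centred influences", {
  set.seed(6)
  expr <- matrix(rnorm(15 * 18), nrow = 15,
                 dimnames = list(sprintf("M%02d", 1:15),
                                 sprintf("S%02d", 1:18)))
  im <- interaction_matrix(expr, ann_config(seed = 4, max_cycles = 500))
  off <- im[row(im) != col(im)]
  expect_lt(abs(median(off)), 0.05)
})

test_that("constant markers are zeroed with a warning", {
  set.seed(7)
  expr <- matrix(rnorm(5 * 12), nrow = 5,
                 dimnames = list(sprintf("M%02d", 1:5),
                                 sprintf("S%02d", 1:12)))
  expr[3, ] <- 2
  expect_warning(im <- interaction_matrix(expr, ann_config(seed = 2)),
                 "constant marker")
  expect_true(all(im[3, ] == 0) && all(im[, 3] == 0))

  allc <- matrix(1, nrow = 3, ncol = 6,
                 dimnames = list(c("a", "b", "c"), sprintf("S%d", 1:6)))
  expect_warning(im0 <- interaction_matrix(allc, ann_config(seed = 2)),
                 "all markers constant")
  expect_true(all(im0 == 0))
})

test_that("strongest edges are extracted with sign labels", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[1, 2] <- 0.9; m[2, 3] <- 0.5; m[3, 1] <- -0.7; m[4, 1] <- -0.1
  class(m) <- c("interaction_matrix", class(m))
  e <- top_edges(m, n = 2)
  expect_equal(e$from[1:2], c("a", "b"))
  expect_equal(e$sign, c("positive", "positive", "negative", "negative"))
  expect_equal(e$influence[3], -0.7)
})
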