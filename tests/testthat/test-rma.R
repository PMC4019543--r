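test_that("background correction is positive, monotone, matches quadrature", {
  set.seed(41)
  x <- rexp(2000, 1 / 300) + rnorm(2000, 60, 15)
  x <- x[x > 0]
  y <- background_correct(x)
  expect_true(all(y > 0))
  o <- order(x)
  expect_true(all(diff(y[o]) >= -1e-12))

  # posterior mean against rescaled numerical integration
  set.seed(42)
  for (i in 1:200) {
    mu <- runif(1, 20, 150)
    sigma <- runif(1, 5, 50)
    alpha <- runif(1, 20, 600)
    xx <- runif(1, 1, 1500)
    est <- normexp_signal(xx, list(mu = mu, sigma = sigma, alpha = alpha))
    ref <- normexp_quadrature(xx, mu, sigma, alpha)
    expect_lt(abs(est - ref), 1e-6)
  }

  expect_warning(background_correct(rep(5, 10)), "constant")
})

test_that("quantile normalization matches its definition and the tie rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  same <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(same), same)

  ties <- cbind(c(1, 1, 2), c(3, 5, 7))
  qn <- quantile_normalize(ties)
  # reference quantiles are (2, 3, 4.5); tied entries share mean(2, 3)
  expect_equal(unname(qn[, 1]), c(2.5, 2.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2, 3, 4.5))

  set.seed(7)
  big <- matrix(rexp(400 * 5, 1 / 50), ncol = 5)
  qb <- quantile_normalize(big)
  # identical multiset in every column
  sorted <- apply(qb, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) == 0))
  # within-column ranks preserved
  expect_equal(apply(qb, 2, rank), apply(big, 2, rank))
  # agreement with the reference implementation in limma
  expect_equal(qb, limma::normalizeQuantiles(big, ties = TRUE),
               tolerance = 1e-12)

  expect_warning(one <- quantile_normalize(big[, 1, drop = FALSE]),
                 "single column")
  expect_equal(one, big[, 1, drop = FALSE])
})

test_that("median polish handles additive and degenerate inputs", {
  r <- c(1, 4, -2)
  cc <- c(0, 2, 5, 7)
  add <- outer(r, cc, `+`) + 3
  mp <- median_polish(add, max_iter = 10, tol = 1e-9)
  expect_equal(max(abs(mp$residuals)), 0)
  expect_equal(unname(mp$estimates - mp$estimates[1]), cc - cc[1])

  one <- matrix(c(1.5, 2.5, 9), nrow = 1)
  expect_equal(unname(median_polish(one)$estimates), c(1.5, 2.5, 9))
})

test_that("median polish matches the independent reference implementation", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    x <- matrix(rnorm(11 * 18, sd = 2), 11, 18)
    mine <- median_polish(x, max_iter = 200, tol = 1e-10)
    ref <- stats::medpolish(x, eps = 1e-12, maxiter = 200,
                            trace.iter = FALSE)
    worst <- max(worst, max(abs((mine$overall + mine$col) -
                                  (ref$overall + ref$col))))
  }
  expect_lt(worst, 1e-8)
})

test_that("residual row/column medians vanish at convergence", {
  set.seed(23)
  x <- matrix(rnorm(9 * 6), 9, 6)
  mp <- median_polish(x, max_iter = 100, tol = 1e-8)
  expect_true(all(abs(apply(mp$residuals, 1, median)) <= 1e-8))
  expect_true(all(abs(apply(mp$residuals, 2, median)) <= 1e-8))
})

test_that("pipeline symmetry: duplicated and permuted samples behave", {
  s <- identity_setup(n_samples = 3)
  cels <- s$cels
  cels[["s02"]] <- cels[["s01"]]
  expr <- rma_pipeline(cels, s$library)
  expect_equal(expr[, "s01"], expr[, "s02"])

  perm <- c(2, 3, 1)
  e1 <- rma_pipeline(s$cels, s$library)
  e2 <- rma_pipeline(s$cels[perm], s$library)
  expect_identical(e2, e1[, perm])
})

test_that("identity-library pipeline equals whole-chip pipeline exactly", {
  s <- identity_setup(n_sets = 4, probes_per_set = 5, n_samples = 4)
  e_lib <- rma_pipeline(s$cels, s$library)
  e_chip <- rma_pipeline(s$cels, s$library, whole_chip = TRUE)
  expect_identical(e_lib, e_chip)
})

test_that("pipeline is scale-aware when background is off", {
  s <- identity_setup(n_samples = 3)
  cfg <- rma_config(background = FALSE)
  e1 <- rma_pipeline(s$cels, s$library, cfg)
  cels2 <- lapply(s$cels, function(c) { c$mean <- c$mean * 8; c })
  e2 <- rma_pipeline(cels2, s$library, cfg)
  expect_equal(e2, e1 + 3, tolerance = 1e-12)
})

test_that("planted fold changes are recovered through the full pipeline", {
  fx <- simulate_fixture(fixture_spec(seed = 11))
  res <- fixture_library(fx)
  expr <- rma_pipeline(fx$intensities$cels, res$library)
  gmap <- stats::setNames(
    vapply(res$library$probesets, `[[`, "", "target_gene_id"),
    vapply(res$library$probesets, `[[`, "", "probeset_id"))
  labels <- stats::setNames(fx$intensities$samples$class,
                            fx$intensities$samples$sample_id)
  fc <- fold_change(expr, labels)
  truth <- fx$intensities$truth_de
  m <- match(unname(gmap[fc$gene_id]), truth$gene_id)
  expect_gte(cor(fc$log2_ratio, truth$planted_log2fc[m]), 0.95)
})
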