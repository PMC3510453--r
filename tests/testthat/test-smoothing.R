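test_that("Gaussian kernel has sigma = M/6, symmetric unit-mass weights", {
  k <- gaussian_kernel(27)
  expect_equal(k$sigma, 4.5)
  expect_length(k$weights, 27L)
  expect_equal(sum(k$weights), 1)
  expect_equal(k$weights, rev(k$weights))
  # density ratio at one step from the center, sigma = 1
  k6 <- gaussian_kernel(6)
  expect_equal(k6$sigma, 1)
  mid <- (length(k6$weights) + 1L) %/% 2L
  expect_equal(k6$weights[mid] / k6$weights[mid + 1L], exp(0.5))
  expect_error(gaussian_kernel(1), "M must be")
})

test_that("convolution leaves a constant track unchanged in both edge modes", {
  for (circ in c(TRUE, FALSE)) {
    r <- replicon("c", 500, circular = circ)
    tr <- coverage_track(r, rep(3.7, 500))
    for (edge in c("wrap", "renormalize")) {
      sm <- convolve_track(tr, gaussian_kernel(27), edge = edge)
      expect_equal(sm$values, rep(3.7, 500), tolerance = 1e-12)
    }
  }
})

test_that("a unit impulse reproduces the kernel weights", {
  r <- replicon("c", 1000)
  x <- numeric(1000); x[501] <- 1
  k <- gaussian_kernel(27)
  sm <- convolve_track(coverage_track(r, x), k, edge = "wrap")
  expect_equal(sm$values[(501 - 13):(501 + 13)], k$weights, tolerance = 1e-12)
  expect_equal(sum(sm$values), 1, tolerance = 1e-12)
})

test_that("convolve_track matches the direct double-loop sum", {
  Ms <- c(5L, 27L, 41L)
  for (i in 1:10) {
    tr <- rand_track(3000, seed = 100 + i, circular = TRUE)
    M <- Ms[(i %% 3) + 1L]
    k <- gaussian_kernel(M)
    got <- convolve_track(tr, k, edge = "wrap")$values
    expect_lt(max(abs(got - brute_convolve(tr$values, k$weights, TRUE))),
              1e-9)
    got <- convolve_track(tr, k, edge = "renormalize")$values
    expect_lt(max(abs(got - brute_convolve(tr$values, k$weights, FALSE))),
              1e-9)
  }
})

test_that("circular smoothing conserves mass and commutes with reversal", {
  tr <- rand_track(4000, seed = 9)
  sm <- convolve_track(tr, gaussian_kernel(27), edge = "wrap")
  expect_equal(sum(sm$values), sum(tr$values), tolerance = 1e-6)
  rev_tr <- coverage_track(tr$replicon, rev(tr$values))
  sm_rev <- convolve_track(rev_tr, gaussian_kernel(27), edge = "wrap")
  expect_equal(sm_rev$values, rev(sm$values), tolerance = 1e-9)
})

test_that("two-pass SMA equals one convolution with the composed kernel", {
  tr <- rand_track(3000, seed = 11)
  got <- two_pass_sma(tr, 40, 15, edge = "wrap")
  w1 <- sma_kernel(40)$weights   # 41 taps
  w2 <- sma_kernel(15)$weights   # 15 taps
  comp <- stats::convolve(w1, rev(w2), type = "open")  # 55 taps, odd
  kc <- structure(list(M = length(comp), offsets = NULL, weights = comp),
                  class = "SMAKernel")
  ref <- convolve_track(tr, kc, edge = "wrap")
  expect_lt(max(abs(got$values - ref$values)), 1e-9)
  # constant track unchanged
  ct <- coverage_track(replicon("k", 300), rep(2, 300))
  expect_equal(two_pass_sma(ct)$values, rep(2, 300), tolerance = 1e-12)
})

test_that("track correlation behaves like Pearson r and rejects constants", {
  tr <- rand_track(1000, seed = 13)
  expect_equal(track_pearson(tr, tr)$r, 1.0)
  neg <- coverage_track(tr$replicon,
                        max(tr$values) - tr$values)  # affine flip
  expect_equal(track_pearson(tr, neg)$r, -1.0)
  const <- coverage_track(tr$replicon, rep(1, 1000))
  expect_error(track_pearson(tr, const), "constant")
})

test_that("MNase-like and featureless control tracks are near-uncorrelated", {
  b <- small_bundle
  expect_lt(abs(track_pearson(b$mnase, b$naked)$r), 0.2)
  sm_m <- convolve_track(b$mnase, gaussian_kernel(27))
  sm_n <- convolve_track(b$naked, gaussian_kernel(27))
  expect_lt(abs(track_pearson(sm_m, sm_n)$r), 0.2)
})

test_that("window selection returns the largest bandwidth above r_min", {
  tr <- rand_track(2000, seed = 17)
  expect_equal(select_window(tr, 3, r_min = 0)$M, 3L)
  sel <- select_window(tr, seq(3, 41, by = 2), r_min = 0.2)
  expect_true(all(diff(sel$table$r) <= 1e-6))  # r non-increasing in M
  expect_equal(sel$M, max(sel$table$M[sel$table$r >= 0.2]))
  expect_error(select_window(tr, c(101, 151), r_min = 0.9999), "no candidate")
})

test_that("selected bandwidth beats extreme bandwidths at dyad recovery", {
  b <- small_bundle
  cov <- fragments_to_coverage(b$fragments, b$replicon, mode = "midpoint")
  sel <- select_window(b$mnase, seq(9, 45, by = 2), r_min = 0.85)
  f1 <- function(M) {
    sm <- convolve_track(cov, gaussian_kernel(M))
    calls <- call_nucleosomes(sm, min_prominence = 0.5 * mean(sm$values))
    tc <- truth_compare(calls, b$truth$dyads$pos, tolerance = 5)
    2 * tc$recall * tc$precision / (tc$recall + tc$precision)
  }
  expect_gt(f1(sel$M), f1(3))
  expect_gte(f1(sel$M), f1(45))
})
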