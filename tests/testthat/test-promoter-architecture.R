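test_that("anchored rows slice the track and flip with strand", {
  r <- replicon("c", 3000, circular = TRUE)
  set.seed(77)
  tr <- smoothed_track(r, stats::runif(3000) + 1, "t")
  un <- data.table::data.table(start = 1000L, end = 1600L, strand = "+",
                               id = "p")
  pm <- anchored_matrix(tr, un, "TSS", F = 200, normalize = "none")
  expect_equal(unname(pm$matrix[1, ]), tr$values[(1000 - 200):(1000 + 200) + 1])
  unm <- data.table::data.table(start = 400L, end = 1001L, strand = "-",
                                id = "m")
  pmm <- anchored_matrix(tr, unm, "TSS", F = 200, normalize = "none")
  expect_equal(unname(pmm$matrix[1, ]),
               rev(tr$values[(1000 - 200):(1000 + 200) + 1]))
  # TTS of a + transcript is its last base
  pm3 <- anchored_matrix(tr, un, "TTS", F = 10, normalize = "none")
  expect_equal(unname(pm3$matrix[1, 11]), tr$values[1600])
})

test_that("row-mean normalization yields unit-mean rows; constant rows 1", {
  r <- replicon("c", 2000, circular = TRUE)
  tr <- smoothed_track(r, rep(4.2, 2000), "t")
  un <- data.table::data.table(start = c(500L, 900L), end = c(800L, 1400L),
                               strand = c("+", "-"), id = c("a", "b"))
  pm <- anchored_matrix(tr, un, "TSS", F = 100)
  expect_true(all(pm$matrix == 1))
  set.seed(1)
  tr2 <- smoothed_track(r, stats::rpois(2000, 30) + 1, "t")
  pm2 <- anchored_matrix(tr2, un, "TSS", F = 100)
  expect_equal(unname(rowMeans(pm2$matrix)), c(1, 1))
  # scaling the track does not change normalized rows
  tr3 <- smoothed_track(r, tr2$values * 7, "t")
  pm3 <- anchored_matrix(tr3, un, "TSS", F = 100)
  expect_equal(pm2$matrix, pm3$matrix)
})

test_that("aggregate of a single-row matrix is that row", {
  r <- replicon("c", 1000, circular = TRUE)
  set.seed(2)
  tr <- smoothed_track(r, stats::runif(1000) + 0.5, "t")
  un <- data.table::data.table(start = 300L, end = 600L, strand = "+",
                               id = "a")
  pm <- anchored_matrix(tr, un, "TSS", F = 50)
  agg <- aggregate_profile(pm, n_boot = 50, seed = 4)
  expect_equal(agg$mean, unname(pm$matrix[1, ]))
  expect_true(all(agg$lo <= agg$mean & agg$mean <= agg$hi))
})

test_that("NDR detection reads depth and width off a V-shaped profile", {
  off <- -200:200
  # V shape: flanks 1.0, minimum 0.4 at -50, linear walls 60 bp wide
  y <- 1 - 0.6 * pmax(0, 1 - abs(off + 50) / 60)
  prof <- data.table::data.table(offset = off, mean = y)
  nd <- detect_ndr(prof)
  expect_equal(nd$min_offset, -50L)
  expect_equal(nd$depth, 0.6, tolerance = 0.02)
  # width at half prominence of a 120-bp-wide V is ~60 bp
  expect_equal(nd$width, 60L, tolerance = 3)
  flat <- data.table::data.table(offset = off, mean = rep(1, length(off)))
  expect_error(detect_ndr(flat), "no flanking maxima")
})

test_that("identical profiles give a zero 5' vs 3' difference", {
  b <- small_bundle
  sm <- convolve_track(b$mnase, gaussian_kernel(27))
  un <- b$units[b$units$expressed & b$units$kind != "novel", ]
  un$id <- un$unit_id
  pm <- anchored_matrix(sm, un, "TSS", F = 200)
  cmp <- compare_ndr(pm, pm, n_boot = 20, seed = 3,
                     search_window = c(-150, 150))
  expect_equal(cmp$depth_diff, 0)
  expect_equal(cmp$width_diff, 0L)
})

test_that("the aggregate TSS profile shows the planted NDR and +1/-1 peaks", {
  b <- small_bundle
  sm <- convolve_track(b$mnase, gaussian_kernel(27))
  un <- b$units[b$units$expressed & b$units$kind != "novel", ]
  un$id <- un$unit_id
  pm5 <- anchored_matrix(sm, un, "TSS", F = 200)
  nd5 <- detect_ndr(aggregate_profile(pm5))
  expect_lte(abs(nd5$min_offset - small_cfg$ndr5$center_offset), 10)
  expect_true(nd5$minus1_offset < nd5$min_offset)
  expect_true(nd5$plus1_offset > nd5$min_offset)
  pm3 <- anchored_matrix(sm, un, "TTS", F = 200)
  cmp <- compare_ndr(pm5, pm3, n_boot = 50, seed = 8,
                     search_window = c(-150, 150))
  expect_gt(cmp$depth_diff, 0)   # 5' NDR deeper
  expect_gt(cmp$width_diff, 0)   # and wider
  expect_gt(cmp$depth_ci[1], 0)
})

test_that("mirrored minus-strand geometry reproduces the plus aggregate", {
  r <- replicon("c", 4000, circular = TRUE)
  set.seed(5)
  v <- stats::rpois(4000, 20) + 1
  tr_fwd <- smoothed_track(r, v, "t")
  tr_rev <- smoothed_track(r, rev(v), "t")
  un_p <- data.table::data.table(start = 1500L, end = 2200L, strand = "+",
                                 id = "x")
  un_m <- data.table::data.table(start = 4000L - 2200L, end = 4000L - 1500L,
                                 strand = "-", id = "x")
  a1 <- aggregate_profile(anchored_matrix(tr_fwd, un_p, "TSS", F = 150))
  a2 <- aggregate_profile(anchored_matrix(tr_rev, un_m, "TSS", F = 150))
  expect_equal(a1$mean, a2$mean)
})

test_that("clustering recovers planted templates and ignores scale/shift", {
  set.seed(9)
  offs <- -100:100
  templates <- rbind(sin(offs / 10), cos(offs / 7), abs(offs) / 100)
  m <- templates[rep(1:3, each = 12), ] +
    matrix(stats::rnorm(36 * 201, 0, 0.01), 36)
  rownames(m) <- paste0("t", 1:36)
  pm <- structure(list(matrix = m, offsets = offs, anchor = "TSS",
                       dropped = character(0)), class = "ProfileMatrix")
  cl <- cluster_profiles(pm, k = 3)
  truth <- rep(1:3, each = 12)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, truth), 1)
  # Pearson distance is invariant to per-row affine rescaling
  m2 <- m * 3 + 10
  rownames(m2) <- rownames(m)
  pm2 <- structure(list(matrix = m2, offsets = offs, anchor = "TSS",
                        dropped = character(0)), class = "ProfileMatrix")
  cl2 <- cluster_profiles(pm2, k = 3)
  expect_equal(cl$assignment, cl2$assignment)
  expect_error(cluster_profiles(pm, k = 40), "fewer than k")
})

test_that("subclade labels are deterministic with non-increasing sizes", {
  b <- small_bundle
  sm <- convolve_track(b$mnase, gaussian_kernel(27))
  un <- b$units[b$units$expressed & b$units$kind != "novel", ]
  un$id <- un$unit_id
  pm <- anchored_matrix(sm, un, "TSS", F = 200)
  cl1 <- cluster_profiles(pm, k = 6)
  cl2 <- cluster_profiles(pm, k = 6)
  expect_identical(cl1$assignment, cl2$assignment)
  expect_true(all(diff(cl1$sizes) <= 0))
  expect_setequal(names(cl1$assignment), cl1$leaf_order)
})

test_that("heatmap export preserves values and leaf-contiguous clusters", {
  b <- small_bundle
  sm <- convolve_track(b$mnase, gaussian_kernel(27))
  un <- b$units[b$units$expressed & b$units$kind != "novel", ]
  un$id <- un$unit_id
  pm <- anchored_matrix(sm, un, "TSS", F = 100)
  cl <- cluster_profiles(pm, k = 4)
  fm <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_tables(pm, cl, fm, fa)
  back <- data.table::fread(fm, header = TRUE)
  expect_setequal(back$id, rownames(pm$matrix))
  expect_equal(as.matrix(back[, -1]), pm$matrix[cl$leaf_order, ],
               ignore_attr = TRUE)
  # cutree groups are contiguous blocks in dendrogram leaf order
  lab <- cl$assignment[cl$leaf_order]
  expect_equal(length(rle(as.integer(lab))$lengths),
               length(unique(lab)))
})
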