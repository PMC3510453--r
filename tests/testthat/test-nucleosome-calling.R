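test_that("extrema alternate, wrap the origin, and collapse plateaus", {
  r <- replicon("c", 5, circular = TRUE)
  sm <- smoothed_track(r, c(0, 1, 0, 1, 0), "test")
  ext <- find_extrema(sm)
  expect_equal(ext$pos[ext$type == "max"], c(1L, 3L))
  # the two zeros at positions 4 and 0 are one wrap plateau, center 4
  expect_setequal(ext$pos[ext$type == "min"], c(2L, 4L))

  lin <- replicon("l", 5, circular = FALSE)
  pl <- smoothed_track(lin, c(0, 1, 1, 1, 0), "test")
  ext <- find_extrema(pl)
  expect_equal(ext$pos[ext$type == "max"], 2L)  # plateau center

  expect_warning(ext <- find_extrema(smoothed_track(r, rep(2, 5), "t")),
                 "constant")
  expect_equal(nrow(ext), 0L)
})

test_that("a sine wave yields maxima at the planted period", {
  n <- 7000L
  r <- replicon("c", n, circular = TRUE)
  y <- sin(2 * pi * ((0:(n - 1)) - 0.3) / 70) + 2
  ext <- find_extrema(smoothed_track(r, y, "sine"))
  mx <- sort(ext$pos[ext$type == "max"])
  expect_length(mx, 100L)
  expect_true(all(diff(mx) == 70L))
  # strict alternation all the way around
  ord <- ext[order(ext$pos), ]
  expect_true(all(ord$type[-1] != ord$type[-nrow(ord)]))
})

test_that("every maximum is called by default; weak peaks merge", {
  r <- replicon("c", 12, circular = FALSE)
  y <- c(0, 5, 1, 5, 0, 8, 0, 2, 0, 6, 1, 0)
  sm <- smoothed_track(r, y, "t")
  calls0 <- call_nucleosomes(sm)
  expect_equal(nrow(calls0), sum(find_extrema(sm)$type == "max"))
  expect_true(all(calls0$prominence >= 0))
  # the two 5-peaks around the shallow trough (prominence 4 each) survive a
  # low threshold, the 2-peak (prominence 2) merges away
  calls <- call_nucleosomes(sm, min_prominence = 3)
  expect_false(7L %in% calls$midpoint)
  expect_true(all(c(5L, 9L) %in% calls$midpoint))
  expect_true(all(calls$prominence >= 3))
  expect_lt(nrow(calls), nrow(calls0))
})

test_that("calls are reproducible and alternation survives merging", {
  b <- small_bundle
  cd1 <- call_dyads(b$fragments, b$replicon)
  cd2 <- call_dyads(b$fragments, b$replicon)
  expect_identical(cd1$calls, cd2$calls)
  # between consecutive midpoints lies exactly one shared trough
  mids <- cd1$calls$midpoint
  expect_true(all(cd1$calls$right_trough[-nrow(cd1$calls)] ==
                    cd1$calls$left_trough[-1]))
  expect_true(all(diff(mids) > 0))
})

test_that("peak spacing stratifies by class and excludes boundary pairs", {
  r <- replicon("c", 200, circular = FALSE)
  regions <- data.table::data.table(start = 0L, end = 200L, class = "genic")
  calls <- data.table::data.table(midpoint = c(10L, 80L, 150L))
  sp <- peak_spacing(calls, regions, r)
  expect_equal(sp$mean[sp$class == "genic"], 70)
  expect_equal(sp$n[sp$class == "genic"], 2L)
  # cross-class pairs are dropped
  regions2 <- data.table::data.table(start = c(0L, 100L), end = c(100L, 200L),
                                     class = c("genic", "non_genic"))
  sp2 <- peak_spacing(calls, regions2, r)
  expect_equal(sp2$n[sp2$class == "genic"], 1L)       # 10-80 only
  expect_equal(sp2$n[sp2$class == "non_genic"], 0L)   # 150 alone
  # single call: empty statistics, no crash
  sp3 <- peak_spacing(head(calls, 1), regions, r)
  expect_true(all(sp3$n == 0L))
  expect_true(all(is.na(sp3$mean)))
})

test_that("spacing includes the wrap-around pair on circular replicons", {
  r <- replicon("c", 100, circular = TRUE)
  regions <- data.table::data.table(start = 0L, end = 100L, class = "genic")
  calls <- data.table::data.table(midpoint = c(10L, 50L, 90L))
  sp <- peak_spacing(calls, regions, r)
  expect_equal(sp$n[sp$class == "genic"], 3L)   # 40, 40 and the wrap 20
  expect_equal(sp$mean[sp$class == "genic"], 100 / 3)
})

test_that("nucleosome density is calls per kilobase", {
  r <- replicon("c", 10000)
  calls <- data.table::data.table(midpoint = seq_len(142))
  expect_equal(nucleosome_density(calls, r), 14.2)
  expect_equal(nucleosome_density(head(calls, 0), r), 0)
})

test_that("occupancy states rescale each segment and honor thresholds", {
  r <- replicon("c", 61, circular = FALSE)
  y <- c(seq(0, 1, length.out = 31), seq(1, 0, length.out = 31)[-1])
  sm <- smoothed_track(r, y, "triangle")
  calls <- call_nucleosomes(sm)
  st <- occupancy_states(sm, calls)
  expect_equal(sort(unique(st$states)), c(0, 0.5, 1))
  mid <- calls$midpoint + 1L
  expect_equal(st$states[mid], 1)                      # peak occupied
  expect_equal(st$states[calls$left_trough + 1L], 0)   # troughs depleted
  inner <- st$states[(calls$left_trough + 1L):(calls$right_trough + 1L)]
  # linear ramp: one third occupied, one third depleted, one third between
  expect_equal(mean(inner == 1), 1/3, tolerance = 0.05)
  expect_equal(mean(inner == 0), 1/3, tolerance = 0.05)
})

test_that("occupied fraction decreases as theta_occ rises", {
  b <- small_bundle
  sm <- convolve_track(b$mnase, gaussian_kernel(27))
  calls <- call_nucleosomes(sm)
  fr <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(th)
    mean(occupancy_states(sm, calls, theta_occ = th)$states == 1),
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("genic regions extend 40 bp upstream strand-aware and partition", {
  r <- replicon("c", 1000, circular = FALSE)
  plus <- data.table::data.table(start = 100L, end = 400L, strand = "+")
  reg <- build_regions(plus, r)
  g <- reg[reg$class == "genic", ]
  expect_equal(c(g$start, g$end), c(60L, 400L))
  minus <- data.table::data.table(start = 100L, end = 400L, strand = "-")
  g <- build_regions(minus, r)
  g <- g[g$class == "genic", ]
  expect_equal(c(g$start, g$end), c(100L, 440L))
  # overlapping extensions merge; classes still partition every base
  two <- data.table::data.table(start = c(100L, 420L), end = c(400L, 700L),
                                strand = c("+", "+"))
  reg <- build_regions(two, r)
  expect_equal(sum(reg$end - reg$start), 1000L)
  expect_true(all(reg$start[-1] == reg$end[-nrow(reg)]))
  expect_warning(build_regions(
    data.table::data.table(start = 1L, end = 10L, strand = "."), r),
    "without strand")
})

test_that("planted dyads are recovered from the protected fragments", {
  b <- small_bundle
  cd <- call_dyads(b$fragments, b$replicon, M = 27)
  tc <- truth_compare(cd$calls, b$truth$dyads$pos, tolerance = 5)
  expect_gte(tc$recall, 0.9)
  expect_lte(tc$mae, 3)
})
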