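mk_rna <- function(values, circular = FALSE) {
  coverage_track(replicon("c", length(values), circular = circular), values)
}

test_that("expression calls follow mean coverage against c_min", {
  rna <- mk_rna(c(rep(0, 10), rep(10, 20), rep(0, 10)))
  ann <- data.table::data.table(chrom = "c", start = c(10L, 0L),
                                end = c(30L, 10L), strand = c("+", "+"),
                                id = c("a", "b"))
  cl <- classify_expressed(ann, rna, c_min = 5)
  expect_equal(cl$expressed, c(TRUE, FALSE))
  expect_equal(cl$mean_coverage, c(10, 0))
  bad <- data.table::data.table(chrom = "c", start = 0L, end = 99L,
                                strand = "+", id = "x")
  expect_error(classify_expressed(bad, rna), "outside replicon")
})

test_that("boundaries are a fixed point when coverage matches the span", {
  x <- numeric(200); x[51:150] <- 20
  rna <- mk_rna(x)
  ann <- data.table::data.table(chrom = "c", start = 50L, end = 150L,
                                strand = "+", id = "a")
  tr <- trim_boundaries(classify_expressed(ann, rna), rna)
  expect_equal(c(tr$start, tr$end), c(50L, 150L))
})

test_that("a covered 5'UTR extends the annotation to the coverage edge", {
  x <- numeric(400)
  x[(141 - 60):260] <- 15          # coverage starts 60 bp upstream of ORF
  rna <- mk_rna(x)
  ann <- data.table::data.table(chrom = "c", start = 140L, end = 260L,
                                strand = "+", id = "a")
  tr <- trim_boundaries(classify_expressed(ann, rna), rna)
  expect_equal(tr$start, 80L)
  expect_equal(tr$end, 260L)
  # extension is capped by max_ext
  tr2 <- trim_boundaries(classify_expressed(ann, rna), rna, max_ext = 30L)
  expect_equal(tr2$start, 110L)
})

test_that("shrinking stops at covered bases; hopeless units are dropped", {
  x <- numeric(200); x[81:120] <- 9
  rna <- mk_rna(x)
  ann <- data.table::data.table(chrom = "c", start = 60L, end = 140L,
                                strand = "+", id = "a")
  tr <- trim_boundaries(classify_expressed(ann, rna, c_min = 1), rna)
  expect_equal(c(tr$start, tr$end), c(80L, 120L))
  dead <- data.table::data.table(chrom = "c", start = 0L, end = 50L,
                                 strand = "+", id = "z")
  cl <- classify_expressed(dead, rna, c_min = 0)
  expect_warning(out <- trim_boundaries(cl, rna), "collapsed")
  expect_equal(nrow(out), 0L)
})

test_that("units merge across fully covered gaps, transitively", {
  x <- numeric(500); x[1:400] <- 10
  rna <- mk_rna(x)
  un <- data.table::data.table(
    chrom = "c", start = c(0L, 130L, 260L), end = c(100L, 230L, 400L),
    strand = "+", id = c("a", "b", "c"), mean_coverage = 10,
    expressed = TRUE, threshold = 3)
  m <- merge_units(un, rna)
  expect_equal(nrow(m), 1L)
  expect_equal(m$status, "merged")
  expect_equal(m$source_ids, "a,b,c")
  expect_equal(c(m$start, m$end), c(0L, 400L))
  # a single uncovered base in the gap blocks the merge
  x2 <- x; x2[115] <- 0
  m2 <- merge_units(un, mk_rna(x2))
  expect_equal(sum(m2$status == "merged"), 1L)   # only b-c still merge
  expect_equal(sum(m2$status == "confirmed"), 1L)
})

test_that("novel units appear only in covered annotation deserts", {
  x <- numeric(1000); x[301:800] <- 12
  rna <- mk_rna(x)
  none <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 id = character())
  nv <- detect_novel(rna, none)
  expect_equal(nrow(nv), 1L)
  expect_equal(c(nv$start, nv$end), c(300L, 800L))
  expect_equal(nv$strand, ".")
  # 1 bp of overlap with a refined unit disqualifies the run
  un <- data.table::data.table(chrom = "c", start = 799L, end = 900L,
                               strand = "+", id = "a")
  expect_equal(nrow(detect_novel(rna, un)), 0L)
  # too-short runs are ignored
  x3 <- numeric(1000); x3[11:60] <- 12
  expect_equal(nrow(detect_novel(mk_rna(x3), none)), 0L)
})

test_that("summary counts partition the predicted annotations", {
  b <- small_bundle
  res <- refine_transcripts(b$annotations, b$rna)
  s <- res$summary
  expect_equal(s$n_predicted, nrow(b$annotations))
  expect_lte(s$n_confirmed, s$n_predicted)
  expect_equal(s$n_expressed / s$n_predicted, s$fraction_expressed)
  expect_equal(s$n_novel, sum(res$units$status == "novel"))
  # every merged unit's span contains all its sources
  merged <- res$units[res$units$status == "merged", ]
  for (i in seq_len(nrow(merged))) {
    src <- strsplit(merged$source_ids[i], ",")[[1]]
    aa <- b$annotations[b$annotations$id %in% src, ]
    expect_true(all(aa$start >= merged$start[i] - 250 &
                      aa$end <= merged$end[i] + 250))
  }
  # refined units never overlap on the same strand
  for (str in c("+", "-")) {
    uu <- res$units[res$units$strand == str, ]
    uu <- uu[order(uu$start), ]
    if (nrow(uu) > 1L) expect_true(all(uu$start[-1] >= uu$end[-nrow(uu)]))
  }
})

test_that("raising c_min never increases the expressed count", {
  b <- small_bundle
  n_expr <- vapply(c(1, 3, 5, 10, 30), function(cm)
    sum(classify_expressed(b$annotations, b$rna, c_min = cm)$expressed),
    numeric(1))
  expect_true(all(diff(n_expr) <= 0))
})

test_that("planted units, operons and novel transcripts are recovered", {
  b <- small_bundle
  res <- refine_transcripts(b$annotations, b$rna)
  tcu <- truth_compare_units(res$units[res$units$status != "novel", ],
                             b$units[b$units$kind != "novel", ],
                             tolerance = 20)
  expect_gte(tcu$boundary_within, 0.95)
  key <- function(x) vapply(strsplit(x, ","), function(v)
    paste(sort(v), collapse = ","), character(1))
  planted_ops <- b$units[b$units$kind == "operon" & b$units$expressed, ]
  merged <- res$units[res$units$status == "merged", ]
  expect_setequal(key(merged$source_ids), key(planted_ops$gene_ids))
  nv <- res$units[res$units$status == "novel", ]
  expect_equal(nrow(nv), sum(b$units$kind == "novel"))
  expect_equal(res$summary$fraction_expressed,
               sum(b$annotations$expressed) / nrow(b$annotations))
})
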