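#' Anchor occupancy around TSS or TTS for a set of transcripts
#'
#' Builds a transcripts x offsets matrix of occupancy values over
#' `anchor +/- F`. Rows from minus-strand transcripts are flipped so that
#' positive offsets always point downstream of transcription. Each row is
#' divided by its own mean, so rows are comparable regardless of local
#' coverage depth ("degree of normalized nucleosome occupancy"); rows with
#' zero mean are dropped and reported. Windows extending past the ends of a
#' circular replicon wrap; on a linear replicon such rows are dropped with a
#' warning.
#'
#' @param track A [smoothed_track()] (or raw [coverage_track()]).
#' @param units data.table with start, end (0-based half-open), strand, id;
#'   strandless units are skipped with a warning.
#' @param anchor `"TSS"` (5' end) or `"TTS"` (3' end).
#' @param F Flank size in bp (default 200, i.e. a 401-column window).
#' @param normalize `"row_mean"` (default), `"zscore"`, or `"none"`.
#' @return List of class `ProfileMatrix`: `matrix` (rownames = unit ids),
#'   `offsets`, `anchor`, `dropped` (ids of excluded rows).
#' @export
anchored_matrix <- function(track, units, anchor = c("TSS", "TTS"),
                            F = 200L, normalize = c("row_mean", "zscore",
                                                    "none")) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  F <- as.integer(F)
  un <- data.table::as.data.table(units)
  no_strand <- !(un$strand %in% c("+", "-"))
  if (any(no_strand)) {
    warning(sum(no_strand), " strandless unit(s) skipped in anchored_matrix")
    un <- un[!no_strand, ]
  }
  if (nrow(un) == 0L) stop("no stranded units to profile")
  x <- track$values
  L <- length(x)
  circular <- track$replicon$circular
  # 5' end: start for +, end-1 for -; 3' end: the mirror
  anc <- if (anchor == "TSS") {
    ifelse(un$strand == "+", un$start, un$end - 1L)
  } else {
    ifelse(un$strand == "+", un$end - 1L, un$start)
  }
  offs <- (-F):F
  rows <- matrix(NA_real_, nrow = nrow(un), ncol = length(offs))
  keep <- rep(TRUE, nrow(un))
  for (i in seq_len(nrow(un))) {
    pos <- if (un$strand[i] == "+") anc[i] + offs else anc[i] - offs
    if (circular) {
      pos <- wrap0(pos, L)
    } else if (any(pos < 0L) || any(pos >= L)) {
      keep[i] <- FALSE
      next
    }
    rows[i, ] <- x[pos + 1L]
  }
  if (any(!keep))
    warning(sum(!keep), " window(s) beyond linear replicon ends dropped")
  ids <- if ("id" %in% names(un)) un$id else as.character(seq_len(nrow(un)))
  dropped <- ids[!keep]
  rows <- rows[keep, , drop = FALSE]
  ids <- ids[keep]
  if (normalize == "row_mean") {
    rm <- rowMeans(rows)
    zero <- rm == 0
    if (any(zero)) {
      dropped <- c(dropped, ids[zero])
      rows <- rows[!zero, , drop = FALSE]
      ids <- ids[!zero]
      rm <- rm[!zero]
    }
    rows <- rows / rm
  } else if (normalize == "zscore") {
    sdv <- apply(rows, 1, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      dropped <- c(dropped, ids[zero])
      rows <- rows[!zero, , drop = FALSE]
      ids <- ids[!zero]
      sdv <- sdv[!zero]
    }
    rows <- (rows - rowMeans(rows)) / sdv
  }
  rownames(rows) <- ids
  colnames(rows) <- offs
  structure(list(matrix = rows, offsets = offs, anchor = anchor,
                 dropped = dropped),
            class = "ProfileMatrix")
}

#' Aggregate an anchored profile matrix over transcripts
#'
#' Column means across transcripts, optionally with a seeded bootstrap
#' percentile band from resampling rows.
#'
#' @param pm A `ProfileMatrix` from [anchored_matrix()].
#' @param n_boot Bootstrap replicates (0 = no band).
#' @param level Confidence level for the band.
#' @param seed Seed for the bootstrap.
#' @return data.table with offset, mean and (when bootstrapped) lo, hi.
#' @export
aggregate_profile <- function(pm, n_boot = 0L, level = 0.95, seed = 1L) {
  m <- pm$matrix
  if (nrow(m) == 0L) stop("empty profile matrix")
  out <- data.table::data.table(offset = pm$offsets, mean = colMeans(m))
  if (n_boot > 0L) {
    old <- .Random.seed_safe()
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(b)
      colMeans(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]),
      numeric(ncol(m)))
    .Random.seed_restore(old)
    a <- (1 - level) / 2
    out$lo <- apply(boots, 1, stats::quantile, probs = a)
    out$hi <- apply(boots, 1, stats::quantile, probs = 1 - a)
  }
  out
}

#' Locate the nucleosome-depleted region in an aggregate profile
#'
#' Finds the minimum of the aggregate within `search_window`, the nearest
#' flanking local maxima (the -1 and +1 nucleosome peaks), and summarizes
#' the NDR as a relative depth and a width.
#'
#' @param profile data.table from [aggregate_profile()] (offset, mean).
#' @param search_window Offsets searched for the minimum, default
#'   `c(-150, 50)` (promoter NDRs sit upstream of the anchor).
#' @param width_frac The NDR width is the contiguous span around the
#'   minimum below `min + width_frac * (flank mean - min)` (default 0.5).
#' @return List of class `NDRCall` with `min_offset` (argmin), `depth`
#'   (`(flank - min)/flank`, in [0,1] for non-negative signal), `width`,
#'   `center_offset` (midpoint of the below-threshold span — a more stable
#'   location estimate than the argmin when the depleted basin has a flat
#'   floor), `flank_mean`, and the flanking maxima offsets.
#' @export
detect_ndr <- function(profile, search_window = c(-150L, 50L),
                       width_frac = 0.5) {
  off <- profile$offset
  y <- profile$mean
  win <- which(off >= search_window[1] & off <= search_window[2])
  if (!length(win)) stop("search window outside the profiled offsets")
  i_min <- win[which.min(y[win])]
  # the -1/+1 nucleosome peaks: highest local maximum within reach on each
  # side. Plateau runs count as one maximum, located at the run point
  # nearest the minimum (so an idealized flat-topped flank reads as a peak
  # at the top of the NDR wall); a constant profile has no maxima.
  reach <- 100L
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  prev <- c(-Inf, r$values[-m])
  nxt <- c(r$values[-1], -Inf)
  is_max <- r$values > prev & r$values > nxt
  if (m == 1L) is_max <- FALSE
  cand_pos <- ifelse(ends < i_min, ends, ifelse(starts > i_min, starts,
                                                NA_integer_))
  lmax <- cand_pos[is_max & !is.na(cand_pos)]
  left <- lmax[lmax < i_min & off[lmax] >= off[i_min] - reach]
  right <- lmax[lmax > i_min & off[lmax] <= off[i_min] + reach]
  if (!length(left) || !length(right))
    stop("no flanking maxima within ", reach,
         " bp of the minimum; widen search_window")
  i_left <- left[which.max(y[left])]
  i_right <- right[which.max(y[right])]
  flank <- mean(c(y[i_left], y[i_right]))
  depth <- (flank - y[i_min]) / flank
  thr <- y[i_min] + width_frac * (flank - y[i_min])
  lo <- i_min
  while (lo > 1L && y[lo - 1L] < thr) lo <- lo - 1L
  hi <- i_min
  while (hi < length(y) && y[hi + 1L] < thr) hi <- hi + 1L
  structure(list(min_offset = off[i_min], depth = depth,
                 width = as.integer(off[hi] - off[lo] + 1L),
                 center_offset = as.integer(round((off[lo] + off[hi]) / 2)),
                 flank_mean = flank,
                 minus1_offset = off[i_left], plus1_offset = off[i_right],
                 min_value = y[i_min]),
            class = "NDRCall")
}

#' @export
print.NDRCall <- function(x, ...) {
  cat(sprintf(
    "<NDRCall> center %+d bp (min %+d), depth %.3f, width %d bp (-1 at %+d, +1 at %+d)\n",
    x$center_offset, x$min_offset, x$depth, x$width,
    x$minus1_offset, x$plus1_offset))
  invisible(x)
}

#' Compare the 5' (TSS) and 3' (TTS) nucleosome-depleted regions
#'
#' Detects the NDR in each aggregate and reports depth and width
#' differences (5' minus 3') with bootstrap percentile confidence intervals
#' obtained by resampling transcripts within each matrix.
#'
#' @param tss_pm,tts_pm `ProfileMatrix` objects for the two anchors.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed.
#' @param ... Passed to [detect_ndr()].
#' @return List with the two `NDRCall`s, `depth_diff`, `width_diff` and
#'   their CIs.
#' @export
compare_ndr <- function(tss_pm, tts_pm, n_boot = 200L, seed = 1L, ...) {
  agg5 <- aggregate_profile(tss_pm)
  agg3 <- aggregate_profile(tts_pm)
  call5 <- detect_ndr(agg5, ...)
  call3 <- detect_ndr(agg3, ...)
  boot_one <- function(pm) {
    m <- pm$matrix
    idx <- sample.int(nrow(m), replace = TRUE)
    prof <- data.table::data.table(offset = pm$offsets,
                                   mean = colMeans(m[idx, , drop = FALSE]))
    nd <- tryCatch(detect_ndr(prof, ...), error = function(e) NULL)
    if (is.null(nd)) c(NA_real_, NA_real_) else c(nd$depth, nd$width)
  }
  old <- .Random.seed_safe()
  set.seed(as.integer(seed))
  b5 <- vapply(seq_len(n_boot), function(i) boot_one(tss_pm), numeric(2))
  b3 <- vapply(seq_len(n_boot), function(i) boot_one(tts_pm), numeric(2))
  .Random.seed_restore(old)
  dd <- b5[1, ] - b3[1, ]
  dw <- b5[2, ] - b3[2, ]
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  list(tss = call5, tts = call3,
       depth_diff = call5$depth - call3$depth, depth_ci = ci(dd),
       width_diff = call5$width - call3$width, width_ci = ci(dw))
}

#' Hierarchically cluster per-transcript occupancy profiles
#'
#' Distance between transcripts is `1 - Pearson r` of their profiles
#' (centered correlation; `uncentered = TRUE` divides by raw second moments
#' instead, for compatibility with classic clustering tools), with average
#' linkage. The tree is cut into `k` groups and the `k` largest subclades
#' are labeled `1..k` in decreasing size (ties broken by first row
#' appearance); any remaining transcripts get label 0. Zero-variance rows
#' cannot be correlated and are dropped and reported.
#'
#' @param pm A `ProfileMatrix`.
#' @param k Number of subclades to label (default 6).
#' @param uncentered Use uncentered correlation (default FALSE).
#' @return List of class `ClusterResult`: `tree` (hclust), `assignment`
#'   (named integer vector), `sizes`, `dropped`, `leaf_order` (ids).
#' @export
cluster_profiles <- function(pm, k = 6L, uncentered = FALSE) {
  m <- pm$matrix
  sdv <- apply(m, 1, stats::sd)
  dropped <- rownames(m)[sdv == 0]
  m <- m[sdv > 0, , drop = FALSE]
  if (nrow(m) < k)
    stop("fewer than k = ", k, " non-degenerate rows (have ", nrow(m), ")")
  if (uncentered) {
    num <- tcrossprod(m)
    nrm <- sqrt(rowSums(m^2))
    r <- num / outer(nrm, nrm)
  } else {
    r <- stats::cor(t(m))
  }
  d <- stats::as.dist(1 - r)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, k = k)
  tab <- sort(table(raw), decreasing = TRUE)
  # decreasing size; among equal sizes keep first-appearance order
  ord <- order(-as.integer(tab), match(names(tab), as.character(raw)))
  ranked <- names(tab)[ord]
  lab <- match(as.character(raw), ranked[seq_len(k)])
  lab[is.na(lab)] <- 0L
  assignment <- stats::setNames(as.integer(lab), rownames(m))
  structure(list(tree = tree, assignment = assignment,
                 sizes = as.integer(tab[ranked[seq_len(min(k, length(ranked)))]]),
                 dropped = dropped,
                 leaf_order = rownames(m)[tree$order]),
            class = "ClusterResult")
}

#' Export clustering results as plain tables
#'
#' Writes the profile matrix reordered by dendrogram leaf order and the
#' subclade assignments as TSV, the layout heatmap viewers ingest.
#'
#' @param pm A `ProfileMatrix`.
#' @param cl A `ClusterResult` from [cluster_profiles()].
#' @param matrix_path,assignment_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
export_heatmap_tables <- function(pm, cl, matrix_path, assignment_path) {
  m <- pm$matrix[cl$leaf_order, , drop = FALSE]
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, matrix_path, sep = "\t")
  adt <- data.table::data.table(id = cl$leaf_order,
                                subclade = cl$assignment[cl$leaf_order])
  data.table::fwrite(adt, assignment_path, sep = "\t")
  invisible(c(matrix_path, assignment_path))
}
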