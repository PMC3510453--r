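#' Classify annotations as expressed by mean RNA-seq coverage
#'
#' An annotation is detectably expressed when its mean per-base RNA-seq
#' coverage reaches `c_min` (default 5x).
#'
#' @param annotations data.table with chrom, start, end (0-based half-open),
#'   strand, id.
#' @param rna A [coverage_track()] of RNA-seq per-base coverage.
#' @param c_min Minimum mean coverage (default 5).
#' @return The annotations with `mean_coverage` and logical `expressed`
#'   columns added.
#' @export
classify_expressed <- function(annotations, rna, c_min = 5) {
  ann <- data.table::as.data.table(annotations)
  L <- rna$replicon$length
  if (any(ann$start < 0L) || any(ann$end > L))
    stop("annotation outside replicon '", rna$replicon$name, "'")
  cs <- c(0, cumsum(rna$values))
  ann$mean_coverage <- (cs[ann$end + 1L] - cs[ann$start + 1L]) /
    (ann$end - ann$start)
  ann$expressed <- ann$mean_coverage >= c_min
  ann
}

#' Adjust transcript 5' and 3' boundaries to the covered region
#'
#' For each expressed annotation a coverage threshold
#' `t = max(3, t_rel * median coverage within the annotation)` is set
#' (default `t_rel = 0.1`). Each end first shrinks inward over bases below
#' `t`, then extends outward over bases at or above `t`, capped at
#' `max_ext` bp beyond the original boundary and stopping before touching
#' the nearest same-strand annotation. An annotation whose span collapses
#' (no base reaches `t`) is dropped with a warning.
#'
#' @param annotations data.table as in [classify_expressed()] with an
#'   `expressed` column; only expressed rows are adjusted.
#' @param rna RNA-seq [coverage_track()].
#' @param t_rel Relative threshold on the within-annotation median.
#' @param max_ext Maximum extension beyond the original boundary (bp).
#' @return The expressed annotations with adjusted start/end plus a
#'   `threshold` column; dropped annotations removed.
#' @export
trim_boundaries <- function(annotations, rna, t_rel = 0.1, max_ext = 250L) {
  ann <- data.table::as.data.table(annotations)
  if (!"expressed" %in% names(ann))
    stop("run classify_expressed() first")
  ann <- ann[ann$expressed %in% TRUE, ]
  if (nrow(ann) == 0L) return(ann)
  x <- rna$values
  L <- length(x)
  ann <- ann[order(ann$start), ]
  new_s <- integer(nrow(ann)); new_e <- integer(nrow(ann))
  thr <- numeric(nrow(ann)); keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[i]; e <- ann$end[i]
    t <- max(3, t_rel * stats::median(x[(s + 1L):e]))
    thr[i] <- t
    inside <- which(x[(s + 1L):e] >= t)
    if (!length(inside)) { keep[i] <- FALSE; next }
    keep[i] <- TRUE
    s2 <- s + inside[1] - 1L           # shrink inward
    e2 <- s + inside[length(inside)]
    # neighbor bounds on the same strand (original coordinates)
    same <- which(ann$strand == ann$strand[i])
    left_lim <- max(c(0L, ann$end[same][ann$end[same] <= s]), na.rm = TRUE)
    right_lim <- min(c(L, ann$start[same][ann$start[same] >= e]),
                     na.rm = TRUE)
    lo <- max(left_lim, s - max_ext)
    while (s2 > lo && x[s2] >= t) s2 <- s2 - 1L    # x[s2] is base s2-1
    hi <- min(right_lim, e + max_ext)
    while (e2 < hi && x[e2 + 1L] >= t) e2 <- e2 + 1L
    new_s[i] <- s2; new_e[i] <- e2
  }
  if (any(!keep))
    warning(sum(!keep), " annotation(s) collapsed below threshold; dropped")
  ann$start <- new_s; ann$end <- new_e; ann$threshold <- thr
  ann[keep, ]
}

#' Merge adjacent same-strand units covered across the gap
#'
#' Two neighboring units on the same strand merge into one transcription
#' unit when every base of the gap between them has coverage at least `t`
#' (an empty gap merges trivially); merging is transitive, so operon chains
#' collapse into a single unit. Merged units absorb the source ids of all
#' members.
#'
#' @param units data.table of trimmed units (chrom, start, end, strand, id).
#' @param rna RNA-seq [coverage_track()].
#' @param t Gap coverage threshold (default 3).
#' @return data.table of units with `status` (`"confirmed"` / `"merged"`)
#'   and `source_ids` columns.
#' @export
merge_units <- function(units, rna, t = 3) {
  un <- data.table::as.data.table(units)
  if (nrow(un) == 0L) {
    un$status <- character(0); un$source_ids <- character(0)
    return(un)
  }
  x <- rna$values
  out <- list()
  for (str in unique(un$strand)) {
    g <- un[un$strand == str, ]
    g <- g[order(g$start), ]
    grp <- integer(nrow(g)); grp[1] <- 1L
    if (nrow(g) > 1L) for (i in 2:nrow(g)) {
      gap_s <- g$end[i - 1L]; gap_e <- g$start[i]
      covered <- gap_e <= gap_s ||
        all(x[(gap_s + 1L):gap_e] >= t)
      grp[i] <- if (covered) grp[i - 1L] else grp[i - 1L] + 1L
    }
    for (k in unique(grp)) {
      m <- g[grp == k, ]
      if (nrow(m) == 1L) {
        m$status <- "confirmed"
        m$source_ids <- m$id
        out[[length(out) + 1L]] <- m
      } else {
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = m$chrom[1], start = min(m$start), end = max(m$end),
          strand = str, id = paste0("merged_", m$id[1]),
          mean_coverage = mean(m$mean_coverage),
          expressed = TRUE, threshold = min(m$threshold),
          status = "merged", source_ids = paste(m$id, collapse = ","))
      }
    }
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  res[order(res$start), ]
}

#' Detect novel transcription units in unannotated covered regions
#'
#' Maximal runs of RNA-seq coverage at or above `t` that are at least
#' `min_len` bp long and overlap no refined unit are reported as novel
#' units. Their strand is unknown from coverage alone and is set to `"."`.
#'
#' @param rna RNA-seq [coverage_track()].
#' @param units Refined units (the output of [merge_units()]).
#' @param t Coverage threshold (default 3).
#' @param min_len Minimum length in bp (default 100).
#' @return data.table of novel units with status `"novel"`.
#' @export
detect_novel <- function(rna, units, t = 3, min_len = 100L) {
  x <- rna$values
  r <- rle(x >= t)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- data.table::data.table(start = starts[r$values],
                                 end = ends[r$values])
  runs <- runs[(runs$end - runs$start) >= min_len, ]
  if (nrow(runs) && nrow(units)) {
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(runs$start + 1L, runs$end),
      IRanges::IRanges(units$start + 1L, units$end))
    runs <- runs[!ov, ]
  }
  if (nrow(runs) == 0L)
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), id = character(), mean_coverage = numeric(),
      status = character(), source_ids = character()))
  cs <- c(0, cumsum(x))
  data.table::data.table(
    chrom = rna$replicon$name, start = runs$start, end = runs$end,
    strand = ".", id = paste0("novel_", seq_len(nrow(runs))),
    mean_coverage = (cs[runs$end + 1L] - cs[runs$start + 1L]) /
      (runs$end - runs$start),
    status = "novel", source_ids = NA_character_)
}

#' Summarize a transcript refinement run
#'
#' @param units Refined units including novel ones.
#' @param annotations The original predicted annotations with `expressed`.
#' @return List with n_predicted, n_expressed, n_confirmed, n_merged_into,
#'   n_novel, fraction_expressed, fraction_confirmed.
#' @export
summarize_units <- function(units, annotations) {
  ann <- data.table::as.data.table(annotations)
  n_pred <- nrow(ann)
  n_expr <- sum(ann$expressed %in% TRUE)
  real <- units[units$status %in% c("confirmed", "merged"), ]
  confirmed_ids <- character(0)
  if (nrow(real)) {
    src <- unlist(strsplit(real$source_ids, ","))
    confirmed_ids <- intersect(ann$id, src)
    # plus any predicted annotation overlapped by a refined expressed unit
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ann$start + 1L, ann$end),
      IRanges::IRanges(real$start + 1L, real$end))
    same_strand <- ann$strand[S4Vectors::from(ov)] ==
      real$strand[S4Vectors::to(ov)]
    confirmed_ids <- union(confirmed_ids,
                           ann$id[S4Vectors::from(ov)][same_strand])
  }
  merged_units <- units[units$status == "merged", ]
  n_merged_into <- if (nrow(merged_units))
    length(unlist(strsplit(merged_units$source_ids, ","))) else 0L
  list(n_predicted = n_pred,
       n_expressed = n_expr,
       n_confirmed = length(confirmed_ids),
       n_merged_into = n_merged_into,
       n_novel = sum(units$status == "novel"),
       fraction_expressed = if (n_pred) n_expr / n_pred else 0,
       fraction_confirmed = if (n_pred) length(confirmed_ids) / n_pred else 0)
}

#' Full transcript refinement pipeline
#'
#' Runs [classify_expressed()], [trim_boundaries()], [merge_units()] and
#' [detect_novel()] in order and summarizes the result.
#'
#' @inheritParams classify_expressed
#' @inheritParams trim_boundaries
#' @param merge_t Gap coverage threshold for merging.
#' @param novel_t,min_novel_len Novel-unit detection parameters.
#' @return List with `units` (refined + novel), `annotations` (with
#'   expression flags) and `summary`.
#' @export
refine_transcripts <- function(annotations, rna, c_min = 5, t_rel = 0.1,
                               max_ext = 250L, merge_t = 3, novel_t = 3,
                               min_novel_len = 100L) {
  ann <- classify_expressed(annotations, rna, c_min = c_min)
  trimmed <- trim_boundaries(ann, rna, t_rel = t_rel, max_ext = max_ext)
  merged <- merge_units(trimmed, rna, t = merge_t)
  novel <- detect_novel(rna, merged, t = novel_t, min_len = min_novel_len)
  units <- data.table::rbindlist(list(merged, novel), fill = TRUE)
  units <- units[order(units$start), ]
  list(units = units, annotations = ann,
       summary = summarize_units(units, ann))
}
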