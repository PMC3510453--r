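#' Detect alternating extrema in a smoothed track
#'
#' Scans the smoothed signal for local maxima and minima. Runs of equal
#' value (plateaus) are collapsed to a single position at the run center
#' (left-of-center when the run has even length). On circular replicons the
#' scan wraps the origin, so the returned sequence alternates max/min all
#' the way around; on linear tracks the boundary runs are classified against
#' their single neighbor.
#'
#' @param smoothed A [smoothed_track()] (any `CoverageTrack` works).
#' @return data.table with `pos` (0-based) and `type` (`"max"`/`"min"`), in
#'   scan order from the lowest position after any wrap rotation. A constant
#'   track yields zero rows with a warning.
#' @export
find_extrema <- function(smoothed) {
  x <- smoothed$values
  n <- length(x)
  if (n < 3L) stop("track too short for extrema detection")
  circular <- smoothed$replicon$circular
  if (length(unique(x)) == 1L) {
    warning("constant track: no extrema")
    return(data.table::data.table(pos = integer(), type = character()))
  }
  rot <- 0L
  if (circular && x[1] == x[n]) {
    # rotate so no plateau straddles the origin
    brk <- which(x != c(x[n], x[-n]))[1]   # first run boundary, 1-based
    rot <- brk - 1L
    x <- c(x[brk:n], x[seq_len(brk - 1L)])
  }
  r <- rle(x)
  v <- r$values
  m <- length(v)
  ends <- cumsum(r$lengths)            # 1-based run ends
  starts <- ends - r$lengths           # 0-based run starts
  centers <- starts + (r$lengths - 1L) %/% 2L
  if (circular) {
    prev <- v[c(m, seq_len(m - 1L))]
    nxt <- v[c(seq_len(m - 1L) + 1L, 1L)]
    is_max <- v > prev & v > nxt
    is_min <- v < prev & v < nxt
  } else {
    prev <- c(NA, v[-m])
    nxt <- c(v[-1], NA)
    is_max <- (is.na(prev) | v > prev) & (is.na(nxt) | v > nxt)
    is_min <- (is.na(prev) | v < prev) & (is.na(nxt) | v < nxt)
  }
  keep <- is_max | is_min
  out <- data.table::data.table(
    pos = wrap0(centers[keep] + rot, n),
    type = ifelse(is_max[keep], "max", "min"))
  if (rot != 0L) out <- out[order(out$pos), ]
  out
}

#' Call nucleosome midpoints from a smoothed track
#'
#' Every retained local maximum becomes one nucleosome call whose midpoint
#' (dyad) is the peak position; the flanking minima bound the call and the
#' prominence is `peak - max(left trough, right trough)`. By default every
#' maximum is kept — peak magnitude is not considered — because even shallow
#' oscillations in the protection signal mark real nucleosomes at this
#' spacing. With `min_prominence > 0`, shallow peaks are merged into their
#' neighbors by removing the peak together with its shallower flanking
#' trough (lowest-prominence first), which keeps the max/min alternation
#' intact.
#'
#' @param smoothed A [smoothed_track()].
#' @param min_prominence Minimum prominence to retain a call (default 0).
#' @return data.table with chrom, midpoint, peak_value, left_trough,
#'   right_trough, trough values and prominence, ordered by midpoint.
#' @export
call_nucleosomes <- function(smoothed, min_prominence = 0) {
  ext <- find_extrema(smoothed)
  empty <- data.table::data.table(
    chrom = character(), midpoint = integer(), peak_value = numeric(),
    left_trough = integer(), right_trough = integer(),
    left_value = numeric(), right_value = numeric(), prominence = numeric())
  if (nrow(ext) < 2L) return(empty)
  x <- smoothed$values
  n <- length(x)
  circular <- smoothed$replicon$circular
  pos <- ext$pos
  typ <- ext$type
  if (!circular) {
    # drop unmatched boundary extrema so the sequence starts/ends usably
    # (interior alternation is guaranteed by construction)
  }
  repeat {
    k <- length(pos)
    imax <- which(typ == "max")
    if (!length(imax)) break
    left_i <- ifelse(imax - 1L >= 1L, imax - 1L, if (circular) k else NA)
    right_i <- ifelse(imax + 1L <= k, imax + 1L, if (circular) 1L else NA)
    lv <- ifelse(is.na(left_i), -Inf, x[pos[left_i] + 1L])
    rv <- ifelse(is.na(right_i), -Inf, x[pos[right_i] + 1L])
    prom <- x[pos[imax] + 1L] - pmax(lv, rv)
    if (min_prominence <= 0 || all(prom >= min_prominence) ||
        length(imax) == 1L) break
    worst <- imax[which.min(prom)]
    wl <- if (worst - 1L >= 1L) worst - 1L else if (circular) k else NA
    wr <- if (worst + 1L <= k) worst + 1L else if (circular) 1L else NA
    # remove the peak and its shallower (higher-valued) flanking trough
    cand <- c(wl, wr)
    cand <- cand[!is.na(cand)]
    shallower <- cand[which.max(x[pos[cand] + 1L])]
    drop <- c(worst, shallower)
    pos <- pos[-drop]
    typ <- typ[-drop]
  }
  k <- length(pos)
  imax <- which(typ == "max")
  if (!length(imax)) return(empty)
  left_i <- ifelse(imax - 1L >= 1L, imax - 1L, if (circular) k else NA)
  right_i <- ifelse(imax + 1L <= k, imax + 1L, if (circular) 1L else NA)
  out <- data.table::data.table(
    chrom = smoothed$replicon$name,
    midpoint = pos[imax],
    peak_value = x[pos[imax] + 1L],
    left_trough = ifelse(is.na(left_i), NA_integer_, pos[left_i]),
    right_trough = ifelse(is.na(right_i), NA_integer_, pos[right_i]),
    left_value = ifelse(is.na(left_i), NA_real_, x[pos[left_i] + 1L]),
    right_value = ifelse(is.na(right_i), NA_real_, x[pos[right_i] + 1L]))
  out$prominence <- out$peak_value -
    pmax(ifelse(is.na(out$left_value), -Inf, out$left_value),
         ifelse(is.na(out$right_value), -Inf, out$right_value))
  out[order(out$midpoint), ]
}

#' Call dyads from protected fragments (standard recipe)
#'
#' The dyad-resolution calling recipe: fragment **midpoint** coverage is
#' Gaussian-smoothed and every peak with prominence at least
#' `min_prominence_frac` times the track mean becomes a call. Midpoint
#' coverage concentrates each fragment's evidence at its center, so peaks
#' sit on the dyad itself rather than on the flat top of the full-fragment
#' pileup, whose maxima drift where coverage is one-sided (e.g. beside
#' NDRs). The relative prominence floor suppresses counting-noise maxima
#' and scales with sequencing depth; set it to 0 to keep every maximum.
#'
#' @param fragments Fragment table (see [read_bed()]).
#' @param repl The [replicon()].
#' @param M Gaussian bandwidth in bp (default 27).
#' @param min_prominence_frac Prominence floor as a fraction of the mean
#'   smoothed midpoint coverage (default 0.5).
#' @return List with `calls` (as [call_nucleosomes()]), `smoothed` (the
#'   smoothed midpoint track) and `min_prominence` used.
#' @export
call_dyads <- function(fragments, repl, M = 27L, min_prominence_frac = 0.5) {
  cov <- fragments_to_coverage(fragments, repl, mode = "midpoint")
  sm <- convolve_track(cov, gaussian_kernel(M))
  mp <- min_prominence_frac * mean(sm$values)
  list(calls = call_nucleosomes(sm, min_prominence = mp),
       smoothed = sm, min_prominence = mp)
}

#' Peak-to-peak spacing statistics, stratified by region class
#'
#' The distance between consecutive called midpoints estimates the
#' nucleosome repeat length. A distance is attributed to a class (genic or
#' non-genic) only when both flanking midpoints fall in intervals of that
#' class; pairs straddling a class boundary are excluded. On circular
#' replicons the wrap-around pair (last to first midpoint) is included.
#'
#' @param calls data.table from [call_nucleosomes()].
#' @param regions data.table from [build_regions()] (start, end, class
#'   partitioning the replicon).
#' @param repl The [replicon()] the calls live on.
#' @return data.table with class, n (spacings used), mean, median, sd.
#'   Classes with fewer than 2 usable calls are reported with n = 0 and NA
#'   statistics.
#' @export
peak_spacing <- function(calls, regions, repl) {
  classes <- sort(unique(regions$class))
  empty <- data.table::data.table(class = classes, n = 0L, mean = NA_real_,
                                  median = NA_real_, sd = NA_real_)
  if (nrow(calls) < 2L) return(empty)
  mid <- sort(calls$midpoint)
  d <- diff(mid)
  a <- mid[-length(mid)]
  b <- mid[-1]
  if (repl$circular) {
    d <- c(d, repl$length - mid[length(mid)] + mid[1])
    a <- c(a, mid[length(mid)])
    b <- c(b, mid[1])
  }
  cls_a <- region_class(regions, a)
  cls_b <- region_class(regions, b)
  same <- !is.na(cls_a) & cls_a == cls_b
  out <- lapply(classes, function(cl) {
    dd <- d[same & cls_a == cl]
    data.table::data.table(
      class = cl, n = length(dd),
      mean = if (length(dd)) mean(dd) else NA_real_,
      median = if (length(dd)) stats::median(dd) else NA_real_,
      sd = if (length(dd) > 1L) stats::sd(dd) else NA_real_)
  })
  data.table::rbindlist(out)
}

# class of each 0-based position under a sorted partition of [0, L)
region_class <- function(regions, pos) {
  regions <- regions[order(regions$start), ]
  idx <- findInterval(pos, regions$start)
  ok <- idx >= 1L & pos < regions$end[pmax(idx, 1L)]
  cls <- rep(NA_character_, length(pos))
  cls[ok] <- regions$class[idx[ok]]
  cls
}

#' Nucleosome density in calls per kilobase
#'
#' @param calls data.table of calls (or anything with `nrow`).
#' @param repl The [replicon()].
#' @return Calls per kb.
#' @export
nucleosome_density <- function(calls, repl) {
  stopifnot(repl$length > 0L)
  nrow(calls) / (repl$length / 1000)
}

#' Normalize occupancy into occupied / depleted / transition states
#'
#' Between each adjacent pair of extrema (peak-to-trough segment) the
#' smoothed signal is min-max rescaled to `[0, 1]`; bases at or above
#' `theta_occ` are occupied, at or below `theta_dep` depleted, anything
#' between is in transition. Segment-wise rescaling makes the states
#' invariant to coverage-depth differences along the genome. A flat segment
#' has no dynamic range and is assigned wholly to transition (with a
#' warning).
#'
#' The numeric encoding is occupied = 1, depleted = 0, transition = 0.5.
#'
#' @param smoothed A [smoothed_track()].
#' @param calls Calls from [call_nucleosomes()]; their midpoints and troughs
#'   define the segment boundaries.
#' @param theta_occ,theta_dep Occupied / depleted thresholds on the rescaled
#'   signal, defaults 2/3 and 1/3.
#' @return List with `replicon`, numeric `states` vector in {1, 0.5, 0} and
#'   the thresholds used.
#' @export
occupancy_states <- function(smoothed, calls, theta_occ = 2/3,
                             theta_dep = 1/3) {
  stopifnot(theta_dep <= theta_occ)
  x <- smoothed$values
  n <- length(x)
  b <- sort(unique(c(calls$midpoint,
                     calls$left_trough[!is.na(calls$left_trough)],
                     calls$right_trough[!is.na(calls$right_trough)])))
  states <- rep(0.5, n)
  if (length(b) >= 2L) {
    circular <- smoothed$replicon$circular
    segs <- if (circular) cbind(b, c(b[-1], b[1] + n))
            else cbind(b[-length(b)], b[-1])
    flat <- FALSE
    for (s in seq_len(nrow(segs))) {
      idx0 <- segs[s, 1]:segs[s, 2]          # 0-based, may exceed n (wrap)
      idx <- wrap0(idx0, n) + 1L
      seg <- x[idx]
      rng <- range(seg)
      if (rng[1] == rng[2]) { flat <- TRUE; next }  # stays transition
      z <- (seg - rng[1]) / (rng[2] - rng[1])
      st <- ifelse(z >= theta_occ, 1, ifelse(z <= theta_dep, 0, 0.5))
      states[idx] <- st
    }
    if (flat) warning("flat segment(s) assigned to transition")
  } else {
    warning("fewer than 2 segment boundaries: whole track is transition")
  }
  list(replicon = smoothed$replicon, states = states,
       theta_occ = theta_occ, theta_dep = theta_dep)
}

#' Partition a replicon into genic and non-genic regions
#'
#' Genic regions are expressed transcript spans extended 40 bp (the average
#' promoter length in this organism) upstream of the 5' end, strand-aware;
#' overlapping extensions are merged. Everything else is non-genic, so the
#' two classes partition the replicon.
#'
#' @param units data.table with start, end (0-based half-open) and strand;
#'   units without strand are excluded with a warning.
#' @param repl The [replicon()].
#' @param upstream Upstream extension in bp (default 40).
#' @return data.table with start, end, class (`"genic"` / `"non_genic"`)
#'   covering every base exactly once.
#' @export
build_regions <- function(units, repl, upstream = 40L) {
  units <- data.table::as.data.table(units)
  L <- repl$length
  no_strand <- !(units$strand %in% c("+", "-"))
  if (any(no_strand)) {
    warning(sum(no_strand), " unit(s) without strand excluded from regions")
    units <- units[!no_strand, ]
  }
  if (nrow(units) == 0L)
    return(data.table::data.table(start = 0L, end = L, class = "non_genic"))
  s <- ifelse(units$strand == "+", units$start - upstream, units$start)
  e <- ifelse(units$strand == "+", units$end, units$end + upstream)
  # resolve wrap on circular replicons by splitting; clip on linear
  iv <- split_wrap(s, e, L, repl$circular)
  red <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  gs <- IRanges::start(red) - 1L
  ge <- IRanges::end(red)
  genic <- data.table::data.table(start = gs, end = ge, class = "genic")
  gap <- IRanges::gaps(red, start = 1L, end = L)
  non <- data.table::data.table(start = IRanges::start(gap) - 1L,
                                end = IRanges::end(gap),
                                class = "non_genic")
  out <- rbind(genic, non)
  out[order(out$start), ]
}

# clip or wrap raw (possibly out-of-bounds) intervals onto [0, L)
split_wrap <- function(s, e, L, circular) {
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)) {
    si <- s[i]; ei <- e[i]
    if (!circular) {
      si <- max(si, 0L); ei <- min(ei, L)
      if (si < ei) { out_s <- c(out_s, si); out_e <- c(out_e, ei) }
      next
    }
    if (ei - si >= L) { out_s <- c(out_s, 0L); out_e <- c(out_e, L); next }
    si2 <- wrap0(si, L)
    ei2 <- si2 + (ei - si)
    if (ei2 <= L) {
      out_s <- c(out_s, si2); out_e <- c(out_e, ei2)
    } else {
      out_s <- c(out_s, si2, 0L); out_e <- c(out_e, L, ei2 - L)
    }
  }
  list(start = as.integer(out_s), end = as.integer(out_e))
}
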