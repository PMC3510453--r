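#' Extract fixed-width sequence windows centered on nucleosome midpoints
#'
#' Windows are taken on the forward genome strand,
#' `sequence[midpoint - halfwidth .. midpoint + halfwidth]`, wrapping the
#' origin on circular replicons. The default halfwidth of 30 bp reflects the
#' ~60 bp that an archaeal histone tetramer protects. Windows containing `N`
#' are dropped and counted. With `symmetrize = TRUE` each window is paired
#' with its reverse complement (both orientations enter the counts), for
#' users wanting palindromic dyad statistics.
#'
#' @param repl A [replicon()] carrying its sequence.
#' @param calls data.table with a `midpoint` column (0-based).
#' @param halfwidth Half window width in bp (default 30).
#' @param symmetrize Also include reverse complements (default FALSE).
#' @return List with `windows` (character vector, uniform length
#'   `2*halfwidth + 1`), `halfwidth`, and `n_dropped` (windows lost to N).
#' @export
extract_dyad_windows <- function(repl, calls, halfwidth = 30L,
                                 symmetrize = FALSE) {
  if (is.null(repl$sequence)) stop("replicon '", repl$name, "' has no sequence")
  halfwidth <- as.integer(halfwidth)
  L <- repl$length
  w <- 2L * halfwidth + 1L
  if (w > L) stop("window wider than replicon")
  mids <- as.integer(calls$midpoint)
  starts <- mids - halfwidth
  if (repl$circular) {
    ext <- paste0(repl$sequence, substr(repl$sequence, 1L, w))
    starts <- wrap0(starts, L)
    windows <- substring(ext, starts + 1L, starts + w)
  } else {
    ok <- starts >= 0L & (starts + w) <= L
    if (any(!ok))
      warning(sum(!ok), " window(s) beyond linear replicon ends dropped")
    windows <- substring(repl$sequence, starts[ok] + 1L, starts[ok] + w)
  }
  has_n <- grepl("N", windows, fixed = TRUE)
  n_dropped <- sum(has_n)
  windows <- windows[!has_n]
  if (symmetrize && length(windows)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(windows)))
    windows <- c(windows, rc)
  }
  list(windows = windows, halfwidth = halfwidth, n_dropped = n_dropped)
}

#' Position-wise nucleotide and dinucleotide composition of dyad windows
#'
#' Counts A/C/G/T at each window offset, the 16 dinucleotides at each offset
#' (dinucleotide position i = bases i and i+1), the per-position GC
#' fraction, the position probability matrix, and the grouped weak
#' (W = AA+AT+TA+TT) and strong (S = CC+CG+GC+GG) dinucleotide series.
#'
#' @param dyad_windows Result of [extract_dyad_windows()], or a character
#'   vector of equal-length windows.
#' @return List of class `PositionCompositionTable` with `offsets`,
#'   `counts` (4 x W matrix), `probs`, `gc` (per-position fraction),
#'   `dinuc_counts` (16 x (W-1)), `W`, `S`, `n_windows`.
#' @export
composition_table <- function(dyad_windows) {
  windows <- if (is.list(dyad_windows)) dyad_windows$windows else dyad_windows
  if (!length(windows)) stop("no windows to tabulate")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("windows differ in length")
  halfwidth <- (wlen - 1L) %/% 2L
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  nwin <- length(windows)
  if (any(colSums(counts) != nwin))
    stop("windows contain non-ACGT characters")
  probs <- counts / nwin
  gc <- (counts["C", ] + counts["G", ]) / nwin
  # dinucleotide counts from the character matrix of the windows
  chm <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                nrow = nwin, byrow = TRUE)
  dn <- matrix(paste0(chm[, -wlen], chm[, -1]), nrow = nwin)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  dinuc_counts <- vapply(seq_len(wlen - 1L), function(j)
    tabulate(match(dn[, j], dinucs), nbins = 16L), integer(16L))
  rownames(dinuc_counts) <- dinucs
  offsets <- (-halfwidth):halfwidth
  Wgrp <- colSums(dinuc_counts[c("AA", "AT", "TA", "TT"), , drop = FALSE])
  Sgrp <- colSums(dinuc_counts[c("CC", "CG", "GC", "GG"), , drop = FALSE])
  structure(list(offsets = offsets, counts = counts, probs = probs, gc = gc,
                 dinuc_counts = dinuc_counts, W = Wgrp, S = Sgrp,
                 n_windows = nwin),
            class = "PositionCompositionTable")
}

#' GC gradient from fragment edge to dyad
#'
#' Summarizes the per-position GC curve of a composition table as the GC
#' fraction at the window center (the dyad) versus the mean GC of the two
#' outermost positions (the protected-fragment edges).
#'
#' @param table A [composition_table()] result.
#' @return List with `gc_midpoint`, `gc_edge`, `delta`
#'   (midpoint minus edge) and the full `curve` (data.table offset, gc).
#' @export
gc_gradient <- function(table) {
  gc <- table$gc
  mid_i <- which(table$offsets == 0L)
  gc_mid <- gc[mid_i]
  gc_edge <- mean(gc[c(1L, length(gc))])
  list(gc_midpoint = unname(gc_mid), gc_edge = gc_edge,
       delta = unname(gc_mid) - gc_edge,
       curve = data.table::data.table(offset = table$offsets, gc = gc))
}

#' Per-position information content of dyad windows
#'
#' Under a uniform background, `IC_i = 2 + sum_b p_ib log2 p_ib` bits
#' (0 to 2). Under the `genome_gc` background, the relative entropy of the
#' position distribution against the genome's base composition, which is 0
#' exactly when the position matches the background. `0*log(0)` is taken
#' as 0.
#'
#' @param table A [composition_table()] result.
#' @param background `"uniform"` or `"genome_gc"`.
#' @param genome_probs Length-4 probability vector (A, C, G, T) of the
#'   genome; required for `genome_gc`.
#' @return Numeric vector of bits per window position.
#' @export
information_content <- function(table, background = c("uniform", "genome_gc"),
                                genome_probs = NULL) {
  background <- match.arg(background)
  p <- table$probs
  plog <- function(x) ifelse(x > 0, x * log2(x), 0)
  if (background == "uniform") {
    ic <- 2 + colSums(plog(p))
  } else {
    if (is.null(genome_probs) || length(genome_probs) != 4L ||
        abs(sum(genome_probs) - 1) > 1e-8)
      stop("genome_gc background needs genome_probs summing to 1 (A,C,G,T)")
    q <- matrix(genome_probs, nrow = 4L, ncol = ncol(p))
    ic <- colSums(ifelse(p > 0, p * log2(p / q), 0))
  }
  unname(ic)
}

#' Permutation test for dinucleotide periodicity around the dyad
#'
#' Tests whether a per-position dinucleotide frequency series oscillates
#' with a period in `period_range` (default 9-11 bp, bracketing the ~10-bp
#' helical repeat seen in some histone-DNA systems). The series is
#' linearly detrended and prewhitened at lag one before testing:
#' dinucleotide indicators at adjacent positions share a base, which gives
#' the null series positive lag-1 autocorrelation and would otherwise make
#' a plain position-permutation test anticonservative in this frequency
#' band. (Lag-one whitening cannot itself generate or remove a ~10-bp
#' oscillation: an AR(1) spectrum peaks only at frequency 0 or 1/2.)
#' Spectral power is then summed over a grid of periods inside the window,
#' and the p-value is the fraction of position-permuted whitened series
#' with power at least as large (exact-rank, `(b+1)/(n+1)`).
#'
#' @param series Numeric per-position frequency series.
#' @param period_range Length-2 numeric, period window in bp.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `power` (observed), `best_period`, `p_value`, `n_perm`.
#' @export
periodicity_test <- function(series, period_range = c(9, 11), n_perm = 999L,
                             seed = 1L) {
  series <- as.numeric(series)
  L <- length(series)
  if (L < 3 * max(period_range))
    stop("series too short: need length >= 3x the longest period")
  idx <- seq_len(L)
  resid <- stats::lm.fit(cbind(1, idx), series)$residuals
  # lag-one prewhitening (Yule-Walker AR(1))
  phi <- sum(resid[-1] * resid[-L]) / sum(resid^2)
  phi <- max(min(phi, 0.95), -0.95)
  resid <- resid[-1] - phi * resid[-L]
  L <- L - 1L
  idx <- seq_len(L)
  periods <- seq(period_range[1], period_range[2], by = 0.5)
  # complex exponential basis at the tested periods
  basis <- exp(-2i * pi * outer(idx, 1 / periods))
  pow <- function(x) Mod(crossprod(basis, x))^2 / L
  obs <- pow(resid)
  obs_total <- sum(obs)
  old <- .Random.seed_safe()
  set.seed(as.integer(seed))
  perm_mat <- vapply(seq_len(n_perm), function(i) resid[sample.int(L)],
                     numeric(L))
  .Random.seed_restore(old)
  perm_pow <- colSums(Mod(crossprod(basis, perm_mat))^2 / L)
  p <- (1 + sum(perm_pow >= obs_total)) / (n_perm + 1)
  list(power = obs_total, best_period = periods[which.max(obs)],
       p_value = p, n_perm = as.integer(n_perm))
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's random stream
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
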