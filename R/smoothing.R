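#' Discrete Gaussian smoothing kernel
#'
#' The kernel samples the Gaussian density
#' \deqn{G(x) = \frac{1}{\sqrt{2\pi}\sigma} e^{-x^2 / 2\sigma^2}}
#' at integer offsets `j = -floor(M/2) .. +floor(M/2)` with `sigma = M/6`,
#' then renormalizes the weights to sum exactly to 1 so that smoothing
#' preserves the track mean. The bandwidth `M` is tied to `6*sigma` because
#' that interval holds essentially all (99.73%) of the Gaussian mass, so
#' truncation at the window edge discards almost nothing.
#'
#' @param M Integer bandwidth in bp, `M >= 2`.
#' @return Object of class `GaussianKernel` with fields `M`, `sigma`,
#'   `offsets` and normalized `weights`.
#' @export
gaussian_kernel <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("M must be an integer >= 2")
  sigma <- M / 6
  half <- M %/% 2L
  j <- (-half):half
  w <- exp(-j^2 / (2 * sigma^2))
  w <- w / sum(w)
  structure(list(M = M, sigma = sigma, offsets = j, weights = w),
            class = "GaussianKernel")
}

#' @export
print.GaussianKernel <- function(x, ...) {
  cat(sprintf("<GaussianKernel> M=%d, sigma=%.4g, %d weights\n",
              x$M, x$sigma, length(x$weights)))
  invisible(x)
}

#' Uniform (simple moving average) kernel
#'
#' @param w Window width in bp, `w >= 2`. The realized window is symmetric
#'   with `floor(w/2)` offsets per side.
#' @return Object of class `SMAKernel`.
#' @export
sma_kernel <- function(w) {
  w <- as.integer(w)
  if (is.na(w) || w < 2L) stop("window must be an integer >= 2")
  half <- w %/% 2L
  j <- (-half):half
  structure(list(M = w, offsets = j,
                 weights = rep(1 / length(j), length(j))),
            class = "SMAKernel")
}

kernel_desc <- function(kernel) {
  if (inherits(kernel, "GaussianKernel"))
    sprintf("gaussian(M=%d, sigma=%.4g)", kernel$M, kernel$sigma)
  else sprintf("sma(w=%d)", kernel$M)
}

#' Symmetric convolution of a coverage track
#'
#' Computes the convolution sum `y[i] = sum_j h[j] * x[i - j]` over the
#' kernel's symmetric offset range. Edge handling:
#' \describe{
#'   \item{wrap}{indexes modulo the track length — the correct treatment on
#'     circular replicons, where position 0 is adjacent to position L-1;}
#'   \item{renormalize}{truncates the kernel at linear track ends and
#'     divides by the in-bounds weight mass, so a constant track stays
#'     constant at the edges.}
#' }
#'
#' @param track A [coverage_track()].
#' @param kernel A [gaussian_kernel()] or [sma_kernel()].
#' @param edge `"wrap"` or `"renormalize"`; default follows the replicon's
#'   circularity flag.
#' @return A [smoothed_track()].
#' @export
convolve_track <- function(track, kernel, edge = NULL) {
  stopifnot(inherits(track, "CoverageTrack"))
  x <- track$values
  n <- length(x)
  w <- kernel$weights
  k <- length(w)
  if (k > n) stop("kernel (", k, " taps) longer than track (", n, " bp)")
  if (is.null(edge))
    edge <- if (track$replicon$circular) "wrap" else "renormalize"
  edge <- match.arg(edge, c("wrap", "renormalize"))
  # kernels are symmetric, so stats::filter's orientation is immaterial
  if (edge == "wrap") {
    y <- as.numeric(stats::filter(x, w, method = "convolution",
                                  sides = 2, circular = TRUE))
  } else {
    half <- (k - 1L) %/% 2L
    pad <- numeric(half)
    xp <- c(pad, x, pad)
    mp <- c(pad, rep(1, n), pad)
    num <- as.numeric(stats::filter(xp, w, method = "convolution",
                                    sides = 2, circular = FALSE))
    den <- as.numeric(stats::filter(mp, w, method = "convolution",
                                    sides = 2, circular = FALSE))
    idx <- (half + 1L):(half + n)
    y <- num[idx] / den[idx]
  }
  smoothed_track(track$replicon, y, kernel_desc(kernel))
}

#' Two-pass simple moving average smoothing
#'
#' Applies a uniform-weight kernel twice (defaults 40 bp then 15 bp), the
#' moving-average alternative to the Gaussian filter. Equivalent to a single
#' convolution with the composition of the two box kernels.
#'
#' @param track A [coverage_track()].
#' @param w1,w2 First- and second-pass window widths in bp.
#' @inheritParams convolve_track
#' @return A [smoothed_track()].
#' @export
two_pass_sma <- function(track, w1 = 40L, w2 = 15L, edge = NULL) {
  s1 <- convolve_track(track, sma_kernel(w1), edge = edge)
  s2 <- convolve_track(coverage_track_like(s1), sma_kernel(w2), edge = edge)
  smoothed_track(track$replicon, s2$values,
                 sprintf("sma2(w1=%d, w2=%d)", as.integer(w1), as.integer(w2)))
}

# reuse a smoothed track as input to another convolution pass
coverage_track_like <- function(tr) {
  structure(list(replicon = tr$replicon, values = tr$values),
            class = "CoverageTrack")
}

#' Pearson correlation between two tracks
#'
#' Standard product-moment correlation over all positions. A constant track
#' has no defined correlation and raises an error rather than returning 0.
#'
#' @param a,b Tracks (or numeric vectors) of equal length >= 3.
#' @return List with `r` and `n`.
#' @export
track_pearson <- function(a, b) {
  av <- if (is.list(a)) a$values else as.numeric(a)
  bv <- if (is.list(b)) b$values else as.numeric(b)
  if (length(av) != length(bv)) stop("tracks differ in length")
  if (length(av) < 3L) stop("need at least 3 positions")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("correlation undefined: at least one track is constant")
  list(r = stats::cor(av, bv), n = length(av))
}

#' Choose the Gaussian bandwidth by correlation with the raw signal
#'
#' Correlation with the raw track is maximized by no smoothing at all, so
#' "optimal" cannot mean maximal r. The rule used here: evaluate
#' `r(raw, smoothed_M)` for every candidate and return the **largest** M
#' whose correlation still meets `r_min` — the strongest smoothing that
#' still tracks the raw signal.
#'
#' @param track A [coverage_track()].
#' @param candidates Integer vector of candidate bandwidths.
#' @param r_min Minimum acceptable correlation with the raw track.
#' @inheritParams convolve_track
#' @return List with `M` (chosen) and `table` (data.table of M, r).
#' @export
select_window <- function(track, candidates, r_min = 0.85, edge = NULL) {
  if (!length(candidates)) stop("no candidate bandwidths")
  candidates <- sort(unique(as.integer(candidates)))
  r <- vapply(candidates, function(M) {
    sm <- convolve_track(track, gaussian_kernel(M), edge = edge)
    track_pearson(track, sm)$r
  }, numeric(1))
  tab <- data.table::data.table(M = candidates, r = r)
  ok <- which(r >= r_min)
  if (!length(ok)) {
    stop("no candidate M reaches r_min = ", r_min, "; best was M = ",
         candidates[which.max(r)], " with r = ",
         formatC(max(r), digits = 4, format = "f"))
  }
  list(M = candidates[max(ok)], table = tab)
}
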