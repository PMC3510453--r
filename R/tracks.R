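#' Replicon descriptor
#'
#' A replicon is one DNA molecule of the genome: a named sequence of known
#' length with a circularity flag. Haloarchaeal genomes are collections of
#' circular replicons, so `circular = TRUE` is the default; linear contigs
#' are supported for generality.
#'
#' @param name Character scalar, unique identifier of the replicon.
#' @param length Positive integer length in bp.
#' @param circular Logical, whether coordinates wrap at the origin.
#' @param sequence Optional nucleotide string over `A,C,G,T,N`; when present
#'   its number of characters must equal `length`.
#' @return An object of class `Replicon`.
#' @export
replicon <- function(name, length, circular = TRUE, sequence = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match declared length (", length, ") for '", name, "'")
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad))
      stop("sequence of '", name, "' contains non-ACGTN characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  structure(list(name = name, length = length,
                 circular = isTRUE(circular), sequence = sequence),
            class = "Replicon")
}

#' @export
print.Replicon <- function(x, ...) {
  cat(sprintf("<Replicon> %s: %d bp, %s%s\n", x$name, x$length,
              if (x$circular) "circular" else "linear",
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

#' Per-base coverage track
#'
#' Holds one non-negative real value per base of a replicon (0-based
#' positions internally). This is the raw signal `x[i]` that all smoothing
#' and peak calling operate on.
#'
#' @param repl A [replicon()].
#' @param values Numeric vector, one finite value >= 0 per base.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(repl, values) {
  stopifnot(inherits(repl, "Replicon"))
  values <- as.numeric(values)
  if (length(values) != repl$length)
    stop("values length (", length(values), ") != replicon length (",
         repl$length, ")")
  if (anyNA(values) || any(!is.finite(values)))
    stop("coverage values must be finite")
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(replicon = repl, values = values), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("<CoverageTrack> %s (%d bp): mean %.3f, max %.3f\n",
              x$replicon$name, x$replicon$length,
              mean(x$values), max(x$values)))
  invisible(x)
}

#' Smoothed coverage track
#'
#' The output `y[i]` of a convolution, carrying a description of the kernel
#' that produced it so downstream tables are self-documenting.
#'
#' @param repl A [replicon()].
#' @param values Numeric vector of smoothed values.
#' @param kernel_desc Character scalar describing kernel type and parameters.
#' @return An object of class `SmoothedTrack` (also a `CoverageTrack`-like
#'   list with `$values`).
#' @export
smoothed_track <- function(repl, values, kernel_desc) {
  stopifnot(inherits(repl, "Replicon"))
  values <- as.numeric(values)
  if (length(values) != repl$length)
    stop("values length != replicon length")
  if (anyNA(values) || any(!is.finite(values)))
    stop("smoothed values must be finite")
  structure(list(replicon = repl, values = values,
                 kernel_desc = as.character(kernel_desc)[1]),
            class = c("SmoothedTrack", "CoverageTrack"))
}

#' @export
print.SmoothedTrack <- function(x, ...) {
  cat(sprintf("<SmoothedTrack> %s (%d bp), kernel: %s\n",
              x$replicon$name, x$replicon$length, x$kernel_desc))
  invisible(x)
}

# wrap a 0-based position onto [0, len) for circular replicons
wrap0 <- function(pos, len) ((pos %% len) + len) %% len
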