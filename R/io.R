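#' Read a genome FASTA into replicons
#'
#' Sequences are upper-cased; characters outside `A,C,G,T,N` are an error.
#' Circularity is not expressible in FASTA, so it is supplied here (default
#' circular, the native state of this organism's replicons) or per-replicon
#' via a named logical vector.
#'
#' @param path FASTA file.
#' @param circular Logical scalar or named logical vector (names = record
#'   ids) marking circular replicons.
#' @return Named list of [replicon()] objects, in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(list())
  }
  nms <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    circ <- if (length(circular) > 1L || !is.null(names(circular))) {
      if (nms[i] %in% names(circular)) circular[[nms[i]]] else TRUE
    } else circular
    out[[i]] <- replicon(nms[i], Biostrings::nchar(seqs[i]),
                         circular = circ,
                         sequence = as.character(seqs[[i]]))
  }
  names(out) <- nms
  if (anyDuplicated(nms)) stop("duplicate replicon names in ", path)
  out
}

#' Write replicons to FASTA
#'
#' @param replicons Named list of [replicon()] objects with sequences.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(replicons, path, width = 70L) {
  seqs <- vapply(replicons, function(r) {
    if (is.null(r$sequence)) stop("replicon '", r$name, "' has no sequence")
    r$sequence
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- vapply(replicons, `[[`, character(1), "name")
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a bedGraph file into per-base coverage tracks
#'
#' bedGraph intervals are 0-based half-open; uncovered bases are 0 and
#' overlapping intervals are summed.
#'
#' @param path bedGraph file (4 columns, no track line).
#' @param replicons Named list of [replicon()] objects; every interval must
#'   name one of them and fit inside it.
#' @return Named list of [coverage_track()], one per replicon (zero tracks
#'   for replicons with no intervals).
#' @export
read_bedgraph <- function(path, replicons) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1, integer = 2:3,
                                            numeric = 4))
  known <- names(replicons)
  bad <- setdiff(unique(dt$chrom), known)
  if (length(bad))
    stop("unknown replicon(s) ", paste(bad, collapse = ", "),
         " in ", path, "; known: ", paste(known, collapse = ", "))
  out <- lapply(replicons, function(r) {
    d <- dt[dt$chrom == r$name, ]
    if (nrow(d) && (any(d$start < 0L) || any(d$end > r$length) ||
                    any(d$start >= d$end)))
      stop("interval outside replicon '", r$name, "' (length ",
           r$length, ") in ", path)
    vals <- numeric(r$length)
    if (nrow(d)) {
      cov <- IRanges::coverage(IRanges::IRanges(d$start + 1L, d$end),
                               weight = d$value, width = r$length)
      vals <- as.numeric(cov)
    }
    coverage_track(r, vals)
  })
  names(out) <- known
  out
}

#' Write coverage tracks as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted so that
#' `read_bedgraph(write_bedgraph(x))` reproduces per-base values.
#'
#' @param tracks A [coverage_track()] or named list of them.
#' @param path Output file.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    r <- rle(tr$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = tr$replicon$name,
                           start = starts[keep], end = ends[keep],
                           value = fmt_num(r$values[keep]))
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer(), value = character())
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# decimal formatting with enough digits for lossless round-trip of doubles
fmt_num <- function(x) {
  i <- x == round(x) & abs(x) < 1e15
  out <- character(length(x))
  out[i] <- format(x[i], scientific = FALSE, trim = TRUE)
  out[!i] <- formatC(x[!i], digits = 17, format = "g")
  out
}

#' Read protected-fragment intervals from BED
#'
#' BED3/BED6; columns beyond the sixth are ignored. Coordinates are kept
#' 0-based half-open. Fragments wrapping the origin of a circular replicon
#' are stored as two records sharing a `wrap_id`.
#'
#' @param path BED file.
#' @return data.table with columns chrom, start, end, name, score, strand,
#'   wrap_id (NA for ordinary fragments).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end = as.integer(dt[[3]]),
    name = if (ncol(dt) >= 4L) as.character(dt[[4]]) else ".",
    score = if (ncol(dt) >= 5L) suppressWarnings(as.numeric(dt[[5]])) else 0,
    strand = if (ncol(dt) >= 6L) as.character(dt[[6]]) else ".")
  if (any(out$start < 0L) || any(out$start >= out$end))
    stop("invalid BED interval (need 0 <= start < end) in ", path)
  # wrap pairs are encoded in the name as "<id>|wrapA" / "<id>|wrapB"
  out$wrap_id <- ifelse(grepl("\\|wrap[AB]$", out$name),
                        sub("\\|wrap[AB]$", "", out$name), NA_character_)
  out
}

#' Write fragment or call intervals as BED6
#'
#' @param dt data.table/data.frame with chrom, start, end and optionally
#'   name, score, strand.
#' @param path Output file.
#' @export
write_bed <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  out <- data.table::data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) fmt_num(as.numeric(dt$score)) else "0",
    strand = if ("strand" %in% names(dt)) dt$strand else ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert protected fragments to a per-base coverage track
#'
#' `pileup` adds 1 to every base a fragment covers (the protection signal:
#' nucleosome-bound DNA escapes MNase digestion along the whole fragment);
#' `midpoint` adds 1 only at `floor((start + end - 1)/2)`, for
#' dyad-resolution work. Wrap pairs on circular replicons are treated as one
#' fragment (their midpoint is the wrapped center of the joined fragment).
#'
#' @param fragments data.table as from [read_bed()].
#' @param repl Target [replicon()].
#' @param mode `"pileup"` or `"midpoint"`.
#' @return A [coverage_track()].
#' @export
fragments_to_coverage <- function(fragments, repl, mode = c("pileup", "midpoint")) {
  mode <- match.arg(mode)
  fr <- data.table::as.data.table(fragments)
  fr <- fr[fr$chrom == repl$name, ]
  if (nrow(fr) && (any(fr$start < 0L) || any(fr$end > repl$length)))
    stop("fragment outside replicon '", repl$name, "'")
  L <- repl$length
  vals <- numeric(L)
  if (nrow(fr) == 0L) return(coverage_track(repl, vals))
  if (mode == "pileup") {
    cov <- IRanges::coverage(IRanges::IRanges(fr$start + 1L, fr$end),
                             width = L)
    vals <- as.numeric(cov)
  } else {
    is_wrap <- !is.na(fr$wrap_id)
    plain <- fr[!is_wrap, ]
    if (nrow(plain)) {
      mid <- (plain$start + plain$end - 1L) %/% 2L
      tab <- tabulate(mid + 1L, nbins = L)
      vals <- vals + tab
    }
    if (any(is_wrap)) {
      if (!repl$circular) stop("wrap pairs on a linear replicon")
      w <- fr[is_wrap, ]
      for (id in unique(w$wrap_id)) {
        pieces <- w[w$wrap_id == id, ]
        if (nrow(pieces) != 2L) stop("wrap pair '", id, "' has ",
                                     nrow(pieces), " records (need 2)")
        # the piece touching the end of the replicon starts the fragment
        a <- pieces[pieces$end == L, ]
        b <- pieces[pieces$start == 0L, ]
        if (nrow(a) != 1L || nrow(b) != 1L)
          stop("wrap pair '", id, "' does not meet at the origin")
        len <- (a$end - a$start) + (b$end - b$start)
        mid <- wrap0(a$start + (len - 1L) %/% 2L, L)
        vals[mid + 1L] <- vals[mid + 1L] + 1
      }
    }
  }
  coverage_track(repl, vals)
}

#' Read GFF3 annotations
#'
#' Coordinates are converted from GFF's 1-based closed convention to the
#' package's 0-based half-open convention at this boundary.
#'
#' @param path GFF3 file.
#' @return data.table with chrom, start, end (0-based half-open), strand,
#'   type, id and any `status` / `source_ids` attributes present.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(gr)
  dt <- data.table::data.table(
    chrom = as.character(mc$seqnames),
    start = mc$start - 1L,
    end = mc$end,
    strand = as.character(mc$strand),
    type = as.character(mc$type),
    id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_)
  if ("status" %in% names(mc)) dt$status <- as.character(mc$status)
  if ("source_ids" %in% names(mc))
    dt$source_ids <- vapply(mc$source_ids, function(x)
      paste(x, collapse = ","), character(1))
  dt
}

#' Write transcription units / annotations as GFF3
#'
#' @param units data.table with chrom, start, end (0-based half-open),
#'   strand, id and optionally type, status, source_ids, mean_coverage.
#' @param path Output file.
#' @param source Column 2 of the GFF.
#' @export
write_gff <- function(units, path, source = "tetramap") {
  units <- data.table::as.data.table(units)
  attrs <- paste0("ID=", units$id)
  if ("status" %in% names(units))
    attrs <- paste0(attrs, ";status=", units$status)
  if ("source_ids" %in% names(units)) {
    has <- !is.na(units$source_ids) & nzchar(units$source_ids)
    attrs[has] <- paste0(attrs[has], ";source_ids=", units$source_ids[has])
  }
  if ("mean_coverage" %in% names(units))
    attrs <- paste0(attrs, ";mean_coverage=",
                    formatC(units$mean_coverage, digits = 4, format = "f"))
  lines <- paste(units$chrom, source,
                 if ("type" %in% names(units)) units$type else "transcript",
                 units$start + 1L, units$end, ".",
                 ifelse(units$strand %in% c("+", "-"), units$strand, "."),
                 ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
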