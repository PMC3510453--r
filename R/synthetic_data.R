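#' Configuration for the chromatin simulator
#'
#' Default values are the study conditions the pipeline is benchmarked
#' under: a circular 65%-GC genome, mean dyad spacing 68.5 bp in genic and
#' 76.1 bp in non-genic regions, 50-60 bp protected fragments at 30x depth
#' with 3 bp midpoint jitter, 75% of annotated transcripts expressed, a
#' deeper/wider nucleosome-depleted region at the 5' end than at the 3'
#' end, and a linear GC ramp from 61% at the protected-fragment edge to 75%
#' at the dyad.
#'
#' @param seed Mandatory integer seed; every random draw of the simulator
#'   comes from this one stream.
#' @param genome_length Genome size in bp.
#' @param gc Genome-wide GC fraction.
#' @param circular Circular replicon flag.
#' @param name Replicon name.
#' @param n_transcripts Number of annotated genes.
#' @param transcript_len Length range (bp) of annotated genes.
#' @param fraction_expressed Fraction of annotated genes expressed; realized
#'   as an exact count, not per-gene coin flips.
#' @param genic_spacing,nongenic_spacing `c(mean, sd)` of dyad-to-dyad
#'   spacing (bp) by region class.
#' @param fragment_len Protected fragment length range (bp).
#' @param jitter_sd SD (bp) of fragment center around the planted dyad.
#' @param depth Target mean pileup coverage over dyad-dense regions.
#' @param ndr5,ndr3 Lists `list(width, scale, center_offset)` describing the
#'   5' and 3' NDR zones: no dyads inside the zone, background fragments at
#'   `scale` times the nucleosomal rate, zone centered `center_offset` bp
#'   from the anchor in the direction of transcription.
#' @param dyad_gc `c(edge, midpoint)` GC targets of the planted ramp.
#' @param dyad_halfwidth Half-width (bp) of the GC-resampled dyad window.
#' @param n_operons Number of operons (adjacent same-strand gene chains with
#'   read-through coverage).
#' @param operon_size Range of genes per operon.
#' @param n_novel Number of unannotated (novel) expressed units.
#' @param novel_len Length range of novel units.
#' @param rna_level Median plateau coverage of expressed units.
#' @param min_gap Minimum gap (bp) between placed units.
#' @param profile_classes Optional integer vector (e.g. `c(4, 5, 6)`): when
#'   set, each expressed unit is assigned a class and its TSS +/- 200 bp
#'   window carries exactly that many evenly spaced dyads (outside the NDR
#'   zone), producing distinct promoter occupancy profiles.
#' @param periodicity Optional `list(period, amplitude)`: plant an AA
#'   dinucleotide periodicity of that period (bp) around dyads; `amplitude`
#'   is the peak per-position probability of forcing an AA.
#' @param upstream Genic upstream extension used for region truth (bp).
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       genome_length = 200000L,
                       gc = 0.65,
                       circular = TRUE,
                       name = "chr",
                       n_transcripts = 150L,
                       transcript_len = c(500L, 1100L),
                       fraction_expressed = 0.75,
                       genic_spacing = c(68.5, 6),
                       nongenic_spacing = c(76.1, 8),
                       fragment_len = c(50L, 60L),
                       jitter_sd = 3,
                       depth = 30,
                       ndr5 = list(width = 120L, scale = 0.05,
                                   center_offset = -50L),
                       ndr3 = list(width = 70L, scale = 0.30,
                                   center_offset = 20L),
                       dyad_gc = c(0.61, 0.75),
                       dyad_halfwidth = 30L,
                       n_operons = 10L,
                       operon_size = c(2L, 4L),
                       n_novel = 5L,
                       novel_len = c(150L, 400L),
                       rna_level = 50,
                       min_gap = 200L,
                       profile_classes = NULL,
                       periodicity = NULL,
                       upstream = 40L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(gc > 0, gc < 1, fraction_expressed >= 0, fraction_expressed <= 1,
            transcript_len[1] <= transcript_len[2],
            fragment_len[1] <= fragment_len[2],
            operon_size[1] <= operon_size[2])
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc = gc, circular = circular, name = name,
              n_transcripts = as.integer(n_transcripts),
              transcript_len = as.integer(transcript_len),
              fraction_expressed = fraction_expressed,
              genic_spacing = genic_spacing,
              nongenic_spacing = nongenic_spacing,
              fragment_len = as.integer(fragment_len),
              jitter_sd = jitter_sd, depth = depth,
              ndr5 = ndr5, ndr3 = ndr3,
              dyad_gc = dyad_gc, dyad_halfwidth = as.integer(dyad_halfwidth),
              n_operons = as.integer(n_operons),
              operon_size = as.integer(operon_size),
              n_novel = as.integer(n_novel), novel_len = as.integer(novel_len),
              rna_level = rna_level, min_gap = as.integer(min_gap),
              profile_classes = profile_classes, periodicity = periodicity,
              upstream = as.integer(upstream))
  class(cfg) <- "SimulationConfig"
  cfg
}

# zone helpers ---------------------------------------------------------------

# oriented NDR zone [start, end) in genome coordinates
ndr_zone <- function(anchor, strand, spec, L) {
  center <- if (strand == "+") anchor + spec$center_offset
            else anchor - spec$center_offset
  half <- spec$width %/% 2L
  c(wrap_lo = center - half, wrap_hi = center - half + spec$width)
}

in_any_zone <- function(pos, zones) {
  if (!nrow(zones)) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, zones$start)
  idx >= 1L & pos < zones$end[pmax(idx, 1L)]
}

#' Simulate a chromatin + transcriptome bundle with ground truth
#'
#' Generates an i.i.d. genome at the target GC, places annotated genes
#' (some chained into operons) and unannotated novel units without overlap,
#' plants nucleosome dyads by a spacing walk whose step distribution
#' depends on the region class, carves NDR zones at the TSS and TTS of
#' expressed units, resamples dyad-window sequence along the GC ramp, draws
#' protected fragments per dyad (Poisson counts, jittered centers), emits a
#' featureless naked-DNA control of equal fragment count, and lays plateau
#' RNA-seq coverage with ragged ends over expressed and novel units.
#'
#' All randomness comes from the single seeded stream of
#' `config$seed`; re-running with the same config is bit-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   FASTA / GFF3 / BED / bedGraph / TSV files.
#' @return List with `replicon`, `annotations`, `units` (transcription-unit
#'   truth), `fragments`, `mnase` / `naked` / `rna` coverage tracks,
#'   `truth` (dyads + regions tables) and `config`.
#' @export
simulate_chromatin <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc

  ## 1. genome
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  ## 2. unit layout: operons, singleton genes, novel units
  n_gene <- config$n_transcripts
  op_sizes <- if (config$n_operons > 0L)
    sample(seq(config$operon_size[1], config$operon_size[2]),
           config$n_operons, replace = TRUE) else integer(0)
  if (sum(op_sizes) > n_gene) stop("operons need more genes than available")
  n_single <- n_gene - sum(op_sizes)
  # unit spec list: each unit = one or more genes, or one novel unit
  spec <- c(lapply(op_sizes, function(s) list(kind = "operon", n = s)),
            replicate(n_single, list(kind = "gene", n = 1L),
                      simplify = FALSE),
            replicate(config$n_novel, list(kind = "novel", n = 1L),
                      simplify = FALSE))
  spec <- spec[sample.int(length(spec))]
  # per-gene lengths and intra-operon gaps
  for (i in seq_along(spec)) {
    u <- spec[[i]]
    if (u$kind == "novel") {
      u$glens <- round(stats::runif(1, config$novel_len[1],
                                    config$novel_len[2]))
      u$igaps <- integer(0)
    } else {
      u$glens <- round(stats::runif(u$n, config$transcript_len[1],
                                    config$transcript_len[2]))
      u$igaps <- if (u$n > 1L) round(stats::runif(u$n - 1L, 20, 60))
                 else integer(0)
    }
    u$span <- sum(u$glens) + sum(u$igaps)
    spec[[i]] <- u
  }
  spans <- vapply(spec, `[[`, numeric(1), "span")
  n_units <- length(spec)
  slack <- L - sum(spans) - n_units * config$min_gap
  if (slack < 0)
    stop("infeasible packing: units + minimum gaps exceed genome length by ",
         -slack, " bp")
  gw <- stats::runif(n_units, 0.5, 1.5)
  gaps <- config$min_gap + floor(slack * gw / sum(gw))
  # place sequentially; first gap before the first unit
  pos <- 0L
  strands <- sample(c("+", "-"), n_units, replace = TRUE)
  genes <- list(); units <- list()
  gene_i <- 0L; novel_i <- 0L
  for (i in seq_len(n_units)) {
    pos <- pos + gaps[i]
    u <- spec[[i]]
    gstarts <- pos + cumsum(c(0L, u$glens[-length(u$glens)] +
                                  u$igaps))
    gends <- gstarts + u$glens
    if (u$kind == "novel") {
      novel_i <- novel_i + 1L
      units[[i]] <- data.table::data.table(
        unit_id = paste0("novel_true_", novel_i), start = gstarts,
        end = gends, strand = strands[i], kind = "novel", n_genes = 0L,
        gene_ids = NA_character_)
    } else {
      ids <- paste0("g", gene_i + seq_along(u$glens))
      gene_i <- gene_i + length(u$glens)
      genes[[length(genes) + 1L]] <- data.table::data.table(
        chrom = config$name, start = gstarts, end = gends,
        strand = strands[i], id = ids, unit_idx = i)
      units[[i]] <- data.table::data.table(
        unit_id = paste0("u", i), start = gstarts[1],
        end = gends[length(gends)], strand = strands[i],
        kind = if (u$n > 1L) "operon" else "gene", n_genes = u$n,
        gene_ids = paste(ids, collapse = ","))
    }
    pos <- units[[i]]$end
  }
  genes <- data.table::rbindlist(genes)
  units <- data.table::rbindlist(units)

  ## 3. expression: exact gene-level fraction, whole units at a time
  target <- round(config$fraction_expressed * n_gene)
  real <- which(units$kind != "novel")
  ord <- sample(real)
  expressed_unit <- rep(FALSE, nrow(units))
  got <- 0L
  for (i in ord) {
    sz <- units$n_genes[i]
    if (got + sz <= target) { expressed_unit[i] <- TRUE; got <- got + sz }
    if (got == target) break
  }
  units$expressed <- expressed_unit | units$kind == "novel"
  genes$expressed <- genes$unit_idx %in% which(expressed_unit)

  ## 4. anchors and NDR zones for expressed annotated units
  units$tss <- ifelse(units$strand == "+", units$start, units$end - 1L)
  units$tts <- ifelse(units$strand == "+", units$end - 1L, units$start)
  exp_ann <- units[units$expressed & units$kind != "novel", ]
  zones <- list()
  for (i in seq_len(nrow(exp_ann))) {
    z5 <- ndr_zone(exp_ann$tss[i], exp_ann$strand[i], config$ndr5, L)
    z3 <- ndr_zone(exp_ann$tts[i], exp_ann$strand[i], config$ndr3, L)
    zones[[length(zones) + 1L]] <- data.table::data.table(
      start = c(z5[1], z3[1]), end = c(z5[2], z3[2]),
      which = c("ndr5", "ndr3"), scale = c(config$ndr5$scale,
                                           config$ndr3$scale))
  }
  zones <- if (length(zones)) data.table::rbindlist(zones) else
    data.table::data.table(start = integer(), end = integer(),
                           which = character(), scale = numeric())
  zones$start <- pmax(zones$start, 0L)
  zones$end <- pmin(zones$end, L)
  zones <- zones[zones$end > zones$start, ]
  zones <- zones[order(zones$start), ]

  ## 5. region truth (genic = expressed annotated spans + upstream ext)
  regions <- build_regions(
    data.table::data.table(start = exp_ann$start, end = exp_ann$end,
                           strand = exp_ann$strand),
    replicon(config$name, L, circular = config$circular),
    upstream = config$upstream)

  ## 6. profile-class forced windows (optional)
  forced <- data.table::data.table(start = integer(), end = integer())
  forced_dyads <- integer(0)
  unit_class <- rep(NA_integer_, nrow(units))
  if (!is.null(config$profile_classes)) {
    cls <- config$profile_classes
    exp_idx <- which(units$expressed & units$kind != "novel")
    unit_class[exp_idx] <- cls[(seq_along(exp_idx) - 1L) %% length(cls) + 1L]
    half5 <- config$ndr5$width %/% 2L
    co5 <- config$ndr5$center_offset
    lo_block <- co5 - half5      # NDR zone in oriented offsets
    hi_block <- co5 + (config$ndr5$width - half5)
    for (i in exp_idx) {
      k <- unit_class[i]
      allow1 <- c(-200L, lo_block - 1L)        # upstream of the NDR
      allow2 <- c(hi_block + 1L, 200L)         # downstream of the NDR
      len1 <- allow1[2] - allow1[1] + 1L
      len2 <- allow2[2] - allow2[1] + 1L
      tpos <- (seq_len(k) - 0.5) / k * (len1 + len2)
      in1 <- tpos <= len1
      offs <- ifelse(in1, allow1[1] + tpos, allow2[1] + (tpos - len1))
      offs <- round(offs + stats::rnorm(k, 0, 2))
      # jitter must not leave the allowed sub-intervals
      offs[in1] <- pmin(pmax(offs[in1], allow1[1]), allow1[2])
      offs[!in1] <- pmin(pmax(offs[!in1], allow2[1]), allow2[2])
      gpos <- if (units$strand[i] == "+") units$tss[i] + offs
              else units$tss[i] - offs
      forced_dyads <- c(forced_dyads, wrap0(as.integer(gpos), L))
      a <- sort(c(units$tss[i] - 200L, units$tss[i] + 200L))
      forced <- rbind(forced, data.table::data.table(start = a[1],
                                                     end = a[2] + 1L))
    }
    forced <- forced[order(forced$start), ]
  }
  units$profile_class <- unit_class

  ## 7. dyad walk
  blocked <- rbind(zones[, c("start", "end")], forced)
  if (nrow(blocked)) {  # merge overlaps so one jump always clears the block
    red <- IRanges::reduce(IRanges::IRanges(blocked$start + 1L, blocked$end))
    blocked <- data.table::data.table(start = IRanges::start(red) - 1L,
                                      end = IRanges::end(red))
  }
  blocked <- blocked[order(blocked$start), ]
  dyads <- integer(0)
  pos <- gaps[1] %/% 2L
  repeat {
    while (any(hit <- in_any_zone(pos, blocked))) {
      idx <- findInterval(pos, blocked$start)
      pos <- blocked$end[idx]
    }
    if (pos >= L) break
    dyads <- c(dyads, pos)
    cls <- region_class(regions, pos)
    par <- if (identical(cls, "genic")) config$genic_spacing
           else config$nongenic_spacing
    step <- max(20L, as.integer(round(stats::rnorm(1, par[1], par[2]))))
    pos <- pos + step
  }
  dyads <- sort(unique(c(dyads, forced_dyads)))
  dyad_class <- region_class(regions, dyads)
  dyad_forced <- dyads %in% forced_dyads

  ## 8. GC ramp around dyads. Dyad windows tile most of the genome at this
  ## spacing, so the raw edge->midpoint ramp is recentered on the genome GC
  ## (same gradient, zero net composition change) to keep global GC on
  ## target.
  hw <- config$dyad_halfwidth
  ramp <- config$dyad_gc[2] -
    (config$dyad_gc[2] - config$dyad_gc[1]) * abs(-hw:hw) / hw
  ramp <- pmin(1, pmax(0, gc + (ramp - mean(ramp))))
  for (d in dyads) {
    idx <- wrap0(d + (-hw:hw), L) + 1L
    is_gc <- stats::runif(length(idx)) < ramp
    strong <- sample(c("C", "G"), length(idx), replace = TRUE)
    weak <- sample(c("A", "T"), length(idx), replace = TRUE)
    bases[idx] <- ifelse(is_gc, strong, weak)
  }

  ## 9. optional planted AA periodicity
  if (!is.null(config$periodicity)) {
    Tp <- config$periodicity$period
    amp <- config$periodicity$amplitude
    rel <- (-hw):(hw - 1L)
    rate <- amp * (1 + cos(2 * pi * rel / Tp)) / 2
    for (d in dyads) {
      force_aa <- stats::runif(length(rel)) < rate
      for (j in which(force_aa)) {
        idx <- wrap0(d + rel[j] + 0:1, L) + 1L
        bases[idx] <- "A"
      }
    }
  }

  ## 10. protected fragments
  flen_mean <- mean(config$fragment_len)
  nd <- length(dyads)
  gap_next <- if (config$circular)
    diff(c(dyads, dyads[1] + L)) else c(diff(dyads), flen_mean)
  gap_prev <- c(gap_next[nd], gap_next[-nd])
  local_sp <- (gap_next + gap_prev) / 2
  lambda <- config$depth * pmin(local_sp, 150) / flen_mean
  n_frag <- stats::rpois(nd, lambda)
  centers <- rep(dyads, n_frag) +
    round(stats::rnorm(sum(n_frag), 0, config$jitter_sd))
  # NDR background fragments
  if (nrow(zones)) {
    zl <- zones$end - zones$start
    zn <- stats::rpois(nrow(zones), zones$scale * config$depth * zl / flen_mean)
    zc <- round(stats::runif(sum(zn), rep(zones$start, zn),
                             rep(zones$end, zn)))
    centers <- c(centers, zc)
  }
  lens <- sample(seq(config$fragment_len[1], config$fragment_len[2]),
                 length(centers), replace = TRUE)
  frag <- make_fragments(centers, lens, L, config$circular, config$name)
  # naked control: same total count, uniform centers
  nk_centers <- floor(stats::runif(nrow_frag_count(frag), 0, L))
  nk_lens <- sample(seq(config$fragment_len[1], config$fragment_len[2]),
                    length(nk_centers), replace = TRUE)
  naked_frag <- make_fragments(nk_centers, nk_lens, L, config$circular,
                               config$name)

  ## 11. RNA coverage
  rna <- numeric(L)
  exp_units <- units[units$expressed, ]
  for (i in seq_len(nrow(exp_units))) {
    lvl <- max(8, stats::rlnorm(1, log(config$rna_level), 0.4))
    s <- exp_units$start[i] + sample(-20:20, 1)
    e <- exp_units$end[i] + sample(-20:20, 1)
    s <- max(0L, s); e <- min(L, e)
    if (s < e) rna[(s + 1L):e] <- rna[(s + 1L):e] + lvl
  }

  ## 12. assemble
  repl <- replicon(config$name, L, circular = config$circular,
                   sequence = paste(bases, collapse = ""))
  mnase <- fragments_to_coverage(frag, repl, mode = "pileup")
  naked <- fragments_to_coverage(naked_frag, repl, mode = "pileup")
  rna_tr <- coverage_track(repl, rna)
  truth_dyads <- data.table::data.table(
    pos = dyads, class = dyad_class, forced = dyad_forced)
  bundle <- list(replicon = repl, annotations = genes, units = units,
                 fragments = frag, naked_fragments = naked_frag,
                 mnase = mnase, naked = naked, rna = rna_tr,
                 truth = list(dyads = truth_dyads, regions = regions,
                              zones = zones),
                 config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

nrow_frag_count <- function(frag) {
  # wrap pairs are two records of one fragment
  nw <- sum(!is.na(frag$wrap_id))
  nrow(frag) - nw / 2L
}

# build a fragment table from centers/lengths, splitting origin-wrappers
make_fragments <- function(centers, lens, L, circular, chrom) {
  starts <- as.integer(centers) - lens %/% 2L
  ends <- starts + lens
  if (!circular) {
    starts <- pmax(starts, 0L); ends <- pmin(ends, L)
    keep <- starts < ends
    return(data.table::data.table(
      chrom = chrom, start = starts[keep], end = ends[keep],
      name = paste0("f", seq_len(sum(keep))), score = 0, strand = ".",
      wrap_id = NA_character_))
  }
  starts <- wrap0(starts, L)
  ends <- starts + lens
  plain <- ends <= L
  out <- data.table::data.table(
    chrom = chrom, start = starts[plain], end = ends[plain],
    name = paste0("f", which(plain)), score = 0, strand = ".",
    wrap_id = NA_character_)
  if (any(!plain)) {
    w <- which(!plain)
    wa <- data.table::data.table(
      chrom = chrom, start = starts[w], end = L,
      name = paste0("f", w, "|wrapA"), score = 0, strand = ".",
      wrap_id = paste0("f", w))
    wb <- data.table::data.table(
      chrom = chrom, start = 0L, end = ends[w] - L,
      name = paste0("f", w, "|wrapB"), score = 0, strand = ".",
      wrap_id = paste0("f", w))
    out <- rbind(out, wa, wb)
  }
  out[order(out$start, out$name), ]
}

#' Write a simulated bundle to disk
#'
#' Emits genome FASTA, gene GFF3, fragment BED, MNase / naked / RNA
#' bedGraphs, ground-truth TSVs and the flat key-value config, in the exact
#' formats the pipeline consumes.
#'
#' @param bundle Result of [simulate_chromatin()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(list(bundle$replicon), p("genome.fasta"))
  ann <- data.table::copy(bundle$annotations)
  ann$type <- "gene"
  write_gff(ann, p("annotations.gff3"))
  write_bed(bundle$fragments, p("mnase_fragments.bed"))
  write_bedgraph(bundle$mnase, p("mnase_coverage.bedgraph"))
  write_bedgraph(bundle$naked, p("naked_coverage.bedgraph"))
  write_bedgraph(bundle$rna, p("rna_coverage.bedgraph"))
  data.table::fwrite(bundle$truth$dyads, p("truth_dyads.tsv"), sep = "\t")
  data.table::fwrite(bundle$units, p("truth_units.tsv"), sep = "\t")
  data.table::fwrite(bundle$truth$regions, p("truth_regions.tsv"), sep = "\t")
  cfg <- bundle$config
  keys <- names(cfg)
  vals <- vapply(cfg, function(v)
    paste(format(unlist(v), trim = TRUE, scientific = FALSE),
          collapse = ","), character(1))
  writeLines(paste0(keys, " = ", vals), p("config.txt"))
  invisible(out_dir)
}

#' Compare called positions against planted ground truth
#'
#' Greedy 1-1 matching: truth positions are visited in order and matched to
#' the nearest unmatched call within `tolerance`.
#'
#' @param calls Numeric vector of called positions (or a calls table with a
#'   `midpoint` column).
#' @param truth Numeric vector of planted positions.
#' @param tolerance Maximum absolute distance (bp) for a match; must be
#'   >= 0.
#' @return List with `recall`, `precision` (NA when there are no calls),
#'   `mae` (mean absolute error of matched pairs), `n_matched`,
#'   `unmatched_truth`, `unmatched_calls`.
#' @export
truth_compare <- function(calls, truth, tolerance) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.data.frame(calls)) calls <- calls$midpoint
  calls <- sort(as.numeric(calls))
  truth <- sort(as.numeric(truth))
  used <- rep(FALSE, length(calls))
  err <- numeric(0)
  matched_truth <- logical(length(truth))
  for (i in seq_along(truth)) {
    lo <- findInterval(truth[i] - tolerance, calls) + 1L
    hi <- findInterval(truth[i] + tolerance, calls)
    if (lo > hi) next
    cand <- lo:hi
    cand <- cand[!used[cand]]
    if (!length(cand)) next
    j <- cand[which.min(abs(calls[cand] - truth[i]))]
    used[j] <- TRUE
    matched_truth[i] <- TRUE
    err <- c(err, abs(calls[j] - truth[i]))
  }
  list(recall = if (length(truth)) mean(matched_truth) else NA_real_,
       precision = if (length(calls)) sum(used) / length(calls) else NA_real_,
       mae = if (length(err)) mean(err) else NA_real_,
       n_matched = length(err),
       unmatched_truth = truth[!matched_truth],
       unmatched_calls = calls[!used])
}

#' Compare refined transcription units against planted units
#'
#' Each planted expressed unit is matched to the overlapping refined unit
#' with the largest overlap; both boundaries are then compared.
#'
#' @param refined Refined units (chrom, start, end, ...).
#' @param truth_units Planted unit table with start, end, expressed.
#' @param tolerance Boundary tolerance in bp.
#' @return List with `boundary_within` (fraction of boundaries within
#'   tolerance), `matched` (fraction of planted units with any overlapping
#'   refined unit), and the per-unit error table.
#' @export
truth_compare_units <- function(refined, truth_units, tolerance = 20L) {
  tu <- truth_units[truth_units$expressed, ]
  ir_t <- IRanges::IRanges(tu$start + 1L, tu$end)
  ir_r <- IRanges::IRanges(refined$start + 1L, refined$end)
  ov <- IRanges::findOverlaps(ir_t, ir_r)
  if (!length(ov))
    return(list(boundary_within = 0, matched = 0,
                errors = data.table::data.table()))
  w <- IRanges::width(IRanges::pintersect(ir_t[S4Vectors::from(ov)],
                                          ir_r[S4Vectors::to(ov)]))
  dt <- data.table::data.table(t = S4Vectors::from(ov),
                               r = S4Vectors::to(ov), w = w)
  best <- dt[order(dt$t, -dt$w), ]
  best <- best[!duplicated(best$t), ]
  err <- data.table::data.table(
    unit_id = tu$unit_id[best$t],
    start_err = abs(refined$start[best$r] - tu$start[best$t]),
    end_err = abs(refined$end[best$r] - tu$end[best$t]))
  list(boundary_within = mean(c(err$start_err, err$end_err) <= tolerance),
       matched = nrow(best) / nrow(tu),
       errors = err)
}

#' Simulate dyad-centered sequence windows directly
#'
#' A lightweight generator for calibration studies of the composition and
#' periodicity statistics: i.i.d. windows at a target GC, optionally with a
#' planted sinusoidal AA-dinucleotide periodicity (as in
#' [sim_config()]'s `periodicity`).
#'
#' @param n Number of windows.
#' @param halfwidth Half window width (window length `2*halfwidth + 1`).
#' @param gc GC fraction of the background.
#' @param periodicity Optional `list(period, amplitude)`.
#' @param seed Integer seed.
#' @return Character vector of windows.
#' @export
sim_dyad_windows <- function(n, halfwidth = 30L, gc = 0.65,
                             periodicity = NULL, seed = 1L) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  w <- 2L * halfwidth + 1L
  m <- matrix(sample(c("A", "C", "G", "T"), n * w, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
              nrow = n)
  if (!is.null(periodicity)) {
    Tp <- periodicity$period
    amp <- periodicity$amplitude
    rel <- seq_len(w - 1L) - 1L - halfwidth
    rate <- amp * (1 + cos(2 * pi * rel / Tp)) / 2
    for (j in seq_len(w - 1L)) {
      force_aa <- stats::runif(n) < rate[j]
      if (any(force_aa)) {
        m[force_aa, j] <- "A"
        m[force_aa, j + 1L] <- "A"
      }
    }
  }
  apply(m, 1, paste, collapse = "")
}
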