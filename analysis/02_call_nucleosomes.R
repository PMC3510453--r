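#!/usr/bin/env Rscript
# Stage 2 — smoothing, bandwidth selection, dyad calling, occupancy states,
# spacing and density statistics.
#
# Reads the stage-1 bundle back through the package's format readers (so
# this stage runs identically on real data exported as FASTA + BED +
# bedGraph + GFF3), smooths the protection signal with the Gaussian
# kernel, calls nucleosome midpoints from fragment-midpoint coverage, and
# scores the calls against the planted truth.

library(tetramap)
library(data.table)

sim <- "results/sim"
out <- "results/nucleosomes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(sim, "genome.fasta"))
repl <- genome[[1]]
mnase <- read_bedgraph(file.path(sim, "mnase_coverage.bedgraph"), genome)[[1]]
fragments <- read_bed(file.path(sim, "mnase_fragments.bed"))
truth_dyads <- fread(file.path(sim, "truth_dyads.tsv"))
regions <- fread(file.path(sim, "truth_regions.tsv"))

# bandwidth selection: strongest smoothing still tracking the raw signal
sel <- select_window(mnase, candidates = seq(9, 45, by = 2), r_min = 0.85)
fwrite(sel$table, file.path(out, "bandwidth_selection.tsv"), sep = "\t")
cat(sprintf("selected Gaussian bandwidth M = %d (r >= 0.85)\n", sel$M))

sm <- convolve_track(mnase, gaussian_kernel(27))
write_bedgraph(coverage_track(repl, sm$values),
               file.path(out, "smoothed_m27.bedgraph"))

cd <- call_dyads(fragments, repl, M = 27)
calls <- copy(cd$calls)
cat(sprintf("called %d nucleosome midpoints (min prominence %.3f)\n",
            nrow(calls), cd$min_prominence))

tc <- truth_compare(calls, truth_dyads$pos, tolerance = 5)
cat(sprintf("recovery vs planted dyads: recall %.3f, precision %.3f, MAE %.2f bp\n",
            tc$recall, tc$precision, tc$mae))

bed <- data.table(chrom = calls$chrom, start = calls$midpoint,
                  end = calls$midpoint + 1L,
                  name = paste0("nuc", seq_len(nrow(calls))),
                  score = round(1000 * calls$prominence /
                                  max(calls$prominence)),
                  strand = ".")
write_bed(bed, file.path(out, "nucleosome_calls.bed"))

sp <- peak_spacing(calls, regions, repl)
fwrite(sp, file.path(out, "spacing_by_class.tsv"), sep = "\t")
cat(sprintf("peak-to-peak spacing: genic %.1f bp (n=%d), non-genic %.1f bp (n=%d)\n",
            sp$mean[sp$class == "genic"], sp$n[sp$class == "genic"],
            sp$mean[sp$class == "non_genic"], sp$n[sp$class == "non_genic"]))
cat(sprintf("nucleosome density: %.1f per kb (planted %.1f per kb)\n",
            nucleosome_density(calls, repl),
            1000 / mean(diff(truth_dyads$pos))))

st <- occupancy_states(sm, call_nucleosomes(sm))
write_bedgraph(coverage_track(repl, st$states),
               file.path(out, "occupancy_states.bedgraph"))
cat(sprintf("occupancy states: %.1f%% occupied, %.1f%% depleted, %.1f%% transition\n",
            100 * mean(st$states == 1), 100 * mean(st$states == 0),
            100 * mean(st$states == 0.5)))

# naked-DNA control: the protection signal should not reflect sequence bias
naked <- read_bedgraph(file.path(sim, "naked_coverage.bedgraph"), genome)[[1]]
cat(sprintf("MNase vs naked-DNA control: r = %.3f\n",
            track_pearson(mnase, naked)$r))
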