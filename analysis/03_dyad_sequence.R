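#!/usr/bin/env Rscript
# Stage 3 — sequence composition around the dyad.
#
# Nucleotide and dinucleotide composition of 61-bp windows centered on
# called midpoints, the edge-to-dyad GC gradient, information content under
# uniform and genome backgrounds, and the permutation test for ~10-bp
# dinucleotide periodicity (on the nucleosomal calls and on the naked-DNA
# control calls).

library(tetramap)
library(data.table)

sim <- "results/sim"
nuc <- "results/nucleosomes"
out <- "results/dyad_sequence"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(sim, "genome.fasta"))
repl <- genome[[1]]
calls <- read_bed(file.path(nuc, "nucleosome_calls.bed"))
calls$midpoint <- calls$start

w <- extract_dyad_windows(repl, calls, halfwidth = 30)
cat(sprintf("%d dyad windows (%d dropped for N)\n",
            length(w$windows), w$n_dropped))
tab <- composition_table(w)

comp <- data.table(offset = tab$offsets, t(tab$counts), gc = tab$gc)
fwrite(comp, file.path(out, "composition.tsv"), sep = "\t")
dinuc <- data.table(offset = head(tab$offsets, -1), t(tab$dinuc_counts),
                    W = tab$W, S = tab$S)
fwrite(dinuc, file.path(out, "dinucleotides.tsv"), sep = "\t")

gg <- gc_gradient(tab)
fwrite(gg$curve, file.path(out, "gc_gradient.tsv"), sep = "\t")
cat(sprintf("GC at dyad %.1f%%, at fragment edge %.1f%% (delta %.1f points)\n",
            100 * gg$gc_midpoint, 100 * gg$gc_edge, 100 * gg$delta))

base_freq <- colSums(Biostrings::letterFrequency(
  Biostrings::DNAStringSet(repl$sequence), c("A", "C", "G", "T")))
base_freq <- base_freq / sum(base_freq)
ic <- data.table(offset = tab$offsets,
                 bits_uniform = information_content(tab, "uniform"),
                 bits_genome = information_content(tab, "genome_gc",
                                                   genome_probs = base_freq),
                 prob_gc = tab$gc)
fwrite(ic, file.path(out, "information_content.tsv"), sep = "\t")
cat(sprintf("information content at dyad: %.3f bits (uniform), %.3f bits (vs genome)\n",
            ic$bits_uniform[tab$offsets == 0], ic$bits_genome[tab$offsets == 0]))

aa <- tab$dinuc_counts["AA", ] / tab$n_windows
pt <- periodicity_test(aa, n_perm = 999, seed = 7)
cat(sprintf("AA periodicity on nucleosomal dyads: power %.4g at best period %.1f bp, p = %.3f\n",
            pt$power, pt$best_period, pt$p_value))

nk <- read_bedgraph(file.path(sim, "naked_coverage.bedgraph"), genome)[[1]]
nk_calls <- call_nucleosomes(convolve_track(nk, gaussian_kernel(27)))
wn <- extract_dyad_windows(repl, nk_calls, halfwidth = 30)
tn <- composition_table(wn)
ptn <- periodicity_test(tn$dinuc_counts["AA", ] / tn$n_windows,
                        n_perm = 999, seed = 8)
cat(sprintf("AA periodicity on naked-control peaks: p = %.3f\n", ptn$p_value))
res <- data.table(track = c("nucleosomal", "naked_control"),
                  best_period = c(pt$best_period, ptn$best_period),
                  p_value = c(pt$p_value, ptn$p_value))
fwrite(res, file.path(out, "periodicity.tsv"), sep = "\t")
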