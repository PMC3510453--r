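#!/usr/bin/env Rscript
# Stage 4 — refine the predicted annotations into expressed transcription
# units using RNA-seq coverage: expression classification, boundary
# adjustment to the covered region, operon merging across covered gaps,
# and detection of unannotated (novel) transcribed units.

library(tetramap)
library(data.table)

sim <- "results/sim"
out <- "results/transcripts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(sim, "genome.fasta"))
annotations <- read_gff(file.path(sim, "annotations.gff3"))
rna <- read_bedgraph(file.path(sim, "rna_coverage.bedgraph"), genome)[[1]]
truth_units <- fread(file.path(sim, "truth_units.tsv"))

res <- refine_transcripts(annotations, rna,
                          c_min = 5, t_rel = 0.1, max_ext = 250,
                          merge_t = 3, min_novel_len = 100)
s <- res$summary
cat(sprintf("predicted annotations: %d\n", s$n_predicted))
cat(sprintf("detectably expressed:  %d (%.1f%%)\n", s$n_expressed,
            100 * s$fraction_expressed))
cat(sprintf("confirmed by a refined unit: %d (%.1f%%)\n", s$n_confirmed,
            100 * s$fraction_confirmed))
cat(sprintf("merged into longer units: %d annotations -> %d units\n",
            s$n_merged_into, sum(res$units$status == "merged")))
cat(sprintf("novel transcribed units: %d\n", s$n_novel))

write_gff(res$units, file.path(out, "refined_units.gff3"))
fwrite(data.table(metric = names(unlist(s)), value = unlist(s)),
       file.path(out, "summary.tsv"), sep = "\t")

tcu <- truth_compare_units(res$units[res$units$status != "novel", ],
                           truth_units[truth_units$kind != "novel", ],
                           tolerance = 20)
cat(sprintf("boundary recovery vs planted units: %.1f%% within 20 bp\n",
            100 * tcu$boundary_within))
fwrite(tcu$errors, file.path(out, "boundary_errors.tsv"), sep = "\t")
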