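# Shared fixtures, built once per test run.

# A small but complete simulated study: 60 kb circular genome, operons,
# novel units, NDRs, GC-enriched dyads.
small_cfg <- sim_config(seed = 42L, genome_length = 60000L,
                        n_transcripts = 45L, n_operons = 4L, n_novel = 3L)
small_bundle <- simulate_chromatin(small_cfg)

# random coverage track on a fresh replicon
rand_track <- function(n, seed, circular = TRUE, lambda = 20) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  r <- replicon(paste0("rt", seed), n, circular = circular)
  tr <- coverage_track(r, stats::rpois(n, lambda))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  tr
}

# direct double-loop convolution sum, the independent oracle for
# convolve_track(); intentionally naive.
brute_convolve <- function(x, w, circular) {
  n <- length(x)
  h <- (length(w) - 1L) %/% 2L
  js <- (-h):h
  if (circular) {
    vapply(seq_len(n), function(i) {
      sum(w * x[((i - 1L - js) %% n) + 1L])
    }, numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      idx <- i - js
      ok <- idx >= 1L & idx <= n
      sum(w[ok] * x[idx[ok]]) / sum(w[ok])
    }, numeric(1))
  }
}

# AA dinucleotide frequency series of a window set
aa_series <- function(windows) {
  tab <- composition_table(windows)
  tab$dinuc_counts["AA", ] / tab$n_windows
}
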