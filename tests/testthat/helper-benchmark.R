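# Synthetic benchmark shared by the heavier acceptance checks.
#
# Conditions: 10 subjects x 20 windows spanning 10 s each (7.5 fps, L = 75 --
# the same 6 cycles/min FFT bin as 30 fps / L = 300), high SNR (noise_sigma =
# 0.005), load shifts +8 bpm / +2 rpm, blink rates 12/24 per minute; model
# d = 16, depth as requested, batch 8, 250 Adam steps at lr 1e-3 (the acceptance script uses 300) with
# z-scored targets and standard rPPG augmentation.  Runs are cached so the
# multi-task recovery and depth-sweep checks share the same fits.

benchmark_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(
        n_subjects = 10L, windows_per_subject = 20L, fps = 7.5, L = 75L,
        noise_sigma = 0.005, seed = 100L))
    cache
  }
})

benchmark_split <- function() subject_split(benchmark_dataset()$manifest$subject_id,
                                            seed = 100L)

benchmark_run <- local({
  cache <- list()
  function(seed, depth = 3L, iter_total = 250L) {
    key <- paste(seed, depth, iter_total, sep = "_")
    if (is.null(cache[[key]])) {
      ds <- benchmark_dataset()
      cfg <- facephys_desk_config(depth = as.integer(depth),
                                  iter_total = as.integer(iter_total),
                                  window_length = 75L, fps = 7.5)
      fit <- facephys(ds, cfg, seed = seed, split = benchmark_split())
      ev <- evaluate_facephys(fit, ds, "test")
      cache[[key]] <<- list(fit_metrics = ev, seed = seed, depth = depth)
    }
    cache[[key]]
  }
})

# trivial baselines computed on the benchmark's train/test split
benchmark_baselines <- function() {
  ds <- benchmark_dataset()
  sp <- benchmark_split()
  man <- ds$manifest
  wsplit <- sp[man$subject_id]
  tr <- man[wsplit == "train", ]
  te <- man[wsplit == "test", ]
  maj <- as.integer(mean(tr$cog) >= 0.5)
  list(majority_accuracy = mean(te$cog == maj),
       mean_hr_mae = mean(abs(mean(tr$hr_bpm) - te$hr_bpm)),
       mean_rr_mae = mean(abs(mean(tr$rr_rpm) - te$rr_rpm)))
}
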