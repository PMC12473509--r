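# Shared fixtures: everything is generated in code at test time.

# tiny architecture for fast structural tests
tiny_config <- function(...) {
  facephys_desk_config(d = 4L, depth = 1L, c1 = 2L, c2 = 3L,
                       stmap_channels = 3L, lm_channels = 2L, head_hidden = 8L,
                       n_state = 4L, dt_rank = 2L, window_length = 40L,
                       fps = 10, batch_size = 2L, iter_total = 4L,
                       val_every = 2L, ...)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(
        n_subjects = 6L, windows_per_subject = 2L, fps = 10, L = 40L,
        noise_sigma = 0.005, seed = 11L))
    cache
  }
})

# one pixel-level window at given scale (cached per parameter set)
pixel_window <- local({
  cache <- list()
  function(fps = 30, L = 300L, noise_sigma = 0, seed = 21L) {
    key <- paste(fps, L, noise_sigma, seed)
    if (is.null(cache[[key]])) {
      cfg <- synthetic_config(n_subjects = 1L, windows_per_subject = 1L,
                              fps = fps, L = L, noise_sigma = noise_sigma,
                              level = "pixel", seed = seed)
      prof <- generate_subject(cfg, 1L)
      cache[[key]] <<- generate_window(prof, 0L, cfg, 1L)
    }
    cache[[key]]
  }
})

# random single-channel LTI instance for the scan/convolution oracles
random_lti <- function(N = NULL) {
  N <- N %||% sample(1:8, 1)
  ssm_params(A = -runif(N, 0.05, 3), B = rnorm(N), C = rnorm(N),
             D_skip = rnorm(1), delta = runif(1, 0.02, 1))
}

zero_branch_params <- function(par) {
  for (nm in names(par))
    if (!grepl("gamma", nm)) par[[nm]][] <- 0
  par
}
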