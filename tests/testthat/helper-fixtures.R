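# Shared fixtures: small, fast worlds used across test files. Everything is
# generated in code; seeds are fixed so expected values frozen in tests are
# reproducible.

# small labelled head model (cached per session): 16 channels drawn from the
# standard montage so C3/Cz/C4/Oz exist
tiny_montage <- function() {
  keep <- c("Fp1", "Fp2", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
            "P3", "Pz", "P4", "O1", "Oz", "O2")
  m <- standard_montage_64()
  m[match(keep, m$label), ]
}

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_head_model(20, 16, seed = 7, montage = tiny_montage())
    }
    cache
  }
})

model40 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_head_model(40, 64, seed = 1)
    cache
  }
})

unit_gains <- function(conditions = c("balls", "simple", "complex", "social")) {
  stats::setNames(rep(1, length(conditions)), conditions)
}

# a tiny fast study configuration: 2 conditions, short clips, low fs
fast_cfg <- function(...) {
  sim_config(n_subjects = 2, conditions = c("balls", "complex"),
             clip_seconds = 6, clips_per_condition = 2, rest_seconds = 12,
             fs = 128, noise_sd = 0.5, pink_sd = 0.5, seed = 11, ...)
}

random_recording <- function(n_ch = 4, n = 256, fs = 128, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n), n_ch, n), fs,
                sprintf("ch%02d", seq_len(n_ch)), condition = "complex")
}
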