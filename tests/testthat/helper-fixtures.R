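# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so the default run stays fast.

# Single-recording generator config with selectable degradation.
quiet_config <- function(noise_sd = 0, wander = 0, corrupt = 0,
                         rr_jitter_ms = 0, ...) {
  synthetic_cohort_config(n_participants = 1, noise_sd = noise_sd,
                          baseline_wander_amplitude = wander,
                          corrupt_beat_fraction = corrupt,
                          rr_jitter_ms = rr_jitter_ms, ...)
}

# A clean 48 bpm recording whose beat windows never overlap (RR > 1.2 s),
# so extraction is exact.
clean_recording <- function(ilvm = 60, sex = "male", seed = 3) {
  cfg <- quiet_config()
  tpl <- make_median_template(ilvm, sex, 48, cfg)
  list(template = tpl, config = cfg,
       ecg = make_raw_ecg(tpl, 48, cfg, seed = seed))
}

# Small random feature set with a planted linear amplitude signal.
toy_feature_set <- function(n = 160, L = 64, seed = 1, signal = TRUE,
                            meta_signal = FALSE) {
  withr::with_seed(seed, {
    x <- array(rnorm(L * 8 * n, 0, 0.1), c(L, 8, n))
    amp <- rnorm(n)
    if (signal) for (i in seq_len(n)) x[30:34, , i] <- x[30:34, , i] + amp[i]
    md <- matrix(runif(n * 15), n, 15)
    y <- 50 + 8 * amp
    if (meta_signal) y <- 50 + 3 * amp + 12 * md[, 1]
    structure(list(ecg = x, metadata = md, y = y,
                   ids = sprintf("T%03d", seq_len(n))),
              class = "fcn_features")
  })
}

# A clinical profile table with derived columns, for metadata tests.
toy_profiles <- function(n = 8, seed = 2) {
  cfg <- synthetic_cohort_config(n_participants = n, seed = seed)
  prof <- sample_clinical_profile(rep(c(TRUE, FALSE), length.out = n),
                                  rep(c(1, 0), length.out = n), cfg,
                                  seed = seed)
  prof$ventricular_rate_bpm <- seq(55, 75, length.out = n)
  prof
}

# Dropout-free small model config (used when comparing the compiled and
# reference network paths, which draw dropout masks differently).
plain_model_config <- function(L = 48, metadata_dim = 15) {
  fcn_config(beat_length = L, metadata_dim = metadata_dim,
             dropout_conv = 0, dropout_fc = 0)
}
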