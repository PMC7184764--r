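# Synthetic fixtures built in code at test time.

# a feature table shaped like extract_features() output, with an
# optional informative column (subband 1, first entropy) that separates
# focal from nonfocal rows
fake_feature_table <- function(n_channels = 4, n_segments = 10,
                               n_soz = 1, n_subbands = 2,
                               informative = TRUE, noise_sd = 0.3,
                               seed = 42) {
  set.seed(seed)
  ents <- entropy_names()
  fcols <- as.vector(t(outer(sprintf("S%02d", seq_len(n_subbands)),
                             ents, paste, sep = ".")))
  chans <- paste0("ch", seq_len(n_channels))
  grid <- expand.grid(segment = seq_len(n_segments), channel = chans,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  focal <- grid$channel %in% chans[seq_len(n_soz)]
  X <- matrix(rnorm(nrow(grid) * length(fcols), sd = 1), nrow(grid))
  colnames(X) <- fcols
  if (informative)
    X[, 1] <- ifelse(focal, 2, 0) + rnorm(nrow(grid), sd = noise_sd)
  out <- data.frame(channel = grid$channel, segment = grid$segment,
                    label = factor(ifelse(focal, "focal", "nonfocal"),
                                   levels = c("focal", "nonfocal")),
                    X, check.names = FALSE)
  structure(out, n_subbands = n_subbands, entropies = ents,
            feature_cols = fcols,
            class = c("ieeg_features", "data.frame"))
}

# desk-scale end-to-end pipeline run: 12 channels / 2 SOZ / 5 min
desk_pipeline <- function(rate_ratio, seed = 11, k = 5) {
  cfg <- synth_config(n_channels = 12, n_soz = 2, duration = 300,
                      rate_ratio = rate_ratio, seed = seed)
  sim <- generate_ieeg(cfg)
  localize_focus(sim$recording, k = k, G = 3, seed = seed)
}
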