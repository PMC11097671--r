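# Shared fixtures: small, fast synthetic configurations.

tiny_config <- function(seed = 1, ...) {
  cohort_config(n_subjects = 20, n_voxels = 16, n_volumes = 30,
                n_latent = 3, coupled_source_index = 2, seed = seed, ...)
}

# Scores-and-strengths only questions don't need realistic geometry.
score_config <- function(seed = 1, ...) {
  cohort_config(n_subjects = 72, n_voxels = 12, n_volumes = 20,
                n_latent = 3, coupled_source_index = 2, seed = seed, ...)
}

# The geometry used for recovery-style checks: mid-sized cohort.
recovery_config <- function(seed = 1, n_subjects = 65, ...) {
  cohort_config(n_subjects = n_subjects, n_voxels = 120, n_volumes = 150,
                seed = seed, ...)
}

# Brute-force Pearson correlation of two vectors.
pearson_brute <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Brute-force framewise displacement.
fd_brute <- function(trace, radius = 50) {
  m <- unclass(trace)
  m[, 4:6] <- m[, 4:6] * radius
  out <- numeric(nrow(m))
  for (t in 2:nrow(m)) out[t] <- sum(abs(m[t, ] - m[t - 1, ]))
  out
}

# Brute-force BH step-up adjustment.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (rank in seq_len(m)) {
    i <- ord[rank]
    adj[i] <- min(1, min(p[ord[rank:m]] * m / (rank:m)))
  }
  adj
}

# PMA draw from the configured truncated normal (for large-n volume checks).
with_seed_pma <- function(n, cfg, seed = 42) {
  set.seed(seed)
  cbgrad:::rtruncnorm(n, cfg$pma_mean, cfg$pma_sd,
                      cfg$pma_range[1], cfg$pma_range[2])
}

# Table 5 uncorrected p-values (10 gradient features per domain).
table5_internalizing <- c(0.713, 0.442, 0.796, 0.912, 0.852,
                          0.157, 0.032, 0.936, 0.514, 0.273)
table5_competence <- c(0.015, 0.468, 0.248, 0.544, 0.996,
                       0.167, 0.464, 0.258, 0.539, 0.042)
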