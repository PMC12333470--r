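# Shared fixtures built in code.

# Three well-separated AR(1) states in 2-D with a sticky chain; the standard
# ground-truth problem for segmentation tests.
gen_ar3 <- function(T_, p_stay = 0.98, seed = 42) {
  set.seed(seed)
  A <- list(diag(0.9, 2), matrix(c(0.6, -0.3, 0.3, 0.6), 2), diag(0.3, 2))
  b <- list(c(0.5, 0), c(0, -1), c(2, 2))
  s <- c(0.3, 0.5, 0.2)
  P <- matrix((1 - p_stay) / 2, 3, 3)
  diag(P) <- p_stay
  z <- integer(T_)
  z[1] <- 1L
  for (t in 2:T_) z[t] <- sample.int(3, 1, prob = P[z[t - 1], ])
  y <- matrix(0, T_, 2)
  for (t in 2:T_)
    y[t, ] <- A[[z[t]]] %*% y[t - 1, ] + b[[z[t]]] + rnorm(2, 0, s[z[t]])
  attr(y, "fps") <- 30
  list(y = y, z = z - 1L, P = P, Sigma = lapply(s, function(v) diag(v^2, 2)))
}

# A small generator world shared across metric tests.
small_world <- function(n_syllables = 6, seed = 11) {
  rep0 <- build_repertoire(n_syllables, c(0, 150), seed = seed)
  trans0 <- build_transition_model(n_syllables, 0.4, 30, seed = seed + 1L)
  list(repertoire = rep0, transitions = trans0)
}

# Per-animal syllable metric table from a pose-free simulated session.
animal_metrics <- function(repertoire, transitions, duration, seed,
                           jitter_sd = 0) {
  s <- simulate_session(repertoire, transitions, duration = duration,
                        fps = 30, jitter_sd = jitter_sd, seed = seed,
                        generate_pose = FALSE)
  seq_ <- syllable_sequence(s$truth$labels, fps = 30)
  sp <- centroid_speed_series(s$truth$centroid, 30)
  v <- syllable_velocity(sp, seq_)
  u <- usage(seq_)
  list(seq = seq_, centroid = s$truth$centroid,
       table = data.frame(syllable = as.integer(names(v)),
                          velocity = as.numeric(v),
                          usage = as.numeric(u[names(v)])))
}
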