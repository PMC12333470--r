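test_that("centroid speed series: straight line, stillness, rotation invariance", {
  track <- cbind(seq_len(10), rep(0, 10))      # 1 mm/frame
  sp <- centroid_speed_series(track, 30)
  expect_equal(sp, rep(30, 10))
  expect_equal(centroid_speed_series(cbind(rep(2, 5), rep(3, 5)), 30),
               rep(0, 5))
  th <- 1.1
  rot <- track %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(centroid_speed_series(rot, 30), sp, tolerance = 1e-12)
  expect_error(centroid_speed_series(track[1, , drop = FALSE], 30), "2 frames")
})

test_that("syllable_velocity averages per label; absent syllables are missing", {
  seq_ <- syllable_sequence(c(0, 0, 1, 1, 0), fps = 30)
  v <- syllable_velocity(c(100, 100, 50, 50, 100), seq_)
  expect_equal(v, c("0" = 100, "1" = 50))
  expect_false("2" %in% names(v))
  expect_error(syllable_velocity(1:3, seq_), "length")

  # generator oracle: interleaved syllables at 50 and 150 mm/s, no jitter
  r <- build_repertoire(2, c(50, 150), seed = 1)
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  s <- simulate_session(r, P, duration = 600, fps = 30, jitter_sd = 0,
                        seed = 5, generate_pose = FALSE)
  seq2 <- syllable_sequence(s$truth$labels, fps = 30)
  sp <- centroid_speed_series(s$truth$centroid, 30)
  v2 <- syllable_velocity(sp, seq2)
  expect_equal(unname(v2["0"]), 150, tolerance = 0.01)
  expect_equal(unname(v2["1"]), 50, tolerance = 0.01)
})

test_that("a motionless syllable reads ~30 mm/s under calibrated jitter", {
  r <- build_repertoire(2, c(0, 0), seed = 2)
  P <- matrix(0.5, 2, 2)
  s <- simulate_session(r, P, duration = 600, fps = 30,
                        jitter_sd = calibrate_noise(30, 30), seed = 6,
                        generate_pose = FALSE)
  # pose-free sessions collapse all parts onto the centroid, so alignment
  # rightly warns about the degenerate heading
  expect_warning(ps <- egocentric_align(s$recording), "coincident")
  sp <- centroid_speed_series(ps$centroid, 30)
  v <- syllable_velocity(sp, syllable_sequence(s$truth$labels, fps = 30))
  expect_equal(unname(mean(v)), 30, tolerance = 0.05)
})

test_that("session velocity agrees with hand values and the speed series", {
  track <- cbind(cumsum(rep(1, 300)), rep(0, 300))
  expect_equal(session_velocity(track, 30), 30, tolerance = 0.01)
  expect_equal(session_velocity(cbind(rep(1, 50), rep(1, 50)), 30), 0)
  set.seed(7)
  wander <- apply(matrix(rnorm(400 * 2), 400, 2), 2, cumsum)
  expect_equal(session_velocity(wander, 30),
               mean(centroid_speed_series(wander, 30)), tolerance = 0.01)
})

test_that("usage and the expression filter", {
  seq_ <- syllable_sequence(c(0, 0, 1, 1, 1, 2), fps = 30)
  expect_equal(usage(seq_), c("0" = 1 / 3, "1" = 1 / 2, "2" = 1 / 6))
  u <- c(a = 0.6, b = 0.004, c = 0.396)
  expect_equal(filter_expressed(u, 0.005), c("a", "c"))
  expect_equal(usage(syllable_sequence(rep(4L, 10), 30)), c("4" = 1))
})

test_that("transition matrix from run-length encoding, hand-checked", {
  seq_ <- syllable_sequence(c(0, 0, 1, 1, 0, 2), fps = 30)
  ts <- transition_matrix(seq_)
  expect_equal(ts$counts["0", "1"], 1)
  expect_equal(ts$counts["1", "0"], 1)
  expect_equal(ts$counts["0", "2"], 1)
  expect_equal(ts$A["0", "1"], 0.5)
  expect_equal(ts$A["0", "2"], 0.5)
  expect_equal(sum(ts$counts), 3)
  expect_equal(diag(ts$counts), c("0" = 0, "1" = 0, "2" = 0))

  const <- transition_matrix(syllable_sequence(rep(1L, 20), 30))
  expect_equal(sum(const$counts), 0)

  # long simulation from a known chain: off-diagonal conditional law recovered
  P <- build_transition_model(4, 0.3, 30, seed = 9)
  r <- build_repertoire(4, c(0, 100), seed = 9)
  s <- simulate_session(r, P, duration = 4000, fps = 30, jitter_sd = 0,
                        seed = 10, generate_pose = FALSE)
  ts2 <- transition_matrix(syllable_sequence(s$truth$labels, fps = 30))
  cond_true <- P
  diag(cond_true) <- 0
  cond_true <- cond_true / rowSums(cond_true)
  for (i in 1:4)
    expect_lt(sum(abs(ts2$A[i, ] - cond_true[i, ])), 0.05)
})

test_that("steady_state solves the balance equations", {
  expect_equal(steady_state(matrix(0.25, 4, 4)), rep(0.25, 4))
  A <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(steady_state(A), c(5 / 6, 1 / 6), tolerance = 1e-10)
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(steady_state(cyc), rep(1 / 3, 3), tolerance = 1e-10)
  # reducible chain: two closed classes, pick the one with more usage
  A2 <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
              c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  expect_warning(pi_ <- steady_state(A2, usage_hint = c(0.1, 0.1, 0.4, 0.4)),
                 "reducible")
  expect_equal(pi_, c(0, 0, 0.5, 0.5))
})

test_that("entropy closed forms and inequalities", {
  mk <- function(A, counts = NULL) {
    K <- nrow(A)
    if (is.null(counts)) counts <- matrix(1, K, K)
    dimnames(A) <- dimnames(counts) <- list(0:(K - 1), 0:(K - 1))
    structure(list(counts = counts, A = A, pi = steady_state(A),
                   entropy = NA, transition_frequency = NA,
                   alphabet = 0:(K - 1), log_base = 2, mode = "rate",
                   self_transitions = "excluded", usage = rep(1 / K, K)),
              class = "transition_summary")
  }
  expect_equal(entropy(mk(matrix(0.25, 4, 4))), 2)         # log2(4) bits
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(entropy(mk(cyc), mode = "rate"), 0)
  expect_equal(entropy(mk(cyc), mode = "local_sum"), 0)
  half <- matrix(0.5, 2, 2)
  expect_equal(entropy(mk(half), mode = "rate"), 1)
  expect_equal(entropy(mk(half), mode = "local_sum"), 2)
  # nats option
  expect_equal(entropy(mk(matrix(0.25, 4, 4)), log_base = exp(1)), log(4))
  expect_error(entropy(mk(half), mode = "weird"), "arg")

  # rate <= local_sum; rate <= log2(K) on an emitted sequence
  set.seed(11)
  seq_ <- syllable_sequence(sample.int(5, 500, replace = TRUE) - 1L, 30)
  ts <- transition_matrix(seq_)
  expect_lte(entropy(ts, mode = "rate"), entropy(ts, mode = "local_sum"))
  expect_lte(entropy(ts, mode = "rate"), log2(5))
  expect_gte(entropy(ts, mode = "rate"), 0)
})

test_that("transition frequency: hand counts and RLE identity", {
  expect_equal(transition_frequency(syllable_sequence(rep(2L, 60), 30)), 0)
  alt <- syllable_sequence(rep(c(0L, 1L), 15), 30)
  expect_equal(transition_frequency(alt), 29)
  # equals (runs - 1) / duration exactly
  set.seed(12)
  z <- sample.int(3, 400, replace = TRUE) - 1L
  s <- syllable_sequence(z, 30)
  r <- rle(z)
  expect_equal(transition_frequency(s),
               (length(r$lengths) - 1) / (400 / 30))
  # chain with mean run 16.7 frames: ~1.8 transitions/s (open-field scale)
  P <- build_transition_model(8, 16.7 / 30, 30, seed = 13)
  rep_ <- build_repertoire(8, c(0, 100), seed = 13)
  sim <- simulate_session(rep_, P, duration = 1e5 / 30, fps = 30,
                          jitter_sd = 0, seed = 14, generate_pose = FALSE)
  tf <- transition_frequency(syllable_sequence(sim$truth$labels, fps = 30))
  expect_equal(tf, 30 / 16.7, tolerance = 0.05)
})

test_that("delta_table matches, drops, and is antisymmetric", {
  a <- data.frame(syllable = c(0, 1, 2), velocity = c(10, 20, 30),
                  usage = c(0.5, 0.3, 0.2))
  expect_equal(delta_table(a, a)$delta_velocity, c(0, 0, 0))
  b <- data.frame(syllable = c(1, 2, 3), velocity = c(15, 35, 1),
                  usage = c(0.2, 0.3, 0.5))
  expect_message(d <- delta_table(a, b), "dropping")
  expect_equal(d$syllable, c(1, 2))
  expect_equal(d$delta_velocity, c(5, -5))
  d_swap <- suppressMessages(delta_table(b, a))
  expect_equal(d_swap$delta_velocity, -d$delta_velocity)
  expect_error(delta_table(a, data.frame(syllable = 9, velocity = 1,
                                         usage = 1)), "shared")
})

test_that("published 6-OHDA table: syllable 14 delta velocity", {
  tab <- reference_syllable_table("6ohda")
  ctrl <- data.frame(syllable = tab$syllable, velocity = tab$velocity_control,
                     usage = tab$usage_control)
  les <- data.frame(syllable = tab$syllable, velocity = tab$velocity_lesion,
                    usage = tab$usage_lesion)
  d <- delta_table(ctrl, les)
  expect_equal(d$delta_velocity[d$syllable == 14], 172.43 - 91.67,
               tolerance = 1e-9)
})

test_that("generator -> metrics closure at moderate scale", {
  # full 1e5-frame closure is in test-acceptance.R; this guards the pipeline
  w <- small_world(n_syllables = 5, seed = 17)
  s <- simulate_session(w$repertoire, w$transitions, duration = 600, fps = 30,
                        jitter_sd = 0, seed = 18, generate_pose = FALSE)
  seq_ <- syllable_sequence(s$truth$labels, fps = 30)
  sp <- centroid_speed_series(s$truth$centroid, 30)
  v <- syllable_velocity(sp, seq_)
  moving <- w$repertoire$speeds > 0
  idx <- as.integer(names(v)) + 1L
  err <- abs(v - w$repertoire$speeds[idx]) /
    pmax(w$repertoire$speeds[idx], 1)
  expect_lt(max(err[moving[idx]]), 0.06)
})

test_that("syllable_stats aggregates per animal then averages", {
  w <- small_world(n_syllables = 4, seed = 19)
  animals <- lapply(1:3, function(i) {
    am <- animal_metrics(w$repertoire, w$transitions, 120, seed = 100 + i)
    list(seq = am$seq, centroid = am$centroid)
  })
  st <- syllable_stats(animals)
  expect_true(all(c("velocity", "velocity_sem", "usage", "usage_sem")
                  %in% names(st$table)))
  expect_equal(sum(st$table$usage), 1, tolerance = 1e-9)
  expect_true(all(st$table$velocity >= 0))
  expect_equal(nrow(st$table), 4)
  expect_length(st$per_animal, 3)
})
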