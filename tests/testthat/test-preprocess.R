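make_rec <- function(coords, lik = NULL, parts = NULL) {
  P <- dim(coords)[2]
  if (is.null(lik)) lik <- matrix(1, dim(coords)[1], P)
  if (is.null(parts)) {
    sk <- default_skeleton()
    parts <- sk$body_parts[seq_len(P)]
  }
  keypoint_recording(coords, lik, parts, fps = 30)
}

test_that("gate_and_interpolate fills gaps linearly and flags errors", {
  coords <- array(0, dim = c(3, 8, 2))
  coords[1, , ] <- 0
  coords[2, , ] <- 5
  coords[3, , ] <- 2
  rec <- make_rec(coords)
  expect_identical(gate_and_interpolate(rec, 0.5)$coords, coords)

  # one bad frame between (0,0) and (2,2) -> (1,1)
  lik <- matrix(1, 3, 8)
  lik[2, 1] <- 0.1
  coords[3, 1, ] <- c(2, 2)
  coords[1, 1, ] <- c(0, 0)
  rec <- make_rec(coords, lik)
  g <- gate_and_interpolate(rec, 0.5)
  expect_equal(g$coords[2, 1, ], c(1, 1))
  expect_equal(g$likelihood[2, 1], 0.5)
  expect_identical(g$coords[, 2, ], coords[, 2, ])   # untouched parts

  bad <- make_rec(coords, matrix(c(rep(1, 3), rep(0, 3 * 7)), 3, 8))
  expect_error(gate_and_interpolate(bad, 0.5), "ear_left")
})

test_that("gating error stays below the track step size under 5% dropouts", {
  set.seed(8)
  T_ <- 500
  t <- seq_len(T_) / 30
  step <- 3                                  # mm per frame along the track
  base <- cbind(cumsum(rep(step, T_)) * cos(t / 5), 200 + 50 * sin(t / 3))
  coords <- array(0, dim = c(T_, 8, 2))
  sk <- default_skeleton()
  for (j in 1:8) coords[, j, ] <- base + rep(sk$template[j, ], each = T_)
  lik <- matrix(1, T_, 8)
  drop <- matrix(runif(T_ * 8) < 0.05, T_, 8)
  drop[1, ] <- drop[T_, ] <- FALSE
  lik[drop] <- 0
  rec <- keypoint_recording(coords, lik, sk$body_parts, fps = 30,
                            arena_size = c(2000, 2000))
  g <- gate_and_interpolate(rec, 0.5)
  err <- abs(g$coords - coords)
  expect_lt(max(err), step * sqrt(2) + 1e-9)
})

test_that("egocentric alignment is rigid-motion invariant and idempotent", {
  sk <- default_skeleton()
  T_ <- 4
  coords <- array(0, dim = c(T_, 8, 2))
  for (j in 1:8) coords[, j, ] <- rep(sk$template[j, ], each = T_)
  coords[, , 1] <- coords[, , 1] + 200    # place in arena
  coords[, , 2] <- coords[, , 2] + 200
  rec <- make_rec(coords)
  ps <- egocentric_align(rec)
  expect_equal(ps$heading, rep(0, T_), tolerance = 1e-12)
  # per-frame centroid of aligned pose is the origin
  expect_lt(max(abs(apply(ps$aligned, c(1, 3), mean))), 1e-9)
  # tail_base -> nose has zero y-component after alignment
  expect_lt(max(abs(ps$aligned[, 1, 2] - ps$aligned[, 8, 2])), 1e-9)

  # rotate 90 degrees and translate by (100, -50): same aligned pose
  th <- pi / 2
  rot <- array(0, dim = dim(coords))
  rot[, , 1] <- coords[, , 1] * cos(th) - coords[, , 2] * sin(th) + 100
  rot[, , 2] <- coords[, , 1] * sin(th) + coords[, , 2] * cos(th) - 50
  ps2 <- egocentric_align(keypoint_recording(rot, rec$likelihood,
                                             rec$body_parts, 30,
                                             arena_size = c(1000, 1000)))
  expect_equal(ps2$aligned, ps$aligned, tolerance = 1e-9)
  cx <- ps$centroid[1, 1]; cy <- ps$centroid[1, 2]
  expect_equal(ps2$centroid[1, ],
               c(cos(th) * cx - sin(th) * cy + 100,
                 sin(th) * cx + cos(th) * cy - 50),
               tolerance = 1e-9, ignore_attr = TRUE)

  # alignment of an aligned pose is a fixed point
  rec3 <- keypoint_recording(ps$aligned + 0, rec$likelihood, rec$body_parts,
                             30, arena_size = c(1000, 1000))
  ps3 <- egocentric_align(rec3)
  expect_equal(ps3$aligned, ps$aligned, tolerance = 1e-9)
})

test_that("coincident nose/tail_base reuses the previous heading with a warning", {
  sk <- default_skeleton()
  coords <- array(0, dim = c(3, 8, 2))
  for (j in 1:8) coords[, j, ] <- rep(sk$template[j, ] + 100, each = 3)
  coords[2, , 1] <- 100   # collapse frame 2 onto a point
  coords[2, , 2] <- 100
  rec <- make_rec(coords)
  expect_warning(ps <- egocentric_align(rec), "coincident")
  expect_equal(ps$heading[2], ps$heading[1])
})

test_that("PCA recovers planted structure and behaves as a projector", {
  set.seed(3)
  w <- small_world(n_syllables = 4, seed = 5)
  s <- simulate_session(w$repertoire, w$transitions, duration = 60, fps = 30,
                        jitter_sd = 0.3, seed = 6)
  ps <- egocentric_align(s$recording)
  model <- fit_pca(ps, 5)
  expect_equal(model$components %*% t(model$components), diag(5),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(model$explained_variance) <= 1e-12))

  z <- transform_pca(model, ps)
  expect_equal(nrow(z), 1800L)
  # training mean maps to zero
  X <- rbind(model$mean, model$mean)
  z0 <- sweep(X, 2, model$mean) %*% t(model$components)
  expect_lt(max(abs(z0)), 1e-10)
  # reconstruct-then-transform is identity on the latent space
  recon <- reconstruct_pca(model, z)
  z2 <- sweep(recon, 2, model$mean) %*% t(model$components)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-10, ignore_attr = TRUE)
  # explained variance of transformed training data matches model fractions
  ev <- apply(z, 2, var)
  frac <- ev / sum(ev)
  frac_model <- model$explained_variance[1:5] / sum(model$explained_variance[1:5])
  expect_equal(frac, frac_model, tolerance = 1e-8, ignore_attr = TRUE)

  # duplicated session: identical components up to sign
  model2 <- fit_pca(list(ps, ps), 5)
  flip <- sign(diag(model$components %*% t(model2$components)))
  expect_equal(model2$components * flip, model$components, tolerance = 1e-8)
})

test_that("data in a plane leaves trailing explained variance at zero", {
  set.seed(4)
  T_ <- 200
  sk <- default_skeleton()
  u <- rnorm(T_); v <- rnorm(T_)
  d1 <- rnorm(16); d2 <- rnorm(16)
  coords <- array(0, dim = c(T_, 8, 2))
  for (j in 1:8) {
    coords[, j, 1] <- 200 + sk$template[j, 1] + u * d1[2 * j - 1] + v * d2[2 * j - 1]
    coords[, j, 2] <- 200 + sk$template[j, 2] + u * d1[2 * j] + v * d2[2 * j]
  }
  # build the pose series directly (no rotation, heading fixed) so planarity
  # is preserved exactly
  cen <- cbind(rowMeans(coords[, , 1]), rowMeans(coords[, , 2]))
  aligned <- coords
  aligned[, , 1] <- coords[, , 1] - cen[, 1]
  aligned[, , 2] <- coords[, , 2] - cen[, 2]
  ps <- structure(list(aligned = aligned, centroid = cen,
                       heading = rep(0, T_), fps = 30,
                       body_parts = sk$body_parts), class = "pose_series")
  model <- fit_pca(ps, 5)
  expect_lt(sum(model$explained_variance[3:16]), 1e-10)
})

test_that("end-to-end rigid motion invariance of the latent series", {
  w <- small_world(n_syllables = 3, seed = 9)
  s <- simulate_session(w$repertoire, w$transitions, duration = 20, fps = 30,
                        jitter_sd = 0, seed = 10)
  rec <- s$recording
  th <- 0.7; shift <- c(30, -20)
  rot <- array(0, dim = dim(rec$coords))
  rot[, , 1] <- rec$coords[, , 1] * cos(th) - rec$coords[, , 2] * sin(th) + shift[1]
  rot[, , 2] <- rec$coords[, , 1] * sin(th) + rec$coords[, , 2] * cos(th) + shift[2]
  rec2 <- keypoint_recording(rot, rec$likelihood, rec$body_parts, rec$fps,
                             arena_size = c(2000, 2000))
  ps1 <- egocentric_align(rec)
  ps2 <- egocentric_align(rec2)
  model <- fit_pca(ps1, 5)
  z1 <- transform_pca(model, ps1)
  z2 <- transform_pca(model, ps2)
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_pca(ps1, 20), "n_components")
})

test_that("centroid track matches the generator within jitter-level error", {
  w <- small_world(n_syllables = 3, seed = 14)
  jit <- calibrate_noise(30, 30)
  s <- simulate_session(w$repertoire, w$transitions, duration = 30, fps = 30,
                        jitter_sd = jit, seed = 15)
  ps <- egocentric_align(s$recording)
  err <- sqrt(rowSums((ps$centroid - s$truth$centroid)^2))
  # error budget: common-mode jitter plus the AR pose wobble of the 8-part
  # centroid -- a few mm on a 400 mm arena
  expect_lt(mean(err), 5)
})
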