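#' Hyperparameters of the sticky AR-HMM
#'
#' The segmentation model is a finite weak-limit approximation of the sticky
#' HDP AR-HMM: `K_max` states, Dirichlet transition rows with concentration
#' `alpha / K_max` per cell plus a self-transition pseudo-count `kappa` on the
#' diagonal, and per-state linear-Gaussian autoregressive emissions of order
#' `ar_order` with a matrix-normal-inverse-Wishart (MNIW) prior whose mean
#' puts the identity on the most recent lag. `kappa` is the stickiness knob
#' that sets syllable durations and is what the duration-targeted scan tunes;
#' `gamma` is the top-level HDP concentration, retained for completeness but
#' inactive in the finite approximation.
#'
#' @param alpha Dirichlet concentration (default 5.7).
#' @param gamma Top-level concentration (default 1e3; documented knob,
#'   inactive in the finite formulation).
#' @param kappa Self-transition pseudo-count (>= 0).
#' @param K_max Maximum number of states (default 100).
#' @param ar_order Number of AR lags L (default 3).
#' @param mniw_k0 Scale of the column-precision prior K0 = mniw_k0 * I.
#' @param mniw_s0 Scale of the innovation prior S0 = mniw_s0 * I.
#' @param mniw_dof Inverse-Wishart dof; default latent dim + 2 (set at fit
#'   time when NULL); must exceed latent dim + 1.
#' @param n_iter Total Gibbs sweeps (default 500).
#' @param burn_in Sweeps regarded as burn-in (default 200); the returned
#'   model/labels are the final sample, so burn_in is documentation of the
#'   portion not to be trusted if sweeps are inspected.
#' @param seed RNG seed; fixed seed gives bit-identical fits.
#' @return Object of class `arhmm_hyper`.
#' @export
arhmm_hyper <- function(alpha = 5.7, gamma = 1e3, kappa = 1e4, K_max = 100L,
                        ar_order = 3L, mniw_k0 = 1, mniw_s0 = 1,
                        mniw_dof = NULL, n_iter = 500L, burn_in = 200L,
                        seed = 0L) {
  check_scalar_num(alpha, "alpha", lower = 0)
  check_scalar_num(gamma, "gamma", lower = 0)
  check_scalar_num(kappa, "kappa", lower = 0)
  if (K_max < 2) stopf("K_max must be >= 2")
  if (ar_order < 1) stopf("ar_order must be >= 1")
  structure(list(alpha = alpha, gamma = gamma, kappa = kappa,
                 K_max = as.integer(K_max), ar_order = as.integer(ar_order),
                 mniw_k0 = mniw_k0, mniw_s0 = mniw_s0, mniw_dof = mniw_dof,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "arhmm_hyper")
}

as_latent_list <- function(latents) {
  if (is.matrix(latents)) latents <- list(latents)
  if (!is.list(latents) || !all(vapply(latents, is.matrix, TRUE)))
    stopf("`latents` must be a matrix or list of matrices")
  latents
}

latent_fps <- function(latents) {
  fps <- attr(latents[[1]], "fps")
  if (is.null(fps)) 30 else fps
}

#' Fit the sticky AR-HMM by Gibbs sampling
#'
#' Alternates (i) conditional label sampling by forward-filter /
#' backward-sample given the AR parameters and transition matrix, and (ii)
#' conjugate parameter updates: MNIW for per-state AR coefficients and
#' innovation covariances, Dirichlet rows with `alpha / K_max` per cell plus
#' `kappa` on the diagonal for transitions. The final Gibbs sample defines the
#' returned model and labels (single-sample convention; no posterior
#' averaging).
#'
#' @param latents A frames x d latent matrix or list of them (one per
#'   session), e.g. from [transform_pca()].
#' @param hyper An [arhmm_hyper()].
#' @return List with `model` (class `arhmm_model`: `A` d x (d L + 1) per
#'   state with the bias in the last column, `Sigma` per state, `trans`
#'   K x K, `usage` frame counts, `hyper`) and `sequences` (list of
#'   `syllable_sequence`).
#' @export
fit_arhmm <- function(latents, hyper = arhmm_hyper()) {
  stopifnot(inherits(hyper, "arhmm_hyper"))
  latents <- as_latent_list(latents)
  d <- ncol(latents[[1]])
  for (y in latents) {
    if (ncol(y) != d) stopf("all latent series must share dimension %d", d)
    if (nrow(y) <= hyper$ar_order)
      stopf("latent series of %d frames is too short for ar_order %d",
            nrow(y), hyper$ar_order)
    if (!all(is.finite(y))) stopf("non-finite values in latent series")
  }
  L <- hyper$ar_order
  p <- d * L + 1L
  nu0 <- if (is.null(hyper$mniw_dof)) d + 2 else hyper$mniw_dof
  if (nu0 <= d + 1) stopf("mniw_dof must exceed latent dim + 1 = %d", d + 1)
  M0 <- matrix(0, d, p); M0[, seq_len(d)] <- diag(d)  # identity on last lag
  K0 <- diag(hyper$mniw_k0, p)
  S0 <- diag(hyper$mniw_s0, d)

  fps <- latent_fps(latents)
  fit <- with_seed(hyper$seed,
    cpp_arhmm_gibbs(lapply(latents, unclass), L, hyper$K_max, hyper$alpha,
                    hyper$kappa, M0, K0, S0, nu0, hyper$n_iter))
  model <- structure(list(A = fit$A, Sigma = fit$Sigma, trans = fit$trans,
                          usage = as.numeric(fit$usage), hyper = hyper,
                          latent_dim = d),
                     class = "arhmm_model")
  seqs <- lapply(seq_along(fit$labels), function(i)
    syllable_sequence(fit$labels[[i]], fps = fps, session = i))
  list(model = model, sequences = seqs)
}

#' @export
print.arhmm_model <- function(x, ...) {
  used <- sum(x$usage > 0)
  cat(sprintf("<arhmm_model> K_max=%d (%d used), d=%d, ar_order=%d, kappa=%g\n",
              x$hyper$K_max, used, x$latent_dim, x$hyper$ar_order,
              x$hyper$kappa))
  invisible(x)
}

#' Per-frame syllable labels
#'
#' @param labels Integer vector of 0-based syllable labels.
#' @param fps Frame rate, Hz.
#' @param session Session identifier.
#' @return Object of class `syllable_sequence`.
#' @export
syllable_sequence <- function(labels, fps = 30, session = 1L) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stopf("empty label sequence")
  if (any(labels < 0L)) stopf("labels must be non-negative")
  structure(list(labels = labels, fps = fps, session = session),
            class = "syllable_sequence")
}

#' @export
print.syllable_sequence <- function(x, ...) {
  cat(sprintf("<syllable_sequence> session %s: %d frames @ %g fps, %d syllables\n",
              x$session, length(x$labels), x$fps, length(unique(x$labels))))
  invisible(x)
}

#' Decode the most probable state path (Viterbi)
#'
#' Deterministic maximum a posteriori path under the model's AR likelihoods
#' and transition matrix.
#'
#' @param model An `arhmm_model`.
#' @param latent A frames x d latent matrix.
#' @param session Session id for the returned sequence.
#' @return A `syllable_sequence`.
#' @export
decode <- function(model, latent, session = 1L) {
  stopifnot(inherits(model, "arhmm_model"))
  latent <- unclass(latent)
  if (ncol(latent) != model$latent_dim)
    stopf("latent dimension %d does not match model (%d)",
          ncol(latent), model$latent_dim)
  fps <- attr(latent, "fps"); if (is.null(fps)) fps <- 30
  lab <- cpp_viterbi(latent, model$hyper$ar_order, model$A, model$Sigma,
                     model$trans)
  syllable_sequence(lab, fps = fps, session = session)
}

#' Forward-algorithm log-likelihood of a latent series under a fitted model
#'
#' @param model An `arhmm_model`.
#' @param latent A frames x d latent matrix.
#' @return Log-likelihood (natural log).
#' @export
arhmm_loglik <- function(model, latent) {
  stopifnot(inherits(model, "arhmm_model"))
  latent <- unclass(latent)
  cpp_forward_loglik(latent, model$hyper$ar_order, model$A, model$Sigma,
                     model$trans)
}

#' Syllable duration statistics
#'
#' Run-length encodes the label sequence; each run is one syllable instance
#' whose duration is its length in frames divided by fps.
#'
#' @param seq A `syllable_sequence` or list of them (pooled).
#' @return List with `mean_ms`, `median_ms`, and `per_syllable_ms` (named
#'   mean duration per syllable).
#' @export
duration_stats <- function(seq) {
  seqs <- if (inherits(seq, "syllable_sequence")) list(seq) else seq
  lens <- c(); vals <- c(); fps <- seqs[[1]]$fps
  for (s in seqs) {
    r <- rle(s$labels)
    lens <- c(lens, r$lengths)
    vals <- c(vals, r$values)
  }
  ms <- lens / fps * 1000
  per <- tapply(ms, vals, mean)
  list(mean_ms = mean(ms), median_ms = median(ms),
       per_syllable_ms = setNames(as.numeric(per), names(per)))
}

#' Duration-targeted kappa scan
#'
#' Fits one model per kappa value (same seed and other hyperparameters for
#' every fit), computes the median syllable duration of each fit's labels,
#' and selects the kappa whose median duration is closest to
#' `target_duration`; ties go to the smaller kappa. The stickier the model
#' (larger kappa), the longer the syllables, so the scan table's median
#' duration trends upward in kappa.
#'
#' @param latents Latent series (matrix or list).
#' @param hyper_base An [arhmm_hyper()]; its kappa is ignored.
#' @param kappa_grid Ascending numeric vector of kappa values.
#' @param target_duration Target median duration in ms (default 400,
#'   i.e. ~12 frames at 30 fps).
#' @return List with `kappa` (chosen), `fit` (the chosen model + sequences),
#'   and `scan` (data.frame: kappa, median_ms, mean_ms).
#' @export
kappa_scan <- function(latents, hyper_base = arhmm_hyper(),
                       kappa_grid, target_duration = 400) {
  if (missing(kappa_grid) || length(kappa_grid) == 0L)
    stopf("`kappa_grid` must be non-empty")
  if (is.unsorted(kappa_grid)) stopf("`kappa_grid` must be ascending")
  fits <- vector("list", length(kappa_grid))
  med <- mn <- numeric(length(kappa_grid))
  for (i in seq_along(kappa_grid)) {
    h <- hyper_base
    h$kappa <- kappa_grid[i]
    fits[[i]] <- fit_arhmm(latents, h)
    ds <- duration_stats(fits[[i]]$sequences)
    med[i] <- ds$median_ms
    mn[i] <- ds$mean_ms
  }
  gap <- abs(med - target_duration)
  best <- which(gap == min(gap))[1]           # ties -> smaller kappa
  list(kappa = kappa_grid[best], fit = fits[[best]],
       scan = data.frame(kappa = kappa_grid, median_ms = med, mean_ms = mn))
}

#' Greedy matching of estimated to true labels
#'
#' Builds the confusion matrix and greedily assigns each estimated state to
#' the true state it most overlaps (largest remaining cell first), for
#' evaluating segmentations against ground truth up to relabeling.
#'
#' @param est,truth Integer label vectors of equal length (0-based).
#' @return List with `mapping` (named vector est -> truth) and `accuracy`
#'   (fraction of frames matched after relabeling).
#' @export
match_labels <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  eu <- sort(unique(est)); tu <- sort(unique(truth))
  conf <- table(factor(est, eu), factor(truth, tu))
  mapping <- setNames(rep(NA_integer_, length(eu)), eu)
  cm <- as.matrix(conf)
  while (any(cm > -1)) {
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[idx[1], idx[2]] < 0) break
    mapping[rownames(cm)[idx[1]]] <- as.integer(colnames(cm)[idx[2]])
    cm[idx[1], ] <- -1
    cm[, idx[2]] <- -1
    if (all(cm < 0)) break
  }
  # unmatched estimated states (more est than true states): map to nearest
  for (e in names(mapping)[is.na(mapping)]) {
    row <- as.matrix(conf)[e, ]
    mapping[e] <- as.integer(names(which.max(row)))
  }
  remapped <- mapping[as.character(est)]
  list(mapping = mapping, accuracy = mean(remapped == truth))
}
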