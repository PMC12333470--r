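#' Per-frame centroid speed
#'
#' `speed[t] = ||centroid[t+1] - centroid[t]|| * fps`; the last frame repeats
#' the previous value so the series aligns one-to-one with frame labels.
#'
#' @param centroid_track frames x 2 matrix, mm.
#' @param fps Frame rate, Hz.
#' @return Numeric vector of speeds, mm/s, same length as the track.
#' @export
centroid_speed_series <- function(centroid_track, fps = 30) {
  centroid_track <- as.matrix(centroid_track)
  T_ <- nrow(centroid_track)
  if (T_ < 2L) stopf("need at least 2 frames")
  d <- diff(centroid_track)
  sp <- sqrt(rowSums(d^2)) * fps
  c(sp, sp[length(sp)])
}

#' Mean speed per syllable
#'
#' Averages the per-frame centroid speed over the frames assigned to each
#' syllable; this is the syllable "velocity" of motion-sequencing analyses.
#' Syllables absent from the sequence are simply not reported (missing, not
#' zero).
#'
#' @param speeds Per-frame speed vector (mm/s), e.g. from
#'   [centroid_speed_series()].
#' @param seq A `syllable_sequence` of the same length.
#' @return Named numeric vector: mean speed (mm/s) per syllable present.
#' @export
syllable_velocity <- function(speeds, seq) {
  stopifnot(inherits(seq, "syllable_sequence"))
  if (length(speeds) != length(seq$labels))
    stopf("speeds (%d) and labels (%d) differ in length",
          length(speeds), length(seq$labels))
  v <- tapply(speeds, seq$labels, mean)
  setNames(as.numeric(v), names(v))
}

#' Conventional session velocity
#'
#' Total distance traveled divided by session time (frames / fps).
#'
#' @inheritParams centroid_speed_series
#' @return Scalar, mm/s.
#' @export
session_velocity <- function(centroid_track, fps = 30) {
  centroid_track <- as.matrix(centroid_track)
  T_ <- nrow(centroid_track)
  if (T_ < 2L) stopf("need at least 2 frames")
  sum(sqrt(rowSums(diff(centroid_track)^2))) / (T_ / fps)
}

#' Syllable usage (time basis)
#'
#' Fraction of frames assigned to each syllable.
#'
#' @param seq A `syllable_sequence` or list of them (pooled).
#' @return Named numeric vector summing to 1.
#' @export
usage <- function(seq) {
  seqs <- if (inherits(seq, "syllable_sequence")) list(seq) else seq
  labels <- unlist(lapply(seqs, `[[`, "labels"))
  tab <- table(labels)
  setNames(as.numeric(tab) / length(labels), names(tab))
}

#' Expression filter
#'
#' Keeps the syllables expressed more than `threshold` of the time (default
#' 0.5%), the usual cut for reporting per-syllable statistics.
#'
#' @param usages Named usage vector from [usage()].
#' @param threshold Usage fraction; strictly greater-than is kept.
#' @return Character vector of retained syllable ids.
#' @export
filter_expressed <- function(usages, threshold = 0.005) {
  names(usages)[usages > threshold]
}

#' Transitions per second
#'
#' Number of label changes between consecutive frames divided by session
#' time; equals (number of run-length runs - 1) / (frames / fps).
#'
#' @param seq A `syllable_sequence`.
#' @return Scalar, transitions per second.
#' @export
transition_frequency <- function(seq) {
  stopifnot(inherits(seq, "syllable_sequence"))
  changes <- sum(diff(seq$labels) != 0)
  changes / (length(seq$labels) / seq$fps)
}

#' Syllable transition matrix and sequence summary
#'
#' Run-length encodes the sequence (self-transitions excluded, the standard
#' motion-sequencing convention), restricts the run sequence to `alphabet`,
#' counts bigrams between consecutive distinct retained syllables, and
#' row-normalizes into the transition matrix A. Rows with no outgoing counts
#' are left as zero rows and excluded from entropy sums. The steady-state
#' distribution, entropy (with the recorded conventions), and transition
#' frequency are attached.
#'
#' @param seq A `syllable_sequence`.
#' @param alphabet Syllable ids (integer) defining the state space; default
#'   all syllables present in the sequence.
#' @param log_base Base for the recorded entropy (default 2, bits).
#' @param mode Entropy mode recorded, "rate" or "local_sum".
#' @return Object of class `transition_summary`: `counts`, `A`, `pi`,
#'   `entropy`, `transition_frequency`, `alphabet`, `log_base`, `mode`,
#'   `self_transitions` (always "excluded"), `usage` (empirical, over
#'   alphabet).
#' @export
transition_matrix <- function(seq, alphabet = NULL, log_base = 2,
                              mode = "rate") {
  stopifnot(inherits(seq, "syllable_sequence"))
  if (is.null(alphabet)) alphabet <- sort(unique(seq$labels))
  alphabet <- as.integer(alphabet)
  if (length(alphabet) == 0L) stopf("`alphabet` must be non-empty")
  runs <- rle(seq$labels)$values
  runs <- runs[runs %in% alphabet]
  K <- length(alphabet)
  counts <- matrix(0, K, K, dimnames = list(alphabet, alphabet))
  if (length(runs) >= 2L) {
    from <- match(runs[-length(runs)], alphabet)
    to <- match(runs[-1L], alphabet)
    keep <- from != to   # removing filtered syllables can abut equal runs
    for (i in which(keep)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  A <- counts
  A[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]

  emp <- table(factor(seq$labels[seq$labels %in% alphabet], alphabet))
  emp <- as.numeric(emp) / max(1, sum(emp))
  out <- structure(list(counts = counts, A = A, pi = NULL, entropy = NULL,
                        transition_frequency = transition_frequency(seq),
                        alphabet = alphabet, log_base = log_base, mode = mode,
                        self_transitions = "excluded", usage = emp),
                   class = "transition_summary")
  out$pi <- steady_state(A, usage_hint = emp)
  out$entropy <- entropy(out, log_base = log_base, mode = mode)
  out
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %d states, entropy=%.3f (%s, base %g), %.2f transitions/s\n",
              length(x$alphabet), x$entropy, x$mode, x$log_base,
              x$transition_frequency))
  invisible(x)
}

# closed communicating classes of a row-stochastic matrix (boolean reachability)
closed_classes <- function(A, tol = 1e-12) {
  K <- nrow(A)
  R <- (A > tol) | diag(TRUE, K)
  for (i in seq_len(ceiling(log2(max(2, K))) + 1L)) R <- (R %*% R) > 0
  classes <- list()
  seen <- rep(FALSE, K)
  for (i in seq_len(K)) {
    if (seen[i]) next
    cls <- which(R[i, ] & R[, i])
    seen[cls] <- TRUE
    reach_out <- any(R[i, ] & !(seq_len(K) %in% cls))
    if (!reach_out) classes[[length(classes) + 1L]] <- cls
  }
  classes
}

#' Steady-state distribution of a transition matrix
#'
#' Principal left eigenvector of A restricted to its recurrent support,
#' found by power iteration to 1e-12 and normalized to sum 1. For a
#' reducible chain with several closed classes, the class holding the most
#' empirical usage mass is used and a warning is emitted.
#'
#' @param A Row-stochastic matrix (zero rows allowed; they are transient).
#' @param usage_hint Optional empirical usage over the same states, used to
#'   pick among multiple closed classes.
#' @return Numeric vector pi of the same length as nrow(A), summing to 1.
#' @export
steady_state <- function(A, usage_hint = NULL) {
  A <- as.matrix(A)
  K <- nrow(A)
  if (K == 1L) return(1)
  support <- rowSums(A) > 1e-9
  if (!any(support)) return(rep(1 / K, K))
  classes <- closed_classes(A[support, support, drop = FALSE])
  idx_support <- which(support)
  if (length(classes) == 0L) classes <- list(seq_len(sum(support)))
  if (length(classes) > 1L) {
    mass <- vapply(classes, function(cls) {
      if (is.null(usage_hint)) length(cls)
      else sum(usage_hint[idx_support[cls]])
    }, numeric(1))
    warnf("reducible chain with %d closed classes; using the class with most mass",
          length(classes))
    cls <- classes[[which.max(mass)]]
  } else cls <- classes[[1]]
  sel <- idx_support[cls]
  M <- A[sel, sel, drop = FALSE]
  M <- M / rowSums(M)
  pi_ <- rep(1 / length(sel), length(sel))
  for (i in seq_len(100000L)) {
    nxt <- as.numeric(pi_ %*% M)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_)) < 1e-12) { pi_ <- nxt; break }
    pi_ <- nxt
  }
  out <- rep(0, K)
  out[sel] <- pi_
  out
}

#' Entropy of the syllable transition structure
#'
#' Mode "rate": H = -sum_ij pi_i A_ij log A_ij over cells with A_ij > 0 --
#' the entropy rate of the Markov chain, a measure of how unpredictable the
#' next syllable is (lower = more stereotyped behavior). Mode "local_sum":
#' the unweighted sum over syllables of their outgoing-row entropies.
#' Both are returned positive; base 2 (bits) by default.
#'
#' @param summary A `transition_summary`.
#' @param log_base Logarithm base (2 for bits, exp(1) for nats).
#' @param mode "rate" or "local_sum".
#' @return Non-negative scalar.
#' @export
entropy <- function(summary, log_base = 2, mode = c("rate", "local_sum")) {
  stopifnot(inherits(summary, "transition_summary"))
  mode <- match.arg(mode)
  A <- summary$A
  rows <- which(rowSums(summary$counts) > 0)
  row_H <- vapply(rows, function(i) {
    p <- A[i, ]
    p <- p[p > 0]
    -sum(p * log(p)) / log(log_base)
  }, numeric(1))
  if (mode == "rate") {
    pi_ <- summary$pi
    sum(pi_[rows] * row_H)
  } else {
    sum(row_H)
  }
}

#' Per-animal syllable statistics table
#'
#' Computes, for each animal, per-syllable velocity and usage (plus duration
#' and instance count), then averages across animals within the group
#' (mean +/- sem), the standard per-animal-then-average aggregation. Animals
#' missing a syllable contribute no velocity estimate for it (not zero).
#'
#' @param animals List of animals; each a list with `seq` (a
#'   `syllable_sequence`) and `centroid` (frames x 2 track, mm).
#' @return List with `table` (data.frame: syllable, velocity, velocity_sem,
#'   usage, usage_sem, duration_ms, instances, n_animals) and `per_animal`
#'   (list of data.frames).
#' @export
syllable_stats <- function(animals) {
  per_animal <- lapply(animals, function(a) {
    sp <- centroid_speed_series(a$centroid, a$seq$fps)
    v <- syllable_velocity(sp, a$seq)
    u <- usage(a$seq)
    r <- rle(a$seq$labels)
    dur <- tapply(r$lengths / a$seq$fps * 1000, r$values, mean)
    inst <- table(r$values)
    data.frame(syllable = as.integer(names(v)),
               velocity = as.numeric(v),
               usage = as.numeric(u[names(v)]),
               duration_ms = as.numeric(dur[names(v)]),
               instances = as.integer(inst[names(v)]))
  })
  all_syl <- sort(unique(unlist(lapply(per_animal, `[[`, "syllable"))))
  agg <- lapply(all_syl, function(s) {
    rows <- lapply(per_animal, function(df) df[df$syllable == s, ])
    v <- unlist(lapply(rows, function(r) if (nrow(r)) r$velocity else NA_real_))
    # usage basis: animals without the syllable used it 0% of the time
    u <- unlist(lapply(rows, function(r) if (nrow(r)) r$usage else 0))
    d <- unlist(lapply(rows, function(r) if (nrow(r)) r$duration_ms else NA_real_))
    i <- unlist(lapply(rows, function(r) if (nrow(r)) r$instances else 0L))
    data.frame(syllable = s,
               velocity = mean(v, na.rm = TRUE), velocity_sem = sem(v),
               usage = mean(u), usage_sem = sem(u),
               duration_ms = mean(d, na.rm = TRUE),
               instances = sum(i), n_animals = sum(!is.na(v)))
  })
  list(table = do.call(rbind, agg), per_animal = per_animal)
}

#' Per-syllable group differences joined with control velocity
#'
#' Computes delta = control minus other for velocity and usage on the matched
#' syllables; unmatched syllables are dropped with a message. The control
#' velocity column supports the delta-vs-velocity regressions that test
#' whether faster syllables are preferentially affected.
#'
#' @param stats_control,stats_other data.frames with columns `syllable`,
#'   `velocity`, `usage` (e.g. `syllable_stats(...)$table`).
#' @return data.frame: syllable, control_velocity, delta_velocity,
#'   delta_usage.
#' @export
delta_table <- function(stats_control, stats_other) {
  shared <- intersect(stats_control$syllable, stats_other$syllable)
  if (length(shared) == 0L) stopf("no shared syllables between groups")
  dropped <- setdiff(union(stats_control$syllable, stats_other$syllable), shared)
  if (length(dropped))
    message(sprintf("delta_table: dropping %d unmatched syllable(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  a <- stats_control[match(shared, stats_control$syllable), ]
  b <- stats_other[match(shared, stats_other$syllable), ]
  data.frame(syllable = shared,
             control_velocity = a$velocity,
             delta_velocity = a$velocity - b$velocity,
             delta_usage = a$usage - b$usage)
}
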