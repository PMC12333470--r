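#' Read a DeepLabCut-dialect keypoint CSV
#'
#' Expects the 3-row header (scorer / bodyparts / coords) with per-part x, y,
#' likelihood columns and a leading frame-index column. Files whose coords
#' row lacks likelihood columns are accepted with likelihood 1 and a warning;
#' inconsistent part column sets are a hard error; malformed numeric cells
#' are reported with their row number.
#'
#' @param path CSV path.
#' @param fps Frame rate (not stored in DLC CSVs; flag or sidecar knowledge).
#' @param arena_size Arena extent in mm.
#' @return A [keypoint_recording()].
#' @export
read_dlc_csv <- function(path, fps = 30, arena_size = c(400, 400)) {
  lines <- readLines(path)
  if (length(lines) < 4L) stopf("'%s': truncated file (%d lines; need 3 header rows + data)",
                                path, length(lines))
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  if (!identical(tolower(hdr[[1]][1]), "scorer") ||
      !identical(tolower(hdr[[2]][1]), "bodyparts") ||
      !identical(tolower(hdr[[3]][1]), "coords"))
    stopf("'%s': expected header rows scorer / bodyparts / coords", path)
  parts_row <- hdr[[2]][-1]
  coords_row <- tolower(hdr[[3]][-1])
  if (!all(coords_row %in% c("x", "y", "likelihood")))
    stopf("'%s': coords row entries must be x, y or likelihood", path)
  body_parts <- unique(parts_row)
  per_part <- split(coords_row, factor(parts_row, levels = body_parts))
  shapes <- vapply(per_part, function(v) paste(sort(v), collapse = "+"), "")
  if (length(unique(shapes)) != 1L)
    stopf("'%s': inconsistent column sets across body parts", path)
  has_lik <- "likelihood" %in% coords_row
  if (!has_lik)
    warnf("'%s': no likelihood columns; assuming likelihood = 1", path)

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(data_lines)]
  T_ <- length(data_lines)
  ncol_expect <- length(parts_row) + 1L
  P <- length(body_parts)
  coords <- array(NA_real_, dim = c(T_, P, 2L))
  lik <- matrix(1, T_, P)
  col_part <- match(parts_row, body_parts)
  for (t in seq_len(T_)) {
    cells <- strsplit(data_lines[t], ",", fixed = TRUE)[[1]]
    if (length(cells) != ncol_expect)
      stopf("'%s': line %d has %d fields, expected %d", path, t + 3L,
            length(cells), ncol_expect)
    vals <- suppressWarnings(as.numeric(cells[-1]))
    bad <- which(is.na(vals) & cells[-1] != "NA" & cells[-1] != "")
    if (length(bad))
      stopf("'%s': malformed numeric cell on line %d (column %d)", path,
            t + 3L, bad[1] + 1L)
    for (c_ in seq_along(vals)) {
      j <- col_part[c_]
      switch(coords_row[c_],
             x = { coords[t, j, 1] <- vals[c_] },
             y = { coords[t, j, 2] <- vals[c_] },
             likelihood = { lik[t, j] <- vals[c_] })
    }
  }
  keypoint_recording(coords, lik, body_parts, fps = fps,
                     arena_size = arena_size)
}

#' Write a keypoint recording as a DeepLabCut-dialect CSV
#'
#' @param rec A [keypoint_recording()].
#' @param path Output path.
#' @param scorer Scorer tag for the first header row.
#' @export
write_dlc_csv <- function(rec, path, scorer = "syllakin") {
  stopifnot(inherits(rec, "keypoint_recording"))
  P <- length(rec$body_parts)
  hdr1 <- c("scorer", rep(scorer, 3L * P))
  hdr2 <- c("bodyparts", rep(rec$body_parts, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), P))
  T_ <- n_frames(rec)
  M <- matrix(0, T_, 3L * P)
  for (j in seq_len(P)) {
    M[, 3L * j - 2L] <- rec$coords[, j, 1]
    M[, 3L * j - 1L] <- rec$coords[, j, 2]
    M[, 3L * j] <- rec$likelihood[, j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  body <- cbind(seq_len(T_) - 1L, format(M, trim = TRUE, digits = 10))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write / read per-frame label CSVs
#'
#' Plain CSV with columns `session`, `frame` (0-based), `label`.
#'
#' @param seqs A `syllable_sequence` or list of them.
#' @param path Output path.
#' @export
write_labels_csv <- function(seqs, path) {
  if (inherits(seqs, "syllable_sequence")) seqs <- list(seqs)
  df <- do.call(rbind, lapply(seqs, function(s)
    data.frame(session = s$session, frame = seq_along(s$labels) - 1L,
               label = s$labels)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @param fps Frame rate to attach to the sequences.
#' @return `read_label_csv`: list of `syllable_sequence`, one per session.
#' @export
read_label_csv <- function(path, fps = 30) {
  df <- read.csv(path)
  if (!"label" %in% names(df)) stopf("'%s': no `label` column", path)
  if (!"session" %in% names(df)) df$session <- 1L
  lapply(split(df, df$session), function(d)
    syllable_sequence(d$label[order(d$frame)], fps = fps,
                      session = d$session[1]))
}

#' Serialize / load an AR-HMM model as JSON
#'
#' @param model An `arhmm_model`.
#' @param path JSON path.
#' @export
save_arhmm_model <- function(model, path) {
  stopifnot(inherits(model, "arhmm_model"))
  obj <- list(hyper = unclass(model$hyper), latent_dim = model$latent_dim,
              A = model$A, Sigma = model$Sigma, trans = model$trans,
              usage = model$usage)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_arhmm_model
#' @return `load_arhmm_model`: the `arhmm_model`.
#' @export
load_arhmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hy <- obj$hyper
  hyper <- arhmm_hyper(alpha = hy$alpha, gamma = hy$gamma, kappa = hy$kappa,
                       K_max = hy$K_max, ar_order = hy$ar_order,
                       mniw_k0 = hy$mniw_k0, mniw_s0 = hy$mniw_s0,
                       mniw_dof = hy$mniw_dof, n_iter = hy$n_iter,
                       burn_in = hy$burn_in, seed = hy$seed)
  A <- lapply(seq_len(dim(obj$A)[1]), function(k) obj$A[k, , ])
  Sigma <- lapply(seq_len(dim(obj$Sigma)[1]), function(k) obj$Sigma[k, , ])
  structure(list(A = A, Sigma = Sigma, trans = obj$trans,
                 usage = obj$usage, hyper = hyper,
                 latent_dim = obj$latent_dim),
            class = "arhmm_model")
}

#' Write ground truth of a simulated session
#'
#' Sidecar pair: `<prefix>_labels.csv` (frame, label) and `<prefix>_truth.json`
#' (true transition matrix, speeds, seed).
#'
#' @param truth `ground_truth` from [simulate_session()].
#' @param prefix Path prefix.
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  write.csv(data.frame(frame = seq_along(truth$labels) - 1L,
                       label = truth$labels),
            paste0(prefix, "_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(transitions = truth$transitions,
                            speeds = truth$speeds, seed = truth$seed),
                       paste0(prefix, "_truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' Published per-syllable summary tables shipped with the package
#'
#' Plain-CSV transcriptions of per-syllable group summary statistics
#' (velocity and usage, mean +/- sem, with raw p values) from an open-field
#' study of parkinsonian mice: a 6-OHDA lesion cohort versus controls, and a
#' progressive (mitoPark) cohort at 8, 14 and 24 weeks versus littermate
#' controls. Used as desk-scale fixtures for the delta-metric regressions and
#' significance-count checks.
#'
#' @param which "6ohda" or "mitopark".
#' @return data.frame; the mitoPark table carries an `age_weeks` column.
#' @export
reference_syllable_table <- function(which = c("6ohda", "mitopark")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("syllable_stats_", which, ".csv"),
                   package = "syllakin", mustWork = TRUE)
  read.csv(f)
}
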