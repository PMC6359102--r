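#' Generate a Stroop-style concurrent label track
#'
#' Emulates the interactive color-word protocol: segments alternate
#' congruent/incongruent within each of four difficulty levels; the raw
#' label is the difficulty (1-4) for congruent segments and difficulty + 4
#' (5-8) for incongruent segments, then normalized to `[0, 1]` by
#' `(raw - 1) / 7`.
#'
#' @param n_segments_per_level congruent/incongruent segment pairs per
#'   difficulty level.
#' @param segment_duration segment length in seconds.
#' @param seed RNG seed.
#' @return data.frame with `difficulty`, `congruency`, `start`, `end`,
#'   `raw_label`, `label`; plus a `label_fun` attribute (step function of
#'   time usable by [segment_windows()]).
#' @export
gen_stroop_labels <- function(n_segments_per_level = 2,
                              segment_duration = 10, seed = 1) {
  stopifnot(n_segments_per_level >= 1)
  set_gen_seed(seed)
  rows <- list()
  t0 <- 0
  for (level in 1:4) {
    for (r in seq_len(n_segments_per_level)) {
      for (cg in c("congruent", "incongruent")) {
        raw <- if (cg == "congruent") level else level + 4
        rows[[length(rows) + 1]] <- data.frame(
          difficulty = level, congruency = cg, start = t0,
          end = t0 + segment_duration, raw_label = raw,
          label = normalize_stroop_label(raw))
        t0 <- t0 + segment_duration
      }
    }
  }
  track <- do.call(rbind, rows)
  lab <- track$label; st <- track$start; en <- track$end
  attr(track, "label_fun") <- function(t) {
    i <- findInterval(t, st)
    ifelse(i >= 1 & t <= en[pmax(i, 1)] + 1e-9, lab[pmax(i, 1)], NA_real_)
  }
  track
}

# generators are pure functions of (parameters, seed): every generator
# reseeds the RNG from its seed argument on entry
set_gen_seed <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}

#' Generate a synthetic blood-volume-pulse signal
#'
#' A phase-locked pulse train: each cardiac cycle is a fixed waveform in
#' beat phase (systolic upstroke and peak plus a smaller dicrotic wave)
#' with the diastolic trough at the cycle boundary. The inter-beat interval
#' shrinks with stress (`IBI = 0.9 - 0.25 * stress` seconds plus per-beat
#' jitter) and the beat amplitude decreases linearly with stress,
#' reflecting peripheral vasoconstriction under sympathetic activation.
#' Additive Gaussian noise.
#'
#' @param stress latent stress level in `[0, 1]`.
#' @param duration seconds.
#' @param fs sampling rate in Hz (default 128).
#' @param seed RNG seed.
#' @param base_ibi override of the stress-determined mean IBI (seconds);
#'   default `0.9 - 0.25 * stress`.
#' @param ibi_jitter_sd per-beat IBI jitter SD in seconds.
#' @param noise_sd additive noise SD.
#' @return A [signal_record()] (channel BVP) with attributes `beat_times`
#'   (diastolic onsets, seconds) and `true_ibi` (the configured mean IBI).
#' @export
gen_bvp_signal <- function(stress, duration = 3, fs = 128, seed = 1,
                           base_ibi = NULL, ibi_jitter_sd = 0.01,
                           noise_sd = 0.02) {
  stopifnot(stress >= 0, stress <= 1, duration > 0)
  set_gen_seed(seed)
  ibi <- if (is.null(base_ibi)) 0.9 - 0.25 * stress else base_ibi
  amp <- 1 - 0.4 * stress
  # diastolic onset times covering [-ibi, duration + ibi] so edge beats are
  # complete; each cardiac cycle is a fixed waveform in beat phase u in
  # [0, 1): systolic upstroke/peak plus a smaller dicrotic wave, with the
  # diastolic trough (the signal minimum) at the cycle boundary
  times <- -2 * ibi
  while (times[length(times)] < duration + 2 * ibi) {
    times <- c(times, times[length(times)] + ibi +
                 stats::rnorm(1, 0, ibi_jitter_sd))
  }
  beat_shape <- function(u) {
    exp(-((u - 0.32)^2) / (2 * 0.16^2)) +
      0.2 * exp(-((u - 0.58)^2) / (2 * 0.1^2))
  }
  t <- (seq_len(round(duration * fs)) - 1) / fs
  cycle <- findInterval(t, times)
  u <- (t - times[cycle]) / (times[cycle + 1] - times[cycle])
  x <- amp * beat_shape(u) + stats::rnorm(length(t), 0, noise_sd)
  rec <- signal_record(x, fs, "BVP")
  attr(rec, "beat_times") <- times[times >= 0 & times < duration]
  attr(rec, "true_ibi") <- ibi
  rec
}

#' Generate a synthetic galvanic-skin-response signal
#'
#' Tonic component: a slowly drifting baseline (random walk) whose level
#' rises with stress. Phasic component: Poisson-count skin conductance
#' responses whose rate and amplitude increase with stress, each with a
#' fast rise and slow exponential decay. Conductance in microsiemens.
#'
#' @param stress latent stress level in `[0, 1]`.
#' @param duration seconds.
#' @param fs sampling rate in Hz (default 4).
#' @param seed RNG seed.
#' @param scr_rate_range SCR events per second at stress 0 and 1.
#' @param scr_amp_range SCR amplitude (uS) at stress 0 and 1.
#' @param drift_sd per-sqrt-second SD of the tonic random walk.
#' @param event_times optional explicit SCR onset times (seconds),
#'   overriding the Poisson draw (used for controlled injection).
#' @return A [signal_record()] (channel GSR) with attribute `scr_times`.
#' @export
gen_gsr_signal <- function(stress, duration = 30, fs = 4, seed = 1,
                           scr_rate_range = c(0.05, 0.3),
                           scr_amp_range = c(0.2, 0.8),
                           drift_sd = 0.01, event_times = NULL) {
  stopifnot(stress >= 0, stress <= 1, duration >= 1 / fs)
  set_gen_seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  # tonic drift is smooth on the sweating/autoregulation timescale: a
  # random walk low-passed by a ~4 s moving average
  walk <- cumsum(stats::rnorm(n, 0, drift_sd / sqrt(fs)))
  w <- max(1, round(4 * fs))
  padded <- c(rep(walk[1], w), walk, rep(walk[n], w))
  sm <- stats::filter(padded, rep(1 / w, w), sides = 2)
  drift <- as.numeric(sm[(w + 1):(w + n)])
  tonic <- 2 + stress + drift
  rate <- scr_rate_range[1] + diff(scr_rate_range) * stress
  if (is.null(event_times)) {
    n_ev <- stats::rpois(1, rate * duration)
    event_times <- sort(stats::runif(n_ev, 0, max(duration - 3, 0)))
  }
  amp0 <- scr_amp_range[1] + diff(scr_amp_range) * stress
  x <- tonic
  tau_r <- 0.75; tau_d <- 2.5
  peak <- (tau_d / tau_r)^(-tau_r / (tau_d - tau_r)) -
    (tau_d / tau_r)^(-tau_d / (tau_d - tau_r)) # kernel maximum, for scaling
  for (et in event_times) {
    a <- amp0 * stats::runif(1, 0.8, 1.2)
    dt <- t - et
    k <- ifelse(dt > 0, exp(-dt / tau_d) - exp(-dt / tau_r), 0)
    x <- x + a * k / peak
  }
  rec <- signal_record(x, fs, "GSR")
  attr(rec, "scr_times") <- event_times
  rec
}

#' Generate a multi-subject feature dataset
#'
#' Emulates the statistical structure of multi-subject peripheral
#' physiological features: labels drawn from the normalized Stroop set
#' (raw 1-8 mapped to `[0, 1]`), per-subject latent stress-to-feature maps
#' (shared linear/quadratic response plus subject-specific deviations
#' scaled by `heterogeneity`), subject-specific feature offsets (strong
#' between-subject dispersion), and Gaussian observation noise.
#' `heterogeneity = 0` gives identical subjects (the homogeneous limit);
#' larger values spread the subjects apart faster than the within-subject
#' label response, as observed in real multi-subject recordings.
#' `imbalance` in `[0, 1)` geometrically thins high labels:
#' `P(raw = r) proportional to (1 - imbalance)^(r - 1)`.
#'
#' @param n_subjects,n_per_subject dataset dimensions.
#' @param heterogeneity between-subject dispersion scale (>= 0).
#' @param imbalance label-thinning factor in `[0, 1)`.
#' @param n_features feature dimension (default 6).
#' @param noise_sd observation noise SD.
#' @param seed RNG seed.
#' @return A [labeled_dataset()]; attribute `profiles` holds each
#'   subject's offset and response coefficients.
#' @export
gen_multisubject_features <- function(n_subjects = 5, n_per_subject = 60,
                                      heterogeneity = 1, imbalance = 0,
                                      n_features = 6, noise_sd = 0.1,
                                      seed = 1) {
  stopifnot(n_subjects >= 1, n_per_subject >= 1, heterogeneity >= 0,
            imbalance >= 0, imbalance < 1)
  set_gen_seed(seed)
  base_slope <- rep_len(c(1, -0.8, 0.6, 1.2, -0.5, 0.9), n_features)
  base_quad <- rep_len(c(0.4, 0, -0.6, 0.2, 0.5, 0), n_features)
  raw_levels <- 1:8
  probs <- (1 - imbalance)^(raw_levels - 1)
  probs <- probs / sum(probs)

  profiles <- list()
  Xs <- list(); ys <- list(); sids <- list()
  for (s in seq_len(n_subjects)) {
    # heterogeneity scales the between-subject positional dispersion
    # (offsets larger than the within-subject response range, as in the
    # strongly clustered embeddings of real multi-subject recordings) and
    # the subject-specific response deviations (different subjects map the
    # same stress level to different feature displacements), which together
    # defeat pooled inductive fits while leaving local structure intact
    offset <- stats::rnorm(n_features, 0, 1.0) * heterogeneity
    dslope <- stats::rnorm(n_features, 0, 0.6) * heterogeneity
    dquad <- stats::rnorm(n_features, 0, 0.8) * heterogeneity
    raw <- sample(raw_levels, n_per_subject, replace = TRUE, prob = probs)
    y <- normalize_stroop_label(raw)
    slope <- base_slope + dslope
    quad <- base_quad + dquad
    X <- outer(y, slope) + outer(y^2, quad) +
      matrix(offset, n_per_subject, n_features, byrow = TRUE) +
      matrix(stats::rnorm(n_per_subject * n_features, 0, noise_sd),
             n_per_subject, n_features)
    profiles[[s]] <- list(subject_id = sprintf("s%02d", s), offset = offset,
                          slope = slope, quad = quad, noise_sd = noise_sd)
    Xs[[s]] <- X; ys[[s]] <- y
    sids[[s]] <- rep(sprintf("s%02d", s), n_per_subject)
  }
  d <- labeled_dataset(do.call(rbind, Xs), unlist(ys), unlist(sids))
  attr(d, "profiles") <- profiles
  d
}

#' Min-max normalize the features of a labeled dataset
#'
#' Convenience wrapper mapping every feature column of the dataset onto
#' `[0, 1]` (see [fit_scaler()]); labels are left unchanged (already on the
#' unit scale).
#'
#' @param dataset a [labeled_dataset()].
#' @param scaler optional scaler fitted elsewhere (e.g. on training data
#'   only); default fits on `dataset` itself.
#' @return A normalized [labeled_dataset()].
#' @export
normalize_dataset <- function(dataset, scaler = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$X)
  if (is.null(scaler)) scaler <- fit_scaler(df)
  labeled_dataset(as.matrix(apply_scaler(scaler, df)), dataset$y,
                  dataset$subject_id)
}

#' Generate a mislabeled-outlier scenario
#'
#' One coherent cluster: features follow a common linear response to
#' labels in a low range, so feature-space neighbors have similar labels.
#' `n_outliers` additional examples are feature-adjacent (drawn from the
#' same feature law) but carry a mislabeled y near the top of the scale.
#' Ground-truth flags are returned so tests can assert which examples the
#' dispersion penalty should exclude.
#'
#' @param n_clean,n_outliers example counts.
#' @param seed RNG seed.
#' @param n_features feature dimension.
#' @return List with `dataset` (a [labeled_dataset()]), logical
#'   `is_outlier`, and `true_y` (the labels the features actually encode).
#' @export
gen_outlier_scenario <- function(n_clean = 30, n_outliers = 4, seed = 1,
                                 n_features = 4) {
  stopifnot(n_outliers >= 1, n_clean >= 5)
  set_gen_seed(seed)
  slope <- rep_len(c(1, -0.7, 0.5, 0.9), n_features)
  y_true <- stats::runif(n_clean + n_outliers, 0.1, 0.35)
  X <- outer(y_true, slope) +
    matrix(stats::rnorm(length(y_true) * n_features, 0, 0.02),
           ncol = n_features)
  is_outlier <- c(rep(FALSE, n_clean), rep(TRUE, n_outliers))
  y_obs <- y_true
  y_obs[is_outlier] <- stats::runif(n_outliers, 0.85, 0.95)
  list(dataset = labeled_dataset(X, y_obs, "s01"),
       is_outlier = is_outlier, true_y = y_true)
}

#' Write a synthetic session to E4-style signal files
#'
#' Generates one BVP and one GSR recording whose latent stress follows a
#' Stroop label track, and writes them as `<session>_BVP.csv` /
#' `<session>_GSR.csv` in `dir`, plus a ground-truth JSON
#' (`<session>_truth.json`) with the seed and the label track.
#'
#' @param dir output directory (created if needed).
#' @param session session name used as the file prefix.
#' @param track a [gen_stroop_labels()] track (generated if `NULL`).
#' @param seed RNG seed.
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_session <- function(dir, session = "session1", track = NULL,
                                    seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(track)) track <- gen_stroop_labels(seed = seed)
  duration <- max(track$end)
  # piecewise-stationary signals: one segment per labeled interval
  bvp <- numeric(0); gsr <- numeric(0)
  for (r in seq_len(nrow(track))) {
    seg_d <- track$end[r] - track$start[r]
    bvp <- c(bvp, gen_bvp_signal(track$label[r], seg_d, 128,
                                 seed = seed + r)$samples)
    gsr <- c(gsr, gen_gsr_signal(track$label[r], seg_d, 4,
                                 seed = seed + r)$samples)
  }
  paths <- list(
    bvp = file.path(dir, paste0(session, "_BVP.csv")),
    gsr = file.path(dir, paste0(session, "_GSR.csv")),
    truth = file.path(dir, paste0(session, "_truth.json"))
  )
  write_signal_csv(signal_record(bvp, 128, "BVP"), paths$bvp)
  write_signal_csv(signal_record(gsr, 4, "GSR"), paths$gsr)
  jsonlite::write_json(
    list(session = session, seed = seed, duration = duration,
         track = track[c("difficulty", "congruency", "start", "end",
                         "raw_label", "label")]),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
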