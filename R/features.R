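#' Locate strict local extrema with a minimum separation
#'
#' Extreme values calculation (EVC): strict local minima or maxima of a
#' sampled signal. When two extrema fall closer than `min_separation`
#' samples, the more extreme one is kept (ties keep the earlier index).
#'
#' @param x numeric signal, `length(x) >= 3`.
#' @param kind `"minima"` or `"maxima"`.
#' @param min_separation minimum index distance between returned extrema.
#' @return Integer vector of extremum indices (possibly empty), increasing.
#' @export
detect_extrema <- function(x, kind = c("minima", "maxima"),
                           min_separation = 1) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (length(x) < 3) stop("need at least 3 samples to detect extrema")
  if (kind == "minima") x <- -x
  n <- length(x)
  interior <- 2:(n - 1)
  cand <- interior[x[interior] > x[interior - 1] & x[interior] > x[interior + 1]]
  if (length(cand) == 0) return(integer(0))
  if (min_separation <= 1) return(as.integer(cand))
  # greedy by extremity: keep the most extreme, drop neighbors within range
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
  }
  as.integer(sort(kept))
}

#' Inter-beat interval statistics from the BVP low band
#'
#' Diastolic points are located on the low-frequency band of a BVP window
#' (the band split removes the dicrotic notch that confounds naive extremum
#' search): systolic peaks are first detected as the prominent local maxima
#' (above the band midrange, separated by at least `min_separation`), and
#' each diastolic point is the minimum between two consecutive systolic
#' peaks. IBIs are the successive differences of diastolic times; the mean
#' and the population SD are returned.
#'
#' @param bvp_low low-band BVP samples (from [wavelet_packet_split()]).
#' @param fs sampling rate in Hz.
#' @param min_separation minimum separation between systolic peaks in
#'   seconds (default 0.3 s, i.e. a 200 bpm physiological ceiling).
#' @return List with `ibi_mean` and `ibi_sd`, both in seconds.
#' @export
ibi_features <- function(bvp_low, fs, min_separation = 0.3) {
  bvp_low <- as.numeric(bvp_low)
  peaks <- detect_extrema(bvp_low, "maxima",
                          min_separation = round(min_separation * fs))
  mid <- (max(bvp_low) + min(bvp_low)) / 2
  peaks <- peaks[bvp_low[peaks] > mid]
  n_dias <- max(length(peaks) - 1, 0)
  if (n_dias < 2) {
    stop("insufficient beats in window (", n_dias,
         " diastolic points); widen the window")
  }
  idx <- vapply(seq_len(n_dias), function(k) {
    seg <- peaks[k]:peaks[k + 1]
    seg[which.min(bvp_low[seg])]
  }, numeric(1))
  ibi <- diff(idx) / fs
  list(ibi_mean = mean(ibi), ibi_sd = pop_sd(ibi))
}

# population (not sample) standard deviation, used for all window statistics
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Third-order cumulant of a signal
#'
#' Biased sample estimate of the third-order cumulant of the demeaned
#' signal, `c3(t1, t2) = (1/L) * sum_n x(n) x(n + t1) x(n + t2)` over the
#' indices for which all three factors exist. Its 2-D Fourier transform is
#' the bispectrum; the zero-lag value `c3(0, 0)` (the third central moment)
#' is the spectral feature exported per band, capturing non-Gaussian,
#' phase-coupled structure that amplitude spectra miss.
#'
#' @param x numeric signal.
#' @param lags integer pair `(t1, t2)`; default `c(0, 0)`.
#' @return The cumulant estimate (scalar).
#' @export
third_order_cumulant <- function(x, lags = c(0, 0)) {
  x <- as.numeric(x)
  L <- length(x)
  t1 <- as.integer(lags[1]); t2 <- as.integer(lags[2])
  if (max(abs(t1), abs(t2)) >= L) {
    stop("lag exceeds signal length (", L, ")")
  }
  xd <- x - mean(x)
  n_lo <- max(1L, 1L - t1, 1L - t2)
  n_hi <- min(L, L - t1, L - t2)
  n <- n_lo:n_hi
  sum(xd[n] * xd[n + t1] * xd[n + t2]) / L
}

#' Full third-order-cumulant lattice
#'
#' Evaluates [third_order_cumulant()] on the square lag lattice
#' `-max_lag..max_lag` in both directions; mainly for inspection and for
#' computing the bispectrum (its 2-D DFT).
#'
#' @param x numeric signal.
#' @param max_lag maximum absolute lag.
#' @return `(2*max_lag+1)^2` matrix, dimnames are the lags.
#' @export
cumulant_lattice <- function(x, max_lag = 4) {
  lags <- -max_lag:max_lag
  out <- outer(lags, lags,
               Vectorize(function(a, b) third_order_cumulant(x, c(a, b))))
  dimnames(out) <- list(lags, lags)
  out
}

#' Skin-conductance-response peak features
#'
#' Counts SCR-like peaks in one GSR band: local maxima whose prominence
#' (height above the higher of the two flanking valleys) is at least
#' `prominence_fraction` of the window's total range. The amplitude of a
#' peak is its height above the window minimum.
#'
#' @param band GSR band samples (from [wavelet_packet_split()]).
#' @param fs sampling rate in Hz (kept for interface symmetry).
#' @param prominence_fraction minimum prominence as a fraction of the
#'   window range (default 0.05).
#' @return List with `count` and `mean_amplitude` (0 when no peaks).
#' @export
gsr_peak_features <- function(band, fs, prominence_fraction = 0.05) {
  band <- as.numeric(band)
  rng <- diff(range(band))
  if (length(band) < 3 || rng == 0) {
    return(list(count = 0L, mean_amplitude = 0))
  }
  peaks <- detect_extrema(band, "maxima")
  if (length(peaks) == 0) return(list(count = 0L, mean_amplitude = 0))
  # prominence: drop to the highest flanking valley, valleys delimited by
  # neighboring higher-or-equal samples (window edges count as valleys)
  prom <- vapply(peaks, function(p) {
    left <- band[seq_len(p - 1)]
    right <- band[seq(p + 1, length(band))]
    higher_l <- which(left >= band[p])
    higher_r <- which(right >= band[p])
    lmin <- min(left[seq(if (length(higher_l)) max(higher_l) else 1,
                         length(left))])
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r)
                              else length(right))])
    band[p] - max(lmin, rmin)
  }, numeric(1))
  keep <- peaks[prom >= prominence_fraction * rng]
  if (length(keep) == 0) return(list(count = 0L, mean_amplitude = 0))
  list(count = length(keep),
       mean_amplitude = mean(band[keep] - min(band)))
}

#' First/second-derivative statistics of a band
#'
#' Forward differences scaled by the sampling rate; `negslope_prop` is the
#' fraction of first-derivative entries that are negative.
#'
#' @param band numeric band samples, `length >= 3`.
#' @param fs sampling rate in Hz.
#' @return List with `d1_mean`, `d1_sd`, `d2_mean`, `d2_sd`,
#'   `negslope_prop`.
#' @export
derivative_stats <- function(band, fs) {
  band <- as.numeric(band)
  if (length(band) < 3) stop("need at least 3 samples for derivative stats")
  d1 <- diff(band) * fs
  d2 <- diff(d1) * fs
  list(d1_mean = mean(d1), d1_sd = pop_sd(d1),
       d2_mean = mean(d2), d2_sd = pop_sd(d2),
       negslope_prop = mean(d1 < 0))
}

#' Feature-extraction configuration
#'
#' @param bvp_wavelet,gsr_wavelet wavelet names per channel.
#' @param bvp_level wavelet packet depth for BVP (default 5: low band is
#'   roughly 0-2 Hz at 128 Hz, isolating the pulse fundamental).
#' @param gsr_level depth for GSR (default 2: low band roughly 0-0.5 Hz at
#'   4 Hz, the tonic component).
#' @param ibi_min_separation minimum diastolic-point separation, seconds.
#' @param prominence_fraction SCR peak prominence threshold, fraction of
#'   window range.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(bvp_wavelet = "db4", bvp_level = 5,
                           gsr_wavelet = "db4", gsr_level = 2,
                           ibi_min_separation = 0.3,
                           prominence_fraction = 0.05) {
  structure(list(bvp_wavelet = bvp_wavelet, bvp_level = bvp_level,
                 gsr_wavelet = gsr_wavelet, gsr_level = gsr_level,
                 ibi_min_separation = ibi_min_separation,
                 prominence_fraction = prominence_fraction),
            class = "feature_config")
}

#' Names of the extracted features, in table order
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("bvp_ibi_mean", "bvp_ibi_sd", "bvp_c3_low", "bvp_mean_low", "bvp_sd_low",
    "gsr_peak_count_high", "gsr_peak_amp_high",
    "gsr_peak_count_low", "gsr_peak_amp_low",
    "gsr_c3_low", "gsr_c3_high",
    "gsr_d1_mean_high", "gsr_d1_sd_high", "gsr_d2_mean_high",
    "gsr_d2_sd_high", "gsr_negslope_prop_high",
    "gsr_d1_mean_low", "gsr_d1_sd_low", "gsr_d2_mean_low",
    "gsr_d2_sd_low", "gsr_negslope_prop_low")
}

#' Extract the feature vector of one windowed segment
#'
#' Composes the band split, diastolic-point IBI statistics, third-order
#' cumulants, SCR peak statistics and derivative statistics. BVP features
#' (IBI, c3, moments) are computed on the BVP low band; GSR peak, cumulant
#' and derivative features on both GSR bands.
#'
#' @param segment a `windowed_segment` with `BVP` and `GSR` channels.
#' @param config a [feature_config()].
#' @return Named numeric vector, names per [feature_names()].
#' @export
extract_features <- function(segment, config = feature_config()) {
  stopifnot(inherits(segment, "windowed_segment"))
  if (!all(c("BVP", "GSR") %in% names(segment$channels))) {
    stop("segment must carry both BVP and GSR channels")
  }
  span <- sprintf("[%g, %g) s", segment$start, segment$end)
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("feature extraction failed for window ", span, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  bvp <- segment$channels$BVP
  gsr <- segment$channels$GSR
  fs_bvp <- segment$fs[["BVP"]]
  fs_gsr <- segment$fs[["GSR"]]

  bvp_bands <- wrap(wavelet_packet_split(bvp, config$bvp_wavelet,
                                         config$bvp_level))
  gsr_bands <- wrap(wavelet_packet_split(gsr, config$gsr_wavelet,
                                         config$gsr_level))

  ibi <- wrap(ibi_features(bvp_bands$low, fs_bvp, config$ibi_min_separation))
  pk_hi <- gsr_peak_features(gsr_bands$high, fs_gsr,
                             config$prominence_fraction)
  pk_lo <- gsr_peak_features(gsr_bands$low, fs_gsr,
                             config$prominence_fraction)
  dv_hi <- wrap(derivative_stats(gsr_bands$high, fs_gsr))
  dv_lo <- wrap(derivative_stats(gsr_bands$low, fs_gsr))

  out <- c(
    bvp_ibi_mean = ibi$ibi_mean, bvp_ibi_sd = ibi$ibi_sd,
    bvp_c3_low = third_order_cumulant(bvp_bands$low),
    bvp_mean_low = mean(bvp_bands$low), bvp_sd_low = pop_sd(bvp_bands$low),
    gsr_peak_count_high = as.numeric(pk_hi$count),
    gsr_peak_amp_high = pk_hi$mean_amplitude,
    gsr_peak_count_low = as.numeric(pk_lo$count),
    gsr_peak_amp_low = pk_lo$mean_amplitude,
    gsr_c3_low = third_order_cumulant(gsr_bands$low),
    gsr_c3_high = third_order_cumulant(gsr_bands$high),
    gsr_d1_mean_high = dv_hi$d1_mean, gsr_d1_sd_high = dv_hi$d1_sd,
    gsr_d2_mean_high = dv_hi$d2_mean, gsr_d2_sd_high = dv_hi$d2_sd,
    gsr_negslope_prop_high = dv_hi$negslope_prop,
    gsr_d1_mean_low = dv_lo$d1_mean, gsr_d1_sd_low = dv_lo$d1_sd,
    gsr_d2_mean_low = dv_lo$d2_mean, gsr_d2_sd_low = dv_lo$d2_sd,
    gsr_negslope_prop_low = dv_lo$negslope_prop
  )
  out[feature_names()]
}

#' Extract a feature table from a recording session
#'
#' Applies [segment_windows()] and [extract_features()] and assembles the
#' standard feature table. Windows whose feature extraction fails (for
#' example too few beats) are dropped with a warning.
#'
#' @param signals list of `signal_record`s (BVP and GSR).
#' @param spec a [window_spec()].
#' @param label_fun optional label track, see [segment_windows()].
#' @param subject_id subject identifier.
#' @param config a [feature_config()].
#' @return `data.frame` with columns `subject_id`, `window_start`,
#'   `window_end`, `label`, then the features.
#' @export
extract_feature_table <- function(signals, spec = window_spec(),
                                  label_fun = NULL, subject_id = "s1",
                                  config = feature_config()) {
  segs <- segment_windows(signals, spec, label_fun, subject_id)
  rows <- lapply(segs, function(sg) {
    fv <- tryCatch(extract_features(sg, config), error = function(e) NULL)
    if (is.null(fv)) return(NULL)
    cbind(data.frame(subject_id = sg$subject_id, window_start = sg$start,
                     window_end = sg$end, label = sg$label),
          as.data.frame(as.list(fv)))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " window(s) dropped (feature extraction failed)")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 4 + length(feature_names()))),
      c("subject_id", "window_start", "window_end", "label", feature_names()))
  }
  rownames(out) <- NULL
  out
}

#' Min-max feature scaler
#'
#' Learns per-column minima and maxima on a training table and maps them to
#' `[0, 1]`. Constant columns map to 0; application to unseen data clips to
#' `[0, 1]`. Normalization of features and labels precedes all model
#' fitting and also bounds the influence of GSR baseline drift on the
#' low-frequency cumulant features.
#'
#' @param table data.frame or matrix of numeric feature columns.
#' @param columns columns to scale; default all numeric columns.
#' @return Object of class `minmax_scaler`.
#' @export
fit_scaler <- function(table, columns = NULL) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) stop("cannot fit a scaler on an empty table")
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  mins <- vapply(table[columns], min, numeric(1))
  maxs <- vapply(table[columns], max, numeric(1))
  structure(list(columns = columns, min = mins, max = maxs),
            class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, table) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  table <- as.data.frame(table)
  for (cn in scaler$columns) {
    if (!cn %in% names(table)) stop("column missing from table: ", cn)
    rng <- scaler$max[[cn]] - scaler$min[[cn]]
    v <- if (rng == 0) rep(0, nrow(table))
         else pmin(1, pmax(0, (table[[cn]] - scaler$min[[cn]]) / rng))
    table[[cn]] <- v
  }
  table
}

#' Normalize raw Stroop labels to the unit interval
#'
#' The interactive Stroop protocol labels congruent segments 1-4 and
#' incongruent segments 5-8 by difficulty level; the fixed map
#' `(raw - 1) / 7` takes the 1-8 scale onto `[0, 1]`, the scale on which
#' predictions are thresholded.
#'
#' @param raw integer labels in 1..8.
#' @return Numeric labels in `[0, 1]`.
#' @export
normalize_stroop_label <- function(raw) (raw - 1) / 7
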