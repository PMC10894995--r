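# Synthetic sEEG recordings of volume-conducted stimulation artifacts.

#' Stimulation pulse model
#'
#' A monophasic rectangular current pulse shaped by a first-order high-pass
#' (capacitive coupling) filter and undersampled by the acquisition system.
#' The pulse lasts 0.3 ms while the sampling period is 1 ms, so the sampled
#' waveform never attains the continuous pulse amplitude; the validation
#' scaling factor absorbs this fixed attenuation together with the unknown
#' stimulation strength.
#'
#' @param duration_ms pulse duration (ms).
#' @param highpass_corner_hz corner frequency of the capacitive high-pass;
#'   the default 80 Hz gives a time constant of ~2 ms, so filter tails
#'   outlast the pulse. 0 disables the filter.
#' @param amplitude_gain ground-truth global gain g mapping unit-source
#'   simulated potentials to recorded amplitudes.
#' @param onset_offset_ms pulse onset relative to the event sample (ms);
#'   a non-integer offset models triggers that fall between samples.
#' @return A \code{pulse_model}.
#' @export
pulse_model <- function(duration_ms = 0.3, highpass_corner_hz = 80,
                        amplitude_gain = 200, onset_offset_ms = 0.4) {
  stopifnot_scalar(duration_ms, "duration_ms", positive = TRUE)
  stopifnot_scalar(amplitude_gain, "amplitude_gain", positive = TRUE)
  stopifnot_scalar(highpass_corner_hz, "highpass_corner_hz")
  if (highpass_corner_hz < 0) stop("corner frequency must be >= 0")
  structure(list(duration_ms = duration_ms,
                 highpass_corner_hz = highpass_corner_hz,
                 amplitude_gain = amplitude_gain,
                 onset_offset_ms = onset_offset_ms),
            class = "pulse_model")
}

#' Sampled stimulation-pulse waveform
#'
#' Generates the unit-amplitude rectangular pulse on an oversampled grid,
#' applies the first-order capacitive high-pass, and decimates to the
#' acquisition rate. Sample 1 corresponds to the event (trigger) sample.
#'
#' @param pulse a \code{pulse_model}.
#' @param fs_hz sampling rate (Hz).
#' @param oversample oversampling factor (>= 10).
#' @param n_samples length of the returned sampled waveform.
#' @return numeric vector of length \code{n_samples} with attributes
#'   \code{sampled_peak} (signed value of the largest-magnitude sample near
#'   the event; its magnitude is strictly below 1 whenever the filter is
#'   active or the pulse straddles samples), \code{peak_offset} (its sample
#'   offset from the event), and \code{oversampled} / \code{oversample_dt}
#'   (the pre-decimation waveform and its sampling step, for energy and
#'   shape diagnostics).
#' @export
pulse_waveform <- function(pulse, fs_hz = 1000, oversample = 32L,
                           n_samples = 30L) {
  if (oversample < 10L) stop("oversample must be >= 10")
  dt <- 1 / (fs_hz * oversample)
  tt <- seq(0, by = dt, length.out = n_samples * oversample)
  t0 <- pulse$onset_offset_ms * 1e-3
  x <- as.numeric(tt >= t0 & tt < t0 + pulse$duration_ms * 1e-3)
  if (pulse$highpass_corner_hz > 0) {
    tau <- 1 / (2 * pi * pulse$highpass_corner_hz)
    a <- tau / (tau + dt)
    y <- numeric(length(x))
    xm1 <- 0
    for (i in seq_along(x)) {
      y[i] <- a * ((if (i > 1) y[i - 1] else 0) + x[i] - xm1)
      xm1 <- x[i]
    }
  } else y <- x
  w <- y[seq(1L, length(y), by = oversample)]
  # the measurement-side peak search looks within +-1 sample of the event,
  # so the effective sampled peak is the larger of the first two samples
  ipk <- which.max(abs(w[seq_len(min(2L, length(w)))]))
  structure(w, sampled_peak = w[ipk], peak_offset = ipk - 1L,
            oversampled = y, oversample_dt = dt)
}

#' Simulate an sEEG recording of stimulation artifacts
#'
#' Builds a monopolar recording in which every stimulation event injects,
#' on each channel, the analytically computed volume-conducted potential
#' (contact minus white-matter reference) of a dipole at the stimulated
#' pair's midpoint, scaled by the ground-truth gain and shaped by the
#' sampled pulse waveform. Ground truth uses the multilayer-sphere
#' analytical solver so that FEM discretization error remains measurable.
#' Gaussian sensor noise is added; designated bad channels are replaced by
#' large-variance noise (10 mV standard deviation) so that the variance
#' exclusion criterion can be exercised.
#'
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @param truth_model a \code{shell_model} describing the true head.
#' @param pulse a \code{pulse_model}.
#' @param noise_sd_uv additive Gaussian noise standard deviation (uV).
#' @param bad_channels contact ids to corrupt.
#' @param duration_samples record length; default covers all events.
#' @param seed RNG seed.
#' @param fs_hz sampling rate.
#' @param reference_mm position of the reference electrode (mm); must lie
#'   inside the head model. Default: head center (deep white matter).
#' @return A \code{recording}: list with \code{data} (samples x channels
#'   matrix, uV), \code{fs_hz}, \code{channels}, \code{events} data frames
#'   and the ground-truth metadata (gain, sampled pulse).
#' @export
simulate_recording <- function(electrodes, plan, truth_model, pulse,
                               noise_sd_uv = 2, bad_channels = character(),
                               duration_samples = NULL, seed = 1L,
                               fs_hz = 1000, reference_mm = c(0, 0, 0)) {
  stopifnot(inherits(truth_model, "shell_model"), inherits(pulse, "pulse_model"))
  if (vnorm(reference_mm) >= max(truth_model$radii_mm))
    stop("reference electrode lies outside the head model")
  pos <- contact_positions(electrodes)
  nch <- nrow(pos)
  w <- pulse_waveform(pulse, fs_hz = fs_hz)
  if (is.null(duration_samples))
    duration_samples <- max(plan$events$sample) + length(w) + 200L
  if (max(plan$events$sample) + length(w) > duration_samples)
    stop("duration_samples too short for the event list")
  g <- pulse$amplitude_gain

  # per pair: analytic potentials at all contacts and the reference
  pts <- rbind(pos, ref = reference_mm)
  vtab <- matrix(0, nrow(plan$pairs), nch,
                 dimnames = list(plan$pairs$pair_id, rownames(pos)))
  for (k in seq_len(nrow(plan$pairs))) {
    pa <- pos[plan$pairs$anode[k], ]
    pc <- pos[plan$pairs$cathode[k], ]
    v <- analytic_dipole_potential(truth_model, (pa + pc) / 2,
                                   (pa - pc) * 1e-3, pts)
    vtab[k, ] <- v[seq_len(nch)] - v[nch + 1L]
  }

  with_seed(seed, {
    data <- matrix(stats::rnorm(duration_samples * nch, sd = noise_sd_uv),
                   duration_samples, nch)
    colnames(data) <- rownames(pos)
    for (e in seq_len(nrow(plan$events))) {
      k <- match(plan$events$pair_id[e], plan$pairs$pair_id)
      s <- plan$events$sample[e]
      rng <- s:(s + length(w) - 1L)
      data[rng, ] <- data[rng, ] + outer(w, g * vtab[k, ])
    }
    if (length(bad_channels)) {
      bad <- intersect(bad_channels, colnames(data))
      data[, bad] <- matrix(stats::rnorm(duration_samples * length(bad),
                                         sd = 1e4),
                            duration_samples, length(bad))
    }
    structure(list(data = data, fs_hz = fs_hz,
                   channels = electrodes$contacts,
                   events = plan$events,
                   reference_mm = reference_mm,
                   gain = g,
                   sampled_peak = attr(w, "sampled_peak"),
                   truth_table = vtab,
                   bad_channels = bad_channels,
                   noise_sd_uv = noise_sd_uv),
              class = "recording")
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channels @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$events)))
  invisible(x)
}
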