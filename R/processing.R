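# Measurement-side sEEG processing: filtering, epoching, baseline
# correction, channel exclusion, bipolar montage, peak extraction.

#' Filter, epoch and baseline-correct an sEEG recording
#'
#' Applies a zero-phase high-pass (4th-order Butterworth, forward-backward)
#' to the continuous data, cuts epochs around every stimulation event, and
#' subtracts the per-epoch baseline mean channel-wise.
#'
#' @param recording a \code{recording}.
#' @param hp_hz high-pass corner frequency (Hz); \code{NULL} or 0 skips the
#'   filter (useful for exact identities on noise-free synthetic data).
#' @param epoch_window_ms epoch limits around the event, e.g. c(-100, 200).
#' @param baseline_window_ms baseline window, must precede the event.
#' @return An \code{epochs} object: list with \code{data} (epochs x samples
#'   x channels array, uV), \code{pair_id} per epoch, \code{times_ms}, and
#'   the filtered continuous data (\code{continuous}).
#' @export
preprocess <- function(recording, hp_hz = 10,
                       epoch_window_ms = c(-100, 200),
                       baseline_window_ms = c(-100, -10)) {
  stopifnot(inherits(recording, "recording"))
  if (baseline_window_ms[2] > 0)
    stop("baseline window must precede the event")
  if (baseline_window_ms[1] < epoch_window_ms[1] ||
      baseline_window_ms[2] > epoch_window_ms[2])
    stop("baseline window must lie within the epoch window")
  fs <- recording$fs_hz
  x <- recording$data
  if (!is.null(hp_hz) && hp_hz > 0) {
    bf <- signal::butter(4, hp_hz / (fs / 2), type = "high")
    for (ch in seq_len(ncol(x))) x[, ch] <- signal::filtfilt(bf, x[, ch])
  }
  spre <- round(epoch_window_ms[1] * fs / 1000)
  spost <- round(epoch_window_ms[2] * fs / 1000)
  times_ms <- (spre:spost) * 1000 / fs
  nsamp <- length(times_ms)
  ev <- recording$events
  ok <- ev$sample + spre >= 1L & ev$sample + spost <= nrow(x)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the record edge were dropped")
  ev <- ev[ok, , drop = FALSE]
  ep <- array(0, dim = c(nrow(ev), nsamp, ncol(x)),
              dimnames = list(NULL, NULL, colnames(x)))
  for (e in seq_len(nrow(ev))) {
    ep[e, , ] <- x[(ev$sample[e] + spre):(ev$sample[e] + spost), ]
  }
  bsel <- times_ms >= baseline_window_ms[1] & times_ms <= baseline_window_ms[2]
  for (e in seq_len(nrow(ev))) {
    seg <- matrix(ep[e, , ], nrow = nsamp)
    bl <- colMeans(seg[bsel, , drop = FALSE])
    ep[e, , ] <- seg - rep(bl, each = nsamp)
  }
  structure(list(data = ep, pair_id = ev$pair_id, event_sample = ev$sample,
                 times_ms = times_ms, fs_hz = fs, continuous = x,
                 channels = recording$channels),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d epochs x %d samples x %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Channel exclusion report for one stimulation pair
#'
#' Applies the three exclusion criteria to every monopolar channel in the
#' context of one stimulation pair: (a) noisy channel, standard deviation of
#' the after-peak signal (event + 5 ms to epoch end) above the threshold;
#' (b) extracranial contact, tissue label in skull/scalp/outside; (c)
#' involvement in or proximity to the stimulation, i.e. one of the
#' stimulated contacts, a same-shaft neighbor of them, or any contact within
#' \code{near_stim_mm} of either stimulated contact.
#'
#' @param epochs an \code{epochs} object.
#' @param volume the \code{labeled_volume} used for tissue lookups.
#' @param electrodes an \code{electrode_set}.
#' @param pair_id stimulation pair id (must appear in the epochs).
#' @param plan the \code{stim_plan} (source of anode/cathode ids).
#' @param variance_threshold_uv after-peak standard-deviation threshold in
#'   uV (default 1e4 uV = 10 mV).
#' @param near_stim_mm Euclidean proximity radius (mm).
#' @return A \code{channel_exclusion} data frame: contact_id, status
#'   (\code{kept}, \code{excluded:variance}, \code{excluded:extracranial},
#'   \code{excluded:near-stimulation}) with thresholds in attributes.
#' @export
exclude_channels <- function(epochs, volume, electrodes, pair_id, plan,
                             variance_threshold_uv = 1e4, near_stim_mm = 5) {
  ct <- electrodes$contacts
  pos <- contact_positions(electrodes)
  pr <- plan$pairs[plan$pairs$pair_id == pair_id, ]
  if (nrow(pr) != 1L) stop("unknown pair_id: ", pair_id)
  an <- ct[ct$contact_id == pr$anode, ]
  cat_ <- ct[ct$contact_id == pr$cathode, ]

  status <- rep("kept", nrow(ct))

  # (a) after-peak variance
  sel <- which(epochs$pair_id == pair_id)
  if (!length(sel)) stop("no epochs for pair ", pair_id)
  post <- epochs$times_ms >= 5
  seg <- epochs$data[sel, post, , drop = FALSE]
  sds <- apply(seg, 3L, stats::sd)
  status[sds > variance_threshold_uv] <- "excluded:variance"

  # (b) extracranial (label outside/scalp/skull)
  lab <- label_at(volume, pos[ct$contact_id, , drop = FALSE])
  status[lab %in% c(0L, TISSUE_LABELS[["scalp"]], TISSUE_LABELS[["skull"]])] <-
    "excluded:extracranial"

  # (c) stimulated pair, same-shaft neighbors, or within near_stim_mm
  stim_idx <- ct$shaft == an$shaft &
    ct$contact >= min(an$contact, cat_$contact) - 1L &
    ct$contact <= max(an$contact, cat_$contact) + 1L
  da <- sqrt(rowSums(sweep(pos[ct$contact_id, , drop = FALSE], 2L,
                           unlist(an[c("x", "y", "z")]), "-")^2))
  dc <- sqrt(rowSums(sweep(pos[ct$contact_id, , drop = FALSE], 2L,
                           unlist(cat_[c("x", "y", "z")]), "-")^2))
  status[stim_idx | da <= near_stim_mm | dc <= near_stim_mm] <-
    "excluded:near-stimulation"

  structure(data.frame(contact_id = ct$contact_id, status = status,
                       stringsAsFactors = FALSE),
            class = c("channel_exclusion", "data.frame"),
            pair_id = pair_id,
            variance_threshold_uv = variance_threshold_uv,
            near_stim_mm = near_stim_mm)
}

#' Bipolar montage channels over kept contacts
#'
#' One bipolar channel per pair of adjacent kept contacts on each shaft;
#' channels touching an excluded contact are dropped.
#'
#' @param electrodes an \code{electrode_set}.
#' @param kept contact ids to keep (default all).
#' @return data frame (channel, contact_a, contact_b); zero rows (with a
#'   warning) if no valid pair exists.
#' @export
montage_channels <- function(electrodes, kept = NULL) {
  mont <- default_montage(electrodes)
  if (!is.null(kept))
    mont <- mont[mont$contact_a %in% kept & mont$contact_b %in% kept, ,
                 drop = FALSE]
  if (!nrow(mont)) warning("no adjacent kept-contact pair; empty montage")
  rownames(mont) <- NULL
  mont
}

#' Re-reference epochs to a bipolar montage
#'
#' @param epochs an \code{epochs} object (monopolar channels).
#' @param montage data frame from \code{\link{montage_channels}}.
#' @return an \code{epochs} object whose channels are the bipolar
#'   differences contact_a - contact_b.
#' @export
apply_montage <- function(epochs, montage) {
  ia <- match(montage$contact_a, dimnames(epochs$data)[[3]])
  ib <- match(montage$contact_b, dimnames(epochs$data)[[3]])
  if (anyNA(ia) || anyNA(ib)) stop("montage references unknown channels")
  out <- epochs
  out$data <- epochs$data[, , ia, drop = FALSE] -
              epochs$data[, , ib, drop = FALSE]
  dimnames(out$data)[[3]] <- montage$channel
  out$continuous <- epochs$continuous[, ia, drop = FALSE] -
                    epochs$continuous[, ib, drop = FALSE]
  colnames(out$continuous) <- montage$channel
  out
}

#' Extract the measured stimulation-peak table
#'
#' For each epoch and channel, takes the signed value of largest magnitude
#' within one sample of the event, then averages across the epochs of each
#' stimulation pair.
#'
#' @param epochs an \code{epochs} object (normally bipolar).
#' @param plan a \code{stim_plan}.
#' @return A \code{potential_table} (pairs x channels, same units as the
#'   recording).
#' @export
extract_peak_table <- function(epochs, plan) {
  chs <- dimnames(epochs$data)[[3]]
  pairs <- plan$pairs$pair_id
  win <- abs(epochs$times_ms) <= 1000 / epochs$fs_hz + 1e-9
  tab <- matrix(NA_real_, length(pairs), length(chs),
                dimnames = list(pairs, chs))
  for (p in seq_along(pairs)) {
    sel <- which(epochs$pair_id == pairs[p])
    if (!length(sel)) {
      warning("no surviving epoch for pair ", pairs[p])
      next
    }
    seg <- epochs$data[sel, win, , drop = FALSE]
    pk <- apply(seg, c(1L, 3L), function(v) v[which.max(abs(v))])
    tab[p, ] <- colMeans(matrix(pk, nrow = length(sel)))
  }
  structure(tab, class = c("potential_table", "matrix"), units = "uV")
}

#' RMS amplitude of the preprocessed recording
#'
#' Root mean square over time samples and kept channels of the preprocessed
#' continuous signal; the normalizer turning absolute errors into relative
#' (percent) errors.
#'
#' @param epochs an \code{epochs} object (use the montage/kept channels on
#'   which errors are computed).
#' @param channels optional channel subset.
#' @return scalar RMS in the recording units (uV).
#' @export
recording_rms <- function(epochs, channels = NULL) {
  x <- epochs$continuous
  if (!is.null(channels)) x <- x[, intersect(channels, colnames(x)),
                                 drop = FALSE]
  if (!length(x)) stop("no channels selected for RMS computation")
  sqrt(mean(x^2))
}

#' Measured potential table from a recording
#'
#' Convenience wrapper running the full measurement chain: preprocess,
#' exclude channels, re-reference to the bipolar montage, extract peaks.
#' Static criteria (variance, extracranial) define the montage; channels
#' near or involved in a given stimulation are set to NA in that pair's row.
#'
#' @inheritParams preprocess
#' @inheritParams exclude_channels
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @return list with \code{table} (measured \code{potential_table}),
#'   \code{montage}, \code{rms_uv}, and \code{exclusions} (per-pair list of
#'   \code{channel_exclusion} reports).
#' @export
measured_peak_table <- function(recording, volume, electrodes, plan,
                                hp_hz = 10, epoch_window_ms = c(-100, 200),
                                baseline_window_ms = c(-100, -10),
                                variance_threshold_uv = 1e4,
                                near_stim_mm = 5) {
  ep <- preprocess(recording, hp_hz, epoch_window_ms, baseline_window_ms)
  excl <- lapply(plan$pairs$pair_id, function(p) {
    exclude_channels(ep, volume, electrodes, p, plan,
                     variance_threshold_uv, near_stim_mm)
  })
  names(excl) <- plan$pairs$pair_id
  # static keep-set: contacts passing variance + extracranial in all contexts
  static_bad <- unique(unlist(lapply(excl, function(r) {
    r$contact_id[r$status %in% c("excluded:variance",
                                 "excluded:extracranial")]
  })))
  kept <- setdiff(electrodes$contacts$contact_id, static_bad)
  mont <- montage_channels(electrodes, kept)
  bp <- apply_montage(ep, mont)
  tab <- extract_peak_table(bp, plan)
  # NA out near-stimulation channels per pair
  for (p in plan$pairs$pair_id) {
    r <- excl[[p]]
    near <- r$contact_id[r$status == "excluded:near-stimulation"]
    drop <- mont$contact_a %in% near | mont$contact_b %in% near
    tab[p, drop] <- NA_real_
  }
  list(table = tab, montage = mont,
       rms_uv = recording_rms(bp),
       exclusions = excl)
}
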