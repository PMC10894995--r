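fake_recording <- function(data, events = data.frame(pair_id = "p01",
                                                     sample = 500L),
                           channels = NULL, fs = 1000) {
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("s01c%02d", seq_len(ncol(data)))
  structure(list(data = data, fs_hz = fs,
                 channels = channels, events = events,
                 reference_mm = c(0, 0, 0), gain = 1, sampled_peak = 1,
                 noise_sd_uv = 0),
            class = "recording")
}

test_that("high-pass and baseline correction remove DC but pass 50 Hz", {
  n <- 2000L
  dc <- fake_recording(matrix(3.7, n, 2L))
  ep <- preprocess(dc)
  # DC is removed twice (filter + baseline); only filter edge ripple remains
  expect_lt(max(abs(ep$data)), 1e-3 * 3.7)

  tt <- seq_len(n) / 1000
  sine <- fake_recording(matrix(sin(2 * pi * 50 * tt), n, 1L))
  eps <- preprocess(sine, baseline_window_ms = c(-100, -10))
  got <- max(abs(eps$continuous[500:1500, 1]))   # away from filter edges
  expect_equal(got, 1, tolerance = 0.01)   # 4th-order 10 Hz corner: gain ~1
})

test_that("epoching drops edge events with a warning and keeps the rest", {
  n <- 1500L
  ev <- data.frame(pair_id = c("p01", "p01", "p02"),
                   sample = c(50L, 500L, 1000L))
  rec <- fake_recording(matrix(stats::rnorm(n * 2L), n, 2L), events = ev)
  expect_warning(ep <- preprocess(rec), "dropped")
  expect_identical(dim(ep$data)[1L], 2L)   # the event at sample 50 is gone
  expect_identical(ep$pair_id, c("p01", "p02"))
  expect_error(preprocess(rec, baseline_window_ms = c(-10, 10)), "precede")
})

test_that("channels are excluded for variance, location, and stimulation", {
  e2e <- fix_e2e_clean()
  # pick an intracranial contact on a shaft not involved in pair 1, so the
  # variance status is not overridden by a stronger criterion
  ct <- e2e$electrodes$contacts
  pr1 <- e2e$plan$pairs[1L, ]
  stim_shaft <- ct$shaft[ct$contact_id == pr1$anode]
  lab_all <- label_at(e2e$vol, contact_positions(e2e$electrodes))
  pos_all <- contact_positions(e2e$electrodes)
  d_an <- sqrt(rowSums(sweep(pos_all, 2L, pos_all[pr1$anode, ], "-")^2))
  d_ca <- sqrt(rowSums(sweep(pos_all, 2L, pos_all[pr1$cathode, ], "-")^2))
  cand <- ct$contact_id[lab_all >= 3L & ct$shaft != stim_shaft &
                          d_an > 6 & d_ca > 6]
  bad_id <- cand[1L]
  rec <- simulate_recording(e2e$electrodes, e2e$plan, e2e$truth,
                            pulse_model(), noise_sd_uv = 2,
                            bad_channels = bad_id, seed = 12)
  ep <- preprocess(rec)
  pid <- e2e$plan$pairs$pair_id[1L]
  rep1 <- exclude_channels(ep, e2e$vol, e2e$electrodes, pid, e2e$plan)
  expect_identical(sort(rep1$contact_id),
                   sort(e2e$electrodes$contacts$contact_id))
  status <- function(id) rep1$status[rep1$contact_id == id]
  expect_identical(status(bad_id), "excluded:variance")
  # the two stimulated contacts are excluded as involved in the stimulation
  pr <- e2e$plan$pairs[e2e$plan$pairs$pair_id == pid, ]
  expect_identical(status(pr$anode), "excluded:near-stimulation")
  expect_identical(status(pr$cathode), "excluded:near-stimulation")
  # contacts sitting in scalp or skull are excluded as extracranial
  pos <- contact_positions(e2e$electrodes)
  lab <- label_at(e2e$vol, pos)
  extr <- rep1$contact_id[lab %in% c(1L, 2L)]
  near <- rep1$contact_id[rep1$status == "excluded:near-stimulation"]
  for (id in setdiff(extr, near))
    expect_identical(status(id), "excluded:extracranial")
})

test_that("exclusions are monotone in the variance threshold", {
  e2e <- fix_e2e_clean()
  rec <- simulate_recording(e2e$electrodes, e2e$plan, e2e$truth,
                            pulse_model(), noise_sd_uv = 2, seed = 13)
  ep <- preprocess(rec)
  pid <- e2e$plan$pairs$pair_id[2L]
  excluded_at <- function(thr) {
    r <- exclude_channels(ep, e2e$vol, e2e$electrodes, pid, e2e$plan,
                          variance_threshold_uv = thr)
    r$contact_id[r$status == "excluded:variance"]
  }
  prev <- excluded_at(1e5)
  for (thr in c(1e4, 1e3, 1e2, 1e1)) {
    cur <- excluded_at(thr)
    expect_true(all(prev %in% cur))   # lowering never un-excludes
    prev <- cur
  }
})

test_that("bipolar montage rejects common mode and pairs kept contacts", {
  e2e <- fix_e2e_clean()
  mont <- montage_channels(e2e$electrodes)
  # 8 shafts x 10 contacts: 9 channels per shaft
  expect_identical(nrow(mont), 72L)
  rec <- e2e$rec
  ep <- preprocess(rec, hp_hz = NULL)
  ep_shift <- ep
  ep_shift$data <- ep$data + 42        # common-mode offset on all channels
  ep_shift$continuous <- ep$continuous + 42
  b1 <- apply_montage(ep, mont)
  b2 <- apply_montage(ep_shift, mont)
  expect_equal(b1$data, b2$data, tolerance = 1e-12)

  kept <- e2e$electrodes$contacts$contact_id[-1L]   # drop one deep contact
  m2 <- montage_channels(e2e$electrodes, kept)
  expect_identical(nrow(m2), 71L)
  expect_warning(montage_channels(e2e$electrodes, character(0)), "empty")
})

test_that("peak extraction picks the signed max-magnitude sample and averages", {
  n <- 1200L
  x <- matrix(0, n, 1L)
  x[499:501, 1] <- c(-3, 7, 2)
  x[620, 1] <- 99    # outside the +-1 sample window and both baselines
  ev <- data.frame(pair_id = c("p01", "p01"), sample = c(500L, 900L))
  x[900, 1] <- 6                       # second epoch peak
  x[500, 1] <- 4                       # first epoch peak (overwrite)
  rec <- fake_recording(x, events = ev)
  ep <- preprocess(rec, hp_hz = NULL, baseline_window_ms = c(-100, -10))
  plan <- structure(list(pairs = data.frame(pair_id = "p01",
                                            anode = "a", cathode = "b"),
                         events = ev), class = "stim_plan")
  tab <- extract_peak_table(ep, plan)
  expect_equal(unname(tab["p01", 1]), (4 + 6) / 2)
})

test_that("the zero-noise measurement chain is an exact identity", {
  e2e <- fix_e2e_clean()
  meas <- measured_peak_table(e2e$rec, e2e$vol, e2e$electrodes, e2e$plan,
                              hp_hz = NULL)
  ana <- analytic_table(e2e$truth, e2e$electrodes, e2e$plan, meas$montage)
  ok <- is.finite(meas$table)
  expect_gt(sum(ok), 200)
  expected <- 200 * e2e$rec$sampled_peak * ana
  expect_lt(max(abs(meas$table[ok] - expected[ok])) /
              max(abs(expected[ok])), 1e-9)
  # montage differencing commutes with the table construction
  posm <- apply_montage(preprocess(e2e$rec, hp_hz = NULL), meas$montage)
  expect_identical(dimnames(posm$data)[[3]], meas$montage$channel)
})

test_that("the measurement chain is deterministic", {
  e2e <- fix_e2e_clean()
  m1 <- measured_peak_table(e2e$rec, e2e$vol, e2e$electrodes, e2e$plan)
  m2 <- measured_peak_table(e2e$rec, e2e$vol, e2e$electrodes, e2e$plan)
  expect_identical(m1$table, m2$table)
  expect_identical(m1$rms_uv, m2$rms_uv)
})
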