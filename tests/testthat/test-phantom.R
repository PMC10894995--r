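test_that("sphere phantom labels voxels by the innermost containing sphere", {
  vol <- sphere_phantom(RADII_TINY, voxel_size_mm = 1, grid_margin_mm = 2.5)
  # grid is 23^3 with integer voxel-center coordinates; center voxel is white
  expect_identical(dim(vol$labels), c(23L, 23L, 23L))
  expect_identical(label_at(vol, c(0, 0, 0)), 5L)          # inside white
  expect_identical(label_at(vol, c(0, 0, 9)), 1L)          # 8 < 9 <= 9: scalp
  expect_identical(label_at(vol, c(0, 0, 5.6)), 4L)        # 5 < 5.6 <= 6: gray
  expect_identical(label_at(vol, c(0, 0, 11)), 0L)         # outside
})

test_that("nonzero voxel count matches the scalp sphere volume within 2%", {
  vol <- sphere_phantom(c(scalp = 92, skull = 86, csf = 80, gray = 78,
                          white = 66), voxel_size_mm = 2)
  n_nonzero <- sum(vol$labels > 0L)
  expected <- (4 / 3) * pi * 46^3      # scalp radius in 2 mm voxel units
  expect_lt(abs(n_nonzero - expected) / expected, 0.02)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(sphere_phantom(c(scalp = 9, skull = 10, csf = 7, gray = 6,
                                white = 5), 1), "strictly decreasing")
  expect_error(sphere_phantom(c(skull = 8, scalp = 9), 1), "outer-to-inner")
  # voxel far larger than a shell: warning, and error if the shell vanishes
  expect_warning(
    expect_error(sphere_phantom(c(scalp = 9, skull = 8.8, csf = 7, gray = 6,
                                  white = 5), voxel_size_mm = 3),
                 "degenerate shell"),
    "thinnest shell")
})

test_that("labels are monotone non-increasing along rays from the center", {
  vol <- sphere_phantom(RADII_TINY, 1)
  set.seed(3)
  for (k in 1:25) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    rr <- seq(0, 12, by = 0.25)
    labs <- label_at(vol, outer(rr, u))
    expect_true(all(diff(labs) <= 0L))
  }
})

test_that("conductivity profiles reproduce the published tissue values", {
  p5 <- conductivity_profile("5C")
  expect_equal(unname(p5$sigma[as.character(1:5)]),
               c(0.43, 0.01, 1.79, 0.33, 0.14))
  p4 <- conductivity_profile("4C")
  expect_equal(unname(p4$sigma[["4"]]), 0.33)   # gray = brain
  expect_equal(unname(p4$sigma[["5"]]), 0.33)   # white merged into brain
  expect_equal(unname(p4$sigma[["3"]]), 1.79)   # CSF kept distinct
  p3 <- conductivity_profile("3C")
  expect_equal(unname(p3$sigma[["3"]]), 0.33)   # CSF treated as brain
  expect_error(conductivity_profile("6C"))
  ov <- conductivity_profile("5C", overrides = c(skull = 0.02))
  expect_equal(unname(ov$sigma[["2"]]), 0.02)
  expect_error(conductivity_profile("5C", overrides = c(bone = 0.02)),
               "override names")
})

test_that("shaft placement yields exact 3.5 mm spacing inside the head", {
  vol <- fix_vol50()
  el <- place_shafts(vol, 3, 10, seed = 21, inside_radius_mm = 50)
  expect_identical(nrow(el$contacts), 30L)
  for (s in split(el$contacts, el$contacts$shaft)) {
    s <- s[order(s$contact), ]
    gaps <- sqrt(diff(s$x)^2 + diff(s$y)^2 + diff(s$z)^2)
    expect_equal(gaps, rep(3.5, nrow(s) - 1L), tolerance = 1e-12)
  }
  expect_true(all(label_at(vol, contact_positions(el)) != 0L))
})

test_that("shaft placement is deterministic and handles edge cases", {
  vol <- fix_vol50()
  a <- place_shafts(vol, 2, 12, seed = 77)
  b <- place_shafts(vol, 2, 12, seed = 77)
  expect_identical(a, b)
  e0 <- place_shafts(vol, 0)
  expect_identical(nrow(e0$contacts), 0L)
  # impossible: 16 contacts (52.5 mm span) within a 10 mm ball
  expect_error(place_shafts(vol, 1, 16, seed = 1, inside_radius_mm = 10,
                            max_tries = 25L), "could not place")
})

test_that("stimulation plans draw neighboring pairs deterministically", {
  vol <- fix_vol50()
  el <- place_shafts(vol, 1, 10, seed = 4, inside_radius_mm = 50)
  # one shaft with 10 contacts has 9 adjacent pairs
  expect_error(make_stimulation_plan(el, 20, seed = 1), "9 available")
  plan <- make_stimulation_plan(el, 9, n_events_per_pair = 2L, seed = 1)
  expect_identical(nrow(plan$events), 18L)
  expect_true(all(diff(plan$events$sample) > 0))          # strictly increasing
  expect_true(all(plan$events$pair_id %in% plan$pairs$pair_id))
  ct <- el$contacts
  idx <- function(id) ct$contact[match(id, ct$contact_id)]
  expect_true(all(abs(idx(plan$pairs$anode) - idx(plan$pairs$cathode)) == 1L))
  expect_identical(plan, make_stimulation_plan(el, 9, 2L, seed = 1))
})

test_that("20 pairs with 2 events each give 40 stimulations", {
  el <- fix_e2e_clean()$electrodes
  plan <- make_stimulation_plan(el, 20, n_events_per_pair = 2L, seed = 9)
  expect_identical(nrow(plan$events), 40L)
})
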