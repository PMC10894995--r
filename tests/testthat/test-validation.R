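# dense grid-search oracle for the L1 scale objective
grid_scale <- function(m, x, lo = NULL, hi = NULL, step_frac = 1e-4) {
  r <- m / x
  lo <- lo %||% min(r)
  hi <- hi %||% max(r)
  grid <- unique(c(seq(lo, hi, by = max((hi - lo) * step_frac, 1e-12)), r))
  obj <- vapply(grid, function(s) sum(abs(m - s * x)), numeric(1))
  grid[which.min(obj)]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the weighted-median scale fit solves the L1 problem exactly", {
  expect_equal(fit_scale(c(2, 4, 6), c(1, 2, 3)), 2)
  expect_equal(sum(abs(c(2, 4, 6) - 2 * c(1, 2, 3))), 0)
  # an outlier pulls the L2 fit but not the L1 fit
  m <- c(2, 4, 30); x <- c(1, 2, 2)
  expect_equal(fit_scale(m, x), 2)
  expect_lt(sum(abs(m - 2 * x)), sum(abs(m - 15 * x)))   # 26 beats 35
  # proportional tables recover the constant for any c > 0
  for (cc in c(0.5, 3, 200)) expect_equal(fit_scale(cc * x, x), cc)
  expect_error(fit_scale(c(1, 2), c(0, 0)), "zero")
})

test_that("weighted median equals dense grid search on random instances", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n)
    x[sample(n, 1)] <- 0                    # zero simulated entries excluded
    m <- 150 * x + stats::rnorm(n, sd = stats::runif(1, 0.1, 5))
    keep <- x != 0
    s_med <- fit_scale(m, x)
    s_grid <- grid_scale(m[keep], x[keep])
    obj <- function(s) sum(abs(m[keep] - s * x[keep]))
    expect_lte(obj(s_med), obj(s_grid) + 1e-9 * obj(s_grid))
    # the L1 minimizer sits at a ratio point
    expect_true(min(abs(s_med - m[keep] / x[keep])) < 1e-12)
  }
})

test_that("pooled fits and the L2 variant behave sensibly", {
  x1 <- c(1, 2, 3); x2 <- c(2, 5)
  expect_equal(fit_scale(list(3 * x1, 3 * x2), list(x1, x2), pool = TRUE), 3)
  expect_equal(fit_scale(c(2, 4, 6), c(1, 2, 3), objective = "l2"), 2)
  # NA entries are ignored
  expect_equal(fit_scale(c(2, NA, 6), c(1, 2, 3)), 2)
})

test_that("error tables normalize absolute errors by the recording RMS", {
  m <- matrix(c(10, 20, 30, 40), 2, 2,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  s <- m / 4
  et <- error_tables(m, s, scale = 4, rms_uv = 96)
  expect_true(all(et$abs_error == 0))
  m2 <- m; m2[1, 1] <- m2[1, 1] + 9.6
  et2 <- error_tables(m2, s, scale = 4, rms_uv = 96)
  expect_equal(unname(et2$rel_error_pct[1, 1]), 10)   # 9.6 uV of 96 uV RMS
  # unit invariance: mV instead of uV scales abs but not rel errors
  et3 <- error_tables(m2 / 1000, s / 1000, scale = 4, rms_uv = 96 / 1000)
  expect_equal(unclass(et3$rel_error_pct), unclass(et2$rel_error_pct),
               tolerance = 1e-12)
  expect_error(error_tables(m, s[1, , drop = FALSE], 4, 96), "layout")
})

test_that("empirical CDF and percentiles follow the counting definition", {
  cp <- cdf_and_percentile(c(1, 2, 3, 4, 5), q = 0.8)
  expect_equal(cp$percentile, 4)
  expect_equal(cdf_and_percentile(c(1, 2, 3, 4, 5), q = 1)$percentile, 5)
  expect_true(all(diff(cp$cdf$fraction) >= 0))
  expect_equal(cp$cdf$fraction[nrow(cp$cdf)], 1)
  expect_error(cdf_and_percentile(c(NA, NA), 0.8), "finite")
  expect_error(cdf_and_percentile(1:5, 0), "q must")
})

test_that("distance bins partition [0, max) in 5 mm steps", {
  b <- distance_bin_stats(c(1, 2, 3), c(3, 7, 12))
  expect_identical(nrow(b), 3L)
  expect_equal(b$n, rep(1L, 3))
  expect_equal(b$bin_lo_mm, c(0, 5, 10))
  # a maximal distance of 44 mm gives ceiling(44/5) = 9 bins
  b9 <- distance_bin_stats(rep(1, 10), seq(2, 44, length.out = 10))
  expect_identical(nrow(b9), 9L)
  # constant errors collapse the quartiles onto the median
  expect_true(all(b9$median == 1 & b9$q1 == 1 & b9$q3 == 1))
  # interior empty bins are kept, trailing empties dropped
  b2 <- distance_bin_stats(c(1, 2), c(2, 17))
  expect_identical(nrow(b2), 4L)
  expect_identical(b2$n, c(1L, 0L, 0L, 1L))
})

test_that("vc_validate fits a shared scale and exposes model methods", {
  set.seed(8)
  m <- matrix(stats::rnorm(40, 100, 30), 5, 8,
              dimnames = list(paste0("p", 1:5), paste0("c", 1:8)))
  sims <- list(A = m / 200 + stats::rnorm(40, sd = 0.01),
               B = m / 200 + stats::rnorm(40, sd = 0.05))
  fit <- vc_validate(m, sims, rms_uv = 100)
  expect_s3_class(fit, "vc_validation")
  expect_named(coef(fit), "scale")
  # level A is closer to the measurements than the degraded level B
  expect_lt(fit$levels$A$median_rel_pct, fit$levels$B$median_rel_pct)
  expect_equal(dim(residuals(fit)), dim(m))
  expect_equal(predict(fit, sims$A), coef(fit)[["scale"]] * sims$A)
  out <- utils::capture.output(print(fit))
  expect_true(any(grepl("scaling factor", out)))
  s <- summary(fit)
  expect_identical(nrow(s$table), 2L)
  # the level ordering is invariant to a shared rescaling of the fit
  fit2 <- vc_validate(m, sims, rms_uv = 100,
                      scale = coef(fit)[["scale"]] * 1.05)
  expect_lt(fit2$levels$A$median_rel_pct, fit2$levels$B$median_rel_pct)
})

test_that("validation reports round-trip through JSON losslessly", {
  set.seed(9)
  m <- matrix(stats::rnorm(20, 50, 10), 4, 5,
              dimnames = list(paste0("p", 1:4), paste0("c", 1:5)))
  d <- matrix(stats::runif(20, 1, 40), 4, 5, dimnames = dimnames(m))
  fit <- vc_validate(m, list(L = m / 3), rms_uv = 50, distances = d)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(report_as_list(fit), f, auto_unbox = TRUE, digits = NA)
  back <- report_from_list(jsonlite::read_json(f))
  expect_equal(back$scale, fit$scale)
  expect_equal(back$levels$L$cdf_value, fit$levels$L$cdf$value)
  expect_equal(back$levels$L$distance_bins$median,
               fit$levels$L$distance_bins$median)
})
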