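# Model-validation statistics: L1-optimal scaling factor, absolute and
# relative error tables, cumulative distributions, distance-binned summaries.

#' L1-optimal scaling factor between measured and simulated potentials
#'
#' Finds the scalar s minimizing \eqn{\sum_i |m_i - s x_i|}, the scaling
#' factor mapping simulated onto measured amplitudes. The exact minimizer is
#' the |x|-weighted median of the ratios m_i / x_i. Entries with simulated
#' value 0 (or missing entries) are excluded from the fit. An L2 variant
#' (\code{objective = "l2"}) is available for sensitivity checks.
#'
#' @param measured,simulated numeric vectors, matrices or
#'   \code{potential_table}s with matching layout; with \code{pool = TRUE}
#'   lists of such tables are pooled into one fit.
#' @param pool fit one scale across a list of datasets.
#' @param objective \code{"l1"} (weighted-median, default) or \code{"l2"}.
#' @return the fitted scale factor (scalar).
#' @examples
#' fit_scale(c(2, 4, 6), c(1, 2, 3))  # exact proportionality: 2
#' @export
fit_scale <- function(measured, simulated, pool = FALSE,
                      objective = c("l1", "l2")) {
  objective <- match.arg(objective)
  if (pool || is.list(measured)) {
    if (!is.list(measured)) { measured <- list(measured); simulated <- list(simulated) }
    m <- unname(unlist(lapply(measured, as.numeric)))
    x <- unname(unlist(lapply(simulated, as.numeric)))
  } else {
    m <- as.numeric(measured); x <- as.numeric(simulated)
  }
  if (length(m) != length(x)) stop("measured/simulated sizes differ")
  keep <- is.finite(m) & is.finite(x) & x != 0
  if (!any(keep)) stop("no usable entry: all simulated values are zero or missing")
  m <- m[keep]; x <- x[keep]
  if (objective == "l2") return(sum(m * x) / sum(x * x))
  r <- m / x
  w <- abs(x)
  o <- order(r)
  r <- r[o]; w <- w[o]
  cw <- cumsum(w)
  unname(r[which(cw >= sum(w) / 2)[1L]])
}

#' Absolute and relative error tables
#'
#' Elementwise mismatch between measured and scaled simulated potentials:
#' \code{abs = |measured - scale * simulated|} and
#' \code{rel = 100 * abs / rms}, where rms is the RMS of the preprocessed
#' recording over time and kept channels (see \code{\link{recording_rms}}).
#'
#' @param measured,simulated matching \code{potential_table}s (uV).
#' @param scale scaling factor (see \code{\link{fit_scale}}).
#' @param rms_uv RMS normalizer (uV), > 0.
#' @return list with \code{abs_error} (uV) and \code{rel_error_pct} tables.
#' @export
error_tables <- function(measured, simulated, scale, rms_uv) {
  stopifnot_scalar(rms_uv, "rms_uv", positive = TRUE)
  if (!identical(dim(measured), dim(simulated)))
    stop("measured and simulated tables have different layouts")
  if (!is.null(dimnames(measured)) && !is.null(dimnames(simulated)) &&
      !identical(dimnames(measured), dimnames(simulated)))
    stop("measured and simulated tables have different pair/channel ids")
  a <- abs(measured - scale * simulated)
  list(abs_error = a, rel_error_pct = 100 * a / rms_uv)
}

#' Empirical CDF and percentile of an error table
#'
#' Pools all finite entries across stimulation pairs and channels.
#'
#' @param errors numeric table/vector of errors.
#' @param q percentile fraction in (0, 1]; the returned value is the
#'   smallest error with cumulative fraction >= q.
#' @return list with \code{cdf} (data frame value/fraction) and
#'   \code{percentile}.
#' @examples
#' cdf_and_percentile(c(1, 2, 3, 4, 5), 0.8)$percentile  # 4
#' @export
cdf_and_percentile <- function(errors, q = 0.8) {
  v <- sort(as.numeric(errors)[is.finite(as.numeric(errors))])
  if (!length(v)) stop("no finite error entries")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  cdf <- data.frame(value = v, fraction = seq_along(v) / length(v))
  list(cdf = cdf, percentile = v[ceiling(q * length(v))])
}

#' Distances between stimulation pairs and bipolar channels
#'
#' Euclidean distance between each stimulation-pair midpoint and each
#' bipolar-channel midpoint, the coordinates the distance-binned error
#' summaries are indexed by.
#'
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @param montage montage data frame (channel, contact_a, contact_b).
#' @return matrix (pairs x channels) of distances in mm.
#' @export
pair_channel_distances <- function(electrodes, plan, montage) {
  pos <- contact_positions(electrodes)
  pm <- pair_midpoints(electrodes, plan)
  cm <- (pos[montage$contact_a, , drop = FALSE] +
         pos[montage$contact_b, , drop = FALSE]) / 2
  d <- matrix(0, nrow(pm), nrow(cm),
              dimnames = list(rownames(pm), montage$channel))
  for (k in seq_len(nrow(pm))) {
    d[k, ] <- sqrt(rowSums(sweep(cm, 2L, pm[k, ], "-")^2))
  }
  d
}

#' Distance-binned error summaries
#'
#' Assigns each (pair, channel) error to 5 mm distance bins
#' \code{[k*bin, (k+1)*bin)} and summarizes each bin with n, median and
#' quartiles (linear-interpolation quantiles). Empty trailing bins are
#' dropped.
#'
#' @param errors error table (pairs x channels), e.g. relative errors.
#' @param distances matching distance matrix (mm), see
#'   \code{\link{pair_channel_distances}}.
#' @param bin_mm bin width (mm).
#' @return data frame: bin_lo_mm, bin_hi_mm, n, median, q1, q3.
#' @export
distance_bin_stats <- function(errors, distances, bin_mm = 5) {
  e <- as.numeric(errors)
  d <- as.numeric(distances)
  keep <- is.finite(e) & is.finite(d)
  e <- e[keep]; d <- d[keep]
  if (!length(e)) {
    return(data.frame(bin_lo_mm = numeric(), bin_hi_mm = numeric(),
                      n = integer(), median = numeric(), q1 = numeric(),
                      q3 = numeric()))
  }
  nb <- max(1L, ceiling(max(d) / bin_mm + 1e-12))
  k <- pmin(floor(d / bin_mm), nb - 1L)
  out <- do.call(rbind, lapply(seq_len(nb) - 1L, function(b) {
    eb <- e[k == b]
    if (length(eb)) {
      qs <- stats::quantile(eb, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(bin_lo_mm = b * bin_mm, bin_hi_mm = (b + 1) * bin_mm,
                 n = length(eb), median = qs[2], q1 = qs[1], q3 = qs[3])
    } else {
      data.frame(bin_lo_mm = b * bin_mm, bin_hi_mm = (b + 1) * bin_mm,
                 n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    }
  }))
  # drop empty trailing bins (max(d) defines the last non-empty one anyway)
  last <- max(which(out$n > 0L))
  out[seq_len(last), , drop = FALSE]
}

#' Validate simulated head models against measured potentials
#'
#' The central fit of the package: given the measured peak-potential table
#' and one simulated table per head-model level (e.g. 3C/4C/5C), fits a
#' single L1-optimal scaling factor shared by all levels (the paper-style
#' pooled fit absorbing the unknown stimulation strength and pulse
#' undersampling), then derives per-level absolute and relative error
#' tables, cumulative distributions, the 80th-percentile absolute error,
#' and 5 mm distance-binned summaries.
#'
#' @param measured measured \code{potential_table} (uV).
#' @param simulated a single simulated table or a named list of tables
#'   (one per model level), same layout as \code{measured} (V or any
#'   common unit; the scale factor absorbs units).
#' @param rms_uv RMS normalizer in uV (see \code{\link{recording_rms}}).
#' @param distances optional distance matrix from
#'   \code{\link{pair_channel_distances}} enabling distance-binned stats.
#' @param scale fix the scaling factor instead of fitting it.
#' @param sim_gain known multiplicative factor already linking simulated to
#'   measured amplitudes (e.g. the sampled-pulse peak of a synthetic
#'   generator); simulated tables are multiplied by it before the fit so
#'   that the fitted scale estimates the generator gain. Default 1.
#' @param pool fit the scale on entries pooled across all levels
#'   (default); otherwise the first level alone determines it.
#' @param objective scale-fit objective, \code{"l1"} or \code{"l2"}.
#' @param bin_mm distance bin width (mm).
#' @param q percentile reported from the absolute-error CDF.
#' @return A \code{vc_validation} object with methods \code{print},
#'   \code{summary}, \code{coef} (the scale factor), \code{residuals},
#'   \code{predict} and \code{plot}.
#' @export
vc_validate <- function(measured, simulated, rms_uv, distances = NULL,
                        scale = NULL, sim_gain = 1, pool = TRUE,
                        objective = c("l1", "l2"), bin_mm = 5, q = 0.8) {
  objective <- match.arg(objective)
  if (!is.list(simulated)) simulated <- list(model = simulated)
  if (is.null(names(simulated)))
    names(simulated) <- paste0("model", seq_along(simulated))
  simulated <- lapply(simulated, function(x) x * sim_gain)
  for (x in simulated) {
    if (!identical(dim(x), dim(measured)))
      stop("simulated tables must share the measured table's layout")
  }
  if (is.null(scale)) {
    scale <- if (pool) {
      fit_scale(rep(list(measured), length(simulated)), simulated,
                pool = TRUE, objective = objective)
    } else {
      fit_scale(measured, simulated[[1L]], objective = objective)
    }
  }
  levels <- lapply(simulated, function(x) {
    et <- error_tables(measured, x, scale, rms_uv)
    cp <- cdf_and_percentile(et$abs_error, q)
    lvl <- list(abs_error = et$abs_error, rel_error_pct = et$rel_error_pct,
                cdf = cp$cdf, percentile_abs_uv = cp$percentile,
                median_rel_pct = stats::median(
                  et$rel_error_pct[is.finite(et$rel_error_pct)]))
    if (!is.null(distances))
      lvl$distance_bins <- distance_bin_stats(et$rel_error_pct, distances,
                                              bin_mm)
    lvl
  })
  structure(list(scale = scale, rms_uv = rms_uv, q = q,
                 levels = levels, distances = distances,
                 sim_gain = sim_gain, objective = objective,
                 measured = measured, simulated = simulated,
                 call = match.call()),
            class = "vc_validation")
}

#' @export
print.vc_validation <- function(x, ...) {
  cat("Volume-conduction model validation\n")
  cat(sprintf("  scaling factor (%s fit): %.4g\n", x$objective, x$scale))
  cat(sprintf("  RMS normalizer: %.4g uV\n", x$rms_uv))
  for (nm in names(x$levels)) {
    l <- x$levels[[nm]]
    cat(sprintf("  %s: median relative error %.2f%%, P%.0f absolute error %.3g uV\n",
                nm, l$median_rel_pct, 100 * x$q, l$percentile_abs_uv))
  }
  invisible(x)
}

#' @export
summary.vc_validation <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$levels), function(nm) {
    l <- object$levels[[nm]]
    data.frame(level = nm,
               n = sum(is.finite(l$abs_error)),
               median_rel_pct = l$median_rel_pct,
               percentile_abs_uv = l$percentile_abs_uv)
  }))
  structure(list(scale = object$scale, rms_uv = object$rms_uv,
                 q = object$q, table = tab,
                 bins = lapply(object$levels, `[[`, "distance_bins")),
            class = "summary.vc_validation")
}

#' @export
print.summary.vc_validation <- function(x, ...) {
  cat(sprintf("Scaling factor: %.6g (RMS %.4g uV, P%.0f)\n",
              x$scale, x$rms_uv, 100 * x$q))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.vc_validation <- function(object, ...) c(scale = object$scale)

#' @export
residuals.vc_validation <- function(object, level = 1L,
                                    type = c("absolute", "relative"), ...) {
  type <- match.arg(type)
  l <- object$levels[[level]]
  if (type == "absolute") l$abs_error else l$rel_error_pct
}

#' @export
predict.vc_validation <- function(object, simulated = NULL, level = 1L, ...) {
  x <- if (is.null(simulated)) object$simulated[[level]]
       else simulated * object$sim_gain
  object$scale * x
}

#' @export
plot.vc_validation <- function(x, which = c("cdf", "distance"), ...) {
  which <- match.arg(which)
  nlev <- length(x$levels)
  cols <- grDevices::hcl.colors(max(3L, nlev), "Dark 3")[seq_len(nlev)]
  if (which == "cdf") {
    xmax <- max(vapply(x$levels, function(l) max(l$cdf$value), numeric(1)))
    graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 100),
                   xlab = "absolute error (uV)",
                   ylab = "% of stimulation-recording pairs",
                   main = "Cumulative error distribution")
    for (i in seq_len(nlev)) {
      l <- x$levels[[i]]
      graphics::lines(l$cdf$value, 100 * l$cdf$fraction, col = cols[i],
                      lwd = 2)
    }
    graphics::abline(h = 100 * x$q, lty = 2, col = "gray40")
    graphics::legend("bottomright", legend = names(x$levels), col = cols,
                     lwd = 2, bty = "n")
  } else {
    if (is.null(x$distances))
      stop("no distances available; refit with 'distances'")
    bins <- x$levels[[1L]]$distance_bins
    graphics::plot(NULL, xlim = range(c(bins$bin_lo_mm, bins$bin_hi_mm)),
                   ylim = c(0, max(vapply(x$levels, function(l)
                     max(l$distance_bins$q3, na.rm = TRUE), numeric(1)))),
                   xlab = "stimulation-recording distance (mm)",
                   ylab = "relative error (%)",
                   main = "Error vs distance (5 mm bins)")
    for (i in seq_len(nlev)) {
      b <- x$levels[[i]]$distance_bins
      mid <- (b$bin_lo_mm + b$bin_hi_mm) / 2 + (i - (nlev + 1) / 2) * 0.6
      graphics::segments(mid, b$q1, mid, b$q3, col = cols[i], lwd = 2)
      graphics::points(mid, b$median, col = cols[i], pch = 19)
    }
    graphics::legend("topright", legend = names(x$levels), col = cols,
                     pch = 19, bty = "n")
  }
  invisible(x)
}
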