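#' Concentric-sphere head phantom
#'
#' Builds a voxelized multi-shell sphere phantom standing in for a segmented
#' head: nested spheres of scalp, skull, CSF, gray and white matter centered
#' at the world origin. Each voxel is labeled by the innermost sphere whose
#' radius is at least the distance from the sphere center to the voxel
#' center; voxels outside the scalp sphere get label 0.
#'
#' @param radii_mm named numeric vector of shell radii in mm, names a subset
#'   of \code{c("scalp","skull","csf","gray","white")} in that (outer to
#'   inner) order, values strictly decreasing. The default is an adult-head
#'   scale five-shell phantom.
#' @param voxel_size_mm cubic voxel edge length in mm.
#' @param grid_margin_mm margin of empty space around the scalp sphere.
#' @return A \code{labeled_volume}: list with \code{labels} (3D integer
#'   array), \code{voxel_size_mm} and \code{origin_mm} (world coordinate of
#'   the center of voxel (1,1,1)).
#' @examples
#' vol <- sphere_phantom(c(scalp = 9, skull = 8, csf = 7, gray = 6, white = 5),
#'                       voxel_size_mm = 1)
#' table(vol$labels)
#' @export
sphere_phantom <- function(radii_mm = c(scalp = 92, skull = 86, csf = 80,
                                        gray = 78, white = 66),
                           voxel_size_mm = 1, grid_margin_mm = 2) {
  stopifnot_scalar(voxel_size_mm, "voxel_size_mm", positive = TRUE)
  stopifnot_scalar(grid_margin_mm, "grid_margin_mm")
  if (is.null(names(radii_mm)) ||
      !all(names(radii_mm) %in% names(TISSUE_LABELS)))
    stop("'radii_mm' must be named with tissues among: ",
         paste(names(TISSUE_LABELS), collapse = ", "))
  # enforce depth order of the supplied subset
  ord <- match(names(radii_mm), names(TISSUE_LABELS))
  if (is.unsorted(ord, strictly = TRUE))
    stop("invalid geometry: tissue names must be in outer-to-inner order ",
         "(scalp, skull, csf, gray, white)")
  if (any(diff(radii_mm) >= 0))
    stop("invalid geometry: radii must be strictly decreasing from scalp inward")
  thick <- -diff(c(radii_mm, 0))[seq_len(length(radii_mm) - 1L)]
  if (length(thick) && any(voxel_size_mm > thick))
    warning("voxel size ", voxel_size_mm, " mm exceeds the thinnest shell (",
            signif(min(thick), 3), " mm); shells may be poorly resolved")

  half <- radii_mm[[1L]] + grid_margin_mm
  n <- ceiling(2 * half / voxel_size_mm)
  # voxel-center coordinates, grid centered on the sphere center
  coords <- (seq_len(n) - (n + 1) / 2) * voxel_size_mm
  r2 <- outer(outer(coords^2, coords^2, "+"), coords^2, "+")
  labels <- array(0L, dim = c(n, n, n))
  # assign outer to inner so inner spheres overwrite
  for (i in seq_along(radii_mm)) {
    labels[r2 <= radii_mm[[i]]^2] <- TISSUE_LABELS[[names(radii_mm)[i]]]
  }
  present <- sort(unique(as.integer(labels[labels > 0L])))
  want <- unname(TISSUE_LABELS[names(radii_mm)])
  if (!all(want %in% present)) {
    gone <- setdiff(want, present)
    stop("degenerate shell: no voxel received label(s) ",
         paste(tissue_name(gone), collapse = ", "),
         "; decrease voxel_size_mm or thicken the shell")
  }
  structure(list(labels = labels,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = rep(coords[1L], 3L)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %g mm\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  tab <- table(factor(tissue_name(as.integer(x$labels)),
                      levels = c("outside", names(TISSUE_LABELS))))
  print(tab)
  invisible(x)
}

#' World coordinates of voxel centers
#'
#' @param volume a \code{labeled_volume}.
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @keywords internal
voxel_center <- function(volume, idx) {
  sweep((idx - 1) * volume$voxel_size_mm, 2L, -volume$origin_mm, "+")
}

#' Tissue label at world coordinates
#'
#' Looks up the label of the voxel containing each point (half-open voxel
#' intervals; points outside the grid get label 0).
#'
#' @param volume a \code{labeled_volume}.
#' @param points_mm n x 3 matrix (or length-3 vector) of world coordinates.
#' @return integer vector of labels.
#' @export
label_at <- function(volume, points_mm) {
  points_mm <- rbind_points(points_mm)
  d <- dim(volume$labels)
  lo <- volume$origin_mm - volume$voxel_size_mm / 2
  idx <- floor(sweep(points_mm, 2L, lo, "-") / volume$voxel_size_mm) + 1L
  ok <- idx[, 1] >= 1L & idx[, 1] <= d[1] &
        idx[, 2] >= 1L & idx[, 2] <= d[2] &
        idx[, 3] >= 1L & idx[, 3] <= d[3]
  out <- integer(nrow(points_mm))
  if (any(ok))
    out[ok] <- volume$labels[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  out
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z in mm)")
  p
}

#' Conductivity profiles for the three head-model levels
#'
#' Returns the tissue conductivities (S/m) of the three isotropic model
#' levels. The five-compartment profile (5C) distinguishes white matter
#' (0.14), gray matter (0.33), CSF (1.79), skull (0.01) and scalp (0.43).
#' The 4C profile merges gray and white matter into one brain compartment
#' (0.33); the 3C profile additionally treats CSF as brain (0.33).
#'
#' @param model_level one of \code{"3C"}, \code{"4C"}, \code{"5C"}.
#' @param overrides optional named numeric vector (names among scalp, skull,
#'   csf, gray, white) replacing individual conductivities after the level
#'   rules are applied.
#' @return A \code{conductivity_profile}: list with \code{model_level} and
#'   \code{sigma} (numeric vector indexed by label code 1..5, S/m).
#' @examples
#' conductivity_profile("3C")$sigma[["3"]]  # CSF treated as brain: 0.33
#' @export
conductivity_profile <- function(model_level = c("5C", "4C", "3C"),
                                 overrides = NULL) {
  model_level <- match.arg(model_level)
  sigma <- c(scalp = 0.43, skull = 0.01, csf = 1.79, gray = 0.33, white = 0.14)
  if (model_level %in% c("4C", "3C")) {
    sigma[["white"]] <- 0.33  # single brain compartment
    sigma[["gray"]] <- 0.33
  }
  if (model_level == "3C") sigma[["csf"]] <- 0.33
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) ||
        !all(names(overrides) %in% names(sigma)))
      stop("override names must be among: ",
           paste(names(sigma), collapse = ", "))
    sigma[names(overrides)] <- overrides
  }
  if (any(sigma <= 0)) stop("conductivities must be strictly positive")
  out <- sigma[names(TISSUE_LABELS)]          # order by label code 1..5
  names(out) <- as.character(unname(TISSUE_LABELS))
  structure(list(model_level = model_level, sigma = out),
            class = "conductivity_profile")
}

#' @export
print.conductivity_profile <- function(x, ...) {
  cat(sprintf("<conductivity_profile> %s\n", x$model_level))
  df <- data.frame(tissue = tissue_name(as.integer(names(x$sigma))),
                   label = names(x$sigma), sigma_S_per_m = unname(x$sigma))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Place sEEG electrode shafts in a head volume
#'
#' Samples straight depth-electrode shafts: each shaft enters at a random
#' point on the head surface and runs toward a random interior target at
#' 15-45 mm depth. Contacts are placed from the deep tip outward at exactly
#' 3.5 mm center-to-center spacing (2 mm contacts separated by 1.5 mm), all
#' inside the head (label != 0).
#'
#' @param volume a \code{labeled_volume}.
#' @param n_shafts number of shafts.
#' @param contacts_per_shaft integer (recycled) or vector of per-shaft
#'   contact counts, each in 10..16 as in clinical implants (values outside
#'   that range are allowed for small test phantoms).
#' @param seed RNG seed; placement is deterministic given the seed.
#' @param depth_range_mm range of tip depths below the entry point.
#' @param max_tries placement attempts per shaft before failing.
#' @param inside_radius_mm optional radius (mm, about the world origin) all
#'   contacts must additionally stay within; set it to the outer sphere
#'   radius when the analytic shell model serves as ground truth, so that
#'   contacts in surface voxels cannot fall outside the ideal sphere.
#' @return An \code{electrode_set}: list with \code{shafts} and
#'   \code{contacts} data frames. Contacts carry ids like \code{"s01c03"};
#'   contact index 1 is the deepest.
#' @export
place_shafts <- function(volume, n_shafts, contacts_per_shaft = 12L,
                         seed = 1L, depth_range_mm = c(15, 45),
                         max_tries = 500L, inside_radius_mm = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (n_shafts == 0L) {
    return(structure(list(
      shafts = data.frame(shaft = integer(), entry_x = numeric(),
                          entry_y = numeric(), entry_z = numeric(),
                          dir_x = numeric(), dir_y = numeric(),
                          dir_z = numeric(), n_contacts = integer()),
      contacts = data.frame(contact_id = character(), shaft = integer(),
                            contact = integer(), x = numeric(),
                            y = numeric(), z = numeric())),
      class = "electrode_set"))
  }
  ncontacts <- rep_len(as.integer(contacts_per_shaft), n_shafts)
  spacing <- 3.5  # mm center-to-center: 2 mm contact + 1.5 mm gap

  with_seed(seed, {
    shafts <- vector("list", n_shafts)
    contacts <- vector("list", n_shafts)
    for (s in seq_len(n_shafts)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- unit_vec(stats::rnorm(3))
        entry <- surface_point(volume, u)
        if (is.null(entry)) next
        inward <- unit_vec(-entry + stats::rnorm(3, sd = 8))
        if (sum(inward * (-unit_vec(entry))) < 0.3) next  # keep heading inward
        depth <- stats::runif(1, depth_range_mm[1], depth_range_mm[2])
        tip <- entry + depth * inward
        pos <- t(vapply(seq_len(ncontacts[s]) - 1L,
                        function(k) tip - k * spacing * inward,
                        numeric(3)))
        ok <- all(label_at(volume, pos) != 0L)
        if (ok && !is.null(inside_radius_mm))
          ok <- all(rowSums(pos^2) < inside_radius_mm^2)
        if (ok) {
          shafts[[s]] <- data.frame(shaft = s, entry_x = entry[1],
                                    entry_y = entry[2], entry_z = entry[3],
                                    dir_x = inward[1], dir_y = inward[2],
                                    dir_z = inward[3],
                                    n_contacts = ncontacts[s])
          contacts[[s]] <- data.frame(
            contact_id = sprintf("s%02dc%02d", s, seq_len(ncontacts[s])),
            shaft = s, contact = seq_len(ncontacts[s]),
            x = pos[, 1], y = pos[, 2], z = pos[, 3])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place shaft ", s, " inside the head after ",
             max_tries, " attempts")
    }
    structure(list(shafts = do.call(rbind, shafts),
                   contacts = do.call(rbind, contacts)),
              class = "electrode_set")
  })
}

# First head-surface point along direction u from outside, by ray marching
# from beyond the grid toward the center. NULL if the ray misses the head.
surface_point <- function(volume, u) {
  rmax <- max(abs(volume$origin_mm)) + volume$voxel_size_mm
  step <- volume$voxel_size_mm / 4
  rr <- seq(rmax, 0, by = -step)
  pts <- outer(rr, u)
  lab <- label_at(volume, pts)
  hit <- which(lab != 0L)
  if (!length(hit)) return(NULL)
  pts[hit[1L], ]
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set> %d shafts, %d contacts\n",
              nrow(x$shafts), nrow(x$contacts)))
  invisible(x)
}

#' Contact coordinates as a matrix
#' @param electrodes an \code{electrode_set}.
#' @return numeric matrix (n_contacts x 3) with contact ids as row names.
#' @export
contact_positions <- function(electrodes) {
  m <- as.matrix(electrodes$contacts[, c("x", "y", "z")])
  rownames(m) <- electrodes$contacts$contact_id
  m
}

#' Stimulation plan over neighboring contact pairs
#'
#' Draws stimulation pairs without replacement from the adjacent-contact
#' pairs of each shaft and lays their events out on a regular grid of sample
#' indices.
#'
#' @param electrodes an \code{electrode_set}.
#' @param n_pairs number of stimulated pairs.
#' @param n_events_per_pair stimulation repetitions per pair.
#' @param inter_event_samples spacing between consecutive events (samples).
#' @param seed RNG seed.
#' @param start_sample sample index of the first event.
#' @param max_midpoint_radius_mm optional cap (mm, about the world origin)
#'   on the pair-midpoint radius; restricts stimulation to deep pairs, e.g.
#'   inside the innermost shell of an analytic ground-truth model.
#' @return A \code{stim_plan}: list with \code{pairs} (pair_id, anode,
#'   cathode) and \code{events} (pair_id, sample) data frames.
#' @export
make_stimulation_plan <- function(electrodes, n_pairs,
                                  n_events_per_pair = 2L,
                                  inter_event_samples = 500L,
                                  seed = 1L, start_sample = 500L,
                                  max_midpoint_radius_mm = NULL) {
  ct <- electrodes$contacts
  avail <- do.call(rbind, lapply(split(ct, ct$shaft), function(d) {
    d <- d[order(d$contact), ]
    if (nrow(d) < 2L) return(NULL)
    data.frame(anode = d$contact_id[-nrow(d)], cathode = d$contact_id[-1L])
  }))
  if (!is.null(avail) && !is.null(max_midpoint_radius_mm)) {
    pos <- contact_positions(electrodes)
    mid <- (pos[avail$anode, , drop = FALSE] +
            pos[avail$cathode, , drop = FALSE]) / 2
    avail <- avail[rowSums(mid^2) < max_midpoint_radius_mm^2, , drop = FALSE]
    if (!nrow(avail)) avail <- NULL
  }
  if (is.null(avail) || n_pairs > nrow(avail))
    stop("n_pairs = ", n_pairs, " exceeds the ",
         if (is.null(avail)) 0L else nrow(avail),
         " available neighboring-contact pairs")
  with_seed(seed, {
    pick <- sort(sample.int(nrow(avail), n_pairs))
    pairs <- data.frame(pair_id = sprintf("p%02d", seq_len(n_pairs)),
                        anode = avail$anode[pick],
                        cathode = avail$cathode[pick])
    n_events <- n_pairs * n_events_per_pair
    events <- data.frame(
      pair_id = rep(pairs$pair_id, each = n_events_per_pair),
      sample = start_sample + (seq_len(n_events) - 1L) * inter_event_samples)
    structure(list(pairs = pairs, events = events), class = "stim_plan")
  })
}

#' @export
print.stim_plan <- function(x, ...) {
  cat(sprintf("<stim_plan> %d pairs, %d events\n",
              nrow(x$pairs), nrow(x$events)))
  invisible(x)
}

#' Midpoints of stimulation pairs
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @return matrix (n_pairs x 3) of pair midpoints (mm), pair ids as row names.
#' @export
pair_midpoints <- function(electrodes, plan) {
  pos <- contact_positions(electrodes)
  m <- (pos[plan$pairs$anode, , drop = FALSE] +
        pos[plan$pairs$cathode, , drop = FALSE]) / 2
  rownames(m) <- plan$pairs$pair_id
  m
}
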