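# File formats: NIfTI labeled volumes, TSV tables, flat-binary recordings.

#' Write / read a labeled volume as NIfTI-1
#'
#' Integer tissue labels on a cubic voxel grid; the voxel size goes into the
#' NIfTI pixdim and the world position of voxel (1,1,1) into the qform
#' translation. Write-then-read is the identity on labels and geometry.
#'
#' @param volume a \code{labeled_volume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(volume$labels)
  vs <- volume$voxel_size_mm
  RNifti::pixdim(img) <- c(vs, vs, vs)
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- volume$origin_mm
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (max(abs(arr - round(arr))) > 0)
    stop("NIfTI file does not contain integer label data")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) stop("NIfTI header lacks voxel dimensions")
  if (max(abs(diff(pd[1:3]))) > 1e-6 * pd[1])
    stop("anisotropic voxels (", paste(signif(pd[1:3], 4), collapse = " x "),
         " mm); resample to cubic voxels first (the pipeline assumes cubic ",
         "1 mm-class voxels)")
  aff <- RNifti::xform(img)
  structure(list(labels = array(as.integer(round(arr)), dim = dim(arr)),
                 voxel_size_mm = pd[1],
                 origin_mm = as.numeric(aff[1:3, 4])),
            class = "labeled_volume")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Electrode and stimulation-plan tables on disk
#'
#' Electrode sets and stimulation plans are stored as TSV files with
#' documented headers: \code{<prefix>_contacts.tsv} (contact_id, shaft,
#' contact, x, y, z in mm world coordinates), \code{<prefix>_shafts.tsv},
#' \code{<prefix>_pairs.tsv} (pair_id, anode, cathode) and
#' \code{<prefix>_events.tsv} (pair_id, sample).
#'
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @param prefix file path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_electrodes <- function(electrodes, prefix) {
  write_tsv(electrodes$shafts, paste0(prefix, "_shafts.tsv"))
  write_tsv(electrodes$contacts, paste0(prefix, "_contacts.tsv"))
  invisible(prefix)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(prefix) {
  structure(list(shafts = read_tsv(paste0(prefix, "_shafts.tsv")),
                 contacts = read_tsv(paste0(prefix, "_contacts.tsv"))),
            class = "electrode_set")
}

#' @rdname write_electrodes
#' @export
write_stim_plan <- function(plan, prefix) {
  write_tsv(plan$pairs, paste0(prefix, "_pairs.tsv"))
  write_tsv(plan$events, paste0(prefix, "_events.tsv"))
  invisible(prefix)
}

#' @rdname write_electrodes
#' @export
read_stim_plan <- function(prefix) {
  structure(list(pairs = read_tsv(paste0(prefix, "_pairs.tsv")),
                 events = read_tsv(paste0(prefix, "_events.tsv"))),
            class = "stim_plan")
}

#' Potential tables on disk
#'
#' Pairs x channels TSV with a leading \code{pair_id} column; values in the
#' units the table carries (volts for simulated, uV for measured).
#'
#' @param table a \code{potential_table}.
#' @param path file path.
#' @export
write_potential_table <- function(table, path) {
  df <- data.frame(pair_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_potential_table
#' @export
read_potential_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$pair_id
  structure(m, class = c("potential_table", "matrix"))
}

#' Recordings on disk (flat binary + TSV tables)
#'
#' The sample matrix is stored as little-endian float64 in
#' \code{<prefix>_data.bin} (column-major, samples x channels), alongside
#' \code{<prefix>_channels.tsv}, \code{<prefix>_events.tsv} and
#' \code{<prefix>_meta.yaml} (fs_hz, dimensions, reference position, gain).
#'
#' @param recording a \code{recording}.
#' @param prefix file path prefix.
#' @export
write_recording <- function(recording, prefix) {
  con <- file(paste0(prefix, "_data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 8L, endian = "little")
  write_tsv(recording$channels, paste0(prefix, "_channels.tsv"))
  write_tsv(recording$events, paste0(prefix, "_events.tsv"))
  yaml::write_yaml(list(fs_hz = recording$fs_hz,
                        n_samples = nrow(recording$data),
                        n_channels = ncol(recording$data),
                        channel_ids = colnames(recording$data),
                        reference_mm = as.numeric(recording$reference_mm),
                        gain = recording$gain,
                        sampled_peak = recording$sampled_peak,
                        noise_sd_uv = recording$noise_sd_uv),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  n <- meta$n_samples * meta$n_channels
  con <- file(paste0(prefix, "_data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  data <- matrix(x, meta$n_samples, meta$n_channels)
  colnames(data) <- unlist(meta$channel_ids)
  structure(list(data = data, fs_hz = meta$fs_hz,
                 channels = read_tsv(paste0(prefix, "_channels.tsv")),
                 events = read_tsv(paste0(prefix, "_events.tsv")),
                 reference_mm = unlist(meta$reference_mm),
                 gain = meta$gain, sampled_peak = meta$sampled_peak,
                 noise_sd_uv = meta$noise_sd_uv),
            class = "recording")
}

#' Hexahedral meshes on disk
#'
#' \code{<prefix>_nodes.tsv} (node id, x, y, z in mm) and
#' \code{<prefix>_elements.tsv} (element id, 8 node ids in VTK corner
#' order, tissue label).
#'
#' @param mesh a \code{hex_mesh}.
#' @param prefix file path prefix.
#' @export
write_hex_mesh <- function(mesh, prefix) {
  nd <- data.frame(node = seq_len(nrow(mesh$nodes)),
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                   z = mesh$nodes[, 3])
  el <- data.frame(element = seq_len(nrow(mesh$elements)), mesh$elements,
                   label = mesh$element_label)
  names(el)[2:9] <- paste0("n", 1:8)
  write_tsv(nd, paste0(prefix, "_nodes.tsv"))
  write_tsv(el, paste0(prefix, "_elements.tsv"))
  invisible(prefix)
}
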