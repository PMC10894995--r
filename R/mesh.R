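# Hexahedral meshing of labeled voxel volumes, with geometry-adapting node
# shift at tissue interfaces.

# local corner signs, VTK hexahedron order
HEX_XI   <- c(-1,  1,  1, -1, -1,  1,  1, -1)
HEX_ETA  <- c(-1, -1,  1,  1, -1, -1,  1,  1)
HEX_ZETA <- c(-1, -1, -1, -1,  1,  1,  1,  1)

# trilinear shape values at local point xi (length 3) -> length-8 vector
hex_shape <- function(xi) {
  (1 + HEX_XI * xi[1]) * (1 + HEX_ETA * xi[2]) * (1 + HEX_ZETA * xi[3]) / 8
}

# local shape gradients at xi -> 8 x 3 matrix d N_i / d xi_b
hex_shape_grad <- function(xi) {
  cbind(HEX_XI   * (1 + HEX_ETA * xi[2]) * (1 + HEX_ZETA * xi[3]),
        HEX_ETA  * (1 + HEX_XI * xi[1]) * (1 + HEX_ZETA * xi[3]),
        HEX_ZETA * (1 + HEX_XI * xi[1]) * (1 + HEX_ETA * xi[2])) / 8
}

GAUSS_1D <- 1 / sqrt(3)
gauss_points_hex <- function() {
  cbind(HEX_XI, HEX_ETA, HEX_ZETA) * GAUSS_1D
}

#' Convert a labeled voxel volume to a hexahedral mesh
#'
#' One trilinear hexahedral element per nonzero-label voxel, nodes at shared
#' voxel corners. Nodes incident to voxels of two or more distinct tissue
#' labels are displaced by \code{node_shift * voxel_size / 2} toward the
#' centroid of their incident voxels carrying the locally-minority label,
#' which smooths the voxel staircase at tissue interfaces while keeping all
#' element Jacobians positive (displacements are halved iteratively if an
#' element would invert).
#'
#' @param volume a \code{labeled_volume}.
#' @param node_shift geometry-adaptation factor in [0, 0.49]; 0 gives a
#'   regular lattice.
#' @return A \code{hex_mesh}: list with \code{nodes} (n x 3, mm),
#'   \code{elements} (ne x 8 node indices, VTK corner order),
#'   \code{element_label}, and grid metadata for point location.
#' @export
voxels_to_hex_mesh <- function(volume, node_shift = 0.3) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (node_shift < 0 || node_shift > 0.49)
    stop("node_shift must be in [0, 0.49]")
  lab <- volume$labels
  d <- dim(lab)
  nz <- which(lab > 0L)
  if (!length(nz)) stop("volume has no nonzero-label voxel")
  vidx <- arrayInd(nz, d)                      # ne x 3, 1-based voxel indices
  ne <- nrow(vidx)
  dc <- d + 1L                                 # corner grid dims

  corner_lin <- function(ci, cj, ck) {
    ci + (cj - 1L) * dc[1] + (ck - 1L) * dc[1] * dc[2]
  }
  # corner ids per element, VTK order
  off <- cbind((HEX_XI + 1L) / 2L, (HEX_ETA + 1L) / 2L, (HEX_ZETA + 1L) / 2L)
  corners <- matrix(0L, ne, 8L)
  for (k in 1:8) {
    corners[, k] <- corner_lin(vidx[, 1] + off[k, 1], vidx[, 2] + off[k, 2],
                               vidx[, 3] + off[k, 3])
  }
  used <- sort(unique(as.integer(corners)))
  remap <- integer(dc[1] * dc[2] * dc[3])
  remap[used] <- seq_along(used)
  elements <- matrix(remap[corners], ne, 8L)

  ci <- arrayInd(used, dc)
  vs <- volume$voxel_size_mm
  nodes <- sweep((ci - 1) * vs, 2L, volume$origin_mm - vs / 2, "+")

  if (node_shift > 0) {
    nodes <- nodes + node_shift_displacements(lab, d, ci, vs, node_shift)
  }

  elem_of_voxel <- array(0L, dim = d)
  elem_of_voxel[nz] <- seq_len(ne)
  mesh <- structure(list(nodes = nodes, elements = elements,
                         element_label = as.integer(lab[nz]),
                         dims = d, voxel_size_mm = vs,
                         origin_mm = volume$origin_mm,
                         elem_of_voxel = elem_of_voxel,
                         node_shift = node_shift),
                    class = "hex_mesh")
  if (node_shift > 0) mesh <- repair_inverted(mesh)
  mesh
}

# Displacement of interface nodes: toward the centroid of incident voxels
# with the locally-minority nonzero label, magnitude node_shift * vs/2.
node_shift_displacements <- function(lab, d, ci, vs, node_shift) {
  nn <- nrow(ci)
  labmat <- matrix(0L, nn, 8L)
  offs <- cbind(rep(c(0L, -1L), 4),
                rep(rep(c(0L, -1L), each = 2), 2),
                rep(c(0L, -1L), each = 4))
  for (k in 1:8) {
    vi <- sweep(ci, 2L, -offs[k, ], "+") - 1L  # voxel index, 1-based
    ok <- vi[, 1] >= 1L & vi[, 1] <= d[1] & vi[, 2] >= 1L & vi[, 2] <= d[2] &
          vi[, 3] >= 1L & vi[, 3] <= d[3]
    v <- integer(nn)
    v[ok] <- lab[cbind(vi[ok, 1], vi[ok, 2], vi[ok, 3])]
    labmat[, k] <- v
  }
  counts <- sapply(1:5, function(l) rowSums(labmat == l))
  ndistinct <- rowSums(counts > 0L)
  move <- ndistinct >= 2L
  # minority nonzero label; ties broken toward the larger (deeper) label
  minlab <- integer(nn)
  bestct <- rep(Inf, nn)
  for (l in 1:5) {
    cl <- counts[, l]
    take <- move & cl > 0L & cl <= bestct
    minlab[take] <- l
    bestct[take] <- cl[take]
  }
  # centroid offset (relative to the node) of incident voxels with minlab;
  # incident voxel centers sit at +- vs/2 per axis from the node
  disp <- matrix(0, nn, 3L)
  csum <- matrix(0, nn, 3L)
  csel <- numeric(nn)
  voff <- -(offs + 0.5) * vs                   # center offsets: +-vs/2
  for (k in 1:8) {
    sel <- move & labmat[, k] == minlab & minlab > 0L
    if (any(sel)) {
      csum[sel, ] <- csum[sel, ] + matrix(voff[k, ], sum(sel), 3, byrow = TRUE)
      csel[sel] <- csel[sel] + 1
    }
  }
  has <- csel > 0
  cen <- csum[has, , drop = FALSE] / csel[has]
  len <- sqrt(rowSums(cen^2))
  pos <- len > 0
  scale <- numeric(sum(has))
  scale[pos] <- node_shift * (vs / 2) / len[pos]
  disp[has, ] <- cen * scale
  disp
}

# Halve displacements of nodes of inverted elements until all Jacobians are
# positive (regular lattice coordinates are always recoverable).
repair_inverted <- function(mesh, max_pass = 30L) {
  for (pass in seq_len(max_pass)) {
    dj <- element_det_jacobians(mesh)
    bad <- which(apply(dj, 1L, min) <= 0)
    if (!length(bad)) return(mesh)
    nid <- unique(as.integer(mesh$elements[bad, ]))
    reg <- regular_node_coords(mesh, nid)
    mesh$nodes[nid, ] <- (mesh$nodes[nid, ] + reg) / 2
  }
  dj <- element_det_jacobians(mesh)
  bad <- which(apply(dj, 1L, min) <= 0)
  stop("node-shift clamping failed; inverted element(s): ",
       paste(utils::head(bad, 5L), collapse = ", "))
}

regular_node_coords <- function(mesh, nid) {
  # undeformed lattice position of the given node ids
  vs <- mesh$voxel_size_mm
  dc <- mesh$dims + 1L
  # recover corner grid index from stored order is not kept; recompute from
  # rounding the undeformed lattice (nodes moved < vs/2, so rounding is safe)
  lo <- mesh$origin_mm - vs / 2
  idx <- round(sweep(mesh$nodes[nid, , drop = FALSE], 2L, lo, "-") / vs)
  sweep(idx * vs, 2L, lo, "+")
}

#' Jacobian determinants at the Gauss points of every element
#'
#' @param mesh a \code{hex_mesh}.
#' @return ne x 8 matrix of determinants (mm^3 scale); all entries must be
#'   positive for a valid mesh.
#' @export
element_det_jacobians <- function(mesh) {
  gp <- gauss_points_hex()
  ne <- nrow(mesh$elements)
  X <- lapply(1:3, function(a) {
    matrix(mesh$nodes[mesh$elements, a], ne, 8L)
  })
  out <- matrix(0, ne, 8L)
  for (g in 1:8) {
    dN <- hex_shape_grad(gp[g, ])
    J <- lapply(1:3, function(a) X[[a]] %*% dN)   # each ne x 3: row a of J
    out[, g] <- J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] -
                               J[[2]][, 3] * J[[3]][, 2]) -
                J[[1]][, 2] * (J[[2]][, 1] * J[[3]][, 3] -
                               J[[2]][, 3] * J[[3]][, 1]) +
                J[[1]][, 3] * (J[[2]][, 1] * J[[3]][, 2] -
                               J[[2]][, 2] * J[[3]][, 1])
  }
  out
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexahedra, node_shift %g\n",
              nrow(x$nodes), nrow(x$elements), x$node_shift))
  invisible(x)
}

# Locate the element containing each point (half-open voxel intervals: a
# point on a shared face belongs to the voxel with the larger index) and its
# local coordinates, inverting the trilinear map by Newton iteration.
locate_points <- function(mesh, points_mm) {
  points_mm <- rbind_points(points_mm)
  d <- mesh$dims
  vs <- mesh$voxel_size_mm
  lo <- mesh$origin_mm - vs / 2
  u <- sweep(points_mm, 2L, lo, "-") / vs
  idx <- floor(u) + 1L
  # a point exactly on the outer grid face belongs to the last voxel (the
  # half-open convention has no element with a larger index there)
  for (a in 1:3) {
    onface <- idx[, a] == d[a] + 1L & u[, a] - d[a] < 1e-9
    idx[onface, a] <- d[a]
  }
  n <- nrow(points_mm)
  elem <- integer(n)
  ok <- idx[, 1] >= 1L & idx[, 1] <= d[1] & idx[, 2] >= 1L &
        idx[, 2] <= d[2] & idx[, 3] >= 1L & idx[, 3] <= d[3]
  elem[ok] <- mesh$elem_of_voxel[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  if (any(elem == 0L)) {
    bad <- which(elem == 0L)[1L]
    stop(sprintf("point (%g, %g, %g) mm lies outside the mesh",
                 points_mm[bad, 1], points_mm[bad, 2], points_mm[bad, 3]))
  }
  xi <- matrix(0, n, 3L)
  for (p in seq_len(n)) {
    Xe <- mesh$nodes[mesh$elements[elem[p], ], , drop = FALSE]
    x0 <- points_mm[p, ]
    z <- 2 * (sweep(matrix(x0, 1), 2L, voxel_center_of(mesh, idx[p, ]),
                    "-")) / vs
    z <- pmin(1, pmax(-1, as.numeric(z)))
    for (it in 1:25) {
      r <- as.numeric(hex_shape(z) %*% Xe) - x0
      if (max(abs(r)) < 1e-12 * vs) break
      J <- t(Xe) %*% hex_shape_grad(z)          # 3 x 3
      z <- z - as.numeric(solve(J, r))
    }
    xi[p, ] <- z
  }
  list(elem = elem, xi = xi)
}

voxel_center_of <- function(mesh, idx) {
  mesh$origin_mm + (idx - 1) * mesh$voxel_size_mm
}

#' Trilinear interpolation of a nodal field at points
#'
#' @param mesh a \code{hex_mesh}.
#' @param potential numeric vector over mesh nodes.
#' @param points_mm n x 3 matrix (or length-3 vector) of points inside the
#'   mesh.
#' @return numeric vector of interpolated values.
#' @export
interpolate_at_points <- function(mesh, potential, points_mm) {
  loc <- locate_points(mesh, points_mm)
  n <- length(loc$elem)
  out <- numeric(n)
  for (p in seq_len(n)) {
    w <- hex_shape(loc$xi[p, ])
    out[p] <- sum(w * potential[mesh$elements[loc$elem[p], ]])
  }
  out
}

# interpolation weights as a sparse nodal vector (used by transfer solves)
interpolation_weights <- function(mesh, point_mm) {
  loc <- locate_points(mesh, point_mm)
  list(index = mesh$elements[loc$elem[1L], ],
       w = hex_shape(loc$xi[1L, ]))
}
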