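# Finite-element forward solver: stiffness assembly, partial-integration
# dipole sources, preconditioned conjugate-gradient solves, potential tables.

#' Assemble the FEM stiffness matrix
#'
#' Galerkin stiffness matrix
#' \eqn{K_{ij} = \sum_e \sigma_e \int_e \nabla\varphi_i \cdot \nabla\varphi_j}
#' over trilinear hexahedral elements with 2x2x2 Gauss quadrature.
#' Coordinates are converted to meters internally, so K is in siemens and
#' solutions of \eqn{K u = b} (b in amperes) are in volts. The matrix is
#' symmetric positive semi-definite with the constant vector in its kernel
#' (insulating Neumann boundary); the gauge is fixed at solve time.
#'
#' @param mesh a \code{hex_mesh}.
#' @param profile a \code{conductivity_profile} (or a numeric vector of
#'   conductivities indexed by label code as character names).
#' @return A \code{stiffness_system}: list with \code{K} (sparse dgCMatrix,
#'   siemens), \code{n_nodes}, and a cache environment for factorizations.
#' @export
assemble_stiffness <- function(mesh, profile) {
  sigma_by_label <- if (inherits(profile, "conductivity_profile"))
    profile$sigma else profile
  labs <- unique(mesh$element_label)
  miss <- setdiff(as.character(labs), names(sigma_by_label))
  if (length(miss))
    stop("no conductivity for label(s): ", paste(miss, collapse = ", "))
  sig_e <- unname(sigma_by_label[as.character(mesh$element_label)])
  if (any(!is.finite(sig_e)) || any(sig_e <= 0))
    stop("conductivities must be strictly positive")

  ne <- nrow(mesh$elements)
  X <- lapply(1:3, function(a) matrix(mesh$nodes[mesh$elements, a] * 1e-3,
                                      ne, 8L))
  gp <- gauss_points_hex()
  Kloc <- matrix(0, ne, 64L)
  for (g in 1:8) {
    dN <- hex_shape_grad(gp[g, ])
    J <- lapply(1:3, function(a) X[[a]] %*% dN)  # J[[a]][, b] = dx_a/dxi_b
    detJ <- J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] -
                           J[[2]][, 3] * J[[3]][, 2]) -
            J[[1]][, 2] * (J[[2]][, 1] * J[[3]][, 3] -
                           J[[2]][, 3] * J[[3]][, 1]) +
            J[[1]][, 3] * (J[[2]][, 1] * J[[3]][, 2] -
                           J[[2]][, 2] * J[[3]][, 1])
    # inverse via adjugate: iJ[[b]][[a]] = (J^-1)_{ba}
    iJ <- inv3x3(J, detJ)
    # physical gradients g_i = J^-T dN_i : G[[i]][, a] = sum_b dN[i,b] iJ_{ba}
    G <- vector("list", 8L)
    for (i in 1:8) {
      G[[i]] <- cbind(
        dN[i, 1] * iJ[[1]][[1]] + dN[i, 2] * iJ[[2]][[1]] +
          dN[i, 3] * iJ[[3]][[1]],
        dN[i, 1] * iJ[[1]][[2]] + dN[i, 2] * iJ[[2]][[2]] +
          dN[i, 3] * iJ[[3]][[2]],
        dN[i, 1] * iJ[[1]][[3]] + dN[i, 2] * iJ[[2]][[3]] +
          dN[i, 3] * iJ[[3]][[3]])
    }
    for (i in 1:8) for (j in i:8) {
      kij <- detJ * rowSums(G[[i]] * G[[j]])
      Kloc[, (i - 1L) * 8L + j] <- Kloc[, (i - 1L) * 8L + j] + kij
      if (j > i) Kloc[, (j - 1L) * 8L + i] <- Kloc[, (j - 1L) * 8L + i] + kij
    }
  }
  Kloc <- Kloc * sig_e
  ii <- mesh$elements[, rep(1:8, each = 8L)]
  jj <- mesh$elements[, rep(1:8, times = 8L)]
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj),
                            x = as.numeric(Kloc), dims = c(n, n))
  structure(list(K = K, n_nodes = n, cache = new.env(parent = emptyenv())),
            class = "stiffness_system")
}

# vectorized 3x3 inverse from row-list J and precomputed determinant;
# returns iJ[[b]][[a]] = (J^-1)_{ba}
inv3x3 <- function(J, detJ) {
  a <- J[[1]]; b <- J[[2]]; c <- J[[3]]
  # cofactor expansion of the inverse (transpose of cofactors / det)
  i11 <- (b[, 2] * c[, 3] - b[, 3] * c[, 2]) / detJ
  i12 <- (a[, 3] * c[, 2] - a[, 2] * c[, 3]) / detJ
  i13 <- (a[, 2] * b[, 3] - a[, 3] * b[, 2]) / detJ
  i21 <- (b[, 3] * c[, 1] - b[, 1] * c[, 3]) / detJ
  i22 <- (a[, 1] * c[, 3] - a[, 3] * c[, 1]) / detJ
  i23 <- (a[, 3] * b[, 1] - a[, 1] * b[, 3]) / detJ
  i31 <- (b[, 1] * c[, 2] - b[, 2] * c[, 1]) / detJ
  i32 <- (a[, 2] * c[, 1] - a[, 1] * c[, 2]) / detJ
  i33 <- (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / detJ
  list(list(i11, i12, i13), list(i21, i22, i23), list(i31, i32, i33))
}

#' @export
print.stiffness_system <- function(x, ...) {
  cat(sprintf("<stiffness_system> %d nodes, %d nonzeros\n",
              x$n_nodes, length(x$K@x)))
  invisible(x)
}

#' Partial-integration dipole load vector
#'
#' Right-hand side for a point current dipole: \eqn{b_i = m \cdot
#' \nabla\varphi_i(x_0)}, nonzero only on the 8 nodes of the element
#' containing the dipole. Entries sum to zero (partition of unity), matching
#' the compatibility condition of the insulating boundary.
#'
#' @param mesh a \code{hex_mesh}.
#' @param position_mm dipole position (mm), inside the mesh.
#' @param moment current dipole moment (A m).
#' @return sparse numeric vector over nodes (amperes).
#' @export
dipole_load_vector <- function(mesh, position_mm, moment) {
  loc <- locate_points(mesh, position_mm)
  el <- loc$elem[1L]
  Xe <- mesh$nodes[mesh$elements[el, ], , drop = FALSE] * 1e-3  # meters
  dN <- hex_shape_grad(loc$xi[1L, ])
  J <- t(Xe) %*% dN                      # J_{ab} = dx_a/dxi_b
  Gphys <- dN %*% solve(J)               # 8 x 3: rows are grad N_i (1/m)
  vals <- as.numeric(Gphys %*% as.numeric(moment))
  b <- numeric(nrow(mesh$nodes))
  b[mesh$elements[el, ]] <- vals
  b
}

#' St. Venant dipole load vector
#'
#' Moment-matching source model: monopole loads on the node patch around
#' the mesh vertex closest to the dipole, chosen as the minimum-norm load
#' reproducing zero total current, the prescribed dipole moment, and zero
#' second moments. Markedly more accurate than partial integration when the
#' dipole falls near an element corner, where shape-function gradients are
#' discontinuous; it is therefore the default source model of the forward
#' table simulation.
#'
#' @inheritParams dipole_load_vector
#' @return sparse numeric vector over nodes (amperes).
#' @export
venant_load_vector <- function(mesh, position_mm, moment) {
  loc <- locate_points(mesh, position_mm)
  el <- loc$elem[1L]
  enodes <- mesh$elements[el, ]
  d2 <- rowSums(sweep(mesh$nodes[enodes, , drop = FALSE], 2L,
                      as.numeric(position_mm), "-")^2)
  v0 <- enodes[which.min(d2)]
  els <- which(rowSums(mesh$elements == v0) > 0)
  cand <- sort(unique(as.integer(mesh$elements[els, ])))
  h <- mesh$voxel_size_mm * 1e-3
  s <- sweep(mesh$nodes[cand, , drop = FALSE] * 1e-3, 2L,
             as.numeric(position_mm) * 1e-3, "-") / h   # scaled offsets
  A <- rbind(rep(1, length(cand)), t(s),
             s[, 1]^2, s[, 2]^2, s[, 3]^2,
             s[, 1] * s[, 2], s[, 1] * s[, 3], s[, 2] * s[, 3])
  rhs <- c(0, as.numeric(moment) / h, rep(0, 6L))
  q <- tryCatch(crossprod(A, solve(A %*% t(A), rhs)),
                error = function(e) {
                  # degenerate patch: drop the second-moment conditions
                  A4 <- A[1:4, , drop = FALSE]
                  crossprod(A4, solve(A4 %*% t(A4), rhs[1:4]))
                })
  b <- numeric(nrow(mesh$nodes))
  b[cand] <- as.numeric(q)
  b
}

#' Dipole load for a chosen source model
#' @inheritParams dipole_load_vector
#' @param source_model \code{"venant"} (default) or \code{"partial"}.
#' @export
source_load_vector <- function(mesh, position_mm, moment,
                               source_model = c("venant", "partial")) {
  source_model <- match.arg(source_model)
  if (source_model == "venant") venant_load_vector(mesh, position_mm, moment)
  else dipole_load_vector(mesh, position_mm, moment)
}

#' Solve the FEM system for a nodal potential
#'
#' Solves \eqn{K u = b} for the singular (pure-Neumann) stiffness system.
#' The default path is a Jacobi-preconditioned conjugate gradient iteration;
#' \code{method = "direct"} uses a cached sparse Cholesky factorization with
#' one grounded node, which pays off when many right-hand sides share a
#' system. Either way the returned potential is shifted to zero mean over
#' nodes (gauge fix).
#'
#' @param system a \code{stiffness_system}.
#' @param load numeric load vector (amperes); must sum to zero.
#' @param rel_tol relative residual tolerance.
#' @param method \code{"cg"} or \code{"direct"}.
#' @param maxit iteration cap for CG; default \code{10 sqrt(n) + 1000}.
#' @return nodal potential vector (volts), zero mean.
#' @export
solve_potential <- function(system, load, rel_tol = 1e-9,
                            method = c("cg", "direct"), maxit = NULL) {
  method <- match.arg(method)
  n <- system$n_nodes
  if (length(load) != n) stop("load length does not match node count")
  bn <- sqrt(sum(load^2))
  if (bn == 0) return(numeric(n))
  if (abs(sum(load)) > 1e-8 * max(abs(load)))
    stop("incompatible load: entries must sum to zero ",
         "(insulating boundary admits no net current)")
  if (method == "direct") {
    u <- solve_direct(system, load)
    return(u - mean(u))
  }
  K <- system$K
  d <- Matrix::diag(K)
  d[d <= 0] <- 1
  if (is.null(maxit)) maxit <- ceiling(10 * sqrt(n)) + 1000L
  x <- numeric(n)
  r <- load
  z <- r / d
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2))
    if (rn <= rel_tol * bn) return(x - mean(x))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("CG did not converge in %d iterations (relative residual %.3e)",
               maxit, rn / bn))
}

solve_direct <- function(system, load) {
  ch <- system$cache$chol
  if (is.null(ch)) {
    n <- system$n_nodes
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(system$K[-n, -n]),
                           LDL = FALSE, perm = TRUE)
    system$cache$chol <- ch
  }
  u <- as.numeric(Matrix::solve(ch, load[-system$n_nodes]))
  c(u, 0)
}

default_montage <- function(electrodes) {
  ct <- electrodes$contacts
  do.call(rbind, lapply(split(ct, ct$shaft), function(d) {
    d <- d[order(d$contact), ]
    if (nrow(d) < 2L) return(NULL)
    data.frame(channel = paste0(d$contact_id[-nrow(d)], "-", d$contact_id[-1]),
               contact_a = d$contact_id[-nrow(d)],
               contact_b = d$contact_id[-1L])
  }))
}

#' Simulate the bipolar potential table for a stimulation plan
#'
#' For every stimulation pair a unit current dipole is placed at the
#' midpoint of anode and cathode, with moment along the cathode-to-anode
#' axis times the contact separation (the overall amplitude is arbitrary and
#' absorbed by the validation scaling factor). Table entry (pair, channel)
#' is the simulated potential at the channel's first contact minus its
#' second contact. With \code{use_transfer = TRUE} the table is computed by
#' reciprocity: one solve per recording channel with a +1/-1 load at its two
#' contacts, dotted with each pair's dipole load vector.
#'
#' @param mesh a \code{hex_mesh}.
#' @param profile a \code{conductivity_profile}.
#' @param electrodes an \code{electrode_set}.
#' @param plan a \code{stim_plan}.
#' @param montage data frame (channel, contact_a, contact_b); defaults to
#'   all adjacent-contact pairs per shaft.
#' @param use_transfer compute via reciprocal (per-channel) solves.
#' @param rel_tol,method,system solver options; \code{system} may pass a
#'   pre-assembled \code{stiffness_system} to reuse across calls.
#' @param source_model dipole discretization, \code{"venant"} (default) or
#'   \code{"partial"}; see \code{\link{venant_load_vector}}.
#' @return A \code{potential_table}: numeric matrix (pairs x channels, V)
#'   with pair/channel ids as dimnames.
#' @export
simulate_potential_table <- function(mesh, profile, electrodes, plan,
                                     montage = NULL, use_transfer = FALSE,
                                     rel_tol = 1e-9,
                                     method = c("cg", "direct"),
                                     system = NULL,
                                     source_model = c("venant", "partial")) {
  method <- match.arg(method)
  source_model <- match.arg(source_model)
  if (is.null(montage)) montage <- default_montage(electrodes)
  if (is.null(system)) system <- assemble_stiffness(mesh, profile)
  pos <- contact_positions(electrodes)
  need <- unique(c(montage$contact_a, montage$contact_b))
  if (!all(need %in% rownames(pos)))
    stop("montage references unknown contacts")
  pairs <- plan$pairs
  loads <- lapply(seq_len(nrow(pairs)), function(k) {
    pa <- pos[pairs$anode[k], ]
    pc <- pos[pairs$cathode[k], ]
    source_load_vector(mesh, (pa + pc) / 2, (pa - pc) * 1e-3,  # I = 1 A
                       source_model = source_model)
  })
  tab <- matrix(NA_real_, nrow(pairs), nrow(montage),
                dimnames = list(pairs$pair_id, montage$channel))
  if (use_transfer) {
    for (ch in seq_len(nrow(montage))) {
      wa <- interpolation_weights(mesh, pos[montage$contact_a[ch], ])
      wb <- interpolation_weights(mesh, pos[montage$contact_b[ch], ])
      lead <- numeric(system$n_nodes)
      lead[wa$index] <- lead[wa$index] + wa$w
      lead[wb$index] <- lead[wb$index] - wb$w
      w <- solve_potential(system, lead, rel_tol = rel_tol, method = method)
      tab[, ch] <- vapply(loads, function(b) sum(w * b), numeric(1))
    }
  } else {
    vpos <- pos[need, , drop = FALSE]
    ia <- match(montage$contact_a, need)
    ib <- match(montage$contact_b, need)
    for (k in seq_len(nrow(pairs))) {
      u <- solve_potential(system, loads[[k]], rel_tol = rel_tol,
                           method = method)
      vc <- interpolate_at_points(mesh, u, vpos)
      tab[k, ] <- vc[ia] - vc[ib]
    }
  }
  structure(tab, class = c("potential_table", "matrix"), units = "V")
}
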