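#' Multilayer concentric-sphere model
#'
#' Describes a head as nested concentric spherical shells of homogeneous
#' isotropic conductivity, with insulating air outside the outermost
#' boundary. Used by the analytical dipole solver
#' \code{\link{analytic_dipole_potential}}.
#'
#' @param radii_mm strictly increasing shell boundary radii in mm, innermost
#'   boundary first; the last entry is the outer (insulating) surface.
#' @param sigma conductivities in S/m, innermost shell first; one per shell
#'   (\code{length(radii_mm)} values).
#' @param n_terms maximum Legendre series degree. Field points radially
#'   just above the source shell converge at rate (b/r)^n, so a generous
#'   ceiling is kept; each degree is cheap.
#' @param tol relative series tail tolerance.
#' @return A \code{shell_model}.
#' @examples
#' # 4-shell head: brain, CSF, skull, scalp
#' shell_model(c(78, 80, 86, 92), c(0.33, 1.79, 0.01, 0.43))
#' @export
shell_model <- function(radii_mm, sigma, n_terms = 400L, tol = 1e-10) {
  radii_mm <- as.numeric(radii_mm)
  sigma <- as.numeric(sigma)
  if (length(radii_mm) != length(sigma))
    stop("need one conductivity per shell")
  if (any(diff(radii_mm) <= 0) || any(radii_mm <= 0))
    stop("radii must be strictly increasing and positive")
  if (any(sigma <= 0)) stop("conductivities must be strictly positive")
  structure(list(radii_mm = radii_mm, sigma = sigma,
                 n_terms = as.integer(n_terms), tol = tol),
            class = "shell_model")
}

#' @export
print.shell_model <- function(x, ...) {
  cat(sprintf("<shell_model> %d shells, outer radius %g mm\n",
              length(x$radii_mm), max(x$radii_mm)))
  print(data.frame(outer_radius_mm = x$radii_mm, sigma_S_per_m = x$sigma),
        row.names = FALSE)
  invisible(x)
}

#' Shell model matching a conductivity profile on a sphere phantom
#'
#' Convenience constructor: given the phantom shell radii and a model level,
#' returns the analytic \code{\link{shell_model}} with the corresponding
#' conductivities. Adjacent shells that receive equal conductivity (e.g.
#' gray and white under 4C) are kept as separate shells; this is physically
#' identical to merging them.
#'
#' @inheritParams sphere_phantom
#' @param profile a \code{conductivity_profile} (or model level string).
#' @param n_terms,tol series controls; the ground-truth generator keeps a
#'   margin (tol 1e-9) so that contacts arbitrarily close above the
#'   innermost interface stay within the truncation budget.
#' @param ... passed to \code{\link{shell_model}}.
#' @export
shell_model_for_profile <- function(radii_mm, profile, n_terms = 800L,
                                    tol = 1e-9, ...) {
  if (is.character(profile)) profile <- conductivity_profile(profile)
  ord <- order(radii_mm)  # innermost first
  labs <- TISSUE_LABELS[names(radii_mm)[ord]]
  shell_model(radii_mm[ord], unname(profile$sigma[as.character(labs)]),
              n_terms = n_terms, tol = tol, ...)
}

#' Analytical dipole potential in a multilayer sphere
#'
#' Electric potential of a current dipole inside the innermost shell of a
#' concentric multilayer sphere with insulating exterior, at arbitrary field
#' points inside or on the outer boundary. The solution is the closed-form
#' infinite-medium dipole term (for field points in the source shell) plus a
#' Legendre-series correction whose per-degree radial coefficients are
#' propagated across shell boundaries with 2x2 transfer matrices enforcing
#' continuity of the potential and of the radial current density, with zero
#' radial current at the outer surface.
#'
#' @param model a \code{\link{shell_model}}.
#' @param position_mm dipole position (length-3, mm), strictly inside the
#'   innermost shell.
#' @param moment current dipole moment (length-3, A m).
#' @param points_mm field points (n x 3 matrix or length-3 vector, mm).
#' @return numeric vector of potentials in volts (reference at infinity of
#'   the primary term; use differences between points).
#' @examples
#' m <- shell_model(78, 0.33)
#' # central radial dipole: V = 3 m cos(theta) / (4 pi sigma R^2) on the surface
#' analytic_dipole_potential(m, c(0, 0, 0), c(0, 0, 1e-9), c(0, 0, 78))
#' @export
analytic_dipole_potential <- function(model, position_mm, moment, points_mm) {
  stopifnot(inherits(model, "shell_model"))
  pts <- rbind_points(points_mm) * 1e-3           # to meters
  pos <- as.numeric(position_mm) * 1e-3
  m <- as.numeric(moment)
  radii <- model$radii_mm * 1e-3
  sig <- model$sigma
  L <- length(radii)
  R <- radii[L]
  b <- vnorm(pos)
  if (b >= radii[1L])
    stop("unsupported configuration: dipole must lie strictly inside the ",
         "innermost shell (|position| = ", signif(b * 1e3, 4), " mm, shell ",
         "radius ", signif(radii[1L] * 1e3, 4), " mm)")
  r <- sqrt(rowSums(pts^2))
  if (any(r > R * (1 + 1e-12)))
    stop("field points must lie inside or on the outer boundary")
  d2 <- rowSums(sweep(pts, 2L, pos, "-")^2)
  if (any(d2 == 0)) stop("field point coincides with the dipole position")

  # source direction; for a central dipole align it with the moment so that
  # the tangential channel vanishes and only degree 1 survives
  eb <- if (b > 0) pos / b else if (vnorm(m) > 0) unit_vec(m) else c(0, 0, 1)
  m_r <- sum(m * eb)

  rbar <- r / R
  bbar <- b / R
  rad_n <- radii / R

  # layer index of each field point (innermost layer whose boundary contains it)
  layer <- rep(L, length(r))
  for (j in rev(seq_len(L))) layer[r <= rad_n[j] * R * (1 + 1e-12)] <- j

  # angular ingredients per point
  rhat <- pts / pmax(r, .Machine$double.xmin)
  zero_r <- r == 0
  if (any(zero_r)) rhat[zero_r, ] <- matrix(eb, sum(zero_r), 3, byrow = TRUE)
  u <- pmin(1, pmax(-1, as.numeric(rhat %*% eb)))
  tang <- as.numeric(rhat %*% m) - u * m_r      # m . (rhat - u*eb)

  k0 <- 1 / (4 * pi * sig[1L] * R^2)

  # Exact infinite-medium primary term at every field point; the series then
  # carries only the induced (reflected) field, which converges at rates set
  # by the interface geometry instead of the slow (b/r)^n multipole rate of
  # the primary for points radially close above the source.
  dd <- sweep(pts, 2L, pos, "-")
  dn <- sqrt(rowSums(dd^2))
  V <- as.numeric(dd %*% m) / (4 * pi * sig[1L] * dn^3)
  in1 <- layer == 1L

  n_terms <- model$n_terms
  tol <- model$tol
  # Legendre recurrences
  Pnm1 <- rep(1, length(u))   # P_0
  Pn <- u                     # P_1
  dPnm1 <- rep(0, length(u))  # P_0'
  dPn <- rep(1, length(u))    # P_1'
  partial_max <- max(abs(V), .Machine$double.xmin)
  tail_small <- 0L
  converged <- FALSE
  bpow <- 1                    # bbar^(n-1)

  for (n in seq_len(n_terms)) {
    cf <- degree_solution(n, rad_n, sig)
    # cf$eval(j, rbar): radial factor of the induced field in layer j per
    # unit outgoing source s * rbar^-(n+1), with the primary r^-(n+1) series
    # subtracted in every layer (it is added above in closed form)
    a1 <- n * m_r * bpow       # multiplies P_n(u)
    a2 <- bpow                 # multiplies P_n'(u) * tang
    term <- numeric(length(u))
    for (j in unique(layer)) {
      sel <- layer == j
      rad <- cf$eval(j, rbar[sel])
      term[sel] <- k0 * rad * (a1 * Pn[sel] + a2 * dPn[sel] * tang[sel])
    }
    V <- V + term
    partial_max <- max(partial_max, max(abs(V)))
    tail_est <- max(abs(term))
    if (tail_est < tol * partial_max) {
      tail_small <- tail_small + 1L
      if (tail_small >= 3L) { converged <- TRUE; break }
    } else tail_small <- 0L
    # advance recurrences
    Pnp1 <- ((2 * n + 1) * u * Pn - n * Pnm1) / (n + 1)
    dPnp1 <- dPnm1 + (2 * n + 1) * Pn
    Pnm1 <- Pn; Pn <- Pnp1
    dPnm1 <- dPn; dPn <- dPnp1
    bpow <- bpow * bbar
    if (bpow == 0 && b > 0) { converged <- TRUE; break }
    if (b == 0 && n >= 1) { converged <- TRUE; break }  # only degree 1
  }
  if (!converged && n_terms > 0)
    stop(sprintf(paste0("series tolerance not reached after %d terms ",
                        "(tail estimate %.3e of partial sum)"),
                 n_terms, max(abs(term)) / partial_max))
  V
}

# Per-degree radial solution for a unit outgoing source field
# s * rbar^-(n+1) emitted from the innermost shell (radii normalized by the
# outer radius). Works in the scaled basis (p, q) = (A r^n, B r^-(n+1))
# evaluated at interface radii -- the physical contributions of the two
# radial branches -- so that interface crossings mix numbers of comparable
# magnitude and no r^(+-n) dynamic range ever meets a subtraction. This is
# the per-degree normalization that keeps the recursion stable at high n.
#
# Interface continuity at radius r between conductivities s1 (inner) and s2
# (outer), with kappa = s1/s2:
#   p' = [ (n+1 + kappa*n) p + (n+1)(1-kappa) q ] / (2n+1)
#   q' = [ n (1-kappa) p + (n + kappa*(n+1)) q ] / (2n+1)
# Within a layer from radius ra to rb: p *= (rb/ra)^n, q *= (rb/ra)^-(n+1).
degree_solution <- function(n, rad_n, sig) {
  L <- length(rad_n)
  r1 <- rad_n[1L]
  if (L == 1L) {
    # insulating boundary at rbar = 1: n*rho - (n+1) = 0
    rho <- (n + 1) / n
    return(list(eval = function(j, rb) rho * rb^n))
  }
  cross <- function(pq, kappa) {
    c(((n + 1) + kappa * n) * pq[1L] + (n + 1) * (1 - kappa) * pq[2L],
      n * (1 - kappa) * pq[1L] + (n + kappa * (n + 1)) * pq[2L]) /
      (2 * n + 1)
  }
  # Outside the source shell the solution is proportional to the unique
  # (up to scale) solution W satisfying the insulating outer boundary.
  # W is propagated INWARD from the surface; its inward growth is genuine
  # (source-like behavior deep inside), so no cancellation occurs -- the
  # outward-built alternative subtracts exponentially growing basis
  # solutions and hits a precision floor at high degree.
  W <- c(n + 1, n)                       # n*p - (n+1)*q = 0 at rbar = 1
  Wj <- vector("list", L)                # W at inner interface of layer j
  Dj <- numeric(L)                       # log-normalization at store time
  logD <- 0
  for (j in seq(L - 1L, 1L)) {
    f <- rad_n[j] / rad_n[j + 1L]        # inward within layer j+1
    W <- W * c(f^n, f^(-(n + 1)))
    mx <- max(abs(W))
    if (mx > 1e100) { W <- W / mx; logD <- logD + log(mx) }
    Wj[[j + 1L]] <- W
    Dj[j + 1L] <- logD
    W <- cross(W, sig[j + 1L] / sig[j])  # to the layer-j side
  }
  pW1 <- W[1L]; qW1 <- W[2L]
  logD1 <- logD
  ratio <- pW1 / qW1                     # regular admixture at r1, per unit q
  s_scale <- r1^(-(n + 1))               # unit source: q = r1^-(n+1) at r1
  list(eval = function(j, rb) {
    if (j == 1L) {
      if (ratio == 0) return(numeric(length(rb)))
      ratio * s_scale * (rb / r1)^n
    } else {
      rin <- rad_n[j - 1L]
      # field = s_scale * W_j / qW1, undoing the running normalization,
      # minus the primary series term rbar^-(n+1) handled in closed form
      resc <- exp(Dj[j] - logD1)
      cp <- Wj[[j]][1L] / qW1 * resc
      cq <- Wj[[j]][2L] / qW1 * resc
      s_scale * (cp * (rb / rin)^n + cq * (rb / rin)^(-(n + 1))) -
        rb^(-(n + 1))
    }
  })
}

#' RDM and MAG forward-solution comparison metrics
#'
#' Standard topography metrics for comparing two forward solutions on the
#' same sensor set: the relative difference measure
#' \eqn{RDM = \| v_t/\|v_t\| - v_r/\|v_r\| \|} (shape error, in [0, 2]) and
#' the magnitude ratio \eqn{MAG = \|v_t\| / \|v_r\|}.
#'
#' @param v_ref reference potentials (e.g. analytic).
#' @param v_test test potentials (e.g. FEM).
#' @return named numeric vector \code{c(rdm = , mag = )}.
#' @examples
#' rdm_mag(c(1, 2, 3), c(2, 4, 6))  # pure magnitude error: rdm 0, mag 2
#' @export
rdm_mag <- function(v_ref, v_test) {
  if (length(v_ref) != length(v_test) || length(v_ref) < 2L)
    stop("potential vectors must have equal length >= 2")
  nr <- vnorm(v_ref)
  if (nr == 0) stop("reference potentials are all zero")
  nt <- vnorm(v_test)
  rdm <- if (nt == 0) sqrt(2) else vnorm(v_test / nt - v_ref / nr)
  c(rdm = rdm, mag = nt / nr)
}
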