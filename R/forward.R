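## Spherical-conductor MEG forward model.
##
## The magnetic field of a current dipole in a homogeneous conducting sphere
## has the closed form of Sarvas (the field outside the sphere depends only
## on the dipole and the sphere centre, not on the conductivity profile).
## Each channel reads the projection of B onto its gradiometer axis at the
## sensor position; in the multiple local-spheres model each channel gets
## its own best-fitting sphere.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares sphere fit to a head-surface point cloud
#'
#' Minimises the geometric objective sum (|p_i - c| - r)^2 (optionally
#' weighted): an algebraic fit provides the initial centre, which is refined
#' by quasi-Newton minimisation of the distance variance; the radius is the
#' (weighted) mean distance at the optimum.
#'
#' @param points m x 3 matrix of surface points, m.
#' @param weights optional non-negative per-point weights.
#' @return list with `center` (3-vector) and `radius`.
#' @examples
#' u <- matrix(rnorm(300), 100, 3)
#' u <- u / sqrt(rowSums(u^2))
#' fitSphere(sweep(0.09 * u, 2, c(0, 0, 0.04), "+"))
#' @export
fitSphere <- function(points, weights = NULL) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 10L) stop("need at least 10 points to fit a sphere")
  if (is.null(weights)) weights <- rep(1, m)
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  ctr <- colSums(points * w)
  pc <- sweep(points, 2, ctr)
  sv <- svd(pc * sqrt(w), nu = 0, nv = 0)$d
  if (sv[3] < 1e-6 * sv[1])
    stop("degenerate point cloud: points are (near-)coplanar")
  # algebraic initialisation: |p|^2 = 2 p.c + (r^2 - |c|^2)
  A <- cbind(2 * points, 1) * sqrt(w)
  b <- rowSums(points^2) * sqrt(w)
  beta <- qr.solve(A, b)
  c0 <- beta[1:3]
  obj <- function(cc) {
    d <- sqrt(rowSums(sweep(points, 2, cc)^2))
    db <- sum(w * d)
    sum(w * (d - db)^2)
  }
  fit <- stats::optim(c0, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  cc <- fit$par
  d <- sqrt(rowSums(sweep(points, 2, cc)^2))
  list(center = cc, radius = sum(w * d))
}

#' Fit a head model
#'
#' `mode = "single_sphere"` fits one sphere to the whole cloud.
#' `mode = "local_spheres"` fits, for every channel, a sphere weighted by a
#' Gaussian of the distance between each surface point and that sensor
#' (tau = 0.05 m), so each channel sees the head curvature under it.  A
#' channel whose effective weighted point count falls below 10 falls back to
#' the single-sphere fit (reported via a message).
#'
#' @param points m x 3 head-surface point cloud, m.
#' @param sensors a [SensorArray-class] (required for local spheres).
#' @param tau Gaussian weighting length scale, m.
#' @return a [HeadModel-class].
#' @export
fitHeadModel <- function(points, sensors = NULL,
                         mode = c("local_spheres", "single_sphere"),
                         tau = 0.05) {
  mode <- match.arg(mode)
  glob <- fitSphere(points)
  if (mode == "single_sphere")
    return(new("HeadModel", mode = "single_sphere",
               center = matrix(glob$center, 1), radius = glob$radius))
  if (is.null(sensors)) stop("local_spheres mode needs the sensor array")
  n <- nChannels(sensors)
  centers <- matrix(0, n, 3)
  radii <- numeric(n)
  nfall <- 0L
  for (k in seq_len(n)) {
    d2 <- rowSums(sweep(points, 2, sensors@position[k, ])^2)
    wk <- exp(-d2 / (2 * tau^2))
    neff <- sum(wk)^2 / sum(wk^2)
    fit <- if (neff < 10) NULL else
      tryCatch(fitSphere(points, wk), error = function(e) NULL)
    if (is.null(fit)) {
      nfall <- nfall + 1L
      fit <- glob
    }
    centers[k, ] <- fit$center
    radii[k] <- fit$radius
  }
  if (nfall > 0)
    message(nfall, " channel(s) used the single-sphere fallback")
  new("HeadModel", mode = "local_spheres", center = centers, radius = radii)
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Evaluates the spherical-conductor closed form per channel, each channel
#' using its own sphere in local-spheres mode, and projects the field onto
#' the gradiometer axis at the sensor position.
#'
#' @param location dipole location, 3-vector, m (head coordinates).
#' @param moment dipole moment vector, Am (direction x magnitude).
#' @param sensors a [SensorArray-class].
#' @param head a [HeadModel-class].
#' @return numeric vector: tesla per channel.
#' @export
leadfieldDipole <- function(location, moment, sensors, head) {
  n <- nChannels(sensors)
  centers <- if (nrow(head@center) == 1L)
    matrix(head@center, n, 3, byrow = TRUE) else head@center
  radii <- if (length(head@radius) == 1L) rep(head@radius, n) else head@radius
  r0 <- sweep(-centers, 2, location, "+")          # dipole re each centre
  dist0 <- sqrt(rowSums(r0^2))
  if (any(dist0 >= radii))
    stop("dipole location outside (or on) a channel's sphere")
  if (any(dist0 < 1e-3))
    stop("dipole location within 1 mm of a sphere centre")
  r <- sensors@position - centers                   # sensor re each centre
  R <- sqrt(rowSums(r^2))
  a_vec <- r - r0
  a <- sqrt(rowSums(a_vec^2))
  adotr <- rowSums(a_vec * r)
  r0dotr <- rowSums(r0 * r)
  F <- a * (R * a + R^2 - r0dotr)
  gF_r <- a^2 / R + adotr / a + 2 * a + 2 * R       # coefficient of r
  gF_r0 <- a + 2 * R + adotr / a                    # coefficient of r0
  gradF <- gF_r * r - gF_r0 * r0
  # q x r0 per channel
  qxr0 <- cbind(moment[2] * r0[, 3] - moment[3] * r0[, 2],
                moment[3] * r0[, 1] - moment[1] * r0[, 3],
                moment[1] * r0[, 2] - moment[2] * r0[, 1])
  B <- 1e-7 * (F * qxr0 - rowSums(qxr0 * r) * gradF) / F^2
  rowSums(B * sensors@orientation)
}

#' Build a volumetric source grid
#'
#' Axis-aligned lattice at the given spacing, clipped to 90% of the (mean)
#' head-sphere radius.  The posterior ("occipital") search mask contains the
#' voxels whose anterior-posterior coordinate lies in the posterior third of
#' the grid.
#'
#' @param head a [HeadModel-class].
#' @param spacing lattice spacing, m.
#' @return a [SourceGrid-class].
#' @export
buildGrid <- function(head, spacing) {
  if (spacing <= 0) stop("spacing must be positive")
  ctr <- colMeans(head@center)
  rad <- mean(head@radius)
  if (spacing > rad) stop("spacing exceeds the head radius")
  rmax <- 0.9 * rad
  g <- seq(0, rmax, by = spacing)
  g <- c(-rev(g[-1]), g)
  vox <- as.matrix(expand.grid(x = g + ctr[1], y = g + ctr[2],
                               z = g + ctr[3]))
  colnames(vox) <- NULL
  keep <- sqrt(rowSums(sweep(vox, 2, ctr)^2)) <= rmax + 1e-12
  vox <- vox[keep, , drop = FALSE]
  xr <- range(vox[, 1])
  mask <- vox[, 1] <= xr[1] + diff(xr) / 3 + 1e-12
  new("SourceGrid", spacing = spacing, origin = ctr, voxels = vox,
      posteriorMask = mask)
}

#' Lead fields for every grid voxel
#'
#' For each voxel, builds the two tangential unit vectors (Gram-Schmidt
#' against the radial direction from the mean sphere centre) and evaluates
#' the dipole field along each.  Voxels within 1 mm of a sphere centre (or
#' outside a channel's sphere) are dropped and counted.
#'
#' @param grid a [SourceGrid-class].
#' @param sensors a [SensorArray-class].
#' @param head a [HeadModel-class].
#' @return a [LeadField-class].
#' @export
computeLeadfields <- function(grid, sensors, head) {
  ctr <- colMeans(head@center)
  n <- nChannels(sensors)
  nv <- nVoxels(grid)
  gain <- array(0, dim = c(n, 2, nv))
  basis <- array(0, dim = c(3, 2, nv))
  ok <- logical(nv)
  for (v in seq_len(nv)) {
    loc <- grid@voxels[v, ]
    ur <- loc - ctr
    nr <- sqrt(sum(ur^2))
    if (nr < 1e-6) next
    ur <- ur / nr
    e <- if (abs(ur[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    b1 <- e - sum(e * ur) * ur
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- .cross3(ur, b1)
    g <- tryCatch(cbind(leadfieldDipole(loc, b1, sensors, head),
                        leadfieldDipole(loc, b2, sensors, head)),
                  error = function(e) NULL)
    if (is.null(g)) next
    gain[, , v] <- g
    basis[, , v] <- cbind(b1, b2)
    ok[v] <- TRUE
  }
  keep <- which(ok)
  if (length(keep) == 0) stop("no valid voxels in the grid")
  nd <- nv - length(keep)
  if (nd > 0) message(nd, " voxel(s) dropped (at a sphere centre or outside a sphere)")
  new("LeadField", grid = grid, keep = as.integer(keep),
      gain = gain[, , keep, drop = FALSE],
      basis = basis[, , keep, drop = FALSE],
      channelId = sensors@channelId)
}
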