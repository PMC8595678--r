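spherePoints <- function(n, center, radius, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(radius * u, 2, center, "+")
}

test_that("sphere fitting recovers exact and noisy spheres", {
  p <- spherePoints(100, c(0, 0, 0.04), 0.09)
  fit <- fitSphere(p)
  expect_lt(max(abs(fit$center - c(0, 0, 0.04))), 1e-9)
  expect_lt(abs(fit$radius - 0.09), 1e-9)

  set.seed(2)
  noisy <- p + matrix(rnorm(300, sd = 1e-3), 100, 3)
  fit2 <- fitSphere(noisy)
  expect_lt(sqrt(sum((fit2$center - c(0, 0, 0.04))^2)), 1e-3)
  # oracle: generic 4-parameter nonlinear least squares on the same
  # geometric objective, independent of the profiled-radius path
  obj4 <- function(par) {
    d <- sqrt(rowSums(sweep(noisy, 2, par[1:3])^2))
    sum((d - par[4])^2)
  }
  ref <- optim(c(0.01, -0.01, 0.05, 0.08), obj4, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(sqrt(sum((fit2$center - ref$par[1:3])^2)), 1e-5)
  expect_lt(abs(fit2$radius - ref$par[4]), 1e-5)
})

test_that("degenerate point clouds are rejected", {
  flat <- cbind(matrix(runif(40), 20, 2), 0.01)
  expect_error(fitSphere(flat), "coplanar")
  expect_error(fitSphere(spherePoints(9, c(0, 0, 0), 0.1)), "at least 10")
})

test_that("local spheres equal the global fit on a spherical head", {
  p <- spherePoints(200, c(0, 0, 0.04), 0.09, seed = 3)
  hm <- fitHeadModel(p, unitSensors(), mode = "local_spheres")
  glob <- fitSphere(p)
  expect_lt(max(abs(sweep(hm@center, 2, glob$center))), 1e-6)
  expect_lt(max(abs(hm@radius - glob$radius)), 1e-6)
})

test_that("local spheres track an ellipsoidal head along its long axis", {
  p <- spherePoints(400, c(0, 0, 0), 1, seed = 4)
  p[, 1] <- p[, 1] * 0.11          # long anterior-posterior axis
  p[, 2] <- p[, 2] * 0.08
  p[, 3] <- p[, 3] * 0.08
  p <- sweep(p, 2, c(0, 0, 0.04), "+")
  sens <- unitSensors()
  hm <- fitHeadModel(p, sens, mode = "local_spheres")
  post <- which(sens@position[, 1] < quantile(sens@position[, 1], 0.2))
  front <- which(sens@position[, 1] > quantile(sens@position[, 1], 0.8))
  # posterior channels' spheres sit behind frontal channels' spheres
  expect_lt(mean(hm@center[post, 1]), mean(hm@center[front, 1]) - 0.005)
})

test_that("channels with degenerate weights fall back to the global sphere", {
  p <- spherePoints(60, c(0, 0, 0.04), 0.09, seed = 5)
  p <- p[p[, 1] > 0, , drop = FALSE]     # hemifield cloud only
  sens <- unitSensors()
  expect_message(hm <- fitHeadModel(p, sens, tau = 0.01), "fallback")
  glob <- fitSphere(p)
  far <- which.min(sens@position[, 1])   # sensor far from all points
  expect_equal(hm@center[far, ], glob$center, tolerance = 1e-12)
})

test_that("radial dipoles are silent in a spherical conductor", {
  sens <- unitSensors()
  head <- defaultHeadSphere()
  set.seed(6)
  for (i in 1:5) {
    loc <- head@center[1, ] + runif(3, -0.04, 0.04)
    ur <- loc - head@center[1, ]
    ur <- ur / sqrt(sum(ur^2))
    tb <- rnorm(3); tb <- tb - sum(tb * ur) * ur; tb <- tb / sqrt(sum(tb^2))
    frad <- leadfieldDipole(loc, ur, sens, head)
    ftan <- leadfieldDipole(loc, tb, sens, head)
    expect_lt(max(abs(frad)) / max(abs(ftan)), 1e-14)
  }
})

test_that("the field is linear in the dipole moment", {
  sens <- unitSensors()
  head <- defaultHeadSphere()
  loc <- c(-0.04, 0.01, 0.06)
  q <- c(0, 1, 0.5)
  f1 <- leadfieldDipole(loc, q, sens, head)
  f2 <- leadfieldDipole(loc, 3.7 * q, sens, head)
  expect_equal(f2, 3.7 * f1, tolerance = 1e-14)
})

test_that("the field is covariant under a common rotation", {
  sens <- unitSensors()
  head <- defaultHeadSphere()
  loc <- c(-0.045, 0.015, 0.055)
  q <- c(0.2, 0.9, -0.1)
  f <- leadfieldDipole(loc, q, sens, head)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- function(m) t(R %*% t(m))
  sensR <- sensorArray(sens@channelId, rot(sens@position),
                       rot(sens@orientation))
  headR <- new("HeadModel", mode = "single_sphere",
               center = rot(head@center), radius = head@radius)
  fR <- leadfieldDipole(drop(R %*% loc), drop(R %*% q), sensR, headR)
  expect_equal(fR, f, tolerance = 1e-12)
})

test_that("the closed form matches an independent implementation", {
  sens <- unitSensors()
  head <- defaultHeadSphere()
  set.seed(8)
  for (i in 1:4) {
    loc <- head@center[1, ] + runif(3, -0.05, 0.05)
    q <- rnorm(3)
    mine <- leadfieldDipole(loc, q, sens, head)
    ref <- sarvasOracle(loc, q, sens@position, sens@orientation,
                        head@center[1, ])
    expect_rel_equal(mine, ref, 1e-10)
  }
})

test_that("invalid dipole locations raise errors", {
  sens <- unitSensors()
  head <- defaultHeadSphere()
  expect_error(leadfieldDipole(c(0, 0, 0.2), c(0, 1, 0), sens, head),
               "outside")
  expect_error(leadfieldDipole(head@center[1, ] + 1e-4, c(0, 1, 0),
                               sens, head), "1 mm")
})

test_that("source grids clip to the head and mask the posterior third", {
  head <- defaultHeadSphere()
  g1 <- buildGrid(head, 0.04)
  r <- sqrt(rowSums(sweep(g1@voxels, 2, head@center[1, ])^2))
  expect_true(all(r <= 0.9 * 0.09 + 1e-12))
  g2 <- buildGrid(head, 0.02)
  expect_gt(nVoxels(g2), nVoxels(g1))
  expect_gt(sum(g1@posteriorMask), 0)
  expect_true(all(g1@voxels[g1@posteriorMask, 1] <=
                  max(g1@voxels[!g1@posteriorMask, 1])))
  expect_error(buildGrid(head, 0.12), "radius")
})

test_that("lead fields follow the dipole solver and attenuate with depth", {
  lf <- unitLeadfield()
  sens <- unitSensors()
  head <- defaultHeadSphere()
  v <- which.max(lf@grid@voxels[lf@keep, 3])       # a superficial voxel
  g1 <- leadfieldDipole(lf@grid@voxels[lf@keep[v], ], lf@basis[, 1, v],
                        sens, head)
  expect_identical(lf@gain[, 1, v], g1)
  # basis orthonormal and orthogonal to the radial direction
  ctr <- colMeans(head@center)
  for (vv in c(1L, v)) {
    b <- lf@basis[, , vv]
    expect_equal(crossprod(b), diag(2), tolerance = 1e-12)
    ur <- lf@grid@voxels[lf@keep[vv], ] - ctr
    expect_lt(max(abs(crossprod(b, ur / sqrt(sum(ur^2))))), 1e-12)
  }
  # deep voxels have weaker gain than superficial voxels on the same ray
  vox <- lf@grid@voxels[lf@keep, ]
  ray <- which(abs(vox[, 1]) < 1e-9 & abs(vox[, 2]) < 1e-9 &
               vox[, 3] > ctr[3] + 1e-9)
  ray <- ray[order(vox[ray, 3])]
  norms <- vapply(ray, function(v) sqrt(sum(lf@gain[, , v]^2)), numeric(1))
  expect_true(all(diff(norms) > 0))
})
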