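test_that("gaussian smoothing honours identity shortcut, mass and peak value", {
  withr::with_seed(1, u <- matrix(runif(40 * 40), 40, 40))
  expect_identical(gaussian_smooth(u, 0), u)
  expect_identical(gaussian_smooth(u, 0.2), u)  # below kernel resolution
  expect_error(gaussian_smooth(u, -1), "non-negative")

  cst <- matrix(0.7, 33, 33)
  expect_equal(gaussian_smooth(cst, 4), cst, tolerance = 1e-12)

  # unit impulse: discrete peak approximates 1 / (2 pi sigma^2)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- gaussian_smooth(imp, 2)
  expect_equal(sm[17, 17], 1 / (2 * pi * 4), tolerance = 0.02)

  # mirror boundaries preserve the mean exactly
  expect_lt(abs(mean(gaussian_smooth(u, 3)) - mean(u)), 1e-12)
})

test_that("structure tensor matches analytic ramps", {
  W <- 64
  ramp <- matrix(rep(seq_len(W) / W, each = 64), 64, W, byrow = FALSE)
  # ramp varies along columns (x): constant gradient g = 1/W
  J <- structure_tensor(ramp, sigma = 1e-4, rho = 4)
  interior <- 20:44
  g <- 1 / W
  expect_equal(mean(J$j11[interior, interior]), g^2, tolerance = 1e-6)
  expect_lt(max(abs(J$j22[interior, interior])), 1e-12)
  expect_lt(max(abs(J$j12[interior, interior])), 1e-12)

  # 45-degree ramp: all three components equal in the interior
  Y <- matrix(seq_len(64), 64, 64)
  X <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  diag_ramp <- (X + Y) / (2 * 64)
  Jd <- structure_tensor(diag_ramp, sigma = 1e-4, rho = 4)
  expect_equal(Jd$j11[interior, interior], Jd$j22[interior, interior],
               tolerance = 1e-6)
  expect_equal(Jd$j11[interior, interior], Jd$j12[interior, interior],
               tolerance = 1e-6)

  # constant image: zero tensor
  Jc <- structure_tensor(matrix(0.5, 32, 32), 1e-4, 4)
  expect_equal(max(abs(Jc$j11), abs(Jc$j12), abs(Jc$j22)), 0)
})

test_that("closed-form 2x2 eigendecomposition agrees with base eigen()", {
  mk <- function(a, b, c) {
    list(j11 = matrix(a, 1, 1), j12 = matrix(b, 1, 1), j22 = matrix(c, 1, 1))
  }
  # diagonal tensor
  E <- eigendecompose(mk(1, 0, 0))
  expect_equal(c(E$mu1, E$mu2), c(1, 0))
  expect_equal(abs(E$v1x[1, 1]), 1)

  # rank-1 tensor at 45 degrees
  E <- eigendecompose(mk(0.5, 0.5, 0.5))
  expect_equal(c(E$mu1, E$mu2), c(1, 0), tolerance = 1e-12)
  expect_equal(abs(c(E$v1x, E$v1y)), c(1, 1) / sqrt(2), tolerance = 1e-12)

  # isotropic: conventional eigenvector
  E <- eigendecompose(mk(0.3, 0, 0.3))
  expect_equal(E$mu1, E$mu2)
  expect_equal(c(E$v1x[1, 1], E$v1y[1, 1]), c(1, 0))

  # random symmetric tensors vs the numeric eigensolver
  withr::with_seed(9, {
    for (i in 1:50) {
      a <- runif(1, 0, 2); c <- runif(1, 0, 2); b <- runif(1, -1, 1)
      E <- eigendecompose(mk(a, b, c))
      ref <- eigen(matrix(c(a, b, b, c), 2, 2), symmetric = TRUE)
      expect_equal(c(E$mu1, E$mu2), ref$values, tolerance = 1e-10)
      v <- c(E$v1x, E$v1y)
      expect_equal(abs(sum(v * ref$vectors[, 1])), 1, tolerance = 1e-8)
      expect_equal(sum(v^2), 1, tolerance = 1e-9)
    }
  })
})

test_that("diffusion tensor assembly has the stated eigenvalue limits", {
  c1 <- 1e-10; c2 <- 1e-3
  iso <- eigendecompose(list(j11 = matrix(0.4, 2, 2),
                             j12 = matrix(0, 2, 2),
                             j22 = matrix(0.4, 2, 2)))
  D <- assemble_diffusion_tensor(iso, c1, c2)
  expect_equal(unclass(D$j11), matrix(c1, 2, 2))
  expect_equal(unclass(D$j22), matrix(c1, 2, 2))
  expect_equal(unclass(D$j12), matrix(0, 2, 2))

  # spot value: (mu1 - mu2)^2 = 1 with c2 = 1e-3 gives
  # lambda2 = c1 + (1 - c1) * exp(-1e-3)
  E <- eigendecompose(list(j11 = matrix(1, 1, 1), j12 = matrix(0, 1, 1),
                           j22 = matrix(0, 1, 1)))
  D <- assemble_diffusion_tensor(E, c1, c2)
  lam2 <- D$j22[1, 1]  # v1 = (1,0): lambda2 acts along y
  expect_equal(lam2, c1 + (1 - c1) * exp(-1e-3), tolerance = 1e-6)
  expect_equal(lam2, 0.9990005, tolerance = 1e-6)
  expect_gt(lam2, 0.999)
  # strong diffusion along y only: D ~ diag(c1, ~1)
  expect_equal(D$j11[1, 1], c1)
  expect_lt(abs(D$j12[1, 1]), 1e-15)

  # reconstructed D has eigenvalues within [c1, 1) on random fields
  withr::with_seed(3, u <- matrix(runif(32 * 32), 32, 32))
  J <- structure_tensor(u, 1e-4, 4)
  D <- assemble_diffusion_tensor(eigendecompose(J), c1, c2)
  Ed <- eigendecompose(D)
  expect_gte(min(Ed$mu2), c1 - 1e-12)
  expect_lt(max(Ed$mu1), 1)
})

test_that("one diffusion step with identity tensor equals the heat-step oracle", {
  withr::with_seed(7, u <- matrix(runif(48 * 48), 48, 48))
  Did <- list(j11 = matrix(1, 48, 48), j12 = matrix(0, 48, 48),
              j22 = matrix(1, 48, 48))
  out <- diffuse_step(u, Did, tau = 0.1)
  oracle <- heat_step_oracle(u, 0.1)
  interior <- 2:47
  expect_lt(max(abs(out[interior, interior] - oracle[interior, interior])),
            1e-10)
})

test_that("diffusion conserves the mean and respects the extremum principle", {
  withr::with_seed(11, {
    for (i in 1:5) {
      u <- matrix(runif(64 * 64), 64, 64)
      J <- structure_tensor(u, 1e-4, 4)
      D <- assemble_diffusion_tensor(eigendecompose(J), c1 = 0.05, c2 = 1e-3)
      out <- diffuse_step(u, D, tau = 0.25)
      expect_lt(abs(mean(out) - mean(u)), 1e-6)
      expect_gte(min(out), min(u) - 1e-9)
      expect_lte(max(out), max(u) + 1e-9)
    }
  })
  # constant images are fixed points for any tensor
  cst <- matrix(0.4, 32, 32)
  J <- structure_tensor(matrix(runif(32 * 32), 32, 32), 1e-4, 4)
  D <- assemble_diffusion_tensor(eigendecompose(J), 1e-10, 1e-3)
  expect_equal(diffuse_step(cst, D, 1), cst, tolerance = 1e-12)
})

test_that("isotropic-limit diffusion reduces to scaled heat flow", {
  withr::with_seed(13, u <- matrix(runif(40 * 40), 40, 40))
  c1 <- 0.2
  Diso <- list(j11 = matrix(c1, 40, 40), j12 = matrix(0, 40, 40),
               j22 = matrix(c1, 40, 40))
  out <- diffuse_step(u, Diso, tau = 0.1)
  oracle <- heat_step_oracle(u, 0.1 * c1)
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("ced is rotation-consistent and smooths interiors more than edges", {
  withr::with_seed(17, base <- matrix(runif(48 * 48, 0, 0.2), 48, 48))
  # horizontal bright lines every 12 px with interior speckle
  base[seq(6, 48, by = 12), ] <- 0.9
  g <- gray_image(base)
  p <- diffusion_params(n_steps = 4)

  out <- ced(g, p)
  rot <- ced(gray_image(rot90_mat(base)), p)
  expect_equal(rot90_mat(unclass(out)), unclass(rot), tolerance = 1e-9,
               ignore_attr = TRUE)

  # constant image unchanged
  cst <- gray_image(matrix(0.5, 32, 32))
  expect_equal(unclass(ced(cst, p)), matrix(0.5, 32, 32), tolerance = 1e-9,
               ignore_attr = TRUE)

  # interior variance drops, line contrast largely survives
  lines <- seq(6, 48, by = 12)
  interior <- setdiff(seq_len(48), c(lines - 1, lines, lines + 1))
  expect_lt(var(as.vector(unclass(out)[interior, ])),
            var(as.vector(base[interior, ])))
  contrast_before <- mean(base[lines, ]) - mean(base[interior, ])
  contrast_after <- mean(unclass(out)[lines, ]) - mean(unclass(out)[interior, ])
  expect_gt(contrast_after, 0.8 * contrast_before)
})

test_that("ced increases coherence along a noisy broken line", {
  withr::with_seed(23, u <- matrix(runif(48 * 48, 0, 0.15), 48, 48))
  u[24, ] <- 0.9
  u[24, c(12, 13, 30, 31)] <- 0.15   # breaks
  out <- ced(gray_image(u), diffusion_params(n_steps = 6))
  coh <- function(m) {
    E <- eigendecompose(structure_tensor(m, 1e-4, 4))
    mean((E$mu1[24, ] - E$mu2[24, ])^2)
  }
  expect_gt(coh(unclass(out)), coh(u))
})
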