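test_that("true effect draws match the Kronecker covariance", {
  expect_equal(drawTrueExposureEffects(50, matrix(0, 1, 1)),
               matrix(0, 50, 1))
  set.seed(21)
  ## p = 1: per-SNP variance h/M, so the M SNPs explain h in expectation
  M <- 20000
  B <- drawTrueExposureEffects(M, matrix(0.3, 1, 1))
  expect_lt(abs(var(as.numeric(B)) / (0.3 / M) - 1), 0.05)
  expect_lt(abs(sum(B^2) - 0.3), 0.02)
  ## p = 2 with genetic correlation 0.6
  D <- diag(sqrt(c(0.3, 0.3)))
  S <- D %*% matrix(c(1, .6, .6, 1), 2) %*% D
  B2 <- drawTrueExposureEffects(5000, S)
  expect_lt(abs(cor(B2[, 1], B2[, 2]) - 0.6), 0.05)
})

test_that("LD in the effect draw induces row correlation", {
  set.seed(22)
  R <- parseCovStructure("ar1(0.8)", 400)
  B <- drawTrueExposureEffects(400, matrix(0.3 / 400, 1, 1), R)
  adj <- cor(B[-400, 1], B[-1, 1])
  expect_lt(abs(adj - 0.8), 0.12)
})

test_that("UHP variance fraction matches its definition", {
  theta <- c(0.2, -0.1)
  D <- diag(sqrt(c(0.3, 0.2)))
  S <- D %*% matrix(c(1, .4, .4, 1), 2) %*% D
  expect_equal(drawUHPEffects(100, 0, 0.5, theta, S), numeric(100))
  expect_equal(drawUHPEffects(100, 10, 0, theta, S), numeric(100))
  set.seed(31)
  M <- 2e4
  g <- drawUHPEffects(M, M, 0.5, theta, S)
  target <- 0.5 * as.numeric(t(theta) %*% S %*% theta) / M
  expect_lt(abs(var(g) / target - 1), 0.05)
  ## ratio to Var(B theta) is rhoU
  B <- drawTrueExposureEffects(M, S)
  expect_lt(abs(var(g) / var(as.numeric(B %*% theta)) - 0.5), 0.05)
})

test_that("CHP support is disjoint from UHP and carries negative slope", {
  set.seed(41)
  theta <- 0.2; S <- matrix(0.3, 1, 1)
  M <- 2000; mU <- 300; mC <- 500
  B <- drawTrueExposureEffects(M, S)
  gU <- drawUHPEffects(M, mU, 0.3, theta, S)
  gC <- drawCHPEffects(M, mC, 0.3, -0.5, theta, S, B, mU)
  expect_true(all(which(gU != 0) <= mU))
  expect_true(all(which(gC != 0) > mU & which(gC != 0) <= mU + mC))
  expect_length(intersect(which(gU != 0), which(gC != 0)), 0)
  sup <- mU + seq_len(mC)
  expect_lt(cor(as.numeric(B %*% theta)[sup], gC[sup]), 0)
  expect_equal(drawCHPEffects(M, 0, 0.3, -0.5, theta, S, B), numeric(M))
  expect_error(drawCHPEffects(10, 8, .1, -.5, theta, S, B[1:10, , drop = FALSE], 5),
               "disjoint")
})

test_that("outcome effects obey the exact structural identity", {
  B <- rbind(c(0.1, 0.2), c(0, 0))
  theta <- c(0.3, -0.1)
  expect_equal(assembleOutcomeEffects(B, theta, c(0.05, 0), c(0, 0)),
               c(0.06, 0))
  set.seed(3)
  M <- 50
  S <- diag(2) * 0.3
  Bm <- drawTrueExposureEffects(M, S)
  gU <- drawUHPEffects(M, 5, .2, theta, S)
  gC <- drawCHPEffects(M, 7, .2, -.5, theta, S, Bm, 5)
  a <- assembleOutcomeEffects(Bm, theta, gU, gC)
  valid <- 13:50
  expect_equal(a[valid], as.numeric(Bm[valid, ] %*% theta))
})

test_that("generateSummary returns the full output contract", {
  sp <- quick_params(p = 3, theta = c(.2, .1, -.1), M = 60, mU = 10,
                     mC = 10, rhoU = .2, rhoC = .2, R = "ar1(0.4)", s = 6,
                     nref = 500, kxY = 1, RxY = 0.3)
  ds <- generateSummary(sp)
  expect_s4_class(ds, "MRDataset")
  expect_equal(ncol(bx(ds)), 3L)
  expect_equal(length(by(ds)), nIV(ds))
  expect_equal(dim(ldMatrix(ds)), dim(ldHatMatrix(ds)))
  expect_false(identical(ldMatrix(ds), ldHatMatrix(ds)))  # finite nref
  expect_equal(dim(rhoME(ds)), c(4L, 4L))
  expect_equal(causalEffects(ds), c(.2, .1, -.1))
  expect_true(all(ivType(ds) %in% c("valid", "UHP", "CHP")))
  expect_equal(nrow(ds@bxUnstd), nIV(ds))
  ## z standardization preserves z-scores and sets se = 1/sqrt(n)
  expect_equal(bx(ds) / bxse(ds), ds@bxUnstd / ds@bxseUnstd)
  expect_equal(unique(round(byse(ds), 12)), round(1 / sqrt(sp@nY), 12))
})

test_that("identical parameters and seed give bit-identical datasets", {
  sp <- quick_params(M = 40, mU = 5, rhoU = .3, nref = 200, R = "ar1(0.3)")
  d1 <- generateSummary(sp)
  d2 <- generateSummary(sp)
  expect_identical(d1@bx, d2@bx)
  expect_identical(d1@ldHatMatrix, d2@ldHatMatrix)
  d3 <- generateSummary(sp, seed = 99)
  expect_false(identical(d1@bx, d3@bx))
})

test_that("pleiotropy raises residual variance around the mediated slope", {
  set.seed(77)
  theta <- 0.2; S <- matrix(0.3, 1, 1); M <- 5000
  B <- drawTrueExposureEffects(M, S)
  Bt <- as.numeric(B %*% theta)
  a0 <- assembleOutcomeEffects(B, theta, numeric(M), numeric(M))
  expect_equal(cov(a0, Bt) / var(Bt), 1)
  expect_lt(max(abs(a0 - Bt)), 1e-12)
  gU <- drawUHPEffects(M, M, 0.4, theta, S)
  aU <- assembleOutcomeEffects(B, theta, gU, numeric(M))
  residVar <- mean(resid(lm(aU ~ Bt))^2)
  expect_lt(abs(residVar / (0.4 * var(Bt)) - 1), 0.1)
})

test_that("arbitrary overlap structures propagate into RhoME blocks", {
  sp <- quick_params(p = 2, theta = c(.2, .1), M = 30, kxY = c(0, 0),
                     Kxx = matrix(c(1, .8, .8, 1), 2), RxY = 0.3)
  ds <- generateSummary(sp)
  expect_equal(rhoME(ds)[1, 2], 0)          # no exposure-outcome overlap
  expect_equal(rhoME(ds)[1, 3], 0)
  expect_gt(rhoME(ds)[2, 3], 0)             # exposure-exposure overlap
})

test_that("stdType none leaves estimates on the raw scale", {
  sp <- quick_params(M = 30, stdType = "none")
  ds <- generateSummary(sp)
  expect_identical(bx(ds), ds@bxUnstd)
  expect_identical(byse(ds), ds@byseUnstd)
})
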