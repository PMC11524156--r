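test_that("independent samples give a diagonal error covariance", {
  ec <- errorCovariance(nx = c(2e4, 5e4), nY = 1e4, kxY = c(0, 0),
                        Kxx = diag(2), RxY = diag(3))
  expect_equal(diag(ec@Omega), c(1e-4, 5e-5, 2e-5))
  expect_equal(ec@Omega[upper.tri(ec@Omega)], rep(0, 3))
  expect_equal(ec@RhoME, diag(3))
})

test_that("complete overlap recovers the phenotypic correlation", {
  RxY <- matrix(c(1, .4, .4, 1), 2)
  ec <- errorCovariance(nx = 1e4, nY = 1e4, kxY = 1, Kxx = diag(1),
                        RxY = RxY)
  expect_equal(ec@RhoME[1, 2], 0.4)
  ec2 <- errorCovariance(nx = 1e4, nY = 1e4, kxY = 0.5, Kxx = diag(1),
                         RxY = RxY)
  expect_equal(ec2@RhoME[1, 2], 0.2)  # |rho_ME| <= overlap proportion
})

test_that("the overlap formula matches a Monte-Carlo OLS oracle", {
  set.seed(101)
  emp <- overlap_cov_oracle(nA = 500, nB = 500, nShared = 250, rho = 0.4,
                            nSNP = 4000)
  pred <- 250 * 0.4 / (500 * 500)
  expect_lt(abs(emp - pred), 3 * sqrt((1 / 500)^2 + pred^2) / sqrt(4000))
})

test_that("Omega respects exposure permutation symmetry", {
  RxY <- matrix(0.3, 3, 3); diag(RxY) <- 1
  Kxx <- matrix(c(1, .5, .5, 1), 2)
  ec <- errorCovariance(nx = c(1e4, 2e4), nY = 3e4, kxY = c(0.2, 0.8),
                        Kxx = Kxx, RxY = RxY)
  perm <- c(1, 3, 2)   # outcome fixed first, exposures swapped
  ec2 <- errorCovariance(nx = c(2e4, 1e4), nY = 3e4, kxY = c(0.8, 0.2),
                         Kxx = Kxx[2:1, 2:1], RxY = RxY[perm, perm])
  expect_equal(ec2@Omega, ec@Omega[perm, perm])
})

test_that("estimation-error draws reproduce Omega empirically", {
  ec <- errorCovariance(nx = c(1e4, 1e4), nY = 1e4, kxY = c(0.5, 0),
                        Kxx = diag(2),
                        RxY = {
                          m <- matrix(c(1, .4, .2, .4, 1, .3, .2, .3, 1), 3)
                          (m + t(m)) / 2
                        })
  set.seed(7)
  M <- 1e5
  e <- drawEstimationErrors(ec, M)
  E <- cbind(e$wAlpha, e$Wbeta)
  emp <- cov(E)
  mcse <- sqrt((outer(diag(ec@Omega), diag(ec@Omega)) + ec@Omega^2) / M)
  expect_true(all(abs(emp - ec@Omega) < 3.5 * mcse))
  ## zero-overlap exposure: its error is uncorrelated with the outcome's
  expect_lt(abs(cor(e$wAlpha, e$Wbeta[, 2])), 3.5 / sqrt(M))
})

test_that("draws are deterministic under a fixed seed", {
  ec <- errorCovariance(nx = 1e4, nY = 1e4, kxY = 0.5, Kxx = diag(1),
                        RxY = matrix(c(1, .4, .4, 1), 2))
  set.seed(33); a <- drawEstimationErrors(ec, 100)
  set.seed(33); b <- drawEstimationErrors(ec, 100)
  expect_identical(a, b)
})

test_that("squared-SE draws have mean 1/n and chi-square spread", {
  set.seed(5)
  n <- 1e4; M <- 1e5
  s2 <- drawSquaredSE(n, M)
  expect_true(all(s2 > 0))
  expect_lt(abs(mean(s2) * n - 1), 0.01)
  ## CV shrinks as sqrt(2/(n-1))
  expect_lt(abs(sd(s2) / mean(s2) / sqrt(2 / (n - 1)) - 1), 0.05)
  expect_error(drawSquaredSE(1, 10), ">= 2")
})

test_that("Wishart LD noise standardizes to a correlation matrix", {
  R <- parseCovStructure("ar1(0.5)", 8)
  expect_identical(drawEstimatedLD(R, Inf), R)
  set.seed(2)
  Rhat <- drawEstimatedLD(R, 500)
  expect_equal(diag(Rhat), rep(1, 8))
  expect_equal(Rhat, t(Rhat))
  expect_false(identical(Rhat, R))
  expect_error(drawEstimatedLD(R, 8), "singular")
})

test_that("reference-panel noise scales like the folded-normal prediction", {
  set.seed(11)
  nref <- 1000
  devs <- replicate(150, {
    Rhat <- drawEstimatedLD(diag(10), nref)
    mean(abs(Rhat[upper.tri(Rhat)]))
  })
  expect_lt(abs(mean(devs) / sqrt(2 / (pi * nref)) - 1), 0.1)
})
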