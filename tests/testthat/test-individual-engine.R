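test_that("raw genotypes are Binomial(2, maf); standardization is exact", {
  set.seed(12)
  G <- drawGenotypes(2e4, 5, maf = 0.3, standardize = FALSE)
  expect_true(all(G %in% 0:2))
  expect_lt(max(abs(colMeans(G) - 0.6)), 0.02)
  expect_lt(max(abs(apply(G, 2, var) - 0.42)), 0.02)
  Gs <- drawGenotypes(5000, 5, maf = 0.3)
  expect_lt(max(abs(colMeans(Gs))), 1e-12)
  expect_equal(unname(apply(Gs, 2, var)), rep(1, 5))
})

test_that("copula LD approaches the latent-threshold target", {
  set.seed(13)
  R <- parseCovStructure("ar1(0.8)", 10)
  G <- drawGenotypes(5e4, 10, maf = 0.3, R = R)
  target <- copula_genotype_corr(0.8, 0.3)
  adj <- mean(sapply(1:9, function(j) cor(G[, j], G[, j + 1])))
  expect_lt(abs(adj - target), 0.05)
  expect_lt(target, 0.8)  # thresholding attenuates the latent correlation
  ## independence limit
  G0 <- drawGenotypes(5000, 8, maf = 0.3)
  cc <- cor(G0)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(5000))
})

test_that("individual pleiotropy components explain their variance share", {
  set.seed(14)
  G <- drawGenotypes(2e4, 50)
  gU <- drawUHPIndividual(G, 10, 0.15)
  expect_true(all(which(gU != 0) <= 10))
  expect_equal(var(as.numeric(G %*% gU)), 0.15, tolerance = 1e-10)
  gC <- drawCHPIndividual(G, 20, 0.2, mU = 10)
  expect_true(all(which(gC != 0) > 10 & which(gC != 0) <= 30))
  expect_equal(var(as.numeric(G %*% gC)), 0.2, tolerance = 1e-10)
  expect_length(intersect(which(gU != 0), which(gC != 0)), 0)
  expect_equal(drawUHPIndividual(G, 10, 0), numeric(50))
  expect_equal(drawCHPIndividual(G, 0, 0.3), numeric(50))
})

test_that("exposure-effect columns carry exact heritability", {
  set.seed(15)
  B <- drawExposureEffectsMatrix(200, c(0.3, 0.1, 0), diag(3))
  expect_equal(unname(diag(crossprod(B))), c(0.3, 0.1, 0),
               tolerance = 1e-14)
  ## genetic correlation approximately survives the rescale
  reps <- replicate(200, {
    b <- drawExposureEffectsMatrix(100, c(0.3, 0.3),
                                   matrix(c(1, .6, .6, 1), 2))
    cor(b[, 1], b[, 2])
  })
  expect_lt(abs(mean(reps) - 0.6), 0.05)
})

test_that("structural model solves the unconfounded limit in closed form", {
  set.seed(16)
  ip <- individualParams(M = 50, p = 1, covXU = diag(1), varYUX = 0.96,
                         n1 = 1000, n0 = 1000)
  B <- drawExposureEffectsMatrix(50, ip@h, ip@Rbb)
  mod <- buildStructuralModel(ip, B, numeric(50), numeric(50))
  expect_equal(mod@piX, 0)
  expect_equal(mod@piY, 0, tolerance = 1e-4)
  expect_equal(mod@theta, 0.2, tolerance = 1e-4)
  ## Var(x) = h + residual => residual = 1 - h
  expect_equal(mod@SigmaEpsX[1, 1], 1 - 0.3, tolerance = 1e-12)
  expect_equal(mod@residSdY^2, 1 - 0.04, tolerance = 1e-6)
})

test_that("confounder variance decomposes as CHP share plus residual", {
  set.seed(17)
  ip <- individualParams(M = 60, p = 1, covXU = matrix(0.8, 1, 1),
                         varYUX = 0.9, mC = 20, sigma2GammaC = 0.25,
                         n1 = 1000, n0 = 1000)
  G <- drawGenotypes(5e4, 60)
  gC <- drawCHPIndividual(G, 20, 0.25)
  B <- drawExposureEffectsMatrix(60, ip@h, ip@Rbb)
  mod <- buildStructuralModel(ip, B, numeric(60), gC)
  expect_equal(mod@residSdU^2 + 0.25, 1, tolerance = 0.02)
  expect_equal(sign(mod@piY), -1)
  expect_equal(mod@implied$condVar, 0.9, tolerance = 1e-5)
})

test_that("infeasible variance budgets fail loudly", {
  ip <- individualParams(M = 20, p = 1, covXU = matrix(0.05, 1, 1),
                         h = 0.9, n1 = 1000, n0 = 1000)
  set.seed(18)
  B <- drawExposureEffectsMatrix(20, 0.9, diag(1))
  expect_error(buildStructuralModel(ip, B, numeric(20), numeric(20)),
               "residual variance")
})

test_that("theta signs follow signTheta", {
  set.seed(19)
  ip <- individualParams(M = 40, p = 2, varYUX = c(0.9, 0.95),
                         signTheta = c(1, -1), n1 = 1000, n0 = 1000)
  B <- drawExposureEffectsMatrix(40, ip@h, ip@Rbb)
  mod <- buildStructuralModel(ip, B, numeric(40), numeric(40))
  expect_gt(mod@theta[1], 0)
  expect_lt(mod@theta[2], 0)
})

test_that("phenotypes follow the structural equations with unit variance", {
  set.seed(20)
  ip <- individualParams(M = 50, p = 2, covXU = matrix(c(.8, .1, .1, .9), 2),
                         varYUX = c(.9, .92), mU = 5, mC = 5,
                         sigma2GammaU = .05, sigma2GammaC = .1,
                         n1 = 1000, n0 = 1000)
  n <- 5e4
  G <- drawGenotypes(n, 50)
  gU <- drawUHPIndividual(G, 5, .05)
  gC <- drawCHPIndividual(G, 5, .1, mU = 5)
  B <- drawExposureEffectsMatrix(50, ip@h, ip@Rbb)
  mod <- buildStructuralModel(ip, B, gU, gC)
  ph <- simulatePhenotypes(G, mod)
  expect_lt(abs(var(ph@U) - 1), 0.05)
  expect_lt(max(abs(apply(ph@x, 2, var) - 1)), 0.05)
  expect_lt(abs(var(ph@Y) - 1), 0.05)
  ## no genetic path to Y at all effects zero: Y is pure noise
  ip0 <- individualParams(M = 10, p = 1, covXU = diag(1), varYUX = 1,
                          n1 = 1000, n0 = 1000, h = 0)
  B0 <- drawExposureEffectsMatrix(10, 0, diag(1))
  m0 <- buildStructuralModel(ip0, B0, numeric(10), numeric(10))
  p0 <- simulatePhenotypes(drawGenotypes(2e4, 10), m0)
  expect_lt(abs(var(p0@Y) - 1), 0.05)
  expect_lt(max(abs(cor(p0@Y, p0@x))), 0.02)
})

test_that("per-SNP OLS matches the closed form and is null-calibrated", {
  g <- c(-1.34, -0.45, 0.45, 1.34)
  y <- c(-1, -0.5, 0.5, 1)
  gw <- runGWAS(matrix(g, 4, 1), y)
  expect_equal(gw$bhat, sum(g * y) / sum(g^2))
  ## perfect fit
  set.seed(23)
  G <- drawGenotypes(500, 3)
  gw2 <- runGWAS(G, G[, 2])
  expect_equal(gw2$bhat[2], 1)
  expect_lt(gw2$se[2], 1e-10)
  ## null calibration: mean z^2 about 1
  yN <- rnorm(1e4)
  GN <- drawGenotypes(1e4, 300)
  gw3 <- runGWAS(GN, yN)
  expect_lt(abs(mean((gw3$bhat / gw3$se)^2) - 1), 0.1)
})

test_that("generateIndividual is deterministic and reports analytic RhoME", {
  ip <- individualParams(M = 40, p = 1, varYUX = 0.96, n1 = 4000,
                         n0 = 4000, p01 = 0, seed = 8)
  d1 <- generateIndividual(ip)
  d2 <- generateIndividual(ip)
  expect_identical(d1@bx, d2@bx)
  expect_equal(rhoME(d1)[1, 2], 0)          # no overlap, no correlation
  ipF <- individualParams(M = 40, p = 1, covXU = matrix(0.7, 1, 1),
                          varYUX = 0.5, n1 = 4000, n0 = 4000, p01 = 1,
                          seed = 8)
  dF <- generateIndividual(ipF)
  expect_gt(abs(rhoME(dF)[1, 2]), 0.05)     # complete overlap
  expect_lt(abs(rhoME(dF)[1, 2]), 1)
})

test_that("overlapping samples correlate the realized estimation errors", {
  set.seed(30)
  reps <- 40
  cors <- replicate(reps, {
    ip <- individualParams(M = 150, p = 1, covXU = matrix(0.7, 1, 1),
                           varYUX = 0.9, n1 = 2000, n0 = 2000, p01 = 1,
                           seed = sample.int(1e6, 1))
    ds <- generateIndividual(ip)
    tr <- trueEffects(ds)
    ex <- ds@bxUnstd[, 1] - tr@B[ivIndex(ds), 1]
    ey <- ds@byUnstd - tr@alpha[ivIndex(ds)]
    c(cor(ex, ey), rhoME(ds)[1, 2])
  })
  expect_lt(abs(mean(cors[1, ]) - mean(cors[2, ])), 0.06)
})

test_that("winner's-curse selection inflates selected effect sizes", {
  set.seed(31)
  ip <- individualParams(M = 200, p = 1, varYUX = 0.96, n1 = 3000,
                         n0 = 3000, tau = 5e-4, stdType = "none",
                         seed = 44)
  ds <- generateIndividual(ip)
  tr <- trueEffects(ds)
  expect_gt(mean(abs(ds@bxUnstd[, 1])),
            mean(abs(tr@B[ivIndex(ds), 1])))
})
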