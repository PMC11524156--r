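test_that("Wald p-values follow the normal quantiles", {
  expect_equal(waldPvalues(0, 1), 1)
  expect_equal(waldPvalues(1.959964, 1), 0.05, tolerance = 1e-6)
  p <- waldPvalues(c(0, 1, 2), c(1, 1, 1))
  expect_length(p, 3)
  expect_true(all(diff(p) < 0))
  expect_error(waldPvalues(1, 0), "positive")
})

test_that("LD pruning keeps the higher-priority SNP of a violating pair", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- sqrt(0.9)
  expect_equal(ldPrune(R, c(0.01, 0.002, 0.5), kappa2 = 0.5), c(2, 3))
  expect_equal(ldPrune(R, c(0.002, 0.01, 0.5), kappa2 = 0.5), c(1, 3))
  expect_equal(ldPrune(R, 1:3, kappa2 = 1), 1:3)
})

test_that("pruned sets agree with the brute-force oracle", {
  set.seed(50)
  for (i in 1:50) {
    d <- sample(5:20, 1)
    R <- random_corr(d)
    pr <- runif(d)
    k2 <- runif(1, 0.05, 0.9)
    kept <- ldPrune(R, pr, k2)
    expect_identical(kept, prune_oracle(R, pr, k2))
    if (length(kept) > 1) {
      sub <- R[kept, kept]^2
      expect_lte(max(sub[upper.tri(sub)]), k2)
    }
  }
})

test_that("IV selection applies the min-p rule then LD pruning", {
  p5 <- c(0.001, 0.2, 0.04, 0.5, 0.01)
  expect_equal(selectIVs(p5, tau = 0.05, R = diag(5), kappa2 = 1),
               c(1L, 3L, 5L))
  expect_equal(selectIVs(p5, tau = 1, R = diag(5), kappa2 = 1), 1:5)
  err <- tryCatch(selectIVs(p5, tau = 1e-5, R = diag(5), kappa2 = 1),
                  error = identity)
  expect_s3_class(err, "MRsimSelectionError")
  expect_match(conditionMessage(err), "relax tau")
  ## multivariable: a SNP qualifies through any exposure
  pm <- cbind(c(0.5, 0.9), c(0.01, 0.8))
  expect_equal(selectIVs(pm, 0.05, diag(2), 1), 1L)
})

test_that("mean F is the average squared z-statistic per exposure", {
  expect_equal(meanFStatistic(c(1, 2), c(1, 2)), 1)
  expect_equal(meanFStatistic(3, 1), 9)
  m <- meanFStatistic(cbind(c(1, 3), c(2, 2)), matrix(1, 2, 2))
  expect_equal(m, c(5, 4))
})

test_that("F-targeting picks the removal step closest to the target", {
  f <- c(100, 50, 10, 5)            # per-SNP F; z = sqrt(F), se = 1
  res <- targetFStatistic(sqrt(f), rep(1, 4), Ftarget = 10)
  ## enumeration oracle: removing the largest one at a time
  means <- c(mean(f), mean(f[-1]), mean(f[-(1:2)]))
  expect_equal(res$trajectory, means)
  best <- which.min(abs(means - 10)) - 1L
  expect_equal(res$achieved, means[best + 1L])
  expect_equal(sort(res$keep), 3:4)
  ## already weak: identity with warning
  expect_warning(res2 <- targetFStatistic(c(1, 2), c(1, 1), 10),
                 "already")
  expect_equal(res2$keep, 1:2)
})

test_that("the removal trajectory strictly decreases", {
  set.seed(60)
  z <- rnorm(300, 0, 3)
  res <- targetFStatistic(z, rep(1, 300), Ftarget = 2)
  expect_true(all(diff(res$trajectory) < 0))
})

test_that("z standardization preserves z-scores and F-statistics", {
  set.seed(61)
  b <- rnorm(20, 0, 0.05); se <- runif(20, 0.01, 0.02)
  out <- standardizeEstimates(b, se, n = 1e4, mode = "z")
  expect_equal(out$b / out$se, b / se)
  expect_equal(out$se, rep(1e-2, 20))
  expect_equal(meanFStatistic(out$b, out$se), meanFStatistic(b, se))
  none <- standardizeEstimates(b, se, 1e4, "none")
  expect_identical(none$b, b)
  ## matrix input with per-column n
  B <- cbind(b, b); SE <- cbind(se, se)
  outM <- standardizeEstimates(B, SE, n = c(1e4, 4e4), mode = "z")
  expect_equal(outM$se[1, ], c(1e-2, 5e-3))
})

test_that("assembled datasets keep index/estimate correspondence", {
  sp <- quick_params(M = 80, mU = 10, mC = 10, rhoU = .3, rhoC = .3,
                     tau = 0.1, nx = 2e4, nY = 2e4, R = "ar1(0.5)", s = 8,
                     kappa2 = 0.2, stdType = "none")
  ds <- generateSummary(sp)
  tr <- trueEffects(ds)
  S <- ivIndex(ds)
  expect_identical(ds@ivType, tr@ivType[S])
  expect_equal(ds@ldMatrix, sp@R[S, S])
  ## no kept pair violates the LD threshold
  r2 <- ds@ldMatrix^2; diag(r2) <- 0
  expect_lte(max(r2), 0.2)
  ## every selected SNP passes tau
  pv <- waldPvalues(ds@bxUnstd, ds@bxseUnstd)
  expect_lt(max(apply(pv, 1, min)), 0.1)
})
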