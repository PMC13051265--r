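one_snp <- function(bx, sx, by, sy)
  HarmonizedSet("v1", bx, sx, by, sy)

test_that("Wald ratio arithmetic, null case and flip invariance", {
  e <- waldRatio(one_snp(0.1, 0.01, 0.05, 0.02))
  expect_equal(e@b, 0.5)
  expect_equal(e@se, 0.2)
  null <- waldRatio(one_snp(0.1, 0.01, 0, 0.02))
  expect_equal(null@b, 0)
  expect_equal(null@pvalue, 1)
  flipped <- waldRatio(one_snp(-0.1, 0.01, -0.05, 0.02))
  expect_equal(flipped@b, e@b)
  expect_error(waldRatio(one_snp(0, 0.01, 0.05, 0.02)), "undefined ratio")
  expect_error(waldRatio(make_hset(3, 1)), "exactly 1")
})

test_that("IVW solves the weighted regression through the origin", {
  h <- HarmonizedSet(c("a", "b", "c"),
                     betaX = c(0.1, 0.2, 0.1), seX = rep(0.01, 3),
                     betaY = c(0.05, 0.10, 0.05), seY = c(0.02, 0.02, 0.04))
  e <- mrIvw(h)
  expect_equal(e@b, 0.5)
  expect_equal(e@q, 0)          # all ratios identical: no heterogeneity
  expect_equal(e@qPvalue, 1)
  # with Q = 0 the multiplicative scale floors at 1: fixed = random
  expect_equal(mrIvw(h, "fixed")@se, e@se)
  expect_error(mrIvw(one_snp(0.1, 0.01, 0.05, 0.02)), "waldRatio")
})

test_that("IVW and Egger match lm and hand normal-equations oracles", {
  withr::with_seed(51, {
    for (rep in 1:200) {
      k <- sample(3:20, 1)
      bx <- runif(k, -0.3, 0.3)
      by <- 0.4 * bx + rnorm(k, 0, 0.05)
      sey <- runif(k, 0.01, 0.1)
      h <- HarmonizedSet(sprintf("v%d", 1:k), bx, rep(0.01, k), by, sey)
      w <- 1 / sey^2
      expect_equal(mrIvw(h)@b, unname(oracle_wls(bx, by, w, intercept = FALSE)))
      # Egger fits on the orientation with all exposure effects positive
      s <- sign(bx)
      fit <- oracle_wls(abs(bx), s * by, w, intercept = TRUE)
      eg <- mrEgger(h)
      expect_equal(eg@eggerIntercept, unname(fit[1]))
      expect_equal(eg@b, unname(fit[2]))
    }
  })
})

test_that("Egger recovers exact-fit slopes and directional intercepts", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  h_exact <- HarmonizedSet(paste0("v", 1:4), bx, rep(0.01, 4), 0.3 * bx,
                           rep(0.02, 4))
  e <- mrEgger(h_exact)
  expect_equal(e@b, 0.3)
  expect_equal(e@eggerIntercept, 0, tolerance = 1e-12)
  h_pleio <- HarmonizedSet(paste0("v", 1:4), bx, rep(0.01, 4),
                           0.02 + 0.3 * bx, rep(0.02, 4))
  e2 <- mrEgger(h_pleio)
  expect_equal(e2@b, 0.3)
  expect_equal(e2@eggerIntercept, 0.02)
  expect_error(mrEgger(make_hset(2, 1)), ">=3")
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights, middle value
  h3 <- HarmonizedSet(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                      c(0.1, 0.5, 0.9), rep(0.02, 3))
  expect_equal(weightedMedian(h3, nBoot = 0, seed = 1)@b, 0.5)
  # even count, equal weights: interpolation lands midway
  h4 <- HarmonizedSet(paste0("v", 1:4), rep(1, 4), rep(0.01, 4),
                      c(0.1, 0.4, 0.6, 0.9), rep(0.02, 4))
  expect_equal(weightedMedian(h4, nBoot = 0, seed = 1)@b, 0.5)
})

test_that("weighted median matches the hand interpolation oracle", {
  withr::with_seed(52, {
    for (rep in 1:200) {
      k <- sample(3:15, 1)
      bx <- runif(k, 0.05, 0.4)
      by <- rnorm(k, 0.3 * bx, 0.05)
      sey <- runif(k, 0.01, 0.1)
      h <- HarmonizedSet(sprintf("v%d", 1:k), bx, rep(0.01, k), by, sey)
      expect_equal(weightedMedian(h, nBoot = 0, seed = 1)@b,
                   oracle_weighted_median(by / bx, bx^2 / sey^2))
    }
  })
})

test_that("weighted median shrugs off one wild outlier", {
  est <- err <- numeric(30)
  for (i in 1:30) {
    h <- make_hset(11, seed = 600 + i, slope = 0.5)
    by <- betaY(h)
    by[4] <- by[4] + 1  # 50-SE outlier
    hh <- HarmonizedSet(variantIds(h), betaX(h), seX(h), by, seY(h))
    e <- weightedMedian(hh, nBoot = 200, seed = 1)
    est[i] <- e@b
    err[i] <- abs(e@b - 0.5) <= 2 * e@se
  }
  expect_gte(mean(err), 0.9)
})

test_that("mode estimate finds the dominant ratio cluster", {
  h <- HarmonizedSet(paste0("v", 1:4), rep(1, 4), rep(0.01, 4),
                     c(0.5, 0.5, 0.5, 2.0), rep(0.02, 4))
  expect_equal(modeEstimate(h, weighted = FALSE, nBoot = 0, seed = 1)@b, 0.5,
               tolerance = 0.02)
  # degenerate bandwidth: all ratios identical
  h_same <- HarmonizedSet(paste0("v", 1:3), rep(1, 3), rep(0.01, 3),
                          rep(0.7, 3), rep(0.02, 3))
  expect_equal(modeEstimate(h_same, nBoot = 0, seed = 1)@b, 0.7)
})

test_that("mode argmax matches a dense-grid density scan", {
  withr::with_seed(53, {
    for (rep in 1:50) {
      k <- sample(5:15, 1)
      bx <- runif(k, 0.05, 0.4)
      by <- rnorm(k, 0.3 * bx, 0.03)
      sey <- runif(k, 0.01, 0.1)
      h <- HarmonizedSet(sprintf("v%d", 1:k), bx, rep(0.01, k), by, sey)
      for (wt in c(TRUE, FALSE)) {
        w <- if (wt) {
          ww <- bx^2 / sey^2
          ww / sum(ww)
        } else rep(1 / k, k)
        theta <- by / bx
        spread <- min(sd(theta), IQR(theta) / 1.349)
        bw <- 0.9 * spread * k^(-1 / 5)
        spacing <- (diff(range(theta)) + 6 * bw) / 511
        expect_lt(abs(modeEstimate(h, weighted = wt, nBoot = 0, seed = 1)@b -
                        oracle_mode(theta, w)), spacing)
      }
    }
  })
})

test_that("Cochran's Q: homogeneity gives zero, hand case reproduces", {
  h <- HarmonizedSet(paste0("v", 1:3), c(0.1, 0.2, 0.4), rep(0.01, 3),
                     0.5 * c(0.1, 0.2, 0.4), rep(0.02, 3))
  qq <- cochranQ(h, 0.5)
  expect_equal(qq$q, 0)
  expect_equal(qq$pvalue, 1)
  # k = 2, ratios 0 and 1, unit weights, evaluated at 0.5
  h2 <- HarmonizedSet(c("a", "b"), c(1, 1), rep(0.01, 2), c(0, 1), c(1, 1))
  expect_equal(cochranQ(h2, 0.5)$q, 0.5)
})

test_that("leave-one-out delegates to the IVW on each reduced set", {
  h <- make_hset(3, seed = 55)
  loo <- leaveOneOut(h)
  expect_identical(nrow(loo), 4L)
  for (j in 1:3)
    expect_equal(loo$b[j], mrIvw(.h <- HarmonizedSet(
      variantIds(h)[-j], betaX(h)[-j], seX(h)[-j], betaY(h)[-j],
      seY(h)[-j]))@b)
  # homogeneous sets keep all LOO estimates near the full estimate
  hh <- make_hset(14, seed = 56, slope = 0.5)
  loo2 <- leaveOneOut(hh)
  full <- loo2[loo2$excluded == "(full)", ]
  base_se <- sqrt(1 / sum(betaX(hh)^2 / seY(hh)^2))
  expect_true(all(abs(loo2$b[loo2$excluded != "(full)"] - full$b) <= base_se))
})

test_that("a planted outlier moves the estimate most when excluded", {
  h <- make_hset(10, seed = 57, slope = 0.5)
  by <- betaY(h)
  by[7] <- by[7] + 0.5
  hh <- HarmonizedSet(variantIds(h), betaX(h), seX(h), by, seY(h))
  loo <- leaveOneOut(hh)
  full_b <- loo$b[loo$excluded == "(full)"]
  shifts <- abs(loo$b[loo$excluded != "(full)"] - full_b)
  expect_identical(which.max(shifts), 7L)
})

test_that("estimator equivariance: scaling the exposure rescales the slope", {
  h <- make_hset(8, seed = 58)
  for (cc in c(0.5, 2, 10)) {
    hs <- HarmonizedSet(variantIds(h), cc * betaX(h), cc * seX(h),
                        betaY(h), seY(h))
    expect_equal(mrIvw(hs)@b, mrIvw(h)@b / cc)
    expect_equal(mrEgger(hs)@b, mrEgger(h)@b / cc)
    expect_equal(weightedMedian(hs, nBoot = 0, seed = 1)@b,
                 weightedMedian(h, nBoot = 0, seed = 1)@b / cc)
    expect_equal(modeEstimate(hs, nBoot = 0, seed = 1)@b,
                 modeEstimate(h, nBoot = 0, seed = 1)@b / cc,
                 tolerance = 1e-6)
  }
})

test_that("all estimators are invariant to joint per-variant sign flips", {
  withr::with_seed(59, {
    for (rep in 1:10) {
      h <- make_hset(9, seed = 590 + rep)
      flip <- sample(c(-1, 1), 9, replace = TRUE)
      hf <- HarmonizedSet(variantIds(h), flip * betaX(h), seX(h),
                          flip * betaY(h), seY(h))
      expect_equal(mrIvw(hf)@b, mrIvw(h)@b)
      expect_equal(mrEgger(hf)@b, mrEgger(h)@b)
      expect_equal(weightedMedian(hf, nBoot = 0, seed = 1)@b,
                   weightedMedian(h, nBoot = 0, seed = 1)@b)
      expect_equal(modeEstimate(hf, nBoot = 0, seed = 1)@b,
                   modeEstimate(h, nBoot = 0, seed = 1)@b)
    }
  })
})

test_that("mrSummary emits the published five-row table with odds columns", {
  h <- make_hset(14, seed = 60, slope = 0.5)
  tab <- resultTable(mrSummary(h, seed = 3, nBoot = 100))
  expect_identical(names(tab),
                   c("Method", "nsnp", "b", "se", "pval", "or", "or_lci95",
                     "or_uci95", "P-heterogeneity", "P-pleiotropy"))
  expect_identical(tab$Method,
                   c("Inverse variance weighted", "MR Egger",
                     "Weighted median", "Weighted mode", "Simple mode"))
  expect_true(all(tab$nsnp == 14))
  expect_equal(tab$or, exp(tab$b))
  expect_equal(tab$or_lci95, exp(tab$b - 1.96 * tab$se))
  expect_equal(tab$or_uci95, exp(tab$b + 1.96 * tab$se))
  expect_true(all(tab$or_lci95 <= tab$or & tab$or <= tab$or_uci95))
  # heterogeneity attaches to IVW and Egger rows, pleiotropy to Egger
  expect_false(is.na(tab$`P-heterogeneity`[1]))
  expect_false(is.na(tab$`P-pleiotropy`[2]))
})

test_that("odds conversion reproduces null and boundary behavior", {
  e0 <- MREstimate("x", 3L, 0, 0.5, 1)
  expect_equal(e0@orval, 1)
  expect_equal(sprintf("%.2f", e0@orval), "1.00")
})
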