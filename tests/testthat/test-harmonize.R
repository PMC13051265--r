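ex1 <- make_ss(list(ss_row("rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.10)))

test_that("swapped alleles flip the other cohort's effect and frequency", {
  out <- make_ss(list(ss_row("rs1", ea = "G", oa = "A", eaf = 0.30,
                             beta = -0.05, se = 0.02)), type = "binary")
  h <- harmonize(ex1, out)
  expect_equal(betaY(h), 0.05)
  expect_equal(betaX(h), 0.10)
})

test_that("strand complements align, with and without a swap", {
  same <- make_ss(list(ss_row("rs1", ea = "T", oa = "C", beta = 0.07)))
  h <- harmonize(ex1, same)
  expect_equal(betaY(h), 0.07)
  swapped <- make_ss(list(ss_row("rs1", ea = "C", oa = "T", beta = 0.07)))
  h2 <- harmonize(ex1, swapped)
  expect_equal(betaY(h2), -0.07)
})

test_that("irreconcilable allele pairs drop with an explicit reason", {
  bad <- make_ss(list(ss_row("rs1", ea = "A", oa = "C")))
  h0 <- harmonize(ex1, bad)
  expect_identical(nVariants(h0), 0L)
  expect_identical(droppedVariants(h0)$reason, "allele mismatch")
  two <- make_ss(list(ss_row("rs1", ea = "A", oa = "G"), ss_row("rs2")))
  bad2 <- make_ss(list(ss_row("rs1", ea = "A", oa = "C"), ss_row("rs2")))
  h <- harmonize(two, bad2)
  expect_identical(variantIds(h), "rs2")
  expect_true(any(droppedVariants(h)$reason == "allele mismatch"))
})

test_that("palindromic variants follow the configured policy", {
  pal_ex <- make_ss(list(ss_row("rs1", ea = "A", oa = "T", eaf = 0.20),
                         ss_row("rs2", ea = "C", oa = "G", eaf = 0.50),
                         ss_row("rs3", ea = "A", oa = "G", eaf = 0.30)))
  pal_out <- make_ss(list(ss_row("rs1", ea = "A", oa = "T", eaf = 0.80,
                                 beta = 0.04),
                          ss_row("rs2", ea = "C", oa = "G", eaf = 0.50,
                                 beta = 0.02),
                          ss_row("rs3", ea = "A", oa = "G", beta = 0.01)))
  # drop policy: both palindromes removed
  hd <- harmonize(pal_ex, pal_out, palindromePolicy = "drop")
  expect_identical(variantIds(hd), "rs3")
  expect_setequal(droppedVariants(hd)$reason[droppedVariants(hd)$variant_id
                                             %in% c("rs1", "rs2")],
                  "palindromic")
  # infer_by_eaf: rs1 frequencies disagree on the minor allele -> flip;
  # rs2 sits at 0.5 -> ambiguous
  hi <- harmonize(pal_ex, pal_out, palindromePolicy = "infer_by_eaf",
                  eafTolerance = 0.08)
  expect_setequal(variantIds(hi), c("rs1", "rs3"))
  expect_equal(betaY(hi)[variantIds(hi) == "rs1"], -0.04)
  expect_identical(
    droppedVariants(hi)$reason[droppedVariants(hi)$variant_id == "rs2"],
    "ambiguous palindrome")
})

test_that("harmonization is idempotent on aligned inputs", {
  ex <- make_ss(list(ss_row("rs1", ea = "A", oa = "G", beta = 0.1),
                     ss_row("rs2", ea = "T", oa = "C", beta = -0.2,
                            eaf = 0.6)))
  out <- make_ss(list(ss_row("rs1", ea = "G", oa = "A", beta = 0.05,
                             eaf = 0.7),
                      ss_row("rs2", ea = "C", oa = "T", beta = 0.08,
                             eaf = 0.4)))
  h1 <- harmonize(ex, out)
  # rebuild the outcome on the aligned orientation and harmonize again
  aligned <- make_ss(list(ss_row("rs1", ea = "A", oa = "G",
                                 beta = betaY(h1)[1], eaf = 0.3),
                          ss_row("rs2", ea = "T", oa = "C",
                                 beta = betaY(h1)[2], eaf = 0.6)))
  h2 <- harmonize(ex, aligned)
  expect_equal(betaY(h2), betaY(h1))
  expect_equal(betaX(h2), betaX(h1))
})

test_that("mediator cohort harmonizes alongside the outcome", {
  med <- make_ss(list(ss_row("rs1", ea = "G", oa = "A", beta = -0.3,
                             se = 0.05)))
  out <- make_ss(list(ss_row("rs1", ea = "A", oa = "G", beta = 0.02)))
  h <- harmonize(ex1, out, mediator = med)
  expect_true(hasMediator(h))
  expect_equal(betaM(h), 0.3)
  expect_equal(seM(h), 0.05)
})

test_that("orientToInhibition sign-flips tuples jointly and drops nulls", {
  h <- HarmonizedSet(c("a", "b", "c"),
                     betaX = c(-0.02, 0.03, 0), seX = rep(0.01, 3),
                     betaY = c(0.03, 0.05, 0.01), seY = rep(0.02, 3),
                     betaM = c(0.1, -0.2, 0.3), seM = rep(0.05, 3))
  o <- orientToInhibition(h)
  expect_equal(betaX(o), c(0.02, 0.03))
  expect_equal(betaY(o), c(-0.03, 0.05))
  expect_equal(betaM(o), c(-0.1, -0.2))
  expect_identical(
    droppedVariants(o)$reason[droppedVariants(o)$variant_id == "c"],
    "null exposure effect")
  # already-positive sets pass through unchanged
  o2 <- orientToInhibition(o)
  expect_equal(betaX(o2), betaX(o))
  expect_equal(betaY(o2), betaY(o))
})

test_that("ratio estimators are invariant to joint per-variant flips and
           negate under a whole-scale exposure flip", {
  h <- make_hset(8, seed = 21)
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  h_flip <- HarmonizedSet(variantIds(h), flip * betaX(h), seX(h),
                          flip * betaY(h), seY(h))
  expect_equal(mrIvw(h_flip)@b, mrIvw(h)@b)
  # negating every exposure effect reverses the exposure scale
  h_neg <- HarmonizedSet(variantIds(h), -betaX(h), seX(h), betaY(h), seY(h))
  expect_equal(mrIvw(h_neg)@b, -mrIvw(h)@b)
})
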