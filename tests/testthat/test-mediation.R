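test_that("BH step-up: worked example, single test identity, cap at one", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04), qMax = 0.05)
  expect_true(all(r$rejected))  # largest i with p_(i) <= i*0.05/4 is i = 4
  expect_equal(r$q_values, c(0.04, 0.04, 0.04, 0.04))
  one <- bhFdr(0.2, qMax = 0.1)
  expect_equal(one$q_values, 0.2)
  expect_false(one$rejected)
  expect_length(bhFdr(numeric(0))$q_values, 0)
})

test_that("BH q-values equal the definition-based double-loop oracle", {
  withr::with_seed(91, {
    for (rep in 1:100) {
      p <- runif(sample(1:40, 1))
      r <- bhFdr(p)
      expect_equal(r$q_values, oracle_bh(p))
      # monotone in p order
      o <- order(p)
      expect_true(all(diff(r$q_values[o]) >= -1e-15))
    }
  })
})

test_that("two-step mediation arithmetic matches the published worked case", {
  m <- twoStepMediation(log(3.01), log(0.79), -1.16)
  expect_equal(round(100 * m@proportion, 1), 22.4)
  expect_identical(m@indirect, m@beta1 * m@beta2)
  expect_identical(m@beta3Direct, m@total - m@indirect)
  # no mediation and complete mediation
  expect_equal(twoStepMediation(0.5, 0, -1)@proportion, 0)
  expect_equal(twoStepMediation(0.5, 0.3, 0.15)@proportion, 1)
  expect_error(twoStepMediation(0.1, 0.1, 0), "undefined proportion")
})

test_that("proportion mediated is invariant to rescaling the exposure", {
  m1 <- twoStepMediation(0.5, 0.3, 0.6)
  for (cc in c(0.1, 2, 7)) {
    # rescaling the exposure scales beta1 and the total identically
    m2 <- twoStepMediation(0.5 * cc, 0.3, 0.6 * cc)
    expect_equal(m2@proportion, m1@proportion)
  }
})

test_that("delta-method SE appears only when variances are supplied", {
  m <- twoStepMediation(0.5, 0.3, 0.6, var1 = 0.04, var2 = 0.01)
  expect_equal(m@seIndirect, sqrt(0.3^2 * 0.04 + 0.5^2 * 0.01))
  expect_true(is.na(twoStepMediation(0.5, 0.3, 0.6)@seIndirect))
})

test_that("panel screen: estimates, q-values and both significance rules", {
  hlist <- list(
    strong = make_hset(5, seed = 92, slope = 1.2, sey = 0.01),
    null1 = make_hset(5, seed = 93, slope = 0, sey = 0.05),
    single = make_hset(1, seed = 94, slope = 0.8, sey = 0.01),
    null2 = make_hset(4, seed = 95, slope = 0, sey = 0.05))
  sc <- screenPanel(hlist, "metabolite_to_outcome")
  rows <- resultTable(sc)
  expect_identical(rows$name[1], "strong")
  expect_true(all(diff(rows$pvalue) >= 0))       # sorted by p
  expect_equal(rows$q_value, bhFdr(rows$pvalue)$q_values)
  expect_identical(rows$n_snp[rows$name == "single"], 1L)  # Wald ratio path
  # single-metabolite panel: q equals p
  sc1 <- screenPanel(hlist["strong"], "metabolite_to_outcome")
  expect_equal(resultTable(sc1)$q_value, resultTable(sc1)$pvalue)
  # fdr rule flags via q
  scf <- screenPanel(hlist, "metabolite_to_outcome", rule = "fdr")
  rf <- resultTable(scf)
  expect_identical(rf$significant, rf$q_value <= 0.10)
})

test_that("metabolites without instruments are excluded with a message", {
  empty <- HarmonizedSet(character(0), numeric(0), numeric(0), numeric(0),
                         numeric(0))
  hlist <- list(ok = make_hset(4, seed = 96, slope = 0.5), bad = empty)
  expect_message(sc <- screenPanel(hlist, "exposure_to_metabolite"),
                 "zero instruments")
  expect_identical(resultTable(sc)$name, "ok")
})

test_that("FDR screening controls the realized false-discovery proportion", {
  # panel of 60 metabolites, 10 causal, 30 reps
  fdp <- vapply(1:30, function(rep) {
    hlist <- lapply(1:60, function(i)
      make_hset(6, seed = rep * 1000 + i,
                slope = if (i <= 10) 0.8 else 0, sey = 0.02))
    names(hlist) <- sprintf("m%02d", 1:60)
    rows <- resultTable(screenPanel(hlist, "metabolite_to_outcome",
                                    rule = "fdr", qMax = 0.10))
    hit <- rows$name[rows$significant]
    if (length(hit) == 0) return(0)
    mean(as.integer(sub("m", "", hit)) > 10)
  }, numeric(1))
  expect_lte(mean(fdp), 0.15)
})

test_that("a null panel flags about alpha of metabolites under the nominal rule", {
  counts <- vapply(1:10, function(rep) {
    hlist <- lapply(1:100, function(i)
      make_hset(5, seed = rep * 500 + i, slope = 0, sey = 0.05))
    names(hlist) <- sprintf("m%03d", 1:100)
    sum(resultTable(screenPanel(hlist, "metabolite_to_outcome",
                                rule = "nominal"))$significant)
  }, numeric(1))
  # expected 5 per 100 tests at alpha = 0.05
  expect_gt(mean(counts), 1)
  expect_lt(mean(counts), 12)
})
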