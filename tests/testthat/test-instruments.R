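cis_stats <- function() {
  rows <- list(
    ss_row("edge_lo", chrom = "16", pos = 31244323L, pvalue = 1e-4),
    ss_row("edge_p", chrom = "16", pos = 31500000L, pvalue = 1e-3),
    ss_row("inside", chrom = "16", pos = 31500000L, pvalue = 5e-4),
    ss_row("outside", chrom = "16", pos = 31752091L, pvalue = 1e-8),
    ss_row("wrong_chr", chrom = "2", pos = 31500000L, pvalue = 1e-8))
  make_ss(rows)
}

test_that("cis window is closed and the p threshold strict", {
  got <- selectCisVariants(cis_stats(), "16", 31494323L, 31502090L,
                           windowBp = 250000L, pMax = 1e-3)
  # lower boundary variant retained; p = 1e-3 excluded; window is closed
  expect_identical(got, c("edge_lo", "inside"))
})

test_that("cis selection matches a double-loop oracle on random data", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 100
      d <- do.call(rbind, lapply(seq_len(n), function(i)
        ss_row(sprintf("v%03d", i),
               chrom = sample(c("16", "2"), 1),
               pos = sample.int(2e6, 1), pvalue = runif(1))))
      s <- SummaryStats(d)
      got <- selectCisVariants(s, "16", 9e5, 1.1e6, windowBp = 2e5,
                               pMax = 0.3)
      expect_identical(got, oracle_cis(d, "16", 7e5, 1.3e6, 0.3))
    }
  })
})

test_that("biomarker filter keeps strictly sub-threshold candidates in order", {
  bio <- make_ss(list(ss_row("a", pvalue = 9.9e-5), ss_row("b", pvalue = 1e-4),
                      ss_row("c", pvalue = 1e-9)))
  expect_identical(filterByBiomarker(c("c", "a", "b"), bio, 1e-4), c("c", "a"))
  expect_message(got <- filterByBiomarker(c("a", "zz"), bio, 1e-4),
                 "absent from biomarker")
  expect_identical(got, "a")
})

test_that("clumping removes r2 > threshold within the window, keeping lowest p", {
  s <- make_ss(list(ss_row("lead", chrom = "1", pos = 1000L, pvalue = 1e-8),
                    ss_row("tag", chrom = "1", pos = 2000L, pvalue = 1e-6)))
  make_ld <- function(r12) {
    LDMatrix(matrix(c(1, r12, r12, 1), 2), c("lead", "tag"))
  }
  expect_identical(
    clumpVariants(s, ld = make_ld(sqrt(0.81)), r2Max = 0.8, windowBp = 250000),
    "lead")
  both <- clumpVariants(s, ld = make_ld(sqrt(0.79)), r2Max = 0.8,
                        windowBp = 250000)
  expect_setequal(both, c("lead", "tag"))
  # outside the window LD is irrelevant
  s2 <- make_ss(list(ss_row("lead", chrom = "1", pos = 1000L, pvalue = 1e-8),
                     ss_row("tag", chrom = "1", pos = 600000L, pvalue = 1e-6)))
  expect_setequal(
    clumpVariants(s2, ld = make_ld(0.99), r2Max = 0.8, windowBp = 250000),
    c("lead", "tag"))
})

test_that("missing LD pairs in window are treated as r2 = 1 and logged", {
  s <- make_ss(list(ss_row("a", chrom = "1", pos = 1000L, pvalue = 1e-8),
                    ss_row("b", chrom = "1", pos = 2000L, pvalue = 1e-6)))
  ld <- LDMatrix(matrix(1, 1, 1), "a")
  expect_message(got <- clumpVariants(s, ld = ld, r2Max = 0.8,
                                      windowBp = 250000),
                 "treated as r2 = 1")
  expect_identical(got, "a")
})

test_that("clumping equals the brute-force greedy oracle on random inputs", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      n <- 20
      ids <- sprintf("v%02d", seq_len(n))
      d <- do.call(rbind, lapply(seq_len(n), function(i)
        ss_row(ids[i], chrom = "1", pos = i * 40000L, pvalue = runif(1))))
      s <- SummaryStats(d)
      a <- matrix(runif(n * n, -1, 1), n)
      r <- (a + t(a)) / 2
      diag(r) <- 1
      ld <- LDMatrix(r, ids)
      got <- clumpVariants(s, ld = ld, r2Max = 0.3, windowBp = 200000)
      expect_identical(got, oracle_clump(d$variant_id, d$pvalue, d$chrom,
                                         d$pos, ld@r, 0.3, 200000))
    }
  })
})

test_that("F statistics follow (beta/se)^2 with a strict strength flag", {
  h <- HarmonizedSet(c("a", "b"), betaX = c(0.1, 0.0316228),
                     seX = c(0.025, 0.01), betaY = c(0, 0),
                     seY = c(1, 1))
  f <- fStatistics(h)
  expect_equal(f$f[1], 16)
  expect_equal(f$f[2], 10, tolerance = 1e-4)
  expect_identical(f$strong, f$f > 10)  # strict > defines the flag
  # invariance under joint sign flips
  h2 <- HarmonizedSet(c("a", "b"), betaX = -h@betaX, seX = h@seX,
                      betaY = h@betaY, seY = h@seY)
  expect_equal(fStatistics(h2)$f, f$f)
})

test_that("simulated drug-target instruments are uniformly strong (F > 16)", {
  for (seed in 1:5) {
    sim <- simulateMediationGwas(simConfig(seed = seed))
    ids <- names(sim$truth@gamma)
    h <- harmonize(subsetVariants(sim$exposure, ids), sim$outcome)
    expect_true(all(fStatistics(h)$f > 16))
  }
})

test_that("metabolite instrument selection applies the fallback cascade", {
  make_met <- function(pvals) {
    rows <- lapply(seq_along(pvals), function(i)
      ss_row(sprintf("m%02d", i), chrom = "1", pos = i * 2e7,
             pvalue = pvals[i], beta = 0.2, se = 0.02))
    make_ss(rows, trait = "met")
  }
  ld <- LDMatrix(diag(6), sprintf("m%02d", 1:6))
  # five independent genome-wide hits: primary threshold suffices
  s5 <- make_met(rep(1e-9, 5))
  is5 <- selectMetaboliteInstruments(s5, ld)
  expect_identical(nVariants(is5), 5L)
  expect_identical(selectionLog(is5)$note[selectionLog(is5)$step ==
                                          "threshold_used"], "primary")
  # two genome-wide, two suggestive: fallback recruits to >= 3
  s4 <- make_met(c(1e-9, 1e-8, 2e-7, 3e-7))
  is4 <- selectMetaboliteInstruments(s4, ld)
  expect_gte(nVariants(is4), 3L)
  expect_identical(selectionLog(is4)$note[selectionLog(is4)$step ==
                                          "threshold_used"], "fallback")
  # nothing below the fallback threshold at all
  expect_error(selectMetaboliteInstruments(make_met(c(0.1, 0.2)), ld),
               "no valid instruments")
  # a single instrument proceeds with a warning
  expect_warning(is1 <- selectMetaboliteInstruments(make_met(c(1e-9, 0.5)), ld),
                 "proceeding")
  expect_identical(nVariants(is1), 1L)
})

test_that("metabolite selection equals filter + clump oracle composition", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      n <- 15
      ids <- sprintf("m%02d", seq_len(n))
      d <- do.call(rbind, lapply(seq_len(n), function(i)
        ss_row(ids[i], chrom = "1", pos = i * 1e6,
               pvalue = 10^runif(1, -12, -5))))
      s <- SummaryStats(d)
      a <- matrix(runif(n * n, -0.9, 0.9), n)
      r <- (a + t(a)) / 2
      diag(r) <- 1
      ld <- LDMatrix(r, ids)
      got <- suppressWarnings(
        selectMetaboliteInstruments(s, ld, r2Max = 0.1, windowBp = 1e7))
      thr <- if (length(oracle_clump(
        d$variant_id[d$pvalue < 5e-8], d$pvalue[d$pvalue < 5e-8],
        d$chrom[d$pvalue < 5e-8], d$pos[d$pvalue < 5e-8],
        ld@r, 0.1, 1e7)) >= 3) 5e-8 else 5e-7
      keep <- d$pvalue < thr
      expected <- oracle_clump(d$variant_id[keep], d$pvalue[keep],
                               d$chrom[keep], d$pos[keep], ld@r, 0.1, 1e7)
      expect_identical(variantIds(got), expected)
    }
  })
})
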