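test_that("direction-bias test is the exact two-sided binomial", {
  # frozen against independent tail enumeration: sum(choose(9, 8:9))/2^9 * 2
  expect_equal(directionBiasTest(8, 9), 2 * sum(choose(9, 8:9)) / 2^9)
  expect_equal(round(directionBiasTest(8, 9), 3), 0.039)
  expect_equal(directionBiasTest(15, 20),
               2 * sum(choose(20, 15:20)) / 2^20)
  expect_equal(round(directionBiasTest(15, 20), 4), 0.0414)
  # symmetric split is not evidence
  expect_equal(directionBiasTest(10, 20), 1)
  # two-sided symmetry, extremes, range
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(1:40, 1); k <- sample(0:n, 1)
    p <- directionBiasTest(k, n)
    expect_equal(p, directionBiasTest(n - k, n))
    expect_true(p > 0 && p <= 1)
    expect_equal(p, binom.test(k, n)$p.value, tolerance = 1e-12)
  }
  expect_equal(directionBiasTest(0, 6), min(1, 2 * 2^-6))
})

test_that("geometric-mean OR comparison uses paired log-scale t", {
  g <- gmeanOrCompare(c(2, 8), c(2, 8))
  expect_equal(g$gmean_central, 4)
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)

  set.seed(52)
  oc <- exp(rnorm(20, 0.3, 0.2))
  os <- oc * exp(rnorm(20, 0.08, 0.1))
  g2 <- gmeanOrCompare(oc, os)
  expect_equal(g2$gmean_southern, exp(mean(log(os))))
  expect_equal(g2$gsd_central, exp(sd(log(oc))))
  d <- log(os) - log(oc)
  expect_equal(g2$t, mean(d) / (sd(d) / sqrt(20)))
  expect_equal(g2$p, t.test(log(os), log(oc), paired = TRUE)$p.value)
  expect_error(gmeanOrCompare(c(1, -1), c(1, 1)), "positive")
})

test_that("risk-allele sums count dosages and impute expected values", {
  m <- dosageMatrix(c(2L, 0L, 2L, 0L, 1L, 1L),
                    c(2L, 0L, NA, 0L, 0L, 2L),
                    markers = c("snpA", "snpB"))
  sm <- toySamples(6, status = c("case", "case", "case",
                                 "control", "control", "control"))
  sm$sample_id <- rownames(m)
  ge <- GenotypeExperiment(m, toyMarkers(c("snpA", "snpB")), sm)
  # control RAF of snpB = (0+0+2)/6 = 1/3 -> imputed dosage 2/3
  rs <- riskAlleleSum(ge, c("snpA", "snpB"), maxMissing = 0.5)
  expect_equal(rs$sum[rs$sample_id == "s03"], 2 + 2 / 3)
  # complete subjects keep integer sums, invariant to SNP order
  expect_equal(rs$sum[rs$sample_id == "s01"], 4)
  rs2 <- riskAlleleSum(ge, c("snpB", "snpA"), maxMissing = 0.5)
  expect_equal(rs2$sum, rs$sum)
  # missing > cap excludes the subject with a warning
  expect_warning(rs3 <- riskAlleleSum(ge, c("snpA", "snpB"),
                                      maxMissing = 0.2), "excluding")
  expect_false("s03" %in% rs3$sample_id)
  # stated example: one missing SNP at collection control RAF 25% -> 0.5
  m4 <- dosageMatrix(c(NA, 1L, 0L, 0L, 1L))
  sm4 <- toySamples(5, status = c("case", rep("control", 4)))
  sm4$sample_id <- rownames(m4)
  g4 <- GenotypeExperiment(m4, toyMarkers("rs1"), sm4)
  r4 <- riskAlleleSum(g4, "rs1", maxMissing = 1)
  expect_equal(r4$sum[1], 0.5)
  # upper bound: homozygous risk everywhere
  nm <- 20
  mm <- matrix(2L, 2, nm, dimnames = list(c("s01", "s02"),
                                          paste0("rs", 1:nm)))
  gub <- GenotypeExperiment(mm, toyMarkers(paste0("rs", 1:nm)),
                            toySamples(2))
  expect_equal(riskAlleleSum(gub, paste0("rs", 1:nm))$sum,
               c(40, 40), ignore_attr = TRUE)
})

test_that("risk-allele summary contrasts groups with Student t", {
  set.seed(53)
  sums <- data.frame(
    sample_id = sprintf("s%03d", 1:200),
    collection_id = rep(c("N", "S"), each = 100),
    status = rep(rep(c("case", "control"), each = 50), 2),
    sum = c(rnorm(50, 14.4), rnorm(50, 12.8), rnorm(50, 14.0),
            rnorm(50, 12.0)))
  part <- c(N = "central", S = "southern")
  sm <- riskAlleleSummary(sums, part)
  cc <- sm$case_control$central
  tt <- t.test(sums$sum[sums$status == "case" & sums$collection_id == "N"],
               sums$sum[sums$status == "control" &
                          sums$collection_id == "N"], var.equal = TRUE)
  expect_equal(cc$p, tt$p.value)
  expect_equal(cc$diff, unname(diff(rev(tt$estimate))))
  expect_true(cc$ci_low < cc$diff && cc$diff < cc$ci_high)
})

test_that("GRS is the dosage-weighted sum of subgroup log ORs", {
  m <- dosageMatrix(c(2L, 1L), c(0L, 2L), c(1L, 1L),
                    markers = c("snpA", "snpB", "snpC"))
  sm <- toySamples(2, collection = c("N", "S"), status = "case")
  sm$sample_id <- rownames(m)
  ge <- GenotypeExperiment(m, toyMarkers(c("snpA", "snpB", "snpC")), sm)
  part <- c(N = "central", S = "southern")
  oc <- c(snpA = 1.2, snpB = 1.5, snpC = 2.0)
  os <- c(snpA = 1.4, snpB = 1.1, snpC = exp(1))
  g <- grsScore(ge, names(oc), oc, os, part)
  # hand sums: subject 1 (central) 2*ln1.2 + 0 + ln2; subject 2 (southern)
  expect_equal(g$scores$grs,
               c(2 * log(1.2) + log(2), log(1.4) + 2 * log(1.1) + 1))
  # single SNP with OR = e and dosage 2 scores exactly 2
  g1 <- grsScore(ge, "snpA", c(snpA = exp(1)), c(snpA = exp(1)), part)
  expect_equal(g1$scores$grs[1], 2)
  # all ORs 1: zero for everyone
  ones <- setNames(rep(1, 3), names(oc))
  expect_equal(grsScore(ge, names(oc), ones, ones, part)$scores$grs,
               c(0, 0))
  # linearity: squaring ORs doubles the score
  expect_equal(grsScore(ge, names(oc), oc^2, os^2, part)$scores$grs,
               2 * g$scores$grs)
  expect_error(grsScore(ge, c("snpA", "snpX"), oc, os, part), "snpX")
})

test_that("weighted Pearson reduces to plain correlation and matches
           hand-computed weighted moments", {
  set.seed(54)
  x <- rnorm(8); y <- 0.6 * x + rnorm(8, 0, 0.4)
  wp <- weightedPearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(wp$r, unname(ct$estimate))
  expect_equal(wp$p, ct$p.value)
  # exact linearity
  expect_equal(weightedPearson(x, 2 * x + 3)$r2, 1)
  # 5-point fixture with weights (2,1,1,1,1): direct weighted moments
  xf <- c(1, 2, 3, 4, 5); yf <- c(2.2, 2.8, 3.1, 4.4, 4.6)
  w <- c(2, 1, 1, 1, 1)
  mx <- sum(w * xf) / sum(w); my <- sum(w * yf) / sum(w)
  r_hand <- sum(w * (xf - mx) * (yf - my)) /
    sqrt(sum(w * (xf - mx)^2) * sum(w * (yf - my)^2))
  expect_equal(weightedPearson(xf, yf, w)$r, r_hand)
  expect_error(weightedPearson(x, rep(1, 8)), "zero variance")
  expect_error(weightedPearson(x[1:2], y[1:2]), "3 collections")
})

test_that("cline analysis recovers exact linear clines and flat nulls", {
  # 5 collections whose control RAF is exactly linear in the score
  set.seed(55)
  score <- c(100, 75, 50, 25, 0)
  raf <- 30 + 0.12 * score          # +12 pp per 100 score units
  n <- 200
  dos <- lapply(raf, function(f) {
    c(rep(2L, round(n * (f / 100)^2)),
      rep(1L, round(n * 2 * (f / 100) * (1 - f / 100))))
  })
  dvec <- unlist(lapply(dos, function(d) c(d, rep(0L, n - length(d)))))
  m <- dosageMatrix(c(dvec, rep(1L, 50)))
  coll <- c(rep(paste0("C", 1:5), each = n), rep(paste0("C", 1:5), 10))
  stat <- c(rep("control", 5 * n), rep("case", 50))
  sm <- data.frame(sample_id = rownames(m), collection_id = coll,
                   status = stat, sex = "female")
  ge <- GenotypeExperiment(m, toyMarkers("rs1"), sm)
  ns <- data.frame(collection_id = paste0("C", 1:5), score = score)
  part <- setNames(c("central", "central", "southern", "southern",
                     "southern"), paste0("C", 1:5))
  cl <- clineAnalysis(ge, part, ns, snpSet = "rs1")
  expect_equal(cl$slope, 12, tolerance = 0.05)
  expect_gt(cl$r_xy, 0.99)
  expect_lt(cl$chisq_p, 0.05)

  # flat frequencies: slope 0, r undefined-free, chi-squared p = 1
  m2 <- dosageMatrix(rep(c(0L, 1L, 1L, 2L), 50))
  coll2 <- rep(paste0("C", 1:5), each = 40)
  sm2 <- data.frame(sample_id = rownames(m2), collection_id = coll2,
                    status = rep(c("control", "case"), 100), sex = "female")
  ge2 <- GenotypeExperiment(m2, toyMarkers("rs1"), sm2)
  cl2 <- clineAnalysis(ge2, part, ns, snpSet = "rs1")
  expect_equal(cl2$slope, 0)
  expect_equal(cl2$chisq_p, 1)
})

test_that("bias report counts direction, tests per-SNP differences and
           is deterministic", {
  ac <- data.frame(marker_id = c("a", "b", "c"), or = c(1.2, 1.5, 1.1),
                   se_lnor = c(0.1, 0.1, 0.1))
  as_ <- data.frame(marker_id = c("a", "b", "c"), or = c(1.4, 1.5, 1.3),
                    se_lnor = c(0.1, 0.1, 0.1))
  rp <- biasReport(ac, as_)
  expect_equal(rp$k_southern_larger, 2)
  expect_equal(rp$n_compared, 2)      # the tie is excluded
  expect_equal(rp$binomial_p, directionBiasTest(2, 2))
  z <- (log(1.4) - log(1.2)) / sqrt(0.02)
  expect_equal(rp$per_snp$z[rp$per_snp$marker_id == "a"], z)
  # identical inputs: no signal
  rp0 <- biasReport(ac, ac)
  expect_equal(rp0$k_southern_larger, 0)
  expect_equal(rp0$n_compared, 0)
  expect_true(is.na(rp0$binomial_p))
  expect_error(biasReport(ac, as_[1:2, ]), "different SNP sets")
})
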