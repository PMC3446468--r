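test_that("strata are allele-count tables per collection", {
  # 2 cases with dosages {2,1}, 2 controls {0,1}: a=3,b=1,c=1,d=3
  m <- dosageMatrix(c(2L, 1L, 0L, 1L))
  sm <- toySamples(4, status = c("case", "case", "control", "control"))
  sm$sample_id <- rownames(m)
  ge <- GenotypeExperiment(m, toyMarkers("rs1"), sm)
  st <- buildStrata(ge, "rs1")
  expect_equal(st[, c("a", "b", "c", "d")],
               data.frame(a = 3, b = 1, c = 1, d = 3))

  # x_linked marker: males never enter the table
  mk <- toyMarkers("rs1", chromosome_type = "x_linked")
  sm$sex <- c("female", "male", "female", "male")
  gx <- GenotypeExperiment(dosageMatrix(c(2L, 1L, 0L, 1L)), mk, sm)
  sx <- buildStrata(gx, "rs1")
  expect_equal(sx$n, 4)  # 2 females x 2 copies
  expect_equal(sx$a, 2)

  # all-missing collection is dropped with a warning
  m2 <- dosageMatrix(c(2L, 1L, NA, NA))
  sm2 <- toySamples(4, collection = rep(c("A", "B"), each = 2),
                    status = rep(c("case", "control"), 2))
  sm2$sample_id <- rownames(m2)
  gd <- GenotypeExperiment(m2, toyMarkers("rs1"), sm2)
  expect_warning(sd_ <- buildStrata(gd, "rs1"), "dropping stratum")
  expect_equal(sd_$collection_id, "A")
})

test_that("Mantel-Haenszel reduces to ad/bc on one stratum and pools as
           the ratio of cross-product sums", {
  one <- data.frame(collection_id = "A", a = 20, b = 10, c = 10, d = 20,
                    n = 60)
  mh <- mantelHaenszel(one)
  expect_equal(mh$association$or, 4)
  expect_equal(mh$association$method, "single_stratum")

  # balanced strata give OR exactly 1
  bal <- data.frame(collection_id = c("A", "B"),
                    a = c(10, 30), b = c(20, 15), c = c(10, 30),
                    d = c(20, 15), n = c(60, 90))
  expect_equal(mantelHaenszel(bal)$association$or, 1)

  # hand-evaluated two-stratum pooling
  two <- data.frame(collection_id = c("A", "B"),
                    a = c(10, 30), b = c(20, 10), c = c(5, 20),
                    d = c(25, 10), n = c(60, 70))
  or <- (10 * 25 / 60 + 30 * 10 / 70) / (20 * 5 / 60 + 10 * 20 / 70)
  expect_equal(mantelHaenszel(two)$association$or, or)

  # MH OR lies between the per-stratum extremes
  set.seed(31)
  for (rep in 1:25) {
    st <- randomStrata(sample(2:6, 1))
    ors <- st$a * st$d / (st$b * st$c)
    expect_gte(mantelHaenszel(st)$association$or, min(ors) - 1e-12)
    expect_lte(mantelHaenszel(st)$association$or, max(ors) + 1e-12)
  }
})

test_that("MH estimate, CI and p agree with the stratified oracles", {
  set.seed(32)
  st <- randomStrata(5)
  mh <- mantelHaenszel(st)
  arr <- array(0, c(2, 2, 5))
  for (i in 1:5) arr[, , i] <- matrix(c(st$a[i], st$c[i], st$b[i],
                                        st$d[i]), 2)
  mt <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(mh$association$or, unname(mt$estimate), tolerance = 1e-10)
  expect_equal(mh$association$p, mt$p.value, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  rm <- metafor::rma.mh(ai = st$a, bi = st$b, ci = st$c, di = st$d,
                        measure = "OR", correct = FALSE)
  expect_equal(log(mh$association$or), unname(rm$beta[1]),
               tolerance = 1e-10)
  expect_equal(mh$association$ci_low, exp(rm$ci.lb), tolerance = 1e-8)
  expect_equal(mh$association$ci_high, exp(rm$ci.ub), tolerance = 1e-8)
})

test_that("random-effects pooling follows DerSimonian-Laird", {
  # identical strata: tau2 = 0 and RE equals fixed inverse-variance
  same <- data.frame(collection_id = c("A", "B", "C"),
                     a = 20, b = 10, c = 10, d = 20, n = 60)
  re <- randomEffectsMeta(same)
  expect_equal(re$tau2, 0)
  expect_equal(re$association$or, 4, tolerance = 1e-12)

  # single stratum: that stratum's OR and Wald CI
  one <- data.frame(collection_id = "A", a = 20, b = 10, c = 10, d = 20,
                    n = 60)
  r1 <- randomEffectsMeta(one)
  expect_equal(r1$association$or, 4)
  expect_equal(r1$association$method, "single_stratum")
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(r1$association$ci_high, exp(log(4) + qnorm(0.975) * se))

  skip_if_not_installed("metafor")
  set.seed(33)
  for (rep in 1:10) {
    st <- randomStrata(sample(3:7, 1))
    re <- randomEffectsMeta(st)
    rm <- metafor::rma(ai = st$a, bi = st$b, ci = st$c, di = st$d,
                       measure = "OR", method = "DL", add = 0, to = "none")
    expect_equal(log(re$association$or), unname(rm$beta[1]),
                 tolerance = 1e-10)
    expect_equal(re$tau2, rm$tau2, tolerance = 1e-10)
    expect_equal(re$heterogeneity$q, rm$QE, tolerance = 1e-10)
    expect_equal(re$heterogeneity$i2,
                 max(0, (rm$QE - (nrow(st) - 1)) / rm$QE) * 100,
                 tolerance = 1e-10)
  }
})

test_that("I-squared bands follow the 25/50/75 convention", {
  band_of <- function(st) mantelHaenszel(st)$heterogeneity$band
  same <- data.frame(collection_id = c("A", "B"), a = 20, b = 10,
                     c = 10, d = 20, n = 60)
  expect_equal(band_of(same), "none")
  opp <- data.frame(collection_id = c("A", "B"),
                    a = c(60, 10), b = c(10, 60), c = c(10, 60),
                    d = c(60, 10), n = 140)
  expect_equal(band_of(opp), "high")
  set.seed(34)
  for (rep in 1:20) {
    h <- mantelHaenszel(randomStrata(sample(2:6, 1)))$heterogeneity
    expect_gte(h$i2, 0); expect_lte(h$i2, 100)
    expect_identical(h$band == "none", h$i2 <= 25)
  }
})

test_that("degenerate strata raise an informative error", {
  inf <- data.frame(collection_id = "A", a = 10, b = 0, c = 0, d = 10,
                    n = 20)
  expect_error(mantelHaenszel(inf), "degenerate")
})

test_that("HWE chi-squared matches hand-computed components", {
  # exact HWE proportions: chi2 = 0, p = 1
  expect_equal(hweTest(25, 50, 25)$p, 1)
  # (40,20,40) vs expected (25,50,25): components 9 + 18 + 9 = 36
  h <- hweTest(40, 20, 40)
  expect_equal(h$chisq, 36)
  expect_lt(h$p, 1e-8)
  # monomorphic: flagged, no test
  hm <- hweTest(0, 0, 50)
  expect_true(hm$monomorphic)
  expect_equal(hm$p, 1)
})

test_that("allelic chi-squared matches direct evaluation and scales", {
  tab <- matrix(c(40, 20, 60, 80), 2)
  res <- allelicChisq(tab)
  expect_equal(res$chisq, 200 * (40 * 80 - 60 * 20)^2 /
                 (100 * 100 * 60 * 140), tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
  # equal frequencies: p = 1
  expect_equal(allelicChisq(matrix(c(30, 30, 70, 70), 2))$p, 1)
  # doubling all cells preserves the OR but strengthens the evidence
  expect_lt(allelicChisq(2 * tab)$p, res$p)
  expect_error(allelicChisq(matrix(c(0, 0, 10, 10), 2)), "zero margin")
})

test_that("conditional independence adjusts within collections", {
  set.seed(41)
  n <- 400
  coll <- rep(c("A", "B"), each = n / 2)
  b <- rbinom(n, 2, 0.4)
  a <- rbinom(n, 2, 0.3)          # independent of b
  eta <- -1 + 0.8 * a
  y <- rbinom(n, 1, plogis(eta))
  m <- cbind(snpA = a, snpB = b)
  rownames(m) <- sprintf("s%03d", 1:n)
  sm <- data.frame(sample_id = rownames(m), collection_id = coll,
                   status = ifelse(y == 1, "case", "control"),
                   sex = "female")
  ge <- GenotypeExperiment(m, toyMarkers(c("snpA", "snpB")), sm)
  res <- conditionalIndependence(ge, "snpA", "snpB")
  expect_true(res$converged)
  # orthogonal adjustment barely moves the estimate
  un <- glm(y ~ a + factor(coll), binomial())
  expect_equal(res$estimate, unname(coef(un)["a"]), tolerance = 0.05)
  expect_lt(res$p, 0.01)

  # duplicated marker: collinearity error
  m2 <- cbind(snpA = a, snpB = a)
  rownames(m2) <- rownames(m)
  ge2 <- GenotypeExperiment(m2, toyMarkers(c("snpA", "snpB")), sm)
  expect_error(conditionalIndependence(ge2, "snpA", "snpB"), "collinear")
})

test_that("conditional LR statistic matches a coarse likelihood scan", {
  set.seed(42)
  n <- 200
  b <- rbinom(n, 2, 0.5)
  a <- rbinom(n, 2, 0.35)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * a + 0.3 * b))
  m <- cbind(snpA = a, snpB = b)
  rownames(m) <- sprintf("s%03d", 1:n)
  sm <- data.frame(sample_id = rownames(m), collection_id = "A",
                   status = ifelse(y == 1, "case", "control"),
                   sex = "female")
  ge <- GenotypeExperiment(m, toyMarkers(c("snpA", "snpB")), sm)
  res <- conditionalIndependence(ge, "snpA", "snpB")
  # brute-force maximum over a parameter grid (coarse pass, then a fine
  # pass around the coarse optimum), independent of glm
  ll <- function(b0, b1, b2) {
    eta <- b0 + b1 * a + b2 * b
    sum(y * eta - log1p(exp(eta)))
  }
  scan <- function(g0, g1, g2) {
    best <- c(-Inf, NA, NA, NA)
    for (b0 in g0) for (b1 in g1) for (b2 in g2) {
      v <- ll(b0, b1, b2)
      if (v > best[1]) best <- c(v, b0, b1, b2)
    }
    best
  }
  maxll <- function(g1) {
    coarse <- scan(seq(-2, 1, 0.1), g1, seq(-1, 1.5, 0.1))
    fine_g1 <- if (length(g1) == 1) g1 else
      seq(coarse[3] - 0.1, coarse[3] + 0.1, 0.01)
    scan(seq(coarse[2] - 0.1, coarse[2] + 0.1, 0.01), fine_g1,
         seq(coarse[4] - 0.1, coarse[4] + 0.1, 0.01))[1]
  }
  lr_oracle <- 2 * (maxll(seq(0, 1.5, 0.1)) - maxll(0))
  expect_equal(res$lr, lr_oracle, tolerance = 0.02)
})
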