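#' Per-collection 2x2 allele-count strata for one risk SNP
#'
#' Builds, for each collection, the allele-count table
#' `a` (risk-allele copies in cases), `b` (other-allele copies in cases),
#' `c` (risk in controls), `d` (other in controls). Autosomal subjects and
#' X-linked females contribute two allele copies; for X-linked markers the
#' table is restricted to females (males are hemizygous and a mixed-sex
#' allele table would conflate dosage scales). Missing dosages contribute
#' nothing. Strata with zero total are dropped with a warning.
#'
#' @param x a [GenotypeExperiment].
#' @param marker a risk-SNP id.
#' @param collections optional subset of collection ids; default all.
#' @return data.frame with columns `collection_id, a, b, c, d, n`.
#' @export
buildStrata <- function(x, marker, collections = NULL) {
  i <- .markerIndex(x, marker)
  if (rowData(x)$role[i] != "risk_snp")
    stop("'", marker, "' is not a risk SNP")
  .strataFromVector(dosages(x)[i, ], colData(x),
                    rowData(x)$chromosome_type[i] == "x_linked",
                    collections, marker)
}

.strataFromVector <- function(d, cd, xlinked, collections, marker) {
  use <- !is.na(d)
  if (xlinked) use <- use & cd$sex == "female"
  colls <- if (is.null(collections)) sort(unique(cd$collection_id))
           else collections
  if (!length(colls)) stop("empty collection set")
  is_case <- cd$status == "case"
  a <- b <- cc_ <- dd <- numeric(length(colls))
  for (k in seq_along(colls)) {
    in_cc <- use & cd$collection_id == colls[k]
    nca <- sum(in_cc & is_case); nco <- sum(in_cc & !is_case)
    a[k] <- sum(d[in_cc & is_case]); b[k] <- 2 * nca - a[k]
    cc_[k] <- sum(d[in_cc & !is_case]); dd[k] <- 2 * nco - cc_[k]
  }
  out <- data.frame(collection_id = colls, a = a, b = b, c = cc_, d = dd,
                    n = a + b + cc_ + dd, stringsAsFactors = FALSE)
  if (any(out$n == 0)) {
    warning("dropping stratum with no data for '", marker, "': ",
            paste(out$collection_id[out$n == 0], collapse = ", "))
    out <- out[out$n > 0, , drop = FALSE]
  }
  if (!nrow(out)) stop("no usable stratum for '", marker, "'")
  rownames(out) <- NULL
  out
}

# Per-stratum log odds ratios and variances for heterogeneity and
# random-effects pooling. Zero-cell policy: a stratum containing any zero
# cell gets 0.5 added to every cell (Haldane-Anscombe); strata with a zero
# margin are dropped.
.strataEffects <- function(strata) {
  m <- as.matrix(strata[, c("a", "b", "c", "d")])
  storage.mode(m) <- "double"
  margin_ok <- (m[, 1] + m[, 2]) > 0 & (m[, 3] + m[, 4]) > 0 &
               (m[, 1] + m[, 3]) > 0 & (m[, 2] + m[, 4]) > 0
  m <- m[margin_ok, , drop = FALSE]
  if (!nrow(m)) stop("no stratum with positive margins")
  zero <- rowSums(m == 0) > 0
  m[zero, ] <- m[zero, , drop = FALSE] + 0.5
  lnor <- log(m[, 1] * m[, 4] / (m[, 2] * m[, 3]))
  v <- rowSums(1 / m)
  data.frame(collection_id = strata$collection_id[margin_ok],
             lnor = lnor, v = v, row.names = NULL)
}

.heterogeneity <- function(eff) {
  k <- nrow(eff)
  w <- 1 / eff$v
  ybar <- sum(w * eff$lnor) / sum(w)
  q <- sum(w * (eff$lnor - ybar)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  band <- if (i2 > 75) "high" else if (i2 > 50) "moderate"
          else if (i2 > 25) "low" else "none"
  list(q = q, df = df, i2 = i2, band = band)
}

.assocRow <- function(or, lo, hi, p, method, se) {
  data.frame(or = or, ci_low = lo, ci_high = hi, p = p, method = method,
             se_lnor = se, stringsAsFactors = FALSE)
}

#' Mantel-Haenszel fixed-effect meta-analysis of 2x2 strata
#'
#' Pooled odds ratio `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`
#' (sporadic zero cells are handled natively, no correction), 95% CI from
#' the Robins-Breslow-Greenland variance of `ln OR_MH`, p-value from the
#' 1-df Mantel-Haenszel chi-squared statistic (no continuity correction),
#' and heterogeneity (Cochran Q, I-squared with the 25/50/75 bands) from
#' the per-stratum log odds ratios.
#'
#' @param strata data.frame from [buildStrata] (columns `a, b, c, d`).
#' @return list with `association` (one-row data.frame: `or`, `ci_low`,
#'   `ci_high`, `p`, `method`, `se_lnor`) and `heterogeneity`
#'   (`q`, `df`, `i2`, `band`).
#' @export
mantelHaenszel <- function(strata) {
  m <- as.matrix(strata[, c("a", "b", "c", "d")])
  storage.mode(m) <- "double"
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (!nrow(m)) stop("no usable stratum")
  n <- rowSums(m)
  R_i <- m[, 1] * m[, 4] / n
  S_i <- m[, 2] * m[, 3] / n
  R <- sum(R_i); S <- sum(S_i)
  if (S == 0 || R == 0)
    stop("Mantel-Haenszel OR degenerate (", if (S == 0) "infinite" else "zero",
         "): every stratum has an empty off-diagonal; counts a,d = ",
         sum(m[, 1]), ",", sum(m[, 4]), " b,c = ", sum(m[, 2]), ",",
         sum(m[, 3]))
  or <- R / S
  # Robins-Breslow-Greenland variance of ln OR_MH
  P_i <- (m[, 1] + m[, 4]) / n
  Q_i <- (m[, 2] + m[, 3]) / n
  v <- sum(P_i * R_i) / (2 * R^2) +
       sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
       sum(Q_i * S_i) / (2 * S^2)
  se <- sqrt(v)
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  # Mantel-Haenszel chi-squared (1 df, continuity-uncorrected)
  r1 <- m[, 1] + m[, 2]; r2 <- m[, 3] + m[, 4]
  c1 <- m[, 1] + m[, 3]; c2 <- m[, 2] + m[, 4]
  expa <- r1 * c1 / n
  vara <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  vara[n <= 1] <- 0
  chi2 <- (sum(m[, 1]) - sum(expa))^2 / sum(vara)
  p <- pchisq(chi2, 1, lower.tail = FALSE)
  method <- if (nrow(m) == 1) "single_stratum" else "mantel_haenszel"
  het <- .heterogeneity(.strataEffects(strata))
  list(association = .assocRow(or, ci[1], ci[2], p, method, se),
       heterogeneity = het)
}

#' DerSimonian-Laird random-effects meta-analysis of 2x2 strata
#'
#' Inverse-variance pooling of per-stratum log odds ratios with the
#' moment-based DerSimonian-Laird between-stratum variance tau-squared;
#' weights `1/(v_i + tau2)`, Wald CI and p. When `Q <= df` (tau2 = 0) the
#' result coincides with fixed-effect inverse-variance pooling. Zero-cell
#' policy as in [mantelHaenszel] heterogeneity: 0.5 added to all cells of
#' a stratum containing a zero; zero-margin strata dropped.
#'
#' @inheritParams mantelHaenszel
#' @return list with `association`, `heterogeneity` and `tau2`.
#' @export
randomEffectsMeta <- function(strata) {
  eff <- .strataEffects(strata)
  het <- .heterogeneity(eff)
  w <- 1 / eff$v
  tau2 <- if (nrow(eff) > 1)
    max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (eff$v + tau2)
  mu <- sum(ws * eff$lnor) / sum(ws)
  se <- sqrt(1 / sum(ws))
  ci <- exp(mu + c(-1, 1) * qnorm(0.975) * se)
  p <- 2 * pnorm(-abs(mu / se))
  method <- if (nrow(eff) == 1) "single_stratum" else "random_effects"
  list(association = .assocRow(exp(mu), ci[1], ci[2], p, method, se),
       heterogeneity = het, tau2 = tau2)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' 1-df Pearson chi-squared test of observed genotype counts against the
#' p^2 / 2pq / q^2 expectation under the sample allele-frequency estimate.
#' Intended for control samples of a single collection (autosomal, or
#' female-only X-linked counts). A monomorphic marker admits no test and
#' returns p = 1 with `monomorphic = TRUE`.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote for the counted
#'   allele, heterozygote, other homozygote).
#' @return list with `p`, `chisq`, `df = 1` and `monomorphic`.
#' @export
hweTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n < 1) stop("no genotypes")
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1)
    return(list(p = 1, chisq = 0, df = 1, monomorphic = TRUE))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
  list(p = pchisq(chi2, 1, lower.tail = FALSE), chisq = chi2, df = 1,
       monomorphic = FALSE)
}

#' Allelic 2x2 Pearson chi-squared test
#'
#' 1-df Pearson chi-squared, no continuity correction, on a 2x2 table of
#' allele counts (rows = groups, columns = risk/other allele).
#'
#' @param tab 2x2 numeric matrix.
#' @return list with `p` and `chisq`.
#' @export
allelicChisq <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(p = ct$p.value, chisq = unname(ct$statistic))
}

#' Conditional independence of two associated SNPs
#'
#' Does `markerA` still carry association after adjusting for `markerB`?
#' Realised as a pooled additive-dosage logistic regression of case status
#' on `markerB` plus collection indicator terms, with a likelihood-ratio
#' test for adding `markerA` (within-collection adjustment, equivalent in
#' target to a stratified conditional analysis and simple to verify by
#' brute force). Only collections containing both cases and controls
#' enter. Perfectly collinear dosages raise an error; non-convergence or
#' separation is flagged.
#'
#' @param x a [GenotypeExperiment].
#' @param markerA SNP being tested.
#' @param markerB SNP conditioned on.
#' @return list with `p` (LR test, 1 df), `lr`, `estimate` (log-odds per
#'   `markerA` allele in the full model) and `converged`.
#' @export
conditionalIndependence <- function(x, markerA, markerB) {
  d <- dosages(x)
  da <- d[.markerIndex(x, markerA), ]
  db <- d[.markerIndex(x, markerB), ]
  cd <- colData(x)
  ok <- !is.na(da) & !is.na(db)
  tab <- table(cd$collection_id[ok], cd$status[ok])
  good_coll <- rownames(tab)[tab[, "case"] > 0 & tab[, "control"] > 0]
  ok <- ok & cd$collection_id %in% good_coll
  if (sum(ok) < 4) stop("too few complete samples")
  da <- da[ok]; db <- db[ok]
  if (sd(da) == 0 || sd(db) == 0 || abs(cor(da, db)) == 1)
    stop("collinear dosages: '", markerA, "' and '", markerB, "'")
  dat <- data.frame(y = as.integer(cd$status[ok] == "case"),
                    a = da, b = db,
                    coll = factor(cd$collection_id[ok]))
  converged <- TRUE
  withCallingHandlers({
    f0 <- if (nlevels(dat$coll) > 1) y ~ b + coll else y ~ b
    m0 <- glm(f0, binomial(), dat)
    m1 <- glm(update(f0, . ~ a + .), binomial(), dat)
  }, warning = function(w) {
    converged <<- FALSE
    invokeRestart("muffleWarning")
  })
  if (!m0$converged || !m1$converged) converged <- FALSE
  lr <- as.numeric(m0$deviance - m1$deviance)
  list(p = pchisq(lr, 1, lower.tail = FALSE), lr = lr,
       estimate = unname(coef(m1)["a"]), converged = converged)
}
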