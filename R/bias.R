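#' Exact binomial test for direction bias of subgroup effect sizes
#'
#' Of `n` loci, `k` show the larger odds ratio in one subgroup. Under no
#' systematic bias each locus falls either way with probability 1/2, so
#' the two-sided exact p-value is twice the smaller binomial tail, capped
#' at 1: `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with
#' `X ~ Binomial(n, 1/2)`. Loci with exactly equal subgroup ORs are ties
#' and must be excluded from `n` by the caller.
#'
#' @param k number of loci with the larger effect in the focal subgroup.
#' @param n number of non-tied loci.
#' @return the two-sided exact p-value.
#' @export
directionBiasTest <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Geometric-mean odds-ratio comparison between subgroups
#'
#' The geometric mean `exp(mean(ln OR))` of each subgroup's per-SNP odds
#' ratios, a geometric SD factor `exp(sd(ln OR))` as the dispersion, and a
#' paired two-sided Student t test on the per-SNP differences of log odds
#' ratios. ORs must be paired by SNP and strictly positive.
#'
#' @param orCentral,orSouthern positive numeric vectors of per-SNP odds
#'   ratios, paired by position.
#' @return list with `gmean_central`, `gsd_central`, `gmean_southern`,
#'   `gsd_southern`, `t`, `df`, `p`.
#' @export
gmeanOrCompare <- function(orCentral, orSouthern) {
  if (length(orCentral) != length(orSouthern))
    stop("OR vectors must be paired by SNP")
  if (any(orCentral <= 0) || any(orSouthern <= 0))
    stop("odds ratios must be positive")
  lc <- log(orCentral); ls <- log(orSouthern)
  d <- ls - lc
  n <- length(d)
  sdd <- if (n > 1) sd(d) else NA_real_
  if (!is.na(sdd) && sdd == 0) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- mean(d) / (sdd / sqrt(n))
    p <- 2 * pt(-abs(tt), n - 1)
  }
  list(gmean_central = exp(mean(lc)), gsd_central = exp(sd(lc)),
       gmean_southern = exp(mean(ls)), gsd_southern = exp(sd(ls)),
       t = tt, df = n - 1, p = p)
}

# expected-dosage imputation values: collection-control RAF (as fraction)
# for every marker in `snpSet`, markers x collections
.controlRafMatrix <- function(x, snpSet) {
  d <- dosages(x)
  cd <- colData(x)
  xl <- setNames(rowData(x)$chromosome_type == "x_linked", rownames(x))
  colls <- unique(cd$collection_id)
  out <- matrix(NA_real_, length(snpSet), length(colls),
                dimnames = list(snpSet, colls))
  for (cc in colls) {
    sel <- cd$collection_id == cc & cd$status == "control"
    for (m in snpSet) {
      ct <- .freqCounts(d[m, ], cd$sex, xl[[m]], sel)
      if (ct[["total"]] > 0)
        out[m, cc] <- ct[["counted"]] / ct[["total"]]
    }
  }
  out
}

.imputeExpected <- function(x, d, snpSet) {
  if (!anyNA(d)) return(d)
  cd <- colData(x)
  ri <- markerInfo(x)
  raf <- .controlRafMatrix(x, snpSet)
  for (m in snpSet) {
    nas <- is.na(d[m, ])
    if (!any(nas)) next
    mult <- if (ri$chromosome_type[ri$marker_id == m] == "x_linked")
      ifelse(cd$sex == "male", 1, 2) else rep(2, ncol(x))
    d[m, nas] <- mult[nas] * raf[m, cd$collection_id[nas]]
  }
  d
}

#' Per-subject sum of risk alleles
#'
#' Sum of counted-allele dosages over a SNP set. Missing dosages are, by
#' default, replaced by their expected value given the subject's
#' collection: `2 x RAF` of the collection's controls (`1 x RAF` for
#' X-linked males). Subjects missing more than `maxMissing` of the SNP set
#' are excluded with a warning. With complete data the sum is an integer
#' between 0 and `2 x #autosomal + {1,2} x #X-linked` (by sex).
#'
#' @param x a [GenotypeExperiment].
#' @param snpSet character vector of risk-SNP ids.
#' @param imputePolicy `"expected"` (default) or `"none"` (missing
#'   dosages propagate `NA`).
#' @param maxMissing maximum tolerated missing fraction per subject
#'   (default 0.2).
#' @return data.frame with `sample_id`, `collection_id`, `status`, `sex`,
#'   `sum`, `n_missing`.
#' @export
riskAlleleSum <- function(x, snpSet, imputePolicy = c("expected", "none"),
                          maxMissing = 0.2) {
  imputePolicy <- match.arg(imputePolicy)
  ri <- markerInfo(x)
  if (!all(snpSet %in% ri$marker_id[ri$role == "risk_snp"]))
    stop("snpSet must be risk SNPs: ",
         paste(setdiff(snpSet, ri$marker_id[ri$role == "risk_snp"]),
               collapse = ", "))
  d <- dosages(x)[snpSet, , drop = FALSE]
  cd <- colData(x)
  dimp <- if (imputePolicy == "expected") .imputeExpected(x, d, snpSet)
          else d
  n_missing <- colSums(is.na(d))
  sums <- colSums(dimp)
  out <- data.frame(sample_id = colnames(x),
                    collection_id = cd$collection_id,
                    status = cd$status, sex = cd$sex,
                    sum = sums, n_missing = n_missing,
                    row.names = NULL, stringsAsFactors = FALSE)
  drop <- n_missing / length(snpSet) > maxMissing
  if (any(drop)) {
    warning("excluding ", sum(drop), " subject(s) missing > ",
            round(100 * maxMissing), "% of the SNP set")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

# mean difference between two groups with normal-theory 95% CI and
# equal-variance (Student) two-sided t test
.groupDiff <- function(a, b) {
  na <- length(a); nb <- length(b)
  diff <- mean(a) - mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- diff / se
  list(diff = diff, ci_low = diff - qnorm(0.975) * se,
       ci_high = diff + qnorm(0.975) * se,
       t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), na + nb - 2))
}

#' Summaries of risk-allele sums by status and subgroup
#'
#' Group means and SDs of per-subject risk-allele sums in the four
#' status x subgroup strata, the case-minus-control difference within each
#' subgroup, and the between-subgroup (central minus southern) difference
#' within each status -- each with a normal-theory 95% CI and a two-sided
#' Student t test.
#'
#' @param sums data.frame from [riskAlleleSum].
#' @param partition named character vector mapping `collection_id` to
#'   `"central"` / `"southern"`.
#' @return list with `groups` (data.frame), `case_control` (per-subgroup
#'   list) and `between_subgroups` (per-status list).
#' @export
riskAlleleSummary <- function(sums, partition) {
  sums$subgroup <- partition[sums$collection_id]
  if (anyNA(sums$subgroup))
    stop("partition missing for collection(s): ",
         paste(unique(sums$collection_id[is.na(sums$subgroup)]),
               collapse = ", "))
  grp <- expand.grid(status = SAMPLE_STATUS,
                     subgroup = c("central", "southern"),
                     stringsAsFactors = FALSE)
  grp$mean <- grp$sd <- grp$n <- NA_real_
  for (i in seq_len(nrow(grp))) {
    v <- sums$sum[sums$status == grp$status[i] &
                  sums$subgroup == grp$subgroup[i]]
    grp$n[i] <- length(v); grp$mean[i] <- mean(v); grp$sd[i] <- sd(v)
  }
  pick <- function(st, sg) sums$sum[sums$status == st & sums$subgroup == sg]
  list(groups = grp,
       case_control = list(
         central = .groupDiff(pick("case", "central"),
                              pick("control", "central")),
         southern = .groupDiff(pick("case", "southern"),
                               pick("control", "southern"))),
       between_subgroups = list(
         control = .groupDiff(pick("control", "central"),
                              pick("control", "southern")),
         case = .groupDiff(pick("case", "central"),
                           pick("case", "southern"))))
}

#' Per-subject genetic risk score
#'
#' `GRS = sum over SNPs of ln(OR) x dosage`, where the OR for each SNP is
#' the Mantel-Haenszel OR estimated in the subject's own subgroup.
#' Missing dosages are imputed as in [riskAlleleSum]. Group means of
#' patients are compared between subgroups with a two-sided Student t
#' test. The score is linear in the log odds ratios: doubling every
#' `ln OR` doubles every subject's GRS.
#'
#' @param x a [GenotypeExperiment].
#' @param snpSet character vector of risk-SNP ids.
#' @param orCentral,orSouthern named numeric vectors of per-SNP subgroup
#'   odds ratios (names = SNP ids, all present in `snpSet`).
#' @param partition named map `collection_id -> "central"/"southern"`.
#' @param status which subjects to score (default `"case"`: patients).
#' @return list with `scores` (per-subject data.frame), `groups`
#'   (mean/sd/n per subgroup), `t`, `df`, `p`.
#' @export
grsScore <- function(x, snpSet, orCentral, orSouthern, partition,
                     status = "case") {
  for (ors in list(orCentral, orSouthern)) {
    miss <- setdiff(snpSet, names(ors))
    if (length(miss))
      stop("missing OR for SNP(s): ", paste(miss, collapse = ", "))
    if (any(ors[snpSet] <= 0)) stop("odds ratios must be positive")
  }
  cd <- colData(x)
  keep <- cd$status %in% status
  sub <- partition[cd$collection_id]
  if (anyNA(sub[keep]))
    stop("partition missing for collection(s): ",
         paste(unique(cd$collection_id[keep][is.na(sub[keep])]),
               collapse = ", "))
  d <- .imputeExpected(x, dosages(x)[snpSet, , drop = FALSE], snpSet)
  grs_c <- drop(log(orCentral[snpSet]) %*% d)
  grs_s <- drop(log(orSouthern[snpSet]) %*% d)
  grs <- ifelse(sub == "central", grs_c, grs_s)
  scores <- data.frame(sample_id = colnames(x),
                       collection_id = cd$collection_id,
                       status = cd$status, subgroup = sub, grs = grs,
                       row.names = NULL, stringsAsFactors = FALSE)
  scores <- scores[keep, , drop = FALSE]
  gc_ <- scores$grs[scores$subgroup == "central"]
  gs <- scores$grs[scores$subgroup == "southern"]
  groups <- data.frame(subgroup = c("central", "southern"),
                       n = c(length(gc_), length(gs)),
                       mean = c(mean(gc_), mean(gs)),
                       sd = c(sd(gc_), sd(gs)))
  cmp <- .groupDiff(gs, gc_)
  list(scores = scores, groups = groups, t = cmp$t, df = cmp$df, p = cmp$p)
}

#' Weighted Pearson correlation
#'
#' Correlation of two per-collection statistics using weighted means and
#' variances (weights typically the collection sample sizes); the p-value
#' uses the t transform with `n - 2` df, `n` the number of collections.
#' With equal weights it reduces to the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors (e.g. N/S score and a per-collection mean).
#' @param w positive weights; default equal.
#' @return list with `r`, `r2`, `p`, `n`.
#' @export
weightedPearson <- function(x, y, w = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(w)) w <- rep(1, n)
  if (n < 3) stop("at least 3 collections required")
  if (any(w <= 0)) stop("weights must be positive")
  cv <- cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)
  if (cv$cov[1, 1] == 0 || cv$cov[2, 2] == 0)
    stop("zero variance: correlation undefined")
  r <- cv$cor[1, 2]
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, r2 = r^2, p = 2 * pt(-abs(tt), n - 2), n = n)
}

#' Allele-frequency cline analysis in controls
#'
#' For each risk SNP, using control data only (controls are the better
#' proxy for the general population): (i) the control allele-count 2x2
#' chi-squared comparison between the central and southern subgroups;
#' (ii) the weighted Pearson correlation `r_xy` of per-collection control
#' RAF with the N/S score; (iii) the weighted least-squares slope of
#' control RAF (percent) on the N/S score scaled to `[0, 1]`, i.e.
#' percentage points per 100 score units, with its regression t-test
#' p-value. Weights default to the per-collection control counts.
#' SNPs monomorphic across collections are skipped with a note.
#'
#' @param x a [GenotypeExperiment].
#' @param partition named map `collection_id -> "central"/"southern"`.
#' @param nsScores data.frame with `collection_id` and `score`
#'   (from [nsScore]).
#' @param snpSet risk-SNP ids; default all risk SNPs.
#' @param weights optional named per-collection weights.
#' @return data.frame with one row per SNP: `marker_id`, `raf_central`,
#'   `raf_southern`, `chisq_p`, `r_xy`, `slope`, `slope_se`, `slope_p`,
#'   `note`.
#' @export
clineAnalysis <- function(x, partition, nsScores, snpSet = NULL,
                          weights = NULL) {
  ri <- markerInfo(x)
  if (is.null(snpSet)) snpSet <- ri$marker_id[ri$role == "risk_snp"]
  cd <- colData(x)
  colls <- intersect(nsScores$collection_id, unique(cd$collection_id))
  if (length(colls) < 3) stop("need at least 3 scored collections")
  score <- setNames(nsScores$score, nsScores$collection_id)[colls]
  sub <- partition[colls]
  if (anyNA(sub))
    stop("partition missing for collection(s): ",
         paste(colls[is.na(sub)], collapse = ", "))
  if (is.null(weights))
    weights <- vapply(setNames(colls, colls), function(cc)
      sum(cd$collection_id == cc & cd$status == "control"), numeric(1))
  d <- dosages(x)
  xlk <- setNames(rowData(x)$chromosome_type == "x_linked", rownames(x))
  rows <- lapply(snpSet, function(m) {
    fr <- vapply(colls, function(cc) {
      sel <- cd$collection_id == cc & cd$status == "control"
      ct <- .freqCounts(d[m, ], cd$sex, xlk[[m]], sel)
      if (ct[["total"]] == 0)
        stop("no control genotype data for '", m, "' in collection '",
             cc, "'")
      c(100 * ct[["counted"]] / ct[["total"]], ct[["counted"]],
        ct[["total"]])
    }, numeric(3))
    raf <- fr[1, ]
    cnt_c <- sum(fr[2, sub == "central"]); tot_c <- sum(fr[3, sub == "central"])
    cnt_s <- sum(fr[2, sub == "southern"]); tot_s <- sum(fr[3, sub == "southern"])
    base <- data.frame(marker_id = m,
                       raf_central = 100 * cnt_c / tot_c,
                       raf_southern = 100 * cnt_s / tot_s,
                       chisq_p = NA_real_, r_xy = NA_real_,
                       slope = NA_real_, slope_se = NA_real_,
                       slope_p = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (sd(raf) == 0) {
      base$note <- "monomorphic_or_constant"
      if (all(raf %in% c(0, 100))) base$note <- "monomorphic"
      # constant RAF: no cline; chi-squared still defined unless margin zero
      tab <- matrix(c(cnt_c, tot_c - cnt_c, cnt_s, tot_s - cnt_s), 2,
                    byrow = TRUE)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        base$chisq_p <- allelicChisq(tab)$p
        base$slope <- 0
      }
      return(base)
    }
    tab <- matrix(c(cnt_c, tot_c - cnt_c, cnt_s, tot_s - cnt_s), 2,
                  byrow = TRUE)
    base$chisq_p <- allelicChisq(tab)$p
    wp <- weightedPearson(score, raf, weights[colls])
    base$r_xy <- wp$r
    fit <- lm(raf ~ I(score / 100), weights = weights[colls])
    sm <- summary(fit)$coefficients
    base$slope <- sm[2, 1]
    base$slope_se <- sm[2, 2]
    base$slope_p <- sm[2, 4]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the effect-size-bias report
#'
#' Joins the per-subgroup association results on a shared SNP set and
#' computes the bias battery: per-SNP two-group z test on the difference
#' of log odds ratios (summed variances -- the conventional interaction
#' test, flagging SNPs whose subgroup difference is individually
#' significant), the count of SNPs with the larger southern OR (exact
#' ties excluded) with its exact binomial p, and the geometric-mean OR
#' comparison. Optional risk-allele-sum and GRS summaries are carried
#' through.
#'
#' @param assocCentral,assocSouthern data.frames with columns
#'   `marker_id`, `or`, `se_lnor` (one row per SNP; e.g. built from
#'   [mantelHaenszel] runs per subgroup).
#' @param sums optional result of [riskAlleleSummary].
#' @param grs optional result of [grsScore].
#' @param clines optional result of [clineAnalysis].
#' @param alpha significance level for the per-SNP flag (default 0.05).
#' @return list with `per_snp` (data.frame with both ORs, lnOR difference,
#'   z, p, flag), `k_southern_larger`, `n_compared`, `binomial_p`,
#'   `gmean` (from [gmeanOrCompare]) and any supplied summaries.
#' @export
biasReport <- function(assocCentral, assocSouthern, sums = NULL, grs = NULL,
                       clines = NULL, alpha = 0.05) {
  if (!setequal(assocCentral$marker_id, assocSouthern$marker_id))
    stop("subgroup association runs cover different SNP sets")
  sn <- assocSouthern[match(assocCentral$marker_id,
                            assocSouthern$marker_id), ]
  per <- data.frame(marker_id = assocCentral$marker_id,
                    or_central = assocCentral$or, or_southern = sn$or,
                    stringsAsFactors = FALSE)
  per$lnor_diff <- log(per$or_southern) - log(per$or_central)
  per$z <- per$lnor_diff /
    sqrt(assocCentral$se_lnor^2 + sn$se_lnor^2)
  per$p <- 2 * pnorm(-abs(per$z))
  per$significant <- per$p < alpha
  ties <- per$or_southern == per$or_central
  k <- sum(per$or_southern > per$or_central)
  n <- sum(!ties)
  list(per_snp = per[order(-per$or_central), ],
       k_southern_larger = k, n_compared = n,
       binomial_p = if (n >= 1) directionBiasTest(k, n) else NA_real_,
       gmean = gmeanOrCompare(per$or_central, per$or_southern),
       sums = sums, grs = grs, clines = clines)
}
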