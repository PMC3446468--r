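#' Genotypic r-squared between two markers
#'
#' Squared Pearson correlation of the dosage vectors over
#' pairwise-complete samples. This is the genotypic (composite) measure
#' of linkage disequilibrium appropriate for unphased dosage data.
#'
#' @param x a [GenotypeExperiment].
#' @param markerA,markerB marker ids.
#' @return r-squared in `[0, 1]`.
#' @export
pairwiseR2 <- function(x, markerA, markerB) {
  d <- dosages(x)
  a <- d[.markerIndex(x, markerA), ]
  b <- d[.markerIndex(x, markerB), ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2)
    stop("fewer than 2 pairwise-complete samples for '", markerA,
         "' and '", markerB, "'")
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0)
    stop("r-squared undefined: constant dosage for '",
         if (sd(a) == 0) markerA else markerB, "'")
  cor(a, b)^2
}

#' Per-collection AIM frequency table
#'
#' Counted-allele frequency (percent, all subjects -- cases and controls
#' pooled) of every AIM in every collection. This is the substrate for
#' AIM selection and for the N/S score.
#'
#' @param x a [GenotypeExperiment].
#' @param aims optional character vector of AIM ids; default every marker
#'   with role `"aim"`.
#' @return data.frame with `collection_id` and one column per AIM.
#' @export
aimFrequencyTable <- function(x, aims = NULL) {
  if (is.null(aims)) aims <- rownames(x)[rowData(x)$role == "aim"]
  if (!length(aims)) stop("no AIMs in the panel")
  d <- dosages(x)
  cd <- colData(x)
  xl <- setNames(rowData(x)$chromosome_type == "x_linked", rownames(x))
  colls <- sort(unique(cd$collection_id))
  out <- data.frame(collection_id = colls, stringsAsFactors = FALSE)
  for (a in aims) {
    out[[a]] <- vapply(colls, function(cc) {
      ct <- .freqCounts(d[a, ], cd$sex, xl[[a]], cd$collection_id == cc)
      if (ct[["total"]] == 0)
        stop("no genotype data for AIM '", a, "' in collection '", cc, "'")
      100 * ct[["counted"]] / ct[["total"]]
    }, numeric(1))
  }
  out
}

#' Pairwise r-squared matrix of the AIM panel
#'
#' @inheritParams aimFrequencyTable
#' @return symmetric matrix of genotypic r-squared values, unit diagonal.
#' @export
aimR2Matrix <- function(x, aims = NULL) {
  if (is.null(aims)) aims <- rownames(x)[rowData(x)$role == "aim"]
  k <- length(aims)
  r2 <- diag(1, k)
  dimnames(r2) <- list(aims, aims)
  if (k > 1)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      r2[i, j] <- r2[j, i] <- pairwiseR2(x, aims[i], aims[j])
  r2
}

#' Drop redundant AIMs
#'
#' Greedy pruning of an AIM panel: while any pair exceeds the r-squared
#' redundancy threshold, take the most redundant pair and drop the member
#' with the smaller across-collection frequency range (ties broken by
#' keeping the lexicographically smaller marker id). The surviving set is
#' pairwise below the threshold.
#'
#' @param r2 symmetric r-squared matrix with marker-id dimnames
#'   (e.g. from [aimR2Matrix]).
#' @param ranges named vector of across-collection frequency ranges
#'   (max - min, percentage points) used to pick the member to keep.
#' @param threshold redundancy cutoff; default 0.8 (redundant pairs in
#'   practice sit near r-squared 0.85 and independent ones below 0.03, so
#'   any cutoff well inside that gap behaves identically).
#' @return character vector of retained AIM ids.
#' @export
pruneRedundantAims <- function(r2, ranges, threshold = 0.8) {
  keep <- rownames(r2)
  if (is.null(keep)) stop("r2 matrix must have marker-id dimnames")
  repeat {
    m <- r2[keep, keep, drop = FALSE]
    diag(m) <- 0
    if (!length(m) || max(m) <= threshold) break
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    pair <- c(keep[ij[1]], keep[ij[2]])
    ra <- ranges[pair]
    drop <- if (ra[1] == ra[2]) max(pair) else pair[which.min(ra)]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Case-control AIM comparison per collection
#'
#' For each collection and each AIM, compares case and control allele
#' frequencies in a 2x2 allele-count table with a 1-df Pearson chi-squared
#' test (no continuity correction). A collection is flagged for exclusion
#' when any AIM differs at `alpha` -- the quality-control step that guards
#' against case-control ancestry mismatch within a recruitment centre.
#' AIMs monomorphic in a collection (zero margin) are skipped with a
#' warning.
#'
#' @param x a [GenotypeExperiment].
#' @param alpha significance level for the exclusion flag; default 0.05,
#'   per-test with no multiplicity adjustment.
#' @param aims optional AIM subset.
#' @return list with `pvalues` (data.frame: collection_id, marker_id, p)
#'   and `exclude` (named logical per collection).
#' @export
aimCaseControlCheck <- function(x, alpha = 0.05, aims = NULL) {
  if (is.null(aims)) aims <- rownames(x)[rowData(x)$role == "aim"]
  d <- dosages(x)
  cd <- colData(x)
  xl <- setNames(rowData(x)$chromosome_type == "x_linked", rownames(x))
  colls <- sort(unique(cd$collection_id))
  rows <- list()
  for (cc in colls) {
    in_cc <- cd$collection_id == cc
    if (!any(in_cc & cd$status == "case") ||
        !any(in_cc & cd$status == "control"))
      stop("collection '", cc, "' lacks cases or controls")
    for (a in aims) {
      fc <- .freqCounts(d[a, ], cd$sex, xl[[a]], in_cc & cd$status == "case")
      fk <- .freqCounts(d[a, ], cd$sex, xl[[a]],
                        in_cc & cd$status == "control")
      tab <- matrix(c(fc[["counted"]], fc[["total"]] - fc[["counted"]],
                      fk[["counted"]], fk[["total"]] - fk[["counted"]]),
                    2, byrow = TRUE)
      p <- if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
        warning("AIM '", a, "' monomorphic in collection '", cc,
                "'; skipped")
        NA_real_
      } else {
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(collection_id = cc, marker_id = a, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  pv <- do.call(rbind, rows)
  excl <- vapply(colls, function(cc) {
    p <- pv$p[pv$collection_id == cc]
    any(!is.na(p) & p < alpha)
  }, logical(1))
  list(pvalues = pv, exclude = excl)
}

#' Select the most informative non-redundant AIMs
#'
#' "Informative" is operationalised as the across-collection frequency
#' range (max - min): an AIM that swings widely along the axis separates
#' collections well, and the measure is scale-free. Ties are broken by
#' lexicographic marker id for determinism.
#'
#' @param freqTable per-collection AIM frequency table
#'   (from [aimFrequencyTable] or supplied).
#' @param k number of AIMs to select (default 3).
#' @param keep optional character vector of non-redundant candidates
#'   (e.g. from [pruneRedundantAims]); default all columns.
#' @return character vector of `k` AIM ids, ordered by decreasing range.
#' @export
selectInformativeAims <- function(freqTable, k = 3, keep = NULL) {
  aims <- setdiff(colnames(freqTable), "collection_id")
  if (!is.null(keep)) aims <- intersect(aims, keep)
  if (length(aims) < k)
    stop("only ", length(aims), " candidate AIM(s) for k = ", k)
  ranges <- vapply(aims, function(a)
    diff(range(freqTable[[a]])), numeric(1))
  aims[order(-ranges, aims)][seq_len(k)]
}

#' North/South axis score per collection
#'
#' Each AIM frequency column (oriented to the Northern-common allele) is
#' min-max rescaled across collections to 0--100% -- 0 where the allele is
#' least abundant, 100 where it is most abundant -- and the rescaled values
#' are averaged into a single per-collection score. A collection at the
#' maximum on every AIM scores 100, one at the minimum scores 0; the score
#' is invariant under any affine transformation applied uniformly to an
#' AIM's raw frequencies.
#'
#' @param freqTable data.frame with `collection_id` and one frequency
#'   column per informative AIM.
#' @return data.frame with `collection_id`, `score` and one
#'   `rescaled_<aim>` column per AIM; the min/max reference frequencies
#'   are attached as attribute `"limits"`.
#' @export
nsScore <- function(freqTable) {
  aims <- setdiff(colnames(freqTable), "collection_id")
  if (nrow(freqTable) < 2) stop("at least 2 collections required")
  if (!length(aims)) stop("no AIM frequency columns")
  out <- data.frame(collection_id = freqTable$collection_id,
                    stringsAsFactors = FALSE)
  limits <- data.frame(marker_id = aims, min = NA_real_, max = NA_real_)
  resc <- matrix(NA_real_, nrow(freqTable), length(aims))
  for (i in seq_along(aims)) {
    f <- freqTable[[aims[i]]]
    lo <- min(f); hi <- max(f)
    if (hi == lo)
      stop("degenerate AIM '", aims[i], "': identical frequency in all ",
           "collections")
    resc[, i] <- (f - lo) / (hi - lo) * 100
    limits$min[i] <- lo; limits$max[i] <- hi
  }
  out$score <- rowMeans(resc)
  colnames(resc) <- paste0("rescaled_", aims)
  out <- cbind(out, as.data.frame(resc))
  attr(out, "limits") <- limits
  out
}
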