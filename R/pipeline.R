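.defaultThresholds <- function() {
  list(aim_alpha = 0.05, r2_threshold = 0.8, alpha = 0.05,
       max_missing = 0.2, n_aims = 3)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration and checks it as a whole,
#' collecting every violation rather than stopping at the first. A valid
#' configuration names either a simulation source (`simulate:
#' paper_like: true`) or the three input TSVs (`inputs: genotypes /
#' markers / samples`), an output directory, a seed, a
#' `collection -> subgroup` partition map (optional when simulating:
#' the generating configuration supplies it), optional `thresholds`
#' (`aim_alpha`, `r2_threshold`, `alpha`, `max_missing`, `n_aims`),
#' `exclude_snps`, `battery_override` and `conditional_pairs` (list of
#' `[candidate, conditioned_on]` SNP pairs).
#'
#' @param path path to a YAML file, or an already-parsed list.
#' @return the validated configuration list (invisibly errors with the
#'   aggregated message otherwise).
#' @export
validateConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  errs <- character()
  has_sim <- !is.null(cfg$simulate) || inherits(cfg$sim_config, "sim_config")
  has_inp <- !is.null(cfg$inputs)
  if (!has_sim && !has_inp)
    errs <- c(errs, "either 'simulate' or 'inputs' must be given")
  if (has_inp) {
    for (f in c("genotypes", "markers", "samples")) {
      if (is.null(cfg$inputs[[f]]))
        errs <- c(errs, paste0("inputs$", f, " is required"))
      else if (!file.exists(cfg$inputs[[f]]))
        errs <- c(errs, paste0("inputs$", f, ": file not found: ",
                               cfg$inputs[[f]]))
    }
    if (is.null(cfg$partition))
      errs <- c(errs, "partition map is required for file inputs")
  }
  th <- utils::modifyList(.defaultThresholds(),
                          if (is.null(cfg$thresholds)) list()
                          else cfg$thresholds)
  for (nm in c("aim_alpha", "alpha"))
    if (!is.numeric(th[[nm]]) || th[[nm]] < 0 || th[[nm]] > 1)
      errs <- c(errs, paste0("thresholds$", nm, " must lie in [0, 1]"))
  if (!is.numeric(th$r2_threshold) || th$r2_threshold < 0 ||
      th$r2_threshold > 1)
    errs <- c(errs, "thresholds$r2_threshold must lie in [0, 1]")
  if (!is.numeric(th$max_missing) || th$max_missing < 0 ||
      th$max_missing >= 1)
    errs <- c(errs, "thresholds$max_missing must lie in [0, 1)")
  if (!is.numeric(th$n_aims) || th$n_aims < 1)
    errs <- c(errs, "thresholds$n_aims must be a positive count")
  if (!is.null(cfg$partition)) {
    bad <- !unlist(cfg$partition) %in% c("central", "southern")
    if (any(bad))
      errs <- c(errs, paste0("partition values must be 'central' or ",
                             "'southern' (offending: ",
                             paste(names(cfg$partition)[bad],
                                   collapse = ", "), ")"))
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    errs <- c(errs, "a numeric seed is required")
  if (is.null(cfg$out_dir))
    errs <- c(errs, "out_dir is required")
  if (length(errs))
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$thresholds <- th
  invisible(cfg)
}

.fmtTable <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                        formatC(df[[j]], digits = 6, format = "g"))
  df
}

.writeTsv <- function(df, dir, name) {
  write.table(.fmtTable(df), file.path(dir, name), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
}

.assocTable <- function(x, snps, collections) {
  d <- dosages(x)
  cd <- colData(x)
  xl <- setNames(rowData(x)$chromosome_type == "x_linked", rownames(x))
  rows <- lapply(snps, function(m) {
    res <- tryCatch({
      st <- suppressWarnings(
        .strataFromVector(d[m, ], cd, xl[[m]], collections, m))
      mh <- mantelHaenszel(st)
      data.frame(marker_id = m, mh$association,
                 q = mh$heterogeneity$q, df = mh$heterogeneity$df,
                 i2 = mh$heterogeneity$i2, band = mh$heterogeneity$band,
                 n_strata = nrow(st), stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(marker_id = m, or = NA, ci_low = NA, ci_high = NA,
                 p = NA, method = "failed", se_lnor = NA, q = NA, df = NA,
                 i2 = NA, band = NA, n_strata = 0,
                 stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  li <- markerInfo(x)
  out <- cbind(out[, "marker_id", drop = FALSE],
               locus = li$locus[match(out$marker_id, li$marker_id)],
               out[, -1])
  rownames(out) <- NULL
  out
}

.distTable <- function(values, status, subgroup, breaks) {
  bins <- cut(values, breaks, include.lowest = TRUE, right = FALSE)
  tab <- table(bin = bins, group = paste(subgroup, status, sep = "_"))
  df <- as.data.frame.matrix(tab)
  data.frame(bin = rownames(df), df, row.names = NULL,
             check.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: acquire data (simulate a cohort or read the
#' genotype/marker/sample TSVs), AIM case-control quality control with
#' collection exclusion, AIM redundancy pruning and N/S axis scoring,
#' combined stratified association with battery selection (SNPs failing
#' the combined association are excluded; designated SNP pairs are pruned
#' by conditional logistic regression), per-subgroup Mantel-Haenszel
#' association, the effect-size-bias battery (direction test,
#' geometric-mean OR, risk-allele sums, GRS), allele-frequency clines in
#' controls, and per-collection means against the N/S score. Writes a
#' fixed set of TSV reports plus a JSON run manifest into `out_dir`;
#' reports are deterministic given `(config, seed)` (the manifest's
#' timestamp is the only volatile field).
#'
#' @param config a configuration list (see [validateConfig]); it is
#'   validated first. In R you may supply `sim_config` directly as a
#'   `"sim_config"` object instead of `simulate: paper_like`.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  message("== stage: data ==")
  simulated <- FALSE
  if (inherits(config$sim_config, "sim_config") ||
      isTRUE(config$simulate$paper_like)) {
    sim <- if (inherits(config$sim_config, "sim_config")) config$sim_config
           else paperLikeConfig(seed = config$seed)
    sim$seed <- as.integer(config$seed)
    x <- generateCohort(sim)
    if (sim$missing_rate > 0)
      x <- missingnessInject(x, sim$missing_rate,
                             seed = as.integer(config$seed) + 1L)
    partition <- setNames(sim$collections$subgroup, sim$collections$id)
    simulated <- TRUE
  } else {
    markers <- readMarkerTsv(config$inputs$markers)
    samples <- readSampleTsv(config$inputs$samples)
    x <- readGenotypeTsv(config$inputs$genotypes, markers, samples)
    partition <- unlist(config$partition)
  }
  n_coll_in <- length(unique(colData(x)$collection_id))

  message("== stage: AIM quality control ==")
  qc <- aimCaseControlCheck(x, alpha = th$aim_alpha)
  excluded <- names(qc$exclude)[qc$exclude]
  retained <- setdiff(unique(colData(x)$collection_id), excluded)
  if (length(retained) < 2) stop("fewer than 2 collections retained")
  x <- x[, colData(x)$collection_id %in% retained]

  message("== stage: N/S score ==")
  ft <- aimFrequencyTable(x)
  aims <- setdiff(colnames(ft), "collection_id")
  ranges <- vapply(aims, function(a) diff(range(ft[[a]])), numeric(1))
  r2 <- aimR2Matrix(x)
  keep <- pruneRedundantAims(r2, ranges, th$r2_threshold)
  informative <- selectInformativeAims(ft, k = th$n_aims, keep = keep)
  ns <- nsScore(ft[, c("collection_id", informative)])
  .writeTsv(ns, config$out_dir, "ns_scores.tsv")

  message("== stage: combined association ==")
  ri <- markerInfo(x)
  all_snps <- setdiff(ri$marker_id[ri$role == "risk_snp"],
                      unlist(config$exclude_snps))
  combined <- .assocTable(x, all_snps, retained)
  .writeTsv(combined, config$out_dir, "association_combined.tsv")
  associated <- combined$marker_id[!is.na(combined$p) &
                                     combined$p <= th$alpha]
  n_dropped_assoc <- length(all_snps) - length(associated)

  message("== stage: conditional pruning ==")
  battery <- associated
  n_dropped_cond <- 0L
  for (pair in config$conditional_pairs) {
    cand <- pair[[1]]; cond <- pair[[2]]
    if (!(cand %in% battery) || !(cond %in% battery)) next
    ci <- conditionalIndependence(x, cand, cond)
    if (ci$p > th$alpha) {
      battery <- setdiff(battery, cand)
      n_dropped_cond <- n_dropped_cond + 1L
    }
  }
  if (!is.null(config$battery_override))
    battery <- intersect(unlist(config$battery_override), all_snps)
  if (length(battery) < 2) stop("battery has fewer than 2 SNPs")

  message("== stage: subgroup association ==")
  coll_c <- retained[partition[retained] == "central"]
  coll_s <- retained[partition[retained] == "southern"]
  assoc_c <- .assocTable(x, battery, coll_c)
  assoc_s <- .assocTable(x, battery, coll_s)
  .writeTsv(assoc_c, config$out_dir, "association_central.tsv")
  .writeTsv(assoc_s, config$out_dir, "association_southern.tsv")

  message("== stage: bias battery ==")
  ok <- !is.na(assoc_c$or) & !is.na(assoc_s$or)
  sums <- suppressWarnings(
    riskAlleleSum(x, battery, maxMissing = th$max_missing))
  sums_sum <- riskAlleleSummary(sums, partition)
  or_c <- setNames(assoc_c$or, assoc_c$marker_id)
  or_s <- setNames(assoc_s$or, assoc_s$marker_id)
  grs <- grsScore(x, battery[ok], or_c[ok], or_s[ok], partition)
  report <- biasReport(assoc_c[ok, c("marker_id", "or", "se_lnor")],
                       assoc_s[ok, c("marker_id", "or", "se_lnor")],
                       sums = sums_sum, grs = grs, alpha = th$alpha)
  .writeTsv(report$per_snp, config$out_dir, "per_snp_bias.tsv")
  gm <- report$gmean
  bias_summary <- data.frame(
    statistic = c("k_southern_larger", "n_compared", "binomial_p",
                  "gmean_or_central", "gmean_or_southern", "gmean_p",
                  "sum_mean_control_central", "sum_mean_control_southern",
                  "sum_mean_case_central", "sum_mean_case_southern",
                  "sum_diff_case_control_central",
                  "sum_diff_case_control_southern",
                  "sum_diff_controls_central_minus_southern",
                  "sum_diff_cases_central_minus_southern",
                  "grs_mean_central", "grs_mean_southern", "grs_p"),
    value = c(report$k_southern_larger, report$n_compared,
              report$binomial_p, gm$gmean_central, gm$gmean_southern,
              gm$p,
              sums_sum$groups$mean[sums_sum$groups$status == "control" &
                                     sums_sum$groups$subgroup == "central"],
              sums_sum$groups$mean[sums_sum$groups$status == "control" &
                                     sums_sum$groups$subgroup == "southern"],
              sums_sum$groups$mean[sums_sum$groups$status == "case" &
                                     sums_sum$groups$subgroup == "central"],
              sums_sum$groups$mean[sums_sum$groups$status == "case" &
                                     sums_sum$groups$subgroup == "southern"],
              sums_sum$case_control$central$diff,
              sums_sum$case_control$southern$diff,
              sums_sum$between_subgroups$control$diff,
              sums_sum$between_subgroups$case$diff,
              grs$groups$mean[1], grs$groups$mean[2], grs$p),
    stringsAsFactors = FALSE)
  .writeTsv(bias_summary, config$out_dir, "bias_summary.tsv")
  breaks <- seq(floor(min(sums$sum)), ceiling(max(sums$sum)) + 1)
  .writeTsv(.distTable(sums$sum, sums$status,
                       partition[sums$collection_id], breaks),
            config$out_dir, "risk_allele_distribution.tsv")
  gb <- pretty(grs$scores$grs, 20)
  .writeTsv(.distTable(grs$scores$grs, grs$scores$status,
                       grs$scores$subgroup, gb),
            config$out_dir, "grs_distribution.tsv")

  message("== stage: clines ==")
  clines <- clineAnalysis(x, partition, ns, snpSet = battery)
  .writeTsv(clines, config$out_dir, "clines.tsv")

  message("== stage: collection means ==")
  cm <- do.call(rbind, lapply(ns$collection_id, function(cc) {
    data.frame(collection_id = cc,
               score = ns$score[ns$collection_id == cc],
               mean_sum_controls = mean(sums$sum[sums$collection_id == cc &
                                                   sums$status == "control"]),
               mean_sum_cases = mean(sums$sum[sums$collection_id == cc &
                                                sums$status == "case"]),
               n_controls = sum(sums$collection_id == cc &
                                  sums$status == "control"),
               n_cases = sum(sums$collection_id == cc &
                               sums$status == "case"),
               stringsAsFactors = FALSE)
  }))
  wp_ctrl <- weightedPearson(cm$score, cm$mean_sum_controls,
                             cm$n_controls + cm$n_cases)
  wp_case <- weightedPearson(cm$score, cm$mean_sum_cases,
                             cm$n_controls + cm$n_cases)
  .writeTsv(cm, config$out_dir, "collection_means.tsv")

  hashed <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "snpclines",
    version = as.character(packageVersion("snpclines")),
    config_hash = rlang::hash(hashed),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    simulated = simulated,
    collections_input = n_coll_in,
    collections_excluded = as.list(excluded),
    collections_retained = length(retained),
    informative_aims = as.list(informative),
    snps_input = length(all_snps),
    snps_dropped_not_associated = n_dropped_assoc,
    snps_dropped_conditional = n_dropped_cond,
    snps_battery = length(battery),
    battery_overridden = !is.null(config$battery_override))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = x, ns_scores = ns, association_combined = combined,
                 association_central = assoc_c,
                 association_southern = assoc_s, report = report,
                 sums = sums, sums_summary = sums_sum, grs = grs,
                 clines = clines, collection_means = cm,
                 correlation_controls = wp_ctrl,
                 correlation_cases = wp_case,
                 manifest = manifest))
}
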