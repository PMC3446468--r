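# Shared in-code fixtures: a small deterministic cohort and random-strata
# generators used across the unit and property tests.

toyMarkers <- function(ids = c("rs1", "rs2"), role = "risk_snp",
                       chromosome_type = "autosomal") {
  data.frame(marker_id = ids, locus = toupper(ids), role = role,
             counted_allele = "T", chromosome_type = chromosome_type,
             phase = ifelse(role == "aim", "aim", "phase1"),
             stringsAsFactors = FALSE)
}

toySamples <- function(n, collection = "NL",
                       status = rep(c("case", "control"), length.out = n),
                       sex = "female") {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             collection_id = collection, status = status, sex = sex,
             stringsAsFactors = FALSE)
}

toyGE <- function(dosage, markers = NULL, samples = NULL, ...) {
  if (is.null(markers)) markers <- toyMarkers(colnames(dosage), ...)
  if (is.null(samples)) samples <- toySamples(nrow(dosage))
  samples$sample_id <- rownames(dosage)
  GenotypeExperiment(dosage, markers, samples)
}

dosageMatrix <- function(..., markers = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  if (is.null(markers)) markers <- paste0("rs", seq_along(cols))
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))), markers)
  m
}

# random valid strata set for meta-analysis property tests
randomStrata <- function(k, min_n = 20, max_n = 200) {
  data.frame(
    collection_id = paste0("C", seq_len(k)),
    a = as.numeric(sample(seq(1, max_n), k, replace = TRUE)),
    b = as.numeric(sample(seq(1, max_n), k, replace = TRUE)),
    c = as.numeric(sample(seq(1, max_n), k, replace = TRUE)),
    d = as.numeric(sample(seq(1, max_n), k, replace = TRUE))) |>
    transform(n = a + b + c + d)
}

# small two-collection case-control cohort with known dosage structure
smallCohortConfig <- function(seed = 7, n = 150, orc = 1.5, ors = 1.5,
                              n_coll = 4, snps = NULL) {
  pos <- seq(0, 1, length.out = n_coll)
  collections <- data.frame(
    id = paste0("C", seq_len(n_coll)), axis_position = pos,
    n_cases = n, n_controls = n,
    subgroup = ifelse(pos <= 0.5, "central", "southern"),
    female_fraction_cases = 0.9, female_fraction_controls = 0.6)
  aims <- data.frame(marker_id = c("aim1", "aim2", "aim3"),
                     freq_north = c(80, 75, 70),
                     freq_south = c(30, 40, 15))
  if (is.null(snps))
    snps <- data.frame(marker_id = c("snpA", "snpB"), locus = c("LA", "LB"),
                       freq_north = c(30, 60), freq_south = c(22, 60),
                       or_central = orc, or_southern = ors,
                       chromosome_type = "autosomal")
  simulationConfig(collections, aims, snps, diseaseModel = "logistic",
                   prevalence = 0.01, seed = seed)
}
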