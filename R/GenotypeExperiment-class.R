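#' GenotypeExperiment: dosage matrix with marker and sample annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' a single `"dosage"` assay with markers in rows and samples in columns.
#' Each cell stores the number of copies of the marker's *counted allele*:
#' the risk allele for risk SNPs, the Northern-common allele for
#' ancestry-informative markers (AIMs). Valid dosages are 0/1/2 for
#' autosomal markers and X-linked females, 0/1 for X-linked (hemizygous)
#' males, and `NA` for a missing call (`NA`, never 0, is the missing
#' sentinel: 0 is a legitimate dosage).
#'
#' Required `rowData` columns (one row per marker):
#' \describe{
#'   \item{locus}{gene/region label.}
#'   \item{role}{`"risk_snp"` or `"aim"`.}
#'   \item{counted_allele}{allele whose copies are stored.}
#'   \item{chromosome_type}{`"autosomal"` or `"x_linked"`; `"x_linked"`
#'     is only allowed for risk SNPs.}
#'   \item{phase}{provenance tag: `"phase1"`, `"phase2"` or `"aim"`.}
#' }
#' Required `colData` columns (one row per sample): `collection_id`,
#' `status` (`"case"`/`"control"`), `sex` (`"female"`/`"male"`/`"unknown"`).
#'
#' Genomic coordinates are deliberately not modelled: no stage of the
#' analysis uses positions.
#'
#' @aliases GenotypeExperiment-class
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
  msg <- character()
  if (!("dosage" %in% assayNames(object)))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  rd <- rowData(object)
  cd <- colData(object)
  need_rd <- c("locus", "role", "counted_allele", "chromosome_type", "phase")
  need_cd <- c("collection_id", "status", "sex")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste0("rowData must contain: ",
                         paste(setdiff(need_rd, colnames(rd)), collapse = ", ")))
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste0("colData must contain: ",
                         paste(setdiff(need_cd, colnames(cd)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "marker ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!all(rd$role %in% MARKER_ROLES))
    msg <- c(msg, "role must be 'risk_snp' or 'aim'")
  if (!all(rd$chromosome_type %in% CHROM_TYPES))
    msg <- c(msg, "chromosome_type must be 'autosomal' or 'x_linked'")
  if (!all(rd$phase %in% MARKER_PHASES))
    msg <- c(msg, "phase must be 'phase1', 'phase2' or 'aim'")
  if (any(rd$chromosome_type == "x_linked" & rd$role != "risk_snp"))
    msg <- c(msg, "x_linked markers are only supported for risk SNPs")
  if (any(!nzchar(as.character(rd$counted_allele))) ||
      any(is.na(rd$counted_allele)))
    msg <- c(msg, "counted_allele must be non-empty")
  if (!all(cd$status %in% SAMPLE_STATUS))
    msg <- c(msg, "status must be 'case' or 'control'")
  if (!all(cd$sex %in% SAMPLE_SEX))
    msg <- c(msg, "sex must be 'female', 'male' or 'unknown'")
  bad <- !is.na(d) & !(d %in% 0:2)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("dosage out of range at marker '%s', sample '%s'",
                          rownames(object)[i[1]], colnames(object)[i[2]]))
  }
  xl <- rd$chromosome_type == "x_linked"
  male <- cd$sex == "male"
  if (any(xl) && any(male)) {
    dx <- d[xl, male, drop = FALSE]
    bad <- !is.na(dx) & dx > 1
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      msg <- c(msg, sprintf(
        "dosage 2 for x_linked marker '%s' in male sample '%s'",
        rownames(object)[xl][i[1]], colnames(object)[male][i[2]]))
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix of counted-allele dosages with samples in
#'   rows and markers in columns (the interchange-TSV orientation); it is
#'   stored transposed, markers x samples, following the
#'   SummarizedExperiment convention. Row names are sample ids, column
#'   names marker ids.
#' @param markers data.frame of marker annotation with columns
#'   `marker_id`, `locus`, `role`, `counted_allele`, `chromosome_type`,
#'   `phase` (see [GenotypeExperiment-class]).
#' @param samples data.frame of sample annotation with columns
#'   `sample_id`, `collection_id`, `status`, `sex`.
#' @return a validated `GenotypeExperiment`.
#' @examples
#' ge <- GenotypeExperiment(
#'   dosage = matrix(c(0, 1, 2, 1), 2, 2,
#'                   dimnames = list(c("s1", "s2"), c("rs1", "rs2"))),
#'   markers = data.frame(marker_id = c("rs1", "rs2"), locus = c("A", "B"),
#'                        role = "risk_snp", counted_allele = "T",
#'                        chromosome_type = "autosomal", phase = "phase1"),
#'   samples = data.frame(sample_id = c("s1", "s2"), collection_id = "NL",
#'                        status = c("case", "control"), sex = "female"))
#' ge
#' @export
GenotypeExperiment <- function(dosage, markers, samples) {
  stopifnot(is.matrix(dosage))
  markers <- as.data.frame(markers)
  samples <- as.data.frame(samples)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must have sample row names and marker column names")
  if (!setequal(colnames(dosage), markers$marker_id))
    stop("dosage marker columns and marker metadata ids differ: ",
         paste(union(setdiff(colnames(dosage), markers$marker_id),
                     setdiff(markers$marker_id, colnames(dosage))),
               collapse = ", "))
  if (!setequal(rownames(dosage), samples$sample_id))
    stop("dosage sample rows and sample metadata ids differ: ",
         paste(union(setdiff(rownames(dosage), samples$sample_id),
                     setdiff(samples$sample_id, rownames(dosage))),
               collapse = ", "))
  d <- t(dosage[samples$sample_id, markers$marker_id, drop = FALSE])
  storage.mode(d) <- "integer"
  rd <- S4Vectors::DataFrame(markers[setdiff(colnames(markers), "marker_id")],
                             row.names = markers$marker_id)
  cd <- S4Vectors::DataFrame(samples[setdiff(colnames(samples), "sample_id")],
                             row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(dosage = d),
                             rowData = rd, colData = cd)
  new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment dosage matrix, markers x samples.
#' @param x a `GenotypeExperiment`.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeExperiment marker annotation as a data.frame with a
#'   `marker_id` column.
#' @export
markerInfo <- function(x) {
  data.frame(marker_id = rownames(x), as.data.frame(rowData(x)),
             row.names = NULL)
}

#' @describeIn GenotypeExperiment sample annotation as a data.frame with a
#'   `sample_id` column.
#' @export
sampleInfo <- function(x) {
  data.frame(sample_id = colnames(x), as.data.frame(colData(x)),
             row.names = NULL)
}

#' Genotyping call rate
#'
#' Fraction of non-missing dosages, per marker or per sample.
#'
#' @param x a [GenotypeExperiment].
#' @param by `"marker"` or `"sample"`.
#' @return named numeric vector of call rates in `[0, 1]`.
#' @export
callRate <- function(x, by = c("marker", "sample")) {
  by <- match.arg(by)
  d <- dosages(x)
  if (by == "marker") rowMeans(!is.na(d)) else colMeans(!is.na(d))
}

setMethod("show", "GenotypeExperiment", function(object) {
  d <- dosages(object)
  cat("GenotypeExperiment:", nrow(object), "markers x", ncol(object),
      "samples\n")
  rd <- rowData(object)
  cd <- colData(object)
  cat("  markers:", sum(rd$role == "risk_snp"), "risk SNPs,",
      sum(rd$role == "aim"), "AIMs\n")
  cat("  samples:", sum(cd$status == "case"), "cases,",
      sum(cd$status == "control"), "controls in",
      length(unique(cd$collection_id)), "collections\n")
  cat("  overall call rate:",
      sprintf("%.2f%%", 100 * mean(!is.na(d))), "\n")
})

# sample-subset resolver: NULL (all), character ids, or logical/integer index
.resolveSamples <- function(x, samples) {
  if (is.null(samples)) return(seq_len(ncol(x)))
  if (is.character(samples)) {
    miss <- setdiff(samples, colnames(x))
    if (length(miss))
      stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    return(match(samples, colnames(x)))
  }
  idx <- seq_len(ncol(x))[samples]
  if (anyNA(idx)) stop("invalid sample subset")
  idx
}

.markerIndex <- function(x, marker) {
  i <- match(marker, rownames(x))
  if (is.na(i)) stop("unknown marker id: ", marker)
  i
}

# counted/total allele copies from a dosage vector (one marker), given
# per-sample sex and the marker's X-linkage; `sel` is a logical subset
.freqCounts <- function(drow, sex, xlinked, sel) {
  d <- drow[sel]
  ok <- !is.na(d)
  copies <- if (xlinked) ifelse(sex[sel] == "male", 1L, 2L)[ok]
            else rep(2L, sum(ok))
  c(counted = sum(d[ok]), total = sum(copies))
}

#' Counted-allele frequency in a sample subset
#'
#' Frequency (in percent) of a marker's counted allele, with denominators
#' that respect hemizygosity: autosomal subjects and X-linked females
#' contribute two allele copies, X-linked males one. Missing dosages
#' contribute nothing.
#'
#' @param x a [GenotypeExperiment].
#' @param marker marker id.
#' @param samples optional sample subset (ids, logical or integer index);
#'   default all samples.
#' @return list with `freq` (percent), `counted` (counted-allele copies)
#'   and `total` (allele copies observed).
#' @export
alleleFrequency <- function(x, marker, samples = NULL) {
  i <- .markerIndex(x, marker)
  j <- .resolveSamples(x, samples)
  sel <- rep(FALSE, ncol(x)); sel[j] <- TRUE
  ct <- .freqCounts(dosages(x)[i, ], colData(x)$sex,
                    rowData(x)$chromosome_type[i] == "x_linked", sel)
  if (ct[["total"]] == 0)
    stop("no genotype data for marker '", marker, "' in the given subset")
  list(freq = 100 * ct[["counted"]] / ct[["total"]],
       counted = ct[["counted"]], total = ct[["total"]])
}

#' Re-orient a marker's dosage to a different counted allele
#'
#' Flips dosages `d -> 2 - d` (autosomal or X-linked female; `1 - d` for
#' X-linked males) so that the stored dosage counts `countedAllele`
#' instead of `storedAllele`. Missing dosages are unchanged, and flipping
#' twice (or flipping to the already-counted allele) is the identity.
#' Needed to express AIMs in terms of the Northern-common allele and risk
#' SNPs in terms of the risk allele.
#'
#' @param x a [GenotypeExperiment].
#' @param marker marker id.
#' @param storedAllele the allele currently counted (must match the
#'   marker's `counted_allele` annotation).
#' @param countedAllele the allele that should be counted.
#' @return a `GenotypeExperiment` with the marker re-oriented.
#' @export
flipToCountedAllele <- function(x, marker, storedAllele, countedAllele) {
  i <- .markerIndex(x, marker)
  cur <- as.character(rowData(x)$counted_allele[i])
  if (!identical(as.character(storedAllele), cur))
    stop("storedAllele '", storedAllele, "' does not match the current ",
         "counted allele '", cur, "' of marker '", marker, "'")
  if (identical(as.character(countedAllele), cur)) return(x)
  d <- assay(x, "dosage")
  mx <- if (rowData(x)$chromosome_type[i] == "x_linked")
    ifelse(colData(x)$sex == "male", 1L, 2L) else rep(2L, ncol(x))
  d[i, ] <- mx - d[i, ]
  assay(x, "dosage") <- d
  rowData(x)$counted_allele[i] <- as.character(countedAllele)
  validObject(x)
  x
}
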