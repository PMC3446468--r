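#' Read a genotype dosage TSV
#'
#' The interchange format is a tab-separated table with a header row, a
#' first column `sample_id` and one column per marker id; cells are
#' `0`/`1`/`2`/`NA` counted-allele dosages.
#'
#' @param path path to the TSV.
#' @param markers,samples marker and sample metadata data.frames as for
#'   [GenotypeExperiment()].
#' @return a validated [GenotypeExperiment].
#' @export
readGenotypeTsv <- function(path, markers, samples) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("empty marker panel: '", path, "' has no marker columns")
  if (colnames(tab)[1] != "sample_id")
    stop("first column must be 'sample_id', found '", colnames(tab)[1], "'")
  ids <- tab$sample_id
  m <- as.matrix(tab[, -1, drop = FALSE])
  bad <- !(m %in% c("0", "1", "2", "NA", NA))
  if (any(bad)) {
    i <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage '%s' at sample '%s', marker '%s'",
                 m[i[1], i[2]], ids[i[1]], colnames(m)[i[2]]))
  }
  suppressWarnings(storage.mode(m) <- "integer")
  rownames(m) <- ids
  GenotypeExperiment(m, markers, samples)
}

#' Write a genotype dosage TSV
#'
#' Inverse of [readGenotypeTsv]: `readGenotypeTsv(writeGenotypeTsv(x))`
#' reproduces `x` exactly. Missing dosages are written as `NA`.
#'
#' @param x a [GenotypeExperiment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTsv <- function(x, path) {
  d <- t(dosages(x))
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read marker / sample metadata TSVs
#'
#' Plain TSVs with the columns of the marker and sample annotation
#' (see [GenotypeExperiment-class]).
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readMarkerTsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname readMarkerTsv
#' @export
readSampleTsv <- readMarkerTsv

#' Minimal VCF import
#'
#' Reads the GT field of a VCF 4.x file into a dosage matrix counted on
#' the ALT allele, plus a provisional marker annotation table.
#' Multiallelic records are skipped with a warning; missing genotypes
#' (`./.`) become `NA`. The caller is expected to supply sample metadata
#' and to re-orient markers to their counted allele with
#' [flipToCountedAllele] before analysis.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return list with `dosage` (samples x markers integer matrix) and
#'   `markers` (data.frame with `marker_id`, `locus`, `role`,
#'   `counted_allele`, `chromosome_type`, `phase`; role defaults to
#'   `"risk_snp"`, chromosome_type to `"autosomal"`, phase to
#'   `"phase2"` -- placeholders to be corrected by the caller).
#' @export
importVcfMinimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  d <- apply(gt, c(1, 2), count_alt)
  d <- t(matrix(as.integer(d), nrow = nrow(gt),
                dimnames = list(ids, colnames(gt))))
  markers <- data.frame(
    marker_id = ids, locus = fix$CHROM, role = "risk_snp",
    counted_allele = fix$ALT, chromosome_type = "autosomal",
    phase = "phase2", stringsAsFactors = FALSE)
  list(dosage = d, markers = markers)
}

.extdata <- function(file) {
  system.file("extdata", file, package = "snpclines", mustWork = TRUE)
}

#' Bundled reference tables
#'
#' `europeanCollections()` returns the bundled description of the 17
#' European SLE case-control collections (sample sizes, proportion of
#' women, frequencies of the three most informative AIMs oriented to the
#' Northern-common allele, published North/South score, subgroup and AIM-QC
#' exclusion status). `slePanel()` returns the bundled 25-SNP SLE risk
#' panel (locus, combined Mantel-Haenszel OR, battery membership, the
#' direction and magnitude of the subgroup effect-size split, and control
#' risk-allele frequencies in the Central and Southern European
#' subgroups). Both are transcriptions of published summary tables and are
#' the inputs for [paperLikeConfig] and for recomputing the N/S score
#' column.
#'
#' @return a data.frame.
#' @export
europeanCollections <- function() {
  read.delim(.extdata("euro_collections.tsv"), check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname europeanCollections
#' @export
slePanel <- function() {
  read.delim(.extdata("sle_snp_panel.tsv"), check.names = FALSE,
             stringsAsFactors = FALSE)
}
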