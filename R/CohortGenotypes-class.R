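#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CohortGenotypes: diploid genotypes for a case-control cohort
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment]
#' holding one `"GT"` assay of alt-allele dosages (variants x samples;
#' integer 0, 1, 2 or `NA` for missing), variant annotations as `rowData`
#' (`chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `impact`, and
#' optionally in-silico scores and an alignment-column mapping) and the
#' sample manifest as `colData` (`breed`, `phenotype`, `cohort`,
#' `lv_wall_cm`).
#'
#' Validity enforces the cohort model: unique sample ids and variant keys,
#' `ref != alt`, 1-based positions, dosages in \{0, 1, 2, NA\}, phenotype
#' and cohort tokens from their controlled vocabularies, and the
#' echocardiographic wall-thickness invariants (an affected cat with a
#' recorded left-ventricular wall must have >= 0.6 cm, an unaffected one
#' < 0.4 cm).
#'
#' @aliases CohortGenotypes
#' @export
setClass("CohortGenotypes", contains = "SummarizedExperiment")

setValidity("CohortGenotypes", function(object) {
  msg <- character()
  if (!"GT" %in% assayNames(object))
    return("assay 'GT' is required")
  gt <- assay(object, "GT")
  ok <- is.na(gt) | gt %in% c(0L, 1L, 2L)
  if (!all(ok))
    msg <- c(msg, "GT values must be 0, 1, 2 or NA")
  rd <- rowData(object)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "impact")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste("rowData missing columns:", paste(miss, collapse = ", ")))
  if (nrow(rd)) {
    if (any(rd$pos < 1L)) msg <- c(msg, "positions must be >= 1 (1-based)")
    if (any(rd$ref == rd$alt)) msg <- c(msg, "ref must differ from alt")
    if (!all(grepl("^[ACGT]+$", rd$ref)) || !all(grepl("^[ACGT]+$", rd$alt)))
      msg <- c(msg, "ref/alt must be non-empty A/C/G/T strings")
    key <- .variantKey(rd$chrom, rd$pos, rd$ref, rd$alt)
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicate variant key: %s", key[duplicated(key)][1]))
    if (!all(rd$impact %in% .IMPACTS))
      msg <- c(msg, "impact must be one of high/moderate/low/modifier")
  }
  cd <- colData(object)
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample_id: %s",
                          colnames(object)[duplicated(colnames(object))][1]))
  if (!all(c("phenotype", "cohort") %in% colnames(cd)))
    return("colData must contain 'phenotype' and 'cohort'")
  if (!all(cd$phenotype %in% .PHENOTYPES))
    msg <- c(msg, "phenotype must be affected/unaffected/unknown")
  if (!all(cd$cohort %in% .COHORTS))
    msg <- c(msg, "cohort must be discovery/validation/population")
  if ("lv_wall_cm" %in% colnames(cd)) {
    lv <- cd$lv_wall_cm
    bad_aff <- cd$phenotype == "affected" & !is.na(lv) & lv < .LV_AFFECTED_MIN
    bad_un  <- cd$phenotype == "unaffected" & !is.na(lv) & lv >= .LV_UNAFFECTED_MAX
    if (any(bad_aff))
      msg <- c(msg, sprintf(
        "sample '%s': affected but lv_wall_cm %.2f < %.1f cm threshold",
        colnames(object)[which(bad_aff)[1]], lv[which(bad_aff)[1]],
        .LV_AFFECTED_MIN))
    if (any(bad_un))
      msg <- c(msg, sprintf(
        "sample '%s': unaffected but lv_wall_cm %.2f >= %.1f cm threshold",
        colnames(object)[which(bad_un)[1]], lv[which(bad_un)[1]],
        .LV_UNAFFECTED_MAX))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortGenotypes object
#'
#' @param gt integer matrix of alt-allele dosages, variants in rows and
#'   samples in columns; `NA` encodes a missing genotype.
#' @param variants `data.frame` (or `DataFrame`) of variant annotations with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `impact`.
#' @param samples `data.frame` of sample records with columns `sample_id`,
#'   `breed`, `phenotype`, `cohort` and optionally `lv_wall_cm`.
#' @return a validated [CohortGenotypes] object.
#' @examples
#' gt <- matrix(c(0L, 1L, 2L), nrow = 1,
#'              dimnames = list(NULL, c("s1", "s2", "s3")))
#' v <- data.frame(chrom = "A3", pos = 100L, ref = "G", alt = "C",
#'                 gene = "ALMS1", consequence = "missense_variant",
#'                 impact = "moderate")
#' m <- data.frame(sample_id = c("s1", "s2", "s3"), breed = "Sphynx",
#'                 phenotype = c("affected", "affected", "unaffected"),
#'                 cohort = "discovery")
#' CohortGenotypes(gt, v, m)
#' @export
CohortGenotypes <- function(gt, variants, samples) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% colnames(samples))
    stop("samples must contain a 'sample_id' column", call. = FALSE)
  gt <- matrix(as.integer(gt), nrow = nrow(variants),
               ncol = nrow(samples),
               dimnames = list(NULL, samples$sample_id))
  variants$pos <- as.integer(variants$pos)
  variants$consequence <- normalizeConsequence(variants$consequence)
  variants$impact <- .matchEnum(variants$impact, .IMPACTS, "impact")
  rd <- DataFrame(variants)
  rownames(rd) <- .variantKey(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  cd <- DataFrame(samples[setdiff(colnames(samples), "sample_id")],
                  row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(GT = gt), rowData = rd,
                             colData = cd)
  rownames(se) <- rownames(rd)
  new("CohortGenotypes", se)
}

#' @describeIn CohortGenotypes the dosage matrix (variants x samples).
#' @param x,object a `CohortGenotypes` object.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn CohortGenotypes variant annotations as a `DataFrame`.
#' @export
variantInfo <- function(x) rowData(x)

#' @describeIn CohortGenotypes the sample manifest as a `data.frame`
#'   (with a `sample_id` column restored from the column names).
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = colnames(x), cd, row.names = NULL)
}

#' @describeIn CohortGenotypes subset to one cohort
#'   (`"discovery"`, `"validation"` or `"population"`).
#' @param cohort cohort label to keep.
#' @export
subsetCohort <- function(x, cohort) {
  cohort <- match.arg(cohort, .COHORTS)
  x[, colData(x)$cohort == cohort]
}

setMethod("show", "CohortGenotypes", function(object) {
  cd <- colData(object)
  cat(sprintf("CohortGenotypes: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  if (ncol(object)) {
    tab <- table(cohort = cd$cohort, phenotype = cd$phenotype)
    print(tab)
  }
  nm <- sum(is.na(assay(object, "GT")))
  cat(sprintf("missing genotypes: %d (%.1f%%)\n", nm,
              100 * nm / max(1, length(assay(object, "GT")))))
})
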