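#' @importFrom VariantAnnotation readVcf ref alt info geno
#' @importFrom Biostrings readAAStringSet
NULL

#' Read a sample manifest
#'
#' Reads a tab-separated manifest with columns `sample_id`, `breed`,
#' `phenotype` (affected / unaffected / unknown), `cohort` (discovery /
#' validation / population) and optionally `lv_wall_cm`, the left
#' ventricular end diastolic wall thickness in cm. Tokens are trimmed and
#' matched case-insensitively. The echocardiographic phenotype definition
#' is enforced: an affected cat with a recorded wall thickness must have at
#' least 0.6 cm, an unaffected one less than 0.4 cm.
#'
#' @param path path to the manifest TSV.
#' @return `data.frame` with one row per sample.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "breed", "phenotype", "cohort")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("manifest missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- trimws(as.character(df$sample_id))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in manifest: ", dup[1], call. = FALSE)
  df$breed <- trimws(as.character(df$breed))
  df$phenotype <- .matchEnum(df$phenotype, .PHENOTYPES, "phenotype",
                             row = seq_len(nrow(df)))
  df$cohort <- .matchEnum(df$cohort, .COHORTS, "cohort",
                          row = seq_len(nrow(df)))
  if ("lv_wall_cm" %in% colnames(df)) {
    lv <- suppressWarnings(as.numeric(df$lv_wall_cm))
    df$lv_wall_cm <- lv
    bad <- which(df$phenotype == "affected" & !is.na(lv) &
                   lv < .LV_AFFECTED_MIN)
    if (length(bad))
      stop(sprintf(
        "sample '%s': phenotype affected requires lv_wall_cm >= %.1f cm, got %.2f",
        df$sample_id[bad[1]], .LV_AFFECTED_MIN, lv[bad[1]]), call. = FALSE)
    bad <- which(df$phenotype == "unaffected" & !is.na(lv) &
                   lv >= .LV_UNAFFECTED_MAX)
    if (length(bad))
      stop(sprintf(
        "sample '%s': phenotype unaffected requires lv_wall_cm < %.1f cm, got %.2f",
        df$sample_id[bad[1]], .LV_UNAFFECTED_MAX, lv[bad[1]]), call. = FALSE)
  }
  df
}

## Decode a matrix of VCF GT strings to alt-allele dosage. "/" and "|" are
## equivalent (phase ignored); "./." and "." are missing.
.decodeGT <- function(gt) {
  dose <- function(s) {
    s <- gsub("|", "/", s, fixed = TRUE)
    al <- strsplit(s, "/", fixed = TRUE)
    vapply(al, function(a) {
      if (any(a == ".") || !length(a) || identical(a, ""))
        return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
  }
  matrix(dose(as.character(gt)), nrow = nrow(gt), ncol = ncol(gt),
         dimnames = dimnames(gt))
}

#' Read cohort genotypes from a VCF
#'
#' Reads a VCF 4.2 call set (GT FORMAT required) into a [CohortGenotypes]
#' container, resolving every VCF sample against the manifest. Genotypes
#' are stored as alt-allele dosage; `./.` and `.` become missing; phased
#' and unphased separators are treated identically. Multiallelic records
#' are rejected: split them upstream (e.g. `bcftools norm -m-`) so dosage
#' semantics stay unambiguous.
#'
#' Variant annotations (gene, consequence, impact) are taken from an
#' ANN-style INFO field (`Allele|Consequence|IMPACT|Gene`, key
#' configurable) or, if `annotations` is supplied, joined from an
#' annotation table read with [readAnnotationTable()] (which then takes
#' precedence).
#'
#' @param path path to the VCF file.
#' @param manifest manifest `data.frame` from [readManifest()].
#' @param annotations optional annotation `data.frame`.
#' @param annKey INFO key carrying the functional annotation (default
#'   `"ANN"`).
#' @return a [CohortGenotypes] object covering the manifest samples present
#'   in the VCF.
#' @export
readCohortVCF <- function(path, manifest, annotations = NULL,
                          annKey = "ANN") {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "cohort")
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  if (any(nalt > 1)) {
    rr <- SummarizedExperiment::rowRanges(vcf)[which(nalt > 1)[1]]
    stop(sprintf("multiallelic site at %s:%d; split before input",
                 as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr)), call. = FALSE)
  }
  vcf_samples <- colnames(vcf)
  unknown <- setdiff(vcf_samples, manifest$sample_id)
  if (length(unknown))
    stop("VCF sample(s) absent from manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  gtRaw <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtRaw)) stop("VCF has no GT FORMAT field", call. = FALSE)
  gt <- .decodeGT(gtRaw)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refv <- as.character(VariantAnnotation::ref(vcf))
  altv <- as.character(unlist(VariantAnnotation::alt(vcf)))

  gene <- cons <- impact <- rep(NA_character_, length(pos))
  inf <- VariantAnnotation::info(vcf)
  if (annKey %in% colnames(inf)) {
    ann <- inf[[annKey]]
    annStr <- vapply(as.list(ann), function(a)
      if (length(a)) as.character(a)[1] else NA_character_, character(1))
    parts <- strsplit(annStr, "|", fixed = TRUE)
    getp <- function(i) vapply(parts, function(p)
      if (length(p) >= i) p[i] else NA_character_, character(1))
    cons <- getp(2); impact <- tolower(getp(3)); gene <- getp(4)
  }
  variants <- data.frame(chrom = chrom, pos = pos, ref = refv, alt = altv,
                         gene = gene, consequence = cons, impact = impact,
                         stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    key <- .variantKey(variants$chrom, variants$pos, variants$ref,
                       variants$alt)
    akey <- .variantKey(annotations$chrom, annotations$pos,
                        annotations$ref, annotations$alt)
    idx <- match(key, akey)
    for (col in setdiff(colnames(annotations),
                        c("chrom", "pos", "ref", "alt"))) {
      val <- annotations[[col]][idx]
      variants[[col]] <- val
    }
  }
  if (all(is.na(variants$impact)) && nrow(variants))
    stop("no variant annotations: provide an ANN-style INFO field or an ",
         "annotation table", call. = FALSE)
  keep <- manifest$sample_id[manifest$sample_id %in% vcf_samples]
  CohortGenotypes(gt[, keep, drop = FALSE], variants,
                  manifest[match(keep, manifest$sample_id), , drop = FALSE])
}

#' Write cohort genotypes to a VCF 4.2 file
#'
#' Emits the container back to a minimal single-sample-format VCF (GT only)
#' with an ANN-style INFO annotation, in the dialect [readCohortVCF()]
#' reads; the round trip preserves dosage including missing genotypes.
#'
#' @param x a [CohortGenotypes] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortVCF <- function(x, path) {
  stopifnot(is(x, "CohortGenotypes"))
  rd <- rowData(x)
  gt <- genotypes(x)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gtStr[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Consequence | IMPACT | Gene'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t"))
  body <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    ann <- sprintf("ANN=%s|%s|%s|%s", rd$alt[i], rd$consequence[i],
                   toupper(rd$impact[i]), rd$gene[i])
    body[i] <- paste(c(rd$chrom[i], rd$pos[i], ".", rd$ref[i], rd$alt[i],
                       ".", "PASS", ann, "GT", gtStr[i, ]), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an orthologue protein multiple alignment
#'
#' Reads an aligned FASTA of orthologue protein sequences into a character
#' matrix (rows = species, columns = alignment positions). The gap
#' character `-` is preserved; conservation scoring excludes it later.
#'
#' @param path path to the aligned FASTA.
#' @return character matrix of single residues.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("alignment not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in alignment file", call. = FALSE)
  if (length(seqs) < 2)
    stop("alignment needs at least 2 sequences", call. = FALSE)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1) {
    bad <- names(seqs)[which(w != w[1])[1]]
    stop(sprintf("unequal aligned lengths: sequence '%s' has %d, expected %d",
                 bad, w[w != w[1]][1], w[1]), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(mat) <- names(seqs)
  mat
}

#' Read a variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `impact`, plus optional in-silico score columns `polyphen` (0-1,
#' damaging high), `sift` (0-1, deleterious low), `provean` (unbounded,
#' deleterious negative) and an optional mapping of each missense variant
#' to its orthologue-alignment column (`aln_column`, `ref_aa`).
#'
#' @param path path to the annotation TSV.
#' @return `data.frame` of annotations, consequences normalized.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path,
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "impact")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$pos <- as.integer(df$pos)
  df$consequence <- normalizeConsequence(df$consequence)
  df$impact <- .matchEnum(df$impact, .IMPACTS, "impact")
  for (col in c("polyphen", "sift")) {
    if (col %in% colnames(df)) {
      v <- df[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        stop(sprintf("%s scores must lie in [0, 1]", col), call. = FALSE)
    }
  }
  df
}

#' Read a gene panel
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the panel file.
#' @return character vector of gene symbols.
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path)) stop("gene panel not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read Ki67 nucleus counts
#'
#' TSV with columns `cat_id`, `group` (`hcm` or `control`) and the five
#' per-slide counting areas `area1`..`area5` (4 borders and the center).
#' Returns the table with a `slide_sum` column, the per-cat value entering
#' the group comparison.
#'
#' @param path path to the counts TSV.
#' @return `data.frame` with `slide_sum` appended.
#' @export
readKi67Counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  areas <- paste0("area", 1:5)
  miss <- setdiff(c("cat_id", "group", areas), colnames(df))
  if (length(miss))
    stop("counts table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$group <- .matchEnum(df$group, c("hcm", "control"), "group",
                         row = seq_len(nrow(df)))
  cnt <- as.matrix(df[, areas])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("area counts must be non-negative integers", call. = FALSE)
  df$slide_sum <- as.integer(rowSums(cnt))
  df
}
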