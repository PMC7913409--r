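#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats pbeta rbeta rbinom rnorm rpois runif setNames var
#' @importFrom utils read.delim write.table
NULL

## Controlled vocabularies used across the pipeline.
.PHENOTYPES <- c("affected", "unaffected", "unknown")
.COHORTS    <- c("discovery", "validation", "population")
.IMPACTS    <- c("high", "moderate", "low", "modifier")

## Echocardiographic phenotype thresholds (cm, left ventricular end
## diastolic wall): affected requires >= 0.6, unaffected requires < 0.4.
.LV_AFFECTED_MIN   <- 0.6
.LV_UNAFFECTED_MAX <- 0.4

#' Normalize a consequence string to Sequence Ontology style
#'
#' Annotation dialects vary ("non synonymous variant", "Stop Gained",
#' "missense variant"); all panel, impact and truncation checks run on
#' lower-cased, underscore-separated Sequence Ontology terms. A handful of
#' common synonyms are mapped onto their SO term.
#'
#' @param x character vector of consequence labels.
#' @return character vector of normalized terms.
#' @examples
#' normalizeConsequence(c("Stop Gained", "nonsynonymous variant"))
#' @export
normalizeConsequence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]+", "_", x)
  synonyms <- c(
    nonsynonymous_variant = "missense_variant",
    non_synonymous_variant = "missense_variant",
    stop_gain             = "stop_gained",
    frameshift            = "frameshift_variant",
    frameshift_indel      = "frameshift_variant",
    splice_site_acceptor  = "splice_acceptor_variant",
    splice_site_donor     = "splice_donor_variant",
    start_gained          = "start_lost",
    altered_start_codon   = "start_lost",
    codon_insertion       = "inframe_insertion",
    codon_deletion        = "inframe_deletion",
    synonymous            = "synonymous_variant"
  )
  hit <- x %in% names(synonyms)
  x[hit] <- unname(synonyms[x[hit]])
  x
}

## Case-insensitive enum matcher for hand-edited TSV tokens.
.matchEnum <- function(x, levels, what, row = NULL) {
  x <- tolower(trimws(as.character(x)))
  bad <- !is.na(x) & nzchar(x) & !(x %in% levels)
  if (any(bad)) {
    where <- if (is.null(row)) "" else sprintf(" (row %d)", row[which(bad)[1]])
    stop(sprintf("unknown %s token '%s'%s; expected one of: %s",
                 what, x[which(bad)[1]], where,
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  x[is.na(x) | !nzchar(x)] <- NA_character_
  x
}

## Variant key used throughout reports and ground truth.
.variantKey <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", chrom, as.integer(pos), ref, alt)
}

## One pseudo-random stream per simulator artifact, keyed on
## (seed, artifact name), so adding an output never perturbs the others.
.ARTIFACT_OFFSETS <- c(
  manifest = 101L, genotypes = 211L, background = 307L, scores = 401L,
  alignment = 503L, ki67 = 601L, null = 701L
)

.withStream <- function(seed, artifact, expr) {
  stopifnot(artifact %in% names(.ARTIFACT_OFFSETS))
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^28)
    stop("seed must be an integer with |seed| <= 2^28", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed * 131L + .ARTIFACT_OFFSETS[[artifact]])
  force(expr)
}
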