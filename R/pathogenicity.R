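#' @importFrom Biostrings GENETIC_CODE
NULL

## Consequences counted as protein-truncating: stop gain, frameshift,
## altered splice site (either side), altered start codon, exon deletion.
.TRUNCATING <- c("stop_gained", "frameshift_variant",
                 "splice_acceptor_variant", "splice_donor_variant",
                 "start_lost", "exon_deletion")

#' In-silico consensus thresholds
#'
#' Per-program deleteriousness cut-offs for the missense consensus
#' (PolyPhen-2 probability of damage, high = damaging; SIFT tolerance
#' probability, low = deleterious; PROVEAN delta score, negative =
#' deleterious). Defaults follow each program's published conventions:
#' PolyPhen >= 0.85 ("probably damaging"), SIFT <= 0.05, PROVEAN <= -2.5.
#' A missense variant needs at least `min_deleterious_calls` programs on
#' the deleterious side.
#'
#' @param polyphen_deleterious_min PolyPhen score at/above which a call is
#'   deleterious (default 0.85).
#' @param sift_deleterious_max SIFT score at/below which a call is
#'   deleterious (default 0.05).
#' @param provean_deleterious_max PROVEAN score at/below which a call is
#'   deleterious (default -2.5).
#' @param min_deleterious_calls votes required (default 2, i.e. 2 of 3).
#' @param conservation_min minimum alignment-identity fraction for a
#'   residue to count as well conserved (default 0.90).
#' @return a list of class `InSilicoThresholds`.
#' @export
inSilicoThresholds <- function(polyphen_deleterious_min = 0.85,
                               sift_deleterious_max = 0.05,
                               provean_deleterious_max = -2.5,
                               min_deleterious_calls = 2L,
                               conservation_min = 0.90) {
  if (!min_deleterious_calls %in% 1:3)
    stop("min_deleterious_calls must be 1, 2 or 3", call. = FALSE)
  structure(list(polyphen_deleterious_min = polyphen_deleterious_min,
                 sift_deleterious_max = sift_deleterious_max,
                 provean_deleterious_max = provean_deleterious_max,
                 min_deleterious_calls = as.integer(min_deleterious_calls),
                 conservation_min = conservation_min),
            class = "InSilicoThresholds")
}

#' Is a consequence protein-truncating?
#'
#' @param consequence consequence string(s); normalized with
#'   [normalizeConsequence()] before the lookup.
#' @return logical vector.
#' @examples
#' isTruncating(c("stop_gained", "missense_variant"))
#' @export
isTruncating <- function(consequence) {
  normalizeConsequence(consequence) %in% .TRUNCATING
}

#' Residue conservation at one alignment column
#'
#' Fraction of non-gap orthologue rows whose residue equals the reference
#' residue at the given column. Gap rows carry no residue evidence and are
#' excluded from the denominator.
#'
#' @param alignment residue matrix from [readAlignment()].
#' @param column 1-based alignment column index.
#' @param reference_residue single-letter amino acid to compare against.
#' @return identity fraction in `[0, 1]`.
#' @export
conservationScore <- function(alignment, column, reference_residue) {
  if (column < 1 || column > ncol(alignment))
    stop(sprintf("column %d outside alignment width %d", column,
                 ncol(alignment)), call. = FALSE)
  col <- alignment[, column]
  col <- col[col != "-"]
  if (!length(col))
    stop(sprintf("alignment column %d is entirely gaps", column),
         call. = FALSE)
  mean(toupper(col) == toupper(reference_residue))
}

#' Count deleterious in-silico votes
#'
#' Counts how many of the present PolyPhen / SIFT / PROVEAN scores fall on
#' the deleterious side of their thresholds. A missing score is a
#' non-vote: it is neither deleterious nor benign, and the absolute vote
#' requirement still applies downstream.
#'
#' @param polyphen,sift,provean scores, each possibly `NA`.
#' @param thresholds an [inSilicoThresholds()] object.
#' @return integer vote count, 0-3.
#' @examples
#' inSilicoVotes(1.0, 0.0, -6.923)  # 3
#' @export
inSilicoVotes <- function(polyphen = NA_real_, sift = NA_real_,
                          provean = NA_real_,
                          thresholds = inSilicoThresholds()) {
  if (is.na(polyphen) && is.na(sift) && is.na(provean))
    stop("no in-silico scores available", call. = FALSE)
  if (!is.na(polyphen) && (polyphen < 0 || polyphen > 1))
    stop("polyphen score must lie in [0, 1]", call. = FALSE)
  if (!is.na(sift) && (sift < 0 || sift > 1))
    stop("sift score must lie in [0, 1]", call. = FALSE)
  votes <- 0L
  if (!is.na(polyphen) && polyphen >= thresholds$polyphen_deleterious_min)
    votes <- votes + 1L
  if (!is.na(sift) && sift <= thresholds$sift_deleterious_max)
    votes <- votes + 1L
  if (!is.na(provean) && provean <= thresholds$provean_deleterious_max)
    votes <- votes + 1L
  votes
}

#' Classify a variant with Standards-and-Guidelines style rules
#'
#' Applies the classification cascade in order: (1) a variant observed in
#' more than 5% of control population alleles is excluded on frequency;
#' (2) a truncating consequence is pathogenic; (3) a missense variant
#' altering a well conserved residue (identity fraction at or above
#' `conservation_min`) with at least `min_deleterious_calls` deleterious
#' in-silico votes is significant; (4) anything else is not significant.
#' Frequency exclusion preempts all other rules.
#'
#' @param consequence consequence string (normalized internally).
#' @param control_allele_fraction fraction of control alleles carrying the
#'   variant.
#' @param conservation residue-identity fraction from
#'   [conservationScore()], or `NA` when no alignment evidence exists.
#' @param polyphen,sift,provean in-silico scores, each possibly `NA`.
#' @param thresholds an [inSilicoThresholds()] object.
#' @param max_control_allele_fraction frequency-exclusion cutoff
#'   (default 0.05; "more than 5%" excludes).
#' @return list of class `PathogenicityCall`: `category` (one of
#'   `excluded_frequency`, `pathogenic_truncating`, `significant_missense`,
#'   `not_significant`), `evidence` (identifiers of the rules that fired),
#'   `deleterious_votes`, `conservation`.
#' @examples
#' classifyVariant("missense_variant", 2 / 428, 1.0,
#'                 polyphen = 1.0, sift = 0.0, provean = -6.923)
#' @export
classifyVariant <- function(consequence, control_allele_fraction,
                            conservation = NA_real_,
                            polyphen = NA_real_, sift = NA_real_,
                            provean = NA_real_,
                            thresholds = inSilicoThresholds(),
                            max_control_allele_fraction = 0.05) {
  consequence <- normalizeConsequence(consequence)
  call <- function(category, evidence, votes = NA_integer_) {
    structure(list(category = category, evidence = evidence,
                   deleterious_votes = votes,
                   conservation = conservation),
              class = "PathogenicityCall")
  }
  if (control_allele_fraction > max_control_allele_fraction)
    return(call("excluded_frequency",
                sprintf("control_alleles>%.2f", max_control_allele_fraction)))
  if (isTruncating(consequence))
    return(call("pathogenic_truncating",
                sprintf("truncating:%s", consequence)))
  if (consequence == "missense_variant") {
    anyScore <- !(is.na(polyphen) && is.na(sift) && is.na(provean))
    votes <- if (anyScore)
      inSilicoVotes(polyphen, sift, provean, thresholds) else 0L
    conserved <- !is.na(conservation) &&
      conservation >= thresholds$conservation_min
    if (conserved && votes >= thresholds$min_deleterious_calls)
      return(call("significant_missense",
                  c("conserved_residue",
                    sprintf("insilico_votes>=%d",
                            thresholds$min_deleterious_calls)),
                  votes))
    return(call("not_significant", character(), votes))
  }
  call("not_significant", character(), NA_integer_)
}

#' Translate a codon substitution
#'
#' Translates reference and alternate codons with the standard genetic
#' code and reports whether the substitution is synonymous. Stop codons
#' translate to `"*"`.
#'
#' @param ref_codon,alt_codon 3-letter A/C/G/T codons.
#' @return list `ref_aa`, `alt_aa`, `synonymous`.
#' @examples
#' aminoAcidChange("GGA", "CGA")  # Gly -> Arg
#' @export
aminoAcidChange <- function(ref_codon, alt_codon) {
  chk <- function(x, what) {
    x <- toupper(x)
    if (nchar(x) != 3 || !grepl("^[ACGT]{3}$", x))
      stop(sprintf("%s must be a 3-letter A/C/G/T codon, got '%s'",
                   what, x), call. = FALSE)
    x
  }
  ref_codon <- chk(ref_codon, "ref_codon")
  alt_codon <- chk(alt_codon, "alt_codon")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  list(ref_aa = ref_aa, alt_aa = alt_aa, synonymous = ref_aa == alt_aa)
}
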