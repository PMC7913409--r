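#' Thresholds for the cosegregation filter cascade
#'
#' Bundles the discovery/validation filtering rules: a variant is carried
#' forward when it is present (carrier status, dosage >= 1) in at least
#' `min_affected_presence` of the informative affected cats, present in at
#' most `max_control_presence` of the informative control cats, observed in
#' at most `max_control_allele_fraction` of control alleles (the
#' per-allele phrasing used at validation and classification), and its
#' predicted impact falls in `retained_impacts`.
#'
#' Comparisons are inclusive/exclusive exactly as the rules are phrased:
#' "at least 50%" is `>=`, "5% or less" is `<=`, "more than 5%" excludes
#' with `>`, "less than 50%" excludes with `<`.
#'
#' @param min_affected_presence minimum carrier fraction among affected
#'   cats (default 0.50).
#' @param max_control_presence maximum carrier fraction among control cats
#'   (default 0.05).
#' @param max_control_allele_fraction maximum fraction of control alleles
#'   carrying the variant (default 0.05).
#' @param retained_impacts impact classes kept (default high + moderate).
#' @return a list of class `FilterThresholds`.
#' @export
filterThresholds <- function(min_affected_presence = 0.50,
                             max_control_presence = 0.05,
                             max_control_allele_fraction = 0.05,
                             retained_impacts = c("high", "moderate")) {
  fr <- c(min_affected_presence, max_control_presence,
          max_control_allele_fraction)
  if (any(fr < 0 | fr > 1))
    stop("threshold fractions must lie in [0, 1]", call. = FALSE)
  retained_impacts <- match.arg(retained_impacts, .IMPACTS,
                                several.ok = TRUE)
  structure(list(min_affected_presence = min_affected_presence,
                 max_control_presence = max_control_presence,
                 max_control_allele_fraction = max_control_allele_fraction,
                 retained_impacts = retained_impacts),
            class = "FilterThresholds")
}

## Phenotype mask helper: status vector aligned with gt names.
.groupIdx <- function(status, group) {
  group <- match.arg(group, .PHENOTYPES)
  which(status == group)
}

#' Carrier presence fraction within a phenotype group
#'
#' Fraction of informative (non-missing) samples of the given phenotype
#' that carry at least one variant allele. Missing genotypes are excluded
#' from numerator and denominator, never imputed.
#'
#' @param gt integer dosage vector for one site (0/1/2/NA), one entry per
#'   sample.
#' @param status phenotype vector aligned with `gt`
#'   (affected/unaffected/unknown).
#' @param group which phenotype group to evaluate (default `"affected"`).
#' @return carrier fraction in `[0, 1]`.
#' @examples
#' presenceFraction(c(0, 1, 2, 0), rep("affected", 4))  # 0.5
#' @export
presenceFraction <- function(gt, status, group = "affected") {
  idx <- .groupIdx(status, group)
  g <- gt[idx]
  g <- g[!is.na(g)]
  if (!length(g))
    stop(sprintf("no informative samples in group '%s'", group),
         call. = FALSE)
  sum(g >= 1L) / length(g)
}

#' Control allele fraction at one site
#'
#' Fraction of control (unaffected) alleles carrying the variant:
#' sum of control dosages over twice the number of informative control
#' samples.
#'
#' @inheritParams presenceFraction
#' @return allele fraction in `[0, 1]`.
#' @examples
#' # 2 heterozygous carriers among 214 controls -> 2/428
#' controlAlleleFraction(c(rep(1, 2), rep(0, 212)), rep("unaffected", 214))
#' @export
controlAlleleFraction <- function(gt, status) {
  idx <- .groupIdx(status, "unaffected")
  g <- gt[idx]
  g <- g[!is.na(g)]
  if (!length(g))
    stop("no informative control samples", call. = FALSE)
  sum(g) / (2 * length(g))
}

#' Is a variant's impact class retained?
#'
#' @param impact impact class string (high/moderate/low/modifier).
#' @param thresholds a [filterThresholds()] object.
#' @return logical.
#' @export
impactRetained <- function(impact, thresholds = filterThresholds()) {
  if (any(is.na(impact)))
    stop("impact must be populated", call. = FALSE)
  impact %in% thresholds$retained_impacts
}

#' Apply the discovery-cohort cosegregation filter
#'
#' Evaluates every variant against the discovery rules on the discovery
#' cohort: carrier presence in at least `min_affected_presence` of affected
#' cats, carrier presence in at most `max_control_presence` of control
#' cats (a per-cat criterion; with 13 discovery controls 5% is less than
#' one cat, so it effectively demands absence from all of them), and a
#' retained impact class. Returns one row per variant with the measured
#' fractions, the rules that failed, and the retention verdict (`retained`
#' is `TRUE` exactly when `reasons` is empty).
#'
#' @param x a [CohortGenotypes] object (the discovery cohort is selected by
#'   the manifest's `cohort` column).
#' @param thresholds a [filterThresholds()] object.
#' @return `data.frame`: `variant`, `affected_presence`,
#'   `control_presence`, `control_allele_fraction`, `retained`, `reasons`
#'   (semicolon-joined rule identifiers, `""` when retained).
#' @export
applyDiscoveryFilter <- function(x, thresholds = filterThresholds()) {
  disc <- subsetCohort(x, "discovery")
  status <- colData(disc)$phenotype
  if (!any(status == "affected") || !any(status == "unaffected"))
    stop("discovery cohort needs at least one affected and one unaffected sample",
         call. = FALSE)
  gt <- genotypes(disc)
  rd <- rowData(disc)
  n <- nrow(disc)
  ap <- cp <- caf <- numeric(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    ap[i] <- presenceFraction(gt[i, ], status, "affected")
    cp[i] <- presenceFraction(gt[i, ], status, "unaffected")
    caf[i] <- controlAlleleFraction(gt[i, ], status)
    r <- character()
    if (ap[i] < thresholds$min_affected_presence)
      r <- c(r, sprintf("affected_presence<%.2f",
                        thresholds$min_affected_presence))
    if (cp[i] > thresholds$max_control_presence)
      r <- c(r, sprintf("control_presence>%.2f",
                        thresholds$max_control_presence))
    if (!impactRetained(rd$impact[i], thresholds))
      r <- c(r, "impact_not_retained")
    reasons[i] <- paste(r, collapse = ";")
  }
  data.frame(variant = rownames(disc), affected_presence = ap,
             control_presence = cp, control_allele_fraction = caf,
             retained = !nzchar(reasons), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Screen variants against gene panels
#'
#' Splits a variant table by panel membership: `hits_in_known` are
#' variants in established disease genes (used as a negative screen — the
#' candidate search continues only because none explains the phenotype),
#' `prioritized` are variants in genes with plausible cardiac involvement.
#'
#' @param variants `data.frame` or `DataFrame` with a `gene` column.
#' @param known_panel character vector of established causative genes.
#' @param cardiac_panel character vector of cardiac-involvement genes.
#' @return list with `hits_in_known` and `prioritized` (both row subsets
#'   of `variants`).
#' @export
screenGenePanels <- function(variants, known_panel = character(),
                             cardiac_panel = character()) {
  variants <- as.data.frame(variants)
  list(hits_in_known = variants[variants$gene %in% known_panel, ,
                                drop = FALSE],
       prioritized = variants[variants$gene %in% cardiac_panel, ,
                              drop = FALSE])
}

#' Validation-cohort exclusion rule
#'
#' A candidate survives validation when it is present (carrier status) in
#' at least 50% of the affected validation cats and observed in no more
#' than 5% of the control population alleles; this stage uses the
#' per-allele control criterion.
#'
#' @param gt dosage vector for the candidate site over the validation
#'   cohort samples.
#' @param status phenotype vector aligned with `gt`.
#' @param thresholds a [filterThresholds()] object.
#' @return list with `retained` (logical), `reason` (`""` when retained),
#'   `affected_presence` and `control_allele_fraction`.
#' @export
validationExclusion <- function(gt, status,
                                thresholds = filterThresholds()) {
  ap <- presenceFraction(gt, status, "affected")
  caf <- controlAlleleFraction(gt, status)
  r <- character()
  if (ap < thresholds$min_affected_presence)
    r <- c(r, sprintf("affected_presence<%.2f",
                      thresholds$min_affected_presence))
  if (caf > thresholds$max_control_allele_fraction)
    r <- c(r, sprintf("control_alleles>%.2f",
                      thresholds$max_control_allele_fraction))
  list(retained = !length(r), reason = paste(r, collapse = ";"),
       affected_presence = ap, control_allele_fraction = caf)
}
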