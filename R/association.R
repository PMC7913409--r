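#' Build an allelic 2x2 contingency table from genotype counts
#'
#' Rows are affected / control, columns are variant / reference alleles:
#' `a` variant alleles in cases (het + 2 hom), `b` reference alleles in
#' cases, `c` and `d` likewise in controls.
#'
#' @param case_het,case_hom,case_n heterozygote, homozygote-alt and total
#'   genotyped counts among affected individuals.
#' @param control_het,control_hom,control_n the same among controls.
#' @return named integer vector `c(a, b, c, d)`.
#' @examples
#' buildAlleleTable(27, 35, 71, 2, 0, 214)  # (97, 45, 2, 426)
#' @export
buildAlleleTable <- function(case_het, case_hom, case_n,
                             control_het, control_hom, control_n) {
  if (case_het + case_hom > case_n || control_het + control_hom > control_n)
    stop("het + hom counts exceed group size", call. = FALSE)
  a <- case_het + 2L * case_hom
  b <- 2L * case_n - a
  c <- control_het + 2L * control_hom
  d <- 2L * control_n - c
  tab <- c(a = a, b = b, c = c, d = d)
  if (any(tab < 0)) stop("negative derived cell count", call. = FALSE)
  as.integer(tab) |> setNames(c("a", "b", "c", "d"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by the point-probability
#' ("minimum likelihood") method: with all margins fixed, p is the sum of
#' hypergeometric point probabilities of every table whose probability
#' does not exceed that of the observed table (a relative tolerance of
#' 1e-7 absorbs floating-point ties). Probabilities are evaluated through
#' cached log-factorials so tables with margins of a few hundred alleles
#' remain exact. A table with an empty row or column carries no
#' information; its p is 1 by convention and the result is flagged.
#'
#' @param a,b,c,d cell counts (row 1 = cases, column 1 = variant allele).
#'   Alternatively `a` may be a length-4 vector or 2x2 matrix.
#' @return list: `p` (two-sided p-value, clipped to `[0, 1]`),
#'   `zero_margin` (logical flag).
#' @examples
#' fisherExactTwoSided(97, 45, 2, 426)$p   # << 1e-4
#' fisherExactTwoSided(3, 1, 1, 3)$p       # 34/70
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- as.integer(a)
    if (length(x) != 4) stop("need 4 cell counts", call. = FALSE)
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0)
    stop("contingency table is empty", call. = FALSE)
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(p = 1.0, zero_margin = TRUE))
  N <- m + n
  lf <- lgamma(seq_len(N + 1))      # lf[x + 1] = log(x!)
  lchoose2 <- function(nn, kk) lf[nn + 1] - lf[kk + 1] - lf[nn - kk + 1]
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  lp <- lchoose2(m, xs) + lchoose2(n, k - xs) - lchoose2(N, k)
  lobs <- lp[match(a, xs)]
  keep <- lp <= lobs + log1p(1e-7)
  p <- sum(exp(lp[keep]))
  list(p = min(1.0, max(0.0, p)), zero_margin = FALSE)
}

#' Penetrance of a candidate variant
#'
#' The probability that a carrier expresses the phenotype, estimated as
#' affected carriers over all carriers in the combined genotyped
#' population.
#'
#' @param affected_carriers,unaffected_carriers carrier counts by
#'   phenotype.
#' @return list: `penetrance` (fraction, `NA` when undefined),
#'   `defined` (logical).
#' @examples
#' penetrance(62, 2)  # 62/64
#' @export
penetrance <- function(affected_carriers, unaffected_carriers) {
  total <- affected_carriers + unaffected_carriers
  if (total <= 0)
    return(list(penetrance = NA_real_, defined = FALSE))
  list(penetrance = affected_carriers / total, defined = TRUE)
}

#' Relative risk of disease in carriers versus non-carriers
#'
#' Risk ratio from a carrier-level table: disease risk among carriers,
#' `a / (a + b)`, over disease risk among non-carriers, `c / (c + d)`,
#' with `a` affected carriers, `b` unaffected carriers, `c` affected
#' non-carriers and `d` unaffected non-carriers. When no non-carrier is
#' affected the ratio is infinite (flagged); an optional Haldane
#' correction adds 0.5 to every cell instead.
#'
#' @param affected_carriers,unaffected_carriers,affected_noncarriers,unaffected_noncarriers
#'   carrier-level counts.
#' @param haldane apply the 0.5 continuity correction (default `FALSE`).
#' @return list: `relative_risk` (positive real or `Inf`), `flag`
#'   (`""`, `"infinite"`, or `"undefined"` when both risks are zero).
#' @examples
#' relativeRisk(62, 2, 9, 212)  # (62/64) / (9/221)
#' @export
relativeRisk <- function(affected_carriers, unaffected_carriers,
                         affected_noncarriers, unaffected_noncarriers,
                         haldane = FALSE) {
  a <- affected_carriers; b <- unaffected_carriers
  c <- affected_noncarriers; d <- unaffected_noncarriers
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  risk_car <- if (a + b > 0) a / (a + b) else NA_real_
  risk_non <- if (c + d > 0) c / (c + d) else NA_real_
  if (is.na(risk_car) || is.na(risk_non) ||
      (risk_car == 0 && risk_non == 0))
    return(list(relative_risk = NA_real_, flag = "undefined"))
  if (risk_non == 0)
    return(list(relative_risk = Inf, flag = "infinite"))
  list(relative_risk = risk_car / risk_non, flag = "")
}

#' Allelic association of one variant in a case-control cohort
#'
#' Builds the allelic 2x2 table from the dosage vector, runs the exact
#' test, and derives allele frequencies, carrier-based penetrance and the
#' carrier-vs-non-carrier relative risk. Missing genotypes are excluded
#' throughout. No multiple-testing correction is applied by default; a
#' Bonferroni divisor can be supplied for a candidate slate.
#'
#' @param gt dosage vector (0/1/2/NA) across the cohort samples.
#' @param status phenotype vector aligned with `gt`.
#' @param alpha significance level (default 0.05).
#' @param bonferroni_m optional number of tests; when > 1 the significance
#'   threshold becomes `alpha / bonferroni_m`.
#' @return list of class `AssociationResult`: `p_two_sided`, `model`
#'   (`"allelic"`), `table`, `case_allele_freq`, `control_allele_freq`,
#'   `penetrance`, `relative_risk`, `significant`, counts
#'   (`case_het`, `case_hom`, `case_n`, `control_het`, `control_hom`,
#'   `control_n`).
#' @export
associateVariant <- function(gt, status, alpha = 0.05, bonferroni_m = 1L) {
  aff <- gt[status == "affected"]
  con <- gt[status == "unaffected"]
  aff <- aff[!is.na(aff)]
  con <- con[!is.na(con)]
  if (!length(aff) || !length(con))
    stop("association needs informative samples in both groups",
         call. = FALSE)
  case_het <- sum(aff == 1L); case_hom <- sum(aff == 2L)
  control_het <- sum(con == 1L); control_hom <- sum(con == 2L)
  tab <- buildAlleleTable(case_het, case_hom, length(aff),
                          control_het, control_hom, length(con))
  ft <- fisherExactTwoSided(tab)
  pen <- penetrance(case_het + case_hom, control_het + control_hom)
  rr <- relativeRisk(case_het + case_hom, control_het + control_hom,
                     length(aff) - case_het - case_hom,
                     length(con) - control_het - control_hom)
  thresh <- alpha / max(1L, as.integer(bonferroni_m))
  structure(list(
    p_two_sided = ft$p, model = "allelic", table = tab,
    zero_margin = ft$zero_margin,
    case_allele_freq = tab[["a"]] / (tab[["a"]] + tab[["b"]]),
    control_allele_freq = tab[["c"]] / (tab[["c"]] + tab[["d"]]),
    penetrance = pen$penetrance, relative_risk = rr$relative_risk,
    rr_flag = rr$flag, significant = ft$p < thresh, alpha = thresh,
    case_het = case_het, case_hom = case_hom, case_n = length(aff),
    control_het = control_het, control_hom = control_hom,
    control_n = length(con)), class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("Allelic association (Fisher exact, two-sided)\n"))
  cat(sprintf("  table (a,b,c,d): %s\n", paste(x$table, collapse = ", ")))
  cat(sprintf("  p = %.4g%s\n", x$p_two_sided,
              if (x$significant) "  (significant)" else ""))
  cat(sprintf("  allele freq: cases %.4f, controls %.4f\n",
              x$case_allele_freq, x$control_allele_freq))
  cat(sprintf("  penetrance %.3f, relative risk %.3g\n",
              x$penetrance, x$relative_risk))
  invisible(x)
}
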