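## Fixture builders and independent oracles shared across the suite.

writeTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

manifestDF <- function(n_aff = 2, n_con = 2, cohort = "discovery",
                       lv = TRUE) {
  df <- data.frame(
    sample_id = c(sprintf("A%02d", seq_len(n_aff)),
                  sprintf("C%02d", seq_len(n_con))),
    breed = c(rep("Sphynx", n_aff), rep("Domestic Short Hair", n_con)),
    phenotype = c(rep("affected", n_aff), rep("unaffected", n_con)),
    cohort = cohort, stringsAsFactors = FALSE)
  if (lv)
    df$lv_wall_cm <- c(rep(0.7, n_aff), rep(0.3, n_con))
  df
}

## Minimal hand-written VCF 4.2 text for reader tests.
writeVcfText <- function(samples, rows, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Consequence | IMPACT | Gene'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r) {
    ann <- sprintf("ANN=%s|%s|%s|%s", r$alt, r$consequence,
                   toupper(r$impact), r$gene)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ann, "GT",
            r$gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

vcfRow <- function(chrom = "A3", pos = 100, ref = "G", alt = "C",
                   gene = "ALMS1", consequence = "missense_variant",
                   impact = "moderate", gts = c("0/0", "0/1")) {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
       consequence = consequence, impact = impact, gts = gts)
}

## Independent Fisher oracle: exhaustive enumeration at fixed margins
## through choose() arithmetic (a different route than the package's
## log-factorial implementation).
bruteFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1.0)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pobs <- probs[xs == a]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

## Brute-force discovery-filter oracle: explicit per-sample loops,
## independent of the package's vectorized bookkeeping.
bruteDiscoveryFilter <- function(gt, phenotype, impact,
                                 min_aff = 0.5, max_con = 0.05,
                                 impacts = c("high", "moderate")) {
  out <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    aff_inf <- aff_car <- con_inf <- con_car <- 0
    for (j in seq_len(ncol(gt))) {
      g <- gt[i, j]
      if (is.na(g)) next
      if (phenotype[j] == "affected") {
        aff_inf <- aff_inf + 1
        if (g >= 1) aff_car <- aff_car + 1
      } else if (phenotype[j] == "unaffected") {
        con_inf <- con_inf + 1
        if (g >= 1) con_car <- con_car + 1
      }
    }
    out[i] <- (aff_car / aff_inf >= min_aff) &&
      (con_car / con_inf <= max_con) && (impact[i] %in% impacts)
  }
  out
}

## Small random cohort as a CohortGenotypes object.
randomSmallCohort <- function(n_var = 10, n_aff = 4, n_con = 4) {
  man <- manifestDF(n_aff, n_con, lv = FALSE)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), n_var * (n_aff + n_con),
                      replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
               nrow = n_var)
  ## keep every variant informative in both groups
  gt[, 1][is.na(gt[, 1])] <- 0L
  gt[, n_aff + 1][is.na(gt[, n_aff + 1])] <- 0L
  variants <- data.frame(
    chrom = "A1", pos = seq_len(n_var) * 100L,
    ref = "A", alt = "G", gene = sprintf("G%03d", seq_len(n_var)),
    consequence = "missense_variant",
    impact = sample(c("high", "moderate", "low", "modifier"), n_var,
                    replace = TRUE), stringsAsFactors = FALSE)
  CohortGenotypes(gt, variants, man)
}

## Write a ready-to-run pipeline config over simulateCohort() output.
writeSimConfig <- function(paths, dir, seed = 1, extra = character()) {
  cfg <- c(sprintf("manifest: %s", paths[["manifest"]]),
           sprintf("vcf: %s", paths[["vcf"]]),
           sprintf("annotations: %s", paths[["annotations"]]),
           sprintf("alignment: %s", paths[["alignment"]]),
           sprintf("known_panel: %s", paths[["known_panel"]]),
           sprintf("cardiac_panel: %s", paths[["cardiac_panel"]]),
           sprintf("ki67_counts: %s", paths[["ki67"]]),
           sprintf("seed: %d", seed), extra)
  p <- file.path(dir, "config.yaml")
  writeLines(cfg, p)
  p
}
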