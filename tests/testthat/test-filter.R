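test_that("presence and allele fractions follow the carrier conventions", {
  aff4 <- rep("affected", 4)
  expect_equal(presenceFraction(c(0, 1, 2, 0), aff4), 0.5)
  ## missing genotypes leave numerator and denominator
  expect_equal(presenceFraction(c(1, 2, NA, 0), aff4), 2 / 3)
  ## validation-scale carrier fraction: 62 of 71 affected cats
  gt <- c(rep(1, 27), rep(2, 35), rep(0, 9))
  expect_equal(presenceFraction(gt, rep("affected", 71)), 62 / 71)
  expect_error(presenceFraction(c(NA, NA), rep("affected", 2)),
               "no informative")

  con <- rep("unaffected", 214)
  expect_equal(controlAlleleFraction(c(1, 1, rep(0, 212)), con), 2 / 428)
  expect_equal(controlAlleleFraction(rep(0, 214), con), 0)
  expect_equal(controlAlleleFraction(c(2, rep(0, 9)),
                                     rep("unaffected", 10)), 0.1)
  expect_error(controlAlleleFraction(c(0, 1), rep("affected", 2)),
               "no informative")
})

test_that("impact retention matches the moderate/high rule", {
  thr <- filterThresholds()
  expect_true(impactRetained("high", thr))
  expect_true(impactRetained("moderate", thr))
  expect_false(impactRetained("low", thr))
  expect_false(impactRetained("modifier", thr))
  expect_error(impactRetained(NA_character_, thr), "populated")
  expect_error(filterThresholds(min_affected_presence = 1.2), "\\[0, 1\\]")
})

test_that("discovery filter applies all three rules with named reasons", {
  man <- manifestDF(10, 13, lv = FALSE)
  gt <- rbind(
    c(rep(1, 10), rep(0, 13)),              # perfect cosegregation
    c(rep(1, 4), rep(0, 6), rep(0, 13)),    # only 40% of affecteds
    c(rep(1, 10), 1, 1, rep(0, 11)),        # 2/13 controls = 15.4%
    c(rep(2, 10), rep(0, 13)))              # low impact
  variants <- data.frame(chrom = "A1", pos = 1:4 * 10L, ref = "G",
                         alt = "C", gene = paste0("G", 1:4),
                         consequence = c("missense_variant",
                                         "missense_variant",
                                         "missense_variant",
                                         "synonymous_variant"),
                         impact = c("moderate", "moderate", "moderate",
                                    "low"))
  x <- CohortGenotypes(gt, variants, man)
  rep <- applyDiscoveryFilter(x)
  expect_equal(rep$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rep$reasons[1], "")
  expect_match(rep$reasons[2], "affected_presence<0.50")
  expect_match(rep$reasons[3], "control_presence>0.05")
  expect_match(rep$reasons[4], "impact_not_retained")
  ## retained is true exactly when no rule fired
  expect_equal(rep$retained, !nzchar(rep$reasons))
  expect_equal(rep$control_presence[3], 2 / 13)
})

test_that("discovery filter agrees with a brute-force oracle on small cohorts", {
  set.seed(101)
  for (rep_i in 1:25) {
    n_var <- sample(3:20, 1)
    x <- randomSmallCohort(n_var, n_aff = sample(2:5, 1),
                           n_con = sample(2:5, 1))
    got <- applyDiscoveryFilter(x)
    want <- bruteDiscoveryFilter(genotypes(x),
                                 sampleInfo(x)$phenotype,
                                 variantInfo(x)$impact)
    expect_equal(got$retained, want)
  }
})

test_that("filter retention is monotone in its thresholds", {
  set.seed(202)
  x <- randomSmallCohort(20, 5, 5)
  grid <- seq(0, 1, by = 0.25)
  prev <- NULL
  for (m in grid) {
    r <- applyDiscoveryFilter(x, filterThresholds(min_affected_presence = m))
    keep <- r$variant[r$retained]
    if (!is.null(prev)) expect_true(all(keep %in% prev))
    prev <- keep
  }
  prev <- NULL
  for (m in rev(grid)) {
    r <- applyDiscoveryFilter(x, filterThresholds(max_control_presence = m))
    keep <- r$variant[r$retained]
    if (!is.null(prev)) expect_true(all(keep %in% prev))
    prev <- keep
  }
})

test_that("variants constructed to satisfy every rule are always retained", {
  for (seed in 1:100) {
    set.seed(seed)
    n_aff <- sample(2:6, 1); n_con <- sample(2:6, 1)
    man <- manifestDF(n_aff, n_con, lv = FALSE)
    ## carriers in all affecteds, absent from all controls, moderate impact
    gt <- matrix(c(sample(1:2, n_aff, replace = TRUE), rep(0L, n_con)),
                 nrow = 1)
    v <- data.frame(chrom = "A1", pos = 10L, ref = "G", alt = "C",
                    gene = "G1", consequence = "missense_variant",
                    impact = "moderate")
    r <- applyDiscoveryFilter(CohortGenotypes(gt, v, man))
    expect_true(r$retained)
  }
})

test_that("gene panel screening splits known hits from prioritized genes", {
  v <- data.frame(gene = c("MYBPC3", "ALMS1", "GENE7"),
                  variant = c("v1", "v2", "v3"))
  known <- c("MYBPC3", "MYH7", "TNNI3", "MYL2", "MYL3", "TPM1", "ACTC1")
  s <- screenGenePanels(v, known, c("ALMS1", "GENE9"))
  expect_equal(s$hits_in_known$gene, "MYBPC3")
  expect_equal(s$prioritized$gene, "ALMS1")
  expect_equal(nrow(screenGenePanels(v, known, character())$prioritized), 0)
})

test_that("validation exclusion uses per-cat cases and per-allele controls", {
  status <- c(rep("affected", 71), rep("unaffected", 214))
  gt <- c(rep(1, 27), rep(2, 35), rep(0, 9), rep(1, 2), rep(0, 212))
  r <- validationExclusion(gt, status)
  expect_true(r$retained)
  expect_equal(r$affected_presence, 62 / 71)
  expect_equal(r$control_allele_fraction, 2 / 428)

  ## 30% affected presence -> excluded on the 50% rule
  gt2 <- c(rep(1, 21), rep(0, 50), rep(0, 214))
  r2 <- validationExclusion(gt2, status)
  expect_false(r2$retained)
  expect_match(r2$reason, "affected_presence<0.50")

  ## control allele fraction just above 5% -> excluded; exactly 5% kept
  gt3 <- c(rep(1, 71), rep(1, 26), rep(0, 188))   # 26/428 > 0.05
  r3 <- validationExclusion(gt3, status)
  expect_false(r3$retained)
  expect_match(r3$reason, "control_alleles>0.05")
  gt4 <- c(rep(1, 71), rep(1, 20), rep(0, 194))   # 20/428 < 0.05
  expect_true(validationExclusion(gt4, status)$retained)
})
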