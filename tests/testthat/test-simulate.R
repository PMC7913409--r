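test_that("simulation config validates feasibility and mixes", {
  expect_s3_class(simConfig(), "SimulationConfig")
  expect_error(simConfig(causal_case_het = 80, n_affected_validation = 71),
               "infeasible genotype counts")
  expect_error(simConfig(impact_mix = c(high = 1, moderate = 1,
                                        low = 0, modifier = 0)),
               "sum to 1")
  expect_error(simConfig(ki67_mean_control = -1), "non-negative")
})

test_that("simulated outputs are byte-identical for a repeated seed", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulateCohort(simConfig(seed = 5, n_background_variants = 10), d1)
  s2 <- simulateCohort(simConfig(seed = 5, n_background_variants = 10), d2)
  for (k in names(s1$paths))
    expect_identical(readLines(s1$paths[[k]]), readLines(s2$paths[[k]]),
                     label = k)
  s3 <- simulateCohort(simConfig(seed = 6, n_background_variants = 10))
  expect_false(identical(genotypes(s1$cohort), genotypes(s3$cohort)))
})

test_that("the planted causal variant matches the configured counts exactly", {
  sim <- simulateCohort(simConfig(seed = 3))
  x <- sim$cohort
  man <- sampleInfo(x)
  g <- genotypes(x)[1, ]
  va <- man$cohort == "validation" & man$phenotype == "affected"
  vc <- man$cohort == "validation" & man$phenotype == "unaffected"
  expect_equal(sum(g[va] == 1), 27)
  expect_equal(sum(g[va] == 2), 35)
  expect_equal(sum(g[vc] == 1), 2)
  expect_equal(sum(g[vc] == 2), 0)
  ## discovery: all affecteds carry, all controls clean
  da <- man$cohort == "discovery" & man$phenotype == "affected"
  dc <- man$cohort == "discovery" & man$phenotype == "unaffected"
  expect_true(all(g[da] >= 1))
  expect_true(all(g[dc] == 0))
  ## causal annotation row carries the deleterious score triplet
  ann <- sim$annotations[1, ]
  expect_equal(ann$gene, "ALMS1")
  expect_gte(ann$polyphen, 0.85)
  expect_lte(ann$sift, 0.05)
  expect_lte(ann$provean, -2.5)
  ## causal alignment column is a fully conserved glycine
  expect_equal(conservationScore(sim$alignment, ann$aln_column, "G"), 1.0)
})

test_that("score generator modes behave as designed", {
  causal <- simulateInSilicoScores(TRUE, seed = 11)
  expect_equal(inSilicoVotes(causal$polyphen, causal$sift,
                             causal$provean), 3L)
  expect_identical(causal, simulateInSilicoScores(TRUE, seed = 11))
  ## benign mode rarely reaches the 2-of-3 consensus
  votes <- vapply(1:1000, function(s) {
    b <- simulateInSilicoScores(FALSE, seed = s)
    inSilicoVotes(b$polyphen, b$sift, b$provean)
  }, integer(1))
  expect_lt(mean(votes >= 2), 0.02)
})

test_that("Ki67 generator hits the configured group means", {
  k <- simulateKi67(simConfig(seed = 2))
  expect_equal(nrow(k), 7)
  expect_equal(as.vector(table(k$group)[c("hcm", "control")]), c(4L, 3L))
  expect_identical(k, simulateKi67(simConfig(seed = 2)))
  ## degenerate Poisson(0)
  k0 <- simulateKi67(simConfig(ki67_mean_control = 0, seed = 2))
  expect_true(all(k0$slide_sum[k0$group == "control"] == 0))
  ## law of large numbers at 10,000 affected cats
  big <- simulateKi67(simConfig(n_ki67_hcm = 10000L, seed = 4))
  expect_lt(abs(mean(big$slide_sum[big$group == "hcm"]) - 10), 0.1)
})

test_that("filter outcomes match ground truth across seeds", {
  for (seed in 1:20) {
    sim <- simulateCohort(simConfig(seed = seed,
                                    n_background_variants = 20))
    filt <- applyDiscoveryFilter(sim$cohort)
    expect_equal(filt$retained,
                 sim$truth$expect_discovery_retained[
                   match(filt$variant, sim$truth$variant)],
                 label = sprintf("seed %d", seed))
    val <- subsetCohort(sim$cohort, "validation")
    st <- sampleInfo(val)$phenotype
    for (i in seq_len(nrow(val))) {
      r <- validationExclusion(genotypes(val)[i, ], st)
      expect_equal(r$retained, sim$truth$expect_validation_retained[i])
    }
    ## the causal variant always passes by construction
    expect_true(filt$retained[1])
    expect_true(sim$truth$expect_validation_retained[1])
  }
})

test_that("planted carrier frequencies are recovered at large cohorts", {
  cfg <- simConfig(n_affected_validation = 5000L,
                   n_control_validation = 5000L,
                   causal_case_het = 1894L, causal_case_hom = 2456L,
                   causal_control_het = 47L,
                   n_background_variants = 5L, seed = 8)
  sim <- simulateCohort(cfg)
  man <- sampleInfo(sim$cohort)
  val <- man$cohort == "validation"
  g <- genotypes(sim$cohort)[1, val]
  st <- man$phenotype[val]
  expect_lt(abs(presenceFraction(g, st, "affected") - 0.87), 0.02)
  con_car <- mean(g[st == "unaffected"] >= 1)
  expect_lt(abs(con_car - 0.0093), 0.02)
})

test_that("a disabled causal effect is rarely flagged significant", {
  ## null calibration at study-scale cohort sizes: both groups share the
  ## causal carrier frequency
  set.seed(77)
  n_rep <- 400
  sig <- 0
  for (i in seq_len(n_rep)) {
    p0 <- 0.2
    gt <- rbinom(285, 2, p0)
    status <- c(rep("affected", 71), rep("unaffected", 214))
    if (associateVariant(gt, status)$significant) sig <- sig + 1
  }
  expect_lte(sig / n_rep, 0.07)
})
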