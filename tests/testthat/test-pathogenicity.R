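test_that("truncating consequences match the guideline list", {
  yes <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
           "splice_donor_variant", "start_lost", "exon_deletion")
  expect_true(all(isTruncating(yes)))
  no <- c("missense_variant", "synonymous_variant", "intron_variant",
          "inframe_insertion")
  expect_false(any(isTruncating(no)))
  ## dialect variants normalize before the lookup
  expect_true(isTruncating("Stop Gain"))
  expect_true(isTruncating("frameshift indel"))
})

test_that("conservation excludes gaps and errors on all-gap columns", {
  aln <- rbind(strsplit("GGG-", "")[[1]], strsplit("GGG-", "")[[1]],
               strsplit("G-A-", "")[[1]], strsplit("GA--", "")[[1]])
  expect_equal(conservationScore(aln, 1, "G"), 1.0)
  expect_equal(conservationScore(aln, 2, "G"), 2 / 3)
  ## one gap excluded from the denominator
  expect_equal(conservationScore(aln, 3, "G"), 2 / 3)
  expect_error(conservationScore(aln, 4, "G"), "entirely gaps")
  expect_error(conservationScore(aln, 9, "G"), "outside alignment")

  big <- matrix("G", 10, 1); big[10, 1] <- "A"
  expect_equal(conservationScore(big, 1, "G"), 0.9)
})

test_that("in-silico votes count present deleterious calls only", {
  ## the published evidence triplet: all three deleterious
  expect_equal(inSilicoVotes(1.0, 0.0, -6.923), 3L)
  expect_equal(inSilicoVotes(0.0, 1.0, 0.0), 0L)
  expect_equal(inSilicoVotes(0.95, 0.2, -3.0), 2L)
  ## missing scores are non-votes
  expect_equal(inSilicoVotes(1.0, NA, NA), 1L)
  expect_error(inSilicoVotes(NA, NA, NA), "no in-silico scores")
  expect_error(inSilicoVotes(polyphen = 2), "\\[0, 1\\]")

  ## monotone: pushing any score to the deleterious side never loses votes
  set.seed(7)
  for (i in 1:50) {
    pp <- runif(1); si <- runif(1); pr <- runif(1, -8, 3)
    v0 <- inSilicoVotes(pp, si, pr)
    expect_gte(inSilicoVotes(min(1, pp + runif(1, 0, 1 - pp)), si, pr), v0)
    expect_gte(inSilicoVotes(pp, si * runif(1), pr), v0)
    expect_gte(inSilicoVotes(pp, si, pr - runif(1, 0, 5)), v0)
  }
})

test_that("classification applies the rules in order with preemption", {
  ## the published candidate evidence
  call <- classifyVariant("missense_variant", 2 / 428, 1.0,
                          polyphen = 1.0, sift = 0.0, provean = -6.923)
  expect_equal(call$category, "significant_missense")
  expect_equal(call$deleterious_votes, 3L)

  ## frequency exclusion preempts everything, even truncation
  expect_equal(classifyVariant("stop_gained", 0.06)$category,
               "excluded_frequency")
  expect_equal(classifyVariant("stop_gained", 0.0)$category,
               "pathogenic_truncating")

  ## exhaustive boundary grid: exactly one category each time
  cats <- c("excluded_frequency", "pathogenic_truncating",
            "significant_missense", "not_significant")
  for (caf in c(0, 0.05, 0.050001, 0.2))
    for (cons in c("stop_gained", "missense_variant", "synonymous_variant"))
      for (conserved in c(0.5, 0.90, 1.0))
        for (votes in list(c(1, 1, 0), c(1, 0, -9), c(0.95, 0.01, -3))) {
          cl <- classifyVariant(cons, caf, conserved,
                                polyphen = votes[1], sift = votes[2],
                                provean = votes[3])
          expect_true(cl$category %in% cats)
          if (caf > 0.05) expect_equal(cl$category, "excluded_frequency")
          else if (cons == "stop_gained")
            expect_equal(cl$category, "pathogenic_truncating")
          else if (cons == "synonymous_variant")
            expect_equal(cl$category, "not_significant")
          else {
            nv <- inSilicoVotes(votes[1], votes[2], votes[3])
            expect_equal(cl$category == "significant_missense",
                         conserved >= 0.90 && nv >= 2)
          }
        }

  ## missense without conservation evidence cannot reach significance
  expect_equal(classifyVariant("missense_variant", 0, NA,
                               polyphen = 1, sift = 0,
                               provean = -9)$category, "not_significant")
})

test_that("codon translation reports residues and synonymy", {
  gr <- aminoAcidChange("GGA", "CGA")
  expect_equal(gr[c("ref_aa", "alt_aa")], list(ref_aa = "G", alt_aa = "R"))
  expect_false(gr$synonymous)
  expect_true(aminoAcidChange("GGG", "GGC")$synonymous)
  stop <- aminoAcidChange("TAC", "TAA")
  expect_equal(stop$alt_aa, "*")
  expect_false(stop$synonymous)
  expect_error(aminoAcidChange("GG", "CGA"), "3-letter")
  expect_error(aminoAcidChange("GGN", "CGA"), "3-letter")
})
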