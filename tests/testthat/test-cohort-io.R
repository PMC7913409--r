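test_that("manifest parsing validates tokens, ids and wall thickness", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   breed = c("Sphynx", "Sphynx", "Persian"),
                   phenotype = c("Affected", "unaffected ", "unknown"),
                   cohort = c("discovery", "Discovery", "population"),
                   lv_wall_cm = c(0.8, 0.35, NA))
  man <- readManifest(writeTSV(df))
  expect_equal(nrow(man), 3)
  ## case-insensitive normalization after trimming
  expect_equal(man$phenotype, c("affected", "unaffected", "unknown"))
  expect_equal(as.vector(table(man$cohort)[c("discovery", "population")]),
               c(2L, 1L))

  dup <- df; dup$sample_id <- c("s1", "s1", "s3")
  expect_error(readManifest(writeTSV(dup)), "duplicate sample_id.*s1")

  bad <- df; bad$phenotype[2] <- "sick"
  expect_error(readManifest(writeTSV(bad)), "unknown phenotype.*row 2")

  ## echocardiographic thresholds are enforced
  thin <- df; thin$lv_wall_cm[1] <- 0.5
  expect_error(readManifest(writeTSV(thin)), "0\\.6")
  thick <- df; thick$lv_wall_cm[2] <- 0.45
  expect_error(readManifest(writeTSV(thick)), "0\\.4")
})

test_that("VCF genotypes decode to dosage with missing and phase handled", {
  man <- manifestDF(2, 2)
  vcf <- writeVcfText(man$sample_id, list(
    vcfRow(pos = 100, gts = c("0/0", "0/1", "1/1", "0/0")),
    vcfRow(pos = 200, ref = "A", alt = "T", gene = "GENE1",
           consequence = "stop_gained", impact = "high",
           gts = c("./.", "0|1", ".", "1|1"))))
  x <- readCohortVCF(vcf, man)
  expect_s4_class(x, "CohortGenotypes")
  expect_equal(unname(genotypes(x)[1, ]), c(0L, 1L, 2L, 0L))
  expect_equal(unname(genotypes(x)[2, ]), c(NA_integer_, 1L, NA, 2L))
  expect_equal(variantInfo(x)$impact, c("moderate", "high"))
  expect_equal(variantInfo(x)$gene, c("ALMS1", "GENE1"))
})

test_that("multiallelic sites and unknown samples are rejected", {
  man <- manifestDF(1, 1)
  multi <- writeVcfText(man$sample_id, list(
    vcfRow(alt = "C,T", gts = c("0/1", "0/2"))))
  expect_error(readCohortVCF(multi, man), "multiallelic.*split before input")

  vcf <- writeVcfText(c(man$sample_id, "GHOST"), list(
    vcfRow(gts = c("0/0", "0/1", "1/1"))))
  expect_error(readCohortVCF(vcf, man), "absent from manifest.*GHOST")
})

test_that("VCF round trip preserves all dosage values including missing", {
  set.seed(42)
  for (rep in 1:5) {
    x <- randomSmallCohort(n_var = 8, n_aff = 3, n_con = 3)
    path <- tempfile(fileext = ".vcf")
    writeCohortVCF(x, path)
    y <- readCohortVCF(path, sampleInfo(x))
    expect_identical(genotypes(y), genotypes(x))
    expect_identical(rownames(y), rownames(x))
    ## dosage conservation: het + 2*hom equals the summed alt count
    gt <- genotypes(y)
    for (i in seq_len(nrow(gt))) {
      g <- gt[i, ][!is.na(gt[i, ])]
      expect_identical(sum(g == 1L) + 2L * sum(g == 2L), as.integer(sum(g)))
    }
  }
})

test_that("alignment reader enforces shape and reports offenders", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">cat", "MGKL-", ">human", "MGKLS", ">mouse", "MGRLS"), p)
  aln <- readAlignment(p)
  expect_equal(dim(aln), c(3, 5))
  expect_equal(unname(aln["cat", 5]), "-")

  writeLines(c(">cat", "MGKL", ">human", "MGKLS"), p)
  expect_error(readAlignment(p), "unequal aligned lengths.*human")

  writeLines(character(), p)
  expect_error(readAlignment(p), "no sequences")

  writeLines(c(">only", "MGKLS"), p)
  expect_error(readAlignment(p), "at least 2")
})

test_that("annotation table and ki67 readers validate their schemas", {
  ann <- data.frame(chrom = "A3", pos = 1, ref = "G", alt = "C",
                    gene = "ALMS1", consequence = "nonsynonymous variant",
                    impact = "MODERATE", polyphen = 1.0, sift = 0.0,
                    provean = -6.923)
  tab <- readAnnotationTable(writeTSV(ann))
  expect_equal(tab$consequence, "missense_variant")
  expect_equal(tab$impact, "moderate")
  ann$polyphen <- 1.5
  expect_error(readAnnotationTable(writeTSV(ann)), "polyphen.*\\[0, 1\\]")

  k <- data.frame(cat_id = c("h1", "c1"), group = c("HCM", "control"),
                  area1 = c(2, 0), area2 = c(3, 1), area3 = c(1, 0),
                  area4 = c(0, 0), area5 = c(4, 0))
  counts <- readKi67Counts(writeTSV(k))
  expect_equal(counts$slide_sum, c(10L, 1L))
  expect_equal(counts$group, c("hcm", "control"))
  expect_error(readKi67Counts(writeTSV(k[, -4])), "area2")
})
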