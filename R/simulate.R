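#' @importFrom Biostrings AAStringSet writeXStringSet
NULL

.CONTROL_BREEDS <- c("Bengal", "Birman", "British Short Hair", "Burmese",
                     "Domestic Short Hair", "Domestic Long Hair",
                     "Himalayan", "Maine Coon", "Manx",
                     "Norwegian Forest Cat", "Persian", "Ragdoll",
                     "Scottish Fold", "Siamese")

.KNOWN_HCM_PANEL <- c("MYH7", "MYBPC3", "TNNI3", "MYL2", "MYL3", "TPM1",
                      "ACTC1")

#' Configuration of a simulated case-control cohort
#'
#' Defaults reproduce the study design the pipeline targets: a
#' whole-genome discovery cohort of 14 affected Sphynx and 13 unaffected
#' control cats, a genotyping validation cohort of 71 affected Sphynx and
#' 214 non-Sphynx controls, and a planted causal missense variant carried
#' by exactly 27 heterozygous and 35 homozygous affected cats and 2
#' heterozygous controls. Background variants are null (one shared allele
#' frequency per site in both groups, drawn from a rare-skewed Beta) with
#' a mixed impact profile; Ki67 counts are Poisson per area with per-cat
#' sums averaging 10 (HCM) versus 1 (control).
#'
#' @param n_affected_discovery,n_control_discovery discovery cohort sizes.
#' @param n_affected_validation,n_control_validation validation cohort
#'   sizes.
#' @param causal_case_het,causal_case_hom planted het / hom-alt counts
#'   among affected validation cats.
#' @param causal_control_het planted het count among validation controls
#'   (homozygous controls are not planted).
#' @param n_background_variants number of null background variants.
#' @param impact_mix named fractions over high/moderate/low/modifier,
#'   summing to 1.
#' @param bg_freq_shape1,bg_freq_shape2 Beta parameters of the background
#'   allele-frequency spectrum.
#' @param missing_rate per-genotype missingness applied to background
#'   sites.
#' @param ki67_mean_hcm,ki67_mean_control expected per-cat Ki67 slide
#'   sums.
#' @param n_ki67_hcm,n_ki67_control cats per Ki67 group.
#' @param n_orthologues orthologue sequences in the simulated protein
#'   alignment.
#' @param seed integer seed; every artifact draws from its own stream
#'   keyed on (seed, artifact), so outputs are individually reproducible.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(n_affected_discovery = 14L,
                      n_control_discovery = 13L,
                      n_affected_validation = 71L,
                      n_control_validation = 214L,
                      causal_case_het = 27L,
                      causal_case_hom = 35L,
                      causal_control_het = 2L,
                      n_background_variants = 50L,
                      impact_mix = c(high = 0.05, moderate = 0.45,
                                     low = 0.30, modifier = 0.20),
                      bg_freq_shape1 = 0.5, bg_freq_shape2 = 3,
                      missing_rate = 0.01,
                      ki67_mean_hcm = 10, ki67_mean_control = 1,
                      n_ki67_hcm = 4L, n_ki67_control = 3L,
                      n_orthologues = 10L,
                      seed = 1L) {
  cfg <- as.list(environment())
  if (causal_case_het + causal_case_hom > n_affected_validation ||
      causal_control_het > n_control_validation)
    stop("infeasible genotype counts: planted carriers exceed group size",
         call. = FALSE)
  if (abs(sum(impact_mix) - 1) > 1e-8 ||
      !setequal(names(impact_mix), .IMPACTS))
    stop("impact_mix must be named over high/moderate/low/modifier and sum to 1",
         call. = FALSE)
  if (ki67_mean_hcm < 0 || ki67_mean_control < 0)
    stop("Ki67 means must be non-negative", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate in-silico score triplets
#'
#' Causal-mode triplets land on the deleterious side of all three default
#' thresholds (PolyPhen near 1, SIFT near 0, strongly negative PROVEAN);
#' background-mode triplets draw from benign-leaning mixtures under which
#' reaching two deleterious votes is rare.
#'
#' @param is_causal draw from the causal (deleterious) generator?
#' @param seed integer seed.
#' @return list `polyphen`, `sift`, `provean`.
#' @export
simulateInSilicoScores <- function(is_causal, seed = 1L) {
  .withStream(seed, "scores", .drawScores(is_causal))
}

.drawScores <- function(is_causal) {
  if (is_causal) {
    list(polyphen = round(runif(1, 0.97, 1.0), 3),
         sift = round(runif(1, 0, 0.01), 3),
         provean = round(runif(1, -8, -4), 3))
  } else {
    list(polyphen = round(rbeta(1, 0.4, 2), 3),
         sift = round(rbeta(1, 2, 0.4), 3),
         provean = round(rnorm(1, -0.5, 1.2), 3))
  }
}

#' Simulate per-cat Ki67 slide counts
#'
#' Five per-area counts per cat, Poisson with mean `group_mean / 5`, so
#' the per-cat slide sum has the configured group mean.
#'
#' @param config a [simConfig()] object.
#' @param seed integer seed (defaults to the config seed).
#' @return `data.frame` with `cat_id`, `group`, `area1..area5`,
#'   `slide_sum`.
#' @export
simulateKi67 <- function(config = simConfig(), seed = config$seed) {
  .withStream(seed, "ki67", {
    draw <- function(n, mean, prefix, group) {
      cnt <- matrix(rpois(5L * n, mean / 5), ncol = 5)
      df <- data.frame(cat_id = sprintf("%s%02d", prefix, seq_len(n)),
                       group = group)
      colnames(cnt) <- paste0("area", 1:5)
      cbind(df, as.data.frame(cnt))
    }
    out <- rbind(draw(config$n_ki67_hcm, config$ki67_mean_hcm,
                      "HCM", "hcm"),
                 draw(config$n_ki67_control, config$ki67_mean_control,
                      "CTL", "control"))
    out$slide_sum <- as.integer(rowSums(out[, paste0("area", 1:5)]))
    out
  })
}

## Sample manifest for the simulated cohorts.
.simManifest <- function(config) {
  .withStream(config$seed, "manifest", {
    aff_d <- data.frame(
      sample_id = sprintf("SPX_D%02d", seq_len(config$n_affected_discovery)),
      breed = "Sphynx", phenotype = "affected", cohort = "discovery",
      lv_wall_cm = round(runif(config$n_affected_discovery, 0.60, 0.95), 2))
    con_d <- data.frame(
      sample_id = sprintf("CTL_D%02d", seq_len(config$n_control_discovery)),
      breed = "Domestic Short Hair", phenotype = "unaffected",
      cohort = "discovery",
      lv_wall_cm = round(runif(config$n_control_discovery, 0.25, 0.39), 2))
    aff_v <- data.frame(
      sample_id = sprintf("SPX_V%03d", seq_len(config$n_affected_validation)),
      breed = "Sphynx", phenotype = "affected", cohort = "validation",
      lv_wall_cm = round(runif(config$n_affected_validation, 0.60, 0.95), 2))
    con_v <- data.frame(
      sample_id = sprintf("CTL_V%03d", seq_len(config$n_control_validation)),
      breed = sample(.CONTROL_BREEDS, config$n_control_validation,
                     replace = TRUE),
      phenotype = "unaffected", cohort = "validation",
      lv_wall_cm = round(runif(config$n_control_validation, 0.25, 0.39), 2))
    rbind(aff_d, con_d, aff_v, con_v)
  })
}

#' Simulate a full case-control cohort with ground truth
#'
#' Generates manifest, genotypes, annotations, the orthologue protein
#' alignment and a ground-truth table, optionally writing them to `dir` in
#' the same dialects [readManifest()], [readCohortVCF()],
#' [readAnnotationTable()] and [readAlignment()] consume (plus gene-panel
#' files and a Ki67 count table). The planted causal variant (the
#' `ALMS1`-like chrA3 G>C missense site) is assigned to carriers by
#' sampling carrier identities without replacement, so the configured
#' het/hom counts are matched exactly and the published contingency table
#' can be reproduced from a default simulation. Background variants are
#' independent across sites with one shared allele frequency per site in
#' both groups.
#'
#' Outputs are deterministic given the seed; each artifact uses its own
#' random stream, so regenerating one artifact never perturbs another.
#'
#' @param config a [simConfig()] object.
#' @param dir optional output directory (created if needed).
#' @return list: `cohort` ([CohortGenotypes]), `manifest`, `annotations`,
#'   `alignment` (residue matrix), `truth` (`data.frame` keyed by
#'   variant), `ki67`, `paths` (named file paths when `dir` was given).
#' @export
simulateCohort <- function(config = simConfig(), dir = NULL) {
  manifest <- .simManifest(config)
  n_samp <- nrow(manifest)
  is_aff <- manifest$phenotype == "affected"
  is_disc <- manifest$cohort == "discovery"

  ## --- planted causal variant ------------------------------------------
  causal <- data.frame(chrom = "A3", pos = 92439157L, ref = "G", alt = "C",
                       gene = "ALMS1", consequence = "missense_variant",
                       impact = "moderate", stringsAsFactors = FALSE)
  gt_causal <- integer(n_samp)
  gt_causal <- .withStream(config$seed, "genotypes", {
    g <- integer(n_samp)
    ## discovery affecteds: all carriers (hom/het split mirroring the
    ## validation hom fraction)
    idx <- which(is_aff & is_disc)
    n_hom_d <- round(length(idx) * config$causal_case_hom /
                       max(1, config$causal_case_het + config$causal_case_hom))
    hom_d <- sample(idx, n_hom_d)
    g[idx] <- 1L
    g[hom_d] <- 2L
    ## validation affecteds: exact het/hom counts by label assignment
    idx <- which(is_aff & !is_disc)
    pick <- sample(idx, config$causal_case_het + config$causal_case_hom)
    g[pick[seq_len(config$causal_case_het)]] <- 1L
    if (config$causal_case_hom > 0)
      g[pick[config$causal_case_het + seq_len(config$causal_case_hom)]] <- 2L
    ## validation controls: exact het count; discovery controls stay 0
    idx <- which(!is_aff & !is_disc)
    if (config$causal_control_het > 0)
      g[sample(idx, config$causal_control_het)] <- 1L
    g
  })

  ## --- background variants ---------------------------------------------
  nb <- config$n_background_variants
  bg <- .withStream(config$seed, "background", {
    if (nb == 0) {
      list(variants = causal[0, ], gt = matrix(integer(), 0, n_samp),
           freq = numeric())
    } else {
      chroms <- c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2",
                  "D1", "D2", "D3", "D4", "E1", "E2", "E3", "F1", "F2")
      impacts <- sample(.IMPACTS, nb, replace = TRUE,
                        prob = config$impact_mix[.IMPACTS])
      consByImpact <- function(im) switch(im,
        high = sample(c("stop_gained", "frameshift_variant",
                        "splice_donor_variant"), 1),
        moderate = sample(c("missense_variant", "inframe_insertion",
                            "inframe_deletion"), 1,
                          prob = c(0.8, 0.1, 0.1)),
        low = "synonymous_variant",
        modifier = "intron_variant")
      cons <- vapply(impacts, consByImpact, character(1))
      bases <- c("A", "C", "G", "T")
      refv <- sample(bases, nb, replace = TRUE)
      altv <- vapply(refv, function(r) sample(setdiff(bases, r), 1),
                     character(1))
      variants <- data.frame(
        chrom = sample(chroms, nb, replace = TRUE),
        pos = 999999L + sample.int(199000000L, nb),
        ref = refv, alt = altv,
        gene = sprintf("GENE%04d", seq_len(nb)),
        consequence = cons, impact = impacts, stringsAsFactors = FALSE)
      freq <- rbeta(nb, config$bg_freq_shape1, config$bg_freq_shape2)
      gt <- matrix(rbinom(nb * n_samp, 2L, rep(freq, n_samp)),
                   nrow = nb, ncol = n_samp)
      if (config$missing_rate > 0) {
        drop <- matrix(runif(nb * n_samp) < config$missing_rate,
                       nrow = nb)
        gt[drop] <- NA_integer_
      }
      list(variants = variants, gt = gt, freq = freq)
    }
  })

  variants <- rbind(causal, bg$variants)
  gt <- rbind(matrix(gt_causal, nrow = 1), bg$gt)

  ## --- in-silico scores and conservation alignment ----------------------
  is_missense <- variants$consequence == "missense_variant"
  scores <- .withStream(config$seed, "scores", {
    out <- data.frame(polyphen = rep(NA_real_, nrow(variants)),
                      sift = NA_real_, provean = NA_real_)
    for (i in which(is_missense)) {
      s <- .drawScores(is_causal = i == 1L)
      out$polyphen[i] <- s$polyphen
      out$sift[i] <- s$sift
      out$provean[i] <- s$provean
    }
    out
  })

  aln <- .withStream(config$seed, "alignment", {
    aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    ncolumns <- max(20L, sum(is_missense))
    nseq <- config$n_orthologues
    ref_aa <- sample(aa, ncolumns, replace = TRUE)
    mat <- matrix("", nseq, ncolumns)
    conserved_frac <- rbeta(ncolumns, 2, 1)
    for (j in seq_len(ncolumns)) {
      keep <- runif(nseq) < conserved_frac[j]
      mat[, j] <- ifelse(keep, ref_aa[j],
                         sample(setdiff(aa, ref_aa[j]), nseq,
                                replace = TRUE))
    }
    ## column for each missense variant; the causal column is a fully
    ## conserved glycine
    cols <- rep(NA_integer_, nrow(variants))
    cols[which(is_missense)] <- sample(ncolumns, sum(is_missense))
    causal_col <- cols[1]
    if (!is.na(causal_col)) {
      mat[, causal_col] <- "G"
      ref_aa[causal_col] <- "G"
    }
    ## a distant orthologue with alignment gaps (never in the causal
    ## column) exercises gap exclusion
    gapped <- setdiff(which(runif(ncolumns) < 0.10), causal_col)
    mat[nseq, gapped] <- "-"
    rownames(mat) <- c("Felis_catus", "Homo_sapiens", "Mus_musculus",
                       "Canis_lupus", "Bos_taurus", "Equus_caballus",
                       "Sus_scrofa", "Gallus_gallus", "Xenopus_laevis",
                       "Danio_rerio")[seq_len(nseq)]
    list(matrix = mat, cols = cols, ref_aa = ref_aa)
  })

  annotations <- cbind(variants, scores)
  annotations$aln_column <- aln$cols
  annotations$ref_aa <- ifelse(is.na(aln$cols), NA_character_,
                               aln$ref_aa[aln$cols])

  cohort <- CohortGenotypes(gt, variants, manifest)

  ## --- ground truth ------------------------------------------------------
  key <- rownames(cohort)
  disc_aff <- is_aff & is_disc
  disc_con <- !is_aff & is_disc
  val_aff <- is_aff & !is_disc
  val_con <- !is_aff & !is_disc
  frac_carrier <- function(g, mask) {
    gg <- g[mask]; gg <- gg[!is.na(gg)]
    if (!length(gg)) NA_real_ else mean(gg >= 1L)
  }
  frac_allele <- function(g, mask) {
    gg <- g[mask]; gg <- gg[!is.na(gg)]
    if (!length(gg)) NA_real_ else sum(gg) / (2 * length(gg))
  }
  thr <- filterThresholds()
  truth <- data.frame(variant = key, is_causal = seq_along(key) == 1L,
                      stringsAsFactors = FALSE)
  truth$disc_affected_presence <- apply(gt, 1, frac_carrier, disc_aff)
  truth$disc_control_presence <- apply(gt, 1, frac_carrier, disc_con)
  truth$val_affected_presence <- apply(gt, 1, frac_carrier, val_aff)
  truth$val_control_allele_fraction <- apply(gt, 1, frac_allele, val_con)
  truth$impact_retained <- variants$impact %in% thr$retained_impacts
  truth$expect_discovery_retained <-
    truth$disc_affected_presence >= thr$min_affected_presence &
    truth$disc_control_presence <= thr$max_control_presence &
    truth$impact_retained
  truth$expect_validation_retained <-
    truth$val_affected_presence >= thr$min_affected_presence &
    truth$val_control_allele_fraction <= thr$max_control_allele_fraction

  ki67 <- simulateKi67(config)

  out <- list(cohort = cohort, manifest = manifest,
              annotations = annotations, alignment = aln$matrix,
              truth = truth, ki67 = ki67, paths = NULL)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(manifest = file.path(dir, "manifest.tsv"),
               vcf = file.path(dir, "cohort.vcf"),
               annotations = file.path(dir, "annotations.tsv"),
               alignment = file.path(dir, "alignment.fasta"),
               truth = file.path(dir, "truth.tsv"),
               known_panel = file.path(dir, "known_hcm_panel.txt"),
               cardiac_panel = file.path(dir, "cardiac_panel.txt"),
               ki67 = file.path(dir, "ki67_counts.tsv"))
    write.table(manifest, paths[["manifest"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeCohortVCF(cohort, paths[["vcf"]])
    write.table(annotations, paths[["annotations"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    seqs <- Biostrings::AAStringSet(apply(aln$matrix, 1, paste,
                                          collapse = ""))
    Biostrings::writeXStringSet(seqs, paths[["alignment"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(.KNOWN_HCM_PANEL, paths[["known_panel"]])
    cardiac <- c("ALMS1",
                 annotations$gene[-1][seq_len(nrow(annotations) - 1) %% 3 == 0])
    writeLines(cardiac, paths[["cardiac_panel"]])
    write.table(ki67, paths[["ki67"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
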