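#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) with keys: `manifest`, `vcf`,
#' `annotations`, `alignment` (optional), `known_panel` (optional),
#' `cardiac_panel` (optional), `ki67_counts` (optional), `alpha` (default
#' 0.05), `seed` (default 1), and optional threshold blocks `filter`
#' (passed to [filterThresholds()]) and `insilico` (passed to
#' [inSilicoThresholds()]). Relative paths are resolved against the
#' config file's directory.
#'
#' @param path path to the config file.
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathKeys <- c("manifest", "vcf", "annotations", "alignment",
                "known_panel", "cardiac_panel", "ki67_counts")
  for (k in pathKeys) {
    if (!is.null(cfg[[k]]) && !grepl("^/", cfg[[k]]))
      cfg[[k]] <- file.path(base, cfg[[k]])
  }
  for (k in c("manifest", "vcf", "annotations")) {
    if (is.null(cfg[[k]]))
      stop("config missing required key: ", k, call. = FALSE)
    if (!file.exists(cfg[[k]]))
      stop("config path does not exist: ", cfg[[k]], call. = FALSE)
  }
  cfg$alpha <- if (is.null(cfg$alpha)) 0.05 else as.numeric(cfg$alpha)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$filter <- do.call(filterThresholds, as.list(cfg$filter))
  cfg$insilico <- do.call(inSilicoThresholds, as.list(cfg$insilico))
  cfg$config_md5 <- unname(tools::md5sum(path))
  structure(cfg, class = "PipelineConfig")
}

## Per-variant classification over a variant table, given the validation
## control allele fractions and the conservation alignment.
.classifyTable <- function(variants, caf, alignment, insilico) {
  n <- nrow(variants)
  out <- data.frame(variant = rownames(variants),
                    gene = variants$gene,
                    consequence = variants$consequence,
                    category = character(n),
                    deleterious_votes = rep(NA_integer_, n),
                    conservation = rep(NA_real_, n),
                    evidence = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cons <- NA_real_
    ac <- variants$aln_column[i]
    if (!is.null(alignment) && !is.null(ac) && !is.na(ac))
      cons <- conservationScore(alignment, ac, variants$ref_aa[i])
    sc <- function(col) {
      v <- variants[[col]][i]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }
    cl <- classifyVariant(variants$consequence[i], caf[i], cons,
                          polyphen = sc("polyphen"), sift = sc("sift"),
                          provean = sc("provean"), thresholds = insilico)
    out$category[i] <- cl$category
    out$deleterious_votes[i] <- cl$deleterious_votes
    out$conservation[i] <- cl$conservation
    out$evidence[i] <- paste(cl$evidence, collapse = ";")
  }
  out
}

#' Run the full discovery-to-association pipeline
#'
#' Executes the cascade on files named in the configuration: read cohort
#' -> discovery cosegregation filter -> gene-panel screen and cardiac
#' prioritization -> validation-cohort exclusion -> pathogenicity
#' classification -> allelic association of the classified candidates ->
#' optional Ki67 group comparison. Stage counts are logged and collected
#' in the report; they never increase along the cascade.
#'
#' @param config a `PipelineConfig` from [readPipelineConfig()], or a path
#'   to a config file.
#' @param outDir optional directory for the report JSON and per-stage
#'   TSVs.
#' @param verbose print per-stage counts (default `TRUE`).
#' @return list of class `RunReport`: `counts` (per-stage), `filter`
#'   (discovery filter table), `known_gene_hits`, `validation`,
#'   `classification`, `association` (one row per candidate),
#'   `ki67` (a `GroupComparison` or `NULL`), `provenance`.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  log <- function(...) if (verbose) message(sprintf(...))

  manifest <- readManifest(config$manifest)
  annotations <- readAnnotationTable(config$annotations)
  cohort <- readCohortVCF(config$vcf, manifest, annotations)
  alignment <- if (!is.null(config$alignment))
    readAlignment(config$alignment) else NULL
  known_panel <- if (!is.null(config$known_panel))
    readGenePanel(config$known_panel) else character()
  cardiac_panel <- if (!is.null(config$cardiac_panel))
    readGenePanel(config$cardiac_panel) else NULL
  log("input: %d variants x %d samples", nrow(cohort), ncol(cohort))

  counts <- list(input = nrow(cohort))

  ## discovery cosegregation filter
  filt <- applyDiscoveryFilter(cohort, config$filter)
  retained <- filt$variant[filt$retained]
  counts$after_discovery_filter <- length(retained)
  log("discovery filter: %d -> %d variants", nrow(cohort),
      length(retained))

  ## gene panels: known-gene screen (reported) + cardiac prioritization
  vi <- as.data.frame(rowData(cohort)[retained, , drop = FALSE])
  rownames(vi) <- retained
  screen <- screenGenePanels(vi, known_panel,
                             if (is.null(cardiac_panel)) character()
                             else cardiac_panel)
  prioritized <- if (is.null(cardiac_panel)) vi else screen$prioritized
  counts$known_gene_hits <- nrow(screen$hits_in_known)
  counts$after_panels <- nrow(prioritized)
  log("panels: %d known-gene hits; %d prioritized", counts$known_gene_hits,
      counts$after_panels)

  ## validation-cohort exclusion
  val <- subsetCohort(cohort, "validation")
  vstatus <- colData(val)$phenotype
  vgt <- genotypes(val)
  vkeys <- rownames(prioritized)
  valres <- lapply(vkeys, function(k)
    validationExclusion(vgt[k, ], vstatus, config$filter))
  validation <- data.frame(
    variant = vkeys,
    affected_presence = vapply(valres, `[[`, 0, "affected_presence"),
    control_allele_fraction = vapply(valres, `[[`, 0,
                                     "control_allele_fraction"),
    retained = vapply(valres, `[[`, TRUE, "retained"),
    reason = vapply(valres, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  surviving <- validation$variant[validation$retained]
  counts$after_validation <- length(surviving)
  log("validation exclusion: %d -> %d variants", length(vkeys),
      length(surviving))

  ## pathogenicity classification
  sv <- prioritized[surviving, , drop = FALSE]
  caf <- validation$control_allele_fraction[match(surviving,
                                                  validation$variant)]
  classification <- .classifyTable(sv, caf, alignment, config$insilico)
  candidates <- classification$variant[classification$category %in%
    c("pathogenic_truncating", "significant_missense")]
  counts$candidates <- length(candidates)
  counts$by_category <- as.list(table(classification$category))
  log("classification: %d candidates (%s)", length(candidates),
      paste(names(counts$by_category), unlist(counts$by_category),
            sep = "=", collapse = ", "))

  ## allelic association of the candidates on the validation cohort
  assocRows <- lapply(candidates, function(k) {
    r <- associateVariant(vgt[k, ], vstatus, alpha = config$alpha)
    data.frame(variant = k, p_two_sided = r$p_two_sided,
               case_allele_freq = r$case_allele_freq,
               control_allele_freq = r$control_allele_freq,
               penetrance = r$penetrance,
               relative_risk = r$relative_risk,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  association <- if (length(assocRows)) do.call(rbind, assocRows) else
    data.frame(variant = character(), p_two_sided = numeric(),
               case_allele_freq = numeric(),
               control_allele_freq = numeric(), penetrance = numeric(),
               relative_risk = numeric(), significant = logical())
  counts$significant <- sum(association$significant)
  log("association: %d significant of %d candidates", counts$significant,
      length(candidates))

  ## optional Ki67 comparison
  ki67 <- NULL
  if (!is.null(config$ki67_counts)) {
    ki67 <- compareKi67(readKi67Counts(config$ki67_counts),
                        alpha = config$alpha)
    log("ki67: means %.2f vs %.2f, p = %.3g", ki67$mean_hcm,
        ki67$mean_control, ki67$p_two_sided)
  }

  report <- structure(list(
    counts = counts, filter = filt,
    known_gene_hits = screen$hits_in_known,
    validation = validation, classification = classification,
    association = association, ki67 = ki67,
    provenance = list(
      config_md5 = if (is.null(config$config_md5)) NA_character_
                   else config$config_md5,
      seed = config$seed, alpha = config$alpha,
      package_version = as.character(utils::packageVersion("VariantCoseg")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "RunReport")
  if (!is.null(outDir)) writeRunReport(report, outDir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the whole report, timestamps included) and
#' per-stage TSVs (`filter_report.tsv`, `validation_exclusion.tsv`,
#' `classification.tsv`, `association.tsv`).
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- report
  class(ser) <- NULL
  if (!is.null(ser$ki67)) ser$ki67 <- unclass(ser$ki67)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  write.table(report$filter, file.path(dir, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$validation,
              file.path(dir, "validation_exclusion.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$classification, file.path(dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$association, file.path(dir, "association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run report\n")
  cn <- x$counts
  cat(sprintf("  variants: %d input -> %d after discovery filter -> %d prioritized -> %d validated -> %d candidates -> %d significant\n",
              cn$input, cn$after_discovery_filter, cn$after_panels,
              cn$after_validation, cn$candidates, cn$significant))
  if (nrow(x$association)) {
    cat("  candidates:\n")
    print(x$association, row.names = FALSE)
  }
  if (!is.null(x$ki67))
    cat(sprintf("  Ki67: %.2f vs %.2f, p = %.3g\n", x$ki67$mean_hcm,
                x$ki67$mean_control, x$ki67$p_two_sided))
  invisible(x)
}
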