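#' Pipeline configuration
#'
#' Collects the file paths, thresholds and seed for an end-to-end run. All
#' thresholds are surfaced here; nothing downstream hard-codes them.
#'
#' @param chrom_sizes path to a chrom.sizes file.
#' @param replicate_beds character vector of per-replicate BED paths.
#' @param pooled_bed,blacklist_bed,neun_pos_bed,neun_neg_bed BED paths
#'   (blacklist and fractions optional, `NULL` to skip).
#' @param state_beds named character vector: state label -> BED path
#'   (optional).
#' @param h3k4me1_bed,h3k4me3_bed histone BED paths (optional).
#' @param genes_tsv gene-model TSV (optional).
#' @param panel_tsv dosage-panel TSV (optional; needed for heritability
#'   and prioritization stages).
#' @param gwas_tsv GWAS summary TSV (z/chisq; heritability stage).
#' @param gwas_assoc_tsv GWAS association TSV with p-values
#'   (prioritization stage; columns snp, chr or chrom, pos, gwas_p,
#'   trait).
#' @param eqtl_tsv eQTL TSV (snp_id, transcript, p; optional).
#' @param min_count replicate support for the consensus (default 2).
#' @param n_sim matched simulations for the permutation test.
#' @param flank annotation extension before heritability regression (bp).
#' @param gwas_threshold,r2_threshold,eqtl_threshold prioritization
#'   cutoffs.
#' @param n_traits traits for the Bonferroni display threshold.
#' @param n_jackknife jackknife blocks for the heritability fit.
#' @param seed integer seed for the permutation stage.
#' @param out_dir output directory.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(chrom_sizes, replicate_beds, pooled_bed,
                            blacklist_bed = NULL, neun_pos_bed = NULL,
                            neun_neg_bed = NULL, state_beds = NULL,
                            h3k4me1_bed = NULL, h3k4me3_bed = NULL,
                            genes_tsv = NULL, panel_tsv = NULL,
                            gwas_tsv = NULL, gwas_assoc_tsv = NULL,
                            eqtl_tsv = NULL,
                            min_count = 2, n_sim = 1000, flank = 500,
                            gwas_threshold = 5e-8, r2_threshold = 0.8,
                            eqtl_threshold = 5e-5, n_traits = 7,
                            n_jackknife = 20, seed = 1,
                            out_dir = tempfile("ocrpipe_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  paths <- c(cfg$chrom_sizes, cfg$replicate_beds, cfg$pooled_bed,
             cfg$blacklist_bed, cfg$neun_pos_bed, cfg$neun_neg_bed,
             cfg$state_beds, cfg$h3k4me1_bed, cfg$h3k4me3_bed,
             cfg$genes_tsv, cfg$panel_tsv, cfg$gwas_tsv,
             cfg$gwas_assoc_tsv, cfg$eqtl_tsv)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("pipeline config refers to missing file(s): ",
         paste(missing, collapse = ", "))
  stopifnot(cfg$min_count >= 1, cfg$n_sim >= 1, cfg$flank >= 0,
            cfg$gwas_threshold > 0, cfg$r2_threshold >= 0,
            cfg$eqtl_threshold > 0, cfg$n_traits >= 1)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: consensus calling (high-confidence OCRs, fraction
#' attribution), histone subsetting, matched-region permutation enrichment
#' against the chromatin-state maps, partitioned-heritability regression,
#' and GWAS SNP prioritization. Stages whose inputs are not configured are
#' skipped. All stage outputs are written under `config$out_dir` together
#' with a JSON run report (parameters, input checksums, per-stage counts);
#' identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly (a list, also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("ocrpipe")),
    seed = cfg$seed,
    parameters = cfg[c("min_count", "n_sim", "flank", "gwas_threshold",
                       "r2_threshold", "eqtl_threshold", "n_traits",
                       "n_jackknife")],
    input_md5 = as.list(tools::md5sum(c(cfg$chrom_sizes,
                                        cfg$replicate_beds,
                                        cfg$pooled_bed))),
    stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genome <- read_chrom_sizes(cfg$chrom_sizes)

  ## consensus ------------------------------------------------------------
  hc <- run_stage("consensus", {
    reps <- lapply(cfg$replicate_beds, read_bed)
    pooled <- read_bed(cfg$pooled_bed, label = "pooled")
    blk <- if (!is.null(cfg$blacklist_bed)) read_bed(cfg$blacklist_bed)
    high_confidence(pooled, reps, blacklist = blk,
                    min_count = cfg$min_count)
  })
  write_bed(hc, file.path(cfg$out_dir, "high_confidence.bed"))
  report$stages$consensus <- list(n_high_confidence = nrow(hc))

  attribution <- NULL
  if (!is.null(cfg$neun_pos_bed) && !is.null(cfg$neun_neg_bed)) {
    attribution <- run_stage("attribution", {
      attribute_fractions(hc, read_bed(cfg$neun_pos_bed),
                          read_bed(cfg$neun_neg_bed))
    })
    data.table::fwrite(data.table::as.data.table(attribution$table),
                       file.path(cfg$out_dir, "attribution.tsv"),
                       sep = "\t")
    report$stages$attribution <- as.list(attribution$counts)
  }

  ## histone subsets --------------------------------------------------------
  hist_sets <- list()
  for (mark in c("h3k4me1", "h3k4me3")) {
    bed <- cfg[[paste0(mark, "_bed")]]
    if (is.null(bed)) next
    sub <- run_stage(paste0("histone_", mark),
                     histone_subset(hc, read_bed(bed, label = mark)))
    hist_sets[[mark]] <- sub
    write_bed(sub, file.path(cfg$out_dir, paste0("ocr_", mark, ".bed")))
    report$stages[[paste0("ocr_", mark)]] <- list(n = nrow(sub))
  }

  ## permutation enrichment -------------------------------------------------
  if (!is.null(cfg$state_beds)) {
    enr <- run_stage("perm_enrich", {
      states <- annotation_map(lapply(cfg$state_beds, read_bed))
      permutation_enrichment(hc, states, n_sim = cfg$n_sim,
                             genome = genome,
                             seed = stage_seed(cfg$seed, 3))
    })
    data.table::fwrite(data.table::as.data.table(enr),
                       file.path(cfg$out_dir, "state_enrichment.tsv"),
                       sep = "\t")
    report$stages$perm_enrich <-
      list(n_states = nrow(enr),
           max_fold_state = enr$state[which.max(enr$fold)])
  }

  ## partitioned heritability ------------------------------------------------
  if (!is.null(cfg$panel_tsv) && !is.null(cfg$gwas_tsv)) {
    h2 <- run_stage("h2_enrich", {
      panel <- read_snp_panel(cfg$panel_tsv)
      gwas <- read_gwas(cfg$gwas_tsv)
      ann <- annotation_matrix(
        nrow(panel$snps),
        list(ocr = annotate_snps(panel, hc, flank = cfg$flank,
                                 genome = genome)))
      ld <- ld_scores(panel, ann)
      fit <- fit_partitioned(gwas, ld, ann, n_blocks = cfg$n_jackknife)
      fold_enrichment(fit)
    })
    h2$bonferroni_threshold <- bonferroni_threshold(0.05, cfg$n_traits)
    data.table::fwrite(data.table::as.data.table(h2),
                       file.path(cfg$out_dir, "h2_enrichment.tsv"),
                       sep = "\t")
    report$stages$h2_enrich <- list(
      fold = h2$fold[h2$category == "ocr"],
      p = h2$p[h2$category == "ocr"])
  }

  ## prioritization -----------------------------------------------------------
  if (!is.null(cfg$panel_tsv) && !is.null(cfg$gwas_assoc_tsv)) {
    pri <- run_stage("prioritize", {
      panel <- read_snp_panel(cfg$panel_tsv)
      dt <- data.table::fread(cfg$gwas_assoc_tsv, sep = "\t")
      chrom_col <- intersect(c("chrom", "chr"), names(dt))[1]
      recs <- snp_records(dt$snp_id %||% dt$snp, dt[[chrom_col]], dt$pos,
                          dt$gwas_p, dt$trait %||% "trait")
      eq <- if (!is.null(cfg$eqtl_tsv))
        as.data.frame(data.table::fread(cfg$eqtl_tsv, sep = "\t"))
      prioritize_snps(recs, hc, panel,
                      h3k4me1 = hist_sets$h3k4me1,
                      h3k4me3 = hist_sets$h3k4me3,
                      attribution = attribution$table, eqtl = eq,
                      gwas_threshold = cfg$gwas_threshold,
                      r2_threshold = cfg$r2_threshold,
                      eqtl_threshold = cfg$eqtl_threshold)
    })
    data.table::fwrite(data.table::as.data.table(pri),
                       file.path(cfg$out_dir, "prioritized_snps.tsv"),
                       sep = "\t")
    report$stages$prioritize <- list(n_prioritized = nrow(pri))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
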