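#' Configuration of the synthetic study generator
#'
#' Defines a desk-scale emulation of the study design behind the pipeline:
#' three biological replicates of bulk open-chromatin peak calls (each an
#' imperfect, jittered observation of a shared set of true peaks plus
#' replicate-private noise), a pooled peak call, NeuN+/NeuN- fraction
#' calls sharing most of the bulk truth, a blacklist, chromatin-state maps
#' whose enrichment around true peaks is planted, histone-mark sets, gene
#' models, an LD-block genotype panel, GWAS summary statistics whose
#' per-SNP heritability is elevated inside the (extended) true-peak
#' annotation, and an eQTL table with planted fine-mapping structure.
#'
#' @param chrom_lengths named vector of chromosome lengths (default three
#'   2 Mb chromosomes).
#' @param n_true_peaks number of true open-chromatin peaks.
#' @param peak_meanlog,peak_sdlog lognormal peak-length parameters
#'   (default median 400 bp).
#' @param min_peak_len,max_peak_len clipping bounds on peak lengths.
#' @param n_replicates biological replicates (>= 2).
#' @param detection_prob probability a replicate detects a true peak.
#' @param pooled_detection_prob detection probability for the pooled call.
#' @param noise_peaks_per_replicate replicate-private false peaks.
#' @param pooled_noise_peaks false peaks in the pooled call.
#' @param jitter_bp maximal uniform boundary jitter (each boundary moves by
#'   up to this many bp in either direction).
#' @param n_blacklist,blacklist_len artifact regions.
#' @param neun_shared_frac fraction of true peaks open in both fractions.
#' @param neun_private_frac fraction private to each fraction.
#' @param state_names chromatin-state labels.
#' @param state_multipliers named multipliers >= 1; states with multiplier
#'   m cover true peaks at rate `base_state_cover * m` (capped at 1).
#' @param base_state_cover baseline probability a state covers a true peak.
#' @param state_bg_regions,state_bg_len background regions per state.
#' @param h3k4me1_frac,h3k4me3_frac fraction of true peaks carrying each
#'   histone mark.
#' @param histone_bg_regions background histone regions per mark.
#' @param n_genes gene models to place.
#' @param n_snps,block_size,ld_rho,n_ind LD panel: SNP count, SNPs per
#'   compound-symmetric block, within-block latent correlation,
#'   genotyped individuals.
#' @param n_gwas GWAS sample size.
#' @param target_fold planted heritability fold enrichment of the
#'   extended-peak annotation.
#' @param total_h2 total SNP heritability on the observed scale.
#' @param snp_flank annotation extension used when planting heritability
#'   (bp; the same 500 bp the estimator uses).
#' @param n_baseline_categories null covariate categories in the
#'   annotation matrix.
#' @param baseline_frac membership rate of each null category.
#' @param n_planted_loci GWAS risk loci planted for the prioritization
#'   stage.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
    n_true_peaks = 300,
    peak_meanlog = log(400), peak_sdlog = 0.4,
    min_peak_len = 150, max_peak_len = 3000,
    n_replicates = 3,
    detection_prob = 0.95,
    pooled_detection_prob = 0.98,
    noise_peaks_per_replicate = 60,
    pooled_noise_peaks = 40,
    jitter_bp = 50,
    n_blacklist = 5, blacklist_len = 2000,
    neun_shared_frac = 0.7,
    neun_private_frac = 0.15,
    state_names = c("Promoter", "Enhancer", "Bivalent", "RegPermissive",
                    "Transcribed", "Quiescent", "FacultativeHet",
                    "ConstitutiveHet"),
    state_multipliers = c(Promoter = 10, Enhancer = 5),
    base_state_cover = 0.05,
    state_bg_regions = 80, state_bg_len = 1500,
    h3k4me1_frac = 0.5, h3k4me3_frac = 0.3,
    histone_bg_regions = 50,
    n_genes = 60,
    n_snps = 5000, block_size = 50, ld_rho = 0.6, n_ind = 200,
    n_gwas = 10000,
    target_fold = 5, total_h2 = 0.5,
    snp_flank = 500,
    n_baseline_categories = 3, baseline_frac = 0.1,
    n_planted_loci = 2,
    seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_replicates >= 2,
            cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            cfg$pooled_detection_prob >= 0, cfg$pooled_detection_prob <= 1,
            cfg$neun_shared_frac >= 0, cfg$neun_shared_frac <= 1,
            cfg$n_true_peaks > 0, cfg$n_snps > 0,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$target_fold > 0, cfg$total_h2 > 0)
  if (cfg$max_peak_len > min(cfg$chrom_lengths))
    stop("peaks may not be longer than the shortest chromosome")
  class(cfg) <- "synthetic_config"
  cfg
}

## Place n non-overlapping intervals with given lengths by sampling
## disjoint slots on the genome (slot width = max length + separation).
place_disjoint <- function(n, lengths, genome, slot_sep = 2000,
                           exclude = NULL) {
  slot_w <- max(lengths) + slot_sep
  slots <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    k <- floor(genome$length[i] / slot_w)
    data.frame(chrom = genome$chrom[i],
               slot_start = (seq_len(k) - 1) * slot_w,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    slot_ps <- peak_set(slots$chrom, slots$slot_start,
                        slots$slot_start + slot_w)
    bad <- IRanges::overlapsAny(as_gr(slot_ps), as_gr(exclude))
    slots <- slots[!bad, , drop = FALSE]
  }
  if (n > nrow(slots))
    stop("genome too small for ", n, " disjoint intervals of this size")
  pick <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  offset <- floor(stats::runif(n) * (slot_w - slot_sep - lengths + 1))
  peak_set(pick$chrom, pick$slot_start + offset,
           pick$slot_start + offset + lengths)
}

## Jittered, probabilistically detected copy of the true peak set.
## detect_p may be a per-peak vector; boundaries move by up to `jitter` bp
## in either direction, clipped to the chromosome and to a positive width.
observe_peaks <- function(truth, genome, detect_p, jitter, label) {
  n <- nrow(truth)
  seen <- which(stats::runif(n) < rep_len(detect_p, n))
  if (length(seen) == 0) {
    out <- peak_set(label = label)
    attr(out, "true_index") <- integer(0)
    return(out)
  }
  len <- chrom_length(genome, truth$chrom[seen])
  ds <- round(stats::runif(length(seen), -jitter, jitter))
  de <- round(stats::runif(length(seen), -jitter, jitter))
  s <- pmax(0, truth$start[seen] + ds)
  e <- pmin(len, truth$end[seen] + de)
  e <- pmax(e, s + 1)
  out <- peak_set(truth$chrom[seen], s, e, label = label)
  attr(out, "true_index") <- seen
  out
}

uniform_noise_peaks <- function(n, genome, meanlog, sdlog, lo, hi, label) {
  if (n == 0) return(peak_set(label = label))
  len <- pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
  chrom <- sample(genome$chrom, n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  clen <- chrom_length(genome, chrom)
  start <- floor(stats::runif(n) * (clen - len + 1))
  peak_set(chrom, start, start + len, label = label)
}

rbind_peaks <- function(a, b, label = peak_label(a)) {
  peak_set(c(a$chrom, b$chrom), c(a$start, b$start), c(a$end, b$end),
           label = label)
}

#' Simulate GWAS summary statistics under block LD
#'
#' The generative model the partitioned-heritability estimator assumes:
#' per LD block with correlation matrix `R`, causal effects
#' `beta_j ~ N(0, sum_c tau_c A[j,c])` and observed z-scores
#' `z = sqrt(N) R beta + eps`, `eps ~ MVN(0, R)`; chi-square = z².
#'
#' @param panel a [snp_panel()]; its `ld_blocks` (or, failing that, LD
#'   estimated from genotypes) define `R`.
#' @param annotations an [annotation_matrix()].
#' @param tau per-category per-SNP heritability coefficients (>= 0),
#'   aligned with the annotation columns.
#' @param N GWAS sample size.
#' @param seed optional integer seed.
#' @return a list: `gwas` (a [gwas_summary()]), `z`, `beta`, and
#'   `realized_prop_h2` (named realized h2 shares per non-base category,
#'   from the drawn `beta`).
#' @export
simulate_gwas <- function(panel, annotations, tau, N, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (any(tau < 0)) stop("tau must be >= 0")
  if (length(tau) != ncol(annotations))
    stop("tau length must match annotation columns")
  n <- nrow(panel$snps)
  var_beta <- drop(annotations %*% tau)
  blocks <- split(seq_len(n), panel$snps$block)
  Rs <- if (!is.null(panel$ld_blocks)) panel$ld_blocks else
    lapply(blocks, function(idx) {
      R <- suppressWarnings(stats::cor(panel$genotypes[, idx, drop = FALSE]))
      R[is.na(R)] <- 0
      R
    })
  with_seed(seed, {
    beta <- stats::rnorm(n, 0, sqrt(var_beta))
    z <- numeric(n)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      R <- Rs[[b]]
      U <- tryCatch(chol(R), error = function(e)
        stop("non-positive-definite LD matrix in block ", b))
      eps <- drop(t(U) %*% stats::rnorm(length(idx)))
      z[idx] <- sqrt(N) * drop(R %*% beta[idx]) + eps
    }
    h_realized <- beta^2
    shares <- vapply(seq_len(ncol(annotations))[-1], function(c)
      sum(h_realized[annotations[, c] == 1]) / sum(h_realized), numeric(1))
    names(shares) <- colnames(annotations)[-1]
    list(gwas = gwas_summary(panel$snps$snp_id, z^2, N),
         z = z, beta = beta, realized_prop_h2 = shares)
  })
}

#' Solve per-SNP heritability coefficients for a planted fold enrichment
#'
#' Given the realized fraction `p` of SNPs inside the focal annotation,
#' returns `c(base = tau0, focal = tau1)` such that the annotation holds
#' `fold * p` of a total heritability `total_h2` spread over `n_snps`
#' SNPs. Requires `fold * p < 1`.
#'
#' @param prop_snps fraction of SNPs in the annotation.
#' @param fold target fold enrichment.
#' @param total_h2 total heritability.
#' @param n_snps number of SNPs.
#' @return named numeric `c(base, focal)`.
#' @export
tau_for_fold <- function(prop_snps, fold, total_h2, n_snps) {
  p <- prop_snps
  if (fold * p >= 1)
    stop("infeasible: fold * prop_snps must be < 1")
  ratio <- (fold - 1) / (1 - fold * p)  # tau1 / tau0
  tau0 <- total_h2 / (n_snps * (1 + p * ratio))
  c(base = tau0, focal = tau0 * ratio)
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces every input the pipeline consumes, plus a `truth` record
#' sufficient to score each stage: the true peak set and which replicate
#' detected which peak, NeuN attribution truth, which true peaks each
#' chromatin state covers, the planted heritability coefficients and fold,
#' and the planted GWAS loci / causal OCR SNPs / eQTL transcripts. The
#' whole bundle is a deterministic function of `config$seed`.
#'
#' True peaks hosting a planted causal SNP are detected in every replicate
#' and in the pooled call, so the planted fine-mapping structure survives
#' consensus calling by construction; all other peaks are detected at the
#' configured probabilities.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, all inputs are written
#'   as plain-text files (BED, TSV, chrom.sizes, truth.yaml) and their
#'   paths returned in `$paths`.
#' @return a list of class `synthetic_study` with elements `genome`,
#'   `true_peaks`, `replicates`, `pooled`, `neun_pos`, `neun_neg`,
#'   `blacklist`, `states` (an [annotation_map()]), `h3k4me1`, `h3k4me3`,
#'   `genes`, `panel`, `annotations`, `tau`, `gwas`, `gwas_records`,
#'   `eqtl`, `truth`, and (optionally) `paths`.
#' @export
generate_study <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genome <- genome_model(names(cfg$chrom_lengths), cfg$chrom_lengths)
  sd_ <- function(k) stage_seed(cfg$seed, k)

  ## -- blacklist and true peaks on disjoint slots ------------------------
  blacklist <- with_seed(sd_(1), {
    set_label(place_disjoint(cfg$n_blacklist,
                             rep(cfg$blacklist_len, cfg$n_blacklist),
                             genome), "blacklist")
  })
  true_peaks <- with_seed(sd_(2), {
    len <- pmin(pmax(round(stats::rlnorm(cfg$n_true_peaks, cfg$peak_meanlog,
                                         cfg$peak_sdlog)),
                     cfg$min_peak_len), cfg$max_peak_len)
    set_label(place_disjoint(cfg$n_true_peaks, len, genome,
                             exclude = blacklist), "true_peaks")
  })

  ## -- LD panel ----------------------------------------------------------
  panel <- with_seed(sd_(60), {
    per_chr <- round(cfg$n_snps * genome$length / sum(genome$length))
    per_chr[length(per_chr)] <- cfg$n_snps - sum(per_chr[-length(per_chr)])
    pos <- unlist(lapply(seq_len(nrow(genome)), function(i)
      sort(sample.int(genome$length[i] - 1, per_chr[i]))), use.names = FALSE)
    chrom <- rep(genome$chrom, per_chr)
    block <- ceiling(seq_len(cfg$n_snps) / cfg$block_size)
    sizes <- tabulate(block)
    Rs <- lapply(sizes, function(m) {
      R <- matrix(cfg$ld_rho, m, m); diag(R) <- 1; R
    })
    maf <- stats::runif(cfg$n_snps, 0.1, 0.5)
    geno <- matrix(0, cfg$n_ind, cfg$n_snps)
    for (b in seq_along(Rs)) {
      idx <- which(block == b)
      U <- chol(Rs[[b]])
      thr <- stats::qnorm(maf[idx])
      for (h in 1:2) {
        lat <- matrix(stats::rnorm(cfg$n_ind * length(idx)), cfg$n_ind) %*% U
        geno[, idx] <- geno[, idx] +
          (lat < matrix(thr, cfg$n_ind, length(idx), byrow = TRUE))
      }
    }
    snp_panel(sprintf("rs%05d", seq_len(cfg$n_snps)), chrom, pos,
              block = block, genotypes = geno, ld_blocks = Rs)
  })

  ## -- planted fine-mapping structure ------------------------------------
  ## causal SNPs sit well inside a true peak (jitter-proof interior)
  interior <- peak_set(true_peaks$chrom,
                       true_peaks$start + cfg$jitter_bp,
                       true_peaks$end - cfg$jitter_bp)
  planted <- with_seed(sd_(70), {
    inside <- which(snp_in_set(panel$snps, interior))
    ## one locus per chromosome so planted loci can never fall inside one
    ## another's clumping window
    ## candidates need >= 2 same-chromosome block mates (index + top eQTL)
    grp <- interaction(panel$snps$block, panel$snps$chrom, drop = TRUE)
    grp_n <- ave(seq_along(grp), grp, FUN = length)
    inside <- inside[grp_n[inside] >= 3]
    by_chr <- split(inside, panel$snps$chrom[inside])
    by_chr <- by_chr[lengths(by_chr) > 0]
    if (length(by_chr) < cfg$n_planted_loci)
      stop("too few chromosomes with SNPs inside true peaks to plant ",
           cfg$n_planted_loci, " loci")
    host_chr <- sample(names(by_chr), cfg$n_planted_loci)
    do.call(rbind, lapply(seq_len(cfg$n_planted_loci), function(k) {
      cands <- by_chr[[host_chr[k]]]
      cs <- if (length(cands) == 1) cands else sample(cands, 1)
      mates <- setdiff(which(panel$snps$block == panel$snps$block[cs] &
                               panel$snps$chrom == panel$snps$chrom[cs]),
                       cs)
      mates_out <- setdiff(mates, inside)
      idx <- if (length(mates_out) > 0) sample(mates_out, 1) else
        sample(mates, 1)
      top2 <- sample(setdiff(mates, idx), 1)
      data.frame(locus = k, causal = cs, index = idx, eqtl_mate = top2)
    }))
  })
  ## perfect LD: causal copies the index; the second transcript's top
  ## eQTL is the mirrored copy (r^2 = 1 either way)
  for (k in seq_len(nrow(planted))) {
    panel$genotypes[, planted$causal[k]] <-
      panel$genotypes[, planted$index[k]]
    panel$genotypes[, planted$eqtl_mate[k]] <-
      2 - panel$genotypes[, planted$index[k]]
  }
  ## true-peak indices hosting a causal SNP: always detected
  host_gr <- GenomicRanges::GRanges(
    panel$snps$chrom[planted$causal],
    IRanges::IRanges(panel$snps$pos[planted$causal],
                     panel$snps$pos[planted$causal]))
  host_idx <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(host_gr, as_gr(true_peaks)))

  ## -- replicate, pooled and fraction peak calls -------------------------
  rep_detect <- rep(cfg$detection_prob, cfg$n_true_peaks)
  rep_detect[host_idx] <- 1
  pooled_detect <- rep(cfg$pooled_detection_prob, cfg$n_true_peaks)
  pooled_detect[host_idx] <- 1

  replicates <- lapply(seq_len(cfg$n_replicates), function(r) {
    with_seed(sd_(10 + r), {
      obs <- observe_peaks(true_peaks, genome, rep_detect,
                           cfg$jitter_bp, sprintf("rep%d", r))
      noise <- uniform_noise_peaks(cfg$noise_peaks_per_replicate, genome,
                                   cfg$peak_meanlog, cfg$peak_sdlog,
                                   cfg$min_peak_len, cfg$max_peak_len,
                                   sprintf("rep%d", r))
      list(obs = obs, noise = noise)
    })
  })
  rep_sets <- lapply(replicates, function(x)
    rbind_peaks(x$obs, x$noise, label = peak_label(x$obs)))
  rep_membership <- lapply(replicates, function(x) attr(x$obs, "true_index"))

  pooled_parts <- with_seed(sd_(20), {
    obs <- observe_peaks(true_peaks, genome, pooled_detect,
                         cfg$jitter_bp, "pooled")
    noise <- uniform_noise_peaks(cfg$pooled_noise_peaks, genome,
                                 cfg$peak_meanlog, cfg$peak_sdlog,
                                 cfg$min_peak_len, cfg$max_peak_len,
                                 "pooled")
    list(obs = obs, noise = noise)
  })
  pooled <- rbind_peaks(pooled_parts$obs, pooled_parts$noise,
                        label = "pooled")
  pooled_truth <- attr(pooled_parts$obs, "true_index")

  neun <- with_seed(sd_(21), {
    n <- cfg$n_true_peaks
    shuffled <- sample.int(n)
    n_shared <- round(cfg$neun_shared_frac * n)
    n_priv <- round(cfg$neun_private_frac * n)
    shared <- shuffled[seq_len(n_shared)]
    pos_only <- shuffled[n_shared + seq_len(min(n_priv, n - n_shared))]
    rest <- setdiff(shuffled, c(shared, pos_only))
    neg_only <- rest[seq_len(min(n_priv, length(rest)))]
    list(pos = sort(c(shared, pos_only)), neg = sort(c(shared, neg_only)),
         shared = sort(shared),
         pos_only = sort(pos_only), neg_only = sort(neg_only))
  })
  take_true <- function(idx) {
    sub <- true_peaks[idx, , drop = FALSE]
    class(sub) <- class(true_peaks)
    sub
  }
  neun_pos <- with_seed(sd_(22),
    observe_peaks(take_true(neun$pos), genome, 1, cfg$jitter_bp,
                  "neun_pos"))
  neun_neg <- with_seed(sd_(23),
    observe_peaks(take_true(neun$neg), genome, 1, cfg$jitter_bp,
                  "neun_neg"))

  ## -- chromatin states: background + planted coverage of true peaks -----
  mult <- stats::setNames(rep(1, length(cfg$state_names)), cfg$state_names)
  mult[names(cfg$state_multipliers)] <- cfg$state_multipliers
  state_truth <- list()
  states <- lapply(seq_along(cfg$state_names), function(si) {
    st <- cfg$state_names[si]
    with_seed(sd_(30 + si), {
      bg <- uniform_noise_peaks(cfg$state_bg_regions, genome,
                                log(cfg$state_bg_len), 0.3, 200,
                                max(cfg$chrom_lengths) %/% 2, st)
      cover_p <- min(1, cfg$base_state_cover * mult[[st]])
      covered <- which(stats::runif(cfg$n_true_peaks) < cover_p)
      state_truth[[st]] <<- covered
      if (length(covered) > 0) {
        ## cover the whole peak plus margin, guaranteeing the >50% rule
        cov <- peak_set(true_peaks$chrom[covered],
                        pmax(0, true_peaks$start[covered] - 100),
                        pmin(chrom_length(genome, true_peaks$chrom[covered]),
                             true_peaks$end[covered] + 100), label = st)
        bg <- rbind_peaks(bg, cov, label = st)
      }
      merge_peaks(bg)
    })
  })
  names(states) <- cfg$state_names
  states <- annotation_map(states)

  ## -- histone marks ------------------------------------------------------
  histone_set <- function(frac, k, label) {
    with_seed(sd_(40 + k), {
      hit <- which(stats::runif(cfg$n_true_peaks) < frac)
      marked <- if (length(hit) > 0)
        peak_set(true_peaks$chrom[hit],
                 pmax(0, true_peaks$start[hit] - 200),
                 pmin(chrom_length(genome, true_peaks$chrom[hit]),
                      true_peaks$end[hit] + 200), label = label)
      else peak_set(label = label)
      bg <- uniform_noise_peaks(cfg$histone_bg_regions, genome,
                                log(1000), 0.3, 200, 5000, label)
      out <- merge_peaks(rbind_peaks(marked, bg, label = label))
      attr(out, "true_index") <- hit
      out
    })
  }
  h3k4me1 <- histone_set(cfg$h3k4me1_frac, 1, "H3K4me1")
  h3k4me3 <- histone_set(cfg$h3k4me3_frac, 2, "H3K4me3")

  ## -- gene models --------------------------------------------------------
  genes <- with_seed(sd_(50), {
    chrom <- sample(genome$chrom, cfg$n_genes, replace = TRUE,
                    prob = genome$length / sum(genome$length))
    clen <- chrom_length(genome, chrom)
    body_len <- round(stats::runif(cfg$n_genes, 5000, 50000))
    start <- floor(stats::runif(cfg$n_genes) * (clen - body_len))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    gene_models(sprintf("gene_%03d", seq_len(cfg$n_genes)), chrom, strand,
                tss = ifelse(strand == "+", start, start + body_len),
                body_start = start, body_end = start + body_len)
  })

  ## -- annotations and GWAS -----------------------------------------------
  ocr_ann <- annotate_snps(panel, true_peaks, flank = cfg$snp_flank,
                           genome = genome)
  baselines <- with_seed(sd_(61), {
    out <- lapply(seq_len(cfg$n_baseline_categories), function(i)
      as.numeric(stats::runif(cfg$n_snps) < cfg$baseline_frac))
    stats::setNames(out, sprintf("baseline_%d", seq_along(out)))
  })
  annotations <- annotation_matrix(cfg$n_snps,
                                   c(list(ocr = ocr_ann), baselines))
  tt <- tau_for_fold(mean(ocr_ann), cfg$target_fold, cfg$total_h2,
                     cfg$n_snps)
  tau <- stats::setNames(numeric(ncol(annotations)), colnames(annotations))
  tau["base"] <- tt[["base"]]
  tau["ocr"] <- tt[["focal"]]
  sim <- simulate_gwas(panel, annotations, tau, cfg$n_gwas, seed = sd_(62))

  ## -- GWAS association p-values and eQTL table ---------------------------
  gwas_records <- with_seed(sd_(71), {
    p <- stats::runif(cfg$n_snps, 0.05, 1)
    p[planted$index] <- 1e-12
    p[planted$causal] <- 1e-9
    snp_records(panel$snps$snp_id, panel$snps$chrom, panel$snps$pos, p,
                trait = "SCZ")
  })
  tr1 <- sprintf("transcript_%d_A", seq_len(nrow(planted)))
  tr2 <- sprintf("transcript_%d_B", seq_len(nrow(planted)))
  eqtl <- data.frame(
    snp_id = panel$snps$snp_id[
      c(planted$causal, planted$causal, planted$eqtl_mate)],
    transcript = c(tr1, tr2, tr2),
    p = c(rep(1e-8, nrow(planted)), rep(2e-7, nrow(planted)),
          rep(1e-9, nrow(planted))),
    stringsAsFactors = FALSE)

  truth <- list(
    true_peaks = true_peaks,
    replicate_membership = rep_membership,
    pooled_membership = pooled_truth,
    pooled_n_noise = nrow(pooled_parts$noise),
    neun = neun,
    state_cover = state_truth,
    h3k4me1_cover = attr(h3k4me1, "true_index"),
    h3k4me3_cover = attr(h3k4me3, "true_index"),
    tau = tau,
    target_fold = cfg$target_fold,
    prop_snps_ocr = mean(ocr_ann),
    realized_prop_h2 = sim$realized_prop_h2,
    planted = data.frame(
      locus = planted$locus,
      causal_snp = panel$snps$snp_id[planted$causal],
      index_snp = panel$snps$snp_id[planted$index],
      transcripts = paste(tr1, tr2, sep = ";"),
      top_eqtl_snp_b = panel$snps$snp_id[planted$eqtl_mate],
      stringsAsFactors = FALSE))

  study <- list(genome = genome, config = cfg, true_peaks = true_peaks,
                replicates = rep_sets, pooled = pooled,
                neun_pos = neun_pos, neun_neg = neun_neg,
                blacklist = blacklist, states = states,
                h3k4me1 = h3k4me1, h3k4me3 = h3k4me3, genes = genes,
                panel = panel, annotations = annotations, tau = tau,
                gwas = sim$gwas, gwas_records = gwas_records,
                eqtl = eqtl, truth = truth)
  class(study) <- "synthetic_study"
  if (!is.null(out_dir)) study$paths <- write_study(study, out_dir)
  study
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic study bundle to disk as plain-text files
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "states"), showWarnings = FALSE)
  p <- list()
  p$chrom_sizes <- write_chrom_sizes(study$genome,
                                     file.path(out_dir, "chrom.sizes"))
  for (r in seq_along(study$replicates))
    p[[sprintf("rep%d", r)]] <- write_bed(
      study$replicates[[r]], file.path(out_dir, sprintf("rep%d.bed", r)))
  for (nm in c("pooled", "neun_pos", "neun_neg", "blacklist",
               "h3k4me1", "h3k4me3", "true_peaks"))
    p[[nm]] <- write_bed(study[[nm]], file.path(out_dir, paste0(nm, ".bed")))
  for (st in names(study$states))
    p[[paste0("state_", st)]] <- write_bed(
      study$states[[st]], file.path(out_dir, "states", paste0(st, ".bed")))
  p$genes <- write_gene_models(study$genes, file.path(out_dir, "genes.tsv"))
  sn <- study$panel$snps
  geno_dt <- data.table::data.table(
    snp = sn$snp_id, chr = sn$chrom, pos = sn$pos, block = sn$block)
  gm <- data.table::as.data.table(t(study$panel$genotypes))
  data.table::setnames(gm, sprintf("ind_%03d",
                                   seq_len(nrow(study$panel$genotypes))))
  p$panel <- file.path(out_dir, "panel_dosages.tsv")
  data.table::fwrite(cbind(geno_dt, gm), p$panel, sep = "\t")
  p$gwas <- file.path(out_dir, "gwas_sumstats.tsv")
  data.table::fwrite(data.table::data.table(
    snp = sn$snp_id, chr = sn$chrom, pos = sn$pos,
    chisq = study$gwas$chisq, N = study$gwas$N), p$gwas, sep = "\t")
  p$gwas_assoc <- file.path(out_dir, "gwas_assoc.tsv")
  data.table::fwrite(data.table::as.data.table(
    unclass(study$gwas_records)), p$gwas_assoc, sep = "\t")
  p$eqtl <- file.path(out_dir, "eqtl.tsv")
  data.table::fwrite(data.table::as.data.table(study$eqtl), p$eqtl,
                     sep = "\t")
  p$annotations <- file.path(out_dir, "annotations.tsv")
  data.table::fwrite(data.table::as.data.table(study$annotations),
                     p$annotations, sep = "\t")
  p$truth <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(list(
    seed = study$config$seed,
    n_true_peaks = nrow(study$true_peaks),
    tau = as.list(study$tau),
    target_fold = study$truth$target_fold,
    prop_snps_ocr = study$truth$prop_snps_ocr,
    realized_prop_h2 = as.list(study$truth$realized_prop_h2),
    neun_shared = length(study$truth$neun$shared),
    planted = lapply(seq_len(nrow(study$truth$planted)), function(i)
      as.list(study$truth$planted[i, ]))), p$truth)
  invisible(p)
}

#' Read a dosage-panel TSV written by [write_study()]
#'
#' @param path TSV with columns `snp, chr, pos, block, ind_*`.
#' @return a [snp_panel()] with genotypes (no reference LD matrices).
#' @export
read_snp_panel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ind_cols <- grep("^ind_", names(dt), value = TRUE)
  geno <- t(as.matrix(dt[, ind_cols, with = FALSE]))
  snp_panel(dt$snp, dt$chr, dt$pos, block = dt$block, genotypes = geno)
}
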