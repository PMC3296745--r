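# Coupled synthetic SNP-map / CN-state / annotation / expression generator
# with planted truth, emulating a small panel of tumour cell lines profiled
# on a 100K-style SNP array and an expression array against a set of
# normal-tissue controls.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package targets: 4 tumour cell
#' lines, ~23.6 kb mean inter-SNP spacing, triplicate tumour expression
#' profiles against 10 controls, with planted gain/loss regions whose
#' recurrence, internal continuity, dosage response, repressed fraction and
#' spatial clustering of deregulation are all controllable.
#'
#' @param n_chromosomes number of chromosomes (default 4).
#' @param chrom_length_bp length of each chromosome (default 50 Mb).
#' @param snp_spacing_mean mean inter-SNP distance in bp (default 23600).
#' @param n_samples tumour samples/cell lines (default 4).
#' @param n_genes total genes (default 1200).
#' @param n_regions candidate CNA regions drawn genome-wide (default 20).
#' @param region_length_meanlog,region_length_sdlog lognormal parameters of
#'   region length in bp (defaults log(1.5e6), 0.6).
#' @param recurrence_prob probability a region is planted in all samples
#'   (default 0.3; otherwise it goes to one random sample).
#' @param continuity fraction of in-region SNPs actually set altered
#'   (default 0.9; 1.0 = fully contiguous alteration).
#' @param direction_mix probability a region is a gain (default 0.55).
#' @param amp_prob probability an altered gain SNP gets state 4 rather
#'   than 3 (default 0.11).
#' @param double_del_prob probability an altered loss SNP gets state 0
#'   (default 0.01).
#' @param dosage_up_prob P(up-regulated | gene in a gained region)
#'   (default 0.4).
#' @param repression_prob baseline P(down-regulated | gene in a gained
#'   region) (default 0.1).
#' @param partial_silencing_slope added P(down) per altered SNP in the gene
#'   span inside discontinuous regions (default 0.02).
#' @param cluster_rho AR(1) spatial autocorrelation of the deregulation
#'   latent field along the gene order (default 0.3).
#' @param background_dereg_prob P(deregulated) for genes outside planted
#'   regions (default 0.12, split evenly up/down).
#' @param noise_sd lognormal sdlog of replicate noise (default 0.25).
#' @param explored_prob probability a gene is on the expression platform
#'   (default 0.63).
#' @param n_tumor_replicates expression replicates per line (default 3).
#' @param n_controls control samples (default 10).
#' @param seed master RNG seed; fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4, chrom_length_bp = 5e7,
                       snp_spacing_mean = 23600, n_samples = 4,
                       n_genes = 1200, n_regions = 20,
                       region_length_meanlog = log(1.5e6),
                       region_length_sdlog = 0.6,
                       recurrence_prob = 0.3, continuity = 0.9,
                       direction_mix = 0.55, amp_prob = 0.11,
                       double_del_prob = 0.01, dosage_up_prob = 0.4,
                       repression_prob = 0.1,
                       partial_silencing_slope = 0.02, cluster_rho = 0.3,
                       background_dereg_prob = 0.12, noise_sd = 0.25,
                       explored_prob = 0.63, n_tumor_replicates = 3,
                       n_controls = 10, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(recurrence_prob, continuity, direction_mix, amp_prob,
             double_del_prob, dosage_up_prob, repression_prob,
             background_dereg_prob, explored_prob)
  stopifnot(all(probs >= 0 & probs <= 1), continuity > 0,
            n_samples >= 2, n_controls >= 2, n_tumor_replicates >= 2)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome: SNP map, cytobands and gene annotation
#'
#' SNP positions follow a Poisson process (exponential spacings) with the
#' configured mean.  Each chromosome is split into a p arm (40% of its
#' length) and a q arm, each partitioned into 4 contiguous sub-bands.
#' Genes get lognormal span lengths and uniform starts within chromosome
#' bounds; an `explored` flag marks presence on the expression platform.
#'
#' @param config a [sim_config].
#' @return list: `probes` (snp_id, chrom, pos), `bands` (`cytoband_map`),
#'   `genes` (annotation data.frame).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length_bp
  probes <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(c) {
    n_exp <- ceiling(1.3 * L / config$snp_spacing_mean)
    pos <- cumsum(1 + rexp(n_exp, 1 / config$snp_spacing_mean))
    pos <- unique(round(pos[pos <= L]))
    data.frame(chrom = sprintf("chr%d", c), pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  probes <- cbind(snp_id = sprintf("snp%06d", seq_len(nrow(probes))),
                  probes, stringsAsFactors = FALSE)

  bands <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(c) {
    p_end <- round(0.4 * L)
    cuts_p <- round(seq(0, p_end, length.out = 5))
    cuts_q <- round(seq(p_end, L, length.out = 5))
    data.frame(chrom = sprintf("chr%d", c),
               start = c(cuts_p[1:4], cuts_q[1:4]),          # 0-based
               end = c(cuts_p[2:5], cuts_q[2:5]),
               band = c(sprintf("p1%d", 4:1), sprintf("q1%d", 1:4)),
               stain = rep(c("gneg", "gpos50"), 4),
               stringsAsFactors = FALSE)
  }))
  bmap <- cytoband_map(bands)

  len <- pmin(round(rlnorm(config$n_genes, log(3e4), 1)), 1e6)
  chrom <- sample(config$n_chromosomes, config$n_genes, replace = TRUE)
  start <- floor(runif(config$n_genes, 1, L - len))
  genes <- data.frame(gene_id = "", symbol = "",
                      chrom = sprintf("chr%d", chrom),
                      start = as.integer(start),
                      end = as.integer(start + len - 1),
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      explored = rbinom(config$n_genes, 1,
                                        config$explored_prob),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
  genes$symbol <- toupper(genes$gene_id)
  rownames(genes) <- NULL
  ann <- locate_band(genes$chrom, genes$start, bmap)
  genes$arm <- ann$arm; genes$cytoband <- ann$cytoband
  list(probes = probes, bands = bmap, genes = genes)
}

#' Plant CNA regions and emit per-sample state tracks
#'
#' Candidate regions are drawn genome-wide without overlap; each is
#' recurrent (planted congruently in every sample) with probability
#' `recurrence_prob`, otherwise private to one random sample.  Inside a
#' planted region each member SNP is set altered independently with
#' probability `continuity`; gains use state 3 (4 with `amp_prob`), losses
#' state 1 (0 with `double_del_prob`).  Log2 ratios are emitted per state
#' with Gaussian probe noise.
#'
#' @param config a [sim_config].
#' @param genome result of [generate_genome].
#' @return list: `snp` (a [snp_data] with log2 ratios), `truth` (regions
#'   data.frame with planted direction, recurrence, SNP spans, and target
#'   samples).
#' @export
plant_cnas <- function(config, genome) {
  set.seed(config$seed + 1L)
  probes <- genome$probes
  L <- config$chrom_length_bp
  samples <- sprintf("S%d", seq_len(config$n_samples))

  regions <- list()
  pad <- 2L * config$snp_spacing_mean
  tries <- 0
  while (length(regions) < config$n_regions && tries < 2000) {
    tries <- tries + 1
    len <- min(round(rlnorm(1, config$region_length_meanlog,
                            config$region_length_sdlog)), L / 4)
    ch <- sample(config$n_chromosomes, 1)
    st <- floor(runif(1, 1, L - len))
    en <- st + len - 1
    clash <- any(vapply(regions, function(r)
      r$chrom == sprintf("chr%d", ch) &&
        st <= r$end + pad && en >= r$start - pad, logical(1)))
    if (clash) next
    inside <- which(probes$chrom == sprintf("chr%d", ch) &
                      probes$pos >= st & probes$pos <= en)
    if (length(inside) < 2) next
    recurrent <- runif(1) < config$recurrence_prob
    regions[[length(regions) + 1]] <- list(
      region_id = sprintf("R%02d", length(regions) + 1),
      chrom = sprintf("chr%d", ch), start = st, end = en,
      direction = if (runif(1) < config$direction_mix) "gain" else "loss",
      recurrent = recurrent,
      samples = if (recurrent) samples else sample(samples, 1),
      snp_idx = inside)
  }

  st_mat <- matrix(2L, nrow(probes), config$n_samples,
                   dimnames = list(probes$snp_id, samples))
  state_log2 <- c(`0` = -1.5, `1` = -0.7, `2` = 0, `3` = 0.45, `4` = 0.9)
  lr <- matrix(rnorm(length(st_mat), 0, 0.08), nrow(probes),
               config$n_samples, dimnames = dimnames(st_mat))
  truth_rows <- list()
  for (r in regions) {
    for (s in r$samples) {
      alt <- r$snp_idx[runif(length(r$snp_idx)) <= config$continuity]
      if (length(alt) == 0) next
      if (r$direction == "gain") {
        sts <- ifelse(runif(length(alt)) < config$amp_prob, 4L, 3L)
      } else {
        sts <- ifelse(runif(length(alt)) < config$double_del_prob, 0L, 1L)
      }
      st_mat[alt, s] <- sts
      lr[alt, s] <- lr[alt, s] + state_log2[as.character(sts)]
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        region_id = r$region_id, sample_id = s, chrom = r$chrom,
        start = r$start, end = r$end, direction = r$direction,
        recurrent = r$recurrent,
        snp_start = probes$pos[min(alt)], snp_end = probes$pos[max(alt)],
        n_altered = length(alt), n_inside = length(r$snp_idx),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame()
  list(snp = snp_data(probes, st_mat, lr), truth = truth)
}

#' Simulate expression coupled to the planted copy-number truth
#'
#' Baseline intensities are lognormal.  For each cell line, genes inside
#' planted regions respond to dosage in proportion to the probability that
#' they are truly CN-altered: 1 in a fully continuous region, otherwise a
#' saturating function k/(k+3) of the altered-SNP count k in the gene span
#' (a gene lying between two altered SNPs of a discontinuous region usually
#' sits in a normal stretch).  In gained regions the concordant response is
#' up-regulation with probability `dosage_up_prob` times that weight, plus
#' a repressed fraction `repression_prob` and a partial-amplification
#' silencing term `partial_silencing_slope` x k; in lost regions the
#' concordant direction is down.  Outside regions a background deregulation
#' rate applies.  A Gaussian-copula AR(1) latent field along the gene order
#' (parameter `cluster_rho`) makes deregulation spatially clustered.
#' Controls are baseline plus replicate noise.
#'
#' @param config a [sim_config].
#' @param genome result of [generate_genome].
#' @param planted result of [plant_cnas].
#' @return list: `expr` (an `expr_matrix` of explored genes), `gene_truth`
#'   (long data.frame gene_id, sample_id, region_id, direction planted,
#'   altered_snps, true_status, true_fc).
#' @export
simulate_expression <- function(config, genome, planted) {
  set.seed(config$seed + 2L)
  genes <- genome$genes
  samples <- sprintf("S%d", seq_len(config$n_samples))
  ng <- nrow(genes)
  baseline <- rlnorm(ng, log(100), 0.8)
  truth <- planted$truth

  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  rows <- list(); fc_true <- matrix(1, ng, config$n_samples,
                                    dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    tr <- truth[truth$sample_id == s, , drop = FALSE]
    region_id <- rep(NA_character_, ng)
    dirn <- rep(NA_character_, ng)
    if (nrow(tr) > 0) {
      tgr <- GenomicRanges::GRanges(tr$chrom,
                                    IRanges::IRanges(tr$start, tr$end))
      ov <- GenomicRanges::findOverlaps(gene_gr, tgr)
      region_id[S4Vectors::queryHits(ov)] <-
        tr$region_id[S4Vectors::subjectHits(ov)]
      dirn[S4Vectors::queryHits(ov)] <-
        tr$direction[S4Vectors::subjectHits(ov)]
    }
    alt_snps <- integer(ng)
    snp_alt <- planted$snp$states[, s] != 2L
    apos <- planted$snp$probes[snp_alt, c("chrom", "pos")]
    if (nrow(apos) > 0) {
      agr <- GenomicRanges::GRanges(apos$chrom,
                                    IRanges::IRanges(apos$pos, width = 1))
      alt_snps <- GenomicRanges::countOverlaps(gene_gr, agr)
    }
    # Probability that a gene inside a planted region is truly CN-altered:
    # in a fully continuous region every gene is; in a discontinuous one the
    # evidence is the altered-SNP count in the gene span (genes lying
    # between two altered SNPs are usually in a normal stretch).
    f_alt <- if (config$continuity >= 1) rep(1, ng) else
      alt_snps / (alt_snps + 3)
    bg <- config$background_dereg_prob / 2
    p_up <- rep(bg, ng); p_down <- rep(bg, ng)
    outside <- is.na(region_id)
    gained <- !outside & dirn == "gain"
    lost <- !outside & dirn == "loss"
    slope_term <- config$partial_silencing_slope * alt_snps *
      (config$continuity < 1)
    p_up[gained] <- bg + config$dosage_up_prob * f_alt[gained]
    p_down[gained] <- bg + config$repression_prob * f_alt[gained] +
      slope_term[gained]
    p_down[lost] <- bg + config$dosage_up_prob * f_alt[lost]
    p_up[lost] <- bg + 0.05 * f_alt[lost]
    p_down <- pmin(p_down, 1)
    p_up <- pmin(p_up, 1 - p_down)

    # AR(1) latent field -> correlated uniforms along the gene order
    rho <- config$cluster_rho
    z <- numeric(ng)
    z[1] <- rnorm(1)
    for (i in seq_len(ng)[-1])
      z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * rnorm(1)
    u <- pnorm(z)
    status <- ifelse(u < p_down, "down",
                     ifelse(u > 1 - p_up, "up", "unchanged"))
    fc <- ifelse(status == "up", runif(ng, 1.7, 4),
                 ifelse(status == "down", runif(ng, 0.25, 0.6), 1))
    fc_true[, s] <- fc
    rows[[s]] <- data.frame(gene_id = genes$gene_id, sample_id = s,
                            region_id = region_id, direction = dirn,
                            altered_snps = alt_snps, true_status = status,
                            true_fc = fc, stringsAsFactors = FALSE)
  }
  gene_truth <- do.call(rbind, rows)
  rownames(gene_truth) <- NULL

  keep <- genes$explored == 1
  tum_cols <- unlist(lapply(samples, function(s)
    sprintf("%s_r%d", s, seq_len(config$n_tumor_replicates))))
  ctl_cols <- sprintf("ctrl%02d", seq_len(config$n_controls))
  mat <- matrix(0, sum(keep), length(tum_cols) + length(ctl_cols),
                dimnames = list(genes$gene_id[keep],
                                c(tum_cols, ctl_cols)))
  for (s in samples)
    for (rpl in seq_len(config$n_tumor_replicates))
      mat[, sprintf("%s_r%d", s, rpl)] <-
        baseline[keep] * fc_true[keep, s] *
        rlnorm(sum(keep), 0, config$noise_sd)
  for (j in ctl_cols)
    mat[, j] <- baseline[keep] * rlnorm(sum(keep), 0, config$noise_sd)
  roles <- c(rep("tumor", length(tum_cols)), rep("control", length(ctl_cols)))
  line <- c(rep(samples, each = config$n_tumor_replicates),
            rep(NA_character_, length(ctl_cols)))
  expr <- expression_matrix(mat, roles, line)
  list(expr = expr, gene_truth = gene_truth)
}

#' Generate a full on-disk dataset with truth
#'
#' One call emits every input format the pipeline reads — SNP state and
#' log2-ratio TSVs, a UCSC-style cytoband file, gene annotation, the
#' expression TSV (per-line triplicates plus controls), small qPCR and FISH
#' fixture tables — together with `truth.json`.  Regeneration with the same
#' seed is byte-identical.
#'
#' @param config a [sim_config].
#' @param dir output directory (created if needed).
#' @return invisible list of the generated in-memory objects.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  planted <- plant_cnas(config, genome)
  sim <- simulate_expression(config, genome, planted)

  write_snp_states(planted$snp, file.path(dir, "snp_states.tsv"),
                   file.path(dir, "snp_log2.tsv"))
  b <- genome$bands$bands
  write.table(data.frame(b$chrom, b$start - 1L, b$end, b$band, b$stain),
              file.path(dir, "cytobands.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gene_annotation(genome$genes, file.path(dir, "genes.tsv"))
  write_expression(sim$expr, file.path(dir, "expression.tsv"))

  # qPCR fixture: one target assayed in the tumour lines + controls, with a
  # planted copy number of 4 in the tumour lines.
  set.seed(config$seed + 3L)
  n_ctl <- 10
  cn_true <- c(rep(4, config$n_samples), rep(2, n_ctl))
  ref <- rlnorm(length(cn_true), log(10), 0.05)
  tgt <- ref * (cn_true / 2) * rlnorm(length(cn_true), 0, 0.05)
  qpcr <- data.frame(sample_id = c(sprintf("S%d", seq_len(config$n_samples)),
                                   sprintf("ctrl%02d", seq_len(n_ctl))),
                     target_quantity = tgt, reference_quantity = ref,
                     is_control = c(rep(0L, config$n_samples),
                                    rep(1L, n_ctl)),
                     true_cn = cn_true)
  write.table(qpcr, file.path(dir, "qpcr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # FISH fixture: 30 nuclei, planted target/control signal ratio 2.
  fish <- data.frame(nucleus_id = sprintf("n%02d", 1:30),
                     target_signals = rpois(30, 4) + 1L,
                     control_signals = rpois(30, 2) + 1L)
  write.table(fish, file.path(dir, "fish.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- list(config = unclass(config),
                regions = planted$truth,
                gene_truth = sim$gene_truth,
                qpcr_true_cn = 4)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(list(genome = genome, planted = planted, sim = sim,
                 dir = dir))
}
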