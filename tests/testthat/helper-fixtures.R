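# In-code fixtures and independent oracles shared by the test files.

# Evenly spaced probe map on one or more chromosomes.
make_probes <- function(n, chrom = "chr1", spacing = 1000L, offset = 0L) {
  data.frame(snp_id = sprintf("%s_s%04d", chrom, seq_len(n)),
             chrom = chrom,
             pos = offset + spacing * seq_len(n),
             stringsAsFactors = FALSE)
}

make_snp <- function(states, probes = NULL, log2 = NULL) {
  states <- as.matrix(states)
  if (is.null(probes)) probes <- make_probes(nrow(states))
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("S%d", seq_len(ncol(states)))
  snp_data(probes, states, log2)
}

# Small contiguous synthetic cytoband table in UCSC coordinates.
make_band_df <- function(chrom = "chr1", arm_split = 4e6, total = 1e7,
                         n_bands = 4) {
  cp <- round(seq(0, arm_split, length.out = n_bands / 2 + 1))
  cq <- round(seq(arm_split, total, length.out = n_bands / 2 + 1))
  data.frame(chrom = chrom,
             start = c(cp[-length(cp)], cq[-length(cq)]),
             end = c(cp[-1], cq[-1]),
             band = c(sprintf("p1%d", rev(seq_len(n_bands / 2))),
                      sprintf("q1%d", seq_len(n_bands / 2))),
             stain = "gneg", stringsAsFactors = FALSE)
}

# Linear-scan oracle for CNA construction from one state vector.
oracle_cnas <- function(states, probes) {
  dir <- ifelse(states %in% c(3, 4), "gain",
                ifelse(states %in% c(0, 1), "loss", "normal"))
  out <- list()
  i <- 1
  n <- length(states)
  while (i <= n) {
    if (dir[i] == "normal") { i <- i + 1; next }
    j <- i
    while (j < n && dir[j + 1] == dir[i] &&
           probes$chrom[j + 1] == probes$chrom[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(
      chrom = probes$chrom[i], start = probes$pos[i], end = probes$pos[j],
      direction = dir[i], n_snps = j - i + 1, stringsAsFactors = FALSE)
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), n_snps = integer())
}

# Per-base-pair membership oracle for the n-way CNA intersection.
oracle_mrr_bp <- function(interval_sets, max_bp) {
  covered <- rep(TRUE, max_bp)
  for (iv in interval_sets) {
    inb <- rep(FALSE, max_bp)
    for (k in seq_len(nrow(iv)))
      inb[iv$start[k]:iv$end[k]] <- TRUE
    covered <- covered & inb
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Manually constructed cna_set (intervals only; enough for find_mrrs).
manual_cnas <- function(sample_id, chrom, start, end, direction = "gain") {
  df <- data.frame(sample_id = sample_id,
                   cna_id = sprintf("%s_c%d", sample_id, seq_along(start)),
                   chrom = chrom, start = start, end = end,
                   direction = direction, n_snps = 1L,
                   stringsAsFactors = FALSE)
  class(df) <- c("cna_set", "data.frame")
  df
}

# Expression matrix with a planted multiplicative shift on some genes.
make_shift_expr <- function(n_genes, shifted = integer(0), fc = 2,
                            n_tumor = 3, n_control = 10, sdlog = 0.2,
                            seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(100), 0.4)
  mat <- base * matrix(rlnorm(n_genes * (n_tumor + n_control), 0, sdlog),
                       n_genes, n_tumor + n_control)
  if (length(shifted))
    mat[shifted, seq_len(n_tumor)] <- mat[shifted, seq_len(n_tumor)] * fc
  rownames(mat) <- sprintf("g%05d", seq_len(n_genes))
  colnames(mat) <- c(sprintf("t%d", seq_len(n_tumor)),
                     sprintf("c%d", seq_len(n_control)))
  expression_matrix(mat, c(rep("tumor", n_tumor), rep("control", n_control)))
}
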