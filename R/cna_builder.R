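# CNA construction: maximal same-direction runs of CN-altered SNPs.

#' Classify a discrete copy-number state
#'
#' States 3 and 4 are gains, 0 and 1 losses, 2 is diploid normal.  The finer
#' 4-class split (single gain vs amplification, single vs double deletion)
#' is kept only in [state_composition_summary].
#'
#' @param state integer vector with values in 0..4.
#' @return character vector in {"gain", "loss", "normal"}.
#' @export
classify_snp_state <- function(state) {
  if (any(!(state %in% 0:4) | is.na(state)))
    stop("CN states must be integers in 0..4")
  c("loss", "loss", "normal", "gain", "gain")[state + 1L]
}

#' Build copy-number-altered regions (CNAs) from one or all state tracks
#'
#' A CNA is a maximal run of consecutive CN-altered SNPs sharing one
#' direction (gain or loss) on one chromosome; an isolated altered SNP forms
#' a single-SNP CNA.  A direction change breaks the run, so every CNA has a
#' single direction label.  The CNA span is the position of the first to the
#' last member SNP.
#'
#' @param snp a [snp_data] object.
#' @param sample optional sample id; default builds CNAs for every sample.
#' @return data.frame of class `cna_set` with columns sample_id, cna_id,
#'   chrom, start, end, direction, n_snps and a list column `snp_ids`.
#' @export
build_cnas <- function(snp, sample = NULL) {
  samples <- if (is.null(sample)) snp$samples else sample
  probes <- snp$probes
  out <- list()
  for (s in samples) {
    st <- snp$states[, s]
    dir <- classify_snp_state(st)
    k <- 0L
    for (ch in unique(probes$chrom)) {
      idx <- which(probes$chrom == ch)
      r <- rle(dir[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (r$values[j] == "normal") next
        k <- k + 1L
        member <- idx[starts[j]:ends[j]]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s,
          cna_id = sprintf("%s_%s_%d", s, chrom_core(ch), k),
          chrom = ch,
          start = probes$pos[member[1]],
          end = probes$pos[member[length(member)]],
          direction = r$values[j],
          n_snps = length(member),
          stringsAsFactors = FALSE)
        out[[length(out)]]$snp_ids <- list(probes$snp_id[member])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), cna_id = character(),
               chrom = character(), start = integer(), end = integer(),
               direction = character(), n_snps = integer(),
               snp_ids = I(list()), stringsAsFactors = FALSE)
  res <- res[order(res$sample_id, res$chrom, res$start), ]
  rownames(res) <- NULL
  class(res) <- c("cna_set", "data.frame")
  res
}

#' Percent of the genome covered by CNAs, per sample
#'
#' Span length is end - start + 1 (a single-SNP CNA contributes 1 bp);
#' within-sample CNAs never overlap by construction.
#'
#' @param cnas a `cna_set`.
#' @param chrom_lengths named integer vector of chromosome lengths (e.g.
#'   the `chrom_lengths` element of a `cytoband_map`).
#' @return named numeric vector of percentages, one per sample present.
#' @export
genome_altered_fraction <- function(cnas, chrom_lengths) {
  miss <- setdiff(unique(cnas$chrom), names(chrom_lengths))
  if (length(miss))
    stop("missing chromosome length for: ", paste(miss, collapse = ", "))
  total <- sum(as.numeric(chrom_lengths))
  vapply(split(cnas, cnas$sample_id), function(x)
    100 * sum(as.numeric(x$end - x$start + 1)) / total, numeric(1))
}

#' Composition of altered SNPs by state class
#'
#' Per sample (plus an average row): the percent of evaluated SNPs that are
#' altered, and the split of altered SNPs into single gains (state 3),
#' single deletions (1), amplifications (4) and double deletions (0),
#' expressed as percent of altered SNPs.
#'
#' @param snp a [snp_data] object.
#' @return data.frame with one row per sample and an "average" row.
#' @export
state_composition_summary <- function(snp) {
  one <- function(st) {
    n <- length(st)
    alt <- st != 2L
    na <- sum(alt)
    pct <- function(k) if (na == 0) 0 else 100 * k / na
    data.frame(n_snps = n, n_altered = na,
               pct_altered = 100 * na / n,
               pct_gain = pct(sum(st == 3L)),
               pct_single_del = pct(sum(st == 1L)),
               pct_amplification = pct(sum(st == 4L)),
               pct_double_del = pct(sum(st == 0L)))
  }
  per <- do.call(rbind, lapply(snp$samples, function(s) {
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          one(snp$states[, s]))
  }))
  avg <- cbind(data.frame(sample_id = "average", stringsAsFactors = FALSE),
               as.data.frame(t(colMeans(per[, -1]))))
  rbind(per, avg)
}

#' Rebuild a state matrix from CNAs (for consistency checks)
#'
#' Reconstructs per-SNP states (2 everywhere, 3 in gain CNAs, 1 in loss
#' CNAs at member SNPs) from a `cna_set`.  Collapses states 4 to 3 and 0 to
#' 1; direction and run structure are preserved exactly.
#'
#' @param cnas a `cna_set`.
#' @param snp the [snp_data] the CNAs were built from (for the probe map).
#' @return integer matrix, probes x samples.
#' @export
states_from_cnas <- function(cnas, snp) {
  st <- matrix(2L, nrow(snp$probes), length(snp$samples),
               dimnames = list(snp$probes$snp_id, snp$samples))
  for (i in seq_len(nrow(cnas))) {
    ids <- cnas$snp_ids[[i]]
    st[ids, cnas$sample_id[i]] <-
      if (cnas$direction[i] == "gain") 3L else 1L
  }
  st
}
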