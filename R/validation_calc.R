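# Orthogonal-validation calculators: qPCR copy number, qRT-PCR
# normalization, FISH signal ratios and cross-platform correlation.

#' Gene copy number from qPCR target/reference quantities
#'
#' Each sample's target quantity is normalized by its reference-assay
#' quantity (or, in Ct mode, by efficiency^-(Ct_target - Ct_reference));
#' the copy number is twice the sample's normalized value divided by the
#' median normalized value of the diploid controls, so a control sitting at
#' the median has CN exactly 2.
#'
#' @param target per-sample target quantities (relative units) or Ct values.
#' @param reference per-sample reference-assay quantities or Ct values.
#' @param is_control logical per sample.
#' @param mode "ratio" (standard-curve quantities, default) or "ct"
#'   (comparative Ct).
#' @param efficiency amplification efficiency base for Ct mode (default 2).
#' @return named numeric vector of copy numbers per sample.
#' @export
qpcr_copy_number <- function(target, reference, is_control,
                             mode = c("ratio", "ct"), efficiency = 2) {
  mode <- match.arg(mode)
  stopifnot(length(target) == length(reference),
            length(target) == length(is_control))
  if (mode == "ratio") {
    if (any(reference <= 0)) stop("reference quantities must be positive")
    norm <- target / reference
  } else {
    norm <- efficiency^(-(target - reference))
  }
  if (sum(is_control) < 3)
    warning("fewer than 3 control samples; the median is unstable")
  ctrl_med <- stats::median(norm[is_control])
  if (ctrl_med <= 0) stop("control median must be positive")
  cn <- 2 * norm / ctrl_med
  names(cn) <- names(target)
  cn
}

#' Reference-normalized qRT-PCR expression
#'
#' Each sample's target quantity is divided by the median of its internal
#' reference quantities (e.g. GAPDH and beta-actin).
#'
#' @param target per-sample target quantities.
#' @param references numeric matrix (reference assays x samples) or a
#'   vector for a single reference.
#' @return named vector of normalized intensities.
#' @export
qrtpcr_normalize <- function(target, references) {
  if (is.null(dim(references)))
    references <- matrix(references, nrow = 1)
  med <- apply(references, 2, stats::median)
  if (any(med <= 0)) stop("reference median must be positive")
  out <- target / med
  names(out) <- names(target)
  out
}

#' Fold change of normalized qRT-PCR intensities against controls
#'
#' @param normalized per-sample normalized intensities
#'   ([qrtpcr_normalize]).
#' @param is_control logical per sample.
#' @return named vector: sample normalized value / mean of control values.
#' @export
qrtpcr_fold_change <- function(normalized, is_control) {
  cm <- mean(normalized[is_control])
  if (cm <= 0) stop("control mean must be positive")
  normalized / cm
}

#' FISH target/control signal ratio over scored nuclei
#'
#' @param target_signals integer signal counts per nucleus (target probe).
#' @param control_signals integer counts per nucleus (control probe).
#' @return ratio of mean target to mean control signals; a warning is
#'   raised when fewer than 20 nuclei were scored.
#' @export
fish_signal_ratio <- function(target_signals, control_signals) {
  stopifnot(length(target_signals) == length(control_signals),
            length(target_signals) >= 1)
  if (length(target_signals) < 20)
    warning("fewer than 20 nuclei scored; ratio is not reportable")
  mc <- mean(control_signals)
  if (mc == 0) stop("mean control signal count is zero")
  mean(target_signals) / mc
}

#' Per-gene correlation between two expression platforms
#'
#' Pearson correlation across paired samples for each gene, with the
#' two-sided p-value, and the average r over genes.
#'
#' @param platform_a genes x samples matrix (e.g. microarray intensities).
#' @param platform_b matching matrix (e.g. qRT-PCR intensities).
#' @return list: `per_gene` data.frame (gene_id, r, p; NA on zero
#'   variance), `average_r`.
#' @export
platform_correlation <- function(platform_a, platform_b) {
  stopifnot(identical(dim(platform_a), dim(platform_b)),
            ncol(platform_a) >= 3)
  ids <- rownames(platform_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(platform_a)))
  rows <- lapply(seq_len(nrow(platform_a)), function(i) {
    x <- platform_a[i, ]; y <- platform_b[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(gene_id = ids[i], r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y)
    data.frame(gene_id = ids[i], r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_gene = per, average_r = mean(per$r, na.rm = TRUE))
}
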