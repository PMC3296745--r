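#' @importFrom stats median quantile rbinom rexp rlnorm rnorm runif rpois
#'   pchisq pnorm chisq.test fisher.test cor cor.test t.test sd complete.cases
#' @importFrom utils read.table write.table head tail
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Coordinate conventions
#
# All coordinates inside the package are 1-based closed intervals, matching
# genome-browser display.  The only conversions happen at BED import/export
# (0-based half-open) and when reading UCSC cytoBand.txt (0-based starts).
# Chromosome names are normalized to "chr"-prefixed strings on input.
# ---------------------------------------------------------------------------

#' Normalize chromosome names to the "chr" prefix
#'
#' @param x character vector of chromosome names.
#' @return character vector with a "chr" prefix on every element.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

chrom_core <- function(x) sub("^chr", "", x)

#' Construct a SNP data object
#'
#' Bundles an ordered probe map with one copy-number state track per sample
#' and, optionally, per-SNP log2 ratios.  States are the discrete 5-state
#' coding: 0 homozygous deletion, 1 heterozygous deletion, 2 diploid,
#' 3 single-copy gain, 4 amplification.
#'
#' @param probes data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based base pairs).
#' @param states integer matrix, probes x samples, values in 0..4.
#' @param log2_ratio optional numeric matrix of the same shape.
#' @return an object of class `snp_data` with elements `probes`, `states`,
#'   `log2_ratio`, `samples`.
#' @export
snp_data <- function(probes, states, log2_ratio = NULL) {
  stopifnot(is.data.frame(probes),
            all(c("snp_id", "chrom", "pos") %in% names(probes)))
  probes$chrom <- normalize_chrom(probes$chrom)
  probes$pos <- as.integer(probes$pos)
  if (any(probes$pos < 1)) stop("SNP positions must be >= 1")
  states <- as.matrix(states)
  if (nrow(states) != nrow(probes))
    stop("states must have one row per probe")
  bad <- which(!(states %in% 0:4) | is.na(states))
  if (length(bad) > 0) {
    row <- ((bad[1] - 1) %% nrow(states)) + 1
    stop(sprintf("invalid CN state at probe row %d (%s): states must be integers 0-4",
                 row, probes$snp_id[row]))
  }
  storage.mode(states) <- "integer"
  ord <- order(probes$chrom, probes$pos)
  probes <- probes[ord, , drop = FALSE]
  states <- states[ord, , drop = FALSE]
  if (!is.null(log2_ratio)) {
    log2_ratio <- as.matrix(log2_ratio)[ord, , drop = FALSE]
    if (!identical(dim(log2_ratio), dim(states)))
      stop("log2_ratio must match the states matrix")
  }
  dup <- duplicated(probes[, c("chrom", "pos")])
  if (any(dup))
    stop(sprintf("duplicate (chrom, pos) at %s:%d",
                 probes$chrom[which(dup)[1]], probes$pos[which(dup)[1]]))
  rownames(probes) <- NULL
  structure(list(probes = probes, states = states,
                 log2_ratio = log2_ratio, samples = colnames(states)),
            class = "snp_data")
}

#' @export
print.snp_data <- function(x, ...) {
  cat(sprintf("snp_data: %d probes on %d chromosome(s), %d sample(s)\n",
              nrow(x$probes), length(unique(x$probes$chrom)),
              length(x$samples)))
  invisible(x)
}

#' Read per-SNP copy-number state tracks
#'
#' The state TSV has header columns `snp_id`, `chrom`, `pos`, followed by one
#' integer state column per sample.  An optional parallel file with the same
#' layout carries per-SNP log2 ratios.
#'
#' @param path path to the state TSV.
#' @param log2_path optional path to a log2-ratio TSV with identical layout.
#' @return a [snp_data] object.
#' @export
read_snp_states <- function(path, log2_path = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("state TSV must have columns snp_id, chrom, pos")
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0) stop("no sample state columns found")
  st <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(st) || any(st != floor(st), na.rm = TRUE)) {
    bad <- which(apply(df[, sample_cols, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.integer(r))))))
    stop(sprintf("non-integer CN state at row %d of %s",
                 if (length(bad)) bad[1] else NA_integer_, path))
  }
  lr <- NULL
  if (!is.null(log2_path)) {
    lf <- read.table(log2_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!identical(lf$snp_id, df$snp_id))
      stop("log2 file probe order differs from state file")
    lr <- as.matrix(lf[, sample_cols, drop = FALSE])
  }
  snp_data(df[, need], st, lr)
}

#' Write per-SNP state tracks (inverse of [read_snp_states])
#'
#' @param snp a [snp_data] object.
#' @param path output TSV path.
#' @param log2_path optional output path for the log2-ratio table.
#' @export
write_snp_states <- function(snp, path, log2_path = NULL) {
  out <- cbind(snp$probes[, c("snp_id", "chrom", "pos")],
               as.data.frame(snp$states))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(log2_path) && !is.null(snp$log2_ratio)) {
    lo <- cbind(snp$probes[, c("snp_id", "chrom", "pos")],
                as.data.frame(snp$log2_ratio))
    write.table(lo, log2_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a UCSC cytoBand.txt file
#'
#' The UCSC dialect is 5 tab-separated columns (chrom, start, end, band,
#' stain) with 0-based half-open coordinates; these are converted to the
#' package's 1-based closed convention.  Bands of each chromosome must be
#' contiguous and non-overlapping.  The arm of a band is the chromosome core
#' name plus the first character of the band name (e.g. "5p").
#'
#' @param path path to a cytoBand.txt-format file (no header).
#' @return an object of class `cytoband_map`: list with `bands` (data.frame
#'   chrom, start, end, band, stain, arm), `arms` (per-arm extents) and
#'   `chrom_lengths` (named integer vector).
#' @export
read_cytobands <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "band", "stain"))
  cytoband_map(df)
}

#' Build a cytoband map from a UCSC-style data.frame
#'
#' @param df data.frame with columns chrom, start (0-based), end, band, stain.
#' @return a `cytoband_map` object (see [read_cytobands]).
#' @export
cytoband_map <- function(df) {
  df$chrom <- normalize_chrom(df$chrom)
  if (!all(grepl("^[pq]", df$band)))
    stop("every band name must begin with 'p' or 'q'")
  df$start <- as.integer(df$start) + 1L   # 0-based -> 1-based closed
  df$end <- as.integer(df$end)
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (nrow(b) > 1) {
      gaps <- b$start[-1] - b$end[-nrow(b)]
      if (any(gaps != 1))
        stop(sprintf("bands of %s have a gap or overlap near position %d",
                     ch, b$end[which(gaps != 1)[1]]))
    }
  }
  df$arm <- paste0(chrom_core(df$chrom), substr(df$band, 1, 1))
  arms <- do.call(rbind, lapply(split(df, paste(df$chrom, df$arm)), function(b)
    data.frame(chrom = b$chrom[1], arm = b$arm[1],
               start = min(b$start), end = max(b$end),
               stringsAsFactors = FALSE)))
  arms <- arms[order(arms$chrom, arms$start), ]
  rownames(arms) <- NULL
  lens <- vapply(split(df$end, df$chrom), max, integer(1))
  rownames(df) <- NULL
  structure(list(bands = df, arms = arms, chrom_lengths = lens),
            class = "cytoband_map")
}

#' Locate the cytoband and arm containing a position
#'
#' Positions on a boundary shared by two closed intervals are assigned to the
#' lower-coordinate band.  Vectorized over `chrom`/`pos`.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @param bands a `cytoband_map`.
#' @return data.frame with columns `arm` and `cytoband` (e.g. "5p",
#'   "5p15.2").
#' @export
locate_band <- function(chrom, pos, bands) {
  chrom <- normalize_chrom(chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  b <- bands$bands
  arm <- cyto <- character(n)
  for (i in seq_len(n)) {
    hit <- which(b$chrom == chrom[i] & b$start <= pos[i] & b$end >= pos[i])
    if (length(hit) == 0)
      stop(sprintf("position %s:%d is outside all annotated bands",
                   chrom[i], pos[i]))
    hit <- hit[1]                       # lower-coordinate band wins ties
    arm[i] <- b$arm[hit]
    cyto[i] <- paste0(chrom_core(b$chrom[hit]), b$band[hit])
  }
  data.frame(arm = arm, cytoband = cyto, stringsAsFactors = FALSE)
}

#' Annotate SNP probes with arm and cytoband
#'
#' @param snp a [snp_data] object.
#' @param bands a `cytoband_map`.
#' @return the `snp_data` object with `arm` and `cytoband` probe columns.
#' @export
annotate_probes <- function(snp, bands) {
  ann <- locate_band(snp$probes$chrom, snp$probes$pos, bands)
  snp$probes$arm <- ann$arm
  snp$probes$cytoband <- ann$cytoband
  snp
}

#' Export genomic regions as BED
#'
#' Internal 1-based closed intervals are written as standard 0-based
#' half-open BED records (name = region id, score = 0, column 6 = direction
#' label).  Regions are sorted before writing.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, an id
#'   column (`cna_id` or `mrr_id` or `name`) and `direction`.
#' @param path output file.
#' @export
export_bed <- function(regions, path) {
  idcol <- intersect(c("cna_id", "mrr_id", "name"), names(regions))[1]
  if (is.na(idcol)) stop("regions need an id column (cna_id/mrr_id/name)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tdirection", con)
  if (nrow(regions) == 0) return(invisible(path))
  if (any(regions$start < 1 | regions$end < regions$start))
    stop("regions must satisfy 1 <= start <= end")
  regions <- regions[order(regions$chrom, regions$start, regions$end), ]
  out <- data.frame(chrom = normalize_chrom(regions$chrom),
                    start = regions$start - 1L,   # to 0-based half-open
                    end = regions$end,
                    name = regions[[idcol]],
                    score = 0L,
                    direction = regions$direction)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions written by [export_bed]
#'
#' @param path BED path.
#' @return data.frame with 1-based closed `chrom`, `start`, `end`, `name`,
#'   `direction`.
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      direction = character(), stringsAsFactors = FALSE))
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "direction"))
  data.frame(chrom = df$chrom, start = df$start + 1L, end = df$end,
             name = as.character(df$name), direction = df$direction,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: gene_id, symbol, chrom, start, end, strand and
#' optionally `explored` (0/1: whether the gene is represented on the
#' expression platform).  Coordinates are 1-based closed.
#'
#' @param path TSV path.
#' @param bands optional `cytoband_map`; when given, arm/cytoband columns are
#'   added from the gene start position.
#' @return data.frame of gene annotation, sorted by (chrom, start).
#' @export
read_gene_annotation <- function(path, bands = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene annotation must have columns gene_id symbol chrom start end strand")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$start > df$end)) stop("gene start must be <= end")
  df$chrom <- normalize_chrom(df$chrom)
  if (!"explored" %in% names(df)) df$explored <- 1L
  df <- df[order(df$chrom, df$start, df$end), ]
  rownames(df) <- NULL
  if (!is.null(bands)) {
    ann <- locate_band(df$chrom, df$start, bands)
    df$arm <- ann$arm
    df$cytoband <- ann$cytoband
  }
  df
}

#' Write a gene annotation table (inverse of [read_gene_annotation])
#' @param genes gene annotation data.frame.
#' @param path output TSV.
#' @export
write_gene_annotation <- function(genes, path) {
  keep <- intersect(c("gene_id", "symbol", "chrom", "start", "end",
                      "strand", "explored"), names(genes))
  write.table(genes[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix object
#'
#' Normalized intensities (positive, relative units) for tumour replicates
#' and controls.  Tumour samples may carry a cell-line label so per-line
#' contrasts can be formed.
#'
#' @param mat numeric matrix, genes x samples, positive entries; rownames are
#'   gene ids.
#' @param roles character vector per sample: "tumor" or "control".
#' @param line optional character per sample; cell-line id for tumour
#'   replicates, NA for controls.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(mat, roles, line = NULL) {
  mat <- as.matrix(mat)
  if (any(mat <= 0)) stop("expression intensities must be positive")
  roles <- as.character(roles)
  if (length(roles) != ncol(mat)) stop("one role per sample required")
  if (!all(roles %in% c("tumor", "control")))
    stop("roles must be 'tumor' or 'control'")
  if (is.null(line)) line <- ifelse(roles == "tumor", "tumor", NA_character_)
  structure(list(mat = mat, roles = roles, line = line,
                 genes = rownames(mat), samples = colnames(mat)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes, %d tumour + %d control samples\n",
              nrow(x$mat), sum(x$roles == "tumor"),
              sum(x$roles == "control")))
  invisible(x)
}

#' Read an expression TSV
#'
#' First line: header `gene_id` then sample names.  Second line: `#role`
#' then one role per sample, either `control` or `tumor[:line]`.  Remaining
#' lines: gene rows of positive intensities.
#'
#' @param path TSV path.
#' @return an [expression_matrix] object.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 2)
  header <- strsplit(lines[1], "\t")[[1]]
  if (!startsWith(lines[2], "#role"))
    stop("expression TSV must carry a '#role' line after the header")
  roletok <- strsplit(lines[2], "\t")[[1]][-1]
  roles <- sub(":.*$", "", roletok)
  line <- ifelse(grepl(":", roletok), sub("^[^:]*:", "", roletok),
                 NA_character_)
  df <- read.table(path, header = FALSE, sep = "\t", skip = 2,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  colnames(mat) <- header[-1]
  expression_matrix(mat, roles, line)
}

#' Write an expression TSV (inverse of [read_expression])
#' @param expr an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr$mat)), collapse = "\t"), con)
  roletok <- ifelse(expr$roles == "tumor" & !is.na(expr$line),
                    paste0("tumor:", expr$line), expr$roles)
  writeLines(paste(c("#role", roletok), collapse = "\t"), con)
  write.table(data.frame(rownames(expr$mat), expr$mat),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to one tumour line plus the controls
#'
#' @param expr an `expr_matrix`.
#' @param line cell-line label to keep (tumour replicates of that line).
#' @return an `expr_matrix` with the line's replicates and all controls.
#' @export
subset_expression <- function(expr, line) {
  keep <- expr$roles == "control" |
    (expr$roles == "tumor" & !is.na(expr$line) & expr$line == line)
  if (!any(expr$roles[keep] == "tumor"))
    stop(sprintf("no tumour replicates labelled '%s'", line))
  expression_matrix(expr$mat[, keep, drop = FALSE], expr$roles[keep],
                    expr$line[keep])
}
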