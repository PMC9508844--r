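# Dropout-screen count analysis: total-count (reads-per-million)
# normalization, library-size factors from non-targeting control guides by
# median-of-ratios, paired log2 fold changes between timepoints, and
# per-region / per-chromosome summaries.

as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Total-count normalization (reads per million)
#'
#' @param x A [count_matrix()] or plain counts matrix.
#' @return Numeric matrix with every column scaled to total 1e6.
#' @export
total_count_normalize <- function(x) {
  m <- as_count_mat(x)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort("sample '%s' has zero total count",
          colnames(m)[which(totals <= 0)[1L]])
  }
  sweep(m, 2L, 1e6 / totals, `*`)
}

#' Library-size factors from control guides (median-of-ratios)
#'
#' Per-sample scale factors estimated from non-targeting control guides
#' only: each control's counts are divided by its geometric mean across
#' samples, and the factor for a sample is the median of those ratios.
#' Controls with any zero count are excluded (their geometric mean is
#' degenerate). Normalizing to controls makes neutral guides read as
#' unchanged even when much of the library depletes.
#'
#' @param x A [count_matrix()] (uses its control flag) or counts matrix.
#' @param is_control Logical per-guide flag; required when `x` is a plain
#'   matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
control_size_factors <- function(x, is_control = NULL) {
  m <- as_count_mat(x)
  if (is.null(is_control)) {
    if (!inherits(x, "count_matrix")) {
      abort("is_control is required for a plain matrix")
    }
    is_control <- x$is_control
  }
  ctrl <- m[is_control, , drop = FALSE]
  ctrl <- ctrl[rowSums(ctrl == 0) == 0L, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    abort("no control guides with nonzero counts in all samples")
  }
  geo <- exp(rowMeans(log(ctrl)))
  sf <- apply(ctrl / geo, 2L, stats::median)
  stats::setNames(as.numeric(sf), colnames(m))
}

#' Paired log2 fold changes between timepoints
#'
#' For each replicate pair (reference sample, target sample), computes per
#' guide `log2((target/sf_target + pc) / (reference/sf_reference + pc))`
#' with pseudocount `pc` added after size-factor scaling; the guide-level
#' value is the mean over replicate pairs. Negative values mean dropout
#' of the guide between the reference (early) and target (late) timepoint.
#'
#' @param x A [count_matrix()] or counts matrix.
#' @param size_factors Named per-sample factors, e.g. from
#'   [control_size_factors()].
#' @param pairs Data.frame with columns `replicate`, `reference`, `target`
#'   naming disjoint sample pairs.
#' @param pseudocount Symmetric pseudocount (default 0.5).
#' @return Data.frame of class `fold_change_table`: `id`, `lfc` (mean over
#'   replicates), plus one `lfc_<replicate>` column per pair.
#' @export
log2_fold_change <- function(x, size_factors, pairs, pseudocount = 0.5) {
  m <- as_count_mat(x)
  need <- c(pairs$reference, pairs$target)
  miss <- setdiff(need, colnames(m))
  if (length(miss)) abort("unknown sample(s) in pairing: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(need)) {
    abort("pairing must cover disjoint sample pairs (sample '%s' reused)",
          need[duplicated(need)][1L])
  }
  miss_sf <- setdiff(need, names(size_factors))
  if (length(miss_sf)) abort("no size factor for sample(s): %s",
                             paste(miss_sf, collapse = ", "))
  stopifnot(pseudocount > 0)
  reps <- vapply(seq_len(nrow(pairs)), function(i) {
    r <- pairs$reference[i]; t <- pairs$target[i]
    log2((m[, t] / size_factors[[t]] + pseudocount) /
         (m[, r] / size_factors[[r]] + pseudocount))
  }, numeric(nrow(m)))
  colnames(reps) <- paste0("lfc_", pairs$replicate)
  out <- data.frame(id = rownames(m), lfc = rowMeans(reps), reps,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regexec("^([^:]+):([0-9]+)-([0-9]*)$", region)
    h <- regmatches(region, m)[[1L]]
    if (length(h) != 4L) abort("cannot parse region '%s'", region)
    region <- list(chrom = h[2L], start = as.numeric(h[3L]),
                   end = if (nzchar(h[4L])) as.numeric(h[4L]) else Inf)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  region
}

#' Compare fold changes of guides inside vs outside a genomic region
#'
#' Dose comparison for copy-number-variable regions (e.g. a trisomic
#' chromosome-arm amplification, where guides cutting inside induce more
#' breaks per cell): partitions guides by cut position and compares the
#' two log2-fold-change distributions with a two-sided rank-sum
#' (Wilcoxon) test.
#'
#' @param fold_changes A `fold_change_table`.
#' @param guides Manifest data.frame with `id`, `chrom`, `cut_pos`.
#' @param region `list(chrom, start, end)` or a string
#'   `"chrom:start-end"` (`"chrom:start-"` for an open right end);
#'   0-based half-open.
#' @return List: `n_inside`, `n_outside`, `median_inside`,
#'   `median_outside`, `median_diff` (inside - outside), `p_value`.
#' @export
region_dose_comparison <- function(fold_changes, guides, region) {
  region <- parse_region(region)
  g <- merge(fold_changes[, c("id", "lfc")],
             guides[, c("id", "chrom", "cut_pos")], by = "id")
  g <- g[!is.na(g$chrom), , drop = FALSE]
  inside <- g$chrom == region$chrom & g$cut_pos >= region$start &
    g$cut_pos < region$end
  if (sum(inside) < 2L || sum(!inside) < 2L) {
    abort("need >= 2 guides inside and outside the region (have %d / %d)",
          sum(inside), sum(!inside))
  }
  test <- stats::wilcox.test(g$lfc[inside], g$lfc[!inside],
                             alternative = "two.sided", exact = FALSE)
  list(n_inside = sum(inside), n_outside = sum(!inside),
       median_inside = stats::median(g$lfc[inside]),
       median_outside = stats::median(g$lfc[!inside]),
       median_diff = stats::median(g$lfc[inside]) -
         stats::median(g$lfc[!inside]),
       p_value = unname(test$p.value))
}

#' Per-chromosome fold-change summaries
#'
#' @param fold_changes A `fold_change_table`.
#' @param guides Manifest data.frame with `id`, `chrom`.
#' @return Data.frame: `chrom`, `n`, `median`, `mad` of guide-level lfc,
#'   sorted by chromosome.
#' @export
chromosome_summary <- function(fold_changes, guides) {
  g <- merge(fold_changes[, c("id", "lfc")], guides[, c("id", "chrom")],
             by = "id")
  g <- g[!is.na(g$chrom), , drop = FALSE]
  chroms <- sort(unique(g$chrom))
  out <- data.frame(
    chrom = chroms,
    n = vapply(chroms, function(ch) sum(g$chrom == ch), 0L),
    median = vapply(chroms, function(ch) stats::median(g$lfc[g$chrom == ch]), 0),
    mad = vapply(chroms, function(ch) stats::mad(g$lfc[g$chrom == ch]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
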