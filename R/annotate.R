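# Windowed chromatin-context annotation: for each guide, summarise the
# chromatin tracks in a fixed window (default 4 kb) centred on the cut
# site, producing the per-guide feature table that the pool filters
# consume.
#
# Fractions use the full nominal window length as denominator even when
# the window is clipped at a chromosome end (the clipped flag records
# this), so thresholds stay comparable across guides; clipped-away and
# uncovered base pairs accrue to "unannotated".

BUILTIN_STATE_LABELS <- as.character(1:10)

#' Window around a guide's cut site
#'
#' @param guide One-row data.frame or list with `chrom` and `cut_pos`.
#' @param window_size Window width in bp (even, >= 2; default 4000).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, the window is clipped at the chromosome bounds and a cut site
#'   outside the chromosome is an error.
#' @return List with `chrom`, `start`, `end` (clipped), `nominal`
#'   (window_size) and `clipped` flag.
#' @export
guide_window <- function(guide, window_size = 4000, chrom_lengths = NULL) {
  if (window_size < 2 || window_size %% 2 != 0) {
    abort("window_size must be an even integer >= 2")
  }
  cut <- guide$cut_pos
  chrom <- guide$chrom
  half <- window_size / 2
  start <- cut - half
  end <- cut + half
  clipped <- FALSE
  if (cut < 0) abort("cut position %d below chromosome start", cut)
  if (start < 0) {
    start <- 0
    clipped <- TRUE
  }
  if (!is.null(chrom_lengths)) {
    if (!chrom %in% names(chrom_lengths)) {
      abort("chromosome '%s' not in the genome namespace", chrom)
    }
    len <- chrom_lengths[[chrom]]
    if (cut > len) {
      abort("cut position %d outside chromosome %s (length %d)",
            cut, chrom, len)
    }
    if (end > len) {
      end <- len
      clipped <- TRUE
    }
  }
  list(chrom = chrom, start = start, end = end,
       nominal = window_size, clipped = clipped)
}

# bp overlap of each track interval (subset to window$chrom) with window
window_overlaps <- function(window, track) {
  t <- track[track$chrom == window$chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(cbind(t, ov = numeric(0)))
  ov <- pmax(0, pmin(t$end, window$end) - pmax(t$start, window$start))
  t$ov <- ov
  t[t$ov > 0, , drop = FALSE]
}

#' State composition of a window
#'
#' Fraction of the window covered by each label of a labeled interval
#' track (ChromHMM-style state calls); uncovered bp accrue to
#' `"unannotated"`. Also reports the breaksite state: the label of the
#' interval containing `cut_pos` (`"unannotated"` if none).
#'
#' @param window A window from [guide_window()].
#' @param states Labeled interval track (see [read_interval_track()]).
#' @param cut_pos Cut-site coordinate for the breaksite call; `NULL` skips it.
#' @param labels Label vocabulary to report (default: labels present in the
#'   track, plus `"1"`..`"10"`).
#' @return List with `fractions` (named, including `"unannotated"`, summing
#'   to 1) and `breaksite_state`.
#' @export
state_fractions <- function(window, states, cut_pos = NULL, labels = NULL) {
  if (is.null(labels)) {
    labels <- sort(unique(c(states$label, BUILTIN_STATE_LABELS)))
  }
  t <- window_overlaps(window, states)
  bp <- stats::setNames(rep(0, length(labels)), labels)
  if (nrow(t)) {
    agg <- tapply(t$ov, t$label, sum)
    bp[names(agg)] <- agg
  }
  frac <- bp / window$nominal
  frac <- c(frac, unannotated = max(0, 1 - sum(frac)))
  breaksite <- "unannotated"
  if (!is.null(cut_pos)) {
    hit <- states$chrom == window$chrom &
      states$start <= cut_pos & cut_pos < states$end
    if (any(hit)) breaksite <- states$label[which(hit)[1L]]
  }
  list(fractions = frac, breaksite_state = breaksite)
}

#' Lamina composition of a window
#'
#' Fractions of the window under LAD and iLAD labels of a lamina
#' segmentation (Lamin-B1 DamID calls).
#'
#' @param window A window from [guide_window()].
#' @param lads Labeled track with labels in {LAD, iLAD}.
#' @return Named vector `c(lad, ilad, unannotated)` summing to 1.
#' @export
lamina_fractions <- function(window, lads) {
  bad <- setdiff(unique(lads$label), c("LAD", "iLAD"))
  if (length(bad)) {
    abort("lamina track has unknown label(s): %s", paste(bad, collapse = ", "))
  }
  t <- window_overlaps(window, lads)
  lad <- sum(t$ov[t$label == "LAD"]) / window$nominal
  ilad <- sum(t$ov[t$label == "iLAD"]) / window$nominal
  c(lad = lad, ilad = ilad, unannotated = max(0, 1 - lad - ilad))
}

#' Signal summaries over a window
#'
#' For a valued track (bedGraph): the maximum value among intervals
#' overlapping the window (0 if none) and the coverage-weighted mean
#' (sum of value x overlap bp over the nominal window length; uncovered bp
#' contribute zero signal).
#'
#' @param window A window from [guide_window()].
#' @param track Valued interval track.
#' @return Named vector `c(max, wmean)`.
#' @export
window_signal <- function(window, track) {
  t <- window_overlaps(window, track)
  if (nrow(t) == 0L) return(c(max = 0, wmean = 0))
  c(max = max(t$value), wmean = sum(t$value * t$ov) / window$nominal)
}

#' Gene context of a cut site
#'
#' @param chrom,cut_pos Cut-site location.
#' @param genes A [read_gene_models()] object.
#' @param expression_threshold Expression above which an overlapping gene
#'   counts as expressed (default 1 normalized-expression unit).
#' @return Named logical vector `c(genic, intronic, exonic, expressed)`.
#'   `exonic` means inside an exon of an overlapping gene; `intronic` is
#'   genic and not exonic; `expressed` is `FALSE` for non-genic sites.
#' @export
gene_context <- function(chrom, cut_pos, genes, expression_threshold = 1) {
  g <- genes$genes
  hit <- g$chrom == chrom & g$start <= cut_pos & cut_pos < g$end
  genic <- any(hit)
  exonic <- FALSE
  expressed <- FALSE
  if (genic) {
    ids <- g$id[hit]
    ex <- genes$exons
    exonic <- any(ex$gene %in% ids & ex$start <= cut_pos & cut_pos < ex$end)
    expressed <- any(g$expression[hit] > expression_threshold)
  }
  c(genic = genic, intronic = genic && !exonic, exonic = exonic,
    expressed = expressed)
}

#' Annotate guides with windowed chromatin features
#'
#' The integration stage: for each placed guide, computes state fractions
#' and breaksite state, LAD/iLAD fractions, DNaseI window maximum,
#' H3K9me3 coverage-weighted mean, and gene context, in a fixed window
#' centred on the cut site. Control rows (`is_control == TRUE` or `NA`
#' placement) are dropped. Deterministic: re-running yields an identical
#' table.
#'
#' A guide chromosome absent from `chrom_lengths` (the genome namespace,
#' when supplied) is an error; a chromosome merely lacking intervals in a
#' track yields unannotated fractions / zero signal for that track.
#'
#' @param guides Manifest data.frame with `id`, `chrom`, `cut_pos`.
#' @param states Labeled state track.
#' @param lads Labeled LAD/iLAD track.
#' @param dnase,h3k9me3 Valued signal tracks.
#' @param genes A `gene_models` object.
#' @param window_size Window width in bp (default 4000).
#' @param expression_threshold See [gene_context()].
#' @param chrom_lengths Optional named chromosome lengths for clipping and
#'   namespace validation.
#' @return Data.frame of class `guide_annotation`, one row per guide:
#'   window coordinates and `clipped`, `state<label>_frac` columns plus
#'   `unannotated_frac`, `breaksite_state`, `lad_frac`, `ilad_frac`,
#'   `lamina_unannotated_frac`, `dnase_max`, `h3k9me3_wmean`, `genic`,
#'   `intronic`, `exonic`, `expressed`.
#' @export
annotate_guides <- function(guides, states, lads, dnase, h3k9me3, genes,
                            window_size = 4000, expression_threshold = 1,
                            chrom_lengths = NULL) {
  if ("is_control" %in% names(guides)) {
    guides <- guides[!guides$is_control, , drop = FALSE]
  }
  guides <- guides[!is.na(guides$chrom), , drop = FALSE]
  labels <- sort(unique(c(states$label, BUILTIN_STATE_LABELS)))
  n <- nrow(guides)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- guides[i, ]
    w <- guide_window(g, window_size, chrom_lengths)
    st <- state_fractions(w, states, cut_pos = g$cut_pos, labels = labels)
    lam <- lamina_fractions(w, lads)
    dn <- window_signal(w, dnase)
    k9 <- window_signal(w, h3k9me3)
    gc <- gene_context(g$chrom, g$cut_pos, genes, expression_threshold)
    frac <- as.list(st$fractions[labels])
    names(frac) <- paste0("state", labels, "_frac")
    rows[[i]] <- data.frame(
      id = g$id, chrom = g$chrom, cut_pos = g$cut_pos,
      window_start = w$start, window_end = w$end, clipped = w$clipped,
      frac, unannotated_frac = unname(st$fractions[["unannotated"]]),
      breaksite_state = st$breaksite_state,
      lad_frac = unname(lam[["lad"]]), ilad_frac = unname(lam[["ilad"]]),
      lamina_unannotated_frac = unname(lam[["unannotated"]]),
      dnase_max = unname(dn[["max"]]), h3k9me3_wmean = unname(k9[["wmean"]]),
      genic = unname(gc[["genic"]]), intronic = unname(gc[["intronic"]]),
      exonic = unname(gc[["exonic"]]), expressed = unname(gc[["expressed"]]),
      stringsAsFactors = FALSE)
  }
  out <- if (n) do.call(rbind, rows) else NULL
  if (is.null(out)) abort("no placed, non-control guides to annotate")
  rownames(out) <- NULL
  class(out) <- c("guide_annotation", "data.frame")
  out
}

#' Construct a synthetic annotation record
#'
#' Builds a one-row `guide_annotation` table with every feature set
#' explicitly (defaults give an unannotated, signal-free, intergenic
#' record). Useful for exercising pool rules against controlled feature
#' values, e.g. threshold boundary sweeps.
#'
#' @param id Guide id.
#' @param chrom,cut_pos Nominal placement.
#' @param state_fracs Named numeric, e.g. `c("2" = 0.7)`; the remainder up
#'   to 1 is assigned to `unannotated`.
#' @param breaksite_state Breaksite state label.
#' @param lad_frac,ilad_frac Lamina fractions.
#' @param dnase_max,h3k9me3_wmean Signal features.
#' @param genic,intronic,exonic,expressed Gene-context flags.
#' @return One-row `guide_annotation` data.frame.
#' @export
make_annotation_record <- function(id = "g1", chrom = "chr1", cut_pos = 10000L,
                                   state_fracs = c(), breaksite_state = "unannotated",
                                   lad_frac = 0, ilad_frac = 0,
                                   dnase_max = 0, h3k9me3_wmean = 0,
                                   genic = FALSE, intronic = FALSE,
                                   exonic = FALSE, expressed = FALSE) {
  labels <- BUILTIN_STATE_LABELS
  frac <- stats::setNames(rep(0, length(labels)), labels)
  if (length(state_fracs)) {
    unknown <- setdiff(names(state_fracs), labels)
    if (length(unknown)) {
      labels <- c(labels, unknown)
      frac <- c(frac, stats::setNames(rep(0, length(unknown)), unknown))
    }
    frac[names(state_fracs)] <- state_fracs
  }
  if (sum(frac) > 1 + 1e-9) abort("state fractions exceed 1")
  cols <- as.list(frac)
  names(cols) <- paste0("state", labels, "_frac")
  out <- data.frame(
    id = id, chrom = chrom, cut_pos = cut_pos,
    window_start = cut_pos - 2000L, window_end = cut_pos + 2000L,
    clipped = FALSE, cols, unannotated_frac = max(0, 1 - sum(frac)),
    breaksite_state = breaksite_state, lad_frac = lad_frac,
    ilad_frac = ilad_frac,
    lamina_unannotated_frac = max(0, 1 - lad_frac - ilad_frac),
    dnase_max = dnase_max, h3k9me3_wmean = h3k9me3_wmean,
    genic = genic, intronic = intronic, exonic = exonic,
    expressed = expressed, stringsAsFactors = FALSE)
  class(out) <- c("guide_annotation", "data.frame")
  out
}

#' Read / write a guide annotation table
#'
#' @param x A `guide_annotation` data.frame.
#' @param path TSV path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_annotation <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(breaksite_state = "character",
                                          chrom = "character"))
  class(out) <- c("guide_annotation", "data.frame")
  out
}
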