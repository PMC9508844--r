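# Readers and writers for the on-disk formats the pipeline touches.
#
# One coordinate convention everywhere: 0-based, half-open [start, end),
# BED-native. Any 1-based display is formatting only. All formats are
# tab-separated; lines starting with '#' are skipped.

#' Read a genome from FASTA
#'
#' Loads all records of a FASTA file into a named character vector
#' (chromosome name -> upper-case sequence over A/C/G/T/N).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) abort("%s: empty FASTA file", path)
  first <- which(!grepl("^#", lines) & nzchar(lines))[1L]
  if (!startsWith(lines[first], ">")) {
    abort("%s: line %d: expected FASTA header ('>'), got %s",
          path, first, shQuote(substr(lines[first], 1, 30)))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort("%s: malformed FASTA: %s", path, conditionMessage(e))
  )
  if (any(Biostrings::width(set) == 0L)) {
    empty <- names(set)[Biostrings::width(set) == 0L][1L]
    abort("%s: empty FASTA record '%s'", path, empty)
  }
  genome <- toupper(as.character(set))
  names(genome) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(genome))) {
    abort("%s: duplicate chromosome name '%s'",
          path, names(genome)[duplicated(names(genome))][1L])
  }
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    abort("%s: record '%s' contains characters outside {A,C,G,T,N}",
          path, names(genome)[bad][1L])
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# shared BED-dialect line reader: returns a data.frame of character columns
read_tab_records <- function(path, min_fields) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1L]
    abort("%s: line %d: expected >= %d tab-separated fields, got %d",
          path, lineno[i], min_fields, nf[i])
  }
  list(fields = fields, lineno = lineno)
}

parse_coords <- function(path, fields, lineno) {
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | !is_wholenumber(start) | !is_wholenumber(end)
  if (any(bad)) {
    abort("%s: line %d: non-integer coordinates", path, lineno[which(bad)[1L]])
  }
  viol <- start >= end | start < 0
  if (any(viol)) {
    i <- which(viol)[1L]
    abort("%s: line %d: invalid interval [%s, %s) (need 0 <= start < end)",
          path, lineno[i], format(start[i]), format(end[i]))
  }
  list(start = as.integer(start), end = as.integer(end))
}

#' Read a BED4/bedGraph interval track
#'
#' In `labeled` mode column 4 is taken as a string label (e.g. ChromHMM
#' state calls, or LAD/iLAD segmentation); in `valued` mode it is parsed as
#' a non-negative real signal value (bedGraph, e.g. DNaseI peak height).
#' Intervals are returned sorted by (chrom, start). Coordinate violations
#' (start >= end) are rejected, never repaired; valued tracks additionally
#' reject overlapping intervals on one chromosome.
#'
#' @param path Path to a BED4 or bedGraph file.
#' @param mode `"labeled"` or `"valued"`.
#' @return A data.frame with columns `chrom`, `start`, `end` and `label`
#'   (labeled) or `value` (valued).
#' @export
read_interval_track <- function(path, mode = c("labeled", "valued")) {
  mode <- match.arg(mode)
  rec <- read_tab_records(path, 4L)
  co <- parse_coords(path, rec$fields, rec$lineno)
  chrom <- vapply(rec$fields, `[[`, "", 1L)
  col4 <- vapply(rec$fields, `[[`, "", 4L)
  if (mode == "labeled") {
    track <- data.frame(chrom = chrom, start = co$start, end = co$end,
                        label = col4, stringsAsFactors = FALSE)
  } else {
    value <- suppressWarnings(as.numeric(col4))
    if (anyNA(value)) {
      abort("%s: line %d: non-numeric value '%s'",
            path, rec$lineno[which(is.na(value))[1L]], col4[which(is.na(value))[1L]])
    }
    if (any(value < 0)) {
      abort("%s: line %d: negative signal value",
            path, rec$lineno[which(value < 0)[1L]])
    }
    track <- data.frame(chrom = chrom, start = co$start, end = co$end,
                        value = value, stringsAsFactors = FALSE)
  }
  track <- sort_track(track)
  if (mode == "valued") assert_no_overlap(track, path)
  rownames(track) <- NULL
  track
}

sort_track <- function(track) {
  track[order(track$chrom, track$start, track$end), , drop = FALSE]
}

assert_no_overlap <- function(track, what = "track") {
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    if (nrow(t) > 1L && any(t$start[-1L] < t$end[-nrow(t)])) {
      abort("%s: overlapping intervals on %s", what, ch)
    }
  }
  invisible(track)
}

#' Write an interval track (BED4 / bedGraph)
#'
#' @param track Data.frame with `chrom`, `start`, `end` and `label` or `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path) {
  col4 <- if ("label" %in% names(track)) track$label else track$value
  out <- data.frame(track$chrom, track$start, track$end, col4)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models (BED12) joined to an expression table
#'
#' Parses BED12 exon block structure and joins a two-column (gene id,
#' expression) TSV; genes absent from the expression table get expression 0.
#' Exon blocks must lie inside the gene span, non-overlapping and sorted.
#'
#' @param path BED12 file of gene models.
#' @param expression_path TSV mapping gene id to a normalized expression
#'   value (header optional); negative values are rejected.
#' @return An object of class `gene_models`: a list with `genes`
#'   (id, chrom, start, end, strand, expression) and `exons`
#'   (gene, chrom, start, end).
#' @export
read_gene_models <- function(path, expression_path = NULL) {
  rec <- read_tab_records(path, 12L)
  co <- parse_coords(path, rec$fields, rec$lineno)
  f <- function(i) vapply(rec$fields, `[[`, "", i)
  chrom <- f(1L); id <- f(4L); strand <- f(6L)
  if (anyDuplicated(id)) {
    abort("%s: duplicate gene id '%s'", path, id[duplicated(id)][1L])
  }
  if (!all(strand %in% c("+", "-"))) {
    abort("%s: line %d: strand must be '+' or '-'",
          path, rec$lineno[which(!strand %in% c("+", "-"))[1L]])
  }
  n_blocks <- suppressWarnings(as.integer(f(10L)))
  exon_list <- vector("list", length(id))
  for (i in seq_along(id)) {
    sizes <- as.integer(strsplit(f(11L)[i], ",")[[1L]])
    starts <- as.integer(strsplit(f(12L)[i], ",")[[1L]])
    if (anyNA(sizes) || anyNA(starts) ||
        length(sizes) != n_blocks[i] || length(starts) != n_blocks[i]) {
      abort("%s: line %d: malformed exon blocks", path, rec$lineno[i])
    }
    es <- co$start[i] + starts
    ee <- es + sizes
    if (any(es < co$start[i]) || any(ee > co$end[i]) || any(sizes <= 0L)) {
      abort("%s: line %d: exon blocks outside gene span", path, rec$lineno[i])
    }
    if (is.unsorted(es, strictly = TRUE) || any(es[-1L] < ee[-length(ee)])) {
      abort("%s: line %d: exon blocks overlap or are unsorted", path, rec$lineno[i])
    }
    exon_list[[i]] <- data.frame(gene = id[i], chrom = chrom[i],
                                 start = es, end = ee,
                                 stringsAsFactors = FALSE)
  }
  expr <- rep(0, length(id))
  names(expr) <- id
  if (!is.null(expression_path)) {
    tab <- read_expression(expression_path)
    hit <- intersect(id, names(tab))
    expr[hit] <- tab[hit]
  }
  genes <- data.frame(id = id, chrom = chrom, start = co$start, end = co$end,
                      strand = strand, expression = unname(expr),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = do.call(rbind, exon_list)),
            class = "gene_models")
}

read_expression <- function(path) {
  rec <- read_tab_records(path, 2L)
  id <- vapply(rec$fields, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(rec$fields, `[[`, "", 2L)))
  # tolerate a single header line
  if (is.na(val[1L]) && length(val) > 1L) {
    id <- id[-1L]; val <- val[-1L]; rec$lineno <- rec$lineno[-1L]
  }
  if (anyNA(val)) {
    abort("%s: line %d: non-numeric expression value",
          path, rec$lineno[which(is.na(val))[1L]])
  }
  if (any(val < 0)) {
    abort("%s: line %d: negative expression value",
          path, rec$lineno[which(val < 0)[1L]])
  }
  stats::setNames(val, id)
}

#' Write gene models to BED12 (+ optional expression TSV)
#'
#' @param models A `gene_models` object.
#' @param path Output BED12 path.
#' @param expression_path Optional TSV path for the expression table.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, expression_path = NULL) {
  g <- models$genes
  rows <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    ex <- models$exons[models$exons$gene == g$id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    rows[i] <- paste(g$chrom[i], g$start[i], g$end[i], g$id[i], 0, g$strand[i],
                     g$start[i], g$end[i], "0,0,0", nrow(ex),
                     paste0(paste(ex$end - ex$start, collapse = ","), ","),
                     paste0(paste(ex$start - g$start[i], collapse = ","), ","),
                     sep = "\t")
  }
  writeLines(rows, path)
  if (!is.null(expression_path)) {
    utils::write.table(data.frame(g$id, g$expression), expression_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Construct a guide count matrix
#'
#' Container for pooled-screen sequencing counts: guides in rows, samples
#' in columns, plus per-sample metadata and a per-guide control flag.
#'
#' @param counts Integer matrix with guide ids as rownames and sample ids
#'   as colnames; all counts non-negative integers.
#' @param samples Data.frame of per-sample metadata with at least a
#'   `sample` column matching `colnames(counts)`; typically also
#'   `timepoint` (days) and `replicate`.
#' @param is_control Logical vector, one per guide (recycled names from
#'   rownames if unnamed).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples = NULL, is_control = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have guide rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate guide id '%s'",
          rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (any(!is_wholenumber(counts)) || any(counts < 0)) {
    abort("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts), stringsAsFactors = FALSE)
  }
  if (!identical(sort(samples$sample), sort(colnames(counts)))) {
    abort("sample metadata does not match count matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(is_control)) is_control <- rep(FALSE, nrow(counts))
  if (length(is_control) != nrow(counts)) {
    abort("is_control must have one entry per guide")
  }
  names(is_control) <- rownames(counts)
  structure(list(counts = counts, samples = samples, is_control = is_control),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%d controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_control)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a screen count table
#'
#' TSV with a header; first column guide id, remaining columns one per
#' sample. Guides whose id starts with `control_prefix` are flagged as
#' non-targeting controls. Sample metadata (`timepoint`, `replicate`) is
#' parsed from column names of the form `d<days>_r<rep>` when present.
#'
#' @param path Path to the count TSV.
#' @param control_prefix Guide-id prefix marking non-targeting controls.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, control_prefix = "CTRL") {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort("%s: need a guide-id column plus >= 1 sample", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    abort("%s: duplicate guide id '%s'", path, ids[duplicated(ids)][1L])
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(!is_wholenumber(m)) || any(m < 0)) {
    abort("%s: counts must be non-negative integers", path)
  }
  rownames(m) <- ids
  samples <- parse_sample_names(colnames(m))
  count_matrix(m, samples = samples,
               is_control = startsWith(ids, control_prefix))
}

parse_sample_names <- function(x) {
  hit <- regmatches(x, regexec("^d([0-9]+)_r([0-9]+)$", x))
  tp <- vapply(hit, function(h) if (length(h)) as.numeric(h[2L]) else NA_real_, 0)
  rep_ <- vapply(hit, function(h) if (length(h)) h[3L] else NA_character_, "")
  data.frame(sample = x, timepoint = tp, replicate = rep_,
             stringsAsFactors = FALSE)
}

#' Write a count matrix to TSV
#'
#' @param x A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  tab <- data.frame(guide = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a guide library manifest
#'
#' Manifest TSV columns: id, protospacer, pam, expression_sequence, chrom,
#' start, strand, cut_pos, is_control. Non-targeting controls have empty
#' genomic placement fields.
#'
#' @param path Manifest TSV path.
#' @return Data.frame with the manifest columns.
#' @export
read_library <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("id", "protospacer", "pam", "expression_sequence", "chrom",
            "start", "strand", "cut_pos", "is_control")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort("%s: missing manifest columns: %s",
                          path, paste(miss, collapse = ", "))
  tab$is_control <- as.logical(tab$is_control)
  tab$chrom[tab$chrom == ""] <- NA_character_
  tab
}

#' @rdname read_library
#' @param library Manifest data.frame.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
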