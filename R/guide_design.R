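# Single-cutter guide design: enumerate 20-nt protospacers next to an NGG
# PAM, search both strands for matches within a Hamming mismatch radius,
# and retain guides with exactly one perfect genomic target and no
# secondary site within the tolerance.
#
# Coordinates: protospacer start is 0-based on the + reference strand.
# SpCas9 cuts bluntly between protospacer bases 17 and 18 (3 bp 5' of the
# PAM); cut_pos is that breakpoint coordinate, so for a + guide starting
# at s it is s + 17 and for a - guide occupying [s, s+20) it is s + 3.

PROTOSPACER_LEN <- 20L
PAM_LEN <- 3L

revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, "", USE.NAMES = FALSE)
}

cut_position <- function(start, strand) {
  ifelse(strand == "+", start + 17L, start + 3L)
}

# cache of integer-encoded chromosome sequences
encode_genome <- function(genome) {
  lapply(genome, utf8ToInt)
}

#' Enumerate all NGG-adjacent protospacers in a genome
#'
#' Scans both strands for every 20-mer followed (3', strand-aware) by an
#' NGG PAM. 20-mers containing N are skipped. Output is in deterministic
#' (chrom, start, strand) order.
#'
#' @param genome Named character vector of chromosome sequences
#'   (see [read_fasta()]).
#' @return Data.frame of candidates: `protospacer`, `pam`, `chrom`,
#'   `strand`, `start` (0-based protospacer start on the + strand),
#'   `cut_pos`.
#' @export
scan_pam_sites <- function(genome) {
  out <- vector("list", 2L * length(genome))
  k <- 0L
  G <- utf8ToInt("G"); C <- utf8ToInt("C")
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    enc <- utf8ToInt(seq)
    L <- length(enc)
    if (L < PROTOSPACER_LEN + PAM_LEN) next
    gg <- which(enc[-L] == G & enc[-1L] == G)     # 1-based pos of first G of GG
    # + strand: PAM N at 0-based g-2 (1-based g-1), protospacer [g-22, g-2)
    plus_start <- gg - 22L                         # 0-based protospacer start
    plus_start <- plus_start[plus_start >= 0L]
    cc <- which(enc[-L] == C & enc[-1L] == C)     # 1-based pos of first C of CC
    # - strand: plus-strand CCN at [c-1, c+2); protospacer [c+2, c+22) 0-based
    minus_start <- cc + 2L                         # 0-based protospacer start
    minus_start <- minus_start[minus_start + PROTOSPACER_LEN <= L]
    mk <- function(starts, strand) {
      if (!length(starts)) return(NULL)
      proto_plus <- substring(seq, starts + 1L, starts + PROTOSPACER_LEN)
      pam_plus <- if (strand == "+") {
        substring(seq, starts + 21L, starts + 23L)
      } else {
        substring(seq, starts - 2L, starts)
      }
      keep <- !grepl("N", proto_plus, fixed = TRUE)
      starts <- starts[keep]
      proto_plus <- proto_plus[keep]
      pam_plus <- pam_plus[keep]
      if (!length(starts)) return(NULL)
      data.frame(
        protospacer = if (strand == "+") proto_plus else revcomp(proto_plus),
        pam = if (strand == "+") pam_plus else revcomp(pam_plus),
        chrom = ch, strand = strand, start = as.integer(starts),
        cut_pos = cut_position(as.integer(starts), strand),
        stringsAsFactors = FALSE
      )
    }
    out[[k <- k + 1L]] <- mk(plus_start, "+")
    out[[k <- k + 1L]] <- mk(minus_start, "-")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(protospacer = character(), pam = character(),
                      chrom = character(), strand = character(),
                      start = integer(), cut_pos = integer(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate random candidate protospacers
#'
#' Uniform i.i.d. 20-mers over {A,C,G,T}; the desk-scale analogue of
#' drawing a large pool of random 20-nt sequences as library candidates.
#'
#' @param n Number of sequences (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return Character vector of `n` 20-nt sequences.
#' @export
random_candidates <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  with_seed(scramble_seed(seed), {
    bases <- sample(c("A", "C", "G", "T"), n * PROTOSPACER_LEN, replace = TRUE)
    m <- matrix(bases, nrow = n)
    apply(m, 1L, paste, collapse = "")
  })
}

# Hamming scan of one pattern against one encoded strand; returns 0-based
# match starts with <= max_mm mismatches.
hamming_hits <- function(enc, pat_int, max_mm) {
  if (length(enc) < length(pat_int)) {
    return(list(start = integer(), mm = integer()))
  }
  .hamming_scan(enc, pat_int, as.integer(max_mm))
}

find_matches_enc <- function(enc_genome, protospacer, max_mismatches,
                             require_pam) {
  G <- utf8ToInt("G"); C <- utf8ToInt("C")
  L <- nchar(protospacer)
  pat_f <- utf8ToInt(protospacer)
  pat_r <- utf8ToInt(revcomp(protospacer))
  out <- list(); k <- 0L
  for (ch in names(enc_genome)) {
    enc <- enc_genome[[ch]]
    Lc <- length(enc)
    fwd <- hamming_hits(enc, pat_f, max_mismatches)
    if (length(fwd$start)) {
      s <- fwd$start
      pam_ok <- s + L + PAM_LEN <= Lc &
        enc[pmin(s + L + 2L, Lc)] == G & enc[pmin(s + L + 3L, Lc)] == G
      out[[k <- k + 1L]] <- data.frame(
        chrom = ch, start = s, strand = "+", mismatches = fwd$mm,
        pam_ok = pam_ok, stringsAsFactors = FALSE)
    }
    rev <- hamming_hits(enc, pat_r, max_mismatches)
    if (length(rev$start)) {
      s <- rev$start
      pam_ok <- s >= PAM_LEN &
        enc[pmax(s - 2L, 1L)] == C & enc[pmax(s - 1L, 1L)] == C
      out[[k <- k + 1L]] <- data.frame(
        chrom = ch, start = s, strand = "-", mismatches = rev$mm,
        pam_ok = pam_ok, stringsAsFactors = FALSE)
    }
  }
  res <- if (k) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               mismatches = integer(), pam_ok = logical(),
               stringsAsFactors = FALSE)
  if (require_pam) res <- res[res$pam_ok, , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find all genomic matches of a protospacer within a mismatch radius
#'
#' Exact Hamming search (no indels) over both strands. With
#' `require_pam = TRUE` only placements followed (3', strand-aware) by an
#' NGG PAM are reported.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param protospacer Sequence over {A,C,G,T}.
#' @param max_mismatches Mismatch radius (1..5 supported).
#' @param require_pam Report only NGG-adjacent placements.
#' @return Data.frame of hits: `chrom`, `start` (0-based), `strand`,
#'   `mismatches`, `pam_ok`, sorted by (chrom, start, strand).
#' @export
find_matches <- function(genome, protospacer, max_mismatches = 3,
                         require_pam = TRUE) {
  if (grepl("[^ACGT]", protospacer)) {
    abort("protospacer must be over {A,C,G,T}: %s", protospacer)
  }
  stopifnot(max_mismatches >= 0, max_mismatches <= 5)
  find_matches_enc(encode_genome(genome), protospacer,
                   as.integer(max_mismatches), require_pam)
}

#' Retain single-cutter guides
#'
#' A candidate is kept iff it has exactly one perfect NGG-adjacent genomic
#' target and zero additional hits with up to `max_mismatches` mismatches
#' (under the configured `require_pam` policy for the secondary sites).
#' Retained guides are placed (chrom, strand, start, cut_pos) at their
#' unique target.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param candidates Character vector of 20-nt protospacers, or the
#'   data.frame returned by [scan_pam_sites()].
#' @param max_mismatches Exclusion radius for secondary sites.
#' @param require_pam Whether secondary sites must carry an NGG PAM to
#'   disqualify a guide.
#' @param id_prefix Prefix for generated guide ids.
#' @return Data.frame of placed guides: `id`, `protospacer`, `pam`,
#'   `expression_sequence` (protospacer with one extra 5' G), `chrom`,
#'   `start`, `strand`, `cut_pos`, `is_control` (all `FALSE`).
#' @export
design_single_cutters <- function(genome, candidates, max_mismatches = 3,
                                  require_pam = TRUE, id_prefix = "SCC") {
  if (is.data.frame(candidates)) candidates <- candidates$protospacer
  candidates <- unique(candidates)
  candidates <- candidates[!grepl("[^ACGT]", candidates)]
  enc <- encode_genome(genome)
  kept <- vector("list", length(candidates))
  n_kept <- 0L
  for (p in candidates) {
    hits <- find_matches_enc(enc, p, as.integer(max_mismatches), require_pam)
    if (nrow(hits) != 1L || hits$mismatches[1L] != 0L || !hits$pam_ok[1L]) next
    n_kept <- n_kept + 1L
    strand <- hits$strand[1L]; s <- hits$start[1L]; ch <- hits$chrom[1L]
    pam_plus <- if (strand == "+") {
      substring(genome[[ch]], s + 21L, s + 23L)
    } else {
      revcomp(substring(genome[[ch]], s - 2L, s))
    }
    kept[[n_kept]] <- data.frame(
      protospacer = p, pam = pam_plus, chrom = ch, start = s,
      strand = strand, cut_pos = cut_position(s, strand),
      stringsAsFactors = FALSE)
  }
  res <- if (n_kept) do.call(rbind, kept[seq_len(n_kept)]) else
    data.frame(protospacer = character(), pam = character(),
               chrom = character(), start = integer(), strand = character(),
               cut_pos = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  res <- data.frame(
    id = sprintf("%s_%04d", id_prefix, seq_len(nrow(res))),
    protospacer = res$protospacer, pam = res$pam,
    expression_sequence = if (nrow(res)) paste0("G", res$protospacer)
                          else character(0),
    chrom = res$chrom, start = res$start, strand = res$strand,
    cut_pos = res$cut_pos, is_control = rep(FALSE, nrow(res)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assemble a library manifest with non-targeting controls
#'
#' Appends rejection-sampled non-targeting control sequences: random
#' 20-mers verified by [find_matches()] to have no genomic placement within
#' `max_mismatches` on either strand (PAM-agnostic, the conservative
#' definition of non-targeting). A 5' G is always prepended to the
#' expressed sequence (U6 expression), giving a 21-nt guide.
#'
#' @param guides Placed targeting guides from [design_single_cutters()].
#' @param genome Genome the controls must not match.
#' @param n_controls Number of controls to generate (default 100).
#' @param control_seed Seed for control sampling.
#' @param max_mismatches Radius within which controls must have zero hits.
#' @param max_attempts Sampling attempts before giving up.
#' @param control_prefix Id prefix for control rows.
#' @return Manifest data.frame: targeting rows then control rows (controls
#'   have `NA` genomic placement and `is_control = TRUE`).
#' @export
assemble_library <- function(guides, genome, n_controls = 100,
                             control_seed = NULL, max_mismatches = 3,
                             max_attempts = 200 * n_controls,
                             control_prefix = "CTRL") {
  enc <- encode_genome(genome)
  controls <- character(0)
  with_seed(scramble_seed(control_seed), {
    attempts <- 0L
    while (length(controls) < n_controls && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- paste(sample(c("A", "C", "G", "T"), PROTOSPACER_LEN,
                           replace = TRUE), collapse = "")
      if (cand %in% controls) next
      hits <- find_matches_enc(enc, cand, as.integer(max_mismatches),
                               require_pam = FALSE)
      if (nrow(hits) == 0L) controls <- c(controls, cand)
    }
  })
  if (length(controls) < n_controls) {
    abort("could only find %d of %d non-matching control sequences",
          length(controls), n_controls)
  }
  ctrl <- data.frame(
    id = sprintf("%s_%03d", control_prefix, seq_len(n_controls)),
    protospacer = controls, pam = NA_character_,
    expression_sequence = paste0("G", controls),
    chrom = NA_character_, start = NA_integer_, strand = NA_character_,
    cut_pos = NA_integer_, is_control = TRUE, stringsAsFactors = FALSE)
  rbind(guides, ctrl)
}
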