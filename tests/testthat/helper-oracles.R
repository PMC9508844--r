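# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive character-level code paths, not the
# package's encoded-scan internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# brute-force all-positions Hamming scan over both strands
oracle_find_matches <- function(genome, proto, max_mm, require_pam = TRUE) {
  L <- nchar(proto)
  out <- list()
  for (ch in names(genome)) {
    g <- strsplit(genome[[ch]], "")[[1L]]
    n <- length(g)
    for (strand in c("+", "-")) {
      pat <- strsplit(if (strand == "+") proto else oracle_revcomp(proto),
                      "")[[1L]]
      if (n < L) next
      for (s in 0:(n - L)) {
        mm <- sum(g[(s + 1):(s + L)] != pat)
        if (mm > max_mm) next
        pam_ok <- if (strand == "+") {
          s + L + 3 <= n && g[s + L + 2] == "G" && g[s + L + 3] == "G"
        } else {
          s >= 3 && g[s - 2] == "C" && g[s - 1] == "C"
        }
        if (require_pam && !pam_ok) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = s, strand = strand, mismatches = mm,
          pam_ok = pam_ok, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               mismatches = integer(), pam_ok = logical(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# regex-style PAM site counter (lookahead so overlapping sites all count)
oracle_count_pam_sites <- function(genome) {
  n <- 0L
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    for (s in c(seq, oracle_revcomp(seq))) {
      m <- gregexpr("(?=[ACGT]{20}[ACGTN]GG)", s, perl = TRUE)[[1L]]
      n <- n + sum(m > 0)
    }
  }
  n
}

random_genome <- function(lens, seed) {
  set.seed(seed)
  g <- vapply(lens, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  names(g) <- paste0("chr", seq_along(g))
  g
}

# write a sequence into a genome at a 0-based position
write_seq <- function(genome, chrom, pos0, seq) {
  substr(genome[[chrom]], pos0 + 1L, pos0 + nchar(seq)) <- seq
  genome
}

# mutate exactly k positions of a 20-mer
mutate_k <- function(proto, k, seed = 1) {
  set.seed(seed)
  chars <- strsplit(proto, "")[[1L]]
  idx <- sample(length(chars), k)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# per-bp counting oracle for window label fractions
oracle_bp_fractions <- function(chrom, start, end, nominal, track) {
  labs <- character(0)
  for (p in seq(start, end - 1L)) {
    hit <- track$chrom == chrom & track$start <= p & p < track$end
    labs <- c(labs, if (any(hit)) track$label[which(hit)[1L]] else "unannotated")
  }
  tab <- table(labs) / nominal
  frac <- as.numeric(tab)
  names(frac) <- names(tab)
  if (!"unannotated" %in% names(frac)) {
    frac <- c(frac, unannotated = (nominal - (end - start)) / nominal)
  } else {
    frac[["unannotated"]] <- frac[["unannotated"]] +
      (nominal - (end - start)) / nominal
  }
  frac
}

# an annotation record satisfying every clause of a given built-in pool
record_passing <- function(pool_name, ...) {
  base <- switch(pool_name,
    pool2 = list(state_fracs = c("2" = 0.80), breaksite_state = "2",
                 dnase_max = 1.0, ilad_frac = 0.95, genic = TRUE,
                 intronic = TRUE, expressed = TRUE),
    pool4 = list(state_fracs = c("4" = 0.60), ilad_frac = 1.0),
    pool7 = list(state_fracs = c("7" = 1.0), dnase_max = 0.01,
                 ilad_frac = 0.95, genic = TRUE, intronic = TRUE,
                 expressed = TRUE),
    pool8a = list(state_fracs = c("8" = 1.0), ilad_frac = 1.0),
    pool8b = list(state_fracs = c("8" = 1.0), lad_frac = 1.0),
    pool9 = list(breaksite_state = "9", h3k9me3_wmean = 8.0, lad_frac = 1.0),
    stop("unknown pool"))
  args <- utils::modifyList(base, list(...))
  do.call(make_annotation_record, args)
}
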