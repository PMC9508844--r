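# Synthetic fixtures: multi-chromosome random genomes, segment-structured
# chromatin tracks (10-state tiling, LAD/iLAD tiling, peaked DNaseI,
# H3K9me3 plateaus), gene models with introns/exons, planted
# pool-qualifying guide sites, and negative-binomial dropout-screen counts
# with planted per-guide depletion. Everything is reproducible under the
# spec seed, so every pipeline stage is testable at desk scale without
# external downloads.

#' Fixture specification
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length in bp (scalar, recycled, or one per
#'   chromosome).
#' @param state_mean_len Mean bp of a chromatin-state segment (exponential
#'   dwell lengths, floored at `state_min_len`).
#' @param state_min_len Minimum segment length in bp.
#' @param lad_mean_len Mean bp of a LAD/iLAD segment.
#' @param dnase_height Range of DNaseI peak heights (signal units).
#' @param dnase_width DNaseI peak width in bp.
#' @param dnase_prob Probability a state-2 segment receives a peak.
#' @param k9_height Range of H3K9me3 plateau heights.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param gene_span Range of gene span lengths in bp.
#' @param exons_per_gene Exons per gene (>= 2 so introns exist).
#' @param exon_len Exon length in bp.
#' @param expressed_fraction Fraction of genes given nonzero expression.
#' @param expression_range Range of nonzero expression values.
#' @param planted Named integer vector of planted-site counts per built-in
#'   pool (names among pool2, pool4, pool7, pool8a, pool8b, pool9).
#' @param seed Master seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chromosomes = 6, chrom_length = 50000,
                         state_mean_len = 3000, state_min_len = 200,
                         lad_mean_len = 12000,
                         dnase_height = c(0.5, 3), dnase_width = 400,
                         dnase_prob = 0.7, k9_height = c(6, 10),
                         genes_per_chrom = 3, gene_span = c(4000, 8000),
                         exons_per_gene = 3, exon_len = 200,
                         expressed_fraction = 0.7,
                         expression_range = c(2, 20),
                         planted = integer(0), seed = 1) {
  lens <- rep_len(as.integer(chrom_length), n_chromosomes)
  if (any(lens <= 0)) abort("chromosome lengths must be positive")
  if (length(planted) && any(planted < 0)) {
    abort("planted counts must be >= 0")
  }
  if (length(planted)) {
    bad <- setdiff(names(planted), names(builtin_pools()))
    if (length(bad)) abort("unknown pool(s) in planted: %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(
    n_chromosomes = n_chromosomes, chrom_lengths = lens,
    state_mean_len = state_mean_len, state_min_len = state_min_len,
    lad_mean_len = lad_mean_len, dnase_height = dnase_height,
    dnase_width = dnase_width, dnase_prob = dnase_prob,
    k9_height = k9_height, genes_per_chrom = genes_per_chrom,
    gene_span = gene_span, exons_per_gene = exons_per_gene,
    exon_len = exon_len, expressed_fraction = expressed_fraction,
    expression_range = expression_range,
    planted = planted, seed = seed
  ), class = "fixture_spec")
}

#' Generate a random genome
#'
#' I.i.d. uniform bases per chromosome, reproducible under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return Named character vector of sequences (chr1, chr2, ...).
#' @export
make_genome <- function(spec) {
  with_seed(spec$seed, {
    genome <- vapply(spec$chrom_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    names(genome) <- paste0("chr", seq_along(genome))
    genome
  })
}

# tile [0, len) with exponential-length segments labelled by label_fun(k)
tile_segments <- function(len, mean_len, min_len, label_fun) {
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  while (pos < len) {
    seg <- max(min_len, round(stats::rexp(1L, 1 / mean_len)))
    end <- min(len, pos + seg)
    starts <- c(starts, pos); ends <- c(ends, as.integer(end))
    pos <- as.integer(end)
  }
  data.frame(start = starts, end = ends,
             label = label_fun(length(starts)), stringsAsFactors = FALSE)
}

#' Generate chromatin tracks and gene models for a genome
#'
#' States tile each chromosome completely with exponential-length segments
#' over labels "1".."10"; LAD/iLAD tile likewise (alternating); DNaseI
#' peaks are placed preferentially inside state-2 segments; H3K9me3
#' plateaus cover state-9 segments; genes (with evenly spaced exons) are
#' placed without overlap and joined to expression values.
#'
#' @param genome From [make_genome()].
#' @param spec A [fixture_spec()].
#' @return List: `states`, `lads` (labeled tracks), `dnase`, `h3k9me3`
#'   (valued tracks), `genes` (a `gene_models` object).
#' @export
make_tracks <- function(genome, spec) {
  with_seed(spec$seed + 1L, {
    states <- list(); lads <- list(); dnase <- list(); k9 <- list()
    genes <- list(); exons <- list()
    gene_i <- 0L
    for (ch in names(genome)) {
      len <- nchar(genome[[ch]])
      st <- tile_segments(len, spec$state_mean_len, spec$state_min_len,
                          function(k) sample(as.character(1:10), k,
                                             replace = TRUE))
      st$chrom <- ch
      states[[ch]] <- st
      first <- sample(c("LAD", "iLAD"), 1L)
      la <- tile_segments(len, spec$lad_mean_len, spec$state_min_len,
                          function(k) {
                            rep(c(first, setdiff(c("LAD", "iLAD"), first)),
                                length.out = k)
                          })
      la$chrom <- ch
      lads[[ch]] <- la
      # DNaseI peaks: mostly in state-2 segments (accessible promoters)
      s2 <- st[st$label == "2" & (st$end - st$start) >= spec$dnase_width, ]
      if (nrow(s2)) {
        take <- stats::runif(nrow(s2)) < spec$dnase_prob
        s2 <- s2[take, , drop = FALSE]
        if (nrow(s2)) {
          ps <- vapply(seq_len(nrow(s2)), function(i) {
            s2$start[i] + sample.int(s2$end[i] - s2$start[i] -
                                       spec$dnase_width + 1L, 1L) - 1L
          }, 0L)
          dnase[[ch]] <- data.frame(
            chrom = ch, start = ps, end = ps + spec$dnase_width,
            value = stats::runif(nrow(s2), spec$dnase_height[1L],
                                 spec$dnase_height[2L]),
            stringsAsFactors = FALSE)
        }
      }
      # H3K9me3 plateaus over state-9 segments
      s9 <- st[st$label == "9", ]
      if (nrow(s9)) {
        k9[[ch]] <- data.frame(
          chrom = ch, start = s9$start, end = s9$end,
          value = stats::runif(nrow(s9), spec$k9_height[1L],
                               spec$k9_height[2L]),
          stringsAsFactors = FALSE)
      }
      # non-overlapping genes
      placed <- data.frame(start = integer(0), end = integer(0))
      tries <- 0L
      while (nrow(placed) < spec$genes_per_chrom && tries < 200L) {
        tries <- tries + 1L
        span <- round(stats::runif(1L, spec$gene_span[1L], spec$gene_span[2L]))
        if (span + 2L >= len) break
        s <- sample.int(len - span, 1L) - 1L
        if (any(pmax(placed$start, s) < pmin(placed$end, s + span))) next
        placed <- rbind(placed, data.frame(start = s, end = s + span))
        gene_i <- gene_i + 1L
        id <- sprintf("gene_%03d", gene_i)
        n_ex <- max(2L, spec$exons_per_gene)
        ex_s <- s + round((seq_len(n_ex) - 1L) *
                            (span - spec$exon_len) / (n_ex - 1L))
        expr <- if (stats::runif(1L) < spec$expressed_fraction) {
          stats::runif(1L, spec$expression_range[1L],
                       spec$expression_range[2L])
        } else 0
        genes[[id]] <- data.frame(
          id = id, chrom = ch, start = s, end = s + span, strand = "+",
          expression = expr, stringsAsFactors = FALSE)
        exons[[id]] <- data.frame(
          gene = id, chrom = ch, start = as.integer(ex_s),
          end = as.integer(ex_s + spec$exon_len), stringsAsFactors = FALSE)
      }
    }
    bind <- function(lst, cols) {
      if (length(lst)) {
        out <- do.call(rbind, lst)[, cols]
        rownames(out) <- NULL
        out
      } else {
        stats::setNames(data.frame(character(), integer(), integer(),
                                   if ("value" %in% cols) numeric()
                                   else character(),
                                   stringsAsFactors = FALSE), cols)
      }
    }
    list(
      states = bind(states, c("chrom", "start", "end", "label")),
      lads = bind(lads, c("chrom", "start", "end", "label")),
      dnase = bind(dnase, c("chrom", "start", "end", "value")),
      h3k9me3 = bind(k9, c("chrom", "start", "end", "value")),
      genes = structure(list(
        genes = if (length(genes)) do.call(rbind, c(genes, list(make.row.names = FALSE)))
                else data.frame(id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character(), expression = numeric(),
                                stringsAsFactors = FALSE),
        exons = if (length(exons)) do.call(rbind, c(exons, list(make.row.names = FALSE)))
                else data.frame(gene = character(), chrom = character(),
                                start = integer(), end = integer(),
                                stringsAsFactors = FALSE)
      ), class = "gene_models")
    )
  })
}

# replace any overlap of [start, end) on chrom with an optional new record
impose_interval <- function(track, chrom, start, end,
                            label = NULL, value = NULL) {
  on_ch <- track$chrom == chrom
  ov <- on_ch & track$start < end & track$end > start
  keep <- track[!ov, , drop = FALSE]
  pieces <- list()
  for (i in which(ov)) {
    row <- track[i, , drop = FALSE]
    if (row$start < start) {
      left <- row; left$end <- start
      pieces <- c(pieces, list(left))
    }
    if (row$end > end) {
      right <- row; right$start <- end
      pieces <- c(pieces, list(right))
    }
  }
  if (!is.null(label)) {
    pieces <- c(pieces, list(data.frame(chrom = chrom, start = start,
                                        end = end, label = label,
                                        stringsAsFactors = FALSE)))
  } else if (!is.null(value)) {
    pieces <- c(pieces, list(data.frame(chrom = chrom, start = start,
                                        end = end, value = value,
                                        stringsAsFactors = FALSE)))
  }
  out <- if (length(pieces)) {
    rbind(keep, do.call(rbind, c(pieces, list(make.row.names = FALSE))))
  } else {
    keep
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

drop_genes_overlapping <- function(models, chrom, start, end) {
  g <- models$genes
  hit <- g$chrom == chrom & g$start < end & g$end > start
  models$genes <- g[!hit, , drop = FALSE]
  models$exons <- models$exons[!models$exons$gene %in% g$id[hit], ,
                               drop = FALSE]
  models
}

add_gene <- function(models, id, chrom, start, end, exon_starts, exon_len,
                     expression) {
  models$genes <- rbind(models$genes, data.frame(
    id = id, chrom = chrom, start = start, end = end, strand = "+",
    expression = expression, stringsAsFactors = FALSE))
  models$exons <- rbind(models$exons, data.frame(
    gene = id, chrom = chrom, start = as.integer(exon_starts),
    end = as.integer(exon_starts + exon_len), stringsAsFactors = FALSE))
  models
}

# per-pool recipe for the 5 kb imposed region around a planted cut site
pool_recipe <- function(pool) {
  switch(pool,
    pool2 = list(state = "2", lamina = "iLAD", dnase = 1.0, k9 = NULL,
                 gene = TRUE),
    pool4 = list(state = "4", lamina = "iLAD", dnase = NULL, k9 = NULL,
                 gene = FALSE),
    pool7 = list(state = "7", lamina = "iLAD", dnase = NULL, k9 = NULL,
                 gene = TRUE),
    pool8a = list(state = "8", lamina = "iLAD", dnase = NULL, k9 = NULL,
                  gene = FALSE),
    pool8b = list(state = "8", lamina = "LAD", dnase = NULL, k9 = NULL,
                  gene = FALSE),
    pool9 = list(state = "9", lamina = "LAD", dnase = NULL, k9 = 8.0,
                 gene = FALSE),
    abort("no recipe for pool '%s'", pool))
}

#' Plant pool-qualifying guide sites into a fixture
#'
#' For each requested pool, engineers genomic regions that satisfy exactly
#' that pool's built-in rule set (state composition, lamina compartment,
#' DNaseI / H3K9me3 signal, gene context) and writes a unique
#' 20-mer + NGG protospacer at each cut site. Sites are distributed
#' round-robin across chromosomes on a non-overlapping slot grid
#' (6 kb spacing), so a pool of size k with a per-chromosome cap c is
#' feasible whenever the genome has >= ceiling(k / c) chromosomes.
#' Planted protospacers are rejection-sampled to have no other genomic
#' placement within `max_mismatches`, then the full set is re-verified as
#' single-cutters.
#'
#' @param genome From [make_genome()].
#' @param tracks From [make_tracks()].
#' @param spec A [fixture_spec()] with a non-empty `planted` vector.
#' @param max_mismatches Single-cutter exclusion radius.
#' @param min_chromosomes Minimum chromosomes required to spread sites.
#' @return List: `genome` (edited), `tracks` (edited), `truth`
#'   (data.frame: id, pool, chrom, start, strand, cut_pos, protospacer).
#' @export
plant_pool_sites <- function(genome, tracks, spec, max_mismatches = 3,
                             min_chromosomes = 5) {
  planted <- spec$planted
  truth0 <- data.frame(id = character(), pool = character(),
                       chrom = character(), start = integer(),
                       strand = character(), cut_pos = integer(),
                       protospacer = character(), stringsAsFactors = FALSE)
  if (!length(planted) || sum(planted) == 0) {
    return(list(genome = genome, tracks = tracks, truth = truth0))
  }
  if (length(genome) < min_chromosomes) {
    abort("need >= %d chromosomes to spread planted sites, have %d",
          min_chromosomes, length(genome))
  }
  # round-robin slot grid over all chromosomes
  slot_list <- lapply(names(genome), function(ch) {
    len <- nchar(genome[[ch]])
    centers <- seq(4000L, len - 4000L, by = 6000L)
    data.frame(chrom = ch, center = as.integer(centers),
               stringsAsFactors = FALSE)
  })
  max_slots <- max(vapply(slot_list, nrow, 0L))
  grid <- do.call(rbind, lapply(seq_len(max_slots), function(i) {
    do.call(rbind, lapply(slot_list, function(s) {
      if (i <= nrow(s)) s[i, , drop = FALSE] else NULL
    }))
  }))
  need <- sum(planted)
  if (need > nrow(grid)) {
    abort("fixture genome has %d planting slots, need %d",
          nrow(grid), need)
  }
  enc <- encode_genome(genome)
  truth <- list()
  slot_i <- 0L
  with_seed(spec$seed + 2L, {
    for (pool in names(planted)) {
      recipe <- pool_recipe(pool)
      for (j in seq_len(planted[[pool]])) {
        slot_i <- slot_i + 1L
        ch <- grid$chrom[slot_i]
        cpos <- grid$center[slot_i]
        r0 <- cpos - 2500L; r1 <- cpos + 2500L
        tracks$states <- impose_interval(tracks$states, ch, r0, r1,
                                         label = recipe$state)
        tracks$lads <- impose_interval(tracks$lads, ch, r0, r1,
                                       label = recipe$lamina)
        tracks$dnase <- impose_interval(tracks$dnase, ch, r0, r1)
        if (!is.null(recipe$dnase)) {
          tracks$dnase <- impose_interval(tracks$dnase, ch, cpos - 200L,
                                          cpos + 200L, value = recipe$dnase)
        }
        tracks$h3k9me3 <- impose_interval(tracks$h3k9me3, ch, r0, r1)
        if (!is.null(recipe$k9)) {
          tracks$h3k9me3 <- impose_interval(tracks$h3k9me3, ch, cpos - 2100L,
                                            cpos + 2100L, value = recipe$k9)
        }
        tracks$genes <- drop_genes_overlapping(tracks$genes, ch, r0, r1)
        if (recipe$gene) {
          gid <- sprintf("pltgene_%s_%02d", pool, j)
          tracks$genes <- add_gene(tracks$genes, gid, ch,
                                   cpos - 2400L, cpos + 2400L,
                                   exon_starts = c(cpos - 2400L, cpos + 2200L),
                                   exon_len = 200L, expression = 10)
        }
        # rejection-sample a protospacer unique in the current genome
        proto <- NULL
        for (try in 1:50) {
          cand <- paste(sample(c("A", "C", "G", "T"), PROTOSPACER_LEN,
                               replace = TRUE), collapse = "")
          hits <- find_matches_enc(enc, cand, as.integer(max_mismatches),
                                   require_pam = FALSE)
          if (nrow(hits) == 0L) {
            proto <- cand
            break
          }
        }
        if (is.null(proto)) abort("could not sample a unique protospacer")
        # protospacer occupies [cpos-17, cpos+3), PAM [cpos+3, cpos+6)
        s <- cpos - 17L
        substr(genome[[ch]], s + 1L, s + 23L) <- paste0(proto, "AGG")
        enc[[ch]] <- utf8ToInt(genome[[ch]])
        truth[[length(truth) + 1L]] <- data.frame(
          id = sprintf("PLT_%s_%02d", pool, j), pool = pool, chrom = ch,
          start = s, strand = "+", cut_pos = cpos, protospacer = proto,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # re-verify: every planted guide must be a single-cutter in the final
  # (fully edited) genome; later edits could in principle collide
  for (i in seq_len(nrow(truth))) {
    hits <- find_matches_enc(enc, truth$protospacer[i],
                             as.integer(max_mismatches), require_pam = TRUE)
    if (nrow(hits) != 1L || hits$mismatches[1L] != 0L) {
      abort("planted guide %s is not a single-cutter after editing (rare seed collision); use a different seed",
            truth$id[i])
    }
  }
  list(genome = genome, tracks = tracks, truth = truth)
}

#' Build a complete fixture
#'
#' Convenience wrapper: [make_genome()], [make_tracks()], then
#' [plant_pool_sites()] when the spec requests planted sites.
#'
#' @param spec A [fixture_spec()].
#' @return List: `genome`, `tracks`, `truth`, `spec`.
#' @export
make_fixture <- function(spec) {
  genome <- make_genome(spec)
  tracks <- make_tracks(genome, spec)
  pl <- plant_pool_sites(genome, tracks, spec)
  list(genome = pl$genome, tracks = pl$tracks, truth = pl$truth, spec = spec)
}

#' Screen simulation specification
#'
#' @param guides Guide ids (targeting + controls).
#' @param is_control Logical per-guide flag (controls must have zero
#'   depletion).
#' @param depletion Per-guide depletion rate per day (>= 0): the rate at
#'   which edited cells carrying the guide drop out.
#' @param efficiency Per-guide editing efficiency in `[0, 1]`; unedited
#'   cells behave neutrally, so expected abundance at day t is
#'   proportional to `(1 - efficiency) + efficiency * 2^(-depletion * t)`.
#' @param timepoints Sampling days (default 4, 8, 16).
#' @param replicates Number of independent infections.
#' @param depth Sequencing reads per sample (>= 1e4).
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Simulation seed.
#' @return List of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(guides, is_control, depletion,
                            efficiency = 1, timepoints = c(4, 8, 16),
                            replicates = 3, depth = 1e6,
                            overdispersion = 0.05, seed = 1) {
  n <- length(guides)
  depletion <- rep_len(depletion, n)
  efficiency <- rep_len(efficiency, n)
  stopifnot(length(is_control) == n)
  if (depth < 1e4) abort("sequencing depth must be >= 1e4")
  if (any(depletion < 0)) abort("depletion rates must be >= 0")
  if (any(efficiency < 0 | efficiency > 1)) {
    abort("editing efficiency must lie in [0, 1]")
  }
  if (any(is_control & depletion > 0)) {
    abort("control guides must have zero depletion")
  }
  structure(list(guides = guides, is_control = is_control,
                 depletion = depletion, efficiency = efficiency,
                 timepoints = timepoints, replicates = replicates,
                 depth = depth, overdispersion = overdispersion,
                 seed = seed),
            class = "screen_sim_spec")
}

#' Simulate a pooled dropout screen
#'
#' Each replicate draws initial relative guide abundances from a flat
#' Dirichlet (independent infections). The expected relative abundance of
#' guide i at day t is proportional to
#' `a0_i * ((1 - e_i) + e_i * 2^(-d_i * t))`: the unedited fraction of
#' cells is neutral and the edited fraction halves every `1/d_i` days.
#' Sample counts are negative binomial around depth x relative abundance.
#'
#' @param sim A [screen_sim_spec()].
#' @return A [count_matrix()] with samples named `d<day>_r<replicate>`.
#' @export
simulate_screen <- function(sim) {
  stopifnot(inherits(sim, "screen_sim_spec"))
  n <- length(sim$guides)
  with_seed(sim$seed, {
    cols <- list()
    meta <- list()
    for (r in seq_len(sim$replicates)) {
      a0 <- stats::rgamma(n, shape = 1, rate = 1)  # flat Dirichlet
      for (t in sim$timepoints) {
        w <- a0 * ((1 - sim$efficiency) +
                     sim$efficiency * 2^(-sim$depletion * t))
        mu <- sim$depth * w / sum(w)
        counts <- if (sim$overdispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / sim$overdispersion)
        } else {
          stats::rpois(n, mu)
        }
        nm <- sprintf("d%d_r%d", t, r)
        cols[[nm]] <- counts
        meta[[nm]] <- data.frame(sample = nm, timepoint = t,
                                 replicate = as.character(r),
                                 stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- sim$guides
    count_matrix(m, samples = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 is_control = sim$is_control)
  })
}
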