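test_that("guide_window centers on the cut site and clips at bounds", {
  w <- guide_window(list(chrom = "chr1", cut_pos = 10000), 4000)
  expect_equal(c(w$start, w$end), c(8000, 12000))
  expect_false(w$clipped)

  w <- guide_window(list(chrom = "chr1", cut_pos = 500), 4000,
                    chrom_lengths = c(chr1 = 100000))
  expect_equal(c(w$start, w$end), c(0, 2500))
  expect_true(w$clipped)
  expect_equal(w$nominal, 4000)

  w <- guide_window(list(chrom = "chr1", cut_pos = 50), 2)
  expect_equal(c(w$start, w$end), c(49, 51))

  expect_error(guide_window(list(chrom = "chr1", cut_pos = 10), 3),
               "even")
  expect_error(guide_window(list(chrom = "chr1", cut_pos = 2e5), 4000,
                            chrom_lengths = c(chr1 = 1e5)),
               "outside chromosome")
  expect_error(guide_window(list(chrom = "chrX", cut_pos = 10), 4000,
                            chrom_lengths = c(chr1 = 1e5)),
               "namespace")
})

test_that("state fractions use half-open overlap and call the breaksite", {
  track <- data.frame(chrom = "chr1", start = c(0L, 3000L),
                      end = c(3000L, 6000L), label = c("2", "7"),
                      stringsAsFactors = FALSE)
  w <- list(chrom = "chr1", start = 1000, end = 5000, nominal = 4000,
            clipped = FALSE)
  st <- state_fractions(w, track, cut_pos = 3000)
  expect_equal(unname(st$fractions[["2"]]), 0.5)
  expect_equal(unname(st$fractions[["7"]]), 0.5)
  expect_equal(unname(st$fractions[["unannotated"]]), 0)
  expect_identical(st$breaksite_state, "7")  # 3000 is in [3000, 6000)

  empty <- track[0, ]
  st0 <- state_fractions(w, empty, cut_pos = 3000)
  expect_equal(unname(st0$fractions[["unannotated"]]), 1)
  expect_identical(st0$breaksite_state, "unannotated")
})

test_that("state fractions match a per-bp counting oracle", {
  spec <- fixture_spec(n_chromosomes = 2, chrom_length = 8000,
                       state_mean_len = 700, seed = 17)
  tr <- make_tracks(make_genome(spec), spec)
  set.seed(18)
  for (i in 1:25) {
    ch <- sample(c("chr1", "chr2"), 1)
    cut <- sample(500:7500, 1)
    w <- guide_window(list(chrom = ch, cut_pos = cut), 1000)
    st <- state_fractions(w, tr$states, cut_pos = cut)
    oracle <- oracle_bp_fractions(ch, w$start, w$end, w$nominal, tr$states)
    expect_equal(sum(st$fractions), 1, tolerance = 1e-9)
    for (lab in names(oracle)) {
      expect_equal(unname(st$fractions[[lab]]), unname(oracle[[lab]]),
                   tolerance = 1e-12)
    }
    lam <- lamina_fractions(w, tr$lads)
    lam_oracle <- oracle_bp_fractions(ch, w$start, w$end, w$nominal, tr$lads)
    lad_expect <- if ("LAD" %in% names(lam_oracle)) lam_oracle[["LAD"]] else 0
    expect_equal(unname(lam[["lad"]]), lad_expect, tolerance = 1e-12)
    expect_equal(sum(lam), 1, tolerance = 1e-9)
  }
})

test_that("lamina fractions split at boundaries and reject bad labels", {
  lads <- data.frame(chrom = "chr1", start = c(0L, 5000L),
                     end = c(5000L, 10000L), label = c("LAD", "iLAD"),
                     stringsAsFactors = FALSE)
  w_in <- list(chrom = "chr1", start = 6000, end = 8000, nominal = 2000)
  expect_equal(unname(lamina_fractions(w_in, lads)[c("lad", "ilad")]),
               c(0, 1))
  w_mid <- list(chrom = "chr1", start = 4000, end = 6000, nominal = 2000)
  expect_equal(unname(lamina_fractions(w_mid, lads)[c("lad", "ilad")]),
               c(0.5, 0.5))
  bad <- lads
  bad$label[1] <- "boundary"
  expect_error(lamina_fractions(w_in, bad), "unknown label")
})

test_that("window signal reports max and coverage-weighted mean", {
  w <- list(chrom = "chr1", start = 0, end = 4000, nominal = 4000)
  tr <- data.frame(chrom = "chr1", start = c(100L, 300L),
                   end = c(200L, 400L), value = c(0.1, 0.3),
                   stringsAsFactors = FALSE)
  expect_equal(unname(window_signal(w, tr)[["max"]]), 0.3)

  full <- data.frame(chrom = "chr1", start = 0L, end = 4000L, value = 6.0)
  expect_equal(unname(window_signal(w, full)[["wmean"]]), 6.0)

  half <- data.frame(chrom = "chr1", start = 0L, end = 2000L, value = 8.0)
  expect_equal(unname(window_signal(w, half)[["wmean"]]), 4.0)

  expect_equal(unname(window_signal(w, tr[0, ])), c(0, 0))
})

test_that("gene context distinguishes interiors, exons and expression", {
  gm <- structure(list(
    genes = data.frame(id = c("on", "off"), chrom = "chr1",
                       start = c(1000L, 9000L), end = c(5000L, 12000L),
                       strand = "+", expression = c(7, 0),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene = c("on", "on", "off"), chrom = "chr1",
                       start = c(1000L, 4500L, 9000L),
                       end = c(1500L, 5000L, 9500L),
                       stringsAsFactors = FALSE)), class = "gene_models")
  expect_equal(unname(gene_context("chr1", 3000, gm)),
               c(TRUE, TRUE, FALSE, TRUE))    # intron of expressed gene
  expect_equal(unname(gene_context("chr1", 7000, gm)),
               c(FALSE, FALSE, FALSE, FALSE)) # intergenic
  expect_equal(unname(gene_context("chr1", 9200, gm)),
               c(TRUE, FALSE, TRUE, FALSE))   # exon of silent gene
})

test_that("annotate_guides is deterministic and translation invariant", {
  spec <- fixture_spec(n_chromosomes = 2, chrom_length = 20000, seed = 23)
  tr <- make_tracks(make_genome(spec), spec)
  guides <- data.frame(id = c("g1", "g2", "g3"), chrom = "chr1",
                       cut_pos = c(4000L, 9000L, 15000L),
                       stringsAsFactors = FALSE)
  a1 <- annotate_guides(guides, tr$states, tr$lads, tr$dnase, tr$h3k9me3,
                        tr$genes)
  a2 <- annotate_guides(guides, tr$states, tr$lads, tr$dnase, tr$h3k9me3,
                        tr$genes)
  expect_identical(a1, a2)
  state_cols <- grepl("^(state.+|unannotated)_frac$", names(a1))
  expect_true(all(abs(rowSums(a1[, state_cols]) - 1) < 1e-9))

  shift <- function(df, k) { df$start <- df$start + k; df$end <- df$end + k; df }
  off <- 12345L
  tr2 <- list(states = shift(tr$states, off), lads = shift(tr$lads, off),
              dnase = shift(tr$dnase, off), h3k9me3 = shift(tr$h3k9me3, off))
  gm2 <- tr$genes
  gm2$genes <- shift(gm2$genes, off)
  gm2$exons <- shift(gm2$exons, off)
  guides2 <- guides
  guides2$cut_pos <- guides2$cut_pos + off
  a3 <- annotate_guides(guides2, tr2$states, tr2$lads, tr2$dnase,
                        tr2$h3k9me3, gm2)
  drop_coords <- function(x) x[, setdiff(names(x),
                                         c("cut_pos", "window_start",
                                           "window_end"))]
  expect_identical(drop_coords(a1), drop_coords(a3))
})

test_that("annotation handles uncovered chromosomes and absent namespaces", {
  spec <- fixture_spec(n_chromosomes = 2, chrom_length = 20000, seed = 29)
  tr <- make_tracks(make_genome(spec), spec)
  g <- data.frame(id = "g1", chrom = "chr9", cut_pos = 5000L,
                  stringsAsFactors = FALSE)
  a <- annotate_guides(g, tr$states, tr$lads, tr$dnase, tr$h3k9me3, tr$genes)
  expect_equal(a$unannotated_frac, 1)
  expect_equal(a$dnase_max, 0)
  expect_identical(a$breaksite_state, "unannotated")

  expect_error(
    annotate_guides(g, tr$states, tr$lads, tr$dnase, tr$h3k9me3, tr$genes,
                    chrom_lengths = c(chr1 = 20000, chr2 = 20000)),
    "namespace")
})

test_that("clipped windows never produce fractions above 1", {
  spec <- fixture_spec(n_chromosomes = 1, chrom_length = 5000, seed = 31)
  tr <- make_tracks(make_genome(spec), spec)
  g <- data.frame(id = c("edge_lo", "edge_hi"), chrom = "chr1",
                  cut_pos = c(100L, 4950L), stringsAsFactors = FALSE)
  a <- annotate_guides(g, tr$states, tr$lads, tr$dnase, tr$h3k9me3, tr$genes,
                       chrom_lengths = c(chr1 = 5000))
  expect_true(all(a$clipped))
  fr <- a[, grepl("_frac$", names(a))]
  expect_true(all(fr >= 0 & fr <= 1))
  state_cols <- grepl("^state|^unannotated", names(a)) & grepl("_frac$", names(a))
  expect_equal(unname(rowSums(a[, state_cols])), c(1, 1), tolerance = 1e-9)
})
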