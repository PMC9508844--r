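# Chromatin-pool filtering and constrained selection: apply the six
# published rule sets over annotated guides and pick k guides per pool
# with a per-chromosome cap.
#
# Threshold inclusivity follows the published wording: "at least 65%" is
# inclusive; thresholds printed with ">" or "exceed" (0.2, 50%, 90%, 99%,
# 5.5) and "<" (0.06) are strict.

#' Define a chromatin pool rule set
#'
#' A pool is a conjunction of clauses over annotation-record fields; every
#' clause left `NULL` (or `"any"`) is skipped.
#'
#' @param name Pool name.
#' @param state Required ChromHMM state label (e.g. `"2"`).
#' @param state_min Minimum window fraction in that state.
#' @param state_inclusive Whether `state_min` passes at equality.
#' @param breaksite_state Required state label at the breaksite itself.
#' @param dnase_gt Strict lower bound on `dnase_max` (accessibility
#'   required), or `NULL`.
#' @param dnase_lt Strict upper bound on `dnase_max` (closed chromatin
#'   required), or `NULL`.
#' @param lamina `"LAD"` or `"iLAD"`: required lamina compartment.
#' @param lamina_min Minimum window fraction in that compartment.
#' @param lamina_inclusive Whether `lamina_min` passes at equality.
#' @param h3k9me3_gt Strict lower bound on the H3K9me3 coverage-weighted
#'   mean, or `NULL`.
#' @param gene_requirement `"any"`, `"genic_intronic"` (genic and
#'   intronic) or `"non_genic"`.
#' @param expression_requirement `"any"`, `"expressed"` or `"non_expressed"`.
#' @return An object of class `pool_definition`.
#' @export
pool_definition <- function(name, state = NULL, state_min = NULL,
                            state_inclusive = FALSE, breaksite_state = NULL,
                            dnase_gt = NULL, dnase_lt = NULL,
                            lamina = NULL, lamina_min = NULL,
                            lamina_inclusive = FALSE, h3k9me3_gt = NULL,
                            gene_requirement = c("any", "genic_intronic",
                                                 "non_genic"),
                            expression_requirement = c("any", "expressed",
                                                       "non_expressed")) {
  gene_requirement <- match.arg(gene_requirement)
  expression_requirement <- match.arg(expression_requirement)
  for (f in c(state_min, lamina_min)) {
    if (!is.null(f) && (f < 0 || f > 1)) abort("fractions must lie in [0, 1]")
  }
  if (!is.null(dnase_gt) && !is.null(dnase_lt)) {
    abort("a pool uses at most one DNaseI bound")
  }
  if (!is.null(lamina) && !lamina %in% c("LAD", "iLAD")) {
    abort("lamina must be 'LAD' or 'iLAD'")
  }
  structure(list(
    name = name, state = state, state_min = state_min,
    state_inclusive = state_inclusive, breaksite_state = breaksite_state,
    dnase_gt = dnase_gt, dnase_lt = dnase_lt, lamina = lamina,
    lamina_min = lamina_min, lamina_inclusive = lamina_inclusive,
    h3k9me3_gt = h3k9me3_gt, gene_requirement = gene_requirement,
    expression_requirement = expression_requirement
  ), class = "pool_definition")
}

#' The six built-in chromatin pools
#'
#' Rule sets targeting one chromatin environment each: promoters (state 2),
#' enhancers (state 4), gene bodies (state 7), polycomb-repressed in iLAD
#' (8a) and in LAD (8b), and H3K9me3 heterochromatin (9).
#'
#' * pool2: >= 65% state 2 (inclusive), breaksite in state 2,
#'   dnase_max > 0.2, iLAD > 90%, genic + intronic, expressed.
#' * pool4: state 4 > 50%, iLAD > 99%, no DNaseI or gene clause.
#' * pool7: state 7 > 99%, dnase_max < 0.06, iLAD > 90%, genic + intronic,
#'   expressed.
#' * pool8a: state 8 > 99%, iLAD > 99%, non-genic.
#' * pool8b: state 8 > 99%, LAD > 99%, non-genic.
#' * pool9: H3K9me3 weighted mean > 5.5, LAD > 99%, non-genic, breaksite
#'   confirmed state 9.
#'
#' @return Named list of six [pool_definition()] objects.
#' @export
builtin_pools <- function() {
  pools <- list(
    pool2 = pool_definition("pool2", state = "2", state_min = 0.65,
                            state_inclusive = TRUE, breaksite_state = "2",
                            dnase_gt = 0.2, lamina = "iLAD", lamina_min = 0.90,
                            gene_requirement = "genic_intronic",
                            expression_requirement = "expressed"),
    pool4 = pool_definition("pool4", state = "4", state_min = 0.50,
                            lamina = "iLAD", lamina_min = 0.99),
    pool7 = pool_definition("pool7", state = "7", state_min = 0.99,
                            dnase_lt = 0.06, lamina = "iLAD",
                            lamina_min = 0.90,
                            gene_requirement = "genic_intronic",
                            expression_requirement = "expressed"),
    pool8a = pool_definition("pool8a", state = "8", state_min = 0.99,
                             lamina = "iLAD", lamina_min = 0.99,
                             gene_requirement = "non_genic"),
    pool8b = pool_definition("pool8b", state = "8", state_min = 0.99,
                             lamina = "LAD", lamina_min = 0.99,
                             gene_requirement = "non_genic"),
    pool9 = pool_definition("pool9", h3k9me3_gt = 5.5,
                            breaksite_state = "9", lamina = "LAD",
                            lamina_min = 0.99, gene_requirement = "non_genic")
  )
  pools
}

record_field <- function(record, field, clause) {
  if (!field %in% names(record)) {
    abort("annotation record lacks field '%s' required by clause '%s'",
          field, clause)
  }
  v <- record[[field]]
  if (is.na(v)) abort("annotation record field '%s' is NA", field)
  v
}

#' Evaluate one pool rule set against one annotation record
#'
#' @param record One-row `guide_annotation` data.frame (or list).
#' @param pool A [pool_definition()].
#' @return List with `pass` (logical) and `reasons` (character vector
#'   naming every failed clause; empty when passing).
#' @export
evaluate_rule <- function(record, pool) {
  reasons <- character(0)
  fail <- function(clause) reasons <<- c(reasons, clause)
  if (!is.null(pool$state)) {
    frac <- record_field(record, paste0("state", pool$state, "_frac"),
                         "state_fraction")
    ok <- if (pool$state_inclusive) frac >= pool$state_min else
      frac > pool$state_min
    if (!ok) fail("state_fraction")
  }
  if (!is.null(pool$breaksite_state)) {
    if (!identical(as.character(record_field(record, "breaksite_state",
                                             "breaksite_state")),
                   pool$breaksite_state)) {
      fail("breaksite_state")
    }
  }
  if (!is.null(pool$dnase_gt) &&
      !(record_field(record, "dnase_max", "dnase_max") > pool$dnase_gt)) {
    fail("dnase_max")
  }
  if (!is.null(pool$dnase_lt) &&
      !(record_field(record, "dnase_max", "dnase_max") < pool$dnase_lt)) {
    fail("dnase_max")
  }
  if (!is.null(pool$lamina)) {
    field <- if (pool$lamina == "LAD") "lad_frac" else "ilad_frac"
    frac <- record_field(record, field, "lamina_fraction")
    ok <- if (pool$lamina_inclusive) frac >= pool$lamina_min else
      frac > pool$lamina_min
    if (!ok) fail("lamina_fraction")
  }
  if (!is.null(pool$h3k9me3_gt) &&
      !(record_field(record, "h3k9me3_wmean", "h3k9me3_wmean") >
        pool$h3k9me3_gt)) {
    fail("h3k9me3_wmean")
  }
  if (pool$gene_requirement == "genic_intronic") {
    if (!(record_field(record, "genic", "gene_context") &&
          record_field(record, "intronic", "gene_context"))) {
      fail("gene_context")
    }
  } else if (pool$gene_requirement == "non_genic") {
    if (record_field(record, "genic", "gene_context")) fail("gene_context")
  }
  if (pool$expression_requirement == "expressed") {
    if (!record_field(record, "expressed", "expression")) fail("expression")
  } else if (pool$expression_requirement == "non_expressed") {
    if (record_field(record, "expressed", "expression")) fail("expression")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Evaluate a pool rule set against an annotation table
#'
#' @param records `guide_annotation` data.frame.
#' @param pool A [pool_definition()].
#' @return Data.frame ledger: `id`, `pool`, `pass`, `reasons`
#'   (comma-joined failed clauses, `""` when passing).
#' @export
evaluate_rules <- function(records, pool) {
  n <- nrow(records)
  pass <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    ev <- evaluate_rule(records[i, ], pool)
    pass[i] <- ev$pass
    reasons[i] <- paste(ev$reasons, collapse = ",")
  }
  data.frame(id = records$id, pool = pool$name, pass = pass,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Select k guides from a passing set under a per-chromosome cap
#'
#' Seeded uniform shuffle of the passing records followed by a greedy scan
#' that takes a guide unless its chromosome already contributed
#' `max_per_chrom` guides. The greedy scan always attains the maximum
#' feasible pool size sum(min(n_chrom, cap)); if that maximum is below
#' `k`, an error of class `chromguide_insufficient_candidates` is raised
#' reporting it.
#'
#' @param passing `guide_annotation` rows that passed the pool's rules.
#' @param k Pool size (default 10).
#' @param max_per_chrom Per-chromosome cap (default 2).
#' @param seed Selection seed.
#' @return List of class `pool_result`: `pool`, `selected` (ids),
#'   `guides` (selected rows), `k`, `max_per_chrom`.
#' @export
select_pool <- function(passing, k = 10, max_per_chrom = 2, seed = NULL) {
  if (nrow(passing) == 0L) {
    abort("no passing candidates (max feasible pool size 0)",
          class = "chromguide_insufficient_candidates")
  }
  feasible <- sum(pmin(table(passing$chrom), max_per_chrom))
  if (feasible < k) {
    abort(paste0("cannot select %d guides with <= %d per chromosome; ",
                 "max feasible pool size is %d"),
          k, max_per_chrom, feasible,
          class = "chromguide_insufficient_candidates")
  }
  ord <- with_seed(seed, sample.int(nrow(passing)))
  shuffled <- passing[ord, , drop = FALSE]
  taken <- integer(0)
  used <- integer(0)
  names(used) <- character(0)
  for (i in seq_len(nrow(shuffled))) {
    ch <- shuffled$chrom[i]
    cnt <- if (ch %in% names(used)) used[[ch]] else 0L
    if (cnt >= max_per_chrom) next
    used[ch] <- cnt + 1L
    taken <- c(taken, i)
    if (length(taken) == k) break
  }
  sel <- shuffled[taken, , drop = FALSE]
  structure(list(pool = NULL, selected = sel$id, guides = sel, k = k,
                 max_per_chrom = max_per_chrom),
            class = "pool_result")
}

#' Design all pools from an annotation table
#'
#' Applies each pool's rules, then selects `k` guides per pool under the
#' per-chromosome cap. With `exclusive = TRUE` (default) a guide selected
#' by an earlier pool is withheld from later pools (first-claim in pool
#' order). Selection errors (insufficient candidates) are collected per
#' pool, not fatal.
#'
#' @param records `guide_annotation` data.frame.
#' @param pools List of [pool_definition()]s (default [builtin_pools()]).
#' @param k Guides per pool.
#' @param max_per_chrom Per-chromosome cap within a pool.
#' @param seed Selection seed.
#' @param exclusive Withhold already-selected guides from later pools.
#' @return List of class `pool_design`: per pool a `pool_result` (with
#'   `$error` set and empty selection when infeasible); attribute
#'   `ledger` holds the full per-guide pass/fail table across pools.
#' @export
design_pools <- function(records, pools = builtin_pools(), k = 10,
                         max_per_chrom = 2, seed = 1, exclusive = TRUE) {
  results <- list()
  ledgers <- list()
  claimed <- character(0)
  for (j in seq_along(pools)) {
    pool <- pools[[j]]
    led <- evaluate_rules(records, pool)
    ledgers[[pool$name]] <- led
    passing <- records[led$pass & !(records$id %in% claimed), , drop = FALSE]
    res <- tryCatch(
      select_pool(passing, k = k, max_per_chrom = max_per_chrom,
                  seed = if (is.null(seed)) NULL else seed + j),
      chromguide_insufficient_candidates = function(e) {
        structure(list(pool = pool$name, selected = character(0),
                       guides = records[0, ], k = k,
                       max_per_chrom = max_per_chrom,
                       error = conditionMessage(e)),
                  class = "pool_result")
      })
    res$pool <- pool$name
    results[[pool$name]] <- res
    if (exclusive) claimed <- c(claimed, res$selected)
  }
  structure(results, ledger = do.call(rbind, ledgers), class = "pool_design")
}

#' @export
print.pool_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("pool %s: FAILED (%s)\n", x$pool %||% "?", x$error))
  } else {
    cat(sprintf("pool %s: %d guides on %d chromosomes\n",
                x$pool %||% "?", length(x$selected),
                length(unique(x$guides$chrom))))
  }
  invisible(x)
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("pool design: %d pools, %d guides selected\n",
              length(x), sum(lengths(lapply(x, `[[`, "selected")))))
  for (r in x) print(r)
  invisible(x)
}

#' Extract the pass/fail ledger from a pool design
#'
#' @param design A `pool_design`.
#' @return Data.frame: `id`, `pool`, `pass`, `reasons`.
#' @export
pool_ledger <- function(design) {
  attr(design, "ledger")
}
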