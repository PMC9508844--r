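test_that("builtin_pools encodes the six published rule sets", {
  pools <- builtin_pools()
  expect_length(pools, 6L)
  expect_equal(pools$pool2$state_min, 0.65)
  expect_true(pools$pool2$state_inclusive)
  expect_equal(pools$pool2$dnase_gt, 0.2)
  expect_equal(pools$pool2$lamina_min, 0.90)
  expect_equal(pools$pool4$state_min, 0.50)
  expect_false(pools$pool4$state_inclusive)
  expect_equal(pools$pool7$dnase_lt, 0.06)
  expect_equal(pools$pool8b$lamina, "LAD")
  expect_equal(pools$pool8b$lamina_min, 0.99)
  expect_equal(pools$pool9$h3k9me3_gt, 5.5)
  expect_identical(pools$pool9$breaksite_state, "9")
})

test_that("rule evaluation respects declared boundary inclusivity", {
  pools <- builtin_pools()
  # 'at least 65%' is inclusive
  at_boundary <- record_passing("pool2", state_fracs = c("2" = 0.65))
  expect_true(evaluate_rule(at_boundary, pools$pool2)$pass)
  # 'required to exceed 0.2' is strict
  dn <- record_passing("pool2", dnase_max = 0.2)
  ev <- evaluate_rule(dn, pools$pool2)
  expect_false(ev$pass)
  expect_identical(ev$reasons, "dnase_max")
  # multiple failing clauses are all named
  two <- record_passing("pool2", dnase_max = 0.1, ilad_frac = 0.5)
  ev2 <- evaluate_rule(two, pools$pool2)
  expect_setequal(ev2$reasons, c("dnase_max", "lamina_fraction"))
})

test_that("every clause of every pool flips exactly at its threshold", {
  pools <- builtin_pools()
  eps <- 1e-6
  sweep_clause <- function(pool, arg, threshold, inclusive,
                           direction = "lower") {
    for (delta in c(-eps, 0, eps)) {
      rec <- do.call(record_passing,
                     stats::setNames(list(pool$name, threshold + delta),
                                     c("pool_name", arg)))
      # record_passing takes state_fracs as a named vector for state clauses
      pass <- evaluate_rule(rec, pool)$pass
      want <- if (direction == "lower") {
        if (inclusive) threshold + delta >= threshold else
          threshold + delta > threshold
      } else {
        threshold + delta < threshold
      }
      expect_identical(pass, want,
                       info = sprintf("%s %s at %+g", pool$name, arg, delta))
    }
  }
  # state-fraction clauses
  for (p in c("pool2", "pool4", "pool7", "pool8a", "pool8b")) {
    pool <- pools[[p]]
    for (delta in c(-eps, 0, eps)) {
      rec <- record_passing(p, state_fracs = stats::setNames(
        pool$state_min + delta, pool$state))
      want <- if (pool$state_inclusive) delta >= 0 else delta > 0
      expect_identical(evaluate_rule(rec, pool)$pass, want,
                       info = sprintf("%s state %+g", p, delta))
    }
  }
  # lamina clauses (all strict)
  for (p in names(pools)) {
    pool <- pools[[p]]
    arg <- if (pool$lamina == "LAD") "lad_frac" else "ilad_frac"
    sweep_clause(pool, arg, pool$lamina_min, inclusive = FALSE)
  }
  # signal clauses
  sweep_clause(pools$pool2, "dnase_max", 0.2, inclusive = FALSE)
  sweep_clause(pools$pool7, "dnase_max", 0.06, inclusive = FALSE,
               direction = "upper")
  sweep_clause(pools$pool9, "h3k9me3_wmean", 5.5, inclusive = FALSE)
  # breaksite clauses
  expect_false(evaluate_rule(record_passing("pool2", breaksite_state = "3"),
                             pools$pool2)$pass)
  expect_false(evaluate_rule(record_passing("pool9", breaksite_state = "8"),
                             pools$pool9)$pass)
  # gene/expression clauses
  expect_false(evaluate_rule(record_passing("pool2", exonic = TRUE,
                                            intronic = FALSE),
                             pools$pool2)$pass)
  expect_false(evaluate_rule(record_passing("pool8a", genic = TRUE),
                             pools$pool8a)$pass)
  expect_false(evaluate_rule(record_passing("pool2", expressed = FALSE),
                             pools$pool2)$pass)
})

test_that("relaxing a threshold never shrinks the passing set", {
  set.seed(77)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    record_passing("pool2", id = paste0("g", i),
                   state_fracs = c("2" = runif(1, 0.4, 1)),
                   dnase_max = runif(1, 0, 0.5),
                   ilad_frac = runif(1, 0.5, 1))
  }))
  base <- builtin_pools()$pool2
  n_pass <- function(pool) sum(evaluate_rules(recs, pool)$pass)
  strict <- n_pass(base)
  relax_state <- base; relax_state$state_min <- 0.5
  relax_dnase <- base; relax_dnase$dnase_gt <- 0.1
  relax_lam <- base; relax_lam$lamina_min <- 0.6
  expect_gte(n_pass(relax_state), strict)
  expect_gte(n_pass(relax_dnase), strict)
  expect_gte(n_pass(relax_lam), strict)
})

test_that("the pass/fail ledger is complete and reasoned", {
  set.seed(78)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    record_passing("pool4", id = paste0("g", i),
                   state_fracs = c("4" = runif(1)),
                   ilad_frac = runif(1))
  }))
  led <- evaluate_rules(recs, builtin_pools()$pool4)
  expect_equal(nrow(led), 40L)
  expect_equal(sum(led$pass) + sum(!led$pass), 40L)
  expect_true(all(nzchar(led$reasons[!led$pass])))
  expect_true(all(led$reasons[led$pass] == ""))
  expect_error(evaluate_rule(data.frame(id = "g"), builtin_pools()$pool4),
               "lacks field")
})

test_that("select_pool honours size, cap, seed and infeasibility", {
  mk <- function(chroms) {
    data.frame(id = paste0("g", seq_along(chroms)), chrom = chroms,
               stringsAsFactors = FALSE)
  }
  passing <- mk(rep(paste0("chr", 1:8), length.out = 15))
  sel <- select_pool(passing, k = 10, max_per_chrom = 2, seed = 3)
  expect_length(sel$selected, 10L)
  expect_true(all(table(sel$guides$chrom) <= 2))
  sel2 <- select_pool(passing, k = 10, max_per_chrom = 2, seed = 3)
  expect_identical(sel$selected, sel2$selected)

  err <- tryCatch(select_pool(mk(rep("chr1", 5)), k = 3, max_per_chrom = 2),
                  chromguide_insufficient_candidates = identity)
  expect_s3_class(err, "chromguide_insufficient_candidates")
  expect_match(conditionMessage(err), "max feasible pool size is 2")
})

test_that("greedy selection agrees with brute-force feasibility", {
  set.seed(79)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    k <- sample(3:5, 1)
    chroms <- paste0("chr", sample(1:4, n, replace = TRUE))
    passing <- data.frame(id = paste0("g", 1:n), chrom = chroms,
                          stringsAsFactors = FALSE)
    combos <- utils::combn(n, k)
    feasible_bf <- any(apply(combos, 2, function(ix) {
      all(table(chroms[ix]) <= 2)
    }))
    res <- tryCatch(select_pool(passing, k = k, max_per_chrom = 2, seed = i),
                    chromguide_insufficient_candidates = function(e) NULL)
    if (feasible_bf) {
      expect_false(is.null(res))
      expect_length(res$selected, k)
      expect_true(all(table(res$guides$chrom) <= 2))
    } else {
      expect_null(res)
    }
  }
})

test_that("design_pools selects per pool, exclusively and reproducibly", {
  set.seed(80)
  recs <- rbind(
    do.call(rbind, lapply(1:12, function(i) {
      record_passing("pool8a", id = sprintf("a%02d", i),
                     chrom = paste0("chr", 1 + (i %% 6)))
    })),
    do.call(rbind, lapply(1:12, function(i) {
      record_passing("pool8b", id = sprintf("b%02d", i),
                     chrom = paste0("chr", 1 + (i %% 6)))
    })))
  pools <- builtin_pools()[c("pool8a", "pool8b", "pool9")]
  d1 <- design_pools(recs, pools, k = 10, max_per_chrom = 2, seed = 5)
  d2 <- design_pools(recs, pools, k = 10, max_per_chrom = 2, seed = 5)
  expect_identical(d1$pool8a$selected, d2$pool8a$selected)
  expect_length(d1$pool8a$selected, 10L)
  expect_length(d1$pool8b$selected, 10L)
  # pool9 has no qualifying records: collected error, not fatal
  expect_false(is.null(d1$pool9$error))
  expect_length(d1$pool9$selected, 0L)
  # exclusivity: no guide claimed twice
  all_sel <- unlist(lapply(d1, `[[`, "selected"))
  expect_false(anyDuplicated(all_sel) > 0)
  led <- pool_ledger(d1)
  expect_equal(nrow(led), nrow(recs) * length(pools))
})
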