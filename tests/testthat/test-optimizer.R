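# Mismatch-pattern search and candidate ranking.

test_that("pattern enumeration matches a brute-force window filter", {
  # independent check: filter all 2^10 subsets of a 10-pair stem
  all_subsets <- function(n) {
    out <- list(integer())
    for (p in seq_len(n)) out <- c(out, lapply(out, function(s) c(s, p)))
    out
  }
  brute <- Filter(function(s) {
    ok <- TRUE
    if (length(s)) {
      for (w in 1:7) if (sum(s >= w & s <= w + 3) > 3) ok <- FALSE
    }
    ok
  }, all_subsets(10))
  pats <- enumerate_mismatch_patterns(10, pinned = integer(), extra_max = 10)
  expect_equal(length(pats), length(brute))
  # {1,2,3,4} violates the rule and is excluded
  expect_false(any(vapply(pats, function(p) identical(p, 1:4), logical(1))))
  # pinning with no extras returns exactly the pinned pattern
  only <- enumerate_mismatch_patterns(20, pinned = c(2, 9, 17), extra_max = 0)
  expect_identical(only, list(c(2L, 9L, 17L)))
  expect_error(enumerate_mismatch_patterns(10, pinned = c(1, 2, 3, 4)),
               "contradictory pins")
  expect_error(enumerate_mismatch_patterns(10, pinned = 12), "contradictory")
})

test_that("the optimizer returns feasible, deterministically ranked designs", {
  opt <- cached("opt_default", optimize_design(mir17(), demo_spacer()))
  expect_s3_class(opt, "tbl_df")
  expect_gt(nrow(opt), 1L)
  cons <- design_constraints()
  expect_true(all(opt$trigger_dg >= cons$dg_window[1] &
                  opt$trigger_dg <= cons$dg_window[2]))
  expect_true(all(opt$seed_duplex_run <= cons$max_seed_duplex_run))
  for (d in opt$design) expect_equal(nrow(validate_design(d)), 0L)
  # determinism: a second run reproduces the ranking exactly
  opt2 <- optimize_design(mir17(), demo_spacer())
  expect_identical(opt$trigger_dg, opt2$trigger_dg)
  expect_identical(purrr::map_chr(opt$design, ~ .x$full_sequence),
                   purrr::map_chr(opt2$design, ~ .x$full_sequence))
})

test_that("recovery: the optimizer reaches the pair-probability target from
           the mismatch-free skeleton", {
  opt <- cached("opt_default", optimize_design(mir17(), demo_spacer()))
  top <- opt$design[[1]]
  trig <- substr(top$full_sequence, 1, top$trigger_hairpin[2])
  ens <- partition_function(trig)
  stem <- top$designed_pairs[!top$designed_pairs$mismatch &
                             top$designed_pairs$j <= top$trigger_hairpin[2], ]
  probs <- ens$bpp[cbind(stem$i, stem$j)]
  expect_lte(abs(stats::median(probs) - 0.90), 0.05)
  # the tuned design is closer to the target than the untuned skeleton,
  # whose mismatch-free stem saturates near probability 1
  skel <- assemble_full_length(mir17(), demo_spacer(),
                               pattern = mismatch_pattern(c(2, 9, 17), integer()))
  trig0 <- substr(skel$full_sequence, 1, skel$trigger_hairpin[2])
  ens0 <- partition_function(trig0)
  stem0 <- skel$designed_pairs[!skel$designed_pairs$mismatch, ]
  med0 <- stats::median(ens0$bpp[cbind(stem0$i, stem0$j)])
  expect_lt(abs(stats::median(probs) - 0.90), abs(med0 - 0.90))
})

test_that("widening the free-energy window never shrinks the feasible set", {
  narrow <- design_constraints(dg_window = c(-16, -14))
  wide <- design_constraints(dg_window = c(-20, -10))
  o_n <- optimize_design(mir17(), demo_spacer(), constraints = narrow)
  o_w <- optimize_design(mir17(), demo_spacer(), constraints = wide)
  n_n <- if (is.data.frame(o_n)) nrow(o_n) else 0L
  n_w <- if (is.data.frame(o_w)) nrow(o_w) else 0L
  expect_gte(n_w, n_n)
})

test_that("rank_designs is a stable deterministic sort", {
  opt <- cached("opt_default", optimize_design(mir17(), demo_spacer()))
  k <- min(4L, nrow(opt))
  designs <- opt$design[seq_len(k)]
  reports <- cached("rank_reports", purrr::map(designs, switch_report))
  rk <- rank_designs(designs, reports)
  expect_identical(rk$rank, seq_len(k))
  # permutation invariance
  perm <- rev(seq_len(k))
  rk2 <- rank_designs(designs[perm], reports[perm])
  expect_identical(purrr::map_chr(rk$design, ~ .x$full_sequence),
                   purrr::map_chr(rk2$design, ~ .x$full_sequence))
  expect_error(rank_designs(designs, reports[-1]), "same length")
})

test_that("an impossible window is reported as unsatisfiable", {
  cons <- design_constraints(dg_window = c(-200, -150))
  res <- optimize_design(mir17(), demo_spacer(), constraints = cons)
  expect_true(is.list(res) && isTRUE(res$unsatisfiable))
  expect_match(res$binding_constraint, "dG window")
})
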