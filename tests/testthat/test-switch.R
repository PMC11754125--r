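# Switching diagnostics: OFF/ON proxy, invasion cost, displacement, scoring.

test_that("the OFF state sequesters the spacer; a standard guide does not", {
  d <- base_design()
  off <- off_state_report(d)
  expect_gte(off$spacer_paired_fraction, 0.8)
  expect_true(all(off$stem_pairs$probability >= 0 &
                  off$stem_pairs$probability <= 1))
  expect_gt(nrow(off$scaffold_stems), 0L)
  sg <- standard_guide(demo_spacer())
  off_sg <- off_state_report(sg)
  expect_lt(off_sg$spacer_paired_fraction, 0.5)
})

test_that("the ON proxy frees the spacer and refuses non-cognate triggers", {
  d <- base_design()
  on <- on_state_proxy(d)
  expect_gte(on$on_gain, 0)
  expect_gt(on$spacer_accessible_fraction, on$off_accessible_fraction - 1e-9)
  expect_error(on_state_proxy(d, mir16()), "not the cognate")
  # standard guide: empty constraint set, ON equals OFF exactly
  sg <- standard_guide(demo_spacer())
  on_sg <- on_state_proxy(sg, NULL)
  expect_identical(on_sg$on_gain, 0)
})

test_that("seed invasion cost is non-negative and drops with a seed mismatch", {
  pat <- base_design()$pattern
  with_mm2 <- assemble_full_length(mir17(), demo_spacer(), pattern = pat,
                                   site_mismatches = c(2, 9, 17))
  no_mm2 <- assemble_full_length(mir17(), demo_spacer(),
                                 pattern = mismatch_pattern(c(9, 17),
                                                            pat$shield_arm),
                                 site_mismatches = c(9, 17))
  c1 <- seed_invasion_cost(with_mm2)
  c0 <- seed_invasion_cost(no_mm2)
  expect_gte(c1, 0)
  expect_gte(c0, 0)
  expect_lt(c1, c0)
  expect_error(seed_invasion_cost(standard_guide(demo_spacer())), "seed-match")
})

test_that("strand displacement: weak-hairpin toy yes, seed-only design no", {
  # toy: shield destroyed (3 mismatches per 4-pair window everywhere), so a
  # perfect full-length duplex easily displaces the ~4-bp residual hairpin
  weak_arm <- setdiff(1:33, seq(4, 32, by = 4))
  toy <- assemble_full_length(mir17(), demo_spacer(),
                              pattern = mismatch_pattern(integer(), weak_arm),
                              site_mismatches = integer())
  disp_toy <- strand_displacement_check(toy)
  expect_true(disp_toy$favorable)
  # a seed-only design offers only a 7-bp duplex: cannot pay initiation
  d <- seed_only_design()
  disp <- strand_displacement_check(d)
  expect_false(disp$favorable)
  expect_gt(disp$displacement_dg, 0)
  # shortening the bound region (seed vs full site) is strictly less favorable
  full <- base_design()
  expect_gt(disp$displacement_dg,
            strand_displacement_check(full)$displacement_dg)
  expect_error(strand_displacement_check(d, mir16()), "cognate")
})

test_that("pathway robustness holds for assembled designs", {
  expect_true(pathway_robustness(base_design()))
  expect_true(pathway_robustness(seed_only_design()))
  # alpha = 0 makes the check trivially true for any sequence
  set.seed(67)
  s <- rand_rna(60)
  expect_true(pathway_robustness(s, cofold = cofold_params(alpha = 0)))
})

test_that("switch_score aggregates criteria deterministically", {
  d <- base_design()
  r <- switch_report(d)
  sc <- switch_score(r)
  expect_equal(nrow(sc$checks), 7L)
  expect_true(sc$score >= 0 && sc$score <= 1)
  # over-stable trigger fails the window criterion
  r_stable <- r
  r_stable$trigger_dg <- -30
  sc2 <- switch_score(r_stable)
  expect_false(sc2$checks$pass[sc2$checks$criterion == "trigger_dg_window"])
  expect_lt(sc2$score, sc$score)
  # an over-blocked seed fails its criterion
  r_blocked <- r
  r_blocked$seed_duplex_run <- 10L
  sc3 <- switch_score(r_blocked)
  expect_false(sc3$checks$pass[sc3$checks$criterion == "seed_not_overblocked"])
})

test_that("glance and tidy expose the report as tibbles", {
  r <- cached("base_report", switch_report(base_design()))
  g <- glance(r)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_true(all(c("on_gain", "trigger_dg", "pathway_robust") %in% names(g)))
  td <- tidy(r)
  expect_true(all(c("i", "j", "probability") %in% names(td)))
})
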