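# Mismatch-placement search.
#
# Trigger-hairpin stability is tuned by where the shield fails to pair its
# arm. The deterministic greedy tuner reproduces the design workflow: start
# from the (very stable) mismatch-free stem, cap the continuous duplex over
# the spacer seed, then add shield-layer mismatches one at a time, each time
# taking the position that brings the hairpin free energy closest to the
# target, until the window is reached. optimize_design() then searches the
# neighbourhood of patterns and ranks candidates by switch score.

trigger_dg_of <- function(design, params) {
  trig <- substr(design$full_sequence, design$trigger_hairpin[1],
                 design$trigger_hairpin[2])
  fold_mfe(trig, params)$delta_g
}

trigger_median_pp <- function(design, params) {
  trig_end <- design$trigger_hairpin[2]
  dp <- design$designed_pairs
  stem <- dp[!dp$mismatch & dp$j <= trig_end, , drop = FALSE]
  if (nrow(stem) == 0L) return(NA_real_)
  trig <- substr(design$full_sequence, design$trigger_hairpin[1], trig_end)
  ens <- partition_function(trig, params)
  stats::median(ens$bpp[cbind(stem$i, stem$j)])
}

# deterministic greedy stability tuner (internal)
tune_shield_pattern <- function(build, mir, spc, constraints,
                                site_mismatches, site_mode = "full_length",
                                seed_rule = TRUE, seed_run = NULL,
                                params = energy_params(), max_iter = 24L) {
  base_pat <- mismatch_pattern(binding_site = site_mismatches,
                               shield_arm = integer())
  d0 <- build(base_pat)
  dp <- d0$designed_pairs
  arm_len <- max(dp$arm_pos)
  seed_pos_global <- spacer_seed_positions(d0)
  seed_arm <- sort(dp$arm_pos[dp$j %in% seed_pos_global])
  shield_arm <- integer()
  if (seed_rule && length(seed_arm) > 0L) {
    seed_run <- seed_run %||% constraints$max_seed_duplex_run
    if (seed_run < length(seed_arm)) {
      # keep the PAM-proximal `seed_run` positions paired; break the duplex
      # just 5' of them
      boundary <- sort(seed_arm, decreasing = TRUE)[seed_run + 1L]
      shield_arm <- boundary
    }
  }
  protected_run <- integer()
  if (seed_rule && length(seed_arm) > 0L && !is.null(seed_run) &&
      seed_run < length(seed_arm)) {
    protected_run <- sort(seed_arm, decreasing = TRUE)[seq_len(seed_run)]
  }
  # mismatches may sit anywhere in the shield (it is only partially
  # complementary to site, guide and G alike); the seed run, the positions
  # the site layer already breaks, and the terminal G stay untouched
  site_layer <- dp$arm_pos[dp$mismatch]
  allowed <- setdiff(seq_len(arm_len - 1L),
                     c(protected_run, shield_arm, site_layer, arm_len))
  dg_lo <- constraints$dg_window[1]
  dg_hi <- constraints$dg_window[2]
  center <- mean(constraints$dg_window)

  # realized-run requirement: when the seed rule applies, the MFE of the
  # trigger hairpin must show exactly the designed continuous duplex over
  # the spacer seed, so candidates that rearrange the stem are rejected
  target_run <- if (seed_rule && length(seed_arm) > 0L) {
    min(seed_run %||% length(seed_arm), length(seed_arm))
  } else NA_integer_
  evaluate <- function(arm) {
    pat <- mismatch_pattern(site_mismatches, arm)
    d <- build(pat)
    trig <- substr(d$full_sequence, d$trigger_hairpin[1], d$trigger_hairpin[2])
    st <- fold_mfe(trig, params)
    run <- if (is.na(target_run)) NA_integer_ else
      longest_duplex_run(st, spacer_seed_positions(d))
    list(dg = st$delta_g, run = run)
  }
  run_ok <- function(ev) is.na(target_run) || identical(ev$run, target_run)
  cur <- sort(shield_arm)
  cur_ev <- evaluate(cur)
  best <- cur; best_gap <- abs(cur_ev$dg - center); best_ok <- run_ok(cur_ev)
  for (iter in seq_len(max_iter)) {
    if (run_ok(cur_ev) && cur_ev$dg >= dg_lo && cur_ev$dg <= dg_hi &&
        abs(cur_ev$dg - center) <= 1) break
    cands <- setdiff(allowed, cur)
    cands <- cands[vapply(cands, function(t) {
      spacing_rule_ok(sort(c(cur, t)), arm_len)
    }, logical(1))]
    if (length(cands) == 0L) break
    evs <- lapply(cands, function(t) evaluate(sort(c(cur, t))))
    ok <- vapply(evs, run_ok, logical(1))
    if (any(ok)) { cands <- cands[ok]; evs <- evs[ok] }
    gaps <- vapply(evs, function(e) abs(e$dg - center), numeric(1))
    pick <- which.min(gaps)               # ties: first, i.e. smallest position
    if (gaps[pick] >= abs(cur_ev$dg - center)) break
    cur <- sort(c(cur, cands[pick]))
    cur_ev <- evs[[pick]]
    if ((run_ok(cur_ev) && !best_ok) ||
        (run_ok(cur_ev) == best_ok && abs(cur_ev$dg - center) < best_gap)) {
      best <- cur; best_gap <- abs(cur_ev$dg - center); best_ok <- run_ok(cur_ev)
    }
  }
  if ((run_ok(cur_ev) && !best_ok) ||
      (run_ok(cur_ev) == best_ok && abs(cur_ev$dg - center) <= best_gap)) {
    best <- cur
  }
  mismatch_pattern(site_mismatches, best)
}

#' Enumerate mismatch patterns satisfying the spacing rule
#'
#' Streams, in deterministic order (by size, then lexicographically), every
#' superset of `pinned` over `1..n_arm` with at most `extra_max` additional
#' positions whose indicator satisfies the sliding-window rule.
#'
#' @param n_arm number of designed pairs in the stem.
#' @param pinned positions that must be present (e.g. `c(2, 9, 17)`).
#' @param extra_max maximum number of additional mismatches.
#' @param window,max_per_window spacing rule.
#' @return list of integer vectors.
#' @export
enumerate_mismatch_patterns <- function(n_arm, pinned = integer(),
                                        extra_max = 3L,
                                        window = 4L, max_per_window = 3L) {
  pinned <- sort(unique(as.integer(pinned)))
  if (any(pinned < 1L | pinned > n_arm)) abort("contradictory pins: outside the stem")
  if (!spacing_rule_ok(pinned, n_arm, window, max_per_window)) {
    abort("contradictory pins: pinned set violates the spacing rule")
  }
  free <- setdiff(seq_len(n_arm), pinned)
  out <- list(pinned)
  for (k in seq_len(min(extra_max, length(free)))) {
    combos <- utils::combn(free, k, simplify = FALSE)
    keep <- purrr::map(combos, function(extra) {
      pat <- sort(c(pinned, extra))
      if (spacing_rule_ok(pat, n_arm, window, max_per_window)) pat else NULL
    })
    out <- c(out, purrr::compact(keep))
  }
  out
}

#' Search configuration for the design optimizer
#'
#' @param seed RNG seed (used by the annealed strategy).
#' @param strategy `"greedy"` (deterministic tuner plus local refinement,
#'   the default), `"exhaustive_small"` (all patterns within `extra_max` of
#'   the pinned set; only for small stems) or `"annealed"`.
#' @param max_candidates cap on evaluated candidates.
#' @param extra_max extra mismatches beyond the tuned pattern to explore.
#' @export
search_config <- function(seed = 1L,
                          strategy = c("greedy", "exhaustive_small", "annealed"),
                          max_candidates = 60L, extra_max = 2L) {
  strategy <- match.arg(strategy)
  structure(list(seed = as.integer(seed), strategy = strategy,
                 max_candidates = as.integer(max_candidates),
                 extra_max = as.integer(extra_max)),
            class = "mir_search_config")
}

#' Optimize a miR-guide design
#'
#' Generates candidate shield-layer mismatch patterns around the
#' deterministic tuner's solution, evaluates each candidate's trigger
#' hairpin (free energy, designed-pair probabilities, spacer-seed duplex
#' run) and ranks the feasible ones. Hard constraints -- free-energy window,
#' seed-run cap, grammar validity -- are enforced; if nothing is feasible an
#' `unsatisfiable` result names the binding constraint.
#'
#' @param mir,spc,scf inputs as for [assemble_full_length()].
#' @param constraints [design_constraints()].
#' @param search [search_config()].
#' @param architecture `"full_length_5prime_hairpin"` or `"seed_only"`.
#' @param params [energy_params()].
#' @return tibble of ranked candidates (columns `rank`, `trigger_dg`,
#'   `median_pair_probability`, `seed_duplex_run`, `score`, and list-columns
#'   `design`, `pattern`), or a list with `unsatisfiable = TRUE`.
#' @export
optimize_design <- function(mir, spc, scf = NULL,
                            constraints = design_constraints(),
                            search = search_config(),
                            architecture = c("full_length_5prime_hairpin",
                                             "seed_only"),
                            params = energy_params()) {
  architecture <- match.arg(architecture)
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold(constraints$scaffold_variant)
  assemble <- if (architecture == "seed_only") assemble_seed_only else assemble_full_length
  site_mm <- if (architecture == "seed_only") 2L else c(2L, 9L, 17L)

  tuned <- assemble(mir, spc, scf, constraints)
  base_arm <- tuned$pattern$shield_arm
  arm_len <- max(tuned$designed_pairs$arm_pos)
  seed_pos_global <- spacer_seed_positions(tuned)
  seed_arm <- sort(tuned$designed_pairs$arm_pos[tuned$designed_pairs$j %in% seed_pos_global])
  site_layer <- tuned$designed_pairs$arm_pos[tuned$designed_pairs$mismatch &
                                             !(tuned$designed_pairs$arm_pos %in% base_arm)]
  run <- constraints$max_seed_duplex_run
  protected_run <- if (length(seed_arm) && run < length(seed_arm)) {
    sort(seed_arm, decreasing = TRUE)[seq_len(run)]
  } else integer()
  protected <- unique(c(protected_run, site_layer, arm_len))

  neighbourhood <- function(arm) {
    free <- setdiff(seq_len(arm_len - 1L), c(protected, arm))
    removable <- setdiff(arm, protected)
    cand <- c(list(arm),
              purrr::map(free, ~ sort(c(arm, .x))),
              purrr::map(removable, ~ setdiff(arm, .x)),
              purrr::map(unlist(purrr::map(removable, function(r) {
                purrr::map(free, function(a) list(r = r, a = a))
              }), recursive = FALSE),
              ~ sort(c(setdiff(arm, .x$r), .x$a))))
    cand <- unique(cand)
    cand[vapply(cand, spacing_rule_ok, logical(1), n_arm = arm_len)]
  }

  pats <- switch(search$strategy,
    greedy = neighbourhood(base_arm),
    exhaustive_small = enumerate_mismatch_patterns(
      arm_len, pinned = base_arm, extra_max = search$extra_max),
    annealed = withr::with_seed(search$seed, {
      out <- list(base_arm)
      arm <- base_arm
      for (k in seq_len(search$max_candidates - 1L)) {
        free <- setdiff(seq_len(arm_len - 1L), c(protected, arm))
        removable <- setdiff(arm, protected)
        move <- sample(c("add", "remove"), 1,
                       prob = c(length(free) > 0, length(removable) > 0))
        arm2 <- if (move == "add") sort(c(arm, sample(free, 1)))
                else setdiff(arm, sample(removable, 1))
        if (spacing_rule_ok(arm2, arm_len)) arm <- arm2
        out <- c(out, list(arm))
      }
      unique(out)
    })
  )
  if (length(pats) > search$max_candidates) pats <- pats[seq_len(search$max_candidates)]

  rows <- purrr::map(pats, function(arm) {
    pat <- mismatch_pattern(site_mm, arm)
    d <- assemble(mir, spc, scf, constraints, pattern = pat)
    if (nrow(validate_design(d)) > 0L) return(NULL)
    dg <- trigger_dg_of(d, params)
    mpp <- trigger_median_pp(d, params)
    trig_mfe <- fold_mfe(substr(d$full_sequence, 1L, d$trigger_hairpin[2]), params)
    run <- longest_duplex_run(trig_mfe, spacer_seed_positions(d))
    tibble::tibble(trigger_dg = dg, median_pair_probability = mpp,
                   seed_duplex_run = run,
                   design = list(d), pattern = list(pat))
  })
  cand <- dplyr::bind_rows(rows)
  if (nrow(cand) == 0L) {
    return(list(unsatisfiable = TRUE, binding_constraint = "design grammar"))
  }
  feasible <- cand |>
    dplyr::filter(.data$trigger_dg >= constraints$dg_window[1],
                  .data$trigger_dg <= constraints$dg_window[2],
                  .data$seed_duplex_run <= constraints$max_seed_duplex_run)
  if (nrow(feasible) == 0L) {
    return(list(unsatisfiable = TRUE,
                binding_constraint = sprintf(
                  "no pattern reaches the dG window [%.1f, %.1f] with seed run <= %d",
                  constraints$dg_window[1], constraints$dg_window[2],
                  constraints$max_seed_duplex_run)))
  }
  feasible <- feasible |>
    dplyr::mutate(
      score = pmax(0, 1 - abs(.data$median_pair_probability -
                                constraints$pair_prob_target) / 0.10) +
              pmax(0, 1 - abs(.data$trigger_dg - mean(constraints$dg_window)) / 10),
      seq = purrr::map_chr(.data$design, ~ .x$full_sequence)
    ) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   abs(.data$trigger_dg - mean(constraints$dg_window)),
                   .data$seq) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "trigger_dg", "median_pair_probability",
                  "seed_duplex_run", "score", "design", "pattern")
  feasible
}

#' Rank design candidates by report quality
#'
#' Stable deterministic sort: passed-criteria count (descending), score
#' (descending), distance of the trigger free energy from the window centre
#' (ascending), then full sequence (lexicographic).
#'
#' @param designs list of `mir_guide`.
#' @param reports matching list of `mir_switch_report`.
#' @param constraints [design_constraints()].
#' @return tibble with `rank` and ordering keys plus list-columns.
#' @export
rank_designs <- function(designs, reports,
                         constraints = design_constraints()) {
  if (length(designs) != length(reports)) {
    abort("designs and reports must have the same length")
  }
  rows <- purrr::map2(designs, reports, function(d, r) {
    sc <- switch_score(r, constraints)
    tibble::tibble(n_pass = sum(sc$checks$pass), score = sc$score,
                   dg_gap = abs(r$trigger_dg - mean(constraints$dg_window)),
                   seq = d$full_sequence,
                   design = list(d), report = list(r))
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n_pass), dplyr::desc(.data$score),
                   .data$dg_gap, .data$seq) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "n_pass", "score", "dg_gap", "design", "report")
}

# ---------------------------------------------------------------------------
# study-condition series

#' Trigger-hairpin stability series
#'
#' Designs one guide per free-energy target (default -15, -19, -25, -30
#' kcal/mol: the reference stability series) by tuning the number of
#' shield-layer mismatches while the binding site stays constant; fewer
#' mismatches means more base pairs and a more stable hairpin.
#'
#' @param mir,spc,scf inputs.
#' @param targets kcal/mol.
#' @param params [energy_params()].
#' @return tibble with `target_dg`, `trigger_dg` and a `design` list-column.
#' @export
design_stability_series <- function(mir, spc, scf = NULL,
                                    targets = c(-15, -19, -25, -30),
                                    params = energy_params()) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold()
  rows <- purrr::map(targets, function(tg) {
    cons <- design_constraints(dg_window = tg + c(-1, 1),
                               max_seed_duplex_run = 17L)
    build <- function(pat) {
      assemble_hairpin_core(mir, spc$sequence, scf$sequence, "scaffold",
                            binding_site_spec("full_length", c(2L, 9L, 17L)),
                            pat, NULL, "full_length_5prime_hairpin",
                            spc, scf, cons)
    }
    pat <- tune_shield_pattern(build, mir, spc, cons,
                               site_mismatches = c(2L, 9L, 17L),
                               seed_rule = FALSE, params = params)
    d <- build(pat)
    tibble::tibble(target_dg = tg, trigger_dg = trigger_dg_of(d, params),
                   design = list(d))
  })
  dplyr::bind_rows(rows)
}

#' Seed-coverage series at constant stability
#'
#' Designs one guide per requested continuous-duplex length over the spacer
#' seed (default 6, 8 and 10 bp), placing compensating mismatches elsewhere
#' to hold the trigger free energy near `dg_target` (default -15 kcal/mol).
#'
#' @param mir,spc,scf inputs.
#' @param runs duplex lengths.
#' @param dg_target kcal/mol.
#' @param params [energy_params()].
#' @return tibble with `target_run`, `trigger_dg`, `seed_duplex_run` (from
#'   the MFE structure) and a `design` list-column.
#' @export
design_seed_block_series <- function(mir, spc, scf = NULL,
                                     runs = c(6L, 8L, 10L),
                                     dg_target = -15,
                                     params = energy_params()) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold()
  rows <- purrr::map(runs, function(r) {
    cons <- design_constraints(dg_window = dg_target + c(-1, 1),
                               max_seed_duplex_run = as.integer(r))
    build <- function(pat) {
      assemble_hairpin_core(mir, spc$sequence, scf$sequence, "scaffold",
                            binding_site_spec("full_length", c(2L, 9L, 17L)),
                            pat, NULL, "full_length_5prime_hairpin",
                            spc, scf, cons)
    }
    pat <- tune_shield_pattern(build, mir, spc, cons,
                               site_mismatches = c(2L, 9L, 17L),
                               seed_rule = TRUE, seed_run = as.integer(r),
                               params = params)
    d <- build(pat)
    mfe <- fold_mfe(substr(d$full_sequence, 1L, d$trigger_hairpin[2]), params)
    tibble::tibble(target_run = as.integer(r),
                   trigger_dg = trigger_dg_of(d, params),
                   seed_duplex_run = longest_duplex_run(mfe, spacer_seed_positions(d)),
                   design = list(d))
  })
  dplyr::bind_rows(rows)
}
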