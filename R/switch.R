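# Switching diagnostics for assembled designs.
#
# The ON state is modelled as "binding site occupied": every binding-site
# position is forced unpaired, a computable surrogate for AGO-miRNA
# occupancy (the package deliberately does not model AGO energetics). OFF
# vs. ON behaviour, the cost of opening the seed sub-duplex, a two-state
# strand-displacement test against the free miRNA, and an equilibrium-vs-
# cotranscriptional robustness check are combined into a SwitchReport.

#' OFF-state report
#'
#' Equilibrium base-pair probabilities of the intact guide: fraction of
#' spacer positions paired (probability >= threshold), per-designed-pair
#' probabilities, and the mean internal pairing of each annotated scaffold
#' stem.
#'
#' @param design `mir_guide`.
#' @param params [energy_params()].
#' @param threshold pairing-probability threshold (default from the design's
#'   constraints).
#' @return list with `spacer_paired_fraction`, `spacer_p_paired`,
#'   `stem_pairs` (tibble of designed pairs with probabilities),
#'   `scaffold_stems` (tibble), and the `mir_ensemble`.
#' @export
off_state_report <- function(design, params = energy_params(),
                             threshold = NULL) {
  threshold <- threshold %||% design$constraints$prob_threshold
  ens <- partition_function(design$full_sequence, params)
  report_state(design, ens, threshold)
}

report_state <- function(design, ens, threshold) {
  comp <- design$components
  spacer_row <- comp[comp$name == "spacer", ]
  spacer_pos <- if (nrow(spacer_row)) seq(spacer_row$start, spacer_row$end) else integer()
  p_paired <- ens$p_paired
  dp <- design$designed_pairs
  stem <- dp[!dp$mismatch, , drop = FALSE]
  stem$probability <- if (nrow(stem)) ens$bpp[cbind(stem$i, stem$j)] else numeric()
  scf_rows <- comp[grepl("^scaffold", comp$name), ]
  stems <- scaffold_stem_integrity(design, ens, scf_rows)
  list(
    spacer_paired_fraction = if (length(spacer_pos)) mean(p_paired[spacer_pos] >= threshold) else NA_real_,
    spacer_p_paired = p_paired[spacer_pos],
    stem_pairs = stem,
    scaffold_stems = stems,
    ensemble = ens,
    threshold = threshold
  )
}

scaffold_stem_integrity <- function(design, ens, scf_rows) {
  if (nrow(scf_rows) == 0L || is.null(design$scaffold)) {
    return(tibble::tibble(stem = character(), mean_internal_pairing = numeric()))
  }
  ann <- design$scaffold$annotations
  stems <- ann[grepl("^stem_loop", ann$name), ]
  offset <- scf_rows$start[nrow(scf_rows)] - 1L
  scf_len <- nchar(design$scaffold$sequence)
  out <- purrr::map(seq_len(nrow(stems)), function(k) {
    iv <- c(stems$start[k], stems$end[k])
    if (iv[2] > scf_len) return(NULL)
    gl <- (iv[1]:iv[2]) + offset
    gl <- gl[gl >= 1 & gl <= nchar(design$full_sequence)]
    if (length(gl) < 4L) return(NULL)
    p_int <- rowSums(ens$bpp[gl, gl, drop = FALSE])
    tibble::tibble(stem = stems$name[k], mean_internal_pairing = mean(p_int))
  })
  dplyr::bind_rows(out)
}

#' ON-state proxy
#'
#' Re-folds the guide with every binding-site position forced unpaired
#' (AGO-miRNA occupancy surrogate) and reports spacer accessibility. The
#' supplied miRNA must be the design's cognate trigger: specificity is
#' enforced at the sequence level.
#'
#' @param design `mir_guide`.
#' @param mir the trigger to apply; must match the design's miRNA.
#' @param params [energy_params()].
#' @param threshold pairing threshold.
#' @return list with `spacer_accessible_fraction`, `on_gain`, plus the OFF
#'   report used for the comparison.
#' @export
on_state_proxy <- function(design, mir = design$mirna,
                           params = energy_params(), threshold = NULL) {
  threshold <- threshold %||% design$constraints$prob_threshold
  site_pos <- site_positions(design)
  if (length(site_pos) > 0L) {
    if (is.null(mir)) abort("design has a binding site; supply its trigger miRNA")
    if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
    if (!identical(mir$sequence, design$mirna$sequence)) {
      abort(sprintf("'%s' is not the cognate trigger of this design (expects %s)",
                    mir$name, design$mirna$name))
    }
  }
  off <- off_state_report(design, params, threshold)
  ens_on <- if (length(site_pos)) {
    partition_function(design$full_sequence, params, forced_unpaired = site_pos)
  } else {
    off$ensemble
  }
  comp <- design$components
  spacer_row <- comp[comp$name == "spacer", ]
  spacer_pos <- if (nrow(spacer_row)) seq(spacer_row$start, spacer_row$end) else integer()
  acc_on <- mean(ens_on$p_paired[spacer_pos] < threshold)
  acc_off <- mean(off$spacer_p_paired < threshold)
  list(spacer_accessible_fraction = acc_on,
       off_accessible_fraction = acc_off,
       on_gain = acc_on - acc_off,
       ensemble_on = ens_on,
       off = off)
}

#' Free-energy cost of opening the seed-match sub-duplex
#'
#' Ensemble free-energy difference between folding with the binding-site
#' positions that face the miRNA seed forced unpaired and unconstrained
#' folding. Non-negative by construction; lower cost means easier AGO
#' invasion.
#'
#' @param design `mir_guide`.
#' @param params [energy_params()].
#' @return kcal/mol.
#' @export
seed_invasion_cost <- function(design, params = energy_params()) {
  sm <- design$site_map
  seed <- design$mirna$seed_region
  pos <- sm$global_pos[sm$mirna_pos >= seed[1] & sm$mirna_pos <= seed[2]]
  if (length(pos) == 0L) abort("no seed-match sub-duplex in this design")
  g_free <- partition_function(design$full_sequence, params, bpp = FALSE)
  g_open <- partition_function(design$full_sequence, params,
                               forced_unpaired = pos, bpp = FALSE)
  max(0, g_open$ensemble_energy - g_free$ensemble_energy)
}

#' Two-state strand-displacement check
#'
#' Compares the intact state (MFE of the guide plus the free miRNA's own
#' MFE) with the displaced state (nearest-neighbour duplex energy of the
#' miRNA bound to the realized binding site, including its mismatches, plus
#' the guide re-folded with the site forced unpaired). The duplex
#' initiation term is an effective standard-state value
#' `4.09 + RT ln(1/c_ref)` at the reference concentration `c_ref`, recorded
#' in the result.
#'
#' @param design `mir_guide`.
#' @param mir cognate trigger.
#' @param params [energy_params()].
#' @param c_ref reference concentration in mol/L (default 5e-8, i.e. 50 nM,
#'   a typical transfection concentration).
#' @return list with `displacement_dg` (displaced minus intact, kcal/mol),
#'   `favorable` (TRUE if < 0), `duplex_dg`, `opening_dg` and `c_ref`.
#' @export
strand_displacement_check <- function(design, mir = design$mirna,
                                      params = energy_params(),
                                      c_ref = 5e-8) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!identical(mir$sequence, design$mirna$sequence)) {
    abort("strand displacement is evaluated against the cognate miRNA")
  }
  site_pos <- site_positions(design)
  if (length(site_pos) == 0L) abort("design has no binding site")
  intact <- fold_mfe(design$full_sequence, params)$delta_g +
    fold_mfe(mir$sequence, params)$delta_g
  open <- constrained_fold(design$full_sequence, params,
                           forced_unpaired = site_pos)$delta_g
  dup <- duplex_energy(design, mir, params, c_ref)
  displaced <- dup + open
  list(displacement_dg = displaced - intact,
       favorable = (displaced - intact) < 0,
       duplex_dg = dup,
       opening_dg = open - fold_mfe(design$full_sequence, params)$delta_g,
       c_ref = c_ref)
}

# nearest-neighbour duplex energy of miRNA::binding-site with the site's
# mismatches; unbound overhangs are free, interior mismatch runs are scored
# as (symmetric) internal loops, terminal AU/GU pays the end penalty.
duplex_energy <- function(design, mir, params = energy_params(), c_ref = 5e-8) {
  sm <- design$site_map
  sm <- sm[order(sm$mirna_pos), ]
  mchars <- rna_chars(mir$sequence)
  schars <- rna_chars(design$full_sequence)
  site_res <- schars[sm$global_pos]
  paired <- pairs_with(site_res, mchars[sm$mirna_pos])
  rt <- 1.98717e-3 * (params$temperature + 273.15)
  init <- 4.09 + rt * log(1 / c_ref)
  if (!any(paired)) return(0)
  idx <- which(paired)
  e <- init
  code <- function(ch) match(ch, RNA_ALPHABET) - 1L
  ptype <- function(k) rsw_pair_code(code(site_res[k]), code(mchars[sm$mirna_pos[k]]))
  for (w in seq_along(idx)[-1]) {
    a <- idx[w - 1]; b <- idx[w]
    gap <- b - a - 1L
    # columns ordered by miRNA position ascending = site index descending;
    # the stack as read 5'->3' on the site strand runs from column b to a
    if (gap == 0L) {
      e <- e + rsw_stack_energy(ptype(b), ptype(a))
    } else {
      ei <- rsw_internal_energy(gap, gap, ptype(b), ptype(a))
      if (is.na(ei)) ei <- 6.0 # beyond the loop cap; generous penalty
      e <- e + ei
    }
  }
  e <- e + rsw_terminal_au(ptype(idx[1])) + rsw_terminal_au(ptype(idx[length(idx)]))
  e
}

#' Folding-pathway robustness
#'
#' TRUE when the equilibrium MFE structure and the cotranscriptional
#' (distance-scaled) MFE structure have identical dot-brackets.
#'
#' @param design `mir_guide` (or a bare sequence).
#' @param params [energy_params()].
#' @param cofold [cofold_params()].
#' @return logical.
#' @export
pathway_robustness <- function(design, params = energy_params(),
                               cofold = cofold_params()) {
  seqs <- if (inherits(design, "mir_guide")) design$full_sequence else as_rna(design)
  eq <- fold_mfe(seqs, params)
  co <- cofold_mfe(seqs, params, cofold)
  identical(eq$dot_bracket, co$dot_bracket)
}

#' Full switch report for a design
#'
#' @param design `mir_guide`.
#' @param mir cognate trigger (defaults to the design's own miRNA).
#' @param params [energy_params()].
#' @param cofold [cofold_params()].
#' @return object of class `mir_switch_report`.
#' @export
switch_report <- function(design, mir = design$mirna,
                          params = energy_params(),
                          cofold = cofold_params()) {
  on <- on_state_proxy(design, mir, params)
  off <- on$off
  trig_seq <- substr(design$full_sequence, design$trigger_hairpin[1],
                     design$trigger_hairpin[2])
  trig_dg <- fold_mfe(trig_seq, params)$delta_g
  has_site <- length(site_positions(design)) > 0L
  disp <- if (has_site) strand_displacement_check(design, mir, params) else NULL
  seed_cost <- if (has_site) seed_invasion_cost(design, params) else NA_real_
  seed_pos <- spacer_seed_positions(design)
  mfe_full <- fold_mfe(design$full_sequence, params)
  seed_run <- if (length(seed_pos)) longest_duplex_run(mfe_full, seed_pos) else NA_integer_
  structure(
    list(design = design,
         off_spacer_paired_fraction = off$spacer_paired_fraction,
         on_spacer_accessible_fraction = on$spacer_accessible_fraction,
         off_spacer_accessible_fraction = on$off_accessible_fraction,
         on_gain = on$on_gain,
         seed_invasion_cost = seed_cost,
         displacement_dg = if (is.null(disp)) NA_real_ else disp$displacement_dg,
         displacement_favorable = if (is.null(disp)) NA else disp$favorable,
         pathway_robust = pathway_robustness(design, params, cofold),
         trigger_dg = trig_dg,
         seed_duplex_run = seed_run,
         stem_pair_probabilities = off$stem_pairs,
         scaffold_stems = off$scaffold_stems,
         threshold = off$threshold),
    class = "mir_switch_report"
  )
}

#' @export
print.mir_switch_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<switch report>\n",
    "  OFF spacer paired fraction: %.2f\n",
    "  ON spacer accessible fraction: %.2f (gain %.2f)\n",
    "  trigger dG: %.2f kcal/mol; seed duplex run: %s\n",
    "  seed invasion cost: %.2f kcal/mol\n",
    "  displacement dG: %s (%s)\n",
    "  pathway robust: %s\n"),
    x$off_spacer_paired_fraction,
    x$on_spacer_accessible_fraction, x$on_gain,
    x$trigger_dg, as.character(x$seed_duplex_run),
    x$seed_invasion_cost,
    ifelse(is.na(x$displacement_dg), "NA", sprintf("%.2f", x$displacement_dg)),
    ifelse(isTRUE(x$displacement_favorable), "favorable", "unfavorable"),
    x$pathway_robust))
  invisible(x)
}

#' @export
glance.mir_switch_report <- function(x, ...) {
  tibble::tibble(
    architecture = x$design$architecture,
    mirna = if (is.null(x$design$mirna)) NA_character_ else x$design$mirna$name,
    off_spacer_paired_fraction = x$off_spacer_paired_fraction,
    on_spacer_accessible_fraction = x$on_spacer_accessible_fraction,
    on_gain = x$on_gain,
    trigger_dg = x$trigger_dg,
    seed_duplex_run = x$seed_duplex_run,
    seed_invasion_cost = x$seed_invasion_cost,
    displacement_dg = x$displacement_dg,
    displacement_favorable = x$displacement_favorable,
    pathway_robust = x$pathway_robust,
    median_pair_probability = stats::median(x$stem_pair_probabilities$probability)
  )
}

#' @export
tidy.mir_switch_report <- function(x, ...) {
  x$stem_pair_probabilities
}

#' Score a switch report against design constraints
#'
#' Deterministic aggregation: a design passes when the OFF state is
#' sequestered, the ON gain clears its threshold, the trigger free energy
#' lies in the window, the designed-pair probabilities sit near the target,
#' the seed duplex is not over-blocked, displacement by the free miRNA is
#' unfavorable, and folding is pathway-robust. The scalar score is the mean
#' of bounded per-criterion subscores.
#'
#' @param report `mir_switch_report`.
#' @param constraints [design_constraints()].
#' @return list with `score`, `pass`, and a `checks` tibble.
#' @export
switch_score <- function(report, constraints = report$design$constraints) {
  dgc <- mean(constraints$dg_window)
  med_pp <- stats::median(report$stem_pair_probabilities$probability)
  checks <- tibble::tibble(
    criterion = c("off_sequestered", "on_gain", "trigger_dg_window",
                  "pair_probability", "seed_not_overblocked",
                  "displacement_unfavorable", "pathway_robust"),
    pass = c(
      report$off_spacer_paired_fraction >= constraints$off_paired_min,
      report$on_gain >= constraints$on_gain_min,
      report$trigger_dg >= constraints$dg_window[1] &
        report$trigger_dg <= constraints$dg_window[2],
      abs(med_pp - constraints$pair_prob_target) <= 0.05,
      is.na(report$seed_duplex_run) ||
        report$seed_duplex_run <= constraints$max_seed_duplex_run,
      !isTRUE(report$displacement_favorable),
      isTRUE(report$pathway_robust)
    ),
    detail = c(
      sprintf("OFF paired fraction %.2f", report$off_spacer_paired_fraction),
      sprintf("ON gain %.2f", report$on_gain),
      sprintf("trigger dG %.2f (window %.1f..%.1f)", report$trigger_dg,
              constraints$dg_window[1], constraints$dg_window[2]),
      sprintf("median designed-pair probability %.3f", med_pp),
      sprintf("seed duplex run %s (max %d)",
              as.character(report$seed_duplex_run),
              constraints$max_seed_duplex_run),
      sprintf("displacement dG %.2f",
              ifelse(is.na(report$displacement_dg), NA, report$displacement_dg)),
      sprintf("pathway robust: %s", report$pathway_robust)
    )
  )
  sub <- c(
    min(1, report$off_spacer_paired_fraction / constraints$off_paired_min),
    max(0, min(1, report$on_gain / max(constraints$on_gain_min, 1e-9))),
    max(0, 1 - abs(report$trigger_dg - dgc) / 10),
    max(0, 1 - abs(med_pp - constraints$pair_prob_target) / 0.10),
    as.numeric(checks$pass[5]),
    as.numeric(checks$pass[6]),
    as.numeric(checks$pass[7])
  )
  list(score = mean(sub), pass = all(checks$pass), checks = checks)
}
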