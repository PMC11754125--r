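# Assembly grammar for miRNA-sensing guides.
#
# A full-length design reads, 5'->3':
#
#   shield | loop (distal binding site) | proximal binding site | spacer | scaffold
#
# The shield is the reverse complement of the "arm" it sequesters -- the
# proximal binding site (miRNA positions <= 16), the spacer, and the first G
# of the repeat -- with deliberate mismatches at two layers: site-layer
# mismatches (binding site vs. miRNA; e.g. the 2/9/17 preset) and
# shield-layer mismatches (indexed along the arm) that tune the trigger
# hairpin's free energy. Because the shield is complementary to the
# *perfect* site, site-layer mismatches destabilise the stem as well: the
# same substitution that frustrates the miRNA also frustrates the shield.

#' Build a miRNA-binding site
#'
#' @param mir [mirna()] object (or sequence).
#' @param spec [binding_site_spec()].
#' @return list with `sequence` (the realized site), `perfect_sequence`
#'   (the exact complement before mismatch injection), and `map`, a tibble
#'   linking each site position to the miRNA position it faces with a
#'   `mismatch` flag.
#' @export
build_binding_site <- function(mir, spec = binding_site_spec()) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  m <- mir$sequence
  L <- nchar(m)
  if (spec$mode == "full_length") {
    lo <- 1L; hi <- L
  } else {
    lo <- mir$seed_region[1]; hi <- mir$seed_region[2]
    outside <- setdiff(spec$mismatch_positions, lo:hi)
    if (length(outside) > 0L) {
      abort(sprintf("seed_only site cannot carry mismatches outside the seed (%s)",
                    paste(outside, collapse = ", ")))
    }
  }
  if (any(spec$mismatch_positions < lo | spec$mismatch_positions > hi)) {
    abort("mismatch positions outside the binding site")
  }
  perfect <- reverse_complement(substr(m, lo, hi))
  site <- perfect
  len <- nchar(site)
  mchars <- rna_chars(m)
  # site index s faces miRNA position hi + 1 - s
  for (p in spec$mismatch_positions) {
    s <- hi + 1L - p
    site <- inject_mismatch(site, s, mchars[p])
  }
  map <- tibble::tibble(
    site_pos = seq_len(len),
    mirna_pos = hi + 1L - seq_len(len),
    mismatch = (hi + 1L - seq_len(len)) %in% spec$mismatch_positions
  )
  list(sequence = site, perfect_sequence = perfect, map = map,
       mode = spec$mode, mirna = mir)
}

#' Build the shield for a trigger hairpin
#'
#' The shield is the reverse complement of the concatenation
#' `[proximal binding site] + [blocked element] + [first repeat G]`, taken
#' from the *perfect* site so that site-layer mismatches carry through to
#' the stem, then modified by the shield-layer mismatches of `pattern`.
#'
#' @param site result of [build_binding_site()].
#' @param blocked sequence of the blocked element (spacer, or antirepeat for
#'   the tracrRNA unit of a split gate).
#' @param pattern [mismatch_pattern()]; `shield_arm` positions index the arm
#'   5'->3' (site part first, then the blocked element, then the G).
#' @param first_g include the first repeat G in the arm (default TRUE).
#' @param covered_max furthest miRNA position the shield may cover.
#' @return list with `sequence`, `arm_realized`, `arm_perfect`,
#'   `n_site_covered` and `arm_len`.
#' @export
build_shield <- function(site, blocked, pattern = mismatch_pattern(),
                         first_g = TRUE, covered_max = 16L) {
  map <- site$map
  covered <- map$mirna_pos <= covered_max
  n_cov <- sum(covered)
  if (n_cov == 0L) abort("shield would cover no binding-site positions")
  cov_idx <- map$site_pos[covered]       # contiguous 3' block of the site
  site_prox_real <- substr(site$sequence, min(cov_idx), max(cov_idx))
  site_prox_perf <- substr(site$perfect_sequence, min(cov_idx), max(cov_idx))
  g <- if (first_g) "G" else ""
  arm_perfect <- paste0(site_prox_perf, blocked, g)
  arm_real <- paste0(site_prox_real, blocked, g)
  arm_len <- nchar(arm_perfect)
  if (length(pattern$shield_arm) && any(pattern$shield_arm > arm_len)) {
    abort("shield-layer mismatch positions beyond the arm")
  }
  if (!spacing_rule_ok(pattern$shield_arm, arm_len,
                       pattern$window, pattern$max_per_window)) {
    abort("shield-layer mismatches violate the spacing rule")
  }
  shield <- reverse_complement(arm_perfect)
  arm_chars <- rna_chars(arm_real)
  for (t in pattern$shield_arm) {
    u <- arm_len + 1L - t
    shield <- inject_mismatch(shield, u, arm_chars[t])
  }
  list(sequence = shield, arm_realized = arm_real, arm_perfect = arm_perfect,
       n_site_covered = n_cov, arm_len = arm_len)
}

# ---------------------------------------------------------------------------
# design object

new_design <- function(architecture, full, components, trigger_hairpin,
                       designed_pairs, site_map, mir, spc, scf, pattern,
                       constraints, blocked_element = "spacer") {
  structure(
    list(architecture = architecture,
         full_sequence = full,
         components = components,
         trigger_hairpin = trigger_hairpin,
         designed_pairs = designed_pairs,
         site_map = site_map,
         mirna = mir, spacer = spc, scaffold = scf,
         pattern = pattern, constraints = constraints,
         blocked_element = blocked_element),
    class = "mir_guide"
  )
}

#' @export
print.mir_guide <- function(x, ...) {
  cat(sprintf("<miR-guide, %s, %d nt, trigger %d-%d>\n",
              x$architecture, nchar(x$full_sequence),
              x$trigger_hairpin[1], x$trigger_hairpin[2]))
  cat(x$full_sequence, "\n")
  comp <- paste(sprintf("%s[%d-%d]", x$components$name,
                        x$components$start, x$components$end),
                collapse = " ")
  cat(comp, "\n")
  invisible(x)
}

#' @export
tidy.mir_guide <- function(x, ...) {
  x$components
}

#' @export
glance.mir_guide <- function(x, ...) {
  tibble::tibble(architecture = x$architecture,
                 length = nchar(x$full_sequence),
                 mirna = x$mirna$name,
                 n_site_mismatches = length(x$pattern$binding_site),
                 n_shield_mismatches = length(x$pattern$shield_arm))
}

# global positions of the spacer seed (PAM-proximal 10 nt)
spacer_seed_positions <- function(design) {
  comp <- design$components
  row <- comp[comp$name == "spacer", ]
  if (nrow(row) == 0L) return(integer())
  len <- row$end - row$start + 1L
  # PAM-proximal position p is string index len + 1 - p
  row$start + (len - 10L):(len - 1L)
}

# global positions of all realized binding-site residues
site_positions <- function(design) {
  design$site_map$global_pos
}

#' Seed-matching segment of a design's binding site
#'
#' Returns the substring of the full guide whose residues face the miRNA
#' seed (positions 2-8); used e.g. for seed-swap experiments.
#'
#' @param design `mir_guide`.
#' @return list with `interval` (global) and `sequence`.
#' @export
seed_site_segment <- function(design) {
  sm <- design$site_map
  seed <- design$mirna$seed_region
  rows <- sm[sm$mirna_pos >= seed[1] & sm$mirna_pos <= seed[2], ]
  iv <- range(rows$global_pos)
  list(interval = iv,
       sequence = substr(design$full_sequence, iv[1], iv[2]))
}

# ---------------------------------------------------------------------------
# assemblers

assemble_hairpin_core <- function(mir, blocked_seq, tail_seq, tail_name,
                                  spec, pattern, loop_override = NULL,
                                  architecture, spc, scf, constraints,
                                  blocked_name = "spacer",
                                  first_g = TRUE) {
  site <- build_binding_site(mir, spec)
  sh <- build_shield(site, blocked_seq, pattern,
                     first_g = first_g, covered_max = spec$covered_max)
  map <- site$map
  covered <- map$mirna_pos <= spec$covered_max
  n_cov <- sum(covered)
  distal_idx <- map$site_pos[!covered]
  loop_seq <- if (!is.null(loop_override)) loop_override
              else if (length(distal_idx) > 0L)
                substr(site$sequence, min(distal_idx), max(distal_idx))
              else ""
  # pad loops shorter than 3 nt with a GAAA tetraloop
  if (nchar(loop_seq) < 3L) loop_seq <- paste0(loop_seq, "GAAA")
  prox_seq <- substr(site$sequence, min(map$site_pos[covered]),
                     max(map$site_pos[covered]))
  A <- sh$arm_len
  nloop <- nchar(loop_seq)
  nb <- nchar(blocked_seq)
  full <- paste0(sh$sequence, loop_seq, prox_seq, blocked_seq, tail_seq)
  comp <- tibble::tibble(
    name = c("shield", "loop", "binding_site", blocked_name, tail_name),
    start = cumsum(c(1L, A, nloop, n_cov, nb))[1:5],
    end = cumsum(c(A, nloop, n_cov, nb, nchar(tail_seq)))
  )
  # designed stem: arm position t faces shield position A + 1 - t
  arm_start <- A + nloop + 1L
  arm_global <- seq(arm_start, arm_start + n_cov + nb - 1L)
  if (first_g) {  # the first G of the tail is part of the arm
    arm_global <- c(arm_global, arm_start + n_cov + nb)
  }
  shield_chars <- rna_chars(sh$sequence)
  arm_chars <- rna_chars(sh$arm_realized)
  t_all <- seq_len(A)
  designed <- tibble::tibble(
    i = A + 1L - t_all,
    j = arm_global[t_all],
    arm_pos = t_all,
    mismatch = !pairs_with(shield_chars[A + 1L - t_all], arm_chars[t_all])
  )
  # global coordinates of the realized site (loop holds the distal part
  # unless a tetraloop replaced it)
  sm <- map
  if (is.null(loop_override) && length(distal_idx) > 0L) {
    sm$global_pos <- ifelse(covered,
                            arm_start + (sm$site_pos - min(map$site_pos[covered])),
                            A + (sm$site_pos - min(distal_idx) + 1L))
  } else {
    sm <- sm[covered, ]
    sm$global_pos <- arm_start + (sm$site_pos - min(map$site_pos[covered]))
  }
  trig <- c(1L, arm_start + n_cov + nb - (1L - as.integer(first_g)))
  new_design(architecture, full, comp, trig, designed, sm, mir = site$mirna,
             spc = spc, scf = scf, pattern = pattern,
             constraints = constraints, blocked_element = blocked_name)
}

#' Assemble a full-length miR-guide
#'
#' Shield, hairpin loop (distal binding site), proximal binding site, spacer
#' and scaffold, in 5'->3' order. With `pattern = NULL` the shield-layer
#' mismatches are placed by the deterministic stability tuner so the trigger
#' hairpin lands in the constraint's free-energy window while the continuous
#' duplex over the spacer seed does not exceed `max_seed_duplex_run`.
#'
#' @param mir [mirna()] (or sequence).
#' @param spc [spacer_guide()] (or sequence).
#' @param scf [scaffold()]; defaults to the variant named in `constraints`.
#' @param constraints [design_constraints()].
#' @param pattern [mismatch_pattern()], or NULL to tune.
#' @param site_mismatches miRNA positions for the site layer (default the
#'   active 2/9/17 preset; use `c(10, 11)` for the AGO-cleavage-ablating
#'   set).
#' @return `mir_guide`.
#' @export
assemble_full_length <- function(mir, spc, scf = NULL,
                                 constraints = design_constraints(),
                                 pattern = NULL,
                                 site_mismatches = c(2L, 9L, 17L)) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold(constraints$scaffold_variant)
  spec <- binding_site_spec("full_length", site_mismatches)
  build <- function(pat) {
    assemble_hairpin_core(mir, spc$sequence, scf$sequence, "scaffold",
                          spec, pat, NULL, "full_length_5prime_hairpin",
                          spc, scf, constraints)
  }
  if (is.null(pattern)) {
    pattern <- tune_shield_pattern(build, mir, spc, constraints,
                                   site_mismatches = site_mismatches)
  }
  build(pattern)
}

#' Assemble a seed-only miR-guide
#'
#' The binding site covers only the miRNA seed; a GAAA tetraloop closes the
#' hairpin. The default site layer carries a single mismatch at miRNA
#' position 2.
#'
#' @inheritParams assemble_full_length
#' @param site_mismatches default `2L`.
#' @return `mir_guide`.
#' @export
assemble_seed_only <- function(mir, spc, scf = NULL,
                               constraints = design_constraints(),
                               pattern = NULL,
                               site_mismatches = 2L) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold(constraints$scaffold_variant)
  spec <- binding_site_spec("seed_only", site_mismatches)
  build <- function(pat) {
    assemble_hairpin_core(mir, spc$sequence, scf$sequence, "scaffold",
                          spec, pat, "GAAA", "seed_only",
                          spc, scf, constraints)
  }
  if (is.null(pattern)) {
    pattern <- tune_shield_pattern(build, mir, spc, constraints,
                                   site_mismatches = site_mismatches,
                                   site_mode = "seed_only")
  }
  build(pattern)
}

#' Assemble a tetraloop-shield miR-guide
#'
#' Alternative architecture: the shield and binding site replace the GAAA
#' tetraloop of stem-loop 1, and the spacer (which stays at the 5' end, as
#' in a standard guide) is sequestered by long-range pairing with the
#' shield. The internal layout (shield segment for spacer+G first, then the
#' segment for the binding site, then the site) is chosen so that all
#' designed pairs nest.
#'
#' @inheritParams assemble_full_length
#' @return `mir_guide`.
#' @export
assemble_tetraloop_shield <- function(mir, spc, scf = NULL,
                                      constraints = design_constraints(),
                                      pattern = NULL,
                                      site_mismatches = c(2L, 9L, 17L)) {
  if (!inherits(mir, "mir_mirna")) mir <- mirna(mir)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  scf <- scf %||% scaffold(constraints$scaffold_variant)
  ann <- scf$annotations
  tl <- ann[ann$name == "tetraloop", ]
  if (nrow(tl) != 1L) abort("scaffold lacks a tetraloop annotation")
  spec <- binding_site_spec("full_length", site_mismatches)
  build <- function(pat) assemble_tetraloop_impl(mir, spc, scf, spec, pat, constraints)
  if (is.null(pattern)) {
    pattern <- tune_shield_pattern(build, mir, spc, constraints,
                                   site_mismatches = site_mismatches)
  }
  build(pattern)
}

assemble_tetraloop_impl <- function(mir, spc, scf, spec, pattern, constraints) {
  site <- build_binding_site(mir, spec)
  map <- site$map
  covered <- map$mirna_pos <= spec$covered_max
  n_cov <- sum(covered)
  ann <- scf$annotations
  tl <- ann[ann$name == "tetraloop", ]
  rep5 <- substr(scf$sequence, 1L, tl$start - 1L)          # repeat incl. first G
  rest <- substr(scf$sequence, tl$end + 1L, nchar(scf$sequence))
  slen <- spc$spacer_length
  arm_len <- n_cov + slen + 1L

  site_prox_perf <- substr(site$perfect_sequence, min(map$site_pos[covered]),
                           max(map$site_pos[covered]))
  shield_sp <- reverse_complement(paste0(spc$sequence, "G"))
  shield_site <- reverse_complement(site_prox_perf)
  # apply shield-layer mismatches, indexed along the conceptual arm
  arm_real <- paste0(substr(site$sequence, min(map$site_pos[covered]),
                            max(map$site_pos[covered])),
                     spc$sequence, "G")
  if (!spacing_rule_ok(pattern$shield_arm, arm_len,
                       pattern$window, pattern$max_per_window)) {
    abort("shield-layer mismatches violate the spacing rule")
  }
  arm_chars <- rna_chars(arm_real)
  for (t in pattern$shield_arm) {
    if (t > arm_len) abort("shield-layer mismatch positions beyond the arm")
    if (t <= n_cov) {
      shield_site <- inject_mismatch(shield_site, n_cov + 1L - t, arm_chars[t])
    } else if (t <= n_cov + slen) {
      s <- t - n_cov
      shield_sp <- inject_mismatch(shield_sp, slen + 2L - s, arm_chars[t])
    } else {
      shield_sp <- inject_mismatch(shield_sp, 1L, arm_chars[t])
    }
  }
  full <- paste0(spc$sequence, rep5, shield_sp, shield_site,
                 site$sequence, rest)
  n_rep <- nchar(rep5)
  comp <- tibble::tibble(
    name = c("spacer", "scaffold_repeat", "shield", "loop", "binding_site",
             "scaffold"),
    start = cumsum(c(1L, slen, n_rep, slen + 1L + n_cov,
                     nchar(site$sequence) - n_cov, n_cov))[1:6],
    end = cumsum(c(slen, n_rep, slen + 1L + n_cov,
                   nchar(site$sequence) - n_cov, n_cov, nchar(rest)))
  )
  # designed pairs
  sp_start <- slen + n_rep + 1L            # global start of shield_sp
  ss_start <- sp_start + slen + 1L         # global start of shield_site
  site_start <- ss_start + n_cov           # global start of the full site
  prox_start <- site_start + (nchar(site$sequence) - n_cov)
  shield_sp_chars <- rna_chars(shield_sp)
  shield_site_chars <- rna_chars(shield_site)
  rows <- purrr::map(seq_len(arm_len), function(t) {
    if (t <= n_cov) {
      i <- ss_start + (n_cov - t)
      j <- prox_start + (t - 1L)
      mm <- !pairs_with(shield_site_chars[n_cov + 1L - t], arm_chars[t])
    } else if (t <= n_cov + slen) {
      s <- t - n_cov
      i <- s
      j <- sp_start + (slen + 1L - s)
      mm <- !pairs_with(shield_sp_chars[slen + 2L - s], arm_chars[t])
    } else {
      i <- slen + 1L                        # the first repeat G
      j <- sp_start
      mm <- !pairs_with(shield_sp_chars[1L], "G")
    }
    tibble::tibble(i = min(i, j), j = max(i, j), arm_pos = t, mismatch = mm)
  })
  designed <- dplyr::bind_rows(rows)
  sm <- map
  sm$global_pos <- site_start + sm$site_pos - 1L
  trig <- c(1L, prox_start + n_cov - 1L)
  new_design("tetraloop_shield", full, comp, trig, designed, sm,
             mir = site$mirna, spc = spc, scf = scf, pattern = pattern,
             constraints = constraints, blocked_element = "spacer")
}

#' Assemble a split AND-gate guide pair
#'
#' Two separately transcribed units: a crRNA unit whose trigger hairpin
#' blocks the spacer (sensing miRNA A) and a tracrRNA unit whose hairpin
#' blocks the antirepeat (sensing miRNA B). Cas9 assembles a functional
#' guide only when both hairpins are opened, i.e. both miRNAs are present.
#'
#' @param mir_a,mir_b distinct trigger miRNAs.
#' @param spc spacer.
#' @param scf scaffold.
#' @param constraints [design_constraints()].
#' @param pattern_a,pattern_b optional [mismatch_pattern()]s (tuned if NULL).
#' @return object of class `mir_split_pair` with elements `cr_unit` and
#'   `tracr_unit`.
#' @export
assemble_split_and_gate <- function(mir_a, mir_b, spc, scf = NULL,
                                    constraints = design_constraints(),
                                    pattern_a = NULL, pattern_b = NULL) {
  if (!inherits(mir_a, "mir_mirna")) mir_a <- mirna(mir_a)
  if (!inherits(mir_b, "mir_mirna")) mir_b <- mirna(mir_b)
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  if (identical(mir_a$sequence, mir_b$sequence)) {
    abort("the two units must sense distinct miRNAs (gate degenerates to one input)")
  }
  scf <- scf %||% scaffold(constraints$scaffold_variant)
  ann <- scf$annotations
  rep_iv <- ann[ann$name == "repeat", ]
  ar_iv <- ann[ann$name == "antirepeat", ]
  crRNA_tail <- substr(scf$sequence, rep_iv$start, rep_iv$end)
  tracr_seq <- substr(scf$sequence, ar_iv$start, nchar(scf$sequence))
  ar_len <- ar_iv$end - ar_iv$start + 1L

  spec_a <- binding_site_spec("full_length", c(2L, 9L, 17L))
  build_cr <- function(pat) {
    assemble_hairpin_core(mir_a, spc$sequence, crRNA_tail, "scaffold",
                          spec_a, pat, NULL, "split_and_gate_unit",
                          spc, scf, constraints, blocked_name = "spacer")
  }
  if (is.null(pattern_a)) {
    pattern_a <- tune_shield_pattern(build_cr, mir_a, spc, constraints,
                                     site_mismatches = c(2L, 9L, 17L))
  }
  cr_unit <- build_cr(pattern_a)

  spec_b <- binding_site_spec("full_length", c(2L, 9L, 17L))
  antirepeat <- substr(tracr_seq, 1L, ar_len)
  tracr_rest <- substr(tracr_seq, ar_len + 1L, nchar(tracr_seq))
  build_tr <- function(pat) {
    assemble_hairpin_core(mir_b, antirepeat, tracr_rest, "scaffold",
                          spec_b, pat, NULL, "split_and_gate_unit",
                          spc, scf, constraints,
                          blocked_name = "antirepeat", first_g = FALSE)
  }
  if (is.null(pattern_b)) {
    pattern_b <- tune_shield_pattern(build_tr, mir_b, NULL, constraints,
                                     site_mismatches = c(2L, 9L, 17L),
                                     seed_rule = FALSE)
  }
  tracr_unit <- build_tr(pattern_b)

  structure(list(cr_unit = cr_unit, tracr_unit = tracr_unit),
            class = "mir_split_pair")
}

#' @export
print.mir_split_pair <- function(x, ...) {
  cat("<split AND-gate pair>\ncrRNA unit:\n")
  print(x$cr_unit)
  cat("tracrRNA unit:\n")
  print(x$tracr_unit)
  invisible(x)
}

#' A standard (non-switch) guide, for comparisons
#'
#' @param spc spacer; @param scf scaffold.
#' @return `mir_guide` with architecture `"standard"`, no shield and no
#'   binding site.
#' @export
standard_guide <- function(spc, scf = scaffold()) {
  if (!inherits(spc, "mir_spacer")) spc <- spacer_guide(spc)
  full <- paste0(spc$sequence, scf$sequence)
  comp <- tibble::tibble(name = c("spacer", "scaffold"),
                         start = c(1L, spc$spacer_length + 1L),
                         end = c(spc$spacer_length, nchar(full)))
  new_design("standard", full, comp, c(1L, spc$spacer_length),
             tibble::tibble(i = integer(), j = integer(),
                            arm_pos = integer(), mismatch = logical()),
             tibble::tibble(site_pos = integer(), mirna_pos = integer(),
                            mismatch = logical(), global_pos = integer()),
             mir = NULL, spc = spc, scf = scf,
             pattern = mismatch_pattern(integer(), integer()),
             constraints = design_constraints())
}

# ---------------------------------------------------------------------------
# backbone fixes and templates

#' Interrupt uracil runs (Pol III anti-termination fix)
#'
#' Every run of U longer than `max_run` receives a U-to-C substitution at
#' its central position; the pass repeats until no long run remains (a
#' single substitution suffices for all runs up to `2 * max_run + 1`), so
#' the operation is idempotent.
#'
#' @param seq RNA sequence.
#' @param max_run longest U run to leave untouched (default 3).
#' @return list with `sequence` and `edits` (tibble position/from/to).
#' @export
fix_poly_u <- function(seq, max_run = 3L) {
  seq <- as_rna(seq)
  edits <- tibble::tibble(position = integer(), from = character(),
                          to = character())
  repeat {
    runs <- gregexpr("U+", seq)[[1]]
    lens <- attr(runs, "match.length")
    long <- which(runs > 0 & lens > max_run)
    if (length(long) == 0L) break
    for (k in long) {
      pos <- runs[k] + ceiling(lens[k] / 2) - 1L
      substr(seq, pos, pos) <- "C"
      edits <- dplyr::bind_rows(edits,
        tibble::tibble(position = pos, from = "U", to = "C"))
    }
  }
  list(sequence = seq, edits = edits)
}

#' Expression-template specification
#'
#' @param promoter `"U6"`, `"H1"`, `"7SK"` (Pol III cassettes: the promoter
#'   itself lives on the vector, so only the transcript body plus a poly-T
#'   terminator is emitted, with a leading G enforced) or `"T7"` (promoter
#'   sequence emitted; the transcript starts GG when `leading_g = TRUE`).
#' @param leading_g enforce the leading-G policy.
#' @param poly_t Pol III terminator length (ignored for T7).
#' @export
template_spec <- function(promoter = c("U6", "H1", "7SK", "T7"),
                          leading_g = TRUE, poly_t = 6L) {
  promoter <- match.arg(promoter)
  structure(list(promoter = promoter, leading_g = leading_g,
                 poly_t = as.integer(poly_t)),
            class = "mir_template_spec")
}

T7_PROMOTER <- "TAATACGACTCACTATAG"

#' Emit a DNA template for a design
#'
#' @param design `mir_guide`.
#' @param spec [template_spec()].
#' @return list of class `mir_template`: `dna` (sense strand), `spec`,
#'   `n_leading_g` (Gs prepended by the leading-G policy).
#' @export
emit_dna_template <- function(design, spec = template_spec()) {
  body_rna <- design$full_sequence
  n_g <- 0L
  if (spec$leading_g) {
    if (spec$promoter == "T7") {
      while (substr(body_rna, 1L, 2L) != "GG" && n_g < 2L) {
        body_rna <- paste0("G", body_rna)
        n_g <- n_g + 1L
      }
    } else if (substr(body_rna, 1L, 1L) != "G") {
      body_rna <- paste0("G", body_rna)
      n_g <- 1L
    }
  }
  body_dna <- chartr("U", "T", body_rna)
  dna <- if (spec$promoter == "T7") {
    paste0(T7_PROMOTER, body_dna)
  } else {
    paste0(body_dna, strrep("T", spec$poly_t))
  }
  structure(list(dna = dna, spec = spec, n_leading_g = n_g),
            class = "mir_template")
}

#' In-silico transcription of an emitted template
#'
#' Strips the promoter (T7) or terminator (Pol III) and any policy-added
#' leading Gs, and back-transcribes T to U; round-trips to the design's
#' full sequence.
#'
#' @param template `mir_template`.
#' @return RNA sequence.
#' @export
transcribe_template <- function(template) {
  dna <- template$dna
  spec <- template$spec
  if (spec$promoter == "T7") {
    dna <- substr(dna, nchar(T7_PROMOTER) + 1L, nchar(dna))
  } else if (spec$poly_t > 0L) {
    dna <- substr(dna, 1L, nchar(dna) - spec$poly_t)
  }
  if (template$n_leading_g > 0L) {
    dna <- substr(dna, template$n_leading_g + 1L, nchar(dna))
  }
  chartr("T", "U", dna)
}
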