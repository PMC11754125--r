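# Grammar validation. Violations are data, not exceptions.

#' Validate an assembled design against the grammar
#'
#' Checks component tiling, the position-16 coverage bound, the mismatch
#' spacing rule, the spacer-length rule, scaffold-annotation integrity, the
#' seed-only tetraloop, and that every declared mismatch really fails to
#' pair. An empty tibble means the design is grammatical.
#'
#' @param design `mir_guide` or `mir_split_pair` (units validated
#'   separately, prefixed in the rule name).
#' @return tibble with columns `rule` and `detail`; zero rows if valid.
#' @export
validate_design <- function(design) {
  if (inherits(design, "mir_split_pair")) {
    v1 <- validate_design(design$cr_unit)
    v2 <- validate_design(design$tracr_unit)
    if (nrow(v1)) v1$rule <- paste0("cr_unit: ", v1$rule)
    if (nrow(v2)) v2$rule <- paste0("tracr_unit: ", v2$rule)
    return(dplyr::bind_rows(v1, v2))
  }
  stopifnot(inherits(design, "mir_guide"))
  out <- list()
  note <- function(rule, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(rule = rule, detail = detail)
  }
  comp <- design$components[order(design$components$start), ]
  n <- nchar(design$full_sequence)

  # component tiling: partition of [1, n] without gaps or overlaps
  if (comp$start[1] != 1L || comp$end[nrow(comp)] != n ||
      (nrow(comp) > 1L && any(comp$start[-1] != comp$end[-nrow(comp)] + 1L))) {
    note("component_tiling", "components do not tile the full sequence")
  }

  # spacer content and length
  sp <- comp[comp$name == "spacer", ]
  if (nrow(sp) == 1L && !is.null(design$spacer)) {
    got <- substr(design$full_sequence, sp$start, sp$end)
    if (!identical(got, design$spacer$sequence)) {
      note("spacer_content", "spacer interval does not contain the input spacer")
    }
    len <- sp$end - sp$start + 1L
    if (len < 17L || len > 20L) {
      note("spacer_length", sprintf("spacer length %d outside 17-20", len))
    }
  }

  # coverage bound: shield may reach no further than miRNA position 16
  dp <- design$designed_pairs
  sm <- design$site_map
  if (nrow(sm) > 0L && nrow(dp) > 0L) {
    covered_mirna <- sm$mirna_pos[sm$global_pos %in% dp$j]
    if (length(covered_mirna) && max(covered_mirna) > 16L) {
      note("covered_position_bound",
           sprintf("covered position > 16 (reaches %d)", max(covered_mirna)))
    }
  }

  # spacing rule on the shield layer
  if (nrow(dp) > 0L) {
    arm_len <- max(dp$arm_pos)
    mm_arm <- sort(dp$arm_pos[dp$mismatch])
    if (!spacing_rule_ok(mm_arm, arm_len,
                         design$pattern$window, design$pattern$max_per_window)) {
      note("mismatch_spacing",
           sprintf("more than %d mismatches in a %d-pair window",
                   design$pattern$max_per_window, design$pattern$window))
    }
    # declared mismatches must truly fail to pair, and declared pairs must pair
    chars <- rna_chars(design$full_sequence)
    really <- !pairs_with(chars[dp$i], chars[dp$j])
    if (any(really != dp$mismatch)) {
      note("mismatch_declaration",
           "declared mismatch flags disagree with the pairing predicate")
    }
  }

  # seed-only designs carry a GAAA tetraloop
  if (identical(design$architecture, "seed_only")) {
    lp <- comp[comp$name == "loop", ]
    loop_seq <- substr(design$full_sequence, lp$start, lp$end)
    if (!identical(loop_seq, "GAAA")) {
      note("tetraloop", sprintf("seed-only loop is %s, expected GAAA", loop_seq))
    }
  }

  # scaffold annotation integrity
  if (!is.null(design$scaffold)) {
    ann <- design$scaffold$annotations
    L <- nchar(design$scaffold$sequence)
    if (any(ann$start < 1L | ann$end > L | ann$start > ann$end)) {
      note("scaffold_annotations", "annotation interval outside the scaffold")
    }
  }

  if (length(out) == 0L) {
    tibble::tibble(rule = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}
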