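# Domain types and low-level sequence utilities.
#
# Conventions used throughout the package:
#  * all coordinates are 1-based closed intervals;
#  * miRNAs are numbered 5'->3' (seed = positions 2-8);
#  * spacer positions are numbered PAM-proximal = 1, i.e. position p of a
#    spacer of length s is string index s + 1 - p (the PAM-proximal end of
#    the spacer abuts the scaffold);
#  * GU wobble counts as a pair, so a "mismatch" is a residue pair that is
#    neither Watson-Crick nor GU.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalise and validate an RNA sequence
#'
#' Uppercases, transcribes DNA input (T becomes U) and rejects any residue
#' outside A/C/G/U. Used on ingest by every function that accepts sequence
#' text, so protospacers may be supplied as DNA.
#'
#' @param x single character string.
#' @param what label used in error messages.
#' @return validated character scalar over A/C/G/U.
#' @export
as_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single character string", what))
  }
  x <- chartr("tu", "TU", toupper(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  if (nchar(x) < 1L) {
    abort(sprintf("%s must be non-empty", what))
  }
  bad <- setdiff(strsplit(x, "")[[1]], RNA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf("%s contains non-RNA characters: %s",
                  what, paste(unique(bad), collapse = ", ")))
  }
  x
}

rna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

rna_codes <- function(x) {
  match(rna_chars(x), RNA_ALPHABET) - 1L
}

#' Watson-Crick / wobble pairing predicate
#'
#' @param a,b single residues.
#' @param wobble logical; count GU as a pair (the default, matching the
#'   folding engine).
#' @return logical.
#' @export
pairs_with <- function(a, b, wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (!wobble) return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA (or DNA, transcribed on ingest) sequence.
#' @return character scalar; an involution.
#' @export
reverse_complement <- function(seq) {
  seq <- as_rna(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  paste(rev(rna_chars(comp)), collapse = "")
}

#' Replace one residue so that it can no longer pair its duplex partner
#'
#' Deterministic substitution: the first of A, C, G, U that neither
#' Watson-Crick pairs nor GU-wobbles with `opposite_base` and differs from
#' the current residue. (Preferring A, then C, avoids creating wobble pairs
#' that the folding engine would silently re-pair.)
#'
#' @param arm sequence carrying the position to disrupt.
#' @param position 1-based index into `arm`.
#' @param opposite_base the residue this position faces in the intended duplex.
#' @return modified `arm`.
#' @export
inject_mismatch <- function(arm, position, opposite_base) {
  arm <- as_rna(arm, "arm")
  opposite_base <- as_rna(opposite_base, "opposite_base")
  if (nchar(opposite_base) != 1L) abort("opposite_base must be one residue")
  n <- nchar(arm)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1L || position > n) {
    abort(sprintf("position %s is outside the arm (length %d)",
                  as.character(position), n))
  }
  chars <- rna_chars(arm)
  current <- chars[position]
  for (cand in RNA_ALPHABET) {
    if (cand != current && !pairs_with(cand, opposite_base)) {
      chars[position] <- cand
      return(paste(chars, collapse = ""))
    }
  }
  abort("no valid substitution exists") # unreachable: every base has one
}

#' Trigger miRNA
#'
#' @param sequence mature miRNA, 5'->3' (typically 21-23 nt).
#' @param name optional identifier.
#' @param seed_region positions of the seed (default 2-8).
#' @param scan_region initial AGO scanning positions (default 2-4); must lie
#'   inside the seed.
#' @return object of class `mir_mirna`.
#' @export
mirna <- function(sequence, name = NULL, seed_region = c(2L, 8L),
                  scan_region = c(2L, 4L)) {
  sequence <- as_rna(sequence, "miRNA sequence")
  n <- nchar(sequence)
  seed_region <- as.integer(seed_region)
  scan_region <- as.integer(scan_region)
  if (seed_region[1] < 1L || seed_region[2] > n || seed_region[1] > seed_region[2]) {
    abort("seed_region must lie within the miRNA")
  }
  if (scan_region[1] < seed_region[1] || scan_region[2] > seed_region[2]) {
    abort("scan_region must lie within the seed_region")
  }
  structure(
    list(sequence = sequence, name = name %||% "miRNA",
         seed_region = seed_region, scan_region = scan_region),
    class = "mir_mirna"
  )
}

#' @export
print.mir_mirna <- function(x, ...) {
  cat(sprintf("<miRNA %s> %s (%d nt, seed %d-%d)\n",
              x$name, x$sequence, nchar(x$sequence),
              x$seed_region[1], x$seed_region[2]))
  invisible(x)
}

#' Cas9 spacer (guide) sequence
#'
#' @param sequence spacer 5'->3' (DNA accepted; transcribed on ingest).
#'   Length 17-20 nt; 17 is the package default, 20 is used for e.g.
#'   dystrophin-targeting guides.
#' @param name optional identifier.
#' @return object of class `mir_spacer`. The guide seed is fixed to the 10
#'   PAM-proximal positions (positions 1-10 counting from the PAM).
#' @export
spacer_guide <- function(sequence, name = NULL) {
  sequence <- as_rna(sequence, "spacer sequence")
  n <- nchar(sequence)
  if (n < 17L || n > 20L) {
    abort(sprintf("spacer length must be 17-20 nt, got %d", n))
  }
  structure(
    list(sequence = sequence, name = name %||% "spacer",
         spacer_length = n, seed_interval = c(1L, 10L)),
    class = "mir_spacer"
  )
}

#' @export
print.mir_spacer <- function(x, ...) {
  cat(sprintf("<spacer %s> %s (%d nt)\n", x$name, x$sequence, x$spacer_length))
  invisible(x)
}

# ---------------------------------------------------------------------------
# scaffold

STANDARD_SCAFFOLD <-
  "GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGC"

# duplex extension used by the optimized backbone (5 bp inserted into the
# repeat:antirepeat stem, next to the tetraloop)
OPT_EXTENSION <- "ACGGC"

#' sgRNA scaffold (tracrRNA-fused backbone)
#'
#' The `standard` variant is the canonical SpCas9 single-guide scaffold. The
#' `optimized` variant is built from it by extending the repeat:antirepeat
#' duplex by 5 bp and interrupting the uracil run of the repeat with a single
#' U-to-C substitution (the Pol III anti-termination fix); both modifications
#' are applied programmatically so the relationship between the variants is
#' explicit.
#'
#' @param variant `"standard"` or `"optimized"`.
#' @return object of class `mir_scaffold` with fields `sequence`,
#'   `annotations` (tibble of named intervals) and `first_repeat_g` (always
#'   position 1: the repeat begins with the G that the shield also covers).
#' @export
scaffold <- function(variant = c("standard", "optimized")) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    seqs <- STANDARD_SCAFFOLD
    ann <- tibble::tribble(
      ~name,                      ~start, ~end,
      "repeat",                       1L,  12L,
      "tetraloop",                   13L,  16L,
      "antirepeat",                  17L,  34L,
      "repeat_antirepeat_duplex",     1L,  34L,
      "stem_loop1",                   1L,  34L,
      "stem_loop2",                  35L,  47L,
      "stem_loop3",                  48L,  76L
    )
  } else {
    ext <- OPT_EXTENSION
    rc_ext <- reverse_complement(ext)
    rep_std <- substr(STANDARD_SCAFFOLD, 1L, 12L)
    rep_fix <- fix_poly_u(rep_std)$sequence
    rest <- substr(STANDARD_SCAFFOLD, 17L, nchar(STANDARD_SCAFFOLD))
    seqs <- paste0(rep_fix, ext, "GAAA", rc_ext, rest)
    k <- nchar(ext)
    ann <- tibble::tribble(
      ~name,                      ~start,        ~end,
      "repeat",                       1L,  12L + k,
      "tetraloop",               13L + k,  16L + k,
      "antirepeat",              17L + k,  34L + 2L * k,
      "repeat_antirepeat_duplex",     1L,  34L + 2L * k,
      "stem_loop1",                   1L,  34L + 2L * k,
      "stem_loop2",        35L + 2L * k,  47L + 2L * k,
      "stem_loop3",        48L + 2L * k,  76L + 2L * k
    )
  }
  structure(
    list(variant = variant, sequence = seqs, annotations = ann,
         first_repeat_g = 1L),
    class = "mir_scaffold"
  )
}

#' @export
print.mir_scaffold <- function(x, ...) {
  cat(sprintf("<sgRNA scaffold, %s backbone, %d nt>\n%s\n",
              x$variant, nchar(x$sequence), x$sequence))
  invisible(x)
}

# ---------------------------------------------------------------------------
# binding-site / mismatch specifications

#' Binding-site specification
#'
#' @param mode `"full_length"` (complement of the whole miRNA; shield covers
#'   miRNA positions up to 16 at most) or `"seed_only"` (complement of the
#'   seed, closed by a GAAA tetraloop).
#' @param mismatch_positions miRNA positions (1-based, 5'->3') at which the
#'   binding site deliberately fails to pair the miRNA. The active default
#'   preset for full-length sites is positions 2, 9 and 17; the
#'   AGO-cleavage-ablating alternative is 10 and 11; seed-only sites default
#'   to a single mismatch at position 2.
#' @param covered_max furthest miRNA position the shield may reach in
#'   full-length mode (fixed at 16; distal positions form the hairpin loop).
#' @return object of class `mir_site_spec`.
#' @export
binding_site_spec <- function(mode = c("full_length", "seed_only"),
                              mismatch_positions = NULL,
                              covered_max = 16L) {
  mode <- match.arg(mode)
  if (is.null(mismatch_positions)) {
    mismatch_positions <- if (mode == "full_length") c(2L, 9L, 17L) else 2L
  }
  mismatch_positions <- sort(unique(as.integer(mismatch_positions)))
  if (mode == "full_length" && covered_max > 16L) {
    abort("shield coverage may not reach beyond miRNA position 16")
  }
  structure(
    list(mode = mode, mismatch_positions = mismatch_positions,
         covered_max = as.integer(covered_max)),
    class = "mir_site_spec"
  )
}

#' Mismatch pattern for a trigger hairpin
#'
#' Two independent layers of deliberate mismatches define a miR-guide:
#' site-layer mismatches (binding site vs. miRNA, e.g. the 2/9/17 preset)
#' and shield-layer mismatches (shield vs. the hairpin arm it covers), which
#' tune the trigger-hairpin free energy. Shield positions are indexed along
#' the covered arm, 5'->3': positions `1..n_site` face the proximal binding
#' site, the next `spacer_length` face the spacer, and the final position
#' faces the first repeat G.
#'
#' @param binding_site miRNA positions mismatched in the binding site.
#' @param shield_arm arm positions left unpaired by the shield.
#' @param window,max_per_window spacing rule: at most `max_per_window`
#'   mismatches in any sliding window of `window` designed pairs.
#' @return object of class `mir_pattern`.
#' @export
mismatch_pattern <- function(binding_site = c(2L, 9L, 17L),
                             shield_arm = integer(),
                             window = 4L, max_per_window = 3L) {
  structure(
    list(binding_site = sort(unique(as.integer(binding_site))),
         shield_arm = sort(unique(as.integer(shield_arm))),
         window = as.integer(window),
         max_per_window = as.integer(max_per_window)),
    class = "mir_pattern"
  )
}

#' Check the mismatch spacing rule on a set of arm positions
#'
#' The design grammar allows 1-3 mismatches every 2-4 nucleotides; the hard
#' constraint enforced here is that no window of `window` consecutive
#' designed pairs contains more than `max_per_window` mismatches.
#'
#' @param positions integer mismatch positions along the arm.
#' @param n_arm arm length.
#' @param window,max_per_window rule parameters.
#' @return logical scalar.
#' @export
spacing_rule_ok <- function(positions, n_arm, window = 4L, max_per_window = 3L) {
  if (length(positions) == 0L) return(TRUE)
  if (any(positions < 1L | positions > n_arm)) return(FALSE)
  ind <- integer(n_arm)
  ind[positions] <- 1L
  if (n_arm < window) return(sum(ind) <= max_per_window)
  runs <- stats::filter(ind, rep(1L, window), sides = 1)
  all(runs[window:n_arm] <= max_per_window)
}

#' Design constraints for a miR-guide
#'
#' @param dg_window target interval for the trigger-hairpin free energy, in
#'   kcal/mol (default centred on -15, the stability at which the reference
#'   designs switch best; more stable hairpins suppress activation).
#' @param pair_prob_target equilibrium probability each designed stem pair
#'   should have of being hybridised (default 0.90, the compromise between a
#'   leak-free OFF state and sensitivity to the trigger).
#' @param max_seed_duplex_run longest continuous duplex allowed over the
#'   spacer seed (PAM-proximal positions 1-10); default 6, the longest run
#'   that still activates.
#' @param architecture,scaffold_variant defaults for assemblers.
#' @param prob_threshold probability above which a position counts as paired.
#' @param off_paired_min,on_gain_min pass thresholds used by [switch_score()].
#' @return object of class `mir_constraints`.
#' @export
design_constraints <- function(dg_window = c(-18, -12),
                               pair_prob_target = 0.90,
                               max_seed_duplex_run = 6L,
                               architecture = "full_length_5prime_hairpin",
                               scaffold_variant = "standard",
                               prob_threshold = 0.5,
                               off_paired_min = 0.8,
                               on_gain_min = 0.05) {
  if (any(dg_window >= 0)) abort("dg_window bounds must be negative")
  if (pair_prob_target <= 0 || pair_prob_target >= 1) {
    abort("pair_prob_target must be in (0, 1)")
  }
  structure(
    list(dg_window = sort(as.numeric(dg_window)),
         pair_prob_target = pair_prob_target,
         max_seed_duplex_run = as.integer(max_seed_duplex_run),
         architecture = architecture,
         scaffold_variant = scaffold_variant,
         prob_threshold = prob_threshold,
         off_paired_min = off_paired_min,
         on_gain_min = on_gain_min),
    class = "mir_constraints"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
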