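# Single-strand RNA secondary-structure thermodynamics.
#
# All folding goes through the compiled nearest-neighbour engine in
# src/thermo.cpp. Sequences are encoded A=0, C=1, G=2, U=3; structures come
# back as dot-bracket strings plus a pair table (partner index per position,
# 0 = unpaired). Energies are kcal/mol at 37 degrees C.

#' Energy-model parameters
#'
#' @param temperature degrees Celsius; enters the Boltzmann factor of the
#'   partition function. The bundled parameter table is defined at 37.
#' @param salt mol/L monovalent cation. Informational only: 1 M Na+ is the
#'   reference condition of the parameter table and no salt correction is
#'   applied.
#' @param dangle_mode `"some"` (default; constant 5'/3' dangle contributions
#'   on helix ends in exterior and multiloops) or `"none"`.
#' @param min_loop minimum hairpin loop size in nucleotides (>= 3).
#' @param parameter_table identifier recorded in reports.
#' @return list of class `mir_energy_params`. Pseudoknots are always
#'   forbidden.
#' @export
energy_params <- function(temperature = 37, salt = 1.0,
                          dangle_mode = c("some", "none"),
                          min_loop = 3L,
                          parameter_table = "mirswitch-nn-1") {
  dangle_mode <- match.arg(dangle_mode)
  min_loop <- as.integer(min_loop)
  if (min_loop < 3L) abort("min_loop must be >= 3")
  structure(
    list(temperature = as.numeric(temperature), salt = as.numeric(salt),
         dangles = dangle_mode, min_loop = min_loop,
         parameter_table = parameter_table, pseudoknots = FALSE),
    class = "mir_energy_params"
  )
}

#' Cotranscriptional folding parameters
#'
#' The pairing reach of nascent transcripts is modelled by down-weighting
#' each pair (i,j) with gamma(d) = alpha * exp(-d / tau) + (1 - alpha),
#' d = j - i. `alpha = 0` recovers the equilibrium fold exactly.
#'
#' @param alpha in `[0, 1]`; default 0.5.
#' @param tau length scale in nucleotides; default 640.
#' @export
cofold_params <- function(alpha = 0.5, tau = 640) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (tau <= 0) abort("tau must be positive")
  structure(list(alpha = as.numeric(alpha), tau = as.numeric(tau)),
            class = "mir_cofold_params")
}

cpp_par <- function(params, alpha = 0, tau = 640) {
  list(min_loop = params$min_loop, dangles = params$dangles,
       temperature = params$temperature, alpha = alpha, tau = tau)
}

constraint_vectors <- function(n, unpaired = integer(), paired = integer()) {
  if (length(intersect(unpaired, paired)) > 0L) {
    abort("contradictory constraints: positions both forced paired and unpaired")
  }
  if (length(unpaired) && any(unpaired < 1L | unpaired > n)) {
    abort("forced-unpaired positions outside the sequence")
  }
  if (length(paired) && any(paired < 1L | paired > n)) {
    abort("forced-paired positions outside the sequence")
  }
  fu <- logical(n); fu[unpaired] <- TRUE
  fp <- logical(n); fp[paired] <- TRUE
  list(fu = fu, fp = fp)
}

new_structure <- function(seq, res, params, method = "mfe") {
  pt <- res$pairs
  idx <- which(pt > seq_len(length(pt)))
  structure(
    list(sequence = seq,
         dot_bracket = res$dot_bracket,
         pairs = tibble::tibble(i = idx, j = pt[idx]),
         pair_table = pt,
         delta_g = res$energy,
         method = method,
         parameter_table = params$parameter_table),
    class = "mir_structure"
  )
}

#' @export
print.mir_structure <- function(x, ...) {
  cat(sprintf("<RNA structure, %s, dG = %.2f kcal/mol>\n%s\n%s\n",
              x$method, x$delta_g, x$sequence, x$dot_bracket))
  invisible(x)
}

#' Minimum-free-energy fold
#'
#' Zuker-style dynamic programming over hairpin, stack, bulge, internal and
#' multibranch loops with deterministic (5'-most) traceback.
#'
#' @param seq RNA sequence (DNA accepted and transcribed).
#' @param params [energy_params()].
#' @return `mir_structure`: dot-bracket, pair list and free energy
#'   (kcal/mol; an open chain scores 0).
#' @export
fold_mfe <- function(seq, params = energy_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  cv <- constraint_vectors(n)
  res <- rsw_fold(rna_codes(seq), cpp_par(params), cv$fu, cv$fp)
  new_structure(seq, res, params, "mfe")
}

#' MFE fold under per-position constraints
#'
#' @param seq sequence.
#' @param params [energy_params()].
#' @param forced_unpaired positions that may not pair.
#' @param forced_paired positions that must pair (with anyone).
#' @return `mir_structure`. With empty constraints this is identical to
#'   [fold_mfe()].
#' @export
constrained_fold <- function(seq, params = energy_params(),
                             forced_unpaired = integer(),
                             forced_paired = integer()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  cv <- constraint_vectors(n, forced_unpaired, forced_paired)
  res <- rsw_fold(rna_codes(seq), cpp_par(params), cv$fu, cv$fp)
  new_structure(seq, res, params, "constrained_mfe")
}

#' Cotranscriptional (distance-scaled) MFE fold
#'
#' @param seq sequence.
#' @param params [energy_params()].
#' @param cofold [cofold_params()]. With `alpha = 0` the result equals
#'   [fold_mfe()] bitwise.
#' @return `mir_structure`; `delta_g` is the scaled objective.
#' @export
cofold_mfe <- function(seq, params = energy_params(), cofold = cofold_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  cv <- constraint_vectors(n)
  res <- rsw_fold(rna_codes(seq), cpp_par(params, cofold$alpha, cofold$tau),
                  cv$fu, cv$fp)
  new_structure(seq, res, params, "cofold_mfe")
}

#' Free energy of an explicit structure
#'
#' Scores a dot-bracket (or pair-table) structure by loop decomposition with
#' the same parameter table as the folding engine; the open chain scores 0.
#' Interior/bulge loops above the engine's 30-nt cap are outside the model
#' and return `NA`.
#'
#' @param seq sequence.
#' @param structure dot-bracket string or integer pair table.
#' @param params [energy_params()].
#' @param cofold optional [cofold_params()] to score under distance scaling.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure, params = energy_params(),
                             cofold = NULL) {
  seq <- as_rna(seq)
  pt <- if (is.character(structure)) parse_dot_bracket(structure) else as.integer(structure)
  if (length(pt) != nchar(seq)) abort("structure length does not match sequence")
  alpha <- if (is.null(cofold)) 0 else cofold$alpha
  tau <- if (is.null(cofold)) 640 else cofold$tau
  rsw_energy(rna_codes(seq), pt, cpp_par(params, alpha, tau))
}

#' Exhaustively enumerate all nested structures of a short sequence
#'
#' Brute-force oracle used to validate the dynamic programming: every nested
#' structure respecting the minimum loop size, scored by the same parameter
#' table.
#'
#' @param seq sequence of length at most `max_n`.
#' @param params [energy_params()].
#' @param max_n length cap (default 22).
#' @param forced_unpaired,forced_paired optional constraints.
#' @param cap safety cap on the number of structures.
#' @return tibble with `dot_bracket` and `energy` columns.
#' @export
enumerate_structures <- function(seq, params = energy_params(), max_n = 22L,
                                 forced_unpaired = integer(),
                                 forced_paired = integer(),
                                 cap = 5e6) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n > max_n) {
    abort(sprintf("sequence length %d exceeds the enumeration cap %d", n, max_n))
  }
  cv <- constraint_vectors(n, forced_unpaired, forced_paired)
  res <- rsw_enumerate(rna_codes(seq), cpp_par(params), cv$fu, cv$fp,
                       as.integer(cap))
  tibble::tibble(dot_bracket = res$dot_bracket, energy = res$energy)
}

#' Partition function and base-pair probabilities
#'
#' McCaskill inside-outside dynamic programming over the same energy model
#' as [fold_mfe()]. Arrays are rescaled per-nucleotide so the computation is
#' overflow-safe for sequences up to at least 200 nt.
#'
#' @param seq sequence.
#' @param params [energy_params()].
#' @param forced_unpaired,forced_paired optional constraints (the ensemble is
#'   then restricted to satisfying structures).
#' @param bpp compute the base-pair probability matrix (default TRUE).
#' @return object of class `mir_ensemble`: `ensemble_energy` (-RT ln Z,
#'   kcal/mol), `lnZ`, `mfe`, `bpp` (symmetric matrix), `p_unpaired`, and
#'   `p_paired` per position.
#' @export
partition_function <- function(seq, params = energy_params(),
                               forced_unpaired = integer(),
                               forced_paired = integer(),
                               bpp = TRUE) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  cv <- constraint_vectors(n, forced_unpaired, forced_paired)
  res <- rsw_partition(rna_codes(seq), cpp_par(params), cv$fu, cv$fp, bpp)
  out <- list(sequence = seq,
              ensemble_energy = res$ensemble_energy,
              lnZ = res$lnZ,
              mfe = res$mfe,
              parameter_table = params$parameter_table)
  if (bpp) {
    out$bpp <- res$bpp
    out$p_paired <- rowSums(res$bpp)
    out$p_unpaired <- 1 - out$p_paired
  }
  structure(out, class = "mir_ensemble")
}

#' @export
print.mir_ensemble <- function(x, ...) {
  cat(sprintf("<RNA ensemble, %d nt, G = %.2f kcal/mol (MFE %.2f)>\n",
              nchar(x$sequence), x$ensemble_energy, x$mfe))
  invisible(x)
}

# ---------------------------------------------------------------------------
# dot-bracket utilities

#' Parse a dot-bracket string into a pair table
#'
#' @param db dot-bracket string (characters `.`, `(`, `)`).
#' @return integer vector: partner index per position, 0 if unpaired.
#' @export
parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    abort("dot-bracket may only contain '.', '(' and ')'")
  }
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) abort("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0L) abort("unbalanced dot-bracket")
  pt
}

#' Longest paired run within a set of positions
#'
#' Length of the longest stretch of consecutive positions in `positions`
#' that are all paired in `structure` to consecutive partners (a continuous
#' duplex).
#'
#' @param structure `mir_structure` or pair table.
#' @param positions positions to scan (need not be contiguous overall).
#' @return integer.
#' @export
longest_duplex_run <- function(structure, positions) {
  pt <- if (inherits(structure, "mir_structure")) structure$pair_table else as.integer(structure)
  positions <- sort(positions)
  best <- 0L; run <- 0L
  prev_pos <- NA_integer_; prev_partner <- NA_integer_
  for (p in positions) {
    contiguous <- !is.na(prev_pos) && p == prev_pos + 1L &&
      pt[p] != 0L && prev_partner != 0L && pt[p] == prev_partner - 1L
    run <- if (pt[p] == 0L) 0L else if (contiguous) run + 1L else 1L
    best <- max(best, run)
    prev_pos <- p
    prev_partner <- pt[p]
  }
  best
}

#' Write a connectivity-table (.ct) file for a folded structure
#'
#' @param structure `mir_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ct <- function(structure, path) {
  n <- nchar(structure$sequence)
  chars <- rna_chars(structure$sequence)
  pt <- structure$pair_table
  lines <- c(sprintf("%d dG = %.2f", n, structure$delta_g),
             sprintf("%d %s %d %d %d %d",
                     seq_len(n), chars, seq_len(n) - 1L,
                     c(seq_len(n - 1L) + 1L, 0L), pt, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.mir_structure <- function(x, ...) {
  x$pairs
}

#' @export
glance.mir_structure <- function(x, ...) {
  tibble::tibble(length = nchar(x$sequence),
                 n_pairs = nrow(x$pairs),
                 delta_g = x$delta_g,
                 method = x$method,
                 parameter_table = x$parameter_table)
}

#' @export
tidy.mir_ensemble <- function(x, ...) {
  if (is.null(x$bpp)) abort("ensemble was computed without base-pair probabilities")
  idx <- which(upper.tri(x$bpp) & x$bpp > 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 probability = x$bpp[idx])
}

#' @export
glance.mir_ensemble <- function(x, ...) {
  tibble::tibble(length = nchar(x$sequence),
                 ensemble_energy = x$ensemble_energy,
                 mfe = x$mfe,
                 parameter_table = x$parameter_table)
}
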