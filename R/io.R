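# File I/O, bundled catalogue, synthetic fixtures and the frameshift
# reporter simulator.

#' Read miRNA/spacer records from FASTA or TSV
#'
#' FASTA is parsed with Biostrings; a TSV must have columns `name` and
#' `sequence`. Sequences are uppercased, DNA is transcribed, duplicate
#' names and non-ACGU residues are rejected.
#'
#' @param path input file.
#' @return tibble with `name` and `sequence`.
#' @export
read_inputs <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, ">")) {
    set <- Biostrings::readBStringSet(path)
    recs <- tibble::tibble(name = names(set),
                           sequence = unname(as.character(set)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "sequence") %in% names(df))) {
      abort("TSV input needs 'name' and 'sequence' columns")
    }
    recs <- tibble::as_tibble(df[, c("name", "sequence")])
  }
  if (anyDuplicated(recs$name)) {
    abort(sprintf("duplicate record names: %s",
                  paste(unique(recs$name[duplicated(recs$name)]), collapse = ", ")))
  }
  recs$sequence <- vapply(seq_len(nrow(recs)), function(i) {
    as_rna(recs$sequence[i], sprintf("record '%s'", recs$name[i]))
  }, character(1))
  recs
}

#' Bundled catalogue of trigger miRNAs
#'
#' Mature miRNA sequences for the triggers discussed throughout the
#' package's documentation (miR-17-5p, miR-16-5p, miR-21-5p, miR-18a-5p,
#' miR-20a-5p, miR-106a-5p, let-7a-5p, miR-206-3p, miR-1a-3p, miR-122-5p,
#' miR-10a-5p), transcribed from the public miRNA registry. miR-206-3p and
#' miR-1a-3p share a seed, a useful specificity edge case.
#'
#' @return tibble with `name` and `sequence`.
#' @export
mirna_catalogue <- function() {
  path <- system.file("extdata", "mirna_catalogue.fa", package = "mirswitch")
  read_inputs(path)
}

#' Fetch one catalogue miRNA as a [mirna()] object
#'
#' @param name catalogue entry, e.g. `"miR-17-5p"`.
#' @export
catalogue_mirna <- function(name) {
  cat <- mirna_catalogue()
  row <- cat[cat$name == name, ]
  if (nrow(row) != 1L) {
    abort(sprintf("'%s' is not in the catalogue (%s)", name,
                  paste(cat$name, collapse = ", ")))
  }
  mirna(row$sequence, name = row$name)
}

#' Demonstration spacer
#'
#' A fixed synthetic 17-nt protospacer (47% GC, no self-complementarity)
#' used by the examples, the acceptance script and the vignettes so that
#' every reported number is reproducible.
#'
#' @return `mir_spacer`.
#' @export
example_spacer <- function() {
  spacer_guide("GACCUGAGUCAUGCUAA", name = "demo-spacer")
}

#' Write FASTA + TSV + JSON design reports
#'
#' @param designs list of `mir_guide`.
#' @param reports matching list of `mir_switch_report` (optional).
#' @param dir output directory (created if missing).
#' @param stem file stem (default "designs").
#' @return named character vector of the files written. Floats are written
#'   with fixed precision and keys sorted so outputs are byte-stable.
#' @export
write_design_report <- function(designs, reports = NULL, dir = ".",
                                stem = "designs") {
  if (!is.null(reports) && length(reports) != length(designs)) {
    abort("designs and reports must have the same length")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fa"))
  db_path <- file.path(dir, paste0(stem, ".db"))
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  js <- file.path(dir, paste0(stem, ".json"))

  nm <- purrr::imap_chr(designs, function(d, i) {
    sprintf("%s_%s_%d", d$architecture,
            if (is.null(d$mirna)) "none" else d$mirna$name, i)
  })
  fa_lines <- unlist(purrr::map2(nm, designs, function(n, d) {
    c(paste0(">", n), d$full_sequence)
  }))
  writeLines(as.character(fa_lines %||% character()), fa)
  db_lines <- unlist(purrr::map2(nm, designs, function(n, d) {
    s <- fold_mfe(d$full_sequence)
    c(paste0(">", n), d$full_sequence,
      sprintf("%s (%.2f)", s$dot_bracket, s$delta_g))
  }))
  writeLines(as.character(db_lines %||% character()), db_path)

  empty_row <- tibble::tibble(
    name = character(), architecture = character(), mirna = character(),
    length = integer(), trigger_dg = numeric(),
    off_spacer_paired_fraction = numeric(), on_gain = numeric(),
    median_pair_probability = numeric(), pass = logical()
  )
  rows <- purrr::map(seq_along(designs), function(i) {
    d <- designs[[i]]
    r <- if (is.null(reports)) NULL else reports[[i]]
    tibble::tibble(
      name = nm[i],
      architecture = d$architecture,
      mirna = if (is.null(d$mirna)) NA_character_ else d$mirna$name,
      length = nchar(d$full_sequence),
      trigger_dg = if (is.null(r)) NA_real_ else round(r$trigger_dg, 2),
      off_spacer_paired_fraction =
        if (is.null(r)) NA_real_ else round(r$off_spacer_paired_fraction, 3),
      on_gain = if (is.null(r)) NA_real_ else round(r$on_gain, 3),
      median_pair_probability = if (is.null(r)) NA_real_ else
        round(stats::median(r$stem_pair_probabilities$probability), 3),
      pass = if (is.null(r)) NA else switch_score(r)$pass
    )
  })
  tab <- dplyr::bind_rows(c(list(empty_row), rows))
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(reports)) {
    payload <- purrr::map(seq_along(reports), function(i) {
      r <- reports[[i]]
      list(name = nm[i],
           architecture = designs[[i]]$architecture,
           off_spacer_paired_fraction = round(r$off_spacer_paired_fraction, 4),
           on_spacer_accessible_fraction = round(r$on_spacer_accessible_fraction, 4),
           on_gain = round(r$on_gain, 4),
           seed_invasion_cost = round(r$seed_invasion_cost, 4),
           displacement_dg = round(r$displacement_dg, 4),
           displacement_favorable = r$displacement_favorable,
           pathway_robust = r$pathway_robust,
           trigger_dg = round(r$trigger_dg, 4),
           seed_duplex_run = r$seed_duplex_run)
    })
    names(payload) <- nm
    jsonlite::write_json(payload, js, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(stats::setNames(list(), character()), js)
  }
  c(fasta = fa, dot_bracket = db_path, tsv = tsv, json = js)
}

# ---------------------------------------------------------------------------
# synthetic fixtures

random_rna <- function(len, gc = c(0.3, 0.7)) {
  repeat {
    s <- paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = "")
    frac <- sum(rna_chars(s) %in% c("G", "C")) / len
    if (frac >= gc[1] && frac <= gc[2]) return(s)
  }
}

#' Generate a synthetic (miRNA, spacer) test panel
#'
#' Seeded generation of 21-23 nt miRNAs and 17-nt spacers with 30-70% GC.
#' The panel always contains adversarial cases: a self-complementary
#' spacer, a spacer with a long U run, and a pair of distinct miRNAs that
#' share an identical seed (mirroring the miR-206-3p / miR-1a-3p
#' situation).
#'
#' @param n number of regular panel rows (>= 1) in addition to the
#'   adversarial ones.
#' @param seed RNG seed.
#' @return tibble with `name`, `mirna`, `spacer`, `case`.
#' @export
generate_fixtures <- function(n = 6L, seed = 1L) {
  if (n < 1L) abort("n must be >= 1")
  withr::with_seed(seed, {
    regular <- purrr::map(seq_len(n), function(i) {
      tibble::tibble(name = sprintf("syn%02d", i),
                     mirna = random_rna(sample(21:23, 1)),
                     spacer = random_rna(17L),
                     case = "regular")
    })
    half <- random_rna(7L)
    selfc <- paste0(half, "AUG", reverse_complement(half))
    mir_a <- random_rna(22L)
    seed7 <- substr(mir_a, 2L, 8L)
    mir_b <- paste0(substr(random_rna(22L), 1L, 1L), seed7,
                    substr(random_rna(22L), 9L, 22L))
    adversarial <- tibble::tibble(
      name = c("selfcomp_spacer", "urun_spacer", "shared_seed_a", "shared_seed_b"),
      mirna = c(random_rna(22L), random_rna(22L), mir_a, mir_b),
      spacer = c(selfc, "GACUUUUUUCAUGCAGA", random_rna(17L), random_rna(17L)),
      case = c("self_complementary", "u_run", "shared_seed", "shared_seed")
    )
    dplyr::bind_rows(c(regular, list(adversarial)))
  })
}

# ---------------------------------------------------------------------------
# Stoplight reporter simulator

#' Simulate the frameshift (Stoplight-style) reporter
#'
#' The reporter carries two out-of-frame fluorescent ORFs downstream of the
#' cut site, at net frame shifts +1 and +2; an INDEL activates the reporter
#' iff its net shift modulo 3 is nonzero. With INDEL sizes uniform on
#' -9..9 excluding 0, two-thirds of repair events activate.
#'
#' @param n_events number of simulated repair events.
#' @param sizes support of the INDEL size distribution (no zeros).
#' @param prob optional probabilities over `sizes`.
#' @param seed RNG seed.
#' @param conf confidence level of the binomial interval.
#' @return list with `fraction`, `ci` (two-sided), `n_events`, `expected`
#'   (the exact frame-rule expectation over the support).
#' @export
simulate_stoplight <- function(n_events = 1e5, sizes = c(-9:-1, 1:9),
                               prob = NULL, seed = 1L, conf = 0.99) {
  if (n_events < 1L) abort("n_events must be >= 1")
  if (any(sizes == 0L) && (is.null(prob) || any(prob[sizes == 0L] > 0))) {
    abort("INDEL size 0 is not a repair event; remove it from the support")
  }
  activates <- function(sz) (sz %% 3L) != 0L
  p <- prob %||% rep(1 / length(sizes), length(sizes))
  expected <- sum(p[activates(sizes)])
  withr::with_seed(seed, {
    draws <- sample(sizes, n_events, replace = TRUE, prob = prob)
    hits <- sum(activates(draws))
  })
  ci <- stats::binom.test(hits, n_events, conf.level = conf)$conf.int
  list(fraction = hits / n_events, ci = as.numeric(ci),
       n_events = as.integer(n_events), expected = expected)
}
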