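# Shared fixtures, built in code and cached so expensive designs are
# assembled once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

mir17 <- function() cached("mir17", catalogue_mirna("miR-17-5p"))
mir16 <- function() cached("mir16", catalogue_mirna("miR-16-5p"))
demo_spacer <- function() cached("spc", example_spacer())

base_design <- function() {
  cached("base_design", assemble_full_length(mir17(), demo_spacer()))
}
seed_only_design <- function() {
  cached("seed_only", assemble_seed_only(mir17(), demo_spacer()))
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# independent recursion for the number of nested structures with a minimum
# loop size (used as the combinatorial oracle for enumerate_structures)
count_structures <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ok <- function(a, b) {
    pairs_with(chars[a], chars[b])
  }
  memo <- array(NA_real_, dim = c(n + 2L, n + 2L))
  cnt <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    total <- cnt(i + 1L, j)                   # i unpaired
    ks <- if (i + min_loop + 1L <= j) (i + min_loop + 1L):j else integer()
    for (k in ks) {
      if (ok(i, k)) total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[i, j] <<- total
    total
  }
  cnt(1L, n)
}

# exhaustive Boltzmann sums from an enumeration, for partition-function checks
boltzmann_reference <- function(seq, params = energy_params()) {
  en <- enumerate_structures(seq, params)
  rt <- 1.98717e-3 * (273.15 + params$temperature)
  w <- exp(-en$energy / rt)
  n <- nchar(seq)
  bpp <- matrix(0, n, n)
  for (m in seq_len(nrow(en))) {
    pt <- parse_dot_bracket(en$dot_bracket[m])
    idx <- which(pt > seq_len(n))
    for (i in idx) {
      bpp[i, pt[i]] <- bpp[i, pt[i]] + w[m]
      bpp[pt[i], i] <- bpp[pt[i], i] + w[m]
    }
  }
  list(Z = sum(w), bpp = bpp / sum(w), min_energy = min(en$energy))
}
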