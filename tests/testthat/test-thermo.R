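# The folding engine against its exhaustive oracle and closed-form cases.

test_that("sequences too short to pair fold open with zero energy", {
  st <- fold_mfe("ACGUA")
  expect_equal(st$dot_bracket, ".....")
  expect_equal(st$delta_g, 0)
  expect_equal(nrow(st$pairs), 0L)
  # poly-A: a single structure, Z = 1, no pair probabilities
  pf <- partition_function("AAAAAAAAAA")
  expect_equal(pf$lnZ, 0)
  expect_true(all(pf$bpp == 0))
  en <- enumerate_structures("AAAA")
  expect_equal(nrow(en), 1L)
})

test_that("enumeration produces every nested structure", {
  en <- enumerate_structures("GCGCAAAAGCGC")
  expect_true("((((....))))" %in% en$dot_bracket)
  expect_false(anyDuplicated(en$dot_bracket) > 0)
  set.seed(23)
  for (k in 1:20) {
    s <- rand_rna(12)
    en <- enumerate_structures(s)
    expect_equal(nrow(en), count_structures(s))
  }
  expect_error(enumerate_structures(rand_rna(30)), "cap")
})

test_that("a single hairpin's energy equals the hand-summed table entries", {
  # ((((....)))) on GGGGAAAACCCC: three GC-on-GC stacks at -3.30 each plus
  # the size-4 hairpin initiation of +5.60; no terminal AU, no dangles apply
  e <- structure_energy("GGGGAAAACCCC", "((((....))))")
  expect_equal(e, 3 * (-3.30) + 5.60, tolerance = 1e-9)
  # open chain scores zero
  expect_equal(structure_energy("GGGGAAAACCCC", "............"), 0)
  expect_error(structure_energy("GGGG", "(..)"), "minimum loop")
})

test_that("energy is additive over independent exterior substructures", {
  p <- energy_params(dangle_mode = "none")  # dangles couple neighbours
  h1 <- "GGGGAAAACCCC"; h2 <- "GCGCUUUUGCGC"
  db1 <- "((((....))))"; db2 <- "((((....))))"
  joint <- paste0(h1, "AAAA", h2)
  dbj <- paste0(db1, "....", db2)
  expect_equal(structure_energy(joint, dbj, p),
               structure_energy(h1, db1, p) + structure_energy(h2, db2, p),
               tolerance = 1e-9)
})

test_that("MFE and partition function match the exhaustive oracle", {
  set.seed(31)
  for (dm in c("some", "none")) {
    p <- energy_params(dangle_mode = dm)
    for (k in 1:40) {
      s <- rand_rna(sample(8:16, 1))
      ref <- boltzmann_reference(s, p)
      st <- fold_mfe(s, p)
      expect_equal(st$delta_g, ref$min_energy, tolerance = 1e-9)
      expect_equal(structure_energy(s, st$dot_bracket, p), st$delta_g,
                   tolerance = 1e-9)
      pf <- partition_function(s, p)
      expect_equal(exp(pf$lnZ), ref$Z, tolerance = 1e-8)
      expect_lt(max(abs(pf$bpp - ref$bpp)), 1e-8)
    }
  }
})

test_that("pair probabilities conserve and stay in [0, 1]", {
  set.seed(37)
  for (k in 1:5) {
    s <- rand_rna(60)
    pf <- partition_function(s)
    expect_true(all(pf$bpp >= 0 & pf$bpp <= 1))
    expect_identical(pf$bpp, t(pf$bpp))
    expect_true(all(abs(pf$p_paired + pf$p_unpaired - 1) < 1e-9))
    expect_true(all(pf$p_paired <= 1 + 1e-9))
    # ensemble free energy lies at or below the MFE weight alone
    expect_lte(pf$ensemble_energy, pf$mfe + 1e-9)
  }
})

test_that("constrained folding equals the restricted exhaustive minimum", {
  set.seed(41)
  for (k in 1:15) {
    s <- rand_rna(sample(10:14, 1))
    n <- nchar(s)
    fu <- sample(n, 2)
    en <- enumerate_structures(s, forced_unpaired = fu)
    st <- constrained_fold(s, forced_unpaired = fu)
    expect_equal(st$delta_g, min(en$energy), tolerance = 1e-9)
    expect_true(all(st$pair_table[fu] == 0L))
  }
  # all positions forced unpaired -> open chain at zero
  s <- rand_rna(12)
  st <- constrained_fold(s, forced_unpaired = 1:12)
  expect_equal(st$delta_g, 0)
  expect_equal(st$dot_bracket, strrep(".", 12))
  # no constraints -> identical to fold_mfe
  expect_identical(constrained_fold(s)$dot_bracket, fold_mfe(s)$dot_bracket)
  expect_error(constrained_fold(s, forced_unpaired = 1, forced_paired = 1),
               "contradictory")
})

test_that("cotranscriptional folding collapses to equilibrium at alpha 0", {
  set.seed(43)
  for (k in 1:20) {
    s <- rand_rna(sample(10:40, 1))
    eq <- fold_mfe(s)
    co <- cofold_mfe(s, cofold = cofold_params(alpha = 0))
    expect_identical(eq$dot_bracket, co$dot_bracket)
    expect_identical(eq$delta_g, co$delta_g)
  }
})

test_that("cofold MFE matches enumeration scored under distance scaling", {
  set.seed(47)
  cf <- cofold_params(alpha = 0.5, tau = 10)
  for (k in 1:10) {
    s <- rand_rna(12)
    en <- enumerate_structures(s)
    scaled <- vapply(en$dot_bracket,
                     function(db) structure_energy(s, db, cofold = cf), 0)
    co <- cofold_mfe(s, cofold = cf)
    expect_equal(co$delta_g, min(scaled), tolerance = 1e-9)
  }
})

test_that("a strong long-range alternative breaks pathway equivalence", {
  # long-range 6-bp duplex (equilibrium winner) vs a short-range 4-bp stem;
  # with a short persistence length the short-range structure wins
  s <- paste0("GGGGGG", strrep("A", 12), "GGGG", "AAAA", "CCCCCC")
  eq <- fold_mfe(s)
  co <- cofold_mfe(s, cofold = cofold_params(alpha = 1, tau = 8))
  expect_false(identical(eq$dot_bracket, co$dot_bracket))
  expect_false(pathway_robustness(s, cofold = cofold_params(alpha = 1, tau = 8)))
  # very large tau approaches a uniform rescaling: the two-candidate toy
  # keeps its equilibrium MFE structure
  co2 <- cofold_mfe(s, cofold = cofold_params(alpha = 0.5, tau = 1e7))
  expect_identical(eq$dot_bracket, co2$dot_bracket)
})

test_that("extending a stack never raises the MFE", {
  for (k in 3:8) {
    inner <- fold_mfe(paste0(strrep("G", k), "AAAA", strrep("C", k)))$delta_g
    outer <- fold_mfe(paste0(strrep("G", k + 1), "AAAA", strrep("C", k + 1)))$delta_g
    expect_lte(outer, inner)
  }
})

test_that("folding is bitwise deterministic", {
  set.seed(53)
  s <- rand_rna(80)
  a <- fold_mfe(s); b <- fold_mfe(s)
  expect_identical(a$dot_bracket, b$dot_bracket)
  expect_identical(a$delta_g, b$delta_g)
  pa <- partition_function(s); pb <- partition_function(s)
  expect_identical(pa$bpp, pb$bpp)
})

test_that("dot-bracket round trips and the ct writer emits valid rows", {
  db <- "((..((...))..))"
  pt <- parse_dot_bracket(db)
  expect_equal(pt[1], 15L)
  expect_equal(pt[5], 11L)
  expect_error(parse_dot_bracket("(("), "unbalanced")
  expect_error(parse_dot_bracket("..x"), "may only contain")
  st <- fold_mfe("GGGGAAAACCCC")
  path <- withr::local_tempfile(fileext = ".ct")
  write_ct(st, path)
  lines <- readLines(path)
  expect_length(lines, 13L)
  expect_match(lines[1], "dG")
})

test_that("longest duplex run detects continuous helices only", {
  #  positions 1..4 pair 12..9 consecutively
  pt <- parse_dot_bracket("((((....))))")
  expect_equal(longest_duplex_run(pt, 1:4), 4L)
  expect_equal(longest_duplex_run(pt, c(1, 2, 4)), 2L)
  expect_equal(longest_duplex_run(pt, 5:8), 0L)
})
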