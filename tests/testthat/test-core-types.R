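test_that("sequence ingest normalises, transcribes and rejects bad residues", {
  expect_equal(as_rna("acgu"), "ACGU")
  expect_equal(as_rna("ACGT"), "ACGU")   # DNA transcribed on ingest
  expect_error(as_rna(""), "non-empty")
  expect_error(as_rna("ACGN"), "non-RNA")
  expect_error(as_rna(c("A", "C")), "single character")
})

test_that("reverse complement is a Watson-Crick involution", {
  expect_equal(reverse_complement("AUGC"), "GCAU")
  expect_error(reverse_complement(""), "non-empty")
  set.seed(101)
  for (k in 1:25) {
    x <- rand_rna(sample(5:40, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
    # every position complements its mirror
    rc <- strsplit(reverse_complement(x), "")[[1]]
    xs <- strsplit(x, "")[[1]]
    expect_true(all(pairs_with(xs, rev(rc), wobble = FALSE)))
  }
})

test_that("mismatch injection destroys pairing without creating wobbles", {
  # C facing G: A is the first candidate that neither pairs nor wobbles
  expect_equal(inject_mismatch("ACGU", 2, "G"), "AAGU")
  expect_error(inject_mismatch("ACGU", 9, "G"), "outside")
  # exhaustive destruction: injecting at all positions of a 10-nt arm leaves
  # nothing paired against its former complement
  arm <- "GAUCCGAUGC"
  partner <- strsplit(reverse_complement(arm), "")[[1]]
  out <- arm
  for (p in 1:10) out <- inject_mismatch(out, p, rev(partner)[p])
  oc <- strsplit(out, "")[[1]]
  expect_false(any(pairs_with(oc, rev(partner))))
  # changed exactly one residue per call, and the predicate agrees
  set.seed(7)
  for (k in 1:30) {
    a <- rand_rna(12); p <- sample(12, 1); opp <- rand_rna(1)
    b <- inject_mismatch(a, p, opp)
    diff <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_identical(diff, p)
    expect_false(pairs_with(substr(b, p, p), opp))
  }
})

test_that("miRNA and spacer constructors enforce their invariants", {
  m <- mirna("CAAAGUGCUUACAGUGCAGGUAG", "miR-17-5p")
  expect_equal(m$seed_region, c(2L, 8L))
  expect_error(mirna("ACGU", seed_region = c(2, 8)), "seed_region")
  expect_error(mirna("CAAAGUGCUUACAGUGCAGGUAG", scan_region = c(1, 4)),
               "scan_region")
  expect_error(spacer_guide("ACGUACGUACGU"), "17-20")
  s <- spacer_guide("GACCUGAGUCAUGCUAA")
  expect_equal(s$spacer_length, 17L)
  expect_equal(s$seed_interval, c(1L, 10L))
})

test_that("scaffold variants differ by duplex extension plus one U->C", {
  std <- scaffold("standard")
  opt <- scaffold("optimized")
  expect_equal(nchar(std$sequence), 76L)
  expect_identical(std$first_repeat_g, 1L)
  expect_true(all(std$annotations$end <= nchar(std$sequence)))
  expect_true(all(opt$annotations$end <= nchar(opt$sequence)))
  # the optimized repeat is the standard repeat with exactly one U->C inside
  # the uracil run, and the duplex gains the extension on both strands
  std_rep <- substr(std$sequence, 1, 12)
  opt_rep12 <- substr(opt$sequence, 1, 12)
  diffs <- which(strsplit(std_rep, "")[[1]] != strsplit(opt_rep12, "")[[1]])
  expect_length(diffs, 1L)
  expect_equal(substr(std_rep, diffs, diffs), "U")
  expect_equal(substr(opt_rep12, diffs, diffs), "C")
  ext <- substr(opt$sequence, 13, 17)
  expect_identical(reverse_complement(ext),
                   substr(opt$sequence, 22, 26))
  # tetraloop annotation still reads GAAA in both variants
  for (sc in list(std, opt)) {
    tl <- sc$annotations[sc$annotations$name == "tetraloop", ]
    expect_identical(substr(sc$sequence, tl$start, tl$end), "GAAA")
  }
})

test_that("the mismatch spacing rule matches a direct window count", {
  expect_true(spacing_rule_ok(c(2, 9, 17), 34))
  expect_false(spacing_rule_ok(1:4, 4))
  expect_true(spacing_rule_ok(c(1, 2, 3), 4))
  set.seed(13)
  for (k in 1:50) {
    n <- sample(6:20, 1)
    pos <- sort(sample(n, sample(0:n, 1)))
    direct <- TRUE
    if (n >= 4) {
      for (w in 1:(n - 3)) {
        if (sum(pos >= w & pos <= w + 3) > 3) direct <- FALSE
      }
    } else direct <- length(pos) <= 3
    expect_identical(spacing_rule_ok(pos, n), direct)
  }
})

test_that("design constraints validate their fields", {
  expect_error(design_constraints(dg_window = c(-5, 5)), "negative")
  expect_error(design_constraints(pair_prob_target = 1.2), "\\(0, 1\\)")
  dc <- design_constraints()
  expect_equal(dc$max_seed_duplex_run, 6L)
  expect_equal(dc$pair_prob_target, 0.9)
})
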