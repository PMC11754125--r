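# The design grammar: binding sites, shields, assemblers, backbone fixes.

test_that("binding sites complement the miRNA with declared mismatches only", {
  m <- mirna(rand_rna_fixed <- "CAAAGUGCUUACAGUGCAGGUA", "syn22")  # 22 nt
  perfect <- build_binding_site(m, binding_site_spec("full_length", integer()))
  expect_equal(perfect$sequence, reverse_complement(m$sequence))
  expect_equal(nchar(perfect$sequence), 22L)

  site <- build_binding_site(m, binding_site_spec("full_length", c(2, 9, 17)))
  pc <- strsplit(perfect$sequence, "")[[1]]
  sc <- strsplit(site$sequence, "")[[1]]
  diffs <- which(pc != sc)
  expect_identical(sort(site$map$mirna_pos[site$map$site_pos %in% diffs]),
                   c(2L, 9L, 17L))
  expect_length(diffs, 3L)
  # mismatched positions no longer pair the miRNA
  mc <- strsplit(m$sequence, "")[[1]]
  for (p in c(2, 9, 17)) {
    s <- 22 + 1 - p
    expect_false(pairs_with(sc[s], mc[p]))
  }

  seed_site <- build_binding_site(m, binding_site_spec("seed_only", 2))
  expect_equal(nchar(seed_site$sequence), 7L)
  expect_identical(sort(seed_site$map$mirna_pos), 2:8)
  expect_error(build_binding_site(m, binding_site_spec("seed_only", 12)),
               "outside the seed")
})

test_that("shield length is covered site + spacer + first G", {
  d <- base_design()
  comp <- d$components
  shield <- comp[comp$name == "shield", ]
  expect_equal(shield$end - shield$start + 1L, 16L + 17L + 1L)  # 34 nt
  # loop holds the distal miRNA positions (17..23 for a 23-nt miRNA)
  loop <- comp[comp$name == "loop", ]
  expect_equal(loop$end - loop$start + 1L,
               nchar(mir17()$sequence) - 16L)
  # the arm ends on the scaffold's first repeat G
  scaf <- comp[comp$name == "scaffold", ]
  expect_identical(substr(d$full_sequence, scaf$start, scaf$start), "G")
  expect_equal(d$trigger_hairpin[2], scaf$start)
})

test_that("assembled designs pass validation and tile the sequence", {
  designs <- list(
    base_design(),
    seed_only_design(),
    assemble_tetraloop_shield(mir17(), demo_spacer())
  )
  for (d in designs) {
    expect_equal(nrow(validate_design(d)), 0L)
    comp <- d$components[order(d$components$start), ]
    expect_equal(comp$start[1], 1L)
    expect_equal(comp$end[nrow(comp)], nchar(d$full_sequence))
    expect_true(all(comp$start[-1] == comp$end[-nrow(comp)] + 1L))
    # spacer interval contains the input spacer verbatim
    sp <- comp[comp$name == "spacer", ]
    expect_identical(substr(d$full_sequence, sp$start, sp$end),
                     demo_spacer()$sequence)
  }
})

test_that("validation flags grammar breaches", {
  d <- base_design()
  # corrupt the coverage bound: pretend the shield reaches position 18
  d_bad <- d
  d_bad$site_map$mirna_pos[d_bad$site_map$mirna_pos == 16] <- 18L
  v <- validate_design(d_bad)
  expect_true("covered_position_bound" %in% v$rule)
  # corrupt mismatch declarations
  d_bad2 <- d
  d_bad2$designed_pairs$mismatch <- !d_bad2$designed_pairs$mismatch
  expect_true("mismatch_declaration" %in% validate_design(d_bad2)$rule)
  # a 4-in-4 mismatch window trips the spacing rule
  d_bad3 <- d
  d_bad3$designed_pairs$mismatch[1:4] <- TRUE
  d_bad3$designed_pairs$mismatch[-(1:4)] <- FALSE
  chars <- strsplit(d_bad3$full_sequence, "")[[1]]
  really <- !pairs_with(chars[d_bad3$designed_pairs$i], chars[d_bad3$designed_pairs$j])
  v3 <- validate_design(d_bad3)
  expect_true("mismatch_spacing" %in% v3$rule)
})

test_that("seed-only designs carry one mismatch at position 2 and a GAAA loop", {
  d <- seed_only_design()
  expect_identical(d$pattern$binding_site, 2L)
  lp <- d$components[d$components$name == "loop", ]
  expect_identical(substr(d$full_sequence, lp$start, lp$end), "GAAA")
  # single-mismatch scan: the variant series moves the mismatch across the seed
  for (p in 2:8) {
    dp <- assemble_seed_only(mir17(), demo_spacer(), site_mismatches = p,
                             pattern = mismatch_pattern(p, d$pattern$shield_arm))
    sm <- dp$site_map
    expect_identical(sm$mirna_pos[sm$mismatch], as.integer(p))
  }
})

test_that("the split AND gate yields two valid units with disjoint blocks", {
  pair <- assemble_split_and_gate(mir17(), mir16(), demo_spacer())
  expect_equal(nrow(validate_design(pair)), 0L)
  expect_identical(pair$cr_unit$blocked_element, "spacer")
  expect_identical(pair$tracr_unit$blocked_element, "antirepeat")
  expect_false(identical(pair$cr_unit$mirna$sequence,
                         pair$tracr_unit$mirna$sequence))
  expect_true("spacer" %in% pair$cr_unit$components$name)
  expect_false("spacer" %in% pair$tracr_unit$components$name)
  expect_error(assemble_split_and_gate(mir17(), mir17(), demo_spacer()),
               "distinct")
})

test_that("seed swapping transplants exactly the seed-facing segment", {
  m206 <- catalogue_mirna("miR-206-3p")
  pat <- base_design()$pattern
  d17 <- assemble_full_length(mir17(), demo_spacer(), pattern = pat)
  d206 <- assemble_full_length(m206, demo_spacer(), pattern = pat)
  seg17 <- seed_site_segment(d17)
  seg206 <- seed_site_segment(d206)
  expect_equal(seg17$interval[2] - seg17$interval[1],
               seg206$interval[2] - seg206$interval[1])
  swapped <- d17$full_sequence
  substr(swapped, seg17$interval[1], seg17$interval[2]) <- seg206$sequence
  expect_identical(substr(swapped, seg17$interval[1], seg17$interval[2]),
                   substr(d206$full_sequence, seg206$interval[1], seg206$interval[2]))
})

test_that("poly-U runs are interrupted once, idempotently", {
  r <- fix_poly_u("GUUUUUG")
  expect_equal(nrow(r$edits), 1L)
  expect_false(grepl("UUUU", r$sequence))
  r2 <- fix_poly_u("GAUUUCA")
  expect_identical(r2$sequence, "GAUUUCA")
  expect_equal(nrow(r2$edits), 0L)
  set.seed(61)
  for (k in 1:25) {
    s <- rand_rna(40)
    once <- fix_poly_u(s)
    twice <- fix_poly_u(once$sequence)
    expect_identical(twice$sequence, once$sequence)
    expect_equal(nrow(twice$edits), 0L)
    expect_false(grepl("UUUU", once$sequence))
    # edits only ever turn U into C
    if (nrow(once$edits)) expect_true(all(once$edits$from == "U" & once$edits$to == "C"))
  }
})

test_that("DNA templates honour promoter policy and round-trip", {
  d <- base_design()
  u6 <- emit_dna_template(d, template_spec("U6", poly_t = 6))
  expect_match(u6$dna, "TTTTTT$")
  expect_false(grepl("U", u6$dna))
  t7 <- emit_dna_template(d, template_spec("T7"))
  expect_true(startsWith(t7$dna, "TAATACGACTCACTATAG"))
  body <- substr(t7$dna, nchar("TAATACGACTCACTATAG") + 1, nchar(t7$dna))
  expect_true(startsWith(body, "GG"))
  for (tpl in list(u6, t7)) {
    expect_identical(transcribe_template(tpl), d$full_sequence)
  }
})
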