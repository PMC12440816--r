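test_that("PWM construction matches hand-computed log-odds", {
  # near-zero pseudocount: consensus scores log2(1/0.25) = 2 per matched base
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 1e-9)
  expect_equal(unname(diag(pwm$mat[c("A", "C", "G", "T"), ])),
               rep(2, 4), tolerance = 1e-6)
  # uniform counts at a position score 0 for every base
  pwm_u <- build_pwm(c("AA", "CA", "GA", "TA"), pseudocount = 1)
  expect_equal(unname(pwm_u$mat[, 1]), rep(0, 4))
  # single site "AA", pseudocount 1, uniform background: arithmetic oracle
  pwm_a <- build_pwm("AA", pseudocount = 1)
  expect_equal(unname(pwm_a$mat["A", ]), rep(log2(1.25 / 2 / 0.25), 2))
  expect_equal(unname(pwm_a$mat["C", ]), rep(log2(0.25 / 2 / 0.25), 2))

  expect_error(build_pwm(c("ACG", "ACGT")), "unequal")
  expect_error(build_pwm("ACGN"), "A/C/G/T")
})

test_that("scanner equals brute-force enumeration on short sequences", {
  pwm <- build_pwm(c("ACGA", "ACGT", "TCGA"), pseudocount = 0.5)
  set.seed(202)
  for (rep in 1:20) {
    seq <- random_dna(sample(10:50, 1))
    got <- scan_both_strands(pwm, seq)
    want <- brute_force_scan(pwm, seq)
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("window score is the sum of per-position entries", {
  pwm <- demo_pwm()
  set.seed(77)
  for (rep in 1:10) {
    win <- random_dna(pwm$width)
    idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    direct <- sum(pwm$mat[cbind(idx, seq_len(pwm$width))])
    hit <- scan_both_strands(pwm, win)
    expect_equal(hit$score[hit$strand == "+"], direct, tolerance = 1e-12)
  }
})

test_that("palindromic PWMs score both strands identically", {
  pwm <- build_pwm("ACGT") # self-reverse-complementary consensus
  set.seed(5)
  seq <- random_dna(30)
  hits <- scan_both_strands(pwm, seq)
  expect_equal(hits$score[hits$strand == "+"], hits$score[hits$strand == "-"])
})

test_that("scanning the reverse complement mirrors positions and strands", {
  pwm <- build_pwm(c("ACGA", "ACGT"))
  set.seed(6)
  seq <- random_dna(40)
  rc <- paste(rev(c(A = "T", C = "G", G = "C",
                    T = "A")[strsplit(seq, "")[[1]]]), collapse = "")
  fwd <- scan_both_strands(pwm, seq)
  rev_ <- scan_both_strands(pwm, rc)
  n <- nchar(seq); w <- pwm$width
  # + hit at s on seq corresponds to - hit at n - w - s on revcomp(seq)
  plus <- fwd[fwd$strand == "+", ]
  minus_rc <- rev_[rev_$strand == "-", ]
  expect_equal(plus$score,
               minus_rc$score[match(n - w - plus$start, minus_rc$start)],
               tolerance = 1e-12)
})

test_that("ambiguous bases skip overlapping windows with a warning", {
  pwm <- build_pwm(c("ACGA", "ACGT"))
  expect_warning(hits <- scan_both_strands(pwm, "ACGTNACGT"), "ambiguous")
  # windows covering offset 4 (the N) are gone: starts 1..4 excluded
  expect_setequal(unique(hits$start), c(0L, 5L))
})

test_that("architecture recovers planted opposed sites and their spacing", {
  gen <- gen_origin_sequences(1, spacing = 90, strength = "strong",
                              seed = 303)
  arch <- origin_architecture(demo_pwm(), gen$sequences[[1]])
  expect_equal(arch$a_site$center, gen$truth$a_center)
  expect_equal(arch$a_site$strand, "+")
  expect_equal(arch$b2_site$center, gen$truth$b2_center)
  expect_equal(arch$b2_site$strand, "-")
  expect_equal(arch$center_distance, 90)
  # inner edges: centers 90 apart, width 17 -> 90 - 17 = 73 bp of room
  expect_equal(arch$inner_edge_distance, 73)
  expect_equal(arch$spacing_class, "fits_single_hexamer")
})

test_that("single planted site yields an absent b2 and single-ORC class", {
  gen <- gen_origin_sequences(1, strength = "absent", seed = 304)
  arch <- origin_architecture(demo_pwm(), gen$sequences[[1]])
  expect_null(arch$b2_site)
  expect_equal(arch$spacing_class, "single_orc_only")
  expect_true(is.na(arch$center_distance))
  expect_error(classify_spacing(arch), "no b2")
})

test_that("no-EACS sequences return an explicit empty architecture", {
  arch <- origin_architecture(demo_pwm(), strrep("GC", 100))
  expect_null(arch$a_site)
  expect_true(is.na(arch$spacing_class))
})

test_that("generator ground truth is recovered for a full strong set", {
  spacings <- rep(c(60, 90, 150), length.out = 50)
  gen <- gen_origin_sequences(50, spacing = spacings, strength = "strong",
                              seed = 71)
  res <- scan_origin_set(demo_pwm(), gen$sequences)
  expect_equal(res$table$a_center, gen$truth$a_center)
  expect_equal(res$table$b2_center, gen$truth$b2_center)
  expect_equal(res$table$center_distance_bp, spacings)
})

test_that("recovery degrades monotonically with mutation load", {
  recovery <- vapply(c(1L, 4L, 8L), function(k) {
    gen <- gen_origin_sequences(40, spacing = 90, strength = "weak",
                                n_mutations = k, seed = 500 + k)
    res <- scan_origin_set(demo_pwm(), gen$sequences)
    mean(!is.na(res$table$b2_center) &
           res$table$b2_center == gen$truth$b2_center)
  }, numeric(1))
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1], 1) # one mutation never loses a 17 bp site
  expect_lt(recovery[3], 0.7)
})

test_that("equal-scoring hits break ties leftmost", {
  # two perfect consensus copies on the + strand
  cons <- demo_consensus()
  seq <- paste0(strrep("G", 20), cons, strrep("G", 30), cons, strrep("G", 20))
  arch <- origin_architecture(demo_pwm(), seq)
  expect_equal(arch$a_site$start, 20)
})

test_that("spacing classes follow the occupancy and footprint thresholds", {
  expect_equal(classify_spacing(10), "single_orc_only")
  expect_equal(classify_spacing(11), "single_orc_only")
  expect_equal(classify_spacing(12), "two_orc_simultaneous")
  expect_equal(classify_spacing(40), "two_orc_simultaneous")
  expect_equal(classify_spacing(41), "fits_single_hexamer")
  expect_equal(classify_spacing(81), "fits_single_hexamer")
  expect_equal(classify_spacing(82), "fits_double_hexamer")
  expect_equal(classify_spacing(-3), "single_orc_only") # overlapping sites
})

test_that("set summary reports exact class fractions that sum to one", {
  gen30 <- gen_origin_sequences(15, spacing = 40, seed = 1) # inner edges 23 bp apart
  gen70 <- gen_origin_sequences(35, spacing = 90, seed = 2) # fits_single_hexamer
  archs <- c(scan_origin_set(demo_pwm(), gen30$sequences)$architectures,
             scan_origin_set(demo_pwm(), gen70$sequences)$architectures)
  s <- summarize_set(archs)
  fr <- s$class_fractions
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$spacing_class == "two_orc_simultaneous"], 0.3)
  expect_equal(fr$fraction[fr$spacing_class == "fits_single_hexamer"], 0.7)
  # identical strong sites: zero asymmetry everywhere
  expect_equal(s$fraction_low_asymmetry, 1)
})
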