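test_that("truth models encode the four enzyme archetypes consistently", {
  asp <- make_truth_model("aspase", 0.9)
  expect_equal(unname(asp$pfm$frequencies["D", "P1"]), 0.9)
  expect_equal(unname(asp$pfm$frequencies["E", "P6"]), 0.9)
  expect_equal(unname(sum(asp$pfm$frequencies[c("F", "Y", "W"), "P4"])), 0.9)

  fy <- make_truth_model("FY-chymase", 0.8)
  pat <- fy$pattern
  expect_true(all(c("F", "Y") %in% pat$allowed[["P1"]]))
  expect_equal(pat$allowed[["P2'"]], "L")

  # near-uniform sharpness gives an unconstrained pattern except required P1
  soft <- make_truth_model("polyR-tryptase", sharpness = 0.05)
  expect_true(all(vapply(soft$pattern$allowed, is.null, logical(1))))

  # the planted pattern is always re-derivable from the planted matrix
  for (nm in c("polyR-tryptase", "aspase", "FK-tryptase", "FY-chymase")) {
    tm <- make_truth_model(nm)
    expect_equal(format_pattern(derive_consensus(tm$pfm)),
                 format_pattern(tm$pattern))
    expect_true(all(abs(colSums(tm$pfm$frequencies) - 1) < 1e-9))
  }
  expect_error(make_truth_model("custom"), "preferences")
})

test_that("library simulation is reproducible and composition-faithful", {
  a <- simulate_library(10, seed = 42)
  b <- simulate_library(10, seed = 42)
  expect_identical(a, b)

  allA <- simulate_library(5, composition = c(1, rep(0, 19)), seed = 1)
  expect_true(all(allA$sequence == "AAAAAAAAA"))

  lib <- simulate_library(1e4, seed = 7)
  freq <- table(factor(unlist(strsplit(lib$sequence, "")),
                       levels = aa_alphabet())) / (9e4)
  # each residue within 3 binomial sd of 1/20
  sd3 <- 3 * sqrt(0.05 * 0.95 / 9e4)
  expect_true(all(abs(freq - 0.05) < sd3 + 1e-3))
})

test_that("null biopanning has unit expected enrichment", {
  # a flat truth model: every clone cleaves at background rate only
  flat <- make_truth_model("polyR-tryptase", sharpness = 0.051)
  cfg <- biopanning_config(library_size = 2e4, rounds = 2, p_max = 0.5,
                           p_background = 0.01, score_midpoint = 1e6,
                           sample_size = 20, seed = 1)
  folds <- vapply(1:20, function(s) {
    cfg$seed <- s
    simulate_biopanning(cfg, flat)$rounds$enrichment_fold[1]
  }, numeric(1))
  # E[fold] = 1; each fold is a ratio of two Binomial(2e4, 0.01) counts
  se <- sqrt(2 * (1 - 0.01) / (2e4 * 0.01)) / sqrt(20)
  expect_lt(abs(mean(folds) - 1), 3 * se + 0.02)
})

test_that("two-class libraries match the closed-form round-1 enrichment", {
  # a genuinely two-valued score distribution: an A/K alphabet with a
  # Lys-at-P1 truth separates clones with any Lys (score ~ +4.2) from
  # all-Ala clones (score ~ -4.3); a steep logistic at midpoint 0 makes the
  # cleavage probability two-class with f = 1 - 0.99^9
  tm <- make_truth_model("custom", sharpness = 0.95,
                         preferences = list("P1" = "K"),
                         positions = subsite_window("P4", "P3'"))
  comp <- setNames(rep(0, 20), aa_alphabet())
  comp[c("A", "K")] <- c(0.99, 0.01)
  cfg <- biopanning_config(library_size = 3e4, rounds = 1, p_max = 0.3,
                           p_background = 0.01, score_midpoint = 0,
                           score_slope = 20, sample_size = 20, seed = 1)
  folds <- vapply(1:15, function(s) {
    cfg$seed <- s
    run <- simulate_biopanning(cfg, tm, composition = comp)
    run$rounds$enrichment_fold[1]
  }, numeric(1))
  f <- 1 - 0.99^9
  expected <- (f * cfg$p_max + (1 - f) * cfg$p_background) /
    cfg$p_background
  expect_lt(abs(mean(folds) - expected) / expected, 0.1)
})

test_that("selection drives round-on-round enrichment of strong clones", {
  tm <- make_truth_model("polyR-tryptase", 0.9)
  runs <- lapply(1:5, function(s) {
    simulate_biopanning(biopanning_config(library_size = 2e4,
                                          sample_size = 48,
                                          seed = 100 + s), tm)
  })
  # the big jump happens before saturation; afterwards the fold plateaus
  expect_true(all(vapply(runs, function(r) {
    r$rounds$enrichment_fold[2] > r$rounds$enrichment_fold[1]
  }, logical(1))))
  # the dominant clone's share of the released pool grows round on round
  mono_top <- vapply(runs, function(r) {
    all(diff(r$rounds$top_clone_fraction) > -0.01)
  }, logical(1))
  expect_gte(mean(mono_top), 0.95)
  run <- simulate_biopanning(biopanning_config(seed = 5), tm)
  expect_equal(nrow(run$sequenced), 96)
  expect_identical(
    simulate_biopanning(biopanning_config(seed = 5), tm)$rounds, run$rounds)
})

test_that("planted proteomes record their sites and flag accidentals", {
  tm <- make_truth_model("aspase")
  plan <- data.frame(protein = c(1, 1, 2), p1 = c(50, 120, 80),
                     source = c("consensus", "pfm", "EWFDVDYPA"))
  pp <- simulate_proteome(2, lengths = 300, truth = tm, planting_plan = plan,
                          seed = 8)
  planted <- pp$registry[!pp$registry$accidental, ]
  expect_equal(nrow(planted), 3)
  # every registry window is literally present at its coordinates
  off <- plabel_offset(tm$pfm$positions)
  for (k in seq_len(nrow(planted))) {
    prot <- pp$proteins$sequence[pp$proteins$id == planted$protein_id[k]]
    expect_equal(substring(prot, planted$p1_position[k] + off[1],
                           planted$p1_position[k] + off[length(off)]),
                 planted$window[k])
  }
  expect_equal(planted$window[3], "EWFDVDYPA")
  expect_equal(planted$mismatches[1], 0L)

  expect_error(simulate_proteome(1, lengths = 300, truth = tm,
                                 planting_plan = data.frame(
                                   protein = 1, p1 = c(50, 52),
                                   source = "consensus"),
                                 seed = 1),
               "overlap")
  expect_error(simulate_proteome(1, lengths = 30, truth = tm,
                                 planting_plan = data.frame(
                                   protein = 1, p1 = 29,
                                   source = "consensus"),
                                 seed = 1),
               "fit")

  # no plants: only (rare) accidental background matches in the registry
  empty <- simulate_proteome(2, lengths = 200, truth = tm, seed = 9)
  expect_true(all(empty$registry$accidental))
})

test_that("simulated assays separate preferred from non-preferred substrates", {
  asp <- make_truth_model("aspase")
  assays <- simulate_assays(asp, seed = 3)
  # synthetic curves are linear throughout, so the full series is fitted
  panel <- panel_rates(assays$absorbance)
  p1 <- substring(panel$sequence, nchar(panel$sequence),
                  nchar(panel$sequence))
  # the extended-specificity model discriminates among Asp-P1 substrates
  # too (context matters), so the class signature is the best-in-class rate
  expect_gt(max(panel$rate[p1 == "D"]), 5 * max(abs(panel$rate[p1 != "D"])))
  expect_equal(classify_specificity_from_rates(panel)$label, "asp-ase")

  # zero noise: the planted slope is recovered exactly
  clean <- simulate_absorbance_series("s", "VEID", 0.0012, noise = 0, seed = 1)
  expect_equal(initial_rate(clean)$rate, 0.0012, tolerance = 1e-12)

  # the optimal linker carries the maximal first-order rate
  planted <- assays$planted[assays$planted$kind == "time-course", ]
  expect_gt(planted$rate[1], planted$rate[2])
})

test_that("direct clone sampling records true registers reproducibly", {
  tm <- sharp_truth()
  a <- sample_cleavage_peptides(30, tm, seed = 5)
  b <- sample_cleavage_peptides(30, tm, seed = 5)
  expect_identical(a, b)
  expect_true(all(nchar(a$peptides$sequence) == 9))
  # informative subsites always land inside the insert
  off <- plabel_offset(tm$pfm$positions)
  ic <- information_content(tm$pfm)
  for (o in off[ic >= 0.5]) {
    expect_true(all(a$p1_index + o >= 4 & a$p1_index + o <= 12))
  }
})
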