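test_that("frequency matrices follow the pseudocount rule and normalize", {
  windows <- rep("RRRAAGS", 4)
  pfm <- subsite:::counts_from_windows(windows, subsite_window(), 0.5)
  # (4 + 0.5) / (4 + 20 * 0.5) at the consensus residue of every column
  expect_equal(unname(pfm$frequencies["A", "P1"]), 4.5 / 14)
  expect_equal(unname(pfm$frequencies["R", "P4"]), 4.5 / 14)
  expect_equal(unname(pfm$frequencies["R", "P1"]), 0.5 / 14)
  expect_true(all(abs(colSums(pfm$frequencies) - 1) < 1e-9))

  # zero pseudocount on a single window gives indicator columns
  one <- subsite:::counts_from_windows("RRRAAGS", subsite_window(), 0)
  expect_true(all(apply(one$frequencies, 2, max) == 1))

  expect_error(position_frequency_matrix(pfm$counts, pseudocount = -1),
               "non-negative")

  # count/pseudocount conservation on random matrices
  set.seed(5)
  for (r in 1:5) {
    n <- sample(2:50, 1)
    pc <- runif(1, 0, 2)
    wins <- replicate(n, paste(sample(aa_alphabet(), 7, TRUE), collapse = ""))
    m <- subsite:::counts_from_windows(wins, subsite_window(), pc)
    expect_equal(unname(colSums(m$counts)), rep(n, 7))
    expect_equal(m$frequencies, (m$counts + pc) / (n + 20 * pc),
                 tolerance = 1e-12)
  }
})

test_that("weight matrices are log2 odds with exact round-trip", {
  windows <- rep(c("RRRAAGS", "KRRAAGS"), 3)
  pfm <- subsite:::counts_from_windows(windows, subsite_window(), 0.5)
  pwm <- pfm_to_pwm(pfm)
  # a residue at exactly background frequency has weight zero
  expect_equal(unname(pwm$weights["R", "P1"]),
               log2(pfm$frequencies["R", "P1"] / 0.05))
  expect_equal(2^pwm$weights * 0.05, pfm$frequencies, tolerance = 1e-12,
               ignore_attr = TRUE)

  uniform <- position_frequency_matrix(
    matrix(1, 20, 7, dimnames = list(aa_alphabet(), subsite_window())),
    pseudocount = 0, n_sequences = 20)
  expect_true(all(abs(pfm_to_pwm(uniform)$weights) < 1e-12))

  zero <- subsite:::counts_from_windows("RRRAAGS", subsite_window(), 0)
  expect_error(pfm_to_pwm(zero), "pseudocount")
  expect_error(pfm_to_pwm(pfm, background = rep(0.06, 20)), "background")
})

test_that("information content matches a direct summation oracle", {
  uniform <- position_frequency_matrix(
    matrix(1, 20, 7, dimnames = list(aa_alphabet(), subsite_window())),
    pseudocount = 0, n_sequences = 20)
  expect_equal(unname(information_content(uniform)), rep(0, 7))

  indicator <- subsite:::counts_from_windows("RRRAAGS", subsite_window(), 0)
  expect_equal(unname(information_content(indicator)), rep(log2(20), 7),
               tolerance = 1e-12)

  set.seed(8)
  for (r in 1:5) {
    wins <- replicate(15, paste(sample(aa_alphabet(), 7, TRUE,
                                       prob = runif(20)), collapse = ""))
    pfm <- subsite:::counts_from_windows(wins, subsite_window(), 0.3)
    bg <- runif(20, 0.5, 2)
    bg <- bg / sum(bg)
    oracle <- vapply(1:7, function(j) {
      sum(vapply(1:20, function(k) {
        f <- pfm$frequencies[k, j]
        if (f == 0) 0 else f * log2(f / bg[k])
      }, numeric(1)))
    }, numeric(1))
    expect_equal(unname(information_content(pfm, bg)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("expected log-odds of a background residue is non-positive", {
  set.seed(13)
  wins <- replicate(30, paste(sample(aa_alphabet(), 7, TRUE,
                                     prob = runif(20)), collapse = ""))
  pfm <- subsite:::counts_from_windows(wins, subsite_window(), 0.5)
  pwm <- pfm_to_pwm(pfm)
  # E_bg[weight] = -KL(bg || f) <= 0, column by column
  expect_true(all(colSums(pwm$weights * pwm$background) < 1e-12))
})

test_that("consensus derivation applies majority, class and forbidden rules", {
  asp <- make_truth_model("aspase")$pattern
  expect_equal(asp$allowed[["P1"]], "D")
  expect_equal(asp$allowed[["P3"]], "D")
  expect_setequal(asp$allowed[["P4"]], c("F", "Y", "W"))
  expect_true("P1" %in% asp$required)
  expect_length(asp$forbidden, 0)

  fk <- make_truth_model("FK-tryptase")$pattern
  expect_equal(fk$allowed[["P1"]], "K")
  expect_true(all(c("F", "Y") %in% fk$allowed[["P2"]]))
  expect_setequal(fk$allowed[["P3'"]], c("K", "R"))
  expect_length(fk$forbidden, 1)
  expect_setequal(fk$forbidden[[1]]$residues, c("D", "E"))

  uniform <- position_frequency_matrix(
    matrix(1, 20, 7, dimnames = list(aa_alphabet(), subsite_window())),
    pseudocount = 0, n_sequences = 20)
  pat <- derive_consensus(uniform)
  expect_true(all(vapply(pat$allowed, is.null, logical(1))))
  expect_equal(pat$required, "P1")

  expect_error(derive_consensus(uniform, majority_threshold = 0), "0, 1")
})

test_that("a single window's consensus matches that window at 0 mismatches", {
  win <- "EWFDVDYPA"
  pfm <- subsite:::counts_from_windows(win, subsite_window("P6", "P3'"), 0)
  pat <- derive_consensus(pfm)
  m <- match_pattern(pat, win)
  expect_true(m$passes)
  expect_equal(m$mismatches, 0L)
})

test_that("the pattern grammar round-trips losslessly", {
  for (nm in c("polyR-tryptase", "aspase", "FK-tryptase", "FY-chymase")) {
    pat <- make_truth_model(nm)$pattern
    txt <- format_pattern(pat)
    back <- parse_pattern(txt)
    expect_equal(back$positions, pat$positions)
    expect_equal(back$allowed, pat$allowed)
    expect_setequal(back$required, pat$required)
    expect_equal(back$forbidden, pat$forbidden)
    expect_equal(back$max_mismatches, pat$max_mismatches)
    expect_equal(format_pattern(back), txt)
  }
  expect_error(parse_pattern("P4:FY P1:D!"), "token")
  expect_error(parse_pattern("P1:D! ; forbid[DE]"), "forbid")
})

test_that("primary specificity calls follow the evidence thresholds", {
  mk_pwm <- function(p1_freq) {
    freq <- matrix(1 / 20, 20, 7, dimnames = list(aa_alphabet(),
                                                  subsite_window()))
    freq[, "P1"] <- p1_freq
    pfm <- position_frequency_matrix(freq, 0, 1)
    pfm_to_pwm(pfm)
  }
  p1 <- setNames(rep(0.1 / 19, 20), aa_alphabet())
  p1["R"] <- 0.9
  expect_equal(classify_specificity_from_pwm(mk_pwm(p1))$label, "tryptase")

  p1 <- setNames(rep(0.15 / 19, 20), aa_alphabet())
  p1["D"] <- 0.85
  expect_equal(classify_specificity_from_pwm(mk_pwm(p1))$label, "asp-ase")

  expect_equal(classify_specificity_from_pwm(mk_pwm(rep(0.05, 20)))$label,
               "undetermined")

  # strong K/R and F/Y together: the dual tryptase/chymase call
  p1 <- setNames(rep(0.1 / 16, 20), aa_alphabet())
  p1[c("R", "K")] <- 0.25
  p1[c("F", "Y")] <- 0.2
  call <- classify_specificity_from_pwm(mk_pwm(p1))
  expect_equal(call$label, "dual(tryptase+chymase)")
  expect_true(all(call$evidence >= 0 & call$evidence <= 1))
})
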