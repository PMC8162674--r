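test_that("window scores equal the per-position summation oracle", {
  tm <- make_truth_model("aspase")
  pwm <- tm$pwm
  expect_error(score_window(pwm, "EWFD"), "length")
  expect_error(score_window(pwm, "EWFDVDYPX"), "non-alphabet")

  # the position-wise argmax window attains the maximal attainable score
  best <- paste(rownames(pwm$weights)[apply(pwm$weights, 2, which.max)],
                collapse = "")
  expect_equal(score_window(pwm, best),
               sum(apply(pwm$weights, 2, max)), tolerance = 1e-12)

  set.seed(3)
  for (r in 1:20) {
    win <- paste(sample(aa_alphabet(), 9, TRUE), collapse = "")
    oracle <- sum(vapply(1:9, function(j) {
      pwm$weights[substring(win, j, j), j]
    }, numeric(1)))
    expect_equal(score_window(pwm, win), oracle, tolerance = 1e-12)
  }

  uniform <- position_frequency_matrix(
    matrix(1, 20, 7, dimnames = list(aa_alphabet(), subsite_window())),
    pseudocount = 0, n_sequences = 20)
  upwm <- pfm_to_pwm(uniform)
  expect_equal(score_window(upwm, "ACDEFGH"), 0, tolerance = 1e-12)
})

test_that("pattern matching enforces required, budget and forbidden rules", {
  asp <- make_truth_model("aspase")$pattern
  m <- match_pattern(asp, "EWFDVDYPA")
  expect_true(m$passes)
  expect_equal(m$mismatches, 0L)
  # the one-mismatch Mucin-5B variant octamer still passes at budget 1
  expect_true(match_pattern(asp, "EWFDVDFPA")$passes)
  # losing the required P1 aspartate kills the match
  expect_false(match_pattern(asp, "EWFDVAYPA")$passes)

  fk <- make_truth_model("FK-tryptase")$pattern
  expect_true(match_pattern(fk, "AAAAFKRLK")$passes)
  expect_true(match_pattern(fk, "AAAAFKLAR")$passes)
  # Asp at P2': forbidden class within +-3 of the scissile bond
  expect_false(match_pattern(fk, "AAAAFKRDK")$passes)

  expect_error(match_pattern(asp, "EWFD"), "length")
})

test_that("scanning recovers the Mucin-5B style site at its coordinates", {
  tm <- make_truth_model("aspase")
  prot <- paste(rep("A", 999), collapse = "")
  substr(prot, 833, 841) <- "EWFDVDYPA"
  hits <- scan_proteins(data.frame(id = "MUC5B", description = "",
                                   sequence = prot),
                        tm$pattern, scan_options(report_span = c("P6", "P2'")))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 833L)
  expect_equal(hits$end, 840L)
  expect_equal(hits$p1_position, 838L)
  expect_equal(hits$window, "EWFDVDYP")

  polyg <- data.frame(id = "g", description = "",
                      sequence = strrep("G", 400))
  expect_equal(nrow(scan_proteins(polyg, tm$pattern)), 0)
})

test_that("vectorized scan equals the naive re-scoring oracle", {
  set.seed(17)
  prots <- data.frame(
    id = sprintf("p%02d", 1:20), description = "",
    sequence = replicate(20, paste(sample(c(aa_alphabet(), "X"), 250, TRUE,
                                          prob = c(rep(0.0495, 20), 0.01)),
                                   collapse = "")))
  tm <- make_truth_model("FK-tryptase")
  for (model in list(tm$pwm, tm$pattern)) {
    for (thr in c(-5, 2)) {
      o <- scan_options(threshold = thr)
      a <- scan_proteins(prots, model, o)
      b <- brute_force_scan(prots, model, o)
      expect_equal(a$protein_id, b$protein_id)
      expect_equal(a$p1_position, b$p1_position)
      expect_equal(a$start, b$start)
      expect_equal(a$score, b$score, tolerance = 1e-9)
      expect_equal(a$mismatches, b$mismatches)
    }
  }
  expect_equal(nrow(brute_force_scan(prots[0, ], tm$pattern)), 0)
})

test_that("raising the threshold or budget changes hits monotonically", {
  set.seed(23)
  prots <- data.frame(
    id = "p1", description = "",
    sequence = paste(sample(aa_alphabet(), 2000, TRUE), collapse = ""))
  tm <- make_truth_model("FY-chymase")

  prev <- Inf
  for (thr in c(-10, -5, 0, 5)) {
    n <- nrow(scan_proteins(prots, tm$pwm, scan_options(threshold = thr)))
    expect_lte(n, prev)
    prev <- n
  }

  pat <- tm$pattern
  prev <- -1
  for (mm in 0:3) {
    pat$max_mismatches <- mm
    n <- nrow(scan_proteins(prots, pat))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("X windows and short proteins are skipped and logged", {
  tm <- make_truth_model("aspase")
  prots <- data.frame(
    id = c("short", "withx"), description = "",
    sequence = c("EWFD", paste0(strrep("A", 50), "EWFDVXYPA",
                                strrep("A", 50))))
  hits <- scan_proteins(prots, tm$pattern)
  lg <- attr(hits, "log")
  expect_equal(lg$n_proteins_too_short, 1L)
  expect_gt(lg$n_skipped, 0)
  # scanning is strictly protein-space: no reverse-complement aliasing of a
  # palindromic arrangement can produce extra hits
  expect_equal(nrow(hits), 0)
})

test_that("planted consensus sites are recovered at the matching budget", {
  tm <- make_truth_model("aspase")
  plan <- data.frame(protein = c(1, 2, 2, 3),
                     p1 = c(100, 60, 200, 150),
                     source = "consensus",
                     mismatches = c(0L, 0L, 1L, 1L))
  pp <- simulate_proteome(3, lengths = 400, truth = tm, planting_plan = plan,
                          seed = 31)
  span <- c(tm$pattern$positions[1],
            tm$pattern$positions[length(tm$pattern$positions)])

  pat0 <- tm$pattern
  pat0$max_mismatches <- 0L
  hits0 <- scan_proteins(pp$proteins, pat0, scan_options(report_span = span))
  exact <- pp$registry[pp$registry$mismatches == 0 & !pp$registry$accidental, ]
  expect_true(all(paste(exact$protein_id, exact$p1_position) %in%
                    paste(hits0$protein_id, hits0$p1_position)))

  pat1 <- tm$pattern
  pat1$max_mismatches <- 1L
  hits1 <- scan_proteins(pp$proteins, pat1, scan_options(report_span = span))
  planted <- pp$registry[!pp$registry$accidental, ]
  expect_true(all(paste(planted$protein_id, planted$p1_position) %in%
                    paste(hits1$protein_id, hits1$p1_position)))
})
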