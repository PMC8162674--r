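test_that("candidate registers enumerate insert P1 placements with flank padding", {
  cr <- candidate_registers("RRRAAGSLV")
  expect_equal(nrow(cr), 9)
  expect_equal(cr$p1_index, 4:12)
  # P1 at insert position 3: window reaches one residue into the PGG flank
  expect_equal(cr$window[cr$p1_index == 6], "GRRRAAG")
  # P1 at insert position 9: prime side drawn from the His flank
  expect_equal(cr$window[cr$p1_index == 12], "GSLVHHH")

  wide <- candidate_registers("RRRAAGSLV", library_context("P", ""),
                              subsite_window("P4", "P3'"))
  # placements whose window runs past either end are dropped
  expect_equal(wide$p1_index, 4:7)
  expect_error(candidate_registers("RRRAAGSLV", library_context("", ""),
                                   subsite_window("P6", "P4'")),
               "wider")
})

test_that("brute-force oracle handles degenerate instances deterministically", {
  # a single peptide: all registers tie; the canonical pick is deterministic
  one <- brute_force_alignment("RRRAAGSLV")
  expect_equal(nrow(one$assignments), 1)
  again <- brute_force_alignment("RRRAAGSLV")
  expect_equal(one$assignments$p1_index, again$assignments$p1_index)

  # two identical peptides are assigned one common register
  two <- brute_force_alignment(c("ARKAAGSLV", "ARKAAGSLV"))
  expect_equal(two$assignments$p1_index[1], two$assignments$p1_index[2])

  expect_error(brute_force_alignment(random_peptides(9, 1)), "8 peptides")
})

test_that("EM attains the brute-force objective on small random instances", {
  worst <- 0
  for (d in 1:20) {
    n <- sample(3:6, 1)
    peps <- random_peptides(n, seed = 500 + d)
    bf <- brute_force_alignment(peps)
    em <- align_registers(peps, seed = d)
    worst <- max(worst, bf$objective_best - em$objective_best)
  }
  expect_lt(worst, 1e-9)
})

test_that("EM and oracle agree on instances with a planted common motif", {
  # three peptides each containing RRR exactly once
  peps <- c("AARRRGSLV", "GRRRAACSV", "CAARRRGSV")
  bf <- brute_force_alignment(peps)
  em <- align_registers(peps, seed = 2)
  expect_equal(em$assignments$p1_index, bf$assignments$p1_index)
  expect_equal(em$objective, bf$objective, tolerance = 1e-9)
})

test_that("copies of a peptide with a unique anchor residue align on it", {
  # the only Lys fixes a unique register family; the canonical register
  # is shared by every copy and its window covers the Lys
  al <- align_registers(rep("AAAAKAAAA", 50), seed = 1, pseudocount = 0.1)
  expect_equal(length(unique(al$assignments$p1_index)), 1)
  expect_true(all(apply(al$pfm$frequencies, 2, max) >= 0.9))
  k_col <- which(al$pfm$frequencies["K", ] >= 0.9)
  expect_length(k_col, 1)
})

test_that("penalized EM objective is non-decreasing on every run", {
  for (d in 1:5) {
    al <- align_registers(random_peptides(30, seed = 40 + d), seed = d)
    expect_true(all(diff(al$loglik_trace) > -1e-9))
  }
})

test_that("signal-free peptides yield a low-information matrix", {
  ics <- replicate(5, {
    al <- align_registers(random_peptides(96, seed = sample.int(1e6, 1)),
                          seed = 7)
    mean(information_content(al$pfm_insert))
  })
  # under the null the learned matrix carries only register-overfitting
  # noise from the 9-way latent register choice; calibrated at a mean of
  # 0.61 bits per subsite (10 uniform replicates), far below the >= 1.5-bit
  # scale of a planted motif
  expect_lt(mean(ics), 0.7)
})

test_that("a global +1 register shift never beats the returned optimum", {
  tm <- sharp_truth()
  sim <- sample_cleavage_peptides(40, tm, seed = 9)
  al <- align_registers(sim$peptides, window_positions = tm$pfm$positions,
                        seed = 3, p1_anchor = "K")
  cand <- subsite:::register_candidates_all(sim$peptides$sequence,
                                            library_context(),
                                            al$window_positions)
  offs <- c(0L, cumsum(cand$n_cand))
  rows <- vapply(seq_len(nrow(sim$peptides)), function(i) {
    rws <- (offs[i] + 1):offs[i + 1]
    rws[match(al$assignments$p1_index[i], cand$p1[rws])]
  }, integer(1))
  bonus <- subsite:::anchor_bonus(cand, al$window_positions, "K", 2)
  log_bg <- log(rep(1 / 20, 20))
  shifted <- rows + 1L
  ok <- all(shifted <= offs[-1][cand$pep[rows]])
  expect_true(ok)
  obj_shift <- subsite:::completed_loglik(cand, shifted, 0.5, log_bg) +
    sum(bonus[shifted])
  expect_lte(obj_shift, al$objective + 1e-9)
})

test_that("anchored alignment recovers planted registers from a sharp model", {
  tm <- sharp_truth()
  expect_gte(mean(information_content(tm$pfm)), 1.5)
  hits <- numeric(3)
  for (s in 1:3) {
    sim <- sample_cleavage_peptides(96, tm, seed = 60 + s)
    al <- align_registers(sim$peptides, window_positions = tm$pfm$positions,
                          seed = s, p1_anchor = "K")
    hits[s] <- mean(al$assignments$p1_index == sim$p1_index)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("alignment reports register posteriors and entropy", {
  al <- align_registers(random_peptides(20, seed = 3), seed = 1)
  expect_true(all(al$assignments$posterior >= 0 &
                    al$assignments$posterior <= 1))
  expect_true(all(al$assignments$entropy >= -1e-9))
  # a sharp motif pins registers: entropies shrink
  tm <- sharp_truth()
  sim <- sample_cleavage_peptides(50, tm, seed = 2)
  al2 <- align_registers(sim$peptides, window_positions = tm$pfm$positions,
                         seed = 1, p1_anchor = "K")
  expect_lt(mean(al2$assignments$entropy), mean(al$assignments$entropy))
})

test_that("alignment rejects invalid inputs", {
  expect_error(align_registers("RRRAAGSLV"), "at least 2")
  expect_error(align_registers(c("RRRAAGSLV", "RRRAAGSLB")), "non-amino")
  expect_error(align_registers(random_peptides(3, 1), max_iter = 0),
               "max_iter")
})
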