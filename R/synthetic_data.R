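# Generators for every input the pipeline consumes: planted specificity
# models for the four enzyme archetypes characterized by phage display,
# biopanning selection dynamics over a scaled-down nonamer library, sequenced
# clone samples, proteomes with planted near-consensus sites, and noisy assay
# time series. All generators are bit-reproducible for a fixed seed.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Planted truth models for the four enzyme archetypes
#'
#' Builds a frequency matrix over P6..P3' concentrating `sharpness` of each
#' preferred subsite's mass on the preferred residue set, the rest spread
#' uniformly:
#' * `"polyR-tryptase"`: Arg at P2, P1 and P1' (tandem basic arrays);
#' * `"aspase"`: Asp at P1 and P3, an aromatic residue at P4, Glu-leaning P6;
#' * `"FK-tryptase"`: Phe/Tyr at P2, Lys at P1, Arg/Lys at P3', and
#'   near-zero acidic residues at every subsite;
#' * `"FY-chymase"`: Phe/Tyr at P1, Leu at P2';
#' * `"custom"`: preferences supplied by the caller.
#'
#' @param name Model name (above).
#' @param sharpness Fraction of column mass on the preferred set, in (0, 1].
#' @param preferences For `"custom"`: named list mapping subsite labels to
#'   preferred residue vectors.
#' @param avoid Residues given only a trace frequency (0.001) at every
#'   subsite (for `"custom"`).
#' @param positions Subsite labels of the model window.
#' @return List of class `"truth_model"`: `name`, `pfm`, `pwm` (`NULL` when
#'   the matrix has zeros), and the `pattern` derived at default thresholds.
#' @export
make_truth_model <- function(name = c("polyR-tryptase", "aspase",
                                      "FK-tryptase", "FY-chymase", "custom"),
                             sharpness = 0.9, preferences = NULL,
                             avoid = NULL,
                             positions = subsite_window("P6", "P3'")) {
  name <- match.arg(name)
  if (sharpness <= 0 || sharpness > 1) stop("sharpness must lie in (0, 1]")
  spec <- switch(name,
    "polyR-tryptase" = list(prefs = list("P2" = "R", "P1" = "R", "P1'" = "R"),
                            avoid = NULL),
    "aspase" = list(prefs = list("P6" = "E", "P4" = c("F", "Y", "W"),
                                 "P3" = "D", "P1" = "D"),
                    avoid = NULL),
    "FK-tryptase" = list(prefs = list("P2" = c("F", "Y"), "P1" = "K",
                                      "P3'" = c("R", "K")),
                         avoid = c("D", "E")),
    "FY-chymase" = list(prefs = list("P1" = c("F", "Y"), "P2'" = "L"),
                        avoid = NULL),
    "custom" = list(prefs = preferences, avoid = avoid)
  )
  if (name == "custom" && is.null(spec$prefs)) {
    stop("custom truth model needs 'preferences'")
  }
  check_window_positions(positions)
  bad_pos <- setdiff(names(spec$prefs), positions)
  if (length(bad_pos) > 0) {
    stop("preference subsite(s) outside model window: ",
         paste(bad_pos, collapse = ", "))
  }
  aa <- aa_alphabet()
  eps <- 0.001
  freq <- matrix(0, nrow = 20, ncol = length(positions),
                 dimnames = list(aa, positions))
  for (j in seq_along(positions)) {
    col <- setNames(rep(0, 20), aa)
    pref <- spec$prefs[[positions[j]]]
    av <- setdiff(spec$avoid, pref)
    col[av] <- eps
    if (!is.null(pref)) {
      col[pref] <- sharpness / length(pref)
      rest <- setdiff(aa, c(pref, av))
      col[rest] <- (1 - sharpness - eps * length(av)) / length(rest)
    } else {
      rest <- setdiff(aa, av)
      col[rest] <- (1 - eps * length(av)) / length(rest)
    }
    freq[, j] <- col
  }
  pfm <- position_frequency_matrix(freq, pseudocount = 0, n_sequences = 1)
  pwm <- if (all(freq > 0)) pfm_to_pwm(pfm) else NULL
  pattern <- derive_consensus(pfm)
  structure(list(name = name, sharpness = sharpness, pfm = pfm, pwm = pwm,
                 pattern = pattern),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("Truth model '%s' (sharpness %.2f): %s\n", x$name, x$sharpness,
              format_pattern(x$pattern)))
  invisible(x)
}

#' Simulate a naive phage-display nonamer library
#'
#' Independent 9-mers drawn residue-wise from a composition (uniform by
#' default); a desk-scale stand-in for the physical library.
#'
#' @param n Number of clones.
#' @param composition Length-20 residue composition; default uniform.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Peptide table (data.frame with `sequence`, `count`, `label`).
#' @export
simulate_library <- function(n, composition = NULL, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  with_seed(seed, {
    chars <- sample(aa_alphabet(), 9 * n, replace = TRUE, prob = composition)
    seqs <- apply(matrix(chars, ncol = 9), 1, paste, collapse = "")
    data.frame(sequence = seqs, count = 1L,
               label = paste0("clone", seq_len(n)))
  })
}

#' Best-register log-odds score of each insert
#'
#' Scores every admissible P1 placement of each insert within the flanked
#' capsid sequence against a weight matrix and keeps the best.
#'
#' @param peptides Character vector of inserts or a peptide table.
#' @param pwm A `"subsite_pwm"`.
#' @param context A [library_context()].
#' @return Data.frame with `score` (best log2 odds) and `p1_index` (extended
#'   coordinate of the best register, ties toward the N-terminus).
#' @export
best_insert_score <- function(peptides, pwm, context = library_context()) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  off <- plabel_offset(pwm$positions)
  nf <- nchar(context$n_flank)
  ins_len <- nchar(peptides[1])
  if (any(nchar(peptides) != ins_len)) stop("inserts must share one length")
  ext_len <- nf + ins_len + nchar(context$c_flank)
  W <- length(off)
  p1s <- (nf + 1L):(nf + ins_len)
  p1s <- p1s[p1s + off[1] >= 1L & p1s + off[W] <= ext_len]
  if (length(p1s) == 0) stop("window does not fit around any insert position")
  ext <- paste0(context$n_flank, peptides, context$c_flank)
  m <- matrix(match(unlist(strsplit(ext, "", fixed = TRUE)), aa_alphabet()),
              ncol = ext_len, byrow = TRUE)
  best <- rep(-Inf, length(peptides))
  best_p1 <- rep(NA_integer_, length(peptides))
  for (p1 in p1s) {
    s <- numeric(length(peptides))
    for (j in seq_len(W)) {
      s <- s + pwm$weights[m[, p1 + off[j]], j]
    }
    better <- s > best + 1e-12
    best[better] <- s[better]
    best_p1[better] <- p1
  }
  data.frame(score = best, p1_index = best_p1)
}

#' Biopanning configuration
#'
#' @param library_size Clones per round (scaled-down stand-in for the
#'   physical library of about 5e7 clones).
#' @param rounds Selection rounds (the experiments ran five to seven).
#' @param p_max Maximal per-encounter cleavage probability.
#' @param p_background Spontaneous release probability (enzyme-independent;
#'   also the control release rate).
#' @param score_midpoint Logistic midpoint on the best-register log-odds
#'   score; `NULL` sets it to the 99.9th percentile of the naive library's
#'   best-register scores.
#' @param score_slope Logistic slope per log2-odds unit.
#' @param sample_size Sequenced clones after the final round (the
#'   experiments sequenced 57-96).
#' @param seed Integer seed for the whole run.
#' @return List of class `"biopanning_config"`.
#' @export
biopanning_config <- function(library_size = 1e5, rounds = 5L, p_max = 0.5,
                              p_background = 0.001, score_midpoint = NULL,
                              score_slope = 1, sample_size = 96L, seed = 1L) {
  if (rounds < 1) stop("rounds must be >= 1")
  stopifnot(p_max > 0, p_max < 1, p_background > 0, p_background < p_max)
  structure(list(library_size = as.integer(library_size),
                 rounds = as.integer(rounds), p_max = p_max,
                 p_background = p_background,
                 score_midpoint = score_midpoint, score_slope = score_slope,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "biopanning_config")
}

#' Simulate iterative biopanning selection
#'
#' Each clone's per-round cleavage probability follows a monotone saturating
#' (logistic) link on its best-register log-odds score:
#' `p = p_background + (p_max - p_background) * plogis(slope * (score - midpoint))`.
#' Released counts are binomial; the buffer control releases every clone at
#' `p_background`; the released pool is re-amplified by unbiased multinomial
#' resampling to `library_size` for the next round; after the final round
#' `sample_size` clones are drawn from the released pool as the sequenced
#' sample. Zero total release ends the run early with a flagged round.
#'
#' @param config A [biopanning_config()].
#' @param truth A `"truth_model"` with a non-`NULL` `pwm`.
#' @param context A [library_context()].
#' @param composition Residue composition of the naive library (default
#'   uniform).
#' @return List of class `"biopanning_run"`: `rounds` (data.frame with
#'   `round`, `released_enzyme`, `released_control`, `enrichment_fold`,
#'   `top_clone_fraction`, `flagged`), `sequenced` (peptide table),
#'   `score_midpoint`, and the initial-library score summary.
#' @export
simulate_biopanning <- function(config, truth, context = library_context(),
                                composition = NULL) {
  if (is.null(truth$pwm)) stop("truth model has no weight matrix")
  with_seed(config$seed, {
    lib <- simulate_library(config$library_size, composition = composition)
    sc <- best_insert_score(lib$sequence, truth$pwm, context)
    midpoint <- config$score_midpoint
    if (is.null(midpoint)) {
      midpoint <- unname(quantile(sc$score, 0.999, type = 7))
    }
    p <- config$p_background + (config$p_max - config$p_background) *
      stats::plogis(config$score_slope * (sc$score - midpoint))
    counts <- rep(1L, nrow(lib))
    rounds <- vector("list", config$rounds)
    sequenced <- NULL
    for (r in seq_len(config$rounds)) {
      released <- rbinom(length(counts), counts, p)
      total_released <- sum(released)
      released_control <- rbinom(1, sum(counts), config$p_background)
      flagged <- total_released == 0 || released_control == 0
      rounds[[r]] <- data.frame(
        round = r,
        released_enzyme = total_released,
        released_control = released_control,
        enrichment_fold = if (released_control > 0) {
          total_released / released_control
        } else NA_real_,
        top_clone_fraction = if (total_released > 0) {
          max(released) / total_released
        } else NA_real_,
        flagged = flagged
      )
      if (total_released == 0) break
      if (r < config$rounds) {
        counts <- as.integer(rmultinom(1, config$library_size,
                                       prob = released))
      } else {
        picked <- sample.int(length(counts), config$sample_size,
                             replace = TRUE, prob = released)
        sequenced <- data.frame(sequence = lib$sequence[picked], count = 1L,
                                label = paste0("seq", seq_along(picked)))
      }
    }
    structure(list(rounds = do.call(rbind, rounds[!vapply(rounds, is.null,
                                                          logical(1))]),
                   sequenced = sequenced, score_midpoint = midpoint,
                   score_summary = summary(sc$score),
                   config = config, truth_name = truth$name),
              class = "biopanning_run")
  })
}

#' @export
print.biopanning_run <- function(x, ...) {
  cat(sprintf("Biopanning run (%s): %d rounds, midpoint %.2f\n",
              x$truth_name, nrow(x$rounds), x$score_midpoint))
  print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' Sample sequenced clones directly from a planted model
#'
#' A fast stand-in for full biopanning when the per-clone true register must
#' be known: each insert gets a register drawn uniformly from the placements
#' in which every informative subsite (information content at least
#' `info_min` bits) falls inside the randomized insert; window residues
#' inside the insert are drawn from the planted matrix columns and the
#' remaining insert residues from the background composition.
#'
#' @param n Number of clones.
#' @param truth A `"truth_model"`.
#' @param context A [library_context()].
#' @param composition Background composition for non-window residues.
#' @param info_min Bits above which a subsite counts as informative.
#' @param seed Optional seed.
#' @return List: `peptides` (peptide table), `p1_index` (true P1 in extended
#'   coordinates, per clone).
#' @export
sample_cleavage_peptides <- function(n, truth, context = library_context(),
                                     composition = NULL, info_min = 0.5,
                                     seed = NULL) {
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  positions <- truth$pfm$positions
  off <- plabel_offset(positions)
  ic <- information_content(truth$pfm)
  info_off <- off[ic >= info_min]
  nf <- nchar(context$n_flank)
  ins_len <- 9L
  ext_len <- nf + ins_len + nchar(context$c_flank)
  p1s <- (nf + 1L):(nf + ins_len)
  p1s <- p1s[p1s + off[1] >= 1L & p1s + off[length(off)] <= ext_len]
  admissible <- p1s[vapply(p1s, function(p) {
    all(p + info_off >= nf + 1L & p + info_off <= nf + ins_len)
  }, logical(1))]
  if (length(admissible) == 0) {
    stop("no register keeps all informative subsites inside the insert")
  }
  with_seed(seed, {
    p1 <- sample(admissible, n, replace = TRUE)
    inserts <- matrix(sample(aa_alphabet(), ins_len * n, replace = TRUE,
                             prob = composition), nrow = n)
    for (j in seq_along(off)) {
      pos_in_ext <- p1 + off[j]
      inside <- pos_in_ext >= nf + 1L & pos_in_ext <= nf + ins_len
      if (any(inside)) {
        draws <- sample(aa_alphabet(), sum(inside), replace = TRUE,
                        prob = truth$pfm$frequencies[, j])
        inserts[cbind(which(inside), pos_in_ext[inside] - nf)] <- draws
      }
    }
    seqs <- apply(inserts, 1, paste, collapse = "")
    list(peptides = data.frame(sequence = seqs, count = 1L,
                               label = paste0("clone", seq_len(n))),
         p1_index = p1)
  })
}

#' Simulate a proteome with planted cleavage sites
#'
#' Background residues are i.i.d. from a composition; planted windows --
#' exact consensus (the position-wise modal window, optionally mutated at
#' `mismatches` non-required subsites), draws from the planted matrix, or
#' explicit strings -- are spliced in at recorded coordinates. Accidental
#' background matches to the truth pattern are detected post hoc with
#' [brute_force_scan()] and appended to the registry flagged as accidental.
#'
#' @param n_proteins Number of proteins.
#' @param lengths Integer vector of protein lengths (recycled), or `NULL`
#'   for lengths drawn from 300-1200.
#' @param composition Background residue composition; default uniform.
#' @param truth A `"truth_model"`.
#' @param planting_plan Data.frame with columns `protein` (index), `p1`
#'   (P1 coordinate), `source` (`"consensus"`, `"pfm"`, or an explicit
#'   window string of the model width), and optional `mismatches` (for
#'   `"consensus"`). `NULL` plants nothing.
#' @param seed Optional seed.
#' @return List of class `"planted_proteome"`: `proteins` (data.frame) and
#'   `registry` (protein_id, p1_position, window, mismatches, passes,
#'   source, accidental).
#' @export
simulate_proteome <- function(n_proteins, lengths = NULL, composition = NULL,
                              truth, planting_plan = NULL, seed = NULL) {
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  positions <- truth$pfm$positions
  off <- plabel_offset(positions)
  W <- length(off)
  with_seed(seed, {
    if (is.null(lengths)) {
      lengths <- sample(300:1200, n_proteins, replace = TRUE)
    }
    lengths <- rep_len(lengths, n_proteins)
    ids <- sprintf("synthetic_protein_%03d", seq_len(n_proteins))
    seq_chars <- lapply(lengths, function(L) {
      sample(aa_alphabet(), L, replace = TRUE, prob = composition)
    })
    registry <- list()
    if (!is.null(planting_plan)) {
      spans <- split(planting_plan, planting_plan$protein)
      for (sp in spans) {
        iv <- cbind(sp$p1 + off[1], sp$p1 + off[W])
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
          stop("overlapping planted windows on protein ",
               sp$protein[1])
        }
      }
      for (k in seq_len(nrow(planting_plan))) {
        row <- planting_plan[k, ]
        i <- row$protein
        L <- lengths[i]
        if (row$p1 + off[1] < 1 || row$p1 + off[W] > L) {
          stop(sprintf("planted window at p1=%d does not fit in protein %d",
                       row$p1, i))
        }
        mm_req <- if (!is.null(row$mismatches) && !is.na(row$mismatches)) {
          as.integer(row$mismatches)
        } else 0L
        win <- switch(row$source,
          consensus = mutate_window(modal_window(truth$pfm), truth$pattern,
                                    mm_req),
          pfm = paste(vapply(seq_len(W), function(j) {
            sample(aa_alphabet(), 1, prob = truth$pfm$frequencies[, j])
          }, character(1)), collapse = ""),
          row$source   # explicit window string
        )
        if (nchar(win) != W) {
          stop("explicit planted window must have the model width")
        }
        seq_chars[[i]][(row$p1 + off[1]):(row$p1 + off[W])] <-
          strsplit(win, "")[[1]]
        m <- match_pattern(truth$pattern, win)
        registry[[length(registry) + 1]] <- data.frame(
          protein_id = ids[i], p1_position = row$p1, window = win,
          mismatches = m$mismatches, passes = m$passes,
          source = if (row$source %in% c("consensus", "pfm")) {
            row$source
          } else "explicit",
          accidental = FALSE
        )
      }
    }
    proteins <- data.frame(
      id = ids, description = "synthetic background protein",
      sequence = vapply(seq_chars, paste, character(1), collapse = "")
    )
    registry <- if (length(registry) > 0) do.call(rbind, registry) else
      data.frame(protein_id = character(), p1_position = integer(),
                 window = character(), mismatches = integer(),
                 passes = logical(), source = character(),
                 accidental = logical())
    # accidental matches: pattern hits not accounted for by the plan
    hits <- brute_force_scan(proteins, truth$pattern,
                             scan_options(report_span = c(positions[1],
                                                          positions[W])))
    planned_keys <- paste(registry$protein_id, registry$p1_position)
    extra <- hits[!paste(hits$protein_id, hits$p1_position) %in% planned_keys,
                  , drop = FALSE]
    if (nrow(extra) > 0) {
      registry <- rbind(registry, data.frame(
        protein_id = extra$protein_id, p1_position = extra$p1_position,
        window = extra$window, mismatches = extra$mismatches,
        passes = TRUE, source = "background", accidental = TRUE))
    }
    structure(list(proteins = proteins, registry = registry),
              class = "planted_proteome")
  })
}

# Mutate m non-required constrained subsites of a window to residues outside
# the allowed set (avoiding forbidden classes, so a 1-mismatch variant still
# passes a mismatch budget of 1).
mutate_window <- function(window, pattern, m) {
  if (m == 0) return(window)
  chars <- strsplit(window, "")[[1]]
  forbidden_res <- unlist(lapply(pattern$forbidden, `[[`, "residues"))
  mutable <- which(!vapply(pattern$allowed, is.null, logical(1)) &
                     !(pattern$positions %in% pattern$required))
  if (length(mutable) < m) {
    stop("not enough mutable constrained subsites for ", m, " mismatches")
  }
  targets <- sample(mutable, m)
  for (j in targets) {
    choices <- setdiff(aa_alphabet(),
                       c(pattern$allowed[[j]], forbidden_res))
    chars[j] <- sample(choices, 1)
  }
  paste(chars, collapse = "")
}

#' The standard eleven-substrate chromogenic panel
#'
#' Non-prime-side sequences of the succinylated pNA substrates used to read
#' out primary specificity (chymase, elastase, tryptase and asp-ase
#' substrates).
#'
#' @return Data.frame with columns `substrate_id` and `sequence`.
#' @export
default_chromogenic_panel <- function() {
  data.frame(
    substrate_id = c("Suc-AAPF-pNA", "Suc-LLVY-pNA", "Suc-AAPI-pNA",
                     "Suc-AAPA-pNA", "Suc-AAPL-pNA", "Suc-AAPV-pNA",
                     "Suc-VLGR-pNA", "Suc-GPR-pNA", "Suc-YVAD-pNA",
                     "Suc-VEID-pNA", "Suc-IEPD-pNA"),
    sequence = c("AAPF", "LLVY", "AAPI", "AAPA", "AAPL", "AAPV",
                 "VLGR", "GPR", "YVAD", "VEID", "IEPD")
  )
}

# Log-odds score of a non-prime substrate sequence (last residue at P1)
# against the columns a truth pwm shares with it, plus the maximal
# achievable score over the same columns.
nonprime_score <- function(pwm, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  k <- length(chars)
  labs <- offset_plabel(seq.int(-(k - 1L), 0L))
  use <- labs %in% pwm$positions
  cols <- match(labs[use], pwm$positions)
  ix <- match(chars[use], aa_alphabet())
  s <- sum(pwm$weights[cbind(ix, cols)])
  s_max <- sum(apply(pwm$weights[, cols, drop = FALSE], 2, max))
  c(score = s, max = s_max)
}

#' Simulate one absorbance series with a planted slope
#'
#' @param substrate_id,sequence Substrate identity.
#' @param rate Planted slope (AU/min).
#' @param times Measurement times (minutes).
#' @param noise Gaussian reading noise (AU).
#' @param blank_level Baseline absorbance.
#' @param n_replicates Replicates (three in the standard assay).
#' @param seed Optional seed.
#' @return An [absorbance_series()].
#' @export
simulate_absorbance_series <- function(substrate_id, sequence, rate,
                                       times = c(0, 20, 40, 60, 120, 180,
                                                 240, 300, 360),
                                       noise = 1e-4, blank_level = 0.05,
                                       n_replicates = 3L, seed = NULL) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_replicates), function(r) {
      blank_level + rate * times + rnorm(length(times), 0, noise)
    }, numeric(length(times)))
    blank <- blank_level + rnorm(length(times), 0, noise)
    absorbance_series(substrate_id, sequence, times, reps, blank)
  })
}

#' Simulate one cleavage time course with a planted rate
#'
#' @param k Planted first-order rate (per minute).
#' @param substrate_name,insert_sequence Substrate identity.
#' @param times Sampling times (minutes).
#' @param noise Gaussian noise on fractions (clamped to `[0, 1]`).
#' @param seed Optional seed.
#' @return A [cleavage_time_course()].
#' @export
simulate_time_course <- function(k, substrate_name = "substrate",
                                 insert_sequence = "VVRRRAAAG",
                                 times = c(0, 15, 45, 150), noise = 0.02,
                                 seed = NULL) {
  with_seed(seed, {
    f <- 1 - exp(-k * times) + rnorm(length(times), 0, noise)
    f[times == 0] <- 0
    cleavage_time_course(substrate_name, insert_sequence, times,
                         pmin(pmax(f, 0), 1))
  })
}

#' Simulate a pair of enzyme titration curves with a planted fold
#'
#' Both curves share a logistic dose response on log-amount; curve b needs
#' `fold` times more enzyme than curve a for the same extent of cleavage.
#'
#' @param fold Planted fold difference (> 0).
#' @param amounts Enzyme amounts of curve a; curve b uses the same grid
#'   scaled by `fold`.
#' @param midpoint_a Amount giving 50 percent cleavage on curve a.
#' @param width Logistic width in log10-amount units.
#' @param noise Gaussian noise on fractions.
#' @param seed Optional seed.
#' @return List with data.frames `a` and `b` (columns `amount`, `fraction`).
#' @export
simulate_titration_pair <- function(fold, amounts = 10^seq(-3, 2,
                                                           length.out = 21),
                                    midpoint_a = 0.03, width = 0.5,
                                    noise = 0, seed = NULL) {
  with_seed(seed, {
    mk <- function(grid, midpoint) {
      f <- stats::plogis((log10(grid) - log10(midpoint)) / width) +
        rnorm(length(grid), 0, noise)
      data.frame(amount = grid, fraction = pmin(pmax(f, 0), 1))
    }
    list(a = mk(amounts, midpoint_a),
         b = mk(amounts * fold, midpoint_a * fold))
  })
}

#' Simulate the full assay readout for a planted enzyme model
#'
#' Chromogenic series get planted slopes proportional to
#' `2^(score - score_max)` of the substrate's non-prime sequence under the
#' model's weight matrix; time courses get first-order rates proportional to
#' `2^(best insert score - maximal score)`.
#'
#' @param truth A `"truth_model"` with a weight matrix.
#' @param panel Chromogenic panel ([default_chromogenic_panel()] layout).
#' @param tc_inserts Named character vector of time-course linker inserts;
#'   `NULL` uses the model's modal window plus a 1-mismatch variant.
#' @param rate_max Slope of the optimal chromogenic substrate (AU/min).
#' @param k_max First-order rate of the optimal linker (per minute).
#' @param noise_abs,noise_frac Gaussian noise levels for absorbances and
#'   fractions.
#' @param seed Optional seed.
#' @return List: `absorbance` (list of [absorbance_series()]), `courses`
#'   (list of [cleavage_time_course()]), `planted` (data.frame of planted
#'   rates).
#' @export
simulate_assays <- function(truth, panel = default_chromogenic_panel(),
                            tc_inserts = NULL, rate_max = 0.002,
                            k_max = 0.06, noise_abs = 1e-4,
                            noise_frac = 0.02, seed = NULL) {
  if (is.null(truth$pwm)) stop("truth model has no weight matrix")
  with_seed(seed, {
    absorbance <- vector("list", nrow(panel))
    planted <- data.frame(substrate = character(), kind = character(),
                          rate = numeric())
    for (i in seq_len(nrow(panel))) {
      sc <- nonprime_score(truth$pwm, panel$sequence[i])
      rate <- rate_max * 2^(sc["score"] - sc["max"])
      absorbance[[i]] <- simulate_absorbance_series(
        panel$substrate_id[i], panel$sequence[i], rate, noise = noise_abs)
      planted <- rbind(planted,
                       data.frame(substrate = panel$substrate_id[i],
                                  kind = "chromogenic", rate = rate))
    }
    if (is.null(tc_inserts)) {
      modal9 <- substring(paste0(modal_window(truth$pfm),
                                 strrep("A", 9)), 1, 9)
      tc_inserts <- c(optimal = modal9,
                      variant = mutate_window_insert(modal9, truth))
    }
    courses <- vector("list", length(tc_inserts))
    smax <- sum(apply(truth$pwm$weights, 2, max))
    for (i in seq_along(tc_inserts)) {
      s <- best_insert_score(tc_inserts[i], truth$pwm)$score
      k <- k_max * 2^(s - smax)
      courses[[i]] <- simulate_time_course(
        k, substrate_name = names(tc_inserts)[i],
        insert_sequence = tc_inserts[i], noise = noise_frac)
      planted <- rbind(planted,
                       data.frame(substrate = names(tc_inserts)[i],
                                  kind = "time-course", rate = k))
    }
    list(absorbance = absorbance, courses = courses, planted = planted)
  })
}

# One-mismatch variant of a nonamer insert w.r.t. a truth model's pattern,
# mutated at the most informative mutable subsite that maps into the insert.
mutate_window_insert <- function(insert, truth) {
  win <- modal_window(truth$pfm)
  mutated <- mutate_window(win, truth$pattern, 1L)
  chars <- strsplit(insert, "")[[1]]
  wchars <- strsplit(mutated, "")[[1]]
  chars[seq_along(wchars)] <- wchars
  paste(chars[1:9], collapse = "")
}
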