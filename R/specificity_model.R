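# Position-specific cleavage specificity models: frequency matrices built from
# aligned cleavage windows, log-odds weight matrices, per-subsite information
# content, degenerate consensus patterns, and primary-specificity calls.

#' Construct a position frequency matrix
#'
#' Frequencies follow the pseudocount rule
#' `(counts + pseudocount) / (n + 20 * pseudocount)` per column, so every
#' column sums to one and no residue has zero frequency when
#' `pseudocount > 0`.
#'
#' @param counts 20 x W matrix of (possibly fractional) residue counts, rows
#'   in [aa_alphabet()] order, columns labeled by subsite.
#' @param pseudocount Non-negative per-residue pseudocount (default 0.5, a
#'   Jeffreys-like choice).
#' @param n_sequences Number of sequences behind the counts; defaults to the
#'   first column sum.
#' @return An object of class `"subsite_pfm"`.
#' @export
position_frequency_matrix <- function(counts, pseudocount = 0.5,
                                      n_sequences = NULL) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (nrow(counts) != 20) stop("counts must have 20 rows")
  if (is.null(rownames(counts))) rownames(counts) <- aa_alphabet()
  positions <- colnames(counts)
  check_window_positions(positions)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(n_sequences)) n_sequences <- sum(counts[, 1])
  denom <- n_sequences + 20 * pseudocount
  if (denom <= 0) stop("need n_sequences > 0 or pseudocount > 0")
  freq <- sweep(counts + pseudocount, 2, rep(denom, ncol(counts)), "/")
  structure(
    list(positions = positions, frequencies = freq, counts = counts,
         pseudocount = pseudocount, n_sequences = n_sequences),
    class = "subsite_pfm"
  )
}

#' @export
print.subsite_pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d subsites (%s), n = %s, pseudocount = %g\n",
              length(x$positions), paste(x$positions, collapse = " "),
              format(x$n_sequences), x$pseudocount))
  ic <- information_content(x)
  cat("information content (bits):",
      paste(sprintf("%s=%.2f", x$positions, ic), collapse = " "), "\n")
  invisible(x)
}

#' Build a frequency matrix from an aligned cleavage set
#'
#' Counts are hard-assignment counts: exactly one window per peptide, taken
#' from the final register assignments.
#'
#' @param aligned An `"aligned_cleavage_set"` from [align_registers()].
#' @param pseudocount Per-residue pseudocount.
#' @return A `"subsite_pfm"`.
#' @export
build_pfm <- function(aligned, pseudocount = 0.5) {
  windows <- aligned$assignments$window
  if (length(windows) == 0) stop("aligned set is empty")
  counts_from_windows(windows, aligned$window_positions, pseudocount)
}

counts_from_windows <- function(windows, positions, pseudocount = 0.5) {
  W <- length(positions)
  counts <- matrix(0, nrow = 20, ncol = W,
                   dimnames = list(aa_alphabet(), positions))
  idx <- vapply(windows, aa_to_int, integer(W))
  for (j in seq_len(W)) {
    tab <- tabulate(idx[j, ], nbins = 20)
    counts[, j] <- tab
  }
  position_frequency_matrix(counts, pseudocount, n_sequences = length(windows))
}

#' Convert a frequency matrix to a log-odds weight matrix
#'
#' Weights are `log2(frequency / background)` elementwise: zero for a residue
#' at its background frequency, finite everywhere when the frequency matrix
#' was built with a positive pseudocount.
#'
#' @param pfm A `"subsite_pfm"`.
#' @param background Background composition (length-20, strictly positive,
#'   sums to 1); default uniform 1/20.
#' @return An object of class `"subsite_pwm"`.
#' @export
pfm_to_pwm <- function(pfm, background = NULL) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be a strictly positive length-20 composition summing to 1")
  }
  if (any(pfm$frequencies == 0)) {
    stop("zero frequencies in matrix: rebuild with a positive pseudocount")
  }
  weights <- log2(pfm$frequencies / background)
  structure(
    list(positions = pfm$positions, weights = weights, background = background),
    class = "subsite_pwm"
  )
}

#' @export
print.subsite_pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix (log2 odds): %d subsites (%s)\n",
              length(x$positions), paste(x$positions, collapse = " ")))
  top <- apply(x$weights, 2, function(w) rownames(x$weights)[which.max(w)])
  cat("top residue per subsite:",
      paste(sprintf("%s:%s", x$positions, top), collapse = " "), "\n")
  invisible(x)
}

#' Per-subsite information content
#'
#' Kullback-Leibler divergence, in bits, of each matrix column from the
#' background composition; quantifies the selectivity of each subsite.
#'
#' @inheritParams pfm_to_pwm
#' @return Named numeric vector (bits), one entry per subsite; non-negative.
#' @export
information_content <- function(pfm, background = NULL) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  f <- pfm$frequencies
  term <- f * log2(sweep(f, 1, background, "/"))
  term[f == 0] <- 0
  pmax(colSums(term), 0)
}

#' The position-wise modal window of a frequency matrix
#'
#' @param pfm A `"subsite_pfm"`.
#' @return Single string: the most frequent residue at every subsite.
#' @export
modal_window <- function(pfm) {
  paste(rownames(pfm$frequencies)[apply(pfm$frequencies, 2, which.max)],
        collapse = "")
}

#' Derive a degenerate consensus pattern from a frequency matrix
#'
#' Per subsite: a residue with frequency at or above `majority_threshold`
#' becomes an allowed singleton; otherwise a chemical class (basic KR, acidic
#' DE, aromatic FYW, aliphatic AVIL, small GST) whose summed frequency reaches
#' `class_threshold` becomes the allowed set; otherwise the subsite is
#' unconstrained. P1 is always a hard-required position. A residue class whose
#' summed frequency stays at or below `forbid_threshold` at every subsite is
#' recorded as forbidden within `forbid_radius` residues of P1 (this captures
#' selections that strikingly avoid, say, negatively charged residues near the
#' scissile bond).
#'
#' @param pfm A `"subsite_pfm"`.
#' @param majority_threshold Singleton threshold in (0, 1]; default 0.6.
#' @param class_threshold Class threshold in (0, 1]; default 0.7.
#' @param forbid_threshold Maximal per-subsite class mass for a forbidden
#'   class; default 0.02.
#' @param forbid_radius Radius (residues around P1) of forbidden-class checks.
#' @param max_mismatches Allowed mismatches at non-required subsites.
#' @param required Subsites that are hard constraints; P1 is always added.
#' @return An object of class `"consensus_pattern"`.
#' @export
derive_consensus <- function(pfm, majority_threshold = 0.6,
                             class_threshold = 0.7, forbid_threshold = 0.02,
                             forbid_radius = 3L, max_mismatches = 1L,
                             required = character()) {
  if (majority_threshold <= 0 || majority_threshold > 1 ||
      class_threshold <= 0 || class_threshold > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  classes <- residue_classes()
  allowed <- vector("list", length(pfm$positions))
  names(allowed) <- pfm$positions
  for (j in seq_along(pfm$positions)) {
    col <- pfm$frequencies[, j]
    if (max(col) >= majority_threshold) {
      allowed[[j]] <- names(col)[which.max(col)]
      next
    }
    class_mass <- vapply(classes, function(set) sum(col[set]), numeric(1))
    if (max(class_mass) >= class_threshold) {
      allowed[[j]] <- classes[[which.max(class_mass)]]
    } else {
      allowed[j] <- list(NULL)   # unconstrained
    }
  }
  forbidden <- list()
  for (cls in names(classes)) {
    mass <- vapply(seq_along(pfm$positions), function(j) {
      sum(pfm$frequencies[classes[[cls]], j])
    }, numeric(1))
    if (all(mass <= forbid_threshold)) {
      forbidden[[length(forbidden) + 1]] <-
        list(residues = classes[[cls]], radius = as.integer(forbid_radius))
    }
  }
  consensus_pattern(positions = pfm$positions, allowed = allowed,
                    required = union("P1", required), forbidden = forbidden,
                    max_mismatches = max_mismatches)
}

#' Construct a consensus pattern
#'
#' @param positions Ordered subsite labels.
#' @param allowed Named list, one entry per subsite: a character vector of
#'   allowed residues, or `NULL` for an unconstrained subsite.
#' @param required Subsite labels that are hard constraints (P1 always is).
#' @param forbidden List of `list(residues =, radius =)` exclusions applied
#'   within `radius` residues of P1.
#' @param max_mismatches Allowed mismatches over non-required subsites.
#' @return An object of class `"consensus_pattern"`.
#' @export
consensus_pattern <- function(positions, allowed, required = "P1",
                              forbidden = list(), max_mismatches = 1L) {
  check_window_positions(positions)
  required <- union("P1", required)
  if (!all(required %in% positions)) {
    stop("required subsites must be part of the pattern positions")
  }
  if (length(allowed) != length(positions)) {
    stop("'allowed' must have one entry per position")
  }
  names(allowed) <- positions
  for (r in forbidden) {
    if (r$radius < 0) stop("forbidden-class radius must be >= 0")
  }
  structure(
    list(positions = positions, allowed = allowed, required = required,
         forbidden = forbidden, max_mismatches = as.integer(max_mismatches)),
    class = "consensus_pattern"
  )
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat("Consensus pattern:", format_pattern(x), "\n")
  invisible(x)
}

#' Serialize / parse the consensus pattern grammar
#'
#' The compact grammar is part of the public contract and round-trips
#' losslessly, e.g. `"P4:[FYW] P3:D P2:. P1:D! P1':. ; forbid[DE]+-3 ; mm<=1"`:
#' `.` marks an unconstrained subsite, `[..]` an allowed set, a trailing `!` a
#' hard-required subsite, `forbid[..]+-r` a residue class forbidden within
#' `r` residues of P1, and `mm<=k` the mismatch budget.
#'
#' @param pattern A `"consensus_pattern"`.
#' @return `format_pattern()`: single string; `parse_pattern()`: the pattern.
#' @export
format_pattern <- function(pattern) {
  pos_tok <- vapply(seq_along(pattern$positions), function(j) {
    lab <- pattern$positions[j]
    set <- pattern$allowed[[j]]
    spec <- if (is.null(set)) "." else if (length(set) == 1) set else
      paste0("[", paste(set, collapse = ""), "]")
    paste0(lab, ":", spec, if (lab %in% pattern$required) "!" else "")
  }, character(1))
  forb_tok <- vapply(pattern$forbidden, function(f) {
    paste0("forbid[", paste(f$residues, collapse = ""), "]+-", f$radius)
  }, character(1))
  paste(c(paste(pos_tok, collapse = " "), forb_tok,
          paste0("mm<=", pattern$max_mismatches)), collapse = " ; ")
}

#' @rdname format_pattern
#' @param text Pattern grammar string.
#' @export
parse_pattern <- function(text) {
  text <- gsub("±", "+-", text)
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  if (length(parts) == 0 || !nzchar(parts[1])) stop("empty pattern grammar")
  pos_tok <- strsplit(parts[1], "\\s+")[[1]]
  tok_re <- "^(P[0-9]+'?):(\\.|[A-Z]|\\[[A-Z]+\\])(!?)$"
  positions <- character(length(pos_tok))
  allowed_full <- vector("list", length(pos_tok))
  required <- character(0)
  for (k in seq_along(pos_tok)) {
    g <- regmatches(pos_tok[k], regexec(tok_re, pos_tok[k]))[[1]]
    if (length(g) == 0) {
      stop(sprintf("pattern grammar: cannot parse token %d ('%s')",
                   k, pos_tok[k]))
    }
    positions[k] <- g[2]
    spec <- g[3]
    allowed_full[k] <- if (spec == ".") list(NULL) else
      list(strsplit(gsub("\\[|\\]", "", spec), "")[[1]])
    if (g[4] == "!") required <- c(required, g[2])
  }
  forbidden <- list(); mm <- 0L
  for (p in parts[-1]) {
    if (grepl("^forbid\\[", p)) {
      g <- regmatches(p, regexec("^forbid\\[([A-Z]+)\\]\\+-([0-9]+)$", p))[[1]]
      if (length(g) == 0) {
        stop("pattern grammar: cannot parse forbid clause '", p, "'")
      }
      forbidden[[length(forbidden) + 1]] <-
        list(residues = strsplit(g[2], "")[[1]], radius = as.integer(g[3]))
    } else if (grepl("^mm<=", p)) {
      mm <- as.integer(sub("^mm<=", "", p))
    } else {
      stop("pattern grammar: unknown clause '", p, "'")
    }
  }
  consensus_pattern(positions = positions, allowed = allowed_full,
                    required = required, forbidden = forbidden,
                    max_mismatches = mm)
}

#' Primary-specificity call from a weight matrix
#'
#' Per-class evidence is the summed P1 frequency over the class P1 sets
#' (tryptase K/R, chymase F/Y/W, asp-ase D/E, elastase A/V/I/L). Classes with
#' evidence at or above `relative_threshold` times the best class qualify,
#' provided the best class reaches `absolute_threshold`; tryptase and chymase
#' qualifying together yield the dual call; no class reaching the absolute
#' threshold yields `"undetermined"`.
#'
#' @param pwm A `"subsite_pwm"` (P1 column required).
#' @param absolute_threshold Minimal best-class P1 mass; default 0.4.
#' @param relative_threshold Fraction of the best class a second class needs
#'   to co-qualify; default 0.5.
#' @return An object of class `"specificity_call"` with fields `label`,
#'   `evidence` (per class, in `[0, 1]`) and `source`.
#' @export
classify_specificity_from_pwm <- function(pwm, absolute_threshold = 0.4,
                                          relative_threshold = 0.5) {
  if (!"P1" %in% pwm$positions) stop("P1 column required")
  p1 <- 2^pwm$weights[, "P1"] * pwm$background
  evidence <- vapply(specificity_classes(), function(set) sum(p1[set]),
                     numeric(1))
  specificity_call_from_evidence(evidence, "pwm",
                                 absolute_threshold, relative_threshold)
}

specificity_call_from_evidence <- function(evidence, source,
                                           absolute_threshold = 0.4,
                                           relative_threshold = 0.5) {
  best <- max(evidence)
  if (best < absolute_threshold) {
    label <- "undetermined"
  } else {
    qualifying <- names(evidence)[evidence >= relative_threshold * best]
    label <- if (all(c("tryptase", "chymase") %in% qualifying)) {
      "dual(tryptase+chymase)"
    } else {
      names(evidence)[which.max(evidence)]
    }
  }
  structure(list(label = label, evidence = evidence, source = source),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("Primary specificity: %s (source: %s)\n", x$label, x$source))
  cat("evidence:",
      paste(sprintf("%s=%.3f", names(x$evidence), x$evidence), collapse = " "),
      "\n")
  invisible(x)
}
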