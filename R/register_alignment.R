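# Inference of the cleavage register: where, within each selected phage
# nonamer, the scissile bond sat. Each insert is embedded in the fixed capsid
# context (n-flank "PGG", c-flank "HHHHHH"); every admissible P1 placement
# inside the insert defines one candidate window, and a one-cleavage-site-
# per-sequence expectation maximization picks the register jointly with the
# specificity matrix it implies.

#' Fixed capsid context around the randomized insert
#'
#' @param n_flank Fixed residues preceding the insert.
#' @param c_flank Fixed residues following the insert (the His6 anchor).
#' @return An object of class `"library_context"`.
#' @export
library_context <- function(n_flank = "PGG", c_flank = "HHHHHH") {
  for (fl in c(n_flank, c_flank)) {
    if (nzchar(fl) && !is_valid_aa(fl)) {
      stop("flank is not a valid amino-acid string: ", fl)
    }
  }
  structure(list(n_flank = n_flank, c_flank = c_flank),
            class = "library_context")
}

#' Candidate cleavage registers for one insert
#'
#' P1 placements are restricted to the insert positions: cleavage within the
#' fixed flanks could not vary across clones and cannot be selected for.
#' Windows reaching into the flanks are filled from the flank residues;
#' placements whose window would run past the flanked sequence are dropped.
#'
#' @param peptide Insert sequence (string over the 20-letter alphabet).
#' @param context A [library_context()].
#' @param window_positions Contiguous subsite labels containing P1.
#' @return Data.frame with columns `p1_index` (1-based position of P1 within
#'   `n_flank + insert + c_flank`) and `window`.
#' @export
candidate_registers <- function(peptide, context = library_context(),
                                window_positions = subsite_window()) {
  off <- check_window_positions(window_positions)
  if (!is_valid_aa(peptide)) {
    stop("peptide contains non-amino-acid characters: ", peptide)
  }
  extended <- paste0(context$n_flank, peptide, context$c_flank)
  L <- nchar(extended)
  W <- length(off)
  if (W > L) {
    stop(sprintf("window (%d) wider than flanked sequence (%d)", W, L))
  }
  nf <- nchar(context$n_flank)
  p1_candidates <- (nf + 1L):(nf + nchar(peptide))
  ok <- p1_candidates + off[1] >= 1L & p1_candidates + off[W] <= L
  p1_candidates <- p1_candidates[ok]
  if (length(p1_candidates) == 0) {
    stop("no admissible register: window does not fit around any insert position")
  }
  windows <- substring(extended, p1_candidates + off[1], p1_candidates + off[W])
  data.frame(p1_index = p1_candidates, window = windows)
}

# Integer residue indices of every candidate window of every peptide, plus a
# mask marking which window positions fall inside the randomized insert.
# Fixed flank residues cannot be selected on, so only insert-derived window
# positions enter the alignment likelihood; flank positions score as
# background.
register_candidates_all <- function(peptides, context, window_positions) {
  cands <- lapply(peptides, candidate_registers, context = context,
                  window_positions = window_positions)
  n_cand <- vapply(cands, nrow, integer(1))
  windows <- unlist(lapply(cands, `[[`, "window"), use.names = FALSE)
  p1 <- unlist(lapply(cands, `[[`, "p1_index"), use.names = FALSE)
  W <- length(window_positions)
  off <- plabel_offset(window_positions)
  idx <- t(vapply(windows, aa_to_int, integer(W)))
  nf <- nchar(context$n_flank)
  pep <- rep(seq_along(peptides), n_cand)
  ins_len <- nchar(peptides)[pep]
  mask <- matrix(FALSE, nrow = length(p1), ncol = W)
  for (j in seq_len(W)) {
    pos <- p1 + off[j]
    mask[, j] <- pos >= nf + 1L & pos <= nf + ins_len
  }
  list(
    pep = pep,
    p1 = p1,
    window = windows,
    idx = idx,
    mask = mask,
    n_cand = n_cand,
    ext_idx = lapply(peptides, function(p) {
      aa_to_int(paste0(context$n_flank, p, context$c_flank))
    })
  )
}

# Window log-odds scores for all (peptide, register) rows given log-ratio
# matrix (20 x W); flank-derived positions contribute zero.
candidate_scores <- function(cand, logratio) {
  s <- numeric(nrow(cand$idx))
  for (j in seq_len(ncol(cand$idx))) {
    s <- s + logratio[cand$idx[, j], j] * cand$mask[, j]
  }
  s
}

# Soft count matrix from per-row weights, insert-derived positions only.
soft_counts <- function(cand, q, W) {
  counts <- matrix(0, nrow = 20, ncol = W)
  for (j in seq_len(W)) {
    qj <- q * cand$mask[, j]
    counts[, j] <- vapply(seq_len(20), function(k) {
      sum(qj[cand$idx[, j] == k])
    }, numeric(1))
  }
  counts
}

# Completed-data log-likelihood of a hard assignment (rows of cand):
# insert-derived window residues score under the pseudocount-smoothed column
# frequencies (per-column effective totals), every other residue of the
# flanked sequence scores under the background.
completed_loglik <- function(cand, rows, pseudocount, log_bg) {
  W <- ncol(cand$idx)
  counts <- matrix(0, nrow = 20, ncol = W)
  for (j in seq_len(W)) {
    sel <- rows[cand$mask[rows, j]]
    counts[, j] <- tabulate(cand$idx[sel, j], nbins = 20)
  }
  coltot <- colSums(counts)
  f <- sweep(counts + pseudocount, 2, coltot + 20 * pseudocount, "/")
  const <- sum(vapply(cand$ext_idx, function(ix) sum(log_bg[ix]), numeric(1)))
  const + sum(counts * (log(f) - log_bg))
}

# Flank-masked frequency estimate of a hard assignment: per-column
# insert-derived counts, smoothed by an empirical-Bayes Dirichlet prior
# whose strength is chosen per column by maximizing the Dirichlet-
# multinomial marginal likelihood against the background. Uninformative
# columns shrink hard toward the background; selective columns barely. This
# is the estimator of the planted specificity; build_pfm() in contrast
# tabulates the full padded windows with the fixed pseudocount rule.
pfm_from_masked_counts <- function(cand, rows, positions, pseudocount,
                                   background = rep(1 / 20, 20)) {
  W <- length(positions)
  counts <- matrix(0, nrow = 20, ncol = W,
                   dimnames = list(aa_alphabet(), positions))
  for (j in seq_len(W)) {
    sel <- rows[cand$mask[rows, j]]
    counts[, j] <- tabulate(cand$idx[sel, j], nbins = 20)
  }
  freq <- apply(counts, 2, eb_column_frequencies, background = background,
                alpha_min = 20 * pseudocount)
  dimnames(freq) <- dimnames(counts)
  structure(
    list(positions = positions, frequencies = freq, counts = counts,
         pseudocount = pseudocount, n_sequences = length(rows)),
    class = "subsite_pfm"
  )
}

# Posterior-mean column frequencies under a Dirichlet(alpha * background)
# prior with alpha chosen by marginal likelihood (floored at the fixed
# pseudocount total so no residue is ever assigned zero frequency).
eb_column_frequencies <- function(c_k, background, alpha_min = 10) {
  n <- sum(c_k)
  if (n == 0) return(background)
  marg <- function(log_alpha) {
    a <- exp(log_alpha) * background
    lgamma(sum(a)) - lgamma(n + sum(a)) +
      sum(lgamma(c_k + a) - lgamma(a))
  }
  opt <- optimize(marg, c(log(max(alpha_min, 1e-3)), log(1e6)),
                  maximum = TRUE)
  alpha <- max(exp(opt$maximum), alpha_min)
  (c_k + alpha * background) / (n + alpha)
}

# With a positive pseudocount the M-step is a MAP (Dirichlet-regularized)
# update, so the monotone quantity is the penalized marginal log-likelihood
# (marginal plus the Dirichlet log-prior term); that is what the trace holds.
em_run <- function(cand, q, n, W, pseudocount, background, max_iter, tol,
                   bonus = NULL) {
  if (is.null(bonus)) bonus <- numeric(nrow(cand$idx))
  log_bg <- log(background)
  trace <- numeric(0)
  ll_prev <- -Inf
  grp <- cand$pep
  for (iter in seq_len(max_iter)) {
    counts <- soft_counts(cand, q, W)
    f <- sweep(counts + pseudocount, 2, colSums(counts) + 20 * pseudocount, "/")
    logratio <- log(f) - log_bg
    s <- candidate_scores(cand, logratio) + bonus
    # log-sum-exp per peptide (register prior = anchor bonus, if any)
    mx <- tapply(s, grp, max)
    lse <- log(tapply(exp(s - mx[grp]), grp, sum)) + mx
    ll <- sum(lse - log(cand$n_cand)) + pseudocount * sum(log(f))
    trace <- c(trace, ll)
    q <- exp(s - lse[grp])
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
  }
  list(q = q, loglik = ll, trace = trace, iterations = iter,
       scores = s, lse = lse)
}

#' Align selected peptides into a common cleavage register
#'
#' One-cleavage-site-per-sequence expectation maximization (in the spirit of
#' the OOPS motif model): the E-step computes register posteriors proportional
#' to the exponentiated window log-odds under the current matrix, the M-step
#' re-estimates the frequency matrix from the posterior-weighted windows with
#' pseudocounts. The marginal log-likelihood is non-decreasing across
#' iterations. Several seeded random starts plus one start from the
#' most-informative-column heuristic guard against local optima; the best run
#' is hardened to per-peptide argmax registers (ties toward the smallest
#' `p1_index`) and polished by coordinate ascent on the completed-data
#' log-likelihood, which is also the reported `objective` (directly comparable
#' to [brute_force_alignment()]).
#'
#' @param peptides Character vector of insert sequences, or a peptide table
#'   from [read_peptide_table()].
#' @param context A [library_context()].
#' @param window_positions Contiguous subsite labels containing P1.
#' @param pseudocount Per-residue pseudocount; default 0.5.
#' @param background Length-20 background composition; default uniform.
#' @param max_iter Maximal EM iterations per start.
#' @param tol Convergence tolerance on the marginal log-likelihood.
#' @param n_starts Number of random restarts (besides the heuristic start).
#' @param seed Integer seed controlling the random restarts.
#' @param p1_anchor Optional character vector of residues favored at P1,
#'   applied as a soft register prior (a log-bonus of `anchor_weight` for
#'   registers placing one of these residues at P1). Phage display leaves the
#'   cleavage register identifiable only up to a shift when selected motifs
#'   crowd one end of the insert; anchoring P1 with the primary specificity
#'   read off a chromogenic panel (see
#'   [classify_specificity_from_rates()]) resolves it, mirroring how such
#'   alignments are anchored in practice.
#' @param anchor_weight Log (natural) bonus of the anchor prior.
#' @return An `"aligned_cleavage_set"`: `assignments` (peptide, `p1_index`,
#'   `window`, `posterior`, `entropy` in bits), `window_positions`,
#'   `objective` (completed-data log-likelihood of the hard assignments,
#'   plus the anchor bonus if any), `loglik_trace` of the winning run,
#'   `iterations`, the full-window hard-count `pfm` and the flank-masked
#'   estimator `pfm_insert`.
#' @export
align_registers <- function(peptides, context = library_context(),
                            window_positions = subsite_window(),
                            pseudocount = 0.5, background = NULL,
                            max_iter = 200L, tol = 1e-8, n_starts = 10L,
                            seed = 1L, p1_anchor = NULL, anchor_weight = 2) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) < 2) stop("need at least 2 peptides")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (is.null(background)) background <- rep(1 / 20, 20)
  bad <- !is_valid_aa(peptides)
  if (any(bad)) {
    stop("non-amino-acid characters in peptide(s): ",
         paste(head(peptides[bad], 3), collapse = ", "))
  }
  cand <- register_candidates_all(peptides, context, window_positions)
  n <- length(peptides)
  W <- length(window_positions)
  log_bg <- log(background)
  bonus <- anchor_bonus(cand, window_positions, p1_anchor, anchor_weight)

  starts <- list()
  # heuristic start: pool all candidate windows, find the most informative
  # column, and hard-assign each peptide to the register whose residue there
  # has the highest pooled frequency
  q0 <- 1 / cand$n_cand[cand$pep]
  pooled_counts <- soft_counts(cand, q0, W)
  dimnames(pooled_counts) <- list(aa_alphabet(), window_positions)
  pooled <- position_frequency_matrix(pooled_counts,
                                      pseudocount = pseudocount,
                                      n_sequences = n)
  j_star <- which.max(information_content(pooled, background))
  pref <- pooled$frequencies[, j_star]
  q_h <- numeric(nrow(cand$idx))
  for (i in seq_len(n)) {
    rows <- which(cand$pep == i)
    best <- rows[which.max(pref[cand$idx[rows, j_star]])]
    q_h[best] <- 1
  }
  starts[[1]] <- q_h

  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (s in seq_len(n_starts)) {
    g <- rgamma(nrow(cand$idx), shape = 1)
    tot <- tapply(g, cand$pep, sum)
    starts[[s + 1]] <- g / tot[cand$pep]
  }

  # run every start to convergence, harden it (argmax posterior, ties toward
  # the N-terminal-most P1) and polish by coordinate ascent; the winner is
  # the start with the best completed-data objective, with the penalized
  # marginal as the recorded trace
  best_run <- NULL
  best_obj <- -Inf
  hard <- NULL
  for (q in starts) {
    run <- em_run(cand, q, n, W, pseudocount, background, max_iter, tol,
                  bonus = bonus)
    h <- integer(n)
    for (i in seq_len(n)) {
      rows <- which(cand$pep == i)
      qi <- run$q[rows]
      h[i] <- rows[which(qi >= max(qi) - 1e-12)[1]]
    }
    h <- icm_polish(cand, h, n, pseudocount, log_bg, bonus)
    obj <- completed_loglik(cand, h, pseudocount, log_bg) + sum(bonus[h])
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best_run <- run
      hard <- h
    }
  }
  # random-restart coordinate ascent complements the EM starts on the
  # rugged landscapes of very small samples (same seeded stream)
  offsets0 <- c(0L, cumsum(cand$n_cand))
  for (s in if (n <= 12) seq_len(10L * n_starts) else integer(0)) {
    h <- offsets0[seq_len(n)] +
      vapply(cand$n_cand, function(k) sample.int(k, 1), integer(1))
    h <- icm_polish(cand, h, n, pseudocount, log_bg, bonus)
    obj <- completed_loglik(cand, h, pseudocount, log_bg) + sum(bonus[h])
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      hard <- h
    }
  }

  # canonicalize the global register shift: whole-solution shifts are exact
  # likelihood ties whenever motif and anchor leave slack; among feasible
  # shifts within 1e-6 of the best (anchored) objective, center the
  # information-weighted columns on P1, then prefer the smaller |shift|
  canon <- canonical_shift(cand, hard, n, window_positions, pseudocount,
                           log_bg, bonus)
  hard <- canon$hard
  objective <- completed_loglik(cand, hard, pseudocount, log_bg) +
    sum(bonus[hard])
  posterior <- best_run$q[hard]
  entropy <- vapply(seq_len(n), function(i) {
    qi <- best_run$q[cand$pep == i]
    qi <- qi[qi > 0]
    -sum(qi * log2(qi))
  }, numeric(1))

  assignments <- data.frame(
    peptide = peptides,
    p1_index = cand$p1[hard],
    window = cand$window[hard],
    posterior = posterior,
    entropy = entropy
  )
  pfm <- counts_from_windows(assignments$window, window_positions, pseudocount)
  pfm_insert <- pfm_from_masked_counts(cand, hard, window_positions,
                                       pseudocount)
  structure(
    list(assignments = assignments, window_positions = window_positions,
         objective = objective, objective_best = canon$best,
         loglik_trace = best_run$trace,
         iterations = best_run$iterations, pfm = pfm,
         pfm_insert = pfm_insert,
         context = context, background = background,
         pseudocount = pseudocount),
    class = "aligned_cleavage_set"
  )
}

# Greedy per-peptide coordinate ascent on the completed-data log-likelihood
# (plus anchor bonus), ties toward the N-terminal-most P1. Maintains the
# count table incrementally so each candidate evaluation is O(window width).
icm_polish <- function(cand, hard, n, pseudocount, log_bg, bonus,
                       max_sweeps = 50L) {
  W <- ncol(cand$idx)
  nmax <- n + 1L
  lg <- c(if (pseudocount > 0) pseudocount * log(pseudocount) else 0,
          (seq_len(n) + pseudocount) * log(seq_len(n) + pseudocount))
  ld <- log(0:n + 20 * pseudocount)
  counts <- matrix(0L, nrow = 20, ncol = W)
  for (j in seq_len(W)) {
    sel <- hard[cand$mask[hard, j]]
    counts[, j] <- tabulate(cand$idx[sel, j], nbins = 20)
  }
  coltot <- colSums(counts)
  # per-column pieces: obj_j = A_j - (tot_j + 20 pc) relief... kept simple:
  # A_j = sum_k (c+pc) log(c+pc) is monotone-equivalent to sum c log(c+pc)
  # up to assignment-independent terms only when totals are fixed, so use
  # the exact form sum_k c_kj (log(c_kj+pc) - log(tot_j+20pc) - log bg_k).
  cell <- function(c) ifelse(c > 0, c * log(c + pseudocount), 0)
  A <- colSums(matrix(cell(counts), nrow = 20))
  B <- colSums(counts * log_bg)
  objective <- function() sum(A - coltot * ld[coltot + 1L] - B)
  apply_row <- function(row, d) {
    for (j in seq_len(W)) {
      if (cand$mask[row, j]) {
        k <- cand$idx[row, j]
        c0 <- counts[k, j]
        c1 <- c0 + d
        A[j] <<- A[j] - cell(c0) + cell(c1)
        B[j] <<- B[j] + d * log_bg[k]
        counts[k, j] <<- c1
        coltot[j] <<- coltot[j] + d
      }
    }
  }
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      rows <- which(cand$pep == i)
      apply_row(hard[i], -1L)
      obj <- numeric(length(rows))
      for (ri in seq_along(rows)) {
        apply_row(rows[ri], +1L)
        obj[ri] <- objective() + bonus[rows[ri]]
        apply_row(rows[ri], -1L)
      }
      pick <- rows[which(obj >= max(obj) - 1e-12)[1]]
      apply_row(pick, +1L)
      if (pick != hard[i]) {
        hard[i] <- pick
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  hard
}

# Canonicalize the global register shift of a hard assignment. A shifted
# solution is an exact or near tie whenever the motif and anchor leave slack,
# and with finite samples the likelihood difference between equivalent shifts
# is pure sampling noise, so shifts are compared with a per-sequence
# tolerance: every global shift is tried (clamped to each peptide's
# admissible register block, then ICM-repaired); candidates within
# `tol_per_seq` log-units per peptide of the best objective are ties,
# resolved by centering the information-weighted columns on P1 and then by
# the lexicographically smallest register vector (basin-independent).
# A genuinely wrong shift loses at least one informative column, costing far
# more than the tolerance per peptide.
canonical_shift <- function(cand, hard, n, window_positions, pseudocount,
                            log_bg, bonus, tol_per_seq = 0.5) {
  offsets <- c(0L, cumsum(cand$n_cand))
  lo <- offsets[cand$pep[hard]] + 1L
  hi <- offsets[cand$pep[hard] + 1L]
  W <- length(window_positions)
  s_range <- (-(W - 1L)):(W - 1L)
  cands <- lapply(s_range, function(s) {
    if (s == 0L) return(hard)
    h0 <- pmin(pmax(hard + s, lo), hi)
    # re-cohere around the shifted register with a short EM restart before
    # the greedy polish, so the candidate is a coherent solution rather
    # than a per-peptide patchwork
    q0 <- numeric(nrow(cand$idx))
    q0[h0] <- 1
    run <- em_run(cand, q0, n, ncol(cand$idx), pseudocount,
                  exp(log_bg), 30L, 1e-8, bonus = bonus)
    h1 <- integer(n)
    for (i in seq_len(n)) {
      rows <- which(cand$pep == i)
      qi <- run$q[rows]
      h1[i] <- rows[which(qi >= max(qi) - 1e-12)[1]]
    }
    icm_polish(cand, h1, n, pseudocount, log_bg, bonus)
  })
  obj <- vapply(cands, function(h) {
    completed_loglik(cand, h, pseudocount, log_bg) + sum(bonus[h])
  }, numeric(1))
  best <- max(obj)
  tied <- which(obj >= best - tol_per_seq * n)
  if (length(tied) > 1) {
    off <- plabel_offset(window_positions)
    centroid <- vapply(tied, function(k) {
      pf <- pfm_from_masked_counts(cand, cands[[k]], window_positions,
                                   pseudocount)
      ic <- information_content(pf)
      if (sum(ic) <= 0) return(Inf)
      abs(sum(ic * off) / sum(ic))
    }, numeric(1))
    tied <- tied[centroid <= min(centroid) + 1e-9]
    if (length(tied) > 1) {
      keys <- vapply(tied, function(k) {
        paste(sprintf("%03d", cand$p1[cands[[k]]]), collapse = "")
      }, character(1))
      tied <- tied[order(keys)]
    }
  }
  list(hard = cands[[tied[1]]], best = best)
}

#' @export
print.aligned_cleavage_set <- function(x, ...) {
  cat(sprintf(
    "Aligned cleavage set: %d peptides, window %s, objective %.4f (%d EM iterations)\n",
    nrow(x$assignments),
    paste(x$window_positions[c(1, length(x$window_positions))],
          collapse = ".."),
    x$objective, x$iterations))
  cat(sprintf("mean register posterior %.3f, mean register entropy %.3f bits\n",
              mean(x$assignments$posterior), mean(x$assignments$entropy)))
  invisible(x)
}

#' Exhaustive register-assignment oracle
#'
#' Enumerates every joint hard register assignment and returns the global
#' maximum of the completed-data log-likelihood under the same pseudocount
#' rule as [align_registers()]. Intended as a validation oracle on tiny
#' instances; refuses more than 8 peptides.
#'
#' @inheritParams align_registers
#' @return An `"aligned_cleavage_set"` (posteriors are 1 by construction;
#'   `iterations` counts enumerated assignments).
#' @export
brute_force_alignment <- function(peptides, context = library_context(),
                                  window_positions = subsite_window(),
                                  pseudocount = 0.5, background = NULL,
                                  p1_anchor = NULL, anchor_weight = 2) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) > 8) {
    stop("brute_force_alignment refuses more than 8 peptides")
  }
  if (is.null(background)) background <- rep(1 / 20, 20)
  cand <- register_candidates_all(peptides, context, window_positions)
  n <- length(peptides)
  W <- length(window_positions)
  log_bg <- log(background)
  bonus <- anchor_bonus(cand, window_positions, p1_anchor, anchor_weight)
  # variable part of the completed log-likelihood, maximized in C++
  res <- bf_align_enumerate(cand$idx, cand$mask * 1L, cand$pep, cand$n_cand,
                            pseudocount, log_bg, bonus)
  hard_local <- res$assignment + 1L   # per-peptide candidate index
  offsets <- c(0L, cumsum(cand$n_cand))
  hard <- offsets[seq_len(n)] + hard_local
  const <- sum(vapply(cand$ext_idx, function(ix) sum(log_bg[ix]),
                      numeric(1)))
  objective_best <- res$objective + const
  canon <- canonical_shift(cand, hard, n, window_positions, pseudocount,
                           log_bg, bonus)
  hard <- canon$hard
  objective <- completed_loglik(cand, hard, pseudocount, log_bg) +
    sum(bonus[hard])
  assignments <- data.frame(
    peptide = peptides,
    p1_index = cand$p1[hard],
    window = cand$window[hard],
    posterior = rep(1, n),
    entropy = rep(0, n)
  )
  pfm <- counts_from_windows(assignments$window, window_positions, pseudocount)
  structure(
    list(assignments = assignments, window_positions = window_positions,
         objective = objective, objective_best = objective_best,
         loglik_trace = numeric(0),
         iterations = res$n_evaluated, pfm = pfm,
         context = context, background = background,
         pseudocount = pseudocount),
    class = "aligned_cleavage_set"
  )
}

# Soft P1-anchor register prior: log bonus for candidate rows whose P1
# residue belongs to the anchor set.
anchor_bonus <- function(cand, window_positions, p1_anchor, anchor_weight) {
  bonus <- numeric(nrow(cand$idx))
  if (is.null(p1_anchor)) return(bonus)
  p1_col <- which(plabel_offset(window_positions) == 0L)
  anchored <- aa_alphabet()[cand$idx[, p1_col]] %in% p1_anchor
  bonus[anchored] <- anchor_weight
  bonus
}
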