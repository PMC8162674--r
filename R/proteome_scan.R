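# Sliding a specificity model across protein collections to nominate
# candidate in vivo cleavage sites. Works in two modes: log-odds scoring with
# a weight matrix, or degenerate consensus-pattern matching with a mismatch
# budget and forbidden-class exclusions near the scissile bond. Unlike phage
# inserts, proteins have no known flanks, so windows truncated by protein
# ends are skipped rather than padded; windows containing the ambiguity
# character X are unscorable and skipped too (both are counted in the scan
# log).

#' Scan options
#'
#' @param mode `"pwm"` or `"pattern"`; `NULL` picks the mode matching the
#'   model object.
#' @param threshold Minimal log-odds score for a hit (pwm mode).
#' @param report_span Pair of subsite labels bounding the reported window;
#'   default P6..P2', an 8-residue span.
#' @param overlap_policy `"all"` or `"best-per-p1"`.
#' @return A list of class `"scan_options"`.
#' @export
scan_options <- function(mode = NULL, threshold = 0,
                         report_span = c("P6", "P2'"),
                         overlap_policy = c("all", "best-per-p1")) {
  overlap_policy <- match.arg(overlap_policy)
  span_off <- plabel_offset(report_span)
  if (span_off[1] > 0 || span_off[2] < 0) {
    stop("report_span must cover P1")
  }
  structure(list(mode = mode, threshold = threshold,
                 report_span = report_span,
                 overlap_policy = overlap_policy),
            class = "scan_options")
}

#' Log-odds score of a single window
#'
#' Sum over subsites of the residue's weight; the window must match the
#' matrix width exactly and contain no ambiguity characters.
#'
#' @param pwm A `"subsite_pwm"`.
#' @param window Window string of the matrix width.
#' @return Numeric score (log2 odds).
#' @export
score_window <- function(pwm, window) {
  W <- length(pwm$positions)
  if (nchar(window) != W) {
    stop(sprintf("window length %d does not match matrix width %d",
                 nchar(window), W))
  }
  ix <- aa_to_int(window)
  if (anyNA(ix)) stop("window contains a non-alphabet character: ", window)
  sum(pwm$weights[cbind(ix, seq_len(W))])
}

#' Match a window against a consensus pattern
#'
#' Required subsites must match their allowed set (any failure means the
#' window does not pass, though mismatches are still counted); mismatches at
#' non-required constrained subsites are counted against the pattern's
#' budget; forbidden residue classes are checked within their radius of P1
#' (clipped to the pattern's window).
#'
#' @param pattern A `"consensus_pattern"`.
#' @param window Window string of the pattern width.
#' @return List with elements `passes` (logical) and `mismatches` (integer
#'   count over non-required subsites).
#' @export
match_pattern <- function(pattern, window) {
  W <- length(pattern$positions)
  if (nchar(window) != W) {
    stop(sprintf("window length %d does not match pattern width %d",
                 nchar(window), W))
  }
  chars <- strsplit(window, "")[[1]]
  off <- plabel_offset(pattern$positions)
  required_ok <- TRUE
  mismatches <- 0L
  for (j in seq_len(W)) {
    set <- pattern$allowed[[j]]
    if (is.null(set)) next
    ok <- chars[j] %in% set
    if (pattern$positions[j] %in% pattern$required) {
      if (!ok) required_ok <- FALSE
    } else if (!ok) {
      mismatches <- mismatches + 1L
    }
  }
  forbidden_hit <- FALSE
  for (f in pattern$forbidden) {
    in_radius <- abs(off) <= f$radius
    if (any(chars[in_radius] %in% f$residues)) forbidden_hit <- TRUE
  }
  list(passes = required_ok && mismatches <= pattern$max_mismatches &&
         !forbidden_hit,
       mismatches = mismatches)
}

model_positions <- function(model) {
  if (inherits(model, "subsite_pwm") || inherits(model, "consensus_pattern")) {
    return(model$positions)
  }
  stop("model must be a subsite_pwm or a consensus_pattern")
}

as_protein_frame <- function(proteins) {
  if (is.data.frame(proteins)) return(proteins)
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    return(data.frame(id = ids, description = "",
                      sequence = unname(proteins)))
  }
  stop("proteins must be a data.frame or a named character vector")
}

empty_hits <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             p1_position = integer(), window = character(),
             score = numeric(), mismatches = integer())
}

#' Scan proteins for candidate cleavage sites
#'
#' Every admissible P1 placement in every protein is evaluated against the
#' model; hits are reported over `options$report_span` with 1-based inclusive
#' coordinates and sorted by `(protein_id, start)`. Placements whose model
#' window or report window would run past a protein end, or whose model
#' window contains `X`, are skipped and counted in the `"log"` attribute.
#'
#' @param proteins Data.frame from [read_fasta()] or a named character
#'   vector of sequences.
#' @param model A `"subsite_pwm"` or `"consensus_pattern"`.
#' @param options A [scan_options()].
#' @return Data.frame of hits with columns `protein_id`, `start`, `end`,
#'   `p1_position`, `window`, `score` (pwm mode, else `NA`), `mismatches`
#'   (pattern mode, else `NA`); attribute `"log"` holds counts of evaluated
#'   and skipped placements.
#' @export
scan_proteins <- function(proteins, model, options = scan_options()) {
  proteins <- as_protein_frame(proteins)
  if (nrow(proteins) == 0) stop("empty protein collection")
  positions <- model_positions(model)
  off <- plabel_offset(positions)
  span_off <- plabel_offset(options$report_span)
  lo <- min(off[1], span_off[1])
  hi <- max(off[length(off)], span_off[2])
  is_pwm <- inherits(model, "subsite_pwm")
  W <- length(positions)

  hit_list <- list()
  n_evaluated <- 0L
  n_skipped <- 0L
  n_short <- 0L

  if (!is_pwm) {
    allow_lut <- lapply(model$allowed, function(set) {
      if (is.null(set)) rep(TRUE, 20) else aa_alphabet() %in% set
    })
    req <- positions %in% model$required
    forb_lut <- lapply(model$forbidden, function(f) {
      list(lut = aa_alphabet() %in% f$residues,
           offs = off[abs(off) <= f$radius])
    })
  }

  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    L <- nchar(seq)
    if (L < hi - lo + 1) {
      n_short <- n_short + 1L
      next
    }
    x <- match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
    p1 <- seq.int(max(1L, 1L - lo), min(L, L - hi))
    if (length(p1) == 0) {
      n_short <- n_short + 1L
      next
    }
    # model-window residue matrix: rows = p1 placements, cols = subsites
    resmat <- do.call(cbind, lapply(off, function(o) x[p1 + o]))
    unscorable <- rowSums(is.na(resmat)) > 0
    n_evaluated <- n_evaluated + length(p1)
    n_skipped <- n_skipped + sum(unscorable)

    if (is_pwm) {
      score <- rep(NA_real_, length(p1))
      okrows <- which(!unscorable)
      if (length(okrows) > 0) {
        s <- numeric(length(okrows))
        for (j in seq_len(W)) {
          s <- s + model$weights[resmat[okrows, j], j]
        }
        score[okrows] <- s
      }
      keep <- !unscorable & score >= options$threshold
      mm <- rep(NA_integer_, length(p1))
    } else {
      okrows <- !unscorable
      mm <- rep(NA_integer_, length(p1))
      req_ok <- rep(TRUE, length(p1))
      mm_cnt <- rep(0L, length(p1))
      for (j in seq_len(W)) {
        ok_j <- rep(FALSE, length(p1))
        ok_j[okrows] <- allow_lut[[j]][resmat[okrows, j]]
        if (req[j]) {
          req_ok <- req_ok & (ok_j | !okrows)
        } else if (!all(allow_lut[[j]])) {
          mm_cnt <- mm_cnt + as.integer(okrows & !ok_j)
        }
      }
      forb <- rep(FALSE, length(p1))
      for (f in forb_lut) {
        for (o in f$offs) {
          r <- x[p1 + o]
          hitf <- !is.na(r) & f$lut[r]
          forb <- forb | hitf
        }
      }
      keep <- okrows & req_ok & (mm_cnt <= model$max_mismatches) & !forb
      mm <- mm_cnt
      score <- rep(NA_real_, length(p1))
    }

    if (any(keep)) {
      kp <- which(keep)
      starts <- p1[kp] + span_off[1]
      ends <- p1[kp] + span_off[2]
      hit_list[[length(hit_list) + 1]] <- data.frame(
        protein_id = proteins$id[i],
        start = starts,
        end = ends,
        p1_position = p1[kp],
        window = substring(seq, starts, ends),
        score = score[kp],
        mismatches = mm[kp]
      )
    }
  }

  hits <- if (length(hit_list) > 0) do.call(rbind, hit_list) else empty_hits()
  if (options$overlap_policy == "best-per-p1" && nrow(hits) > 0) {
    key <- paste(hits$protein_id, hits$p1_position)
    ord <- order(key, -replace(hits$score, is.na(hits$score), 0))
    hits <- hits[ord[!duplicated(key[ord])], , drop = FALSE]
  }
  hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "log") <- list(n_evaluated = n_evaluated, n_skipped = n_skipped,
                            n_proteins_too_short = n_short)
  hits
}

#' Naive re-scoring scan oracle
#'
#' Enumerates every placement and re-evaluates each window independently via
#' [score_window()] / [match_pattern()]; semantics identical to
#' [scan_proteins()] by definition. Refuses collections above one million
#' residues.
#'
#' @inheritParams scan_proteins
#' @return Data.frame of hits in the same layout as [scan_proteins()].
#' @export
brute_force_scan <- function(proteins, model, options = scan_options()) {
  proteins <- as_protein_frame(proteins)
  if (sum(nchar(proteins$sequence)) > 1e6) {
    stop("brute_force_scan refuses more than 1e6 residues")
  }
  positions <- model_positions(model)
  off <- plabel_offset(positions)
  span_off <- plabel_offset(options$report_span)
  is_pwm <- inherits(model, "subsite_pwm")
  hit_list <- list()
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    L <- nchar(seq)
    lo <- min(off[1], span_off[1])
    hi <- max(off[length(off)], span_off[2])
    p1_range <- seq.int(max(1L, 1L - lo), length.out = max(0L, min(L, L - hi) - max(1L, 1L - lo) + 1L))
    for (p1 in p1_range) {
      win <- substring(seq, p1 + off[1], p1 + off[length(off)])
      if (grepl("[^A-Z]|X", win)) next
      if (!is_valid_aa(win)) next
      if (is_pwm) {
        s <- score_window(model, win)
        if (s < options$threshold) next
        mm <- NA_integer_
      } else {
        m <- match_pattern(model, win)
        if (!m$passes) next
        s <- NA_real_
        mm <- m$mismatches
      }
      hit_list[[length(hit_list) + 1]] <- data.frame(
        protein_id = proteins$id[i],
        start = p1 + span_off[1], end = p1 + span_off[2],
        p1_position = p1,
        window = substring(seq, p1 + span_off[1], p1 + span_off[2]),
        score = s, mismatches = mm
      )
    }
  }
  hits <- if (length(hit_list) > 0) do.call(rbind, hit_list) else empty_hits()
  if (options$overlap_policy == "best-per-p1" && nrow(hits) > 0) {
    key <- paste(hits$protein_id, hits$p1_position)
    ord <- order(key, -replace(hits$score, is.na(hits$score), 0))
    hits <- hits[ord[!duplicated(key[ord])], , drop = FALSE]
  }
  hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
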