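#' Candidate asp-ase cleavage octamers in bovine Mucin-5B
#'
#' The six candidate cleavage-site octamers identified in bovine salivary
#' Mucin-5B when the cow proteome is screened with the bovine asp-ase
#' consensus (P6..P2' spans, 1-based inclusive start coordinates): five
#' copies of EWFDVDYP and one EWFDVDFP. The octamers read, in subsite terms,
#' E(P6) W(P5) F(P4) D(P3) V(P2) D(P1) | Y/F(P1') P(P2'), matching the
#' asp-ase preference for Asp at P1 and P3 with an aromatic P4.
#'
#' @return Data.frame with columns `start`, `end` and `octamer`.
#' @export
mucin5b_candidate_octamers <- function() {
  start <- c(833L, 1293L, 1897L, 2446L, 3057L, 3590L)
  octamer <- c("EWFDVDYP", "EWFDVDYP", "EWFDVDYP", "EWFDVDYP",
               "EWFDVDYP", "EWFDVDFP")
  data.frame(start = start, end = start + 7L, octamer = octamer)
}

#' Count windows equal to the position-wise modal window
#'
#' Builds a frequency matrix from a set of equal-length windows over the
#' given subsites, computes the position-wise modal window, and counts how
#' many of the input windows equal it exactly.
#'
#' @param windows Character vector of aligned windows (equal length).
#' @param positions Subsite labels of the window span.
#' @return List: `modal` (the modal window) and `n_modal` (count of exact
#'   copies among the inputs).
#' @export
count_modal_windows <- function(windows,
                                positions = subsite_window("P6", "P2'")) {
  pfm <- counts_from_windows(windows, positions, pseudocount = 0.5)
  modal <- modal_window(pfm)
  list(modal = modal, n_modal = sum(windows == modal))
}
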