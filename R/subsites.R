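# Schechter-Berger subsite bookkeeping and the amino-acid alphabet shared by
# every module. Substrate residues are numbered P4..P1 N-terminally of the
# scissile bond and P1'..P3' C-terminally; cleavage occurs between P1 and P1'.

#' The 20-letter amino-acid alphabet
#'
#' Residue order used by every matrix in the package (alphabetical one-letter
#' codes). `X` is not part of the alphabet: it marks unscorable positions in
#' protein sequences and is handled explicitly by the scanner.
#'
#' @return Character vector of the 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Chemical residue classes used for consensus derivation and primary
# specificity calls. His is deliberately kept out of "basic": the His6 capsid
# flank would otherwise contaminate windows near the insert C-terminus.
residue_classes <- function() {
  list(
    basic     = c("K", "R"),
    acidic    = c("D", "E"),
    aromatic  = c("F", "Y", "W"),
    aliphatic = c("A", "V", "I", "L"),
    small     = c("G", "S", "T")
  )
}

# Map a primary-specificity label to its P1 residue class.
specificity_classes <- function() {
  list(
    tryptase = c("K", "R"),
    chymase  = c("F", "Y", "W"),
    `asp-ase` = c("D", "E"),
    elastase = c("A", "V", "I", "L")
  )
}

is_valid_aa <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) all(ch %in% aa_alphabet()), logical(1))
}

aa_to_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
}

#' Subsite labels and scissile-bond offsets
#'
#' Converts between subsite labels (`"P4"`, `"P1'"`, ...) and integer offsets
#' relative to P1 (offset 0). Non-primed labels `Pk` sit at offset `-(k - 1)`;
#' primed labels `Pk'` at `+k`.
#'
#' @param labels Character vector of subsite labels.
#' @return `plabel_offset()`: integer offsets; `offset_plabel()`: labels.
#' @examples
#' plabel_offset(c("P4", "P1", "P1'"))
#' offset_plabel(-3:3)
#' @export
plabel_offset <- function(labels) {
  m <- regmatches(labels, regexec("^P([0-9]+)('?)$", labels))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("invalid subsite label(s): ", paste(labels[bad], collapse = ", "))
  }
  vapply(m, function(g) {
    k <- as.integer(g[2])
    if (k < 1) stop("invalid subsite label: ", g[1])
    if (g[3] == "'") k else -(k - 1L)
  }, integer(1))
}

#' @rdname plabel_offset
#' @param offsets Integer offsets relative to P1.
#' @export
offset_plabel <- function(offsets) {
  ifelse(offsets <= 0, paste0("P", 1L - offsets), paste0("P", offsets, "'"))
}

#' Default P4-P3' alignment window
#'
#' @param from,to Subsite labels bounding the window (inclusive).
#' @return Character vector of contiguous subsite labels containing P1.
#' @export
subsite_window <- function(from = "P4", to = "P3'") {
  lo <- plabel_offset(from)
  hi <- plabel_offset(to)
  if (lo > hi) stop("'from' must be N-terminal of 'to'")
  if (lo > 0 || hi < 0) stop("subsite window must contain P1")
  offset_plabel(lo:hi)
}

check_window_positions <- function(window_positions) {
  off <- plabel_offset(window_positions)
  if (any(diff(off) != 1L)) {
    stop("window positions must be contiguous subsites")
  }
  if (!0L %in% off) stop("window positions must include P1")
  off
}
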