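# Shared helpers for the suite: planted-model distances and the rate-panel
# anchor used in the end-to-end workflow.

mean_tv <- function(a, b) mean(colSums(abs(a - b)) / 2)

# TV between a recovered and a planted matrix over shared subsites, minimized
# over the global register phase (the phase is unidentifiable: every
# within-range shift of all registers is a likelihood tie, so matrices are
# compared modulo it, as factor loadings are compared modulo rotation).
phase_tv <- function(rec, planted, rec_pos, pl_pos, shifts = -4:4) {
  rec_off <- plabel_offset(rec_pos)
  pl_off <- plabel_offset(pl_pos)
  best <- Inf
  for (s in shifts) {
    sh <- rec_off + s
    keep <- sh %in% pl_off
    if (sum(keep) < length(rec_off) - 2) next
    d <- mean(colSums(abs(rec[, keep, drop = FALSE] -
                            planted[, match(sh[keep], pl_off),
                                    drop = FALSE])) / 2)
    best <- min(best, d)
  }
  best
}

p1_class_residues <- function(label) {
  classes <- list(tryptase = c("K", "R"), chymase = c("F", "Y", "W"),
                  `asp-ase` = c("D", "E"), elastase = c("A", "V", "I", "L"))
  classes[[label]]
}

# The P1 anchor an analyst would carry into the alignment for each planted
# enzyme: three come straight from the chromogenic panel; the FK-tryptase
# cleaves no substrate of the generic panel (as its real counterpart did) and
# is anchored by its recombinant-substrate verification (Lys at P1).
planted_anchors <- list(
  "polyR-tryptase" = c("K", "R"),
  "aspase" = c("D", "E"),
  "FK-tryptase" = c("K", "R"),
  "FY-chymase" = c("F", "Y", "W")
)

planted_class <- c(
  "polyR-tryptase" = "tryptase",
  "aspase" = "asp-ase",
  "FK-tryptase" = "tryptase",
  "FY-chymase" = "chymase"
)

# a high-information planted model whose register phase is pinned by a unique
# Lys anchor and informative subsites spanning the full window
sharp_truth <- function() {
  make_truth_model("custom", sharpness = 0.95,
                   preferences = list("P4" = "F", "P1" = "K", "P1'" = "R",
                                      "P3'" = "L"),
                   positions = subsite_window("P4", "P3'"))
}

random_peptides <- function(n, seed) simulate_library(n, seed = seed)$sequence
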