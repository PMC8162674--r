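---
title: "Profiling protease cleavage specificity from phage display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protease cleavage specificity from phage display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsite)
```

## The problem

Serine proteases of the chymase locus read their substrates over several
residues around the scissile bond. In Schechter–Berger nomenclature the
substrate positions are P4…P1 on the N-terminal (non-prime) side and
P1′…P3′ on the C-terminal side, with cleavage between P1 and P1′. The
primary specificity is the P1 preference — basic (tryptase), aromatic
(chymase), acidic (asp-ase) or small aliphatic (elastase) — and the
extended specificity is the full profile over the surrounding subsites.

`subsite` implements the computational side of a phage-display
characterization of such enzymes, as applied to the ruminant and pig
intestinal duodenases. The laboratory workflow it models is:

1. a T7 phage library displays random nonamers in the fixed capsid context
   `PGG(X)9HHHHHH`; the His6 tag anchors phages to a Ni-NTA matrix, and a
   protease releases exactly those phages whose insert it can cleave;
2. five to seven rounds of selection enrich cleavable inserts; 57–96
   released clones are sequenced;
3. the sequenced nonamers are aligned into a common P-position register
   and summarized as a position frequency matrix, a log-odds weight
   matrix, and a degenerate consensus pattern;
4. a chromogenic substrate panel (Suc-XXXX-pNA) independently reads out
   the primary specificity, and recombinant two-domain (2×Trx) substrates
   verify the consensus through cleavage time courses;
5. the consensus is slid across a proteome to nominate candidate in vivo
   substrates.

Every stage has a synthetic counterpart in the package, so the whole
pipeline is testable end to end without external data.

## The register-alignment model

The scientific crux is step 3: the sequenced insert tells us *that* the
enzyme cleaved it, not *where*. We model the cleavage register with a
one-cleavage-site-per-sequence likelihood in the spirit of the OOPS motif
model. For insert $x$ embedded in the flanked sequence, each admissible P1
placement $r$ (restricted to the nine insert positions) defines a window
over the model subsites (default P4…P3′). Window positions drawn from the
randomized insert follow the unknown frequency matrix $\theta$; every
other insert position follows the background $b$ (uniform by default).

Two modeling points deserve emphasis:

* **Fixed flanks are excluded from the likelihood.** A window that reaches
  into `PGG` or `HHHHHH` sees residues that are identical in every clone
  and carry no selectable information. If they were treated as data, the
  all-His edge of the insert would act as a spurious perfectly-conserved
  motif and attract the whole alignment (we observed exactly this failure
  before masking). Extracted windows still *show* the flank residues —
  they are part of the substrate the enzyme saw — but only insert-derived
  positions enter the estimation.
* **EM with restarts, then hardening.** Register posteriors are
  proportional to the exponentiated window log-odds; the M-step
  re-estimates $\theta$ with pseudocounts (default 0.5 per residue per
  column, a Jeffreys-like choice). With a positive pseudocount the M-step
  is a Dirichlet MAP update, so the quantity that increases monotonically
  is the penalized marginal log-likelihood; that is what `loglik_trace`
  records. Ten seeded random restarts plus one start from the
  most-informative-column heuristic are each hardened (per-peptide argmax,
  ties toward the N-terminal-most P1) and polished by coordinate ascent;
  on instances of up to eight peptides the result is checked against exact
  enumeration (`brute_force_alignment`, the same objective maximized in
  C++).

## What the data cannot tell you: register identifiability

A subtle and, we think, under-appreciated property of this assay is that
the register is identifiable only up to a global shift. Shifting *every*
clone's P1 by one position and re-estimating the matrix gives exactly the
same likelihood whenever the motif does not press against the admissible
range — and for a tandem-repeat motif such as an Arg run, "which Arg is
P1" is unknowable from sequences alone. The original experiments hit the
same wall: for the most selective enzyme the cleavage position could not
be determined from phage display and was pinned later with recombinant
substrates.

`subsite` handles this in two documented ways:

* **An optional P1 anchor.** `align_registers(p1_anchor = c("K","R"))`
  applies a soft register prior (log-bonus 2 by default) to placements
  whose P1 residue belongs to the anchor set. In the intended workflow the
  anchor comes from the chromogenic panel
  (`classify_specificity_from_rates()`): the panel fixes the primary
  specificity, phage display contributes the extended specificity. This is
  the division of labor of the original study.
* **Canonicalization of the residual phase.** After optimization, all
  global shifts of the solution are re-fitted; candidates within 0.5
  log-units per clone of the best objective are declared ties (equivalent
  phases differ only by register-overfitting noise, which we measured at
  0.1–0.5 log-units per clone at $n = 96$, while losing a genuinely
  informative column costs several log-units per clone). Ties resolve by
  centering the information-weighted columns on P1, then by the
  lexicographically smallest register vector. This is a reporting
  convention for an unidentifiable phase — the same role sign conventions
  play in factor analysis — and `objective_best` always records the
  maximal objective found.

Per-clone register uncertainty is never hidden: each assignment carries
its posterior and posterior entropy (bits), so a profile aligned from an
enzyme with genuinely ambiguous cleavage positions advertises itself.

## Matrices, consensus patterns and calls

`build_pfm()` tabulates the final hard windows with the fixed pseudocount
rule $(c + 0.5)/(n + 10)$ — the direct analogue of the published
alignment figures, including any flank residues that genuinely sat in the
windows. For *recovering the underlying specificity*, the aligner also
returns `pfm_insert`: insert-derived counts only, smoothed per column by
an empirical-Bayes Dirichlet prior whose strength maximizes the
Dirichlet–multinomial marginal likelihood against the background. With 20
residues and 96 clones, the raw per-column sampling noise alone amounts to
a mean total-variation distance of about 0.15 from the truth;
uninformative columns should and do shrink hard toward background, while
selective columns are left essentially unshrunk. This moderation is the
same idea as variance moderation in differential-expression analysis.

`derive_consensus()` reduces a matrix to a degenerate pattern: a residue
with frequency ≥ 0.6 becomes an allowed singleton; otherwise a chemical
class — basic KR, acidic DE, aromatic FYW, aliphatic AVIL, small GST —
with summed frequency ≥ 0.7 becomes the allowed set; P1 is always a hard
constraint; and a class whose mass stays ≤ 0.02 at every subsite is
recorded as forbidden within three residues of P1 (this captures
selections that strikingly avoid acidic residues near the scissile bond).
His is deliberately not counted as basic: the His6 anchor would otherwise
contaminate windows near the insert's C-terminus. Patterns serialize to a
compact grammar, e.g.

```{r}
format_pattern(make_truth_model("FK-tryptase")$pattern)
```

which parses back losslessly.

Primary-specificity calls sum the P1 frequency over the class sets; the
best class must reach 0.4, a second class qualifies at half the best, and
tryptase plus chymase qualifying together yields the dual call. The same
thresholds serve the rate-panel classifier, which additionally returns
`undetermined` when every class activity sits below three pooled replicate
standard deviations — the fate of a highly selective enzyme on a generic
panel.

## Assay kinetics

Chromogenic series are reduced to blank-subtracted per-replicate OLS
slopes. The default fit window is 0–60 min, where real curves can be
assumed linear; synthetic curves are linear throughout, so the synthetic
analyses fit the full series (which halves nothing conceptually and
improves the slope standard error about eightfold). Gel-based fraction-
cleaved time courses are fitted as $f(t) = 1 - e^{-kt}$ by 1-D
minimization over $k \in [0, 1]\,\mathrm{min}^{-1}$ — a first-order model
chosen because substrate excess over enzyme is uncharacterized, and the
published comparisons are ratio-level statements that this model supports.
Fold differences come either from rate ratios (exactly reciprocal by
construction) or from titration equivalence: the enzyme amounts reaching a
target cleavage fraction are located by piecewise-linear interpolation on
log-amount (a running maximum first flattens noise wiggles), and their
ratio is the fold.

## Proteome scanning

`scan_proteins()` slides either a weight matrix (log-odds sum with a
threshold) or a consensus pattern (required subsites, a mismatch budget
over the constrained ones, forbidden classes within a radius of P1) over
every admissible P1 placement. Proteins, unlike phage inserts, have no
known flanks: windows truncated by protein ends are skipped, as are
windows containing the ambiguity residue X, and both are counted in the
scan log rather than silently dropped. Hits report 1-based inclusive
coordinates over a configurable span (default P6…P2′, an 8-residue window
chosen because the published candidate sites in bovine Mucin-5B are
octamers that align as E(P6) W(P5) F(P4) D(P3) V(P2) D(P1) | Y(P1′)
P(P2′)). The scanner is validated against a naive per-window re-scoring
oracle, and no significance model is attached: hit counts per protein are
reported, multiple-testing correction deliberately is not, matching the
qualitative "near-consensus" character of the original screen.

## The synthetic data, and what it does not emulate

The generators define the study conditions:

* **Truth models** span P6…P3′ (the stated preferences reach P6 on the
  asp-ase side and P3′ on the F/Y-K tryptase side) and place `sharpness`
  (default 0.9) of each preferred column's mass on the preferred set.
* **Biopanning** uses a scaled library of $10^5$ clones (the physical
  library held about $5\times10^7$), five rounds, a maximal per-encounter
  cleavage probability of 0.5, a background release probability of 0.001,
  and a logistic link from best-register log-odds score to cleavage
  probability with unit slope and midpoint at the 99.9th percentile of the
  naive library's scores. The experiments imply no particular selection
  model; a monotone saturating link is the minimal assumption consistent
  with release by cleavage. Amplification is unbiased multinomial; the buffer control
  releases every clone at the background rate. Under these defaults the
  round-5 enrichment lands in the few-hundred-fold range, the order of
  magnitude the experiments reported for their five-round selections.
* **Clone samples with known registers** (`sample_cleavage_peptides`)
  draw each clone's register uniformly among placements that keep every
  informative subsite inside the randomized insert — the placements
  selection would actually admit — then fill window positions from the
  planted matrix.
* **Assays** plant chromogenic slopes proportional to
  $2^{s - s_{\max}}$ of the substrate's non-prime score (so a generic
  panel genuinely fails to detect an enzyme whose motif it cannot
  express), absorbance noise of $10^{-4}$ AU, first-order linker rates up
  to 0.06 min$^{-1}$ read at 0/15/45/150 min with fraction noise 0.02,
  and logistic titration curves on log-amount.
* **Proteomes** are i.i.d. background with consensus, matrix-sampled or
  explicit windows spliced at recorded coordinates; accidental background
  matches are detected with the exhaustive scanner and flagged.

Deliberately not modeled: sequencing errors, phage fitness differences,
amplification bias, densitometry of gels (fractions are taken as given),
and any secondary-structure or glycosylation effect on real cleavage
sites. Passing tests therefore demonstrate that the inference machinery
recovers what selection-by-cleavage puts into sequence data — not that
real proteomic hits are in vivo substrates.

## Numerical choices and problem sizes

Tolerances: EM convergence at $10^{-8}$ on the penalized marginal
log-likelihood, at most 200 iterations; oracle agreement asserted at
$10^{-9}$; matrix files round-trip to at least 12 decimals. Degenerate
inputs: an all-zero time course returns $k = 0$; fractions equal to 1 are
shrunk to $1 - 10^{-3}$ before fitting; a zero denominator rate directs
the user to the titration method; proteins shorter than the window are
skipped with a log entry. Ties everywhere break deterministically
(N-terminal-most P1 within a solution; canonical phase across solutions).

The shipped analyses and tests run at desk scale: libraries of $10^4$ to
$10^5$ clones, 96-clone sequencing samples, proteomes of tens of proteins
of a few hundred residues, a few seeds per stochastic claim. These sizes
were chosen so the whole suite re-runs in minutes on one core while
keeping every statistical claim at the sample sizes the original
experiments actually had (57–96 sequenced clones).

## Known limitations

* The register phase of a tandem-repeat motif is unidentifiable; the
  canonical phase is a convention, and downstream users should rely on
  the P1-class call plus the pattern, not on absolute subsite labels,
  when the anchor was weak.
* `run_profile()` without an anchor reports the unanchored fit; for
  enzymes whose panel call is `undetermined`, an anchor must come from
  outside (as it did for the real Lys-specific tryptase).
* The logistic selection link absorbs everything the washing and
  re-clearing steps do; its parameters are not identifiable from the
  round summaries alone and are treated as fixed study conditions.
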