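---
title: "Cross-link search methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link search methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlsearch)
```

This vignette documents the models inside `xlsearch`, the parameters that
matter, the assumptions behind the synthetic fixtures, and the places where
the design was genuinely open and a choice had to be made.

## Mass bookkeeping

All internal masses are **neutral monoisotopic** Da. Singly-protonated m/z
appears only at the I/O boundary (proton = 1.007276 Da). This convention is
chosen because both search engines consume spectra that have been
de-isotoped and deconvoluted to charge one, so neutral-mass arithmetic
avoids an entire class of convention bugs; `neutral_to_mz()` /
`mz_to_neutral()` convert at the edges.

Fragment ladders are neutral too: `b_k` is the sum of the first *k* residue
masses (plus modifications), `y_k` the sum of the last *k* plus water, so
`b_k + y_(n-k)` equals the neutral peptide mass exactly — a property the
test suite asserts over random peptides.

Cross-linker presets (DSS, BS3, DSSO, DSBU) are configuration, not code:
they live in `inst/extdata/linkers.txt` with residual masses from the
vendor fragmentation chemistry (DSSO: alkene +54.010565 Da / sulfenic acid
+103.993200 Da; DSBU: amide +85.052764 Da / isocyanate +111.032028 Da).
Every cleavable linker must satisfy `short + long = intact` to 1e-6 Da —
enforced at construction. Monolinks default to `intact + 18.010565`
(hydrolyzed linker), looplinks to `intact`; both are overridable because
quenching chemistry varies between protocols.

## Search space

Digestion is fully specific (trypsin by default: after K/R, not before P),
with up to `max_missed_cleavages` (default 3) internal sites, a minimum
peptide length of 6 and a maximum peptide mass of 6000 Da. Decoys reverse
each protein keeping its C-terminal residue in place — an involutive
transform that preserves length, composition, and approximately the tryptic
peptide mass distribution — and are digested identically.

A link site is a residue in the linker specificity set, excluding the
peptide C-terminal K/R when it was the cleavage site (a cross-linked lysine
would not have been cleaved); the exclusion is a flag because the
convention varies across engines. Heterobifunctional specificity (two
residue sets) is supported; the protein N-terminus can be declared a site.

Products: singles, monolinks (one per site), looplinks (one per unordered
distinct site pair), dipeptides (one per unordered peptide pair — self
pairs included, since homodimeric cross-links are real and some engines
miss them — times one site on each constituent), and optionally
higher-order products (a dipeptide carrying one extra monolink). Deeper
combinations are excluded to bound the space; higher-order products are off
by default for the same reason. Products are held in a mass-sorted
data.frame in memory and queried with `findInterval` at ppm tolerance; at
the problem sizes this package targets (well under a million products) an
on-disk product store would add machinery without a measurable benefit, so
the index is deliberately memory-resident. `query_index()` is tested
against a linear-scan oracle.

## Spectrum processing

De-isotoping walks each candidate charge from high to low; an envelope is a
maximal peak run spaced by 1.00286864/z within the fragment tolerance, with
at least two members and non-increasing intensity after its apex. Accepted
envelopes collapse to their monoisotopic member at the charge-1-equivalent
neutral mass with summed intensity; everything else passes through at
assumed charge 1. This is a deliberately transparent rule — a full
averagine-correlation scorer would be better on dense real spectra but is
not testable at this scale; the simplification is documented as such, and
its failure mode (accidental collapse of coincidentally spaced fragment
pairs) is exercised in the tests.

The score's window filter keeps the `q` most intense peaks per half-open
100 Da window, ties to the lower mass, `q = Inf` being the identity.
NH3/H2O neutral-loss *fragment* generation is off by default — losses are
handled only where the cleavable engine restores ammonia losses on
signature peaks, which is a separate mechanism.

## The match score

For each `q` in 1..`q_max` (default 10), count the `k` of `n` theoretical
fragments matched in the q-filtered spectrum at the fragment tolerance
(each theoretical position at most once), and score
`-10*log10 P(X >= k)`, `X ~ Binomial(n, p)`, maximizing over `q`. The
single-match chance is `p = q * 2 * tol_Da / window`. Because the ppm
tolerance makes `tol_Da` mass-dependent while the binomial model needs a
constant `p`, `tol_Da` is evaluated at the **mean theoretical fragment
mass** — a per-candidate constant; any fixed reference point would do, and
this one keeps `p` commensurate with where the fragments actually lie. The
tail is evaluated with `pbinom(..., log.p = TRUE)` so perfect matches do
not underflow (k = n = 10 at p = 0.01 scores exactly 200). The test suite
holds the tail to an exhaustive-summation oracle at 1e-12 relative error
for all n ≤ 30.

Partial scores re-run the same maximization on one peptide's fragments
only, independently per fragment set (whether the reference engine
maximizes q jointly is not documented anywhere; independent maximization
is the cleaner contract and is what the partial score means as a
standalone quantity). Alpha is the longer peptide; equal lengths fall back
to the lexicographically smaller sequence so the assignment is total and
deterministic. Ranking is fully deterministic: score descending, then
fewer variable modifications, then product identity string.

One subtlety the tests encode: two peptides sharing a C-terminal residue
share their `y1` mass (and the complementary `b_(n-1)` of the whole
product), so a "beta partial score of zero when only alpha ions are
present" is only true for peptides with distinct C-termini. This is
physics, not an implementation artifact.

## The cleavable cascade

With neutral masses the four signature species obey
`m_βl = m_βs + Δm`, `m_αs = m_p − m_βl`, `m_αl = m_p − m_βs`, which imply
`m_α + m_β + intact = m_p` exactly for every hypothesis the three stages
emit — the acceptance suite checks the identity across 1000 random
fixtures at twice the matching tolerance.

1. **Strict quadruplet**: every peak above `min_signature_mass` (default
   200 Da, skipping the immonium region) is tried as βs; the other three
   peaks are required within tolerance. Homodimers degenerate cleanly: βs
   and αs coincide, so two observed peaks satisfy all four constraints.
2. **Top intensity** (only when strict finds nothing): each of the
   `n_top = 3` most intense peaks is read as either residual state,
   optionally after restoring +17.026549 (NH3); the partner mass follows
   from `m_p`. Hypotheses with either peptide below `min_peptide_mass`
   (default 500 Da, matching the smallest tryptic 6-mers) are dropped, and
   duplicates are removed on a tolerance grid.
3. **Relaxed pair** (only when both fail): any Δm-spaced peak pair is read
   as the β doublet.

Candidate peptides are fetched by mass for each hypothesis; theoretical
spectra carry site-containing fragments in *both* residual states, with a
matched doublet position counting once (physically one fragment, two
states). The total score adds a signature bonus — a binomial tail over the
four signature positions with the same chance model, weight configurable —
because the functional form of the score combination is not documented
anywhere; additive log-probabilities are the natural choice when the two
pieces of evidence are treated as independent.

Whether β must be the lighter constituent *before* derivation is another
open point; masses are ordered after derivation instead, which is
equivalent for every reachable case and avoids an arbitrary pre-filter.

## MS1 peak refinement

Two 3D peaks at the same m/z separated in retention time join one putative
cluster iff a bridging peak one isotope spacing away (candidate charges
1..max, bridge acceptance lowest-first) covers the RT gap; touching
intervals merge unconditionally. A cluster is joined into one peak (union
RT interval, concatenated profile) only when its isotope context spans at
least three isotopic positions. The context is evaluated over all candidate
charges and the best-spanning charge decides — using only the lowest
bridging charge would undercount positions that a higher charge explains,
and the join criterion is about the isotope pattern, not the bridge.

Monoisotopic reassignment uses a Poisson surrogate for the averagine
isotope distribution, λ = mass/1800: for each candidate left-shift `s`
(0..3), the observed normalized intensities are compared against the
expected profile at indices `s..s+m−1` and the smallest squared deviation
wins, ties to the smaller shift. A complete pattern therefore never moves
(the fit at `s = 0` is exact on clean data), while patterns whose leading
isotopes were lost shift left by the right amount. The "without refinement"
baseline used in the benefit comparison takes the lowest-m/z member of the
assembled pattern as the monoisotopic peak — i.e. refinement comprises both
the rejoining and the model-based reassignment, which is exactly the
module's job description. On 500 damaged heavy patterns (≥2500 Da, deleted
leading isotopes and/or RT-split members) refinement raises assignment
accuracy from 0 % to ~87 %; the residual errors are RT-split members whose
gap intensity is genuinely lost, distorting the profile enough to misfit
the shift by one — rejoining cannot recover intensity that was never
recorded.

## PEP and FDR

The PEP model is logistic regression of the decoy label on total score,
minimum partial score, log(1 + modifications), precursor charge, and the
largest missed-cleavage count, followed by isotonic calibration of the
decoy probability against the linear predictor. The minimum partial score
replaces peptide length as the dipeptide covariate because a dipeptide can
score well with evidence from only one constituent; the tests verify that
one-sided matches receive systematically higher PEPs than balanced ones at
the same total score. The score coefficient is required to be negative;
if a degenerate fit violates that, the model falls back to score-only (as
it also does below 50 target or 50 decoy-class training CSMs). Monotone
non-increasing PEP in score at fixed covariates is then structural, not
empirical. The calibration is a step function, so distribution-level
properties (e.g. doubling decoys doubling the PEP) hold in aggregate
rather than pointwise — the tests compare means over a score grid.

FDR walks the PEP-sorted list computing `(#TD + #DD) / #TT` (single-peptide
products contribute their D/T counts analogously); the printed formula is
implemented literally, without the ×2 corrections some tools apply, which
makes the estimator conservative (a false match is TT only ~25 % of the
time under independent constituents, while TD+DD counts the other 75 %).
q-values are the running minimum from the bottom; acceptance is q ≤ 1 % by
default. Separate intra/inter estimation partitions dipeptides by stripped
protein accession (decoy prefix removed) and runs independently; a subset
with no target CSMs accepts nothing. Reporting filters (minimum partial
score 10; optional score and fragment-count cuts, all off by default)
apply after PEP fitting and before FDR; the order is configurable because
the reference behavior is undocumented. Unique cross-links are rolled up
by canonical residue pair for reporting only — FDR is controlled at the
CSM level, not the unique-link level.

## What the simulator does and does not emulate

`make_database()` draws residues at natural-ish frequencies with
controllable K/R density (defaults 8 %/5 %, near natural abundance, giving
tryptic peptides with a realistic density of linkable lysines).
Spectrum generators plant exact theoretical peaks: b/y ladders with the
correct cross-link shifts (noncleavable) or residual-carrying linear
ladders plus selectable signature species with optional NH3 variants
(cleavable), exact precursors, seeded uniform noise, and seeded dropout.
Intensities are rank-based draws — only ordinal assumptions enter any
algorithm under test — with cleavable signature peaks drawn above the
fragment band, which is the top-intensity stage's stated assumption about
real spectra. Optional Gaussian ppm mass error exercises tolerance
handling.

Passing tests on these fixtures demonstrate algorithmic correctness —
search-space completeness, score calibration against oracles, cascade
control flow, FDR accounting — on spectra whose peaks are either exactly
right or pure noise. They do not demonstrate robustness to correlated
real-spectrum structure: co-eluting precursors, unmodeled fragment series
(a/x/c/z, internal fragments), calibration drift, or intensity-dependent
mass error. Claims about real data remain the user's to validate.

## Problem sizes and budgets

The acceptance suite uses 5-protein databases (~190 peptide variants,
~2600 products), 200 fixtures per engine noise-free plus 100 each at 20 %
dropout with 30 noise peaks, 1000 cascade fixtures for the mass
identities, 20-seed FDR mixtures of 1000 true + 800 false CSMs, and 500
isotope fixtures. These sizes were chosen so the full suite completes in
about two minutes on one CPU while every rate estimate has enough trials
to be stable to a few percent; all scale linearly if larger runs are
wanted.
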