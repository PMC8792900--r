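# xlsearch

An R search engine for cross-linking mass spectrometry (XL-MS).

In an XL-MS experiment a bifunctional reagent covalently joins two
spatially close residues; after tryptic digestion the sample contains
cross-linked dipeptides (two peptides joined by one linker), mono-linked
and loop-linked peptides, and ordinary linear peptides. `xlsearch`
identifies these products in centroided MS/MS spectra:

* **Noncleavable linkers** (DSS, BS3): the full cross-link product space is
  enumerated from the FASTA database — singles, monolinks, looplinks, all
  dipeptide pairs including homodimers, optionally higher-order products —
  and indexed by mass. Each spectrum is matched against candidates within
  the precursor tolerance using a binomial-tail score: for peak depths
  q = 1..q_max the spectrum is filtered to the q most intense peaks per
  100 Da window, k of n theoretical b/y fragments are matched at the
  fragment tolerance, and the score is

  `S = max_q [ -10 log10 P(X >= k) ]`, `X ~ Binomial(n, p)`, `p = q · 2·tol_Da / window`.

  Fragments containing the linked residue are shifted by the intact linker
  mass plus the full partner-peptide mass. Each dipeptide match also gets
  two *partial scores* (the same score restricted to one peptide's ions,
  α = longer peptide); the minimum partial score guards against matches
  with one-sided fragment evidence.

* **MS-cleavable linkers** (DSSO, DSBU): the linker fragments in MS/MS,
  leaving a short or long residual on each peptide and producing up to four
  signature peaks (βs, βl, αs, αl) with the characteristic spacing
  Δm = long − short and the precursor relations
  `m_βl = m_βs + Δm`, `m_αs = m_p − m_βl`, `m_αl = m_p − m_βs`.
  Signature peaks are detected by three successive strategies — strict
  quadruplet, top-n-intensity (n = 3, with NH3-loss restoration), relaxed
  single pair — and the implied α/β peptide masses select linear-peptide
  candidates whose doublet-state b/y spectra are scored as above, plus a
  signature-peak bonus.

* **MS1 peak refinement**: 3D peaks (m/z × retention time × intensity) of
  heavy precursors that were fragmented by noise are rejoined when an
  isotope-neighbor peak bridges the RT gap and the cluster spans ≥ 3
  isotopic positions, and the monoisotopic member is reassigned by testing
  leftward extension against a Poisson averagine expectation
  (λ = mass/1800). This matters for cross-linked dipeptides, which are
  heavy and often lose their leading isotopes.

* **FDR control**: decoys are reversed proteins (C-terminal residue kept in
  place), so dipeptide matches fall into TT/TD/DD classes. A logistic
  posterior-error-probability model on (score, min partial score,
  modifications, charge, missed cleavages) with isotonic calibration ranks
  CSMs; walking down the list, FDR = (#TD + #DD)/#TT, q-values are the
  running minimum, and CSMs with q ≤ 1 % are accepted (optionally
  separately for intra- and inter-protein links).

A seeded simulator (`make_database()`, `make_noncleavable_spectrum()`,
`make_cleavable_spectrum()`, `make_isotope_fixture()`) generates every
fixture with known ground truth; nothing is downloaded.

## Worked example

```r
library(xlsearch)

lk <- linker_preset("DSS")
db <- make_database(5, seed = 1)                    # 5 synthetic proteins
peps <- digest_db(db, max_missed_cleavages = 1, min_length = 6,
                  max_mass = 4000)                  # targets + decoys
space <- build_products(peps, lk)
space
#> <xl_space> 2603 products over 188 peptide variants (linker DSS)
#> dipeptide  looplink  monolink    single
#>      2346         1        68       188

# simulate a cross-linked dipeptide spectrum and search it
sites <- lapply(seq_len(nrow(peps)), function(i)
  link_sites(peps$sequence[i], "K", peps$start[i]))
ok <- which(lengths(sites) > 0 & !peps$is_decoy)
fx <- make_noncleavable_spectrum(peps$sequence[ok[1]], peps$sequence[ok[2]],
                                 sites[[ok[1]]][1], sites[[ok[2]]][1],
                                 lk, seed = 7)
res <- search_spectrum(deisotope_deconvolute(fx$spectrum), space)
res[1, c("kind", "seq_a", "seq_b", "score", "partial_alpha",
         "partial_beta", "decoy_class")]
#>        kind    seq_a             seq_b    score partial_alpha partial_beta
#> 1 dipeptide TKGGQAFR HPAFYGTVLAKANESMR 1169.421      843.4051     355.4223
#>   decoy_class
#> 1          TT
```

The generating pair ranks first with a score of ~1169 (the −10·log10
probability that this many fragments match by chance); both partial scores
are well above the default reporting cut of 10, so the match has fragment
evidence from both peptides. A full pipeline — digestion, search, PEP,
FDR, output tables — runs via `run_search(search_config(...), out_dir)` or
the `exec/xlsearch` command line (`search`, `simulate`, `fdr`, `refine`).

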