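test_that("binomial tail matches direct evaluation on the worked cases", {
  # no matches: no evidence
  expect_equal(binomial_match_score(0L, 10L, 0.01), 0)
  # perfect match of 10 at p = 0.01: P = 1e-20, score 200
  expect_equal(binomial_match_score(10L, 10L, 0.01), 200, tolerance = 1e-9)
  # n=4, k=2, p=0.1: P = 0.0523
  expect_equal(10^(-binomial_match_score(2L, 4L, 0.1) / 10), 0.0523,
               tolerance = 1e-10)
})

test_that("binomial tail agrees with the exhaustive-summation oracle", {
  for (n in c(1L, 3L, 10L, 30L)) for (p in c(1e-4, 0.01, 0.2, 0.5)) {
    for (k in unique(c(1L, n %/% 2L + 1L, n))) {
      P_impl <- 10^(-binomial_match_score(k, n, p) / 10)
      P_oracle <- binom_tail_oracle(k, n, p)
      expect_equal(P_impl, P_oracle, tolerance = 1e-12)
    }
  }
})

test_that("dipeptide theoretical spectra shift site-containing fragments", {
  lk <- crosslinker("X", "K", intact_mass = 100)
  peps <- data.frame(sequence = c("AKR", "EKF"), protein_id = "P",
                     start = 1L, end = 3L, missed_cleavages = 0L,
                     is_decoy = FALSE)
  peps$mass <- vapply(peps$sequence, peptide_mass, 0)
  sp <- build_products(peps, lk, enable_single = FALSE, enable_mono = FALSE,
                       enable_loop = FALSE, exclude_cterm_cleavage = FALSE)
  dip <- which(sp$products$kind == "dipeptide" &
                 sp$products$pep_a != sp$products$pep_b)
  fr <- theoretical_spectrum(sp, dip[1])
  # (3-1) fragments x 2 series x 2 peptides
  expect_equal(nrow(fr), 8L)
  # y1 of AKR (R alone) unshifted; y2 (KR) shifted by linker + partner
  expected_y <- fragment_ladder("AKR", "y", 2, 100 + peptide_mass("EKF"))
  y <- fr[substr(fr$label, 1, 1) == "y", ]
  expect_true(all(expected_y$mass %in% y$mass))
  y1 <- expected_y$mass[expected_y$label == "y1"]
  y2 <- expected_y$mass[expected_y$label == "y2"]
  expect_equal(y1, peptide_mass("R"), tolerance = 1e-9)  # unshifted
  expect_equal(y2, peptide_mass("KR") + 100 + peptide_mass("EKF"),
               tolerance = 1e-9)
  # every shifted fragment is below the product total mass
  expect_true(all(fr$mass < sp$products$total_mass[dip[1]]))
  # non-dipeptide rejection of partial-score path is honored upstream
  expect_error(theoretical_spectrum(sp, nrow(sp$products) + 1L))
})

test_that("looplink spectra omit ring-spanning single-site fragments", {
  lk <- linker_preset("DSS")
  peps <- data.frame(sequence = "AKGKAR", protein_id = "P", start = 1L,
                     end = 6L, missed_cleavages = 2L, is_decoy = FALSE,
                     mass = peptide_mass("AKGKAR"))
  sp <- build_products(peps, lk, enable_single = FALSE, enable_mono = FALSE,
                       enable_dipeptide = FALSE)
  loop <- which(sp$products$kind == "looplink")
  fr <- theoretical_spectrum(sp, loop[1])
  # b1 (before both sites) and b4..b5 / y3.. (after both) survive;
  # b2, b3 (between sites) do not
  expect_false(any(fr$label %in% c("b2", "b3")))
  expect_true("b1" %in% fr$label)
  b4 <- fr[fr$label == "b4", ]
  expect_equal(b4$mass,
               sum(residue_masses()[c("A", "K", "G", "K")]) + lk$looplink_mass,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("score maximized over q dominates the q = 1 score", {
  set.seed(41)
  sp <- small_space(seed = 1)
  lt <- linkable_targets(sp)
  for (r in 1:5) {
    ij <- sample(lt$idx, 2L)
    fx <- make_noncleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], sp$linker,
      dropout_frac = 0.2, n_noise_peaks = 40, seed = 100 + r)
    proc <- deisotope_deconvolute(fx$spectrum)
    cand <- query_index(sp, proc$precursor_neutral_mass, 10)
    fr <- theoretical_spectrum(sp, cand[1])
    full <- andromeda_score(fr, proc, score_params())
    q1 <- andromeda_score(fr, proc, score_params(q_max = 1L))
    expect_gte(full$score, q1$score)
  }
})

test_that("partial scores isolate per-peptide evidence", {
  lk <- crosslinker("X", "K", intact_mass = 100)
  # distinct C-terminal residues: otherwise the shared y1 (and complementary
  # b_{n-1}) masses coincide across peptides and the beta partial is nonzero
  peps <- data.frame(sequence = c("AKGGER", "EKFLMV"), protein_id = "P",
                     start = 1L, end = 6L, missed_cleavages = 0L,
                     is_decoy = FALSE)
  peps$mass <- vapply(peps$sequence, peptide_mass, 0)
  sp <- build_products(peps, lk, enable_single = FALSE, enable_mono = FALSE,
                       enable_loop = FALSE)
  dip <- which(sp$products$kind == "dipeptide" &
                 sp$products$pep_a != sp$products$pep_b)[1]
  fr <- theoretical_spectrum(sp, dip)
  alpha_tag <- fr$peptide[1]
  # spectrum holding only alpha fragments: beta partial is 0
  only_a <- fr[fr$peptide == "alpha", ]
  spec <- processed_spectrum("p", sp$products$total_mass[dip],
                             only_a$mass, rep(100, nrow(only_a)))
  ps <- partial_scores(fr, spec, score_params())
  expect_gt(ps$alpha$score, 0)
  expect_equal(ps$beta$score, 0)
  # homodimer with its full spectrum: symmetric partials
  hom <- which(sp$products$kind == "dipeptide" &
                 sp$products$pep_a == sp$products$pep_b)[1]
  frh <- theoretical_spectrum(sp, hom)
  spech <- processed_spectrum("h", sp$products$total_mass[hom],
                              frh$mass, rep(100, nrow(frh)))
  psh <- partial_scores(frh, spech, score_params())
  expect_equal(psh$alpha$score, psh$beta$score, tolerance = 1e-9)
  # partials agree with an independent brute-force binomial evaluation
  k <- ps$alpha$k; n <- ps$alpha$n
  p <- ps$alpha$q * 2 * 20e-6 * mean(only_a$mass) / 100
  expect_equal(10^(-ps$alpha$score / 10), binom_tail_oracle(k, n, p),
               tolerance = 1e-9)
})

test_that("indexed search equals the exhaustive all-products scan", {
  sp <- small_space(seed = 6)
  lt <- linkable_targets(sp)
  params <- score_params()
  brute_force <- function(proc) {
    masses <- sp$products$total_mass
    cand <- which(abs(masses - proc$precursor_neutral_mass) /
                    proc$precursor_neutral_mass <= 10e-6)
    if (!length(cand)) return(NULL)
    scores <- vapply(cand, function(i)
      andromeda_score(theoretical_spectrum(sp, i), proc, params)$score, 0)
    ids <- sp$products$id[cand]
    ids[order(-scores, ids)][1]
  }
  set.seed(55)
  for (r in 1:8) {
    ij <- sample(lt$idx, 2L, replace = TRUE)
    fx <- make_noncleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], sp$linker,
      dropout_frac = 0.1, n_noise_peaks = 20, seed = 200 + r)
    proc <- deisotope_deconvolute(fx$spectrum)
    res <- search_spectrum(proc, sp, params)
    bf <- brute_force(proc)
    if (is.null(bf)) expect_equal(nrow(res), 0L) else
      expect_equal(res$product_id[1], bf)
  }
  # no candidate in tolerance: empty result
  off <- processed_spectrum("off", 123.456, c(100, 200), c(1, 1))
  expect_equal(nrow(search_spectrum(off, sp, params)), 0L)
})

test_that("noise-free fixtures rank the generating dipeptide first", {
  sp <- small_space(seed = 8)
  lt <- linkable_targets(sp)
  set.seed(77)
  hits <- 0L; n <- 20L
  for (r in seq_len(n)) {
    ij <- sample(lt$idx, 2L, replace = TRUE)
    fx <- make_noncleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], sp$linker,
      seed = 300 + r)
    res <- search_spectrum(deisotope_deconvolute(fx$spectrum), sp)
    top <- res[1, ]
    ok <- top$kind == "dipeptide" &&
      setequal(c(top$seq_a, top$seq_b),
               c(fx$truth$pep_a, fx$truth$pep_b))
    hits <- hits + ok
  }
  expect_gte(hits / n, 0.95)
})
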