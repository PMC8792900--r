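dsso_like <- function() crosslinker("XSO", "K", intact_mass = 158.0,
                                    cleavable = TRUE, short_residual = 63.0,
                                    long_residual = 95.0)

test_that("strict quadruplets apply the three signature-mass equations", {
  lk <- crosslinker("Q", "K", intact_mass = 150, cleavable = TRUE,
                    short_residual = 59, long_residual = 91)  # dm = 32
  # m_p = 2000, beta_s = 800: beta_l = 832, alpha_s = 1168, alpha_l = 1200
  s <- processed_spectrum("q", 2000, c(800, 832, 1168, 1200), rep(10, 4))
  h <- strict_quadruplets(s, lk, tol_ppm = 10)
  expect_equal(nrow(h), 1L)
  expect_equal(h$m_beta, 800 - 59)
  expect_equal(h$m_alpha, 1168 - 59)
  expect_equal(h$evidence, "quadruplet")
  # missing one signature peak: nothing strict
  s2 <- processed_spectrum("q2", 2000, c(800, 832, 1168), rep(10, 3))
  expect_equal(nrow(strict_quadruplets(s2, lk, tol_ppm = 10)), 0L)
})

test_that("homodimeric quadruplets degenerate to two observed peaks", {
  lk <- dsso_like()
  m <- peptide_mass("SAMPLEKAR")
  mp <- 2 * m + lk$intact_mass
  peaks <- c(m + lk$short_residual, m + lk$long_residual)
  s <- processed_spectrum("h", mp, peaks, c(10, 10))
  h <- strict_quadruplets(s, lk, tol_ppm = 10)
  expect_gte(nrow(h), 1L)
  expect_equal(h$m_alpha[1], m, tolerance = 1e-6)
  expect_equal(h$m_beta[1], m, tolerance = 1e-6)
})

test_that("top-intensity hypotheses enumerate residuals and NH3 states", {
  lk <- dsso_like()
  mp <- 3000
  # one dominant peak; 2 residual states (+ NH3 restoration) survive filters
  s <- processed_spectrum("t", mp, c(300, 900, 1200), c(1, 2, 100))
  h <- top_intensity_hypotheses(s, lk, n_top = 1L, min_peptide_mass = 500,
                                allow_nh3 = TRUE)
  expect_true(all(h$evidence == "top_intensity"))
  expect_lte(nrow(h), 4L)
  expect_gte(nrow(h), 1L)
  # derived masses respect the precursor relation
  expect_true(all(abs(h$m_alpha + h$m_beta + lk$intact_mass - mp) < 1e-6))
  # all partners below the minimum mass: empty
  h2 <- top_intensity_hypotheses(
    processed_spectrum("t2", 1200, c(1100), c(10)), lk,
    min_peptide_mass = 500)
  expect_equal(nrow(h2), 0L)
})

test_that("relaxed pairs accept a single delta_m doublet", {
  lk <- crosslinker("Q", "K", intact_mass = 150, cleavable = TRUE,
                    short_residual = 59, long_residual = 91)
  s <- processed_spectrum("r", 2000, c(800, 832), c(5, 5))
  h <- relaxed_pairs(s, lk, tol_ppm = 10)
  expect_equal(nrow(h), 1L)
  expect_equal(h$m_beta, 800 - 59)
  expect_equal(h$m_alpha, 2000 - 150 - (800 - 59))
  # no pair within tolerance
  s2 <- processed_spectrum("r2", 2000, c(800, 840), c(5, 5))
  expect_equal(nrow(relaxed_pairs(s2, lk, tol_ppm = 10)), 0L)
})

test_that("relaxed detection contains every strict beta doublet", {
  lk <- dsso_like()
  sp <- small_space(lk, seed = 12)
  lt <- linkable_targets(sp)
  set.seed(66)
  for (r in 1:5) {
    ij <- sample(lt$idx, 2L)
    fx <- make_cleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], lk,
      n_noise_peaks = 15, seed = 400 + r)
    proc <- deisotope_deconvolute(fx$spectrum)
    hs <- strict_quadruplets(proc, lk)
    hr <- relaxed_pairs(proc, lk)
    if (nrow(hs)) {
      for (i in seq_len(nrow(hs)))
        expect_true(any(abs(hr$m_beta - hs$m_beta[i]) < 1e-6))
    }
  }
})

test_that("every cascade hypothesis satisfies the precursor-sum identity", {
  lk <- linker_preset("DSSO")
  sp <- small_space(lk, seed = 13)
  lt <- linkable_targets(sp)
  set.seed(99)
  combos <- list(
    c("beta_s", "beta_l", "alpha_s", "alpha_l"),
    c("alpha_l"), c("beta_s", "beta_l"), character())
  for (r in 1:12) {
    ij <- sample(lt$idx, 2L, replace = TRUE)
    fx <- make_cleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], lk,
      which_signatures = combos[[1 + r %% 4]],
      n_noise_peaks = 10, seed = 500 + r)
    proc <- deisotope_deconvolute(fx$spectrum)
    casc <- signature_cascade(proc, lk)
    if (!nrow(casc$hypotheses)) next
    mp <- proc$precursor_neutral_mass
    tol2 <- 2 * 10e-6 * mp
    h <- casc$hypotheses
    lhs1 <- (h$m_alpha + lk$short_residual) + (h$m_beta + lk$long_residual)
    lhs2 <- (h$m_alpha + lk$long_residual) + (h$m_beta + lk$short_residual)
    expect_true(all(abs(lhs1 - mp) <= tol2))
    expect_true(all(abs(lhs2 - mp) <= tol2))
  }
})

test_that("the cascade stages fire in order and are logged", {
  lk <- linker_preset("DSSO")
  sp <- small_space(lk, seed = 14)
  lt <- linkable_targets(sp)
  i <- lt$idx[2]; j <- lt$idx[4]
  args <- list(sp$peptides$sequence[i], sp$peptides$sequence[j],
               lt$sites[[i]][1], lt$sites[[j]][1], lk)
  # all four signatures: strict; top-intensity absent from the audit
  fx <- do.call(make_cleavable_spectrum, c(args, list(seed = 21)))
  res <- search_spectrum_cleavable(deisotope_deconvolute(fx$spectrum), sp)
  expect_equal(attr(res, "audit")$stage, "strict")
  # only one intense alpha_l signature: top-intensity stage
  fx2 <- do.call(make_cleavable_spectrum,
                 c(args, list(which_signatures = "alpha_l", seed = 22)))
  res2 <- search_spectrum_cleavable(deisotope_deconvolute(fx2$spectrum), sp)
  expect_equal(attr(res2, "audit")$stage, "top_intensity")
  expect_equal(res2$seq_a[1], sp$peptides$sequence[i])
  # beta doublet only, planted at low intensity: relaxed stage
  fx3 <- do.call(make_cleavable_spectrum,
                 c(args, list(which_signatures = c("beta_s", "beta_l"),
                              seed = 23)))
  proc3 <- deisotope_deconvolute(fx3$spectrum)
  # suppress the planted doublet below the top-3 so the relaxed stage runs
  o <- order(-proc3$intensity)
  sig <- fx3$truth$signature_masses[c("beta_s", "beta_l")]
  drop <- sapply(proc3$mass, function(m) any(abs(m - sig) < 1e-3))
  proc3$intensity[drop] <- 0.5
  res3 <- search_spectrum_cleavable(proc3, sp, min_peptide_mass = 1e5)
  expect_equal(attr(res3, "audit")$stage, "relaxed_pair")
})

test_that("cleavable search identifies planted dipeptides incl. homodimers", {
  lk <- linker_preset("DSBU")
  sp <- small_space(lk, seed = 15)
  lt <- linkable_targets(sp)
  set.seed(88)
  hits <- 0L; n <- 12L
  for (r in seq_len(n)) {
    homo <- r %% 4L == 0L
    ij <- if (homo) rep(sample(lt$idx, 1L), 2L) else sample(lt$idx, 2L)
    fx <- make_cleavable_spectrum(
      sp$peptides$sequence[ij[1]], sp$peptides$sequence[ij[2]],
      lt$sites[[ij[1]]][1], lt$sites[[ij[2]]][1], lk, seed = 600 + r)
    res <- search_spectrum_cleavable(deisotope_deconvolute(fx$spectrum), sp)
    if (nrow(res) &&
        setequal(c(res$seq_a[1], res$seq_b[1]),
                 c(fx$truth$pep_a, fx$truth$pep_b)))
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("hypotheses without database support produce no CSMs", {
  lk <- linker_preset("DSSO")
  sp <- small_space(lk, seed = 16)
  # quadruplet for masses no peptide in the database has
  mb <- 777.77; ma <- 1234.56
  mp <- ma + mb + lk$intact_mass
  peaks <- c(mb + lk$short_residual, mb + lk$long_residual,
             ma + lk$short_residual, ma + lk$long_residual)
  s <- processed_spectrum("none", mp, peaks, rep(10, 4))
  res <- search_spectrum_cleavable(s, sp)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "audit")$stage, "strict")
  expect_gte(attr(res, "audit")$n_hypotheses, 1L)
})
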