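# Seeded fixture generators: protein databases, noncleavable and cleavable
# MS/MS spectra with known ground truth, and 3D isotope-pattern fixtures.
# All randomness is local: each generator seeds its own RNG and restores
# the caller's state.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate a random protein database
#'
#' Residues are drawn with frequencies close to natural abundance; the
#' lysine (and arginine) frequency is controllable so the density of tryptic
#' cleavage and cross-link sites can be tuned.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (residues).
#' @param seed Integer seed; the same seed reproduces identical output.
#' @param k_freq,r_freq Relative frequencies of K and R.
#' @return `data.frame(id, sequence, is_decoy)`.
#' @export
make_database <- function(n_proteins, length_range = c(80L, 160L), seed = 1L,
                          k_freq = 0.08, r_freq = 0.05) {
  aa <- setdiff(names(residue_masses()), c("K", "R", "I"))
  w <- stats::setNames(rep(1, length(aa)), aa)
  w[c("L", "A", "G", "S", "E", "V")] <- 1.6
  w <- w / sum(w) * (1 - k_freq - r_freq)
  letters_all <- c(aa, "K", "R")
  probs <- c(w, K = k_freq, R = r_freq)
  .with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(n)
      paste(sample(letters_all, n, replace = TRUE, prob = probs),
            collapse = ""), "")
    data.frame(id = sprintf("SYN%03d", seq_len(n_proteins)),
               sequence = seqs, is_decoy = FALSE)
  })
}

# Rank-based fragment intensity model: intensities decrease with draw rank
# so only ordinal assumptions enter the algorithms under test.
.rank_intensities <- function(n, top = 1000) {
  if (!n) return(numeric())
  top * stats::runif(n)^2
}

#' Simulate a noncleavable cross-linked dipeptide spectrum
#'
#' b/y fragments of both peptides (site-containing fragments shifted by the
#' intact linker plus the partner mass) are planted at the requested
#' fragment charges, thinned by `dropout_frac`, and mixed with uniform noise
#' peaks. The precursor m/z is exact for the dipeptide mass.
#'
#' @param pep_a,pep_b Peptide sequences.
#' @param site_a,site_b 1-based linked positions.
#' @param linker An `xl_linker`.
#' @param precursor_charge Precursor charge state.
#' @param fragment_charges Charge states at which fragment peaks appear.
#' @param dropout_frac Fraction of fragment peaks removed at random.
#' @param n_noise_peaks Number of uniform noise peaks added.
#' @param seed Integer seed.
#' @param scan_id Scan identifier.
#' @return List: `spectrum` (`xl_rawspec`) and `truth` (generating product,
#'   planted peak provenance, parameters, seed).
#' @export
make_noncleavable_spectrum <- function(pep_a, pep_b, site_a, site_b, linker,
                                       precursor_charge = 3L,
                                       fragment_charges = 1L,
                                       dropout_frac = 0, n_noise_peaks = 0,
                                       seed = 1L, scan_id = NULL) {
  ma <- peptide_mass(pep_a); mb <- peptide_mass(pep_b)
  total <- ma + mb + linker$intact_mass
  fr <- rbind(
    .pep_fragments(pep_a, "", site_a, linker$intact_mass + mb, "alpha"),
    .pep_fragments(pep_b, "", site_b, linker$intact_mass + ma, "beta"))
  .with_seed(seed, {
    keep <- stats::runif(nrow(fr)) >= dropout_frac
    fr <- fr[keep, , drop = FALSE]
    mz <- if (nrow(fr)) unlist(lapply(fragment_charges, function(z)
      neutral_to_mz(fr$mass, z))) else numeric()
    prov <- if (nrow(fr)) rep(paste0("fragment:", fr$peptide, ":", fr$label),
                              length(fragment_charges)) else character()
    ints <- .rank_intensities(length(mz))
    if (n_noise_peaks > 0) {
      lim <- c(100, neutral_to_mz(total, 1L))
      nmz <- stats::runif(n_noise_peaks, lim[1L], lim[2L])
      mz <- c(mz, nmz)
      ints <- c(ints, .rank_intensities(n_noise_peaks, top = 300))
      prov <- c(prov, rep("noise", n_noise_peaks))
    }
    o <- order(mz)
    if (is.null(scan_id))
      scan_id <- sprintf("nc_%s_%s_s%d", pep_a, pep_b, seed)
    spec <- raw_spectrum(scan_id, neutral_to_mz(total, precursor_charge),
                         precursor_charge, mz[o], ints[o])
    list(spectrum = spec,
         truth = list(kind = "dipeptide", pep_a = pep_a, pep_b = pep_b,
                      site_a = site_a, site_b = site_b,
                      linker = linker$name, total_mass = total,
                      provenance = prov[o], dropout_frac = dropout_frac,
                      n_noise_peaks = n_noise_peaks, seed = seed))
  })
}

#' Simulate an MS-cleavable cross-linked dipeptide spectrum
#'
#' Plants the selected signature peaks (optionally as NH3-loss variants),
#' the b/y ladders of both linear peptides with the short linker residual on
#' site-containing fragments, dropout and uniform noise. Signature peaks are
#' drawn from the top intensity decile so the top-intensity stage can find
#' them. A homodimeric fixture (`pep_a == pep_b`) collapses the four
#' signature species onto two observed masses.
#'
#' @param pep_a,pep_b Peptide sequences (alpha is taken as the longer).
#' @param site_a,site_b Linked positions on `pep_a` / `pep_b`.
#' @param linker A cleavable `xl_linker`.
#' @param which_signatures Subset of
#'   `c("beta_s", "beta_l", "alpha_s", "alpha_l")` to plant.
#' @param nh3_on Subset of `which_signatures` planted as -NH3 variants.
#' @param precursor_charge Precursor charge state.
#' @param dropout_frac,n_noise_peaks,seed,scan_id As in
#'   [make_noncleavable_spectrum()].
#' @return List: `spectrum` and `truth` (with the four signature masses).
#' @export
make_cleavable_spectrum <- function(pep_a, pep_b, site_a, site_b, linker,
                                    which_signatures = c("beta_s", "beta_l",
                                                         "alpha_s", "alpha_l"),
                                    nh3_on = character(),
                                    precursor_charge = 3L,
                                    dropout_frac = 0, n_noise_peaks = 0,
                                    seed = 1L, scan_id = NULL) {
  stopifnot(linker$cleavable)
  ma <- peptide_mass(pep_a); mb <- peptide_mass(pep_b)
  # alpha = longer peptide
  if (mb > ma || (mb == ma && pep_b < pep_a)) {
    tmp <- pep_a; pep_a <- pep_b; pep_b <- tmp
    tmp <- site_a; site_a <- site_b; site_b <- tmp
    tmp <- ma; ma <- mb; mb <- tmp
  }
  total <- ma + mb + linker$intact_mass
  sig <- c(beta_s = mb + linker$short_residual,
           beta_l = mb + linker$long_residual,
           alpha_s = ma + linker$short_residual,
           alpha_l = ma + linker$long_residual)
  planted <- sig[which_signatures]
  planted[names(planted) %in% nh3_on] <-
    planted[names(planted) %in% nh3_on] - MASS_CONST[["nh3"]]
  fr <- rbind(
    .cleavable_fragments(pep_a, "", site_a, linker, "alpha"),
    .cleavable_fragments(pep_b, "", site_b, linker, "beta"))
  fr <- fr[!endsWith(fr$label, "*"), , drop = FALSE]  # short-residual state
  .with_seed(seed, {
    keep <- stats::runif(nrow(fr)) >= dropout_frac
    fr <- fr[keep, , drop = FALSE]
    mz <- neutral_to_mz(fr$mass, 1L)
    # fragments stay below the signature-intensity band: the top-intensity
    # detection stage assumes signature peaks are among the most intense
    ints <- .rank_intensities(length(mz), top = 700)
    prov <- if (nrow(fr)) paste0("fragment:", fr$peptide, ":", fr$label) else
      character()
    if (length(planted)) {
      mz <- c(mz, neutral_to_mz(unname(planted), 1L))
      ints <- c(ints, stats::runif(length(planted), 900, 1000))
      prov <- c(prov, paste0("signature:", names(planted)))
    }
    if (n_noise_peaks > 0) {
      lim <- c(100, neutral_to_mz(total, 1L))
      nmz <- stats::runif(n_noise_peaks, lim[1L], lim[2L])
      mz <- c(mz, nmz)
      ints <- c(ints, .rank_intensities(n_noise_peaks, top = 300))
      prov <- c(prov, rep("noise", n_noise_peaks))
    }
    o <- order(mz)
    if (is.null(scan_id))
      scan_id <- sprintf("cl_%s_%s_s%d", pep_a, pep_b, seed)
    spec <- raw_spectrum(scan_id, neutral_to_mz(total, precursor_charge),
                         precursor_charge, mz[o], ints[o])
    list(spectrum = spec,
         truth = list(kind = "dipeptide", pep_a = pep_a, pep_b = pep_b,
                      site_a = site_a, site_b = site_b,
                      linker = linker$name, total_mass = total,
                      signature_masses = sig,
                      which_signatures = which_signatures, nh3_on = nh3_on,
                      provenance = prov[o], dropout_frac = dropout_frac,
                      n_noise_peaks = n_noise_peaks, seed = seed))
  })
}

#' Simulate a 3D isotope-pattern fixture
#'
#' Builds an isotope pattern of `n_isotopes` 3D peaks with Poisson averagine
#' intensities for the given neutral mass and charge. `gap_spec` can delete
#' leading isotopes (`drop_leading`) and/or split the RT profile of one
#' member into two fragments separated by a gap (`split_member`, 1-based
#' after deletion), emulating noise-fragmented peaks of heavy precursors;
#' the neighboring members stay intact and bridge the gap.
#'
#' @param true_mono_mass Neutral monoisotopic mass in Da.
#' @param charge Pattern charge.
#' @param n_isotopes Number of isotope members before deletions.
#' @param rt_center,rt_width RT apex and full width (seconds).
#' @param gap_spec List with optional `drop_leading` (integer) and
#'   `split_member` (integer).
#' @param seed Integer seed (jitters RT bounds).
#' @return List: `peaks` (list of `xl_peak3d`) and `truth`
#'   (`true_mono_mass`, `charge`, `gap_spec`).
#' @export
make_isotope_fixture <- function(true_mono_mass, charge = 2L,
                                 n_isotopes = 5L, rt_center = 100,
                                 rt_width = 30, gap_spec = list(),
                                 seed = 1L) {
  drop_leading <- if (is.null(gap_spec$drop_leading)) 0L else
    as.integer(gap_spec$drop_leading)
  split_member <- gap_spec$split_member
  expec <- .averagine_profile(true_mono_mass, n_isotopes)
  sp <- MASS_CONST[["isotope"]] / charge
  mono_mz <- neutral_to_mz(true_mono_mass, charge)
  .with_seed(seed, {
    peaks <- list()
    for (i in seq_len(n_isotopes)) {
      if (i <= drop_leading) next
      mz_i <- mono_mz + (i - 1L) * sp
      lo <- rt_center - rt_width / 2 + stats::runif(1, -1, 1)
      hi <- rt_center + rt_width / 2 + stats::runif(1, -1, 1)
      inten <- expec[i] * 1e6
      if (!is.null(split_member) &&
          i == drop_leading + as.integer(split_member)) {
        gap <- sort(stats::runif(2, lo + 0.2 * (hi - lo),
                                 hi - 0.2 * (hi - lo)))
        if (diff(gap) < 1) gap <- mean(gap) + c(-1, 1)
        f1 <- (gap[1L] - lo) / (hi - lo); f2 <- (hi - gap[2L]) / (hi - lo)
        peaks <- c(peaks, list(
          peak3d(mz_i, lo, gap[1L],
                 data.frame(rt = c(lo, gap[1L]),
                            intensity = rep(inten * f1 / 2, 2L))),
          peak3d(mz_i, gap[2L], hi,
                 data.frame(rt = c(gap[2L], hi),
                            intensity = rep(inten * f2 / 2, 2L)))))
      } else {
        peaks <- c(peaks, list(
          peak3d(mz_i, lo, hi,
                 data.frame(rt = c(lo, hi), intensity = rep(inten / 2, 2L)))))
      }
    }
    peaks <- peaks[order(vapply(peaks, `[[`, 0, "mz"))]
    list(peaks = peaks,
         truth = list(true_mono_mass = true_mono_mass, charge = charge,
                      n_isotopes = n_isotopes, drop_leading = drop_leading,
                      split_member = split_member, seed = seed))
  })
}

#' Write a fixture truth sidecar
#'
#' @param truth Truth list from a generator.
#' @param path Output path (JSON).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
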