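# MS-cleavable cross-link search.  When the labile linker bonds break
# during fragmentation, each constituent peptide appears with either the
# short or the long linker residual, giving up to four signature peaks
# (beta_s, beta_l, alpha_s, alpha_l) related by
#   m_beta_l  = m_beta_s + delta_m
#   m_alpha_s = m_p - m_beta_l
#   m_alpha_l = m_p - m_beta_s
# where m_p is the neutral precursor mass of the whole dipeptide.  Three
# detection strategies are applied in succession: the strict quadruplet
# approach, the top-intensity approach (with optional NH3-loss restoration),
# and a relaxed single-pair approach.

.hypothesis <- function(m1, m2, evidence, peaks, nh3 = FALSE) {
  data.frame(m_alpha = max(m1, m2), m_beta = min(m1, m2),
             evidence = evidence,
             peaks = paste(sprintf("%.5f", peaks), collapse = ";"),
             nh3_loss_used = nh3)
}

.dedup_hypotheses <- function(h, tol_da) {
  if (!nrow(h)) return(h)
  key <- paste(round(h$m_alpha / tol_da), round(h$m_beta / tol_da))
  h[!duplicated(key), , drop = FALSE]
}

# A peak exists within +/- tol of target (tol in Da)?
.has_peak <- function(mass, target, tol) any(abs(mass - target) <= tol)

#' Strict quadruplet signature-peak detection
#'
#' Every peak above `min_signature_mass` is hypothesized to be the
#' short-residual beta peak; the three remaining signature peaks are then
#' required at their implied masses within tolerance. Degenerate
#' (homodimeric) matches, where the beta and alpha doublets coincide, are
#' allowed.
#'
#' @param spectrum An `xl_procspec` with known precursor mass.
#' @param linker A cleavable `xl_linker`.
#' @param min_signature_mass Smallest peak mass considered (Da, default 200
#'   to skip the immonium region).
#' @param tol_ppm Tolerance in ppm of the precursor mass.
#' @return `data.frame(m_alpha, m_beta, evidence, peaks, nh3_loss_used)`;
#'   peptide masses have the short residual removed and `m_alpha >= m_beta`.
#' @export
strict_quadruplets <- function(spectrum, linker, min_signature_mass = 200,
                               tol_ppm = 10) {
  stopifnot(linker$cleavable)
  mp <- spectrum$precursor_neutral_mass
  tol <- tol_ppm * 1e-6 * mp
  mass <- spectrum$mass
  cand <- mass[mass >= min_signature_mass]
  out <- list()
  for (bs in cand) {
    bl <- bs + linker$delta_m
    as_ <- mp - bl
    al <- mp - bs
    if (as_ < min_signature_mass) next
    if (.has_peak(mass, bl, tol) && .has_peak(mass, as_, tol) &&
        .has_peak(mass, al, tol)) {
      out[[length(out) + 1L]] <- .hypothesis(
        as_ - linker$short_residual, bs - linker$short_residual,
        "quadruplet", c(bs, bl, as_, al))
    }
  }
  h <- if (length(out)) do.call(rbind, out) else .hypothesis(0, 0, "", 0)[0L, ]
  h <- h[h$m_beta > 0, , drop = FALSE]
  .dedup_hypotheses(h, tol)
}

#' Top-intensity signature-peak hypotheses
#'
#' Invoked when the strict approach finds nothing. Each of the `n_top` most
#' intense peaks is hypothesized to carry either the short or the long
#' residual, optionally after restoring an NH3 loss; the partner peptide
#' mass follows from the precursor mass. Hypotheses where either peptide is
#' below `min_peptide_mass` are dropped.
#'
#' @param spectrum An `xl_procspec`.
#' @param linker A cleavable `xl_linker`.
#' @param n_top Number of top-intensity peaks tried (default 3).
#' @param min_peptide_mass Minimum derived peptide mass (Da).
#' @param allow_nh3 Also try restoring an ammonia loss on the peak.
#' @param tol_ppm Tolerance used for deduplication.
#' @return Hypothesis `data.frame` as in [strict_quadruplets()].
#' @export
top_intensity_hypotheses <- function(spectrum, linker, n_top = 3L,
                                     min_peptide_mass = 500,
                                     allow_nh3 = TRUE, tol_ppm = 10) {
  stopifnot(linker$cleavable)
  mp <- spectrum$precursor_neutral_mass
  if (!length(spectrum$mass)) return(.hypothesis(0, 0, "", 0)[0L, ])
  o <- order(-spectrum$intensity, spectrum$mass)
  top <- spectrum$mass[o[seq_len(min(n_top, length(o)))]]
  losses <- if (allow_nh3) c(0, MASS_CONST[["nh3"]]) else 0
  out <- list()
  for (pk in top) for (loss in losses) {
    obs <- pk + loss  # loss-restored signature peak mass
    for (res in c(linker$short_residual, linker$long_residual)) {
      m_this <- obs - res
      m_partner <- mp - linker$intact_mass - m_this
      if (m_this >= min_peptide_mass && m_partner >= min_peptide_mass)
        out[[length(out) + 1L]] <- .hypothesis(m_this, m_partner,
                                               "top_intensity", pk,
                                               nh3 = loss > 0)
    }
  }
  h <- if (length(out)) do.call(rbind, out) else .hypothesis(0, 0, "", 0)[0L, ]
  .dedup_hypotheses(h, tol_ppm * 1e-6 * mp)
}

#' Relaxed single-pair signature detection
#'
#' Final fallback: any peak pair separated by delta_m within tolerance is
#' read as the beta short/long doublet; the alpha mass is inferred from the
#' precursor mass without requiring its peaks to be observed.
#'
#' @inheritParams strict_quadruplets
#' @return Hypothesis `data.frame` as in [strict_quadruplets()].
#' @export
relaxed_pairs <- function(spectrum, linker, min_signature_mass = 200,
                          tol_ppm = 10) {
  stopifnot(linker$cleavable)
  mp <- spectrum$precursor_neutral_mass
  tol <- tol_ppm * 1e-6 * mp
  mass <- spectrum$mass[spectrum$mass >= min_signature_mass]
  out <- list()
  for (bs in mass) {
    if (.has_peak(mass, bs + linker$delta_m, tol)) {
      m_beta <- bs - linker$short_residual
      m_alpha <- mp - linker$intact_mass - m_beta
      if (m_beta > 0 && m_alpha > 0)
        out[[length(out) + 1L]] <- .hypothesis(m_alpha, m_beta,
                                               "relaxed_pair",
                                               c(bs, bs + linker$delta_m))
    }
  }
  h <- if (length(out)) do.call(rbind, out) else .hypothesis(0, 0, "", 0)[0L, ]
  .dedup_hypotheses(h, tol)
}

#' Run the three-stage signature-peak cascade
#'
#' Strict quadruplets first; if empty, top-intensity hypotheses; if still
#' empty, relaxed pairs.
#'
#' @inheritParams top_intensity_hypotheses
#' @param min_signature_mass Passed to the strict and relaxed stages.
#' @return List: `hypotheses` (data.frame) and `stage` (`"strict"`,
#'   `"top_intensity"`, `"relaxed_pair"` or `"none"`).
#' @export
signature_cascade <- function(spectrum, linker, min_signature_mass = 200,
                              n_top = 3L, min_peptide_mass = 500,
                              allow_nh3 = TRUE, tol_ppm = 10) {
  h <- strict_quadruplets(spectrum, linker, min_signature_mass, tol_ppm)
  if (nrow(h)) return(list(hypotheses = h, stage = "strict"))
  h <- top_intensity_hypotheses(spectrum, linker, n_top, min_peptide_mass,
                                allow_nh3, tol_ppm)
  if (nrow(h)) return(list(hypotheses = h, stage = "top_intensity"))
  h <- relaxed_pairs(spectrum, linker, min_signature_mass, tol_ppm)
  list(hypotheses = h, stage = if (nrow(h)) "relaxed_pair" else "none")
}

# Signature-peak bonus: binomial tail over the four signature positions
# with the same chance model as fragment matching.
.signature_bonus <- function(spectrum, linker, m_alpha, m_beta, params,
                             weight = 1) {
  mp <- spectrum$precursor_neutral_mass
  targets <- c(m_beta + linker$short_residual, m_beta + linker$long_residual,
               m_alpha + linker$short_residual, m_alpha + linker$long_residual)
  k <- sum(.count_matches(targets, spectrum$mass, params$frag_tol_ppm))
  if (k == 0L) return(0)
  p <- .match_p(1L, targets, params$frag_tol_ppm, params$window)
  weight * binomial_match_score(k, 4L, p)
}

# Theoretical doublet fragments of one linear peptide in a cleavable
# dipeptide: site-containing fragments appear in both residual states;
# matching either counts once per theoretical position (dedup by label).
.cleavable_fragments <- function(sequence, mods_str, site, linker, tag) {
  fs <- .pep_fragments(sequence, mods_str, site, linker$short_residual, tag)
  fl <- .pep_fragments(sequence, mods_str, site, linker$long_residual, tag)
  fl <- fl[fl$mass != fs$mass, , drop = FALSE]  # only shifted positions differ
  fl$label <- paste0(fl$label, "*")
  rbind(fs, fl)
}

# Deduplicating match count for doublet fragments: a theoretical position
# (label without the doublet star) counts at most once.
.count_doublet_matches <- function(fr, peak_mass, tol_ppm) {
  hit <- .count_matches(fr$mass, peak_mass, tol_ppm)
  pos <- paste(fr$peptide, sub("\\*$", "", fr$label))
  length(unique(pos[hit]))
}

# Score doublet fragments: binomial over the number of distinct theoretical
# positions, maximized over q as in andromeda_score.
.doublet_score <- function(fr, spectrum, params) {
  n <- length(unique(paste(fr$peptide, sub("\\*$", "", fr$label))))
  if (n == 0L) return(list(score = 0, k = 0L, n = 0L, q = NA_integer_))
  best <- list(score = 0, k = 0L, n = n, q = 1L)
  for (q in seq_len(params$q_max)) {
    filt <- window_filter(spectrum, q, params$window)
    k <- .count_doublet_matches(fr, filt$mass, params$frag_tol_ppm)
    if (k == 0L) next
    p <- .match_p(q, fr$mass, params$frag_tol_ppm, params$window)
    sc <- binomial_match_score(k, n, p)
    if (sc > best$score) best <- list(score = sc, k = as.integer(k), n = n,
                                      q = q)
  }
  best
}

#' Search one spectrum with the MS-cleavable engine
#'
#' Runs the signature cascade, fetches candidate alpha/beta peptides by mass
#' for each hypothesis, assembles dipeptide candidates, scores the combined
#' doublet-state b/y spectrum plus a signature-peak bonus, and ranks
#' deterministically. Candidate peptides must carry an eligible link site.
#'
#' @param spectrum An `xl_procspec`.
#' @param space An `xl_space` built over the same linker (its peptide table
#'   provides the linear-peptide mass index).
#' @param params [score_params()].
#' @param precursor_tol_ppm Tolerance for peptide-mass lookup and the
#'   cascade.
#' @param min_signature_mass,n_top,min_peptide_mass,allow_nh3 Cascade
#'   parameters.
#' @param signature_weight Weight of the signature bonus added to the
#'   fragment score.
#' @param top_n Keep at most this many ranked CSMs.
#' @return `data.frame` of CSMs (as [search_spectrum()]) with attribute
#'   `audit`: a one-row data.frame (scan_id, stage, n_hypotheses,
#'   n_candidates).
#' @export
search_spectrum_cleavable <- function(spectrum, space,
                                      params = score_params(),
                                      precursor_tol_ppm = 10,
                                      min_signature_mass = 200, n_top = 3L,
                                      min_peptide_mass = 500,
                                      allow_nh3 = TRUE,
                                      signature_weight = 1, top_n = Inf) {
  linker <- space$linker
  stopifnot(linker$cleavable)
  peps <- space$peptides
  sites_a <- lapply(seq_len(nrow(peps)), function(i)
    link_sites(peps$sequence[i], union(linker$specificity_a,
                                       linker$specificity_b), peps$start[i]))
  casc <- signature_cascade(spectrum, linker, min_signature_mass, n_top,
                            min_peptide_mass, allow_nh3, precursor_tol_ppm)
  audit <- data.frame(scan_id = spectrum$scan_id, stage = casc$stage,
                      n_hypotheses = nrow(casc$hypotheses), n_candidates = 0L)
  empty <- .empty_csms()
  attr(empty, "audit") <- audit
  if (!nrow(casc$hypotheses)) return(empty)

  mp <- spectrum$precursor_neutral_mass
  linkable <- which(lengths(sites_a) > 0L)
  pmass <- peps$mass[linkable]
  find_peps <- function(m) {
    tol <- precursor_tol_ppm * 1e-6 * max(m, 1)
    linkable[abs(pmass - m) <= tol]
  }
  rows <- list()
  seen <- character()
  for (hrow in seq_len(nrow(casc$hypotheses))) {
    hyp <- casc$hypotheses[hrow, , drop = FALSE]
    cand_a <- find_peps(hyp$m_alpha)
    cand_b <- find_peps(hyp$m_beta)
    if (!length(cand_a) || !length(cand_b)) next
    for (ia in cand_a) for (ib in cand_b) {
      for (sa in sites_a[[ia]]) for (sb in sites_a[[ib]]) {
        key <- if (ia < ib || (ia == ib && sa <= sb))
          paste(ia, sa, ib, sb) else paste(ib, sb, ia, sa)
        if (key %in% seen) next
        seen <- c(seen, key)
        A <- peps[ia, , drop = FALSE]; B <- peps[ib, , drop = FALSE]
        a_first <- nchar(A$sequence) > nchar(B$sequence) ||
          (nchar(A$sequence) == nchar(B$sequence) && A$sequence <= B$sequence)
        if (a_first) { al <- A; als <- sa; be <- B; bes <- sb }
        else { al <- B; als <- sb; be <- A; bes <- sa }
        fr <- rbind(
          .cleavable_fragments(al$sequence, al$mods, als, linker, "alpha"),
          .cleavable_fragments(be$sequence, be$mods, bes, linker, "beta"))
        total <- .doublet_score(fr, spectrum, params)
        bonus <- .signature_bonus(spectrum, linker, al$mass, be$mass, params,
                                  signature_weight)
        pa <- .doublet_score(fr[fr$peptide == "alpha", , drop = FALSE],
                             spectrum, params)
        pb <- .doublet_score(fr[fr$peptide == "beta", , drop = FALSE],
                             spectrum, params)
        strip <- function(x) sub("^REV_", "", x)
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = spectrum$scan_id, product_row = NA_integer_,
          product_id = paste0("dipeptide|", al$sequence, "@",
                              al$protein_id, ":", al$start, "(", als, ")|",
                              be$sequence, "@", be$protein_id, ":",
                              be$start, "(", bes, ")"),
          kind = "dipeptide",
          seq_a = al$sequence, seq_b = be$sequence,
          protein_a = al$protein_id, protein_b = be$protein_id,
          pos_a = al$start + als - 1L, pos_b = be$start + bes - 1L,
          n_mods = al$n_mods + be$n_mods,
          missed_cleavages = max(al$missed_cleavages, be$missed_cleavages),
          score = total$score + bonus,
          partial_alpha = pa$score, partial_beta = pb$score,
          n_matched_alpha = pa$k, n_matched_beta = pb$k,
          decoy_class = .decoy_class2(al$is_decoy, be$is_decoy),
          intra = strip(al$protein_id) == strip(be$protein_id),
          total_mass = al$mass + be$mass + linker$intact_mass,
          evidence = hyp$evidence)
      }
    }
  }
  audit$n_candidates <- length(rows)
  if (!length(rows)) { attr(empty, "audit") <- audit; return(empty) }
  csms <- do.call(rbind, rows)
  o <- order(-csms$score, csms$n_mods, csms$product_id)
  csms <- csms[o, , drop = FALSE]
  csms$rank <- seq_len(nrow(csms))
  rownames(csms) <- NULL
  csms <- utils::head(csms, top_n)
  attr(csms, "audit") <- audit
  csms
}
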