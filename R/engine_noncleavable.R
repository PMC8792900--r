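# Noncleavable cross-link search: theoretical dipeptide spectra with
# cross-link mass shifts, the binomial-tail (Andromeda-style) score with
# top-q window filtering, per-peptide partial scores, and the indexed
# precursor search.

#' Scoring parameters
#'
#' @param window Peak-filter window width in Da.
#' @param q_max Peaks-per-window ceiling; the score is maximized over
#'   q = 1..q_max.
#' @param frag_tol_ppm Fragment match tolerance in ppm.
#' @param consider_losses Generate NH3/H2O neutral-loss fragments (off by
#'   default).
#' @return An `xl_score_params` list.
#' @export
score_params <- function(window = 100, q_max = 10L, frag_tol_ppm = 20,
                         consider_losses = FALSE) {
  stopifnot(q_max >= 1L, window > 0, frag_tol_ppm > 0)
  structure(list(window = window, q_max = as.integer(q_max),
                 frag_tol_ppm = frag_tol_ppm,
                 consider_losses = isTRUE(consider_losses)),
            class = "xl_score_params")
}

# Theoretical b/y fragments of one peptide variant, tagged with a peptide
# label; site-containing fragments carry shift_mass.
.pep_fragments <- function(sequence, mods_str, shift_site, shift_mass, tag,
                           consider_losses = FALSE) {
  mods <- .parse_mods(mods_str)
  out <- rbind(
    fragment_ladder(sequence, "b", shift_site, shift_mass, mods),
    fragment_ladder(sequence, "y", shift_site, shift_mass, mods))
  if (consider_losses && nrow(out)) {
    out <- rbind(out,
                 transform(out, label = paste0(label, "-NH3"),
                           mass = mass - MASS_CONST[["nh3"]]),
                 transform(out, label = paste0(label, "-H2O"),
                           mass = mass - MASS_CONST[["water"]]))
  }
  if (nrow(out)) out$peptide <- tag
  out
}

#' Theoretical fragment spectrum of a cross-link product
#'
#' For a dipeptide, b/y ladders of both constituents; fragments containing
#' the linked residue of one peptide are shifted by the intact linker mass
#' plus the full partner-peptide mass (the partner stays attached on a
#' noncleavable linker). Monolinks shift site-containing fragments by the
#' monolink mass; looplinks generate only fragments containing both linked
#' sites (shifted by the looplink mass) or neither, since the enclosed ring
#' cannot produce a simple b/y ion; singles are plain ladders.
#'
#' @param space An `xl_space`.
#' @param product_row Row index into `space$products`.
#' @param consider_losses Generate neutral-loss fragments.
#' @return `data.frame(label, index, mass, peptide)` with `peptide` in
#'   `"alpha"`, `"beta"` (dipeptides) or `"a"`.
#' @export
theoretical_spectrum <- function(space, product_row, consider_losses = FALSE) {
  pr <- space$products[product_row, , drop = FALSE]
  peps <- space$peptides
  lk <- space$linker
  kind <- pr$kind
  A <- peps[pr$pep_a, , drop = FALSE]
  if (kind == "single") {
    return(.pep_fragments(A$sequence, A$mods, NULL, 0, "a", consider_losses))
  }
  if (kind == "monolink") {
    return(.pep_fragments(A$sequence, A$mods, pr$site_a, lk$monolink_mass,
                          "a", consider_losses))
  }
  if (kind == "looplink") {
    fr <- .pep_fragments(A$sequence, A$mods, NULL, 0, "a", consider_losses)
    n <- nchar(A$sequence)
    contains <- function(idx, series, site)
      ifelse(series == "b", idx >= site, idx >= (n - site + 1L))
    series <- substr(fr$label, 1L, 1L)
    in1 <- contains(fr$index, series, pr$site_a)
    in2 <- contains(fr$index, series, pr$site_b)
    fr$mass[in1 & in2] <- fr$mass[in1 & in2] + lk$looplink_mass
    return(fr[!(xor(in1, in2)), , drop = FALSE])
  }
  if (kind %in% c("dipeptide", "higher_order")) {
    B <- peps[pr$pep_b, , drop = FALSE]
    # alpha is the longer constituent; ties broken lexicographically
    a_first <- nchar(A$sequence) > nchar(B$sequence) ||
      (nchar(A$sequence) == nchar(B$sequence) && A$sequence <= B$sequence)
    if (a_first) {
      al <- A; als <- pr$site_a; be <- B; bes <- pr$site_b
    } else {
      al <- B; als <- pr$site_b; be <- A; bes <- pr$site_a
    }
    mono_extra_a <- 0; mono_extra_b <- 0
    if (kind == "higher_order") {
      on_alpha <- (pr$extra_on == "a") == a_first
      if (on_alpha) mono_extra_a <- lk$monolink_mass else
        mono_extra_b <- lk$monolink_mass
    }
    shift_a <- lk$intact_mass + be$mass + mono_extra_b
    shift_b <- lk$intact_mass + al$mass + mono_extra_a
    fa <- .pep_fragments(al$sequence, al$mods, als, shift_a, "alpha",
                         consider_losses)
    fb <- .pep_fragments(be$sequence, be$mods, bes, shift_b, "beta",
                         consider_losses)
    # an extra monolink on a constituent also shifts its site-containing
    # fragments
    if (kind == "higher_order") {
      shift_extra <- function(fr, seq, site) {
        n <- nchar(seq)
        series <- substr(fr$label, 1L, 1L)
        hit <- ifelse(series == "b", fr$index >= site,
                      fr$index >= (n - site + 1L))
        fr$mass[hit] <- fr$mass[hit] + lk$monolink_mass
        fr
      }
      if (mono_extra_a > 0) fa <- shift_extra(fa, al$sequence, pr$extra_site)
      if (mono_extra_b > 0) fb <- shift_extra(fb, be$sequence, pr$extra_site)
    }
    return(rbind(fa, fb))
  }
  stop("unknown product kind: ", kind)
}

# Count theoretical fragments matched by spectrum peaks within ppm
# tolerance (each theoretical position at most once).
.count_matches <- function(frag_mass, peak_mass, tol_ppm) {
  if (!length(frag_mass) || !length(peak_mass))
    return(logical(length(frag_mass)))
  pm <- sort(peak_mass)
  tol <- tol_ppm * 1e-6 * frag_mass
  lo <- findInterval(frag_mass - tol, pm, left.open = TRUE) + 1L
  hi <- findInterval(frag_mass + tol, pm)
  hi >= lo
}

# Single-peak chance model: a spurious match lands in a 2*tol window out of
# a `window`-Da stretch holding q peaks.  tol in Da is evaluated at the mean
# theoretical fragment mass, making p constant across the binomial trials.
.match_p <- function(q, frag_mass, tol_ppm, window) {
  mref <- if (length(frag_mass)) mean(frag_mass) else 1000
  p <- q * 2 * tol_ppm * 1e-6 * mref / window
  min(max(p, 1e-12), 1 - 1e-12)
}

#' Match score from a binomial tail
#'
#' `-10*log10( P(X >= k) )` for `X ~ Binomial(n, p)`, evaluated in log space
#' so extreme tails (e.g. k = n = 10, p = 0.01 giving a score of 200) do not
#' underflow.
#'
#' @param k Matched fragments.
#' @param n Theoretical fragments.
#' @param p Single-match chance.
#' @return Non-negative score; 0 when `k` is 0 or `n` is 0.
#' @export
binomial_match_score <- function(k, n, p) {
  if (n == 0L || k == 0L) return(0)
  max(0, -10 * stats::pbinom(k - 1L, n, p, lower.tail = FALSE,
                             log.p = TRUE) / log(10))
}

#' Binomial-tail fragment-match score
#'
#' For each peak depth q in 1..q_max the spectrum is filtered to the q most
#' intense peaks per window, the k of n theoretical fragments with a peak
#' within tolerance are counted, and the score is
#' `-10*log10( P(X >= k) )` for `X ~ Binomial(n, p)` with single-match
#' chance `p = q * 2*tol_Da / window`. The maximum over q is returned.
#'
#' @param fragments `data.frame` with a `mass` column (neutral Da).
#' @param spectrum An `xl_procspec`.
#' @param params [score_params()].
#' @return List: `score`, `k` (matched at the best q), `n` (theoretical
#'   fragments), `q` (best depth).
#' @export
andromeda_score <- function(fragments, spectrum, params = score_params()) {
  n <- nrow(fragments)
  if (is.null(n) || n == 0L)
    return(list(score = 0, k = 0L, n = 0L, q = NA_integer_))
  best <- list(score = 0, k = 0L, n = n, q = 1L)
  for (q in seq_len(params$q_max)) {
    filt <- window_filter(spectrum, q, params$window)
    k <- sum(.count_matches(fragments$mass, filt$mass, params$frag_tol_ppm))
    if (k == 0L) next
    p <- .match_p(q, fragments$mass, params$frag_tol_ppm, params$window)
    sc <- binomial_match_score(k, n, p)
    if (sc > best$score) best <- list(score = sc, k = as.integer(k), n = n,
                                      q = q)
  }
  best
}

#' Per-peptide partial scores of a dipeptide match
#'
#' The partial score is the fragment-match score restricted to the ions of
#' one constituent peptide; alpha is the longer peptide (ties broken
#' lexicographically). The depth q is maximized independently per fragment
#' set.
#'
#' @param fragments Labeled fragments from [theoretical_spectrum()].
#' @param spectrum An `xl_procspec`.
#' @param params [score_params()].
#' @return List with `alpha` and `beta` score lists (as [andromeda_score()]).
#' @export
partial_scores <- function(fragments, spectrum, params = score_params()) {
  list(alpha = andromeda_score(fragments[fragments$peptide == "alpha", ,
                                         drop = FALSE], spectrum, params),
       beta  = andromeda_score(fragments[fragments$peptide == "beta", ,
                                         drop = FALSE], spectrum, params))
}

.empty_csms <- function() data.frame(
  scan_id = character(), product_row = integer(), product_id = character(),
  kind = character(), seq_a = character(), seq_b = character(),
  protein_a = character(), protein_b = character(), pos_a = integer(),
  pos_b = integer(), n_mods = integer(), missed_cleavages = integer(),
  score = numeric(), partial_alpha = numeric(), partial_beta = numeric(),
  n_matched_alpha = integer(), n_matched_beta = integer(),
  decoy_class = character(), intra = logical(), total_mass = numeric(),
  rank = integer())

# Assemble one CSM row.
.csm_row <- function(space, product_row, spectrum, total, parts) {
  pr <- space$products[product_row, , drop = FALSE]
  peps <- space$peptides
  A <- peps[pr$pep_a, , drop = FALSE]
  B <- if (!is.na(pr$pep_b)) peps[pr$pep_b, , drop = FALSE] else NULL
  dip <- pr$kind %in% c("dipeptide", "higher_order")
  strip <- function(x) sub("^REV_", "", x)
  data.frame(
    scan_id = spectrum$scan_id,
    product_row = product_row,
    product_id = pr$id,
    kind = pr$kind,
    seq_a = A$sequence,
    seq_b = if (dip) B$sequence else NA_character_,
    protein_a = A$protein_id,
    protein_b = if (dip) B$protein_id else NA_character_,
    pos_a = if (!is.na(pr$site_a)) A$start + pr$site_a - 1L else NA_integer_,
    pos_b = if (dip) B$start + pr$site_b - 1L else
      if (pr$kind == "looplink") A$start + pr$site_b - 1L else NA_integer_,
    n_mods = A$n_mods + if (dip) B$n_mods else 0L,
    missed_cleavages = max(A$missed_cleavages,
                           if (dip) B$missed_cleavages else 0L),
    score = total$score,
    partial_alpha = if (dip) parts$alpha$score else NA_real_,
    partial_beta = if (dip) parts$beta$score else NA_real_,
    n_matched_alpha = if (dip) parts$alpha$k else total$k,
    n_matched_beta = if (dip) parts$beta$k else NA_integer_,
    decoy_class = pr$decoy_class,
    intra = if (dip) strip(A$protein_id) == strip(B$protein_id) else NA,
    total_mass = pr$total_mass)
}

#' Search one spectrum against the noncleavable product index
#'
#' Every product whose indexed mass lies within the precursor tolerance of
#' the spectrum's neutral precursor mass is scored; results are ranked by
#' score descending, ties broken by fewer variable modifications and then
#' by product identity.
#'
#' @param spectrum An `xl_procspec`.
#' @param space An `xl_space`.
#' @param params [score_params()].
#' @param precursor_tol_ppm Precursor tolerance in ppm.
#' @param top_n Keep at most this many ranked CSMs (default all).
#' @return `data.frame` of CSMs with a `rank` column (possibly empty).
#' @export
search_spectrum <- function(spectrum, space, params = score_params(),
                            precursor_tol_ppm = 10, top_n = Inf) {
  empty <- .empty_csms()
  if (!nrow(space$products)) return(empty)
  if (!is.finite(spectrum$precursor_neutral_mass)) {
    message("spectrum ", spectrum$scan_id, " skipped: no precursor mass")
    return(empty)
  }
  cand <- query_index(space, spectrum$precursor_neutral_mass,
                      precursor_tol_ppm)
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(i) {
    fr <- theoretical_spectrum(space, i, params$consider_losses)
    total <- andromeda_score(fr, spectrum, params)
    parts <- if (space$products$kind[i] %in% c("dipeptide", "higher_order"))
      partial_scores(fr, spectrum, params) else NULL
    .csm_row(space, i, spectrum, total, parts)
  })
  csms <- do.call(rbind, rows)
  nv <- space$peptides$n_mods[space$products$pep_a[csms$product_row]] +
    ifelse(is.na(space$products$pep_b[csms$product_row]), 0L,
           space$peptides$n_mods[space$products$pep_b[csms$product_row]])
  o <- order(-csms$score, nv, csms$product_id)
  csms <- csms[o, , drop = FALSE]
  csms$rank <- seq_len(nrow(csms))
  rownames(csms) <- NULL
  utils::head(csms, top_n)
}
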