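# CSM validation: posterior error probability with covariate corrections,
# target-decoy FDR with TT/TD/DD accounting, and reporting filters.

#' Decoy class of a cross-link product
#'
#' @param decoy_a,decoy_b Logical decoy flags of the constituents
#'   (`decoy_b = NA` for single-peptide products).
#' @return `"TT"`, `"TD"`, `"DD"`, `"T"` or `"D"`; order-independent.
#' @export
classify_decoy <- function(decoy_a, decoy_b = NA) {
  if (is.na(decoy_b)) return(if (decoy_a) "D" else "T")
  .decoy_class2(decoy_a, decoy_b)
}

.is_false_class <- function(cls) cls %in% c("TD", "DD", "D")
.is_target_class <- function(cls) cls %in% c("TT", "T")

# Covariate matrix for the PEP model.  Dipeptides use the minimum partial
# score in place of peptide length; single-product CSMs fall back to the
# total score for that covariate.
.pep_covariates <- function(csms, score_only = FALSE) {
  minp <- pmin(csms$partial_alpha, csms$partial_beta)
  minp[is.na(minp)] <- csms$score[is.na(minp)]
  if (score_only) return(data.frame(score = csms$score))
  data.frame(
    score = csms$score,
    min_partial = minp,
    log_nmods = log1p(if (is.null(csms$n_mods)) 0 else csms$n_mods),
    charge = if (is.null(csms$precursor_charge)) 0 else csms$precursor_charge,
    missed = if (is.null(csms$missed_cleavages)) 0 else csms$missed_cleavages)
}

#' Fit a posterior-error-probability model to scored CSMs
#'
#' Logistic regression of the decoy label on the total score, the minimum
#' partial score, log(1 + number of modifications), precursor charge and
#' the largest missed-cleavage count, followed by an isotonic calibration of
#' the decoy probability against the linear predictor. The score coefficient
#' is required to be negative (higher score, lower PEP); if the fit violates
#' this, or when fewer than `min_counts` target or decoy-containing CSMs are
#' available, a score-only model is used instead.
#'
#' @param csms CSM `data.frame` with columns `score`, `partial_alpha`,
#'   `partial_beta`, `decoy_class` (and optionally `n_mods`,
#'   `precursor_charge`, `missed_cleavages`).
#' @param min_counts Minimum TT and (TD+DD) CSM counts for the full model.
#' @return An `xl_pep_model` with a `predict` method.
#' @export
fit_pep <- function(csms, min_counts = 50L) {
  y <- as.integer(.is_false_class(csms$decoy_class))
  if (all(y == 1L)) stop("cannot fit PEP model: all CSMs are decoy-class")
  if (all(y == 0L)) stop("cannot fit PEP model: no decoy-class CSMs")
  score_only <- sum(y == 0L) < min_counts || sum(y == 1L) < min_counts
  fit_one <- function(so) {
    X <- .pep_covariates(csms, score_only = so)
    keep <- vapply(X, function(col) stats::var(col) > 0, TRUE)
    X <- X[, keep | names(X) == "score", drop = FALSE]
    df <- cbind(y = y, X)
    g <- stats::glm(y ~ ., family = stats::binomial(), data = df)
    list(glm = g, cols = names(X))
  }
  f <- fit_one(score_only)
  if (is.na(stats::coef(f$glm)["score"]) ||
      stats::coef(f$glm)["score"] >= 0) {
    score_only <- TRUE
    f <- fit_one(TRUE)
    if (stats::coef(f$glm)["score"] >= 0)
      warning("PEP model is not decreasing in score; calibration may be poor")
  }
  lp <- stats::predict(f$glm, type = "link")
  # isotonic calibration: P(false) non-decreasing in the linear predictor
  o <- order(lp)
  iso <- stats::isoreg(lp[o], y[o])
  cal_x <- iso$x; cal_y <- iso$yf
  structure(list(glm = f$glm, cols = f$cols, score_only = score_only,
                 cal_x = cal_x, cal_y = cal_y),
            class = "xl_pep_model")
}

#' Predict posterior error probabilities
#'
#' @param object An `xl_pep_model`.
#' @param newdata CSM `data.frame`.
#' @param ... Unused.
#' @return Numeric vector of PEPs in `[0, 1]`, monotone non-increasing in
#'   score at fixed covariates.
#' @export
predict.xl_pep_model <- function(object, newdata, ...) {
  X <- .pep_covariates(newdata, score_only = object$score_only)
  X <- X[, object$cols, drop = FALSE]
  lp <- stats::predict(object$glm, newdata = X, type = "link")
  pep <- stats::approx(object$cal_x, object$cal_y, xout = lp, rule = 2L,
                       ties = "ordered")$y
  pmin(pmax(pep, 0), 1)
}

#' Target-decoy FDR control on CSMs
#'
#' CSMs are sorted by PEP ascending (score descending on ties); walking down
#' the list, the running FDR is the number of decoy-containing CSMs (#TD +
#' #DD, plus #D for single-peptide products) divided by the number of
#' all-target CSMs. q-values are the running minimum of the FDR from the
#' bottom of the list; CSMs with `q <= level` are accepted. With
#' `separate_intra_inter`, the procedure runs independently on intra- and
#' inter-protein dipeptide subsets (single-peptide products go with intra).
#' A subset without any target CSM yields no acceptances.
#'
#' @param csms CSM `data.frame` with a `pep` column (see [fit_pep()]).
#' @param level FDR threshold in (0, 1] (default 0.01).
#' @param separate_intra_inter Run the FDR separately per subset.
#' @return The CSMs with `fdr`, `qvalue` and `accepted` columns, sorted by
#'   PEP within subset.
#' @export
apply_fdr <- function(csms, level = 0.01, separate_intra_inter = FALSE) {
  if (!is.numeric(level) || level <= 0 || level > 1)
    stop("level must be in (0, 1]")
  run_one <- function(d) {
    if (!nrow(d)) {
      d$fdr <- numeric(); d$qvalue <- numeric(); d$accepted <- logical()
      return(d)
    }
    o <- order(d$pep, -d$score)
    d <- d[o, , drop = FALSE]
    n_false <- cumsum(.is_false_class(d$decoy_class))
    n_target <- cumsum(.is_target_class(d$decoy_class))
    d$fdr <- ifelse(n_target > 0, n_false / n_target, Inf)
    d$qvalue <- rev(cummin(rev(d$fdr)))
    d$accepted <- d$qvalue <= level
    d
  }
  if (separate_intra_inter) {
    intra <- is.na(csms$intra) | csms$intra
    out <- rbind(run_one(csms[intra, , drop = FALSE]),
                 run_one(csms[!intra, , drop = FALSE]))
  } else out <- run_one(csms)
  rownames(out) <- NULL
  out
}

#' Post-search reporting filters
#'
#' Dipeptides whose minimum partial score falls below `min_partial` are
#' removed; optional minimum-score filters for dipeptides and for other
#' cross-linked products, and a minimum matched-fragment count per peptide,
#' are applied when set. All filters at 0 is the identity.
#'
#' @param csms CSM `data.frame`.
#' @param min_partial Minimum of the two partial scores (default 10).
#' @param min_score_dipeptide Minimum total score for dipeptides.
#' @param min_score_other Minimum total score for mono-/loop-linked and
#'   single products.
#' @param min_fragments_each Minimum matched fragments from each peptide of
#'   a dipeptide.
#' @return Filtered CSM `data.frame`.
#' @export
reporting_filters <- function(csms, min_partial = 10,
                              min_score_dipeptide = 0,
                              min_score_other = 0,
                              min_fragments_each = 0) {
  if (!nrow(csms)) return(csms)
  dip <- csms$kind %in% c("dipeptide", "higher_order")
  keep <- rep(TRUE, nrow(csms))
  if (min_partial > 0)
    keep[dip] <- keep[dip] &
      pmin(csms$partial_alpha[dip], csms$partial_beta[dip]) >= min_partial
  if (min_score_dipeptide > 0)
    keep[dip] <- keep[dip] & csms$score[dip] >= min_score_dipeptide
  if (min_score_other > 0)
    keep[!dip] <- keep[!dip] & csms$score[!dip] >= min_score_other
  if (min_fragments_each > 0)
    keep[dip] <- keep[dip] &
      csms$n_matched_alpha[dip] >= min_fragments_each &
      csms$n_matched_beta[dip] >= min_fragments_each
  csms[keep, , drop = FALSE]
}

#' Roll CSMs up to unique residue-pair cross-links
#'
#' Unique cross-links are keyed by (protein A, position A, protein B,
#' position B) with the two sides in canonical order; each row reports the
#' best CSM score and the CSM count. The rollup is reported as-is: FDR is
#' controlled at the CSM level only.
#'
#' @param csms Dipeptide CSM `data.frame`.
#' @return `data.frame(protein_a, pos_a, protein_b, pos_b, best_score,
#'   n_csms, intra)`.
#' @export
unique_crosslinks <- function(csms) {
  d <- csms[csms$kind %in% c("dipeptide", "higher_order"), , drop = FALSE]
  if (!nrow(d)) return(data.frame(protein_a = character(), pos_a = integer(),
                                  protein_b = character(), pos_b = integer(),
                                  best_score = numeric(), n_csms = integer(),
                                  intra = logical()))
  swap <- d$protein_a > d$protein_b |
    (d$protein_a == d$protein_b & d$pos_a > d$pos_b)
  pa <- ifelse(swap, d$protein_b, d$protein_a)
  xa <- ifelse(swap, d$pos_b, d$pos_a)
  pb <- ifelse(swap, d$protein_a, d$protein_b)
  xb <- ifelse(swap, d$pos_a, d$pos_b)
  key <- paste(pa, xa, pb, xb, sep = "|")
  agg <- lapply(split(seq_len(nrow(d)), key), function(ix) {
    data.frame(protein_a = pa[ix[1L]], pos_a = xa[ix[1L]],
               protein_b = pb[ix[1L]], pos_b = xb[ix[1L]],
               best_score = max(d$score[ix]), n_csms = length(ix),
               intra = d$intra[ix[1L]])
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$best_score), , drop = FALSE]
}
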