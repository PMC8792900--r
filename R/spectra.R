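# MS/MS spectrum containers, MGF I/O, de-isotoping with charge-1
# deconvolution, and top-q-per-window peak filtering.

#' Construct a raw (as-acquired, centroided) MS/MS spectrum
#'
#' @param scan_id Scan identifier.
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Precursor charge (>= 1).
#' @param mz,intensity Peak lists (sorted by m/z on construction).
#' @param rt Retention time in seconds (optional).
#' @return An `xl_rawspec` object.
#' @export
raw_spectrum <- function(scan_id, precursor_mz, precursor_charge,
                         mz, intensity, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (!is.na(precursor_charge) && precursor_charge < 1L)
    stop("precursor_charge must be >= 1")
  o <- order(mz)
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 rt = rt),
            class = "xl_rawspec")
}

#' Construct a processed (neutral-mass, charge-1) spectrum
#'
#' @param scan_id Scan identifier.
#' @param precursor_neutral_mass Neutral precursor mass m_p in Da.
#' @param mass,intensity Neutral fragment masses and intensities.
#' @param rt Retention time (optional).
#' @return An `xl_procspec` object.
#' @export
processed_spectrum <- function(scan_id, precursor_neutral_mass,
                               mass, intensity, rt = NA_real_) {
  stopifnot(length(mass) == length(intensity))
  o <- order(mass)
  structure(list(scan_id = as.character(scan_id),
                 precursor_neutral_mass = as.numeric(precursor_neutral_mass),
                 mass = as.numeric(mass[o]), intensity = as.numeric(intensity[o]),
                 rt = rt),
            class = "xl_procspec")
}

#' Read spectra from an MGF file
#'
#' Honors TITLE, PEPMASS, CHARGE and RTINSECONDS fields.
#'
#' @param path MGF file path.
#' @return List of `xl_rawspec` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end)) stop("unbalanced BEGIN/END IONS in ", path)
  lapply(seq_along(begin), function(i) {
    block <- lines[(begin[i] + 1L):(end[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
    fld <- stats::setNames(as.list(vals), keys)
    pk <- block[!is_kv & nzchar(trimws(block))]
    mzint <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(x)
        as.numeric(x[1:2])))
      m
    } else matrix(numeric(), ncol = 2L)
    charge <- if (!is.null(fld$CHARGE))
      as.integer(sub("\\+$", "", fld$CHARGE)) else 1L
    pepmass <- if (!is.null(fld$PEPMASS))
      as.numeric(strsplit(fld$PEPMASS, "\\s+")[[1L]][1L]) else NA_real_
    raw_spectrum(scan_id = if (!is.null(fld$TITLE)) fld$TITLE else paste0("scan", i),
                 precursor_mz = pepmass, precursor_charge = charge,
                 mz = mzint[, 1L], intensity = mzint[, 2L],
                 rt = if (!is.null(fld$RTINSECONDS))
                   as.numeric(fld$RTINSECONDS) else NA_real_)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `xl_rawspec` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$scan_id),
                 paste0("PEPMASS=", sprintf("%.6f", s$precursor_mz)),
                 paste0("CHARGE=", s$precursor_charge, "+"),
                 if (!is.na(s$rt)) paste0("RTINSECONDS=", sprintf("%.3f", s$rt)),
                 sprintf("%.6f %.2f", s$mz, s$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

# Greedy isotope-envelope assignment on an m/z peak list.  An envelope at
# charge z is a maximal run of peaks spaced by 1.00286864/z (within
# tolerance) with >= 2 members and non-increasing intensity after its apex.
# Higher charges are tried first so compressed spacings are not absorbed by
# a charge-1 interpretation.
.collapse_envelopes <- function(mz, intensity, frag_tol_ppm, max_charge) {
  n <- length(mz)
  used <- rep(FALSE, n)
  out_mass <- numeric(0); out_int <- numeric(0)
  for (z in seq(max_charge, 1L)) {
    spacing <- MASS_CONST[["isotope"]] / z
    i <- 1L
    while (i <= n) {
      if (used[i]) { i <- i + 1L; next }
      members <- i
      cur <- i
      repeat {
        target <- mz[cur] + spacing
        tol <- frag_tol_ppm * 1e-6 * target
        cand <- which(!used & abs(mz - target) <= tol)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(mz[cand] - target))]
        members <- c(members, nxt)
        cur <- nxt
      }
      if (length(members) >= 2L) {
        ints <- intensity[members]
        apex <- which.max(ints)
        ok <- apex == length(ints) ||
          all(diff(ints[apex:length(ints)]) <= 0)
        if (ok) {
          used[members] <- TRUE
          out_mass <- c(out_mass, z * (mz[members[1L]] - MASS_CONST[["proton"]]))
          out_int <- c(out_int, sum(ints))
        }
      }
      i <- i + 1L
    }
  }
  left <- which(!used)
  list(mass = c(out_mass, mz[left] - MASS_CONST[["proton"]]),
       intensity = c(out_int, intensity[left]))
}

#' De-isotope a spectrum and collapse fragment charges to one
#'
#' Isotope envelopes (peak runs spaced by 1.00286864/z within tolerance with
#' an intensity-plausible shape) are collapsed to their monoisotopic member,
#' emitted once at the charge-1-equivalent neutral mass with summed
#' intensity. Unassigned peaks pass through at assumed charge 1. The
#' precursor neutral mass is `charge * (precursor_mz - proton)`.
#'
#' @param raw An `xl_rawspec`.
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param max_fragment_charge Highest fragment charge considered.
#' @return An `xl_procspec`.
#' @export
deisotope_deconvolute <- function(raw, frag_tol_ppm = 20,
                                  max_fragment_charge = 2L) {
  res <- .collapse_envelopes(raw$mz, raw$intensity, frag_tol_ppm,
                             max_fragment_charge)
  processed_spectrum(raw$scan_id,
                     raw$precursor_charge *
                       (raw$precursor_mz - MASS_CONST[["proton"]]),
                     res$mass, res$intensity, rt = raw$rt)
}

#' Keep the q most intense peaks per mass window
#'
#' Windows are half-open `[k*window, (k+1)*window)` Da; ties are broken in
#' favor of the lower mass. `q = Inf` is the identity.
#'
#' @param spectrum An `xl_procspec`.
#' @param q Peaks kept per window (>= 1).
#' @param window Window width in Da (default 100).
#' @return Filtered `xl_procspec`.
#' @export
window_filter <- function(spectrum, q, window = 100) {
  if (q < 1) stop("q must be >= 1")
  if (!length(spectrum$mass) || is.infinite(q)) return(spectrum)
  win <- floor(spectrum$mass / window)
  keep <- unlist(lapply(split(seq_along(win), win), function(ix) {
    o <- ix[order(-spectrum$intensity[ix], spectrum$mass[ix])]
    o[seq_len(min(q, length(o)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  processed_spectrum(spectrum$scan_id, spectrum$precursor_neutral_mass,
                     spectrum$mass[keep], spectrum$intensity[keep],
                     rt = spectrum$rt)
}
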