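# MS1 3D-peak refinement: rejoin noise-fragmented peaks of heavy precursors
# and reassign the monoisotopic member of isotope patterns.

#' Construct a 3D MS1 peak
#'
#' A 3D peak is spanned by m/z, retention time and intensity: a centroid m/z
#' plus an RT interval with an intensity profile.
#'
#' @param mz Centroid m/z in Th.
#' @param rt_start,rt_end Retention-time interval in seconds (half-open,
#'   `rt_start < rt_end`).
#' @param profile `data.frame(rt, intensity)`; defaults to the interval
#'   endpoints at unit intensity.
#' @return An `xl_peak3d` object.
#' @export
peak3d <- function(mz, rt_start, rt_end, profile = NULL) {
  if (!(rt_start < rt_end)) stop("rt_start must be < rt_end")
  if (is.null(profile))
    profile <- data.frame(rt = c(rt_start, rt_end), intensity = c(1, 1))
  if (!nrow(profile)) stop("empty intensity profile")
  structure(list(mz = as.numeric(mz), rt_start = as.numeric(rt_start),
                 rt_end = as.numeric(rt_end), profile = profile),
            class = "xl_peak3d")
}

#' Total (summed) intensity of a 3D peak
#' @param peak An `xl_peak3d`.
#' @return Numeric scalar.
#' @export
peak3d_intensity <- function(peak) sum(peak$profile$intensity)

#' Read/write a 3D-peak table (tabular text)
#'
#' Columns: `mz, rt_start, rt_end, profile` where `profile` serializes
#' `rt:intensity` points separated by `;`.
#'
#' @param path File path.
#' @param peaks List of `xl_peak3d` (for writing).
#' @return For reading, a list of `xl_peak3d`.
#' @export
read_peak3d_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    pts <- strsplit(strsplit(tab$profile[i], ";", fixed = TRUE)[[1L]], ":",
                    fixed = TRUE)
    peak3d(tab$mz[i], tab$rt_start[i], tab$rt_end[i],
           data.frame(rt = as.numeric(vapply(pts, `[`, "", 1L)),
                      intensity = as.numeric(vapply(pts, `[`, "", 2L))))
  })
}

#' @rdname read_peak3d_table
#' @export
write_peak3d_table <- function(peaks, path) {
  tab <- data.frame(
    mz = vapply(peaks, `[[`, 0, "mz"),
    rt_start = vapply(peaks, `[[`, 0, "rt_start"),
    rt_end = vapply(peaks, `[[`, 0, "rt_end"),
    profile = vapply(peaks, function(p)
      paste(sprintf("%.4f:%.4f", p$profile$rt, p$profile$intensity),
            collapse = ";"), ""))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Do two RT intervals leave a positive gap?  Touching intervals do not.
.rt_gap <- function(a, b) {
  lo <- min(a$rt_end, b$rt_end); hi <- max(a$rt_start, b$rt_start)
  if (hi > lo) c(lo, hi) else NULL
}

#' Cluster noise-fragmented 3D peaks
#'
#' Two peaks at the same m/z (within tolerance) that are separated in
#' retention time are placed in one putative cluster iff a bridging peak
#' exists at an m/z distance of one isotope spacing (1.00286864/z for a
#' candidate charge z, lowest first) whose RT interval covers the gap.
#' Touching or overlapping same-m/z peaks are clustered unconditionally.
#'
#' @param peaks List of `xl_peak3d`, sorted by m/z.
#' @param mz_tol_ppm m/z tolerance in ppm.
#' @param max_charge Highest candidate charge for the bridge spacing.
#' @return List of clusters; each cluster is a list with `members` (indices
#'   into `peaks`), `charge` (bridging charge or NA) and `iso_positions`
#'   (distinct isotope offsets, including 0, with supporting peaks).
#' @export
cluster_gapped_peaks <- function(peaks, mz_tol_ppm = 10, max_charge = 6L) {
  n <- length(peaks)
  if (!n) return(list())
  mz <- vapply(peaks, `[[`, 0, "mz")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) parent[find(i)] <<- find(j)
  charge_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    tol <- mz_tol_ppm * 1e-6 * mz[i]
    if (abs(mz[i] - mz[j]) > tol) next
    gap <- .rt_gap(peaks[[i]], peaks[[j]])
    if (is.null(gap)) { unite(i, j); next }
    for (z in seq_len(max_charge)) {
      sp <- MASS_CONST[["isotope"]] / z
      bridge <- which(abs(abs(mz - mz[i]) - sp) <= tol)
      ok <- bridge[vapply(bridge, function(b)
        peaks[[b]]$rt_start <= gap[1L] && peaks[[b]]$rt_end >= gap[2L], TRUE)]
      if (length(ok)) {
        unite(i, j)
        charge_of[i] <- charge_of[j] <- z
        break
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  lapply(split(seq_len(n), comp), function(members) {
    # isotope context: the candidate charge spanning the most isotopic
    # positions wins, ties to the lowest charge
    best_z <- NA_integer_; best_iso <- 0L
    if (!all(is.na(charge_of[members]))) {
      for (z in seq_len(max_charge)) {
        iso <- .isotope_positions(mz, members, z, mz_tol_ppm)
        if (length(iso) > length(best_iso) || is.na(best_z)) {
          best_z <- z; best_iso <- iso
        }
      }
    } else best_iso <- 0L
    list(members = members, charge = best_z, iso_positions = best_iso)
  })
}

# Distinct isotope offsets (relative to a cluster's m/z) at which some peak
# in the full list sits, for the given charge; offset 0 is the cluster.
.isotope_positions <- function(mz, members, z, mz_tol_ppm, span = 3L) {
  if (is.na(z)) return(0L)
  mu <- mz[members[1L]]
  tol <- mz_tol_ppm * 1e-6 * mu
  sp <- MASS_CONST[["isotope"]] / z
  offs <- seq(-span, span)
  offs[vapply(offs, function(k)
    any(abs(mz - (mu + k * sp)) <= tol), TRUE)]
}

#' Join clustered peaks in the retention-time direction
#'
#' A cluster is merged into one 3D peak (union RT interval, concatenated
#' profile, intensity-weighted mean m/z) when its isotope context spans at
#' least three isotopic positions; otherwise its members are left untouched.
#'
#' @param clusters Output of [cluster_gapped_peaks()].
#' @param peaks The original peak list the clusters index into.
#' @return Refined list of `xl_peak3d`.
#' @export
join_clusters <- function(clusters, peaks) {
  out <- list()
  for (cl in clusters) {
    mem <- peaks[cl$members]
    if (length(mem) >= 2L && length(cl$iso_positions) >= 3L) {
      prof <- do.call(rbind, lapply(mem, `[[`, "profile"))
      prof <- prof[order(prof$rt), , drop = FALSE]
      ints <- vapply(mem, peak3d_intensity, 0)
      out[[length(out) + 1L]] <- peak3d(
        sum(vapply(mem, `[[`, 0, "mz") * ints) / sum(ints),
        min(vapply(mem, `[[`, 0, "rt_start")),
        max(vapply(mem, `[[`, 0, "rt_end")),
        prof)
    } else out <- c(out, mem)
  }
  out[order(vapply(out, `[[`, 0, "mz"))]
}

#' Refine a 3D peak list
#'
#' Convenience wrapper: [cluster_gapped_peaks()] followed by
#' [join_clusters()]. Idempotent: refining refined output is a no-op.
#'
#' @inheritParams cluster_gapped_peaks
#' @return Refined list of `xl_peak3d`.
#' @export
refine_peaks <- function(peaks, mz_tol_ppm = 10, max_charge = 6L) {
  join_clusters(cluster_gapped_peaks(peaks, mz_tol_ppm, max_charge), peaks)
}

# Poisson averagine surrogate: expected isotope intensities at a given
# neutral mass follow Poisson(lambda = mass / 1800).
.averagine_profile <- function(mass, n) {
  stats::dpois(seq_len(n) - 1L, lambda = mass / 1800)
}

#' Assemble an isotope pattern from a refined peak list
#'
#' Starting from the most intense peak (the apex), members are collected at
#' multiples of 1.00286864/charge within tolerance, taking the most intense
#' candidate per position, walking outward until a position is empty.
#'
#' @param peaks List of `xl_peak3d`.
#' @param charge Pattern charge.
#' @param mz_tol_ppm m/z tolerance in ppm.
#' @return An `xl_isopattern`: member m/z, member intensities, charge.
#' @export
build_isotope_pattern <- function(peaks, charge, mz_tol_ppm = 10) {
  stopifnot(length(peaks) >= 1L)
  mz <- vapply(peaks, `[[`, 0, "mz")
  ints <- vapply(peaks, peak3d_intensity, 0)
  sp <- MASS_CONST[["isotope"]] / charge
  apex <- which.max(ints)
  pick <- function(target) {
    tol <- mz_tol_ppm * 1e-6 * target
    cand <- which(abs(mz - target) <= tol)
    if (!length(cand)) NA_integer_ else cand[which.max(ints[cand])]
  }
  sel <- apex
  for (dir in c(-1, 1)) {
    k <- 1L
    repeat {
      idx <- pick(mz[apex] + dir * k * sp)
      if (is.na(idx)) break
      sel <- c(sel, idx)
      k <- k + 1L
    }
  }
  sel <- sel[order(mz[sel])]
  structure(list(mz = mz[sel], intensity = ints[sel],
                 charge = as.integer(charge)),
            class = "xl_isopattern")
}

#' Determine a precursor monoisotopic mass from a 3D peak list
#'
#' The full refinement pipeline: noise-fragmented peaks are rejoined
#' ([refine_peaks()]), the isotope pattern is assembled, and the
#' monoisotopic member is reassigned by the averagine left-extension test
#' ([assign_monoisotopic()]). With `refine = FALSE` the pattern is
#' assembled from the raw peaks and the monoisotopic mass is simply the
#' lowest-m/z member — the conventional assignment that fails when leading
#' isotopes of heavy precursors are lost to noise.
#'
#' @param peaks List of `xl_peak3d`.
#' @param charge Pattern charge.
#' @param refine Apply rejoining and monoisotopic reassignment.
#' @param mz_tol_ppm m/z tolerance in ppm.
#' @return Monoisotopic neutral mass in Da.
#' @export
assign_precursor_mass <- function(peaks, charge, refine = TRUE,
                                  mz_tol_ppm = 10) {
  if (refine) peaks <- refine_peaks(peaks, mz_tol_ppm)
  pattern <- build_isotope_pattern(peaks, charge, mz_tol_ppm)
  if (!refine)
    return(charge * (pattern$mz[1L] - MASS_CONST[["proton"]]))
  assign_monoisotopic(pattern)
}

#' Assign the monoisotopic mass of an isotope pattern
#'
#' Tests leftward extension against a Poisson averagine expectation
#' (lambda = mass/1800): for each candidate shift s (the observed first
#' member being isotope index s), the observed normalized intensities are
#' compared to the expected profile at indices s..s+m-1; the shift with the
#' smallest squared deviation wins, ties to the smaller shift. The
#' monoisotopic neutral mass is the first member's neutral mass minus
#' s isotope spacings.
#'
#' @param pattern An `xl_isopattern`.
#' @param max_shift Largest leftward extension tested.
#' @return Monoisotopic neutral mass in Da.
#' @export
assign_monoisotopic <- function(pattern, max_shift = 3L) {
  z <- pattern$charge
  first_neutral <- z * (pattern$mz[1L] - MASS_CONST[["proton"]])
  m <- length(pattern$mz)
  obs <- pattern$intensity / sum(pattern$intensity)
  best_s <- 0L; best_err <- Inf
  for (s in 0:max_shift) {
    mono <- first_neutral - s * MASS_CONST[["isotope"]]
    if (mono <= 0) break
    expec <- .averagine_profile(mono, s + m)[(s + 1L):(s + m)]
    if (sum(expec) <= 0) next
    expec <- expec / sum(expec)
    err <- sum((obs - expec)^2)
    if (err < best_err - 1e-12) { best_err <- err; best_s <- s }
  }
  first_neutral - best_s * MASS_CONST[["isotope"]]
}
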