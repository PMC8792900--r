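# Monoisotopic mass bookkeeping: residues, modifications, cross-linkers,
# fragment ladders.  All internal masses are NEUTRAL monoisotopic Da;
# singly-protonated m/z appears only at the I/O boundary.

#' Physical mass constants (monoisotopic, Da)
#'
#' Neutral water, the proton, ammonia, and the average isotope spacing used
#' for envelope detection.
#'
#' @format Named numeric vector.
#' @export
MASS_CONST <- c(
  water   = 18.010565,
  proton  = 1.007276,
  nh3     = 17.026549,
  isotope = 1.00286864
)

# Monoisotopic residue masses for the 20 standard amino acids.
.RESIDUE_MASS <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic residue mass table
#'
#' @return Named numeric vector of the 20 standard amino-acid residue masses.
#' @export
residue_masses <- function() .RESIDUE_MASS

#' Define a post-translational modification
#'
#' @param name Modification name.
#' @param delta_mass Mass shift in Da (finite).
#' @param site Residue letter the modification applies to, or `"nterm"` /
#'   `"cterm"`.
#' @param fixed Logical; fixed modifications are applied to every matching
#'   site, variable ones are combinatorially expanded.
#' @return An object of class `xl_mod`.
#' @export
modification <- function(name, delta_mass, site, fixed = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(delta_mass)) stop("delta_mass must be finite")
  if (!is.character(site) || length(site) != 1L || !nzchar(site))
    stop("site must be a nonempty string")
  structure(list(name = name, delta_mass = as.numeric(delta_mass),
                 site = site, fixed = isTRUE(fixed)),
            class = "xl_mod")
}

#' Define a bifunctional cross-linker
#'
#' A noncleavable linker is described by the intact mass added to the sum of
#' two peptide masses; an MS-cleavable linker additionally carries the two
#' residual masses left on a peptide after the labile bonds break, whose
#' difference is the signature doublet spacing `delta_m`.
#'
#' @param name Linker name.
#' @param specificity_a,specificity_b Character vectors of residue letters the
#'   two reactive ends attack; `"nterm"` marks the protein N-terminus.
#' @param intact_mass Mass (Da) added to the sum of two peptide masses in a
#'   cross-linked dipeptide.
#' @param cleavable Logical; `TRUE` for MS-cleavable chemistry.
#' @param short_residual,long_residual Residual masses (Da) on the cleavage
#'   products of a cleavable linker. Must sum to `intact_mass`.
#' @param monolink_mass Mass added by a hydrolyzed/quenched linker on a single
#'   peptide; defaults to `intact_mass` + water.
#' @param looplink_mass Mass added when both linker ends attach to one
#'   peptide; defaults to `intact_mass`.
#' @return An object of class `xl_linker`.
#' @export
crosslinker <- function(name, specificity_a, specificity_b = specificity_a,
                        intact_mass, cleavable = FALSE,
                        short_residual = NA_real_, long_residual = NA_real_,
                        monolink_mass = intact_mass + MASS_CONST[["water"]],
                        looplink_mass = intact_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(intact_mass) || intact_mass <= 0)
    stop("intact_mass must be > 0")
  if (cleavable) {
    if (!is.finite(short_residual) || !is.finite(long_residual))
      stop("cleavable linker needs short_residual and long_residual")
    if (short_residual <= 0 || long_residual <= 0)
      stop("residual masses must be > 0")
    if (long_residual <= short_residual)
      stop("long_residual must exceed short_residual")
    if (abs(short_residual + long_residual - intact_mass) > 1e-6)
      stop("short_residual + long_residual must equal intact_mass (1e-6 Da)")
  }
  structure(list(
    name = name,
    specificity_a = unique(specificity_a),
    specificity_b = unique(specificity_b),
    intact_mass = as.numeric(intact_mass),
    cleavable = isTRUE(cleavable),
    short_residual = as.numeric(short_residual),
    long_residual = as.numeric(long_residual),
    delta_m = if (cleavable) as.numeric(long_residual - short_residual) else NA_real_,
    monolink_mass = as.numeric(monolink_mass),
    looplink_mass = as.numeric(looplink_mass)
  ), class = "xl_linker")
}

# Preset cache; filled lazily from the shipped registry file.
.preset_env <- new.env(parent = emptyenv())

#' Built-in cross-linker presets
#'
#' Presets are configuration, not code: they are parsed from the registry
#' file `system.file("extdata", "linkers.txt", package = "xlsearch")`, which
#' documents the vendor fragmentation chemistry behind each residual mass.
#'
#' @param name One of `"DSS"`, `"BS3"`, `"DSSO"`, `"DSBU"`.
#' @return An `xl_linker`.
#' @export
linker_preset <- function(name) {
  if (is.null(.preset_env$linkers)) {
    path <- system.file("extdata", "linkers.txt", package = "xlsearch")
    .preset_env$linkers <- read_linker_registry(path)
  }
  lk <- .preset_env$linkers[[toupper(name)]]
  if (is.null(lk))
    stop("unknown linker preset '", name, "'; available: ",
         paste(names(.preset_env$linkers), collapse = ", "))
  lk
}

#' Read cross-linker definitions from a flat key-value registry file
#'
#' One `key = value` pair per line; records are separated by blank lines or a
#' line starting with `[`. Recognised keys: name, specificity_a,
#' specificity_b (comma-separated residue letters), intact_mass, cleavable,
#' short_residual, long_residual, monolink_mass, looplink_mass.
#'
#' @param path File path.
#' @return Named list of `xl_linker` objects.
#' @export
read_linker_registry <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  breaks <- cumsum(lines == "" | startsWith(lines, "["))
  recs <- split(lines[lines != "" & !startsWith(lines, "[")],
                breaks[lines != "" & !startsWith(lines, "[")])
  out <- list()
  for (rec in recs) {
    if (!length(rec)) next
    kv <- strsplit(rec, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed registry line: ", rec[bad][1L])
    keys <- trimws(vapply(kv, `[`, "", 1L))
    vals <- trimws(vapply(kv, `[`, "", 2L))
    f <- stats::setNames(as.list(vals), keys)
    if (is.null(f$name)) stop("registry record missing 'name'")
    num <- function(k) if (is.null(f[[k]])) NA_real_ else as.numeric(f[[k]])
    spl <- function(k) if (is.null(f[[k]])) character() else
      trimws(strsplit(f[[k]], ",", fixed = TRUE)[[1L]])
    cleav <- !is.na(num("short_residual")) && !is.na(num("long_residual"))
    args <- list(name = f$name, specificity_a = spl("specificity_a"),
                 intact_mass = num("intact_mass"), cleavable = cleav,
                 short_residual = num("short_residual"),
                 long_residual = num("long_residual"))
    if (length(spl("specificity_b"))) args$specificity_b <- spl("specificity_b")
    if (!is.na(num("monolink_mass"))) args$monolink_mass <- num("monolink_mass")
    if (!is.na(num("looplink_mass"))) args$looplink_mass <- num("looplink_mass")
    out[[f$name]] <- do.call(crosslinker, args)
  }
  out
}

# Residue masses for a sequence, with per-position modification deltas added.
# mods: data.frame(site = 1-based position, delta = Da) or NULL.
.residue_vector <- function(sequence, mods = NULL) {
  if (!nzchar(sequence)) stop("empty peptide sequence")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("unknown residue '", aa[bad], "' at position ", bad)
  }
  m <- unname(m)
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$site < 1L | mods$site > length(aa)))
      stop("modification site out of range")
    for (i in seq_len(nrow(mods))) m[mods$site[i]] <- m[mods$site[i]] + mods$delta[i]
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus modification deltas.
#'
#' @param sequence Peptide sequence (20 standard letters).
#' @param mods Optional `data.frame(site, delta)` of modification mass shifts
#'   at 1-based positions.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  sum(.residue_vector(sequence, mods)) + MASS_CONST[["water"]]
}

#' b/y fragment ladder with optional cross-link mass shift
#'
#' Returns the n-1 neutral fragment masses of one ion series for an n-residue
#' peptide. Every fragment whose residue span contains `shift_site` carries
#' `shift_mass` — for a noncleavable dipeptide that is the intact linker plus
#' the full partner peptide; for a cleavable search it is a linker residual.
#'
#' @param sequence Peptide sequence.
#' @param series `"b"` or `"y"`.
#' @param shift_site 1-based linked position, or `NULL` for none.
#' @param shift_mass Mass shift in Da applied to site-containing fragments.
#' @param mods Optional `data.frame(site, delta)`.
#' @return `data.frame(label, index, mass)` of neutral fragment masses; b_k is
#'   the sum of the first k residues, y_k the sum of the last k plus water, so
#'   `b_k + y_(n-k)` equals the neutral peptide mass.
#' @export
fragment_ladder <- function(sequence, series = c("b", "y"),
                            shift_site = NULL, shift_mass = 0,
                            mods = NULL) {
  series <- match.arg(series)
  rv <- .residue_vector(sequence, mods)
  n <- length(rv)
  if (n < 2L) return(data.frame(label = character(), index = integer(),
                                mass = numeric()))
  if (!is.null(shift_site)) {
    if (shift_site < 1L || shift_site > n) stop("shift_site out of range")
  }
  k <- seq_len(n - 1L)
  if (series == "b") {
    mass <- cumsum(rv)[k]
    contains <- if (is.null(shift_site)) rep(FALSE, n - 1L) else k >= shift_site
  } else {
    mass <- cumsum(rev(rv))[k] + MASS_CONST[["water"]]
    contains <- if (is.null(shift_site)) rep(FALSE, n - 1L) else
      k >= (n - shift_site + 1L)
  }
  mass[contains] <- mass[contains] + shift_mass
  data.frame(label = paste0(series, k), index = k, mass = mass)
}

#' Convert neutral mass to singly-protonated m/z and back
#'
#' @param neutral_mass,mz Masses in Da / Th.
#' @param z Charge state.
#' @return Numeric vector.
#' @export
neutral_to_mz <- function(neutral_mass, z = 1L)
  (neutral_mass + z * MASS_CONST[["proton"]]) / z

#' @rdname neutral_to_mz
#' @export
mz_to_neutral <- function(mz, z = 1L) z * (mz - MASS_CONST[["proton"]])
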