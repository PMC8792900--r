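# Search configuration and the end-to-end pipeline driver.

#' Default search configuration
#'
#' Returns the full search configuration with every default resolved, so a
#' written config is a complete provenance record of a run.
#'
#' @param ... Named overrides of any default.
#' @return An `xl_config` list.
#' @export
search_config <- function(...) {
  cfg <- list(
    fasta = character(),
    spectra = character(),
    linker = "DSS",
    cleavable = FALSE,
    enzyme = "trypsin",
    max_missed_cleavages = 3L,
    min_peptide_length = 6L,
    max_peptide_mass = 6000,
    precursor_tol_ppm = 10,
    frag_tol_ppm = 20,
    max_fragment_charge = 2L,
    fixed_mods = character(),
    var_mods = character(),
    max_var_mods = 2L,
    enable_single = TRUE,
    enable_mono = TRUE,
    enable_loop = TRUE,
    enable_dipeptide = TRUE,
    enable_higher_order = FALSE,
    q_max = 10L,
    window = 100,
    consider_losses = FALSE,
    n_top = 3L,
    min_signature_mass = 200,
    min_peptide_mass = 500,
    allow_nh3 = TRUE,
    min_partial = 10,
    min_score_dipeptide = 0,
    min_score_other = 0,
    min_fragments_each = 0,
    fdr = 0.01,
    separate_intra_inter = FALSE,
    peak_refinement = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "xl_config")
}

#' Validate a search configuration
#'
#' @param cfg An `xl_config`.
#' @return Invisibly `TRUE`; otherwise an error listing every problem.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$precursor_tol_ppm > 0, "precursor_tol_ppm must be > 0")
  chk(cfg$frag_tol_ppm > 0, "frag_tol_ppm must be > 0")
  chk(cfg$fdr > 0 && cfg$fdr <= 1, "fdr must be in (0, 1]")
  chk(cfg$min_peptide_length >= 1, "min_peptide_length must be >= 1")
  chk(cfg$max_peptide_mass > 0, "max_peptide_mass must be > 0")
  chk(cfg$q_max >= 1, "q_max must be >= 1")
  chk(cfg$window > 0, "window must be > 0")
  chk(cfg$n_top >= 1, "n_top must be >= 1")
  chk(cfg$max_missed_cleavages >= 0, "max_missed_cleavages must be >= 0")
  for (f in c(cfg$fasta, cfg$spectra))
    chk(file.exists(f), paste0("missing input file: ", f))
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

# Flat key = value serialization; vectors are comma-separated.
.cfg_known_names <- function() names(search_config())

#' Write / read a resolved configuration (round-trippable)
#'
#' @param cfg An `xl_config`.
#' @param path File path.
#' @return `read_config` returns an `xl_config`.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) paste(ifelse(v, "true", "false"), collapse = ",")
    else paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
               collapse = ",")
  }
  writeLines(vapply(names(cfg), function(k)
    paste0(k, " = ", fmt(cfg[[k]])), ""), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  proto <- search_config()
  cfg <- proto
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(proto)) stop("unknown config key: ", k)
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1L]]
    v <- trimws(v)
    tmpl <- proto[[k]]
    cfg[[k]] <- if (is.logical(tmpl)) v == "true"
    else if (is.integer(tmpl)) as.integer(v)
    else if (is.numeric(tmpl)) as.numeric(v)
    else if (!length(v)) character() else v
  }
  if (!length(vals[keys == "fasta"]) || !nzchar(vals[keys == "fasta"][1L]))
    cfg$fasta <- character()
  if (!length(vals[keys == "spectra"]) || !nzchar(vals[keys == "spectra"][1L]))
    cfg$spectra <- character()
  structure(cfg, class = "xl_config")
}

.resolve_linker <- function(cfg) {
  lk <- linker_preset(cfg$linker)
  if (cfg$cleavable && !lk$cleavable)
    stop("linker ", lk$name, " is not MS-cleavable")
  lk
}

.parse_mod_spec <- function(specs, fixed) {
  lapply(specs, function(s) {
    # "name:site:delta", e.g. "cam:C:57.021464"
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("modification spec must be name:site:delta, got '", s, "'")
    modification(parts[1L], as.numeric(parts[3L]), parts[2L], fixed = fixed)
  })
}

#' Run a complete cross-link search
#'
#' Reads FASTA and MGF inputs, digests with decoys, expands modifications,
#' builds the product space, processes and searches every spectrum with the
#' engine matching the linker chemistry, keeps the top-ranked CSM per
#' spectrum, applies reporting filters, fits the PEP model, controls the
#' FDR, and writes `csms.tsv`, `crosslinks.tsv`, `audit.tsv` and the
#' resolved `config.txt` into `out_dir`. Identical config and inputs give
#' identical outputs.
#'
#' @param cfg An `xl_config` (see [search_config()]).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the final `csms`, `crosslinks`, `audit`
#'   and per-stage `counters`.
#' @export
run_search <- function(cfg, out_dir) {
  validate_config(cfg)
  lk <- .resolve_linker(cfg)
  cleavable <- cfg$cleavable || lk$cleavable
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  db <- do.call(rbind, lapply(cfg$fasta, read_fasta_db))
  peps <- digest_db(db, enzyme_rule(), cfg$max_missed_cleavages,
                    cfg$min_peptide_length, cfg$max_peptide_mass)
  peps <- expand_modifications(peps,
                               .parse_mod_spec(cfg$fixed_mods, TRUE),
                               .parse_mod_spec(cfg$var_mods, FALSE),
                               cfg$max_var_mods)
  space <- build_products(peps, lk,
                          enable_single = cfg$enable_single,
                          enable_mono = cfg$enable_mono,
                          enable_loop = cfg$enable_loop,
                          enable_dipeptide = cfg$enable_dipeptide,
                          enable_higher_order = cfg$enable_higher_order)
  params <- score_params(cfg$window, cfg$q_max, cfg$frag_tol_ppm,
                         cfg$consider_losses)

  raws <- unlist(lapply(cfg$spectra, read_mgf), recursive = FALSE)
  counters <- list(spectra = length(raws), peptides = nrow(peps),
                   products = nrow(space$products))
  audit <- list(); hits <- list()
  for (raw in raws) {
    proc <- deisotope_deconvolute(raw, cfg$frag_tol_ppm,
                                  cfg$max_fragment_charge)
    if (cleavable) {
      res <- search_spectrum_cleavable(
        proc, space, params, cfg$precursor_tol_ppm, cfg$min_signature_mass,
        cfg$n_top, cfg$min_peptide_mass, cfg$allow_nh3, top_n = 1L)
      audit[[length(audit) + 1L]] <- attr(res, "audit")
    } else {
      res <- search_spectrum(proc, space, params, cfg$precursor_tol_ppm,
                             top_n = 1L)
      audit[[length(audit) + 1L]] <-
        data.frame(scan_id = proc$scan_id, stage = "indexed",
                   n_hypotheses = NA_integer_, n_candidates = nrow(res))
    }
    if (nrow(res)) {
      res$precursor_charge <- raw$precursor_charge
      hits[[length(hits) + 1L]] <- res
    }
  }
  csms <- if (length(hits)) {
    cols <- Reduce(intersect, lapply(hits, names))
    do.call(rbind, lapply(hits, `[`, cols))
  } else .empty_csms()
  counters$csms_raw <- nrow(csms)

  if (nrow(csms)) {
    fit_ok <- length(unique(.is_false_class(csms$decoy_class))) == 2L
    if (fit_ok) {
      model <- fit_pep(csms)
      csms$pep <- predict(model, csms)
    } else csms$pep <- 1 - pmin(csms$score / max(csms$score, 1), 1)
    csms <- reporting_filters(csms, cfg$min_partial, cfg$min_score_dipeptide,
                              cfg$min_score_other, cfg$min_fragments_each)
    counters$csms_filtered <- nrow(csms)
    csms <- apply_fdr(csms, cfg$fdr, cfg$separate_intra_inter)
  } else counters$csms_filtered <- 0L
  counters$csms_accepted <- sum(csms$accepted %in% TRUE)

  accepted <- csms[csms$accepted %in% TRUE & csms$decoy_class %in%
                     c("TT", "T"), , drop = FALSE]
  xl <- unique_crosslinks(accepted)
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(scan_id = character(), stage = character(),
               n_hypotheses = integer(), n_candidates = integer())

  utils::write.table(csms, file.path(out_dir, "csms.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(xl, file.path(out_dir, "crosslinks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(audit_df, file.path(out_dir, "audit.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_config(cfg, file.path(out_dir, "config.txt"))
  invisible(list(csms = csms, crosslinks = xl, audit = audit_df,
                 counters = counters))
}
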