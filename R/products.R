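# Cross-link product space: mono-, loop-, dipeptide and higher-order
# products over a digested target-decoy peptide set, plus a ppm mass index.

# Serialize/parse per-peptide modification placements ("site:delta;...").
.fmt_mods <- function(df) {
  if (is.null(df) || !nrow(df)) return("")
  paste(sprintf("%d:%.6f", df$site, df$delta), collapse = ";")
}

.parse_mods <- function(s) {
  if (is.na(s) || !nzchar(s)) return(data.frame(site = integer(), delta = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(site = as.integer(vapply(parts, `[`, "", 1L)),
             delta = as.numeric(vapply(parts, `[`, "", 2L)))
}

#' Apply fixed modifications and expand variable-modification combinations
#'
#' Fixed modifications are placed on every matching residue. Variable
#' modifications are expanded combinatorially, up to `max_var_mods` per
#' peptide; each combination becomes one peptide variant row.
#'
#' @param peptides Peptide `data.frame` from [digest_db()].
#' @param fixed_mods,var_mods Lists of [modification()] objects.
#' @param max_var_mods Maximum variable modifications per peptide.
#' @return Peptide `data.frame` with columns `mods` (serialized placements),
#'   `n_mods`, and `mass` including all modification deltas.
#' @export
expand_modifications <- function(peptides, fixed_mods = list(),
                                 var_mods = list(), max_var_mods = 2L) {
  res <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, , drop = FALSE]
    aa <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    fix <- data.frame(site = integer(), delta = numeric())
    for (m in fixed_mods) {
      hits <- which(aa == m$site)
      if (length(hits))
        fix <- rbind(fix, data.frame(site = hits, delta = m$delta_mass))
    }
    vsites <- data.frame(site = integer(), delta = numeric())
    for (m in var_mods) {
      hits <- which(aa == m$site)
      if (length(hits))
        vsites <- rbind(vsites, data.frame(site = hits, delta = m$delta_mass))
    }
    combos <- list(data.frame(site = integer(), delta = numeric()))
    if (nrow(vsites) && max_var_mods >= 1L) {
      for (k in seq_len(min(max_var_mods, nrow(vsites)))) {
        idx <- utils::combn(nrow(vsites), k, simplify = FALSE)
        idx <- Filter(function(ix) !anyDuplicated(vsites$site[ix]), idx)
        combos <- c(combos, lapply(idx, function(ix) vsites[ix, , drop = FALSE]))
      }
    }
    rows <- lapply(combos, function(vm) {
      all_m <- rbind(fix, vm)
      all_m <- all_m[order(all_m$site), , drop = FALSE]
      out <- p
      out$mods <- .fmt_mods(all_m)
      out$n_mods <- nrow(vm)
      out$mass <- peptide_mass(p$sequence, all_m)
      out
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Eligible cross-link sites on a peptide
#'
#' A residue is eligible when its letter is in the linker specificity set.
#' The peptide C-terminal residue is excluded when it was the enzymatic
#' cleavage site (a cross-linked lysine would not have been cleaved);
#' toggleable. The protein N-terminus counts as a site (position 1) when the
#' specificity set contains `"nterm"` and the peptide starts the protein.
#'
#' @param sequence Peptide sequence.
#' @param residues Specificity set (residue letters, optionally `"nterm"`).
#' @param start 1-based start of the peptide in its protein.
#' @param exclude_cterm_cleavage Drop a C-terminal K/R site.
#' @param cleave_after Enzyme cleavage residues (for the exclusion rule).
#' @return Integer vector of eligible 1-based positions.
#' @export
link_sites <- function(sequence, residues, start = 1L,
                       exclude_cterm_cleavage = TRUE,
                       cleave_after = c("K", "R")) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  sites <- which(aa %in% setdiff(residues, "nterm"))
  if (exclude_cterm_cleavage && n %in% sites && aa[n] %in% cleave_after)
    sites <- setdiff(sites, n)
  if ("nterm" %in% residues && start == 1L) sites <- union(1L, sites)
  sort(unique(as.integer(sites)))
}

.decoy_class2 <- function(da, db) {
  n <- da + db
  c("TT", "TD", "DD")[n + 1L]
}

#' Build the cross-link product search space
#'
#' Enumerates, over all peptide variants: plain single peptides, monolinks
#' (one per eligible site), looplinks (one per unordered distinct site pair
#' on a peptide), dipeptides (one per unordered peptide pair, self-pairs
#' included, times one eligible site on each constituent), and optionally
#' higher-order products (a dipeptide carrying one extra monolink).
#'
#' @param peptides Peptide variant `data.frame` from [expand_modifications()]
#'   (or [digest_db()]; missing `mods`/`n_mods` columns are added empty).
#' @param linker An `xl_linker`.
#' @param enable_single,enable_mono,enable_loop,enable_dipeptide,enable_higher_order
#'   Product-type toggles.
#' @param exclude_cterm_cleavage Passed to [link_sites()].
#' @return An `xl_space` list: `peptides` (the variant table), `products`
#'   (`data.frame` with kind, constituent indices, sites, total_mass,
#'   n_links, decoy_class, id), `linker`, and a mass-sorted index.
#' @export
build_products <- function(peptides, linker,
                           enable_single = TRUE, enable_mono = TRUE,
                           enable_loop = TRUE, enable_dipeptide = TRUE,
                           enable_higher_order = FALSE,
                           exclude_cterm_cleavage = TRUE) {
  if (is.null(peptides$mods)) peptides$mods <- ""
  if (is.null(peptides$n_mods)) peptides$n_mods <- 0L
  np <- nrow(peptides)
  sites_a <- lapply(seq_len(np), function(i)
    link_sites(peptides$sequence[i], linker$specificity_a, peptides$start[i],
               exclude_cterm_cleavage))
  sites_b <- if (identical(sort(linker$specificity_a),
                           sort(linker$specificity_b))) sites_a else
    lapply(seq_len(np), function(i)
      link_sites(peptides$sequence[i], linker$specificity_b, peptides$start[i],
                 exclude_cterm_cleavage))
  sites_any <- mapply(union, sites_a, sites_b, SIMPLIFY = FALSE)

  parts <- list()
  blank <- function(n) data.frame(
    kind = character(n), pep_a = integer(n), pep_b = NA_integer_,
    site_a = NA_integer_, site_b = NA_integer_, extra_site = NA_integer_,
    extra_on = NA_character_, total_mass = numeric(n), n_links = integer(n),
    decoy_class = character(n))

  if (enable_single && np) {
    d <- blank(np)
    d$kind <- "single"; d$pep_a <- seq_len(np)
    d$total_mass <- peptides$mass; d$n_links <- 0L
    d$decoy_class <- ifelse(peptides$is_decoy, "D", "T")
    parts$single <- d
  }
  if (enable_mono) {
    idx <- rep(seq_len(np), lengths(sites_any))
    if (length(idx)) {
      d <- blank(length(idx))
      d$kind <- "monolink"; d$pep_a <- idx
      d$site_a <- unlist(sites_any)
      d$total_mass <- peptides$mass[idx] + linker$monolink_mass
      d$n_links <- 1L
      d$decoy_class <- ifelse(peptides$is_decoy[idx], "D", "T")
      parts$mono <- d
    }
  }
  if (enable_loop) {
    lp <- list()
    for (i in seq_len(np)) {
      sa <- sites_a[[i]]; sb <- sites_b[[i]]
      if (!length(sa) || !length(sb)) next
      pr <- unique(t(apply(expand.grid(a = sa, b = sb), 1L, sort)))
      pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]
      if (!nrow(pr)) next
      d <- blank(nrow(pr))
      d$kind <- "looplink"; d$pep_a <- i
      d$site_a <- as.integer(pr[, 1L]); d$site_b <- as.integer(pr[, 2L])
      d$total_mass <- peptides$mass[i] + linker$looplink_mass
      d$n_links <- 1L
      d$decoy_class <- if (peptides$is_decoy[i]) "D" else "T"
      lp[[length(lp) + 1L]] <- d
    }
    if (length(lp)) parts$loop <- do.call(rbind, lp)
  }
  if (enable_dipeptide) {
    linkable <- which(lengths(sites_any) > 0L)
    nl <- length(linkable)
    if (nl) {
      pi <- rep(linkable, nl - seq_len(nl) + 1L)
      pj <- unlist(lapply(seq_len(nl), function(k) linkable[k:nl]))
      # site combinations: a-end on pep_i, b-end on pep_j; for
      # heterobifunctional linkers the reverse orientation is added below
      cc <- {
        la <- lengths(sites_a[pi]); lb <- lengths(sites_b[pj])
        cnt <- la * lb
        pa <- rep(pi, cnt); pb <- rep(pj, cnt)
        sa <- unlist(mapply(function(s, l) if (l > 0L) rep(s, each = l) else integer(),
                            sites_a[pi], lb, SIMPLIFY = FALSE))
        sb <- unlist(mapply(function(s, l) if (length(s)) rep(s, times = l) else integer(),
                            sites_b[pj], la, SIMPLIFY = FALSE))
        list(pa = pa, pb = pb, sa = sa, sb = sb)
      }
      if (!identical(sites_a, sites_b)) {
        # heterobifunctional: also a-end on pep_j, b-end on pep_i
        la2 <- lengths(sites_a[pj]); lb2 <- lengths(sites_b[pi])
        cnt2 <- la2 * lb2
        cc$pa <- c(cc$pa, rep(pj, cnt2)); cc$pb <- c(cc$pb, rep(pi, cnt2))
        cc$sa <- c(cc$sa, unlist(mapply(function(s, l) if (l > 0L) rep(s, each = l) else integer(),
                                        sites_a[pj], lb2, SIMPLIFY = FALSE)))
        cc$sb <- c(cc$sb, unlist(mapply(function(s, l) if (length(s)) rep(s, times = l) else integer(),
                                        sites_b[pi], la2, SIMPLIFY = FALSE)))
      }
      # canonical orientation + dedup (self-pairs and double-counted combos)
      key <- ifelse(cc$pa < cc$pb | (cc$pa == cc$pb & cc$sa <= cc$sb),
                    paste(cc$pa, cc$sa, cc$pb, cc$sb),
                    paste(cc$pb, cc$sb, cc$pa, cc$sa))
      keep <- !duplicated(key)
      pa <- cc$pa[keep]; pb <- cc$pb[keep]
      sa <- cc$sa[keep]; sb <- cc$sb[keep]
      swap <- pa > pb | (pa == pb & sa > sb)
      tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
      tmp <- sa[swap]; sa[swap] <- sb[swap]; sb[swap] <- tmp
      d <- blank(length(pa))
      d$kind <- "dipeptide"; d$pep_a <- pa; d$pep_b <- pb
      d$site_a <- sa; d$site_b <- sb
      d$total_mass <- peptides$mass[pa] + peptides$mass[pb] + linker$intact_mass
      d$n_links <- 1L
      d$decoy_class <- .decoy_class2(peptides$is_decoy[pa], peptides$is_decoy[pb])
      parts$dipep <- d
      if (enable_higher_order) {
        ho <- list()
        for (r in seq_len(nrow(d))) {
          for (side in c("a", "b")) {
            pp <- if (side == "a") d$pep_a[r] else d$pep_b[r]
            used <- if (side == "a") d$site_a[r] else d$site_b[r]
            extra <- setdiff(sites_any[[pp]], used)
            if (!length(extra)) next
            h <- d[rep(r, length(extra)), , drop = FALSE]
            h$kind <- "higher_order"
            h$extra_site <- extra; h$extra_on <- side
            h$total_mass <- h$total_mass + linker$monolink_mass
            h$n_links <- 2L
            ho[[length(ho) + 1L]] <- h
          }
        }
        if (length(ho)) parts$higher <- do.call(rbind, ho)
      }
    }
  }
  products <- if (length(parts)) do.call(rbind, parts) else blank(0L)
  rownames(products) <- NULL
  pep_id <- function(i) ifelse(is.na(i), "",
    paste0(peptides$sequence[i],
           ifelse(nzchar(peptides$mods[i]), paste0("[", peptides$mods[i], "]"), ""),
           "@", peptides$protein_id[i], ":", peptides$start[i]))
  products$id <- paste0(products$kind, "|", pep_id(products$pep_a),
                        "(", products$site_a, ")|",
                        pep_id(products$pep_b), "(", products$site_b, ")",
                        ifelse(is.na(products$extra_site), "",
                               paste0("+mono", products$extra_on,
                                      products$extra_site)))
  ord <- order(products$total_mass, products$id)
  structure(list(peptides = peptides, products = products[ord, , drop = FALSE],
                 linker = linker),
            class = "xl_space")
}

#' @export
print.xl_space <- function(x, ...) {
  cat("<xl_space> ", nrow(x$products), " products over ",
      nrow(x$peptides), " peptide variants (linker ", x$linker$name, ")\n",
      sep = "")
  print(table(x$products$kind))
  invisible(x)
}

#' Query the product mass index at a ppm tolerance
#'
#' Returns the rows of `space$products` whose total mass `m` satisfies
#' `|m - precursor_mass| / precursor_mass <= tol_ppm * 1e-6`.
#'
#' @param space An `xl_space` (products sorted by mass).
#' @param precursor_mass Neutral precursor mass in Da (> 0).
#' @param tol_ppm Relative tolerance in ppm.
#' @return Integer row indices into `space$products`.
#' @export
query_index <- function(space, precursor_mass, tol_ppm) {
  if (!is.finite(precursor_mass) || precursor_mass <= 0)
    stop("precursor_mass must be positive")
  tol <- tol_ppm * 1e-6 * precursor_mass
  m <- space$products$total_mass
  lo <- findInterval(precursor_mass - tol, m, left.open = TRUE) + 1L
  hi <- findInterval(precursor_mass + tol, m)
  if (hi < lo) integer() else lo:hi
}
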