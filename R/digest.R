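# In-silico digestion and target-decoy database construction.

#' Read a protein FASTA database
#'
#' @param path FASTA file path.
#' @return `data.frame(id, sequence, is_decoy)`; the accession is the header
#'   up to the first whitespace.
#' @export
read_fasta_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  data.frame(id = ids, sequence = as.character(aa), is_decoy = FALSE,
             row.names = NULL)
}

#' Write a protein database to FASTA
#'
#' @param db `data.frame(id, sequence)`.
#' @param path Output path.
#' @export
write_fasta_db <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- db$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Generate decoy proteins
#'
#' Each protein is reversed while keeping its C-terminal residue in place, so
#' decoys match targets in length and amino-acid composition and tryptic
#' peptide mass distributions stay comparable. The transform is involutive on
#' the non-terminal part. Decoy accessions are prefixed `REV_`.
#'
#' @param db `data.frame(id, sequence)` of target proteins.
#' @return `data.frame` of decoy proteins with `is_decoy = TRUE`.
#' @export
make_decoys <- function(db) {
  if (!nrow(db)) stop("empty protein database")
  rev_keep_last <- function(s) {
    n <- nchar(s)
    if (n <= 1L) return(s)
    paste0(paste(rev(strsplit(substr(s, 1L, n - 1L), "", fixed = TRUE)[[1L]]),
                 collapse = ""), substr(s, n, n))
  }
  data.frame(id = paste0("REV_", db$id),
             sequence = vapply(db$sequence, rev_keep_last, "", USE.NAMES = FALSE),
             is_decoy = TRUE, row.names = NULL)
}

#' Enzymatic cleavage rule
#'
#' @param cleave_after Residues after which the enzyme cuts.
#' @param not_before Residues that suppress cleavage when they follow the
#'   cut site (trypsin: proline).
#' @return An `xl_enzyme` object.
#' @export
enzyme_rule <- function(cleave_after = c("K", "R"), not_before = "P") {
  structure(list(cleave_after = cleave_after, not_before = not_before),
            class = "xl_enzyme")
}

# Cut positions: index i means a cut between residue i and i+1.
.cut_sites <- function(aa, enz) {
  n <- length(aa)
  if (n < 2L) return(integer())
  i <- which(aa[-n] %in% enz$cleave_after)
  i[!(aa[i + 1L] %in% enz$not_before)]
}

#' In-silico digestion of a protein
#'
#' @param sequence Protein sequence.
#' @param enzyme An [enzyme_rule()].
#' @param max_missed_cleavages Maximum internal uncleaved sites.
#' @param min_length Minimum peptide length (residues).
#' @param max_mass Maximum unmodified peptide mass (Da).
#' @param protein_id Accession recorded on each peptide.
#' @param is_decoy Logical flag propagated to peptides.
#' @return `data.frame(sequence, protein_id, start, end, missed_cleavages,
#'   is_decoy, mass)` with 1-based inclusive protein coordinates.
#' @export
digest <- function(sequence, enzyme = enzyme_rule(),
                   max_missed_cleavages = 3L, min_length = 1L,
                   max_mass = Inf, protein_id = NA_character_,
                   is_decoy = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  bounds <- c(0L, .cut_sites(aa, enzyme), n)  # segment boundaries
  nseg <- length(bounds) - 1L
  out <- vector("list", 64L); nout <- 0L
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed_cleavages)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L < min_length) next
      pep <- substr(sequence, s, e)
      m <- tryCatch(peptide_mass(pep), error = function(e) NA_real_)
      if (is.na(m) || m > max_mass) next
      nout <- nout + 1L
      if (nout > length(out)) out <- c(out, vector("list", length(out)))
      out[[nout]] <- data.frame(sequence = pep, protein_id = protein_id,
                                start = s, end = e,
                                missed_cleavages = j - i, is_decoy = is_decoy,
                                mass = m)
    }
  }
  if (!nout) return(data.frame(sequence = character(), protein_id = character(),
                               start = integer(), end = integer(),
                               missed_cleavages = integer(),
                               is_decoy = logical(), mass = numeric()))
  do.call(rbind, out[seq_len(nout)])
}

#' Digest a whole database (targets plus decoys)
#'
#' @param db Protein `data.frame(id, sequence, is_decoy)`.
#' @param add_decoys Append [make_decoys()] of the target entries first.
#' @inheritParams digest
#' @return Combined peptide `data.frame` (unique by sequence/protein/start).
#' @export
digest_db <- function(db, enzyme = enzyme_rule(), max_missed_cleavages = 3L,
                      min_length = 6L, max_mass = 6000, add_decoys = TRUE) {
  if (add_decoys) db <- rbind(db, make_decoys(db[!db$is_decoy, , drop = FALSE]))
  peps <- do.call(rbind, lapply(seq_len(nrow(db)), function(i)
    digest(db$sequence[i], enzyme, max_missed_cleavages, min_length, max_mass,
           protein_id = db$id[i], is_decoy = db$is_decoy[i])))
  if (is.null(peps)) stop("digestion produced no peptides")
  peps[!duplicated(peps[c("sequence", "protein_id", "start")]), , drop = FALSE]
}
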