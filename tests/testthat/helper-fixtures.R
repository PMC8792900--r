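# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no binary fixtures.

# Small target-decoy search space over a random database.
small_space <- function(linker = linker_preset("DSS"), n_proteins = 5L,
                        seed = 1L, max_mc = 1L, higher = FALSE) {
  db <- make_database(n_proteins, seed = seed)
  peps <- digest_db(db, max_missed_cleavages = max_mc, min_length = 6L,
                    max_mass = 4000)
  build_products(peps, linker, enable_higher_order = higher)
}

# Indices of linkable target peptides in a space, with their first site.
linkable_targets <- function(space) {
  peps <- space$peptides
  sites <- lapply(seq_len(nrow(peps)), function(i)
    link_sites(peps$sequence[i], space$linker$specificity_a, peps$start[i]))
  idx <- which(lengths(sites) > 0L & !peps$is_decoy)
  list(idx = idx, sites = sites)
}

# Independent exhaustive binomial-tail oracle (plain summation).
binom_tail_oracle <- function(k, n, p) {
  if (k == 0L) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Simulated CSM score table with known truth labels, for PEP/FDR tests.
# False matches carry decoy classes at the 1:2:1 TT:TD:DD odds of two
# independent constituents.
simulate_csms <- function(n_true = 500L, n_false = 400L, seed = 1L,
                          mu_true = 45, mu_false = 15) {
  set.seed(seed)
  mk <- function(n, mu, cls) data.frame(
    kind = "dipeptide",
    score = pmax(0, stats::rnorm(n, mu, 8)),
    partial_alpha = pmax(0, stats::rnorm(n, mu / 2, 5)),
    partial_beta = pmax(0, stats::rnorm(n, mu / 2.5, 5)),
    n_mods = stats::rpois(n, 0.3),
    precursor_charge = sample(3:5, n, replace = TRUE),
    missed_cleavages = stats::rpois(n, 0.5),
    decoy_class = cls, intra = TRUE)
  rbind(cbind(mk(n_true, mu_true, "TT"), truth = TRUE),
        cbind(mk(n_false, mu_false,
                 sample(c("TT", "TD", "TD", "DD"), n_false, replace = TRUE)),
              truth = FALSE))
}
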