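test_that("tryptic digestion honors cleavage and suppression rules", {
  d0 <- digest("MKRPEPTIDEK", max_missed_cleavages = 0L)
  expect_setequal(d0$sequence, c("MK", "RPEPTIDEK"))
  d1 <- digest("MKRPEPTIDEK", max_missed_cleavages = 1L)
  expect_setequal(d1$sequence, c("MK", "RPEPTIDEK", "MKRPEPTIDEK"))
  d5 <- digest("MKRPEPTIDEK", max_missed_cleavages = 0L, min_length = 5L)
  expect_equal(d5$sequence, "RPEPTIDEK")
  # positions are 1-based inclusive
  expect_equal(d0$start[d0$sequence == "RPEPTIDEK"], 3L)
  expect_equal(d0$end[d0$sequence == "RPEPTIDEK"], 11L)
  # missed-cleavage counts recorded
  expect_equal(d1$missed_cleavages[d1$sequence == "MKRPEPTIDEK"], 1L)
})

test_that("decoy generation reverses keeping the C-terminal residue", {
  db <- data.frame(id = "P1", sequence = "PEPTIDEK", is_decoy = FALSE)
  dec <- make_decoys(db)
  expect_equal(dec$sequence, "EDITPEPK")
  expect_equal(dec$id, "REV_P1")
  expect_true(dec$is_decoy)
  # involutive on the non-terminal part
  dec2 <- make_decoys(transform(dec, is_decoy = FALSE))
  expect_equal(dec2$sequence, "PEPTIDEK")
  # cardinality and composition preserved
  db2 <- make_database(7, seed = 3)
  decs <- make_decoys(db2)
  expect_equal(nrow(decs), 7L)
  srt <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(vapply(decs$sequence, srt, ""),
               vapply(db2$sequence, srt, ""), ignore_attr = TRUE)
})

test_that("link-site eligibility follows specificity and the C-term rule", {
  expect_equal(link_sites("AKGKR", "K"), c(2L, 4L))
  # C-terminal K excluded as cleavage site, toggleable
  expect_equal(link_sites("AGKK", "K"), 3L)
  expect_equal(link_sites("AGKK", "K", exclude_cterm_cleavage = FALSE),
               c(3L, 4L))
  # protein N-terminus only for peptides starting the protein
  expect_equal(link_sites("AGR", c("K", "nterm"), start = 1L), 1L)
  expect_equal(link_sites("AGR", c("K", "nterm"), start = 10L), integer())
})

test_that("product space enumerates the documented product census", {
  # one peptide AKR with a single site: single, monolink, homodimer dipeptide
  peps <- data.frame(sequence = "AKR", protein_id = "P", start = 1L,
                     end = 3L, missed_cleavages = 1L, is_decoy = FALSE,
                     mass = peptide_mass("AKR"))
  lk <- linker_preset("DSS")
  sp <- build_products(peps, lk)
  expect_setequal(sp$products$kind, c("single", "monolink", "dipeptide"))
  m <- peptide_mass("AKR")
  expect_equal(sp$products$total_mass[sp$products$kind == "single"], m)
  expect_equal(sp$products$total_mass[sp$products$kind == "monolink"],
               m + lk$intact_mass + 18.010565, tolerance = 1e-9)
  expect_equal(sp$products$total_mass[sp$products$kind == "dipeptide"],
               2 * m + lk$intact_mass, tolerance = 1e-9)
  # two eligible sites on one peptide give exactly one looplink
  peps2 <- data.frame(sequence = "AKKAR", protein_id = "P", start = 1L,
                      end = 5L, missed_cleavages = 1L, is_decoy = FALSE,
                      mass = peptide_mass("AKKAR"))
  sp2 <- build_products(peps2, lk)
  expect_equal(sum(sp2$products$kind == "looplink"), 1L)
})

test_that("decoy classes follow the exact pairing identities", {
  # 2 targets + their 2 decoys, all-vs-all with self-pairs: 10 pairs
  peps <- data.frame(
    sequence = c("AKGGGR", "GGKAAR", "GGAKGR", "AAKGGR"),
    protein_id = c("P1", "P2", "REV_P1", "REV_P2"),
    start = 1L, end = 6L, missed_cleavages = 0L,
    is_decoy = c(FALSE, FALSE, TRUE, TRUE))
  peps$mass <- vapply(peps$sequence, peptide_mass, 0)
  sp <- build_products(peps, linker_preset("DSS"), enable_single = FALSE,
                       enable_mono = FALSE, enable_loop = FALSE)
  cls <- table(sp$products$decoy_class)
  expect_equal(nrow(sp$products), 10L)
  expect_equal(unname(cls["TT"]), 3L)   # n_T (n_T + 1) / 2
  expect_equal(unname(cls["TD"]), 4L)   # n_T * n_D
  expect_equal(unname(cls["DD"]), 3L)
})

test_that("every product mass is recomputable from its constituents", {
  sp <- small_space(seed = 11)
  p <- sp$products
  m <- sp$peptides$mass
  lk <- sp$linker
  expected <- ifelse(p$kind == "single", m[p$pep_a],
              ifelse(p$kind == "monolink", m[p$pep_a] + lk$monolink_mass,
              ifelse(p$kind == "looplink", m[p$pep_a] + lk$looplink_mass,
                     m[p$pep_a] + m[p$pep_b] + lk$intact_mass)))
  expect_true(all(abs(p$total_mass - expected) / p$total_mass < 1e-9))
})

test_that("mass-index queries equal a linear scan", {
  sp <- small_space(seed = 2)
  # worked example: 5 ppm of 1000 is 0.005
  fake <- sp
  fake$products <- data.frame(kind = "single", pep_a = 1L, pep_b = NA,
                              site_a = NA, site_b = NA, extra_site = NA,
                              extra_on = NA,
                              total_mass = c(1000.000, 1000.004, 1001.0),
                              n_links = 0L, decoy_class = "T",
                              id = c("a", "b", "c"))
  expect_equal(query_index(fake, 1000.0, 5), c(1L, 2L))
  expect_equal(query_index(fake, 999.0, 5), integer())
  expect_error(query_index(fake, -5, 5), "positive")
  # brute-force equivalence on the real space
  set.seed(9)
  masses <- sp$products$total_mass
  for (q in sample(masses, 50)) {
    qq <- q * (1 + stats::runif(1, -2e-5, 2e-5))
    hit <- query_index(sp, qq, 10)
    oracle <- which(abs(masses - qq) / qq <= 10e-6)
    expect_equal(hit, oracle)
  }
})

test_that("dipeptide pair count matches n(n+1)/2 over linkable peptides", {
  sp <- small_space(seed = 4)
  peps <- sp$peptides
  sites <- lapply(seq_len(nrow(peps)), function(i)
    link_sites(peps$sequence[i], sp$linker$specificity_a, peps$start[i]))
  n <- sum(lengths(sites) > 0L)
  dip <- sp$products[sp$products$kind == "dipeptide", ]
  n_pairs <- length(unique(paste(dip$pep_a, dip$pep_b)))
  expect_equal(n_pairs, n * (n + 1L) / 2L)
})

test_that("variable modifications expand combinatorially up to the cap", {
  peps <- digest("AMKGMMR", max_missed_cleavages = 1L)
  peps$protein_id <- "P"
  ox <- modification("ox", 15.994915, "M")
  ex <- expand_modifications(peps[peps$sequence == "AMKGMMR", ],
                             var_mods = list(ox), max_var_mods = 2L)
  # 3 M sites: C(3,0) + C(3,1) + C(3,2) = 1 + 3 + 3 variants
  expect_equal(nrow(ex), 7L)
  expect_equal(sort(unique(ex$n_mods)), 0:2)
  expect_equal(max(ex$mass) - min(ex$mass), 2 * 15.994915, tolerance = 1e-9)
  # fixed mods apply everywhere and are not counted
  cam <- modification("cam", 57.021464, "C", fixed = TRUE)
  pc <- digest("ACCKR", max_missed_cleavages = 1L)
  pc$protein_id <- "P"
  exc <- expand_modifications(pc[pc$sequence == "ACCKR", ],
                              fixed_mods = list(cam))
  expect_equal(exc$n_mods, 0L)
  expect_equal(exc$mass, peptide_mass("ACCKR") + 2 * 57.021464,
               tolerance = 1e-9)
})
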