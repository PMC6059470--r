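test_that("K2P closed form and pairwise deletion match hand derivations", {
  expect_equal(k2p("ACGT", "ACGT")$distance, 0)
  expect_equal(k2p("ACGT", "ACGT")$P, 0)

  # 100 sites with 10 transitions (A->G) and 5 transversions (A->C):
  # P = 0.1, Q = 0.05, d = -1/2 ln(0.75 * sqrt(0.90)) = 0.170181
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  r <- k2p(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$distance, -0.5 * log(0.75 * sqrt(0.90)), tolerance = 1e-12)
  expect_equal(r$distance, 0.170181, tolerance = 1e-5)

  # pairwise deletion drops sites with a gap in either row
  r2 <- k2p("A-GT", "AC-T")
  expect_equal(r2$n_sites, 2)
  expect_equal(r2$distance, 0)
  expect_error(k2p("ACGT", "ACG"), "equal length")
})

test_that("K2P equals the brute-force oracle on random gapped pairs", {
  set.seed(21)
  for (i in 1:200) {
    L <- sample(20:80, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T", "-", "N"), L,
                                  replace = TRUE,
                                  prob = c(.22, .22, .22, .22, .06, .06)),
                           collapse = "")
    a <- mk(); b <- mk()
    mine <- k2p(a, b)
    orc <- oracle_k2p(a, b)
    expect_equal(mine$n_sites, orc$n_sites)
    if (is.na(orc$distance)) {
      expect_false(mine$defined)
    } else {
      expect_equal(mine$distance, orc$distance, tolerance = 1e-12)
    }
  }
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(33)
  # related sequences (moderate divergence) so no pair saturates
  base <- strsplit(random_seq(300), "")[[1]]
  seqs <- vapply(1:6, function(i) {
    mut <- base
    idx <- sample(300, 40)
    mut[idx] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    paste(mut, collapse = "")
  }, character(1))
  aln <- as_alignment(data.frame(specimen_id = paste0("s", 1:6),
                                 sequence = seqs))
  dm <- distance_matrix(aln)
  bin <- ape::as.DNAbin(do.call(rbind, lapply(seqs, function(s)
    tolower(strsplit(s, "")[[1]]))))
  rownames(bin) <- paste0("s", 1:6)
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[aln$ids, aln$ids]),
               tolerance = 1e-9)
})

test_that("the K2P correction never shrinks and is monotone in P", {
  set.seed(55)
  for (i in 1:50) {
    a <- random_seq(100)
    b <- random_seq(100)
    r <- k2p(a, b)
    if (!r$defined) next
    raw <- (r$P + r$Q)
    expect_gte(r$distance, raw - 1e-12)
  }
  # increasing transition count at fixed transversions increases d
  d_at <- function(nts) {
    a <- strrep("A", 100)
    b <- paste0(strrep("G", nts), strrep("C", 5), strrep("A", 95 - nts))
    k2p(a, b)$distance
  }
  ds <- vapply(c(5, 10, 15, 20), d_at, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("distance_matrix equals per-pair k2p and masks saturation", {
  sim <- small_library(seed = 61)
  aln <- progressive_align(sim$its2)
  dm <- distance_matrix(aln)
  n <- length(aln$ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_equal(dm$d[i, j],
                   k2p(aln$seqs[i], aln$seqs[j])$distance,
                   tolerance = 1e-12)
    }
  }
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))

  # saturated pair (all transversions) is masked with a reason
  sat <- as_alignment(data.frame(specimen_id = c("x", "y", "z"),
                                 sequence = c("AAAAAAAA", "CCCCCCCC",
                                              "AAAAAAAA")))
  dms <- distance_matrix(sat)
  expect_true(is.na(dms$d["x", "y"]))
  expect_equal(dms$masked$reason[1], "saturated")
  pruned <- prune_undefined(dms)
  expect_false(anyNA(pruned$d))
})

test_that("rank summaries pool the right comparisons", {
  # species with specimen counts {3, 2, 1}: 3 + 1 + 0 conspecific pairs
  tax <- data.frame(
    specimen_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    species = c("A", "A", "A", "B", "B", "C"),
    genus = c("G1", "G1", "G1", "G1", "G1", "G2"),
    family = "F", stringsAsFactors = FALSE)
  seqs <- c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC", a3 = "ACGTACGTAC",
            b1 = "ACGTACGTAA", b2 = "ACGTACGTAA", c1 = "ACGTACGGTA")
  aln <- as_alignment(data.frame(specimen_id = names(seqs),
                                 sequence = unname(seqs)))
  dm <- distance_matrix(aln)
  sp <- summarize_rank(dm, tax, "species")
  expect_equal(sp$n_comparisons, 4)
  expect_equal(sp$n_taxa, 2) # C is a singleton
  expect_equal(sp$min_pct, 0)
  expect_equal(sp$max_pct, 0)
  expect_equal(sp$mean_pct, 0)
  gn <- summarize_rank(dm, tax, "genus")
  expect_equal(gn$n_comparisons, 3 * 2) # A-B cross pairs only
  fm <- summarize_rank(dm, tax, "family")
  expect_equal(fm$n_comparisons, 5) # G1 x G2 pairs

  # all-singleton input: empty summary with a warning
  solo <- as_alignment(data.frame(specimen_id = c("a1", "c1"),
                                  sequence = c("ACGT", "ACGA")))
  solo_tax <- tax[tax$specimen_id %in% c("a1", "c1"), ]
  expect_warning(out <- summarize_rank(distance_matrix(solo), solo_tax,
                                       "species"), "no comparable")
  expect_equal(nrow(out), 0)
})

test_that("species-level mean distance recovers the simulated scale", {
  cfg <- library_config(n_families = 3, genera_per_family = 2,
                        species_per_genus = 3, specimens_per_species = 4,
                        its2_length = c(250, 250), d_intra = 0.006,
                        seed = 71)
  sim <- simulate_library(cfg)
  aln <- progressive_align(sim$its2)
  dm <- distance_matrix(aln)
  m <- summarize_rank(dm, sim$taxonomy, "species")$mean_pct
  expect_gt(m, 0.6 * 0.8)
  expect_lt(m, 0.6 * 1.2)
})
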