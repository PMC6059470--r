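test_that("taxonomy counts follow the configuration", {
  cfg <- library_config(n_families = 2, genera_per_family = 2,
                        species_per_genus = 2, specimens_per_species = 2,
                        seed = 1)
  tax <- generate_taxonomy(cfg)
  expect_equal(nrow(tax), 16)
  expect_equal(length(unique(tax$species)), 8)
  expect_equal(length(unique(tax$genus)), 4)
  expect_equal(length(unique(tax$family)), 2)
  expect_false(anyDuplicated(tax$specimen_id) > 0)
})

test_that("taxonomy with ranged counts is seed-deterministic", {
  cfg <- library_config(specimens_per_species = c(1, 3), seed = 99)
  t1 <- generate_taxonomy(cfg)
  t2 <- generate_taxonomy(cfg)
  expect_identical(t1, t2)
  expect_true(any(table(t1$species) == 1)) # singletons possible
})

test_that("degenerate configurations are rejected", {
  expect_error(library_config(species_per_genus = 0), "species_per_genus")
  expect_error(library_config(d_intra = 0.2), "d_intra < d_species")
  expect_error(library_config(its2_length = c(300, 200)), "its2_length")
  expect_error(library_config(flank_5p = ""), "flank")
  expect_error(library_config(kappa = -1), "kappa")
})

test_that("zero intraspecific rate yields identical conspecific sequences", {
  cfg <- library_config(n_families = 1, genera_per_family = 1,
                        species_per_genus = 3, specimens_per_species = 3,
                        d_intra = 0, d_species = 0.1, d_genus = 0.2,
                        d_family = 0.3, indel_rate = 0, seed = 5)
  sim <- simulate_library(cfg)
  by_sp <- split(sim$its2$sequence, sim$taxonomy$species)
  for (seqs in by_sp) expect_length(unique(seqs), 1)
})

test_that("realized transition:transversion counts match the K2P model", {
  # single branch d = 0.1 at kappa = 2: instantaneous transition rate is
  # kappa * beta against 2 * beta for the two transversion targets, so
  # realized transitions/transversions ~ kappa / 2 = 1 at small d
  set.seed(17)
  ns <- asNamespace("barcodeval")
  ratios <- replicate(5, {
    root <- ns$random_root(10000, 0.5)
    child <- ns$mutate_seq(root, 0.1, 2)
    diff <- root != child
    purine <- function(x) x == 1L | x == 3L
    ts <- sum(diff & purine(root) == purine(child))
    tv <- sum(diff & purine(root) != purine(child))
    ts / tv
  })
  expect_gt(mean(ratios), 0.88)
  expect_lt(mean(ratios), 1.08)
})

test_that("same seed reproduces a byte-identical FASTA", {
  cfg <- library_config(n_families = 2, genera_per_family = 1,
                        species_per_genus = 2, specimens_per_species = 2,
                        seed = 123)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  sim1 <- simulate_library(cfg)
  write_fasta(sim1$amplicons, f1)
  sim2 <- simulate_library(cfg)
  write_fasta(sim2$amplicons, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("root GC matches the target and rank distances are ordered", {
  cfg <- library_config(n_families = 4, genera_per_family = 2,
                        species_per_genus = 2, specimens_per_species = 2,
                        its2_length = c(300, 300), indel_rate = 0,
                        seed = 31)
  set.seed(cfg$seed)
  ns <- asNamespace("barcodeval")
  root <- ns$random_root(300, cfg$gc_target)
  gc <- mean(root %in% c(2L, 3L))
  expect_lt(abs(gc - cfg$gc_target), 0.05)

  sim <- simulate_library(cfg)
  aln <- progressive_align(sim$its2)
  dm <- distance_matrix(aln)
  m_sp <- summarize_rank(dm, sim$taxonomy, "species")$mean_pct
  m_gn <- summarize_rank(dm, sim$taxonomy, "genus")$mean_pct
  m_fm <- summarize_rank(dm, sim$taxonomy, "family")$mean_pct
  expect_lt(m_sp, m_gn)
  expect_lt(m_gn, m_fm)
})

test_that("flanking and trimming are exact inverses", {
  cfg <- library_config(n_families = 1, genera_per_family = 1,
                        species_per_genus = 2, specimens_per_species = 2,
                        seed = 8)
  sim <- simulate_library(cfg)
  amp <- sim$amplicons
  expect_equal(substr(amp$sequence, amp$its2_start + 1, amp$its2_end),
               sim$its2$sequence)
  expect_equal(amp$sequence[1],
               paste0(cfg$flank_5p, sim$its2$sequence[1], cfg$flank_3p))
  expect_error(add_flanks(data.frame(specimen_id = "x", sequence = ""),
                          cfg), "zero-length")
})

test_that("expected divergences from the ground-truth tree match config", {
  cfg <- library_config(n_families = 2, genera_per_family = 2,
                        species_per_genus = 2, specimens_per_species = 2,
                        indel_rate = 0, seed = 4)
  sim <- simulate_library(cfg)
  ed <- expected_divergence(sim$ground_truth)
  tax <- sim$taxonomy
  pick <- function(i, j) ed[tax$specimen_id[i], tax$specimen_id[j]]
  # conspecific pair
  expect_equal(pick(1, 2), cfg$d_intra, tolerance = 1e-9)
  # different family pair
  i <- 1; j <- which(tax$family != tax$family[1])[1]
  expect_equal(pick(i, j), cfg$d_family, tolerance = 1e-9)
})
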