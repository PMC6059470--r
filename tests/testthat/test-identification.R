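test_that("an exact library match is the single best hit", {
  lib <- data.frame(specimen_id = c("r1", "r2", "r3"),
                    sequence = c("ACGTACGTACGTACGTACGT",
                                 "ACGTACGTACGTACGTACGA",
                                 "TTTTTTTTTTGGGGGGGGGG"),
                    stringsAsFactors = FALSE)
  tax <- data.frame(specimen_id = c("r1", "r2", "r3"),
                    species = c("A", "B", "C"),
                    genus = c("G1", "G1", "G2"),
                    family = "F", stringsAsFactors = FALSE)
  q <- list(specimen_id = "q", sequence = "ACGTACGTACGTACGTACGT")
  hits <- best_match(q, lib, tax, leave_one_out = FALSE)
  expect_equal(hits$subject_id[hits$best], "r1")
  expect_equal(hits$identity[1], 1.0)
  expect_equal(hits$coverage[1], 1.0)
})

test_that("equidistant references produce a tied best-hit set", {
  lib <- data.frame(specimen_id = c("r1", "r2"),
                    sequence = c("ACGTACGTACGTACGTACGA",
                                 "ACGTACGTACGTACGTACGG"),
                    stringsAsFactors = FALSE)
  tax <- data.frame(specimen_id = c("r1", "r2"),
                    species = c("A", "B"), genus = c("G1", "G2"),
                    family = "F", stringsAsFactors = FALSE)
  q <- list(specimen_id = "q", sequence = "ACGTACGTACGTACGTACGT")
  hits <- best_match(q, lib, tax, min_identity = 0.9,
                     leave_one_out = FALSE)
  expect_equal(sum(hits$best), 2)
  cl <- classify("A", hits)
  expect_equal(cl$species_call, "ambiguous")
})

test_that("the three-way rule matches the truth table on all small multisets", {
  labels <- c("A", "B", "C")
  for (size in 1:4) {
    combos <- do.call(expand.grid,
                      c(rep(list(labels), size),
                        stringsAsFactors = FALSE))
    for (row in seq_len(nrow(combos))) {
      multiset <- unlist(combos[row, ], use.names = FALSE)
      hits <- make_hits(multiset)
      cl <- classify("A", hits)
      expect_equal(cl$species_call, oracle_three_way("A", multiset),
                   info = paste(multiset, collapse = ","))
    }
  }
  # no hits at all
  expect_equal(classify("A", make_hits(character(0)))$species_call,
               "no_hit")
})

test_that("success rates aggregate calls with reported denominators", {
  res <- data.frame(
    query_id = paste0("q", 1:4),
    true_species = "A",
    species_call = c("correct", "correct", "ambiguous", "incorrect"),
    genus_call = c("correct", "correct", "correct", "correct"),
    best_species = "A", top_identity = 0.99, n_best = 1,
    species_evaluable = TRUE, genus_evaluable = TRUE,
    stringsAsFactors = FALSE)
  sr <- success_rates(res, "species")
  expect_equal(sr$correct_pct, 50)
  expect_equal(sr$ambiguous_pct, 25)
  expect_equal(sr$incorrect_pct, 25)
  expect_equal(sr$n_evaluated, 4)
  expect_error(success_rates(res[0, ], "species"), "no identification")
})

test_that("conspecific consistency distinguishes cryptic from ambiguous", {
  res <- data.frame(
    query_id = paste0("q", 1:6),
    true_species = c("S1", "S1", "S2", "S2", "S3", "S3"),
    species_call = "correct",
    genus_call = "correct",
    best_species = c("A", "A",      # consistent
                     "A", "B",      # disjoint -> cryptic candidate
                     "A", "A,B"),   # overlapping but unequal
    top_identity = 0.99, n_best = 1,
    species_evaluable = TRUE, genus_evaluable = TRUE,
    stringsAsFactors = FALSE)
  cc <- conspecific_consistency(res)
  expect_equal(cc$status[cc$species == "S1"], "consistent")
  expect_equal(cc$status[cc$species == "S2"], "cryptic_candidate")
  expect_equal(cc$status[cc$species == "S3"], "inconsistent_ambiguous")
})

test_that("lowering the identity threshold never loses hits", {
  sim <- small_library(seed = 515, n_fam = 1, gpf = 2, spg = 2, spec = 2,
                       len = c(150, 150))
  tax <- sim$taxonomy
  q <- sim$its2[1, ]
  n_hits <- vapply(c(0.99, 0.97, 0.9, 0.5), function(thr)
    nrow(best_match(q, sim$its2, tax, min_identity = thr,
                    min_coverage = 0.5)), numeric(1))
  expect_true(all(diff(n_hits) >= 0))
})

test_that("leave-one-out on a well-separated library is fully correct", {
  sim <- small_library(seed = 616)
  res <- identify_library(sim$its2, sim$taxonomy)
  sr_sp <- success_rates(res, "species")
  sr_gn <- success_rates(res, "genus")
  expect_equal(sr_sp$correct_pct, 100)
  expect_equal(sr_gn$correct_pct, 100)
  cc <- conspecific_consistency(res)
  expect_true(all(cc$status %in% c("consistent", "single_query")))
})

test_that("duplicate-specimen libraries stay fully correct under leave-one-out", {
  # every species has two identical specimens: removing the query still
  # leaves an exact conspecific match
  base <- c("ACGTACGTACGTACGTACGTACGTACGTAC",
            "TTGCATGCATGCATGCATGCATGCATGCAT",
            "GGGGCCCCAAAATTTTGGGGCCCCAAAATT")
  lib <- data.frame(specimen_id = paste0("s", 1:6),
                    sequence = rep(base, each = 2),
                    stringsAsFactors = FALSE)
  tax <- data.frame(specimen_id = lib$specimen_id,
                    species = rep(c("A", "B", "C"), each = 2),
                    genus = rep(c("G1", "G2", "G3"), each = 2),
                    family = "F", stringsAsFactors = FALSE)
  res <- identify_library(lib, tax)
  expect_equal(success_rates(res, "species")$correct_pct, 100)
  expect_equal(success_rates(res, "genus")$correct_pct, 100)
})
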