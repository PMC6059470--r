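test_that("the three-taxon tree uses the three-point formulas", {
  ids <- c("A", "B", "C")
  m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(ids, ids))
  tr <- nj_tree(m)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("A", "B", "C")]), c(0.05, 0.15, 0.25))
})

test_that("NJ reproduces additive matrices exactly", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    true_tree <- ape::rtree(n)
    D <- ape::cophenetic.phylo(true_tree)
    tr <- nj_tree(D)
    D2 <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
  }
})

test_that("degenerate and invalid matrices are handled", {
  ids <- c("a", "b", "c", "d")
  zero <- matrix(0, 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(zero)
  expect_true(all(tr$edge.length == 0))

  withNA <- zero
  withNA[1, 2] <- withNA[2, 1] <- NA
  expect_error(nj_tree(withNA), "a-b")
  expect_error(nj_tree(zero[1:2, 1:2]), ">= 3 taxa")
})

test_that("exclusivity matches the monophyly oracle on random labelings", {
  set.seed(20)
  for (rep in 1:10) {
    n_sp <- 5
    tips_per <- 3
    cfg <- library_config(n_families = 1, genera_per_family = 1,
                          species_per_genus = n_sp,
                          specimens_per_species = tips_per,
                          d_intra = sample(c(0.004, 0.08), 1),
                          d_species = 0.12, d_genus = 0.3,
                          d_family = 0.45, its2_length = c(150, 150),
                          indel_rate = 0, seed = 300 + rep)
    sim <- simulate_library(cfg)
    dm <- distance_matrix(progressive_align(sim$its2))
    tr <- nj_tree(dm)
    cl <- species_clusters(tr, sim$taxonomy)
    for (row in seq_len(nrow(cl$per_species))) {
      sp <- cl$per_species$species[row]
      tips <- sim$taxonomy$specimen_id[sim$taxonomy$species == sp]
      outgroup <- setdiff(tr$tip.label, tips)[1]
      rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
      oracle <- ape::is.monophyletic(rooted, tips)
      expect_equal(cl$per_species$status[row] == "identified", oracle,
                   info = sp)
    }
  }
})

test_that("clean and mixed four-leaf topologies are scored as expected", {
  tax <- data.frame(specimen_id = c("a1", "a2", "b1", "b2"),
                    species = c("A", "A", "B", "B"),
                    genus = "G", family = "F", stringsAsFactors = FALSE)
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  cl <- species_clusters(good, tax)
  expect_equal(cl$report$n_species_identified, 2)
  expect_equal(cl$report$discrimination_rate, 1.0)
  expect_equal(cl$report$n_clusters, 2)

  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  cl2 <- species_clusters(bad, tax)
  expect_equal(cl2$report$n_species_identified, 0)
  expect_equal(cl2$report$discrimination_rate, 0.0)
  expect_equal(cl2$report$n_clusters, 1) # one mixed cluster of 2 species
})

test_that("singletons are excluded from the discrimination denominator", {
  tax <- data.frame(specimen_id = c("a1", "a2", "b1", "b2", "c1"),
                    species = c("A", "A", "B", "B", "C"),
                    genus = "G", family = "F", stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,((b1:1,b2:1):1,c1:2):1);")
  cl <- species_clusters(tr, tax)
  expect_equal(cl$report$n_singletons, 1)
  expect_equal(cl$report$n_species_identified, 2)
  expect_equal(cl$report$discrimination_rate, 1.0)
})

test_that("bootstrap supports are percentages with expected behaviour", {
  sim <- small_library(seed = 404, n_fam = 2, gpf = 1, spg = 2, spec = 2,
                       len = c(150, 150))
  aln <- progressive_align(sim$its2)
  tr <- nj_tree(distance_matrix(aln))

  b1 <- bootstrap_support(aln, tr, B = 1, seed = 2)
  s1 <- attr(b1, "support")$support
  expect_true(all(s1 %in% c(0, 100)))

  b2 <- bootstrap_support(aln, tr, B = 30, seed = 3)
  b3 <- bootstrap_support(aln, tr, B = 30, seed = 3)
  expect_identical(attr(b2, "support"), attr(b3, "support"))
  expect_true(all(attr(b2, "support")$support >= 0 &
                  attr(b2, "support")$support <= 100))
  # topology of the full-data tree is untouched by bootstrapping
  expect_equal(ape::dist.topo(b2, tr), setNames(0, "PH85"),
               ignore_attr = TRUE)

  # deep split between the two families saturates
  fam_split <- attr(b2, "support")
  fam_tips <- sim$taxonomy$specimen_id[sim$taxonomy$family == "F01"]
  key_has_family <- vapply(strsplit(fam_split$bipartition, "|",
                                    fixed = TRUE), function(s)
    setequal(s, fam_tips) ||
      setequal(s, setdiff(sim$taxonomy$specimen_id, fam_tips)),
    logical(1))
  expect_true(any(key_has_family))
  expect_equal(fam_split$support[key_has_family], 100)

  expect_error(bootstrap_support(aln, tr, B = 0), "B must be")
})
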