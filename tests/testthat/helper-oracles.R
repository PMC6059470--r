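# Independent oracles used across the suite. These re-derive results by
# direct enumeration or by the closed form, without touching the code
# paths they check.

# K2P from two gapped rows by direct character comparison
oracle_k2p <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  acgt <- c("A", "C", "G", "T")
  ok <- ca %in% acgt & cb %in% acgt
  n <- sum(ok)
  if (n == 0) return(list(distance = NA_real_, P = NA, Q = NA, n_sites = 0))
  ca <- ca[ok]; cb <- cb[ok]
  purine <- function(x) x %in% c("A", "G")
  diff <- ca != cb
  ts <- sum(diff & purine(ca) == purine(cb))
  tv <- sum(diff & purine(ca) != purine(cb))
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 > 0 && w2 > 0) -0.5 * log(w1 * sqrt(w2)) else NA_real_
  list(distance = d, P = P, Q = Q, n_sites = n)
}

# maximum global alignment score by exhaustive recursion with affine gaps
# (first gap column -open, extensions -ext); tiny inputs only
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca)) {
      g <- if (last == "A") -ext else -open
      best <- max(best, g + rec(i + 1, j, "A"))
    }
    if (j <= length(cb)) {
      g <- if (last == "B") -ext else -open
      best <- max(best, g + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "none")
}

# random A/C/G/T string
random_seq <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# three-way classification truth by direct set logic on a label multiset
oracle_three_way <- function(truth, labels) {
  u <- unique(labels)
  if (all(u == truth)) "correct"
  else if (truth %in% u) "ambiguous"
  else "incorrect"
}

# small well-separated library shared by several tests
small_library <- function(seed = 101, n_fam = 2, gpf = 2, spg = 2,
                          spec = 3, len = c(200, 220), d_intra = 0.004) {
  cfg <- library_config(n_families = n_fam, genera_per_family = gpf,
                        species_per_genus = spg,
                        specimens_per_species = spec,
                        its2_length = len, d_intra = d_intra,
                        seed = seed)
  simulate_library(cfg)
}

# build a hits data.frame in the shape returned by best_match()
make_hits <- function(species, identity = NULL) {
  n <- length(species)
  if (is.null(identity)) identity <- rep(0.99, n)
  if (n == 0) identity <- numeric(0)
  data.frame(subject_id = sprintf("s%d", seq_len(n)),
             subject_species = species,
             subject_genus = sub("S.*$", "", species),
             identity = identity, coverage = rep(1, n),
             score = identity,
             best = if (n) identity >= max(identity) - 1e-9 else logical(0),
             stringsAsFactors = FALSE)
}
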