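#' Kimura 2-parameter distance between two aligned rows
#'
#' Sites where either row carries a gap or a non-ACGT symbol are excluded
#' (pairwise deletion). With transition proportion P and transversion
#' proportion Q over the compared sites, the distance is
#' \deqn{d = -\tfrac{1}{2}\,\ln\bigl[(1 - 2P - Q)\sqrt{1 - 2Q}\bigr].}
#' The distance is undefined (masked, not clamped) when no sites can be
#' compared or when either logarithm argument is non-positive.
#'
#' @param row_i,row_j equal-length gapped sequence strings.
#' @return list with `distance`, `P`, `Q`, `n_sites`, `defined`, and
#'   `reason` (`NA` when defined; `"no_sites"` or `"saturated"`).
#' @examples
#' k2p("ACGT", "ACGT") # d = 0
#' k2p("A-GT", "AC-T") # compared on 2 sites only
#' @export
k2p <- function(row_i, row_j) {
  a <- encode_seq(row_i)
  b <- encode_seq(row_j)
  if (length(a) != length(b)) stop("rows must have equal length")
  ok <- a > 0 & b > 0
  n <- sum(ok)
  if (n == 0)
    return(list(distance = NA_real_, P = NA_real_, Q = NA_real_,
                n_sites = 0L, defined = FALSE, reason = "no_sites"))
  x <- a[ok]; y <- b[ok]
  diff <- x != y
  purine_x <- x == 1L | x == 3L
  purine_y <- y == 1L | y == 3L
  ts <- sum(diff & (purine_x == purine_y))
  tv <- sum(diff & (purine_x != purine_y))
  k2p_from_counts(ts, tv, n)
}

k2p_from_counts <- function(ts, tv, n) {
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(distance = NA_real_, P = P, Q = Q, n_sites = as.integer(n),
                defined = FALSE, reason = "saturated"))
  list(distance = -0.5 * log(w1 * sqrt(w2)), P = P, Q = Q,
       n_sites = as.integer(n), defined = TRUE, reason = NA_character_)
}

#' K2P distance matrix with pairwise deletion
#'
#' Computes the K2P distance for every pair of alignment rows. Undefined
#' entries (no comparable sites, or saturation making a logarithm argument
#' non-positive) are `NA` in the matrix and listed with a reason in
#' `$masked`.
#'
#' @param alignment a `barcode_alignment`.
#' @return object of class `k2p_dist`: list with `ids`, `d` (symmetric
#'   matrix, `NA` where undefined), `P`, `Q`, `n_sites` (per-pair
#'   proportions/counts), and `masked` (data.frame `id_i`, `id_j`,
#'   `reason`).
#' @export
distance_matrix <- function(alignment) {
  codes <- alignment_codes(alignment)
  n <- nrow(codes)
  cnt <- k2p_counts_cpp(codes)
  ns <- cnt$n_sites
  P <- ifelse(ns > 0, cnt$transitions / ns, NA_real_)
  Q <- ifelse(ns > 0, cnt$transversions / ns, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- matrix(NA_real_, n, n)
  ok <- which(!is.na(w1) & w1 > 0 & w2 > 0)
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  diag(d) <- 0
  ids <- alignment$ids
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(ns) <-
    list(ids, ids)
  masked <- data.frame(id_i = character(0), id_j = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  und <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
  if (nrow(und)) {
    reason <- ifelse(ns[und] == 0, "no_sites", "saturated")
    masked <- data.frame(id_i = ids[und[, 1]], id_j = ids[und[, 2]],
                         reason = reason, stringsAsFactors = FALSE)
  }
  structure(list(ids = ids, d = d, P = P, Q = Q, n_sites = ns,
                 masked = masked),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("k2p_dist: %d sequences, %d pairs (%d undefined)\n",
              length(x$ids), choose(length(x$ids), 2), nrow(x$masked)))
  invisible(x)
}

#' Remove sequences until all pairwise distances are defined
#'
#' Greedily drops the sequence involved in the most undefined pairs until
#' none remain; the guided remedy before [nj_tree()], which rejects
#' matrices with undefined entries.
#'
#' @param dmat a `k2p_dist`.
#' @return a `k2p_dist` restricted to the retained sequences, with
#'   attribute `"dropped"` naming the removed ids.
#' @export
prune_undefined <- function(dmat) {
  d <- dmat$d
  dropped <- character(0)
  while (anyNA(d)) {
    bad <- rowSums(is.na(d))
    worst <- which.max(bad)
    dropped <- c(dropped, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  keep <- match(rownames(d), dmat$ids)
  out <- structure(list(ids = dmat$ids[keep],
                        d = d,
                        P = dmat$P[keep, keep, drop = FALSE],
                        Q = dmat$Q[keep, keep, drop = FALSE],
                        n_sites = dmat$n_sites[keep, keep, drop = FALSE],
                        masked = dmat$masked[0, ]),
                   class = "k2p_dist")
  attr(out, "dropped") <- dropped
  out
}

#' Rank-level distance summary
#'
#' Pools pairwise distances within taxa at a rank, following the nested
#' convention of barcode "distance summary" tables: `species` compares
#' conspecific pairs; `genus` compares congeneric pairs of different
#' species; `family` compares confamilial pairs of different genera.
#' Undefined (masked) distances are excluded and counted.
#'
#' @param dmat a `k2p_dist`.
#' @param taxonomy taxonomy data.frame covering all ids.
#' @param rank one of `"species"`, `"genus"`, `"family"`.
#' @return one-row data.frame: `rank`, `n_taxa` (taxa contributing at
#'   least one comparison), `n_comparisons`, `min_pct`, `max_pct`,
#'   `mean_pct` (distances in percent), `n_undefined`. Zero-row when no
#'   taxon has a comparable pair.
#' @export
summarize_rank <- function(dmat, taxonomy, rank = c("species", "genus",
                                                    "family")) {
  rank <- match.arg(rank)
  tax <- taxonomy[match(dmat$ids, taxonomy$specimen_id), ]
  if (anyNA(tax$species)) stop("taxonomy does not cover all ids")
  same <- function(v) outer(v, v, "==")
  sel <- switch(rank,
    species = same(tax$species),
    genus = same(tax$genus) & !same(tax$species),
    family = same(tax$family) & !same(tax$genus))
  sel <- sel & upper.tri(sel)
  vals <- dmat$d[sel]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    out <- data.frame(rank = character(0), n_taxa = integer(0),
                      n_comparisons = integer(0), min_pct = numeric(0),
                      max_pct = numeric(0), mean_pct = numeric(0),
                      n_undefined = integer(0))
    warning("no comparable pairs at rank ", rank)
    return(out)
  }
  group_of <- switch(rank, species = tax$species, genus = tax$genus,
                     family = tax$family)
  pair_idx <- which(sel & !is.na(dmat$d), arr.ind = TRUE)
  n_taxa <- length(unique(group_of[pair_idx[, 1]]))
  data.frame(rank = rank, n_taxa = n_taxa,
             n_comparisons = length(vals),
             min_pct = 100 * min(vals), max_pct = 100 * max(vals),
             mean_pct = 100 * mean(vals),
             n_undefined = n_undef, stringsAsFactors = FALSE)
}

#' Write a distance matrix as square TSV and lower-triangle PHYLIP text
#'
#' @param dmat a `k2p_dist`.
#' @param path_tsv,path_phylip output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_distance_matrix <- function(dmat, path_tsv = NULL,
                                  path_phylip = NULL) {
  if (!is.null(path_tsv)) {
    df <- data.frame(specimen_id = dmat$ids, dmat$d, check.names = FALSE)
    write_tsv(df, path_tsv)
  }
  if (!is.null(path_phylip)) {
    n <- length(dmat$ids)
    lines <- c(sprintf("%5d", n),
               vapply(seq_len(n), function(i) {
                 vals <- if (i > 1)
                   paste(sprintf("%.6f", dmat$d[i, seq_len(i - 1)]),
                         collapse = " ")
                 else ""
                 trimws(paste(sprintf("%-12s", dmat$ids[i]), vals),
                        which = "right")
               }, character(1)))
    writeLines(lines, path_phylip)
  }
  invisible(list(tsv = path_tsv, phylip = path_phylip))
}
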