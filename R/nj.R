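#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q-criterion \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}, with branch
#' lengths from the two-point formulas; the final three nodes are joined
#' by the three-point formulas. Ties in the Q-criterion break to the
#' lowest (row, column) index pair, so the result is deterministic.
#' Negative branch lengths are clamped to zero. Matrices with undefined
#' entries are rejected with the offending pairs listed; prune them first
#' with [prune_undefined()].
#'
#' @param dmat a `k2p_dist` object, or a symmetric numeric matrix with
#'   dimnames.
#' @return an unrooted [ape] `phylo` tree over the sequence ids.
#' @examples
#' m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- nj_tree(m)
#' tr$edge.length # 0.05, 0.15, 0.25
#' @export
nj_tree <- function(dmat) {
  d <- if (inherits(dmat, "k2p_dist")) dmat$d else dmat
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 taxa for a neighbor-joining tree")
  if (anyNA(d)) {
    bad <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
    stop("distance matrix has undefined entries; prune these pairs first: ",
         paste(sprintf("%s-%s", ids[bad[, 1]], ids[bad[, 2]])[
           seq_len(min(10, nrow(bad)))], collapse = ", "))
  }

  # active nodes carry their phylo node number; tips 1..n,
  # internals n+1 .. 2n-2 allocated as joins happen
  node_of <- seq_len(n)
  next_internal <- n + 1L
  n_internal_total <- n - 2L
  edges <- matrix(0L, nrow = 2L * n - 3L, ncol = 2)
  elen <- numeric(2L * n - 3L)
  n_edge <- 0L
  add_edge <- function(parent, child, len) {
    n_edge <<- n_edge + 1L
    edges[n_edge, ] <<- c(parent, child)
    elen[n_edge] <<- max(0, len)
  }

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    # first minimum in row-major order over i < j gives the lowest
    # (row, col) pair
    flat <- which(t(q) == min(q))
    ij <- arrayInd(flat[1], c(m, m))
    i <- ij[2]; j <- ij[1]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    u <- next_internal
    next_internal <- next_internal + 1L
    add_edge(u, node_of[i], bi)
    add_edge(u, node_of[j], bj)
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    node_of <- c(node_of[keep], u)
    d <- d_new
  }

  # final trifurcation by the three-point formulas
  a <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  b <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  c3 <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  u <- next_internal
  add_edge(u, node_of[1], a)
  add_edge(u, node_of[2], b)
  add_edge(u, node_of[3], c3)

  edges <- edges[seq_len(n_edge), , drop = FALSE]
  elen <- elen[seq_len(n_edge)]
  # renumber internals so the root (last created) is n+1, per phylo
  # convention internal numbering is arbitrary but root-first reading
  # order is tidier
  relab <- integer(2L * n)
  relab[seq_len(n)] <- seq_len(n)
  internals <- (n + 1L):(n + n_internal_total)
  relab[internals] <- n + 1L + (n + n_internal_total) - internals
  edges[] <- relab[edges]
  tree <- structure(list(edge = edges, edge.length = elen,
                         tip.label = ids,
                         Nnode = n_internal_total),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Bootstrap support for the edges of the full-data NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' matrix and NJ tree per replicate, and scores every internal edge of
#' the full-data tree by the percentage of replicates containing the same
#' leaf bipartition. Replicate matrices with undefined entries have those
#' entries imputed with the replicate's maximum defined distance (the
#' full-data tree itself never imputes).
#'
#' @param alignment a `barcode_alignment`.
#' @param tree the full-data tree from [nj_tree()] on this alignment.
#' @param B number of replicates (>= 1).
#' @param seed seed for the resampling stream.
#' @return the tree with `node.label` set to the support (%) of the edge
#'   above each internal node (root label empty), plus attribute
#'   `"support"`, a data.frame of bipartitions and supports.
#' @export
bootstrap_support <- function(alignment, tree, B = 100, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  codes <- alignment_codes(alignment)
  full_bip <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(full_bip)), names(full_bip))
  L <- ncol(codes)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_codes <- codes[, cols, drop = FALSE]
    cnt <- k2p_counts_cpp(rep_codes)
    ns <- cnt$n_sites
    P <- ifelse(ns > 0, cnt$transitions / ns, NA_real_)
    Q <- ifelse(ns > 0, cnt$transversions / ns, NA_real_)
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    d <- matrix(NA_real_, nrow(ns), ncol(ns))
    ok <- which(!is.na(w1) & w1 > 0 & w2 > 0)
    d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
    diag(d) <- 0
    if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
    dimnames(d) <- list(alignment$ids, alignment$ids)
    rep_tree <- nj_tree(d)
    rep_bip <- names(tree_bipartitions(rep_tree))
    present <- names(full_bip) %in% rep_bip
    hits[present] <- hits[present] + 1
  }
  support <- 100 * hits / B
  df <- data.frame(bipartition = names(full_bip),
                   node = unname(full_bip),
                   support = unname(support),
                   stringsAsFactors = FALSE)
  labs <- rep("", tree$Nnode)
  labs[df$node - length(tree$tip.label)] <-
    formatC(df$support, format = "f", digits = 0)
  tree$node.label <- labs
  attr(tree, "support") <- df
  tree
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# for each internal edge, the tip set of the side NOT containing the
# first tip, sorted and pasted. Returns named integer vector mapping
# key -> child node of the edge.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  clades <- clade_tips(tree)
  keys <- character(0); nodes <- integer(0)
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- clades[[node]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next # trivial
    side <- if (1L %in% tips) setdiff(seq_len(n), tips) else tips
    keys <- c(keys, paste(sort(tree$tip.label[side]), collapse = "|"))
    nodes <- c(nodes, node)
  }
  setNames(nodes, keys)
}

# tip indices descending from every node (tips map to themselves)
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  out <- vector("list", total)
  for (i in seq_len(n)) out[[i]] <- i
  # postorder: children before parents
  edge_po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge_po))) {
    p <- edge_po[e, 1]; ch <- edge_po[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Species discrimination on a tree
#'
#' A species is identified when its specimens form an exclusive cluster:
#' some edge of the unrooted tree separates exactly that species' leaves
#' from everything else (monophyly). Singleton species are excluded from
#' the discrimination denominator. Remaining leaves are grouped into
#' mixed clusters: maximal clades composed entirely of unidentified
#' species' leaves (the cluster-count convention is reported for
#' completeness; only the identified count and rate are comparable across
#' tools).
#'
#' @param tree a `phylo` over the library specimens.
#' @param taxonomy taxonomy covering the tree's tips.
#' @return list with `report` (class `cluster_report`: `n_clusters`,
#'   `n_single_species_clusters`, `n_species_identified`,
#'   `n_species_unidentified`, `n_singletons`, `discrimination_rate`) and
#'   `per_species` (data.frame `species`, `n`, `status`:
#'   identified/unidentified/singleton).
#' @export
species_clusters <- function(tree, taxonomy) {
  n <- length(tree$tip.label)
  tax <- taxonomy[match(tree$tip.label, taxonomy$specimen_id), ]
  if (anyNA(tax$species)) stop("taxonomy does not cover all tree tips")
  species <- sort(unique(tax$species))
  leaf_sets <- lapply(setNames(species, species),
                      function(sp) which(tax$species == sp))

  clades <- clade_tips(tree)
  all_sides <- lapply(clades[(n + 1L):(n + tree$Nnode)], sort)
  side_keys <- vapply(all_sides, paste, character(1), collapse = ",")
  comp_keys <- vapply(all_sides, function(s)
    paste(setdiff(seq_len(n), s), collapse = ","), character(1))
  # leaf edges isolate single tips, so their complements are also sides
  tip_comp_keys <- vapply(seq_len(n), function(t)
    paste(setdiff(seq_len(n), t), collapse = ","), character(1))

  status <- vapply(species, function(sp) {
    ls <- leaf_sets[[sp]]
    if (length(ls) == 1) return("singleton")
    key <- paste(ls, collapse = ",")
    if (key %in% side_keys || key %in% comp_keys ||
        key %in% tip_comp_keys) "identified"
    else "unidentified"
  }, character(1))

  per_species <- data.frame(
    species = species,
    n = vapply(leaf_sets, length, integer(1)),
    status = status, stringsAsFactors = FALSE)
  rownames(per_species) <- NULL

  n_singleton <- sum(status == "singleton")
  n_ident <- sum(status == "identified")
  n_unident <- sum(status == "unidentified")

  # mixed clusters: maximal clades whose tips all belong to unidentified,
  # non-singleton species
  unident_tips <- which(tax$species %in% species[status == "unidentified"])
  in_pool <- seq_len(n) %in% unident_tips
  mixed <- 0L
  covered <- rep(FALSE, n)
  # scan clades from largest to smallest; a maximal all-pool clade not
  # inside an already-taken one forms one mixed cluster
  ord <- order(vapply(all_sides, length, integer(1)), decreasing = TRUE)
  for (k in ord) {
    tips <- all_sides[[k]]
    if (all(in_pool[tips]) && !any(covered[tips])) {
      mixed <- mixed + 1L
      covered[tips] <- TRUE
    }
  }
  # pool tips not inside any all-pool clade count singly
  mixed <- mixed + sum(in_pool & !covered)

  report <- structure(list(
    n_clusters = n_ident + mixed + n_singleton,
    n_single_species_clusters = n_ident,
    n_species_identified = n_ident,
    n_species_unidentified = n_unident,
    n_singletons = n_singleton,
    discrimination_rate = if (n_ident + n_unident > 0)
      n_ident / (n_ident + n_unident) else NA_real_),
    class = "cluster_report")
  list(report = report, per_species = per_species)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("clusters: %d (%d single-species)\n",
              x$n_clusters, x$n_single_species_clusters))
  cat(sprintf("species identified: %d / %d (%.2f%%); %d singletons excluded\n",
              x$n_species_identified,
              x$n_species_identified + x$n_species_unidentified,
              100 * x$discrimination_rate, x$n_singletons))
  invisible(x)
}
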