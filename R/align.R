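# Progressive multiple alignment: 6-mer guide distances, UPGMA guide tree,
# profile-profile Needleman-Wunsch merges (match +1, mismatch -1, gap open
# -2, extend -0.5). Deterministic: hclust merge order and the C++
# traceback tie preference are fixed.

ALN_MATCH <- 1
ALN_MISMATCH <- -1
ALN_GAP_OPEN <- 2   # cost of the first gap column (positive)
ALN_GAP_EXT <- 0.5  # cost of each further gap column

kmer_counts <- function(codes, k = 6L) {
  L <- length(codes)
  if (L < k) return(integer(0))
  valid <- codes > 0
  # rolling base-4 encoding of each k-mer; windows with ambiguity dropped
  idx <- seq_len(L - k + 1L)
  km <- integer(length(idx))
  ok <- rep(TRUE, length(idx))
  for (p in seq_len(k)) {
    c_p <- codes[idx + p - 1L]
    ok <- ok & c_p > 0
    km <- km * 4L + (c_p - 1L)
  }
  km[ok]
}

# 1 - fraction of shared 6-mers (with multiplicity), relative to the
# shorter sequence's k-mer count
kmer_distance_matrix <- function(code_list, k = 6L) {
  n <- length(code_list)
  tabs <- lapply(code_list, function(x) table(kmer_counts(x, k)))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- tabs[[i]]; tj <- tabs[[j]]
      shared <- intersect(names(ti), names(tj))
      common <- sum(pmin(ti[shared], tj[shared]))
      denom <- max(1L, min(sum(ti), sum(tj)))
      d[i, j] <- d[j, i] <- 1 - common / denom
    }
  }
  d
}

# profile = list(ids, rows): rows is a character matrix (n_seq x n_col)
profile_from_seq <- function(id, s) {
  list(ids = id, rows = matrix(seq_chars(s), nrow = 1))
}

# fraction of each base (A,C,G,T) per column, plus non-gap weight
profile_freqs <- function(prof) {
  n <- nrow(prof$rows)
  f <- vapply(c("A", "C", "G", "T"),
              function(b) colSums(prof$rows == b) / n,
              numeric(ncol(prof$rows)))
  if (ncol(prof$rows) == 1) f <- matrix(f, nrow = 1)
  t(f) # 4 x n_col
}

merge_profiles <- function(pa, pb) {
  fa <- profile_freqs(pa)
  fb <- profile_freqs(pb)
  wa <- colSums(fa)
  wb <- colSums(fb)
  # expected pairwise column score: +1 on matches, -1 on mismatches
  # = 2 * sum_x fa_x fb_x - wa * wb
  S <- 2 * crossprod(fa, fb) - outer(wa, wb)
  path <- profile_nw_cpp(S, ALN_GAP_OPEN, ALN_GAP_EXT)
  na <- nrow(pa$rows); nb <- nrow(pb$rows)
  L <- length(path$path_a)
  rows <- matrix("-", nrow = na + nb, ncol = L)
  ia <- path$path_a > 0
  ib <- path$path_b > 0
  rows[seq_len(na), ia] <- pa$rows[, path$path_a[ia], drop = FALSE]
  rows[na + seq_len(nb), ib] <- pb$rows[, path$path_b[ib], drop = FALSE]
  list(ids = c(pa$ids, pb$ids), rows = rows)
}

#' Progressive multiple sequence alignment
#'
#' Aligns barcode sequences by sequential profile-profile merges along a
#' UPGMA guide tree built from fractional-common-6-mer distances. Scoring:
#' match +1, mismatch -1, gap open -2, gap extend -0.5; ties in the
#' dynamic program resolve deterministically. Intended as a convenience
#' for desk-scale libraries; externally aligned FASTA can be supplied to
#' downstream steps instead via [as_alignment()].
#'
#' @param records data.frame with `specimen_id`, `sequence` (>= 1 row).
#' @return object of class `barcode_alignment`: list with `ids` and
#'   `seqs` (equal-length gapped strings, in input order).
#' @export
progressive_align <- function(records) {
  n <- nrow(records)
  if (n < 1) stop("no records to align")
  if (n == 1)
    return(new_alignment(records$specimen_id, records$sequence))
  profs <- mapply(profile_from_seq, records$specimen_id, records$sequence,
                  SIMPLIFY = FALSE)
  if (n == 2) {
    merged <- merge_profiles(profs[[1]], profs[[2]])
  } else {
    codes <- lapply(records$sequence, encode_seq)
    d <- kmer_distance_matrix(codes)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    nodes <- vector("list", n - 1)
    for (m in seq_len(n - 1)) {
      pick <- function(x) if (x < 0) profs[[-x]] else nodes[[x]]
      nodes[[m]] <- merge_profiles(pick(hc$merge[m, 1]),
                                   pick(hc$merge[m, 2]))
    }
    merged <- nodes[[n - 1]]
  }
  ord <- match(records$specimen_id, merged$ids)
  seqs <- apply(merged$rows[ord, , drop = FALSE], 1, paste, collapse = "")
  new_alignment(records$specimen_id, seqs)
}

new_alignment <- function(ids, seqs) {
  if (anyDuplicated(ids)) stop("alignment ids must be unique")
  if (length(unique(nchar(seqs))) > 1)
    stop("alignment rows must have equal length")
  structure(list(ids = ids, seqs = unname(seqs)),
            class = "barcode_alignment")
}

#' Construct an alignment object from pre-aligned sequences
#'
#' @param records data.frame with `specimen_id` and equal-length gapped
#'   `sequence` strings (e.g. read from an externally aligned FASTA).
#' @return a `barcode_alignment`.
#' @export
as_alignment <- function(records) {
  new_alignment(records$specimen_id, records$sequence)
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d sequences x %d columns\n",
              length(x$ids), nchar(x$seqs[1])))
  invisible(x)
}

# integer-coded matrix (n x L) of an alignment; gaps/ambiguity -> 0
alignment_codes <- function(aln) {
  do.call(rbind, lapply(aln$seqs, encode_seq))
}
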