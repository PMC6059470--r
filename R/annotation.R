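#' Build a position-weight motif profile
#'
#' Column-wise nucleotide frequencies of one or more equal-length motif
#' instances, with a pseudocount added to every cell before normalization
#' so that log-odds scores stay finite. The profile stands in for a full
#' profile HMM: the 5.8S tail and 28S head flanking the ITS2 are conserved
#' and nearly gap-free, so a PWM log-odds scan recovers the same
#' boundaries deterministically.
#'
#' @param motifs character vector of equal-length A/C/G/T strings.
#' @param pseudocount value added to each cell (default 0.5).
#' @param min_score_frac score threshold for [trim_its2()], as a fraction
#'   of the profile's maximum attainable score (default 0.6).
#' @return object of class `motif_profile`: list with `freq` (4 x width
#'   matrix, rows A,C,G,T, columns summing to 1), `min_score`, `width`.
#' @examples
#' p <- build_profile("ACGT", pseudocount = 0)
#' scan_profile("TTACGTTT", p) # offset 2 (0-based), score 4 * log(4)
#' @export
build_profile <- function(motifs, pseudocount = 0.5, min_score_frac = 0.6) {
  w <- unique(nchar(motifs))
  if (length(w) != 1 || w == 0)
    stop("motifs must be non-empty and of equal length")
  counts <- matrix(pseudocount, nrow = 4, ncol = w,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (m in motifs) {
    codes <- encode_seq(m)
    if (any(codes == 0)) stop("motifs must contain only A/C/G/T")
    for (i in seq_len(w)) counts[codes[i], i] <- counts[codes[i], i] + 1
  }
  freq <- sweep(counts, 2, colSums(counts), "/")
  max_score <- sum(log(apply(freq, 2, max) / 0.25))
  structure(list(freq = freq, width = w,
                 min_score = min_score_frac * max_score,
                 max_score = max_score),
            class = "motif_profile")
}

#' Scan a sequence for the best profile hit
#'
#' Scores every offset by the summed per-position log-odds
#' `log(freq / 0.25)` (uniform background) and returns the maximum; ties
#' resolve to the smallest offset. Positions with a non-ACGT symbol
#' contribute the background log-odds 0.
#'
#' @param seq nucleotide string.
#' @param profile a [build_profile()] object.
#' @return list with `offset` (0-based start of the best hit, or `NA` if
#'   the sequence is shorter than the profile) and `score`.
#' @export
scan_profile <- function(seq, profile) {
  codes <- encode_seq(seq)
  w <- profile$width
  L <- length(codes)
  if (L < w) return(list(offset = NA_integer_, score = -Inf))
  lo <- log(profile$freq / 0.25) # 4 x w log-odds
  n_off <- L - w + 1L
  scores <- numeric(n_off)
  for (p in seq_len(w)) {
    col <- codes[p:(p + n_off - 1L)]
    contrib <- numeric(n_off)
    ok <- col > 0
    contrib[ok] <- lo[col[ok] + (p - 1L) * 4L]
    scores <- scores + contrib
  }
  best <- which.max(scores) # which.max takes the first maximum: smallest offset
  list(offset = best - 1L, score = scores[best])
}

#' Trim an amplicon to the ITS2 region
#'
#' Locates the conserved 5.8S tail and 28S head motifs by profile scan and
#' extracts the subsequence strictly between the end of the 5' hit and the
#' start of the 3' hit. Coordinates are 0-based half-open throughout.
#'
#' @param sequence amplicon string.
#' @param p5,p3 [build_profile()] objects for the 5' and 3' motifs.
#' @return list with `status` (`"ok"`, `"flank_not_found"`,
#'   `"out_of_order"`, `"empty_its2"`), `its2` (string or `NA`), `start`,
#'   `end` (ITS2 span in the amplicon), `score5`, `score3`.
#' @export
trim_its2 <- function(sequence, p5, p3) {
  fail <- function(status, s5 = NA_real_, s3 = NA_real_)
    list(status = status, its2 = NA_character_,
         start = NA_integer_, end = NA_integer_,
         score5 = s5, score3 = s3)
  h5 <- scan_profile(sequence, p5)
  h3 <- scan_profile(sequence, p3)
  if (is.na(h5$offset) || is.na(h3$offset) ||
      h5$score < p5$min_score || h3$score < p3$min_score)
    return(fail("flank_not_found", h5$score, h3$score))
  start <- h5$offset + p5$width # end of the 5' motif
  end <- h3$offset              # start of the 3' motif
  if (end < start) return(fail("out_of_order", h5$score, h3$score))
  if (end == start) return(fail("empty_its2", h5$score, h3$score))
  list(status = "ok",
       its2 = substr(sequence, start + 1L, end),
       start = start, end = end,
       score5 = h5$score, score3 = h3$score)
}

#' Annotate a set of amplicons to the ITS2
#'
#' Applies [trim_its2()] to every record. With `trim = FALSE` the input is
#' passed through unchanged (for pre-trimmed libraries).
#'
#' @param records data.frame with `specimen_id`, `sequence`.
#' @param p5,p3 motif profiles; defaults built from the config motifs.
#' @param config [library_config()] supplying default motifs.
#' @param trim set `FALSE` to pass pre-trimmed sequences through.
#' @return list with `records` (successfully trimmed records) and `report`
#'   (data.frame `specimen_id`, `start`, `end`, `score5`, `score3`,
#'   `status` for all inputs).
#' @export
annotate_library <- function(records, p5 = NULL, p3 = NULL,
                             config = library_config(), trim = TRUE) {
  if (!trim) {
    report <- data.frame(specimen_id = records$specimen_id,
                         start = 0L, end = nchar(records$sequence),
                         score5 = NA_real_, score3 = NA_real_,
                         status = "passthrough", stringsAsFactors = FALSE)
    return(list(records = records, report = report))
  }
  if (is.null(p5)) p5 <- build_profile(config$flank_5p)
  if (is.null(p3)) p3 <- build_profile(config$flank_3p)
  res <- lapply(records$sequence, trim_its2, p5 = p5, p3 = p3)
  report <- data.frame(
    specimen_id = records$specimen_id,
    start = vapply(res, function(x) as.integer(x$start), integer(1)),
    end = vapply(res, function(x) as.integer(x$end), integer(1)),
    score5 = vapply(res, function(x) as.numeric(x$score5), numeric(1)),
    score3 = vapply(res, function(x) as.numeric(x$score3), numeric(1)),
    status = vapply(res, function(x) x$status, character(1)),
    stringsAsFactors = FALSE)
  ok <- report$status == "ok"
  trimmed <- data.frame(
    specimen_id = records$specimen_id[ok],
    sequence = vapply(res[ok], function(x) x$its2, character(1)),
    stringsAsFactors = FALSE)
  list(records = trimmed, report = report)
}

#' Per-sequence and per-group composition statistics
#'
#' Length is the count of non-gap characters; GC is (G+C)/(A+C+G+T), with
#' gaps and ambiguity codes excluded from the denominator. Group summaries
#' report median and interquartile range; quantiles use linear
#' interpolation (R type 7).
#'
#' @param records data.frame with `specimen_id`, `sequence`.
#' @param groups optional vector of group labels (one per record).
#' @return list with `per_record` (length, GC, base fractions) and
#'   `by_group` (n, median/quartiles of length and GC) data.frames. Empty
#'   sequences are excluded with a warning.
#' @export
seq_stats <- function(records, groups = NULL) {
  if (nrow(records) == 0) stop("no records")
  counts <- t(vapply(records$sequence, function(s) {
    codes <- encode_seq(s)
    c(A = sum(codes == 1), C = sum(codes == 2),
      G = sum(codes == 3), T = sum(codes == 4),
      len = sum(seq_chars(s) != "-"))
  }, c(A = 0, C = 0, G = 0, T = 0, len = 0), USE.NAMES = FALSE))
  colnames(counts) <- c("A", "C", "G", "T", "len")
  acgt <- rowSums(counts[, 1:4, drop = FALSE])
  empty <- counts[, "len"] == 0
  if (any(empty)) {
    warning(sum(empty), " empty sequence(s) excluded from statistics")
    counts <- counts[!empty, , drop = FALSE]
    acgt <- acgt[!empty]
    records <- records[!empty, , drop = FALSE]
    if (!is.null(groups)) groups <- groups[!empty]
  }
  per_record <- data.frame(
    specimen_id = records$specimen_id,
    length = as.integer(counts[, "len"]),
    gc = (counts[, "G"] + counts[, "C"]) / acgt,
    frac_A = counts[, "A"] / acgt, frac_C = counts[, "C"] / acgt,
    frac_G = counts[, "G"] / acgt, frac_T = counts[, "T"] / acgt,
    stringsAsFactors = FALSE)
  rownames(per_record) <- NULL
  if (is.null(groups)) groups <- rep("all", nrow(per_record))
  summ <- function(x) c(median = median(x),
                        q25 = unname(quantile(x, 0.25, type = 7)),
                        q75 = unname(quantile(x, 0.75, type = 7)),
                        mean = mean(x))
  by_group <- do.call(rbind, lapply(split(seq_len(nrow(per_record)), groups),
    function(idx) {
      sl <- summ(per_record$length[idx])
      sg <- summ(per_record$gc[idx])
      data.frame(group = groups[idx[1]], n = length(idx),
                 median_length = sl["median"], q25_length = sl["q25"],
                 q75_length = sl["q75"], mean_length = sl["mean"],
                 median_gc = sg["median"], q25_gc = sg["q25"],
                 q75_gc = sg["q75"], mean_gc = sg["mean"],
                 stringsAsFactors = FALSE)
    }))
  rownames(by_group) <- NULL
  list(per_record = per_record, by_group = by_group)
}

#' Write a motif profile to a column-frequency text file
#'
#' @param profile a [build_profile()] object.
#' @param path output TSV (columns `pos`, `A`, `C`, `G`, `T`).
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(pos = seq_len(profile$width), t(profile$freq))
  write_tsv(df, path)
}

#' Read a motif profile from a column-frequency text file
#'
#' @param path TSV written by [write_profile()].
#' @param min_score_frac threshold fraction as in [build_profile()].
#' @return a `motif_profile` object.
#' @export
read_profile <- function(path, min_score_frac = 0.6) {
  df <- read.table(path, header = TRUE, sep = "\t")
  freq <- t(as.matrix(df[, c("A", "C", "G", "T")]))
  dimnames(freq) <- list(c("A", "C", "G", "T"), NULL)
  max_score <- sum(log(apply(freq, 2, max) / 0.25))
  structure(list(freq = freq, width = ncol(freq),
                 min_score = min_score_frac * max_score,
                 max_score = max_score),
            class = "motif_profile")
}
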