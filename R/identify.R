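#' Best-match search of a query against a reference library
#'
#' Globally aligns the query against every library sequence (same scoring
#' as [progressive_align()]: match +1, mismatch -1, gap open -2, extend
#' -0.5) and ranks hits by identity, computed as matches over aligned
#' columns with end gaps excluded (semi-global convention, mimicking
#' local-alignment identity on full-length barcodes). Hits must clear
#' `min_identity` and `min_coverage` (fraction of the query inside the
#' aligned span). The best-hit set contains every hit within 1e-9 of the
#' top identity, so exact ties are returned together.
#'
#' @param query list or one-row data.frame with `specimen_id`, `sequence`.
#' @param library records data.frame (the reference library).
#' @param taxonomy taxonomy covering the library ids.
#' @param min_identity,min_coverage hit filters (defaults 0.97 / 0.95,
#'   the cutoffs observed for correctly identified ITS2 barcodes).
#' @param leave_one_out drop library records with the query's own
#'   `specimen_id` before searching.
#' @return data.frame of hits sorted by decreasing identity
#'   (`subject_id`, `subject_species`, `subject_genus`, `identity`,
#'   `coverage`, `score`, `best` flag); zero rows when nothing clears the
#'   thresholds.
#' @export
best_match <- function(query, library, taxonomy,
                       min_identity = 0.97, min_coverage = 0.95,
                       leave_one_out = TRUE) {
  if (nrow(library) == 0) stop("reference library is empty")
  if (leave_one_out)
    library <- library[library$specimen_id != query$specimen_id, ,
                       drop = FALSE]
  if (nrow(library) == 0) stop("library empty after leave-one-out")
  tax <- taxonomy[match(library$specimen_id, taxonomy$specimen_id), ]
  q <- encode_seq(gsub("-", "", query$sequence, fixed = TRUE))
  qlen <- length(q)
  stats <- lapply(library$sequence, function(s) {
    pair_align_stats_cpp(q, encode_seq(gsub("-", "", s, fixed = TRUE)),
                         ALN_MATCH, ALN_MISMATCH,
                         ALN_GAP_OPEN, ALN_GAP_EXT)
  })
  identity <- vapply(stats, function(x)
    if (x$aligned_cols > 0) x$matches / x$aligned_cols else 0, numeric(1))
  coverage <- vapply(stats, function(x) x$a_span / qlen, numeric(1))
  score <- vapply(stats, function(x) x$score, numeric(1))
  hits <- data.frame(subject_id = library$specimen_id,
                     subject_species = tax$species,
                     subject_genus = tax$genus,
                     identity = identity, coverage = coverage,
                     score = score, stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity &
               hits$coverage >= min_coverage, , drop = FALSE]
  if (nrow(hits) == 0) {
    hits$best <- logical(0)
    return(hits)
  }
  hits <- hits[order(-hits$identity, hits$subject_id), , drop = FALSE]
  hits$best <- hits$identity >= hits$identity[1] - 1e-9
  rownames(hits) <- NULL
  hits
}

#' Three-way identification call from a best-hit set
#'
#' Identification is correct when every top hit is conspecific with the
#' query, ambiguous when the top hits mix conspecific and heterospecific
#' labels, and incorrect when no top hit is conspecific. The genus call
#' applies the same rule to the genus labels of the best-hit set. When the
#' true species is unknown the lexicographically first top label stands in
#' and the result is marked unsupervised.
#'
#' @param true_species true species label (or `NA`).
#' @param hits data.frame from [best_match()].
#' @param true_genus true genus label (or `NA`); defaults to the genus of
#'   conspecific hits when resolvable.
#' @return list: `species_call`, `genus_call` (each
#'   `"correct"|"ambiguous"|"incorrect"|"no_hit"`), `unsupervised` flag,
#'   `best_species` (labels of the best-hit set), `top_identity`.
#' @export
classify <- function(true_species, hits, true_genus = NA_character_) {
  if (nrow(hits) == 0)
    return(list(species_call = "no_hit", genus_call = "no_hit",
                unsupervised = FALSE, best_species = character(0),
                top_identity = NA_real_))
  best <- hits[hits$best, , drop = FALSE]
  sp_labels <- unique(best$subject_species)
  gn_labels <- unique(best$subject_genus)
  unsupervised <- is.na(true_species)
  if (unsupervised) true_species <- sort(sp_labels)[1]
  if (is.na(true_genus)) true_genus <- best$subject_genus[
    match(true_species, best$subject_species)]
  three_way <- function(truth, labels) {
    if (is.na(truth)) return("incorrect")
    if (all(labels == truth)) "correct"
    else if (truth %in% labels) "ambiguous"
    else "incorrect"
  }
  list(species_call = three_way(true_species, sp_labels),
       genus_call = three_way(true_genus, gn_labels),
       unsupervised = unsupervised,
       best_species = sp_labels,
       top_identity = best$identity[1])
}

#' Leave-one-out identification of a whole library
#'
#' Runs [best_match()] + [classify()] for every sequence, removing the
#' query itself from the reference. Queries whose species has no other
#' representative in the library mirror novel barcodes: they are excluded
#' from species-level statistics but kept at the genus level when the top
#' identity exceeds `genus_admit_identity`.
#'
#' @param records library records.
#' @param taxonomy taxonomy covering the records.
#' @param min_identity,min_coverage hit filters, see [best_match()].
#' @param genus_admit_identity identity above which a query without
#'   conspecific references still counts at the genus level (default
#'   0.95).
#' @return data.frame with one row per query: `query_id`, `true_species`,
#'   `species_call`, `genus_call`, `best_species` (comma-joined),
#'   `top_identity`, `n_best`, `species_evaluable`, `genus_evaluable`.
#' @export
identify_library <- function(records, taxonomy,
                             min_identity = 0.97, min_coverage = 0.95,
                             genus_admit_identity = 0.95) {
  tax <- taxonomy[match(records$specimen_id, taxonomy$specimen_id), ]
  sp_counts <- table(tax$species)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    hits <- best_match(records[i, ], records, taxonomy,
                       min_identity = min_identity,
                       min_coverage = min_coverage,
                       leave_one_out = TRUE)
    cl <- classify(tax$species[i], hits, tax$genus[i])
    has_conspecific_ref <- sp_counts[tax$species[i]] > 1
    data.frame(query_id = records$specimen_id[i],
               true_species = tax$species[i],
               species_call = cl$species_call,
               genus_call = cl$genus_call,
               best_species = paste(cl$best_species, collapse = ","),
               top_identity = cl$top_identity,
               n_best = length(cl$best_species),
               species_evaluable = as.logical(has_conspecific_ref),
               genus_evaluable = has_conspecific_ref ||
                 (!is.na(cl$top_identity) &&
                  cl$top_identity > genus_admit_identity),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identification success rates
#'
#' Percentages of correct, ambiguous and incorrect calls over the
#' evaluable, classified queries at the chosen level (no-hit queries are
#' reported separately in the denominator columns).
#'
#' @param results data.frame from [identify_library()].
#' @param level `"species"` or `"genus"`.
#' @return one-row data.frame: `level`, `n_evaluated`, `n_no_hit`,
#'   `correct_pct`, `ambiguous_pct`, `incorrect_pct`.
#' @export
success_rates <- function(results, level = c("species", "genus")) {
  level <- match.arg(level)
  if (nrow(results) == 0) stop("no identification results")
  keep <- if (level == "species") results$species_evaluable
          else results$genus_evaluable
  calls <- if (level == "species") results$species_call[keep]
           else results$genus_call[keep]
  n_no_hit <- sum(calls == "no_hit")
  calls <- calls[calls != "no_hit"]
  if (!length(calls)) stop("no classified queries at level ", level)
  pct <- function(what) 100 * mean(calls == what)
  data.frame(level = level, n_evaluated = length(calls),
             n_no_hit = n_no_hit,
             correct_pct = pct("correct"),
             ambiguous_pct = pct("ambiguous"),
             incorrect_pct = pct("incorrect"),
             stringsAsFactors = FALSE)
}

#' Conspecific consistency and cryptic-diversity candidates
#'
#' Compares the best-match species sets of conspecific queries. A species
#' is `consistent` when all its queries return the same best-match set,
#' a `cryptic_candidate` when two queries return disjoint sets (different
#' best-match species for different individuals, the signature of hidden
#' lineage structure or mislabeling), and `inconsistent_ambiguous` when
#' the sets differ but overlap.
#'
#' @param results data.frame from [identify_library()].
#' @return data.frame `species`, `n_queries`, `status`; species with a
#'   single classified query are `single_query`.
#' @export
conspecific_consistency <- function(results) {
  res <- results[results$species_call != "no_hit", , drop = FALSE]
  sets <- lapply(strsplit(res$best_species, ",", fixed = TRUE), unique)
  rows <- lapply(split(seq_len(nrow(res)), res$true_species), function(idx) {
    sp <- res$true_species[idx[1]]
    if (length(idx) < 2)
      return(data.frame(species = sp, n_queries = length(idx),
                        status = "single_query", stringsAsFactors = FALSE))
    ss <- sets[idx]
    disjoint <- FALSE; differ <- FALSE
    for (i in seq_along(ss)[-length(ss)]) {
      for (j in (i + 1):length(ss)) {
        if (!setequal(ss[[i]], ss[[j]])) differ <- TRUE
        if (length(intersect(ss[[i]], ss[[j]])) == 0) disjoint <- TRUE
      }
    }
    status <- if (disjoint) "cryptic_candidate"
              else if (differ) "inconsistent_ambiguous"
              else "consistent"
    data.frame(species = sp, n_queries = length(idx), status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
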