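#' Per-species barcoding-gap table
#'
#' For every non-singleton species, compares the maximum intraspecific
#' K2P distance with the minimum distance to any sequence of another
#' species (the nearest neighbor). A species violates the barcoding gap
#' when its maximum intraspecific distance is strictly greater than the
#' minimum interspecific distance; ties are reported separately as
#' non-violations. Undefined (masked) distances are excluded from both
#' extrema; a species whose entire intraspecific set is undefined is
#' excluded with a reason.
#'
#' @param dmat a `k2p_dist`.
#' @param taxonomy taxonomy covering all ids.
#' @return data.frame with one row per evaluated species: `species`, `n`,
#'   `max_intra_pct`, `nn_species` (arg-min species, lexicographic first
#'   on ties), `min_inter_pct`, `violation`, `tie`. Attribute
#'   `"excluded"` is a data.frame of skipped species with reasons
#'   (`singleton` or `intra_undefined`). Warns when every species is a
#'   singleton.
#' @export
gap_table <- function(dmat, taxonomy) {
  tax <- taxonomy[match(dmat$ids, taxonomy$specimen_id), ]
  if (anyNA(tax$species)) stop("taxonomy does not cover all ids")
  species <- sort(unique(tax$species))
  rows <- list(); excluded <- list()
  for (sp in species) {
    in_sp <- tax$species == sp
    n_sp <- sum(in_sp)
    if (n_sp < 2) {
      excluded[[sp]] <- "singleton"
      next
    }
    intra <- dmat$d[in_sp, in_sp][upper.tri(diag(n_sp))]
    intra <- intra[!is.na(intra)]
    if (!length(intra)) {
      excluded[[sp]] <- "intra_undefined"
      next
    }
    inter <- dmat$d[in_sp, !in_sp, drop = FALSE]
    other_sp <- tax$species[!in_sp]
    ok <- !is.na(inter)
    if (!any(ok)) {
      excluded[[sp]] <- "inter_undefined"
      next
    }
    min_inter <- min(inter[ok])
    # nearest neighbor: species attaining the minimum; lexicographic
    # first on ties
    at_min <- which(ok & inter <= min_inter + 0, arr.ind = TRUE)
    nn <- sort(unique(other_sp[at_min[, 2]]))[1]
    max_intra <- max(intra)
    rows[[sp]] <- data.frame(
      species = sp, n = n_sp,
      max_intra_pct = 100 * max_intra,
      nn_species = nn,
      min_inter_pct = 100 * min_inter,
      violation = max_intra > min_inter,
      tie = max_intra == min_inter,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no species with >= 2 specimens and defined distances")
    out <- data.frame(species = character(0), n = integer(0),
                      max_intra_pct = numeric(0), nn_species = character(0),
                      min_inter_pct = numeric(0), violation = logical(0),
                      tie = logical(0))
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "excluded") <- data.frame(
    species = if (length(excluded)) names(excluded) else character(0),
    reason = if (length(excluded)) unlist(excluded, use.names = FALSE)
             else character(0),
    stringsAsFactors = FALSE)
  out
}
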