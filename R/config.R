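#' Configuration for a simulated barcode reference library
#'
#' Defines the taxonomic hierarchy (families > genera > species >
#' specimens), the divergence scale at each rank, and the sequence model
#' used by [simulate_library()]. Count arguments accept either a single
#' integer or a length-2 range `c(lo, hi)` from which per-parent counts are
#' drawn uniformly; `specimens_per_species = c(1, 3)` therefore produces
#' singleton species.
#'
#' Divergence scales are expected Kimura 2-parameter distances in
#' substitutions/site between two specimens whose most recent common
#' ancestor sits at that rank: `d_intra` for conspecific pairs, `d_species`
#' for congeneric pairs of different species, `d_genus` for confamilial
#' pairs of different genera, and `d_family` for pairs from different
#' families. They must be strictly increasing. Defaults mirror the rank
#' means typically reported for plant ITS2 libraries (about 0.6% within
#' species, 12% within genera, 37% within families).
#'
#' @param n_families number of families.
#' @param genera_per_family,species_per_genus,specimens_per_species counts
#'   or ranges as described above.
#' @param its2_length length-2 range (bp) for the ITS2 region; per-family
#'   lengths are drawn from a Beta(2, 3.67) stretched over this range so
#'   the mean falls near 225 bp on the default range.
#' @param gc_target GC fraction of the root sequence.
#' @param d_intra,d_species,d_genus,d_family divergence scales
#'   (substitutions/site), strictly increasing.
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param indel_rate per-site probability of an indel event in terminal
#'   sequences (0 disables indels).
#' @param flank_5p,flank_3p conserved flanking motifs (5.8S tail and 28S
#'   head) used by [add_flanks()]; defaults are built around the universal
#'   ITS2 primer sites.
#' @param seed integer seed for the single random stream of a run.
#' @return An object of class `library_config` (a validated list).
#' @examples
#' cfg <- library_config(n_families = 2, genera_per_family = 1,
#'                       species_per_genus = 3, specimens_per_species = 2)
#' tax <- generate_taxonomy(cfg)
#' nrow(tax) # 2 * 1 * 3 * 2 specimens
#' @export
library_config <- function(n_families = 5,
                           genera_per_family = 2,
                           species_per_genus = 5,
                           specimens_per_species = 5,
                           its2_length = c(158, 348),
                           gc_target = 0.63,
                           d_intra = 0.006,
                           d_species = 0.12,
                           d_genus = 0.37,
                           d_family = 0.50,
                           kappa = 2,
                           indel_rate = 0.002,
                           flank_5p = "ATGCGATACTTGGTGTGAATTGCAGAATCC",
                           flank_3p = "ATTGTAGTCTGGAGAAGCGTC",
                           seed = 42L) {
  cfg <- list(n_families = n_families,
              genera_per_family = genera_per_family,
              species_per_genus = species_per_genus,
              specimens_per_species = specimens_per_species,
              its2_length = its2_length,
              gc_target = gc_target,
              d_intra = d_intra, d_species = d_species,
              d_genus = d_genus, d_family = d_family,
              kappa = kappa, indel_rate = indel_rate,
              flank_5p = flank_5p, flank_3p = flank_3p,
              seed = as.integer(seed))
  cfg <- validate_config(cfg)
  class(cfg) <- "library_config"
  cfg
}

count_range <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || length(x) > 2 || any(is.na(x)))
    stop(sprintf("'%s' must be a count or a length-2 range", name),
         call. = FALSE)
  x <- as.integer(round(x))
  if (length(x) == 1) x <- c(x, x)
  if (x[1] > x[2] || x[1] < 1)
    stop(sprintf("'%s' must be a positive count or non-empty range", name),
         call. = FALSE)
  x
}

validate_config <- function(cfg) {
  cfg$n_families <- count_range(cfg$n_families, "n_families")[1]
  for (nm in c("genera_per_family", "species_per_genus",
               "specimens_per_species"))
    cfg[[nm]] <- count_range(cfg[[nm]], nm)
  len <- cfg$its2_length
  if (!is.numeric(len) || length(len) != 2 || len[1] > len[2] || len[1] < 1)
    stop("'its2_length' must be a positive range c(lo, hi)", call. = FALSE)
  d <- c(cfg$d_intra, cfg$d_species, cfg$d_genus, cfg$d_family)
  if (any(d < 0)) stop("divergence scales must be >= 0", call. = FALSE)
  if (!all(diff(d) > 0))
    stop("require d_intra < d_species < d_genus < d_family", call. = FALSE)
  if (cfg$kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (cfg$indel_rate < 0 || cfg$indel_rate > 1)
    stop("'indel_rate' must be in [0, 1]", call. = FALSE)
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1)
    stop("'gc_target' must be in (0, 1)", call. = FALSE)
  if (!nzchar(cfg$flank_5p) || !nzchar(cfg$flank_3p))
    stop("flank motifs must be non-empty", call. = FALSE)
  invisible(cfg)
}

#' @export
print.library_config <- function(x, ...) {
  cat("Library simulation config\n")
  cat(sprintf("  taxonomy: %d families x %s genera x %s species x %s specimens\n",
              x$n_families,
              paste(unique(x$genera_per_family), collapse = "-"),
              paste(unique(x$species_per_genus), collapse = "-"),
              paste(unique(x$specimens_per_species), collapse = "-")))
  cat(sprintf("  ITS2 length %d-%d bp, GC target %.2f\n",
              x$its2_length[1], x$its2_length[2], x$gc_target))
  cat(sprintf("  divergence d_intra=%.3g d_species=%.3g d_genus=%.3g d_family=%.3g\n",
              x$d_intra, x$d_species, x$d_genus, x$d_family))
  cat(sprintf("  kappa=%.2f indel_rate=%.3g seed=%d\n",
              x$kappa, x$indel_rate, x$seed))
  invisible(x)
}
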