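#' Generate a hierarchical taxonomy table
#'
#' Draws a families > genera > species > specimens hierarchy according to a
#' [library_config()]. Counts given as ranges are sampled uniformly per
#' parent taxon, so `specimens_per_species = c(1, 3)` yields a mixture of
#' singleton and multi-specimen species.
#'
#' @param config a [library_config()].
#' @param seed seed to set before drawing; `NULL` continues the current
#'   random stream (used by [simulate_library()], which seeds once).
#' @return A data.frame with columns `specimen_id`, `species`, `genus`,
#'   `family`.
#' @export
generate_taxonomy <- function(config, seed = config$seed) {
  config <- validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(rg) if (rg[1] == rg[2]) rg[1] else
    sample(seq(rg[1], rg[2]), 1)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    for (g in seq_len(draw(config$genera_per_family))) {
      gen <- sprintf("%sG%02d", fam, g)
      for (s in seq_len(draw(config$species_per_genus))) {
        sp <- sprintf("%sS%02d", gen, s)
        n_spec <- draw(config$specimens_per_species)
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_%02d", sp, seq_len(n_spec)),
          species = sp, genus = gen, family = fam,
          stringsAsFactors = FALSE)
      }
    }
  }
  tax <- do.call(rbind, rows)
  rownames(tax) <- NULL
  tax
}

# K80 transition probabilities for a branch of expected length d
# (substitutions/site) at transition/transversion rate ratio kappa.
# With rates alpha (transition) and beta (each transversion target),
# scaled so alpha + 2*beta = 1 substitution per unit time:
#   p_transition  = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   p_transversion (each of two targets) = 1/4 - 1/4 e^{-4 beta t}
k80_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1 # each of the two transversion targets
  c(ts = p_ts, tv = p_tv)
}

# Evolve an integer-coded sequence (1..4) along a branch of length d.
# Transition partner: A<->G (1<->3), C<->T (2<->4). Transversion targets
# are the two bases of the other chemical class.
mutate_seq <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  p <- k80_probs(d, kappa)
  L <- length(codes)
  u <- runif(L)
  out <- codes
  ts_partner <- c(3L, 4L, 1L, 2L)
  ts_idx <- which(u < p["ts"])
  if (length(ts_idx)) out[ts_idx] <- ts_partner[codes[ts_idx]]
  tv_idx <- which(u >= p["ts"] & u < p["ts"] + 2 * p["tv"])
  if (length(tv_idx)) {
    # pick one of the two cross-class targets uniformly
    pick <- runif(length(tv_idx)) < 0.5
    purine <- codes[tv_idx] == 1L | codes[tv_idx] == 3L
    out[tv_idx] <- ifelse(purine, ifelse(pick, 2L, 4L), ifelse(pick, 1L, 3L))
  }
  out
}

random_root <- function(L, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(1:4, L, replace = TRUE, prob = probs[c("A", "C", "G", "T")])
}

apply_indels <- function(codes, rate, gc) {
  if (rate <= 0) return(codes)
  n_events <- rbinom(1, length(codes), rate)
  if (n_events == 0) return(codes)
  for (k in seq_len(n_events)) {
    pos <- sample(length(codes), 1)
    len <- sample(1:3, 1)
    if (runif(1) < 0.5) { # deletion
      drop <- pos:min(pos + len - 1, length(codes))
      if (length(drop) < length(codes)) codes <- codes[-drop]
    } else {             # insertion after pos
      ins <- random_root(len, gc)
      codes <- append(codes, ins, after = pos)
    }
  }
  codes
}

#' Evolve sequences down the taxonomic rank tree
#'
#' Simulates ITS2-like sequences under the Kimura two-parameter
#' substitution process on a star-within-rank tree: a single library root
#' at the target GC composition, family ancestors, genus ancestors, species
#' ancestors and finally specimens, each child diverging independently from
#' its rank ancestor. Branch lengths are chosen so the expected pairwise
#' distance between two specimens whose most recent common ancestor sits at
#' rank r equals the configured scale `d_r` (each lineage contributes half
#' the pairwise expectation, hence the per-branch increments
#' `(d_r - d_subrank) / 2`). Per-family sequence lengths are truncations of
#' a common full-length root so that cross-family distances remain defined.
#' Indels, if enabled, are applied to terminal sequences after substitution.
#'
#' @param taxonomy data.frame from [generate_taxonomy()].
#' @param config a [library_config()].
#' @param seed seed, or `NULL` to continue the current stream.
#' @return A list with `records` (data.frame `specimen_id`, `sequence`) and
#'   `ground_truth` (class `barcode_ground_truth`: taxonomy, the generating
#'   tree as an [ape] `phylo` with specimens as tips, and the config).
#' @export
evolve_library <- function(taxonomy, config, seed = config$seed) {
  config <- validate_config(config)
  if (nrow(taxonomy) == 0) stop("taxonomy is empty")
  if (!is.null(seed)) set.seed(seed)

  kappa <- config$kappa
  b_fam  <- (config$d_family - config$d_genus) / 2
  b_gen  <- (config$d_genus - config$d_species) / 2
  b_sp   <- (config$d_species - config$d_intra) / 2
  b_spec <- config$d_intra / 2

  L_max <- config$its2_length[2]
  root <- random_root(L_max, config$gc_target)

  fams <- unique(taxonomy$family)
  # per-family target length: Beta(2, 3.67) stretched over the range, so
  # the default range 158-348 has mean near 225 bp
  lo <- config$its2_length[1]
  fam_len <- round(lo + (L_max - lo) * rbeta(length(fams), 2, 3.67))
  names(fam_len) <- fams

  edges <- list(); edge_len <- c()
  tip_labels <- taxonomy$specimen_id
  n_tip <- length(tip_labels)
  node_id <- new.env(parent = emptyenv())
  next_node <- n_tip + 1L
  get_node <- function(key) {
    if (!exists(key, envir = node_id, inherits = FALSE)) {
      assign(key, next_node, envir = node_id)
      next_node <<- next_node + 1L
    }
    get(key, envir = node_id, inherits = FALSE)
  }
  root_node <- get_node(".root")
  add_edge <- function(parent, child, len) {
    edges[[length(edges) + 1L]] <<- c(parent, child)
    edge_len <<- c(edge_len, len)
  }

  records <- vector("list", n_tip)
  idx <- 1L
  for (fam in fams) {
    fam_seq <- mutate_seq(root, b_fam, kappa)[seq_len(fam_len[fam])]
    add_edge(root_node, get_node(fam), b_fam)
    tf <- taxonomy[taxonomy$family == fam, , drop = FALSE]
    for (gen in unique(tf$genus)) {
      gen_seq <- mutate_seq(fam_seq, b_gen, kappa)
      add_edge(get_node(fam), get_node(gen), b_gen)
      tg <- tf[tf$genus == gen, , drop = FALSE]
      for (sp in unique(tg$species)) {
        sp_seq <- mutate_seq(gen_seq, b_sp, kappa)
        add_edge(get_node(gen), get_node(sp), b_sp)
        ids <- tg$specimen_id[tg$species == sp]
        for (id in ids) {
          tip_seq <- mutate_seq(sp_seq, b_spec, kappa)
          tip_seq <- apply_indels(tip_seq, config$indel_rate,
                                  config$gc_target)
          add_edge(get_node(sp), match(id, tip_labels), b_spec)
          records[[idx]] <- data.frame(specimen_id = id,
                                       sequence = decode_seq(tip_seq),
                                       stringsAsFactors = FALSE)
          idx <- idx + 1L
        }
      }
    }
  }

  edge_mat <- do.call(rbind, edges)
  storage.mode(edge_mat) <- "integer"
  tree <- structure(list(edge = edge_mat,
                         edge.length = edge_len,
                         tip.label = tip_labels,
                         Nnode = as.integer(next_node - n_tip - 1L)),
                    class = "phylo")
  # ranks with a single child create degree-2 nodes; drop them so the
  # tree is a clean phylo for downstream ape operations
  tree <- ape::collapse.singles(tree)
  gt <- structure(list(taxonomy = taxonomy, tree = tree, config = config),
                  class = "barcode_ground_truth")
  list(records = do.call(rbind, records), ground_truth = gt)
}

#' Expected pairwise divergences implied by the generating tree
#'
#' Path lengths between specimen tips of the ground-truth tree, i.e. the
#' expected K2P distance for every pair under the simulation model.
#'
#' @param ground_truth object from [evolve_library()].
#' @return symmetric numeric matrix with specimen ids as dimnames.
#' @export
expected_divergence <- function(ground_truth) {
  stopifnot(inherits(ground_truth, "barcode_ground_truth"))
  ape::cophenetic.phylo(ground_truth$tree)
}

#' Add conserved flanking motifs to ITS2 sequences
#'
#' Prepends the 5.8S tail motif and appends the 28S head motif to each
#' record, producing full amplicons, and records the true ITS2 span
#' (0-based, half-open) for annotation ground truth.
#'
#' @param records data.frame with `specimen_id`, `sequence`.
#' @param config a [library_config()] supplying `flank_5p` / `flank_3p`.
#' @return records with `sequence` replaced by the amplicon and new columns
#'   `its2_start`, `its2_end` (0-based half-open span of the ITS2).
#' @export
add_flanks <- function(records, config) {
  if (!nzchar(config$flank_5p) || !nzchar(config$flank_3p))
    stop("flank motifs must be non-empty")
  if (any(nchar(records$sequence) == 0))
    stop("zero-length ITS2 sequence cannot be flanked")
  n5 <- nchar(config$flank_5p)
  records$its2_start <- n5
  records$its2_end <- n5 + nchar(records$sequence)
  records$sequence <- paste0(config$flank_5p, records$sequence,
                             config$flank_3p)
  records
}

#' Replace a fraction of bases with the ambiguity code N
#'
#' Optional corruption step for testing pairwise-deletion behaviour;
#' generation itself is restricted to A/C/G/T.
#'
#' @param records records data.frame.
#' @param rate per-site probability of replacement.
#' @return records with corrupted sequences.
#' @export
corrupt_records <- function(records, rate = 0.01) {
  records$sequence <- vapply(records$sequence, function(s) {
    ch <- seq_chars(s)
    hit <- runif(length(ch)) < rate
    ch[hit] <- "N"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  records
}

#' Simulate a complete reference library
#'
#' Seeds the single random stream once, then draws the taxonomy, evolves
#' ITS2 sequences, and attaches the conserved flanks. This is the one-call
#' entry point used by the analysis scripts and tests.
#'
#' @param config a [library_config()].
#' @return list with `amplicons` (flanked records incl. true ITS2 spans),
#'   `its2` (unflanked records), `taxonomy`, and `ground_truth`.
#' @export
simulate_library <- function(config = library_config()) {
  config <- validate_config(config)
  set.seed(config$seed)
  taxonomy <- generate_taxonomy(config, seed = NULL)
  lib <- evolve_library(taxonomy, config, seed = NULL)
  list(amplicons = add_flanks(lib$records, config),
       its2 = lib$records,
       taxonomy = taxonomy,
       ground_truth = lib$ground_truth)
}

#' Write a library to FASTA and TSV files
#'
#' @param records records data.frame (`specimen_id`, `sequence`).
#' @param taxonomy taxonomy data.frame.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written (`fasta`, `taxonomy`).
#' @export
write_library <- function(records, taxonomy, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "library.fasta")
  tsv <- file.path(out_dir, "taxonomy.tsv")
  write_fasta(records, fa)
  write.table(taxonomy[, c("specimen_id", "species", "genus", "family")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fa, taxonomy = tsv))
}
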