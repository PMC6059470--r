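#' Configuration for a full evaluation run
#'
#' Either a simulation config (library generated on the fly) or input
#' FASTA + taxonomy paths must be supplied, not neither. Stage toggles
#' allow partial runs; outputs of each stage are plain TSV/FASTA/newick
#' files plus a consolidated JSON summary.
#'
#' @param simulation a [library_config()], or `NULL` when reading inputs.
#' @param fasta,taxonomy input paths (ignored when `simulation` given).
#' @param aligned set `TRUE` when the input FASTA is already aligned
#'   (bypasses the progressive aligner).
#' @param trim run the ITS2 annotation stage.
#' @param stages character subset of
#'   `c("annotate", "distance", "gap", "tree", "identify")`.
#' @param bootstrap_B bootstrap replicates for the NJ tree (0 disables).
#' @param min_identity,min_coverage identification thresholds.
#' @param out_dir output directory.
#' @param seed run seed (all randomness flows from it).
#' @return validated list of class `run_config`.
#' @export
pipeline_config <- function(simulation = library_config(),
                            fasta = NULL, taxonomy = NULL,
                            aligned = FALSE, trim = TRUE,
                            stages = c("annotate", "distance", "gap",
                                       "tree", "identify"),
                            bootstrap_B = 0,
                            min_identity = 0.97, min_coverage = 0.95,
                            out_dir = tempfile("barcodeval_run_"),
                            seed = 42L) {
  if (is.null(simulation) && (is.null(fasta) || is.null(taxonomy)))
    stop("supply either a simulation config or fasta + taxonomy paths")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(simulation = simulation, fasta = fasta,
                 taxonomy = taxonomy, aligned = aligned, trim = trim,
                 stages = stages, bootstrap_B = bootstrap_B,
                 min_identity = min_identity,
                 min_coverage = min_coverage,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the evaluation pipeline
#'
#' Executes the enabled stages in order (simulate/load, annotate, align +
#' distance, barcoding gap, NJ tree + discrimination, leave-one-out
#' identification), writing each stage's artifacts under `out_dir` and a
#' consolidated `summary.json`. Idempotent given the seed. A stage
#' failure halts the run with the failing stage named; artifacts of
#' completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`records`, `taxonomy`, `alignment`, `dmat`, `rank_summary`, `gap`,
#'   `tree`, `clusters`, `identification`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  summary <- list(seed = config$seed,
                  stages = config$stages,
                  package_version = as.character(
                    utils::packageVersion("barcodeval")))

  if (!is.null(config$simulation)) {
    cfg <- config$simulation
    cfg$seed <- config$seed
    sim <- stage("simulate", simulate_library(cfg))
    records <- sim$amplicons
    taxonomy <- sim$taxonomy
    out$ground_truth <- sim$ground_truth
    write_library(records, taxonomy, config$out_dir)
    sim_cfg <- cfg
  } else {
    records <- stage("load", read_fasta(config$fasta))
    taxonomy <- stage("load", read_taxonomy(config$taxonomy))
    sim_cfg <- library_config()
  }
  summary$n_sequences <- nrow(records)
  summary$n_species <- length(unique(taxonomy$species))

  if ("annotate" %in% config$stages) {
    ann <- stage("annotate",
                 annotate_library(records, config = sim_cfg,
                                  trim = config$trim))
    write_tsv(ann$report, file.path(config$out_dir, "annotation.tsv"))
    records <- ann$records
    out$annotation <- ann$report
    st <- seq_stats(records)
    write_tsv(st$per_record, file.path(config$out_dir, "seq_stats.tsv"))
    summary$annotation <- list(
      n_ok = sum(ann$report$status %in% c("ok", "passthrough")),
      n_failed = sum(!ann$report$status %in% c("ok", "passthrough")),
      median_length_bp = st$by_group$median_length[1],
      mean_gc_pct = 100 * st$by_group$mean_gc[1])
    out$seq_stats <- st
  }
  out$records <- records
  out$taxonomy <- taxonomy

  needs_aln <- any(c("distance", "gap", "tree", "identify") %in%
                   config$stages)
  if (needs_aln) {
    aln <- stage("align",
      if (config$aligned) as_alignment(records)
      else progressive_align(records))
    write_fasta(data.frame(specimen_id = aln$ids, sequence = aln$seqs),
                file.path(config$out_dir, "alignment.fasta"))
    out$alignment <- aln
    dmat <- stage("distance", distance_matrix(aln))
    write_distance_matrix(dmat,
      path_tsv = file.path(config$out_dir, "distances.tsv"),
      path_phylip = file.path(config$out_dir, "distances.phy"))
    out$dmat <- dmat
    if ("distance" %in% config$stages) {
      rs <- stage("distance", do.call(rbind, lapply(
        c("species", "genus", "family"),
        function(r) summarize_rank(dmat, taxonomy, r))))
      write_tsv(rs, file.path(config$out_dir, "rank_summary.tsv"))
      out$rank_summary <- rs
      summary$rank_summary <- rs
    }
  }

  if ("gap" %in% config$stages) {
    gt <- stage("gap", gap_table(dmat, taxonomy))
    write_tsv(gt, file.path(config$out_dir, "gap_table.tsv"))
    write_tsv(data.frame(x_max_intra_pct = gt$max_intra_pct,
                         y_min_inter_pct = gt$min_inter_pct,
                         species = gt$species),
              file.path(config$out_dir, "gap_scatter.tsv"))
    out$gap <- gt
    summary$gap <- list(n_species = nrow(gt),
                        n_violations = sum(gt$violation),
                        n_ties = sum(gt$tie))
  }

  if ("tree" %in% config$stages) {
    dmat_t <- dmat
    if (nrow(dmat_t$masked) > 0) {
      dmat_t <- prune_undefined(dmat_t)
      summary$tree_pruned <- attr(dmat_t, "dropped")
    }
    tree <- stage("tree", nj_tree(dmat_t))
    if (config$bootstrap_B > 0)
      tree <- stage("tree", bootstrap_support(out$alignment, tree,
                                              B = config$bootstrap_B,
                                              seed = config$seed))
    ape::write.tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
    cl <- stage("tree", species_clusters(tree, taxonomy))
    write_tsv(cl$per_species,
              file.path(config$out_dir, "species_status.tsv"))
    out$tree <- tree
    out$clusters <- cl
    summary$tree <- list(
      n_clusters = cl$report$n_clusters,
      n_species_identified = cl$report$n_species_identified,
      n_singletons = cl$report$n_singletons,
      discrimination_rate = cl$report$discrimination_rate)
  }

  if ("identify" %in% config$stages) {
    idres <- stage("identify",
                   identify_library(records, taxonomy,
                                    min_identity = config$min_identity,
                                    min_coverage = config$min_coverage))
    write_tsv(idres, file.path(config$out_dir, "identification.tsv"))
    rates <- rbind(success_rates(idres, "species"),
                   success_rates(idres, "genus"))
    write_tsv(rates, file.path(config$out_dir, "success_rates.tsv"))
    cons <- conspecific_consistency(idres)
    write_tsv(cons, file.path(config$out_dir, "consistency.tsv"))
    out$identification <- idres
    out$success_rates <- rates
    out$consistency <- cons
    summary$identification <- rates
    summary$consistency <- list(
      n_cryptic = sum(cons$status == "cryptic_candidate"))
  }

  out$summary <- summary
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out)
}
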