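#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full simulated run:
#' which species to simulate, which toxin families each expresses and with
#' how many gene copies, and the parameter blocks of every stage.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed; every random stage derives from it.
#' @param species Named list (one entry per species) of named lists (one per
#'   family) with elements `n_paralogs`, `divergence` (within-species paralog
#'   divergence), and optional `weight` (per-gene expression weight, default
#'   1) and `efficiency` (translational efficiency, default 1).
#' @param n_reads Reads per species (scalar or named vector).
#' @param species_divergence Divergence of each species' family ancestor from
#'   the panel reference (emulates between-species sequence divergence).
#' @param contamination Fraction of each species' reads drawn from the
#'   housekeeping (non-toxin) transcript, exercising the non-toxin
#'   classification path.
#' @param read_sim Named list of [read_sim_config()] overrides.
#' @param homology Named list of [homology_params()] overrides.
#' @param distinctness Named list of [distinctness_params()] overrides.
#' @param consensus Named list of [consensus_params()] overrides.
#' @param pca_scale Autoscale the abundance PCA?
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, species, n_reads = 400L,
                            species_divergence = 0.04, contamination = 0.06,
                            read_sim = list(), homology = list(),
                            distinctness = list(), consensus = list(),
                            pca_scale = TRUE) {
  if (contamination < 0 || contamination >= 1)
    stop("contamination must be in [0, 1)")
  if (length(species) < 1L) stop("at least one species is required")
  if (is.null(names(species)) || any(names(species) == ""))
    stop("species list must be named")
  known <- c(.toxin_family_labels())
  for (sp in names(species)) {
    fams <- names(species[[sp]])
    bad <- setdiff(fams, known)
    if (length(bad))
      stop("unknown family label(s) for ", sp, ": ", paste(bad, collapse = ", "))
    for (f in fams) {
      blk <- species[[sp]][[f]]
      if (is.null(blk$n_paralogs) || blk$n_paralogs < 1)
        stop("n_paralogs must be >= 1 for ", sp, "/", f)
      if (is.null(blk$divergence) || blk$divergence < 0 || blk$divergence > 0.2)
        stop("divergence must be in [0, 0.2] for ", sp, "/", f)
    }
  }
  if (length(n_reads) == 1L)
    n_reads <- stats::setNames(rep(n_reads, length(species)), names(species))
  if (!all(names(species) %in% names(n_reads)))
    stop("n_reads must cover every species")
  cfg <- structure(
    list(outdir = outdir, seed = as.integer(seed), species = species,
         n_reads = n_reads, species_divergence = species_divergence,
         contamination = contamination, read_sim = read_sim,
         homology = homology, distinctness = distinctness,
         consensus = consensus, pca_scale = pca_scale),
    class = "pipeline_config")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Demo configuration: three synthetic species, five toxin families
#'
#' A small self-contained run exercising every stage: three species express
#' the five shared major families (BPP, LAO, PLA2, SVMP, SP) with known
#' per-family gene-copy numbers, so the copy-number matrix and the final
#' report can be checked against ground truth.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n_reads Reads per species.
#' @export
demo_config <- function(outdir, seed = 101L, n_reads = 350L) {
  fam <- function(k, d, w = 1, eff = 1)
    list(n_paralogs = k, divergence = d, weight = w, efficiency = eff)
  pipeline_config(
    outdir = outdir, seed = seed,
    species = list(
      speciesA = list(SVMP = fam(3, 0.06), PLA2 = fam(2, 0.06),
                      SP = fam(2, 0.06), LAO = fam(1, 0), BPP = fam(1, 0)),
      speciesB = list(SVMP = fam(2, 0.06), PLA2 = fam(1, 0),
                      SP = fam(3, 0.06), LAO = fam(2, 0.06),
                      BPP = fam(1, 0, eff = 0.2)),
      speciesC = list(SVMP = fam(1, 0), PLA2 = fam(2, 0.06),
                      SP = fam(1, 0), LAO = fam(1, 0),
                      BPP = fam(2, 0.06, eff = 2))),
    n_reads = n_reads)
}

.derive_seed <- function(base, k) (as.integer(base) %% 9999991L) * 97L + k

.log <- function(verbose, fmt, ...) if (verbose) message(sprintf(fmt, ...))

#' Run the full pipeline
#'
#' Orchestrates simulate -> demultiplex -> mask -> annotate -> copy-number ->
#' consensus -> quantify -> cladogram on a simulated multiplexed run, writes
#' every artifact (plus a checksum manifest) to `config$outdir`, and returns
#' the run report. Re-running with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress?
#' @return Object of class `venom_run_report` (invisibly): demux stats,
#'   annotation stats, abundance table, copy-number matrix, consensus
#'   sequences, PCA, tree, proteome comparisons, truth, and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(config$outdir, ...)
  sp_names <- names(config$species)
  all_fams <- sort(unique(unlist(lapply(config$species, names))))

  ## stage 1: gene models and expression profiles --------------------------
  panel <- reference_panel(all_fams, include_nontoxin = TRUE)
  models <- list(); weights <- numeric(0); effs <- numeric(0)
  gene_species <- character(0)
  truth_copies <- matrix(0L, length(sp_names), length(all_fams),
                         dimnames = list(sp_names, all_fams))
  k <- 0L
  for (sp in sp_names) for (f in names(config$species[[sp]])) {
    blk <- config$species[[sp]][[f]]
    k <- k + 1L
    anc <- simulate_gene_family(f, 2L, config$species_divergence,
                                ancestor = panel$models[[paste0(f, "_ref1")]],
                                seed = .derive_seed(config$seed, 2L * k))[[2L]]
    fam_models <- simulate_gene_family(f, blk$n_paralogs, blk$divergence,
                                       ancestor = anc,
                                       seed = .derive_seed(config$seed, 2L * k + 1L))
    for (g in fam_models) {
      g$gene_id <- paste(sp, f, g$paralog_id, sep = "|")
      models[[g$gene_id]] <- g
      weights[g$gene_id] <- blk$weight %||% 1
      effs[g$gene_id] <- blk$efficiency %||% 1
      gene_species[g$gene_id] <- sp
    }
    truth_copies[sp, f] <- as.integer(blk$n_paralogs)
  }
  # housekeeping contamination: each species also expresses the PDI
  # transcript (non-toxin), at the configured share of its reads
  if (config$contamination > 0) {
    pdi_panel <- reference_panel(all_fams[1], include_nontoxin = TRUE)
    for (sp in sp_names) {
      g <- pdi_panel$models[["PDI_ref1"]]
      g$gene_id <- paste(sp, "PDI", 1L, sep = "|")
      models[[g$gene_id]] <- g
      weights[g$gene_id] <- 0        # set after normalization below
      effs[g$gene_id] <- 0           # housekeeping: not in the venom proteome
      gene_species[g$gene_id] <- sp
    }
  }
  # scale weights so expected reads per species match n_reads (sampling is
  # length-weighted, so normalize by the weight x length mass)
  glen <- vapply(models, function(m) nchar(m$mrna), 0L)
  for (sp in sp_names) {
    sel <- gene_species == sp & !grepl("\\|PDI\\|", names(weights))
    weights[sel] <- weights[sel] / sum(weights[sel] * glen[names(weights)[sel]]) *
      config$n_reads[sp] * (1 - config$contamination)
    if (config$contamination > 0) {
      pid <- paste(sp, "PDI", 1L, sep = "|")
      weights[pid] <- config$n_reads[sp] * config$contamination / glen[pid]
    }
  }
  profile <- expression_profile(models, unname(weights[names(models)]),
                                unname(effs[names(models)]))
  .log(verbose, "simulated %d gene models for %d species", length(models),
       length(sp_names))

  ## stage 2: reads ---------------------------------------------------------
  rs_args <- config$read_sim
  rs_args$mid_set <- rs_args$mid_set %||%
    stats::setNames(default_mid_set(length(sp_names)), sp_names)
  rs_args$seed <- .derive_seed(config$seed, 7919L)
  cfg <- do.call(read_sim_config, rs_args)
  run <- simulate_reads(models, profile, cfg, sum(config$n_reads),
                        species = gene_species)
  write_reads_fastq(run, outfile("reads.fastq"))
  write_truth_tsv(run, outfile("truth.tsv"))
  write_gene_models(models, outfile("gene_models.fasta"),
                    outfile("gene_models.tsv"))
  write_panel(panel, outfile("panel.fasta"), outfile("panel.tsv"))
  .log(verbose, "simulated %d reads (mean insert %.1f nt)", length(run$reads),
       mean(run$truth$end - run$truth$start))

  ## stage 3: demultiplex + mask -------------------------------------------
  dmx <- demultiplex(run$reads, cfg$mid_set)
  .log(verbose, "demultiplexed: %d assigned, %d unassigned (%.2f%%)",
       dmx$stats$n_assigned, dmx$stats$n_unassigned, dmx$stats$error_rate_mid)
  hp <- do.call(homology_params, config$homology)
  dp <- do.call(distinctness_params, config$distinctness)
  cp <- do.call(consensus_params, config$consensus)

  hits_all <- NULL; masked_by_sp <- list(); iv_all <- NULL
  for (sp in sp_names) {
    mk <- mask_run(dmx$assigned[[sp]])
    masked_by_sp[[sp]] <- mk
    if (nrow(mk$intervals)) iv_all <- rbind(iv_all, cbind(species = sp, mk$intervals))
    msf <- vapply(mk$masked, microsat_fraction, 0)
    h <- assign_families(mk$reads, panel, hp, microsat_frac = msf)
    h <- cbind(species = sp, h)
    hits_all <- rbind(hits_all, h)
    .log(verbose, "%s: %d reads, %d toxin hits, %d non-toxin, %d no-hit", sp,
         nrow(h), sum(h$category == "toxin"), sum(h$category == "non_toxin"),
         sum(h$category == "no_hit"))
  }
  write_hits_tsv(hits_all, outfile("hits.tsv"))
  if (!is.null(iv_all)) write_intervals_bed(iv_all[, -1L], outfile("masked.bed"))

  ## stage 4: abundance ------------------------------------------------------
  counts <- matrix(0L, length(sp_names), length(all_fams),
                   dimnames = list(sp_names, all_fams))
  tox <- hits_all[hits_all$category == "toxin", ]
  tc <- table(tox$species, tox$family)
  counts[rownames(tc), colnames(tc)] <- as.integer(tc)
  abund <- abundance_table(counts, ntref(panel))
  stats <- annotation_stats(
    n_masked_reads = nrow(hits_all),
    n_hits = sum(hits_all$category != "no_hit"),
    n_venom = sum(hits_all$category == "toxin"),
    region_tally = table(tox$region))
  utils::write.table(cbind(species = rownames(abund$counts), as.data.frame(abund$counts)),
                     outfile("abundance_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cbind(species = rownames(abund$reads_pct),
                           round(as.data.frame(abund$reads_pct), 3)),
                     outfile("abundance_reads_pct.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(species = rownames(abund$mol_pct),
                           round(as.data.frame(abund$mol_pct), 3)),
                     outfile("abundance_mol_pct.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 5: copy number ----------------------------------------------------
  estimates <- list(); est_sp <- character(0); est_fam <- character(0)
  for (sp in sp_names) for (f in all_fams) {
    sel <- tox$species == sp & tox$family == f & !is.na(tox$region) &
      tox$region == "ORF"
    rids <- tox$read_id[sel]
    reads_f <- masked_by_sp[[sp]]$reads[rids]
    est <- estimate_min_genes(reads_f, panel$sequences[[paste0(f, "_ref1")]],
                              dp, hp)
    estimates[[paste(sp, f, sep = "|")]] <- est
    est_sp <- c(est_sp, sp); est_fam <- c(est_fam, f)
  }
  table3 <- make_table3(estimates, est_sp, est_fam)
  write_cluster_report(estimates, est_sp, est_fam, outfile("cluster_report.tsv"))
  utils::write.table(cbind(species = rownames(table3), as.data.frame(table3)),
                     outfile("min_gene_copies.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .log(verbose, "copy-number matrix: %s",
       paste(apply(table3, 1L, paste, collapse = "/"), collapse = "; "))

  ## stage 6: consensus + cladistics -----------------------------------------
  shared <- intersect(concatenation_order(), all_fams)
  cons_by_sp <- list(); concats <- list()
  for (sp in sp_names) {
    cons_by_sp[[sp]] <- list()
    for (f in shared) {
      sel <- tox$species == sp & tox$family == f & !is.na(tox$region) &
        tox$region == "ORF"
      peps <- best_frame_peptides(masked_by_sp[[sp]]$reads[tox$read_id[sel]],
                                  panel$proteins[[paste0(f, "_ref1")]], hp)
      cons_by_sp[[sp]][[f]] <- build_consensus(
        peps, panel$proteins[[paste0(f, "_ref1")]], cp, hp,
        family = f, species = sp)
    }
    write_consensus(cons_by_sp[[sp]],
                    outfile(paste0("consensus_", sp, ".fasta")),
                    outfile(paste0("consensus_", sp, ".tsv")))
  }
  tree <- NULL; D <- NULL
  if (length(sp_names) >= 3L && length(shared) == length(concatenation_order())) {
    concats <- lapply(sp_names, function(sp)
      concatenate_consensus(cons_by_sp[[sp]], species = sp))
    names(concats) <- sp_names
    D <- distance_matrix(concats, hp)
    write_phylip_dist(D, outfile("distances.phylip"))
    tree <- neighbor_joining(D)
    ape::write.tree(tree, outfile("cladogram.nwk"))
    .log(verbose, "cladogram written (%d taxa)", length(sp_names))
  }

  ## stage 7: proteome comparison + PCA --------------------------------------
  comparisons <- list()
  for (sp in sp_names) {
    sel <- gene_species == sp
    prot <- simulate_proteome(models[names(which(sel))],
                              profile[profile$gene_id %in% names(which(sel)), ])
    prot <- prot[names(prot) %in% all_fams]       # venom families only
    if (sum(counts[sp, ]) > 0)
      comparisons[[sp]] <- compare_with_proteome(counts[sp, ], abund$ntref, prot)
  }
  pca <- NULL
  if (length(sp_names) >= 3L) {
    keep <- colSums(abund$counts) > 0
    pca <- pca_abundance(abund$reads_pct[, keep, drop = FALSE],
                         scale = config$pca_scale)
    utils::write.table(cbind(species = rownames(pca$scores),
                             round(as.data.frame(pca$scores), 5)),
                       outfile("pca_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cbind(family = rownames(pca$loadings),
                             round(as.data.frame(pca$loadings), 5)),
                       outfile("pca_loadings.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## stage 8: report + manifest ----------------------------------------------
  report_json <- list(
    n_reads = length(run$reads),
    demux = dmx$stats[c("n_total", "n_assigned", "n_unassigned", "error_rate_mid")],
    annotation = stats[c("n_masked_reads", "n_hits", "n_venom", "pct_hits",
                         "pct_venom_of_hits")],
    masking = lapply(masked_by_sp, function(m) m$stats),
    min_gene_copies = as.data.frame(table3),
    pca_variance = if (!is.null(pca)) pca$variance_explained else NULL)
  jsonlite::write_json(report_json, outfile("run_report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files))),
    bytes = unname(file.size(file.path(config$outdir, files))))
  jsonlite::write_json(manifest, outfile("manifest.json"), pretty = TRUE)

  structure(list(config = config, demux_stats = dmx$stats,
                 annotation_stats = stats, abundance = abund,
                 min_gene_copies = table3, truth_copies = truth_copies,
                 consensus = cons_by_sp, concatenated = concats,
                 distances = D, tree = tree, pca = pca,
                 proteome_comparisons = comparisons, truth = run$truth,
                 hits = hits_all, manifest = manifest),
            class = "venom_run_report")
}

#' @export
print.venom_run_report <- function(x, ...) {
  cat("<venom_run_report>\n")
  print(x$demux_stats)
  print(x$annotation_stats)
  cat("  minimum gene copies:\n")
  print(x$min_gene_copies)
  if (!is.null(x$pca))
    cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%%\n",
                x$pca$variance_explained[1], x$pca$variance_explained[2]))
  invisible(x)
}

#' Species x family matrix of minimum gene-copy counts
#'
#' Arranges per-species, per-family copy-number estimates into a matrix;
#' species/family combinations with no ORF-coding reads get 0.
#'
#' @param estimates List of [estimate_min_genes()] results.
#' @param species,family Character vectors parallel to `estimates`.
#' @return Integer matrix, species x family.
#' @export
make_table3 <- function(estimates, species, family) {
  sp <- unique(species); fam <- unique(family)
  out <- matrix(0L, length(sp), length(fam), dimnames = list(sp, fam))
  for (k in seq_along(estimates))
    out[species[k], family[k]] <- estimates[[k]]$count
  out
}
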