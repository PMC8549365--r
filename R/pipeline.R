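# End-to-end orchestration: simulate -> call -> dist -> tree -> mst -> amova.
# Every artifact is written under one output directory together with a run
# manifest recording the full configuration and seed.

#' Default pipeline configuration
#'
#' Defaults follow the study conditions the package emulates: a handful of
#' regions with nested habitats and hosts, max_edits = 5, a 33 nt length
#' filter, and 1000-permutation tests.
#'
#' @param ... overrides of any default element.
#' @return a named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_haplotypes = 20, ancestor_length = 35, rho = 0, time_scale = 0.3,
    design = c(region = 3, habitat = 2, host = 3),
    weights = c(region = 1, habitat = 0, host = 0.2),
    depth = 60,
    sub_rate = 0.005, indel_rate = 0.005,
    dropout_frac = 0.1, truncate_frac = 0.02,
    max_edits = 5, min_len = 33, spacing_tol = 5,
    t_max = 10, n_perm = 199,
    primers = c(FWD = "ACGGTCTTAGGCTTACCGTACGT",
                REV = "TGCACCTAGGTTCAAGCCTTGAA"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full synthetic pipeline
#'
#' Chains \code{simulate_oisl_tree}, \code{simulate_hierarchy},
#' \code{simulate_reads}, \code{call_haplotypes},
#' \code{oisl_distance_matrix}, \code{rooted_nj},
#' \code{min_spanning_network} and \code{amova}, writing each stage's
#' artifact under \code{out_dir} plus a \code{manifest.txt} with the
#' configuration and seed.
#'
#' @param out_dir output directory (created).
#' @param config list from \code{\link{pipeline_config}}.
#' @param seed mandatory integer seed covering every stochastic stage.
#' @param write_reads write per-sample FASTQ files (default FALSE; they are
#'   the bulkiest artifact).
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), seed,
                         write_reads = FALSE) {
  if (missing(seed)) ct_error("seed_required", "seed is mandatory")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)
  sim <- simulate_oisl_tree(
    n_haplotypes = config$n_haplotypes,
    ancestor_length = config$ancestor_length,
    rho = config$rho, time_scale = config$time_scale, seed = seed)
  names(sim$haplotypes) <- vapply(sim$haplotypes, haplotype_label,
                                  character(1))
  sim$haplotypes <- sim$haplotypes[!duplicated(names(sim$haplotypes))]
  write_spacer_catalog(sim$catalog, file.path(out_dir, "catalog.fasta"))
  write_tree_newick(sim$tree, file.path(out_dir, "true_tree.nwk"))
  hier <- simulate_hierarchy(sim$haplotypes, config$design, config$weights,
                             depth = config$depth, seed = seed + 1L)
  utils::write.table(hier, file.path(out_dir, "hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reads <- simulate_reads(hier, sim$haplotypes, sim$catalog, config$primers,
                          sub_rate = config$sub_rate,
                          indel_rate = config$indel_rate,
                          dropout_frac = config$dropout_frac,
                          truncate_frac = config$truncate_frac,
                          seed = seed + 2L)
  if (write_reads) write_simulated_fastq(reads, file.path(out_dir, "reads"))
  call <- call_haplotypes(reads, sim$catalog, config$primers,
                          max_edits = config$max_edits,
                          min_len = config$min_len,
                          spacing_tol = config$spacing_tol)
  write_haplotype_table(call$table, file.path(out_dir, "haplotypes.tsv"))
  utils::write.table(call$qc, file.path(out_dir, "qc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- oisl_distance_matrix(call$haplotypes, t_max = config$t_max)
  write_phylip_dist(d, file.path(out_dir, "distances.phylip"))
  tree <- rooted_nj(d)
  write_tree_newick(tree, file.path(out_dir, "nj_tree.nwk"))
  dp <- patristic_distances(tree)[rownames(d), colnames(d)]
  # node attributes: per-sample read counts per haplotype
  cnt <- tapply(call$table$read_count,
                list(call$table$haplotype_id, call$table$sample_id), sum)
  cnt[is.na(cnt)] <- 0
  msn <- min_spanning_network(d, as.data.frame.matrix(cnt))
  write_msn(msn, file.path(out_dir, "msn_edges.tsv"),
            file.path(out_dir, "msn_nodes.tsv"))
  # AMOVA on Lingoes-corrected patristic distances, levels from the design
  lev <- names(config$design)
  # rebuild the AMOVA table from the *called* per-sample haplotype counts
  calls <- call$table
  sid <- strsplit(calls$sample_id, ":", fixed = TRUE)
  amova_tab <- data.frame(do.call(rbind, sid), stringsAsFactors = FALSE)
  names(amova_tab) <- lev
  amova_tab$haplotype_id <- calls$haplotype_id
  amova_tab$count <- calls$read_count
  dl <- lingoes_correct(dp)
  am <- amova(amova_tab, dl, levels = lev, n_perm = config$n_perm,
              seed = seed + 3L)
  am_out <- cbind(level = rownames(am$table), am$table)
  utils::write.table(am_out, file.path(out_dir, "amova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("crisprtype run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", seed),
    sprintf("%s: %s", names(config),
            vapply(config, function(v) paste(format(v), collapse = ","),
                   character(1))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(sim = sim, hierarchy = hier, call = call, dist = d,
                 tree = tree, patristic = dp, msn = msn, amova = am,
                 config = config, seed = seed))
}
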