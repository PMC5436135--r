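#' Default pipeline configuration
#'
#' All analysis thresholds default to the standard operating values:
#' fraction-genome-altered threshold 0.2, arm-loss threshold -0.2,
#' dendrogram cut height 0.9, classifier correlation margin 0.05, combined
#' 3p lost-cutoff 0.8, mutation filters depth >= 15 and VAF >= 0.15.
#'
#' @param seed integer seed for the synthetic stages.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("rccmatch_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    genome = list(n_chromosomes = 22, genes_per_arm = 25, scale = 0.001),
    cohort = list(n_per_group = 100, n_cell_lines_per_group = 10,
                  segment_noise_sd = 0.1),
    views = list(drop = 0.05, alter = 0.05, extent_shift = 0.05),
    expression = list(n_per_class = 100, n_intermediate = 40,
                      class_effect_size = 2, n_marker_genes = 200,
                      batches = 2, batch_shift = 1, batch_scale = 1.2,
                      noise_sd = 0.5),
    clinical = list(stage_logit_slope = 8, grade_logit_slope = 6),
    thresholds = list(fga = 0.2, loss = -0.2, cut_height = 0.9,
                      margin = 0.05, lost_cutoff = 0.8,
                      min_depth = 15, min_vaf = 0.15),
    panel_size = 16
  )
}

#' Validate a pipeline configuration
#' @param config configuration list (see [default_config()]).
#' @return the config, invisibly; errors on out-of-range values.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  if (is.null(config$seed)) stop("config error: seed is required")
  if (th$fga <= 0) stop("config error: fga threshold must be positive")
  if (th$loss >= 0) stop("config error: loss threshold must be negative")
  if (th$cut_height < 0) stop("config error: cut_height must be >= 0")
  if (th$margin < 0 || th$margin > 1) {
    stop("config error: margin must be in [0,1]")
  }
  if (th$lost_cutoff < 0 || th$lost_cutoff > 1) {
    stop("config error: lost_cutoff must be in [0,1]")
  }
  if (th$min_vaf < 0 || th$min_vaf > 1) {
    stop("config error: min_vaf must be in [0,1]")
  }
  rates <- unlist(config$views)
  if (any(rates < 0 | rates > 1)) stop("config error: view rates in [0,1]")
  invisible(config)
}

#' Read a pipeline configuration from YAML, merged over defaults
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(upd[[k]]) && is.list(base[[k]])) {
        merge_into(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  validate_config(merge_into(cfg, user))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> harmonize -> similarity -> cluster/FGA/3p ->
#' concordance tiers -> expression classification -> aggressiveness
#' comparison, writing stage TSVs, a machine-readable \code{summary.json}
#' and a run log into \code{config$out_dir}. Re-running with the same
#' config and seed reproduces all outputs.
#'
#' @param config configuration list (see [default_config()]).
#' @param quiet suppress progress messages.
#' @return the summary list, invisibly; all artefacts on disk.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  logf("init", sprintf("rccmatch %s, seed %d",
                       as.character(utils::packageVersion("rccmatch")),
                       config$seed))
  logf("init", paste("thresholds:", paste(names(config$thresholds),
                                          unlist(config$thresholds),
                                          sep = "=", collapse = " ")))
  th <- config$thresholds

  # --- simulate ---
  sim <- run_stage("simulate", {
    genome <- make_genome(config$genome$n_chromosomes,
                          config$genome$genes_per_arm,
                          config$genome$scale, seed = config$seed)
    arch <- default_archetypes(genome)
    cohort <- simulate_cna_cohort(genome, arch,
                                  n_per_group = config$cohort$n_per_group,
                                  n_cell_lines_per_group =
                                    config$cohort$n_cell_lines_per_group,
                                  segment_noise_sd =
                                    config$cohort$segment_noise_sd,
                                  seed = config$seed)
    muts <- simulate_mutation_records(cohort$truth, genome,
                                      seed = config$seed)
    list(genome = genome, arch = arch, cohort = cohort, muts = muts)
  })
  write_seg(sim$cohort$segments, file.path(config$out_dir, "segments.seg"))
  write_maf(sim$muts, file.path(config$out_dir, "mutations.maf.tsv"))
  write_gene_table(sim$genome$genes, file.path(config$out_dir, "genes.tsv"))
  logf("simulate", sprintf("%d samples, %d segments, %d mutation records",
                           nrow(sim$cohort$truth$samples),
                           nrow(sim$cohort$segments), nrow(sim$muts)))

  # --- harmonize ---
  harm <- run_stage("harmonize", {
    gene_mat <- segments_to_genes(sim$cohort$segments, sim$genome)
    gistic <- discretize_gistic(gene_mat)
    filtered <- filter_mutations(sim$muts, min_depth = th$min_depth,
                                 min_vaf = th$min_vaf)
    list(gene_mat = gene_mat, gistic = gistic, filtered = filtered)
  })
  logf("harmonize", sprintf("gene matrix %d x %d; %d/%d mutations pass filters",
                            nrow(harm$gene_mat), ncol(harm$gene_mat),
                            nrow(harm$filtered), nrow(sim$muts)))

  # --- two-source views + similarity ---
  truth <- sim$cohort$truth
  cl_ids <- truth$samples$sample[truth$samples$is_cell_line]
  tum_ids <- truth$samples$sample[!truth$samples$is_cell_line]
  views <- run_stage("similarity", {
    cl_mut <- harm$filtered[harm$filtered$sample %in% cl_ids, , drop = FALSE]
    simulate_two_source_views(cl_mut,
                              harm$gistic[, cl_ids, drop = FALSE],
                              rates = config$views, seed = config$seed)
  })
  simres <- run_stage("similarity", {
    prof_a <- binarize_mutations(views$mut_a, sim$genome$genes$gene,
                                 samples = cl_ids)
    prof_b <- binarize_mutations(views$mut_b, sim$genome$genes$gene,
                                 samples = cl_ids)
    jac <- jaccard_matrix(prof_a, prof_b)
    cna_cor <- profile_correlation(harm$gene_mat[, cl_ids, drop = FALSE],
                                   harm$gene_mat[, cl_ids, drop = FALSE],
                                   method = "pearson")
    pairs <- data.frame(row = cl_ids, col = cl_ids,
                        stringsAsFactors = FALSE)
    list(jaccard = jac, cna_cor = cna_cor,
         matched = matched_vs_unmatched(jac, pairs))
  })
  utils::write.table(simres$jaccard,
                     file.path(config$out_dir, "similarity_jaccard.tsv"),
                     sep = "\t", quote = FALSE)
  logf("similarity", sprintf("matched Jaccard ranked first: %.2f",
                             simres$matched$fraction_first))

  # --- clustering / FGA / 3p ---
  cna <- run_stage("cluster", {
    tree <- cluster_profiles(harm$gene_mat)
    groups <- stats::setNames(
      ifelse(truth$samples$is_cell_line, "cell_line", truth$samples$group),
      truth$samples$sample)
    cut <- cut_and_summarize(tree, h = th$cut_height, group_labels = groups)
    tum_subtypes <- stats::setNames(truth$samples$group[!truth$samples$is_cell_line],
                                    tum_ids)
    calls <- assign_cell_line_subtype(cut, tum_subtypes)
    fga <- fraction_genome_altered(sim$cohort$segments, threshold = th$fga)
    loss3p <- arm_loss_fraction(sim$cohort$segments, sim$genome, "3p",
                                loss_thresh = th$loss)
    list(tree = tree, cut = cut, calls = calls, fga = fga, loss3p = loss3p)
  })
  write_dendrogram_newick(cna$tree, file.path(config$out_dir, "dendrogram.nwk"))
  utils::write.table(cna$calls, file.path(config$out_dir, "subtype_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cna$fga, file.path(config$out_dir, "fga.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("cluster", sprintf("%d clusters at h = %g",
                          length(unique(cna$cut$labels)), th$cut_height))

  # --- tiers ---
  tiers <- run_stage("tiers", {
    mut_genes <- unique(names(unlist(unname(
      lapply(sim$arch, `[[`, "mutation_rates")))))
    panel <- utils::head(c(mut_genes,
                           setdiff(sim$genome$genes$gene, mut_genes)),
                         config$panel_size)
    tt <- tier_table(views$mut_a, views$mut_b, views$cna_a, views$cna_b,
                     panel, cell_lines = cl_ids)
    list(panel = panel, table = tt,
         report = reliability_report(tt, panel))
  })
  utils::write.table(tiers$table, file.path(config$out_dir, "tier_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tiers$report,
                     file.path(config$out_dir, "reliability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("tiers", sprintf("%d perfect-agreement cell line(s)",
                        sum(tiers$report$all_tier1_mutations &
                              tiers$report$all_tier1_cna)))

  # --- expression classifier ---
  expr <- run_stage("classify", {
    ex <- simulate_expression(sim$genome$genes$gene,
                              n_per_class = config$expression$n_per_class,
                              n_intermediate = config$expression$n_intermediate,
                              class_effect_size = config$expression$class_effect_size,
                              n_marker_genes = config$expression$n_marker_genes,
                              batch_assignment = config$expression$batches,
                              batch_shift = config$expression$batch_shift,
                              batch_scale = config$expression$batch_scale,
                              noise_sd = config$expression$noise_sd,
                              seed = config$seed)
    adj <- combat_adjust(ex$expr, ex$truth$samples$batch)
    lab <- ex$truth$samples$class
    core <- lab != "intermediate"
    model <- train_nsc(adj$adjusted[, core, drop = FALSE], lab[core],
                       seed = config$seed)
    calls <- classify_margin(model, adj$adjusted, margin = th$margin)
    calls$true_class <- lab[match(calls$sample, ex$truth$samples$sample)]
    list(truth = ex$truth, model = model, calls = calls)
  })
  utils::write.table(expr$calls, file.path(config$out_dir, "ccAccB_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_nsc_json(expr$model, file.path(config$out_dir, "nsc_model.json"))
  core_calls <- expr$calls[expr$calls$true_class != "intermediate", ]
  acc <- mean(core_calls$call == core_calls$true_class)
  logf("classify", sprintf("delta = %g, %d genes, training-cohort accuracy %.3f",
                           expr$model$delta, length(expr$model$surviving), acc))

  # --- aggressiveness ---
  agg <- run_stage("aggressiveness", {
    fga_v <- stats::setNames(cna$fga$fga, cna$fga$sample)
    clin <- simulate_clinical(truth, fga_v[tum_ids],
                              stage_logit_slope = config$clinical$stage_logit_slope,
                              grade_logit_slope = config$clinical$grade_logit_slope,
                              seed = config$seed)
    cc_tum <- truth$samples$sample[!truth$samples$is_cell_line &
                                     truth$samples$group == "ccRCC"]
    split <- split_by_coclustering(cna$cut, cc_tum, cl_ids)
    profs <- binarize_mutations(harm$filtered, sim$genome$genes$gene,
                                samples = truth$samples$sample)
    cmp <- compare_groups(split$with_group, split$away_group, clin, profs,
                          cna$fga, gene_panel = tiers$panel)
    list(clinical = clin, split = split, comparison = cmp)
  })
  utils::write.table(agg$clinical, file.path(config$out_dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("aggressiveness",
       sprintf("with/away = %d/%d, stage p = %.4g, mean FGA %.3f vs %.3f",
               length(agg$split$with_group), length(agg$split$away_group),
               agg$comparison$stage_test$p_value,
               agg$comparison$fga$mean[1], agg$comparison$fga$mean[2]))

  # --- summary ---
  fga_by <- split(cna$fga$fga,
                  truth$samples$is_cell_line[match(cna$fga$sample,
                                                   truth$samples$sample)])
  summary <- list(
    seed = config$seed,
    thresholds = config$thresholds,
    n_samples = nrow(truth$samples),
    n_clusters = length(unique(cna$cut$labels)),
    cell_line_calls = as.list(table(cna$calls$call)),
    median_fga_tumours = stats::median(fga_by[["FALSE"]]),
    median_fga_cell_lines = stats::median(fga_by[["TRUE"]]),
    matched_fraction_first = simres$matched$fraction_first,
    perfect_cell_lines = sum(tiers$report$all_tier1_mutations &
                               tiers$report$all_tier1_cna),
    classifier_delta = expr$model$delta,
    classifier_n_genes = length(expr$model$surviving),
    classifier_accuracy = acc,
    stage_p = agg$comparison$stage_test$p_value,
    fga_with = agg$comparison$fga$mean[1],
    fga_away = agg$comparison$fga$mean[2]
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  logf("done", "summary.json written")
  invisible(summary)
}
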