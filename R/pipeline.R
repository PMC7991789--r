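## End-to-end orchestration: simulate (or load) -> clean -> connectivity
## -> global/nodal metrics -> modular analysis -> NBS -> group statistics
## -> psychometric subtyping, with every stage seeded and serialized to a
## run directory.

#' Pipeline configuration
#'
#' Validates and bundles every tunable of the full analysis. All random
#' stages derive their seeds from `seed`.
#'
#' @param cohort a [cohort_spec()] for simulation, or a directory path
#'   holding a cohort written by [write_cohort()].
#' @param sparsity proportional-threshold grid for subject networks.
#' @param tau_grid occurrence thresholds for the control-group modular
#'   architecture.
#' @param reference_sparsity sparsity at which individual graphs enter
#'   the occurrence graphs and the modular metrics.
#' @param n_null degree-preserving null graphs per threshold.
#' @param nbs_primary_f,nbs_n_perm NBS primary F threshold and
#'   permutation count.
#' @param nbs_residualize residualize z values on age/gender before the
#'   edgewise ANOVA.
#' @param fd_thresh,dvars_thresh,scrub_rule scrubbing parameters.
#' @param band_low,band_high band-pass edges in Hz.
#' @param bonferroni_global Bonferroni denominator for the global metric
#'   family.
#' @param corr_families Bonferroni denominators for the three
#'   correlation families (regional, inter-module, RSFC).
#' @param subtype_k_range candidate cluster numbers for subtyping.
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            sparsity = sparsity_grid(),
                            tau_grid = seq(0.50, 0.70, 0.01),
                            reference_sparsity = 0.20,
                            n_null = 100,
                            nbs_primary_f = 12,
                            nbs_n_perm = 10000,
                            nbs_residualize = TRUE,
                            fd_thresh = 0.5,
                            dvars_thresh = 0.5,
                            scrub_rule = "and",
                            band_low = 0.01,
                            band_high = 0.08,
                            bonferroni_global = 7,
                            corr_families = c(regional = 40, intermodule = 8,
                                              rsfc = 64),
                            subtype_k_range = 2:6,
                            seed = 1L) {
  stop_if_not(all(sparsity > 0 & sparsity < 1) && all(diff(sparsity) > 0),
              "sparsity grid must be strictly increasing within (0,1)")
  stop_if_not(all(tau_grid > 0 & tau_grid <= 1),
              "tau grid must lie in (0,1]")
  stop_if_not(reference_sparsity > 0 && reference_sparsity < 1,
              "reference_sparsity must be in (0,1)")
  stop_if_not(n_null >= 0, "n_null must be nonnegative")
  stop_if_not(nbs_primary_f > 0, "nbs_primary_f must be positive")
  stop_if_not(nbs_n_perm >= 1, "nbs_n_perm must be at least 1")
  stop_if_not(band_low >= 0 && band_low < band_high,
              "band edges must satisfy 0 <= low < high")
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full connectome analysis pipeline
#'
#' Executes all stages in order and writes delimited-text/JSON artifacts
#' plus a manifest to `out_dir`. Re-running with an identical
#' configuration produces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files overwritten).
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## 1 — cohort
  say("stage cohort")
  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_spec")) {
      generate_cohort(config$cohort)
    } else {
      read_cohort(config$cohort)
    }
  })
  subjects <- cohort$subjects
  write_tsv(subjects, file.path(out_dir, "subjects.tsv"))
  write_tsv(cohort$atlas, file.path(out_dir, "atlas.tsv"))
  n <- nrow(subjects)
  groups <- factor(subjects$group, levels = unique(subjects$group))

  ## 2 — temporal cleaning
  say("stage clean")
  cleaned <- stage("clean", lapply(seq_len(n), function(i)
    clean_timeseries(cohort$timeseries[[i]], cohort$motion[[i]],
                     fd_thresh = config$fd_thresh,
                     dvars_thresh = config$dvars_thresh,
                     rule = config$scrub_rule,
                     low = config$band_low, high = config$band_high)))
  write_qc_report(lapply(cleaned, `[[`, "qc"), file.path(out_dir, "qc.json"))

  ## 3 — connectivity and subject graphs at the reference sparsity
  say("stage network")
  zs <- stage("network", lapply(cleaned, function(cl)
    correlation_matrix(cl$ts, node_labels = cohort$atlas$label)))
  ref_graphs <- lapply(zs, binarize, sparsity = config$reference_sparsity)

  ## 4 — global and nodal metric curves with AUC
  say("stage metrics")
  keep <- c("cp", "lp", "gamma", "lambda", "sigma", "e_glob", "e_loc")
  metr <- stage("metrics", lapply(seq_len(n), function(i) {
    global_metric_curves(zs[[i]], grid = config$sparsity,
                         n_null = config$n_null,
                         seed = derive_seed(config$seed, 200000L + i))
  }))
  global_auc <- data.frame(subject_id = subjects$subject_id,
                           group = subjects$group)
  for (n_m in keep) global_auc[[n_m]] <-
    vapply(metr, function(m) m[[n_m]]$auc, 0)
  write_tsv(global_auc, file.path(out_dir, "global_auc.tsv"))
  nod <- lapply(zs, nodal_metric_curves, grid = config$sparsity)
  deg_auc <- t(vapply(nod, `[[`, numeric(ncol(zs[[1L]])), "degree_auc"))
  eff_auc <- t(vapply(nod, `[[`, numeric(ncol(zs[[1L]])), "efficiency_auc"))
  colnames(deg_auc) <- colnames(eff_auc) <- cohort$atlas$label
  write_tsv(cbind(subjects["subject_id"], as.data.frame(round(deg_auc, 6L))),
            file.path(out_dir, "nodal_degree_auc.tsv"))
  write_tsv(cbind(subjects["subject_id"], as.data.frame(round(eff_auc, 6L))),
            file.path(out_dir, "nodal_efficiency_auc.tsv"))

  ## 5 — modular architecture from the control group
  say("stage modules")
  hc_idx <- which(subjects$group == levels(groups)[1L])
  modres <- stage("modules", hc_reference_partitions(
    ref_graphs[hc_idx], tau_grid = config$tau_grid, atlas = cohort$atlas))
  write_tsv(data.frame(
    tau = vapply(modres$partitions, `[[`, 0, "source_tau"),
    q = vapply(modres$partitions, `[[`, 0, "q"),
    n_modules = vapply(modres$partitions, `[[`, 0L, "n_modules")),
    file.path(out_dir, "partition_q_by_tau.tsv"))
  write_partition(modres$best, file.path(out_dir, "partition.tsv"),
                  atlas = cohort$atlas)

  ## modular metrics per subject under each tau's partition, AUC over tau
  tau_used <- vapply(modres$partitions, `[[`, 0, "source_tau")
  mod_stage <- stage("modular metrics", lapply(seq_len(n), function(i) {
    per_tau <- lapply(modres$partitions, function(p)
      modular_metrics(ref_graphs[[i]], p, z = zs[[i]]))
    wd <- vapply(per_tau, `[[`, numeric(nrow(zs[[1L]])), "within_degree")
    we <- vapply(per_tau, `[[`, numeric(nrow(zs[[1L]])), "within_efficiency")
    pc <- vapply(per_tau, `[[`, numeric(nrow(zs[[1L]])), "participation")
    ## module-pair connectivity needs a fixed module identity, so it is
    ## evaluated under the reporting (max-Q) partition only
    conn <- modular_metrics(ref_graphs[[i]], modres$best,
                            z = zs[[i]])$module_conn
    list(wd_auc = apply(wd, 1L, function(y) trapz(tau_used, y)),
         we_auc = apply(we, 1L, function(y) trapz(tau_used, y)),
         pc_auc = apply(pc, 1L, function(y) trapz(tau_used, y)),
         conn = conn)
  }))
  wd_auc <- t(vapply(mod_stage, `[[`, numeric(nrow(zs[[1L]])), "wd_auc"))
  colnames(wd_auc) <- cohort$atlas$label
  write_tsv(cbind(subjects["subject_id"], as.data.frame(round(wd_auc, 6L))),
            file.path(out_dir, "within_module_degree_auc.tsv"))

  ## inter-module connectivity AUC per module pair (upper triangle)
  M <- modres$best$n_modules
  mnames <- modres$best$module_names %||% as.character(seq_len(M))
  pair_idx <- which(upper.tri(diag(M), diag = TRUE), arr.ind = TRUE)
  conn_auc <- t(vapply(mod_stage, function(ms) ms$conn[pair_idx],
                       numeric(nrow(pair_idx))))
  colnames(conn_auc) <- sprintf("%s__%s", mnames[pair_idx[, 1L]],
                                mnames[pair_idx[, 2L]])
  conn_df <- cbind(subjects[c("subject_id", "group")],
                   as.data.frame(round(conn_auc, 6L)))
  write_tsv(conn_df, file.path(out_dir, "module_connectivity.tsv"))

  ## 6 — network-based statistic
  say("stage nbs")
  nbs <- stage("nbs", nbs_anova(
    zs, groups, primary_f = config$nbs_primary_f,
    n_perm = config$nbs_n_perm,
    seed = derive_seed(config$seed, 300000L),
    age = if (config$nbs_residualize) subjects$age else NULL,
    gender = if (config$nbs_residualize) subjects$gender else NULL))
  ph <- if (any(nbs$significant)) posthoc_edges(nbs, zs, groups) else NULL
  write_nbs_result(nbs, out_dir, posthoc = ph)

  ## 7 — group statistics
  say("stage stats")
  glob_stats <- stage("stats", group_metric_tests(
    global_auc[keep], groups, age = subjects$age, gender = subjects$gender,
    method = "bonferroni", family_size = config$bonferroni_global))
  write_tsv(glob_stats, file.path(out_dir, "stats_global.tsv"))

  nodal_stats <- stage("stats nodal", {
    p <- apply(deg_auc, 2L, function(v)
      oneway_anova(residualize(v, subjects$age, subjects$gender), groups)$p)
    f <- apply(deg_auc, 2L, function(v)
      oneway_anova(residualize(v, subjects$age, subjects$gender), groups)$f)
    fdr <- correct_p(p, method = "fdr")
    data.frame(node = cohort$atlas$label, f = f, p = p,
               p_fdr = fdr$p_adjusted, significant = fdr$significant)
  })
  write_tsv(nodal_stats, file.path(out_dir, "stats_nodal_degree.tsv"))

  ## partial correlations: key-region degree AUC and SN-SMN connectivity
  ## vs clinical measures within each patient group
  clin <- c("difficulty_defecation", "incomplete_evacuation",
            "abdominal_distension", "abdominal_pain",
            "sds", "sas", "sai", "tai")
  key_nodes <- intersect(c("rACC_L", "rACC_R", "THA_L", "THA_R"),
                         colnames(deg_auc))
  snsmn <- grep("^(SN__SMN|SMN__SN)$", colnames(conn_auc), value = TRUE)
  corr_rows <- list()
  for (g in setdiff(levels(groups), levels(groups)[1L])) {
    gi <- which(subjects$group == g)
    if (length(gi) < 6L) next
    cov_g <- subjects[gi, c("age", "gender")]
    for (v in clin) {
      y <- subjects[[v]][gi]
      if (anyNA(y)) next
      for (nd in key_nodes) {
        pc <- partial_corr(deg_auc[gi, nd], y, cov_g,
                           family_size = config$corr_families[["regional"]])
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          group = g, x = paste0("degree_auc_", nd), y = v, r = pc$r,
          p = pc$p, family = pc$family_size,
          significant = pc$p < 0.05 / pc$family_size)
      }
      for (cn in snsmn) {
        pc <- partial_corr(conn_auc[gi, cn], y, cov_g,
                           family_size = config$corr_families[["intermodule"]])
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          group = g, x = paste0("conn_auc_", cn), y = v, r = pc$r,
          p = pc$p, family = pc$family_size,
          significant = pc$p < 0.05 / pc$family_size)
      }
    }
  }
  if (length(corr_rows)) {
    write_tsv(do.call(rbind, corr_rows),
              file.path(out_dir, "correlations.tsv"))
  }

  ## 8 — psychometric subtyping of the patient groups
  say("stage subtype")
  pat <- which(subjects$group != levels(groups)[1L])
  sub <- stage("subtype", {
    sol <- subtype_patients(subjects[pat, c("sds", "sas", "sai", "tai")],
                            k_range = config$subtype_k_range)
    ret <- retest_concordance(subjects[pat, c("sds", "sas", "sai", "tai")],
                              sol$k, sol$labels,
                              seed = derive_seed(config$seed, 400000L))
    list(solution = sol, retest = ret)
  })
  write_tsv(data.frame(subject_id = subjects$subject_id[pat],
                       cluster = sub$solution$labels,
                       subtype = sub$solution$subtype),
            file.path(out_dir, "subtype_labels.tsv"))
  write_tsv(sub$solution$indices, file.path(out_dir, "subtype_indices.tsv"))
  jsonlite::write_json(
    list(linkage_heights = sub$solution$linkage_heights,
         votes = as.list(sub$solution$votes),
         ari_kmedoids = sub$retest$ari_kmedoids,
         ari_fuzzy_cmeans = sub$retest$ari_fuzzy_cmeans),
    file.path(out_dir, "subtype_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## manifest
  cfg <- config
  cfg$cohort <- if (inherits(config$cohort, "cohort_spec")) {
    c(unclass(config$cohort)[c("group_sizes", "n_nodes", "module_sizes",
                               "n_frames", "tr_seconds", "within_r",
                               "between_r", "seed")],
      list(n_effects = length(config$cohort$effect_map)))
  } else config$cohort
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("fconnectome")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = lapply(unclass(cfg), function(x)
           if (is.numeric(x) || is.character(x) || is.logical(x) ||
               is.list(x)) x else NULL)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, global_auc = global_auc,
                 nodal_degree_auc = deg_auc, nodal_efficiency_auc = eff_auc,
                 partition = modres$best, module_conn_auc = conn_df,
                 nbs = nbs, global_stats = glob_stats,
                 nodal_stats = nodal_stats, subtype = sub))
}
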