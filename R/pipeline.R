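# End-to-end orchestration: simulate -> condition -> connectome -> metrics ->
# nbs -> stats, with a run manifest written before any stage output and a
# human-readable summary report.

#' Run the full motor-network analysis
#'
#' Executes the pipeline stages in order on a synthetic cohort (or a cohort
#' supplied by the caller), writing a machine-readable manifest before any
#' stage output, per-stage TSV/JSON outputs under `out_dir`, and a summary
#' report. A rerun with the same configuration and seed reproduces every
#' numeric output.
#'
#' @param spec A [cohort_spec()]; ignored when `cohort` is supplied.
#' @param out_dir Output directory for the run.
#' @param seed Master seed for simulation, null ensembles, and permutations.
#' @param cohort Optional pre-built cohort tibble (skips the simulate stage).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "condition", "connectome", "metrics", "nbs", "stats")`.
#'   Disabling an upstream stage that a requested stage needs is an error.
#' @param cfg A [conditioning_config()].
#' @param alpha,edge_sign Connectivity thresholding parameters.
#' @param n_nulls Null-ensemble size per subject for gamma/lambda/sigma.
#' @param metrics_mode `"both"`, `"binary"`, or `"weighted"`.
#' @param covariates Covariate columns for NBS and group statistics.
#' @param nbs_primary_alpha,nbs_n_perm,nbs_statistic NBS parameters.
#' @param fdr_alpha FDR level for nodal-degree comparisons.
#' @return Invisibly, a list of in-memory stage results (`cohort`, `metrics`,
#'   `nodal`, `nbs`, `global_comparisons`, `nodal_comparisons`,
#'   `clinical_correlations`, `run_dir`).
#' @export
run_full_analysis <- function(spec = cohort_spec(), out_dir,
                              seed = spec$seed, cohort = NULL,
                              stages = c("simulate", "condition",
                                         "connectome", "metrics", "nbs",
                                         "stats"),
                              cfg = conditioning_config(tr = spec$tr),
                              alpha = 0.05,
                              edge_sign = c("positive", "abs"),
                              n_nulls = 100,
                              metrics_mode = "both",
                              covariates = c("age", "sex", "mean_fd"),
                              nbs_primary_alpha = 0.01, nbs_n_perm = 5000,
                              nbs_statistic = "extent", fdr_alpha = 0.05) {
  edge_sign <- match.arg(edge_sign)
  all_stages <- c("simulate", "condition", "connectome", "metrics", "nbs",
                  "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "motornet",
    version = as.character(utils::packageVersion("motornet")),
    seed = seed, stages = stages,
    spec = list(n_patients = spec$n_patients, n_controls = spec$n_controls,
                n_timepoints = spec$n_timepoints, tr = spec$tr,
                n_rois = spec$n_rois,
                ar_coefficient = spec$ar_coefficient,
                motion_scale = spec$motion_scale,
                planted_edges = spec$planted_edges),
    conditioning = unclass(cfg),
    threshold = list(alpha = alpha, edge_sign = edge_sign),
    metrics = list(n_nulls = n_nulls, mode = metrics_mode),
    nbs = list(primary_alpha = nbs_primary_alpha, n_perm = nbs_n_perm,
               statistic = nbs_statistic, covariates = covariates),
    fdr_alpha = fdr_alpha
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  results <- list(run_dir = out_dir)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(
        list(stage = name, error = conditionMessage(e)),
        file.path(out_dir, "error.json"), auto_unbox = TRUE
      )
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  need <- function(what, from) {
    if (is.null(what)) {
      rlang::abort(sprintf(
        "stage requires output of disabled stage '%s'", from
      ))
    }
    what
  }

  if ("simulate" %in% stages && is.null(cohort)) {
    cohort <- run_stage("simulate", {
      ch <- simulate_cohort(spec, seed = seed)
      write_cohort(ch, file.path(out_dir, "cohort"))
      ch
    })
  }
  if ("condition" %in% stages) {
    cohort <- run_stage("condition", {
      ch <- condition_cohort(need(cohort, "simulate"), cfg)
      qc <- ch[, c("subject_id", "group", "mean_fd", "n_spikes")]
      write_tsv_(as.data.frame(qc), file.path(out_dir, "qc.tsv"))
      ch
    })
  }
  if ("connectome" %in% stages) {
    cohort <- run_stage("connectome", {
      ch <- cohort_connectivity(need(cohort, "condition"), alpha = alpha,
                                edge_sign = edge_sign)
      cdir <- file.path(out_dir, "connectivity")
      for (i in seq_len(nrow(ch))) {
        write_connectivity(ch$connectivity[[i]], cdir, ch$subject_id[i])
      }
      ch
    })
  }
  if ("metrics" %in% stages) {
    stage_out <- run_stage("metrics", {
      need(cohort$connectivity, "connectome")
      metrics <- cohort_graph_metrics(cohort, mode = metrics_mode,
                                      n_nulls = n_nulls, seed = seed + 1L)
      nodal <- cohort_nodal_degree(cohort, mode = metrics_mode)
      write_tsv_(as.data.frame(metrics),
                 file.path(out_dir, "global_metrics.tsv"))
      write_tsv_(as.data.frame(nodal),
                 file.path(out_dir, "nodal_degree.tsv"))
      list(metrics = metrics, nodal = nodal)
    })
    results$metrics <- stage_out$metrics
    results$nodal <- stage_out$nodal
  }
  if ("nbs" %in% stages) {
    results$nbs <- run_stage("nbs", {
      need(cohort$connectivity, "connectome")
      nb <- nbs(cohort, covariates = covariates,
                primary_alpha = nbs_primary_alpha, n_perm = nbs_n_perm,
                statistic = nbs_statistic, seed = seed + 2L)
      write_tsv_(as.data.frame(nb$edge_t),
                 file.path(out_dir, "nbs_edge_t.tsv"), rownames = TRUE)
      write_tsv_(data.frame(null_max = nb$null_max_stats),
                 file.path(out_dir, "nbs_null_max.tsv"))
      comp <- tidy(nb)
      comp_json <- purrr::pmap(comp, function(component, n_nodes, n_edges,
                                              statistic, nodes, edges,
                                              fwer_p) {
        list(component = component, n_nodes = n_nodes, n_edges = n_edges,
             statistic = statistic, fwer_p = fwer_p, nodes = nodes,
             edges = edges)
      })
      jsonlite::write_json(comp_json,
                           file.path(out_dir, "nbs_components.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      nb
    })
  }
  if ("stats" %in% stages) {
    stage_out <- run_stage("stats", {
      metrics <- need(results$metrics, "metrics")
      covs <- cohort[, c("subject_id", "age", "sex", "onset_age", "duration")]
      mjoin <- dplyr::left_join(metrics, covs, by = "subject_id")
      global_comparisons <- compare_global_metrics(mjoin,
                                                   covariates = covariates)
      njoin <- dplyr::left_join(
        results$nodal,
        cohort[, c("subject_id", "age", "sex", "mean_fd")],
        by = "subject_id"
      )
      nodal_comparisons <- compare_nodal_degree(njoin,
                                                covariates = covariates,
                                                alpha = fdr_alpha)
      clinical_correlations <- correlate_clinical(mjoin)
      write_tsv_(as.data.frame(global_comparisons),
                 file.path(out_dir, "global_comparisons.tsv"))
      write_tsv_(as.data.frame(nodal_comparisons),
                 file.path(out_dir, "nodal_comparisons.tsv"))
      write_tsv_(as.data.frame(clinical_correlations),
                 file.path(out_dir, "clinical_correlations.tsv"))
      list(global_comparisons = global_comparisons,
           nodal_comparisons = nodal_comparisons,
           clinical_correlations = clinical_correlations)
    })
    results <- c(results, stage_out)
  }
  results$cohort <- cohort
  write_report(out_dir, results)
  invisible(results)
}

#' Write the summary report for a run
#'
#' Produces a human-readable `report.md` cross-referencing each number to its
#' source file. An incomplete run yields a partial report with explicit gaps.
#'
#' @param run_dir The run directory.
#' @param results Optional in-memory results list from [run_full_analysis()];
#'   when absent the report is assembled from the files in `run_dir`.
#' @return The report path, invisibly.
#' @export
write_report <- function(run_dir, results = NULL) {
  lines <- c("# Motor execution network analysis report", "")
  man_path <- file.path(run_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path)
    lines <- c(lines, sprintf(
      "Run of motornet %s, seed %s. Cohort: %s patients + %s controls, %s ROIs, %s time points (source: manifest.json).",
      man$version, man$seed, man$spec$n_patients, man$spec$n_controls,
      man$spec$n_rois, man$spec$n_timepoints
    ), sprintf(
      "Candidate edges: %d.",
      as.numeric(man$spec$n_rois) * (as.numeric(man$spec$n_rois) - 1) / 2
    ), "")
  }
  gm_path <- file.path(run_dir, "global_metrics.tsv")
  if (file.exists(gm_path)) {
    gm <- utils::read.table(gm_path, sep = "\t", header = TRUE)
    summ <- gm |>
      dplyr::group_by(.data$group, .data$graph_mode) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(c("cp", "lp", "gamma", "lambda", "sigma", "eg",
                        "eloc")),
        ~mean(.x, na.rm = TRUE)
      ), .groups = "drop")
    lines <- c(lines, "## Group-mean global metrics (global_metrics.tsv)", "",
               utils::capture.output(print(as.data.frame(summ),
                                           digits = 3)), "")
  } else {
    lines <- c(lines, "## Group-mean global metrics", "",
               "Not available: metrics stage did not run.", "")
  }
  nc_path <- file.path(run_dir, "nodal_comparisons.tsv")
  if (file.exists(nc_path)) {
    nc <- utils::read.table(nc_path, sep = "\t", header = TRUE)
    hits <- nc[nc$reject, , drop = FALSE]
    lines <- c(lines, "## Nodal degree group differences (nodal_comparisons.tsv)", "")
    if (nrow(hits) == 0) {
      lines <- c(lines, "No node survives FDR correction.", "")
    } else {
      lines <- c(lines, utils::capture.output(
        print(hits[, c("graph_mode", "label", "t_stat", "p_raw", "p_fdr")],
              digits = 3, row.names = FALSE)
      ), "")
    }
  }
  comp_path <- file.path(run_dir, "nbs_components.json")
  if (file.exists(comp_path)) {
    comps <- jsonlite::read_json(comp_path)
    lines <- c(lines, "## NBS components (nbs_components.json)", "")
    if (length(comps) == 0) {
      lines <- c(lines, "No suprathreshold components found.", "")
    } else {
      for (cp in comps) {
        lines <- c(lines, sprintf(
          "- component %s: %s edges / %s nodes, statistic %s, corrected p = %s; nodes: %s",
          cp$component, cp$n_edges, cp$n_nodes, cp$statistic,
          signif(as.numeric(cp$fwer_p), 3),
          paste(unlist(cp$nodes), collapse = ", ")
        ))
      }
      lines <- c(lines, "")
    }
  } else {
    lines <- c(lines, "## NBS components", "",
               "Not available: nbs stage did not run.", "")
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
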