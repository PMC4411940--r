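# One-call orchestration of the full analysis battery: MDSet -> strata ->
# centrality/enrichment/robustness/complex/class statistics, with every
# stochastic stage seeded from one top-level seed (a fixed sub-stream per
# stage, so stage-level re-runs reproduce report entries exactly).

#' @keywords internal
read_study_dir <- function(dir) {
  paths <- list(network = file.path(dir, "network.tsv"),
                essential = file.path(dir, "essential.txt"),
                complexes = file.path(dir, "complexes.tsv"),
                classes = file.path(dir, "classes.tsv"))
  if (!file.exists(paths$network)) {
    stop(sprintf("study directory %s has no network.tsv", dir))
  }
  list(
    network = read_edge_list(paths$network, "tsv", quiet = TRUE),
    essential = if (file.exists(paths$essential)) read_gene_set(paths$essential) else NULL,
    catalog = if (file.exists(paths$complexes)) read_complex_catalog(paths$complexes, "long") else NULL,
    annotation = if (file.exists(paths$classes)) read_class_annotation(paths$classes) else NULL
  )
}

#' @keywords internal
run_stage <- function(report, name, expr) {
  report[[name]] <- tryCatch(expr, error = function(e) {
    message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  report
}

#' Run the full MDSet analysis battery on a study
#'
#' Executes, in dependency order: network summary; exact MDSet; strata
#' (essential / MDSet / e-MDSet) with the one-sided Fisher overlap test;
#' degree-threshold enrichment curves and log-degree bin fractions;
#' betweenness bottleneck enrichment per stratum; degree-ordered deletion
#' robustness (e-MDSet versus equally many top-degree essential proteins);
#' complex participation coefficients with the e-MDSet versus essential
#' Wilcoxon comparison and intra/inter-complex interaction enrichment per
#' stratum; and functional class enrichment per stratum. Stages whose inputs
#' are missing (no essential list, catalog or annotation) are skipped with a
#' message; a failing stage is recorded in the report and does not abort
#' independent stages.
#'
#' @param study A study directory path (as written by [generate_study()]), a
#'   `synthetic_study`, or a list with components `network` (required),
#'   `essential`, `catalog`, `annotation`.
#' @param reps Randomizations per resampling null (default 10000).
#' @param seed Integer master seed; every stochastic stage derives a fixed
#'   sub-stream from it.
#' @param time_limit MDSet solver budget in seconds.
#' @param bottleneck_quantile Betweenness quantile defining bottlenecks.
#' @return An `mdset_report` (nested list; see [write_report()]).
#' @export
run_full_analysis <- function(study, reps = 10000, seed = 1L, time_limit = 60,
                              bottleneck_quantile = 0.20) {
  if (is.character(study)) study <- read_study_dir(study)
  net <- study$network
  stopifnot(inherits(net, "protein_network"))
  essential <- study$essential
  catalog <- study$catalog
  annotation <- study$annotation
  rep_out <- list(params = list(reps = reps, seed = seed, time_limit = time_limit,
                                bottleneck_quantile = bottleneck_quantile))

  rep_out <- run_stage(rep_out, "summary", network_summary(net))
  rep_out <- run_stage(rep_out, "mdset", solve_mdset(net, time_limit = time_limit))
  mdset <- rep_out$mdset

  strata <- NULL
  if (is.null(essential) || length(essential) == 0L) {
    message("no essential gene list: strata-dependent stages skipped")
    rep_out$strata <- "skipped"
  } else if (!inherits(mdset, "stage_error")) {
    rep_out <- run_stage(rep_out, "strata", stratify(net, mdset, essential))
    strata <- if (!inherits(rep_out$strata, "stage_error")) rep_out$strata
    if (!is.null(strata)) {
      rep_out <- run_stage(rep_out, "fisher", list(
        p = fisher_overlap(length(net$nodes), length(strata$mdset),
                           length(strata$essential_in_network),
                           length(strata$e_mdset)),
        n_nodes = length(net$nodes),
        n_mdset = length(strata$mdset),
        n_essential_in_network = length(strata$essential_in_network),
        n_e_mdset = length(strata$e_mdset)))
    }
  }

  strata_sets <- if (!is.null(strata)) {
    list(essential = strata$essential_in_network, mdset = strata$mdset,
         e_mdset = strata$e_mdset)
  } else if (!inherits(mdset, "stage_error")) {
    list(mdset = mdset$members)
  } else list()

  if (length(strata_sets)) {
    rep_out <- run_stage(rep_out, "degree_enrichment", {
      out <- lapply(seq_along(strata_sets), function(i) {
        degree_enrichment_curve(net, strata_sets[[i]], reps = reps,
                                seed = sub_seed(seed, 10L + i))
      })
      names(out) <- names(strata_sets)
      out
    })
  }

  if (!is.null(strata)) {
    rep_out <- run_stage(rep_out, "log_degree_bins",
                         log_degree_bin_fractions(net, strata$e_mdset,
                                                  strata$essential_in_network))
  }

  rep_out <- run_stage(rep_out, "bottleneck", {
    scores <- betweenness_centrality(net)
    bset <- bottleneck_set(scores, bottleneck_quantile)
    enr <- lapply(seq_along(strata_sets), function(i) {
      set_overlap_enrichment(net, bset, strata_sets[[i]], reps = reps,
                             seed = sub_seed(seed, 20L + i))
    })
    names(enr) <- names(strata_sets)
    list(set = bset, enrichment = enr)
  })

  if (!is.null(strata) && length(strata$e_mdset) > 0L) {
    rep_out <- run_stage(rep_out, "robustness",
                         compare_trajectories(net, strata$e_mdset,
                                              strata$essential_in_network))
  } else {
    rep_out$robustness <- "skipped"
  }

  if (is.null(catalog)) {
    message("no complex catalog: complex stages skipped")
    rep_out$participation <- rep_out$complex_interactions <- "skipped"
  } else {
    rep_out <- run_stage(rep_out, "participation", {
      pres <- participation_coefficients(net, catalog)
      cmp <- if (!is.null(strata) && length(strata$e_mdset) > 0L) {
        compare_participation(pres, strata$e_mdset, strata$essential_in_network,
                              labels = c("e-MDSet", "essential"))
      }
      list(coefficients = pres, comparison = cmp)
    })
    rep_out <- run_stage(rep_out, "complex_interactions", {
      out <- lapply(seq_along(strata_sets), function(i) {
        complex_null_enrichment(net, catalog, strata_sets[[i]], reps = reps,
                                seed = sub_seed(seed, 30L + i))
      })
      names(out) <- names(strata_sets)
      out
    })
  }

  if (is.null(annotation)) {
    message("no class annotation: functional class stage skipped")
    rep_out$class_enrichment <- "skipped"
  } else if (length(strata_sets)) {
    rep_out <- run_stage(rep_out, "class_enrichment", {
      universe <- intersect(names(annotation), net$nodes)
      out <- lapply(seq_along(strata_sets), function(i) {
        class_enrichment(annotation, universe,
                         intersect(strata_sets[[i]], universe), reps = reps,
                         seed = sub_seed(seed, 40L + i))
      })
      names(out) <- names(strata_sets)
      out
    })
  }
  structure(rep_out, class = "mdset_report")
}

#' @export
print.mdset_report <- function(x, ...) {
  cat("MDSet analysis report\n")
  if (!inherits(x$summary, "stage_error")) {
    cat("  network: "); print(x$summary)
  }
  if (inherits(x$mdset, "dominating_set")) {
    cat(sprintf("  MDSet: %d proteins (%.1f%%), status %s\n", x$mdset$objective,
                100 * x$mdset$objective / x$summary$n_nodes, x$mdset$status))
  }
  if (inherits(x$strata, "mdset_strata")) {
    cat(sprintf("  essential in network: %d; e-MDSet: %d (Fisher p = %.3g)\n",
                x$strata$sizes[["essential_in_network"]],
                x$strata$sizes[["e_mdset"]],
                if (!is.null(x$fisher) && !inherits(x$fisher, "stage_error"))
                  x$fisher$p else NA))
  }
  skipped <- names(x)[vapply(x, identical, TRUE, "skipped")]
  if (length(skipped)) cat("  skipped stages:", paste(skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mdset_report <- function(object, ...) {
  print(object)
  if (is.list(object$degree_enrichment)) {
    for (nm in names(object$degree_enrichment)) {
      cur <- object$degree_enrichment[[nm]]
      if (is.data.frame(cur) && nrow(cur) > 1) {
        rho <- stats::cor(cur$k, cur$enrichment, method = "spearman",
                          use = "complete.obs")
        cat(sprintf("  degree-enrichment trend (%s): Spearman rho = %.2f\n", nm, rho))
      }
    }
  }
  invisible(object)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full report, data frames as row-wise records)
#' plus one TSV per tabular stage.
#'
#' @param report An `mdset_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  if (is.list(report$degree_enrichment)) {
    for (nm in names(report$degree_enrichment)) {
      cur <- report$degree_enrichment[[nm]]
      if (is.data.frame(cur)) {
        utils::write.table(cur, file.path(dir, sprintf("degree_enrichment_%s.tsv", nm)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  if (inherits(report$robustness, "trajectory_comparison")) {
    utils::write.table(report$robustness$a, file.path(dir, "robustness_e_mdset.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report$robustness$b, file.path(dir, "robustness_essential_hubs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (is.list(report$class_enrichment)) {
    for (nm in names(report$class_enrichment)) {
      cur <- report$class_enrichment[[nm]]
      if (is.data.frame(cur)) {
        utils::write.table(cur, file.path(dir, sprintf("class_enrichment_%s.tsv", nm)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(dir)
}

#' @keywords internal
report_to_list <- function(x) {
  if (inherits(x, "protein_network")) {
    return(list(n_nodes = length(x$nodes), n_edges = nrow(x$edges), name = x$name))
  }
  if (is.list(x)) {
    if (is.data.frame(x)) return(x)
    return(lapply(unclass(x), report_to_list))
  }
  x
}
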