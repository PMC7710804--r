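#' @title Study pipeline: simulate, measure, compare, correlate, report
#'
#' @description End-to-end orchestration of a two-cohort connectome
#'   robustness study: obtain a dataset (synthetic or from disk), compute
#'   the four local measures (strength, betweenness centrality, clustering
#'   coefficient, node curvature) and the global measures per subject,
#'   compare cohorts nodewise (two-tailed, Holm-Sidak per measure family)
#'   and globally (one-tailed with stated directions), correlate measures
#'   with the CI index at the significant nodes, and assemble a report
#'   with a community/hemisphere summary and a reproducibility manifest.
#'   All randomness flows from one root seed, fanned out deterministically
#'   per subject and stage.
#' @name pipeline
NULL

#' Study configuration
#'
#' @param generator a [generator_config()] for synthetic studies, or
#'   `NULL` when reading a dataset from disk.
#' @param node_table,manifest paths to an on-disk study (used when
#'   `generator` is `NULL`).
#' @param idleness lazy-walk idleness for curvature (default 0.5).
#' @param ground_metric curvature ground metric, `"hop"` or `"weighted"`.
#' @param binarize analyse binarized graphs instead of weighted ones.
#' @param normalized_betweenness report normalized betweenness.
#' @param measures local measures to compute, subset of
#'   `c("strength", "betweenness", "clustering", "curvature")`.
#' @param alpha family-wise error level (default 0.05).
#' @param do_global compute and compare global measures.
#' @param small_worldness include the surrogate-based small-worldness
#'   statistic among the global measures (costly; default `FALSE`).
#' @param sw_nulls surrogates for small-worldness (default 100).
#' @param global_directions named direction vector for the one-tailed
#'   global tests (see [global_test_directions()]); required when
#'   `do_global = TRUE`.
#' @param correct_correlations apply Holm-Sidak over the correlated node
#'   set (default `FALSE`, mirroring uncorrected per-node plots).
#' @param seed root seed of the run.
#' @return list of class `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         node_table = NULL, manifest = NULL,
                         idleness = 0.5,
                         ground_metric = c("hop", "weighted"),
                         binarize = FALSE,
                         normalized_betweenness = FALSE,
                         measures = c("strength", "betweenness",
                                      "clustering", "curvature"),
                         alpha = 0.05,
                         do_global = TRUE,
                         small_worldness = FALSE,
                         sw_nulls = 100,
                         global_directions = NULL,
                         correct_correlations = FALSE,
                         seed = 1) {
  ground_metric <- match.arg(ground_metric)
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(generator = generator, node_table = node_table,
                 manifest = manifest, idleness = idleness,
                 ground_metric = ground_metric, binarize = binarize,
                 normalized_betweenness = normalized_betweenness,
                 measures = measures, alpha = alpha,
                 do_global = do_global,
                 small_worldness = small_worldness, sw_nulls = sw_nulls,
                 global_directions = global_directions,
                 correct_correlations = correct_correlations,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from YAML or JSON
#'
#' Unknown keys are rejected; the `generator` and `global_directions`
#' sections are converted to their structured forms.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a [study_config()].
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), c(known, "paths"))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$paths)) {
    raw$node_table <- raw$paths$node_table
    raw$manifest <- raw$paths$manifest
    raw$paths <- NULL
  }
  if (!is.null(raw$generator))
    raw$generator <- do.call(generator_config, raw$generator)
  else if (!is.null(raw$node_table))
    raw["generator"] <- list(NULL)
  if (!is.null(raw$global_directions))
    raw$global_directions <- do.call(global_test_directions,
                                     as.list(raw$global_directions))
  do.call(study_config, raw)
}

# Obtain the dataset a config describes: in-memory generator or on-disk
# node table + manifest.
resolve_dataset <- function(config) {
  if (!is.null(config$generator))
    return(generate_cohort_study(config$generator))
  if (is.null(config$node_table) || is.null(config$manifest))
    stop("config needs either a generator or node_table + manifest paths",
         call. = FALSE)
  parc <- read_node_table(config$node_table)
  read_cohort_manifest(config$manifest, parc)
}

#' Compute all per-subject measure tables for a study
#'
#' The measurement stage: for every included (non-borderline) subject,
#' the requested local measures and, optionally, the global measures.
#'
#' @param dataset a [cohort_dataset()].
#' @param config a [study_config()].
#' @return list of class `measure_tables`: `local` (named list of
#'   subjects x nodes matrices), `global` (data frame), `subject_ids`,
#'   `groups`, `ci`, `parcellation`.
#' @export
compute_measure_tables <- function(dataset, config = study_config()) {
  dataset <- included_subjects(dataset)
  subs <- dataset$subjects
  n <- length(subs)
  if (n < 4L) stop("need at least 2 subjects per cohort", call. = FALSE)
  N <- n_nodes(dataset$parcellation)
  local <- lapply(config$measures, function(m) {
    matrix(NA_real_, n, N)
  })
  names(local) <- config$measures
  global_rows <- vector("list", n)
  for (k in seq_len(n)) {
    cn <- subs[[k]]$connectome
    if (is.null(cn)) stop("subject ", subs[[k]]$subject_id,
                          " has no connectome", call. = FALSE)
    if (config$binarize) cn <- binarize(cn)
    orc <- NULL
    if ("curvature" %in% config$measures || config$do_global)
      orc <- orc_curvature(cn, idleness = config$idleness,
                           ground_metric = config$ground_metric)
    for (m in config$measures) {
      local[[m]][k, ] <- switch(m,
        strength = node_strength(cn),
        betweenness = betweenness_centrality(
          cn, normalized = config$normalized_betweenness),
        clustering = clustering_coefficient(cn),
        curvature = orc$node_curvatures)
    }
    if (config$do_global) {
      gm <- global_measures(cn,
                            small_worldness = config$small_worldness,
                            n_null = config$sw_nulls,
                            seed = fan_out_seed(config$seed, 100000 + k))
      global_rows[[k]] <- data.frame(
        density = gm$density,
        global_efficiency = gm$global_efficiency,
        characteristic_path_length = gm$characteristic_path_length,
        diameter = gm$diameter,
        clustering_mean = gm$clustering_mean,
        small_worldness = gm$small_worldness,
        curvature = orc$global_curvature)
    }
  }
  structure(list(
    local = local,
    global = if (config$do_global) do.call(rbind, global_rows) else NULL,
    subject_ids = vapply(subs, function(s) s$subject_id, character(1)),
    groups = cohort_groups(dataset),
    ci = vapply(subs, function(s) s$ci_index, numeric(1)),
    parcellation = dataset$parcellation), class = "measure_tables")
}

#' Compare, correlate and summarise from measure tables
#'
#' The analysis stage, separated from measurement so that a report can be
#' regenerated from saved measure tables: nodewise comparisons per
#' measure (each its own Holm-Sidak family of m = N nodes), the global
#' one-tailed comparison, correlations of each measure with the CI index
#' at its significant nodes, and the significant-node summary grouped by
#' functional community and hemisphere.
#'
#' @param mt a [compute_measure_tables()] result.
#' @param config a [study_config()].
#' @return list of class `study_report`.
#' @export
analyze_measures <- function(mt, config = study_config()) {
  stopifnot(inherits(mt, "measure_tables"))
  is_msci <- mt$groups == "MSCI"
  is_msni <- mt$groups == "MSNI"
  if (sum(is_msci) < 2L || sum(is_msni) < 2L)
    stop("each cohort needs at least 2 subjects", call. = FALSE)
  nodewise <- lapply(names(mt$local), function(m) {
    nodewise_comparison(mt$local[[m]][is_msci, , drop = FALSE],
                        mt$local[[m]][is_msni, , drop = FALSE],
                        alpha = config$alpha, measure_name = m)
  })
  names(nodewise) <- names(mt$local)

  global_table <- NULL
  if (!is.null(mt$global)) {
    if (is.null(config$global_directions))
      stop("global comparison requires config$global_directions",
           call. = FALSE)
    gtab <- mt$global
    keep <- vapply(gtab, function(col) !all(is.na(col)), logical(1))
    global_table <- global_comparison(
      gtab[is_msci, keep, drop = FALSE],
      gtab[is_msni, keep, drop = FALSE],
      directions = config$global_directions, alpha = config$alpha)
  }

  correlations <- NULL
  corr_rows <- lapply(names(nodewise), function(m) {
    sig <- nodewise[[m]]$node[which(nodewise[[m]]$reject)]
    if (length(sig) == 0L) return(NULL)
    correlate_nodes_with_ci(mt$local[[m]], mt$ci, nodes = sig,
                            measure_name = m,
                            correct = config$correct_correlations,
                            alpha = config$alpha)
  })
  corr_rows <- corr_rows[!vapply(corr_rows, is.null, logical(1))]
  if (length(corr_rows) > 0L) correlations <- do.call(rbind, corr_rows)

  global_ci_correlation <- NULL
  if (!is.null(mt$global)) {
    global_ci_correlation <- do.call(rbind, lapply(
      names(mt$global)[vapply(mt$global, function(col) !all(is.na(col)),
                              logical(1))],
      function(m) {
        res <- tryCatch(correlate_with_ci(mt$global[[m]], mt$ci),
                        error = function(e)
                          list(pearson_r = NA_real_, p_value = NA_real_,
                               n = length(mt$ci)))
        data.frame(measure = m, pearson_r = res$pearson_r,
                   p_value = res$p_value, n = res$n)
      }))
  }

  summary <- significant_node_summary(nodewise, mt$parcellation)
  manifest <- list(
    package_version = as.character(utils::packageVersion("orcnet")),
    n_subjects = length(mt$subject_ids),
    n_msci = sum(is_msci), n_msni = sum(is_msni),
    n_nodes = n_nodes(mt$parcellation),
    params = config[c("idleness", "ground_metric", "binarize",
                      "normalized_betweenness", "measures", "alpha",
                      "small_worldness", "sw_nulls",
                      "correct_correlations", "seed")],
    global_directions = as.list(config$global_directions),
    generator = if (!is.null(config$generator))
      unclass(config$generator) else NULL)

  structure(list(nodewise = nodewise, global = global_table,
                 correlations = correlations,
                 global_ci_correlation = global_ci_correlation,
                 summary = summary, manifest = manifest),
            class = "study_report")
}

# Group the significant nodes of every measure family by functional
# community and hemisphere, with left/right asymmetry counts.
significant_node_summary <- function(nodewise, parc) {
  rows <- lapply(names(nodewise), function(m) {
    tab <- nodewise[[m]]
    sig <- which(tab$reject)
    if (length(sig) == 0L) return(NULL)
    data.frame(measure = m, node = sig,
               node_id = parc$node_id[sig], label = parc$label[sig],
               community = parc$community[sig],
               hemisphere = parc$hemisphere[sig],
               direction = ifelse(tab$direction[sig] > 0,
                                  "MSCI_higher", "MSCI_lower"),
               adjusted_p = tab$adjusted_p[sig])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  nodes <- if (length(rows) > 0L) do.call(rbind, rows)
    else data.frame(measure = character(0), node = integer(0),
                    node_id = integer(0), label = character(0),
                    community = character(0), hemisphere = character(0),
                    direction = character(0), adjusted_p = numeric(0))
  list(significant_nodes = nodes,
       n_left = sum(nodes$hemisphere == "L"),
       n_right = sum(nodes$hemisphere == "R"))
}

#' Run a complete study
#'
#' @param config a [study_config()].
#' @param dataset optional pre-built [cohort_dataset()]; when omitted the
#'   dataset is generated or read according to the config.
#' @return a `study_report` (see [analyze_measures()]) with the measure
#'   tables attached as attribute `"measure_tables"`.
#' @export
run_study <- function(config = study_config(), dataset = NULL) {
  if (is.null(dataset)) dataset <- resolve_dataset(config)
  mt <- compute_measure_tables(dataset, config)
  report <- analyze_measures(mt, config)
  attr(report, "measure_tables") <- mt
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report\n")
  cat(sprintf("  cohorts: %d MSCI vs %d MSNI, %d nodes\n",
              x$manifest$n_msci, x$manifest$n_msni, x$manifest$n_nodes))
  for (m in names(x$nodewise)) {
    nsig <- sum(x$nodewise[[m]]$reject, na.rm = TRUE)
    cat(sprintf("  %-12s %d/%d nodes significant (alpha %.2f, Holm-Sidak)\n",
                m, nsig, attr(x$nodewise[[m]], "m"),
                attr(x$nodewise[[m]], "alpha")))
  }
  if (!is.null(x$global)) {
    sig <- x$global$measure[x$global$reject]
    cat(sprintf("  global: %s\n",
                if (length(sig)) paste("significant:",
                                       paste(sig, collapse = ", "))
                else "no significant measure"))
  }
  cat(sprintf("  significant nodes: %d left, %d right hemisphere\n",
              x$summary$n_left, x$summary$n_right))
  invisible(x)
}

# ---- file-based stages -----------------------------------------------

measure_table_df <- function(mt, m) {
  tab <- as.data.frame(mt$local[[m]])
  names(tab) <- paste0("node_", seq_len(ncol(tab)))
  cbind(data.frame(subject_id = mt$subject_ids, group = mt$groups,
                   ci_index = mt$ci), tab)
}

#' Write measure tables to a directory
#'
#' One TSV per local measure (`measure_<name>.tsv`: `subject_id`,
#' `group`, `ci_index`, `node_1` ... `node_N`), the global table
#' (`global_measures.tsv`) and a copy of the node table
#' (`nodes.tsv`) so the analysis stage is self-contained.
#'
#' @param mt a [compute_measure_tables()] result.
#' @param dir output directory.
#' @return `invisible(dir)`.
#' @export
write_measure_tables <- function(mt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(mt$local))
    write_results_table(measure_table_df(mt, m),
                        file.path(dir, paste0("measure_", m, ".tsv")))
  if (!is.null(mt$global))
    write_results_table(
      cbind(data.frame(subject_id = mt$subject_ids, group = mt$groups,
                       ci_index = mt$ci), mt$global),
      file.path(dir, "global_measures.tsv"))
  write_node_table(mt$parcellation, file.path(dir, "nodes.tsv"))
  invisible(dir)
}

#' Read measure tables back from a directory
#'
#' @param dir directory written by [write_measure_tables()].
#' @return a `measure_tables` object.
#' @export
read_measure_tables <- function(dir) {
  parc <- read_node_table(file.path(dir, "nodes.tsv"))
  files <- list.files(dir, pattern = "^measure_.*\\.tsv$")
  if (length(files) == 0L)
    stop("no measure tables found in ", dir, call. = FALSE)
  local <- list()
  meta <- NULL
  for (f in files) {
    m <- sub("^measure_(.*)\\.tsv$", "\\1", f)
    tab <- read_results_table(file.path(dir, f))
    meta <- tab[, c("subject_id", "group", "ci_index")]
    local[[m]] <- as.matrix(tab[, grep("^node_", names(tab)), drop = FALSE])
    dimnames(local[[m]]) <- NULL
  }
  gpath <- file.path(dir, "global_measures.tsv")
  global <- NULL
  if (file.exists(gpath)) {
    gtab <- read_results_table(gpath)
    global <- gtab[, setdiff(names(gtab),
                             c("subject_id", "group", "ci_index")),
                   drop = FALSE]
  }
  order_measures <- intersect(c("strength", "betweenness", "clustering",
                                "curvature"), names(local))
  structure(list(local = local[order_measures], global = global,
                 subject_ids = as.character(meta$subject_id),
                 groups = as.character(meta$group),
                 ci = as.numeric(meta$ci_index),
                 parcellation = parc), class = "measure_tables")
}

#' Write a study report to a directory
#'
#' Nodewise tables (`nodewise_<measure>.tsv`), the global comparison
#' (`global_comparison.tsv`), correlation tables, and a machine-readable
#' JSON summary (`summary.json`: significant nodes with communities and
#' directions, hemisphere asymmetry counts, run manifest).
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `invisible(dir)`.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(report$nodewise))
    write_results_table(report$nodewise[[m]],
                        file.path(dir, paste0("nodewise_", m, ".tsv")))
  if (!is.null(report$global))
    write_results_table(report$global,
                        file.path(dir, "global_comparison.tsv"))
  if (!is.null(report$correlations))
    write_results_table(report$correlations,
                        file.path(dir, "correlations.tsv"))
  if (!is.null(report$global_ci_correlation))
    write_results_table(report$global_ci_correlation,
                        file.path(dir, "global_ci_correlation.tsv"))
  jsonlite::write_json(
    list(significant_nodes = report$summary$significant_nodes,
         hemisphere_asymmetry = list(left = report$summary$n_left,
                                     right = report$summary$n_right),
         manifest = report$manifest),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(dir)
}

# ---- command-line interface ------------------------------------------

cli_usage <- function() {
  paste(
    "usage: orcnet <command> [options]",
    "",
    "commands:",
    "  simulate   --config <file> [--seed <int>] --out <dir>",
    "  measures   --config <file> --study <dir> --out <dir>",
    "  compare    --config <file> --measures-dir <dir> --out <dir>",
    "  correlate  --config <file> --measures-dir <dir> --out <dir>",
    "  report     --config <file> --measures-dir <dir> --out <dir>",
    "  run        --config <file> [--seed <int>] --out <dir>",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(argv)) stop("missing value for ", a, call. = FALSE)
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `measures`, `compare`, `correlate`, `report`
#' and `run` (see the thin wrapper script in `inst/cli/orcnet`). Returns
#' an exit code instead of quitting so it can be tested in-process: 0 on
#' success, 2 on usage or validation errors.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
orcnet_main <- function(argv) {
  if (length(argv) == 0L ||
      !argv[1] %in% c("simulate", "measures", "compare", "correlate",
                      "report", "run")) {
    message(cli_usage())
    return(2L)
  }
  cmd <- argv[1]
  res <- tryCatch({
    opts <- parse_cli_args(argv[-1])
    if (is.null(opts$config)) stop("--config is required", call. = FALSE)
    config <- load_study_config(opts$config)
    if (!is.null(opts$seed)) {
      config$seed <- as.integer(opts$seed)
      if (!is.null(config$generator))
        config$generator$seed <- as.integer(opts$seed)
    }
    if (is.null(opts$out)) stop("--out is required", call. = FALSE)

    if (cmd == "simulate") {
      if (is.null(config$generator))
        stop("simulate needs a generator section in the config",
             call. = FALSE)
      simulate_study_files(config$generator, opts$out)
    } else if (cmd == "run") {
      report <- run_study(config)
      write_measure_tables(attr(report, "measure_tables"),
                           file.path(opts$out, "measures"))
      write_study_report(report, opts$out)
    } else if (cmd == "measures") {
      if (is.null(opts$study)) stop("--study is required", call. = FALSE)
      config$node_table <- file.path(opts$study, "nodes.tsv")
      config$manifest <- file.path(opts$study, "manifest.tsv")
      config["generator"] <- list(NULL)
      mt <- compute_measure_tables(resolve_dataset(config), config)
      write_measure_tables(mt, opts$out)
    } else {
      if (is.null(opts$measures_dir))
        stop("--measures-dir is required", call. = FALSE)
      mt <- read_measure_tables(opts$measures_dir)
      report <- analyze_measures(mt, config)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      if (cmd == "compare") {
        for (m in names(report$nodewise))
          write_results_table(report$nodewise[[m]],
                              file.path(opts$out,
                                        paste0("nodewise_", m, ".tsv")))
        if (!is.null(report$global))
          write_results_table(report$global,
                              file.path(opts$out, "global_comparison.tsv"))
      } else if (cmd == "correlate") {
        if (!is.null(report$correlations))
          write_results_table(report$correlations,
                              file.path(opts$out, "correlations.tsv"))
        if (!is.null(report$global_ci_correlation))
          write_results_table(report$global_ci_correlation,
                              file.path(opts$out,
                                        "global_ci_correlation.tsv"))
      } else {  # report
        write_study_report(report, opts$out)
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(cli_usage())
    2L
  })
  res
}
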