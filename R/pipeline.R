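#' Default pipeline configuration
#'
#' Flat list of every tunable of the end-to-end run; see [run_all()].
#'
#' @param ... overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_total = 0, min_prevalence = 0.5,
    threshold = NA_real_,          # NA = automatic RMT scan
    t_min = 0.30, t_max = 0.99, t_step = 0.01,
    min_eigenvalues = 30, nnsd_bins = 30, nnsd_alpha = 0.05,
    min_module_size = 6,
    mantel_permutations = 999, null_reps = 100,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

write_config <- function(cfg, path) {
  writeLines(sprintf("%s\t%s", names(cfg),
                     vapply(cfg, format, character(1))), path)
  invisible(path)
}

#' Run the full network pipeline
#'
#' One call from OTU table to every artifact of the analysis: filtering,
#' log transform, Pearson similarity, RMT threshold (automatic scan or a
#' fixed value), network construction and export, topological index
#' panel, degree-preserving null comparison, module detection, Zi-Pi
#' roles, module eigengenes and their hierarchy, and — when an
#' environment table is supplied — the module-environment heatmap and
#' Mantel tests. All outputs are plain text in `out_dir`; the
#' configuration and seed are written alongside so a run is fully
#' reproducible.
#'
#' @param otu an [otu_table] or path to one.
#' @param env optional [env_table] or path; environment stages are
#'   skipped (with a logged notice) when absent.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return invisibly, a named list (manifest) of the objects computed:
#'   `scan`, `network`, `report`, `partition`, `roles`, `eigengenes`,
#'   `hierarchy`, `null`, `heatmap`, `mantel`, `diversity`, plus
#'   `outputs` (paths written).
#' @export
run_all <- function(otu, env = NULL, out_dir, config = pipeline_config(),
                    verbose = FALSE) {
  if (is.character(otu)) otu <- read_otu_table(otu)
  if (is.character(env)) env <- read_env_table(env)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  paths <- c()
  emit <- function(name) paths[name] <<- file.path(out_dir, name)

  stage <- "config"
  res <- tryCatch({
    write_config(config, emit("run_config.txt"))

    stage <- "diversity"
    say("diversity: %d samples", ncol(otu))
    div <- diversity_panel(otu)
    utils::write.table(div, emit("diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "similarity"
    filt <- filter_otus(otu, config$min_total, config$min_prevalence)
    say("filter: %d of %d OTUs kept", nrow(filt), nrow(otu))
    la <- log_transform(filt)
    sim <- pearson_similarity(la)

    stage <- "threshold"
    manual <- if (is.na(config$threshold)) NULL else config$threshold
    scan <- scan_thresholds(sim, t_min = config$t_min, t_max = config$t_max,
                            step = config$t_step,
                            min_eigenvalues = config$min_eigenvalues,
                            n_bins = config$nnsd_bins,
                            alpha = config$nnsd_alpha,
                            threshold = manual,
                            run_scan = is.null(manual))
    if (!is.null(scan$scan)) write_scan(scan, emit("threshold_scan.tsv"))
    thr <- scan$chosen_threshold
    say("threshold: %.3f (%s)", thr, if (scan$auto) "RMT scan" else "manual")

    stage <- "network"
    g <- build_network(sim, thr, taxonomy = taxonomy(filt))
    write_network(g, emit("network.graphml"), emit("network.sif"))
    say("network: %d nodes, %d links", igraph::vcount(g), igraph::ecount(g))

    stage <- "modules"
    part <- detect_modules(g)
    roles <- zi_pi(g, part)
    utils::write.table(roles, emit("node_roles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    eig <- module_eigengene(part, la, min_module_size = config$min_module_size)
    hier <- NULL
    if (!is.null(eig$eigengenes)) {
      edf <- data.frame(sample = rownames(eig$eigengenes), eig$eigengenes,
                        check.names = FALSE)
      utils::write.table(edf, emit("eigengenes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      hier <- eigengene_hierarchy(eig, newick_path = emit("eigengene_hierarchy.nwk"))
    }
    say("modules: %d total, Q = %.3f", length(part$sizes), part$modularity)

    stage <- "report"
    rep <- suppressWarnings(topology_stats(g, partition = part))
    write_report(rep, emit("topology_report.tsv"), partition = part,
                 roles = roles)

    stage <- "null_model"
    nul <- null_comparison(g, n_reps = config$null_reps, seed = config$seed)
    utils::write.table(nul, emit("null_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    heat <- NULL; mant <- NULL
    if (is.null(env)) {
      say("environment table absent: Mantel and heatmap stages skipped")
    } else {
      stage <- "env_association"
      mant <- mantel_panel(otu, env, n_perm = config$mantel_permutations,
                           seed = config$seed)
      utils::write.table(mant, emit("mantel.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (!is.null(eig$eigengenes)) {
        heat <- module_env_heatmap(eig, env)
        utils::write.table(data.frame(module = rownames(heat$r), heat$r,
                                      check.names = FALSE),
                           emit("module_env_r.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(data.frame(module = rownames(heat$p), heat$p,
                                      check.names = FALSE),
                           emit("module_env_p.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }

    list(scan = scan, network = g, report = rep, partition = part,
         roles = roles, eigengenes = eig, hierarchy = hier, null = nul,
         heatmap = heat, mantel = mant, diversity = div, outputs = paths)
  }, error = function(e) {
    log_lines <<- c(log_lines,
                    sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
                    sprintf("partial outputs: %s", paste(names(paths), collapse = ", ")))
    writeLines(log_lines, logf)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  writeLines(log_lines, logf)
  invisible(res)
}
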