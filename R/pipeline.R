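# End-to-end orchestration: simulate -> decompose -> workspace -> roles ->
# stats, with every artefact written to disk alongside provenance, and a
# manifest of file checksums so identical configurations provably produce
# identical outputs.

#' Build a pipeline configuration
#'
#' Collects every knob of the synthetic end-to-end analysis with its
#' default. All stochastic stages derive their seeds from `seed`.
#'
#' @param n_nodes,module_sizes Network size and module structure.
#' @param within_coupling,between_coupling,noise_corr_within Generator
#'   parameters (see [make_modular_system()]).
#' @param n_subjects Subjects per condition.
#' @param conditions Condition labels (first = baseline).
#' @param design `"paired"` or `"unpaired"`.
#' @param effect_edges,effect_scale Planted condition effect (see
#'   [simulate_group_dataset()]).
#' @param n_timepoints Timepoints per scan.
#' @param tau Lag in samples for the information measures.
#' @param measures Networks to compute.
#' @param workspace_rule `"sign"` or `"percentile"`.
#' @param threshold,alpha,n_perm,component_measure NBS settings.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_nodes = 12, module_sizes = c(4, 4, 4),
                            within_coupling = 0.2, between_coupling = 0.05,
                            noise_corr_within = 0.3, n_subjects = 10,
                            conditions = c("baseline", "effect"),
                            design = "paired",
                            effect_edges = cbind(1, 5), effect_scale = 1.5,
                            n_timepoints = 500, tau = 1,
                            measures = c("synergy", "redundancy", "phi_r"),
                            workspace_rule = "sign",
                            threshold = 9, alpha = 0.05, n_perm = 1000,
                            component_measure = "intensity",
                            seed = 1, out_dir = tempfile("phidnet_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$effect_edges)) {
    vals$effect_edges <- matrix(unlist(vals$effect_edges), ncol = 2,
                                byrow = TRUE)
  }
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL # location must not change the hash
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (sum(config$module_sizes) != config$n_nodes) {
    stop("validation error: module_sizes must sum to n_nodes", call. = FALSE)
  }
  if (length(config$conditions) < 2) {
    stop("validation error: stats stage needs at least two conditions",
         call. = FALSE)
  }
  if (!all(config$measures %in%
           c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r"))) {
    stop("validation error: unknown measure requested", call. = FALSE)
  }
  if (!all(c("synergy", "redundancy") %in% config$measures)) {
    stop("validation error: workspace stage needs synergy and redundancy",
         call. = FALSE)
  }
  invisible(config)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> decompose -> workspace -> roles -> stats on a
#' modular synthetic system, writing every intermediate artefact (timeseries,
#' per-subject and group-averaged networks with provenance sidecars, node
#' table, NBS report) under `config$out_dir`, and returns a manifest listing
#' each file with its MD5 checksum. Re-running an identical configuration
#' reproduces identical artefacts (and therefore identical checksums).
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return The manifest (invisibly also written as `manifest.json`): config
#'   hash, seed, stage timings and a file/checksum table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(format(length(log_lines) + 1), ": ", ...))
  }
  timings <- c()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    note("stage ", name, " done")
    res
  }

  seeds <- child_seeds(config$seed, 3)

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    ms <- make_modular_system(config$n_nodes, config$module_sizes,
                              within_coupling = config$within_coupling,
                              between_coupling = config$between_coupling,
                              noise_corr_within = config$noise_corr_within,
                              seed = seeds[1])
    ds <- simulate_group_dataset(ms$system, config$n_subjects,
                                 conditions = config$conditions,
                                 effect_edges = config$effect_edges,
                                 effect_scale = config$effect_scale,
                                 n_timepoints = config$n_timepoints,
                                 design = config$design, seed = seeds[2])
    dir.create(file.path(out, "timeseries"), showWarnings = FALSE)
    for (r in seq_len(nrow(ds))) {
      write_timeseries(ds$ts[[r]], file.path(
        out, "timeseries",
        paste0(ds$subject_id[r], "_", ds$condition[r], ".tsv")))
    }
    write_partition(ms$partition, file.path(out, "partition.tsv"))
    jsonlite::write_json(
      list(A = ms$system$A, noise_cov = ms$system$noise_cov,
           region_ids = ms$system$region_ids),
      file.path(out, "system.json"), digits = NA, matrix = "rowmajor")
    list(ms = ms, ds = ds)
  })

  # -- decompose -----------------------------------------------------------
  nets <- stage("decompose", {
    dir.create(file.path(out, "networks"), showWarnings = FALSE)
    per_subject <- lapply(seq_len(nrow(sim$ds)), function(r) {
      nw <- pairwise_networks(sim$ds$ts[[r]], tau = config$tau,
                              measures = config$measures)
      for (m in names(nw)) {
        write_network(nw[[m]], file.path(
          out, "networks",
          paste0(sim$ds$subject_id[r], "_", sim$ds$condition[r], "_", m,
                 ".tsv")),
          extra = list(config_hash = hash, seed = config$seed))
      }
      nw
    })
    baseline <- sim$ds$condition == config$conditions[1]
    averaged <- lapply(config$measures, function(m) {
      avg <- group_average(lapply(per_subject[baseline], `[[`, m))
      write_network(avg, file.path(out, paste0("group_", m, ".tsv")),
                    extra = list(config_hash = hash, seed = config$seed,
                                 group = config$conditions[1]))
      avg
    })
    names(averaged) <- config$measures
    list(per_subject = per_subject, averaged = averaged)
  })

  # -- workspace + roles ---------------------------------------------------
  profiles <- stage("workspace_roles", {
    prof <- node_profiles(nets$averaged$synergy, nets$averaged$redundancy,
                          partition = sim$ms$partition,
                          rule = config$workspace_rule)
    write_node_table(prof, file.path(out, "node_profiles.tsv"))
    prof
  })

  # -- stats ---------------------------------------------------------------
  stats_res <- stage("stats", {
    measure <- if ("phi_r" %in% config$measures) "phi_r"
               else config$measures[1]
    cond_a <- config$conditions[1]
    cond_b <- config$conditions[2]
    grab <- function(cond) as_edge_samples(
      lapply(which(sim$ds$condition == cond),
             function(r) nets$per_subject[[r]][[measure]]),
      subject_ids = sim$ds$subject_id[sim$ds$condition == cond])
    res <- nbs(grab(cond_a), grab(cond_b), design = config$design,
               threshold = config$threshold,
               component_measure = config$component_measure,
               n_perm = config$n_perm, alpha = config$alpha,
               seed = seeds[3])
    write_edge_list(res$edges, file.path(out, "nbs_edges.tsv"))
    jsonlite::write_json(
      list(measure = measure, contrast = paste(cond_b, "vs", cond_a),
           threshold = res$threshold, n_perm = res$n_perm,
           alpha = res$alpha, config_hash = hash,
           components = res$components,
           signed_f_sum = res$signed_f_sum),
      file.path(out, "nbs_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res
  })

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.json", "run_log.txt")))
  manifest <- list(
    tool = paste0("phidnet ",
                  as.character(utils::packageVersion("phidnet"))),
    config_hash = hash, seed = config$seed, tau = config$tau,
    units = "nats", stage_timings_s = as.list(timings),
    files = tibble::tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(out, files))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(manifest = manifest, profiles = profiles,
                 nbs = stats_res, out_dir = out))
}
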