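#' Build a resolved run configuration
#'
#' Merges user settings (an R list or a YAML file path) over the package
#' defaults. Numeric defaults are taken directly from [beta_params()],
#' [sasa_params()] and the module defaults, so the pipeline has a single
#' source of truth. Validation problems are aggregated into one error.
#'
#' @param config named list or path to a YAML file. Recognised sections:
#'   `input` (`structure`, `format`, `trajectory`, `trajectory_format`),
#'   `groups` (group name -> chain ids), `beta` (fields of [beta_params()]),
#'   `sasa` (fields of [sasa_params()]), `cluster` (`group`, `cutoff`),
#'   `contact` (`cutoff`), `interface` (`group_a`, `group_b`), `stride`,
#'   `outdir`, `seed`, `class_table` (path).
#' @return list of class `run_config` with fully resolved values.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bp <- beta_params(); sp <- sasa_params()
  defaults <- list(
    input = list(structure = NULL, format = "auto", trajectory = NULL,
                 trajectory_format = "auto"),
    groups = NULL,
    beta = list(angle_min = bp$angle_min, contact_dist = bp$contact_dist,
                min_seq_sep = bp$min_seq_sep,
                min_strand_len = bp$min_strand_len),
    sasa = list(probe_radius = sp$probe_radius,
                n_sphere_points = sp$n_sphere_points,
                default_bead_radius = sp$default_bead_radius),
    cluster = list(group = "detergent", cutoff = 0.6),
    contact = list(cutoff = 0.6),
    interface = list(group_a = "protein", group_b = "peptide"),
    pair_dist = 0.6,
    stride = 1,
    outdir = ".",
    seed = 1,
    class_table = NULL
  )
  merged <- utils::modifyList(defaults, config)

  problems <- character(0)
  if (!is.null(merged$input$structure) &&
      !file.exists(merged$input$structure)) {
    problems <- c(problems, paste0("input structure file not found: ",
                                   merged$input$structure))
  }
  if (!is.null(merged$input$trajectory) &&
      !file.exists(merged$input$trajectory)) {
    problems <- c(problems, paste0("input trajectory file not found: ",
                                   merged$input$trajectory))
  }
  if (merged$stride < 1) problems <- c(problems, "stride must be >= 1")
  for (p in c("probe_radius", "n_sphere_points", "default_bead_radius")) {
    if (!is.numeric(merged$sasa[[p]])) {
      problems <- c(problems, paste0("sasa$", p, " must be numeric"))
    }
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(merged) <- "run_config"
  merged
}

config_beta_params <- function(config) {
  do.call(beta_params, config$beta)
}

config_sasa_params <- function(config) {
  do.call(sasa_params, config$sasa)
}

load_config_inputs <- function(config) {
  if (is.null(config$input$structure)) {
    stop("run configuration has no input structure", call. = FALSE)
  }
  ct <- if (is.null(config$class_table)) default_class_table()
  else read_class_table(config$class_table)
  st <- read_structure(config$input$structure,
                       format = config$input$format, class_table = ct,
                       groups = config$groups)
  traj <- NULL
  if (!is.null(config$input$trajectory)) {
    traj <- read_trajectory(config$input$trajectory,
                            format = config$input$trajectory_format,
                            system = st$system)
  }
  list(system = st$system, frame = st$frame, trajectory = traj)
}

write_run_log <- function(config, path, stage) {
  lines <- c(
    paste0("stage: ", stage),
    paste0("structure: ", config$input$structure %||% "(in-memory)"),
    paste0("trajectory: ", config$input$trajectory %||% "(none)"),
    paste0("beta.angle_min: ", config$beta$angle_min),
    paste0("beta.contact_dist: ", config$beta$contact_dist),
    paste0("beta.min_seq_sep: ", config$beta$min_seq_sep),
    paste0("beta.min_strand_len: ", config$beta$min_strand_len),
    paste0("sasa.probe_radius: ", config$sasa$probe_radius),
    paste0("sasa.n_sphere_points: ", config$sasa$n_sphere_points),
    paste0("sasa.default_bead_radius: ", config$sasa$default_bead_radius),
    paste0("cluster.cutoff: ", config$cluster$cutoff),
    paste0("stride: ", config$stride),
    paste0("seed: ", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

stage_paths <- function(config, names) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  setNames(file.path(config$outdir, names), names)
}

#' Run the beta-assignment stage
#'
#' Assigns beta structure on the input structure (and, when a trajectory is
#' configured, computes the beta-content time series), writing
#' `beta_assignment.tsv`, optionally `beta_timeseries.csv`, and a
#' `beta.log` with every parameter used.
#'
#' @param config a [run_config()] (or list/path coerced through it).
#' @return list with `assignment`, `timeseries` (or NULL) and `files`.
#' @export
run_beta <- function(config) {
  config <- as_run_config(config)
  inp <- load_config_inputs(config)
  params <- config_beta_params(config)
  assignment <- assign_beta(inp$frame, inp$system, params)
  files <- stage_paths(config, c("beta_assignment.tsv", "beta.log"))
  write_beta_tsv(assignment, files[[1]])
  ts <- NULL
  if (!is.null(inp$trajectory)) {
    ts <- beta_timeseries(inp$trajectory, params, stride = config$stride)
    tsf <- file.path(config$outdir, "beta_timeseries.csv")
    write_timeseries_csv(ts, tsf, value_col = "beta_percent")
    files <- c(files, beta_timeseries.csv = tsf)
  }
  write_run_log(config, files[[2]], "beta")
  list(assignment = assignment, timeseries = ts, files = files)
}

#' Run the buried-interface stage
#'
#' Computes the buried interface area between the two configured groups on
#' the structure (and per frame over the trajectory when configured),
#' writing `interface.csv` and `interface.log`.
#'
#' @param config a [run_config()].
#' @return list with `interface`, `timeseries` (or NULL) and `files`.
#' @export
run_interface <- function(config) {
  config <- as_run_config(config)
  inp <- load_config_inputs(config)
  params <- config_sasa_params(config)
  ga <- config$interface$group_a; gb <- config$interface$group_b
  res <- interface_area(inp$frame, inp$system, ga, gb, params)
  files <- stage_paths(config, c("interface.csv", "interface.log"))
  ts <- NULL
  if (!is.null(inp$trajectory)) {
    ts <- interface_timeseries(inp$trajectory, ga, gb, params,
                               stride = config$stride)
  } else {
    ts <- data.frame(time_ps = inp$frame$time, area_nm2 = res$area)
  }
  write_timeseries_csv(ts, files[[1]], value_col = "area_nm2")
  write_run_log(config, files[[2]], "interface")
  list(interface = res, timeseries = ts, files = files)
}

#' Run the aggregate-clustering stage
#'
#' Single-linkage clustering of the configured molecule group, writing
#' `clusters.csv` (cluster_id, size, member_chains) and `clusters.log`.
#'
#' @param config a [run_config()].
#' @return list with `clusters` and `files`.
#' @export
run_clusters <- function(config) {
  config <- as_run_config(config)
  inp <- load_config_inputs(config)
  cl <- cluster_molecules(inp$frame, inp$system, config$cluster$group,
                          cutoff = config$cluster$cutoff)
  files <- stage_paths(config, c("clusters.csv", "clusters.log"))
  write_cluster_csv(cl, files[[1]])
  write_run_log(config, files[[2]], "clusters")
  list(clusters = cl, files = files)
}

#' Run the combined report
#'
#' Runs beta assignment, strand finding and pairing, interface area (when
#' both groups exist) and clustering (when the molecule group exists), and
#' writes a plain-text `report.txt` plus the per-stage CSV/TSV outputs.
#'
#' @param config a [run_config()].
#' @return list with the per-stage results and `files`.
#' @export
run_report <- function(config) {
  config <- as_run_config(config)
  inp <- load_config_inputs(config)
  bp <- config_beta_params(config)
  sp <- config_sasa_params(config)
  out <- list()
  out$beta <- run_beta(config)
  segs <- find_strands(out$beta$assignment, inp$frame, inp$system, bp)
  pairs <- pair_strands(segs, inp$frame, inp$system,
                        pair_dist = config$pair_dist)
  out$strands <- segs
  out$pairings <- pairs
  groups <- names(inp$system$groups)
  if (all(c(config$interface$group_a, config$interface$group_b) %in% groups)) {
    out$interface <- run_interface(config)
  }
  if (config$cluster$group %in% groups) {
    out$clusters <- run_clusters(config)
  }
  rp <- file.path(config$outdir, "report.txt")
  lines <- c(
    sprintf("beads: %d  chains: %d", nrow(inp$system$beads),
            length(inp$system$chains)),
    sprintf("beta_percent: %.3f", beta_fraction(out$beta$assignment)),
    sprintf("n_strands: %d", nrow(segs)),
    sprintf("n_pairings: %d", nrow(pairs))
  )
  if (!is.null(out$interface)) {
    lines <- c(lines, sprintf("interface_nm2: %.3f",
                              out$interface$interface$area))
  }
  if (!is.null(out$clusters)) {
    lines <- c(lines, sprintf("n_clusters: %d",
                              out$clusters$clusters$n_clusters))
  }
  writeLines(lines, rp)
  out$files <- c(report = rp)
  out
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else run_config(config)
}

write_timeseries_csv <- function(ts, path, value_col) {
  out <- data.frame(time_ps = sprintf("%.3f", ts$time_ps),
                    v = sprintf("%.6f", ts[[value_col]]))
  names(out)[2] <- value_col
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
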