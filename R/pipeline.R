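#' Default pipeline configuration
#'
#' All pipeline defaults live here; [validate_config()] merges a user YAML
#' over these values and rejects unknown keys. Stages: simulate, segment,
#' skeletonize, graph, metrics, compare.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "vasculograph_run",
    log_level = "info",
    stages = c("simulate", "segment", "skeletonize", "graph", "metrics",
               "compare"),
    simulate = list(
      n_per_group = 5L,
      phenotypes = c("normal", "tumor_like"),
      grid_shape = c(128L, 96L, 64L),
      noise_sd = 10,
      write_volumes = FALSE
    ),
    segment = list(
      scales_um = NULL,       # default: 1-3 voxels
      low_pct = 1, high_pct = 99,
      grow_tol = 0.25, dilate = 2L
    ),
    skeletonize = list(
      prune_um = NULL         # default: 3 voxel edges
    ),
    metrics = list(
      apl_convention = "zero_fill"
    ),
    compare = list(
      grouping = "group",
      metrics = c("CC", "NSE", "APL"),
      var_equal = TRUE,
      alpha = 0.05
    )
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key: %s",
                   paste(c(path, key), collapse = ".")))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config key %s must be a mapping",
                     paste(c(path, key), collapse = ".")))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Parses a YAML configuration, fills defaults from [default_config()],
#' rejects unknown keys by name, and range-checks the fields that drive the
#' phantom generator and statistics.
#'
#' @param path YAML file, or a list already in memory.
#' @return validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$simulate$n_per_group < 1) stop("simulate.n_per_group must be >= 1")
  if (any(cfg$simulate$grid_shape < 16)) {
    stop("simulate.grid_shape values must be >= 16")
  }
  if (cfg$simulate$noise_sd < 0) stop("simulate.noise_sd must be >= 0")
  if (!all(cfg$simulate$phenotypes %in% c("normal", "tumor_like"))) {
    stop("simulate.phenotypes must be 'normal' and/or 'tumor_like'")
  }
  if (!cfg$metrics$apl_convention %in% c("zero_fill", "connected_pairs")) {
    stop("metrics.apl_convention must be zero_fill or connected_pairs")
  }
  if (cfg$compare$alpha <= 0 || cfg$compare$alpha >= 1) {
    stop("compare.alpha must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(level, cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  lf <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(msg, "\n", file = lf, append = TRUE)
  invisible(NULL)
}

#' Run the full phantom-to-comparison pipeline
#'
#' Simulates `n_per_group` phantoms per phenotype, runs segmentation,
#' skeletonization, graph construction and metrics on each, writes the tidy
#' per-specimen metrics table, the two-group comparison, and a run manifest
#' with MD5 hashes of every written output. Deterministic stages re-run with
#' an identical config produce identical hashes (timestamps live in a
#' separate manifest field).
#'
#' @param config a `pipeline_config` from [validate_config()] (or a path /
#'   list accepted by it).
#' @return the run manifest (list), invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(
                     utils::packageVersion("vasculograph")),
                   started = format(Sys.time()),
                   stages = list(), outputs = character(0))
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  on.exit(save_manifest(), add = TRUE)

  reports <- list()
  specimen_seed <- 0L
  for (ph in cfg$simulate$phenotypes) {
    for (i in seq_len(cfg$simulate$n_per_group)) {
      specimen_seed <- specimen_seed + 1L
      sid <- sprintf("%s_%02d", ph, i)
      seed_i <- cfg$seed * 1000L + specimen_seed
      log_msg("info", cfg, "simulating %s (seed %d)", sid, seed_i)
      spec <- phantom_preset(ph, seed = seed_i,
                             grid_shape = cfg$simulate$grid_shape,
                             noise_sd = cfg$simulate$noise_sd)
      phant <- simulate_phantom(spec)
      if (isTRUE(cfg$simulate$write_volumes)) {
        vp <- file.path(cfg$out_dir, paste0(sid, "_volume.nii.gz"))
        write_volume_nifti(phant$volume, vp)
        manifest$outputs <- c(manifest$outputs, vp)
      }
      if (!"segment" %in% cfg$stages) {
        # simulate-only run: persist the ground-truth network and move on
        np <- file.path(cfg$out_dir, paste0(sid, "_truth_nodes.csv"))
        ep <- file.path(cfg$out_dir, paste0(sid, "_truth_edges.csv"))
        readr::write_csv(phant$network$nodes, np)
        readr::write_csv(dplyr::select(phant$network$edges, -"polyline"), ep)
        manifest$outputs <- c(manifest$outputs, np, ep)
        next
      }
      log_msg("info", cfg, "analyzing %s", sid)
      res <- analyze_volume(phant$volume,
                            scales_um = cfg$segment$scales_um,
                            prune_um = cfg$skeletonize$prune_um,
                            apl_convention = cfg$metrics$apl_convention,
                            specimen_id = sid,
                            grow_tol = cfg$segment$grow_tol)
      gp <- write_graph_files(res$graph, cfg$out_dir, stem = sid)
      manifest$outputs <- c(manifest$outputs, unname(gp))
      reports[[sid]] <- dplyr::mutate(res$report, group = ph,
                                      seed = seed_i)
    }
  }
  metrics_tbl <- dplyr::bind_rows(reports)
  if (nrow(metrics_tbl) > 0) {
    mt_path <- file.path(cfg$out_dir, "metrics.csv")
    readr::write_csv(metrics_tbl, mt_path)
    manifest$outputs <- c(manifest$outputs, mt_path)
    manifest$stages$metrics <- list(n_specimens = nrow(metrics_tbl))
  }

  if ("compare" %in% cfg$stages && nrow(metrics_tbl) > 0 &&
      length(unique(metrics_tbl$group)) == 2 &&
      min(table(metrics_tbl$group)) >= 3) {
    cmp <- batch_compare(metrics_tbl, grouping = cfg$compare$grouping,
                         metrics = cfg$compare$metrics,
                         var_equal = cfg$compare$var_equal,
                         alpha = cfg$compare$alpha)
    cmp_path <- file.path(cfg$out_dir, "comparison.csv")
    readr::write_csv(tidy(cmp), cmp_path)
    manifest$outputs <- c(manifest$outputs, cmp_path)
    manifest$stages$compare <- list(p_values = stats::setNames(
      vapply(cmp$comparisons, function(x) x$p_value, numeric(1)),
      names(cmp$comparisons)))
  }

  manifest$hashes <- as.list(tools::md5sum(manifest$outputs))
  manifest$finished <- format(Sys.time())
  save_manifest()
  log_msg("info", cfg, "pipeline complete: %d outputs",
          length(manifest$outputs))
  invisible(manifest)
}
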