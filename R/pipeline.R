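## End-to-end pipeline: register -> map cells -> reconstruct volumes ->
## quantify axons -> connectivity map, driven by a single YAML config with
## full provenance serialization.

#' Default pipeline configuration
#'
#' @return Named list of defaults: 100-um voxel grid, 10 x lambda 0.5
#'   Laplacian smoothing, connectivity thresholds (include 1%, edge 5%,
#'   cap 20%), seed 1.
#' @export
default_config <- function() {
  list(
    voxel_size_um = 100,
    smoothing = list(iterations = 10L, lambda = 0.5),
    thresholds = list(include_pct = 1, edge_pct = 5, cap_pct = 20),
    cortex_region_id = 10L,
    seed = 1L
  )
}

load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out <- utils::modifyList(default_config(), cfg)
  th <- out$thresholds
  if (!(th$include_pct >= 0 && th$include_pct <= th$edge_pct &&
        th$edge_pct <= th$cap_pct)) {
    stopf("config thresholds must satisfy 0 <= include <= edge <= cap",
          class = "atlastrace_configuration_error")
  }
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full quantification pipeline
#'
#' Executes, in order: atlas loading, per-section affine registration, cell
#' mapping and mediolateral binning, injection-volume reconstruction with
#' structure overlaps, axon quantification with per-animal normalization,
#' and connectivity-map construction. Every stage's outputs are written to
#' `out_dir` and all parameters are serialized into `provenance.json`.
#' Re-running with the same config and inputs reproduces identical outputs.
#'
#' @param config A list or YAML path. Recognized fields: `atlas_volume`,
#'   `atlas_regions`, `control_points`, `cells`, `outlines`,
#'   `axon_manifest`, `axon_dir`, `overlap_targets` (region acronyms),
#'   plus the defaults of [default_config()]. Input stages whose files are
#'   absent are skipped.
#' @param out_dir Output directory.
#' @return Invisibly, a list with each stage's results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(config = cfg)

  atl <- run_stage("atlas", {
    if (is.null(cfg$atlas_volume)) NULL
    else load_atlas(cfg$atlas_volume, cfg$atlas_regions)
  })
  results$atlas <- atl

  transforms <- NULL
  if (!is.null(cfg$control_points) && file.exists(cfg$control_points)) {
    transforms <- run_stage("register", {
      cp <- read_table_csv(cfg$control_points)
      tr <- fit_section_transforms(cp)
      write_transforms(tr, file.path(out_dir, "transforms.json"))
      tr
    })
    results$transforms <- transforms
  }

  if (!is.null(transforms) && !is.null(cfg$cells) && file.exists(cfg$cells)) {
    results$cells <- run_stage("map-cells", {
      cells <- read_table_csv(cfg$cells)
      rec <- map_cells(transforms, cells, atl, cfg$cortex_region_id)
      write_table_csv(rec, file.path(out_dir, "cell_records.csv"))
      summary <- list(class_counts = count_by_class(rec),
                      axis_distribution = summarize_distribution(rec))
      write_json_file(summary, file.path(out_dir, "cell_summary.json"))
      list(records = rec, summary = summary)
    })
  }

  if (!is.null(cfg$outlines) && file.exists(cfg$outlines)) {
    results$injections <- run_stage("reconstruct-volume", {
      ol <- read_table_csv(cfg$outlines)
      per_label <- split(ol, paste(ol$animal_id, ol$label))
      all_overlaps <- list()
      recon <- lapply(per_label, function(sub) {
        rec <- reconstruct_injection(
          as.matrix(sub[, c("x_um", "z_um", "ml_um")]),
          voxel_size_um = cfg$voxel_size_um,
          smooth_iterations = cfg$smoothing$iterations,
          smooth_lambda = cfg$smoothing$lambda)
        if (!is.null(atl)) {
          ## default overlap targets: leaf regions of the hierarchy
          leaves <- !atl$regions$region_id %in% atl$regions$parent_id
          targets <- cfg$overlap_targets %||% atl$regions$acronym[leaves]
          rids <- atl$regions$region_id[atl$regions$acronym %in% targets]
          if (length(rids)) {
            ov <- structure_overlaps(rec$solid, atl, rids,
                                     source_label = sub$label[1])
            ov$animal_id <- sub$animal_id[1]
            all_overlaps[[length(all_overlaps) + 1L]] <<- ov
          }
        }
        rec
      })
      if (length(all_overlaps)) {
        write_table_csv(do.call(rbind, all_overlaps),
                        file.path(out_dir, "injection_overlap.csv"))
      }
      recon
    })
  }

  fractions <- NULL
  if (!is.null(cfg$axon_manifest) && file.exists(cfg$axon_manifest)) {
    results$axons <- run_stage("quantify-axons", {
      man <- read_table_csv(cfg$axon_manifest)
      base <- cfg$axon_dir %||% dirname(cfg$axon_manifest)
      per_sec <- quantify_sections(man, base_dir = base)
      agg <- aggregate_and_normalize(per_sec)
      if ("group" %in% names(man)) {
        agg$group <- man$group[match(agg$animal_id, man$animal_id)]
      }
      write_table_csv(agg, file.path(out_dir, "axon_fractions.csv"))
      agg
    })
    fractions <- results$axons
  }

  if (!is.null(fractions) && "group" %in% names(fractions)) {
    results$connectivity <- run_stage("connectivity", {
      stats_tbl <- group_means(fractions)
      map <- build_map(stats_tbl,
                       include_pct = cfg$thresholds$include_pct,
                       edge_pct = cfg$thresholds$edge_pct,
                       cap_pct = cfg$thresholds$cap_pct)
      write_map_json(map, file.path(out_dir, "connectivity.json"))
      write_table_csv(map_to_table(map),
                      file.path(out_dir, "connectivity.csv"))
      map
    })
  }

  prov <- list(
    package = "atlastrace",
    version = as.character(utils::packageVersion("atlastrace")),
    config = cfg)
  write_json_file(prov, file.path(out_dir, "provenance.json"))
  invisible(results)
}
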