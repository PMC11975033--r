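## Group-level connectivity maps from per-animal innervation fractions.
## Inclusion/edge/cap thresholds follow the figure conventions: regions with
## mean input > 1% of signal are shown, edges drawn above 5%, line
## thickness scales linearly up to a 20% cap.

#' Group means of innervation fractions across animals
#'
#' Regions missing in an animal (no mask, zero rows) are imputed as
#' fraction 0 for that animal before averaging, otherwise group means would
#' be biased upward.
#'
#' @param fractions Data frame with `group`, `animal_id`, `region_id`,
#'   `norm_fraction`.
#' @return Data frame per (group, region): `mean_fraction`, `sem`,
#'   `n_animals`. Groups with one animal get `NA` SEM and a warning.
#' @export
group_means <- function(fractions) {
  need <- c("group", "animal_id", "region_id", "norm_fraction")
  missing <- setdiff(need, names(fractions))
  if (length(missing)) {
    stopf("fraction table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (g in sort(unique(fractions$group))) {
    sub <- fractions[fractions$group == g, ]
    animals <- sort(unique(sub$animal_id))
    regions <- sort(unique(sub$region_id))
    full <- expand.grid(animal_id = animals, region_id = regions,
                        stringsAsFactors = FALSE)
    full <- merge(full, sub[, c("animal_id", "region_id", "norm_fraction")],
                  by = c("animal_id", "region_id"), all.x = TRUE)
    n_imputed <- sum(is.na(full$norm_fraction))
    if (n_imputed > 0) {
      message(sprintf(
        "group_means: group '%s': %d missing (animal, region) pair(s) imputed as fraction 0",
        g, n_imputed))
      full$norm_fraction[is.na(full$norm_fraction)] <- 0
    }
    if (length(animals) == 1L) {
      warnf("group '%s' has a single animal; SEM undefined", g)
    }
    for (rid in regions) {
      v <- full$norm_fraction[full$region_id == rid]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region_id = rid, mean_fraction = mean(v), sem = sem(v),
        n_animals = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build a thresholded connectivity map
#'
#' A region becomes a node iff its mean fraction exceeds `include_pct`
#' percent (strictly); an edge is drawn iff it exceeds `edge_pct`; edge
#' thickness weight is the mean percent capped at `cap_pct` and scaled
#' linearly to (0, 1]. Bubble values carry the mean fraction per node.
#'
#' @param stats Output of [group_means()].
#' @param include_pct Node inclusion threshold in percent (default 1).
#' @param edge_pct Edge threshold in percent (default 5).
#' @param cap_pct Thickness cap in percent (default 20).
#' @return An object of class `connectivity_map`: list of per-group entries,
#'   each with `nodes` and `edges` data frames, plus the thresholds.
#' @export
build_map <- function(stats, include_pct = 1, edge_pct = 5, cap_pct = 20) {
  if (!(include_pct >= 0 && include_pct <= edge_pct && edge_pct <= cap_pct)) {
    stopf("thresholds must satisfy 0 <= include <= edge <= cap (got %g, %g, %g)",
          include_pct, edge_pct, cap_pct,
          class = "atlastrace_configuration_error")
  }
  groups <- sort(unique(stats$group))
  maps <- lapply(groups, function(g) {
    sub <- stats[stats$group == g, ]
    pct <- 100 * sub$mean_fraction
    nodes <- sub[pct > include_pct, , drop = FALSE]
    nodes$bubble <- nodes$mean_fraction
    edges <- sub[pct > edge_pct, c("group", "region_id", "mean_fraction")]
    edges$strength_pct <- 100 * edges$mean_fraction
    edges$thickness <- pmin(edges$strength_pct, cap_pct) / cap_pct
    rownames(nodes) <- rownames(edges) <- NULL
    list(group = g, nodes = nodes, edges = edges)
  })
  names(maps) <- groups
  structure(list(groups = maps,
                 thresholds = list(include_pct = include_pct,
                                   edge_pct = edge_pct, cap_pct = cap_pct)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d group(s); thresholds include > %g%%, edge > %g%%, cap %g%%\n",
              length(x$groups), x$thresholds$include_pct,
              x$thresholds$edge_pct, x$thresholds$cap_pct))
  for (g in x$groups) {
    cat(sprintf("  %s: %d node(s), %d edge(s)\n", g$group, nrow(g$nodes),
                nrow(g$edges)))
  }
  invisible(x)
}

#' Serialize a connectivity map to JSON
#'
#' @param map A `connectivity_map`.
#' @param path Output JSON path.
#' @export
write_map_json <- function(map, path) {
  out <- list(
    thresholds = map$thresholds,
    groups = lapply(unname(map$groups), function(g) {
      list(group = g$group,
           nodes = lapply(seq_len(nrow(g$nodes)), function(i) {
             n <- g$nodes[i, ]
             list(region_id = n$region_id, mean = n$mean_fraction,
                  sem = if (is.na(n$sem)) NULL else n$sem,
                  bubble = n$bubble)
           }),
           edges = lapply(seq_len(nrow(g$edges)), function(i) {
             e <- g$edges[i, ]
             list(region_id = e$region_id, strength_pct = e$strength_pct,
                  thickness = e$thickness)
           }))
    }))
  write_json_file(out, path)
}

#' Flatten a connectivity map to a table
#'
#' @param map A `connectivity_map`.
#' @return Data frame with one row per node carrying edge membership and
#'   thickness where applicable.
#' @export
map_to_table <- function(map) {
  rows <- lapply(map$groups, function(g) {
    n <- g$nodes
    if (nrow(n) == 0L) return(NULL)
    n$is_edge <- n$region_id %in% g$edges$region_id
    n$thickness <- g$edges$thickness[match(n$region_id, g$edges$region_id)]
    n
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
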