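#' Normalize single-cell marker intensities per image
#'
#' Rescales each marker to `[0, 1]` by dividing by the per-image maximum of
#' that marker, the convention used before hierarchical gating so that gate
#' thresholds are comparable across images. All-zero markers are left at 0
#' and flagged with a warning.
#'
#' @param cells Data frame of single-cell records.
#' @param markers Character vector of intensity columns to normalize.
#' @param image Optional column name identifying the image each cell belongs
#'   to; when `NULL` all cells are treated as one image.
#' @return Tibble with the marker columns rescaled.
#' @export
normalize_intensities <- function(cells, markers, image = NULL) {
  check_columns(cells, c(markers, image), "`cells`")
  if (any(as.matrix(as_tibble(cells)[markers]) < 0, na.rm = TRUE)) {
    abort("marker intensities must be non-negative")
  }
  cells <- as_tibble(cells)
  grouped <- if (is.null(image)) cells else group_by(cells, .data[[image]])
  flagged <- character(0)
  out <- grouped |>
    mutate(across(dplyr::all_of(markers), function(x) {
      mx <- max(x)
      if (mx == 0) {
        flagged <<- c(flagged, dplyr::cur_column())
        x
      } else {
        x / mx
      }
    })) |>
    ungroup()
  if (length(flagged) > 0) {
    warn(sprintf(
      "all-zero marker(s) left unscaled: %s",
      paste(unique(flagged), collapse = ", ")
    ))
  }
  out
}

#' Define a hierarchical gating node
#'
#' A gate splits cells on one marker at a threshold: cells with intensity
#' `>= threshold` follow the `above` branch, the rest follow `below`. Branches
#' are either further [gate_node()]s or leaf population labels (strings).
#' Thresholds are expressed on the normalized `[0, 1]` intensity scale.
#'
#' @param marker Marker column the node gates on.
#' @param threshold Gate threshold; cells exactly at the threshold take the
#'   `above` branch.
#' @param above,below Child nodes or leaf labels.
#' @param name Optional display name for the node (defaults to
#'   `"marker>=threshold"`).
#' @return A `gate_node` object.
#' @export
gate_node <- function(marker, threshold, above, below, name = NULL) {
  structure(
    list(
      marker = marker, threshold = threshold,
      above = above, below = below,
      name = name %||% sprintf("%s>=%g", marker, threshold)
    ),
    class = "gate_node"
  )
}

gate_leaves <- function(node) {
  if (is.character(node)) {
    return(node)
  }
  c(gate_leaves(node$above), gate_leaves(node$below))
}

gate_markers <- function(node) {
  if (is.character(node)) {
    return(character(0))
  }
  unique(c(node$marker, gate_markers(node$above), gate_markers(node$below)))
}

#' Route cells through a hierarchical gating tree
#'
#' Every cell deterministically reaches exactly one leaf population; cells
#' exactly at a threshold take the `>=` branch. Leaf counts are attached as
#' the `"population_counts"` attribute.
#'
#' @param cells Data frame with the marker columns the tree references.
#' @param tree A [gate_node()] tree.
#' @return `cells` with a `population` column of leaf labels.
#' @export
apply_gating_tree <- function(cells, tree) {
  missing <- setdiff(gate_markers(tree), names(cells))
  if (length(missing) > 0) {
    abort(sprintf(
      "gating tree references marker(s) absent from `cells`: %s",
      paste(missing, collapse = ", ")
    ))
  }
  route <- function(node, idx) {
    if (is.character(node)) {
      return(setNames(rep(node, length(idx)), NULL))
    }
    x <- cells[[node$marker]][idx]
    up <- x >= node$threshold
    out <- character(length(idx))
    out[up] <- route(node$above, idx[up])
    out[!up] <- route(node$below, idx[!up])
    out
  }
  out <- as_tibble(cells)
  out$population <- route(tree, seq_len(nrow(out)))
  counts <- out |> count(.data$population, name = "n")
  attr(out, "population_counts") <- counts
  out
}

# Walk a gating tree collecting (population, parent) rows for internal nodes
# and leaves; the root's parent is "total".
gate_hierarchy <- function(node, parent = "total") {
  if (is.character(node)) {
    return(tibble(population = node, parent = parent, leaves = list(node)))
  }
  bind_rows(
    tibble(
      population = node$name, parent = parent,
      leaves = list(gate_leaves(node))
    ),
    gate_hierarchy(node$above, node$name),
    gate_hierarchy(node$below, node$name)
  )
}

#' Composition metrics for gated cell populations
#'
#' Reports, per population (leaves and, when the gating tree is supplied,
#' internal gate populations): cell count, percentage of total nucleated
#' cells, percentage of the parent population, and density in cells per square
#' millimetre of tissue analysed. Counts and tissue areas from multiple ROIs
#' are summed before any percentage is formed.
#'
#' @param cells Gated cells (from [apply_gating_tree()], with a `population`
#'   column).
#' @param tissue_area_mm2 Tissue area per ROI in mm^2 (a vector is summed).
#' @param tree The gating tree, to report internal populations and
#'   parent-relative percentages; when `NULL`, every population's parent is
#'   the total.
#' @return Tibble `population`, `parent`, `n`, `pct_total`, `pct_parent`,
#'   `density_mm2`.
#' @export
composition_metrics <- function(cells, tissue_area_mm2, tree = NULL) {
  check_columns(cells, "population", "`cells`")
  area <- sum(tissue_area_mm2)
  if (area <= 0) abort("`tissue_area_mm2` must sum to a positive area")
  total <- nrow(cells)
  if (total == 0) {
    warn("no cells supplied; composition report zeroed")
  }
  leaf_counts <- as_tibble(cells) |> count(.data$population, name = "n")
  if (is.null(tree)) {
    hier <- tibble(
      population = leaf_counts$population,
      parent = "total",
      leaves = as.list(leaf_counts$population)
    )
  } else {
    hier <- gate_hierarchy(tree)
  }
  count_of <- function(leaves) {
    sum(leaf_counts$n[leaf_counts$population %in% leaves])
  }
  hier$n <- vapply(hier$leaves, count_of, numeric(1))
  parent_n <- unname(vapply(hier$parent, function(p) {
    if (p == "total") {
      return(total)
    }
    hier$n[hier$population == p][1]
  }, numeric(1)))
  hier |>
    mutate(
      pct_total = if (total == 0) 0 else 100 * .data$n / total,
      pct_parent = ifelse(parent_n > 0, 100 * .data$n / parent_n, NA_real_),
      density_mm2 = .data$n / area
    ) |>
    select("population", "parent", "n", "pct_total", "pct_parent", "density_mm2")
}

#' Distance from cell centroids to the nearest ECM mask pixel
#'
#' Euclidean distance in micrometres from each nuclear centroid to the centre
#' of the nearest positive mask pixel. A cell whose centroid falls inside a
#' positive pixel is inside the matrix and reports distance 0. The mask
#' follows image conventions: pixel (row 1, col 1) at the top-left, x
#' rightward along columns, y downward along rows, pixel centres at
#' `(col - 0.5, row - 0.5) * pixel_size`.
#'
#' @param cells Data frame with `centroid_x`, `centroid_y` in micrometres.
#' @param mask Logical or 0/1 matrix of positive ECM staining.
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @return Numeric vector of distances (um), one per cell.
#' @export
distance_to_mask <- function(cells, mask, pixel_size = 1) {
  check_columns(cells, c("centroid_x", "centroid_y"), "`cells`")
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  pos <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pos) == 0) abort("the ECM mask contains no positive pixels")
  px <- (pos[, "col"] - 0.5) * pixel_size
  py <- (pos[, "row"] - 0.5) * pixel_size
  cx <- cells$centroid_x
  cy <- cells$centroid_y
  if (any(!is.finite(cx)) || any(!is.finite(cy))) {
    abort("cell centroids must be finite")
  }
  n <- length(cx)
  out <- numeric(n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(cx[idx], px, "-")^2 + outer(cy[idx], py, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  # centroids lying inside a positive pixel are at distance 0
  col_idx <- floor(cx / pixel_size) + 1
  row_idx <- floor(cy / pixel_size) + 1
  inside <- col_idx >= 1 & col_idx <= ncol(mask) &
    row_idx >= 1 & row_idx <= nrow(mask)
  in_mask <- inside
  in_mask[inside] <- mask[cbind(row_idx[inside], col_idx[inside])] != 0
  out[in_mask] <- 0
  out
}

#' Intensity-versus-distance binning and ANOVA
#'
#' Cells are grouped into half-open distance bins (`[0,25)`, `[25,50)`,
#' `[50,75)` micrometres by default; cells beyond the last edge are excluded)
#' and the per-bin intensity distributions of each requested marker are
#' compared with a one-way ANOVA. P-values are Bonferroni-corrected across
#' every marker-by-stratum test performed in the invocation (the correction
#' family), capped at 1, and flagged significant below `sig_level`. A test
#' with fewer than two usable bins (each needing at least `min_cells` cells)
#' is reported as untestable.
#'
#' @param cells Data frame with the marker columns and a distance column.
#' @param markers Marker column(s) to test.
#' @param dist Name of the distance column (micrometres), e.g. the output of
#'   [distance_to_mask()].
#' @param breaks Ascending bin edges in micrometres.
#' @param by Optional stratification column (e.g. biopsy); each stratum is
#'   tested separately and enlarges the Bonferroni family.
#' @param min_cells Minimum cells per usable bin.
#' @param sig_level Significance threshold on the adjusted p-value.
#' @return A `distance_bin_result` object: `$tests` (one row per test:
#'   `marker`, stratum, per-bin n and means, `f_statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `untestable`), `$cells` (binned cells),
#'   `$breaks`.
#' @export
bin_and_test <- function(cells, markers, dist = "dist_um",
                         breaks = c(0, 25, 50, 75), by = NULL,
                         min_cells = 2, sig_level = 0.001) {
  check_columns(cells, c(markers, dist, by), "`cells`")
  if (is.unsorted(breaks, strictly = TRUE)) abort("`breaks` must be strictly increasing")
  cells <- as_tibble(cells)
  cells$.bin <- cut(cells[[dist]],
    breaks = breaks, right = FALSE,
    labels = sprintf("[%g,%g)", head(breaks, -1), tail(breaks, -1))
  )
  binned <- cells[!is.na(cells$.bin), , drop = FALSE]
  strata <- if (is.null(by)) list(`all` = binned) else split(binned, binned[[by]])

  grid <- tidyr::expand_grid(stratum = names(strata), marker = markers)
  tests <- purrr::pmap_dfr(grid, function(stratum, marker) {
    df <- strata[[stratum]]
    per_bin <- df |>
      summarise(
        n = dplyr::n(), mean = mean(.data[[marker]]),
        .by = ".bin"
      )
    usable <- per_bin$n[per_bin$n >= min_cells]
    row <- tibble(marker = marker, stratum = stratum)
    for (lv in levels(binned$.bin)) {
      i <- which(per_bin$.bin == lv)
      row[[paste0("n_", lv)]] <- if (length(i)) per_bin$n[i] else 0L
      row[[paste0("mean_", lv)]] <- if (length(i)) per_bin$mean[i] else NA_real_
    }
    if (length(usable) < 2) {
      row$f_statistic <- NA_real_
      row$p_value <- NA_real_
      row$untestable <- TRUE
      return(row)
    }
    keep <- df$.bin %in% per_bin$.bin[per_bin$n >= min_cells]
    fit <- stats::oneway.test(df[[marker]][keep] ~ droplevels(df$.bin[keep]),
      var.equal = TRUE
    )
    row$f_statistic <- unname(fit$statistic)
    row$p_value <- fit$p.value
    row$untestable <- FALSE
    row
  })
  family <- sum(!tests$untestable)
  tests <- tests |>
    mutate(
      p_adjusted = pmin(.data$p_value * family, 1),
      significant = !.data$untestable & .data$p_adjusted < sig_level
    )
  out <- list(
    tests = tests, cells = binned, breaks = breaks,
    dist = dist, family = family, sig_level = sig_level
  )
  class(out) <- "distance_bin_result"
  out
}

#' @export
print.distance_bin_result <- function(x, ...) {
  cat(sprintf(
    "Distance-bin ANOVA: %d test(s), Bonferroni family %d, significance at adjusted p < %g\n",
    nrow(x$tests), x$family, x$sig_level
  ))
  print(x$tests, ...)
  invisible(x)
}

#' @method tidy distance_bin_result
#' @export
tidy.distance_bin_result <- function(x, ...) {
  x$tests
}

#' @method glance distance_bin_result
#' @export
glance.distance_bin_result <- function(x, ...) {
  tibble(
    n_tests = nrow(x$tests),
    n_untestable = sum(x$tests$untestable),
    family = x$family,
    n_significant = sum(x$tests$significant, na.rm = TRUE),
    min_p_adjusted = suppressWarnings(min(x$tests$p_adjusted, na.rm = TRUE))
  )
}
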