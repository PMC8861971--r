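toy_cells <- function() {
  tibble::tibble(
    cell_id = paste0("c", 1:6),
    image = rep(c("img1", "img2"), each = 3),
    centroid_x = c(1, 2, 3, 4, 5, 6),
    centroid_y = 1,
    CD45 = c(0, 5, 10, 2, 4, 8),
    PanCK = c(3, 0, 6, 1, 1, 2)
  )
}

test_that("per-image max normalization rescales to [0, 1]", {
  cells <- toy_cells()
  norm <- normalize_intensities(cells, c("CD45", "PanCK"), image = "image")
  brute <- unlist(lapply(split(cells$CD45, cells$image), function(x) x / max(x)))
  expect_equal(norm$CD45, unname(brute))
  expect_equal(max(norm$CD45[norm$image == "img1"]), 1)
  expect_equal(max(norm$PanCK[norm$image == "img2"]), 1)
  expect_warning(
    z <- normalize_intensities(dplyr::mutate(cells, CD45 = 0), "CD45"),
    "all-zero"
  )
  expect_true(all(z$CD45 == 0))
  expect_error(
    normalize_intensities(dplyr::mutate(cells, CD45 = -1), "CD45"),
    "non-negative"
  )
})

test_that("gating trees route every cell to exactly one leaf, >= at the boundary", {
  cells <- tibble::tibble(CD45 = c(0.2, 0.5, 0.9), CD3 = c(0.1, 0.8, 0.4))
  simple <- gate_node("CD45", 0.5, "immune", "other")
  gated <- apply_gating_tree(cells, simple)
  expect_equal(gated$population, c("other", "immune", "immune")) # 0.5 -> above
  nested <- gate_node(
    "CD45", 0.5,
    above = gate_node("CD3", 0.5, "tcell", "myeloid"),
    below = "other"
  )
  gated2 <- apply_gating_tree(cells, nested)
  expect_equal(gated2$population, c("other", "tcell", "myeloid"))
  expect_error(
    apply_gating_tree(tibble::tibble(x = 1), simple),
    "CD45"
  )
})

test_that("gating matches a brute-force boolean oracle on a 3-level tree", {
  withr::with_seed(60, {
    cells <- tibble::tibble(
      a = runif(100), b = runif(100), c = runif(100)
    )
  })
  tree <- gate_node(
    "a", 0.4,
    above = gate_node(
      "b", 0.6,
      above = gate_node("c", 0.5, "abc", "ab"),
      below = "a_only"
    ),
    below = "neg"
  )
  got <- apply_gating_tree(cells, tree)$population
  oracle <- ifelse(cells$a < 0.4, "neg",
    ifelse(cells$b < 0.6, "a_only",
      ifelse(cells$c >= 0.5, "abc", "ab")
    )
  )
  expect_equal(got, oracle)
  # every cell reaches exactly one leaf
  expect_equal(sum(table(got)), 100)
})

test_that("composition metrics report percentages and densities with ROI pooling", {
  cells <- tibble::tibble(population = c(rep("CD45pos", 9), rep("CD45neg", 91)))
  rep_ <- composition_metrics(cells, tissue_area_mm2 = 1)
  cd45 <- rep_[rep_$population == "CD45pos", ]
  expect_equal(cd45$pct_total, 9)
  expect_equal(cd45$density_mm2, 9)
  # two ROIs pool counts and area before forming percentages and density
  roi_cells <- tibble::tibble(population = c(rep("x", 60), rep("y", 40)))
  pooled <- composition_metrics(roi_cells, tissue_area_mm2 = c(0.5, 1.5))
  expect_equal(pooled$pct_total[pooled$population == "x"], 60)
  expect_equal(pooled$density_mm2[pooled$population == "x"], 30)
})

test_that("sibling percentages sum to their parent's percentage", {
  tree <- gate_node(
    "CD45", 0.5,
    above = gate_node("CD3", 0.5, "tcell", "other_immune"),
    below = "non_immune",
    name = "immune_gate"
  )
  withr::with_seed(9, {
    cells <- tibble::tibble(CD45 = runif(500), CD3 = runif(500))
  })
  gated <- apply_gating_tree(cells, tree)
  comp <- composition_metrics(gated, 2, tree = tree)
  parent <- comp[comp$population == "CD3>=0.5", ]
  kids <- comp[comp$parent == "CD3>=0.5", ]
  expect_equal(sum(kids$pct_total), parent$pct_total, tolerance = 1e-9)
  expect_equal(sum(kids$n), parent$n)
  # child percentage of its parent population
  expect_equal(
    kids$pct_parent,
    100 * kids$n / parent$n,
    tolerance = 1e-9
  )
  root <- comp[comp$population == "immune_gate", ]
  expect_equal(root$pct_total, 100)
})

test_that("distance to mask matches the exhaustive pixel-scan oracle exactly", {
  withr::with_seed(90, {
    for (i in 1:6) {
      mask <- matrix(rbinom(30 * 30, 1, 0.05), 30, 30)
      if (sum(mask) == 0) mask[15, 15] <- 1
      px <- runif(2, 0.5, 2)[1]
      cells <- tibble::tibble(
        centroid_x = runif(12, 0, 30 * px),
        centroid_y = runif(12, 0, 30 * px)
      )
      expect_equal(
        distance_to_mask(cells, mask, px),
        distance_oracle(cells, mask, px)
      )
    }
  })
})

test_that("distance geometry: on-pixel cells are 0 and offsets are exact", {
  mask <- matrix(0, 10, 10)
  mask[4, 7] <- 1 # centre at x = 6.5, y = 3.5 for pixel_size 1
  cells <- tibble::tibble(
    centroid_x = c(6.5, 6.7, 9.5),
    centroid_y = c(3.5, 3.6, 7.5)
  )
  d <- distance_to_mask(cells, mask, 1)
  expect_equal(d[1], 0)
  expect_equal(d[2], 0) # inside the positive pixel
  expect_equal(d[3], sqrt(3^2 + 4^2))
  expect_error(distance_to_mask(cells, matrix(0, 5, 5), 1), "no positive")
})

test_that("distance binning is half-open with exclusion beyond the last edge", {
  cells <- tibble::tibble(
    marker = rnorm(8),
    dist_um = c(0, 24.999, 25, 49.9, 50, 74.9, 75, 80)
  )
  res <- bin_and_test(cells, "marker", min_cells = 1)
  counts <- table(res$cells$.bin)
  expect_equal(unname(counts[["[0,25)"]]), 2)
  expect_equal(unname(counts[["[25,50)"]]), 2) # 25 falls in the second bin
  expect_equal(unname(counts[["[50,75)"]]), 2) # 75 and 80 are excluded
  expect_equal(nrow(res$cells), 6)
})

test_that("identical bin distributions give F near 0 and planted gradients reject", {
  withr::with_seed(12, {
    flat <- tibble::tibble(
      marker = rnorm(900, 100, 5),
      dist_um = runif(900, 0, 74.9)
    )
  })
  res_flat <- bin_and_test(flat, "marker")
  expect_gt(res_flat$tests$p_value, 0.01)
  tissue <- simulate_spatial_tissue(
    n_cells = 3000, gradient_slope = 5,
    noise_sd = 50, seed = 13
  )
  res_grad <- bin_and_test(tissue$cells, "marker")
  expect_true(res_grad$tests$significant)
  expect_lt(res_grad$tests$p_adjusted, 1e-3)
  # bin means decrease monotonically away from the rim under a positive slope
  means <- unlist(res_grad$tests[paste0("mean_", levels(res_grad$cells$.bin))])
  expect_true(all(diff(means) < 0))
})

test_that("the Bonferroni family spans all marker-by-stratum tests in one call", {
  withr::with_seed(19, {
    cells <- tibble::tibble(
      m1 = rnorm(300), m2 = rnorm(300),
      biopsy = rep(c("Bx2", "Bx3"), 150),
      dist_um = runif(300, 0, 74)
    )
  })
  res <- bin_and_test(cells, c("m1", "m2"), by = "biopsy")
  expect_equal(nrow(res$tests), 4)
  expect_equal(res$family, 4)
  expect_equal(res$tests$p_adjusted, pmin(res$tests$p_value * 4, 1))
  # too-small strata are reported untestable, not errors
  tiny <- tibble::tibble(m1 = rnorm(3), dist_um = c(1, 2, 60))
  res_tiny <- bin_and_test(tiny, "m1")
  expect_true(res_tiny$tests$untestable)
})

test_that("spatial simulator geometry and gradient behave as configured", {
  tis <- simulate_spatial_tissue(n_cells = 400, seed = 5)
  expect_equal(nrow(tis$cells), 400)
  expect_true(all(tis$cells$dist_um >= 0 & tis$cells$dist_um <= 80))
  # the analytic distance agrees with the rasterized mask to about a pixel
  measured <- distance_to_mask(tis$cells, tis$mask, tis$pixel_size)
  expect_lt(max(abs(measured - tis$cells$dist_um)), tis$pixel_size)
  # slope 0 gives equal bin means in expectation
  flat <- simulate_spatial_tissue(n_cells = 4000, gradient_slope = 0, seed = 6, make_mask = FALSE)
  res <- bin_and_test(flat$cells, "marker")
  expect_gt(res$tests$p_value, 0.001)
})
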