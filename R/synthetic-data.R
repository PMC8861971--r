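#' Define a clonal tree for biopsy simulation
#'
#' Describes the evolutionary structure a set of serial biopsies is simulated
#' from: clones with parent links (a single root representing the germline
#' ancestor), a count of somatic mutations acquired on the branch leading to
#' each clone, a mapping of each biopsy to the clone it samples, and the tumor
#' purity of each biopsy.
#'
#' @param parent Named character vector: `parent["B"] = "A"` places clone B
#'   below clone A; the root has `NA` as parent.
#' @param branch_mutations Named integer vector: mutations acquired on the
#'   branch above each clone (root branch = truncal/ubiquitous mutations).
#' @param sample_map Named character vector mapping biopsy IDs to clone IDs.
#' @param purity Named numeric vector in `[0, 1]`, tumor purity per biopsy
#'   (recycled from a scalar).
#' @return A `clonal_tree` object.
#' @export
#' @examples
#' clonal_tree(
#'   parent = c(trunk = NA, A = "trunk", B = "trunk"),
#'   branch_mutations = c(trunk = 10, A = 5, B = 5),
#'   sample_map = c(Bx1 = "A", Bx2 = "B"),
#'   purity = c(Bx1 = 0.6, Bx2 = 0.4)
#' )
clonal_tree <- function(parent, branch_mutations, sample_map, purity) {
  clones <- names(parent)
  if (is.null(clones) || anyDuplicated(clones)) {
    abort("`parent` must be a named vector with unique clone names")
  }
  roots <- clones[is.na(parent)]
  if (length(roots) != 1) abort("the tree must have exactly one root clone")
  if (!all(stats::na.omit(parent) %in% clones)) {
    abort("every parent must itself be a clone in the tree")
  }
  # connectivity: every clone must reach the root without cycles
  for (cl in clones) {
    seen <- character(0)
    node <- cl
    while (!is.na(parent[node])) {
      if (node %in% seen) abort("the clone tree contains a cycle")
      seen <- c(seen, node)
      node <- parent[[node]]
    }
    if (node != roots) abort("the clone tree is disconnected")
  }
  if (!setequal(names(branch_mutations), clones)) {
    abort("`branch_mutations` must name every clone exactly once")
  }
  if (any(branch_mutations < 0)) abort("branch mutation counts must be >= 0")
  if (!all(sample_map %in% clones)) {
    abort("every biopsy must map to a clone in the tree")
  }
  if (length(purity) == 1) {
    purity <- setNames(rep(purity, length(sample_map)), names(sample_map))
  }
  if (!setequal(names(purity), names(sample_map))) {
    abort("`purity` must name every biopsy in `sample_map`")
  }
  check_fraction(purity, "purity")
  structure(
    list(
      parent = parent, root = roots,
      branch_mutations = branch_mutations,
      sample_map = sample_map, purity = purity
    ),
    class = "clonal_tree"
  )
}

# Clones on the path from the root down to `clone`, inclusive.
clone_path <- function(tree, clone) {
  path <- clone
  while (!is.na(tree$parent[clone])) {
    clone <- tree$parent[[clone]]
    path <- c(clone, path)
  }
  path
}

#' Mutation-to-branch truth table of a clonal tree
#'
#' @param tree A [clonal_tree()].
#' @return Tibble `variant_id`, `clone` (the branch carrying the mutation).
#' @export
tree_mutations <- function(tree) {
  purrr::map_dfr(names(tree$branch_mutations), function(cl) {
    m <- tree$branch_mutations[[cl]]
    if (m == 0) {
      return(tibble(variant_id = character(0), clone = character(0)))
    }
    tibble(
      variant_id = sprintf("%s_m%03d", cl, seq_len(m)),
      clone = cl
    )
  })
}

#' Simulate somatic variant tables for serial biopsies from a clonal tree
#'
#' A clone carries every mutation on its root path. For each biopsy the true
#' VAF of a carried mutation is `purity * 0.5` (heterozygous, diploid; no
#' copy-number change) and 0 otherwise; observed alternate read counts are
#' binomial at the stated depth. The caller emulation marks a variant as
#' called when it has at least 3 supporting reads and an observed VAF of at
#' least 5%, mirroring the downstream variant filter.
#'
#' @param tree A [clonal_tree()].
#' @param depth_mean Sequencing depth per site (>= 30).
#' @param min_alt_called,min_vaf_called Caller-emulation thresholds.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   output.
#' @return Tibble `sample_id`, `variant_id`, `vaf`, `depth`, `called`,
#'   `supporting_reads`, plus the simulation truth columns `true_vaf` and
#'   `clone`.
#' @export
simulate_clonal_biopsies <- function(tree, depth_mean = 100,
                                     min_alt_called = 3, min_vaf_called = 0.05,
                                     seed = NULL) {
  if (!inherits(tree, "clonal_tree")) abort("`tree` must be a `clonal_tree`")
  if (depth_mean < 30) abort("`depth_mean` must be at least 30 reads")
  muts <- tree_mutations(tree)
  if (nrow(muts) == 0) abort("the tree carries no mutations")
  with_seed_if(seed, {
    purrr::map_dfr(names(tree$sample_map), function(bx) {
      clone <- tree$sample_map[[bx]]
      carried <- muts$clone %in% clone_path(tree, clone)
      true_vaf <- ifelse(carried, tree$purity[[bx]] * 0.5, 0)
      depth <- rep(as.integer(depth_mean), nrow(muts))
      alt <- rbinom(nrow(muts), depth, true_vaf)
      vaf <- alt / depth
      tibble(
        sample_id = bx,
        variant_id = muts$variant_id,
        vaf = vaf,
        depth = depth,
        called = alt >= min_alt_called & vaf >= min_vaf_called,
        supporting_reads = alt,
        true_vaf = true_vaf,
        clone = muts$clone
      )
    })
  })
}

#' Simulate UMI read families at one panel site
#'
#' Each family represents one original cfDNA molecule: the molecule's allele
#' is mutant with probability `true_vaf`, the family size is geometric with
#' the requested mean (minimum 1 read), and every read is an independently
#' corrupted copy of the template with a per-base substitution probability of
#' `error_rate` (substitutions are uniform over the three other bases).
#'
#' @param true_vaf True variant allele fraction of the molecule pool.
#' @param n_families Number of UMI families.
#' @param error_rate Per-base substitution probability per read.
#' @param family_size_mean Mean family size (geometric distribution).
#' @param window Reference bases of the site window.
#' @param mutant_pos 1-based position of the variant within the window.
#' @param mutant_base Alternate base carried by mutant molecules.
#' @param seed Optional integer seed.
#' @return Tibble `umi`, `site_window`, `bases` (one row per read) with a
#'   `true_mutant` truth column per family.
#' @export
simulate_umi_reads <- function(true_vaf, n_families = 1000, error_rate = 1e-3,
                               family_size_mean = 5, window = "ACGTACGTA",
                               mutant_pos = 5, mutant_base = "T", seed = NULL) {
  check_fraction(true_vaf, "true_vaf")
  check_fraction(error_rate, "error_rate")
  if (n_families < 1) abort("`n_families` must be positive")
  ref <- strsplit(window, "", fixed = TRUE)[[1]]
  if (mutant_pos < 1 || mutant_pos > length(ref)) {
    abort("`mutant_pos` must fall inside the window")
  }
  if (ref[mutant_pos] == mutant_base) {
    abort("`mutant_base` must differ from the reference base at `mutant_pos`")
  }
  width <- length(ref)
  bases4 <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    sizes <- rgeom(n_families, 1 / family_size_mean) + 1L
    mutant <- runif(n_families) < true_vaf
    fam <- rep(seq_len(n_families), sizes)
    n_reads <- length(fam)
    m <- matrix(rep(ref, each = n_reads), nrow = n_reads)
    m[mutant[fam], mutant_pos] <- mutant_base
    if (error_rate > 0) {
      err <- matrix(runif(n_reads * width) < error_rate, nrow = n_reads)
      idx <- which(err)
      if (length(idx) > 0) {
        cur <- m[idx]
        shift <- sample.int(3, length(idx), replace = TRUE)
        m[idx] <- bases4[(match(cur, bases4) - 1L + shift) %% 4L + 1L]
      }
    }
    tibble(
      umi = sprintf("F%06d", fam),
      site_window = "site1",
      bases = do.call(paste0, lapply(seq_len(width), function(j) m[, j])),
      true_mutant = mutant[fam]
    )
  })
}

#' Simulate a random signed regulon network
#'
#' Each regulator controls its own disjoint block of target genes with signed
#' effects, a convenient structure for parameter-recovery studies (removing a
#' regulator cannot affect another's targets).
#'
#' @param n_regulators,n_targets Number of regulators and targets per
#'   regulator.
#' @param prop_negative Proportion of repressive (-1) edges.
#' @param seed Optional integer seed.
#' @return A `regulon_network` tibble (`regulator`, `target`, `sign`).
#' @export
sim_regulon_network <- function(n_regulators = 50, n_targets = 20,
                                prop_negative = 0.3, seed = NULL) {
  check_fraction(prop_negative, "prop_negative")
  with_seed_if(seed, {
    edges <- tidyr::expand_grid(
      reg_i = seq_len(n_regulators),
      tgt_i = seq_len(n_targets)
    ) |>
      mutate(
        regulator = sprintf("R%03d", .data$reg_i),
        target = sprintf("R%03d_T%03d", .data$reg_i, .data$tgt_i),
        sign = ifelse(runif(dplyr::n()) < prop_negative, -1, 1)
      ) |>
      select("regulator", "target", "sign")
    class(edges) <- c("regulon_network", class(edges))
    edges
  })
}

#' Simulate regulator-driven expression data
#'
#' Generates a genes-by-samples matrix of Gaussian noise and, in the
#' designated active samples, shifts the targets of each active regulator by
#' `+effect_size` (positive edges) or `-effect_size` (negative edges) in
#' units of expression; the active regulator's own expression is shifted by
#' `+effect_size` in the same samples, since a regulator drives its targets
#' by being overexpressed or activated itself. With `effect_size = 0` the
#' matrix is pure noise.
#'
#' @param network A `regulon_network` tibble.
#' @param active Character vector of active regulators (subset of the
#'   network's regulators).
#' @param n_samples Cohort size.
#' @param active_samples Indices (or names) of the samples in which the
#'   regulators are active; defaults to the first sample, leaving the rest of
#'   the cohort as an unperturbed reference.
#' @param effect_size Shift applied to targets, in expression units.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed Optional integer seed.
#' @return Genes-by-samples numeric matrix (samples `S01`, `S02`, ...).
#' @export
simulate_regulator_expression <- function(network, active, n_samples = 30,
                                          active_samples = 1,
                                          effect_size = 3, noise_sd = 1,
                                          seed = NULL) {
  check_columns(network, c("regulator", "target", "sign"), "`network`")
  if (nrow(network) == 0) abort("`network` must contain at least one edge")
  if (!all(active %in% network$regulator)) {
    abort("`active` must be a subset of the network's regulators")
  }
  genes <- unique(c(network$regulator, network$target))
  with_seed_if(seed, {
    expr <- matrix(
      rnorm(length(genes) * n_samples, 0, noise_sd),
      nrow = length(genes),
      dimnames = list(genes, sprintf("S%02d", seq_len(n_samples)))
    )
    for (r in active) {
      edges <- network[network$regulator == r, ]
      expr[edges$target, active_samples] <-
        expr[edges$target, active_samples] + edges$sign * effect_size
      # the active regulator is itself overexpressed in the samples it drives
      expr[r, active_samples] <- expr[r, active_samples] + effect_size
    }
    expr
  })
}

#' Simulate a tumor nest with a collagen rim and an intensity gradient
#'
#' Cells are placed uniformly inside a circular tumor nest; the extracellular
#' matrix is an annular collagen rim just outside the nest, rasterized as a
#' binary mask. Marker intensity decreases linearly with the (analytic)
#' distance to the rim at `gradient_slope` intensity units per micrometre,
#' plus Gaussian noise, planting the intensity-versus-distance association the
#' distance-bin ANOVA is designed to detect. Defaults approximate nuclear
#' marker levels near collagen boundaries in breast cancer biopsies
#' (baseline ~800 at the boundary, ~300 lower 75 um inside).
#'
#' @param n_cells Number of cells.
#' @param nest_radius Tumor nest radius in micrometres.
#' @param rim_width Collagen rim thickness in micrometres.
#' @param gradient_slope Intensity decrease per micrometre of distance from
#'   the rim (0 = no gradient).
#' @param baseline Intensity at the rim boundary.
#' @param noise_sd Gaussian intensity noise SD.
#' @param pixel_size Mask pixel size in micrometres per pixel.
#' @param make_mask Rasterize the rim mask (disable for pure statistical
#'   studies that only need `dist_um`).
#' @param seed Optional integer seed.
#' @return List with `cells` (tibble: `cell_id`, `centroid_x`, `centroid_y`
#'   in um, `marker` intensity, and the analytic `dist_um` to the rim),
#'   `mask` (binary matrix or `NULL`), and `pixel_size`.
#' @export
simulate_spatial_tissue <- function(n_cells = 3000, nest_radius = 80,
                                    rim_width = 5, gradient_slope = 5,
                                    baseline = 800, noise_sd = 50,
                                    pixel_size = 1, make_mask = TRUE,
                                    seed = NULL) {
  if (n_cells < 1) abort("`n_cells` must be positive")
  if (nest_radius <= 0 || rim_width <= 0 || pixel_size <= 0) {
    abort("geometry parameters must be positive")
  }
  with_seed_if(seed, {
    # uniform placement in the nest disc
    r <- nest_radius * sqrt(runif(n_cells))
    theta <- runif(n_cells, 0, 2 * pi)
    centre <- nest_radius + rim_width + 2 * pixel_size
    x <- centre + r * cos(theta)
    y <- centre + r * sin(theta)
    dist_um <- nest_radius - r
    marker <- baseline - gradient_slope * dist_um + rnorm(n_cells, 0, noise_sd)
    cells <- tibble(
      cell_id = sprintf("c%05d", seq_len(n_cells)),
      centroid_x = x, centroid_y = y,
      marker = marker, dist_um = dist_um
    )
    mask <- NULL
    if (make_mask) {
      extent <- ceiling(2 * centre / pixel_size)
      cx <- (seq_len(extent) - 0.5) * pixel_size
      rho <- sqrt(outer(cx - centre, cx - centre, function(a, b) a^2 + b^2))
      # rows are y (downward), columns x; the field is radially symmetric
      mask <- rho >= nest_radius & rho <= nest_radius + rim_width
      storage.mode(mask) <- "integer"
    }
    list(cells = cells, mask = mask, pixel_size = pixel_size)
  })
}
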