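#' Build a signed expression-control regulon network
#'
#' Restricts a pairwise molecular-interaction table (SIF triples) to
#' `controls-expression-of` edges whose regulator and target are both present
#' in the expression data, optionally composing secondary (two-step)
#' regulator -> intermediate -> target interactions into direct edges with the
#' product of the signs.
#'
#' @param sif_edges Data frame with columns `source`, `relation`, `target`
#'   and an optional `sign` column (+1/-1; defaults to +1 with a warning when
#'   absent). See [read_sif()].
#' @param expressed_genes Character vector of genes represented in the
#'   expression matrix.
#' @param relation The expression-control relation label to retain.
#' @param expand_secondary Compose two-step expression-control paths into
#'   direct signed edges (depth limited to 2); direct edges win on conflict.
#' @return A `regulon_network` tibble: `regulator`, `target`, `sign`.
#' @export
build_regulon_network <- function(sif_edges, expressed_genes,
                                  relation = "controls-expression-of",
                                  expand_secondary = TRUE) {
  check_columns(sif_edges, c("source", "relation", "target"), "`sif_edges`")
  sif_edges <- as_tibble(sif_edges)
  if (!"sign" %in% names(sif_edges)) {
    warn("no `sign` column in SIF input; assuming all edges are positive")
    sif_edges$sign <- 1
  }
  if (!all(sif_edges$sign %in% c(-1, 1))) abort("`sign` must be +1 or -1")
  prim <- sif_edges |>
    filter(.data$relation == !!relation, .data$source != .data$target) |>
    select(regulator = "source", target = "target", "sign") |>
    distinct(.data$regulator, .data$target, .keep_all = TRUE)

  edges <- prim
  if (expand_secondary && nrow(prim) > 0) {
    sec <- prim |>
      inner_join(prim,
        by = c("target" = "regulator"),
        suffix = c("_1", "_2"), relationship = "many-to-many"
      ) |>
      transmute(
        regulator = .data$regulator,
        target = .data$target_2,
        sign = .data$sign_1 * .data$sign_2
      ) |>
      filter(.data$regulator != .data$target) |>
      distinct(.data$regulator, .data$target, .keep_all = TRUE)
    edges <- bind_rows(prim, sec) |>
      distinct(.data$regulator, .data$target, .keep_all = TRUE) # direct edges first
  }
  edges <- edges |>
    filter(
      .data$regulator %in% expressed_genes,
      .data$target %in% expressed_genes
    )
  if (nrow(edges) == 0) {
    abort("no expression-control edges remain after restricting to expressed genes")
  }
  class(edges) <- c("regulon_network", class(edges))
  edges
}

#' Assign evidence weights to regulator-target edges
#'
#' Each edge is weighted from two evidence sources measured across the cohort:
#' the Spearman rank correlation \eqn{\rho} between regulator and target
#' expression (direction and monotone association) and the F statistic of the
#' univariate linear regression of target on regulator (linear dependency).
#' The combined weight is \eqn{w = \rho (1 - p_F)}, sign-preserving and
#' monotone in both sources; edges with a constant regulator or target get
#' weight 0, and edges whose regulator is absent from the matrix are dropped
#' with a warning.
#'
#' @param network A `regulon_network` tibble.
#' @param expression_matrix Numeric genes-by-samples matrix (at least 4
#'   samples).
#' @return The network with `rho`, `f_stat`, `p_f` and `weight` columns.
#' @export
assign_edge_weights <- function(network, expression_matrix) {
  check_columns(network, c("regulator", "target", "sign"), "`network`")
  if (ncol(expression_matrix) < 4) {
    abort("at least 4 samples are required to estimate edge weights")
  }
  genes <- rownames(expression_matrix)
  missing_reg <- !(network$regulator %in% genes)
  missing_tgt <- !(network$target %in% genes)
  if (any(missing_reg | missing_tgt)) {
    warn(sprintf(
      "%d edge(s) dropped: regulator or target absent from the expression matrix",
      sum(missing_reg | missing_tgt)
    ))
    network <- network[!(missing_reg | missing_tgt), ]
  }
  n <- ncol(expression_matrix)
  reg <- expression_matrix[network$regulator, , drop = FALSE]
  tgt <- expression_matrix[network$target, , drop = FALSE]

  row_cor <- function(x, y) {
    # per-row Pearson correlation of two conformable matrices
    xc <- x - rowMeans(x)
    yc <- y - rowMeans(y)
    sx <- sqrt(rowSums(xc^2))
    sy <- sqrt(rowSums(yc^2))
    out <- rowSums(xc * yc) / (sx * sy)
    out[sx == 0 | sy == 0] <- NA_real_
    out
  }
  rank_rows <- function(m) t(apply(m, 1, rank, ties.method = "average"))

  rho <- unname(row_cor(rank_rows(reg), rank_rows(tgt)))
  r_lin <- unname(row_cor(reg, tgt))
  f_stat <- (n - 2) * r_lin^2 / pmax(1 - r_lin^2, .Machine$double.eps)
  p_f <- pf(f_stat, 1, n - 2, lower.tail = FALSE)

  out <- as_tibble(network) |>
    mutate(
      rho = rho,
      f_stat = f_stat,
      p_f = p_f,
      weight = ifelse(is.na(rho) | is.na(p_f), 0, rho * (1 - p_f))
    ) |>
    mutate(
      rho = ifelse(is.na(.data$rho), 0, .data$rho),
      f_stat = ifelse(is.na(.data$f_stat), 0, .data$f_stat),
      p_f = ifelse(is.na(.data$p_f), 1, .data$p_f)
    )
  class(out) <- c("regulon_network", class(out))
  out
}

#' Median-reference gene signature for one sample
#'
#' The per-gene signature score is the sample's (log-scale) expression minus
#' the cohort median for that gene; genes are then ranked by descending score
#' (rank 1 = most over-expressed), ties by average rank.
#'
#' @param expression_matrix Numeric genes-by-samples matrix (>= 3 samples).
#' @param sample_id Column name of the query sample.
#' @return Tibble `gene`, `score`, `rank`.
#' @export
compute_signature <- function(expression_matrix, sample_id) {
  if (!sample_id %in% colnames(expression_matrix)) {
    abort(sprintf("sample `%s` not found in the expression matrix", sample_id))
  }
  if (ncol(expression_matrix) < 3) {
    abort("at least 3 cohort samples are required for a median-reference signature")
  }
  med <- apply(expression_matrix, 1, median)
  score <- expression_matrix[, sample_id] - med
  tibble(
    gene = rownames(expression_matrix),
    score = unname(score),
    rank = rank_desc(score)
  )
}

# Directional quantiles of regulon targets. `positions` are ascending-score
# ranks (1 = lowest score) within a reference list of size m; positive-edge
# targets use rank/(m+1) (activation pushes them up), negative-edge targets
# the reversed ranking.
directional_quantiles <- function(position, sign, m) {
  q <- position / (m + 1)
  ifelse(sign > 0, q, 1 - q)
}

# Repeat counts proportional to |weight| (1..10 bins), used to weight-integrate
# quantiles into a median.
weight_reps <- function(w) {
  aw <- abs(w)
  if (length(aw) == 0 || max(aw) == 0) {
    return(rep(1L, length(aw)))
  }
  1L + as.integer(floor(9 * aw / max(aw)))
}

regulon_targets_in_signature <- function(network, signature, regulator) {
  network |>
    filter(.data$regulator == !!regulator) |>
    inner_join(signature, by = c("target" = "gene"))
}

# Component cores operating on a prejoined regulon-target table `tg`
# (columns sign, weight, score). Shared by the single-regulator wrappers and
# the vectorised regulon_activity() driver.
ldc_core <- function(tg) {
  if (nrow(tg) == 0) {
    return(NA_real_)
  }
  per_group <- vapply(c(1, -1), function(s) {
    g <- tg[tg$sign == s, ]
    if (nrow(g) < 2) {
      return(NA_real_)
    }
    dir_rank <- if (s > 0) rank(g$score) else rank(-g$score)
    w_rank <- rank(abs(g$weight))
    if (sd(dir_rank) == 0 || sd(w_rank) == 0) {
      return(NA_real_)
    }
    cor(w_rank, dir_rank, method = "spearman")
  }, numeric(1))
  if (all(is.na(per_group))) {
    return(NA_real_)
  }
  mean(per_group, na.rm = TRUE)
}

le_core <- function(tg) {
  m <- nrow(tg)
  if (m == 0) {
    return(NA_real_)
  }
  n_pos <- sum(tg$sign > 0)
  n_neg <- m - n_pos
  if (n_pos == 0 || n_neg == 0) {
    # a one-sign regulon carries no within-regulon directional contrast
    return(NA_real_)
  }
  r_all <- rank(tg$score, ties.method = "average")
  is_pos <- tg$sign > 0
  shift <- numeric(m)
  # positive targets: fraction of negative-edge targets ranked below them
  shift[is_pos] <- (r_all[is_pos] - rank(tg$score[is_pos], ties.method = "average")) / n_neg
  # negative targets: fraction of positive-edge targets ranked above them
  shift[!is_pos] <- ((m - r_all[!is_pos]) -
    (n_neg - rank(tg$score[!is_pos], ties.method = "average"))) / n_pos
  reps <- weight_reps(tg$weight)
  2 * (median(rep(shift, times = reps)) - 0.5)
}

ge_core <- function(tg, global_rank, m) {
  if (nrow(tg) == 0) {
    return(NA_real_)
  }
  q <- directional_quantiles(global_rank[tg$.gene_idx], tg$sign, m)
  2 * (median(q) - 0.5)
}

# Robust (winsorized at 3 MAD) ascending ranks of the signature scores.
robust_global_ranks <- function(score) {
  med <- median(score)
  lim <- 3 * mad(score)
  if (lim > 0) score <- pmin(pmax(score, med - lim), med + lim)
  rank(score, ties.method = "average")
}

#' Local delta concordance component of a regulon enrichment signature
#'
#' Within the regulon-restricted feature space, positive-edge targets are
#' ranked ascending by signature score and negative-edge targets descending.
#' The component is the Spearman correlation between the |weight| ranks and
#' these directional signature ranks, computed independently per edge-sign
#' group and averaged over the groups that are defined — so the signal of an
#' under-represented edge group still contributes.
#'
#' @param network A weighted `regulon_network` (see [assign_edge_weights()]).
#' @param signature A signature tibble from [compute_signature()].
#' @param regulator The regulator to score.
#' @return A single score in `[-1, 1]`, or `NA` when no group supports a
#'   correlation.
#' @export
local_delta_concordance <- function(network, signature, regulator) {
  check_columns(network, c("regulator", "target", "sign", "weight"), "`network`")
  ldc_core(regulon_targets_in_signature(network, signature, regulator))
}

#' Local enrichment component of a regulon enrichment signature
#'
#' Measures the directional separation of the two edge-sign groups within the
#' regulon-restricted ranked list. Each target's position is
#' quantile-transformed to (0, 1) against the complementary sign group — for a
#' positive-edge target, the fraction of negative-edge targets ranked below
#' it; for a negative-edge target, the fraction of positive-edge targets
#' ranked above it — so activation pushes every transformed position toward 1
#' and repression toward 0. Each quantile is repeated in proportion to its
#' edge |weight| (10 bins) and the component is `2 * (median - 0.5)` of the
#' weighted multiset: +1 at perfect directional separation, 0 under the
#' permutation null, -1 at perfect inversion. One-sign regulons carry no
#' within-regulon directional contrast and return `NA` (the component is then
#' excluded from integration).
#'
#' @inheritParams local_delta_concordance
#' @return Score in `[-1, 1]`, `NA` when no targets are present.
#' @export
local_enrichment <- function(network, signature, regulator) {
  check_columns(network, c("regulator", "target", "sign", "weight"), "`network`")
  le_core(regulon_targets_in_signature(network, signature, regulator))
}

#' Global enrichment component of a regulon enrichment signature
#'
#' Projects the regulon targets onto the global ranked feature space: all
#' signature scores are winsorized at 3 MAD around the median (the robust
#' transform), ranked ascending, and quantile-transformed as `rank/(m+1)`
#' over all genes; negative-edge targets are read off the reversed ranking.
#' The component is `2 * (median quantile - 0.5)` — the median of the robust
#' quantile-transformed ranked positions, recentred — reaching +1 when the
#' regulon occupies the global extremes consistent with activation and -1
#' for symmetric repression.
#'
#' @inheritParams local_delta_concordance
#' @return Score in `[-1, 1]`, `NA` when no targets are present.
#' @export
global_enrichment <- function(network, signature, regulator) {
  check_columns(network, c("regulator", "target", "sign", "weight"), "`network`")
  tg <- regulon_targets_in_signature(network, signature, regulator)
  tg$.gene_idx <- match(tg$target, signature$gene)
  ge_core(tg, robust_global_ranks(signature$score), length(signature$score))
}

#' Integrate the three regulon components into activity scores
#'
#' Each component is standardized across regulators by its median and MAD
#' (components with zero MAD standardize to 0), and the integrated score is
#' the mean of the available standardized components. Regulators are ranked
#' by integrated score.
#'
#' @param components Tibble with columns `regulator`,
#'   `local_delta_concordance`, `local_enrichment`, `global_enrichment`
#'   (NA = component undefined for that regulator).
#' @return A `regulon_scores` tibble adding standardized components (`*_z`),
#'   `integrated` and `rank`.
#' @export
integrate_scores <- function(components) {
  check_columns(
    components,
    c("regulator", "local_delta_concordance", "local_enrichment", "global_enrichment"),
    "`components`"
  )
  if (nrow(components) == 0) abort("no regulators to integrate")
  robust_z <- function(x) {
    m <- median(x, na.rm = TRUE)
    s <- mad(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      return(ifelse(is.na(x), NA_real_, 0))
    }
    (x - m) / s
  }
  out <- as_tibble(components) |>
    mutate(
      local_delta_concordance_z = robust_z(.data$local_delta_concordance),
      local_enrichment_z = robust_z(.data$local_enrichment),
      global_enrichment_z = robust_z(.data$global_enrichment)
    )
  zmat <- as.matrix(out[c(
    "local_delta_concordance_z",
    "local_enrichment_z", "global_enrichment_z"
  )])
  if (any(rowSums(!is.na(zmat)) == 0)) {
    abort("every regulator needs at least one defined component")
  }
  out <- out |>
    mutate(
      integrated = rowMeans(zmat, na.rm = TRUE),
      rank = rank_desc(.data$integrated)
    ) |>
    arrange(.data$rank)
  class(out) <- c("regulon_scores", class(out))
  out
}

#' Regulator activity scores for one sample
#'
#' End-to-end convenience wrapper: computes the median-reference signature for
#' `sample_id`, evaluates the three enrichment components for every regulator
#' in the weighted network, and integrates them with [integrate_scores()].
#'
#' @param network A weighted `regulon_network`; if the `weight` column is
#'   missing it is estimated from `expression_matrix` with
#'   [assign_edge_weights()].
#' @param expression_matrix Genes-by-samples matrix.
#' @param sample_id Query sample.
#' @return A `regulon_scores` tibble (see [integrate_scores()]).
#' @export
regulon_activity <- function(network, expression_matrix, sample_id) {
  if (!"weight" %in% names(network)) {
    network <- assign_edge_weights(network, expression_matrix)
  }
  check_columns(network, c("regulator", "target", "sign", "weight"), "`network`")
  signature <- compute_signature(expression_matrix, sample_id)
  joined <- inner_join(as_tibble(network), signature, by = c("target" = "gene"))
  joined$.gene_idx <- match(joined$target, signature$gene)
  g_rank <- robust_global_ranks(signature$score)
  m <- length(signature$score)
  regulators <- unique(network$regulator)
  split_tg <- split(joined, factor(joined$regulator, levels = regulators))
  components <- tibble(
    regulator = regulators,
    local_delta_concordance = vapply(split_tg, ldc_core, numeric(1)),
    local_enrichment = vapply(split_tg, le_core, numeric(1)),
    global_enrichment = vapply(
      split_tg, function(tg) ge_core(tg, g_rank, m), numeric(1)
    )
  )
  integrate_scores(components)
}

#' Change in regulator activity between two samples or timepoints
#'
#' @param scores_t1,scores_t2 `regulon_scores` tibbles over the same
#'   regulator set (e.g. two serial biopsies).
#' @return Tibble with per-regulator integrated scores at both timepoints,
#'   their difference (`delta`, t2 - t1) and ratio, ranked by absolute delta.
#' @export
activity_delta <- function(scores_t1, scores_t2) {
  check_columns(scores_t1, c("regulator", "integrated"), "`scores_t1`")
  check_columns(scores_t2, c("regulator", "integrated"), "`scores_t2`")
  shared <- intersect(scores_t1$regulator, scores_t2$regulator)
  if (length(shared) == 0) abort("the two score tables share no regulators")
  tibble(regulator = shared) |>
    left_join(as_tibble(scores_t1)[c("regulator", "integrated")], by = "regulator") |>
    rename(integrated_t1 = "integrated") |>
    left_join(as_tibble(scores_t2)[c("regulator", "integrated")], by = "regulator") |>
    rename(integrated_t2 = "integrated") |>
    mutate(
      delta = .data$integrated_t2 - .data$integrated_t1,
      ratio = ifelse(.data$integrated_t1 == 0, NA_real_,
        .data$integrated_t2 / .data$integrated_t1
      )
    ) |>
    arrange(desc(abs(.data$delta)))
}

#' @method tidy regulon_scores
#' @export
tidy.regulon_scores <- function(x, ...) {
  as_tibble(x)[c(
    "regulator", "local_delta_concordance", "local_enrichment",
    "global_enrichment", "integrated", "rank"
  )]
}

#' @method glance regulon_scores
#' @export
glance.regulon_scores <- function(x, ...) {
  tibble(
    n_regulators = nrow(x),
    top_regulator = x$regulator[x$rank == 1][1],
    top_score = max(x$integrated)
  )
}
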