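#' Filter somatic variant records by VAF and depth
#'
#' Removes observations with VAF lower than 5% or sequencing depth lower than
#' 30 reads; records sitting exactly on either boundary are kept ("lower than"
#' is a strict removal rule).
#'
#' @param records Data frame with at least `vaf` and `depth` columns.
#' @param min_vaf,min_depth Inclusive retention thresholds.
#' @return Tibble of retained records.
#' @export
filter_variants <- function(records, min_vaf = 0.05, min_depth = 30) {
  check_columns(records, c("vaf", "depth"), "`records`")
  as_tibble(records) |>
    filter(.data$vaf >= min_vaf, .data$depth >= min_depth)
}

#' Classify somatic variants across serial tumor samples
#'
#' Each (variant, sample) pair receives an evidence state: `called` when the
#' somatic caller flagged it, `supported` when it was not independently called
#' but at least `min_supporting` reads carry the alternate allele (the
#' reduced-opacity state in cross-biopsy mutation heatmaps), and `absent`
#' otherwise (including pairs missing from the table). Variants are then
#' categorised from their called evidence: `ubiquitous` (called in every
#' sample), `shared` (called in at least two), or `private` (called in exactly
#' one). Variants called nowhere are excluded with a warning.
#'
#' @param records Data frame with `sample_id`, `variant_id`, `called`
#'   (logical) and `supporting_reads` columns.
#' @param samples Character vector fixing the sample set; defaults to the
#'   samples observed in `records`.
#' @param count_supported When `TRUE`, the `supported` state also counts as
#'   presence for category assignment (the default counts called evidence
#'   only, treating support as annotation).
#' @param min_supporting Read-support threshold for the `supported` state.
#' @return A `variant_classification` tibble, one row per (variant, sample):
#'   `variant_id`, `sample_id`, `evidence`, `category`.
#' @export
classify_across_samples <- function(records, samples = NULL,
                                    count_supported = FALSE,
                                    min_supporting = 2) {
  check_columns(records,
    c("sample_id", "variant_id", "called", "supporting_reads"), "`records`"
  )
  records <- as_tibble(records)
  samples <- samples %||% unique(records$sample_id)
  extra <- setdiff(records$sample_id, samples)
  if (length(extra) > 0) {
    abort(sprintf("records contain samples outside `samples`: %s", paste(extra, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    variant_id = unique(records$variant_id),
    sample_id = samples
  )
  long <- grid |>
    left_join(
      records |> select("variant_id", "sample_id", "called", "supporting_reads"),
      by = c("variant_id", "sample_id")
    ) |>
    mutate(
      evidence = dplyr::case_when(
        !is.na(.data$called) & .data$called ~ "called",
        !is.na(.data$supporting_reads) & .data$supporting_reads >= min_supporting ~ "supported",
        TRUE ~ "absent"
      )
    )
  cats <- long |>
    summarise(
      n_called = sum(.data$evidence == "called"),
      n_present = sum(.data$evidence == "called" |
        (count_supported & .data$evidence == "supported")),
      .by = "variant_id"
    ) |>
    mutate(
      category = dplyr::case_when(
        .data$n_called == 0 ~ NA_character_,
        .data$n_present == length(samples) ~ "ubiquitous",
        .data$n_present >= 2 ~ "shared",
        TRUE ~ "private"
      )
    )
  dropped <- cats$variant_id[is.na(cats$category)]
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d variant(s) called in no sample were excluded: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  out <- long |>
    inner_join(cats |> filter(!is.na(.data$category)) |>
      select("variant_id", "category"), by = "variant_id") |>
    select("variant_id", "sample_id", "evidence", "category")
  class(out) <- c("variant_classification", class(out))
  attr(out, "samples") <- samples
  out
}

#' Binary presence table from classified variants
#'
#' @param classified Output of [classify_across_samples()].
#' @param use Evidence states that count as presence (`"called"` by default,
#'   mirroring the category rule).
#' @return Integer 0/1 matrix, samples in rows, variants in columns ordered by
#'   `variant_id`.
#' @export
binary_matrix <- function(classified, use = "called") {
  check_columns(classified, c("variant_id", "sample_id", "evidence"), "`classified`")
  samples <- attr(classified, "samples") %||% unique(classified$sample_id)
  variants <- sort(unique(classified$variant_id))
  m <- matrix(0L, length(samples), length(variants),
    dimnames = list(samples, variants)
  )
  hits <- classified[classified$evidence %in% use, ]
  m[cbind(
    match(hits$sample_id, samples),
    match(hits$variant_id, variants)
  )] <- 1L
  m
}

#' Pairwise genetic distance on a binary variant table
#'
#' The distance between two samples is the number of variant columns in which
#' they differ (pairwise Hamming count over presence/absence calls).
#'
#' @param mat Samples-by-variants 0/1 matrix.
#' @return Symmetric numeric matrix with zero diagonal and the sample labels
#'   as dimnames.
#' @export
pairwise_gene_distance <- function(mat) {
  if (!all(mat %in% c(0, 1))) abort("`mat` must be a 0/1 matrix")
  d <- as.matrix(stats::dist(mat, method = "manhattan"))
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

# --- exhaustive unrooted topology enumeration ------------------------------

# A topology is a list(edges = 2-col matrix of node ids, n_nodes). Leaves are
# 1..n; internal nodes are numbered above n. Trees are grown by attaching each
# new leaf to every edge of every smaller tree, which enumerates all
# (2n-5)!! unrooted binary topologies exactly once.
enumerate_topologies <- function(n) {
  base <- list(list(
    edges = cbind(c(n + 1L, n + 1L, n + 1L), c(1L, 2L, 3L)),
    n_nodes = n + 1L
  ))
  if (n == 3) {
    return(base)
  }
  trees <- base
  for (k in 4:n) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(e) {
        w <- tr$n_nodes + 1L
        edges <- rbind(
          tr$edges[-e, , drop = FALSE],
          c(tr$edges[e, 1], w),
          c(w, tr$edges[e, 2]),
          c(w, k)
        )
        list(edges = edges, n_nodes = w)
      })
    }), recursive = FALSE)
  }
  trees
}

# Adjacency list (node -> neighbours with edge index) for an edge matrix.
adjacency_list <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]
    v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  adj
}

# Pair-by-edge path incidence matrix for leaves 1..n (pairs in combn order).
path_incidence <- function(edges, n, n_nodes) {
  adj <- adjacency_list(edges, n_nodes)
  n_edges <- nrow(edges)
  pairs <- utils::combn(n, 2)
  A <- matrix(0L, ncol(pairs), n_edges)
  for (i in seq_len(n)) {
    # BFS from leaf i, recording the edge used to reach each node
    parent_edge <- rep(NA_integer_, n_nodes)
    parent_node <- rep(NA_integer_, n_nodes)
    visited <- rep(FALSE, n_nodes)
    queue <- i
    visited[i] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- adj[[u]]
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (!visited[v]) {
          visited[v] <- TRUE
          parent_edge[v] <- nb[r, 2]
          parent_node[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    for (j in seq_len(n)) {
      if (j <= i) next
      row <- which(pairs[1, ] == i & pairs[2, ] == j)
      node <- j
      while (node != i) {
        A[row, parent_edge[node]] <- 1L
        node <- parent_node[node]
      }
    }
  }
  A
}

# Canonical Newick string of a topology (optionally with branch lengths),
# rooted at the internal neighbour of leaf 1, children sorted by smallest
# descendant label. Used for deterministic tie-breaking and for export.
canonical_newick <- function(edges, n_nodes, labels, lengths = NULL) {
  adj <- adjacency_list(edges, n_nodes)
  build <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (nrow(kids) == 0) {
      return(list(str = labels[node], min = labels[node]))
    }
    parts <- lapply(seq_len(nrow(kids)), function(r) {
      sub <- build(kids[r, 1], node)
      str <- sub$str
      if (!is.null(lengths)) {
        str <- sprintf("%s:%.17g", str, lengths[kids[r, 2]])
      }
      list(str = str, min = sub$min)
    })
    ord <- order(vapply(parts, function(p) p$min, character(1)))
    list(
      str = paste0("(", paste(vapply(parts[ord], function(p) p$str, character(1)),
        collapse = ","
      ), ")"),
      min = min(vapply(parts, function(p) p$min, character(1)))
    )
  }
  root <- adj[[1]][1, 1] # the internal node attached to leaf 1
  paste0(build(root, -1L)$str, ";")
}

#' Minimum-evolution phylogeny by exhaustive OLS search
#'
#' Enumerates every unrooted binary topology over the samples (exact for 3-8
#' taxa), fits branch lengths to the observed distances by ordinary least
#' squares of leaf-to-leaf path lengths, and returns the topology whose total
#' branch length (negative OLS estimates clamped to zero for the length
#' criterion) is minimal — the minimum-evolution optimum, found without
#' heuristics. Ties are broken deterministically by canonical Newick string
#' order.
#'
#' @param d Symmetric distance matrix with sample labels as dimnames (e.g.
#'   from [pairwise_gene_distance()]), or a `dist` object.
#' @return An object of class `me_tree`: `tree` (an [ape::read.tree()] `phylo`
#'   with clamped branch lengths), `newick`, `tree_length`, `raw_lengths`
#'   (unclamped OLS estimates, edge order matching `edges`), `fitted` and
#'   `residuals` on the leaf-pair distances, and `n_topologies` searched.
#' @export
minimum_evolution_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) abort("at least 3 taxa are required")
  if (n > 8) {
    abort("exhaustive minimum-evolution search supports at most 8 taxa; use a heuristic ME implementation for larger problems")
  }
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    abort("`d` must be symmetric with a zero diagonal")
  }
  pairs <- utils::combn(n, 2)
  dv <- d[cbind(pairs[1, ], pairs[2, ])]

  topos <- enumerate_topologies(n)
  best <- NULL
  for (tr in topos) {
    A <- path_incidence(tr$edges, n, tr$n_nodes)
    fit <- stats::lm.fit(A, dv)
    b <- fit$coefficients
    len <- sum(pmax(b, 0))
    key <- canonical_newick(tr$edges, tr$n_nodes, labels)
    if (is.null(best) || len < best$len - 1e-12 ||
      (abs(len - best$len) <= 1e-12 && key < best$key)) {
      best <- list(tr = tr, b = b, len = len, key = key, A = A)
    }
  }
  clamped <- pmax(best$b, 0)
  newick <- canonical_newick(best$tr$edges, best$tr$n_nodes, labels, clamped)
  fitted <- as.numeric(best$A %*% best$b)
  out <- list(
    tree = ape::read.tree(text = newick),
    newick = newick,
    tree_length = best$len,
    raw_lengths = unname(best$b),
    edges = best$tr$edges,
    labels = labels,
    fitted = fitted,
    residuals = dv - fitted,
    distances = dv,
    n_topologies = length(topos)
  )
  class(out) <- "me_tree"
  out
}

#' Export a fitted tree as Newick text
#'
#' @param tree An `me_tree` object or an `ape` `phylo` tree.
#' @return A Newick string (with branch lengths) that round-trips through
#'   [ape::read.tree()].
#' @export
to_newick <- function(tree) {
  if (inherits(tree, "me_tree")) {
    return(tree$newick)
  }
  if (inherits(tree, "phylo")) {
    return(ape::write.tree(tree))
  }
  abort("`tree` must be an `me_tree` or `phylo` object")
}

#' @export
print.me_tree <- function(x, ...) {
  cat("Minimum-evolution tree (exhaustive OLS search)\n")
  cat(sprintf(
    "  %d taxa, %d topologies searched, tree length %.6g\n",
    length(x$labels), x$n_topologies, x$tree_length
  ))
  cat("  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' @method tidy me_tree
#' @export
tidy.me_tree <- function(x, ...) {
  tibble(
    parent = x$edges[, 1],
    child = x$edges[, 2],
    label = ifelse(x$edges[, 2] <= length(x$labels),
      x$labels[x$edges[, 2]], NA_character_
    ),
    raw_length = x$raw_lengths,
    length = pmax(x$raw_lengths, 0)
  )
}

#' @method glance me_tree
#' @export
glance.me_tree <- function(x, ...) {
  tibble(
    n_taxa = length(x$labels),
    n_topologies = x$n_topologies,
    tree_length = x$tree_length,
    max_abs_residual = max(abs(x$residuals))
  )
}

#' @export
plot.me_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, type = "unrooted", ...)
  invisible(x)
}
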