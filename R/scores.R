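#' RPPA pathway score for one sample
#'
#' Sum of the positively associated predictor proteins minus the negatively
#' associated ones, divided by the number of predictors used. Predictors
#' missing from `values` are excluded with a warning and the divisor reduced
#' accordingly; a pathway with no usable predictor is an error.
#'
#' @param values Named numeric vector of (phospho)protein abundances for one
#'   sample.
#' @param positive,negative Character vectors of predictor proteins; must be
#'   disjoint and jointly non-empty.
#' @return A single pathway score.
#' @export
#' @examples
#' pathway_score(c(a = 2, b = 4, c = 1), positive = c("a", "b"), negative = "c") # (2+4-1)/3
pathway_score <- function(values, positive, negative = character(0)) {
  if (length(intersect(positive, negative)) > 0) {
    abort("positive and negative predictor lists must be disjoint")
  }
  if (length(positive) + length(negative) == 0) {
    abort("at least one predictor is required")
  }
  pos_have <- intersect(positive, names(values))
  neg_have <- intersect(negative, names(values))
  missing <- setdiff(c(positive, negative), names(values))
  if (length(missing) > 0) {
    warn(sprintf(
      "predictor(s) missing from sample and excluded: %s",
      paste(missing, collapse = ", ")
    ))
  }
  n_used <- length(pos_have) + length(neg_have)
  if (n_used == 0) abort("no usable predictors for this pathway")
  (sum(values[pos_have]) - sum(values[neg_have])) / n_used
}

#' Pathway scores for a cohort from a predictor definition table
#'
#' @param protein_matrix Proteins-by-samples numeric matrix.
#' @param definitions Tibble with columns `pathway`, `protein`, `direction`
#'   (`"positive"`/`"negative"`).
#' @return Tibble `sample`, `pathway`, `score`.
#' @export
pathway_scores <- function(protein_matrix, definitions) {
  check_columns(definitions, c("pathway", "protein", "direction"), "`definitions`")
  if (!all(definitions$direction %in% c("positive", "negative"))) {
    abort("`direction` must be \"positive\" or \"negative\"")
  }
  pathways <- split(definitions, definitions$pathway)
  purrr::map_dfr(names(pathways), function(pw) {
    def <- pathways[[pw]]
    tibble(
      sample = colnames(protein_matrix),
      pathway = pw,
      score = unname(vapply(
        colnames(protein_matrix),
        function(s) {
          pathway_score(
            setNames(protein_matrix[, s], rownames(protein_matrix)),
            positive = def$protein[def$direction == "positive"],
            negative = def$protein[def$direction == "negative"]
          )
        },
        numeric(1)
      ))
    )
  })
}

#' Robust cohort z-scores for a protein or expression matrix
#'
#' Per feature (row), `z = (x - cohort median) / cohort SD`. Features with
#' zero SD are set to 0 and flagged in the `"constant_features"` attribute.
#'
#' @param mat Features-by-samples numeric matrix (>= 3 samples).
#' @return Matrix of the same shape.
#' @export
cohort_zscore <- function(mat) {
  if (ncol(mat) < 3) abort("at least 3 samples are required for cohort z-scoring")
  med <- apply(mat, 1, median)
  s <- apply(mat, 1, sd)
  const <- s == 0
  s[const] <- 1
  z <- sweep(sweep(mat, 1, med, "-"), 1, s, "/")
  z[const, ] <- 0
  if (any(const)) {
    warn(sprintf("%d constant feature(s) z-scored to 0", sum(const)))
    attr(z, "constant_features") <- rownames(mat)[const]
  }
  z
}

#' PAM50 intrinsic subtype assignment by centroid correlation
#'
#' The query sample is pooled with a background cohort, the combined matrix is
#' mean-centred per gene, and the centred query profile is correlated
#' (Spearman) against each subtype centroid over the shared gene set. The
#' sample is assigned the subtype with the highest correlation; ties break by
#' the fixed subtype order of the centroid table columns. A best correlation
#' that is negative is flagged (`low_confidence`), but the argmax label is
#' still returned.
#'
#' @param sample_expr Named numeric vector of the query sample's expression.
#' @param centroids Genes-by-subtypes numeric matrix of centroid profiles
#'   (e.g. LumA, LumB, Her2, Basal, Normal).
#' @param background_cohort Genes-by-samples matrix used for mean-centring
#'   (e.g. a 20 ER+ / 20 ER- reference cohort).
#' @param min_genes Minimum number of genes shared between sample, background
#'   and centroids.
#' @return One-row tibble: `subtype`, per-subtype correlations,
#'   `low_confidence`.
#' @export
pam50_assign <- function(sample_expr, centroids, background_cohort, min_genes = 10) {
  genes <- Reduce(intersect, list(
    names(sample_expr), rownames(centroids), rownames(background_cohort)
  ))
  if (length(genes) < min_genes) {
    abort(sprintf(
      "only %d gene(s) shared between sample, centroids and background (need >= %d)",
      length(genes), min_genes
    ))
  }
  combined <- cbind(background_cohort[genes, , drop = FALSE], sample_expr[genes])
  centred <- combined - rowMeans(combined)
  query <- centred[, ncol(centred)]
  cors <- vapply(
    colnames(centroids),
    function(s) cor(query, centroids[genes, s], method = "spearman"),
    numeric(1)
  )
  best <- which.max(cors) # ties: first in centroid column order
  out <- tibble(subtype = colnames(centroids)[best], low_confidence = cors[best] < 0)
  bind_cols(out, as_tibble(as.list(cors)))
}

#' Tumor mutational burden
#'
#' Number of somatic nonsynonymous mutations per megabase of targeted
#' sequence.
#'
#' @param n_nonsynonymous Count of nonsynonymous somatic mutations.
#' @param target_size_mb Size of the targeted regions in megabases (> 0).
#' @return Mutations per megabase.
#' @export
#' @examples
#' tmb(60, 50) # 1.2 mut/Mb
tmb <- function(n_nonsynonymous, target_size_mb) {
  if (any(target_size_mb <= 0)) abort("`target_size_mb` must be positive")
  if (any(n_nonsynonymous < 0)) abort("`n_nonsynonymous` must be non-negative")
  n_nonsynonymous / target_size_mb
}

#' Filter neoepitopes by MHC binding affinity
#'
#' Retains peptides predicted to bind at least one patient allele with
#' affinity strictly below the threshold (nM; lower is stronger binding).
#'
#' @param records Long tibble with columns `peptide`, `allele`,
#'   `affinity_nm`, plus any annotation columns.
#' @param threshold_nm Strict upper bound on the best (minimum) affinity.
#' @return The rows of `records` belonging to retained peptides.
#' @export
filter_neoepitopes <- function(records, threshold_nm = 500) {
  check_columns(records, c("peptide", "affinity_nm"), "`records`")
  if (any(records$affinity_nm <= 0, na.rm = TRUE)) {
    abort("binding affinities must be positive")
  }
  if (nrow(records) == 0) {
    return(as_tibble(records))
  }
  as_tibble(records) |>
    group_by(.data$peptide) |>
    filter(min(.data$affinity_nm) < threshold_nm) |>
    ungroup()
}

#' Neoepitopes present in every sample
#'
#' Set intersection over per-sample presence flags, e.g. to find candidate
#' vaccine targets present in the primary tumor and every metastatic biopsy.
#'
#' @param records Tibble with a `peptide` column and one logical presence
#'   column per sample.
#' @param sample_set Character vector naming the presence columns to
#'   intersect.
#' @return Rows of `records` whose peptide is present in all samples.
#' @export
shared_neoepitopes <- function(records, sample_set) {
  check_columns(records, c("peptide", sample_set), "`records`")
  present <- as.matrix(as_tibble(records)[sample_set])
  if (!is.logical(present)) {
    storage.mode(present) <- "logical"
  }
  as_tibble(records)[rowSums(present) == length(sample_set), ]
}
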