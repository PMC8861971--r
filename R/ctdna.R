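#' Select candidate bait sites for a patient-specific ctDNA panel
#'
#' Applies the frequency and depth filters used when designing hybridization
#' capture baits against somatic SNVs: a candidate is eligible when its variant
#' allele frequency (VAF) exceeds 5% in the tumor, stays below 2% in the
#' matched normal, and both libraries are adequately covered (tumor > 30x,
#' normal > 15x). All inequalities are strict.
#'
#' @param candidates Data frame with columns `variant_id`, `tumor_vaf`,
#'   `normal_vaf`, `tumor_depth`, `normal_depth`.
#' @param min_tumor_vaf,max_normal_vaf,min_tumor_depth,min_normal_depth
#'   Selection thresholds (strict inequalities).
#' @return A tibble of eligible candidates, input order preserved.
#' @export
#' @examples
#' baits <- tibble::tibble(
#'   variant_id = c("v1", "v2"), tumor_vaf = c(0.06, 0.05),
#'   normal_vaf = c(0.01, 0.01), tumor_depth = c(40, 40), normal_depth = c(20, 20)
#' )
#' select_bait_sites(baits) # v2 sits exactly at 5% and is excluded
select_bait_sites <- function(candidates,
                              min_tumor_vaf = 0.05,
                              max_normal_vaf = 0.02,
                              min_tumor_depth = 30,
                              min_normal_depth = 15) {
  check_columns(candidates,
    c("variant_id", "tumor_vaf", "normal_vaf", "tumor_depth", "normal_depth"),
    "`candidates`"
  )
  needed <- candidates[c("tumor_vaf", "normal_vaf", "tumor_depth", "normal_depth")]
  if (anyNA(needed)) {
    abort("`candidates` contains missing VAF or depth values")
  }
  check_fraction(candidates$tumor_vaf, "tumor_vaf")
  check_fraction(candidates$normal_vaf, "normal_vaf")
  as_tibble(candidates) |>
    filter(
      .data$tumor_vaf > min_tumor_vaf,
      .data$normal_vaf < max_normal_vaf,
      .data$tumor_depth > min_tumor_depth,
      .data$normal_depth > min_normal_depth
    )
}

#' Reduce a designed bait set to the monitored panel
#'
#' Drops baits that failed wet-lab QC (non-missing `qc_flag`, e.g. the
#' inconsistent-coverage flag) and sites whose VAF in unrelated negative-control
#' plasma exceeds 1%, the exclusion rule that protects the detection statistic
#' from noisy loci.
#'
#' @param baits Data frame of designed baits with a `variant_id` column and an
#'   optional `qc_flag` column (`NA` = passed QC).
#' @param negctrl_vaf Optional data frame (`variant_id`, `negctrl_vaf`) or named
#'   numeric vector of negative-control VAFs; sites absent from it are treated
#'   as 0.
#' @param max_negctrl_vaf Exclusion threshold on the negative-control VAF.
#' @return Tibble of monitored panel sites.
#' @export
filter_panel <- function(baits, negctrl_vaf = NULL, max_negctrl_vaf = 0.01) {
  check_columns(baits, "variant_id", "`baits`")
  baits <- as_tibble(baits)
  if (!"qc_flag" %in% names(baits)) baits$qc_flag <- NA_character_
  out <- filter(baits, is.na(.data$qc_flag))
  if (!is.null(negctrl_vaf)) {
    if (is.numeric(negctrl_vaf)) {
      negctrl_vaf <- tibble(
        variant_id = names(negctrl_vaf),
        negctrl_vaf = unname(negctrl_vaf)
      )
    }
    check_columns(negctrl_vaf, c("variant_id", "negctrl_vaf"), "`negctrl_vaf`")
    nc <- negctrl_vaf$negctrl_vaf[match(out$variant_id, negctrl_vaf$variant_id)]
    nc[is.na(nc)] <- 0
    out <- out[nc <= max_negctrl_vaf, ]
  }
  out
}

# Consensus of a reads-by-positions character matrix; "N" where the modal base
# fails the agreement threshold among non-N observations.
consensus_from_matrix <- function(m, min_agreement) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  counts <- matrix(counts, ncol = 4L)
  non_n <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  top_n <- counts[cbind(seq_len(nrow(counts)), top)]
  out <- ifelse(non_n > 0 & top_n / non_n >= min_agreement, bases[top], "N")
  paste(out, collapse = "")
}

#' Collapse one UMI read family to a consensus sequence
#'
#' Families with fewer than `min_reads` reads are omitted (returned as `NA`).
#' At each position the modal base is emitted only when its fraction among
#' non-N reads reaches `min_agreement` (inclusive), otherwise an `N`. `N`
#' inputs count toward neither the numerator nor the denominator.
#'
#' @param reads Character vector of equal-length read strings over
#'   `{A,C,G,T,N}`.
#' @param min_reads Minimum family size required to emit a consensus.
#' @param min_agreement Minimum per-position agreement fraction (inclusive).
#' @return A single consensus string, or `NA_character_` when the family is
#'   omitted.
#' @export
#' @examples
#' collapse_family(c("ACGT", "ACGT", "ACTT")) # position 3: 2/3 < 0.9 -> "N"
collapse_family <- function(reads, min_reads = 3, min_agreement = 0.9) {
  if (length(reads) == 0) abort("`reads` must be non-empty")
  widths <- nchar(reads)
  if (length(unique(widths)) != 1) {
    abort("all reads in a family must have equal length")
  }
  if (length(reads) < min_reads) {
    return(NA_character_)
  }
  m <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
    nrow = length(reads), byrow = TRUE
  )
  if (!all(m %in% c("A", "C", "G", "T", "N"))) {
    abort("reads may only contain A, C, G, T or N")
  }
  consensus_from_matrix(m, min_agreement)
}

#' Collapse all UMI families in a read table
#'
#' Reads are grouped on `(umi, site_window)`; each group is collapsed with
#' [collapse_family()]. Omitted families (fewer than `min_reads` members) do
#' not appear in the output.
#'
#' @param reads Data frame with columns `umi`, `site_window`, `bases`.
#' @inheritParams collapse_family
#' @return Tibble with columns `umi`, `site_window`, `consensus`,
#'   `family_size`.
#' @export
collapse_families <- function(reads, min_reads = 3, min_agreement = 0.9) {
  check_columns(reads, c("umi", "site_window", "bases"), "`reads`")
  as_tibble(reads) |>
    summarise(
      consensus = collapse_family(.data$bases, min_reads, min_agreement),
      family_size = dplyr::n(),
      .by = c("umi", "site_window")
    ) |>
    filter(!is.na(.data$consensus))
}

#' Mask the ends of consensus reads
#'
#' Replaces the first and last `n_bases` positions of each consensus string
#' with `N`, suppressing end-of-fragment artifacts. Reads of length
#' `<= 2 * n_bases` carry no interior signal and are dropped with a warning.
#'
#' @param consensus Character vector of consensus strings, or a tibble from
#'   [collapse_families()] (its `consensus` column is masked in place).
#' @param n_bases Number of bases to mask at each end.
#' @return Same shape as the input with masked sequences; dropped reads are
#'   removed.
#' @export
mask_read_ends <- function(consensus, n_bases = 3) {
  if (is.data.frame(consensus)) {
    check_columns(consensus, "consensus", "`consensus`")
    masked <- mask_strings(consensus$consensus, n_bases)
    dropped <- sum(is.na(masked) & !is.na(consensus$consensus))
    if (dropped > 0) {
      warn(sprintf(
        "%d read(s) shorter than 2 * n_bases + 1 were omitted during end masking",
        dropped
      ))
    }
    out <- as_tibble(consensus)[!is.na(masked), , drop = FALSE]
    out$consensus <- masked[!is.na(masked)]
    return(out)
  }
  out <- mask_strings(consensus, n_bases)
  if (anyNA(out) && !anyNA(consensus)) {
    warn(sprintf(
      "%d read(s) shorter than 2 * n_bases + 1 were omitted during end masking",
      sum(is.na(out) & !is.na(consensus))
    ))
  }
  out[!is.na(out)]
}

mask_strings <- function(x, n_bases) {
  if (n_bases == 0) {
    return(x)
  }
  len <- nchar(x)
  out <- rep(NA_character_, length(x))
  keep <- len > 2 * n_bases
  mask <- strrep("N", n_bases)
  out[keep] <- paste0(
    mask,
    substr(x[keep], n_bases + 1L, len[keep] - n_bases),
    mask
  )
  out
}

#' Merge overlapping consensus mates into a single fragment sequence
#'
#' Overlapping positions are counted once: agreeing bases are kept,
#' disagreements become `N` (conservative), and a base paired with an `N`
#' passes through. Non-overlapping positions are concatenated unchanged.
#'
#' @param mate1,mate2 Consensus strings for the two mates.
#' @param offset 0-based start position of `mate2` relative to `mate1` within
#'   the shared site window; must be non-negative (`mate1` starts first).
#' @return The merged consensus string spanning both mates.
#' @export
merge_mate_overlap <- function(mate1, mate2, offset) {
  if (length(mate1) != 1 || length(mate2) != 1) {
    abort("`mate1` and `mate2` must be single strings")
  }
  if (!is.numeric(offset) || offset < 0 || offset != round(offset)) {
    abort("`offset` must be a non-negative integer (mate1 starts first)")
  }
  n1 <- nchar(mate1)
  n2 <- nchar(mate2)
  total <- max(n1, offset + n2)
  b1 <- rep("N", total)
  b2 <- rep("N", total)
  b1[seq_len(n1)] <- strsplit(mate1, "", fixed = TRUE)[[1]]
  b2[offset + seq_len(n2)] <- strsplit(mate2, "", fixed = TRUE)[[1]]
  merged <- ifelse(
    b1 == "N", b2,
    ifelse(b2 == "N", b1, ifelse(b1 == b2, b1, "N"))
  )
  paste(merged, collapse = "")
}

#' Tally mutant and total consensus observations at a panel site
#'
#' The VAF at a site is the mutant consensus read count divided by the total
#' non-N consensus read count. `N` observations are excluded from both
#' numerator and denominator; a site covered only by `N`s reports VAF 0 with a
#' warning.
#'
#' @param consensus Character vector of (masked, merged) consensus strings.
#' @param site_pos 1-based position of the site of interest within the window.
#' @param mutant_base The expected mutant base at the site.
#' @param site_id Label for the site.
#' @param timepoint,group Optional labels carried into the tally.
#' @return One-row tibble: `site_id`, `mutant_reads`, `total_reads`, `vaf`,
#'   plus `timepoint`/`group` when given.
#' @export
tally_site <- function(consensus, site_pos, mutant_base, site_id,
                       timepoint = NA_character_, group = NA_character_) {
  if (any(site_pos > nchar(consensus))) {
    abort("`site_pos` lies outside at least one consensus window")
  }
  obs <- substr(consensus, site_pos, site_pos)
  obs <- obs[obs != "N"]
  n <- length(obs)
  k <- sum(obs == mutant_base)
  if (n == 0) {
    warn(sprintf("site %s has no informative consensus reads; VAF reported as 0", site_id))
  }
  tibble(
    site_id = site_id,
    mutant_reads = k,
    total_reads = n,
    vaf = if (n == 0) 0 else k / n,
    timepoint = timepoint,
    group = group
  )
}

# Scalar overlap coefficient of Beta(k1+1, n1-k1+1) and Beta(k0+1, n0-k0+1):
# integral of the pointwise minimum of the two densities. Computed exactly from
# the crossing points of the log-density difference
#   g(x) = C + alpha*log(x) + beta*log(1-x),
# which has at most one interior stationary point and hence at most two roots;
# the overlap is then a sum of pbeta increments of whichever density is smaller
# on each piece.
beta_overlap_scalar <- function(k1, n1, k0, n0) {
  a1 <- k1 + 1
  b1 <- n1 - k1 + 1
  a0 <- k0 + 1
  b0 <- n0 - k0 + 1
  if (a1 == a0 && b1 == b0) {
    return(1)
  }
  al <- a1 - a0
  be <- b1 - b0
  cc <- lbeta(a0, b0) - lbeta(a1, b1)
  g <- function(x) cc + al * log(x) + be * log1p(-x)

  eps <- 1e-14
  knots <- c(eps, 1 - eps)
  if (al != 0 && be != 0 && sign(al) == sign(be)) {
    xs <- al / (al + be) # interior stationary point of g
    if (xs > eps && xs < 1 - eps) knots <- c(eps, xs, 1 - eps)
  }
  roots <- numeric(0)
  for (i in seq_len(length(knots) - 1)) {
    lo <- knots[i]
    hi <- knots[i + 1]
    glo <- g(lo)
    ghi <- g(hi)
    if (is.finite(glo) && is.finite(ghi) && sign(glo) != sign(ghi)) {
      roots <- c(roots, uniroot(g, c(lo, hi), tol = 1e-13)$root)
    }
  }
  cuts <- sort(unique(c(0, roots, 1)))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    lo <- cuts[i]
    hi <- cuts[i + 1]
    mid <- (lo + hi) / 2
    if (g(mid) < 0) { # f1 is the smaller density on this piece
      total <- total + pbeta(hi, a1, b1) - pbeta(lo, a1, b1)
    } else {
      total <- total + pbeta(hi, a0, b0) - pbeta(lo, a0, b0)
    }
  }
  min(max(total, 0), 1)
}

#' Beta-overlap coefficient between sample and negative-control VAFs
#'
#' The detection statistic for error-corrected ctDNA data: the Weitzman
#' overlapping coefficient \eqn{\int_0^1 \min(f_1, f_0)\,dx} of the posterior
#' Beta densities of the sample VAF (\eqn{f_1}, `Beta(k1+1, n1-k1+1)`) and the
#' pooled negative-control VAF (\eqn{f_0}), both under a flat `Beta(1, 1)`
#' prior. It equals 1 for identical count data and decays toward 0 as the two
#' VAF posteriors separate, and is used directly as the p-value for the null
#' hypothesis that sample and control VAFs share one distribution.
#'
#' @param mutant_reads,total_reads Sample mutant and total consensus counts
#'   (vectorised).
#' @param control_mutant,control_total Negative-control counts.
#' @return Numeric vector of overlap coefficients in `[0, 1]`.
#' @export
#' @examples
#' beta_overlap_pvalue(5, 1000, 1, 1000)
beta_overlap_pvalue <- function(mutant_reads, total_reads,
                                control_mutant, control_total) {
  if (any(total_reads <= 0)) abort("sample `total_reads` must be positive")
  if (any(control_total <= 0)) abort("`control_total` must be positive")
  if (any(mutant_reads < 0 | mutant_reads > total_reads) ||
    any(control_mutant < 0 | control_mutant > control_total)) {
    abort("mutant counts must satisfy 0 <= k <= n")
  }
  mapply(
    beta_overlap_scalar,
    mutant_reads, total_reads, control_mutant, control_total
  )
}

#' Call ctDNA detection against matched negative controls
#'
#' Joins sample and control site tallies on `site_id`, computes the
#' beta-overlap p-value per site, and flags detection at `p <= alpha`
#' (boundary inclusive; the non-detection rule is `p > alpha`).
#'
#' @param sample_counts,control_counts Tibbles as produced by [tally_site()]
#'   (columns `site_id`, `mutant_reads`, `total_reads`).
#' @param alpha Detection threshold on the overlap p-value.
#' @return A `ctdna_detection` tibble: `site_id`, sample counts, `vaf`,
#'   `p_value`, `detected`.
#' @export
detect_ctdna <- function(sample_counts, control_counts, alpha = 0.05) {
  check_columns(sample_counts, c("site_id", "mutant_reads", "total_reads"), "`sample_counts`")
  check_columns(control_counts, c("site_id", "mutant_reads", "total_reads"), "`control_counts`")
  joined <- inner_join(
    as_tibble(sample_counts),
    as_tibble(control_counts) |>
      select("site_id",
        control_mutant = "mutant_reads",
        control_total = "total_reads"
      ),
    by = "site_id"
  )
  if (nrow(joined) == 0) abort("no shared `site_id` between sample and control counts")
  out <- joined |>
    mutate(
      vaf = .data$mutant_reads / .data$total_reads,
      p_value = beta_overlap_pvalue(
        .data$mutant_reads, .data$total_reads,
        .data$control_mutant, .data$control_total
      ),
      detected = .data$p_value <= alpha
    )
  class(out) <- c("ctdna_detection", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Pool site tallies into mutational-group tallies
#'
#' Sums mutant and total counts over sites that share a mutational-group label
#' (depth-weighted pooling), so that a single overlap p-value can be computed
#' per group, e.g. mutations shared by several biopsies versus private ones.
#' All pooled sites must come from the same timepoint.
#'
#' @param counts Tibble of site tallies with `group` (and optionally
#'   `timepoint`) labels.
#' @return One tally row per group; its `vaf` is the depth-weighted mean of the
#'   member site VAFs.
#' @export
aggregate_group <- function(counts) {
  check_columns(counts, c("site_id", "mutant_reads", "total_reads", "group"), "`counts`")
  counts <- as_tibble(counts)
  if ("timepoint" %in% names(counts)) {
    n_tp <- counts |>
      summarise(n_tp = dplyr::n_distinct(.data$timepoint), .by = "group")
    if (any(n_tp$n_tp > 1)) {
      abort("cannot pool sites across different timepoints within one group")
    }
  } else {
    counts$timepoint <- NA_character_
  }
  counts |>
    summarise(
      site_id = paste0("group:", dplyr::first(.data$group)),
      mutant_reads = sum(.data$mutant_reads),
      total_reads = sum(.data$total_reads),
      timepoint = dplyr::first(.data$timepoint),
      .by = "group"
    ) |>
    mutate(vaf = ifelse(.data$total_reads == 0, 0, .data$mutant_reads / .data$total_reads)) |>
    select("site_id", "mutant_reads", "total_reads", "vaf", "timepoint", "group")
}
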