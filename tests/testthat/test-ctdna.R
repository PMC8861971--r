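test_that("bait selection applies strict frequency and depth thresholds", {
  candidates <- tibble::tibble(
    variant_id = paste0("v", 1:6),
    tumor_vaf = c(0.06, 0.05, 0.30, 0.10, 0.10, 0.10),
    normal_vaf = c(0.01, 0.01, 0.02, 0.019, 0.00, 0.00),
    tumor_depth = c(40, 40, 100, 100, 30, 100),
    normal_depth = c(20, 20, 50, 50, 50, 15)
  )
  kept <- select_bait_sites(candidates)
  # v1 passes; v2 sits exactly at 5% tumor VAF; v3 exactly at 2% normal VAF;
  # v5 exactly at 30x tumor depth; v6 exactly at 15x normal depth
  expect_equal(kept$variant_id, c("v1", "v4"))
  expect_equal(nrow(select_bait_sites(candidates[0, ])), 0)
  expect_error(
    select_bait_sites(dplyr::mutate(candidates, tumor_vaf = NA_real_)),
    "missing"
  )
})

test_that("panel filtering drops QC-flagged baits and noisy negative-control sites", {
  baits <- demo_bait_panel()
  expect_equal(nrow(baits), 55)
  expect_equal(sum(!is.na(baits$qc_flag)), 2)
  expect_equal(nrow(filter_panel(baits)), 53)

  clean <- tibble::tibble(variant_id = c("a", "b", "c"))
  nc <- tibble::tibble(variant_id = c("a", "b"), negctrl_vaf = c(0.012, 0.01))
  out <- filter_panel(clean, nc)
  expect_equal(out$variant_id, c("b", "c")) # 1.2% removed, 1.0% kept, missing -> 0
  expect_equal(filter_panel(clean)$variant_id, clean$variant_id)
})

test_that("UMI family collapse enforces size and agreement rules", {
  expect_identical(collapse_family(c("ACGT", "ACGT")), NA_character_)
  expect_identical(collapse_family(rep("ACGT", 3)), "ACGT")
  # 9 of 10 reads agree: 0.9 >= 0.9, inclusive boundary
  expect_identical(
    collapse_family(c(rep("A", 9), "C"), min_reads = 3),
    "A"
  )
  # 8 of 10: below threshold -> N
  expect_identical(collapse_family(c(rep("A", 8), "C", "C")), "N")
  # N reads are excluded from the agreement denominator
  expect_identical(collapse_family(c("A", "A", "A", "N", "N")), "A")
  expect_error(collapse_family(c("AC", "ACG", "AC")), "equal length")
  expect_error(collapse_family(c("AX", "AC", "AC")), "A, C, G, T or N")
})

test_that("collapsed tables keep only large-enough families with valid alphabets", {
  reads <- simulate_umi_reads(0.3, n_families = 300, error_rate = 0.05, seed = 42)
  cons <- collapse_families(reads)
  sizes <- dplyr::count(reads, umi)
  expect_true(all(cons$family_size >= 3))
  expect_setequal(cons$umi, sizes$umi[sizes$n >= 3])
  expect_true(all(strsplit(paste(cons$consensus, collapse = ""), "")[[1]] %in%
    c("A", "C", "G", "T", "N")))
})

test_that("end masking replaces flanks with N and drops degenerate reads", {
  expect_identical(mask_read_ends("ACGTACGT"), "NNNTANNN")
  expect_identical(mask_read_ends("ACGT", n_bases = 0), "ACGT")
  expect_warning(out <- mask_read_ends(c("ACGTAC", "ACGTACG")), "omitted")
  expect_identical(out, "NNNTNNN") # only the 7-base read survives
})

test_that("mate overlap merging counts shared positions once and is conservative", {
  expect_identical(merge_mate_overlap("ACGT", "ACGT", offset = 0), "ACGT")
  # disagreement in the overlap -> N; N yields to the informative mate
  expect_identical(merge_mate_overlap("ACGT", "ACTT", offset = 0), "ACNT")
  expect_identical(merge_mate_overlap("ACNT", "ACGT", offset = 0), "ACGT")
  # partial overlap with offset: positions 3-4 agree, 5-6 come from mate2
  expect_identical(merge_mate_overlap("AAAA", "AATT", offset = 2), "AAAATT")
  # no overlap -> concatenation
  expect_identical(merge_mate_overlap("AC", "GT", offset = 2), "ACGT")
  expect_error(merge_mate_overlap("AC", "GT", offset = -1), "non-negative")
})

test_that("site tallies exclude N observations and flag empty sites", {
  cons <- c(rep("ACGTA", 99), "ACTTA", "ACNTA")
  tal <- tally_site(cons, 3, "T", "s1")
  expect_equal(tal$total_reads, 100) # the N read does not count
  expect_equal(tal$mutant_reads, 1)
  expect_equal(tal$vaf, 0.01)
  expect_warning(
    empty <- tally_site(c("AANAA", "AANAA"), 3, "T", "s2"),
    "no informative"
  )
  expect_equal(empty$vaf, 0)
})

test_that("beta overlap matches an independent fine-grid oracle", {
  expect_lt(abs(beta_overlap_pvalue(5, 100, 5, 100) - 1), 1e-9)
  expect_lt(beta_overlap_pvalue(900, 1000, 0, 1000), 1e-6)
  expect_lt(
    abs(beta_overlap_pvalue(5, 1000, 1, 1000) - riemann_overlap(5, 1000, 1, 1000)),
    5e-3
  )
  withr::with_seed(101, {
    for (i in 1:40) {
      n1 <- sample(30:3000, 1)
      n0 <- sample(30:3000, 1)
      k1 <- rbinom(1, n1, runif(1, 0, 0.2))
      k0 <- rbinom(1, n0, runif(1, 0, 0.2))
      expect_lt(
        abs(beta_overlap_pvalue(k1, n1, k0, n0) - riemann_overlap(k1, n1, k0, n0)),
        5e-3
      )
    }
  })
})

test_that("beta overlap is symmetric, maximal only at identity, and decays with separation", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n1 <- sample(50:2000, 1)
      n0 <- sample(50:2000, 1)
      k1 <- sample(0:n1, 1)
      k0 <- sample(0:n0, 1)
      expect_equal(
        beta_overlap_pvalue(k1, n1, k0, n0),
        beta_overlap_pvalue(k0, n0, k1, n1)
      )
    }
  })
  expect_identical(beta_overlap_pvalue(10, 500, 10, 500), 1)
  expect_lt(beta_overlap_pvalue(11, 500, 10, 500), 1)
  # monotone decay as the sample VAF moves away from the control VAF
  p_grid <- beta_overlap_pvalue(seq(10, 90, by = 10), 1000, 10, 1000)
  expect_true(all(diff(p_grid) < 0))
  expect_error(beta_overlap_pvalue(1, 0, 1, 100), "positive")
})

test_that("detection applies the inclusive p <= alpha rule at the stated boundary", {
  s <- tibble::tibble(site_id = "x", mutant_reads = 5, total_reads = 1000)
  ctrl <- tibble::tibble(site_id = "x", mutant_reads = 1, total_reads = 1000)
  det <- detect_ctdna(s, ctrl, alpha = 0.05)
  expect_equal(det$p_value, beta_overlap_pvalue(5, 1000, 1, 1000))
  expect_false(det$detected) # p ~ 0.27 > 0.05
  # boundary: detected exactly at p == alpha
  det_at <- detect_ctdna(s, ctrl, alpha = det$p_value)
  expect_true(det_at$detected)
  det_hot <- detect_ctdna(
    tibble::tibble(site_id = "x", mutant_reads = 60, total_reads = 1000), ctrl
  )
  expect_true(det_hot$detected)
})

test_that("group aggregation pools counts depth-weighted within a timepoint", {
  counts <- tibble::tibble(
    site_id = c("a", "b"), mutant_reads = c(1, 3), total_reads = c(1000, 1000),
    timepoint = "t1", group = "shared"
  )
  agg <- aggregate_group(counts)
  expect_equal(agg$mutant_reads, 4)
  expect_equal(agg$total_reads, 2000)
  # group VAF equals the depth-weighted mean of member VAFs
  w <- counts$total_reads / sum(counts$total_reads)
  expect_equal(agg$vaf, sum(w * counts$mutant_reads / counts$total_reads))
  single <- aggregate_group(counts[1, ])
  expect_equal(single$mutant_reads, counts$mutant_reads[1])
  expect_error(
    aggregate_group(dplyr::mutate(counts, timepoint = c("t1", "t2"))),
    "timepoint"
  )
})

test_that("error suppression: consensus collapse removes nearly all raw errors", {
  reads <- simulate_umi_reads(
    true_vaf = 0, n_families = 5000, error_rate = 1e-3,
    family_size_mean = 5, seed = 2024
  )
  cons <- collapse_families(reads)
  masked <- mask_read_ends(cons)
  tal <- tally_site(masked$consensus, 5, "T", "site1")
  expect_gt(tal$total_reads, 2000)
  expect_lt(tal$mutant_reads / tal$total_reads, 1e-4)
})
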