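sif_fixture <- function() {
  tibble::tibble(
    source = c("TF1", "TF1", "TF2", "TF1", "G1"),
    relation = c(
      "controls-expression-of", "controls-expression-of",
      "controls-expression-of", "in-complex-with", "controls-expression-of"
    ),
    target = c("G1", "G2", "G3", "G9", "G4"),
    sign = c(1, -1, 1, 1, 1)
  )
}

test_that("network building keeps expression-control edges over expressed genes", {
  net <- build_regulon_network(sif_fixture(), c("TF1", "TF2", "G1", "G2", "G3", "G4"),
    expand_secondary = FALSE
  )
  expect_equal(nrow(net), 4) # the in-complex-with edge is dropped
  expect_false("G9" %in% net$target)
  net2 <- build_regulon_network(sif_fixture(), c("TF1", "TF2", "G1", "G2", "G3"),
    expand_secondary = FALSE
  )
  expect_false("G4" %in% net2$target) # unexpressed target dropped
  expect_error(
    build_regulon_network(sif_fixture(), "ZZZ"),
    "no expression-control edges"
  )
})

test_that("secondary interactions compose into signed direct edges at depth 2", {
  sif <- tibble::tibble(
    source = c("TF1", "M1", "M2"),
    relation = "controls-expression-of",
    target = c("M1", "M2", "G1"),
    sign = c(-1, -1, 1)
  )
  net <- build_regulon_network(sif, c("TF1", "M1", "M2", "G1"))
  # TF1 -| M1 -| M2 gives TF1 -> M2 with sign (+1); depth stops at 2, so
  # TF1 has no composed edge onto G1
  tf1 <- net[net$regulator == "TF1", ]
  expect_equal(tf1$sign[tf1$target == "M2"], 1)
  expect_false("G1" %in% tf1$target)
})

test_that("edge weights reward monotone dependency and zero out degenerate pairs", {
  x <- seq_len(20)
  expr <- rbind(
    TF1 = x,
    G1 = x^3, # exact monotone function
    G2 = rep(1, 20), # constant target
    G3 = c(x[-1], 0) * 0 + rnorm(20) # noise
  )
  colnames(expr) <- paste0("s", 1:20)
  net <- tibble::tibble(
    regulator = "TF1", target = c("G1", "G2", "G3"), sign = 1
  )
  w <- assign_edge_weights(net, expr)
  expect_gt(w$weight[w$target == "G1"], 0.99)
  expect_equal(w$weight[w$target == "G2"], 0)
  expect_lt(abs(w$weight[w$target == "G3"]), 1)
  expect_warning(
    assign_edge_weights(
      tibble::tibble(regulator = "NOPE", target = "G1", sign = 1), expr
    ),
    "dropped"
  )
})

test_that("null edge weights centre on zero", {
  withr::with_seed(5, {
    expr <- matrix(rnorm(2 * 200 * 50), nrow = 100)
    rownames(expr) <- c(paste0("R", 1:50), paste0("T", 1:50))
    colnames(expr) <- paste0("s", seq_len(ncol(expr)))
    net <- tibble::tibble(regulator = paste0("R", 1:50), target = paste0("T", 1:50), sign = 1)
    w <- assign_edge_weights(net, expr)
    expect_lt(abs(mean(w$weight)), 0.05)
  })
})

test_that("median-reference signatures subtract the cohort median per gene", {
  withr::with_seed(2, {
    expr <- matrix(rnorm(50 * 7), 50,
      dimnames = list(paste0("g", 1:50), paste0("s", 1:7))
    )
  })
  sig <- compute_signature(expr, "s3")
  brute <- vapply(seq_len(50), function(i) expr[i, "s3"] - median(expr[i, ]), numeric(1))
  expect_equal(sig$score, brute)
  expect_equal(sort(sig$rank), sort(rank(-sig$score)))
  # a sample equal to the cohort median scores zero everywhere
  expr0 <- cbind(expr[, 1:6], med = apply(expr[, 1:6], 1, median))
  expect_true(all(abs(compute_signature(expr0, "med")$score) < 1e-12))
})

test_that("local delta concordance hits +/-1 for aligned and anti-aligned weights", {
  sig <- tibble::tibble(gene = paste0("g", 1:10), score = 1:10, rank = rank(-(1:10)))
  net <- tibble::tibble(
    regulator = "TF", target = paste0("g", 1:10), sign = 1,
    weight = seq(0.1, 1, by = 0.1) # largest weight on highest score
  )
  expect_equal(local_delta_concordance(net, sig, "TF"), 1)
  net$weight <- rev(net$weight)
  expect_equal(local_delta_concordance(net, sig, "TF"), -1)
  # one-sign regulon equals that group's correlation (no averaging partner)
  expect_equal(
    local_delta_concordance(net[1:5, ], sig, "TF"),
    cor(rank(abs(net$weight[1:5])), rank(sig$score[1:5]), method = "spearman")
  )
})

test_that("local enrichment is +1 at perfect separation, -1 inverted, ~0 at random", {
  sig <- tibble::tibble(gene = paste0("g", 1:20), score = 1:20, rank = rank(-(1:20)))
  net <- tibble::tibble(
    regulator = "TF", target = paste0("g", 1:20),
    sign = rep(c(-1, 1), each = 10), weight = 0.5
  )
  # negatives carry the lowest scores, positives the highest: perfect separation
  expect_equal(local_enrichment(net, sig, "TF"), 1)
  net_inv <- dplyr::mutate(net, sign = -sign)
  expect_equal(local_enrichment(net_inv, sig, "TF"), -1)
  # permutation null centres at zero
  withr::with_seed(11, {
    vals <- replicate(500, {
      s <- tibble::tibble(gene = paste0("g", 1:20), score = sample(20), rank = 1)
      local_enrichment(net, s, "TF")
    })
  })
  expect_lt(abs(mean(vals)), 0.05)
  # one-sign regulons carry no local contrast
  expect_true(is.na(local_enrichment(net[net$sign > 0, ], sig, "TF")))
})

test_that("global enrichment reaches the extremes and matches its permutation null", {
  m <- 500
  withr::with_seed(3, scores <- rnorm(m))
  sig <- tibble::tibble(gene = paste0("g", seq_len(m)), score = scores, rank = rank(-scores))
  ord <- order(scores)
  top <- sig$gene[ord[(m - 9):m]]
  bottom <- sig$gene[ord[1:10]]
  net <- tibble::tibble(
    regulator = "TF",
    target = c(top, bottom),
    sign = rep(c(1, -1), each = 10),
    weight = 1
  )
  expect_gt(global_enrichment(net, sig, "TF"), 0.9)
  # repression: same targets with flipped signs score symmetrically negative
  net_rep <- dplyr::mutate(net, sign = -sign)
  expect_lt(global_enrichment(net_rep, sig, "TF"), -0.9)
  # random 20-gene regulon: null mean ~ 0, SD close to the permutation oracle
  withr::with_seed(21, {
    vals <- replicate(2000, {
      tg <- sample(sig$gene, 20)
      g <- tibble::tibble(regulator = "TF", target = tg, sign = 1, weight = 1)
      global_enrichment(g, sig, "TF")
    })
    oracle <- replicate(2000, 2 * (median(sample(m, 20) / (m + 1)) - 0.5))
  })
  expect_lt(abs(mean(vals)), 0.03)
  expect_lt(abs(sd(vals) - sd(oracle)), 0.03)
})

test_that("integration standardizes components and ranks a planted regulator first", {
  flat <- tibble::tibble(
    regulator = paste0("R", 1:5),
    local_delta_concordance = 0.3,
    local_enrichment = 0.1,
    global_enrichment = -0.2
  )
  out <- integrate_scores(flat)
  expect_true(all(out$integrated == 0)) # zero-MAD guard
  net <- sim_regulon_network(50, 20, seed = 31)
  expr <- simulate_regulator_expression(net, "R013",
    n_samples = 30,
    effect_size = 3, noise_sd = 1, seed = 32
  )
  sc <- regulon_activity(net, expr, "S01")
  expect_equal(glance(sc)$top_regulator, "R013")
  expect_error(integrate_scores(flat[0, ]), "no regulators")
})

test_that("sign flip of the signature negates component scores", {
  net <- sim_regulon_network(10, 15, seed = 41)
  expr <- simulate_regulator_expression(net, "R003",
    n_samples = 20,
    effect_size = 2, noise_sd = 1, seed = 42
  )
  wnet <- assign_edge_weights(net, expr)
  sig <- compute_signature(expr, "S01")
  sig_neg <- dplyr::mutate(sig, score = -score, rank = rank(-score))
  for (r in c("R003", "R007")) {
    expect_equal(
      global_enrichment(wnet, sig_neg, r),
      -global_enrichment(wnet, sig, r),
      tolerance = 1e-8
    )
    expect_equal(
      local_enrichment(wnet, sig_neg, r),
      -local_enrichment(wnet, sig, r),
      tolerance = 1e-8
    )
  }
})

test_that("removing a regulator leaves other regulators' components unchanged", {
  net <- sim_regulon_network(8, 12, seed = 51)
  expr <- simulate_regulator_expression(net, "R002",
    n_samples = 20,
    effect_size = 2, noise_sd = 1, seed = 52
  )
  full <- regulon_activity(net, expr, "S01")
  reduced <- regulon_activity(net[net$regulator != "R005", ], expr, "S01")
  expect_false("R005" %in% reduced$regulator)
  shared <- intersect(full$regulator, reduced$regulator)
  for (comp in c("local_delta_concordance", "local_enrichment", "global_enrichment")) {
    expect_equal(
      full[[comp]][match(shared, full$regulator)],
      reduced[[comp]][match(shared, reduced$regulator)]
    )
  }
})

test_that("activity deltas report differences and ratios over shared regulators", {
  s1 <- tibble::tibble(regulator = c("A", "B"), integrated = c(1, 2))
  s2 <- tibble::tibble(regulator = c("A", "B"), integrated = c(1, 6))
  d <- activity_delta(s1, s2)
  expect_equal(d$delta[d$regulator == "B"], 4)
  expect_equal(d$ratio[d$regulator == "B"], 3)
  expect_equal(d$regulator[1], "B") # largest |delta| first
  expect_true(all(activity_delta(s1, s1)$delta == 0))
  expect_error(
    activity_delta(s1, tibble::tibble(regulator = "Z", integrated = 1)),
    "no regulators"
  )
})
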