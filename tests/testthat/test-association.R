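toy_clustered_values <- function() {
  list(
    phenotypes = tibble::tibble(
      accession = sprintf("A%d", 1:6),
      tpc = c(10, 20, 30, 40, 50, 60),
      anthocyanin = c(1, 1, 1, 1, 1, 100)
    ),
    clusters = tibble::tibble(
      accession = sprintf("A%d", 1:6),
      cluster = c("A", "A", "A", "B", "B", "B")
    )
  )
}

test_that("above_mean_counts matches a hand tally with strict inequality", {
  toy <- toy_clustered_values()
  # mean tpc = 35; above: A4? no (40>35 yes), A5, A6 -> cluster B has 3, A has 0
  res <- above_mean_counts(toy$phenotypes, toy$clusters, "tpc")
  expect_identical(res$n_above[res$cluster == "A"], 0L)
  expect_identical(res$n_above[res$cluster == "B"], 3L)
  expect_equal(attr(res, "mean"), 35)
  expect_identical(attr(res, "total_above"), 3L)
  # conservation: totals match a direct population count
  expect_identical(sum(res$n_above), sum(toy$phenotypes$tpc > 35))

  # all values equal: nothing is strictly above the mean
  eq <- toy$phenotypes
  eq$tpc <- 5
  res_eq <- above_mean_counts(eq, toy$clusters, "tpc")
  expect_identical(sum(res_eq$n_above), 0L)

  # skewed anthocyanin: single accession above
  res_a <- above_mean_counts(toy$phenotypes, toy$clusters, "anthocyanin")
  expect_identical(attr(res_a, "total_above"), 1L)
})

test_that("hypergeometric enrichment matches its closed form", {
  # cluster X holds all and only the 3 trait carriers among N = 6:
  # one-sided p = P(all 3 draws are carriers) = 1 / choose(6, 3)
  clusters <- tibble::tibble(accession = sprintf("A%d", 1:6),
                             cluster = rep(c("X", "Y"), each = 3))
  traits <- tibble::tibble(accession = sprintf("A%d", 1:6),
                           color = rep(c("purple", "cream"), each = 3))
  res <- enrichment_test(clusters, traits)
  p_xp <- res$p[res$cluster == "X" & res$value == "purple"]
  expect_equal(p_xp, 1 / choose(6, 3))
  expect_equal(res$probability[res$cluster == "X" & res$value == "purple"], 1)
  # counts are consistent: per-value counts sum to the value total
  sums <- tapply(res$count, res$value, sum)
  expect_identical(as.integer(sums[c("cream", "purple")]), c(3L, 3L))
  # BH never decreases a p-value
  expect_true(all(res$p_adj >= res$p - 1e-15))
})

test_that("permutation and hypergeometric p-values agree within Monte-Carlo error", {
  set.seed(50)
  clusters <- tibble::tibble(accession = sprintf("A%02d", 1:30),
                             cluster = rep(c("A", "B", "C"), each = 10))
  traits <- tibble::tibble(accession = sprintf("A%02d", 1:30),
                           color = sample(c("purple", "cream"), 30, replace = TRUE))
  hyp <- enrichment_test(clusters, traits, method = "hypergeometric")
  perm <- enrichment_test(clusters, traits, method = "permutation", n_perm = 4000)
  key <- function(x) paste(x$cluster, x$value)
  perm <- perm[match(key(hyp), key(perm)), ]
  expect_lt(max(abs(hyp$p - perm$p)), 0.05)
})

test_that("enrichment p-values are valid under the null across cluster configurations", {
  set.seed(60)
  for (sizes in list(c(20, 20), c(10, 30), c(15, 15, 10))) {
    n <- sum(sizes)
    clusters <- tibble::tibble(
      accession = sprintf("A%03d", 1:n),
      cluster = rep(LETTERS[seq_along(sizes)], sizes)
    )
    rejections <- 0L
    n_sim <- 150
    for (i in seq_len(n_sim)) {
      traits <- tibble::tibble(
        accession = clusters$accession,
        color = sample(c("purple", "cream"), n, replace = TRUE)
      )
      res <- enrichment_test(clusters, traits)
      rejections <- rejections +
        as.integer(res$p[res$cluster == "A" & res$value == "purple"] <= 0.05)
    }
    rate <- rejections / n_sim
    # exact test: never anticonservative beyond binomial noise
    expect_lte(rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / n_sim))
  }
})

test_that("color_content_summary reproduces class means, ratios and range folds", {
  # class means as published for the potato collection: purple vs cream TPC
  ph <- phenotype_table(tibble::tibble(
    accession = c("P1", "C1"),
    skin_primary = c("blackish", "brown"),
    skin_secondary = c("none", "none"),
    flesh_primary = c("purple", "cream"),
    flesh_secondary = c("none", "none"),
    tpc = c(6383, 3999),
    anthocyanin = c(920, 0.3)
  ))
  cs <- color_content_summary(ph)
  ratios <- fold_ratios(cs)
  expect_equal(
    ratios$tpc_ratio[ratios$color_a == "purple" & ratios$color_b == "cream"], 1.6
  )
  expect_equal(
    ratios$tpc_ratio[ratios$color_a == "cream" & ratios$color_b == "cream"], 1
  )
  # population max/min fold-difference truncated to integer
  expect_equal(unname(range_fold(cs)["anthocyanin"]), 3066)

  # single class: means only, self-ratio 1
  single <- ph[1, ]
  cs1 <- color_content_summary(phenotype_table(single))
  expect_identical(nrow(cs1), 1L)
  expect_equal(fold_ratios(cs1)$tpc_ratio, 1)
})

test_that("content-color correlations behave on constructed inputs", {
  base <- tibble::tibble(
    accession = sprintf("A%03d", 1:200),
    skin_primary = "yellow", skin_secondary = "none",
    flesh_secondary = "none"
  )
  set.seed(70)
  base$flesh_primary <- sample(flesh_colors(), 200, replace = TRUE)
  base$tpc <- runif(200, 1000, 10000)
  base$anthocyanin <- 2 * base$tpc
  ph <- phenotype_table(base)
  res <- content_color_correlation(ph)
  expect_equal(res$r[res$pair == "tpc~anthocyanin"], 1)

  # independent vectors: near-zero correlation
  set.seed(71)
  big <- base
  big$anthocyanin <- runif(200, 0, 100)
  ind <- content_color_correlation(phenotype_table(big))
  expect_lt(abs(ind$r[ind$pair == "tpc~anthocyanin"]), 0.2)

  # planted pigment effect gives a positive score correlation
  cfg <- simulation_config(n_accessions = 500)
  set.seed(72)
  truth <- tibble::tibble(accession = sprintf("A%03d", 1:500),
                          cluster = sample(1:7, 500, replace = TRUE))
  sim_ph <- simulate_phenotypes(truth, cfg)
  planted <- content_color_correlation(sim_ph)
  expect_gt(planted$r[planted$pair == "anthocyanin~flesh_score"], 0.2)

  const <- base
  const$tpc <- 5
  expect_error(content_color_correlation(phenotype_table(const)), "constant")
})

test_that("the planted purple enrichment is detected at FDR 0.05", {
  cfg <- simulation_config()
  set.seed(80)
  truth <- tibble::tibble(accession = sprintf("A%03d", 1:290),
                          cluster = sample(1:7, 290, replace = TRUE))
  ph <- simulate_phenotypes(truth, cfg)
  clusters <- tibble::tibble(accession = truth$accession,
                             cluster = LETTERS[truth$cluster])
  res <- enrichment_test(clusters, ph[c("accession", "flesh_primary")])
  hits <- res[res$value == "purple" & res$significant, "cluster", drop = TRUE]
  expect_true(all(LETTERS[cfg$pigment_clusters] %in% hits))
})
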