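# Intra/inter scoring, quadrant partition, metric agreement,
# enrichment.  Hand values and enumeration oracles live in
# helper-fixtures.R.

test_that("intra score matches the hand-worked two-patient example", {
  co <- worked_example_cohort()
  # per-patient SDs sd(1,3) = sd(5,7) = sqrt(2); mean = 1.41421
  expect_equal(unname(intra_heterogeneity(co)), sqrt(2), tolerance = 1e-6)

  # gene constant within every patient -> 0
  flat <- build_cohort(list(g1 = list(P1 = c(2, 2), P2 = c(9, 9))))
  expect_equal(unname(intra_heterogeneity(flat)), 0)

  # sigma = 0 synthetic cohort -> all intra scores 0
  arch <- list(gene_archetype("Q4-like", 8, tau = 1, sigma = 0),
               gene_archetype("Q2-like", 8, tau = 0.1, sigma = 0))
  syn <- generate_cohort(synthetic_config(n_patients = 10,
    archetypes = arch, planted = planted_signature(n_genes = 0), seed = 4))
  expect_true(all(intra_heterogeneity(syn$cohort) == 0))
})

test_that("intra skips single-region patients and errors when none remain", {
  co <- build_cohort(list(g1 = list(P1 = c(1, 3), P2 = 10, P3 = c(5, 7))))
  expect_equal(unname(intra_heterogeneity(co)), sqrt(2), tolerance = 1e-6)
  single <- build_cohort(list(g1 = list(P1 = 1, P2 = 2)))
  expect_error(intra_heterogeneity(single), ">= 2 tumor regions")
})

test_that("inter matches exhaustive enumeration and Monte-Carlo converges", {
  co <- worked_example_cohort()
  oracle <- oracle_inter_sd(co)                      # 2.82843 by enumeration
  expect_equal(unname(oracle), 2.828427, tolerance = 1e-6)
  expect_equal(inter_heterogeneity(co, method = "exhaustive"), oracle)
  mc <- inter_heterogeneity(co, n_reps = 1e4, seed = 11)
  expect_lt(abs(mc - oracle) / oracle, 0.02)

  # a richer cohort: 4 patients, uneven regions, 3 genes
  set.seed(15)
  vals <- lapply(1:3, function(i)
    list(P1 = rnorm(3), P2 = rnorm(2), P3 = rnorm(4), P4 = rnorm(1)))
  names(vals) <- paste0("g", 1:3)
  co2 <- build_cohort(vals)
  o2 <- oracle_inter_sd(co2)
  expect_equal(inter_heterogeneity(co2, method = "exhaustive"), o2,
               tolerance = 1e-12)
  mc2 <- inter_heterogeneity(co2, n_reps = 1e4, seed = 2)
  expect_true(all(abs(mc2 - o2) / o2 < 0.02))
})

test_that("inter is deterministic without randomness and zero without signal", {
  one_region <- build_cohort(list(g1 = list(P1 = 2, P2 = 5, P3 = 11)))
  a <- inter_heterogeneity(one_region, seed = 1)
  b <- inter_heterogeneity(one_region, seed = 999)
  expect_identical(a, b)
  expect_equal(unname(a), sd(c(2, 5, 11)))

  const <- build_cohort(list(g1 = list(P1 = c(4, 4), P2 = c(4, 4))))
  expect_equal(unname(inter_heterogeneity(const, seed = 3)), 0)
  expect_error(inter_heterogeneity(build_cohort(
    list(g1 = list(P1 = c(1, 2))))), ">= 2 patients")
})

test_that("scores are invariant to column order and patient relabeling", {
  syn <- generate_cohort(synthetic_config(n_patients = 12,
    archetypes = default_archetypes(n_genes = 15), seed = 6))
  co <- syn$cohort
  set.seed(1); perm <- sample(n_samples(co))
  shuf <- multiregion_cohort(co$expression[, perm], co$samples[perm, ],
                             co$survival)
  expect_equal(intra_heterogeneity(shuf), intra_heterogeneity(co))
  relab <- co$samples
  relab$patient_id <- paste0("ZZ_", relab$patient_id)
  co_relab <- multiregion_cohort(co$expression, relab)
  expect_equal(intra_heterogeneity(co_relab), intra_heterogeneity(co))
  # inter: exhaustive form is order-invariant exactly
  small <- multiregion_cohort(co$expression[1:5, 1:9], co$samples[1:9, ])
  set.seed(2); perm2 <- sample(9)
  small_shuf <- multiregion_cohort(small$expression[, perm2],
                                   small$samples[perm2, ])
  expect_equal(inter_heterogeneity(small, method = "exhaustive"),
               inter_heterogeneity(small_shuf, method = "exhaustive"))
})

test_that("MAD and CV metrics follow their definitions", {
  co <- build_cohort(list(g1 = list(P1 = c(1, 2, 6), P2 = c(10, 11, 15))))
  expect_equal(unname(intra_heterogeneity(co, "MAD")),
               mean(c(mad(c(1, 2, 6)), mad(c(10, 11, 15)))))
  expect_equal(unname(intra_heterogeneity(co, "CV")),
               mean(c(sd(c(1, 2, 6)) / 3, sd(c(10, 11, 15)) / 12)))
  # CV guard: near-zero mean -> NA
  co0 <- build_cohort(list(g1 = list(P1 = c(-1, 1), P2 = c(2, 3))))
  expect_true(is.na(intra_heterogeneity(co0, "CV")))
})

test_that("quadrant assignment applies the mean-threshold rule", {
  intra <- c(a = 3, b = 1, c = 3, d = 1)
  inter <- c(a = 1, b = 1, c = 3, d = 3)
  ht <- assign_quadrants(intra, inter)
  expect_equal(as.character(ht$quadrant), c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(attr(ht, "thresholds"),
               c(mean_intra = 2, mean_inter = 2))

  # all-identical scores land in Q3 under the >= convention
  same <- assign_quadrants(c(x = 1, y = 1), c(x = 2, y = 2))
  expect_true(all(same$quadrant == "Q3"))

  expect_error(assign_quadrants(c(a = 1), c(b = 1)), "universe")
})

test_that("quadrant partition is exhaustive and gene-order independent", {
  syn <- generate_cohort(synthetic_config(n_patients = 30,
    archetypes = default_archetypes(n_genes = 40), seed = 13))
  ht <- heterogeneity_table(syn$cohort, n_reps = 10, seed = 1)
  expect_equal(sum(table(ht$quadrant)), nrow(ht))       # partition
  expect_false(anyNA(ht$quadrant))
  intra <- intra_heterogeneity(syn$cohort)
  inter <- inter_heterogeneity(syn$cohort, n_reps = 10, seed = 1)
  set.seed(3); perm <- sample(length(intra))
  a <- assign_quadrants(intra, inter)
  b <- assign_quadrants(intra[perm], inter[perm])
  expect_equal(a$quadrant[match(b$gene, a$gene)], b$quadrant)
})

test_that("archetypes with identifiable separation are recovered >= 95%", {
  # separation chosen so that each archetype's expected (intra, inter)
  # sits on the correct side of both thresholds: sigma_high stays well
  # below the Q3/Q4 tau level, keeping the one-region-per-patient
  # intertumor estimate sqrt(tau^2 + sigma^2) low for Q1-like genes
  arch <- list(gene_archetype("Q1-like", 250, tau = 0.2, sigma = 0.6),
               gene_archetype("Q2-like", 250, tau = 0.2, sigma = 0.1),
               gene_archetype("Q3-like", 250, tau = 1.5, sigma = 0.6),
               gene_archetype("Q4-like", 250, tau = 1.5, sigma = 0.1))
  cfg <- synthetic_config(n_patients = 100, regions_per_patient = 3,
                          archetypes = arch,
                          planted = planted_signature(n_genes = 0),
                          seed = 41)
  syn <- generate_cohort(cfg)
  ht <- heterogeneity_table(syn$cohort, n_reps = 10, seed = 41)
  truth <- sub("-like", "", truth_quadrant(cfg))
  assigned <- as.character(ht$quadrant[match(names(truth), ht$gene)])
  recovery <- tapply(assigned == truth, truth, mean)
  expect_true(all(recovery >= 0.95))
})

test_that("metric agreement is high under normality and null under noise", {
  # genes span a range of true region-level dispersions, so both SD
  # and MAD track the underlying sigma
  set.seed(17)
  ng <- 2000; P <- 25; R <- 3
  sigma <- runif(ng, 0.1, 1.5)
  pid <- rep(sprintf("P%02d", 1:P), each = R)
  expr <- 7 + matrix(rnorm(ng * P * R), ng) * sigma
  dimnames(expr) <- list(paste0("g", 1:ng),
                         paste0(pid, "_R", rep(1:R, P)))
  co <- multiregion_cohort(expr, data.frame(
    sample_id = colnames(expr), patient_id = pid,
    region_id = paste0("R", rep(1:R, P)), tissue = "tumor"))
  ma <- metric_agreement(co)
  expect_gt(ma$r[ma$metric_a == "SD" & ma$metric_b == "MAD"], 0.9)
  expect_gt(min(ma$r), 0.5)
  expect_lt(max(ma$p), 1e-10)

  # a metric against itself correlates perfectly
  x <- intra_heterogeneity(co, "SD")
  expect_equal(cor(x, x), 1)

  # independent random scores are uncorrelated
  set.seed(9)
  r_null <- cor(rnorm(2000), rnorm(2000))
  expect_lt(abs(r_null), 0.1)

  expect_error(metric_agreement(build_cohort(
    list(g1 = list(P1 = c(1, 2), P2 = c(3, 4))))), ">= 3 genes")
})

test_that("quadrant enrichment reports observed/expected folds", {
  intra <- c(q1 = 3, q2a = 1, q2b = 1, q2c = 1, q3 = 3, q4 = 1)
  inter <- c(q1 = 1, q2a = 1, q2b = 1, q2c = 1, q3 = 3, q4 = 3)
  ht <- assign_quadrants(intra, inter)

  all_g <- quadrant_enrichment(ht, names(intra))
  expect_equal(all_g$fold[all_g$universe_n > 0], rep(1, 4))

  only_q4 <- quadrant_enrichment(ht, "q4")
  expect_equal(only_q4$observed_frac[only_q4$quadrant == "Q4"], 1)
  # universe share of Q4 is 1/6 -> fold 6
  expect_equal(only_q4$fold[only_q4$quadrant == "Q4"], 6)

  expect_warning(out <- quadrant_enrichment(ht, c("q4", "nope")),
                 "dropped")
  expect_equal(attr(out, "n_dropped"), 1)
  expect_error(suppressWarnings(quadrant_enrichment(ht, "nope")),
               "no query gene")
})

test_that("published-signature style enrichment reproduces the 2x fold", {
  # universe with an 8.3% Q4 share; a query with 16% of its genes in
  # Q4 shows a ~1.93-fold enrichment
  n_uni <- 13235; n_q4 <- 1101
  quadrant <- rep(c("Q4", "Q2"), c(n_q4, n_uni - n_q4))
  intra <- ifelse(quadrant == "Q4", 0, 2)
  inter <- ifelse(quadrant == "Q4", 3, 0)
  names(intra) <- names(inter) <- paste0("g", seq_len(n_uni))
  ht <- assign_quadrants(intra, inter)
  expect_equal(mean(ht$quadrant == "Q4"), n_q4 / n_uni, tolerance = 1e-12)
  query <- c(paste0("g", 1:16), paste0("g", n_q4 + (1:84)))  # 16% in Q4
  enr <- quadrant_enrichment(ht, query)
  fold_q4 <- enr$fold[enr$quadrant == "Q4"]
  expect_equal(fold_q4, 0.16 / (n_q4 / n_uni), tolerance = 1e-12)
  expect_equal(fold_q4, 1.93, tolerance = 0.01)
})

test_that("heterogeneity functions insist on tumor-only cohorts", {
  co <- build_cohort(list(g1 = list(P1 = c(1, 2), P2 = c(3, 4))),
                     tissue = c("tumor", "normal", "tumor", "tumor"))
  expect_error(intra_heterogeneity(co), "subset_tumor")
  expect_error(inter_heterogeneity(co), "subset_tumor")
  expect_silent(intra_heterogeneity(subset_tumor(co)))
})
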