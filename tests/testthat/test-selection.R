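# Univariate screen, lasso refinement, learner registry, benchmark
# plumbing.  The heavier end-to-end recovery and null benchmarks live
# in test-acceptance.R.

test_that("aggregate_by_patient averages regions and aligns survival", {
  surv <- data.frame(patient_id = c("P2", "P1"), time = c(50, 100),
                     event = c(1, 0))
  co <- build_cohort(list(g1 = list(P1 = c(1, 3), P2 = c(10, 20)),
                          g2 = list(P1 = c(0, 0), P2 = c(5, 5))),
                     survival = surv)
  agg <- aggregate_by_patient(co)
  expect_equal(agg$expression["g1", ], c(P1 = 2, P2 = 15))
  expect_equal(agg$time, c(100, 50))   # reordered to matrix columns
  expect_equal(agg$event, c(0L, 1L))
  expect_error(aggregate_by_patient(
    build_cohort(list(g1 = list(P1 = 1, P2 = 2)))), "no survival")
})

test_that("univariate screen finds strong signal and flags degenerate genes", {
  fx <- quick_synth(seed = 101, n_patients = 300, n_genes = 10)
  agg <- aggregate_by_patient(fx$cohort)
  # a synthetic covariate equal to the true linear predictor
  lp <- fx$truth$patients$lp
  expr <- rbind(agg$expression[1:10, ],
                truelp = lp[match(colnames(agg$expression),
                                  fx$truth$patients$patient_id)],
                flatg = rep(1, ncol(agg$expression)))
  uc <- univariate_cox(expr, fx$cohort$survival)
  expect_lt(uc$table$p[uc$table$gene == "truelp"], 1e-6)
  expect_true("truelp" %in% uc$selected)
  expect_true("flatg" %in% uc$flagged)
  expect_false("flatg" %in% uc$selected)
  # selected = p < alpha among unflagged
  expect_setequal(uc$selected,
                  uc$table$gene[!uc$table$flagged & uc$table$p < 0.05])
})

test_that("univariate Wald estimates match coxph run independently", {
  fx <- quick_synth(seed = 102, n_patients = 80, n_genes = 6)
  agg <- aggregate_by_patient(fx$cohort)
  uc <- univariate_cox(agg$expression, fx$cohort$survival)
  for (g in rownames(agg$expression)[1:3]) {
    fit <- survival::coxph(
      survival::Surv(agg$time, agg$event) ~ agg$expression[g, ],
      ties = "efron")
    expect_equal(uc$table$log_hr[uc$table$gene == g],
                 unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("lasso refinement is reproducible and recovers planted genes", {
  fx <- quick_synth(seed = 103, n_patients = 250, n_genes = 40)
  agg <- aggregate_by_patient(fx$cohort)
  tq <- truth_quadrant(synthetic_config(
    n_patients = 250, regions_per_patient = 1,
    archetypes = default_archetypes(n_genes = 40), seed = 103))
  pool <- agg$expression[tq %in% c("Q4-like", "Q2-like"), ]
  a <- lasso_refine(pool, fx$cohort$survival, seed = 7)
  b <- lasso_refine(pool, fx$cohort$survival, seed = 7)
  expect_identical(a$genes, b$genes)
  expect_true(all(a$genes %in% rownames(pool)))
  planted <- fx$truth$genes$gene[fx$truth$genes$beta != 0]
  expect_gt(length(intersect(a$genes, planted)) / length(planted), 0.6)
  expect_equal(sort(names(a$coefficients)), sort(a$genes))
})

test_that("unavailable learners error naming the available registry", {
  reg <- default_learners()
  expect_false(reg$CoxBoost$available)
  fx <- quick_synth(seed = 104, n_patients = 60, n_genes = 6)
  agg <- aggregate_by_patient(fx$cohort)
  err <- expect_error(
    fit_learner(reg$CoxBoost, agg$expression, fx$cohort$survival))
  expect_match(conditionMessage(err), "unavailable")
  expect_match(conditionMessage(err), "StepCoxForward")
  expect_match(conditionMessage(err), "RSF")
  expect_error(learner_spec("NotALearner"), "unknown learner")
  expect_error(learner_spec("Enet", params = list(alpha = c(0, 0.5))),
               "alpha")
})

test_that("forward stepwise picks the one informative gene", {
  set.seed(105)
  n <- 80
  signal <- rnorm(n)
  time <- rexp(n, rate = 0.002 * exp(1.5 * signal))
  surv <- data.frame(patient_id = paste0("P", 1:n), time = time, event = 1L)
  expr <- rbind(hit = signal,
                n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n))
  colnames(expr) <- surv$patient_id
  m <- fit_learner(learner_spec("StepCoxForward"), expr, surv)
  nz <- names(m$coefficients[m$coefficients != 0])
  expect_true("hit" %in% nz)
  expect_equal(names(which.max(abs(m$coefficients))), "hit")
  expect_true(m$linear)
})

test_that("linear learners score by their exported coefficients", {
  fx <- quick_synth(seed = 106, n_patients = 120, n_genes = 12)
  agg <- aggregate_by_patient(fx$cohort)
  for (nm in c("Ridge", "LassoCV")) {
    m <- fit_learner(learner_spec(nm), agg$expression, fx$cohort$survival,
                     seed = 9)
    sc <- m$predict(agg$expression)
    nz <- m$coefficients[m$coefficients != 0]
    manual <- as.numeric(crossprod(agg$expression[names(nz), , drop = FALSE],
                                   nz))
    expect_equal(unname(sc), manual)
    expect_gte(m$train_cindex, 0.5)  # orientation normalized
  }
})

test_that("orientation flip keeps higher score = higher hazard", {
  fx <- quick_synth(seed = 107, n_patients = 150, n_genes = 10)
  agg <- aggregate_by_patient(fx$cohort)
  for (nm in c("RSF", "GBM")) {
    spec <- learner_spec(nm, params = list(num.trees = 100, nrounds = 100,
                                           eta = 0.05))
    m <- fit_learner(spec, agg$expression, fx$cohort$survival, seed = 3)
    expect_gte(m$train_cindex, 0.5)
    expect_false(m$linear)
    sc <- m$predict(agg$expression)
    expect_gte(harrell_cindex(sc, agg$time, agg$event), 0.5)
  }
})

test_that("benchmark mean is the plain average of internal and external C", {
  tr <- quick_synth(seed = 108, n_patients = 150, n_genes = 15)
  va <- quick_synth(seed = 109, n_patients = 100, n_genes = 15)
  br <- benchmark_select(tr$cohort, list(ext = va$cohort),
                         learners = list(learner_spec("LassoCV")),
                         k = 3, seed = 42)
  cx <- br$cindex
  expect_setequal(cx$dataset, c("train_cv", "ext"))
  expect_equal(br$summary$mean_cindex, mean(cx$cindex))
  expect_equal(br$winner, "LassoCV")
  expect_s3_class(br$signature, "gene_signature")
  # signature coefficients are the winner's nonzero coefficients
  expect_equal(sort(br$signature$genes),
               sort(names(which(br$winner_model$coefficients != 0))))
})

test_that("duplicating a gene column does not lift the CV C-index beyond noise", {
  fx <- quick_synth(seed = 110, n_patients = 200, n_genes = 15)
  agg <- aggregate_by_patient(fx$cohort)
  base <- lasso_refine(agg$expression, fx$cohort$survival, seed = 5)
  dup <- rbind(agg$expression,
               dupgene = agg$expression[base$genes[1], ])
  with_dup <- lasso_refine(dup, fx$cohort$survival, seed = 5)
  expect_lt(with_dup$cindex - base$cindex, 0.02)
})

test_that("benchmark records disqualified learners instead of failing", {
  tr <- quick_synth(seed = 111, n_patients = 60, n_genes = 8, censor = 0)
  va <- quick_synth(seed = 112, n_patients = 40, n_genes = 8, censor = 0)
  # an RSF with an impossible parameter fails and is recorded
  bad <- learner_spec("RSF", params = list(num.trees = -5))
  br <- benchmark_select(tr$cohort, list(va$cohort),
                         learners = list(learner_spec("LassoCV"), bad),
                         k = 3, seed = 1)
  expect_match(br$summary$status[br$summary$learner == "RSF"],
               "disqualified")
  expect_equal(br$winner, "LassoCV")
})
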