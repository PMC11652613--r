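# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (enumeration, double loops, direct likelihood optimization) so
# they stay independent of the package's code paths.

# Cohort with explicit per-patient region values.  `values` is a list
# of gene -> list(patient -> numeric region values).
build_cohort <- function(values, tissue = NULL, survival = NULL) {
  pats <- names(values[[1]])
  sample_ids <- unlist(lapply(pats, function(p)
    paste0(p, "_R", seq_along(values[[1]][[p]]))))
  expr <- do.call(rbind, lapply(values, function(v) unlist(v)))
  rownames(expr) <- names(values)
  colnames(expr) <- sample_ids
  meta <- data.frame(
    sample_id = sample_ids,
    patient_id = rep(pats, times = lengths(values[[1]])),
    region_id = unlist(lapply(values[[1]], function(v)
      paste0("R", seq_along(v)))),
    tissue = tissue %||% "tumor",
    stringsAsFactors = FALSE)
  multiregion_cohort(expr, meta, survival)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 2-patient / 2-region worked example: P1 regions (1, 3), P2
# regions (5, 7).
worked_example_cohort <- function(extra_genes = 0) {
  vals <- list(g1 = list(P1 = c(1, 3), P2 = c(5, 7)))
  if (extra_genes > 0)
    for (i in seq_len(extra_genes))
      vals[[paste0("x", i)]] <- list(P1 = c(i, i), P2 = c(i, i))
  build_cohort(vals)
}

# Brute-force intertumor score: average the per-gene metric over every
# combination of one-region-per-patient picks.
oracle_inter_sd <- function(cohort) {
  expr <- cohort$expression
  by_pat <- split(seq_len(ncol(expr)), cohort$samples$patient_id)
  grid <- expand.grid(by_pat, KEEP.OUT.ATTRS = FALSE)
  out <- rep(0, nrow(expr))
  for (i in seq_len(nrow(grid))) {
    cols <- unlist(grid[i, ])
    out <- out + apply(expr[, cols, drop = FALSE], 1, sd)
  }
  stats::setNames(out / nrow(grid), rownames(expr))
}

# O(n^2) pair-enumeration Harrell C oracle.
oracle_cindex <- function(scores, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pair")
  num / den
}

# Exact single-covariate Cox partial likelihood (no censoring, no tied
# times), optimized directly; returns the MLE and its Wald SE from a
# numerical second derivative.
oracle_cox_uncensored <- function(x, time) {
  stopifnot(!anyDuplicated(time))
  ord <- order(time)
  x <- x[ord]
  # analytic score and information of the partial likelihood: at each
  # failure the risk set is everyone still alive
  score <- function(b) {
    s <- 0
    for (i in seq_along(x)) {
      r <- i:length(x)
      w <- exp(b * x[r])
      s <- s + x[i] - sum(x[r] * w) / sum(w)
    }
    s
  }
  info <- function(b) {
    v <- 0
    for (i in seq_along(x)) {
      r <- i:length(x)
      w <- exp(b * x[r]) / sum(exp(b * x[r]))
      m <- sum(x[r] * w)
      v <- v + sum(x[r]^2 * w) - m^2
    }
    v
  }
  b <- stats::uniroot(score, c(-40, 40), tol = 1e-14)$root
  list(beta = b, se = sqrt(1 / info(b)))
}

# Synthetic single-region cohort list for learner tests.
quick_synth <- function(seed, n_patients, n_genes = 30, regions = 1,
                        beta = 0.6, n_planted = 10, censor = 0.3) {
  n_planted <- min(n_planted, n_genes)
  cfg <- synthetic_config(
    n_patients = n_patients, regions_per_patient = regions,
    archetypes = default_archetypes(n_genes = n_genes),
    planted = planted_signature(n_genes = n_planted, beta = beta),
    censor_rate = censor, seed = seed)
  generate_cohort(cfg)
}
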