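# Prognostic gene selection and the multi-learner survival benchmark:
# univariate Cox screen -> cross-validated lasso refinement -> a
# registry of survival learners compared by average Harrell C-index.

#' Collapse a multiregion cohort to one value per patient
#'
#' Survival is a patient attribute, so model fitting operates on a
#' gene x patient matrix: tumor regions of each patient are averaged
#' per gene.  Single-region cohorts pass through unchanged.
#'
#' @param cohort A tumor-only [multiregion_cohort()] with survival
#'   data.
#' @return List: `expression` (gene x patient), `time`, `event`,
#'   `patient_id`.
#' @export
aggregate_by_patient <- function(cohort) {
  assert_tumor_only(cohort, "aggregate_by_patient")
  if (is.null(cohort$survival))
    stop("cohort carries no survival data", call. = FALSE)
  pid <- cohort$samples$patient_id
  pats <- unique(pid)
  expr <- vapply(pats,
                 function(p) rowMeans(cohort$expression[, pid == p,
                                                        drop = FALSE]),
                 numeric(n_genes(cohort)))
  if (n_genes(cohort) == 1L)
    expr <- matrix(expr, 1L, dimnames = list(rownames(cohort$expression),
                                             pats))
  colnames(expr) <- pats
  sv <- align_survival(expr, cohort$survival)
  list(expression = expr, time = sv$time, event = sv$event,
       patient_id = pats)
}

# Accept either a multiregion_cohort or a pre-built
# list(expression, time, event) in model-facing functions.
as_patient_data <- function(x) {
  if (inherits(x, "multiregion_cohort")) return(aggregate_by_patient(x))
  stopifnot(is.list(x), !is.null(x$expression),
            !is.null(x$time), !is.null(x$event))
  x
}

#' Univariate Cox screen
#'
#' One single-covariate proportional-hazards fit per gene (Efron
#' ties, via [survival::coxph()]), Wald p-values, and the selected set
#' `p < alpha` with no multiplicity correction --- the screen is a
#' deliberate coarse filter ahead of penalized refinement, so the
#' per-gene type-I rate is the quantity controlled.  Constant and
#' non-converging genes are flagged and excluded from selection.
#'
#' @param expr Gene x patient matrix (one value per patient; use
#'   [aggregate_by_patient()] for multiregion cohorts).
#' @param survival `data.frame` with `patient_id`, `time`, `event`
#'   covering the matrix columns.
#' @param alpha Selection threshold on the Wald p-value.
#' @return List of class `univariate_cox`: `table` (per gene: `hr`,
#'   `log_hr`, `se`, `p`, `flagged`), `selected` (gene ids), `flagged`
#'   (gene ids), `alpha`.
#' @export
univariate_cox <- function(expr, survival, alpha = 0.05) {
  expr <- as.matrix(expr)
  sv <- align_survival(expr, survival)
  if (sum(sv$event) < 10)
    warning("fewer than 10 events; univariate screen will be unstable",
            call. = FALSE)
  y <- survival::Surv(sv$time, sv$event)
  fit_one <- function(x) {
    if (stats::sd(x) == 0)
      return(c(NA_real_, NA_real_, NA_real_, 1))
    flagged <- FALSE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(y ~ x, ties = "efron",
                               control = survival::coxph.control(
                                 eps = 1e-11, iter.max = 50,
                                 toler.chol = 1e-13)),
               error = function(e) NULL),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit) || flagged || !is.finite(stats::coef(fit)[1]))
      return(c(NA_real_, NA_real_, NA_real_, 1))
    b <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    c(b, se, 2 * stats::pnorm(-abs(b / se)), 0)
  }
  res <- t(apply(expr, 1L, fit_one))
  table <- data.frame(gene = rownames(expr), log_hr = res[, 1],
                      hr = exp(res[, 1]), se = res[, 2], p = res[, 3],
                      flagged = res[, 4] == 1,
                      stringsAsFactors = FALSE, row.names = NULL)
  selected <- table$gene[!table$flagged & !is.na(table$p) & table$p < alpha]
  structure(list(table = table, selected = selected,
                 flagged = table$gene[table$flagged], alpha = alpha),
            class = "univariate_cox")
}

#' @export
print.univariate_cox <- function(x, ...) {
  cat("univariate_cox: ", nrow(x$table), " genes | selected (p < ",
      x$alpha, "): ", length(x$selected), " | flagged: ",
      length(x$flagged), "\n", sep = "")
  invisible(x)
}

# cv.glmnet emits benign numerical warnings on hard Cox paths (it
# falls back to the solved part of the lambda path); muffle those.
quiet_cv_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::cv.glmnet(...),
    warning = function(w) {
      if (grepl("lambda|glmnet|converge", conditionMessage(w),
                ignore.case = TRUE))
        invokeRestart("muffleWarning")
    })
}

# Deterministic fold assignment from (k, seed, patient count).
make_foldid <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Lasso refinement of the univariate survivors
#'
#' L1-penalized Cox over a 100-point log-spaced lambda path
#' ([glmnet::cv.glmnet], `family = "cox"`), with the penalty chosen to
#' maximize the mean k-fold cross-validated Harrell C-index.  Genes
#' are standardized internally (glmnet's per-column scaling); fold
#' assignment is a pure function of `(k, seed, n)` so runs are
#' reproducible.
#'
#' @inheritParams univariate_cox
#' @param k Number of CV folds.
#' @param seed Fold-assignment seed.
#' @param nlambda Length of the lambda path.
#' @return List of class `lasso_refine`: `genes` (nonzero-coefficient
#'   genes at the selected lambda), `coefficients`, `lambda`,
#'   `cindex` (the CV C-index at the selected lambda), and the
#'   underlying `cv_fit`.  A path on which no lambda retains a gene
#'   is a hard error.
#' @export
lasso_refine <- function(expr, survival, k = 5, seed = 1, nlambda = 100) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("lasso_refine() needs >= 2 genes", call. = FALSE)
  sv <- align_survival(expr, survival)
  x <- t(expr)
  y <- survival::Surv(sv$time, sv$event)
  foldid <- make_foldid(ncol(expr), k, seed)
  cv <- quiet_cv_glmnet(x, y, family = "cox", type.measure = "C",
                        alpha = 1, nlambda = nlambda, foldid = foldid,
                        standardize = TRUE)
  lam <- cv$lambda.min   # for type.measure = "C" this maximizes the C-index
  cf <- as.matrix(stats::coef(cv, s = lam))[, 1]
  genes <- names(cf)[cf != 0]
  if (!length(genes))
    stop("degenerate lasso path: no lambda retains a gene", call. = FALSE)
  structure(list(genes = genes, coefficients = cf[cf != 0], lambda = lam,
                 cindex = cv$cvm[cv$lambda == lam][1], cv_fit = cv,
                 k = k, seed = seed),
            class = "lasso_refine")
}

#' @export
print.lasso_refine <- function(x, ...) {
  cat("lasso_refine: ", length(x$genes), " genes at lambda = ",
      signif(x$lambda, 4), " (CV C-index ", signif(x$cindex, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Survival learner registry
#'
#' The benchmark's default learner suite with its standing parameters:
#' stepwise Cox in three directions (AIC criterion), ridge
#' (`alpha = 0`), elastic net (`alpha` grid 0.1--0.9), lasso with
#' CV-selected penalty, random survival forest (`num.trees = 1000`),
#' and a Cox-objective gradient boosting machine (10000 trees, depth
#' 3, shrinkage 0.001, minimum node size 10).  `CoxBoost`, `plsRcox`,
#' `SuperPC`, and `SurvivalSVM` are registered but marked unavailable:
#' no supported implementation is installed, and the registry keeps
#' the benchmark explicit about which learners actually ran.
#'
#' @return Named list of `learner_spec` entries.
#' @export
default_learners <- function() {
  specs <- list(
    learner_spec("StepCoxForward"),
    learner_spec("StepCoxBackward"),
    learner_spec("StepCoxBoth"),
    learner_spec("Ridge"),
    learner_spec("Enet", params = list(alpha = seq(0.1, 0.9, by = 0.1))),
    learner_spec("LassoCV"),
    learner_spec("RSF", params = list(num.trees = 1000)),
    learner_spec("GBM", params = list(nrounds = 10000, eta = 0.001,
                                      max_depth = 3, min_child_weight = 10)),
    learner_spec("CoxBoost", available = FALSE),
    learner_spec("plsRcox", available = FALSE),
    learner_spec("SuperPC", available = FALSE),
    learner_spec("SurvivalSVM", available = FALSE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' @rdname default_learners
#' @param name Learner name (see [default_learners()] for the known
#'   set).
#' @param params Named list of learner parameters overriding the
#'   defaults.
#' @param available Whether an implementation backs this entry.
#' @export
learner_spec <- function(name, params = list(), available = TRUE) {
  known <- c("StepCoxForward", "StepCoxBackward", "StepCoxBoth", "Ridge",
             "Enet", "LassoCV", "RSF", "GBM", "CoxBoost", "plsRcox",
             "SuperPC", "SurvivalSVM")
  if (!name %in% known)
    stop("unknown learner ", dQuote(name), call. = FALSE)
  if (name == "Enet") {
    a <- params$alpha %||% seq(0.1, 0.9, by = 0.1)
    if (any(a <= 0 | a >= 1))
      stop("Enet alpha grid must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(name = name, params = params, available = available),
            class = "learner_spec")
}

available_learner_names <- function() {
  reg <- default_learners()
  names(reg)[vapply(reg, `[[`, TRUE, "available")]
}

#' Fit one survival learner
#'
#' Trains the learner named by `spec` and returns a deterministic
#' scoring closure.  Every learner's output is orientation-normalized
#' so that a higher score always means higher predicted hazard: if
#' the training C-index of the raw output falls below 0.5 the sign is
#' flipped.
#'
#' @param spec A [learner_spec()] with `available = TRUE`.
#' @param expr Gene x patient training matrix.
#' @param survival Survival table covering the matrix columns.
#' @param seed Seed driving fold assignment (penalized learners) and
#'   tree growth (RSF).
#' @return A `risk_model`: list with `learner`, `predict(expr)`,
#'   `coefficients` (named vector for coefficient-based learners,
#'   otherwise `NULL`), `linear`, `genes`, `train_cindex`, `flipped`.
#' @export
fit_learner <- function(spec, expr, survival, seed = 123) {
  stopifnot(inherits(spec, "learner_spec"))
  if (!spec$available)
    stop("learner ", dQuote(spec$name), " is registered but unavailable; ",
         "available learners: ",
         paste(available_learner_names(), collapse = ", "), call. = FALSE)
  expr <- as.matrix(expr)
  sv <- align_survival(expr, survival)
  p <- spec$params
  fit <- switch(spec$name,
    StepCoxForward  = fit_stepcox(expr, sv, "forward"),
    StepCoxBackward = fit_stepcox(expr, sv, "backward"),
    StepCoxBoth     = fit_stepcox(expr, sv, "both"),
    Ridge   = fit_glmnet_cox(expr, sv, alpha = 0, k = p$k %||% 5,
                             seed = seed),
    Enet    = fit_glmnet_cox(expr, sv,
                             alpha = p$alpha %||% seq(0.1, 0.9, by = 0.1),
                             k = p$k %||% 5, seed = seed),
    LassoCV = fit_glmnet_cox(expr, sv, alpha = 1, k = p$k %||% 5,
                             seed = seed),
    RSF     = fit_rsf(expr, sv, num.trees = p$num.trees %||% 1000,
                      seed = seed),
    GBM     = fit_gbm(expr, sv, nrounds = p$nrounds %||% 10000,
                      eta = p$eta %||% 0.001,
                      max_depth = p$max_depth %||% 3,
                      min_child_weight = p$min_child_weight %||% 10),
    stop("unhandled learner ", spec$name, call. = FALSE))

  raw_scores <- fit$predict(expr)
  cidx <- tryCatch(harrell_cindex(raw_scores, sv$time, sv$event),
                   error = function(e) NA_real_)
  flip <- is.finite(cidx) && cidx < 0.5
  base_pred <- fit$predict
  predict_fn <- if (flip) function(e) -base_pred(e) else base_pred
  coefs <- fit$coefficients
  if (flip && !is.null(coefs)) coefs <- -coefs
  structure(list(learner = spec$name, predict = predict_fn,
                 coefficients = coefs, linear = fit$linear,
                 genes = rownames(expr),
                 train_cindex = if (flip) 1 - cidx else cidx,
                 flipped = flip),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model [", x$learner, "]: ",
      if (x$linear) paste0(sum(x$coefficients != 0), " nonzero coefficients")
      else paste0("nonlinear, ", length(x$genes), " genes"),
      " | train C-index ", signif(x$train_cindex, 4), "\n", sep = "")
  invisible(x)
}

# -- learner backends ------------------------------------------------

# Linear scorer from a named coefficient vector; signature-gene
# subsetting mirrors risk_score(): missing genes are dropped.
linear_backend <- function(coefs) {
  function(expr) {
    g <- intersect(names(coefs)[coefs != 0], rownames(expr))
    if (!length(g))
      return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
    stats::setNames(
      as.numeric(crossprod(expr[g, , drop = FALSE], coefs[g])),
      colnames(expr))
  }
}

fit_stepcox <- function(expr, sv, direction) {
  vn <- make.names(rownames(expr), unique = TRUE)
  df <- data.frame(t(expr))
  colnames(df) <- vn
  df$.time <- sv$time
  df$.event <- sv$event
  null_fit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = df,
                              ties = "efron")
  upper <- stats::as.formula(paste("~", paste(vn, collapse = " + ")))
  start <- if (direction == "forward") null_fit else {
    survival::coxph(stats::as.formula(
      paste("survival::Surv(.time, .event) ~", paste(vn, collapse = " + "))),
      data = df, ties = "efron")
  }
  sel <- suppressWarnings(
    stats::step(start, scope = list(lower = ~ 1, upper = upper),
                direction = direction, trace = 0))
  b <- stats::coef(sel)
  coefs <- stats::setNames(rep(0, nrow(expr)), rownames(expr))
  if (length(b)) coefs[rownames(expr)[match(names(b), vn)]] <- unname(b)
  list(predict = linear_backend(coefs), coefficients = coefs, linear = TRUE)
}

fit_glmnet_cox <- function(expr, sv, alpha, k, seed) {
  x <- t(expr)
  y <- survival::Surv(sv$time, sv$event)
  foldid <- make_foldid(ncol(expr), k, seed)
  best <- NULL
  for (a in alpha) {
    cv <- quiet_cv_glmnet(x, y, family = "cox", type.measure = "C",
                          alpha = a, foldid = foldid, standardize = TRUE)
    cm <- cv$cvm[cv$lambda == cv$lambda.min][1]
    if (is.null(best) || cm > best$cm) best <- list(cv = cv, cm = cm, a = a)
  }
  cf <- as.matrix(stats::coef(best$cv, s = best$cv$lambda.min))[, 1]
  coefs <- stats::setNames(rep(0, nrow(expr)), rownames(expr))
  coefs[names(cf)] <- unname(cf)
  list(predict = linear_backend(coefs), coefficients = coefs, linear = TRUE)
}

fit_rsf <- function(expr, sv, num.trees, seed) {
  df <- data.frame(t(expr))
  vn <- colnames(df)
  df$.time <- sv$time
  df$.event <- sv$event
  fit <- ranger::ranger(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(vn, collapse = " + "))),
    data = df, num.trees = num.trees, seed = seed, num.threads = 1,
    verbose = FALSE)
  list(predict = function(expr) {
    nd <- data.frame(t(expr))
    colnames(nd) <- make.names(rownames(expr), unique = TRUE)
    chf <- stats::predict(fit, data = nd)$chf
    stats::setNames(chf[, ncol(chf)], colnames(expr))
  }, coefficients = NULL, linear = FALSE)
}

fit_gbm <- function(expr, sv, nrounds, eta, max_depth, min_child_weight) {
  # survival:cox encodes censoring as a negative label
  lab <- ifelse(sv$event == 1L, sv$time, -sv$time)
  dtrain <- xgboost::xgb.DMatrix(t(expr), label = lab)
  bst <- xgboost::xgb.train(
    params = list(objective = "survival:cox", eta = eta,
                  max_depth = max_depth,
                  min_child_weight = min_child_weight, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  list(predict = function(expr) {
    d <- xgboost::xgb.DMatrix(t(expr))
    stats::setNames(stats::predict(bst, d, outputmargin = TRUE),
                    colnames(expr))
  }, coefficients = NULL, linear = FALSE)
}

# -- benchmark -------------------------------------------------------

# z-score each gene within one cohort; constant genes become 0.
standardize_genes <- function(expr) {
  mu <- rowMeans(expr)
  sd <- row_sds(expr)
  sd[sd == 0] <- 1
  (expr - mu) / sd
}

#' Cross-validated multi-learner benchmark
#'
#' Fits every available learner on the candidate genes of the
#' training cohort and ranks learners by the unweighted mean of (a)
#' the mean held-out Harrell C-index over `k` cross-validation folds
#' of the training cohort and (b) the C-index of the train-fitted
#' model applied, without refitting, to each external validation
#' cohort.  Expression is standardized per gene within each cohort
#' independently before fitting or scoring (cross-platform
#' comparability), so exported coefficients live on the standardized
#' scale.  Ties on the mean C-index break toward the learner with
#' fewer selected genes, then lexicographic name.
#'
#' @param train Training cohort: a tumor-only [multiregion_cohort()]
#'   with survival (multiregion cohorts are region-averaged per
#'   patient) or a list `(expression, time, event)`.
#' @param validations Non-empty list of validation cohorts in either
#'   form.
#' @param candidates Candidate gene ids (default: all genes shared by
#'   every cohort).  Genes absent from any cohort are dropped with a
#'   warning.
#' @param learners List of [learner_spec()]s; unavailable entries are
#'   skipped and recorded.
#' @param k Cross-validation folds.
#' @param seed Fold-assignment and learner seed.
#' @return A `benchmark_result` list: `cindex` (long `data.frame`
#'   learner x dataset), `summary` (per learner: `mean_cindex`,
#'   `internal_cindex`, `n_genes`, `status`), `winner`, `signature` (a
#'   [gene_signature()] of the winner's nonzero standardized-scale
#'   coefficients when the winner is coefficient-based, else `NULL`),
#'   and `winner_model`.
#' @export
benchmark_select <- function(train, validations, candidates = NULL,
                             learners = default_learners(), k = 5,
                             seed = 123) {
  if (inherits(validations, "multiregion_cohort")) validations <- list(validations)
  if (!length(validations))
    stop("benchmark_select() needs >= 1 validation cohort", call. = FALSE)
  if (is.null(names(validations)) || any(names(validations) == ""))
    names(validations) <- paste0("validation", seq_along(validations))
  tr <- as_patient_data(train)
  va <- lapply(validations, as_patient_data)

  candidates <- candidates %||% rownames(tr$expression)
  shared <- Reduce(intersect, c(list(rownames(tr$expression)),
                                lapply(va, function(v) rownames(v$expression))))
  dropped <- setdiff(candidates, shared)
  if (length(dropped))
    warning(length(dropped), " candidate gene(s) absent from some cohort; ",
            "dropped", call. = FALSE)
  candidates <- intersect(candidates, shared)
  if (length(candidates) < 2)
    stop("fewer than 2 candidate genes shared across cohorts", call. = FALSE)

  tr_x <- standardize_genes(tr$expression[candidates, , drop = FALSE])
  va_x <- lapply(va, function(v)
    standardize_genes(v$expression[candidates, , drop = FALSE]))

  tr_sv <- data.frame(patient_id = colnames(tr_x), time = tr$time,
                      event = tr$event)
  n <- ncol(tr_x)
  foldid <- make_foldid(n, k, seed)

  if (inherits(learners, "learner_spec")) learners <- list(learners)
  names(learners) <- vapply(learners, `[[`, "", "name")
  run <- Filter(function(s) s$available, learners)
  skipped <- setdiff(names(learners), names(run))

  rows <- list(); summary_rows <- list()
  models <- list()
  for (nm in names(run)) {
    spec <- run[[nm]]
    res <- tryCatch({
      fold_c <- vapply(seq_len(k), function(f) {
        in_tr <- foldid != f
        m <- fit_learner(spec, tr_x[, in_tr, drop = FALSE],
                         tr_sv[in_tr, , drop = FALSE], seed = seed)
        sc <- m$predict(tr_x[, !in_tr, drop = FALSE])
        harrell_cindex(sc, tr$time[!in_tr], tr$event[!in_tr])
      }, numeric(1))
      full <- fit_learner(spec, tr_x, tr_sv, seed = seed)
      ext <- vapply(seq_along(va_x), function(i) {
        sc <- full$predict(va_x[[i]])
        harrell_cindex(sc, va[[i]]$time, va[[i]]$event)
      }, numeric(1))
      list(internal = mean(fold_c), ext = ext, full = full)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      summary_rows[[nm]] <- data.frame(
        learner = nm, internal_cindex = NA_real_, mean_cindex = NA_real_,
        n_genes = NA_integer_,
        status = paste0("disqualified: ", conditionMessage(res)),
        stringsAsFactors = FALSE)
      next
    }
    models[[nm]] <- res$full
    cvec <- c(train_cv = res$internal,
              stats::setNames(res$ext, names(validations)))
    rows[[nm]] <- data.frame(learner = nm, dataset = names(cvec),
                             cindex = unname(cvec),
                             stringsAsFactors = FALSE)
    ng <- if (res$full$linear) sum(res$full$coefficients != 0)
          else length(candidates)
    summary_rows[[nm]] <- data.frame(
      learner = nm, internal_cindex = res$internal,
      mean_cindex = mean(cvec), n_genes = as.integer(ng), status = "ok",
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  cindex <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else stop("every learner failed", call. = FALSE)

  ok <- summary[summary$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("every learner was disqualified", call. = FALSE)
  ord <- order(-ok$mean_cindex, ok$n_genes, ok$learner)
  winner <- ok$learner[ord[1]]
  wm <- models[[winner]]
  signature <- NULL
  if (wm$linear) {
    nz <- wm$coefficients[wm$coefficients != 0]
    if (length(nz)) signature <- gene_signature(names(nz), unname(nz),
                                                name = winner)
  }
  structure(list(cindex = cindex, summary = summary, winner = winner,
                 signature = signature, winner_model = wm,
                 skipped = skipped, candidates = candidates,
                 k = k, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result: ", sum(x$summary$status == "ok"),
      " learners on ", length(x$candidates), " candidate genes (k = ",
      x$k, ", seed = ", x$seed, ")\n", sep = "")
  s <- x$summary[order(-x$summary$mean_cindex), ]
  print(s, row.names = FALSE, digits = 4)
  cat("winner: ", x$winner,
      if (!is.null(x$signature))
        paste0(" (", length(x$signature$genes), "-gene signature)")
      else " (non-linear model; no coefficient signature)", "\n", sep = "")
  invisible(x)
}
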