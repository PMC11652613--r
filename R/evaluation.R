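# Survival evaluation utilities: Harrell's C, Kaplan-Meier/log-rank,
# multivariate Cox, IPCW time-dependent AUC, fixed-effect HR pooling.

#' Harrell's concordance index
#'
#' Probability, over comparable patient pairs, that the patient with
#' the higher risk score fails earlier.  A pair (i, j) is comparable
#' when the earlier time is an observed event (`t_i < t_j` with
#' `event_i = 1`), or the times are tied with exactly one event (the
#' event patient is the earlier failure).  Pairs tied on time with
#' two events are not comparable; tied scores on a comparable pair
#' count 0.5.
#'
#' @param scores Numeric risk scores (higher = higher predicted
#'   hazard).
#' @param time Follow-up times (> 0).
#' @param event Event indicator, 0 censored / 1 event.
#' @return Concordant share in `[0, 1]`.  Errors when no pair is
#'   comparable.
#' @export
harrell_cindex <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  event <- as.integer(event)
  ok <- is.finite(scores) & is.finite(time)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  n <- length(time)
  if (n < 2) stop("harrell_cindex() needs >= 2 usable patients", call. = FALSE)
  # ordered pairs (i earlier failure, j longer survivor)
  ti <- matrix(time, n, n)            # ti[i, j] = time_i
  di <- matrix(event, n, n)
  comp <- (ti < t(ti) & di == 1L) |
          (ti == t(ti) & di == 1L & t(di) == 0L)
  diag(comp) <- FALSE
  if (!any(comp)) stop("no comparable pair", call. = FALSE)
  si <- matrix(scores, n, n)
  conc <- (si > t(si)) + 0.5 * (si == t(si))
  sum(conc[comp]) / sum(comp)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per risk class and the two-group log-rank
#' statistic (hypergeometric variance, 1 df chi-squared).
#'
#' @param classes Per-patient group labels (exactly two non-empty
#'   groups, e.g. `"high"`/`"low"`).
#' @param time,event Survival outcome per patient.
#' @return List: `fit` (a [survival::survfit] object), `chisq`, `p`,
#'   and the per-group `n`/`events` table.  A group with zero events
#'   keeps the statistic defined but triggers a warning.
#' @export
km_logrank <- function(classes, time, event) {
  classes <- as.character(classes)
  if (length(unique(classes)) != 2)
    stop("km_logrank() needs exactly two groups", call. = FALSE)
  event <- as.integer(event)
  ev_by <- tapply(event, classes, sum)
  if (any(ev_by == 0))
    warning("group with zero events: ",
            paste(names(ev_by)[ev_by == 0], collapse = ", "), call. = FALSE)
  df <- data.frame(time = time, event = event, group = classes)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd$chisq
  list(fit = fit, chisq = unname(chisq),
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       table = data.frame(group = names(ev_by),
                          n = as.integer(table(classes)[names(ev_by)]),
                          events = as.integer(ev_by)))
}

#' Multivariate Cox adjustment
#'
#' Joint proportional-hazards fit (Efron ties) of a risk score
#' alongside clinical covariates, to ask whether the score remains an
#' independent prognostic factor after adjustment.
#'
#' @param design Patient x covariate `data.frame` or matrix (include
#'   the risk score as one column).  Must be full rank after adding
#'   the intercept; collinear columns are a hard error naming them.
#' @param time,event Survival outcome, aligned with the design rows.
#' @param conf_level Confidence level for the Wald intervals.
#' @return `data.frame` per covariate: `term`, `log_hr`, `hr`, `se`,
#'   `lower`, `upper`, `p`.  Fewer than 10 events per covariate
#'   triggers a warning.
#' @export
multivariate_cox <- function(design, time, event, conf_level = 0.95) {
  design <- as.data.frame(design)
  if (!nrow(design) || nrow(design) != length(time))
    stop("design rows must match the outcome length", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = design)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  event <- as.integer(event)
  if (sum(event) < 10 * ncol(design))
    warning("fewer than 10 events per covariate (",
            sum(event), " events, ", ncol(design), " covariates)",
            call. = FALSE)
  df <- cbind(data.frame(.time = time, .event = event), design)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(beta), log_hr = unname(beta),
             hr = exp(unname(beta)), se = unname(se),
             lower = exp(unname(beta) - z * se),
             upper = exp(unname(beta) + z * se),
             p = 2 * stats::pnorm(-abs(unname(beta) / se)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Time-dependent AUC with IPCW censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each evaluation time:
#' cases are patients with an observed event by `t`, controls those
#' still at risk beyond `t`.  Cases are weighted by the inverse
#' Kaplan-Meier censoring survival at their event time (left limit),
#' which removes the bias from informative loss of early cases under
#' censoring; with no censoring before `t` the estimate equals the
#' empirical case/control AUC.
#'
#' @param scores Per-patient risk scores.
#' @param time,event Survival outcome.
#' @param eval_times Evaluation horizons (same unit as `time`); each
#'   should lie below the last observed follow-up time.
#' @return `data.frame` per horizon: `time`, `auc`, `n_cases`,
#'   `n_controls`.  A horizon with no case or no control gets `NA`.
#' @export
time_dependent_auc <- function(scores, time, event, eval_times) {
  event <- as.integer(event)
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  # right-continuous KM of the censoring distribution; G(u-) is the
  # value just before u
  Gfun <- stats::stepfun(cf$time, c(1, cf$surv), right = FALSE)
  G_left <- function(u) Gfun(u - 1e-10)
  rows <- lapply(eval_times, function(tt) {
    case <- which(time <= tt & event == 1L)
    ctrl <- which(time > tt)
    if (!length(case) || !length(ctrl))
      return(data.frame(time = tt, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl)))
    w <- 1 / vapply(time[case], G_left, numeric(1))
    w[!is.finite(w)] <- 0
    if (all(w == 0))
      return(data.frame(time = tt, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl)))
    sc <- scores[case]; sj <- scores[ctrl]
    gt <- outer(sc, sj, ">") + 0.5 * outer(sc, sj, "==")
    auc <- sum(w * rowSums(gt)) / (sum(w) * length(ctrl))
    data.frame(time = tt, auc = auc, n_cases = length(case),
               n_controls = length(ctrl))
  })
  do.call(rbind, rows)
}

#' Fixed-effect pooling of per-study hazard ratios
#'
#' Inverse-variance fixed-effect meta-analysis of per-study log hazard
#' ratios with Cochran's Q heterogeneity statistic and
#' `I2 = max(0, (Q - df) / Q)`.
#'
#' @param log_hr Per-study log hazard ratios (>= 2 studies).
#' @param se Matching standard errors (> 0).
#' @param conf_level Confidence level for the pooled interval.
#' @return A `meta_result` list: `pooled_log_hr`, `pooled_hr`, `se`,
#'   `lower`, `upper`, `p` (pooled effect), `Q`, `df`, `I2`, `p_het`.
#' @export
pool_hr <- function(log_hr, se, conf_level = 0.95) {
  if (length(log_hr) < 2) stop("pool_hr() needs >= 2 studies", call. = FALSE)
  if (length(se) != length(log_hr))
    stop("log_hr and se differ in length", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * log_hr) / sum(w)
  pse <- sqrt(1 / sum(w))
  Q <- sum(w * (log_hr - pooled)^2)
  df <- length(log_hr) - 1L
  I2 <- max(0, (Q - df) / Q)
  if (Q == 0) I2 <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(pooled_log_hr = pooled, pooled_hr = exp(pooled), se = pse,
                 lower = exp(pooled - z * pse), upper = exp(pooled + z * pse),
                 p = 2 * stats::pnorm(-abs(pooled / pse)),
                 Q = Q, df = df, I2 = I2,
                 p_het = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("fixed-effect pooled HR ", signif(x$pooled_hr, 4), " [",
      signif(x$lower, 4), ", ", signif(x$upper, 4), "], p = ",
      signif(x$p, 3), "\n", sep = "")
  cat("heterogeneity: Q = ", signif(x$Q, 4), " (df ", x$df, "), I2 = ",
      round(100 * x$I2, 1), "%, p = ", signif(x$p_het, 3), "\n", sep = "")
  invisible(x)
}
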