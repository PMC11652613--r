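# Synthetic multiregion cohorts with known variance components.
#
# Generative model, per gene g, patient p, region r:
#   x[g,p,r] = mu_g + b[g,p] + e[g,p,r]
#   b ~ Normal(0, tau_g^2)     patient-level (intertumor) component
#   e ~ Normal(0, sigma_g^2)   region-level (intratumor) component
# Survival is an exponential proportional-hazards outcome driven only
# by the patient-level signal of the planted genes:
#   hazard_p = h0 * exp( sum_j beta_j * (mu_j + b[j,p]) )
# so prognosis is a patient attribute and region noise is pure
# sampling nuisance.  Censoring is an independent exponential time
# whose rate is solved numerically so that the expected censored
# fraction matches `censor_rate`.

#' Define a gene archetype block
#'
#' An archetype is a block of genes sharing the same mean `mu`,
#' patient-level SD `tau`, and region-level SD `sigma`.  The labels
#' mirror the heterogeneity quadrants: `Q4-like` genes are stable
#' within a tumor but variable between patients (high `tau`, low
#' `sigma`), `Q1-like` the reverse, `Q2-like` low on both components,
#' `Q3-like` high on both.
#'
#' @param label One of `"Q1-like"`, `"Q2-like"`, `"Q3-like"`,
#'   `"Q4-like"`.
#' @param n_genes Number of genes in the block (>= 0).
#' @param mu Mean log-expression of the block.
#' @param tau Patient-level SD (>= 0).
#' @param sigma Region-level SD (>= 0).
#' @return A `gene_archetype` list.
#' @export
gene_archetype <- function(label = c("Q1-like", "Q2-like", "Q3-like", "Q4-like"),
                           n_genes, mu = 7, tau, sigma) {
  label <- match.arg(label)
  n_genes <- as.integer(n_genes)
  if (n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  if (tau < 0 || sigma < 0) stop("tau and sigma must be >= 0", call. = FALSE)
  structure(list(label = label, n_genes = n_genes, mu = mu,
                 tau = tau, sigma = sigma),
            class = "gene_archetype")
}

#' Default four-archetype gene panel
#'
#' One block per quadrant archetype with shared high/low component
#' levels.
#'
#' @param n_genes Genes per block.
#' @param mu Mean log-expression for every block.
#' @param tau_levels,sigma_levels Named numeric `c(low = , high = )`
#'   levels for the patient- and region-level SDs.
#' @return List of four [gene_archetype()] blocks (Q1- to Q4-like).
#' @export
default_archetypes <- function(n_genes = 250, mu = 7,
                               tau_levels = c(low = 0.2, high = 1),
                               sigma_levels = c(low = 0.2, high = 1)) {
  list(
    gene_archetype("Q1-like", n_genes, mu, tau_levels[["low"]],  sigma_levels[["high"]]),
    gene_archetype("Q2-like", n_genes, mu, tau_levels[["low"]],  sigma_levels[["low"]]),
    gene_archetype("Q3-like", n_genes, mu, tau_levels[["high"]], sigma_levels[["high"]]),
    gene_archetype("Q4-like", n_genes, mu, tau_levels[["high"]], sigma_levels[["low"]])
  )
}

#' Define the planted prognostic signature
#'
#' The planted genes are drawn from the Q4-like block (stable within a
#' tumor, variable between patients) and carry the log-hazard effects
#' that drive the synthetic survival outcome.
#'
#' @param n_genes Number of planted genes (0 disables survival
#'   generation).
#' @param beta Scalar effect magnitude; the default assigns
#'   alternating signs `+beta, -beta, ...` across the planted genes.
#' @param betas Optional explicit numeric vector of per-gene
#'   log-hazard effects, overriding `beta`.
#' @param gene_indices Optional explicit row indices (into the
#'   generated matrix) of the planted genes; these must fall inside
#'   the Q4-like block.  Default: the first `n_genes` Q4-like rows.
#' @return A `planted_signature` list.
#' @export
planted_signature <- function(n_genes = 10, beta = 0.6, betas = NULL,
                              gene_indices = NULL) {
  if (!is.null(betas)) n_genes <- length(betas)
  n_genes <- as.integer(n_genes)
  if (is.null(betas)) betas <- beta * rep_len(c(1, -1), n_genes)
  if (!is.null(gene_indices) && length(gene_indices) != n_genes)
    stop("gene_indices and betas differ in length", call. = FALSE)
  structure(list(n_genes = n_genes, betas = as.numeric(betas),
                 gene_indices = gene_indices),
            class = "planted_signature")
}

#' Configure a synthetic multiregion cohort
#'
#' Defaults encode a mid-sized multiregion study: 100 patients with 3
#' tumor regions each, four 250-gene archetype blocks with component
#' SDs 0.2 (low) and 1.0 (high) on a mean log-expression of 7, a
#' 10-gene planted signature of alternating-sign effects |beta| = 0.6
#' per expression unit, an exponential baseline hazard giving a
#' 900-day median survival at the baseline linear predictor, and 30%
#' expected censoring.
#'
#' @param n_patients Number of patients (>= 2).
#' @param regions_per_patient Scalar or per-patient integer vector of
#'   tumor regions (>= 1).
#' @param archetypes List of [gene_archetype()] blocks.
#' @param planted A [planted_signature()].
#' @param baseline_hazard Baseline event rate `h0` (events/day, > 0).
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Integer seed; drives every draw via fixed per-stage
#'   sub-seeds (`seed` patient effects, `seed + 1` region noise,
#'   `seed + 2` event times, `seed + 3` censoring times).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 100, regions_per_patient = 3,
                             archetypes = default_archetypes(),
                             planted = planted_signature(),
                             baseline_hazard = log(2) / 900,
                             censor_rate = 0.3, seed = 1) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  regions <- as.integer(rep_len(regions_per_patient, n_patients))
  if (any(regions < 1)) stop("regions_per_patient must be >= 1", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  if (!all(vapply(archetypes, inherits, TRUE, "gene_archetype")))
    stop("archetypes must be a list of gene_archetype objects", call. = FALSE)
  check_archetype_levels(archetypes)
  structure(list(n_patients = n_patients, regions_per_patient = regions,
                 archetypes = archetypes, planted = planted,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Archetype labels must be consistent with the config's realized
# high/low component levels (e.g. Q4-like tau above Q1/Q2-like tau).
check_archetype_levels <- function(archetypes) {
  lab <- vapply(archetypes, `[[`, "", "label")
  tau <- vapply(archetypes, `[[`, 0, "tau")
  sig <- vapply(archetypes, `[[`, 0, "sigma")
  tau_hi <- lab %in% c("Q3-like", "Q4-like")
  sig_hi <- lab %in% c("Q1-like", "Q3-like")
  if (any(tau_hi) && any(!tau_hi) && min(tau[tau_hi]) <= max(tau[!tau_hi]))
    stop("archetype tau levels contradict labels (Q3/Q4-like must have ",
         "higher tau than Q1/Q2-like)", call. = FALSE)
  if (any(sig_hi) && any(!sig_hi) && min(sig[sig_hi]) <= max(sig[!sig_hi]))
    stop("archetype sigma levels contradict labels (Q1/Q3-like must have ",
         "higher sigma than Q2/Q4-like)", call. = FALSE)
  invisible(archetypes)
}

#' True archetype label per generated gene row
#'
#' Deterministic bookkeeping: the generated expression matrix lays the
#' archetype blocks out in the order they appear in the config, and
#' this returns the matching label per row, named by gene id.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector, one archetype label per gene row.
#' @export
truth_quadrant <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labs <- unlist(lapply(config$archetypes,
                        function(a) rep(a$label, a$n_genes)))
  stats::setNames(labs, synthetic_gene_ids(config))
}

synthetic_gene_ids <- function(config) {
  unlist(lapply(config$archetypes, function(a) {
    if (a$n_genes == 0) return(character())
    sprintf("%s_%04d", sub("-like", "like", a$label), seq_len(a$n_genes))
  }))
}

# Resolve planted gene rows; they must sit inside the Q4-like block.
resolve_planted <- function(config, labels) {
  pl <- config$planted
  if (is.null(pl) || pl$n_genes == 0) return(NULL)
  q4 <- which(labels == "Q4-like")
  if (is.null(pl$gene_indices)) {
    if (length(q4) < pl$n_genes)
      stop("not enough Q4-like genes to plant the signature", call. = FALSE)
    idx <- q4[seq_len(pl$n_genes)]
  } else {
    idx <- as.integer(pl$gene_indices)
    if (!all(idx %in% q4))
      stop("planted gene index outside the Q4-like block", call. = FALSE)
  }
  list(idx = idx, betas = pl$betas)
}

# Solve the exponential censoring rate c so that the expected censored
# fraction, mean_p c / (c + hazard_p), equals the target.
solve_censor_rate <- function(hazard, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + hazard)) - target
  lo <- log(min(hazard)) - 25
  hi <- log(max(hazard)) + 25
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Generate a synthetic multiregion cohort with ground truth
#'
#' Draws expression per the additive two-component model described
#' above, and (when a planted signature is configured) an exponential
#' proportional-hazards survival outcome driven by the patient-level
#' signal `sum_j beta_j * (mu_j + b[j, p])` of the planted genes.
#' With a fixed config the output is bit-reproducible.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{cohort}{a [multiregion_cohort()] (all samples tumor);}
#'     \item{truth}{ground truth: per-gene `genes` table (archetype,
#'       mu, tau, sigma, beta), per-patient `patients` table (linear
#'       predictor, latent event/censor times, observed time/event),
#'       the patient-effect matrix `b`, the solved censoring hazard,
#'       and the realized censored fraction.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- truth_quadrant(config)
  ng <- length(labels)
  if (ng == 0) stop("config generates zero genes", call. = FALSE)
  gid <- names(labels)
  mu <- unlist(lapply(config$archetypes, function(a) rep(a$mu, a$n_genes)))
  tau <- unlist(lapply(config$archetypes, function(a) rep(a$tau, a$n_genes)))
  sigma <- unlist(lapply(config$archetypes, function(a) rep(a$sigma, a$n_genes)))

  P <- config$n_patients
  regions <- config$regions_per_patient
  pid <- sprintf("P%03d", seq_len(P))
  pat_of_sample <- rep(seq_len(P), regions)
  reg_of_sample <- unlist(lapply(regions, seq_len))
  sid <- sprintf("%s_R%d", pid[pat_of_sample], reg_of_sample)

  set.seed(config$seed)
  b <- matrix(stats::rnorm(ng * P), ng, P) * tau
  dimnames(b) <- list(gid, pid)
  set.seed(config$seed + 1L)
  e <- matrix(stats::rnorm(ng * length(sid)), ng, length(sid)) * sigma
  expr <- mu + b[, pat_of_sample, drop = FALSE] + e
  dimnames(expr) <- list(gid, sid)

  samples <- data.frame(sample_id = sid,
                        patient_id = pid[pat_of_sample],
                        region_id = paste0("R", reg_of_sample),
                        tissue = "tumor", stringsAsFactors = FALSE)

  beta <- numeric(ng)
  planted <- resolve_planted(config, labels)
  survival <- NULL
  patients <- data.frame(patient_id = pid, lp = NA_real_,
                         event_time = NA_real_, censor_time = NA_real_,
                         time = NA_real_, event = NA_integer_,
                         stringsAsFactors = FALSE)
  censor_hazard <- NA_real_
  if (!is.null(planted)) {
    beta[planted$idx] <- planted$betas
    lp <- as.numeric(crossprod(mu[planted$idx] + b[planted$idx, , drop = FALSE],
                               planted$betas))
    hazard <- config$baseline_hazard * exp(lp)
    set.seed(config$seed + 2L)
    t_event <- stats::rexp(P, rate = hazard)
    censor_hazard <- solve_censor_rate(hazard, config$censor_rate)
    if (censor_hazard > 0) {
      set.seed(config$seed + 3L)
      t_cens <- stats::rexp(P, rate = censor_hazard)
    } else {
      t_cens <- rep(Inf, P)
    }
    patients$lp <- lp
    patients$event_time <- t_event
    patients$censor_time <- t_cens
    patients$time <- pmin(t_event, t_cens)
    patients$event <- as.integer(t_event <= t_cens)
    survival <- data.frame(patient_id = pid, time = patients$time,
                           event = patients$event,
                           stringsAsFactors = FALSE)
  }

  truth <- list(
    genes = data.frame(gene = gid, archetype = unname(labels), mu = mu,
                       tau = tau, sigma = sigma, beta = beta,
                       stringsAsFactors = FALSE),
    patients = patients,
    b = b,
    censor_hazard = censor_hazard,
    censor_rate_target = config$censor_rate,
    censor_rate_realized = if (is.null(survival)) NA_real_
                           else mean(survival$event == 0L),
    seed = config$seed
  )
  structure(list(cohort = multiregion_cohort(expr, samples, survival),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort (seed ", x$truth$seed, ")\n", sep = "")
  print(x$cohort)
  n_planted <- sum(x$truth$genes$beta != 0)
  if (n_planted)
    cat("  planted signature: ", n_planted, " genes | realized censoring: ",
        round(100 * x$truth$censor_rate_realized, 1), "%\n", sep = "")
  invisible(x)
}
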