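# Linear risk scoring, median stratification, and the multiregion
# sampling-bias audit of a gene signature.

#' Signature risk score per sample
#'
#' `score_s = sum_i coefficient_i * expression[i, s]` over the
#' signature genes present in the cohort's matrix.  Signature genes
#' absent from the matrix are dropped (never zero-imputed: on
#' log-scale data a zero is an actual expression value, and silent
#' imputation would shift every score); the dropped ids are attached
#' as the `"dropped_genes"` attribute so the loss is auditable.
#'
#' @param cohort A [multiregion_cohort()].
#' @param signature A [gene_signature()].
#' @return Named numeric vector of per-sample scores with attribute
#'   `"dropped_genes"`.  Zero overlapping genes is a hard error
#'   listing the signature's genes.
#' @export
risk_score <- function(cohort, signature) {
  stopifnot(inherits(cohort, "multiregion_cohort"),
            inherits(signature, "gene_signature"))
  present <- signature$genes %in% rownames(cohort$expression)
  if (!any(present))
    stop("no signature gene found in the cohort; signature genes: ",
         paste(signature$genes, collapse = ", "), call. = FALSE)
  g <- signature$genes[present]
  scores <- as.numeric(crossprod(cohort$expression[g, , drop = FALSE],
                                 signature$coefficients[g]))
  names(scores) <- colnames(cohort$expression)
  attr(scores, "dropped_genes") <- signature$genes[!present]
  scores
}

#' Stratify scores into high/low risk classes
#'
#' Default cutoff is the cohort median of the supplied scores (for an
#' even count, the mean of the central pair).  A sample is classed
#' high iff its score is strictly greater than the cutoff; ties at
#' the cutoff are classed low, so an even cohort splits exactly in
#' half under the median policy.
#'
#' @param scores Named numeric vector of risk scores.
#' @param cutoff Optional externally supplied cutoff; when omitted the
#'   cohort median is used (requires >= 2 samples).
#' @return A `risk_profile`: `data.frame` with columns `sample_id`,
#'   `score`, `class` (`"high"`/`"low"`), plus attributes `cutoff` and
#'   `cutoff_policy` (`"cohort_median"` or `"supplied"`).
#' @export
stratify <- function(scores, cutoff = NULL) {
  scores <- drop_attributes(scores)
  policy <- if (is.null(cutoff)) "cohort_median" else "supplied"
  if (is.null(cutoff)) {
    if (length(scores) < 2)
      stop("median stratification needs >= 2 samples", call. = FALSE)
    cutoff <- stats::median(scores)
    if (all(scores == scores[1]))
      warning("all scores identical; every sample classed low",
              call. = FALSE)
  }
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  out <- data.frame(sample_id = names(scores) %||%
                      as.character(seq_along(scores)),
                    score = unname(scores),
                    class = ifelse(scores > cutoff, "high", "low"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("risk_profile", "data.frame"),
            cutoff = unname(cutoff), cutoff_policy = policy)
}

drop_attributes <- function(x) {
  nm <- names(x)
  attributes(x) <- NULL
  names(x) <- nm
  x
}

#' Multiregion concordance audit of a signature
#'
#' Scores every tumor region, stratifies at the cohort-wide median
#' over all tumor region samples, and labels each patient by the set
#' of its regions' risk classes: `concordant_low` (all low),
#' `concordant_high` (all high), or `discordant` (a mixture --
#' single-region patients can never be discordant).  A signature is
#' flagged `biased` for the cohort when more than half of the
#' patients are discordant.
#'
#' @param cohort A tumor-only [multiregion_cohort()].
#' @param signature A [gene_signature()].
#' @param cutoff Optional externally supplied cutoff (default: median
#'   over all tumor region scores).
#' @return A `concordance_summary` list: `patients` (`data.frame` with
#'   `patient_id`, `n_regions`, `label`), `discordant_fraction`
#'   (discordant patients / all patients), `biased`
#'   (`discordant_fraction > 0.5`), `cutoff`, and the per-sample
#'   `profile`.
#' @export
region_concordance <- function(cohort, signature, cutoff = NULL) {
  assert_tumor_only(cohort, "region_concordance")
  scores <- risk_score(cohort, signature)
  profile <- stratify(scores, cutoff = cutoff)
  cls <- split(profile$class, cohort$samples$patient_id)
  label <- vapply(cls, function(k) {
    if (all(k == "low")) "concordant_low"
    else if (all(k == "high")) "concordant_high"
    else "discordant"
  }, character(1))
  patients <- data.frame(patient_id = names(cls),
                         n_regions = lengths(cls),
                         label = unname(label),
                         stringsAsFactors = FALSE, row.names = NULL)
  frac <- mean(label == "discordant")
  structure(list(patients = patients,
                 discordant_fraction = frac,
                 biased = frac > 0.5,
                 cutoff = attr(profile, "cutoff"),
                 profile = profile),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("concordance_summary: ", nrow(x$patients), " patients | discordant ",
      round(100 * x$discordant_fraction, 1), "% | biased (>50%): ",
      x$biased, "\n", sep = "")
  print(table(x$patients$label))
  invisible(x)
}

#' Per-patient dispersion of region risk scores
#'
#' The sample SD of each multiregion patient's region scores --- a
#' direct measure of how much a single-biopsy risk score could move
#' depending on which region was sampled.  Patients with fewer than
#' two regions are excluded; the cohort summary is the mean of the
#' per-patient SDs.
#'
#' @inheritParams region_concordance
#' @return List with `per_patient` (`data.frame`: `patient_id`,
#'   `n_regions`, `sd`) and `mean_sd`.  Errors when no patient has
#'   >= 2 regions.
#' @export
risk_dispersion <- function(cohort, signature) {
  assert_tumor_only(cohort, "risk_dispersion")
  scores <- risk_score(cohort, signature)
  by_pat <- split(unname(scores), cohort$samples$patient_id)
  by_pat <- by_pat[lengths(by_pat) >= 2]
  if (!length(by_pat))
    stop("no patient has >= 2 tumor regions", call. = FALSE)
  sds <- vapply(by_pat, stats::sd, numeric(1))
  list(per_patient = data.frame(patient_id = names(by_pat),
                                n_regions = lengths(by_pat),
                                sd = unname(sds),
                                stringsAsFactors = FALSE,
                                row.names = NULL),
       mean_sd = mean(sds))
}

#' Cohort-level variance of signature scores
#'
#' Sample variance (n-1 denominator) of the per-sample risk scores
#' across the whole cohort.  Higher variance means sharper separation
#' between patients, i.e. more usable intertumor signal.
#'
#' @inheritParams region_concordance
#' @return A single number.  Errors with < 2 samples.
#' @export
score_variance <- function(cohort, signature) {
  stopifnot(inherits(cohort, "multiregion_cohort"))
  if (n_samples(cohort) < 2)
    stop("score_variance() needs >= 2 samples", call. = FALSE)
  scores <- risk_score(cohort, signature)
  stats::var(drop_attributes(scores))
}

#' Audit one or more signatures for multiregion sampling bias
#'
#' Convenience wrapper running [region_concordance()],
#' [risk_dispersion()], and [score_variance()] for each signature on
#' the same tumor-only multiregion cohort.
#'
#' @param cohort A tumor-only [multiregion_cohort()].
#' @param signatures A [gene_signature()] or list of them.
#' @return `data.frame` with one row per signature: `signature`,
#'   `n_genes`, `n_genes_used`, `discordant_fraction`, `biased`,
#'   `mean_dispersion`, `score_variance`.
#' @export
audit_bias <- function(cohort, signatures) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  rows <- lapply(signatures, function(sig) {
    conc <- region_concordance(cohort, sig)
    disp <- risk_dispersion(cohort, sig)
    sc <- risk_score(cohort, sig)
    data.frame(signature = sig$name, n_genes = length(sig$genes),
               n_genes_used = length(sig$genes) -
                 length(attr(sc, "dropped_genes")),
               discordant_fraction = conc$discordant_fraction,
               biased = conc$biased,
               mean_dispersion = disp$mean_sd,
               score_variance = score_variance(cohort, sig),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
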