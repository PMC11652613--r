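# Shared internal helpers.

#' Unbiasing constant for the sample standard deviation
#'
#' `c4(n)` is the factor by which the sample SD of `n` independent
#' normal draws underestimates the true sigma: `E[s] = c4(n) * sigma`.
#' It is used in variance-component recovery checks, where the mean
#' within-patient SD of a gene over many patients converges to
#' `c4(n_regions) * sigma`, not to sigma itself.
#'
#' @param n Number of observations per sample SD (integer >= 2).
#' @return `sqrt(2/(n-1)) * gamma(n/2) / gamma((n-1)/2)`.
#' @examples
#' c4_constant(3) # 0.8862...
#' @export
c4_constant <- function(n) {
  if (any(n < 2)) stop("c4_constant() requires n >= 2", call. = FALSE)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# Row-wise sample SD (n-1 denominator) of a numeric matrix.
row_sds <- function(m) {
  if (ncol(m) < 2) stop("row_sds() needs >= 2 columns", call. = FALSE)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

# Row-wise MAD with the 1.4826 normal-consistency constant.
row_mads <- function(m, constant = 1.4826) {
  apply(m, 1L, stats::mad, constant = constant)
}

# Row-wise dispersion under a named metric.  CV divides the row SD by
# the row mean and returns NA where |mean| falls under `eps` (log-scale
# expression can sit arbitrarily close to zero, making CV unstable).
row_dispersion <- function(m, metric = c("SD", "MAD", "CV"), eps = 1e-8) {
  metric <- match.arg(metric)
  switch(metric,
    SD  = row_sds(m),
    MAD = row_mads(m),
    CV  = {
      mu <- rowMeans(m)
      cv <- row_sds(m) / mu
      cv[abs(mu) < eps] <- NA_real_
      cv
    }
  )
}

# Order survival rows to match the columns of a gene x patient matrix.
# Returns list(time, event) or errors on missing/duplicated patients.
align_survival <- function(expr, survival) {
  survival <- as.data.frame(survival)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(survival)))
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(survival$patient_id))
    stop("duplicated patient_id in survival table", call. = FALSE)
  idx <- match(colnames(expr), survival$patient_id)
  if (anyNA(idx)) {
    miss <- colnames(expr)[is.na(idx)]
    stop("no survival record for patient(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  list(time = as.numeric(survival$time[idx]),
       event = as.integer(survival$event[idx]))
}

# Delimiter from file extension: .csv -> comma, anything else -> tab.
# Deliberately extension-driven (no content sniffing) so that the same
# file always parses the same way.
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
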