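# Per-gene intratumor / intertumor heterogeneity scores, the quadrant
# partition, metric agreement, and quadrant enrichment of gene sets.
#
# Conventions fixed here and documented in the methods vignette:
#  * Intra score = per-patient dispersion across that patient's tumor
#    regions, averaged over patients with >= 2 regions.  Pooling all
#    regions of all patients instead would conflate intertumor with
#    intratumor variation, defeating the quadrant logic.
#  * Inter score = dispersion across patients of one randomly chosen
#    region per patient, averaged over `n_reps` independent draws
#    (regions resampled with replacement across repetitions); patients
#    with a single region contribute it deterministically.
#  * Quadrant thresholds are the arithmetic means of each axis; ">="
#    counts as high on both axes (deterministic tie-breaking).

#' Per-gene intratumor heterogeneity
#'
#' For every gene, the chosen dispersion metric is computed across
#' each patient's tumor regions (patients with fewer than two regions
#' are skipped) and averaged over the eligible patients.  SD uses the
#' n-1 denominator; MAD uses the 1.4826 normal-consistency constant;
#' CV is SD/mean and is returned as `NA` for any gene whose relevant
#' mean is within 1e-8 of zero.
#'
#' @param cohort A tumor-only [multiregion_cohort()] (call
#'   [subset_tumor()] first) with at least one patient having >= 2
#'   regions.
#' @param metric `"SD"` (default), `"MAD"`, or `"CV"`.
#' @return Named numeric vector of per-gene scores (>= 0).
#' @export
intra_heterogeneity <- function(cohort, metric = c("SD", "MAD", "CV")) {
  metric <- match.arg(metric)
  assert_tumor_only(cohort, "intra_heterogeneity")
  expr <- cohort$expression
  by_pat <- split(seq_len(ncol(expr)), cohort$samples$patient_id)
  by_pat <- by_pat[lengths(by_pat) >= 2]
  if (!length(by_pat))
    stop("no patient has >= 2 tumor regions", call. = FALSE)
  disp <- vapply(by_pat,
                 function(cols) row_dispersion(expr[, cols, drop = FALSE],
                                               metric),
                 numeric(nrow(expr)))
  if (nrow(expr) == 1L) disp <- matrix(disp, nrow = 1L)
  stats::setNames(rowMeans(disp), rownames(expr))
}

#' Per-gene intertumor heterogeneity
#'
#' Per repetition, one tumor region is drawn uniformly at random per
#' patient (the same draw for all genes) and the dispersion metric is
#' computed across the selected per-patient values; the returned score
#' is the mean over `n_reps` repetitions.  With a fixed seed the
#' result is bit-reproducible.  `method = "exhaustive"` replaces the
#' random draws with the exact average over every possible combination
#' of region choices (only feasible for small cohorts; guarded at 1e5
#' combinations).
#'
#' @inheritParams intra_heterogeneity
#' @param n_reps Number of random-selection repetitions (>= 1).
#' @param seed Integer seed for the region draws.
#' @param method `"sample"` (the 10-repetition protocol) or
#'   `"exhaustive"` (full enumeration).
#' @return Named numeric vector of per-gene scores.
#' @export
inter_heterogeneity <- function(cohort, metric = c("SD", "MAD", "CV"),
                                n_reps = 10, seed = 1,
                                method = c("sample", "exhaustive")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  assert_tumor_only(cohort, "inter_heterogeneity")
  expr <- cohort$expression
  by_pat <- split(seq_len(ncol(expr)), cohort$samples$patient_id)
  if (length(by_pat) < 2)
    stop("inter_heterogeneity() needs >= 2 patients", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)

  score_pick <- function(cols)
    row_dispersion(expr[, cols, drop = FALSE], metric)

  if (method == "exhaustive") {
    combos <- prod(lengths(by_pat))
    if (combos > 1e5)
      stop("exhaustive enumeration infeasible: ", combos,
           " region combinations", call. = FALSE)
    grid <- expand.grid(by_pat, KEEP.OUT.ATTRS = FALSE)
    acc <- 0
    for (i in seq_len(nrow(grid))) acc <- acc + score_pick(unlist(grid[i, ]))
    return(stats::setNames(acc / nrow(grid), rownames(expr)))
  }

  set.seed(seed)
  acc <- 0
  for (r in seq_len(n_reps)) {
    cols <- vapply(by_pat,
                   function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                   integer(1))
    acc <- acc + score_pick(cols)
  }
  stats::setNames(acc / n_reps, rownames(expr))
}

#' Partition genes into heterogeneity quadrants
#'
#' The thresholds are the arithmetic means of the two axes over all
#' genes with finite scores.  Quadrants follow the convention that the
#' x-axis is intertumor and the y-axis intratumor heterogeneity:
#' Q1 low inter / high intra, Q2 low/low, Q3 high/high, Q4 high inter /
#' low intra (the stable-within, variable-between candidate pool).
#' `>=` threshold counts as high on both axes, so a degenerate input
#' with identical scores lands entirely in Q3.
#'
#' @param intra,inter Named per-gene score vectors over the same gene
#'   universe (any order).
#' @param metric,n_reps,seed Provenance fields recorded on the result.
#' @return A `het_table`: `data.frame` with columns `gene`, `intra`,
#'   `inter`, `quadrant`, carrying the thresholds and provenance as
#'   attributes.  Genes with a missing score (e.g. the CV guard) get
#'   an `NA` quadrant and are excluded from the threshold means.
#' @export
assign_quadrants <- function(intra, inter, metric = "SD", n_reps = NA_integer_,
                             seed = NA_integer_) {
  if (is.null(names(intra)) || is.null(names(inter)))
    stop("intra and inter must be named by gene", call. = FALSE)
  if (!setequal(names(intra), names(inter)) ||
      length(intra) != length(inter))
    stop("intra and inter cover different gene universes", call. = FALSE)
  inter <- inter[names(intra)]
  thr_intra <- mean(intra[is.finite(intra)])
  thr_inter <- mean(inter[is.finite(inter)])
  hi_intra <- intra >= thr_intra
  hi_inter <- inter >= thr_inter
  quadrant <- ifelse(hi_inter,
                     ifelse(hi_intra, "Q3", "Q4"),
                     ifelse(hi_intra, "Q1", "Q2"))
  quadrant[!is.finite(intra) | !is.finite(inter)] <- NA_character_
  out <- data.frame(gene = names(intra), intra = unname(intra),
                    inter = unname(inter),
                    quadrant = factor(quadrant, levels = paste0("Q", 1:4)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("het_table", "data.frame"),
            thresholds = c(mean_intra = thr_intra, mean_inter = thr_inter),
            metric = metric, n_reps = n_reps, seed = seed)
}

#' One-call heterogeneity table for a cohort
#'
#' Convenience wrapper: intra score, inter score (random-region
#' protocol), and quadrant assignment with full provenance.
#'
#' @inheritParams inter_heterogeneity
#' @param expressed_only Drop genes with zero variance across the
#'   tumor samples before scoring (default `TRUE`); such genes carry
#'   no heterogeneity information on either axis.
#' @param min_expression_quantile Optional extra pre-filter: drop
#'   genes whose mean expression falls below this cohort quantile
#'   (default `NULL`, off).
#' @return A `het_table` (see [assign_quadrants()]).
#' @export
heterogeneity_table <- function(cohort, metric = c("SD", "MAD", "CV"),
                                n_reps = 10, seed = 1,
                                expressed_only = TRUE,
                                min_expression_quantile = NULL) {
  metric <- match.arg(metric)
  assert_tumor_only(cohort, "heterogeneity_table")
  keep <- rep(TRUE, n_genes(cohort))
  if (expressed_only) {
    v <- row_sds(cohort$expression)
    keep <- keep & v > 0
  }
  if (!is.null(min_expression_quantile)) {
    mu <- rowMeans(cohort$expression)
    keep <- keep & mu >= stats::quantile(mu, min_expression_quantile)
  }
  if (!any(keep)) stop("no gene passes the expression filter", call. = FALSE)
  sub <- multiregion_cohort(cohort$expression[keep, , drop = FALSE],
                            cohort$samples, cohort$survival)
  assign_quadrants(intra_heterogeneity(sub, metric),
                   inter_heterogeneity(sub, metric, n_reps = n_reps,
                                       seed = seed),
                   metric = metric, n_reps = n_reps, seed = seed)
}

#' @export
print.het_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat("het_table: ", nrow(x), " genes | metric ", attr(x, "metric"),
      " | thresholds intra ", signif(thr[["mean_intra"]], 4),
      ", inter ", signif(thr[["mean_inter"]], 4), "\n", sep = "")
  print(table(quadrant = x$quadrant, useNA = "ifany"))
  invisible(x)
}

#' Agreement between dispersion metrics
#'
#' Pearson correlation (with test p-value) between the per-gene
#' intratumor scores computed under SD, MAD, and CV.  High agreement
#' indicates the absence of influential outliers and supports SD as
#' the working metric.
#'
#' @inheritParams intra_heterogeneity
#' @return `data.frame` with one row per metric pair: `metric_a`,
#'   `metric_b`, `r`, `p`, `n` (genes with both scores finite).
#' @export
metric_agreement <- function(cohort) {
  assert_tumor_only(cohort, "metric_agreement")
  if (n_genes(cohort) < 3)
    stop("metric_agreement() needs >= 3 genes", call. = FALSE)
  scores <- list(SD = intra_heterogeneity(cohort, "SD"),
                 MAD = intra_heterogeneity(cohort, "MAD"),
                 CV = intra_heterogeneity(cohort, "CV"))
  pairs <- list(c("SD", "MAD"), c("SD", "CV"), c("MAD", "CV"))
  rows <- lapply(pairs, function(pp) {
    a <- scores[[pp[1]]]; b <- scores[[pp[2]]]
    ok <- is.finite(a) & is.finite(b)
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    data.frame(metric_a = pp[1], metric_b = pp[2],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quadrant enrichment of a gene set
#'
#' Compares the quadrant composition of a query gene set against the
#' quadrant shares of the whole scored universe, e.g. to ask whether
#' previously published signature genes over-represent the
#' stable-within / variable-between quadrant.
#'
#' @param table A `het_table` from [assign_quadrants()].
#' @param genes Character vector of query genes.  Genes outside the
#'   table's universe are dropped with a warning; an empty
#'   intersection is an error.
#' @return `data.frame` per quadrant: `observed_frac` (share of the
#'   query), `expected_frac` (share of the universe), `fold`
#'   (observed/expected; `NA` where the universe share is zero), and
#'   the underlying counts.  The number of dropped query genes is
#'   attached as attribute `"n_dropped"`.
#' @export
quadrant_enrichment <- function(table, genes) {
  stopifnot(inherits(table, "het_table"))
  genes <- unique(as.character(genes))
  hit <- genes %in% table$gene
  if (sum(!hit))
    warning(sum(!hit), " query gene(s) not in the scored universe; dropped",
            call. = FALSE)
  genes <- genes[hit]
  if (!length(genes))
    stop("no query gene overlaps the scored universe", call. = FALSE)
  universe <- table$quadrant[!is.na(table$quadrant)]
  qgenes <- table$quadrant[match(genes, table$gene)]
  qgenes <- qgenes[!is.na(qgenes)]
  exp_n <- table(universe)
  obs_n <- table(qgenes)
  expected <- as.numeric(exp_n) / length(universe)
  observed <- as.numeric(obs_n) / length(qgenes)
  fold <- ifelse(expected > 0, observed / expected, NA_real_)
  out <- data.frame(quadrant = names(exp_n),
                    observed_n = as.integer(obs_n),
                    universe_n = as.integer(exp_n),
                    observed_frac = observed, expected_frac = expected,
                    fold = fold, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!hit)
  out
}
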