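#' Reliability of a nodal metric under subsampling
#'
#' Classical-test-theory reliability `R = sigma_T^2 / (sigma_T^2 +
#' sigma_E^2)`. The error variance `sigma_E^2` is the variance of the
#' subsampled metric across iterations, averaged across electrode contacts
#' (each contact contributes the variance over only the iterations in which
#' it was retained); the true-score variance `sigma_T^2` is the variance of
#' the subsampled metric across the retained contacts within an iteration,
#' averaged over iterations. `R = 1` means no variance is attributable to
#' subsampling; `R = 0.5` means subsampling noise equals the true metric
#' variance. Variances use the unbiased `n - 1` denominator.
#'
#' @param values Iterations x contacts numeric matrix of subsampled nodal
#'   metric values, `NA` where a contact was removed (the output of
#'   [ensemble_metric()] for a nodal metric). Contacts retained in fewer
#'   than 2 iterations are excluded from the error-variance average with a
#'   warning.
#' @param metric Optional metric name carried into the report.
#' @param removal_fraction Optional removal fraction carried into the
#'   report.
#' @return A list of class `reliability_report`: `metric`,
#'   `removal_fraction`, `R`, `var_true`, `var_error`, `n_iter`.
#' @export
reliability_nodal <- function(values, metric = NA_character_,
                              removal_fraction = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 iterations")
  n_ok <- colSums(!is.na(values))
  usable <- n_ok >= 2
  if (!any(usable)) stop("no contact retained in at least 2 iterations")
  if (any(!usable))
    warning(sum(!usable),
            " contact(s) retained in fewer than 2 iterations excluded from the error variance")
  var_error <- mean(apply(values[, usable, drop = FALSE], 2,
                          stats::var, na.rm = TRUE))
  row_vars <- apply(values, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::var(v)
  })
  var_true <- mean(row_vars, na.rm = TRUE)
  reliability_report(var_true, var_error, metric, removal_fraction,
                     n_iter = nrow(values))
}

#' Reliability of a global metric across a cohort
#'
#' For global metrics the true-score variance is taken across patients
#' (averaged over iterations) and the error variance across iterations
#' (averaged over patients), so the reliability compares subsampling noise
#' with genuine between-patient differences.
#'
#' @param values Patients x iterations numeric matrix of subsampled global
#'   metric values (rows from [ensemble_metric()] per patient).
#' @param metric,removal_fraction Optional annotations for the report.
#' @return A `reliability_report` (see [reliability_nodal()]).
#' @export
reliability_global <- function(values, metric = NA_character_,
                               removal_fraction = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 patients and 2 iterations")
  var_error <- mean(apply(values, 1, stats::var, na.rm = TRUE))
  var_true <- mean(apply(values, 2, stats::var, na.rm = TRUE))
  reliability_report(var_true, var_error, metric, removal_fraction,
                     n_iter = ncol(values))
}

reliability_report <- function(var_true, var_error, metric,
                               removal_fraction, n_iter) {
  total <- var_true + var_error
  if (!is.finite(total) || total <= 0)
    stop("reliability undefined: total variance is zero")
  structure(list(metric = metric, removal_fraction = removal_fraction,
                 R = var_true / total, var_true = var_true,
                 var_error = var_error, n_iter = n_iter),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s: R = %.4f (var_true %.4g, var_error %.4g, %d iterations)\n",
              ifelse(is.na(x$metric), "metric", x$metric),
              x$R, x$var_true, x$var_error, x$n_iter))
  invisible(x)
}

#' Rank stability of a nodal metric
#'
#' Mean Spearman rank correlation between the original nodal metric vector
#' and each subsampled vector, each comparison restricted to that
#' iteration's retained contacts. Iterations with an undefined correlation
#' (constant vector) are excluded with a warning and counted.
#'
#' @param original Named numeric vector of the metric on the full network.
#' @param values Iterations x contacts matrix as in [reliability_nodal()].
#' @return List with `mean_rho`, `rho` (per iteration, `NA` where dropped),
#'   `n_dropped`.
#' @export
rank_stability <- function(original, values) {
  values <- as.matrix(values)
  if (ncol(values) != length(original))
    stop("original vector and ensemble matrix contact counts differ")
  rho <- apply(values, 1, function(v) {
    keep <- !is.na(v)
    if (sum(keep) < 3) return(NA_real_)
    suppressWarnings(stats::cor(original[keep], v[keep],
                                method = "spearman"))
  })
  n_dropped <- sum(is.na(rho))
  if (n_dropped)
    warning(n_dropped,
            " iteration(s) with undefined rank correlation excluded")
  list(mean_rho = mean(rho, na.rm = TRUE), rho = rho,
       n_dropped = n_dropped)
}

#' Agreement between original and subsampled metrics
#'
#' For nodal metrics, agreement is the Spearman rank correlation between the
#' original and subsampled values over the retained contacts (`a` in
#' `[-1, 1]`). For global metrics, it is the negative absolute relative
#' difference `a = -|(m_new - m_old)/m_old|` (`a <= 0`, equal to 0 exactly
#' at perfect agreement).
#'
#' @param original Full-network metric: a named vector (nodal) or scalar
#'   (global, nonzero).
#' @param subsampled Subsampled metric: a vector on the retained contacts
#'   (nodal) or scalar (global).
#' @param metric_class `"nodal"` or `"global"`.
#' @param retained For nodal metrics, the retained contact indices or
#'   labels aligning `subsampled` with `original`; defaults to the names of
#'   `subsampled`.
#' @return Scalar agreement `a`.
#' @export
agreement <- function(original, subsampled,
                      metric_class = c("nodal", "global"),
                      retained = NULL) {
  metric_class <- match.arg(metric_class)
  if (metric_class == "global") {
    if (length(original) != 1 || length(subsampled) != 1)
      stop("global agreement expects scalar metric values")
    if (original == 0) stop("global agreement undefined: original metric is 0")
    return(-abs((subsampled - original) / original) + 0)  # avoid IEEE -0
  }
  if (is.null(retained)) retained <- names(subsampled)
  if (is.null(retained)) stop("retained contacts required for nodal agreement")
  orig <- if (is.character(retained)) original[retained]
          else original[as.integer(retained)]
  if (length(orig) < 3 || length(orig) != length(subsampled))
    stop("nodal agreement needs at least 3 aligned contacts")
  suppressWarnings(stats::cor(as.numeric(orig), as.numeric(subsampled),
                              method = "spearman"))
}

#' Distance-agreement association
#'
#' Spearman rank correlation between contiguous-removal agreement values and
#' the centroid distance of each removed patch from the seizure onset zone,
#' plus its Fisher transformation `z = atanh(rho)` for cohort-level
#' aggregation.
#'
#' @param distance_mm Numeric vector of centroid distances
#'   ([centroid_distance()] per removal set).
#' @param a Numeric vector of agreement values, same length (at least 4).
#' @return List with `rho` and `z`.
#' @export
distance_agreement_association <- function(distance_mm, a) {
  if (length(distance_mm) != length(a) || length(a) < 4)
    stop("need at least 4 paired (distance, agreement) records")
  rho <- suppressWarnings(stats::cor(distance_mm, a, method = "spearman"))
  if (is.na(rho)) stop("rank correlation undefined (constant input)")
  if (abs(rho) >= 1 - 1e-12)
    stop("Fisher transformation infinite at |rho| = 1")
  list(rho = rho, z = atanh(rho))
}

#' Targeted versus sparing seizure-onset-zone comparison
#'
#' Compares the agreement under SOZ-targeted removal with the distribution
#' of agreements under SOZ-sparing removal: the mean sparing agreement, the
#' difference (mean sparing minus targeted), and the fraction of sparing
#' agreements strictly greater than the targeted agreement (the percentile
#' used for the cohort null of 50%).
#'
#' @param targeted Scalar agreement from the SOZ-targeted subsample.
#' @param sparing Numeric vector of agreements from the SOZ-sparing
#'   ensemble (nonempty).
#' @return List with `mean_sparing_a`, `diff`, `percentile`.
#' @export
soz_comparison <- function(targeted, sparing) {
  if (!length(sparing)) stop("sparing ensemble is empty")
  m <- mean(sparing)
  list(mean_sparing_a = m, diff = m - targeted,
       percentile = mean(sparing > targeted))
}

#' Signed relative difference of a global metric
#'
#' `(m_new - m_old)/m_old` with the sign preserved — unlike the agreement
#' measure, which is unsigned — so the direction of a perturbation (e.g.
#' whether onset-zone removal increases transitivity) is visible.
#'
#' @param original Original (nonzero) global metric value.
#' @param subsampled Subsampled global metric value.
#' @return Signed relative difference.
#' @export
signed_relative_difference <- function(original, subsampled) {
  if (original == 0) stop("relative difference undefined: original is 0")
  (subsampled - original) / original
}

#' Cohort-level metric comparison (Friedman + Dunn-Sidak)
#'
#' Friedman test across metrics blocked by patient, followed — when
#' significant at `alpha` — by all pairwise Dunn-Sidak post hoc
#' comparisons of mean ranks (normal approximation with Sidak-adjusted
#' p-values).
#'
#' @param values Patients x metrics numeric matrix (no missing cells), e.g.
#'   per-patient reliabilities; at least 3 patients and 2 metrics.
#' @param alpha Family-wise significance level.
#' @return List with `chisq`, `df`, `p`, `sidak_alpha` (per-comparison
#'   threshold `1 - (1 - alpha)^(1/m)`), and `posthoc` (data.frame of
#'   pairwise comparisons, or `NULL` when the Friedman test is not
#'   significant).
#' @export
cohort_metric_comparison <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in the patients x metrics table")
  if (nrow(values) < 3) stop("need at least 3 patients")
  k <- ncol(values)
  if (k < 2) stop("need at least 2 metrics")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("metric", seq_len(k))
  ft <- stats::friedman.test(values)
  n <- nrow(values)
  m <- choose(k, 2)
  sidak_alpha <- 1 - (1 - alpha)^(1 / m)
  posthoc <- NULL
  if (ft$p.value < alpha) {
    ranks <- t(apply(values, 1, rank))
    mean_ranks <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(k, 2)
    posthoc <- data.frame(
      metric_1 = colnames(values)[pairs[1, ]],
      metric_2 = colnames(values)[pairs[2, ]],
      z = (mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]) / se,
      stringsAsFactors = FALSE)
    p_raw <- 2 * stats::pnorm(-abs(posthoc$z))
    posthoc$p_sidak <- 1 - (1 - p_raw)^m
    posthoc$significant <- posthoc$p_sidak < alpha
  }
  list(chisq = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, sidak_alpha = sidak_alpha, posthoc = posthoc)
}

#' Bonferroni-corrected significance level
#'
#' @param family_alpha Family-wise significance level.
#' @param n_tests Number of tests in the family (at least 1).
#' @return Per-test alpha `family_alpha / n_tests` (e.g. 0.05/8 = 0.00625
#'   for the eight network metrics).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests) {
  check_count(n_tests, "n_tests")
  if (n_tests < 1) stop("n_tests must be at least 1")
  family_alpha / n_tests
}

#' Association between network size and reliability
#'
#' Spearman rank correlation across patients between the original contact
#' count and the per-patient reliability of a metric.
#'
#' @param n_contacts Integer vector of per-patient contact counts (at least
#'   4 patients).
#' @param R Numeric vector of per-patient reliabilities, same length.
#' @return List with `rho` and `p` (two-sided).
#' @export
size_reliability_association <- function(n_contacts, R) {
  if (length(n_contacts) != length(R) || length(R) < 4)
    stop("need at least 4 paired (contact count, reliability) records")
  if (stats::sd(n_contacts) == 0 || stats::sd(R) == 0)
    stop("rank correlation undefined (constant input)")
  ct <- suppressWarnings(
    stats::cor.test(n_contacts, R, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
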