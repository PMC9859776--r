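#' Variance homogeneity check between two replicate samples
#'
#' Two-sided F-test on the variance ratio (as in [stats::var.test()]):
#' the samples are declared homogeneous when the p-value is at least
#' `alpha`. Degenerate cases are decided, not errored: identical samples
#' (or both variances zero) are homogeneous; exactly one zero variance is
#' treated as maximally inhomogeneous (p = 0).
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param alpha significance level for the homogeneity decision.
#' @return `TRUE` if variances are homogeneous.
#' @export
variance_check <- function(x, y, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L)
    stop("variance_check needs >= 2 observations per sample")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) return(TRUE)
  if (vx == 0 || vy == 0) return(FALSE)
  var.test(x, y)$p.value >= alpha
}

#' Replicate-wise 13C-enrichment test for one feature
#'
#' Compares a feature's read proportions between 12C and 13C replicate
#' libraries: Student's pooled-variance t-test when [variance_check()]
#' passes, Welch's t-test (Welch-Satterthwaite degrees of freedom)
#' otherwise, two-sided by default. The feature is called enriched when the
#' p-value is below `alpha` AND the 13C mean exceeds the 12C mean — the
#' significance is directional even though the test is two-sided. No
#' multiple-testing correction is applied here; see [soil_differential()]
#' and the pipeline's `p_adjust` switch for Benjamini-Hochberg.
#'
#' Degenerate inputs are decided: when both groups are constant and equal,
#' t = 0 and p = 1; when both are constant but different, t is signed
#' infinite and p = 0.
#'
#' @param x_12c,x_13c proportions in the 12C and 13C replicate libraries.
#' @param alpha significance level.
#' @param alternative `"two.sided"` (default) or `"greater"` (13C > 12C).
#' @param var_alpha significance level of the variance homogeneity F-test.
#' @return a one-row data.frame: `mean_12C`, `mean_13C`, `var_12C`,
#'   `var_13C`, `variance_homogeneous`, `test_used`, `t_stat`, `df`,
#'   `p_value`, `enriched`.
#' @export
#' @examples
#' enrichment_test(c(0.010, 0.012, 0.011), c(0.030, 0.028, 0.032))
enrichment_test <- function(x_12c, x_13c, alpha = 0.05,
                            alternative = c("two.sided", "greater"),
                            var_alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(x_12c) < 2L || length(x_13c) < 2L)
    stop("enrichment_test needs >= 2 replicates per treatment")
  homog <- variance_check(x_12c, x_13c, var_alpha)
  m1 <- mean(x_12c); m2 <- mean(x_13c)
  v1 <- var(x_12c); v2 <- var(x_13c)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) { t_stat <- 0; p <- 1; df <- NA_real_ }
    else { t_stat <- sign(m2 - m1) * Inf; p <- 0; df <- NA_real_ }
  } else {
    tt <- t.test(x_13c, x_12c, var.equal = homog,
                 alternative = if (alternative == "greater") "greater"
                               else "two.sided")
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  data.frame(
    mean_12C = m1, mean_13C = m2, var_12C = v1, var_13C = v2,
    variance_homogeneous = homog,
    test_used = if (homog) "student" else "welch",
    t_stat = t_stat, df = df, p_value = p,
    enriched = (p < alpha) && (m2 > m1),
    stringsAsFactors = FALSE)
}

#' Enrichment tests across a feature table
#'
#' Applies [enrichment_test()] to each row of two replicate proportion
#' matrices (features x replicates), with optional Benjamini-Hochberg
#' adjustment of the p-values before the enrichment decision.
#'
#' @param p_12c,p_13c numeric matrices, features x replicates, equal
#'   rownames.
#' @param alpha,alternative,var_alpha as in [enrichment_test()].
#' @param p_adjust `"none"` (default, matching the replicate-wise
#'   per-feature testing) or `"BH"`.
#' @return data.frame with one row per feature (`feature_id` first).
#' @export
enrichment_table <- function(p_12c, p_13c, alpha = 0.05,
                             alternative = "two.sided", var_alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(identical(rownames(p_12c), rownames(p_13c)))
  rows <- lapply(rownames(p_12c), function(f)
    enrichment_test(p_12c[f, ], p_13c[f, ], alpha, alternative, var_alpha))
  out <- do.call(rbind, rows)
  out <- data.frame(feature_id = rownames(p_12c), out,
                    stringsAsFactors = FALSE)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_adjusted < alpha & out$mean_13C > out$mean_12C
  }
  rownames(out) <- NULL
  out
}

#' Between-soil differential relative abundance on LBD libraries
#'
#' The same test machinery as [enrichment_test()] applied to each feature's
#' proportions in pH 4.5 vs pH 7.5 LBD libraries. Each feature is labeled
#' with the soil it is significantly more relatively abundant in, or `"ns"`.
#'
#' @param p_soil_a,p_soil_b proportion matrices (features x replicates) for
#'   the two soils, equal rownames.
#' @param soil_a,soil_b soil labels used in the output.
#' @param alpha,var_alpha significance levels.
#' @return data.frame: `feature_id`, means/variances per soil, `test_used`,
#'   `p_value`, `label` in `{soil_a, soil_b, "ns"}`.
#' @export
soil_differential <- function(p_soil_a, p_soil_b, soil_a = "pH4.5",
                              soil_b = "pH7.5", alpha = 0.05,
                              var_alpha = 0.05) {
  stopifnot(identical(rownames(p_soil_a), rownames(p_soil_b)))
  rows <- lapply(rownames(p_soil_a), function(f) {
    r <- enrichment_test(p_soil_a[f, ], p_soil_b[f, ], alpha,
                         var_alpha = var_alpha)
    label <- if (r$p_value < alpha) {
      if (r$mean_13C > r$mean_12C) soil_b else soil_a
    } else "ns"
    data.frame(feature_id = f,
               mean_a = r$mean_12C, mean_b = r$mean_13C,
               var_a = r$var_12C, var_b = r$var_13C,
               test_used = r$test_used, p_value = r$p_value, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", soil_a)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", soil_b)
  names(out)[names(out) == "var_a"] <- paste0("var_", soil_a)
  names(out)[names(out) == "var_b"] <- paste0("var_", soil_b)
  rownames(out) <- NULL
  out
}

#' ln(reads per kb) heatmap matrix over vOTUs and libraries
#'
#' Entry (v, l) is `ln(mapped_read_count / (contig_length / 1000))` for the
#' vOTU's contig in library l. Entries with zero reads or failing the
#' detection filters (mean depth >= `min_depth`, breadth >= `min_breadth`)
#' are masked (NA), never imputed: ln(0) cannot appear, and masking mirrors
#' an inclusion rule that already excludes low-evidence entries.
#'
#' @param mappings list of `sip_mapping`, one per library.
#' @param votus a `sip_votus` table.
#' @param min_depth,min_breadth detection filters.
#' @return class `sip_heatmap`: list with `values` (vOTU x library matrix,
#'   NA where masked) and `mask` (logical matrix, TRUE = masked).
#' @export
heatmap_matrix <- function(mappings, votus, min_depth = 1,
                           min_breadth = 0.75) {
  if (inherits(mappings, "sip_mapping")) mappings <- list(mappings)
  lib_ids <- vapply(mappings, function(m) m$library_id[1] %||% NA_character_, "")
  values <- matrix(NA_real_, NROW(votus), length(mappings),
                   dimnames = list(votus$contig_id, lib_ids))
  mask <- matrix(TRUE, NROW(votus), length(mappings),
                 dimnames = dimnames(values))
  for (j in seq_along(mappings)) {
    m <- mappings[[j]]
    idx <- match(votus$contig_id, m$contig_id)
    cnt <- m$mapped_read_count[idx]
    ok <- !is.na(idx) & cnt > 0 & m$mean_depth[idx] >= min_depth &
      m$breadth[idx] >= min_breadth
    values[ok, j] <- log(cnt[ok] / (votus$length[ok] / 1000))
    mask[, j] <- !ok
  }
  structure(list(values = values, mask = mask), class = "sip_heatmap")
}
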