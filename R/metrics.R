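#' Dice similarity coefficient between two binary masks
#'
#' \deqn{DSC = 2 |A \cap B| / (|A| + |B|)}: 1 means perfect agreement, 0
#' no overlap. Two empty masks score 1 (vacuous agreement); exactly one
#' empty mask scores 0.
#'
#' @param mask,truth `binary_mask` objects (or 3-D logical arrays) on the
#'   same grid
#' @return numeric in [0, 1]
#' @export
dsc <- function(mask, truth) {
  a <- if (inherits(mask, "binary_mask")) mask$mask else mask
  b <- if (inherits(truth, "binary_mask")) truth$mask else truth
  if (!all(dim(a) == dim(b))) stop("masks are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Summarize volume-estimation records per gland volume group
#'
#' For each gland volume group (and a pooled row spanning all volumes),
#' computes the mean absolute error of the relative volumes in percent
#' \eqn{MAE = 100 \cdot \frac{1}{N}\sum |\hat V_i / V_i - 1|}, the mean
#' relative volume \eqn{MRV = \bar V = \frac{1}{N}\sum \hat V_i / V_i},
#' and the sample standard deviation of the relative volumes
#' \eqn{S = \sqrt{\frac{1}{N-1}\sum (\hat V_i / V_i - \bar V)^2}}.
#'
#' @param records data.frame with columns `method`, `volume_ml`
#'   (true volume group), `est_volume_ml`
#' @return data.frame with columns `method`, `group`, `n`, `mae_pct`,
#'   `mrv`, `sd`
#' @export
summarize_records <- function(records) {
  stopifnot(all(c("method", "volume_ml", "est_volume_ml") %in% names(records)))
  rel <- records$est_volume_ml / records$volume_ml
  one <- function(idx, method, group) {
    if (length(idx) < 2) stop("need at least 2 records per group")
    r <- rel[idx]
    data.frame(method = method, group = group, n = length(idx),
               mae_pct = 100 * mean(abs(r - 1)), mrv = mean(r),
               sd = stats::sd(r))
  }
  out <- list()
  vols <- sort(unique(records$volume_ml))
  for (m in unique(records$method)) {
    for (v in vols) {
      idx <- which(records$method == m & records$volume_ml == v)
      out[[length(out) + 1L]] <- one(idx, m, format(v))
    }
    idx <- which(records$method == m)
    out[[length(out) + 1L]] <-
      one(idx, m, paste(min(vols), max(vols), sep = "-"))
  }
  do.call(rbind, out)
}

#' Paired t-test on per-case DSC values of two methods
#'
#' Classical paired t-test on the case-wise differences, two-sided p-value
#' from the t distribution with N - 1 degrees of freedom. Degenerate
#' inputs are handled explicitly: all differences zero gives t = 0, p = 1;
#' zero variance with a nonzero mean gives p = 0 with a warning.
#'
#' @param dsc_a,dsc_b equal-length numeric vectors paired by case
#' @return list with `t`, `p`, `df`, `mean_diff` (a - b)
#' @export
paired_t <- function(dsc_a, dsc_b) {
  stopifnot(length(dsc_a) == length(dsc_b), length(dsc_a) >= 2)
  d <- dsc_a - dsc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1L,
                                  mean_diff = 0))
    warning("zero variance of differences with nonzero mean; p = 0")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(dsc_a, dsc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

#' Misclassification projections along an anatomical axis
#'
#' Sums missed object voxels (in truth but not in the mask) and false
#' positives (in the mask but not in truth) along the chosen axis,
#' producing the two 2-D count maps used to display the spatial
#' distribution of segmentation errors. The default axis is
#' anterior-posterior (the y axis, axis 2 of the (z, y, x) grid).
#'
#' @param mask,truth `binary_mask` objects (or logical arrays) on the
#'   same grid
#' @param axis axis to sum along: 1 (z), 2 (y, default), 3 (x)
#' @return list with integer matrices `missed` and `false_positive`
#' @export
misclass_projection <- function(mask, truth, axis = 2L) {
  a <- if (inherits(mask, "binary_mask")) mask$mask else mask
  b <- if (inherits(truth, "binary_mask")) truth$mask else truth
  if (!all(dim(a) == dim(b))) stop("masks are on different grids")
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  keep <- setdiff(1:3, axis)
  list(missed = apply(b & !a, keep, sum),
       false_positive = apply(a & !b, keep, sum))
}
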