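# BraTS-protocol evaluation: nested region masks, Dice similarity, 95th
# percentile Hausdorff surface distance, the enhancing-tumor special-case
# rule and special-value removal during aggregation.

#' Extract the three nested evaluation regions
#'
#' Labels use the remapped coding 0 = background, 1 = necrotic/non-enhancing
#' core, 2 = peritumoral edema, 3 = enhancing tumor.  The regions are
#' whole tumor WT = \{1,2,3\}, tumor core TC = \{1,3\} and enhancing tumor
#' ET = \{3\}; by construction ET is a subset of TC is a subset of WT.
#'
#' @param labels integer matrix/array with values in 0:3.
#' @return list of logical masks `et`, `tc`, `wt`.
#' @export
extract_regions <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("labels outside 0:3: ", paste(bad, collapse = ", "))
  list(et = labels == 3L, tc = labels == 1L | labels == 3L, wt = labels >= 1L)
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)` between two binary masks.  When both masks are
#' empty the score is defined as 1 (perfect agreement on absence).
#'
#' @param pred,gt logical (or 0/1) masks of identical shape.
#' @export
dsc <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  pred <- as.logical(pred); gt <- as.logical(gt)
  tp <- sum(pred & gt)
  den <- 2 * tp + sum(pred & !gt) + sum(!pred & gt)
  if (den == 0) 1 else 2 * tp / den
}

mask_boundary <- function(m) {
  # set pixels with at least one unset 4-neighbor (image border counts)
  d <- dim(m)
  up <- rbind(FALSE, m[-d[1], , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -d[2], drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

directed_p95 <- function(a, b) {
  # a, b: n x 2 coordinate matrices (already scaled by spacing)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  mins <- sqrt(apply(d2, 1, min))
  stats::quantile(mins, 0.95, names = FALSE)
}

#' 95th percentile Hausdorff distance
#'
#' Boundary pixels (set pixels with an unset 4-neighbor) of the two masks
#' are compared with Euclidean distances; the 95th percentile of the
#' nearest-neighbor distances is taken in each direction and the two
#' directed values are combined by `max` (the default) or by pooling both
#' distance sets before taking the percentile.
#'
#' @param pred,gt binary masks of identical shape.
#' @param spacing pixel spacing (length 2).
#' @param method `"max"` or `"pooled"` symmetrization.
#' @return nonnegative distance, or `NA` with a `reason` attribute when a
#'   mask is empty.
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1), method = c("max", "pooled")) {
  method <- match.arg(method)
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  dm <- dim(pred)
  pred <- array(as.logical(pred), dm); gt <- array(as.logical(gt), dm)
  if (!any(pred) || !any(gt)) {
    out <- NA_real_
    attr(out, "reason") <- if (!any(gt)) "empty ground truth" else "empty prediction"
    return(out)
  }
  pa <- which(mask_boundary(pred), arr.ind = TRUE)
  ga <- which(mask_boundary(gt), arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, "*")
  ga <- sweep(ga, 2, spacing, "*")
  if (method == "max") {
    max(directed_p95(pa, ga), directed_p95(ga, pa))
  } else {
    d2 <- outer(pa[, 1], ga[, 1], "-")^2 + outer(pa[, 2], ga[, 2], "-")^2
    pooled <- c(sqrt(apply(d2, 1, min)), sqrt(apply(d2, 2, min)))
    stats::quantile(pooled, 0.95, names = FALSE)
  }
}

#' Score one predicted label map against the ground truth
#'
#' Per-region DSC and HD95 over the ET/TC/WT masks.  The enhancing-tumor
#' special rule: when the ground truth has no enhancing tumor, the ET Dice
#' is 0 if the prediction contains enhancing tumor and 1 if it does not,
#' and the value is flagged `special` so aggregation can remove it.
#'
#' @param pred_labels,gt_labels integer label maps (values 0:3), same shape.
#' @param case case identifier carried into the record.
#' @return data frame with one row per region: `case`, `region`, `dsc`,
#'   `hd95`, `special`, `hd95_reason`.
#' @export
score_case <- function(pred_labels, gt_labels, case = "case") {
  if (!identical(dim(pred_labels), dim(gt_labels))) stop("label shapes differ")
  pr <- extract_regions(pred_labels)
  gr <- extract_regions(gt_labels)
  rows <- lapply(c("et", "tc", "wt"), function(rg) {
    p <- pr[[rg]]; g <- gr[[rg]]
    special <- FALSE
    if (rg == "et" && !any(g)) {
      d <- if (any(p)) 0 else 1
      special <- TRUE
    } else {
      d <- dsc(p, g)
    }
    h <- hd95(p, g)
    data.frame(case = case, region = toupper(rg), dsc = d,
               hd95 = as.numeric(h), special = special,
               hd95_reason = if (is.na(h)) attr(h, "reason") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate evaluation records
#'
#' Special-flagged Dice values and undefined HD95 values are removed before
#' averaging; each region mean is computed over its remaining records and
#' the overall means are the arithmetic means of the three region means.
#' A region with no remaining values is reported as `NA`, never as 0.
#'
#' @param records data frame as produced by [score_case()] /
#'   [evaluate_network()] (rows from several cases concatenated).
#' @return list with `per_region` (data frame: region, mean_dsc, mean_hd95,
#'   n_dsc, n_hd95) and `overall` (mean_dsc, mean_hd95).
#' @export
aggregate_records <- function(records) {
  stopifnot(nrow(records) > 0)
  per <- lapply(c("ET", "TC", "WT"), function(rg) {
    r <- records[records$region == rg, , drop = FALSE]
    dv <- r$dsc[!r$special]
    hv <- r$hd95[!is.na(r$hd95)]
    data.frame(region = rg,
               mean_dsc = if (length(dv)) mean(dv) else NA_real_,
               mean_hd95 = if (length(hv)) mean(hv) else NA_real_,
               n_dsc = length(dv), n_hd95 = length(hv))
  })
  per <- do.call(rbind, per)
  list(per_region = per,
       overall = list(mean_dsc = mean(per$mean_dsc),
                      mean_hd95 = mean(per$mean_hd95)))
}
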