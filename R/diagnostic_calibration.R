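# ROC analysis of case-level smFISH scores against reference labels,
# parameter sweeps, and the nonparametric comparison statistics used
# throughout the package.

#' ROC curve over the fixed cutoff grid
#'
#' Sweeps 200 cutoffs t = 0.001, 0.002, ..., 0.200 dots/um^3.  At each
#' cutoff a case is called positive when `score >= t`, and
#' TP/FP/TN/FN, sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) are
#' tabulated against the reference labels.  Scores above 0.2 are therefore
#' called positive at every cutoff.
#'
#' @param scores Numeric case scores (dots/um^3).
#' @param labels Logical (or 0/1) reference labels, same length.
#' @param cutoffs Cutoff grid; default `(1:200) * 0.001`.
#' @return Object of class `roc_result`: list with `table` (data frame of
#'   t, TP, FP, TN, FN, sensitivity, specificity), `n_positive`,
#'   `n_negative`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels, cutoffs = (1:200) * 0.001) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels)) stop("no positive cases: ROC is undefined")
  if (all(labels)) stop("no negative cases: ROC is undefined")
  np <- sum(labels); nn <- sum(!labels)
  tp <- vapply(cutoffs, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(cutoffs, function(t) sum(scores >= t & !labels), numeric(1))
  tab <- data.frame(t = cutoffs, TP = tp, FP = fp, TN = nn - fp, FN = np - tp)
  tab$sensitivity <- tab$TP / (tab$TP + tab$FN)
  tab$specificity <- tab$TN / (tab$TN + tab$FP)
  structure(list(table = tab, n_positive = np, n_negative = nn,
                 scores = scores, labels = labels), class = "roc_result")
}

#' Area under the ROC curve
#'
#' `mode = "conventional"` (default) integrates the (1 - specificity,
#' sensitivity) polyline by the trapezoidal rule with (0,0) and (1,1)
#' appended, which is the AUC convention on a 0-1 scale (0.5 = chance).
#' `mode = "curve-minus-diagonal"` reports the area between the curve and
#' the chance diagonal instead, i.e. conventional minus 0.5.
#'
#' @param roc A [roc_curve()] result.
#' @param mode `"conventional"` or `"curve-minus-diagonal"`.
#' @return Scalar area.
#' @export
roc_auc <- function(roc, mode = c("conventional", "curve-minus-diagonal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(roc, "roc_result"))
  x <- c(0, 1 - roc$table$specificity, 1)
  y <- c(0, roc$table$sensitivity, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  a <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (mode == "curve-minus-diagonal") a - 0.5 else a
}

#' Best operating point of a ROC curve
#'
#' The cutoff whose (1 - specificity, sensitivity) point lies closest
#' (Euclidean) to the perfect-classification corner (0, 1); ties go to the
#' smallest cutoff.
#'
#' @param roc A [roc_curve()] result.
#' @return List: `t`, `sensitivity`, `specificity`, `distance`.
#' @export
best_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  tab <- roc$table
  d <- sqrt((1 - tab$specificity)^2 + (1 - tab$sensitivity)^2)
  i <- which.min(d)  # which.min takes the first minimum = smallest t
  list(t = tab$t[i], sensitivity = tab$sensitivity[i],
       specificity = tab$specificity[i], distance = d[i])
}

#' Sweep grid order (or dilation margin) and dot threshold over a cohort
#'
#' Recomputes every case's smFISH score and the resulting ROC AUC for each
#' parameter combination.  With `unit = "pseudocell"`, `axis1` holds grid
#' orders; with `unit = "cell"`, dilation margins in pixels (cells are
#' re-scored per margin, which is considerably slower).
#'
#' @param cohort A `sim_cohort` (or a list with `cases`, each having `fovs`).
#' @param labels Logical reference labels, one per case.
#' @param channel Channel to score.
#' @param axis1 Grid orders (default `c(9:14, 16)`) or margins.
#' @param thresholds Dot thresholds (default `0:3`).
#' @param unit `"pseudocell"` or `"cell"`.
#' @param auc_mode Passed to [roc_auc()].
#' @param policy Passed to [case_score()].
#' @return Matrix of AUCs (rows = `axis1`, cols = thresholds) with the best
#'   combination in attributes `best_axis1`, `best_threshold`, `best_auc`.
#' @export
parameter_sweep <- function(cohort, labels, channel = "HER2",
                            axis1 = c(9:14, 16), thresholds = 0:3,
                            unit = c("pseudocell", "cell"),
                            auc_mode = "conventional",
                            policy = "exclude") {
  unit <- match.arg(unit)
  out <- matrix(NA_real_, length(axis1), length(thresholds),
                dimnames = list(axis1, thresholds))
  for (a in seq_along(axis1)) {
    score_fun <- if (unit == "pseudocell") {
      function(case, thr) {
        grids <- lapply(case$fovs, function(f) {
          pseudocell_densities(grid_counts(f$spots, f$meta, g = axis1[a],
                                           channels = channel))
        })
        case_score(grids, channel, thr, policy)$score
      }
    } else {
      function(case, thr) {
        cells <- do.call(rbind, lapply(case$fovs, function(f) {
          score_cells(f$spots, f$outlines, f$meta, margin_px = axis1[a],
                      channels = channel)
        }))
        cell_case_score(cells, channel, thr, policy)$score
      }
    }
    for (th in seq_along(thresholds)) {
      scores <- vapply(cohort$cases, score_fun, numeric(1), thresholds[th])
      out[a, th] <- roc_auc(roc_curve(scores, labels), mode = auc_mode)
    }
  }
  best <- which(out == max(out), arr.ind = TRUE)[1, ]
  attr(out, "best_axis1") <- axis1[best[1]]
  attr(out, "best_threshold") <- thresholds[best[2]]
  attr(out, "best_auc") <- max(out)
  out
}

## exact two-sided Mann-Whitney P by complete enumeration of group
## assignments (handles ties; feasible for combined n <= 12)
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, u_of)
  p_low <- mean(u_all <= u_obs + 1e-9)
  p_high <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Two-tailed test of a location difference.  For combined sample sizes up
#' to 12 the P value is computed exactly by enumerating all group
#' assignments (valid under ties); larger samples use the tie-corrected
#' normal approximation (no continuity correction) via [stats::wilcox.test].
#'
#' @param a,b Numeric samples.
#' @return List: `U` (Mann-Whitney U of sample `a`), `p.value`, `method`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1, !anyNA(a), !anyNA(b))
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(a) + length(b) <= 12L) {
    list(U = u, p.value = mw_exact_p(a, b), method = "exact enumeration")
  } else {
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    list(U = u, p.value = w$p.value, method = "normal approximation")
  }
}

#' Spearman rank correlation with t-distribution P value
#'
#' rho is the Pearson correlation of mid-ranks; the two-tailed P value comes
#' from t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' Zero-variance input yields `rho = NA` with `flagged = TRUE`.
#'
#' @param x,y Numeric vectors (pairs with NA in either are dropped).
#' @return List: `rho`, `p.value`, `n`, `flagged`.
#' @export
rank_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p.value = NA_real_, n = n, flagged = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n, flagged = FALSE)
}
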