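#' Anderson-Darling test of normality
#'
#' Tests a sample against the normal family with mean and variance
#' estimated from the data. The statistic is
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)
#'   [\ln \Phi(z_{(i)}) + \ln(1 - \Phi(z_{(n+1-i)}))]}
#' with z the standardized order statistics. The p-value uses the
#' small-sample-adjusted statistic \eqn{A^{*2} = A^2 (1 + 0.75/n +
#' 2.25/n^2)} and the standard piecewise-exponential approximation for the
#' estimated-parameters case.
#'
#' @param x numeric sample, n >= 8, not constant.
#' @return List with \code{statistic} (A^2), \code{adjusted} (A*^2),
#'   \code{p_value}, \code{n}.
#' @export
anderson_darling <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("Anderson-Darling test needs n >= 8", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample", call. = FALSE)
  z <- sort((x - mean(x)) / stats::sd(x))
  logp <- stats::pnorm(z, log.p = TRUE)
  logq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  a2s <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a2s >= 0.6) exp(1.2937 - 5.709 * a2s + 0.0186 * a2s^2)
       else if (a2s >= 0.34) exp(0.9177 - 4.279 * a2s - 1.38 * a2s^2)
       else if (a2s > 0.2) 1 - exp(-8.318 + 42.796 * a2s - 59.938 * a2s^2)
       else 1 - exp(-13.436 + 101.14 * a2s - 223.73 * a2s^2)
  list(statistic = a2, adjusted = a2s, p_value = min(max(p, 0), 1), n = n)
}

#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with the one-tailed p-value in a
#' direction declared in advance: \code{"greater"} tests whether the mean
#' of \code{a} exceeds that of \code{b}, \code{"less"} the reverse.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param direction \code{"greater"} or \code{"less"}.
#' @return List with \code{t}, \code{df} (Welch-Satterthwaite),
#'   \code{p_value}, \code{direction}, group means.
#' @export
one_tailed_t <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both samples have zero variance", call. = FALSE)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (direction == "greater") stats::pt(tstat, df, lower.tail = FALSE)
       else stats::pt(tstat, df)
  list(t = tstat, df = df, p_value = p, direction = direction,
       mean_a = mean(a), mean_b = mean(b))
}

#' Cross-correlation between temporospatial and volumetric indices
#'
#' Pairwise Pearson coefficients between every temporospatial column and
#' every volumetric column of a cohort table. Constant columns give NA
#' entries and are reported.
#'
#' @param table data.frame of one row per subject.
#' @param temporospatial,volumetric column names for the two index
#'   families.
#' @return Numeric matrix (temporospatial x volumetric) of Pearson R, with
#'   attribute \code{flagged} naming constant columns.
#' @export
cross_correlation <- function(table,
                              temporospatial = c("periodicity", "coherence"),
                              volumetric = c("edv_ml", "esv_ml", "sv_ml",
                                             "ef_pct")) {
  temporospatial <- intersect(temporospatial, names(table))
  volumetric <- intersect(volumetric, names(table))
  keep <- stats::complete.cases(table[, c(temporospatial, volumetric)])
  if (sum(keep) < 3L) stop("need at least 3 complete rows", call. = FALSE)
  tab <- table[keep, ]
  flagged <- character(0)
  out <- matrix(NA_real_, length(temporospatial), length(volumetric),
                dimnames = list(temporospatial, volumetric))
  for (i in temporospatial) for (j in volumetric) {
    if (stats::sd(tab[[i]]) == 0 || stats::sd(tab[[j]]) == 0) {
      flagged <- union(flagged,
                       c(i, j)[c(stats::sd(tab[[i]]) == 0,
                                 stats::sd(tab[[j]]) == 0)])
    } else out[i, j] <- stats::cor(tab[[i]], tab[[j]])
  }
  attr(out, "flagged") <- flagged
  out
}

#' Summarize a cohort table and compare groups
#'
#' Per group and index: mean, SD, median, 25th/75th percentiles (type-7
#' quantiles: linear interpolation between order statistics) and the
#' Anderson-Darling normality check (when n >= 8). With exactly two
#' groups, a one-tailed Welch t-test per index in the declared direction
#' (first group vs second, \code{"greater"} by default: the reference
#' group is expected to score higher). Scatter-plot data for
#' (coherence, periodicity) and (esv_ml, ef_pct) are returned with group
#' labels.
#'
#' @param table data.frame with a group column and index columns.
#' @param group_col name of the group column.
#' @param indices index columns to summarize (defaults to those present).
#' @param direction one-tailed direction for group 1 vs group 2.
#' @param groups optional character vector fixing group order (group 1 is
#'   the reference arm of the t-test).
#' @return Object of class \code{cohort_summary}: list with
#'   \code{summaries} (data.frame), \code{tests} (data.frame or NULL),
#'   \code{scatter} (list of data.frames), \code{dropped_rows}.
#' @export
summarize_cohort <- function(table, group_col = "group",
                             indices = NULL,
                             direction = c("greater", "less"),
                             groups = NULL) {
  direction <- match.arg(direction)
  known <- c("periodicity", "coherence", "edv_ml", "esv_ml", "sv_ml",
             "ef_pct")
  if (is.null(indices)) indices <- intersect(known, names(table))
  if (!group_col %in% names(table))
    stop("no '", group_col, "' column", call. = FALSE)
  keep <- stats::complete.cases(table[, indices, drop = FALSE])
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " row(s) with missing index values dropped")
  tab <- table[keep, ]
  if (is.null(groups)) groups <- unique(as.character(tab[[group_col]]))

  summaries <- do.call(rbind, lapply(groups, function(g) {
    sub <- tab[tab[[group_col]] == g, ]
    do.call(rbind, lapply(indices, function(ix) {
      v <- sub[[ix]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      ad <- if (length(v) >= 8L && stats::sd(v) > 0) anderson_darling(v)
            else list(statistic = NA_real_, p_value = NA_real_)
      data.frame(group = g, index = ix, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 q25 = q[1], median = q[2], q75 = q[3],
                 ad_statistic = ad$statistic, ad_p = ad$p_value)
    }))
  }))

  tests <- NULL
  if (length(groups) == 2L) {
    tests <- do.call(rbind, lapply(indices, function(ix) {
      a <- tab[[ix]][tab[[group_col]] == groups[1]]
      b <- tab[[ix]][tab[[group_col]] == groups[2]]
      tt <- tryCatch(one_tailed_t(a, b, direction),
                     error = function(e) list(t = NA_real_, df = NA_real_,
                                              p_value = NA_real_))
      data.frame(index = ix, group_a = groups[1], group_b = groups[2],
                 t = tt$t, df = tt$df, p_value = tt$p_value,
                 direction = direction)
    }))
  }

  scatter <- list()
  if (all(c("coherence", "periodicity") %in% indices))
    scatter$temporospatial <- data.frame(group = tab[[group_col]],
                                         coherence = tab$coherence,
                                         periodicity = tab$periodicity)
  if (all(c("esv_ml", "ef_pct") %in% indices))
    scatter$volumetric <- data.frame(group = tab[[group_col]],
                                     esv_ml = tab$esv_ml,
                                     ef_pct = tab$ef_pct)

  structure(list(summaries = summaries, tests = tests, scatter = scatter,
                 dropped_rows = dropped, groups = groups),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> groups:", paste(x$groups, collapse = ", "), "\n")
  print(x$summaries, row.names = FALSE, digits = 4)
  if (!is.null(x$tests)) {
    cat("one-tailed Welch t-tests:\n")
    print(x$tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Exact linear separability of two labelled point sets in the plane
#'
#' Two finite point sets are linearly separable iff their convex hulls do
#' not intersect. Hull intersection is checked by edge-crossing and
#' point-in-polygon tests, so the result is exact up to floating point.
#'
#' @param xy two-column numeric matrix of coordinates.
#' @param group length-nrow factor/vector with exactly two levels.
#' @return TRUE if a separating line exists.
#' @export
linearly_separable <- function(xy, group) {
  xy <- as.matrix(xy)
  g <- as.character(group)
  lv <- unique(g)
  if (length(lv) != 2L) stop("need exactly two groups", call. = FALSE)
  a <- xy[g == lv[1], , drop = FALSE]
  b <- xy[g == lv[2], , drop = FALSE]
  hull <- function(p) p[grDevices::chull(p), , drop = FALSE]
  ha <- hull(a); hb <- hull(b)
  if (hulls_intersect(ha, hb)) return(FALSE)
  TRUE
}

# segment-crossing + containment test between two convex polygons
# (degenerate hulls of 1-2 points handled by the same predicates)
hulls_intersect <- function(pa, pb) {
  seg <- function(p) {
    n <- nrow(p)
    if (n == 1L) cbind(p, p) else cbind(p, p[c(2:n, 1), , drop = FALSE])
  }
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  on_seg <- function(p, q, r)
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
    min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
    d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
      (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
  }
  sa <- seg(pa); sb <- seg(pb)
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb)))
    if (seg_int(sa[i, 1:2], sa[i, 3:4], sb[j, 1:2], sb[j, 3:4]))
      return(TRUE)
  point_in <- function(pt, poly) {
    n <- nrow(poly)
    if (n < 3L) return(FALSE)
    sgn <- vapply(seq_len(n), function(i)
      cross(poly[i, ], poly[i %% n + 1L, ], pt), numeric(1))
    all(sgn >= 0) || all(sgn <= 0)
  }
  point_in(pa[1, ], pb) || point_in(pb[1, ], pa)
}
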