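#' Peak decoding performance of one participant
#'
#' The maximum of the fold-mean curve and its window-centre time; on ties
#' the earliest window wins. If a threshold is supplied the peak is flagged
#' significant when it lies strictly above it.
#'
#' @param trajectory a `DecodeTrajectory`.
#' @param threshold optional chance-level threshold (e.g. from
#'   [group_threshold()]).
#' @param participant_id,group_label metadata carried into the result.
#' @return one-row data.frame: `participant_id`, `group_label`,
#'   `max_score`, `peak_time` (seconds), `significant`.
#' @export
extract_peak <- function(trajectory, threshold = NA_real_,
                         participant_id = NA_character_,
                         group_label = NA_character_) {
  if (length(trajectory$mean_curve) == 0) stop("empty trajectory")
  i <- which.max(trajectory$mean_curve)
  data.frame(participant_id = participant_id, group_label = group_label,
             max_score = trajectory$mean_curve[i],
             peak_time = trajectory$window_centers[i],
             significant = if (is.na(threshold)) NA
               else trajectory$mean_curve[i] > threshold,
             stringsAsFactors = FALSE)
}

#' Choose the parametric or nonparametric analysis route
#'
#' Shapiro-Wilk per group at `alpha`; the parametric route is taken only
#' when every group passes (p > alpha). Groups with (near-)zero variance
#' cannot be normal and force the nonparametric route.
#'
#' @param values_by_group named list of numeric vectors (>= 3 values each).
#' @param alpha gate level, default 0.05.
#' @return list with `route` (`"parametric"` / `"nonparametric"`) and
#'   `p_values` (per group; `NA` for degenerate groups).
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  if (any(vapply(values_by_group, length, 1L) < 3))
    stop("every group needs at least 3 values")
  p <- vapply(values_by_group, function(v) {
    if (stats::sd(v) < .Machine$double.eps^0.5) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, 1.0)
  route <- if (all(!is.na(p)) && all(p > alpha)) "parametric"
    else "nonparametric"
  list(route = route, p_values = p)
}

# Dunn's z tests on mean ranks with tie correction; returns a data.frame.
dunn_test <- function(values_by_group) {
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 1L)),
              levels = names(values_by_group))
  v <- unlist(values_by_group, use.names = FALSE)
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1, k], levels(g)); j <- match(pairs[2, k], levels(g))
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    out$statistic[k] <- z
    out$p_raw[k] <- 2 * stats::pnorm(-abs(z))
  }
  out
}

#' Omnibus group comparison with post-hoc tests and FDR correction
#'
#' Parametric route: one-way ANOVA (`F` with `k - 1`, `N - k` df) followed
#' by all-pairs Welch t tests. Nonparametric route: Kruskal-Wallis
#' (tie-corrected `H`) followed by Dunn's z tests on mean ranks. Post-hoc
#' p-values are Benjamini-Hochberg adjusted within the family; post hocs
#' are only reported when the omnibus test is significant at `alpha`.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups).
#' @param route `"parametric"`, `"nonparametric"`, or `NULL` to decide via
#'   [normality_gate()].
#' @param alpha significance level, default 0.05.
#' @return A `GroupStatsResult`: list with `omnibus` (test, statistic,
#'   df, p), `posthoc` (data.frame with `p_raw`, `p_fdr`, or `NULL`),
#'   `normality_gate`.
#' @export
omnibus_and_posthoc <- function(values_by_group, route = NULL, alpha = 0.05) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(values_by_group, length, 1L) == 0)) stop("empty group")
  gate <- if (is.null(route)) normality_gate(values_by_group)
    else list(route = route, p_values = NULL)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 1L)),
              levels = names(values_by_group))
  v <- unlist(values_by_group, use.names = FALSE)
  if (gate$route == "parametric") {
    fit <- stats::anova(stats::lm(v ~ g))
    omnibus <- list(test = "anova", statistic = fit$`F value`[1],
                    df = c(fit$Df[1], fit$Df[2]), p = fit$`Pr(>F)`[1])
    pairs <- utils::combn(names(values_by_group), 2)
    posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          statistic = NA_real_, p_raw = NA_real_,
                          stringsAsFactors = FALSE)
    for (k in seq_len(ncol(pairs))) {
      tt <- stats::t.test(values_by_group[[pairs[1, k]]],
                          values_by_group[[pairs[2, k]]])
      posthoc$statistic[k] <- unname(tt$statistic)
      posthoc$p_raw[k] <- tt$p.value
    }
  } else {
    kw <- stats::kruskal.test(v, g)
    omnibus <- list(test = "kruskal", statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value)
    posthoc <- dunn_test(values_by_group)
  }
  posthoc$p_fdr <- fdr_adjust(posthoc$p_raw)
  if (!(omnibus$p < alpha)) posthoc <- NULL
  structure(list(omnibus = omnibus, posthoc = posthoc,
                 normality_gate = gate, alpha = alpha),
            class = "GroupStatsResult")
}

#' @export
print.GroupStatsResult <- function(x, ...) {
  o <- x$omnibus
  cat(sprintf("<GroupStatsResult> %s: statistic %.3f (df %s), p = %.4g [%s]\n",
              o$test, o$statistic, paste(o$df, collapse = ", "), o$p,
              x$normality_gate$route))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  %d post-hoc pairs, %d significant after FDR\n",
                nrow(x$posthoc), sum(x$posthoc$p_fdr < x$alpha)))
  } else cat("  omnibus not significant; no post hocs\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order preserving and
#' never smaller than the raw p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
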