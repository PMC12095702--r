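#' Routing-layout audit of a channel-similarity matrix
#'
#' Operationalizes the diagnostic that discriminates crosstalk from volume
#' conduction: under volume conduction alone, similarity between a
#' reference channel and the others should decay monotonically with
#' cortical distance and show no dependence on routing adjacency. The audit
#' fits a monotone-decreasing trend of the metric versus cortical distance
#' using only channels *not* routed with the reference (isotonic
#' regression), measures each routing-mate's excess above the trend
#' prediction at its own distance, and
#'
#' * flags a routing pair whose excess exceeds
#'   `max(flag_mult * MAD(trend residuals), min_excess)`, and
#' * issues the summary verdict `"crosstalk-suspect"` when the median
#'   routing-mate excess is large compared with the exact permutation
#'   distribution obtained by relabeling which channels count as routing
#'   mates (all label subsets are enumerated when feasible, so the test is
#'   deterministic; otherwise a seeded random subset is used).
#'
#' @param metric symmetric channels x channels similarity matrix (e.g. a
#'   band-limited [correlation_matrix()])
#' @param layout an [electrode_layout()] covering all channels
#' @param reference_channel channel against which the profile is taken
#'   (default 1)
#' @param flag_mult multiple of the residual MAD above which a mate's
#'   excess is flagged (default 2)
#' @param min_excess absolute floor on a flaggable excess (default 0.02):
#'   boosts smaller than this are not practically meaningful for
#'   correlation-type metrics
#' @param alpha significance level of the permutation verdict (default
#'   0.05)
#' @param max_exact maximum number of label subsets to enumerate exactly
#'   (default 20000); beyond this, `n_perm` seeded random subsets are drawn
#' @param n_perm random permutations when enumeration is infeasible
#' @param seed seed for the random-permutation fallback
#' @return An object of class `routing_audit`: per-mate table (`channel`,
#'   `distance_um`, `metric`, `trend`, `excess`, `flagged`), trend residual
#'   spread `sigma`, the median-excess statistic, `p_value`, and `verdict`
#'   (`"crosstalk-suspect"` or `"clean"`).
#' @export
routing_audit <- function(metric, layout, reference_channel = 1,
                          flag_mult = 2, min_excess = 0.02,
                          alpha = 0.05, max_exact = 20000, n_perm = 999,
                          seed = 1) {
  validate_layout(layout)
  nch <- nrow(layout)
  if (!is.matrix(metric) || nrow(metric) != nch || ncol(metric) != nch)
    stop("metric must be a ", nch, " x ", nch, " matrix matching the layout",
         call. = FALSE)
  if (max(abs(metric - t(metric)), na.rm = TRUE) > 1e-8)
    stop("metric must be symmetric", call. = FALSE)
  ref <- reference_channel
  others <- setdiff(layout$channel, ref)
  ref_group <- layout$routing_group[match(ref, layout$channel)]
  mates <- setdiff(layout$channel[layout$routing_group == ref_group], ref)
  non_mates <- setdiff(others, mates)
  if (length(non_mates) < 6)
    stop("insufficient data: need at least 6 channels not routed with the ",
         "reference", call. = FALSE)

  d <- layout_distance(layout, ref, others)
  names(d) <- others
  m <- metric[ref, others]
  names(m) <- others
  if (any(is.na(m)))
    stop("metric contains NA entries for the reference row", call. = FALSE)

  # monotone-decreasing trend on a channel subset; returns a predictor
  fit_trend <- function(ch) {
    x <- d[as.character(ch)]; y <- m[as.character(ch)]
    o <- order(x)
    iso <- stats::isoreg(x[o], -y[o])
    list(x = iso$x, yf = -iso$yf)
  }
  predict_trend <- function(tr, xq) {
    stats::approx(tr$x, tr$yf, xout = xq, rule = 2, ties = mean)$y
  }
  excess_of <- function(set) {
    tr <- fit_trend(setdiff(others, set))
    m[as.character(set)] - predict_trend(tr, d[as.character(set)])
  }

  obs_excess <- excess_of(mates)
  obs_stat <- stats::median(obs_excess)

  tr0 <- fit_trend(non_mates)
  resid0 <- m[as.character(non_mates)] -
    predict_trend(tr0, d[as.character(non_mates)])
  sigma <- stats::mad(resid0)
  flag_threshold <- max(flag_mult * sigma, min_excess)
  flagged <- obs_excess > flag_threshold

  # permutation null: which channels are labeled "routing mates"
  k <- length(mates)
  n_subsets <- choose(length(others), k)
  if (n_subsets <= max_exact) {
    sets <- utils::combn(others, k, simplify = FALSE)
  } else {
    sets <- with_seed(seed, replicate(n_perm, sample(others, k),
                                      simplify = FALSE))
    sets <- c(list(mates), sets)
  }
  perm_stats <- vapply(sets, function(s) stats::median(excess_of(s)),
                       numeric(1))
  p_value <- mean(perm_stats >= obs_stat)

  structure(list(
    reference_channel = ref,
    mates = data.frame(channel = mates,
                       distance_um = unname(d[as.character(mates)]),
                       metric = unname(m[as.character(mates)]),
                       trend = unname(m[as.character(mates)] - obs_excess),
                       excess = unname(obs_excess),
                       flagged = unname(flagged)),
    sigma = sigma, flag_threshold = flag_threshold,
    statistic = obs_stat, p_value = p_value, alpha = alpha,
    n_permutations = length(sets),
    verdict = if (p_value <= alpha) "crosstalk-suspect" else "clean"),
    class = "routing_audit")
}

#' @export
print.routing_audit <- function(x, ...) {
  cat("Routing audit vs channel ", x$reference_channel, ": verdict ",
      x$verdict, " (median excess ", signif(x$statistic, 3),
      ", p = ", signif(x$p_value, 3), ")\n", sep = "")
  print(x$mates, row.names = FALSE)
  cat("trend residual MAD ", signif(x$sigma, 3), ", flag threshold ",
      signif(x$flag_threshold, 3), "\n", sep = "")
  invisible(x)
}
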