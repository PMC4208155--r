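# Pre/post outcome statistics: per-patient deltas, cohort means, clinical
# score banding, rank correlations and improvement counts.

#' Bundled six-patient example cohort
#'
#' Wide pre/post tables (clinical scores, walking/running spatiotemporal
#' values, stair metrics, knee-velocity power values) for a six-patient
#' knee-arthroplasty cohort measured the day before and 12 months after
#' surgery. Used by the worked examples and the acceptance checks.
#'
#' @return named list of data.frames: scores, walking, stairs, power.
#' @export
cohort_tables <- function() {
  rd <- function(f) read.csv(system.file("extdata", f, package = "kneegait"))
  list(scores = rd("cohort_scores.csv"),
       walking = rd("cohort_walking.csv"),
       stairs = rd("cohort_stairs.csv"),
       power = rd("cohort_power.csv"))
}

#' Split a wide pre/post table into matched pre and post tables
#'
#' @param wide data.frame with subject_id and `<metric>_pre` / `<metric>_post`
#'   column pairs.
#' @return list(pre, post): data.frames with subject_id + metric columns.
#' @export
split_timepoints <- function(wide) {
  pre_cols <- grep("_pre$", names(wide), value = TRUE)
  post_cols <- grep("_post$", names(wide), value = TRUE)
  pre <- wide[c("subject_id", pre_cols)]
  post <- wide[c("subject_id", post_cols)]
  names(pre) <- sub("_pre$", "", names(pre))
  names(post) <- sub("_post$", "", names(post))
  list(pre = pre, post = post)
}

#' Per-patient deltas and cohort mean deltas
#'
#' @param pre_metrics,post_metrics data.frames keyed by subject_id with
#'   identical numeric metric columns.
#' @return object of class `outcome_report`: `per_patient` (long data.frame
#'   with metric, subject_id, pre, post, delta = post - pre) and `cohort`
#'   (metric, mean_pre, mean_post, mean_delta, n over patients with both
#'   timepoints).
#' @export
delta_table <- function(pre_metrics, post_metrics) {
  common <- intersect(names(pre_metrics), names(post_metrics))
  metrics <- setdiff(common[vapply(pre_metrics[common], is.numeric, TRUE)],
                     "subject_id")
  ids <- intersect(pre_metrics$subject_id, post_metrics$subject_id)
  per <- do.call(rbind, lapply(metrics, function(m) {
    pre <- pre_metrics[match(ids, pre_metrics$subject_id), m]
    post <- post_metrics[match(ids, post_metrics$subject_id), m]
    data.frame(metric = m, subject_id = ids, pre = pre, post = post,
               delta = post - pre)
  }))
  cohort <- do.call(rbind, lapply(metrics, function(m) {
    d <- per[per$metric == m & is.finite(per$delta), ]
    data.frame(metric = m, mean_pre = mean(d$pre), mean_post = mean(d$post),
               mean_delta = mean(d$delta), n = nrow(d))
  }))
  structure(list(per_patient = per, cohort = cohort), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("<outcome_report> cohort mean deltas:\n")
  print(x$cohort, row.names = FALSE)
  invisible(x)
}

#' Band KSS and OKS scores into the standard quality labels
#'
#' KSS: <60 poor, 60-69 fair, 70-79 good, 80-100 excellent.
#' OKS: 0-19 poor, 20-29 fair, 30-39 good, 40-48 excellent.
#'
#' @param kss,oks numeric score vectors (either may be NULL).
#' @return character vector (single score type) or list(kss=, oks=) when both
#'   are given.
#' @export
band_scores <- function(kss = NULL, oks = NULL) {
  lab <- c("poor", "fair", "good", "excellent")
  bk <- function(x) lab[findInterval(x, c(-Inf, 60, 70, 80))]
  bo <- function(x) lab[findInterval(x, c(-Inf, 20, 30, 40))]
  if (!is.null(kss) && !is.null(oks)) return(list(kss = bk(kss), oks = bo(oks)))
  if (!is.null(kss)) return(bk(kss))
  if (!is.null(oks)) return(bo(oks))
  kg_stop("no scores given", "kneegait_outcome_error")
}

#' Rank correlation between a gait metric and a clinical score
#'
#' Spearman by default (average ranks on ties); no p-value is attached for
#' the typical n = 6 cohort -- correlations are descriptive.
#'
#' @param metric_values,score_values paired numeric vectors, n >= 4.
#' @param method passed to [stats::cor()].
#' @return correlation coefficient.
#' @export
correlate <- function(metric_values, score_values, method = "spearman") {
  ok <- is.finite(metric_values) & is.finite(score_values)
  if (sum(ok) < 4)
    kg_stop("need at least 4 paired values", "kneegait_outcome_error")
  cor(metric_values[ok], score_values[ok], method = method)
}

#' Count patients whose value improved from pre to post
#'
#' @param pre,post paired numeric vectors (matched patients).
#' @param direction "increase" counts post > pre, "decrease" post < pre.
#' @return list(improved, n).
#' @export
improvement_counts <- function(pre, post, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  ok <- is.finite(pre) & is.finite(post)
  imp <- if (direction == "increase") post[ok] > pre[ok] else post[ok] < pre[ok]
  list(improved = sum(imp), n = sum(ok))
}
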