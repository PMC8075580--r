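#' A set of bound-fraction values from experimental repeats
#'
#' @param label condition name.
#' @param fbound_values bound fractions from each technical repeat, in
#'   \[0, 1\].
#' @param pooled_fbound optional bound fraction from fitting the pooled
#'   data.
#' @return an object of class `repeat_set`.
#' @export
repeat_set <- function(label, fbound_values, pooled_fbound = NULL) {
  v <- as.numeric(fbound_values)
  if (any(v < 0 | v > 1)) stop("bound fractions must lie in [0, 1]")
  structure(list(label = label, fbound_values = v,
                 pooled_fbound = pooled_fbound),
            class = "repeat_set")
}

#' Mean, SD and SEM of repeat bound fractions
#'
#' @param repeats a [repeat_set()] (or a bare numeric vector).
#' @return list with `mean`, `sd` (n-1 denominator), `sem` and `n`.
#' @export
summarize_fbound <- function(repeats) {
  v <- if (inherits(repeats, "repeat_set")) repeats$fbound_values
       else as.numeric(repeats)
  if (length(v) < 2L)
    stop(errorCondition("need at least 2 repeats to summarise",
                        class = c("sptkin_insufficient_error", "error",
                                  "condition")))
  list(mean = mean(v), sd = stats::sd(v),
       sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

#' Two-tailed unpaired t-test between two repeat sets
#'
#' Student's pooled-variance t-test of the per-repeat bound fractions,
#' two-tailed.  If both groups are constant and equal, the test is
#' degenerate; t = 0 and p = 1 are returned with a warning.
#'
#' @param a,b [repeat_set()] objects (or numeric vectors).
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_fbound <- function(a, b) {
  va <- if (inherits(a, "repeat_set")) a$fbound_values else as.numeric(a)
  vb <- if (inherits(b, "repeat_set")) b$fbound_values else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L)
    stop(errorCondition("each group needs at least 2 repeats",
                        class = c("sptkin_insufficient_error", "error",
                                  "condition")))
  na <- length(va); nb <- length(vb)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(va) + (nb - 1) * stats::var(vb)) / df
  if (sp2 == 0) {
    if (mean(va) == mean(vb)) {
      warning("zero pooled variance with equal means; returning p = 1")
      return(list(t = 0, p = 1, df = df, mean_a = mean(va),
                  mean_b = mean(vb)))
    }
    return(list(t = sign(mean(va) - mean(vb)) * Inf, p = 0, df = df,
                mean_a = mean(va), mean_b = mean(vb)))
  }
  t <- (mean(va) - mean(vb)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df, mean_a = mean(va), mean_b = mean(vb))
}

#' Write a condition-comparison CSV
#'
#' One row per compared pair: `label_a,label_b,mean_a,mean_b,t,df,p`.
#'
#' @param comparisons list of lists as returned by [compare_fbound()],
#'   each augmented with `label_a` and `label_b`.
#' @param path output path.
#' @export
write_comparison_csv <- function(comparisons, path) {
  rows <- lapply(comparisons, function(cm)
    data.frame(label_a = cm$label_a, label_b = cm$label_b,
               mean_a = cm$mean_a, mean_b = cm$mean_b,
               t = cm$t, df = cm$df, p = cm$p))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
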