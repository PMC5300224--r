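# Agreement metric and group-level reporting for estimated compositions.

#' Negative-log agreement between two sets of composition estimates
#'
#' `D = -log_base( aggregate_i (a_i - b_i)^2 )`, with the aggregate (mean
#' by default, optionally sum) floored at `floor` inside the logarithm so
#' identical inputs give the capped maximum `-log_base(floor)` rather than
#' infinity.  Larger D means closer agreement; values are conventionally
#' read against an empirical similarity threshold of 2.
#'
#' @param comp_a,comp_b per-sample fraction estimates of the same
#'   reference component (e.g. the taurine fraction), same samples.
#' @param base logarithm base (default 10).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @param floor lower floor inside the log (default 1e-12).
#' @return scalar D; attribute `capped` is `TRUE` when the floor was hit.
#' @examples
#' composition_distance(rep(0.6, 10), rep(0.5, 10))  # -log10(0.01) = 2
#' @export
composition_distance <- function(comp_a, comp_b, base = 10,
                                 aggregate = c("mean", "sum"),
                                 floor = 1e-12) {
  aggregate <- match.arg(aggregate)
  .stop_if(length(comp_a) != length(comp_b),
           "composition vectors differ in length")
  ok <- !is.na(comp_a) & !is.na(comp_b)
  .stop_if(!any(ok), "no samples to compare")
  sq <- (comp_a[ok] - comp_b[ok])^2
  agg <- if (aggregate == "mean") mean(sq) else sum(sq)
  capped <- agg < floor
  d <- -log(max(agg, floor), base = base)
  attr(d, "capped") <- capped
  d
}

#' Group summaries of estimated compositions against expectations
#'
#' Per-group mean, SD, minimum and maximum of each composition component,
#' plus the signed deviation of the group mean from the pedigree-expected
#' fraction when one is supplied.
#'
#' @param comp samples-by-components matrix of composition estimates
#'   (e.g. `coef()` of a fit).
#' @param groups per-sample group labels.
#' @param expected optional groups-by-components matrix of pedigree
#'   expectations (rownames = group labels); groups absent from it get
#'   `NA` deviations.
#' @return data.frame with one row per (group, component): `group`,
#'   `component`, `n`, `mean`, `sd`, `min`, `max`, `expected`,
#'   `deviation` (estimate minus expectation, sign preserved).
#' @export
summarize_group_means <- function(comp, groups, expected = NULL) {
  comp <- as.matrix(comp)
  .stop_if(length(groups) != nrow(comp),
           "groups must label every sample")
  comps <- colnames(comp)
  if (is.null(comps)) comps <- paste0("comp", seq_len(ncol(comp)))
  rows <- list()
  for (gr in unique(groups)) {
    sel <- groups == gr
    for (cc in seq_along(comps)) {
      v <- comp[sel, cc]
      v <- v[!is.na(v)]
      exp_v <- NA_real_
      if (!is.null(expected) && gr %in% rownames(expected) &&
          comps[cc] %in% colnames(expected))
        exp_v <- expected[gr, comps[cc]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, component = comps[cc], n = length(v),
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        expected = exp_v, deviation = mean(v) - exp_v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
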