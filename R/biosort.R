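## Worm-sorter reporter quantification: per-worm Green/TOF ratios, scaling so
## that the control group has mean ratio 1, and nonparametric comparison of
## groups against the control (Kruskal-Wallis omnibus + Dunn's z tests).

#' Per-worm fluorescence-to-size ratios
#'
#' Normalizes each worm's green fluorescence by its size (time of flight),
#' the standard read-out for population-level reporter expression.
#'
#' @param pop Per-worm `data.frame` with columns `group`, `tof`, `green`
#'   ([read_worm_population()] / [gen_biosort()]).
#' @return `data.frame` with columns `group` and `ratio` (one row per worm;
#'   record count preserved per group).
#' @export
green_tof_ratio <- function(pop) {
  bad <- which(!is.finite(pop$tof) | pop$tof <= 0)
  if (length(bad) > 0L)
    stop("tof must be > 0; offending record ", bad[1L], " (group ",
         sQuote(pop$group[bad[1L]]), ")")
  data.frame(group = pop$group, ratio = pop$green / pop$tof,
             stringsAsFactors = FALSE)
}

#' Scale ratios so the control group has mean 1
#'
#' Every worm's ratio is divided by the arithmetic mean of the control
#' group's ratios, so the control mean becomes exactly 1 and all groups are
#' expressed relative to it.
#'
#' @param ratios `data.frame` with columns `group`, `ratio`.
#' @param control Label of the control group.
#' @return The `data.frame` with `ratio` rescaled.
#' @export
normalize_to_control <- function(ratios, control) {
  ctl <- ratios$ratio[ratios$group == control]
  if (length(ctl) == 0L) stop("control group ", sQuote(control), " not found")
  m <- mean(ctl)
  if (m <= 0) stop("control group mean must be > 0")
  ratios$ratio <- ratios$ratio / m
  ratios
}

#' Kruskal-Wallis omnibus with Dunn's comparisons against the control
#'
#' Ranks all worms jointly (average ranks on ties) and compares each
#' non-control group to the control with Dunn's z statistic
#' \deqn{z = (\bar R_i - \bar R_c) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_c)}}
#' with tie correction \eqn{T = \sum (t^3 - t) / (12 (N - 1))}, two-sided
#' normal p values, and optional Bonferroni adjustment over the number of
#' vs-control comparisons.
#'
#' @param ratios `data.frame` with columns `group`, `ratio`.
#' @param control Label of the control group.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A list with `kruskal` (the [stats::kruskal.test()] result when
#'   there are >= 2 groups) and `comparisons`, a `data.frame` with one row
#'   per non-control group: `group`, `n`, `mean_rank`, `z`, `p_raw`,
#'   `p_adjusted`, `stars`.
#' @export
kruskal_dunn <- function(ratios, control, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- unique(ratios$group)
  if (!control %in% groups) stop("control group ", sQuote(control),
                                 " not found")
  if (length(groups) < 2L) stop("need at least 2 groups")
  counts <- table(ratios$group)
  if (any(counts == 0L)) stop("every group needs at least 1 observation")

  r <- rank(ratios$ratio)
  N <- length(r)
  t_sizes <- table(ratios$ratio)
  tie_corr <- sum(t_sizes^3 - t_sizes) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr

  mean_ranks <- tapply(r, ratios$group, mean)
  ns <- tapply(r, ratios$group, length)
  others <- setdiff(groups, control)
  z <- vapply(others, function(g) {
    (mean_ranks[[g]] - mean_ranks[[control]]) /
      sqrt(var_term * (1 / ns[[g]] + 1 / ns[[control]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjust == "bonferroni") pmin(1, p_raw * length(others))
           else p_raw
  comparisons <- data.frame(
    group = others, n = as.integer(ns[others]),
    mean_rank = as.numeric(mean_ranks[others]),
    z = unname(z), p_raw = unname(p_raw), p_adjusted = unname(p_adj),
    stars = p_stars(unname(p_adj)),
    stringsAsFactors = FALSE)
  kw <- stats::kruskal.test(ratios$ratio, factor(ratios$group))
  list(kruskal = kw, comparisons = comparisons)
}

#' Map p values to the significance bands used in the figures
#'
#' `"****"` below 1e-4, then `"***"` (< 1e-3), `"**"` (< 1e-2), `"*"`
#' (< 0.05) and `"ns"` at or above 0.05.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star bands.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Per-group summary of sorter ratios
#'
#' @param ratios `data.frame` with columns `group`, `ratio`.
#' @param control Optional control label; when given, a `normalized_mean`
#'   column (group mean divided by control mean) is included.
#' @return `data.frame` with `group`, `n`, `mean_ratio`, `median_ratio` and
#'   optionally `normalized_mean`.
#' @export
summarize_ratios <- function(ratios, control = NULL) {
  out <- do.call(rbind, lapply(split(ratios$ratio, ratios$group), function(v)
    data.frame(n = length(v), mean_ratio = mean(v),
               median_ratio = stats::median(v))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  if (!is.null(control)) {
    m <- out$mean_ratio[out$group == control]
    if (length(m) != 1L) stop("control group ", sQuote(control), " not found")
    out$normalized_mean <- out$mean_ratio / m
  }
  out
}
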