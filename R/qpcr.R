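## Cycling-threshold arithmetic: delta-Ct normalization to a reference gene,
## delta-delta-Ct fold induction, ratio paired t tests on the log scale, and
## ChIP-qPCR percent-input / fold-enrichment.  Amplification efficiency is
## fixed at 2 (one Ct cycle = one doubling).

#' Delta-Ct: target Ct minus reference-gene Ct
#'
#' Each sample is normalized to its own reference-gene measurement (e.g.
#' act-1), so both Cts must come from the same sample.
#'
#' @param ct_target,ct_reference Finite Ct values from the same sample
#'   (vectorized).
#' @return `ct_target - ct_reference`, in cycles.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  ct_target - ct_reference
}

#' Fold induction from paired delta-Ct values
#'
#' `2^-(delta_ct_treated - delta_ct_reference)`: the delta-delta-Ct fold
#' change of the treated condition relative to the reference condition
#' (e.g. infected relative to uninfected worms).
#'
#' @param delta_ct_treated,delta_ct_reference Delta-Ct values for the same
#'   experiment and target (vectorized).
#' @return Positive fold change; `log2(fold)` equals minus the
#'   delta-delta-Ct exactly.
#' @export
fold_induction <- function(delta_ct_treated, delta_ct_reference) {
  2^(-(delta_ct_treated - delta_ct_reference))
}

#' Per-experiment fold induction for every target in a Ct table
#'
#' For each `(experiment_id, target)` the target Ct is normalized to the
#' reference gene within the same experiment and condition (delta-Ct), then
#' the treated condition is expressed relative to the reference condition
#' (delta-delta-Ct fold).
#'
#' @param ct_table Long-form Ct `data.frame` ([read_ct_long()]).
#' @param reference_gene Reference amplicon (default `"act-1"`).
#' @param reference_condition,treated_condition Condition labels (defaults
#'   `"uninfected"` and `"infected"`).
#' @return `data.frame` with columns `experiment_id`, `target`,
#'   `delta_ct_reference`, `delta_ct_treated`, `fold`.
#' @export
fold_induction_table <- function(ct_table, reference_gene = "act-1",
                                 reference_condition = "uninfected",
                                 treated_condition = "infected") {
  get_ct <- function(exp, cond, tgt) {
    hit <- ct_table$experiment_id == exp & ct_table$condition == cond &
      ct_table$target == tgt
    if (sum(hit) != 1L) return(NA_real_)
    ct_table$ct[hit]
  }
  targets <- setdiff(unique(ct_table$target), reference_gene)
  experiments <- unique(ct_table$experiment_id)
  grid <- expand.grid(experiment_id = experiments, target = targets,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    exp <- grid$experiment_id[i]; tgt <- grid$target[i]
    dct_ref <- delta_ct(get_ct(exp, reference_condition, tgt),
                        get_ct(exp, reference_condition, reference_gene))
    dct_trt <- delta_ct(get_ct(exp, treated_condition, tgt),
                        get_ct(exp, treated_condition, reference_gene))
    data.frame(experiment_id = exp, target = tgt,
               delta_ct_reference = dct_ref, delta_ct_treated = dct_trt,
               fold = fold_induction(dct_trt, dct_ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Ratio paired t test on fold changes
#'
#' One-sample t test of `log2(folds)` against 0 with `df = n - 1` — the
#' paired test on the ratio scale used for per-experiment fold inductions.
#' The one-tailed p is half the two-tailed p when the sample mean lies on
#' the alternative side, else one minus that half.
#'
#' @param folds Positive fold changes, one per independent experiment
#'   (length >= 2).
#' @param tails `"one"` or `"two"`.
#' @param alternative For the one-tailed test: `"greater"` (induction; the
#'   default) or `"less"`.
#' @return A list with `t`, `p`, `df` and `mean_log2_fold`.
#' @export
ratio_paired_t <- function(folds, tails = c("one", "two"),
                           alternative = c("greater", "less")) {
  tails <- match.arg(tails)
  alternative <- match.arg(alternative)
  if (any(folds <= 0)) stop("folds must be > 0")
  n <- length(folds)
  if (n < 2L) stop("need folds from at least 2 experiments")
  l <- log2(folds)
  df <- n - 1L
  s <- stats::sd(l)
  if (s == 0) {
    if (mean(l) == 0) {
      t <- 0
    } else {
      warning("zero variance with nonzero mean log fold; t is infinite")
      t <- sign(mean(l)) * Inf
    }
  } else {
    t <- mean(l) / (s / sqrt(n))
  }
  p_two <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  if (t == 0 && s == 0) p_two <- 1
  if (tails == "two") {
    p <- p_two
  } else {
    on_side <- if (alternative == "greater") t > 0 else t < 0
    half <- if (is.infinite(t)) 0 else stats::pt(abs(t), df,
                                                 lower.tail = FALSE)
    p <- if (t == 0) 0.5 else if (on_side) half else 1 - half
  }
  list(t = t, p = p, df = df, mean_log2_fold = mean(l))
}

#' Percent input for a ChIP-qPCR sample
#'
#' The input aliquot is only a fraction of the chromatin used for the
#' immunoprecipitation, so its Ct is first adjusted by
#' `log2(1/input_fraction)` cycles; the immunoprecipitated DNA is then
#' expressed as `100 * 2^(adjusted input Ct - sample Ct)` percent.  The
#' study takes 5% of the material as input (`input_fraction = 0.05`).
#'
#' @param ct_sample Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input aliquot.
#' @param input_fraction Fraction of material taken as input, in (0, 1].
#' @return Percent of input (positive; vectorized).
#' @export
percent_input <- function(ct_sample, ct_input, input_fraction = 0.05) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_sample)
}

#' ChIP fold enrichment over the nonspecific control
#'
#' Ratio of the percent-input of the specific ChIP to that of the
#' nonspecific (blocked-bead) control, both normalized to the same input.
#' When the two share one input the input Ct cancels and the result equals
#' `2^(ct_nonspecific - ct_chip)`.
#'
#' @param ct_chip,ct_nonspecific,ct_input Ct values from the same amplicon
#'   and chromatin preparation.
#' @param input_fraction Fraction of material taken as input (default 0.05).
#' @return Positive fold enrichment; 1 is the nonspecific-binding baseline.
#' @export
chip_fold_enrichment <- function(ct_chip, ct_nonspecific, ct_input,
                                 input_fraction = 0.05) {
  percent_input(ct_chip, ct_input, input_fraction) /
    percent_input(ct_nonspecific, ct_input, input_fraction)
}
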