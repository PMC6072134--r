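## Significance calling for bait interactors: pooled-variance t statistics,
## the SAM-style modified statistic d = delta / (se + s0), and the hyperbolic
## combined threshold it traces in volcano coordinates.

#' Equal-variance two-sample t test
#'
#' Pooled-variance Student t with `df = na + nb - 2` and a two-sided p value.
#' When the pooled variance is zero the statistic degenerates: with a
#' nonzero mean difference `t` is reported as +/-Inf with `p = 0` (and a
#' warning); with a zero difference `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return A list with elements `t`, `p`, `df`, `se` (pooled standard error
#'   of the mean difference) and `diff` (`mean(a) - mean(b)`).
#' @export
two_sample_t_equal_var <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 values")
  df <- na + nb - 2L
  diff <- mean(a) - mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    if (diff == 0) return(list(t = 0, p = 1, df = df, se = 0, diff = 0))
    warning("zero pooled variance with nonzero difference; t is infinite")
    return(list(t = sign(diff) * Inf, p = 0, df = df, se = 0, diff = diff))
  }
  t <- diff / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, se = se, diff = diff)
}

#' SAM modified t statistic
#'
#' `d = log2_diff / (se + s0)`.  The fudge factor `s0` damps the
#' significance of tiny-variance proteins; at `s0 = 0`, `d` equals the
#' ordinary t statistic computed from the same groups.
#'
#' @param log2_diff Mean log2 difference (bait minus control).
#' @param se Pooled standard error of the difference (>= 0).
#' @param s0 Non-negative fudge factor on the same scale as `se`.
#' @return The modified statistic `d` (vectorized).
#' @export
sam_d <- function(log2_diff, se, s0) {
  if (any(se < 0)) stop("se must be >= 0")
  if (any(s0 < 0)) stop("s0 must be >= 0")
  denom <- se + s0
  if (any(denom == 0)) stop("se + s0 must be > 0")
  log2_diff / denom
}

#' Apply the combined (hyperbolic) significance threshold
#'
#' A protein is called significant when its modified statistic reaches
#' `t0`: for `side = "enrichment"` (the default, matching an interactor
#' screen that calls only enriched partners), `d >= t0` and `log2_diff > 0`;
#' for `side = "both"`, `|d| >= t0`.  Blacklisted rows are never
#' significant.
#'
#' @param rows `data.frame` with columns `log2_diff` and `se` (and optionally
#'   `blacklist_hit`).
#' @param s0 Non-negative SAM fudge factor (study default 1.5).
#' @param t0 Positive threshold on the modified statistic (study default
#'   1.2, within the accepted 0.9-1.5 range).
#' @param side `"enrichment"` or `"both"`.
#' @return `rows` with columns `d` and `significant` added/overwritten.
#' @export
combined_threshold <- function(rows, s0 = 1.5, t0 = 1.2,
                               side = c("enrichment", "both")) {
  side <- match.arg(side)
  if (t0 <= 0) stop("t0 must be > 0")
  rows$d <- sam_d(rows$log2_diff, rows$se, s0)
  sig <- if (side == "enrichment") rows$d >= t0 & rows$log2_diff > 0
         else abs(rows$d) >= t0
  if (!is.null(rows$blacklist_hit)) sig <- sig & !rows$blacklist_hit
  rows$significant <- sig
  rows
}

#' Critical curve of the combined threshold in volcano coordinates
#'
#' For each log2 difference `delta` on the grid with `delta > t0 * s0`, the
#' curve gives the largest p value at which a protein with that difference
#' is still called: the spread solving `d = t0` is `s* = delta / t0 - s0`,
#' the corresponding t statistic is `t* = delta / s*`, and the critical p is
#' the two-sided t tail at `t*` with `df` degrees of freedom.  Grid points
#' with `delta <= t0 * s0` are unreachable (no finite critical value) and
#' are returned with `critical_neg_log10_p = NA` and `reachable = FALSE`.
#' A point (`delta`, `p`) lies under the curve, i.e. `p <= critical p`, iff
#' its `d >= t0`.
#'
#' @param s0,t0 SAM parameters.
#' @param df Degrees of freedom of the per-protein t statistic (>= 1).
#' @param diff_grid Numeric vector of log2 differences.
#' @return `data.frame` with columns `log2_diff`, `critical_neg_log10_p`,
#'   `reachable`.
#' @export
significance_curve <- function(s0, t0, df, diff_grid) {
  if (df < 1) stop("df must be >= 1")
  reachable <- diff_grid > t0 * s0
  crit <- rep(NA_real_, length(diff_grid))
  s_star <- diff_grid[reachable] / t0 - s0
  t_star <- diff_grid[reachable] / s_star
  p_crit <- 2 * stats::pt(-abs(t_star), df)
  crit[reachable] <- -log10(p_crit)
  data.frame(log2_diff = diff_grid, critical_neg_log10_p = crit,
             reachable = reachable)
}

## vectorized pooled t over matrix rows; returns diff, se, t, p
row_pooled_t <- function(values, bait_cols, control_cols) {
  A <- values[, bait_cols, drop = FALSE]
  B <- values[, control_cols, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  df <- na + nb - 2L
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[t == 0 & se == 0] <- 1
  list(diff = diff, se = se, t = t, p = p, df = df)
}

#' Run the full bait-interactor calling pipeline
#'
#' Composition of the stages applied to a protein-groups table: drop decoy
#' and contaminant rows; keep proteins quantified in at least `min_valid`
#' bait replicates; log2-transform; impute missing values per sample column
#' from a down-shifted normal; per-protein equal-variance t and SAM `d`;
#' hyperbolic combined threshold; cross-reactive blacklist and annotation
#' flags.  Deterministic given `seed`.
#'
#' @param table Protein-groups `data.frame` ([read_protein_groups()] /
#'   [gen_lfq()]).
#' @param design Design `data.frame` ([sample_design()]).
#' @param min_valid Minimum bait-replicate presence (default 2).
#' @param width,shift Imputation parameters (defaults 0.3 and 1.8).
#' @param s0,t0,side Combined-threshold parameters (defaults 1.5, 1.2,
#'   `"enrichment"`).
#' @param seed Integer master seed for the imputation draws.
#' @param blacklist Character vector of cross-reactive protein ids; they are
#'   flagged `blacklist_hit` and never called significant.
#' @param annotations Optional character vector of protein ids carrying the
#'   "DNA-binding" gene-ontology annotation; sets the `dna_binding` flag.
#' @return A volcano `data.frame` with one row per retained protein:
#'   `protein_id`, `log2_diff`, `se`, `t`, `p`, `d`, `significant`,
#'   `dna_binding`, `blacklist_hit`, `n_imputed_bait`, `n_imputed_control`.
#' @export
run_apms_pipeline <- function(table, design, min_valid = 2L, width = 0.3,
                              shift = 1.8, s0 = 1.5, t0 = 1.2,
                              side = c("enrichment", "both"), seed = 1L,
                              blacklist = character(), annotations = NULL) {
  side <- match.arg(side)
  m <- as_lfq_matrix(table, design, drop_flagged = TRUE)
  m <- filter_min_valid(m, design, min_valid)
  m <- log2_transform(m)
  m <- impute_downshifted(m, width = width, shift = shift, seed = seed)

  bait <- design$sample_id[design$group == "bait"]
  control <- design$sample_id[design$group == "control"]
  st <- row_pooled_t(m$values, bait, control)

  rows <- data.frame(
    protein_id = rownames(m$values),
    log2_diff = unname(st$diff),
    se = unname(st$se),
    t = unname(st$t),
    p = unname(st$p),
    blacklist_hit = rownames(m$values) %in% blacklist,
    stringsAsFactors = FALSE)
  rows <- combined_threshold(rows, s0 = s0, t0 = t0, side = side)
  rows$dna_binding <- if (is.null(annotations)) FALSE else
    rows$protein_id %in% annotations
  rows$n_imputed_bait <- unname(rowSums(m$imputed[, bait, drop = FALSE]))
  rows$n_imputed_control <- unname(rowSums(m$imputed[, control, drop = FALSE]))
  rows[, c("protein_id", "log2_diff", "se", "t", "p", "d", "significant",
           "dna_binding", "blacklist_hit", "n_imputed_bait",
           "n_imputed_control")]
}
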