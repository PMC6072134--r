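## Synthetic-data generators reproducing the statistical structure each assay
## assumes: an LFQ pull-down table with intensity-dependent (MNAR)
## missingness, long-form Ct tables under induction effects, per-worm sorter
## populations, and censored Weibull survival cohorts.  All generators are
## deterministic under a fixed seed.

#' Generate a synthetic protein-groups LFQ table
#'
#' Emulates a pull-down experiment with `n_bait` anti-GFP and `n_control`
#' blocked-resin replicates.  Each background protein has one common log2
#' abundance in both groups, drawn from `Normal(background_mean,
#' background_sd)`; planted interactors add `effect_log2` in bait columns
#' only.  Per-cell Gaussian noise of sd `noise_sd` is added, then each cell
#' is masked missing with probability
#' `plogis((mnar_midpoint - value) * mnar_slope)`, so missingness increases
#' as log2 intensity decreases (missing-not-at-random).  Stored intensities
#' are `2^value`.  Bait-specific proteins arise naturally from MNAR at low
#' control abundance; `structural_missing = TRUE` additionally blanks all
#' control cells of planted proteins for stress tests.
#'
#' @param n_background,n_planted Protein counts.
#' @param effect_log2 Bait-specific log2 enrichment of planted proteins
#'   (scalar or one value per planted protein).
#' @param n_bait,n_control Replicate counts (>= 2 each).
#' @param noise_sd Per-cell Gaussian noise sd on the log2 scale.
#' @param background_mean,background_sd Distribution of per-protein log2
#'   abundances.
#' @param mnar_midpoint Log2 intensity at which the missingness probability
#'   is one half.
#' @param mnar_slope Steepness of the logistic missingness curve (per log2
#'   unit); as it approaches 0, missingness becomes intensity-independent at
#'   rate 0.5.
#' @param planted_ids Optional identifiers for the planted proteins
#'   (recycled defaults `PLANT0001...`).
#' @param planted_mu Optional baseline log2 abundance for the planted
#'   proteins (scalar or vector), overriding the background draw — e.g. to
#'   model stoichiometric complex subunits at reliably detectable levels.
#' @param structural_missing Force all planted-protein control cells
#'   missing.
#' @param seed Integer seed.
#' @return A list with `table` (a protein-groups `data.frame` in the
#'   [read_protein_groups()] schema, intensity columns named
#'   `"LFQ intensity GFP_i"` / `"LFQ intensity CTL_i"`), `design` (the
#'   matching [sample_design()]) and `truth` (planted ids and the generator
#'   parameters).
#' @export
gen_lfq <- function(n_background = 2000L, n_planted = 50L, effect_log2 = 4,
                    n_bait = 3L, n_control = 3L, noise_sd = 0.5,
                    background_mean = 25, background_sd = 2,
                    mnar_midpoint = 22.5, mnar_slope = 1,
                    planted_ids = NULL, planted_mu = NULL,
                    structural_missing = FALSE, seed = 1L) {
  stopifnot(n_background >= 0, n_planted >= 0, n_bait >= 2, n_control >= 2,
            noise_sd > 0, mnar_slope >= 0)
  set.seed(seed)
  n <- n_background + n_planted
  ids <- c(sprintf("BG%04d", seq_len(n_background)),
           if (is.null(planted_ids)) sprintf("PLANT%04d", seq_len(n_planted))
           else rep_len(planted_ids, n_planted))
  planted <- c(rep(FALSE, n_background), rep(TRUE, n_planted))

  bait_cols <- sprintf("LFQ intensity GFP_%d", seq_len(n_bait))
  control_cols <- sprintf("LFQ intensity CTL_%d", seq_len(n_control))
  mu <- stats::rnorm(n, background_mean, background_sd)
  if (!is.null(planted_mu)) mu[planted] <- rep_len(planted_mu, n_planted)
  truth_mat <- matrix(mu, n, n_bait + n_control)
  truth_mat[planted, seq_len(n_bait)] <-
    truth_mat[planted, seq_len(n_bait)] + rep_len(effect_log2, n_planted)
  values <- truth_mat + matrix(stats::rnorm(n * (n_bait + n_control),
                                            0, noise_sd),
                               n, n_bait + n_control)
  p_miss <- stats::plogis((mnar_midpoint - values) * mnar_slope)
  miss <- matrix(stats::runif(length(values)) < p_miss, n,
                 n_bait + n_control)
  if (structural_missing && n_planted > 0)
    miss[planted, n_bait + seq_len(n_control)] <- TRUE
  raw <- 2^values
  raw[miss] <- NA_real_

  tab <- data.frame(protein_id = ids, gene_names = ids,
                    stringsAsFactors = FALSE)
  cols <- c(bait_cols, control_cols)
  for (j in seq_along(cols)) tab[[cols[j]]] <- raw[, j]
  tab$reverse <- FALSE
  tab$contaminant <- FALSE

  design <- sample_design(cols,
                          c(rep("bait", n_bait), rep("control", n_control)))
  list(table = tab, design = design,
       truth = list(planted_ids = ids[planted], effect_log2 = effect_log2,
                    background_mean = background_mean,
                    background_sd = background_sd, noise_sd = noise_sd,
                    mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                    seed = seed))
}

#' Six NuRD/MEC chromatin-remodelling subunits validated as bait interactors
#'
#' @return Character vector of the six subunit names.
#' @export
nurd_mec_subunits <- function() {
  c("LIN-40", "LIN-53", "LET-418", "HDA-1", "MEP-1", "DCP-66")
}

#' Synthetic stand-in for the study-scale pull-down experiment
#'
#' Builds a synthetic protein-groups table emulating the uninfected
#' pull-down experiment: three anti-GFP against three control replicates,
#' about 1400 quantified protein groups of which 53 are true high-confidence
#' bait partners.  Planted enrichments are spread uniformly over 4-10 log2
#' units (the range spanned by the called partners on the volcano), and the
#' six NuRD/MEC complex subunits among them are modelled as stoichiometric
#' complex members: baseline abundance one log2 unit above the background
#' mean and 7 log2 units of bait-specific enrichment, so they are
#' quantified in every pull-down replicate.  This is synthetic data — a
#' stand-in with the experiment's statistical structure, not the deposited
#' measurements.
#'
#' @param n_background Number of non-interacting background proteins.
#' @param seed Integer seed.
#' @return As [gen_lfq()]: a list with `table`, `design`, `truth`.
#' @export
gen_study_pulldown_synthetic <- function(n_background = 1350L, seed = 1L) {
  nurd <- nurd_mec_subunits()
  n_planted <- 53L
  ids <- c(nurd, sprintf("HC%04d", seq_len(n_planted - length(nurd))))
  effects <- c(rep(7, length(nurd)),
               seq(4, 10, length.out = n_planted - length(nurd)))
  set.seed(derive_seed(seed, 1L))
  mu <- c(rep(26, length(nurd)),
          stats::rnorm(n_planted - length(nurd), 25, 2))
  gen_lfq(n_background = n_background, n_planted = n_planted,
          effect_log2 = effects, planted_ids = ids, planted_mu = mu,
          seed = seed)
}

#' Generate a long-form Ct table with known induction effects
#'
#' For each experiment and condition the reference gene's Ct is drawn from
#' `Normal(reference_ct, reference_sd)`; each target's Ct is the reference
#' Ct plus a baseline delta-Ct, lowered by `log2(fold)` cycles in the
#' treated condition, plus measurement noise.  With zero noise the fold is
#' recovered exactly by the delta-delta-Ct computation.
#'
#' @param n_experiments Number of independent experiments.
#' @param targets Character vector of target amplicons.
#' @param induction_folds Named positive vector of true fold inductions per
#'   target (single value recycled).
#' @param reference_gene Reference amplicon name (default `"act-1"`).
#' @param reference_ct Mean reference-gene Ct (cycles).
#' @param reference_sd Between-run sd of the reference Ct.
#' @param baseline_delta_ct Uninduced target Ct minus reference Ct.
#' @param noise_sd Per-measurement Ct noise (cycles).
#' @param conditions Length-2 labels, reference condition first.
#' @param seed Integer seed.
#' @return A long-form Ct `data.frame` (schema of [read_ct_long()]).
#' @export
gen_ct <- function(n_experiments = 3L, targets = c("nlp-29", "nlp-31"),
                   induction_folds = 8, reference_gene = "act-1",
                   reference_ct = 16, reference_sd = 0.5,
                   baseline_delta_ct = 8, noise_sd = 0.15,
                   conditions = c("uninfected", "infected"), seed = 1L) {
  stopifnot(n_experiments >= 1, all(induction_folds > 0),
            length(conditions) == 2L)
  folds <- rep_len(induction_folds, length(targets))
  if (!is.null(names(induction_folds)) &&
      all(targets %in% names(induction_folds)))
    folds <- induction_folds[targets]
  set.seed(seed)
  rows <- list()
  for (e in seq_len(n_experiments)) {
    exp_id <- sprintf("exp%d", e)
    for (cond_i in 1:2) {
      cond <- conditions[cond_i]
      ref_ct <- stats::rnorm(1, reference_ct, reference_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = exp_id, condition = cond, target = reference_gene,
        ct = ref_ct, stringsAsFactors = FALSE)
      for (k in seq_along(targets)) {
        ct <- ref_ct + baseline_delta_ct -
          log2(folds[k]) * (cond_i == 2L) +
          (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = exp_id, condition = cond, target = targets[k],
          ct = ct, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a per-worm sorter population
#'
#' Per worm, TOF is lognormal; green fluorescence is the group's mean ratio
#' times TOF with lognormal noise of the stated dispersion; extinction and
#' red fluorescence are filled analogously with fixed reference ratios.
#'
#' @param groups Named list, each element `list(n = <count>, mean_ratio =
#'   <positive>)`.
#' @param dispersion Lognormal sdlog of the per-worm ratio noise.
#' @param tof_meanlog,tof_sdlog Lognormal parameters of the size
#'   distribution.
#' @param seed Integer seed.
#' @return A per-worm `data.frame` (schema of [read_worm_population()]).
#' @export
gen_biosort <- function(groups = list(control = list(n = 80, mean_ratio = 1),
                                      treated = list(n = 80, mean_ratio = 2)),
                        dispersion = 0.3, tof_meanlog = log(400),
                        tof_sdlog = 0.2, seed = 1L) {
  set.seed(seed)
  out <- lapply(names(groups), function(g) {
    n <- groups[[g]]$n
    mr <- groups[[g]]$mean_ratio
    stopifnot(n >= 1, mr > 0)
    tof <- stats::rlnorm(n, tof_meanlog, tof_sdlog)
    ## divide by the lognormal mean factor so E[green/tof] = mean_ratio
    green <- mr * tof * stats::rlnorm(n, -dispersion^2 / 2, dispersion)
    ext <- 0.5 * tof * stats::rlnorm(n, -0.1^2 / 2, 0.1)
    red <- 0.2 * tof * stats::rlnorm(n, -0.1^2 / 2, 0.1)
    data.frame(group = g, tof = tof, ext = ext, green = green, red = red,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a censored survival cohort
#'
#' Event times are Weibull per group; times beyond `censor_time` are
#' recorded as censored at `censor_time`.
#'
#' @param groups Named list, each element `list(n = <count>, scale =
#'   <positive>, shape = <positive>)` of Weibull parameters.
#' @param censor_time End of follow-up (same units as the event times).
#' @param seed Integer seed.
#' @return A per-animal `data.frame` (schema of [read_survival_cohort()]).
#' @export
gen_survival <- function(groups = list(control = list(n = 50, scale = 10,
                                                      shape = 2),
                                       treated = list(n = 50, scale = 7,
                                                      shape = 2)),
                         censor_time = 20, seed = 1L) {
  set.seed(seed)
  out <- lapply(names(groups), function(g) {
    n <- groups[[g]]$n
    stopifnot(n >= 1, groups[[g]]$scale > 0, groups[[g]]$shape > 0)
    t <- stats::rweibull(n, shape = groups[[g]]$shape,
                         scale = groups[[g]]$scale)
    event <- as.integer(t <= censor_time)
    data.frame(group = g, time = pmin(t, censor_time), event = event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
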