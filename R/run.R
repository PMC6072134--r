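## Single entry point wiring the stages into reproducible runs: every run
## validates its parameters before computing, writes its outputs to declared
## paths only, and records a provenance file (fully resolved parameters +
## seed + package version) alongside.

stage_defaults <- list(
  `apms-call` = list(min_valid = 2L, width = 0.3, shift = 1.8, s0 = 1.5,
                     t0 = 1.2, side = "enrichment"),
  overlap = list(),
  qpcr = list(reference_gene = "act-1", reference_condition = "uninfected",
              treated_condition = "infected", tails = "one",
              alternative = "greater"),
  chip = list(input_fraction = 0.05, dilution = 50),
  biosort = list(adjust = "bonferroni"),
  survival = list()
)

#' Run one analysis stage with provenance
#'
#' Validates the parameters against the stage's defaults, executes the
#' stage, writes its output tables under `out_prefix`, and writes
#' `<out_prefix>.provenance.json` holding the fully resolved configuration,
#' the seed and the package version.  Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param stage One of `"apms-call"`, `"overlap"`, `"qpcr"`, `"chip"`,
#'   `"biosort"`, `"survival"`.
#' @param inputs Named list of input file paths (stage-dependent:
#'   `table`, `design`, `blacklist`, `annotations`, `list_a`, `list_b`).
#' @param params Named list of stage parameters overriding the embedded
#'   defaults (the study's printed values).
#' @param seed Integer seed for any stochastic step.
#' @param out_prefix Path prefix for output files.
#' @return Invisibly, a named list of the output file paths.
#' @export
run_stage <- function(stage, inputs = list(), params = list(), seed = 1L,
                      out_prefix = "run") {
  if (!stage %in% names(stage_defaults))
    stop("unknown stage ", sQuote(stage), "; available: ",
         paste(names(stage_defaults), collapse = ", "))
  defaults <- stage_defaults[[stage]]
  unknown <- setdiff(names(params), c(names(defaults), "universe_size",
                                      "control", "group_a", "group_b",
                                      "hypothesized_worse"))
  if (length(unknown) > 0L)
    stop("unknown parameter(s) for stage ", sQuote(stage), ": ",
         paste(sQuote(unknown), collapse = ", "))
  cfg <- utils::modifyList(defaults, params)
  validate_stage_config(stage, cfg)
  for (f in unlist(inputs)) if (!file.exists(f))
    stop("input file not found: ", sQuote(f))

  outputs <- switch(stage,
    `apms-call` = {
      design <- read_sample_design(inputs$design)
      tab <- read_protein_groups(inputs$table, design$sample_id)
      blacklist <- if (!is.null(inputs$blacklist))
        read_id_list(inputs$blacklist) else character()
      annotations <- if (!is.null(inputs$annotations))
        read_id_list(inputs$annotations) else NULL
      volcano <- run_apms_pipeline(tab, design, min_valid = cfg$min_valid,
                                   width = cfg$width, shift = cfg$shift,
                                   s0 = cfg$s0, t0 = cfg$t0, side = cfg$side,
                                   seed = seed, blacklist = blacklist,
                                   annotations = annotations)
      curve <- significance_curve(cfg$s0, cfg$t0,
                                  df = sum(design$group == "bait") +
                                    sum(design$group == "control") - 2L,
                                  diff_grid = seq(0, 12, by = 0.05))
      paths <- c(volcano = paste0(out_prefix, ".volcano.tsv"),
                 curve = paste0(out_prefix, ".curve.tsv"))
      write_results_table(volcano, paths[["volcano"]])
      write_results_table(curve, paths[["curve"]])
      paths
    },
    overlap = {
      res <- overlap_test(read_id_list(inputs$list_a),
                          read_id_list(inputs$list_b),
                          params$universe_size)
      paths <- c(overlap = paste0(out_prefix, ".overlap.tsv"))
      write_results_table(res, paths[["overlap"]])
      paths
    },
    qpcr = {
      ct <- read_ct_long(inputs$table)
      folds <- fold_induction_table(ct, reference_gene = cfg$reference_gene,
                                    reference_condition =
                                      cfg$reference_condition,
                                    treated_condition = cfg$treated_condition)
      tests <- do.call(rbind, lapply(split(folds, folds$target), function(d) {
        tt <- ratio_paired_t(d$fold, tails = cfg$tails,
                             alternative = cfg$alternative)
        data.frame(target = d$target[1], n = nrow(d),
                   mean_fold = mean(d$fold),
                   sd_fold = stats::sd(d$fold),
                   mean_log2_fold = tt$mean_log2_fold,
                   sd_log2_fold = stats::sd(log2(d$fold)),
                   t = tt$t, p = tt$p, df = tt$df)
      }))
      paths <- c(folds = paste0(out_prefix, ".folds.tsv"),
                 tests = paste0(out_prefix, ".tests.tsv"))
      write_results_table(folds, paths[["folds"]])
      write_results_table(tests, paths[["tests"]])
      paths
    },
    chip = {
      ct <- read_ct_long(inputs$table)
      res <- chip_enrichment_table(ct, input_fraction = cfg$input_fraction)
      paths <- c(chip = paste0(out_prefix, ".chip.tsv"))
      write_results_table(res, paths[["chip"]])
      paths
    },
    biosort = {
      pop <- read_worm_population(inputs$table)
      ratios <- green_tof_ratio(pop)
      summary <- summarize_ratios(ratios, control = params$control)
      kd <- kruskal_dunn(ratios, control = params$control,
                         adjust = cfg$adjust)
      paths <- c(summary = paste0(out_prefix, ".summary.tsv"),
                 comparisons = paste0(out_prefix, ".comparisons.tsv"))
      write_results_table(summary, paths[["summary"]])
      write_results_table(kd$comparisons, paths[["comparisons"]])
      paths
    },
    survival = {
      cohort <- read_survival_cohort(inputs$table)
      lr <- logrank_onesided(cohort, params$group_a, params$group_b,
                             params$hypothesized_worse %||% params$group_b)
      km <- do.call(rbind, lapply(c(params$group_a, params$group_b),
                                  function(g)
                                    cbind(group = g, km_estimate(cohort, g))))
      test <- data.frame(group_a = params$group_a, group_b = params$group_b,
                         chi2 = lr$chi2, p_two_sided = lr$p_two_sided,
                         p_one_sided = lr$p_one_sided,
                         direction = lr$direction)
      paths <- c(km = paste0(out_prefix, ".km.tsv"),
                 test = paste0(out_prefix, ".test.tsv"))
      write_results_table(km, paths[["km"]])
      write_results_table(test, paths[["test"]])
      paths
    })

  provenance <- list(stage = stage, parameters = cfg,
                     extra = params[setdiff(names(params), names(cfg))],
                     inputs = inputs, seed = seed,
                     package = "wormassays",
                     version = as.character(utils::packageVersion("wormassays")))
  jsonlite::write_json(provenance, paste0(out_prefix, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(as.list(outputs))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_stage_config <- function(stage, cfg) {
  check_pos <- function(name, allow_zero = FALSE) {
    if (!is.null(cfg[[name]])) {
      ok <- is.numeric(cfg[[name]]) &&
        (cfg[[name]] > 0 || (allow_zero && cfg[[name]] >= 0))
      if (!ok) stop("invalid ", sQuote(name), ": must be ",
                    if (allow_zero) ">= 0" else "> 0")
    }
  }
  if (stage == "apms-call") {
    check_pos("width"); check_pos("shift", allow_zero = TRUE)
    check_pos("s0", allow_zero = TRUE); check_pos("t0")
    if (cfg$min_valid < 0) stop("invalid 'min_valid': must be >= 0")
    if (!cfg$side %in% c("enrichment", "both"))
      stop("invalid 'side': must be 'enrichment' or 'both'")
  }
  if (stage == "chip") {
    if (cfg$input_fraction <= 0 || cfg$input_fraction > 1)
      stop("invalid 'input_fraction': must be in (0, 1]")
  }
  invisible(TRUE)
}

#' Per-amplicon ChIP fold enrichment from a long-form Ct table
#'
#' Expects conditions `"chip"`, `"nonspecific"` and `"input"` per
#' `(experiment_id, target)`; returns percent-input for the specific and
#' nonspecific immunoprecipitations and their ratio (fold enrichment).
#'
#' @param ct_table Long-form Ct `data.frame` ([read_ct_long()]).
#' @param input_fraction Fraction of material taken as input (default 0.05).
#' @return `data.frame` with one row per `(experiment_id, target)`:
#'   `percent_input_chip`, `percent_input_mock`, `fold_enrichment`.
#' @export
chip_enrichment_table <- function(ct_table, input_fraction = 0.05) {
  key <- unique(ct_table[, c("experiment_id", "target")])
  res <- lapply(seq_len(nrow(key)), function(i) {
    sub <- ct_table[ct_table$experiment_id == key$experiment_id[i] &
                    ct_table$target == key$target[i], , drop = FALSE]
    get1 <- function(cond) {
      v <- sub$ct[sub$condition == cond]
      if (length(v) != 1L) NA_real_ else v
    }
    chip <- get1("chip"); mock <- get1("nonspecific"); input <- get1("input")
    pc <- percent_input(chip, input, input_fraction)
    pm <- percent_input(mock, input, input_fraction)
    data.frame(experiment_id = key$experiment_id[i], target = key$target[i],
               percent_input_chip = pc, percent_input_mock = pm,
               fold_enrichment = pc / pm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[stats::complete.cases(out), , drop = FALSE]
}
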