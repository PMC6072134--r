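## Tabular I/O for every assay: protein-groups TSV in the dialect written by
## the upstream quantification suite, and plain CSV for Ct, worm-sorter and
## survival records.  Column matching is exact and case-sensitive.

#' Read a protein-groups quantification table
#'
#' Parses the tab-separated protein-groups table produced by the upstream
#' label-free quantification suite.  Intensity cells that are empty or `0`
#' are stored as `NA` (not quantified); decoy and contaminant flag columns
#' use the `"+"` marker convention.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param sample_columns Character vector of intensity column names, e.g.
#'   `"LFQ intensity GFP_1"`.  Matched exactly and case-sensitively.
#' @param id_column Name of the protein-group identifier column.
#' @param gene_column Optional gene-names column (`NULL` to skip).
#' @param reverse_column,contaminant_column Names of the decoy and
#'   contaminant flag columns; a `"+"` in a cell sets the flag.  Either may
#'   be absent from the file, in which case the flag is `FALSE` everywhere.
#' @return A `data.frame` with columns `protein_id`, `gene_names`, one
#'   non-negative numeric column per entry of `sample_columns` (`NA` =
#'   missing), and logical `reverse` and `contaminant` columns.
#' @export
read_protein_groups <- function(path, sample_columns,
                                id_column = "Protein IDs",
                                gene_column = "Gene names",
                                reverse_column = "Reverse",
                                contaminant_column = "Potential contaminant") {
  raw <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(c(id_column, sample_columns), names(raw))
  if (length(missing_cols) > 0L)
    stop("protein-groups table is missing required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "))

  out <- data.frame(protein_id = raw[[id_column]], stringsAsFactors = FALSE)
  out$gene_names <- if (!is.null(gene_column) && gene_column %in% names(raw))
    raw[[gene_column]] else out$protein_id

  for (sc in sample_columns) {
    cell <- raw[[sc]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & nzchar(trimws(cell)) & is.na(val))
    if (length(bad) > 0L)
      stop("unparsable numeric cell in column ", sQuote(sc),
           " at data row ", bad[1L], ": ", sQuote(cell[bad[1L]]))
    val[is.na(val) | val == 0] <- NA_real_
    if (any(val < 0, na.rm = TRUE))
      stop("negative intensity in column ", sQuote(sc))
    out[[sc]] <- val
  }
  flag <- function(column) {
    if (column %in% names(raw)) trimws(raw[[column]]) == "+" else
      rep(FALSE, nrow(raw))
  }
  out$reverse <- flag(reverse_column)
  out$contaminant <- flag(contaminant_column)
  out
}

#' Write a protein-groups table in the dialect `read_protein_groups` reads
#'
#' @param table Data frame as returned by [read_protein_groups()] or
#'   [gen_lfq()].
#' @param path Output path (tab-separated, header row).
#' @export
write_protein_groups <- function(table, path) {
  out <- table
  meta <- c("protein_id", "gene_names", "reverse", "contaminant")
  sample_cols <- setdiff(names(out), meta)
  names(out)[names(out) == "protein_id"] <- "Protein IDs"
  names(out)[names(out) == "gene_names"] <- "Gene names"
  out$reverse <- ifelse(table$reverse, "+", "")
  out$contaminant <- ifelse(table$contaminant, "+", "")
  names(out)[names(out) == "reverse"] <- "Reverse"
  names(out)[names(out) == "contaminant"] <- "Potential contaminant"
  for (sc in sample_cols) out[[sc]][is.na(out[[sc]])] <- 0
  write_results_table(out, path)
}

#' Read a long-form cycling-threshold (Ct) table
#'
#' Expects a CSV with columns `experiment_id`, `condition`, `target`, `ct`.
#' Technical replicates (duplicate `(experiment_id, condition, target)`
#' tuples) are averaged on the Ct scale at read time and the multiplicity is
#' reported via a message; biological replicates (distinct `experiment_id`)
#' are never merged.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per
#'   `(experiment_id, condition, target)` tuple and numeric `ct`.
#' @export
read_ct_long <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("experiment_id", "condition", "target", "ct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("Ct table is missing required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "))
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(is.na(ct) | !is.finite(ct))
  if (length(bad) > 0L)
    stop("non-numeric or non-finite ct at data row ", bad[1L], ": ",
         sQuote(raw$ct[bad[1L]]))
  raw$ct <- ct
  if (nrow(raw) == 0L) return(raw[, need])

  key <- interaction(raw$experiment_id, raw$condition, raw$target, drop = TRUE)
  agg <- stats::aggregate(ct ~ experiment_id + condition + target, data = raw,
                          FUN = mean)
  n_dup <- nrow(raw) - nrow(agg)
  if (n_dup > 0L)
    message(n_dup, " technical replicate(s) averaged on the Ct scale")
  agg[order(agg$experiment_id, agg$condition, agg$target), , drop = FALSE]
}

#' Read per-worm sorter records
#'
#' CSV with columns `group`, `tof`, `ext`, `green`, `red` (one row per worm).
#' Time of flight (`tof`) must be strictly positive so that
#' fluorescence-per-size ratios are defined.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of per-worm records.
#' @export
read_worm_population <- function(path) {
  pop <- utils::read.csv(path, check.names = FALSE)
  need <- c("group", "tof", "ext", "green", "red")
  missing_cols <- setdiff(need, names(pop))
  if (length(missing_cols) > 0L)
    stop("worm table is missing required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "))
  if (any(!is.finite(pop$tof)) || any(pop$tof <= 0))
    stop("tof must be finite and > 0 for every record")
  pop
}

#' Read a survival cohort
#'
#' CSV with columns `group`, `time`, `event` (`1` = death observed, `0` =
#' censored).  Times are arbitrary non-negative reals: daily counts and
#' short-interval imaging assays are both accepted.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of per-animal records.
#' @export
read_survival_cohort <- function(path) {
  cohort <- utils::read.csv(path, check.names = FALSE)
  need <- c("group", "time", "event")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stop("survival table is missing required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "))
  if (any(cohort$time < 0)) stop("time must be >= 0")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  cohort
}

#' Write any stage's output records as tab-separated text
#'
#' Missing values are written as empty fields and floating values at full
#' precision, so that a read/write round trip preserves numbers to floating
#' representation.
#'
#' @param rows A `data.frame` sharing one schema across rows.
#' @param path Output path.
#' @export
write_results_table <- function(rows, path) {
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Read a table written by `write_results_table`
#'
#' @param path Path to the tab-separated file.
#' @return A `data.frame`; empty fields become `NA`.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "")
}

## full-precision numeric formatting (17 significant digits round-trips
## doubles exactly)
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE,
                                            trim = TRUE)
  }, character(1))
  out
}
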