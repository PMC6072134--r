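## The LfqMatrix container: a protein x sample grid of intensities with an
## explicit missingness mask and a scale tag ("raw" or "log2") guarding the
## transform order.  Kept as a light S3 object around a base matrix.

#' Construct an LFQ matrix
#'
#' @param values Numeric matrix (proteins x samples) with `NA` for
#'   not-quantified cells; rownames are protein identifiers, colnames sample
#'   identifiers.
#' @param scale Either `"raw"` (intensities, all present values > 0) or
#'   `"log2"`.
#' @param imputed Optional logical matrix of the same shape marking imputed
#'   cells.
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(values, scale = c("raw", "log2"), imputed = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry protein rownames and sample colnames")
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be > 0 where present")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  structure(list(values = values, scale = scale, imputed = imputed),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("lfq_matrix: %d proteins x %d samples [%s scale], %d missing, %d imputed\n",
              nrow(x$values), ncol(x$values), x$scale,
              sum(is.na(x$values)), sum(x$imputed)))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Define the pull-down design
#'
#' Assigns each sample column to the bait (anti-GFP pull-down) or control
#' (blocked-resin) group.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Character vector, each `"bait"` or `"control"`.
#' @param replicate Positive integer replicate indices (defaults to 1..n
#'   within each group).
#' @return A `data.frame` with columns `sample_id`, `group`, `replicate`.
#' @export
sample_design <- function(sample_id, group, replicate = NULL) {
  if (!all(group %in% c("bait", "control")))
    stop("group must be 'bait' or 'control'")
  if (sum(group == "bait") < 2L || sum(group == "control") < 2L)
    stop("need at least 2 bait and 2 control samples")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  data.frame(sample_id = sample_id, group = group, replicate = replicate,
             stringsAsFactors = FALSE)
}

#' Read a sample design CSV (sample_id, group, replicate)
#'
#' @param path Path to the CSV file.
#' @return A design `data.frame` as from [sample_design()].
#' @export
read_sample_design <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(sample_id = "character",
                                      group = "character"))
  sample_design(d$sample_id, d$group,
                if ("replicate" %in% names(d)) d$replicate else NULL)
}

#' Build an LFQ matrix from a protein-groups table
#'
#' Decoy (`reverse`) and contaminant rows are dropped first (before any
#' replicate filtering), then the design's sample columns are extracted.
#'
#' @param table Protein-groups `data.frame` from [read_protein_groups()].
#' @param design Design `data.frame` from [sample_design()]; `sample_id`
#'   values must name intensity columns of `table`.
#' @param drop_flagged Drop decoy/contaminant rows (default `TRUE`).
#' @return An `lfq_matrix` on the raw scale.
#' @export
as_lfq_matrix <- function(table, design, drop_flagged = TRUE) {
  missing_cols <- setdiff(design$sample_id, names(table))
  if (length(missing_cols) > 0L)
    stop("design references sample column(s) absent from the table: ",
         paste(sQuote(missing_cols), collapse = ", "))
  if (drop_flagged) table <- table[!table$reverse & !table$contaminant, ,
                                   drop = FALSE]
  values <- as.matrix(table[, design$sample_id, drop = FALSE])
  rownames(values) <- table$protein_id
  lfq_matrix(values, scale = "raw")
}

#' Keep proteins quantified in enough bait replicates
#'
#' Retains exactly the proteins with at least `min_valid` present values
#' among the bait-group samples; presence in control samples is not a
#' criterion.  The study design requires quantification in at least two of
#' the three anti-GFP pull-down replicates (two of two for the
#' infected-worm experiment), so `min_valid` may equal the bait replicate
#' count.
#'
#' @param m An `lfq_matrix`.
#' @param design Design `data.frame`.
#' @param min_valid Non-negative integer, at most the number of bait samples.
#' @return The filtered `lfq_matrix`.
#' @export
filter_min_valid <- function(m, design, min_valid = 2L) {
  bait <- design$sample_id[design$group == "bait"]
  missing_cols <- setdiff(design$sample_id, colnames(m$values))
  if (length(missing_cols) > 0L)
    stop("design references sample id(s) absent from the matrix: ",
         paste(sQuote(missing_cols), collapse = ", "))
  if (min_valid > length(bait))
    stop("min_valid exceeds the number of bait samples")
  keep <- rowSums(!is.na(m$values[, bait, drop = FALSE])) >= min_valid
  lfq_matrix(m$values[keep, , drop = FALSE], scale = m$scale,
             imputed = m$imputed[keep, , drop = FALSE])
}

#' Log2-transform a raw-scale LFQ matrix
#'
#' @param m An `lfq_matrix` with scale tag `"raw"`.
#' @return The matrix with every present value replaced by its base-2
#'   logarithm and the scale tag set to `"log2"`; the missing mask is
#'   unchanged.
#' @export
log2_transform <- function(m) {
  if (m$scale != "raw")
    stop("log2_transform requires a raw-scale matrix (already log2?)")
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive intensity for protein ",
         sQuote(rownames(m$values)[bad[1, 1]]), " in sample ",
         sQuote(colnames(m$values)[bad[1, 2]]))
  lfq_matrix(log2(m$values), scale = "log2", imputed = m$imputed)
}

## Deterministic per-column seed stream: changing column order never changes
## the draws assigned to another column name.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 7919 * as.double(index)
  as.integer(s %% 2147483647)
}

#' Impute missing values from a down-shifted normal distribution
#'
#' For each sample column with observed mean `mu` and observed standard
#' deviation `sigma`, every missing value is replaced by an independent draw
#' from `Normal(mu - shift * sigma, width * sigma)`, simulating low-intensity
#' signals below the detection limit (missing-not-at-random).  Defaults
#' `width = 0.3`, `shift = 1.8`.  Draws are reproducible given `seed`: each
#' column uses a stream derived from `(seed, column index)`.
#'
#' @param m An `lfq_matrix` on the log2 scale.
#' @param width Positive spread of the imputation distribution, as a fraction
#'   of the column's observed standard deviation.
#' @param shift Non-negative down-shift, in observed-standard-deviation
#'   units.
#' @param seed Integer seed.
#' @return The `lfq_matrix` with no missing values; imputed cells are marked
#'   in the `imputed` mask.
#' @export
impute_downshifted <- function(m, width = 0.3, shift = 1.8, seed = 1L) {
  if (m$scale != "log2") stop("impute_downshifted requires a log2-scale matrix")
  if (width <= 0) stop("width must be > 0")
  if (shift < 0) stop("shift must be >= 0")
  values <- m$values
  imputed <- m$imputed
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    obs <- col[!is.na(col)]
    n_miss <- sum(is.na(col))
    if (n_miss == 0L) next
    if (length(obs) < 2L)
      stop("sample ", sQuote(colnames(values)[j]),
           " has fewer than 2 observed values; sd undefined")
    mu <- mean(obs)
    sigma <- stats::sd(obs)
    set.seed(derive_seed(seed, j))
    draws <- stats::rnorm(n_miss, mean = mu - shift * sigma,
                          sd = width * sigma)
    miss_idx <- which(is.na(col))
    values[miss_idx, j] <- draws
    imputed[miss_idx, j] <- TRUE
  }
  lfq_matrix(values, scale = m$scale, imputed = imputed)
}

#' Remove cross-reactive proteins from the matrix
#'
#' Proteins binding the affinity resin in a strain lacking the tagged bait
#' are removed before significance calling.  Unknown identifiers are ignored
#' with a message.
#'
#' @param m An `lfq_matrix`.
#' @param blacklist Character vector of protein identifiers.
#' @return The `lfq_matrix` without blacklisted rows.
#' @export
apply_blacklist <- function(m, blacklist) {
  if (length(blacklist) == 0L) return(m)
  hit <- rownames(m$values) %in% blacklist
  unknown <- setdiff(blacklist, rownames(m$values))
  if (length(unknown) > 0L)
    message(length(unknown), " blacklist id(s) not present in the matrix")
  lfq_matrix(m$values[!hit, , drop = FALSE], scale = m$scale,
             imputed = m$imputed[!hit, , drop = FALSE])
}
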