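#' Construct an abundance matrix
#'
#' The pipeline's central object: a proteins x biological-samples matrix of
#' ratio-to-reference values (linear or log2, tracked by a scale attribute)
#' bound to its study design.  Missing entries are permitted and kept
#' explicit — no imputation happens here; downstream operations declare their
#' own missing-data policies.
#'
#' @param values Numeric matrix, rownames = protein ids, colnames = sample
#'   ids matching the design's biological samples.
#' @param design A `study_design`.
#' @param scale Either `"linear_ratio"` or `"log2_ratio"`.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, design, scale = c("linear_ratio", "log2_ratio")) {
  scale <- match.arg(scale)
  validate_study_design(design)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!setequal(colnames(values), design$samples$sample_id)) {
    abort("matrix columns must equal the design's biological samples",
          class = "coabund_design_error")
  }
  values <- values[, design$samples$sample_id, drop = FALSE]
  if (scale == "linear_ratio" && any(values <= 0, na.rm = TRUE)) {
    abort("linear ratios must be positive where present",
          class = "coabund_value_error")
  }
  structure(list(values = values, design = design, scale = scale),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<abundance_matrix> %d proteins x %d samples [%s], %.1f%% missing\n",
              nrow(v), ncol(v), x$scale, 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Long tidy view of an abundance matrix
#'
#' @param x An `abundance_matrix`.
#' @param ... Unused.
#' @return Tibble with `protein_id`, `sample_id`, `value` (missing entries
#'   omitted) joined to the design metadata.
#' @export
tidy.abundance_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "protein_id") %>%
    tidyr::pivot_longer(-protein_id, names_to = "sample_id",
                        values_to = "value") %>%
    filter(!is.na(value)) %>%
    left_join(x$design$samples, by = "sample_id")
}

#' @export
glance.abundance_matrix <- function(x, ...) {
  tibble(n_proteins = nrow(x$values), n_samples = ncol(x$values),
         scale = x$scale, frac_missing = mean(is.na(x$values)),
         n_complete = sum(complete.cases(x$values)))
}

#' Ratios to the reference channel of one plex
#'
#' Converts a plex's linear channel intensities to relative quantitative
#' ratios against the plex's pooled-reference channel, the step that makes
#' plexes comparable.  Proteins whose reference intensity is zero or missing
#' cannot be expressed as ratios; they are dropped and the drop is reported,
#' never silent.
#'
#' @param plex Tibble: `protein_id` plus one numeric column per channel.
#' @param reference_channel Name of the reference column.
#' @return Tibble of ratios with the reference column removed; attributes
#'   `n_dropped` and `dropped_proteins` record exclusions.
#' @examples
#' pl <- tibble::tibble(protein_id = c("a", "b"),
#'                      c1 = c(200, 50), c2 = c(100, 100), c3 = c(100, 100))
#' reference_ratios(pl, "c3")
#' @export
reference_ratios <- function(plex, reference_channel) {
  plex <- as_tibble(plex)
  stopifnot("protein_id" %in% names(plex))
  if (!reference_channel %in% names(plex)) {
    abort(sprintf("reference channel '%s' absent from plex table",
                  reference_channel), class = "coabund_design_error")
  }
  if (anyDuplicated(plex$protein_id) > 0) {
    abort("duplicate protein_id within plex", class = "coabund_value_error")
  }
  ref <- plex[[reference_channel]]
  bad <- is.na(ref) | ref <= 0
  dropped <- plex$protein_id[bad]
  if (length(dropped) > 0) {
    inform(sprintf("reference_ratios: dropped %d protein(s) with zero/absent reference intensity",
                   length(dropped)))
  }
  out <- plex[!bad, , drop = FALSE]
  chans <- setdiff(names(out), c("protein_id", reference_channel))
  out[chans] <- lapply(out[chans], function(v) v / out[[reference_channel]])
  out[[reference_channel]] <- NULL
  attr(out, "n_dropped") <- length(dropped)
  attr(out, "dropped_proteins") <- dropped
  out
}

#' Merge per-plex ratio tables into one abundance matrix
#'
#' Takes the union of proteins across plexes; a protein absent from a plex
#' yields missing entries for that plex's samples.  Columns are mapped from
#' (plex, channel) to sample ids via the design and ordered as in the design.
#'
#' @param ratio_tables Named list of ratio tibbles (names = plex ids), as
#'   produced by [reference_ratios()].
#' @param design A `study_design`.
#' @return A linear-scale `abundance_matrix`.
#' @export
merge_plexes <- function(ratio_tables, design) {
  validate_study_design(design)
  stopifnot(is.list(ratio_tables), !is.null(names(ratio_tables)))
  proteins <- unique(unlist(map(ratio_tables, "protein_id")))
  smp <- design$samples
  values <- matrix(NA_real_, length(proteins), nrow(smp),
                   dimnames = list(proteins, smp$sample_id))
  claimed <- character(0)
  for (p in names(ratio_tables)) {
    tab <- ratio_tables[[p]]
    sub <- smp[smp$plex == p, , drop = FALSE]
    miss <- setdiff(sub$channel, names(tab))
    if (length(miss) > 0) {
      abort(sprintf("plex '%s' is missing channel(s): %s", p,
                    paste(miss, collapse = ", ")),
            class = "coabund_design_error")
    }
    if (any(sub$sample_id %in% claimed)) {
      abort("sample claimed by two plexes", class = "coabund_design_error")
    }
    claimed <- c(claimed, sub$sample_id)
    values[tab$protein_id, sub$sample_id] <-
      as.matrix(tab[, sub$channel, drop = FALSE])
  }
  abundance_matrix(values, design, scale = "linear_ratio")
}

#' Filter proteins by missingness
#'
#' Retains proteins whose fraction of missing sample entries is at most
#' `max_missing_fraction` (boundary inclusive).  The default 0 keeps only
#' complete cases, the conventional choice before correlation-network
#' analysis of plex-based experiments.
#'
#' @param matrix An `abundance_matrix`.
#' @param max_missing_fraction Allowed missing fraction in `[0, 1]`.
#' @return Filtered `abundance_matrix`; attributes `n_retained`/`n_dropped`
#'   report the counts (also messaged).
#' @export
filter_missing <- function(matrix, max_missing_fraction = 0) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(matrix$values))
  keep <- frac <= max_missing_fraction
  inform(sprintf("filter_missing: retained %d of %d proteins (threshold %.3g)",
                 sum(keep), length(keep), max_missing_fraction))
  out <- abundance_matrix(matrix$values[keep, , drop = FALSE], matrix$design,
                          scale = matrix$scale)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Log2-transform a linear ratio matrix
#'
#' @param matrix A linear-scale `abundance_matrix` with positive values.
#' @return The matrix on the log2 scale; missing entries preserved.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$scale != "linear_ratio") {
    abort("log_transform expects a linear_ratio matrix",
          class = "coabund_value_error")
  }
  v <- matrix$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("nonpositive ratio for protein '%s', sample '%s'",
                  rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
          class = "coabund_value_error")
  }
  out <- matrix
  out$values <- log2(v)
  out$scale <- "log2_ratio"
  out
}

#' Inverse of [log_transform()]
#' @param matrix A log2-scale `abundance_matrix`.
#' @return The matrix back on the linear ratio scale.
#' @export
unlog_transform <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$scale != "log2_ratio") {
    abort("unlog_transform expects a log2_ratio matrix",
          class = "coabund_value_error")
  }
  out <- matrix
  out$values <- 2^matrix$values
  out$scale <- "linear_ratio"
  out
}
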