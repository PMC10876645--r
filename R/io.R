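#' Read and write the pipeline's TSV dialects
#'
#' Tab-delimited, UTF-8, first column `protein_id`, header row of sample ids,
#' empty cell = missing.  Readers reject ragged rows.  Round trips are
#' value-exact at the printed precision (15 significant digits).
#'
#' @param matrix An `abundance_matrix`.
#' @param path File path.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_abundance_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  df <- as.data.frame(matrix$values)
  df <- cbind(protein_id = rownames(matrix$values), df)
  write_tsv_plain(df, path)
  invisible(path)
}

#' @rdname matrix_io
#' @param design A `study_design` for the samples in the file.
#' @param scale Scale attribute of the stored values.
#' @export
read_abundance_tsv <- function(path, design, scale = c("linear_ratio", "log2_ratio")) {
  scale <- match.arg(scale)
  df <- read_tsv_strict(path)
  stopifnot(names(df)[1] == "protein_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$protein_id
  abundance_matrix(values, design, scale = scale)
}

#' @rdname matrix_io
#' @export
write_design_tsv <- function(design, path) {
  validate_study_design(design)
  s <- design$samples
  s$reference_channel <- unname(design$reference_channels[s$plex])
  write_tsv_plain(s, path)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_design_tsv <- function(path) {
  df <- read_tsv_strict(path)
  # labels are labels even when they look numeric (e.g. channel "131")
  df <- df %>% mutate(across(dplyr::everything(), as.character))
  ref <- df %>% distinct(plex, reference_channel)
  new_study_design(df %>% select(sample_id, plex, channel, genotype, timepoint),
                   setNames(ref$reference_channel, ref$plex))
}

#' Read / write GMT gene-set files
#'
#' Standard tab-delimited gene-set format: one set per line, fields
#' `set_id`, `description`, then member identifiers.
#'
#' @param path File path.
#' @return `read_gmt()`: tibble with `set_id`, `description` and a
#'   list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]),
          class = "coabund_schema_error")
  }
  tibble(set_id = map_chr(parts, 1),
         description = map_chr(parts, 2),
         members = map(parts, ~ unique(.x[-(1:2)])))
}

#' @rdname read_gmt
#' @param sets Tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("set_id", "description", "members") %in% names(sets)))
  lines <- pmap(list(sets$set_id, sets$description, sets$members),
                function(id, d, m) paste(c(id, d, m), collapse = "\t"))
  writeLines(unlist(lines), path, useBytes = TRUE)
  invisible(path)
}

# -- internal TSV plumbing ---------------------------------------------------

write_tsv_plain <- function(df, path) {
  # 15 significant digits keeps write -> read round trips value-exact
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- ifelse(is.na(v), "", sprintf("%.15g", v))
    out
  })
  readr::write_tsv(df, path, na = "", progress = FALSE)
}

read_tsv_strict <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  if (length(raw) == 0) abort("empty file", class = "coabund_schema_error")
  # field count = tab count + 1 (robust to trailing empty cells)
  nfields <- vapply(gregexpr("\t", raw, fixed = TRUE), function(m) {
    if (m[1] == -1L) 1L else length(m) + 1L
  }, integer(1))
  ncol_hdr <- nfields[1]
  ragged <- which(nfields != ncol_hdr)
  if (length(ragged) > 0) {
    abort(sprintf("ragged row %d: %d fields, expected %d",
                  ragged[1], nfields[ragged[1]], ncol_hdr),
          class = "coabund_schema_error")
  }
  readr::read_tsv(path, na = "", show_col_types = FALSE, progress = FALSE)
}
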