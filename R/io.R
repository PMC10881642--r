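#' Read a cohort table of regional SUVr values
#'
#' Reads a delimited text file (comma- or tab-separated, auto-detected from
#' the header line) holding one row per subject: metadata columns
#' (`subject_id`, `group`, and optionally `age`, `sex`, `site`, `scanner`,
#' `mmse`, `dat_ratio_putamen_L`, `dat_ratio_putamen_R`, `dat_z_left`,
#' `dat_z_right`) followed by the 77 regional global-mean-scaled SUVr
#' columns named after the atlas regions. Region columns are reordered to
#' canonical atlas order. Subjects with any missing regional value are
#' dropped (listwise exclusion) with a message.
#'
#' @param path Path to a CSV/TSV file.
#' @param atlas A `dlb_atlas` (default [hammers_atlas()]).
#' @return A tibble with metadata columns first, then the 77 region columns
#'   in atlas order.
#' @export
read_cohort_table <- function(path, atlas = hammers_atlas()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  df <- tibble::as_tibble(df)
  regions <- atlas_regions(atlas)
  missing_cols <- setdiff(regions, names(df))
  if (length(missing_cols)) {
    stop("input table is missing region column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"subject_id" %in% names(df)) stop("input table needs a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  if ("group" %in% names(df)) {
    unknown <- setdiff(unique(df$group), cohort_groups)
    if (length(unknown)) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "))
    }
  }
  meta_cols <- setdiff(names(df), regions)
  vals <- df[, regions, drop = FALSE]
  complete <- stats::complete.cases(vals)
  if (any(!complete)) {
    message(sum(!complete), " subject(s) excluded listwise for missing regional values: ",
            paste(df$subject_id[!complete], collapse = ", "))
  }
  out <- dplyr::bind_cols(df[complete, meta_cols, drop = FALSE],
                          vals[complete, , drop = FALSE])
  vm <- cohort_values(out, atlas)
  if (any(vm <= 0)) stop("regional SUVr values must be strictly positive")
  out
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble.
#' @param path Output path; written as CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read labelled square matrices
#'
#' Serializes a labelled square matrix (for example a connectivity matrix)
#' as TSV with region names as row and column headers; values round-trip to
#' better than 1e-12. Asymmetric matrices are accepted but flagged with a
#' comment line in the file.
#'
#' @param m A square numeric matrix with identical row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("m must carry identical row and column labels")
  }
  con <- file(path, "w")
  on.exit(close(con))
  sym <- isTRUE(all.equal(m, t(m), tolerance = 0))
  writeLines(paste0("# symmetric: ", if (sym) "true" else "false"), con)
  writeLines(paste(c("region", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = lines, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a structured report
#'
#' Serializes a (possibly nested) list of tables and scalars as JSON.
#'
#' @param x A list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
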