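#' Construct a study table of gene-level EST expression profiles
#'
#' A study table holds one row per gene with non-negative integer
#' transcripts-per-million (TPM) values for the three compared tissues:
#' mammary (`tpm_ma`), skin (`tpm_s`) and muscle (`tpm_mu`). Optional
#' columns `tpm_adult` / `tpm_young` carry stage-specific TPMs and
#' `bioprocess` a functional category label. Row order is preserved
#' throughout the pipeline.
#'
#' @param df A data frame with at least columns `gene`, `tpm_ma`, `tpm_s`,
#'   `tpm_mu`.
#' @param source_label Free-text provenance, stored as an attribute.
#' @return A tibble of class `study_table`.
#' @seealso [read_study_table()]
#' @export
study_table <- function(df, source_label = "unspecified") {
  df <- tibble::as_tibble(df)
  required <- c("gene", "tpm_ma", "tpm_s", "tpm_mu")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_enorthern(
      paste0("study table is missing column(s): ", paste(missing, collapse = ", ")),
      "enorthern_validation_error"
    )
  }
  if (nrow(df) == 0) {
    stop_enorthern("study table has no rows", "enorthern_validation_error")
  }
  if (!("bioprocess" %in% names(df))) df$bioprocess <- "unannotated"
  df$gene <- as.character(df$gene)
  if (any(!nzchar(df$gene) | is.na(df$gene))) {
    stop_enorthern("gene symbols must be non-empty", "enorthern_validation_error")
  }
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0) {
    stop_enorthern(
      paste0("duplicate gene symbol(s): ", paste(dup, collapse = ", ")),
      "enorthern_validation_error"
    )
  }
  tpm_cols <- intersect(c("tpm_ma", "tpm_s", "tpm_mu", "tpm_adult", "tpm_young"), names(df))
  for (col in tpm_cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      stop_enorthern(paste0(col, " must be numeric"), "enorthern_validation_error")
    }
    ok <- is.na(x) | (x >= 0 & x <= 1e6 & x == trunc(x))
    if (!all(ok)) {
      bad <- df$gene[!ok][1]
      stop_enorthern(
        paste0(col, " must be an integer in [0, 1e6]; offending gene: ", bad),
        "enorthern_validation_error"
      )
    }
    if (col %in% c("tpm_ma", "tpm_s", "tpm_mu") && anyNA(x)) {
      stop_enorthern(paste0(col, " must not contain missing values"),
                     "enorthern_validation_error")
    }
    df[[col]] <- as.integer(x)
  }
  attr(df, "source_label") <- source_label
  class(df) <- c("study_table", class(df))
  df
}

#' Read a gene x tissue TPM table from TSV
#'
#' Parses a UTF-8 tab-delimited file with a header row naming at least
#' `gene`, `tpm_ma`, `tpm_s` and `tpm_mu` (names remappable through
#' `col_map`). TPM cells must be plain non-negative integers: empty cells
#' and the em-dash placeholder are rejected with the offending line number,
#' because a dash is only meaningful in derived output columns, never in
#' input TPMs. Optional `tpm_adult` / `tpm_young` columns may contain empty
#' cells, which become missing stage TPMs.
#'
#' @param path Path to a TSV file.
#' @param dialect Input dialect; only `"tsv"` is supported.
#' @param col_map Named character vector mapping canonical names
#'   (`gene`, `bioprocess`, `tpm_ma`, `tpm_s`, `tpm_mu`, `tpm_adult`,
#'   `tpm_young`) to the header names used in the file.
#' @return A [study_table()].
#' @examples
#' tab <- read_study_table(enorthern_example("table2.tsv"))
#' nrow(tab)
#' @export
read_study_table <- function(path, dialect = "tsv", col_map = NULL) {
  if (!identical(dialect, "tsv")) {
    stop_enorthern(paste0("unsupported dialect: ", dialect), "enorthern_validation_error")
  }
  if (!file.exists(path)) {
    stop_enorthern(paste0("file not found: ", path), "enorthern_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  canonical <- c("gene", "bioprocess", "tpm_ma", "tpm_s", "tpm_mu", "tpm_adult", "tpm_young")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  for (canon in names(map)) {
    file_name <- map[[canon]]
    if (file_name %in% names(raw) && canon != file_name) {
      names(raw)[names(raw) == file_name] <- canon
    }
  }
  required <- c("gene", "tpm_ma", "tpm_s", "tpm_mu")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_enorthern(
      paste0("header is missing column(s): ", paste(missing, collapse = ", ")),
      "enorthern_parse_error"
    )
  }
  tpm_cols <- intersect(c("tpm_ma", "tpm_s", "tpm_mu", "tpm_adult", "tpm_young"), names(raw))
  optional <- c("tpm_adult", "tpm_young")
  for (col in tpm_cols) {
    cells <- raw[[col]]
    blank <- !nzchar(trimws(cells))
    if (col %in% optional) {
      cells[blank] <- NA_character_
      blank <- rep(FALSE, length(cells))
    }
    malformed <- !is.na(cells) & (blank | !grepl("^-?[0-9]+$", trimws(cells)))
    if (any(malformed)) {
      line <- which(malformed)[1] + 1L  # header is line 1
      stop_enorthern(
        paste0("line ", line, ": column '", col, "' has non-integer TPM cell '",
               cells[malformed][1], "'"),
        "enorthern_parse_error"
      )
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(!is.na(vals) & vals < 0)) {
      line <- which(!is.na(vals) & vals < 0)[1] + 1L
      stop_enorthern(paste0("line ", line, ": negative TPM in column '", col, "'"),
                     "enorthern_validation_error")
    }
    raw[[col]] <- vals
  }
  keep <- intersect(canonical, names(raw))
  study_table(raw[keep], source_label = path)
}

#' Write a results table as TSV
#'
#' Writes the derived statistics in the layout of the source study:
#' columns `gene`, `tpm_ma`, `tpm_s`, `tpm_mu`, `pct_abundance`,
#' `ratio_ma_s`, `e_r`, `status`. Undefined statistics are rendered as an
#' em-dash; defined values with exactly `decimals` decimal places.
#'
#' @param results Result tibble from [run_enorthern()].
#' @param path Output file path.
#' @param decimals Decimal places for numeric cells (default 3).
#' @return Invisibly, the path written.
#' @export
write_results_table <- function(results, path, decimals = 3) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop_enorthern("results must be a non-empty data frame", "enorthern_validation_error")
  }
  out <- tibble::tibble(
    gene = results$gene,
    tpm_ma = results$tpm_ma,
    tpm_s = results$tpm_s,
    tpm_mu = results$tpm_mu,
    pct_abundance = format_cell(results$pct_abundance, decimals),
    ratio_ma_s = format_cell(results$ratio_ma_s, decimals),
    e_r = format_cell(results$e_r, decimals),
    status = as.character(results$status)
  )
  ok <- tryCatch({
    readr::write_tsv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_enorthern(paste0("cannot write results to: ", path), "enorthern_io_error")
  }
  invisible(path)
}

#' Gene symbol aliases for network joins
#'
#' The bundled 45-gene milk-fat panel uses the symbols of its source study
#' verbatim (e.g. `ADFP`, `ASAHL`, `LASS2`). Interaction databases such as
#' STRING label the same proteins with current HGNC symbols, so joining the
#' panel against an edge list may need translation. Returns a two-column
#' tibble mapping panel symbols to current symbols for the genes whose names
#' have changed.
#'
#' @return A tibble with columns `panel_symbol` and `current_symbol`.
#' @examples
#' gene_aliases()
#' @export
gene_aliases <- function() {
  tibble::tribble(
    ~panel_symbol, ~current_symbol,
    "ACBP",   "DBI",
    "ADFP",   "PLIN2",
    "AGPAT6", "GPAT4",
    "ASAHL",  "NAAA",
    "LASS2",  "CERS2",
    "PLIN",   "PLIN1"
  )
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
enorthern_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "enorthern"))
  } else {
    path <- system.file("extdata", file, package = "enorthern")
    if (!nzchar(path)) {
      stop_enorthern(paste0("no bundled file called '", file, "'"), "enorthern_io_error")
    }
    path
  }
}
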