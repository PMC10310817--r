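# Readers/writers and validation for the three table types the analysis
# consumes: per-lineage growth trajectories, estradiol concentrations, and
# (cell number, area, fluorescence) calibration records.

.schemas <- list(
  growth = list(
    cols = c("cell_line", "composition", "lineage", "replicate", "day",
             "dose_nM", "modifier", "modifier_dose_nM", "count"),
    numeric = c("composition", "replicate", "day", "dose_nM",
                "modifier_dose_nM", "count")
  ),
  estradiol = list(
    cols = c("sample_id", "s_cells", "r_cells", "dose_nM", "estradiol_pg_ml"),
    numeric = c("s_cells", "r_cells", "dose_nM", "estradiol_pg_ml")
  ),
  calibration = list(
    cols = c("n_sensitive", "n_resistant", "area", "fluor_s", "fluor_r"),
    numeric = c("n_sensitive", "n_resistant", "area", "fluor_s", "fluor_r")
  )
)

check_numeric_cols <- function(df, cols, schema) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad) > 0)
        stop_("parse error in %s table: column '%s' is non-numeric at row %d",
              schema, cl, bad[1])
      df[[cl]] <- num
    }
  }
  df
}

validate_rows <- function(df, schema) {
  s <- .schemas[[schema]]
  missing <- setdiff(s$cols, names(df))
  if (length(missing) > 0)
    stop_("schema error: %s table is missing required column(s): %s",
          schema, paste(missing, collapse = ", "))
  df <- df[, s$cols, drop = FALSE]
  df <- check_numeric_cols(df, s$numeric, schema)

  if (schema == "growth") {
    bad <- which(!is.finite(df$count) | df$count < 0)
    if (length(bad) > 0)
      stop_("parse error in growth table: negative or non-finite count at row %d",
            bad[1])
    if (any(df$composition < 0 | df$composition > 1))
      stop_("growth table: composition must lie in [0, 1]")
    if (any(df$day < 0)) stop_("growth table: day must be non-negative")
    if (any(df$dose_nM < 0)) stop_("growth table: dose_nM must be non-negative")
    key <- interaction(df$cell_line, df$composition, df$lineage,
                       df$replicate, df$dose_nM, df$modifier,
                       df$modifier_dose_nM, drop = TRUE)
    for (k in levels(key)) {
      d <- df$day[key == k]
      if (anyDuplicated(d))
        stop_("growth table: duplicated day within replicate series '%s'", k)
    }
  } else if (schema == "estradiol") {
    if (any(df$estradiol_pg_ml < 0))
      stop_("estradiol table: concentrations must be >= 0")
    if (any(df$s_cells < 0 | df$r_cells < 0))
      stop_("estradiol table: cell counts must be >= 0")
    df$below_llod <- df$estradiol_pg_ml == 0
  } else if (schema == "calibration") {
    for (cl in s$numeric)
      if (any(df[[cl]] < 0))
        stop_("calibration table: column '%s' must be >= 0", cl)
  }
  attr(df, "schema") <- schema
  df
}

#' Read a validated analysis table
#'
#' Reads a delimiter-separated text file with a header row and validates it
#' against one of the three table schemas used throughout the package.
#' Row order is preserved.
#'
#' @param path path to a CSV file.
#' @param schema one of `"growth"`, `"estradiol"`, `"calibration"`.
#' @return a validated `data.frame`; estradiol tables gain a logical
#'   `below_llod` column (zero concentrations are flagged).
#' @export
#' @examples
#' tab <- gen_logistic(r = 0.3, K = 2e4, n0 = 500, days = c(4, 7, 11),
#'                     reps = 2, noise = noise_spec(0.1, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_table(tab, f)
#' identical(dim(read_table(f, "growth")), dim(tab))
read_table <- function(path, schema = c("growth", "estradiol", "calibration")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_rows(df, schema)
}

#' Write a validated analysis table
#'
#' Writes a table in the fixed column order of its schema so that
#' `read_table()` round-trips it (values preserved to at least 12
#' significant digits).
#'
#' @param rows a table previously validated (or produced by a generator).
#' @param path output file path.
#' @param schema schema name; defaults to the table's recorded schema.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, schema = NULL) {
  schema <- schema %||% attr(rows, "schema")
  if (is.null(schema)) stop_("cannot infer schema; pass `schema` explicitly")
  rows <- validate_rows(as.data.frame(rows), schema)
  out <- rows[, .schemas[[schema]]$cols, drop = FALSE]
  ok <- tryCatch({
    write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_("could not write table to '%s'", path)
  invisible(path)
}

#' Summarise the experimental design of a growth table
#'
#' Reports the unique dose set, compositions, replicate counts per condition
#' and the day grid, and flags conditions observed at fewer than two time
#' points (which no growth model can be fitted to).
#'
#' @param rows a validated growth table.
#' @return an object of class `design_summary` with elements `doses`,
#'   `compositions`, `replicates` (per-condition data frame), `day_grid`,
#'   and `flagged` (conditions with < 2 time points or a single replicate).
#' @export
validate_design <- function(rows) {
  rows <- validate_rows(as.data.frame(rows), "growth")
  if (nrow(rows) == 0) stop_("empty growth table")
  cond <- interaction(rows$cell_line, rows$composition, rows$dose_nM,
                      rows$modifier, rows$modifier_dose_nM,
                      drop = TRUE, sep = "|")
  reps <- do.call(rbind, lapply(levels(cond), function(k) {
    d <- rows[cond == k, ]
    data.frame(condition = k,
               n_replicates = length(unique(d$replicate)),
               n_timepoints = length(unique(d$day)),
               stringsAsFactors = FALSE)
  }))
  flagged <- reps$condition[reps$n_timepoints < 2 | reps$n_replicates < 2]
  structure(list(
    doses = sort(unique(rows$dose_nM)),
    compositions = sort(unique(rows$composition)),
    replicates = reps[order(reps$condition), , drop = FALSE],
    day_grid = sort(unique(rows$day)),
    flagged = as.character(flagged)
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Spheroid panel design\n")
  cat("  doses (nM):    ", paste(x$doses, collapse = ", "), "\n")
  cat("  compositions:  ", paste(x$compositions, collapse = ", "), "\n")
  cat("  day grid:      ", paste(x$day_grid, collapse = ", "), "\n")
  cat("  conditions:    ", nrow(x$replicates), "\n")
  if (length(x$flagged) > 0)
    cat("  flagged (<2 time points or single replicate):",
        length(x$flagged), "\n")
  invisible(x)
}
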