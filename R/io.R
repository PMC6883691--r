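#' Read a region-state BED file
#'
#' The file is tab-separated with a header line (optionally prefixed `#`)
#' naming at least `chrom`, `start`, `end`, optionally `region_id`, plus one
#' binary 0/1 column per cell type. Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @param state_columns character vector naming the K cell-type columns;
#'   defaults to every column after the coordinate/id columns.
#' @return A [region_state_matrix()].
#' @export
read_regions <- function(path, state_columns = NULL) {
  .stop_if(!file.exists(path), "file not found: ", path)
  header <- readLines(path, n = 1L)
  header <- sub("^#", "", header)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          check.names = FALSE)
  .stop_if(!all(c("chrom", "start", "end") %in% cols),
           "region file must have chrom/start/end columns; got: ",
           paste(cols, collapse = ", "))
  if (is.null(state_columns)) {
    state_columns <- setdiff(cols, c("chrom", "start", "end", "region_id"))
  }
  .stop_if(length(state_columns) == 0, "no cell-type state columns found")
  missing_cols <- setdiff(state_columns, cols)
  .stop_if(length(missing_cols) > 0, "state columns absent from file: ",
           paste(missing_cols, collapse = ", "))
  suppressWarnings({
    st <- as.integer(df$start); en <- as.integer(df$end)
  })
  .stop_if(anyNA(st) || anyNA(en), "malformed coordinates in ", path)
  Z <- as.matrix(df[, state_columns, drop = FALSE])
  region_state_matrix(df[, intersect(c("chrom", "start", "end", "region_id"),
                                     cols), drop = FALSE], Z,
                      cell_types = state_columns)
}

#' Write a region-state matrix as a BED-style file with state columns
#'
#' @param rsm a [region_state_matrix()].
#' @param path output path.
#' @export
write_regions <- function(rsm, path) {
  df <- cbind(rsm$regions[, c("chrom", "start", "end", "region_id")],
              as.data.frame(rsm$Z, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chrom", "start", "end", "region_id", rsm$cell_types),
                   collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a beta-value table (one sample per column)
#'
#' Expects a tab- or comma-separated file with header columns `cpg_id`,
#' `chrom`, `pos` followed by one beta column per sample. Positions are
#' 0-based. Returns one [cpg_measurement_table()] per sample column.
#'
#' @param path file path.
#' @param clamp clip betas slightly outside \[0, 1\]; without it values more
#'   than 1e-9 outside the unit interval raise an error.
#' @param platform platform tag attached to each sample table.
#' @return A named list of `CpGMeasurementTable` objects.
#' @export
read_beta_table <- function(path, clamp = FALSE, platform = "array") {
  .stop_if(!file.exists(path), "file not found: ", path)
  sep <- if (grepl(",", readLines(path, n = 1L), fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .stop_if(!all(c("cpg_id", "chrom", "pos") %in% names(df)),
           "beta table needs columns cpg_id, chrom, pos")
  samples <- setdiff(names(df), c("cpg_id", "chrom", "pos"))
  .stop_if(length(samples) == 0, "no sample beta columns in ", path)
  out <- lapply(samples, function(s) {
    cpg_measurement_table(s, df$chrom, df$pos, beta = df[[s]],
                          cpg_id = df$cpg_id, platform = platform,
                          clamp = clamp)
  })
  names(out) <- samples
  out
}

#' Write a list of array-style measurement tables as one beta table
#'
#' All tables must share an identical CpG grid. Values are written with 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param tables list of `CpGMeasurementTable` (array type).
#' @param path output path.
#' @export
write_beta_table <- function(tables, path) {
  if (inherits(tables, "CpGMeasurementTable")) tables <- list(tables)
  base <- tables[[1]]$data[, c("cpg_id", "chrom", "pos")]
  out <- base
  for (tb in tables) {
    .stop_if(!identical(tb$data$cpg_id, base$cpg_id),
             "all samples must share the same CpG grid")
    out[[tb$sample_id]] <- sprintf("%.17g", tb$data$level)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Six tab-separated columns without header: chromosome, start (1-based),
#' end (1-based inclusive), methylation percentage, methylated count,
#' unmethylated count. Positions are converted to the package's 0-based
#' convention. CpGs with zero total coverage are kept with a missing level.
#'
#' @param path file path.
#' @param sample_id sample name (defaults to the file name).
#' @param platform platform tag.
#' @return A `CpGMeasurementTable` (sequencing type).
#' @export
read_bismark_coverage <- function(path, sample_id = NULL,
                                  platform = "sequencing") {
  .stop_if(!file.exists(path), "file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  .stop_if(ncol(df) < 6, "Bismark coverage files have 6 columns; got ", ncol(df))
  cpg_measurement_table(sample_id, chrom = df[[1]], pos = df[[2]] - 1L,
                        meth = df[[5]], unmeth = df[[6]], platform = platform)
}

#' Write a sequencing-style measurement table in Bismark coverage format
#'
#' @param table a `CpGMeasurementTable` of type "sequencing".
#' @param path output path.
#' @export
write_bismark_coverage <- function(table, path) {
  .stop_if(table$type != "sequencing", "coverage output needs count data")
  d <- table$data
  pct <- ifelse(is.na(d$level), 0, 100 * d$level)
  out <- data.frame(d$chrom, d$pos + 1L, d$pos + 1L, sprintf("%.6g", pct),
                    d$meth, d$unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a region-level methylation matrix as TSV
#'
#' Region ids as rows, sample ids as columns; missing entries are `NA`.
#'
#' @param rmm a [region_methylation_matrix()].
#' @param path output path.
#' @export
write_region_matrix <- function(rmm, path) {
  out <- data.frame(region_id = rownames(rmm$Y),
                    rmm$Y, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a composition estimate as TSV (samples x cell types)
#'
#' @param est a [composition_estimate()].
#' @param path output path.
#' @export
write_composition <- function(est, path) {
  out <- data.frame(sample_id = est$sample_ids, est$pi, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-type reference profile (CpG id x cell type TSV)
#'
#' @param path TSV with header `cpg_id` followed by one column per cell type.
#' @return A [cell_type_reference_profile()].
#' @export
read_reference_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .stop_if(!"cpg_id" %in% names(df), "reference profile needs a cpg_id column")
  X <- as.matrix(df[, setdiff(names(df), "cpg_id"), drop = FALSE])
  cell_type_reference_profile(df$cpg_id, X)
}
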