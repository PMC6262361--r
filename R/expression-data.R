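# Expression time-series input/output and validation.
#
# The working representation of a dataset is a long tibble with columns
# gene, condition, time, mean, sd -- one row per observed point.  The five
# target genes (TFL1a, TFL1c, FD, LFY, AP1) are fit targets; the FT homologs
# are drivers whose traces force the model and whose rows never count
# towards the data-point total m.

#' Read an expression time-series table
#'
#' Reads a long-format delimited table of expression means and standard
#' deviations (columns `gene`, `condition`, `time`, `mean`, `sd`; one row
#' per observation) and returns a validated tibble.  Times are days after
#' sowing; expression is in relative (arbitrary) units.
#'
#' Zero or near-zero standard deviations are floored at
#' `max(sd_floor_abs, sd_floor_rel * max(mean))` per (gene, condition)
#' series so that the weighted residual sum of squares stays finite.
#'
#' @param path Path to a TSV/CSV file.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param cultivar Optional cultivar label attached as an attribute.
#' @param sd_floor_abs,sd_floor_rel Absolute and relative floor applied to
#'   the per-point standard deviations (see Details).
#' @return A tibble of class `grn_expression` with columns
#'   `gene`, `condition`, `time`, `mean`, `sd`, sorted by gene, condition
#'   and time.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_expression.tsv", package = "flornet")
#' dat <- read_expression_table(path)
#' n_data_points(dat)
read_expression_table <- function(path,
                                  format = c("auto", "tsv", "csv"),
                                  cultivar = NULL,
                                  sd_floor_abs = 1e-6,
                                  sd_floor_rel = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "flornet_format_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) {
      abort(paste0("cannot parse expression table: ", conditionMessage(e)),
            class = "flornet_format_error")
    }
  )
  if (nrow(raw) == 0) {
    abort("expression table is empty", class = "flornet_format_error")
  }
  as_expression_data(raw, cultivar = cultivar,
                     sd_floor_abs = sd_floor_abs, sd_floor_rel = sd_floor_rel)
}

#' Coerce and validate a data frame of expression observations
#'
#' @param x A data frame with columns `gene`, `condition`, `time`, `mean`, `sd`.
#' @inheritParams read_expression_table
#' @return A validated `grn_expression` tibble.
#' @export
as_expression_data <- function(x, cultivar = NULL,
                               sd_floor_abs = 1e-6, sd_floor_rel = 0.01) {
  required <- c("gene", "condition", "time", "mean", "sd")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "flornet_format_error")
  }
  dat <- tibble::as_tibble(x[required])
  dat$gene <- as.character(dat$gene)
  dat$condition <- as.character(dat$condition)
  for (col in c("time", "mean", "sd")) {
    dat[[col]] <- as.numeric(dat[[col]])
    if (anyNA(dat[[col]])) {
      abort(paste0("non-numeric or missing values in column '", col, "'"),
            class = "flornet_validation_error")
    }
  }
  if (any(dat$mean < 0)) {
    abort("negative expression means are not allowed",
          class = "flornet_validation_error")
  }
  if (any(dat$sd < 0)) {
    abort("negative standard deviations are not allowed",
          class = "flornet_validation_error")
  }
  key <- paste(dat$gene, dat$condition, dat$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- dat[duplicated(key), , drop = FALSE]
    abort(paste0("duplicated (gene, condition, time) row(s), e.g. ",
                 dup$gene[1], "/", dup$condition[1], " at t = ", dup$time[1]),
          class = "flornet_validation_error")
  }
  dat <- dplyr::arrange(dat, .data$gene, .data$condition, .data$time)
  # strictly increasing times within each series is now guaranteed by the
  # sort + duplicate check; series need >= 1 point by construction
  dat <- dat |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::mutate(sd = pmax(.data$sd,
                            max(sd_floor_abs, sd_floor_rel * max(.data$mean)))) |>
    dplyr::ungroup()
  structure(dat,
            class = c("grn_expression", class(dat)),
            cultivar = cultivar %||% attr(x, "cultivar", exact = TRUE))
}

#' Write an expression table back to disk
#'
#' Inverse of [read_expression_table()]; writes the long-format table with a
#' header row.
#'
#' @param data An expression tibble.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  write.table(as.data.frame(data[c("gene", "condition", "time", "mean", "sd")]),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count model-fitting data points
#'
#' The data-point total m used by the information criterion counts only the
#' target-gene observations (FT homologs are drivers, not fit targets).
#' A 5-gene, 7-time-point, 2-condition dataset has m = 70; a single
#' condition gives m = 35.
#'
#' @param data An expression tibble.
#' @param conditions Conditions to count (default: all present).
#' @param targets Genes counted as fit targets.
#' @return Integer number of data points.
#' @export
n_data_points <- function(data, conditions = NULL, targets = target_genes()) {
  conditions <- conditions %||% unique(data$condition)
  sum(data$gene %in% targets & data$condition %in% conditions)
}

#' Summarize a dataset as a descriptor list
#'
#' @param data An expression tibble.
#' @param path Optional path; when given the descriptor is written as JSON.
#' @return A list with cultivar, genes, conditions and point counts.
#' @export
dataset_descriptor <- function(data, path = NULL) {
  desc <- list(
    cultivar = attr(data, "cultivar", exact = TRUE) %||% NA_character_,
    genes = sort(unique(data$gene)),
    conditions = sort(unique(data$condition)),
    n_rows = nrow(data),
    n_target_points = n_data_points(data),
    points_per_series = stats::setNames(
      as.list(table(paste(data$gene, data$condition, sep = ":"))), NULL)
  )
  desc$points_per_series <- as.list(table(paste(data$gene, data$condition, sep = ":")))
  if (!is.null(path)) {
    jsonlite::write_json(desc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  desc
}

#' Check that a dataset is fittable
#'
#' A fittable dataset contains all five target genes and at least one FT
#' driver in every requested condition.
#'
#' @param data An expression tibble.
#' @param conditions Conditions that must be complete.
#' @return `data`, invisibly; errors otherwise.
#' @export
assert_fittable <- function(data, conditions = photoperiod_conditions()) {
  for (cond in conditions) {
    genes <- unique(data$gene[data$condition == cond])
    missing_targets <- setdiff(target_genes(), genes)
    if (length(missing_targets) > 0) {
      abort(paste0("condition ", cond, " lacks target gene(s): ",
                   paste(missing_targets, collapse = ", ")),
            class = "flornet_validation_error")
    }
    if (!any(ft_genes() %in% genes)) {
      abort(paste0("condition ", cond, " has no FT driver series"),
            class = "flornet_validation_error")
    }
  }
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
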