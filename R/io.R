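# Reading plate setups and data groups; writing inputs, result tables and
# run logs.
#
# Exchange formats (all text, UTF-8, '.' decimal point, blank field = blank
# well):
#   * layout CSV: the plate-setup matrix, one well per field, from the top
#     left corner;
#   * data CSV: group blocks stacked vertically — a row whose first field
#     holds the group name, then exactly the layout's rows of values, blocks
#     separated by >= 1 fully blank row; alternatively one CSV per group,
#     named by file stem;
#   * .xlsx workbooks with sheets "PlateSetup" and "Data" (same stacked
#     block convention) are read via readxl.
# Results are written as tab-separated sheet files (results, aggregated,
# outliers, config) — plain text diffs and versions cleanly and needs no
# spreadsheet program to inspect.

#' Read a plate layout and data groups from files
#'
#' @param layout_source Path to the layout: a CSV matrix, or an `.xlsx`
#'   workbook (sheet `"PlateSetup"`; `data_source` may then be the same
#'   workbook, sheet `"Data"`).
#' @param data_source Path(s) to the observed values: one stacked-block CSV,
#'   several per-group CSVs, or an `.xlsx` workbook.
#' @return A list with `layout` (a `plate_layout`) and `data` (a
#'   `plate_data` with all groups).
#' @export
read_inputs <- function(layout_source, data_source) {
  layout <- read_layout(layout_source)
  data <- read_groups(data_source, layout)
  list(layout = layout, data = data)
}

read_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("layout source not found: ", path))
  cells <- if (is_xlsx(path)) {
    read_sheet_matrix(path, "PlateSetup")
  } else {
    read_csv_matrix(path)
  }
  parse_layout(cells)
}

read_groups <- function(paths, layout) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("data source not found: ", paste(missing, collapse = ", ")))
  }
  if (length(paths) == 1L && is_xlsx(paths)) {
    return(parse_blocks(read_sheet_matrix(paths, "Data"), layout,
                        source = paste0(paths, "#Data")))
  }
  if (length(paths) == 1L) {
    m <- read_csv_matrix(paths)
    if (has_blocks(m, layout)) {
      return(parse_blocks(m, layout, source = paths))
    }
    # single bare matrix: one group named after the file
    return(bind_group(layout, file_stem(paths), m))
  }
  groups <- lapply(paths, function(p) {
    bind_group(layout, file_stem(p), read_csv_matrix(p))
  })
  bind_groups(groups)
}

is_xlsx <- function(path) grepl("\\.xlsx?$", path, ignore.case = TRUE)

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

# raw cell matrix of a CSV, preserving blanks; no headers anywhere
read_csv_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  ncol <- max(lengths(fields), 1L)
  m <- matrix("", nrow = length(lines), ncol = ncol)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f)) m[i, seq_along(f)] <- f
  }
  m
}

read_sheet_matrix <- function(path, sheet) {
  df <- readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                           col_types = "text", .name_repair = "minimal")
  m <- as.matrix(df)
  m[is.na(m)] <- ""
  m
}

blank_row <- function(m, i) all(trimws(m[i, ]) == "")

has_blocks <- function(m, layout) {
  # a stacked-block file starts with a name row: first field non-numeric text
  first <- trimws(m[1, 1])
  nzchar(first) && is.na(suppressWarnings(as.numeric(first)))
}

parse_blocks <- function(m, layout, source = "") {
  d <- layout_dims(layout)
  groups <- list()
  i <- 1L
  while (i <= nrow(m)) {
    if (blank_row(m, i)) {
      i <- i + 1L
      next
    }
    name <- trimws(m[i, which(nzchar(trimws(m[i, ])))[1]])
    if (!is.na(suppressWarnings(as.numeric(name)))) {
      abort(sprintf(
        "malformed data block starting at row %d of %s: expected a group name, found '%s'",
        i, source, name
      ))
    }
    if (i + d[1] > nrow(m)) {
      abort(sprintf(
        "malformed data block '%s' starting at row %d of %s: needs %d data rows",
        name, i, source, d[1]
      ))
    }
    block <- m[(i + 1L):(i + d[1]), , drop = FALSE]
    if (any(vapply(seq_len(nrow(block)), function(j) blank_row(block, j), logical(1)))) {
      abort(sprintf(
        "malformed data block '%s' starting at row %d of %s: blank row inside the block",
        name, i, source
      ))
    }
    if (ncol(block) < d[2]) {
      abort(sprintf(
        "malformed data block '%s' starting at row %d of %s: %d columns, layout has %d",
        name, i, source, ncol(block), d[2]
      ))
    }
    extra <- block[, -seq_len(d[2]), drop = FALSE]
    if (length(extra) && any(nzchar(trimws(extra)))) {
      abort(sprintf(
        "malformed data block '%s' starting at row %d of %s: values beyond layout column %d",
        name, i, source, d[2]
      ))
    }
    groups[[length(groups) + 1L]] <- bind_group(layout, name, block[, seq_len(d[2]), drop = FALSE])
    i <- i + d[1] + 1L
  }
  if (!length(groups)) abort(paste0("no data blocks found in ", source))
  bind_groups(groups)
}

#' Write a layout and data groups as a CSV pair
#'
#' Writes the formats [read_inputs()] reads: the layout matrix and the
#' stacked named data blocks. Numbers are written with full round-trip
#' precision, so write-then-read reproduces the matrices exactly.
#'
#' @param layout A `plate_layout`.
#' @param data A `plate_data` (one or more groups).
#' @param layout_path,data_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_inputs <- function(layout, data, layout_path, data_path) {
  write_matrix_csv(layout_matrix(layout), layout_path)
  d <- layout_dims(layout)
  lines <- character()
  for (g in unique(data$group)) {
    sub <- data[data$group == g, ]
    m <- matrix(NA_real_, d[1], d[2])
    m[cbind(sub$row + 1L, sub$col + 1L)] <- sub$value
    lines <- c(lines, g, matrix_csv_lines(m), "")
  }
  writeLines(lines, data_path)
  invisible(c(layout_path, data_path))
}

num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

matrix_csv_lines <- function(m) {
  apply(m, 1, function(r) paste(num_chr(r), collapse = ","))
}

write_matrix_csv <- function(m, path) {
  writeLines(matrix_csv_lines(m), path)
}

#' Write the result tables of an analysis run
#'
#' Writes four tab-separated sheet files into `out_dir`: `results.tsv` (one
#' row per group: fitted parameters, standard errors, goodness of fit,
#' outlier counts), `aggregated.tsv` (per group and test: mean, variation,
#' replicate count), `outliers.tsv` (every flagged well with its Grubbs
#' statistic and critical value) and `config.tsv` (an echo of the run
#' settings). Output is deterministic: identical runs produce byte-identical
#' files.
#'
#' @param run A `platefit_run` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_results <- function(run, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    abort(paste0("output directory not writable: ", out_dir))
  }
  paths <- c(
    results = file.path(out_dir, "results.tsv"),
    aggregated = file.path(out_dir, "aggregated.tsv"),
    outliers = file.path(out_dir, "outliers.tsv"),
    config = file.path(out_dir, "config.tsv")
  )
  write_tsv_plain(run$results, paths["results"])
  write_tsv_plain(run$aggregated, paths["aggregated"])
  write_tsv_plain(run$outlier_report, paths["outliers"])
  cfg <- run$config
  cfg$out_dir <- NULL # where the sheets live, not part of the analysis
  cfg_tbl <- tibble(
    key = names(cfg),
    value = vapply(cfg, function(v) {
      if (is.null(v)) "" else paste(format(v, digits = 17, trim = TRUE), collapse = ";")
    }, character(1))
  )
  write_tsv_plain(cfg_tbl, paths["config"])
  invisible(paths)
}

# readr-free TSV writer with fixed number formatting => byte-stable output
write_tsv_plain <- function(df, path) {
  df <- as_tibble(df)
  fmt <- function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "", vapply(col, format, character(1),
                                    digits = 17, scientific = TRUE, trim = TRUE))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }
  body <- if (nrow(df)) {
    do.call(paste, c(lapply(df, fmt), sep = "\t"))
  } else {
    character()
  }
  writeLines(c(paste(names(df), collapse = "\t"), body), path)
}

#' Write the per-stage run log
#'
#' One timestamped block per pipeline stage per group, recording what each
#' stage consumed and produced (reference means, flagged wells, start and
#' final parameters, goodness of fit). Skipped stages are logged as skipped.
#'
#' @param run A `platefit_run`.
#' @param path Output file (default `run.log` in the run's output dir).
#' @return Invisibly, the path.
#' @export
write_log <- function(run, path = file.path(run$config$out_dir, "run.log")) {
  ok <- tryCatch({
    writeLines(format_log(run$log), path)
    TRUE
  }, error = function(e) {
    warning("could not write log: ", conditionMessage(e), call. = FALSE)
    FALSE
  })
  invisible(if (ok) path else NA_character_)
}

format_log <- function(log) {
  unlist(lapply(seq_len(nrow(log)), function(i) {
    c(
      sprintf("[%s] group=%s stage=%s", log$time[i], log$group[i], log$stage[i]),
      paste0("  ", strsplit(log$detail[i], "\n", fixed = TRUE)[[1]]),
      ""
    )
  }))
}
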