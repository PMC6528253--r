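# Plate layout: which wells are replicates of which test value.

#' Convert 0-based well coordinates to an A1-style label
#'
#' Rows map to letters (`A`, `B`, ..., `Z`, `AA`, ...) and columns to 1-based
#' numbers, the usual microplate convention.
#'
#' @param row,col Integer vectors of 0-based well coordinates.
#' @return Character vector of labels such as `"A1"` or `"H12"`.
#' @examples
#' well_label(0, 0)   # "A1"
#' well_label(7, 11)  # "H12"
#' @export
well_label <- function(row, col) {
  stopifnot(all(row >= 0), all(col >= 0))
  paste0(vapply(as.integer(row), row_letters, character(1)), col + 1L)
}

row_letters <- function(r) {
  # bijective base-26: A..Z, AA..AZ, BA.. etc.
  s <- ""
  r <- r + 1L
  while (r > 0L) {
    r <- r - 1L
    s <- paste0(LETTERS[r %% 26L + 1L], s)
    r <- r %/% 26L
  }
  s
}

#' Convert A1-style labels back to 0-based coordinates
#'
#' Inverse of [well_label()].
#'
#' @param label Character vector of A1-style labels.
#' @return A tibble with integer columns `row` and `col` (0-based).
#' @export
well_coords <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)$", label))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    abort(paste0("invalid well label(s): ", paste(label[bad], collapse = ", ")))
  }
  row <- vapply(m, function(p) {
    ch <- strsplit(p[2], "")[[1]]
    sum((match(ch, LETTERS)) * 26^(rev(seq_along(ch)) - 1L)) - 1L
  }, double(1))
  col <- vapply(m, function(p) as.integer(p[3]) - 1L, integer(1))
  tibble(row = as.integer(row), col = as.integer(col))
}

#' Parse a plate-setup matrix into a plate layout
#'
#' The plate setup is a rectangular matrix whose cells hold the numeric
#' "test" values (e.g. compound concentrations): wells carrying the same
#' test value are replicates of one condition, and the test values form the
#' abscissa of all downstream plots and fits. Blank (`NA`) cells mark unused
#' wells. Matching is by exact numeric equality of the parsed values.
#'
#' @param cells A numeric matrix (or data frame coercible to one) with `NA`
#'   for blank wells. Character matrices are parsed; a non-numeric non-blank
#'   cell is an error naming the offending well.
#' @return A `plate_layout`: a tibble with one row per non-blank well, in
#'   row-major order, and columns `row`, `col` (0-based), `well` (A1 label)
#'   and `test`. Plate dimensions are kept in attributes `n_rows`, `n_cols`.
#' @examples
#' parse_layout(rbind(c(0, 0), c(10, 10)))
#' @export
parse_layout <- function(cells) {
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (!is.matrix(cells)) cells <- matrix(cells, nrow = 1)
  if (length(cells) == 0L) abort("empty layout: the plate-setup matrix has no cells")
  num <- parse_cell_matrix(cells, what = "plate setup")
  if (all(is.na(num))) abort("empty layout: all plate-setup cells are blank")
  idx <- which(!is.na(num), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  out <- tibble(
    row = as.integer(idx[, "row"]) - 1L,
    col = as.integer(idx[, "col"]) - 1L,
    test = num[idx]
  )
  out$well <- well_label(out$row, out$col)
  out <- out[, c("row", "col", "well", "test")]
  new_plate_layout(out, nrow(num), ncol(num))
}

new_plate_layout <- function(df, n_rows, n_cols) {
  structure(as_tibble(df),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    class = c("plate_layout", class(as_tibble(df)))
  )
}

# Parse a character/numeric matrix of cells into numerics, erroring with the
# well label on unparseable non-blank entries.  "" and NA are blank.
parse_cell_matrix <- function(cells, what = "data") {
  if (is.numeric(cells)) {
    storage.mode(cells) <- "double"
    if (any(is.infinite(cells))) {
      bad <- which(is.infinite(cells), arr.ind = TRUE)[1, ]
      abort(sprintf("non-finite %s value at well %s", what,
                    well_label(bad[1] - 1L, bad[2] - 1L)))
    }
    return(cells)
  }
  chr <- trimws(as.character(cells))
  dim(chr) <- dim(cells)
  chr[chr == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- !is.na(chr) & (is.na(num) | is.infinite(num))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("cannot parse %s cell at well %s: %s", what,
                  well_label(w[1] - 1L, w[2] - 1L), chr[w[1], w[2]]))
  }
  num
}

#' Distinct test values of a layout
#'
#' @param layout A `plate_layout`.
#' @return Sorted numeric vector of distinct test values (ascending), the
#'   iteration order used throughout the pipeline.
#' @export
layout_tests <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  sort(unique(layout$test))
}

layout_dims <- function(layout) {
  c(attr(layout, "n_rows"), attr(layout, "n_cols"))
}

#' Rebuild the layout matrix from a plate layout
#'
#' @param layout A `plate_layout`.
#' @return Numeric matrix with `NA` at blank wells.
#' @export
layout_matrix <- function(layout) {
  d <- layout_dims(layout)
  m <- matrix(NA_real_, d[1], d[2])
  m[cbind(layout$row + 1L, layout$col + 1L)] <- layout$test
  m
}

#' Bind a matrix of observed values to a plate layout as a data group
#'
#' A "group" is one dataset (one compound, one enzyme, ...) whose observed
#' values occupy a full layout-shaped block. Values at blank layout wells are
#' ignored; a blank value at a labelled well is a missing observation, kept
#' in the table with `value = NA` and excluded from all statistics (distinct
#' from an outlier-masked value).
#'
#' @param layout A `plate_layout`.
#' @param name Group name (single string).
#' @param values Matrix of observed values with the layout's dimensions
#'   (`NA`/blank allowed).
#' @return A `plate_data` tibble with columns `group`, `row`, `col`, `well`,
#'   `test`, `value`, `masked` — one row per non-blank layout well, row-major.
#' @examples
#' lay <- parse_layout(rbind(c(0, 0), c(10, 10)))
#' bind_group(lay, "drugA", rbind(c(1, 3), c(5, 7)))
#' @export
bind_group <- function(layout, name, values) {
  stopifnot(inherits(layout, "plate_layout"), is.character(name), length(name) == 1L)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  d <- layout_dims(layout)
  if (!identical(dim(values), as.integer(d))) {
    abort(sprintf(
      "layout mismatch for group '%s': data block is %dx%d but layout is %dx%d",
      name, nrow(values), ncol(values), d[1], d[2]
    ))
  }
  num <- parse_cell_matrix(values, what = sprintf("group '%s'", name))
  out <- layout
  class(out) <- setdiff(class(out), "plate_layout")
  out$group <- name
  out$value <- num[cbind(out$row + 1L, out$col + 1L)]
  out$masked <- FALSE
  new_plate_data(out[, c("group", "row", "col", "well", "test", "value", "masked")], d)
}

new_plate_data <- function(df, dims) {
  structure(as_tibble(df),
    n_rows = as.integer(dims[1]), n_cols = as.integer(dims[2]),
    class = c("plate_data", setdiff(class(as_tibble(df)), "plate_data"))
  )
}

#' Combine several data groups into one table
#'
#' @param ... `plate_data` tibbles from [bind_group()], or a single list of
#'   them.
#' @return One `plate_data` tibble stacking all groups. Group names must be
#'   unique.
#' @export
bind_groups <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1]], "data.frame")) gs <- gs[[1]]
  stopifnot(length(gs) >= 1L)
  nms <- vapply(gs, function(g) g$group[1], character(1))
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate group names: ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  dims <- layout_dims(gs[[1]])
  new_plate_data(bind_rows(lapply(gs, as_tibble)), dims)
}

#' Replicate sets of a bound data group
#'
#' Partitions the wells of each group by test value. Every non-blank layout
#' well belongs to exactly one replicate set.
#'
#' @param data A `plate_data` tibble.
#' @return A nested tibble with one row per group x test value (tests
#'   ascending within group): columns `group`, `test`, `n_members` and
#'   `members`, a list column of tibbles (`row`, `col`, `well`, `value`,
#'   `masked`) in row-major well order.
#' @export
replicate_sets <- function(data) {
  stopifnot(is.data.frame(data))
  data |>
    as_tibble() |>
    arrange(.data$group, .data$test, .data$row, .data$col) |>
    tidyr::nest(members = c("row", "col", "well", "value", "masked")) |>
    mutate(n_members = vapply(.data$members, nrow, integer(1))) |>
    select("group", "test", "n_members", "members")
}

#' Mask all replicates of a test value
#'
#' Sets the outlier mask for every well carrying `test_value` (in every group
#' present, or only in `groups` when given). Masking never alters stored
#' values; masked wells are excluded from reference means, aggregation and
#' fitting. Idempotent.
#'
#' @param data A `plate_data` tibble.
#' @param test_value A test value present in the layout.
#' @param groups Optional character vector restricting which groups to mask.
#' @return The data with updated `masked` column.
#' @export
mask_test <- function(data, test_value, groups = NULL) {
  stopifnot(is.data.frame(data), is.numeric(test_value), length(test_value) == 1L)
  if (!any(data$test == test_value)) {
    abort(sprintf(
      "unknown test value %g; available: %s", test_value,
      paste(sort(unique(data$test)), collapse = ", ")
    ))
  }
  hit <- data$test == test_value
  if (!is.null(groups)) hit <- hit & data$group %in% groups
  data$masked <- data$masked | hit
  data
}

#' Mask individual wells
#'
#' @param data A `plate_data` tibble.
#' @param wells Character vector of A1-style well labels.
#' @param groups Optional character vector restricting which groups to mask.
#' @return The data with updated `masked` column.
#' @export
mask_wells <- function(data, wells, groups = NULL) {
  unknown <- setdiff(wells, data$well)
  if (length(unknown)) {
    abort(paste0("unknown well label(s): ", paste(unknown, collapse = ", ")))
  }
  hit <- data$well %in% wells
  if (!is.null(groups)) hit <- hit & data$group %in% groups
  data$masked <- data$masked | hit
  data
}
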