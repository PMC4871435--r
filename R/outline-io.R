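#' @keywords internal
"_PACKAGE"

# ---- containers -------------------------------------------------------------

#' Construct a raw 3D outline
#'
#' A raw outline bundles a specimen identifier, the three anchor landmarks
#' (L1 = tip of the point, then L2 and L3 clockwise at the two opposite
#' corner angles) and the ordered closed 3D contour digitized along the
#' sharpest edge of the piece. The first contour point must coincide with L1:
#' the contour is digitized clockwise starting at the tip.
#'
#' @param specimen_id single character string, unique within an assemblage.
#' @param anchors numeric 3 x 3 matrix, one landmark per row (x, y, z), in mm.
#' @param contour numeric k x 3 matrix (k >= 3) of ordered contour points in
#'   mm; the closing edge from the last point back to the first is implicit.
#' @param snap_tol if L1 and the first contour point disagree by more than
#'   this distance (mm), a warning is emitted and L1 is snapped onto the
#'   contour start.
#' @return an object of class `"outline"`.
#' @export
outline <- function(specimen_id, anchors, contour, snap_tol = 1e-6) {
  specimen_id <- as.character(specimen_id)
  if (length(specimen_id) != 1L || is.na(specimen_id) || !nzchar(specimen_id))
    stop("'specimen_id' must be a single non-empty string")
  anchors <- as_point_matrix(anchors, "anchors")
  contour <- as_point_matrix(contour, "contour")
  if (nrow(anchors) != 3L)
    stop("exactly 3 anchor landmarks are required, got ", nrow(anchors))
  if (nrow(contour) < 3L)
    stop("contour needs at least 3 points, got ", nrow(contour))
  gap <- sqrt(sum((anchors[1L, ] - contour[1L, ])^2))
  if (gap > snap_tol) {
    warning(sprintf(
      "specimen '%s': landmark 1 is %.3g mm away from the contour start; snapping L1 onto the contour",
      specimen_id, gap))
  }
  anchors[1L, ] <- contour[1L, ]
  structure(
    list(specimen_id = specimen_id, anchors = anchors, contour = contour),
    class = "outline")
}

as_point_matrix <- function(x, what = "points") {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop("'", what, "' must have 3 columns (x, y, z)")
  if (anyNA(m) || any(!is.finite(m))) stop("'", what, "' contains non-finite coordinates")
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Bundle outlines into an assemblage collection
#'
#' @param ... outlines, or a single list of outlines.
#' @return an object of class `"outline_set"` (a named list of outlines).
#' @export
outline_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "outline")) xs <- xs[[1L]]
  if (!all(vapply(xs, inherits, logical(1L), "outline")))
    stop("all elements must be 'outline' objects")
  ids <- vapply(xs, `[[`, character(1L), "specimen_id")
  if (anyDuplicated(ids))
    stop("duplicate specimen IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(xs) <- ids
  structure(xs, class = "outline_set")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("3D outline '%s': %d contour points + 3 anchors\n",
              x$specimen_id, nrow(x$contour)))
  invisible(x)
}

#' @export
print.outline_set <- function(x, ...) {
  k <- if (length(x)) nrow(x[[1L]]$contour) else 0L
  cat(sprintf("outline_set: %d specimens (%d contour points each in first specimen)\n",
              length(x), k))
  invisible(x)
}

#' Full point configuration of an outline
#'
#' Stacks the three anchors on top of the contour points, giving the
#' (3 + k) x 3 configuration used for centroid size and alignment.
#'
#' @param x an `outline`.
#' @return numeric matrix.
#' @export
full_config <- function(x) {
  stopifnot(inherits(x, "outline"))
  rbind(x$anchors, x$contour)
}

# ---- closed vocabularies ----------------------------------------------------

factor_vocabulary <- list(
  material     = c("SH", "H", "IND"),
  trace_side   = c("R", "L", "LR"),
  localization = c("edges", "edges+point"),
  action       = c("T", "L", "P"))

# ---- readers ----------------------------------------------------------------

read_table_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = NA)
  }
}

#' Read a landmark + semi-landmark coordinate table
#'
#' Reads tables laid out one specimen per row: an ID column, 9 columns for
#' the x, y, z coordinates of the 3 anchor landmarks, then 3 k columns for
#' the x, y, z coordinates of k ordered contour points (the deposited-data
#' layout uses k = 196). Coordinate triplets are grouped per point
#' (x, y, z, x, y, z, ...). The first contour point is expected to coincide
#' with landmark 1; if they differ by more than `snap_tol` a warning is
#' issued and L1 is snapped onto the contour.
#'
#' Both delimited text (comma, semicolon or tab) and spreadsheet (`.xlsx`)
#' files are accepted; the internal representation is the same either way.
#' Coordinates are taken to be millimetres.
#'
#' @param path file to read.
#' @param layout `"s1_dataset"` enforces exactly 196 contour points;
#'   `"generic_csv"` accepts any k >= 3.
#' @param snap_tol L1 / contour-start disagreement tolerance in mm.
#' @return an [outline_set()].
#' @export
read_outline_table <- function(path, layout = c("s1_dataset", "generic_csv"),
                               snap_tol = 1e-6) {
  layout <- match.arg(layout)
  df <- read_table_any(path)
  if (nrow(df) == 0L) {
    warning("outline table '", path, "' has no data rows")
    return(outline_set(list()))
  }
  nc <- ncol(df)
  k <- (nc - 1L - 9L) / 3L
  if (nc < 1L + 9L + 9L || k != floor(k))
    stop(sprintf(
      "malformed outline table '%s': %d columns; expected 1 ID + 9 landmark + 3*k semi-landmark columns",
      path, nc))
  k <- as.integer(k)
  if (layout == "s1_dataset" && k != 196L)
    stop("s1_dataset layout requires 196 semi-landmarks per row, found ", k)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate specimen IDs in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (anyNA(v))
      stop(sprintf("non-numeric or missing value in '%s', row %d, column %d",
                   path, if (length(bad)) bad[1L] else which(is.na(v))[1L], j + 1L))
    num[[j]] <- v
  }
  num <- as.matrix(num)
  outs <- lapply(seq_len(nrow(num)), function(i) {
    anchors <- matrix(num[i, 1:9], nrow = 3L, byrow = TRUE)
    contour <- matrix(num[i, 10:(9L + 3L * k)], nrow = k, byrow = TRUE)
    outline(ids[i], anchors, contour, snap_tol = snap_tol)
  })
  outline_set(outs)
}

validate_codes <- function(x, vocab, column, path) {
  x <- trimws(as.character(x))
  bad <- which(!(x %in% vocab))
  if (length(bad))
    stop(sprintf("unknown %s code '%s' in '%s' (row %d); allowed: %s",
                 column, x[bad[1L]], path, bad[1L], paste(vocab, collapse = ", ")))
  factor(x, levels = vocab)
}

#' Read a use-wear factor table
#'
#' Expects columns `id`, `material` (SH = semi-hard, H = hard,
#' IND = indeterminate worked material), `trace_side` (R, L, LR), `localization`
#' (`edges` or `edges+point`) and `action` (T = transversal, L = longitudinal,
#' P = piercing contact action). Codes are validated against these closed
#' vocabularies and per-factor class counts are reported.
#'
#' @param path file to read (delimited text or spreadsheet).
#' @param quiet suppress the class-count message.
#' @return a data.frame of class `"factor_table"` with factor columns.
#' @export
read_factor_table <- function(path, quiet = FALSE) {
  df <- read_table_any(path)
  names(df) <- tolower(names(df))
  needed <- c("id", names(factor_vocabulary))
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("factor table '", path, "' lacks columns: ", paste(miss, collapse = ", "))
  out <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$id))
    stop("duplicate specimen IDs in factor table '", path, "'")
  for (f in names(factor_vocabulary))
    out[[f]] <- validate_codes(df[[f]], factor_vocabulary[[f]], f, path)
  if (!quiet)
    for (f in names(factor_vocabulary))
      message(sprintf("factor %s: %s", f,
                      paste(sprintf("%s=%d", levels(out[[f]]), table(out[[f]])), collapse = " ")))
  class(out) <- c("factor_table", "data.frame")
  out
}

#' Read a size table
#'
#' Expects columns `id`, `centroid_size_mm` (optional: it can always be
#' recomputed from the coordinates with [centroid_size()]) and `volume_mm3`.
#'
#' @param path file to read.
#' @return a data.frame of class `"size_table"`.
#' @export
read_size_table <- function(path) {
  df <- read_table_any(path)
  names(df) <- tolower(names(df))
  if (!all(c("id", "volume_mm3") %in% names(df)))
    stop("size table '", path, "' must have columns 'id' and 'volume_mm3'")
  out <- data.frame(id = as.character(df$id),
                    centroid_size_mm = if ("centroid_size_mm" %in% names(df))
                      as.numeric(df$centroid_size_mm) else NA_real_,
                    volume_mm3 = as.numeric(df$volume_mm3),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicate specimen IDs in size table '", path, "'")
  if (any(!is.na(out$volume_mm3) & out$volume_mm3 <= 0))
    stop("volumes must be strictly positive in '", path, "'")
  if (any(!is.na(out$centroid_size_mm) & out$centroid_size_mm <= 0))
    stop("centroid sizes must be strictly positive in '", path, "'")
  class(out) <- c("size_table", "data.frame")
  out
}

# ---- writers ----------------------------------------------------------------

#' Write an outline set in the one-row-per-specimen coordinate layout
#'
#' Columns are `id`, `Lcoord1..9` (x, y, z of the three anchors), then
#' `slcoord1..3k` (x, y, z of the k contour points), matching the layout
#' accepted by [read_outline_table()].
#'
#' @param x an `outline_set` whose outlines share the same contour length.
#' @param path output file (comma-delimited, UTF-8, header included).
#' @return `path`, invisibly.
#' @export
write_outline_table <- function(x, path) {
  stopifnot(inherits(x, "outline_set"), length(x) > 0L)
  k <- nrow(x[[1L]]$contour)
  rows <- lapply(x, function(o) {
    if (nrow(o$contour) != k)
      stop("all outlines must share the same contour length to be written as a table")
    c(as.vector(t(o$anchors)), as.vector(t(o$contour)))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("Lcoord", 1:9), paste0("slcoord", seq_len(3L * k)))
  df <- data.frame(id = names(x), m, check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname write_outline_table
#' @export
write_factor_table <- function(x, path) {
  stopifnot(inherits(x, "data.frame"))
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_outline_table
#' @export
write_size_table <- function(x, path) {
  stopifnot(inherits(x, "data.frame"))
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

# full-precision, locale-independent CSV writer (round-trips doubles exactly)
write_csv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Persist a set of result tables as delimited text
#'
#' Each element of `tables` (matrix or data.frame) is written to
#' `<out_dir>/<name>.csv` with headers, full precision and deterministic
#' column order. Matrices with row names gain a leading `id` column.
#'
#' @param tables named list of matrices / data.frames.
#' @param out_dir output directory (created if missing).
#' @return character vector of file paths written (empty, with a warning,
#'   if `tables` is empty).
#' @export
write_results <- function(tables, out_dir) {
  if (length(tables) == 0L) {
    warning("no result tables to write")
    return(character(0L))
  }
  stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory '", out_dir, "'")
  paths <- character(0L)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.matrix(tab)) {
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      if (!is.null(rownames(tab)))
        df <- cbind(id = rownames(tab), df, stringsAsFactors = FALSE)
    } else df <- as.data.frame(tab, stringsAsFactors = FALSE)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_csv_full(df, p)
    paths <- c(paths, p)
  }
  paths
}
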