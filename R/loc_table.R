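#' Construct a localization table
#'
#' A localization table is the central data container of the package: one row
#' per single-molecule localization with continuous coordinates in nanometres
#' (image convention: x rightward, y downward, origin at the field-of-view
#' top-left). Additional columns (e.g. `photons`, `z`) are carried along
#' unchanged by all operations.
#'
#' @param x,y Numeric coordinates in nm. Must be finite.
#' @param frame Non-negative integer acquisition frame (default 0).
#' @param channel Character channel identifier (default `"AF647"`).
#' @param z Optional axial coordinate in nm.
#' @param photons Optional positive photon count per localization.
#' @param ... Further per-localization columns, recycled to length.
#'
#' @return A `data.frame` of class `loc_table` with at least columns
#'   `x`, `y`, `frame`, `channel`.
#' @export
loc_table <- function(x = numeric(), y = numeric(), frame = 0L,
                      channel = "AF647", z = NULL, photons = NULL, ...) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("localization coordinates must be finite")
  n <- length(x)
  df <- data.frame(
    x = x, y = y,
    frame = as.integer(rep_len(frame, n)),
    channel = rep_len(as.character(channel), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(z)) df$z <- rep_len(as.numeric(z), n)
  if (!is.null(photons)) {
    photons <- rep_len(as.numeric(photons), n)
    if (any(photons <= 0, na.rm = TRUE)) stop("photons must be positive")
    df$photons <- photons
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  if (n && any(df$frame < 0L)) stop("frame must be non-negative")
  class(df) <- c("loc_table", "data.frame")
  df
}

as_loc_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("x", "y")) {
    if (!col %in% names(df)) stop("missing mandatory column: ", col)
  }
  if (!"frame" %in% names(df)) df$frame <- rep_len(0L, nrow(df))
  if (!"channel" %in% names(df)) df$channel <- rep_len("AF647", nrow(df))
  class(df) <- unique(c("loc_table", class(df)))
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, channels: %s\n",
              nrow(x), paste(unique(x$channel), collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a localization table from delimited text
#'
#' Reads CSV/TSV localization files with a named header. The default dialect
#' maps `x[nm]`, `y[nm]`, optional `z[nm]`, `frame`, `channel` and `photons`
#' onto the canonical columns; plain `x`/`y`/`z` headers are accepted too.
#' All coordinates are taken to be in nanometres. Unknown columns are kept
#' verbatim. Delimited text is the only on-disk table format supported.
#'
#' @param path Path to an existing delimited text file with a header row.
#' @param dialect Named character vector mapping canonical column names
#'   (`x`, `y`, `z`, `frame`, `channel`, `photons`) to header names in the
#'   file. Defaults cover the common `x[nm]`-style headers.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#'
#' @return A [loc_table].
#' @export
read_localizations <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  default_map <- list(
    x = c("x", "x[nm]", "x [nm]", "x_nm"),
    y = c("y", "y[nm]", "y [nm]", "y_nm"),
    z = c("z", "z[nm]", "z [nm]", "z_nm"),
    frame = "frame", channel = "channel", photons = "photons"
  )
  if (!is.null(dialect)) {
    for (nm in names(dialect)) default_map[[nm]] <- dialect[[nm]]
  }
  out <- df
  for (canon in names(default_map)) {
    hit <- intersect(default_map[[canon]], names(df))
    if (length(hit)) {
      out[[canon]] <- df[[hit[[1L]]]]
      if (!identical(hit[[1L]], canon)) out[[hit[[1L]]]] <- NULL
    }
  }
  for (col in c("x", "y")) {
    if (!col %in% names(out))
      stop("localization file is missing mandatory column: ", col)
    v <- out[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric %s coordinate at data row %d", col, bad[[1L]]))
      out[[col]] <- vn
    }
  }
  as_loc_table(out)
}

#' Write a localization table to delimited text
#'
#' @param table A [loc_table].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_localizations <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

n_locs <- function(table) nrow(table)
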