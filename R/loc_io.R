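#' Localization tables
#'
#' The canonical in-memory container for single-molecule localization data
#' is a plain `data.frame` of class `loc_table` with one row per localized
#' fluorophore blink and columns `x`, `y`, `z` (nm; z is the optical axis),
#' `channel` (integer; by convention 1 = nucleoid stain, 2 = mtFISH probe)
#' and optional `frame`, `photons`, `uncertainty` (nm). Free-form
#' provenance (source file, applied filters, seeds) lives in the
#' `metadata` attribute.
#'
#' @param x,y,z numeric coordinates in nm.
#' @param channel integer channel labels.
#' @param frame,photons,uncertainty optional non-negative columns.
#' @param metadata named list of provenance entries.
#' @return a `loc_table`.
#' @examples
#' tb <- loc_table(x = c(0, 50), y = c(0, 0), z = c(0, 10), channel = c(1, 2))
#' split_channels(tb)
#' @export
loc_table <- function(x = numeric(), y = numeric(), z = numeric(),
                      channel = integer(), frame = NULL, photons = NULL,
                      uncertainty = NULL, metadata = list()) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   channel = as.integer(channel))
  if (!is.null(frame)) df$frame <- as.integer(frame)
  if (!is.null(photons)) df$photons <- as.numeric(photons)
  if (!is.null(uncertainty)) df$uncertainty <- as.numeric(uncertainty)
  validate_loc_table(structure(df, metadata = metadata, unit = "nm",
                               class = c("loc_table", "data.frame")))
}

#' @rdname loc_table
#' @param table object to validate / test.
#' @export
validate_loc_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("x", "y", "z", "channel")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (cc in c("x", "y", "z"))
    if (any(!is.finite(table[[cc]])))
      stop("non-finite coordinate in column ", cc)
  for (cc in c("frame", "photons", "uncertainty"))
    if (cc %in% names(table) && any(table[[cc]] < 0, na.rm = TRUE))
      stop("negative values in column ", cc)
  ndup <- sum(duplicated(table[c("x", "y", "z")]))
  if (ndup > 0)
    attr(table, "metadata")$duplicate_coordinates <- ndup
  table
}

#' @rdname loc_table
#' @export
is.loc_table <- function(table) inherits(table, "loc_table")

#' Coordinate matrix of a localization table
#' @param table a `loc_table`.
#' @return n x 3 numeric matrix (nm).
#' @export
loc_coords <- function(table) {
  as.matrix(as.data.frame(table)[, c("x", "y", "z")])
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("loc_table: %d localization(s), channels {%s} [nm]\n",
              nrow(x), paste(sort(unique(x$channel)), collapse = ",")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Column-mapping dialect for localization CSV files
#'
#' Describes how columns of a CSV map onto the canonical fields and the
#' multiplicative factor taking file units into nm. The default is the
#' canonical dialect written by [write_localizations()]
#' (`x_nm,y_nm,z_nm,channel,frame,photons,uncertainty_nm`); the
#' `"thunderstorm"` preset reads a generic ThunderSTORM-like export
#' (`x [nm]`, `y [nm]`, `z [nm]`, `frame`, `uncertainty [nm]`, one file
#' per channel).
#'
#' @param x,y,z,channel,frame,photons,uncertainty column names in the file
#'   (`NA` for "not present"; a missing `channel` column requires
#'   `channel_value`).
#' @param scale factor multiplying coordinates into nm (e.g. 1000 for um).
#' @param channel_value fixed channel label for per-channel files.
#' @export
loc_dialect <- function(x = "x_nm", y = "y_nm", z = "z_nm",
                        channel = "channel", frame = "frame",
                        photons = "photons", uncertainty = "uncertainty_nm",
                        scale = 1, channel_value = NA_integer_) {
  structure(list(x = x, y = y, z = z, channel = channel, frame = frame,
                 photons = photons, uncertainty = uncertainty,
                 scale = scale, channel_value = as.integer(channel_value)),
            class = "loc_dialect")
}

#' @rdname loc_dialect
#' @export
thunderstorm_dialect <- function(channel_value = 1L, scale = 1) {
  loc_dialect(x = "x [nm]", y = "y [nm]", z = "z [nm]", channel = NA,
              frame = "frame", photons = "intensity [photon]",
              uncertainty = "uncertainty [nm]", scale = scale,
              channel_value = channel_value)
}

#' Read a localization table from CSV
#'
#' @param path CSV file path.
#' @param dialect a [loc_dialect()] describing the column mapping and unit
#'   scale. Extra columns are ignored.
#' @return a validated [loc_table] in nm; `metadata` records the source
#'   path and dialect.
#' @export
read_localizations <- function(path, dialect = loc_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE)
  grab <- function(col, what, mandatory = FALSE) {
    if (is.na(col) || !nzchar(col)) return(NULL)
    if (!col %in% names(raw)) {
      if (mandatory) stop(sprintf("missing mandatory column '%s' (%s)",
                                  col, what))
      return(NULL)
    }
    v <- raw[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric %s value(s) at row(s) %s of %s",
                     what, paste(head(bad, 5L), collapse = ", "), path))
      v <- vn
    }
    v
  }
  x <- grab(dialect$x, "x", mandatory = TRUE)
  y <- grab(dialect$y, "y", mandatory = TRUE)
  z <- grab(dialect$z, "z", mandatory = TRUE)
  ch <- if (!is.na(dialect$channel)) {
    if (!dialect$channel %in% names(raw) && !is.na(dialect$channel_value))
      rep(dialect$channel_value, nrow(raw))
    else grab(dialect$channel, "channel", mandatory = TRUE)
  } else {
    if (is.na(dialect$channel_value))
      stop("missing mandatory column 'channel'")
    rep(dialect$channel_value, nrow(raw))
  }
  loc_table(x = x * dialect$scale, y = y * dialect$scale,
            z = z * dialect$scale, channel = ch,
            frame = grab(dialect$frame, "frame"),
            photons = grab(dialect$photons, "photons"),
            uncertainty = grab(dialect$uncertainty, "uncertainty"),
            metadata = list(source = path, dialect = dialect))
}

#' Write a localization table as canonical CSV
#'
#' Writes the canonical header `x_nm,y_nm,z_nm,channel[,frame][,photons]
#' [,uncertainty_nm]`; optional columns absent from the table are omitted.
#' `read_localizations()` on the result reproduces the table record for
#' record.
#'
#' @param table a [loc_table].
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  table <- validate_loc_table(table)
  df <- as.data.frame(table)
  out <- data.frame(x_nm = df$x, y_nm = df$y, z_nm = df$z,
                    channel = df$channel)
  if ("frame" %in% names(df)) out$frame <- df$frame
  if ("photons" %in% names(df)) out$photons <- df$photons
  if ("uncertainty" %in% names(df)) out$uncertainty_nm <- df$uncertainty
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter localizations by uncertainty
#'
#' Accuracy-based filtering: keeps records with `uncertainty <=
#' max_uncertainty` (nm). Records without an uncertainty value are kept
#' with a warning, so that minimal dialects are not silently emptied.
#'
#' @param table a [loc_table].
#' @param max_uncertainty positive threshold in nm.
#' @export
filter_by_uncertainty <- function(table, max_uncertainty) {
  if (!is.numeric(max_uncertainty) || length(max_uncertainty) != 1L ||
      is.na(max_uncertainty) || max_uncertainty <= 0)
    stop("max_uncertainty must be a positive number (nm)")
  n0 <- nrow(table)
  if (!"uncertainty" %in% names(table)) {
    warning("no uncertainty column: all localizations kept")
    keep <- rep(TRUE, n0)
  } else {
    keep <- is.na(table$uncertainty) | table$uncertainty <= max_uncertainty
    if (anyNA(table$uncertainty))
      warning("localizations without uncertainty were kept")
  }
  out <- table[keep, , drop = FALSE]
  md <- attr(table, "metadata")
  md$uncertainty_filter <- list(max_uncertainty = max_uncertainty,
                                removed = n0 - sum(keep))
  attr(out, "metadata") <- md
  out
}

#' Split a localization table by channel
#'
#' @param table a [loc_table].
#' @return named list of single-channel `loc_table`s; the union of the
#'   outputs equals the input (a partition).
#' @export
split_channels <- function(table) {
  chans <- sort(unique(table$channel))
  out <- lapply(chans, function(ch) {
    s <- table[table$channel == ch, , drop = FALSE]
    attr(s, "metadata") <- c(attr(table, "metadata"), list(channel = ch))
    s
  })
  setNames(out, as.character(chans))
}
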