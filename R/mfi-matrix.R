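#' Construct a sample-by-marker MFI matrix
#'
#' The central data container of the pipeline: a numeric matrix of median
#' fluorescence intensities with samples in rows and antigen-isotype
#' channels in columns, plus a marker annotation table and a scale flag.
#' Column names follow the `"SYMBOL|IgG"` / `"SYMBOL|IgA"` convention so
#' that both isotype channels of one antigen remain unambiguous.
#'
#' @param values numeric matrix, samples x markers, with sample ids as row
#'   names and marker keys (`"SYMBOL|ISOTYPE"`) as column names.
#' @param markers optional marker annotation `data.frame` with columns
#'   `marker_id`, `isotype` and `source`; parsed from the column names when
#'   omitted.
#' @param scale one of `"linear"`, `"log2"`, `"log2_centered"`. Linear
#'   values must be strictly positive (a bead region always yields a
#'   positive MFI); scale transitions happen only through
#'   [log2_transform()] and [median_center()].
#'
#' @return An object of class `mfi_matrix`.
#' @seealso [read_mfi_matrix()], [log2_transform()], [median_center()]
#' @export
mfi_matrix <- function(values, markers = NULL, scale = "linear") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids as rownames and marker keys as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated marker columns: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  scale <- match.arg(scale, c("linear", "log2", "log2_centered"))
  if (is.null(markers)) markers <- parse_marker_keys(colnames(values))
  check_markers(markers)
  if (!identical(marker_key(markers), colnames(values)))
    stop("marker annotation does not match the value columns")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing MFI value for sample '%s', marker '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (scale == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive MFI value for sample '%s', marker '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(list(values = values, markers = markers, scale = scale),
            class = "mfi_matrix")
}

#' Marker keys of an annotation table
#'
#' @param markers a marker annotation `data.frame`.
#' @return Character vector `"SYMBOL|ISOTYPE"`.
#' @export
marker_key <- function(markers) paste(markers$marker_id, markers$isotype, sep = "|")

parse_marker_keys <- function(keys, source = "discovery") {
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed marker column name(s): ", paste(keys[bad], collapse = ", "),
         " (expected 'SYMBOL|IgG' or 'SYMBOL|IgA')")
  out <- data.frame(
    marker_id = vapply(parts, `[`, "", 1L),
    isotype = vapply(parts, `[`, "", 2L),
    source = source,
    stringsAsFactors = FALSE
  )
  check_markers(out)
  out
}

check_markers <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "isotype") %in% names(markers)))
  if (!"source" %in% names(markers)) markers$source <- "discovery"
  if (any(!nzchar(markers$marker_id))) stop("empty marker_id")
  if (!all(markers$isotype %in% .ISOTYPES))
    stop("isotype must be one of: ", paste(.ISOTYPES, collapse = ", "))
  if (!all(markers$source %in% c("discovery", "literature", "pathway")))
    stop("marker source must be one of: discovery, literature, pathway")
  if (anyDuplicated(marker_key(markers)))
    stop("duplicated (marker_id, isotype) pair")
  invisible(markers)
}

#' Read an MFI matrix from CSV
#'
#' Two dialects are supported. `wide`: one row per sample, first column
#' the sample id, remaining columns named `"SYMBOL|ISOTYPE"`. `long`: one
#' row per measurement with columns `sample_id`, `marker_id`, `isotype`,
#' `mfi`; the table is pivoted and must cover the full sample-by-marker
#' grid (the assay yields a value for every bead region, so missing cells
#' are rejected). Both dialects yield identical objects for the same data.
#'
#' @param path CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param scale scale of the stored values (files exported mid-pipeline
#'   may hold `"log2"` or `"log2_centered"` values).
#' @return An [mfi_matrix()].
#' @export
read_mfi_matrix <- function(path, dialect = c("wide", "long"), scale = "linear") {
  dialect <- match.arg(dialect)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2L) stop("wide MFI file needs a sample id column plus markers")
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric MFI values in ", path)
    rownames(vals) <- ids
    return(mfi_matrix(vals, scale = scale))
  }
  need <- c("sample_id", "marker_id", "isotype", "mfi")
  if (!all(need %in% names(df)))
    stop("long MFI file must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$marker_id, df$isotype, sep = "|")
  if (anyDuplicated(paste(df$sample_id, key)))
    stop("duplicate (sample, marker) entries in ", path)
  ids <- unique(as.character(df$sample_id))
  keys <- unique(key)
  vals <- matrix(NA_real_, length(ids), length(keys),
                 dimnames = list(ids, keys))
  vals[cbind(match(df$sample_id, ids), match(key, keys))] <- df$mfi
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("long MFI file does not cover the full grid: missing sample '%s', marker '%s'",
                 ids[bad[1L]], keys[bad[2L]]))
  }
  mfi_matrix(vals, scale = scale)
}

# restrict to a marker subset (keys), preserving order of `keys`
subset_markers <- function(m, keys) {
  stopifnot(inherits(m, "mfi_matrix"))
  missing <- setdiff(keys, colnames(m$values))
  if (length(missing))
    stop("markers absent from matrix: ", paste(missing, collapse = ", "))
  idx <- match(keys, colnames(m$values))
  structure(list(values = m$values[, idx, drop = FALSE],
                 markers = m$markers[idx, , drop = FALSE],
                 scale = m$scale),
            class = "mfi_matrix")
}

#' @export
print.mfi_matrix <- function(x, ...) {
  cat(sprintf("mfi_matrix: %d samples x %d markers (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$markers$isotype)
  cat("  isotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mfi_matrix <- function(x) dim(x$values)
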