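#' Write a pipeline result to disk
#'
#' Tabular results (screen results, cutoff tables, prevalence and
#' co-prevalence tables, binary call matrices) are written as CSV;
#' panel models and run manifests as JSON. Reader counterparts
#' ([read_cutoff_table()], [read_panel_model()], [read_binary_matrix()],
#' [read_screen_result()]) round-trip their objects exactly.
#'
#' @param obj a result object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) UseMethod("write_results")

#' @export
write_results.default <- function(obj, path) {
  stop("no writer for objects of class ", paste(class(obj), collapse = "/"))
}

#' @export
write_results.data.frame <- function(obj, path) {
  write.csv(precise_cols(obj), path, row.names = FALSE)
  invisible(path)
}

# render doubles with full round-trip precision so persisted tables
# (notably cutoffs) reproduce downstream calls bit-identically
precise_cols <- function(df) {
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.double(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- NA
      df[[j]] <- out
    }
  }
  df
}

#' @export
write_results.screen_result <- write_results.data.frame

#' @export
write_results.cutoff_table <- write_results.data.frame

#' @export
write_results.prevalence_table <- write_results.data.frame

#' @export
write_results.association_result <- write_results.data.frame

#' @export
write_results.coprevalence_matrix <- function(obj, path) {
  df <- data.frame(marker_key = rownames(obj), as.data.frame(unclass(obj)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.binary_matrix <- function(obj, path) {
  df <- data.frame(sample_id = rownames(obj$calls),
                   as.data.frame(obj$calls + 0L), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.mfi_matrix <- function(obj, path) {
  df <- data.frame(sample_id = rownames(obj$values),
                   as.data.frame(obj$values), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.panel_model <- function(obj, path) {
  lst <- list(rule = obj$rule, markers = obj$markers, gains = obj$gains)
  if (!is.null(obj$cutoffs)) lst$cutoffs <- as.data.frame(obj$cutoffs)
  if (!is.null(obj$metrics)) lst$metrics <- unclass(obj$metrics)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back pipeline results
#'
#' @param path file written by [write_results()].
#' @return The reconstructed object.
#' @export
read_cutoff_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cutoff_table", "data.frame")
  df
}

#' @rdname read_cutoff_table
#' @export
read_screen_result <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("screen_result", "data.frame")
  df
}

#' @rdname read_cutoff_table
#' @export
read_binary_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1L, drop = FALSE]) == 1L
  rownames(calls) <- df[[1L]]
  structure(list(calls = calls, markers = parse_marker_keys(colnames(calls))),
            class = "binary_matrix")
}

#' @rdname read_cutoff_table
#' @export
read_panel_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoffs <- NULL
  if (!is.null(lst$cutoffs)) {
    cutoffs <- as.data.frame(lst$cutoffs)
    class(cutoffs) <- c("cutoff_table", "data.frame")
  }
  metrics <- lst$metrics
  if (!is.null(metrics)) class(metrics) <- "panel_metrics"
  panel_model(lst$markers, cutoffs = cutoffs, metrics = metrics,
              gains = lst$gains)
}

#' Emit a run manifest
#'
#' The manifest records everything needed to reproduce a run
#' bit-identically: the configuration, the seed, the group sizes, the
#' package version and the MD5 digest of every emitted file. Re-running
#' from a manifest (see [replay_manifest()]) reproduces all outputs.
#'
#' @param out_dir directory whose files are digested.
#' @param config the [pipeline_config()] used.
#' @param extra named list of additional fields (e.g. group sizes).
#' @param path output path; default `manifest.json` inside `out_dir`.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, config, extra = list(),
                           path = file.path(out_dir, "manifest.json")) {
  files <- setdiff(list.files(out_dir), basename(path))
  digests <- md5sum(file.path(out_dir, files))
  manifest <- c(list(package = "seropanel",
                     version = as.character(packageVersion("seropanel")),
                     config = unclass(config),
                     files = as.list(setNames(unname(digests), files))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
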