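#' Read a sample metadata table
#'
#' The metadata table carries one row per serum sample: the study group
#' (`SjD`, `HC`, `NSS`, `RA`, `SLE`, `SSc`), the recruiting cohort/center,
#' the Ro/SSA serostatus, and any number of binary clinical or laboratory
#' flags (ESSDAI domains, ANA, rheumatoid factor, biopsy grade, ...).
#' Empty cells in flag columns are preserved as `NA`; downstream
#' association screens use complete-case analysis.
#'
#' @param path CSV file with at least `sample_id` and `group` columns;
#'   optional `cohort` and `ro_ssa_positive` columns; all remaining
#'   columns are treated as binary clinical flags.
#' @return A `data.frame` with logical flag columns.
#' @export
read_sample_meta <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_sample_meta(df)
}

check_sample_meta <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample metadata needs 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), .GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.GROUPS, collapse = ", "), ")")
  if (!"cohort" %in% names(df)) df$cohort <- "unspecified"
  fixed <- c("sample_id", "group", "cohort")
  for (col in setdiff(names(df), fixed)) df[[col]] <- as_flag(df[[col]], col)
  if (!"ro_ssa_positive" %in% names(df)) df$ro_ssa_positive <- NA
  df
}

# coerce a flag column to logical, keeping empty cells as NA
as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x)))
      stop(sprintf("flag column '%s' must be binary (0/1)", name))
    return(x == 1)
  }
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  up <- toupper(x)
  ok <- up %in% c("TRUE", "FALSE", "T", "F", "1", "0") | is.na(up)
  if (!all(ok))
    stop(sprintf("flag column '%s' has non-binary values: %s", name,
                 paste(unique(x[!ok]), collapse = ", ")))
  up %in% c("TRUE", "T", "1") & !is.na(up)
  out <- up %in% c("TRUE", "T", "1")
  out[is.na(up)] <- NA
  out
}

#' Join an MFI matrix with sample metadata
#'
#' Validates that every sample in the matrix resolves to exactly one
#' metadata row, reorders the metadata to the matrix sample order, warns
#' about (and drops) metadata rows without measurements, and reports the
#' per-group sample counts.
#'
#' @param m an [mfi_matrix()].
#' @param meta a metadata `data.frame` as returned by [read_sample_meta()].
#' @return A `cohort_bundle`: list with elements `mfi`, `meta` (aligned to
#'   the matrix) and `group_counts`.
#' @export
join_metadata <- function(m, meta) {
  stopifnot(inherits(m, "mfi_matrix"))
  meta <- check_sample_meta(meta)
  ids <- rownames(m$values)
  orphans <- setdiff(ids, meta$sample_id)
  if (length(orphans))
    stop("matrix sample(s) without metadata: ", paste(orphans, collapse = ", "))
  extra <- setdiff(meta$sample_id, ids)
  if (length(extra)) {
    warning(length(extra), " metadata row(s) without measurements dropped: ",
            paste(head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
    meta <- meta[meta$sample_id %in% ids, , drop = FALSE]
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  counts <- table(factor(meta$group, levels = .GROUPS))
  counts <- counts[counts > 0]
  message("cohort bundle: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  structure(list(mfi = m, meta = meta, group_counts = counts),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle\n")
  print(x$mfi)
  cat("  groups:",
      paste(sprintf("%s=%d", names(x$group_counts), x$group_counts),
            collapse = ", "), "\n")
  invisible(x)
}

# resolve a target-subgroup selector against a metadata table.
# `target` is a logical vector, or one of the named selectors.
target_selector <- function(meta, target) {
  if (is.logical(target)) {
    stopifnot(length(target) == nrow(meta))
    return(target)
  }
  if (is.character(target) && length(target) == 1L) {
    if (target == "ro_ssa_negative") {
      sel <- meta$group == "SjD"
      if (any(sel & is.na(meta$ro_ssa_positive)))
        stop("ro_ssa_positive must be known for every SjD sample used in panel selection")
      return(sel & !meta$ro_ssa_positive)
    }
    if (target %in% .GROUPS) return(meta$group == target)
  }
  stop("unknown target selector; give a logical vector, a group label, ",
       "or 'ro_ssa_negative'")
}
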