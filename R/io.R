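# File interface: feature tables, label files, feature-set assignments and
# result tables.  Delimited text only; upstream peak picking, alignment and
# scaling are assumed done.

#' Read a feature abundance table
#'
#' Reads a CSV/TSV with the feature identifier in the first column and one
#' column per sample.  Optional `mz` and `rt` (retention time) columns are
#' kept as feature annotation, not abundances.  Empty cells and explicit
#' zeros both mean "absent" and map to 0.  Negative abundances and duplicate
#' feature ids are errors.
#'
#' @param path File path.
#' @param sep Field separator; guessed from the extension when `NULL`
#'   (`.csv` = comma, otherwise tab).
#' @param transpose If `TRUE` the file has samples as rows and features as
#'   columns.
#' @return List of class `abundance_matrix`: `values` (features x samples),
#'   `feature_ids`, `sample_ids`, and `annotation` (data.frame with any
#'   mz/rt columns, possibly empty).
#' @export
read_feature_table <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (transpose) {
    ids <- df[[1]]
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[-1] <- ids
  }
  feature_ids <- as.character(df[[1]])
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids in ", path)
  rest <- df[, -1, drop = FALSE]
  ann_cols <- tolower(colnames(rest)) %in% c("mz", "m/z", "rt",
                                             "retention_time")
  annotation <- rest[, ann_cols, drop = FALSE]
  vals <- rest[, !ann_cols, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      v[trimws(v) == ""] <- "0"
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) stop("non-numeric abundance in column ",
                          colnames(vals)[j])
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("negative abundance values in ", path)
  rownames(m) <- feature_ids
  structure(list(values = m, feature_ids = feature_ids,
                 sample_ids = colnames(m), annotation = annotation),
            class = "abundance_matrix")
}

#' Write a feature abundance table
#'
#' @param x An `abundance_matrix` or a features-by-samples matrix.
#' @param path Output path; extension chooses the separator as in
#'   [read_feature_table()].
#' @export
write_feature_table <- function(x, path) {
  m <- if (inherits(x, "abundance_matrix")) x$values else as.matrix(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature = rownames(m) %||% paste0("f", seq_len(nrow(m))),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read group labels
#'
#' Two-column delimited file `(sample_id, label)` with labels 0/1.  The
#' labels are reordered to match the abundance matrix's sample order; every
#' sample must have exactly one label.
#'
#' @param path File path.
#' @param abundance Optional `abundance_matrix` (or character vector of
#'   sample ids) to align against.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return Named numeric 0/1 vector in the matrix's sample order.
#' @export
read_labels <- function(path, abundance = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("label file needs columns (sample_id, label)")
  lab <- df[[2]]
  if (!all(lab %in% c(0, 1))) stop("labels must be 0 or 1")
  names(lab) <- as.character(df[[1]])
  if (!is.null(abundance)) {
    ids <- if (inherits(abundance, "abundance_matrix")) {
      abundance$sample_ids
    } else {
      as.character(abundance)
    }
    missing_ids <- setdiff(ids, names(lab))
    if (length(missing_ids)) {
      stop("samples without labels: ", paste(missing_ids, collapse = ", "))
    }
    extra <- setdiff(names(lab), ids)
    if (length(extra)) {
      stop("labels for unknown samples: ", paste(extra, collapse = ", "))
    }
    lab <- lab[ids]
  }
  lab
}

#' Read a precomputed feature-set assignment
#'
#' Two-column file `(feature_id, set_id)`.
#'
#' @param path File path.
#' @param feature_ids Optional feature ids to align and validate against.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return Integer set index per feature, named by feature id.
#' @export
read_feature_sets <- function(path, feature_ids = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  set_id <- as.integer(factor(df[[2]], levels = unique(df[[2]])))
  names(set_id) <- as.character(df[[1]])
  if (!is.null(feature_ids)) {
    if (!setequal(names(set_id), feature_ids)) {
      stop("feature-set file does not cover exactly the table's features")
    }
    set_id <- set_id[feature_ids]
  }
  set_id
}

#' Run the kernel score test over every feature-set of a table
#'
#' The main analysis entry point: optionally groups features (or takes a
#' precomputed assignment; by default every feature is its own set), runs the
#' kernel score test per set, and returns one row per set.
#'
#' @param abundance An `abundance_matrix` (or features-by-samples matrix).
#' @param labels 0/1 labels in the matrix's sample order.
#' @param family Kernel family.
#' @param grid A [bandwidth_grid()].
#' @param sets Optional set index per feature (e.g. from
#'   [read_feature_sets()] or a [group_features()] membership); default
#'   singletons.
#' @param normalize If `TRUE`, apply [normalize_nonzero()] first.
#' @return data.frame: `set_id`, `n_features`, `members`, `max_score`,
#'   `total_variation`, `p_upper`, `family`.
#' @export
test_feature_sets <- function(abundance, labels, family = "distance",
                              grid = bandwidth_grid(), sets = NULL,
                              normalize = FALSE) {
  m <- if (inherits(abundance, "abundance_matrix")) {
    abundance$values
  } else {
    as_set_matrix(abundance)
  }
  if (normalize) m <- normalize_nonzero(m)
  if (is.null(sets)) sets <- seq_len(nrow(m))
  idx <- split(seq_len(nrow(m)), sets)
  fid <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- lapply(seq_along(idx), function(s) {
    Xs <- m[idx[[s]], , drop = FALSE]
    # an uninformative set (constant Gram matrix at every bandwidth, e.g.
    # identical measurements across samples) gets p = 1
    r <- tryCatch(kernel_score_test(Xs, labels, family = family, grid = grid),
                  error = function(e) list(max_score = NA_real_,
                                           total_variation = NA_real_,
                                           p_upper = 1))
    data.frame(set_id = names(idx)[s],
               n_features = length(idx[[s]]),
               members = paste(fid[idx[[s]]], collapse = ";"),
               max_score = r$max_score,
               total_variation = r$total_variation,
               p_upper = r$p_upper,
               family = family,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# metadata header written at the top of every CLI output file
metadata_header <- function(params) {
  paste0("# kernmet ", as.character(utils::packageVersion("kernmet")), " | ",
         paste(names(params), unlist(lapply(params, paste, collapse = ",")),
               sep = "=", collapse = " | "))
}

write_with_metadata <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(params), con)
  utils::write.table(format(df, digits = 6, scientific = NA), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
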