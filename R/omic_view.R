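#' Construct an omic view
#'
#' An omic view is one feature-by-sample matrix from a single assay,
#' carrying a modality tag that records how its values are to be
#' interpreted: raw sequencing counts (\code{"counts"}), mass-spectrometry
#' abundances (\code{"abundance"}), or values that have already been
#' normalized/transformed (\code{"normalized"}).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param view_name name of the view, e.g. \code{"muscle_rna"} or
#'   \code{"lipids"}.
#' @param modality one of \code{"counts"}, \code{"abundance"},
#'   \code{"normalized"}.
#' @param feature_ids,sample_ids optional character vectors; default to the
#'   dimnames of \code{values}.
#' @return An object of class \code{omic_view}: a list with elements
#'   \code{view_name}, \code{feature_ids}, \code{sample_ids}, \code{values}
#'   and \code{modality}.
#' @export
omic_view <- function(values, view_name, modality = c("counts", "abundance", "normalized"),
                      feature_ids = rownames(values), sample_ids = colnames(values)) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length (", length(feature_ids), ") != nrow(values) (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != ncol(values) (", ncol(values), ")")
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature IDs in view '", view_name, "': ",
         paste(utils::head(dup, 10), collapse = ", "))
  storage.mode(values) <- "double"
  if (modality == "counts") {
    if (any(values < 0, na.rm = TRUE)) stop("counts modality requires non-negative values")
    if (any(abs(values - round(values)) > 1e-8, na.rm = TRUE))
      stop("counts modality requires integer-valued entries")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(view_name = as.character(view_name),
                 feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 values = values,
                 modality = modality),
            class = "omic_view")
}

#' @export
print.omic_view <- function(x, ...) {
  cat(sprintf("omic_view '%s' [%s]: %d features x %d samples\n",
              x$view_name, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omic_view <- function(x) dim(x$values)

#' Read an omic view from delimited text
#'
#' Expects a TSV with feature IDs in the first column and sample IDs in the
#' header. Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @param view_name name for the view; defaults to the file name sans
#'   extension.
#' @param modality modality tag, see [omic_view()].
#' @return An [omic_view()].
#' @export
read_view <- function(path, view_name = sub("\\.[^.]*$", "", basename(path)),
                      modality = c("counts", "abundance", "normalized")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("view file '", path, "' needs a feature-ID column plus >=1 sample column")
  feature_ids <- df[[1]]
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature IDs in '", path, "': ", paste(utils::head(dup, 10), collapse = ", "))
  sample_ids <- colnames(df)[-1]
  num <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df), ncol = length(sample_ids))
  bad <- which(is.na(num) & !is.na(as.matrix(df[-1])) & as.matrix(df[-1]) != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value in '", path, "' at feature '", feature_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "'")
  omic_view(num, view_name = view_name, modality = modality,
            feature_ids = feature_ids, sample_ids = sample_ids)
}

#' Write an omic view as delimited text
#'
#' Inverse of [read_view()]: first column \code{feature_id}, one column per
#' sample. Values are written at full precision so a round trip is exact
#' for integer counts and reproducible to ~1e-15 for doubles.
#'
#' @param view an [omic_view()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_view <- function(view, path) {
  stopifnot(inherits(view, "omic_view"))
  df <- data.frame(feature_id = view$feature_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- view$values
  for (j in seq_along(view$sample_ids))
    df[[view$sample_ids[j]]] <- format(vals[, j], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# valid group and tissue levels used across the pipeline
GROUP_LEVELS <- c("WT", "mdx", "mdxUtrnPP", "mdxUtrnPM")
TISSUE_LEVELS <- c("blood", "muscle", "plasma")

#' Read and validate a sample metadata table
#'
#' The table must contain columns \code{sample_id}, \code{mouse_id},
#' \code{group}, \code{week}, \code{tissue}. Groups are validated against
#' the four-level genotype set (WT, mdx, mdxUtrnPP, mdxUtrnPM) and weeks
#' must be positive integers.
#'
#' @param path path to the metadata TSV.
#' @return A data.frame with validated, typed columns; \code{group} and
#'   \code{tissue} are factors with the full level sets.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a metadata data.frame
#'
#' @param df data.frame with the five metadata columns (character or typed).
#' @return the validated, typed data.frame.
#' @export
validate_metadata <- function(df) {
  needed <- c("sample_id", "mouse_id", "group", "week", "tissue")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[needed]
  df$sample_id <- as.character(df$sample_id)
  df$mouse_id <- as.character(df$mouse_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in metadata: ", paste(utils::head(dup, 10), collapse = ", "))
  badg <- setdiff(unique(as.character(df$group)), GROUP_LEVELS)
  if (length(badg))
    stop("unknown group level(s): ", paste(badg, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = ", "), ")")
  wk <- suppressWarnings(as.numeric(as.character(df$week)))
  if (any(is.na(wk))) stop("non-numeric week value(s): ",
                           paste(utils::head(unique(df$week[is.na(wk)]), 5), collapse = ", "))
  if (any(wk <= 0 | wk != round(wk))) stop("week must be a positive integer")
  badt <- setdiff(unique(as.character(df$tissue)), TISSUE_LEVELS)
  if (length(badt))
    stop("unknown tissue level(s): ", paste(badt, collapse = ", "))
  df$group <- factor(as.character(df$group), levels = GROUP_LEVELS)
  df$week <- as.integer(wk)
  df$tissue <- factor(as.character(df$tissue), levels = TISSUE_LEVELS)
  df
}

#' Write a sample metadata table
#' @param meta metadata data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
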