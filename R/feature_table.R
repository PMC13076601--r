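#' Construct a feature table
#'
#' The central data container of the package: a numeric matrix of lipid
#' abundances with samples as rows and lipid species (features) as columns,
#' plus a per-sample two-level group label (`"case"` / `"control"`).
#' Abundances must be non-negative or missing (`NA`).
#'
#' @param values numeric matrix, samples x features. Row names are taken as
#'   sample identifiers and column names as feature identifiers when
#'   `sample_ids` / `feature_ids` are not given.
#' @param group character or factor of length `nrow(values)` with levels
#'   `"case"` and `"control"`, or `NULL` for an unlabelled table.
#' @param sample_ids,feature_ids optional identifier vectors overriding the
#'   dimnames. Must be unique.
#' @return An object of class `feature_table`: a list with elements
#'   `values` (the matrix, dimnames set), `sample_ids`, `feature_ids`,
#'   `group` (factor or `NULL`).
#' @examples
#' x <- matrix(rexp(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
#' ft <- feature_table(x, group = c("case", "case", "control", "control"))
#' dim(ft)
#' @export
feature_table <- function(values, group = NULL, sample_ids = NULL,
                          feature_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be >= 0 or NA")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(values))
      stop("length(group) must equal nrow(values)")
    bad <- setdiff(unique(group), c("case", "control"))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
    group <- factor(group, levels = c("case", "control"))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, group = group),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat(sprintf("  groups: %d case / %d control\n",
                tab[["case"]], tab[["control"]]))
  }
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(x$values)))
  invisible(x)
}

#' Subset a feature table
#'
#' @param x a [feature_table()].
#' @param i,j sample and feature indices (any standard matrix index).
#' @param ... ignored.
#' @return A `feature_table` restricted to the selected samples/features.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  keep <- stats::setNames(seq_along(x$sample_ids), x$sample_ids)[
    rownames(x$values[i, , drop = FALSE])]
  feature_table(x$values[i, j, drop = FALSE],
                group = if (is.null(x$group)) NULL
                        else as.character(x$group)[keep])
}

# two-group split helper used throughout; errors if a group is empty
split_groups <- function(ft) {
  if (is.null(ft$group)) stop("feature table has no group labels")
  idx <- split(seq_along(ft$group), ft$group)
  if (length(idx$case) == 0L || length(idx$control) == 0L)
    stop("both groups must be non-empty")
  idx
}

# ---- delimited text I/O ------------------------------------------------

detect_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0L) stop("empty file: ", path)
  ntab <- lengths(regmatches(hdr, gregexpr("\t", hdr)))
  ncom <- lengths(regmatches(hdr, gregexpr(",", hdr)))
  if (ntab >= ncom && ntab > 0) "\t" else ","
}

NA_TOKENS <- c("", "na", "nan")

parse_numeric_cells <- function(df, path) {
  out <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    raw <- trimws(as.character(df[[j]]))
    miss <- tolower(raw) %in% NA_TOKENS | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric cell in '%s' at data row %d, column '%s': \"%s\"",
                   path, bad[1], colnames(df)[j], raw[bad[1]]))
    val[miss] <- NA_real_
    out[, j] <- val
  }
  dimnames(out) <- list(rownames(df), colnames(df))
  out
}

#' Read a feature table from delimited text
#'
#' Reads a CSV or TSV export (delimiter auto-detected from the header line
#' unless given) with one header row and one leading identifier column.
#' Empty cells and the tokens `NA` / `NaN` (case-insensitive) become missing
#' values. Tables exported features-as-rows are transposed to the package's
#' samples-as-rows orientation.
#'
#' @param path path to the delimited file.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @param group optional per-sample group labels to attach (in file sample
#'   order), or the name of a metadata data frame column via [read_metadata()].
#' @param delim optional delimiter override (`","` or `"\t"`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               group = NULL, delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  m <- parse_numeric_cells(df, path)
  if (orientation == "features_as_rows") m <- t(m)
  feature_table(m, group = group)
}

#' Write a feature table to delimited text
#'
#' Values are written with full double precision (`format = "%.17g"`
#' equivalent via [format()] with 17 significant digits) so that a
#' write/read round trip is bit-exact.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param orientation written layout; see [read_feature_table()].
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path,
                                orientation = c("samples_as_rows",
                                                "features_as_rows"),
                                delim = ",") {
  orientation <- match.arg(orientation)
  m <- ft$values
  if (orientation == "features_as_rows") m <- t(m)
  txt <- matrix("", nrow(m), ncol(m))
  ok <- !is.na(m)
  txt[ok] <- sprintf("%.17g", m[ok])
  txt[!ok] <- "NA"
  lines <- c(paste(c("id", colnames(m)), collapse = delim),
             paste(rownames(m), apply(txt, 1, paste, collapse = delim),
                   sep = delim))
  writeLines(lines, path)
  invisible(path)
}
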