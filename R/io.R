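#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one tab-separated line per set, fields
#' `name`, `description`, then member gene symbols. Duplicate members
#' within a line are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return A named list of gene sets, each a list with `name`,
#'   `description` and `members` (character vector, unique, non-empty).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   k, length(f)))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members removed", k, f[1]))
      members <- unique(members)
    }
    if (length(members) == 0L)
      stop(sprintf("GMT line %d ('%s') has no members", k, f[1]))
    out[[k]] <- list(name = f[1], description = f[2], members = members)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes")] <- TRUE
  out[x %in% c("0", "false", "no")] <- FALSE
  bad <- !is.na(x) & nzchar(x) & !(x %in% c("1", "0", "true", "false", "yes", "no", "na", "nan"))
  if (any(bad))
    stop("unparseable boolean value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read sample metadata
#'
#' Delimited text with required columns `sample_id` and `group`
#' (`case`/`control`) and optional clinical columns: `gender`
#' (`male`/`female`), `age` (years), comorbidity flags `t2d`,
#' `hypertension`, `obesity` (0/1, true/false or yes/no) and conventional
#' lipids `tc`, `tg`, `ldl_c`, `hdl_c` (mmol/L). Absent optional columns
#' are returned as `NA` (missing), never silently as `FALSE`.
#'
#' @param path path to the metadata file.
#' @param delim optional delimiter override.
#' @return A data frame, one row per sample, with the columns above.
#' @export
read_metadata <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  grp <- trimws(df$group)
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  n <- nrow(df)
  num_or_na <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, n))
    raw <- trimws(df[[col]])
    raw[tolower(raw) %in% NA_TOKENS] <- NA
    v <- suppressWarnings(as.numeric(raw))
    if (any(!is.na(raw) & is.na(v)))
      stop("non-numeric value in metadata column '", col, "'")
    v
  }
  flag_or_na <- function(col) {
    if (!col %in% names(df)) return(rep(NA, n))
    parse_flag(df[[col]])
  }
  lipids <- lapply(c(tc = "tc", tg = "tg", ldl_c = "ldl_c", hdl_c = "hdl_c"),
                   num_or_na)
  for (nm in names(lipids))
    if (any(lipids[[nm]] <= 0, na.rm = TRUE))
      stop("metadata column '", nm, "' must be > 0 when present")
  out <- data.frame(
    sample_id = trimws(df$sample_id),
    group = factor(grp, levels = c("case", "control")),
    gender = if ("gender" %in% names(df))
      factor(tolower(trimws(df$gender)), levels = c("male", "female"))
      else factor(rep(NA_character_, n), levels = c("male", "female")),
    age = num_or_na("age"),
    t2d = flag_or_na("t2d"),
    hypertension = flag_or_na("hypertension"),
    obesity = flag_or_na("obesity"),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(lipids))
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in metadata")
  out
}

#' Write sample metadata
#'
#' @param metadata a metadata data frame as returned by [read_metadata()]
#'   or [simulate_covariates()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, delim = ",") {
  utils::write.table(metadata, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default pipeline thresholds
#'
#' The thresholds applied throughout the pipeline, overridable through a
#' YAML/JSON config file ([read_config()]): `vip` (VIP cutoff, strict >),
#' `p` (univariate significance), `abs_log2fc` (fold-change cutoff,
#' strict >; `NA` disables it for the validation-stage filter), `n_perm`
#' (label permutations for model validation), `cv_folds` (stratified CV
#' folds for Q2), `eigen_min` (eigenvalue retention cutoff, strict >),
#' `panel_size` (lipids in the diagnostic panel) and `seed`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(vip = 1.0, p = 0.05, abs_log2fc = 1.0, n_perm = 200L,
       cv_folds = 7L, eigen_min = 1.0, panel_size = 5L, seed = 1L)
}

#' Read a pipeline config file
#'
#' YAML or JSON (by extension); unknown keys are rejected, missing keys
#' filled from [default_config()]. Every threshold actually applied is
#' reported via `message()` by the functions that use it.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   the defaults.
#' @return Named list with the fields of [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
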