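.trial_columns <- c("STIMID", "USERID", "RT", "ERR", "USERAGE", "GENDER")

#' Read a trial-level behavior table
#'
#' CSV with columns `STIMID`, `USERID`, `RT`, `ERR`, `USERAGE`, `GENDER`
#' (case-insensitive, any order). `ERR` must be 0 (correct) or 1 (error);
#' `GENDER` is validated against 1 (male) / 2 (female).
#'
#' @param path CSV file path.
#' @return Typed trial data frame with the canonical column names.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx <- match(tolower(.trial_columns), tolower(names(df)))
  if (anyNA(idx))
    stop("missing required column(s): ",
         paste(.trial_columns[is.na(idx)], collapse = ", "))
  df <- df[, idx]
  names(df) <- .trial_columns
  df$RT <- as.numeric(df$RT)
  err <- suppressWarnings(as.integer(df$ERR))
  bad <- which(is.na(err) | !(err %in% c(0L, 1L)))
  if (length(bad))
    stop("ERR outside {0, 1} at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$ERR <- err
  g <- suppressWarnings(as.integer(df$GENDER))
  if (any(is.na(g) | !(g %in% c(1L, 2L))))
    stop("GENDER must be 1 (male) or 2 (female)")
  df$GENDER <- g
  df$USERAGE <- as.numeric(df$USERAGE)
  df$STIMID <- as.character(df$STIMID)
  df$USERID <- as.character(df$USERID)
  df
}

#' Write a trial-level behavior table
#' @param trials trial data frame.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.trial_columns %in% names(trials)))
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a stimulus-list table
#'
#' Schema: `STIMID`, `style`, `file_a`, `file_b`, `file_joint`, `n_a`,
#' `n_b`, `area_condition`, `seed` (file columns empty where a style writes
#' no such image).
#'
#' @param path CSV file path.
#' @param stimlist stimulus-list data frame.
#' @return `read_stimlist` the data frame; `write_stimlist` the path,
#'   invisibly.
#' @export
read_stimlist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(STIMID = "character"))
  for (col in c("file_a", "file_b", "file_joint"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df
}

#' @rdname read_stimlist
#' @export
write_stimlist <- function(stimlist, path) {
  utils::write.csv(stimlist, path, row.names = FALSE)
  invisible(path)
}
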