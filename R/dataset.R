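#' Build a validated multi-target dataset
#'
#' Wraps a data frame together with a target specification. Feature columns
#' are every column not consumed by a target; numeric columns stay numeric,
#' everything else becomes a categorical feature whose levels are ordered by
#' first appearance (deterministic candidate enumeration). Rows with a
#' missing value in any target-associated column are dropped with a message;
#' missing feature values are retained and handled at split time.
#'
#' @param df A data frame with a column for every target (and event/exposure
#'   column) plus zero or more feature columns.
#' @param targets An [mt_targets] specification.
#' @return An object of class `mt_dataset`.
#' @export
mt_dataset <- function(df, targets) {
  if (!is.data.frame(df)) mt_stop_config("'df' must be a data.frame")
  if (!inherits(targets, "mt_targets")) targets <- mt_targets(targets)
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  tcols <- mt_target_columns(targets)
  missing_cols <- setdiff(tcols, names(df))
  if (length(missing_cols))
    mt_stop_config(sprintf("column(s) not found in data: %s",
                           paste(missing_cols, collapse = ", ")))

  # Parse/validate target-associated columns.
  parse_num <- function(col, what) {
    x <- df[[col]]
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x)) {
      y <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(y))
      if (length(bad))
        mt_stop_parse(sprintf(
          "non-numeric value '%s' in %s column '%s' at row %d",
          x[bad[1]], what, col, bad[1]))
      y
    } else if (is.numeric(x) || is.logical(x)) {
      as.numeric(x)
    } else {
      mt_stop_parse(sprintf("column '%s' cannot be read as %s", col, what))
    }
  }
  for (t in targets) {
    switch(t$type,
      continuous = { df[[t$name]] <- parse_num(t$name, "continuous") },
      categorical = {
        x <- df[[t$name]]
        df[[t$name]] <- as.character(if (is.factor(x)) as.character(x) else x)
      },
      count = {
        y <- parse_num(t$name, "count")
        bad <- which(!is.na(y) & (y < 0 | y != round(y)))
        if (length(bad))
          mt_stop_parse(sprintf(
            "count column '%s' must hold non-negative integers (row %d)",
            t$name, bad[1]))
        df[[t$name]] <- y
        if (!is.null(t$exposure)) {
          e <- parse_num(t$exposure, "exposure")
          bad <- which(!is.na(e) & e <= 0)
          if (length(bad))
            mt_stop_parse(sprintf(
              "exposure column '%s' must be positive (row %d)",
              t$exposure, bad[1]))
          df[[t$exposure]] <- e
        }
      },
      survival = {
        tt <- parse_num(t$name, "survival time")
        bad <- which(!is.na(tt) & tt < 0)
        if (length(bad))
          mt_stop_parse(sprintf(
            "survival time column '%s' must be >= 0 (row %d)", t$name, bad[1]))
        df[[t$name]] <- tt
        ev <- parse_num(t$event, "event indicator")
        bad <- which(!is.na(ev) & !(ev %in% c(0, 1)))
        if (length(bad))
          mt_stop_parse(sprintf(
            "event column '%s' must be 0/1 (row %d)", t$event, bad[1]))
        df[[t$event]] <- ev
      })
  }

  # Drop rows with missing target-associated values.
  keep <- !Reduce(`|`, lapply(tcols, function(cl) is.na(df[[cl]])),
                  accumulate = FALSE, init = rep(FALSE, nrow(df)))
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("mt_dataset: dropped %d row(s) with missing target values",
                    n_drop))
    df <- df[keep, , drop = FALSE]
  }
  if (!nrow(df)) mt_stop_config("no complete rows remain in the dataset")

  fcols <- setdiff(names(df), tcols)
  ftypes <- character(0)
  flevels <- list()
  for (cl in fcols) {
    x <- df[[cl]]
    if (is.numeric(x)) {
      ftypes[cl] <- "numeric"
    } else {
      x <- as.character(if (is.factor(x)) as.character(x) else x)
      x[!is.na(x) & x == ""] <- NA_character_
      df[[cl]] <- x
      ftypes[cl] <- "categorical"
      flevels[[cl]] <- unique(x[!is.na(x)])  # first-appearance order
    }
  }

  structure(list(
    data = df,
    targets = targets,
    features = ftypes,
    feature_levels = flevels,
    n_rows = nrow(df),
    row_ids = seq_len(nrow(df))
  ), class = "mt_dataset")
}

#' Read a delimited multi-target dataset
#'
#' Reads a header-ed delimited text file (UTF-8; `NA` and the empty string
#' denote missing) and validates it against a target specification via
#' [mt_dataset()].
#'
#' @param path File path.
#' @param targets An [mt_targets] specification.
#' @param delimiter Field separator, `","` or `"\t"`.
#' @return An `mt_dataset`.
#' @export
mt_read_dataset <- function(path, targets, delimiter = ",") {
  if (!file.exists(path))
    mt_stop_config(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  mt_dataset(df, targets)
}

#' Write a multi-target dataset to delimited text
#'
#' Inverse of [mt_read_dataset()] up to floating-point text representation.
#'
#' @param x An `mt_dataset`.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @export
mt_write_dataset <- function(x, path, delimiter = ",") {
  stopifnot(inherits(x, "mt_dataset"))
  utils::write.table(x$data, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat(sprintf("mt_dataset: %d rows, %d feature(s), %d target(s)\n",
              x$n_rows, length(x$features), length(x$targets)))
  invisible(x)
}

# Row subset preserving metadata (row_ids track the original dataset).
mt_subset <- function(x, rows) {
  x$data <- x$data[rows, , drop = FALSE]
  x$row_ids <- x$row_ids[rows]
  x$n_rows <- length(rows)
  x
}
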