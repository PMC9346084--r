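# Readers/writers for the tube-level survival CSV and the base-fraction TSV.
# Both readers validate against the declared schemas and raise classed
# conditions ("ad_schema_error", "ad_parse_error"); nothing is coerced
# silently.  Writers emit a canonical form (fixed column order, sorted rows,
# fixed float formatting) so that write(read(x)) is byte-stable.

#' Read a tube-level survival count table
#'
#' The CSV holds one row per replicate tube: the binomial outcome
#' (`n_alive` of `n_total`) plus the experimental factor levels. Factor
#' levels are checked against the declared vocabularies; counts must be
#' non-negative integers with `n_alive <= n_total`; the pair
#' (`experiment`, `tube_id`) must be unique.
#'
#' @param path Path to a CSV file with the columns listed in
#'   [survival_columns()].
#' @return A `survival_table` (a validated data frame).
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) ad_stop("ad_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("NA", ""), check.names = FALSE)
  validate_survival_table(df)
}

#' @rdname read_survival_table
#' @param df A data frame with the survival-table columns (all character or
#'   already typed).
#' @export
validate_survival_table <- function(df) {
  need <- survival_columns()
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ad_stop("ad_schema_error", "missing required column(s): %s",
            paste(missing, collapse = ", "))
  }
  df <- df[need]
  if (nrow(df) == 0L) {
    df$n_total <- integer(0); df$n_alive <- integer(0)
    class(df) <- c("survival_table", "data.frame")
    return(df)
  }
  for (col in c("n_total", "n_alive")) {
    raw <- as.character(df[[col]])
    bad <- which(is.na(raw) | !grepl("^[0-9]+$", raw))
    if (length(bad)) {
      ad_stop("ad_parse_error", "column %s: non-integer count at row %d",
              col, bad[1])
    }
    df[[col]] <- as.integer(raw)
  }
  bad <- which(df$n_alive > df$n_total)
  if (length(bad)) {
    ad_stop("ad_schema_error",
            "n_alive > n_total at row %d (tube %s)", bad[1], df$tube_id[bad[1]])
  }
  if (any(df$n_total == 0L)) {
    ad_stop("ad_schema_error", "degenerate tube with n_total = 0 at row %d",
            which(df$n_total == 0L)[1])
  }
  voc <- survival_vocab()
  for (col in names(voc)) {
    x <- as.character(df[[col]])
    ok_na <- col %in% na_ok_factors()
    bad <- which(!(x %in% voc[[col]]) & !(ok_na & is.na(x)))
    if (length(bad)) {
      ad_stop("ad_schema_error",
              "column %s: level '%s' at row %d not in declared vocabulary {%s}",
              col, x[bad[1]], bad[1], paste(voc[[col]], collapse = ", "))
    }
    df[[col]] <- x
  }
  df$family_id <- as.character(df$family_id)
  df$tube_id <- as.character(df$tube_id)
  key <- paste(df$experiment, df$tube_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ad_stop("ad_schema_error", "duplicate (experiment, tube_id): %s",
            gsub("\r", ", ", d, fixed = TRUE))
  }
  rownames(df) <- NULL
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a survival table in canonical form
#'
#' Rows are sorted by (`experiment`, `tube_id`), columns are written in the
#' declared order, and missing factor levels are written as `NA`, so writing
#' a table that was just read reproduces the file byte for byte.
#'
#' @param x A `survival_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  x <- validate_survival_table(as.data.frame(x))
  x <- x[order(x$experiment, x$tube_id), survival_columns(), drop = FALSE]
  lines <- paste(survival_columns(), collapse = ",")
  if (nrow(x)) {
    cells <- vapply(survival_columns(), function(col) {
      v <- as.character(x[[col]])
      v[is.na(v)] <- "NA"
      v
    }, character(nrow(x)))
    cells <- matrix(cells, nrow = nrow(x))
    lines <- c(lines, apply(cells, 1, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample base-fraction table
#'
#' Long-format TSV with one row per (sample, position, base): the fraction
#' of reads carrying that base and the total coverage at the position.
#' Positions are 1-based on the (circular) mitochondrial reference.
#' Fractions must lie in `[0, 1]` and sum to at most `1 + 1e-6` within a
#' (sample, position); duplicate (sample, position, base) rows are schema
#' errors.
#'
#' @param path Path to a TSV with columns `sample`, `position`, `base`,
#'   `fraction`, `coverage`.
#' @return A `base_fraction_table` (a validated data frame).
#' @export
read_base_fraction_table <- function(path) {
  if (!file.exists(path)) ad_stop("ad_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character(0), check.names = FALSE)
  validate_base_fraction_table(df)
}

#' @rdname read_base_fraction_table
#' @param df A data frame with the base-fraction columns.
#' @export
validate_base_fraction_table <- function(df) {
  need <- c("sample", "position", "base", "fraction", "coverage")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ad_stop("ad_schema_error", "missing required column(s): %s",
            paste(missing, collapse = ", "))
  }
  df <- df[need]
  if (nrow(df) == 0L) {
    df$position <- integer(0); df$fraction <- numeric(0)
    df$coverage <- integer(0)
    class(df) <- c("base_fraction_table", "data.frame")
    return(df)
  }
  pos_raw <- as.character(df$position)
  bad <- which(!grepl("^[0-9]+$", pos_raw) | as.numeric(pos_raw) < 1)
  if (length(bad)) {
    ad_stop("ad_parse_error", "invalid 1-based position at row %d", bad[1])
  }
  df$position <- as.integer(pos_raw)
  if (!all(df$base %in% c("A", "C", "G", "T"))) {
    bad <- which(!(df$base %in% c("A", "C", "G", "T")))[1]
    ad_stop("ad_schema_error", "base '%s' at row %d not in {A,C,G,T}",
            df$base[bad], bad)
  }
  frac <- suppressWarnings(as.numeric(df$fraction))
  bad <- which(is.na(frac) | frac < 0 | frac > 1)
  if (length(bad)) {
    ad_stop("ad_parse_error", "fraction outside [0, 1] at row %d", bad[1])
  }
  df$fraction <- frac
  cov <- suppressWarnings(as.numeric(df$coverage))
  bad <- which(is.na(cov) | cov < 0 | cov != round(cov))
  if (length(bad)) {
    ad_stop("ad_parse_error", "invalid coverage at row %d", bad[1])
  }
  df$coverage <- as.integer(round(cov))
  key3 <- paste(df$sample, df$position, df$base)
  if (anyDuplicated(key3)) {
    d <- key3[duplicated(key3)][1]
    ad_stop("ad_schema_error", "duplicate (sample, position, base): %s", d)
  }
  sums <- tapply(df$fraction, paste(df$sample, df$position), sum)
  if (any(sums > 1 + 1e-6)) {
    bad <- names(sums)[which(sums > 1 + 1e-6)[1]]
    ad_stop("ad_schema_error",
            "fractions sum to %.6g > 1 at (sample, position) %s",
            max(sums), bad)
  }
  rownames(df) <- NULL
  class(df) <- c("base_fraction_table", "data.frame")
  df
}

#' Write a base-fraction table in canonical form
#'
#' Rows sorted by (sample, position, base); fractions formatted with 9
#' significant digits so values round-trip exactly at the precision the
#' table carries, and rewriting a freshly read canonical file is
#' byte-stable.
#'
#' @param x A `base_fraction_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_base_fraction_table <- function(x, path) {
  x <- validate_base_fraction_table(as.data.frame(x))
  x <- x[order(x$sample, x$position, x$base), , drop = FALSE]
  header <- paste(c("sample", "position", "base", "fraction", "coverage"),
                  collapse = "\t")
  lines <- header
  if (nrow(x)) {
    body <- paste(x$sample, x$position, x$base, fmt_num(x$fraction),
                  x$coverage, sep = "\t")
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the sample-metadata sidecar for base-fraction tables
#'
#' TSV with columns `sample`, `type` (`individual` or `pool`), `year`,
#' `replicate`. Years and replicates may be `NA` for individuals.
#'
#' @param path TSV path.
#' @return A data frame with the four columns, `year` integer.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) ad_stop("ad_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c("sample", "type", "year", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ad_stop("ad_schema_error", "missing required column(s): %s",
            paste(missing, collapse = ", "))
  }
  if (!all(df$type %in% c("individual", "pool"))) {
    ad_stop("ad_schema_error", "type must be 'individual' or 'pool'")
  }
  df$year <- as.integer(df$year)
  df[need]
}

#' @rdname read_sample_metadata
#' @param x The metadata data frame.
#' @export
write_sample_metadata <- function(x, path) {
  x <- x[order(x$sample), c("sample", "type", "year", "replicate")]
  lines <- c("sample\ttype\tyear\treplicate",
             if (nrow(x)) {
               y <- as.character(x$year); y[is.na(y)] <- "NA"
               r <- as.character(x$replicate); r[is.na(r)] <- "NA"
               paste(x$sample, x$type, y, r, sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}
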