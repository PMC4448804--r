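#' Default binarization rules for the CAD clinical variables
#'
#' One rule per variable of [clinical_variables()] (29 rules), transcribing
#' the positivity definitions used in the reference cohort: age >= 66
#' years, male sex, yes for every history/risk/therapy flag, left main
#' stenosis >= 50%, CFR <= 2.0, 1-3 diseased vessels, resting LAD velocity
#' >= 30 cm/s, rest/peak WMSI >= 1.6, delta WMSI >= 0.4.  All `>=`/`<=`
#' comparisons are inclusive at the boundary.
#'
#' @return A list of `binarization_rule` objects, each with fields
#'   `variable_id`, `source_column`, `comparator` (`ge`, `le`, `eq`, `in`)
#'   and `threshold`.
#' @export
default_rules <- function() {
  ref <- clinical_variables()
  lapply(seq_len(nrow(ref)), function(i) {
    thr <- ref$threshold[i]
    cmp <- ref$comparator[i]
    threshold <- switch(cmp,
      ge = as.numeric(thr),
      le = as.numeric(thr),
      eq = thr,
      `in` = strsplit(thr, ",")[[1]]
    )
    structure(list(variable_id = ref$id[i],
                   source_column = ref$source_column[i],
                   comparator = cmp, threshold = threshold),
              class = "binarization_rule")
  })
}

#' @export
print.binarization_rule <- function(x, ...) {
  cat(sprintf("%s: positive iff %s %s %s\n", x$variable_id, x$source_column,
              switch(x$comparator, ge = ">=", le = "<=", eq = "==",
                     `in` = "in"),
              paste(x$threshold, collapse = ",")))
  invisible(x)
}

apply_rule <- function(rule, col) {
  if (rule$comparator %in% c("ge", "le")) {
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d under a numeric comparator",
                     rule$source_column, bad[1]), call. = FALSE)
      }
      col <- suppressWarnings(as.numeric(col))
    }
    out <- if (rule$comparator == "ge") col >= rule$threshold else col <= rule$threshold
  } else if (rule$comparator == "eq") {
    out <- as.character(col) == rule$threshold
  } else {  # in-set
    out <- as.character(col) %in% rule$threshold
    out[is.na(col)] <- NA
  }
  as.integer(out)
}

#' Binarize a raw patient table
#'
#' Applies a list of rules (see [default_rules()]) to the columns of a raw
#' table.  An entry is 1 iff the rule's comparison holds (with inclusive
#' `>=`/`<=` boundaries), 0 if it fails, and missing when the source value
#' is missing.  Column order of the result follows rule order.
#'
#' @param raw A data.frame, one row per patient, with the rules' source
#'   columns.
#' @param rules List of `binarization_rule` objects (default
#'   [default_rules()]).
#' @return Integer matrix in \{0, 1, NA\} with one column per rule, named
#'   by `variable_id`.
#' @examples
#' raw <- data.frame(age = c(66, 65), CFR = c(2.0, 2.1))
#' rules <- Filter(function(r) r$variable_id %in% c("age", "CFR"),
#'                 default_rules())
#' binarize(raw, rules)
#' @export
binarize <- function(raw, rules = default_rules()) {
  if (!is.data.frame(raw)) stop("raw must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(vapply(rules, `[[`, "", "source_column"),
                          names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing source column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cols <- lapply(rules, function(r) apply_rule(r, raw[[r$source_column]]))
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(rules, `[[`, "", "variable_id")
  if ("patient_id" %in% names(raw)) rownames(out) <- as.character(raw$patient_id)
  out
}

#' Load a raw delimited patient table
#'
#' Reads a delimited text file (comma by default, tab accepted) with one
#' header row and one row per patient.  Columns declared numeric are
#' coerced; unparseable cells become missing, with the total count reported
#' as a warning.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (sniff the header line), `"comma"` or `"tab"`.
#' @param numeric_columns Columns to coerce to numeric; defaults to the
#'   continuous measurements of the CAD variable set.
#' @return A data.frame.
#' @export
load_raw_table <- function(path, dialect = c("auto", "comma", "tab"),
                           numeric_columns = c("age", "LM", "CFR",
                                               "Rest_vel_LAD", "Rest_WMSI",
                                               "Peak_WMSI", "Delta_WMSI",
                                               "follow_up_months")) {
  dialect <- match.arg(dialect)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) {
    stop("file has no header row", call. = FALSE)
  }
  sep <- switch(dialect, comma = ",", tab = "\t",
                auto = if (grepl("\t", header)) "\t" else ",")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if ("patient_id" %in% names(raw) && anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }
  n_bad <- 0L
  for (col in intersect(numeric_columns, names(raw))) {
    v <- raw[[col]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    n_bad <- n_bad + sum(is.na(num) & !is.na(v))
    raw[[col]] <- num
  }
  for (col in setdiff(names(raw), numeric_columns)) {
    raw[[col]][raw[[col]] == ""] <- NA
  }
  if (n_bad > 0) {
    warning(sprintf("%d unparseable numeric cell(s) set to missing", n_bad),
            call. = FALSE)
  }
  raw
}

#' Write a binarized table as delimited text
#'
#' @param table Binary matrix (0/1/NA) with variable-ID column names.
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_binary_table <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Reported ischemia-by-CFR cross-tabulation of the reference cohort
#'
#' Reconstructs the published 2x2 cross-tabulation of stress-echo ischemia
#' against reduced coronary flow reserve: of 4313 patients, 1419 had
#' CFR <= 2 (516 of them ischemic) and 2894 had CFR > 2 (249 ischemic).
#' Used as a worked arithmetic example for [mi_mm()].
#'
#' @return A 2x2 integer matrix with dimnames
#'   `ischemia` x `cfr_le2`.
#' @export
ischemia_cfr_table <- function() {
  m <- matrix(c(516L, 903L, 249L, 2645L), nrow = 2,
              dimnames = list(ischemia = c("yes", "no"),
                              cfr_le2 = c("yes", "no")))
  m
}
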