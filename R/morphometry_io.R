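#' Parse a FreeSurfer aseg.stats volume table
#'
#' Reads the whitespace-delimited segmentation statistics dialect: lines
#' starting with `#` are header/comment lines; data rows carry the structure
#' volume in column 4 (`Volume_mm3`) and the structure name in column 5
#' (`StructName`). Parsing is column-position based, matching the FreeSurfer
#' convention (data rows carry no inline header).
#'
#' @param lines Character vector of file lines, or a file path of length 1
#'   pointing to an existing file.
#' @return Named numeric vector: structure name -> volume in mm^3.
#' @examples
#' parse_aseg_stats(c(
#'   "# Title: segmentation statistics",
#'   " 7  10  4717  4712.8  Left-Cerebellum-White-Matter  80.9  4.2  71.0 98.0 27.0"
#' ))
#' @export
parse_aseg_stats <- function(lines) {
  lines <- read_stats_lines(lines)
  out <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 5) {
      stop("malformed aseg.stats data row at line ", i,
           ": expected >= 5 columns, got ", length(tok))
    }
    vol <- suppressWarnings(as.numeric(tok[4]))
    if (is.na(vol)) {
      stop("malformed aseg.stats data row at line ", i,
           ": non-numeric volume '", tok[4], "'")
    }
    out[tok[5]] <- vol
  }
  out
}

#' Parse a FreeSurfer aparc-style cortical statistics table
#'
#' Reads the per-region cortical table dialect: `#` header lines, data rows
#' with the region name in column 1 (`StructName`) and the mean thickness in
#' column 5 (`ThickAvg`). Keys are returned prefixed with the hemisphere code
#' (`lh_` or `rh_`).
#'
#' @param lines Character vector of lines or a path, as in
#'   [parse_aseg_stats()].
#' @param hemisphere `"lh"` or `"rh"`.
#' @return Named numeric vector: `lh_region`/`rh_region` -> mean thickness mm.
#' @export
parse_aparc_stats <- function(lines, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  lines <- read_stats_lines(lines)
  out <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 5) {
      stop("malformed aparc stats data row at line ", i,
           ": expected >= 5 columns (ThickAvg missing?), got ", length(tok))
    }
    thick <- suppressWarnings(as.numeric(tok[5]))
    if (is.na(thick)) {
      stop("malformed aparc stats data row at line ", i,
           ": non-numeric ThickAvg '", tok[5], "'")
    }
    key <- paste0(hemisphere, "_", tok[1])
    if (key %in% names(out)) {
      stop("duplicate region name '", tok[1], "' at line ", i)
    }
    out[key] <- thick
  }
  out
}

read_stats_lines <- function(lines) {
  if (length(lines) == 1 && !grepl("\n", lines) && file.exists(lines)) {
    lines <- readLines(lines)
  }
  as.character(lines)
}

#' Write a minimal valid aseg.stats stream (fixture writer)
#'
#' Emits the segmentation-statistics dialect [parse_aseg_stats()] reads, so
#' that tests can round-trip synthetic volume maps through the parser.
#'
#' @param volumes Named numeric vector, structure name -> volume mm^3.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return The lines, invisibly if written to `path`.
#' @export
write_aseg_stats <- function(volumes, path = NULL) {
  stopifnot(is.numeric(volumes), !is.null(names(volumes)))
  lines <- c(
    "# Title Segmentation Statistics",
    "# ColHeaders  Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange",
    sprintf(" %2d %3d %6d  %.4f  %s  0.0 0.0 0.0 0.0 0.0",
            seq_along(volumes), 10 + seq_along(volumes),
            as.integer(round(unname(volumes))), unname(volumes), names(volumes))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a minimal valid aparc stats stream (fixture writer)
#'
#' @param thickness Named numeric vector, bare region name -> mean thickness.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return The lines, invisibly if written to `path`.
#' @export
write_aparc_stats <- function(thickness, path = NULL) {
  stopifnot(is.numeric(thickness), !is.null(names(thickness)))
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd",
    sprintf("%s  %d  %d  %d  %.4f  0.5  0.1  0.02  10  1.0",
            names(thickness), 1000 + seq_along(thickness),
            700 + seq_along(thickness), 2000 + seq_along(thickness),
            unname(thickness))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Construct a morphometry table
#'
#' The subject-by-feature table is the pipeline's universal currency: one row
#' per subject, 113 morphometric features in canonical schema order, plus
#' diagnosis label, age and sex covariates.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param label Diagnosis per subject, each one of `"HC"`, `"SCZ"`, `"FEP"`.
#' @param age Age in years.
#' @param sex Sex code: 0 = female, 1 = male.
#' @param features Numeric matrix, subjects x 113, with column names equal to
#'   `feature_schema()$feature_names` in canonical order (columns given in a
#'   different order are reordered).
#' @param provenance Free-text processing state: `"raw"`, `"residualized"`,
#'   `"zscored"` or `"synthetic"`.
#' @param schema A [feature_schema()].
#' @return An object of class `morph_table`.
#' @export
morph_table <- function(subject_id, label, age, sex, features,
                        provenance = "raw", schema = feature_schema()) {
  subject_id <- as.character(subject_id)
  label <- as.character(label)
  n <- length(subject_id)
  if (length(label) != n || length(age) != n || length(sex) != n ||
      nrow(features) != n) {
    stop("subject_id, label, age, sex and feature rows must have equal length")
  }
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  bad <- setdiff(unique(label), diagnosis_levels)
  if (length(bad)) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "),
         " (accepted: ", paste(diagnosis_levels, collapse = "/"), ")")
  }
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0 (female) / 1 (male)")
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    if (ncol(features) != length(schema$feature_names)) {
      stop("unnamed feature matrix must have ", length(schema$feature_names),
           " columns")
    }
    colnames(features) <- schema$feature_names
  }
  missing_cols <- setdiff(schema$feature_names, colnames(features))
  extra_cols <- setdiff(colnames(features), schema$feature_names)
  if (length(missing_cols) || length(extra_cols)) {
    stop("feature columns do not match the schema; missing: [",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         "], unexpected: [", paste(utils::head(extra_cols, 5), collapse = ", "), "]")
  }
  features <- features[, schema$feature_names, drop = FALSE]
  if (anyNA(features) || any(!is.finite(features))) {
    bad_feat <- colnames(features)[colSums(!is.finite(features)) > 0]
    stop("non-finite feature values in: ", paste(utils::head(bad_feat, 5), collapse = ", "))
  }
  rownames(features) <- subject_id
  structure(
    list(subject_id = subject_id, label = label,
         age = as.numeric(age), sex = as.numeric(sex),
         features = features, provenance = provenance, schema = schema),
    class = "morph_table"
  )
}

#' @export
print.morph_table <- function(x, ...) {
  cat("<morph_table> ", nrow(x$features), " subjects x ", ncol(x$features),
      " features [", x$provenance, "]\n", sep = "")
  print(table(factor(x$label, levels = diagnosis_levels)))
  invisible(x)
}

#' Number of subjects in a morphometry table
#' @param table A `morph_table`.
#' @export
n_subjects <- function(table) length(table$subject_id)

#' Assemble a morphometry table from per-subject parsed records
#'
#' @param records Named list (one element per subject) of named numeric
#'   vectors holding that subject's features (e.g. the concatenation of two
#'   [parse_aparc_stats()] calls and one [parse_aseg_stats()] call).
#' @param demographics Data frame with columns `subject_id`, `label`, `age`,
#'   `sex`, one row per subject in `records`.
#' @param schema A [feature_schema()].
#' @return A `morph_table` with provenance `"raw"`.
#' @export
assemble_table <- function(records, demographics, schema = feature_schema()) {
  ids <- names(records)
  if (is.null(ids)) stop("records must be a named list keyed by subject id")
  if (!all(ids %in% demographics$subject_id)) {
    stop("demographics missing subject(s): ",
         paste(setdiff(ids, demographics$subject_id), collapse = ", "))
  }
  demo <- demographics[match(ids, demographics$subject_id), ]
  feats <- matrix(NA_real_, length(ids), length(schema$feature_names),
                  dimnames = list(ids, schema$feature_names))
  for (i in seq_along(ids)) {
    rec <- records[[i]]
    missing <- setdiff(schema$feature_names, names(rec))
    if (length(missing)) {
      stop("subject '", ids[i], "' is missing feature(s): ",
           paste(utils::head(missing, 8), collapse = ", "))
    }
    feats[i, ] <- rec[schema$feature_names]
  }
  morph_table(ids, demo$label, demo$age, demo$sex, feats,
              provenance = "raw", schema = schema)
}

#' Read / write the canonical delimited feature table
#'
#' Comma-delimited UTF-8 text with a header row; columns are `subject_id`,
#' `label`, `age`, `sex`, then the 113 schema features in canonical order.
#' The processing provenance travels in a `# provenance:` comment on the
#' first line. Numeric values are written with 15 significant digits, so a
#' write/read round trip reproduces values to at least 12 significant digits.
#'
#' @param table A `morph_table`.
#' @param path File path.
#' @param schema A [feature_schema()].
#' @return `read_table()` returns a `morph_table`; `write_table()` returns
#'   `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "morph_table"))
  df <- data.frame(subject_id = table$subject_id, label = table$label,
                   age = table$age, sex = table$sex, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$features, check.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", table$provenance), con)
  writeLines(paste(colnames(df), collapse = ","), con)
  num <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(df$subject_id[i], df$label[i],
            format(as.numeric(df[i, -(1:2)]), digits = 15, trim = TRUE,
                   scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(num, con)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table <- function(path, schema = feature_schema()) {
  first <- readLines(path, n = 1)
  provenance <- "raw"
  skip <- 0
  if (grepl("^# provenance:", first)) {
    provenance <- trimws(sub("^# provenance:", "", first))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "age", "sex", schema$feature_names)
  if (!identical(colnames(df), need)) {
    stop("table header does not match the canonical schema (",
         length(need), " columns expected)")
  }
  morph_table(df$subject_id, df$label, df$age, df$sex,
              as.matrix(df[, schema$feature_names, drop = FALSE]),
              provenance = provenance, schema = schema)
}

#' Subset a morphometry table by row
#'
#' @param table A `morph_table`.
#' @param rows Integer or logical row index.
#' @return A `morph_table` with the selected subjects.
#' @export
subset_table <- function(table, rows) {
  morph_table(table$subject_id[rows], table$label[rows], table$age[rows],
              table$sex[rows], table$features[rows, , drop = FALSE],
              provenance = table$provenance, schema = table$schema)
}
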