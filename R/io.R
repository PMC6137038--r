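#' Read and write necropsy / stranding record files
#'
#' Records travel as comma-delimited UTF-8 text with a header row and "."
#' decimal separator. A missing debris mass is encoded as an empty field.
#' Numeric fields are written with 17 significant digits so a write-then-read
#' round trip reproduces the records exactly. Unknown columns are preserved
#' but ignored by the models. Rows violating the record invariants (e.g. a KP
#' death with no debris) are rejected with the offending file line number.
#'
#' @param path file path.
#' @param schema either "necropsy" or "strandnet".
#' @return `read_records()` returns a validated `data.frame`;
#'   `write_records()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- generate_necropsy_cohort(generator_params(n_animals = 5))
#' write_records(cohort, f)
#' identical(read_records(f, "necropsy"), cohort)
#' @export
read_records <- function(path, schema = c("necropsy", "strandnet")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if (schema == "necropsy") {
    req <- c("animal_id", "species", "age_class", "ccl_cm", "cod",
             "debris_count", "debris_mass_g")
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0) {
      stop("missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (nrow(df) == 0) return(empty_necropsy_records())
    df$animal_id <- as.character(df$animal_id)
    df$ccl_cm <- as.numeric(df$ccl_cm)
    df$debris_count <- as.integer(df$debris_count)
    df$debris_mass_g <- as.numeric(df$debris_mass_g)
    validate_necropsy_records(df, line_offset = 1L)
  } else {
    req <- c("record_id", "debris_present", "exam_level", "adult", "cod",
             "species")
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0) {
      stop("missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (nrow(df) == 0) return(empty_strandnet_records())
    df$record_id <- as.character(df$record_id)
    df$debris_present <- parse_logical(df$debris_present, "debris_present")
    df$adult <- parse_logical(df$adult, "adult")
    df$exam_level <- as.integer(df$exam_level)
    validate_strandnet_records(df, line_offset = 1L)
  }
}

parse_logical <- function(x, field) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("unparseable %s '%s' at line %d", field, x[bad[1]],
                 bad[1] + 1L), call. = FALSE)
  }
  out
}

#' @param records a record `data.frame` matching one of the two schemas; the
#'   schema is inferred from its columns.
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  if ("animal_id" %in% names(records)) {
    validate_necropsy_records(records)
    out <- records
    out$ccl_cm <- num17(records$ccl_cm)
    out$debris_mass_g <- num17(records$debris_mass_g)
  } else if ("record_id" %in% names(records)) {
    validate_strandnet_records(records)
    out <- records
  } else {
    stop("records match neither the necropsy nor the strandnet schema")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Format numerics with enough digits for an exact double round trip.
num17 <- function(x) {
  out <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out
}
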