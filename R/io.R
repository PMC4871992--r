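#' Read an encounter table from CSV
#'
#' The input dialect is long (tidy): one row per observed acuity entry, with
#' header exactly `note_id, patient_id, eye, field_name, response_text`
#' (UTF-8, comma-delimited). Blank responses are kept (they normalize to
#' `EMPTY`), and duplicate `(note, eye, field)` rows are legal — a field can
#' hold several measurements. Eye and field names are validated against the
#' closed vocabularies (OD/OS, [acuity_fields()]) with the offending row
#' numbers in the error message.
#'
#' @param path Path to an encounters CSV.
#' @return A validated long data frame (character columns).
#' @export
read_encounters <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("note_id", "patient_id", "eye", "field_name", "response_text")
  if (!identical(names(df), required)) {
    stop("encounters file must have header exactly: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df$response_text[is.na(df$response_text)] <- ""
  validate_encounters(df)
  df
}

#' @rdname read_encounters
#' @param encounters A long encounter table.
#' @export
write_encounters <- function(encounters, path) {
  validate_encounters(encounters)
  utils::write.csv(encounters, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read BDVA results
#'
#' Results are written one row per (note, eye), sorted by `note_id` then
#' eye, with header `note_id, eye, bdva, rank, source_field, n_candidates,
#' status`. `NO_ACUITY` rows carry empty `bdva`/`rank`/`source_field`.
#'
#' @param results A BDVA result table from [extract_bdva()].
#' @param path Output CSV path.
#' @export
write_bdva <- function(results, path) {
  out <- results[order(results$note_id, results$eye), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_bdva
#' @export
read_bdva <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("note_id", "eye", "bdva", "rank", "source_field",
                "n_candidates", "status")
  if (!identical(names(df), required)) {
    stop("BDVA file must have header exactly: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df$bdva[df$bdva == ""] <- NA_character_
  df$source_field[df$source_field == ""] <- NA_character_
  df$rank <- suppressWarnings(as.integer(df$rank))
  df$n_candidates <- as.integer(df$n_candidates)
  df
}

#' Read a gold-standard BDVA file
#'
#' Gold files mirror a clinician chart review: header exactly
#' `note_id, eye, bdva`, where `bdva` is a scale label or the literal
#' `NO_ACUITY`.
#'
#' @param path Path to the gold CSV.
#' @return Data frame with character columns.
#' @export
read_gold <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("note_id", "eye", "bdva"))) {
    stop("gold file must have header exactly: note_id, eye, bdva",
         call. = FALSE)
  }
  bad <- !df$eye %in% c("OD", "OS")
  if (any(bad)) {
    stop("invalid eye in gold row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  df
}

#' Compare algorithm BDVA with a gold standard
#'
#' Mirrors a chart-review audit: each gold (note, eye) is compared with the
#' algorithm's extracted category on the label itself (not the rank), with a
#' missing acuity on either side compared as the literal `NO_ACUITY`.
#' Accuracy is simple percentage agreement, reported per eye and overall,
#' with every discordant eye listed. Every gold (note, eye) must be present
#' in the algorithm output; one note per patient is assumed when counting
#' patients.
#'
#' @param results A BDVA result table from [extract_bdva()] or [read_bdva()].
#' @param gold A gold table (`note_id, eye, bdva`) or a path to one.
#' @return An object of class `bdva_accuracy`: a list with `n_patients`,
#'   `n_eyes`, `right_accuracy`, `left_accuracy`, `overall_accuracy`
#'   (percent) and a `discordances` data frame
#'   (`note_id, eye, algorithm_bdva, gold_bdva`).
#' @export
evaluate_accuracy <- function(results, gold) {
  if (is.character(gold) && length(gold) == 1L) gold <- read_gold(gold)
  stopifnot(all(c("note_id", "eye", "bdva") %in% names(gold)))

  pred_label <- ifelse(results$status == "NO_ACUITY", "NO_ACUITY",
                       results$bdva)
  key_pred <- paste(results$note_id, results$eye, sep = "\r")
  key_gold <- paste(gold$note_id, gold$eye, sep = "\r")
  idx <- match(key_gold, key_pred)
  if (anyNA(idx)) {
    miss <- gold[is.na(idx), c("note_id", "eye")]
    stop("gold (note, eye) pairs absent from algorithm output: ",
         paste(paste(miss$note_id, miss$eye), collapse = "; "),
         call. = FALSE)
  }
  algo <- pred_label[idx]
  ok <- algo == gold$bdva

  pct <- function(mask) {
    if (!any(mask)) return(NA_real_)
    100 * sum(ok[mask]) / sum(mask)
  }
  disc <- data.frame(note_id = gold$note_id[!ok], eye = gold$eye[!ok],
                     algorithm_bdva = algo[!ok], gold_bdva = gold$bdva[!ok])
  rownames(disc) <- NULL
  structure(list(n_patients = length(unique(gold$note_id)),
                 n_eyes = nrow(gold),
                 right_accuracy = pct(gold$eye == "OD"),
                 left_accuracy = pct(gold$eye == "OS"),
                 overall_accuracy = pct(rep(TRUE, nrow(gold))),
                 discordances = disc),
            class = "bdva_accuracy")
}

#' @export
print.bdva_accuracy <- function(x, ...) {
  cat("BDVA chart-review comparison\n")
  cat(sprintf("  patients reviewed: %d\n", x$n_patients))
  cat(sprintf("  eyes evaluated:    %d\n", x$n_eyes))
  cat(sprintf("  right eye accuracy: %.1f%%\n", x$right_accuracy))
  cat(sprintf("  left eye accuracy:  %.1f%%\n", x$left_accuracy))
  cat(sprintf("  overall accuracy:   %.1f%%\n", x$overall_accuracy))
  if (nrow(x$discordances)) {
    cat(sprintf("  discordant eyes: %d\n", nrow(x$discordances)))
    print(x$discordances)
  } else {
    cat("  no discordances\n")
  }
  invisible(x)
}

#' Convert a wide per-eye table to the long encounter dialect
#'
#' Some sites export one row per note with a column per (field, eye), e.g.
#' `corrected_od`, `pinhole_os`. This utility stacks such columns into the
#' long format [read_encounters()] defines. Column names must be
#' `<field_name>_<od|os>` (case-insensitive eye suffix); empty cells are
#' dropped.
#'
#' @param wide Data frame with `note_id`, `patient_id` and per-eye acuity
#'   columns.
#' @return A long encounter table.
#' @export
encounters_from_wide <- function(wide) {
  stopifnot(all(c("note_id", "patient_id") %in% names(wide)))
  value_cols <- setdiff(names(wide), c("note_id", "patient_id"))
  pieces <- lapply(value_cols, function(col) {
    m <- regmatches(col, regexec("^(.*)_(od|os)$", tolower(col)))[[1]]
    if (length(m) != 3L || !m[2] %in% acuity_fields()) {
      stop("unrecognized wide column: ", col,
           " (expected <field_name>_<od|os>)", call. = FALSE)
    }
    txt <- as.character(wide[[col]])
    keep <- !is.na(txt) & nzchar(trimws(txt))
    data.frame(note_id = as.character(wide$note_id)[keep],
               patient_id = as.character(wide$patient_id)[keep],
               eye = toupper(m[3]), field_name = m[2],
               response_text = txt[keep])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$note_id, out$eye, out$field_name), , drop = FALSE]
  rownames(out) <- NULL
  validate_encounters(out)
  out
}
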