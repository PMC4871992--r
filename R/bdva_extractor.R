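#' The defined visual acuity fields
#'
#' Acuity can be recorded in eight structured fields per eye: six distance
#' fields — uncorrected, corrected, pinhole, manifest refraction (before
#' dilating drops), cycloplegic refraction (after drops), autorefraction —
#' and two near-vision fields. Only distance fields contribute BDVA
#' candidates; near entries are parsed for auditability but always excluded,
#' because the target quantity is distance Snellen acuity. Any other field
#' name is a hard validation error.
#'
#' @return Character vector of field names.
#' @export
distance_fields <- function() {
  c("uncorrected", "corrected", "pinhole", "manifest_refraction",
    "cycloplegic_refraction", "autorefraction")
}

#' @rdname distance_fields
#' @export
near_fields <- function() c("near_uncorrected", "near_corrected")

#' @rdname distance_fields
#' @export
acuity_fields <- function() c(distance_fields(), near_fields())

#' Field priority used to report the source of a tied BDVA
#'
#' When two fields tie at the best rank the BDVA value is identical either
#' way; the reported `source_field` is chosen by a fixed priority that
#' prefers the most deliberate measurement: manifest refraction, then
#' cycloplegic refraction, pinhole, corrected, uncorrected, autorefraction.
#'
#' @return Character vector of the six distance fields, highest priority
#'   first.
#' @export
default_field_priority <- function() {
  c("manifest_refraction", "cycloplegic_refraction", "pinhole",
    "corrected", "uncorrected", "autorefraction")
}

#' Pick the reported source among tied best candidates
#'
#' @param candidates Data frame with columns `label` and `field_name`, all
#'   rows sharing the minimal rank.
#' @param field_priority Field order, highest priority first.
#' @return The single winning row (category unchanged by construction).
#' @export
tie_break <- function(candidates, field_priority = default_field_priority()) {
  stopifnot(nrow(candidates) >= 1L)
  pr <- match(candidates$field_name, field_priority)
  candidates[order(pr)[1], , drop = FALSE]
}

validate_encounters <- function(encounters) {
  required <- c("note_id", "patient_id", "eye", "field_name", "response_text")
  if (!is.data.frame(encounters) || !all(required %in% names(encounters))) {
    stop("encounters must be a data frame with columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  row <- seq_len(nrow(encounters))
  bad_eye <- !encounters$eye %in% c("OD", "OS")
  if (any(bad_eye)) {
    stop("invalid eye (must be OD or OS) in row(s) ",
         paste(row[bad_eye], collapse = ", "), ": ",
         paste(unique(encounters$eye[bad_eye]), collapse = ", "),
         call. = FALSE)
  }
  bad_field <- !encounters$field_name %in% acuity_fields()
  if (any(bad_field)) {
    stop("invalid field_name in row(s) ",
         paste(row[bad_field], collapse = ", "), ": ",
         paste(unique(encounters$field_name[bad_field]), collapse = ", "),
         call. = FALSE)
  }
  invisible(encounters)
}

#' Normalize every entry of an encounter table
#'
#' Convenience wrapper that validates a long encounter table and appends the
#' per-entry normalization columns of [normalize_acuity()] (`canonical`,
#' `label`, `rank`, `status`, `matched_token`). [extract_bdva()] and
#' [unmapped_report()] both build on this.
#'
#' @param encounters Long data frame with columns `note_id`, `patient_id`,
#'   `eye` (OD/OS), `field_name` (one of [acuity_fields()]) and
#'   `response_text`.
#' @inheritParams normalize_acuity
#' @return The input with normalization columns appended.
#' @export
normalize_entries <- function(encounters, vocab = default_vocabulary(),
                              scale = acuity_scale()) {
  validate_encounters(encounters)
  norm <- normalize_acuity(encounters$response_text, vocab, scale)
  cbind(encounters,
        norm[, c("canonical", "label", "rank", "status", "matched_token")])
}

#' Extract the best documented visual acuity per eye per note
#'
#' For every note, every entry in the defined acuity fields is normalized to
#' a Snellen category; near-vision, unmapped and empty entries are then
#' discarded, and among the remaining distance-field candidates the
#' best-ranked category is returned separately for each eye. A note with no
#' usable distance entry for an eye gets an explicit `NO_ACUITY` status
#' rather than a sentinel value. One result row is produced for each of OD
#' and OS for every note, sorted by `note_id` then eye, and the computation
#' is fully deterministic.
#'
#' @inheritParams normalize_entries
#' @param field_priority Field order used only to pick the reported
#'   `source_field` on rank ties; the BDVA value itself never depends on it.
#' @param verbose If `TRUE`, log every fallback hit and every unmapped
#'   response (with its note id) via [message()] — the hook for ongoing
#'   vocabulary maintenance.
#' @return Data frame with columns `note_id`, `eye`, `bdva` (label or `NA`),
#'   `rank`, `source_field`, `n_candidates` and `status`
#'   (`FOUND`/`NO_ACUITY`).
#' @examples
#' visit_a <- data.frame(
#'   note_id = "A", patient_id = "p1",
#'   eye = c("OD", "OS", "OD", "OS"),
#'   field_name = c("corrected", "corrected",
#'                  "manifest_refraction", "manifest_refraction"),
#'   response_text = c("20/100", "20/40", "20/60", "20/20"))
#' extract_bdva(visit_a)
#' @export
extract_bdva <- function(encounters, vocab = default_vocabulary(),
                         scale = acuity_scale(),
                         field_priority = default_field_priority(),
                         verbose = FALSE) {
  entries <- normalize_entries(encounters, vocab, scale)

  if (verbose) {
    fb <- entries$status == "FALLBACK_HIT"
    for (i in which(fb)) {
      message(sprintf("note %s: fallback matched '%s' -> %s in \"%s\"",
                      entries$note_id[i], entries$matched_token[i],
                      entries$label[i], entries$response_text[i]))
    }
    um <- entries$status == "UNMAPPED"
    for (i in which(um)) {
      message(sprintf("note %s: unmapped response \"%s\"",
                      entries$note_id[i], entries$response_text[i]))
    }
  }

  cand <- entries[entries$status %in% c("VOCAB_HIT", "FALLBACK_HIT") &
                    entries$field_name %in% distance_fields(), , drop = FALSE]

  notes <- unique(as.character(encounters$note_id))
  grid <- data.frame(note_id = rep(notes, each = 2L),
                     eye = rep(c("OD", "OS"), times = length(notes)))
  n_out <- nrow(grid)
  out <- data.frame(note_id = grid$note_id, eye = grid$eye,
                    bdva = rep(NA_character_, n_out),
                    rank = rep(NA_integer_, n_out),
                    source_field = rep(NA_character_, n_out),
                    n_candidates = rep(0L, n_out),
                    status = rep("NO_ACUITY", n_out))

  if (nrow(cand)) {
    key <- paste(cand$note_id, cand$eye, sep = "\r")
    out_key <- paste(out$note_id, out$eye, sep = "\r")
    # order candidates best-first: rank, then field priority, then input order
    ord <- order(cand$rank, match(cand$field_name, field_priority))
    cand <- cand[ord, , drop = FALSE]
    key <- key[ord]
    win <- !duplicated(key)
    idx <- match(key[win], out_key)
    out$bdva[idx] <- cand$label[win]
    out$rank[idx] <- cand$rank[win]
    out$source_field[idx] <- cand$field_name[win]
    counts <- table(key)
    out$n_candidates[idx] <- as.integer(counts[key[win]])
    out$status[idx] <- "FOUND"
  }

  out <- out[order(out$note_id, out$eye), , drop = FALSE]
  rownames(out) <- NULL
  out
}
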