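#' Default sampling weights over the acuity scale
#'
#' The categorical distribution clean acuity values are drawn from: mass is
#' concentrated on 20/20 (38.7%) and 20/25 (18.9%), the most common lines in
#' routine adult ophthalmology clinics, with 86.2% of draws at 20/100 or
#' better and a thin tail through the qualitative categories.
#'
#' @return Named numeric vector over the 17 scale labels, summing to 1.
#' @export
default_acuity_weights <- function() {
  c("20/10" = 0.015, "20/20" = 0.387, "20/25" = 0.189, "20/30" = 0.085,
    "20/40" = 0.060, "20/50" = 0.040, "20/60" = 0.030, "20/70" = 0.022,
    "20/80" = 0.016, "20/100" = 0.018, "20/125" = 0.040, "20/200" = 0.045,
    "20/400" = 0.030, "CF" = 0.012, "HM" = 0.006, "LP" = 0.003,
    "NLP" = 0.002)
}

#' Annotation phrase bank
#'
#' Templates for the free-text commentary clinicians append to an acuity
#' value; `{tok}` marks where the acuity token goes. The bank includes the
#' classic examples seen in real charts ("slow", head tilt, ointment,
#' lighting) and, by construction, contains no competing acuity token — so a
#' decorated entry always normalizes back to its planted category.
#'
#' @return Character vector of templates containing `{tok}`.
#' @export
phrase_bank <- function() {
  c("{tok} slow",
    "after waiting 1 min {tok} in lighted room",
    "{tok} w/head tilted down",
    "{tok} blinking with ointment",
    "{tok} with glasses",
    "{tok} eccentrically",
    "{tok} thru tears",
    "{tok} pt squinting",
    "{tok} difficult exam")
}

# templates used only in adversarial mode; {tok2} is a second, competing
# acuity token that the truth calculation accounts for
adversarial_templates <- function() {
  c("{tok} improved from {tok2}",
    "{tok} was {tok2} last visit",
    "{tok} ph {tok2}")
}

junk_bank <- function() {
  c("not tested", "unable", "poor view", "no view", "eyes closed",
    "deferred", "pt declined exam", "see note")
}

#' Configuration for the synthetic encounter generator
#'
#' Defines the statistical shape of a generated corpus: how many notes, how
#' often a note carries more than one acuity per eye (54% by default, the
#' typical multi-measurement rate of an academic ophthalmology clinic), the
#' per-eye entry cap (7), the acuity distribution, and the per-entry
#' corruption rates — free-text annotation, letter-O-for-zero transposition,
#' plus/minus line modifiers, extra near-vision (Jaeger) entries, and
#' token-free junk entries. `adversarial = TRUE` lets annotations embed a
#' second, competing acuity token (with the ground truth recomputed
#' accordingly) to exercise the multi-token best-of rule.
#'
#' @param n_notes Number of notes to generate.
#' @param seed Integer seed; the same seed and config always yield an
#'   identical corpus.
#' @param p_multi Probability a note has more than one entry for at least
#'   one eye.
#' @param max_entries_per_eye Per-eye entry cap.
#' @param acuity_weights Named weights over scale labels (must sum to 1).
#' @param p_annotation Probability an entry gains surrounding free text.
#' @param p_o_transposition Probability zeros in an entry are typed as the
#'   letter O.
#' @param p_modifier Probability a numeric entry carries a line modifier
#'   such as `+2`.
#' @param p_near_entry Probability an eye gains an extra near-vision entry.
#' @param p_unmappable Probability an entry is token-free junk instead of an
#'   acuity.
#' @param adversarial Plant competing tokens inside annotations.
#' @param scale The acuity scale the weights refer to.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_notes, seed = 1L, p_multi = 0.54,
                              max_entries_per_eye = 7L,
                              acuity_weights = default_acuity_weights(),
                              p_annotation = 0.35, p_o_transposition = 0.05,
                              p_modifier = 0.15, p_near_entry = 0.15,
                              p_unmappable = 0.05, adversarial = FALSE,
                              scale = acuity_scale()) {
  stopifnot(length(n_notes) == 1L, n_notes >= 1L,
            length(seed) == 1L, is.finite(seed),
            max_entries_per_eye >= 1L)
  probs <- c(p_multi = p_multi, p_annotation = p_annotation,
             p_o_transposition = p_o_transposition, p_modifier = p_modifier,
             p_near_entry = p_near_entry, p_unmappable = p_unmappable)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(acuity_weights)) ||
      !all(names(acuity_weights) %in% scale$label) ||
      any(acuity_weights < 0) ||
      abs(sum(acuity_weights) - 1) > 1e-8) {
    stop("acuity_weights must be non-negative, named by scale labels, ",
         "and sum to 1", call. = FALSE)
  }
  structure(list(n_notes = as.integer(n_notes), seed = as.integer(seed),
                 p_multi = p_multi,
                 max_entries_per_eye = as.integer(max_entries_per_eye),
                 acuity_weights = acuity_weights,
                 p_annotation = p_annotation,
                 p_o_transposition = p_o_transposition,
                 p_modifier = p_modifier, p_near_entry = p_near_entry,
                 p_unmappable = p_unmappable,
                 adversarial = isTRUE(adversarial)),
            class = "simulation_config")
}

# distribution of per-eye entry counts inside a multi-acuity note (0..7) and
# field usage frequencies; chosen to keep means near 1.5 entries per eye
multi_count_weights <- function() c(0.10, 0.30, 0.32, 0.14, 0.07, 0.04, 0.02, 0.01)

field_usage_weights <- function() {
  c(uncorrected = 0.20, corrected = 0.45, pinhole = 0.15,
    manifest_refraction = 0.12, cycloplegic_refraction = 0.05,
    autorefraction = 0.03)
}

#' Generate a synthetic encounter corpus with known ground truth
#'
#' Builds `n_notes` synthetic ophthalmology notes in the long encounter
#' dialect, together with a truth table holding the best documented visual
#' acuity each eye should yield. Each entry starts from a clean category
#' drawn from `acuity_weights`; its rendered text is then optionally
#' decorated — annotation phrases from [phrase_bank()], plus/minus line
#' modifiers, letter-O-for-zero typos — and eyes may gain near-vision or
#' junk entries. Decorations are truth-preserving by construction (except in
#' adversarial mode, where planted competing tokens are folded into the
#' truth), so the truth file is an exact oracle for end-to-end extraction.
#' Identical config and seed yield a byte-identical corpus; the caller's RNG
#' state is left untouched.
#'
#' @param config A [simulation_config()].
#' @param scale The acuity scale to draw from.
#' @return A list with `encounters` (long entry table) and `truth`
#'   (`note_id, eye, true_bdva`, where `true_bdva` is a label or
#'   `NO_ACUITY`).
#' @examples
#' corpus <- generate_corpus(simulation_config(n_notes = 3, seed = 7))
#' corpus$truth
#' @export
generate_corpus <- function(config, scale = acuity_scale()) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  labs <- names(config$acuity_weights)
  w <- config$acuity_weights
  numeric_labels <- scale$label[!is.na(scale$denominator)]
  cw <- multi_count_weights()[seq_len(config$max_entries_per_eye + 1L)]

  enc <- vector("list", config$n_notes)
  truth <- vector("list", config$n_notes)

  for (i in seq_len(config$n_notes)) {
    note_id <- sprintf("N%06d", i)
    patient_id <- sprintf("P%06d", i)

    if (stats::runif(1) < config$p_multi) {
      repeat {
        n_od <- sample.int(length(cw), 1L, prob = cw) - 1L
        n_os <- sample.int(length(cw), 1L, prob = cw) - 1L
        if (max(n_od, n_os) >= 2L) break
      }
    } else {
      pick <- sample.int(3L, 1L, prob = c(0.8, 0.1, 0.1))
      n_od <- c(1L, 1L, 0L)[pick]
      n_os <- c(1L, 0L, 1L)[pick]
    }

    rows <- list()
    tb <- c(OD = "NO_ACUITY", OS = "NO_ACUITY")
    for (eye in c("OD", "OS")) {
      n <- if (eye == "OD") n_od else n_os
      eff <- character(0)  # categories that count toward the truth
      if (n > 0L) {
        fields <- sample(names(field_usage_weights()), n, replace = TRUE,
                         prob = field_usage_weights())
        for (k in seq_len(n)) {
          if (stats::runif(1) < config$p_unmappable) {
            txt <- sample(junk_bank(), 1L)
          } else {
            cat_k <- sample(labs, 1L, prob = w)
            eff <- c(eff, cat_k)
            txt <- render_entry(cat_k, config, numeric_labels)
            if (config$adversarial && stats::runif(1) < 0.3) {
              cat2 <- sample(labs, 1L, prob = w)
              tmpl <- sample(adversarial_templates(), 1L)
              txt <- sub("{tok2}", cat2,
                         sub("{tok}", txt, tmpl, fixed = TRUE), fixed = TRUE)
              eff <- c(eff, cat2)
            }
            if (stats::runif(1) < config$p_o_transposition) {
              txt <- gsub("0", "O", txt, fixed = TRUE)
            }
          }
          rows[[length(rows) + 1L]] <-
            c(note_id, patient_id, eye, fields[k], txt)
        }
      }
      if (stats::runif(1) < config$p_near_entry) {
        rows[[length(rows) + 1L]] <-
          c(note_id, patient_id, eye, "near_corrected",
            sample(c("J1", "J2", "J3", "J5", "J10"), 1L))
      }
      if (length(eff)) tb[[eye]] <- best_of(eff, scale)
    }

    enc[[i]] <- do.call(rbind, rows)
    truth[[i]] <- data.frame(note_id = note_id, eye = c("OD", "OS"),
                             true_bdva = unname(tb[c("OD", "OS")]))
  }

  m <- do.call(rbind, enc)
  encounters <- data.frame(note_id = m[, 1], patient_id = m[, 2],
                           eye = m[, 3], field_name = m[, 4],
                           response_text = m[, 5])
  list(encounters = encounters, truth = do.call(rbind, truth))
}

# render one clean category as free text, with optional modifier/annotation
render_entry <- function(category, config, numeric_labels) {
  txt <- category
  if (category %in% numeric_labels &&
      stats::runif(1) < config$p_modifier) {
    txt <- paste0(txt, sample(c("+1", "+2", "-1", "-2"), 1L))
  } else if (!category %in% numeric_labels && stats::runif(1) < 0.3) {
    long <- c(CF = "counting fingers", HM = "hand motion",
              LP = "light perception", NLP = "no light perception")
    txt <- long[[category]]
  }
  if (stats::runif(1) < config$p_annotation) {
    txt <- sub("{tok}", txt, sample(phrase_bank(), 1L), fixed = TRUE)
  }
  txt
}

#' @rdname generate_corpus
#' @param truth A truth table as returned by `generate_corpus()`.
#' @param path Output CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
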