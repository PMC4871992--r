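# Shared fixtures and independent oracles.

# --- worked-example encounters -------------------------------------------

make_encounter <- function(note_id, od = character(0), os = character(0),
                           od_fields = NULL, os_fields = NULL) {
  od_fields <- od_fields %||% rep("corrected", length(od))
  os_fields <- os_fields %||% rep("corrected", length(os))
  data.frame(
    note_id = note_id, patient_id = paste0("pt_", note_id),
    eye = c(rep("OD", length(od)), rep("OS", length(os))),
    field_name = c(od_fields, os_fields),
    response_text = c(od, os))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three sample visits: glasses check (refracted), retina visit (pinhole),
# eyelid visit (single correction check)
visit_a <- function() make_encounter(
  "visit_a",
  od = c("20/100", "20/60"), os = c("20/40", "20/20"),
  od_fields = c("corrected", "manifest_refraction"),
  os_fields = c("corrected", "manifest_refraction"))

visit_b <- function() make_encounter(
  "visit_b",
  od = c("20/100", "20/70"), os = c("20/40", "20/25"),
  od_fields = c("corrected", "pinhole"),
  os_fields = c("corrected", "pinhole"))

visit_c <- function() make_encounter(
  "visit_c", od = "20/100", os = "20/40")

# two acuity fields per eye, as captured from a provider input screen
screenshot_note <- function() make_encounter(
  "screenshot",
  od = c("20/50", "20/30"), os = c("20/30", "20/20"),
  od_fields = c("uncorrected", "pinhole"),
  os_fields = c("uncorrected", "pinhole"))

bdva_for <- function(results, note, eye) {
  results$bdva[results$note_id == note & results$eye == eye]
}

# --- independent oracles --------------------------------------------------

# ordering key built directly from clinical semantics, independent of the
# scale's stored ranks: numeric categories order by denominator, qualitative
# ones sit below all of them in CF < HM < LP < NLP order
oracle_key <- function(label) {
  vapply(label, function(l) {
    if (grepl("^20/[0-9]+$", l)) return(as.numeric(sub("^20/", "", l)))
    1e6 + match(l, c("CF", "HM", "LP", "NLP"))
  }, numeric(1))
}

# brute-force best: pairwise comparison by key
oracle_best <- function(labels) {
  best <- labels[1]
  for (l in labels[-1]) if (oracle_key(l) < oracle_key(best)) best <- l
  best
}

oracle_snap <- function(d) {
  dens <- c(10, 20, 25, 30, 40, 50, 60, 70, 80, 100, 125, 200, 400)
  delta <- abs(dens - d)
  cand <- dens[delta == min(delta)]
  paste0("20/", max(cand))  # tie toward the worse (larger) denominator
}

all_labels <- function() c(paste0("20/", c(10, 20, 25, 30, 40, 50, 60, 70,
                                           80, 100, 125, 200, 400)),
                           "CF", "HM", "LP", "NLP")

# annotation words guaranteed free of acuity tokens
safe_words <- function() {
  c("patient", "blinking", "slow", "tearing", "with", "glasses", "dim",
    "room", "ointment", "squinting", "tilt", "head", "down", "eccentric")
}
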