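---
title: "Extracting best documented visual acuity from ophthalmology EHR notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting best documented visual acuity from ophthalmology EHR notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdva)
```

## The problem

Visual acuity is the vital sign of ophthalmology, yet in most EHRs it is
stored as free text inside defined structured fields. A single encounter can
record several acuities per eye — uncorrected, with current glasses, through
a pinhole, after a manifest or cycloplegic refraction, by autorefraction,
and for near vision — each typed by a provider who may append commentary
("20/20 slow", "20/60 w/head tilted down"), use a plus/minus line modifier
("20/25+2"), or mistype the letter O for a zero ("2O/2O"). Research use of
these notes needs one number per eye per visit.

That number is the **best documented visual acuity (BDVA)**: the best
distance acuity recorded anywhere in the encounter's defined fields for one
eye. It is deliberately not called best *corrected* acuity (BCVA): BCVA is
only knowable when a refraction was actually performed, while BDVA is always
defined by what the chart contains. The package's job is therefore (1)
normalize every free-text response onto a fixed ordinal Snellen scale, and
(2) select the best-ranked category per eye per note.

## The ordinal Snellen scale

All comparisons run over a closed scale of 17 categories: thirteen Snellen
lines from 20/10 through 20/400, then the qualitative categories CF
(counting fingers), HM (hand motion), LP (light perception) and NLP (no
light perception). Rank 1 is 20/10 (best); numeric categories order by
denominator; every qualitative category ranks below 20/400, in the order
CF < HM < LP < NLP. The qualitative order and their position below the
numeric lines follow standard clinical semantics — CF is what gets recorded
when the largest chart optotype cannot be read — and CF measured at
different distances ("CF @ 3ft", "CF @ 5ft") collapses to the single CF
category, since finer distinctions cannot be represented on the scale.

The scale ships as a plain CSV (`label, denominator, rank`) so a site can
add lines such as 20/15 without touching code; `read_acuity_scale()`
enforces the ordering invariants on any replacement.

Denominators seen in text but absent from the scale (20/15, 20/150) are
snapped to the nearest on-scale denominator, with ties broken toward the
*worse* (larger) denominator — a deliberately conservative rule that never
inflates documented vision; so 20/15 snaps to 20/20, not 20/10.

## Two-stage normalization

Stage one is an exact lookup in a curated vocabulary after canonicalization
(trim, case-fold, whitespace collapse, and O-for-zero repair restricted to
positions adjacent to a digit or a digit-flanked slash, so prose like
"ointment" is never altered). Vocabulary targets are a scale label, `NEAR`
(Jaeger values and print sizes, which measure near vision and must never
count toward a distance BDVA), or `UNMAPPED` (curated non-informative text
such as "not tested"). The curated vocabulary is authoritative: a response
it knows never reaches stage two, even when the text contains an embedded
token that would scan differently. The shipped default vocabulary is a
compact starter set — real deployments are expected to grow it from the
`unmapped_report()` maintenance loop.

Stage two, used only on vocabulary misses, is a literal token scan: Snellen
`20/<digits>` patterns (with trailing line modifiers such as `+2`/`-1`
stripped to the base line, the only choice that is lossless with respect to
a scale that has no modifier categories; the hyphen in "20/20-2" is read as
a modifier, the clinical convention, not a range) and the qualitative
keywords in short or long form, matching "no light perception" before
"light perception". When a field contains several tokens, the best-ranked
one wins — mirroring the encounter-level "best documented" semantics and
checkable against a brute-force oracle; earliest occurrence breaks rank
ties, which cannot change the value. No fuzzy or edit-distance matching is
attempted anywhere: approximate matching could silently change a clinical
value, and the fallback is defined as literal search. Pinhole "NI"/"no
improvement" contributes nothing (it is curated `UNMAPPED`) rather than
inheriting another field's value, since no defensible inheritance rule
exists at the note level.

## Per-eye selection

`extract_bdva()` validates the long entry table against the closed eye
(OD/OS) and field vocabularies — an unknown field name is a hard error, not
a silent inclusion, because BDVA semantics depend on knowing a field is a
distance measurement. All entries are normalized; `NEAR`, `UNMAPPED` and
`EMPTY` entries are discarded; among the remaining distance-field
candidates the minimal rank wins per eye. Near-vision entries are parsed
and carried (for audit) but never become candidates, including a Jaeger
value mistyped into a distance field. An eye with no usable entry gets the
explicit status `NO_ACUITY`, never a sentinel category, so downstream
denominators ("notes with acuity present") stay honest. Autorefraction is
included as a distance candidate field since it is one of the defined
acuity fields.

When two fields tie at the best rank the reported `source_field` is chosen
by a fixed priority (manifest refraction, cycloplegic refraction, pinhole,
corrected, uncorrected, autorefraction — most deliberate measurement
first). This is reporting convenience only; the BDVA value is identical
across tied fields by construction.

## Accuracy evaluation

`evaluate_accuracy()` mirrors a chart-review audit: gold per-eye BDVAs
(`note_id, eye, bdva`, with `NO_ACUITY` as an explicit label) are compared
with the algorithm's output on the category *label*, not the rank, and
percentage agreement is reported per eye and overall together with every
discordant eye. Each gold pair must exist in the algorithm output; patients
are counted as unique note ids (one audited note per patient).

## What the synthetic generator emulates — and what it does not

No public corpus of ophthalmology acuity fields exists, so the package
generates its own validation data. `generate_corpus()` emulates the
structural features of a real academic-clinic corpus: 0–7 entries per eye,
54% of notes carrying more than one acuity for at least one eye, a
categorical acuity distribution peaked at 20/20 (38.7%) and 20/25 (18.9%)
with 86.2% of mass at 20/100 or better, free-text annotation phrases
(including the classic "slow"/"lighted room"/"head tilted"/"ointment"
examples), plus/minus modifiers, O-for-zero typos, extra Jaeger near
entries, and token-free junk entries. Defaults for the corruption rates the
literature does not quantify were fixed once at field-realistic values —
annotation 0.35, O-transposition 0.05, modifier 0.15, near entry 0.15, junk
0.05 — and are not tuned thereafter.

Decorations are truth-preserving by construction: annotation templates
contain no competing acuity token, so the truth file (best clean category
per eye, before decoration) is an exact oracle for end-to-end extraction. A
separate adversarial mode plants a second, competing token inside
annotations and folds it into the recomputed truth, exercising the
multi-token best-of rule. A single integer seed drives one deterministic
stream (the caller's RNG state is saved and restored), so identical
configurations yield byte-identical corpora.

What passing these tests shows is that the *pipeline* is internally
consistent under the stated corpus structure. What it cannot show is
performance on a real EHR: real free text contains misspellings beyond
O-for-zero, institution-specific shorthand, and acuities buried in
narrative sections such as the history of present illness — the last being
a known error source that is explicitly outside the defined-fields design,
here and in any structured-field extractor. Real deployments should expect
an initial unmapped rate and use `unmapped_report()` to curate the
vocabulary, which is the intended maintenance loop.

## Numerical and validation choices

Everything is deterministic: there are no tolerances, no optimization and
no tie left to chance (rank ties break by field priority then input order;
snap ties break to the worse denominator). The validation suite uses
problem sizes chosen to make the property tests sharp while keeping the
suite quick: 10,000 random multisets for the best-of oracle equivalence, a
5,000-note decorated corpus for 100% end-to-end truth recovery, 500
random-position token embeddings for fallback recovery, planted
discordances for exact accuracy arithmetic, and byte-identity checks for
determinism. The 54% multi-entry rate is itself property-checked against a
99% binomial interval at n = 500 notes.

## Limitations

* Distance Snellen only: no logMAR, ETDRS or metric conversion, and no
  pediatric or low-vision scales; near vision is recognized solely to be
  excluded.
* Narrative-text acuities (history of present illness and similar prose
  sections) are out of scope by design.
* The shipped vocabulary is a starter set, not a substitute for
  site-specific curation; the two-stage design assumes the curated map is
  trustworthy wherever it speaks.
* Longitudinal BDVA trajectories across visits, and any BCVA inference, are
  out of scope: BCVA is unknowable from a note without a refraction.
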