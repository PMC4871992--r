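#' Canonicalize a raw free-text acuity response
#'
#' Applies the lossless text repairs every later stage relies on: trim
#' leading/trailing whitespace, case-fold to lower case, collapse internal
#' whitespace runs to single spaces, and repair the common letter-O-for-zero
#' transposition (`"2O/2O"` was typed for `"20/20"`). An `o` is rewritten to
#' `0` only when it sits next to a digit or next to a slash flanked by a
#' digit, so prose such as "room" or "ointment" is never touched. `NA` and
#' blank input canonicalize to the empty string.
#'
#' @param raw Character vector of raw responses.
#' @return Character vector of canonical text, same length.
#' @examples
#' canonicalize_text(c("  20/40 ", "2O/2O", "CF @ 3FT"))
#' @export
canonicalize_text <- function(raw) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  repeat {
    y <- gsub("([0-9])o", "\\10", x)
    y <- gsub("o([0-9])", "0\\1", y)
    y <- gsub("([0-9]/)o", "\\10", y)
    y <- gsub("o(/[0-9])", "0\\1", y)
    if (identical(y, x)) break
    x <- y
  }
  x
}

#' Load an acuity vocabulary
#'
#' The vocabulary is the curated, exact-match stage of normalization: a CSV
#' with header `raw_text, target` mapping each known free-text response
#' (compared after [canonicalize_text()]) to a scale label, to `NEAR` for
#' near-vision responses (Jaeger values, print sizes) that must never count
#' toward distance acuity, or to `UNMAPPED` for curated non-informative
#' responses ("not tested"). The loader validates targets and duplicate keys
#' and reports offending file line numbers.
#'
#' @param path Path to a vocabulary CSV (UTF-8, header required).
#' @param scale The `acuity_scale` the targets must belong to.
#' @return A data frame of class `acuity_vocabulary` with columns `raw_text`
#'   (canonicalized, unique) and `target`.
#' @examples
#' vocab <- default_vocabulary()
#' head(vocab)
#' @export
read_acuity_vocabulary <- function(path, scale = acuity_scale()) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("raw_text", "target"))) {
    stop("vocabulary file must have header exactly: raw_text, target",
         call. = FALSE)
  }
  df$raw_text <- canonicalize_text(df$raw_text)
  line <- seq_len(nrow(df)) + 1L  # file line number, accounting for header
  dup <- duplicated(df$raw_text)
  if (any(dup)) {
    stop("duplicate vocabulary keys at line(s) ",
         paste(line[dup], collapse = ", "), ": ",
         paste(unique(df$raw_text[dup]), collapse = ", "), call. = FALSE)
  }
  valid <- df$target %in% c(scale$label, "NEAR", "UNMAPPED")
  if (!all(valid)) {
    stop("invalid vocabulary target(s) at line(s) ",
         paste(line[!valid], collapse = ", "), ": ",
         paste(unique(df$target[!valid]), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("acuity_vocabulary", "data.frame")
  df
}

#' @rdname read_acuity_vocabulary
#' @export
default_vocabulary <- function() {
  cached <- get0("default_vocab", envir = .bdva_cache)
  if (is.null(cached)) {
    path <- system.file("extdata", "default_vocabulary.csv",
                        package = "bdva", mustWork = TRUE)
    cached <- read_acuity_vocabulary(path)
    assign("default_vocab", cached, envir = .bdva_cache)
  }
  cached
}

# statuses a normalization result can carry
normalization_statuses <- function() {
  c("VOCAB_HIT", "FALLBACK_HIT", "NEAR", "UNMAPPED", "EMPTY")
}

#' Exact vocabulary lookup
#'
#' Stage one of normalization: an exact lookup of the canonicalized text in
#' the curated vocabulary. A hit returns `VOCAB_HIT` (with the mapped scale
#' label), `NEAR`, or `UNMAPPED` according to the curated target. A miss is
#' reported as status `NA` — deliberately distinct from `UNMAPPED` — so the
#' caller knows to proceed to the fallback scan.
#'
#' @param raw Character vector of raw responses.
#' @param vocab An `acuity_vocabulary`.
#' @return Data frame with one row per input: `label` (scale label or `NA`)
#'   and `status` (`NA` on a vocabulary miss).
#' @examples
#' vocab_lookup(c("20/40", "J1", "no light perception", "novel text"),
#'              default_vocabulary())
#' @export
vocab_lookup <- function(raw, vocab = default_vocabulary()) {
  canon <- canonicalize_text(raw)
  target <- vocab$target[match(canon, vocab$raw_text)]
  status <- ifelse(is.na(target), NA_character_,
            ifelse(target == "NEAR", "NEAR",
            ifelse(target == "UNMAPPED", "UNMAPPED", "VOCAB_HIT")))
  label <- ifelse(!is.na(status) & status == "VOCAB_HIT", target, NA_character_)
  data.frame(label = label, status = status)
}

# token patterns for the fallback scan; qualitative patterns are tried in an
# order that keeps "no light perception" from being read as light perception
snellen_token_pattern <- function() {
  "(?<![0-9])20[[:space:]]*/[[:space:]]*([0-9]{1,4})"
}

qualitative_patterns <- function() {
  c(NLP = "\\bnlp\\b|\\bno light perception\\b",
    LP  = "\\blp\\b|(?<!no )\\blight perception\\b",
    HM  = "\\bhm\\b|\\bhand motions?\\b",
    CF  = "\\bcf\\b|\\bcount(?:ing)? fingers\\b")
}

#' Fallback token scan
#'
#' Stage two of normalization, used only when the curated vocabulary misses:
#' the canonicalized text is scanned for literal acuity tokens — Snellen
#' `20/<digits>` patterns (any trailing plus/minus line modifier such as
#' `"+2"` or `"-1"` is stripped to the base line) and the qualitative
#' keywords for CF, HM, LP and NLP. Off-chart denominators pass through
#' [snap_to_scale()]. If several tokens are present the best-ranked one wins
#' (earliest occurrence on a rank tie) and is reported as `matched_token`;
#' with no recognizable token the result is `UNMAPPED`, or `EMPTY` for blank
#' input. No fuzzy matching is attempted: only literal token search.
#'
#' @param raw Character vector of raw responses.
#' @inheritParams rank_of
#' @return Data frame with one row per input: `label`, `status`
#'   (`FALLBACK_HIT`, `UNMAPPED` or `EMPTY`) and `matched_token`.
#' @examples
#' fallback_scan(c("20/20 slow", "20/60 w/head tilted down", "no view"))
#' @export
fallback_scan <- function(raw, scale = acuity_scale()) {
  canon <- canonicalize_text(raw)
  out <- lapply(canon, fallback_scan_one, scale = scale)
  data.frame(label = vapply(out, `[[`, character(1), "label"),
             status = vapply(out, `[[`, character(1), "status"),
             matched_token = vapply(out, `[[`, character(1), "matched_token"))
}

fallback_scan_one <- function(canon, scale) {
  if (!nzchar(canon)) {
    return(list(label = NA_character_, status = "EMPTY",
                matched_token = NA_character_))
  }
  x <- gsub("[−–—]", "-", canon)  # unicode minus/dashes
  labels <- character(0)
  tokens <- character(0)
  pos <- integer(0)

  m <- gregexpr(snellen_token_pattern(), x, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    toks <- regmatches(x, list(m))[[1]]
    dens <- as.integer(sub("^20[[:space:]]*/[[:space:]]*", "", toks))
    labels <- c(labels, snap_to_scale(dens, scale))
    tokens <- c(tokens, toks)
    pos <- c(pos, as.integer(m))
  }
  for (lab in names(qualitative_patterns())) {
    if (!lab %in% scale$label) next
    q <- regexpr(qualitative_patterns()[[lab]], x, perl = TRUE)
    if (q != -1L) {
      labels <- c(labels, lab)
      tokens <- c(tokens, regmatches(x, q))
      pos <- c(pos, as.integer(q))
    }
  }
  if (!length(labels)) {
    return(list(label = NA_character_, status = "UNMAPPED",
                matched_token = NA_character_))
  }
  best <- order(rank_of(labels, scale), pos)[1]
  list(label = labels[best], status = "FALLBACK_HIT",
       matched_token = tokens[best])
}

#' Normalize free-text acuity responses
#'
#' The full two-stage normalization: the curated vocabulary is consulted
#' first (it is authoritative — the fallback is never allowed to override a
#' curated mapping), and only responses the vocabulary has never seen go to
#' the literal token scan of [fallback_scan()]. Deterministic for a fixed
#' vocabulary.
#'
#' @param raw Character vector of raw responses.
#' @inheritParams vocab_lookup
#' @inheritParams rank_of
#' @return Data frame with one row per input: `raw`, `canonical`, `label`
#'   (scale label or `NA`), `rank` (integer or `NA`), `status` (one of
#'   `VOCAB_HIT`, `FALLBACK_HIT`, `NEAR`, `UNMAPPED`, `EMPTY`) and
#'   `matched_token` (the triggering substring for fallback hits).
#' @examples
#' normalize_acuity(c("20/60 blinking with ointment", "J2", ""),
#'                  default_vocabulary())
#' @export
normalize_acuity <- function(raw, vocab = default_vocabulary(),
                             scale = acuity_scale()) {
  canon <- canonicalize_text(raw)
  n <- length(canon)
  label <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  token <- rep(NA_character_, n)

  status[!nzchar(canon)] <- "EMPTY"

  todo <- is.na(status)
  if (any(todo)) {
    hit <- vocab_lookup(canon[todo], vocab)
    label[todo] <- hit$label
    status[todo] <- hit$status
  }
  todo <- is.na(status)
  if (any(todo)) {
    fb <- fallback_scan(canon[todo], scale)
    label[todo] <- fb$label
    status[todo] <- fb$status
    token[todo] <- fb$matched_token
  }
  rank <- rep(NA_integer_, n)
  has <- !is.na(label)
  if (any(has)) rank[has] <- rank_of(label[has], scale)
  data.frame(raw = as.character(raw), canonical = canon, label = label,
             rank = rank, status = status, matched_token = token)
}

#' Report unmapped responses for vocabulary maintenance
#'
#' A free-text field accepts strings the vocabulary has never seen, so the
#' mapping needs ongoing curation. This report tallies every response that
#' ended `UNMAPPED` (neither curated nor containing a recognizable token),
#' most frequent first, so a maintainer can triage new vocabulary entries.
#'
#' @param normalized A data frame holding at least columns `response_text`
#'   (or `raw`) and `status`, e.g. the output of [normalize_entries()].
#' @return Data frame with columns `raw_text` and `n`, sorted by descending
#'   count, ties broken lexicographically.
#' @export
unmapped_report <- function(normalized) {
  text_col <- if ("response_text" %in% names(normalized)) "response_text" else "raw"
  if (!all(c(text_col, "status") %in% names(normalized))) {
    stop("normalized entries must have a text column and a status column",
         call. = FALSE)
  }
  um <- normalized[[text_col]][normalized$status == "UNMAPPED"]
  if (!length(um)) {
    return(data.frame(raw_text = character(0), n = integer(0)))
  }
  tab <- table(um)
  out <- data.frame(raw_text = names(tab), n = as.integer(tab))
  out <- out[order(-out$n, out$raw_text), , drop = FALSE]
  rownames(out) <- NULL
  out
}
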