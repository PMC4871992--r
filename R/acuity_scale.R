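#' The canonical Snellen category scale
#'
#' The scale is the fixed, totally ordered set of acuity categories that every
#' free-text response is mapped onto: thirteen numeric Snellen lines from
#' 20/10 down to 20/400, followed by the four qualitative categories CF
#' (counting fingers), HM (hand motion), LP (light perception) and NLP (no
#' light perception). Rank 1 is the best vision (20/10); larger ranks are
#' worse. Every qualitative category ranks below every numeric line, in the
#' order CF, HM, LP, NLP: CF is recorded when the largest chart optotype
#' cannot be read, so it is worse than 20/400, and the remaining three are
#' progressively more severe.
#'
#' The scale ships as a plain CSV resource (`label, denominator, rank`) so a
#' site can extend it (for example, add a 20/15 line) without code changes;
#' [read_acuity_scale()] validates any replacement file against the same
#' invariants.
#'
#' @param path Path to a scale CSV. Defaults to the packaged scale.
#' @return A data frame of class `acuity_scale` with columns `label`
#'   (character, unique), `denominator` (integer, `NA` for qualitative
#'   categories) and `rank` (integer, consecutive from 1, best first).
#' @examples
#' scale <- acuity_scale()
#' scale$label[scale$rank <= 2]
#' @export
acuity_scale <- function() {
  cached <- get0("default_scale", envir = .bdva_cache)
  if (is.null(cached)) {
    cached <- read_acuity_scale(default_scale_path())
    assign("default_scale", cached, envir = .bdva_cache)
  }
  cached
}

.bdva_cache <- new.env(parent = emptyenv())

#' @rdname acuity_scale
#' @export
default_scale_path <- function() {
  system.file("extdata", "snellen_scale.csv", package = "bdva", mustWork = TRUE)
}

#' @rdname acuity_scale
#' @export
read_acuity_scale <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(df), c("label", "denominator", "rank"))) {
    stop("scale file must have header exactly: label, denominator, rank",
         call. = FALSE)
  }
  df$denominator <- suppressWarnings(as.integer(df$denominator))
  df$rank <- suppressWarnings(as.integer(df$rank))
  validate_acuity_scale(df)
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("acuity_scale", "data.frame")
  df
}

qualitative_labels <- function() c("CF", "HM", "LP", "NLP")

validate_acuity_scale <- function(df) {
  n <- nrow(df)
  if (n < 1L) stop("scale is empty", call. = FALSE)
  if (anyDuplicated(df$label)) stop("scale labels must be unique", call. = FALSE)
  if (anyNA(df$rank) || !setequal(df$rank, seq_len(n))) {
    stop("scale ranks must be unique and consecutive from 1", call. = FALSE)
  }
  num <- df[!is.na(df$denominator), , drop = FALSE]
  qual <- df[is.na(df$denominator), , drop = FALSE]
  if (any(num$denominator <= 0L)) {
    stop("numeric scale denominators must be positive", call. = FALSE)
  }
  # rank order and denominator order must agree for numeric lines
  num <- num[order(num$rank), , drop = FALSE]
  if (is.unsorted(num$denominator, strictly = TRUE)) {
    stop("numeric categories must rank strictly by denominator", call. = FALSE)
  }
  if (nrow(qual)) {
    if (!all(qual$label %in% qualitative_labels())) {
      stop("qualitative categories must be among: ",
           paste(qualitative_labels(), collapse = ", "), call. = FALSE)
    }
    if (nrow(num) && min(qual$rank) <= max(num$rank)) {
      stop("every qualitative category must rank worse than every numeric one",
           call. = FALSE)
    }
    expected <- qualitative_labels()[qualitative_labels() %in% qual$label]
    if (!identical(qual$label[order(qual$rank)], expected)) {
      stop("qualitative categories must be ordered CF < HM < LP < NLP",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Rank of a Snellen category
#'
#' Returns the ordinal rank of one or more category labels on the scale,
#' where rank 1 is the best vision (20/10 on the default scale, with 20/20 at
#' rank 2) and larger ranks are progressively worse.
#'
#' @param label Character vector of category labels, e.g. `"20/40"`, `"CF"`.
#' @param scale An `acuity_scale`, by default the packaged scale.
#' @return Integer vector of ranks, same length as `label`.
#' @examples
#' rank_of(c("20/10", "20/20", "NLP"))
#' @export
rank_of <- function(label, scale = acuity_scale()) {
  idx <- match(label, scale$label)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("not on the acuity scale: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scale$rank[idx]
}

#' Best of a set of Snellen categories
#'
#' Selects the category with the best vision (minimal rank) from a non-empty
#' collection. Duplicates are allowed; the result is always a member of the
#' input. This is the selection rule applied per eye per encounter to obtain
#' the best documented visual acuity.
#'
#' @param labels Non-empty character vector of scale labels.
#' @inheritParams rank_of
#' @return A single category label.
#' @examples
#' best_of(c("20/100", "20/60"))
#' @export
best_of <- function(labels, scale = acuity_scale()) {
  if (length(labels) == 0L) {
    stop("best_of() requires at least one category; ",
         "handle 'no acuity recorded' before calling", call. = FALSE)
  }
  labels[which.min(rank_of(labels, scale))]
}

#' Snap an arbitrary Snellen denominator onto the scale
#'
#' Free text can contain Snellen lines that are not on the canonical chart
#' (e.g. 20/15, 20/150). Such denominators are mapped to the on-scale
#' category with the nearest denominator; a tie is broken toward the worse
#' (larger) denominator so that snapping never inflates documented vision.
#'
#' @param denominator Positive integer vector of Snellen denominators (feet).
#' @inheritParams rank_of
#' @return Character vector of on-scale labels.
#' @examples
#' snap_to_scale(c(40, 15, 150))
#' @export
snap_to_scale <- function(denominator, scale = acuity_scale()) {
  denominator <- as.numeric(denominator)
  if (anyNA(denominator) || any(denominator <= 0)) {
    stop("denominator must be positive", call. = FALSE)
  }
  dens <- scale$denominator[!is.na(scale$denominator)]
  labs <- scale$label[!is.na(scale$denominator)]
  vapply(denominator, function(d) {
    delta <- abs(dens - d)
    cand <- which(delta == min(delta))
    # tie: take the larger (worse) denominator
    labs[cand[which.max(dens[cand])]]
  }, character(1))
}
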