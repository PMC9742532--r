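# Binned-points risk score tables (questionnaire scores such as the New
# Chinese Diabetes Risk Score or the ADA risk test). Point values are
# configuration data, not package constants: the shipped JSON files under
# inst/extdata are clearly-marked placeholders with the published cutoffs.

#' Construct a binned-points risk score table
#'
#' @param name Score name.
#' @param items List of items; each item is a list with `feature` (column
#'   name), `breaks` (numeric cut points defining half-open intervals
#'   `[b_i, b_{i+1})`, implicitly extended by -Inf/Inf) OR `categories`
#'   (list mapping category sets to points), and `points` (integer vector,
#'   one per bin, same length as `length(breaks) + 1` for numeric items).
#' @param cutoff Total score at or above which a person screens positive.
#' @return Object of class `score_table`.
#' @export
score_table <- function(name, items, cutoff) {
  stopifnot(is.character(name), length(items) >= 1)
  for (it in items) {
    if (is.null(it$feature)) stop("every item needs a feature name", call. = FALSE)
    if (!is.null(it$breaks)) {
      if (is.unsorted(it$breaks, strictly = TRUE)) {
        stop("item '", it$feature, "': breaks must be strictly increasing",
             call. = FALSE)
      }
      if (length(it$points) != length(it$breaks) + 1L) {
        stop("item '", it$feature, "': need length(breaks)+1 point values",
             call. = FALSE)
      }
    } else if (is.null(it$categories)) {
      stop("item '", it$feature, "' needs breaks or categories", call. = FALSE)
    }
    pts <- if (!is.null(it$breaks)) it$points else unlist(it$categories)
    if (any(pts < 0) || any(pts != round(pts))) {
      stop("item '", it$feature, "': points must be non-negative integers",
           call. = FALSE)
    }
  }
  structure(list(name = name, items = items, cutoff = cutoff),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> ", x$name, " (cutoff ", x$cutoff, ")\n", sep = "")
  for (it in x$items) cat("  - ", it$feature, "\n", sep = "")
  invisible(x)
}

score_item <- function(item, values) {
  if (!is.null(item$breaks)) {
    bin <- findInterval(values, item$breaks) + 1L   # 1..length(points)
    item$points[bin]
  } else {
    keys <- names(item$categories)
    idx <- match(as.character(values), keys)
    if (anyNA(idx[!is.na(values)])) {
      bad <- unique(values[is.na(idx) & !is.na(values)])
      stop(sprintf("feature '%s': value(s) %s outside all declared categories",
                   item$feature, paste(bad, collapse = ", ")), call. = FALSE)
    }
    unlist(item$categories)[idx]
  }
}

#' Apply a score table to a population
#'
#' Total score is the sum of the per-item points of the bin containing each
#' person's value; screen-positive means total score at or above the cutoff.
#'
#' @param table A [score_table()].
#' @param pop Population table containing every item's feature, complete.
#' @return Tibble with `id` (if present), `score` and `positive`.
#' @export
apply_score_table <- function(table, pop) {
  stopifnot(inherits(table, "score_table"))
  missing_feats <- setdiff(vapply(table$items, `[[`, "", "feature"), names(pop))
  if (length(missing_feats) > 0) {
    stop("population lacks score features: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  total <- rep(0L, nrow(pop))
  for (it in table$items) {
    v <- pop[[it$feature]]
    if (anyNA(v)) {
      stop(sprintf("feature '%s' has missing values; impute before scoring",
                   it$feature), call. = FALSE)
    }
    total <- total + as.integer(score_item(it, v))
  }
  out <- tibble::tibble(score = total, positive = total >= table$cutoff)
  if ("id" %in% names(pop)) out <- tibble::add_column(out, id = pop$id, .before = 1)
  out
}

#' Read / write a score table as JSON
#'
#' Schema: `{name, cutoff, items: [{feature, breaks, points} |
#' {feature, categories}]}`.
#'
#' @param path JSON file path.
#' @return [score_table()] object.
#' @export
read_score_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(raw$items, function(it) {
    out <- list(feature = it$feature)
    if (!is.null(it$breaks)) {
      out$breaks <- as.numeric(unlist(it$breaks))
      out$points <- as.integer(unlist(it$points))
    }
    if (!is.null(it$categories)) out$categories <- lapply(it$categories, as.integer)
    out
  })
  score_table(raw$name, items, as.integer(raw$cutoff))
}

#' @rdname read_score_table
#' @param table A [score_table()] to serialise.
#' @export
write_score_table <- function(table, path) {
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
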