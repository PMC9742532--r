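# File I/O for population tables and configuration, plus structured
# logging. CSV is the population contract (full-precision numerics,
# unknown columns preserved); YAML carries configuration.

population_mandatory_cols <- function() c("id", "fpg", "p2hpg", "hba1c", "dm_status")

#' Write / read a population table as CSV
#'
#' Numerics are written at full (shortest round-trip) precision, so a
#' write-read cycle is value-exact. Unknown columns are preserved; the
#' `subtype` column is restored as a factor with the canonical levels.
#'
#' @param pop Population table.
#' @param path CSV path.
#' @export
write_population <- function(pop, path) {
  readr::write_csv(pop, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @return `read_population()` returns a tibble.
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(population_mandatory_cols(), names(pop))
  if (length(miss) > 0) {
    stop("population file lacks mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pop$dm_status <- as.logical(pop$dm_status)
  if ("subtype" %in% names(pop)) {
    pop$subtype <- factor(pop$subtype, levels = subtype_levels())
  }
  pop
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML path.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$feature_baselines <- lapply(raw$feature_baselines, function(b) {
    b$iqr <- as.numeric(unlist(b$iqr)); b
  })
  raw$target_subtype_fractions <- unlist(raw$target_subtype_fractions)
  do.call(generator_config, raw)
}

#' Write / read a cost schedule as YAML
#'
#' @param schedule A [cost_schedule()].
#' @param path YAML path.
#' @export
write_cost_schedule <- function(schedule, path) {
  yaml::write_yaml(list(
    medical = as.list(schedule$medical),
    nonmedical = as.list(schedule$nonmedical),
    complication_per_dm_year = lapply(schedule$complication_per_dm_year,
                                      as.numeric)), path)
  invisible(path)
}

#' @rdname write_cost_schedule
#' @export
read_cost_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  cost_schedule(medical = unlist(raw$medical),
                nonmedical = unlist(raw$nonmedical),
                complication_per_dm_year = lapply(raw$complication_per_dm_year,
                                                  as.numeric))
}

#' Structured log line
#'
#' Emits `<ISO timestamp> [LEVEL] stage: message` as an R message and, when
#' `file` is given, appends it there. Timestamps never enter report files.
#'
#' @param level "INFO", "WARNING" or "ERROR".
#' @param stage Pipeline stage name.
#' @param msg Message text.
#' @param file Optional log file to append to.
#' @return The formatted line, invisibly.
#' @export
log_event <- function(level = c("INFO", "WARNING", "ERROR"), stage, msg,
                      file = NULL) {
  level <- match.arg(level)
  line <- sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg)
  message(line)
  if (!is.null(file)) cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}

#' Descriptive cohort summary stratified by diabetes status
#'
#' Medians (IQRs) for continuous features with Kruskal-Wallis p-values,
#' counts (%) for integer-coded categoricals with chi-square p-values.
#'
#' @param pop Population table.
#' @return Tidy tibble: `feature`, `kind`, `overall`, `non_dm`, `dm`,
#'   `p_value`.
#' @export
descriptive_table <- function(pop) {
  feat_cols <- setdiff(names(pop), c("id", "dm_status", "subtype"))
  grp <- as.logical(pop$dm_status)
  fmt_miqr <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
  }
  rows <- lapply(feat_cols, function(cl) {
    x <- pop[[cl]]
    categorical <- length(unique(stats::na.omit(x))) <= 5
    if (categorical) {
      tab <- table(x, grp)
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      fmt <- function(v) paste(sprintf("%d (%.1f%%)", as.integer(table(v)),
                                       100 * prop.table(table(v))),
                               collapse = "; ")
      tibble::tibble(feature = cl, kind = "categorical",
                     overall = fmt(x), non_dm = fmt(x[!grp]), dm = fmt(x[grp]),
                     p_value = p)
    } else {
      p <- tryCatch(stats::kruskal.test(x, factor(grp))$p.value,
                    error = function(e) NA_real_)
      tibble::tibble(feature = cl, kind = "continuous",
                     overall = fmt_miqr(x), non_dm = fmt_miqr(x[!grp]),
                     dm = fmt_miqr(x[grp]), p_value = p)
    }
  })
  dplyr::bind_rows(rows)
}
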