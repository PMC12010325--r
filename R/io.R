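#' Write a spectrum as two-column plain text
#'
#' Energy/intensity pairs, one per line, preceded by `# key: value` header
#' lines carrying scalar metadata. Numbers are printed with 17 significant
#' digits, so `read_spectrum(write_spectrum(s))` round-trips exactly.
#'
#' @param s An [xas_spectrum()].
#' @param path Output file path.
#' @param sep Column separator for the data lines (`" "` or `","`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = " ") {
  stopifnot(is_xas_spectrum(s))
  meta <- s$meta[vapply(s$meta, function(v)
    (is.character(v) || is.numeric(v) || is.logical(v)) && length(v) == 1L, TRUE)]
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) format(v, digits = 17), ""))
  body <- paste(sprintf("%.17g", s$energies), sprintf("%.17g", s$intensities),
                sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-column spectrum file
#'
#' Accepts whitespace- or comma-separated energy/intensity columns and
#' `# key: value` header lines (stored in `meta`). Malformed, non-finite or
#' non-monotone rows are rejected with the offending line number.
#'
#' @param path Input file path.
#' @return An [xas_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  energies <- numeric(0); intensities <- numeric(0)
  data_line_no <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1L]]
      if (length(m) == 3L) {
        val <- m[3L]
        num <- suppressWarnings(as.numeric(val))
        meta[[trimws(m[2L])]] <- if (!is.na(num)) num else val
      }
      next
    }
    parts <- strsplit(ln, "[,[:space:]]+")[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L)
      stop(sprintf("%s line %d: expected two columns, got %d", path, i, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || any(!is.finite(vals)))
      stop(sprintf("%s line %d: non-numeric or non-finite value", path, i))
    energies <- c(energies, vals[1L]); intensities <- c(intensities, vals[2L])
    data_line_no <- c(data_line_no, i)
  }
  if (!length(energies)) stop(sprintf("%s: no data rows", path))
  bad <- which(diff(energies) <= 0)
  if (length(bad))
    stop(sprintf("%s line %d: energies not strictly increasing", path,
                 data_line_no[bad[1L] + 1L]))
  xas_spectrum(energies, intensities, meta)
}

#' Write candidate models as a delimited stick table
#'
#' One row per transition with header
#' `model_id,site,energy_eV,intensity` (plus `binding_mode_class`).
#'
#' @param models List of [model_entry()] objects (or a single one).
#' @param path Output file path.
#' @param sep Field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_stick_table <- function(models, path, sep = ",") {
  if (inherits(models, "model_entry")) models <- list(models)
  stopifnot(is.list(models), all(vapply(models, inherits, TRUE, "model_entry")))
  rows <- do.call(rbind, lapply(models, function(m)
    do.call(rbind, lapply(m$sites, function(st)
      if (length(st$energies))
        data.frame(model_id = m$model_id, site = st$site,
                   energy_eV = st$energies, intensity = st$intensities,
                   binding_mode_class = m$binding_mode_class,
                   stringsAsFactors = FALSE)))))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stick table into candidate models
#'
#' Accepts comma- or tab-separated files with a header naming at least
#' `model_id`, `site`, `energy_eV` and `intensity` (an optional
#' `binding_mode_class` column is honoured). Rows may appear in any order;
#' they are grouped by model and site. Unknown site labels and missing
#' columns are rejected by name. Sites without rows for a model are given
#' empty transition lists so that every model carries all four sites.
#'
#' @param path Input file path.
#' @return Named list of [model_entry()] objects, ordered by first
#'   appearance.
#' @export
read_stick_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("model_id", "site", "energy_eV", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  bad_site <- setdiff(unique(df$site), SITE_LABELS)
  if (length(bad_site))
    stop(sprintf("%s: unknown site label(s): %s", path,
                 paste(bad_site, collapse = ", ")))
  ids <- unique(df$model_id)
  models <- lapply(ids, function(id) {
    sub <- df[df$model_id == id, , drop = FALSE]
    sites <- lapply(SITE_LABELS, function(lab) {
      ss <- sub[sub$site == lab, , drop = FALSE]
      stick_spectrum(lab, ss$energy_eV, ss$intensity)
    })
    cls <- if ("binding_mode_class" %in% names(sub)) sub$binding_mode_class[1L] else "unknown"
    model_entry(id, sites, cls)
  })
  names(models) <- ids
  models
}

#' Write a ranking table as CSV
#'
#' @param ranking A `"ranking_result"` from [rank_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking_result"))
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
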