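#' Read a delimited-text cytometry event table
#'
#' Canonical event-table dialect: delimited text with one row per event and
#' named channel columns `FSC-A`, `SSC-A`, `FL1-A` (case-insensitive;
#' `fsc_a`-style names also accepted). Delimiter is sniffed by readr.
#'
#' @param path File path.
#' @param sample_id Optional sample label; defaults to the file name without
#'   extension when the file carries no `sample_id` column.
#' @return A tibble with columns `sample_id`, `fsc_a`, `ssc_a` (if present),
#'   `fl1_a`.
#' @export
read_events <- function(path, sample_id = NULL) {
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(gsub("[^[:alnum:]]+", "_", names(raw)))
  names(raw) <- nm
  needed <- c("fsc_a", "fl1_a")
  if (!all(needed %in% nm)) {
    abort(sprintf("event file must contain FSC-A and FL1-A columns; found: %s",
                  paste(names(raw), collapse = ", ")))
  }
  if (!"sample_id" %in% nm) {
    raw$sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  }
  keep <- intersect(c("sample_id", "fsc_a", "ssc_a", "fl1_a"), names(raw))
  check_event_table(as_tibble(raw[keep]))
}

#' Write an event table as delimited text
#'
#' Writes the cytometer-style header (`FSC-A`, `SSC-A`, `FL1-A`); hidden
#' ground-truth label columns from the synthetic generator are dropped, as a
#' real instrument would not report them.
#'
#' @param events Event table.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  check_event_table(events)
  out <- events[intersect(c("sample_id", "fsc_a", "ssc_a", "fl1_a"), names(events))]
  names(out) <- sub("^fsc_a$", "FSC-A", names(out))
  names(out) <- sub("^ssc_a$", "SSC-A", names(out))
  names(out) <- sub("^fl1_a$", "FL1-A", names(out))
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path) else readr::write_csv(out, path)
  invisible(path)
}

#' Read a binary FCS cytometry file (optional adapter)
#'
#' Converts a standard FCS file into the package's event-table tibble.
#' Requires the Bioconductor package \pkg{flowCore}, which is not a hard
#' dependency; without it this function stops with an informative message.
#' The delimited-text dialect of [read_events()] is the canonical format.
#'
#' @param path FCS file path.
#' @param sample_id Optional sample label.
#' @return A tibble as from [read_events()].
#' @export
read_fcs_events <- function(path, sample_id = NULL) {
  if (!requireNamespace("flowCore", quietly = TRUE)) {
    abort(paste0(
      "Reading binary FCS files requires the 'flowCore' package. ",
      "Install it from Bioconductor, or export the events as delimited text ",
      "and use read_events()."
    ))
  }
  ff <- flowCore::read.FCS(path, transformation = FALSE)
  m <- flowCore::exprs(ff)
  cols <- colnames(m)
  pick <- function(ch) {
    hit <- grep(paste0("^", ch, "$"), cols, ignore.case = TRUE)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  idx <- c(fsc_a = pick("FSC-A"), ssc_a = pick("SSC-A"), fl1_a = pick("FL1-A"))
  if (any(is.na(idx[c("fsc_a", "fl1_a")]))) {
    abort("FCS file lacks FSC-A / FL1-A channels.")
  }
  out <- tibble(
    sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
    fsc_a = m[, idx["fsc_a"]],
    fl1_a = m[, idx["fl1_a"]]
  )
  if (!is.na(idx["ssc_a"])) out$ssc_a <- m[, idx["ssc_a"]]
  check_event_table(out[unique(c("sample_id", "fsc_a", intersect("ssc_a", names(out)), "fl1_a"))])
}

#' Serialize a gate to JSON / read it back
#'
#' @param gate A [derive_gate()] result.
#' @param path JSON file path.
#' @return `write_gate()` returns `path` invisibly; `read_gate()` returns the
#'   `lox_gate` object.
#' @export
write_gate <- function(gate, path) {
  if (!inherits(gate, "lox_gate")) abort("`gate` must be a lox_gate.")
  jsonlite::write_json(unclass(gate), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(x$fl1_low) || is.data.frame(x$fl1_low)) x$fl1_low <- as_tibble(x$fl1_low)
  structure(x, class = "lox_gate")
}
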