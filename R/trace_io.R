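#' Construct a force-rotation trace
#'
#' A trace is one device test on one plant: ordered samples of rotation
#' (degrees, from the footplate IMU) and force (newtons, from the load
#' cell), together with the height at which the load was applied and the
#' identity of the test. Tests on a plant are labelled `"A"`, `"B"`, ... in
#' the order they were performed; in a whorl-removal series `"A"` is the
#' test with all brace roots intact.
#'
#' @param samples data frame with numeric columns `index`, `rotation_deg`,
#'   `force_N`; `index` must be strictly increasing.
#' @param load_height_m height of the applied load above the plant base, in
#'   meters (must be positive; 0.64 m and 0.60 m are typical).
#' @param plant_id,test_label identity of the tested plant and the test
#'   label (one uppercase letter).
#' @return An object of class `frt_trace`.
#' @examples
#' tr <- force_rotation_trace(
#'   data.frame(index = 0:1, rotation_deg = c(0, 5), force_N = c(0, 2.5)),
#'   load_height_m = 0.64, plant_id = "p1", test_label = "A"
#' )
#' @export
force_rotation_trace <- function(samples, load_height_m, plant_id, test_label) {
  if (!is.data.frame(samples) ||
      !all(c("index", "rotation_deg", "force_N") %in% names(samples))) {
    abort_br("samples must be a data frame with columns index, rotation_deg, force_N",
             "braceroot_format_error")
  }
  samples <- samples[, c("index", "rotation_deg", "force_N")]
  if (nrow(samples) < 2L) {
    abort_br("a trace needs at least 2 samples", "braceroot_insufficient_data")
  }
  for (col in names(samples)) {
    if (!is.numeric(samples[[col]]) || anyNA(samples[[col]]) ||
        any(!is.finite(samples[[col]]))) {
      abort_br(sprintf("column '%s' must be finite numeric", col),
               "braceroot_parse_error")
    }
  }
  if (any(diff(samples$index) <= 0)) {
    abort_br("sample index must be strictly increasing", "braceroot_format_error")
  }
  if (!is_scalar_number(load_height_m) || load_height_m <= 0) {
    abort_br("load_height_m must be a positive number", "braceroot_domain_error")
  }
  if (!is_test_label(test_label)) {
    abort_br("test_label must be a single uppercase letter", "braceroot_format_error")
  }
  structure(
    list(
      samples = samples,
      load_height_m = load_height_m,
      plant_id = as.character(plant_id),
      test_label = test_label
    ),
    class = "frt_trace"
  )
}

#' @export
print.frt_trace <- function(x, ...) {
  cat(sprintf(
    "<force-rotation trace> plant %s test %s: %d samples, load height %.3g m, rotation %.2f..%.2f deg\n",
    x$plant_id, x$test_label, nrow(x$samples), x$load_height_m,
    min(x$samples$rotation_deg), max(x$samples$rotation_deg)
  ))
  invisible(x)
}

trace_csv_header <- c("index", "rotation_deg", "force_N")

#' Read a force-rotation trace from CSV
#'
#' The file must carry the header `index,rotation_deg,force_N` (an optional
#' `time_s` column is ignored) and at least two data rows. Rows are kept in
#' file order; nothing is filtered or reordered.
#'
#' @param path path to the CSV file.
#' @inheritParams force_rotation_trace
#' @return An [force_rotation_trace()] object.
#' @seealso [write_trace_csv()]
#' @export
read_trace_csv <- function(path, load_height_m, plant_id, test_label) {
  if (!file.exists(path)) {
    abort_br(sprintf("trace file not found: %s", path), "braceroot_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  extra <- setdiff(names(raw), c(trace_csv_header, "time_s"))
  if (!all(trace_csv_header %in% names(raw)) || length(extra) > 0L) {
    abort_br(sprintf(
      "malformed header in %s: expected 'index,rotation_deg,force_N' (optional time_s), got '%s'",
      path, paste(names(raw), collapse = ",")
    ), "braceroot_format_error")
  }
  if (nrow(raw) < 2L) {
    abort_br(sprintf("%s: need at least 2 data rows", path),
             "braceroot_insufficient_data")
  }
  out <- list()
  for (col in trace_csv_header) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0L) {
      abort_br(sprintf("%s: non-numeric value in column '%s' at data row %d",
                       path, col, bad[1L]), "braceroot_parse_error")
    }
    out[[col]] <- vals
  }
  force_rotation_trace(as.data.frame(out), load_height_m, plant_id, test_label)
}

#' Write a force-rotation trace to CSV
#'
#' Writes the exact header `index,rotation_deg,force_N`; numbers are
#' rendered with 12 significant digits so that read-after-write reproduces
#' the values at working precision and a second write is byte-identical.
#'
#' @param trace an [force_rotation_trace()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frt_trace"))
  s <- trace$samples
  lines <- c(
    paste(trace_csv_header, collapse = ","),
    sprintf("%s,%s,%s",
            sprintf("%.12g", s$index),
            sprintf("%.12g", s$rotation_deg),
            sprintf("%.12g", s$force_N))
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_br(sprintf("cannot write trace to %s", path), "braceroot_io_error")
  invisible(path)
}

#' Construct a plant metadata record
#'
#' @param plant_id,plot_id identifiers.
#' @param whorls_in_soil number of brace-root whorls entering the soil
#'   (these are the whorls a removal series excises one by one).
#' @param whorls_total total number of brace-root whorls on the plant.
#' @param attachment_height_m height of the attachment point of the highest
#'   soil-entering whorl, in meters; `NA` when not measured (the beam-length
#'   correction is then skipped for this plant).
#' @param load_height_m load-cell height used for this plant's tests.
#' @param group free-form grouping tag (e.g. time of day, generation).
#' @return A one-row data frame (class `plant_record` rows are plain rows).
#' @export
plant_record <- function(plant_id, plot_id = NA_character_,
                         whorls_in_soil = 0L, whorls_total = whorls_in_soil,
                         attachment_height_m = NA_real_,
                         load_height_m = 0.64, group = NA_character_) {
  whorls_in_soil <- as.integer(whorls_in_soil)
  whorls_total <- as.integer(whorls_total)
  if (whorls_in_soil < 0L || whorls_in_soil > whorls_total) {
    abort_br("need 0 <= whorls_in_soil <= whorls_total", "braceroot_domain_error")
  }
  if (!is.na(attachment_height_m) && attachment_height_m < 0) {
    abort_br("attachment_height_m must be >= 0 when present", "braceroot_domain_error")
  }
  data.frame(
    plant_id = as.character(plant_id), plot_id = as.character(plot_id),
    whorls_in_soil = whorls_in_soil, whorls_total = whorls_total,
    attachment_height_m = as.numeric(attachment_height_m),
    load_height_m = as.numeric(load_height_m),
    group = as.character(group),
    stringsAsFactors = FALSE
  )
}

metadata_base_cols <- c("plant_id", "plot_id", "whorls_in_soil", "whorls_total",
                        "attachment_height_m", "load_height_m", "group")

#' Read / write the plant metadata table
#'
#' The metadata CSV has one row per plant with columns `plant_id`,
#' `plot_id`, `whorls_in_soil`, `whorls_total`, `attachment_height_m`,
#' `load_height_m`, `group`, plus one `file_<label>` column per test label
#' referencing that test's trace CSV (relative to the metadata file's
#' directory).
#'
#' @param path metadata CSV path.
#' @return A data frame of plant records (with any `file_*` columns).
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) {
    abort_br(sprintf("metadata file not found: %s", path), "braceroot_io_error")
  }
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(metadata_base_cols, names(md))
  if (length(missing) > 0L) {
    abort_br(sprintf("metadata is missing columns: %s",
                     paste(missing, collapse = ", ")), "braceroot_format_error")
  }
  md
}

#' @rdname read_metadata_csv
#' @param metadata data frame of plant records.
#' @export
write_metadata_csv <- function(metadata, path) {
  missing <- setdiff(metadata_base_cols, names(metadata))
  if (length(missing) > 0L) {
    abort_br(sprintf("metadata is missing columns: %s",
                     paste(missing, collapse = ", ")), "braceroot_format_error")
  }
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble whorl-removal series from traces and metadata
#'
#' Groups traces by plant and checks that each plant's test labels form a
#' contiguous alphabetic sequence starting at `"A"` (the intact test). When
#' `whorls_in_soil` is known, the number of labels must equal
#' `whorls_in_soil + 1` (one excision per soil-entering whorl plus the
#' intact test).
#'
#' @param metadata data frame of plant records ([plant_record()] rows).
#' @param traces list of [force_rotation_trace()] objects.
#' @param on_problem `"error"` to stop at the first invalid plant,
#'   `"report"` to return all valid series plus a `problems` data frame
#'   (plants are reported, never silently dropped).
#' @return For `on_problem = "error"`, a list of `removal_series` objects.
#'   For `"report"`, a list with elements `series` and `problems`.
#' @export
assemble_series <- function(metadata, traces, on_problem = c("error", "report")) {
  on_problem <- match.arg(on_problem)
  stopifnot(is.data.frame(metadata))
  if (length(traces) == 0L) {
    res <- list()
    return(if (on_problem == "report") {
      list(series = res, problems = empty_problems())
    } else res)
  }
  if (!all(vapply(traces, inherits, logical(1), "frt_trace"))) {
    abort_br("traces must all be force_rotation_trace objects", "braceroot_format_error")
  }
  ids <- vapply(traces, function(t) t$plant_id, character(1))
  labs <- vapply(traces, function(t) t$test_label, character(1))
  series <- list()
  problems <- empty_problems()
  for (pid in unique(ids)) {
    sel <- which(ids == pid)
    plant_labels <- labs[sel]
    meta_row <- metadata[metadata$plant_id == pid, , drop = FALSE]
    problem <- NULL
    if (anyDuplicated(plant_labels)) {
      problem <- c("duplicate_label",
                   sprintf("plant %s has duplicate test label(s): %s", pid,
                           paste(unique(plant_labels[duplicated(plant_labels)]),
                                 collapse = ",")))
    } else {
      expected <- LETTERS[seq_along(plant_labels)]
      if (!setequal(plant_labels, expected)) {
        problem <- c("contiguity",
                     sprintf("plant %s labels {%s} are not contiguous from A", pid,
                             paste(sort(plant_labels), collapse = ",")))
      } else if (nrow(meta_row) == 1L && !is.na(meta_row$whorls_in_soil) &&
                 length(plant_labels) != meta_row$whorls_in_soil + 1L) {
        problem <- c("label_count",
                     sprintf("plant %s has %d tests but whorls_in_soil=%d implies %d",
                             pid, length(plant_labels), meta_row$whorls_in_soil,
                             meta_row$whorls_in_soil + 1L))
      }
    }
    if (!is.null(problem)) {
      if (on_problem == "error") {
        abort_br(problem[2L],
                 if (problem[1L] == "duplicate_label") "braceroot_conflict_error"
                 else "braceroot_contiguity_error")
      }
      problems <- rbind(problems, data.frame(
        plant_id = pid, problem = problem[1L], detail = problem[2L],
        stringsAsFactors = FALSE
      ))
      next
    }
    ord <- sel[order(plant_labels)]
    tl <- traces[ord]
    names(tl) <- sort(plant_labels)
    series[[pid]] <- structure(
      list(plant = if (nrow(meta_row) == 1L) meta_row else plant_record(pid),
           traces = tl),
      class = "removal_series"
    )
  }
  if (on_problem == "report") list(series = series, problems = problems) else series
}

empty_problems <- function() {
  data.frame(plant_id = character(), problem = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.removal_series <- function(x, ...) {
  cat(sprintf("<removal series> plant %s: tests %s\n",
              x$plant$plant_id, paste(names(x$traces), collapse = ", ")))
  invisible(x)
}
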