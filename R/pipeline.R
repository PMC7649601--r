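# Pipeline layer: dataset (de)serialisation and the four stages --
# simulate, extract, contribution, stats -- each a plain function over
# tables so a full run equals stage-by-stage manual invocation.

write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "darling_dataset"))
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(trace_dir)) {
    abort_br(sprintf("cannot create output directory %s", out_dir),
             "braceroot_io_error")
  }
  md <- dataset$metadata
  labels <- sort(unique(vapply(dataset$traces, function(t) t$test_label,
                               character(1))))
  for (lab in labels) md[[paste0("file_", lab)]] <- NA_character_
  for (key in names(dataset$traces)) {
    tr <- dataset$traces[[key]]
    rel <- file.path("traces", sprintf("%s_%s.csv", tr$plant_id, tr$test_label))
    write_trace_csv(tr, file.path(out_dir, rel))
    md[md$plant_id == tr$plant_id, paste0("file_", tr$test_label)] <- rel
  }
  write_metadata_csv(md, file.path(out_dir, "metadata.csv"))
  utils::write.csv(dataset$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Read a dataset directory back into memory
#'
#' Reads `metadata.csv` (one row per plant with `file_<label>` trace
#' references) and every referenced trace, plus `tests.csv` and
#' `ground_truth.csv` when present.
#'
#' @param dir dataset directory, as written by [pipeline_simulate()].
#' @return A `darling_dataset`.
#' @export
read_dataset <- function(dir) {
  md <- read_metadata_csv(file.path(dir, "metadata.csv"))
  file_cols <- grep("^file_", names(md), value = TRUE)
  traces <- list()
  for (i in seq_len(nrow(md))) {
    for (fc in file_cols) {
      rel <- md[[fc]][i]
      if (is.na(rel) || !nzchar(rel)) next
      lab <- sub("^file_", "", fc)
      traces[[paste0(md$plant_id[i], "/", lab)]] <-
        read_trace_csv(file.path(dir, rel), md$load_height_m[i],
                       md$plant_id[i], lab)
    }
  }
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  structure(
    list(traces = traces, metadata = md[, setdiff(names(md), file_cols)],
         tests = read_opt("tests.csv"), truth = read_opt("ground_truth.csv"),
         design = NULL, protocol = NULL),
    class = "darling_dataset"
  )
}

#' Simulate a dataset to disk with a run manifest
#'
#' Runs [simulate_experiment()] and writes the trace CSVs, metadata,
#' per-test table, ground truth, and a `manifest.json` recording the seed,
#' design and protocol, so the run is reproducible bit for bit.
#'
#' @param design an [experiment_design()].
#' @param protocol a [protocol_config()].
#' @param out_dir output directory (created).
#' @param seed RNG seed recorded in the manifest.
#' @return The in-memory `darling_dataset`, invisibly.
#' @export
pipeline_simulate <- function(design, protocol = protocol_config(), out_dir,
                              seed = 1L) {
  ds <- simulate_experiment(design, protocol, seed = seed, out_dir = out_dir)
  manifest <- list(
    package = "braceroot",
    version = as.character(utils::packageVersion("braceroot")),
    seed = seed,
    design = design[!vapply(design, is.function, logical(1))],
    protocol = unclass(protocol)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Extract slopes for every trace of a dataset
#'
#' Computes all three method slopes per trace where possible, and selects
#' the configured method as the working `slope` column, falling back to
#' the full-trace fit (flagged) when the cycle parser finds nothing. The
#' full-trace fit is the default working method. Unreadable or degenerate
#' traces are logged as failed rows; the run continues.
#'
#' @param dataset a `darling_dataset` (in memory) or a dataset directory.
#' @param method working slope method: `"full"` (default), `"loading"`,
#'   or `"ransac"`.
#' @param min_run,min_span_m cycle-parser thresholds.
#' @param ransac_n_iter RANSAC hypotheses per cycle.
#' @param fallback_to_full fall back when no cycle is found?
#' @param all_methods compute all three method columns per trace (default)
#'   or only the working method (faster on large simulations; the
#'   full-trace column is always present for the fallback).
#' @param seed base seed; each trace's RANSAC uses `seed + row index`.
#' @return Data frame with one row per trace: `plant_id`, `test_label`,
#'   `n_samples`, `cycles_found`, `slope_full`, `slope_loading`,
#'   `slope_ransac`, `r2_full`, the selected `slope`, `method_used`,
#'   `fallback`, `failed`.
#' @export
pipeline_extract <- function(dataset, method = c("full", "loading", "ransac"),
                             min_run = 10L, min_span_m = 0.02,
                             ransac_n_iter = 200L, fallback_to_full = TRUE,
                             all_methods = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "darling_dataset"))
  rows <- lapply(seq_along(dataset$traces), function(i) {
    tr <- dataset$traces[[i]]
    base <- data.frame(
      plant_id = tr$plant_id, test_label = tr$test_label,
      n_samples = nrow(tr$samples), cycles_found = NA_integer_,
      slope_full = NA_real_, slope_loading = NA_real_, slope_ransac = NA_real_,
      r2_full = NA_real_, slope = NA_real_, method_used = NA_character_,
      fallback = FALSE, failed = FALSE, stringsAsFactors = FALSE
    )
    out <- tryCatch({
      fd <- trace_deflection(tr)
      cycles <- parse_loading_cycles(fd, min_run, min_span_m)
      full <- fit_slope_full(fd)
      base$cycles_found <- nrow(cycles)
      base$slope_full <- full$slope_N_per_m
      base$r2_full <- full$r_squared
      if (nrow(cycles) > 0L) {
        if (all_methods || method == "loading") {
          base$slope_loading <-
            tryCatch(fit_slope_loading(fd, cycles)$slope_N_per_m,
                     braceroot_error = function(e) NA_real_)
        }
        if (all_methods || method == "ransac") {
          base$slope_ransac <-
            tryCatch(fit_slope_ransac(fd, cycles, n_iter = ransac_n_iter,
                                      seed = seed + i)$slope_N_per_m,
                     braceroot_error = function(e) NA_real_)
        }
      }
      sel <- switch(method, full = base$slope_full,
                    loading = base$slope_loading, ransac = base$slope_ransac)
      if (is.na(sel) && method != "full") {
        if (!fallback_to_full) {
          abort_br(sprintf("no usable cycles for %s/%s and fallback disabled",
                           tr$plant_id, tr$test_label), "braceroot_no_cycle")
        }
        base$slope <- base$slope_full
        base$method_used <- "full"
        base$fallback <- TRUE
      } else {
        base$slope <- sel
        base$method_used <- method
      }
      base
    }, braceroot_error = function(e) {
      base$failed <- TRUE
      base
    })
    out
  })
  do.call(rbind, rows)
}

#' Per-plant contribution table
#'
#' Applies [contribution_result()] to every plant's extracted slopes.
#' Plants whose labels are not contiguous from `A`, or with failed
#' extractions, are reported in the `problems` attribute and excluded --
#' never silently dropped.
#'
#' @param slopes slope table from [pipeline_extract()] (columns
#'   `plant_id`, `test_label`, `slope`).
#' @param metadata plant metadata (for whorl counts, load and attachment
#'   heights).
#' @param direction beam-correction direction, see
#'   [beam_corrected_ratio()].
#' @return Data frame with one row per valid plant: slopes per label,
#'   `ratio`, `difference`, `whorl1..whorl3`, `corrected_ratio`; the
#'   attribute `"problems"` lists excluded plants.
#' @export
pipeline_contribution <- function(slopes, metadata,
                                  direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  stopifnot(all(c("plant_id", "test_label", "slope") %in% names(slopes)))
  problems <- empty_problems()
  rows <- list()
  for (pid in unique(slopes$plant_id)) {
    sl <- slopes[slopes$plant_id == pid, ]
    meta <- metadata[metadata$plant_id == pid, , drop = FALSE]
    if (any(is.na(sl$slope))) {
      problems <- rbind(problems, data.frame(
        plant_id = pid, problem = "failed_extraction",
        detail = sprintf("plant %s has failed or missing slopes", pid)))
      next
    }
    s <- stats::setNames(sl$slope, sl$test_label)
    res <- tryCatch(
      contribution_result(
        s,
        load_height_m = if (nrow(meta) == 1L) meta$load_height_m else NA_real_,
        attachment_height_m = if (nrow(meta) == 1L) meta$attachment_height_m else NA_real_,
        direction = direction
      ),
      braceroot_error = function(e) e
    )
    if (inherits(res, "condition")) {
      problems <- rbind(problems, data.frame(
        plant_id = pid, problem = "invalid_series",
        detail = conditionMessage(res)))
      next
    }
    row <- data.frame(plant_id = pid, stringsAsFactors = FALSE)
    if (nrow(meta) == 1L) {
      row$plot_id <- meta$plot_id
      row$whorls_in_soil <- meta$whorls_in_soil
    }
    for (lab in names(s)) row[[paste0("slope_", lab)]] <- s[[lab]]
    row$ratio <- res$ratio
    row$difference <- res$difference
    for (j in seq_len(3L)) {
      row[[paste0("whorl", j)]] <-
        if (j <= length(res$whorl_ratios)) unname(res$whorl_ratios[j]) else NA_real_
    }
    row$corrected_ratio <- res$corrected_ratio
    rows[[pid]] <- row
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = character())
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Statistical report over a contribution table
#'
#' Reproduces the analysis shape of a removal study on the supplied
#' tables: one-way ANOVA and Tukey HSD of slope across test labels,
#' Pearson correlations of the contribution ratio with the number of
#' soil-entering whorls and with the per-whorl ratios, per-whorl group
#' means, and -- when a repeat-test table is supplied -- repeatability of
#' the slope across plants.
#'
#' @param contrib contribution table from [pipeline_contribution()].
#' @param slopes slope table from [pipeline_extract()].
#' @param tests optional per-test table with `test_repeat` set (repeat
#'   designs); enables the repeatability component.
#' @param n_boot bootstrap replicates for repeatability.
#' @param seed RNG seed for the stochastic components.
#' @return An object of class `braceroot_report`: list with components
#'   `removal_anova`, `removal_tukey`, `cor_ratio_whorls`,
#'   `cor_whorl_vs_ratio`, `whorl_means`, `repeatability`, `settings`
#'   (components are `NULL` where the data do not support them).
#' @export
pipeline_stats <- function(contrib, slopes, tests = NULL, n_boot = 1000L,
                           seed = 1L) {
  quiet <- function(expr) tryCatch(expr, braceroot_error = function(e) NULL,
                                   error = function(e) NULL)
  ok <- slopes[!slopes$failed & !is.na(slopes$slope), ]
  groups <- split(ok$slope, ok$test_label)
  groups <- groups[lengths(groups) >= 2L]
  report <- list(
    removal_anova = quiet(if (length(groups) >= 2L) one_way_anova(groups)),
    removal_tukey = quiet(if (length(groups) >= 2L) tukey_hsd(groups)),
    cor_ratio_whorls = quiet(pearson(contrib$ratio, contrib$whorls_in_soil)),
    cor_whorl_vs_ratio = lapply(
      stats::setNames(paste0("whorl", 1:3), paste0("whorl", 1:3)),
      function(cc) quiet(pearson(contrib[[cc]], contrib$ratio))
    ),
    whorl_means = vapply(paste0("whorl", 1:3), function(cc) {
      v <- contrib[[cc]]
      if (is.null(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    repeatability = quiet(
      if (!is.null(tests) && any(!is.na(tests$test_repeat))) {
        m <- merge(tests, ok[, c("plant_id", "test_label", "slope")],
                   by = c("plant_id", "test_label"))
        repeatability(m$slope, m$plant_id, n_boot = n_boot, seed = seed)
      }
    ),
    settings = list(n_boot = n_boot, seed = seed)
  )
  structure(report, class = "braceroot_report")
}

#' @export
print.braceroot_report <- function(x, ...) {
  cat("== Brace-root anchorage report ==\n")
  if (!is.null(x$removal_anova)) {
    cat(sprintf("Removal effect (one-way ANOVA across test labels): F = %.3g, p = %.3g\n",
                x$removal_anova$F, x$removal_anova$p))
  }
  if (!is.null(x$removal_tukey)) {
    cat("Tukey HSD pairs:\n")
    print(x$removal_tukey, digits = 3)
  }
  if (!is.null(x$cor_ratio_whorls)) {
    cat(sprintf("Ratio vs whorls in soil: r = %.3f, p = %.3g\n",
                x$cor_ratio_whorls$r, x$cor_ratio_whorls$p))
  }
  if (!all(is.na(x$whorl_means))) {
    cat("Per-whorl ratio means:",
        paste(sprintf("%s = %.3f", names(x$whorl_means), x$whorl_means),
              collapse = ", "), "\n")
  }
  if (!is.null(x$repeatability)) print(x$repeatability)
  invisible(x)
}
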