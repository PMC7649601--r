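# Synthetic DARLING-style field generator. A plant is modelled as a
# tip-loaded cantilever with an anchorage-dependent force-deflection slope
# k (N/m): the device rotates through a triangle-wave protocol, and force
# responds linearly in deflection with a multiplicative hysteresis factor
# on unloading legs, Gaussian sensor noise, and optional serially
# correlated "wind burst" noise on both channels.

#' Testing-protocol configuration for simulated traces
#'
#' Defaults follow the field protocol: three cycles, each slowly rotating
#' to about 15 degrees and back, with the load cell at 0.64 m (0.60 m is
#' the common alternative).
#'
#' @param n_cycles number of load cycles (>= 1).
#' @param points_per_leg samples per loading (and per unloading) leg.
#' @param max_angle_deg peak rotation per cycle, degrees (0, 90).
#' @param load_height_m load-cell height, meters.
#' @param noise_sd_N standard deviation of iid Gaussian force noise,
#'   newtons (sensor + contact noise floor).
#' @param hysteresis_factor multiplier in (0, 1] applied to the elastic
#'   force on unloading legs (1 = no hysteresis).
#' @param wind_burst list with elements `prob` (per-trace probability of a
#'   burst), `magnitude_N` and `magnitude_deg` (stationary SD of the
#'   correlated noise added to force and rotation inside the burst),
#'   `duration` (samples), and `ar` (lag-1 autocorrelation).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_cycles = 3L, points_per_leg = 50L,
                            max_angle_deg = 15, load_height_m = 0.64,
                            noise_sd_N = 0.2, hysteresis_factor = 0.85,
                            wind_burst = list(prob = 0, magnitude_N = 1.5,
                                              magnitude_deg = 3,
                                              duration = 40L, ar = 0.9)) {
  stopifnot(n_cycles >= 1L, points_per_leg >= 2L,
            max_angle_deg > 0, max_angle_deg < 90,
            load_height_m > 0, noise_sd_N >= 0,
            hysteresis_factor > 0, hysteresis_factor <= 1)
  wb <- utils::modifyList(
    list(prob = 0, magnitude_N = 1.5, magnitude_deg = 3, duration = 40L, ar = 0.9),
    wind_burst %||% list()
  )
  stopifnot(wb$prob >= 0, wb$prob <= 1, wb$duration >= 1L,
            wb$ar >= 0, wb$ar < 1)
  structure(
    list(n_cycles = as.integer(n_cycles),
         points_per_leg = as.integer(points_per_leg),
         max_angle_deg = max_angle_deg, load_height_m = load_height_m,
         noise_sd_N = noise_sd_N, hysteresis_factor = hysteresis_factor,
         wind_burst = wb),
    class = "protocol_config"
  )
}

#' Ground truth for one simulated plant
#'
#' @param base_slope_N_per_m true force-deflection slope with all whorls
#'   intact.
#' @param whorl_factors multiplicative anchorage factors `f1..fK` in
#'   (0, 1], ordered soil-closest first: removing the top remaining whorl
#'   multiplies the true slope by that whorl's factor, so the true slope
#'   after removing the top `m` whorls is `k_A * f_K * ... * f_(K-m+1)`
#'   and the true contribution ratio is the product of all factors.
#' @param attachment_height_m attachment height of the highest
#'   soil-entering whorl (meters, `NA` when unmeasured).
#' @param load_height_m load height for this plant's tests (`NA` to use
#'   the protocol's).
#' @param plant_id identifier.
#' @return An object of class `plant_truth`.
#' @export
plant_truth <- function(base_slope_N_per_m, whorl_factors,
                        attachment_height_m = NA_real_,
                        load_height_m = NA_real_, plant_id = "plant1") {
  stopifnot(is_scalar_number(base_slope_N_per_m), base_slope_N_per_m > 0,
            is.numeric(whorl_factors), length(whorl_factors) >= 1L,
            all(whorl_factors > 0), all(whorl_factors <= 1))
  structure(
    list(base_slope_N_per_m = base_slope_N_per_m,
         whorl_factors = as.numeric(whorl_factors),
         attachment_height_m = attachment_height_m,
         load_height_m = load_height_m,
         plant_id = as.character(plant_id)),
    class = "plant_truth"
  )
}

# triangle-wave rotation protocol: per cycle, points_per_leg + 1 samples
# rise 0 -> max (peak included in the loading leg), points_per_leg - 1 fall
# back toward 0 without duplicating the joins
triangle_protocol <- function(protocol) {
  P <- protocol$points_per_leg
  t <- seq_len(2L * P * protocol$n_cycles) - 1L
  phase <- t %% (2L * P)
  angle <- ifelse(phase <= P, phase / P, (2L * P - phase) / P) *
    protocol$max_angle_deg
  list(angle_deg = angle, is_loading = phase <= P)
}

#' Simulate one force-rotation trace
#'
#' Rotation follows the triangle-wave protocol; force is
#' `k_true * h * sin(theta)` on loading legs, scaled by the hysteresis
#' factor on unloading legs, plus iid Gaussian sensor noise. With
#' probability `wind_burst$prob` a window of serially correlated (AR(1))
#' noise is added to both force and rotation, emulating wind shaking the
#' plant and device. Deterministic for a given seed.
#'
#' @param k_true true force-deflection slope, N/m.
#' @param protocol a [protocol_config()].
#' @param plant_id,test_label trace identity.
#' @param seed RNG seed (`NULL` draws from the current stream).
#' @return An [force_rotation_trace()] object.
#' @export
simulate_trace <- function(k_true, protocol = protocol_config(),
                           plant_id = "plant1", test_label = "A",
                           seed = NULL) {
  stopifnot(inherits(protocol, "protocol_config"),
            is_scalar_number(k_true), k_true > 0)
  with_seed(seed, {
    tri <- triangle_protocol(protocol)
    n <- length(tri$angle_deg)
    rotation <- tri$angle_deg
    defl <- rotation_to_deflection(degrees_to_radians(rotation),
                                   protocol$load_height_m)
    k_eff <- ifelse(tri$is_loading, k_true,
                    protocol$hysteresis_factor * k_true)
    force <- k_eff * defl + stats::rnorm(n, 0, protocol$noise_sd_N)
    wb <- protocol$wind_burst
    if (wb$prob > 0 && stats::runif(1) < wb$prob) {
      dur <- min(wb$duration, n)
      start <- sample.int(n - dur + 1L, 1L)
      win <- start:(start + dur - 1L)
      innov_sd <- sqrt(1 - wb$ar^2)
      ou <- as.numeric(stats::filter(stats::rnorm(dur, 0, innov_sd),
                                     wb$ar, method = "recursive"))
      force[win] <- force[win] + wb$magnitude_N * ou
      ou2 <- as.numeric(stats::filter(stats::rnorm(dur, 0, innov_sd),
                                      wb$ar, method = "recursive"))
      rotation[win] <- rotation[win] + wb$magnitude_deg * ou2
    }
    force_rotation_trace(
      data.frame(index = seq_len(n) - 1L, rotation_deg = rotation,
                 force_N = force),
      load_height_m = protocol$load_height_m,
      plant_id = plant_id, test_label = test_label
    )
  })
}

#' Simulate a whorl-removal series with known ground truth
#'
#' Emits `K + 1` traces labelled `A` (intact) onward. The uppermost
#' soil-entering whorl is excised first, so the true slope sequence is
#' `k_A`, `k_A * f_K`, `k_A * f_K * f_(K-1)`, ..., down to
#' `k_A * prod(f)` with all whorls removed.
#'
#' @param truth a [plant_truth()].
#' @param protocol a [protocol_config()].
#' @param seed RNG seed.
#' @return A `removal_series` whose `true_slopes` element carries the
#'   generating slopes (named by test label).
#' @export
simulate_removal_series <- function(truth, protocol = protocol_config(),
                                    seed = NULL) {
  stopifnot(inherits(truth, "plant_truth"))
  h <- if (is.finite(truth$load_height_m)) truth$load_height_m else protocol$load_height_m
  protocol$load_height_m <- h
  K <- length(truth$whorl_factors)
  ks <- truth$base_slope_N_per_m * cumprod(c(1, rev(truth$whorl_factors)))
  labels <- LETTERS[seq_len(K + 1L)]
  names(ks) <- labels
  with_seed(seed, {
    traces <- lapply(seq_along(ks), function(i) {
      simulate_trace(ks[i], protocol, plant_id = truth$plant_id,
                     test_label = labels[i])
    })
    names(traces) <- labels
    structure(
      list(plant = plant_record(truth$plant_id, whorls_in_soil = K,
                                whorls_total = K,
                                attachment_height_m = truth$attachment_height_m,
                                load_height_m = h),
           traces = traces, true_slopes = ks),
      class = "removal_series"
    )
  })
}

#' Simulate a removal that only lengthens the beam
#'
#' The geometry-only null for the beam-length correction: anchorage is
#' unchanged and brace-root removal merely moves the cantilever base from
#' the attachment height `a` to the soil surface. With slope `3 EI / L^3`
#' for a tip-loaded cantilever, the intact test (`A`) uses `L = h - a` and
#' the removed test (`B`) uses `L = h`, so the true ratio is
#' `((h - a)/h)^3` and [beam_corrected_ratio()] must return exactly 1.
#'
#' @param EI_like flexural-stiffness-like constant (N m^2).
#' @param load_height_m,attachment_height_m beam geometry (`0 <= a < h`).
#' @param protocol a [protocol_config()] (its load height is overridden by
#'   `load_height_m`).
#' @param seed RNG seed.
#' @return A `removal_series` with two traces and `true_slopes`.
#' @export
simulate_pure_beam_lengthening <- function(EI_like, load_height_m = 0.64,
                                           attachment_height_m = 0.032,
                                           protocol = protocol_config(),
                                           seed = NULL) {
  stopifnot(is_scalar_number(EI_like), EI_like > 0)
  if (!is_scalar_number(attachment_height_m) || attachment_height_m < 0 ||
      attachment_height_m >= load_height_m) {
    abort_br("need 0 <= attachment_height_m < load_height_m",
             "braceroot_geometry_error")
  }
  protocol$load_height_m <- load_height_m
  C <- 3 * EI_like
  ks <- c(A = C / (load_height_m - attachment_height_m)^3,
          B = C / load_height_m^3)
  with_seed(seed, {
    traces <- lapply(names(ks), function(lab) {
      simulate_trace(ks[[lab]], protocol, plant_id = "beam_null",
                     test_label = lab)
    })
    names(traces) <- names(ks)
    structure(
      list(plant = plant_record("beam_null", whorls_in_soil = 1L,
                                whorls_total = 1L,
                                attachment_height_m = attachment_height_m,
                                load_height_m = load_height_m),
           traces = traces, true_slopes = ks),
      class = "removal_series"
    )
  })
}

#' Design of a simulated field experiment
#'
#' Encodes the population and measurement design: plant-level variation in
#' the base slope (between-plant SD), per-test repositioning error
#' (within-plant SD, applied between repeat tests of a plant, not across
#' the stages of a removal series), the soil-entering whorl-count mix,
#' per-plant hysteresis, attachment heights, and optional time-of-day
#' slope multipliers.
#'
#' @param n_plants number of plants (>= 1).
#' @param repeats_per_plant repeat tests per plant per time point (repeat
#'   designs only).
#' @param removal if `TRUE`, each plant yields a whorl-removal series; if
#'   `FALSE`, intact repeat tests.
#' @param whorl_probs named probabilities over soil-entering whorl counts,
#'   e.g. `c("2" = .5, "3" = .5)`; must sum to 1.
#' @param whorl_factors per-whorl anchorage factors `f1..f3`
#'   (soil-closest first); a plant with `K` whorls uses the first `K`.
#' @param mean_base_slope,between_sd mean and between-plant SD of the
#'   intact slope, N/m.
#' @param within_sd per-test repositioning SD, N/m.
#' @param hysteresis_range per-plant hysteresis factor drawn uniformly
#'   from this range (constant within a plant).
#' @param time_multipliers named slope multipliers per time point (e.g.
#'   `c("0900" = 1, "1200" = .85, "1600" = .7)` for declining turgor).
#' @param attachment_height_range per-plant attachment heights drawn
#'   uniformly from this range, meters.
#' @param plot_names plot replicate labels; plants are split evenly.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_plants = 23L, repeats_per_plant = 1L,
                              removal = FALSE,
                              whorl_probs = c("2" = 0.5, "3" = 0.5),
                              whorl_factors = c(0.65, 0.85, 0.95),
                              mean_base_slope = 40, between_sd = 8,
                              within_sd = 3,
                              hysteresis_range = c(0.70, 0.95),
                              time_multipliers = c("0900" = 1),
                              attachment_height_range = c(0.015, 0.032),
                              plot_names = c("A", "B")) {
  stopifnot(n_plants >= 1L, repeats_per_plant >= 1L,
            abs(sum(whorl_probs) - 1) < 1e-9,
            all(as.integer(names(whorl_probs)) >= 1L),
            all(whorl_factors > 0), all(whorl_factors <= 1),
            max(as.integer(names(whorl_probs))) <= length(whorl_factors),
            mean_base_slope > 0, between_sd >= 0, within_sd >= 0,
            length(hysteresis_range) == 2L,
            all(hysteresis_range > 0), all(hysteresis_range <= 1),
            length(time_multipliers) >= 1L, all(time_multipliers > 0),
            length(attachment_height_range) == 2L,
            all(attachment_height_range >= 0))
  structure(
    list(n_plants = as.integer(n_plants),
         repeats_per_plant = as.integer(repeats_per_plant),
         removal = isTRUE(removal), whorl_probs = whorl_probs,
         whorl_factors = whorl_factors,
         mean_base_slope = mean_base_slope, between_sd = between_sd,
         within_sd = within_sd, hysteresis_range = sort(hysteresis_range),
         time_multipliers = time_multipliers,
         attachment_height_range = sort(attachment_height_range),
         plot_names = plot_names),
    class = "experiment_design"
  )
}

#' Bundled whorl-removal scenario
#'
#' Two plots of 12 and 11 plants with a mix of two and three soil-entering
#' whorls, matching the design size of the removal experiment the pipeline
#' is built for.
#'
#' @inheritParams experiment_design
#' @return An `experiment_design`.
#' @export
design_removal_cml258 <- function(whorl_factors = c(0.65, 0.85, 0.95)) {
  experiment_design(n_plants = 23L, removal = TRUE,
                    whorl_probs = c("2" = 0.5, "3" = 0.5),
                    whorl_factors = whorl_factors,
                    plot_names = c("A", "B"))
}

#' Simulate a whole field experiment with ground truth
#'
#' Draws each plant's base slope, whorl count, hysteresis factor and
#' attachment height from the design, then simulates every test's trace
#' through the protocol. Removal designs produce one series per plant
#' (labels `A`..); repeat designs produce `repeats_per_plant` tests per
#' time point, labelled alphabetically in test order, with the per-test
#' repositioning error applied. Deterministic given the seed.
#'
#' @param design an [experiment_design()].
#' @param protocol a [protocol_config()]; per-plant hysteresis from the
#'   design overrides its `hysteresis_factor`.
#' @param seed RNG seed.
#' @param out_dir when given, the dataset is also written to disk in the
#'   trace/metadata CSV formats (see [pipeline_simulate()]).
#' @return An object of class `darling_dataset`: list with `traces`
#'   (named `"plant/label"`), `metadata` (one row per plant), `tests`
#'   (one row per test with the true test-level slope `k_true`, time and
#'   repeat), `truth` (per-plant parameters), plus the design and
#'   protocol.
#' @export
simulate_experiment <- function(design, protocol = protocol_config(),
                                seed = NULL, out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(protocol, "protocol_config"))
  with_seed(seed, {
    n <- design$n_plants
    pid <- sprintf("p%02d", seq_len(n))
    plot_id <- rep(design$plot_names, length.out = ceiling(n / length(design$plot_names)) *
                     length(design$plot_names))[seq_len(n)]
    plot_id <- sort(plot_id) # contiguous plots, sizes as even as possible
    K <- as.integer(sample(names(design$whorl_probs), n, replace = TRUE,
                           prob = design$whorl_probs))
    k_plant <- pmax(stats::rnorm(n, design$mean_base_slope, design$between_sd), 1)
    hyst <- stats::runif(n, design$hysteresis_range[1L], design$hysteresis_range[2L])
    attach <- stats::runif(n, design$attachment_height_range[1L],
                           design$attachment_height_range[2L])
    traces <- list()
    tests <- list()
    for (i in seq_len(n)) {
      proto_i <- protocol
      proto_i$hysteresis_factor <- hyst[i]
      if (design$removal) {
        tr <- plant_truth(k_plant[i], design$whorl_factors[seq_len(K[i])],
                          attachment_height_m = attach[i],
                          plant_id = pid[i])
        series <- simulate_removal_series(tr, proto_i)
        for (lab in names(series$traces)) {
          traces[[paste0(pid[i], "/", lab)]] <- series$traces[[lab]]
          tests[[length(tests) + 1L]] <- data.frame(
            plant_id = pid[i], test_label = lab, time = NA_character_,
            test_repeat = NA_integer_, k_true = series$true_slopes[[lab]],
            stringsAsFactors = FALSE
          )
        }
      } else {
        lab_i <- 0L
        for (tm in names(design$time_multipliers)) {
          for (r in seq_len(design$repeats_per_plant)) {
            lab_i <- lab_i + 1L
            lab <- LETTERS[lab_i]
            k_test <- max(k_plant[i] * design$time_multipliers[[tm]] +
                            stats::rnorm(1, 0, design$within_sd), 0.5)
            traces[[paste0(pid[i], "/", lab)]] <-
              simulate_trace(k_test, proto_i, plant_id = pid[i],
                             test_label = lab)
            tests[[length(tests) + 1L]] <- data.frame(
              plant_id = pid[i], test_label = lab, time = tm,
              test_repeat = r, k_true = k_test, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    metadata <- do.call(rbind, lapply(seq_len(n), function(i) {
      plant_record(pid[i], plot_id = plot_id[i], whorls_in_soil = K[i],
                   whorls_total = K[i], attachment_height_m = attach[i],
                   load_height_m = protocol$load_height_m,
                   group = plot_id[i])
    }))
    truth <- data.frame(
      plant_id = pid, plot_id = plot_id, whorls_in_soil = K,
      k_plant = k_plant, hysteresis = hyst, attachment_height_m = attach,
      f1 = ifelse(K >= 1L, design$whorl_factors[1L], NA_real_),
      f2 = ifelse(K >= 2L, design$whorl_factors[2L], NA_real_),
      f3 = ifelse(K >= 3L, design$whorl_factors[3L], NA_real_),
      stringsAsFactors = FALSE
    )
    ds <- structure(
      list(traces = traces, metadata = metadata,
           tests = do.call(rbind, tests), truth = truth,
           design = design, protocol = protocol),
      class = "darling_dataset"
    )
    if (!is.null(out_dir)) write_dataset(ds, out_dir)
    ds
  })
}

#' @export
print.darling_dataset <- function(x, ...) {
  cat(sprintf("<simulated field dataset> %d plants, %d traces (%s design)\n",
              nrow(x$metadata), length(x$traces),
              if (x$design$removal) "whorl-removal" else "repeat-test"))
  invisible(x)
}

#' Simulate line means for the flowering-time / height regression
#'
#' Generates per-line means of days-to-silking (DTS), plant height (PH)
#' and the intact force-deflection slope, with correlated predictors and
#' opposing true effects, for exercising
#' [two_predictor_regression()].
#'
#' @param n_lines number of lines.
#' @param b0,b_dts,b_ph true intercept and effects (defaults: positive DTS
#'   effect 0.44, negative PH effect -0.07).
#' @param predictor_cor correlation between DTS and PH (default 0.8).
#' @param dts_mean,dts_sd,ph_mean,ph_sd predictor distributions (days and
#'   cm). The default spreads, together with `resid_sd`, put the
#'   two-predictor model near R-squared 0.4 with a clearly significant DTS
#'   effect and a weaker but detectable PH effect at 26 lines.
#' @param resid_sd residual SD of the slope means.
#' @param seed RNG seed.
#' @return Data frame with columns `line_id`, `dts`, `ph`, `slope`.
#' @export
simulate_line_means <- function(n_lines = 26L, b0 = 20, b_dts = 0.44,
                                b_ph = -0.07, predictor_cor = 0.8,
                                dts_mean = 75, dts_sd = 5.4,
                                ph_mean = 245, ph_sd = 20,
                                resid_sd = 1.86, seed = NULL) {
  stopifnot(n_lines >= 4L, abs(predictor_cor) < 1)
  with_seed(seed, {
    z1 <- stats::rnorm(n_lines)
    z2 <- predictor_cor * z1 + sqrt(1 - predictor_cor^2) * stats::rnorm(n_lines)
    dts <- dts_mean + dts_sd * z1
    ph <- ph_mean + ph_sd * z2
    slope <- b0 + b_dts * dts + b_ph * ph + stats::rnorm(n_lines, 0, resid_sd)
    data.frame(line_id = sprintf("line%02d", seq_len(n_lines)),
               dts = dts, ph = ph, slope = slope)
  })
}
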