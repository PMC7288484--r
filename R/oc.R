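#' Estimate operating characteristics of a design by simulation
#'
#' Replicates a design under one or more true-effect scenarios and
#' aggregates the frequentist operating characteristics: the proportion of
#' simulated trials declared successful (the type I error under the null
#' scenario; the power under the target-effect scenario), its Monte-Carlo
#' standard error sqrt(p(1-p)/n), the mean information (events or patients)
#' at stopping, and the proportions stopping early by reason.
#'
#' @param design A [tte_design()] or [binary_design()].
#' @param scenarios For a time-to-event design, a numeric vector of true
#'   hazard ratios (default `c(1, 0.9, 0.8, 0.7)`). For a binary design, a
#'   [binary_scenario()] or list of them (default null and target-effect
#'   scenarios, 44\%/44\% and 35\%/44\%).
#' @param n_sims Replications per scenario. Defaults to 10^6 for the
#'   time-to-event design (cheap draws) and 10^4 for the patient-level
#'   binary design.
#' @param seed Integer master seed. Scenarios and designs evaluated with the
#'   same seed share underlying random streams (common random numbers).
#' @return An object of class `"trial_oc"`: a list with the OC table
#'   (`$oc`), the design, and the seed. `as.data.frame()` extracts the
#'   table.
#' @examples
#' d <- tte_design(interim_rule = "efficacy")
#' run_oc(d, scenarios = c(1, 0.7), n_sims = 1e4, seed = 1)
#' @export
run_oc <- function(design, scenarios = NULL, n_sims = NULL, seed = 1L) {
  UseMethod("run_oc")
}

oc_row <- function(label, res, info_col) {
  n <- nrow(res)
  p <- mean(res$success)
  data.frame(
    scenario = label,
    n_sims = n,
    success_proportion = p,
    mc_standard_error = sqrt(p * (1 - p) / n),
    mean_info_at_stop = mean(res[[info_col]]),
    prop_stop_efficacy = mean(res$stop_reason == "efficacy"),
    prop_stop_futility = mean(res$stop_reason == "futility"),
    prop_stopped_early = mean(res$stopped_early),
    stringsAsFactors = FALSE
  )
}

new_trial_oc <- function(oc, design, seed, info_unit) {
  structure(list(oc = oc, design = design, seed = seed,
                 info_unit = info_unit),
            class = "trial_oc")
}

#' @rdname run_oc
#' @export
run_oc.tte_design <- function(design, scenarios = c(1, 0.9, 0.8, 0.7),
                              n_sims = NULL, seed = 1L) {
  n_sims <- check_count(n_sims %||% 1e6, "n_sims", lower = 1L)
  rows <- lapply(scenarios, function(hr) {
    res <- simulate(design, nsim = n_sims, seed = seed, true_hr = hr)
    row <- oc_row(sprintf("HR = %g", hr), res, "events_at_stop")
    row$true_hr <- hr
    row
  })
  new_trial_oc(do.call(rbind, rows), design, seed, "events")
}

#' @rdname run_oc
#' @export
run_oc.binary_design <- function(design, scenarios = NULL, n_sims = NULL,
                                 seed = 1L) {
  n_sims <- check_count(n_sims %||% 1e4, "n_sims", lower = 1L)
  if (is.null(scenarios))
    scenarios <- list(binary_scenario(0.44, 0.44),
                      binary_scenario(0.44, 0.35))
  if (inherits(scenarios, "binary_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(sc) {
    res <- simulate(design, nsim = n_sims, seed = seed, scenario = sc)
    row <- oc_row(sc$label, res, "n_enrolled_at_stop")
    row$p_control <- sc$p_control
    row$p_intervention <- sc$p_intervention
    row
  })
  new_trial_oc(do.call(rbind, rows), design, seed, "patients")
}

#' @export
print.trial_oc <- function(x, digits = 4, ...) {
  cat("Operating characteristics (", format(x$oc$n_sims[1], big.mark = ","),
      " simulated trials per scenario, seed ", x$seed, ")\n\n", sep = "")
  tab <- x$oc
  tab$success_proportion <- round(tab$success_proportion, digits)
  tab$mc_standard_error <- signif(tab$mc_standard_error, 3)
  tab$mean_info_at_stop <- round(tab$mean_info_at_stop, 1)
  cols <- c("scenario", "success_proportion", "mc_standard_error",
            "mean_info_at_stop", "prop_stop_efficacy", "prop_stop_futility")
  print(tab[, intersect(cols, names(tab))], row.names = FALSE)
  cat("\nmean_info_at_stop is in ", x$info_unit, ".\n", sep = "")
  invisible(x)
}

#' @export
summary.trial_oc <- function(object, ...) object$oc

#' @export
as.data.frame.trial_oc <- function(x, ...) x$oc

#' Sweep the number of evenly spaced interim analyses of a binary design
#'
#' Rebuilds the design template with each requested number of evenly spaced
#' interims and estimates operating characteristics for every
#' (interim count, scenario) pair. With `common_rng = TRUE` (the default)
#' all designs are simulated from the same master seed, so they share
#' patient-level outcome streams and — at any look position two schedules
#' have in common — imputation streams, making comparisons across designs
#' path-wise rather than merely statistical.
#'
#' @param design A [binary_design()] template; its schedule is replaced.
#' @param interim_counts Integer vector of interim counts (e.g. `0:10`).
#' @param scenarios As in [run_oc()].
#' @param n_sims Replications per scenario.
#' @param seed Integer master seed.
#' @param common_rng Share random streams across designs (default `TRUE`);
#'   `FALSE` gives each design an independent stream.
#' @return A `"trial_oc"` object (subclass `"oc_sweep"`) whose table has one
#'   row per (interim count, scenario), with an `n_interims` column.
#' @export
sweep_interims <- function(design, interim_counts, scenarios = NULL,
                           n_sims = NULL, seed = 1L, common_rng = TRUE) {
  if (!inherits(design, "binary_design"))
    stop_invalid("`design` must be a binary_design template")
  interim_counts <- vapply(interim_counts, check_count, integer(1),
                           name = "interim_counts")
  rows <- lapply(seq_along(interim_counts), function(j) {
    k <- interim_counts[j]
    d <- design
    d$schedule <- build_even_schedule(design$n_max, k)
    s <- if (common_rng) seed else mix_seed(seed, 91L, j)
    oc <- run_oc(d, scenarios = scenarios, n_sims = n_sims, seed = s)$oc
    oc$n_interims <- k
    oc
  })
  out <- new_trial_oc(do.call(rbind, rows), design, seed, "patients")
  class(out) <- c("oc_sweep", class(out))
  out
}

#' Plot operating characteristics against the number of interim analyses
#'
#' One line per scenario: the success proportion (type I error under the
#' null scenario, power under an effect scenario) as a function of the
#' number of evenly spaced interim looks.
#'
#' @param x An `"oc_sweep"` object from [sweep_interims()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.oc_sweep <- function(x, ...) {
  tab <- x$oc
  wide <- stats::reshape(
    tab[, c("n_interims", "scenario", "success_proportion")],
    idvar = "n_interims", timevar = "scenario", direction = "wide")
  wide <- wide[order(wide$n_interims), , drop = FALSE]
  ys <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$n_interims, ys, type = "b", pch = 19, lty = 1,
                    xlab = "Number of interim analyses",
                    ylab = "Proportion of trials successful", ...)
  graphics::legend("topleft",
                   legend = sub("^success_proportion\\.", "",
                                colnames(ys)),
                   col = seq_len(ncol(ys)), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write an operating-characteristics table to CSV or JSON
#'
#' The JSON form embeds the design configuration and seed so a run can be
#' reproduced bit-identically from its output alone.
#'
#' @param x A `"trial_oc"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oc_csv <- function(x, path) {
  if (!inherits(x, "trial_oc")) stop_invalid("`x` must be a trial_oc object")
  utils::write.csv(x$oc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oc_csv
#' @export
write_oc_json <- function(x, path) {
  if (!inherits(x, "trial_oc")) stop_invalid("`x` must be a trial_oc object")
  payload <- list(
    design = design_as_config(x$design),
    seed = x$seed,
    info_unit = x$info_unit,
    operating_characteristics = x$oc
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
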