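# The outer phase-extension loop: DM -> AMB -> PHSCMB, iterated, with
# per-cycle audit records.

#' Iterative phase extension (DM / AMB / PHSCMB loop)
#'
#' The package's core fitting routine.  Each cycle runs prime-and-switch
#' density modification on the current phases, traces a pseudo-Calpha
#' model in the modified map, converts it into a second phase source, and
#' combines the two with sigma-A weights.  Cycle 1 walks the full
#' extension schedule; later cycles re-modify at the final resolution.
#' A transient phase-error increase after combination is tolerated (it
#' plays the role of the heating step in simulated annealing); only a DM
#' -stage regression in two consecutive cycles aborts the loop.
#'
#' @param obs [reflection_set()] of observed amplitudes.
#' @param start_phases [reflection_set()] with `phi` (+ `fom`) at the
#'   starting (EM) resolution.
#' @param config a [dm_config()] carrying the extension schedule, solvent
#'   fraction, NCS operators and grid.
#' @param reference_hist histogram target passed to [prime_and_switch()].
#' @param sym crystal [sym_ops()].
#' @param n_cycles outer cycles (default 4).
#' @param truth_phases optional phased [reflection_set()]; when given,
#'   every stage is scored with [weighted_mean_phase_error()] and map
#'   correlations.
#' @param truth_model optional [atom_model()] for Calpha-recovery and map
#'   -correlation audit columns.
#' @param build_sigma_cut peak threshold for the building stage.
#' @param max_peaks cap on peaks handed to the tracer.
#' @param early_exit_tol stop when the DM-stage mean FOM changes by less
#'   than this between cycles (default 0.005; 0 disables).
#' @param verbose print one line per stage.
#' @return Object of class `phase_extension`: list with `final` (the
#'   extended [reflection_set()]), `reports` (one row per stage:
#'   cycle, stage, d_min, mean_fom, wmpe, map_cc_*, ca_frac, n_built),
#'   `config`, and `models` (the per-cycle built models).
#' @export
phase_extend <- function(obs, start_phases, config, reference_hist = NULL,
                         sym = sym_p1(), n_cycles = 4,
                         truth_phases = NULL, truth_model = NULL,
                         build_sigma_cut = 1.5, max_peaks = 600,
                         early_exit_tol = 0.005, verbose = FALSE) {
  cell <- get_cell(obs)
  grid <- if (is.null(config$grid))
    grid_for_resolution(cell, min(config$extension_schedule)) else
      config$grid
  # truth-map machinery for map-CC audit, computed once
  audit <- !is.null(truth_phases)
  cc_ctx <- NULL
  if (audit && !is.null(truth_model)) {
    mm <- model_density_map(truth_model, cell, grid, sym)
    mm <- lowpass_map(mm, min(config$extension_schedule))
    rd <- role_distance_arrays(truth_model, cell, grid, sym, 2)
    cc_ctx <- list(model_map = mm, rd = rd)
  }
  reports <- list()
  models <- list()
  current <- start_phases
  note <- function(cycle, stage, refl, model = NULL) {
    have <- !is.na(refl$phi)
    r <- data.frame(cycle = cycle, stage = stage,
                    d_min = min(refl$d[have]),
                    mean_fom = mean(refl$fom[have], na.rm = TRUE),
                    wmpe = NA_real_, map_cc_all = NA_real_,
                    map_cc_main = NA_real_, map_cc_side = NA_real_,
                    ca_frac = NA_real_,
                    n_built = if (is.null(model)) NA_integer_ else
                      nrow(model))
    if (audit)
      r$wmpe <- weighted_mean_phase_error(refl, truth_phases)
    if (audit && !is.null(cc_ctx) && stage == "DM") {
      m <- map_from_structure_factors(refl[have, , drop = FALSE],
                                      grid = grid, use_fom_weights = TRUE)
      for (reg in c("all", "main", "side")) {
        sel <- switch(reg,
                      all = cc_ctx$rd$main <= 2 | cc_ctx$rd$side <= 2,
                      main = cc_ctx$rd$main <= 2 &
                        cc_ctx$rd$main <= cc_ctx$rd$side,
                      side = cc_ctx$rd$side <= 2 &
                        cc_ctx$rd$side < cc_ctx$rd$main)
        r[[paste0("map_cc_", reg)]] <-
          cor(as.vector(m$rho)[sel], as.vector(cc_ctx$model_map$rho)[sel])
      }
    }
    if (!is.null(model) && !is.null(truth_model) && nrow(model) > 0)
      r$ca_frac <- ca_recovery(model, truth_model, cutoff = 1.5,
                               cell = cell, sym = sym)
    if (verbose)
      message(sprintf("cycle %d %-6s d_min %.2f  mean fom %.3f  wMPE %s",
                      cycle, stage, r$d_min, r$mean_fom,
                      if (is.na(r$wmpe)) "-" else sprintf("%.1f", r$wmpe)))
    reports[[length(reports) + 1]] <<- r
    r
  }
  sched_full <- config$extension_schedule
  dm_fom_prev <- NA_real_
  regressions <- 0
  for (cy in seq_len(max(n_cycles, 0))) {
    cfg <- config
    if (cy > 1)
      cfg$extension_schedule <- tail(sched_full, 1)
    current <- prime_and_switch(obs, current, cfg, reference_hist)
    rdm <- note(cy, "DM", current)
    # automatic model building in the FOM-weighted DM map
    have <- !is.na(current$phi)
    dm_map <- map_from_structure_factors(current[have, , drop = FALSE],
                                         grid = grid,
                                         use_fom_weights = TRUE)
    peaks <- head(find_peaks(dm_map, build_sigma_cut), max_peaks)
    built <- trace_ca_chain(peaks)
    models[[cy]] <- built
    if (nrow(built) >= 4) {
      model_phases <- phases_from_built_model(built, obs, sym)
      note(cy, "AMB", model_phases, model = built)
      current <- combine_phases(current, model_phases)
      note(cy, "PHSCMB", current)
    } else {
      note(cy, "AMB", current, model = built)
    }
    if (!is.na(dm_fom_prev)) {
      if (rdm$mean_fom < dm_fom_prev - 0.002) {
        regressions <- regressions + 1
        if (regressions >= 2) {
          warning("DM-stage figure of merit regressed in two consecutive cycles; stopping")
          break
        }
      } else regressions <- 0
      if (early_exit_tol > 0 &&
          abs(rdm$mean_fom - dm_fom_prev) < early_exit_tol && cy < n_cycles)
        break
    }
    dm_fom_prev <- rdm$mean_fom
  }
  structure(list(final = current,
                 reports = if (length(reports))
                   do.call(rbind, reports) else
                     data.frame(),
                 config = config, models = models),
            class = "phase_extension")
}

#' @export
print.phase_extension <- function(x, ...) {
  r <- x$reports
  cat(sprintf("phase_extension: %d stage(s) over %d cycle(s)\n",
              nrow(r), if (nrow(r)) max(r$cycle) else 0))
  if (nrow(r)) {
    last <- r[nrow(r), ]
    cat(sprintf("  final: d_min %.2f A, mean FOM %.3f%s\n", last$d_min,
                last$mean_fom,
                if (is.na(last$wmpe)) "" else
                  sprintf(", wMPE %.1f deg", last$wmpe)))
  }
  invisible(x)
}

#' @export
summary.phase_extension <- function(object, ...) {
  cat("Phase extension audit trail\n")
  print(object$reports, digits = 3, row.names = FALSE)
  invisible(object$reports)
}

#' @export
as.data.frame.phase_extension <- function(x, ...) x$reports

#' @export
plot.phase_extension <- function(x, ...) {
  r <- x$reports
  if (!nrow(r) || all(is.na(r$wmpe))) {
    plot(seq_len(nrow(r)), r$mean_fom, type = "b", xlab = "stage",
         ylab = "mean FOM", main = "phase extension trajectory", ...)
    return(invisible(x))
  }
  plot(seq_len(nrow(r)), r$wmpe, type = "b", xlab = "stage",
       ylab = "wMPE (degrees)", xaxt = "n",
       main = "phase extension trajectory", ...)
  graphics::axis(1, at = seq_len(nrow(r)),
                 labels = paste0(r$cycle, ":", r$stage), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Run the full pipeline from a config and write artifacts
#'
#' Synthetic-mode orchestration: generate (or load) the scenario, run the
#' phase-extension loop, and write placement.json, per-cycle final
#' reflections (hkl), the final FOM-weighted map (mrc), the built model
#' (pdb), report.json and a log.
#'
#' @param config a list or path to a YAML file; recognised fields:
#'   `mode` ("synthetic"), `seed`, `n_cycles`, plus overrides passed to
#'   [standard_scenario()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the `phase_extension` object.
#' @export
run_full <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$mode)) config$mode <- "synthetic"
  if (config$mode != "synthetic")
    stop("only synthetic mode is supported by run_full; use the individual verbs for file inputs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_cycles <- if (is.null(config$n_cycles)) 4L else as.integer(config$n_cycles)
  sc <- standard_scenario(seed)
  logf <- file.path(outdir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  logline <- function(...) writeLines(sprintf(...), logcon)
  logline("stage=simulate seed=%d n_obs=%d", seed, nrow(sc$obs))
  # the synthetic EM map is generated at the true position in the crystal
  # cell, so the placement is the identity
  pl <- placement(diag(3), c(0, 0, 0), score = NA_real_)
  jsonlite::write_json(list(rotation = as.vector(pl$rotation),
                            translation = pl$translation,
                            score = pl$score, z_score = pl$z_score),
                       file.path(outdir, "placement.json"),
                       auto_unbox = TRUE, digits = NA)
  fit <- phase_extend(sc$obs, sc$start_phases, sc$config,
                      reference_hist = sc$reference_hist, sym = sc$sym,
                      n_cycles = n_cycles, truth_phases = sc$truth_phases,
                      truth_model = sc$truth_model)
  for (i in seq_len(nrow(fit$reports)))
    logline("stage=%s cycle=%d mean_fom=%.4f wmpe=%.2f",
            fit$reports$stage[i], fit$reports$cycle[i],
            fit$reports$mean_fom[i], fit$reports$wmpe[i])
  write_hkl(fit$final, file.path(outdir, "final.hkl"))
  have <- !is.na(fit$final$phi)
  final_map <- map_from_structure_factors(fit$final[have, , drop = FALSE],
                                          grid = sc$config$grid,
                                          use_fom_weights = TRUE)
  write_mrc(final_map, file.path(outdir, "final.mrc"))
  built <- fit$models[[length(fit$models)]]
  if (!is.null(built) && nrow(built) > 0)
    write_pdb_model(built, file.path(outdir, "built.pdb"))
  jsonlite::write_json(fit$reports, file.path(outdir, "report.json"),
                       dataframe = "rows", na = "null", digits = 10)
  invisible(fit)
}
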