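# Synthetic observation tables with the statistical structure of the
# underlying experiments, driven by a ground-truth parameter set.

#' Map epinephrine concentrations (nM) to the model stress input
#'
#' Model inputs are dimensionless; nanomolar epinephrine doses are mapped by
#' a saturating log transform with unit EC50,
#' `stress = 100 * log1p(epi_nM) / log1p(1000)`, so the largest dose of the
#' dose-series design (1000 nM) maps to the high-stress level 100.
#'
#' @param epi_nM Epinephrine concentration(s) in nM.
#' @return Dimensionless stress level(s).
#' @export
epinephrine_to_stress <- function(epi_nM) {
  stopifnot(all(epi_nM >= 0))
  100 * log1p(epi_nM) / log1p(1000)
}

#' Generator configuration for synthetic observation tables
#'
#' @param design One of `"epi_dose_series"` (8 conditions: control, LY294002
#'   alone, and LY294002 for 2 h followed by six epinephrine doses
#'   0.01-1000 nM for 1 h; readouts pS112BAD and pCREB),
#'   `"ly_egf_timecourse"` (10 conditions: control, four EGF time points,
#'   LY294002 alone, and LY294002 followed by EGF 2 h later at four time
#'   points; readouts pAKT_S473, pERK, pS112BAD, pS136BAD), or
#'   `"apoptosis_panel"` (9 treatments x 3 replicate counts of >= `n_cells`
#'   cells, endpoint apoptosis).
#' @param truth Ground-truth `parameter_set` (default
#'   [reference_parameters()]).
#' @param noise_lognorm_sd SD of multiplicative lognormal densitometry noise
#'   (default 0.1; 0 disables).
#' @param noise_add_sd SD of additive Gaussian noise on the normalized scale
#'   (default 0).
#' @param n_cells Cells counted per apoptosis replicate (binomial counting
#'   noise; default 350).
#' @param replicates Apoptosis replicates per treatment (default 3).
#' @param seed Mandatory integer seed.
#' @param variant Apoptosis model variant of the ground truth.
#' @return A `generator_config` list.
#' @export
generator_config <- function(design = c("epi_dose_series", "ly_egf_timecourse",
                                        "apoptosis_panel"),
                             truth = reference_parameters(),
                             noise_lognorm_sd = 0.1, noise_add_sd = 0,
                             n_cells = 350, replicates = 3, seed,
                             variant = "bad_mcl1") {
  design <- match.arg(design)
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(noise_lognorm_sd >= 0, noise_add_sd >= 0, n_cells >= 1,
            replicates >= 1)
  structure(list(design = design, truth = truth,
                 noise_lognorm_sd = noise_lognorm_sd,
                 noise_add_sd = noise_add_sd, n_cells = n_cells,
                 replicates = replicates, seed = as.integer(seed),
                 variant = variant),
            class = "generator_config")
}

.design_epi_dose_series <- function() {
  epi <- c(0.01, 0.1, 1, 10, 100, 1000)
  conds <- c(list(
    list(id = "EPI_control", sched = "control"),
    list(id = "EPI_LY", sched = "LY294002:10@0")),
    lapply(seq_along(epi), function(i) list(
      id = sprintf("EPI_LY_epi%g", epi[i]),
      sched = sprintf("LY294002:10@0+STRESS:%g@2",
                      epinephrine_to_stress(epi[i])))))
  list(conditions = conds, time = 3, horizon = 3,
       readouts = c(pS112BAD = "to_control", pCREB = "to_max"))
}

.design_ly_egf_timecourse <- function() {
  tp <- c(1 / 6, 0.5, 1, 2)
  conds <- c(list(list(id = "TC_control", sched = "control", time = 2)),
             lapply(seq_along(tp), function(i) list(
               id = sprintf("TC_EGF_%gh", tp[i]), sched = "EGF:1@0",
               time = tp[i])),
             list(list(id = "TC_LY", sched = "LY294002:10@0", time = 2)),
             lapply(seq_along(tp), function(i) list(
               id = sprintf("TC_LY_EGF_%gh", tp[i]),
               sched = "LY294002:10@0+EGF:1@2", time = 2 + tp[i])))
  list(conditions = conds, horizon = 4.5,
       readouts = c(pAKT_S473 = "to_control", pERK = "to_total",
                    pS112BAD = "to_control", pS136BAD = "to_control"))
}

.design_apoptosis_panel <- function(horizon = 48) {
  sched <- c(
    AP_control = "control",
    AP_LY = "LY294002:1@0",
    AP_LY_EGF = "LY294002:1@0+EGF:1@0",
    AP_LY_VIP = "LY294002:1@0+STRESS:10@0",
    AP_LY_C4BRaf = "LY294002:1@0+C4BRaf:1@0",
    AP_LY_DNPAK1 = "LY294002:1@0+DN-PAK1:1@0",
    AP_LY_DNPAK1_C4BRaf = "LY294002:1@0+DN-PAK1:1@0+C4BRaf:1@0",
    AP_LY_BADS112A = "LY294002:1@0+BADS112A:1@0",
    AP_EGF_LY_C4BRaf_DNPAK1 = "EGF:1@0+LY294002:1@0+C4BRaf:1@0+DN-PAK1:1@0")
  list(schedules = sched, horizon = horizon)
}

#' Generate a synthetic observation table
#'
#' Simulates the ground-truth model through the chosen experimental design,
#' applies the design's normalization rules (control-normalized species
#' levels, max-normalized pCREB, total-normalized pERK), then applies
#' observation noise: multiplicative lognormal plus additive Gaussian noise
#' for densitometry readouts, binomial counting noise (`n_cells` cells per
#' replicate) for apoptosis percentages. Negative noisy values are clipped at
#' 0 and counted in the `clipped` attribute. Noise-free generation is exactly
#' the simulation module's output.
#'
#' @param cfg A `generator_config`.
#' @return An `observation_table` with attributes `provenance` (list: design,
#'   seed, noise settings) and `clipped`.
#' @export
generate_observations <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  p <- cfg$truth
  clipped <- 0L
  if (cfg$design == "apoptosis_panel") {
    d <- .design_apoptosis_panel()
    rows <- list()
    for (id in names(d$schedules)) {
      cond <- parse_schedule(d$schedules[[id]], horizon = d$horizon, id = id)
      ca <- endpoint_apoptosis(p, cond, variant = cfg$variant)
      for (r in seq_len(cfg$replicates)) {
        val <- if (cfg$noise_lognorm_sd > 0 || cfg$noise_add_sd > 0)
          100 * rbinom(1, cfg$n_cells, min(ca, 100) / 100) / cfg$n_cells
        else ca
        rows[[length(rows) + 1]] <- data.frame(
          condition_id = id, schedule = d$schedules[[id]],
          readout = "apoptosis_pct", time = d$horizon, value = val,
          rule = "none", replicate = r, horizon = d$horizon,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
  } else {
    d <- if (cfg$design == "epi_dose_series") .design_epi_dose_series()
         else .design_ly_egf_timecourse()
    rows <- list()
    for (cc in d$conditions) {
      tmeas <- if (!is.null(cc$time)) cc$time else d$time
      cond <- parse_schedule(cc$sched, horizon = d$horizon, id = cc$id)
      tr <- simulate_trajectory(p, cond, times = sort(unique(c(0, tmeas))),
                                variant = cfg$variant)
      i <- match(tmeas, tr$times)
      for (ro in names(d$readouts)) {
        rows[[length(rows) + 1]] <- data.frame(
          condition_id = cc$id, schedule = cc$sched, readout = ro,
          time = tmeas, value = tr$states[i, .readout_species[[ro]]],
          rule = d$readouts[[ro]], replicate = 1L, horizon = d$horizon,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    # densitometry noise on the raw simulated signal
    if (cfg$noise_lognorm_sd > 0)
      tab$value <- tab$value * exp(rnorm(nrow(tab), 0, cfg$noise_lognorm_sd))
    if (cfg$noise_add_sd > 0)
      tab$value <- tab$value + rnorm(nrow(tab), 0, cfg$noise_add_sd)
    clipped <- sum(tab$value < 0)
    tab$value <- pmax(tab$value, 0)
    # max-normalized readouts are scaled like the measured data
    for (ro in unique(tab$readout[tab$rule == "to_max"])) {
      sel <- tab$readout == ro
      mx <- max(tab$value[sel])
      if (mx > 0) tab$value[sel] <- tab$value[sel] / mx
    }
  }
  rownames(tab) <- NULL
  out <- observation_table(tab)
  attr(out, "provenance") <- list(design = cfg$design, seed = cfg$seed,
                                  noise_lognorm_sd = cfg$noise_lognorm_sd,
                                  noise_add_sd = cfg$noise_add_sd,
                                  n_cells = cfg$n_cells,
                                  variant = cfg$variant)
  attr(out, "clipped") <- clipped
  out
}

#' Generate the full fixture suite used by the pipeline tests
#'
#' Noiseless and noisy variants of all three designs under both apoptosis
#' model variants, plus a merged signaling table (56 rows) matching the
#' signaling fit set and a 27-row apoptosis panel. Byte-stable under a fixed
#' seed.
#'
#' @param seed Integer seed.
#' @param truth Ground-truth `parameter_set`.
#' @return Named list of `observation_table`s: `signaling_noiseless`,
#'   `signaling_noisy`, `apoptosis_noiseless`, `apoptosis_noisy` (model 2)
#'   and `apoptosis_noiseless_m1`, `apoptosis_noisy_m1` (model 1).
#' @export
make_fixture_suite <- function(seed, truth = reference_parameters()) {
  gen <- function(design, sd, variant, seed_off, ncells = 350) {
    generate_observations(generator_config(
      design, truth = truth, noise_lognorm_sd = sd, n_cells = ncells,
      seed = seed + seed_off, variant = variant))
  }
  merge_sig <- function(a, b) observation_table(rbind(as.data.frame(a),
                                                      as.data.frame(b)))
  list(
    signaling_noiseless = merge_sig(gen("epi_dose_series", 0, "bad_mcl1", 1),
                                    gen("ly_egf_timecourse", 0, "bad_mcl1", 2)),
    signaling_noisy = merge_sig(gen("epi_dose_series", 0.1, "bad_mcl1", 3),
                                gen("ly_egf_timecourse", 0.1, "bad_mcl1", 4)),
    apoptosis_noiseless = gen("apoptosis_panel", 0, "bad_mcl1", 5),
    apoptosis_noisy = gen("apoptosis_panel", 0.1, "bad_mcl1", 6),
    apoptosis_noiseless_m1 = gen("apoptosis_panel", 0, "bad_only", 7),
    apoptosis_noisy_m1 = gen("apoptosis_panel", 0.1, "bad_only", 8))
}
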