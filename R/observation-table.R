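# Observation tables: normalized experimental (or synthetic) measurements.

.valid_readouts <- c("pS112BAD", "pS136BAD", "pCREB", "pAKT_S473", "pERK",
                     "apoptosis_pct")
.readout_species <- c(pS112BAD = "pS112BAD", pS136BAD = "pS136BAD",
                      pCREB = "CREB", pAKT_S473 = "AKT", pERK = "ERK")
.valid_rules <- c("to_control", "to_max", "to_total", "none")

#' Construct an observation table
#'
#' A validated table of normalized measurements, one row per (condition,
#' readout, time, replicate). Conditions are carried as schedule descriptor
#' strings (see [format_schedule()]) so tables round-trip through CSV.
#'
#' @param df `data.frame` with columns `condition_id`, `schedule`, `readout`,
#'   `time`, `value`, `rule` and optionally `replicate` (defaults to 1) and
#'   `horizon` (defaults to `max(time)` per condition).
#' @return An object of classes `observation_table` and `data.frame`.
#' @export
observation_table <- function(df) {
  need <- c("condition_id", "schedule", "readout", "time", "value", "rule")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"horizon" %in% names(df)) {
    hz <- tapply(df$time, df$condition_id, max)
    df$horizon <- as.numeric(hz[df$condition_id])
  }
  bad <- setdiff(unique(df$readout), .valid_readouts)
  if (length(bad))
    stop("unknown readout(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$rule), .valid_rules)
  if (length(bad))
    stop("unknown normalization rule(s): ", paste(bad, collapse = ", "))
  if (any(df$value < 0)) stop("normalized values must be >= 0")
  if (any(df$time < 0)) stop("times must be >= 0")
  key <- paste(df$condition_id, df$readout, df$time, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, readout, time, replicate) rows")
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Read / write observation tables as CSV
#' @param path CSV path.
#' @return `read_observation_table()` returns an `observation_table`.
#' @export
read_observation_table <- function(path) {
  observation_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observation_table
#' @param tab An `observation_table`.
#' @export
write_observation_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Simulate the model readouts matching an observation table
#'
#' Runs one simulation per condition and extracts, for every table row, the
#' model prediction on the same normalized scale as the observation:
#' control-normalized species levels are used directly (the untreated control
#' sits at the baseline level 1), `to_max` readouts are divided by the
#' maximal predicted value of that readout across the table, and apoptosis
#' percentages are kept on the percentage scale.
#'
#' @param p A `parameter_set`.
#' @param tab An `observation_table`.
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return Numeric vector of predictions, aligned with the rows of `tab`.
#' @export
predict_observations <- function(p, tab, variant = "bad_mcl1", step = 0.01) {
  stopifnot(inherits(tab, "observation_table"))
  pred <- numeric(nrow(tab))
  for (cid in unique(tab$condition_id)) {
    idx <- which(tab$condition_id == cid)
    sched <- unique(tab$schedule[idx])
    if (length(sched) != 1)
      stop("condition '", cid, "' has inconsistent schedule descriptors")
    horizon <- max(tab$horizon[idx])
    cond <- tryCatch(parse_schedule(sched, horizon = horizon, id = cid),
                     error = function(e)
                       stop("condition '", cid, "' cannot be simulated: ",
                            conditionMessage(e)))
    tt <- sort(unique(tab$time[idx]))
    times <- sort(unique(c(0, tt)))
    apo_step <- if (horizon > 12) 0.05 else step
    tr <- simulate_trajectory(p, cond, times = times, step = apo_step,
                              variant = variant)
    full <- cbind(tr$states, apoptosis_pct = tr$apoptosis)
    for (i in idx) {
      var <- if (tab$readout[i] == "apoptosis_pct") "apoptosis_pct"
             else .readout_species[[tab$readout[i]]]
      pred[i] <- full[match(tab$time[i], times), var]
    }
  }
  # to_max readouts are normalized across the table, like the data
  for (ro in unique(tab$readout[tab$rule == "to_max"])) {
    sel <- tab$readout == ro
    mx <- max(pred[sel])
    if (mx > 0) pred[sel] <- pred[sel] / mx
  }
  pred
}

#' Fitting objective: mean squared error between model and observations
#'
#' The fitness used for parameter estimation: the mean of squared residuals
#' between predicted and observed normalized values over all table rows.
#' Apoptosis percentages enter on the fractional (0-1) scale so signaling and
#' apoptosis residuals are comparable.
#'
#' @inheritParams predict_observations
#' @return Scalar mean squared error.
#' @export
objective <- function(p, tab, variant = "bad_mcl1", step = 0.01) {
  pred <- predict_observations(p, tab, variant = variant, step = step)
  obs <- tab$value
  apo <- tab$readout == "apoptosis_pct"
  pred[apo] <- pred[apo] / 100
  obs[apo] <- obs[apo] / 100
  mean((pred - obs)^2)
}

#' Merge apoptosis datasets measured in different experimental environments
#'
#' Rescales the second table by the ratio of anchor-treatment means so both
#' datasets report apoptosis on a common scale, then row-binds them. The
#' anchor treatments (by default LY294002 alone and LY294002 + EGF) must be
#' present in both tables.
#'
#' @param tab_a Reference `observation_table` (apoptosis rows).
#' @param tab_b Table to rescale.
#' @param anchors Character vector of anchor schedule strings.
#' @return List with `merged` (observation_table) and `scale_factor`.
#' @export
scale_apoptosis_datasets <- function(tab_a, tab_b,
                                     anchors = c("LY294002:1@0",
                                                 "LY294002:1@0+EGF:1@0")) {
  mean_anchor <- function(tab, which_tab) {
    sel <- tab$schedule %in% anchors & tab$readout == "apoptosis_pct"
    if (!all(anchors %in% tab$schedule[sel]))
      stop("anchor treatment(s) missing from ", which_tab, ": ",
           paste(setdiff(anchors, tab$schedule[sel]), collapse = ", "))
    mean(tab$value[sel])
  }
  f <- mean_anchor(tab_a, "first table") / mean_anchor(tab_b, "second table")
  tab_b$value <- tab_b$value * f
  if (any(tab_b$condition_id %in% tab_a$condition_id))
    tab_b$condition_id <- paste0(tab_b$condition_id, "_b")
  merged <- rbind(as.data.frame(tab_a), as.data.frame(tab_b))
  list(merged = observation_table(merged), scale_factor = f)
}
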