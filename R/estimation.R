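# Genetic-algorithm parameter estimation and apoptosis model selection.

#' Default fit bounds for the free parameters
#'
#' Dimensionless state levels are of order 1, so velocities and Michaelis
#' coefficients default to \[1e-3, 1e2\], decay rates to \[1e-3, 10\], the
#' apoptosis rate to \[1e-4, 10\], Hill-type apoptosis constants to
#' \[1e-2, 10\], exponents to \[1, 4\] and the Mcl-1 strength to \[1e-3, 1\].
#'
#' @param free Character vector of free parameter names (flattened notation,
#'   see [flatten_parameters()]).
#' @return 2-column matrix (`lo`, `hi`) with one row per free parameter.
#' @export
default_bounds <- function(free) {
  lo <- numeric(length(free)); hi <- numeric(length(free))
  for (i in seq_along(free)) {
    nm <- free[i]
    b <- if (grepl("^V_|^K_", nm)) c(1e-3, 1e2)
    else if (grepl("^d_", nm)) c(1e-3, 10)
    else if (nm == "k_a") c(1e-4, 10)
    else if (nm %in% c("n_bad", "n_mcl") || grepl("^n_", nm)) c(1, 4)
    else if (nm == "beta_mcl") c(1e-3, 1)
    else if (nm == "bad_total") c(1, 10)
    else if (nm %in% c("K_bad", "K_mcl")) c(1e-2, 10)
    else stop("no default bounds for parameter '", nm, "'")
    lo[i] <- b[1]; hi[i] <- b[2]
  }
  cbind(lo = setNames(lo, free), hi = setNames(hi, free))
}

#' Names of all free parameters of a submodel
#' @param stage `"signaling"` (37 parameters) or `"apoptosis"` (7).
#' @return Character vector in flattened notation.
#' @export
free_parameter_names <- function(stage = c("signaling", "apoptosis")) {
  stage <- match.arg(stage)
  if (stage == "signaling")
    c(paste0("V_", reaction_names()), paste0("K_", reaction_names()),
      paste0("d_", c(.egfr_branch_species, .zero_baseline_species)))
  else apoptosis_parameter_names()
}

#' Genetic-algorithm fit configuration
#'
#' @param free Free parameter names (flattened notation).
#' @param bounds Bounds matrix as from [default_bounds()].
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param crossover Uniform-crossover probability.
#' @param mutation Per-gene mutation probability (Gaussian in log10 space).
#' @param mutation_sd Mutation standard deviation (log10 units).
#' @param elitism Number of elite individuals copied unchanged.
#' @param tournament Tournament size for selection.
#' @param seed Integer seed, recorded in every fit report.
#' @param polish Run a derivative-free Nelder-Mead polish after the GA.
#' @param step RK4 step used inside the objective (h).
#' @return A `fit_config` list.
#' @export
fit_config <- function(free, bounds = default_bounds(free), pop_size = 100,
                       generations = 200, crossover = 0.8, mutation = 0.1,
                       mutation_sd = 0.15, elitism = 2, tournament = 3,
                       seed = 1, polish = TRUE, step = 0.01) {
  stopifnot(length(free) >= 1, nrow(bounds) == length(free),
            all(bounds[, "lo"] > 0), all(is.finite(bounds)),
            all(bounds[, "hi"] > bounds[, "lo"]))
  structure(list(free = free, bounds = bounds, pop_size = pop_size,
                 generations = generations, crossover = crossover,
                 mutation = mutation, mutation_sd = mutation_sd,
                 elitism = elitism, tournament = tournament, seed = seed,
                 polish = polish, step = step),
            class = "fit_config")
}

#' Fit free parameters to an observation table with a genetic algorithm
#'
#' Real-coded GA searched in log10 space (parameters are positive and span
#' scales): tournament selection, uniform crossover, per-gene Gaussian
#' mutation, elitism, with every individual clamped inside the bounds. An
#' optional Nelder-Mead polish refines the GA optimum. Parameters not listed
#' in `cfg$free` stay at their values in `template`; derived decay rates are
#' re-closed for every candidate.
#'
#' @param tab An `observation_table`.
#' @param cfg A `fit_config`.
#' @param template A `parameter_set` providing the fixed parameters
#'   (defaults to [reference_parameters()]).
#' @param variant Apoptosis model variant.
#' @return A `fit_report`: list with `parameters` (best `parameter_set`),
#'   `mse`, `history` (best MSE per generation), `seed`, `config`,
#'   `improved` (whether the GA beat the best initial individual).
#' @export
fit_parameters <- function(tab, cfg, template = reference_parameters(),
                           variant = "bad_mcl1") {
  stopifnot(inherits(tab, "observation_table"), inherits(cfg, "fit_config"),
            nrow(tab) > 0)
  set.seed(cfg$seed)
  free <- cfg$free
  lo <- log10(cfg$bounds[, "lo"]); hi <- log10(cfg$bounds[, "hi"])
  k <- length(free)
  evalfun <- function(z) {
    z <- pmin(pmax(z, lo), hi) # simplex polish may probe outside the box
    vals <- setNames(10^z, free)
    p <- update_parameters(template, vals)
    objective(p, tab, variant = variant, step = cfg$step)
  }
  pop <- matrix(runif(cfg$pop_size * k, rep(lo, each = cfg$pop_size),
                      rep(hi, each = cfg$pop_size)), cfg$pop_size, k)
  fit <- apply(pop, 1, evalfun)
  init_best <- min(fit)
  history <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    while (nrow(newpop) < cfg$pop_size) {
      pick <- function() {
        cand <- sample.int(cfg$pop_size, cfg$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (runif(1) < cfg$crossover) {
        mask <- runif(k) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- runif(k) < cfg$mutation
      child[mut] <- child[mut] + rnorm(sum(mut), 0, cfg$mutation_sd * (hi - lo)[mut])
      child <- pmin(pmax(child, lo), hi)
      newpop <- rbind(newpop, child)
    }
    pop <- newpop
    fit <- apply(pop, 1, evalfun)
    history[g] <- min(fit)
  }
  best <- pop[which.min(fit), ]
  best_mse <- min(fit)
  if (cfg$polish) {
    res <- optim(best, evalfun, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10))
    if (res$value < best_mse) { best <- pmin(pmax(res$par, lo), hi); best_mse <- evalfun(best) }
  }
  improved <- best_mse <= init_best
  if (!improved)
    warning("GA failed to improve beyond the best initial individual")
  params <- update_parameters(template, setNames(10^best, free))
  structure(list(parameters = params, mse = best_mse, history = history,
                 seed = cfg$seed, config = cfg, improved = improved),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %d free parameters, %d generations, final MSE %.4g (seed %d)\n",
              length(x$config$free), x$config$generations, x$mse, x$seed))
  invisible(x)
}

#' Select between the BAD-only and BAD+Mcl-1 apoptosis models
#'
#' Fits the 7 apoptosis parameters of both model variants on the training
#' treatments (by default LY294002 alone, LY294002 + EGF and LY294002 +
#' stress), evaluates each fitted variant on the held-out conditions, and
#' selects the variant with the lower holdout MSE; ties break toward the
#' more parsimonious BAD-only model.
#'
#' @param tab Apoptosis `observation_table` (readout `apoptosis_pct`).
#' @param signaling A `parameter_set` with the signaling stage already fixed.
#' @param train_schedules Schedule strings defining the training set.
#' @param cfg A `fit_config` for the apoptosis stage (7 free parameters);
#'   defaults to a reduced GA budget.
#' @return List with `choice` (`"bad_only"` or `"bad_mcl1"`), `holdout_mse`
#'   (named numeric, both variants), `fits` (both fit reports), and the
#'   train/holdout split.
#' @export
model_select <- function(tab, signaling = reference_parameters(),
                         train_schedules = c("LY294002:1@0",
                                             "LY294002:1@0+EGF:1@0",
                                             "LY294002:1@0+STRESS:10@0"),
                         cfg = NULL) {
  stopifnot(inherits(tab, "observation_table"))
  train <- tab[tab$schedule %in% train_schedules, , drop = FALSE]
  holdout <- tab[!tab$schedule %in% train_schedules, , drop = FALSE]
  if (!nrow(train)) stop("no training rows match the training schedules")
  if (!nrow(holdout)) stop("holdout set is empty")
  train <- observation_table(as.data.frame(train))
  holdout <- observation_table(as.data.frame(holdout))
  if (is.null(cfg))
    cfg <- fit_config(free_parameter_names("apoptosis"), pop_size = 60,
                      generations = 60, seed = 1, step = 0.05)
  fits <- list()
  hold_mse <- c(bad_only = NA_real_, bad_mcl1 = NA_real_)
  for (v in c("bad_only", "bad_mcl1")) {
    cfg_v <- cfg
    if (v == "bad_only") {
      # the Mcl-1 strength is structurally absent from model 1
      keep <- cfg$free != "beta_mcl"
      cfg_v <- fit_config(cfg$free[keep], cfg$bounds[keep, , drop = FALSE],
                          pop_size = cfg$pop_size, generations = cfg$generations,
                          crossover = cfg$crossover, mutation = cfg$mutation,
                          mutation_sd = cfg$mutation_sd, elitism = cfg$elitism,
                          tournament = cfg$tournament, seed = cfg$seed,
                          polish = cfg$polish, step = cfg$step)
    }
    fits[[v]] <- fit_parameters(train, cfg_v, template = signaling, variant = v)
    hold_mse[v] <- objective(fits[[v]]$parameters, holdout, variant = v,
                             step = cfg$step)
  }
  choice <- if (hold_mse["bad_mcl1"] < hold_mse["bad_only"]) "bad_mcl1" else "bad_only"
  list(choice = choice, holdout_mse = hold_mse, fits = fits,
       train = train, holdout = holdout)
}
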