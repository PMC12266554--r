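#' Configuration for one simulated feeding cage
#'
#' The simulator emulates a caged cohort of nurse bees feeding for several
#' days from one dish (no-choice), two complementary dishes (choice), or no
#' dish at all (no-food control). Surviving bees demand an equal share of a
#' per-bee intake trajectory set by a rule of compromise toward the intake
#' target; daily cage intake is perturbed by multiplicative lognormal
#' feeding noise, and each equilibrated dish mass carries additive Gaussian
#' weighing noise.
#'
#' @param diets Diets on offer: a list of 0, 1 or 2 \code{bee_diet} objects
#'   (or canonical names). Empty list = no-food control cage.
#' @param rule Rule governing the agents: one of [compromise_rules()] or
#'   \code{"no_regulation"} (each dish eaten at its own no-choice rate split
#'   evenly across dishes, with no compensation between dishes).
#' @param target \code{intake_target}, per bee over the full horizon.
#' @param n_bees Bees at day 0.
#' @param n_days Experiment duration in days.
#' @param daily_mortality_hazard Per-bee, per-day death probability. The
#'   default 0.0267 yields about 15% cumulative mortality over six days
#'   (1 - (1 - 0.0267)^6 = 0.150).
#' @param feeding_noise_cv Coefficient of variation of the daily cage-level
#'   feeding noise (lognormal, mean 1).
#' @param weighing_noise_sd Additive Gaussian noise (mg) on each equilibrated
#'   final dish mass.
#' @param initial_dish_mass Dish mass (mg) at the start of each day;
#'   must be ad libitum for the configured demand.
#' @param cage_id Identifier string.
#' @param seed Integer seed making the cage fully reproducible.
#' @return A \code{cage_config}.
#' @export
cage_config <- function(diets, rule = "strict_restraint",
                        target = intake_target(30, 20, "design default"),
                        n_bees = 30, n_days = 6,
                        daily_mortality_hazard = 0.0267,
                        feeding_noise_cv = 0.15,
                        weighing_noise_sd = 0.5,
                        initial_dish_mass = 5000,
                        cage_id = "cage-01",
                        seed = 1L) {
  if (!is.list(diets)) diets <- list(diets)
  diets <- lapply(diets, as_bee_diet)
  if (length(diets) > 2L)
    stop("a cage offers at most two dishes", call. = FALSE)
  rule <- match.arg(rule, c(compromise_rules(), "no_regulation"))
  stopifnot(inherits(target, "intake_target"))
  if (n_bees <= 0) stop("n_bees must be positive", call. = FALSE)
  if (daily_mortality_hazard < 0 || daily_mortality_hazard >= 1)
    stop("daily_mortality_hazard must be in [0, 1)", call. = FALSE)
  if (feeding_noise_cv < 0 || weighing_noise_sd < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(diets = diets, rule = rule, target = target,
                 n_bees = as.integer(n_bees), n_days = as.integer(n_days),
                 daily_mortality_hazard = daily_mortality_hazard,
                 feeding_noise_cv = feeding_noise_cv,
                 weighing_noise_sd = weighing_noise_sd,
                 initial_dish_mass = initial_dish_mass,
                 cage_id = cage_id, seed = as.integer(seed)),
            class = "cage_config")
}

# Per-bee, full-horizon food amounts (mg) demanded from each dish under the
# configured rule. Choice cages under a regulating rule mix the two
# complementary rails so the summed intake point moves directly toward the
# target; if the target lies outside the cone spanned by the rails, agents
# use the admissible rail closest to the target (flagged).
dish_demands <- function(config) {
  diets <- config$diets
  target <- config$target
  if (length(diets) == 0L)
    return(list(amounts = numeric(0), flag = NULL))
  if (config$rule == "no_regulation") {
    amts <- vapply(diets, function(d)
      predict_intake("strict_restraint", d, target)$amount, numeric(1)) /
      length(diets)
    return(list(amounts = amts, flag = NULL))
  }
  if (length(diets) == 1L) {
    pr <- predict_intake(config$rule, diets[[1]], target)
    return(list(amounts = pr$amount, flag = pr$flag))
  }
  # two dishes: solve a1 * (p1, l1) + a2 * (p2, l2) = (P_T, L_T)
  M <- cbind(c(diets[[1]]$protein_frac, diets[[1]]$lipid_frac),
             c(diets[[2]]$protein_frac, diets[[2]]$lipid_frac))
  tg <- c(target$point$protein_mg, target$point$lipid_mg)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(det) > 1e-12) {
    a <- solve(M, tg)
    if (all(a >= -1e-9))
      return(list(amounts = pmax(a, 0), flag = NULL))
  }
  # target outside the cone (or parallel rails): nearest admissible rail
  ang <- vapply(diets, function(d)
    abs(atan2(d$lipid_frac, d$protein_frac) - atan2(tg[2], tg[1])), numeric(1))
  k <- which.min(ang)
  pr <- predict_intake(config$rule, diets[[k]], target)
  amts <- numeric(length(diets)); amts[k] <- pr$amount
  list(amounts = amts, flag = "target_outside_cone")
}

#' Simulate one feeding cage
#'
#' Each day, per-bee deaths are drawn independently at the daily mortality
#' hazard and dead bees are removed; the survivors then consume their daily
#' share (full-horizon demand / n_days) of each dish, scaled by a single
#' lognormal cage-day feeding-noise factor with mean 1. Final equilibrated
#' dish masses carry additive Gaussian weighing noise. The record is fully
#' reproducible from the config seed.
#'
#' @param config A [cage_config()].
#' @return A \code{cage_record}: dish-day masses, deaths and live counts by
#'   day, any flags, and the noise-free truth (per-dish per-capita totals and
#'   the cumulative intake point) used by endpoint simulation and tests.
#' @examples
#' rec <- simulate_cage(cage_config(list("P30:L20"), seed = 42))
#' rec$alive_by_day
#' @export
simulate_cage <- function(config) {
  stopifnot(inherits(config, "cage_config"))
  set.seed(config$seed)
  dem <- dish_demands(config)
  n_dish <- length(config$diets)
  daily_per_bee <- if (n_dish) dem$amounts / config$n_days else numeric(0)

  sdlog <- sqrt(log(1 + config$feeding_noise_cv^2))
  alive <- config$n_bees
  deaths_by_day <- integer(config$n_days)
  alive_by_day <- integer(config$n_days)
  rows <- vector("list", config$n_days)
  percap <- numeric(n_dish)  # true per-capita totals per dish

  for (day in seq_len(config$n_days)) {
    deaths <- if (config$daily_mortality_hazard > 0 && alive > 0)
      stats::rbinom(1L, alive, config$daily_mortality_hazard) else 0L
    alive <- alive - deaths
    deaths_by_day[day] <- deaths
    alive_by_day[day] <- alive

    if (n_dish) {
      noise <- if (config$feeding_noise_cv > 0)
        stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
      intake <- daily_per_bee * alive * noise
      if (any(intake > config$initial_dish_mass))
        stop(sprintf("dish exhausted on day %d of cage %s: demand %.1f mg exceeds dish mass %.1f mg",
                     day, config$cage_id, max(intake),
                     config$initial_dish_mass), call. = FALSE)
      wnoise <- if (config$weighing_noise_sd > 0)
        stats::rnorm(n_dish, 0, config$weighing_noise_sd) else numeric(n_dish)
      rows[[day]] <- data.frame(
        cage_id = config$cage_id, day = day,
        diet = vapply(config$diets, `[[`, character(1), "name"),
        initial_mass_mg = rep(config$initial_dish_mass, n_dish),
        final_mass_mg = config$initial_dish_mass - intake + wnoise,
        stringsAsFactors = FALSE)
      if (alive > 0) percap <- percap + intake / alive
    }
  }

  dish_days <- if (n_dish) do.call(rbind, rows) else
    data.frame(cage_id = character(0), day = integer(0), diet = character(0),
               initial_mass_mg = numeric(0), final_mass_mg = numeric(0))
  truth_point <- c(protein_mg = 0, lipid_mg = 0)
  for (k in seq_len(n_dish)) {
    d <- config$diets[[k]]
    truth_point <- truth_point + percap[k] * c(d$protein_frac, d$lipid_frac)
  }
  structure(list(cage_id = config$cage_id,
                 config = config,
                 dish_days = dish_days,
                 deaths_by_day = deaths_by_day,
                 alive_by_day = alive_by_day,
                 flags = dem$flag,
                 truth = list(per_dish_per_capita = stats::setNames(
                                percap,
                                vapply(config$diets, `[[`, character(1), "name")),
                              point = truth_point)),
            class = "cage_record")
}

#' @export
print.cage_record <- function(x, ...) {
  cat(sprintf("Cage %s: %d bees at day 0, %d alive after day %d; %d dish(es)\n",
              x$cage_id, x$config$n_bees,
              utils::tail(x$alive_by_day, 1), x$config$n_days,
              length(x$config$diets)))
  invisible(x)
}

#' Parameters for per-bee endpoint simulation
#'
#' Mean hypopharyngeal-gland (HPG) acinus diameter increases linearly with
#' cumulative protein intake; total body lipid is drawn from a
#' diet-independent lognormal, reflecting the finding that adult bees barely
#' assimilate dietary lipid.
#'
#' @param baseline_um Mean acinus diameter (um) at zero protein intake.
#' @param slope_protein_um_per_mg Increase in mean diameter per mg protein.
#' @param slope_lipid_um_per_mg Increase per mg lipid (0 by default).
#' @param bee_sd_um Between-bee SD of the mean diameter.
#' @param acinus_sd_um Within-bee SD across acini.
#' @param acini_per_bee Acini measured per bee.
#' @param body_lipid_meanlog,body_lipid_sdlog Lognormal parameters of total
#'   body lipid (mg).
#' @return A list of parameters.
#' @export
bee_outcome_params <- function(baseline_um = 60,
                               slope_protein_um_per_mg = 0.5,
                               slope_lipid_um_per_mg = 0,
                               bee_sd_um = 3,
                               acinus_sd_um = 2,
                               acini_per_bee = 10L,
                               body_lipid_meanlog = log(3),
                               body_lipid_sdlog = 0.25) {
  list(baseline_um = baseline_um,
       slope_protein_um_per_mg = slope_protein_um_per_mg,
       slope_lipid_um_per_mg = slope_lipid_um_per_mg,
       bee_sd_um = bee_sd_um, acinus_sd_um = acinus_sd_um,
       acini_per_bee = as.integer(acini_per_bee),
       body_lipid_meanlog = body_lipid_meanlog,
       body_lipid_sdlog = body_lipid_sdlog)
}

#' Simulate one bee's HPG and body-lipid endpoints
#'
#' @param per_capita_protein Cumulative protein intake, mg per bee.
#' @param per_capita_lipid Cumulative lipid intake, mg per bee.
#' @param params See [bee_outcome_params()].
#' @param cage_id Cage the bee was sampled from.
#' @return A \code{bee_outcome}: acinus diameters (um, length
#'   \code{acini_per_bee}) and total body lipid (mg).
#' @export
simulate_bee_outcomes <- function(per_capita_protein, per_capita_lipid,
                                  params = bee_outcome_params(),
                                  cage_id = NA_character_) {
  if (per_capita_protein < 0 || per_capita_lipid < 0)
    stop("intakes must be non-negative", call. = FALSE)
  mu <- params$baseline_um +
    params$slope_protein_um_per_mg * per_capita_protein +
    params$slope_lipid_um_per_mg * per_capita_lipid
  bee_mean <- mu + (if (params$bee_sd_um > 0)
    stats::rnorm(1, 0, params$bee_sd_um) else 0)
  diam <- bee_mean + (if (params$acinus_sd_um > 0)
    stats::rnorm(params$acini_per_bee, 0, params$acinus_sd_um)
    else numeric(params$acini_per_bee))
  diam <- pmax(diam, 1e-6)
  lip <- stats::rlnorm(1, params$body_lipid_meanlog, params$body_lipid_sdlog)
  structure(list(cage_id = cage_id,
                 hpg_acinus_diameters = diam,
                 body_lipid_mg = lip),
            class = "bee_outcome")
}

# Stable child seed from a master seed and a cage identifier (31-based
# string hash, reduced modulo 2^31 - 1).
child_seed <- function(master, cage_id) {
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(as.character(cage_id)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Full study design description
#'
#' The default mirrors the caged-nurse-bee study layout: a no-choice arm of
#' five diets plus a no-food control, 12 cages of 30 bees each; and a choice
#' arm of three food pairings, 12 cages of 25 bees each; six days throughout.
#'
#' @param replicates Cages per treatment.
#' @param n_bees_no_choice,n_bees_choice Bees per cage in each arm.
#' @param n_days Days of feeding.
#' @param rule Generating rule of compromise.
#' @param target Generating intake target (per bee, full horizon).
#' @param include_control Include the no-food control treatment.
#' @param daily_mortality_hazard,feeding_noise_cv,weighing_noise_sd See
#'   [cage_config()].
#' @param outcome_params See [bee_outcome_params()].
#' @return A \code{study_design} list.
#' @export
study_design <- function(replicates = 12L,
                         n_bees_no_choice = 30L,
                         n_bees_choice = 25L,
                         n_days = 6L,
                         rule = "strict_restraint",
                         target = intake_target(30, 20, "design default"),
                         include_control = TRUE,
                         daily_mortality_hazard = 0.0267,
                         feeding_noise_cv = 0.15,
                         weighing_noise_sd = 0.5,
                         outcome_params = bee_outcome_params()) {
  structure(list(replicates = as.integer(replicates),
                 n_bees_no_choice = as.integer(n_bees_no_choice),
                 n_bees_choice = as.integer(n_bees_choice),
                 n_days = as.integer(n_days),
                 rule = rule, target = target,
                 include_control = include_control,
                 daily_mortality_hazard = daily_mortality_hazard,
                 feeding_noise_cv = feeding_noise_cv,
                 weighing_noise_sd = weighing_noise_sd,
                 outcome_params = outcome_params,
                 diets = study_diets(),
                 pairings = food_pairings()),
            class = "study_design")
}

#' Simulate a full no-choice + choice experiment
#'
#' Generates every cage of the design with deterministic per-cage child
#' seeds derived from the master seed, then samples one bee per no-choice
#' cage (including controls) for HPG and body-lipid endpoints.
#'
#' @param design A [study_design()].
#' @param seed Master integer seed.
#' @return A \code{cage_experiment}: \code{cages} (named list of
#'   \code{cage_record}), \code{bees} (list of \code{bee_outcome}),
#'   \code{design}, \code{seed}.
#' @examples
#' ex <- simulate_experiment(study_design(replicates = 2L), seed = 1)
#' length(ex$cages)
#' @export
simulate_experiment <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (design$replicates < 1L) stop("invalid design: replicates < 1", call. = FALSE)
  cages <- list()

  nochoice_treatments <- names(design$diets)
  if (design$include_control)
    nochoice_treatments <- c(nochoice_treatments, "CTRL")
  for (tr in nochoice_treatments) {
    for (r in seq_len(design$replicates)) {
      cid <- sprintf("NC-%s-%02d", tr, r)
      cfg <- cage_config(
        diets = if (tr == "CTRL") list() else list(design$diets[[tr]]),
        rule = design$rule, target = design$target,
        n_bees = design$n_bees_no_choice, n_days = design$n_days,
        daily_mortality_hazard = design$daily_mortality_hazard,
        feeding_noise_cv = design$feeding_noise_cv,
        weighing_noise_sd = design$weighing_noise_sd,
        cage_id = cid, seed = child_seed(seed, cid))
      cages[[cid]] <- simulate_cage(cfg)
      cages[[cid]]$treatment <- tr
      cages[[cid]]$arm <- if (tr == "CTRL") "control" else "no_choice"
    }
  }
  for (fpt in names(design$pairings)) {
    for (r in seq_len(design$replicates)) {
      cid <- sprintf("C-%s-%02d", fpt, r)
      cfg <- cage_config(
        diets = lapply(design$pairings[[fpt]], function(nm) design$diets[[nm]]),
        rule = design$rule, target = design$target,
        n_bees = design$n_bees_choice, n_days = design$n_days,
        daily_mortality_hazard = design$daily_mortality_hazard,
        feeding_noise_cv = design$feeding_noise_cv,
        weighing_noise_sd = design$weighing_noise_sd,
        cage_id = cid, seed = child_seed(seed, cid))
      cages[[cid]] <- simulate_cage(cfg)
      cages[[cid]]$treatment <- fpt
      cages[[cid]]$arm <- "choice"
    }
  }

  # endpoint sampling: one bee per no-choice cage (controls included)
  bees <- list()
  for (cid in names(cages)) {
    rec <- cages[[cid]]
    if (rec$arm == "choice") next
    set.seed(child_seed(seed, paste0("bee-", cid)))
    bees[[cid]] <- simulate_bee_outcomes(
      rec$truth$point[["protein_mg"]], rec$truth$point[["lipid_mg"]],
      params = design$outcome_params, cage_id = cid)
  }

  structure(list(cages = cages, bees = bees, design = design, seed = seed),
            class = "cage_experiment")
}

#' @export
print.cage_experiment <- function(x, ...) {
  arms <- vapply(x$cages, `[[`, character(1), "arm")
  cat(sprintf("Simulated cage experiment (seed %d): %d no-choice, %d control, %d choice cages; %d endpoint bees\n",
              x$seed, sum(arms == "no_choice"), sum(arms == "control"),
              sum(arms == "choice"), length(x$bees)))
  invisible(x)
}

#' Write a simulated experiment to CSV files
#'
#' Writes \code{dishes.csv} (cage_id, day, diet, initial_mass_mg,
#' final_mass_mg), \code{cages.csv} (cage_id, treatment, arm, n_bees0,
#' deaths_day1..n) and \code{bees.csv} (cage_id, acinus_diameters_um
#' semicolon-joined, body_lipid_mg).
#'
#' @param experiment A \code{cage_experiment}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment_csv <- function(experiment, dir) {
  stopifnot(inherits(experiment, "cage_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dishes <- do.call(rbind, lapply(experiment$cages, `[[`, "dish_days"))
  utils::write.csv(dishes, file.path(dir, "dishes.csv"), row.names = FALSE)

  n_days <- experiment$design$n_days
  cages <- do.call(rbind, lapply(experiment$cages, function(rec) {
    row <- data.frame(cage_id = rec$cage_id, treatment = rec$treatment,
                      arm = rec$arm, n_bees0 = rec$config$n_bees,
                      stringsAsFactors = FALSE)
    for (d in seq_len(n_days))
      row[[sprintf("deaths_day%d", d)]] <- rec$deaths_by_day[d]
    row
  }))
  utils::write.csv(cages, file.path(dir, "cages.csv"), row.names = FALSE)

  bees <- do.call(rbind, lapply(experiment$bees, function(b)
    data.frame(cage_id = b$cage_id,
               acinus_diameters_um = paste(sprintf("%.4f", b$hpg_acinus_diameters),
                                           collapse = ";"),
               body_lipid_mg = b$body_lipid_mg, stringsAsFactors = FALSE)))
  utils::write.csv(bees, file.path(dir, "bees.csv"), row.names = FALSE)
  invisible(dir)
}
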