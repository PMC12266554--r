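#' Daily per-capita consumption from one dish-day record
#'
#' Consumption is the drop in equilibrated dish mass divided by the number
#' of bees still alive in the cage on that day (dead bees are removed daily,
#' so the census is the end-of-day live count). Small apparent mass gains,
#' within \code{tolerance}, are retained as (flagged) measurement noise
#' rather than clamped to zero; gains beyond the tolerance indicate a
#' suspect record.
#'
#' @param initial_mass Equilibrated dish mass (mg) going in.
#' @param final_mass Equilibrated dish mass (mg) coming out.
#' @param alive_count Live bees in the cage that day.
#' @param tolerance Largest tolerated apparent mass gain (mg); default 1.
#' @return Per-capita consumption (mg per bee), with attribute
#'   \code{flagged = TRUE} when negative.
#' @examples
#' daily_per_capita(500, 440, 30)
#' @export
daily_per_capita <- function(initial_mass, final_mass, alive_count,
                             tolerance = 1.0) {
  if (!is.finite(initial_mass) || initial_mass <= 0)
    stop("initial_mass must be positive and finite", call. = FALSE)
  if (!is.finite(final_mass))
    stop("final_mass must be finite", call. = FALSE)
  if (is.na(alive_count) || alive_count <= 0)
    stop("empty cage: alive_count must be positive", call. = FALSE)
  gain <- final_mass - initial_mass
  if (gain > tolerance)
    stop(sprintf("suspect record: dish gained %.3f mg (> tolerance %.3f mg)",
                 gain, tolerance), call. = FALSE)
  out <- (initial_mass - final_mass) / alive_count
  attr(out, "flagged") <- out < 0
  out
}

#' Cage totals of food, protein and lipid intake
#'
#' Sums daily per-capita consumption per dish over the experiment, then maps
#' each dish total onto its food rail and adds the rails to get the cage's
#' cumulative protein-lipid intake point. Dish-day records whose apparent
#' mass gain exceeds the tolerance are excluded from totals and reported in
#' the result (never silently dropped).
#'
#' @param cage A \code{cage_record} (or a list with \code{dish_days} and
#'   \code{alive_by_day} in the same layout).
#' @param diets Named list of \code{bee_diet} resolving every diet name in
#'   the record; defaults to parsing the names.
#' @param tolerance Passed to [daily_per_capita()].
#' @return A \code{cage_intake}: cage_id, total_food (mg/bee),
#'   \code{total_point} (\code{nutrient_point}), per_dish_totals, ratio
#'   (protein/lipid, NA when lipid <= 0), counts of flagged and excluded
#'   records.
#' @export
cage_totals <- function(cage, diets = NULL, tolerance = 1.0) {
  dd <- cage$dish_days
  if (nrow(dd) == 0L)
    stop("cage has no dish records (no-food control?)", call. = FALSE)
  alive <- cage$alive_by_day
  dnames <- unique(dd$diet)
  resolve <- function(nm) {
    if (!is.null(diets)) {
      if (!nm %in% names(diets))
        stop(sprintf("unknown diet name '%s'", nm), call. = FALSE)
      as_bee_diet(diets[[nm]])
    } else parse_diet_name(nm)
  }
  dietobjs <- stats::setNames(lapply(dnames, resolve), dnames)

  per_dish <- stats::setNames(numeric(length(dnames)), dnames)
  n_flagged <- 0L
  excluded <- list()
  for (i in seq_len(nrow(dd))) {
    day <- dd$day[i]
    val <- tryCatch(
      daily_per_capita(dd$initial_mass_mg[i], dd$final_mass_mg[i],
                       alive[day], tolerance = tolerance),
      error = function(e) e)
    if (inherits(val, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(cage_id = dd$cage_id[i], day = day, diet = dd$diet[i],
                   reason = conditionMessage(val), stringsAsFactors = FALSE)
      next
    }
    if (isTRUE(attr(val, "flagged"))) n_flagged <- n_flagged + 1L
    per_dish[[dd$diet[i]]] <- per_dish[[dd$diet[i]]] + as.numeric(val)
  }
  pt <- c(0, 0)
  for (nm in dnames) {
    d <- dietobjs[[nm]]
    pt <- pt + per_dish[[nm]] * c(d$protein_frac, d$lipid_frac)
  }
  total_point <- nutrient_point(pt[1], pt[2])
  structure(list(cage_id = cage$cage_id,
                 total_food = sum(per_dish),
                 total_point = total_point,
                 per_dish_totals = per_dish,
                 ratio = if (pt[2] > 0) pt[1] / pt[2] else NA_real_,
                 n_flagged_negative = n_flagged,
                 excluded_records = if (length(excluded))
                   do.call(rbind, excluded) else NULL),
            class = "cage_intake")
}

#' @export
print.cage_intake <- function(x, ...) {
  cat(sprintf("Cage %s: %.2f mg food/bee; P %.2f, L %.2f mg/bee (P:L %s)\n",
              x$cage_id, x$total_food,
              x$total_point$protein_mg, x$total_point$lipid_mg,
              if (is.na(x$ratio)) "NA" else pl_display(x$ratio)))
  if (x$n_flagged_negative > 0)
    cat(sprintf("  %d dish-day record(s) with flagged negative consumption\n",
                x$n_flagged_negative))
  if (!is.null(x$excluded_records))
    cat(sprintf("  %d suspect record(s) excluded\n", nrow(x$excluded_records)))
  invisible(x)
}

#' Self-selected protein:lipid ratio of a cage
#'
#' Total protein eaten divided by total lipid eaten over the whole
#' experiment (not a mean of daily ratios).
#'
#' @param intake A \code{cage_intake} or a \code{nutrient_point}.
#' @return The dimensionless ratio.
#' @export
self_selected_ratio <- function(intake) {
  pt <- if (inherits(intake, "cage_intake")) intake$total_point
        else if (inherits(intake, "nutrient_point")) intake
        else stop("expected a cage_intake or nutrient_point", call. = FALSE)
  if (pt$lipid_mg <= 0)
    stop("undefined ratio: total lipid intake is not positive", call. = FALSE)
  pt$protein_mg / pt$lipid_mg
}

#' Per-cage intake table for an experiment
#'
#' Applies [cage_totals()] to every non-control cage of a simulated (or
#' imported) experiment and returns one row per cage.
#'
#' @param experiment A \code{cage_experiment}.
#' @param tolerance Passed to [cage_totals()].
#' @return Data frame: cage_id, treatment, arm, total_food_mg, protein_mg,
#'   lipid_mg, ratio, plus one per-dish total column per diet involved.
#' @export
experiment_intake_table <- function(experiment, tolerance = 1.0) {
  diets <- experiment$design$diets
  rows <- lapply(experiment$cages, function(rec) {
    if (rec$arm == "control") return(NULL)
    ci <- cage_totals(rec, diets = diets, tolerance = tolerance)
    df <- data.frame(cage_id = rec$cage_id, treatment = rec$treatment,
                     arm = rec$arm, total_food_mg = ci$total_food,
                     protein_mg = ci$total_point$protein_mg,
                     lipid_mg = ci$total_point$lipid_mg,
                     ratio = ci$ratio, stringsAsFactors = FALSE)
    for (nm in names(ci$per_dish_totals))
      df[[paste0("dish_", nm, "_mg")]] <- ci$per_dish_totals[[nm]]
    df
  })
  rows <- Filter(Negate(is.null), rows)
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA_real_
    df[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a per-bee survival table from cage records
#'
#' One row per bee: day of death (1..n_days) with status 1, or n_days with
#' status 0 for bees alive at the end.
#'
#' @param cages List of \code{cage_record}.
#' @return Data frame: cage_id, treatment, arm, time, status.
#' @export
survival_table <- function(cages) {
  rows <- lapply(cages, function(rec) {
    n_days <- rec$config$n_days
    times <- integer(0); status <- integer(0)
    for (d in seq_len(n_days)) {
      k <- rec$deaths_by_day[d]
      if (k > 0) { times <- c(times, rep(d, k)); status <- c(status, rep(1L, k)) }
    }
    n_alive <- rec$alive_by_day[n_days]
    if (n_alive > 0) {
      times <- c(times, rep(n_days, n_alive))
      status <- c(status, rep(0L, n_alive))
    }
    data.frame(cage_id = rec$cage_id,
               treatment = if (!is.null(rec$treatment)) rec$treatment else NA,
               arm = if (!is.null(rec$arm)) rec$arm else NA,
               time = times, status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
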