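#' Classify the rule of compromise behind observed intake points
#'
#' Given observed cumulative protein-lipid intake points on two or more
#' single-diet rails and an intake target, computes the predicted intake
#' point for each diet under each of the five rules of compromise and scores
#' each rule by the summed squared Euclidean distance (mg^2) between observed
#' and predicted points. The best-fitting rule is the residual minimiser;
#' exact ties are broken deterministically in the order strict_restraint,
#' closest_distance, equal_distance, protein_priority, lipid_priority.
#'
#' Diets whose rail passes through the target are uninformative (all rules
#' predict the target point there); at least two informative diets are
#' required.
#'
#' @param observed Observed intake per diet: either a named list of
#'   \code{nutrient_point}s, or a data frame with columns \code{diet},
#'   \code{protein_mg}, \code{lipid_mg} (one row per diet).
#' @param target An \code{intake_target}.
#' @param standardize If \code{TRUE}, distances are computed after dividing
#'   each axis by the standard deviation of the observed coordinates on that
#'   axis (off by default; both axes are already in mg).
#' @return An object of class \code{rule_fit}; see
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{fitted} and \code{plot} methods.
#' @examples
#' it <- intake_target(30, 20)
#' obs <- lapply(study_diets(), function(d)
#'   predict_intake("strict_restraint", d, it)$point)
#' fit <- classify_rule(obs, it)
#' fit$best_rule
#' @export
classify_rule <- function(observed, target, standardize = FALSE) {
  stopifnot(inherits(target, "intake_target"))
  obs <- as_observed_points(observed)
  diets <- lapply(names(obs), as_bee_diet)
  names(diets) <- names(obs)

  # informative = rail does not pass through the target
  informative <- vapply(diets, function(d)
    abs(d$protein_frac * target$point$lipid_mg -
        d$lipid_frac * target$point$protein_mg) > 1e-9, logical(1))
  if (sum(informative) < 2L)
    stop("insufficient data: need >= 2 diets whose rails miss the target",
         call. = FALSE)

  rules <- compromise_rules()
  preds <- lapply(rules, function(r)
    lapply(diets, function(d) predict_intake(r, d, target)))
  names(preds) <- rules

  om <- t(vapply(obs, function(pt) c(pt$protein_mg, pt$lipid_mg), numeric(2)))
  w <- c(1, 1)
  if (standardize) {
    w <- 1 / apply(om, 2, stats::sd)
    w[!is.finite(w)] <- 1
  }
  resid_by_rule <- vapply(rules, function(r) {
    pm <- t(vapply(preds[[r]], function(pr)
      c(pr$point$protein_mg, pr$point$lipid_mg), numeric(2)))
    sum(((om - pm) %*% diag(w))^2)
  }, numeric(1))

  best <- rules[which.min(resid_by_rule)]  # which.min honours rule order on ties

  structure(list(best_rule = best,
                 residuals = resid_by_rule,
                 n_diets = length(obs),
                 informative = informative,
                 observed = obs,
                 predictions = preds,
                 target = target,
                 diets = diets,
                 standardize = standardize),
            class = "rule_fit")
}

as_observed_points <- function(observed) {
  if (is.data.frame(observed)) {
    need <- c("diet", "protein_mg", "lipid_mg")
    if (!all(need %in% names(observed)))
      stop("observed data frame needs columns diet, protein_mg, lipid_mg",
           call. = FALSE)
    obs <- lapply(seq_len(nrow(observed)), function(i)
      nutrient_point(observed$protein_mg[i], observed$lipid_mg[i]))
    names(obs) <- as.character(observed$diet)
  } else if (is.list(observed)) {
    if (is.null(names(observed)))
      stop("observed list must be named by diet", call. = FALSE)
    obs <- lapply(observed, function(x) {
      if (inherits(x, "nutrient_point")) x else nutrient_point(x[1], x[2])
    })
  } else stop("observed must be a named list or a data frame", call. = FALSE)
  if (length(obs) < 2L)
    stop("insufficient data: need >= 2 observed diets", call. = FALSE)
  obs
}

#' @export
print.rule_fit <- function(x, ...) {
  cat("Rule-of-compromise classification\n")
  cat(sprintf("  %d diets (%d informative); target P:L %s\n",
              x$n_diets, sum(x$informative), pl_display(x$target$ratio)))
  cat(sprintf("  best rule: %s (RSS %.4g mg^2)\n",
              x$best_rule, x$residuals[[x$best_rule]]))
  invisible(x)
}

#' @export
summary.rule_fit <- function(object, ...) {
  res <- sort(object$residuals)
  tab <- data.frame(rule = names(res), rss_mg2 = as.numeric(res),
                    row.names = NULL)
  structure(list(fit = object, table = tab), class = "summary.rule_fit")
}

#' @export
print.summary.rule_fit <- function(x, ...) {
  print(x$fit)
  cat("\nResidual sum of squares by rule (mg^2):\n")
  print(x$table, row.names = FALSE)
  dev <- t(vapply(names(x$fit$observed), function(nm)
    deviation_from_target(x$fit$observed[[nm]], x$fit$target), numeric(2)))
  cat("\nObserved deviation from intake target (mg; + over, - under):\n")
  print(round(dev, 3))
  invisible(x)
}

#' @export
coef.rule_fit <- function(object, ...) {
  vapply(object$predictions[[object$best_rule]], `[[`, numeric(1), "amount")
}

#' @export
fitted.rule_fit <- function(object, ...) {
  pts <- object$predictions[[object$best_rule]]
  t(vapply(pts, function(pr) c(protein_mg = pr$point$protein_mg,
                               lipid_mg = pr$point$lipid_mg), numeric(2)))
}

#' @export
residuals.rule_fit <- function(object, ...) {
  om <- t(vapply(object$observed, function(pt)
    c(protein_mg = pt$protein_mg, lipid_mg = pt$lipid_mg), numeric(2)))
  om - fitted(object)
}

#' Predict intake points under a fitted rule for new diets
#'
#' @param object A \code{rule_fit}.
#' @param newdiets Diets to predict for: list of \code{bee_diet} or canonical
#'   names; defaults to the fitted diets.
#' @param rule Rule to use; defaults to the best-fitting rule.
#' @param ... Unused.
#' @return Data frame with diet, amount eaten (mg/bee) and the predicted
#'   protein and lipid coordinates.
#' @export
predict.rule_fit <- function(object, newdiets = NULL, rule = NULL, ...) {
  if (is.null(rule)) rule <- object$best_rule
  if (is.null(newdiets)) newdiets <- object$diets
  newdiets <- lapply(newdiets, as_bee_diet)
  out <- do.call(rbind, lapply(newdiets, function(d) {
    pr <- predict_intake(rule, d, object$target)
    data.frame(diet = d$name, rule = rule, amount_mg = pr$amount,
               protein_mg = pr$point$protein_mg, lipid_mg = pr$point$lipid_mg)
  }))
  rownames(out) <- NULL
  out
}

#' Plot observed and predicted intakes in protein-lipid space
#'
#' Draws the food rails, the intake target, the observed intake points and
#' the best-fitting rule's predictions, in the style of a nutritional-
#' geometry intake plot.
#'
#' @param x A \code{rule_fit}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.rule_fit <- function(x, ...) {
  om <- t(vapply(x$observed, function(pt)
    c(pt$protein_mg, pt$lipid_mg), numeric(2)))
  pm <- fitted(x)
  PT <- x$target$point$protein_mg; LT <- x$target$point$lipid_mg
  xmax <- max(om[, 1], pm[, 1], PT) * 1.15
  ymax <- max(om[, 2], pm[, 2], LT) * 1.15
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "Protein eaten (mg/bee)", ylab = "Lipid eaten (mg/bee)",
                 main = sprintf("Rule of compromise: %s", x$best_rule), ...)
  for (d in x$diets) {
    a <- xmax / d$protein_frac
    graphics::segments(0, 0, a * d$protein_frac, a * d$lipid_frac,
                       lty = 3, col = "grey50")
  }
  graphics::points(om[, 1], om[, 2], pch = 19, col = "black")
  graphics::points(pm[, 1], pm[, 2], pch = 1, col = "red", cex = 1.4)
  graphics::points(PT, LT, pch = 17, col = "blue", cex = 1.4)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", sprintf("predicted (%s)", x$best_rule),
                              "intake target", "food rails"),
                   pch = c(19, 1, 17, NA), lty = c(NA, NA, NA, 3),
                   col = c("black", "red", "blue", "grey50"))
  invisible(x)
}
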