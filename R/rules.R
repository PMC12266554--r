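#' The five rules of compromise
#'
#' Order is the deterministic tie-break order used by [classify_rule()].
#'
#' @return Character vector of rule names.
#' @export
compromise_rules <- function() {
  c("strict_restraint", "closest_distance", "equal_distance",
    "protein_priority", "lipid_priority")
}

#' Construct a protein-lipid intake target
#'
#' The intake target (IT) is the combination and amount of protein and lipid
#' a bee regulates toward when unconstrained, expressed per bee over the
#' whole experiment horizon.
#'
#' @param protein_mg Target protein intake, mg per bee (> 0).
#' @param lipid_mg Target lipid intake, mg per bee (> 0).
#' @param source Label recording which dataset or procedure inferred it.
#' @return An \code{intake_target} with fields \code{point}, \code{ratio},
#'   \code{source}.
#' @export
intake_target <- function(protein_mg, lipid_mg, source = "assumed") {
  if (!is.finite(protein_mg) || !is.finite(lipid_mg) ||
      protein_mg <= 0 || lipid_mg <= 0)
    stop("intake target coordinates must be strictly positive", call. = FALSE)
  structure(list(point = nutrient_point(protein_mg, lipid_mg),
                 ratio = protein_mg / lipid_mg,
                 source = source),
            class = "intake_target")
}

#' @export
print.intake_target <- function(x, ...) {
  cat(sprintf("Intake target: P = %.2f mg, L = %.2f mg per bee (P:L %s; source: %s)\n",
              x$point$protein_mg, x$point$lipid_mg,
              pl_display(x$ratio), x$source))
  invisible(x)
}

#' Predicted intake point on a single food rail under a rule of compromise
#'
#' On a single imbalanced diet the intake target is usually unreachable; the
#' amount eaten, \code{a}, is set by the rule of compromise. With rail
#' fractions (p, l) and target (P_T, L_T):
#' \describe{
#'   \item{protein_priority}{eat until protein is met: a = P_T / p.}
#'   \item{lipid_priority}{eat until lipid is met: a = L_T / l.}
#'   \item{closest_distance}{orthogonal projection of the target onto the
#'     rail: a = (P_T p + L_T l) / (p^2 + l^2), minimising Euclidean distance
#'     to the target.}
#'   \item{equal_distance}{a = (P_T + L_T) / (p + l); the nutrient in excess
#'     is overeaten by exactly the amount the other is undereaten.}
#'   \item{strict_restraint}{feeding stops as soon as either threshold is
#'     reached: a = min(P_T / p, L_T / l); neither nutrient is ever
#'     overconsumed.}
#' }
#' When the rail passes through the target, all five rules return the target
#' point itself.
#'
#' @param rule One of [compromise_rules()].
#' @param diet A \code{bee_diet} (or canonical name).
#' @param target An \code{intake_target}.
#' @return A \code{rule_prediction}: rule, diet, amount (mg food per bee)
#'   and the resulting \code{nutrient_point}.
#' @examples
#' it <- intake_target(30, 20)
#' predict_intake("strict_restraint", "P20:L30", it)
#' @export
predict_intake <- function(rule, diet, target) {
  rule <- match.arg(rule, compromise_rules())
  diet <- as_bee_diet(diet)
  stopifnot(inherits(target, "intake_target"))
  p <- diet$protein_frac; l <- diet$lipid_frac
  PT <- target$point$protein_mg; LT <- target$point$lipid_mg
  if (p <= 0 || l <= 0)
    stop("degenerate rail: diet must contain both protein and lipid",
         call. = FALSE)
  a <- switch(rule,
    protein_priority = PT / p,
    lipid_priority   = LT / l,
    closest_distance = (PT * p + LT * l) / (p^2 + l^2),
    equal_distance   = (PT + LT) / (p + l),
    strict_restraint = min(PT / p, LT / l))
  flag <- NULL
  if (rule == "equal_distance" && a <= 0) {
    # unreachable trade-off geometry: fall back to the distance minimiser
    a <- (PT * p + LT * l) / (p^2 + l^2)
    flag <- "equal_distance_fallback_closest"
  }
  structure(list(rule = rule, diet = diet, amount = a,
                 point = rail_point(diet, a), flag = flag),
            class = "rule_prediction")
}

#' @export
print.rule_prediction <- function(x, ...) {
  cat(sprintf("%s on %s: eat %.2f mg/bee -> (P %.2f, L %.2f) mg/bee\n",
              x$rule, x$diet$name, x$amount,
              x$point$protein_mg, x$point$lipid_mg))
  invisible(x)
}

#' Infer the intake target from no-choice consumption summaries
#'
#' The target is taken as the intake point of the no-choice diet eaten in
#' the greatest per-capita amount: unconstrained on its own best rail, the
#' colony's demand is revealed by maximal consumption. An exact tie in
#' consumption is broken in favour of the diet whose P:L ratio is nearest
#' 1 on the log scale (symmetric in the two nutrients); the tie is recorded
#' in the returned target's \code{source}.
#'
#' @param no_choice_summary Named numeric vector: mean total per-capita food
#'   eaten (mg per bee) per diet, names parseable by [parse_diet_name()]
#'   (or a named list of \code{bee_diet} supplied via \code{diets}).
#' @param diets Optional named list of \code{bee_diet} objects to resolve
#'   the summary names against; defaults to parsing names.
#' @return An \code{intake_target}.
#' @examples
#' infer_intake_target(c("P20:L30" = 60, "P30:L20" = 100, "P35:L15" = 80))
#' @export
infer_intake_target <- function(no_choice_summary, diets = NULL) {
  if (length(no_choice_summary) == 0L)
    stop("empty no-choice summary", call. = FALSE)
  if (is.null(names(no_choice_summary)) || any(names(no_choice_summary) == ""))
    stop("no-choice summary must be named by diet", call. = FALSE)
  vals <- as.numeric(no_choice_summary)
  if (sum(vals > 0) < 2L)
    stop("need at least two diets with positive consumption", call. = FALSE)
  resolve <- function(nm) {
    if (!is.null(diets) && nm %in% names(diets)) as_bee_diet(diets[[nm]])
    else parse_diet_name(nm)
  }
  best <- max(vals)
  idx <- which(vals == best)
  tie <- length(idx) > 1L
  if (tie) {
    dd <- vapply(names(no_choice_summary)[idx], function(nm)
      abs(log(pl_ratio(resolve(nm)))), numeric(1))
    idx <- idx[which.min(dd)]
  } else idx <- idx[1]
  nm <- names(no_choice_summary)[idx]
  d <- resolve(nm)
  pt <- rail_point(d, vals[idx])
  src <- sprintf("no-choice argmax consumption (%s, %.2f mg/bee)%s",
                 nm, vals[idx],
                 if (tie) "; tie broken by P:L ratio nearest 1 (log scale)" else "")
  intake_target(pt$protein_mg, pt$lipid_mg, source = src)
}

#' Deviation of an intake point from the target
#'
#' Positive components are overconsumption, negative are underconsumption,
#' relative to the intake target.
#'
#' @param point A \code{nutrient_point}.
#' @param target An \code{intake_target}.
#' @return Named numeric vector \code{c(delta_protein, delta_lipid)} in mg.
#' @export
deviation_from_target <- function(point, target) {
  stopifnot(inherits(point, "nutrient_point"), inherits(target, "intake_target"))
  c(delta_protein = point$protein_mg - target$point$protein_mg,
    delta_lipid = point$lipid_mg - target$point$lipid_mg)
}
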