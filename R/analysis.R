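#' Analyse the no-choice arm of an experiment
#'
#' Computes per-cage intake totals, the consumption / protein / lipid
#' one-way ANOVAs with Tukey letters, the intake-target inference, the
#' rule-of-compromise classification of the treatment-mean intake points,
#' the HPG ANOVA (on log-transformed diameters, control included) and the
#' HPG-on-intake treatment-mean regressions, the body-lipid ANOVA, and the
#' Cox frailty survival comparison across diets.
#'
#' @param experiment A \code{cage_experiment}.
#' @return A \code{no_choice_report} list.
#' @export
analyze_no_choice <- function(experiment) {
  stopifnot(inherits(experiment, "cage_experiment"))
  it <- experiment_intake_table(experiment)
  nc <- it[it$arm == "no_choice", ]
  if (nrow(nc) == 0L) stop("experiment has no no-choice cages", call. = FALSE)

  consumption_anova <- anova_tukey(nc$total_food_mg, nc$treatment)
  protein_anova <- anova_tukey(nc$protein_mg, nc$treatment)
  lipid_anova <- anova_tukey(nc$lipid_mg, nc$treatment)

  means <- tapply(nc$total_food_mg, nc$treatment, mean)
  target <- infer_intake_target(stats::setNames(as.numeric(means), names(means)),
                                diets = experiment$design$diets)

  obs_pts <- lapply(split(nc, nc$treatment), function(g)
    nutrient_point(mean(g$protein_mg), mean(g$lipid_mg)))
  rulefit <- classify_rule(obs_pts, target)

  # endpoint tables: one sampled bee per no-choice cage (controls included)
  hpg <- NULL; lipid_content <- NULL; hpg_reg <- NULL
  if (length(experiment$bees)) {
    bt <- do.call(rbind, lapply(experiment$bees, function(b) {
      rec <- experiment$cages[[b$cage_id]]
      data.frame(cage_id = b$cage_id, treatment = rec$treatment,
                 hpg_um = mean(b$hpg_acinus_diameters),
                 body_lipid_mg = b$body_lipid_mg, stringsAsFactors = FALSE)
    }))
    rownames(bt) <- NULL
    hpg <- anova_tukey(log(bt$hpg_um), bt$treatment)
    lipid_content <- anova_tukey(bt$body_lipid_mg, bt$treatment)

    tm <- do.call(rbind, lapply(split(nc, nc$treatment), function(g)
      data.frame(diet = g$treatment[1], protein_mg = mean(g$protein_mg),
                 lipid_mg = mean(g$lipid_mg), stringsAsFactors = FALSE)))
    tm$hpg_um <- vapply(tm$diet, function(d)
      mean(bt$hpg_um[bt$treatment == d]), numeric(1))
    rownames(tm) <- NULL
    hpg_reg <- hpg_intake_regression(tm)
    hpg_reg$treatment_means <- tm
  }

  surv <- survival_table(experiment$cages)
  surv_nc <- surv[surv$arm %in% c("no_choice", "control"), ]
  survival_test <- tryCatch(cox_survival_compare(surv_nc),
                            error = function(e) list(error = conditionMessage(e)))

  structure(list(intake_table = nc,
                 consumption_anova = consumption_anova,
                 protein_anova = protein_anova,
                 lipid_anova = lipid_anova,
                 no_choice_means = stats::setNames(as.numeric(means), names(means)),
                 target = target,
                 rule_fit = rulefit,
                 hpg_anova = hpg,
                 hpg_regression = hpg_reg,
                 lipid_content_anova = lipid_content,
                 survival = survival_test,
                 bee_table = if (length(experiment$bees)) bt else NULL),
            class = "no_choice_report")
}

#' @export
print.no_choice_report <- function(x, ...) {
  cat("== No-choice NGF analysis ==\n")
  cat(sprintf("Total consumption ANOVA: F_%d,%d = %.2f, p = %.3g\n",
              x$consumption_anova$anova$df1, x$consumption_anova$anova$df2,
              x$consumption_anova$anova$F, x$consumption_anova$anova$p))
  print(x$target)
  print(x$rule_fit)
  if (!is.null(x$hpg_regression))
    cat(sprintf("HPG ~ protein: R2 = %.3f (p = %.3g); HPG ~ lipid: R2 = %.3f (p = %.3g)\n",
                x$hpg_regression$protein$r_squared, x$hpg_regression$protein$p,
                x$hpg_regression$lipid$r_squared, x$hpg_regression$lipid$p))
  if (is.null(x$survival$error))
    cat(sprintf("Survival (Cox frailty LRT): chi2_%d = %.2f, p = %.3f\n",
                x$survival$df, x$survival$chisq, x$survival$p))
  invisible(x)
}

#' Full choice-regulation analysis
#'
#' The inferential core of the choice experiment:
#' \enumerate{
#'   \item dish-preference tests: per food pairing, the per-cage difference
#'     between the two dish totals (protein-rich minus lipid-rich) is tested
#'     against 0 (one-sample t, Bonferroni family m = 3);
#'   \item theoretical-vs-experimental consumption: per diet within each
#'     pairing, Welch t between the experimental per-dish totals and the
#'     halved no-choice cage totals (Bonferroni family m = 6);
#'   \item P:L ratios vs the intake target: the experimental per-cage ratios
#'     and the theoretical ratios (from pairwise-matched halved no-choice
#'     cage totals) are each tested against the target ratio (one-sample t,
#'     Bonferroni family m = 6);
#'   \item self-selected ratio ANOVA across pairings, mixed ANOVA of
#'     consumption (between = pairing, within = dish role, random = cage),
#'     and MANOVA of the per-cage (protein, lipid) totals.
#' }
#'
#' @param experiment A \code{cage_experiment} containing both arms.
#' @param target Intake target; defaults to inferring it from the no-choice
#'   arm via [infer_intake_target()].
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param m_preference,m_theoretical Bonferroni family sizes (defaults 3
#'   and 6: one preference test per pairing; two diets in each of three
#'   pairings).
#' @return A \code{choice_regulation_report}.
#' @export
run_choice_regulation_analysis <- function(experiment, target = NULL,
                                           family_alpha = 0.05,
                                           m_preference = 3L,
                                           m_theoretical = 6L) {
  stopifnot(inherits(experiment, "cage_experiment"))
  it <- experiment_intake_table(experiment)
  nc <- it[it$arm == "no_choice", ]
  ch <- it[it$arm == "choice", ]
  if (nrow(nc) == 0L || nrow(ch) == 0L)
    stop("experiment must contain both no-choice and choice cages", call. = FALSE)

  pairings <- experiment$design$pairings
  for (fpt in unique(ch$treatment))
    if (!fpt %in% names(pairings))
      stop(sprintf("config error: choice treatment '%s' not in design pairings", fpt),
           call. = FALSE)
  used <- unique(unlist(pairings))
  if (!all(used %in% nc$treatment))
    stop("config error: paired diets missing from the no-choice arm", call. = FALSE)

  nc_means <- tapply(nc$total_food_mg, nc$treatment, mean)
  nc_means <- stats::setNames(as.numeric(nc_means), names(nc_means))
  if (is.null(target))
    target <- infer_intake_target(nc_means, diets = experiment$design$diets)

  theo <- theoretical_choice_dataset(nc_means, pairings,
                                     diets = experiment$design$diets)

  dish_col <- function(nm) paste0("dish_", nm, "_mg")
  nc_totals <- function(nm) nc$total_food_mg[nc$treatment == nm]

  # dish role: the more protein-rich diet of the pairing is "protein-rich"
  roles <- lapply(pairings, function(pair) {
    r <- vapply(pair, function(nm)
      pl_ratio(as_bee_diet(experiment$design$diets[[nm]])), numeric(1))
    list(protein_rich = pair[which.max(r)], lipid_rich = pair[which.min(r)])
  })

  # 1. dish preference
  pref_samples <- lapply(names(pairings), function(fpt) {
    g <- ch[ch$treatment == fpt, ]
    g[[dish_col(roles[[fpt]]$protein_rich)]] -
      g[[dish_col(roles[[fpt]]$lipid_rich)]]
  })
  names(pref_samples) <- sprintf("%s: %s - %s", names(pairings),
                                 vapply(roles, `[[`, character(1), "protein_rich"),
                                 vapply(roles, `[[`, character(1), "lipid_rich"))
  preference <- bonferroni_t_tests(pref_samples, null_value = 0,
                                   family_alpha = family_alpha,
                                   m = m_preference)

  # 2. theoretical vs experimental per-dish consumption (Welch)
  tve <- do.call(rbind, lapply(names(pairings), function(fpt) {
    g <- ch[ch$treatment == fpt, ]
    do.call(rbind, lapply(pairings[[fpt]], function(nm)
      bonferroni_welch_test(g[[dish_col(nm)]], nc_totals(nm) / 2,
                            family_alpha = family_alpha, m = m_theoretical,
                            label = sprintf("%s: %s exp vs theo", fpt, nm))))
  }))

  # 3. ratios vs the target ratio
  exp_ratio_samples <- lapply(names(pairings), function(fpt)
    ch$ratio[ch$treatment == fpt])
  names(exp_ratio_samples) <- sprintf("%s experimental ratio", names(pairings))
  theo_ratio_samples <- lapply(names(pairings), function(fpt) {
    pair <- pairings[[fpt]]
    a <- nc[nc$treatment == pair[1], c("protein_mg", "lipid_mg")] / 2
    b <- nc[nc$treatment == pair[2], c("protein_mg", "lipid_mg")] / 2
    n <- min(nrow(a), nrow(b))
    (a$protein_mg[seq_len(n)] + b$protein_mg[seq_len(n)]) /
      (a$lipid_mg[seq_len(n)] + b$lipid_mg[seq_len(n)])
  })
  names(theo_ratio_samples) <- sprintf("%s theoretical ratio", names(pairings))
  ratio_tests <- bonferroni_t_tests(c(theo_ratio_samples, exp_ratio_samples),
                                    null_value = target$ratio,
                                    family_alpha = family_alpha,
                                    m = m_theoretical)

  # 4. designed-experiment summaries
  ratio_anova <- anova_tukey(ch$ratio, ch$treatment)

  long <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    fpt <- ch$treatment[i]
    do.call(rbind, lapply(c("protein_rich", "lipid_rich"), function(role)
      data.frame(cage_id = ch$cage_id[i], fpt = fpt, role = role,
                 consumption = ch[[dish_col(roles[[fpt]][[role]])]][i],
                 stringsAsFactors = FALSE)))
  }))
  long$fpt <- factor(long$fpt); long$role <- factor(long$role)
  mix <- stats::aov(consumption ~ fpt * role + Error(cage_id), data = long)
  mix_sum <- summary(mix)
  mixed_anova <- list(model = mix, summary = mix_sum)

  man <- stats::manova(cbind(protein_mg, lipid_mg) ~ treatment,
                       data = ch)
  # noise-free data leave rank-deficient residuals; the multivariate test is
  # then undefined and reported as such
  manova_res <- list(model = man,
                     multivariate = tryCatch(summary(man, test = "Pillai"),
                                             error = function(e)
                                               list(degenerate = conditionMessage(e))),
                     univariate = tryCatch(stats::summary.aov(man),
                                           error = function(e)
                                             list(degenerate = conditionMessage(e))))

  structure(list(target = target,
                 no_choice_means = nc_means,
                 theoretical = theo,
                 preference = preference,
                 theoretical_vs_experimental = tve,
                 ratio_tests = ratio_tests,
                 ratio_anova = ratio_anova,
                 mixed_anova = mixed_anova,
                 manova = manova_res,
                 intake_table = ch,
                 experimental_ratio_means = vapply(
                   split(ch$ratio, ch$treatment), mean, numeric(1)),
                 family_alpha = family_alpha),
            class = "choice_regulation_report")
}

#' @export
print.choice_regulation_report <- function(x, ...) {
  cat("== Choice regulation analysis ==\n")
  print(x$target)
  cat(sprintf("Experimental self-selected P:L ratios (cage means): %s\n",
              paste(sprintf("%s = %.2f", names(x$experimental_ratio_means),
                            x$experimental_ratio_means), collapse = ", ")))
  cat(sprintf("\nDish-preference tests (Bonferroni adjusted alpha = %.4f):\n",
              x$preference$adjusted_alpha[1]))
  print(x$preference[, c("label", "statistic", "df", "raw_p", "significant")],
        row.names = FALSE, digits = 4)
  cat(sprintf("\nTheoretical vs experimental consumption (adjusted alpha = %.4f):\n",
              x$theoretical_vs_experimental$adjusted_alpha[1]))
  print(x$theoretical_vs_experimental[, c("label", "statistic", "df", "raw_p",
                                          "significant")],
        row.names = FALSE, digits = 4)
  cat(sprintf("\nP:L ratios vs target %.2f (adjusted alpha = %.4f):\n",
              x$target$ratio, x$ratio_tests$adjusted_alpha[1]))
  print(x$ratio_tests[, c("label", "mean", "statistic", "df", "raw_p",
                          "significant")],
        row.names = FALSE, digits = 4)
  cat(sprintf("\nSelf-selected ratio ANOVA: F_%d,%d = %.2f, p = %.3g\n",
              x$ratio_anova$anova$df1, x$ratio_anova$anova$df2,
              x$ratio_anova$anova$F, x$ratio_anova$anova$p))
  invisible(x)
}

#' Write a choice-regulation report as JSON
#'
#' Presentation rounding only: ratios to 2 decimals, alphas to 4.
#'
#' @param report A \code{choice_regulation_report}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "choice_regulation_report"))
  df2list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  out <- list(
    target = list(protein_mg = report$target$point$protein_mg,
                  lipid_mg = report$target$point$lipid_mg,
                  ratio = round(report$target$ratio, 2),
                  source = report$target$source),
    no_choice_means_mg = as.list(report$no_choice_means),
    experimental_ratio_means = lapply(report$experimental_ratio_means,
                                      function(v) round(v, 2)),
    theoretical = lapply(report$theoretical$pairings, function(p)
      list(diets = p$diets, theoretical_mg = as.list(p$theoretical_mg),
           ratio = if (is.na(p$ratio)) NULL else round(p$ratio, 2))),
    preference_tests = df2list(report$preference),
    theoretical_vs_experimental = df2list(report$theoretical_vs_experimental),
    ratio_tests = df2list(report$ratio_tests),
    ratio_anova = report$ratio_anova$anova,
    family_alpha = round(report$family_alpha, 4),
    adjusted_alpha = round(report$ratio_tests$adjusted_alpha[1], 4))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
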