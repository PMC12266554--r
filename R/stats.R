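#' Theoretical (no-regulation) choice consumption table
#'
#' In the absence of protein-lipid regulation, each dish in a choice cage
#' would be eaten at the rate observed when that diet was the only food
#' available, split evenly across the dishes on offer: theoretical per-dish
#' consumption = no-choice mean / number of dishes. The implied theoretical
#' intake point is the sum of the per-dish rail points, and the theoretical
#' P:L ratio follows from that point.
#'
#' @param no_choice_means Named numeric vector: mean total per-capita
#'   consumption (mg per bee) per diet from the no-choice experiment.
#' @param pairings Named list of length-2 character vectors of diet names
#'   (default [food_pairings()]).
#' @param n_dishes Dishes per choice cage (default 2).
#' @param diets Optional named list of \code{bee_diet} to resolve names.
#' @return A \code{theoretical_choice_table}: per pairing, the per-diet
#'   theoretical consumption, the theoretical \code{nutrient_point} and P:L
#'   ratio (NA and flagged when degenerate).
#' @examples
#' theoretical_choice_dataset(c("P20:L30" = 60, "P30:L20" = 90),
#'                            pairings = list(FPT1 = c("P20:L30", "P30:L20")))
#' @export
theoretical_choice_dataset <- function(no_choice_means,
                                       pairings = food_pairings(),
                                       n_dishes = 2L, diets = NULL) {
  resolve <- function(nm) {
    if (!is.null(diets) && nm %in% names(diets)) as_bee_diet(diets[[nm]])
    else parse_diet_name(nm)
  }
  out <- lapply(pairings, function(pair) {
    if (!all(pair %in% names(no_choice_means)))
      stop(sprintf("no-choice mean missing for diet(s): %s",
                   paste(setdiff(pair, names(no_choice_means)), collapse = ", ")),
           call. = FALSE)
    theo <- as.numeric(no_choice_means[pair]) / n_dishes
    pt <- c(0, 0)
    for (k in seq_along(pair)) {
      d <- resolve(pair[k])
      pt <- pt + theo[k] * c(d$protein_frac, d$lipid_frac)
    }
    degenerate <- pt[2] <= 0
    list(diets = pair,
         theoretical_mg = stats::setNames(theo, pair),
         point = nutrient_point(pt[1], pt[2]),
         ratio = if (degenerate) NA_real_ else pt[1] / pt[2],
         flag = if (degenerate) "undefined_ratio" else NULL)
  })
  structure(list(pairings = out, n_dishes = n_dishes),
            class = "theoretical_choice_table")
}

#' @export
print.theoretical_choice_table <- function(x, ...) {
  cat(sprintf("Theoretical (no-regulation) choice consumption, %d dishes per cage:\n",
              x$n_dishes))
  for (nm in names(x$pairings)) {
    p <- x$pairings[[nm]]
    cat(sprintf("  %s: %s; point (P %.2f, L %.2f), P:L %s\n", nm,
                paste(sprintf("%s = %.2f mg", names(p$theoretical_mg),
                              p$theoretical_mg), collapse = ", "),
                p$point$protein_mg, p$point$lipid_mg,
                if (is.na(p$ratio)) "NA" else sprintf("%.3f", p$ratio)))
  }
  invisible(x)
}

#' One-sample t-tests with Bonferroni family control
#'
#' Each sample is tested (two-sided) against the common null value. The
#' family-wise threshold is family_alpha / m and each raw p-value is
#' Bonferroni-adjusted to min(1, p * m). A zero-variance sample whose mean
#' equals the null is a defined degenerate case (statistic 0, p 1), not an
#' error.
#'
#' @param samples Named list of numeric vectors (each n >= 2).
#' @param null_value Null mean.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons in the family; must be at least the number
#'   of tests (default: the number of samples).
#' @return Data frame, one row per sample: label, n, mean, statistic, df,
#'   raw_p, adjusted_p, adjusted_alpha, m, significant.
#' @examples
#' bonferroni_t_tests(list(a = c(1, 2, 3)), null_value = 0, m = 6)
#' @export
bonferroni_t_tests <- function(samples, null_value = 0,
                               family_alpha = 0.05, m = length(samples)) {
  if (!is.list(samples)) samples <- list(sample = samples)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  if (m < length(samples))
    stop("m must be at least the number of tests", call. = FALSE)
  rows <- lapply(names(samples), function(nm) {
    x <- samples[[nm]]
    if (length(x) < 2L)
      stop(sprintf("insufficient data in sample '%s' (n < 2)", nm),
           call. = FALSE)
    if (stats::sd(x) == 0) {
      if (abs(mean(x) - null_value) < .Machine$double.eps^0.5) {
        stat <- 0; p <- 1
      } else { stat <- sign(mean(x) - null_value) * Inf; p <- 0 }
      df <- length(x) - 1
    } else {
      tt <- stats::t.test(x, mu = null_value)
      stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(label = nm, n = length(x), mean = mean(x),
               statistic = stat, df = df, raw_p = p,
               adjusted_p = min(1, p * m),
               adjusted_alpha = family_alpha / m, m = m,
               significant = p < family_alpha / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test within a Bonferroni family
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param family_alpha Family-wise error rate.
#' @param m Comparisons in the family.
#' @param label Test label.
#' @return One-row data frame in the same layout as [bonferroni_t_tests()].
#' @export
bonferroni_welch_test <- function(x, y, family_alpha = 0.05, m = 1L,
                                  label = "welch") {
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient data: both samples need n >= 2", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    df <- length(x) + length(y) - 2
    p <- if (stat == 0) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  data.frame(label = label, n = length(x) + length(y),
             mean = mean(x) - mean(y), statistic = stat, df = df,
             raw_p = p, adjusted_p = min(1, p * m),
             adjusted_alpha = family_alpha / m, m = m,
             significant = p < family_alpha / m, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fits a one-way ANOVA, runs Tukey HSD pairwise comparisons, and derives a
#' compact letter display (groups sharing a letter do not differ at
#' \code{alpha}) by the insert-and-absorb algorithm on the Tukey-adjusted
#' p-values. The all-identical degenerate case (zero between- and
#' within-group variance) is reported as F = 0, p = 1.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels, each n >= 2).
#' @param alpha Significance level for the letters.
#' @return An \code{anova_tukey} list: \code{anova} (F, df1, df2, p),
#'   \code{tukey} (pairwise table), \code{letters} (named character),
#'   \code{means}.
#' @examples
#' anova_tukey(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("insufficient data: every group needs n >= 2", call. = FALSE)
  df <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = df)
  at <- stats::anova(fit)
  Fv <- at$`F value`[1]; p <- at$`Pr(>F)`[1]
  # scale-aware zero-variance detection (aov can return tiny non-zero SS
  # for exactly constant data)
  eps <- 1e-10 * (1 + mean(values)^2)
  ss_between <- at$`Sum Sq`[1]; ss_within <- at$`Sum Sq`[2]
  if (ss_within < eps) {
    # zero residual variance: defined degenerate cases
    if (ss_between < eps) { Fv <- 0; p <- 1 } else { Fv <- Inf; p <- 0 }
  }
  means <- tapply(df$y, df$g, mean)
  if (is.finite(Fv) && ss_within > eps) {
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
    pmat <- matrix(1, nlevels(groups), nlevels(groups),
                   dimnames = list(levels(groups), levels(groups)))
    for (i in seq_len(nrow(tukey))) {
      ab <- strsplit(tukey$comparison[i], "-", fixed = TRUE)[[1]]
      pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tukey$p_adj[i]
    }
    letters <- cld_letters(pmat, means, alpha = alpha)
  } else {
    tukey <- NULL
    letters <- if (is.infinite(Fv)) {
      # zero within-group variance: groups separate exactly by their means
      stats::setNames(letters[match(means, sort(unique(means),
                                                decreasing = TRUE))],
                      names(means))
    } else stats::setNames(rep("a", nlevels(groups)), levels(groups))
  }
  structure(list(anova = list(F = Fv, df1 = at$Df[1], df2 = at$Df[2], p = p),
                 tukey = tukey, letters = letters, means = means,
                 alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F_%d,%d = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  tab <- data.frame(group = names(x$means), mean = as.numeric(x$means),
                    letters = x$letters[names(x$means)])
  print(tab, row.names = FALSE)
  invisible(x)
}

# Compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different at alpha according to pmat (pairwise p-values).
cld_letters <- function(pmat, means, alpha = 0.05) {
  gnames <- names(sort(means, decreasing = TRUE))
  cols <- list(stats::setNames(rep(TRUE, length(gnames)), gnames))
  for (i in seq_along(gnames)) {
    for (j in seq_along(gnames)) {
      if (j <= i) next
      a <- gnames[i]; b <- gnames[j]
      if (pmat[a, b] >= alpha) next
      newcols <- list()
      for (col in cols) {
        if (col[a] && col[b]) {
          c1 <- col; c1[a] <- FALSE
          c2 <- col; c2[b] <- FALSE
          newcols <- c(newcols, list(c1, c2))
        } else newcols <- c(newcols, list(col))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
        if (u == v || !keep[u] || !keep[v]) next
        if (all(newcols[[u]] <= newcols[[v]]) &&
            any(newcols[[u]] < newcols[[v]])) keep[u] <- FALSE
        else if (u < v && identical(newcols[[u]], newcols[[v]])) keep[v] <- FALSE
      }
      cols <- newcols[keep]
    }
  }
  lets <- stats::setNames(rep("", length(gnames)), gnames)
  for (k in seq_along(cols)) {
    lab <- letters[(k - 1L) %% 26L + 1L]
    if (k > 26L) lab <- paste0(lab, (k - 1L) %/% 26L)
    for (g in gnames[cols[[k]][gnames]]) lets[g] <- paste0(lets[g], lab)
  }
  lets[order(names(lets))][names(means)]
}

#' Compare survival between treatments with a Cox frailty model
#'
#' Fits a Cox proportional-hazards model with treatment as the fixed effect
#' and a gamma frailty (random effect) on cage, and compares it against the
#' frailty-only null model by likelihood ratio.
#'
#' @param surv_df Data frame with columns \code{time} (day of death or end
#'   of follow-up), \code{status} (1 = died, 0 = censored),
#'   \code{treatment}, \code{cage_id}.
#' @return List: chisq, df, p, n_events, full and null model fits.
#' @export
cox_survival_compare <- function(surv_df) {
  need <- c("time", "status", "treatment", "cage_id")
  if (!all(need %in% names(surv_df)))
    stop("surv_df needs columns time, status, treatment, cage_id", call. = FALSE)
  surv_df$treatment <- factor(surv_df$treatment)
  if (nlevels(surv_df$treatment) < 2L)
    stop("need at least two treatments", call. = FALSE)
  if (sum(surv_df$status) == 0L)
    stop("degenerate model: no death events observed", call. = FALSE)
  full <- survival::coxph(
    survival::Surv(time, status) ~ treatment + survival::frailty(cage_id),
    data = surv_df)
  null <- survival::coxph(
    survival::Surv(time, status) ~ survival::frailty(cage_id),
    data = surv_df)
  # gamma frailty reports the integrated (marginal) likelihood; models with
  # and without the fixed effect are compared on that scale
  iloglik <- function(fit) {
    h <- fit$history[[1]]
    if (!is.null(h$c.loglik)) h$c.loglik else fit$loglik[2]
  }
  chisq <- 2 * (iloglik(full) - iloglik(null))
  df <- nlevels(surv_df$treatment) - 1L
  p <- stats::pchisq(max(chisq, 0), df = df, lower.tail = FALSE)
  list(chisq = unname(chisq), df = df, p = unname(p),
       n_events = sum(surv_df$status), full = full, null = null)
}

#' Regressions of mean HPG acinus size on treatment-mean intakes
#'
#' Ordinary least squares of the treatment-level mean acinus diameter on
#' mean protein intake and, separately, on mean lipid intake.
#'
#' @param treatment_means Data frame with columns \code{diet},
#'   \code{protein_mg}, \code{lipid_mg}, \code{hpg_um} (one row per
#'   treatment; >= 3 rows).
#' @return List with elements \code{protein} and \code{lipid}, each
#'   containing slope, intercept, r_squared and p.
#' @export
hpg_intake_regression <- function(treatment_means) {
  need <- c("protein_mg", "lipid_mg", "hpg_um")
  if (!all(need %in% names(treatment_means)))
    stop("treatment_means needs columns protein_mg, lipid_mg, hpg_um",
         call. = FALSE)
  if (nrow(treatment_means) < 3L)
    stop("insufficient data: need >= 3 treatment means", call. = FALSE)
  one <- function(xname) {
    f <- stats::lm(stats::reformulate(xname, "hpg_um"), data = treatment_means)
    sm <- summary(f)
    r2 <- sm$r.squared
    co <- sm$coefficients
    p <- if (nrow(co) >= 2L) co[2, 4] else NA_real_
    if (!is.finite(r2)) r2 <- 0
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r_squared = r2, p = unname(p))
  }
  list(protein = one("protein_mg"), lipid = one("lipid_mg"))
}
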