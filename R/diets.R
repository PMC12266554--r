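#' Construct an artificial diet
#'
#' An artificial nurse-bee diet is described by the mass fraction (wet weight)
#' of each of its five components: soy protein, linseed oil (lipid), 50% w/v
#' sucrose solution, vitamin mix, and cellulose filler. In protein-lipid
#' nutrient space a fixed-composition diet defines a "food rail": the ray
#' through the origin along which any amount eaten of that diet must lie.
#'
#' The study diets all hold protein + lipid at 50% of wet mass and share the
#' same carbohydrate-vitamin-filler background (39.5% sucrose solution, 0.5%
#' vitamin mix, 10% cellulose); only the protein:lipid split varies.
#'
#' @param protein_frac Protein mass fraction of wet weight, in (0, 1).
#' @param lipid_frac Lipid mass fraction of wet weight, in (0, 1).
#' @param name Diet label. Defaults to the canonical "P{pp}:L{ll}" name built
#'   from the percentages.
#' @param sucrose_solution_frac Mass fraction of 50% w/v sucrose solution.
#' @param vitamin_frac Mass fraction of vitamin mix.
#' @param cellulose_frac Mass fraction of cellulose filler.
#' @return An object of class \code{bee_diet}.
#' @examples
#' d <- bee_diet(0.30, 0.20)
#' pl_ratio(d)
#' @export
bee_diet <- function(protein_frac, lipid_frac, name = NULL,
                     sucrose_solution_frac = 0.395,
                     vitamin_frac = 0.005,
                     cellulose_frac = 0.100) {
  fr <- c(protein = protein_frac, lipid = lipid_frac,
          sucrose_solution = sucrose_solution_frac,
          vitamin = vitamin_frac, cellulose = cellulose_frac)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all diet mass fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop(sprintf("diet mass fractions must sum to 1 (got %.12f)", sum(fr)),
         call. = FALSE)
  if (protein_frac <= 0 || lipid_frac <= 0)
    stop("protein_frac and lipid_frac must be strictly positive", call. = FALSE)
  if (is.null(name))
    name <- sprintf("P%g:L%g", 100 * protein_frac, 100 * lipid_frac)
  structure(list(name = name,
                 protein_frac = protein_frac,
                 lipid_frac = lipid_frac,
                 sucrose_solution_frac = sucrose_solution_frac,
                 vitamin_frac = vitamin_frac,
                 cellulose_frac = cellulose_frac),
            class = "bee_diet")
}

#' @export
print.bee_diet <- function(x, ...) {
  cat(sprintf("Artificial diet %s: %.1f%% protein, %.1f%% lipid (P:L %s);\n",
              x$name, 100 * x$protein_frac, 100 * x$lipid_frac,
              pl_display(pl_ratio(x))))
  cat(sprintf("  background: %.1f%% sucrose solution, %.1f%% vitamin mix, %.1f%% cellulose\n",
              100 * x$sucrose_solution_frac, 100 * x$vitamin_frac,
              100 * x$cellulose_frac))
  invisible(x)
}

#' Parse a canonical diet name
#'
#' Understands labels of the form \code{"P30:L20"} (case-insensitive,
#' whitespace-tolerant) and returns the corresponding study diet with the
#' standard carbohydrate-vitamin-filler background.
#'
#' @param name Character label, e.g. \code{"P30:L20"} or \code{"p 30 : l 20"}.
#' @return A \code{bee_diet}.
#' @export
parse_diet_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- gsub("[[:space:]]", "", toupper(name))
  m <- regmatches(s, regexec("^P([0-9]+\\.?[0-9]*):L([0-9]+\\.?[0-9]*)$", s))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse diet name '%s' (expected 'P<pp>:L<ll>')", name),
         call. = FALSE)
  p <- as.numeric(m[2]) / 100
  l <- as.numeric(m[3]) / 100
  bee_diet(p, l, name = sprintf("P%g:L%g", 100 * p, 100 * l))
}

#' The five study diets
#'
#' The experimental diet series spans protein:lipid ratios from 1:2.3
#' (P15:L35) to 2.3:1 (P35:L15) while holding protein + lipid at 50% of
#' wet mass.
#'
#' @return A named list of \code{bee_diet} objects
#'   (P35:L15, P30:L20, P25:L25, P20:L30, P15:L35).
#' @export
study_diets <- function() {
  nm <- c("P35:L15", "P30:L20", "P25:L25", "P20:L30", "P15:L35")
  stats::setNames(lapply(nm, parse_diet_name), nm)
}

#' The three choice food-pairing treatments
#'
#' Each pairing offers two nutritionally complementary diets whose rails
#' bracket the intake target: FPT1 = P20:L30 with P30:L20,
#' FPT2 = P20:L30 with P35:L15, FPT3 = P25:L25 with P35:L15.
#'
#' @return A named list of length-2 character vectors of diet names.
#' @export
food_pairings <- function() {
  list(FPT1 = c("P20:L30", "P30:L20"),
       FPT2 = c("P20:L30", "P35:L15"),
       FPT3 = c("P25:L25", "P35:L15"))
}

#' Formulate a diet batch from its protein and lipid percentages
#'
#' Applies the study recipe rule: protein + lipid must total 50% of wet mass;
#' the remainder is always 39.5% sucrose solution (50% w/v), 0.5% vitamin mix
#' and 10% cellulose. Component masses scale linearly with batch mass, e.g.
#' 100 g of P30:L20 contains 30 g protein, 20 g lipid, 39.5 g sucrose
#' solution, 0.5 g vitamin mix and 10 g cellulose.
#'
#' @param protein_pct Protein content in percent of wet mass.
#' @param lipid_pct Lipid content in percent of wet mass.
#' @param batch_mass Total batch mass in grams.
#' @return A \code{recipe_batch}: the diet plus a named vector of component
#'   masses (g) summing to \code{batch_mass}.
#' @examples
#' formulate_diet(30, 20, 100)
#' @export
formulate_diet <- function(protein_pct, lipid_pct, batch_mass = 100) {
  if (abs(protein_pct + lipid_pct - 50) > 1e-9)
    stop(sprintf(
      "invalid composition: protein_pct + lipid_pct must equal 50 (got %g)",
      protein_pct + lipid_pct), call. = FALSE)
  if (!is.finite(batch_mass) || batch_mass <= 0)
    stop("batch_mass must be a positive mass in grams", call. = FALSE)
  d <- bee_diet(protein_pct / 100, lipid_pct / 100)
  masses <- c(protein = d$protein_frac,
              lipid = d$lipid_frac,
              sucrose_solution = d$sucrose_solution_frac,
              vitamin = d$vitamin_frac,
              cellulose = d$cellulose_frac) * batch_mass
  structure(list(diet = d, batch_mass = batch_mass, component_masses = masses),
            class = "recipe_batch")
}

#' @export
print.recipe_batch <- function(x, ...) {
  cat(sprintf("Recipe for %g g of diet %s:\n", x$batch_mass, x$diet$name))
  for (nm in names(x$component_masses))
    cat(sprintf("  %-17s %8.3f g\n", nm, x$component_masses[[nm]]))
  invisible(x)
}

#' A point in protein-lipid nutrient space
#'
#' Coordinates are cumulative intake in mg per bee: protein on the first
#' axis, lipid on the second. Small negative coordinates can arise from dish
#' weighing noise at the accounting layer; they are accepted but flagged.
#'
#' @param protein_mg Protein intake, mg per bee.
#' @param lipid_mg Lipid intake, mg per bee.
#' @return A \code{nutrient_point}.
#' @export
nutrient_point <- function(protein_mg, lipid_mg) {
  stopifnot(is.finite(protein_mg), is.finite(lipid_mg))
  structure(list(protein_mg = protein_mg, lipid_mg = lipid_mg,
                 flagged_negative = (protein_mg < 0 || lipid_mg < 0)),
            class = "nutrient_point")
}

#' @export
print.nutrient_point <- function(x, ...) {
  cat(sprintf("(P = %.3f, L = %.3f) mg/bee%s\n", x$protein_mg, x$lipid_mg,
              if (isTRUE(x$flagged_negative)) "  [negative coordinate flagged]" else ""))
  invisible(x)
}

#' Point reached on a diet's food rail after eating a given amount
#'
#' Eating \code{amount_eaten} mg of a fixed-composition diet moves the intake
#' point to (amount x protein fraction, amount x lipid fraction): all
#' reachable points lie on the ray through the origin whose slope is the
#' diet's lipid:protein ratio.
#'
#' @param diet A \code{bee_diet}.
#' @param amount_eaten Food eaten, mg per bee (>= 0).
#' @return A \code{nutrient_point}.
#' @export
rail_point <- function(diet, amount_eaten) {
  stopifnot(inherits(diet, "bee_diet"))
  if (!is.finite(amount_eaten) || amount_eaten < 0)
    stop("amount_eaten must be a non-negative mass in mg", call. = FALSE)
  nutrient_point(amount_eaten * diet$protein_frac,
                 amount_eaten * diet$lipid_frac)
}

#' Protein:lipid ratio of a diet or intake point
#'
#' @param x A \code{bee_diet}, a \code{nutrient_point}, or a numeric
#'   length-2 vector (protein, lipid).
#' @return The dimensionless ratio protein/lipid.
#' @seealso [pl_display()] for the canonical "X:1" / "1:X" display string.
#' @export
pl_ratio <- function(x) UseMethod("pl_ratio")

#' @export
pl_ratio.bee_diet <- function(x) {
  if (x$lipid_frac == 0)
    stop("undefined ratio: lipid fraction is zero", call. = FALSE)
  x$protein_frac / x$lipid_frac
}

#' @export
pl_ratio.nutrient_point <- function(x) {
  if (x$lipid_mg == 0)
    stop("undefined ratio: lipid intake is zero", call. = FALSE)
  x$protein_mg / x$lipid_mg
}

#' @export
pl_ratio.numeric <- function(x) {
  stopifnot(length(x) == 2L)
  if (x[2] == 0) stop("undefined ratio: lipid coordinate is zero", call. = FALSE)
  x[1] / x[2]
}

#' Canonical one-decimal display of a protein:lipid ratio
#'
#' The larger side is scaled to 1 and shown with one decimal place, so
#' 2.333 displays as "2.3:1" and 0.4286 as "1:2.3"; a trailing ".0" is
#' dropped (1.0 displays as "1:1"). Internal values keep full precision;
#' rounding happens only here.
#'
#' @param ratio Dimensionless protein/lipid ratio (> 0).
#' @return A display string.
#' @export
pl_display <- function(ratio) {
  stopifnot(is.finite(ratio), ratio > 0)
  fmt1 <- function(v) sub("\\.0$", "", sprintf("%.1f", v))
  if (ratio >= 1) sprintf("%s:1", fmt1(ratio)) else sprintf("1:%s", fmt1(1 / ratio))
}

#' Read or write diets as CSV
#'
#' One row per diet with columns name, protein_frac, lipid_frac,
#' sucrose_solution_frac, vitamin_frac, cellulose_frac.
#'
#' @param diets A list of \code{bee_diet} objects.
#' @param path File path.
#' @return \code{write_diets_csv} returns \code{path} invisibly;
#'   \code{read_diets_csv} returns a named list of \code{bee_diet} objects.
#' @export
write_diets_csv <- function(diets, path) {
  df <- do.call(rbind, lapply(diets, function(d)
    data.frame(name = d$name, protein_frac = d$protein_frac,
               lipid_frac = d$lipid_frac,
               sucrose_solution_frac = d$sucrose_solution_frac,
               vitamin_frac = d$vitamin_frac,
               cellulose_frac = d$cellulose_frac)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diets_csv
#' @export
read_diets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "protein_frac", "lipid_frac", "sucrose_solution_frac",
            "vitamin_frac", "cellulose_frac")
  if (!all(need %in% names(df)))
    stop("diet CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    bee_diet(df$protein_frac[i], df$lipid_frac[i], name = df$name[i],
             sucrose_solution_frac = df$sucrose_solution_frac[i],
             vitamin_frac = df$vitamin_frac[i],
             cellulose_frac = df$cellulose_frac[i]))
  stats::setNames(out, df$name)
}

# Resolve a diet argument that may be a bee_diet or a canonical name.
as_bee_diet <- function(x) {
  if (inherits(x, "bee_diet")) return(x)
  if (is.character(x)) return(parse_diet_name(x))
  stop("expected a bee_diet or a diet name like 'P30:L20'", call. = FALSE)
}
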