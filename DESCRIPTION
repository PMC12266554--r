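Package: beeNGF
Title: Nutritional Geometry of Protein-Lipid Regulation in Caged Nurse Honeybees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Nutritional Geometry Framework (NGF) analyses of
    protein-lipid regulation in caged nurse honeybees. Represents artificial
    diets as food rails in protein-lipid space, computes closed-form predicted
    intake points under five rules of compromise (strict restraint, closest
    distance, equal distance, protein priority, lipid priority), infers
    protein-lipid intake targets from no-choice feeding data, and classifies
    the rule that best explains observed intakes. Includes a seeded stochastic
    simulator of cage feeding experiments (no-choice and choice designs,
    mortality, hypopharyngeal-gland and body-lipid endpoints), per-capita
    intake accounting from daily dish masses and cage censuses, and the
    designed-experiment statistics used in such studies: theoretical
    no-regulation choice expectations, Bonferroni-corrected preference tests,
    one-way and mixed ANOVA with Tukey HSD letters, MANOVA, and Cox frailty
    survival comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
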