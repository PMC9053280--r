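#' VPA-related molecules observable in exhaled breath
#'
#' Monoisotopic neutral masses (Da) of valproic acid and its three
#' breath-detectable metabolites: 3-heptanone (non-enzymatic end product of
#' beta-oxidation), 4-OH-gamma-lactone (end product of omega-1-oxidation) and
#' heptanedione (C7H12O2).
#'
#' @return A tibble with columns `molecule`, `formula`, `mass`, `pathway_role`.
#' @export
vpa_molecules <- function() {
  tibble(
    molecule = c("3-heptanone", "4-OH-gamma-lactone", "heptanedione", "valproic-acid"),
    formula = c("C7H14O", "C8H14O2", "C7H12O2", "C8H16O2"),
    mass = c(114.104465, 142.099380, 128.083730, 144.115030),
    pathway_role = c("beta-oxidation", "omega1-oxidation", "unassigned", "parent")
  )
}

# The 11 drug-related mass-spectral features: protonated, sodiated and
# 13C-isotope ions of the four molecules, with within-molecule relative
# abundances. Used by the cohort generator and available as ground truth.
drug_feature_defs <- function() {
  mol <- vpa_molecules()
  m <- setNames(mol$mass, mol$molecule)
  defs <- tibble(
    molecule = c(
      "3-heptanone", "3-heptanone", "3-heptanone",
      "4-OH-gamma-lactone", "4-OH-gamma-lactone", "4-OH-gamma-lactone",
      "heptanedione", "heptanedione",
      "valproic-acid", "valproic-acid", "valproic-acid"
    ),
    ion = c("M+H", "M+H+1", "M+Na",
            "M+H", "M+H+1", "M+Na",
            "M+H", "M+H+1",
            "M+H", "M+H+1", "M+Na"),
    rel_abund = c(1, 0.08, 0.25, 1, 0.09, 0.3, 1, 0.08, 1, 0.09, 0.2)
  )
  delta <- c("M+H" = PROTON_MASS, "M+H+1" = PROTON_MASS + C13_DELTA,
             "M+Na" = NA_ADDUCT)
  defs$mz <- unname(m[defs$molecule] + delta[defs$ion])
  # per-molecule ionisation efficiency: amplitude (a.u.) per mg/L free VPA
  amp <- c("3-heptanone" = 16, "4-OH-gamma-lactone" = 24,
           "heptanedione" = 6, "valproic-acid" = 10)
  defs$amp_per_mgL <- unname(amp[defs$molecule]) * defs$rel_abund
  defs
}

#' Generate a toy pathway database with known compound masses
#'
#' Stands in for a metabolic pathway map (e.g. KEGG-style amino-acid pathways)
#' in synthetic runs: pathways of compounds with unique monoisotopic masses in
#' [100, 400] Da, pairwise separated by more than `min_sep_ppm` so that
#' accurate-mass annotation at a tighter tolerance is unambiguous. The four
#' VPA molecules are always included, flagged as drug compounds and excluded
#' from endogenous pathway membership. Pathways may share compounds.
#'
#' @param n_pathways Number of endogenous pathways.
#' @param compounds_per_pathway Compounds per pathway.
#' @param seed Integer seed.
#' @param mass_range Neutral monoisotopic mass range (Da) for generated
#'   compounds (kept inside scan range after protonation).
#' @param min_sep_ppm Minimum pairwise mass separation (ppm) enforced among all
#'   compounds, drug molecules included.
#' @param share_frac Fraction of pathway slots (after the first pathway) filled
#'   by a compound shared with a previously generated pathway.
#' @param max_retries Bounded number of redraws per compound before failing
#'   with a mass-collision error.
#'
#' @return A `pathway_db` object: list with tibbles `compounds`
#'   (`compound_id`, `name`, `mass`, `is_drug`) and `pathways` (`pathway_id`,
#'   `name`, and a `compound_ids` list-column).
#' @export
make_toy_pathway_db <- function(n_pathways = 8, compounds_per_pathway = 6,
                                seed = 1L, mass_range = c(100, 380),
                                min_sep_ppm = 10, share_frac = 0.1,
                                max_retries = 50) {
  stopifnot(is_count(n_pathways), is_count(compounds_per_pathway))
  with_seed(seed, {
    mol <- vpa_molecules()
    masses <- mol$mass
    draw_mass <- function() {
      for (i in seq_len(max_retries)) {
        cand <- runif(1, mass_range[1], mass_range[2])
        if (all(ppm_diff(cand, masses) > min_sep_ppm)) return(cand)
      }
      stop("could not place a compound mass without a ", min_sep_ppm,
           " ppm collision after ", max_retries, " retries", call. = FALSE)
    }
    membership <- vector("list", n_pathways)
    n_endo <- 0
    endo_masses <- numeric(0)
    for (p in seq_len(n_pathways)) {
      ids <- integer(0)
      for (s in seq_len(compounds_per_pathway)) {
        reuse <- p > 1 && n_endo > 0 && runif(1) < share_frac
        if (reuse) {
          cand <- sample(setdiff(seq_len(n_endo), ids), 1)
          ids <- c(ids, cand)
        } else {
          mz <- draw_mass()
          masses <- c(masses, mz)
          endo_masses <- c(endo_masses, mz)
          n_endo <- n_endo + 1
          ids <- c(ids, n_endo)
        }
      }
      membership[[p]] <- sort(unique(ids))
    }
    drug <- tibble(
      compound_id = sprintf("D%02d", seq_len(nrow(mol))),
      name = mol$molecule, mass = mol$mass, is_drug = TRUE
    )
    endo <- tibble(
      compound_id = sprintf("C%03d", seq_len(n_endo)),
      name = sprintf("toy compound %d", seq_len(n_endo)),
      mass = endo_masses, is_drug = FALSE
    )
    pathways <- tibble(
      pathway_id = sprintf("P%02d", seq_len(n_pathways)),
      name = sprintf("toy pathway %d", seq_len(n_pathways)),
      compound_ids = lapply(membership, function(i) endo$compound_id[i])
    )
    structure(list(compounds = bind_rows(drug, endo), pathways = pathways),
              class = "pathway_db")
  })
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, %d compounds (%d drug-flagged)\n",
              nrow(x$pathways), nrow(x$compounds), sum(x$compounds$is_drug)))
  invisible(x)
}

#' Long-format pathway membership
#'
#' @param db A `pathway_db`.
#' @return Tibble with one row per (pathway, compound) pair.
#' @export
pathway_members <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  tidyr::unnest(
    dplyr::transmute(db$pathways, pathway_id = .data$pathway_id,
                     compound_id = .data$compound_ids),
    "compound_id"
  )
}
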