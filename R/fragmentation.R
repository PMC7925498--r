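# Negative-mode MS/MS fragment prediction for sulfolipids.
#
# Two fragment families drive MRM design and annotation: headgroup
# diagnostic ions shared by all sulfoquinovosyl lipids, and fatty-acid
# neutral-loss fragments that differ between acyl compositions.

#' Sulfoquinovose diagnostic fragment ions
#'
#' The six headgroup fragments characteristic of all sulfoquinovosyl
#' lipids in negative mode, nominal m/z 81, 125, 153, 165, 225 and 255.
#' Monoisotopic values are attached where the elemental assignment is
#' established (81 = HSO3⁻, 153 = C3H5O5S⁻, 165 = C4H5O5S⁻,
#' 225 = C6H9O7S⁻, the dehydrated deprotonated sulfoquinovose). The 125
#' (C2H5O4S⁻) and 255 (palmitate carboxylate C16H31O2⁻) assignments are
#' plausible but not established and are flagged `assignment_uncertain`;
#' matching against observed products uses nominal values only.
#'
#' @return Tibble with columns `kind`, `formula`, `mz_monoisotopic`,
#'   `mz_nominal`, `assignment_uncertain`, `lost_chain`.
#' @examples
#' diagnostic_fragments()
#' @export
diagnostic_fragments <- function() {
  frag <- tibble::tibble(
    formula = c("HSO3", "C2H5O4S", "C3H5O5S", "C4H5O5S", "C6H9O7S", "C16H31O2"),
    assignment_uncertain = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  tibble::tibble(
    kind = "diagnostic",
    formula = frag$formula,
    mz_monoisotopic = vapply(frag$formula, formula_mass, numeric(1),
                             USE.NAMES = FALSE),
    mz_nominal = vapply(
      frag$formula, function(f) as.integer(formula_mass(f, "nominal")),
      integer(1), USE.NAMES = FALSE
    ),
    assignment_uncertain = frag$assignment_uncertain,
    lost_chain = NA_character_
  )
}

#' Fatty-acid neutral-loss fragments of a species
#'
#' For each acyl chain, three predictions: loss of the free fatty acid
#' (CnH(2n-2d)O2), loss of the corresponding ketene (CnH(2n-2d-2)O), and
#' the released fatty-acid carboxylate anion itself. Mass balance holds by
#' construction: precursor \[M-H\]⁻ = fragment m/z + neutral-loss mass.
#'
#' @param species one-row species tibble from [sq_species()].
#' @return Tibble with columns `kind` (`acid_loss`, `ketene_loss`,
#'   `carboxylate`), `lost_chain`, `formula` (of the fragment ion),
#'   `mz_monoisotopic`, `mz_nominal`, `neutral_loss_monoisotopic`.
#' @examples
#' neutral_loss_fragments(sq_species("16:0", "18:3"))
#' @export
neutral_loss_fragments <- function(species) {
  stopifnot(nrow(species) == 1L)
  chains <- c(species$chain1, species$chain2)
  chains <- chains[!is.na(chains)]
  if (length(chains) == 0L) {
    stop("species has no acyl chains to lose", call. = FALSE)
  }
  prec_counts <- species_formula_counts(chains)
  prec_mono <- formula_mass(prec_counts) - .H_MASS
  prec_nom <- formula_mass(prec_counts, "nominal") - 1L
  purrr::map_dfr(unique(chains), function(ch) {
    acid <- parse_formula(chain_formula(ch, "acid"))
    ketene <- parse_formula(chain_formula(ch, "ketene"))
    # fragment ion composition: deprotonated precursor minus the neutral
    frag_acid <- prec_counts - acid
    frag_ketene <- prec_counts - ketene
    carboxylate <- acid - element_count(H = 1)  # RCOO⁻ anion
    tibble::tibble(
      kind = c("acid_loss", "ketene_loss", "carboxylate"),
      lost_chain = ch,
      formula = vapply(
        list(frag_acid, frag_ketene, carboxylate), format_formula, character(1)
      ),
      mz_monoisotopic = c(
        formula_mass(frag_acid) - .H_MASS,
        formula_mass(frag_ketene) - .H_MASS,
        formula_mass(carboxylate)
      ),
      mz_nominal = as.integer(c(
        formula_mass(frag_acid, "nominal") - 1,
        formula_mass(frag_ketene, "nominal") - 1,
        formula_mass(carboxylate, "nominal")
      )),
      neutral_loss_monoisotopic = c(
        formula_mass(acid),
        formula_mass(ketene),
        prec_mono - (formula_mass(acid) - .H_MASS)
      )
    )
  })
}

#' Rank sn positions from acid-loss fragment intensities
#'
#' On collision-induced dissociation the loss of the sn1 fatty acid gives
#' the more intense fragment, so relative acid-loss intensities order the
#' glycerol regiochemistry. Equal or missing intensities leave the
#' assignment ambiguous.
#'
#' @param species one-row SQDG species tibble.
#' @param loss_intensities named numeric vector, names = chains (`"C:D"`),
#'   values = acid-loss fragment intensities.
#' @return Tibble with columns `sn1_chain`, `sn2_chain`, `confidence`
#'   (`"assigned"` or `"ambiguous"`).
#' @examples
#' rank_sn_assignment(sq_species("16:0", "18:3"),
#'                    c("18:3" = 1000, "16:0" = 400))
#' @export
rank_sn_assignment <- function(species, loss_intensities) {
  stopifnot(nrow(species) == 1L)
  if (species$lipid_class != "SQDG") {
    stop("sn ranking requires an SQDG (two chains); got ",
         species$lipid_class, call. = FALSE)
  }
  chains <- c(species$chain1, species$chain2)
  int <- loss_intensities[chains]
  if (length(loss_intensities) < 2L || any(is.na(int)) ||
      isTRUE(int[[1]] == int[[2]])) {
    return(tibble::tibble(
      sn1_chain = NA_character_, sn2_chain = NA_character_,
      confidence = "ambiguous"
    ))
  }
  ord <- order(int, decreasing = TRUE)
  tibble::tibble(
    sn1_chain = chains[ord[1]],
    sn2_chain = chains[ord[2]],
    confidence = "assigned"
  )
}

#' Annotate a precursor from its product ions
#'
#' Enumerates candidate SQDG and SQMG species at the precursor's nominal
#' mass and scores each by how many observed product ions its predicted
#' fragments explain. Diagnostic ions are matched on nominal m/z (shared
#' by all candidates, so they confirm the lipid class without separating
#' isobars); acid/ketene-loss fragments are matched on monoisotopic m/z
#' and carry the discriminating evidence. Candidates are ranked by match
#' count, ties broken by total absolute mass error.
#'
#' @param precursor_mz observed precursor m/z.
#' @param product_mzs numeric vector of observed product m/z values.
#' @param tolerance match tolerance in m/z (default 0.5, unit-resolution
#'   triple quadrupole).
#' @param pool fatty-acid pool (see [enumerate_species()]).
#' @return Tibble of candidates with `name`, `lipid_class`, `chain1`,
#'   `chain2`, `n_matched`, `total_abs_error`, `matched_products`
#'   (list-column of matched observed m/z), ordered best-first.
#' @examples
#' annotate_precursor(815.5, c(81.0, 225.0, 537.3, 559.3))
#' @export
annotate_precursor <- function(precursor_mz, product_mzs, tolerance = 0.5,
                               pool = default_fa_pool()) {
  stopifnot(tolerance > 0)
  # acyl mass defect puts monoisotopic [M-H]⁻ about half a unit above the
  # nominal value, so consider both flanking nominal masses and keep the
  # candidates whose monoisotopic precursor agrees with the observation
  nominal <- unique(c(floor(precursor_mz), ceiling(precursor_mz)))
  cands <- dplyr::bind_rows(
    purrr::map_dfr(nominal, enumerate_species, lipid_class = "SQDG",
                   pool = pool),
    purrr::map_dfr(nominal, enumerate_species, lipid_class = "SQMG",
                   pool = pool)
  )
  cands <- cands[abs(cands$mz_monoisotopic - precursor_mz) <= 0.5, ]
  if (nrow(cands) == 0L) {
    return(tibble::tibble(
      name = character(), lipid_class = character(),
      chain1 = character(), chain2 = character(),
      n_matched = integer(), total_abs_error = numeric(),
      matched_products = list()
    ))
  }
  diag <- diagnostic_fragments()
  scored <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    sp <- cands[i, ]
    losses <- neutral_loss_fragments(sp)
    pred <- c(diag$mz_nominal, losses$mz_monoisotopic)
    err <- vapply(product_mzs, function(p) min(abs(p - pred)), numeric(1))
    hit <- err <= tolerance
    tibble::tibble(
      name = sp$name, lipid_class = sp$lipid_class,
      chain1 = sp$chain1, chain2 = sp$chain2,
      n_matched = sum(hit),
      total_abs_error = sum(err[hit]),
      matched_products = list(product_mzs[hit])
    )
  })
  dplyr::arrange(scored, dplyr::desc(.data$n_matched), .data$total_abs_error)
}
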