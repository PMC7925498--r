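# Sulfolipid species model: acyl chains, SQMG/SQDG assembly, nominal
# nomenclature, and isobaric enumeration against a fatty-acid pool.
#
# Species are represented as one-row tibbles (rowbindable into species
# tables) with chains encoded as "C:D" strings; all masses derive from the
# elemental composition in masses.R.

# sulfoquinovosyl-glycerol core: sulfoquinovose (C6H12O8S) + glycerol
# (C3H8O3) - H2O, i.e. the zero-acyl backbone every species is built on
.SQ_CORE <- c(C = 9L, H = 18L, N = 0L, O = 10L, S = 1L)

.WATER <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)

#' Acyl-chain descriptors
#'
#' An acyl chain is written `"C:D"` (total carbons : double bonds), e.g.
#' `"16:0"` for palmitic or `"18:3"` for alpha-linolenic acid. The free
#' fatty acid has composition CnH(2n-2d)O2; the ketene (acid minus water)
#' CnH(2n-2d-2)O.
#'
#' @param chain chain string(s) `"C:D"`.
#' @return `acyl_chain()`: a tibble with columns `chain`, `carbons`,
#'   `double_bonds`. `chain_formula()`: formula string(s).
#' @examples
#' acyl_chain(c("16:0", "18:3"))
#' chain_formula("18:3")
#' chain_formula("18:3", "ketene")
#' @export
acyl_chain <- function(chain) {
  stopifnot(is.character(chain))
  ok <- grepl("^[0-9]+:[0-9]+$", chain)
  if (!all(ok)) {
    stop("malformed acyl chain: ", paste(chain[!ok], collapse = ", "),
         " (expected \"C:D\")", call. = FALSE)
  }
  carbons <- as.integer(sub(":.*", "", chain))
  dbs <- as.integer(sub(".*:", "", chain))
  bad <- carbons < 2L | dbs < 0L | dbs > (carbons - 2L) %/% 2L
  if (any(bad)) {
    stop("impossible acyl chain: ", paste(chain[bad], collapse = ", "),
         " (need carbons >= 2 and 0 <= double_bonds <= (carbons-2)/2)",
         call. = FALSE)
  }
  tibble::tibble(chain = chain, carbons = carbons, double_bonds = dbs)
}

#' @rdname acyl_chain
#' @param form `"acid"` for the free fatty acid, `"ketene"` for the
#'   dehydrated acyl fragment lost alongside it.
#' @export
chain_formula <- function(chain, form = c("acid", "ketene")) {
  form <- match.arg(form)
  ac <- acyl_chain(chain)
  h <- 2L * ac$carbons - 2L * ac$double_bonds - if (form == "acid") 0L else 2L
  o <- if (form == "acid") 2L else 1L
  vapply(
    seq_len(nrow(ac)),
    function(i) format_formula(element_count(C = ac$carbons[i], H = h[i], O = o)),
    character(1)
  )
}

#' Construct sulfolipid species
#'
#' Assembles SQMG (one acyl chain) or SQDG (two chains) species on the
#' sulfoquinovosyl-glycerol core, computing the elemental formula,
#' monoisotopic and nominal deprotonated m/z, and the class-plus-nominal-mass
#' display name used throughout (e.g. `"SQDG 815"`). Chain order within an
#' SQDG is not positional: sn assignment is a fragmentation-level question.
#'
#' @param chain1 first acyl chain, `"C:D"`.
#' @param chain2 second acyl chain for SQDG, or `NA` for SQMG.
#' @param lipid_class `"SQDG"`, `"SQMG"`, or `"auto"` (inferred from the
#'   number of chains).
#' @param alias optional vendor/display alias stored alongside the name.
#' @return One-row tibble with columns `name`, `lipid_class`, `chain1`,
#'   `chain2`, `formula`, `mz_monoisotopic`, `mz_nominal`, `alias`.
#' @examples
#' sq_species("16:0", "18:3")       # the commercial standard, SQDG 815
#' sq_species("16:0")               # SQMG 555
#' @export
sq_species <- function(chain1, chain2 = NA_character_,
                       lipid_class = c("auto", "SQDG", "SQMG"),
                       alias = NA_character_) {
  lipid_class <- match.arg(lipid_class)
  has2 <- !is.na(chain2)
  inferred <- if (has2) "SQDG" else "SQMG"
  if (lipid_class == "auto") lipid_class <- inferred
  if (lipid_class != inferred) {
    stop(lipid_class, " requires ", if (lipid_class == "SQDG") 2 else 1,
         " acyl chain(s)", call. = FALSE)
  }
  chains <- c(chain1, if (has2) chain2)
  acyl_chain(chains)  # validates
  counts <- species_formula_counts(chains)
  mono <- formula_mass(counts) - .H_MASS
  nom <- as.integer(formula_mass(counts, "nominal")) - 1L
  # canonical chain order: by carbons then double bonds (pair is unordered)
  if (has2) {
    ac <- acyl_chain(chains)
    ord <- order(ac$carbons, ac$double_bonds)
    chains <- chains[ord]
  }
  tibble::tibble(
    name = paste(lipid_class, nom),
    lipid_class = lipid_class,
    chain1 = chains[1],
    chain2 = if (has2) chains[2] else NA_character_,
    formula = format_formula(counts),
    mz_monoisotopic = mono,
    mz_nominal = nom,
    alias = alias
  )
}

# element counts of the neutral species with the given chains (0, 1 or 2)
species_formula_counts <- function(chains) {
  chains <- chains[!is.na(chains)]
  counts <- .SQ_CORE
  for (ch in chains) {
    counts <- counts + parse_formula(chain_formula(ch)) - .WATER
  }
  counts
}

#' Elemental formula of sulfolipid species
#'
#' Core (C9H18O10S) plus chain compositions minus one water per ester bond.
#'
#' @param species species tibble from [sq_species()] (any number of rows).
#' @return Character vector of formula strings, one per row.
#' @examples
#' elemental_formula(sq_species("16:0", "18:3"))  # "C43H76O12S"
#' @export
elemental_formula <- function(species) {
  vapply(
    seq_len(nrow(species)),
    function(i) {
      format_formula(species_formula_counts(
        c(species$chain1[i], species$chain2[i])
      ))
    },
    character(1)
  )
}

#' Deprotonated m/z of sulfolipid species
#'
#' Sulfolipids ionise in negative mode as the quasi-molecular ion
#' \[M-H\]⁻. Monoisotopic m/z subtracts one hydrogen-atom mass (electron
#' mass ignored, < 1 mDa); nominal m/z is the integer-mass-number sum minus
#' one, computed independently of the monoisotopic value.
#'
#' @param species species tibble.
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @return Numeric vector of m/z values.
#' @examples
#' mz_deprotonated(sq_species("16:0", "18:3"))             # 815.498
#' mz_deprotonated(sq_species("16:0"), mode = "nominal")   # 555
#' @export
mz_deprotonated <- function(species, mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  vapply(
    seq_len(nrow(species)),
    function(i) {
      counts <- species_formula_counts(c(species$chain1[i], species$chain2[i]))
      if (mode == "monoisotopic") {
        formula_mass(counts) - .H_MASS
      } else {
        formula_mass(counts, "nominal") - 1
      }
    },
    numeric(1)
  )
}

#' Nominal display name of a species
#'
#' Names follow the `<class> <nominal [M-H]⁻>` convention of the reference
#' panel, e.g. `"SQDG 815"` for the 16:0/18:3 species.
#'
#' @param species species tibble.
#' @return Character vector of names.
#' @export
nominal_name <- function(species) {
  paste(species$lipid_class, mz_deprotonated(species, "nominal"))
}

#' Default fatty-acid pool
#'
#' Acyl chains commonly found in cyanobacterial, microalgal and plant
#' glycolipids; used by [enumerate_species()] and configurable because
#' the biologically admissible set is matrix-dependent.
#'
#' @return Tibble of acyl chains (see [acyl_chain()]).
#' @export
default_fa_pool <- function() {
  acyl_chain(c(
    "14:0", "15:0", "16:0", "16:1", "17:0", "18:0", "18:1",
    "18:2", "18:3", "18:4", "20:4", "20:5", "22:6"
  ))
}

.validate_pool <- function(pool) {
  if (is.character(pool)) pool <- acyl_chain(pool)
  if (anyDuplicated(pool$chain) > 0) {
    stop("fatty-acid pool contains duplicate chains", call. = FALSE)
  }
  pool
}

#' Enumerate isobaric species at a nominal precursor mass
#'
#' Unit-resolution MRM cannot distinguish isobaric acyl combinations: a
#' single nominal \[M-H\]⁻ may correspond to several unordered chain pairs
#' (e.g. 815 to 16:0/18:3 and 16:1/18:2). This enumerates every chain
#' combination from the pool whose nominal deprotonated mass equals the
#' query, duplicate-free and order-insensitive.
#'
#' @param precursor_nominal integer nominal \[M-H\]⁻ m/z.
#' @param lipid_class `"SQDG"` (unordered pairs, repetition allowed) or
#'   `"SQMG"` (single chains).
#' @param pool fatty-acid pool tibble or character vector of `"C:D"` chains;
#'   defaults to [default_fa_pool()].
#' @return Species tibble (possibly zero rows).
#' @examples
#' enumerate_species(815, "SQDG")$chain1
#' enumerate_species(555, "SQMG")
#' @export
enumerate_species <- function(precursor_nominal,
                              lipid_class = c("SQDG", "SQMG"),
                              pool = default_fa_pool()) {
  lipid_class <- match.arg(lipid_class)
  stopifnot(length(precursor_nominal) == 1L, precursor_nominal > 0)
  pool <- .validate_pool(pool)
  n <- nrow(pool)
  if (n == 0L) return(sq_species("16:0")[0, ])
  combos <- if (lipid_class == "SQMG") {
    lapply(pool$chain, function(ch) c(ch, NA_character_))
  } else {
    out <- list()
    for (i in seq_len(n)) for (j in i:n) {
      out[[length(out) + 1L]] <- c(pool$chain[i], pool$chain[j])
    }
    out
  }
  hits <- purrr::map_dfr(combos, function(ch) {
    sp <- sq_species(ch[1], ch[2], lipid_class = lipid_class)
    if (sp$mz_nominal == precursor_nominal) sp else sp[0, ]
  })
  hits[!duplicated(hits[c("chain1", "chain2")]), ]
}

#' Read or write species tables as CSV
#'
#' Columns: `name, lipid_class, chain1, chain2, formula, mz_monoisotopic,
#' mz_nominal`.
#'
#' @param species species tibble.
#' @param path file path.
#' @return `write_species()` returns `species` invisibly; `read_species()`
#'   returns the species tibble.
#' @export
write_species <- function(species, path) {
  cols <- c("name", "lipid_class", "chain1", "chain2", "formula",
            "mz_monoisotopic", "mz_nominal")
  readr::write_csv(species[cols], path)
  invisible(species)
}

#' @rdname write_species
#' @export
read_species <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      lipid_class = readr::col_character(),
      chain1 = readr::col_character(),
      chain2 = readr::col_character(),
      formula = readr::col_character(),
      mz_monoisotopic = readr::col_double(),
      mz_nominal = readr::col_integer()
    )
  )
}
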