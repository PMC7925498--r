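# MRM transition panels: CSV IO with validation, classification, panel
# generation from the species model, and transition matching.
#
# A panel is a long tibble (one row per transition) with class "sq_panel";
# each analyte carries exactly three transitions, one of them the
# quantifier. The bundled reference panel covers 25 SQDGs, one SQMG and
# the sulfogalactosylceramide internal standard.

.PANEL_COLS <- c("analyte", "class", "rt_min", "precursor_mz", "product_mz",
                 "role", "dwell_ms", "dp_v", "ep_v", "ce", "cxp_v")
.ROLES <- c("quantifier", "qualifier1", "qualifier2")

new_sq_panel <- function(x) {
  structure(x, class = c("sq_panel", class(tibble::tibble())))
}

#' Path to the bundled reference transition panel
#'
#' @return File path of the packaged panel CSV.
#' @export
sq_panel_path <- function() {
  system.file("extdata", "mrm_panel_sulfolipids.csv", package = "sqmrm",
              mustWork = TRUE)
}

#' Load the bundled reference transition panel
#'
#' 27 analytes (25 SQDGs, one SQMG, the cerebroside internal standard),
#' three negative-mode transitions each, with retention times and
#' instrument potentials. Two screening-only analytes (867, 871) have no
#' retention time and are excluded from retention-time assignment.
#'
#' @return An `sq_panel` tibble (81 rows).
#' @examples
#' count_by_class(sq_reference_panel())
#' @export
sq_reference_panel <- function() {
  load_panel(sq_panel_path())
}

#' Read and write MRM transition panels
#'
#' The CSV schema is fixed: header
#' `analyte,class,rt_min,precursor_mz,product_mz,role,dwell_ms,dp_v,ep_v,ce,cxp_v`
#' with one row per transition. On load the panel is validated (three
#' transitions per analyte, exactly one quantifier, precursor > product > 0,
#' positive dwell times) and a `molar_mass_g_mol` column is attached: the
#' internal standard's printed molar mass is 794 g/mol, sulfolipid analytes
#' carry the nominal mass their label encodes.
#'
#' @param source path to a panel CSV.
#' @param panel an `sq_panel` tibble.
#' @param sink output path.
#' @return `load_panel()`: validated `sq_panel` tibble. `write_panel()`:
#'   `panel`, invisibly.
#' @examples
#' p <- sq_reference_panel()
#' tmp <- tempfile(fileext = ".csv")
#' write_panel(p, tmp)
#' identical(load_panel(tmp), p)
#' @export
load_panel <- function(source) {
  header <- names(utils::read.csv(source, nrows = 1, check.names = FALSE))
  if (!identical(header, .PANEL_COLS)) {
    stop("panel CSV header must be exactly: ",
         paste(.PANEL_COLS, collapse = ","), call. = FALSE)
  }
  x <- readr::read_csv(
    source,
    col_types = readr::cols(
      analyte = readr::col_character(),
      class = readr::col_character(),
      rt_min = readr::col_double(),
      precursor_mz = readr::col_double(),
      product_mz = readr::col_double(),
      role = readr::col_character(),
      dwell_ms = readr::col_double(),
      dp_v = readr::col_double(),
      ep_v = readr::col_double(),
      ce = readr::col_double(),
      cxp_v = readr::col_double()
    )
  )
  attr(x, "problems") <- NULL
  attr(x, "spec") <- NULL
  x <- tibble::as_tibble(x)
  validate_panel(x)
  x$molar_mass_g_mol <- ifelse(
    x$class == "ISD", 794,
    suppressWarnings(as.numeric(sub(" .*", "", x$analyte)))
  )
  new_sq_panel(x)
}

validate_panel <- function(x) {
  line <- function(i) paste0(" (line ", i + 1L, ")")  # +1 for header
  bad_role <- which(!x$role %in% .ROLES)
  if (length(bad_role)) {
    stop("unknown transition role '", x$role[bad_role[1]], "'",
         line(bad_role[1]), call. = FALSE)
  }
  bad_class <- which(!x$class %in% c("SQDG", "SQMG", "ISD"))
  if (length(bad_class)) {
    stop("unknown analyte class '", x$class[bad_class[1]], "'",
         line(bad_class[1]), call. = FALSE)
  }
  bad_mz <- which(!(x$precursor_mz > x$product_mz & x$product_mz > 0))
  if (length(bad_mz)) {
    stop("requires precursor_mz > product_mz > 0", line(bad_mz[1]),
         call. = FALSE)
  }
  bad_dwell <- which(!(x$dwell_ms > 0))
  if (length(bad_dwell)) {
    stop("dwell_ms must be positive", line(bad_dwell[1]), call. = FALSE)
  }
  for (a in unique(x$analyte)) {
    rows <- which(x$analyte == a)
    if (length(rows) != 3L) {
      stop("analyte '", a, "' has ", length(rows),
           " transitions, expected 3", line(rows[1]), call. = FALSE)
    }
    if (sum(x$role[rows] == "quantifier") != 1L) {
      stop("analyte '", a, "' must have exactly one quantifier",
           line(rows[1]), call. = FALSE)
    }
    if (anyDuplicated(x$role[rows])) {
      stop("analyte '", a, "' has duplicate transition roles",
           line(rows[1]), call. = FALSE)
    }
    if (length(unique(x$class[rows])) != 1L ||
        length(unique(round(x$rt_min[rows], 6))) > 1L) {
      stop("analyte '", a, "' has inconsistent class or retention time",
           line(rows[1]), call. = FALSE)
    }
  }
  invisible(x)
}

#' @rdname load_panel
#' @export
write_panel <- function(panel, sink) {
  readr::write_csv(panel[.PANEL_COLS], sink, na = "")
  invisible(panel)
}

#' Classify panel analytes
#'
#' `classify_analyte()` returns the lipid class of a named analyte (or the
#' analyte matching a precursor m/z); `count_by_class()` tallies analytes
#' per class. The reference panel counts 25 SQDGs, one SQMG, one internal
#' standard.
#'
#' @param panel an `sq_panel` tibble.
#' @param analyte analyte name, or a numeric precursor m/z.
#' @param tolerance m/z tolerance when looking up by precursor.
#' @return `classify_analyte()`: single class string. `count_by_class()`:
#'   tibble with `class`, `n_analytes`.
#' @examples
#' classify_analyte(sq_reference_panel(), "555")
#' count_by_class(sq_reference_panel())
#' @export
classify_analyte <- function(panel, analyte, tolerance = 0.5) {
  if (is.numeric(analyte)) {
    hit <- abs(panel$precursor_mz - analyte) <= tolerance
    if (!any(hit)) {
      stop("no analyte with precursor within ", tolerance, " of ", analyte,
           call. = FALSE)
    }
    return(panel$class[which(hit)[1]])
  }
  # "792" matches the flagged name "792 (ISD)"
  hit <- panel$analyte == analyte | sub(" .*", "", panel$analyte) == analyte
  if (!any(hit)) stop("unknown analyte: ", analyte, call. = FALSE)
  panel$class[which(hit)[1]]
}

#' @rdname classify_analyte
#' @export
count_by_class <- function(panel) {
  analytes <- dplyr::distinct(
    tibble::as_tibble(panel)[c("analyte", "class")]
  )
  dplyr::count(analytes, .data$class, name = "n_analytes")
}

#' Generate MRM transitions for a species
#'
#' Builds the three-transition set the panel design uses: precursor =
#' monoisotopic \[M-H\]⁻ rounded to one decimal; quantifier on the
#' sulfonate diagnostic ion (m/z 81), qualifiers on further headgroup
#' diagnostics (default 225 and 165). Instrument potentials are left at
#' configurable defaults — on a real instrument they come from compound
#' optimisation.
#'
#' @param species one-row species tibble.
#' @param quantifier_product,qualifier_products nominal product ions.
#' @param dwell_ms,dp_v,ep_v,ce,cxp_v default instrument parameters.
#' @return An `sq_panel` tibble with three rows.
#' @examples
#' generate_transitions(sq_species("16:0", "18:3"))
#' @export
generate_transitions <- function(species,
                                 quantifier_product = 81,
                                 qualifier_products = c(225, 165),
                                 dwell_ms = 150, dp_v = -150, ep_v = -10,
                                 ce = -100, cxp_v = -10) {
  stopifnot(nrow(species) == 1L, length(qualifier_products) == 2L)
  prec <- round(mz_deprotonated(species), 1)
  name <- as.character(mz_deprotonated(species, "nominal"))
  x <- tibble::tibble(
    analyte = name,
    class = species$lipid_class,
    rt_min = NA_real_,
    precursor_mz = prec,
    product_mz = c(quantifier_product, qualifier_products),
    role = .ROLES,
    dwell_ms = dwell_ms, dp_v = dp_v, ep_v = ep_v, ce = ce, cxp_v = cxp_v
  )
  validate_panel(x)
  new_sq_panel(x)
}

#' Match an observed transition to a panel
#'
#' Finds the panel transition nearest to an observed precursor/product
#' pair, requiring both ions within tolerance. If several transitions fall
#' inside the tolerance the nearest (by summed m/z distance) wins with a
#' warning and an `ambiguous` flag.
#'
#' @param panel an `sq_panel` tibble.
#' @param precursor_mz,product_mz observed ion m/z values.
#' @param tolerance m/z tolerance on each ion (default 0.5).
#' @return One-row tibble `analyte`, `class`, `role`, `ambiguous`, or a
#'   zero-row tibble when nothing matches.
#' @examples
#' match_transition(sq_reference_panel(), 815.4, 80.9)
#' @export
match_transition <- function(panel, precursor_mz, product_mz,
                             tolerance = 0.5) {
  stopifnot(tolerance > 0)
  d_prec <- abs(panel$precursor_mz - precursor_mz)
  d_prod <- abs(panel$product_mz - product_mz)
  hit <- which(d_prec <= tolerance & d_prod <= tolerance)
  if (length(hit) == 0L) {
    return(tibble::tibble(analyte = character(), class = character(),
                          role = character(), ambiguous = logical()))
  }
  if (length(hit) > 1L) {
    warning("ambiguous transition match (", length(hit),
            " candidates); nearest wins", call. = FALSE)
  }
  best <- hit[which.min(d_prec[hit] + d_prod[hit])]
  tibble::tibble(
    analyte = panel$analyte[best],
    class = panel$class[best],
    role = panel$role[best],
    ambiguous = length(hit) > 1L
  )
}
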