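# Elemental bookkeeping for sulfolipid species and fragments.
#
# Element counts are plain named integer vectors over the CHNOS alphabet;
# all higher-level objects (species tables, fragment tables) carry formulas
# as strings and convert through these helpers.

# monoisotopic atomic masses (u), CODATA/IUPAC values
.MONO_MASS <- c(
  C = 12.000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706900
)

# integer mass numbers of the most abundant isotope
.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L, S = 32L)

.ELEMENTS <- names(.MONO_MASS)

#' Build an element-count vector
#'
#' @param C,H,N,O,S non-negative integer atom counts.
#' @return Named integer vector over `c("C","H","N","O","S")`.
#' @examples
#' element_count(C = 9, H = 18, O = 10, S = 1)
#' @export
element_count <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  x <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

.as_element_count <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  out <- element_count()
  stopifnot(all(names(x) %in% .ELEMENTS))
  out[names(x)] <- as.integer(x)
  out
}

#' Parse a molecular formula string into element counts
#'
#' Accepts Hill-style CHNOS formulas such as `"C43H76O12S"`.
#'
#' @param formula formula string.
#' @return Named integer element-count vector.
#' @examples
#' parse_formula("C25H48O11S")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  out <- element_count()
  for (p in parts) {
    sym <- gsub("[0-9]", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% .ELEMENTS) {
      stop("unsupported element '", sym, "' in formula ", formula, call. = FALSE)
    }
    out[sym] <- out[sym] + n
  }
  out
}

#' Format element counts as a formula string
#'
#' @param counts named element-count vector (or formula string, returned as-is
#'   after normalisation).
#' @return Formula string in C, H, N, O, S order; unit counts drop the digit.
#' @examples
#' format_formula(element_count(C = 43, H = 76, O = 12, S = 1))
#' @export
format_formula <- function(counts) {
  counts <- .as_element_count(counts)
  keep <- counts > 0L
  paste0(
    names(counts)[keep],
    ifelse(counts[keep] > 1L, counts[keep], ""),
    collapse = ""
  )
}

#' Monoisotopic or nominal mass of an elemental composition
#'
#' Nominal masses are computed from integer mass numbers, never by rounding
#' the monoisotopic mass, so accumulated mass defect cannot shift the
#' nominal value.
#'
#' @param counts element-count vector or formula string.
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @return Mass in u (numeric; integer-valued for `"nominal"`).
#' @examples
#' formula_mass("C43H76O12S")
#' formula_mass("C43H76O12S", "nominal")
#' @export
formula_mass <- function(counts, mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  counts <- .as_element_count(counts)
  tab <- if (mode == "monoisotopic") .MONO_MASS else .NOMINAL_MASS
  sum(counts * tab[names(counts)])
}

# mass of a hydrogen atom, used for [M-H]^- (electron mass ignored: < 1 mDa)
.H_MASS <- .MONO_MASS[["H"]]
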