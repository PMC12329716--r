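#' Parse a molecular formula string
#'
#' Parses Hill-style molecular formulas such as `"C6H12O6"` or `"C4H8O5"`
#' into element counts. Element symbols are one uppercase letter optionally
#' followed by a lowercase letter; a missing count means 1. A trailing or
#' embedded charge is not parsed from the string; supply it via `charge`.
#'
#' @param x formula string, e.g. `"C6H12O6"`.
#' @param charge net charge of the ion (integer, default 0).
#' @return An object of class `molecular_formula`: a named integer vector of
#'   element counts with a `charge` attribute.
#' @examples
#' parse_formula("C4H8O5")
#' nosc(parse_formula("C4H8O5"))
#' @export
parse_formula <- function(x, charge = 0L) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- gsub("\\s", "", x)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: ", x)
  }
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- if (is.na(counts[el])) n else counts[el] + n
  }
  molecular_formula(counts, charge = charge)
}

#' Construct a molecular formula from element counts
#'
#' @param counts named integer vector of element counts (names are element
#'   symbols, e.g. `c(C = 6, H = 12, O = 6)`).
#' @param charge net charge (default 0).
#' @return A `molecular_formula` object.
#' @export
molecular_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("element counts must be nonnegative")
  storage.mode(counts) <- "integer"
  structure(counts, charge = as.integer(charge), class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  z <- attr(x, "charge")
  cat("<molecular_formula> ",
      paste0(names(x), ifelse(unclass(x) > 1, unclass(x), ""), collapse = ""),
      if (z != 0) sprintf(" (charge %+d)", z), "\n", sep = "")
  invisible(x)
}

elem_count <- function(f, el) {
  i <- match(el, names(f))
  if (is.na(i)) 0L else unclass(f)[[i]]
}

#' Nominal oxidation state of carbon (NOSC)
#'
#' Computes the average oxidation state of carbon from a molecular formula,
#' in the LaRowe-Van Cappellen form
#' \deqn{NOSC = 4 - \frac{-Z + 4C + H - 3N - 2O + 5P - 2S}{C}}
#' where Z is the net charge. Higher NOSC means more oxidized carbon and a
#' smaller energy yield on oxidation; CH4 scores -4 and carbohydrates 0.
#'
#' @param formula a `molecular_formula` (see [parse_formula()]) or a formula
#'   string, which is parsed with charge 0 unless `charge` is given.
#' @param charge net charge, used only when `formula` is a string.
#' @return NOSC as a single numeric value.
#' @examples
#' nosc("CH4")      # -4
#' nosc("C6H12O6") # 0
#' nosc("C4H8O5")  # 0.5, threonic acid
#' @export
nosc <- function(formula, charge = 0L) {
  if (is.character(formula)) formula <- parse_formula(formula, charge = charge)
  stopifnot(inherits(formula, "molecular_formula"))
  C <- elem_count(formula, "C")
  if (C < 1L) stop("NOSC requires at least one carbon atom")
  H <- elem_count(formula, "H")
  N <- elem_count(formula, "N")
  O <- elem_count(formula, "O")
  P <- elem_count(formula, "P")
  S <- elem_count(formula, "S")
  Z <- attr(formula, "charge")
  4 - (-Z + 4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C
}

#' Does a formula contain halogen atoms?
#'
#' @param formula a `molecular_formula` or formula string.
#' @return `TRUE` if the formula contains F, Cl, Br or I with count >= 1.
#' @export
contains_halogen <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  any(names(formula) %in% c("F", "Cl", "Br", "I"))
}

#' Molarity of a media component
#'
#' Converts a mass concentration to micromolar, reported to 3 significant
#' figures, for checking incubation-media recipes (e.g. 0.25 g/L ammonium
#' chloride is about 4670 uM ammonium).
#'
#' @param mass_g_per_L mass concentration in g/L (positive).
#' @param molar_mass_g_per_mol molar mass in g/mol (positive).
#' @return concentration in uM, 3 significant figures.
#' @examples
#' media_molarity(0.25, 53.49) # NH4Cl -> 4670 uM
#' media_molarity(0.10, 74.55) # KCl   -> 1340 uM
#' @export
media_molarity <- function(mass_g_per_L, molar_mass_g_per_mol) {
  if (!is.numeric(mass_g_per_L) || mass_g_per_L <= 0) {
    stop("mass_g_per_L must be positive")
  }
  if (!is.numeric(molar_mass_g_per_mol) || molar_mass_g_per_mol <= 0) {
    stop("molar_mass_g_per_mol must be positive")
  }
  signif(mass_g_per_L / molar_mass_g_per_mol * 1e6, 3)
}
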