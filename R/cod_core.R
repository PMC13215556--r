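# Elemental-formula chemistry: theoretical oxygen demand (ThOD) as the
# specific COD of nutrients, microbial biomass and gases, plus unit helpers.

# Integer atomic masses. With C=12, H=1, O=16, N=14 the specific COD of
# microbial biomass C5H7O2N is exactly 160/113 = 1.42 gCOD/g (2 d.p.), the
# convention used throughout the anaerobic-treatment literature; exact masses
# would give 1.415 -> 1.41.
.ATOMIC_MASS <- c(C = 12, H = 1, O = 16, N = 14)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of C, H, O and N atom counts.
#' Sulfur and other elements are deliberately excluded: no S-bearing species
#' appears in the model's reaction network (a documented limitation that rules
#' out cysteine/methionine as explicit nutrients).
#'
#' @param C,H,O,N Non-negative integer atom counts.
#' @return A named integer vector of class `elemental_formula`.
#' @examples
#' elemental_formula(C = 5, H = 7, O = 2, N = 1)  # microbial biomass
#' @export
elemental_formula <- function(C = 0, H = 0, O = 0, N = 0) {
  counts <- c(C = unname(C), H = unname(H), O = unname(O), N = unname(N))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("atom counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("formula must contain at least one atom", call. = FALSE)
  structure(as.integer(round(counts)), names = names(counts),
            class = "elemental_formula")
}

#' Parse a formula string such as "C6H12O6"
#'
#' @param x A character scalar using element symbols C, H, O, N with optional
#'   integer counts (missing count means 1), e.g. `"CH4"`, `"C5H7O2N"`.
#' @return An [elemental_formula()].
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("formula must be a single non-empty string", call. = FALSE)
  tokens <- regmatches(x, gregexpr("([CHON])([0-9]*)", x))[[1]]
  if (sum(nchar(tokens)) != nchar(x))
    stop("cannot parse formula '", x, "': only C, H, O, N are supported",
         call. = FALSE)
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L)
  for (tok in tokens) {
    el <- substr(tok, 1, 1)
    n <- substr(tok, 2, nchar(tok))
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  elemental_formula(C = counts["C"], H = counts["H"],
                    O = counts["O"], N = counts["N"])
}

#' Molar mass of a formula (integer atomic masses)
#'
#' @param formula An [elemental_formula()] or formula string.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(.ATOMIC_MASS * as.numeric(f))
}

#' Theoretical oxygen demand per gram (specific COD)
#'
#' Balances full oxidation of `CcHhOoNn`: carbon terminates as CO2, hydrogen
#' as H2O, and nitrogen as NH3 (no nitrification, so 3 H per N are diverted
#' from water formation). Moles of O2 per mole of compound are
#' `c + (h - 3n)/4 - o/2`; the specific COD is `32 * molO2 / molar mass`.
#'
#' @param formula An [elemental_formula()] or formula string.
#' @return Specific COD in gCOD per g. Fully oxidized species (e.g. CO2)
#'   return 0.
#' @examples
#' thod_per_gram("C5H7O2N")  # 1.42 gCOD/g biomass
#' thod_per_gram("C6H12O6")  # 1.0667 gCOD/g glucose
#' thod_per_gram("H2")       # 8 gCOD/g
#' thod_per_gram("CH4")      # 4 gCOD/g
#' @export
thod_per_gram <- function(formula) {
  f <- parse_formula(formula)
  c_ <- f[["C"]]; h <- f[["H"]]; o <- f[["O"]]; n <- f[["N"]]
  mol_o2 <- c_ + (h - 3 * n) / 4 - o / 2
  mol_o2 <- max(mol_o2, 0)
  32 * mol_o2 / molar_mass(f)
}

#' Define a nutrient (or metabolite) species
#'
#' @param id Identifier string, e.g. `"glucose"`.
#' @param nutrient_class One of `"amino_acid"`, `"sugar"`, `"starch"`,
#'   `"fiber"`, `"fat"`, `"scfa"`, `"gas"`, `"biomass"`.
#' @param formula Optional formula string or [elemental_formula()].
#' @param cod_specific Optional explicit specific COD (gCOD/g). When both
#'   `formula` and `cod_specific` are given they must agree within 1%.
#' @return A list of class `nutrient_spec`.
#' @export
nutrient_spec <- function(id, nutrient_class, formula = NULL,
                          cod_specific = NULL) {
  classes <- c("amino_acid", "sugar", "starch", "fiber", "fat",
               "scfa", "gas", "biomass")
  nutrient_class <- match.arg(nutrient_class, classes)
  if (is.null(formula) && is.null(cod_specific))
    stop("nutrient '", id, "': need a formula or an explicit cod_specific",
         call. = FALSE)
  thod <- if (!is.null(formula)) thod_per_gram(formula) else NULL
  if (is.null(cod_specific)) cod_specific <- thod
  if (!is.numeric(cod_specific) || cod_specific <= 0)
    stop("nutrient '", id, "': cod_specific must be > 0", call. = FALSE)
  if (!is.null(thod) && thod > 0 &&
      abs(cod_specific - thod) / thod > 0.01)
    stop("nutrient '", id, "': cod_specific ", signif(cod_specific, 4),
         " disagrees with ThOD ", signif(thod, 4), " by more than 1%",
         call. = FALSE)
  structure(list(id = id, nutrient_class = nutrient_class,
                 formula = if (!is.null(formula)) parse_formula(formula),
                 cod_specific = cod_specific),
            class = "nutrient_spec")
}

#' COD of a mass of nutrient
#'
#' @param mass_g Mass in grams (non-negative).
#' @param spec A [nutrient_spec()] or a bare specific COD (gCOD/g).
#' @return gCOD.
#' @export
cod_of_mass <- function(mass_g, spec) {
  if (!is.numeric(mass_g) || any(mass_g < 0))
    stop("mass_g must be non-negative", call. = FALSE)
  sp <- if (inherits(spec, "nutrient_spec")) spec$cod_specific else spec
  if (!is.numeric(sp) || any(sp <= 0))
    stop("specific COD must be positive", call. = FALSE)
  mass_g * sp
}

#' Convert between COD and metabolizable energy
#'
#' A single configurable linear factor (kcal per gCOD). The shipped default of
#' 3.2 kcal/gCOD approximates published regressions between metabolizable
#' energy and metabolizable COD; it is a configuration value, not a model
#' constant, and can be replaced wholesale.
#'
#' @param cod gCOD.
#' @param kcal kcal.
#' @param factor kcal per gCOD, strictly positive.
#' @return `cod_to_kcal`: kcal; `kcal_to_cod`: gCOD.
#' @export
cod_to_kcal <- function(cod, factor = 3.2) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("kcal-per-gCOD factor must be a positive scalar", call. = FALSE)
  cod * factor
}

#' @rdname cod_to_kcal
#' @export
kcal_to_cod <- function(kcal, factor = 3.2) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("kcal-per-gCOD factor must be a positive scalar", call. = FALSE)
  kcal / factor
}

#' Convert a methane gas volume to COD
#'
#' Ideal-gas conversion of a daily CH4 volume to gCOD/d, using 4 gCOD per g
#' CH4 (ThOD of methane) and 16 g/mol.
#'
#' @param ml_per_day Volume in mL/d.
#' @param temp_c Temperature in degrees Celsius (default 25).
#' @param pressure_atm Pressure in atm (default 1).
#' @return gCOD/d.
#' @export
ch4_volume_to_gcod <- function(ml_per_day, temp_c = 25, pressure_atm = 1) {
  if (any(ml_per_day < 0)) stop("volume must be non-negative", call. = FALSE)
  mol <- pressure_atm * (ml_per_day / 1000) / (0.082057 * (273.15 + temp_c))
  mol * 16 * 4
}

#' @export
print.nutrient_spec <- function(x, ...) {
  cat(sprintf("<nutrient_spec> %s [%s]: %.4f gCOD/g\n",
              x$id, x$nutrient_class, x$cod_specific))
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) {
  parts <- vapply(names(x), function(el) {
    n <- x[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format(x), "\n")
  invisible(x)
}
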