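# Nutrient registry: the species the model resolves, with elemental formulas
# and specific COD. Individual amino acids and sugars, starch (digestible and
# resistant), a single fiber class, saturated/unsaturated lipids, and the
# metabolite species (SCFAs, gases, biomass).

#' Default nutrient registry
#'
#' Returns the built-in registry as a data frame with one row per species:
#' `id`, `nutrient_class`, `formula`, `cod_specific` (gCOD/g, computed from
#' the formula with integer atomic masses). Amino acids are free amino acid
#' formulas; cysteine and methionine are omitted because the formula algebra
#' excludes sulfur. Triglyceride formulas (tripalmitin, triolein) represent
#' saturated and unsaturated fat. Fiber and starch share the anhydroglucose
#' unit C6H10O5.
#'
#' @return A data frame of class `nutrient_registry`.
#' @export
default_nutrient_registry <- function() {
  def <- list(
    # amino acids (free forms, no S)
    alanine       = c("amino_acid", "C3H7NO2"),
    arginine      = c("amino_acid", "C6H14N4O2"),
    asparagine    = c("amino_acid", "C4H8N2O3"),
    aspartate     = c("amino_acid", "C4H7NO4"),
    glutamate     = c("amino_acid", "C5H9NO4"),
    glutamine     = c("amino_acid", "C5H10N2O3"),
    glycine       = c("amino_acid", "C2H5NO2"),
    histidine     = c("amino_acid", "C6H9N3O2"),
    isoleucine    = c("amino_acid", "C6H13NO2"),
    leucine       = c("amino_acid", "C6H13NO2"),
    lysine        = c("amino_acid", "C6H14N2O2"),
    phenylalanine = c("amino_acid", "C9H11NO2"),
    proline       = c("amino_acid", "C5H9NO2"),
    serine        = c("amino_acid", "C3H7NO3"),
    threonine     = c("amino_acid", "C4H9NO3"),
    tryptophan    = c("amino_acid", "C11H12N2O2"),
    tyrosine      = c("amino_acid", "C9H11NO3"),
    valine        = c("amino_acid", "C5H11NO2"),
    # sugars
    glucose       = c("sugar", "C6H12O6"),
    fructose      = c("sugar", "C6H12O6"),
    sucrose       = c("sugar", "C12H22O11"),
    lactose       = c("sugar", "C12H22O11"),
    # complex carbohydrate (anhydroglucose polymer unit)
    starch           = c("starch", "C6H10O5"),
    resistant_starch = c("starch", "C6H10O5"),
    fiber            = c("fiber", "C6H10O5"),
    # fats as triglycerides
    fat_saturated   = c("fat", "C51H98O6"),
    fat_unsaturated = c("fat", "C57H104O6"),
    # metabolites
    acetate    = c("scfa", "C2H4O2"),
    propionate = c("scfa", "C3H6O2"),
    butyrate   = c("scfa", "C4H8O2"),
    h2         = c("gas", "H2"),
    ch4        = c("gas", "CH4"),
    biomass    = c("biomass", "C5H7O2N")
  )
  reg <- data.frame(
    id = names(def),
    nutrient_class = vapply(def, `[`, character(1), 1L),
    formula = vapply(def, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  reg$cod_specific <- vapply(reg$formula, thod_per_gram, numeric(1))
  rownames(reg) <- NULL
  class(reg) <- c("nutrient_registry", "data.frame")
  reg
}

#' Read a nutrient registry from CSV
#'
#' Expected columns: `id`, `nutrient_class`, `formula` (may be empty when
#' `cod_specific` is given), optional `cod_specific` override. Each row is
#' validated through [nutrient_spec()], so an explicit `cod_specific` must
#' agree with the formula's ThOD within 1% when both are present.
#'
#' @param path CSV file path.
#' @return A `nutrient_registry` data frame.
#' @export
read_nutrient_registry <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "nutrient_class")
  if (!all(needed %in% names(raw)))
    stop("registry CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$formula)) raw$formula <- NA_character_
  if (is.null(raw$cod_specific)) raw$cod_specific <- NA_real_
  specs <- lapply(seq_len(nrow(raw)), function(i) {
    f <- raw$formula[i]
    cs <- raw$cod_specific[i]
    nutrient_spec(raw$id[i], raw$nutrient_class[i],
                  formula = if (!is.na(f) && nzchar(f)) f else NULL,
                  cod_specific = if (!is.na(cs)) cs else NULL)
  })
  reg <- data.frame(
    id = vapply(specs, `[[`, character(1), "id"),
    nutrient_class = vapply(specs, `[[`, character(1), "nutrient_class"),
    formula = vapply(specs, function(s)
      if (is.null(s$formula)) NA_character_ else format(s$formula),
      character(1)),
    cod_specific = vapply(specs, `[[`, numeric(1), "cod_specific"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(reg$id))
    stop("duplicate nutrient ids in registry", call. = FALSE)
  class(reg) <- c("nutrient_registry", "data.frame")
  reg
}

#' Look up one nutrient in a registry
#'
#' @param registry A `nutrient_registry`.
#' @param id Nutrient id.
#' @return A [nutrient_spec()].
#' @export
registry_lookup <- function(registry, id) {
  i <- match(id, registry$id)
  if (is.na(i))
    stop("unknown nutrient id '", id, "'", call. = FALSE)
  nutrient_spec(registry$id[i], registry$nutrient_class[i],
                formula = if (!is.na(registry$formula[i])) registry$formula[i],
                cod_specific = registry$cod_specific[i])
}

registry_class <- function(registry, ids) {
  i <- match(ids, registry$id)
  if (anyNA(i))
    stop("unknown nutrient id(s): ", paste(ids[is.na(i)], collapse = ", "),
         call. = FALSE)
  registry$nutrient_class[i]
}

registry_cod <- function(registry, ids) {
  i <- match(ids, registry$id)
  if (anyNA(i))
    stop("unknown nutrient id(s): ", paste(ids[is.na(i)], collapse = ", "),
         call. = FALSE)
  registry$cod_specific[i]
}
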