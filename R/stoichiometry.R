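# COD-conserving fermentation stoichiometry. Because anaerobic fermentation
# has no external electron acceptor, every row of the matrix routes 1 gCOD of
# substrate into exactly 1 gCOD of products: a fraction fs of donor electrons
# goes to cell synthesis (biomass), the remaining (1 - fs) splits across the
# catabolic products (acetate, propionate, butyrate, H2) in fixed ratios.

.STOICH_PRODUCTS <- c("acetate", "propionate", "butyrate", "h2",
                      "biomass", "ch4")

#' Build one fermentation stoichiometry row
#'
#' @param fs Fraction of donor electrons to cell synthesis, `0 <= fs < 1`.
#' @param ratios Named numeric with entries among `acetate`, `propionate`,
#'   `butyrate`, `h2`; non-negative, summing to 1 (the catabolic split).
#' @return Named numeric over all products (gCOD product per gCOD substrate);
#'   sums to 1.
#' @examples
#' build_fermentation_row(0.2, c(acetate = 0.5, propionate = 0.25,
#'                               butyrate = 0.15, h2 = 0.10))
#' @export
build_fermentation_row <- function(fs, ratios) {
  if (!is.numeric(fs) || length(fs) != 1L || fs < 0 || fs >= 1)
    stop("fs must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(ratios) || is.null(names(ratios)) || any(ratios < 0))
    stop("ratios must be a named non-negative numeric vector", call. = FALSE)
  extra <- setdiff(names(ratios), c("acetate", "propionate", "butyrate", "h2"))
  if (length(extra))
    stop("unknown product(s) in ratios: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("product ratios must sum to 1 (got ", signif(sum(ratios), 6), ")",
         call. = FALSE)
  row <- stats::setNames(numeric(length(.STOICH_PRODUCTS)), .STOICH_PRODUCTS)
  row[names(ratios)] <- (1 - fs) * ratios
  row["biomass"] <- fs
  row
}

#' Build the hydrogenotrophic methanogenesis row
#'
#' Per gCOD of H2 consumed: `1 - fs_m` gCOD appears as CH4 and `fs_m` as
#' methanogen biomass (donor electrons to synthesis). The acetate carbon the
#' methanogens assimilate is carbon bookkeeping only and does not enter the
#' COD ledger, which keeps the row COD-conserving.
#'
#' @param fs_m Methanogen synthesis fraction, `0 <= fs_m < 1`.
#' @return Named numeric over all products; sums to 1.
#' @export
build_methanogenesis_row <- function(fs_m) {
  if (!is.numeric(fs_m) || length(fs_m) != 1L || fs_m < 0 || fs_m >= 1)
    stop("fs_m must lie in [0, 1)", call. = FALSE)
  row <- stats::setNames(numeric(length(.STOICH_PRODUCTS)), .STOICH_PRODUCTS)
  row["ch4"] <- 1 - fs_m
  row["biomass"] <- fs_m
  row
}

#' Default product-ratio configuration
#'
#' Loads `extdata/stoichiometry_defaults_synthetic.yaml`: a global `fs` (0.2)
#' and `fs_m` (0.08), one catabolic split for all carbohydrate substrates
#' (three SCFAs, no H2 by default), and per-amino-acid splits that include an
#' H2 fraction. The amino-acid ratios are a plausible reconstruction of
#' mixed-culture protein fermentation spectra, shipped as editable config;
#' they are inputs, not fitted values.
#'
#' @param path Optional alternative YAML path.
#' @return A list with `fs`, `fs_m`, `carbohydrate` (named ratios) and
#'   `amino_acids` (list of named ratios).
#' @export
default_product_ratios <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stoichiometry_defaults_synthetic.yaml",
                        package = "damm", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  cfg$carbohydrate <- unlist(cfg$carbohydrate)
  cfg$amino_acids <- lapply(cfg$amino_acids, unlist)
  cfg
}

#' Assemble the full stoichiometry matrix for a registry
#'
#' One row per fermentable substrate (every amino acid, sugar, starch and
#' fiber species in the registry) plus the `h2` methanogenesis row. By
#' default carbohydrate fermentation produces no H2 (products limited to the
#' three main SCFAs); `carb_h2 = TRUE` reroutes a fraction of the
#' carbohydrate catabolic split to H2 for sensitivity studies.
#'
#' @param registry A `nutrient_registry`.
#' @param ratios Product-ratio configuration as from
#'   [default_product_ratios()].
#' @param carb_h2 Allow an H2 fraction in the carbohydrate split (default
#'   FALSE; when TRUE, `ratios$carbohydrate_h2` — a full 4-product split —
#'   is used for carbohydrates if present).
#' @return Matrix with substrate rownames and product colnames
#'   (gCOD product / gCOD substrate), class `stoich_matrix`.
#' @export
build_stoich_matrix <- function(registry, ratios = default_product_ratios(),
                                carb_h2 = FALSE) {
  ferm <- registry[registry$nutrient_class %in%
                     c("amino_acid", "sugar", "starch", "fiber"), ]
  carb_ratios <- ratios$carbohydrate
  if (carb_h2 && !is.null(ratios$carbohydrate_h2))
    carb_ratios <- unlist(ratios$carbohydrate_h2)
  if (!carb_h2 && isTRUE(carb_ratios["h2"] > 0))
    stop("carbohydrate H2 fraction must be 0 unless carb_h2 = TRUE",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(ferm)), function(i) {
    id <- ferm$id[i]
    if (ferm$nutrient_class[i] == "amino_acid") {
      r <- ratios$amino_acids[[id]]
      if (is.null(r))
        stop("no product ratios configured for amino acid '", id, "'",
             call. = FALSE)
    } else {
      r <- carb_ratios
    }
    build_fermentation_row(ratios$fs, r)
  })
  m <- do.call(rbind, c(rows, list(build_methanogenesis_row(ratios$fs_m))))
  rownames(m) <- c(ferm$id, "h2")
  class(m) <- c("stoich_matrix", class(m))
  m
}

#' Validate a stoichiometry matrix
#'
#' Reports (does not throw) COD-conservation and sign violations: every row
#' must sum to 1 within 1e-9 and contain no negative entries.
#'
#' @param m A matrix with substrate rownames and product colnames.
#' @return Character vector of violation messages; empty when well formed.
#' @export
validate_stoich_matrix <- function(m) {
  out <- character(0)
  for (s in rownames(m)) {
    row <- m[s, ]
    if (any(row < 0))
      out <- c(out, sprintf(
        "substrate '%s': negative entry for product(s) %s", s,
        paste(colnames(m)[row < 0], collapse = ", ")))
    if (abs(sum(row) - 1) > 1e-9)
      out <- c(out, sprintf(
        "substrate '%s': row sums to %.6g, not 1 (COD not conserved)",
        s, sum(row)))
  }
  out
}
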