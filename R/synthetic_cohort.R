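# Self-contained synthetic crossover cohort: two diet templates (one
# fiber/resistant-starch-rich, one low-fiber "western" style), lognormal
# colonic transit times, a mixture of methanogen-positive and -negative
# participants, and noisy pseudo-measurements generated by the model itself.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort generator specification
#'
#' Defaults emulate the structure of a 17-person randomized crossover study:
#' total gross intake around 630 +/- 105 gCOD/d (energy-matched across the
#' two diets within a participant), lognormal colonic transit time with
#' median 1.5 d (sdlog 0.4, spanning the typical 1-2 day range), roughly 30%
#' of participants methanogen-positive with lognormal fecal mcrA counts, and
#' multiplicative Gaussian measurement noise per channel.
#'
#' @param n_participants Number of participants (each sees both diets).
#' @param total_cod_mean,total_cod_sd Normal distribution of the
#'   per-participant daily gross COD target (gCOD/d), truncated at 300.
#' @param ctt_meanlog,ctt_sdlog Lognormal CTT parameters (days).
#' @param methanogen_pos_frac Fraction of participants carrying methanogens.
#' @param mcra_meanlog,mcra_sdlog Lognormal fecal mcrA copy-number
#'   parameters for methanogen-positive participants.
#' @param xm_factor Generating methanogen retention factor used when the
#'   cohort's pseudo-measurements are simulated.
#' @param noise Named multiplicative noise sd per measurement channel
#'   (`fecal`, `scfa`, `ch4`, `h2`).
#' @param seed Integer seed; identical spec + seed gives an identical cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 17,
                        total_cod_mean = 630, total_cod_sd = 105,
                        ctt_meanlog = log(1.5), ctt_sdlog = 0.4,
                        methanogen_pos_frac = 0.3,
                        mcra_meanlog = log(5e11), mcra_sdlog = 1,
                        xm_factor = 2.58,
                        noise = c(fecal = 0.05, scfa = 0.10,
                                  ch4 = 0.10, h2 = 0.10),
                        seed = 1) {
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (methanogen_pos_frac < 0 || methanogen_pos_frac > 1)
    stop("methanogen_pos_frac must lie in [0, 1]", call. = FALSE)
  if (total_cod_sd < 0 || ctt_sdlog < 0 || any(noise < 0))
    stop("spread parameters must be non-negative", call. = FALSE)
  if (total_cod_mean <= 0 || xm_factor <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  need <- c("fecal", "scfa", "ch4", "h2")
  if (!all(need %in% names(noise)))
    stop("noise needs entries: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(n_participants = n_participants,
                 total_cod_mean = total_cod_mean, total_cod_sd = total_cod_sd,
                 ctt_meanlog = ctt_meanlog, ctt_sdlog = ctt_sdlog,
                 methanogen_pos_frac = methanogen_pos_frac,
                 mcra_meanlog = mcra_meanlog, mcra_sdlog = mcra_sdlog,
                 xm_factor = xm_factor, noise = noise, seed = seed),
            class = "cohort_spec")
}

# amino-acid profile of dietary protein (normalized in code)
.PROTEIN_PROFILE <- c(
  glutamate = 0.19, aspartate = 0.09, leucine = 0.09, lysine = 0.07,
  proline = 0.07, valine = 0.06, alanine = 0.06, arginine = 0.06,
  serine = 0.06, glycine = 0.05, isoleucine = 0.05, threonine = 0.05,
  phenylalanine = 0.05, tyrosine = 0.04, histidine = 0.03,
  tryptophan = 0.01, glutamine = 0.02, asparagine = 0.02
)

.food_row <- function(food_id, ...) {
  parts <- c(...)
  data.frame(food_id = food_id, nutrient_id = names(parts),
             fraction = unname(parts), stringsAsFactors = FALSE)
}

# expand a "protein" pseudo-nutrient into individual amino acids
.expand_protein <- function(parts) {
  if (!"protein" %in% names(parts)) return(parts)
  prof <- .PROTEIN_PROFILE / sum(.PROTEIN_PROFILE)
  aa <- prof * parts[["protein"]]
  parts <- parts[names(parts) != "protein"]
  merged <- c(parts, aa)
  tapply(merged, names(merged), sum)
}

#' Synthetic food composition library
#'
#' A dozen composite foods with per-gram nutrient fractions (protein expanded
#' into individual amino acids with a typical dietary profile). Whole-grain
#' cereal, legumes, vegetables and fruit carry the fiber and resistant
#' starch; refined bread, a sweet beverage, beef, cheese, butter and refined
#' potato make up the low-fiber template.
#'
#' @return Data frame with columns `food_id`, `nutrient_id`, `fraction`.
#' @export
synthetic_food_library <- function() {
  foods <- list(
    wholegrain_cereal = c(protein = 0.12, starch = 0.50,
                          resistant_starch = 0.05, fiber = 0.11,
                          sucrose = 0.02, fat_unsaturated = 0.03),
    legumes = c(protein = 0.21, starch = 0.35, resistant_starch = 0.08,
                fiber = 0.15, sucrose = 0.02, fat_unsaturated = 0.02),
    vegetables = c(protein = 0.02, starch = 0.03, fiber = 0.03,
                   glucose = 0.015, fructose = 0.015),
    fruit = c(glucose = 0.03, fructose = 0.05, sucrose = 0.02,
              fiber = 0.02),
    poultry = c(protein = 0.27, fat_saturated = 0.02,
                fat_unsaturated = 0.03),
    olive_oil = c(fat_unsaturated = 0.85, fat_saturated = 0.14),
    white_bread = c(protein = 0.09, starch = 0.47, fiber = 0.025,
                    sucrose = 0.03, fat_saturated = 0.01,
                    fat_unsaturated = 0.02),
    sweet_beverage = c(sucrose = 0.05, glucose = 0.03, fructose = 0.03),
    beef = c(protein = 0.26, fat_saturated = 0.08, fat_unsaturated = 0.07),
    cheese = c(protein = 0.25, fat_saturated = 0.20,
               fat_unsaturated = 0.07, lactose = 0.01),
    butter = c(fat_saturated = 0.51, fat_unsaturated = 0.23),
    potato_refined = c(starch = 0.15, protein = 0.02, fat_saturated = 0.03,
                       fat_unsaturated = 0.05, fiber = 0.01)
  )
  do.call(rbind, lapply(names(foods), function(id)
    .food_row(id, .expand_protein(foods[[id]]))))
}

# daily menus in grams before scaling to the participant's COD target
.DIET_TEMPLATES <- list(
  MBD = c(wholegrain_cereal = 90, legumes = 70, vegetables = 250,
          fruit = 200, poultry = 230, olive_oil = 80),
  WD = c(white_bread = 320, sweet_beverage = 450, beef = 140, cheese = 70,
         butter = 20, potato_refined = 450, fruit = 180, vegetables = 120)
)

#' Generate a synthetic crossover cohort
#'
#' Every participant receives both diet templates (MBD-like fiber-rich and
#' WD-like low-fiber) scaled to the same per-participant daily gross COD
#' target, so diets are energy-matched within person while the fiber and
#' resistant-starch COD share is strictly higher on the MBD-like template.
#' CTT is drawn per participant-diet; mcrA counts are zero for
#' methanogen-negative participants.
#'
#' @param spec A [cohort_spec()].
#' @param registry A `nutrient_registry` (used to scale menus to COD).
#' @return A list of class `damm_cohort`: `participants` (one row per
#'   participant-diet: `participant_id`, `diet_label`, `ctt_days`,
#'   `mcra_copies`), `foods` (food log rows), `composition`, and the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            registry = default_nutrient_registry()) {
  composition <- synthetic_food_library()
  with_seed(spec$seed, {
    n <- spec$n_participants
    ids <- sprintf("P%02d", seq_len(n))
    target <- stats::rnorm(n, spec$total_cod_mean, spec$total_cod_sd)
    target <- pmax(target, 300)
    pos <- stats::runif(n) < spec$methanogen_pos_frac

    rows <- list(); logs <- list()
    for (i in seq_len(n)) {
      for (diet in names(.DIET_TEMPLATES)) {
        menu <- .DIET_TEMPLATES[[diet]]
        base <- aggregate_diet(
          data.frame(food_id = names(menu), grams_per_day = unname(menu)),
          composition, registry)
        scale <- target[i] / base$total
        ctt <- stats::rlnorm(1, spec$ctt_meanlog, spec$ctt_sdlog)
        mcra <- if (pos[i])
          stats::rlnorm(1, spec$mcra_meanlog, spec$mcra_sdlog) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], diet_label = diet,
          ctt_days = ctt, mcra_copies = mcra,
          target_gcod = target[i], stringsAsFactors = FALSE)
        logs[[length(logs) + 1L]] <- data.frame(
          participant_id = ids[i], diet_label = diet,
          food_id = names(menu), grams_per_day = unname(menu) * scale,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(participants = do.call(rbind, rows),
                   foods = do.call(rbind, logs),
                   composition = composition, spec = spec),
              class = "damm_cohort")
  })
}

#' @export
print.damm_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf(
    "<damm_cohort> %d participants x %d diets (%d rows); %d methanogen-positive; CTT %.2f-%.2f d\n",
    length(unique(p$participant_id)), length(unique(p$diet_label)), nrow(p),
    sum(p$mcra_copies > 0 & !duplicated(p$participant_id)),
    min(p$ctt_days), max(p$ctt_days)))
  invisible(x)
}

#' Diet intake for one cohort row
#'
#' @param cohort A `damm_cohort`.
#' @param participant_id,diet_label Row selector.
#' @param registry A `nutrient_registry`.
#' @return A `diet_intake`.
#' @export
cohort_diet_intake <- function(cohort, participant_id, diet_label,
                               registry = default_nutrient_registry()) {
  sel <- cohort$foods$participant_id == participant_id &
    cohort$foods$diet_label == diet_label
  if (!any(sel))
    stop("no food log for ", participant_id, " on ", diet_label,
         call. = FALSE)
  aggregate_diet(cohort$foods[sel, c("food_id", "grams_per_day")],
                 cohort$composition, registry)
}

#' Simulate pseudo-measurements for a cohort
#'
#' Runs the model for every participant-diet with the spec's generating
#' retention factor and perturbs each output channel with multiplicative
#' Gaussian noise, `measured = predicted * (1 + eps)` with eps truncated so
#' values stay positive. With `noise_scale = 0` the measurements equal the
#' model predictions exactly.
#'
#' @param cohort A `damm_cohort` from [generate_cohort()].
#' @param config A [damm_config()].
#' @param noise_scale Multiplier on the spec's per-channel noise sds (0 for
#'   noiseless, 1 for the spec's defaults).
#' @param seed Seed for the noise draws; defaults to `spec$seed + 1000`.
#' @return Data frame, one row per participant-diet: intake and measured
#'   fecal COD, per-acid fecal SCFA COD, CH4 and H2 COD (gCOD/d).
#' @export
simulate_measurements <- function(cohort, config = damm_config(),
                                  noise_scale = 1,
                                  seed = cohort$spec$seed + 1000) {
  p <- cohort$participants
  gen <- config$methanogen
  gen$xm_factor <- cohort$spec$xm_factor
  truth <- lapply(seq_len(nrow(p)), function(i) {
    diet <- cohort_diet_intake(cohort, p$participant_id[i], p$diet_label[i],
                               config$registry)
    x_m <- xm0_from_mcra(p$mcra_copies[i], gen)
    run_damm(diet, p$ctt_days[i], x_m, config)
  })
  sd <- cohort$spec$noise * noise_scale
  noisy <- function(x, channel) {
    if (sd[[channel]] == 0) return(x)
    eps <- stats::rnorm(length(x), 0, sd[[channel]])
    for (iter in 1:100) {
      bad <- (1 + eps) <= 0.01
      if (!any(bad)) break
      eps[bad] <- stats::rnorm(sum(bad), 0, sd[[channel]])
    }
    x * (1 + eps)
  }
  g <- function(f) vapply(truth, f, numeric(1))
  with_seed(seed, data.frame(
    participant_id = p$participant_id, diet_label = p$diet_label,
    intake_gcod = g(function(r) r$cod_g_ugi),
    fecal_cod = noisy(g(function(r) r$cod_f), "fecal"),
    fecal_scfa_acetate = noisy(g(function(r) r$scfa_fecal[["acetate"]]), "scfa"),
    fecal_scfa_propionate = noisy(g(function(r) r$scfa_fecal[["propionate"]]), "scfa"),
    fecal_scfa_butyrate = noisy(g(function(r) r$scfa_fecal[["butyrate"]]), "scfa"),
    ch4_gcod_per_day = noisy(g(function(r) r$cod_ch4), "ch4"),
    h2_gcod_per_day = noisy(g(function(r) r$h2_gas), "h2"),
    stringsAsFactors = FALSE))
}
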