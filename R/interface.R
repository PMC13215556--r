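# Orchestration: run the model across a cohort, evaluate predictions against
# measurements, write/read the CSV interchange formats.

#' Run the model for every participant-diet in a cohort
#'
#' @param cohort A `damm_cohort` (or compatible list with `participants`,
#'   `foods`, `composition`).
#' @param config A [damm_config()].
#' @param xm_factor Methanogen retention factor applied on top of the
#'   mcrA-derived seeding (1 = counts taken at face value).
#' @return Data frame, one row per participant-diet: the full COD ledger
#'   (see [as.data.frame.damm_result()]) plus macronutrient grams and the
#'   Atwater baseline prediction (`atwater_cod_m`).
#' @export
run_damm_cohort <- function(cohort, config = damm_config(), xm_factor = 1) {
  p <- cohort$participants
  mg <- config$methanogen
  mg$xm_factor <- xm_factor
  at <- atwater_params(kcal_per_gcod = config$kcal_per_gcod)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    sel <- cohort$foods$participant_id == p$participant_id[i] &
      cohort$foods$diet_label == p$diet_label[i]
    foods <- cohort$foods[sel, c("food_id", "grams_per_day")]
    diet <- aggregate_diet(foods, cohort$composition, config$registry)
    x_m <- xm0_from_mcra(p$mcra_copies[i], mg)
    res <- run_damm(diet, p$ctt_days[i], x_m, config)
    grams <- diet_macronutrient_grams(foods, cohort$composition,
                                      config$registry)
    cbind(
      data.frame(participant_id = p$participant_id[i],
                 diet_label = p$diet_label[i],
                 ctt_days = p$ctt_days[i],
                 mcra_copies = p$mcra_copies[i],
                 stringsAsFactors = FALSE),
      as.data.frame(res),
      data.frame(protein_g = grams[["protein_g"]],
                 carb_g = grams[["carb_g"]], fat_g = grams[["fat_g"]],
                 atwater_cod_m = as.numeric(
                   atwater_cod_m(grams[["protein_g"]], grams[["carb_g"]],
                                 grams[["fat_g"]], at))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# derive "measured" metabolizable COD from measurement channels
measured_cod_m <- function(measurements,
                           definition = c("fecal_and_gas", "fecal_only")) {
  definition <- match.arg(definition)
  m <- measurements$intake_gcod - measurements$fecal_cod
  if (definition == "fecal_and_gas") {
    ch4 <- if (!is.null(measurements$ch4_gcod_per_day))
      measurements$ch4_gcod_per_day else 0
    h2 <- if (!is.null(measurements$h2_gcod_per_day))
      measurements$h2_gcod_per_day else 0
    m <- m - ch4 - h2
  }
  m
}

#' Evaluate metabolizable-COD predictions against measurements
#'
#' Joins model results to measurements by participant and diet, derives the
#' measured metabolizable COD from the chosen definition, and returns
#' per-diet and combined agreement reports for the requested method.
#'
#' @param results Output of [run_damm_cohort()].
#' @param measurements Output of [simulate_measurements()] (or a real
#'   measurement table with the same columns).
#' @param method `"damm"` (model ledger COD_m) or `"atwater"` (baseline).
#' @param definition Measured-COD_m definition; defaults to the ledger
#'   definition `"fecal_and_gas"`. See [damm_config()].
#' @return A list of class `damm_evaluation`: one [agreement_report()] per
#'   diet label plus `"combined"`, with `method` and a `table` (one row per
#'   report, mirroring a per-diet/combined statistics table).
#' @export
evaluate_predictions <- function(results, measurements,
                                 method = c("damm", "atwater"),
                                 definition = c("fecal_and_gas",
                                                "fecal_only")) {
  method <- match.arg(method)
  definition <- match.arg(definition)
  key <- c("participant_id", "diet_label")
  j <- merge(results, measurements, by = key)
  if (nrow(j) != nrow(results) || nrow(j) != nrow(measurements))
    stop("results and measurements do not match one-to-one on ",
         "participant_id x diet_label", call. = FALSE)
  pred <- if (method == "damm") j$cod_m else j$atwater_cod_m
  meas <- measured_cod_m(j, definition)
  groups <- c(split(seq_len(nrow(j)), j$diet_label),
              list(combined = seq_len(nrow(j))))
  reports <- lapply(groups, function(ix)
    agreement_report(pred[ix], meas[ix]))
  tab <- do.call(rbind, lapply(names(reports), function(nm)
    cbind(data.frame(method = method, treatment = nm,
                     stringsAsFactors = FALSE),
          as.data.frame(reports[[nm]]))))
  structure(list(method = method, definition = definition,
                 reports = reports, table = tab),
            class = "damm_evaluation")
}

#' @export
print.damm_evaluation <- function(x, ...) {
  cat(sprintf("Metabolizable-COD agreement, method = %s (measured as %s)\n",
              x$method, x$definition))
  tab <- x$table
  tab$r2 <- sprintf("%.2f%%", 100 * tab$r2)
  print(tab[, c("treatment", "n", "r2", "sigma_est", "mean_diff",
                "t", "t_p", "tau", "tau_p")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare model and baseline on the same measurements
#'
#' @inheritParams evaluate_predictions
#' @return Data frame with one row per method x (diet, combined) cell.
#' @export
compare_methods <- function(results, measurements,
                            definition = c("fecal_and_gas", "fecal_only")) {
  definition <- match.arg(definition)
  rbind(
    evaluate_predictions(results, measurements, "damm", definition)$table,
    evaluate_predictions(results, measurements, "atwater", definition)$table
  )
}

#' Write cohort CSVs
#'
#' Writes the interchange files a shell run reads: `participants.csv`
#' (`participant_id`, `diet_label`, `ctt_days`, `mcra_copies`), `diet.csv`
#' (food log), `composition.csv` (per-100 g nutrient content).
#'
#' @param cohort A `damm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             diet = file.path(dir, "diet.csv"),
             composition = file.path(dir, "composition.csv"))
  utils::write.csv(cohort$participants[
    c("participant_id", "diet_label", "ctt_days", "mcra_copies")],
    paths["participants"], row.names = FALSE)
  utils::write.csv(cohort$foods, paths["diet"], row.names = FALSE)
  comp <- cohort$composition
  comp$g_per_100g <- comp$fraction * 100
  utils::write.csv(comp[c("food_id", "nutrient_id", "g_per_100g")],
                   paths["composition"], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSVs
#'
#' Counterpart of [write_cohort_csvs()].
#'
#' @param dir Directory holding `participants.csv`, `diet.csv`,
#'   `composition.csv`.
#' @return A `damm_cohort` (without a generator spec).
#' @export
read_cohort_csvs <- function(dir) {
  pf <- file.path(dir, "participants.csv")
  df <- file.path(dir, "diet.csv")
  cf <- file.path(dir, "composition.csv")
  for (f in c(pf, df, cf))
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  participants <- utils::read.csv(pf, stringsAsFactors = FALSE)
  needed <- c("participant_id", "diet_label", "ctt_days", "mcra_copies")
  if (!all(needed %in% names(participants)))
    stop("participants.csv needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  structure(list(participants = participants,
                 foods = read_diet_csv(df),
                 composition = read_composition_csv(cf),
                 spec = NULL),
            class = "damm_cohort")
}
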