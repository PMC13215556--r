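# shared fixtures built in code

# a randomized colon-reactor instance: one amino acid, one carbohydrate and a
# fat stream; every fourth instance pushes the carbohydrate influent well
# below the washout threshold so both steady-state branches are exercised
random_reactor_instance <- function(i, registry, stoich) {
  ctt <- stats::runif(1, 0.5, 3)
  aa <- sample(c("alanine", "leucine", "glutamate", "lysine"), 1)
  carb <- sample(c("glucose", "fiber", "starch"), 1)
  q <- stats::setNames(stats::runif(3, 0.5, 30),
                       c(aa, carb, "fat_unsaturated"))
  if (i %% 4 == 0) q[2] <- 0.3 / ctt^2  # below washout threshold for any k >= 1
  x_m <- if (i %% 3 == 0) stats::runif(1, 0, 1) else 0
  list(influent = q, ctt = ctt, x_m = x_m)
}

# max elementwise deviation with a unit floor, used for steady-state ledgers
max_rel_dev <- function(a, b) {
  max(abs(unlist(a) - unlist(b)) / pmax(abs(unlist(b)), 1))
}

# small fixed diet used where a full cohort would be overkill
tiny_diet <- function(registry = default_nutrient_registry()) {
  comp <- data.frame(
    food_id = "meal",
    nutrient_id = c("leucine", "glucose", "fiber", "fat_unsaturated"),
    fraction = c(0.05, 0.10, 0.04, 0.06))
  aggregate_diet(data.frame(food_id = "meal", grams_per_day = 500),
                 comp, registry)
}
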