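# The colon as a CSTR whose solids retention time equals the measured colonic
# transit time (CTT). All pools are gCOD amounts; effluent flux = amount/CTT;
# microbial rates are mixed second order (k * S * X, k in 1/(gCOD d)).
# Closed-form steady states are the default solver; a stiff ODE integrator
# over the same balances serves as an independent oracle.

#' Kinetic parameter set
#'
#' Defaults: fat absorption `k_f_abs` 0.48 1/d; simple-sugar fermentation
#' `k_c_ferm` 10, complex-carbohydrate hydrolysis `k_c_hyd` 1, protein
#' hydrolysis `k_p_hyd` 5, methanogenesis `k_m` 0.5 (all 1/(gCOD d));
#' SCFA-absorption half-saturation `K_scfa_abs` 0.02 d (the CTT at which half
#' of produced SCFAs are absorbed).
#'
#' @param k_f_abs,k_c_ferm,k_c_hyd,k_p_hyd,k_m,K_scfa_abs Strictly positive
#'   scalars, units as above.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_f_abs = 0.48, k_c_ferm = 10, k_c_hyd = 1,
                           k_p_hyd = 5, k_m = 0.5, K_scfa_abs = 0.02) {
  p <- list(k_f_abs = k_f_abs, k_c_ferm = k_c_ferm, k_c_hyd = k_c_hyd,
            k_p_hyd = k_p_hyd, k_m = k_m, K_scfa_abs = K_scfa_abs)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1))))
    stop("all kinetic parameters must be strictly positive scalars",
         call. = FALSE)
  structure(p, class = "kinetic_params")
}

# rate constant for a fermentable substrate, by nutrient class
kinetic_rate_for_class <- function(nutrient_class, kinetics) {
  switch(nutrient_class,
         amino_acid = kinetics$k_p_hyd,
         sugar = kinetics$k_c_ferm,
         starch = ,
         fiber = kinetics$k_c_hyd,
         stop("no fermentation kinetics for class '", nutrient_class, "'",
              call. = FALSE))
}

#' Mixed second-order rate
#'
#' `k * S * X`: rate proportional to both the substrate amount and the
#' biomass amount, the form used for hydrolysis, fermentation and
#' methanogenesis.
#'
#' @param k Rate constant, 1/(gCOD d).
#' @param S Substrate amount, gCOD.
#' @param X Biomass amount, gCOD.
#' @return Rate in gCOD/d.
#' @export
rate_mixed_second_order <- function(k, S, X) {
  if (any(c(k, S, X) < 0))
    stop("rate inputs must be non-negative", call. = FALSE)
  k * S * X
}

#' Fraction of produced SCFAs absorbed in the colon
#'
#' Saturation relationship in colonic transit time:
#' `e = CTT / (CTT + K_scfa_abs)`. At `CTT = K_scfa_abs` exactly half of the
#' microbially produced SCFAs are absorbed.
#'
#' @param ctt Colonic transit time, days (>= 0).
#' @param K_scfa_abs Half-saturation constant, days (> 0); default 0.02 d.
#' @return Fraction in `[0, 1)`.
#' @export
scfa_absorption_fraction <- function(ctt, K_scfa_abs = 0.02) {
  if (any(ctt < 0)) stop("CTT must be non-negative", call. = FALSE)
  if (any(K_scfa_abs <= 0)) stop("K_scfa_abs must be positive", call. = FALSE)
  ctt / (ctt + K_scfa_abs)
}

#' Steady state of one fermentable substrate and its biomass pool
#'
#' CSTR balances `dS/dt = Q - S/CTT - kSX` and `dX/dt = YkSX - X/CTT`.
#' The nontrivial steady state is `S* = 1/(Y k CTT)`,
#' `X* = Y CTT (Q - S*/CTT)`, valid when the influent exceeds the washout
#' threshold `Q > 1/(Y k CTT^2)`; below it, growth cannot match dilution and
#' the biomass pool washes out (`X* = 0`, `S* = Q CTT`).
#'
#' @param q_in Influent COD, gCOD/d (>= 0).
#' @param k Mixed second-order rate constant, 1/(gCOD d).
#' @param yield Biomass yield Y, gCOD biomass per gCOD substrate (= fs).
#' @param ctt Colonic transit time, d (> 0).
#' @return List: `S` and `X` (gCOD), `r_ut` (substrate utilization, gCOD/d),
#'   `washout` (logical).
#' @export
steady_state_substrate <- function(q_in, k, yield, ctt) {
  if (ctt <= 0) stop("CTT must be positive", call. = FALSE)
  if (q_in < 0 || k <= 0 || yield <= 0)
    stop("q_in must be >= 0; k and yield must be > 0", call. = FALSE)
  s_star <- 1 / (yield * k * ctt)
  x_star <- yield * ctt * (q_in - s_star / ctt)
  if (x_star > 0) {
    list(S = s_star, X = x_star, r_ut = q_in - s_star / ctt, washout = FALSE)
  } else {
    list(S = q_in * ctt, X = 0, r_ut = 0, washout = TRUE)
  }
}

#' Steady state of a colonic fat pool
#'
#' First-order absorption competes with washout:
#' `fat* = Q / (1/CTT + k_f_abs)`; absorbed `= k_f_abs * fat*`; fecal
#' `= fat*/CTT`. Absorbed + fecal equals the influent exactly.
#'
#' @param q_in Influent fat COD, gCOD/d (>= 0).
#' @param k_f_abs First-order absorption constant, 1/d.
#' @param ctt Colonic transit time, d (> 0).
#' @return List: `fat` (gCOD), `absorbed`, `fecal` (gCOD/d).
#' @export
steady_state_fat <- function(q_in, k_f_abs, ctt) {
  if (ctt <= 0) stop("CTT must be positive", call. = FALSE)
  if (q_in < 0 || k_f_abs <= 0)
    stop("q_in must be >= 0 and k_f_abs > 0", call. = FALSE)
  fat <- q_in / (1 / ctt + k_f_abs)
  list(fat = fat, absorbed = k_f_abs * fat, fecal = fat / ctt)
}

#' Steady state of the H2 pool under methanogenesis
#'
#' H2 produced by amino-acid fermentation is either consumed by methanogens
#' (rate `k_m * H2 * X_M`) or leaves as gas (`H2/CTT`):
#' `H2* = R_prod / (k_m X_M + 1/CTT)`. Consumption + gas equals production
#' exactly.
#'
#' @param r_prod H2 production rate, gCOD/d (>= 0).
#' @param k_m Methanogenesis rate constant, 1/(gCOD d).
#' @param x_m Methanogen biomass, gCOD (>= 0; 0 means no methanogens).
#' @param ctt Colonic transit time, d (> 0).
#' @return List: `H2` (gCOD), `r_meth` (H2 COD consumed, gCOD/d), `h2_gas`
#'   (gCOD/d).
#' @export
steady_state_h2 <- function(r_prod, k_m, x_m, ctt) {
  if (ctt <= 0) stop("CTT must be positive", call. = FALSE)
  if (r_prod < 0 || k_m < 0 || x_m < 0)
    stop("inputs must be non-negative", call. = FALSE)
  h2 <- r_prod / (k_m * x_m + 1 / ctt)
  list(H2 = h2, r_meth = k_m * h2 * x_m, h2_gas = h2 / ctt)
}

# split an influent vector into fermentables and fats, with per-substrate
# rate constants and stoichiometry rows resolved
.lgi_arrange <- function(influent, stoich, kinetics, registry) {
  if (any(influent < 0)) stop("influent COD must be non-negative", call. = FALSE)
  ids <- names(influent)
  cls <- registry_class(registry, ids)
  ok <- cls %in% c("amino_acid", "sugar", "starch", "fiber", "fat")
  if (any(!ok))
    stop("influent contains non-substrate species: ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  ferm_ids <- ids[cls != "fat"]
  missing <- setdiff(ferm_ids[influent[ferm_ids] > 0], rownames(stoich))
  if (length(missing))
    stop("no stoichiometry row for substrate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ferm_ids <- intersect(ferm_ids, rownames(stoich))
  list(ferm_ids = ferm_ids,
       fat_ids = ids[cls == "fat"],
       k = vapply(cls[match(ferm_ids, ids)], kinetic_rate_for_class,
                  numeric(1), kinetics = kinetics))
}

# assemble the full ledger from per-substrate steady states; shared by the
# closed-form solver and the ODE endpoint
.lgi_ledger <- function(influent, arr, sub_states, h2_state, fat_states,
                        stoich, kinetics, ctt, x_m) {
  ferm_ids <- arr$ferm_ids
  fat_ids <- arr$fat_ids
  acids <- c("acetate", "propionate", "butyrate")

  r_ut <- vapply(sub_states, `[[`, numeric(1), "r_ut")
  S <- vapply(sub_states, `[[`, numeric(1), "S")
  X <- vapply(sub_states, `[[`, numeric(1), "X")
  names(r_ut) <- names(S) <- names(X) <- ferm_ids

  scfa_prod <- stats::setNames(numeric(3), acids)
  for (a in acids)
    scfa_prod[a] <- sum(r_ut * stoich[ferm_ids, a])
  e_scfa <- scfa_absorption_fraction(ctt, kinetics$K_scfa_abs)
  scfa_absorbed <- e_scfa * scfa_prod
  scfa_fecal <- (1 - e_scfa) * scfa_prod

  ch4 <- stoich["h2", "ch4"] * h2_state$r_meth
  meth_growth <- stoich["h2", "biomass"] * h2_state$r_meth

  fat_absorbed <- vapply(fat_states, `[[`, numeric(1), "absorbed")
  fat_fecal <- vapply(fat_states, `[[`, numeric(1), "fecal")
  fat_pool <- vapply(fat_states, `[[`, numeric(1), "fat")
  names(fat_absorbed) <- names(fat_fecal) <- names(fat_pool) <- fat_ids

  fecal_substrate <- sum(S) / ctt
  biomass_washout <- sum(X) / ctt + meth_growth
  fecal_total <- fecal_substrate + biomass_washout + sum(scfa_fecal) +
    sum(fat_fecal)
  absorbed_total <- sum(scfa_absorbed) + sum(fat_absorbed)
  influent_total <- sum(influent)
  out_total <- absorbed_total + fecal_total + ch4 + h2_state$h2_gas
  balance_rel <- if (influent_total > 0)
    abs(influent_total - out_total) / influent_total else abs(out_total)

  structure(list(
    ctt = ctt, x_m = x_m, e_scfa = e_scfa,
    substrate = data.frame(id = ferm_ids, S = unname(S), X = unname(X),
                           r_ut = unname(r_ut), k = unname(arr$k),
                           stringsAsFactors = FALSE),
    h2_pool = h2_state$H2, h2_prod = h2_state$r_meth + h2_state$h2_gas,
    r_meth = h2_state$r_meth, h2_gas = h2_state$h2_gas,
    ch4 = ch4, meth_growth = meth_growth,
    scfa_production = scfa_prod, scfa_absorbed = scfa_absorbed,
    scfa_fecal = scfa_fecal,
    fat_pool = fat_pool, fat_absorbed = fat_absorbed, fat_fecal = fat_fecal,
    fecal_substrate = fecal_substrate, fecal_biomass = biomass_washout,
    fecal_scfa = sum(scfa_fecal), fecal_fat = sum(fat_fecal),
    fecal_total = fecal_total,
    absorbed_scfa = sum(scfa_absorbed), absorbed_fat = sum(fat_absorbed),
    absorbed_total = absorbed_total,
    influent_total = influent_total, balance_rel_error = balance_rel
  ), class = "lgi_steady_state")
}

#' Solve the colon reactor at steady state
#'
#' Each fermentable substrate is uncoupled from the others given the
#' stoichiometry, so per-substrate closed forms apply; the H2/methanogenesis
#' chain is solved after amino-acid fermentation, with the methanogen pool
#' held at the seeded `x_m` (slow growers; their growth COD is routed to
#' fecal biomass). SCFA absorption follows the transit-time saturation
#' fraction; residual fat is absorbed first order.
#'
#' @param influent Named numeric, gCOD/d per nutrient entering the colon
#'   (classes amino_acid, sugar, starch, fiber, fat).
#' @param ctt Colonic transit time, d (> 0).
#' @param x_m Methanogen biomass, gCOD (>= 0).
#' @param stoich Stoichiometry matrix from [build_stoich_matrix()].
#' @param kinetics A [kinetic_params()].
#' @param registry A `nutrient_registry`.
#' @return An `lgi_steady_state` list holding pools, rates and the fecal /
#'   absorbed / gas COD ledger; `balance_rel_error` reports ledger closure.
#' @export
solve_lgi <- function(influent, ctt, x_m, stoich = NULL,
                      kinetics = kinetic_params(),
                      registry = default_nutrient_registry()) {
  if (ctt <= 0) stop("CTT must be positive", call. = FALSE)
  if (x_m < 0) stop("methanogen biomass must be non-negative", call. = FALSE)
  if (is.null(stoich)) stoich <- build_stoich_matrix(registry)
  viol <- validate_stoich_matrix(stoich)
  if (length(viol))
    stop("invalid stoichiometry:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  arr <- .lgi_arrange(influent, stoich, kinetics, registry)

  sub_states <- lapply(seq_along(arr$ferm_ids), function(i) {
    id <- arr$ferm_ids[i]
    q <- influent[[id]]
    if (q == 0) return(list(S = 0, X = 0, r_ut = 0, washout = TRUE))
    steady_state_substrate(q, arr$k[i], stoich[id, "biomass"], ctt)
  })
  r_ut <- vapply(sub_states, `[[`, numeric(1), "r_ut")
  r_h2 <- sum(r_ut * stoich[arr$ferm_ids, "h2"])
  h2_state <- steady_state_h2(r_h2, kinetics$k_m, x_m, ctt)
  fat_states <- lapply(arr$fat_ids, function(id)
    steady_state_fat(influent[[id]], kinetics$k_f_abs, ctt))

  .lgi_ledger(influent, arr, sub_states, h2_state, fat_states,
              stoich, kinetics, ctt, x_m)
}

#' @export
print.lgi_steady_state <- function(x, ...) {
  cat(sprintf(
    "<lgi_steady_state> influent %.2f gCOD/d | SCFA abs %.2f, fat abs %.2f, fecal %.2f, CH4 %.4f, H2 gas %.4f gCOD/d | ledger rel err %.1e\n",
    x$influent_total, x$absorbed_scfa, x$absorbed_fat, x$fecal_total,
    x$ch4, x$h2_gas, x$balance_rel_error))
  invisible(x)
}

#' Integrate the colon reactor balances in time
#'
#' Independent check on [solve_lgi()]: the same CSTR balances
#' (`dS = Q - S/CTT - kSX`, `dX = YkSX - X/CTT`, H2 and fat pools likewise)
#' integrated with a stiff solver. At long horizons the endpoint converges to
#' the closed-form steady state (exponentially, except arbitrarily close to
#' the washout threshold).
#'
#' @inheritParams solve_lgi
#' @param horizon Integration horizon in days.
#' @param init Optional named initial state; defaults to empty substrate
#'   pools with a small inoculum (0.01 gCOD) in every fermenter biomass pool.
#' @param rtol,atol Solver tolerances (deSolve::lsoda).
#' @return List: `trajectory` (deSolve matrix of all pools over time) and
#'   `final` (an `lgi_steady_state` ledger evaluated at the endpoint).
#' @export
simulate_lgi_ode <- function(influent, ctt, x_m, stoich = NULL,
                             kinetics = kinetic_params(),
                             registry = default_nutrient_registry(),
                             horizon = 2000, init = NULL,
                             rtol = 1e-10, atol = 1e-12) {
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (ctt <= 0) stop("CTT must be positive", call. = FALSE)
  if (is.null(stoich)) stoich <- build_stoich_matrix(registry)
  arr <- .lgi_arrange(influent, stoich, kinetics, registry)
  nf <- length(arr$ferm_ids)
  nl <- length(arr$fat_ids)

  state_names <- c(paste0("S_", arr$ferm_ids), paste0("X_", arr$ferm_ids),
                   "H2", if (nl) paste0("F_", arr$fat_ids))
  y0 <- stats::setNames(numeric(length(state_names)), state_names)
  if (nf) y0[paste0("X_", arr$ferm_ids)] <- 0.01
  if (!is.null(init)) {
    bad <- setdiff(names(init), state_names)
    if (length(bad))
      stop("unknown state(s) in init: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
    y0[names(init)] <- init
  }

  q_ferm <- if (nf) as.numeric(influent[arr$ferm_ids]) else numeric(0)
  q_fat <- if (nl) as.numeric(influent[arr$fat_ids]) else numeric(0)
  yields <- if (nf) stoich[arr$ferm_ids, "biomass"] else numeric(0)
  h2_coef <- if (nf) stoich[arr$ferm_ids, "h2"] else numeric(0)

  deriv <- function(t, y, parms) {
    S <- y[seq_len(nf)]
    X <- y[nf + seq_len(nf)]
    H2 <- y[2 * nf + 1]
    Fp <- if (nl) y[2 * nf + 1 + seq_len(nl)] else numeric(0)
    r <- arr$k * pmax(S, 0) * pmax(X, 0)
    dS <- q_ferm - S / ctt - r
    dX <- yields * r - X / ctt
    dH2 <- sum(h2_coef * r) - H2 / ctt - kinetics$k_m * max(H2, 0) * x_m
    dF <- if (nl) q_fat - Fp / ctt - kinetics$k_f_abs * Fp else numeric(0)
    list(c(dS, dX, dH2, dF))
  }

  times <- seq(0, horizon, length.out = 201)
  traj <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                       method = "lsoda", rtol = rtol, atol = atol)
  if (attr(traj, "istate")[1] < 0)
    stop("ODE solver failed to converge; istate = ",
         attr(traj, "istate")[1], call. = FALSE)
  yT <- traj[nrow(traj), -1]

  sub_states <- lapply(seq_len(nf), function(i) {
    S <- max(yT[[paste0("S_", arr$ferm_ids[i])]], 0)
    X <- max(yT[[paste0("X_", arr$ferm_ids[i])]], 0)
    list(S = S, X = X, r_ut = arr$k[i] * S * X,
         washout = X < .Machine$double.eps)
  })
  H2 <- max(yT[["H2"]], 0)
  h2_state <- list(H2 = H2, r_meth = kinetics$k_m * H2 * x_m,
                   h2_gas = H2 / ctt)
  fat_states <- lapply(seq_len(nl), function(j) {
    Fp <- max(yT[[paste0("F_", arr$fat_ids[j])]], 0)
    list(fat = Fp, absorbed = kinetics$k_f_abs * Fp, fecal = Fp / ctt)
  })

  list(trajectory = traj,
       final = .lgi_ledger(influent, arr, sub_states, h2_state, fat_states,
                           stoich, kinetics, ctt, x_m))
}
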