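#' Dose regimens
#'
#' A dose regimen is a tibble of dosing events with columns `drug`
#' (`"pa"` or `"napa"`), `route` (`"iv_bolus"` or `"iv_infusion"`),
#' `amount` (µg), `start` (min) and `duration` (min; 0 for a bolus).
#' `regimen_iv_bolus()` builds a single-bolus regimen;
#' `regimen_loading_infusion()` builds the loading-dose + constant-infusion
#' design used for steady-state tissue partitioning studies.
#'
#' @param amount Bolus amount, µg.
#' @param drug `"pa"` or `"napa"`.
#' @param time Bolus time, min.
#' @param loading Loading-dose amount, µg.
#' @param rate Infusion rate, µg/min.
#' @param duration Infusion duration, min.
#' @return A `dose_regimen` tibble.
#' @export
regimen_iv_bolus <- function(amount, drug = "pa", time = 0) {
  dose_regimen(tibble::tibble(drug = drug, route = "iv_bolus",
                              amount = amount, start = time, duration = 0))
}

#' @rdname regimen_iv_bolus
#' @export
regimen_loading_infusion <- function(loading, rate, duration, drug = "pa") {
  dose_regimen(tibble::tibble(
    drug = drug,
    route = c("iv_bolus", "iv_infusion"),
    amount = c(loading, rate * duration),
    start = 0,
    duration = c(0, duration)
  ))
}

#' @rdname regimen_iv_bolus
#' @param events A tibble with columns `drug`, `route`, `amount`, `start`,
#'   `duration`.
#' @export
dose_regimen <- function(events) {
  events <- tibble::as_tibble(events)
  needed <- c("drug", "route", "amount", "start", "duration")
  missing <- setdiff(needed, names(events))
  if (length(missing)) stop("regimen is missing columns: ", paste(missing, collapse = ", "))
  stopifnot(all(events$drug %in% c("pa", "napa")),
            all(events$route %in% c("iv_bolus", "iv_infusion")),
            all(events$amount >= 0), all(events$start >= 0))
  if (any(events$route == "iv_infusion" & events$duration <= 0)) {
    stop("infusion events must have a positive duration")
  }
  events <- dplyr::arrange(events, .data$start)
  class(events) <- c("dose_regimen", class(events))
  events
}

#' Assemble the parent-metabolite PBPK model
#'
#' Builds the whole-body model: perfusion-limited tissues for both drugs, a
#' well-stirred liver in which a fraction `f_napa` of the parent drug's
#' hepatic elimination forms the metabolite (mass-corrected by the molecular
#' weight ratio), and a three-subcompartment semi-mechanistic kidney with
#' unbound basolateral uptake/efflux (`fup*PSin`, `fu_kidney*PSout`),
#' glomerular filtration (`fup*GFR`, vascular to lumen), apical secretion
#' (`fu_kidney*CLu,int,r`, cell to lumen), luminal reabsorption (`CLrabs`,
#' lumen to cell) and a luminal washout flux into urine.
#'
#' The luminal washout clearance defaults to the glomerular filtration rate
#' (a single well-mixed lumen flushed at the filtrate flow, with water
#' reabsorption concentrating the urine downstream without changing the
#' solute flux); set `washout = "urine_flow"` or a numeric clearance (mL/min)
#' to change this.
#'
#' @param physiology A [rat_physiology()] object.
#' @param pa,napa `drug_params` bundles for the parent drug and metabolite.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param washout `"gfr"`, `"urine_flow"`, or a numeric clearance in mL/min.
#' @param mw_correction Apply the metabolite/parent molecular-weight ratio
#'   when converting eliminated parent mass to formed metabolite mass
#'   (default `TRUE`).
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(physiology, pa, napa, rtol = 1e-8, atol = 1e-10,
                       washout = "gfr", mw_correction = TRUE) {
  stopifnot(inherits(physiology, "rat_physiology"),
            inherits(pa, "drug_params"), inherits(napa, "drug_params"),
            rtol > 0, atol > 0)
  q_wash <- if (is.numeric(washout)) {
    stopifnot(washout >= 0)
    washout
  } else {
    switch(match.arg(washout, c("gfr", "urine_flow")),
           gfr = physiology$gfr, urine_flow = physiology$urine_flow)
  }
  mw_ratio <- if (mw_correction) {
    napa$properties$molecular_weight / pa$properties$molecular_weight
  } else 1
  structure(
    list(physiology = physiology, drugs = list(pa = pa, napa = napa),
         rtol = rtol, atol = atol, q_wash = q_wash, mw_ratio = mw_ratio),
    class = "pbpk_model"
  )
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model> rat", x$physiology$body_weight, "kg;",
      "drugs:", paste(vapply(x$drugs, `[[`, "", "name"), collapse = " -> "), "\n")
  invisible(x)
}

# compartments exchanging directly with the plasma pool
.simple_tissues <- c("lung", "adipose", "bone", "brain", "heart",
                     "muscle", "skin")

.state_names <- function() {
  per_drug <- c("plasma", .simple_tissues, "gut", "spleen", "liver",
                "kid_vasc", "kid_cell", "kid_lumen", "urine", "hep_elim")
  c(paste0("pa_", per_drug), "pa_hep_napa",
    paste0("napa_", per_drug), "napa_formed")
}

# Right-hand side of the ODE system. `p` is the precompiled parameter
# environment built by .compile_model().
.pbpk_rhs <- function(t, y, p) {
  d <- numeric(length(y))
  inf_pa <- 0
  inf_napa <- 0
  if (p$n_inf > 0) {
    act <- t >= p$inf_start & t < p$inf_end
    if (any(act)) {
      inf_pa <- sum(p$inf_rate[act & p$inf_drug == "pa"])
      inf_napa <- sum(p$inf_rate[act & p$inf_drug == "napa"])
    }
  }
  for (k in 1:2) {
    i <- p$idx[[k]]       # named integer index vector for this drug
    dp <- p$drug[[k]]     # drug-specific constants
    c_pl <- y[i[["plasma"]]] / p$v_blood
    c_simple <- y[i[["simple"]]] / dp$vkp_simple
    c_gut <- y[i[["gut"]]] / dp$vkp_gut
    c_spl <- y[i[["spleen"]]] / dp$vkp_spleen
    c_liv <- y[i[["liver"]]] / dp$vkp_liver
    c_kv <- y[i[["kid_vasc"]]] / p$v_kv
    c_kc <- y[i[["kid_cell"]]] / p$v_kc
    c_kl <- y[i[["kid_lumen"]]] / p$v_kl

    hep_elim <- dp$clu_int * dp$fup * c_liv
    d[i[["simple"]]] <- p$q_simple * (c_pl - c_simple)
    d[i[["gut"]]] <- p$q_gut * (c_pl - c_gut)
    d[i[["spleen"]]] <- p$q_spleen * (c_pl - c_spl)
    d[i[["liver"]]] <- p$q_ha * c_pl + p$q_gut * c_gut + p$q_spleen * c_spl -
      p$q_liver * c_liv - hep_elim
    d[i[["kid_vasc"]]] <- p$q_kidney * (c_pl - c_kv) -
      dp$fup * (p$gfr + dp$ps_in) * c_kv + dp$fuk * dp$ps_out * c_kc
    d[i[["kid_cell"]]] <- dp$fup * dp$ps_in * c_kv -
      dp$fuk * (dp$ps_out + dp$clu_int_r) * c_kc + dp$cl_rabs * c_kl
    d[i[["kid_lumen"]]] <- dp$fup * p$gfr * c_kv + dp$fuk * dp$clu_int_r * c_kc -
      (dp$cl_rabs + p$q_wash) * c_kl
    d[i[["urine"]]] <- p$q_wash * c_kl
    d[i[["hep_elim"]]] <- hep_elim
    d[i[["plasma"]]] <- sum(p$q_simple * c_simple) - p$q_to_simple * c_pl -
      (p$q_gut + p$q_spleen + p$q_ha) * c_pl + p$q_liver * c_liv +
      p$q_kidney * (c_kv - c_pl)

    if (k == 1L) {
      form_pa_mass <- dp$f_napa * hep_elim
      d[p$i_hep_napa] <- form_pa_mass
      p$form_rate <- form_pa_mass * p$mw_ratio
      d[i[["plasma"]]] <- d[i[["plasma"]]] + inf_pa
    } else {
      d[i[["liver"]]] <- d[i[["liver"]]] + p$form_rate
      d[p$i_formed] <- p$form_rate
      d[i[["plasma"]]] <- d[i[["plasma"]]] + inf_napa
    }
  }
  list(d)
}

.compile_model <- function(model, regimen) {
  phys <- model$physiology
  states <- .state_names()
  idx_of <- function(nm) match(nm, states)
  p <- new.env(parent = emptyenv())
  p$v_blood <- phys$volumes[["blood"]]
  p$v_kv <- phys$kidney_subvolumes[["vascular"]]
  p$v_kc <- phys$kidney_subvolumes[["cell"]]
  p$v_kl <- phys$kidney_subvolumes[["lumen"]]
  fl <- phys$flows
  p$q_simple <- c(lung = phys$cardiac_output,
                  fl[setdiff(.simple_tissues, "lung")])[.simple_tissues]
  p$q_to_simple <- sum(p$q_simple)
  p$q_gut <- fl[["gut"]]; p$q_spleen <- fl[["spleen"]]
  p$q_ha <- fl[["liver_arterial"]]; p$q_liver <- fl[["liver"]]
  p$q_kidney <- fl[["kidney"]]
  p$gfr <- phys$gfr
  p$q_wash <- model$q_wash
  p$mw_ratio <- model$mw_ratio
  p$form_rate <- 0

  p$idx <- list()
  p$drug <- list()
  for (k in 1:2) {
    dn <- c("pa", "napa")[k]
    b <- model$drugs[[dn]]
    pre <- function(nm) idx_of(paste0(dn, "_", nm))
    p$idx[[k]] <- list(
      plasma = pre("plasma"),
      simple = vapply(.simple_tissues, pre, integer(1)),
      gut = pre("gut"), spleen = pre("spleen"), liver = pre("liver"),
      kid_vasc = pre("kid_vasc"), kid_cell = pre("kid_cell"),
      kid_lumen = pre("kid_lumen"), urine = pre("urine"),
      hep_elim = pre("hep_elim")
    )
    vols <- phys$volumes
    p$drug[[k]] <- list(
      fup = b$properties$fup, fuk = b$properties$fu_kidney,
      clu_int = b$hepatic$clu_int, f_napa = b$hepatic$f_napa,
      ps_in = b$kidney$ps_in, ps_out = b$kidney$ps_pas,
      clu_int_r = b$kidney$clu_int_r, cl_rabs = b$kidney$cl_rabs,
      vkp_simple = vols[.simple_tissues] * b$kp[.simple_tissues],
      vkp_gut = vols[["gut"]] * b$kp[["gut"]],
      vkp_spleen = vols[["spleen"]] * b$kp[["spleen"]],
      vkp_liver = vols[["liver"]] * b$kp[["liver"]]
    )
  }
  p$i_hep_napa <- idx_of("pa_hep_napa")
  p$i_formed <- idx_of("napa_formed")

  inf <- regimen[regimen$route == "iv_infusion", ]
  p$n_inf <- nrow(inf)
  p$inf_start <- inf$start
  p$inf_end <- inf$start + inf$duration
  p$inf_rate <- if (p$n_inf) inf$amount / inf$duration else numeric(0)
  p$inf_drug <- inf$drug
  p
}

#' Simulate the PBPK model
#'
#' Integrates the coupled parent-metabolite ODE system over a time grid with
#' a stiff-capable adaptive solver ([deSolve::lsoda()]). Bolus events are
#' applied as state jumps; infusions as piecewise-constant input rates (the
#' window edges are inserted into the integration grid).
#'
#' @param model A [pbpk_model()] object.
#' @param regimen A [dose_regimen()] tibble.
#' @param times Output time grid, min; must cover all dose events.
#' @return An object of class `pbpk_simulation` with elements `times`,
#'   `amounts` (matrix of compartment amounts, µg), `model`, `regimen` and
#'   `dose` (administered amount per drug, µg). Use [as_tibble()] /
#'   [sim_profile()] / [sim_urine()] to extract tidy views.
#' @export
simulate_pbpk <- function(model, regimen, times) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dose_regimen"))
  times <- sort(unique(as.numeric(times)))
  if (min(times) > min(regimen$start)) {
    stop("`times` must start at or before the first dose event")
  }
  p <- .compile_model(model, regimen)
  states <- .state_names()
  y0 <- stats::setNames(numeric(length(states)), states)

  bol <- regimen[regimen$route == "iv_bolus" & regimen$amount > 0, ]
  eventdat <- NULL
  if (nrow(bol)) {
    eventdat <- data.frame(
      var = paste0(bol$drug, "_plasma"),
      time = bol$start, value = bol$amount, method = "add"
    )
  }
  solver_times <- sort(unique(c(times, bol$start, p$inf_start, p$inf_end)))
  solver_times <- solver_times[solver_times <= max(times)]

  out <- deSolve::lsoda(
    y = y0, times = solver_times, func = .pbpk_rhs, parms = p,
    rtol = model$rtol, atol = model$atol,
    events = if (!is.null(eventdat)) list(data = eventdat) else NULL
  )
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed to converge (istate = ",
         attr(out, "istate")[1], ")")
  }
  keep <- out[, "time"] %in% times
  amounts <- out[keep, states, drop = FALSE]
  dose <- c(
    pa = sum(regimen$amount[regimen$drug == "pa"]),
    napa = sum(regimen$amount[regimen$drug == "napa"])
  )
  structure(
    list(times = out[keep, "time"], amounts = amounts, model = model,
         regimen = regimen, dose = dose),
    class = "pbpk_simulation"
  )
}

#' @export
print.pbpk_simulation <- function(x, ...) {
  cat("<pbpk_simulation>", length(x$times), "time points,",
      format(max(x$times)), "min;",
      "dose PA", x$dose[["pa"]], "ug, NAPA", x$dose[["napa"]], "ug\n")
  invisible(x)
}

#' Tidy view of a simulation
#'
#' @param x A `pbpk_simulation`.
#' @param ... Unused.
#' @return A long tibble with `time` (min), `drug`, `compartment`, `amount`
#'   (µg) and, where a physical volume is defined, `concentration` (µg/mL).
#' @export
as_tibble.pbpk_simulation <- function(x, ...) {
  phys <- x$model$physiology
  vols <- c(
    plasma = phys$volumes[["blood"]],
    phys$volumes[c(.simple_tissues, "gut", "spleen", "liver")],
    kid_vasc = phys$kidney_subvolumes[["vascular"]],
    kid_cell = phys$kidney_subvolumes[["cell"]],
    kid_lumen = phys$kidney_subvolumes[["lumen"]]
  )
  tibble::as_tibble(as.data.frame(x$amounts)) |>
    dplyr::mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "amount") |>
    tidyr::separate_wider_regex(
      "state", c(drug = "^(?:pa|napa)", "_", compartment = ".*$")
    ) |>
    dplyr::mutate(
      concentration = .data$amount / unname(vols[.data$compartment])
    )
}

#' Extract a plasma concentration profile from a simulation
#'
#' @param sim A `pbpk_simulation`.
#' @param drug `"pa"` or `"napa"`.
#' @return A tibble with `time` (min) and `conc` (µg/mL).
#' @export
sim_profile <- function(sim, drug = c("pa", "napa")) {
  drug <- match.arg(drug)
  v <- sim$model$physiology$volumes[["blood"]]
  tibble::tibble(
    time = sim$times,
    conc = sim$amounts[, paste0(drug, "_plasma")] / v
  )
}

#' Extract cumulative urinary excretion from a simulation
#'
#' @param sim A `pbpk_simulation`.
#' @param drug `"pa"` or `"napa"`.
#' @param calibration Multiplicative observation-scale calibration factor
#'   applied to the simulated urinary amounts (default 1).
#' @return A tibble with `time` (min) and `amount` (µg, cumulative).
#' @export
sim_urine <- function(sim, drug = c("pa", "napa"), calibration = 1) {
  drug <- match.arg(drug)
  tibble::tibble(
    time = sim$times,
    amount = sim$amounts[, paste0(drug, "_urine")] * calibration
  )
}

#' Mass balance audit of a simulation
#'
#' For the parent drug the conserved quantity is the administered dose; for
#' the metabolite it is the cumulative formed amount (plus any directly
#' administered metabolite dose). Returns the relative mass-balance error at
#' every output time after the first dose.
#'
#' @param sim A `pbpk_simulation`.
#' @return A tibble with `time`, `drug` and `rel_error`.
#' @export
mass_balance <- function(sim) {
  states <- colnames(sim$amounts)
  per_drug <- function(drug) {
    comp <- states[startsWith(states, paste0(drug, "_")) &
                   !states %in% paste0(drug, c("_hep_napa", "_formed"))]
    total <- rowSums(sim$amounts[, comp, drop = FALSE])
    dosed <- vapply(sim$times, function(t) {
      ev <- sim$regimen[sim$regimen$drug == drug, ]
      if (!nrow(ev)) return(0)
      sum(ifelse(ev$route == "iv_bolus",
                 ifelse(t > ev$start, ev$amount, 0),
                 ev$amount / ev$duration * pmax(0, pmin(t, ev$start + ev$duration) - ev$start)))
    }, numeric(1))
    if (drug == "napa") dosed <- dosed + sim$amounts[, "napa_formed"]
    tibble::tibble(
      time = sim$times, drug = drug,
      rel_error = ifelse(dosed > 0, abs(total - dosed) / dosed, abs(total))
    )
  }
  dplyr::bind_rows(per_drug("pa"), per_drug("napa"))
}

#' Steady-state tissue-to-plasma coefficients from an infusion simulation
#'
#' Simulates a loading-dose + constant-infusion regimen and returns the
#' tissue-to-plasma concentration ratio of every tissue at `sample_time`.
#' The plasma concentration must be within 5% of its asymptote (taken as the
#' simulated concentration at five times the sampling time) or a warning is
#' issued with the attained fraction.
#'
#' @param model A [pbpk_model()] object.
#' @param regimen A [dose_regimen()]; typically [regimen_loading_infusion()].
#' @param sample_time Sampling time, min (> 0).
#' @param drug `"pa"` or `"napa"`.
#' @return A tibble with `tissue`, `kp_ss` and the plasma concentration used.
#' @export
steady_state_kpss <- function(model, regimen, sample_time, drug = c("pa", "napa")) {
  drug <- match.arg(drug)
  if (sample_time <= 0) stop("`sample_time` must be positive")
  horizon <- 5 * sample_time
  times <- sort(unique(c(seq(0, horizon, length.out = 501), sample_time)))
  sim <- simulate_pbpk(model, regimen, times)
  prof <- sim_profile(sim, drug)
  c_ss <- prof$conc[prof$time == sample_time]
  c_inf <- prof$conc[nrow(prof)]
  if (c_inf <= 0) stop("no drug in plasma at the sampling time")
  attained <- c_ss / c_inf
  if (abs(attained - 1) > 0.05) {
    warning(sprintf(
      "plasma not at steady state at %g min: %.1f%% of asymptote", sample_time,
      100 * attained
    ))
  }
  phys <- model$physiology
  row <- which(sim$times == sample_time)
  amt <- function(nm) sim$amounts[row, paste0(drug, "_", nm)]
  tissues <- c(.simple_tissues, "gut", "spleen", "liver")
  conc <- vapply(tissues, function(t) amt(t) / phys$volumes[[t]], numeric(1))
  kidney_conc <- (amt("kid_vasc") + amt("kid_cell") + amt("kid_lumen")) /
    phys$volumes[["kidney"]]
  tibble::tibble(
    tissue = c(tissues, "kidney"),
    kp_ss = unname(c(conc, kidney_conc)) / c_ss,
    c_plasma = c_ss
  )
}
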