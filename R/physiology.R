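#' Reference rat physiology (per-kg values)
#'
#' Per-kilogram reference tissue volumes and regional plasma flows for the
#' laboratory rat, in the spirit of the standard compendium tables used by
#' whole-body PBPK models. Flows are expressed as fractions of cardiac output
#' so that the organ flow balance holds exactly for any body weight; the
#' fractions are normalised over the tissues represented in the model (a small
#' "rest of body" flow is folded in proportionally). Blood:plasma ratio is 1
#' for both drugs handled by this package, so plasma and blood flows are
#' interchangeable and the model works in plasma concentrations throughout.
#'
#' All values can be overridden, either by passing a modified list to
#' [rat_physiology()] or from a YAML file via [read_physiology_config()].
#'
#' @return A named list with elements:
#' * `volumes_per_kg`: named numeric, tissue volumes in mL/kg body weight
#'   (adipose, bone, brain, gut, heart, kidney, liver, lung, muscle, skin,
#'   spleen, blood).
#' * `flow_fractions`: named numeric, arterial plasma flow to each tissue as a
#'   fraction of cardiac output (hepatic artery listed as `liver_arterial`);
#'   sums to 1.
#' * `cardiac_output_per_kg`: mL/min/kg.
#' * `gfr_per_kg`: glomerular filtration rate, mL/min/kg.
#' * `urine_flow_per_kg`: urine flow, mL/min/kg.
#' * `kidney_fractions`: fractions of kidney volume assigned to the vascular,
#'   cell and lumen subcompartments; sums to 1.
#' @export
rat_physiology_defaults <- function() {
  flow_raw <- c(
    adipose = 0.070, bone = 0.122, brain = 0.020, gut = 0.141,
    heart = 0.049, kidney = 0.141, liver_arterial = 0.021,
    muscle = 0.278, skin = 0.058, spleen = 0.012
  )
  list(
    volumes_per_kg = c(
      adipose = 76.0, bone = 41.5, brain = 5.7, gut = 27.0,
      heart = 3.3, kidney = 7.3, liver = 36.6, lung = 5.0,
      muscle = 404.0, skin = 190.0, spleen = 2.0, blood = 64.0
    ),
    # normalised so that modelled organ flows account for all of cardiac output
    flow_fractions = flow_raw / sum(flow_raw),
    cardiac_output_per_kg = 296.0,
    gfr_per_kg = 5.2,
    urine_flow_per_kg = 0.05,
    kidney_fractions = c(vascular = 0.15, cell = 0.75, lumen = 0.10)
  )
}

#' Build a body-weight-scaled rat physiology set
#'
#' Scales the per-kg reference volumes and flows linearly by body weight and
#' assembles the complete physiology used by the PBPK model: tissue volumes,
#' regional plasma flows, cardiac output, hepatic inflow (hepatic artery plus
#' gut and spleen outflows), glomerular filtration rate, urine flow and the
#' kidney vascular/cell/lumen subvolumes.
#'
#' @param body_weight Body weight in kg; must lie in \[0.1, 1\] (adult rat).
#' @param reference Per-kg reference values, as returned by
#'   [rat_physiology_defaults()]; any element may be overridden.
#' @return An object of class `rat_physiology`: a list with `body_weight` (kg),
#'   `volumes` (named, mL), `kidney_subvolumes` (vascular/cell/lumen, mL),
#'   `flows` (named tissue plasma flows, mL/min, with `liver_arterial` the
#'   hepatic-artery component and `liver` the total hepatic inflow),
#'   `cardiac_output` (mL/min), `gfr` (mL/min) and `urine_flow` (mL/min).
#' @examples
#' phys <- rat_physiology(0.25)
#' phys$flows[["kidney"]]
#' @export
rat_physiology <- function(body_weight, reference = rat_physiology_defaults()) {
  stopifnot(is.numeric(body_weight), length(body_weight) == 1L, is.finite(body_weight))
  if (body_weight < 0.1 || body_weight > 1.0) {
    stop("`body_weight` must be between 0.1 and 1 kg, got ", body_weight)
  }
  ref <- utils::modifyList(rat_physiology_defaults(), reference)
  vols <- ref$volumes_per_kg * body_weight
  co <- ref$cardiac_output_per_kg * body_weight
  fr <- ref$flow_fractions
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("flow fractions must sum to 1 (got ", signif(sum(fr), 6), ")")
  }
  flows <- fr * co
  flows[["liver"]] <- flows[["liver_arterial"]] + flows[["gut"]] + flows[["spleen"]]
  kf <- ref$kidney_fractions
  if (abs(sum(kf) - 1) > 1e-8) stop("kidney subvolume fractions must sum to 1")
  out <- structure(
    list(
      body_weight = body_weight,
      volumes = vols,
      kidney_subvolumes = kf * vols[["kidney"]],
      flows = flows,
      cardiac_output = co,
      gfr = ref$gfr_per_kg * body_weight,
      urine_flow = ref$urine_flow_per_kg * body_weight
    ),
    class = "rat_physiology"
  )
  validate_physiology(out)
  out
}

validate_physiology <- function(phys) {
  with(phys, {
    if (any(volumes <= 0) || any(flows <= 0) || gfr <= 0 || urine_flow <= 0) {
      stop("all physiological volumes and flows must be positive")
    }
    arterial <- flows[setdiff(names(flows), "liver")]
    if (abs(sum(arterial) - cardiac_output) > 1e-8 * cardiac_output) {
      stop("organ arterial flows do not sum to cardiac output")
    }
    if (abs(flows[["liver"]] -
            (flows[["liver_arterial"]] + flows[["gut"]] + flows[["spleen"]])) >
        1e-8 * flows[["liver"]]) {
      stop("hepatic inflow must equal hepatic artery + gut + spleen outflows")
    }
    if (abs(sum(kidney_subvolumes) - volumes[["kidney"]]) > 1e-8 * volumes[["kidney"]]) {
      stop("kidney subvolumes must sum to the kidney volume")
    }
  })
  invisible(phys)
}

#' @export
print.rat_physiology <- function(x, ...) {
  cat("<rat_physiology> body weight", x$body_weight, "kg\n")
  cat("  cardiac output:", signif(x$cardiac_output, 4), "mL/min;",
      "GFR:", signif(x$gfr, 4), "mL/min\n")
  cat("  hepatic inflow:", signif(x$flows[["liver"]], 4), "mL/min;",
      "renal flow:", signif(x$flows[["kidney"]], 4), "mL/min\n")
  invisible(x)
}

#' Read a physiology override config (YAML)
#'
#' Reads per-kg reference overrides from a YAML file. Any subset of the fields
#' of [rat_physiology_defaults()] may be given; missing fields keep their
#' defaults. Named vectors are given as YAML mappings.
#'
#' @param path Path to a YAML file.
#' @return A reference list suitable for the `reference` argument of
#'   [rat_physiology()].
#' @export
read_physiology_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- rat_physiology_defaults()
  for (nm in intersect(names(raw), names(ref))) {
    val <- raw[[nm]]
    if (is.list(val)) val <- unlist(val)
    if (is.null(names(val)) && length(val) == 1L) {
      ref[[nm]] <- as.numeric(val)
    } else {
      ref[[nm]][names(val)] <- as.numeric(val)
    }
  }
  ref
}
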