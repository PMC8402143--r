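#' Construct a drug parameter bundle
#'
#' Bundles everything the PBPK model needs for one drug in one arm:
#' physicochemical and binding properties, tissue partition coefficients,
#' hepatic elimination and semi-mechanistic kidney transport clearances.
#'
#' @param name Drug label (e.g. `"PA"`).
#' @param properties Named list: `molecular_weight` (g/mol), `pka`, `logp`,
#'   `fup` (plasma unbound fraction), `blood_plasma_ratio`, `fu_kidney`
#'   (kidney-cell unbound fraction), `fu_inc` (incubation unbound fraction).
#' @param kp Named numeric of tissue-to-plasma partition coefficients; must
#'   cover adipose, bone, brain, gut, heart, kidney, liver, lung, muscle,
#'   skin, spleen.
#' @param kp_provenance Named character, one of `"observed_kpss"`,
#'   `"retrograde"`, `"model_based"`, `"in_silico"` per tissue; eliminating
#'   tissues (kidney, liver) must not be plain observed values.
#' @param hepatic Named list: `clu_int` (mL/min), `f_napa` (fraction of
#'   hepatic elimination forming the metabolite, 0 for the metabolite itself),
#'   `extraction_ratio`.
#' @param kidney Named list: `ps_in`, `ps_pas` (= PSout), `clu_int_r`,
#'   `cl_rabs` (all mL/min) and `extraction_ratio`.
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(name, properties, kp, kp_provenance, hepatic, kidney) {
  tissues <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "skin", "spleen")
  missing <- setdiff(tissues, names(kp))
  if (length(missing)) stop("missing Kp for: ", paste(missing, collapse = ", "))
  if (any(kp[tissues] <= 0)) stop("all Kp must be positive")
  fr <- unlist(properties[c("fup", "fu_kidney", "fu_inc")])
  if (any(fr <= 0) || any(fr > 1)) stop("unbound fractions must lie in (0, 1]")
  if (properties$molecular_weight <= 0) stop("molecular weight must be positive")
  with(hepatic, stopifnot(clu_int >= 0, f_napa >= 0, f_napa <= 1,
                          extraction_ratio >= 0, extraction_ratio < 1))
  with(kidney, {
    stopifnot(ps_in >= 0, ps_pas >= 0, clu_int_r >= 0, cl_rabs >= 0)
    if (ps_in < ps_pas) stop("kidney ps_in must be at least ps_pas")
  })
  for (t in c("kidney", "liver")) {
    if (identical(kp_provenance[[t]], "observed_kpss")) {
      stop(t, " Kp must be retrograde or model-based, not a raw steady-state value")
    }
  }
  structure(
    list(name = name, properties = properties, kp = kp[tissues],
         kp_provenance = kp_provenance, hepatic = hepatic, kidney = kidney),
    class = "drug_params"
  )
}

#' @export
print.drug_params <- function(x, ...) {
  cat("<drug_params>", x$name, "\n")
  cat("  fup", x$properties$fup, "| CLu,int", x$hepatic$clu_int,
      "mL/min | FNAPA", x$hepatic$f_napa, "\n")
  cat("  kidney: PSin", x$kidney$ps_in, "PSout", x$kidney$ps_pas,
      "CLu,int,r", x$kidney$clu_int_r, "CLrabs", x$kidney$cl_rabs, "mL/min\n")
  invisible(x)
}

#' Reference parameter bundles for procainamide and N-acetylprocainamide
#'
#' Control-arm and treatment-arm parameter bundles for the parent drug (PA)
#' and its N-acetyl metabolite (NAPA) in rat. Eliminating-tissue Kp values
#' carry retrograde or model-based provenance; adipose, bone, gut, muscle and
#' skin Kp are fixed in-silico predictions taken as inputs. Treatment-arm
#' bundles reflect the transporter fold changes (renal active uptake and
#' MATE-mediated secretion) and the independently re-derived hepatic block.
#'
#' @param arm `"control"` or `"treated"`.
#' @return A `drug_params` object.
#' @export
pa_params <- function(arm = c("control", "treated")) {
  arm <- match.arg(arm)
  props <- list(molecular_weight = 235.33, pka = 9.04, logp = 0.83,
                fup = 0.87, blood_plasma_ratio = 1,
                fu_kidney = 0.223, fu_inc = 0.380)
  kp_common <- c(adipose = 0.721, bone = 1.96, gut = 4.87,
                 muscle = 3.93, skin = 2.96)
  prov <- c(adipose = "in_silico", bone = "in_silico", gut = "in_silico",
            muscle = "in_silico", skin = "in_silico",
            brain = "observed_kpss", heart = "observed_kpss",
            lung = "observed_kpss", spleen = "observed_kpss",
            kidney = "retrograde", liver = "retrograde")
  if (arm == "control") {
    drug_params(
      "PA", props,
      kp = c(kp_common, brain = 0.3904, heart = 2.362, lung = 0.9077,
             spleen = 2.027, kidney = 11.4, liver = 1.44),
      kp_provenance = prov,
      hepatic = list(clu_int = 47.9, f_napa = 0.562, extraction_ratio = 0.682),
      kidney = list(ps_in = 22.1, ps_pas = 7.61, clu_int_r = 4.67,
                    cl_rabs = 0.415, extraction_ratio = 0.253)
    )
  } else {
    prov[c("kidney", "liver")] <- c("model_based", "retrograde")
    drug_params(
      "PA", props,
      kp = c(kp_common, brain = 0.2861, heart = 1.658, lung = 0.9282,
             spleen = 1.507, kidney = 10.7, liver = 0.649),
      kp_provenance = prov,
      hepatic = list(clu_int = 25, f_napa = 0.845, extraction_ratio = 0.529),
      kidney = list(ps_in = 17.4, ps_pas = 7.61, clu_int_r = 1.46,
                    cl_rabs = 0.415, extraction_ratio = 0.0892)
    )
  }
}

#' @rdname pa_params
#' @export
napa_params <- function(arm = c("control", "treated")) {
  arm <- match.arg(arm)
  props <- list(molecular_weight = 277.36, pka = 9.04, logp = 0.93,
                fup = 0.688, blood_plasma_ratio = 1,
                fu_kidney = 0.0588, fu_inc = 1)
  kp_common <- c(adipose = 0.967, bone = 2.2, gut = 6.23,
                 muscle = 4.61, skin = 3.64)
  prov <- c(adipose = "in_silico", bone = "in_silico", gut = "in_silico",
            muscle = "in_silico", skin = "in_silico",
            brain = "observed_kpss", heart = "observed_kpss",
            lung = "observed_kpss", spleen = "observed_kpss",
            kidney = "retrograde", liver = "retrograde")
  if (arm == "control") {
    drug_params(
      "NAPA", props,
      kp = c(kp_common, brain = 0.1268, heart = 2.67, lung = 5.448,
             spleen = 6.432, kidney = 14.7, liver = 9.62),
      kp_provenance = prov,
      hepatic = list(clu_int = 4.04, f_napa = 0, extraction_ratio = 0.125),
      kidney = list(ps_in = 9.59, ps_pas = 7.61, clu_int_r = 9.16,
                    cl_rabs = 0.415, extraction_ratio = 0.195)
    )
  } else {
    prov[c("kidney", "liver")] <- c("model_based", "retrograde")
    drug_params(
      "NAPA", props,
      kp = c(kp_common, brain = 0.2458, heart = 2.29, lung = 4.191,
             spleen = 5.186, kidney = 14.5, liver = 7.25),
      kp_provenance = prov,
      hepatic = list(clu_int = 4.04, f_napa = 0, extraction_ratio = 0.125),
      kidney = list(ps_in = 8.95, ps_pas = 7.61, clu_int_r = 2.86,
                    cl_rabs = 0.415, extraction_ratio = 0.116)
    )
  }
}

#' Treatment-effect scalars
#'
#' The multiplicative fold changes that map a control parameter bundle to a
#' treatment bundle: the fitted fold change of renal active basolateral
#' uptake (`r_act`, shared by parent and metabolite), the measured renal
#' MATE-protein fold (`r_mate`), the hepatic OCT1 protein fold and the
#' saturable fraction of hepatic uptake it acts on, and per-drug multiplicative
#' calibration factors applied to simulated urinary recovery on the
#' observation scale.
#'
#' @param r_act Fold change of renal active uptake (> 0).
#' @param r_mate MATE-protein fold change (> 0).
#' @param oct1_liver_fold Hepatic OCT1 protein fold change (> 0).
#' @param saturable_hepatic_fraction Saturable fraction of hepatic uptake.
#' @param urinary_calibration Named numeric (`pa`, `napa`): multiplicative
#'   factors on simulated urinary amounts.
#' @return A list of class `treatment_scalars`.
#' @export
treatment_scalars <- function(r_act = 0.675, r_mate = 0.312,
                              oct1_liver_fold = 0.309,
                              saturable_hepatic_fraction = 0.557,
                              urinary_calibration = c(pa = 1.29, napa = 0.836)) {
  stopifnot(r_act > 0, r_mate > 0, oct1_liver_fold > 0,
            saturable_hepatic_fraction >= 0, saturable_hepatic_fraction <= 1,
            all(urinary_calibration > 0))
  structure(list(r_act = r_act, r_mate = r_mate,
                 oct1_liver_fold = oct1_liver_fold,
                 saturable_hepatic_fraction = saturable_hepatic_fraction,
                 urinary_calibration = urinary_calibration),
            class = "treatment_scalars")
}

#' Derive a treatment-arm bundle from a control bundle
#'
#' Applies the treatment-effect scalars to a control parameter bundle:
#' renal basolateral uptake via [apply_ract()], apical secretion via
#' [apply_rmate()], and the kidney partition coefficient re-derived from the
#' scaled clearances via [kidney_kp_model()]. All other fields carry over
#' unless explicitly overridden (the hepatic block and observed tissue Kp
#' values are typically replaced from treatment-arm observations).
#'
#' @param control A `drug_params` bundle for the control arm.
#' @param scalars A [treatment_scalars()] object.
#' @param overrides Optional named list with any of `kp` (named numeric,
#'   merged), `hepatic` (list, merged), `kp_provenance` (merged).
#' @return A `drug_params` bundle for the treatment arm.
#' @examples
#' trt <- apply_treatment(pa_params("control"), treatment_scalars())
#' trt$kidney$ps_in # 17.4 (3 s.f.)
#' @export
apply_treatment <- function(control, scalars, overrides = NULL) {
  stopifnot(inherits(control, "drug_params"), inherits(scalars, "treatment_scalars"))
  kid <- control$kidney
  kid$ps_in <- apply_ract(kid$ps_in, kid$ps_pas, scalars$r_act)
  kid$clu_int_r <- apply_rmate(kid$clu_int_r, scalars$r_mate)
  kp <- control$kp
  prov <- control$kp_provenance
  kp[["kidney"]] <- kidney_kp_model(control$properties$fup, kid$ps_in,
                                    control$properties$fu_kidney, kid$ps_pas)
  prov[["kidney"]] <- "model_based"
  hepatic <- control$hepatic
  if (!is.null(overrides)) {
    if (!is.null(overrides$kp)) kp[names(overrides$kp)] <- overrides$kp
    if (!is.null(overrides$hepatic)) hepatic <- utils::modifyList(hepatic, overrides$hepatic)
    if (!is.null(overrides$kp_provenance)) {
      prov[names(overrides$kp_provenance)] <- overrides$kp_provenance
    }
  }
  drug_params(control$name, control$properties, kp, prov, hepatic, kid)
}

#' Flatten drug parameter bundles to a tidy parameter table
#'
#' Converts one or more `drug_params` bundles to a long tibble with columns
#' `block`, `parameter`, `drug`, `arm`, `value`, `units`, `provenance` —
#' the tabular layout used for CSV round-tripping.
#'
#' @param ... Named `drug_params` bundles; names give the `arm` labels, e.g.
#'   `parameter_table(control = pa_params("control"))`.
#' @return A tibble.
#' @export
parameter_table <- function(...) {
  bundles <- list(...)
  arms <- names(bundles)
  if (is.null(arms) || any(arms == "")) stop("bundles must be named by arm")
  purrr::map2_dfr(bundles, arms, function(b, arm) {
    props <- tibble::tibble(
      block = "physchem_binding",
      parameter = c("molecular_weight", "pka", "logp", "fup",
                    "blood_plasma_ratio", "fu_kidney", "fu_inc"),
      value = unlist(b$properties[parameter]),
      units = c("g/mol", "", "", "", "", "", ""),
      provenance = "input"
    )
    kp <- tibble::tibble(
      block = "distribution_kp",
      parameter = paste0("kp_", names(b$kp)),
      value = unname(b$kp),
      units = "",
      provenance = unname(b$kp_provenance[names(b$kp)])
    )
    hep <- tibble::tibble(
      block = "nonrenal_elimination",
      parameter = c("clu_int", "f_napa", "extraction_ratio"),
      value = unlist(b$hepatic[parameter]),
      units = c("mL/min", "", ""),
      provenance = "derived"
    )
    kid <- tibble::tibble(
      block = "semi_mechanistic_kidney",
      parameter = c("ps_in", "ps_pas", "clu_int_r", "cl_rabs", "extraction_ratio"),
      value = unlist(b$kidney[parameter]),
      units = c("mL/min", "mL/min", "mL/min", "mL/min", ""),
      provenance = "derived"
    )
    dplyr::bind_rows(props, kp, hep, kid) |>
      dplyr::mutate(drug = b$name, arm = arm) |>
      dplyr::select("block", "parameter", "drug", "arm", "value",
                    "units", "provenance")
  })
}

#' Rebuild a drug parameter bundle from a tidy parameter table
#'
#' Inverse of [parameter_table()] for a single drug and arm.
#'
#' @param tbl A tibble in the [parameter_table()] layout.
#' @param drug Drug label to extract.
#' @param arm Arm label to extract.
#' @return A `drug_params` bundle.
#' @export
params_from_table <- function(tbl, drug, arm) {
  sub <- dplyr::filter(tbl, .data$drug == .env$drug, .data$arm == .env$arm)
  if (nrow(sub) == 0) stop("no rows for drug ", drug, ", arm ", arm)
  val <- function(block, parameter) {
    row <- sub[sub$block == block & sub$parameter == parameter, ]
    if (nrow(row) != 1) stop("missing or duplicated parameter: ", parameter)
    row$value
  }
  kp_rows <- sub[sub$block == "distribution_kp", ]
  kp <- stats::setNames(kp_rows$value, sub("^kp_", "", kp_rows$parameter))
  prov <- stats::setNames(kp_rows$provenance, names(kp))
  drug_params(
    drug,
    properties = list(
      molecular_weight = val("physchem_binding", "molecular_weight"),
      pka = val("physchem_binding", "pka"),
      logp = val("physchem_binding", "logp"),
      fup = val("physchem_binding", "fup"),
      blood_plasma_ratio = val("physchem_binding", "blood_plasma_ratio"),
      fu_kidney = val("physchem_binding", "fu_kidney"),
      fu_inc = val("physchem_binding", "fu_inc")
    ),
    kp = kp, kp_provenance = prov,
    hepatic = list(clu_int = val("nonrenal_elimination", "clu_int"),
                   f_napa = val("nonrenal_elimination", "f_napa"),
                   extraction_ratio = val("nonrenal_elimination", "extraction_ratio")),
    kidney = list(ps_in = val("semi_mechanistic_kidney", "ps_in"),
                  ps_pas = val("semi_mechanistic_kidney", "ps_pas"),
                  clu_int_r = val("semi_mechanistic_kidney", "clu_int_r"),
                  cl_rabs = val("semi_mechanistic_kidney", "cl_rabs"),
                  extraction_ratio = val("semi_mechanistic_kidney", "extraction_ratio"))
  )
}

#' Read or write a parameter table CSV
#'
#' Lossless CSV round trip of the tidy parameter-table layout
#' (`block, parameter, drug, arm, value, units, provenance`).
#'
#' @param tbl A parameter-table tibble.
#' @param path File path.
#' @return `read_parameter_table()` returns a tibble; `write_parameter_table()`
#'   returns `path` invisibly.
#' @export
write_parameter_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("block", "parameter", "drug", "arm", "value", "units", "provenance")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    stop("parameter table is missing columns: ", paste(missing, collapse = ", "))
  }
  tbl$units[is.na(tbl$units)] <- ""
  tbl
}
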