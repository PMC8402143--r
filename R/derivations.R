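#' Retrograde tissue partition coefficient from a steady-state measurement
#'
#' An eliminating tissue sampled at infusion steady state shows an apparently
#' depressed tissue-to-plasma ratio, because elimination keeps the intra-tissue
#' concentration below its distributional equilibrium. The true partition
#' coefficient used by a perfusion-limited PBPK compartment is recovered by
#' dividing out the fraction escaping elimination:
#' `Kp = Kp,ss / (1 - ER)`.
#'
#' @param kp_ss Observed steady-state tissue-to-plasma ratio (> 0).
#' @param er Organ extraction ratio in \[0, 1).
#' @return The retrograde partition coefficient (unitless).
#' @examples
#' retrograde_kp(8.484, 0.253) # kidney, parent drug
#' @export
retrograde_kp <- function(kp_ss, er) {
  stopifnot(is.numeric(kp_ss), is.numeric(kp_ss), all(kp_ss > 0))
  if (any(er < 0) || any(er >= 1)) {
    stop("`er` must lie in [0, 1): a tissue cannot extract more than its inflow")
  }
  kp_ss / (1 - er)
}

#' Steady-state kidney cell-to-plasma partitioning from transport clearances
#'
#' In the semi-mechanistic kidney, the tubular-cell partition coefficient at
#' distributional steady state is set by the balance of unbound basolateral
#' uptake and efflux:
#' `Kp,KI = (fup * PSin) / (fu,kidney * PSout)`.
#'
#' @param fup Unbound fraction in plasma (0, 1].
#' @param ps_in Basolateral uptake clearance, mL/min.
#' @param fu_kidney Unbound fraction in kidney cells (0, 1].
#' @param ps_out Basolateral efflux (passive) clearance, mL/min.
#' @return Kidney cell-to-plasma partition coefficient (unitless).
#' @examples
#' kidney_kp_model(0.87, 22.1, 0.223, 7.61)
#' @export
kidney_kp_model <- function(fup, ps_in, fu_kidney, ps_out) {
  vals <- c(fup, ps_in, fu_kidney, ps_out)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs to kidney_kp_model() must be positive and finite")
  }
  (fup * ps_in) / (fu_kidney * ps_out)
}

#' Invert the kidney partition relation for the uptake clearance
#'
#' Retrograde counterpart of [kidney_kp_model()]: given a kidney partition
#' coefficient (typically obtained by [retrograde_kp()] from an observed
#' Kp,ss), solve for the basolateral uptake clearance
#' `PSin = Kp,KI * fu,kidney * PSout / fup`.
#'
#' @inheritParams kidney_kp_model
#' @param kp_ki Kidney cell-to-plasma partition coefficient (> 0).
#' @return Basolateral uptake clearance PSin, mL/min.
#' @export
ps_in_from_kidney_kp <- function(kp_ki, fup, fu_kidney, ps_out) {
  vals <- c(kp_ki, fup, fu_kidney, ps_out)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs to ps_in_from_kidney_kp() must be positive and finite")
  }
  kp_ki * fu_kidney * ps_out / fup
}

#' Well-stirred hepatic clearance and its retrograde inverse
#'
#' `well_stirred_clearance()` is the forward well-stirred (venous equilibrium)
#' liver model, `CLh = Q * fup * CLu,int / (Q + fup * CLu,int)`.
#' `well_stirred_retrograde()` inverts it to recover the unbound intrinsic
#' clearance from an observed organ clearance:
#' `CLu,int = Q * CL / (fup * (Q - CL))`. The two are exact inverses on
#' `0 < CL < Q`.
#'
#' @param q_li Hepatic plasma flow, mL/min.
#' @param clu_int Unbound intrinsic clearance, mL/min.
#' @param cl_nr Observed (non-renal) organ clearance, mL/min.
#' @param fup Unbound fraction in plasma (0, 1].
#' @return Clearance in mL/min.
#' @examples
#' well_stirred_retrograde(20, 10, 1) # -> 20
#' well_stirred_clearance(20, 1, 20)  # -> 10 (round trip)
#' @export
well_stirred_clearance <- function(q_li, fup, clu_int) {
  stopifnot(q_li > 0, fup > 0, fup <= 1, clu_int >= 0)
  q_li * fup * clu_int / (q_li + fup * clu_int)
}

#' @rdname well_stirred_clearance
#' @export
well_stirred_retrograde <- function(q_li, cl_nr, fup) {
  stopifnot(q_li > 0, fup > 0, fup <= 1, cl_nr >= 0)
  if (cl_nr >= q_li) {
    stop("organ clearance cannot equal or exceed organ flow (CL = ",
         cl_nr, ", Q = ", q_li, ")")
  }
  q_li * cl_nr / (fup * (q_li - cl_nr))
}

#' Organ extraction ratio
#'
#' Fraction of drug removed in a single pass through an eliminating organ,
#' `ER = CL / Q` with the clearance referenced to the organ plasma flow.
#'
#' @param cl Organ clearance, mL/min (0 <= cl < q).
#' @param q Organ plasma flow, mL/min.
#' @return Extraction ratio in \[0, 1).
#' @export
extraction_ratio <- function(cl, q) {
  stopifnot(q > 0, cl >= 0)
  if (cl >= q) stop("clearance exceeds organ flow: ER would be >= 1")
  cl / q
}

#' Scale renal active uptake by a fitted fold change
#'
#' The basolateral uptake clearance is the sum of an active (transporter) and
#' a passive component, `PSin = PSact + PSpas`. A treatment that changes
#' transporter function by a fold `Ract` acts on the active component only:
#' `PSin' = PSact * Ract + PSpas`.
#'
#' @param ps_in Control basolateral uptake clearance, mL/min.
#' @param ps_pas Passive component (equal to the basolateral efflux PSout),
#'   mL/min; must not exceed `ps_in`.
#' @param r_act Fold change of the active component (> 0).
#' @return Scaled uptake clearance, mL/min.
#' @examples
#' apply_ract(22.1, 7.61, 0.675)
#' @export
apply_ract <- function(ps_in, ps_pas, r_act) {
  stopifnot(ps_pas >= 0, r_act > 0)
  if (ps_in < ps_pas) {
    stop("`ps_in` must be at least `ps_pas`: the active component cannot be negative")
  }
  (ps_in - ps_pas) * r_act + ps_pas
}

#' Scale apical secretory clearance by a protein fold change
#'
#' MATE-type apical efflux is assumed proportional to transporter protein, so
#' a measured protein fold change multiplies the secretory intrinsic
#' clearance directly: `CLu,int,r' = CLu,int,r * Rmate`.
#'
#' @param clu_int_r Apical secretory intrinsic clearance, mL/min (>= 0).
#' @param r_mate Protein fold change (>= 0).
#' @return Scaled clearance, mL/min.
#' @export
apply_rmate <- function(clu_int_r, r_mate) {
  if (clu_int_r < 0 || r_mate < 0) stop("inputs must be non-negative")
  clu_int_r * r_mate
}

#' Percent decrease in hepatic uptake implied by a protein fold change
#'
#' Hepatic basolateral uptake has a saturable (transporter-mediated) and a
#' non-saturable component. Scaling only the saturable fraction `f` by a
#' protein fold `r` gives a new total fold `f * r + (1 - f)`; the return value
#' is the implied percent decrease `100 * (1 - (f * r + 1 - f))`.
#'
#' @param saturable_fraction Saturable fraction of total uptake, in \[0, 1\].
#' @param protein_fold Fold change in transporter protein (> 0).
#' @return Percent decrease in total uptake clearance.
#' @examples
#' scale_hepatic_uptake(0.557, 0.309)
#' @export
scale_hepatic_uptake <- function(saturable_fraction, protein_fold) {
  stopifnot(saturable_fraction >= 0, saturable_fraction <= 1, protein_fold > 0)
  new_fold <- saturable_fraction * protein_fold + (1 - saturable_fraction)
  (1 - new_fold) * 100
}

#' Relative expression fold from a delta-delta-Ct value
#'
#' Standard comparative-Ct quantification of qPCR data: fold expression
#' relative to control is `2^(-ddCt)`.
#'
#' @param delta_delta_ct Delta-delta-Ct, in cycles (finite numeric).
#' @return Fold expression relative to control.
#' @export
expression_fold <- function(delta_delta_ct) {
  stopifnot(all(is.finite(delta_delta_ct)))
  2^(-delta_delta_ct)
}

#' Percent change from control to treated
#'
#' `(control - treated) / control * 100`; positive values are decreases.
#'
#' @param control Control-arm value (non-zero).
#' @param treated Treated-arm value.
#' @return Percent change.
#' @export
percent_change <- function(control, treated) {
  if (any(control == 0)) stop("`control` must be non-zero")
  (control - treated) / control * 100
}
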