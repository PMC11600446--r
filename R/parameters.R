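# Nominal parameter table for the reduced-order cardiorenal model.
#
# The model is anchored at a "normal" physiological operating point:
# MAP 94 mmHg, GFR 129.6 mL/min (snGFR
# 54 nL/min x 2.4e6 nephrons), RBF 1,100 mL/min, glomerular pressure 52 mmHg,
# Ang II 12 pg/mL, aldosterone 11 ng/dL, ANP 27 pmol/L, ECFV 15 L, LV mass
# 223 g.  Structural constants below are solved so that this operating point
# is an exact fixed point of the daily map (see the methods vignette).
#
# Perturbation classes:
#   narrow - varied +/-5% when building virtual patients,
#   wide   - the named subset varied up to +100% (lower bound keeps
#            positivity),
#   fixed  - never perturbed (unit constants, protocol constants, and the
#            damage law whose threshold/delay are trial-level facts).

# Derived structural constants (kept symbolic here so the arithmetic is
# auditable):
#   per-kidney flow 550 mL/min, per-kidney GFR 64.8 mL/min
#   ra_base  = (94 - 0.004*550 - 52) / 550          = 0.07236364
#   re_base  = (52 - 4) / (550 - 64.8)              = 0.09892827
#   kf_ks    = 150*24/54 - 24                       = 42.666667
#   fe_dist0 = [123 / (129.6*0.14*1440)] / 0.30     = 0.015692357
#   md0      = 129.6*0.14*0.30                      = 5.4432 mEq/min

.param_rows <- function() {
  r <- function(name, nominal, units, class, descr)
    data.frame(name = name, nominal = nominal, units = units,
               class = class, description = descr,
               stringsAsFactors = FALSE)
  sig4 <- function(prefix, A, b, m, s, units_in, descr) {
    rbind(
      r(paste0(prefix, ".A"), A, "mult", "narrow", paste(descr, "amplitude")),
      r(paste0(prefix, ".b"), b, "mult", "narrow", paste(descr, "offset")),
      r(paste0(prefix, ".m"), m, units_in, "narrow", paste(descr, "midpoint")),
      r(paste0(prefix, ".s"), s, units_in, "narrow", paste(descr, "slope scale"))
    )
  }
  rbind(
    # -- intake and body fluid --------------------------------------------
    r("salt_intake", 123, "mEq/day", "wide", "dietary sodium intake"),
    r("na_conc", 140, "mEq/L", "fixed", "plasma sodium concentration (osmolar clamp)"),
    r("ecfv0", 15, "L", "narrow", "normal extracellular fluid volume"),
    # -- systemic circulation ---------------------------------------------
    r("map_base", 94, "mmHg", "narrow", "normal mean arterial pressure"),
    r("gv_gain", 6, "-", "narrow", "long-term volume->pressure gain (whole-body autoregulation)"),
    r("co_base", 5, "L/min", "narrow", "normal cardiac output (diagnostic)"),
    r("pulse_pressure", 36, "mmHg", "narrow", "pulse pressure (SBP = MAP + 2/3 PP)"),
    r("venous_p", 4, "mmHg", "fixed", "renal venous pressure"),
    r("sns_tone", 1, "mult", "wide", "baseline sympathetic nerve activity"),
    r("hr_setpoint", 1, "mult", "wide", "heart-rate set point (cardiac pressor scale)"),
    r("baro_gain", 1, "mult", "wide", "baroreceptor sensitivity (exponent on baroreflex curve)"),
    r("w_sns_map", 0.5, "-", "narrow", "weight of sympathetic tone on arterial pressure"),
    r("w_sns_renin", 0.5, "-", "narrow", "weight of sympathetic tone on renin secretion"),
    r("w_hr", 0.3, "-", "narrow", "weight of heart-rate set point on arterial pressure"),
    # -- renal vasculature -------------------------------------------------
    r("rvr_scale", 1, "mult", "wide", "renal vascular resistance scale"),
    r("r_preaff", 0.004, "mmHg/(mL/min)", "narrow", "renal artery + interlobar resistance, per kidney"),
    r("ra_base", 39.8 / 550, "mmHg/(mL/min)", "narrow", "afferent resistance per kidney at 1.2e6 nephrons/kidney"),
    r("re_base", 48 / 485.2, "mmHg/(mL/min)", "narrow", "efferent resistance per kidney at 1.2e6 nephrons/kidney"),
    r("myogenic_gain", 1, "mult", "wide", "myogenic sensitivity (exponent on myogenic curve)"),
    r("aff_scale_exp", 0.84, "-", "narrow", "exponent of afferent resistance on inverse nephron mass (remnant preglomerular adaptation)"),
    r("w_tgf", 0.6, "-", "narrow", "weight (exponent) of TGF signal on afferent tone"),
    # -- filtration --------------------------------------------------------
    r("n_nephrons0", 2.4e6, "nephrons", "fixed", "nominal nephron number before CKD induction"),
    r("kf_smax", 150, "nL/min", "narrow", "single-nephron filtration ceiling"),
    r("kf_ks", 150 * 24 / 54 - 24, "mmHg", "narrow", "half-saturation of net filtration pressure"),
    r("popp", 28, "mmHg", "narrow", "lumped Bowman + oncotic opposing pressure"),
    # -- tubular sodium handling ------------------------------------------
    r("prox_reabs", 0.70, "fraction", "wide", "proximal tubule fractional sodium reabsorption"),
    r("dist_reabs_gain", 1, "mult", "wide", "distal tubule reabsorption gain (divides fractional excretion)"),
    r("fe_dist0", 123 / (129.6 * 0.14 * 1440) / 0.30, "fraction", "narrow",
      "fractional escape of distally-delivered sodium at the operating point"),
    r("pn_set", 94, "mmHg", "narrow", "pressure-natriuresis setpoint"),
    r("pn_slope", 18, "mmHg", "narrow", "pressure-natriuresis e-fold scale"),
    # -- hormones ----------------------------------------------------------
    r("renin_gain", 1, "mult", "wide", "baseline renin secretion gain"),
    r("aldo_gain", 1, "mult", "wide", "baseline aldosterone secretion gain"),
    r("angii_base", 12, "pg/mL", "narrow", "normal plasma angiotensin II"),
    r("aldo_base", 11, "ng/dL", "narrow", "normal plasma aldosterone"),
    r("anp_base", 27, "pmol/L", "narrow", "normal plasma ANP"),
    r("tau_hormone", 0.25, "days", "fixed", "hormone relaxation time constant"),
    # -- left ventricle ----------------------------------------------------
    r("lv_base", 223, "g", "narrow", "normal left-ventricular mass"),
    r("lv_tau", 100, "days", "narrow", "LV mass remodeling time constant"),
    # -- amlodipine PK/PD --------------------------------------------------
    r("amlo_ka", 0.3, "1/h", "narrow", "amlodipine first-order absorption rate"),
    r("amlo_cl", log(2) / 36 * 1225, "L/h", "wide", "amlodipine apparent clearance"),
    r("amlo_vd", 1225, "L", "narrow", "amlodipine apparent distribution volume"),
    r("amlo_f", 0.64, "fraction", "narrow", "amlodipine bioavailability (gut permeability)"),
    r("ccb_emax_sys", 0.35, "fraction", "narrow", "max fractional systemic arteriolar dilation"),
    r("ccb_emax_aff", 0.45, "fraction", "narrow", "max fractional afferent arteriolar dilation"),
    r("ccb_ec50", 12, "ng/mL", "narrow", "amlodipine half-effect concentration"),
    r("ccb_nat_emax", 2.2, "fraction", "narrow", "max fractional direct tubular natriuretic effect of amlodipine"),
    # -- glomerulosclerosis ------------------------------------------------
    r("damage_threshold", 70, "mmHg", "fixed", "glomerular pressure threshold for nephron damage"),
    r("damage_delay", 120, "days", "fixed", "delay before scheduled damage is realized"),
    r("damage_gain", 40, "nephrons/day/mmHg", "fixed",
      "damage rate per mmHg above threshold (tuned to chronic GFR decline)"),
    # -- sigmoid couplings -------------------------------------------------
    # (md0 = 5.4432 mEq/min is the normal macula densa sodium delivery)
    sig4("tgf_md", 1.6, 0.2, 5.4432, 5.40, "mEq/min", "TGF vs macula densa Na delivery:"),
    sig4("tgf_ang", 1.0, 0.5, 12, 20, "pg/mL", "TGF sensitization by Ang II:"),
    sig4("renin_md", 1.4, 0.3, 5.4432, 2.0, "mEq/min", "renin secretion vs macula densa Na delivery (decreasing):"),
    sig4("renin_p", 1.0, 0.5, 94, 18, "mmHg", "renin secretion vs renal perfusion pressure (decreasing):"),
    sig4("ald_ang", 1.2, 0.4, 12, 8, "pg/mL", "aldosterone vs Ang II:"),
    sig4("ald_gfr", 1.6, 0.2, 129.6, 40, "mL/min", "aldosterone vs GFR (potassium-retention proxy, decreasing):"),
    sig4("anp_v", 2.2, 1 - 2.2 / (1 + exp(2)), 15.7, 0.35, "L", "ANP vs extracellular volume:"),
    sig4("fe_ald", 0.8, 0.6, 11, 8, "ng/dL", "sodium excretion vs aldosterone (decreasing):"),
    sig4("fe_ang", 0.35, 0.825, 12, 10, "pg/mL", "sodium excretion vs Ang II (decreasing):"),
    sig4("fe_anp", 2.0, 1 - 2.0 / (1 + exp(1.5)), 45, 12, "pmol/L", "sodium excretion vs ANP:"),
    sig4("myo", 0.6, 0.7, 94, 20, "mmHg", "myogenic afferent tone vs arterial pressure:"),
    sig4("baro", 0.4, 0.8, 94, 15, "mmHg", "baroreflex sympathetic scaling vs arterial pressure (decreasing):"),
    sig4("ang_aff", 0.2, 0.9, 12, 15, "pg/mL", "afferent tone vs Ang II:"),
    sig4("ang_eff", 1.4, 0.3, 12, 8, "pg/mL", "efferent tone vs Ang II:"),
    sig4("pres_ang", 0.15, 0.925, 12, 10, "pg/mL", "systemic pressor effect of Ang II:"),
    sig4("pres_anp", 0.3, 0.85, 27, 20, "pmol/L", "systemic depressor effect of ANP (decreasing):"),
    sig4("lv_load", 0.8, 0.6, 118, 20, "mmHg", "LV mass target vs systolic load:")
  )
}

# Sigmoids whose logistic argument is negated (decreasing couplings).
.decreasing_sigmoids <- c("renin_md", "renin_p", "ald_gfr", "fe_ald",
                          "fe_ang", "baro", "pres_anp")

#' Nominal parameter table
#'
#' One row per model parameter: name, nominal value, units, perturbation
#' class (\code{narrow} = varied 5\%, \code{wide} = varied up to 100\%,
#' \code{fixed} = never varied), and a short description.  This table is the
#' single source of truth for the model's constants; virtual patients are
#' expressed as multiplicative perturbations of it.
#'
#' @return a \code{data.frame} with columns \code{name}, \code{nominal},
#'   \code{units}, \code{class}, \code{description}.
#' @export
parameter_table <- function() .param_rows()

#' Default (nominal) model parameters
#'
#' @return named numeric vector of nominal parameter values.
#' @export
default_parameters <- function() {
  tab <- parameter_table()
  stats::setNames(tab$nominal, tab$name)
}

#' Patient parameters: nominal values times perturbation multipliers
#'
#' @param multipliers named numeric vector of perturbation factors; names must
#'   be parameter names from \code{\link{parameter_table}}.  Unnamed
#'   parameters keep multiplier 1.
#' @return object of class \code{"patient_parameters"} with fields
#'   \code{nominal}, \code{multipliers} and \code{values}
#'   (\code{nominal * multipliers}).
#' @export
patient_parameters <- function(multipliers = numeric(0)) {
  nominal <- default_parameters()
  mult <- stats::setNames(rep(1, length(nominal)), names(nominal))
  if (length(multipliers)) {
    bad <- setdiff(names(multipliers), names(nominal))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    mult[names(multipliers)] <- multipliers
  }
  values <- nominal * mult
  .validate_param_values(values)
  structure(list(nominal = nominal, multipliers = mult, values = values),
            class = "patient_parameters")
}

.validate_param_values <- function(values) {
  must_pos <- c("salt_intake", "ecfv0", "map_base", "rvr_scale", "ra_base",
                "re_base", "kf_smax", "renin_gain", "aldo_gain", "sns_tone",
                "baro_gain", "myogenic_gain", "amlo_cl", "amlo_vd",
                "prox_reabs", "dist_reabs_gain", "hr_setpoint")
  bad <- must_pos[values[must_pos] <= 0]
  if (length(bad)) {
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (abs(values[["n_nephrons0"]] - 2.4e6) > 1e-6) {
    stop("nominal nephron number must be 2,400,000 before CKD induction",
         call. = FALSE)
  }
  invisible(values)
}

# Coerce the various parameter representations to a plain named vector of
# absolute values (single patient).
as_param_values <- function(params) {
  if (inherits(params, "patient_parameters")) return(params$values)
  if (is.numeric(params) && !is.null(names(params))) return(params)
  stop("params must be a patient_parameters object or a named numeric vector",
       call. = FALSE)
}

#' Write / read a parameter configuration (JSON)
#'
#' The on-disk format is one entry per parameter with its name, nominal
#' value, units, and perturbation class, plus an optional multiplier.  It
#' round-trips losslessly through \code{read_parameter_config}.
#'
#' @param params a \code{patient_parameters} object.
#' @param path file path for the JSON config.
#' @return \code{write_parameter_config} returns \code{path} invisibly;
#'   \code{read_parameter_config} returns a \code{patient_parameters} object.
#' @export
write_parameter_config <- function(params, path) {
  params <- if (inherits(params, "patient_parameters")) params
            else patient_parameters()
  tab <- parameter_table()
  tab$multiplier <- params$multipliers[tab$name]
  jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parameter_config
#' @export
read_parameter_config <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_parameters(stats::setNames(tab$multiplier, tab$name))
}

# Retrieve one of the model's named sigmoid couplings, with per-patient
# perturbed parameters.  `p` is a list of per-patient parameter vectors (or a
# single named vector); returns evaluation at x.
model_sig <- function(p, prefix, x) {
  sig_eval(x,
           A = p[[paste0(prefix, ".A")]],
           b = p[[paste0(prefix, ".b")]],
           m = p[[paste0(prefix, ".m")]],
           s = p[[paste0(prefix, ".s")]],
           decreasing = prefix %in% .decreasing_sigmoids)
}
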