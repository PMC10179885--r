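#' Gradient elution program
#'
#' Linear binary gradient: the share of the stronger solvent B (toluene for
#' the hexane/toluene system III) rises linearly from
#' \code{percent_B_start} at \code{slope} percent per minute and is clipped
#' at 100\%. The optimized separation used 0.5 \%/min; 1.00, 0.75 and 0.66
#' \%/min are steeper alternatives with poorer within-class resolution.
#'
#' @param system Solvent system label: \code{"I"} (hexane/acetonitrile/
#'   2-propanol), \code{"II"} (isooctane/acetonitrile/2-propanol) or
#'   \code{"III"} (hexane/toluene).
#' @param percent_B_start Starting \%B (default 0).
#' @param slope Gradient slope in \%B per minute (default 0.5).
#' @param duration Optional program duration in minutes.
#' @return Object of class \code{gradient_program}.
#' @export
gradient_program <- function(system = "III", percent_B_start = 0,
                             slope = 0.5, duration = NULL) {
  if (percent_B_start < 0 || percent_B_start > 100)
    stop("percent_B_start must lie in [0, 100]")
  if (slope < 0) stop("slope must be >= 0")
  structure(list(system = system, percent_B_start = percent_B_start,
                 slope = slope, duration = duration),
            class = "gradient_program")
}

#' \%B of the mobile phase at a given time
#'
#' @param t Time in minutes (>= 0); vectorized.
#' @param program A \code{\link{gradient_program}}.
#' @return \%B in [0, 100].
#' @examples
#' gradient_percent_B(10, gradient_program(slope = 0.5))  # 5
#' @export
gradient_percent_B <- function(t, program = gradient_program()) {
  if (any(t < 0)) stop("time must be non-negative")
  pmin(program$percent_B_start + program$slope * t, 100)
}

#' Retention model for silver-ion chromatography of hydrocarbons
#'
#' Retention in Ag-HPLC is driven by the complexation of C=C electrons with
#' the immobilized silver ions: species elute in groups by double-bond count
#' (the unsaturation class), and within each class the retention time falls
#' slightly with carbon number (a residual normal-phase contribution), while
#' trans double bonds complex more weakly than cis so all-trans species
#' elute ahead of their cis counterparts. The model is
#' \deqn{Rt = apex(system, T, DB) + s_{DB} (CN - CN^{ref}_{DB})
#'       - \Delta_{trans} + k \cdot spacing}
#' where \code{apex} is the class apex retention time (the class's most
#' abundant peak), \code{s_DB < 0} the within-class carbon-number slope,
#' \code{Delta_trans > 0} is subtracted for all-trans species, and \code{k}
#' is a signed positional-isomer slot relative to the class anchor.
#'
#' @param class_apex data.frame with columns \code{system},
#'   \code{temperature_c}, \code{db_class}, \code{apex_min}; defaults to the
#'   packaged class-apex reference table.
#' @param ref_cn Named numeric: reference carbon number per class at which
#'   the class apex is anchored (defaults to the most abundant species per
#'   class of the packaged fly profile: C30:0, C39:1, C41:2, C43:3).
#' @param cn_slope Named numeric, minutes per carbon within class; must be
#'   negative (heavier species elute earlier).
#' @param isomer_spacing Minutes between adjacent positional-isomer
#'   sub-peaks (default 0.4, the typical spacing in the diene region).
#' @param trans_offset Named numeric (classes 1..3), minutes subtracted for
#'   an all-trans species; must be positive (trans before cis).
#' @param peak_sigma Named numeric, Gaussian chromatographic standard
#'   deviation in minutes per class. Saturated species co-elute in a few
#'   seconds; later-eluting classes broaden, but the defaults stay well
#'   below the positional-isomer spacing so that isomer sub-peaks remain
#'   close to baseline-separated, as observed for the diene region.
#' @param rt_jitter_rel Relative run-to-run retention jitter (1 sd) applied
#'   by the simulator; default 0.5\%, inside the published same-day
#'   reproducibility of about 1\%.
#' @return Object of class \code{retention_model}.
#' @export
retention_model <- function(class_apex = NULL,
                            ref_cn = c(`0` = 30, `1` = 39, `2` = 41, `3` = 43),
                            cn_slope = c(`0` = -0.005, `1` = -0.08,
                                         `2` = -0.25, `3` = -0.6),
                            isomer_spacing = 0.4,
                            trans_offset = c(`1` = 6, `2` = 14, `3` = 20),
                            peak_sigma = c(`0` = 0.02, `1` = 0.04,
                                           `2` = 0.08, `3` = 0.12),
                            rt_jitter_rel = 0.005) {
  if (is.null(class_apex)) class_apex <- load_fixture("table2")
  if (any(cn_slope >= 0)) stop("cn_slope must be negative")
  if (any(trans_offset <= 0)) stop("trans_offset must be positive")
  if (any(peak_sigma <= 0)) stop("peak_sigma must be positive")
  structure(list(class_apex = class_apex, ref_cn = ref_cn,
                 cn_slope = cn_slope, isomer_spacing = isomer_spacing,
                 trans_offset = trans_offset, peak_sigma = peak_sigma,
                 rt_jitter_rel = rt_jitter_rel),
            class = "retention_model")
}

.class_apexes <- function(model, system, temperature) {
  ca <- model$class_apex
  sel <- ca$system == system & ca$temperature_c == temperature
  if (!any(sel))
    stop("no class apex data for system ", system, " at ", temperature,
         " degrees C")
  ap <- ca[sel, ]
  ap <- ap[order(ap$db_class), ]
  apex <- stats::setNames(ap$apex_min, ap$db_class)
  if (any(diff(apex) <= 0))
    stop("class apexes must be strictly increasing with double-bond count ",
         "(system ", system, ", ", temperature, " degrees C: ",
         paste(apex, collapse = ", "), ")")
  apex
}

#' Predict the retention time of a hydrocarbon
#'
#' @param species An \code{hc_species}; an all-trans geometry shifts the
#'   species earlier by the class trans offset.
#' @param model A \code{\link{retention_model}}.
#' @param system,temperature Chromatographic condition; the pair must be
#'   present in the model's class-apex table and its apexes must be strictly
#'   increasing with the double-bond class.
#' @param isomer Signed positional-isomer slot relative to the class anchor
#'   peak (default 0). Isomer identity is an opaque elution-order index;
#'   double-bond positions are not modeled.
#' @return Retention time in minutes.
#' @examples
#' predict_rt(hc_species(30, 0))                       # saturated cluster
#' predict_rt(hc_species(41, 2))                       # diene class apex
#' @export
predict_rt <- function(species, model = retention_model(), system = "III",
                       temperature = 15, isomer = 0) {
  stopifnot(inherits(species, "hc_species"))
  apex <- .class_apexes(model, system, temperature)
  cls <- as.character(species$double_bonds)
  if (!cls %in% names(apex))
    stop("no apex for double-bond class ", cls)
  rt <- apex[[cls]] +
    model$cn_slope[[cls]] * (species$carbon_number - model$ref_cn[[cls]]) +
    isomer * model$isomer_spacing
  if (species$double_bonds > 0 && !is.null(species$geometry) &&
      all(species$geometry == "trans"))
    rt <- rt - model$trans_offset[[cls]]
  unname(rt)
}

# Piecewise-linear adduct-fraction knots for the hexane/toluene system,
# anchored at %toluene 0/10/25/50/75/100. Only the qualitative shape is
# constrained by observation: the C3H3+ adduct dominates in pure hexane, the
# protonated molecule peaks at 40-60% toluene, and di-/tri-unsaturated
# species pick up radical cations and protonated-toluene adducts at high
# %toluene; saturated species always ionize mainly as [M-H]+.
.TOLUENE_KNOT_PCT <- c(0, 10, 25, 50, 75, 100)
.TOLUENE_KNOTS <- list(
  `0` = rbind("[M-H]+"     = c(.60, .60, .60, .60, .60, .60),
              "[M+H]+"     = c(.05, .08, .10, .10, .08, .06),
              "[M]+."      = c(.03, .03, .04, .05, .06, .07),
              "[M+C3H3]+"  = c(.25, .12, .06, .03, .02, .01),
              "[M+C7H9]+"  = c(.00, .02, .04, .06, .08, .10)),
  `1` = rbind("[M-H]+"     = c(.10, .08, .06, .05, .04, .03),
              "[M+H]+"     = c(.15, .45, .55, .60, .45, .30),
              "[M]+."      = c(.05, .06, .08, .10, .13, .15),
              "[M+C3H3]+"  = c(.60, .25, .10, .04, .02, .01),
              "[M+C7H9]+"  = c(.00, .02, .04, .08, .13, .18)),
  `2` = rbind("[M-H]+"     = c(.08, .06, .05, .04, .03, .02),
              "[M+H]+"     = c(.15, .45, .55, .58, .40, .25),
              "[M]+."      = c(.06, .08, .12, .16, .26, .34),
              "[M+C3H3]+"  = c(.60, .25, .10, .04, .02, .01),
              "[M+C7H9]+"  = c(.00, .03, .06, .11, .19, .28)))
.TOLUENE_KNOTS[["3"]] <- .TOLUENE_KNOTS[["2"]]

# Fixed adduct profiles for the isocratic-like elution in systems I and II
# (the analytes elute in nearly pure hexane / isooctane): hexane gives the
# +39 (C3H3+) and +85 (C6H13+) adducts, isooctane the +57 (C4H9+) adduct.
.FIXED_PROFILES <- list(
  I = list(
    `0` = c("[M-H]+" = .45, "[M+H]+" = .05, "[M]+." = .05,
            "[M+C3H3]+" = .25, "[M+C6H13]+" = .20),
    un  = c("[M-H]+" = .15, "[M+H]+" = .10, "[M]+." = .10,
            "[M+C3H3]+" = .40, "[M+C6H13]+" = .25)),
  II = list(
    `0` = c("[M-H]+" = .45, "[M+H]+" = .08, "[M]+." = .05,
            "[M+C3H3]+" = .07, "[M+C4H9]+" = .35),
    un  = c("[M-H]+" = .20, "[M+H]+" = .20, "[M]+." = .10,
            "[M+C3H3]+" = .10, "[M+C4H9]+" = .40)))

#' APCI response model
#'
#' Bundles the mobile-phase-dependent adduct fractions, the
#' unsaturation-dependent relative response factors, and the low-mass
#' fragment floor used by the simulator.
#'
#' @param db_response Named numeric, relative response factor per
#'   double-bond class; must be non-decreasing (APCI response grows with
#'   unsaturation, which is why peak areas are only comparable within a
#'   class). Defaults 1:3:5:7 for 0-3 double bonds.
#' @param fragment_floor Fraction of a species' adduct ion current emitted
#'   as low-mass chain fragments below m/z 350 (default 0.08).
#' @param toluene_knots List (per double-bond class) of adduct x knot
#'   matrices of raw fractions for the hexane/toluene gradient.
#' @param knot_pct \%toluene positions of the knots.
#' @param fixed_profiles Fixed adduct fraction sets for solvent systems I
#'   and II.
#' @return Object of class \code{response_model}.
#' @export
response_model <- function(db_response = c(`0` = 1, `1` = 3, `2` = 5, `3` = 7),
                           fragment_floor = 0.08,
                           toluene_knots = .TOLUENE_KNOTS,
                           knot_pct = .TOLUENE_KNOT_PCT,
                           fixed_profiles = .FIXED_PROFILES) {
  if (any(diff(db_response) < 0))
    stop("db_response must be non-decreasing in the double-bond class")
  if (fragment_floor < 0 || fragment_floor >= 1)
    stop("fragment_floor must lie in [0, 1)")
  structure(list(db_response = db_response, fragment_floor = fragment_floor,
                 toluene_knots = toluene_knots, knot_pct = knot_pct,
                 fixed_profiles = fixed_profiles),
            class = "response_model")
}

#' Adduct fractions at a given mobile-phase composition
#'
#' Piecewise-linear interpolation of the class-specific adduct fractions
#' over \%toluene, normalized to sum to 1.
#'
#' @param db_class Double-bond count (0-3; higher classes reuse the
#'   triunsaturated profile).
#' @param percent_toluene \%toluene in the mobile phase, in [0, 100].
#' @param model A \code{\link{response_model}}.
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' adduct_profile(0, 5)    # saturated: [M-H]+ dominated
#' adduct_profile(1, 50)   # monoene: [M+H]+ at its maximum
#' @export
adduct_profile <- function(db_class, percent_toluene,
                           model = response_model()) {
  if (percent_toluene < 0 || percent_toluene > 100)
    stop("percent_toluene must lie in [0, 100]")
  cls <- as.character(min(db_class, length(model$toluene_knots) - 1L))
  kn <- model$toluene_knots[[cls]]
  raw <- apply(kn, 1L, function(y)
    stats::approx(model$knot_pct, y, xout = percent_toluene, rule = 2)$y)
  raw / sum(raw)
}

# fractions for a species given solvent system; %B only used for system III
.adduct_fractions <- function(db_class, system, percent_B, model) {
  if (system == "III") return(adduct_profile(db_class, percent_B, model))
  fp <- model$fixed_profiles[[system]]
  if (is.null(fp)) stop("unknown solvent system: ", system)
  f <- if (db_class == 0) fp[["0"]] else fp[["un"]]
  f / sum(f)
}

#' Build a ground-truth composition from a report table
#'
#' Turns a reference report (e.g. a packaged profile table) into a simulator
#' composition whose within-class abundances equal the report's relative
#' areas. Positional isomers sharing CN:DB are kept as separate entries
#' indexed by elution order, with the most abundant isomer of each (class,
#' CN) group taken as the anchor sitting at the class-model retention time.
#' Optionally, a trace all-trans counterpart of every unsaturated species is
#' added at a configurable overall trans:cis area proportion, eluting ahead
#' of its cis counterpart; within-class abundances are then renormalized to
#' 100.
#'
#' @param report A \code{fixture_table} or a data.frame of report rows
#'   (columns \code{rt_min}, \code{cn}, \code{db}, \code{rel_area_pct},
#'   optional \code{geometry}).
#' @param class_shares Named numeric of class area shares (\%); taken from
#'   the fixture when \code{report} is a \code{fixture_table}.
#' @param trans_trace_share Ratio of summed trans-containing to
#'   cis-containing abundance to inject (e.g. \code{1/1000} for the
#'   trace level reported for insect profiles); 0 adds no trans entries.
#' @return Object of class \code{hc_composition}: data.frame with columns
#'   \code{cn}, \code{db}, \code{geometry}, \code{iso_index},
#'   \code{iso_offset}, \code{rt_hint}, \code{abundance_pct},
#'   \code{class_share_pct}.
#' @examples
#' comp <- composition_from_report(load_fixture("table4"))
#' nrow(comp)  # 44
#' @export
composition_from_report <- function(report, class_shares = NULL,
                                    trans_trace_share = 0) {
  if (inherits(report, "fixture_table")) {
    if (is.null(class_shares)) class_shares <- report$class_shares
    rows <- report$rows
  } else rows <- as.data.frame(report)
  if (is.null(class_shares))
    stop("class_shares must be supplied when report is a plain data.frame")
  if (any(rows$rel_area_pct <= 0))
    stop("report rows must have positive areas")
  present <- as.character(sort(unique(rows$db)))
  if (!all(present %in% names(class_shares)))
    stop("class share missing for double-bond class(es): ",
         paste(setdiff(present, names(class_shares)), collapse = ", "))
  if (trans_trace_share < 0) stop("trans_trace_share must be >= 0")
  rows <- rows[order(rows$db, rows$cn, rows$rt_min), ]
  geo <- if ("geometry" %in% names(rows)) rows$geometry else
    ifelse(rows$db > 0, "cis", "")
  geo[is.na(geo) | geo == ""] <- ifelse(rows$db[is.na(geo) | geo == ""] > 0,
                                        "cis", "")
  iso <- stats::ave(seq_len(nrow(rows)), rows$db, rows$cn, FUN = seq_along)
  # anchor = most abundant isomer of each (class, CN) group
  anchor <- stats::ave(rows$rel_area_pct, rows$db, rows$cn,
                       FUN = function(a) which.max(a))
  comp <- data.frame(cn = rows$cn, db = rows$db, geometry = geo,
                     iso_index = iso, iso_offset = iso - anchor,
                     rt_hint = rows$rt_min,
                     abundance_pct = rows$rel_area_pct,
                     class_share_pct = unname(class_shares[as.character(rows$db)]))
  if (trans_trace_share > 0) {
    uns <- comp[comp$db > 0, ]
    if (nrow(uns)) {
      tr <- uns
      tr$geometry <- "trans"
      tr$abundance_pct <- uns$abundance_pct * trans_trace_share
      tr$rt_hint <- NA_real_
      comp <- rbind(comp, tr)
    }
  }
  # renormalize each class to 100 (trace injection perturbs the sum)
  tot <- stats::ave(comp$abundance_pct, comp$db, FUN = sum)
  comp$abundance_pct <- comp$abundance_pct / tot * 100
  comp <- comp[order(comp$db, comp$cn, comp$iso_index,
                     comp$geometry != "trans"), ]
  rownames(comp) <- NULL
  class(comp) <- c("hc_composition", "data.frame")
  comp
}
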