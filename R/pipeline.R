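#' Annotate an Ag-HPLC/APCI-MS run
#'
#' The full inference pipeline. For every candidate species (carbon-number
#' grid crossed with the double-bond classes), the summed-ion chromatogram
#' of the three quantification channels ([M-H]+, [M]+., [M+H]+) is
#' reconstructed, restricted to that species' unsaturation-class retention
#' window, and integrated; each detected peak becomes an annotation with a
#' cis/trans geometry call from the per-class retention boundary, and
#' within-class relative areas are computed over the whole class.
#'
#' Restricting each species' chromatogram to its class window is what makes
#' the assignment unambiguous: every solvent-adduct channel of one species
#' coincides in ion formula only with species of a \emph{different}
#' double-bond class (e.g. the +39 C3H3+ adduct of CN:DB has the formula of
#' the [M-H]+ ion of (CN+3):(DB+1)), so inside a window the quantification
#' channels of distinct species never collide, and the alkane/alkene
#' CnH2n1+ degeneracy cannot leak a one-double-bond call into the saturated
#' window or vice versa.
#'
#' Species below the reporting threshold are moved to a traces section and
#' the main report is renormalized; with \code{traces = TRUE} the detection
#' floor is lowered so that trace-level peaks (such as rare all-trans
#' counterparts at a thousandth of the cis abundance) are still integrated.
#'
#' Every annotation must show signal in at least two of the three
#' quantification channels across the peak (the channels cross-feed through
#' the isotope envelope, so genuine species always do); this rejects
#' single-channel ghosts such as the M+2 isotope of a +39 solvent adduct
#' leaking into the deprotonated-molecule channel of the species three
#' carbons up.
#'
#' @param run A \code{synthetic_run} or mzML file path.
#' @param model A \code{\link{retention_model}} providing class windows and
#'   the geometry boundaries.
#' @param system,temperature Chromatographic condition; defaults are taken
#'   from the run metadata when present.
#' @param tolerance m/z tolerance in Da (> 0).
#' @param cn_range Carbon-number search grid.
#' @param min_height_frac Peak detection threshold as a fraction of the
#'   strongest class signal (default 0.002, low enough to reach the
#'   sub-percent species of real cuticular profiles while staying far above
#'   the instrument baseline).
#' @param min_width_scans Minimum peak width in scans.
#' @param threshold_pct Reporting threshold: species below this within-class
#'   relative area (\%) go to the traces section (default 0.1).
#' @param traces Lower the detection floor to \code{trace_height_frac} to
#'   pick up trace-level peaks (default \code{FALSE}).
#' @param trace_height_frac Detection floor used when \code{traces = TRUE}.
#' @param registry Adduct registry.
#' @return Object of class \code{hc_annotation}: list with \code{report}
#'   (main rows, within-class \code{rel_area_pct} summing to 100 per
#'   class), \code{traces}, \code{annotations} (all detected, with
#'   \code{rel_area_pct} over the full class), \code{class_shares} (share
#'   of total area per class, indicative only), \code{windows} and
#'   \code{params}.
#' @examples
#' \donttest{
#' comp <- composition_from_report(load_fixture("table4"))
#' run <- simulate_run(comp, seed = 1)
#' ann <- annotate_run(run)
#' head(ann$report)
#' }
#' @export
annotate_run <- function(run, model = retention_model(),
                         system = NULL, temperature = NULL,
                         tolerance = 0.3, cn_range = c(25L, 63L),
                         min_height_frac = 0.002, min_width_scans = 3L,
                         threshold_pct = 0.1, traces = FALSE,
                         trace_height_frac = 1e-5,
                         registry = adduct_registry()) {
  run <- .run_flat(run)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive number of Da")
  if (is.null(system)) system <- run$metadata$system %||% "III"
  if (is.null(temperature)) temperature <- run$metadata$temperature %||% 15
  if (!length(run$rt) || !nrow(run$centroids)) {
    warning("run holds no spectra; returning an empty annotation")
    empty <- .empty_annotation_df()
    return(structure(list(report = empty, traces = empty,
                          annotations = empty, class_shares = numeric(0),
                          windows = NULL,
                          params = list(tolerance = tolerance)),
                     class = "hc_annotation"))
  }
  windows <- calibrate_class_windows(run, model, system, temperature)
  bounds <- geometry_boundaries(model, system, temperature)
  ix <- .mz_index(run)
  hf <- if (traces) trace_height_frac else min_height_frac
  cns <- cn_range[1]:cn_range[2]

  ann <- list()
  for (wi in seq_len(nrow(windows))) {
    cls <- windows$db[wi]
    in_win <- run$rt >= windows$start[wi] & run$rt < windows$end[wi]
    if (!any(in_win)) next
    # first pass: traces for every candidate CN, to fix the class floor
    traces_cls <- lapply(cns, function(cn) {
      if (cls > (cn - 1) %/% 2) return(NULL)
      sp <- hc_species(cn, cls)
      targets <- vapply(.QUANT_ADDUCTS, function(a)
        ion_mz(sp, a, "monoisotopic", registry), numeric(1))
      tr <- .eic_from_index(ix, targets, tolerance)
      tr[!in_win] <- 0
      tr
    })
    class_max <- max(c(0, vapply(traces_cls,
                                 function(tr) if (is.null(tr)) 0 else max(tr),
                                 numeric(1))))
    if (class_max <= 0) next
    floor_abs <- hf * class_max
    scans_per_min <- 1 / stats::median(diff(run$rt))
    smooth <- .smooth_width(model$peak_sigma[[as.character(cls)]],
                            scans_per_min)
    # genuine class peaks span many scans; anything narrower than ~3 sigma
    # is an isolated noise spike
    min_width_cls <- max(min_width_scans,
                         round(3 * model$peak_sigma[[as.character(cls)]] *
                                 scans_per_min))
    for (k in seq_along(cns)) {
      tr <- traces_cls[[k]]
      if (is.null(tr) || max(tr) < floor_abs) next
      sp <- hc_species(cns[k], cls)
      targets <- vapply(.QUANT_ADDUCTS, function(a)
        ion_mz(sp, a, "monoisotopic", registry), numeric(1))
      eic <- data.frame(rt = run$rt, intensity = tr)
      pks <- detect_peaks(eic, min_height_frac = 0,
                          min_width_scans = min_width_cls,
                          floor_abs = floor_abs, smooth_scans = smooth)
      if (!nrow(pks)) next
      ok <- vapply(seq_len(nrow(pks)), function(p)
        .channels_present(ix, targets, tolerance, run$rt,
                          pks$left_rt[p], pks$right_rt[p]) >= 2L,
        logical(1))
      pks <- pks[ok, , drop = FALSE]
      if (!nrow(pks)) next
      geo <- if (cls == 0) rep("", nrow(pks)) else
        vapply(seq_len(nrow(pks)), function(p)
          call_geometry(data.frame(db = cls, apex_rt = pks$apex_rt[p]),
                        bounds), character(1))
      ann[[length(ann) + 1L]] <- data.frame(
        cn = cns[k], db = cls, geometry = geo,
        apex_rt = pks$apex_rt, left_rt = pks$left_rt,
        right_rt = pks$right_rt, area = pks$area, height = pks$height,
        matched_adducts = paste(.QUANT_ADDUCTS, collapse = ";"),
        assigned = TRUE)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    .empty_annotation_df()
  if (!nrow(annotations)) {
    warning("no peaks detected")
    return(structure(list(report = annotations, traces = annotations,
                          annotations = annotations,
                          class_shares = numeric(0), windows = windows,
                          params = list(tolerance = tolerance)),
                     class = "hc_annotation"))
  }
  annotations <- annotations[order(annotations$db, annotations$apex_rt), ]
  rownames(annotations) <- NULL
  annotations$iso_index <- stats::ave(
    seq_len(nrow(annotations)), annotations$db, annotations$cn,
    annotations$geometry, FUN = seq_along)
  annotations <- quantify_within_class(annotations)
  annotations$rt_min <- annotations$apex_rt

  main <- annotations[annotations$rel_area_pct >= threshold_pct, ]
  trc <- annotations[annotations$rel_area_pct < threshold_pct, ]
  main <- quantify_within_class(main)  # renormalize the reported set to 100
  tot <- tapply(annotations$area, annotations$db, sum)
  class_shares <- 100 * tot / sum(tot)
  structure(list(report = main, traces = trc, annotations = annotations,
                 class_shares = class_shares, windows = windows,
                 params = list(tolerance = tolerance, system = system,
                               temperature = temperature,
                               min_height_frac = hf,
                               threshold_pct = threshold_pct,
                               traces = traces)),
            class = "hc_annotation")
}

.empty_annotation_df <- function() {
  data.frame(cn = integer(), db = integer(), geometry = character(),
             apex_rt = numeric(), left_rt = numeric(), right_rt = numeric(),
             area = numeric(), height = numeric(),
             matched_adducts = character(), assigned = logical(),
             iso_index = integer(), rel_area_pct = numeric(),
             rt_min = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of quantification channels with non-trivial signal across a peak
.channels_present <- function(ix, targets, tolerance, rt, left_rt, right_rt,
                              min_frac = 0.05) {
  sums <- vapply(targets, function(t) {
    i1 <- findInterval(t - tolerance, ix$mz) + 1L
    i2 <- findInterval(t + tolerance, ix$mz)
    if (i2 < i1) return(0)
    j <- i1:i2
    sel <- rt[ix$scan[j]] >= left_rt & rt[ix$scan[j]] <= right_rt
    sum(ix$intensity[j][sel])
  }, numeric(1))
  if (max(sums) <= 0) return(0L)
  sum(sums >= min_frac * max(sums))
}

# odd moving-average width matched to the class peak width (about 0.8 sigma)
.smooth_width <- function(sigma_min, scans_per_min) {
  w <- round(0.8 * sigma_min * scans_per_min)
  w <- max(3L, min(11L, as.integer(w)))
  if (w %% 2L == 0L) w + 1L else w
}

#' @export
print.hc_annotation <- function(x, ...) {
  cat("<hc_annotation> ", nrow(x$report), " reported species (",
      nrow(x$traces), " traces) across classes ",
      paste(sort(unique(x$report$db)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' cis:trans summed-area ratio
#'
#' Ratio of the summed peak areas of cis-called to trans-called unsaturated
#' annotations (the headline estimate used to describe how rare trans
#' double bonds are in a cuticular profile). Uses all annotations including
#' the traces section.
#'
#' @param annotation An \code{hc_annotation} or a data.frame of annotations
#'   with \code{db}, \code{geometry}, \code{area}.
#' @return The cis:trans area ratio (Inf when no trans species was
#'   detected; NaN when neither was).
#' @export
cis_trans_ratio <- function(annotation) {
  a <- if (inherits(annotation, "hc_annotation")) annotation$annotations
       else annotation
  a <- a[a$db > 0, ]
  sum(a$area[a$geometry == "cis"]) / sum(a$area[a$geometry == "trans"])
}

#' Score an annotation report against ground truth
#'
#' Truth entries and produced annotations are matched within each (CN, DB)
#' pair by nearest retention time (greedily, closest pairs first, each peak
#' used once). Reported metrics: species precision and recall, geometry
#' accuracy over matched unsaturated species, and the RMSE (percentage
#' points) between produced and true within-class relative areas, overall
#' and per class.
#'
#' @param report An \code{hc_annotation}, or a data.frame of produced rows
#'   with \code{cn}, \code{db}, \code{geometry}, retention (\code{rt_min}
#'   or \code{apex_rt}) and \code{rel_area_pct}.
#' @param truth A ground-truth table: the \code{ground_truth} of a
#'   \code{synthetic_run}, an \code{hc_composition}, or a data.frame with
#'   \code{cn}, \code{db}, \code{geometry}, \code{abundance_pct} and a true
#'   retention column (\code{rt_true} or \code{rt_hint}).
#' @param rt_tol Maximum |delta Rt| (minutes) for a valid match (default 2).
#' @return List with \code{precision}, \code{recall},
#'   \code{geometry_accuracy}, \code{area_rmse}, \code{area_rmse_by_class},
#'   \code{n_truth}, \code{n_produced}, \code{n_matched} and the matched
#'   pair table.
#' @export
evaluate_recovery <- function(report, truth, rt_tol = 2) {
  prod <- if (inherits(report, "hc_annotation")) report$annotations
          else as.data.frame(report)
  tr <- if (inherits(truth, "synthetic_run")) truth$ground_truth
        else as.data.frame(truth)
  if (!nrow(prod) || !nrow(tr))
    stop("evaluate_recovery needs non-empty report and truth")
  prt <- if ("apex_rt" %in% names(prod)) prod$apex_rt else prod$rt_min
  trt <- if ("rt_true" %in% names(tr)) tr$rt_true else tr$rt_hint
  if (is.null(trt)) stop("truth needs an rt_true or rt_hint column")
  if (!"geometry" %in% names(tr)) tr$geometry <- ifelse(tr$db > 0, "cis", "")
  tr$geometry[is.na(tr$geometry)] <- ""

  matches <- list()
  used_p <- logical(nrow(prod))
  for (key in unique(paste(tr$cn, tr$db))) {
    ti <- which(paste(tr$cn, tr$db) == key)
    pi <- which(paste(prod$cn, prod$db) == key)
    if (!length(pi)) next
    # greedy nearest-Rt pairing
    cand <- expand.grid(t = ti, p = pi)
    cand$d <- abs(trt[cand$t] - prt[cand$p])
    cand <- cand[cand$d <= rt_tol, ]
    cand <- cand[order(cand$d), ]
    taken_t <- integer(0); taken_p <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (cand$t[r] %in% taken_t || cand$p[r] %in% taken_p) next
      taken_t <- c(taken_t, cand$t[r]); taken_p <- c(taken_p, cand$p[r])
      matches[[length(matches) + 1L]] <- data.frame(
        cn = tr$cn[cand$t[r]], db = tr$db[cand$t[r]],
        rt_true = trt[cand$t[r]], rt_produced = prt[cand$p[r]],
        geometry_true = tr$geometry[cand$t[r]],
        geometry_called = prod$geometry[cand$p[r]],
        area_true = tr$abundance_pct[cand$t[r]],
        area_produced = if ("rel_area_pct" %in% names(prod))
          prod$rel_area_pct[cand$p[r]] else NA_real_)
      used_p[cand$p[r]] <- TRUE
    }
  }
  m <- if (length(matches)) do.call(rbind, matches) else
    data.frame(cn = integer(), db = integer(), rt_true = numeric(),
               rt_produced = numeric(), geometry_true = character(),
               geometry_called = character(), area_true = numeric(),
               area_produced = numeric())
  uns <- m[m$db > 0, ]
  geom_acc <- if (nrow(uns))
    mean(uns$geometry_called == uns$geometry_true) else NA_real_
  dev <- m$area_produced - m$area_true
  rmse_by_class <- if (nrow(m))
    tapply(dev, m$db, function(x) sqrt(mean(x^2))) else numeric(0)
  list(precision = nrow(m) / nrow(prod),
       recall = nrow(m) / nrow(tr),
       geometry_accuracy = geom_acc,
       area_rmse = if (nrow(m)) sqrt(mean(dev^2)) else NA_real_,
       area_rmse_by_class = rmse_by_class,
       n_truth = nrow(tr), n_produced = nrow(prod), n_matched = nrow(m),
       matches = m)
}
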