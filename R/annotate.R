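.QUANT_ADDUCTS <- c("[M-H]+", "[M]+.", "[M+H]+")

.run_flat <- function(run) {
  if (is.character(run)) run <- read_mzml(run)
  stopifnot(inherits(run, "synthetic_run"))
  run
}

# centroids sorted by m/z with scan/intensity carried along, for fast
# repeated window queries via findInterval
.mz_index <- function(run) {
  cent <- run$centroids
  o <- order(cent$mz)
  list(mz = cent$mz[o], scan = cent$scan[o], intensity = cent$intensity[o],
       n_scan = length(run$rt))
}

.eic_from_index <- function(ix, targets, tolerance) {
  trace <- numeric(ix$n_scan)
  for (t in targets) {
    i1 <- findInterval(t - tolerance, ix$mz) + 1L
    i2 <- findInterval(t + tolerance, ix$mz)
    if (i2 < i1) next
    j <- i1:i2
    agg <- rowsum(ix$intensity[j], ix$scan[j])
    trace[as.integer(rownames(agg))] <- trace[as.integer(rownames(agg))] +
      agg[, 1L]
  }
  trace
}

#' Extract a summed-ion chromatogram
#'
#' Reconstructs the chromatogram of one species by summing, per scan, all
#' centroid intensities within the m/z tolerance of each of its target
#' adduct ions. The default adduct set is the three quantification channels
#' ([M-H]+, [M]+., [M+H]+); solvent adducts are used for identification
#' only, never for areas.
#'
#' @param run A \code{synthetic_run} or an mzML file path.
#' @param species An \code{hc_species}.
#' @param adducts Non-empty character vector of adduct names.
#' @param tolerance m/z tolerance in Da (default 0.3, matching
#'   unit-resolution data).
#' @param registry Adduct registry.
#' @return Object of class \code{eic}: data.frame with columns \code{rt},
#'   \code{intensity} (one row per scan) carrying the target m/z values as
#'   an attribute.
#' @export
extract_eic <- function(run, species, adducts = .QUANT_ADDUCTS,
                        tolerance = 0.3, registry = adduct_registry()) {
  run <- .run_flat(run)
  if (!length(run$rt)) stop("run is empty")
  if (!length(adducts)) stop("adduct set must not be empty")
  targets <- vapply(adducts, function(a)
    ion_mz(species, a, "monoisotopic", registry), numeric(1))
  ix <- .mz_index(run)
  trace <- .eic_from_index(ix, targets, tolerance)
  out <- data.frame(rt = run$rt, intensity = trace)
  attr(out, "targets") <- targets
  attr(out, "species") <- format(species)
  class(out) <- c("eic", "data.frame")
  out
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima above a height threshold become peak apexes; each peak's
#' boundaries are the flanking local minima (or trace ends), and its area is
#' the trapezoidal integral of the raw trace between them. Peaks narrower
#' than \code{min_width_scans} are discarded.
#'
#' @param eic An \code{eic} (or data.frame with \code{rt},
#'   \code{intensity}).
#' @param min_height_frac Detection threshold as a fraction of the trace
#'   maximum (default 0.01).
#' @param min_width_scans Minimum peak width in scans (default 3).
#' @param floor_abs Optional absolute intensity floor; the effective
#'   threshold is \code{max(min_height_frac * max(trace), floor_abs)}.
#' @param smooth_scans Odd moving-average window (in scans) applied only for
#'   apex and boundary finding; the area is always the trapezoidal integral
#'   of the \emph{raw} trace between the boundaries. Default 1 (no
#'   smoothing).
#' @param merge_valley_frac Adjacent apexes whose connecting valley stays
#'   above this fraction of the lower apex are fused into one peak (noise
#'   shoulders are not independent peaks). Default 0.6.
#' @return data.frame of peaks ordered by retention time: \code{apex_rt},
#'   \code{left_rt}, \code{right_rt}, \code{area}, \code{height}. Zero rows
#'   when nothing exceeds the threshold.
#' @export
detect_peaks <- function(eic, min_height_frac = 0.01, min_width_scans = 3L,
                         floor_abs = 0, smooth_scans = 1L,
                         merge_valley_frac = 0.6) {
  y0 <- eic$intensity
  t <- eic$rt
  n <- length(y0)
  if (n < 3L) stop("trace must have at least 3 points")
  empty <- data.frame(apex_rt = numeric(), left_rt = numeric(),
                      right_rt = numeric(), area = numeric(),
                      height = numeric())
  if (all(y0 <= 0)) return(empty)
  y <- if (smooth_scans > 1L) .movavg(y0, as.integer(smooth_scans)) else y0
  thr <- max(min_height_frac * max(y), floor_abs)
  # strict maxima (ties broken toward the earlier scan)
  apex <- which(c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                         y[2:(n - 1)] > y[3:n], FALSE) & y > thr)
  if (!length(apex)) return(empty)
  # fuse apexes separated by shallow valleys (noise shoulders)
  if (length(apex) > 1L && merge_valley_frac > 0) {
    grp <- integer(length(apex)); grp[1] <- 1L
    for (k in 2:length(apex)) {
      valley <- min(y[apex[k - 1L]:apex[k]])
      grp[k] <- if (valley > merge_valley_frac * min(y[apex[k - 1L]],
                                                     y[apex[k]]))
        grp[k - 1L] else grp[k - 1L] + 1L
    }
    apex <- unname(vapply(split(apex, grp), function(ix)
      ix[which.max(y[ix])], integer(1)))
  }
  m <- length(apex)
  out <- lapply(seq_len(m), function(j) {
    i <- apex[j]
    blev <- max(0.005 * y[i], 0)   # edge boundary: 0.5% of apex height
    # left: no further than the inter-apex minimum, else the level crossing
    lo_lim <- if (j > 1L) apex[j - 1L] - 1L +
      which.min(y[apex[j - 1L]:i]) else 1L
    lo <- i
    while (lo > lo_lim && y[lo - 1L] > blev) lo <- lo - 1L
    hi_lim <- if (j < m) i - 1L + which.min(y[i:apex[j + 1L]]) else n
    hi <- i
    while (hi < hi_lim && y[hi + 1L] > blev) hi <- hi + 1L
    if (hi - lo + 1L < min_width_scans) return(NULL)
    seg <- lo:hi
    area <- sum((y0[seg[-length(seg)]] + y0[seg[-1]]) / 2 * diff(t[seg]))
    if (area <= 0) return(NULL)
    data.frame(apex_rt = t[i], left_rt = t[lo], right_rt = t[hi],
               area = area, height = y0[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$apex_rt), ]
  rownames(out) <- NULL
  out
}

.movavg <- function(y, w) {
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  n <- length(y)
  pad <- (w - 1L) %/% 2L
  ys <- stats::filter(c(rep(y[1], pad), y, rep(y[n], pad)), k, sides = 2)
  as.numeric(ys[(pad + 1L):(pad + n)])
}

#' Average spectrum over a retention-time window
#'
#' Mean centroid intensity per m/z across the scans inside the window
#' (intensities are summed per distinct m/z and divided by the number of
#' scans, so a single-scan window returns that scan unchanged).
#'
#' @param run A \code{synthetic_run} or mzML path.
#' @param rt_window Numeric \code{c(from, to)} in minutes.
#' @return data.frame with \code{mz}, \code{intensity}, sorted by m/z.
#' @export
average_spectrum <- function(run, rt_window) {
  run <- .run_flat(run)
  scans <- which(run$rt >= rt_window[1] & run$rt <= rt_window[2])
  if (!length(scans)) stop("rt_window does not overlap the run")
  cent <- run$centroids[run$centroids$scan %in% scans, ]
  if (!nrow(cent))
    return(data.frame(mz = numeric(), intensity = numeric()))
  agg <- rowsum(cent$intensity, cent$mz)
  out <- data.frame(mz = as.numeric(rownames(agg)),
                    intensity = agg[, 1L] / length(scans))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}

#' Unsaturation-class retention windows
#'
#' Hydrocarbons elute from silver-ion columns in groups ordered by
#' double-bond count, so the time axis can be partitioned into one window
#' per class: each window is centered on the configured class apex with
#' boundaries at the midpoints between adjacent apexes; the first window
#' starts at 0 and the last ends at the run end.
#'
#' @param run Optional \code{synthetic_run} (or mzML path) supplying the run
#'   end; otherwise \code{run_end} is used.
#' @param model A \code{\link{retention_model}} holding the class apexes.
#' @param system,temperature Condition to look up; the apexes must be
#'   strictly increasing in the double-bond class (an error otherwise).
#' @param run_end Run end in minutes when no run is given (default
#'   \code{Inf}).
#' @return data.frame with columns \code{db}, \code{start}, \code{end},
#'   \code{apex}; windows are ordered and non-overlapping.
#' @examples
#' calibrate_class_windows(model = retention_model(), run_end = 140)
#' @export
calibrate_class_windows <- function(run = NULL, model = retention_model(),
                                    system = "III", temperature = 15,
                                    run_end = Inf) {
  apex <- .class_apexes(model, system, temperature)
  if (!is.null(run)) {
    run <- .run_flat(run)
    run_end <- max(run$rt)
  }
  k <- length(apex)
  mid <- (apex[-k] + apex[-1]) / 2
  data.frame(db = as.integer(names(apex)),
             start = c(0, mid), end = c(mid, run_end),
             apex = unname(apex), row.names = NULL)
}

#' Assign a species to a chromatographic peak
#'
#' The double-bond class comes from the retention window containing the
#' peak apex; the carbon number comes from matching the averaged spectrum
#' across the peak against candidate ions restricted to that class. The
#' restriction resolves the alkane [M-H]+ / alkene [M+H]+ ion-formula
#' degeneracy: a CnH2n+1+ base ion inside the saturated window is always
#' read as the alkane.
#'
#' @param peak One row of \code{\link{detect_peaks}} output.
#' @param run The run the peak came from.
#' @param windows Class windows from \code{\link{calibrate_class_windows}}.
#' @param tolerance m/z tolerance in Da.
#' @param cn_range Carbon-number search range.
#' @param registry Adduct registry.
#' @return A one-row data.frame annotation: \code{cn}, \code{db},
#'   \code{geometry}, \code{apex_rt}, \code{left_rt}, \code{right_rt},
#'   \code{area}, \code{height}, \code{matched_adducts}, \code{assigned}.
#'   Peaks with no candidate within tolerance come back with
#'   \code{assigned = FALSE} and \code{cn = NA} for review.
#' @export
assign_species <- function(peak, run, windows, tolerance = 0.3,
                           cn_range = c(25L, 63L),
                           registry = adduct_registry()) {
  run <- .run_flat(run)
  w <- windows[windows$start <= peak$apex_rt & peak$apex_rt < windows$end, ]
  if (!nrow(w)) stop("peak apex at ", peak$apex_rt,
                     " min lies in no class window")
  cls <- w$db[1]
  spec <- average_spectrum(run, c(peak$left_rt, peak$right_rt))
  spec <- spec[order(-spec$intensity), ]
  spec <- utils::head(spec, 12L)
  best_cn <- NA_integer_; matched <- character(0)
  # score each candidate CN by the summed intensity of all its matched ions
  scores <- list()
  for (i in seq_len(nrow(spec))) {
    cand <- candidates_for_mz(spec$mz[i], tolerance,
                              adducts = registry$name,
                              cn_range = cn_range, db_range = c(cls, cls),
                              scale = "monoisotopic", registry = registry)
    for (j in seq_len(nrow(cand))) {
      key <- as.character(cand$carbon_number[j])
      cur <- scores[[key]]
      if (is.null(cur)) cur <- list(score = 0, adducts = character(0))
      cur$score <- cur$score + spec$intensity[i]
      cur$adducts <- union(cur$adducts, cand$adduct[j])
      scores[[key]] <- cur
    }
  }
  if (length(scores)) {
    sc <- vapply(scores, function(s) s$score, numeric(1))
    best_cn <- as.integer(names(scores)[which.max(sc)])
    matched <- scores[[which.max(sc)]]$adducts
  }
  data.frame(cn = best_cn, db = cls,
             geometry = NA_character_,
             apex_rt = peak$apex_rt, left_rt = peak$left_rt,
             right_rt = peak$right_rt, area = peak$area,
             height = peak$height,
             matched_adducts = paste(matched, collapse = ";"),
             assigned = !is.na(best_cn))
}

#' Default cis/trans boundary retention times per class
#'
#' The geometry call uses one reference boundary per unsaturation class:
#' all-trans species elute ahead of it, cis species after. The default
#' places the boundary midway between the class apex and the apex shifted
#' by the class trans offset, i.e. between the trans and cis sub-clusters.
#'
#' @param model A \code{\link{retention_model}}.
#' @param system,temperature Condition.
#' @return Named numeric, boundary Rt (minutes) per class \code{"1"},
#'   \code{"2"}, \code{"3"}.
#' @export
geometry_boundaries <- function(model = retention_model(), system = "III",
                                temperature = 15) {
  apex <- .class_apexes(model, system, temperature)
  cls <- intersect(names(apex), names(model$trans_offset))
  stats::setNames(apex[cls] - model$trans_offset[cls] / 2, cls)
}

#' Call cis/trans geometry from retention
#'
#' @param annotation One-row annotation (needs \code{db} >= 1 and
#'   \code{apex_rt}).
#' @param geometry_reference Named numeric of per-class boundary retention
#'   times, as from \code{\link{geometry_boundaries}}.
#' @return \code{"trans"} if the apex elutes before the class boundary,
#'   \code{"cis"} after, \code{"unknown"} if the class has no reference.
#' @export
call_geometry <- function(annotation, geometry_reference) {
  if (annotation$db == 0)
    stop("geometry is undefined for saturated hydrocarbons")
  b <- geometry_reference[as.character(annotation$db)]
  if (is.na(b) || !length(b)) return("unknown")
  if (annotation$apex_rt < b) "trans" else "cis"
}

#' Double-bond geometry from the allylic 13C shift
#'
#' In disubstituted alkenes the carbon allylic to a cis double bond
#' resonates near 27 ppm while the trans counterpart sits near 32.6 ppm (a
#' steric upfield shift of about 5.4 ppm in the cis isomer). The classifier
#' splits at the midpoint between those anchors.
#'
#' @param delta_c Allylic 13C chemical shift in ppm; must lie in the
#'   plausible 20-40 ppm range.
#' @return \code{"cis"} if below 30 ppm, \code{"trans"} otherwise.
#' @examples
#' geometry_from_allylic_shift(27.20)  # cis
#' geometry_from_allylic_shift(32.60)  # trans
#' @export
geometry_from_allylic_shift <- function(delta_c) {
  if (delta_c < 20 || delta_c > 40)
    stop("allylic 13C shift outside the plausible 20-40 ppm range: ",
         delta_c)
  if (delta_c < 30) "cis" else "trans"
}

#' Within-class relative areas
#'
#' Fills \code{rel_area_pct} as 100 x area / (summed area of the same
#' double-bond class). Relative areas are never compared across classes
#' because the APCI response grows with unsaturation.
#'
#' @param annotations data.frame of annotations with \code{db} and
#'   \code{area} columns.
#' @return The same data.frame with \code{rel_area_pct} filled; each class
#'   sums to 100.
#' @export
quantify_within_class <- function(annotations) {
  if (!nrow(annotations)) return(annotations)
  tot <- stats::ave(annotations$area, annotations$db, FUN = sum)
  if (any(tot <= 0)) stop("a double-bond class has zero total area")
  annotations$rel_area_pct <- 100 * annotations$area / tot
  annotations
}
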