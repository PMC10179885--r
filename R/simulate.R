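#' Simulate an Ag-HPLC/APCI-MS run
#'
#' Generates a seeded, centroided LC-MS run from a ground-truth composition:
#' each species elutes as a Gaussian chromatographic peak at the retention
#' time given by the retention model (with a run-level retention drift plus a
#' small per-species jitter), ionizing into the adduct channels dictated by
#' the response model at the local mobile-phase composition, with isotope
#' envelopes, a low-mass fragment floor, multiplicative log-normal intensity
#' noise and a sparse random baseline. The total ion current contributed by
#' a species is proportional to (within-class abundance) x (class share) x
#' (class response factor), so peak areas are comparable within an
#' unsaturation class but deliberately not across classes.
#'
#' @param composition An \code{hc_composition} (see
#'   \code{\link{composition_from_report}}) or a data.frame with columns
#'   \code{cn}, \code{db}, \code{geometry}, \code{iso_offset},
#'   \code{abundance_pct}, \code{class_share_pct}.
#' @param retention A \code{\link{retention_model}}.
#' @param response A \code{\link{response_model}}.
#' @param gradient A \code{\link{gradient_program}}; its \code{system} field
#'   selects the adduct chemistry.
#' @param temperature Column temperature in degrees C.
#' @param noise_sd Log-normal intensity noise (sd of log intensity, default
#'   0.05); 0 disables intensity noise.
#' @param scan_rate Scans per second (default 2).
#' @param seed Integer seed; identical seeds give identical runs. The global
#'   RNG state is left untouched.
#' @param mz_range Recorded m/z window (default 200-900); centroids outside
#'   it are discarded.
#' @param n_isotopes Isotope peaks per adduct channel (default 3).
#' @param intensity_scale Arbitrary ion-current unit of the run.
#' @param baseline_rate Mean number of random baseline centroids per scan
#'   (Poisson); 0 disables the baseline.
#' @param baseline_height Mean intensity of baseline centroids.
#' @param duration Run length in minutes; defaults to covering the last peak
#'   plus a margin. Species whose retention time falls outside the run are
#'   dropped with a warning and recorded in the metadata.
#' @param registry Adduct registry.
#' @return Object of class \code{synthetic_run}: list with \code{rt} (scan
#'   times, minutes), \code{centroids} (data.table: \code{scan}, \code{mz},
#'   \code{intensity}), \code{ground_truth} (the realized composition with
#'   true retention times and ion currents) and \code{metadata}.
#' @examples
#' comp <- composition_from_report(load_fixture("table4"))
#' run <- simulate_run(comp, seed = 1, noise_sd = 0)
#' run
#' @export
simulate_run <- function(composition,
                         retention = retention_model(),
                         response = response_model(),
                         gradient = gradient_program(),
                         temperature = 15,
                         noise_sd = 0.05,
                         scan_rate = 2,
                         seed = 1,
                         mz_range = c(200, 900),
                         n_isotopes = 3L,
                         intensity_scale = 1e6,
                         baseline_rate = 5,
                         baseline_height = intensity_scale * 1e-5,
                         duration = NULL,
                         registry = adduct_registry()) {
  comp <- .validate_composition(composition)
  if (scan_rate <= 0) stop("scan_rate must be > 0")
  system <- gradient$system
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))

  cls <- as.character(comp$db)
  sigma <- unname(retention$peak_sigma[cls])
  rt0 <- vapply(seq_len(nrow(comp)), function(i)
    predict_rt(.comp_species(comp, i), retention, system, temperature,
               isomer = comp$iso_offset[i]), numeric(1))
  # run-level drift (reproducibility of the physical column) plus a small
  # independent per-species jitter
  drift <- 1 + stats::rnorm(1, 0, retention$rt_jitter_rel)
  jit <- if (retention$rt_jitter_rel > 0)
    stats::rnorm(nrow(comp), 0, 0.02) else 0
  rt <- rt0 * drift + jit
  if (is.null(duration))
    duration <- max(rt + 6 * sigma) + 2
  keep <- rt - 4 * sigma > 0 & rt + 2 * sigma < duration
  truncated <- comp[!keep, , drop = FALSE]
  if (nrow(truncated)) {
    warning(nrow(truncated), " species fall outside the run duration and ",
            "were truncated")
  }
  dt_scan <- 1 / (scan_rate * 60)
  rt_scans <- seq(0, duration, by = dt_scan)
  n_scan <- length(rt_scans)

  amount <- comp$abundance_pct / 100 * comp$class_share_pct / 100 *
    unname(response$db_response[cls]) * intensity_scale
  frag_share <- response$fragment_floor / (1 + response$fragment_floor)
  frag_mz <- .fragment_ladder()

  pieces <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    if (!keep[i]) next
    sp <- .comp_species(comp, i)
    pB <- gradient_percent_B(min(rt[i], duration), gradient)
    fr <- .adduct_fractions(comp$db[i], system, pB, response)
    fr <- fr[fr > 0]
    mzs <- numeric(0); totals <- numeric(0)
    for (a in names(fr)) {
      reg_row <- registry[registry$name == a, ]
      ion_formula <- c(C = sp$carbon_number + reg_row$delta_C,
                       H = sp$hydrogens + reg_row$delta_H)
      pat <- isotope_pattern(ion_formula, n_isotopes)
      w <- pat$intensity / sum(pat$intensity)
      mz_a <- ion_mz(sp, a, "monoisotopic", registry) +
        (seq_len(n_isotopes) - 1L) * .MASS$iso_space
      mzs <- c(mzs, mz_a)
      totals <- c(totals, amount[i] * (1 - frag_share) * fr[[a]] * w)
    }
    # low-mass chain fragments, a fixed CnH2n+1+ ladder below m/z 350
    mzs <- c(mzs, frag_mz$mz)
    totals <- c(totals, amount[i] * frag_share * frag_mz$w)
    ok <- mzs >= mz_range[1] & mzs <= mz_range[2]
    mzs <- mzs[ok]; totals <- totals[ok]
    if (!length(mzs)) next
    win <- which(abs(rt_scans - rt[i]) <= 5 * sigma[i])
    if (!length(win)) next
    dens <- stats::dnorm(rt_scans[win], rt[i], sigma[i]) * dt_scan
    inten <- as.vector(outer(dens, totals))
    pieces[[i]] <- data.table::data.table(
      scan = rep(win, times = length(mzs)),
      mz = rep(mzs, each = length(win)),
      intensity = inten)
  }
  centroids <- data.table::rbindlist(pieces)
  if (noise_sd > 0 && nrow(centroids))
    centroids[, "intensity" := centroids$intensity *
                exp(stats::rnorm(nrow(centroids), 0, noise_sd))]
  if (baseline_rate > 0) {
    nb <- stats::rpois(n_scan, baseline_rate)
    if (sum(nb) > 0) {
      bl <- data.table::data.table(
        scan = rep(seq_len(n_scan), nb),
        mz = stats::runif(sum(nb), mz_range[1], mz_range[2]),
        intensity = stats::rexp(sum(nb), rate = 1 / baseline_height))
      centroids <- data.table::rbindlist(list(centroids, bl))
    }
  }
  data.table::setorderv(centroids, c("scan", "mz"))
  gt <- comp
  gt$rt_true <- rt
  gt$total_current <- amount
  gt <- gt[keep, , drop = FALSE]
  structure(list(
    rt = rt_scans,
    centroids = centroids,
    ground_truth = as.data.frame(gt),
    metadata = list(seed = as.integer(seed), system = system,
                    temperature = temperature, gradient = gradient,
                    scan_rate = scan_rate, mz_range = mz_range,
                    noise_sd = noise_sd, intensity_scale = intensity_scale,
                    duration = duration,
                    truncated = as.data.frame(truncated))),
    class = "synthetic_run")
}

.fragment_ladder <- function() {
  n <- 15:20  # CnH2n+1+ acylium-like chain fragments, all below m/z 350
  mz <- n * .MASS$C12 + (2 * n + 1) * .MASS$H1 - .MASS$electron
  w <- exp(-0.4 * seq_along(n))
  list(mz = mz, w = w / sum(w))
}

.comp_species <- function(comp, i) {
  g <- comp$geometry[i]
  geo <- if (comp$db[i] > 0 && !is.na(g) && nzchar(g))
    rep(g, comp$db[i]) else NULL
  hc_species(comp$cn[i], comp$db[i], geometry = geo)
}

.validate_composition <- function(composition) {
  comp <- as.data.frame(composition)
  need <- c("cn", "db", "abundance_pct", "class_share_pct")
  if (!all(need %in% names(comp)))
    stop("composition needs columns: ", paste(need, collapse = ", "))
  if (!"geometry" %in% names(comp))
    comp$geometry <- ifelse(comp$db > 0, "cis", "")
  if (!"iso_offset" %in% names(comp)) comp$iso_offset <- 0
  csum <- tapply(comp$abundance_pct, comp$db, sum)
  if (any(abs(csum - 100) > 0.1))
    stop("within-class abundances must sum to 100 +/- 0.1")
  shares <- tapply(comp$class_share_pct, comp$db, function(x) x[1])
  if (abs(sum(shares) - 100) > 0.1)
    stop("class shares must sum to 100 +/- 0.1")
  comp
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("<synthetic_run> ", length(x$rt), " scans over ",
      sprintf("%.1f", max(x$rt)), " min, ",
      nrow(x$centroids), " centroids, ", nrow(x$ground_truth),
      " species (system ", x$metadata$system, ", ",
      x$metadata$temperature, " degC, seed ", x$metadata$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write the ground truth of a simulated run as TSV
#'
#' @param run A \code{synthetic_run}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(run, path) {
  stopifnot(inherits(run, "synthetic_run"))
  utils::write.table(run$ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth TSV
#'
#' @param path Path written by \code{\link{write_ground_truth}} (or any TSV
#'   with the composition columns).
#' @return data.frame of ground-truth entries.
#' @export
read_ground_truth <- function(path) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  gt$geometry[is.na(gt$geometry)] <- ""
  gt
}
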