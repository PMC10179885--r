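# Elemental constants used throughout. Nominal arithmetic uses integer C = 12,
# H = 1; monoisotopic arithmetic uses the lightest-isotope masses. Cation
# masses subtract one electron mass.
.MASS <- list(
  C12       = 12,
  H1        = 1.0078250319,
  electron  = 0.00054858,
  iso_space = 1.0033548,   # 13C - 12C; dominates heavy-isotope spacing
  abund_13C = 0.0107,
  abund_2H  = 0.000115
)

#' Construct a hydrocarbon species
#'
#' A neutral straight-chain aliphatic hydrocarbon identified by its carbon
#' number (CN) and number of C=C double bonds (DB), the usual CN:DB shorthand
#' of cuticular-hydrocarbon work (e.g. \code{C41:2}). Geometry (cis/trans per
#' double bond) and double-bond positions are optional labels; they never
#' affect mass, only retention and reporting.
#'
#' @param carbon_number Integer number of carbons, >= 1.
#' @param double_bonds Integer number of C=C double bonds,
#'   0 <= DB <= floor((CN - 1) / 2).
#' @param geometry Optional character vector of length \code{double_bonds},
#'   each element one of \code{"cis"}, \code{"trans"}, \code{"unknown"}
#'   (abbreviations \code{"c"}/\code{"t"} are accepted).
#' @param positions Optional integer vector of double-bond locants
#'   (informational only).
#' @return An object of class \code{hc_species} with fields
#'   \code{carbon_number}, \code{double_bonds}, \code{hydrogens},
#'   \code{geometry}, \code{positions}.
#' @examples
#' hc_species(41, 2)
#' hc_species(32, 1, geometry = "cis", positions = 13)
#' @export
hc_species <- function(carbon_number, double_bonds = 0L, geometry = NULL,
                       positions = NULL) {
  cn <- as.integer(carbon_number)
  db <- as.integer(double_bonds)
  if (length(cn) != 1L || is.na(cn) || cn < 1L)
    stop("carbon_number must be a single integer >= 1 (got ",
         deparse(carbon_number), ")")
  if (length(db) != 1L || is.na(db) || db < 0L)
    stop("double_bonds must be a single non-negative integer")
  db_max <- (cn - 1L) %/% 2L
  if (db > db_max)
    stop("double_bonds = ", db, " exceeds the bound floor((CN - 1)/2) = ",
         db_max, " for carbon_number = ", cn)
  if (!is.null(geometry)) {
    geometry <- .normalize_geometry(geometry)
    if (length(geometry) != db)
      stop("geometry must have one entry per double bond (", db, "), got ",
           length(geometry))
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != db)
      stop("positions must have one entry per double bond")
  }
  structure(
    list(carbon_number = cn, double_bonds = db,
         hydrogens = 2L * cn + 2L - 2L * db,
         geometry = geometry, positions = positions),
    class = "hc_species")
}

.normalize_geometry <- function(geometry) {
  g <- tolower(as.character(geometry))
  g[g == "c"] <- "cis"
  g[g == "t"] <- "trans"
  bad <- !g %in% c("cis", "trans", "unknown")
  if (any(bad))
    stop("unknown geometry label(s): ", paste(unique(g[bad]), collapse = ", "))
  g
}

#' @export
format.hc_species <- function(x, ...) {
  lab <- sprintf("C%d:%d", x$carbon_number, x$double_bonds)
  if (!is.null(x$geometry) && length(x$geometry))
    lab <- paste0(lab, " (", paste(x$geometry, collapse = ","), ")")
  lab
}

#' @export
print.hc_species <- function(x, ...) {
  cat("<hc_species> ", format(x), "  formula ",
      .formula_string(neutral_formula(x)), "\n", sep = "")
  invisible(x)
}

.formula_string <- function(f) sprintf("C%dH%d", f[["C"]], f[["H"]])

#' Parse a CN:DB shorthand label
#'
#' Accepts labels such as \code{"41:2"}, \code{"C41:2"}, or with a geometry
#' prefix in the style used for standards, e.g. \code{"13c-C32:1"} or
#' \code{"13t-C32:1"} (locant + c/t).
#'
#' @param label Character vector of CN:DB labels.
#' @return A list of \code{hc_species} (a single object if length 1).
#' @export
parse_cn_db <- function(label) {
  out <- lapply(label, function(s) {
    s0 <- trimws(s)
    m <- regmatches(s0, regexec(
      "^(?:([0-9]+)\\s*([ct])\\s*-\\s*)?C?([0-9]+):([0-9]+)$", s0))[[1]]
    if (!length(m)) stop("cannot parse CN:DB label: ", s)
    cn <- as.integer(m[4]); db <- as.integer(m[5])
    geo <- NULL; pos <- NULL
    if (nzchar(m[3])) {
      geo <- rep(if (m[3] == "c") "cis" else "trans", db)
      pos <- rep(as.integer(m[2]), db)
    }
    hc_species(cn, db, geometry = geo, positions = pos)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Elemental composition of a hydrocarbon
#'
#' @param species An \code{hc_species}.
#' @return Named integer vector \code{c(C = CN, H = 2 CN + 2 - 2 DB)}.
#' @examples
#' neutral_formula(hc_species(39, 2))  # C39 H76
#' @export
neutral_formula <- function(species) {
  stopifnot(inherits(species, "hc_species"))
  c(C = species$carbon_number, H = species$hydrogens)
}

#' Neutral mass of a hydrocarbon
#'
#' Nominal mass uses integer masses (C = 12, H = 1); monoisotopic mass uses
#' C = 12 exactly and H = 1.00783.
#'
#' @param species An \code{hc_species}.
#' @param scale \code{"nominal"} or \code{"monoisotopic"}.
#' @return Mass in Da.
#' @examples
#' neutral_mass(hc_species(39, 2))                   # 544
#' neutral_mass(hc_species(39, 2), "monoisotopic")
#' @export
neutral_mass <- function(species, scale = c("nominal", "monoisotopic")) {
  scale <- match.arg(scale)
  f <- neutral_formula(species)
  if (scale == "nominal") f[["C"]] * 12 + f[["H"]] * 1
  else f[["C"]] * .MASS$C12 + f[["H"]] * .MASS$H1
}

#' m/z of a hydrocarbon ion
#'
#' Adds the adduct mass offset to the neutral mass; all registry adducts are
#' singly charged, so the result is the ion m/z directly.
#'
#' @param species An \code{hc_species}.
#' @param adduct Adduct name (see \code{\link{adduct_registry}}) or a single
#'   registry row.
#' @param scale \code{"nominal"} or \code{"monoisotopic"}.
#' @param registry Adduct registry table; defaults to the built-in one.
#' @return m/z value.
#' @examples
#' ion_mz(hc_species(39, 2), "[M+H]+")  # 545, cf. the C39:2 ion series
#' @export
ion_mz <- function(species, adduct, scale = c("nominal", "monoisotopic"),
                   registry = adduct_registry()) {
  scale <- match.arg(scale)
  off <- adduct_offset(adduct, registry = registry)
  neutral_mass(species, scale) +
    if (scale == "nominal") off[["nominal"]] else off[["monoisotopic"]]
}

#' Isotope pattern of an elemental composition
#'
#' Relative heavy-isotope peak intensities from the exact convolution of the
#' binomial distributions of carbon-13 (abundance 0.0107) and deuterium
#' (0.000115) over the formula, with the all-light peak normalized to 1.
#' Peaks are placed at the monoisotopic mass plus multiples of the 13C-12C
#' spacing (1.00335 Da), which dominates for hydrocarbons.
#'
#' @param formula Named integer vector with elements \code{C} and \code{H}
#'   (as from \code{\link{neutral_formula}}), or an \code{hc_species}.
#' @param n_peaks Number of peaks to return (>= 1).
#' @return data.frame with columns \code{mz}, \code{intensity}; intensity of
#'   the first (all-light) peak is 1 and m/z is strictly increasing.
#' @examples
#' isotope_pattern(neutral_formula(hc_species(39, 2)), 3)
#' @export
isotope_pattern <- function(formula, n_peaks = 3L) {
  if (inherits(formula, "hc_species")) formula <- neutral_formula(formula)
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  nC <- as.integer(formula[["C"]]); nH <- as.integer(formula[["H"]])
  if ((is.na(nC) || nC == 0L) && (is.na(nH) || nH == 0L))
    stop("empty formula: need at least one C or H atom")
  if (is.na(nC)) nC <- 0L
  if (is.na(nH)) nH <- 0L
  k <- 0:(n_peaks - 1L)
  pC <- stats::dbinom(0:(n_peaks - 1L), size = nC, prob = .MASS$abund_13C)
  pH <- stats::dbinom(0:(n_peaks - 1L), size = nH, prob = .MASS$abund_2H)
  # convolution: P(total k heavy atoms) = sum_j P(j 13C) P(k - j 2H)
  p <- vapply(k, function(kk)
    sum(pC[seq_len(kk + 1L)] * rev(pH[seq_len(kk + 1L)])), numeric(1))
  mono <- nC * .MASS$C12 + nH * .MASS$H1
  data.frame(mz = mono + k * .MASS$iso_space, intensity = p / p[1])
}

#' Candidate hydrocarbons for an observed m/z
#'
#' Exhaustively enumerates (CN, DB, adduct) triples over the given ranges and
#' returns every combination whose ion m/z lies within the tolerance of the
#' query, ranked by absolute mass error, then fewer double bonds, then lower
#' carbon number. Note that an alkane [M-H]+ and the one-double-bond alkene
#' [M+H]+ of the same CN share the ion formula CnH2n+1+ and are therefore
#' indistinguishable by mass alone; the chromatographic unsaturation class is
#' needed to resolve them.
#'
#' @param mz Query m/z.
#' @param tolerance Matching tolerance in Da (> 0). The default 0.3 Da suits
#'   unit-resolution ion-trap data.
#' @param adducts Character vector of adduct names or a registry subset; an
#'   empty set yields an empty result.
#' @param cn_range,db_range Integer intervals \code{c(lo, hi)} to search.
#' @param scale Mass scale for matching.
#' @param registry Adduct registry.
#' @return data.frame with columns \code{carbon_number}, \code{double_bonds},
#'   \code{adduct}, \code{ion_mz}, \code{error} (observed - computed, Da),
#'   ordered as described. May have zero rows.
#' @examples
#' candidates_for_mz(545, adducts = "[M+H]+", cn_range = c(20, 70),
#'                   db_range = c(0, 6))
#' @export
candidates_for_mz <- function(mz, tolerance = 0.3,
                              adducts = adduct_registry()$name,
                              cn_range = c(20L, 70L), db_range = c(0L, 6L),
                              scale = c("nominal", "monoisotopic"),
                              registry = adduct_registry()) {
  scale <- match.arg(scale)
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  if (length(cn_range) != 2L || length(db_range) != 2L ||
      cn_range[1] > cn_range[2] || db_range[1] > db_range[2])
    stop("cn_range and db_range must be non-empty intervals c(lo, hi)")
  empty <- data.frame(carbon_number = integer(), double_bonds = integer(),
                      adduct = character(), ion_mz = numeric(),
                      error = numeric())
  if (is.data.frame(adducts)) adducts <- adducts$name
  if (!length(adducts)) return(empty)
  adducts <- vapply(adducts, .normalize_adduct_name, character(1),
                    USE.NAMES = FALSE)
  reg <- registry[match(adducts, registry$name), , drop = FALSE]
  if (anyNA(reg$name))
    stop("adduct(s) not in registry: ",
         paste(adducts[is.na(reg$name)], collapse = ", "))
  grid <- expand.grid(carbon_number = cn_range[1]:cn_range[2],
                      double_bonds = db_range[1]:db_range[2],
                      adduct_i = seq_len(nrow(reg)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$double_bonds <= (grid$carbon_number - 1L) %/% 2L, ]
  if (!nrow(grid)) return(empty)
  hyd <- 2L * grid$carbon_number + 2L - 2L * grid$double_bonds
  if (scale == "nominal") {
    m <- grid$carbon_number * 12 + hyd +
      reg$nominal_offset[grid$adduct_i]
  } else {
    m <- grid$carbon_number * .MASS$C12 + hyd * .MASS$H1 +
      reg$monoisotopic_offset[grid$adduct_i]
  }
  err <- mz - m
  keep <- abs(err) <= tolerance
  if (!any(keep)) return(empty)
  out <- data.frame(carbon_number = grid$carbon_number[keep],
                    double_bonds = grid$double_bonds[keep],
                    adduct = reg$name[grid$adduct_i[keep]],
                    ion_mz = m[keep], error = err[keep])
  out <- out[order(abs(out$error), out$double_bonds, out$carbon_number), ]
  rownames(out) <- NULL
  out
}
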