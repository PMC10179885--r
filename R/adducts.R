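# APCI ionization channels observed for aliphatic hydrocarbons. The seven
# defaults cover deprotonated and protonated molecules, the radical molecular
# cation, and the solvent-derived adducts elicited by hexane (+C3H3, +C6H13),
# isooctane (+C4H9) and toluene (+C7H9, i.e. protonated toluene).
.ADDUCT_DEFAULTS <- data.frame(
  name = c("[M-H]+", "[M+H]+", "[M]+.", "[M+C3H3]+", "[M+C4H9]+",
           "[M+C6H13]+", "[M+C7H9]+"),
  delta_C = c(0L, 0L, 0L, 3L, 4L, 6L, 7L),
  delta_H = c(-1L, 1L, 0L, 3L, 9L, 13L, 9L),
  charge = 1L,
  source_solvent = c("any", "toluene", "toluene", "hexane", "isooctane",
                     "hexane", "toluene"),
  stringsAsFactors = FALSE
)

.adduct_complete <- function(reg) {
  reg$nominal_offset <- reg$delta_C * 12L + reg$delta_H * 1L
  # cation: added atoms at monoisotopic mass, minus one electron
  reg$monoisotopic_offset <- reg$delta_C * .MASS$C12 +
    reg$delta_H * .MASS$H1 - reg$charge * .MASS$electron
  reg
}

# accept unicode minus/middle-dot variants and the paper-style nominal-offset
# aliases ("[M+39]+" etc.)
.normalize_adduct_name <- function(name) {
  s <- gsub("−", "-", name)
  s <- gsub("·|⋅", ".", s)
  s <- gsub("\\s+", "", s)
  alias <- c("[M+39]+" = "[M+C3H3]+", "[M+57]+" = "[M+C4H9]+",
             "[M+85]+" = "[M+C6H13]+", "[M+93]+" = "[M+C7H9]+",
             "[M]+" = "[M]+.")
  if (s %in% names(alias)) s <- alias[[s]]
  s
}

#' The APCI adduct registry
#'
#' Returns the table of ionization channels used for m/z arithmetic and
#' annotation. Each row defines the elemental offset added to the neutral
#' hydrocarbon, its nominal and monoisotopic mass offsets, and the mobile
#' phase solvent that elicits it. The seven built-in channels have nominal
#' offsets -1, +1, 0, +39, +57, +85 and +93 Da. The registry is
#' user-extensible: supply extra rows via \code{extra} or load a modified
#' registry from a config file with \code{\link{read_adduct_registry}}.
#'
#' @param extra Optional data.frame with columns \code{name}, \code{delta_C},
#'   \code{delta_H}, \code{charge}, \code{source_solvent} appended to the
#'   defaults; mass offsets are derived from the elemental deltas.
#' @return data.frame with one row per adduct.
#' @examples
#' adduct_registry()
#' @export
adduct_registry <- function(extra = NULL) {
  reg <- .ADDUCT_DEFAULTS
  if (!is.null(extra)) {
    need <- c("name", "delta_C", "delta_H", "charge", "source_solvent")
    if (!all(need %in% names(extra)))
      stop("extra adduct rows need columns: ", paste(need, collapse = ", "))
    reg <- rbind(reg, extra[need])
  }
  .adduct_complete(reg)
}

#' Mass offset of an adduct
#'
#' @param name Adduct name; unicode minus signs and the nominal-offset
#'   aliases \code{"[M+39]+"}, \code{"[M+57]+"}, \code{"[M+85]+"},
#'   \code{"[M+93]+"} are accepted.
#' @param registry Adduct registry table.
#' @return Named numeric vector \code{c(nominal = , monoisotopic = )} in Da.
#' @examples
#' adduct_offset("[M+C3H3]+")   # +39 nominal
#' adduct_offset("[M-H]+")
#' @export
adduct_offset <- function(name, registry = adduct_registry()) {
  if (is.data.frame(name)) {
    row <- name
    if (nrow(row) != 1L) stop("adduct must be a single registry row or name")
  } else {
    nm <- .normalize_adduct_name(name)
    row <- registry[registry$name == nm, , drop = FALSE]
    if (!nrow(row)) stop("unknown adduct: ", name)
  }
  c(nominal = as.numeric(row$nominal_offset),
    monoisotopic = row$monoisotopic_offset)
}

#' Read / write an adduct registry config file
#'
#' The registry is serialized as a tab-separated file with columns
#' \code{name}, \code{delta_C}, \code{delta_H}, \code{charge},
#' \code{source_solvent}; mass offsets are recomputed on load so the file
#' cannot drift out of sync with the elemental definitions.
#'
#' @param path File path.
#' @return \code{read_adduct_registry} returns the completed registry table;
#'   \code{write_adduct_registry} returns \code{path} invisibly.
#' @export
read_adduct_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "delta_C", "delta_H", "charge", "source_solvent")
  if (!all(need %in% names(reg)))
    stop("adduct registry file must have columns: ",
         paste(need, collapse = ", "))
  .adduct_complete(reg[need])
}

#' @rdname read_adduct_registry
#' @param registry Registry table to serialize.
#' @export
write_adduct_registry <- function(registry = adduct_registry(), path) {
  cols <- c("name", "delta_C", "delta_H", "charge", "source_solvent")
  utils::write.table(registry[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
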