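#' Load a packaged reference table
#'
#' The package ships machine-readable versions of three published reference
#' tables: the class apex retention times per solvent system and column
#' temperature (\code{"table2"}), the 136-species cuticular hydrocarbon
#' profile of the flesh fly \emph{Neobellieria bullata} (\code{"table3"}),
#' and the 44-species profile of the cockroach \emph{Periplaneta americana}
#' (\code{"table4"}). Values are kept verbatim as printed; where the printed
#' peak numbering is duplicated or disordered the fixture assigns clean
#' sequential \code{peak_no} and preserves the printed number in
#' \code{printed_id}. Loaders verify a stored digest of each file and the
#' structural invariants (row counts, CN:DB validity, class sums).
#'
#' @param source One of \code{"table2"}, \code{"table3"}, \code{"table4"}.
#' @param check_digest Verify the md5 digest of the fixture file (default
#'   \code{TRUE}).
#' @return For \code{"table3"}/\code{"table4"}: a \code{fixture_table}
#'   object, a list with \code{rows} (data.frame: \code{peak_no},
#'   \code{printed_id}, \code{rt_min}, \code{cn}, \code{db}, \code{geometry},
#'   \code{rel_area_pct}), \code{class_shares} (named numeric, \% of total
#'   area per double-bond class) and \code{source}. For \code{"table2"}: a
#'   data.frame of (system, temperature, class) apex retention times.
#' @examples
#' t4 <- load_fixture("table4")
#' nrow(t4$rows)        # 44
#' t4$class_shares      # 2.5 / 17.0 / 65.3 / 15.2
#' @export
load_fixture <- function(source = c("table3", "table4", "table2"),
                         check_digest = TRUE) {
  source <- match.arg(source)
  file <- paste0(source, ".tsv")
  path <- system.file("extdata", file, package = "agHC", mustWork = TRUE)
  if (check_digest) .check_fixture_digest(file, path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (source == "table2") {
    if (nrow(tab) != 36L || length(unique(paste(tab$system, tab$temperature_c))) != 9L)
      stop("fixture corruption: table2 must hold 9 (system, temperature) ",
           "apex quadruples")
    return(tab)
  }
  shares_file <- paste0(source, "_shares.tsv")
  shares_path <- system.file("extdata", shares_file, package = "agHC",
                             mustWork = TRUE)
  if (check_digest) .check_fixture_digest(shares_file, shares_path)
  sh <- utils::read.delim(shares_path, stringsAsFactors = FALSE)
  class_shares <- stats::setNames(sh$class_share_pct, sh$db)
  expected_n <- c(table3 = 136L, table4 = 44L)[[source]]
  tab$geometry[is.na(tab$geometry)] <- ""
  out <- structure(list(rows = tab, class_shares = class_shares,
                        source = source), class = "fixture_table")
  .validate_fixture(out, expected_n)
  out
}

.check_fixture_digest <- function(file, path) {
  dig_path <- system.file("extdata", "fixtures.md5", package = "agHC",
                          mustWork = TRUE)
  dig <- utils::read.delim(dig_path, header = FALSE,
                           col.names = c("file", "md5"))
  want <- dig$md5[dig$file == file]
  if (!length(want)) stop("no stored digest for fixture ", file)
  got <- unname(tools::md5sum(path))
  if (!identical(got, want))
    stop("fixture corruption: digest mismatch for ", file)
  invisible(TRUE)
}

.validate_fixture <- function(x, expected_n = NULL) {
  rows <- x$rows
  need <- c("peak_no", "rt_min", "cn", "db", "rel_area_pct")
  if (!all(need %in% names(rows)))
    stop("fixture rows need columns: ", paste(need, collapse = ", "))
  if (!is.null(expected_n) && nrow(rows) != expected_n)
    stop("fixture corruption: expected ", expected_n, " rows, found ",
         nrow(rows))
  if (any(rows$rt_min <= 0) || any(rows$rel_area_pct <= 0))
    stop("fixture rows must have positive Rt and relative area")
  # every CN:DB must be a constructible species
  invisible(mapply(hc_species, rows$cn, rows$db))
  if (abs(sum(x$class_shares) - 100) > 0.1)
    stop("class shares must sum to 100 +/- 0.1")
  if (!all(as.character(sort(unique(rows$db))) %in% names(x$class_shares)))
    stop("class share missing for a double-bond class present in rows")
  # printed within-class areas carry rounding; allow +/- 0.5 around 100
  csum <- tapply(rows$rel_area_pct, rows$db, sum)
  if (any(abs(csum - 100) > 0.5))
    stop("within-class areas deviate from 100 by more than 0.5: ",
         paste(sprintf("db %s: %.1f", names(csum), csum), collapse = "; "))
  invisible(x)
}

#' @export
print.fixture_table <- function(x, ...) {
  cat("<fixture_table> ", x$source, ": ", nrow(x$rows), " species rows, ",
      "classes ", paste(names(x$class_shares), collapse = "/"),
      " with shares ", paste(x$class_shares, collapse = "/"), "%\n", sep = "")
  invisible(x)
}

#' Species counts per double-bond class
#'
#' @param table A \code{fixture_table} or a data.frame of report rows with a
#'   \code{db} column.
#' @return Named integer vector, rows per double-bond class (empty input
#'   gives an empty vector).
#' @examples
#' class_counts(load_fixture("table4"))  # 31 / 7 / 3 / 3
#' @export
class_counts <- function(table) {
  rows <- if (inherits(table, "fixture_table")) table$rows else table
  if (!nrow(rows)) return(stats::setNames(integer(), character()))
  cnt <- table(rows$db)
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Compare a produced report against a reference table
#'
#' Rows are matched on (CN, DB, within-class elution-order index), i.e. the
#' k-th peak of a given CN:DB in retention-time order must correspond to the
#' k-th such peak of the reference. Returns matched pairs with retention and
#' area deltas, plus reference rows that were not produced (missing) and
#' produced rows absent from the reference (spurious).
#'
#' @param produced data.frame of report rows (columns \code{rt_min},
#'   \code{cn}, \code{db}, \code{rel_area_pct}).
#' @param fixture A \code{fixture_table} or an equivalent row data.frame.
#' @param rt_tol Retention-time tolerance in minutes for flagging (matches
#'   are still made by order; pairs whose |delta Rt| exceeds the tolerance
#'   are flagged in the \code{rt_ok} column). Default 2 min.
#' @param area_tol Flagging tolerance for the within-class area difference in
#'   percentage points. Default 2.
#' @return List with \code{matches}, \code{missing}, \code{spurious}
#'   data.frames and summary counts.
#' @export
compare_reports <- function(produced, fixture, rt_tol = 2, area_tol = 2) {
  ref <- if (inherits(fixture, "fixture_table")) fixture$rows else fixture
  if (!nrow(produced) || !nrow(ref))
    stop("compare_reports needs non-empty produced and reference tables")
  key <- function(d) {
    d <- d[order(d$db, d$cn, d$rt_min), ]
    idx <- stats::ave(seq_len(nrow(d)), d$db, d$cn, FUN = seq_along)
    d$iso_index <- idx
    d$key <- paste(d$cn, d$db, idx, sep = ":")
    d
  }
  p <- key(as.data.frame(produced))
  r <- key(as.data.frame(ref))
  m <- match(r$key, p$key)
  hit <- !is.na(m)
  matches <- data.frame(
    cn = r$cn[hit], db = r$db[hit], iso_index = r$iso_index[hit],
    rt_ref = r$rt_min[hit], rt_produced = p$rt_min[m[hit]],
    area_ref = r$rel_area_pct[hit], area_produced = p$rel_area_pct[m[hit]])
  matches$rt_delta <- matches$rt_produced - matches$rt_ref
  matches$area_delta <- matches$area_produced - matches$area_ref
  matches$rt_ok <- abs(matches$rt_delta) <= rt_tol
  matches$area_ok <- abs(matches$area_delta) <= area_tol
  list(matches = matches,
       missing = r[!hit, setdiff(names(r), "key"), drop = FALSE],
       spurious = p[!p$key %in% r$key, setdiff(names(p), "key"), drop = FALSE],
       n_matched = sum(hit), n_missing = sum(!hit),
       n_spurious = sum(!p$key %in% r$key))
}

#' Write an annotation report as TSV
#'
#' Emits the report in the reference-table layout: one row per peak
#' (\code{peak_no}, \code{rt_min}, \code{cn_db}, \code{geometry},
#' \code{rel_area_pct}) grouped by double-bond class, preceded by one
#' commented class-share line per class.
#'
#' @param rows data.frame of report rows with columns \code{rt_min},
#'   \code{cn}, \code{db}, \code{rel_area_pct} and optionally
#'   \code{geometry}.
#' @param path Output file; \code{""} writes to stdout.
#' @param class_shares Optional named numeric of class area shares (\%).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(rows, path = "", class_shares = NULL) {
  rows <- as.data.frame(rows)
  rows <- rows[order(rows$db, rows$rt_min), ]
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  writeLines("peak_no\trt_min\tcn_db\tgeometry\trel_area_pct", con)
  peak_no <- 0L
  for (cls in sort(unique(rows$db))) {
    share <- if (!is.null(class_shares)) class_shares[[as.character(cls)]]
             else NA_real_
    writeLines(sprintf("# %d double bond(s)%s", cls,
                       if (is.na(share)) "" else sprintf("\t%.1f", share)),
               con)
    blk <- rows[rows$db == cls, ]
    for (i in seq_len(nrow(blk))) {
      peak_no <- peak_no + 1L
      geo <- if ("geometry" %in% names(blk)) blk$geometry[i] else ""
      if (is.na(geo)) geo <- ""
      writeLines(sprintf("%d\t%.2f\t%d:%d\t%s\t%.2f", peak_no,
                         blk$rt_min[i], blk$cn[i], blk$db[i], geo,
                         blk$rel_area_pct[i]), con)
    }
  }
  invisible(path)
}
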