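#' Write a simulated run to mzML
#'
#' Serializes the run as a standard centroided, positive-mode mzML file
#' (retention times are stored in seconds per the format's conventions).
#' Scans with no centroids are written as empty spectra; a run with zero
#' scans yields a valid mzML with an empty spectrum list.
#'
#' @param run A \code{synthetic_run}.
#' @param path Output file path (conventionally \code{.mzML}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_mzml}}
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "synthetic_run"))
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- length(run$rt)
  if (n == 0L) return(.write_empty_mzml(path))
  cent <- run$centroids
  idx <- split(seq_len(nrow(cent)), factor(cent$scan, levels = seq_len(n)))
  pks <- lapply(idx, function(j)
    cbind(mz = cent$mz[j], intensity = cent$intensity[j]))
  counts <- vapply(pks, nrow, integer(1))
  bp <- vapply(seq_len(n), function(i) {
    if (counts[i] == 0L) return(c(0, 0))
    k <- which.max(pks[[i]][, 2L])
    c(pks[[i]][k, 1L], pks[[i]][k, 2L])
  }, numeric(2))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = run$rt * 60,
    basePeakMZ = bp[1L, ], basePeakIntensity = bp[2L, ],
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = run$metadata$mz_range[1], highMZ = run$metadata$mz_range[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = run$metadata$mz_range[1],
    scanWindowUpperLimit = run$metadata$mz_range[2],
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(pks), path, header = hdr, outformat = "mzml")
  invisible(path)
}

.write_empty_mzml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
    '  <cvList count="2">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '    </fileContent>',
    '  </fileDescription>',
    '  <softwareList count="1">',
    '    <software id="agHC" version="0.9.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="agHC"/>',
    '    </software>',
    '  </softwareList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1">',
    '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '    </instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="dp">',
    '      <processingMethod order="0" softwareRef="agHC">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="empty_run" defaultInstrumentConfigurationRef="IC1">',
    '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
    '  </run>',
    '</mzML>'), path)
  invisible(path)
}

#' Read a centroided mzML file
#'
#' Reads MS1 scans into the in-memory run representation used by the
#' annotation functions. Retention times are converted to minutes.
#'
#' @param path mzML file path.
#' @return A \code{synthetic_run}-shaped object (with empty ground truth).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  if (!file.exists(path)) stop("no such file: ", path)
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  if (!nrow(hdr)) {
    return(structure(list(rt = numeric(0),
                          centroids = data.table::data.table(
                            scan = integer(), mz = numeric(),
                            intensity = numeric()),
                          ground_truth = data.frame(),
                          metadata = list(source = path)),
                     class = "synthetic_run"))
  }
  pks <- mzR::peaks(ms)
  if (is.matrix(pks)) pks <- list(pks)
  counts <- vapply(pks, nrow, integer(1))
  centroids <- data.table::data.table(
    scan = rep(seq_along(pks), counts),
    mz = unlist(lapply(pks, function(p) p[, 1L]), use.names = FALSE),
    intensity = unlist(lapply(pks, function(p) p[, 2L]), use.names = FALSE))
  mzr <- c(suppressWarnings(min(hdr$lowMZ)), suppressWarnings(max(hdr$highMZ)))
  structure(list(
    rt = hdr$retentionTime / 60,
    centroids = centroids,
    ground_truth = data.frame(),
    metadata = list(source = path, mz_range = mzr,
                    scan_rate = if (nrow(hdr) > 1)
                      1 / (60 * stats::median(diff(hdr$retentionTime / 60)))
                    else NA_real_)),
    class = "synthetic_run")
}
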