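# Chromatogram long-CSV and mzML SRM chromatogram interfaces.

#' Read / write chromatogram traces as long CSV
#'
#' Columns: `sample_id, compound_id, time_min, intensity`.
#'
#' @param path File path.
#' @return `read_chromatograms()` returns the long data.frame.
#' @export
read_chromatograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound_id", "time_min", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("chromatogram file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_chromatograms
#' @param chroms Long chromatogram data.frame.
#' @export
write_chromatograms <- function(chroms, path) {
  utils::write.csv(chroms, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Integrate chromatogram traces into a peak table
#'
#' Runs [integrate_peak()] per (sample, compound) over the compound's panel
#' retention window. Compounds whose trace never rises above baseline carry a
#' `no_peak` flag and area 0.
#'
#' @param chroms Long chromatogram data.frame.
#' @param panel The `attribute_panel` (supplies windows).
#' @param baseline Passed to [integrate_peak()]. Simulated traces have no
#'   baseline offset, so the default is off.
#' @return Peak table `sample_id, compound_id, rt_min, area` with a `flags`
#'   attribute naming no-peak compounds.
#' @export
chromatograms_to_peaks <- function(chroms, panel, baseline = FALSE) {
  win <- panel[, c("compound_id", "rt_start_min", "rt_end_min")]
  rows <- list()
  flags <- character(0)
  for (s in unique(chroms$sample_id)) {
    for (cid in unique(chroms$compound_id[chroms$sample_id == s])) {
      w <- win[win$compound_id == cid, ]
      if (!nrow(w)) stop("compound not in panel: ", cid, call. = FALSE)
      tr <- chroms[chroms$sample_id == s & chroms$compound_id == cid,
                   c("time_min", "intensity")]
      tr <- tr[order(tr$time_min), ]
      res <- integrate_peak(tr, window = c(max(w$rt_start_min, min(tr$time_min)),
                                           min(w$rt_end_min, max(tr$time_min))),
                            baseline = baseline)
      apex <- if (res$area > 0) tr$time_min[which.max(tr$intensity)] else
        (w$rt_start_min + w$rt_end_min) / 2
      if (res$flag == "no_peak") flags <- c(flags, paste0(s, ":", cid))
      rows[[length(rows) + 1L]] <- data.frame(sample_id = s, compound_id = cid,
                                              rt_min = apex, area = res$area,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  out
}

.b64_doubles <- function(x) {
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                               size = 8, endian = "little")))
}

#' Write SRM chromatograms as mzML
#'
#' Serializes long-format chromatogram traces as an mzML file with one SRM
#' chromatogram per (sample, compound): uncompressed 64-bit float time
#' (minutes) and intensity arrays, precursor/product isolation targets taken
#' from the panel's Q1/Q3. One file per sample id.
#'
#' @param chroms Long chromatogram data.frame for a single sample.
#' @param panel Panel supplying Q1/Q3 per compound.
#' @param path Output path.
#' @export
write_srm_mzml <- function(chroms, panel, path) {
  if (length(unique(chroms$sample_id)) != 1L) {
    stop("write one mzML file per sample", call. = FALSE)
  }
  q1 <- stats::setNames(panel$q1_mz, panel$compound_id)
  q3 <- stats::setNames(panel$q3_mz, panel$compound_id)
  cids <- unique(chroms$compound_id)
  entries <- character(length(cids))
  for (i in seq_along(cids)) {
    cid <- cids[i]
    if (!cid %in% names(q1)) stop("compound not in panel: ", cid, call. = FALSE)
    tr <- chroms[chroms$compound_id == cid, ]
    tb <- .b64_doubles(tr$time_min)
    ib <- .b64_doubles(tr$intensity)
    entries[i] <- sprintf(paste0(
      '<chromatogram index="%d" id="SRM SIC Q1=%.4f Q3=%.4f sample=1 period=1 experiment=1 transition=%d" defaultArrayLength="%d">',
      '<precursor><isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></isolationWindow></precursor>',
      '<product><isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></isolationWindow></product>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/><binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></chromatogram>'),
      i - 1L, q1[[cid]], q3[[cid]], i, nrow(tr), q1[[cid]], q3[[cid]],
      nchar(tb), tb, nchar(ib), ib)
  }
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml"><mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="%s">',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/uo.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="mrmqa"/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="%s" defaultInstrumentConfigurationRef="IC">',
    '<chromatogramList count="%d" defaultDataProcessingRef="dp">%s</chromatogramList>',
    '</run></mzML></indexedmzML>'),
    chroms$sample_id[1], chroms$sample_id[1], length(cids),
    paste(entries, collapse = ""))
  writeLines(doc, path)
  invisible(path)
}

#' Read SRM chromatograms from mzML
#'
#' Reads an mzML chromatogram list (via mzR) and maps each SRM chromatogram to
#' a panel compound by matching its precursor/product isolation targets to the
#' panel's Q1/Q3 within `tol` m/z. Unmatched chromatograms are reported in the
#' `unmatched` attribute (and a warning), never silently dropped.
#'
#' @param path mzML file.
#' @param panel The `attribute_panel`.
#' @param tol Match tolerance in m/z (applied to Q1 and Q3).
#' @param sample_id Sample id to stamp on the traces (defaults to the run id).
#' @return Long chromatogram data.frame with an `unmatched` attribute.
#' @export
read_srm_mzml <- function(path, panel, tol = 0.7, sample_id = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  ms <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(ms))
  hdr <- mzR::chromatogramHeader(ms)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  out <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(hdr))) {
    q1 <- hdr$precursorIsolationWindowTargetMZ[i]
    q3 <- hdr$productIsolationWindowTargetMZ[i]
    if (is.na(q1) || is.na(q3)) {
      unmatched <- c(unmatched, hdr$chromatogramId[i])
      next
    }
    hit <- which(abs(panel$q1_mz - q1) <= tol & abs(panel$q3_mz - q3) <= tol)
    if (!length(hit)) {
      unmatched <- c(unmatched, hdr$chromatogramId[i])
      next
    }
    cc <- mzR::chromatogram(ms, hdr$chromatogramIndex[i])
    for (h in hit) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, compound_id = panel$compound_id[h],
        time_min = cc[[1]], intensity = cc[[2]], stringsAsFactors = FALSE)
    }
  }
  if (length(unmatched)) {
    warning(length(unmatched), " mzML chromatogram(s) matched no panel transition",
            call. = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), compound_id = character(0),
               time_min = numeric(0), intensity = numeric(0))
  rownames(res) <- NULL
  attr(res, "unmatched") <- unmatched
  res
}
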