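# MRM chromatogram traces: long-format CSV and mzML chromatogram-list IO.
#
# A traces object is a long tibble (transition_id, time_min, intensity)
# with class "sq_traces". Channel ids are either "<analyte>:<role>"
# (simulator CSV convention) or SRM identifiers
# "SRM SIC Q1=<precursor> Q3=<product>" (mzML convention); both resolve to
# panel analytes. mzML stores time in seconds; everything in-package is
# minutes.

new_sq_traces <- function(x) {
  structure(x, class = c("sq_traces", class(tibble::tibble())))
}

#' Read MRM chromatogram traces
#'
#' CSV input is long format with columns `transition_id,time_min,intensity`.
#' mzML input is read through the `mzR` chromatogram interface (one trace
#' per SRM chromatogram, channel id = chromatogram id, seconds converted to
#' minutes). Per channel, time must be strictly increasing and intensities
#' non-negative.
#'
#' @param source file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"mzml"`.
#' @return An `sq_traces` tibble.
#' @export
read_traces <- function(source, format = c("auto", "csv", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", source, ignore.case = TRUE)) "mzml"
              else if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv"
              else stop("cannot infer trace format from: ", source,
                        call. = FALSE)
  }
  x <- if (format == "csv") read_traces_csv(source) else read_traces_mzml(source)
  validate_traces(x)
  new_sq_traces(x)
}

read_traces_csv <- function(source) {
  if (file.size(source) == 0) stop("empty trace file: ", source, call. = FALSE)
  x <- readr::read_csv(
    source,
    col_types = readr::cols(
      transition_id = readr::col_character(),
      time_min = readr::col_double(),
      intensity = readr::col_double()
    )
  )
  if (nrow(x) == 0L) stop("no trace rows in: ", source, call. = FALSE)
  x
}

read_traces_mzml <- function(source) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML reading requires the 'mzR' package", call. = FALSE)
  }
  fh <- mzR::openMSfile(source, backend = "pwiz")
  on.exit(mzR::close(fh))
  hdr <- mzR::chromatogramHeader(fh)
  if (is.null(hdr) || nrow(hdr) == 0L) {
    stop("no chromatograms in: ", source, call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(hdr)), function(i) {
    ch <- mzR::chromatogram(fh, i)
    tibble::tibble(
      transition_id = hdr$chromatogramId[i],
      time_min = ch[[1]] / 60,  # mzML time in seconds
      intensity = ch[[2]]
    )
  })
}

validate_traces <- function(x) {
  stopifnot(all(c("transition_id", "time_min", "intensity") %in% names(x)))
  for (id in unique(x$transition_id)) {
    t <- x$time_min[x$transition_id == id]
    if (any(diff(t) <= 0)) {
      stop("non-monotone time axis in channel '", id, "'", call. = FALSE)
    }
  }
  if (any(x$intensity < 0)) {
    stop("negative intensities in traces", call. = FALSE)
  }
  invisible(x)
}

#' Write MRM traces
#'
#' CSV uses the long `transition_id,time_min,intensity` schema. mzML writes
#' a chromatogram-list file (one SRM chromatogram per channel, ids
#' `SRM SIC Q1=<precursor> Q3=<product>`, 64-bit little-endian base64
#' arrays, time in seconds) readable by proteowizard-based tools including
#' `mzR`; it requires the channels to be resolvable against `panel`.
#'
#' @param traces an `sq_traces` tibble.
#' @param sink output path.
#' @param format `"csv"` or `"mzml"`.
#' @param panel panel used to map channel ids to Q1/Q3 (mzML only).
#' @return `traces`, invisibly.
#' @export
write_traces <- function(traces, sink, format = c("csv", "mzml"),
                         panel = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(
      tibble::as_tibble(traces)[c("transition_id", "time_min", "intensity")],
      sink
    )
  } else {
    write_traces_mzml(traces, sink, panel)
  }
  invisible(traces)
}

# resolve "<analyte>:<role>" or "SRM SIC Q1=.. Q3=.." ids to analyte/role
resolve_channel <- function(transition_id, panel, tolerance = 0.5) {
  purrr::map_dfr(transition_id, function(id) {
    if (grepl("^SRM SIC Q1=", id)) {
      q1 <- as.numeric(sub("^SRM SIC Q1=([0-9.]+) Q3=.*$", "\\1", id))
      q3 <- as.numeric(sub("^.*Q3=([0-9.]+)$", "\\1", id))
      m <- match_transition(panel, q1, q3, tolerance)
      if (nrow(m) == 0L) {
        return(tibble::tibble(transition_id = id, analyte = NA_character_,
                              role = NA_character_))
      }
      return(tibble::tibble(transition_id = id, analyte = m$analyte,
                            role = m$role))
    }
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% panel$analyte &&
        parts[2] %in% .ROLES) {
      return(tibble::tibble(transition_id = id, analyte = parts[1],
                            role = parts[2]))
    }
    tibble::tibble(transition_id = id, analyte = NA_character_,
                   role = NA_character_)
  })
}

channel_srm_id <- function(analyte, role, panel) {
  row <- which(panel$analyte == analyte & panel$role == role)
  stopifnot(length(row) == 1L)
  sprintf("SRM SIC Q1=%s Q3=%s",
          format(panel$precursor_mz[row], trim = TRUE),
          format(panel$product_mz[row], trim = TRUE))
}

write_traces_mzml <- function(traces, sink, panel) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("mzML writing requires the 'xml2' package", call. = FALSE)
  }
  if (is.null(panel)) {
    stop("mzML writing requires a panel to map channels to Q1/Q3",
         call. = FALSE)
  }
  b64_doubles <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
    gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)
  }
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("mzML writing requires the 'jsonlite' package", call. = FALSE)
  }
  ids <- unique(traces$transition_id)
  res <- resolve_channel(ids, panel)
  if (any(is.na(res$analyte))) {
    stop("cannot resolve channels against panel: ",
         paste(ids[is.na(res$analyte)], collapse = ", "), call. = FALSE)
  }
  chrom_xml <- vapply(seq_along(ids), function(i) {
    tr <- traces[traces$transition_id == ids[i], ]
    row <- which(panel$analyte == res$analyte[i] & panel$role == res$role[i])
    srm_id <- channel_srm_id(res$analyte[i], res$role[i], panel)
    time_b64 <- b64_doubles(tr$time_min * 60)
    int_b64 <- b64_doubles(tr$intensity)
    paste0(
      '<chromatogram index="', i - 1L, '" id="', srm_id,
      '" defaultArrayLength="', nrow(tr), '">\n',
      '<cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>\n',
      '<precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="',
      panel$precursor_mz[row],
      '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow></precursor>\n',
      '<product><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="',
      panel$product_mz[row],
      '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow></product>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="', nchar(time_b64), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
      '<binary>', time_b64, '</binary>',
      '</binaryDataArray>\n',
      '<binaryDataArray encodedLength="', nchar(int_b64), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>', int_b64, '</binary>',
      '</binaryDataArray>\n',
      '</binaryDataArrayList>\n',
      '</chromatogram>'
    )
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sqmrm" version="0.1"/></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="sqmrm">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="sqmrm_run" defaultInstrumentConfigurationRef="IC1">\n',
    '<chromatogramList count="', length(ids), '" defaultDataProcessingRef="dp1">\n',
    paste(chrom_xml, collapse = "\n"), '\n',
    '</chromatogramList>\n</run>\n</mzML>\n'
  )
  # parse/serialise through xml2 to guarantee well-formedness
  xml2::write_xml(xml2::read_xml(doc), sink)
  invisible(sink)
}
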