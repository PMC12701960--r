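## mzML reading and spectrum records.
##
## The pre-installed stack has no dedicated mzML reader, so this module
## implements the subset of mzML 1.1 the package needs directly on xml2:
## spectrum cvParams, precursor/activation blocks, and base64-encoded
## binary arrays (64/32-bit floats, optionally zlib-compressed).

.CV_MS_LEVEL      <- "MS:1000511"
.CV_TIC           <- "MS:1000285"
.CV_CENTROID      <- "MS:1000127"
.CV_PROFILE       <- "MS:1000128"
.CV_SCAN_START    <- "MS:1000016"
.CV_MZ_ARRAY      <- "MS:1000514"
.CV_INT_ARRAY     <- "MS:1000515"
.CV_FLOAT64       <- "MS:1000523"
.CV_FLOAT32       <- "MS:1000521"
.CV_ZLIB          <- "MS:1000574"
.CV_NO_COMPRESS   <- "MS:1000576"
.CV_SELECTED_MZ   <- "MS:1000744"
.CV_CHARGE        <- "MS:1000041"

.ACTIVATION_CV <- list(
  HCD = c("MS:1000422",                       # beam-type CID
          "MS:1002481"),                      # HCD energy (appears with it)
  ETD_FAMILY = c("MS:1000598",                # electron transfer dissociation
                 "MS:1002631"),               # EThcD-style combined term
  UVPD = c("MS:1003246", "MS:1000435")        # UVPD / photodissociation
)

#' Construct a spectrum record
#'
#' A centroided MS/MS scan: parallel peak arrays plus acquisition
#' metadata. Peaks are stored sorted by ascending m/z.
#'
#' @param scan_number Integer scan number.
#' @param mz,intensity Numeric peak arrays (equal length).
#' @param ms_level Integer MS level (1 = survey, 2 = MS/MS).
#' @param activation One of `"HCD"`, `"ETD_FAMILY"`, `"UVPD"`, `"OTHER"`.
#' @param tic Total ion current; recomputed from `intensity` when `NULL`.
#' @param noise Optional per-peak noise estimates (enables S/N filtering).
#' @param precursor_mz,precursor_charge Optional precursor descriptors.
#' @param retention_time Optional retention time in minutes.
#' @return A `spectrum` object (list).
#' @export
spectrum_record <- function(scan_number, mz, intensity, ms_level = 2L,
                            activation = "HCD", tic = NULL, noise = NULL,
                            precursor_mz = NA_real_,
                            precursor_charge = NA_integer_,
                            retention_time = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity", call. = FALSE)
  if (!is.null(noise) && length(noise) != length(mz))
    stop("noise array length mismatch", call. = FALSE)
  activation <- match.arg(activation, c("HCD", "ETD_FAMILY", "UVPD", "OTHER"))
  o <- order(mz)
  if (is.null(tic)) tic <- sum(intensity)
  structure(list(
    scan_number = as.integer(scan_number),
    ms_level = as.integer(ms_level),
    activation = activation,
    tic = tic,
    mz = as.numeric(mz)[o],
    intensity = as.numeric(intensity)[o],
    noise = if (is.null(noise)) NULL else as.numeric(noise)[o],
    precursor_mz = precursor_mz,
    precursor_charge = precursor_charge,
    retention_time = retention_time
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("MS", x$ms_level, " scan ", x$scan_number, " [", x$activation, "]: ",
      length(x$mz), " peaks, TIC ", format(x$tic, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Map activation metadata to an activation class
#'
#' Classifies a scan's dissociation from its mzML controlled-vocabulary
#' accessions and/or term names. Any ETD-centric term (ETD, EThcD,
#' AI-ETD, ETcaD), even combined with supplemental collisional
#' activation, maps to `ETD_FAMILY`; beam-type CID maps to `HCD`;
#' photodissociation terms to `UVPD`; anything else to `OTHER`.
#'
#' @param accessions Character vector of CV accessions (e.g.
#'   `"MS:1000598"`); may be empty.
#' @param names Character vector of CV term names or a Thermo filter
#'   string fallback; may be empty.
#' @return One of `"HCD"`, `"ETD_FAMILY"`, `"UVPD"`, `"OTHER"`.
#' @export
detect_activation <- function(accessions = character(0),
                              names = character(0)) {
  text <- tolower(paste(names, collapse = " "))
  if (any(.ACTIVATION_CV$ETD_FAMILY %in% accessions) ||
      grepl("electron transfer|ethcd|etcad|ai-etd|\\betd\\b", text))
    return("ETD_FAMILY")
  if (any(.ACTIVATION_CV$UVPD %in% accessions) ||
      grepl("ultraviolet photodissociation|\\buvpd\\b|photodissociation", text))
    return("UVPD")
  if (any(.ACTIVATION_CV$HCD %in% accessions) ||
      grepl("beam-type collision|\\bhcd\\b", text))
    return("HCD")
  "OTHER"
}

.decode_binary_array <- function(node) {
  cv <- xml2::xml_find_all(node, "./cvParam")
  acc <- xml2::xml_attr(cv, "accession")
  b64 <- xml2::xml_text(xml2::xml_find_first(node, "./binary"))
  b64 <- gsub("[[:space:]]", "", b64)
  raw <- if (nzchar(b64)) jsonlite::base64_dec(b64) else raw(0)
  if (.CV_ZLIB %in% acc) raw <- memDecompress(raw, type = "gzip")
  size <- if (.CV_FLOAT32 %in% acc) 4L else 8L
  vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                  endian = "little")
  kind <- if (.CV_MZ_ARRAY %in% acc) "mz"
          else if (.CV_INT_ARRAY %in% acc) "intensity"
          else {
            nm <- xml2::xml_attr(cv, "name")
            if (any(grepl("noise", nm, ignore.case = TRUE))) "noise" else "other"
          }
  list(kind = kind, values = vals)
}

.cv_value <- function(node, accession) {
  hit <- xml2::xml_find_first(
    node, sprintf("./cvParam[@accession='%s']", accession))
  if (inherits(hit, "xml_missing")) return(NULL)
  xml2::xml_attr(hit, "value")
}

.parse_spectrum_node <- function(node) {
  id <- xml2::xml_attr(node, "id")
  scan_number <- suppressWarnings(
    as.integer(sub(".*scan=([0-9]+).*", "\\1", id)))
  if (is.na(scan_number))
    scan_number <- as.integer(xml2::xml_attr(node, "index")) + 1L
  ms_level <- as.integer(.cv_value(node, .CV_MS_LEVEL) %||% "0")
  profile <- !inherits(
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                       .CV_PROFILE)), "xml_missing")
  if (profile && ms_level >= 2L)
    stop("profile-mode MS", ms_level, " spectrum in scan ", scan_number,
         ": MS/MS scans must contain only centroided peaks ",
         "(centroid during mzML conversion)", call. = FALSE)
  tic_meta <- suppressWarnings(as.numeric(.cv_value(node, .CV_TIC) %||% NA))

  rt <- NA_real_
  scan_node <- xml2::xml_find_first(node, ".//scan")
  if (!inherits(scan_node, "xml_missing")) {
    rt_node <- xml2::xml_find_first(
      scan_node, sprintf("./cvParam[@accession='%s']", .CV_SCAN_START))
    if (!inherits(rt_node, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
      unit <- xml2::xml_attr(rt_node, "unitName")
      if (identical(unit, "second")) rt <- rt / 60
    }
  }

  activation <- "OTHER"; prec_mz <- NA_real_; prec_z <- NA_integer_
  prec <- xml2::xml_find_first(node, ".//precursor")
  if (!inherits(prec, "xml_missing")) {
    act_cv <- xml2::xml_find_all(prec, ".//activation/cvParam")
    activation <- detect_activation(xml2::xml_attr(act_cv, "accession"),
                                    xml2::xml_attr(act_cv, "name"))
    sel <- xml2::xml_find_first(prec, ".//selectedIon")
    if (!inherits(sel, "xml_missing")) {
      prec_mz <- suppressWarnings(as.numeric(.cv_value(sel, .CV_SELECTED_MZ) %||% NA))
      prec_z <- suppressWarnings(as.integer(.cv_value(sel, .CV_CHARGE) %||% NA))
    }
  }

  arrays <- lapply(xml2::xml_find_all(node, ".//binaryDataArray"),
                   .decode_binary_array)
  get_arr <- function(kind) {
    for (a in arrays) if (a$kind == kind) return(a$values)
    NULL
  }
  mz <- get_arr("mz") %||% numeric(0)
  intensity <- get_arr("intensity") %||% numeric(0)
  noise <- get_arr("noise")

  ## Centroid heuristic: profile data packs peaks at near-instrument
  ## spacing; >500 peaks with median spacing < 0.005 Da means profile.
  if (ms_level >= 2L && length(mz) > 500L &&
      stats::median(diff(sort(mz))) < 0.005)
    stop("scan ", scan_number, " looks like profile data ",
         "(median peak spacing < 0.005 Da over >500 peaks): ",
         "MS/MS scans must contain only centroided peaks", call. = FALSE)

  tic <- sum(intensity)
  ## Prefer file metadata unless it disagrees with the peak sum by >20%;
  ## the oxonium TIC fraction must be self-consistent with matched peaks.
  if (!is.na(tic_meta) && tic_meta > 0) {
    if (tic == 0 || abs(tic_meta - tic) / tic <= 0.20) tic <- tic_meta
    else message("scan ", scan_number, ": file TIC ", format(tic_meta),
                 " disagrees with peak sum ", format(tic), "; using peak sum")
  }

  spectrum_record(scan_number, mz, intensity, ms_level = ms_level,
                  activation = activation, tic = tic, noise = noise,
                  precursor_mz = prec_mz, precursor_charge = prec_z,
                  retention_time = rt)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read MS/MS scans from an mzML file
#'
#' Parses an mzML 1.1 file (plain or indexed; binary arrays may be
#' zlib-compressed) and returns the scans at the requested MS levels, in
#' file order. Gzip-packaged files (`.mzML.gz`) are rejected. Profile-mode
#' MS/MS spectra raise an error instructing centroiding. Empty scans
#' (no positive intensity) are skipped with a warning. The scan TIC is
#' taken from file metadata when it agrees with the peak-intensity sum
#' to within 20%, otherwise the peak sum is used.
#'
#' @param path Path to an mzML file.
#' @param ms_levels Integer vector of MS levels to keep (default `2`).
#' @return List of `spectrum` records.
#' @export
read_mzml <- function(path, ms_levels = 2L) {
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  head_bytes <- readBin(path, "raw", n = 2)
  if (length(head_bytes) == 2 && head_bytes[1] == as.raw(0x1f) &&
      head_bytes[2] == as.raw(0x8b))
    stop("gzip-packaged file: ", path,
         " — decompress to plain .mzML before reading", call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable mzML file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  out <- vector("list", length(nodes))
  kept <- 0L
  for (node in nodes) {
    sp <- .parse_spectrum_node(node)
    if (!sp$ms_level %in% ms_levels) next
    if (length(sp$intensity) == 0L || sum(sp$intensity) <= 0) {
      warning("scan ", sp$scan_number, ": no positive intensity, skipped",
              call. = FALSE)
      next
    }
    kept <- kept + 1L
    out[[kept]] <- sp
  }
  out[seq_len(kept)]
}

#' Write spectra to a minimal mzML file
#'
#' Serializes spectrum records to standard-conformant plain mzML 1.1
#' (64-bit little-endian base64 arrays), readable by [read_mzml()] and by
#' standard mzML consumers. Used by the synthetic-fixture generator.
#'
#' @param spectra List of `spectrum` records.
#' @param path Output path.
#' @param zlib Compress binary arrays with zlib (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path, zlib = FALSE) {
  enc <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
    if (zlib) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  compress_cv <- if (zlib)
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  act_cv <- c(
    HCD = '<cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation"/>',
    ETD_FAMILY = '<cvParam cvRef="MS" accession="MS:1000598" name="electron transfer dissociation"/>',
    UVPD = '<cvParam cvRef="MS" accession="MS:1003246" name="ultraviolet photodissociation"/>',
    OTHER = '<cvParam cvRef="MS" accession="MS:1000044" name="dissociation method"/>'
  )
  bda <- function(values, kind_cv) paste0(
    '<binaryDataArray encodedLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    compress_cv, kind_cv, "<binary>", enc(values), "</binary>",
    "</binaryDataArray>")
  body <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    precursor <- if (sp$ms_level >= 2L) paste0(
      "<precursorList count=\"1\"><precursor><selectedIonList count=\"1\"><selectedIon>",
      if (!is.na(sp$precursor_mz)) sprintf(
        '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
        sp$precursor_mz) else "",
      if (!is.na(sp$precursor_charge)) sprintf(
        '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
        sp$precursor_charge) else "",
      "</selectedIon></selectedIonList><activation>", act_cv[[sp$activation]],
      "</activation></precursor></precursorList>") else ""
    rt <- if (!is.na(sp$retention_time)) sprintf(
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitName="minute"/></scan></scanList>',
      sp$retention_time) else ""
    narr <- if (is.null(sp$noise)) "" else paste0(
      '<binaryDataArray encodedLength="0" arrayLength="', length(sp$noise), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      compress_cv,
      '<cvParam cvRef="MS" accession="MS:1002744" name="sampled noise intensity array"/>',
      "<binary>", enc(sp$noise), "</binary></binaryDataArray>")
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, sp$scan_number, length(sp$mz)),
      sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
              sp$ms_level),
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000285" name="total ion current" value="%.8e"/>',
              sp$tic),
      rt, precursor,
      sprintf('<binaryDataArrayList count="%d">', 2L + !is.null(sp$noise)),
      bda(sp$mz, '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitName="m/z"/>'),
      bda(sp$intensity, '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>'),
      narr,
      "</binaryDataArrayList></spectrum>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<run id="run1">',
    sprintf('<spectrumList count="%d">', length(spectra)),
    paste(body, collapse = ""),
    "</spectrumList></run></mzML>\n")
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
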