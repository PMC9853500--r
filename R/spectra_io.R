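#' Read a mass spectrum from disk
#'
#' The canonical on-disk format is two-column delimited text (m/z,
#' intensity; comma, tab or whitespace separated, autodetected) with
#' optional `#`-prefixed header lines carrying `sample_id`, `replicate_id`
#' and `role`. A minimal mzML reader (spectrum list only, 32/64-bit
#' little-endian uncompressed or zlib-compressed binary arrays) is also
#' provided.
#'
#' Rows with duplicated m/z are averaged (export-rounding artifacts;
#' averaging is idempotent) and unsorted m/z values are re-sorted, each with
#' a warning.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"delimited"` or `"mzml"`.
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "delimited", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "delimited"
  if (format == "mzml") return(read_spectrum_mzml(path))
  read_spectrum_delimited(path)
}

read_spectrum_delimited <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("no data rows in ", path, call. = FALSE)
  meta <- list(sample_id = "unknown", replicate_id = 1L, role = "sample")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\w+)\\s*[:=]\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  first <- lines[body_idx[1]]
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  parts <- strsplit(lines[body_idx], if (sep == "") "\\s+" else sep)
  # tolerate a single non-numeric header row
  if (length(parts) && suppressWarnings(is.na(as.numeric(parts[[1]][1])))) {
    parts <- parts[-1]
    body_idx <- body_idx[-1]
  }
  n_fields <- lengths(parts)
  bad <- which(n_fields < 2L)
  if (length(bad))
    stop("malformed row at line ", body_idx[bad[1]], " of ", path,
         ": expected 2 delimited numeric fields", call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(mz) || anyNA(it)) {
    bad <- which(is.na(mz) | is.na(it))[1]
    stop("nonnumeric value at line ", body_idx[bad], " of ", path,
         call. = FALSE)
  }
  if (any(it < 0)) {
    bad <- which(it < 0)[1]
    stop("negative intensity at line ", body_idx[bad], " of ", path,
         call. = FALSE)
  }
  if (is.unsorted(mz, strictly = FALSE)) {
    warning("m/z not ascending in ", basename(path), "; re-sorting")
    o <- order(mz); mz <- mz[o]; it <- it[o]
  }
  if (anyDuplicated(mz)) {
    warning("duplicated m/z rows in ", basename(path), "; averaging")
    it <- as.numeric(tapply(it, mz, mean))
    mz <- sort(unique(mz))
  }
  mass_spectrum(mz, it, sample_id = meta$sample_id,
                replicate_id = as.integer(meta$replicate_id),
                role = match.arg(meta$role, c("sample", "matrix_blank")))
}

#' Write a mass spectrum to disk
#'
#' Writes the canonical two-column delimited format (with metadata header)
#' or a minimal mzML document; both round-trip exactly through
#' [read_spectrum()] at full double precision.
#'
#' @param spectrum a validated [mass_spectrum()].
#' @param path destination file.
#' @param format `"delimited"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           format = c("delimited", "mzml")) {
  format <- match.arg(format)
  validate_spectrum(spectrum)
  if (format == "mzml") return(write_spectrum_mzml(spectrum, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id: ", spectrum$sample_id),
    paste0("# replicate_id: ", spectrum$replicate_id),
    paste0("# role: ", spectrum$role),
    paste(format(spectrum$mz, digits = 17, scientific = FALSE, trim = TRUE),
          format(spectrum$intensity, digits = 17, scientific = FALSE,
                 trim = TRUE),
          sep = ",")), con)
  invisible(path)
}

# --- minimal mzML ----------------------------------------------------------

b64_encode_doubles <- function(x)
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                               size = 8,
                                               endian = "little")),
       fixed = TRUE)

write_spectrum_mzml <- function(spectrum, path) {
  n <- length(spectrum$mz)
  mz64 <- b64_encode_doubles(spectrum$mz)
  it64 <- b64_encode_doubles(spectrum$intensity)
  arr <- function(data, acc, name) paste0(
    '      <binaryDataArray encodedLength="', nchar(data), '">\n',
    '       <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '       <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '       <cvParam cvRef="MS" accession="', acc, '" name="', name,
    '" value=""', if (acc == "MS:1000514") ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"' else
      ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"', '/>\n',
    '       <binary>', data, '</binary>\n',
    '      </binaryDataArray>\n')
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    ' <cvList count="1">\n',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    ' </cvList>\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <softwareList count="1">\n',
    '  <software id="painprint" version="0.1.0"/>\n',
    ' </softwareList>\n',
    ' <instrumentConfigurationList count="1">\n',
    '  <instrumentConfiguration id="IC1"/>\n',
    ' </instrumentConfigurationList>\n',
    ' <dataProcessingList count="1">\n',
    '  <dataProcessing id="DP1">\n',
    '   <processingMethod order="1" softwareRef="painprint">\n',
    '    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '   </processingMethod>\n',
    '  </dataProcessing>\n',
    ' </dataProcessingList>\n',
    ' <run id="', xml_escape(spectrum$sample_id), '" defaultInstrumentConfigurationRef="IC1">\n',
    '  <spectrumList count="1" defaultDataProcessingRef="DP1">\n',
    '   <spectrum index="0" id="scan=1" defaultArrayLength="', n, '">\n',
    '    <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>\n',
    '    <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
    '    <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '    <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>\n',
    '    <binaryDataArrayList count="2">\n',
    arr(mz64, "MS:1000514", "m/z array"),
    arr(it64, "MS:1000515", "intensity array"),
    '    </binaryDataArrayList>\n',
    '   </spectrum>\n',
    '  </spectrumList>\n',
    ' </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

read_spectrum_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrum")
  if (is.na(spec)) stop("no <spectrum> element in ", path, call. = FALSE)
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  decoded <- list()
  for (a in arrays) {
    accs <- xml2::xml_attr(xml2::xml_find_all(a, "./cvParam"), "accession")
    raw <- jsonlite::base64_dec(xml2::xml_text(
      xml2::xml_find_first(a, "./binary")))
    if ("MS:1000574" %in% accs) raw <- memDecompress(raw, type = "gzip")
    size <- if ("MS:1000521" %in% accs) 4L else 8L
    vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                    endian = "little")
    if ("MS:1000514" %in% accs) decoded$mz <- vals
    if ("MS:1000515" %in% accs) decoded$intensity <- vals
  }
  if (is.null(decoded$mz) || is.null(decoded$intensity))
    stop("mzML file lacks m/z or intensity arrays: ", path, call. = FALSE)
  run_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//run"), "id")
  mass_spectrum(decoded$mz, pmax(decoded$intensity, 0),
                sample_id = if (is.na(run_id)) "unknown" else run_id)
}

# --- cohort manifest -------------------------------------------------------

#' Write a synthetic cohort to a directory
#'
#' Persists every spectrum as delimited text plus `manifest.csv` (sample
#' table: sample_id, group, replicate, role, file), `behavior.csv` and a
#' `ground_truth.json` manifest echoing the generator configuration and
#' latent parameters.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- c(cohort$spectra, cohort$blanks)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    fn <- sprintf("%s_rep%d.csv", s$sample_id, s$replicate_id)
    write_spectrum(s, file.path(dir, fn))
    data.frame(sample_id = s$sample_id,
               group = if (s$role == "sample")
                 cohort$truth$labels[[s$sample_id]] else NA_character_,
               replicate = s$replicate_id, role = s$role, file = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  beh <- do.call(rbind, lapply(cohort$behavior, function(b) data.frame(
    sample_id = b$sample_id,
    latency_trials = paste(b$latency_trials, collapse = ";"),
    vf_sequence = paste(sprintf("%g:%s", b$vf_sequence$force,
                                ifelse(b$vf_sequence$response, "X", "O")),
                        collapse = ";"),
    latency_mean = b$derived_latency_mean,
    threshold_50 = b$derived_threshold_50, stringsAsFactors = FALSE)))
  write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return A list with `spectra`, `blanks`, `labels` (named character
#'   vector) and `behavior` (data frame).
#' @export
read_cohort <- function(dir) {
  mf <- read.table(file.path(dir, "manifest.csv"), sep = ",", header = TRUE,
                   stringsAsFactors = FALSE)
  paths <- file.path(dir, mf$file)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("manifest references missing file(s): ",
         paste(mf$file[missing], collapse = ", "), call. = FALSE)
  specs <- lapply(paths, read_spectrum)
  is_blank <- mf$role == "matrix_blank"
  labels <- mf[!is_blank & mf$replicate == 1, c("sample_id", "group")]
  beh_path <- file.path(dir, "behavior.csv")
  behavior <- if (file.exists(beh_path))
    read.table(beh_path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  else NULL
  list(spectra = specs[!is_blank], blanks = specs[is_blank],
       labels = setNames(labels$group, labels$sample_id),
       behavior = behavior)
}
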