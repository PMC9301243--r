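# Peak-list input/output.  Spectra travel as a plain data.frame with one
# row per MS1 feature and a list-column of MS/MS peak matrices, the
# shape used throughout the annotation layer.

.empty_spectra <- function() {
  data.frame(feature_id = character(0), precursor_mz = numeric(0),
             rt = numeric(0), sample_id = character(0),
             ms2 = I(list()), stringsAsFactors = FALSE)
}

#' Assemble a spectra table
#'
#' @param feature_id Character vector of feature ids.
#' @param precursor_mz Precursor m/z (Th).
#' @param rt Retention time (minutes), `NA` allowed.
#' @param ms2 List of two-column matrices (`mz`, `intensity`); a zero-row
#'   matrix marks an MS1-only feature.
#' @param sample_id Optional sample labels.
#' @return A data.frame with a `ms2` list-column.
#' @export
spectra_table <- function(feature_id, precursor_mz, rt = NA_real_,
                          ms2 = NULL, sample_id = NA_character_) {
  n <- length(feature_id)
  if (is.null(ms2)) ms2 <- replicate(n, .empty_ms2(), simplify = FALSE)
  ms2 <- lapply(ms2, function(p) {
    p <- as.matrix(p)
    if (!ncol(p)) p <- .empty_ms2()
    colnames(p) <- c("mz", "intensity")
    if (nrow(p) && any(p[, "mz"] <= 0)) stop("ms2 m/z must be positive")
    p
  })
  data.frame(feature_id = as.character(feature_id),
             precursor_mz = as.numeric(precursor_mz),
             rt = rep_len(as.numeric(rt), n),
             sample_id = rep_len(as.character(sample_id), n),
             ms2 = I(ms2), stringsAsFactors = FALSE)
}

.empty_ms2 <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
}

#' Read peak lists into a spectra table
#'
#' Supported formats: Mascot generic format (`.mgf`), centroided mzML
#' (`.mzML`, uncompressed or zlib 32/64-bit float arrays), and a simple
#' CSV dialect with columns `feature_id, precursor_mz, rt_min, ms2_mz,
#' ms2_intensity, sample_id` where the two `ms2_*` fields are
#' `"|"`-joined number lists.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"mgf"`, `"csv"` or `"mzml"`.
#' @return A spectra data.frame (see [spectra_table()]).  An empty file
#'   yields an empty table with a warning.
#' @export
read_peaklists <- function(path, format = c("auto", "mgf", "csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", csv = "csv", mzml = "mzml",
                     stop("cannot infer peak-list format from extension: ", ext))
  }
  switch(format,
         mgf = .read_mgf(path),
         csv = .read_peaklist_csv(path),
         mzml = .read_mzml(path))
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty peak-list file: ", path)
    return(.empty_spectra())
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  recs <- lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- strsplit(block[kv], "=", fixed = TRUE)
    keys <- toupper(vapply(hdr, `[`, "", 1L))
    vals <- vapply(hdr, function(x) paste(x[-1], collapse = "="), "")
    pep <- vals[keys == "PEPMASS"]
    if (!length(pep)) stop("MGF block without PEPMASS in ", path)
    rt <- vals[keys == "RTINSECONDS"]
    title <- vals[keys == "TITLE"]
    peaks <- block[!kv]
    pm <- if (length(peaks)) {
      do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), function(x)
        as.numeric(x[1:2])))
    } else .empty_ms2()
    colnames(pm) <- c("mz", "intensity")
    list(feature_id = if (length(title)) title[1] else paste0("spectrum_", i),
         precursor_mz = as.numeric(strsplit(pep[1], "[ \t]+")[[1]][1]),
         rt = if (length(rt)) as.numeric(rt[1]) / 60 else NA_real_,
         ms2 = pm)
  })
  spectra_table(
    feature_id = vapply(recs, `[[`, "", "feature_id"),
    precursor_mz = vapply(recs, `[[`, 0, "precursor_mz"),
    rt = vapply(recs, `[[`, 0, "rt"),
    ms2 = lapply(recs, `[[`, "ms2"))
}

.read_peaklist_csv <- function(path) {
  if (file.size(path) == 0) {
    warning("empty peak-list file: ", path)
    return(.empty_spectra())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!nrow(df)) {
    warning("empty peak-list file: ", path)
    return(.empty_spectra())
  }
  need <- c("feature_id", "precursor_mz", "rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak-list CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  split_nums <- function(x) if (is.na(x) || !nzchar(x)) numeric(0) else
    as.numeric(strsplit(x, "|", fixed = TRUE)[[1]])
  ms2 <- lapply(seq_len(nrow(df)), function(i) {
    mz <- if ("ms2_mz" %in% names(df)) split_nums(df$ms2_mz[i]) else numeric(0)
    it <- if ("ms2_intensity" %in% names(df)) split_nums(df$ms2_intensity[i])
          else rep(NA_real_, length(mz))
    if (length(it) != length(mz)) stop("ms2_mz / ms2_intensity length mismatch, row ", i)
    cbind(mz = mz, intensity = it)
  })
  spectra_table(df$feature_id, as.numeric(df$precursor_mz),
                as.numeric(df$rt_min), ms2,
                if ("sample_id" %in% names(df)) df$sample_id else NA_character_)
}

#' Write a spectra table as MGF or as the CSV peak-list dialect
#'
#' @param spectra A spectra data.frame (see [spectra_table()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", spectra$feature_id[i]),
                 paste0("PEPMASS=", sprintf("%.6f", spectra$precursor_mz[i])),
                 if (!is.na(spectra$rt[i]))
                   paste0("RTINSECONDS=", sprintf("%.3f", spectra$rt[i] * 60))),
               con)
    p <- spectra$ms2[[i]]
    if (nrow(p))
      writeLines(sprintf("%.6f %.4f", p[, "mz"], p[, "intensity"]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' @rdname write_mgf
#' @export
write_peaklist_csv <- function(spectra, path) {
  join <- function(v, fmt) paste(sprintf(fmt, v), collapse = "|")
  df <- data.frame(
    feature_id = spectra$feature_id,
    precursor_mz = sprintf("%.6f", spectra$precursor_mz),
    rt_min = spectra$rt,
    ms2_mz = vapply(spectra$ms2, function(p)
      if (nrow(p)) join(p[, "mz"], "%.6f") else "", ""),
    ms2_intensity = vapply(spectra$ms2, function(p)
      if (nrow(p)) join(p[, "intensity"], "%.4f") else "", ""),
    sample_id = spectra$sample_id,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# --- minimal centroided mzML support -----------------------------------
# Covers the common encoding: base64 little-endian 32/64-bit float
# arrays, optionally zlib-compressed, one precursor per MS2 spectrum.
# MS1-only files are accepted (spectra without precursors are skipped
# unless they carry none at all, in which case each MS1 scan is a
# feature without fragments).

.decode_binary <- function(b64, bits, zlib) {
  if (is.na(b64) || !nzchar(b64)) return(numeric(0))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, "double", n = length(raw) %/% (bits / 8),
          size = bits / 8, endian = "little")
}

.read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(nodes)) {
    warning("empty peak-list file: ", path)
    return(.empty_spectra())
  }
  parse_arrays <- function(sp) {
    out <- list(mz = numeric(0), intensity = numeric(0))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      acc <- xml2::xml_attr(xml2::xml_find_all(bda, ".//cvParam"), "accession")
      kind <- if ("MS:1000514" %in% acc) "mz"
              else if ("MS:1000515" %in% acc) "intensity" else next
      bits <- if ("MS:1000521" %in% acc) 32 else 64
      zlib <- "MS:1000574" %in% acc
      b64 <- xml2::xml_text(xml2::xml_find_first(bda, ".//binary"))
      if (bits == 32) {
        raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
        if (zlib) raw <- memDecompress(raw, type = "gzip")
        out[[kind]] <- readBin(raw, "double", n = length(raw) %/% 4,
                               size = 4, endian = "little")
      } else {
        out[[kind]] <- .decode_binary(b64, 64, zlib)
      }
    }
    out
  }
  recs <- lapply(seq_along(nodes), function(i) {
    sp <- nodes[[i]]
    id <- xml2::xml_attr(sp, "id")
    sel <- xml2::xml_find_first(
      sp, ".//precursor//cvParam[@accession='MS:1000744']")
    pmz <- if (inherits(sel, "xml_missing")) NA_real_
           else as.numeric(xml2::xml_attr(sel, "value"))
    rtn <- xml2::xml_find_first(sp, ".//cvParam[@accession='MS:1000016']")
    rt <- NA_real_
    if (!inherits(rtn, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(rtn, "value"))
      unit <- xml2::xml_attr(rtn, "unitName")
      if (!is.na(unit) && grepl("second", unit)) rt <- rt / 60
    }
    arr <- parse_arrays(sp)
    list(id = if (is.na(id)) paste0("scan_", i) else id,
         pmz = pmz, rt = rt,
         ms2 = cbind(mz = arr$mz, intensity = arr$intensity))
  })
  with_prec <- vapply(recs, function(r) !is.na(r$pmz), TRUE)
  if (!any(with_prec))
    stop("mzML file has no precursor m/z values: ", path)
  recs <- recs[with_prec]  # one record per MS/MS-bearing precursor
  spectra_table(vapply(recs, `[[`, "", "id"),
                vapply(recs, `[[`, 0, "pmz"),
                vapply(recs, `[[`, 0, "rt"),
                lapply(recs, `[[`, "ms2"))
}

#' Write a spectra table as minimal centroided mzML
#'
#' Emits one MS2 spectrum per feature with uncompressed 64-bit m/z and
#' intensity arrays and a single selected precursor ion; intended for
#' round-trip tests and for interoperability with standard viewers.
#'
#' @param spectra A spectra data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  enc <- function(v) jsonlite::base64_enc(writeBin(as.numeric(v), raw(),
                                                   size = 8, endian = "little"))
  sp_xml <- vapply(seq_len(nrow(spectra)), function(i) {
    p <- spectra$ms2[[i]]
    paste0(
      '<spectrum id="', spectra$feature_id[i], '" index="', i - 1,
      '" defaultArrayLength="', nrow(p), '">',
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      '<scanList count="1"><scan>',
      '<cvParam accession="MS:1000016" name="scan start time" value="',
      spectra$rt[i], '" unitName="minute"/>',
      '</scan></scanList>',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      '<cvParam accession="MS:1000744" name="selected ion m/z" value="',
      sprintf("%.6f", spectra$precursor_mz[i]), '"/>',
      '</selectedIon></selectedIonList></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="MS:1000576" name="no compression"/>',
      '<cvParam accession="MS:1000514" name="m/z array"/>',
      '<binary>', enc(p[, "mz"]), '</binary></binaryDataArray>',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="MS:1000576" name="no compression"/>',
      '<cvParam accession="MS:1000515" name="intensity array"/>',
      '<binary>', enc(p[, "intensity"]), '</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, "")
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="', nrow(spectra), '">',
    paste(sp_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
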