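# The flavonoid building-block model: aglycone cores, glycosyl/acyl
# residues, composition of conjugates, combinatorial decomposition of
# precursor masses, family / glycosylation-degree classification.

#' Packaged flavonoid aglycone table
#'
#' The eleven aglycone cores underlying the packaged suspect library,
#' spanning the five families observed in *Medicago truncatula*:
#' anthocyanidins (peonidin, a permanently charged flavylium cation),
#' flavones (apigenin, tricin, chrysoeriol), isoflavones (daidzein,
#' formononetin, biochanin A, afrormosin, irisolidone), the pterocarpan
#' medicarpin and the chalcone-form flavanone precursor naringenin
#' chalcone.
#'
#' Afrormosin is stored as C17H14O5 (298.0841 Da): the literature
#' source prints C17H12O5 next to a 298.0841 Da mass, which are mutually
#' inconsistent; the formula consistent with the printed mass and with
#' every afrormosin conjugate formula is used.
#'
#' @return A data.frame with columns `name`, `family`, `formula`,
#'   `is_native_cation`, `neutral_mass`.
#' @export
flavonoid_aglycones <- function() {
  df <- data.frame(
    name = c("Peonidin", "Apigenin", "Tricin", "Chrysoeriol",
             "Naringenin Chalcone", "Daidzein", "Formononetin",
             "Biochanin A", "Afrormosin", "Irisolidone", "Medicarpin"),
    family = c("anthocyanidin", "flavone", "flavone", "flavone",
               "flavanone", "isoflavone", "isoflavone", "isoflavone",
               "isoflavone", "isoflavone", "pterocarpan"),
    formula = c("C16H13O6+", "C15H10O5", "C17H14O7", "C16H12O6",
                "C15H12O5", "C15H10O4", "C16H12O4", "C16H12O5",
                "C17H14O5", "C17H14O6", "C16H14O4"),
    stringsAsFactors = FALSE
  )
  df$is_native_cation <- grepl("\\+$", df$formula)
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, numeric(1),
                            USE.NAMES = FALSE)
  df
}

#' Packaged glycosyl and acyl residue table
#'
#' Residues are stored dehydrated (condensation water already removed),
#' so conjugate composition is pure formula addition.  Sugars: glucose
#' (Glc, C6H10O5, 162.0528 Da) and glucuronic acid (GlcA, C6H8O6,
#' 176.0321 Da).  Acyl decorations of the sugars: malonyl (Mal, C3H2O3,
#' 86.0004 Da), feruloyl (Fer, C10H8O3, 176.0473 Da) and coumaroyl
#' (Cou, C9H6O2, 146.0368 Da).
#'
#' @return A data.frame with columns `key`, `formula`, `klass`,
#'   `residue_mass`.
#' @export
flavonoid_residues <- function() {
  df <- data.frame(
    key = c("Glc", "GlcA", "Mal", "Fer", "Cou"),
    formula = c("C6H10O5", "C6H8O6", "C3H2O3", "C10H8O3", "C9H6O2"),
    klass = c("sugar", "sugar", "acyl", "acyl", "acyl"),
    stringsAsFactors = FALSE
  )
  df$residue_mass <- vapply(df$formula, monoisotopic_mass, numeric(1),
                            USE.NAMES = FALSE)
  df
}

# canonical residue ordering for names: acyl keys first, then sugars,
# each block alphabetical by key (positional linkage is never resolved)
.order_residues <- function(keys, residues = flavonoid_residues()) {
  if (!length(keys)) return(character(0))
  kl <- residues$klass[match(keys, residues$key)]
  keys[order(kl != "acyl", keys)]
}

#' Classify a residue multiset by glycosylation degree
#'
#' @param residues Character vector of residue keys (possibly empty), or
#'   a `compound_record`.
#' @return A list with `glyco_class` (one of `"Agly"`, `"Gly"`,
#'   `"GlyGly"`, `"GlyGlyGly"`) and logical `acylated`.
#' @examples
#' classify_glyco(c("GlcA", "GlcA"))  # GlyGly, not acylated
#' @export
classify_glyco <- function(residues) {
  if (inherits(residues, "compound_record")) residues <- residues$residues
  rtab <- flavonoid_residues()
  if (length(residues)) {
    bad <- setdiff(residues, rtab$key)
    if (length(bad)) stop("unknown residue key(s): ", paste(bad, collapse = ", "))
  }
  n_sugar <- sum(rtab$klass[match(residues, rtab$key)] == "sugar")
  if (n_sugar > 3) stop("more than 3 sugar residues is outside the model")
  list(
    glyco_class = c("Agly", "Gly", "GlyGly", "GlyGlyGly")[n_sugar + 1L],
    acylated = any(rtab$klass[match(residues, rtab$key)] == "acyl")
  )
}

#' Compose a glycoconjugate from an aglycone and a residue multiset
#'
#' Derives formula, neutral monoisotopic mass and precursor m/z by pure
#' addition of dehydrated residues onto the aglycone core; the precursor
#' is `[M+H]+` for neutral compounds and the bare cation for native
#' cations (anthocyanidins).  Names follow the field's style:
#' acyl prefixes before sugar suffixes, e.g. `"Medicarpin MalGlc"`.
#'
#' @param aglycone Aglycone name (row of [flavonoid_aglycones()]) or a
#'   one-row data.frame in that shape.
#' @param residues Character vector of residue keys, e.g.
#'   `c("Mal", "Glc")`; empty for the free aglycone.
#' @param max_residues Maximum multiset size (default 4: up to three
#'   sugars plus one acyl, the largest chain in the packaged library).
#' @param name Optional explicit compound name (used by the packaged
#'   library to keep literature names such as `"Irisolidone isomer"`).
#' @param rt Optional retention time in minutes.
#' @return A `compound_record`: list with `name`, `aglycone`, `family`,
#'   `residues`, `formula` ([element_counts()]), `formula_string`,
#'   `neutral_mass`, `precursor_mz`, `is_native_cation`, `glyco_class`,
#'   `acylated`, `rt`.
#' @examples
#' compose_compound("Medicarpin", c("Mal", "Glc"))
#' @export
compose_compound <- function(aglycone, residues = character(0),
                             max_residues = 4L, name = NULL, rt = NA_real_) {
  atab <- flavonoid_aglycones()
  rtab <- flavonoid_residues()
  if (is.character(aglycone)) {
    i <- match(aglycone, atab$name)
    if (is.na(i)) stop("unknown aglycone: ", aglycone)
    aglycone <- atab[i, ]
  }
  residues <- residues[nzchar(residues)]
  if (length(residues) > max_residues)
    stop("residue multiset exceeds maximum of ", max_residues)
  bad <- setdiff(residues, rtab$key)
  if (length(bad)) stop("unknown residue key(s): ", paste(bad, collapse = ", "))

  residues <- .order_residues(residues, rtab)
  f <- parse_formula(aglycone$formula)
  for (k in residues) f <- formula_add(f, parse_formula(rtab$formula[rtab$key == k]))
  neutral_mass <- monoisotopic_mass(f)
  precursor_mz <- if (aglycone$is_native_cation)
    adduct_mz(neutral_mass, "M+") else adduct_mz(neutral_mass, "[M+H]+")
  cls <- classify_glyco(residues)
  if (is.null(name)) {
    name <- if (length(residues))
      paste(aglycone$name, paste(residues, collapse = "")) else aglycone$name
  }
  structure(list(
    name = name,
    aglycone = aglycone$name,
    family = aglycone$family,
    residues = residues,
    formula = f,
    formula_string = format_formula(f),
    neutral_mass = neutral_mass,
    precursor_mz = precursor_mz,
    is_native_cation = aglycone$is_native_cation,
    glyco_class = cls$glyco_class,
    acylated = cls$acylated,
    rt = rt
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s (%s, %s%s)\n  %s  M = %.4f Da  precursor m/z = %.4f\n",
              x$name, x$family, x$glyco_class,
              if (x$acylated) ", acylated" else "",
              x$formula_string, x$neutral_mass, x$precursor_mz))
  invisible(x)
}

#' Load the packaged flavonoid suspect library
#'
#' Builds the 46-entry *M. truncatula* flavonoid suspect library from
#' the packaged plain-text table: every compound is re-composed from its
#' aglycone and residue multiset, so formulas, monoisotopic masses and
#' precursor m/z are derived, not copied.  The literature-reported
#' values travel alongside as `ref_*` columns for cross-checking.
#'
#' @param path Optional path to a library TSV in the packaged dialect
#'   (see [write_library_tsv()]); default: the packaged fixture.
#' @return A `suspect_library`: list with data.frames `aglycones`,
#'   `residues` and `compounds`.
#' @examples
#' lib <- flavonoid_library()
#' table(lib$compounds$family)
#' @export
flavonoid_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "flavonoid_suspects.tsv",
                        package = "flavomics", mustWork = TRUE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "aglycone", "residues", "rt_min")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("library table lacks column(s): ",
                         paste(miss, collapse = ", "))
  recs <- lapply(seq_len(nrow(raw)), function(i) {
    res <- strsplit(raw$residues[i], ";", fixed = TRUE)[[1]]
    compose_compound(raw$aglycone[i], res, name = raw$name[i],
                     rt = as.numeric(raw$rt_min[i]))
  })
  compounds <- do.call(rbind, lapply(recs, function(r) data.frame(
    name = r$name, aglycone = r$aglycone, family = r$family,
    residues = paste(r$residues, collapse = ";"),
    formula = r$formula_string, neutral_mass = r$neutral_mass,
    precursor_mz = r$precursor_mz, is_native_cation = r$is_native_cation,
    rt = r$rt, glyco_class = r$glyco_class, acylated = r$acylated,
    n_residues = length(r$residues), stringsAsFactors = FALSE)))
  if (anyDuplicated(compounds$name))
    stop("compound names in the library must be unique")
  for (col in c("peak", "ref_mass", "ref_mz")) {
    if (col %in% names(raw)) compounds[[col]] <- as.numeric(raw[[col]])
  }
  if ("ref_ms2" %in% names(raw)) compounds$ref_ms2 <- raw$ref_ms2
  if ("formula" %in% names(raw)) compounds$ref_formula <- raw$formula
  structure(list(aglycones = flavonoid_aglycones(),
                 residues = flavonoid_residues(),
                 compounds = compounds),
            class = "suspect_library")
}

#' @export
print.suspect_library <- function(x, ...) {
  cat(sprintf("<suspect_library> %d compounds, %d aglycones, %d residues\n",
              nrow(x$compounds), nrow(x$aglycones), nrow(x$residues)))
  print(table(x$compounds$family))
  invisible(x)
}

# all residue multisets up to the configured bounds, as a data.frame of
# per-key counts (one row per multiset, including the empty one)
.residue_multisets <- function(residues = flavonoid_residues(),
                               max_residues = 4L, max_sugars = 3L,
                               max_acyls = 1L) {
  per_key <- lapply(seq_len(nrow(residues)), function(i) {
    cap <- if (residues$klass[i] == "sugar") max_sugars else max_acyls
    0:min(cap, max_residues)
  })
  names(per_key) <- residues$key
  grid <- do.call(expand.grid, per_key)
  sug <- residues$key[residues$klass == "sugar"]
  acy <- residues$key[residues$klass == "acyl"]
  keep <- rowSums(grid) <= max_residues &
    rowSums(grid[, sug, drop = FALSE]) <= max_sugars &
    rowSums(grid[, acy, drop = FALSE]) <= max_acyls
  grid[keep, , drop = FALSE]
}

.multiset_keys <- function(counts_row) {
  rep(names(counts_row), unlist(counts_row))
}

#' Decompose a precursor m/z into aglycone + residue explanations
#'
#' Exhaustively enumerates every aglycone and residue multiset (within
#' the configured bounds) whose composed precursor m/z falls within
#' `tol_ppm` of the query.  Candidates are ranked by absolute ppm error,
#' then by fewest residues, then by name, giving a deterministic order.
#'
#' @param precursor_mz Observed precursor m/z (Th), positive scalar.
#' @param lib A `suspect_library` (its aglycone and residue tables set
#'   the search space).
#' @param tol_ppm Matching tolerance in ppm (default 10, the accuracy
#'   gate of high-resolution QTOF suspect screening).
#' @param max_residues,max_sugars,max_acyls Chain bounds (defaults 4 /
#'   3 / 1: up to acylated triglycosides).
#' @return data.frame with columns `aglycone`, `residues` (";"-joined
#'   keys), `mz_theoretical`, `ppm`, `n_residues`.
#' @examples
#' lib <- flavonoid_library()
#' decompose_mass(669.1662, lib)  # contains Tricin + {Glc, GlcA}
#' @export
decompose_mass <- function(precursor_mz, lib, tol_ppm = 10,
                           max_residues = 4L, max_sugars = 3L,
                           max_acyls = 1L) {
  stopifnot(inherits(lib, "suspect_library"))
  if (!nrow(lib$aglycones)) stop("empty library")
  if (precursor_mz <= 0) stop("precursor_mz must be > 0")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  sets <- .residue_multisets(lib$residues, max_residues, max_sugars, max_acyls)
  set_mass <- as.matrix(sets) %*% lib$residues$residue_mass[
    match(colnames(sets), lib$residues$key)]
  out <- vector("list", nrow(lib$aglycones))
  for (i in seq_len(nrow(lib$aglycones))) {
    ag <- lib$aglycones[i, ]
    neutral <- ag$neutral_mass + set_mass[, 1]
    mz <- if (ag$is_native_cation) adduct_mz(neutral, "M+")
          else adduct_mz(neutral, "[M+H]+")
    ppm <- ppm_error(precursor_mz, mz)
    hit <- which(abs(ppm) <= tol_ppm)
    if (length(hit)) {
      out[[i]] <- data.frame(
        aglycone = ag$name,
        residues = vapply(hit, function(h) paste(
          .order_residues(.multiset_keys(sets[h, ]), lib$residues),
          collapse = ";"), character(1)),
        mz_theoretical = mz[hit],
        ppm = ppm[hit],
        n_residues = rowSums(sets[hit, , drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(aglycone = character(0), residues = character(0),
                      mz_theoretical = numeric(0), ppm = numeric(0),
                      n_residues = integer(0)))
  out <- out[order(abs(out$ppm), out$n_residues, out$aglycone, out$residues), ]
  rownames(out) <- NULL
  out
}

#' Assign retention-order Roman-numeral isomer indices
#'
#' Within each group of compounds sharing an identical composition
#' (same aglycone, same residue multiset), positional isomers are
#' distinguished only by elution order: Roman numerals I, II, III ... are
#' assigned by ascending retention time.  Singleton compositions get no
#' index.  Exact retention-time ties are broken by input order and
#' flagged in the `rt_tie` column.
#'
#' @param compounds The `compounds` data.frame of a `suspect_library`
#'   (columns `aglycone`, `residues`, `rt`, `name`), or any data.frame
#'   in that shape.
#' @param base_name Optional column of composition base names; default
#'   is rebuilt from aglycone + residues.
#' @return The input with `isomer_index` (Roman numeral or `NA`),
#'   `name` rewritten as `"<base> <numeral>"` for multi-member groups,
#'   and logical `rt_tie`.
#' @export
assign_isomer_indices <- function(compounds, base_name = NULL) {
  df <- compounds
  if (is.null(base_name)) {
    base_name <- ifelse(nzchar(df$residues),
                        paste(df$aglycone, gsub(";", "", df$residues)),
                        df$aglycone)
  }
  key <- paste(df$aglycone, df$residues, sep = "|")
  df$isomer_index <- NA_character_
  df$rt_tie <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    if (anyNA(df$rt[idx]))
      stop("missing retention time within isomer group: ", k)
    ord <- order(df$rt[idx])  # stable: ties keep input order
    df$rt_tie[idx] <- duplicated(df$rt[idx]) | duplicated(df$rt[idx], fromLast = TRUE)
    numerals <- as.character(utils::as.roman(seq_along(idx)))
    df$isomer_index[idx[ord]] <- numerals
    df$name[idx[ord]] <- paste(base_name[idx[ord]], numerals)
  }
  df
}

#' Write / read a suspect library compound table
#'
#' One compound per row, tab-separated plain text: `name`, `aglycone`,
#' `residues` (";"-joined keys), `formula`, `rt_min`.  The companion
#' reader re-derives all masses via [compose_compound()], so the file
#' carries composition, not numbers.
#'
#' @param lib A `suspect_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "suspect_library"))
  df <- lib$compounds[, c("name", "aglycone", "residues", "formula")]
  df$rt_min <- lib$compounds$rt
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) flavonoid_library(path)
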