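# MS1 suspect screening and MS/MS neutral-loss annotation.
#
# The CID fragmentation of flavonoid glycoconjugates is dominated by
# consecutive glycosidic-bond cleavages: the precursor loses sugar
# residues one by one down to the (protonated or native-cation)
# aglycone ion.  Acylated glycosides additionally yield fragment ions
# with the charge retained on the acylated glycan (acyl + sugar chain
# + proton).  Annotation walks these loss chains against a candidate's
# residue multiset and grades the evidence into tiers.

.tier_levels <- c("ms1_only", "partial_ms2", "full_chain")

.residue_mass_lookup <- function(lib) {
  stats::setNames(lib$residues$residue_mass, lib$residues$key)
}

# m/z of the charged aglycone ion: [aglycone+H]+ for neutral cores,
# the bare flavylium cation for anthocyanidins
.aglycone_ion_mz <- function(compound, lib) {
  ag <- lib$aglycones[match(compound$aglycone, lib$aglycones$name), ]
  if (ag$is_native_cation) adduct_mz(ag$neutral_mass, "M+")
  else adduct_mz(ag$neutral_mass, "[M+H]+")
}

.compound_row <- function(compound, lib) {
  if (is.character(compound)) {
    i <- match(compound, lib$compounds$name)
    if (is.na(i)) stop("compound not in library: ", compound)
    compound <- lib$compounds[i, ]
  }
  compound
}

.split_residues <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0)
  else strsplit(s, ";", fixed = TRUE)[[1]]
}

# distinct orderings of a residue multiset, preferred orderings first
# (sugars lost before acyl units, matching the observed fragmentation)
.residue_orderings <- function(keys, lib) {
  if (!length(keys)) return(list(character(0)))
  perm <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in unique(v)) {
      rest <- v[-match(k, v)]
      out <- c(out, lapply(perm(rest), function(p) c(k, p)))
    }
    out
  }
  ords <- perm(keys)
  kl <- stats::setNames(lib$residues$klass, lib$residues$key)
  # rank orderings: earlier acyl positions are penalised
  pen <- vapply(ords, function(o) sum(which(kl[o] == "acyl")), numeric(1))
  ords[order(-pen)]  # acyls as late as possible first
}

# expected ion ladder for one loss ordering: precursor, then the ion
# after each successive residue loss (last = aglycone ion)
.loss_ladder <- function(compound, ordering, lib) {
  rmass <- .residue_mass_lookup(lib)
  compound$precursor_mz - cumsum(c(0, rmass[ordering]))
}

# acylated-glycan diagnostic ions: acyl + non-empty sugar sub-multiset
# + proton, charge retained on the glycan (oxocarbenium-type)
.acyl_glycan_ions <- function(compound, lib) {
  keys <- .split_residues(compound$residues)
  kl <- stats::setNames(lib$residues$klass, lib$residues$key)
  rmass <- .residue_mass_lookup(lib)
  acyls <- keys[kl[keys] == "acyl"]
  sugars <- keys[kl[keys] == "sugar"]
  if (!length(acyls) || !length(sugars))
    return(data.frame(role = character(0), label = character(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  subs <- unique(unlist(lapply(seq_along(sugars), function(n)
    utils::combn(sugars, n, simplify = FALSE)), recursive = FALSE))
  subs <- subs[!duplicated(vapply(subs, function(s)
    paste(sort(s), collapse = ";"), ""))]
  rows <- list()
  for (a in unique(acyls)) for (s in subs) {
    rows[[length(rows) + 1L]] <- data.frame(
      role = "acyl_glycan",
      label = paste0(a, paste(sort(s), collapse = "")),
      mz = rmass[[a]] + sum(rmass[s]) + .proton_mass,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# every fragment ion the model predicts for a compound: the precursor
# minus every sub-multiset of residues (covers all loss-chain
# intermediates of every ordering, ending at the aglycone ion) plus the
# acylated-glycan diagnostics.  Used by the spectrum generator.
.all_fragment_ions <- function(compound, lib) {
  keys <- .split_residues(compound$residues)
  if (!length(keys))  # free aglycone: the molecular ion is the aglycone ion
    return(data.frame(role = "aglycone", label = "",
                      mz = compound$precursor_mz, stringsAsFactors = FALSE))
  rmass <- .residue_mass_lookup(lib)
  cnt <- table(keys)
  grid <- do.call(expand.grid, lapply(cnt, function(n) 0:n))
  loss <- as.matrix(grid) %*% rmass[names(cnt)]
  ions <- data.frame(
    role = ifelse(rowSums(grid) == 0, "precursor",
                  ifelse(rowSums(grid) == length(keys), "aglycone", "loss")),
    label = apply(grid, 1, function(r)
      paste(rep(names(cnt), r), collapse = "")),
    mz = compound$precursor_mz - as.numeric(loss),
    stringsAsFactors = FALSE)
  rbind(ions, .acyl_glycan_ions(compound, lib))
}

#' Screen MS1 features against a suspect library
#'
#' Accurate-mass matching of feature precursor m/z against every library
#' compound within a ppm tolerance.  The retention-time window, when
#' given, is a hard co-elution gate; by default RT is not gated (it is
#' used later, advisorily, to rank positional isomers).
#'
#' @param spectra Spectra data.frame (see [spectra_table()]).
#' @param lib A `suspect_library`.
#' @param tol_ppm MS1 tolerance in ppm (default 10).
#' @param rt_window Optional window in minutes; candidates whose library
#'   RT differs more are dropped (features or compounds without RT pass).
#' @return data.frame with `feature_id`, `compound`, `ppm`, `rt_diff`.
#' @export
screen_ms1 <- function(spectra, lib, tol_ppm = 10, rt_window = NULL) {
  stopifnot(inherits(lib, "suspect_library"))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (!nrow(spectra))
    return(data.frame(feature_id = character(0), compound = character(0),
                      ppm = numeric(0), rt_diff = numeric(0)))
  ppm <- outer(spectra$precursor_mz, lib$compounds$precursor_mz,
               function(o, t) 1e6 * (o - t) / t)
  hit <- which(abs(ppm) <= tol_ppm, arr.ind = TRUE)
  out <- data.frame(
    feature_id = spectra$feature_id[hit[, 1]],
    compound = lib$compounds$name[hit[, 2]],
    ppm = ppm[hit],
    rt_diff = spectra$rt[hit[, 1]] - lib$compounds$rt[hit[, 2]],
    stringsAsFactors = FALSE)
  if (!is.null(rt_window))
    out <- out[is.na(out$rt_diff) | abs(out$rt_diff) <= rt_window, ]
  rownames(out) <- NULL
  out
}

#' Annotate one MS/MS spectrum against one candidate compound
#'
#' Scores every distinct ordering of the candidate's residue multiset as
#' a consecutive neutral-loss chain from the precursor; the
#' best-supported ordering (most intermediate ions observed within
#' `frag_tol_mda`) is reported, ties resolved toward orderings that lose
#' sugars before acyl-glycan units.  The aglycone ion and acylated-
#' glycan fragment ions are checked as diagnostic ions.  Tiers:
#' `full_chain` when the loss chain reaches an observed aglycone ion,
#' `partial_ms2` when some chain or diagnostic ion matched,
#' `ms1_only` otherwise (including spectra without MS/MS peaks).
#'
#' @param spectrum One-row spectra data.frame (or a list with
#'   `feature_id`, `precursor_mz`, `rt`, `ms2`).
#' @param compound Library compound name or one row of
#'   `lib$compounds`.
#' @param lib A `suspect_library`.
#' @param frag_tol_mda Fragment tolerance in mDa (default 5; printed
#'   product ions of this compound class deviate from theory by
#'   <= 2 mDa, and 5 mDa still separates the Fer/GlcA isobars).
#' @return An `annotation_result` list: `feature_id`, `compound`,
#'   `family`, `glyco_class`, `acylated`, `ms1_ppm`, `rt_diff`, `tier`,
#'   `matched_losses` (data.frame), `matched_diagnostics` (data.frame).
#' @export
annotate_msms <- function(spectrum, compound, lib, frag_tol_mda = 5) {
  compound <- .compound_row(compound, lib)
  if (is.data.frame(spectrum)) {
    stopifnot(nrow(spectrum) == 1L)
    spectrum <- list(feature_id = spectrum$feature_id,
                     precursor_mz = spectrum$precursor_mz,
                     rt = spectrum$rt, ms2 = spectrum$ms2[[1]])
  }
  tol <- frag_tol_mda / 1000
  peaks <- spectrum$ms2
  obs <- if (!is.null(peaks) && nrow(peaks)) peaks[, "mz"] else numeric(0)
  match_mz <- function(expected) {
    if (!length(obs)) return(NA_real_)
    d <- abs(obs - expected)
    if (min(d) <= tol) obs[which.min(d)] else NA_real_
  }

  keys <- .split_residues(compound$residues)
  best <- NULL
  for (ord in .residue_orderings(keys, lib)) {
    ladder <- .loss_ladder(compound, ord, lib)  # [1] = precursor
    hits <- vapply(ladder[-1], match_mz, numeric(1))
    score <- sum(!is.na(hits))
    if (is.null(best) || score > best$score)
      best <- list(ordering = ord, ladder = ladder, hits = hits, score = score)
    if (!is.null(best) && best$score == length(keys)) break
  }

  # losses between consecutive observed rungs (unobserved intermediates
  # are folded into a single merged loss)
  matched_losses <- data.frame(
    residues = character(0), from_mz = numeric(0), to_mz = numeric(0),
    observed_loss = numeric(0), expected_loss = numeric(0),
    mda_error = numeric(0), stringsAsFactors = FALSE)
  if (length(keys) && best$score > 0) {
    rung_obs <- c(spectrum$precursor_mz, best$hits)
    rung_exp <- best$ladder
    seen <- which(!is.na(rung_obs))
    for (j in seq_along(seen)[-1]) {
      a <- seen[j - 1]; b <- seen[j]
      matched_losses <- rbind(matched_losses, data.frame(
        residues = paste(best$ordering[a:(b - 1)], collapse = "+"),
        from_mz = rung_obs[a], to_mz = rung_obs[b],
        observed_loss = rung_obs[a] - rung_obs[b],
        expected_loss = rung_exp[a] - rung_exp[b],
        mda_error = 1000 * ((rung_obs[a] - rung_obs[b]) -
                              (rung_exp[a] - rung_exp[b])),
        stringsAsFactors = FALSE))
    }
  }

  agly_mz <- .aglycone_ion_mz(compound, lib)
  diag <- rbind(
    data.frame(role = "aglycone", label = compound$aglycone, mz = agly_mz,
               stringsAsFactors = FALSE),
    .acyl_glycan_ions(compound, lib))
  diag$observed_mz <- vapply(diag$mz, match_mz, numeric(1))
  matched_diag <- diag[!is.na(diag$observed_mz), , drop = FALSE]
  names(matched_diag)[names(matched_diag) == "mz"] <- "expected_mz"
  rownames(matched_diag) <- NULL

  aglycone_seen <- any(matched_diag$role == "aglycone")
  tier <- if (aglycone_seen) "full_chain"
          else if (best$score > 0 || nrow(matched_diag)) "partial_ms2"
          else "ms1_only"

  structure(list(
    feature_id = spectrum$feature_id,
    compound = compound$name,
    family = compound$family,
    glyco_class = compound$glyco_class,
    acylated = compound$acylated,
    ms1_ppm = ppm_error(spectrum$precursor_mz, compound$precursor_mz),
    rt_diff = spectrum$rt - compound$rt,
    tier = tier,
    n_matched_losses = if (length(keys)) best$score else 0L,
    matched_losses = matched_losses,
    matched_diagnostics = matched_diag
  ), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s -> %s [%s]  ms1 %+.2f ppm, %d loss ions\n",
              x$feature_id, x$compound, x$tier, x$ms1_ppm, x$n_matched_losses))
  invisible(x)
}

#' Annotate a whole feature set against the suspect library
#'
#' Runs [screen_ms1()] then [annotate_msms()] for every candidate and
#' keeps the best annotation per feature: highest tier, then lowest
#' absolute MS1 ppm error, then smallest retention-time difference to
#' the library entry (this is what separates positional isomers), then
#' fewest residues, then name.  One feature maps to at most one
#' compound; remaining candidates are kept as a runner-up list.
#'
#' @param spectra Spectra data.frame.
#' @param lib A `suspect_library`.
#' @param ms1_tol_ppm MS1 gate in ppm (default 10).
#' @param frag_tol_mda Fragment tolerance in mDa (default 5).
#' @param rt_window Optional hard RT gate in minutes (default none; RT
#'   stays advisory).
#' @return An `annotation_table`: list with `annotations` (one row per
#'   annotated feature), `unannotated` (feature ids), and `census`
#'   (distinct-compound counts by family and by glycosylation class).
#' @examples
#' lib <- flavonoid_library()
#' sp <- generate_spectra(lib, ppm_jitter = 0, frag_dropout = 0, seed = 1)
#' ann <- annotate_dataset(sp, lib)
#' ann$census$family
#' @export
annotate_dataset <- function(spectra, lib, ms1_tol_ppm = 10,
                             frag_tol_mda = 5, rt_window = NULL) {
  cand <- screen_ms1(spectra, lib, tol_ppm = ms1_tol_ppm,
                     rt_window = rt_window)
  rows <- list()
  for (fid in unique(spectra$feature_id)) {
    ci <- which(cand$feature_id == fid)
    if (!length(ci)) next
    sp <- spectra[match(fid, spectra$feature_id), ]
    anns <- lapply(ci, function(i)
      annotate_msms(sp, cand$compound[i], lib, frag_tol_mda))
    tier <- match(vapply(anns, `[[`, "", "tier"), .tier_levels)
    nres <- lib$compounds$n_residues[
      match(vapply(anns, `[[`, "", "compound"), lib$compounds$name)]
    rtd <- vapply(anns, function(a) abs(a$rt_diff), numeric(1))
    rtd[is.na(rtd)] <- Inf
    ord <- order(-tier, abs(vapply(anns, `[[`, 0, "ms1_ppm")), rtd, nres,
                 vapply(anns, `[[`, "", "compound"))
    best <- anns[[ord[1]]]
    runner <- vapply(anns[ord[-1]], `[[`, "", "compound")
    rows[[fid]] <- data.frame(
      feature_id = fid, compound = best$compound, family = best$family,
      glyco_class = best$glyco_class, acylated = best$acylated,
      ms1_ppm = best$ms1_ppm, rt_diff = best$rt_diff, tier = best$tier,
      n_matched_losses = best$n_matched_losses,
      matched_losses = paste(best$matched_losses$residues, collapse = ";"),
      runner_up = paste(runner, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  annotations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), compound = character(0),
               family = character(0), glyco_class = character(0),
               acylated = logical(0), ms1_ppm = numeric(0),
               rt_diff = numeric(0), tier = character(0),
               n_matched_losses = integer(0), matched_losses = character(0),
               runner_up = character(0), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  distinct <- !duplicated(annotations$compound)
  census <- list(
    n_compounds = sum(distinct),
    family = table(factor(annotations$family[distinct],
                          levels = sort(unique(lib$compounds$family)))),
    glyco_class = table(factor(annotations$glyco_class[distinct],
                               levels = c("Agly", "Gly", "GlyGly", "GlyGlyGly"))),
    acylated = sum(annotations$acylated[distinct]))
  structure(list(
    annotations = annotations,
    unannotated = setdiff(spectra$feature_id, annotations$feature_id),
    census = census), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d features annotated (%d distinct compounds), %d unannotated\n",
              nrow(x$annotations), x$census$n_compounds, length(x$unannotated)))
  print(x$census$family)
  invisible(x)
}

#' Write an annotation table as TSV
#'
#' @param ann An `annotation_table` from [annotate_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_table"))
  utils::write.table(ann$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
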