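# In-silico spectra and intensity matrices with the statistical
# structure of the study design: 4 cultivars (three Hg-tolerant, one
# sensitive) x 2 tissues x 2 treatments x 3 biological replicates x 3
# analytical injections, log-normal intensities, tissue-specific family
# composition, and per-compound Hg effect sizes.

#' Build the factorial study design
#'
#' @param cultivars Cultivar labels; the default order is from most to
#'   least Hg-tolerant (three tolerant lines and one sensitive).
#' @param tissues,treatments Factor levels.
#' @param bio_reps Biological replicates per arm (default 3).
#' @param injections Analytical injections per biological replicate
#'   (default 3).
#' @return data.frame with one row per injection-level sample:
#'   `sample_id`, `cultivar`, `tissue`, `treatment`, `replicate`,
#'   `injection`.
#' @examples
#' nrow(study_design())  # 4 * 2 * 2 * 3 * 3 = 144
#' @export
study_design <- function(cultivars = c("LR1", "LR2", "LR3", "LR4"),
                         tissues = c("leaf", "root"),
                         treatments = c("control", "Hg"),
                         bio_reps = 3L, injections = 3L) {
  stopifnot(bio_reps >= 1, injections >= 1,
            length(cultivars) >= 1, length(tissues) >= 1,
            length(treatments) >= 1)
  d <- expand.grid(injection = seq_len(injections),
                   replicate = seq_len(bio_reps),
                   treatment = treatments, tissue = tissues,
                   cultivar = cultivars,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("cultivar", "tissue", "treatment", "replicate", "injection")]
  d$sample_id <- sprintf("%s_%s_%s_r%d_i%d", d$cultivar,
                         substr(d$tissue, 1, 1), d$treatment,
                         d$replicate, d$injection)
  d
}

# Hg-stress effects (log2 fold change, treated vs control) of the
# differential preset, per compound x tissue x cultivar
.hg_effect_preset <- function() {
  tab <- c(
    "Afrormosin MalGlc|leaf|LR2|1.4",
    "Biochanin A MalGlc I|leaf|LR2|0.5",
    "Biochanin A MalGlc II|leaf|LR1|2.1",
    "Daidzein|leaf|LR1|2.6", "Daidzein|leaf|LR2|1.9",
    "Formononetin|leaf|LR3|2.1",
    "Formononetin Glc II|leaf|LR1|1.4", "Formononetin Glc II|leaf|LR2|2.4",
    "Formononetin MalGlc|leaf|LR1|1.4", "Formononetin MalGlc|leaf|LR2|3.3",
    "Irisolidone isomer|leaf|LR1|1.6", "Irisolidone isomer|leaf|LR3|1.6",
    "Medicarpin MalGlc II|leaf|LR1|2.6", "Medicarpin MalGlc II|leaf|LR3|2.4",
    "Medicarpin MalGlc II|leaf|LR4|4.1",
    "Peonidin Glc I|leaf|LR1|2.9", "Peonidin Glc I|leaf|LR3|1.8",
    "Peonidin Glc I|leaf|LR4|1.6",
    "Tricin FerGlcAGlcA III|leaf|LR1|2.2",
    "Afrormosin|root|LR2|3.3", "Afrormosin|root|LR4|2.3",
    "Afrormosin Glc I|root|LR4|3.3",
    "Afrormosin MalGlc|root|LR2|1.6",
    "Apigenin GlcAGlcA|root|LR1|2.4",
    "Apigenin FerGlcAGlcAGlcA I|root|LR2|3.7",
    "Apigenin FerGlcAGlcAGlcA I|root|LR3|1.6",
    "Apigenin CouGlcAGlcAGlcA I|root|LR2|3.6",
    "Apigenin CouGlcAGlcAGlcA I|root|LR3|3.8",
    "Apigenin FerGlcAGlcAGlcA II|root|LR4|2.1",
    "Biochanin A MalGlc I|root|LR2|2.7", "Biochanin A MalGlc I|root|LR3|2.2",
    "Biochanin A MalGlc I|root|LR4|2.2",
    "Biochanin A MalGlc II|root|LR2|1.7", "Biochanin A MalGlc II|root|LR3|2.1",
    "Biochanin A MalGlc II|root|LR4|1.8",
    "Biochanin A|root|LR2|1.3", "Biochanin A|root|LR3|1.4",
    "Biochanin A|root|LR4|1.9",
    "Daidzein|root|LR2|3.4", "Daidzein|root|LR3|1.6", "Daidzein|root|LR4|2.3",
    "Formononetin|root|LR3|1.6", "Formononetin|root|LR4|1.8",
    "Formononetin Glc II|root|LR3|2.3", "Formononetin Glc II|root|LR4|2.6",
    "Formononetin MalGlc|root|LR2|2.4", "Formononetin MalGlc|root|LR3|2.5",
    "Formononetin MalGlc|root|LR4|1.8",
    "Irisolidone|root|LR2|1.6", "Irisolidone|root|LR3|3.7",
    "Irisolidone|root|LR4|2.9",
    "Irisolidone isomer|root|LR2|1.6", "Irisolidone isomer|root|LR4|1.3",
    "Medicarpin MalGlc I|root|LR2|2.5", "Medicarpin MalGlc I|root|LR3|2.4",
    "Medicarpin MalGlc I|root|LR4|1.9",
    "Medicarpin MalGlc II|root|LR2|1.5",
    "Tricin GlcAGlcA|root|LR2|3.3", "Tricin GlcAGlcA|root|LR4|1.4",
    "Tricin Glc I|root|LR3|3.1",
    "Tricin FerGlcAGlcA I|root|LR2|3.1",
    "Tricin CouGlcAGlcA I|root|LR1|3.1", "Tricin CouGlcAGlcA I|root|LR2|4.8")
  f <- do.call(rbind, strsplit(tab, "|", fixed = TRUE))
  data.frame(compound = f[, 1], tissue = f[, 2], cultivar = f[, 3],
             log2fc = as.numeric(f[, 4]), stringsAsFactors = FALSE)
}

#' Construct the simulation ground truth
#'
#' Baselines are built by inversion of the composition formulas so the
#' noise-free matrix reproduces the stated tissue structure exactly:
#' per tissue, each flavonoid family receives its target share of the
#' total signal (free aglycones, which all belong to the isoflavone
#' family in the packaged library, receive the aglycone share within
#' the isoflavone budget), equally split within group, and per-cultivar
#' leaf totals are the configured multiple of the root total.
#'
#' Scenarios: `"null"` (all Hg effects zero) and `"hg"` (the
#' differential preset: nonzero log2 fold changes exactly for the
#' compound x tissue x cultivar cells of the reported differential set,
#' signs as reported).
#'
#' @param lib A `suspect_library`.
#' @param cultivars Cultivar labels (must cover the effect preset's
#'   cultivars when `scenario = "hg"`).
#' @param scenario `"null"` or `"hg"`.
#' @param family_shares Named list with `leaf` and `root` named vectors
#'   of family signal fractions (each summing to 1).
#' @param agly_share Named vector, fraction of total tissue signal
#'   carried by free aglycones (`leaf` 0.02, `root` 0.5 by default).
#' @param leaf_root_ratio Named per-cultivar ratio of total leaf to
#'   total root signal (defaults 4.6, 7.0, 7.2, 16.0 for LR1..LR4).
#' @param root_total Arbitrary linear-intensity total per root sample.
#' @param bio_sd,tech_sd Biological / technical SD on the log2 scale
#'   (defaults 0.5 and 0.15).
#' @return A `simulation_truth` list: `grid` (compound x tissue x
#'   cultivar with `baseline_log2` and `effect_log2fc`), `bio_sd`,
#'   `tech_sd`, plus the composition targets used.
#' @export
simulation_truth <- function(lib,
                             cultivars = c("LR1", "LR2", "LR3", "LR4"),
                             scenario = c("null", "hg"),
                             family_shares = list(
                               leaf = c(flavone = 0.85, anthocyanidin = 0.06,
                                        isoflavone = 0.05, pterocarpan = 0.02,
                                        flavanone = 0.02),
                               root = c(isoflavone = 0.82, flavone = 0.09,
                                        pterocarpan = 0.05,
                                        anthocyanidin = 0.02,
                                        flavanone = 0.02)),
                             agly_share = c(leaf = 0.02, root = 0.5),
                             leaf_root_ratio = c(LR1 = 4.6, LR2 = 7.0,
                                                 LR3 = 7.2, LR4 = 16.0),
                             root_total = 1e6,
                             bio_sd = 0.5, tech_sd = 0.15) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(lib, "suspect_library"), bio_sd >= 0, tech_sd >= 0)
  cmp <- lib$compounds
  for (t in c("leaf", "root")) {
    sh <- family_shares[[t]]
    if (abs(sum(sh) - 1) > 1e-9)
      stop("family shares for ", t, " must sum to 1")
    if (!all(sort(names(sh)) == sort(unique(cmp$family))))
      stop("family shares must cover exactly the library families")
    if (agly_share[[t]] > sh[["isoflavone"]])
      stop("aglycone share cannot exceed the isoflavone family share")
  }
  if (!all(cmp$family[cmp$glyco_class == "Agly"] == "isoflavone"))
    stop("baseline inversion assumes all free aglycones are isoflavones")

  grid <- expand.grid(compound = cmp$name, tissue = c("leaf", "root"),
                      cultivar = cultivars, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  fam <- cmp$family[match(grid$compound, cmp$name)]
  agly <- cmp$glyco_class[match(grid$compound, cmp$name)] == "Agly"
  n_agly <- sum(cmp$glyco_class == "Agly")
  n_iso_conj <- sum(cmp$family == "isoflavone" & cmp$glyco_class != "Agly")
  grid$baseline_log2 <- NA_real_
  for (cv in cultivars) for (t in c("leaf", "root")) {
    total <- if (t == "root") root_total else {
      r <- leaf_root_ratio[[cv]]
      if (is.null(r) || is.na(r)) stop("no leaf/root ratio for ", cv)
      r * root_total
    }
    sh <- family_shares[[t]]
    sel <- grid$cultivar == cv & grid$tissue == t
    base <- numeric(sum(sel))
    fam_s <- fam[sel]; agly_s <- agly[sel]
    for (f in names(sh)) {
      if (f == "isoflavone") {
        base[agly_s] <- agly_share[[t]] * total / n_agly
        base[fam_s == f & !agly_s] <-
          (sh[[f]] - agly_share[[t]]) * total / n_iso_conj
      } else {
        base[fam_s == f] <- sh[[f]] * total / sum(fam_s == f)
      }
    }
    grid$baseline_log2[sel] <- log2(base)
  }

  grid$effect_log2fc <- 0
  if (scenario == "hg") {
    eff <- .hg_effect_preset()
    if (!all(eff$compound %in% cmp$name))
      stop("effect preset names a compound outside the library")
    key <- paste(grid$compound, grid$tissue, grid$cultivar, sep = "|")
    ekey <- paste(eff$compound, eff$tissue, eff$cultivar, sep = "|")
    hit <- match(ekey, key)
    if (anyNA(hit)) stop("effect preset cell outside the design grid")
    grid$effect_log2fc[hit] <- eff$log2fc
  }
  structure(list(grid = grid, scenario = scenario, bio_sd = bio_sd,
                 tech_sd = tech_sd, family_shares = family_shares,
                 agly_share = agly_share, leaf_root_ratio = leaf_root_ratio,
                 root_total = root_total),
            class = "simulation_truth")
}

#' Serialize the simulation ground truth
#'
#' @param truth A `simulation_truth`.
#' @return Its `grid` data.frame (compound x tissue x cultivar with
#'   `baseline_log2`, `effect_log2fc`), for parameter-recovery tests.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  truth$grid
}

#' @rdname truth_report
#' @param path CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth_report(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_report
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate a sample x compound intensity matrix
#'
#' Log2 intensity = baseline + Hg effect (treated samples only) +
#' biological noise (one draw per compound and biological replicate) +
#' technical noise (one draw per injection), then exponentiated to the
#' linear scale — the standard log-normal LC-MS intensity model.
#'
#' @param design A [study_design()] data.frame.
#' @param truth A [simulation_truth()].
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return An `intensity_matrix`: list with `values` (samples x
#'   compounds, linear scale) and `meta` (the design).
#' @export
generate_intensities <- function(design, truth, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(seed)
  grid <- truth$grid
  compounds <- unique(grid$compound)
  need <- unique(paste(design$tissue, design$cultivar, sep = "|"))
  have <- unique(paste(grid$tissue, grid$cultivar, sep = "|"))
  if (!all(need %in% have))
    stop("truth grid does not cover the design (tissue x cultivar)")

  key <- paste(grid$compound, grid$tissue, grid$cultivar, sep = "|")
  bio_unit <- unique(design[, c("cultivar", "tissue", "treatment", "replicate")])
  bio_id <- do.call(paste, c(bio_unit, sep = "|"))
  bio_noise <- matrix(stats::rnorm(nrow(bio_unit) * length(compounds),
                                   0, truth$bio_sd),
                      nrow = nrow(bio_unit),
                      dimnames = list(bio_id, compounds))
  vals <- matrix(NA_real_, nrow(design), length(compounds),
                 dimnames = list(design$sample_id, compounds))
  for (i in seq_len(nrow(design))) {
    s <- design[i, ]
    cell <- match(paste(compounds, s$tissue, s$cultivar, sep = "|"), key)
    mu <- grid$baseline_log2[cell] +
      if (s$treatment == "Hg") grid$effect_log2fc[cell] else 0
    b <- bio_noise[paste(s$cultivar, s$tissue, s$treatment, s$replicate,
                         sep = "|"), ]
    tech <- stats::rnorm(length(compounds), 0, truth$tech_sd)
    vals[i, ] <- 2 ^ (mu + b + tech)
  }
  structure(list(values = vals, meta = design), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d samples x %d compounds\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Average analytical injections within biological replicates
#'
#' Collapses injection-level samples to one (linear-scale mean) row per
#' biological replicate, the default unit for the statistics layer:
#' treating injections as independent replicates would inflate
#' significance.
#'
#' @param im An `intensity_matrix`.
#' @return An `intensity_matrix` with one row per biological replicate.
#' @export
average_injections <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  meta <- im$meta
  unit <- paste(meta$cultivar, meta$tissue, meta$treatment, meta$replicate,
                sep = "|")
  keep <- !duplicated(unit)
  sums <- rowsum(im$values, unit)
  counts <- table(unit)
  vals <- sums / as.vector(counts[rownames(sums)])
  vals <- vals[unit[keep], , drop = FALSE]
  meta2 <- meta[keep, setdiff(names(meta), "injection"), drop = FALSE]
  meta2$sample_id <- sub("_i[0-9]+$", "", meta2$sample_id)
  rownames(vals) <- meta2$sample_id
  structure(list(values = vals, meta = meta2), class = "intensity_matrix")
}

#' Generate noise-controlled synthetic spectra for a library
#'
#' One spectrum per library compound: the precursor at its theoretical
#' m/z perturbed by `Normal(0, ppm_jitter)` ppm, and MS/MS peaks at
#' every loss-chain intermediate, the aglycone ion and the
#' acylated-glycan diagnostic ions (same jitter), each independently
#' dropped with probability `frag_dropout`.  Retention times are copied
#' from the library.
#'
#' @param lib A `suspect_library`.
#' @param ppm_jitter Gaussian m/z jitter in ppm (default 0).
#' @param frag_dropout Per-fragment dropout probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A spectra data.frame (see [spectra_table()]).
#' @examples
#' sp <- generate_spectra(flavonoid_library(), seed = 1)
#' @export
generate_spectra <- function(lib, ppm_jitter = 0, frag_dropout = 0,
                             seed = NULL) {
  stopifnot(inherits(lib, "suspect_library"),
            ppm_jitter >= 0, frag_dropout >= 0, frag_dropout < 1)
  if (!is.null(seed)) set.seed(seed)
  cmp <- lib$compounds
  jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_jitter) * 1e-6)
  ms2 <- vector("list", nrow(cmp))
  pmz <- numeric(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    ions <- .all_fragment_ions(cmp[i, ], lib)
    keep <- stats::runif(nrow(ions)) >= frag_dropout
    ions <- ions[keep, , drop = FALSE]
    inten <- c(precursor = 300, loss = 600, aglycone = 1000,
               acyl_glycan = 400)[ions$role]
    ms2[[i]] <- cbind(mz = jit(ions$mz), intensity = unname(inten))
    pmz[i] <- jit(cmp$precursor_mz[i])
  }
  spectra_table(sprintf("F%02d", seq_len(nrow(cmp))), pmz, cmp$rt, ms2)
}
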