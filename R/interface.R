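# Pipeline entry points: a declarative config object and the three
# stages (simulate, annotate, stats) wired into reproducible runs that
# write plain-text artifacts plus a resolved-config copy.

#' Build and validate a pipeline configuration
#'
#' @param library_path `"packaged"` (default) or a path to a library
#'   TSV in the [write_library_tsv()] dialect.
#' @param spectra_path Input peak-list file for the annotate stage.
#' @param spectra_format `"auto"`, `"mgf"`, `"csv"` or `"mzml"`.
#' @param intensity_path,metadata_path Intensity matrix CSV (samples x
#'   compounds, first column sample ids) and sample metadata CSV for
#'   the stats stage.
#' @param ms1_tol_ppm,frag_tol_mda Annotation tolerances (10 ppm,
#'   5 mDa).
#' @param p_cut,fc_up,fc_down Differential thresholds (0.05, 2.5, 0.4).
#' @param var_equal,average_injections,fdr Stats options.
#' @param scenario Simulation scenario (`"null"` or `"hg"`).
#' @param ppm_jitter,frag_dropout Simulated spectra noise.
#' @param seed Integer seed recorded in every output header.
#' @param outdir Output directory (created if needed).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(library_path = "packaged",
                            spectra_path = NULL, spectra_format = "auto",
                            intensity_path = NULL, metadata_path = NULL,
                            ms1_tol_ppm = 10, frag_tol_mda = 5,
                            p_cut = 0.05, fc_up = 2.5, fc_down = 0.4,
                            var_equal = FALSE, average_injections = TRUE,
                            fdr = FALSE, scenario = "null",
                            ppm_jitter = 0, frag_dropout = 0,
                            seed = 1L, outdir = tempfile("flavomics_run_")) {
  cfg <- list(library_path = library_path, spectra_path = spectra_path,
              spectra_format = spectra_format,
              intensity_path = intensity_path, metadata_path = metadata_path,
              ms1_tol_ppm = ms1_tol_ppm, frag_tol_mda = frag_tol_mda,
              p_cut = p_cut, fc_up = fc_up, fc_down = fc_down,
              var_equal = var_equal, average_injections = average_injections,
              fdr = fdr, scenario = scenario, ppm_jitter = ppm_jitter,
              frag_dropout = frag_dropout, seed = as.integer(seed),
              outdir = outdir)
  for (nm in c("ms1_tol_ppm", "frag_tol_mda", "p_cut", "fc_up", "fc_down"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive number")
  if (!cfg$scenario %in% c("null", "hg"))
    stop("unknown simulation scenario: ", cfg$scenario)
  if (cfg$ppm_jitter < 0 || cfg$frag_dropout < 0 || cfg$frag_dropout >= 1)
    stop("ppm_jitter must be >= 0 and frag_dropout in [0, 1)")
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

.load_library <- function(cfg) {
  if (identical(cfg$library_path, "packaged")) flavonoid_library()
  else flavonoid_library(cfg$library_path)
}

.write_stamped <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flavomics seed=%d config=%s", cfg$seed,
                     .config_hash(cfg)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_stamped <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

.prepare_outdir <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  resolved <- file.path(cfg$outdir, "config_resolved.txt")
  writeLines(c(sprintf("# flavomics resolved config (hash %s)",
                       .config_hash(cfg)),
               paste(names(cfg), vapply(cfg, function(v)
                 paste(format(v), collapse = ","), ""), sep = " = ")),
             resolved)
  invisible(cfg$outdir)
}

#' Run the simulation stage
#'
#' Emits a synthetic dataset bundle: spectra (MGF + CSV dialect),
#' injection-level intensity matrix, sample metadata and the ground
#' truth, all deterministic under the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of written file paths, invisibly; the generated
#'   objects as attributes `"spectra"`, `"intensities"`, `"truth"`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  .prepare_outdir(cfg)
  lib <- .load_library(cfg)
  design <- study_design()
  truth <- simulation_truth(lib, scenario = cfg$scenario)
  sp <- generate_spectra(lib, cfg$ppm_jitter, cfg$frag_dropout,
                         seed = cfg$seed)
  im <- generate_intensities(design, truth, seed = cfg$seed + 1L)
  paths <- list(
    spectra_mgf = file.path(cfg$outdir, "spectra.mgf"),
    spectra_csv = file.path(cfg$outdir, "spectra.csv"),
    intensities = file.path(cfg$outdir, "intensities.csv"),
    metadata = file.path(cfg$outdir, "sample_metadata.csv"),
    truth = file.path(cfg$outdir, "truth.csv"))
  write_mgf(sp, paths$spectra_mgf)
  write_peaklist_csv(sp, paths$spectra_csv)
  utils::write.csv(data.frame(sample_id = rownames(im$values),
                              im$values, check.names = FALSE),
                   paths$intensities, row.names = FALSE)
  utils::write.csv(im$meta, paths$metadata, row.names = FALSE)
  write_truth_csv(truth, paths$truth)
  out <- paths
  attr(out, "spectra") <- sp
  attr(out, "intensities") <- im
  attr(out, "truth") <- truth
  invisible(out)
}

#' Run the annotation stage
#'
#' Reads the configured peak lists, annotates against the library and
#' writes the annotation table, the family / glycosylation census and a
#' run log with tolerances.
#'
#' @param cfg A [pipeline_config()] with `spectra_path` set.
#' @return The `annotation_table`, invisibly; files under
#'   `cfg$outdir`.
#' @export
run_annotate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$spectra_path))
    stop("config field 'spectra_path' is required for the annotate stage")
  if (!file.exists(cfg$spectra_path))
    stop("spectra input not found: ", cfg$spectra_path)
  .prepare_outdir(cfg)
  lib <- .load_library(cfg)
  sp <- read_peaklists(cfg$spectra_path, cfg$spectra_format)
  ann <- annotate_dataset(sp, lib, ms1_tol_ppm = cfg$ms1_tol_ppm,
                          frag_tol_mda = cfg$frag_tol_mda)
  .write_stamped(ann$annotations,
                 file.path(cfg$outdir, "annotations.tsv"), cfg)
  census <- rbind(
    data.frame(kind = "family", level = names(ann$census$family),
               n = as.vector(ann$census$family)),
    data.frame(kind = "glyco_class", level = names(ann$census$glyco_class),
               n = as.vector(ann$census$glyco_class)))
  .write_stamped(census, file.path(cfg$outdir, "census.tsv"), cfg)
  writeLines(c(sprintf("# flavomics annotate log (seed %d)", cfg$seed),
               sprintf("ms1_tol_ppm = %g", cfg$ms1_tol_ppm),
               sprintf("frag_tol_mda = %g", cfg$frag_tol_mda),
               sprintf("library = %s (%d compounds)", cfg$library_path,
                       nrow(lib$compounds)),
               sprintf("features = %d, annotated = %d, unannotated = %d",
                       nrow(sp), nrow(ann$annotations),
                       length(ann$unannotated))),
             file.path(cfg$outdir, "annotate.log"))
  invisible(ann)
}

#' Run the statistics stage
#'
#' Loads the intensity matrix and metadata, then writes per tissue x
#' cultivar differential tables, family and glycosylation profiles,
#' PCA scores/loadings, sample dendrograms in Newick form, and simple
#' heatmap / score-plot images.
#'
#' @param cfg A [pipeline_config()] with `intensity_path` and
#'   `metadata_path` set.
#' @return Named list of result objects, invisibly.
#' @export
run_stats <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$intensity_path) || is.null(cfg$metadata_path))
    stop("config fields 'intensity_path' and 'metadata_path' are required")
  for (p in c(cfg$intensity_path, cfg$metadata_path))
    if (!file.exists(p)) stop("stats input not found: ", p)
  .prepare_outdir(cfg)
  lib <- .load_library(cfg)
  vals <- utils::read.csv(cfg$intensity_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(cfg$metadata_path, stringsAsFactors = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals[[1]]
  im <- structure(list(values = m, meta = meta), class = "intensity_matrix")

  fam <- family_relative_abundance(im, lib)
  gly <- glyco_profile(im, lib)
  lr <- tryCatch(leaf_root_ratio(im), error = function(e) NULL)
  .write_stamped(fam, file.path(cfg$outdir, "family_profile.tsv"), cfg)
  .write_stamped(gly, file.path(cfg$outdir, "glyco_profile.tsv"), cfg)
  if (!is.null(lr))
    .write_stamped(data.frame(cultivar = names(lr), ratio = lr),
                   file.path(cfg$outdir, "leaf_root_ratio.tsv"), cfg)

  diffs <- list()
  for (t in unique(meta$tissue)) for (cv in unique(meta$cultivar)) {
    if (!any(meta$tissue == t & meta$cultivar == cv &
               meta$treatment != "control")) next
    d <- differential_test(im, t, cv,
                           average_injections = cfg$average_injections,
                           var_equal = cfg$var_equal, p_cut = cfg$p_cut,
                           fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                           fdr = cfg$fdr)
    d <- cbind(tissue = t, cultivar = cv, d)
    diffs[[paste(t, cv)]] <- d
  }
  diff_tab <- do.call(rbind, diffs)
  rownames(diff_tab) <- NULL
  .write_stamped(diff_tab, file.path(cfg$outdir, "differential.tsv"), cfg)

  # multivariate views on log2 data
  iml <- if (cfg$average_injections && "injection" %in% names(meta))
    average_injections(im) else im
  lx <- log2(iml$values + 1e-9)
  pca <- pca_autoscaled(iml$values)
  .write_stamped(data.frame(sample_id = rownames(pca$scores), pca$scores),
                 file.path(cfg$outdir, "pca_scores.tsv"), cfg)
  .write_stamped(data.frame(compound = rownames(pca$loadings), pca$loadings),
                 file.path(cfg$outdir, "pca_loadings.tsv"), cfg)
  cl <- hierarchical_cluster(lx)
  cluster_newick(cl, file.path(cfg$outdir, "sample_dendrogram.nwk"))

  grDevices::png(file.path(cfg$outdir, "heatmap.png"), 900, 700)
  stats::heatmap(t(scale(lx)), distfun = function(z)
    stats::as.dist(1 - stats::cor(t(z))),
    hclustfun = function(d) stats::hclust(d, "complete"),
    scale = "none", margins = c(8, 10))
  grDevices::dev.off()
  grDevices::png(file.path(cfg$outdir, "pca_scores.png"), 700, 700)
  graphics::plot(pca$scores[, 1], pca$scores[, 2],
                 xlab = sprintf("PC1 (%.0f%%)", 100 * pca$explained_variance[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * pca$explained_variance[2]),
                 pch = 19, col = factor(iml$meta$treatment))
  graphics::text(pca$scores[, 1], pca$scores[, 2],
                 labels = iml$meta$sample_id, cex = 0.5, pos = 3)
  grDevices::dev.off()

  invisible(list(family = fam, glyco = gly, leaf_root = lr,
                 differential = diff_tab, pca = pca, cluster = cl))
}

#' Run all three stages on a simulated dataset
#'
#' Convenience wrapper: simulate, then annotate the simulated spectra,
#' then run the statistics stage on the simulated matrix.
#'
#' @param cfg A [pipeline_config()].
#' @return List of stage results, invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- run_simulate(cfg)
  cfg$spectra_path <- sim$spectra_mgf
  cfg$spectra_format <- "mgf"
  cfg$intensity_path <- sim$intensities
  cfg$metadata_path <- sim$metadata
  ann <- run_annotate(cfg)
  st <- run_stats(cfg)
  invisible(list(simulate = sim, annotate = ann, stats = st))
}
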