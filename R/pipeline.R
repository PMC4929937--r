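#' Quantify every scene in a directory
#'
#' Runs the full morphometry chain — read, grid construction, systematic
#' cell selection, counting-frame quantification — over a set of scene
#' images, producing one row per specimen. Per-scene selection seeds are
#' derived deterministically from the run seed and the sorted file order,
#' so a rerun with the same seed reproduces every number. Scenes that fail
#' to read or quantify are reported as warnings and skipped.
#'
#' @param scenes a directory containing scene images (+ JSON sidecars), or
#'   a character vector of image paths.
#' @param target_cells,k quadrate-sampling parameters (defaults 100 and
#'   10).
#' @param seed integer run seed (mandatory).
#' @param out optional TSV path; written with [utils::write.table()].
#' @return data frame with columns `specimen_id`, `species`, `ecology`,
#'   `N_s`, `A_s_mm2`, `A_c_mm2`, `density_per_mm2`, `mean_size_um2`,
#'   `coverage_pct`, `V_h_mm3`, `seed`.
#' @export
run_quantify <- function(scenes, target_cells = 100, k = 10, seed,
                         out = NULL) {
  if (missing(seed)) stopf("`seed` is required (deterministic reruns)")
  if (length(scenes) == 1L && dir.exists(scenes))
    scenes <- list.files(scenes, pattern = "\\.(png|tif|tiff)$",
                         full.names = TRUE, ignore.case = TRUE)
  scenes <- sort(scenes)
  if (!length(scenes)) stopf("no readable scene images found")
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    rows[[i]] <- tryCatch({
      sc <- read_scene(scenes[i])
      grid <- build_grid(sc, target_cells = target_cells)
      grid <- select_cells(grid, k = min(k, nrow(grid$cells)),
                           seed = seed + i - 1L)
      q <- quantify_scene(sc, grid)
      m <- sc$meta
      vh <- if (!is.null(m$head_l_mm) && !is.null(m$head_w_mm) &&
                !is.null(m$head_h_mm))
        head_volume(m$head_l_mm, m$head_w_mm, m$head_h_mm) else NA_real_
      data.frame(specimen_id = sc$specimen_id,
                 species = m$species %||% NA_character_,
                 ecology = m$ecology %||% NA_character_,
                 N_s = q$sample$N_s, A_s_mm2 = q$sample$A_s,
                 A_c_mm2 = q$sample$A_c,
                 density_per_mm2 = q$stats$density,
                 mean_size_um2 = q$stats$mean_size,
                 coverage_pct = q$stats$coverage,
                 V_h_mm3 = vh, seed = grid$seed,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("scene '%s' skipped: %s", scenes[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) stopf("no scene could be quantified")
  if (!is.null(out)) write_tsv(res, out)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' @param path TSV with a `species` column and numeric trait columns.
#' @return data frame.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stopf("species table '%s' not found", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

default_pairs <- list(
  c(y = "density",   x = "V_h"),
  c(y = "coverage",  x = "V_h"),
  c(y = "mean_size", x = "V_h"),
  c(y = "mean_size", x = "density"),
  c(y = "coverage",  x = "density"))

#' Contrast regressions and ancestral reconstruction for a species table
#'
#' The comparative half of the pipeline: log10-transforms each trait,
#' computes phylogenetic independent contrasts, fits the configured
#' allometric regressions with F tests, and reconstructs ancestral states
#' of one trait (coverage by default, since mean sensillum size strongly
#' covaries with density) under Brownian motion. Optionally repeats the
#' regressions with listed taxa excluded, appending flagged rows.
#'
#' @param species data frame with `species` plus trait columns named as in
#'   `pairs`.
#' @param phy bifurcating [ape::phylo] time tree whose tips match
#'   `species$species` exactly (apply `synonyms` for declared
#'   substitutions).
#' @param pairs list of `c(y = , x = )` trait-name pairs; the default is
#'   the five standard sensilla regressions (density, coverage and mean
#'   size against head volume; mean size and coverage against density).
#' @param intercept_mode fit an intercept on the contrasts (see
#'   [regress_contrasts()]).
#' @param asr_trait trait to reconstruct (default `"coverage"`).
#' @param exclude optional character vector of taxa for exclusion reruns.
#' @param synonyms optional named character vector mapping data species
#'   names to tree tip names (declared substitutions, e.g. a congener used
#'   for DNA).
#' @param out_dir optional directory; writes `fits.tsv`, `asr_nodes.tsv`
#'   and `asr.nex` there.
#' @return list with `fits` (data frame mirroring an allometry table:
#'   `y`, `x`, `a`, `b`, `ci95`, `r2`, `df1`, `df2`, `F`, `p`, `mode`,
#'   `excluded`, `note`) and `asr` (an `asr_estimate`).
#' @export
run_comparative <- function(species, phy, pairs = default_pairs,
                            intercept_mode = FALSE,
                            asr_trait = "coverage", exclude = NULL,
                            synonyms = NULL, out_dir = NULL) {
  if (!is.data.frame(species) || !"species" %in% names(species))
    stopf("`species` must be a data frame with a `species` column")
  if (length(phy$tip.label) < 4L) stopf("need at least 4 tips")
  if (!is.null(synonyms))
    species$species <- ifelse(species$species %in% names(synonyms),
                              unname(synonyms[species$species]),
                              species$species)
  traits <- unique(unlist(pairs))
  missing_cols <- setdiff(c(traits, asr_trait), names(species))
  if (length(missing_cols))
    stopf("species table lacks trait column(s): %s",
          paste(missing_cols, collapse = ", "))

  trait_vec <- function(df, tr) {
    v <- df[[tr]]
    names(v) <- df$species
    log10_transform(v, trait = tr)
  }
  fit_all <- function(df, tree, excluded_flag) {
    cs <- lapply(stats::setNames(traits, traits),
                 function(tr) pic_contrasts(tree, trait_vec(df, tr)))
    do.call(rbind, lapply(pairs, function(p) {
      f <- regress_contrasts(cs[[p[["y"]]]], cs[[p[["x"]]]],
                             intercept_mode = intercept_mode)
      data.frame(y = p[["y"]], x = p[["x"]], a = f$a, b = f$b,
                 ci95 = f$ci95, r2 = f$r2, df1 = f$df1, df2 = f$df2,
                 F = f$F, p = f$p,
                 mode = if (intercept_mode) "intercept" else "origin",
                 excluded = excluded_flag,
                 note = sprintf("%d regressions, no multiplicity correction",
                                length(pairs)),
                 stringsAsFactors = FALSE)
    }))
  }
  fits <- fit_all(species, phy, "none")
  for (sp in exclude) {
    pruned <- exclude_taxon(phy, species, sp)
    fits <- rbind(fits, fit_all(pruned$x, pruned$phy, sp))
  }
  asr <- asr_bm(phy, trait_vec(species, asr_trait), trait = asr_trait)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(fits, file.path(out_dir, "fits.tsv"))
    write_tsv(asr$nodes, file.path(out_dir, "asr_nodes.tsv"))
    write_annotated_nexus(phy, asr, file.path(out_dir, "asr.nex"))
  }
  list(fits = fits, asr = asr)
}

#' Run the full analysis end-to-end
#'
#' Orchestrates scenes -> specimen stats -> species means -> contrast
#' regressions -> ancestral reconstruction, writing all result tables and
#' a manifest that suffices to reproduce the run.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `scenes` (directory), `tree` (newick path), `out` (output directory),
#'   `seed` (mandatory), and optionally `target_cells`, `k`,
#'   `intercept_mode`, `asr_trait`, `exclude`, `synonyms`.
#' @return list with `specimens`, `species`, `fits`, `asr`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config '%s' not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("scenes", "tree", "out", "seed"))
    if (is.null(config[[f]])) stopf("config lacks required field `%s`", f)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  specimens <- run_quantify(config$scenes,
                            target_cells = config$target_cells %||% 100,
                            k = config$k %||% 10, seed = config$seed,
                            out = file.path(config$out, "specimens.tsv"))
  sp <- aggregate_species(specimens,
                          traits = c("density_per_mm2", "mean_size_um2",
                                     "coverage_pct", "V_h_mm3"))
  species <- data.frame(species = sp$species, n = sp$n,
                        density = sp$density_per_mm2_mean,
                        mean_size = sp$mean_size_um2_mean,
                        coverage = sp$coverage_pct_mean,
                        V_h = sp$V_h_mm3_mean,
                        stringsAsFactors = FALSE)
  write_tsv(species, file.path(config$out, "species.tsv"))

  phy <- read_newick(file = config$tree)
  syn <- config$synonyms
  if (!is.null(syn)) syn <- unlist(syn)
  comp <- run_comparative(species, phy,
                          intercept_mode = isTRUE(config$intercept_mode),
                          asr_trait = config$asr_trait %||% "coverage",
                          exclude = config$exclude,
                          synonyms = syn, out_dir = config$out)
  manifest <- list(config = config,
                   n_scenes = nrow(specimens),
                   n_species = nrow(species),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("sensquad")))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(specimens = specimens, species = species,
                 fits = comp$fits, asr = comp$asr))
}
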