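# End-to-end orchestration: landmarks -> completion -> GPA -> consensus ->
# morphospace -> disparity/tanglegram -> shift detection -> model
# comparison, driven by a single validated config, with a manifest and
# per-stage resumability.

#' Build and validate a pipeline configuration
#'
#' @param landmarks Path to a landmark CSV (long dialect) or a
#'   `landmark_dataset`.
#' @param tree Path to a Newick/NEXUS tree or a `phylo`.
#' @param curve_spec Optional curve-spec JSON path.
#' @param states Optional CSV path (`species,<character>,...`) or data
#'   frame of discrete characters for stochastic mapping.
#' @param out_dir Output directory for the report bundle.
#' @param scope `"full"` or a vector of species names delimiting a
#'   monophyletic subclade.
#' @param correction `"ppca"`, `"pca"` or `"both"`.
#' @param n_sim Simulations for the DTT and tanglegram nulls.
#' @param max_shifts Shift cap; defaults to 50 for the full tree and 20 for
#'   a subclade scope.
#' @param criterion Shift selection criterion.
#' @param n_bootstrap Bootstrap replicates for shift support (0 disables).
#' @param n_maps Stochastic character maps per discrete character.
#' @param slide Slide semilandmarks during GPA.
#' @param score_scale Score multiplier before shift detection/model fits.
#' @param seed Integer seed for all stochastic stages.
#' @param resume Reuse stage outputs already present in `out_dir`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, tree, curve_spec = NULL,
                            states = NULL, out_dir = tempfile("morphoshift_"),
                            scope = "full",
                            correction = c("ppca", "pca", "both"),
                            n_sim = 1000, max_shifts = NULL,
                            criterion = c("pbic", "bic"), n_bootstrap = 0,
                            n_maps = 100,
                            slide = FALSE, score_scale = 100, seed = 1,
                            resume = FALSE) {
  correction <- match.arg(correction)
  criterion <- match.arg(criterion)
  for (p in list(landmarks, tree, curve_spec, states)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("referenced file does not exist: ", p, call. = FALSE)
  }
  subclade <- !identical(scope, "full")
  if (is.null(max_shifts)) max_shifts <- if (subclade) 20 else 50
  structure(list(landmarks = landmarks, tree = tree,
                 curve_spec = curve_spec, states = states,
                 out_dir = out_dir, scope = scope, correction = correction,
                 n_sim = n_sim, max_shifts = max_shifts,
                 criterion = criterion, n_bootstrap = n_bootstrap,
                 n_maps = n_maps,
                 slide = slide, score_scale = score_scale, seed = seed,
                 resume = resume),
            class = "pipeline_config")
}

#' Prune a tree to a species list with name normalization
#'
#' Names are trimmed, internal whitespace collapsed to underscores; exact
#' matches are tried first, then case-insensitive matches (with a warning).
#'
#' @param tree `phylo`.
#' @param species Character vector of species names.
#' @return List with `tree` (pruned), `dropped_tips`, `unmatched_species`,
#'   and the name `mapping` used.
#' @export
prune_and_match <- function(tree, species) {
  ms_assert_phylo(tree)
  norm <- function(x) gsub("\\s+", "_", trimws(x))
  sp <- norm(species)
  tips <- norm(tree$tip.label)
  hit <- match(sp, tips)
  ci <- is.na(hit) & !is.na(match(tolower(sp), tolower(tips)))
  if (any(ci)) {
    warning("case-insensitive matches used for: ",
            paste(species[ci], collapse = ", "), call. = FALSE)
    hit[ci] <- match(tolower(sp[ci]), tolower(tips))
  }
  matched <- tree$tip.label[hit[!is.na(hit)]]
  if (length(matched) < 2)
    stop("fewer than 2 species shared with the tree", call. = FALSE)
  pruned <- ape::keep.tip(tree, matched)
  list(tree = pruned,
       dropped_tips = setdiff(tree$tip.label, matched),
       unmatched_species = species[is.na(hit)],
       mapping = setNames(matched, species[!is.na(hit)]))
}

stage_file <- function(config, name) file.path(config$out_dir, name)

stage_cached <- function(config, name) {
  config$resume && file.exists(stage_file(config, name))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order, writing each stage's tables (CSV/JSON)
#' plus a manifest into the configured output directory. With
#' `resume = TRUE`, stages whose output files already exist are reloaded
#' rather than recomputed.
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_result` with all stage objects and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(files = files, done = TRUE)
  }

  # stage 1: inputs
  dataset <- if (inherits(config$landmarks, "landmark_dataset"))
    config$landmarks
  else read_landmarks(config$landmarks, "csv",
                      curve_spec_path = config$curve_spec)
  tree <- if (inherits(config$tree, "phylo")) config$tree
  else ape::read.tree(config$tree)

  # stage 2: completion
  dataset <- estimate_missing(dataset)
  log_stage("impute", character(0))

  # stage 3: superimposition + species consensus
  align <- gpa_align(dataset, slide = config$slide)
  cons <- species_consensus(align, dataset$species,
                            bilateral_pairs = dataset$bilateral_pairs,
                            midline = dataset$midline)
  f_cons <- stage_file(config, "consensus_shapes.csv")
  write.csv(data.frame(species = rep(dimnames(cons)[[1]], each = dim(cons)[2]),
                       landmark = rep(seq_len(dim(cons)[2]),
                                      dim(cons)[1]),
                       x = as.vector(t(cons[, , 1])),
                       y = as.vector(t(cons[, , 2])),
                       z = as.vector(t(cons[, , 3]))),
            f_cons, row.names = FALSE)
  log_stage("gpa", basename(f_cons))

  # stage 4: tree matching / scope
  pm <- prune_and_match(tree, dimnames(cons)[[1]])
  tree <- pm$tree
  if (!identical(config$scope, "full")) {
    keep <- prune_and_match(tree, config$scope)$tree$tip.label
    mrca_tips <- ape::extract.clade(
      tree, ape::getMRCA(tree, keep))$tip.label
    if (!setequal(mrca_tips, keep))
      stop("scope subclade is not monophyletic in the tree", call. = FALSE)
    tree <- ape::keep.tip(tree, keep)
  }
  cons <- cons[tree$tip.label, , , drop = FALSE]
  log_stage("tree", character(0))

  # stage 5: morphospace(s)
  tracks <- switch(config$correction, ppca = "ppca", pca = "pca",
                   both = c("ppca", "pca"))
  spaces <- list()
  for (tk in tracks) {
    ms <- if (tk == "ppca") ppca(cons, tree) else pca(cons)
    ms$n_critical <- as.integer(parallel_analysis(
      flatten_shapes(cons), tree = if (tk == "ppca") tree else NULL,
      n_perm = 100, seed = config$seed))
    ncrit <- max(1L, ms$n_critical)
    ms$r2 <- axis_variance_r2(cons, ms$scores[, seq_len(ncrit), drop = FALSE])
    spaces[[tk]] <- ms
    write.csv(data.frame(species = rownames(ms$scores), ms$scores),
              stage_file(config, paste0("scores_", tk, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(correction = ms$correction, n_critical = ms$n_critical,
           eigenvalues = ms$eigenvalues, r2 = ms$r2),
      stage_file(config, paste0("morphospace_", tk, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  log_stage("morphospace", paste0("scores_", tracks, ".csv"))

  # stage 6: disparity through time
  dtt <- mdi_test(tree, cons, n_sim = config$n_sim, seed = config$seed)
  jsonlite::write_json(list(mdi = dtt$mdi, p_value = dtt$p_value,
                            n_sim = dtt$n_sim),
                       stage_file(config, "dtt.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(data.frame(time = dtt$times, observed = dtt$observed,
                       median_sim = dtt$median_sim, dtt$envelope),
            stage_file(config, "dtt_curve.csv"), row.names = FALSE)
  log_stage("dtt", c("dtt.json", "dtt_curve.csv"))

  # stage 7: tanglegram
  tg <- displacement_null_test(tree, cons, n_sim = config$n_sim,
                               seed = config$seed)
  jsonlite::write_json(list(td = tg$td, p_value = tg$p_value,
                            crossings = tg$crossings,
                            null_range = range(tg$null_td)),
                       stage_file(config, "tanglegram.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("tanglegram", "tanglegram.json")

  # stage 8: shift detection per track
  shifts <- list()
  for (tk in tracks) {
    ms <- spaces[[tk]]
    ncrit <- max(1L, ms$n_critical)
    sc <- scale_scores(ms$scores[, seq_len(ncrit), drop = FALSE],
                       config$score_scale)
    st <- search_settings(max_shifts = config$max_shifts,
                          criterion = config$criterion, seed = config$seed)
    cfg <- detect_shifts(tree, sc, st)
    if (config$n_bootstrap >= 20 && length(cfg$edges))
      cfg <- bootstrap_support(tree, sc, cfg,
                               n_bootstrap = config$n_bootstrap,
                               seed = config$seed)
    shifts[[tk]] <- cfg
    df <- if (length(cfg$edges))
      data.frame(edge = cfg$edges,
                 tip_set = vapply(cfg$edges, function(e) paste(
                   sort(tree$tip.label[tree_geometry(tree)$desc[[e]]]),
                   collapse = "|"), character(1)),
                 beta = I(round(cfg$beta, 6)),
                 support = if (!is.null(cfg$support)) cfg$support else NA)
    else data.frame(edge = integer(0))
    write.csv(df, stage_file(config, paste0("shifts_", tk, ".csv")),
              row.names = FALSE)
  }
  log_stage("shifts", paste0("shifts_", tracks, ".csv"))

  # stage 9: model comparison (primary track)
  tk <- tracks[1]
  ms <- spaces[[tk]]
  ncrit <- max(1L, min(ms$n_critical, 4L))
  sc <- scale_scores(ms$scores[, seq_len(ncrit), drop = FALSE],
                     config$score_scale)
  fits <- list(BM = fit_bm(tree, sc), OU1 = fit_ou1(tree, sc, n_restarts = 2),
               EB = fit_eb(tree, sc))
  if (length(shifts[[tk]]$edges))
    fits$shift_model <- fit_oum(tree, sc,
                                painting_from_shifts(tree, shifts[[tk]]),
                                alpha_structure = "diagonal")
  if (!is.null(config$states)) {
    st_df <- if (is.data.frame(config$states)) config$states else
      read.csv(config$states, stringsAsFactors = FALSE)
    for (cname in setdiff(names(st_df), "species")) {
      xs <- setNames(as.character(st_df[[cname]]), st_df$species)
      xs <- xs[names(xs) %in% tree$tip.label]
      if (length(unique(xs)) < 2 || length(xs) < ape::Ntip(tree)) next
      maps <- simmap(tree, xs, n_maps = config$n_maps, seed = config$seed)
      fits[[paste0("OU_", toupper(cname))]] <-
        lapply(maps$paintings, function(pp)
          fit_oum(tree, sc, pp, alpha_structure = "symmetric",
                  n_restarts = 1))
    }
  }
  cmp <- compare_models(fits)
  write.csv(as.data.frame(cmp), stage_file(config, "model_comparison.csv"),
            row.names = FALSE)
  log_stage("models", "model_comparison.csv")

  jsonlite::write_json(manifest, stage_file(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(config = config, dataset = dataset, alignment = align,
                 consensus = cons, tree = tree, morphospaces = spaces,
                 dtt = dtt, tanglegram = tg, shifts = shifts,
                 models = cmp, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("morphoshift pipeline result\n")
  cat(sprintf("  %d species, %d landmarks\n", ape::Ntip(x$tree),
              dim(x$consensus)[2]))
  cat(sprintf("  MDI = %.4g (p = %.3g); TD = %.3g (p = %.3g)\n",
              x$dtt$mdi, x$dtt$p_value, x$tanglegram$td,
              x$tanglegram$p_value))
  for (tk in names(x$shifts))
    cat(sprintf("  %s shifts: %d\n", tk, length(x$shifts[[tk]]$edges)))
  cat("  model ranking: ", paste(x$models$model, collapse = " < "), "\n")
  invisible(x)
}
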