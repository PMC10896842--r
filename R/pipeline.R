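#' Configuration for the end-to-end protocol-design pipeline
#'
#' Bundles the per-stage settings of [run_pipeline()]: the synthetic EEG
#' spec, detection parameters, clustering settings, the ground-truth
#' stimulation paradigm whose CD serves as the optimization target, the
#' montage/waveform/dt search grid, the CD-dataset synthesis settings, the
#' classifier settings and the GA configuration. Defaults describe a small
#' self-contained scenario that exercises every stage.
#'
#' @param stage Sleep stage analyzed (`"SWS"` or `"S2"`).
#' @param dt_ms Time resolution used throughout (20/50/100/200).
#' @param eeg Named list of [synth_eeg()] arguments (without `seed`).
#' @param detection An [so_detection_params()].
#' @param cluster Named list: `delay`, `replicates`.
#' @param true_paradigm Named list defining the ground-truth paradigm:
#'   `kind`, `params`, `montage` (four electrode names).
#' @param grid_montages List of four-electrode character vectors searched
#'   by the optimizer; must include the true montage.
#' @param kinds Waveform families searched.
#' @param cd Named list for [synth_cd_paradigms()]: `n_global`,
#'   `n_nonglobal`, `amp_jitter`, `noise_frac`.
#' @param classifier Named list: `n_trees`, `folds`, `min_node`.
#' @param ga A [ga_config()] (its seed is overridden per run).
#' @param transfer Named list for [synth_transfer()]: `length_scale`.
#' @return A list of class `so_pipeline_config`.
#' @export
so_pipeline_config <- function(stage = "SWS", dt_ms = 100,
                               eeg = list(),
                               detection = so_detection_params(),
                               cluster = list(delay = 0.4, replicates = 50),
                               true_paradigm = list(
                                 kind = "sine",
                                 params = c(0.2, 0.9, pi / 2, 0.05),
                                 montage = c("F3", "F4", "P3", "P4")
                               ),
                               grid_montages = list(
                                 c("F3", "F4", "P3", "P4"),
                                 c("F7", "F8", "O1", "O2"),
                                 c("AF3", "F8", "P7", "PO4")
                               ),
                               kinds = "sine",
                               cd = list(
                                 n_global = 60, n_nonglobal = 120,
                                 amp_jitter = 0.2, noise_frac = 0.2
                               ),
                               classifier = list(
                                 n_trees = 100, folds = 5, min_node = 5
                               ),
                               ga = ga_config(pop_size = 80),
                               transfer = list(length_scale = 0.6)) {
  check_dt(dt_ms)
  true_key <- montage(true_paradigm$montage)$key
  grid_keys <- vapply(grid_montages, function(e) montage(e)$key, character(1))
  if (!true_key %in% grid_keys) {
    stop_sostim("the true paradigm's montage must be one of grid_montages")
  }
  structure(
    list(
      stage = stage, dt_ms = dt_ms, eeg = eeg, detection = detection,
      cluster = cluster, true_paradigm = true_paradigm,
      grid_montages = grid_montages, kinds = kinds, cd = cd,
      classifier = classifier, ga = ga, transfer = transfer
    ),
    class = "so_pipeline_config"
  )
}

#' Run the end-to-end protocol-design pipeline
#'
#' Executes the full chain on synthetic data: generate EEG and detect SOs;
#' cluster co-detections into Global/Frontal/Local; build the transfer
#' model and the target CD (the ground-truth paradigm's CD, standing in for
#' the average global-SO CD); synthesize the labeled CD training set;
#' compute ANOVA-F feature weights; train and cross-validate the
#' classifier; GA-optimize every grid cell; and select the protocol by
#' classifier posterior. All stage seeds derive from the single `seed`, so
#' identical configurations reproduce identical manifests.
#'
#' @param cfg An [so_pipeline_config()].
#' @param seed Integer master seed.
#' @param verbose Emit per-stage messages (default `TRUE`).
#' @return A list of class `so_pipeline_result` with the per-stage outputs
#'   (`events`, `cluster`, `target`, `cd_data`, `weights`, `model`, `cv`,
#'   `grid`, `selection`), summary fields (`true_cell`,
#'   `selected_matches_truth`) and a reproducibility `manifest`.
#' @export
run_pipeline <- function(cfg = so_pipeline_config(), seed = 1, verbose = TRUE) {
  stopifnot(inherits(cfg, "so_pipeline_config"))
  say <- function(...) if (verbose) message("[sostim] ", sprintf(...))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sostim("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("stage 1/6: synthetic EEG + SO detection")
  synth <- step("eeg", do.call(synth_eeg, c(
    cfg$eeg,
    list(stage = cfg$stage, seed = derive_seed(seed, 1))
  )))
  events <- step("detect", detect_sos(synth$recording, cfg$detection, cfg$stage))
  say("  %d events detected (%d planted deflections)", nrow(events), nrow(synth$truth))

  say("stage 2/6: co-detection clustering")
  clust <- step("cluster", cluster_so_events(
    events,
    frontal = synth$frontal, posterior = synth$posterior,
    electrodes = synth$recording$channel_names,
    delay = cfg$cluster$delay, replicates = cfg$cluster$replicates,
    seed = derive_seed(seed, 2)
  ))
  n_global_ev <- sum(clust$events$is_global)
  say(
    "  cluster sizes %s; %d/%d events labeled global",
    paste(clust$model$sizes, collapse = "/"), n_global_ev, nrow(events)
  )

  say("stage 3/6: transfer model + target CD")
  tm <- step("transfer", synth_transfer(
    seed = derive_seed(seed, 3),
    length_scale = cfg$transfer$length_scale
  ))
  true_p <- step("target", paradigm(
    montage(cfg$true_paradigm$montage),
    waveform(cfg$true_paradigm$kind, cfg$true_paradigm$params),
    cfg$dt_ms
  ))
  target <- estimate_paradigm_cd(true_p, tm)

  say("stage 4/6: CD dataset, feature weights, classifier")
  grid_mons <- lapply(cfg$grid_montages, montage)
  true_key <- montage(cfg$true_paradigm$montage)$key
  decoys <- grid_mons[vapply(grid_mons, function(m) m$key != true_key, logical(1))]
  cd_data <- step("cd_dataset", synth_cd_paradigms(
    target, tm, decoys,
    n_global = cfg$cd$n_global, n_nonglobal = cfg$cd$n_nonglobal,
    amp_jitter = cfg$cd$amp_jitter, noise_frac = cfg$cd$noise_frac,
    seed = derive_seed(seed, 4)
  ))
  weights <- step("weights", anova_f_weights(cd_data$X, cd_data$y))
  cv <- step("crossval", crossval_mcc(
    cd_data$X, cd_data$y,
    folds = cfg$classifier$folds,
    seed = derive_seed(seed, 5), n_trees = cfg$classifier$n_trees,
    min_node = cfg$classifier$min_node
  ))
  model <- step("train", train_so_classifier(
    cd_data$X, cd_data$y,
    seed = derive_seed(seed, 6),
    n_trees = cfg$classifier$n_trees, min_node = cfg$classifier$min_node
  ))
  say("  cross-validated MCC: %.3f", cv$mcc)

  say("stage 5/6: GA optimization of %d grid cells", length(grid_mons) *
    length(cfg$kinds))
  ga_cfg <- cfg$ga
  ga_cfg$seed <- derive_seed(seed, 7)
  grid <- step("optimize", optimize_grid(
    grid_mons, cfg$kinds, cfg$dt_ms, target, tm,
    weights = weights, config = ga_cfg
  ))

  say("stage 6/6: protocol selection")
  sel <- step("select", select_protocol(grid, model))
  matches <- sel$selected$montage_key == true_key &&
    sel$selected$kind == cfg$true_paradigm$kind &&
    sel$selected$dt_ms == cfg$dt_ms
  say(
    "  selected %s (posterior %.3f)%s", sel$selected$montage_key,
    sel$selected$posterior,
    if (matches) " - matches ground truth" else ""
  )

  manifest <- list(
    seed = seed,
    stage_seeds = vapply(1:7, function(i) derive_seed(seed, i), integer(1)),
    hashes = list(
      events = rlang::hash(events),
      target = rlang::hash(unclass(target)),
      weights = rlang::hash(weights),
      grid = rlang::hash(dplyr::select(grid, -"candidate")),
      selection = rlang::hash(dplyr::select(sel$results, -"candidate"))
    )
  )
  structure(
    list(
      events = clust$events, cluster = clust$model, target = target,
      cd_data = cd_data, weights = weights, model = model, cv = cv,
      grid = grid, selection = sel, true_cell = tibble::tibble(
        montage_key = true_key, kind = cfg$true_paradigm$kind,
        dt_ms = cfg$dt_ms
      ),
      selected_matches_truth = matches, manifest = manifest, config = cfg
    ),
    class = "so_pipeline_result"
  )
}

#' @export
print.so_pipeline_result <- function(x, ...) {
  cat("<so_pipeline_result>\n")
  cat("  events detected:   ", nrow(x$events), "\n")
  cat("  global events:     ", sum(x$events$is_global), "\n")
  cat("  cross-val MCC:     ", round(x$cv$mcc, 3), "\n")
  cat("  selected protocol: ", x$selection$selected$montage_key, "|",
    x$selection$selected$kind, "| dt", x$selection$selected$dt_ms, "ms\n")
  cat("  posterior:         ", round(x$selection$selected$posterior, 3), "\n")
  cat("  matches truth:     ", x$selected_matches_truth, "\n")
  invisible(x)
}

#' @export
glance.so_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events), n_global = sum(x$events$is_global),
    cv_mcc = x$cv$mcc,
    selected = x$selection$selected$montage_key,
    posterior = x$selection$selected$posterior,
    wcc = x$selection$selected$wcc,
    matches_truth = x$selected_matches_truth
  )
}
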