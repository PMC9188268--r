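# Experiment orchestration: structured configuration, validation, and the
# top-level runner tying the model chains together.

#' Build an experiment configuration
#'
#' The `desk` profile caps the corpus size, nerve-cell count, HMM size and
#' SNR grid so a complete run finishes on a single desktop core; `full`
#' uses the study-scale defaults (120 sentences, 8 training mixtures,
#' 2200 nerve cells, 8 states per word).
#'
#' @param scenarios character vector of scenario ids
#' @param beamformers character vector of beamformer ids
#' @param models subset of `c("fade", "bsim", "isnr")`
#' @param side_mode `"bimodal"`, `"acoustic"` or `"ci"`
#' @param profile `"desk"` or `"full"`
#' @param seed master seed
#' @param overrides named list of deep overrides (e.g.
#'   `list(grid = list(train_snrs = c(-9, 0)))`)
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(scenarios = "S0N-90",
                              beamformers = c("NoBF", "MVDR"),
                              models = c("fade", "bsim", "isnr"),
                              side_mode = "bimodal",
                              profile = c("desk", "full"), seed = 1,
                              overrides = list()) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  cfg <- list(
    scenarios = scenarios, beamformers = beamformers, models = models,
    side_mode = side_mode, profile = profile, seed = seed,
    corpus = list(n_alternatives = if (desk) 10 else 10,
                  n_sentences = if (desk) 10 else 120),
    grid = list(train_snrs = if (desk) c(-21, -9) else NULL,
                test_snrs = if (desk) seq(-33, -3, by = 6) else NULL,
                n_train_mixtures = if (desk) 2 else 8,
                n_test_mixtures = 1),
    hmm = list(states_word = if (desk) 2 else 8,
               states_sil = if (desk) 2 else 6,
               states_edge = if (desk) 1 else 3),
    pop = list(n_cells = if (desk) 220 else 2200),
    ir = list(n_groups = 46),
    ace = list(M = 22, N = 8),
    bsim = list())
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Cross-field checks; returns (and prints) all offending keys rather than
#' stopping at the first.
#'
#' @param cfg an [experiment_config()]
#' @return character vector of error messages (empty when valid),
#'   invisibly; attribute `warnings` lists non-fatal notes
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  warns <- character(0)
  bad_sc <- setdiff(cfg$scenarios, SCENARIOS)
  if (length(bad_sc))
    errs <- c(errs, paste0("scenarios: unknown id(s) ",
                           paste(bad_sc, collapse = ", ")))
  bad_bf <- setdiff(cfg$beamformers, c("NoBF", "ADM", "MVDR"))
  if (length(bad_bf))
    errs <- c(errs, paste0("beamformers: unknown id(s) ",
                           paste(bad_bf, collapse = ", ")))
  bad_mod <- setdiff(cfg$models, c("fade", "bsim", "isnr"))
  if (length(bad_mod))
    errs <- c(errs, paste0("models: unknown id(s) ",
                           paste(bad_mod, collapse = ", ")))
  if (!is.null(cfg$ace) && cfg$ace$N > cfg$ace$M)
    errs <- c(errs, "ace: N must not exceed M")
  for (ref in c("sii_ref_acoustic", "sii_ref_ci")) {
    v <- cfg$bsim[[ref]]
    if (!is.null(v) && (v <= 0 || v >= 1))
      errs <- c(errs, paste0("bsim$", ref, ": reference outside (0, 1)"))
  }
  g <- cfg$grid
  if (!is.null(g$train_snrs) && is.unsorted(g$train_snrs))
    errs <- c(errs, "grid$train_snrs: must be sorted")
  if (!is.null(g$test_snrs) && is.unsorted(g$test_snrs))
    errs <- c(errs, "grid$test_snrs: must be sorted")
  if (cfg$corpus$n_sentences %% cfg$corpus$n_alternatives != 0)
    errs <- c(errs, "corpus: n_sentences not divisible by n_alternatives")
  if (!is.null(cfg$pop$n_cells) && cfg$pop$n_cells != 2200)
    warns <- c(warns, "pop$n_cells differs from the physiological default")
  structure(invisible(errs), warnings = warns)
}

# materialize stage objects from a config
build_stages <- function(cfg) {
  pop <- do.call(nerve_population, cfg$pop)
  list(corpus = generate_corpus(
         default_vocabulary(cfg$corpus$n_alternatives),
         cfg$corpus$n_sentences, seed = derive_seed(cfg$seed, 1)),
       pipeline = pipeline_config(
         pop = pop, ir = do.call(ir_config, cfg$ir),
         ace = do.call(ace_config, cfg$ace), side_mode = cfg$side_mode),
       hmm = do.call(hmm_config, cfg$hmm),
       bsim = do.call(bsim_config, cfg$bsim))
}

#' Run a configured experiment
#'
#' Executes the requested model chains over the scenario-by-beamformer
#' matrix and collects SRTs, beamformer benefits and recognition matrices,
#' plus the resolved configuration for exact replay.
#'
#' @param cfg an [experiment_config()]
#' @param verbose print progress
#' @return list with `srt` (data.frame scenario x beamformer x model),
#'   `matrices` (recognition matrices of the fade runs), `isnr`
#'   (instrumental benefits) and `config`
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config:\n  ", paste(errs,
                                                      collapse = "\n  "))
  st <- build_stages(cfg)
  rows <- list(); mats <- list(); isnr_rows <- list()
  for (sc in cfg$scenarios) {
    for (bf in cfg$beamformers) {
      if ("fade" %in% cfg$models) {
        g <- cfg$grid
        tr <- if (is.null(g$train_snrs)) default_snr_range(sc, bf)
              else g$train_snrs
        te <- if (is.null(g$test_snrs)) default_snr_range(sc, bf)
              else g$test_snrs
        grid <- snr_grid(tr, te, g$n_train_mixtures, g$n_test_mixtures)
        rm_ <- run_grid(st$corpus, sc, bf, grid, st$pipeline, st$hmm,
                        seed = derive_seed(cfg$seed, 2), verbose = verbose)
        mats[[paste(sc, bf)]] <- rm_
        srt <- tryCatch(as.numeric(extract_srt(rm_)),
                        error = function(e) NA_real_)
        rows[[length(rows) + 1]] <-
          data.frame(scenario = sc, beamformer = bf, model = "fade",
                     srt_db = srt)
      }
      if ("bsim" %in% cfg$models) {
        srt <- as.numeric(bsim_predict(st$corpus, sc, bf, st$pipeline,
                                       st$bsim, side_mode = cfg$side_mode,
                                       seed = derive_seed(cfg$seed, 3)))
        rows[[length(rows) + 1]] <-
          data.frame(scenario = sc, beamformer = bf, model = "bsim",
                     srt_db = srt)
      }
      if ("isnr" %in% cfg$models) {
        sp <- make_speech_shaped_noise(st$corpus, 1.5,
                                       seed = derive_seed(cfg$seed, 4))
        scene <- scene_spec(sc, 0)
        bank <- make_noise_bank(st$corpus, scene,
                                derive_seed(cfg$seed, 5), 1.7)
        parts <- mix_scene(scene, sp, st$pipeline$head,
                           noise_signals = lapply(bank, fix_length,
                                                  n = length(sp)))
        for (side in c("left", "right")) {
          r <- instrumental_snr(parts$speech_only, parts$noise_only, bf,
                                side, st$pipeline$head)
          isnr_rows[[length(isnr_rows) + 1]] <-
            data.frame(scenario = sc, beamformer = bf, side = side,
                       input_snr = r$input_snr, output_snr = r$output_snr,
                       improvement = r$improvement)
        }
      }
    }
  }
  list(srt = do.call(rbind, rows), matrices = mats,
       isnr = if (length(isnr_rows)) do.call(rbind, isnr_rows) else NULL,
       config = cfg)
}

#' Write / read an experiment configuration as YAML
#' @param cfg an [experiment_config()]
#' @param path file path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "experiment_config")
}
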