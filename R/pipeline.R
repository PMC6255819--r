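#' Configuration for an end-to-end pipeline run
#'
#' Validates and normalises the configuration consumed by [run_pipeline()].
#' Stages run in the fixed order phantoms -> pvm -> synthesis -> experiments
#' -> analysis; selecting a later stage requires the stages it feeds on.
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Character subset of
#'   `c("phantoms", "pvm", "synthesis", "experiments", "analysis")`.
#' @param seed Master seed recorded in every manifest row and fanned out to
#'   all stage seeds via [derive_seed()].
#' @param n_per_class Phantoms per diagnostic class.
#' @param phantom_size Phantom side in pixels.
#' @param pvm_size Patch side `w` in pixels.
#' @param synth_iters Synthesis iterations per patch.
#' @param n_observers_exp1,n_observers_exp2 Simulated panel sizes.
#' @param min_presentations Presentations per image (Exp 1) / pair (Exp 2).
#' @param network Optional [network_config()] (default [desk_net_config()]).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("phantoms", "pvm", "synthesis",
                                  "experiments", "analysis"),
                       seed = 1L, n_per_class = 2L, phantom_size = 64L,
                       pvm_size = 32L, synth_iters = 60L,
                       n_observers_exp1 = 14L, n_observers_exp2 = 12L,
                       min_presentations = 10L, network = NULL,
                       log_level = "info") {
  all_stages <- c("phantoms", "pvm", "synthesis", "experiments", "analysis")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  log_level <- match.arg(log_level, c("info", "quiet"))
  deps <- list(pvm = "phantoms", synthesis = "pvm", experiments = "pvm",
               analysis = c("pvm", "experiments"))
  for (s in stages) {
    if (!all(deps[[s]] %in% stages))
      abort_param(sprintf("stage '%s' requires stage(s) %s", s,
                          paste(deps[[s]], collapse = ", ")))
  }
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 phantom_size = as.integer(phantom_size),
                 pvm_size = as.integer(pvm_size),
                 synth_iters = as.integer(synth_iters),
                 n_observers_exp1 = as.integer(n_observers_exp1),
                 n_observers_exp2 = as.integer(n_observers_exp2),
                 min_presentations = as.integer(min_presentations),
                 network = network %||% desk_net_config(),
                 log_level = log_level),
            class = "run_config")
}

#' Run the full deep-synthesis pipeline
#'
#' Executes the selected stages end to end: generate a phantom cohort,
#' extract partial-view patches, synthesize a texture metamer per patch,
#' simulate Experiments 1 and 2 on one original/synthesized pair per
#' diagnostic class, and run the analyses (d-prime, RDM, congruity between
#' split halves of the panel, hierarchical clustering, paired rating test).
#' Every written artifact gets a manifest row (stage, file, seed, md5
#' checksum); re-running with the same configuration reproduces all outputs
#' bit-identically.
#'
#' @param config A [run_config()].
#' @return The manifest tibble, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort_param("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (config$log_level == "info")
    message(sprintf(...))
  manifest <- list()
  note <- function(stage, file, params = "") {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, file = basename(file), seed = config$seed,
      params = params, md5 = unname(tools::md5sum(file)))
  }
  stage_on <- function(s) s %in% config$stages
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) mm_abort(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      "pipeline_error"))
  }

  cohort <- NULL; pvms <- NULL; synths <- NULL
  net <- build_network(config$network)

  if (stage_on("phantoms")) wrap_stage("phantoms", {
    log_msg("stage phantoms: %d per class, %d px", config$n_per_class,
            config$phantom_size)
    cohort <- generate_cohort(config$n_per_class, config$phantom_size,
                              derive_seed(config$seed, 1))
    man <- cohort_manifest(cohort)
    for (i in seq_along(cohort)) {
      f <- file.path(config$out_dir, sprintf("%s.png", man$id[i]))
      write_image(cohort[[i]]$image, f, 8L)
      note("phantoms", f, man$class_label[i])
      fm <- file.path(config$out_dir, sprintf("%s_mask.png", man$id[i]))
      write_image(cohort[[i]]$roi_mask * 1.0, fm, 8L)
      note("phantoms", fm, "mask")
    }
    f <- file.path(config$out_dir, "phantoms.csv")
    utils::write.csv(man, f, row.names = FALSE)
    note("phantoms", f)
  })

  if (stage_on("pvm")) wrap_stage("pvm", {
    log_msg("stage pvm: w = %d", config$pvm_size)
    pvms <- extract_cohort_pvms(cohort, config$pvm_size)
    for (i in seq_along(pvms$records)) {
      rec <- pvms$records[[i]]
      f <- file.path(config$out_dir, sprintf("pvm_%03d.png", i))
      write_image(rec$crop, f, 8L)
      note("pvm", f, sprintf("%s:%s", rec$class_label, rec$provenance))
    }
    f <- file.path(config$out_dir, "pvms.csv")
    utils::write.csv(pvms$manifest, f, row.names = FALSE)
    note("pvm", f)
  })

  if (stage_on("synthesis")) wrap_stage("synthesis", {
    log_msg("stage synthesis: %d iterations per patch", config$synth_iters)
    synths <- vector("list", length(pvms$records))
    for (i in seq_along(pvms$records)) {
      rec <- pvms$records[[i]]
      sres <- synthesize(net, rec$crop, synthesis_options(
        max_iters = config$synth_iters,
        init_seed = derive_seed(config$seed, 3, i)))
      f <- file.path(config$out_dir, sprintf("synth_%03d.pgm", i))
      write_image(sres$image, f, 16L)
      note("synthesis", f, sprintf("loss=%.4g", sres$final_loss))
      synths[[i]] <- sres
    }
    losses <- tibble::tibble(
      patch = seq_along(synths),
      class_label = vapply(pvms$records, `[[`, "", "class_label"),
      initial_loss = vapply(synths, function(s) s$loss_trajectory[1], 0),
      final_loss = vapply(synths, `[[`, 0, "final_loss"),
      iterations = vapply(synths, `[[`, 0L, "iterations_run"))
    f <- file.path(config$out_dir, "synthesis.csv")
    utils::write.csv(losses, f, row.names = FALSE)
    note("synthesis", f)
  })

  exp1_tab <- NULL; exp2_tab <- NULL; stimuli <- NULL
  if (stage_on("experiments")) wrap_stage("experiments", {
    classes <- vapply(pvms$records, `[[`, "", "class_label")
    picks <- match(unique(classes), classes)
    stimuli <- stimulus_set(length(picks), classes[picks])
    log_msg("stage experiments: %d pairs, %d+%d observers", nrow(stimuli),
            config$n_observers_exp1, config$n_observers_exp2)
    s1 <- make_schedule(stimuli, config$min_presentations, 1L,
                        derive_seed(config$seed, 4, 1))
    obs1 <- lapply(seq_len(config$n_observers_exp1), function(i)
      observer_chance(derive_seed(config$seed, 4, 10 + i)))
    exp1_tab <- simulate_panel(s1, obs1)
    s2 <- make_schedule(stimuli, config$min_presentations, 2L,
                        derive_seed(config$seed, 4, 2))
    obs2 <- lapply(seq_len(config$n_observers_exp2), function(i)
      observer_rater(seed = derive_seed(config$seed, 4, 100 + i)))
    exp2_tab <- simulate_panel(s2, obs2)
    for (tb in list(list(exp1_tab, "exp1_trials.csv"),
                    list(exp2_tab, "exp2_trials.csv"))) {
      f <- file.path(config$out_dir, tb[[2]])
      utils::write.csv(as.data.frame(tb[[1]]), f, row.names = FALSE)
      note("experiments", f)
    }
  })

  if (stage_on("analysis")) wrap_stage("analysis", {
    log_msg("stage analysis")
    dp <- dprime(exp1_tab)
    f <- file.path(config$out_dir, "dprime.csv")
    utils::write.csv(as.data.frame(dp), f, row.names = FALSE)
    note("analysis", f)
    rdm <- build_rdm(exp2_tab)
    f <- file.path(config$out_dir, "rdm.csv")
    utils::write.csv(as.data.frame(unclass(rdm)), f)
    note("analysis", f)
    subj <- unique(exp2_tab$subject)
    if (length(subj) >= 2) {
      half <- seq_len(floor(length(subj) / 2))
      rdm_a <- build_rdm(exp2_tab[exp2_tab$subject %in% subj[half], ])
      rdm_b <- build_rdm(exp2_tab[!exp2_tab$subject %in% subj[half], ])
      cg <- rdm_congruity(rdm_a, rdm_b, 1000L, derive_seed(config$seed, 5, 1))
      prt <- paired_rating_test(exp2_tab, stimuli)
      f <- file.path(config$out_dir, "stats.csv")
      utils::write.csv(data.frame(
        statistic = c("congruity_rho", "congruity_p", "paired_t", "paired_p"),
        value = c(cg$rho, cg$p, prt$t, prt$p)), f, row.names = FALSE)
      note("analysis", f)
    }
    tree <- hca(rdm)
    f <- file.path(config$out_dir, "hca.newick")
    writeLines(linkage_newick(tree), f)
    note("analysis", f)
  })

  out <- dplyr::bind_rows(manifest)
  utils::write.csv(out, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out)
}
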