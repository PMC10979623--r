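#' Fit the external/real transformer pair and train the class GANs
#'
#' Convenience wrapper over the full GAN training path: chooses per-feature
#' scalers for the external and real data, fits the external transformer on
#' 200 random external rows and the real transformer on all real rows,
#' pre-trains progressively on the transformed external data, and re-trains
#' one GAN per class of the transformed real data.
#'
#' @param real Labeled [labeled_matrix()] ("real" data).
#' @param external Unlabeled [labeled_matrix()] of the same features.
#' @param pretrain_cfg,retrain_cfg [training_config()] objects.
#' @param hyper Shared [gan_hyperparams()].
#' @param alpha_under,alpha_over Dispersion coefficients for retraining.
#' @param seed Master seed.
#' @param pretrained Optionally reuse an existing [pretrain_progressive()]
#'   result (the transfer-learning contract: one pre-training shared by all
#'   retrainings of a dataset).
#' @param classic Train the no-transfer ablation (see
#'   [retrain_class_gans()]).
#' @param n_external_fit Rows used to fit the external transformer
#'   (default 200).
#' @return A list with `gans`, `real_transformer`, `external_transformer`
#'   and `pretrained`.
#' @export
train_gan_pipeline <- function(real, external,
                               pretrain_cfg = pretrain_config(),
                               retrain_cfg = retrain_config(),
                               hyper = gan_hyperparams(),
                               alpha_under = 0, alpha_over = 0, seed = 1L,
                               pretrained = NULL, classic = FALSE,
                               n_external_fit = 200L) {
  real_plan <- choose_feature_transforms(real)
  real_tf <- fit_transformer(real, real_plan)
  if (is.null(pretrained) && !classic) {
    ext_plan <- choose_feature_transforms(external)
    ext_tf <- fit_transformer(external, ext_plan,
                              n_fit_samples = n_external_fit,
                              seed = derive_seed(seed, 41L))
    ext_scaled <- transform_data(ext_tf, external)
    pretrained <- pretrain_progressive(ext_scaled, pretrain_cfg, hyper,
                                       seed = derive_seed(seed, 42L))
    pretrained$transformer <- ext_tf
  }
  real_scaled <- transform_data(real_tf, real)
  gans <- retrain_class_gans(pretrained, real_scaled, retrain_cfg, hyper,
                             alpha_under = alpha_under, alpha_over = alpha_over,
                             seed = derive_seed(seed, 43L), classic = classic)
  list(gans = gans, real_transformer = real_tf,
       external_transformer = if (!classic) pretrained$transformer,
       pretrained = if (!classic) pretrained)
}

#' Run the full experiment grid
#'
#' End-to-end study workflow per design: shared simulated dataset (one
#' external and one validation split reused across designs), per-design real
#' data, one shared pre-training run, per-design and per-alpha-combination
#' retraining, all requested balancing methods, the repeated-validation
#' protocol, alpha-combination selection for the GAN methods, and pairwise
#' Welch/BH comparisons within each design. GAN training is lazy: with only
#' `smote` / `random_oversample` requested, no GAN is trained.
#'
#' @param designs List of [experiment_design()] (default the standard nine).
#' @param sim_config A [simulation_config()].
#' @param methods Balancing methods to evaluate.
#' @param alpha_combos List of `c(alpha_under, alpha_over)` combinations for
#'   the GAN methods (default `0/0`, `1/0`, `1/1`).
#' @param pretrain_cfg,retrain_cfg [training_config()] objects.
#' @param hyper Shared [gan_hyperparams()].
#' @param grid A [classifier_grid()].
#' @param n_iterations Validation iterations per method (default 100).
#' @param multiplier Expansion multiplier for `gan_expand` (default 1).
#' @param seed Master seed; every stage derives a named substream.
#' @return A list with per-design results (`reports`, `comparison`,
#'   `best_alpha`) and a `manifest` recording the configuration and seeds.
#' @export
run_experiment_grid <- function(designs = experiment_grid(),
                                sim_config = simulation_config(),
                                methods = c("gan_balance", "gan_expand",
                                            "smote", "random_oversample"),
                                alpha_combos = list(c(0, 0), c(1, 0), c(1, 1)),
                                pretrain_cfg = pretrain_config(),
                                retrain_cfg = retrain_config(),
                                hyper = gan_hyperparams(),
                                grid = classifier_grid(),
                                n_iterations = 100L, multiplier = 1.0,
                                seed = 1L) {
  assert_that(length(designs) >= 1, "designs must be non-empty")
  gan_methods <- intersect(methods, c("gan_balance", "gan_expand"))
  need_gan <- length(gan_methods) > 0

  max_real <- max(vapply(designs, function(d) d$n_controls + d$n_cases, numeric(1)))
  n_total <- sim_config$n_validation + sim_config$n_external + 2 * max_real + 200
  dataset <- simulate_two_cluster_dataset(n_total, sim_config)

  pretrained <- NULL
  ext_tf <- NULL
  if (need_gan) {
    first_split <- split_experiment(dataset, designs[[1]], sim_config)
    ext_plan <- choose_feature_transforms(first_split$external)
    ext_tf <- fit_transformer(first_split$external, ext_plan,
                              n_fit_samples = min(200L, sim_config$n_external),
                              seed = derive_seed(seed, 41L))
    ext_scaled <- transform_data(ext_tf, first_split$external)
    pretrained <- pretrain_progressive(ext_scaled, pretrain_cfg, hyper,
                                       seed = derive_seed(seed, 42L))
    pretrained$transformer <- ext_tf
  }

  results <- list()
  n_failed <- 0L
  for (d in seq_along(designs)) {
    results[[d]] <- tryCatch(
      local({
    design <- designs[[d]]
    splits <- split_experiment(dataset, design, sim_config)
    real <- splits$real
    validation <- splits$validation
    dseed <- derive_seed(seed, 1000L + d)

    real_tf <- NULL
    pairs <- list()
    if (need_gan) {
      real_plan <- choose_feature_transforms(real)
      real_tf <- fit_transformer(real, real_plan)
      real_scaled <- transform_data(real_tf, real)
      for (i in seq_along(alpha_combos)) {
        ac <- alpha_combos[[i]]
        key <- paste(ac, collapse = "/")
        pairs[[key]] <- retrain_class_gans(pretrained, real_scaled, retrain_cfg,
                                           hyper, alpha_under = ac[1],
                                           alpha_over = ac[2],
                                           seed = derive_seed(dseed, i))
      }
    }

    eval_one <- function(mode, gans, eseed) {
      first_balanced <- apply_balancing(real, mode, gans = gans,
                                        transformer = real_tf,
                                        multiplier = multiplier,
                                        seed = derive_seed(eseed, 0L))
      tuned <- tune_classifier(first_balanced, grid, seed = derive_seed(eseed, 1L))
      evaluate_balancing(real, validation, mode, tuned, gans = gans,
                         transformer = real_tf, n_iterations = n_iterations,
                         multiplier = multiplier, seed = derive_seed(eseed, 2L))
    }

    reports <- list()
    best_alpha <- list()
    for (m in methods) {
      if (m %in% gan_methods) {
        combos <- if (m == "gan_balance") {
          # balance mode only draws from the minority generator, so only the
          # under-class alpha matters: deduplicate on it
          unique_unders <- unique(vapply(alpha_combos, `[`, numeric(1), 1))
          lapply(unique_unders, function(u) {
            keys <- names(pairs)[vapply(alpha_combos, `[`, numeric(1), 1) == u]
            keys[1]
          })
        } else {
          as.list(names(pairs))
        }
        combo_reports <- list()
        for (key in combos) {
          combo_reports[[key]] <- eval_one(m, pairs[[key]],
                                           derive_seed(dseed, 50L + match(m, methods) * 10L +
                                                         match(key, names(pairs))))
        }
        sel <- select_alpha_combination(combo_reports)
        best_alpha[[m]] <- sel$combination
        reports[[m]] <- sel$report
        reports[[m]]$alpha_combination <- sel$combination
        reports[[m]]$all_combinations <- combo_reports
      } else {
        reports[[m]] <- eval_one(m, NULL,
                                 derive_seed(dseed, 50L + match(m, methods) * 10L))
      }
    }
    comparison <- if (length(reports) >= 2) compare_methods(reports) else NULL
    list(design = design, reports = reports,
         comparison = comparison, best_alpha = best_alpha)
      }),
      error = function(e) {
        # a failed design is recorded and the grid continues
        n_failed <<- n_failed + 1L
        warning("design ", d, " failed: ", conditionMessage(e), call. = FALSE)
        list(design = designs[[d]], error = conditionMessage(e))
      })
  }

  manifest <- list(seed = seed, sim_config = sim_config,
                   methods = methods, n_iterations = n_iterations,
                   multiplier = multiplier,
                   designs = lapply(designs, unclass),
                   n_failed_designs = n_failed,
                   package_version = as.character(utils::packageVersion("ganbalance")))
  list(results = results, manifest = manifest)
}
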