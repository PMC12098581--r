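## End-to-end orchestration: load or simulate a dataset, run both
## clustering tracks, evaluate cluster quality in each track's latent
## space, profile the clusters, and write per-stage artifacts.

#' Load and validate an item-response dataset
#'
#' Expects the generator's CSV schema: `participant_id`, `age`, then the
#' 54 item columns named `<subtest>_<k>`. Types and ranges are enforced
#' per the instrument schema; violations name the offending column.
#'
#' @param path CSV file path.
#' @return A validated data frame (class `item_dataset`).
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  sch <- item_schema()
  expected <- c("participant_id", "age", sch$name)
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$age)) || any(df$age < 0)) {
    stop("schema error: column age must be nonnegative", call. = FALSE)
  }
  for (j in seq_len(nrow(sch))) {
    v <- df[[sch$name[j]]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("schema error: column ", sch$name[j], " must be numeric",
           call. = FALSE)
    }
    ok <- switch(sch$scale[j],
                 binary = all(v %in% c(0, 1)),
                 unit_interval = all(v >= 0 & v <= 1),
                 nonnegative_continuous = all(v >= 0))
    if (!ok) {
      stop("range error: column ", sch$name[j], " violates scale ",
           sch$scale[j], call. = FALSE)
    }
  }
  class(df) <- c("item_dataset", class(df))
  df
}

#' Comparison configuration
#'
#' @param simulate list with `n`, `seed` and optionally `mode`
#'   (`"fmm"`/`"profiles"`) describing the synthetic dataset, or `NULL`
#'   when `data_path` is given.
#' @param data_path CSV input (ignored when `simulate` is given).
#' @param class_grid,factor_grid ladder grids.
#' @param ladder_restarts EM restarts per ladder cell.
#' @param cgmvae a [cgmvae_config()] for the deep track.
#' @param min_cluster_n small-cluster reporting filter.
#' @param seed master seed.
#' @export
compare_config <- function(simulate = list(n = 1000L, seed = 1L,
                                           mode = "fmm"),
                           data_path = NULL, class_grid = 1:2,
                           factor_grid = 1L, ladder_restarts = 2L,
                           cgmvae = cgmvae_config(hidden_dim = 48L,
                                                  latent_dim = 8L,
                                                  n_components = 4L,
                                                  epochs = 15L),
                           min_cluster_n = 10L, seed = 1L) {
  structure(as.list(environment()), class = "compare_config")
}

#' Read a comparison configuration from YAML
#'
#' Field names mirror [compare_config()]; the `cgmvae` block mirrors
#' [cgmvae_config()].
#'
#' @param path YAML file.
#' @export
read_compare_config <- function(path) {
  y <- yaml::read_yaml(path)
  cg <- do.call(cgmvae_config, y$cgmvae %||% list())
  y$cgmvae <- NULL
  do.call(compare_config, c(y, list(cgmvae = cg)))
}

#' Run the two-track comparison
#'
#' Simulates (or loads) a dataset, runs the model ladder and keeps the
#' BIC winner, trains the CGMVAE, computes cluster quality for both
#' solutions in their own latent spaces (posterior expected factor scores
#' for the mixture model; deterministic encoder embeddings for the
#' CGMVAE), and profiles the CGMVAE clusters in feature space with the
#' small-cluster filter. Per-stage artifacts (CSV/JSON) are written under
#' `outdir` when given. A failing stage is recorded in the report rather
#' than raised.
#'
#' @param config a [compare_config()].
#' @param outdir optional artifact directory.
#' @return Object of class `comparison_report`.
#' @export
run_compare <- function(config = compare_config(), outdir = NULL) {
  stopifnot(inherits(config, "compare_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  report <- list(config = list(seed = config$seed,
                               class_grid = config$class_grid,
                               factor_grid = config$factor_grid),
                 stages = list(), failures = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      report$failures[[name]] <<- conditionMessage(e)
      NULL
    })
    report$stages[[name]] <<-
      list(seconds = as.numeric(Sys.time() - tic, units = "secs"),
           ok = is.null(report$failures[[name]]))
    out
  }
  ## -- data ---------------------------------------------------------------
  sim <- NULL
  data <- stage("data", {
    if (!is.null(config$simulate)) {
      s <- config$simulate
      sim <- if (identical(s$mode %||% "fmm", "profiles")) {
        simulate_profiles(s$n, seed = s$seed)
      } else {
        simulate_fmm1(s$n, seed = s$seed)
      }
      if (!is.null(outdir)) {
        write_dataset(sim, file.path(outdir, "dataset.csv"),
                      file.path(outdir, "labels.csv"))
      }
      sim$data
    } else {
      if (is.null(config$data_path)) {
        stop("config needs either a simulate block or data_path",
             call. = FALSE)
      }
      load_dataset(config$data_path)
    }
  })
  if (is.null(data)) return(.finish_report(report, t0, outdir))
  bins <- bin_ages(data$age)
  ## -- model ladder --------------------------------------------------------
  ladder <- stage("ladder", {
    model_ladder(data, covariate = bins$code,
                 class_grid = config$class_grid,
                 factor_grid = config$factor_grid,
                 restarts = config$ladder_restarts, seed = config$seed)
  })
  if (!is.null(ladder)) {
    report$ladder <- ladder$table
    report$winner <- as.list(ladder$winner)
    if (!is.null(outdir)) {
      utils::write.csv(ladder$table, file.path(outdir, "ladder.csv"),
                       row.names = FALSE)
    }
    fit <- ladder$winner_fit
    if (!is.null(fit)) {
      sm <- summary(fit)
      report$fmm <- list(
        variant = fit$spec$variant, K = fit$spec$K, F = fit$spec$F,
        loglik = fit$loglik, BIC = fit$BIC, AIC = fit$AIC,
        class_proportions = as.numeric(sm$class_proportions),
        alpha = as.numeric(fit$params$alpha[, 1L]),
        gamma0 = fit$params$gamma0, gamma1 = fit$params$gamma1,
        odds_ratios = sm$odds_ratios)
      fmm_space <- predict(fit, type = "factor_score")
      fmm_labels <- predict(fit, type = "class")
      q_fmm <- stage("fmm_quality", {
        quality_report(fmm_space, labels = fmm_labels,
                       U = fit$responsibilities, space = "factor scores")
      })
      report$fmm_quality <- unclass_quality(q_fmm)
    }
  }
  ## -- CGMVAE --------------------------------------------------------------
  vae <- stage("cgmvae", {
    cf <- config$cgmvae
    cf$seed <- config$seed
    cgmvae(data, cf)
  })
  if (!is.null(vae)) {
    report$cgmvae <- list(best_epoch = vae$best_epoch,
                          best_val = vae$best_val,
                          config = list(latent_dim = vae$config$latent_dim,
                                        n_components =
                                          vae$config$n_components,
                                        epochs = vae$config$epochs))
    if (!is.null(outdir)) {
      utils::write.csv(vae$history, file.path(outdir, "cgmvae_history.csv"),
                       row.names = FALSE)
    }
    U <- membership(vae)
    emb <- latent_embedding(vae)
    labels <- max.col(U, ties.method = "first")
    q_vae <- stage("cgmvae_quality", {
      quality_report(emb, labels = labels, U = U, space = "latent embedding")
    })
    report$cgmvae_quality <- unclass_quality(q_vae)
    prof <- stage("profile", {
      p <- cluster_feature_zscores(data, labels, bin = bins$bin)
      filter_small_clusters(p, config$min_cluster_n)
    })
    if (!is.null(prof)) {
      report$profile <- list(clusters = prof$clusters, n = prof$n,
                             z = prof$z,
                             age_distribution = prof$age_distribution)
      if (!is.null(outdir)) {
        utils::write.csv(data.frame(cluster = prof$clusters, n = prof$n,
                                    prof$z, check.names = FALSE),
                         file.path(outdir, "profiles.csv"),
                         row.names = FALSE)
      }
    }
    if (!is.null(outdir)) {
      utils::write.csv(data.frame(participant_id = data$participant_id,
                                  label = labels, U, check.names = FALSE),
                       file.path(outdir, "memberships.csv"),
                       row.names = FALSE)
    }
  }
  .finish_report(report, t0, outdir)
}

unclass_quality <- function(q) {
  if (is.null(q)) return(NULL)
  q <- unclass(q)
  q$flags <- NULL
  lapply(q, function(v) if (is.numeric(v)) as.numeric(v) else v)
}

.finish_report <- function(report, t0, outdir) {
  report$elapsed_seconds <- as.numeric(Sys.time() - t0, units = "secs")
  report <- structure(report, class = "comparison_report")
  if (!is.null(outdir)) {
    save_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' Serialize / restore a comparison report
#'
#' @param report a `comparison_report`.
#' @param path JSON file path.
#' @export
save_report <- function(report, path) {
  out <- tryCatch(
    jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE),
    error = function(e) stop("cannot write report: ", conditionMessage(e),
                             call. = FALSE))
  invisible(path)
}

unclass_report <- function(report) {
  r <- unclass(report)
  if (!is.null(r$ladder)) r$ladder <- as.data.frame(r$ladder)
  if (!is.null(r$profile$z)) {
    r$profile$z <- as.data.frame(r$profile$z)
  }
  if (!is.null(r$profile$age_distribution)) {
    r$profile$age_distribution <- as.data.frame(
      as.matrix(r$profile$age_distribution))
  }
  r
}

#' @rdname save_report
#' @export
load_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "comparison_report")
}

#' Human-readable summary of a comparison report
#'
#' @param report a `comparison_report`.
#' @return Character vector of lines (also usable via `print`).
#' @export
render_summary <- function(report) {
  ln <- character(0)
  push <- function(...) ln <<- c(ln, sprintf(...))
  push("two-track cluster comparison")
  if (length(report$failures)) {
    for (nm in names(report$failures)) {
      push("stage %s FAILED: %s", nm, report$failures[[nm]])
    }
  }
  if (!is.null(report$winner)) {
    push("ladder winner: %s (K = %s, F = %s), BIC %.2f",
         report$winner$model, report$winner$K, report$winner$F,
         report$winner$BIC)
  }
  if (!is.null(report$fmm)) {
    push("class proportions: %s",
         paste(sprintf("%.1f%%", 100 * report$fmm$class_proportions),
               collapse = ", "))
    if (!is.null(report$fmm$gamma1) && length(report$fmm$gamma1)) {
      or <- odds_ratio_from_coefficient(report$fmm$gamma1[1L])
      push("age effect (class 1 vs %d): slope %.3f, OR %.3f (%+.1f%%)",
           length(report$fmm$gamma1) + 1L, report$fmm$gamma1[1L],
           or$odds_ratio, or$percent_change)
    }
  }
  fmt_q <- function(q, label) {
    if (is.null(q)) return()
    push("%s: Silhouette %.3f | Calinski-Harabasz %.3f | Davies-Bouldin %.3f",
         label, q$silhouette, q$calinski_harabasz, q$davies_bouldin)
    if (!is.null(q$xie_beni)) {
      push("%s: Xie-Beni %.3f | partition coefficient %.3f | partition entropy %.3f",
           label, q$xie_beni, q$fpc, q$partition_entropy)
    }
  }
  fmt_q(report$fmm_quality, "FMM quality")
  fmt_q(report$cgmvae_quality, "CGMVAE quality")
  if (!is.null(report$cgmvae)) {
    push("CGMVAE best validation loss %.4f (epoch %d)",
         report$cgmvae$best_val, report$cgmvae$best_epoch)
  }
  ln
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(paste(render_summary(x), collapse = "\n"), "\n")
  invisible(x)
}
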