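#' Strategy names for the shimming comparison
#' @return Character vector of the seven strategies.
#' @export
shim_strategies <- function() {
  c("measured", "individual_registered", "averaged_registered",
    "individual_fixed", "averaged_fixed", "random", "tuneup")
}

#' Leave-one-out cross-validated comparison of shimming strategies
#'
#' For each subject in the cohort, a field-map template and all
#' database-derived quantities (individual fixed shims, their average,
#' the random-shim ranges) are computed from the remaining subjects only —
#' no information from the held-out subject leaks into its own
#' evaluation. Each requested strategy then produces a shim for the
#' held-out subject, and the residual field standard deviation over that
#' subject's true field and brain mask is recorded. The per-individual
#' and random strategies yield a whole distribution per subject.
#'
#' Strategies: `measured` (shim fit to the subject's own field — the
#' least-squares optimum), `individual_registered` (another subject's
#' field warped into this subject's space, one shim per donor),
#' `averaged_registered` (the template mean warped into subject space —
#' the template-based prediction), `individual_fixed` (another subject's
#' own optimal shim applied unchanged), `averaged_fixed` (termwise mean
#' of the training fixed shims), `random` (uniform draws within the
#' training per-term min/max), and `tuneup` (no subject-specific shim;
#' represented by the all-zero setting on synthetic data, since no
#' phantom calibration exists here).
#'
#' @param cohort An [sample_cohort()] result.
#' @param strategies Subset of [shim_strategies()].
#' @param max_order Shim order (1, 2 or 3).
#' @param n_random Random-shim draws per subject.
#' @param transform_source `"true"` uses the cohort's recorded
#'   subject-to-standard transforms; `"register"` estimates each by
#'   registering the subject structural to the standard anatomy (12 dof).
#' @param seed Seed for the random-shim draws.
#' @return Object of class `shim_evaluation`: `results` (one row per
#'   subject x strategy, distribution strategies summarized by their
#'   mean), `distributions` (long format), `shims` (per-subject settings
#'   for the point strategies), `summary` (per-strategy mean and
#'   quartiles across subjects).
#' @export
loocv_evaluate <- function(cohort,
                           strategies = shim_strategies(),
                           max_order = 2L, n_random = 100L,
                           transform_source = c("true", "register"),
                           seed = NULL) {
  transform_source <- match.arg(transform_source)
  strategies <- match.arg(strategies, shim_strategies(),
                          several.ok = TRUE)
  subjects <- cohort$subjects
  n <- length(subjects)
  if (n < 3L)
    stop_fieldshim("leave-one-out evaluation needs >= 3 subjects",
                   "fs_invalid_argument")
  seed <- seed %||% (cohort$config$seed + 7919L)
  grid <- cohort$standard$grid
  basis <- build_basis(grid, max_order)
  ids <- vapply(subjects, `[[`, "", "id")

  transforms <- lapply(subjects, function(s) {
    if (transform_source == "true") s$transform
    else register(s$structural, cohort$standard$structural, dof = 12L,
                  source_space = "subject", target_space = "standard")
  })
  fixed_shims <- lapply(subjects, function(s)
    compute_shim(s$field_true, basis, s$brain_mask, max_order))

  rows <- list(); dists <- list(); shims_out <- list()
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (i %in% train)
      stop_fieldshim("leakage guard tripped: held-out subject in training",
                     "fs_leakage")
    si <- subjects[[i]]
    mask_i <- si$brain_mask
    res_of <- function(shim) residual_std(si$field_true, shim, basis,
                                          mask_i)
    add_row <- function(strategy, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = si$id, strategy = strategy, residual_std_Hz = value,
        stringsAsFactors = FALSE)
    add_dist <- function(strategy, sample_ids, values)
      dists[[length(dists) + 1L]] <<- data.frame(
        subject = si$id, strategy = strategy, sample = sample_ids,
        residual_std_Hz = values, stringsAsFactors = FALSE)
    shim_i <- list()

    if ("measured" %in% strategies) {
      sh <- compute_shim(si$field_true, basis, mask_i, max_order)
      shim_i$measured <- sh
      add_row("measured", res_of(sh))
    }
    template_i <- NULL
    if ("averaged_registered" %in% strategies) {
      template_i <- build_template(
        lapply(train, function(j) list(field = subjects[[j]]$field_true,
                                       transform = transforms[[j]])),
        grid)
      if (template_i$n != n - 1L)
        stop_fieldshim("leakage guard tripped: template size mismatch",
                       "fs_leakage")
      pred <- predict_fieldmap(template_i, si$structural,
                               subject_grid = grid,
                               transform = transforms[[i]])
      fit_mask <- mask_i & pred$brain_mask
      sh <- compute_shim(pred, basis, fit_mask, max_order)
      shim_i$averaged_registered <- sh
      add_row("averaged_registered", res_of(sh))
    }
    if ("individual_registered" %in% strategies) {
      vals <- vapply(train, function(j) {
        t_ji <- compose(transforms[[j]], invert(transforms[[i]]))
        wf <- resample(subjects[[j]]$field_true, t_ji, grid, "trilinear")
        wm <- resample(volume(subjects[[j]]$brain_mask, grid), t_ji,
                       grid, "nearest")$values
        fit_mask <- mask_i & wm & !is.na(wf$values)
        wf$values[is.na(wf$values)] <- 0
        sh <- compute_shim(field_map(wf$values, grid), basis, fit_mask,
                           max_order)
        res_of(sh)
      }, 0)
      add_dist("individual_registered", ids[train], vals)
      add_row("individual_registered", mean(vals))
    }
    if ("individual_fixed" %in% strategies) {
      vals <- vapply(train, function(j) res_of(fixed_shims[[j]]), 0)
      add_dist("individual_fixed", ids[train], vals)
      add_row("individual_fixed", mean(vals))
    }
    if ("averaged_fixed" %in% strategies) {
      sh <- averaged_fixed_shim(fixed_shims[train])
      shim_i$averaged_fixed <- sh
      add_row("averaged_fixed", res_of(sh))
    }
    if ("random" %in% strategies) {
      rng <- shim_range(fixed_shims[train])
      draws <- random_shims(n_random, rng, seed = seed + i)
      vals <- residual_std_many(si$field_true, shim_matrix(draws),
                                colnames(rng), basis, mask_i)
      add_dist("random", seq_len(n_random), vals)
      add_row("random", mean(vals))
    }
    if ("tuneup" %in% strategies) {
      sh <- zero_shim(max_order)
      shim_i$tuneup <- sh
      add_row("tuneup", res_of(sh))
    }
    shims_out[[si$id]] <- shim_i
  }
  results <- do.call(rbind, rows)
  distributions <- if (length(dists)) do.call(rbind, dists) else NULL
  summary <- do.call(rbind, lapply(split(results, results$strategy),
                                   function(df) data.frame(
    strategy = df$strategy[1], mean_Hz = mean(df$residual_std_Hz),
    median_Hz = median(df$residual_std_Hz),
    q25_Hz = unname(quantile(df$residual_std_Hz, 0.25)),
    q75_Hz = unname(quantile(df$residual_std_Hz, 0.75)),
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(results = results, distributions = distributions,
                 shims = shims_out, summary = summary,
                 max_order = as.integer(max_order),
                 transform_source = transform_source, n_subjects = n),
            class = "shim_evaluation")
}

#' @export
print.shim_evaluation <- function(x, ...) {
  cat(sprintf(
    "<shim_evaluation> %d subjects, order %d, transforms: %s\n",
    x$n_subjects, x$max_order, x$transform_source))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
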