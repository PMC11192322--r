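# Spatial (leave-region-out) cross-validation, Brier/RMSE scoring, and
# prevalence prediction intervals.

#' Leave-one-region-out folds from a region partition
#'
#' Each fold holds out all field visits in one region and trains on the rest.
#' Regions with zero locations are dropped with a warning.
#'
#' @param points point set of the field-visit locations.
#' @param labels region label per location (factor or character).
#' @return Object of class `region_folds`: list of folds, each with
#'   `region`, `train` and `test` index vectors.
#' @export
make_folds <- function(points, labels) {
  points <- as_points(points)
  labels <- as.character(labels)
  if (length(labels) != nrow(points))
    stop("need one region label per location")
  regions <- unique(labels)
  counts <- table(labels)
  empty <- setdiff(regions, names(counts)[counts > 0])
  if (length(empty)) {
    warning("dropping empty regions: ", paste(empty, collapse = ", "))
    regions <- setdiff(regions, empty)
  }
  if (length(regions) < 2)
    stop("need at least 2 non-empty regions for leave-region-out validation")
  folds <- lapply(regions, function(r) {
    test <- which(labels == r)
    list(region = r, test = test, train = setdiff(seq_along(labels), test))
  })
  structure(list(folds = folds, labels = labels, points = points),
            class = "region_folds")
}

#' Leave-region-out cross-validated occurrence predictions
#'
#' For each fold, refits the requested model on the training field visits and
#' computes the held-out posterior predictive occurrence probability at the
#' test locations. By default only species field visits are held out; the
#' abiotic measurements remain available to every fold (they are typically a
#' separate survey with full coverage). Pass `abiotic_labels` to additionally
#' remove abiotic observations inside the held-out region
#' (`hold_out_abiotic = TRUE`).
#'
#' @param kind "direct", "two_stage" or "joint".
#' @param species a [species_observations()].
#' @param abiotic named list of `field_realization`s (empty for direct).
#' @param spec an [sdm_spec()].
#' @param folds a [make_folds()] result on the species locations.
#' @param priors,inference see [fit_two_stage()].
#' @param hold_out_abiotic also hold out abiotic observations by region.
#' @param abiotic_labels region label per abiotic observation (required when
#'   `hold_out_abiotic = TRUE`).
#' @param n_draws held-out posterior draws kept per location.
#' @return Object of class `cv_predictions`: data frame `pred` (location,
#'   region, fold, y, mu_mean), matrix `mu_draws` (locations x draws, rows in
#'   the original location order), and metadata including the held-out-unit
#'   policy. Failed folds are flagged and their locations marked missing.
#' @export
cross_validate <- function(kind = c("two_stage", "joint", "direct"),
                           species, abiotic = list(), spec, folds,
                           priors = prior_config(),
                           inference = inference_config(),
                           hold_out_abiotic = FALSE, abiotic_labels = NULL,
                           n_draws = 200) {
  kind <- match.arg(kind)
  stopifnot(inherits(folds, "region_folds"),
            inherits(species, "species_observations"))
  if (hold_out_abiotic && length(abiotic) > 0 && is.null(abiotic_labels))
    stop("hold_out_abiotic = TRUE requires abiotic_labels")
  N <- length(species$y)
  mu_mean <- rep(NA_real_, N)
  mu_draws <- matrix(NA_real_, N, n_draws)
  fold_id <- rep(NA_integer_, N)
  failed <- character(0)
  for (fi in seq_along(folds$folds)) {
    fd <- folds$folds[[fi]]
    tr <- fd$train; te <- fd$test
    sp_tr <- species_observations(
      points_df(species$points$x[tr], species$points$y[tr]),
      species$y[tr],
      if (!is.null(species$covariates)) species$covariates[tr, , drop = FALSE])
    ab <- abiotic
    if (hold_out_abiotic && length(ab) > 0) {
      keep <- abiotic_labels != fd$region
      ab <- lapply(ab, function(f)
        field_realization(points_df(f$points$x[keep], f$points$y[keep]),
                          f$values[keep], f$seed))
    }
    res <- tryCatch({
      fit <- switch(kind,
        direct = fit_direct(sp_tr, spec, inference),
        two_stage = fit_two_stage(sp_tr, ab, spec, priors, inference),
        joint = fit_joint(sp_tr, ab, spec, priors, inference))
      newcov <- if (!is.null(species$covariates))
        species$covariates[te, , drop = FALSE] else NULL
      pr <- sdm_predict_eta_draws(
        fit, points_df(species$points$x[te], species$points$y[te]),
        new_known_cov = newcov, n_draws = n_draws,
        seed = inference$seed + fi)
      stats::plogis(pr$eta)
    }, error = function(e) {
      warning(sprintf("fold %s failed: %s", fd$region, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, fd$region); next }
    mu_draws[te, ] <- res
    mu_mean[te] <- rowMeans(res)
    fold_id[te] <- fi
  }
  structure(list(
    pred = data.frame(location = seq_len(N), region = folds$labels,
                      fold = fold_id, y = species$y, mu_mean = mu_mean),
    mu_draws = mu_draws, failed_regions = failed, kind = kind,
    hold_out_abiotic = hold_out_abiotic), class = "cv_predictions")
}

#' Root-mean-square error of probability predictions (root Brier score)
#'
#' `sqrt(mean((y - E[mu])^2))`: the square root of the Brier score, a proper
#' scoring rule for binary outcomes measuring both discrimination and
#' calibration. Bounded in [0, 1] when `mu_mean` is in [0, 1].
#'
#' @param y binary 0/1 outcomes.
#' @param mu_mean predicted occurrence probabilities in [0, 1].
#' @return RMSE (scalar).
#' @export
rmse_score <- function(y, mu_mean) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(mu_mean)) stop("lengths differ")
  if (any(mu_mean < 0 | mu_mean > 1, na.rm = TRUE))
    stop("mu_mean must be in [0, 1]")
  sqrt(mean((y - mu_mean)^2))
}

#' Per-region prevalence prediction intervals
#'
#' Samples occurrence-probability vectors from the (cross-validated) joint
#' posterior, then samples 0/1 occurrences from them, and summarizes the
#' distribution of region prevalence: the prediction interval therefore
#' carries both posterior and binomial sampling uncertainty. True prevalence
#' is the observed fraction of visits with the species present.
#'
#' @param cv a `cv_predictions` object.
#' @param n_samples prevalence samples (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return Data frame with one row per region: `region`, `n`,
#'   `true_prevalence`, `predicted_mean`, `q2.5`, `q97.5`.
#' @export
prevalence_intervals <- function(cv, n_samples = 1000, seed = 1L) {
  stopifnot(inherits(cv, "cv_predictions"))
  if (n_samples < 100)
    warning("fewer than 100 samples; prevalence intervals will be noisy")
  ok <- !is.na(cv$pred$mu_mean)
  regions <- unique(cv$pred$region[ok])
  nd <- ncol(cv$mu_draws)
  with_seed(seed, {
    out <- lapply(regions, function(r) {
      idx <- which(cv$pred$region == r & ok)
      prev <- numeric(n_samples)
      for (s in seq_len(n_samples)) {
        mu <- cv$mu_draws[idx, sample.int(nd, 1)]
        prev[s] <- mean(stats::rbinom(length(idx), 1, mu))
      }
      data.frame(region = r, n = length(idx),
                 true_prevalence = mean(cv$pred$y[idx]),
                 predicted_mean = mean(prev),
                 q2.5 = unname(stats::quantile(prev, 0.025)),
                 q97.5 = unname(stats::quantile(prev, 0.975)))
    })
    do.call(rbind, out)
  })
}
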