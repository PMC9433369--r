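# Seeded Monte-Carlo grid over the 12-cell simulation design
# (3 error-correlation levels x 2 error magnitudes x 2 model versions) and
# the strong-condition verification suite.

# Deterministic sub-seed derivation; keeps every stream independent of which
# other cells run, and below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed %% 65011, ...)
  acc <- 104729
  for (x in parts) acc <- (acc * 3331 + (x + 1) * 7907) %% 2147483629
  as.integer(acc)
}

#' Configuration for the simulation grid
#'
#' Defaults mirror the study design: `n = 200`, `p = 12`, `m = 3`, all three
#' correlation levels, both error magnitudes, both model versions, all four
#' estimators.
#'
#' @param n,p,m data dimensions (`n > p > m`).
#' @param reps replications per cell.
#' @param versions subset of `c("N", "R")`.
#' @param corr_levels subset of `c("CN", "CL", "CH")`.
#' @param error_levels subset of `c("EL", "EH")`.
#' @param methods subset of `c("LVFA-LS", "LVFA-ML", "MDFA", "CDFA")`.
#' @param seed integer master seed.
#' @param drop_improper exclude covariances with improper least-squares
#'   solutions from the LS-vs-ML comparison.
#' @param opts [compfa_options()] passed to the fitters.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(n = 200L, p = 12L, m = 3L, reps = 50L,
                        versions = c("N", "R"),
                        corr_levels = c("CN", "CL", "CH"),
                        error_levels = c("EL", "EH"),
                        methods = c("LVFA-LS", "LVFA-ML", "MDFA", "CDFA"),
                        seed = 1L, drop_improper = TRUE,
                        opts = compfa_options()) {
  stopifnot(reps >= 1, n > p, p > m, m >= 1)
  versions <- match.arg(versions, c("N", "R"), several.ok = TRUE)
  corr_levels <- match.arg(corr_levels, c("CN", "CL", "CH"), several.ok = TRUE)
  error_levels <- match.arg(error_levels, c("EL", "EH"), several.ok = TRUE)
  methods <- match.arg(methods, c("LVFA-LS", "LVFA-ML", "MDFA", "CDFA"),
                       several.ok = TRUE)
  structure(
    list(n = as.integer(n), p = as.integer(p), m = as.integer(m),
         reps = as.integer(reps), versions = versions,
         corr_levels = corr_levels, error_levels = error_levels,
         methods = methods, seed = as.integer(seed),
         drop_improper = drop_improper, opts = opts),
    class = "grid_config"
  )
}

fit_one <- function(method, cov, m, opts) {
  switch(method,
         "LVFA-LS" = fit_lvfa_ls(cov, m, opts),
         "LVFA-ML" = fit_lvfa_ml(cov, m, opts),
         "MDFA" = fit_mdfa(cov, m, opts),
         "CDFA" = fit_cdfa(cov, m, opts),
         stop("unknown method ", method))
}

#' Run the Monte-Carlo recovery grid
#'
#' For each replication one shared truth (loadings, specific variances, and
#' the diagonal error scaffold) is drawn; an error correlation matrix is
#' drawn once per correlation level; each of the design cells then realizes
#' its covariance and every requested estimator is fitted to it. Loadings are
#' Procrustes-aligned to the truth before the mean-absolute-difference
#' metrics are computed. Fully reproducible from `config$seed`; a hard
#' failure in one estimator aborts only that cell's record.
#'
#' @param config a [grid_config()].
#' @return A list of class `compfa_grid`: `results` (tibble, one row per
#'   replication x cell x method), `percov` (tibble, one row per
#'   replication x cell with the Delta statistic and the LS/ML agreement
#'   measures), and `config`.
#' @export
run_grid <- function(config = grid_config()) {
  p <- config$p
  m <- config$m
  n <- config$n
  opts <- config$opts
  cells <- expand.grid(version = config$versions,
                       corr_level = config$corr_levels,
                       error_level = config$error_levels,
                       stringsAsFactors = FALSE)

  res <- vector("list", config$reps)
  pc <- vector("list", config$reps)
  for (rep_i in seq_len(config$reps)) {
    set.seed(derive_seed(config$seed, rep_i, 0))
    truth <- draw_truth(p, m)
    d_r <- stats::runif(p, 0.1, 0.8)
    phis <- list()
    for (cl in config$corr_levels) {
      set.seed(derive_seed(config$seed, rep_i, match(cl, c("CN", "CL", "CH"))))
      phis[[cl]] <- build_error_cov(p, cl, d_r)
    }
    rows <- list()
    prows <- list()
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      phi <- phis[[cell$corr_level]]
      alpha <- scale_errors(phi, truth$loadings, cell$error_level)
      set.seed(derive_seed(config$seed, rep_i, 10 + ci))
      sim <- if (cell$version == "N") {
        gen_cov_nonrandom(truth, n, phi, alpha)
      } else {
        gen_cov_random(truth, n, phi, alpha)
      }
      ref2 <- truth$theta2
      ref2d <- truth$theta2 + sim$dee_true
      fits <- list()
      for (method in config$methods) {
        fit <- tryCatch(fit_one(method, sim$cov, m, opts),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          warning("cell (", rep_i, ", ", paste(cell, collapse = "/"),
                  ") method ", method, " failed: ", conditionMessage(fit))
          next
        }
        fits[[method]] <- fit
        aligned <- procrustes_align(fit$loadings, truth$loadings)$rotated
        rows[[length(rows) + 1L]] <- tibble::tibble(
          replication = rep_i,
          version = cell$version,
          corr_level = cell$corr_level,
          error_level = cell$error_level,
          method = method,
          mad_lambda = mad_loadings(aligned, truth$loadings),
          mad_theta2 = mad_diag(fit$diag_var, ref2),
          mad_theta2_dee = mad_diag(fit$diag_var, ref2d),
          loss = fit$loss,
          converged = fit$converged,
          proper = fit$proper
        )
      }
      delta <- if (all(c("LVFA-ML", "MDFA") %in% names(fits))) {
        delta_stat(mad_diag(fits[["LVFA-ML"]]$diag_var, ref2),
                   mad_diag(fits[["MDFA"]]$diag_var, ref2))
      } else NA_real_
      lsml_l <- lsml_p <- NA_real_
      ls_proper <- NA
      if (all(c("LVFA-LS", "LVFA-ML") %in% names(fits))) {
        Lls <- fits[["LVFA-LS"]]$loadings
        Lml <- fits[["LVFA-ML"]]$loadings
        # align LS to ML: the comparison is of the common-part estimates,
        # which are identified only up to rotation
        Lls <- procrustes_align(Lls, Lml)$rotated
        lsml_l <- mean(abs(Lls - Lml))
        lsml_p <- mean(abs(fits[["LVFA-LS"]]$diag_var -
                             fits[["LVFA-ML"]]$diag_var))
        ls_proper <- fits[["LVFA-LS"]]$proper
      }
      prows[[length(prows) + 1L]] <- tibble::tibble(
        replication = rep_i,
        version = cell$version,
        corr_level = cell$corr_level,
        error_level = cell$error_level,
        delta = delta,
        lsml_loading_diff = lsml_l,
        lsml_psi2_diff = lsml_p,
        ls_proper = ls_proper
      )
    }
    res[[rep_i]] <- dplyr::bind_rows(rows)
    pc[[rep_i]] <- dplyr::bind_rows(prows)
  }
  structure(
    list(results = dplyr::bind_rows(res), percov = dplyr::bind_rows(pc),
         config = config),
    class = "compfa_grid"
  )
}

#' @export
print.compfa_grid <- function(x, ...) {
  cat(sprintf("<compfa_grid> %d replications x %d cells, methods: %s\n",
              x$config$reps,
              length(x$config$versions) * length(x$config$corr_levels) *
                length(x$config$error_levels),
              paste(x$config$methods, collapse = ", ")))
  invisible(x)
}

#' Summarize a simulation grid
#'
#' Computes the study's margin tables from the raw grid results: mean MAD per
#' procedure and reference matrix (with the maximum-likelihood fit standing
#' for the latent-variable procedure), per reference matrix and error level,
#' per model version, the matrix main effects, the Delta-positive count, the
#' LS/ML agreement over proper solutions, and the improper-solution count.
#'
#' @param grid a `compfa_grid` from [run_grid()].
#' @return A list of tibbles and scalars; see details in the grid vignette.
#' @export
summarize_grid <- function(grid) {
  stopifnot(inherits(grid, "compfa_grid"))
  res <- grid$results
  pcv <- grid$percov
  main <- dplyr::filter(res, .data$method %in% c("LVFA-ML", "MDFA", "CDFA")) |>
    dplyr::mutate(procedure = dplyr::recode(.data$method,
                                            "LVFA-ML" = "LVFA"))
  long <- tidyr::pivot_longer(
    main, c("mad_lambda", "mad_theta2", "mad_theta2_dee"),
    names_to = "matrix", values_to = "mad")

  proc_matrix <- long |>
    dplyr::group_by(.data$procedure, .data$matrix) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")
  matrix_error <- long |>
    dplyr::group_by(.data$matrix, .data$error_level) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")
  version <- long |>
    dplyr::group_by(.data$version) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")
  matrix_main <- long |>
    dplyr::group_by(.data$matrix) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")
  cell_means <- long |>
    dplyr::group_by(.data$procedure, .data$matrix, .data$version,
                    .data$corr_level, .data$error_level) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")

  deltas <- pcv$delta[!is.na(pcv$delta)]
  delta_by_corr <- pcv |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::group_by(.data$corr_level) |>
    dplyr::summarise(mean_delta = mean(.data$delta), .groups = "drop")

  lsml <- pcv
  if (isTRUE(grid$config$drop_improper)) {
    lsml <- dplyr::filter(lsml, .data$ls_proper | is.na(.data$ls_proper))
  }
  list(
    cell_means = cell_means,
    proc_matrix = proc_matrix,
    matrix_error = matrix_error,
    version = version,
    matrix_main = matrix_main,
    delta_positive = sum(deltas > 0),
    delta_total = length(deltas),
    delta_mean = if (length(deltas)) mean(deltas) else NA_real_,
    delta_by_corr = delta_by_corr,
    lsml_loading_diff = mean(lsml$lsml_loading_diff, na.rm = TRUE),
    lsml_psi2_diff = mean(lsml$lsml_psi2_diff, na.rm = TRUE),
    improper_count = sum(!pcv$ls_proper, na.rm = TRUE)
  )
}

#' Strong-condition verification suite
#'
#' Repeatedly builds covariances whose realized error scatter is exactly
#' diagonal and checks that every estimator fits them perfectly: losses near
#' zero, diagonal-variance estimates equal to the generating specific
#' variances plus the injected error variances, and the common part equal to
#' the generating one.
#'
#' @param p,m dimensions.
#' @param reps number of replications.
#' @param seed integer seed.
#' @param methods estimators to check.
#' @param loss_tol,param_tol tolerances for the loss and parameter identities.
#' @return A tibble with one row per replication x method: the loss, the
#'   maximum deviations of the diagonal variances and the common part, and a
#'   `pass` flag.
#' @export
run_strong_condition_suite <- function(p = 12L, m = 3L, reps = 20L, seed = 1L,
                                       methods = c("LVFA-LS", "LVFA-ML",
                                                   "MDFA", "CDFA"),
                                       loss_tol = 1e-8, param_tol = 1e-5) {
  rows <- list()
  for (rep_i in seq_len(reps)) {
    set.seed(derive_seed(seed, rep_i, 99))
    truth <- draw_truth(p, m)
    alpha <- scale_errors(diag(stats::runif(p, 0.1, 0.8), p), truth$loadings,
                          "EL")
    dee <- alpha^2 * stats::runif(p, 0.1, 0.8)
    sim <- gen_strong_condition_cov(truth, dee, n = 200L)
    target_diag <- truth$theta2 + dee
    LLt <- tcrossprod(truth$loadings)
    for (method in methods) {
      fit <- fit_one(method, sim$cov, m, compfa_options())
      dev_diag <- max(abs(fit$diag_var - target_diag))
      dev_common <- max(abs(tcrossprod(fit$loadings) - LLt))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replication = rep_i, method = method, loss = fit$loss,
        dev_diag_var = dev_diag, dev_common = dev_common,
        pass = fit$loss < loss_tol && dev_diag < param_tol &&
          dev_common < param_tol
      )
    }
  }
  dplyr::bind_rows(rows)
}
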