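# End-to-end desk-scale study: apo vs ligand-perturbed flip model -> HLDA
# training -> OneOPES ladder -> FES on (HLDA, hydration) -> dG, ddG,
# convergence, and trajectory analytics.

#' Configure the two-condition flip study
#'
#' Defaults re-enact the published experiment in miniature: the apo landscape
#' has a free-energy gap of -10.9 kJ/mol (-2.6 kcal/mol) between stacked and
#' bulged basins, and the ligand term of 12.6 kJ/mol shifts the holo gap to
#' about -23.4 kJ/mol (-5.6 kcal/mol). Holo and apo share everything except
#' the ligand strength, and the holo condition reuses the apo-trained HLDA CV
#' (the ligand is assumed to retain its binding mode in both states).
#'
#' @param delta_g_target apo free-energy gap in kJ/mol
#' @param ligand_strength holo ligand stabilization in kJ/mol
#' @param barrier flip barrier in kJ/mol
#' @param coupling hydration-gate coupling (dimensionless)
#' @param n_replicas ladder size
#' @param n_steps integration steps per replica
#' @param n_train labeled samples per basin for HLDA training
#' @param main_pace,aux_pace deposition paces of the main and auxiliary
#'   layers, scaled to the desk-scale step budget
#' @param seed global seed; per-stage seeds are derived from it
#' @param temperature thermostat temperature in K
#' @param dt,friction integrator parameters
#' @param colvar_stride recording stride
#' @param n_analysis_frames frames embedded for structural analytics
#' @return object of class \code{study_config}
#' @export
study_config <- function(delta_g_target = -10.9, ligand_strength = 12.6,
                         barrier = 20, coupling = 0.2, n_replicas = 8L,
                         n_steps = 8e6, n_train = 2000L,
                         main_pace = 500L, aux_pace = 1000L,
                         seed = 1L, temperature = 300, dt = 0.002,
                         friction = 10, colvar_stride = 100L,
                         n_analysis_frames = 400L) {
  structure(as.list(environment()), class = "study_config")
}

# embed a flip-coordinate series as a 10-site pseudo-structure trajectory:
# site i sits at base_i + d_i * u_i with fixed seeded scatter bases and unit
# directions, so the structural analytics (which need non-collinear frames)
# apply to toy runs
.embed_features <- function(model, x, seed) {
  feats <- feature_map(model, x, noise = TRUE, seed = seed)
  g <- matrix(counter_normals(991, 0, 9, 60), 10, 6)
  base <- g[, 1:3]
  u <- g[, 4:6] / sqrt(rowSums(g[, 4:6]^2))
  arr <- array(0, c(length(x), 10, 3))
  for (k in 1:3) arr[, , k] <- outer(rep(1, length(x)), base[, k]) +
    feats * outer(rep(1, length(x)), u[, k])
  arr
}

.run_condition <- function(config, model, cv_toy, seed) {
  kT <- kT_of(config$temperature)
  ladder <- build_default_ladder(
    cv_toy, toy_aux_cvs(model, min(7L, config$n_replicas - 1L)),
    n_replicas = config$n_replicas, temperature = config$temperature,
    main_barrier = 20, main_pace = config$main_pace,
    aux_barrier = 3, aux_pace = config$aux_pace)
  run <- run_oneopes(ladder, model, config$n_steps, seed = seed,
                     dt = config$dt, friction = config$friction,
                     colvar_stride = config$colvar_stride)
  cv0 <- run$replicas[[1]]$colvar
  burn <- cv0$time > 0.2 * max(cv0$time)   # discard the bias-filling transient
  s <- cv0$cv.hlda[burn]
  hyd <- cv0$y[burn]
  w <- reweight_weights(cv0[burn, ], kT)
  dg <- basin_delta_g(s, w, kT)
  conv <- convergence_report(dg, window = 10L, tolerance = 0.5 * kT)
  surf2d <- fes_2d(s, hyd, w, kT, nbins = 60L,
                   axis_names = c("hlda", "hydration"))
  # structural analytics on an embedded pseudo-structure trajectory
  idx <- round(seq(1, sum(burn), length.out = min(config$n_analysis_frames, sum(burn))))
  arr <- .embed_features(model, cv0$x[burn][idx], seed = seed + 13L)
  cca <- cross_correlation(arr, superpose = FALSE)
  fluct <- rmsf(arr, superpose = FALSE)
  pm <- principal_modes(arr, superpose = FALSE)
  cl <- gromos_cluster(arr[seq(1, dim(arr)[1],
                               length.out = min(120, dim(arr)[1])), , ,
                           drop = FALSE], cutoff = 0.2)
  list(model = model, run = run, delta_g = dg, convergence = conv,
       fes2d = surf2d, cca = cca, rmsf = fluct, modes = pm, clusters = cl,
       weights = w, hlda = s, hydration = hyd)
}

#' Run the full two-condition study
#'
#' Per condition: sample both basins, train (apo) or reuse the HLDA CV, run
#' the OneOPES ladder, reweight replica 0 onto (HLDA, hydration), estimate
#' the basin free-energy difference with its convergence report, and compute
#' the trajectory analytics. Fully reproducible per seed.
#'
#' @param config a \code{study_config}
#' @return object of class \code{study_report}
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  kT <- kT_of(config$temperature)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e)))

  apo <- stage("model_apo", make_flip_model(
    delta_g_target = config$delta_g_target, barrier = config$barrier,
    coupling = config$coupling, ligand_strength = 0,
    temperature = config$temperature))
  holo <- stage("model_holo", make_flip_model(
    delta_g_target = config$delta_g_target, barrier = config$barrier,
    coupling = config$coupling, ligand_strength = config$ligand_strength,
    temperature = config$temperature))

  s_stack <- stage("sample_stacked",
    sample_basin(apo, "stacked", config$n_train, seed = config$seed + 101L))
  s_bulge <- stage("sample_bulged",
    sample_basin(apo, "bulged", config$n_train, seed = config$seed + 202L))
  cv <- stage("train_hlda", train_hlda(s_stack, s_bulge))
  cv_toy <- hlda_as_toy_cv(cv, apo)

  res_apo <- stage("oneopes_apo",
                   .run_condition(config, apo, cv_toy, config$seed + 1000L))
  res_holo <- stage("oneopes_holo",
                    .run_condition(config, holo, cv_toy, config$seed + 2000L))

  ddg <- res_holo$delta_g$delta_g - res_apo$delta_g$delta_g
  ddg_err <- sqrt(sum(c(res_apo$delta_g$error, res_holo$delta_g$error)^2,
                      na.rm = TRUE))
  structure(list(config = config, hlda = cv, apo = res_apo, holo = res_holo,
                 delta_g_apo = res_apo$delta_g$delta_g,
                 delta_g_holo = res_holo$delta_g$delta_g,
                 ddg = ddg, ddg_error = ddg_err,
                 truth_apo = apo$delta_g_truth, truth_holo = holo$delta_g_truth,
                 kT = kT),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  dG apo : %8.2f kJ/mol (%.2f kcal/mol)  [quadrature truth %8.2f]%s\n",
              x$delta_g_apo, x$delta_g_apo / KCAL_TO_KJ, x$truth_apo,
              if (isTRUE(x$apo$convergence$converged)) "" else "  NOT CONVERGED"))
  cat(sprintf("  dG holo: %8.2f kJ/mol (%.2f kcal/mol)  [quadrature truth %8.2f]%s\n",
              x$delta_g_holo, x$delta_g_holo / KCAL_TO_KJ, x$truth_holo,
              if (isTRUE(x$holo$convergence$converged)) "" else "  NOT CONVERGED"))
  cat(sprintf("  ddG    : %8.2f +/- %.2f kJ/mol (injected ligand term %.2f)\n",
              x$ddg, x$ddg_error, -x$config$ligand_strength))
  invisible(x)
}

#' Side-by-side comparison of the apo and holo conditions
#'
#' Free-energy differences in both unit systems, mean RMSF, mean off-diagonal
#' correlation magnitude, and the first principal-mode eigenvalue, with
#' apo-holo deltas.
#'
#' @param report a \code{study_report}
#' @return data frame with one row per summary quantity
#' @export
compare_conditions <- function(report) {
  stopifnot(inherits(report, "study_report"))
  offdiag <- function(C) {
    v <- abs(C[upper.tri(C)])
    mean(v[is.finite(v)])
  }
  rows <- list(
    c(quantity = "delta_g_kj_mol", apo = report$delta_g_apo,
      holo = report$delta_g_holo),
    c(quantity = "delta_g_kcal_mol", apo = report$delta_g_apo / KCAL_TO_KJ,
      holo = report$delta_g_holo / KCAL_TO_KJ),
    c(quantity = "mean_rmsf_nm", apo = mean(report$apo$rmsf),
      holo = mean(report$holo$rmsf)),
    c(quantity = "mean_abs_offdiag_correlation", apo = offdiag(report$apo$cca),
      holo = offdiag(report$holo$cca)),
    c(quantity = "first_mode_eigenvalue_nm2",
      apo = report$apo$modes$values[1], holo = report$holo$modes$values[1]))
  out <- data.frame(quantity = vapply(rows, `[[`, "", "quantity"),
                    apo = as.numeric(vapply(rows, `[[`, "", "apo")),
                    holo = as.numeric(vapply(rows, `[[`, "", "holo")),
                    stringsAsFactors = FALSE)
  out$delta <- out$holo - out$apo
  out
}
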