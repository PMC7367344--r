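#' Default configuration of the end-to-end reproduction pipeline
#'
#' All numeric defaults are the study conditions: time step 0.0025
#' \eqn{t_s}, cutoff \eqn{1.5 r_a}, volume fraction 0.12, size ratio
#' 1:1.1, continuous square-well steepnesses (7000, 700), critical
#' attraction probed around \eqn{\epsilon/k_BT = 2.5}, master-equation
#' truncation \eqn{k_{max} = 10^4}.  The particle count and quench length
#' default to a desk-scale setting; the full-scale values (N = 32768, long
#' quenches) are a config change.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    simulation = list(
      n_particles = 2000, phi = 0.12, size_ratio = 1.1, dt = 0.0025,
      zeta = 1, eq_duration = 20, quench_duration = 150, frame_interval = 2,
      fine_interval = 0.05, potential = "mie", n = 30, m = 20, cutoff = 1.5,
      eps_over_kT = c(2, 4)),
    analysis = list(exclude_spanning_xi = TRUE, fz_window = c(0.02, 0.5)),
    kinetics = list(eps_over_kT = 4, duration = 20),
    master = list(lambda_grid = seq(0.2, 3, by = 0.05), k_max = 2000,
                  lambda_sol = 1.1, lambda_gel = 0.5),
    virial = list(eps_over_kT = 2.5),
    seed = 1)
}

#' Run the full reproduction pipeline
#'
#' Executes, at the scale set by the config: (1) the Baxter-stickiness
#' mapping of the Mie potential at the critical attraction; (2) the
#' master-equation phase scan (critical point, stationary branches,
#' cluster-mass tail exponents, cutoff divergence); (3) Langevin quenches
#' at the configured attractions with cluster metrics and percolation
#' detection; (4) association/dissociation rates from a finely sampled
#' segment.  Returns a report; optionally writes JSON/CSV artifacts.
#'
#' @param config nested list (see [default_run_config()]) or a YAML file
#'   path; missing entries fall back to the defaults.
#' @param out_dir optional output directory for JSON/CSV artifacts.
#' @return A `"gelkin_report"` list.
#' @export
run_reproduction <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_run_config(), config %||% list())
  set.seed(config$seed)
  report <- list(config = config)

  # --- potentials: Baxter stickiness at the critical attraction
  pot <- mie_potential(n = config$simulation$n, m = config$simulation$m,
                       cutoff = config$simulation$cutoff)
  vir <- second_virial(pot, kT = 1 / config$virial$eps_over_kT)
  report$baxter <- list(eps_over_kT = config$virial$eps_over_kT,
                        B2_reduced = vir$B2_reduced,
                        tau_B = vir$baxter_tau)

  # --- master equation: phase scan and tails
  mc <- config$master
  scan <- suppressWarnings(lambda_scan(mc$lambda_grid, k_max = mc$k_max))
  ck_sol <- series_coefficients(mc$lambda_sol, k_max = mc$k_max)
  kc <- cutoff_size(mc$lambda_sol)
  fit_sol <- tail_fit(seq_along(ck_sol), ck_sol,
                      window = round(kc * c(2, 12)), correction = TRUE)
  ck_gel <- series_coefficients(mc$lambda_gel, k_max = mc$k_max)
  fit_gel <- tail_fit(seq_along(ck_gel), ck_gel,
                      window = c(10, min(1000, mc$k_max)), pin_kc = TRUE)
  delta <- c(1e-2, 1e-3, 1e-4)
  ls <- diff(log(cutoff_size(1 + delta))) / diff(log(delta))
  gmid <- sqrt(delta[-1] * delta[-length(delta)])
  kc_slope <- ls[2] + (ls[2] - ls[1]) * gmid[2] / (gmid[1] - gmid[2])
  report$master <- list(
    lambda_c = locate_transition(scan),
    max_branch_error = max(abs(scan$N_inf -
      ifelse(scan$phase == "sol", scan$N_sol, scan$N_gel))),
    tau_sol = fit_sol$exponent, k_c_sol = fit_sol$k_c,
    tau_gel = fit_gel$exponent, kc_divergence_slope = kc_slope,
    d_f_hyperscaling = hyperscaling_df(2.5, 3))
  report$scan <- scan

  # --- simulation quenches
  sims <- list()
  for (eps in config$simulation$eps_over_kT) {
    sc <- do.call(sim_config, utils::modifyList(
      config$simulation[setdiff(names(config$simulation), "eps_over_kT")],
      list(eps_over_kT = eps, seed = config$seed)))
    start <- init_equilibrate(sc)
    traj <- run_quench(start, sc)
    crit <- bond_criterion("simulation", potential = pot)
    met <- trajectory_metrics(traj, crit,
      exclude_spanning_xi = config$analysis$exclude_spanning_xi)
    final_cs <- cluster_labels(contact_pairs(traj$frames[[length(traj$frames)]],
                                             crit))
    sims[[as.character(eps)]] <- list(
      eps_over_kT = eps, metrics = met,
      percolated = any(met$percolating),
      z_max = max(met$z), final_sizes = final_cs$sizes,
      trajectory = traj)
  }
  report$simulations <- lapply(sims, function(s)
    s[c("eps_over_kT", "metrics", "percolated", "z_max", "final_sizes")])

  # --- divergence fits on the strongest quench
  strongest <- sims[[length(sims)]]
  met <- strongest$metrics
  pre <- met[!met$percolating & met$f_z > 0, , drop = FALSE]
  report$scaling <- list()
  if (nrow(pre) >= 6) {
    report$scaling$f_z <- tryCatch(
      fit_divergence(pre$z, pre$f_z, window = config$analysis$fz_window),
      error = function(e) NULL)
    report$scaling$xi <- tryCatch(
      fit_divergence(pre$z[pre$xi > 0], pre$xi[pre$xi > 0]),
      error = function(e) NULL)
  }

  # --- kinetics on a finely sampled segment of the strongest quench
  kin <- config$kinetics
  sck <- do.call(sim_config, utils::modifyList(
    config$simulation[setdiff(names(config$simulation), "eps_over_kT")],
    list(eps_over_kT = kin$eps_over_kT, seed = config$seed + 1)))
  startk <- init_equilibrate(sck)
  fine <- run_quench(startk, sck, duration = kin$duration,
                     frame_interval = sck$fine_interval)
  ev <- track_events(fine, bond_criterion("simulation", potential = pot))
  rt <- rate_constants(ev)
  report$rates <- list(events = nrow(ev), by_size = rates_by_size(rt))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[c("baxter", "master", "scaling")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    utils::write.csv(report$scan, file.path(out_dir, "lambda_scan.csv"),
                     row.names = FALSE)
    for (nm in names(sims))
      utils::write.csv(sims[[nm]]$metrics,
                       file.path(out_dir, paste0("metrics_eps", nm, ".csv")),
                       row.names = FALSE)
  }
  structure(report, class = "gelkin_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gelkin_report <- function(x, ...) {
  cat("gelation reproduction report\n")
  cat(sprintf("  Baxter tau_B at eps/kT = %.3g: %.4f\n",
              x$baxter$eps_over_kT, x$baxter$tau_B))
  cat(sprintf("  master equation: lambda_c = %.3f, tails tau = %.3f (sol) / %.3f (gel)\n",
              x$master$lambda_c, x$master$tau_sol, x$master$tau_gel))
  cat(sprintf("  k_c divergence slope: %.4f; hyperscaling d_f = %.3g\n",
              x$master$kc_divergence_slope, x$master$d_f_hyperscaling))
  for (s in x$simulations)
    cat(sprintf("  quench eps/kT = %.3g: z_max = %.2f, percolated = %s\n",
                s$eps_over_kT, s$z_max, s$percolated))
  if (!is.null(x$scaling$f_z))
    cat(sprintf("  f_z divergence: z_c = %.2f, exponent = %.2f\n",
                x$scaling$f_z$critical, x$scaling$f_z$exponent))
  invisible(x)
}
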