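# End-to-end orchestration: metabolite balancing -> natural-abundance
# correction -> isotopomer fitting -> report files. The numbered scripts
# under analysis/ are thin drivers over this module.

#' Run the three-stage flux-analysis pipeline
#'
#' (1) metabolic steady-state balancing: fits growth and cell-specific
#' extracellular rates from the culture profile; (2) corrects raw MIDs for
#' naturally occurring isotopes (skipped when corrected MIDs are supplied);
#' (3) fits the network's free fluxes and reversibilities to the MID time
#' courses and applies the chi-squared verdict.
#'
#' @param config list with entries: `network` (path or `instcho_network`),
#'   `culture` (path or data.frame), `mids` (path or data.frame),
#'   `mids_are_raw` (logical, default FALSE), `fragments` (table, default
#'   [default_fragments()]), `params`/`fixed` (fit parameter selection),
#'   `optimizer` (list: pop_factor, generations, seed, rtol),
#'   `experiment` (default [default_experiment()]), `out_dir` (optional),
#'   `ci` (logical: profile confidence intervals), `sens` (logical:
#'   objective sensitivities)
#' @return list with `rates`, `growth`, `mids` (corrected), `fit`,
#'   `ci` and `sens` (when requested), `accepted`
#' @export
run_pipeline <- function(config) {
  cfg <- config
  # validate inputs before writing anything: a missing file must fail
  # cleanly with no partial outputs
  for (what in c("culture", "mids")) {
    x <- cfg[[what]]
    if (!is.null(x) && !is.data.frame(x) && !file.exists(x))
      stop("pipeline input '", what, "' not found: ", x)
  }
  net <- if (inherits(cfg$network, "instcho_network")) cfg$network
         else load_network(cfg$network)
  frags <- cfg$fragments %||% default_fragments()
  exp_des <- cfg$experiment %||% default_experiment()
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: metabolite balancing
  culture <- if (is.data.frame(cfg$culture)) cfg$culture
             else read.csv(cfg$culture)
  growth <- fit_growth(culture)
  kd <- cfg$kd %||% c(GLN_ex = 0.0033)
  rates <- fit_all_rates(culture, growth, kd = kd)
  if (!is.null(out_dir))
    write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)

  # stage 2: MID correction
  mids <- if (is.data.frame(cfg$mids)) cfg$mids else read_mid_csv(cfg$mids)
  if (isTRUE(cfg$mids_are_raw)) {
    mcols <- intersect(paste0("m", 0:6), names(mids))
    for (i in seq_len(nrow(mids))) {
      k <- match(mids$fragment[i], frags$fragment)
      nb <- frags$n_backbone[k]
      raw <- as.numeric(mids[i, mcols])
      raw <- raw[!is.na(raw)]
      corr <- correct_natural_abundance(raw, frags[k, ])
      mids[i, mcols] <- NA_real_
      mids[i, paste0("m", 0:nb)] <- corr
    }
  }
  if (!is.null(out_dir))
    write_mid_csv(mids, file.path(out_dir, "corrected_mids.csv"))

  # stage 3: isotopomer fitting
  dat <- mid_data(mids, frags)
  opt <- modifyList(list(pop_factor = 40, generations = 50, seed = 1,
                         rtol = 1e-6), cfg$optimizer %||% list())
  fit <- global_fit(net, dat, params = cfg$params, fixed = cfg$fixed,
                    config = opt, experiment = exp_des)

  res <- list(growth = growth, rates = rates, mids = mids, fit = fit,
              accepted = fit$accepted)
  if (isTRUE(cfg$ci)) {
    res$ci <- confidence_intervals(fit)
    if (!is.null(out_dir))
      write.csv(res$ci, file.path(out_dir, "confidence_intervals.csv"),
                row.names = FALSE)
  }
  if (isTRUE(cfg$sens)) {
    res$sens <- sensitivity_of_objective(fit, seed = opt$seed)
    if (!is.null(out_dir))
      write.csv(data.frame(parameter = names(res$sens), sens = res$sens),
                file.path(out_dir, "objective_sensitivity.csv"),
                row.names = FALSE)
  }
  if (!is.null(out_dir)) {
    sim <- fit$objective$simulate(fit$par)
    write_mid_csv(sim_to_mid_table(sim),
                  file.path(out_dir, "simulated_mids.csv"))
    jsonlite::write_json(
      list(network = net$name, ssqd = fit$ssqd, n_data = fit$n_data,
           n_par = fit$n_par, chi2_threshold = fit$chi2_threshold,
           accepted = fit$accepted, seed = opt$seed,
           parameters = as.list(fit$par)),
      file.path(out_dir, "fit_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
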