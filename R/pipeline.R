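#' Configuration for the end-to-end workflow
#'
#' Collects the thresholds, seeds and experimental settings used by
#' [run_pipeline]. All defaults are the package's standard analysis
#' conditions: 0.2 ppm CSP interface cutoff, 2.4 A clash cutoff, 9 A
#' isopeptide-linkage feasibility distance and 0.7 PRE ratio cutoff.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master RNG seed; every stochastic stage derives its seed
#'   from it and logs the value used.
#' @param csp_threshold interface CSP cutoff, ppm.
#' @param clash_cutoff heavy-atom clash distance, A.
#' @param linkage_threshold isopeptide feasibility distance, A.
#' @param pre_threshold,pre_min_run PRE region-call settings.
#' @param pre_sites spin-label residues probed on copy U1.
#' @param itc_cell,itc_syringe,itc_kd,itc_dh ITC protocol (uM) and truth
#'   (uM, cal/mol) for the simulated titration.
#' @param titration a [titration_spec]; defaults to
#'   `titration_spec(seed + 1)`.
#' @param solenoid a [solenoid_spec]; defaults to `solenoid_spec(seed)`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            csp_threshold = 0.2, clash_cutoff = 2.4,
                            linkage_threshold = 9.0,
                            pre_threshold = 0.7, pre_min_run = 2,
                            pre_sites = c(6L, 39L, 48L, 57L),
                            itc_cell = 150, itc_syringe = 3000,
                            itc_kd = 70, itc_dh = -2000,
                            titration = NULL, solenoid = NULL) {
  if (missing(out_dir) || missing(seed))
    stop("out_dir and seed are required")
  stopifnot(csp_threshold > 0, clash_cutoff > 0, linkage_threshold > 0,
            pre_threshold > 0)
  if (is.null(titration)) titration <- titration_spec(seed = seed + 1L)
  if (is.null(solenoid)) solenoid <- solenoid_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 csp_threshold = csp_threshold, clash_cutoff = clash_cutoff,
                 linkage_threshold = linkage_threshold,
                 pre_threshold = pre_threshold, pre_min_run = pre_min_run,
                 pre_sites = as.integer(pre_sites),
                 itc_cell = itc_cell, itc_syringe = itc_syringe,
                 itc_kd = itc_kd, itc_dh = itc_dh,
                 titration = titration, solenoid = solenoid),
            class = "pipeline_config")
}

## internal: deterministic TSV writer
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x)
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           sprintf("%.6f", x)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic workflow
#'
#' Executes the stages in experiment order on synthetic inputs derived
#' from the config seed: (1) build the solenoid and assign its helices and
#' overlapping-UBA units; (2) scan the sequence for signature motifs;
#' (3) simulate an HSQC titration, compute endpoint CSPs, map interface
#' residues and fit the shared Kd; (4) dock one ubiquitin per UBA unit
#' from the synthetic template and tabulate clashes and K48/K63 linkage
#' distances; (5) predict and simulate PRE profiles for the configured
#' spin-label sites and score region agreement; (6) simulate and fit a
#' single-site ITC run. Reports are plain TSV plus a human-readable
#' summary; a rerun with the same config is byte-identical. A failure in
#' any stage stops with the stage named; files already written remain.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the main in-memory results and the paths
#'   of all written reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("thresholds: csp %.3g ppm, clash %.3g A, linkage %.3g A, pre ratio %.3g (min run %d)",
                   config$csp_threshold, config$clash_cutoff,
                   config$linkage_threshold, config$pre_threshold,
                   config$pre_min_run))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. structure
  sol <- stage("structure", make_solenoid(config$solenoid))
  helices <- stage("structure", assign_helices(sol$structure))
  units <- stage("decomposition", decompose_overlapping_ubas(helices))
  paths$solenoid <- file.path(config$out_dir, "solenoid.pdb")
  write_pdb(sol$structure, paths$solenoid)
  paths$helices <- write_tsv(as.data.frame(helices),
                             file.path(config$out_dir, "helices.tsv"))
  paths$units <- write_tsv(as.data.frame(units),
                           file.path(config$out_dir, "uba_units.tsv"))
  log <- c(log, sprintf("structure: %d helices -> %d overlapping UBA units",
                        nrow(helices), nrow(units)))

  ## 2. motifs
  motifs <- stage("motifs", scan_signature_motifs(sol$sequence))
  paths$motifs <- write_tsv(motifs, file.path(config$out_dir, "motifs.tsv"))
  log <- c(log, sprintf("motifs: %d signature hit(s) at %s", nrow(motifs),
                        paste(motifs$position, collapse = ", ")))

  ## 3. titration / CSP
  series <- stage("csp", simulate_titration(config$titration))
  endpoint <- series$peaklists[[length(series$peaklists)]]
  prof <- stage("csp", compute_csp(series$peaklists[[1]], endpoint))
  iface <- map_interface_residues(prof, config$csp_threshold)
  tfit <- stage("csp", fit_titration_kd(series))
  paths$csp <- write_csp_profile(prof, file.path(config$out_dir, "csp.tsv"))
  paths$interface <- write_tsv(
    data.frame(residue = iface),
    file.path(config$out_dir, "interface_residues.tsv"))
  paths$titration_fit <- write_tsv(
    data.frame(residue = as.integer(names(tfit$dmax)),
               dmax_ppm = unname(tfit$dmax), kd_uM = tfit$kd),
    file.path(config$out_dir, "titration_fit.tsv"))
  log <- c(log, sprintf("csp: %d interface residue(s) > %.2f ppm; fitted Kd %.4g uM (titration seed %d)",
                        length(iface), config$csp_threshold, tfit$kd,
                        config$titration$seed))

  ## 4. docking
  template <- stage("docking", make_template_complex(seed = config$seed + 2L))
  model <- stage("docking", dock_ubiquitins(sol$structure, units, template))
  clashes <- stage("docking", detect_clashes(model, config$clash_cutoff))
  link <- rbind(
    stage("docking", assess_linkage(model, "K48", config$linkage_threshold)),
    stage("docking", assess_linkage(model, "K63", config$linkage_threshold)))
  paths$model <- file.path(config$out_dir, "docked_model.pdb")
  write_pdb(model$structure, paths$model)
  counts <- stats::aggregate(
    n_clashes ~ chain, cbind(
      data.frame(chain = model$placements$chain),
      n_clashes = vapply(model$placements$chain, function(ch)
        sum(clashes$counts$n_clashes[clashes$counts$chain1 == ch |
                                       clashes$counts$chain2 == ch]),
        numeric(1))), sum)
  dock_tab <- merge(model$placements,
                    stats::setNames(counts, c("chain", "n_clashes")),
                    by = "chain")
  dock_tab <- dock_tab[order(dock_tab$unit),
                       c("unit", "chain", "rmsd", "n_clashes")]
  paths$docking <- write_tsv(dock_tab,
                             file.path(config$out_dir, "docking.tsv"))
  paths$linkage <- write_tsv(link, file.path(config$out_dir, "linkage.tsv"))
  log <- c(log, sprintf("docking: %d ubiquitins placed (mean rmsd %.3f A), %d clash pair(s); linkage feasible: %s",
                        nrow(model$placements),
                        mean(model$placements$rmsd),
                        nrow(clashes$contacts),
                        if (any(link$feasible)) paste(
                          link$linkage[link$feasible], collapse = ", ")
                        else "none"))

  ## 5. PRE
  pre_rows <- list(); cmp_rows <- list()
  for (i in seq_along(config$pre_sites)) {
    r <- config$pre_sites[i]
    site <- stage("pre", attach_spin_label(model, 1L, r))
    pred <- stage("pre", predict_attenuation(model, site))
    obs <- stage("pre", simulate_pre_observed(
      model, site, noise_sd = 0.05, seed = config$seed + 10L + i))
    cmp <- stage("pre", compare_pre(obs, pred, config$pre_threshold,
                                    config$pre_min_run))
    reg <- significant_regions(pred, config$pre_threshold,
                               config$pre_min_run)
    pre_rows[[i]] <- if (nrow(reg) > 0)
      cbind(site = r, reg) else
        data.frame(site = r, start = NA_integer_, end = NA_integer_,
                   n_residues = 0L)
    cmp_rows[[i]] <- data.frame(site = r, n_regions = nrow(reg),
                                jaccard = cmp$jaccard,
                                seed = config$seed + 10L + i)
    paths[[paste0("pre_site_", r)]] <- write_tsv(
      data.frame(residue = pred$residue,
                 predicted = pred$ratio,
                 observed = obs$ratio[match(pred$residue, obs$residue)],
                 distance_A = pred$distance),
      file.path(config$out_dir, sprintf("pre_site_%d.tsv", r)))
  }
  paths$pre_regions <- write_tsv(do.call(rbind, pre_rows),
                                 file.path(config$out_dir,
                                           "pre_regions.tsv"))
  pre_cmp <- do.call(rbind, cmp_rows)
  paths$pre_compare <- write_tsv(pre_cmp,
                                 file.path(config$out_dir,
                                           "pre_compare.tsv"))
  log <- c(log, sprintf("pre: sites %s -> %s significant region(s)",
                        paste(config$pre_sites, collapse = "/"),
                        paste(pre_cmp$n_regions, collapse = "/")))

  ## 6. ITC
  protocol <- itc_protocol(config$itc_cell, config$itc_syringe)
  truth <- single_site_fit(n = 1, kd = config$itc_kd, dh = config$itc_dh)
  ref <- simulate_itc(protocol, truth, noise_sd = 0)
  noise <- 0.02 * max(abs(ref$heat_ucal))
  thermo <- stage("itc", simulate_itc(protocol, truth, noise_sd = noise,
                                      seed = config$seed + 20L))
  fit <- stage("itc", suppressWarnings(fit_itc(thermo, protocol)))
  paths$thermogram <- write_itc_thermogram(
    thermo, file.path(config$out_dir, "itc_thermogram.tsv"))
  paths$itc_fit <- write_tsv(
    data.frame(parameter = c("n", "kd_uM", "dh_cal_mol", "offset_ucal"),
               truth = c(1, config$itc_kd, config$itc_dh, 0),
               fitted = c(fit$n, fit$kd, fit$dh, fit$offset),
               se = unname(fit$se)),
    file.path(config$out_dir, "itc_fit.tsv"))
  log <- c(log, sprintf("itc: simulated Kd %.4g uM (noise %.3g ucal, seed %d) -> fitted %.4g uM",
                        config$itc_kd, noise, config$seed + 20L, fit$kd))

  paths$summary <- file.path(config$out_dir, "summary.txt")
  writeLines(c("ubamap pipeline report", log), paths$summary)
  invisible(list(solenoid = sol, helices = helices, units = units,
                 motifs = motifs, csp = prof, interface = iface,
                 titration_fit = tfit, model = model, clashes = clashes,
                 linkage = link, pre = pre_cmp, itc_fit = fit,
                 paths = paths))
}
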