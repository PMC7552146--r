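#' Assemble a run configuration
#'
#' One object drives the whole pipeline: the simulation world, the
#' calibration settings, the genetics chain, which traits get genetic
#' analyses, and a single master seed from which every stage derives its
#' own (see [seed_for()]).
#'
#' @param sim a [sim_config()] (its `seed` is overwritten by `seed`).
#' @param repetitions,test_frac training-testing settings.
#' @param pi0 BayesB prior exclusion probability.
#' @param calibration_chain,genetics_chain [chain_settings()] for the two
#'   samplers.
#' @param genetics_traits traits given a univariate genetic analysis.
#' @param genetics_pairs list of 2-trait character vectors given bivariate
#'   analyses (reference vs prediction).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), repetitions = 10, test_frac = 0.2,
                       pi0 = 0.95,
                       calibration_chain = chain_settings(3000, 500, 5),
                       genetics_chain = chain_settings(15000, 3000, 10),
                       genetics_traits = c("ch4_cm", "ch4_cm_ir"),
                       genetics_pairs = list(c("ch4_cm", "ch4_cm_ir")),
                       seed = 1L) {
  sim$seed <- seed
  structure(list(sim = sim, repetitions = repetitions,
                 test_frac = test_frac, pi0 = pi0,
                 calibration_chain = calibration_chain,
                 genetics_chain = genetics_chain,
                 genetics_traits = genetics_traits,
                 genetics_pairs = genetics_pairs, seed = seed),
            class = "run_config")
}

config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "spectral_loadings")]),
               collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

write_csv_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a tabular output back, skipping the provenance header
#' @param path CSV written by the pipeline.
#' @return data.frame.
#' @export
read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Validate pipeline inputs
#'
#' Structural diagnostics before any fitting: cows missing from the
#' pedigree, unsorted/cyclic pedigrees, spectra/phenotype row mismatches
#' and out-of-range fatty-acid values. Fatal issues are reported with
#' `fatal = TRUE`.
#'
#' @param pheno phenotype data.frame; @param ped a [pedigree()];
#' @param spectra spectra matrix (optional).
#' @return data.frame of diagnostics (zero rows when clean).
#' @export
validate_inputs <- function(pheno, ped, spectra = NULL) {
  diags <- data.frame(issue = character(), fatal = logical())
  note <- function(issue, fatal)
    rbind(diags, data.frame(issue = issue, fatal = fatal))
  ok_ped <- tryCatch({ validate_pedigree(ped); TRUE },
                     error = function(e) conditionMessage(e))
  if (!isTRUE(ok_ped)) diags <- note(paste("pedigree:", ok_ped), TRUE)
  else {
    orphan <- setdiff(pheno$cow_id, ped$animal)
    if (length(orphan))
      diags <- note(sprintf("%d phenotyped cow(s) absent from pedigree",
                            length(orphan)), TRUE)
  }
  if (!is.null(spectra) && nrow(spectra) != nrow(pheno))
    diags <- note("spectra row count differs from phenotype row count", TRUE)
  fa_cols <- intersect(names(pheno), names(default_trait_means())[1:6])
  if (length(fa_cols)) {
    m <- as.matrix(pheno[fa_cols])
    if (any(m < 0 | m > 100, na.rm = TRUE))
      diags <- note("fatty-acid value(s) outside [0, 100] g/100 g", TRUE)
  }
  diags
}

calibrate_trait <- function(y, spectra, cfg, seed) {
  ok <- is.finite(y)
  cv <- crossvalidate(y[ok], spectra[ok, , drop = FALSE],
                      repetitions = cfg$repetitions,
                      test_frac = cfg$test_frac, pi0 = cfg$pi0,
                      chain = cfg$calibration_chain, seed = seed)
  # re-expand to the full record set
  full <- matrix(NA_real_, length(y), ncol(cv$predictions))
  full[ok, ] <- cv$predictions
  cv$predictions <- full
  cv
}

#' Run the full pipeline
#'
#' simulate -> reference traits -> spectral calibration of the five direct
#' and nine informative traits -> inflation-safe validation database and
#' the eight indirect predictions -> univariate and bivariate genetic
#' analyses. Writes stamped CSVs (`records.csv`, `pedigree.csv`,
#' `calibration_metrics.csv`, `validation_db.csv`, `genetics_univariate.csv`,
#' `genetics_bivariate.csv`, `summary.txt`) under `out_dir` and returns the
#' pieces invisibly.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param quiet suppress progress messages.
#' @return list with `records`, `validation_db`, `calibration_metrics`,
#'   `univariate`, `bivariate`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  say("[simulate] seed=%s hash=%s", cfg$seed, hash)
  dat <- stage("simulate", simulate_dataset(cfg$sim))
  recs <- stage("traits", compute_all_eme(dat$records))

  diags <- validate_inputs(recs, dat$pedsim$ped, dat$spectra)
  if (any(diags$fatal)) stop("[validate] ", paste(diags$issue, collapse = "; "))

  direct <- stats::setNames(paste0(eme_trait_names(), "_ir"), eme_trait_names())
  informative <- informative_trait_names()
  cvs <- list()
  metrics <- NULL
  # one split sequence shared by every trait: the indirect traits combine
  # several component predictions per sample, which only exist jointly when
  # the same samples are held out for all components
  seed_splits <- seed_for(cfg$seed, "calibration_splits")
  for (tr in c(eme_trait_names(), informative)) {
    seed_tr <- seed_splits
    cv <- stage("calibrate", calibrate_trait(recs[[tr]], dat$spectra, cfg,
                                             seed_tr))
    key <- if (tr %in% names(direct)) direct[[tr]] else tr
    cvs[[key]] <- cv
    metrics <- rbind(metrics,
                     data.frame(trait = key, r2_cv = cv$r2_cv,
                                rmse_cv = cv$rmse_cv,
                                n_used = sum(rowSums(!is.na(cv$predictions)) > 0)))
    say("[calibrate] %s R2cv=%.3f RMSEcv=%.3f", key, cv$r2_cv, cv$rmse_cv)
  }

  db <- stage("assemble", assemble_validation_db(cvs, ids = recs$cow_id))
  db <- stage("indirect", indirect_predictions(db, recs))
  say("[assemble] %d of %d samples retained", nrow(db), nrow(recs))

  # genetics phenotype table: measured reference traits + predictions
  pheno <- merge(recs[c("cow_id", "herd_date_id", "parity_class", "dim_class",
                        eme_trait_names())],
                 db, by.x = "cow_id", by.y = "id", all.x = TRUE)
  ainv <- stage("genetics", build_a_inverse(dat$pedsim$ped))

  uni <- NULL
  for (tr in cfg$genetics_traits) {
    if (!tr %in% names(pheno)) stop("[genetics] unknown trait: ", tr)
    spec <- model_spec(tr, chain = cfg$genetics_chain,
                       seed = seed_for(cfg$seed, paste0("gen_", tr)))
    dr <- stage("genetics", gibbs_univariate(pheno, ainv, spec))
    h2 <- heritability(dr); hh <- herd_fraction(dr)
    uni <- rbind(uni, data.frame(
      trait = tr, n = dr$n, var_a = mean(dr$va), var_h = mean(dr$vh),
      var_e = mean(dr$ve), h2 = h2$mean, h2_hpd_low = h2$hpd_low,
      h2_hpd_high = h2$hpd_high, h_herd = hh$mean,
      h_herd_hpd_low = hh$hpd_low, h_herd_hpd_high = hh$hpd_high))
    say("[genetics] %s h2=%.3f h_herd=%.3f", tr, h2$mean, hh$mean)
  }

  biv <- NULL
  for (pair in cfg$genetics_pairs) {
    spec <- model_spec(pair, chain = cfg$genetics_chain,
                       seed = seed_for(cfg$seed,
                                       paste0("gen_", paste(pair, collapse = "_"))))
    dr <- stage("genetics", gibbs_bivariate(pheno, ainv, spec))
    cors <- component_correlations(dr)
    row <- data.frame(trait1 = pair[1], trait2 = pair[2], n = dr$n)
    for (nm in names(cors)) {
      cs <- cors[[nm]]
      row[[nm]] <- cs$mean
      row[[paste0(nm, "_p")]] <- cs$p_sign
      row[[paste0(nm, "_relevant")]] <- cs$relevant
    }
    biv <- rbind(biv, row)
    say("[genetics] %s~%s rG=%.2f rP=%.2f", pair[1], pair[2],
        cors$r_G$mean, cors$r_P$mean)
  }

  out <- list(records = recs, pedigree = dat$pedsim$ped,
              calibration_metrics = metrics, validation_db = db,
              univariate = uni, bivariate = biv, seed = cfg$seed,
              config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) if (!is.null(df))
      write_csv_stamped(df, file.path(out_dir, f), cfg$seed, hash)
    w(recs, "records.csv")
    write_pedigree(dat$pedsim$ped, file.path(out_dir, "pedigree.csv"),
                   header_comment = sprintf("seed=%s config=%s", cfg$seed, hash))
    w(metrics, "calibration_metrics.csv")
    w(db, "validation_db.csv")
    w(uni, "genetics_univariate.csv")
    w(biv, "genetics_bivariate.csv")
    writeLines(c(sprintf("seed=%s config=%s", cfg$seed, hash),
                 sprintf("records=%d retained=%d", nrow(recs), nrow(db)),
                 utils::capture.output(print(metrics)),
                 if (!is.null(uni)) utils::capture.output(print(uni)),
                 if (!is.null(biv)) utils::capture.output(print(biv))),
               file.path(out_dir, "summary.txt"))
  }
  invisible(out)
}
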