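#' Pipeline configuration
#'
#' Assembles (with defaults) every setting of the full analysis pipeline.
#' Exactly one of `spectra_csv` or `synthetic` must be supplied as input.
#'
#' @param spectra_csv Path to a wide-format spectra CSV (see
#'   [read_spectra_csv()]).
#' @param synthetic List of arguments for [simulate_trial()] (at least
#'   `seed`); used when no CSV is given.
#' @param splice_boundaries,apply_msc,apply_sg,sg_w,sg_order Preprocessing
#'   settings (see [preprocess_spectra()]).
#' @param cum_threshold,loading_threshold PCA retention and salience
#'   settings (see [spectra_pca()]).
#' @param weight_method,weight_cutoff Spatial weight construction for
#'   Moran/Geary (see [build_weight_matrix()]).
#' @param alpha Significance level used by every branch decision
#'   (normality screen, Levene grouping, variogram model selection,
#'   significance flags).
#' @param lag_width,max_dist Empirical variogram settings.
#' @param group_factor Factor eligible for heteroscedastic residual
#'   grouping (only `"main"` is supported; the five-level sub-plot factor
#'   is refused for lack of per-group information).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spectra_csv = NULL, synthetic = NULL,
                            splice_boundaries = c(1000, 1800),
                            apply_msc = FALSE, apply_sg = FALSE,
                            sg_w = 11, sg_order = 2,
                            cum_threshold = 0.97, loading_threshold = 80,
                            weight_method = "binary", weight_cutoff = 1.0,
                            alpha = 0.05,
                            lag_width = 0.5, max_dist = NULL,
                            group_factor = "main") {
  if (is.null(spectra_csv) && is.null(synthetic))
    stop("either 'spectra_csv' or 'synthetic' input must be provided")
  stopifnot(identical(group_factor, "main"))
  structure(list(spectra_csv = spectra_csv, synthetic = synthetic,
                 splice_boundaries = splice_boundaries,
                 apply_msc = apply_msc, apply_sg = apply_sg,
                 sg_w = sg_w, sg_order = sg_order,
                 cum_threshold = cum_threshold,
                 loading_threshold = loading_threshold,
                 weight_method = weight_method,
                 weight_cutoff = weight_cutoff,
                 alpha = alpha, lag_width = lag_width, max_dist = max_dist,
                 group_factor = group_factor),
            class = "pipeline_config")
}

# polynomial rolling hash of the serialized config, for the run log
.config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes, per the configured settings: preprocessing (splice correction
#' and 10-nm binning, optional MSC and Savitzky-Golay) -> correlation PCA
#' with VARIMAX rotation and salient-band selection -> then for every
#' retained component: basic statistics; composite normality tests with the
#' rank-normal (Blom) transform applied when at least 2 of the 3 tests
#' reject at `alpha`; Levene's test per fixed effect; an OLS fit whose
#' residuals feed Moran's I, Geary's c and the empirical variogram;
#' least-squares variogram model selection; a REML spatial mixed-model fit
#' (grouped by the main-plot factor when its Levene test rejects at
#' `alpha`), F tests of the fixed effects, pairwise LS-mean contrasts, and
#' the OLS comparison F table. Every branch decision is recorded with its
#' triggering statistic in the run log.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: `pca`, a per-component
#'   list `components` (named `PC1`, ...), and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    invisible(msg)
  }
  say("config hash: %s", .config_hash(config))

  if (!is.null(config$spectra_csv)) {
    raw <- read_spectra_csv(config$spectra_csv)
    say("input: %s (%d spectra x %d bands)", config$spectra_csv,
        nrow(raw$reflectance), length(raw$wavelengths))
  } else {
    trial <- do.call(simulate_trial, config$synthetic)
    raw <- trial$spectra
    say("input: synthetic trial (seed %s, %d spectra x %d bands)",
        config$synthetic$seed %||% 1L, nrow(raw$reflectance),
        length(raw$wavelengths))
  }

  s <- preprocess_spectra(raw, config$splice_boundaries,
                          config$apply_msc, config$apply_sg,
                          config$sg_w, config$sg_order)
  say("preprocess: splice + 10-nm binning -> %d bands%s%s",
      length(s$wavelengths),
      if (config$apply_msc) " + MSC" else "",
      if (config$apply_sg) " + Savitzky-Golay" else "")

  pca <- spectra_pca(s, config$cum_threshold, config$loading_threshold)
  k <- pca$n_retained
  say("pca: retained %d component(s), cumulative variance %.2f%%", k,
      100 * pca$cum_var[k])

  meta <- pca$scores[META_COLS]
  locations <- meta[, c("x", "y")]
  w <- build_weight_matrix(locations, config$weight_method,
                           config$weight_cutoff)
  fd <- build_fixed_design(meta)
  alpha <- config$alpha

  components <- list()
  for (j in seq_len(k)) {
    pc_name <- paste0("PC", j)
    x <- pca$scores[[pc_name]]
    comp <- list(name = pc_name)

    comp$basic <- data.frame(
      variable = pc_name, mean = mean(x), median = median(x), sd = sd(x),
      skewness = sample_skewness(x), kurtosis = sample_kurtosis(x))

    comp$normality <- normality_tests(x)
    n_reject <- sum(comp$normality$p < alpha)
    comp$transformed <- n_reject >= 2
    if (comp$transformed) {
      x <- blom_transform(x)$y
      say("%s: %d/3 normality tests reject at %.2g -> Blom rank-normal scores",
          pc_name, n_reject, alpha)
    } else {
      say("%s: %d/3 normality tests reject at %.2g -> raw scores kept",
          pc_name, n_reject, alpha)
    }
    comp$values <- x

    comp$levene <- rbind(
      cbind(effect = "main", levene_test(x, meta$main)),
      cbind(effect = "sub", levene_test(x, meta$sub)))

    comp$ols <- ols_fit(x, fd, locations)
    res <- comp$ols$residuals

    comp$autocorrelation <- rbind(morans_i(res, w), gearys_c(res, w))

    ev <- empirical_variogram(res, locations, config$lag_width,
                              config$max_dist)
    comp$variogram <- ev
    sel <- select_model(ev, alpha)
    comp$lse_model <- sel
    say("%s: variogram selection -> %s", pc_name, attr(sel, "selection"))

    p_lev_main <- comp$levene$p[comp$levene$effect == "main"]
    grouped <- p_lev_main < alpha && length(fd$main_levels) == 2
    if (grouped) {
      say("%s: Levene main-effect p = %.4g < %.2g -> group-specific residual models",
          pc_name, p_lev_main, alpha)
      init <- list()
      family <- character()
      for (g in fd$main_levels) {
        idx <- meta$main == g
        ev_g <- empirical_variogram(res[idx], locations[idx, ],
                                    config$lag_width, config$max_dist)
        m_g <- select_model(ev_g, alpha)
        init[[g]] <- m_g
        family[g] <- m_g$family
        say("%s: group %s residual variogram -> %s", pc_name, g,
            attr(m_g, "selection"))
      }
      comp$reml <- reml_fit(x, fd, locations, family = family,
                            groups = meta$main, init = init)
    } else {
      say("%s: Levene main-effect p = %.4g -> single residual model",
          pc_name, p_lev_main)
      comp$reml <- reml_fit(x, fd, locations, family = sel$family,
                            init = sel)
    }

    comp$f_tests <- fixed_effect_f_tests(comp$reml)
    comp$contrasts <- rbind(lsmean_differences(comp$reml, "main", alpha),
                            lsmean_differences(comp$reml, "sub", alpha),
                            lsmean_differences(comp$reml, "interaction",
                                               alpha))
    comp$f_tests_ols <- fixed_effect_f_tests(comp$ols)
    components[[pc_name]] <- comp
  }

  structure(list(pca = pca, components = components, log = log,
                 config = config),
            class = "pipeline_result")
}

#' Write the pipeline report bundle
#'
#' Emits one CSV per report table — basic statistics, normality tests,
#' Levene tests, spatial autocorrelation, least-squares variogram fits,
#' REML random- and fixed-effect estimates, significant LS-mean contrasts
#' and the OLS comparison — plus the run log and a short summary.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  comps <- result$components
  gather <- function(field, extract = identity) {
    do.call(rbind, lapply(names(comps), function(nm) {
      tb <- extract(comps[[nm]][[field]])
      if (is.null(tb) || nrow(tb) == 0) return(NULL)
      cbind(variable = nm, tb)
    }))
  }
  tables <- list(
    table1_basic_stats = do.call(rbind, lapply(comps, `[[`, "basic")),
    table2_normality = gather("normality"),
    table3_levene = gather("levene"),
    table4_autocorrelation = gather("autocorrelation"),
    table5_variogram_lse = gather("lse_model", function(m) m$fit_table),
    # mirrors the two-part layout: random-effect (variogram) parameters with
    # Wald z tests, then fixed-effect F tests
    table6_reml = rbind(
      gather("reml", function(f) {
        rt <- do.call(rbind, lapply(f$models, `[[`, "fit_table"))
        data.frame(part = "random", group = rt$group, term = rt$parameter,
                   estimate = rt$estimate, se = rt$se, stat = rt$z,
                   p = rt$p)
      }),
      gather("f_tests", function(ft) {
        data.frame(part = "fixed", group = NA, term = ft$effect,
                   estimate = NA, se = NA, stat = ft$F, p = ft$p)
      })),
    table7_contrasts = gather("contrasts",
                              function(ct) ct[ct$significant, , drop = FALSE]),
    table8_ols = gather("f_tests_ols"))

  paths <- character()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb))
      tb <- data.frame(variable = character(), note = character())
    path <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(as.data.frame(tb), path)
    paths <- c(paths, path)
  }

  log_path <- file.path(dir, "run_log.txt")
  writeLines(result$log, log_path)
  summary_path <- file.path(dir, "summary.txt")
  k <- result$pca$n_retained
  lines <- c(
    sprintf("Retained components: %d (cumulative variance %.2f%%)", k,
            100 * result$pca$cum_var[k]),
    vapply(names(comps), function(nm) {
      co <- comps[[nm]]
      sprintf("%s: %s scores; residual model(s): %s; fixed effects: %s",
              nm,
              if (co$transformed) "rank-normal (Blom)" else "raw",
              paste(vapply(co$reml$models, function(m) m$family, ""),
                    collapse = "/"),
              paste(sprintf("%s p=%.4g", co$f_tests$effect, co$f_tests$p),
                    collapse = ", "))
    }, character(1)))
  writeLines(lines, summary_path)
  invisible(c(paths, log_path, summary_path))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$components), "retained component(s)\n")
  for (nm in names(x$components)) {
    co <- x$components[[nm]]
    cat(sprintf("  %s (%s): REML F tests: %s\n", nm,
                if (co$transformed) "Blom scores" else "raw",
                paste(sprintf("%s F=%.2f p=%.4g", co$f_tests$effect,
                              co$f_tests$F, co$f_tests$p), collapse = "; ")))
  }
  invisible(x)
}
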