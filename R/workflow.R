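# End-to-end orchestration: covariate residualization, one-twin selection,
# listwise deletion, and the full pipeline producing table-shaped reports.

#' Residualize covariates out of the item scores
#'
#' Per item, an ordinary least-squares regression of the score on the
#' covariates is fitted over all individuals (twin 1 and twin 2 pooled) with
#' complete covariates and that item observed; scores are replaced by the
#' residuals. Missing items stay missing. Cohort enters as categorical
#' dummies, sex as 0/1, age in years as-is. Constant covariates are dropped
#' with a warning. Pooling twins affects only standard errors, which are not
#' used here.
#'
#' @param data a [twin_data] object with raw scores.
#' @param covariates subset of `c("age", "sex", "cohort")`.
#' @return a [twin_data] object with residualized (continuous) scores.
#' @export
residualize <- function(data, covariates = c("age", "sex", "cohort")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  st <- data$structure
  p <- data$pairs
  long <- rbind(
    data.frame(row = seq_len(nrow(p)), twin = 1L, age = p$age1, sex = p$sex1,
               cohort = p$cohort1),
    data.frame(row = seq_len(nrow(p)), twin = 2L, age = p$age2, sex = p$sex2,
               cohort = p$cohort2))
  keep <- covariates
  for (cv in covariates) {
    vals <- long[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      warning("covariate '", cv, "' is constant and was dropped")
      keep <- setdiff(keep, cv)
    }
  }
  if (!length(keep)) return(data)
  fm <- stats::as.formula(paste(
    "~", paste(ifelse(keep == "cohort", "factor(cohort)", keep),
               collapse = " + ")))
  for (i in seq_len(st$n_items)) {
    y <- c(p[[sprintf("i%02d_t1", i)]], p[[sprintf("i%02d_t2", i)]])
    ok <- !is.na(y) & stats::complete.cases(long[, keep, drop = FALSE])
    if (!any(ok)) next
    X <- stats::model.matrix(fm, long[ok, , drop = FALSE])
    res <- stats::lm.fit(X, y[ok])$residuals
    y[ok] <- res
    y[!ok & !is.na(y)] <- NA  # item observed but covariates missing: drop
    p[[sprintf("i%02d_t1", i)]] <- y[long$twin == 1L]
    p[[sprintf("i%02d_t2", i)]] <- y[long$twin == 2L]
  }
  twin_data(p, st)
}

#' Select one random twin per pair
#'
#' A seeded fair coin picks twin 1 or twin 2 from every pair, producing an
#' individual-level table for the phenotypic (psychometric) analysis where
#' twins within a pair would otherwise violate independence.
#'
#' @param data a [twin_data] object.
#' @param seed integer seed; the selection is reproducible.
#' @return data frame with columns `pair_id`, `twin`, `zygosity`, `age`,
#'   `sex`, `cohort` and one column per item (`i01` ... `i<n>`).
#' @export
select_one_per_pair <- function(data, seed = 1L) {
  set.seed(seed)
  p <- data$pairs
  st <- data$structure
  twin <- stats::rbinom(nrow(p), 1L, 0.5) + 1L
  out <- data.frame(pair_id = p$pair_id, twin = twin, zygosity = p$zygosity,
                    age = ifelse(twin == 1L, p$age1, p$age2),
                    sex = ifelse(twin == 1L, p$sex1, p$sex2),
                    cohort = ifelse(twin == 1L, p$cohort1, p$cohort2),
                    stringsAsFactors = FALSE)
  for (i in seq_len(st$n_items)) {
    out[[sprintf("i%02d", i)]] <- ifelse(
      twin == 1L, p[[sprintf("i%02d_t1", i)]], p[[sprintf("i%02d_t2", i)]])
  }
  out
}

#' Listwise deletion of incomplete rows
#'
#' Drops every row with any missing item score (columns named `i01`, `i02`,
#' ...), reporting the retained fraction.
#'
#' @param table data frame as returned by [select_one_per_pair()].
#' @param quiet suppress the retained-fraction message.
#' @return the filtered data frame, with attribute `"retained"`.
#' @export
listwise_delete <- function(table, quiet = FALSE) {
  icols <- grep("^i[0-9]+$", names(table), value = TRUE)
  keep <- stats::complete.cases(table[, icols, drop = FALSE])
  if (!any(keep)) stop("listwise deletion removed every row")
  out <- table[keep, , drop = FALSE]
  attr(out, "retained") <- mean(keep)
  if (!quiet) {
    message(sprintf("listwise deletion: retained %d of %d rows (%.1f%%)",
                    sum(keep), length(keep), 100 * mean(keep)))
  }
  out
}

#' Pipeline configuration
#'
#' @param input path to a twin-pair CSV, or a [twin_data] object.
#' @param seed integer seed used by every stochastic step.
#' @param covariates covariates to residualize out (default age, sex,
#'   cohort).
#' @param analyses subset of `c("psychometrics", "cp", "ip", "compare",
#'   "indices")`.
#' @param components submodels to fit per family.
#' @param bootstrap_B bootstrap replicates for the CP factor effects
#'   (0 disables the bootstrap).
#' @param outdir output directory for JSON/TSV reports (`NULL` for none).
#' @param n_starts optimizer starts per fit.
#' @param structure item structure used when `input` is a CSV path
#'   (default [conners_structure()]).
#' @param quiet suppress progress messages.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, seed = 1L,
                       covariates = c("age", "sex", "cohort"),
                       analyses = c("psychometrics", "cp", "ip", "compare",
                                    "indices"),
                       components = c("ACE", "AE", "CE", "E"),
                       bootstrap_B = 0L, outdir = NULL, n_starts = 2L,
                       structure = conners_structure(), quiet = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!length(analyses)) stop("analysis list must be non-empty")
  structure(list(input = input, seed = as.integer(seed),
                 covariates = covariates, analyses = analyses,
                 components = components, bootstrap_B = as.integer(bootstrap_B),
                 outdir = outdir, n_starts = n_starts,
                 structure = structure, quiet = quiet),
            class = "run_config")
}

pipeline_log <- function(config, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Validates and residualizes the input, then runs the requested branches:
#' the psychometric branch (one random twin per pair, listwise deletion,
#' Direct Schmid-Leiman bifactor, reliability indices -> a loading-table
#' report) and the genetic branch (CP and IP fits for the requested
#' submodels -> fit-statistic, effect-estimate and per-source index
#' reports). All randomness derives from `config$seed`. When
#' `config$outdir` is set, each report is written as JSON plus a TSV mirror,
#' and the bundle records provenance (input hash, seed, package version).
#'
#' @param config a [run_config].
#' @return (invisibly) a named list of report objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- config$input
  input_hash <- NA_character_
  if (is.character(data)) {
    input_hash <- unname(tools::md5sum(data))
    data <- read_twin_csv(data, config$structure %||% conners_structure())
  }
  st <- data$structure
  problems <- validate_dataset(data)
  if (length(problems)) {
    stop("input failed validation:\n  ", paste(problems, collapse = "\n  "))
  }
  pipeline_log(config, "residualizing covariates: %s",
               paste(config$covariates, collapse = ", "))
  rdata <- residualize(data, config$covariates)
  reports <- list(provenance = list(
    input_hash = input_hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("biftwin")),
    n_pairs = n_pairs(data), analyses = config$analyses))

  if ("psychometrics" %in% config$analyses) {
    tab <- select_one_per_pair(rdata, seed = config$seed)
    tab <- listwise_delete(tab, quiet = config$quiet)
    icols <- grep("^i[0-9]+$", names(tab), value = TRUE)
    R <- stats::cor(as.matrix(tab[, icols]))
    L <- fit_dsl_bifactor(R, st)
    raw <- attr(L, "raw")
    rep1 <- list(
      n_used = nrow(tab),
      loadings = cbind(
        data.frame(item = seq_len(st$n_items), label = st$item_labels,
                   subscale = st$group_names[st$group_of]),
        stats::setNames(as.data.frame(raw, optional = TRUE),
                        c("general", st$group_names))),
      indices = unclass(index_report(L, label = "phenotypic bifactor")),
      summary = loading_summary(L))
    reports$psychometrics <- rep1
  }

  fits <- list()
  sat <- ind <- NULL
  families <- intersect(c("cp", "ip"), config$analyses)
  if (length(families)) {
    pipeline_log(config, "fitting reference (saturated/independence) models")
    sat <- fit_saturated(rdata)
    ind <- fit_independence(rdata)
    for (fam in families) {
      for (comp in config$components) {
        pipeline_log(config, "fitting %s %s", toupper(fam), comp)
        fits[[paste(fam, comp, sep = "_")]] <- fit_model(
          rdata, model_spec(fam, comp, st), n_starts = config$n_starts,
          seed = config$seed)
      }
    }
    effects <- lapply(fits, function(f) {
      aggregate_standardized_effects(f)$table
    })
    reports$effects <- effects
  }

  if ("compare" %in% config$analyses && length(fits)) {
    cmp <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      fs <- fit_statistics(f, sat, ind)
      full <- fits[[paste(f$spec$family, "ACE", sep = "_")]]
      lp <- if (!is.null(full) && f$spec$components != "ACE") {
        lrt(full, f)$p_value
      } else NA_real_
      data.frame(model = nm, family = f$spec$family,
                 components = f$spec$components, rmsea = fs$rmsea,
                 cfi = fs$cfi, minus2LL = fs$minus2LL, aic = fs$aic,
                 bic = fs$bic, lrt_p = lp, converged = f$converged)
    }))
    reports$comparison <- cmp
  }

  if ("indices" %in% config$analyses && !is.null(fits$ip_ACE)) {
    idx <- twin_bifactor_indices(fits$ip_ACE)
    reports$indices <- lapply(idx, unclass)
  }

  if (config$bootstrap_B > 0L && !is.null(fits$cp_ACE)) {
    pipeline_log(config, "bootstrapping CP factor effects (B = %d)",
                 config$bootstrap_B)
    reports$bootstrap <- bootstrap_ci(
      rdata, fits$cp_ACE$spec, B = config$bootstrap_B, seed = config$seed,
      statistic = function(f) {
        fe <- f$factor_effects
        stats::setNames(fe[, "a"], paste0("a2_", rownames(fe) %||%
                                            seq_len(nrow(fe))))
      },
      fit = fits$cp_ACE, n_starts = 1L)[c("estimate", "lower", "upper",
                                          "B", "n_dropped", "flagged")]
  }

  reports$fits <- lapply(fits, function(f) {
    list(family = f$spec$family, components = f$spec$components,
         minus2LL = f$minus2LL, n_free_params = f$n_free_params,
         converged = f$converged)
  })

  if (!is.null(config$outdir)) write_reports(reports, config$outdir)
  invisible(reports)
}

write_reports <- function(reports, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(reports, file.path(outdir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  if (!is.null(reports$psychometrics)) {
    utils::write.table(reports$psychometrics$loadings,
                       file.path(outdir, "loadings.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(reports$comparison)) {
    utils::write.table(reports$comparison,
                       file.path(outdir, "model_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(reports$effects)) {
    eff <- do.call(rbind, lapply(names(reports$effects), function(nm) {
      cbind(model = nm, reports$effects[[nm]])
    }))
    utils::write.table(eff, file.path(outdir, "effect_estimates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(reports$indices)) {
    idx <- do.call(rbind, lapply(names(reports$indices), function(s) {
      r <- reports$indices[[s]]
      data.frame(source = s, omega_h = r$omega_h, h_index = r$h_index,
                 ecv = r$ecv)
    }))
    utils::write.table(idx, file.path(outdir, "general_factor_indices.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(outdir)
}
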