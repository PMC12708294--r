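# Cohort data model: the 34-indicator codebook, the LANG outcome, CSV I/O
# with validation, quality-control filtering, and the synthetic cohort
# generator parameterized by the published per-sex summary statistics.

#' Indicator codebook
#'
#' One row per indicator: name, display label, model symbol (the network
#' modules use `PQ3` = admission ADL, `PQ5` = admission GCS, `PSQ3` =
#' postoperative ASPECTS, `PSQ6` = discharge mRS, `BIOC4` = C-reactive
#' protein, `BIOC19` = glycated haemoglobin, `VOL` = infarct volume,
#' `CE1` = affected hemisphere, `LANG` = language deterioration score),
#' variable type, admissible range, integer flag, and the per-sex
#' mean/SD (continuous) or prevalence (binary) defaults of the simulator.
#'
#' @return A data.frame, one row per indicator.
#' @export
cohort_codebook <- function() {
  cc <- function(name, label, symbol, type, lo, hi, int,
                 mm, sm, mf, sf) {
    data.frame(name = name, label = label, symbol = symbol, type = type,
               lo = lo, hi = hi, integer = int, mean_male = mm, sd_male = sm,
               mean_female = mf, sd_female = sf, prev_male = NA_real_,
               prev_female = NA_real_, stringsAsFactors = FALSE)
  }
  cb <- function(name, label, symbol, pm, pf) {
    data.frame(name = name, label = label, symbol = symbol, type = "binary",
               lo = 0, hi = 1, integer = TRUE, mean_male = NA_real_,
               sd_male = NA_real_, mean_female = NA_real_, sd_female = NA_real_,
               prev_male = pm, prev_female = pf, stringsAsFactors = FALSE)
  }
  rbind(
    cc("age", "Age (years)", NA, "continuous", 18, 105, TRUE,
       69.39, 10.72, 73.51, 9.38),
    cc("adl", "ADL admission score", "PQ3", "score", 0, 100, TRUE,
       20.69, 15.46, 20.24, 15.69),
    cc("gcs", "GCS admission score", "PQ5", "score", 3, 15, TRUE,
       8.90, 2.22, 8.54, 2.58),
    cc("cdr", "CDR admission score", NA, "score", 0, 18, FALSE,
       8.88, 4.80, 9.37, 4.86),
    cc("aspects_adm", "ASPECTS admission score", NA, "score", 0, 10, TRUE,
       9.58, 0.78, 9.60, 0.71),
    cc("mrs_adm", "mRS admission score", NA, "score", 0, 6, TRUE,
       4.35, 0.70, 4.33, 0.74),
    cc("his", "HIS admission score", NA, "score", 0, 18, TRUE,
       10.60, 2.05, 10.68, 2.35),
    cc("vol", "Infarct volume (mL)", "VOL", "continuous", 0, Inf, FALSE,
       22.72, 6.65, 15.19, 6.36),
    cb("hemisphere_left", "Affected hemisphere left", "CE1",
       43 / 101, 23 / 63),
    cb("cerebellar", "Cerebellar damage", NA, 26 / 101, 19 / 63),
    cb("language_area", "Language area damage", NA, 7 / 101, 3 / 63),
    cb("broca", "Broca's area damage", NA, 2 / 101, 0 / 63),
    cb("wernicke", "Wernicke's area damage", NA, 5 / 101, 3 / 63),
    cc("k", "K (mmol/L)", NA, "continuous", 2, 7, FALSE,
       4.01, 0.42, 3.88, 0.48),
    cc("na", "Na (mmol/L)", NA, "continuous", 110, 160, FALSE,
       137.08, 3.58, 137.36, 3.61),
    cc("cl", "Cl (mmol/L)", NA, "continuous", 80, 125, FALSE,
       102.89, 3.33, 102.48, 4.20),
    cc("co2", "CO2 binding capacity (mmol/L)", NA, "continuous", 0, Inf, FALSE,
       26.01, 19.13, 23.91, 2.94),
    cc("neutrophils", "Neutrophils (10^9/L)", NA, "continuous", 0, Inf, FALSE,
       7.18, 8.83, 7.18, 4.08),
    cc("lymphocytes", "Lymphocytes (10^9/L)", NA, "continuous", 0, Inf, FALSE,
       1.57, 1.61, 1.35, 0.69),
    cc("monocytes", "Monocytes (10^9/L)", NA, "continuous", 0, Inf, FALSE,
       0.55, 0.44, 0.53, 0.47),
    cc("crp", "C-reactive protein (mg/L)", "BIOC4", "continuous", 0, Inf,
       FALSE, 11.83, 21.67, 12.79, 19.94),
    cc("inr", "INR", NA, "continuous", 0.5, 5, FALSE, 1.13, 0.13, 1.13, 0.12),
    cc("ddimer", "D-dimer (ng/mL)", NA, "continuous", 0, Inf, FALSE,
       610.68, 1184.42, 436.51, 364.69),
    cc("fibrinogen", "Fibrinogen (ng/mL)", NA, "continuous", 0, Inf, FALSE,
       64.63, 608.56, 3.99, 0.91),
    cc("ldh", "Lactate dehydrogenase (U/L)", NA, "continuous", 0, Inf, FALSE,
       208.32, 48.95, 234.25, 71.64),
    cc("glucose", "Blood glucose (mmol/L)", NA, "continuous", 1, Inf, FALSE,
       7.14, 2.78, 8.06, 4.40),
    cc("aspects_post", "ASPECTS postoperative score", "PSQ3", "score", 0, 10,
       TRUE, 7.11, 2.79, 6.83, 2.69),
    cc("triglycerides", "Triglycerides (mmol/L)", NA, "continuous", 0, Inf,
       FALSE, 1.36, 0.76, 1.36, 0.78),
    cc("cholesterol", "Total cholesterol (mmol/L)", NA, "continuous", 0, Inf,
       FALSE, 4.38, 1.21, 4.14, 1.27),
    cc("hdl", "HDL (mmol/L)", NA, "continuous", 0, Inf, FALSE,
       1.14, 0.31, 1.23, 0.32),
    cc("ldl", "LDL (mmol/L)", NA, "continuous", 0, Inf, FALSE,
       2.74, 0.83, 2.61, 0.83),
    cc("hba1c", "Glycated haemoglobin (%)", "BIOC19", "continuous", 3, 20,
       FALSE, 6.76, 1.69, 6.68, 1.71),
    cc("mrs_discharge", "mRS discharge score", "PSQ6", "score", 0, 6, TRUE,
       3.38, 1.14, 3.67, 1.28)
  )
}

#' Language deterioration score (LANG)
#'
#' LANG is the postoperative minus preoperative NIHSS item-9 (best language)
#' score; a value below zero is classified as improvement (class 1), all
#' other values as non-improvement (class 0).
#'
#' @param pre_item9,post_item9 integer scores in 0-3 (vectorized).
#' @return List with `lang` (integer, -3..3) and `improved` (0/1).
#' @export
compute_lang <- function(pre_item9, post_item9) {
  ok <- function(x) all(!is.na(x)) && all(x == as.integer(x)) &&
    all(x >= 0 & x <= 3)
  if (!ok(pre_item9) || !ok(post_item9))
    stop_asym("lang", "NIHSS item-9 scores must be integers in 0-3")
  lang <- as.integer(post_item9) - as.integer(pre_item9)
  list(lang = lang, improved = as.integer(lang < 0))
}

id_cols <- c("patient_id", "gender")
item9_cols <- c("nihss9_pre", "nihss9_post")
derived_cols <- c("lang", "lang_improved")

as_cohort_table <- function(df, provenance = list(source = "real")) {
  structure(df, class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.cohort_table <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<cohort_table> %d patients (%d male, %d female), source: %s\n",
              nrow(x), sum(x$gender == "male"), sum(x$gender == "female"),
              pv$source %||% "unknown"))
  invisible(x)
}

validate_cohort <- function(df, codebook = cohort_codebook()) {
  needed <- c(id_cols, item9_cols, codebook$name)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop_asym("cohort", paste("missing columns:",
                              paste(missing_cols, collapse = ", ")))
  unknown <- setdiff(names(df),
                     c(needed, derived_cols, "mrs_3mo", "mrs_12mo",
                       "homocysteine"))
  if (length(unknown))
    stop_asym("cohort", paste("unknown columns:",
                              paste(unknown, collapse = ", ")))
  if (anyDuplicated(df$patient_id))
    stop_asym("cohort", "patient_id values must be unique")
  if (!all(df$gender %in% c("male", "female")))
    stop_asym("cohort", "gender must be 'male' or 'female'")
  for (i in seq_len(nrow(codebook))) {
    v <- codebook$name[i]
    x <- df[[v]]
    bad <- which(!is.na(x) & (x < codebook$lo[i] | x > codebook$hi[i]))
    if (length(bad))
      stop_asym("cohort", sprintf(
        "%s out of range [%g, %g] in row(s) %s", v, codebook$lo[i],
        codebook$hi[i], paste(head(bad, 5), collapse = ",")))
  }
  for (v in item9_cols) {
    x <- df[[v]]
    bad <- which(!is.na(x) & (x < 0 | x > 3 | x != round(x)))
    if (length(bad))
      stop_asym("cohort", sprintf("%s must be integers in 0-3 (row %d)", v,
                                  bad[1]))
  }
  cmpl <- !is.na(df$nihss9_pre) & !is.na(df$nihss9_post)
  lng <- rep(NA_integer_, nrow(df))
  if (any(cmpl))
    lng[cmpl] <- compute_lang(df$nihss9_pre[cmpl], df$nihss9_post[cmpl])$lang
  if (!is.null(df$lang)) {
    disc <- which(cmpl & !is.na(df$lang) & df$lang != lng)
    if (length(disc))
      stop_asym("cohort", sprintf(
        "supplied LANG inconsistent with item-9 pair in row(s) %s",
        paste(head(disc, 5), collapse = ",")))
  }
  df$lang <- lng
  df$lang_improved <- ifelse(is.na(lng), NA_integer_, as.integer(lng < 0))
  df
}

#' Load a cohort table from CSV
#'
#' Reads, types and validates a cohort CSV against the [cohort_codebook()]:
#' range checks per indicator, LANG recomputed from the NIHSS item-9 pair and
#' checked against any supplied LANG column. A per-column missingness report
#' is attached as attribute `"missingness"`.
#'
#' @param csv_path path to a CSV file (UTF-8, `.` decimal).
#' @param codebook indicator codebook; default [cohort_codebook()].
#' @return A `cohort_table`.
#' @export
load_cohort <- function(csv_path, codebook = cohort_codebook()) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  df <- validate_cohort(df, codebook)
  out <- as_cohort_table(df, provenance = list(source = "csv",
                                               path = csv_path))
  attr(out, "missingness") <- vapply(df, function(x) sum(is.na(x)), 0L)
  out
}

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Quality-control filtering: drop variables, then incomplete cases
#'
#' Removes the listed variables (those measured too infrequently to keep),
#' then removes every row with any remaining missing indicator. The returned
#' table carries a report (`attr(., "qc_report")`): n before/after and
#' per-variable missing counts.
#'
#' @param table a `cohort_table`.
#' @param exclude_vars character vector of columns to drop first.
#' @return The filtered `cohort_table`.
#' @export
drop_incomplete <- function(table, exclude_vars = character()) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(exclude_vars, names(table))
  if (length(unknown))
    stop_asym("qc", paste("exclude_vars not in table:",
                          paste(unknown, collapse = ", ")))
  df <- as.data.frame(table)
  miss_before <- vapply(df, function(x) sum(is.na(x)), 0L)
  df2 <- df[, setdiff(names(df), exclude_vars), drop = FALSE]
  keep <- complete.cases(df2)
  out <- as_cohort_table(df2[keep, , drop = FALSE],
                         provenance = attr(table, "provenance"))
  attr(out, "qc_report") <- list(
    n_before = nrow(df), n_after = sum(keep),
    excluded_vars = exclude_vars, missing_per_var = miss_before)
  out
}

#' Simulation parameters for the synthetic cohort
#'
#' Continuous indicators are drawn per sex as (rounded, truncated) normals
#' with the codebook's published means/SDs; binary lesion flags as Bernoulli
#' with the published prevalences. The LANG outcome follows a latent linear
#' model on standardized GCS, ADL, discharge mRS and infarct volume, then is
#' discretized through the NIHSS item-9 pre/post pair.
#'
#' @param n_male,n_female group sizes (defaults: the published cohort).
#' @param codebook indicator codebook with per-sex parameter columns.
#' @param outcome_coefs named coefficients of the latent LANG model on
#'   standardized predictors.
#' @param outcome_mean,outcome_sd latent intercept and noise SD.
#' @param pre_item9_probs probabilities of preoperative item-9 scores 0-3.
#' @param n_incomplete rows to receive a missing value in a retained
#'   indicator (quality-control emulation; 0 = fully complete table).
#' @param followup_missing_rate missingness rate of the three follow-up
#'   variables (3-/12-month mRS, homocysteine) when `add_followup = TRUE`.
#' @param add_followup add the sparsely measured follow-up columns.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_male = 101, n_female = 63,
                              codebook = cohort_codebook(),
                              outcome_coefs = c(gcs = 0.35, adl = 0.15,
                                                mrs_discharge = 0.30,
                                                vol = -0.20),
                              outcome_mean = -0.2, outcome_sd = 0.85,
                              pre_item9_probs = c(0.25, 0.35, 0.25, 0.15),
                              n_incomplete = 0,
                              followup_missing_rate = 0.65,
                              add_followup = FALSE, seed = 1L) {
  if (any(codebook$sd_male <= 0, na.rm = TRUE) ||
      any(codebook$sd_female <= 0, na.rm = TRUE))
    stop_asym("simulate", "all SDs must be > 0")
  pv <- c(codebook$prev_male, codebook$prev_female)
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    stop_asym("simulate", "prevalences must be in [0, 1]")
  if (outcome_sd <= 0) stop_asym("simulate", "outcome_sd must be > 0")
  stopifnot(length(pre_item9_probs) == 4, all(pre_item9_probs >= 0))
  structure(list(n_male = n_male, n_female = n_female, codebook = codebook,
                 outcome_coefs = outcome_coefs, outcome_mean = outcome_mean,
                 outcome_sd = outcome_sd,
                 pre_item9_probs = pre_item9_probs / sum(pre_item9_probs),
                 n_incomplete = n_incomplete,
                 followup_missing_rate = followup_missing_rate,
                 add_followup = isTRUE(add_followup), seed = as.integer(seed)),
            class = "simulation_params")
}

# truncated normal by inverse-CDF (vectorized over n)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort of `n_male + n_female` patients under
#' [simulation_params()]. Deterministic per seed. With `add_followup` and
#' `n_incomplete > 0` the table emulates the enrolment-stage data (before
#' quality control): sparse follow-up variables plus rows with missing
#' retained indicators, so that [drop_incomplete()] reproduces the published
#' enrolment-to-analysis flow.
#'
#' @param params a [simulation_params()].
#' @return A `cohort_table` (provenance records generator and seed).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  cb <- params$codebook
  n <- params$n_male + params$n_female
  with_seed(params$seed, {
    gender <- c(rep("male", params$n_male), rep("female", params$n_female))
    df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     gender = gender, stringsAsFactors = FALSE)
    male <- gender == "male"
    for (i in seq_len(nrow(cb))) {
      v <- cb$name[i]
      x <- numeric(n)
      if (cb$type[i] == "binary") {
        x[male] <- rbinom(sum(male), 1, cb$prev_male[i])
        x[!male] <- rbinom(sum(!male), 1, cb$prev_female[i])
      } else {
        x[male] <- rtruncnorm(sum(male), cb$mean_male[i], cb$sd_male[i],
                              cb$lo[i], cb$hi[i])
        x[!male] <- rtruncnorm(sum(!male), cb$mean_female[i], cb$sd_female[i],
                               cb$lo[i], cb$hi[i])
        if (cb$integer[i]) x <- round(x)
      }
      df[[v]] <- x
    }
    # outcome model: latent deterioration score, discretized via item 9
    z <- function(v) as.numeric(scale(df[[v]]))
    lin <- params$outcome_mean
    for (v in names(params$outcome_coefs)) {
      if (sd(df[[v]]) > 0) lin <- lin + params$outcome_coefs[[v]] * z(v)
    }
    latent <- lin + rnorm(n, 0, params$outcome_sd)
    pre <- sample(0:3, n, replace = TRUE, prob = params$pre_item9_probs)
    post <- pmin(pmax(pre + round(latent), 0), 3)
    df$nihss9_pre <- pre
    df$nihss9_post <- post
    lng <- compute_lang(pre, post)
    df$lang <- lng$lang
    df$lang_improved <- lng$improved
    if (params$add_followup) {
      df$mrs_3mo <- round(rtruncnorm(n, 3, 1.3, 0, 6))
      df$mrs_12mo <- round(rtruncnorm(n, 2.6, 1.4, 0, 6))
      df$homocysteine <- rtruncnorm(n, 15, 6, 2, 60)
      for (v in c("mrs_3mo", "mrs_12mo", "homocysteine")) {
        df[[v]][runif(n) < params$followup_missing_rate] <- NA
      }
    }
    if (params$n_incomplete > 0) {
      # distinct rows each lose one retained biochemistry value
      rows <- sample.int(n, params$n_incomplete)
      targets <- sample(c("crp", "ddimer", "fibrinogen", "ldh", "hba1c"),
                        params$n_incomplete, replace = TRUE)
      for (j in seq_along(rows)) df[rows[j], targets[j]] <- NA
    }
  })
  as_cohort_table(df, provenance = list(
    source = "synthetic", seed = params$seed,
    generator = "simulate_cohort",
    n_male = params$n_male, n_female = params$n_female))
}

#' Simulate the enrolment-stage cohort (quality-control emulation)
#'
#' A 204-row table whose missingness is concentrated in the three sparsely
#' measured follow-up variables, plus `n_incomplete` rows missing a retained
#' indicator, so that excluding the follow-up variables and complete-case
#' filtering yields exactly `204 - n_incomplete` analysable patients.
#'
#' @param seed integer RNG seed.
#' @param n_male,n_female enrolment group sizes (default 126/78 = 204,
#'   the analysed 101/63 scaled to the enrolment count).
#' @param n_incomplete rows with missing retained indicators (default 40).
#' @return A `cohort_table` with follow-up columns and missing values.
#' @export
simulate_enrollment <- function(seed = 1L, n_male = 126, n_female = 78,
                                n_incomplete = 40) {
  simulate_cohort(simulation_params(n_male = n_male, n_female = n_female,
                                    n_incomplete = n_incomplete,
                                    add_followup = TRUE, seed = seed))
}

#' Follow-up variables excluded by quality control
#' @return Character vector of column names.
#' @export
followup_vars <- function() c("mrs_3mo", "mrs_12mo", "homocysteine")
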