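#' Apply the standard variable transforms
#'
#' Adds `sqrt_body_fat` (body fat is square-root transformed for
#' normality) and natural-log columns for any kinematic summaries present
#' (`v_mean`, `v_max`, `a_mean`, `a_max`); originals are always retained.
#' Rows with non-positive values in a log column are excluded with a
#' message stating the count. Negative body fat is an input error.
#'
#' @param df cohort records and/or kinematics table.
#' @return the transformed tibble.
#' @export
apply_transforms <- function(df) {
  df <- tibble::as_tibble(df)
  if ("body_fat" %in% names(df)) {
    if (any(df$body_fat < 0, na.rm = TRUE)) {
      stop("negative body fat; cannot square-root transform", call. = FALSE)
    }
    df$sqrt_body_fat <- sqrt(df$body_fat)
  }
  kin <- intersect(c("v_mean", "v_max", "a_mean", "a_max"), names(df))
  if (length(kin) > 0) {
    bad <- rep(FALSE, nrow(df))
    for (col in kin) bad <- bad | (!is.na(df[[col]]) & df[[col]] <= 0)
    if (any(bad)) {
      message(sprintf("apply_transforms: excluded %d row(s) with non-positive kinematic values",
                      sum(bad)))
      df <- df[!bad, ]
    }
    for (col in kin) df[[paste0("ln_", col)]] <- log(df[[col]])
  }
  df
}

#' Build the fixed-effect design table
#'
#' Expands cohort records into the model design: intercept, treatment
#' (LF = 0, HF = 1), experimental day, day squared, age (days), the
#' treatment x day and treatment x age interactions, the alive flag, and
#' all grouping columns present (`mother_id`, `offspring_id`,
#' `dish_label`, `trial_index`). One row per observation; nothing is
#' dropped. The coding is recorded in the `coding` attribute.
#'
#' @param records cohort records with `treatment`, `experimental_day`,
#'   `age_days` (and optionally `alive` plus grouping columns).
#' @return design tibble.
#' @export
build_design <- function(records) {
  if (!all(records$treatment %in% c("LF", "HF"))) {
    bad <- setdiff(unique(records$treatment), c("LF", "HF"))
    stop("unknown treatment level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  trt <- as.integer(records$treatment == "HF")
  design <- tibble::tibble(
    intercept = 1L,
    treatment = trt,
    day = records$experimental_day,
    day2 = records$experimental_day^2,
    age = records$age_days,
    treatment_day = trt * records$experimental_day,
    treatment_age = trt * records$age_days)
  if ("alive" %in% names(records)) design$alive <- as.integer(records$alive)
  for (g in intersect(c("mother_id", "offspring_id", "dish_label", "trial_index"),
                      names(records))) {
    design[[g]] <- records[[g]]
  }
  attr(design, "coding") <- c(
    "treatment: LF = 0, HF = 1",
    "day: experimental day (1-51), uncentred; day2 = day^2 on the raw scale",
    "age: days after birth (0 or 7)",
    "interactions: products of the coded columns",
    "alive: found alive = 1, dead = 0")
  design
}

#' Per-treatment day slopes with a clustered bootstrap
#'
#' A desk-scale estimator of the treatment x day interaction: within each
#' treatment the slope of a trait against experimental day is estimated by
#' pooled least squares on mother-mean-centred data (centring removes the
#' maternal random intercepts exactly), with age at measurement partialled
#' out alongside day when it varies, so the day slope is not contaminated
#' by chance day-age correlation. Uncertainty comes from resampling
#' mothers -- the top-level cluster -- with replacement (percentile
#' intervals on per-mother sufficient statistics). The interaction
#' contrast is the LF minus HF slope difference.
#'
#' @param records cohort records (`mother_id`, `treatment`,
#'   `experimental_day`, and the trait column).
#' @param trait name of the trait column.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return a tibble with rows `LF`, `HF` and `interaction`: `trait`,
#'   `group`, `slope` (trait units/day), `ci_lo`, `ci_hi`, `n_mothers`,
#'   `n_boot`, `seed`.
#' @export
estimate_treatment_slopes <- function(records, trait, n_boot = 1000,
                                      seed = 1L, conf = 0.95) {
  stopifnot(trait %in% names(records))
  y_all <- records[[trait]]
  alpha <- (1 - conf) / 2

  has_age <- "age_days" %in% names(records) &&
    stats::var(records$age_days) > 0
  stats_by_trt <- lapply(c("LF", "HF"), function(trt) {
    sel <- records$treatment == trt
    mids <- unique(records$mother_id[sel])
    if (length(mids) < 5) {
      stop(sprintf("need at least 5 mothers in treatment %s", trt), call. = FALSE)
    }
    k <- if (has_age) 2L else 1L
    sxx <- array(0, c(k, k, length(mids)))
    sxy <- matrix(0, k, length(mids))
    for (i in seq_along(mids)) {
      m <- sel & records$mother_id == mids[i]
      x <- cbind(day = records$experimental_day[m],
                 if (has_age) records$age_days[m])
      x <- sweep(x, 2, colMeans(x))
      yc <- y_all[m] - mean(y_all[m])
      sxx[, , i] <- crossprod(x)
      sxy[, i] <- crossprod(x, yc)
    }
    if (sum(sxx[1, 1, ]) == 0) {
      stop(sprintf("degenerate design in treatment %s: no within-mother day variation", trt),
           call. = FALSE)
    }
    list(sxx = sxx, sxy = sxy, n = length(mids))
  })
  names(stats_by_trt) <- c("LF", "HF")
  slope_of <- function(st, idx) {
    a <- rowSums(st$sxx[, , idx, drop = FALSE], dims = 2)
    b <- rowSums(st$sxy[, idx, drop = FALSE])
    # drop the age column if it is collinear in this (re)sample
    if (ncol(a) == 2 && (a[2, 2] == 0 || abs(det(a)) < 1e-10 * a[1, 1])) {
      a <- a[1, 1, drop = FALSE]
      b <- b[1]
    }
    solve(a, b)[1]
  }
  slopes <- vapply(stats_by_trt, function(st) slope_of(st, seq_len(st$n)), numeric(1))

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("LF", "HF")))
  for (b in seq_len(n_boot)) {
    for (trt in c("LF", "HF")) {
      st <- stats_by_trt[[trt]]
      boot[b, trt] <- slope_of(st, sample.int(st$n, st$n, replace = TRUE))
    }
  }
  boot_int <- boot[, "LF"] - boot[, "HF"]
  ci <- function(x) stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)

  tibble::tibble(
    trait = trait,
    group = c("LF", "HF", "interaction"),
    slope = unname(c(slopes, slopes[["LF"]] - slopes[["HF"]])),
    ci_lo = c(ci(boot[, "LF"])[1], ci(boot[, "HF"])[1], ci(boot_int)[1]),
    ci_hi = c(ci(boot[, "LF"])[2], ci(boot[, "HF"])[2], ci(boot_int)[2]),
    n_mothers = c(stats_by_trt$LF$n, stats_by_trt$HF$n,
                  stats_by_trt$LF$n + stats_by_trt$HF$n),
    n_boot = n_boot, seed = seed)
}

# column glossary used by the data dictionary
.column_glossary <- c(
  fish_id = "fish identifier",
  mother_id = "mother identifier (top-level cluster)",
  offspring_id = "offspring identifier",
  trial_id = "trial identifier",
  trial_index = "startle trial number within fish (1-3)",
  dish_label = "Petri-dish grid position",
  treatment = "maternal food ration: LF (low) / HF (high)",
  experimental_day = "day of the experiment at birth (1-51)",
  age_days = "age at measurement, days",
  period = "feeding-session period: control / feeding",
  segment = "profile segment label",
  frame = "0-based frame index",
  time_s = "time, s",
  x_mm = "centroid x, mm (origin dish centre, rightwards)",
  y_mm = "centroid y, mm (origin dish centre, downwards)",
  v = "speed, mm/s", a = "acceleration, mm/s^2",
  v_mean = "mean speed, mm/s",
  v_max = "robust maximum speed (mean above the 95% quantile), mm/s",
  a_mean = "mean acceleration, mm/s^2",
  a_max = "robust maximum acceleration (mean above the 95% quantile), mm/s^2",
  n_frames = "number of valid frames summarised",
  q = "quantile used for the robust maximum",
  dry_mass = "dry mass, mg",
  lean_mass = "lean dry mass (dry mass minus body fat), mg",
  body_fat = "body fat, mg",
  sqrt_body_fat = "sqrt(body fat), sqrt(mg) [normalising transform]",
  alive = "offspring found alive (TRUE/1) or dead (FALSE/0)",
  response = "classified as fast-start response",
  threshold = "response threshold, mm/s",
  valid = "frame carries a valid measurement",
  gap_filled = "frame position linearly interpolated over a short gap")

#' Export analysis-ready tables with a data dictionary
#'
#' Writes each table as UTF-8 CSV (one observation per row) plus a
#' `data_dictionary.txt` listing every column with its unit and transform,
#' ready for external mixed-model software.
#'
#' @param tables named list of data frames.
#' @param dir destination directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_tidy <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  dict <- c("Data dictionary", "===============", "")
  for (nm in names(tables)) {
    tbl <- as.data.frame(tables[[nm]])
    path <- file.path(dir, paste0(nm, ".csv"))
    if (nrow(tbl) == 0) warning(sprintf("table '%s' is empty; writing header only", nm))
    utils::write.csv(tbl, path, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
    dict <- c(dict, paste0(nm, ".csv (", nrow(tbl), " rows)"))
    for (col in names(tbl)) {
      desc <- if (startsWith(col, "ln_")) {
        paste0("ln(", sub("^ln_", "", col), "), natural log of the raw column")
      } else {
        .column_glossary[col]
      }
      if (is.na(desc)) desc <- paste0("(", class(tbl[[col]])[1], ")")
      dict <- c(dict, sprintf("  %-18s %s", col, desc))
    }
    dict <- c(dict, "")
  }
  dict_path <- file.path(dir, "data_dictionary.txt")
  writeLines(dict, dict_path)
  invisible(c(paths, dict_path))
}
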