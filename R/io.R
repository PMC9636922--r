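#' salmodyn: adaptive dynamics of salmon body size under river regulation
#'
#' The package covers four analysis stages: a temporal Wright-Fisher drift
#' null model for allele-frequency change ([fit_drift_model()],
#' [focal_posterior()], [drift_envelope()], [drift_probability()]); a
#' sex-specific natural genetic effect model for log body mass at two
#' large-effect loci ([fit_effect_model()], [genotype_mass_ratio()]); a
#' moving-optimum state-space quantitative-genetic model fitted by penalized
#' maximum likelihood ([fit_dynamics()]); and rates-of-evolution summaries
#' ([rate_of_change()], [decompose_mass_change()]). A synthetic-data
#' generator ([sim_scenario()], [simulate_study()]) emulates the study
#' design with known ground truth, and [run_pipeline()] orchestrates an
#' end-to-end run.
#'
#' @keywords internal
"_PACKAGE"

## NULL sentinel used for period/year columns read from CSV
.sex_levels <- c("F", "M", "unknown")
.origin_levels <- c("wild", "hatchery", "unknown")

#' Construct a genotype panel
#'
#' A genotype panel stores biallelic calls as tracked-allele counts
#' (0, 1, 2 or `NA`) for a set of individuals at a set of loci, together with
#' individual metadata (sampling period, sex, origin) and locus metadata
#' (class `neutral`/`focal`, tracked-allele label). For focal loci the
#' tracked allele is the early-maturation allele `E`; the late allele `L`
#' has frequency `1 - freq(E)`.
#'
#' @param calls integer matrix, individuals x loci, entries in `{0,1,2,NA}`.
#' @param info data.frame with columns `individual_id`, `period`, `sex`
#'   (`F`/`M`/`unknown`), `origin` (`wild`/`hatchery`/`unknown`), one row per
#'   row of `calls`.
#' @param loci data.frame with columns `locus_id`, `class`
#'   (`neutral`/`focal`), `tracked_allele`; one row per column of `calls`.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(calls, info, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(info))
    stop("`info` must have one row per individual in `calls`", call. = FALSE)
  if (ncol(calls) != nrow(loci))
    stop("`loci` must have one row per column of `calls`", call. = FALSE)
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE))
    stop("genotype calls must be 0, 1, 2 or missing", call. = FALSE)
  req <- c("individual_id", "period", "sex", "origin")
  if (!all(req %in% names(info)))
    stop("info lacks mandatory columns: ",
         paste(setdiff(req, names(info)), collapse = ", "), call. = FALSE)
  if (!all(c("locus_id", "class") %in% names(loci)))
    stop("loci lacks mandatory columns locus_id/class", call. = FALSE)
  if (!all(loci$class %in% c("neutral", "focal")))
    stop("locus class must be 'neutral' or 'focal'", call. = FALSE)
  if (is.null(loci$tracked_allele)) loci$tracked_allele <- NA_character_
  info$sex <- .check_levels(info$sex, .sex_levels, "sex")
  info$origin <- .check_levels(info$origin, .origin_levels, "origin")
  rownames(calls) <- info$individual_id
  colnames(calls) <- loci$locus_id
  structure(list(calls = calls, info = as.data.frame(info),
                 loci = as.data.frame(loci)),
            class = "genotype_panel")
}

.check_levels <- function(x, levels, what) {
  x <- as.character(x)
  x[is.na(x)] <- "unknown"
  if (!all(x %in% levels))
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(setdiff(x, levels)), collapse = ", ")),
         call. = FALSE)
  x
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d loci (%d neutral, %d focal)\n",
              nrow(x$calls), ncol(x$calls),
              sum(x$loci$class == "neutral"), sum(x$loci$class == "focal")))
  cat("periods:", paste(unique(x$info$period), collapse = ", "), "\n")
  invisible(x)
}

#' Per-individual genotyping call rate
#'
#' @param panel a [genotype_panel()].
#' @return numeric vector, fraction of non-missing calls per individual.
#' @export
call_rate <- function(panel) {
  rowMeans(!is.na(panel$calls))
}

#' Read a genotype panel from CSV
#'
#' Expects one row per individual with metadata columns and one column per
#' locus, plus a companion locus table (`locus_id`, `class`,
#' `tracked_allele`). Unparseable calls become missing.
#'
#' @param path path to the genotype CSV.
#' @param loci_path path to the locus metadata CSV.
#' @param mapping named list mapping the canonical column names
#'   `individual_id`, `period`, `sex`, `origin` to the headers used in the
#'   file (defaults to identity).
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, loci_path, mapping = list()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  loci <- utils::read.csv(loci_path, stringsAsFactors = FALSE)
  cn <- c(individual_id = "individual_id", period = "period",
          sex = "sex", origin = "origin")
  cn[names(mapping)] <- unlist(mapping)
  miss <- setdiff(unname(cn), names(raw))
  if (length(miss))
    stop("genotype file lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("locus_id", "class") %in% names(loci)))
    stop("locus file lacks locus_id/class columns", call. = FALSE)
  locus_cols <- intersect(loci$locus_id, names(raw))
  if (!length(locus_cols))
    stop("no locus columns from the locus table found in the genotype file",
         call. = FALSE)
  loci <- loci[match(locus_cols, loci$locus_id), , drop = FALSE]
  calls <- suppressWarnings(
    vapply(raw[locus_cols], function(v) as.integer(v), integer(nrow(raw))))
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = nrow(raw))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) {
    nb <- unique(calls[!ok])
    stop("non-biallelic genotype coding (values outside 0/1/2): ",
         paste(nb, collapse = ", "), call. = FALSE)
  }
  info <- data.frame(individual_id = raw[[cn["individual_id"]]],
                     period = raw[[cn["period"]]],
                     sex = raw[[cn["sex"]]],
                     origin = raw[[cn["origin"]]],
                     stringsAsFactors = FALSE)
  genotype_panel(calls, info, loci)
}

#' Write a genotype panel to CSV
#'
#' Writes the genotype table and its companion locus table; the canonical
#' dialect round-trips losslessly through [read_genotypes()].
#'
#' @param panel a [genotype_panel()].
#' @param path,loci_path output CSV paths.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, loci_path) {
  out <- cbind(panel$info[c("individual_id", "period", "sex", "origin")],
               as.data.frame(panel$calls, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.csv(panel$loci[c("locus_id", "class", "tracked_allele")],
                   loci_path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Remove individuals with low genotyping success
#'
#' @param panel a [genotype_panel()].
#' @param min_rate minimum fraction of non-missing calls; individuals with
#'   call rate `>= min_rate` are retained. Default 0.7, the study's filter.
#' @return filtered [genotype_panel()]; the number removed is attached as
#'   attribute `n_removed` and reported via `message()`.
#' @export
filter_call_rate <- function(panel, min_rate = 0.7) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  keep <- call_rate(panel) >= min_rate
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(sprintf("filter_call_rate: removed %d individual(s) below %.2f",
                    n_rm, min_rate))
  out <- genotype_panel(panel$calls[keep, , drop = FALSE],
                        panel$info[keep, , drop = FALSE], panel$loci)
  attr(out, "n_removed") <- n_rm
  out
}

#' Tracked-allele counts per locus and period
#'
#' For each locus `i` and sampling period `t`, computes `A(i,t)`, the number
#' of tracked alleles among non-missing calls, and `T(i,t) = 2 x` the number
#' of non-missing individuals. Loci fixed (`A = 0` or `A = T`) in every
#' period can be dropped, as done for the neutral drift panel.
#'
#' @param panel a [genotype_panel()].
#' @param drop_fixed drop loci fixed in all periods (default `TRUE`).
#' @param periods optional character vector giving the period order; defaults
#'   to order of first appearance.
#' @return data.frame of class `allele_counts` with columns `locus_id`,
#'   `class`, `period`, `A`, `T`.
#' @export
count_alleles <- function(panel, drop_fixed = TRUE, periods = NULL) {
  if (is.null(periods)) periods <- unique(panel$info$period)
  res <- vector("list", length(periods))
  for (k in seq_along(periods)) {
    rows <- panel$info$period == periods[k]
    sub <- panel$calls[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    A <- colSums(sub, na.rm = TRUE)
    res[[k]] <- data.frame(locus_id = panel$loci$locus_id,
                           class = panel$loci$class,
                           period = periods[k],
                           A = as.integer(A), T = as.integer(2L * n_ok),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (drop_fixed) {
    fixed_all <- vapply(split(out, out$locus_id), function(d)
      all(d$A == 0L | d$A == d$T), logical(1))
    drop <- names(fixed_all)[fixed_all]
    out <- out[!(out$locus_id %in% drop), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Read catch records from CSV
#'
#' @param path CSV with columns `year`, `mass_kg` and optionally `date`,
#'   `sea_age`, `smolt_age`, `sex`, `origin`.
#' @return data.frame of class `catch_table`; records with non-positive mass
#'   are rejected with a warning.
#' @export
read_catch <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "mass_kg")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("catch file lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("date", "sea_age", "smolt_age", "sex", "origin"))
    if (is.null(raw[[col]]))
      raw[[col]] <- if (col %in% c("sea_age", "smolt_age")) NA_integer_ else NA_character_
  catch_table(raw)
}

#' Construct/validate a catch table
#'
#' @param df data.frame with at least `year` and `mass_kg`.
#' @return data.frame of class `catch_table`.
#' @export
catch_table <- function(df) {
  df <- as.data.frame(df)
  df$year <- as.integer(df$year)
  df$mass_kg <- as.numeric(df$mass_kg)
  bad <- !is.finite(df$mass_kg) | df$mass_kg <= 0
  if (any(bad)) {
    warning(sprintf("catch_table: rejected %d record(s) with non-positive mass",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (!is.null(df$sea_age)) {
    df$sea_age <- as.integer(df$sea_age)
    if (any(df$sea_age < 1, na.rm = TRUE))
      stop("sea_age must be >= 1 when present", call. = FALSE)
  }
  if (!is.null(df$sex)) df$sex <- .check_levels(df$sex, .sex_levels, "sex")
  if (!is.null(df$origin))
    df$origin <- .check_levels(df$origin, .origin_levels, "origin")
  rownames(df) <- NULL
  class(df) <- c("catch_table", "data.frame")
  df
}

#' Annual phenotype summaries on the natural-log-gram scale
#'
#' Mass is analysed as `ln(grams)`; kilograms on input are converted before
#' taking logs, so that e.g. 10.5 kg maps to about 9.26 ln g. The per-year
#' mean is the mean of per-record log values (not the log of the mean mass).
#' Years inside `years` with no records are kept with `n = 0` and missing
#' summaries, representing data gaps explicitly.
#'
#' @param catch a [catch_table()].
#' @param years optional integer vector of years to cover (gap years appear
#'   with `n = 0`); defaults to observed years only.
#' @return data.frame of class `annual_phenotypes` with columns `year`, `n`,
#'   `mean_ln_mass`, `se_ln_mass`, `sd_ln_mass`, `mean_mass_kg`.
#' @export
annual_summary <- function(catch, years = NULL) {
  stopifnot(nrow(catch) >= 1)
  ln_g <- log(catch$mass_kg * 1000)
  if (is.null(years)) years <- sort(unique(catch$year))
  out <- data.frame(year = as.integer(years), n = 0L,
                    mean_ln_mass = NA_real_, se_ln_mass = NA_real_,
                    sd_ln_mass = NA_real_, mean_mass_kg = NA_real_)
  for (k in seq_along(years)) {
    idx <- catch$year == years[k]
    n <- sum(idx)
    out$n[k] <- n
    if (n == 0) next
    out$mean_ln_mass[k] <- mean(ln_g[idx])
    out$mean_mass_kg[k] <- mean(catch$mass_kg[idx])
    if (n > 1) {
      out$sd_ln_mass[k] <- stats::sd(ln_g[idx])
      out$se_ln_mass[k] <- out$sd_ln_mass[k] / sqrt(n)
    }
  }
  class(out) <- c("annual_phenotypes", "data.frame")
  out
}

#' Read an annual waterflow series from CSV
#'
#' @param path CSV with columns `year` and `flow_m3s` (June-September mean
#'   discharge in m^3/s).
#' @return data.frame of class `flow_series` with the derived log-flow
#'   covariate `ln_flow`.
#' @export
read_flow <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "flow_m3s") %in% names(raw)))
    stop("flow file needs columns year, flow_m3s", call. = FALSE)
  flow_series(raw$year, raw$flow_m3s)
}

#' Construct a flow series
#'
#' @param year integer years (must be contiguous).
#' @param flow_m3s positive flows, m^3/s.
#' @return data.frame of class `flow_series`.
#' @export
flow_series <- function(year, flow_m3s) {
  year <- as.integer(year)
  flow_m3s <- as.numeric(flow_m3s)
  stopifnot(length(year) == length(flow_m3s))
  if (any(!is.finite(flow_m3s) | flow_m3s <= 0))
    stop("flow must be positive", call. = FALSE)
  o <- order(year)
  year <- year[o]; flow_m3s <- flow_m3s[o]
  if (length(year) > 1 && any(diff(year) != 1L))
    stop("flow series must be contiguous in year", call. = FALSE)
  out <- data.frame(year = year, flow_m3s = flow_m3s,
                    ln_flow = log(flow_m3s))
  class(out) <- c("flow_series", "data.frame")
  out
}

#' Write catch and flow tables
#'
#' @param x a `catch_table` or `flow_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  cols <- if (inherits(x, "flow_series")) c("year", "flow_m3s") else names(x)
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}
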