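#' Derive weekly FV days and the non-daily outcome
#'
#' Weekly fruit days and vegetable days are summed and capped at 7 to
#' give the days-per-week of fruit/vegetable (FV) consumption; a
#' respondent is a non-daily consumer when that capped sum is below 7.
#' Note the semantics of the cap: fruit on 4 days plus vegetables on 3
#' days counts as daily even if the two never coincide; the rule is
#' applied verbatim.
#'
#' @param fruit_days,veg_days integer vectors in 0..7.
#' @return data.frame with columns \code{fv_days} (0..7) and
#'   \code{non_daily} (logical).
#' @examples
#' derive_outcome(5, 4)  # fv_days 7, daily
#' derive_outcome(3, 3)  # fv_days 6, non-daily
#' @export
derive_outcome <- function(fruit_days, veg_days) {
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 7 & v == floor(v)))
  if (!ok(fruit_days) || !ok(veg_days))
    stop("fruit_days and veg_days must be integers in 0..7")
  fv <- pmin(fruit_days + veg_days, 7)
  data.frame(fv_days = fv, non_daily = fv < 7)
}

#' Apply the analytic-sample exclusion rules
#'
#' Drops records missing age, gender, education, or either of the two
#' FV items, and logs how many records were missing each field
#' (a record missing several fields is counted under each).
#'
#' @param records participant data.frame with columns \code{age},
#'   \code{gender}, \code{education}, \code{fruit_days},
#'   \code{veg_days}.
#' @return list with \code{analytic} (retained rows, unaltered),
#'   \code{n_excluded}, and \code{exclusion_log} (named counts per
#'   field).
#' @export
apply_exclusions <- function(records) {
  fields <- c("age", "gender", "education", "fruit_days", "veg_days")
  miss <- setdiff(fields, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(records)) {
    warning("all records excluded: analytic set is empty")
    return(list(analytic = records, n_excluded = 0L,
                exclusion_log = stats::setNames(rep(0L, length(fields)), fields)))
  }
  is_missing <- sapply(fields, function(f) {
    v <- records[[f]]
    is.na(v) | (is.character(v) & !nzchar(as.character(v)))
  })
  if (nrow(records) == 1) is_missing <- matrix(is_missing, nrow = 1,
                                               dimnames = list(NULL, fields))
  drop <- apply(is_missing, 1, any)
  log <- colSums(is_missing[drop, , drop = FALSE])
  analytic <- records[!drop, , drop = FALSE]
  rownames(analytic) <- NULL
  if (!nrow(analytic))
    warning("all records excluded: analytic set is empty")
  list(analytic = analytic,
       n_excluded = sum(drop),
       exclusion_log = log)
}

#' Add derived outcome and education recode to an analytic set
#'
#' Convenience wrapper: runs \code{\link{derive_outcome}} and adds the
#' binary education recode (below completed secondary vs completed
#' secondary or above) used by the models, keeping the 4-level variable
#' for descriptive tables.
#'
#' @param analytic analytic participant data.frame.
#' @return the input with columns \code{fv_days}, \code{non_daily},
#'   \code{education_low} appended.
#' @export
prepare_outcome <- function(analytic) {
  d <- derive_outcome(analytic$fruit_days, analytic$veg_days)
  analytic$fv_days <- d$fv_days
  analytic$non_daily <- d$non_daily
  analytic$education_low <- analytic$education %in% c("<primary", "primary")
  analytic
}

.mw_test <- function(v, g) {
  # Mann-Whitney, normal approximation with tie correction
  if (min(table(g)) < 1 || length(unique(v)) < 2) return(NA_real_)
  suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE, correct = TRUE)$p.value)
}

.fmt_median_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Bivariate daily vs non-daily comparison table
#'
#' Descriptive comparison of participants by FV consumption frequency:
#' categorical rows (gender, 4-level education) compared with the
#' chi-square test (no continuity correction), continuous rows (age,
#' population density, social environment index, and every
#' establishment density) with the Mann-Whitney U test (normal
#' approximation with tie correction); continuous rows report median
#' and interquartile range.
#'
#' @param participants analytic set from \code{\link{prepare_outcome}}.
#' @param metrics \code{\link{neighbourhood_metrics}} joined by
#'   \code{neighbourhood_id}.
#' @return data.frame with columns \code{variable}, \code{total},
#'   \code{daily}, \code{non_daily}, \code{test}, \code{p_value}.
#' @export
bivariate_table <- function(participants, metrics) {
  if (!nrow(participants)) stop("analytic set is empty")
  dat <- merge(participants, metrics, by.x = "neighbourhood_id", by.y = "id",
               all.x = TRUE, sort = FALSE)
  g <- factor(ifelse(dat$non_daily, "non_daily", "daily"),
              levels = c("daily", "non_daily"))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(..., stringsAsFactors = FALSE)

  n_tab <- table(g)
  add(variable = "n", total = as.character(nrow(dat)),
      daily = as.character(n_tab[["daily"]]),
      non_daily = as.character(n_tab[["non_daily"]]), test = "", p_value = NA_real_)

  for (v in c("gender", "education")) {
    tab <- table(dat[[v]], g)
    p <- if (all(dim(tab) >= 2) && all(rowSums(tab) > 0))
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value) else NA_real_
    for (lev in rownames(tab)) {
      tot <- sum(tab[lev, ])
      add(variable = paste0(v, ": ", lev),
          total = sprintf("%d (%.1f)", tot, 100 * tot / nrow(dat)),
          daily = sprintf("%d (%.1f)", tab[lev, "daily"],
                          100 * tab[lev, "daily"] / max(n_tab[["daily"]], 1)),
          non_daily = sprintf("%d (%.1f)", tab[lev, "non_daily"],
                              100 * tab[lev, "non_daily"] / max(n_tab[["non_daily"]], 1)),
          test = "chi-square",
          p_value = if (lev == rownames(tab)[1]) p else NA_real_)
    }
  }

  cont <- c("age", "popdens", "sei",
            grep("^density_", names(dat), value = TRUE))
  for (v in intersect(cont, names(dat))) {
    vv <- dat[[v]]
    if (all(is.na(vv))) next
    add(variable = v,
        total = .fmt_median_iqr(vv[!is.na(vv)]),
        daily = .fmt_median_iqr(vv[g == "daily" & !is.na(vv)]),
        non_daily = .fmt_median_iqr(vv[g == "non_daily" & !is.na(vv)]),
        test = "mann-whitney",
        p_value = .mw_test(vv[!is.na(vv)], g[!is.na(vv)]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
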