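# Immunoreactive score (IRS): the product of a 0-4 positive-cell
# proportion score and a 0-3 staining intensity score, binned into
# negative (0-1), mild (2-3), moderate (4-8) and strong (9-12) expression.
# The published proportion bins are stated on integers and leave (50,51)
# and (80,81) undefined for continuous percentages; they are closed as
# 0: pct = 0; 1: 0 < pct < 10; 2: 10 <= pct <= 50; 3: 50 < pct <= 80;
# 4: pct > 80, preserving every printed integer anchor and yielding a
# total function on [0, 100].

#' Staining proportion score (0-4)
#'
#' @param pct percentage of positive cells, in \[0, 100\]. Vectorized.
#' @return integer score: 0 iff pct = 0; 1 iff 0 < pct < 10;
#'   2 iff 10 <= pct <= 50; 3 iff 50 < pct <= 80; 4 iff pct > 80.
#' @export
proportion_score <- function(pct) {
  if (any(is.na(pct)) || any(pct < 0 | pct > 100))
    stop("positive-cell percentage must lie in [0, 100]")
  ifelse(pct == 0, 0L,
  ifelse(pct < 10, 1L,
  ifelse(pct <= 50, 2L,
  ifelse(pct <= 80, 3L, 4L))))
}

#' Immunoreactive score and expression category
#'
#' `IRS = proportion_score(pct) * intensity`, binned as negative (0-1),
#' mild (2-3), moderate (4-8), strong (9-12).
#'
#' @param pct percentage of positive cells in \[0, 100\]. Vectorized.
#' @param intensity integer staining intensity 0-3.
#' @return data.frame with `proportion_score`, `intensity_score`, `irs`,
#'   `category` (factor negative/mild/moderate/strong).
#' @export
irs_score <- function(pct, intensity) {
  if (any(is.na(intensity)) || any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3))
    stop("intensity must be an integer in 0..3")
  ps <- proportion_score(pct)
  irs <- ps * as.integer(intensity)
  category <- cut(irs, breaks = c(-0.5, 1.5, 3.5, 8.5, 12.5),
                  labels = c("negative", "mild", "moderate", "strong"))
  data.frame(proportion_score = ps, intensity_score = as.integer(intensity),
             irs = irs, category = category)
}

#' Score an IHC specimen table
#'
#' @param specimens data.frame with columns `specimen_id`, `marker`,
#'   `group`, `positive_cell_pct`, `intensity`.
#' @return the input with IRS columns appended.
#' @export
score_ihc_table <- function(specimens) {
  req <- c("specimen_id", "marker", "group", "positive_cell_pct", "intensity")
  miss <- setdiff(req, colnames(specimens))
  if (length(miss)) stop("IHC table missing column(s): ",
                         paste(miss, collapse = ", "))
  cbind(specimens, irs_score(specimens$positive_cell_pct,
                             specimens$intensity))
}

#' Two-sample t-test (Welch by default)
#'
#' Hand-implemented two-tailed two-sample t statistic; Welch
#' (unequal-variance) by default, pooled-variance Student's via
#' `var_equal = TRUE`. Two identical groups give t = 0, p = 1.
#'
#' @param x,y numeric vectors with >= 2 observations each.
#' @param var_equal pool the variances (classic Student's t)?
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 observations")
  n1 <- length(x); n2 <- length(y)
  m <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, df = df, p_value = if (m == 0) 1 else 0,
                mean_diff = m))
  }
  t <- m / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df), mean_diff = m)
}

#' Compare marker IRS between each group and a control group
#'
#' @param scored data.frame from [score_ihc_table()].
#' @param control name of the control group (default `"normal"`).
#' @param var_equal forwarded to [welch_t_test()].
#' @return data.frame with one row per (marker, non-control group):
#'   group means, t, df, p_value.
#' @export
compare_to_control <- function(scored, control = "normal",
                               var_equal = FALSE) {
  if (!control %in% scored$group)
    stop("control group '", control, "' not present")
  rows <- list()
  for (mk in unique(scored$marker)) {
    d <- scored[scored$marker == mk, ]
    ctrl <- d$irs[d$group == control]
    for (g in setdiff(unique(d$group), control)) {
      tt <- welch_t_test(d$irs[d$group == g], ctrl, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, group = g, control = control,
        mean_group = mean(d$irs[d$group == g]), mean_control = mean(ctrl),
        t = tt$t, df = tt$df, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
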