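#' Weight-loss component of the disease activity index
#'
#' Rubric: 0 for loss <= 2\%, 1 for 3-6\%, 2 for 7-12\%, 3 for > 12\%.
#' The bins are integer-labelled, so the percent loss is rounded to the
#' nearest integer before lookup; weight gains count as 0\% loss.
#'
#' @param percent_loss Percent body-weight loss from baseline,
#'   `100 * (baseline - current) / baseline`. Vectorized.
#' @return Integer subscore(s) in 0-3.
#' @export
weight_loss_subscore <- function(percent_loss) {
  if (any(!is.finite(percent_loss)))
    stop("`percent_loss` must be finite")
  p <- round(pmax(percent_loss, 0))
  unname(ifelse(p <= 2, 0L, ifelse(p <= 6, 1L, ifelse(p <= 12, 2L, 3L))))
}

#' Stool categories of the disease activity index
#' @return Named list of the consistency and color category orderings
#'   (score = position - 1).
#' @export
stool_categories <- function() {
  list(consistency = c("normal", "semi_solid", "loose_pasty", "diarrhea"),
       color = c("brown", "dark_brown", "black", "bloody"))
}

#' Stool component of the disease activity index
#'
#' Consistency rubric: normal 0, semi-solid 1, loose/pasty 2,
#' diarrhea 3. Color rubric: brown 0, dark brown 1, black 2, bloody 3.
#'
#' @param kind `"consistency"` or `"color"`.
#' @param category Observed category. Vectorized.
#' @return Integer subscore(s) in 0-3.
#' @export
stool_subscore <- function(kind = c("consistency", "color"), category) {
  kind <- match.arg(kind)
  levels <- stool_categories()[[kind]]
  idx <- match(as.character(category), levels)
  if (any(is.na(idx)))
    stop(sprintf("unknown stool %s category '%s' (valid: %s)",
                 kind, as.character(category)[which(is.na(idx))[1]],
                 paste(levels, collapse = ", ")))
  idx - 1L
}

#' Total disease activity index for one observation
#'
#' Sum of the weight-loss, stool-consistency and stool-color subscores
#' (0-9). The baseline is the animal's day-0 weight.
#'
#' @param body_weight Current body weight, g (> 0).
#' @param baseline_weight Day-0 body weight, g (> 0).
#' @param stool_consistency,stool_color Observed categories, see
#'   [stool_categories()].
#' @return A `dai_score`: list with the three subscores, `percent_loss`,
#'   and `total`.
#' @export
total_dai <- function(body_weight, baseline_weight, stool_consistency,
                      stool_color) {
  if (!is.finite(baseline_weight) || baseline_weight <= 0)
    stop("`baseline_weight` must be > 0 g")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("`body_weight` must be > 0 g")
  loss <- 100 * (baseline_weight - body_weight) / baseline_weight
  w <- weight_loss_subscore(loss)
  cns <- stool_subscore("consistency", stool_consistency)
  col <- stool_subscore("color", stool_color)
  structure(
    list(weight_subscore = w, consistency_subscore = cns,
         color_subscore = col, percent_loss = loss, total = w + cns + col),
    class = "dai_score"
  )
}

#' @export
print.dai_score <- function(x, ...) {
  cat(sprintf(
    "<dai_score> total %d (weight %d [%.1f%% loss], consistency %d, color %d)\n",
    x$total, x$weight_subscore, x$percent_loss, x$consistency_subscore,
    x$color_subscore))
  invisible(x)
}

#' Score a daily-observation table
#'
#' Applies [total_dai()] across a long table of daily observations,
#' taking each animal's day-0 weight as its baseline. Alongside the
#' same-day scores, per-animal peak scores are reported as a
#' convenience summary.
#'
#' @param obs Data.frame with columns `animal_id`, `day`,
#'   `body_weight_g`, `stool_consistency`, `stool_color`.
#' @return A list: `daily` (the input plus subscore/total columns) and
#'   `peak` (per animal: max total, the day it occurred, max percent
#'   loss).
#' @export
score_dai <- function(obs) {
  need <- c("animal_id", "day", "body_weight_g", "stool_consistency",
            "stool_color")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop(sprintf("observations lack column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  obs <- obs[order(obs$animal_id, obs$day), ]
  base <- obs[obs$day == 0, c("animal_id", "body_weight_g")]
  if (!nrow(base)) stop("no day-0 rows to define baseline weights")
  names(base)[2] <- "baseline_g"
  m <- merge(obs, base, by = "animal_id", all.x = TRUE, sort = FALSE)
  if (any(is.na(m$baseline_g)))
    stop(sprintf("animal(s) without a day-0 baseline: %s",
                 paste(unique(m$animal_id[is.na(m$baseline_g)]),
                       collapse = ", ")))
  loss <- 100 * (m$baseline_g - m$body_weight_g) / m$baseline_g
  m$percent_loss <- loss
  m$weight_subscore <- weight_loss_subscore(loss)
  m$consistency_subscore <- stool_subscore("consistency",
                                           m$stool_consistency)
  m$color_subscore <- stool_subscore("color", m$stool_color)
  m$dai_total <- m$weight_subscore + m$consistency_subscore +
    m$color_subscore
  m <- m[order(m$animal_id, m$day), ]
  rownames(m) <- NULL
  peak <- do.call(rbind, lapply(split(m, m$animal_id), function(d) {
    i <- which.max(d$dai_total)
    data.frame(animal_id = d$animal_id[1], peak_dai = d$dai_total[i],
               peak_day = d$day[i],
               peak_percent_loss = max(d$percent_loss),
               stringsAsFactors = FALSE)
  }))
  rownames(peak) <- NULL
  list(daily = m, peak = peak)
}

#' Colon morphometric disease indicators
#'
#' Colon shortening and weight gain accompany colitis; the
#' colon-weight/body-weight and colon-weight/colon-length ratios index
#' hypertrophy.
#'
#' @param colon_weight Colon weight, g (> 0).
#' @param body_weight Body weight, g (> 0).
#' @param length Colon length, cm (> 0).
#' @return A `colon_morphometrics`: list with `length`, `colon_weight`,
#'   `weight_to_body` (g/g), `weight_to_length` (g/cm).
#' @export
colon_morphometrics <- function(colon_weight, body_weight, length) {
  vals <- c(colon_weight = colon_weight, body_weight = body_weight,
            length = length)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad))
    stop(sprintf("non-positive input(s): %s",
                 paste(names(vals)[bad], collapse = ", ")))
  structure(
    list(length = length, colon_weight = colon_weight,
         weight_to_body = colon_weight / body_weight,
         weight_to_length = colon_weight / length),
    class = "colon_morphometrics"
  )
}

#' @export
print.colon_morphometrics <- function(x, ...) {
  cat(sprintf(
    "<colon_morphometrics> %.3g cm, %.3g g; weight/body = %.4g g/g, weight/length = %.4g g/cm\n",
    x$length, x$colon_weight, x$weight_to_body, x$weight_to_length))
  invisible(x)
}
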