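#' Kaplan-Meier median survival for one strain
#'
#' Product-limit median of the day of death, with censoring at the end of
#' the 10-day observation window. Animals euthanized at the body-weight-loss
#' endpoint are recorded as deaths, not censored. When the survival curve
#' never drops to 0.5 the median is undefined and `Inf` is returned
#' (reported downstream as ">=10").
#'
#' @param records `data.frame` with columns `strain`, `survival_day`
#'   (integer day 1..10) and `status` (1 = death, 0 = censored alive at
#'   `survival_day`).
#' @param strain strain id to evaluate.
#' @return median survival in days, or `Inf` when undefined.
#' @export
median_survival <- function(records, strain) {
  r <- records[records$strain == strain, , drop = FALSE]
  if (nrow(r) == 0L) stop("no animals recorded for strain ", strain)
  fit <- survival::survfit(survival::Surv(r$survival_day, r$status) ~ 1)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  if (is.na(med)) Inf else med
}

#' Fraction of a strain's animals surviving beyond a day
#'
#' Animals count as surviving day `d` if they died after `d` or were
#' censored alive (all censoring occurs at the end of follow-up).
#'
#' @inheritParams median_survival
#' @param day day to evaluate, 0..10.
#' @return fraction in `[0, 1]`.
#' @export
survival_rate <- function(records, strain, day) {
  stopifnot(day >= 0, day <= 10)
  r <- records[records$strain == strain, , drop = FALSE]
  if (nrow(r) == 0L) stop("no animals recorded for strain ", strain)
  mean(r$survival_day > day | r$status == 0)
}

#' Body-weight loss of a strain at a given day
#'
#' Per-animal loss is baseline weight (day -1) minus the weight on `day`,
#' reported as a positive magnitude when weight was lost (so a gain yields a
#' negative loss); percent is relative to each animal's baseline, making it
#' invariant to the weight unit. The strain value averages over animals with
#' a weight recorded on that day (animals already dead drop out).
#'
#' @param weights `data.frame` with columns `strain`, `animal_id`, `day`,
#'   `body_weight` (baseline rows have `day = -1`).
#' @param strain strain id.
#' @param day post-treatment day to evaluate.
#' @return list with `grams` (mean loss, weight units), `percent`
#'   (mean percent loss) and `n` animals contributing.
#' @export
bw_loss <- function(weights, strain, day) {
  w <- weights[weights$strain == strain, , drop = FALSE]
  if (nrow(w) == 0L) stop("no weights recorded for strain ", strain)
  base <- w[w$day == -1, c("animal_id", "body_weight")]
  cur <- w[w$day == day, c("animal_id", "body_weight")]
  m <- merge(cur, base, by = "animal_id", suffixes = c("", "_base"))
  skipped <- setdiff(cur$animal_id, m$animal_id)
  if (length(skipped))
    warning("no baseline weight for: ", paste(skipped, collapse = ", "))
  if (nrow(m) == 0L) stop("no animal has both baseline and day-", day,
                          " weights for strain ", strain)
  loss <- m$body_weight_base - m$body_weight
  list(grams = mean(loss),
       percent = mean(100 * loss / m$body_weight_base),
       n = nrow(m))
}

#' 2Z + 8 normalization
#'
#' Affine standardization to mean 8 and sample standard deviation 2,
#' the convention used for expression arrays to keep all values positive:
#' `2 * (x - mean(x)) / sd(x) + 8`. Idempotent on its own image and
#' invariant to affine transformation of the input.
#'
#' @param x numeric vector, length >= 2 with nonzero sample SD.
#' @return normalized vector (mean 8, sample SD 2).
#' @export
normalize_2z8 <- function(x) {
  if (length(x) < 2L) stop("need at least two values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero standard deviation: constant input")
  2 * (x - mean(x)) / s + 8
}

#' Paired baseline vs day-5 change in an echocardiographic trait
#'
#' Strain means of a trait at baseline (day -1) and day 5 after treatment,
#' with a paired two-sided t-test on the per-animal differences. The day-5
#' strain mean is the quantity used for genetic mapping.
#'
#' @param echo long `data.frame` with columns `strain`, `animal_id`, `day`
#'   (-1 or 5), `trait`, `value`.
#' @param strain strain id.
#' @param trait trait name (e.g. `"EF"`, `"LVVol_s"`).
#' @return list with `baseline_mean`, `day5_mean`, `mean_diff`, `p_value`
#'   (`NA` with `flag = "too_few_pairs"` below 2 pairs; `NA` with
#'   `flag = "zero_variance"` when all differences are identical and
#'   nonzero; exact 1 when all differences are zero) and `n_pairs`.
#' @export
echo_delta <- function(echo, strain, trait) {
  e <- echo[echo$strain == strain & echo$trait == trait, , drop = FALSE]
  base <- e[e$day == -1, c("animal_id", "value")]
  d5 <- e[e$day == 5, c("animal_id", "value")]
  m <- merge(base, d5, by = "animal_id", suffixes = c("_base", "_d5"))
  out <- list(baseline_mean = mean(base$value), day5_mean = mean(d5$value),
              mean_diff = NA_real_, p_value = NA_real_,
              n_pairs = nrow(m), flag = NA_character_)
  if (nrow(m) == 0L) stop("no paired measurements for ", strain, "/", trait)
  diffs <- m$value_d5 - m$value_base
  out$mean_diff <- mean(diffs)
  if (nrow(m) < 2L) {
    out$flag <- "too_few_pairs"
  } else if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) out$p_value <- 1 else out$flag <- "zero_variance"
  } else {
    out$p_value <- stats::t.test(m$value_d5, m$value_base,
                                 paired = TRUE)$p.value
  }
  out
}

#' Aggregate per-animal records to a strain trait table
#'
#' Unweighted mean per (strain, trait), sexes pooled — the convention for
#' mapping strain averages in an RI panel. Use `sex` to restrict.
#'
#' @param records `data.frame` with columns `strain`, `trait`, `value`, and
#'   optionally `sex`.
#' @param sex optional `"M"` or `"F"` filter.
#' @return `data.frame` of class `strain_trait_table`: `strain`, `trait`,
#'   `value`, `n_animals`.
#' @export
strain_trait_table <- function(records, sex = NULL) {
  if (!is.null(sex)) records <- records[records$sex == sex, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records to aggregate")
  agg <- stats::aggregate(value ~ strain + trait, data = records, FUN = mean)
  n <- stats::aggregate(value ~ strain + trait, data = records, FUN = length)
  out <- data.frame(strain = agg$strain, trait = agg$trait,
                    value = agg$value, n_animals = n$value,
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_trait_table", "data.frame")
  out
}

#' Extract one trait as a named vector keyed by strain
#'
#' @param traits a [strain_trait_table()].
#' @param trait trait name.
#' @return named numeric vector (names = strains).
#' @export
trait_vector <- function(traits, trait) {
  t0 <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(t0) == 0L) stop("trait not found: ", trait)
  stats::setNames(t0$value, t0$strain)
}
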