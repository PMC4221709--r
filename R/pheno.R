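#' Normality screening with conditional log2 transform
#'
#' Applies a Shapiro-Wilk test to the non-missing values and log2-transforms
#' the trait only when normality is strongly violated (p < `p_threshold`,
#' default 1e-8). The Shapiro-Wilk statistic is computed on at most 5000
#' values (an evenly spaced deterministic subset for larger vectors, the
#' test's supported range).
#'
#' @param values numeric trait vector (NA allowed).
#' @param p_threshold transform when Shapiro p falls below this.
#' @param offset optional constant added before log2 (e.g. 1 for
#'   zero-inflated traits); `NULL` (default) means non-positive values at
#'   transform time are an error.
#' @return list `(values, transformed, shapiro_p)`; `values` keeps the
#'   input's length and missingness pattern.
#' @export
normality_screen_and_transform <- function(values, p_threshold = 1e-8,
                                           offset = NULL) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3)
    stop("degenerate input: need at least 3 non-missing values", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate input: constant trait, normality test undefined",
         call. = FALSE)
  xs <- if (length(x) > 5000)
    x[round(seq(1, length(x), length.out = 5000))] else x
  p <- stats::shapiro.test(xs)$p.value
  if (p >= p_threshold)
    return(list(values = values, transformed = FALSE, shapiro_p = p))
  if (!is.null(offset)) x2 <- values + offset else x2 <- values
  npos <- sum(x2[ok] <= 0)
  if (npos > 0)
    stop(sprintf("transformation error: %d non-positive value(s) under log2",
                 npos), call. = FALSE)
  list(values = log2(x2), transformed = TRUE, shapiro_p = p)
}

#' Hue angle from Minolta colour coordinates
#'
#' H* = arctan(b*/a*), the meat-colour hue angle from yellowness (b*) and
#' redness (a*), reported in degrees.
#'
#' @param a_star Minolta a* (redness); must be non-zero.
#' @param b_star Minolta b* (yellowness).
#' @return hue angle in degrees, in (-90, 90).
#' @export
hue_angle <- function(a_star, b_star) {
  if (any(a_star == 0))
    stop("undefined input: a* must be non-zero", call. = FALSE)
  atan(b_star / a_star) * 180 / pi
}

#' Sex effect on a trait with batch adjustment
#'
#' Least-squares fit of trait ~ sex + batch; reports the male-minus-female
#' contrast, its standard error and two-sided p-value, raw per-sex means and
#' their fold ratio (male/female, untransformed scale).
#'
#' @param values numeric trait vector.
#' @param sex "M"/"F" labels.
#' @param batch batch labels; dropped with a warning if fewer than 2 levels.
#' @param raw_values optional untransformed values for the fold computation
#'   (defaults to `values`).
#' @return list of class `sex_effect`: `estimate`, `se`, `p`, `fold`,
#'   `mean_male`, `mean_female`, `n_male`, `n_female`, `degenerate`.
#' @export
sex_effect_model <- function(values, sex, batch, raw_values = values) {
  ok <- !is.na(values) & !is.na(sex) & !is.na(batch)
  values <- values[ok]; sex <- sex[ok]; batch <- batch[ok]
  raw_values <- raw_values[ok]
  if (length(unique(sex)) < 2)
    stop("identifiability error: both sexes must be represented", call. = FALSE)
  sexf <- factor(sex, levels = c("F", "M"))
  use_batch <- length(unique(batch)) >= 2
  if (!use_batch) warning("fewer than 2 batches; batch term dropped")
  df <- data.frame(y = values, sex = sexf, batch = factor(batch))
  res <- list(n_male = sum(sex == "M"), n_female = sum(sex == "F"),
              mean_male = mean(raw_values[sex == "M"]),
              mean_female = mean(raw_values[sex == "F"]))
  res$fold <- if (res$mean_female != 0) res$mean_male / res$mean_female else NA
  if (stats::sd(values) == 0) {
    res <- c(res, list(estimate = 0, se = NA_real_, p = NA_real_,
                       degenerate = TRUE))
    class(res) <- "sex_effect"
    return(res)
  }
  fml <- if (use_batch) y ~ sex + batch else y ~ sex
  fit <- stats::lm(fml, data = df)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("identifiability error: rank-deficient design (sex confounded with batch?)",
         call. = FALSE)
  sm <- summary(fit)$coefficients
  res <- c(res, list(estimate = sm["sexM", "Estimate"],
                     se = sm["sexM", "Std. Error"],
                     p = sm["sexM", "Pr(>|t|)"], degenerate = FALSE))
  class(res) <- "sex_effect"
  res
}

#' @export
print.sex_effect <- function(x, ...) {
  cat(sprintf("sex effect (M - F): %.4g +/- %.3g, p = %.3g, fold M/F = %.3g (n = %d M / %d F)\n",
              x$estimate, x$se, x$p, x$fold, x$n_male, x$n_female))
  invisible(x)
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up quantities scaled by an estimate of the null
#' proportion pi0 (fixed at 1 by default; `pi0 = "storey"` estimates it on
#' a lambda grid with a smoothing spline). Output preserves input order.
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0 1 (default, plain BH), a number in (0, 1], or `"storey"`.
#' @return q-values in [0, 1], same order as `p`.
#' @export
qvalues <- function(p, pi0 = 1) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  if (identical(pi0, "storey")) {
    lam <- seq(0.05, 0.90, by = 0.05)
    pl <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lam, pl, df = 3)
    pi0 <- min(1, max(stats::predict(sp, x = max(lam))$y, 1 / length(p)))
  }
  stopifnot(is.numeric(pi0), pi0 > 0, pi0 <= 1)
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Sex-dimorphism screen across a trait table
#'
#' Runs [normality_screen_and_transform()] then [sex_effect_model()] on each
#' trait column of a trait table and attaches [qvalues()] across traits.
#'
#' @param traits a trait table (`id`, `sex`, `batch`, trait columns).
#' @param p_threshold Shapiro threshold passed through.
#' @param pi0 passed to [qvalues()].
#' @return data.frame: trait, transformed, shapiro_p, estimate, se, p, q,
#'   fold, mean_male, mean_female, n_male, n_female.
#' @export
sex_effect_screen <- function(traits, p_threshold = 1e-8, pi0 = 1) {
  nm <- setdiff(names(traits), c("id", "sex", "batch"))
  rows <- lapply(nm, function(tn) {
    tv <- normality_screen_and_transform(traits[[tn]], p_threshold)
    se <- sex_effect_model(tv$values, traits$sex, traits$batch,
                           raw_values = traits[[tn]])
    data.frame(trait = tn, transformed = tv$transformed,
               shapiro_p = tv$shapiro_p, estimate = se$estimate, se = se$se,
               p = se$p, fold = se$fold, mean_male = se$mean_male,
               mean_female = se$mean_female, n_male = se$n_male,
               n_female = se$n_female, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- qvalues(out$p, pi0 = pi0)
  out[, c("trait", "transformed", "shapiro_p", "estimate", "se", "p", "q",
          "fold", "mean_male", "mean_female", "n_male", "n_female")]
}
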