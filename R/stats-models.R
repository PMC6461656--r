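#' @importFrom lme4 glmer lmer fixef VarCorr
NULL

waldP <- function(est, se) 2 * pnorm(-abs(est / se))

newModelFit <- function(kind, formulaText, coefs, omnibus = numeric(),
                        posthoc = emptyPosthoc(), fit = NULL) {
  new("ModelFit", modelKind = kind, formulaText = formulaText,
      coefficients = coefs, omnibus = omnibus, posthoc = posthoc, fit = fit)
}

emptyPosthoc <- function() {
  data.frame(contrast = character(), dpt = numeric(), estimate = numeric(),
             se = numeric(), p = numeric(), p_holm = numeric())
}

#' Poisson GLMM for longitudinal sprout counts
#'
#' Fits `count ~ dpt + (1 | animal)` with a log link by Laplace
#' approximation, then converts the slope to the count scale: with
#' marginal mean `mu(t) = exp(b0 + b1 t + s^2/2)` (s^2 the random-intercept
#' variance), the count-scale slope is the average derivative over the
#' observed range, `(mu(t_max) - mu(t_min)) / (t_max - t_min)`, with a
#' delta-method standard error over `(b0, b1)`.  A log-link coefficient
#' cannot itself be a per-day count increment; this conversion makes the
#' estimate comparable to a "sprouts per day" slope.
#'
#' @param data data.frame with columns `animal_id`, `dpt`, `count`.
#' @return a [ModelFit-class]; coefficient `count_slope` carries the
#'   count-scale slope.
#' @export
fitPoissonGlmm <- function(data) {
  stopIfNot(all(c("animal_id", "dpt", "count") %in% names(data)),
            "data needs animal_id, dpt, count")
  stopIfNot(all(data$count == round(data$count)), "counts must be integers")
  if (all(data$count == 0)) stop("degenerate fit: all counts are zero")
  stopIfNot(min(table(data$animal_id)) >= 2, "need >= 2 sessions per animal")
  if (var(data$count) > 0) {
    fit <- glmer(count ~ dpt + (1 | animal_id), data = data,
                 family = "poisson")
    b <- fixef(fit)
    V <- as.matrix(vcov(fit))
    s2 <- as.numeric(VarCorr(fit)$animal_id)
  } else {
    ## zero-variance response: the random intercept is unidentifiable and
    ## the PIRLS iterations can fail; the plain GLM is the same model with
    ## the intercept variance pinned at 0
    fit <- stats::glm(count ~ dpt, data = data, family = "poisson")
    b <- coef(fit)
    V <- as.matrix(stats::vcov(fit))
    s2 <- 0
  }
  t0 <- min(data$dpt); t1 <- max(data$dpt)
  mu <- function(t) exp(b[1] + b[2] * t + s2 / 2)
  slope <- (mu(t1) - mu(t0)) / (t1 - t0)
  grad <- c((mu(t1) - mu(t0)) / (t1 - t0),
            (t1 * mu(t1) - t0 * mu(t0)) / (t1 - t0))
  seSlope <- sqrt(drop(t(grad) %*% V %*% grad))
  seB <- sqrt(diag(V))
  coefs <- data.frame(
    term = c("log_intercept", "log_dpt", "count_slope"),
    estimate = c(unname(b), slope),
    se = c(seB, seSlope),
    p = c(waldP(b[1], seB[1]), waldP(b[2], seB[2]), waldP(b[2], seB[2])),
    stringsAsFactors = FALSE)
  newModelFit("poisson_glmm", "count ~ dpt + (1 | animal_id), family poisson",
              coefs, fit = fit)
}

#' Linear mixed model for mean sprout length
#'
#' Fits `mean_length ~ dpt + (1 | animal)`; sessions with no sprouts carry
#' a missing response and are dropped by the fit (unbalanced data are
#' expected).
#'
#' @param data data.frame with columns `animal_id`, `dpt`, `mean_length`.
#' @return a [ModelFit-class]; coefficient `dpt` is the µm/day slope.
#' @export
fitLmm <- function(data) {
  stopIfNot(all(c("animal_id", "dpt", "mean_length") %in% names(data)),
            "data needs animal_id, dpt, mean_length")
  data <- data[!is.na(data$mean_length), , drop = FALSE]
  if (length(unique(data$animal_id)) < 3)
    stop("refusing to fit: fewer than 3 animals with data")
  fit <- lmer(mean_length ~ dpt + (1 | animal_id), data = data, REML = TRUE)
  b <- fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  coefs <- data.frame(term = names(b), estimate = unname(b), se = se,
                      p = waldP(unname(b), se), stringsAsFactors = FALSE)
  newModelFit("lmm", "mean_length ~ dpt + (1 | animal_id)", coefs, fit = fit)
}

#' Mixed linear regression with treatment-by-time interaction
#'
#' Fits `value ~ group * dpt + (1 | animal)` (random intercept per animal)
#' and reports per-group time slopes, a Wald omnibus F over the
#' interaction (denominator df = n - p; no Satterthwaite machinery is
#' available), and Holm-corrected pairwise post-hoc t-tests between the
#' groups' predicted means at each observed session day.  With a single
#' group the model reduces to `value ~ dpt + (1 | animal)`.  Censored
#' delta-t rows must be excluded upstream (they carry `NA`).
#'
#' @param data data.frame with columns `animal_id`, `group`, `dpt`,
#'   `value`.
#' @param reference reference group level (default `"control"`).
#' @return a [ModelFit-class]; per-group slopes appear as
#'   `slope_<group>`.
#' @export
fitMlmrInteraction <- function(data, reference = "control") {
  stopIfNot(all(c("animal_id", "group", "dpt", "value") %in% names(data)),
            "data needs animal_id, group, dpt, value")
  data <- data[!is.na(data$value), , drop = FALSE]
  ## drop groups with < 2 animals
  byGroup <- tapply(data$animal_id, data$group, function(a) length(unique(a)))
  weak <- names(byGroup)[byGroup < 2]
  if (length(weak)) {
    warning("dropping group(s) with < 2 animals: ", paste(weak, collapse = ", "))
    data <- data[!data$group %in% weak, , drop = FALSE]
  }
  lv <- unique(data$group)
  lv <- c(intersect(reference, lv), setdiff(lv, reference))
  data$group <- factor(data$group, levels = lv)
  nG <- nlevels(data$group)
  if (nG == 1L) {
    fit <- lmer(value ~ dpt + (1 | animal_id), data = data, REML = TRUE)
    b <- fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    coefs <- data.frame(term = c("(Intercept)", paste0("slope_", lv)),
                        estimate = unname(b), se = se,
                        p = waldP(unname(b), se), stringsAsFactors = FALSE)
    return(newModelFit("mlmr_interaction", "value ~ dpt + (1 | animal_id)",
                       coefs, fit = fit))
  }
  fit <- lmer(value ~ group * dpt + (1 | animal_id), data = data, REML = FALSE)
  b <- fixef(fit)
  V <- as.matrix(vcov(fit))
  nm <- names(b)
  ## per-group slopes: reference slope plus its interaction adjustment
  slopeRows <- lapply(levels(data$group), function(g) {
    L <- as.numeric(nm == "dpt")
    if (g != levels(data$group)[1])
      L <- L + as.numeric(nm == paste0("group", g, ":dpt"))
    est <- drop(L %*% b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    data.frame(term = paste0("slope_", g), estimate = est, se = se,
               p = waldP(est, se), stringsAsFactors = FALSE)
  })
  coefs <- rbind(
    data.frame(term = nm, estimate = unname(b), se = sqrt(diag(V)),
               p = waldP(unname(b), sqrt(diag(V))), stringsAsFactors = FALSE),
    do.call(rbind, slopeRows))
  ## omnibus Wald F over the interaction block
  intIdx <- grep(":dpt$", nm)
  Lb <- b[intIdx]
  Vb <- V[intIdx, intIdx, drop = FALSE]
  Fstat <- drop(t(Lb) %*% solve(Vb) %*% Lb) / length(intIdx)
  df1 <- length(intIdx)
  df2 <- nrow(data) - length(b)
  omnibus <- c(F = Fstat, df1 = df1, df2 = df2,
               p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  ## post-hoc: pairwise group contrasts of predicted means at each dpt
  days <- sort(unique(data$dpt))
  pairs <- utils::combn(levels(data$group), 2, simplify = FALSE)
  ph <- do.call(rbind, lapply(days, function(d) {
    do.call(rbind, lapply(pairs, function(pr) {
      L <- groupMeanContrast(nm, levels(data$group), pr[1], d) -
        groupMeanContrast(nm, levels(data$group), pr[2], d)
      est <- drop(L %*% b)
      se <- sqrt(drop(t(L) %*% V %*% L))
      data.frame(contrast = paste(pr, collapse = " - "), dpt = d,
                 estimate = est, se = se, p = waldP(est, se),
                 stringsAsFactors = FALSE)
    }))
  }))
  ph$p_holm <- holmAdjust(ph$p)
  newModelFit("mlmr_interaction", "value ~ group * dpt + (1 | animal_id)",
              coefs, omnibus = omnibus, posthoc = ph, fit = fit)
}

groupMeanContrast <- function(nm, levels, g, d) {
  L <- as.numeric(nm == "(Intercept)") + d * as.numeric(nm == "dpt")
  if (g != levels[1])
    L <- L + as.numeric(nm == paste0("group", g)) +
      d * as.numeric(nm == paste0("group", g, ":dpt"))
  L
}

#' Through-origin mixed regression of perfused on total sprouts
#'
#' Fits `perfused ~ 0 + total + (1 | animal)`; the slope is the perfused
#' fraction.  Falls back to through-origin least squares when the mixed
#' fit is singular or fails (one observation per animal leaves the
#' random-intercept variance unidentified).
#'
#' @param data data.frame with columns `animal_id`, `perfused`, `total`.
#' @return a [ModelFit-class]; coefficient `total` is the fraction.
#' @export
fitPerfusedRatio <- function(data) {
  stopIfNot(all(c("animal_id", "perfused", "total") %in% names(data)),
            "data needs animal_id, perfused, total")
  stopIfNot(all(data$perfused <= data$total), "perfused cannot exceed total")
  if (all(data$total == 0)) stop("degenerate fit: all totals are zero")
  fit <- tryCatch(
    suppressMessages(lmer(perfused ~ 0 + total + (1 | animal_id),
                          data = data, REML = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    b <- fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
  } else {
    fit <- stats::lm(perfused ~ 0 + total, data = data)
    b <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  coefs <- data.frame(term = "total", estimate = unname(b), se = unname(se),
                      p = waldP(unname(b), unname(se)), stringsAsFactors = FALSE)
  newModelFit("through_origin_mixed", "perfused ~ 0 + total + (1 | animal_id)",
              coefs, fit = fit)
}
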